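# Habitat x locality effect decomposition, allele-frequency shift
# summaries, gene-region overlap, the cross-population gene-sharing
# resampling null, and hypergeometric overrepresentation.

#' Decompose habitat and locality effects on genotype dosage
#'
#' Per SNP, a two-way fixed-effects ANOVA of ALT dosage (0/1/2) on habitat,
#' locality and their interaction, with type-II sums of squares (robust to
#' the mildly unbalanced 10-16 per-site design). Effect sizes are partial
#' eta-squared, \eqn{SS_{term} / (SS_{term} + SS_{residual})}. A SNP whose
#' habitat effect exceeds its interaction effect shows consistent
#' urban-rural shifts across localities (\code{consistent} flag). SNPs
#' with an empty locality x habitat cell or constant dosage are skipped
#' and reported in the \code{skipped} attribute.
#'
#' @param panel a \linkS4class{HaplotypePanel}
#' @param samples sample table (every locality sampled in both habitats)
#' @param snpSubset site indices to analyse (default: all)
#' @return data.frame(chrom, pos, eta2_habitat, eta2_locality,
#'   eta2_interaction, p_habitat, p_locality, p_interaction, consistent).
#' @export
decomposeEffects <- function(panel, samples, snpSubset = NULL) {
  if (is.null(snpSubset)) snpSubset <- seq_len(nSites(panel))
  d <- dosageMatrix(panel)[samples$individual, snpSubset, drop = FALSE]
  hab <- factor(samples$habitat); loc <- factor(samples$locality)
  if (any(table(loc, hab) == 0))
    stop("every locality must be sampled in both habitats")
  res <- lapply(seq_along(snpSubset), function(j)
    .etaDecomposition(d[, j], hab, loc))
  skipped <- vapply(res, is.null, TRUE)
  out <- do.call(rbind, res[!skipped])
  out <- cbind(data.frame(chrom = chromOf(panel)[snpSubset][!skipped],
                          pos = posOf(panel)[snpSubset][!skipped]), out)
  attr(out, "skipped") <-
    data.frame(chrom = chromOf(panel)[snpSubset][skipped],
               pos = posOf(panel)[snpSubset][skipped])
  out
}

# type-II partial eta^2 for y ~ habitat + locality + habitat:locality;
# car::Anova does the sums of squares except for perfect fits (zero
# residual), where it refuses and the same type-II comparisons are formed
# directly from nested models (p-values are then undefined)
.etaDecomposition <- function(y, hab, loc) {
  if (var(y) == 0) return(NULL)
  fit <- lm(y ~ hab * loc)
  a2 <- tryCatch(car::Anova(fit, type = 2), error = function(e) NULL)
  if (is.null(a2)) {
    rss <- function(f) sum(lm(f)$residuals^2)
    full <- rss(y ~ hab * loc)
    both <- rss(y ~ hab + loc)
    ss <- c(rss(y ~ loc) - both, rss(y ~ hab) - both, both - full, full)
    a2 <- data.frame("Sum Sq" = ss, "Pr(>F)" = NA_real_,
                     check.names = FALSE,
                     row.names = c("hab", "loc", "hab:loc", "Residuals"))
  }
  ss <- a2[["Sum Sq"]]; pv <- a2[["Pr(>F)"]]
  rn <- rownames(a2)
  ssRes <- ss[rn == "Residuals"]
  pick <- function(term) {
    i <- match(term, rn)
    denom <- ss[i] + ssRes
    c(if (denom > 0) ss[i] / denom else 0, pv[i])
  }
  h <- pick("hab"); l <- pick("loc"); x <- pick("hab:loc")
  data.frame(eta2_habitat = h[1L], eta2_locality = l[1L],
             eta2_interaction = x[1L], p_habitat = h[2L],
             p_locality = l[2L], p_interaction = x[2L],
             consistent = h[1L] > x[1L])
}

#' Habitat/locality decomposition of principal-component axes
#'
#' PCA of the candidate-SNP dosage matrix (see \code{\link{genotypePca}}),
#' then the same habitat x locality ANOVA applied to each of the first
#' \code{nAxes} score vectors. Summarises whether coordinated
#' allele-frequency divergence along each axis is habitat-driven.
#'
#' @param panel,samples,snpSubset as in \code{\link{decomposeEffects}}
#' @param nAxes number of leading axes to decompose
#' @return data.frame(axis, pve, eta2_habitat, eta2_locality,
#'   eta2_interaction, p_habitat, p_locality, p_interaction, consistent).
#' @export
pcLevelDecomposition <- function(panel, samples, snpSubset = NULL,
                                 nAxes = 3) {
  pca <- genotypePca(panel, snpSubset)
  sc <- pca$scores[samples$individual, , drop = FALSE]
  rank <- sum(pca$pve > 1e-12)
  if (nAxes > rank) stop("nAxes exceeds available rank (", rank, ")")
  hab <- factor(samples$habitat); loc <- factor(samples$locality)
  out <- lapply(seq_len(nAxes), function(ax)
    cbind(data.frame(axis = ax, pve = pca$pve[ax]),
          .etaDecomposition(sc[, ax], hab, loc)))
  do.call(rbind, out)
}

#' Allele-frequency shift and minor-allele directionality summary
#'
#' Per SNP and locality, the absolute urban-rural ALT frequency difference
#' |dAF|; per SNP, the number of urban populations whose local minor
#' allele matches the global minor allele (pooled over all urban
#' populations; frequency ties at 0.5 resolve toward ALT), and the
#' direction concordance: the larger of the counts of localities where the
#' ALT allele is at higher, or lower, urban than rural frequency.
#'
#' @param panel a \linkS4class{HaplotypePanel}
#' @param samples sample table
#' @param snpSubset site indices (default all)
#' @return list with \code{deltaAf} (localities x SNPs matrix of |dAF|)
#'   and \code{perSnp} data.frame(chrom, pos, n_concordant_minor,
#'   n_direction, n_ties).
#' @export
shiftSummary <- function(panel, samples, snpSubset = NULL) {
  if (is.null(snpSubset)) snpSubset <- seq_len(nSites(panel))
  fr <- populationFrequencies(panel, samples)[, snpSubset, drop = FALSE]
  labs <- rownames(fr)
  locs <- unique(sub("\\.(urban|rural)$", "", labs))
  fu <- fr[paste0(locs, ".urban"), , drop = FALSE]
  frr <- fr[paste0(locs, ".rural"), , drop = FALSE]
  dAf <- abs(fu - frr)
  rownames(dAf) <- locs
  pooled <- colMeans(fu)
  globalMinor <- ifelse(pooled > 0.5, 0L, 1L)  # tie -> ALT is minor
  localMinor <- ifelse(fu > 0.5, 0L, 1L)
  nConc <- colSums(localMinor == rep(globalMinor, each = nrow(fu)))
  up <- colSums(fu > frr); down <- colSums(fu < frr)
  ties <- colSums(fu == frr)
  data.frame(chrom = chromOf(panel)[snpSubset],
             pos = posOf(panel)[snpSubset]) -> key
  list(deltaAf = dAf,
       perSnp = cbind(key, data.frame(
         n_concordant_minor = as.integer(nConc),
         n_direction = as.integer(pmax(up, down)),
         n_ties = as.integer(ties))))
}

#' Genes overlapping outlier windows/regions, per population
#'
#' A gene is flagged for a population iff its interval intersects any of
#' that population's significant outlier windows or merged regions by at
#' least 1 bp (half-open semantics: intervals that merely abut do not
#' overlap).
#'
#' @param regionsPerPop named list of \code{GRanges}, one per population
#' @param genes gene table from \code{\link{readGeneAnnotation}}
#' @return named list of character vectors of gene_ids.
#' @export
genesUnderSelection <- function(regionsPerPop, genes) {
  lapply(regionsPerPop, function(reg) {
    if (!length(reg)) return(character())
    hits <- GenomicRanges::findOverlaps(genes, reg, minoverlap = 1L,
                                        ignore.strand = TRUE)
    unique(S4Vectors::mcols(genes)$gene_id[S4Vectors::queryHits(hits)])
  })
}

#' Resampling null for cross-population gene sharing
#'
#' Observed: for each k = 2..P, the number of genes flagged in at least k
#' populations. Null: per replicate, each population draws (with
#' replacement) as many genes from the universe as it has flagged, the
#' draw is reduced to unique genes, and the >= k sharing counts recorded.
#' Summaries are the null mean, percentile 95% CI, and the add-one
#' Monte-Carlo p-value per k. Counts for exactly-k sharing are reported
#' alongside (the >= k reading is primary).
#'
#' @param geneSets named list of character vectors (flagged genes per
#'   population), each a subset of \code{universe}
#' @param universe character vector of all candidate genes
#' @param reps resampling replicates (the study-scale default is 100000;
#'   scale down for quick checks)
#' @param seed RNG seed
#' @param nDraws per-population number of with-replacement draws in the
#'   null (defaults to the observed set sizes; a self-coverage experiment
#'   passes the draw counts of its generating process instead)
#' @return data.frame(k, observed, observed_exact, null_mean, null_ci_low,
#'   null_ci_high, p).
#' @export
sharingNull <- function(geneSets, universe, reps = 1e5, seed = 1,
                        nDraws = NULL) {
  if (reps < 1) stop("reps must be >= 1")
  P <- length(geneSets)
  G <- length(universe)
  sizes <- if (is.null(nDraws)) lengths(geneSets) else rep_len(nDraws, P)
  if (any(lengths(geneSets) > G)) stop("gene set larger than universe")
  if (!all(unlist(geneSets) %in% universe))
    stop("gene sets must be subsets of the universe")
  ks <- 2:P
  member <- vapply(geneSets, function(s) universe %in% s,
                   logical(G))
  obsCount <- rowSums(member)
  observed <- vapply(ks, function(k) sum(obsCount >= k), 1L)
  observedExact <- vapply(ks, function(k) sum(obsCount == k), 1L)
  set.seed(seed)
  nullCounts <- matrix(0L, reps, length(ks))
  for (r in seq_len(reps)) {
    cnt <- integer(G)
    for (p in seq_len(P)) {
      drawn <- unique(sample.int(G, sizes[p], replace = TRUE))
      cnt[drawn] <- cnt[drawn] + 1L
    }
    tab <- tabulate(cnt, P)
    nullCounts[r, ] <- rev(cumsum(rev(tab)))[ks]
  }
  data.frame(
    k = ks, observed = observed, observed_exact = observedExact,
    null_mean = colMeans(nullCounts),
    null_ci_low = apply(nullCounts, 2, quantile, 0.025, names = FALSE),
    null_ci_high = apply(nullCounts, 2, quantile, 0.975, names = FALSE),
    p = vapply(seq_along(ks), function(i)
      (1 + sum(nullCounts[, i] >= observed[i])) / (reps + 1), 1.0))
}

#' Mantel tests of shared-outlier counts against distance
#'
#' The shared-count similarity matrix is negated into a distance and
#' tested against genetic and geographic distance matrices.
#'
#' @param sharedCounts symmetric matrix of per-pair shared counts
#' @param geneticDist,geoDist symmetric distance matrices (same order)
#' @param nPerm,seed passed to \code{\link{mantelTest}}
#' @return data.frame with rows \code{genetic} and \code{geographic}.
#' @export
sharedSetsVsDistance <- function(sharedCounts, geneticDist, geoDist,
                                 nPerm = 999, seed = 1) {
  d <- -as.matrix(sharedCounts)
  diag(d) <- 0
  rbind(cbind(against = "genetic",
              mantelTest(d, geneticDist, nPerm = nPerm, seed = seed)),
        cbind(against = "geographic",
              mantelTest(d, geoDist, nPerm = nPerm, seed = seed)))
}

#' Hypergeometric overrepresentation of annotation terms
#'
#' Per term, the upper-tail hypergeometric p-value for the overlap between
#' the gene set and the term's members within the universe;
#' Benjamini-Hochberg FDR across terms, significant at
#' \code{fdr}.
#'
#' @param geneset character vector, subset of \code{universe}
#' @param annotation data.frame(gene, term) membership map
#' @param universe character vector of background genes
#' @param fdr significance threshold on the adjusted p
#' @return data.frame(term, n_term, n_overlap, expected, p, q,
#'   significant), sorted by p.
#' @export
overrepresentation <- function(geneset, annotation, universe,
                               fdr = 0.05) {
  if (!length(geneset)) stop("empty gene set")
  if (!all(geneset %in% universe))
    stop("gene set must be a subset of the universe")
  ann <- annotation[annotation$gene %in% universe, , drop = FALSE]
  terms <- split(ann$gene, ann$term)
  terms <- terms[lengths(terms) >= 1]
  N <- length(universe); n <- length(geneset)
  res <- lapply(names(terms), function(tm) {
    m <- length(unique(terms[[tm]]))
    ov <- length(intersect(geneset, terms[[tm]]))
    data.frame(term = tm, n_term = m, n_overlap = ov,
               expected = n * m / N,
               p = phyper(ov - 1, m, N - m, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- p.adjust(out$p, "BH")
  out$significant <- out$q < fdr
  out[order(out$p), ]
}
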