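# Diversity, differentiation, pruning, ordination and distance-based
# population structure.

.popDosages <- function(panel, samples, population) {
  pop <- populationOf(samples)
  ids <- samples$individual[pop == population]
  if (!length(ids)) stop("empty population: ", population)
  dosageMatrix(panel)[ids, , drop = FALSE]
}

#' Expected heterozygosity of a population
#'
#' Mean over all SNPs (polymorphic and monomorphic) of \eqn{2 \hat p (1 -
#' \hat p)}, with \eqn{\hat p} the population ALT-allele frequency.
#'
#' @param panel a \linkS4class{HaplotypePanel}
#' @param samples sample table
#' @param population population label (\code{locality.habitat})
#' @return data.frame(population, He).
#' @export
expectedHeterozygosity <- function(panel, samples, population) {
  d <- .popDosages(panel, samples, population)
  if (nrow(d) < 2) stop("need >= 2 samples in population ", population)
  p <- colMeans(d) / 2
  data.frame(population = population, He = mean(2 * p * (1 - p)))
}

#' Weir-Cockerham FST between two populations
#'
#' Per-SNP Weir & Cockerham (1984) theta-hat from the a, b, c variance
#' components of genotype counts (two populations, random-mating form with
#' the observed-heterozygosity correction). SNPs monomorphic across both
#' populations have undefined theta and are excluded from the pair mean;
#' the pair mean clamps negative per-SNP estimates to zero first, matching
#' the convention of averaging after setting negatives to zero.
#'
#' @param panel a \linkS4class{HaplotypePanel}
#' @param samples sample table
#' @param popA,popB population labels
#' @return list with \code{perSnp} data.frame(chrom, pos, theta),
#'   \code{pairMean}, and \code{nUndefined}.
#' @export
wcFst <- function(panel, samples, popA, popB) {
  dA <- .popDosages(panel, samples, popA)
  dB <- .popDosages(panel, samples, popB)
  if (nrow(dA) < 2 || nrow(dB) < 2) stop("need >= 2 diploids per population")
  comp <- .wcComponents(dA, dB)
  theta <- comp$theta
  def <- !is.na(theta)
  list(perSnp = data.frame(chrom = chromOf(panel), pos = posOf(panel),
                           theta = theta),
       pairMean = if (any(def)) mean(pmax(theta[def], 0)) else NA_real_,
       nUndefined = sum(!def))
}

# vectorised WC84 a,b,c components for two populations of dosage matrices
.wcComponents <- function(dA, dB) {
  n1 <- nrow(dA); n2 <- nrow(dB); r <- 2
  p1 <- colMeans(dA) / 2; p2 <- colMeans(dB) / 2
  h1 <- colMeans(dA == 1L); h2 <- colMeans(dB == 1L)
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                              hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  theta <- ifelse(abs(denom) < .Machine$double.eps * 4, NA_real_,
                  a / denom)
  list(a = a, b = b, c = cc, theta = theta)
}

#' Permutation test for pairwise FST
#'
#' Individuals are permuted between the two populations (preserving sample
#' sizes); the statistic is the clamped pair-mean FST on a thinned SNP set
#' (the first SNP of every 50 kb bin, bins anchored at position 1 of each
#' chromosome). The p-value uses the add-one estimator
#' \eqn{p = (1 + \#\{perm \ge obs\}) / (n_{perm} + 1)}.
#'
#' @param panel,samples,popA,popB as in \code{\link{wcFst}}
#' @param nPerm number of permutations (>= 99)
#' @param seed RNG seed
#' @param thinBp thinning bin width in bp
#' @return list(observed, permP, nThinned).
#' @export
fstPermutationTest <- function(panel, samples, popA, popB, nPerm = 999,
                               seed = 1, thinBp = 5e4) {
  if (nPerm < 99) stop("nPerm must be >= 99")
  pop <- populationOf(samples)
  idsA <- samples$individual[pop == popA]
  idsB <- samples$individual[pop == popB]
  if (length(idsA) + length(idsB) < 4) stop("need >= 4 samples in total")
  bin <- paste0(chromOf(panel), ":",
                (posOf(panel) - 1L) %/% as.integer(thinBp))
  keep <- !duplicated(bin)
  d <- dosageMatrix(panel[keep, ])[c(idsA, idsB), , drop = FALSE]
  nA <- length(idsA)
  statOf <- function(rows) {
    th <- .wcComponents(d[rows[seq_len(nA)], , drop = FALSE],
                        d[rows[-seq_len(nA)], , drop = FALSE])$theta
    def <- !is.na(th)
    if (!any(def)) return(NA_real_)
    mean(pmax(th[def], 0))
  }
  obs <- statOf(seq_len(nrow(d)))
  set.seed(seed)
  perm <- vapply(seq_len(nPerm), function(i) statOf(sample.int(nrow(d))),
                 1.0)
  list(observed = obs,
       permP = (1 + sum(perm >= obs, na.rm = TRUE)) / (nPerm + 1),
       nThinned = sum(keep))
}

#' LD pruning by variance inflation factor
#'
#' Within sliding windows of \code{windowSnps} SNPs (advancing
#' \code{stepSnps}, per chromosome), the SNP with the highest VIF is
#' removed iteratively until all VIFs are below \code{vifThreshold}. VIFs
#' are the diagonal of the inverse dosage correlation matrix, with a small
#' ridge (1e-8) on the diagonal against singularity and a cap at 1e6 so
#' that perfectly collinear SNPs tie. Monomorphic SNPs carry no LD
#' information and are always retained. Deterministic (no RNG); near-ties
#' resolve to the lowest SNP index.
#'
#' @param panel a \linkS4class{HaplotypePanel}
#' @param windowSnps,stepSnps window size and step in SNPs
#' @param vifThreshold VIF threshold (plink-style \code{indep} semantics)
#' @return integer vector of retained site indices.
#' @export
ldPrune <- function(panel, windowSnps = 50, stepSnps = 5,
                    vifThreshold = 2) {
  d <- dosageMatrix(panel)
  removed <- rep(FALSE, nSites(panel))
  poly <- apply(d, 2, var) > 0
  for (cc in unique(chromOf(panel))) {
    cidx <- which(chromOf(panel) == cc)
    starts <- seq(1L, max(1L, length(cidx)), by = stepSnps)
    for (st in starts) {
      win <- cidx[st:min(st + windowSnps - 1L, length(cidx))]
      repeat {
        act <- win[!removed[win] & poly[win]]
        if (length(act) < 2L) break
        Cm <- cor(d[, act, drop = FALSE])
        Ci <- solve(Cm + diag(1e-8, nrow(Cm)))
        # capped so that perfectly collinear SNPs tie; near-ties (and
        # perfect collinearity) resolve to the lowest SNP index
        vif <- pmin(diag(Ci), 1e6)
        if (max(vif) < vifThreshold) break
        top <- which(vif >= max(vif) * (1 - 1e-9))[1L]
        removed[act[top]] <- TRUE
      }
      if (st + windowSnps - 1L >= length(cidx)) break
    }
  }
  which(!removed)
}

#' Genotype PCA on centred, scaled dosages
#'
#' Dosages are centred per SNP and scaled by \eqn{\sqrt{\hat p (1 - \hat
#' p)}}; zero-variance SNPs are dropped with a warning. Axis signs are
#' fixed by making the largest-magnitude loading of each axis positive.
#'
#' @param panel a \linkS4class{HaplotypePanel}
#' @param snpSubset optional site index vector
#' @return list(scores samples x axes, loadings, pve).
#' @export
genotypePca <- function(panel, snpSubset = NULL) {
  d <- dosageMatrix(panel)
  if (!is.null(snpSubset)) d <- d[, snpSubset, drop = FALSE]
  if (nrow(d) < 2 || ncol(d) < 1) stop("need >= 2 samples and >= 1 SNP")
  p <- colMeans(d) / 2
  keep <- apply(d, 2, var) > 0
  if (!all(keep)) warning(sum(!keep), " zero-variance SNPs dropped")
  if (!any(keep)) stop("no polymorphic SNPs for PCA")
  X <- scale(d[, keep, drop = FALSE], center = TRUE, scale = FALSE)
  X <- sweep(X, 2, sqrt(p[keep] * (1 - p[keep])), "/")
  sv <- svd(X)
  pos <- apply(sv$v, 2, function(v) sign(v[which.max(abs(v))]))
  scores <- sweep(sv$u %*% diag(sv$d, length(sv$d)), 2, pos, "*")
  rownames(scores) <- rownames(d)
  list(scores = scores,
       loadings = sweep(sv$v, 2, pos, "*"),
       pve = sv$d^2 / sum(sv$d^2))
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal upper triangles, with
#' significance from joint row/column permutations of the second matrix.
#' Two-sided by default (\eqn{|r_{perm}| \ge |r_{obs}|}); add-one p-value
#' estimator.
#'
#' @param distA,distB symmetric matrices with zero diagonals
#' @param nPerm permutation count
#' @param seed RNG seed
#' @param alternative "two.sided" or "greater"
#' @return data.frame(r, p, n_perm).
#' @export
mantelTest <- function(distA, distB, nPerm = 999, seed = 1,
                       alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  a <- as.matrix(distA); b <- as.matrix(distB)
  if (!isTRUE(all.equal(dim(a), dim(b))) || nrow(a) != ncol(a))
    stop("matrices must be square with matching dimensions")
  ut <- upper.tri(a)
  if (sd(a[ut]) == 0 || sd(b[ut]) == 0)
    stop("constant distance matrix; Mantel r undefined")
  robs <- cor(a[ut], b[ut])
  set.seed(seed)
  rperm <- vapply(seq_len(nPerm), function(i) {
    o <- sample.int(nrow(b))
    cor(a[ut], b[o, o][ut])
  }, 1.0)
  hits <- if (alternative == "two.sided") sum(abs(rperm) >= abs(robs))
          else sum(rperm >= robs)
  data.frame(r = robs, p = (1 + hits) / (nPerm + 1), n_perm = nPerm)
}

#' Great-circle distance matrix between sites (haversine, R = 6371 km)
#'
#' @param lon,lat decimal degrees, one value per site
#' @return symmetric matrix of distances in km.
#' @export
haversineMatrix <- function(lon, lat) {
  n <- length(lon)
  rad <- pi / 180
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dlat <- (lat[j] - lat[i]) * rad / 2
    dlon <- (lon[j] - lon[i]) * rad / 2
    h <- sin(dlat)^2 + cos(lat[i] * rad) * cos(lat[j] * rad) * sin(dlon)^2
    m[i, j] <- 2 * 6371 * asin(pmin(1, sqrt(h)))
  }
  m
}

#' Isolation by distance within each habitat
#'
#' Runs the Mantel test separately on the urban-only and the rural-only
#' sub-matrices of a pairwise FST matrix against great-circle geographic
#' distance (haversine km). Raw (non-linearised) FST is used.
#'
#' @param fstPairs symmetric matrix of pairwise FST across all populations,
#'   with \code{locality.habitat} dimnames
#' @param siteTable site table (see \code{\link{readSiteTable}})
#' @param nPerm,seed passed to \code{\link{mantelTest}}
#' @return data.frame with one row per habitat (r, p, n_perm).
#' @export
ibdByHabitat <- function(fstPairs, siteTable, nPerm = 999, seed = 1) {
  labs <- rownames(fstPairs)
  out <- lapply(c("urban", "rural"), function(hb) {
    sel <- labs[endsWith(labs, paste0(".", hb))]
    if (length(sel) < 4) stop("need >= 4 populations in habitat ", hb)
    st <- siteTable[match(sel, paste(siteTable$locality,
                                     siteTable$habitat, sep = ".")), ]
    geo <- haversineMatrix(st$longitude, st$latitude)
    res <- mantelTest(fstPairs[sel, sel], geo, nPerm = nPerm, seed = seed,
                      alternative = "greater")
    cbind(habitat = hb, res)
  })
  do.call(rbind, out)
}
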