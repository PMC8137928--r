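# Genotype-environment association: a deterministic latent-factor
# regression with genomic-control calibration (the LFMM-style analysis),
# a covariance-aware population-frequency association with a closed-form
# g-prior Bayes factor (the BayPass-style analysis), habitat-randomisation
# thresholds, and the core-SNP intersection.

#' Latent-factor genotype-environment association
#'
#' Per-SNP association of ALT dosage with an environmental value (here the
#' urbanisation score mapped from populations to individuals), correcting
#' for unobserved structure with K latent factors: the top-K left singular
#' vectors of the centred dosage matrix after projecting out the
#' environment. Each SNP is then fit by least squares on
#' \code{[env, factors]}; z-scores are calibrated by genomic control
#' (divide z^2 by lambda = median(z^2) / 0.4549) and converted to
#' chi-square(1) p-values with Benjamini-Hochberg q-values. SNPs with
#' q < fdr are flagged.
#'
#' @param panel a \linkS4class{HaplotypePanel}
#' @param env numeric per-individual environmental value (panel sample
#'   order); must vary
#' @param K number of latent factors (0 <= K < min(samples, SNPs))
#' @param fdr flag threshold on the q-value
#' @return data.frame(chrom, pos, z, p, q, significant_lfmm) with
#'   attributes \code{K} and \code{lambda}.
#' @export
latentFactorGea <- function(panel, env, K, fdr = 0.01) {
  d <- dosageMatrix(panel)
  n <- nrow(d)
  if (length(env) != n) stop("env must have one value per sample")
  if (sd(env) == 0) stop("env is constant")
  if (K < 0 || K >= min(n, ncol(d))) stop("K must be in [0, min(n, S))")
  D <- scale(d, center = TRUE, scale = FALSE)
  e <- env - mean(env)
  U <- NULL
  if (K > 0) {
    Dp <- D - e %*% (crossprod(e, D) / sum(e^2))
    U <- svd(Dp, nu = K, nv = 0)$u
  }
  X <- cbind(1, e, U)
  k <- ncol(X)
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, D)
  resid <- D - X %*% B
  sigma2 <- colSums(resid^2) / (n - k)
  se <- sqrt(XtXi[2L, 2L] * sigma2)
  z <- ifelse(se > 0, B[2L, ] / se, NA_real_)
  poly <- apply(d, 2, var) > 0          # monomorphic SNPs are untestable
  z[!poly] <- NA_real_
  lambda <- median(z[poly]^2, na.rm = TRUE) / qchisq(0.5, 1)
  if (!is.finite(lambda) || lambda <= 0) lambda <- 1
  z2 <- z^2 / lambda
  p <- pchisq(z2, 1, lower.tail = FALSE)
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- p.adjust(p[!is.na(p)], "BH")
  out <- data.frame(chrom = chromOf(panel), pos = posOf(panel),
                    z = sign(z) * sqrt(z2), p = p, q = q,
                    significant_lfmm = !is.na(q) & q < fdr)
  attr(out, "K") <- K
  attr(out, "lambda") <- lambda
  out
}

#' Habitat-randomisation significance threshold for GEA z-scores
#'
#' The population-level environment values are permuted across populations
#' \code{nRand} times (all individuals of a population move together), the
#' latent-factor association rerun each time, and the threshold taken as
#' the given percentile of the pooled null |z| distribution. SNPs whose
#' observed |z| exceeds the threshold are flagged.
#'
#' @param panel,env,K as in \code{\link{latentFactorGea}}
#' @param samples sample table defining the populations
#' @param nRand number of randomisations (>= 1)
#' @param percentile percentile of the pooled null |z| distribution
#' @param seed RNG seed
#' @return list(threshold, flags, observed) where \code{observed} is the
#'   unpermuted result table.
#' @export
randomisationThreshold <- function(panel, env, samples, K, nRand = 20,
                                   percentile = 95, seed = 1) {
  if (nRand < 1) stop("nRand must be >= 1")
  obs <- latentFactorGea(panel, env, K)
  pop <- populationOf(samples)
  upop <- unique(pop)
  popEnv <- vapply(upop, function(pp) env[match(TRUE, pop == pp)], 1.0)
  set.seed(seed)
  nullz <- lapply(seq_len(nRand), function(i) {
    permEnv <- setNames(popEnv[sample.int(length(upop))], upop)
    abs(latentFactorGea(panel, unname(permEnv[pop]), K)$z)
  })
  thr <- quantile(unlist(nullz), percentile / 100, type = 7, names = FALSE)
  list(threshold = thr, flags = abs(obs$z) > thr, observed = obs)
}

#' Covariance-aware population-frequency association (g-prior Bayes factor)
#'
#' Population ALT frequencies are regressed on the population environment
#' by generalised least squares with error covariance Omega-hat, the
#' covariance of standardised population allele frequencies estimated from
#' an LD-pruned SNP set (BayPass-style structure correction). Evidence for
#' the environmental coefficient comes from the closed-form Zellner
#' g-prior Bayes factor (unit information, g = number of populations),
#' reported in deciban (10 log10 BF); dB > \code{dbThreshold} is flagged.
#' A near-singular Omega-hat is regularised by flooring its eigenvalues at
#' 1e-6 of its trace.
#'
#' @param panel a \linkS4class{HaplotypePanel}
#' @param samples sample table
#' @param env named numeric, one environment value per population
#'   (\code{locality.habitat} names)
#' @param prunedSnps site indices used for Omega-hat (default: all sites)
#' @param dbThreshold significance threshold in deciban
#' @return data.frame(chrom, pos, bf_db, significant_cov) with the
#'   population covariance matrix in attribute \code{omega}.
#' @export
covarianceAssociation <- function(panel, samples, env, prunedSnps = NULL,
                                  dbThreshold = 20) {
  fr <- populationFrequencies(panel, samples)
  P <- nrow(fr)
  if (P < 3) stop("need >= 3 populations")
  env <- env[rownames(fr)]
  if (anyNA(env)) stop("env must be named by population (locality.habitat)")
  if (is.null(prunedSnps)) prunedSnps <- seq_len(nSites(panel))
  fp <- fr[, prunedSnps, drop = FALSE]
  pbar <- colMeans(fp)
  ok <- pbar > 0 & pbar < 1
  Xs <- sweep(fp[, ok, drop = FALSE], 2, pbar[ok]) /
    rep(sqrt(pbar[ok] * (1 - pbar[ok])), each = P)
  omega <- tcrossprod(Xs) / sum(ok)
  eg <- eigen(omega, symmetric = TRUE)
  floorv <- 1e-6 * sum(diag(omega))
  vals <- pmax(eg$values, floorv)
  W <- eg$vectors %*% diag(1 / sqrt(vals), P) %*% t(eg$vectors)
  X0 <- W %*% cbind(rep(1, P))
  X1 <- W %*% cbind(1, env)
  Y <- W %*% fr
  rss <- function(X, Y) {
    Q <- qr.Q(qr(X))
    colSums((Y - Q %*% crossprod(Q, Y))^2)
  }
  r0 <- rss(X0, Y); r1 <- rss(X1, Y)
  # frequency vectors with no variation across populations carry no
  # association information (and r0 ~ 0 makes R2 pure rounding noise)
  info <- apply(fr, 2, var) > 0
  R2 <- ifelse(info & r0 > .Machine$double.eps * 100, 1 - r1 / r0, 0)
  R2 <- pmin(pmax(R2, 0), 1)
  g <- P
  logBF <- ((P - 2) / 2) * log1p(g) -
    ((P - 1) / 2) * log1p(g * (1 - R2))
  db <- 10 * logBF / log(10)
  out <- data.frame(chrom = chromOf(panel), pos = posOf(panel),
                    bf_db = db, significant_cov = db > dbThreshold)
  attr(out, "omega") <- omega
  out
}

#' Core urbanisation SNPs: intersection of the two GEA analyses
#'
#' SNPs significant both in the latent-factor analysis (FDR flag) and in
#' the covariance-aware analysis (deciban flag). Enrichment of the overlap
#' relative to independence is tested with the hypergeometric upper tail
#' \eqn{P(X \ge observed)} and, optionally, a
#' resampling-without-replacement check (draw \code{|B|} SNPs from the
#' universe R times and count the overlap with A).
#'
#' @param lfmm result of \code{\link{latentFactorGea}}
#' @param cov result of \code{\link{covarianceAssociation}} on the same
#'   SNP universe
#' @param resampleReps replicates for the resampling check (0 = skip)
#' @param seed RNG seed for the resampling check
#' @return list(core, nCore, overlapExpected, overlapP, resampleP) where
#'   \code{core} is a data.frame of the intersecting SNPs.
#' @export
coreIntersection <- function(lfmm, cov, resampleReps = 0, seed = 1) {
  if (nrow(lfmm) != nrow(cov) || !all(lfmm$chrom == cov$chrom) ||
      !all(lfmm$pos == cov$pos))
    stop("results must be indexed on the same SNP universe")
  total <- nrow(lfmm)
  A <- which(lfmm$significant_lfmm)
  B <- which(cov$significant_cov)
  ov <- intersect(A, B)
  expd <- length(A) * length(B) / total
  pHyper <- phyper(length(ov) - 1, length(A), total - length(A),
                   length(B), lower.tail = FALSE)
  pRes <- NA_real_
  if (resampleReps > 0) {
    set.seed(seed)
    cnt <- vapply(seq_len(resampleReps), function(i)
      length(intersect(sample.int(total, length(B)), A)), 1L)
    pRes <- (1 + sum(cnt >= length(ov))) / (resampleReps + 1)
  }
  list(core = data.frame(chrom = lfmm$chrom[ov], pos = lfmm$pos[ov]),
       nCore = length(ov), overlapExpected = expd, overlapP = pHyper,
       resampleP = pRes)
}
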