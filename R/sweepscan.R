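# Haplotype-homozygosity selection statistics, computed from scratch on
# phased panels. The genome scans use a pairwise mismatch-tract
# representation: for every haplotype pair and every core SNP, the maximal
# interval containing the core over which the pair is identical. EHHS decay
# curves, their physical-distance integrals (iES) and segregating-sites-by-
# length means (nSL) all derive from those tracts; cross-population ratios
# (Rsb from iES, XP-nSL from nSL) are oriented so that positive values mean
# longer haplotype homozygosity in the urban population.

# per-chromosome tract table: H is sites x haplotypes (one chromosome)
.pairTracts <- function(H) {
  n <- ncol(H); S <- nrow(H)
  pr <- which(upper.tri(diag(n)), arr.ind = TRUE)
  npair <- nrow(pr)
  Lm <- matrix(0L, npair, S); Rm <- matrix(0L, npair, S)
  cov <- matrix(FALSE, npair, S)
  for (p in seq_len(npair)) {
    X <- H[, pr[p, 1L]] != H[, pr[p, 2L]]
    mm <- which(X)
    jle <- findInterval(seq_len(S), mm)
    Lm[p, ] <- c(0L, mm)[jle + 1L] + 1L
    Rm[p, ] <- c(mm, S + 1L)[jle + 1L] - 1L
    cov[p, ] <- !X
  }
  list(L = Lm, R = Rm, cover = cov, npair = npair)
}

# trapezoidal integral of one decay side; pos/val start at the core
# (val[1] == 1) and move outward; truncation at the cutoff, at gaps wider
# than maxGap, or at the chromosome end (end of the curve)
.iesSide <- function(pos, val, cutoff, maxGap) {
  k <- length(pos)
  if (k < 2L) return(0)
  w <- abs(diff(pos))
  stop1 <- which(val[-1L] < cutoff | w > maxGap)
  K <- if (length(stop1)) stop1[1L] - 1L else k - 1L
  if (K < 1L) return(0)
  sum(w[seq_len(K)] * (val[seq_len(K)] + val[seq_len(K) + 1L]) / 2)
}

#' EHH decay curve for one core allele
#'
#' Extended haplotype homozygosity: at each successive SNP outward from the
#' core, the fraction of pairs of core-allele-carrying haplotypes that are
#' identical over the whole interval from the core to that SNP. The curve
#' starts at 1 and is monotone non-increasing.
#'
#' @param panel a \linkS4class{HaplotypePanel} (one population)
#' @param coreIndex site index of the core SNP
#' @param coreAllele 0 (REF) or 1 (ALT)
#' @param direction "right" or "left"
#' @return data.frame(pos, ehh), first row the core itself.
#' @export
ehh <- function(panel, coreIndex, coreAllele,
                direction = c("right", "left")) {
  direction <- match.arg(direction)
  H <- hapMatrix(panel)
  cc <- chromOf(panel)[coreIndex]
  cidx <- which(chromOf(panel) == cc)
  carriers <- which(H[coreIndex, ] == coreAllele)
  if (length(carriers) < 2) stop("need >= 2 carriers of the core allele")
  pr <- which(upper.tri(diag(length(carriers))), arr.ind = TRUE)
  a <- carriers[pr[, 1L]]; b <- carriers[pr[, 2L]]
  walk <- if (direction == "right") cidx[cidx >= coreIndex]
          else rev(cidx[cidx <= coreIndex])
  eq <- rep(TRUE, nrow(pr))
  vals <- numeric(length(walk))
  for (k in seq_along(walk)) {
    eq <- eq & (H[walk[k], a] == H[walk[k], b])
    vals[k] <- mean(eq)
  }
  data.frame(pos = posOf(panel)[walk], ehh = vals)
}

#' Site-specific EHHS decay curve (Tang-normalised)
#'
#' EHHS over all haplotypes, unconditioned on the core allele: the
#' probability that two random haplotypes are identical over the interval
#' from the core to x and also identical at the core, normalised by its
#' value at the core so the curve starts at 1. A monomorphic core reduces
#' to plain unconditioned homozygosity; the result is then flagged via the
#' \code{monomorphicCore} attribute.
#'
#' @param panel a \linkS4class{HaplotypePanel} (one population)
#' @param coreIndex site index of the core SNP
#' @param direction "right" or "left"
#' @return data.frame(pos, ehhs), first row the core.
#' @export
ehhs <- function(panel, coreIndex, direction = c("right", "left")) {
  direction <- match.arg(direction)
  H <- hapMatrix(panel)
  if (ncol(H) < 2) stop("need >= 2 haplotypes")
  cc <- chromOf(panel)[coreIndex]
  cidx <- which(chromOf(panel) == cc)
  n <- ncol(H)
  pr <- which(upper.tri(diag(n)), arr.ind = TRUE)
  a <- pr[, 1L]; b <- pr[, 2L]
  eq <- H[coreIndex, a] == H[coreIndex, b]
  hCore <- mean(eq)
  walk <- if (direction == "right") cidx[cidx >= coreIndex]
          else rev(cidx[cidx <= coreIndex])
  vals <- numeric(length(walk))
  for (k in seq_along(walk)) {
    eq <- eq & (H[walk[k], a] == H[walk[k], b])
    vals[k] <- mean(eq) / hCore
  }
  out <- data.frame(pos = posOf(panel)[walk], ehhs = vals)
  attr(out, "monomorphicCore") <- hCore == 1
  out
}

#' Integrate an EHHS decay curve over physical distance
#'
#' Trapezoidal integral of left and right decay curves, truncated where
#' the curve drops below \code{cutoff}, at inter-SNP gaps wider than
#' \code{maxGap}, or at the chromosome end; the two side integrals are
#' summed.
#'
#' @param left,right decay curves as returned by \code{\link{ehhs}} (first
#'   row the core, value 1)
#' @param cutoff EHHS truncation level
#' @param maxGap maximum tolerated inter-SNP gap in bp
#' @return iES in bp (0 when both sides are empty beyond the core).
#' @export
integrateIes <- function(left, right, cutoff = 0.05, maxGap = 2e5) {
  .iesSide(right[[1L]], right[[2L]], cutoff, maxGap) +
    .iesSide(left[[1L]], left[[2L]], cutoff, maxGap)
}

#' Mean pairwise segregating-site lengths at a core SNP
#'
#' For each haplotype pair, L is the number of consecutive SNPs in the
#' maximal interval containing the core over which the pair is identical
#' (truncated as observed at chromosome edges); pairs differing at the core
#' contribute 0. Means are returned for the REF-carrier set, the
#' ALT-carrier set (the nSL split) and the whole population (the XP-nSL
#' ingredient).
#'
#' @param panel a \linkS4class{HaplotypePanel} (one population)
#' @param coreIndex site index of the core SNP
#' @return list(ref, alt, all) of mean pairwise lengths in SNP units
#'   (\code{NA} for a carrier set with fewer than 2 haplotypes).
#' @export
nslLengths <- function(panel, coreIndex) {
  H <- hapMatrix(panel)
  cc <- chromOf(panel)[coreIndex]
  cidx <- which(chromOf(panel) == cc)
  Hc <- H[cidx, , drop = FALSE]
  i <- match(coreIndex, cidx)
  tr <- .pairTracts(Hc)
  len <- (tr$R[, i] - tr$L[, i] + 1L) * tr$cover[, i]
  pr <- which(upper.tri(diag(ncol(H))), arr.ind = TRUE)
  carA <- which(Hc[i, ] == 1L); carR <- which(Hc[i, ] == 0L)
  meanSet <- function(set) {
    if (length(set) < 2) return(NA_real_)
    sel <- pr[, 1L] %in% set & pr[, 2L] %in% set
    mean(len[sel])
  }
  list(ref = meanSet(carR), alt = meanSet(carA), all = mean(len))
}

# full per-chromosome scans used by rsbScan / xpnslScan ----------------------

# iES for every core index in `use` (logical over chromosome sites)
.iesScan <- function(Hc, posC, use, cutoff, maxGap) {
  tr <- .pairTracts(Hc)
  S <- nrow(Hc)
  out <- rep(NA_real_, S)
  for (i in which(use)) {
    covi <- tr$cover[, i]
    m <- sum(covi)
    if (m == 0L) next
    rext <- sort.int(tr$R[covi, i])
    js <- i:rext[m]
    cntR <- m - findInterval(js - 1L, rext)
    iR <- .iesSide(posC[js], cntR / m, cutoff, maxGap)
    lext <- sort.int(tr$L[covi, i])
    js <- i:lext[1L]
    cntL <- findInterval(js, lext)
    iL <- .iesSide(posC[js], cntL / m, cutoff, maxGap)
    out[i] <- iR + iL
  }
  out
}

# whole-population mean pairwise segregating-site length per core
.slScan <- function(Hc) {
  tr <- .pairTracts(Hc)
  colSums((tr$R - tr$L + 1L) * tr$cover) / tr$npair
}

.checkSameMap <- function(pu, pr) {
  if (nSites(pu) != nSites(pr) || !all(chromOf(pu) == chromOf(pr)) ||
      !all(posOf(pu) == posOf(pr)))
    stop("urban and rural panels must share an identical site map")
}

# pooled-sample MAF: a fixed difference (urban 1 / rural 0) has pooled
# frequency 0.5 and must stay in the scan; only sites nearly monomorphic
# across the pooled sample are dropped
.mafUse <- function(pu, pr, mafMin) {
  nu <- ncol(hapMatrix(pu)); nr <- ncol(hapMatrix(pr))
  f <- (rowSums(hapMatrix(pu)) + rowSums(hapMatrix(pr))) / (nu + nr)
  pmin(f, 1 - f) >= mafMin
}

# shared scan skeleton: statFun(Hc, posC, use) -> per-site raw statistic
.crossPopScan <- function(panelUrban, panelRural, statFun, standardise,
                          mafMin) {
  .checkSameMap(panelUrban, panelRural)
  use <- .mafUse(panelUrban, panelRural, mafMin)
  S <- nSites(panelUrban)
  su <- rep(NA_real_, S); sr <- rep(NA_real_, S)
  for (cc in unique(chromOf(panelUrban))) {
    ci <- which(chromOf(panelUrban) == cc)
    posC <- posOf(panelUrban)[ci]
    su[ci] <- statFun(hapMatrix(panelUrban)[ci, , drop = FALSE], posC,
                      use[ci])
    sr[ci] <- statFun(hapMatrix(panelRural)[ci, , drop = FALSE], posC,
                      use[ci])
  }
  lnr <- ifelse(su > 0 & sr > 0, log(su / sr), NA_real_)
  lnr[!use] <- NA_real_
  z <- rep(NA_real_, S)
  for (cl in unique(siteClass(panelUrban))) {
    sel <- siteClass(panelUrban) == cl & !is.na(lnr)
    if (!any(sel)) next
    z[sel] <- standardise(lnr[sel])
  }
  list(statUrban = su, statRural = sr, lnRatio = lnr, z = z)
}

#' Rsb scan: standardised log-ratio of integrated EHHS
#'
#' Per SNP, \code{ln(iES_urban / iES_rural)}, oriented so positive values
#' mean haplotype homozygosity extends further in the urban population,
#' then standardised by subtracting the median and dividing by the SD --
#' separately for autosomes and the Z chromosome. SNPs with undefined iES
#' in either population (or below the MAF guard in both) are dropped
#' (\code{NA}). When the log-ratios are degenerate (zero SD, e.g. identical
#' panels) the standardised scores are set to 0.
#'
#' @param panelUrban,panelRural panels with identical site maps
#' @param cutoff,maxGap iES integration controls (see
#'   \code{\link{integrateIes}})
#' @param mafMin SNPs below this minor-allele frequency in both
#'   populations are excluded as cores
#' @param outlierAt standardised-score outlier threshold
#' @return data.frame(chrom, pos, ies_urban, ies_rural, ln_ratio, rsb,
#'   outlier).
#' @export
rsbScan <- function(panelUrban, panelRural, cutoff = 0.05, maxGap = 2e5,
                    mafMin = 0.05, outlierAt = 4) {
  res <- .crossPopScan(panelUrban, panelRural,
    function(Hc, posC, use) .iesScan(Hc, posC, use, cutoff, maxGap),
    function(v) if (sd(v) == 0) rep(0, length(v))
                else (v - median(v)) / sd(v),
    mafMin)
  data.frame(chrom = chromOf(panelUrban), pos = posOf(panelUrban),
             ies_urban = res$statUrban, ies_rural = res$statRural,
             ln_ratio = res$lnRatio, rsb = res$z,
             outlier = !is.na(res$z) & res$z >= outlierAt)
}

#' XP-nSL scan: cross-population segregating-sites-by-length statistic
#'
#' Per SNP, \code{ln(SL_urban / SL_rural)} of whole-population mean
#' pairwise segregating-site lengths (SNP units), standardised genome-wide
#' to mean 0 and unit SD, separately for autosomes and the Z chromosome.
#' Positive scores mean longer haplotype homozygosity in the urban
#' population (ongoing or recent sweeps).
#'
#' @param panelUrban,panelRural panels with identical site maps
#' @param mafMin MAF guard as in \code{\link{rsbScan}}
#' @param outlierAt standardised-score outlier threshold
#' @return data.frame(chrom, pos, sl_urban, sl_rural, ln_ratio, xpnsl,
#'   outlier).
#' @export
xpnslScan <- function(panelUrban, panelRural, mafMin = 0.05,
                      outlierAt = 2) {
  res <- .crossPopScan(panelUrban, panelRural,
    function(Hc, posC, use) .slScan(Hc),
    function(v) if (sd(v) == 0) rep(0, length(v))
                else (v - mean(v)) / sd(v),
    mafMin)
  data.frame(chrom = chromOf(panelUrban), pos = posOf(panelUrban),
             sl_urban = res$statUrban, sl_rural = res$statRural,
             ln_ratio = res$lnRatio, xpnsl = res$z,
             outlier = !is.na(res$z) & res$z > outlierAt)
}
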