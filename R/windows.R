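# Window construction, z-standardisation, dual-criterion outlier windows,
# region merging, and the recombination proxies (windowed LD, intronic GC).
#
# Interval conventions: windows and regions are GRanges (1-based closed
# internally, 0-based half-open when written); a 1-based SNP position p
# belongs to a half-open window [start, end) iff p - 1 is in it.

#' Build a sliding-window skeleton
#'
#' Windows start at 0, step, 2*step, ... while the start is inside the
#' chromosome; each window ends at \code{min(start + size, length)}.
#' \code{step == size} gives non-sliding tiles.
#'
#' @param chromLengths named numeric of chromosome lengths (bp)
#' @param size,step window size and step in bp (\code{size >= step > 0})
#' @param chromClass optional named autosome/Z classes (default autosome)
#' @return \code{GRanges} with mcols \code{chrom_class}.
#' @export
makeWindows <- function(chromLengths, size = 2e5, step = 5e4,
                        chromClass = NULL) {
  if (!(size >= step && step > 0)) stop("need size >= step > 0")
  out <- lapply(names(chromLengths), function(cc) {
    len <- chromLengths[[cc]]
    starts <- seq(0, len - 1, by = step)
    data.frame(chrom = cc, start = starts + 1,
               end = pmin(starts + size, len))
  })
  df <- do.call(rbind, out)
  gr <- GenomicRanges::GRanges(
    factor(df$chrom, levels = names(chromLengths)),
    IRanges::IRanges(df$start, df$end))
  cls <- setNames(rep("autosome", length(chromLengths)),
                  names(chromLengths))
  if (!is.null(chromClass))
    cls[names(chromClass)[names(chromClass) %in% names(cls)]] <-
      chromClass[names(chromClass) %in% names(cls)]
  S4Vectors::mcols(gr)$chrom_class <-
    unname(cls[as.character(GenomicRanges::seqnames(gr))])
  gr
}

#' Summarise a per-SNP statistic in windows
#'
#' Per window: the number of contained SNPs, the mean statistic, and the
#' proportion of contained SNPs above \code{snpThreshold} (SNP-level
#' outliers). Windows with fewer than \code{minSnps} SNPs are marked
#' ineligible; they never enter percentile computations. SNPs with missing
#' statistic values are ignored.
#'
#' @param snpStats data.frame(chrom, pos, stat), position-sorted within
#'   chromosome
#' @param windows window skeleton from \code{\link{makeWindows}}
#' @param snpThreshold SNP-level outlier threshold
#' @param minSnps eligibility floor on the per-window SNP count
#' @return \code{GRanges} with mcols n_snps, mean_stat,
#'   prop_outlier_snps, chrom_class, eligible.
#' @export
summariseInWindows <- function(snpStats, windows, snpThreshold,
                               minSnps = 10) {
  for (cc in unique(snpStats$chrom))
    if (is.unsorted(snpStats$pos[snpStats$chrom == cc], strictly = FALSE))
      stop("snpStats must be position-sorted within chromosome")
  ok <- !is.na(snpStats$stat)
  snps <- GenomicRanges::GRanges(snpStats$chrom[ok],
                                 IRanges::IRanges(snpStats$pos[ok],
                                                  width = 1L))
  hits <- GenomicRanges::findOverlaps(snps, windows)
  wi <- S4Vectors::subjectHits(hits)
  vals <- snpStats$stat[ok][S4Vectors::queryHits(hits)]
  n <- length(windows)
  cnt <- tabulate(wi, n)
  sm <- rep(0, n); sm[sort(unique(wi))] <-
    vapply(split(vals, wi), sum, 1.0)
  no <- rep(0, n); no[sort(unique(wi))] <-
    vapply(split(vals > snpThreshold, wi), sum, 1.0)
  out <- windows
  S4Vectors::mcols(out)$n_snps <- cnt
  S4Vectors::mcols(out)$mean_stat <- ifelse(cnt > 0, sm / cnt, NA_real_)
  S4Vectors::mcols(out)$prop_outlier_snps <-
    ifelse(cnt > 0, no / cnt, NA_real_)
  S4Vectors::mcols(out)$eligible <- cnt >= minSnps
  out
}

#' z-standardise values within chromosome classes
#'
#' \code{z = (v - mean) / sd} computed separately within each class, with
#' the population SD (denominator n). Used for the window-level ZFST.
#'
#' @param values numeric vector (NAs propagate)
#' @param chromClassOf character vector of classes, same length
#' @return numeric vector of z-values.
#' @export
zscoreByClass <- function(values, chromClassOf) {
  z <- rep(NA_real_, length(values))
  for (cl in unique(chromClassOf)) {
    sel <- chromClassOf == cl & !is.na(values)
    if (sum(sel) < 2) stop("need >= 2 values per class")
    v <- values[sel]
    s <- sqrt(mean((v - mean(v))^2))
    if (s == 0) stop("zero SD in class ", cl)
    z[sel] <- (v - mean(v)) / s
  }
  z
}

#' Dual-criterion outlier windows
#'
#' A window is an outlier iff its mean statistic is at or above the
#' \code{percentile}-th percentile of the genome-wide distribution AND its
#' proportion of SNP-level outliers is at or above the same percentile --
#' percentiles (type-7) computed within chromosome class over eligible
#' windows only. Degenerate classes (zero spread in the mean statistic)
#' yield no flags. Classes with fewer than 20 eligible windows trigger a
#' warning (unstable percentile).
#'
#' @param windowTable output of \code{\link{summariseInWindows}}
#' @param percentile percentile for both criteria
#' @return logical flags, one per window (FALSE for ineligible windows).
#' @export
dualCriterionOutliers <- function(windowTable, percentile = 95) {
  mc <- S4Vectors::mcols(windowTable)
  flags <- rep(FALSE, length(windowTable))
  for (cl in unique(mc$chrom_class)) {
    sel <- which(mc$chrom_class == cl & mc$eligible)
    if (!length(sel)) next
    if (length(sel) < 20)
      warning("fewer than 20 eligible windows in class ", cl,
              "; percentile unstable")
    m <- mc$mean_stat[sel]; pr <- mc$prop_outlier_snps[sel]
    if (sd(m) == 0) next
    thrM <- quantile(m, percentile / 100, type = 7, names = FALSE)
    thrP <- quantile(pr, percentile / 100, type = 7, names = FALSE)
    flags[sel] <- m >= thrM & pr >= thrP
  }
  flags
}

#' ZFST outlier windows (single-criterion variant)
#'
#' Flags windows whose z-transformed mean FST exceeds \code{threshold}
#' (z computed within chromosome class over eligible windows).
#'
#' @param windowTable output of \code{\link{summariseInWindows}} on FST
#' @param threshold ZFST threshold (4 = four SDs)
#' @return list(zfst, flags).
#' @export
zfstOutliers <- function(windowTable, threshold = 4) {
  mc <- S4Vectors::mcols(windowTable)
  v <- ifelse(mc$eligible, mc$mean_stat, NA_real_)
  z <- zscoreByClass(v, mc$chrom_class)
  list(zfst = z, flags = !is.na(z) & z > threshold)
}

#' Merge flagged windows into outlier regions
#'
#' Overlapping or nearby flagged windows are merged into one region when
#' the gap between them is at most \code{maxGap} bp; the region spans the
#' minimum start to the maximum end. Idempotent: merging the output again
#' changes nothing.
#'
#' @param flags logical flags from \code{\link{dualCriterionOutliers}}
#' @param windows the matching window skeleton
#' @param maxGap maximum merged gap in bp
#' @return \code{GRanges} of regions with mcols n_windows and peak_stat.
#' @export
mergeRegions <- function(flags, windows, maxGap = 2e5) {
  fw <- windows[flags]
  if (!length(fw)) return(GenomicRanges::GRanges())
  reg <- GenomicRanges::reduce(GenomicRanges::sort(fw),
                               min.gapwidth = maxGap + 1)
  hits <- GenomicRanges::findOverlaps(fw, reg)
  S4Vectors::mcols(reg)$n_windows <-
    tabulate(S4Vectors::subjectHits(hits), length(reg))
  pk <- vapply(split(S4Vectors::mcols(fw)$mean_stat[
    S4Vectors::queryHits(hits)], S4Vectors::subjectHits(hits)),
    function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE),
    1.0)
  S4Vectors::mcols(reg)$peak_stat <- NA_real_
  S4Vectors::mcols(reg)$peak_stat[as.integer(names(pk))] <- pk
  reg
}

#' Mean pairwise LD (r^2) in non-sliding windows
#'
#' r^2 is the squared Pearson correlation of dosages for all SNP pairs at
#' most \code{maxDistBp} apart within the same non-sliding window; pairs
#' involving a monomorphic SNP are skipped. The window value is the mean
#' over contributing pairs.
#'
#' @param panel a \linkS4class{HaplotypePanel} (one population)
#' @param windowBp non-sliding window size in bp
#' @param maxDistBp maximum pair distance in bp
#' @return data.frame(chrom, start, end, n_pairs, mean_r2) with 0-based
#'   half-open window coordinates.
#' @export
ldWindows <- function(panel, windowBp = 2e5, maxDistBp = 2e5) {
  d <- dosageMatrix(panel)
  chrom <- chromOf(panel); pos <- posOf(panel)
  out <- list()
  for (cc in unique(chrom)) {
    ci <- which(chrom == cc)
    win <- (pos[ci] - 1L) %/% as.integer(windowBp)
    for (w in unique(win)) {
      sel <- ci[win == w]
      v <- apply(d[, sel, drop = FALSE], 2, var)
      sel <- sel[v > 0]
      r2 <- NA_real_; np <- 0L
      if (length(sel) >= 2) {
        cm <- cor(d[, sel, drop = FALSE])^2
        dist <- abs(outer(pos[sel], pos[sel], "-"))
        use <- upper.tri(cm) & dist <= maxDistBp
        np <- sum(use)
        if (np > 0) r2 <- mean(cm[use])
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = cc, start = w * windowBp, end = (w + 1) * windowBp,
        n_pairs = np, mean_r2 = r2, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Mean intronic GC content in non-sliding windows
#'
#' Per-intron GC = (G + C) / (A + C + G + T), ignoring Ns; each intron is
#' assigned to the window containing its midpoint; the window value is the
#' unweighted mean over its introns.
#'
#' @param fasta path to the reference FASTA (or a loaded
#'   \code{DNAStringSet})
#' @param genes gene table from \code{\link{readGeneAnnotation}} (introns
#'   in mcols)
#' @param windowBp non-sliding window size in bp
#' @return data.frame(chrom, start, end, n_introns, mean_gc) with 0-based
#'   half-open window coordinates.
#' @export
intronicGcWindows <- function(fasta, genes, windowBp = 2e5) {
  seqs <- if (is.character(fasta)) Biostrings::readDNAStringSet(fasta)
          else fasta
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  introns <- unlist(S4Vectors::mcols(genes)$introns)
  if (!length(introns))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_introns = integer(),
                      mean_gc = numeric()))
  ic <- as.character(GenomicRanges::seqnames(introns))
  if (!all(ic %in% names(seqs)))
    stop("FASTA does not cover all annotated chromosomes")
  if (any(GenomicRanges::end(introns) >
            Biostrings::width(seqs)[match(ic, names(seqs))]))
    stop("intron beyond sequence end")
  sub <- Biostrings::subseq(seqs[ic], GenomicRanges::start(introns),
                            GenomicRanges::end(introns))
  fr <- Biostrings::letterFrequency(sub, c("A", "C", "G", "T"))
  gc <- (fr[, "G"] + fr[, "C"]) / rowSums(fr)
  mid <- floor((GenomicRanges::start(introns) - 1 +
                  GenomicRanges::end(introns) - 1) / 2)  # half-open midpoint
  win <- mid %/% windowBp
  key <- paste0(ic, ":", win)
  agg <- vapply(split(gc, key), mean, 1.0)
  cnt <- vapply(split(gc, key), length, 1L)
  parts <- strsplit(names(agg), ":", fixed = TRUE)
  df <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                   start = as.numeric(vapply(parts, `[`, "", 2L)) *
                     windowBp,
                   n_introns = cnt, mean_gc = unname(agg),
                   stringsAsFactors = FALSE)
  df$end <- df$start + windowBp
  df[order(df$chrom, df$start),
     c("chrom", "start", "end", "n_introns", "mean_gc")]
}

#' Pearson correlation between two window-level statistics
#'
#' Complete cases only; two-sided p from the t distribution.
#'
#' @param a,b matched numeric vectors of window values
#' @return data.frame(r, p, n).
#' @export
correlateWindows <- function(a, b) {
  ok <- complete.cases(a, b)
  if (sum(ok) < 3) stop("need >= 3 complete window pairs")
  ct <- cor.test(a[ok], b[ok], method = "pearson")
  data.frame(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
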