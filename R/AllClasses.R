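#' @import methods
#' @importFrom stats aggregate aov cor cor.test lm median pchisq phyper
#'   p.adjust qchisq quantile rbinom rnorm rpois runif sd setNames var
#'   model.matrix complete.cases pf pt
#' @importFrom utils head read.delim write.table
NULL

#' HaplotypePanel: phased biallelic haplotypes with site metadata
#'
#' Central container of the package: a sites x (2 * n samples) matrix of
#' phased allele codes (0 = REF, 1 = ALT) together with per-site chromosome,
#' 1-based physical position and alleles, and a per-chromosome class flag
#' (\code{"autosome"} or \code{"Z"}) used to standardise selection statistics
#' separately for autosomes and the sex chromosome.
#'
#' Columns \code{2*i - 1} and \code{2*i} of \code{haplotypes} are the two
#' phased haplotypes of sample \code{i}. Panels are strictly biallelic and
#' complete: missing calls are rejected at load time, never imputed.
#'
#' @slot sampleIds character vector of sample identifiers (VCF header order).
#' @slot chrom character vector, per-site chromosome label.
#' @slot pos integer vector, per-site 1-based position (bp), strictly
#'   increasing within each chromosome.
#' @slot refAllele,altAllele single-character alleles per site.
#' @slot haplotypes integer matrix of 0/1, sites x (2 * n samples).
#' @slot chromClass named character vector mapping each chromosome label to
#'   \code{"autosome"} or \code{"Z"}.
#'
#' @examples
#' p <- HaplotypePanel(sampleIds = c("a", "b"),
#'                     chrom = c("chr1", "chr1"), pos = c(100L, 200L),
#'                     refAllele = c("A", "C"), altAllele = c("G", "T"),
#'                     haplotypes = matrix(0L, 2, 4))
#' nSites(p)
#' @export
setClass("HaplotypePanel",
  representation(sampleIds = "character", chrom = "character",
                 pos = "integer", refAllele = "character",
                 altAllele = "character", haplotypes = "matrix",
                 chromClass = "character"))

setValidity("HaplotypePanel", function(object) {
  msg <- character()
  h <- object@haplotypes
  s <- length(object@pos)
  if (nrow(h) != s) msg <- c(msg, "haplotype rows must equal number of sites")
  if (length(object@chrom) != s || length(object@refAllele) != s ||
      length(object@altAllele) != s)
    msg <- c(msg, "per-site metadata lengths disagree")
  if (ncol(h) != 2L * length(object@sampleIds))
    msg <- c(msg, "haplotype columns must equal 2 x number of samples")
  if (s > 0 && !all(h == 0L | h == 1L))
    msg <- c(msg, "haplotype entries must all be 0 or 1")
  if (s > 0) {
    for (cc in unique(object@chrom)) {
      p <- object@pos[object@chrom == cc]
      if (any(diff(p) <= 0)) {
        msg <- c(msg, sprintf("positions not strictly increasing on %s", cc))
        break
      }
    }
  }
  if (length(object@chromClass) &&
      !all(object@chromClass %in% c("autosome", "Z")))
    msg <- c(msg, "chromClass values must be 'autosome' or 'Z'")
  if (s > 0 && !all(unique(object@chrom) %in% names(object@chromClass)))
    msg <- c(msg, "every chromosome needs a chromClass entry")
  if (length(msg)) msg else TRUE
})

#' Construct a HaplotypePanel
#'
#' @param sampleIds,chrom,pos,refAllele,altAllele,haplotypes see
#'   \linkS4class{HaplotypePanel}.
#' @param chromClass named character vector; chromosomes absent from it
#'   default to \code{"autosome"}.
#' @return A \linkS4class{HaplotypePanel}.
#' @export
HaplotypePanel <- function(sampleIds, chrom, pos, refAllele, altAllele,
                           haplotypes, chromClass = NULL) {
  chroms <- unique(as.character(chrom))
  cc <- setNames(rep("autosome", length(chroms)), chroms)
  if (!is.null(chromClass)) cc[names(chromClass)[names(chromClass) %in%
                                                 names(cc)]] <-
      chromClass[names(chromClass) %in% names(cc)]
  storage.mode(haplotypes) <- "integer"
  new("HaplotypePanel", sampleIds = as.character(sampleIds),
      chrom = as.character(chrom), pos = as.integer(pos),
      refAllele = as.character(refAllele), altAllele = as.character(altAllele),
      haplotypes = haplotypes, chromClass = cc)
}

#' @describeIn HaplotypePanel number of SNP sites
#' @param x,object a \code{HaplotypePanel}
#' @export
nSites <- function(x) length(x@pos)

#' @describeIn HaplotypePanel number of diploid samples
#' @export
nSamples <- function(x) length(x@sampleIds)

#' @describeIn HaplotypePanel sample identifiers
#' @export
sampleIds <- function(x) x@sampleIds

#' @describeIn HaplotypePanel per-site chromosome labels
#' @export
chromOf <- function(x) x@chrom

#' @describeIn HaplotypePanel per-site 1-based positions
#' @export
posOf <- function(x) x@pos

#' @describeIn HaplotypePanel sites x haplotypes 0/1 matrix
#' @export
hapMatrix <- function(x) x@haplotypes

#' @describeIn HaplotypePanel per-chromosome class (autosome/Z)
#' @export
chromClass <- function(x) x@chromClass

#' @describeIn HaplotypePanel per-site chromosome class (autosome/Z)
#' @export
siteClass <- function(x) unname(x@chromClass[x@chrom])

#' Genotype dosage matrix
#'
#' ALT-allele dosage (0/1/2) per sample, computed by summing the two phased
#' haplotypes of each sample.
#'
#' @param x a \linkS4class{HaplotypePanel}
#' @return integer matrix, samples x sites, with sample ids as rownames.
#' @export
dosageMatrix <- function(x) {
  h <- x@haplotypes
  n <- nSamples(x)
  d <- t(h[, seq(1L, 2L * n, 2L), drop = FALSE] +
           h[, seq(2L, 2L * n, 2L), drop = FALSE])
  rownames(d) <- x@sampleIds
  d
}

#' Subset a panel by sites and/or samples
#'
#' @param x a \linkS4class{HaplotypePanel}
#' @param i site index (logical or integer); must keep positions ordered
#' @param j sample index (logical, integer or character ids)
#' @param ... ignored
#' @param drop ignored
#' @export
setMethod("[", "HaplotypePanel", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nSites(x))
  if (missing(j)) j <- seq_len(nSamples(x))
  if (is.character(j)) j <- match(j, x@sampleIds)
  if (is.logical(j)) j <- which(j)
  hcols <- as.vector(rbind(2L * j - 1L, 2L * j))
  HaplotypePanel(x@sampleIds[j], x@chrom[i], x@pos[i], x@refAllele[i],
                 x@altAllele[i], x@haplotypes[i, hcols, drop = FALSE],
                 chromClass = x@chromClass)
})

setMethod("show", "HaplotypePanel", function(object) {
  cls <- table(factor(unname(object@chromClass[unique(object@chrom)]),
                      levels = c("autosome", "Z")))
  cat(sprintf(paste0("HaplotypePanel: %d sites x %d samples ",
                     "(%d haplotypes)\n  chromosomes: %d autosome, %d Z\n"),
              nSites(object), nSamples(object), ncol(object@haplotypes),
              cls[["autosome"]], cls[["Z"]]))
})

#' Per-population ALT allele frequencies
#'
#' @param panel a \linkS4class{HaplotypePanel}
#' @param samples a sample table (see \code{\link{sampleFrame}})
#' @return matrix populations x sites of ALT frequencies; rownames are
#'   \code{locality.habitat} population labels.
#' @export
populationFrequencies <- function(panel, samples) {
  d <- dosageMatrix(panel)
  pop <- populationOf(samples)
  groups <- split(match(samples$individual, rownames(d)), pop)
  out <- matrix(0, length(groups), nSites(panel),
                dimnames = list(names(groups), NULL))
  for (g in seq_along(groups))
    out[g, ] <- colMeans(d[groups[[g]], , drop = FALSE]) / 2
  out
}
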