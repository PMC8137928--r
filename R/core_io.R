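# Readers/writers and the coordinate/allele conventions used everywhere:
# SNP positions are 1-based inclusive; all intervals (genes, windows,
# regions) are GRanges internally (1-based closed) and 0-based half-open in
# BED-style input/output. Allele code 1 is always ALT.

#' Validate a sample metadata table
#'
#' A sample table has one row per diploid individual with columns
#' \code{individual}, \code{locality}, \code{habitat} (urban/rural) and
#' \code{sex} (M/F/unknown). A (locality, habitat) combination defines a
#' population; a locality present with both habitats forms an urban-rural
#' pair. Loaders warn (only) when a site has fewer than 10 or more than 16
#' individuals, the design range of the paired-deme study template.
#'
#' @param df data.frame with the four columns above.
#' @return the validated data.frame (character columns, invisibly checked).
#' @export
sampleFrame <- function(df) {
  need <- c("individual", "locality", "habitat", "sex")
  if (!all(need %in% names(df)))
    stop("sample table needs columns: ", paste(need, collapse = ", "))
  df <- df[need]
  df[] <- lapply(df, as.character)
  if (anyDuplicated(df$individual))
    stop("duplicated individual identifiers in sample table")
  if (!all(df$habitat %in% c("urban", "rural")))
    stop("habitat must be 'urban' or 'rural'")
  if (!all(df$sex %in% c("M", "F", "unknown")))
    stop("sex must be 'M', 'F' or 'unknown'")
  n <- table(paste(df$locality, df$habitat))
  bad <- n[n < 10 | n > 16]
  if (length(bad))
    warning("sites outside the 10-16 individuals design range: ",
            paste(names(bad), collapse = ", "))
  df
}

#' Population label (locality.habitat) per sample
#' @param samples a sample table
#' @return character vector of population labels
#' @export
populationOf <- function(samples) paste(samples$locality, samples$habitat,
                                        sep = ".")

#' Read TSV sidecars (samples, sites, chromosome classes)
#'
#' \code{readSampleTable} reads the per-individual metadata TSV;
#' \code{readSiteTable} the per-population coordinates TSV (site_id,
#' locality, habitat, longitude, latitude); \code{readChromTable} the
#' chromosome sidecar (chrom, class, length) that declares which chromosome
#' is the Z -- chromosome class is never guessed from names.
#'
#' @param path file path
#' @return a data.frame; for \code{readChromTable}, with a named
#'   \code{class} vector in attribute-free column form.
#' @export
readSampleTable <- function(path)
  sampleFrame(read.delim(path, stringsAsFactors = FALSE))

#' @rdname readSampleTable
#' @export
readSiteTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("site_id", "locality", "habitat", "longitude", "latitude")
  if (!all(need %in% names(df)))
    stop("site table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df[c("locality", "habitat")]))
    stop("site table must have one record per (locality, habitat)")
  df
}

#' @rdname readSampleTable
#' @export
readChromTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "class", "length")
  if (!all(need %in% names(df)))
    stop("chromosome table needs columns: ", paste(need, collapse = ", "))
  if (!all(df$class %in% c("autosome", "Z")))
    stop("chromosome class must be 'autosome' or 'Z'")
  df
}

#' Read a phased biallelic VCF into a HaplotypePanel
#'
#' Accepts VCFv4.x with phased GT fields only. Every record must be a
#' biallelic SNP and every call phased (\code{|} separator) and complete;
#' unphased, missing or non-SNP records abort with the offending record
#' named. Sample order is preserved from the VCF header.
#'
#' @param path VCF file (plain text or gzipped).
#' @param chromClass optional named vector (or chromosome sidecar
#'   data.frame from \code{\link{readChromTable}}) assigning
#'   autosome/Z classes; unlisted chromosomes are autosomes.
#' @return a \linkS4class{HaplotypePanel}.
#' @export
readPhasedVcf <- function(path, chromClass = NULL) {
  if (is.data.frame(chromClass))
    chromClass <- setNames(chromClass$class, chromClass$chrom)
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- v@fix
  gt <- v@gt
  if (nrow(fix) == 0L) {
    ids <- if (ncol(gt) > 1L) colnames(gt)[-1L] else character()
    if (!length(ids)) ids <- .vcfHeaderSamples(path)
    return(HaplotypePanel(ids, character(), integer(), character(),
                          character(),
                          matrix(integer(), 0L, 2L * length(ids)),
                          chromClass = chromClass))
  }
  ids <- colnames(gt)[-1L]
  rec <- paste0(fix[, "CHROM"], ":", fix[, "POS"])
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  bad <- which(nchar(ref) != 1L | is.na(alt) | nchar(alt) != 1L |
                 grepl(",", alt))
  if (length(bad))
    stop("multiallelic or non-SNP record at ", rec[bad[1L]])
  gtf <- vcfR::extract.gt(v, element = "GT")
  if (anyNA(gtf)) {
    i <- which(is.na(gtf), arr.ind = TRUE)[1L, ]
    stop("missing genotype call at ", rec[i[1L]], " sample ", ids[i[2L]])
  }
  ok <- matrix(grepl("^[01]\\|[01]$", gtf), nrow(gtf))
  if (!all(ok)) {
    i <- which(!ok, arr.ind = TRUE)[1L, ]
    stop("unphased or invalid genotype '", gtf[i[1L], i[2L]], "' at ",
         rec[i[1L]], " sample ", ids[i[2L]])
  }
  n <- length(ids)
  h <- matrix(0L, nrow(gtf), 2L * n)
  h[, seq(1L, 2L * n, 2L)] <- as.integer(substr(gtf, 1L, 1L))
  h[, seq(2L, 2L * n, 2L)] <- as.integer(substr(gtf, 3L, 3L))
  HaplotypePanel(ids, fix[, "CHROM"], as.integer(fix[, "POS"]), ref, alt, h,
                 chromClass = chromClass)
}

.vcfHeaderSamples <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  on.exit(close(con))
  for (ln in readLines(con, n = 2000L)) {
    if (startsWith(ln, "#CHROM")) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      return(if (length(f) > 9L) f[-(1:9)] else character())
    }
  }
  stop("no #CHROM header line found in ", path)
}

#' Write a HaplotypePanel as a phased VCFv4.2 file
#'
#' Plain-text, byte-stable output; round-trips losslessly through
#' \code{\link{readPhasedVcf}} (sites, samples, phase and alleles).
#'
#' @param panel a \linkS4class{HaplotypePanel}
#' @param path output file path
#' @return \code{path}, invisibly.
#' @export
writePhasedVcf <- function(panel, path) {
  n <- nSamples(panel)
  h <- hapMatrix(panel)
  a <- h[, seq(1L, 2L * n, 2L), drop = FALSE]
  b <- h[, seq(2L, 2L * n, 2L), drop = FALSE]
  gtm <- matrix(paste0(a, "|", b), nrow = nrow(h))
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sampleIds(panel)), collapse = "\t"))
  if (nSites(panel) > 0) {
    body <- paste(chromOf(panel), posOf(panel), ".", panel@refAllele,
                  panel@altAllele, ".", "PASS", ".", "GT",
                  apply(gtm, 1L, paste, collapse = "\t"), sep = "\t")
    if (n == 0L)  # degenerate: no samples
      body <- paste(chromOf(panel), posOf(panel), ".", panel@refAllele,
                    panel@altAllele, ".", "PASS", ".", "GT", sep = "\t")
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene annotation (GFF3 or BED) into a gene table
#'
#' Returns a \code{GRanges} of genes with metadata column \code{gene_id}
#' and, for GFF3 input, an \code{introns} column: a \code{GRangesList} of
#' intron intervals inferred as the gaps between consecutive exons of the
#' same transcript, unioned over transcripts of each gene. BED input yields
#' empty intron sets. Interval semantics follow the usual conventions
#' (GFF3 1-based closed, BED 0-based half-open); internally everything is a
#' 1-based closed \code{GRanges}.
#'
#' @param path GFF3 (\code{.gff/.gff3}) or BED file.
#' @return \code{GRanges} with mcols \code{gene_id} and \code{introns}.
#' @export
readGeneAnnotation <- function(path) {
  fmt <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed"
         else "gff3"
  gr <- rtracklayer::import(path, format = fmt)
  if (fmt == "bed") {
    ids <- if (!is.null(gr$name)) as.character(gr$name)
           else paste0("gene", seq_along(gr))
    out <- GenomicRanges::granges(gr)
    S4Vectors::mcols(out)$gene_id <- ids
    S4Vectors::mcols(out)$introns <-
      GenomicRanges::GRangesList(rep(list(GenomicRanges::GRanges()),
                                     length(out)))
    return(out)
  }
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  if (!length(genes)) stop("no gene features in ", path)
  gid <- as.character(genes$ID)
  tx <- gr[type %in% c("mRNA", "transcript")]
  ex <- gr[type == "exon"]
  txParent <- vapply(tx$Parent, function(p) as.character(p)[1L], "")
  exParent <- vapply(ex$Parent, function(p) as.character(p)[1L], "")
  introns <- vector("list", length(genes))
  for (g in seq_along(genes)) {
    txIds <- as.character(tx$ID)[txParent == gid[g]]
    if (!length(txIds)) txIds <- gid[g]  # exons hung directly off the gene
    acc <- GenomicRanges::GRanges()
    for (t in txIds) {
      exT <- ex[exParent == t]
      if (!length(exT)) next
      if (any(GenomicRanges::start(exT) < GenomicRanges::start(genes[g])) ||
          any(GenomicRanges::end(exT) > GenomicRanges::end(genes[g])))
        stop("exon outside parent gene span for gene ", gid[g])
      gaps <- GenomicRanges::setdiff(
        GenomicRanges::reduce(GenomicRanges::granges(genes[g]),
                              ignore.strand = TRUE),
        GenomicRanges::reduce(GenomicRanges::granges(exT),
                              ignore.strand = TRUE),
        ignore.strand = TRUE)
      # only internal gaps (between first and last exon) are introns
      gaps <- gaps[GenomicRanges::start(gaps) >
                     min(GenomicRanges::start(exT)) &
                   GenomicRanges::end(gaps) < max(GenomicRanges::end(exT))]
      acc <- GenomicRanges::union(acc, gaps, ignore.strand = TRUE)
    }
    introns[[g]] <- GenomicRanges::reduce(acc)
  }
  out <- GenomicRanges::granges(genes)
  S4Vectors::mcols(out)$gene_id <- gid
  S4Vectors::mcols(out)$introns <- GenomicRanges::GRangesList(introns)
  out
}

#' Interval coordinate converters
#'
#' \code{toHalfOpen} converts a 1-based closed \code{GRanges} to a
#' data.frame of 0-based half-open intervals (BED convention);
#' \code{fromHalfOpen} is its exact inverse. The two are inverse bijections
#' for any valid interval set.
#'
#' @param gr a \code{GRanges}
#' @param df data.frame with columns chrom, start, end (0-based half-open)
#' @return a data.frame (chrom, start, end) or a \code{GRanges}.
#' @export
toHalfOpen <- function(gr)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)

#' @rdname toHalfOpen
#' @export
fromHalfOpen <- function(df)
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end))

#' Write per-SNP statistics / regions to disk
#'
#' \code{writeSnpStats} writes a tab-delimited per-SNP statistic table with
#' a deterministic column order (chrom, pos, then remaining columns in
#' their table order), full precision (15 significant digits).
#' \code{writeRegions} writes intervals as BED (0-based half-open), sorted
#' by chromosome then start.
#'
#' @param table data.frame with at least chrom and pos columns
#' @param regions a \code{GRanges} (scores/names in mcols become BED cols)
#' @param path output path
#' @return \code{path}, invisibly.
#' @export
writeSnpStats <- function(table, path) {
  if (!all(c("chrom", "pos") %in% names(table)))
    stop("snp stat table needs chrom and pos columns")
  if (is.character(table$chrom) || is.factor(table$chrom)) {
    o <- order(as.character(table$chrom), table$pos)
  } else stop("unsortable chromosome naming")
  table <- table[o, c("chrom", "pos",
                      setdiff(names(table), c("chrom", "pos")))]
  num <- vapply(table, is.double, TRUE)
  table[num] <- lapply(table[num], function(x) signif(x, 15))
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSnpStats
#' @export
writeRegions <- function(regions, path) {
  df <- toHalfOpen(GenomicRanges::sort(regions))
  extra <- S4Vectors::mcols(regions)[GenomicRanges::order(regions), ,
                                     drop = FALSE]
  if (ncol(extra)) df <- cbind(df, as.data.frame(extra))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
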