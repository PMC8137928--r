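# End-to-end orchestration from one YAML config: simulate (or load) ->
# urbanisation score -> population structure -> GEA -> haplotype scans ->
# windows/regions -> gene sharing, with per-stage seeds derived from one
# global seed by a fixed counter scheme and a machine-readable manifest.

.knownKeys <- list(
  top = c("seed", "out_dir", "simulate", "urbanisation", "structure",
          "gea", "scan", "windows", "share"),
  simulate = c("n_localities", "n_anc", "n_rural", "n_urban",
               "founder_size", "t_burnin", "t_split", "t_urban", "m_rr",
               "m_ur", "mu", "rho", "chrom_lengths", "z_chrom",
               "n_sites_target", "n_sample", "sweeps", "polygenic",
               "optimum_shift", "omega", "condition_on_sweep"),
  urbanisation = c("concentration", "n_cells"),
  structure = c("n_perm", "vif_threshold", "window_snps", "step_snps"),
  gea = c("k", "fdr", "db_threshold", "n_rand"),
  scan = c("maf_min", "cutoff", "max_gap"),
  windows = c("size", "step", "percentile", "min_snps", "merge_gap",
              "zfst_threshold"),
  share = c("reps"))

.stageSeed <- function(seed, stage)
  (seed + 1000L * match(stage, c("simulate", "urbanisation", "structure",
                                 "gea", "scan", "windows", "share"))) %%
    .Machine$integer.max

#' Run the full analysis pipeline from a configuration
#'
#' Stages run in dependency order on a simulated paired-deme dataset:
#' simulation, urbanisation scoring, population structure (He, pairwise
#' FST, PCA on the VIF-pruned set), genotype-environment association
#' (latent-factor + covariance-aware + core intersection), Rsb and XP-nSL
#' scans per locality, window summaries with dual-criterion outliers and
#' merged regions, and the gene-sharing null. All tabular outputs are
#' written as TSV/BED under \code{outDir}; rerunning with the same config
#' and seed reproduces byte-identical files. Unknown config keys abort
#' before any stage runs.
#'
#' @param config path to a YAML file or an equivalent nested list. Every
#'   stage block carries the package defaults (200 kb/50 kb windows, FDR
#'   1\%, 20 dB, Rsb >= 4, XP-nSL > 2, 95th percentiles, 200 kb merge gap,
#'   100000 sharing replicates) and may override them.
#' @param outDir output directory (created if needed); overrides
#'   \code{out_dir} in the config.
#' @return the run manifest (named list, also written as
#'   \code{manifest.json}).
#' @export
runPipeline <- function(config, outDir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  .checkKeys(cfg, .knownKeys$top, "top level")
  for (blk in setdiff(names(cfg), c("seed", "out_dir")))
    .checkKeys(cfg[[blk]], .knownKeys[[blk]], blk)
  seed <- as.integer(cfg$seed %||% 1L)
  outDir <- outDir %||% cfg$out_dir %||% stop("no output directory given")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, stages = list())
  t0 <- Sys.time()
  note <- function(stage, files) {
    manifest$stages[[stage]] <<- list(
      seed = .stageSeed(seed, stage),
      outputs = as.list(tools::md5sum(file.path(outDir, files))),
      wall_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }
  g <- function(blk, key, dflt) cfg[[blk]][[key]] %||% dflt

  # --- simulate ------------------------------------------------------------
  sc <- cfg$simulate %||% list()
  lens <- unlist(sc$chrom_lengths %||%
                   list(chr1 = 4e6, chr2 = 4e6, chrZ = 3e6))
  mk <- function(df) if (is.null(df)) NULL else
    as.data.frame(do.call(rbind, lapply(df, as.data.frame)))
  scfg <- simConfig(
    nLocalities = sc$n_localities %||% 9, nAnc = sc$n_anc %||% 100,
    nRural = sc$n_rural %||% 100, nUrban = sc$n_urban %||% 100,
    founderSize = sc$founder_size %||% 20,
    tBurnin = sc$t_burnin %||% 50, tSplit = sc$t_split %||% 80,
    tUrban = sc$t_urban %||% 40, mRR = sc$m_rr %||% 0.02,
    mUR = sc$m_ur %||% 0.02, mu = sc$mu %||% 1e-6,
    rho = sc$rho %||% 1e-7, chromLengths = lens,
    zChrom = sc$z_chrom %||% grep("Z", names(lens), value = TRUE)[1],
    nSitesTarget = sc$n_sites_target %||% 1500,
    sweeps = mk(sc$sweeps), polygenic = mk(sc$polygenic),
    optimumShift = sc$optimum_shift %||% 1, omega = sc$omega %||% 2,
    nSample = sc$n_sample %||% 12,
    conditionOnSweep = isTRUE(sc$condition_on_sweep),
    seed = .stageSeed(seed, "simulate"))
  sim <- simulatePanel(scfg)
  panel <- sim$panel; samples <- sim$samples
  writePhasedVcf(panel, file.path(outDir, "panel.vcf"))
  write.table(samples, file.path(outDir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth, file.path(outDir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  note("simulate", c("panel.vcf", "samples.tsv", "truth.tsv"))

  # --- urbanisation score --------------------------------------------------
  pops <- sort(unique(populationOf(samples)))
  siteDf <- data.frame(site_id = pops, stringsAsFactors = FALSE)
  intensity <- ifelse(endsWith(pops, ".urban"), 0.8, 0.1)
  lc <- generateLandcover(siteDf, intensity,
                          seed = .stageSeed(seed, "urbanisation"),
                          nCells = g("urbanisation", "n_cells", 100),
                          concentration =
                            g("urbanisation", "concentration", 50))
  us <- scoreUrbanisation(lc)
  write.table(us$scores, file.path(outDir, "urbanisation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  note("urbanisation", "urbanisation.tsv")
  envPop <- setNames(us$scores$pc_urb, us$scores$site_id)

  # --- population structure ------------------------------------------------
  he <- do.call(rbind, lapply(pops, function(pp)
    expectedHeterozygosity(panel, samples, pp)))
  write.table(he, file.path(outDir, "heterozygosity.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  fstM <- matrix(0, length(pops), length(pops),
                 dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_len(i - 1L)) {
    fstM[i, j] <- fstM[j, i] <-
      wcFst(panel, samples, pops[i], pops[j])$pairMean
  }
  write.table(round(fstM, 6), file.path(outDir, "fst_matrix.tsv"),
              sep = "\t", quote = FALSE)
  pruned <- ldPrune(panel, g("structure", "window_snps", 50),
                    g("structure", "step_snps", 5),
                    g("structure", "vif_threshold", 2))
  pca <- genotypePca(panel, pruned)
  write.table(data.frame(individual = rownames(pca$scores),
                         round(pca$scores[, 1:2], 6)),
              file.path(outDir, "pca_scores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  note("structure", c("heterozygosity.tsv", "fst_matrix.tsv",
                      "pca_scores.tsv"))

  # --- GEA -----------------------------------------------------------------
  env <- unname(envPop[populationOf(samples)])
  env <- env[match(sampleIds(panel), samples$individual)]
  K <- g("gea", "k", 2)
  lf <- latentFactorGea(panel, env, K, fdr = g("gea", "fdr", 0.01))
  cv <- covarianceAssociation(panel, samples, envPop, pruned,
                              dbThreshold = g("gea", "db_threshold", 20))
  core <- coreIntersection(lf, cv)
  gea <- data.frame(lf[c("chrom", "pos", "z", "p", "q",
                         "significant_lfmm")],
                    bf_db = cv$bf_db, significant_cov = cv$significant_cov)
  writeSnpStats(gea, file.path(outDir, "gea.tsv"))
  writeSnpStats(if (nrow(core$core)) core$core else
                  data.frame(chrom = character(), pos = integer()),
                file.path(outDir, "core_snps.tsv"))
  note("gea", c("gea.tsv", "core_snps.tsv"))

  # --- haplotype scans + windows + regions per locality --------------------
  locs <- unique(samples$locality)
  wins <- makeWindows(lens, g("windows", "size", 2e5),
                      g("windows", "step", 5e4),
                      chromClass = chromClass(panel))
  regionsPerPop <- list()
  scanFiles <- character()
  for (lc1 in locs) {
    pu <- panel[, samples$individual[samples$locality == lc1 &
                                       samples$habitat == "urban"]]
    pr <- panel[, samples$individual[samples$locality == lc1 &
                                       samples$habitat == "rural"]]
    rsb <- rsbScan(pu, pr, cutoff = g("scan", "cutoff", 0.05),
                   maxGap = g("scan", "max_gap", 2e5),
                   mafMin = g("scan", "maf_min", 0.05))
    xp <- xpnslScan(pu, pr, mafMin = g("scan", "maf_min", 0.05))
    scan <- data.frame(rsb[c("chrom", "pos", "ies_urban", "ies_rural",
                             "rsb")], xpnsl = xp$xpnsl)
    f <- sprintf("scan_%s.tsv", lc1)
    writeSnpStats(scan, file.path(outDir, f))
    scanFiles <- c(scanFiles, f)
    wt <- summariseInWindows(
      data.frame(chrom = xp$chrom, pos = xp$pos, stat = xp$xpnsl),
      wins, snpThreshold = 2, minSnps = g("windows", "min_snps", 10))
    flags <- dualCriterionOutliers(wt, g("windows", "percentile", 95))
    reg <- mergeRegions(flags, wt, g("windows", "merge_gap", 2e5))
    regionsPerPop[[paste0(lc1, ".urban")]] <- reg
    f <- sprintf("regions_%s.bed", lc1)
    writeRegions(reg, file.path(outDir, f))
    scanFiles <- c(scanFiles, f)
  }
  note("scan", scanFiles)
  note("windows", scanFiles[grepl("^regions_", scanFiles)])

  # --- gene sharing --------------------------------------------------------
  universe <- sprintf("gene%04d", seq_len(300))
  genes <- .syntheticGeneModels(lens, universe)
  sets <- genesUnderSelection(regionsPerPop, genes)
  flagged <- unlist(lapply(names(sets), function(nm)
    if (length(sets[[nm]])) paste(nm, sets[[nm]], sep = "\t")))
  writeLines(c("population\tgene_id", flagged %||% character()),
             file.path(outDir, "gene_sets.tsv"))
  sn <- sharingNull(sets, universe, reps = g("share", "reps", 2000),
                    seed = .stageSeed(seed, "share"))
  write.table(sn, file.path(outDir, "sharing_null.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  note("share", c("gene_sets.tsv", "sharing_null.tsv"))

  manifest$wall_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  json <- jsonlite::toJSON(manifest[c("seed", "stages")],
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(json, file.path(outDir, "manifest.json"))
  invisible(manifest)
}

# evenly spaced synthetic gene models used by the pipeline demo
.syntheticGeneModels <- function(chromLengths, ids) {
  per <- ceiling(length(ids) / length(chromLengths))
  df <- do.call(rbind, lapply(names(chromLengths), function(cc) {
    starts <- round(seq(1, chromLengths[[cc]] - 20000, length.out = per))
    data.frame(chrom = cc, start = starts)
  }))
  gr <- GenomicRanges::GRanges(
    factor(df$chrom, levels = names(chromLengths)),
    IRanges::IRanges(df$start, df$start + 14999))
  gr <- gr[seq_along(ids)]
  S4Vectors::mcols(gr)$gene_id <- ids
  gr
}

.checkKeys <- function(block, known, where) {
  if (is.null(block)) return(invisible())
  bad <- setdiff(names(block), known)
  if (length(bad))
    stop("unknown config key(s) in ", where, ": ",
         paste(bad, collapse = ", "))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
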