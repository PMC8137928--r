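# builds a panel with explicit per-cell dosages: cells[[locality]][[habitat]]
# is a vector of dosages for one SNP per individual
cellPanel <- function(cells) {
  ids <- character(); loc <- character(); hab <- character()
  dos <- integer()
  for (l in names(cells)) for (h in names(cells[[l]])) {
    v <- cells[[l]][[h]]
    ids <- c(ids, sprintf("%s_%s_%02d", l, substr(h, 1, 3), seq_along(v)))
    loc <- c(loc, rep(l, length(v))); hab <- c(hab, rep(h, length(v)))
    dos <- c(dos, v)
  }
  hapA <- pmin(dos, 1L); hapB <- dos - hapA
  hap <- matrix(0L, 1, 2 * length(dos))
  hap[1, seq(1, ncol(hap), 2)] <- hapA
  hap[1, seq(2, ncol(hap), 2)] <- hapB
  panel <- toyPanel(hap)
  panel@sampleIds <- ids
  samples <- suppressWarnings(sampleFrame(data.frame(
    individual = ids, locality = loc, habitat = hab, sex = "unknown",
    stringsAsFactors = FALSE)))
  list(panel = panel, samples = samples)
}

test_that("the 8-genotype ANOVA fixture gives eta2 = (0.5, 0, 0)", {
  fx <- cellPanel(list(
    L1 = list(rural = c(0L, 1L), urban = c(1L, 2L)),
    L2 = list(rural = c(0L, 1L), urban = c(1L, 2L))))
  res <- decomposeEffects(fx$panel, fx$samples)
  expect_equal(res$eta2_habitat, 0.5, tolerance = 1e-12)
  expect_equal(res$eta2_locality, 0, tolerance = 1e-12)
  expect_equal(res$eta2_interaction, 0, tolerance = 1e-12)
  expect_true(res$consistent)
})

test_that("opposite urban shifts in two localities load the interaction", {
  fx <- cellPanel(list(
    L1 = list(rural = c(1L, 1L, 1L), urban = c(2L, 2L, 2L)),
    L2 = list(rural = c(1L, 1L, 1L), urban = c(0L, 0L, 0L))))
  res <- decomposeEffects(fx$panel, fx$samples)
  expect_gt(res$eta2_interaction, res$eta2_habitat)
  expect_false(res$consistent)
})

test_that("partial eta2 matches the model-comparison oracle on random
           unbalanced data", {
  set.seed(31)
  for (r in 1:25) {
    cells <- list(
      L1 = list(rural = sample(0:2, sample(4:7, 1), TRUE),
                urban = sample(0:2, sample(4:7, 1), TRUE)),
      L2 = list(rural = sample(0:2, sample(4:7, 1), TRUE),
                urban = sample(0:2, sample(4:7, 1), TRUE)),
      L3 = list(rural = sample(0:2, sample(4:7, 1), TRUE),
                urban = sample(0:2, sample(4:7, 1), TRUE)))
    fx <- cellPanel(cells)
    res <- decomposeEffects(fx$panel, fx$samples)
    if (!nrow(res)) next  # constant dosage draw
    y <- dosageMatrix(fx$panel)[fx$samples$individual, 1]
    want <- eta2Oracle(y, factor(fx$samples$habitat),
                       factor(fx$samples$locality))
    expect_equal(res$eta2_habitat, unname(want["habitat"]),
                 tolerance = 1e-8)
    expect_equal(res$eta2_locality, unname(want["locality"]),
                 tolerance = 1e-8)
    expect_equal(res$eta2_interaction, unname(want["interaction"]),
                 tolerance = 1e-8)
  }
})

test_that("constant dosages are skipped and sample order is irrelevant", {
  fx <- cellPanel(list(
    L1 = list(rural = c(1L, 1L), urban = c(1L, 1L)),
    L2 = list(rural = c(1L, 1L), urban = c(1L, 1L))))
  res <- decomposeEffects(fx$panel, fx$samples)
  expect_equal(nrow(res), 0)
  expect_equal(nrow(attr(res, "skipped")), 1)
  fx2 <- cellPanel(list(
    L1 = list(rural = c(0L, 1L, 2L), urban = c(1L, 2L, 2L)),
    L2 = list(rural = c(0L, 0L, 1L), urban = c(2L, 1L, 2L))))
  r1 <- decomposeEffects(fx2$panel, fx2$samples)
  shuffled <- fx2$samples[sample(nrow(fx2$samples)), ]
  r2 <- decomposeEffects(fx2$panel, shuffled)
  expect_equal(r1$eta2_habitat, r2$eta2_habitat, tolerance = 1e-12)
})

test_that("PC-level decomposition finds a habitat-driven axis for a
           uniform urban shift", {
  set.seed(33)
  L <- 4
  labs <- c(paste0("L", 1:L, ".urban"), paste0("L", 1:L, ".rural"))
  f <- matrix(runif(8 * 60, 0.2, 0.6), 8, 60, dimnames = list(labs, NULL))
  f[1:L, ] <- f[1:L, ] + 0.3  # uniform urban shift on every SNP
  sim <- simulateFrequencyPanel(f, nPerPop = 8)
  res <- pcLevelDecomposition(sim$panel, sim$samples, nAxes = 2)
  expect_gt(res$eta2_habitat[1], res$eta2_interaction[1])
  expect_gt(res$eta2_habitat[1], 0.5)
  expect_error(pcLevelDecomposition(sim$panel, sim$samples, nAxes = 1e4),
               "rank")
})

test_that("shift summary counts minor-allele and direction concordance", {
  L <- 3
  labs <- c(paste0("L", 1:L, ".urban"), paste0("L", 1:L, ".rural"))
  # SNP1: ALT minor everywhere urban (0.1); SNP2 alternating 0.1/0.9
  f <- rbind(c(0.1, 0.1), c(0.1, 0.9), c(0.1, 0.1),
             c(0.6, 0.5), c(0.2, 0.5), c(0.3, 0.5))
  rownames(f) <- labs
  set.seed(8)
  sim <- simulateFrequencyPanel(f, nPerPop = 200)  # large n: freqs ~exact
  ss <- shiftSummary(sim$panel, sim$samples)
  expect_equal(ss$perSnp$n_concordant_minor[1], 3L)  # unanimous
  expect_equal(ss$perSnp$n_concordant_minor[2], 2L)  # the two 0.1 pops
  expect_equal(dim(ss$deltaAf), c(3L, 2L))
  # |dAF| arithmetic: urban 0.2 vs rural 0.7 -> 0.5
  f2 <- rbind(c(0.2), c(0.7))
  rownames(f2) <- c("X.urban", "X.rural")
  sim2 <- simulateFrequencyPanel(f2, nPerPop = 400)
  ss2 <- shiftSummary(sim2$panel, sim2$samples)
  expect_equal(unname(ss2$deltaAf[1, 1]), 0.5, tolerance = 0.06)
})

test_that("gene flagging respects half-open overlap semantics and matches
           brute force", {
  genes <- fromHalfOpen(data.frame(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(100000, 150000, 0), end = c(150000, 200000, 50000)))
  S4Vectors::mcols(genes)$gene_id <- c("gA", "gB", "gC")
  regions <- list(
    P1 = fromHalfOpen(data.frame(chrom = "chr1", start = 140000,
                                 end = 340000)))
  sets <- genesUnderSelection(regions, genes)
  expect_equal(sets$P1, c("gA", "gB"))
  # gene ending exactly at region start does not overlap
  regions2 <- list(P1 = fromHalfOpen(data.frame(
    chrom = "chr1", start = 150000, end = 200000)))
  expect_equal(genesUnderSelection(regions2, genes)$P1, "gB")
  # empty region set flags nothing
  expect_equal(genesUnderSelection(list(P1 = GenomicRanges::GRanges()),
                                   genes)$P1, character())
  # randomised brute-force agreement
  set.seed(41)
  for (r in 1:15) {
    gs <- sort(sample.int(1e6, 8))
    ge <- gs + sample.int(5e4, 8)
    G <- fromHalfOpen(data.frame(chrom = "chr1", start = gs, end = ge))
    S4Vectors::mcols(G)$gene_id <- paste0("g", 1:8)
    rs <- sort(sample.int(1e6, 3)); re <- rs + sample.int(2e5, 3)
    R <- list(P = fromHalfOpen(data.frame(chrom = "chr1", start = rs,
                                          end = re)))
    got <- genesUnderSelection(R, G)$P
    idx <- which(vapply(1:8, function(i)
      any(gs[i] < re & ge[i] > rs), TRUE))
    want <- if (length(idx)) paste0("g", idx) else character()
    expect_equal(got, want)
  }
})

test_that("sharing null mean matches the with-replacement closed form and
           saturates correctly", {
  universe <- paste0("g", 1:100)
  set.seed(51)
  sets <- list(A = sample(universe, 10), B = sample(universe, 10))
  sn <- sharingNull(sets, universe, reps = 4000, seed = 3)
  # closed form: E[shared] = G * (1 - (1 - 1/G)^10)^2
  G <- 100
  want <- G * (1 - (1 - 1 / G)^10)^2
  expect_lt(abs(sn$null_mean[sn$k == 2] - want), 0.08)
  # saturation: every set = universe
  sat <- sharingNull(list(A = universe, B = universe), universe,
                     reps = 50, seed = 1)
  expect_equal(sat$observed, 100L)
  expect_lt(sat$p, 0.05)
  expect_error(sharingNull(sets, universe, reps = 0), "reps")
  expect_error(sharingNull(list(A = c(universe, "zzz")), universe, 10),
               "subset|larger")
})

test_that("sharing null 95% CI covers its own generating process", {
  universe <- paste0("g", 1:150)
  set.seed(61)
  cover <- vapply(1:60, function(r) {
    sets <- lapply(1:4, function(i)
      unique(sample(universe, 25, replace = TRUE)))
    names(sets) <- paste0("P", 1:4)
    sn <- sharingNull(sets, universe, reps = 250, seed = 1000 + r)
    row <- sn[sn$k == 2, ]
    row$observed >= row$null_ci_low && row$observed <= row$null_ci_high
  }, TRUE)
  expect_gte(mean(cover), 0.85)  # 95% nominal, 60 replicates
  expect_lte(mean(cover), 1.0)
})

test_that("shared counts vs distance Mantel behaves at the boundaries", {
  geo <- as.matrix(dist(1:5)) * 100
  shared <- -geo  # shared counts exactly anti-proportional to distance
  res <- sharedSetsVsDistance(shared, geo, geo, nPerm = 99)
  expect_equal(res$r, c(1, 1), tolerance = 1e-12)
  expect_error(sharedSetsVsDistance(matrix(3, 5, 5), geo, geo), "constant")
})

test_that("overrepresentation reproduces the exact hypergeometric tail", {
  universe <- paste0("g", 1:20)
  ann <- data.frame(gene = c(paste0("g", 1:5), paste0("g", 6:9)),
                    term = c(rep("T1", 5), rep("T2", 4)))
  geneset <- c("g1", "g2", "g3", "g10", "g11")
  res <- overrepresentation(geneset, ann, universe)
  t1 <- res[res$term == "T1", ]
  expect_equal(t1$p, hyperTailOracle(3, 5, 15, 5), tolerance = 1e-12)
  expect_equal(t1$n_overlap, 3L)
  # disjoint term -> p = 1
  t2 <- res[res$term == "T2", ]
  expect_equal(t2$p, hyperTailOracle(0, 4, 16, 5), tolerance = 1e-12)
  expect_equal(t2$p, 1, tolerance = 1e-12)
  # term identical to the gene set in a large universe -> significant
  uni2 <- paste0("h", 1:200)
  ann2 <- data.frame(gene = uni2[1:5], term = "T")
  res2 <- overrepresentation(uni2[1:5], ann2, uni2)
  expect_true(res2$significant)
  expect_error(overrepresentation(character(), ann, universe), "empty")
})
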