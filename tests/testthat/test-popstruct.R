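test_that("expected heterozygosity follows 2p(1-p)", {
  # 3 SNPs with p = 0.1, 0.5, 0.9 in a 10-diploid population
  hap <- rbind(c(rep(1L, 2), rep(0L, 18)),
               c(rep(1L, 10), rep(0L, 10)),
               c(rep(1L, 18), rep(0L, 2)))
  p <- toyPanel(hap)
  p@sampleIds <- sprintf("LOC1_rur_%02d", 1:10)
  sm <- samplesOf(p)
  he <- expectedHeterozygosity(p, sm, "LOC1.rural")
  expect_equal(he$He, mean(c(0.18, 0.5, 0.18)), tolerance = 1e-12)
  mono <- toyPanel(matrix(0L, 3, 20))
  mono@sampleIds <- sprintf("LOC1_rur_%02d", 1:10)
  expect_equal(expectedHeterozygosity(mono, samplesOf(mono),
                                      "LOC1.rural")$He, 0)
})

test_that("WC FST matches the independent per-SNP oracle on random
           fixtures", {
  set.seed(42)
  for (rep in 1:30) {
    nA <- sample(4:10, 1); nB <- sample(4:10, 1)
    gA <- matrix(sample(0:2, nA * 6, TRUE), nA)
    gB <- matrix(sample(0:2, nB * 6, TRUE), nB)
    hapOf <- function(g) {  # any phasing with the right dosage
      a <- pmin(g, 1L); b <- g - a
      m <- matrix(0L, ncol(g), 2 * nrow(g))
      m[, seq(1, 2 * nrow(g), 2)] <- t(a)
      m[, seq(2, 2 * nrow(g), 2)] <- t(b)
      m
    }
    pan <- toyPanel(cbind(hapOf(gA), hapOf(gB)))
    pan@sampleIds <- c(sprintf("LOC1_urb_%02d", seq_len(nA)),
                       sprintf("LOC1_rur_%02d", seq_len(nB)))
    sm <- samplesOf(pan)
    got <- wcFst(pan, sm, "LOC1.urban", "LOC1.rural")
    want <- vapply(1:6, function(j) wcOracle(gA[, j], gB[, j]), 1.0)
    expect_equal(got$perSnp$theta, want, tolerance = 1e-8)
    # symmetry
    rev <- wcFst(pan, sm, "LOC1.rural", "LOC1.urban")
    expect_identical(got$perSnp$theta, rev$perSnp$theta)
  }
})

test_that("WC FST hits the boundary cases exactly", {
  # fixed difference, 10 diploids each -> theta = 1
  pan <- toyPanel(cbind(matrix(1L, 1, 20), matrix(0L, 1, 20)))
  pan@sampleIds <- c(sprintf("A_urb_%02d", 1:10),
                     sprintf("A_rur_%02d", 1:10))
  sm <- samplesOf(pan)
  res <- wcFst(pan, sm, "A.urban", "A.rural")
  expect_equal(res$perSnp$theta, 1, tolerance = 1e-9)
  # identical sample sets -> theta <= 0, clamped mean 0
  set.seed(1)
  h <- matrix(rbinom(5 * 20, 1, 0.4), 5, 20)
  pan2 <- toyPanel(cbind(h, h))
  pan2@sampleIds <- c(sprintf("A_urb_%02d", 1:10),
                      sprintf("A_rur_%02d", 1:10))
  res2 <- wcFst(pan2, samplesOf(pan2), "A.urban", "A.rural")
  expect_true(all(res2$perSnp$theta <= 1e-9, na.rm = TRUE))
  expect_equal(res2$pairMean, 0)
  # monomorphic-in-both SNPs are excluded and counted
  pan3 <- toyPanel(rbind(c(rep(1L, 10), rep(0L, 30)), rep(0L, 40)))
  pan3@sampleIds <- c(sprintf("A_urb_%02d", 1:10),
                      sprintf("A_rur_%02d", 1:10))
  res3 <- wcFst(pan3, samplesOf(pan3), "A.urban", "A.rural")
  expect_equal(res3$nUndefined, 1L)
})

test_that("FST permutation p is deterministic, extreme for fixed
           differences, and calibrated under the null", {
  pan <- toyPanel(matrix(c(rep(1L, 12), rep(0L, 12)), 4, 24, byrow = TRUE))
  pan@sampleIds <- c(sprintf("A_urb_%02d", 1:6),
                     sprintf("A_rur_%02d", 1:6))
  sm <- samplesOf(pan)
  r1 <- fstPermutationTest(pan, sm, "A.urban", "A.rural", nPerm = 99,
                           seed = 3)
  r2 <- fstPermutationTest(pan, sm, "A.urban", "A.rural", nPerm = 99,
                           seed = 3)
  expect_identical(r1$permP, r2$permP)
  expect_equal(r1$permP, 1 / 100)  # observed is maximal
  # null calibration: one panmictic pool split in two labels
  set.seed(9)
  rej <- vapply(1:120, function(r) {
    f <- matrix(runif(30, 0.2, 0.8), 1, 30)
    fr <- rbind(f, f)
    rownames(fr) <- c("A.urban", "A.rural")
    sim <- simulateFrequencyPanel(fr, nPerPop = 8)
    fstPermutationTest(sim$panel, sim$samples, "A.urban", "A.rural",
                       nPerm = 99, seed = r)$permP <= 0.05
  }, TRUE)
  # binomial 95% band around 0.05 with 120 replicates
  expect_gte(mean(rej), 0.05 - 1.96 * sqrt(0.05 * 0.95 / 120))
  expect_lte(mean(rej), 0.05 + 1.96 * sqrt(0.05 * 0.95 / 120))
})

test_that("VIF pruning matches the exhaustive oracle and its trivial
           cases", {
  set.seed(7)
  # independent SNPs: all retained
  f <- matrix(runif(40, 0.3, 0.7), 1, 40)
  sim <- simulateFrequencyPanel(rbind(f), nPerPop = 100)
  expect_equal(ldPrune(sim$panel, windowSnps = 10), seq_len(40))
  # duplicated SNP: exactly one of the two removed
  hap <- hapMatrix(sim$panel)
  dup <- toyPanel(rbind(hap[1, , drop = FALSE], hap[1, , drop = FALSE],
                        hap[2:6, ]))
  kept <- ldPrune(dup)
  expect_equal(sum(kept %in% 1:2), 1L)
  # random 5-SNP toys against the exhaustive matrix-inversion oracle
  for (r in 1:20) {
    base <- matrix(rbinom(5 * 30, 1, 0.5), 5, 30)
    base[2, ] <- ifelse(runif(30) < 0.85, base[1, ], base[2, ])
    base[4, ] <- ifelse(runif(30) < 0.9, base[5, ], base[4, ])
    pan <- toyPanel(base)
    got <- ldPrune(pan, windowSnps = 5, stepSnps = 5, vifThreshold = 2)
    d <- dosageMatrix(pan)
    want <- vifPruneOracle(d, 2)
    expect_equal(got, want)
  }
})

test_that("genotype PCA separates duplicated clusters and matches an
           eigendecomposition oracle up to sign", {
  set.seed(11)
  a <- rbinom(30, 1, 0.5); b <- rbinom(30, 1, 0.5)
  hap <- t(rbind(a, a, a, a, b, b, b, b))  # 2 clusters of 2 diploids
  pan <- toyPanel(hap)
  pca <- suppressWarnings(genotypePca(pan))
  expect_equal(sd(pca$scores[1:2, 1]), 0, tolerance = 1e-9)
  expect_equal(sd(pca$scores[3:4, 1]), 0, tolerance = 1e-9)
  expect_gt(abs(mean(pca$scores[1:2, 1]) - mean(pca$scores[3:4, 1])), 1)
  expect_true(all(diff(pca$pve) <= 1e-12))
  expect_lte(sum(pca$pve), 1 + 1e-12)
  # oracle: eigendecomposition of the scaled covariance
  d <- dosageMatrix(pan)
  keep <- apply(d, 2, var) > 0
  p <- colMeans(d)[keep] / 2
  X <- scale(d[, keep], scale = FALSE)
  X <- sweep(X, 2, sqrt(p * (1 - p)), "/")
  ev <- eigen(tcrossprod(X))
  expect_equal(abs(pca$scores[, 1]), abs(ev$vectors[, 1] *
                                           sqrt(ev$values[1])),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("genotype PCA scores match the eigen oracle on a random toy", {
  set.seed(23)
  pan <- toyPanel(matrix(rbinom(9 * 8, 1, 0.5), 9, 8))
  pca <- suppressWarnings(genotypePca(pan))
  d <- dosageMatrix(pan)
  keep <- apply(d, 2, var) > 0
  p <- colMeans(d)[keep] / 2
  X <- sweep(scale(d[, keep], scale = FALSE), 2, sqrt(p * (1 - p)), "/")
  ev <- eigen(tcrossprod(X))
  for (ax in 1:3)
    expect_equal(abs(pca$scores[, ax]),
                 abs(ev$vectors[, ax] * sqrt(pmax(ev$values[ax], 0))),
                 tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("Mantel r equals the direct upper-triangle correlation and is
           calibrated", {
  set.seed(5)
  a <- as.matrix(dist(runif(4)))
  b <- as.matrix(dist(runif(4)))
  got <- mantelTest(a, b, nPerm = 199)
  expect_equal(got$r, cor(a[upper.tri(a)], b[upper.tri(b)]),
               tolerance = 1e-12)
  expect_equal(mantelTest(a, a, nPerm = 99)$r, 1)
  expect_error(mantelTest(a, matrix(0, 4, 4)), "constant")
  # agreement with the vegan implementation on a bigger matrix
  a2 <- as.matrix(dist(runif(8))); b2 <- as.matrix(dist(runif(8)))
  expect_equal(mantelTest(a2, b2, nPerm = 99)$r,
               unname(vegan::mantel(a2, b2, permutations = 2)$statistic),
               tolerance = 1e-12)
  # type-I calibration under shuffled distances
  rej <- vapply(1:150, function(r) {
    set.seed(r + 500)
    x <- as.matrix(dist(runif(7))); y <- as.matrix(dist(runif(7)))
    mantelTest(x, y, nPerm = 99, seed = r)$p <= 0.05
  }, TRUE)
  expect_lte(mean(rej), 0.05 + 2.5 * sqrt(0.05 * 0.95 / 150))
})

# rural-only Mantel (the simulated fixture has no urban spread)
ruralIbd <- function(fm, st) {
  geo <- haversineMatrix(st$longitude, st$latitude)
  mantelTest(fm, geo, nPerm = 199, alternative = "greater")
}

test_that("isolation by distance recovers the stepping-stone gradient", {
  hits <- vapply(1:5, function(r) {
    cfg <- simConfig(nLocalities = 5, nAnc = 40, nRural = 40,
                     nUrban = 40, founderSize = 10, tBurnin = 10,
                     tSplit = 120, tUrban = 5, mRR = 0.05, mUR = 0.05,
                     mu = 0, rho = 1e-7, chromLengths = c(chr1 = 1e6),
                     zChrom = NA, nSitesTarget = 150, nSample = 10,
                     seed = 700 + r)
    sim <- simulatePanel(cfg)
    pops <- paste0("LOC", 1:5, ".rural")
    fm <- matrix(0, 5, 5, dimnames = list(pops, pops))
    for (i in 1:5) for (j in seq_len(i - 1)) {
      fm[i, j] <- fm[j, i] <-
        wcFst(sim$panel, sim$samples, pops[i], pops[j])$pairMean
    }
    st <- data.frame(site_id = pops, locality = paste0("LOC", 1:5),
                     habitat = "rural", longitude = seq(0, 8, 2),
                     latitude = 45)
    res <- suppressWarnings(ruralIbd(fm, st))
    res$r > 0
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("ibdByHabitat enforces its preconditions", {
  pops <- c(paste0("L", 1:3, ".urban"), paste0("L", 1:3, ".rural"))
  fm <- matrix(0.1, 6, 6, dimnames = list(pops, pops)); diag(fm) <- 0
  st <- data.frame(site_id = pops, locality = rep(paste0("L", 1:3), 2),
                   habitat = rep(c("urban", "rural"), each = 3),
                   longitude = 1:6, latitude = 40 + 1:6)
  expect_error(ibdByHabitat(fm, st), ">= 4 populations")
  pops4 <- c(paste0("L", 1:4, ".urban"), paste0("L", 1:4, ".rural"))
  fm4 <- matrix(0.1, 8, 8, dimnames = list(pops4, pops4)); diag(fm4) <- 0
  st4 <- data.frame(site_id = pops4, locality = rep(paste0("L", 1:4), 2),
                    habitat = rep(c("urban", "rural"), each = 4),
                    longitude = 1:8, latitude = 40 + 1:8)
  expect_error(ibdByHabitat(fm4, st4), "constant")  # all-equal FST
})
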