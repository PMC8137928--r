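# Fixture builders and independent brute-force oracles. Every oracle here
# is written from the defining formula or by exhaustive enumeration, on a
# different code path from the package implementation it cross-checks.

# panel from a sites x haplotypes 0/1 matrix (even number of columns)
toyPanel <- function(hap, chrom = NULL, pos = NULL, chromClass = NULL) {
  hap <- as.matrix(hap)
  S <- nrow(hap); n <- ncol(hap) / 2
  if (is.null(chrom)) chrom <- rep("chr1", S)
  if (is.null(pos)) pos <- seq_len(S) * 100L
  HaplotypePanel(paste0("s", seq_len(n)), chrom, pos,
                 rep("A", S), rep("T", S), hap, chromClass = chromClass)
}

# sample table for a panel whose ids follow LOC_hab_nn naming
samplesOf <- function(panel) {
  ids <- sampleIds(panel)
  parts <- strsplit(ids, "_", fixed = TRUE)
  suppressWarnings(sampleFrame(data.frame(
    individual = ids,
    locality = vapply(parts, `[`, "", 1L),
    habitat = ifelse(vapply(parts, `[`, "", 2L) == "urb", "urban",
                     "rural"),
    sex = "unknown", stringsAsFactors = FALSE)))
}

# random panel with two populations and given frequencies per pop
randomTwoPopPanel <- function(nSnp = 20, nPerPop = 8, seed = 1) {
  set.seed(seed)
  f <- matrix(runif(2 * nSnp, 0.05, 0.95), 2, nSnp,
              dimnames = list(c("LOC1.urban", "LOC1.rural"), NULL))
  simulateFrequencyPanel(f, nPerPop)
}

# --- Weir-Cockerham 1984, scalar per-SNP oracle -----------------------------
# written from the printed a/b/c component formulas, one SNP at a time
wcOracle <- function(gA, gB) {
  n1 <- length(gA); n2 <- length(gB)
  p1 <- mean(gA) / 2; p2 <- mean(gB) / 2
  h1 <- mean(gA == 1); h2 <- mean(gB == 1)
  r <- 2
  nbar <- mean(c(n1, n2))
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  ssq <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (ssq - (pbar * (1 - pbar) - (r - 1) / r * ssq - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * ssq -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

# --- EHHS / EHH by exhaustive pair enumeration ------------------------------
# fraction of haplotype pairs identical over every site of idx (and at the
# core for EHHS), normalised at the core
ehhsEnumOracle <- function(H, core, direction = "right") {
  n <- ncol(H)
  pairs <- combn(n, 2)
  idsTo <- function(to) {
    rng <- if (direction == "right") core:to else to:core
    apply(pairs, 2, function(pr)
      all(H[rng, pr[1]] == H[rng, pr[2]]))
  }
  hCore <- mean(idsTo(core))
  walk <- if (direction == "right") core:nrow(H) else core:1
  vapply(walk, function(to) mean(idsTo(to)) / hCore, 1.0)
}

# --- nSL mean pairwise tract length, exhaustive scan ------------------------
nslOracle <- function(H, core, set = seq_len(ncol(H))) {
  if (length(set) < 2) return(NA_real_)
  pairs <- combn(set, 2)
  S <- nrow(H)
  lens <- apply(pairs, 2, function(pr) {
    if (H[core, pr[1]] != H[core, pr[2]]) return(0)
    l <- core
    while (l > 1 && H[l - 1, pr[1]] == H[l - 1, pr[2]]) l <- l - 1
    r <- core
    while (r < S && H[r + 1, pr[1]] == H[r + 1, pr[2]]) r <- r + 1
    r - l + 1
  })
  mean(lens)
}

# --- iES fine-grid trapezoid oracle (single side) ---------------------------
iesSideOracle <- function(pos, val, cutoff = 0.05, maxGap = 2e5) {
  tot <- 0
  for (k in seq_len(length(pos) - 1)) {
    if (val[k + 1] < cutoff) break
    if (abs(pos[k + 1] - pos[k]) > maxGap) break
    tot <- tot + abs(pos[k + 1] - pos[k]) * (val[k] + val[k + 1]) / 2
  }
  tot
}

# --- exhaustive max-VIF pruning oracle (single window) ----------------------
vifPruneOracle <- function(d, threshold = 2) {
  keep <- seq_len(ncol(d))
  repeat {
    act <- keep[apply(d[, keep, drop = FALSE], 2, var) > 0]
    if (length(act) < 2) break
    vif <- vapply(seq_along(act), function(i) {
      y <- d[, act[i]]
      X <- d[, act[-i], drop = FALSE]
      rss <- sum(resid(lm(y ~ X))^2)
      tss <- sum((y - mean(y))^2)
      min(1 / max(rss / tss, 1e-12), 1e6)  # same collinearity cap
    }, 1.0)
    if (max(vif) < threshold) break
    keep <- setdiff(keep, act[which(vif >= max(vif) * (1 - 1e-9))[1]])
  }
  keep
}

# --- type-II partial eta^2 via explicit model comparisons -------------------
eta2Oracle <- function(y, hab, loc) {
  rss <- function(f) sum(resid(lm(f))^2)
  full <- rss(y ~ hab * loc)
  ssInt <- rss(y ~ hab + loc) - full
  ssHab <- rss(y ~ loc) - rss(y ~ hab + loc)
  ssLoc <- rss(y ~ hab) - rss(y ~ hab + loc)
  c(habitat = ssHab / (ssHab + full), locality = ssLoc / (ssLoc + full),
    interaction = ssInt / (ssInt + full))
}

# --- exact hypergeometric upper tail by enumeration -------------------------
hyperTailOracle <- function(obs, m, nOther, k) {
  i <- obs:min(m, k)
  sum(choose(m, i) * choose(nOther, k - i)) / choose(m + nOther, k)
}

# --- brute-force window membership ------------------------------------------
# 1-based SNP position p is in half-open window [start, end) iff
# p - 1 in [start, end)
windowMembersOracle <- function(pos, starts, ends)
  vapply(seq_along(starts), function(w)
    sum(pos - 1 >= starts[w] & pos - 1 < ends[w]), 1L)

# small deterministic VCF fixture (2 samples, 3 sites)
writeFixtureVcf <- function(path, gts = c("0|1", "1|1", "0|0")) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", "ind1", "ind2"), collapse = "\t"),
    paste("chr1", 101, ".", "A", "G", ".", "PASS", ".", "GT",
          gts[1], gts[2], sep = "\t"),
    paste("chr1", 205, ".", "C", "T", ".", "PASS", ".", "GT",
          gts[2], gts[3], sep = "\t"),
    paste("chr2", 50, ".", "G", "A", ".", "PASS", ".", "GT",
          gts[3], gts[1], sep = "\t"))
  writeLines(lines, path)
  path
}
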