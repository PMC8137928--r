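# Forward-time Wright-Fisher simulator of paired urban-rural demes.
#
# Discrete non-overlapping generations; each offspring draws two parents
# with probability proportional to fitness; each gamete is formed by
# Poisson(rho * chromosome length) crossovers and Bernoulli(mu) per-site
# mutation (0 <-> 1); migrants are swapped symmetrically between connected
# demes each generation. Rural demes sit on a stepping-stone chain in
# locality order; each urban deme is founded from its paired rural deme
# `tUrban` generations before the present by a founder bottleneck and
# exchanges migrants only with that rural deme.

#' Simulation configuration for the paired-deme simulator
#'
#' Desk-scale defaults (deme sizes <= 200, a few thousand segregating sites,
#' three ~10 Mb chromosomes, one of them the Z carried by all individuals as
#' an ordinary chromosome) keep a full nine-locality run in minutes while
#' preserving the study design being emulated: nine localities, each with an
#' urban and a rural population of 10-16 sampled diploids.
#'
#' @slot nLocalities number of urban-rural locality pairs.
#' @slot nAnc,nRural,nUrban diploid deme sizes.
#' @slot founderSize diploids founding each urban deme.
#' @slot tBurnin,tSplit,tUrban generation counts: ancestral burn-in, time
#'   since the rural demes split, time since urban founding
#'   (\code{tUrban <= tSplit}).
#' @slot mRR,mUR per-generation migration rates (rural-rural along the
#'   stepping-stone chain; urban-rural within a pair).
#' @slot mu per-site per-generation mutation rate (0/1 flip).
#' @slot rho per-bp per-generation recombination rate.
#' @slot chromLengths named numeric, bp per chromosome.
#' @slot zChrom name of the chromosome flagged as Z.
#' @slot nSitesTarget segregating-site target at initialisation.
#' @slot sweeps data.frame(locality, chrom, pos, s, init_freq): hard sweeps
#'   planted in the urban founders of \code{locality} (advantageous-allele
#'   fitness 1 + s * dosage, urban demes only).
#' @slot polygenic data.frame(chrom, pos, effect): additive trait loci under
#'   Gaussian stabilising selection, optimum 0 in rural demes and
#'   \code{optimumShift} in urban demes, width \code{omega}.
#' @slot optimumShift,omega polygenic optimum displacement and width.
#' @slot nSample diploids sampled per deme for the output panel (10-16).
#' @slot conditionOnSweep logical; retry the urban phase (up to
#'   \code{retryCap} times) if a planted sweep allele is lost.
#' @slot retryCap maximum retries when conditioning.
#' @slot seed RNG seed used by \code{\link{simulatePanel}}.
#' @export
setClass("SimConfig", representation(
  nLocalities = "integer", nAnc = "integer", nRural = "integer",
  nUrban = "integer", founderSize = "integer", tBurnin = "integer",
  tSplit = "integer", tUrban = "integer", mRR = "numeric", mUR = "numeric",
  mu = "numeric", rho = "numeric", chromLengths = "numeric",
  zChrom = "character", nSitesTarget = "integer", sweeps = "data.frame",
  polygenic = "data.frame", optimumShift = "numeric", omega = "numeric",
  nSample = "integer", conditionOnSweep = "logical", retryCap = "integer",
  seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  rates <- c(object@mRR, object@mUR, object@mu, object@rho)
  if (any(rates < 0 | rates >= 1)) msg <- c(msg, "rates must be in [0, 1)")
  if (any(c(object@nAnc, object@nRural, object@nUrban,
            object@founderSize) < 2L))
    msg <- c(msg, "deme sizes must be >= 2")
  if (object@tUrban > object@tSplit)
    msg <- c(msg, "tUrban must be <= tSplit")
  if (is.null(names(object@chromLengths)))
    msg <- c(msg, "chromLengths must be named")
  if (!object@zChrom %in% c(names(object@chromLengths), NA_character_))
    msg <- c(msg, "zChrom must name a chromosome")
  for (df in list(object@sweeps, object@polygenic)) {
    if (nrow(df) && (!all(df$chrom %in% names(object@chromLengths)) ||
                     any(df$pos < 1) ||
                     any(df$pos > object@chromLengths[df$chrom])))
      msg <- c(msg, "planted locus outside chromosome lengths")
  }
  if (length(msg)) msg else TRUE
})

#' Build a SimConfig
#'
#' @param nLocalities,nAnc,nRural,nUrban,founderSize,tBurnin,tSplit,tUrban
#'   see \linkS4class{SimConfig}.
#' @param mRR,mUR,mu,rho,chromLengths,zChrom,nSitesTarget,sweeps,polygenic
#'   see \linkS4class{SimConfig}.
#' @param optimumShift,omega,nSample,conditionOnSweep,retryCap,seed see
#'   \linkS4class{SimConfig}.
#' @return a validated \linkS4class{SimConfig}.
#' @export
simConfig <- function(nLocalities = 9, nAnc = 100, nRural = 100,
                      nUrban = 100, founderSize = 20, tBurnin = 100,
                      tSplit = 150, tUrban = 50, mRR = 0.02, mUR = 0.02,
                      mu = 1e-6, rho = 1e-7,
                      chromLengths = c(chr1 = 1e7, chr2 = 1e7, chrZ = 8e6),
                      zChrom = "chrZ", nSitesTarget = 3000,
                      sweeps = NULL, polygenic = NULL, optimumShift = 1,
                      omega = 2, nSample = 12, conditionOnSweep = FALSE,
                      retryCap = 20, seed = 1) {
  empty <- function(cols) as.data.frame(setNames(
    rep(list(numeric()), length(cols)), cols))
  if (is.null(sweeps))
    sweeps <- empty(c("locality", "chrom", "pos", "s", "init_freq"))
  if (is.null(polygenic)) polygenic <- empty(c("chrom", "pos", "effect"))
  new("SimConfig", nLocalities = as.integer(nLocalities),
      nAnc = as.integer(nAnc), nRural = as.integer(nRural),
      nUrban = as.integer(nUrban), founderSize = as.integer(founderSize),
      tBurnin = as.integer(tBurnin), tSplit = as.integer(tSplit),
      tUrban = as.integer(tUrban), mRR = mRR, mUR = mUR, mu = mu,
      rho = rho, chromLengths = chromLengths,
      zChrom = as.character(zChrom),
      nSitesTarget = as.integer(nSitesTarget), sweeps = sweeps,
      polygenic = polygenic, optimumShift = optimumShift, omega = omega,
      nSample = as.integer(nSample),
      conditionOnSweep = isTRUE(conditionOnSweep),
      retryCap = as.integer(retryCap), seed = as.integer(seed))
}

# --- internal machinery -----------------------------------------------------

# site map: data.frame(chrom, pos) plus per-chromosome column index ranges
.makeSiteMap <- function(cfg) {
  lens <- cfg@chromLengths
  nPer <- round(cfg@nSitesTarget * lens / sum(lens))
  nPer[nPer < 1] <- 1
  chrom <- character(); pos <- integer()
  for (cc in names(lens)) {
    p <- sort(sample.int(lens[[cc]], nPer[[cc]]))
    forced <- c(cfg@sweeps$pos[cfg@sweeps$chrom == cc],
                cfg@polygenic$pos[cfg@polygenic$chrom == cc])
    p <- sort(unique(c(p, as.integer(forced))))
    chrom <- c(chrom, rep(cc, length(p)))
    pos <- c(pos, p)
  }
  data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

# one generation of reproduction within a deme; H is 2N x S (rows = haps)
.stepDeme <- function(H, nNext, w, sites, cfg) {
  nPar <- nrow(H) %/% 2L
  p1 <- sample.int(nPar, nNext, replace = TRUE, prob = w)
  p2 <- sample.int(nPar, nNext, replace = TRUE, prob = w)
  G1 <- .makeGametes(H, p1, sites, cfg@rho)
  G2 <- .makeGametes(H, p2, sites, cfg@rho)
  newH <- matrix(0L, 2L * nNext, ncol(H))
  newH[seq(1L, 2L * nNext, 2L), ] <- G1
  newH[seq(2L, 2L * nNext, 2L), ] <- G2
  if (cfg@mu > 0) {
    nm <- rbinom(1L, length(newH), cfg@mu)
    if (nm > 0L) {
      idx <- sample.int(length(newH), nm)
      newH[idx] <- 1L - newH[idx]
    }
  }
  newH
}

.makeGametes <- function(H, par, sites, rho) {
  n <- length(par)
  G <- matrix(0L, n, ncol(H))
  for (cc in unique(sites$chrom)) {
    sidx <- which(sites$chrom == cc)
    posC <- sites$pos[sidx]
    k <- rpois(n, rho * attr(sites, "lens")[[cc]])
    startHap <- sample.int(2L, n, replace = TRUE) - 1L
    C <- matrix(startHap, n, length(sidx))
    for (j in which(k > 0L)) {
      bp <- sort(runif(k[j], 0, attr(sites, "lens")[[cc]]))
      C[j, ] <- (startHap[j] + findInterval(posC, bp)) %% 2L
    }
    A <- H[2L * par - 1L, sidx, drop = FALSE]
    B <- H[2L * par, sidx, drop = FALSE]
    G[, sidx] <- A + (B - A) * C
  }
  G
}

# fitness vector for a deme; returns NULL when no selection applies
.fitnessOf <- function(H, selCols, sweepS, polyEff, optimum, omega) {
  if (!length(selCols)) return(NULL)
  odd <- seq(1L, nrow(H), 2L)
  D <- H[odd, selCols, drop = FALSE] + H[odd + 1L, selCols, drop = FALSE]
  w <- rep(1, nrow(D))
  ns <- length(sweepS)
  if (ns) for (l in seq_len(ns))
    w <- w * (1 + sweepS[l] * D[, l])
  if (length(polyEff)) {
    z <- D[, ns + seq_along(polyEff), drop = FALSE] %*% polyEff
    w <- w * exp(-(z - optimum)^2 / (2 * omega^2))
  }
  w
}

.migrateSwap <- function(Hlist, d1, d2, m) {
  n1 <- nrow(Hlist[[d1]]) %/% 2L
  n2 <- nrow(Hlist[[d2]]) %/% 2L
  nm <- rbinom(1L, min(n1, n2), m)
  if (nm > 0L) {
    i1 <- sample.int(n1, nm); i2 <- sample.int(n2, nm)
    r1 <- as.vector(rbind(2L * i1 - 1L, 2L * i1))
    r2 <- as.vector(rbind(2L * i2 - 1L, 2L * i2))
    tmp <- Hlist[[d1]][r1, , drop = FALSE]
    Hlist[[d1]][r1, ] <- Hlist[[d2]][r2, , drop = FALSE]
    Hlist[[d2]][r2, ] <- tmp
  }
  Hlist
}

#' Simulate a paired urban-rural haplotype panel
#'
#' Runs the forward Wright-Fisher model of \linkS4class{SimConfig}:
#' ancestral burn-in, split into stepping-stone rural demes, urban founding
#' bottlenecks, migration, planted hard sweeps (urban demes only) and
#' polygenic stabilising selection with an urban optimum shift. Initial
#' variation is drawn from a neutral-shaped site frequency spectrum
#' (density proportional to 1/p) so that the burn-in only has to establish
#' linkage disequilibrium, not variation. The run is deterministic under
#' \code{config@seed}.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list with \code{panel} (\linkS4class{HaplotypePanel}),
#'   \code{samples} (sample table, 10-16 diploids per deme) and
#'   \code{truth} (data.frame: one row per planted locus per deme with the
#'   realised final allele frequency and a \code{lost} flag).
#' @export
simulatePanel <- function(config) {
  cfg <- config
  set.seed(cfg@seed)
  sites <- .makeSiteMap(cfg)
  attr(sites, "lens") <- as.list(cfg@chromLengths)
  S <- nrow(sites)
  loc <- paste0("LOC", seq_len(cfg@nLocalities))

  sweepCols <- integer(0)
  if (nrow(cfg@sweeps))
    sweepCols <- vapply(seq_len(nrow(cfg@sweeps)), function(i)
      which(sites$chrom == cfg@sweeps$chrom[i] &
              sites$pos == cfg@sweeps$pos[i]), 1L)
  polyCols <- integer(0)
  if (nrow(cfg@polygenic))
    polyCols <- vapply(seq_len(nrow(cfg@polygenic)), function(i)
      which(sites$chrom == cfg@polygenic$chrom[i] &
              sites$pos == cfg@polygenic$pos[i]), 1L)
  selCols <- c(sweepCols, polyCols)
  polyEff <- if (length(polyCols)) cfg@polygenic$effect else numeric(0)

  # ancestral deme: SFS-shaped frequencies, linkage-equilibrium start
  pmin <- 1 / (2 * cfg@nAnc)
  p0 <- pmin * ((1 - pmin) / pmin)^runif(S)
  p0[sweepCols] <- 0  # sweep alleles arise only in the urban founders
  anc <- matrix(rbinom(2L * cfg@nAnc * S, 1L, rep(p0, each = 2L * cfg@nAnc)),
                2L * cfg@nAnc, S)
  for (g in seq_len(cfg@tBurnin))
    anc <- .stepDeme(anc, cfg@nAnc, NULL, sites, cfg)

  # rural demes split from the ancestral pool
  rural <- lapply(seq_len(cfg@nLocalities), function(d) {
    ind <- sample.int(cfg@nAnc, cfg@nRural, replace = TRUE)
    anc[as.vector(rbind(2L * ind - 1L, 2L * ind)), , drop = FALSE]
  })
  ruralFit <- function(H) .fitnessOf(H, selCols,
                                     rep(0, length(sweepCols)),
                                     polyEff, 0, cfg@omega)
  for (g in seq_len(cfg@tSplit - cfg@tUrban)) {
    rural <- lapply(rural, function(H)
      .stepDeme(H, cfg@nRural, ruralFit(H), sites, cfg))
    if (cfg@nLocalities > 1L && cfg@mRR > 0)
      for (d in seq_len(cfg@nLocalities - 1L))
        rural <- .migrateSwap(rural, d, d + 1L, cfg@mRR)
  }

  # urban founding + joint phase, optionally conditioned on sweep survival
  runUrbanPhase <- function(rural) {
    urban <- lapply(seq_len(cfg@nLocalities), function(d) {
      ind <- sample.int(cfg@nRural, cfg@founderSize,
                        replace = cfg@founderSize > cfg@nRural)
      H <- rural[[d]][as.vector(rbind(2L * ind - 1L, 2L * ind)), ,
                      drop = FALSE]
      sw <- which(cfg@sweeps$locality == loc[d])
      for (i in sw) {  # plant the sweep allele on founder haplotypes
        ncar <- max(1L, round(cfg@sweeps$init_freq[i] * nrow(H)))
        carriers <- sample.int(nrow(H), ncar)
        H[, sweepCols[i]] <- 0L
        H[carriers, sweepCols[i]] <- 1L
      }
      H
    })
    urbanFit <- function(H, d) .fitnessOf(
      H, selCols,
      ifelse(cfg@sweeps$locality == loc[d], cfg@sweeps$s, 0),
      polyEff, cfg@optimumShift, cfg@omega)
    for (g in seq_len(cfg@tUrban)) {
      urban <- lapply(seq_len(cfg@nLocalities), function(d)
        .stepDeme(urban[[d]], cfg@nUrban, urbanFit(urban[[d]], d),
                  sites, cfg))
      rural <- lapply(rural, function(H)
        .stepDeme(H, cfg@nRural, ruralFit(H), sites, cfg))
      if (cfg@nLocalities > 1L && cfg@mRR > 0)
        for (d in seq_len(cfg@nLocalities - 1L))
          rural <- .migrateSwap(rural, d, d + 1L, cfg@mRR)
      if (cfg@mUR > 0)
        for (d in seq_len(cfg@nLocalities)) {
          both <- .migrateSwap(list(urban[[d]], rural[[d]]), 1L, 2L,
                               cfg@mUR)
          urban[[d]] <- both[[1L]]; rural[[d]] <- both[[2L]]
        }
    }
    list(urban = urban, rural = rural)
  }

  tries <- 0L
  repeat {
    res <- runUrbanPhase(rural)
    tries <- tries + 1L
    if (!cfg@conditionOnSweep || !nrow(cfg@sweeps)) break
    surv <- vapply(seq_len(nrow(cfg@sweeps)), function(i) {
      d <- match(cfg@sweeps$locality[i], loc)
      mean(res$urban[[d]][, sweepCols[i]]) > 0
    }, TRUE)
    if (all(surv)) break
    if (tries > cfg@retryCap)
      stop("sweep allele lost in all ", cfg@retryCap, " retries")
  }

  # sample, assemble panel + samples + truth
  demes <- c(res$urban, res$rural)
  habitat <- rep(c("urban", "rural"), each = cfg@nLocalities)
  locality <- rep(loc, 2L)
  hapList <- list(); ids <- character(); sl <- character(); sh <- character()
  for (d in seq_along(demes)) {
    N <- nrow(demes[[d]]) %/% 2L
    ind <- sort(sample.int(N, cfg@nSample))
    rows <- as.vector(rbind(2L * ind - 1L, 2L * ind))
    hapList[[d]] <- demes[[d]][rows, , drop = FALSE]
    ids <- c(ids, sprintf("%s_%s_%02d", locality[d],
                          substr(habitat[d], 1, 3), seq_len(cfg@nSample)))
    sl <- c(sl, rep(locality[d], cfg@nSample))
    sh <- c(sh, rep(habitat[d], cfg@nSample))
  }
  H <- t(do.call(rbind, hapList))  # sites x haplotypes
  cc <- setNames(rep("autosome", length(cfg@chromLengths)),
                 names(cfg@chromLengths))
  if (!is.na(cfg@zChrom)) cc[cfg@zChrom] <- "Z"
  panel <- HaplotypePanel(ids, sites$chrom, sites$pos,
                          rep("A", S), rep("T", S), H, chromClass = cc)
  samples <- suppressWarnings(sampleFrame(data.frame(
    individual = ids, locality = sl, habitat = sh,
    sex = rep_len(c("M", "F"), length(ids)), stringsAsFactors = FALSE)))

  planted <- rbind(
    if (nrow(cfg@sweeps)) data.frame(
      locality = cfg@sweeps$locality, chrom = cfg@sweeps$chrom,
      pos = cfg@sweeps$pos, type = "sweep",
      s_or_effect = cfg@sweeps$s, col = sweepCols,
      stringsAsFactors = FALSE),
    if (nrow(cfg@polygenic)) data.frame(
      locality = NA_character_, chrom = cfg@polygenic$chrom,
      pos = cfg@polygenic$pos, type = "polygenic",
      s_or_effect = cfg@polygenic$effect, col = polyCols,
      stringsAsFactors = FALSE))
  truth <- NULL
  if (!is.null(planted) && nrow(planted)) {
    truth <- do.call(rbind, lapply(seq_along(demes), function(d)
      data.frame(locality = planted$locality, chrom = planted$chrom,
                 pos = planted$pos, type = planted$type,
                 s_or_effect = planted$s_or_effect,
                 deme = paste(locality[d], habitat[d], sep = "."),
                 final_freq = colMeans(demes[[d]][, planted$col,
                                                  drop = FALSE]),
                 stringsAsFactors = FALSE)))
    truth$lost <- truth$final_freq == 0
    rownames(truth) <- NULL
  } else {
    truth <- data.frame(locality = character(), chrom = character(),
                        pos = integer(), type = character(),
                        s_or_effect = numeric(), deme = character(),
                        final_freq = numeric(), lost = logical())
  }
  list(panel = panel, samples = samples, truth = truth)
}

#' Simulate genotypes directly from per-population allele frequencies
#'
#' A light-weight generator for calibration and power studies of the
#' association machinery: each population's genotypes are binomial draws
#' from its specified ALT frequency, so there is no linkage or shared
#' drift beyond what \code{freqs} encodes.
#'
#' @param freqs matrix populations x sites of ALT allele frequencies;
#'   rownames are \code{locality.habitat} labels.
#' @param nPerPop diploids per population.
#' @param chrom,pos optional site map (defaults to one long autosome with
#'   1 kb spacing).
#' @return list(panel, samples) as in \code{\link{simulatePanel}}.
#' @export
simulateFrequencyPanel <- function(freqs, nPerPop = 12, chrom = NULL,
                                   pos = NULL) {
  P <- nrow(freqs); S <- ncol(freqs)
  if (is.null(chrom)) chrom <- rep("chr1", S)
  if (is.null(pos)) pos <- seq_len(S) * 1000L
  labs <- rownames(freqs)
  if (is.null(labs)) labs <- paste0("LOC", seq_len(P), ".rural")
  hap <- matrix(0L, S, 2L * nPerPop * P)
  ids <- character(); slc <- character(); shb <- character()
  for (p in seq_len(P)) {
    cols <- (p - 1L) * 2L * nPerPop + seq_len(2L * nPerPop)
    hap[, cols] <- rbinom(S * 2L * nPerPop, 1L, rep(freqs[p, ],
                                                    times = 2L * nPerPop))
    lh <- strsplit(labs[p], ".", fixed = TRUE)[[1L]]
    ids <- c(ids, sprintf("%s_%s_%02d", lh[1L], substr(lh[2L], 1, 3),
                          seq_len(nPerPop)))
    slc <- c(slc, rep(lh[1L], nPerPop))
    shb <- c(shb, rep(lh[2L], nPerPop))
  }
  panel <- HaplotypePanel(ids, chrom, pos, rep("A", S), rep("T", S), hap)
  samples <- suppressWarnings(sampleFrame(data.frame(
    individual = ids, locality = slc, habitat = shb,
    sex = rep_len(c("M", "F"), length(ids)), stringsAsFactors = FALSE)))
  list(panel = panel, samples = samples)
}

#' Generate per-site land-cover proportions
#'
#' Emulates digitised land cover for a 1 x 1 km square around each site,
#' divided into 100 cells of 100 x 100 m: per-cell proportions of
#' buildings, vegetation and paved surface drawn from a Dirichlet whose
#' building + paved mass increases monotonically with the site's
#' urbanisation intensity (mean building share \code{0.7 * intensity},
#' paved \code{0.3 * intensity}, vegetation the complement).
#'
#' @param sites data.frame with a \code{site_id} column (one row per site).
#' @param urbanIntensity numeric in [0, 1], one value per site.
#' @param seed RNG seed.
#' @param nCells cells per site.
#' @param concentration Dirichlet concentration; \code{Inf} gives
#'   noise-free proportions equal to the means.
#' @return data.frame(site_id, cell_id, p_buildings, p_vegetation,
#'   p_paved); proportions sum to 1 per cell.
#' @export
generateLandcover <- function(sites, urbanIntensity, seed = 1,
                              nCells = 100, concentration = 50) {
  if (length(urbanIntensity) != nrow(sites))
    stop("one intensity per site required")
  if (any(urbanIntensity < 0 | urbanIntensity > 1))
    stop("urbanIntensity must be in [0, 1]")
  set.seed(seed)
  out <- lapply(seq_len(nrow(sites)), function(i) {
    m <- c(0.7, 0.3) * urbanIntensity[i]
    means <- c(buildings = m[1L], vegetation = 1 - sum(m), paved = m[2L])
    if (is.infinite(concentration)) {
      pr <- matrix(means, nCells, 3L, byrow = TRUE)
    } else {
      alpha <- pmax(means * concentration, 1e-9)
      g <- matrix(stats::rgamma(nCells * 3L, shape = rep(alpha,
                                                         each = nCells)),
                  nCells, 3L)
      pr <- g / rowSums(g)
      pr[is.nan(pr)] <- 0
      zero <- means == 0           # exact zeros stay exact
      pr[, zero] <- 0
      pr <- pr / pmax(rowSums(pr), 1e-300)
    }
    data.frame(site_id = sites$site_id[i], cell_id = seq_len(nCells),
               p_buildings = pr[, 1L], p_vegetation = pr[, 2L],
               p_paved = pr[, 3L], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compare planted loci with detected outlier regions
#'
#' A planted locus counts as detected when it lies inside a merged outlier
#' region or within \code{slack} bp of one (interval membership follows the
#' package-wide convention that 1-based position p occupies half-open
#' coordinate p - 1).
#'
#' @param truth truth table from \code{\link{simulatePanel}} (or any
#'   data.frame with chrom and pos columns; duplicate loci are collapsed).
#' @param regions merged outlier regions as a \code{GRanges}.
#' @param slack detection slack in bp.
#' @return data.frame(chrom, pos, detected, distance).
#' @export
truthRecall <- function(truth, regions, slack = 1e5) {
  loci <- unique(truth[c("chrom", "pos")])
  reg <- toHalfOpen(regions)
  res <- lapply(seq_len(nrow(loci)), function(i) {
    x <- loci$pos[i] - 1  # half-open coordinate of the SNP
    r <- reg[reg$chrom == loci$chrom[i], , drop = FALSE]
    if (!nrow(r)) return(c(detected = 0, distance = Inf))
    d <- pmax(r$start - x, x - (r$end - 1), 0)
    c(detected = as.numeric(min(d) <= slack), distance = min(d))
  })
  res <- do.call(rbind, res)
  data.frame(chrom = loci$chrom, pos = loci$pos,
             detected = res[, "detected"] == 1,
             distance = res[, "distance"], row.names = NULL)
}
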