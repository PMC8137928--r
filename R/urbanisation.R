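# Urbanisation score: PCA of per-site mean land-cover proportions, with a
# fixed orientation (higher built cover => higher score), plus rater
# repeatability via the intraclass correlation coefficient.

#' Urbanisation score from land-cover proportions
#'
#' Per-site means of the three cover variables (buildings, vegetation,
#' paved) are column-standardised and the first principal component taken
#' as the urbanisation score. The PCA runs on the correlation matrix so the
#' score is invariant to rescaling any cover variable; the axis sign is
#' fixed so that the loading of the building proportion is positive, giving
#' negative scores to the less urbanised and positive scores to the more
#' urbanised sites.
#'
#' @param landcover data.frame(site_id, cell_id, p_buildings,
#'   p_vegetation, p_paved), e.g. from \code{\link{generateLandcover}}.
#' @return list with \code{scores} (data.frame site_id, pc_urb),
#'   \code{loadings} (per-variable PC1 loading) and \code{pve}
#'   (proportion of variance explained by PC1).
#' @export
scoreUrbanisation <- function(landcover) {
  vars <- c("p_buildings", "p_vegetation", "p_paved")
  if (!all(vars %in% names(landcover)))
    stop("landcover needs columns: ", paste(vars, collapse = ", "))
  agg <- aggregate(landcover[vars], list(site_id = landcover$site_id), mean)
  if (nrow(agg) < 3) stop("need at least 3 sites for a PCA")
  X <- as.matrix(agg[vars])
  keep <- apply(X, 2, sd) > 0
  if (!any(keep)) stop("zero variance in all cover variables; PCA undefined")
  Z <- scale(X[, keep, drop = FALSE])
  e <- eigen(cor(X[, keep, drop = FALSE]), symmetric = TRUE)
  v <- e$vectors[, 1L]
  load <- setNames(rep(0, length(vars)), vars)
  load[keep] <- v
  # orientation: building loading positive; fall back to -vegetation
  if (load["p_buildings"] != 0) {
    if (load["p_buildings"] < 0) load <- -load
  } else if (load["p_vegetation"] > 0) load <- -load
  scores <- drop(Z %*% load[keep])
  list(scores = data.frame(site_id = agg$site_id, pc_urb = scores,
                           stringsAsFactors = FALSE),
       loadings = load,
       pve = e$values[1L] / sum(e$values))
}

#' Average urbanisation scores over grouped capture sites
#'
#' When birds of one population were captured at more than one location,
#' the population score is the arithmetic mean of its member sites.
#'
#' @param scores data.frame(site_id, pc_urb) from
#'   \code{\link{scoreUrbanisation}}.
#' @param siteGroups named list: population label -> character vector of
#'   member site_ids (a partition of the scored sites).
#' @return data.frame(population, pc_urb).
#' @export
averageMultisite <- function(scores, siteGroups) {
  out <- lapply(names(siteGroups), function(g) {
    m <- siteGroups[[g]]
    if (!length(m)) stop("empty site group: ", g)
    if (!all(m %in% scores$site_id)) stop("unknown site in group ", g)
    data.frame(population = g,
               pc_urb = mean(scores$pc_urb[match(m, scores$site_id)]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Intraclass correlation coefficient for scorer repeatability
#'
#' Two-way mixed-effects, absolute-agreement, single-measure ICC (ICC(A,1)
#' in the Shrout-Fleiss/McGraw-Wong scheme), computed from the ANOVA mean
#' squares of a sites x replicates table:
#' \deqn{ICC = (MS_R - MS_E) / (MS_R + (k-1) MS_E + k (MS_C - MS_E) / n)}
#' with \eqn{MS_R} the between-site, \eqn{MS_C} the between-replicate and
#' \eqn{MS_E} the residual mean square, \eqn{n} sites and \eqn{k}
#' replicates.
#'
#' @param measurements numeric matrix, sites x replicates (>= 2 replicates,
#'   no missing values).
#' @return ICC value in (-Inf, 1].
#' @export
iccRepeatability <- function(measurements) {
  m <- as.matrix(measurements)
  if (anyNA(m) || ncol(m) < 2)
    stop("need >= 2 complete replicates per site")
  n <- nrow(m); k <- ncol(m)
  if (var(as.vector(m)) == 0 || all(apply(m, 2, var) == 0) &&
      var(rowMeans(m)) == 0)
    stop("zero between-site variance; ICC undefined")
  grand <- mean(m)
  msr <- k * sum((rowMeans(m) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - grand)^2) / (k - 1)
  sse <- sum((m - outer(rowMeans(m), colMeans(m), "+") + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}
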