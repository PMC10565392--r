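#' Shading configuration
#'
#' Parameters of the distance-weighted shading index: the neighbourhood
#' radius, the dbh bounds splitting neighbours into three size classes
#' (class 1 up to 100 mm, class 2 up to 300 mm, class 3 above), and one
#' distance-decay coefficient alpha (m^-1) per class. Larger alpha means
#' a neighbour's shading influence falls off faster with distance.
#'
#' @param alpha Length-3 vector of decay coefficients, one per size class.
#' @param radius Neighbourhood radius in m (neighbours at exactly the
#'   radius are included).
#' @param size_class_bounds Two strictly increasing dbh thresholds (mm).
#' @param alpha_grid Candidate alpha values for [select_alpha()].
#' @return An object of class `shading_config`.
#' @export
shading_config <- function(alpha = c(0.5, 0.2, 0.7), radius = 10,
                           size_class_bounds = c(100, 300),
                           alpha_grid = c(0, 0.1, 0.2, 0.3, 0.5, 0.7, 1.0)) {
  stopifnot(length(alpha) == 3, all(is.finite(alpha)), all(alpha >= 0))
  stopifnot(length(radius) == 1, radius > 0)
  stopifnot(length(size_class_bounds) == 2,
            size_class_bounds[1] < size_class_bounds[2])
  stopifnot(length(alpha_grid) >= 1, all(alpha_grid >= 0))
  structure(list(alpha = alpha, radius = radius,
                 size_class_bounds = size_class_bounds,
                 alpha_grid = sort(unique(alpha_grid))),
            class = "shading_config")
}

size_class <- function(dbh, bounds) {
  1L + (dbh > bounds[1]) + (dbh > bounds[2])
}

#' Shading index of a single focal tree
#'
#' Sum over neighbours strictly larger than the focal tree (by census-1
#' dbh) and within the radius of the neighbour's basal area (m^2) decayed
#' exponentially with distance: sum BA * exp(-alpha_class * distance). A
#' neighbour's decay coefficient is picked by its own size class. Ties in
#' dbh are not "larger" and are excluded; a self-entry in `neighbours`
#' (same tag) is excluded by identity, even at distance zero.
#'
#' @param focal A one-row data.frame with columns `x`, `y`, `dbh1` and
#'   optionally `tag`.
#' @param neighbours A data.frame of candidate neighbours with the same
#'   columns.
#' @param config A [shading_config()].
#' @return Shading index in m^2 (>= 0).
#' @export
shading_index <- function(focal, neighbours, config = shading_config()) {
  stopifnot(nrow(focal) == 1)
  if (is.null(focal$x) || is.na(focal$x) || is.na(focal$y)) {
    stop("focal tree must have coordinates")
  }
  if (nrow(neighbours) == 0) return(0)
  keep <- neighbours$dbh1 > focal$dbh1
  if (!is.null(focal$tag) && !is.null(neighbours$tag)) {
    keep <- keep & neighbours$tag != focal$tag
  }
  nb <- neighbours[keep, , drop = FALSE]
  if (nrow(nb) == 0) return(0)
  d <- sqrt((nb$x - focal$x)^2 + (nb$y - focal$y)^2)
  inr <- d <= config$radius
  if (!any(inr)) return(0)
  a <- config$alpha[size_class(nb$dbh1[inr], config$size_class_bounds)]
  sum(basal_area(nb$dbh1[inr]) * exp(-a * d[inr]))
}

# Per-plot shading components: for each tree, the decay-weighted larger-
# neighbour basal area split by neighbour size class and candidate alpha.
# Returns array [tree, class, alpha]; the index for a given alpha triplet
# is S[, 1, a1] + S[, 2, a2] + S[, 3, a3]. Computing the components once
# makes the full-factorial AIC grid cheap.
plot_shading_components <- function(x, y, dbh, alphas, bounds, radius) {
  n <- length(x)
  S <- array(0, dim = c(n, 3, length(alphas)))
  if (n < 2) return(S)
  d <- as.matrix(stats::dist(cbind(x, y)))
  diag(d) <- Inf                       # self excluded by identity
  larger <- outer(dbh, dbh, FUN = "<") # [i, j]: neighbour j larger than focal i
  within <- d <= radius
  cls <- size_class(dbh, bounds)
  ba <- basal_area(dbh)
  for (cc in 1:3) {
    j <- which(cls == cc)
    if (length(j) == 0) next
    mask <- within[, j, drop = FALSE] & larger[, j, drop = FALSE]
    dsub <- d[, j, drop = FALSE]
    # clamp masked-out (infinite self) distances so alpha = 0 stays finite
    dcl <- pmin(dsub, radius)
    for (ai in seq_along(alphas)) {
      W <- exp(-alphas[ai] * dcl) * mask
      S[, cc, ai] <- W %*% ba[j]
    }
  }
  S
}

#' Shading index for every tree in a census
#'
#' Computes the distance-weighted shading index for all trees, plot by
#' plot. All mapped stems of a plot act as potential neighbours,
#' including trees later excluded as focal trees by the edge buffer.
#'
#' @param census Census data.frame with columns `plot`, `x`, `y`, `dbh1`.
#' @param config A [shading_config()].
#' @return The census with a `shading` column (m^2) appended.
#' @export
compute_shading <- function(census, config = shading_config()) {
  stopifnot(all(c("plot", "x", "y", "dbh1") %in% names(census)))
  shading <- numeric(nrow(census))
  for (pl in unique(census$plot)) {
    idx <- which(census$plot == pl)
    S <- plot_shading_components(census$x[idx], census$y[idx],
                                 census$dbh1[idx], alphas = config$alpha,
                                 bounds = config$size_class_bounds,
                                 radius = config$radius)
    shading[idx] <- S[, 1, 1] + S[, 2, 2] + S[, 3, 3]
  }
  census$shading <- shading
  census
}

#' Exclude trees near plot edges
#'
#' Trees within `radius` of any plot boundary cannot have their shading
#' index computed completely (neighbours outside the plot are unmapped)
#' and are dropped as focal trees. They remain in the full census and
#' still act as neighbours when shading is computed.
#'
#' @param census Census data.frame with `plot`, `x`, `y`.
#' @param plots Plot table with `plot`, `width`, `height`.
#' @param radius Buffer width in m (default 10).
#' @return The census restricted to interior (focal) trees.
#' @export
edge_exclude <- function(census, plots, radius = 10) {
  keep <- is_interior(census, plots, radius)
  if (!any(keep)) warning("no interior trees: plots smaller than twice the edge buffer?")
  census[keep, , drop = FALSE]
}

is_interior <- function(census, plots, radius = 10) {
  m <- match(census$plot, plots$plot)
  if (anyNA(m)) stop("census contains plots absent from the plot table")
  w <- plots$width[m]; h <- plots$height[m]
  census$x > radius & census$x < w - radius &
    census$y > radius & census$y < h - radius
}

#' Shading offset
#'
#' The constant added to the shading index before log-transformation: the
#' global median shading index over all focal trees, so trees with no
#' larger neighbour within the radius stay finite on the log scale. In
#' the degenerate case of a median of zero (very sparse stands where most
#' focal trees have no larger neighbour) the smallest positive index is
#' used instead, with a floor of 1e-6 m^2.
#'
#' @param shading Shading indices of the focal trees.
#' @return The offset (a single number, > 0).
#' @export
shading_offset <- function(shading) {
  m <- stats::median(shading)
  if (!is.finite(m) || m <= 0) {
    pos <- shading[shading > 0]
    m <- if (length(pos) > 0) min(pos) else 1e-6
    m <- max(m, 1e-6)
  }
  m
}

#' Per-species shade association
#'
#' A species' shade association is the median, over its individuals, of
#' the individual's shading index centred on the median shading index of
#' its plot (site). Centring removes among-plot differences in stand
#' density; positive values mark shade-tolerant species, negative values
#' light-demanding ones. Plot medians are computed over the focal
#' (edge-excluded) trees supplied.
#'
#' @param census Focal census with columns `species`, `plot`, `shading`.
#' @return data.frame with columns `species` and `shade_assoc`.
#' @export
shade_association <- function(census) {
  stopifnot(all(c("species", "plot", "shading") %in% names(census)))
  plot_med <- tapply(census$shading, census$plot, stats::median)
  centred <- census$shading - plot_med[as.character(census$plot)]
  out <- tapply(centred, census$species, stats::median)
  data.frame(species = names(out), shade_assoc = as.numeric(out),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select distance-decay coefficients by AIC
#'
#' Exhaustive search over the full factorial grid of candidate alpha
#' values for the three neighbour size classes. For each combination the
#' shading index of every focal survivor is recomputed, the shading
#' offset refreshed, and a pooled (single-level, Gaussian) linear
#' regression of RGR on log(shading + offset), log(dbh), log(resin P) and
#' moisture deficit is fitted; the combination minimizing AIC wins. The
#' pooled preliminary model is deliberately simple: only the AIC ranking
#' across alpha combinations matters, not the model itself.
#'
#' @param census Census data.frame (both censuses) with `plot`, `x`, `y`,
#'   `dbh1`, `dbh2`, `status`, `date1`, `date2`.
#' @param plots Plot table with `plot`, `resin_p`, `moisture`, `width`,
#'   `height`.
#' @param config A [shading_config()]; `alpha_grid` gives the candidates.
#' @return List with `alpha` (the selected triplet), `aic` (its AIC) and
#'   `aic_table` (data.frame of all combinations and AICs).
#' @export
select_alpha <- function(census, plots, config = shading_config()) {
  grid <- config$alpha_grid
  focal <- is_interior(census, plots, config$radius)
  surv <- focal & census$status == "alive" &
    !is.na(census$dbh2) & census$dbh2 > 0
  if (!any(surv)) stop("no focal survivors: cannot select alpha")

  # shading components per plot for the focal survivors only
  n_focal <- sum(surv)
  S <- array(0, dim = c(n_focal, 3, length(grid)))
  focal_rows <- which(surv)
  for (pl in unique(census$plot)) {
    idx <- which(census$plot == pl)
    Sp <- plot_shading_components(census$x[idx], census$y[idx],
                                  census$dbh1[idx], alphas = grid,
                                  bounds = config$size_class_bounds,
                                  radius = config$radius)
    keep <- idx %in% focal_rows
    S[match(idx[keep], focal_rows), , ] <- Sp[keep, , , drop = FALSE]
  }

  rgr <- compute_rgr(census$dbh1[surv], census$dbh2[surv],
                     census$date2[surv] - census$date1[surv])
  m <- match(census$plot[surv], plots$plot)
  log_dbh <- log(census$dbh1[surv])
  log_p <- log(plots$resin_p[m])
  moist <- plots$moisture[m]
  n <- length(rgr)

  combos <- expand.grid(a1 = seq_along(grid), a2 = seq_along(grid),
                        a3 = seq_along(grid))
  aics <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    sh <- S[, 1, combos$a1[i]] + S[, 2, combos$a2[i]] + S[, 3, combos$a3[i]]
    off <- shading_offset(sh)
    X <- cbind(1, log(sh + off), log_dbh, log_p, moist)
    fit <- stats::.lm.fit(X, rgr)
    rss <- sum(fit$residuals^2)
    k <- ncol(X) + 1  # + residual variance
    aics[i] <- n * log(2 * pi * rss / n) + n + 2 * k
  }
  best <- which.min(aics)
  tab <- data.frame(alpha1 = grid[combos$a1], alpha2 = grid[combos$a2],
                    alpha3 = grid[combos$a3], aic = aics)
  list(alpha = c(grid[combos$a1[best]], grid[combos$a2[best]],
                 grid[combos$a3[best]]),
       aic = aics[best], aic_table = tab[order(tab$aic), ])
}
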