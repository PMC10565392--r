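#' Relative growth rate from two diameter measurements
#'
#' RGR is the difference in log stem diameter between two censuses divided
#' by the census interval, in mm mm^-1 yr^-1. Negative values (apparent
#' shrinkage, usually measurement error) are retained; the robust Student-t
#' growth likelihood absorbs them through its normality parameter.
#'
#' @param dbh1,dbh2 Stem diameter at breast height (mm) at the first and
#'   second census. Must be positive.
#' @param interval Census interval in years. Must be positive.
#' @return Numeric vector of relative growth rates (mm mm^-1 yr^-1).
#' @examples
#' compute_rgr(100, 110, 5)
#' @export
compute_rgr <- function(dbh1, dbh2, interval) {
  if (any(!is.finite(dbh1)) || any(dbh1 <= 0)) stop("dbh1 must be positive and finite")
  if (any(!is.finite(dbh2)) || any(dbh2 <= 0)) stop("dbh2 must be positive and finite")
  if (any(!is.finite(interval)) || any(interval <= 0)) stop("interval must be positive and finite")
  (log(dbh2) - log(dbh1)) / interval
}

#' Basal area from diameter
#'
#' @param dbh Diameter at breast height in mm.
#' @return Basal area in m^2: pi * (dbh / 2000)^2.
#' @export
basal_area <- function(dbh) pi * (dbh / 2000)^2

# Names of the five first-level coefficients, in model order:
# intercept, log(shading + offset), log(dbh), log(resin P), moisture deficit.
COEF_NAMES <- c("intercept", "shading", "size", "p", "moisture")

# Names of the eight second-level design columns: intercept, the three
# species associations, their pairwise products and the triple product.
ASSOC_NAMES <- c("intercept", "p", "s", "m", "ps", "pm", "sm", "psm")

#' First-level covariate matrix
#'
#' Builds the design matrix of the first level of both demographic models:
#' an intercept, log(shading index + offset), log(dbh), log(resin P) and
#' the raw dry-season moisture deficit (mm, negative). The offset added to
#' the shading index before logging is the median shading index of the
#' focal trees, which keeps trees with no larger neighbour finite.
#'
#' @param shading Shading index (m^2) per tree.
#' @param dbh Initial dbh (mm) per tree.
#' @param resin_p Resin-extractable soil P (mg P kg^-1) of each tree's plot.
#' @param moisture Dry-season moisture deficit (mm) of each tree's plot.
#' @param offset Shading offset (m^2) added before the log transform.
#' @return Numeric matrix with columns intercept, shading, size, p, moisture.
#' @export
demog_covariates <- function(shading, dbh, resin_p, moisture, offset) {
  stopifnot(length(offset) == 1, is.finite(offset))
  if (any(shading + offset <= 0)) stop("shading + offset must be positive before logging")
  if (any(resin_p <= 0)) stop("resin P must be positive before logging")
  if (any(dbh <= 0)) stop("dbh must be positive before logging")
  X <- cbind(1, log(shading + offset), log(dbh), log(resin_p), moisture)
  colnames(X) <- COEF_NAMES
  if (any(!is.finite(X))) stop("non-finite covariates")
  X
}

#' Predicted relative growth rate
#'
#' Linear predictor of the growth model: beta0 + beta1 log(shading+offset)
#' + beta2 log(dbh) + beta3 log(resin P) + beta4 moisture deficit.
#'
#' @param beta Numeric vector of 5 coefficients (see [demog_covariates()]
#'   for the order), or a matrix with 5 columns (one row per observation).
#' @param x Covariate vector of length 5, or a matrix with 5 columns.
#' @return Predicted RGR (mm mm^-1 yr^-1).
#' @export
growth_predictor <- function(beta, x) {
  linear_predictor(beta, x)
}

linear_predictor <- function(beta, x) {
  if (is.matrix(x) && !is.matrix(beta)) return(drop(x %*% beta))
  if (is.matrix(x) && is.matrix(beta)) {
    stopifnot(nrow(x) == nrow(beta))
    return(rowSums(x * beta))
  }
  stopifnot(length(beta) == length(x))
  sum(beta * x)
}

#' Log density of the robust Student-t growth likelihood
#'
#' Location-scale Student-t log density: observed RGR is t-distributed
#' around the predicted RGR with scale `sigma` and normality (degrees of
#' freedom) `nu`. Small `nu` gives fat tails, making the fit robust to
#' growth outliers; `nu` above about 30 is practically Gaussian.
#'
#' @param rgr_obs Observed RGR.
#' @param rgr_pred Predicted RGR (same length or scalar).
#' @param sigma Scale parameter, > 0.
#' @param nu Normality parameter, > 0 (> 1 under the model prior).
#' @return Log density, vectorized over observations.
#' @export
growth_loglik <- function(rgr_obs, rgr_pred, sigma, nu) {
  if (any(!is.finite(sigma) | sigma <= 0)) stop("sigma must be > 0")
  if (any(!is.finite(nu) | nu <= 0)) stop("nu must be > 0")
  z <- (rgr_obs - rgr_pred) / sigma
  lgamma((nu + 1) / 2) - lgamma(nu / 2) - 0.5 * log(nu * pi) - log(sigma) -
    (nu + 1) / 2 * log1p(z^2 / nu)
}

#' Annual mortality probability
#'
#' Logistic-link annual probability of mortality from the five-coefficient
#' linear predictor on the mortality covariates.
#'
#' @inheritParams growth_predictor
#' @return Probability in (0, 1).
#' @export
annual_mortality <- function(beta, x) {
  plogis(linear_predictor(beta, x))
}

#' Mortality probability over a census interval
#'
#' Annual survival raised to the power of the census interval:
#' p_interval = 1 - (1 - p_annual)^T. This makes plots with census
#' intervals from a few to many years comparable on an annual scale.
#'
#' @param p_annual Annual mortality probability in \[0, 1\].
#' @param interval Census interval in years, > 0.
#' @return Interval mortality probability.
#' @export
interval_mortality <- function(p_annual, interval) {
  if (any(p_annual < 0 | p_annual > 1, na.rm = TRUE)) stop("p_annual must be in [0,1]")
  if (any(interval <= 0)) stop("interval must be > 0")
  # expm1/log1p form keeps precision for small annual rates
  -expm1(interval * log1p(-p_annual))
}

#' Bernoulli log probability of observed status
#'
#' @param status 0 (alive) or 1 (dead) at the second census.
#' @param p_mortality Interval mortality probability in \[0, 1\].
#' @return Log probability; -Inf where an impossible outcome was observed
#'   (dead with p = 0 or alive with p = 1).
#' @export
mortality_loglik <- function(status, p_mortality) {
  if (any(!status %in% c(0, 1))) stop("status must be 0 or 1")
  if (any(p_mortality < 0 | p_mortality > 1)) stop("p_mortality must be in [0,1]")
  ll <- ifelse(status == 1, log(p_mortality), log1p(-p_mortality))
  ll[status == 1 & p_mortality == 0] <- -Inf
  ll[status == 0 & p_mortality == 1] <- -Inf
  ll
}

#' Second-level mean of a species coefficient
#'
#' The species-level coefficient beta_k is modelled as Normal(mu_k, sigma_k)
#' where mu_k is linear in the species' P, shade and moisture associations,
#' their three pairwise interactions and the triple interaction:
#' mu_k = g0 + g1 P + g2 S + g3 M + g4 PS + g5 PM + g6 SM + g7 PSM.
#'
#' @param gamma_row Numeric vector of 8 second-level coefficients.
#' @param p_assoc,shade_assoc,moisture_assoc Species association effect sizes.
#' @return mu_k, vectorized over species.
#' @export
second_level_mean <- function(gamma_row, p_assoc, shade_assoc, moisture_assoc) {
  stopifnot(length(gamma_row) == 8)
  A <- assoc_design(p_assoc, shade_assoc, moisture_assoc)
  drop(A %*% gamma_row)
}

#' Second-level design matrix from species associations
#'
#' @inheritParams second_level_mean
#' @return Matrix with columns intercept, p, s, m, ps, pm, sm, psm.
#' @export
assoc_design <- function(p_assoc, shade_assoc, moisture_assoc) {
  A <- cbind(1, p_assoc, shade_assoc, moisture_assoc,
             p_assoc * shade_assoc, p_assoc * moisture_assoc,
             shade_assoc * moisture_assoc,
             p_assoc * shade_assoc * moisture_assoc)
  colnames(A) <- ASSOC_NAMES
  A
}

#' Maximum-likelihood annual mortality rate from interval data
#'
#' Estimates a single annual mortality probability from dead/alive status
#' over heterogeneous census intervals. The interval-aware estimator
#' maximizes the Bernoulli likelihood with p_i = 1 - (1 - p)^T_i; the
#' naive variant ignores the intervals and returns the raw death fraction,
#' which is biased whenever intervals differ from one year.
#'
#' @param status 0/1 vector (1 = dead).
#' @param interval Census interval in years per tree.
#' @param interval_aware If `FALSE`, return the pooled death fraction.
#' @return Estimated annual mortality probability.
#' @export
annual_mortality_mle <- function(status, interval, interval_aware = TRUE) {
  stopifnot(length(status) == length(interval))
  if (!interval_aware) return(mean(status))
  nll <- function(p) -sum(mortality_loglik(status, interval_mortality(p, interval)))
  stats::optimize(nll, c(1e-8, 1 - 1e-8))$minimum
}
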