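#' Standardized environmental scenario
#'
#' A fixed environment at which species demographic rates are compared:
#' resin P at a chosen quantile of the plot distribution, moisture
#' deficit and shading at their medians, and dbh fixed at 100 mm.
#' Quantiles use linear interpolation between order statistics (R's
#' default type-7 rule). The shading value is the raw index median; the
#' shading offset is applied afterwards, when the predictor is evaluated.
#'
#' @param plots Plot table with `resin_p` and `moisture`.
#' @param census Focal census with a `shading` column (supplies the
#'   shading median).
#' @param p_quantile Quantile of resin P in \[0, 1\] (e.g. 0.05, 0.5,
#'   0.95 for infertile, intermediate and fertile conditions).
#' @param dbh Reference dbh in mm (default 100).
#' @return An object of class `demog_scenario`.
#' @export
scenario_from_data <- function(plots, census, p_quantile = 0.5, dbh = 100) {
  if (nrow(plots) == 0) stop("plot table is empty")
  if (p_quantile < 0 || p_quantile > 1) stop("quantile must be in [0,1]")
  if (is.null(census$shading)) stop("census must carry shading indices")
  structure(list(resin_p = unname(stats::quantile(plots$resin_p, p_quantile)),
                 moisture = unname(stats::quantile(plots$moisture, 0.5)),
                 shading = unname(stats::quantile(census$shading, 0.5)),
                 dbh = dbh, p_quantile = p_quantile),
            class = "demog_scenario")
}

#' @export
print.demog_scenario <- function(x, ...) {
  cat("Scenario: resin P ", signif(x$resin_p, 3), " mg/kg (q",
      x$p_quantile, "), moisture ", signif(x$moisture, 4),
      " mm, shading ", signif(x$shading, 3), ", dbh ", x$dbh, " mm\n", sep = "")
  invisible(x)
}

#' Species eligible for interspecific comparisons
#'
#' Keeps species with at least 10 individuals and a maximum initial dbh
#' of at least 100 mm in the analysis census, the filter applied before
#' all interspecific regressions.
#'
#' @param census Analysis census with `species` and `dbh1`.
#' @param min_n Minimum number of individuals (default 10, inclusive).
#' @param min_max_dbh Minimum maximum dbh in mm (default 100, inclusive).
#' @return Character vector of eligible species names.
#' @export
species_filter <- function(census, min_n = 10, min_max_dbh = 100) {
  n <- table(census$species)
  mx <- tapply(census$dbh1, census$species, max)
  names(n)[n >= min_n & mx[names(n)] >= min_max_dbh]
}

#' Per-species demographic predictions at a standardized scenario
#'
#' Evaluates, for every posterior draw, the species' predicted RGR
#' (growth fit) or annual mortality (mortality fit) at the scenario
#' covariates, and summarizes as posterior median and central 95%
#' interval. The shading offset stored in the fit (the one used when the
#' model was fitted) is added to the scenario's raw shading index before
#' logging.
#'
#' @param fit A `demog_fit`.
#' @param scenario A [scenario_from_data()] scenario.
#' @return data.frame with one row per species: `species`, `estimate`,
#'   `lower`, `upper`, `n_individuals`, `max_dbh`, `p_assoc`,
#'   `shade_assoc`, `m_assoc`.
#' @export
predict_species <- function(fit, scenario) {
  stopifnot(inherits(fit, "demog_fit"), inherits(scenario, "demog_scenario"))
  x <- c(1, log(scenario$shading + fit$offset), log(scenario$dbh),
         log(scenario$resin_p), scenario$moisture)
  draws <- vapply(COEF_NAMES, function(k) species_coef_draws(fit, k),
                  matrix(0, prod(dim(fit$draws)[1:2]), length(fit$species)),
                  USE.NAMES = TRUE)  # draws x species x coef
  eta <- matrix(0, dim(draws)[1], dim(draws)[2])
  for (k in seq_along(COEF_NAMES)) eta <- eta + draws[, , k] * x[k]
  if (fit$kind == "mortality") eta <- plogis(eta)
  q <- t(apply(eta, 2, stats::quantile, c(0.025, 0.5, 0.975), names = FALSE))
  st <- fit$species_table
  m <- match(fit$species, st$species)
  data.frame(species = fit$species, estimate = q[, 2], lower = q[, 1],
             upper = q[, 3], n_individuals = fit$n_per_species,
             max_dbh = as.numeric(fit$max_dbh),
             p_assoc = st$p_assoc[m], shade_assoc = st$shade_assoc[m],
             m_assoc = st$m_assoc[m],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Abundance-weighted association regression with backward selection
#'
#' Weighted least-squares regression of a predicted demographic rate on
#' the three species associations (P, shade, moisture), weighted by the
#' species' individual counts, followed by backward elimination by AIC
#' (`stats::step`). Mortality is log-transformed (toward normality)
#' before regression.
#'
#' @param predictions Output of [predict_species()], restricted to
#'   eligible species (see [species_filter()]).
#' @param response `"rgr"` for growth predictions or `"log_mortality"`
#'   for mortality predictions (log-transforms `estimate`).
#' @param select Run backward AIC elimination (default `TRUE`).
#' @return List of class `assoc_regression`: the final `lm` fit,
#'   `retained` predictor names, `coefficients`, `r_squared`, `p_values`,
#'   `n`, and a `weights` description.
#' @export
association_regression <- function(predictions,
                                   response = c("rgr", "log_mortality"),
                                   select = TRUE) {
  response <- match.arg(response)
  if (nrow(predictions) < 3) stop("need at least 3 species")
  df <- data.frame(y = if (response == "rgr") predictions$estimate
                   else log(predictions$estimate),
                   p_assoc = predictions$p_assoc,
                   shade_assoc = predictions$shade_assoc,
                   m_assoc = predictions$m_assoc,
                   w = predictions$n_individuals)
  full <- stats::lm(y ~ p_assoc + shade_assoc + m_assoc, data = df, weights = w)
  qrx <- qr(stats::model.matrix(full))
  if (qrx$rank < ncol(stats::model.matrix(full))) {
    stop("degenerate design: rank ", qrx$rank, " < ",
         ncol(stats::model.matrix(full)), " columns")
  }
  fit <- if (select) stats::step(full, direction = "backward", trace = 0) else full
  sm <- summary(fit)
  structure(list(fit = fit, response = response,
                 retained = setdiff(names(stats::coef(fit)), "(Intercept)"),
                 coefficients = stats::coef(fit),
                 r_squared = sm$r.squared,
                 p_values = sm$coefficients[, 4],
                 n = nrow(df),
                 weights = "species individual counts"),
            class = "assoc_regression")
}

#' @export
print.assoc_regression <- function(x, ...) {
  cat("Abundance-weighted regression of", x$response, "on species associations\n")
  cat("  retained:", if (length(x$retained)) paste(x$retained, collapse = ", ")
      else "(intercept only)", "\n")
  cat("  R^2 =", round(x$r_squared, 3), " n =", x$n, "\n")
  invisible(x)
}

#' Growth-mortality trade-off regressions by P-association group
#'
#' Splits species into low-P (P association < 0) and high-P (>= 0)
#' groups and, within each group, regresses log annual mortality on RGR
#' (both predicted at the all-median scenario), weighted by species
#' individual counts. A positive slope within a group is the classic
#' growth-mortality trade-off.
#'
#' @param growth_pred,mortality_pred Outputs of [predict_species()] at
#'   the median scenario, already filtered to eligible species.
#' @param log_mortality Regress log mortality (default) or raw mortality.
#' @return data.frame with one row per group: `group`, `slope`,
#'   `intercept`, `r_squared`, `p_value`, `n`.
#' @export
tradeoff_regression <- function(growth_pred, mortality_pred,
                                log_mortality = TRUE) {
  m <- merge(growth_pred[, c("species", "estimate", "n_individuals", "p_assoc")],
             mortality_pred[, c("species", "estimate")],
             by = "species", suffixes = c("_rgr", "_mort"))
  m$group <- ifelse(m$p_assoc < 0, "low-P", "high-P")
  out <- lapply(c("low-P", "high-P"), function(gr) {
    d <- m[m$group == gr, ]
    if (nrow(d) < 3) {
      warning("group ", gr, " has fewer than 3 species: skipped")
      return(NULL)
    }
    y <- if (log_mortality) log(d$estimate_mort) else d$estimate_mort
    fit <- stats::lm(y ~ estimate_rgr, data = data.frame(y = y,
                     estimate_rgr = d$estimate_rgr),
                     weights = d$n_individuals)
    sm <- summary(fit)
    data.frame(group = gr, slope = stats::coef(fit)[2],
               intercept = stats::coef(fit)[1],
               r_squared = sm$r.squared,
               p_value = sm$coefficients[2, 4], n = nrow(d),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
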