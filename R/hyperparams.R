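#' Hyperparameters of the two-level demographic model
#'
#' Bundles the second-level coefficient matrix `gamma` (5 first-level
#' coefficients x 8 association terms), the hyper-standard-deviations
#' `sigma_k` of the species coefficients around their second-level means,
#' and, for the growth model, the global Student-t scale `sigma` and
#' normality `nu`.
#'
#' @param gamma 5 x 8 numeric matrix. Rows follow the first-level
#'   coefficient order (intercept, shading, size, p, moisture); columns
#'   the second-level terms (intercept, p, s, m, ps, pm, sm, psm).
#' @param sigma_k Length-5 positive vector of hyper-SDs.
#' @param sigma,nu Growth-only globals (t scale > 0, normality > 1);
#'   leave `NULL` for mortality.
#' @param kind `"growth"` or `"mortality"`.
#' @return An object of class `hyperparameters`.
#' @export
hyperparameters <- function(gamma, sigma_k, sigma = NULL, nu = NULL,
                            kind = c("growth", "mortality")) {
  kind <- match.arg(kind)
  gamma <- as.matrix(gamma)
  stopifnot(identical(dim(gamma), c(5L, 8L)), all(is.finite(gamma)))
  stopifnot(length(sigma_k) == 5, all(sigma_k > 0))
  dimnames(gamma) <- list(COEF_NAMES, ASSOC_NAMES)
  names(sigma_k) <- COEF_NAMES
  if (kind == "growth") {
    stopifnot(is.numeric(sigma), sigma > 0, is.numeric(nu), nu > 1)
  } else {
    sigma <- NULL; nu <- NULL
  }
  structure(list(gamma = gamma, sigma_k = sigma_k, sigma = sigma, nu = nu,
                 kind = kind), class = "hyperparameters")
}

#' @export
print.hyperparameters <- function(x, ...) {
  cat("Hyperparameters (", x$kind, ")\n", sep = "")
  cat("gamma (5 coefficients x 8 association terms):\n")
  print(signif(x$gamma, 3))
  cat("sigma_k:", signif(x$sigma_k, 3), "\n")
  if (x$kind == "growth") cat("sigma:", x$sigma, " nu:", x$nu, "\n")
  invisible(x)
}

#' Default generating hyperparameters for the synthetic community
#'
#' Growth defaults place typical RGR near 0.025 mm mm^-1 yr^-1 with a
#' negative shading response, a negative size response, a positive mean
#' soil-P response whose strength increases with species P association
#' (gamma\[p, p\] > 0), and faster intrinsic growth for low-P-associated
#' and light-demanding species. Mortality defaults give ~2% yr^-1 annual
#' mortality on average, a soil-P response that decreases with P
#' association (gamma\[p, p\] < 0, so low-P species lose their survival
#' advantage on fertile soils), and higher mortality for low-P-associated
#' and light-demanding species. Together these encode the community
#' structure the analysis pipeline is expected to detect.
#'
#' @return A [hyperparameters()] object.
#' @export
default_growth_hyperparams <- function() {
  g <- matrix(0, 5, 8, dimnames = list(COEF_NAMES, ASSOC_NAMES))
  g["intercept", "intercept"] <- -0.24
  g["intercept", "p"] <- -0.004    # low-P species intrinsically faster
  g["intercept", "s"] <- -0.002    # light-demanding species faster
  g["shading", "intercept"] <- -0.05
  g["shading", "s"] <- 0.002       # shade-tolerants less hurt by shading
  g["size", "intercept"] <- -0.008
  g["p", "intercept"] <- 0.004
  g["p", "p"] <- 0.003             # high-P species respond more to P
  g["p", "ps"] <- 0.001
  g["moisture", "intercept"] <- -2e-5
  hyperparameters(g, sigma_k = c(0.008, 0.002, 0.003, 0.002, 5e-6),
                  sigma = 0.012, nu = 2.16, kind = "growth")
}

#' @rdname default_growth_hyperparams
#' @export
default_mortality_hyperparams <- function() {
  g <- matrix(0, 5, 8, dimnames = list(COEF_NAMES, ASSOC_NAMES))
  g["intercept", "intercept"] <- -3.65
  g["intercept", "p"] <- 0.3       # high-P species die more at median P
  g["intercept", "s"] <- -0.2      # shade-tolerants die less
  g["size", "intercept"] <- -0.1
  g["p", "p"] <- -0.25             # low-P species' mortality rises with P
  g["moisture", "intercept"] <- -0.001
  hyperparameters(g, sigma_k = c(0.4, 0.05, 0.05, 0.05, 2e-4),
                  kind = "mortality")
}
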