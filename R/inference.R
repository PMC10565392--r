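#' MCMC configuration
#'
#' Chain protocol and priors for the hierarchical fits. Defaults are the
#' desk-scale protocol (3 chains, 2000 warm-up + 2000 recorded draws);
#' the long protocol used for full field datasets (3 chains, 300000
#' burn-in + 10000 draws) is available by overriding `n_burnin` and
#' `n_samples`. Priors: second-level coefficients gamma ~ Normal(0, sd
#' `gamma_sd`); hyper-SDs and the growth t scale uniform on their ranges;
#' normality nu = 1 + Exponential(mean `nu_mean`), sampled on log(nu - 1).
#'
#' @param n_chains Number of chains (>= 2, needed for convergence
#'   diagnostics).
#' @param n_burnin,n_samples,thin Warm-up iterations, recorded draws per
#'   chain, thinning interval.
#' @param seed Integer seed; chain c runs under `seed + (c-1) * 1009`.
#' @param rhat_threshold Gelman-Rubin threshold above which a warning is
#'   issued (default 1.1).
#' @param gamma_sd Prior SD of the second-level coefficients (default 10,
#'   the weakly-informative reading of a BUGS-style precision of 0.01).
#' @param sigma_k_range,sigma_range Uniform prior bounds for the
#'   hyper-SDs and the growth t scale (default 1/1000 to 1000). With
#'   covariates on raw scales (moisture deficit in mm) some coefficient
#'   rows live below 1/1000; lower `sigma_k_range[1]` in that case.
#' @param nu_mean Mean of the exponential prior on nu - 1 (default 29,
#'   giving prior mean nu = 30).
#' @param fixed_hyper If `TRUE`, hold gamma and sigma_k fixed at
#'   `fixed_gamma` / `fixed_sigma_k` (used for reduced, non-hierarchical
#'   fits: the species coefficients then have independent
#'   Normal(A gamma_k, sigma_k) priors).
#' @param fixed_gamma,fixed_sigma_k Values used when `fixed_hyper = TRUE`
#'   (defaults: zero matrix; unit SDs).
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3, n_burnin = 2000, n_samples = 2000,
                        thin = 1, seed = 1, rhat_threshold = 1.1,
                        gamma_sd = 10, sigma_k_range = c(1e-3, 1e3),
                        sigma_range = c(1e-3, 1e3), nu_mean = 29,
                        fixed_hyper = FALSE, fixed_gamma = NULL,
                        fixed_sigma_k = NULL) {
  stopifnot(n_chains >= 2, n_burnin > 0, n_samples > 0, thin >= 1)
  stopifnot(sigma_k_range[1] > 0, sigma_k_range[1] < sigma_k_range[2])
  stopifnot(sigma_range[1] > 0, sigma_range[1] < sigma_range[2])
  structure(list(n_chains = n_chains, n_burnin = n_burnin,
                 n_samples = n_samples, thin = thin, seed = seed,
                 rhat_threshold = rhat_threshold, gamma_sd = gamma_sd,
                 sigma_k_range = sigma_k_range, sigma_range = sigma_range,
                 nu_mean = nu_mean, fixed_hyper = fixed_hyper,
                 fixed_gamma = fixed_gamma, fixed_sigma_k = fixed_sigma_k),
            class = "mcmc_config")
}

#' Prepare a model dataset from census tables
#'
#' Computes shading indices at the given distance-decay coefficients,
#' applies the edge buffer, selects the model population (growth: trees
#' alive at both censuses with valid positive dbh at both, the smaller
#' dataset; mortality: all trees alive at census 1), sets the shading
#' offset to the median index of the selected trees, and assembles the
#' covariates, response and second-level association design.
#'
#' @param census Census table (`tag`, `species`, `plot`, `x`, `y`,
#'   `dbh1`, `dbh2`, `status`, `date1`, `date2`).
#' @param plots Plot table (`plot`, `resin_p`, `moisture`, `width`,
#'   `height`).
#' @param species Species table with `species`, `p_assoc`, `shade_assoc`,
#'   `m_assoc` (associations are exogenous inputs; `shade_assoc` may come
#'   from [shade_association()]).
#' @param kind `"growth"` or `"mortality"`.
#' @param shading A [shading_config()] giving the alpha triplet.
#' @return An object of class `demog_data`.
#' @export
prepare_data <- function(census, plots, species,
                         kind = c("growth", "mortality"),
                         shading = shading_config()) {
  kind <- match.arg(kind)
  if (is.null(census$shading)) census <- compute_shading(census, shading)
  census <- edge_exclude(census, plots, shading$radius)
  if (kind == "growth") {
    keep <- census$status == "alive" & !is.na(census$dbh2) & census$dbh2 > 0 &
      census$dbh1 > 0
  } else {
    keep <- census$dbh1 > 0
  }
  census <- census[keep, , drop = FALSE]
  miss <- setdiff(unique(census$species), species$species)
  if (length(miss) > 0) {
    stop("species present in data but missing associations: ",
         paste(miss, collapse = ", "))
  }
  species <- species[species$species %in% census$species, , drop = FALSE]
  species <- species[order(species$species), , drop = FALSE]
  census <- census[order(census$species), , drop = FALSE]
  off <- shading_offset(census$shading)
  m <- match(census$plot, plots$plot)
  X <- demog_covariates(census$shading, census$dbh1, plots$resin_p[m],
                        plots$moisture[m], off)
  interval <- census$date2 - census$date1
  y <- if (kind == "growth") {
    compute_rgr(census$dbh1, census$dbh2, interval)
  } else {
    as.numeric(census$status == "dead")
  }
  sp <- factor(census$species, levels = species$species)
  A <- assoc_design(species$p_assoc, species$shade_assoc, species$m_assoc)
  rownames(A) <- species$species
  structure(list(kind = kind, X = X, y = y, interval = interval,
                 species = sp, A = A, offset = off,
                 species_table = species, alpha = shading$alpha,
                 n_per_species = as.integer(table(sp)),
                 max_dbh = tapply(census$dbh1, sp, max)),
            class = "demog_data")
}

#' @export
print.demog_data <- function(x, ...) {
  cat("demog_data (", x$kind, "): ", length(x$y), " trees, ",
      nlevels(x$species), " species; shading offset ",
      signif(x$offset, 3), "\n", sep = "")
  invisible(x)
}

chain_inits <- function(data, config, chain) {
  X <- data$X
  sdx <- pmax(apply(X, 2, stats::sd), 0.5)
  if (data$kind == "growth") {
    ls <- stats::.lm.fit(X, data$y)
    bhat <- ls$coefficients
    rsd <- stats::sd(ls$residuals)
    prop_scale <- rsd / sdx / sqrt(length(data$y) / nlevels(data$species))
  } else {
    p0 <- annual_mortality_mle(data$y, data$interval)
    bhat <- c(stats::qlogis(p0), 0, 0, 0, 0)
    rsd <- 1
    prop_scale <- 2 / sdx / sqrt(length(data$y) / nlevels(data$species))
  }
  S <- nlevels(data$species)
  jit <- function(scale, n) stats::rnorm(n, 0, scale)
  beta <- matrix(rep(bhat, each = S), S, 5) +
    matrix(jit(rep(prop_scale, each = S), S * 5), S, 5)
  gamma <- matrix(0, 5, 8)
  gamma[, 1] <- bhat + jit(prop_scale, 5)
  sk <- pmin(pmax(prop_scale, config$sigma_k_range[1] * 1.05),
             config$sigma_k_range[2] * 0.95)
  list(beta = beta, gamma = gamma, sigma_k = sk,
       sigma = min(max(rsd * stats::runif(1, 0.5, 2), config$sigma_range[1] * 1.05),
                   config$sigma_range[2] * 0.95),
       nu = 1 + stats::rexp(1, 1 / 5),
       prop_scale = prop_scale)
}

fit_demog <- function(data, config) {
  stopifnot(inherits(data, "demog_data"), inherits(config, "mcmc_config"))
  S <- nlevels(data$species)
  spi <- as.integer(data$species) - 1L
  stopifnot(!is.unsorted(spi))
  start <- match(0:(S - 1), spi) - 1L
  end <- c(start[-1], length(spi))
  prior <- list(gamma_sd = config$gamma_sd,
                sigma_k_lo = config$sigma_k_range[1],
                sigma_k_hi = config$sigma_k_range[2],
                sigma_lo = config$sigma_range[1],
                sigma_hi = config$sigma_range[2],
                nu_mean = config$nu_mean)
  growth <- data$kind == "growth"
  pn <- c(paste0("beta[", rep(levels(data$species), each = 5), ",",
                 rep(COEF_NAMES, S), "]"),
          paste0("gamma[", rep(COEF_NAMES, each = 8), ",",
                 rep(ASSOC_NAMES, 5), "]"),
          paste0("sigma_k[", COEF_NAMES, "]"),
          if (growth) c("sigma", "nu"))
  draws <- array(NA_real_, dim = c(config$n_samples, config$n_chains, length(pn)),
                 dimnames = list(NULL, paste0("chain", seq_len(config$n_chains)), pn))
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + (ch - 1L) * 1009L)
    ini <- chain_inits(data, config, ch)
    if (config$fixed_hyper) {
      ini$gamma <- if (is.null(config$fixed_gamma)) matrix(0, 5, 8)
                   else config$fixed_gamma
      ini$sigma_k <- if (is.null(config$fixed_sigma_k)) rep(1, 5)
                     else config$fixed_sigma_k
    }
    out <- run_demog_chain(data$X, data$y, start, end, data$A, growth,
                           as.numeric(data$interval), ini, prior,
                           config$n_burnin, config$n_samples, config$thin,
                           config$fixed_hyper)
    draws[, ch, ] <- out
  }
  rhat <- apply(draws, 3, function(m) gelman_rubin(m, warn_degenerate = FALSE))
  flagged <- names(rhat)[!is.na(rhat) & rhat > config$rhat_threshold]
  if (!config$fixed_hyper && length(flagged) > 0) {
    warning(length(flagged), " parameter(s) with Rhat > ",
            config$rhat_threshold, " (worst: ",
            flagged[which.max(rhat[flagged])], " = ",
            round(max(rhat[flagged], na.rm = TRUE), 3), ")")
  }
  structure(list(kind = data$kind, draws = draws, rhat = rhat,
                 species = levels(data$species), offset = data$offset,
                 alpha = data$alpha, config = config,
                 species_table = data$species_table,
                 n_per_species = data$n_per_species,
                 max_dbh = data$max_dbh),
            class = "demog_fit")
}

#' Fit the hierarchical growth model
#'
#' Samples the joint posterior of the two-level growth model: per-species
#' coefficient vectors (Student-t likelihood on observed RGR with global
#' scale sigma and normality nu), second-level coefficients gamma linking
#' species coefficients to their P, shade and moisture associations, and
#' hyper-SDs sigma_k. Sampling uses an adaptive Metropolis-within-Gibbs
#' scheme with exact conjugate draws for the gamma rows; proposals adapt
#' only during warm-up. Gelman-Rubin diagnostics are computed for every
#' parameter and a warning (not an error) is raised when any exceeds the
#' configured threshold.
#'
#' @param data A `demog_data` from [prepare_data()] with `kind = "growth"`.
#' @param config An [mcmc_config()].
#' @return A `demog_fit` object: draws array (iteration x chain x
#'   parameter), per-parameter Rhat, and dataset metadata.
#' @export
fit_growth <- function(data, config = mcmc_config()) {
  stopifnot(data$kind == "growth")
  fit_demog(data, config)
}

#' Fit the hierarchical mortality model
#'
#' As [fit_growth()], for the interval-censored Bernoulli mortality model
#' (no sigma/nu): annual mortality is logistic in the covariates and the
#' interval mortality is 1 - (1 - p_annual)^interval.
#'
#' @param data A `demog_data` from [prepare_data()] with
#'   `kind = "mortality"`.
#' @param config An [mcmc_config()].
#' @return A `demog_fit` object.
#' @export
fit_mortality <- function(data, config = mcmc_config()) {
  stopifnot(data$kind == "mortality")
  fit_demog(data, config)
}

#' @export
print.demog_fit <- function(x, ...) {
  cat("Hierarchical ", x$kind, " fit: ", length(x$species), " species, ",
      dim(x$draws)[2], " chains x ", dim(x$draws)[1], " draws\n", sep = "")
  cat("  max Rhat: ", round(max(x$rhat, na.rm = TRUE), 3), "\n", sep = "")
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic between/within-chain variance diagnostic for one parameter:
#' with m chains of n draws, W the mean within-chain variance and B/n the
#' variance of the chain means, the pooled variance estimate is
#' V = (n-1)/n W + B/n and Rhat = sqrt(V / W). Values near 1 indicate the
#' chains have mixed; 1.1 is the conventional convergence threshold.
#'
#' @param x Matrix of draws, iterations in rows, one column per chain.
#' @param warn_degenerate Warn when the within-chain variance is zero
#'   (constant chains), for which Rhat is undefined (`NA`).
#' @return Rhat (a single number).
#' @export
gelman_rubin <- function(x, warn_degenerate = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (m < 2) stop("need at least 2 chains")
  if (n < 10) stop("need at least 10 iterations per chain")
  W <- mean(apply(x, 2, stats::var))
  B_over_n <- stats::var(colMeans(x))
  if (W <= 0) {
    if (B_over_n <= 0) return(1)  # all chains constant and equal
    if (warn_degenerate) warning("zero within-chain variance: Rhat degenerate")
    return(NA_real_)
  }
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Posterior summaries
#'
#' Median and central 95% interval (2.5th/50th/97.5th percentiles pooled
#' across chains), Rhat and a significance flag (interval excludes zero)
#' for each requested parameter.
#'
#' @param fit A `demog_fit`.
#' @param pars Character vector of parameter names (default: all).
#' @return data.frame with columns `parameter`, `median`, `lower`,
#'   `upper`, `rhat`, `significant`.
#' @export
posterior_summary <- function(fit, pars = NULL) {
  stopifnot(inherits(fit, "demog_fit"))
  all_pars <- dimnames(fit$draws)[[3]]
  if (is.null(pars)) pars <- all_pars
  unknown <- setdiff(pars, all_pars)
  if (length(unknown) > 0) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  q <- t(vapply(pars, function(p) {
    stats::quantile(fit$draws[, , p], c(0.025, 0.5, 0.975), names = FALSE)
  }, numeric(3)))
  data.frame(parameter = pars, median = q[, 2], lower = q[, 1],
             upper = q[, 3], rhat = unname(fit$rhat[pars]),
             significant = q[, 1] > 0 | q[, 3] < 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Extract per-species coefficient draws
#'
#' @param fit A `demog_fit`.
#' @param coef One of `"intercept"`, `"shading"`, `"size"`, `"p"`,
#'   `"moisture"`.
#' @return Matrix (pooled draws x species).
#' @export
species_coef_draws <- function(fit, coef = COEF_NAMES) {
  coef <- match.arg(coef)
  pn <- paste0("beta[", fit$species, ",", coef, "]")
  d <- fit$draws[, , pn, drop = FALSE]
  out <- matrix(d, prod(dim(d)[1:2]), length(pn))
  colnames(out) <- fit$species
  out
}
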