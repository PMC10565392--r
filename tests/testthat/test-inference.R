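# MCMC machinery: Gelman-Rubin, posterior summaries, and distributional
# correctness of the sampler against an independent grid posterior.

test_that("gelman_rubin matches an explicit spreadsheet-style evaluation", {
  # hand-computable 2-chain, small example, fixed numbers
  ch1 <- c(1.0, 1.2, 0.8, 1.1, 0.9, 1.3, 1.05, 0.95, 1.15, 0.85)
  ch2 <- c(1.4, 1.6, 1.3, 1.5, 1.45, 1.55, 1.35, 1.65, 1.5, 1.4)
  x <- cbind(ch1, ch2)
  n <- 10; m <- 2
  mean1 <- sum(ch1) / n; mean2 <- sum(ch2) / n
  var1 <- sum((ch1 - mean1)^2) / (n - 1)
  var2 <- sum((ch2 - mean2)^2) / (n - 1)
  W <- (var1 + var2) / 2
  grand <- (mean1 + mean2) / 2
  B_over_n <- ((mean1 - grand)^2 + (mean2 - grand)^2) / (m - 1)
  rhat_byhand <- sqrt(((n - 1) / n * W + B_over_n) / W)
  expect_equal(gelman_rubin(x), rhat_byhand, tolerance = 1e-12)
})

test_that("gelman_rubin separates converged from diverged chains", {
  set.seed(21)
  conv <- cbind(rnorm(4000), rnorm(4000), rnorm(4000))
  expect_lt(gelman_rubin(conv), 1.05)
  div <- cbind(rnorm(500), rnorm(500) + 10)  # offset by 10 SDs
  expect_gt(gelman_rubin(div), 1.1)
  # degenerate constant chains are flagged
  expect_warning(r <- gelman_rubin(cbind(rep(1, 50), rep(2, 50))),
                 "degenerate")
  expect_true(is.na(r))
  expect_equal(suppressWarnings(gelman_rubin(cbind(rep(3, 50), rep(3, 50)))), 1)
  expect_error(gelman_rubin(matrix(1:20, ncol = 1)), "2 chains")
  expect_error(gelman_rubin(matrix(1:8, ncol = 2)), "10 iterations")
})

test_that("posterior_summary reports pooled quantiles and significance", {
  draws <- array(0, dim = c(100, 2, 3),
                 dimnames = list(NULL, c("chain1", "chain2"),
                                 c("const", "seq", "norm")))
  draws[, , "const"] <- 5
  draws[, , "seq"] <- matrix(1:100, 100, 2)  # both chains 1..100
  set.seed(31)
  big <- matrix(rnorm(2e5), ncol = 2)
  fit <- structure(list(kind = "growth", draws = draws,
                        rhat = c(const = NA, seq = 1, norm = 1),
                        species = "spA"), class = "demog_fit")
  s <- posterior_summary(fit, c("const", "seq"))
  expect_equal(s$median, c(5, 50.5))
  expect_equal(s$lower[1], 5); expect_equal(s$upper[1], 5)
  expect_true(s$significant[1])
  expect_error(posterior_summary(fit, "nope"), "unknown parameter")
  # large standard-normal sample: interval ~ (-1.96, 1.96)
  fit$draws <- array(big, dim = c(1e5, 2, 1),
                     dimnames = list(NULL, NULL, "z"))
  fit$rhat <- c(z = 1)
  sz <- posterior_summary(fit, "z")
  expect_equal(sz$lower, qnorm(0.025), tolerance = 0.05)
  expect_equal(sz$upper, qnorm(0.975), tolerance = 0.05)
  expect_false(sz$significant)
})

test_that("sampler posterior agrees with an independent grid posterior on a
           single-species mortality reduction", {
  # Two effective parameters: intercept and soil-P response; the other
  # rows are pinned by near-zero hyper-SDs under fixed hyperparameters.
  set.seed(41)
  n <- 250
  logp <- log(runif(n, 0.2, 12.9))
  X <- cbind(1, -5, log(100), logp, -480)
  colnames(X) <- c("intercept", "shading", "size", "p", "moisture")
  interval <- runif(n, 3, 16)
  b_true <- c(-3, 0.4)
  p_ann <- plogis(b_true[1] + b_true[2] * logp)
  status <- as.numeric(runif(n) < interval_mortality(p_ann, interval))
  dat <- make_demog_data(X, status, interval, assoc_design(0, 0, 0),
                         "mortality")
  cfg <- mcmc_config(n_chains = 3, n_burnin = 1500, n_samples = 1500,
                     seed = 2, fixed_hyper = TRUE,
                     sigma_k_range = c(1e-9, 1e3))
  # fixed hyperparameters: diffuse on intercept and P, pinned elsewhere
  fit <- with_fixed_hyper_fit(dat, cfg,
                              sigma_k = c(10, 1e-8, 1e-8, 10, 1e-8))
  b0 <- fit$draws[, , "beta[spA,intercept]"]
  b3 <- fit$draws[, , "beta[spA,p]"]

  # independent oracle: dense grid over (b0, b3)
  g0 <- seq(-6, 0, length.out = 241)
  g3 <- seq(-1, 2, length.out = 241)
  ll <- outer(g0, g3, Vectorize(function(a, b) {
    pa <- plogis(a + b * logp)
    sum(mortality_loglik(status, interval_mortality(pa, interval)))
  }))
  lp <- ll + outer(dnorm(g0, 0, 10, log = TRUE),
                   dnorm(g3, 0, 10, log = TRUE), "+")
  w <- exp(lp - max(lp)); w <- w / sum(w)
  m0 <- sum(rowSums(w) * g0); m3 <- sum(colSums(w) * g3)
  s0 <- sqrt(sum(rowSums(w) * (g0 - m0)^2))
  s3 <- sqrt(sum(colSums(w) * (g3 - m3)^2))

  expect_lt(abs(mean(b0) - m0) / s0, 0.25)
  expect_lt(abs(mean(b3) - m3) / s3, 0.25)
  expect_equal(sd(b0), s0, tolerance = 0.2)
  expect_equal(sd(b3), s3, tolerance = 0.2)
})

test_that("the normality parameter is recovered from heavy-tailed growth", {
  g <- default_growth_hyperparams()
  g$nu <- 2
  cfg <- scenario_config(n_plots = 20, n_species = 20, stems_per_plot = 500,
                         growth = g)
  d <- simulate_dataset(cfg, seed = 11)
  gd <- prepare_data(d$census, d$plots, d$species, "growth",
                     shading_config())
  expect_gte(length(gd$y), 4500)
  fit <- suppressWarnings(fit_growth(gd, recovery_mcmc(seed = 3)))
  nu_med <- posterior_summary(fit, "nu")$median
  expect_gt(nu_med, 1.5); expect_lt(nu_med, 3)
  sig <- posterior_summary(fit, "sigma")
  expect_equal(sig$median, g$sigma, tolerance = 0.15)
})

test_that("an all-alive cohort pushes the intrinsic mortality strongly
           negative", {
  d <- simulate_dataset(tiny_scenario(), seed = 13)
  d$census$status <- "alive"
  d$census$dbh2[is.na(d$census$dbh2)] <- d$census$dbh1[is.na(d$census$dbh2)]
  md <- prepare_data(d$census, d$plots, d$species, "mortality",
                     shading_config())
  fit <- suppressWarnings(fit_mortality(md, quick_mcmc(seed = 4)))
  # under a zero-centred prior the annual mortality at typical covariates
  # would be ~0.5; an all-alive cohort must force it near zero for every
  # species (individual coefficients stay unidentified along collinear
  # directions, so the check is on the predictor, not the intercept)
  xbar <- colMeans(md$X)
  coefs <- c("intercept", "shading", "size", "p", "moisture")
  p_med <- vapply(coefs, function(k) species_coef_draws(fit, k),
                  matrix(0, prod(dim(fit$draws)[1:2]),
                         length(fit$species)), USE.NAMES = TRUE)
  eta <- matrix(0, dim(p_med)[1], dim(p_med)[2])
  for (k in seq_along(coefs)) eta <- eta + p_med[, , k] * xbar[k]
  p_ann <- apply(plogis(eta), 2, median)
  expect_true(all(p_ann < 0.1))
  expect_lt(median(p_ann), 0.02)
})

test_that("fits are reproducible under the configured seed and error on
           missing associations", {
  d <- simulate_dataset(tiny_scenario(), seed = 17)
  gd <- prepare_data(d$census, d$plots, d$species, "growth",
                     shading_config())
  f1 <- suppressWarnings(fit_growth(gd, quick_mcmc(seed = 7)))
  f2 <- suppressWarnings(fit_growth(gd, quick_mcmc(seed = 7)))
  expect_identical(f1$draws, f2$draws)
  f3 <- suppressWarnings(fit_growth(gd, quick_mcmc(seed = 8)))
  expect_false(identical(f1$draws, f3$draws))
  expect_error(prepare_data(d$census, d$plots, d$species[-1, ], "growth",
                            shading_config()),
               "missing associations")
  expect_error(mcmc_config(n_chains = 1), "n_chains")
})
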