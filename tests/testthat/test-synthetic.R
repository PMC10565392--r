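# Synthetic plot-network generator: configuration, tables and the
# forward demographic simulation.

test_that("scenario_config validates its ranges", {
  expect_s3_class(scenario_config(), "scenario_config")
  expect_error(scenario_config(resin_p_range = c(0, 10)), "resin_p")
  expect_error(scenario_config(census_interval_range = c(0.5, 3)), "interval")
  expect_error(scenario_config(plot_width = 18), "20 m")
  expect_error(scenario_config(n_species = 1), "n_species")
})

test_that("generated plots respect the configured gradients", {
  cfg <- scenario_config(n_plots = 43, resin_p_range = c(0.2, 12.9))
  set.seed(1); plots <- generate_plots(cfg)
  expect_equal(nrow(plots), 43)
  expect_true(all(plots$resin_p >= 0.2 & plots$resin_p <= 12.9))
  expect_equal(range(plots$resin_p), c(0.2, 12.9), tolerance = 1e-12)
  expect_true(all(plots$moisture >= -580 & plots$moisture <= -392))
  iv <- plots$date2 - plots$date1
  expect_true(all(iv >= 3 & iv <= 16))
  # degenerate single plot
  set.seed(1); single <- generate_plots(scenario_config(n_plots = 1))
  expect_equal(nrow(single), 1)
  expect_true(single$resin_p >= 0.2 && single$resin_p <= 12.9)
  # determinism under a fixed seed
  set.seed(9); a <- generate_plots(cfg)
  set.seed(9); b <- generate_plots(cfg)
  expect_identical(a, b)
})

test_that("species pool has the configured size and distributions", {
  cfg <- scenario_config(n_species = 407)
  set.seed(2); sp <- generate_species(cfg)
  expect_equal(nrow(sp), 407)
  expect_equal(sum(sp$abundance), 1)
  # point-mass association distributions give all-generalist pools
  set.seed(2)
  flat <- generate_species(scenario_config(assoc_sd = c(0, 0, 0)))
  expect_true(all(flat$p_assoc == 0 & flat$shade_assoc == 0 &
                    flat$m_assoc == 0))
  set.seed(5); a <- generate_species(cfg)
  set.seed(5); b <- generate_species(cfg)
  expect_identical(a, b)
})

test_that("stem maps stay inside the plot and honour degenerate configs", {
  cfg <- scenario_config(stems_per_plot = 1000)
  set.seed(3)
  plots <- generate_plots(cfg)
  sp <- generate_species(cfg)
  m <- generate_stem_map(plots[1, ], sp, cfg)
  expect_equal(nrow(m), 1000)
  expect_true(all(m$x >= 0 & m$x <= 100 & m$y >= 0 & m$y <= 100))
  expect_true(all(m$dbh1 >= 10))
  # empty stem map is valid
  empty <- generate_stem_map(plots[1, ],
                             sp, scenario_config(stems_per_plot = 0))
  expect_equal(nrow(empty), 0)
  # monodominant pool: placement bias has nothing to act on
  mono <- sp[1, ]; mono$abundance <- 1
  m1 <- generate_stem_map(plots[1, ], mono, scenario_config())
  expect_true(all(m1$species == sp$species[1]))
})

test_that("simulated mortality matches the closed-form interval risk", {
  # fixed covariate cell: beta_M intercept-only, p_annual = 0.02, T = 10;
  # the cohort is spread over many plots to keep the per-plot neighbour
  # matrices small
  cfg <- scenario_config(n_plots = 25, n_species = 2, stems_per_plot = 2000,
                         census_interval_range = c(10, 10))
  set.seed(4)
  plots <- generate_plots(cfg)
  plots$date2 <- plots$date1 + 10
  sp <- generate_species(cfg)
  maps <- do.call(rbind, lapply(seq_len(nrow(plots)), function(i)
    generate_stem_map(plots[i, ], sp, cfg)))
  beta_m <- matrix(c(qlogis(0.02), 0, 0, 0, 0), 2, 5, byrow = TRUE,
                   dimnames = list(sp$species, NULL))
  beta_g <- matrix(c(0.02, 0, 0, 0, 0), 2, 5, byrow = TRUE,
                   dimnames = list(sp$species, NULL))
  out <- simulate_demography(maps, plots, beta_g, beta_m, cfg)
  p_expected <- 1 - 0.98^10  # 0.1829272
  n <- nrow(out)
  se <- sqrt(p_expected * (1 - p_expected) / n)
  expect_lt(abs(mean(out$status == "dead") - p_expected), 3 * se)
  # dead trees carry no dbh2; survivors grow by exp(RGR * T)
  expect_true(all(is.na(out$dbh2[out$status == "dead"])))
  expect_true(all(out$dbh2[out$status == "alive"] > 0))
})

test_that("beta_M = 0 over a one-year interval kills with probability 1/2", {
  cfg <- scenario_config(n_plots = 8, n_species = 2, stems_per_plot = 1000,
                         census_interval_range = c(1, 1))
  set.seed(6)
  plots <- generate_plots(cfg); plots$date2 <- plots$date1 + 1
  sp <- generate_species(cfg)
  maps <- do.call(rbind, lapply(seq_len(nrow(plots)), function(i)
    generate_stem_map(plots[i, ], sp, cfg)))
  zeros <- matrix(0, 2, 5, dimnames = list(sp$species, NULL))
  out <- simulate_demography(maps, plots, zeros, zeros, cfg)
  expect_lt(abs(mean(out$status == "dead") - 0.5), 3 * sqrt(0.25 / nrow(out)))
})

test_that("degenerate growth noise reproduces the deterministic growth path", {
  g <- default_growth_hyperparams()
  g$sigma <- 1e-12; g$nu <- 1e6
  cfg <- scenario_config(n_plots = 2, n_species = 5, stems_per_plot = 50,
                         growth = g)
  d <- simulate_dataset(cfg, seed = 8)
  surv <- d$census[d$census$status == "alive", ]
  off <- d$truth$shading_offset
  m <- match(surv$plot, d$plots$plot)
  X <- demog_covariates(surv$shading, surv$dbh1, d$plots$resin_p[m],
                        d$plots$moisture[m], off)
  pred <- growth_predictor(d$truth$beta_growth[surv$species, ], X)
  expect_equal(surv$dbh2,
               surv$dbh1 * exp(pred * (surv$date2 - surv$date1)),
               tolerance = 1e-6)
})

test_that("growth residuals follow the generating t distribution", {
  cfg <- scenario_config(n_plots = 10, n_species = 5, stems_per_plot = 1200)
  d <- simulate_dataset(cfg, seed = 10)
  surv <- d$census[d$census$status == "alive", ]
  off <- d$truth$shading_offset
  m <- match(surv$plot, d$plots$plot)
  X <- demog_covariates(surv$shading, surv$dbh1, d$plots$resin_p[m],
                        d$plots$moisture[m], off)
  pred <- growth_predictor(d$truth$beta_growth[surv$species, ], X)
  rgr <- compute_rgr(surv$dbh1, surv$dbh2, surv$date2 - surv$date1)
  z <- (rgr - pred) / d$truth$growth$sigma
  n <- min(length(z), 10000)
  ks <- suppressWarnings(
    stats::ks.test(z[seq_len(n)], stats::pt, df = d$truth$growth$nu))
  expect_gt(ks$p.value, 0.01)
})

test_that("the full generator is deterministic under a fixed seed", {
  a <- simulate_dataset(tiny_scenario(), seed = 123)
  b <- simulate_dataset(tiny_scenario(), seed = 123)
  expect_identical(a$census, b$census)
  expect_identical(a$truth$beta_growth, b$truth$beta_growth)
  c2 <- simulate_dataset(tiny_scenario(), seed = 124)
  expect_false(identical(a$census$dbh2, c2$census$dbh2))
})

test_that("scenario configurations round-trip through YAML exactly", {
  cfg <- scenario_config(n_plots = 7, seed = 42)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_scenario_config(cfg, f)
  back <- read_scenario_config(f)
  expect_equal(unclass(back$growth$gamma), unclass(cfg$growth$gamma),
               ignore_attr = TRUE)
  expect_equal(back$growth$sigma_k, cfg$growth$sigma_k,
               ignore_attr = TRUE)
  expect_equal(back$mortality$gamma, cfg$mortality$gamma)
  for (f2 in setdiff(names(cfg), c("growth", "mortality"))) {
    expect_equal(back[[f2]], cfg[[f2]], ignore_attr = TRUE)
  }
  # an identical simulation follows from the reconstructed config
  expect_identical(simulate_dataset(back, seed = 3)$census,
                   simulate_dataset(cfg, seed = 3)$census)
})
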