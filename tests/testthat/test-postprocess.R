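# Standardized scenarios, species filtering, posterior predictions and
# the abundance-weighted regressions.

test_that("scenarios take resin P at the requested type-7 quantile", {
  plots <- hand_plots(plot = c("a", "b", "c"), resin_p = c(1, 2, 3),
                      moisture = c(-500, -450, -400))
  census <- hand_census(x = c(50, 60), y = 50, dbh1 = c(50, 80))
  census$shading <- c(0.01, 0.03)
  sc <- scenario_from_data(plots, census, 0.5)
  expect_equal(sc$resin_p, 2)
  expect_equal(sc$moisture, -450)
  expect_equal(sc$shading, 0.02)
  expect_equal(sc$dbh, 100)
  # single plot: every quantile returns that plot's value
  one <- hand_plots(resin_p = 5.5)
  for (q in c(0, 0.3, 1)) {
    expect_equal(scenario_from_data(one, census, q)$resin_p, 5.5)
  }
  # sort-based oracle on a larger synthetic plot table
  set.seed(19)
  rp <- exp(runif(43, log(0.2), log(12.9)))
  many <- hand_plots(plot = sprintf("p%02d", 1:43), resin_p = rp,
                     moisture = runif(43, -580, -392))
  sc95 <- scenario_from_data(many, census, 0.95)
  s <- sort(rp); h <- (43 - 1) * 0.95 + 1
  oracle <- s[floor(h)] + (h - floor(h)) * (s[floor(h) + 1] - s[floor(h)])
  expect_equal(sc95$resin_p, oracle, tolerance = 1e-12)
  expect_error(scenario_from_data(many, census, 1.2), "quantile")
})

test_that("species filter applies both inclusive thresholds", {
  census <- data.frame(
    species = c(rep("a", 9), rep("b", 10), rep("c", 12), rep("d", 15)),
    dbh1 = c(rep(200, 9),            # a: 9 individuals (too few)
             rep(10, 9), 100,        # b: 10 individuals, max exactly 100
             rep(99, 12),            # c: max dbh below 100
             rep(150, 15)))          # d: passes comfortably
  expect_setequal(species_filter(census), c("b", "d"))
})

test_that("predictions from a point-mass posterior equal direct formula
           evaluation", {
  sc <- structure(list(resin_p = 2.3, moisture = -480, shading = 0.01,
                       dbh = 100, p_quantile = 0.5),
                  class = "demog_scenario")
  beta <- c(-0.1, -0.02, 0.01, 0.005, -1e-5)
  pn <- paste0("beta[spA,", c("intercept", "shading", "size", "p",
                              "moisture"), "]")
  draws <- array(rep(beta, each = 40 * 2), dim = c(40, 2, 5),
                 dimnames = list(NULL, NULL, pn))
  fit <- structure(list(kind = "mortality", draws = draws,
                        rhat = setNames(rep(1, 5), pn), species = "spA",
                        offset = 0.004,
                        species_table = data.frame(species = "spA",
                                                   p_assoc = 0.2,
                                                   shade_assoc = 0,
                                                   m_assoc = 0),
                        n_per_species = 25L, max_dbh = 320),
                   class = "demog_fit")
  pred <- predict_species(fit, sc)
  x <- c(1, log(0.01 + 0.004), log(100), log(2.3), -480)
  expect_equal(pred$estimate, plogis(sum(beta * x)), tolerance = 1e-12)
  expect_equal(pred$lower, pred$estimate)
  expect_equal(pred$upper, pred$estimate)
  fit$kind <- "growth"
  expect_equal(predict_species(fit, sc)$estimate, sum(beta * x),
               tolerance = 1e-12)
})

test_that("association regression recovers exact structure and matches the
           normal equations", {
  set.seed(23)
  n <- 40
  pred <- data.frame(species = sprintf("s%02d", 1:n),
                     estimate = NA, p_assoc = rnorm(n),
                     shade_assoc = rnorm(n), m_assoc = rnorm(n),
                     n_individuals = rep(10, n))
  # (near-)noise-free linear response in p_assoc only, equal weights;
  # the 1e-9 jitter keeps the AIC comparisons of the perfect fit defined
  pred$estimate <- 0.02 + 0.007 * pred$p_assoc + rnorm(n, 0, 1e-11)
  r <- association_regression(pred, "rgr")
  expect_equal(unname(r$coefficients["p_assoc"]), 0.007, tolerance = 1e-8)
  expect_equal(r$retained, "p_assoc")        # AIC drops the dead terms
  expect_equal(r$r_squared, 1, tolerance = 1e-8)
  # weighted fit vs an independent normal-equations solve (no selection)
  pred$estimate <- 0.02 + 0.007 * pred$p_assoc - 0.003 * pred$shade_assoc +
    rnorm(n, 0, 0.004)
  pred$n_individuals <- sample(10:200, n)
  rw <- association_regression(pred, "rgr", select = FALSE)
  Xm <- cbind(1, pred$p_assoc, pred$shade_assoc, pred$m_assoc)
  W <- diag(pred$n_individuals)
  oracle <- solve(t(Xm) %*% W %*% Xm, t(Xm) %*% W %*% pred$estimate)
  expect_equal(unname(rw$coefficients), as.numeric(oracle), tolerance = 1e-10)
  # all-equal weights equal the unweighted fit
  pred$n_individuals <- rep(7, n)
  req <- association_regression(pred, "rgr", select = FALSE)
  unw <- lm(estimate ~ p_assoc + shade_assoc + m_assoc, data = pred)
  expect_equal(unname(req$coefficients), unname(coef(unw)), tolerance = 1e-10)
})

test_that("a dominating weight forces interpolation of that species", {
  set.seed(29)
  n <- 12
  pred <- data.frame(species = sprintf("s%02d", 1:n),
                     estimate = rnorm(n, 0.02, 0.01),
                     p_assoc = rnorm(n), shade_assoc = rnorm(n),
                     m_assoc = rnorm(n),
                     n_individuals = c(1e9, rep(1, n - 1)))
  r <- association_regression(pred, "rgr", select = FALSE)
  fitted1 <- sum(r$coefficients * c(1, pred$p_assoc[1], pred$shade_assoc[1],
                                    pred$m_assoc[1]))
  expect_equal(fitted1, pred$estimate[1], tolerance = 1e-6)
})

test_that("degenerate designs are rejected with diagnostics", {
  pred <- data.frame(species = c("a", "b", "c", "d"),
                     estimate = c(0.01, 0.02, 0.03, 0.01),
                     p_assoc = 1, shade_assoc = 1, m_assoc = 1,
                     n_individuals = 10)
  expect_error(association_regression(pred, "rgr"), "degenerate design")
  expect_error(association_regression(pred[1:2, ], "rgr"), "3 species")
})

test_that("trade-off regression is group-symmetric, honest under the null
           and positive under generative coupling", {
  make_preds <- function(rgr, mort, p_assoc, n = NULL) {
    n <- n %||% rep(20, length(rgr))
    g <- data.frame(species = sprintf("s%03d", seq_along(rgr)),
                    estimate = rgr, n_individuals = n, p_assoc = p_assoc)
    m <- data.frame(species = g$species, estimate = mort)
    list(g = g, m = m)
  }
  # identical groups give identical results, and row order is irrelevant
  set.seed(37)
  rgr <- runif(40, 0.01, 0.05)
  mort <- exp(rnorm(40, -3.5, 0.3))
  p <- make_preds(rep(rgr[1:20], 2), rep(mort[1:20], 2),
                  p_assoc = rep(c(-1, 1), each = 20))
  t1 <- tradeoff_regression(p$g, p$m)
  expect_equal(t1[t1$group == "low-P", -1], t1[t1$group == "high-P", -1],
               tolerance = 1e-10, ignore_attr = TRUE)
  shuf <- sample(40)
  t1b <- tradeoff_regression(p$g[shuf, ], p$m[shuf, ])
  expect_equal(t1b, t1, tolerance = 1e-10)
  # zero assigned to the high-P group (closed on the right)
  p3 <- make_preds(rgr[1:6], mort[1:6], p_assoc = c(-1, -1, -1, 0, 0, 0))
  t3 <- tradeoff_regression(p3$g, p3$m)
  expect_equal(t3$n, c(3, 3))
  # null: no true slope; p-values not extreme across seeds
  for (s in 1:3) {
    set.seed(100 + s)
    rgr0 <- runif(100, 0.01, 0.05)
    mort0 <- exp(rnorm(100, -3.5, 0.3))
    pn <- make_preds(rgr0, mort0, p_assoc = rnorm(100))
    tn <- tradeoff_regression(pn$g, pn$m)
    expect_true(all(tn$p_value > 0.001))
  }
  # generative positive coupling within groups -> positive fitted slopes
  set.seed(43)
  rgrc <- runif(120, 0.01, 0.06)
  mortc <- exp(-4 + 25 * rgrc + rnorm(120, 0, 0.2))
  pc <- make_preds(rgrc, mortc, p_assoc = rnorm(120))
  tc <- tradeoff_regression(pc$g, pc$m)
  expect_true(all(tc$slope > 0))
  expect_true(all(tc$p_value < 0.01))
  # undersized group is skipped with a warning
  p4 <- make_preds(rgr[1:10], mort[1:10], p_assoc = c(-1, rep(1, 9)))
  expect_warning(t4 <- tradeoff_regression(p4$g, p4$m), "fewer than 3")
  expect_equal(t4$group, "high-P")
})
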