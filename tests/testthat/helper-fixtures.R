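# Small scenarios and hand-built tables used across the suite.

# Desk-scale scenario: the package defaults (20 plots, 60 species,
# 150 stems/plot) used by the recovery suites.
desk_scenario <- function(...) scenario_config(...)

# Tiny scenario for plumbing tests where MCMC quality is not at stake.
tiny_scenario <- function(...) {
  scenario_config(n_plots = 6, n_species = 15, stems_per_plot = 80, ...)
}

# MCMC config for desk-scale recovery: default protocol with the
# hyper-SD prior lower bound below the moisture row's natural scale.
recovery_mcmc <- function(seed = 1, ...) {
  mcmc_config(seed = seed, sigma_k_range = c(1e-8, 1e3), ...)
}

# Short-chain config for structural/determinism tests.
quick_mcmc <- function(seed = 1, ...) {
  mcmc_config(seed = seed, n_burnin = 400, n_samples = 300,
              sigma_k_range = c(1e-8, 1e3), ...)
}

# A minimal one-plot census laid out by hand.
hand_census <- function(x, y, dbh1, species = NULL, plot = "p01",
                        dbh2 = dbh1 * 1.1, status = "alive",
                        tag_prefix = "t") {
  n <- length(x)
  data.frame(tag = paste0(tag_prefix, seq_len(n)),
             species = species %||% rep("spA", n),
             plot = plot, x = x, y = y, dbh1 = dbh1, dbh2 = dbh2,
             status = rep(status, length.out = n),
             date1 = 2000, date2 = 2010, stringsAsFactors = FALSE)
}

hand_plots <- function(plot = "p01", resin_p = 2, moisture = -480,
                       width = 100, height = 100) {
  data.frame(plot = plot, resin_p = resin_p, moisture = moisture,
              width = width, height = height, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build a demog_data object directly (used by the grid-oracle test).
make_demog_data <- function(X, y, interval, A, kind) {
  structure(list(kind = kind, X = X, y = y, interval = interval,
                 species = factor(rep("spA", length(y))),
                 A = A, offset = 0.005,
                 species_table = data.frame(species = "spA", p_assoc = 0,
                                            shade_assoc = 0, m_assoc = 0),
                 alpha = c(0.5, 0.2, 0.7),
                 n_per_species = length(y),
                 max_dbh = max(exp(X[, "size"]))),
            class = "demog_data")
}

# Single-species fit with the second level held fixed (diffuse on some
# rows, pinned near zero on the rest).
with_fixed_hyper_fit <- function(dat, cfg, sigma_k) {
  cfg$fixed_hyper <- TRUE
  cfg$fixed_gamma <- matrix(0, 5, 8)
  cfg$fixed_sigma_k <- sigma_k
  fit_demog_fn <- if (dat$kind == "growth") fit_growth else fit_mortality
  suppressWarnings(fit_demog_fn(dat, cfg))
}
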