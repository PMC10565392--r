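#' Scenario configuration for the synthetic plot network
#'
#' Describes a synthetic census campaign: the plot network (count,
#' geometry, resin-P and moisture-deficit ranges, census intervals), the
#' species pool (count, association and abundance distributions), the
#' stem maps (stems per plot, initial size distribution) and the true
#' demographic hyperparameters used to simulate growth and death. The
#' defaults are a desk-scale analogue of a lowland-Panama plot network:
#' a ~65-fold resin-P gradient (0.2-12.9 mg P kg^-1), dry-season moisture
#' deficits of -580 to -392 mm, census intervals of 3-16 years, and
#' heavy-tailed growth residuals; they are also the conditions the test
#' suite uses.
#'
#' @param n_plots Number of plots.
#' @param plot_width,plot_height Plot dimensions in m (> 20 so a 10 m
#'   edge buffer leaves interior trees).
#' @param resin_p_range (min, max) resin-extractable P, mg P kg^-1; min > 0.
#'   Plots are spaced log-evenly over this range.
#' @param moisture_range (min, max) dry-season moisture deficit, mm
#'   (negative; more negative = drier). Uniform draws.
#' @param n_species Species-pool size (>= 2).
#' @param stems_per_plot Stems mapped per plot at census 1.
#' @param census_interval_range (min, max) census interval, years (>= 1).
#' @param dbh_meanlog,dbh_sdlog,dbh_min Lognormal initial-dbh parameters
#'   (mm), left-truncated at `dbh_min`.
#' @param assoc_sd Length-3 SDs of the Normal(0, sd) draws of species P,
#'   shade and moisture associations.
#' @param abundance_sdlog Lognormal sd of relative species abundances
#'   (heavy-tailed, as in tropical tree communities).
#' @param growth,mortality True [hyperparameters()] for the two models.
#' @param alpha True distance-decay coefficients used when simulating
#'   (length 3, per neighbour size class).
#' @param seed Optional RNG seed stored with the config.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n_plots = 20, plot_width = 100, plot_height = 100,
                            resin_p_range = c(0.2, 12.9),
                            moisture_range = c(-580, -392),
                            n_species = 60, stems_per_plot = 150,
                            census_interval_range = c(3, 16),
                            dbh_meanlog = log(30), dbh_sdlog = 1.2, dbh_min = 10,
                            assoc_sd = c(1, 1, 1), abundance_sdlog = 1,
                            growth = default_growth_hyperparams(),
                            mortality = default_mortality_hyperparams(),
                            alpha = c(0.5, 0.2, 0.7), seed = NULL) {
  stopifnot(n_plots >= 1, n_species >= 2, stems_per_plot >= 0)
  if (resin_p_range[1] <= 0 || resin_p_range[1] > resin_p_range[2])
    stop("resin_p_range must be positive and increasing")
  if (moisture_range[1] > moisture_range[2]) stop("moisture_range must be increasing")
  if (census_interval_range[1] < 1 || census_interval_range[1] > census_interval_range[2])
    stop("census intervals must be >= 1 year and increasing")
  if (plot_width <= 20 || plot_height <= 20)
    stop("plot dimensions must exceed 20 m (10 m edge buffer on each side)")
  stopifnot(inherits(growth, "hyperparameters"), growth$kind == "growth")
  stopifnot(inherits(mortality, "hyperparameters"), mortality$kind == "mortality")
  stopifnot(length(assoc_sd) == 3, all(assoc_sd >= 0), length(alpha) == 3)
  structure(list(n_plots = n_plots, plot_width = plot_width,
                 plot_height = plot_height, resin_p_range = resin_p_range,
                 moisture_range = moisture_range, n_species = n_species,
                 stems_per_plot = stems_per_plot,
                 census_interval_range = census_interval_range,
                 dbh_meanlog = dbh_meanlog, dbh_sdlog = dbh_sdlog,
                 dbh_min = dbh_min, assoc_sd = assoc_sd,
                 abundance_sdlog = abundance_sdlog,
                 growth = growth, mortality = mortality, alpha = alpha,
                 seed = seed),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Synthetic scenario:", x$n_plots, "plots,", x$n_species, "species,",
      x$stems_per_plot, "stems/plot\n")
  cat("  resin P", x$resin_p_range[1], "-", x$resin_p_range[2], "mg/kg;",
      "moisture deficit", x$moisture_range[1], "to", x$moisture_range[2], "mm\n")
  cat("  census intervals", x$census_interval_range[1], "-",
      x$census_interval_range[2], "y; true alpha:",
      paste(x$alpha, collapse = ", "), "\n")
  invisible(x)
}

#' Generate the plot environment table
#'
#' Resin P is spaced log-evenly from min to max (covering the full
#' gradient deterministically), moisture deficit drawn uniformly, and
#' each plot is assigned census dates whose interval is uniform over the
#' configured range.
#'
#' @param config A [scenario_config()].
#' @return data.frame with columns `plot`, `resin_p`, `moisture`,
#'   `width`, `height`, `date1`, `date2`.
#' @export
generate_plots <- function(config) {
  n <- config$n_plots
  rp <- if (n == 1) sqrt(prod(config$resin_p_range)) else
    exp(seq(log(config$resin_p_range[1]), log(config$resin_p_range[2]),
            length.out = n))
  date1 <- stats::runif(n, 1995, 2005)
  interval <- stats::runif(n, config$census_interval_range[1],
                           config$census_interval_range[2])
  data.frame(plot = sprintf("p%02d", seq_len(n)),
             resin_p = rp,
             moisture = stats::runif(n, config$moisture_range[1],
                                     config$moisture_range[2]),
             width = config$plot_width, height = config$plot_height,
             date1 = date1, date2 = date1 + interval,
             stringsAsFactors = FALSE)
}

#' Generate the species pool
#'
#' Species P, shade and moisture associations are drawn independently
#' from centred normal distributions; relative abundance from a lognormal
#' (heavy-tailed, so abundance weighting is exercised).
#'
#' @param config A [scenario_config()].
#' @return data.frame with columns `species`, `p_assoc`, `shade_assoc`,
#'   `m_assoc`, `abundance`.
#' @export
generate_species <- function(config) {
  n <- config$n_species
  ab <- stats::rlnorm(n, 0, config$abundance_sdlog)
  data.frame(species = sprintf("sp%03d", seq_len(n)),
             p_assoc = stats::rnorm(n, 0, config$assoc_sd[1]),
             shade_assoc = stats::rnorm(n, 0, config$assoc_sd[2]),
             m_assoc = stats::rnorm(n, 0, config$assoc_sd[3]),
             abundance = ab / sum(ab),
             stringsAsFactors = FALSE)
}

# Truncated-lognormal initial diameters via inverse-CDF sampling
rdbh <- function(n, config) {
  p0 <- stats::plnorm(config$dbh_min, config$dbh_meanlog, config$dbh_sdlog)
  stats::qlnorm(stats::runif(n, p0, 1), config$dbh_meanlog, config$dbh_sdlog)
}

#' Generate the census-1 stem map of one plot
#'
#' Stems are placed uniformly at random in the plot rectangle. Species
#' identity is sampled with probability proportional to abundance times
#' exp(p_assoc * z(log resin P) + m_assoc * z(moisture)), where z() is
#' standardization across the plot network, a minimal mechanism producing
#' species turnover along the P and moisture gradients. Initial dbh is
#' drawn from the truncated lognormal size distribution.
#'
#' @param plot_row One row of the plot table from [generate_plots()].
#' @param species Species table from [generate_species()].
#' @param config A [scenario_config()].
#' @param env_scale Optional list with `mean_logp`, `sd_logp`,
#'   `mean_moist`, `sd_moist` used for standardization (computed from the
#'   full plot table by [simulate_dataset()]).
#' @return Census-1 data.frame: `tag`, `species`, `plot`, `x`, `y`,
#'   `dbh1`, `date1`, `date2`.
#' @export
generate_stem_map <- function(plot_row, species, config, env_scale = NULL) {
  n <- config$stems_per_plot
  if (n == 0) {
    return(data.frame(tag = character(), species = character(),
                      plot = character(), x = numeric(), y = numeric(),
                      dbh1 = numeric(), date1 = numeric(), date2 = numeric(),
                      stringsAsFactors = FALSE))
  }
  zp <- if (is.null(env_scale)) 0 else
    (log(plot_row$resin_p) - env_scale$mean_logp) / env_scale$sd_logp
  zm <- if (is.null(env_scale)) 0 else
    (plot_row$moisture - env_scale$mean_moist) / env_scale$sd_moist
  w <- species$abundance * exp(species$p_assoc * zp + species$m_assoc * zm)
  sp <- sample(species$species, n, replace = TRUE, prob = w)
  data.frame(tag = paste0(plot_row$plot, "-", seq_len(n)),
             species = sp, plot = plot_row$plot,
             x = stats::runif(n, 0, plot_row$width),
             y = stats::runif(n, 0, plot_row$height),
             dbh1 = rdbh(n, config),
             date1 = plot_row$date1, date2 = plot_row$date2,
             stringsAsFactors = FALSE)
}

#' Draw species coefficients from the second level
#'
#' For each species, the five first-level coefficients are drawn from
#' Normal(mu_k, sigma_k) where mu_k is the second-level linear function
#' of the species' associations ([second_level_mean()]).
#'
#' @param species Species table with `p_assoc`, `shade_assoc`, `m_assoc`.
#' @param hyper A [hyperparameters()] object.
#' @return Matrix (n_species x 5) of coefficients, row names = species.
#' @export
draw_species_coefficients <- function(species, hyper) {
  A <- assoc_design(species$p_assoc, species$shade_assoc, species$m_assoc)
  mu <- A %*% t(hyper$gamma)  # n_species x 5
  beta <- mu + matrix(stats::rnorm(length(mu)), nrow(mu), 5) %*%
    diag(hyper$sigma_k)
  dimnames(beta) <- list(species$species, COEF_NAMES)
  beta
}

#' Simulate two-census demographic outcomes
#'
#' Runs the demographic model forward: shading indices are computed with
#' the true distance-decay coefficients (the shading offset is the median
#' index over interior trees); each tree dies over its census interval
#' with probability 1 - (1 - p_annual)^T, where p_annual is the
#' logistic-link annual mortality; survivors receive an observed RGR
#' drawn from the location-scale Student-t around the predicted RGR and a
#' second-census dbh of dbh1 * exp(RGR * T). Dead trees carry `dbh2 = NA`.
#'
#' @param stem_map Census-1 table (possibly several plots) from
#'   [generate_stem_map()].
#' @param plots Plot table.
#' @param beta_growth,beta_mortality Coefficient matrices from
#'   [draw_species_coefficients()].
#' @param config A [scenario_config()] (supplies `alpha` and the growth
#'   globals `sigma`, `nu`).
#' @return The census completed with `shading`, `status` ("alive"/"dead")
#'   and `dbh2`, plus attribute `shading_offset`.
#' @export
simulate_demography <- function(stem_map, plots, beta_growth, beta_mortality,
                                config) {
  census <- compute_shading(stem_map, shading_config(alpha = config$alpha))
  if (is.null(census$shading)) stop("shading indices missing")
  interior <- is_interior(census, plots, 10)
  off <- shading_offset(census$shading[interior])
  m <- match(census$plot, plots$plot)
  X <- demog_covariates(census$shading, census$dbh1, plots$resin_p[m],
                        plots$moisture[m], off)
  miss <- setdiff(unique(census$species), rownames(beta_growth))
  if (length(miss)) stop("species without coefficients: ", paste(miss, collapse = ", "))
  interval <- census$date2 - census$date1
  bm <- beta_mortality[census$species, , drop = FALSE]
  p_ann <- annual_mortality(bm, X)
  p_int <- interval_mortality(p_ann, interval)
  dead <- stats::runif(nrow(census)) < p_int
  bg <- beta_growth[census$species, , drop = FALSE]
  rgr_pred <- growth_predictor(bg, X)
  rgr_obs <- rgr_pred + config$growth$sigma * stats::rt(nrow(census),
                                                        df = config$growth$nu)
  census$status <- ifelse(dead, "dead", "alive")
  census$dbh2 <- ifelse(dead, NA_real_, census$dbh1 * exp(rgr_obs * interval))
  attr(census, "shading_offset") <- off
  census
}

#' Simulate a complete synthetic dataset
#'
#' Full generator pipeline: plots, species pool, true species
#' coefficients, stem maps and two-census demography, with all ground
#' truth retained for parameter-recovery testing.
#'
#' @param config A [scenario_config()].
#' @param seed RNG seed (overrides `config$seed`); every stage of the
#'   generator is driven by this single seed.
#' @return An object of class `synthetic_dataset`: a list with `census`,
#'   `plots`, `species` and `truth` (coefficient matrices, hyperparams,
#'   alpha, shading offset).
#' @export
simulate_dataset <- function(config = scenario_config(), seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  plots <- generate_plots(config)
  species <- generate_species(config)
  env_scale <- list(mean_logp = mean(log(plots$resin_p)),
                    sd_logp = max(stats::sd(log(plots$resin_p)), 1e-8),
                    mean_moist = mean(plots$moisture),
                    sd_moist = max(stats::sd(plots$moisture), 1e-8))
  maps <- lapply(seq_len(nrow(plots)), function(i)
    generate_stem_map(plots[i, ], species, config, env_scale))
  stem_map <- do.call(rbind, maps)
  beta_g <- draw_species_coefficients(species, config$growth)
  beta_m <- draw_species_coefficients(species, config$mortality)
  census <- simulate_demography(stem_map, plots, beta_g, beta_m, config)
  structure(list(census = census, plots = plots, species = species,
                 truth = list(beta_growth = beta_g, beta_mortality = beta_m,
                              growth = config$growth,
                              mortality = config$mortality,
                              alpha = config$alpha,
                              shading_offset = attr(census, "shading_offset")),
                 config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic dataset:", nrow(x$census), "stems,",
      nrow(x$plots), "plots,", length(unique(x$census$species)), "species\n")
  cat("  dead fraction:", round(mean(x$census$status == "dead"), 3), "\n")
  invisible(x)
}

#' Write / read a scenario configuration as YAML
#'
#' Serializes every field of a [scenario_config()], including the true
#' hyperparameter matrices, so a scenario (and therefore a whole
#' synthetic study) can be archived and reconstructed exactly.
#'
#' @param config A [scenario_config()].
#' @param path YAML file path.
#' @return `path` invisibly (write); the reconstructed `scenario_config`
#'   (read).
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  x <- unclass(config)
  gamma_rows <- function(g) lapply(seq_len(nrow(g)),
                                   function(i) as.numeric(g[i, ]))
  x$growth <- list(gamma = gamma_rows(x$growth$gamma),
                   sigma_k = as.numeric(x$growth$sigma_k),
                   sigma = x$growth$sigma, nu = x$growth$nu)
  x$mortality <- list(gamma = gamma_rows(x$mortality$gamma),
                      sigma_k = as.numeric(x$mortality$sigma_k))
  yaml::write_yaml(x, path, precision = 17)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  x <- yaml::read_yaml(path)
  as_gamma <- function(g) do.call(rbind, lapply(g, as.numeric))
  growth <- hyperparameters(as_gamma(x$growth$gamma), x$growth$sigma_k,
                            sigma = x$growth$sigma, nu = x$growth$nu,
                            kind = "growth")
  mortality <- hyperparameters(as_gamma(x$mortality$gamma),
                               x$mortality$sigma_k, kind = "mortality")
  scenario_config(n_plots = x$n_plots, plot_width = x$plot_width,
                  plot_height = x$plot_height,
                  resin_p_range = as.numeric(x$resin_p_range),
                  moisture_range = as.numeric(x$moisture_range),
                  n_species = x$n_species,
                  stems_per_plot = x$stems_per_plot,
                  census_interval_range = as.numeric(x$census_interval_range),
                  dbh_meanlog = x$dbh_meanlog, dbh_sdlog = x$dbh_sdlog,
                  dbh_min = x$dbh_min, assoc_sd = as.numeric(x$assoc_sd),
                  abundance_sdlog = x$abundance_sdlog,
                  growth = growth, mortality = mortality,
                  alpha = as.numeric(x$alpha), seed = x$seed)
}
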