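CENSUS_COLS <- c("tag", "species", "plot", "x", "y", "dbh1", "dbh2",
                 "status", "date1", "date2")
PLOT_COLS <- c("plot", "resin_p", "moisture", "width", "height")
SPECIES_COLS <- c("species", "p_assoc", "shade_assoc", "m_assoc", "abundance")

validate_census <- function(census, strict = TRUE) {
  problems <- character()
  bad <- function(rows, why) {
    if (length(rows)) sprintf("rows %s: %s",
                              paste(utils::head(rows, 5), collapse = ","), why)
  }
  problems <- c(problems,
                bad(which(!is.finite(census$dbh1) | census$dbh1 <= 0),
                    "non-positive dbh1"),
                bad(which(!census$status %in% c("alive", "dead")),
                    "status not alive/dead"),
                bad(which(census$status == "alive" &
                            (!is.finite(census$dbh2) | census$dbh2 <= 0)),
                    "alive tree with invalid dbh2"),
                bad(which(census$date2 <= census$date1),
                    "census interval not positive"),
                bad(which(!is.finite(census$x) | !is.finite(census$y)),
                    "missing coordinates"))
  problems <- problems[!vapply(problems, is.null, logical(1))]
  ok <- is.finite(census$dbh1) & census$dbh1 > 0 &
    census$status %in% c("alive", "dead") &
    !(census$status == "alive" & (!is.finite(census$dbh2) | census$dbh2 <= 0)) &
    census$date2 > census$date1 &
    is.finite(census$x) & is.finite(census$y)
  if (strict && length(problems) > 0) {
    stop("census validation failed:\n  ", paste(problems, collapse = "\n  "))
  }
  list(census = census[ok, , drop = FALSE], problems = unlist(problems),
       n_rejected = sum(!ok))
}

#' Read a census/plot/species dataset from CSV files
#'
#' Readers for the documented CSV schemas. Column names can be remapped
#' with `col_map` (a named character vector, `c(file_column = "schema_column")`)
#' rather than guessed. Palms (or any non-secondary-growth group) are
#' dropped when the census has a logical `palm` column. Validation is
#' row-indexed: under `strict = TRUE` (default) any invalid row aborts
#' with a message naming the rows; under lenient mode invalid rows are
#' dropped and reported in the `validation` attribute.
#'
#' @param census_file,plot_file,species_file Paths to the three CSVs.
#' @param col_map Optional named character vector renaming file columns
#'   to schema columns.
#' @param strict Abort on invalid rows (default) or drop them.
#' @return List of class `demog_dataset` with `census`, `plots`,
#'   `species`, and a `validation` element (problems, rejected count).
#' @export
read_dataset <- function(census_file, plot_file, species_file,
                         col_map = NULL, strict = TRUE) {
  rd <- function(f) utils::read.csv(f, stringsAsFactors = FALSE)
  census <- rd(census_file); plots <- rd(plot_file); species <- rd(species_file)
  if (!is.null(col_map)) {
    for (tab in c("census", "plots", "species")) {
      x <- get(tab)
      hit <- names(x) %in% names(col_map)
      names(x)[hit] <- col_map[names(x)[hit]]
      assign(tab, x)
    }
  }
  need <- function(x, cols, what) {
    missing_cols <- setdiff(cols, names(x))
    if (length(missing_cols) > 0) {
      stop(what, " file lacks columns: ", paste(missing_cols, collapse = ", "))
    }
  }
  need(census, CENSUS_COLS, "census")
  need(plots, PLOT_COLS, "plot")
  need(species, setdiff(SPECIES_COLS, "abundance"), "species")
  if ("palm" %in% names(census)) {
    census <- census[!isTRUE_vec(census$palm), , drop = FALSE]
  }
  v <- validate_census(census, strict = strict)
  census <- v$census
  unknown_sp <- setdiff(unique(census$species), species$species)
  if (length(unknown_sp) > 0) {
    stop("census contains species absent from the species table: ",
         paste(utils::head(unknown_sp, 5), collapse = ", "))
  }
  unknown_pl <- setdiff(unique(census$plot), plots$plot)
  if (length(unknown_pl) > 0) {
    stop("census contains plots absent from the plot table: ",
         paste(utils::head(unknown_pl, 5), collapse = ", "))
  }
  structure(list(census = census, plots = plots, species = species,
                 validation = v[c("problems", "n_rejected")],
                 provenance = list(census = census_file, plots = plot_file,
                                   species = species_file)),
            class = "demog_dataset")
}

isTRUE_vec <- function(x) !is.na(x) & (x == TRUE | x == "TRUE" | x == 1)

#' Write a dataset to CSV files
#'
#' Writes `census.csv`, `plots.csv` and `species.csv` under `dir`, plus a
#' `metadata.json` sidecar declaring the units of every column. A
#' `synthetic_dataset` additionally gets its ground truth written to
#' `truth.yaml` (hyperparameter matrices, alpha, shading offset) so
#' recovery studies can be rerun from disk.
#'
#' @param dataset A `demog_dataset` or `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, f) utils::write.csv(x, file.path(dir, f), row.names = FALSE)
  census <- dataset$census
  census <- census[, intersect(c(CENSUS_COLS, "shading"), names(census))]
  wr(census, "census.csv")
  wr(dataset$plots[, intersect(c(PLOT_COLS, "date1", "date2"),
                               names(dataset$plots))], "plots.csv")
  wr(dataset$species, "species.csv")
  meta <- list(
    census = list(tag = "stem identifier", species = "species code",
                  plot = "plot code", x = "m", y = "m", dbh1 = "mm",
                  dbh2 = "mm (NA when dead)", status = "alive|dead",
                  date1 = "decimal year", date2 = "decimal year",
                  shading = "m^2 (distance-decayed larger-neighbour basal area)"),
    plots = list(plot = "plot code", resin_p = "mg P kg^-1",
                 moisture = "mm (dry-season moisture deficit, negative)",
                 width = "m", height = "m", date1 = "decimal year",
                 date2 = "decimal year"),
    species = list(species = "species code",
                   p_assoc = "occurrence slope vs soil P (effect size)",
                   shade_assoc = "median site-centred shading index",
                   m_assoc = "occurrence slope vs moisture deficit (effect size)",
                   abundance = "relative abundance (fraction)"))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (inherits(dataset, "synthetic_dataset")) {
    tr <- dataset$truth
    yaml::write_yaml(list(
      alpha = as.numeric(tr$alpha),
      shading_offset = as.numeric(tr$shading_offset),
      growth = list(gamma = unclass(tr$growth$gamma),
                    sigma_k = as.numeric(tr$growth$sigma_k),
                    sigma = tr$growth$sigma, nu = tr$growth$nu),
      mortality = list(gamma = unclass(tr$mortality$gamma),
                       sigma_k = as.numeric(tr$mortality$sigma_k)),
      beta_growth = unclass(tr$beta_growth),
      beta_mortality = unclass(tr$beta_mortality)),
      file.path(dir, "truth.yaml"), precision = 17)
  }
  invisible(dir)
}

#' Run the full analysis pipeline
#'
#' End-to-end pipeline on a dataset (synthetic or read from disk):
#' distance-decay selection by AIC, shade-association computation,
#' hierarchical growth and mortality fits, standardized predictions at
#' the requested resin-P quantiles, abundance-weighted association
#' regressions and the growth-mortality trade-off regression at the
#' median scenario. All stage outputs are written as CSVs under
#' `out_dir` together with a JSON run summary (seed, selected alpha,
#' convergence, regression results).
#'
#' @param dataset A `demog_dataset` or `synthetic_dataset`.
#' @param out_dir Output directory.
#' @param mcmc An [mcmc_config()] (its `seed` drives every stage).
#' @param shading A [shading_config()]; its `alpha_grid` is searched.
#' @param quantiles Resin-P quantiles for standardized predictions.
#' @param select_alpha If `FALSE`, skip AIC selection and use
#'   `shading$alpha` as-is.
#' @param use_true_associations For synthetic datasets: use the
#'   generator's species table (default uses shade associations
#'   recomputed from the data, as for field data).
#' @return List of class `demog_pipeline` with all stage results.
#' @export
run_pipeline <- function(dataset, out_dir = NULL, mcmc = mcmc_config(),
                         shading = shading_config(),
                         quantiles = c(0.05, 0.5, 0.95),
                         select_alpha = TRUE,
                         use_true_associations = FALSE) {
  census <- dataset$census; plots <- dataset$plots
  set.seed(mcmc$seed)
  sel <- NULL
  if (select_alpha) {
    sel <- treedemog::select_alpha(census, plots, shading)
    shading <- shading_config(alpha = sel$alpha, radius = shading$radius,
                              size_class_bounds = shading$size_class_bounds,
                              alpha_grid = shading$alpha_grid)
  }
  census <- compute_shading(census, shading)
  species <- dataset$species
  if (!use_true_associations) {
    focal <- edge_exclude(census, plots, shading$radius)
    sa <- shade_association(focal)
    species <- merge(species[, setdiff(names(species), "shade_assoc")],
                     sa, by = "species")
  }
  gd <- prepare_data(census, plots, species, "growth", shading)
  md <- prepare_data(census, plots, species, "mortality", shading)
  fit_g <- fit_growth(gd, mcmc)
  fit_m <- fit_mortality(md, mcmc)
  focal <- edge_exclude(census, plots, shading$radius)
  eligible <- species_filter(focal)
  preds <- lapply(quantiles, function(q) {
    sc <- scenario_from_data(plots, focal, q)
    list(scenario = sc,
         growth = predict_species(fit_g, sc),
         mortality = predict_species(fit_m, sc))
  })
  names(preds) <- paste0("q", quantiles * 100)
  keep <- function(p) p[p$species %in% eligible, , drop = FALSE]
  regressions <- lapply(preds, function(p) {
    list(growth = association_regression(keep(p$growth), "rgr"),
         mortality = association_regression(keep(p$mortality), "log_mortality"))
  })
  med <- preds[[which.min(abs(quantiles - 0.5))]]
  tradeoff <- tradeoff_regression(keep(med$growth), keep(med$mortality))
  result <- structure(list(alpha_selection = sel, shading = shading,
                           species = species, fit_growth = fit_g,
                           fit_mortality = fit_m, predictions = preds,
                           regressions = regressions, tradeoff = tradeoff,
                           eligible = eligible, seed = mcmc$seed),
                      class = "demog_pipeline")
  if (!is.null(out_dir)) write_pipeline(result, out_dir)
  result
}

write_pipeline <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, f) utils::write.csv(x, file.path(out_dir, f),
                                        row.names = FALSE)
  if (!is.null(result$alpha_selection)) {
    wr(result$alpha_selection$aic_table, "alpha_aic.csv")
  }
  for (q in names(result$predictions)) {
    wr(result$predictions[[q]]$growth, paste0("pred_growth_", q, ".csv"))
    wr(result$predictions[[q]]$mortality, paste0("pred_mortality_", q, ".csv"))
  }
  wr(posterior_summary(result$fit_growth), "posterior_growth.csv")
  wr(posterior_summary(result$fit_mortality), "posterior_mortality.csv")
  wr(result$tradeoff, "tradeoff.csv")
  summarize_reg <- function(r) list(retained = r$retained,
                                    coefficients = as.list(r$coefficients),
                                    r_squared = r$r_squared, n = r$n)
  summary <- list(
    seed = result$seed,
    alpha = as.numeric(result$shading$alpha),
    shading_offset_growth = result$fit_growth$offset,
    max_rhat_growth = max(result$fit_growth$rhat, na.rm = TRUE),
    max_rhat_mortality = max(result$fit_mortality$rhat, na.rm = TRUE),
    n_eligible_species = length(result$eligible),
    regressions = lapply(result$regressions, function(x)
      list(growth = summarize_reg(x$growth),
           mortality = summarize_reg(x$mortality))),
    tradeoff = result$tradeoff)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.demog_pipeline <- function(x, ...) {
  cat("Demographic analysis pipeline (seed ", x$seed, ")\n", sep = "")
  if (!is.null(x$alpha_selection)) {
    cat("  selected alpha:", paste(x$shading$alpha, collapse = ", "), "\n")
  }
  cat("  eligible species:", length(x$eligible), "\n")
  cat("  growth max Rhat:", round(max(x$fit_growth$rhat, na.rm = TRUE), 3),
      "; mortality max Rhat:",
      round(max(x$fit_mortality$rhat, na.rm = TRUE), 3), "\n")
  cat("  trade-off slopes:",
      paste(sprintf("%s %.2f", x$tradeoff$group, x$tradeoff$slope),
            collapse = "; "), "\n")
  invisible(x)
}
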