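#' Read a delimited phenotype file
#'
#' Reads a CSV or TSV phenotype table (delimiter auto-detected from the
#' header line) with required columns `genotype`, `replication`, `day`,
#' `yield` and optional `plot`.
#'
#' @param path File path.
#' @param schedule A [harvest_schedule()] for validation.
#' @return A [phenotype_table()].
#' @export
read_phenotypes <- function(path, schedule) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  phenotype_table(df, schedule)
}

#' Per-harvest yield means
#'
#' Arithmetic mean yield per measured day over non-missing records, and the
#' percent excess of the top mean over the second-best (a standard summary
#' of how strongly the best season out-yields the rest).
#'
#' @param table A [phenotype_table()] or raw data frame with `day` and
#'   `yield`.
#' @return A list: `means` (named by day, in day order), `excess_pct`
#'   (rounded to the nearest integer; `NULL` with fewer than 2 days).
#' @export
summarize_harvest_means <- function(table) {
  if (nrow(table) == 0L) stop("empty phenotype table")
  ok <- !is.na(table$yield)
  means <- tapply(table$yield[ok], table$day[ok], mean)
  means <- means[order(as.integer(names(means)))]
  means <- stats::setNames(as.numeric(means), names(means))
  excess <- NULL
  if (length(means) >= 2L) {
    srt <- sort(as.numeric(means), decreasing = TRUE)
    excess <- if (srt[2L] > 0) round(100 * (srt[1L] - srt[2L]) / srt[2L])
              else NULL
  }
  list(means = means, excess_pct = excess)
}

#' Assemble a pipeline run configuration
#'
#' Validates the configuration of an end-to-end analysis run. Unknown keys
#' are rejected so that typos fail loudly before any computation.
#'
#' @param input Path to a phenotype file, or a `phenotype_table` / data
#'   frame given directly.
#' @param schedule A [harvest_schedule()], or a list with `days`,
#'   `measured`, and optional `day_min`/`day_max` (the YAML form).
#' @param model_grid Character vector of model labels (e.g. `"Leg4.1.D"`)
#'   or a list of [model_spec()]s; default [default_model_grid()].
#' @param force_model Optional label overriding minimum-BIC selection for
#'   the extraction stage.
#' @param accuracy_form `"sqrt"` or `"linear"`.
#' @param include_perm_in_h2 Heritability denominator flag.
#' @param persistence_range Day range of the persistence sum.
#' @param persistence_harvests_only Restrict the persistence sum to the
#'   measured harvest days instead of every integer day.
#' @param output_dir Directory for CSV/JSON (and optional plot) outputs;
#'   `NULL` writes nothing.
#' @param plots Write diagnostic plots (requires `output_dir`).
#' @param compute_lrt Compute term-wise LRTs during the scan.
#' @param seed Seed for all stochastic restarts.
#' @param control A [reml_control()]; its seed is overridden by `seed`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input, schedule, model_grid = NULL,
                       force_model = NULL,
                       accuracy_form = c("sqrt", "linear"),
                       include_perm_in_h2 = TRUE,
                       persistence_range = c(250, 1615),
                       persistence_harvests_only = FALSE,
                       output_dir = NULL, plots = FALSE,
                       compute_lrt = TRUE,
                       seed = 20180913L, control = reml_control()) {
  accuracy_form <- match.arg(accuracy_form)
  if (is.list(schedule) && !inherits(schedule, "harvest_schedule"))
    schedule <- do.call(harvest_schedule, schedule)
  if (is.null(model_grid)) model_grid <- default_model_grid()
  if (is.character(model_grid))
    model_grid <- lapply(model_grid, parse_model_spec)
  if (!length(model_grid) || !all(vapply(model_grid, inherits, TRUE, "model_spec")))
    stop("model_grid must be model specs or labels")
  if (!is.null(force_model)) force_model <- as.character(force_model)
  control$seed <- as.integer(seed)
  structure(list(input = input, schedule = schedule, model_grid = model_grid,
                 force_model = force_model, accuracy_form = accuracy_form,
                 include_perm_in_h2 = include_perm_in_h2,
                 persistence_range = as.numeric(persistence_range),
                 persistence_harvests_only = persistence_harvests_only,
                 output_dir = output_dir, plots = plots,
                 compute_lrt = compute_lrt,
                 seed = as.integer(seed), control = control),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose keys mirror the arguments of [run_config()]
#' (with `schedule:` given as `days`/`measured`/`day_min`/`day_max`).
#' Unknown keys raise an error.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- setdiff(names(formals(run_config)), "control")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}

#' Run the end-to-end longitudinal genetic analysis
#'
#' Reads the phenotypes, scans the model grid, selects the minimum-BIC
#' converged model (or the `force_model` override), extracts variance and
#' heritability trajectories, genetic values (including prediction-only
#' days), accuracies and eigenfunctions, computes the persistence index,
#' and (optionally) writes every table as CSV plus a JSON run report and
#' diagnostic plots.
#'
#' @param config A [run_config()].
#' @return A list of class `run_report`: `comparison`, `chosen_model`,
#'   `fit`, `trajectories`, `genetic_values`, `accuracy`, `eigenfunctions`,
#'   `persistence`, `harvest_means`, `provenance`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop("`config` must be a run_config")
  sch <- config$schedule
  tab <- if (is.character(config$input)) read_phenotypes(config$input, sch)
         else phenotype_table(config$input, sch)
  nh <- sum(sch$measured)
  max_order <- max(vapply(config$model_grid,
                          function(s) max(s$genetic_order, s$perm_order), 0L))
  if (max_order > nh)
    stop("model grid orders exceed the ", nh, " measured harvest(s)")

  hm <- summarize_harvest_means(tab)
  cmp <- scan_models(tab, sch, config$model_grid, config$control,
                     compute_lrt = config$compute_lrt)
  chosen <- config$force_model
  if (is.null(chosen)) chosen <- cmp$best
  if (is.na(chosen) || is.null(cmp$fits[[chosen]]))
    stop("no converged model available for extraction; attempted fits:\n",
         paste(utils::capture.output(print(cmp)), collapse = "\n"))
  fit <- cmp$fits[[chosen]]

  grid <- seq(sch$day_min, sch$day_max)
  traj <- trajectories(fit, grid, config$include_perm_in_h2)
  gv <- genetic_values(fit, grid)
  acc <- accuracy(fit, grid, config$accuracy_form)
  ef <- eigenfunctions(fit, grid = grid)
  pers <- persistence_index(
    gv, config$persistence_range,
    days_only = if (config$persistence_harvests_only) measured_days(sch))

  report <- structure(
    list(comparison = cmp, chosen_model = chosen, fit = fit,
         trajectories = traj, genetic_values = gv, accuracy = acc,
         eigenfunctions = ef, persistence = pers, harvest_means = hm,
         provenance = list(package_version = as.character(
                             utils::packageVersion("rrpersist")),
                           seed = config$seed,
                           n_records = fit$n_records,
                           timestamp = format(Sys.time(), tz = "UTC"))),
    class = "run_report")
  if (!is.null(config$output_dir))
    write_report(report, config$output_dir, plots = config$plots)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Longitudinal genetic analysis report\n")
  cat("  chosen model:", x$chosen_model, "\n")
  h2 <- x$trajectories$h2
  cat(sprintf("  h2 range over days: %.3f - %.3f\n", min(h2), max(h2)))
  cat("  eigen-proportions (%):",
      paste(sprintf("%.2f", x$eigenfunctions$proportions), collapse = ", "), "\n")
  cat("  top persistence:", x$persistence$genotype[1L],
      sprintf("(%.2f%%)\n", x$persistence$persistence[1L]))
  invisible(x)
}

write_report <- function(report, dir, plots = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  w(report$comparison$table, "comparison.csv")
  w(report$trajectories, "trajectories.csv")
  gv <- report$genetic_values
  w(data.frame(genotype = rownames(gv$values),
               as.data.frame(gv$values, check.names = FALSE)),
    "genetic_values.csv")
  w(data.frame(genotype = rownames(report$accuracy),
               as.data.frame(report$accuracy, check.names = FALSE)),
    "accuracy.csv")
  ef <- report$eigenfunctions
  w(data.frame(day = ef$days,
               stats::setNames(as.data.frame(ef$functions),
                               paste0("psi", seq_along(ef$values)))),
    "eigenfunctions.csv")
  w(report$persistence, "persistence.csv")
  w(data.frame(genotype = rownames(report$fit$alpha_hat),
               report$fit$alpha_hat, check.names = FALSE),
    "genetic_coefficients.csv")
  w(data.frame(plot = rownames(report$fit$p_hat),
               report$fit$p_hat, check.names = FALSE),
    "perm_env_coefficients.csv")
  jsonlite::write_json(
    list(chosen_model = report$chosen_model,
         minimum_bic_model = report$comparison$best,
         parsimony_model = report$comparison$parsimony,
         logL = report$fit$logL,
         converged = report$fit$converged,
         K_g = report$fit$params$K_g,
         K_p = report$fit$params$K_p,
         residual = report$fit$params$R_params,
         eigen_proportions = ef$proportions,
         h2_range = range(report$trajectories$h2),
         harvest_means = as.list(report$harvest_means$means),
         harvest_mean_excess_pct = report$harvest_means$excess_pct,
         provenance = report$provenance),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  if (plots) write_plots(report, dir)
  invisible(dir)
}

write_plots <- function(report, dir) {
  save_plot <- function(p, name) {
    grDevices::png(file.path(dir, name), width = 1400, height = 900, res = 150)
    print(p)
    grDevices::dev.off()
  }
  save_plot(plot_trajectories(report$trajectories), "trajectories.png")
  save_plot(plot_genetic_values(report$genetic_values), "genetic_values.png")
  save_plot(plot_eigenfunctions(report$eigenfunctions), "eigenfunctions.png")
  save_plot(plot_persistence(report$genetic_values, report$persistence),
            "persistence.png")
  invisible(NULL)
}
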