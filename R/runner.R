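#' Study configuration
#'
#' Canonical configuration object for a simulation run: factor overrides,
#' replication count, base seed, covariate variants, parallelism and the
#' estimator options. Absent fields take the documented defaults
#' (`reps = 5000`, `base_seed = 20191003`, both covariate variants). The
#' object round-trips losslessly through its JSON file representation via
#' [write_study_config()] / [read_study_config()].
#'
#' @param rho,n1,level,pbar Optional factor overrides (subsets or
#'   replacements of the default levels); `NULL` keeps the defaults.
#' @param reps Replications per condition.
#' @param base_seed Integer base seed.
#' @param variants Covariate variants to run (`TRUE` = included).
#' @param workers Parallel workers.
#' @param out_dir Output directory for CSV results.
#' @param correction Cluster-robust small-sample correction (`"CR1"` or
#'   `"none"`).
#' @param quantile_mode Sample-size quantile convention.
#' @return A list of class `"study_config"`.
#' @export
study_config <- function(rho = NULL, n1 = NULL, level = NULL, pbar = NULL,
                         reps = 5000, base_seed = 20191003,
                         variants = c(TRUE, FALSE), workers = 1,
                         out_dir = ".", correction = "CR1",
                         quantile_mode = "t-refined") {
  stopifnot(reps >= 1, is.numeric(base_seed), length(variants) >= 1,
            is.logical(variants), workers >= 1,
            correction %in% c("CR1", "none"),
            quantile_mode %in% c("t-refined", "normal"))
  # canonical types so the object is invariant under a JSON round-trip
  if (!is.null(rho)) rho <- as.numeric(rho)
  if (!is.null(n1)) n1 <- as.numeric(n1)
  if (!is.null(level)) level <- as.character(level)
  if (!is.null(pbar)) pbar <- as.numeric(pbar)
  structure(
    list(rho = rho, n1 = n1, level = level, pbar = pbar,
         reps = as.integer(reps), base_seed = as.integer(base_seed),
         variants = variants, workers = as.integer(workers),
         out_dir = out_dir, correction = correction,
         quantile_mode = quantile_mode),
    class = "study_config"
  )
}

#' Write a study configuration to JSON
#'
#' @param config A [study_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a study configuration from JSON
#'
#' Fields absent from the file take the [study_config()] defaults, so a
#' written configuration reads back identical.
#'
#' @param path JSON file path.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  raw <- raw[!vapply(raw, is.null, logical(1))]
  do.call(study_config, raw)
}

#' Run a configured simulation study and write its outputs
#'
#' Builds the condition grid from the configuration's factor overrides,
#' runs the Monte-Carlo study, and writes `grid.csv` (one row per
#' condition), `summary.csv` (performance criteria), `fits.csv`
#' (per-replication results) and `manifest.json` (configuration echo,
#' package version and seed — sufficient to reproduce the run) into the
#' output directory.
#'
#' @param config A [study_config()].
#' @param out_dir Output directory; defaults to the configuration's.
#' @param conditions_filter Optional character vector of condition ids to
#'   restrict the run to.
#' @return The performance-summary data frame, invisibly.
#' @export
run_simulation_study <- function(config, out_dir = config$out_dir,
                                 conditions_filter = NULL) {
  stopifnot(inherits(config, "study_config"))
  grid <- build_condition_grid(rho = config$rho, n1 = config$n1,
                               level = config$level, pbar = config$pbar,
                               quantile_mode = config$quantile_mode)
  if (!is.null(conditions_filter)) {
    grid <- grid[grid$condition_id %in% conditions_filter, , drop = FALSE]
    if (nrow(grid) == 0L)
      stop("conditions filter matched no condition")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  res <- run_study(grid, reps = config$reps, base_seed = config$base_seed,
                   variants = config$variants, workers = config$workers,
                   correction = config$correction, return_fits = TRUE)
  fits <- attr(res, "fits")
  fit_cols <- c("condition_id", "rep", "approach", "with_covariate",
                "estimate", "se", "ci_low", "ci_high", "p_value",
                "converged", "n_subjects_used", "n_clusters_used",
                "partial_F")

  utils::write.csv(grid, file.path(out_dir, "grid.csv"), row.names = FALSE)
  utils::write.csv(res, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(fits[, fit_cols], file.path(out_dir, "fits.csv"),
                   row.names = FALSE)
  manifest <- list(
    package = "crtcompliance",
    version = as.character(utils::packageVersion("crtcompliance")),
    config = unclass(config),
    n_conditions = nrow(grid))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(res)
}

# (level, covariate-variant) combinations of the four published panels
.figure_presets <- list(
  `2` = list(level = "cluster", with_covariate = TRUE),
  `3` = list(level = "cluster", with_covariate = FALSE),
  `4` = list(level = "subject", with_covariate = TRUE),
  `5` = list(level = "subject", with_covariate = FALSE)
)

#' Reproduce one of the published result figures
#'
#' Runs all six average non-compliance probabilities at intraclass
#' correlation 0.05 and cluster size 20 for the figure's (level of
#' non-compliance, covariate variant) combination — figure 2:
#' cluster/with covariate, 3: cluster/without, 4: subject/with,
#' 5: subject/without — and returns the tidy four-metric-by-pbar table.
#'
#' @param figure_id 2, 3, 4 or 5.
#' @param reps Replications per condition.
#' @param base_seed Integer base seed.
#' @param workers Parallel workers.
#' @return A [figure_export()] table: 6 pbar levels x 4 approaches x
#'   4 metrics.
#' @export
reproduce_figure <- function(figure_id, reps = 500, base_seed = 20191003,
                             workers = 1L) {
  key <- as.character(figure_id)
  if (!key %in% names(.figure_presets))
    stop("usage error: figure id must be one of 2, 3, 4, 5")
  preset <- .figure_presets[[key]]
  grid <- build_condition_grid(rho = 0.05, n1 = 20, level = preset$level)
  res <- run_study(grid, reps = reps, base_seed = base_seed,
                   variants = preset$with_covariate, workers = workers)
  figure_export(res, grid, figure = as.integer(figure_id))
}
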