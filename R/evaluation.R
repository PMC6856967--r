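#' Target estimand of an analysis approach
#'
#' ITT estimates the causal effect of treatment *assignment*, which under
#' never-taker non-compliance equals `beta1 * (1 - pbar)`; AT, PP and IV
#' target the causal effect of treatment *received*, `beta1` (for IV, the
#' complier average causal effect, which coincides with `beta1` under this
#' generating model).
#'
#' @param approach One of `"ITT"`, `"AT"`, `"PP"`, `"IV"`.
#' @param condition A [simulation_condition()] (or coercible).
#' @return The population value the approach's mean estimate is compared
#'   against.
#' @examples
#' cond <- simulation_condition(rho = 0.05, n1 = 20,
#'                              level = "cluster", pbar = 0.5)
#' target_estimand("ITT", cond)  # 0.1
#' target_estimand("IV", cond)   # 0.2
#' @export
target_estimand <- function(approach, condition) {
  condition <- as_condition(condition)
  b1 <- condition$design$beta1
  switch(approach,
         ITT = b1 * (1 - condition$compliance$pbar),
         AT = b1, PP = b1, IV = b1,
         stop("unknown approach: ", approach))
}

#' Summarize replications of one condition into performance criteria
#'
#' Computes, per (approach, covariate variant), the four evaluation
#' criteria: mean and standard deviation of the treatment-effect estimates,
#' coverage of the 95% confidence interval with respect to the approach's
#' target estimand, and empirical power (fraction of replications with
#' two-sided p < `alpha`). Non-converged replications are excluded from
#' all four metrics and counted.
#'
#' @param fits Data frame of `FitResult` rows from repeated analyses of
#'   trials generated under `condition`.
#' @param condition The [simulation_condition()] the fits belong to.
#' @param alpha Significance level for the power criterion.
#' @return Data frame with one row per (approach, with_covariate) present
#'   in `fits`: `condition_id, approach, with_covariate, target_estimand,
#'   mean_estimate, sd_estimate, coverage, power, n_reps, n_converged`.
#'   With zero converged replications the metrics are `NA`.
#' @export
summarize_condition <- function(fits, condition, alpha = 0.05) {
  condition <- as_condition(condition)
  groups <- unique(fits[, c("approach", "with_covariate")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- fits[fits$approach == groups$approach[i] &
                fits$with_covariate == groups$with_covariate[i], ]
    tgt <- target_estimand(groups$approach[i], condition)
    conv <- g[g$converged, ]
    n_conv <- nrow(conv)
    data.frame(
      condition_id = condition$condition_id,
      approach = groups$approach[i],
      with_covariate = groups$with_covariate[i],
      target_estimand = tgt,
      mean_estimate = if (n_conv > 0L) mean(conv$estimate) else NA_real_,
      sd_estimate = if (n_conv > 1L) stats::sd(conv$estimate) else NA_real_,
      coverage = if (n_conv > 0L)
        mean(conv$ci_low <= tgt & tgt <= conv$ci_high) else NA_real_,
      power = if (n_conv > 0L) mean(conv$p_value < alpha) else NA_real_,
      n_reps = nrow(g), n_converged = n_conv,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(match(out$approach, c("ITT", "AT", "PP", "IV")),
               !out$with_covariate)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# deterministic per-replication seed from (base_seed, condition_id, rep):
# a Lehmer-style mix mod 2^31 - 1, so replication streams are independent
# of scheduling order and safe for 32-bit set.seed()
.MOD31 <- 2147483647
rep_seed <- function(base_seed, condition_id, rep_index) {
  h <- 0
  for (ch in utf8ToInt(condition_id)) h <- (h * 131 + ch) %% .MOD31
  s <- base_seed %% .MOD31
  s <- (s * 48271 + h) %% .MOD31
  s <- (s * 48271 + rep_index) %% .MOD31
  as.integer(s)
}

# run all replications of a single condition; returns per-replication fits
.run_condition <- function(cond, reps, base_seed, approaches, variants,
                           correction, f_type) {
  fits <- vector("list", reps)
  for (r in seq_len(reps)) {
    trial <- generate_trial(cond, seed = rep_seed(base_seed,
                                                  cond$condition_id, r))
    f <- tryCatch(
      fit_all_approaches(trial, approaches = approaches,
                         variants = variants, correction = correction,
                         f_type = f_type),
      error = function(e) {
        warning("replication ", r, " of ", cond$condition_id,
                " failed: ", conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(f)) next
    f$condition_id <- cond$condition_id
    f$rep <- r
    fits[[r]] <- f
  }
  do.call(rbind, fits)
}

#' Run the Monte-Carlo simulation study
#'
#' For every condition and replication, generates one trial and analyzes
#' that same dataset with every requested approach and covariate variant,
#' then reduces the replications to the four performance criteria via
#' [summarize_condition()]. Replication seeds are derived from
#' `(base_seed, condition_id, rep)`, so results are deterministic for a
#' fixed configuration and identical whether conditions are run serially
#' or in parallel.
#'
#' @param conditions A condition grid from [build_condition_grid()] (any
#'   subset of rows), or a single [simulation_condition()].
#' @param reps Replications per condition.
#' @param base_seed Integer base seed.
#' @param approaches Subset of `c("ITT", "AT", "PP", "IV")` to fit.
#' @param variants Covariate variants: `TRUE` (included), `FALSE`
#'   (omitted), or both.
#' @param workers Number of parallel workers (forked; conditions are the
#'   unit of work).
#' @param correction,f_type Passed to [fit_iv()].
#' @param alpha Significance level for the power criterion.
#' @param return_fits Also attach the per-replication fit table as
#'   attribute `"fits"` of the summary.
#' @return Data frame of per-(condition, approach, variant) performance
#'   summaries; see [summarize_condition()].
#' @examples
#' \donttest{
#' cond <- build_condition_grid(rho = 0.05, n1 = 20,
#'                              level = "cluster", pbar = 0)
#' run_study(cond, reps = 5, base_seed = 1, approaches = "ITT",
#'           variants = TRUE)
#' }
#' @export
run_study <- function(conditions, reps, base_seed = 20191003,
                      approaches = c("ITT", "AT", "PP", "IV"),
                      variants = c(TRUE, FALSE), workers = 1L,
                      correction = c("CR1", "none"),
                      f_type = c("cluster-robust", "classical"),
                      alpha = 0.05, return_fits = FALSE) {
  stopifnot(reps >= 1)
  correction <- match.arg(correction)
  f_type <- match.arg(f_type)
  approaches <- match.arg(approaches, several.ok = TRUE)
  cond_list <- if (inherits(conditions, "simulation_condition")) {
    list(conditions)
  } else {
    lapply(seq_len(nrow(conditions)),
           function(i) as_condition(conditions[i, , drop = FALSE]))
  }

  one <- function(cond) {
    fits <- .run_condition(cond, reps, base_seed, approaches, variants,
                           correction, f_type)
    list(summary = summarize_condition(fits, cond, alpha = alpha),
         fits = fits)
  }
  results <- if (workers > 1L) {
    parallel::mclapply(cond_list, one, mc.cores = workers)
  } else {
    lapply(cond_list, one)
  }

  summary <- do.call(rbind, lapply(results, `[[`, "summary"))
  rownames(summary) <- NULL
  if (return_fits) {
    fits <- do.call(rbind, lapply(results, `[[`, "fits"))
    first <- c("condition_id", "rep")
    fits <- fits[, c(first, setdiff(names(fits), first))]
    rownames(fits) <- NULL
    attr(summary, "fits") <- fits
  }
  summary
}

#' Reshape a performance summary into tidy figure-export form
#'
#' One row per (condition, approach, variant, metric), mirroring the
#' four-panel layout (mean estimate, SD, coverage, power) against the
#' average probability of non-compliance.
#'
#' @param summary Output of [run_study()] / [summarize_condition()].
#' @param conditions The condition grid used, to recover `pbar` and
#'   `level` per condition id.
#' @param figure Optional figure label attached to every row.
#' @return Data frame with columns `figure, panel, pbar, approach, metric,
#'   value`, where `panel` identifies the (level, variant) combination.
#' @export
figure_export <- function(summary, conditions, figure = NA) {
  idx <- match(summary$condition_id, conditions$condition_id)
  metrics <- c("mean_estimate", "sd_estimate", "coverage", "power")
  rows <- lapply(metrics, function(m) {
    data.frame(figure = figure,
               panel = paste0(conditions$level[idx], "/",
                              ifelse(summary$with_covariate,
                                     "with_covariate", "without_covariate")),
               pbar = conditions$pbar[idx],
               approach = summary$approach,
               metric = m,
               value = summary[[m]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$metric, out$panel, out$pbar,
                   match(out$approach, c("ITT", "AT", "PP", "IV"))), ]
  rownames(out) <- NULL
  out
}
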