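#' Design parameters for a two-level cluster randomized trial
#'
#' Bundles the fixed effects, variance components and error rates that define
#' one simulated trial design. The residual outcome variance is split into a
#' between-cluster component `tau2 = rho * total_var` and a within-cluster
#' component `sigma2 = (1 - rho) * total_var`, so `rho` is the intraclass
#' correlation conditional on treatment received and the covariate.
#'
#' @param rho Intraclass correlation coefficient, in `[0, 1)`.
#' @param n1 Subjects per cluster (constant across clusters), `>= 1`.
#' @param n2 Number of clusters. If `NULL`, filled in by
#'   [required_clusters()] so the trial has the target power under full
#'   compliance.
#' @param beta0 Outcome intercept (expected control-arm outcome at X = 0).
#' @param beta1 Causal effect of treatment received.
#' @param beta2 Direct covariate effect on the outcome.
#' @param total_var Total residual variance `tau2 + sigma2`.
#' @param alpha Two-sided type I error rate.
#' @param power_target Desired power for the test of the treatment effect.
#' @param quantile_mode Sample-size quantile convention passed to
#'   [required_clusters()] when `n2` is `NULL`.
#'
#' @return An object of class `"design_params"`: a list with the arguments
#'   plus the derived components `tau2` and `sigma2`.
#' @examples
#' dp <- design_params(rho = 0.05, n1 = 20)
#' dp$n2      # clusters needed for 80% power
#' dp$tau2 + dp$sigma2 == dp$total_var
#' @export
design_params <- function(rho, n1, n2 = NULL, beta0 = 0, beta1 = 0.2,
                          beta2 = 0.2, total_var = 1, alpha = 0.05,
                          power_target = 0.8,
                          quantile_mode = c("t-refined", "normal")) {
  quantile_mode <- match.arg(quantile_mode)
  stopifnot(is.numeric(rho), length(rho) == 1L, rho >= 0, rho < 1,
            is.numeric(n1), length(n1) == 1L, n1 >= 1,
            is.numeric(total_var), total_var > 0,
            alpha > 0, alpha < 1, power_target > 0, power_target < 1)
  if (is.null(n2)) {
    n2 <- required_clusters(n1 = n1, rho = rho, beta1 = beta1,
                            total_var = total_var, alpha = alpha,
                            power_target = power_target,
                            quantile_mode = quantile_mode)
  }
  stopifnot(is.numeric(n2), length(n2) == 1L, n2 >= 2)
  structure(
    list(rho = rho, n1 = as.integer(n1), n2 = as.integer(n2),
         beta0 = beta0, beta1 = beta1, beta2 = beta2,
         total_var = total_var,
         tau2 = rho * total_var, sigma2 = (1 - rho) * total_var,
         alpha = alpha, power_target = power_target),
    class = "design_params"
  )
}

#' Number of clusters required for a target power
#'
#' Computes the number of clusters `n2` for a two-arm cluster randomized
#' trial with 1:1 allocation, equal cluster sizes and a continuous outcome,
#' using the design-effect formula
#' \deqn{n_2 = 4 (\sigma^2+\tau^2) \frac{1 + (n_1 - 1)\rho}{n_1}
#'   \left(\frac{z_{1-\alpha/2} + z_{1-\beta}}{\beta_1}\right)^2,}
#' rounded upwards to the nearest integer. The default `"t-refined"` mode
#' then recomputes the formula once with Student-t quantiles at
#' `df = n2 - 2` (and rounds up again), which guards against the slight
#' undercoverage of normal quantiles at small numbers of clusters;
#' `"normal"` mode stops after the first stage. Over the default factor grid
#' the refined rule returns between 38 and 152 clusters.
#'
#' @param n1 Cluster size, `>= 1`.
#' @param rho Intraclass correlation, in `[0, 1)`.
#' @param beta1 Treatment effect to detect; must be nonzero.
#' @param total_var Total residual variance.
#' @param alpha Two-sided type I error rate.
#' @param power_target Desired power.
#' @param quantile_mode `"t-refined"` (default) or `"normal"`.
#'
#' @return Integer number of clusters, always `>= 2`.
#' @examples
#' required_clusters(n1 = 50, rho = 0.025)  # 38
#' required_clusters(n1 = 10, rho = 0.1)    # 152
#' @export
required_clusters <- function(n1, rho, beta1 = 0.2, total_var = 1,
                              alpha = 0.05, power_target = 0.8,
                              quantile_mode = c("t-refined", "normal")) {
  quantile_mode <- match.arg(quantile_mode)
  if (!is.numeric(rho) || rho < 0 || rho >= 1)
    stop("invalid design: rho must lie in [0, 1)")
  if (!is.numeric(beta1) || beta1 == 0)
    stop("invalid design: beta1 must be nonzero")
  stopifnot(n1 >= 1, total_var > 0,
            alpha > 0, alpha < 1, power_target > 0, power_target < 1)
  de <- 1 + (n1 - 1) * rho
  base <- 4 * total_var * de / n1 / beta1^2
  n2 <- ceiling(base * (stats::qnorm(1 - alpha / 2) +
                          stats::qnorm(power_target))^2)
  if (quantile_mode == "t-refined") {
    df <- max(n2 - 2, 1)
    n2 <- ceiling(base * (stats::qt(1 - alpha / 2, df) +
                            stats::qt(power_target, df))^2)
  }
  max(as.integer(n2), 2L)
}

# default factor levels of the simulation grid
.default_factors <- function() {
  list(rho = c(0.025, 0.05, 0.1),
       n1 = c(10, 20, 50),
       level = c("cluster", "subject"),
       pbar = c(0, 0.1, 0.2, 0.3, 0.4, 0.5))
}

#' Stable identifier for one simulation condition
#'
#' @param rho,n1,level,pbar Factor levels of the condition.
#' @return Character key, a deterministic function of the factor levels.
#' @keywords internal
condition_id <- function(rho, n1, level, pbar) {
  sprintf("rho%.3f_n1.%02d_%s_pbar%.2f", rho, as.integer(n1), level, pbar)
}

#' Enumerate the simulation condition grid
#'
#' Builds the Cartesian product of the factor levels (intraclass
#' correlation, cluster size, level of non-compliance, average
#' non-compliance probability), fills in the number of clusters via
#' [required_clusters()] and assigns a stable `condition_id`. The default
#' levels give the full 3 x 3 x 2 x 6 = 108-condition grid.
#'
#' @param rho,n1,level,pbar Factor levels; each may be overridden with a
#'   non-empty subset or replacement of the defaults.
#' @param beta0,beta1,beta2,total_var,alpha,power_target Fixed design
#'   constants shared by all conditions.
#' @param quantile_mode Quantile convention for [required_clusters()].
#'
#' @return A data frame with one row per condition and columns
#'   `condition_id, rho, n1, n2, level, pbar, beta0, beta1, beta2,
#'   total_var`, ordered by `(rho, n1, level, pbar)`.
#' @examples
#' nrow(build_condition_grid())                 # 108
#' nrow(build_condition_grid(rho = 0.05))       # 36
#' @export
build_condition_grid <- function(rho = NULL, n1 = NULL, level = NULL,
                                 pbar = NULL, beta0 = 0, beta1 = 0.2,
                                 beta2 = 0.2, total_var = 1, alpha = 0.05,
                                 power_target = 0.8,
                                 quantile_mode = c("t-refined", "normal")) {
  quantile_mode <- match.arg(quantile_mode)
  fac <- .default_factors()
  if (!is.null(rho)) fac$rho <- rho
  if (!is.null(n1)) fac$n1 <- n1
  if (!is.null(level)) fac$level <- level
  if (!is.null(pbar)) fac$pbar <- pbar
  for (nm in names(fac)) {
    if (length(fac[[nm]]) == 0L)
      stop("invalid config: empty factor list for '", nm, "'")
  }
  if (!all(fac$level %in% c("cluster", "subject")))
    stop("invalid config: level must be 'cluster' or 'subject'")
  if (any(fac$pbar < 0 | fac$pbar > 0.5))
    stop("invalid config: pbar must lie in [0, 0.5]")

  g <- expand.grid(pbar = sort(fac$pbar),
                   level = sort(unique(as.character(fac$level))),
                   n1 = sort(fac$n1), rho = sort(fac$rho),
                   stringsAsFactors = FALSE)
  g <- g[, c("rho", "n1", "level", "pbar")]
  g <- g[order(g$rho, g$n1, g$level, g$pbar), , drop = FALSE]

  # n2 depends only on (rho, n1); compute once per pair
  key <- paste(g$rho, g$n1)
  ukey <- !duplicated(key)
  n2map <- vapply(which(ukey), function(i) {
    required_clusters(n1 = g$n1[i], rho = g$rho[i], beta1 = beta1,
                      total_var = total_var, alpha = alpha,
                      power_target = power_target,
                      quantile_mode = quantile_mode)
  }, integer(1))
  names(n2map) <- key[ukey]

  out <- data.frame(
    condition_id = condition_id(g$rho, g$n1, g$level, g$pbar),
    rho = g$rho, n1 = as.integer(g$n1), n2 = as.integer(n2map[key]),
    level = g$level, pbar = g$pbar,
    beta0 = beta0, beta1 = beta1, beta2 = beta2, total_var = total_var,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "power_target") <- power_target
  out
}

#' Assemble a single simulation condition
#'
#' Convenience constructor joining a [design_params()] object with a
#' [compliance_spec()] under a stable condition identifier.
#'
#' @inheritParams design_params
#' @param level `"cluster"` or `"subject"` level non-compliance.
#' @param pbar Average probability of non-compliance, in `[0, 0.5]`.
#' @return A list of class `"simulation_condition"` with elements `design`,
#'   `compliance` and `condition_id`.
#' @examples
#' cond <- simulation_condition(rho = 0.05, n1 = 20,
#'                              level = "cluster", pbar = 0.3)
#' cond$design$n2
#' @export
simulation_condition <- function(rho, n1, level, pbar, n2 = NULL, beta0 = 0,
                                 beta1 = 0.2, beta2 = 0.2, total_var = 1,
                                 alpha = 0.05, power_target = 0.8,
                                 quantile_mode = c("t-refined", "normal")) {
  design <- design_params(rho = rho, n1 = n1, n2 = n2, beta0 = beta0,
                          beta1 = beta1, beta2 = beta2,
                          total_var = total_var, alpha = alpha,
                          power_target = power_target,
                          quantile_mode = match.arg(quantile_mode))
  structure(
    list(design = design,
         compliance = compliance_spec(level = level, pbar = pbar),
         condition_id = condition_id(rho, n1, level, pbar)),
    class = "simulation_condition"
  )
}

#' Coerce a condition-grid row to a simulation condition
#'
#' @param x A `"simulation_condition"`, or a one-row data frame as produced
#'   by [build_condition_grid()].
#' @param ... Passed on to [simulation_condition()] for data-frame input.
#' @return A `"simulation_condition"` object.
#' @export
as_condition <- function(x, ...) {
  if (inherits(x, "simulation_condition")) return(x)
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    return(simulation_condition(rho = x$rho, n1 = x$n1, level = x$level,
                                pbar = x$pbar, n2 = x$n2, beta0 = x$beta0,
                                beta1 = x$beta1, beta2 = x$beta2,
                                total_var = x$total_var, ...))
  }
  stop("cannot coerce object of class '", class(x)[1L],
       "' to a simulation condition")
}
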