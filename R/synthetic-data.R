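#' Covariate-driven non-compliance specification
#'
#' Non-compliance is restricted to never-takers: a never-taking subject (or
#' cluster) does not receive the intervention regardless of assignment, and
#' no control subject can access it. The probability of being a never-taker
#' depends on a covariate X through its tertile band: below the lower
#' standard-normal tertile the probability is `0.5 * pbar`, between the
#' tertiles it is `pbar`, and at or above the upper tertile `1.5 * pbar`.
#' Because the bands have equal mass and the multipliers average to one,
#' the marginal never-taker probability is exactly `pbar`.
#'
#' @param level `"cluster"` (whole clusters share one compliance status) or
#'   `"subject"` (independent statuses within clusters).
#' @param pbar Average probability of non-compliance; `1.5 * pbar` must not
#'   exceed 1.
#' @return A list of class `"compliance_spec"` with elements `level`,
#'   `pbar`, `multipliers` and `cutoffs` (standard-normal tertiles).
#' @examples
#' compliance_spec("cluster", 0.3)
#' @export
compliance_spec <- function(level = c("cluster", "subject"), pbar) {
  level <- match.arg(level)
  stopifnot(is.numeric(pbar), length(pbar) == 1L, pbar >= 0)
  if (1.5 * pbar > 1)
    stop("invalid compliance spec: 1.5 * pbar exceeds 1")
  structure(
    list(level = level, pbar = pbar,
         multipliers = c(0.5, 1, 1.5),
         cutoffs = stats::qnorm(c(1 / 3, 2 / 3))),
    class = "compliance_spec"
  )
}

#' Probability of non-compliance given the covariate
#'
#' Piecewise-constant probability over the covariate's standard-normal
#' tertile bands. Bands are left-closed: values equal to a cutoff fall in
#' the upper band, a measure-zero convention fixed for determinism.
#'
#' @param x Covariate value(s).
#' @param spec A [compliance_spec()].
#' @return Numeric vector of never-taker probabilities, same length as `x`.
#' @examples
#' sp <- compliance_spec("subject", 0.2)
#' noncompliance_probability(c(-1, 0, 1), sp)  # 0.1 0.2 0.3
#' @export
noncompliance_probability <- function(x, spec) {
  stopifnot(inherits(spec, "compliance_spec"))
  band <- findInterval(x, spec$cutoffs) + 1L  # 1,2,3 = lower,middle,upper
  spec$pbar * spec$multipliers[band]
}

# canonical subject -> cluster layout: n2 clusters of n1 subjects
.cluster_ids <- function(design) rep(seq_len(design$n2), each = design$n1)

#' Draw the compliance covariate
#'
#' Under cluster-level non-compliance, X is a single standard-normal draw
#' per cluster, shared by all its subjects. Under subject-level
#' non-compliance, X has a between-cluster component `B_j ~ N(0, rho)` and
#' a within component `W_ij ~ N(0, 1 - rho)`, so its marginal variance is 1
#' and its intraclass correlation matches the outcome's.
#'
#' Draws come from the current R random-number stream; callers seed it
#' (see [generate_trial()]).
#'
#' @param condition A [simulation_condition()] (or coercible via
#'   [as_condition()]).
#' @return Numeric vector of per-subject covariate values, in cluster-major
#'   order (cluster 1 subjects first).
#' @export
draw_covariate <- function(condition) {
  condition <- as_condition(condition)
  d <- condition$design
  if (condition$compliance$level == "cluster") {
    rep(stats::rnorm(d$n2), each = d$n1)
  } else {
    rep(stats::rnorm(d$n2, 0, sqrt(d$rho)), each = d$n1) +
      stats::rnorm(d$n1 * d$n2, 0, sqrt(1 - d$rho))
  }
}

#' Assign complier / never-taker status
#'
#' Cluster-level non-compliance draws one Bernoulli never-taker indicator
#' per cluster from that cluster's covariate value; subject-level draws one
#' per subject. The complier indicator is `C = 1 - never_taker`.
#'
#' @param condition A [simulation_condition()] (or coercible).
#' @param X Per-subject covariate vector as returned by [draw_covariate()];
#'   for cluster-level conditions it must be constant within clusters.
#' @return Integer vector of per-subject complier indicators (0/1).
#' @export
assign_compliance <- function(condition, X) {
  condition <- as_condition(condition)
  d <- condition$design
  sp <- condition$compliance
  cl <- .cluster_ids(d)
  stopifnot(length(X) == d$n1 * d$n2)
  if (sp$level == "cluster") {
    xj <- X[!duplicated(cl)]
    if (any(stats::ave(X, cl, FUN = stats::var) > 0, na.rm = TRUE))
      stop("contract violation: cluster-level covariate varies within clusters")
    never <- stats::rbinom(d$n2, 1L, noncompliance_probability(xj, sp))
    1L - never[cl]
  } else {
    1L - stats::rbinom(length(X), 1L, noncompliance_probability(X, sp))
  }
}

#' Generate one simulated cluster randomized trial
#'
#' Simulation order: (1) clusters are randomized 1:1 to intervention and
#' control, the intervention arm receiving the extra cluster when `n2` is
#' odd, with arm labels permuted at random; (2) the covariate X is drawn;
#' (3) complier status C is assigned from X; (4) treatment received is
#' `D = Z * C` (never-takers only — no control subject receives the
#' intervention); (5) the outcome is
#' `Y = beta0 + beta1 * D + beta2 * X + u_j + e_ij` with
#' `u_j ~ N(0, rho * total_var)` and `e_ij ~ N(0, (1 - rho) * total_var)`.
#' Intervention-arm never-takers therefore follow the same outcome model as
#' control subjects with the same covariate value.
#'
#' @param condition A [simulation_condition()] (or coercible).
#' @param seed Optional integer seed set before any draws; identical
#'   `(condition, seed)` pairs give bit-identical trials.
#' @return A data frame with one row per subject and columns `cluster_id`,
#'   `Z` (assignment, constant within cluster), `X`, `C` (complier), `D`
#'   (treatment received), `Y`, plus the latent effects `u` (cluster effect,
#'   repeated within cluster) and `e`, retained for testing. The condition
#'   is attached as attribute `"condition"`.
#' @examples
#' cond <- simulation_condition(rho = 0.05, n1 = 5, level = "cluster",
#'                              pbar = 0.3, n2 = 8)
#' tr <- generate_trial(cond, seed = 1)
#' all(tr$D == tr$Z * tr$C)
#' @export
generate_trial <- function(condition, seed = NULL) {
  condition <- as_condition(condition)
  d <- condition$design
  if (!is.null(seed)) set.seed(seed)
  cl <- .cluster_ids(d)

  n_int <- ceiling(d$n2 / 2)
  z_cluster <- sample(rep(c(1L, 0L), c(n_int, d$n2 - n_int)))
  Z <- z_cluster[cl]

  X <- draw_covariate(condition)
  C <- assign_compliance(condition, X)
  D <- Z * C

  u_cluster <- stats::rnorm(d$n2, 0, sqrt(d$tau2))
  e <- stats::rnorm(d$n1 * d$n2, 0, sqrt(d$sigma2))
  Y <- d$beta0 + d$beta1 * D + d$beta2 * X + u_cluster[cl] + e

  out <- data.frame(cluster_id = cl, Z = Z, X = X, C = C, D = D, Y = Y,
                    u = u_cluster[cl], e = e)
  attr(out, "condition") <- condition
  out
}

#' Write one simulated trial to CSV
#'
#' Dumps the observable columns (`cluster_id, Z, X, C, D, Y`) of a trial,
#' for debugging and for building plain-text fixtures.
#'
#' @param trial A trial data frame from [generate_trial()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  utils::write.csv(trial[, c("cluster_id", "Z", "X", "C", "D", "Y")],
                   path, row.names = FALSE)
  invisible(path)
}
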