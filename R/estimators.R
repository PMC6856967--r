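#' @importFrom stats pnorm qnorm var coef resid
NULL

# Wald-type inference convention: 95% CI = est +/- 1.96 se, two-sided z
# p-value. Applied uniformly to all four approaches so that coverage and
# power are mutually consistent.
.z_crit <- 1.96

.fit_result <- function(approach, with_covariate, estimate = NA_real_,
                        se = NA_real_, converged = FALSE,
                        n_subjects_used = NA_integer_,
                        n_clusters_used = NA_integer_,
                        alpha0 = NA_real_, alpha1 = NA_real_,
                        partial_F = NA_real_) {
  if (converged) {
    ci_low <- estimate - .z_crit * se
    ci_high <- estimate + .z_crit * se
    p_value <- 2 * stats::pnorm(-abs(estimate / se))
  } else {
    estimate <- se <- ci_low <- ci_high <- p_value <- NA_real_
  }
  data.frame(approach = approach, with_covariate = with_covariate,
             estimate = estimate, se = se, ci_low = ci_low,
             ci_high = ci_high, p_value = p_value, converged = converged,
             n_subjects_used = as.integer(n_subjects_used),
             n_clusters_used = as.integer(n_clusters_used),
             alpha0 = alpha0, alpha1 = alpha1, partial_F = partial_F,
             stringsAsFactors = FALSE)
}

#' Random-intercept linear mixed model by REML
#'
#' Fits `outcome ~ predictors + (1 | cluster)` by restricted maximum
#' likelihood. Fixed effects are the generalized-least-squares estimates at
#' the REML variance components; their standard errors come from the
#' fixed-effects covariance at those components. REML is used because it
#' corrects the variance components for the fixed-effects degrees of
#' freedom, which matters when the number of clusters is modest.
#'
#' @param outcome Numeric response vector.
#' @param predictors Matrix or data frame of design columns (no intercept
#'   column; one is always added).
#' @param clusters Cluster identifier per observation.
#' @return A list with `coefficients` (data frame: term, estimate, se),
#'   `varcomp` (named vector `tau2`, `sigma2`), `converged`, `n_obs`,
#'   `n_clusters`. A singular or otherwise unstable fit is flagged
#'   `converged = FALSE`, never raised.
#' @examples
#' set.seed(1)
#' cl <- rep(1:10, each = 4)
#' x <- rnorm(40)
#' y <- 0.5 * x + rnorm(10)[cl] + rnorm(40)
#' fit_random_intercept_reml(y, cbind(x = x), cl)$coefficients
#' @export
fit_random_intercept_reml <- function(outcome, predictors, clusters) {
  predictors <- as.data.frame(predictors)
  n <- length(outcome)
  stopifnot(nrow(predictors) == n, length(clusters) == n)
  if (length(unique(clusters)) < 2L)
    stop("degenerate data: at least 2 clusters are required")

  dat <- cbind(.y = outcome, predictors,
               .cl = factor(clusters, levels = unique(clusters)))
  form <- stats::as.formula(paste(
    ".y ~", paste(names(predictors), collapse = " + "), "+ (1 | .cl)"))
  fit <- tryCatch(
    suppressMessages(lme4::lmer(
      form, data = dat, REML = TRUE,
      control = lme4::lmerControl(calc.derivs = FALSE,
                                  check.conv.singular = "ignore"))),
    error = function(e) NULL)

  k <- ncol(predictors) + 1L
  if (is.null(fit) || length(lme4::fixef(fit)) != k ||
      anyNA(lme4::fixef(fit))) {
    return(list(coefficients = NULL,
                varcomp = c(tau2 = NA_real_, sigma2 = NA_real_),
                converged = FALSE, n_obs = n,
                n_clusters = length(unique(clusters))))
  }
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  vc <- lme4::VarCorr(fit)
  list(coefficients = data.frame(term = names(est), estimate = unname(est),
                                 se = unname(se), stringsAsFactors = FALSE),
       varcomp = c(tau2 = unname(vc$.cl[1L, 1L]),
                   sigma2 = attr(vc, "sc")^2),
       converged = TRUE, n_obs = n,
       n_clusters = length(unique(clusters)))
}

# shared backend for ITT / AT / PP: mixed model of Y on one treatment
# column (+ X), inference on the treatment coefficient
.fit_mixed_approach <- function(approach, data, treat_col, with_covariate) {
  preds <- data.frame(trt = data[[treat_col]])
  if (with_covariate) preds$X <- data$X
  fit <- fit_random_intercept_reml(data$Y, preds, data$cluster_id)
  if (!fit$converged) {
    return(.fit_result(approach, with_covariate,
                       n_subjects_used = nrow(data),
                       n_clusters_used = fit$n_clusters))
  }
  i <- match("trt", fit$coefficients$term)
  .fit_result(approach, with_covariate,
              estimate = fit$coefficients$estimate[i],
              se = fit$coefficients$se[i], converged = TRUE,
              n_subjects_used = nrow(data),
              n_clusters_used = fit$n_clusters)
}

#' Intention-to-treat analysis
#'
#' Mixed-model regression of the outcome on treatment *assignment* Z (plus
#' the covariate if requested), using all subjects. Its estimand is the
#' causal effect of assignment, `beta1 * (1 - pbar)` under never-taker
#' non-compliance.
#'
#' @param data A trial data frame from [generate_trial()].
#' @param with_covariate Include the covariate X in the model?
#' @return One-row data frame (a `FitResult`): `approach, with_covariate,
#'   estimate, se, ci_low, ci_high, p_value, converged, n_subjects_used,
#'   n_clusters_used, alpha0, alpha1, partial_F` (the last three are only
#'   populated by [fit_iv()]).
#' @export
fit_itt <- function(data, with_covariate = TRUE) {
  .fit_mixed_approach("ITT", data, "Z", with_covariate)
}

#' As-treated analysis
#'
#' Mixed-model regression of the outcome on treatment *received* D, all
#' subjects retained. Never-takers in the intervention arm are analyzed
#' alongside the control arm, which breaks randomization: D is correlated
#' with the covariate that drives compliance, so the estimate is biased
#' when that covariate is omitted.
#'
#' @inheritParams fit_itt
#' @return A `FitResult` row; see [fit_itt()].
#' @export
fit_at <- function(data, with_covariate = TRUE) {
  .fit_mixed_approach("AT", data, "D", with_covariate)
}

#' Per-protocol analysis
#'
#' Drops subjects whose treatment received differs from their assignment
#' (intervention-arm never-takers; the control arm is fully retained since
#' D = Z = 0 there), then regresses the outcome on D as in [fit_at()].
#' Clusters emptied by the exclusion are dropped. If fewer than two
#' clusters with at least one subject remain in either arm, the result is
#' flagged non-converged rather than raised.
#'
#' @inheritParams fit_itt
#' @return A `FitResult` row; see [fit_itt()]. `n_subjects_used` and
#'   `n_clusters_used` reflect the exclusions.
#' @export
fit_pp <- function(data, with_covariate = TRUE) {
  keep <- data$D == data$Z
  sub <- data[keep, , drop = FALSE]
  arms <- tapply(sub$cluster_id, sub$Z, function(x) length(unique(x)))
  if (length(arms) < 2L || any(arms < 2L)) {
    return(.fit_result("PP", with_covariate, n_subjects_used = nrow(sub),
                       n_clusters_used = length(unique(sub$cluster_id))))
  }
  .fit_mixed_approach("PP", sub, "D", with_covariate)
}

#' Cluster-robust (Huber-White) covariance of regression coefficients
#'
#' Sandwich estimator for coefficients of a linear model whose residuals
#' may be correlated within clusters: the bread is the inverse
#' cross-product of the design matrix and the meat sums, over clusters,
#' the outer products of within-cluster score totals. The default `"CR1"`
#' small-sample correction scales the sandwich by
#' `G/(G-1) * (N-1)/(N-k)`; with one subject per cluster this reduces to
#' the HC1 heteroskedasticity-robust estimator.
#'
#' @param design Numeric design matrix (including the intercept column),
#'   full column rank.
#' @param residuals Residual vector; for two-stage least squares these must
#'   be formed with the observed (not first-stage fitted) regressors.
#' @param clusters Cluster identifier per row.
#' @param correction `"CR1"` (default) or `"none"`.
#' @return Symmetric covariance matrix of the coefficients.
#' @examples
#' x <- cbind(1, rnorm(12)); y <- x %*% c(1, 2) + rnorm(12)
#' b <- qr.solve(x, y)
#' cluster_robust_covariance(x, y - x %*% b, rep(1:4, each = 3))
#' @export
cluster_robust_covariance <- function(design, residuals, clusters,
                                      correction = c("CR1", "none")) {
  correction <- match.arg(correction)
  design <- as.matrix(design)
  n <- nrow(design)
  k <- ncol(design)
  stopifnot(length(residuals) == n, length(clusters) == n)
  if (qr(design)$rank < k)
    stop("rank-deficient design matrix")
  bread <- solve(crossprod(design))
  # G x k matrix of within-cluster score sums X_g' e_g
  scores <- rowsum(design * residuals, group = clusters)
  meat <- crossprod(scores)
  v <- bread %*% meat %*% bread
  if (correction == "CR1") {
    g <- nrow(scores)
    if (g < 2L) stop("cluster-robust covariance needs at least 2 clusters")
    v <- v * g / (g - 1) * (n - 1) / (n - k)
  }
  (v + t(v)) / 2
}

# first-stage partial F for the instrument: squared Wald statistic of the
# coefficient on Z, with cluster-robust (default) or classical variance
.partial_F <- function(W, D, clusters, zcol, correction, classical = FALSE) {
  a <- qr.solve(W, D)
  r1 <- D - drop(W %*% a)
  if (classical) {
    s2 <- sum(r1^2) / (length(D) - ncol(W))
    va <- s2 * solve(crossprod(W))[zcol, zcol]
  } else {
    va <- cluster_robust_covariance(W, r1, clusters, correction)[zcol, zcol]
  }
  list(alpha = a, F = unname(a[zcol]^2 / va))
}

#' Instrumental-variable (two-stage least squares) analysis
#'
#' Estimates the complier average causal effect using treatment assignment
#' Z as an instrument for treatment received D. Stage one regresses D on Z
#' (plus X if requested); stage two regresses Y on the fitted values (plus
#' X). The coefficient on fitted D is the CACE estimate. Standard errors
#' use the cluster-robust sandwich of [cluster_robust_covariance()] with
#' residuals formed from the *observed* D. The first-stage partial F for
#' the instrument (Staiger-Stock rule: F of at least 10 indicates a
#' non-weak instrument) is returned alongside the first-stage coefficients.
#'
#' @inheritParams fit_itt
#' @param correction Small-sample correction for the sandwich.
#' @param f_type Partial-F variance: cluster-robust Wald (default) or the
#'   classical homoskedastic F.
#' @return A `FitResult` row (see [fit_itt()]) with `alpha0`, `alpha1` and
#'   `partial_F` populated.
#' @export
fit_iv <- function(data, with_covariate = TRUE,
                   correction = c("CR1", "none"),
                   f_type = c("cluster-robust", "classical")) {
  correction <- match.arg(correction)
  f_type <- match.arg(f_type)
  n <- nrow(data)
  ncl <- length(unique(data$cluster_id))
  if (length(unique(data$Z)) < 2L) {
    return(.fit_result("IV", with_covariate, n_subjects_used = n,
                       n_clusters_used = ncl))
  }
  W <- if (with_covariate) cbind(`(Intercept)` = 1, Z = data$Z, X = data$X)
       else cbind(`(Intercept)` = 1, Z = data$Z)
  fs <- .partial_F(W, data$D, data$cluster_id, zcol = "Z",
                   correction = correction,
                   classical = f_type == "classical")
  if (fs$alpha["Z"] == 0 || !is.finite(fs$F)) {
    return(.fit_result("IV", with_covariate, n_subjects_used = n,
                       n_clusters_used = ncl,
                       alpha0 = unname(fs$alpha["(Intercept)"]),
                       alpha1 = unname(fs$alpha["Z"])))
  }
  Dhat <- drop(W %*% fs$alpha)
  X2 <- if (with_covariate) cbind(`(Intercept)` = 1, D = Dhat, X = data$X)
        else cbind(`(Intercept)` = 1, D = Dhat)
  beta <- qr.solve(X2, data$Y)
  Xobs <- X2
  Xobs[, "D"] <- data$D
  res <- data$Y - drop(Xobs %*% beta)
  V <- cluster_robust_covariance(X2, res, data$cluster_id, correction)
  .fit_result("IV", with_covariate, estimate = unname(beta["D"]),
              se = sqrt(V["D", "D"]), converged = TRUE,
              n_subjects_used = n, n_clusters_used = ncl,
              alpha0 = unname(fs$alpha["(Intercept)"]),
              alpha1 = unname(fs$alpha["Z"]), partial_F = fs$F)
}

#' Fit all requested approaches to one trial
#'
#' Convenience wrapper running [fit_itt()], [fit_at()], [fit_pp()] and
#' [fit_iv()] (or a subset) under one or both covariate variants on the
#' same dataset.
#'
#' @inheritParams fit_iv
#' @param approaches Subset of `c("ITT", "AT", "PP", "IV")`.
#' @param variants Logical vector of covariate variants to run
#'   (`TRUE` = covariate included).
#' @return Data frame of `FitResult` rows.
#' @export
fit_all_approaches <- function(data, approaches = c("ITT", "AT", "PP", "IV"),
                               variants = c(TRUE, FALSE),
                               correction = c("CR1", "none"),
                               f_type = c("cluster-robust", "classical")) {
  approaches <- match.arg(approaches, several.ok = TRUE)
  correction <- match.arg(correction)
  f_type <- match.arg(f_type)
  out <- list()
  for (wc in variants) {
    for (ap in approaches) {
      out[[length(out) + 1L]] <- switch(
        ap,
        ITT = fit_itt(data, wc),
        AT = fit_at(data, wc),
        PP = fit_pp(data, wc),
        IV = fit_iv(data, wc, correction = correction, f_type = f_type))
    }
  }
  do.call(rbind, out)
}
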