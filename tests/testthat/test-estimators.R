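test_that("balanced cluster-level regressor: mixed model equals arm-mean difference", {
  tr <- generate_trial(small_condition(pbar = 0, n1 = 8, n2 = 12), seed = 8)
  fit <- fit_random_intercept_reml(tr$Y, data.frame(Z = tr$Z),
                                   tr$cluster_id)
  diff_means <- mean(tr$Y[tr$Z == 1]) - mean(tr$Y[tr$Z == 0])
  expect_true(fit$converged)
  expect_equal(fit$coefficients$estimate[fit$coefficients$term == "Z"],
               diff_means, tolerance = 1e-8)
})

test_that("zero between-cluster variance reduces REML to ordinary least squares", {
  # noise centered within clusters: the between-cluster mean square is
  # below its expectation under independence, so REML must land on the
  # tau2 = 0 boundary, where GLS and OLS coincide
  set.seed(44)
  cl <- rep(1:15, each = 6)
  x <- rnorm(90)
  e <- rnorm(90)
  e <- e - ave(e, cl)
  y <- 1 + 0.3 * x + e
  fit <- fit_random_intercept_reml(y, data.frame(x = x), cl)
  ols <- lm(y ~ x)
  expect_true(fit$converged)
  expect_lt(fit$varcomp["tau2"], 1e-8)
  est <- fit$coefficients$estimate[fit$coefficients$term == "x"]
  expect_equal(est, unname(coef(ols)["x"]), tolerance = 1e-6)
})

test_that("REML engine agrees with an independent implementation", {
  tr <- generate_trial(small_condition(pbar = 0.3, n1 = 10, n2 = 20),
                       seed = 77)
  fit <- fit_random_intercept_reml(tr$Y, data.frame(D = tr$D, X = tr$X),
                                   tr$cluster_id)
  ref <- nlme::lme(Y ~ D + X, random = ~ 1 | cluster_id, data = tr,
                   method = "REML")
  expect_equal(fit$coefficients$estimate,
               unname(nlme::fixef(ref)), tolerance = 1e-6)
  expect_equal(fit$coefficients$se,
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-4)
  expect_equal(unname(fit$varcomp["tau2"]),
               as.numeric(nlme::VarCorr(ref)[1, 1]), tolerance = 1e-4)
})

test_that("degenerate and singular designs are handled as specified", {
  expect_error(fit_random_intercept_reml(rnorm(5), data.frame(x = rnorm(5)),
                                         rep(1, 5)),
               "degenerate data")
  set.seed(9)
  cl <- rep(1:8, each = 4)
  x <- rnorm(32)
  y <- x + rnorm(32)
  fit <- fit_random_intercept_reml(y, data.frame(a = x, b = 2 * x), cl)
  expect_false(fit$converged)
})

test_that("a large trial recovers the generative parameters", {
  cond <- simulation_condition(rho = 0.05, n1 = 20, level = "cluster",
                               pbar = 0, n2 = 500)
  tr <- generate_trial(cond, seed = 13)
  fit <- fit_random_intercept_reml(tr$Y, data.frame(D = tr$D, X = tr$X),
                                   tr$cluster_id)
  co <- fit$coefficients
  d_row <- match("D", co$term)
  x_row <- match("X", co$term)
  expect_lt(abs(co$estimate[d_row] - 0.2), 3 * co$se[d_row])
  expect_lt(abs(co$estimate[x_row] - 0.2), 3 * co$se[x_row])
  expect_gt(fit$varcomp["tau2"], 0.03)
  expect_lt(fit$varcomp["tau2"], 0.07)
})

test_that("under full compliance ITT, AT and PP coincide", {
  tr <- generate_trial(small_condition(pbar = 0, n1 = 10, n2 = 14),
                       seed = 21)
  for (wc in c(TRUE, FALSE)) {
    itt <- fit_itt(tr, wc)
    at <- fit_at(tr, wc)
    pp <- fit_pp(tr, wc)
    expect_equal(itt$estimate, at$estimate, tolerance = 1e-12)
    expect_equal(at$estimate, pp$estimate, tolerance = 1e-12)
    expect_identical(pp$n_subjects_used, nrow(tr))
  }
})

test_that("ITT never reads compliance or treatment received", {
  tr <- generate_trial(small_condition(pbar = 0.4, n1 = 10, n2 = 14),
                       seed = 22)
  ref <- fit_itt(tr, TRUE)
  set.seed(1)
  tr2 <- tr
  tr2$C <- sample(tr$C)
  tr2$D <- tr2$Z * tr2$C
  perm <- fit_itt(tr2, TRUE)
  expect_identical(ref$estimate, perm$estimate)
  expect_identical(ref$se, perm$se)
})

test_that("per-protocol exclusions follow the compliance structure", {
  # cluster-level: whole clusters are excluded, so the count is a
  # multiple of the cluster size
  tr <- generate_trial(small_condition(level = "cluster", pbar = 0.5,
                                       n1 = 6, n2 = 20), seed = 30)
  pp <- fit_pp(tr, TRUE)
  excluded <- nrow(tr) - pp$n_subjects_used
  expect_gt(excluded, 0)
  expect_identical(excluded %% 6L, 0L)

  # subject-level: exclusion rate among intervention subjects tracks pbar
  cond <- simulation_condition(rho = 0.05, n1 = 20, level = "subject",
                               pbar = 0.3, n2 = 200)
  tr <- generate_trial(cond, seed = 31)
  pp <- fit_pp(tr, TRUE)
  n_int <- sum(tr$Z == 1)
  frac <- (nrow(tr) - pp$n_subjects_used) / n_int
  expect_gt(frac, 0.26)
  expect_lt(frac, 0.34)
})

test_that("per-protocol flags an unanalyzable restriction instead of failing", {
  tr <- generate_trial(small_condition(level = "cluster", pbar = 0,
                                       n1 = 4, n2 = 6), seed = 3)
  tr$C[tr$Z == 1] <- 0L  # every intervention cluster refuses
  tr$D <- tr$Z * tr$C
  res <- fit_pp(tr, TRUE)
  expect_false(res$converged)
  expect_true(is.na(res$estimate))
})

test_that("cluster-robust sandwich matches a brute-force double loop", {
  # printed fixture: 3 clusters x 2 subjects
  X <- cbind(1, c(0.5, -1.2, 0.3, 2.1, -0.7, 1.0))
  e <- c(0.2, -0.1, 0.4, -0.3, 0.25, -0.15)
  cl <- c(1, 1, 2, 2, 3, 3)
  bread <- solve(t(X) %*% X)
  meat <- matrix(0, 2, 2)
  for (g in unique(cl)) {
    s <- rep(0, 2)
    for (i in which(cl == g)) s <- s + X[i, ] * e[i]
    meat <- meat + s %*% t(s)
  }
  n <- 6; k <- 2; G <- 3
  expect_equal(cluster_robust_covariance(X, e, cl, correction = "none"),
               bread %*% meat %*% bread, tolerance = 1e-10)
  expect_equal(cluster_robust_covariance(X, e, cl, correction = "CR1"),
               bread %*% meat %*% bread * G / (G - 1) * (n - 1) / (n - k),
               tolerance = 1e-10)
})

test_that("cluster-robust sandwich agrees with the sandwich package", {
  set.seed(6)
  n <- 40
  cl <- rep(1:10, each = 4)
  x <- rnorm(n)
  y <- 1 + 2 * x + rep(rnorm(10), each = 4) + rnorm(n)
  m <- lm(y ~ x)
  X <- cbind(1, x)
  expect_equal(unname(cluster_robust_covariance(X, resid(m), cl, "CR1")),
               unname(sandwich::vcovCL(m, cluster = cl, type = "HC1")),
               tolerance = 1e-10)
  # one subject per cluster reduces to the HC1 estimator
  expect_equal(unname(cluster_robust_covariance(X, resid(m), 1:n, "CR1")),
               unname(sandwich::vcovHC(m, type = "HC1")),
               tolerance = 1e-10)
})

test_that("with homoskedastic independent errors the sandwich nears the OLS covariance", {
  set.seed(10)
  n <- 20000
  x <- rnorm(n)
  y <- 1 + 0.5 * x + rnorm(n)
  m <- lm(y ~ x)
  X <- cbind(1, x)
  v_cr <- cluster_robust_covariance(X, resid(m), seq_len(n), "CR1")
  v_ols <- vcov(m)
  expect_true(all(abs(v_cr / v_ols - 1) < 0.1))
})

test_that("sandwich rejects a rank-deficient design", {
  X <- cbind(1, c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_error(cluster_robust_covariance(X, rnorm(4), c(1, 1, 2, 2)),
               "rank")
})

test_that("two-stage least squares reduces to the Wald ratio", {
  tr <- generate_trial(small_condition(level = "subject", pbar = 0.4,
                                       n1 = 10, n2 = 16), seed = 40)
  iv <- fit_iv(tr, with_covariate = FALSE)
  wald <- (mean(tr$Y[tr$Z == 1]) - mean(tr$Y[tr$Z == 0])) /
    (mean(tr$D[tr$Z == 1]) - mean(tr$D[tr$Z == 0]))
  expect_equal(iv$estimate, wald, tolerance = 1e-10)
  expect_gte(iv$partial_F, 0)
})

test_that("with full compliance 2SLS equals OLS of outcome on assignment", {
  tr <- generate_trial(small_condition(pbar = 0, n1 = 8, n2 = 12), seed = 41)
  iv <- fit_iv(tr, with_covariate = FALSE)
  ols <- lm(Y ~ Z, data = tr)
  expect_equal(iv$estimate, unname(coef(ols)["Z"]), tolerance = 1e-10)
  # and matches the mixed-model approaches (balanced GLS = OLS for a
  # cluster-level regressor, even number of clusters)
  itt <- fit_itt(tr, FALSE)
  expect_equal(iv$estimate, itt$estimate, tolerance = 1e-8)
})

test_that("first-stage coefficients describe the compliance rate", {
  cond <- simulation_condition(rho = 0.05, n1 = 20, level = "subject",
                               pbar = 0.4, n2 = 200)
  tr <- generate_trial(cond, seed = 50)
  iv <- fit_iv(tr, with_covariate = FALSE)
  expect_equal(iv$alpha0, 0, tolerance = 1e-10)      # control arm: D = 0
  expect_equal(iv$alpha1, 1 - 0.4, tolerance = 0.06) # complier rate
  expect_gt(iv$partial_F, 10)
  # classical F variant runs and is also large here
  iv_c <- fit_iv(tr, with_covariate = FALSE, f_type = "classical")
  expect_gt(iv_c$partial_F, 10)
  expect_equal(iv_c$estimate, iv$estimate, tolerance = 1e-12)
})

test_that("a dead first stage is flagged, not raised", {
  tr <- generate_trial(small_condition(pbar = 0, n1 = 4, n2 = 8), seed = 60)
  tr$D <- 0L  # no one receives treatment: instrument has no bite
  res <- fit_iv(tr, with_covariate = FALSE)
  expect_false(res$converged)
  expect_true(is.na(res$estimate))
})

test_that("confidence intervals and p-values follow the 1.96 z convention", {
  tr <- generate_trial(small_condition(pbar = 0.3, n1 = 10, n2 = 14),
                       seed = 70)
  fits <- fit_all_approaches(tr)
  conv <- fits[fits$converged, ]
  expect_equal(conv$ci_low, conv$estimate - 1.96 * conv$se,
               tolerance = 1e-12)
  expect_equal(conv$ci_high, conv$estimate + 1.96 * conv$se,
               tolerance = 1e-12)
  expect_equal(conv$p_value,
               2 * pnorm(-abs(conv$estimate / conv$se)),
               tolerance = 1e-12)
  expect_true(all(conv$se > 0))
  expect_true(all(conv$p_value >= 0 & conv$p_value <= 1))
})

test_that("omitting the covariate never changes which subjects are analyzed", {
  tr <- generate_trial(small_condition(level = "subject", pbar = 0.4,
                                       n1 = 10, n2 = 16), seed = 80)
  fits <- fit_all_approaches(tr)
  for (ap in c("ITT", "AT", "PP", "IV")) {
    rows <- fits[fits$approach == ap, ]
    expect_identical(rows$n_subjects_used[1], rows$n_subjects_used[2])
    expect_identical(rows$n_clusters_used[1], rows$n_clusters_used[2])
  }
})
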