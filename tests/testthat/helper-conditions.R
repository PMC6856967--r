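# small, fast conditions for unit tests (n2 overridden downward; the
# power-calibrated n2 of 38-152 clusters is only needed for the
# Monte-Carlo anchors)
small_condition <- function(rho = 0.05, n1 = 10, level = "cluster",
                            pbar = 0.3, n2 = 12, ...) {
  simulation_condition(rho = rho, n1 = n1, level = level, pbar = pbar,
                       n2 = n2, ...)
}

# moment (ANOVA) estimator of the intraclass correlation for a balanced
# two-level layout; independent of the package's model-fitting code
moment_icc <- function(x, cluster) {
  n1 <- length(x) / length(unique(cluster))
  msb <- n1 * var(tapply(x, cluster, mean))
  msw <- mean(tapply(x, cluster, var))
  (msb - msw) / (msb + (n1 - 1) * msw)
}
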