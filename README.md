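# crtcompliance

Monte-Carlo toolkit for studying what treatment non-compliance does to a
two-arm **cluster randomized trial** (CRT) with a continuous outcome.

In a CRT whole clusters — families, classes, wards — are randomized, and
non-compliance can strike at either level: an entire cluster refuses the
intervention, or individual subjects within it do. When the refusal
probability depends on a baseline covariate, the four standard analysis
approaches behave very differently:

| Approach | Compares | Target estimand |
|---|---|---|
| ITT (intention to treat) | groups as randomized (`Z`) | effect of assignment, `β₁(1 − P̄NC)` |
| AT (as treated) | groups as received (`D`), all subjects | effect of treatment received, `β₁` |
| PP (per protocol) | `D`, after dropping subjects with `D ≠ Z` | `β₁` |
| IV (instrumental variable) | 2SLS with `Z` instrumenting `D` | complier average causal effect (`β₁` here) |

The package simulates trials from the two-level model

```
Y_ij = β₀ + β₁ D_ij + β₂ X_ij + u_j + e_ij,   u_j ~ N(0, ρ), e_ij ~ N(0, 1 − ρ)
```

with never-taker status driven by the covariate's tertile band
(probability `0.5·P̄NC / P̄NC / 1.5·P̄NC` in the low/middle/high band),
fits all four approaches — ITT/AT/PP by random-intercept REML mixed
models, IV by two-stage least squares with cluster-robust (CR1) sandwich
standard errors — and scores each on **mean estimate, SD, 95% CI
coverage and empirical power** against its own estimand. The number of
clusters per condition comes from the design-effect sample-size formula
`n₂ = 4(1+(n₁−1)ρ)/n₁ · ((z_{1−α/2}+z_{1−β})/β₁)²` with a one-step
Student-t refinement (38–152 clusters over the default grid).

See `vignettes/noncompliance-simulation.Rmd` for the full model,
conventions and design choices.

## Worked example

Run the headline design cell (ICC 0.05, clusters of 20 subjects, hence
79 clusters) under cluster-level non-compliance with 30% average refusal,
covariate included:

```r
library(crtcompliance)
grid <- build_condition_grid(rho = 0.05, n1 = 20,
                             level = "cluster", pbar = 0.3)
run_study(grid, reps = 200, base_seed = 20191003, variants = TRUE)
```

```
                     condition_id approach with_covariate target_estimand
1 rho0.050_n1.20_cluster_pbar0.30      ITT           TRUE            0.14
2 rho0.050_n1.20_cluster_pbar0.30       AT           TRUE            0.20
3 rho0.050_n1.20_cluster_pbar0.30       PP           TRUE            0.20
4 rho0.050_n1.20_cluster_pbar0.30       IV           TRUE            0.20
  mean_estimate sd_estimate coverage power n_reps n_converged
1         0.137      0.0770    0.935 0.450    200         200
2         0.204      0.0729    0.940 0.805    200         200
3         0.203      0.0791    0.960 0.735    200         200
4         0.199      0.1108    0.925 0.490    200         200
```

Read: ITT estimates the *assignment* effect `0.2 × (1 − 0.3) = 0.14`
essentially without bias, and its power (0.45) is well below the 0.80
the trial was sized for — the estimand itself shrank. AT, PP and IV all
recover the received-treatment effect 0.2 when the compliance covariate
is in the model, but IV pays for it with a ~45% larger SD (0.111 vs
0.073–0.079) and correspondingly low power; coverage stays near 95% for
all four (Monte-Carlo error at 200 replications is about ±0.015 on a
coverage proportion). Re-running with `variants = FALSE` (covariate omitted) reproduces
the characteristic failures: AT and PP biased toward zero with
undercovering intervals, ITT and IV still centered but noisier.

Preset scenario tables for the four published panel layouts
(cluster/subject non-compliance × covariate in/out at ρ = 0.05,
n₁ = 20):

```r
fig2 <- reproduce_figure(2, reps = 500)   # cluster level, covariate in
```

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/crtcompliance.R grid --out grid.csv
Rscript inst/cli/crtcompliance.R simulate --config config.json --out results/
Rscript inst/cli/crtcompliance.R reproduce-figure --figure 2 --reps 500
```

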