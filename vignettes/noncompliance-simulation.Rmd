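---
title: "Simulating treatment non-compliance in cluster randomized trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating treatment non-compliance in cluster randomized trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crtcompliance)
```

## The problem

In a cluster randomized trial (CRT) intact groups — school classes,
families, hospital wards — are randomized to an intervention or a control
condition. When some clusters or subjects assigned to the intervention
never actually receive it, the trial's analysis faces a choice: compare
groups as randomized (intention to treat, ITT), as treated (AT), only
among protocol-compliant subjects (per protocol, PP), or estimate the
complier average causal effect with assignment as an instrumental
variable (IV). These four approaches answer different questions, and
non-compliance affects their bias, efficiency, confidence-interval
coverage and power in different ways. `crtcompliance` implements a
Monte-Carlo laboratory for quantifying those effects in a two-level CRT
with a continuous outcome and never-taker non-compliance driven by a
baseline covariate.

## Generative model

For subject $i$ in cluster $j$, with treatment received $D_{ij}$ and
covariate $X_{ij}$,

$$Y_{ij} = \beta_0 + \beta_1 D_{ij} + \beta_2 X_{ij} + u_j + e_{ij},
\qquad u_j \sim N(0, \tau^2),\; e_{ij} \sim N(0, \sigma^2),$$

with total residual variance $\tau^2 + \sigma^2 = 1$ and intraclass
correlation $\rho = \tau^2/(\tau^2+\sigma^2)$ conditional on $D$ and $X$.
Defaults are $\beta_1 = \beta_2 = 0.2$ (a small standardized effect) and
$\beta_0 = 0$; the intercept is never stated by the study conditions and
all four estimators are location-invariant, so its value is
inconsequential.

Clusters are randomized 1:1 ($Z_j \in \{0,1\}$); with an odd number of
clusters the intervention arm receives the extra one, and which physical
clusters land in which arm is re-randomized every replication.
Compliance is restricted to **compliers** and **never-takers**: treatment
received is $D_{ij} = Z_j C_{ij}$, so no control subject can access the
intervention and an intervention-arm never-taker's outcome follows
exactly the control model. The never-taker probability depends on the
covariate through its standard-normal tertile bands,

$$P_{NC}(x) = \bar P_{NC} \times \begin{cases}
0.5 & x < z_{1/3}\\ 1 & z_{1/3} \le x < z_{2/3}\\ 1.5 & x \ge z_{2/3},
\end{cases}$$

so the marginal never-taker rate is exactly $\bar P_{NC}$ (the bands have
equal mass and the multipliers average to one). Bands are left-closed — a
covariate value exactly at a cutoff takes the upper band — a measure-zero
convention fixed purely for determinism. Non-compliance operates at one
of two levels:

* **cluster**: $X$ is one standard-normal draw per cluster and a single
  Bernoulli draw decides the whole cluster's status;
* **subject**: $X = B_j + W_{ij}$ with $B_j \sim N(0,\rho)$,
  $W_{ij} \sim N(0,1-\rho)$, so $X$ has unit marginal variance and the
  same ICC as the outcome, and each subject's status is drawn
  independently. Tertile cutoffs are applied to the *marginal* (standard
  normal) distribution of $X$ in both cases.

## Sample size

The number of clusters per condition is the smallest $n_2$ with 80% power
for a two-sided 5% test of $\beta_1$ under full compliance,

$$n_2 = 4(\sigma^2+\tau^2)\,\frac{1+(n_1-1)\rho}{n_1}
\left(\frac{z_{1-\alpha/2}+z_{1-\beta}}{\beta_1}\right)^2,$$

rounded up. `required_clusters()` applies this normal-quantile formula
and then refines it once with Student-t quantiles at $n_2 - 2$ degrees of
freedom (rounding up again). The refinement compensates for the slight
optimism of normal quantiles at a modest number of clusters; over the
default grid it yields 38 to 152 clusters, whereas the pure-normal rule
(available as `quantile_mode = "normal"`) yields 35 to 150. Power is
therefore slightly above 0.80 in every cell, because of the rounding.

## Analysis approaches and conventions

ITT, AT and PP are random-intercept linear mixed models fitted by REML
(via `lme4`), regressing $Y$ on $Z$ (ITT) or $D$ (AT, PP), with PP first
discarding subjects whose $D \ne Z$ — i.e. intervention-arm
never-takers; the control arm is always retained in full. REML is
preferred to full ML because its variance components are less biased
with a modest number of clusters. IV is two-stage least squares: a
*linear* first stage of $D$ on $Z$, then $Y$ on the fitted values, with
standard errors from a cluster-robust (Huber-White) sandwich whose
residuals use the observed $D$. The first-stage partial F statistic for
the instrument is computed as the squared cluster-robust Wald statistic
of the coefficient on $Z$ (a classical homoskedastic F is available by
flag); by the Staiger-Stock rule of thumb, values above 10 indicate the
instrument is not weak.

Design choices worth making explicit:

* **Inference convention.** Every approach reports
  $\hat\beta_1 \pm 1.96\,\mathrm{se}$ and a two-sided z p-value, so the
  coverage and power criteria are mutually consistent. t-based p-values
  would differ negligibly at 38+ clusters.
* **Covariate in the IV stages.** When the covariate variant is on, $X$
  enters *both* stages as an exogenous regressor, the standard 2SLS
  treatment of included exogenous variables.
* **Small-sample correction.** The sandwich uses the CR1 factor
  $\frac{G}{G-1}\cdot\frac{N-1}{N-k}$ by default (`correction = "none"`
  disables it); with one subject per cluster it reduces to HC1.
* **Non-convergence.** Singular or unanalyzable fits (e.g. a PP
  restriction leaving fewer than two clusters in an arm, or a dead first
  stage) are flagged, excluded from all four performance metrics and
  counted — never imputed.

## Evaluation criteria

Each approach is scored against its own target estimand: $\beta_1$ for
AT, PP and IV (for IV this is the complier average causal effect, which
equals $\beta_1$ under this generative model), and
$\beta_1(1-\bar P_{NC})$ — the effect of *assignment* — for ITT. Per
condition and covariate variant, `summarize_condition()` reports the mean
and standard deviation of the estimates, the fraction of 95% intervals
containing the target (coverage), and the fraction of replications with
$p < 0.05$ (power), over converged replications only. With $R$
replications a proportion $p$ carries Monte-Carlo error
$\sqrt{p(1-p)/R}$; tests and anchors use two such standard errors as
their tolerance.

## Reproducibility and problem sizes

Every replication's seed is a deterministic mix of
(base seed, condition id, replication index), so serial and parallel runs
of the same configuration are identical and any single replication can be
regenerated in isolation. The full factorial study uses
$3 \times 3 \times 2 \times 6 = 108$ conditions at 5000 replications
each; the package's own test suite and acceptance checks run the headline
cell ($\rho = 0.05$, $n_1 = 20$) at 200-1000 replications, sizes chosen
so that Monte-Carlo error (about 4% relative on a standard deviation at
300 replications, 0.013 on a power estimate at 1000) is small against
the effects being asserted.

```{r, eval = FALSE}
grid <- build_condition_grid(rho = 0.05, n1 = 20, level = "cluster")
summary <- run_study(grid, reps = 500, base_seed = 20191003)
head(summary)
# or the preset panels:
fig2 <- reproduce_figure(2, reps = 500)
```

## What the generator does and does not emulate

The synthetic trials capture the features that drive the statistical
behavior of interest: clustering of outcomes, covariate-driven
never-taking at either level, and the resulting confounding of $D$ with
$X$ in AT/PP comparisons. They deliberately omit always-takers and
defiers, partial or dose-dependent compliance, missing outcomes,
non-normal outcomes, unequal cluster sizes and multi-arm designs. Results
under this model therefore speak to trials with tightly gate-kept
interventions and (approximately) equal cluster sizes; a passing test
suite shows the estimators behave as theory predicts *under this model*,
not that any of the approaches is robust to violations of it (e.g.
outcome-dependent compliance, which breaks the exclusion restriction).

## Known limitations

* The AT/PP/IV target estimands coincide at $\beta_1$ here; in real
  trials the complier and full-population effects generally differ, so
  agreement among approaches in these simulations should not be read as
  interchangeability.
* The IV variance is asymptotic in the number of clusters; the grid's
  minimum of 38 clusters is near the edge of where cluster-robust
  standard errors are trustworthy.
* `run_study()` parallelizes over conditions with forked workers; on
  platforms without fork it falls back to serial execution semantics via
  `parallel::mclapply`'s behavior.
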