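---
title: "Network-regularized Cox regression: model, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-regularized Cox regression: model, algorithms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netcox)
```

## The model

For patient $i$ with gene expression profile $x_i \in \mathbb{R}^p$, the
hazard is the Cox proportional form
$h(t \mid x_i) = h_0(t)\,e^{\beta^\top x_i}$ with an unspecified baseline
$h_0$. With censored follow-up $(t_i, \delta_i)$, $\delta_i = 1$ indicating
an observed event, the total log-likelihood over $(\beta, h_0)$ is

$$
\ell(\beta, h_0) \;=\; \sum_i \big[\delta_i\{\log h_0(t_i) + \beta^\top x_i\}
  \;-\; H_0(t_i)\, e^{\beta^\top x_i}\big],
$$

where $H_0$ is the cumulative baseline hazard. Profiling $h_0$ out at fixed
$\beta$ yields the Breslow step-function estimator, with increment
$d_t / \sum_{j \in R(t)} e^{\beta^\top x_j}$ at each distinct event time
($d_t$ = events at $t$; risk sets are closed, $R(t) = \{j: t_j \ge t\}$, and
ties follow the Breslow convention), and the profiled likelihood is the Cox
partial likelihood up to a constant.

When $p \gg n$ the maximizer is unidentifiable, so `netcox` maximizes the
penalized objective

$$
\ell(\beta, h_0) \;-\; \lambda\, \beta^\top \Gamma(\alpha)\, \beta,
\qquad
\Gamma(\alpha) = \alpha I + (1-\alpha)(I - S),
$$

where $S = D^{-1/2} W D^{-1/2}$ is the symmetrically normalized adjacency of
a weighted gene relation network $W$ ($D$ = diagonal degree matrix).
$\beta^\top(I - S)\beta$ is a graph-Laplacian smoothness cost: each edge
charges in proportion to its weight and the squared difference of its
endpoint coefficients, so strongly connected genes are pushed toward similar
coefficients. The identity
$\beta^\top\Gamma\beta = \alpha\lVert\beta\rVert^2 +
(1-\alpha)\,\beta^\top(I-S)\beta$ holds exactly and is tested. Because the
eigenvalues of $I - S$ lie in $[0, 2]$, $\Gamma$ is positive definite with
smallest eigenvalue at least $\alpha$; at $\alpha = 1$ the model is exactly
ridge-penalized Cox regression and provably ignores the network (the test
suite asserts bitwise invariance to swapping networks at $\alpha = 1$).

## Parameters that matter

* `lambda` $\ge 0$ — overall penalty weight, on the scale of the
  log-likelihood (the objective carries **no** $1/n$ factor, so comparable
  `lambda` values grow with the sample size; see "Model selection" below).
* `alpha` $\in (0, 1]$ — trust in the network. Small values (0.01–0.1) put
  most weight on the Laplacian smoothness; 1 is pure ridge. Default grid:
  $\{0.01, 0.1, 0.5, 0.95, 1\}$; the randomization studies use
  $\{0.01, 0.1, 0.5, 0.95\}$.
* Risk-group fraction — 0.40: the top 40% of prognostic indices form the
  high-risk group, the bottom 40% the low-risk group.
* Randomization replicates — 20 shuffled networks for CVPL nulls, 50 for
  log-likelihood and gene-overlap nulls.

## Networks

The built-in co-expression network uses a mutual-rank reliability score:
$W_{ij} = 1/\sqrt{r_i(j)\, r_j(i)}$, where $r_i(j)$ is the rank (1 = best)
of gene $j$ among all other genes sorted by decreasing absolute Pearson
correlation with gene $i$. Weights lie in $(0, 1]$; mutual nearest
neighbours get 1. Ties in $|r|$ receive average ranks, which keeps the
construction deterministic and order-independent. Constant expression
columns are assigned correlation 0 with every other gene — they stay in the
model with the worst ranks rather than producing undefined correlations. The
dense $W$ is the default because nothing in the construction requires
sparsity; an optional `top_k` flag keeps only each gene's strongest
neighbours (as a symmetric union) for very large $p$. Externally built
networks (e.g. functional-linkage resources) are consumed as three-column
edge lists. Isolated genes get zero rows in $S$, which makes their $\Gamma$
coordinates pure ridge — the natural limit of the normalization as the
degree goes to 0.

Edge shuffling, used for significance assessment, reassigns the edges to
uniformly random distinct gene pairs, preserving the edge count and the
weight multiset. This is the plainest reading of "shuffling the weighted
edges"; a degree-preserving double-edge-swap variant is available via
`preserve_degree = TRUE` for users who want to condition on the degree
sequence.

## Optimization

The objective is maximized by alternating (i) a Breslow update of the
baseline at the current $\beta$ with (ii) a safeguarded Newton step in
$\beta$. A subtlety matters here: the Hessian of the total log-likelihood at
a *fixed* baseline, $-X^\top \mathrm{diag}(\mu) X - 2\lambda\Gamma$ with
$\mu_i = H_0(t_i)e^{\beta^\top x_i}$ (exposed as `penalized_hessian()`),
under-estimates the curvature of the *profiled* likelihood, and an
alternation that uses it converges only linearly — at $p = 2000$, $n = 50$
the per-iteration improvement stalls around $10^{-4}$ and the scheme
effectively never converges. `netcox` therefore takes the Newton step with
the exact profiled curvature

$$
-\big(X^\top \mathrm{diag}(\mu) X - B\,\mathrm{diag}(d)\,B^\top\big)
- 2\lambda\Gamma,
\qquad B = X^\top P,
$$

where $P_{ik} = e^{\beta^\top x_i} \mathbf{1}(t_i \ge t_k) / \sum_{j \in
R(t_k)} e^{\beta^\top x_j}$ collects the risk-set membership probabilities
at each distinct event time $k$. The fixed point is unchanged — the penalized
partial likelihood is strictly concave for $\lambda > 0$, so the optimum is
unique — but convergence is quadratic (5–16 outer iterations in all tests).
Steps that fail to improve the objective are halved, up to 30 times, so the
recorded objective trace is nondecreasing by construction; the trace is
reported as the penalized total log-likelihood at the self-consistent
Breslow baseline.

For $p \gg n$ the dual parameterization $\beta = \Gamma^{-1}X^\top\gamma$
reduces the problem to $n$ dimensions: with $K = X\Gamma^{-1}X^\top$, the
linear predictor is $K\gamma$ and the penalty $\gamma^\top K \gamma$. One
Cholesky factorization of $\Gamma$ and one triangular solve for
$\Gamma^{-1}X^\top$ are the only $p$-sized operations. The primal and dual
paths agree to better than $10^{-5}$ in every coefficient on random
instances, which is itself an acceptance check.

Numerical choices: all risk-set sums are computed as streaming exact
log-sum-exps (a max-shifted version underflowed to $\log 0$ for the extreme
linear predictors that arise at near-zero `lambda` in the $p \approx n$
regime); the outer loop stops when the relative objective change is below
$10^{-9}$ *and* no coefficient moved by more than $10^{-7}$, or at 200
iterations; the inner Newton safeguard declares convergence when no halved
step improves the objective. `lambda = 0` is refused when $p \ge n$
(non-identifiable), and the dual solver requires `lambda > 0`.

## Model selection

Five-fold cross-validation maximizes
$\mathrm{CVPL}(\lambda,\alpha) = \sum_k [\,l(\hat\beta_{(-k)}) -
l_{(-k)}(\hat\beta_{(-k)})\,]$, the held-out contribution to the partial
likelihood. Folds are stratified by the event indicator — without
stratification, small training sets can lose all their events and the
partial likelihood degenerates. Repeated splits (default 5 repeats of
5-fold, seeds `seed + r`) are averaged.

The default `lambda` grid is $\{10^{-5}, \dots, 10^{-1}, 1\}$. Because the
objective has no $1/n$ scaling, the location of the CVPL optimum moves with
the cohort size and the expression scale: on the synthetic cohorts generated
here the optimum typically sits at $\lambda \sim 10$–$100$, above the
default grid's ceiling. Experiments in the test suite that need the
CVPL-optimal $\lambda$ therefore search the ladder
$\{0.01, 0.1, 1, 10, 100\}$; comparisons between the network model and the
ridge model are made at each model's own CVPL optimum, since comparing them
at a common arbitrary $\lambda$ confounds the direction of shrinkage with
its amount. The co-expression network used inside cross-validation is built
once from the full dataset (networks are dataset-specific); a strict mode
that rebuilds it per training fold is available (`network` can be
re-supplied per fold by the caller), trading a small information leak for
cheaper, more stable networks — with $n$ in the hundreds the leak is
negligible because the network enters only through the penalty.

## Evaluation

Patients are ranked by the prognostic index $\beta^\top x$; the top and
bottom 40% (floors of $0.4n$) form the high- and low-risk groups, with index
ties broken by stable sample order so the split is reproducible. Group
separation is tested with the Mantel log-rank test ($\chi^2_1$).
Discrimination over time uses cumulative/dynamic time-dependent ROC curves:
cases at horizon $t$ are subjects with an event by $t$, controls those
event-free at $t$, and censoring is handled by the Kaplan-Meier/Bayes-rule
estimator
$\mathrm{sens}(c,t) = \{1 - S(t \mid M > c)\}P(M > c)/\{1 - S(t)\}$,
$\mathrm{spec}(c,t) = S(t \mid M \le c)P(M \le c)/S(t)$, with conditional
survival estimated by Kaplan-Meier within the threshold subgroups; estimates
are clipped to $[0,1]$ and integrated by trapezoid over all observed
cutoffs. Without censoring this reduces exactly to the empirical two-sample
AUC with ties counted one half, which the tests verify by brute-force pair
counting. A simpler inverse-probability-of-censoring-weighted estimator is
available with `method = "ipcw"` as a cross-check.

Genes are ranked by $|\beta|$ (signs retained so hazard-increasing genes are
identifiable). Consensus rankings across datasets score each gene by the
best (lowest) rank it attains anywhere, with ties broken by the
next-smallest rank and then gene id; overlap curves report the fraction of
the top-$k$ sets common to all datasets. Randomization assessment
recomputes a chosen statistic (CVPL, full-data partial likelihood, or top-k
overlap) on edge-shuffled networks and reports the observed value, the null
sample, and the empirical exceedance proportion — a proportion rather than a
parametric p-value, because the null is summarized as a distribution, not a
test.

## The synthetic-data generator

`sim_config()` describes the structure the model assumes: a modular weighted
network (10 modules of 20 genes by default; within-module edges with
probability 0.8 and weights in [0.5, 1], between-module edges with
probability 0.02 and weights in [0.05, 0.2]); coefficients equal to the
effect size (0.5) on two active modules plus Gaussian jitter (sd 0.05) and
zero elsewhere — smooth over the network by construction; expression drawn
from a block-exchangeable Gaussian with within-module correlation 0.6 (one
latent factor per module); and event times drawn from an exponential
proportional-hazards model with baseline rate 0.05 and independent
exponential censoring whose rate is solved numerically so the expected
censoring fraction matches the 30% target under the realized risk-score
distribution (this keeps `censor_target` meaningful across effect sizes).
The exponential baseline was chosen over Weibull because it gives closed
forms for the median and the proportional-hazards ratio that the tests check
by Monte-Carlo.

The default cohort (200 genes, 150 samples) is the desk-scale condition used
throughout the acceptance experiments; unit tests use smaller cohorts
(e.g. 60 genes, 80–250 samples) so the full suite runs in minutes. What the
generator deliberately does **not** emulate: probe-level microarray
artifacts, normalization and batch effects, heavy-tailed expression, hub
genes and scale-free degree distributions, and hazards that violate
proportionality. Passing tests on these data show that the estimator
recovers structure it was designed for; they do not certify performance on
real cohorts, where the network may be partly wrong and the signal is not
block-constant.

## Known limitations

* Ties are handled by the Breslow convention only (no Efron or exact
  corrections); time-varying covariates and stratified baselines are out of
  scope.
* The penalty is quadratic, so no coefficients are set exactly to zero; gene
  selection is by ranking, not sparsity.
* The CVPL-optimal `lambda` depends on the data scale because the objective
  is unscaled by $n$; users porting `lambda` values across cohorts should
  re-run the grid search.
* The Kaplan-Meier ROC estimator can be locally non-monotone under heavy
  censoring (a known property of the subgroup-KM construction); values are
  clipped, and the IPCW alternative is provided.
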