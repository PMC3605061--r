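# netcox

Network-regularized Cox proportional hazards regression for
high-dimensional gene expression survival analysis.

## The problem

In microarray or RNA-seq survival cohorts the number of genes *p* runs into
the thousands while the number of patients *n* is a few hundred, so the
classical Cox model is unusable without regularization. Ridge and lasso
penalties shrink coefficients but treat genes as exchangeable. `netcox`
instead encodes prior knowledge from a weighted gene relation network — a
co-expression network computed from the data, or an externally built
functional-linkage network — so that genes connected by strong edges receive
similar regression coefficients. The intended users are biostatisticians and
computational biologists fitting prognostic gene signatures to censored
survival outcomes.

## The model

The hazard for patient *i* with expression profile *x<sub>i</sub>* is the
Cox form *h(t | x<sub>i</sub>) = h₀(t) exp(βᵀx<sub>i</sub>)*. Coefficients
are estimated by maximizing the penalized total log-likelihood

> l(β, h₀) − λ βᵀ Γ(α) β,  Γ(α) = αI + (1 − α)(I − S),

where *S* is the symmetrically normalized weighted adjacency matrix of the
gene network (*S = D<sup>−1/2</sup> W D<sup>−1/2</sup>*), λ ≥ 0 is the
penalty weight, and α ∈ (0, 1] balances a plain ridge term against the graph
Laplacian smoothness cost βᵀ(I − S)β, which charges every edge
proportionally to its weight and to the difference of its endpoint
coefficients. At α = 1 the network is ignored and the model reduces to
ridge-penalized Cox regression. The baseline hazard is estimated by the
Breslow step-function estimator, and the solver alternates Breslow updates
with safeguarded Newton steps; a dual formulation reduces the optimization
to *n* dimensions so that *p* ≫ *n* problems remain cheap.

Model selection maximizes the cross-validated partial likelihood (CVPL)

> CVPL(λ, α) = Σ<sub>k</sub> [ l(β̂₍₋ₖ₎) − l₍₋ₖ₎(β̂₍₋ₖ₎) ],

over a (λ, α) grid, where β̂₍₋ₖ₎ is fitted without fold *k*. Evaluation
tools include 40%/40% high/low risk groups from the prognostic index βᵀx,
Kaplan-Meier curves and the log-rank test, time-dependent ROC/AUC for
censored outcomes, coefficient-magnitude gene rankings with consensus lists
and top-k overlap curves, and a randomization test that compares any of
these statistics against networks with shuffled edges.

## Worked example

```r
library(netcox)

# synthetic cohort: 200 genes in 10 modules, 150 patients, 30% censoring,
# two modules carrying a hazard effect of 0.5
sim <- make_dataset(sim_config(seed = 1))
sim$dataset
#> survival_dataset: 150 samples x 200 genes, 102 events (32% censored)

# choose lambda by 5-fold CVPL with the network trusted (alpha = 0.1)
folds <- make_folds(150, 5, seed = 1, event = sim$dataset$event)
ladder <- c(0.01, 0.1, 1, 10, 100)
v <- sapply(ladder, function(l) cvpl(sim$dataset, sim$network, l, 0.1, folds))
data.frame(lambda = ladder, cvpl = round(v, 1))
#>   lambda    cvpl
#> 1  1e-02 -2534.9
#> 2  1e-01 -1299.7
#> 3  1e+00  -564.8
#> 4  1e+01  -301.9
#> 5  1e+02  -322.8

fit <- netcox_fit(sim$dataset, penalty_matrix(sim$network, alpha = 0.1),
                  lambda = 10)
fit
#> netcox_fit (dual): 200 genes, lambda = 10, alpha = 0.1
#>   converged: TRUE after 8 outer iterations, objective -283.775547
#>   200 nonzero |beta| > 1e-8, max |beta| = 0.7747

cor(fit$beta, sim$beta_true)
#> [1] 0.9564743

# the ridge fit (alpha = 1) recovers the signal less faithfully
ridge <- netcox_fit(sim$dataset, NULL, lambda = 10, engine = "dual")
cor(ridge$beta, sim$beta_true)
#> [1] 0.9083246

# risk groups and evaluation
pi <- prognostic_index(fit, sim$dataset$X)
groups <- assign_risk_groups(pi)            # top/bottom 40%
keep <- groups != "unassigned"
logrank_test(sim$dataset$time[keep], sim$dataset$event[keep], groups[keep])$p
#> [1] 2.014486e-34

head(rank_genes(fit), 3)
#>   rank  gene      beta  abs_beta
#> 1    1 g0031 0.7747306 0.7747306
#> 2    2 g0003 0.7721698 0.7721698
#> 3    3 g0007 0.7618722 0.7618722
```

The CVPL ladder is maximized at λ = 10; at that fit the coefficients
correlate 0.956 with the generating truth (the ridge model reaches 0.908),
the two 60-patient risk groups defined by the prognostic index have sharply
separated survival curves, and the top-ranked genes fall in the
signal-carrying modules (genes g0001–g0040).

A shell interface drives the same pipeline on tab-separated files:

```sh
inst/cli/netcox simulate --out sim --p 200 --n 150 --seed 1
inst/cli/netcox fit --expression sim/expression.tsv --clinical sim/clinical.tsv \
    --network sim/network.tsv --lambda 0.1 --alpha 0.1 --out fit
inst/cli/netcox cv --expression sim/expression.tsv --clinical sim/clinical.tsv \
    --network sim/network.tsv --seed 1 --out cv
```

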