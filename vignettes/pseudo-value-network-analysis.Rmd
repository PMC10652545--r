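---
title: "Pseudo-value regression for covariate-adjusted differential network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo-value regression for covariate-adjusted differential network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psvnet)
```

## The model

Differential network (DN) analysis compares the topology of gene–gene
association networks estimated under two biological conditions and asks
which genes change their connectivity. The statistic of interest for gene
$k$ in group $z$ is its weighted degree centrality (total connectivity)

$$\hat\theta_{zk} = \sum_{j \ne k} w_{kj}^{(z)},$$

where $w^{(z)}$ is the group's association matrix after ARACNE
data-processing-inequality (DPI) pruning. Degree is a *group-level*
functional of the expression matrix; it has no per-sample definition, so
covariates cannot be adjusted for by ordinary regression. The package's
core idea is to manufacture per-sample responses with first-order
jackknife pseudo-values,

$$\tilde\theta_{ik} = n_z\,\hat\theta_k - (n_z - 1)\,\hat\theta_k^{(-i)},$$

where $\hat\theta^{(-i)}$ is the degree re-estimated with sample $i$ held
out. The pseudo-value measures sample $i$'s contribution to the group's
connectivity estimate; its group mean is the bias-corrected jackknife
estimate of $\theta$ and its empirical variance estimates the sampling
variance of $\hat\theta$ — *provided the functional is smooth* (more on
this below). Pooling both groups, each gene's pseudo-values are regressed
on the binary condition indicator plus all covariates with a robust MM
estimator; the group coefficient's p-value, screened by an empirical
Bayes adjustment across genes, decides differential connectivity.

Key assumptions: the two groups are independent samples; the covariates
enter the connectivity linearly on the pseudo-value scale; and
pseudo-values are approximately independent within a group (exactly true
for linear statistics, approximately for the smoothed degree used here,
which is why the package's type-I behavior is verified by simulation in
the test suite rather than assumed).

## Network estimation

**MI estimators.** Two estimators are provided, selected by
`net_config(estimator = )`:

* `"gaussian_rank"` (default): $w_{ij} = -\tfrac12 \log(1 - \rho_s^2)$,
  the mutual information of a bivariate Gaussian copula with Spearman
  rank correlation $\rho_s$. It is smooth in the data, invariant under
  monotone transformations, and its null bias is $O(1/n)$.
* `"empirical"`: the plug-in MI of equal-frequency-discretized profiles
  with $b$ bins ($b = \lfloor\sqrt n\rfloor$ under `"auto"`), natural log
  by default. Ties in the binning are broken by a stable order on
  (value, original sample position), so bin assignment is deterministic.
  Note the plug-in null bias is approximately $(b-1)^2/(2n)$ *per pair*,
  which under $\sqrt n$ binning does not vanish with $n$ and at
  $n \approx 60$ is comparable to the MI of a $\rho = 0.7$ signal. That
  bias is shared across pairs and cancels in two-group contrasts, but it
  inflates the variance of degree sums; the rank estimator is therefore
  the default and the binned estimator is retained for discrete-data use
  and for its exact small-sample closed forms (two identical profiles at
  $n = 9$, $b = 3$ give MI $= \log 3$ exactly).

Constant genes have zero entropy and get MI $0$ against everything —
deliberately not an error, so a leave-one-out subset that flattens a gene
cannot crash the jackknife.

**DPI pruning.** For every triplet, edge $(i,j)$ is scheduled for removal
when $w_{ij} < \min(w_{ik}, w_{kj}) - \varepsilon$; decisions are
evaluated against the input matrix and applied simultaneously, so the
result is independent of iteration order. The default tolerance is
$\varepsilon = 0.1$, inside the range the ARACNE authors recommend for
absorbing MI estimation error. The choice matters scientifically: with
$\varepsilon = 0$ a tightly co-expressed module — whose within-module MI
values are all nearly equal — is pruned down to a spanning tree, and most
of the very connectivity signal a DN analysis is looking for is
discarded. A modest tolerance keeps near-ties intact while still removing
clearly indirect edges. $\varepsilon$ is config-exposed.

**Degree.** The weighted marginal sum of the pruned matrix. No
binarization threshold is applied anywhere.

## Leave-one-out smoothing

The jackknife variance estimator is only consistent for smooth
functionals. Two steps of the network pipeline are *not* smooth: hard DPI
edge selection, and (for the binned estimator) the re-ranking of bin
boundaries when a sample is removed. Monte Carlo calibration during
development showed that re-selecting edges per leave-one-out subset makes
the pseudo-value variance understate the true sampling variance of
$\hat\theta$ several-fold, which wrecks the type-I error of the
downstream regression. The defaults therefore *freeze the full-group DPI
edge set* and (for the binned estimator) *pin the full-group bin
assignments* during leave-one-out re-estimation, recomputing only the MI
weights on the reduced sample. The statistic whose pseudo-values are
formed is thus "degree over the group's selected edge set", a smooth
functional whose jackknife SE matches its Monte Carlo sampling SD.

Both behaviors are switches (`loo_reprune`, `loo_rediscretize` in
`net_config()`), and with both enabled the leave-one-out networks are
re-estimated from scratch, including the bin count
($\lfloor\sqrt{n_z-1}\rfloor$ under `"auto"`, unless
`recompute_bins_loo = FALSE` pins the full-group count).

One analysis costs exactly $n_1 + n_2$ leave-one-out network fits plus
two full fits. The leave-one-out fits are pure functions of the reduced
data and may run on several workers (`jobs`); scheduling cannot change
the result.

## Per-gene robust regression

The design matrix is intercept, group indicator ($0$ = Group A, the
lexicographically smaller condition level unless levels are named
explicitly; $1$ = Group B), then every covariate in phenotype-table
order, categoricals treatment-coded against their lexicographically first
level. Rank deficiency is an error naming the collinear columns; a
categorical level observed in only one group triggers a confounding
warning.

Each gene's pseudo-values are fitted by MM estimation (`MASS::rlm`,
method `"MM"`): a high-breakdown initial S-estimate of scale followed by
an IRLS M-step with Tukey's bisquare, tuned for 95% asymptotic efficiency
under Gaussian errors ($c = 4.685$), up to 200 iterations at a $10^{-8}$
coefficient tolerance. Robust regression is used because pseudo-values of
network statistics are heavy-tailed by construction: a single influential
sample produces one extreme pseudo-value, which bisquare down-weights.
P-values are two-sided t tests of coefficient over robust SE with
$\mathrm{df} = n - \mathrm{ncol}(X)$ (the standard Wald choice; a normal
reference would differ negligibly at the suite's $n = 120$).

Degenerate cases never abort a multi-gene run: a zero-residual fit
returns the interpolating coefficients with p-values $0$/$1$ and flag
`perfect_fit`; non-convergence falls back to ordinary least squares with
flag `ols_fallback`. Flags are carried in the result and summarized.

The initial S-estimate subsamples candidate rows at random. To keep
whole-pipeline determinism — bit-identical results across reruns and
worker counts — each gene's fit runs under a seed derived from
`run_config(seed)` and the gene index. This also makes the per-gene
results equivariant under gene permutation.

## Multiplicity adjustment

The default screen is empirical Bayes (EBS): model the $m = p$ gene-level
p-values of one predictor as the two-group mixture
$f(p) = \pi_0 \cdot 1 + (1 - \pi_0) f_1(p)$ and report the estimated
posterior null probability $\min(1, \hat\pi_0 / \hat f(p))$. $\hat f$ is
a Gaussian kernel density estimate of the probit-transformed p-values
($z = \Phi^{-1}(p)$, bandwidth `bw.nrd0` under `"auto"`),
back-transformed with the Jacobian $\phi(z)$. $\hat\pi_0$ is the median
of $\hat f$ over $p \in [0.95, 1]$, guarded from below by the Storey-type
tail count $(1 + \#\{p > 0.5\})/(m/2)$ — without the guard, a family with
no p-values near 1 drives the density there toward 0 and every posterior
null probability with it — and capped at `pi0_cap`. A final isotonic
regression enforces monotone non-decreasing adjusted values in $p$.

Families with fewer than 10 p-values, or all-identical p-values, fall
back to Benjamini–Hochberg with a warning; `method = "bh"` selects the
standard step-up BH adjustment outright (`stats::p.adjust`), which is
deterministic down to the last bit and free of density-estimation
choices. Each predictor's column of p-values is adjusted as its own
family, preserving the genes × predictors shape of the output.
Significance is strict inequality: adjusted $p < \alpha$, default
$\alpha = 0.05$.

EBS posterior null probabilities and BH adjusted p-values are different
quantities on the same $[0,1]$ scale; thresholding the former at
$\alpha$ is a local-fdr-style screen. Exact numeric agreement with other
EBS implementations is not guaranteed — the mixture-density internals are
tuning choices, all exposed in `adjust_config()`.

## The synthetic-data generator

`synthetic_scenario()` / `simulate_two_group()` generate the two-group
structure the method targets: latent multivariate normal samples with a
"hub" block of `hub_size` genes equicorrelated at `base_rho` in Group A
and `perturbed_rho` in Group B against an independent background, plus
additive $N(0, \text{noise\_sd}^2)$ measurement noise
(`noise_sd = 0.1` default, a small technical-noise floor). Under
`count_model = "negbin"` the latent normals are pushed through a Gaussian
copula to negative-binomial margins (`mu = 100`, `size = 5` by default —
moderately deep, overdispersed RNA-seq-like counts). Because both MI
estimators are rank-based, the latent correlation structure is exactly
what the estimator sees; the copula changes margins, not ranks. Truth is
defined at the gene level: the hub genes are the differentially connected
set whenever the two correlations differ, otherwise no gene is.

The phenotype carries the group label, one numeric covariate whose group
means differ by `confounding_strength`, and a balanced two-level
categorical. With `covariate_driven_rho = TRUE` the hub correlation is
driven by a binary covariate whose prevalence differs between groups by
`confounding_strength` — a true confounder of connectivity, used to
demonstrate that adjusting for it removes spurious group-level DC calls.

What the generator does *not* emulate: library-size variation,
gene-specific mean/dispersion profiles, zero inflation, batch effects on
correlation structure, or more realistic graph topologies
(scale-free/modular). Passing the simulation suite therefore shows
correct calibration and power *against the generative model the method
assumes*, not performance guarantees on arbitrary real RNA-seq data.

`make_copd_like_fixture()` produces a 406-sample × 28-gene
negative-binomial dataset with six clinical variables (current smoking
status as the condition, plus pack years, age, gender, race, FEV1
percent) and Entrez-style numeric gene identifiers. It mirrors only the
*shape* of the published COPD smoking panel; its values are synthetic,
and no attempt is made to reproduce that study's gene list.

## Validation scale and numerical choices

The simulation checks in the test suite and `scripts/acceptance.R` use 20
replicates of $n = 2 \times 60$ samples and $p = 30$ genes (hub size 6,
$\rho: 0.2 \to 0.7$ for power, equal $\rho$ for the null), sizes at which
one full analysis costs 122 network fits and completes in about a second;
the COPD-shaped fixture exercises the $406 \times 28$ scale end to end.
Tolerances: jackknife closed-form identities at $10^{-10}$; MI and BH
oracles at $10^{-12}$; DPI uses a $10^{-12}$ strict-inequality slack to
absorb float noise. TSV output is written at 17 significant digits so
files round-trip bit-exactly, and the JSON run manifest serializes
doubles at full precision for the same reason — a manifest-reconstructed
configuration reproduces a run identically.

## Limitations

* Inference rides on the pseudo-value approximation; within-group
  dependence of pseudo-values is only approximately zero, so p-values are
  approximate (the suite verifies calibration at desk scale).
* Degree centrality is the only topology statistic; betweenness or
  eigenvector centrality would need their own smoothness analysis.
* One binary condition; no multi-level or continuous "group" variable.
* No variable selection over covariates — all supplied covariates enter
  the model.
* The jackknife costs $n$ network re-estimations per group; for very
  large cohorts the `jobs` option parallelizes but the cost is inherent.
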