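---
title: "Estimating burnout test accuracy without a gold standard: the Hui-Walter latent class model in hwblcm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating burnout test accuracy without a gold standard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hwblcm)
```

## The problem

Burnout has no accepted gold-standard diagnosis. When two imperfect
instruments — here a clinician-completed early-detection tool (EDTB) and the
self-reported Oldenburg Burnout Inventory (OLBI, total score 16–64,
classified positive above 44) — are applied to the same individuals, naive
agreement statistics confound the instruments' error rates with the true
burnout prevalence. The Hui–Walter latent class model resolves this by
treating true status as an unobserved class and exploiting a second source
of information: the same two tests applied to two (or more) populations with
different prevalences.

## The model

For test $i \in \{1,2\}$ let $Se_i$ and $Sp_i$ denote diagnostic sensitivity
and specificity, assumed common across populations (the Hui–Walter
assumption), and let $P_k$ be the prevalence in population $k$. Writing
$a(t_1,t_2)$ for the joint probability of results $(t_1,t_2)$ among the
latent positives and $b(t_1,t_2)$ among the latent negatives, the observed
2×2 cell probabilities in population $k$ are the mixture

$$\Pr(t_1,t_2 \mid k) \;=\; P_k\, a(t_1,t_2) + (1-P_k)\, b(t_1,t_2),$$

and the counts $(n_{11},n_{10},n_{01},n_{00})_k$ are multinomial. Under
conditional independence, $a$ and $b$ factorise, e.g.
$a(1,1) = Se_1 Se_2$ and $b(1,1) = (1-Sp_1)(1-Sp_2)$. With two populations
this gives 6 parameters against 6 degrees of freedom: just identified.

Conditional dependence is modelled by covariance terms: among positives

$$a(t_1,t_2) = Se_1^{t_1}(1-Se_1)^{1-t_1}\,Se_2^{t_2}(1-Se_2)^{1-t_2}
  + \gamma\, c^{+},$$

with $\gamma = +1$ on concordant and $-1$ on discordant outcomes, and
likewise $c^{-}$ among negatives built from the specificities. For the cell
probabilities to stay in $[0,1]$ each covariance must lie in

$$\max\{-(1-u)(1-v),\,-uv\} \;\le\; c \;\le\; \min(u,v) - uv,$$

where $(u,v)$ are the within-class positive probabilities
($Se_1, Se_2$ for $c^{+}$; $1-Sp_1, 1-Sp_2$ for $c^{-}$). Zero is always
feasible, so the independence model is nested. Note the dependence model has
8 parameters against 6 degrees of freedom: it is not identified by the data
alone and is regularised by the priors — which is exactly why its role here
is confined to the selection rule below.

## Priors

"Minimally informative" is implemented as Beta(1, 1) (uniform) for all six
probability parameters; the covariance terms receive uniform priors over
their feasibility interval conditional on the current accuracies. Users can
supply informative priors directly as shape pairs or elicit them from a
mode plus a percentile constraint with `elicit_beta()` (shapes are
constrained to $\ge 1$ so the mode is interior; not every mode/percentile
pair is achievable — a beta with both shapes at least 1 never has heavier
tails than the uniform, and infeasible requests error rather than silently
returning something else).

## Posterior computation

`gibbs_independence()` implements data-augmentation Gibbs sampling. Each
iteration draws, for every population and observed cell, the latent count of
true positives from its binomial full conditional with success probability
$P_k a / (P_k a + (1-P_k) b)$, then draws each prevalence and accuracy
parameter from its conjugate beta full conditional (prior shape plus
augmented successes/failures).

The augmentation alone mixes slowly when both tests are imperfect: each
individual's latent class is then genuinely uncertain, the fraction of
missing information is high, and the chain's autocorrelation grows with the
sample size (at 5000 individuals per population the plain Gibbs chain is
worth only a few hundred effective draws per 20,000 retained). Each
iteration therefore ends with two sweeps of univariate slice sampling
(stepping-out and shrinkage, fixed width 0.1, bounded to the parameter's
support) on the observed-data posterior. Slice updates leave the target
distribution unchanged, require no tuning, and restore near-independent
mixing — the same reason general-purpose Bayesian engines favour slice
updates for bounded parameters. With them, the study protocol yields
effective sample sizes in the thousands at every sample size we simulate.

`mwg_dependence()` extends this kernel to the covariance model. The
covariances are updated by random-walk Metropolis (reflected Gaussian
proposal, default sd 0.05, mixed with an occasional uniform draw over the
feasibility interval so the weakly identified covariance direction is
traversed), rejecting proposals outside the bounds evaluated at the current
accuracies. The accuracy parameters cannot keep their conjugate updates once
a covariance is nonzero — the within-class likelihood no longer factorises —
so they are updated by Metropolis–Hastings using the independence beta full
conditional as the proposal, with the covariance correction and the
conditional-uniform prior normalisation in the acceptance ratio. When both
covariances are zero the ratio is exactly one and the sampler reduces,
bit for bit, to the independence Gibbs sampler; `proposal_sd = 0` pins the
covariances at zero and makes that reduction explicit.

Chain $c$ is seeded with `seed + c` and starts from a draw out of the
priors, which gives the overdispersed starting points the Gelman–Rubin
diagnostic assumes. Identical data, priors and configuration reproduce the
draws exactly.

### Label switching

Latent class models are invariant under swapping the class labels. The swap
that preserves the likelihood maps $Se_i \to 1-Sp_i$, $Sp_i \to 1-Se_i$,
$P_k \to 1-P_k$ and exchanges $c^+$ with $c^-$ (the often-quoted shorthand
$Se \to 1-Se$, $Sp \to 1-Sp$ is *not* likelihood-invariant and would be an
incorrect relabeling). By default, states in which both tests have
$Se_i + Sp_i < 1$ are relabelled into the conventional mode; the fit records
how often this fired, and `enforce_identifiability()` exposes the
transformation for post-hoc use. On well-separated posteriors,
sampling-time and post-hoc relabeling give the same posterior (this is
property-tested).

## Diagnostics, summaries and model selection

`psrf()` is the classic two-stage Gelman–Rubin statistic
$\sqrt{((n-1)/n\,W + B/n)/W}$ without the degrees-of-freedom correction —
simple enough to verify by hand, which the tests do. Identical constant
chains give 1; distinct constant chains give $\infty$.

`effective_sample_size()` is $N / (1 + 2\sum_t \rho_t)$ with the
autocorrelation sum truncated by the initial monotone positive sequence
rule (consecutive lag-pair sums kept while positive, forced non-increasing).
Multi-chain input averages per-chain autocorrelations, each demeaned by its
own chain mean. The estimate is capped at $1.5N$ (slight anticorrelation can
push it above $N$, as in the study's own reported values) and defined as 0
for constant chains.

`summarize_draws()` reports the pooled-chain median and equal-tailed 2.5%/
97.5% quantiles (linear interpolation of order statistics, R's default
quantile type). The study's results table does not say whether its
"estimate" is a mean or a median; the median was chosen for robustness, and
the tolerance used when comparing against the published table absorbs the
difference.

`select_model()` encodes the study's rule: fit the covariance model and
retain conditional independence if and only if both covariance 95% credible
intervals contain 0, with closed (inclusive) endpoints — an interval
$[0, 0.05]$ counts as containing 0.

Convergence is judged against the study's thresholds, psrf < 1.05 and
ESS > 1000, per parameter; `run_study()` reports the failing parameters and
the analysis drivers exit nonzero on failure.

## Predictive values

For test $i$ in population $k$,

$$\mathrm{PPV} = \frac{P_k\,Se_i}{P_k\,Se_i + (1-P_k)(1-Sp_i)}, \qquad
  \mathrm{NPV} = \frac{(1-P_k)\,Sp_i}{P_k(1-Se_i) + (1-P_k)\,Sp_i}.$$

The headline report computes both for the first test (the clinician-rated
EDTB): the published PPV/NPV percentages are reproduced, to the printed
rounding, only by the EDTB estimates — the study text does not name the
test, so this attribution is arithmetic inference, not quotation.

## The synthetic data generator

`simulate_study()` emulates the study design: two populations (defaults 100
"Belgian" and 42 "Swiss" individuals), latent status Bernoulli with
prevalences 0.518 and 0.817, and each individual's joint test pattern drawn
from the within-class bivariate Bernoulli implied by the accuracies
(EDTB 0.905/0.822, OLBI 0.730/0.726 by default) and optional covariances.
Optional OLBI total scores are drawn uniformly on 45–64 for positives and
16–44 for negatives — the study gives no score distribution, and only the
dichotomy enters the model, so the uniform choice is a neutral default that
exercises the score-to-dichotomy pipeline. Every dataset can be written with
a JSON truth manifest so recovery analyses are self-describing.

What the generator does *not* emulate: item-level responses of either
instrument, missing data, clinician behaviour, or any within-population
heterogeneity beyond the latent class itself. Passing recovery tests on
synthetic data therefore demonstrates the estimator is consistent with its
own model family, not that the model describes real burnout data; that
question belongs to the study's (deposited) dataset.

## Numerical and design choices

* **Cell convention.** Cells are always ordered (1,1), (1,0), (0,1), (0,0),
  first index = test 1 (EDTB), 1 = positive; file formats carry explicit
  column names so the convention cannot silently transpose.
* **OLBI cut-off.** Strictly greater than 44 is positive; a score of exactly
  44 is negative. The instrument's description ("higher than 44") supports
  the strict reading, but tie handling at exactly 44 is a documented choice.
* **Populations.** Any $K \ge 2$ is accepted; the study instance has
  $K = 2$. One population is refused unless explicitly overridden (the base
  model is then unidentifiable under flat priors).
* **Sensitivity replacement.** The study replaced each minimally informative
  prior in turn with an alternative distribution it does not print; the
  replacement here is configurable, defaulting to Beta(2, 1).
* **Degenerate inputs.** A zero cell probability facing a positive count
  yields a log-likelihood of $-\infty$, not an error; covariance intervals
  of width below 1e-10 pin the covariance to 0; empty populations and
  negative counts are rejected at construction.
* **Protocol defaults.** Two chains, burn-in 5000, 10,000 retained
  iterations, thin 1 — the study's protocol. Analysis drivers use these
  defaults; the prior-sensitivity driver shortens to burn-in 2000 / 4000
  iterations per refit, ample at the study's sample size where successive
  draws are nearly independent.
* **Simulation scales.** Recovery checks run at 5000 individuals per
  population (point recovery within ±0.05), interval-coverage checks at 50
  replicates of 1000 per population with 2000 retained draws each, and
  dependence-detection checks at 2000 per population — sizes at which the
  respective posterior features are visible without excess computation.

## Known limitations

* The dependence model is not identified from two populations; its
  covariance posteriors are prior-regularised, and the package uses it only
  through the interval-based selection rule, mirroring the study.
* With very small samples the posterior of a specificity can be strongly
  skewed and the pooled median a crude point estimate; the full draws are
  always exportable (`write_draws()`) for richer summaries.
* `elicit_beta()` restricts shapes to $\ge 1$; priors with boundary spikes
  must be given as explicit shape pairs.
* Reported effective sample sizes use one specific truncation rule; other
  software (different truncation, cross-chain variance handling) will give
  somewhat different numbers for the same chains.
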