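---
title: "Estimating diet from fatty-acid signatures: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating diet from fatty-acid signatures: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Predators integrate the fatty acids (FAs) of their prey into their storage
lipids largely intact, which makes the proportional FA composition of
adipose tissue — the *FA signature*, a vector of percentages over a few
dozen named FAs — a dietary tracer with far more dimensions than the two
or three stable isotopes traditionally used in mixing models. Two
complications stand between the signature and the diet:

1. **Trophic modification.** Consumers do not deposit prey FAs one-for-one;
   metabolism scales each FA up or down. The standard correction is a
   per-FA *calibration coefficient* (CC) estimated from a feeding trial at
   (near-)complete turnover: `cc_j = consumer mean_j / diet-weighted prey
   mean_j`. Multiplying a prey signature by the CCs takes it to *predator
   space*, after which modification can be treated as zero in the model.

2. **Turnover.** Tissue FAs are replaced gradually, so after a diet switch
   the signature is a convex mixture of the old and new diets. Estimates
   from switch-day samples legitimately differ from the diet being fed.

`famix` implements the full workflow: data preparation and tracer
filtering, a statistical check that the candidate prey are distinguishable
at all, a Bayesian mixing model for the diet proportions, and a synthetic
feeding-trial generator that makes every stage testable against known
truths.

## The mixing model

For consumer $i$ at level $l$ of an optional fixed factor (sampling day,
diet group), tracer $j$, and $K$ sources with predator-space means
$\mu'_{jk}$ and SDs $\sigma'_{jk}$:

$$y_{ij} \sim \mathrm{Normal}\!\left(\sum_k p_{lk}\,\mu'_{jk},\;
  \sqrt{\epsilon_j \sum_k p_{lk}^2\,\sigma'^2_{jk}}\right),\qquad
  p_{l\cdot} \sim \mathrm{Dirichlet}(\alpha_l),\qquad
  \epsilon_j \sim \mathrm{Uniform}(0, 20).$$

* The variance is the "Residual\*Process" structure: the process variance
  induced by source variability, scaled per tracer by a multiplicative
  residual $\epsilon_j$. The upper bound 20 is vague relative to
  percent-scale tracers and is configurable (`eps_upper`).
* Tracers are treated as conditionally independent given $p$ and
  $\epsilon$ — the price of entering sources as means and SDs rather than
  full multivariate samples. Real FA profiles are compositional and
  correlated; this is the model's main simplification.
* Each factor level gets an independent diet vector and prior; there is no
  pooling across levels.
* Trophic modification is additive in the general tracer-mixing equation
  but is fixed at zero here because CCs are applied to the sources first
  (`apply_ccs()`), which is exactly what makes that legitimate.

The model is written in the JAGS language and sampled with `rjags`. Diet
vectors are parameterised as independent $\mathrm{Gamma}(\alpha_k, 1)$
variables normalised onto the simplex: JAGS then samples unconstrained
positive scalars (no bespoke simplex proposals), the implied prior is
exactly $\mathrm{Dirichlet}(\alpha)$, and every saved draw closes the
simplex to machine precision — the tests assert this. Chains initialise at
the prior mean and carry per-chain Mersenne–Twister seeds derived from the
user seed, so every fit is exactly reproducible.

Defaults mirror a "normal" mixing-model run: 3 chains × 100,000
iterations, 50,000 burn-in, thinning 50. Unit tests and the benchmark
scripts use 3 × 20,000 (half burn-in, thin 10) on toy dimensions
($K \le 6$, $J \le 14$, $n \le 10$ consumers); at those sizes the sampler
converges in seconds and the Gelman–Rubin statistics sit below 1.01.

### Priors

Non-informative fits use $\alpha = (1, \dots, 1)$. `informative_alpha()`
converts prior diet weights $w$ (e.g. prey-mass proportions observed in
the field) to $\alpha_k = K w_k$, floored at 0.01: the *total*
concentration stays at $K$, so external knowledge relocates the prior
without inflating its strength, and a zero-weight source remains
admissible — in a Bayesian mixing model no proportion can be exactly zero,
so an absent source shows up as a small minimum, not as zero.

### Convergence

`gelman_rubin()` implements the classic potential-scale-reduction formula;
chains stuck at different constants return an `Inf` sentinel rather than
an error so that a failed fit is flagged, not crashed. `geweke()` compares
early (10%) and late (50%) window means with AR-spectral variance
estimates. A fit "passes" when all rhat < 1.05 and at least 90% of the
per-chain, per-parameter |z| < 2 — with dozens of parameters a few
excursions above 2 are expected by chance, which is why the pass criterion
is a fraction rather than a maximum. All three thresholds are arguments.

## Data preparation

* **Profiles** are percent compositions; raw empirical tables must sum to
  100 within ±2 percentage points (published tables routinely omit trace
  FAs — the tolerance is configurable). Predator-space and simulated
  profiles are exempt: CC multiplication intentionally breaks closure, and
  nothing downstream needs it (the likelihood is per-tracer).
* **Simulated consumers** (`simulate_consumers_from_summary()`): published
  studies usually report only means and SDs, while the model wants raw
  rows. Each FA is drawn independently from
  $\mathrm{Normal}(\bar y_j, s_j)$; negative draws are *redrawn* rather
  than truncated at zero, because truncation shifts the mean upward by
  more. Rows are not renormalised to 100 — renormalisation would reintroduce
  the compositional coupling the model does not assume.
* **Tracer selection** (`select_fas()`): an FA is retained iff its
  grand-mean abundance exceeds 0.5% (below that, measurement noise
  dominates), it is classified dietary or extended-dietary (endogenous FAs
  reflect the consumer, not the diet), and its CC is at most 2 (a consumer
  holding more than twice the prey proportion indicates endogenous origin
  or preferential accrual). The classification is data, not code: a
  packaged table covers common marine FAs and any named vector can replace
  it. FA names match exactly after whitespace stripping; no nomenclature
  fuzzing.
* **CCs under uncertainty**: `apply_ccs()` scales source SDs by the same
  factor as the means — the CC is treated as a deterministic scalar on the
  source distribution. Zero-SD sources get a small variance floor
  (`sd_floor`, default 1e-3 on the SD scale) to keep the likelihood
  proper. For CCs from mixed diets, the denominator is the mass-weighted
  mean of the prey means.

## Source separation

Mixing models need sources that differ. `permanova()` implements one-way
PERMANOVA directly on the squared-dissimilarity partition (Anderson's
pseudo-F; label permutations; $p = (\#\{F^* \ge F\} + 1)/(B + 1)$), with
Bray–Curtis as the default metric for proportional data and 999
permutations so the smallest attainable p is 0.001. The in-package
implementation exists because the pipeline and calibration tests run
thousands of PERMANOVAs; its pseudo-F is verified against
`vegan::adonis2` to 10 decimal places in the test suite, and its type-I
error is checked at the 5% level over 1000 null datasets.
`pairwise_permanova()` runs each unordered pair on its own deterministic
seed (`seed + pair index`) and applies Bonferroni correction — the most
conservative standard choice, appropriate for a gate that should fail
loudly. The pipeline treats a non-separated pair as a warning, not an
error: the fit proceeds, flagged.

## The synthetic feeding trials

`trial_scenario()` emulates the statistical structure of captive feeding
trials: a source library, a true CC vector, a diet schedule whose first
entry is the acclimation diet (consumers start at its equilibrium), and
first-order turnover kinetics

$$S(t+1) = (1 - \lambda)\,S(t) + \lambda\,T(t), \qquad
  \lambda = \text{turnover rate} \times \text{deposition fraction},$$

where $T(t)$ is the predator-space target of the diet active on day $t$.
Geometric approach to equilibrium is the simplest kinetics consistent with
the qualitative turnover statements in the feeding-trial literature
("near complete by 69 days"); per-species rates are genuinely unknown, so
the rate is a free parameter and preset values are chosen to match the
qualitative bounds of each trial (e.g. 0.065/day makes 69 days ~99%
complete). The deposition fraction multiplies the daily replacement —
low-fat diets deposit less, so the signature lags — and a 25%-deposition
run stays closer to the initial signature than a 100% run, monotonically
in $\lambda$. Per-consumer noise is independent normal per FA with SD
equal to the diet-weighted predator-space source SD (scaled by
`noise_sd_scale`), mirroring how consumers are simulated from published
summaries.

The five `scenario_preset()` designs transcribe real trial structures
(sample sizes, true diets, switch days, deposition): a five-source sea-duck
double switch, four salmon-oil cohorts at complete turnover, seabird
chicks with parental prior weights (0.72-dominant) and an absent prey, a
low-fat-diet seal trial at deposition 0.25, and three seal cohorts with
group structure. FA compositions and CCs are synthetic (drawn from the
packaged dietary FA pool); the presets fix their seeds so the "study"
datasets are stable. The parental mass proportions of the chick preset
(0.72, 0.15, 0.06, 0.04, 0.03) transcribe the reported prey ranking with
the dominant share at 0.72; the smaller shares are a synthetic completion
summing to 1.

What the generator does **not** emulate: compositional correlation between
FAs, chromatographic measurement error, blubber stratification (inner
layers turn over faster than outer), or physiological lipid routing.
Passing the benchmarks therefore demonstrates that the estimator recovers
truth *when the data follow the model's own assumptions* (closure of the
generator under the likelihood is itself a tested invariant at
$\lambda = 1$); it does not certify accuracy on real tissue data, where
the turnover gap and the independence assumption are the dominant caveats.

## Benchmark properties

`tests/testthat/test-acceptance.R` and `scripts/acceptance.R` recompute
the same seven properties end to end (3 chains × 20k iterations, toy
dimensions):

1. **Identity recovery** — CCs computed from the consumers themselves make
   the true source's predator-space signature coincide with the consumer
   mean; a single-prey fit must put its posterior median above 0.90.
2. **Mixture recovery** — a 70/30 two-source diet recovered within ±10
   percentage points.
3. **Absent source** — a never-fed prey included in the model receives the
   minimum posterior median, below 5%.
4. **Informative-prior pull** — on a confusable source pair the
   0.72-dominant prior moves the dominant source's median by >10 points
   versus a flat-prior fit.
5. **PERMANOVA calibration** — type-I error 0.05 ± 0.02 over 1000 null
   datasets at 199 permutations.
6. **Sampler correctness** — on two-source problems the MCMC posterior
   mean agrees with deterministic grid integration
   (`grid_posterior_2source()`, which integrates the residual multipliers
   over their prior on a quadrature grid — fully independent of JAGS)
   within 3 Monte-Carlo standard errors.
7. **Turnover direction** — in the double-switch preset the combined
   estimated share of the newly introduced prey rises strictly across
   sampling days 0 → 21 → 50.

## A property of Residual\*Process error worth knowing

Integrating $\epsilon_j \sim \mathrm{Uniform}(0, U)$ out of the likelihood
contributes, per tracer, a factor proportional to
$1/\sum_k p_{lk}^2 \sigma'^2_{jk}$ to the marginal posterior of $p$ (for
$U$ large relative to the residuals). With many tracers this accumulates
into a strong preference for diet vectors that *spread* mass across
sources with similar SDs, i.e. toward even splits within confusable
pairs — strong enough to overwhelm any fixed Dirichlet prior. The
informative-prior benchmark therefore constructs its confusable pair with
small source SDs, so that the pair's contribution to the process variance
is negligible and the within-pair allocation is genuinely prior-driven.
Users combining informative priors with highly variable, similar sources
should expect the prior to move estimates less than the prior weights
suggest; this is a property of the error structure, not a sampler
artefact.

## Degenerate inputs and numerical choices

* All-zero profiles are rejected by Bray–Curtis (undefined denominator).
* A CC denominator of zero with a nonzero consumer mean is a hard error
  naming the FA (the FA must be excluded upstream); any non-positive CC is
  rejected by construction.
* Groups with a single member yield a PERMANOVA warning; a single group is
  an error.
* Zero within-chain variance → `Inf` rhat sentinel; degenerate Geweke
  windows → `NA`, flagged.
* Sampler initialisation failures retry up to 3 times with jittered
  initial values before erroring.
* Ties in `rank_sources()` break alphabetically, so rankings are
  deterministic and invariant to input order.

## Limitations

* No concentration dependence: fat-rich prey contribute more FA mass per
  gram eaten than the model credits them for.
* No multivariate consumer likelihood, no random effects, no continuous
  covariates, no joint FA + stable-isotope model.
* One-way PERMANOVA only; no dispersion (PERMDISP) companion test.
* Turnover in the generator is a single-pool first-order process; real
  adipose tissue is at least two pools (stratified blubber).
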