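# famix — Bayesian diet estimation from fatty-acid signatures

Quantitative ecologists estimate *what* and *how much* a predator eats
from the fatty-acid (FA) composition of its storage lipids: prey FAs are
deposited largely intact, so a consumer's FA signature (percent of total
identified FAs, a few dozen tracers) is a high-dimensional dietary
record. `famix` is for trophic ecologists who want to run that analysis
as a Bayesian mixing model rather than through distance-minimisation
(QFASA-style) methods, and for methodologists who want to benchmark the
approach on feeding trials with known diets.

## The model

Trophic modification is handled multiplicatively: per-FA *calibration
coefficients* (CCs), `cc_j = consumer mean_j / diet-weighted prey mean_j`
estimated from a feeding trial at complete turnover, take prey ("source")
signatures to *predator space*, after which modification in the mixing
model is set to zero. For consumer *i* at level *l* of a fixed factor
(sampling day, diet group) and tracer *j*:

    y_ij ~ Normal( Σ_k p_lk μ'_jk ,  sqrt( ε_j Σ_k p_lk² σ'²_jk ) )
    p_l· ~ Dirichlet(α_l)          ε_j ~ Uniform(0, 20)

with predator-space source means μ'\_jk and SDs σ'\_jk — the
"Residual\*Process" error structure: per-tracer residual multipliers ε_j
scale the process variance induced by source variability. Priors are
non-informative (α = 1) or built from external diet weights with
`informative_alpha()`. The model is authored as a JAGS program and
sampled via `rjags` with exact seed control; convergence is assessed by
Gelman–Rubin and Geweke diagnostics.

Around the model, the package implements the standard workflow:

* **Data preparation** — CSV I/O for consumer/source/CC tables,
  simulation of consumer rows from published means/SDs, CC computation
  and application, and the tracer filters (abundance > 0.5%,
  dietary/extended-dietary class, CC ≤ 2).
* **Source separation** — one-way PERMANOVA (Bray–Curtis, permutation p)
  with Bonferroni-corrected pairwise comparisons, as a gate before any
  fit.
* **Synthetic feeding trials** — preset scenarios with known diets,
  diet-switch schedules, first-order turnover and reduced lipid
  deposition, so every stage can be scored against truth.
* **Evaluation** — posterior-median vs truth recovery reports with
  credible-interval coverage, and source rankings (an absent source shows
  up as a small minimum, never zero).

## Worked example

A seal cohort is switched from herring to low-fat pollock for 30 days; on
a low-fat diet only ~25% of dietary FA intake is deposited, so the
blubber signature lags far behind the fed diet:

```r
library(famix)

sc <- scenario_preset("harpseal_lowfat")          # herring -> pollock, n = 5
consumers <- simulate_trial(sc, days = c(0, 14, 30))
tracers   <- select_fas(consumers, sc$true_cc)     # abundance/class/CC gates
sources   <- apply_ccs(sc$sources, sc$true_cc)     # to predator space
spec      <- mixing_model_spec(sources, fa_names = tracers,
                               factor_name = "day")
post      <- fit(build_model(consumers, spec),
                 n_chains = 3, n_iter = 20000, n_burnin = 10000,
                 thin = 10, seed = 1)
print(post)
```

```
Diet posterior (3 chains x 1000 saved draws)
 level  source  mean median  q2.5   q25   q75 q97.5
     0 herring 0.991  0.992 0.978 0.988 0.996 1.000
     0 pollock 0.009  0.008 0.000 0.004 0.012 0.022
    14 herring 0.737  0.737 0.714 0.729 0.744 0.759
    14 pollock 0.263  0.263 0.241 0.256 0.271 0.286
    30 herring 0.542  0.542 0.523 0.536 0.549 0.561
    30 pollock 0.458  0.458 0.439 0.451 0.464 0.477
Convergence: PASSED (max rhat 1.0012, 96% of |geweke z| < 2)
```

Day 0 correctly reads as pure herring (posterior median 99.2%). On days
14 and 30 the seals were eating only pollock, yet its estimated share is
26% and 46%: with replacement rate 0.08/day × deposition 0.25, the
reachable pollock share after 30 days is (1 − (1 − 0.02)³⁰) ≈ 45% — the
estimator tracks the tissue, and the tissue lags the diet. Scoring
against those reachable shares (`compare_to_truth()`) gives a mean
absolute error below 1 percentage point.

## The analysis workflow

The numbered scripts under `analysis/` run the whole study on the five
preset trials and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_trials.R     # datasets + manifests
Rscript analysis/02_source_separation.R   # pairwise PERMANOVA gate
Rscript analysis/03_fit_diet_models.R     # all mixing-model fits
Rscript analysis/04_evaluate_recovery.R   # recovery vs fed/reachable diets
```

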