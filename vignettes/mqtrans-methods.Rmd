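---
title: "Detecting altered transcriptional regulation with mqTrans features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting altered transcriptional regulation with mqTrans features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mqtrans)
```

## The problem

Differential-expression analysis asks whether a gene's expression *level*
changes with disease. A regulatory relationship can be disrupted without any
level change: if a transcription factor (TF) stops driving its target, the
target's expression may stay in its usual range while no longer tracking the
TF. `mqtrans` targets exactly this blind spot in case/control transcriptome
studies (bulk microarray or any continuous expression matrix).

## The model

Features are split into TF features (gene symbol present in a TF catalogue),
mRNA features (annotated protein-coding features outside the catalogue — the
regression targets) and dropped features (no symbol annotation). For each
mRNA target $i$, expression is modelled as a sparse linear combination of all
TF features,

$$\widehat{\mathrm{mRNA}}(i) = w_0 + \sum_k w_{k,i}\,\mathrm{TF}(k),$$

fitted by L1-penalized least squares on a randomly chosen fraction (default
70%) of the **control** samples only:

$$\min_{w_0, w} \; \frac{1}{2n}\sum_j \Big(y_j - w_0 - \sum_k w_k x_{jk}\Big)^2
  + \alpha \sum_k |w_k|,$$

with the intercept unpenalized. TFs with non-zero weight are read as the
target's regulators. For any sample, the **mqTrans feature** of target $i$ is
the absolute prediction residual

$$\mathrm{mqTrans}(i) = \big|\,\mathrm{mRNA}(i) - \widehat{\mathrm{mRNA}}(i)\,\big|,$$

near zero while the control-derived regulatory programme holds and elevated
where it is broken. One mRNA gene may be measured by several probes; probes
are modelled independently (probe-level analysis), each named by its probe id
and annotated with its symbol. Regulation among TF genes themselves is out of
scope.

## Screening cascade

Candidate targets pass four nested screens, each applied to the survivors of
the previous one:

1. **Model exists** — at least one non-zero TF weight. Targets whose penalty
   zeroes every weight keep an intercept-only model (useful for scoring) but
   are not candidates.
2. **Correlation QC** — Pearson correlation between observed and predicted
   target values on the *hold-out* controls must exceed `pcc_min` (default
   0.5) with two-sided significance below `p_max` (default 0.05), both strict.
   The hold-out set is used so QC is not flattered by in-sample fit;
   train-set QC is recorded separately for diagnostics.
3. **Alteration** — mqTrans must be elevated in cases: group-mean ratio
   case/control above `ratio_min` (default 1) *and* a one-sided Mann–Whitney
   test (case > control) with Benjamini–Hochberg q below `q_alt` (default
   0.05). A pure-ratio mode exists for sensitivity analysis, because an
   error-controlled test plus direction is a design choice, not a forced one.
4. **FDR restriction** — BH-adjusted q of the model's QC significance below
   `q_fdr` (default 0.01, strict: q ≥ 0.01 is excluded).

Both BH families are the QC survivors within the same dataset: adjusting over
all candidate targets would mix models that never entered the later stages
into the error control.

mqTrans group comparisons use hold-out controls and case samples only;
training controls never enter the case/control contrast, again to avoid
in-sample optimism. The Mann–Whitney test uses the normal approximation with
continuity correction throughout, which keeps behaviour identical across
group sizes and tied values; a fully tied comparison (e.g. all-zero
residuals) is reported as `p = 1`.

Cross-dataset confirmation has two modes. **Transfer** applies the trained
models to an independent dataset — a model transfers only when its target and
all its regulators exist there (feature spaces differ across exports of the
same platform), and QC is recomputed on that dataset's controls. **Retrain**
reruns the whole pipeline on each dataset's own controls. A feature is
*confirmed* only if altered in every dataset (the strictest reading);
exclusive Venn region counts are reported alongside.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `train_fraction` | 0.7 | fraction of controls used to fit models |
| `penalty` | 1.0 | L1 strength $\alpha$ (unitless, scale-dependent) |
| `pcc_min`, `p_max` | 0.5, 0.05 | correlation QC gate (strict) |
| `q_alt` | 0.05 | BH threshold of the one-sided alteration test |
| `ratio_min` | 1.0 | required case/control mqTrans mean ratio |
| `q_fdr` | 0.01 | BH threshold on model significance (strict) |
| `standardize` | FALSE | opt-in TF standardization inside the lasso |

The L1 penalty is the one parameter whose *meaning depends on the data
scale*. The default 1.0 matches the common default of widely used lasso
implementations on microarray intensity data. The simulator below works on
an additive, unit-variance scale, where theory gives the appropriate rate:
the universal threshold $\alpha = \sigma\sqrt{2\log(p)/n}$ (`universal_penalty()`),
the smallest penalty that keeps pure-noise TFs out of the model with high
probability. All simulation-based validation in this package fits at that
rate. A penalty far above the scale of the TF–target covariances zeroes or
heavily shrinks every weight, and a sign-flipped regulator then barely moves
the residual (the variance excess is $4\,w\,\hat w$, which vanishes with
$\hat w$) — detection degrades gracefully but substantially. On real
intensity-scale data the default is a starting point, not a recommendation
to skip sensitivity checks.

Values are modelled exactly as distributed (no re-normalization or log
transform); gene symbols are matched after upper-casing and whitespace
stripping, with no alias resolution.

## Numerical choices

* The lasso is solved by coordinate descent (\pkg{glmnet}, `alpha = 1`,
  `standardize = FALSE` unless opted in) at a convergence threshold of
  `1e-18` with up to $10^7$ passes. The tight threshold costs nothing
  measurable and makes the near-zero-penalty limit reproduce ordinary least
  squares to $\sim 10^{-7}$, so the noiseless simulation is reconstructed
  essentially exactly. The test suite verifies the fitted penalized objective
  against an independent FISTA minimizer.
* A constant training response short-circuits to the intercept-only model
  (mean of $y$); glmnet cannot represent this case. A single-TF design is
  padded with a zero column (whose coefficient provably stays zero) for the
  same reason.
* Pearson QC p-values use the exact t-transform with $n-2$ degrees of
  freedom; a constant observed or predicted vector makes the correlation
  undefined and the record is flagged and excluded by the QC screen rather
  than raised as an error.
* The mean ratio is guarded by $\varepsilon = 10^{-12}$; a control mean below
  $\varepsilon$ flags the ratio as infinite, and infinite ratios sort above
  every finite ratio in rankings. Ranking ties are broken by target id,
  lexicographically, so orderings are stable across runs.
* Randomness enters only in the control split and the simulator, both
  seeded; artifact writers print numbers with 17 significant digits, so a
  rerun under an identical configuration is byte-identical.

## What the simulator emulates

`generate_network()` + `simulate_dataset()` produce data that satisfy the
model class exactly: each target is an intercept plus `k_regulators`
(default 3) TF contributions with weight magnitudes uniform in
`weight_range` (default [0.5, 1.5]) and Gaussian noise (default sd 0.2);
TFs are i.i.d. standard normal per sample, optionally equicorrelated
(`tf_rho`) to stress sparse selection under collinearity. Case samples are
generated from the same law except that chosen targets use perturbed
weights: the default perturbation flips the sign of one randomly chosen true
regulator, which *preserves the target's marginal variance* — altered targets
are invisible to differential expression of the target itself, isolating
precisely the signal mqTrans is meant to capture. `delete_regulator` and
`weight_shift` (by `magnitude`, away from zero) cover loss and dose-response
settings.

Consequences worth keeping in mind when reading the test results:

* Simulated data are additive and exactly linear. Real microarray data carry
  probe effects, batch effects, non-linear saturation and correlated noise;
  the simulator makes no attempt at these. Passing the recovery benchmark
  shows the estimator and the screening logic are correct, not that any
  particular biological dataset will yield comparable power.
* Under sign-flip, a target is detectable only if the fitted model retains
  the flipped regulator; with the universal-threshold penalty and benchmark
  weights this is essentially always the case, which is why recovery is
  near-perfect there.

## Reference problem sizes

The packaged validation uses: 20 random instances ($n = 30$, 5 TFs) for the
optimizer cross-check; 50 TFs × 100 targets, 200 noiseless controls for the
exact-reconstruction check; 50 TFs × 20 targets, 2,000 controls at noise sd
0.5 for the half-normal law ($\mathbb{E}\,\mathrm{mqTrans} = \sigma\sqrt{2/\pi}
\approx 0.399$); and the recovery benchmark of 200 TFs × 300 targets, 3
regulators each, 80 + 80 samples with 60 sign-flipped targets, averaged over
5 seeds. Null calibration uses 50 replicates of a 20 TF × 60 target design
with no perturbation, where the per-target detection frequency of the default
rule stays below the nominal q threshold. These sizes are large enough that
the binomial/sampling tolerances quoted in the tests are meaningful, and
small enough to run routinely.

## Known limitations

* The penalty is fixed, not tuned per target; cross-validated penalty paths
  and elastic-net variants are out of scope by design.
* TF–TF regulation is not modelled, and probes are never collapsed to genes.
* The alteration rule tests a one-sided location shift of the absolute
  residual; regulatory changes that *shrink* residual dispersion in cases
  (ratio < 1) are deliberately not flagged.
* Transfer mode inherits the training dataset's split and penalty; datasets
  with very few controls give weak QC and alteration tests in both modes —
  confirmation lists shrink accordingly rather than being error-controlled
  upward.

## A minimal run

```{r quickstart}
net <- generate_network(50, 60, k_regulators = 3, noise_sigma = 0.2, seed = 1)
pert <- perturbation_spec(net, n_altered = 15, mode = "sign_flip", seed = 2)
sim <- simulate_dataset(net, n_control = 60, n_case = 60, pert, seed = 3)

cfg <- mqtrans_config(seed = 4, penalty = universal_penalty(0.2, 50, 42))
run <- run_pipeline(sim$dataset, net$tf_ids, cfg)
run

ev <- evaluate_recovery(run$screen$stages$altered, sim$truth$altered_targets,
                        setNames(run$alteration$ratio, run$alteration$target_id))
unlist(ev[c("sensitivity", "specificity", "auroc")])
```
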