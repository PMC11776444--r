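---
title: "Quantifying the rhythm of quadruped gaits from footfall onsets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the rhythm of quadruped gaits from footfall onsets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(gaitrhythm)
```

## The problem

The sound of a moving horse is audibly rhythmic, and the rhythm differs by
gait: walk is a four-beat gait, trot a two-beat diagonal gait, canter a
three-beat gait with an airborne suspension phase. `gaitrhythm` quantifies
that rhythmicity from *footfall onset annotations* — the instants, in
seconds, at which a hoof strikes the ground, typically annotated by hand on
a point tier of a Praat TextGrid. Everything downstream is built from two
elementary quantities:

* the **inter-onset interval** $t_k$, the time between two successive
  footfalls, and
* the **rhythmic ratio**
  $r_k = t_k / (t_k + t_{k+1}) \in (0, 1)$,
  which normalizes each pair of adjacent intervals; $r_k = 1/2$ means two
  equal intervals (isochrony, a 1:1 relationship), $1/3$ a short–long (1:2)
  and $2/3$ a long–short (2:1) relationship.

The package tests whether ratios concentrate on such *small-integer
categories*, how accurately and precisely a gait realizes isochrony, and
whether the local temporal structure of three adjacent intervals suffices
to classify gait and individual identity.

## Synthetic gaits: what the generator emulates

Field recordings of this kind are rarely redistributable, so the package
ships a seeded generator (`simulate_recording()`, `simulate_population()`)
that reproduces the statistical structure the analysis assumes:

* **Gait templates.** Walk and trot repeat a single base interval (defaults
  0.287 s and 0.360 s, the modal interval durations of ridden horses on a
  firm surface); canter repeats a three-interval motion cycle (0.148,
  0.148, 0.267 s) whose long third interval spans the suspension phase —
  roughly a 1:1:2 pattern within the cycle.
* **Timing jitter.** Each realized interval is multiplied by mean-one
  log-normal noise with coefficient of variation `jitter_cv`. Multiplicative
  log-normal noise keeps intervals positive by construction (additive
  Gaussian noise would not) and makes the CV the natural variability knob.
  The mean-one parameterization (`exp(N(-σ²/2, σ²))`) makes the expected
  interval equal the template value exactly. Defaults are trot 0.03 < canter
  0.05 < walk 0.06: a tunable calibration encoding the observation that trot,
  with its mirrored two-limb coordination, is the most metronome-like gait.
  They are defaults, not measurements — per-individual within-gait CVs are
  not published for this system.
* **Individual tempo.** Each individual carries one log-normal tempo
  multiplier with median 1, shared across its gaits, emulating
  morphology-driven tempo differences (a larger horse is slower in every
  gait). The default SD on the log scale is 0.15, chosen once so that the
  pooled interval CV (within-individual jitter plus between-individual
  spread, ≈ `sqrt(0.06² + 0.15²)` ≈ 0.16–0.17 for walk) matches the pooled
  variability typical of multi-horse datasets in this system.
* **Annotation granularity.** Onsets are rounded to 1 ms, the practical
  precision of manual annotation in Praat. A consequence worth knowing:
  "exact" zero-jitter ratios are exact only up to this quantization and
  double-precision arithmetic, which is why tests compare them at 1e-9
  rather than bitwise.

What the generator does *not* emulate: tempo drift within a recording,
annotation outliers (missed or double-marked footfalls beyond the 1 ms
collapse rule), surface or speed changes, and gait transitions (assumed
pre-excised). Passing the simulation-based tests therefore shows the
pipeline recovers structure *of this idealized kind*; it does not validate
the biological claims on real recordings.

```{r simulate}
recs <- simulate_population(population_spec(n_individuals = 19, seed = 1),
                            default_gait_specs(duration_s = 60))
length(recs)
recs[[3]]
```

## The ratio bin scheme

Category tests compare *on-integer* acceptance ranges around the reference
ratios 1/3, 1/2, 2/3 with flanking *off-integer* control ranges. All edges
are reciprocals of denominators stepped by 0.25 and mirrored around 1/2:
the 1:2 on-bin spans [1/3.25, 1/2.75), isochrony spans [1/2.25, 1−1/2.25),
2:1 spans [1−1/2.75, 1−1/3.25), and the off bins are centered at 1/3.5,
1/2.5, 1−1/2.5 and 1−1/3.5. Exact fractions are used internally; printed
decimals such as 0.308 or 0.444 are display roundings. The seven bins tile
[1/3.75, 1−1/3.75] with half-open intervals (the outermost edge closed), so
every ratio maps to exactly one bin or to "outside"; ratios outside the
covered range belong to no category and are excluded from the category
tests (but kept for densities).

```{r bins}
build_bin_scheme()
```

Two construction choices were genuinely open and are fixed here: off-bin
*edges* (the field convention prints off-bin centers only) are placed at
the same reciprocal-denominator steps of ±0.25 around each off center,
which is the unique symmetric choice that tiles the axis without gaps; and
each category's "off" factor level pools its two flanking off bins, with
the model offset using the pooled width — the symmetric reading of a
six-level on/off factor.

## Canter motion cycles

A canter stride is three footfalls plus a suspension: in the interval
sequence, a repeating short–short–long pattern whose long interval spans
the suspension. Because the published protocols annotate footfalls but not
cycle boundaries, segmentation here is pattern-based: a deterministic
two-cluster split of log $t_k$ (centers initialized at the quartiles)
labels long intervals, and every run between consecutive long intervals
that contains exactly two shorts becomes a cycle $(t_1, t_2, t_3)$.
Fragments that do not match — leading/trailing partial cycles, runs with
missed beats — are dropped and counted in the diagnostics. If the two
clusters' geometric means are closer than a factor 1.2 the sequence is not
bimodal and segmentation fails loudly rather than guessing.

Per cycle, three phase ratios are computed: $r_{k1} = t_1/(t_1+t_2)$
(expected near 1:1), $r_{k2} = t_2/(t_2+t_3)$ (near 1:2), and
$r_{k3} = t_3/(t_3+t_1')$ with $t_1'$ the first beat of the *next* cycle
(near 2:1). $r_{k3}$ is only computed when the next cycle follows
immediately, so dropped fragments never create spurious cross-fragment
ratios; the last cycle yields none.

```{r canter}
iv <- compute_intervals(recs[[3]])
cy <- segment_canter_cycles(iv)
cy
head(compute_canter_phase_ratios(cy)$r, 6)
```

## Category tests

For walk and trot, per-individual counts in the six bin levels are modeled
with a hierarchical count regression: bin level as fixed factor, individual
as random intercept, log bin width as offset (so the comparison is of
densities, not raw counts), negative-binomial family by default. The
category-structure test is the likelihood ratio of this full model against
a null containing only the random intercept and offset; bin contrasts are
Tukey-adjusted. A category is supported when its off − on contrast is
negative and significant. For canter, each category gets its own Poisson
model on the per-phase counts with bin (on/off), phase and their
interaction as fixed effects — the interaction is included so the test has
the df of the full cross-classification — plus the random intercept and
offset.

Numerical robustness choices:

* Synthetic (and occasionally real) data produce *structurally empty* bins
  — a jitter-free trot puts every ratio in the isochrony bin. Maximum
  likelihood then drives the empty level's coefficient to −∞ and Wald
  summaries (hence Tukey z-tests) return NaN. For any key on-vs-off
  contrast with a degenerate Wald summary the package falls back to the
  exact conditional rate test: given the two cells' total, the off-cell
  count is Binomial(n, w_off/(w_off+w_on)) under equal densities. The
  fallback is Bonferroni-adjusted over the contrast family and recorded in
  the result's notes.
* A negative-binomial fit on equidispersed counts can hit the dispersion
  boundary (non-positive-definite Hessian); it is then refit as Poisson,
  with a note. If the mixed fit fails entirely, the model degrades to a
  fixed-effects count regression, again noted: the contract is the
  inferential output, not one optimizer.
* Poisson fits report the Pearson dispersion ratio so overdispersion is
  visible.

The walk–trot tempo comparison takes each individual's median $t_k$ per
gait and applies a paired t-test (df = n − 1), with Shapiro–Wilk checks on
both sets of medians. Identical median sets are a measure-zero edge case
where the t statistic is pinned to 0 rather than NaN.

## Isochrony accuracy and precision

Within the open window $0.4 < r_k < 0.6$ (endpoints excluded, the literal
reading of the boundary definition), **accuracy** is the per-ratio deviance
$|r_k - 0.5|$ and **precision** is the per-individual interquartile range
of in-window ratios — smaller is better for both. The IQR uses type-7
(linear-interpolation) quantiles, stated here because no convention is
canonical and fixing one makes results bit-stable. Fewer than four
in-window ratios leave the IQR undefined and flagged rather than silently
extrapolated.

Across-gait comparisons mirror the category models: gait fixed, individual
random. Accuracy is modeled at the per-ratio level and precision at the
per-individual level, matching their definitions. The response family is
chosen by an AIC screen (via `fitdistrplus`) over feasible candidates —
Gaussian always; Gamma with log link and log-normal only when the response
is strictly positive, which accuracy typically is not (1 ms quantization
produces exact zeros). The selected family is recorded in the result's
notes, as a logged decision rather than a hidden default.

## Classification

The temporal signature of a gait lives in the relationship of *three*
adjacent intervals, so overlapping triplets $(t_k, t_{k+1}, t_{k+2})$
(stride 1, maximizing data) are embedded in two dimensions with UMAP
(defaults: 15 neighbors, minimum distance 0.1, Euclidean metric — the
conventional defaults, exposed as arguments) and classified with a
1000-tree random forest on the coordinates (V1, V2). Triplets enter *raw*,
not normalized: walk and trot differ chiefly in tempo, and normalizing
triplets to proportions would discard exactly that signal. The embedding is
single-threaded and seeded, so reports are reproducible bit for bit.

The 70/30 split is stratified by the supervising label (without
stratification, rare classes can vanish from the training set). The report
exposes two accuracies side by side: the pooled train+test accuracy
(resubstitution on training rows — the convention matched by the headline
numbers of this literature) and the test-only accuracy, which is the
defensible generalization estimate. ROC curves are one-vs-rest on class
vote fractions (out-of-bag votes for training rows, predicted votes for
test rows) with trapezoid-rule AUCs.

```{r classify, eval = FALSE}
trip <- make_triplets(lapply(recs, compute_intervals))
emb <- embed_triplets(trip, seed = 1)
train_classifier(emb, "gait", seed = 1)
train_classifier(emb, "individual", seed = 1)
```

Supervising the same embedding on individual identity instead of gait
gives markedly lower accuracy on the simulated defaults: between-individual
tempo spread (SD 0.15) separates individuals less than the gait templates
separate gaits. The package's tests assert the ordering, not any specific
percentage, because the percentages depend on the generator's calibration.

## Problem sizes used in the test suite

The simulation batteries use the study-scale configuration — 19
individuals, 60 s per gait, three gaits — with 100 replicates for category
recovery, 200 for type-I control of the category LRT (uniform,
width-proportional null counts), and 10 seeds each for the metric-ordering
and classifier-ordering checks. Module unit tests run on reduced fixtures
(3–6 individuals, 20–40 s) since they exercise contracts, not power.

## Known limitations

* Canter segmentation assumes a detectably bimodal interval distribution;
  heavily jittered or tempo-drifting canter can defeat it, and it fails
  with diagnostics rather than returning doubtful cycles.
* The isochrony window applies to sliding ratios for every gait, including
  canter, where only the 1:1 phase typically falls in-window; tail
  spillover from the 1:2 and 2:1 phases legitimately inflates canter's
  deviance.
* The exact conditional fallback for degenerate contrasts ignores the
  individual random effect (it conditions on pooled totals); it is used
  only where the mixed-model Wald test is undefined, and is flagged.
* TextGrid support covers the two text dialects (long and short) in UTF-8
  and UTF-16; binary TextGrids are not read.
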