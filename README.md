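# gaitrhythm

Rhythm analysis of quadruped footfall sound sequences in R: from annotated
footfall onsets to inter-onset intervals, small-integer rhythmic-ratio
category tests, isochrony accuracy/precision metrics, and gait/individual
classification.

## Who this is for

Bioacousticians and behavioural scientists studying locomotor rhythm — for
instance the footfall sounds of horses across walk, trot and canter — who
annotate footfall onsets (e.g. on Praat TextGrid point tiers) and want a
tested, reproducible implementation of the standard rhythm-analysis
pipeline, plus a seeded synthetic gait generator so every stage can be
exercised without field recordings.

## The quantities at the core

For an onset sequence, the inter-onset intervals and rhythmic ratios are

    t_k = onset_{k+1} − onset_k
    r_k = t_k / (t_k + t_{k+1})      ∈ (0, 1)

A ratio of 1/2 marks isochrony (1:1 — equal adjacent intervals), 1/3 a 1:2
and 2/3 a 2:1 relationship. The package:

* tests whether ratios pile up in **on-integer bins** around 1/3, 1/2, 2/3
  versus flanking **off-integer bins** (edges at reciprocal denominators
  1/3.75 … 1−1/3.75), using hierarchical count models with individual random
  intercepts and a log bin-width offset, with likelihood-ratio tests and
  Tukey-adjusted contrasts;
* segments canter interval sequences into short–short–long motion cycles
  (the long interval spans the suspension phase) and tests each cycle phase
  ratio r_k1, r_k2, r_k3 against its own category;
* quantifies **accuracy** (|r_k − 0.5| inside the open window 0.4–0.6) and
  **precision** (per-individual IQR of in-window ratios) of isochrony and
  compares them across gaits;
* embeds adjacent-interval triplets (t_k, t_k+1, t_k+2) in 2-D with UMAP and
  classifies gait — and, separately, individual identity — with a 1000-tree
  random forest, reporting OOB error, confusion, per-class AUC and accuracy;
* reads and writes Praat TextGrid point tiers (long/short dialect, UTF-8 or
  UTF-16) and long-format onset CSVs (`individual_id,gait,onset_s`).

## Worked example

```r
library(gaitrhythm)

recs <- simulate_population(population_spec(n_individuals = 19, seed = 1),
                            default_gait_specs(duration_s = 60))
report <- analyze_recordings(recs, seed = 1)
report
```

Abbreviated output (as printed by the code above):

```
<rhythm_report> 57 recordings, seed 1
<category_test> walk (nbinom family)
  full vs null: Chisq = 229.958, df = 5, p = 1.09e-47
  key contrasts:
     contrast estimate    SE z_ratio   p_adj
 off12 - on12    2.623    NA      NA 0.06765
 off11 - on11   -5.337 0.195  -27.36 0.00000
 off21 - on21    2.400    NA      NA 0.35543
...
<duration_comparison> walk vs trot: t = -30.725, df = 18, p = 5.26e-17
  mean median difference = -0.0764 s
<category_test> accuracy (gaussian family)
  full vs null: Chisq = 885.149, df = 2, p = 6.2e-193
...
<classifier_report> supervised on gait (3 classes, 1000 trees)
  OOB error: 10.14%  overall accuracy (train+test): 96.89%  test-only: 89.65%
  mean one-vs-rest AUC: 0.978
<classifier_report> supervised on individual (19 classes, 1000 trees)
  OOB error: 71.21%  overall accuracy (train+test): 78.75%  test-only: 29.17%
  mean one-vs-rest AUC: 0.868
```

Reading it: walk's isochrony contrast (`off11 - on11` = −5.34, adjusted
p ≈ 0) says the on-isochrony bin holds overwhelmingly more ratios than its
off bins — walk is isochronous; its 1:2 and 2:1 contrasts are not
significant. Trot intervals are significantly longer than walk's (negative
paired t on per-individual medians). Accuracy and precision contrasts put
trot closest to a perfect metronome. Gait labels are recovered far better
than individual identity from the same embedding (96.9% vs 78.8% pooled
accuracy), i.e. the three-interval temporal signature is chiefly a gait
signature. Where a contrast is marked with `SE = NA`, a structurally empty
bin made the Wald test degenerate and the reported p comes from an exact
conditional rate test (see the result's `notes`).

Figures: `plot_interval_density()`, `plot_ratio_density()`,
`plot_ternary()`, `plot_peak_lollipop()`, `plot_embedding()`, `plot_roc()`.
Tables: `write_report(report, "outdir")`.

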