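# fgrms

Serum proteome profiling for fetal growth restriction screening by
affinity MALDI-ToF mass spectrometry.

## The problem

Fetal growth restriction (FGR) — the pathological failure of a fetus to reach
its growth potential — affects roughly 3–8% of pregnancies, and antenatal
detection by ultrasound alone misses a large fraction of cases. A
blood-based assay that separates high-risk FGR pregnancies from
constitutionally small-for-gestational-age (SGA) and unaffected control
(CTRL) pregnancies can refer the right patients to closer surveillance.

This package implements, end to end, a multi-parametric classifier built on
maternal serum profiles recorded by affinity (bead-enrichment) MALDI-ToF
mass spectrometry in linear positive mode, m/z 4,000–20,000. It is aimed at
analysts who work with such profile spectra and want a tested, reproducible
implementation of the scoring procedure — plus a synthetic-cohort simulator
so every stage can be exercised and validated without patient data.

## The method

Each spectrum is internally **recalibrated** on two calibrant ion signals —
apolipoprotein C-I (m/z 6631.6) and transthyretin (m/z 13,762.4) — by the
two-point affine map that sends the observed apexes onto the reference
masses. Five marker ion signals are then integrated (trapezoidal area over a
±25 Da window after linear-endpoint baseline subtraction): apolipoprotein
C-II (m/z 8205), apoC-III_0 (m/z 8766), pro-apoC-II (m/z 8916), apoC-III_1
(m/z 9422) and apoC-III_2 (m/z 9713). Within each spectrum the areas are
brought into context by three quotients, which cancel absolute intensity:

```
A = area(8916) / area(8205)
B = area(8766) / (area(9422) + area(9713))
C = area(8916) / (area(8766) + area(9422) + area(9713))
```

Per-quotient **cut-offs** are trained by a Youden-index scan: the training
values are ranked, augmented with two sentinels (min − 1, max + 1),
candidate thresholds are the midpoints of neighbouring values, and the
candidate maximizing J = sensitivity + specificity − 1 is the best cut-off
(FGR values are the higher ones, so value > cut-off calls positive). Two
cut-off sets from independent training sets are **combined** into dual
lower/upper thresholds, opening three scoring regimes per quotient: 0.0 at
or below the lower, 0.5 in between, 1.0 above the upper. The **cumulative
score** (0.0–3.0 in steps of 0.5) classifies a spectrum: at or below the 1.0
discriminator → CTRL, above → FGR. Replicate spectra of a patient must agree
unanimously; disagreeing patients are *indeterminate* and excluded from
performance statistics. Performance is summarized by the confusion metrics
(sensitivity, specificity, PPV, NPV, Youden J), rank-based ROC/AUC on the
cumulative scores, and a normal-approximation minimal sample size for
comparing two means (α = 0.05, power = 0.80).

Spectra failing quality control are excluded with a machine-readable
reason: dominant serum amyloid A1 signals at m/z 11,527.0 / 11,683.5
(`exclude_saa`) or a failed internal recalibration (`exclude_calibration`).

## Worked example

```r
library(fgrms)

run <- run_pipeline(sim_config(), mode = "dual", seed = 1)
run
#> <fgr_run> mode: dual  seed: 1
#>   spectra: 150 simulated, 4 excluded (SAA 0, calibration 4)
#>   training spectra: 58  test spectra: 88  indeterminate patients: 0
#>   spectrum-level AUC: 0.973  min n per group: 2
#>   patient-level performance:
#> <confusion_metrics>
#>   TP 29  FP 3  TN 41  FN 0
#>   sensitivity 1.00  specificity 0.93  PPV 0.91  NPV 1.00
#>   accuracy 0.96  Youden J 0.93
```

This simulates the default cohort (30 CTRL, 15 SGA and 30 FGR patients, two
measurement series each = 150 spectra), excludes 4 spectra whose calibrant
peaks could not anchor the recalibration, trains cut-offs on the first
measurement series of the CTRL and FGR patients (58 spectra after
exclusions), combines them with the shipped prior-study cut-off set "W",
scores the remaining 88 spectra with the dual 0.0/0.5/1.0 rule, and
consolidates them into patient calls. With seed 1 the patient-level
confusion table is TP 29, FP 3, TN 41, FN 0 — sensitivity 1.00, specificity
0.93, PPV 0.91, NPV 1.00 — and the spectrum-level AUC on cumulative scores
is 0.97. SGA patients count as negatives: they carry the control serum
profile and should classify with CTRL.

The pieces compose individually, data frame in, tibble out:

```r
cohort    <- simulate_cohort(sim_config(seed = 1))     # spectra + ground truth
areas     <- preprocess_spectra(cohort)                # recalibrate, integrate, QC
quotients <- compute_quotients(areas)                  # add A, B, C
trained   <- train_cutoff_set(dplyr::filter(quotients, series_id == "MS1",
                                            cohort != "SGA"))
tidy(trained)
#> # A tibble: 3 × 5
#>   quotient cutoff j_max sensitivity specificity
#> 1 A          3.91 0.931       0.966       0.966
#> 2 B          4.09 0.793       0.862       0.931
#> 3 C          2.79 0.690       0.759       0.931

dual   <- combine_cutoffs(trained, cutoff_set(3.4, 7.0, 5.1, "W"))
scores <- score_spectra(quotients, dual)               # 0.0/0.5/1.0 per quotient
calls  <- aggregate_patients(scores)                   # unanimity per patient
confusion_metrics(calls$final, ifelse(calls$cohort == "FGR", "FGR", "CTRL"))
```

`autoplot()` draws spectra and ROC curves; `plot_score_distribution()` shows
cumulative scores by group; `tidy()`/`glance()` give broom-style tables for
cut-off sets, confusion metrics and ROC results. A thin command-line wrapper
with subcommands `simulate`, `preprocess`, `train-cutoffs`, `score`,
`evaluate` and `run` ships in `inst/cli/fgrms.R`.

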