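---
title: "Serum proteome profiling for FGR screening: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum proteome profiling for FGR screening: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgrms)
```

## The assay and its statistical model

The assay classifies pregnancies as fetal growth restriction (FGR) or
unaffected (CTRL, with constitutionally small SGA expected to behave like
CTRL) from maternal serum protein profiles recorded by affinity MALDI-ToF
mass spectrometry in linear positive mode over m/z 4,000–20,000. Five
apolipoprotein ion signals carry the discriminating information: apoC-II
(m/z 8205), apoC-III\_0 (8766), pro-apoC-II (8916), apoC-III\_1 (9422) and
apoC-III\_2 (9713). Because absolute MALDI intensities are not quantitative
across spots, the assay works entirely on within-spectrum ratios:

$$A = \frac{a_{8916}}{a_{8205}},\qquad
  B = \frac{a_{8766}}{a_{9422}+a_{9713}},\qquad
  C = \frac{a_{8916}}{a_{8766}+a_{9422}+a_{9713}},$$

where $a_m$ is the integrated area of the signal at m/z $m$. All three
quotients run higher in FGR sera, which fixes the direction convention used
throughout: *value above threshold calls FGR-positive*. The classifier
never auto-detects direction; a data set in which the convention fails is a
modelling problem, not a tuning problem.

### Cut-off training

Per quotient, all training values (both groups pooled) are ranked and
augmented with two sentinel values, $\min - 1$ and $\max + 1$, so the scan
also evaluates "everything negative" and "everything positive". Candidate
thresholds interpolate linearly between neighbouring values; the
interpolation fraction is not prescribed by the procedure's description, so
the package uses the midpoint (fraction 0.5), the symmetric and conventional
choice. At each candidate the Youden index $J = \text{sensitivity} +
\text{specificity} - 1$ is evaluated; the maximizing candidate is the best
cut-off. At ties the *smallest* candidate wins, which favours sensitivity —
defensible in a screening assay where a false negative is the costlier
error. The sentinel offset is the absolute constant 1, not scale-relative,
mirroring the published recipe; for quotients of order 1–10 that places the
sentinels clearly outside the data.

### Dual cut-offs and cumulative scoring

Two independently trained cut-off sets (here: the freshly trained set "O"
and the shipped prior set "W" = 4.2/5.0/4.0 and 3.4/7.0/5.1 for A/B/C) are
combined per quotient into lower = min and upper = max, opening three
regimes scored 0.0 (value ≤ lower), 0.5 (lower < value ≤ upper) and 1.0
(value > upper). Boundary semantics are exact and strict as printed —
"below or equal" scores down, "higher than" scores up — with no epsilon
slop; scores are compared on raw floats. Equal cut-offs for a quotient
leave no middle regime, so combining them is refused as degenerate rather
than silently collapsing to single-threshold behaviour.

The cumulative score (sum over A, B, C; 0.0–3.0 in 0.5 steps) is compared
with the fixed discriminator 1.0: at or below calls CTRL, above calls FGR.
The discriminator is a configuration constant, deliberately not re-trained —
it is part of the assay definition, and re-optimizing it on each data set
would leak test information into the decision rule.

### Patient-level consolidation

Each patient contributes replicate spectra (duplicate spotting; two or four
measurement series). The package consolidates by *unanimity*: a patient is
called FGR or CTRL only when all non-excluded replicate spectra agree, and
*indeterminate* otherwise; indeterminate patients are excluded from
confusion statistics. Unanimity is the only aggregation rule under which a
within-patient disagreement forces exclusion of the whole patient, which is
exactly how indeterminate patients are handled in this assay's reporting.

### Evaluation

Confusion metrics follow the standard definitions, with undefined rates
(zero denominators) reported as `NA` and serialized as empty fields, never
as 0. Reported rates are rounded half away from zero to 2 decimals (the
presentation convention); raw values are retained in every output object
and file. AUC is computed by the rank (Mann–Whitney) formulation with ties
credited 0.5, on the *cumulative scores* rather than binary calls — a graded
statistic is what makes a nontrivial ROC possible for a discrete 7-level
score. The minimal sample size per group for a two-sided comparison of two
means uses the closed-form normal approximation
$n = \lceil 2 (z_{1-\alpha/2} + z_{\beta})^2 / d^2 \rceil$ with
$\alpha = 0.05$ and power $0.80$; this tracks the noncentral-*t* iteration
of dedicated power software to within about one unit of $n$ at $d \approx 1$
(the test suite asserts agreement with `power.t.test` to ±1).

## Preprocessing: recalibration, integration, QC

**Recalibration.** Every spectrum is internally recalibrated on
apolipoprotein C-I (m/z 6631.6) and transthyretin (m/z 13,762.4). The apex
nearest each calibrant within the matching tolerance is located, and the
two-point affine map sending the observed apexes to the reference masses is
applied to the whole axis, so both calibrant apexes land exactly on their
reference masses. The model is strictly affine because two points determine
a line; recalibration is idempotent to numerical precision. A spectrum
fails calibration when (a) a calibrant peak is absent — the apex within the
window falls below 5% of the spectrum's maximum intensity, a scale-invariant
peak-presence check — or (b) the fitted slope deviates from 1 by more than
0.01. The presence check carries the practical load: within a ±10 Da window
a two-point fit can never produce a slope deviation above ~0.003, so a
slope-only criterion would never fire.

**Integration.** The original area determination was done in vendor
software whose exact parameters are documented only in prior work; the
integration dialect here is an explicit, configurable stand-in. Defaults:
apex = grid maximum within ±25 Da of the target (no sub-grid interpolation —
a 1 Da grid is an order of magnitude finer than the ±10 Da matching
tolerance), linear-endpoint baseline chord subtracted and clipped at zero,
trapezoidal integration across the window. A ±25 Da window is ±6.25σ at the
default 4 Da peak width, capturing > 99.99% of a Gaussian peak's mass; the
test suite verifies 1% closed-form agreement for σ ∈ [2, 8] Da. Whether the
original areas were baseline-subtracted is not documented; subtraction is
the default here because the simulator injects a baseline, and it is
switchable (`baseline = "none"`) for users matching other software.

**Quality control.** Two exclusion rules, each with a machine-readable
reason. `exclude_saa`: apexes at both m/z 11,527.0 and 11,683.5 (des-Arg
and full-length serum amyloid A1 — an acute-phase serum composition unlike
the screening population) exceed twice the median marker apex intensity;
the factor 2 is configurable, and the rule is a ratio of intensities, hence
invariant to uniform intensity scaling. `exclude_calibration`: internal
recalibration failed as above.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates the study conditions the analysis assumes:
spectra on a regular 1 Da grid over m/z 4,000–20,000 (linear-mode
resolution scale), ~60 protein signals each (5 markers + 2 calibrants + 53
background peaks), Gaussian peaks of σ = 4 Da, a decaying chemical
baseline, additive Gaussian noise clipped at zero, a bounded per-spectrum
affine m/z drift (the recalibration model is two-point linear, so the
injected distortion is the matching two-parameter family), replicate
measurement series per patient, and per-patient QC artifacts at roughly the
1-in-75 rate seen in a mid-sized cohort.

Marker areas are log-normal — areas are positive and right-skewed in MALDI
profiling — with a between-patient log-SD of 0.2 (~20% CV, typical
profiling reproducibility) and a series-level technical jitter of 0.05
(~5% CV, duplicate spotting of the same extract). The variance split is a
package addition: without it, replicate unanimity at the patient level
would be uninformative, because independent full-variance draws would
disagree as often as two strangers. No distributional parameters for the
original cohorts are published; all of these values are documented
assumptions about a plausible cohort, not estimates of any real one.

The group effect raises the FGR log-means of m/z 8916 by +1.0 and m/z 8766
by +0.7 (≥ 2 marker-level log-SD, the separation regime the analysis is
designed for), which raises the expected values of A, B and C jointly; the
configuration validator refuses parameter sets whose expected FGR quotients
do not exceed CTRL's, since such a simulation contradicts the direction
convention. Control geometric-mean areas (1400/1200/3520/250/150 for
8205/8766/8916/9422/9713) put the control quotients at A = 2.51, B = 3.00,
C = 2.20 — the same order of magnitude as the published cut-offs. SGA
patients are drawn from the control distribution, reflecting that SGA sera
cluster with controls.

Background peak positions are uniform with a ±50 Da exclusion zone around
every panel position, keeping integration windows interference-free: the
simulator is built to test the scoring procedure, not peak deconvolution.
The drift bound defaults to 0.001 (slope `1 + U(−d/2, d/2)`, intercept
`U(−d/2, d/2) × 4000` Da), which keeps the worst-case calibrant
displacement within the 10 Da matching tolerance — a larger drift would not
be recoverable by an internal recalibration that must first *find* its
calibrants.

Deliberately absent: isotope envelopes, detector saturation, matrix
clusters, peak-shape asymmetry, overlapping signals, gestational-age or BMI
covariates, and any correlation structure between markers beyond the shared
patient effect. Passing tests on simulated cohorts therefore demonstrate
the correctness and stability of the *procedure* — integration accuracy,
cut-off optimality, scoring semantics, aggregation and evaluation — not the
clinical performance of the assay on real sera.

## Numerical choices and degenerate inputs

* Ties in the Youden scan: smallest candidate (above). Equal neighbouring
  values produce duplicate candidates; they evaluate to a J no better than
  their neighbours and are harmless.
* `score_single`/`score_dual` boundaries are strict as printed; equality
  scores down.
* Zero or missing denominator areas make a quotient undefined and raise a
  validation error rather than propagating `Inf`.
* An all-zero integration window returns area 0 with flag `"zero_window"`
  instead of failing, so sparse background regions can be probed.
* Confusion rates with zero denominators are `NA` ("undefined"), never 0.
* Pipeline problem sizes: the default simulated cohort (150 spectra of
  16,001 points) runs in a few seconds on one core; the test suite uses
  cohorts of 30 + 30 spectra per arm for the end-to-end separation checks
  and 1,000 randomized lists for the Youden oracle comparison.

## Known limitations

* The integration dialect approximates, but is not, the vendor software's
  area determination; absolute areas are not comparable across dialects
  (quotients largely are, which is the point of forming them).
* The published cut-off preset (`cutoffs_paper_ow()`) derives from the
  original human cohorts; applying it to simulated data exercises the
  scoring machinery but says nothing about clinical accuracy.
* Patient aggregation by unanimity is one defensible reading of
  "indeterminate results"; majority or mean-score rules would admit more
  patients at the cost of confidence. The rule is isolated in
  `aggregate_patients()` if users need a different policy.
* The simulator's independence assumptions (markers independent given
  group; background independent of markers) make it easier, not harder,
  than real serum — effect sizes that separate here may not separate in
  practice.
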