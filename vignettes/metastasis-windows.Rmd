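---
title: "Metastasis surveillance windows from exponential growth kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metastasis surveillance windows from exponential growth kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcmets)
```

## The model

`bcmets` treats a breast-cancer primary tumor (PT) and each of its secondary
distant metastases as spheres growing exponentially in volume from a single
10 µm cell. The single kinetic parameter is the tumor volume doubling time
(TVDT): volume doubles once per TVDT, and since volume scales with the cube
of diameter, a tumor of diameter $d$ mm has undergone

$$N(d) = 3 \log_2\!\left(\frac{d}{0.01\ \text{mm}}\right)$$

volume doublings. A 15.1 mm PT at surgery has accumulated $N(15.1) = 31.7$
doublings; a diameter doubling always costs exactly 3 volume doublings.
Everything else in the package is bookkeeping on this identity:

* **Seeding.** Metastatic cells are shed from the moment the PT passes the
  1 mm seeding threshold — its 20th volume doubling — until resection.
* **Detection.** A metastasis becomes detectable by multimodal imaging at
  9 mm ($N(9) = 29.44$ doublings).
* **Death.** The lethal burden is 40 doublings (about $1.1\times10^{12}$
  cells, a ~102 mm sphere).
* **Whole history.** Seeding index (20) plus lethal count (40) spans the
  fixed 60-doubling natural history. The per-metastasis doubling ledger
  telescopes to exactly 60 for *every* PT size — `whole_history_identity()`
  verifies the algebraic cancellation.

The pure exponential regime is used throughout. The constants block carries
a `linear_phase_theta` term for the late linear growth phase of the fuller
growth law, but no published quantity reproduced here activates it, so it is
stored and ignored. Gompertzian deceleration at large volumes, treatment
effects on kinetics, dormancy, and metastasis-from-metastasis seeding are
all out of scope.

### The two seeding anchors

MTS-I (the pre-surgery life of a metastasis) is measured from the PT's
passage of the 1 mm threshold at its *real-valued* doubling count
$N(1) = 3\log_2(100) = 19.93$. MTS-II (the post-surgery latency) instead
assumes the lesion was seeded at the PT's *integer* 20th doubling, so at
surgery it has $N_{pt} - 20$ doublings and needs
$N(9) - (N_{pt} - 20)$ more to surface. This pair is deliberate: it is the
unique combination that reproduces the published period tables at 2-decimal
precision (4.34 y requires 19.93; 6.56 y requires 20). Both anchors live in
`model_constants()` as documented "table-parity" values.

## The four periods and the two scenarios

For a PT of diameter $d_{PT}$ and a metastasis TVDT band $[T_{min}, T_{max}]$:

* `earliest_scenario()` — the lesion is already 1 mm at resection and grows
  at $T_{min}$: the fastest possible course.
* `latest_scenario()` — the lesion was seeded at the PT's 20th doubling and
  grows at $T_{max}$: the slowest course.

Each returns the non-visible MTS-I and MTS-II periods, the visible period
(9 mm to 40 doublings), and survival = MTS-II + visible (an identity, tested
as such). For the 15.1 mm worked case at the rapid band (10–135 d) these are
0.55–4.34, 0.26–6.56, 0.29–3.90 and 0.55–10.47 years.

`seeded_at_surgery_window()` handles the continuous seeding spread: at a
fixed TVDT, lesions seeded between the 20th doubling and resection reach
9 mm over an interval whose low end is the latest-scenario MTS-II and whose
width is the seeding spread $(N_{pt} - N(1)) \cdot T$. Its high end is
reported as $N(9)\cdot T$ — a single cell seeded at the moment of resection.

## Subtype bands

Five ER/PR/HER2/Ki-67 groups partition TVDT $[10, 270]$ days with closed
integer-day edges:

| band | surrogate subtype | rule | TVDT (d) | screening |
|------|-------------------|------|----------|-----------|
| V | triple-negative | HR−/HER2− | 10–135 | 3 mo |
| IV | HER2-positive | HR−/HER2+ | 136–165 | 5 mo |
| III | luminal B | HR+/HER2−, Ki-67 ≥ 14% | 166–195 | 6 mo |
| II | luminal B | HR+/HER2+ | 196–230 | 8 mo |
| I | luminal A | HR+/HER2−, Ki-67 < 14% | 231–270 | 12 mo |

Design choices that were genuinely open:

* **Band edges.** Only integer-day bands are ever published, so a measured
  real-valued TVDT is rounded to the nearest day before lookup; 135.4 d is
  rapid, 135.6 d is intermediate. TVDTs in (270, 310] are accepted, mapped
  to band I and flagged `out_of_band`; beyond 310 d the model refuses.
* **Band-I screening interval.** The tabulated screening times say 12
  months; the narrative recommendation says nine. Both are shipped
  (`screening_interval(band, source)`), default `"table"`.
* **Display ranges.** The tabulated mean-metastasis-TVDT rows (40–67, …,
  116–135 d) and the rapid band's "80–110–135" PT display range are stored
  as registry data for rendering only; no computed quantity uses them. They
  are *not* uniformly floor(range/2) of the band edges (one published cell
  says 116 where the halving rule gives 115), which is why they are data,
  not derivation.
* **Ki-67 below 14% with HR−/HER2−** is not covered by the published group
  definitions; it classifies as band V with a warning rather than failing.

## Diagnostic columns and chaining

A column for PT subtype $s$ stacks: the rapid window (metastases may always
grow rapidly), every band at least as fast as $s$'s own, and a "(+)"
extension at $s$'s band-edge TVDT (subtype I, already the slowest, has
none). Which bands appear per column is registry *data*
(`inst/extdata/subtype_bands.yaml`), mirroring the published column
structure rather than re-deriving it.

The rapid window's diagnosis period is its own width; each slower band
contributes its MTS-II high minus the previous band's high; the "(+)" row
contributes the seeding spread. Two chaining modes exist because the
published totals are sums of *rounded* cells:

* `"unrounded"` (default) chains full-precision values; totals agree with
  the published ones within 0.05 y (0.005 y for the telescoping subtype-I
  column, which has no "(+)" row).
* `"printed-parity"` rounds every bound half-up to 2 decimals before
  differencing, reproducing 10.64 / 13.07 / 15.49 / 18.32 / 12.87
  digit-for-digit.

The "(+)" rows' MTS-I and visible-period cells in the published table match
no constant set derivable from the model anchors; they are rendered as
`"unreconstructed"` rather than guessed.

## Surveillance plans

`build_plan()` turns a column into examination blocks: the first starts at
the rapid window's MTS-II low (before which nothing can have surfaced), each
subsequent block starts where the previous ends, and the plan is gap-free up
to the considered-healthy horizon (the column total). Within a block, exams
step by the band's interval in calendar months (month-end clamped;
`stepping = "exact-day"` uses 30.44-day steps instead); an exam always
falls on the window start and the last exam is the first at or past the
window end — conservative coverage, so adjacent blocks may overlap by less
than one interval. The "(+)" block inherits the interval of the next slower
band's block, matching the published layout. `write_ical()` exports one
all-day VEVENT per exam with a fixed DTSTAMP so output is byte-reproducible.

## The synthetic generator

`synth_generate()` emulates the two-examination measurement process: band
drawn uniformly, TVDT uniform within the band, first diameter uniform on
5–15 mm, gap uniform on 60–365 days, and the second diameter is the
exponential prediction times lognormal noise (σ = 0.05 on the log scale, the
conventional multiplicative error model for caliper/ultrasound sizing).
Receptor status is drawn consistent with the band.

What passing tests show — and what they do not. Noiseless records recover
the drawn TVDT to machine precision, confirming the estimator inverts the
growth law. With σ = 0.05, recovery is structurally hard: a 60-day gap at
TVDT 270 d carries only ~0.07 doublings of signal, so 5% diameter noise is a
~100% TVDT error, and the 30-day-wide bands cannot absorb it. Measured at
the default conditions (500 records, fixed seed): 466 records estimable
(noise can push the estimate outside the model range or below growth), 229
re-classified into the drawn band, median relative TVDT error 0.101. These
are frozen as regression values. Real data add biases the generator does not
model — inter-observer and inter-modality differences, non-exponential
growth, measurement truncation — so band recovery in practice depends on
exam spacing far more than on the classifier.

## Numerical choices

* Year length 365.25 days (indistinguishable from 365 at the printed
  2-decimal precision; one value was picked and documented).
* Presentation rounding is half away from zero (`round_half_up()`), with an
  epsilon guard so values stored a hair below a half-cent boundary (1.945
  as 1.94499…) still round up; all chaining and summing happens on
  unrounded values unless printed-parity mode is requested.
* Validation problem sizes: the day-stepped simulation oracle cross-checks
  closed-form threshold crossings within one day on 1,000 random
  (d_PT, TVDT) pairs; the whole-history identity is checked on 100 random
  PT sizes; estimator inversion on 50 random trajectories at <1e-9 relative
  error.
* Degenerate inputs are typed conditions: non-growing pairs are
  `bcmets_estimation_error`, TVDTs outside [10, 310] are
  `bcmets_out_of_model`, kinetic/receptor band disagreement is a warning (or
  `bcmets_band_mismatch` in strict mode — the measured kinetics drive the
  schedule, since the band-from-TVDT mapping is what the period arithmetic
  consumes).

## Limitations

T4 disease is outside the model. Treatment effects on kinetics are not
represented: all periods are natural-history times. The 9 mm detection
threshold is a single modality-independent constant. Organ-specific
metastasis biology is not modelled; multi-lesion cases are handled by
running the calculator once per lesion TVDT.

## A worked session

```{r}
col <- diagnostic_column("V", d_pt = 15.1)
col
plan <- build_plan(col, surgery_date = "2020-08-19")
plan
rec <- patient_record("example",
  tumor_measurement("2020-01-06", 8.0),
  tumor_measurement("2020-09-04", 15.1),
  receptor_status("-", "-", "-", 30))
run_prognosis(rec)
```
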