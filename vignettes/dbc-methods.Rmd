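---
title: "Dual boundary classification for acute hypotensive episodes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual boundary classification for acute hypotensive episodes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbcahe)
```

## The prediction problem

An acute hypotensive episode (AHE) is a 30-minute period in which at least
27 of the 30 minute-sampled mean arterial pressure (MAP) values are no
greater than 60 mmHg — that is, at least 90% of the window is at or below
the hypotension threshold. Untreated episodes can cause organ damage and
death, so the clinically useful task is not detection but *prediction*:
raising an alert minutes to hours before onset.

`dbcahe` casts this as supervised binary classification on extremely
simple features. Each patient contributes one number per vital: the mean
of the measurements inside an *observation window*. Three parameters in
minutes position the windows relative to a prediction anchor (the episode
onset for positive patients):

* **P** (prediction window): the lead time. Windows end at `anchor - P`;
  nothing inside `[anchor - P, anchor)` is ever used.
* **O** (observation window): `[anchor - P - O, anchor - P)` supplies
  training means.
* **T** (test window): `[anchor - P - T, anchor - P)` supplies the mean
  `z` classified at prediction time.

Mean-based features deliberately avoid any dependence on sampling
regularity: a window mean is well defined however many measurements fall
inside it, which suits ICU data with irregular and missing samples.

## The dual boundary classifier

Let `y_A` and `y_NA` be the vectors of per-patient observation-window
means for the at-risk (A) and not-at-risk (NA) classes, with means
`mu_A < mu_NA`, standard deviations `sigma_A`, `sigma_NA` and population
variances `nu_A`, `nu_NA`. For a width multiplier `kappa >= 0`, two
boundaries

```
L = mu_A + kappa * sigma_A,   U = mu_NA - kappa * sigma_NA
```

split the feature axis into an *AHE region* (`z < L`), a *non-AHE region*
(`z > U`) and an open *uncertainty region* `(L, U)`. Training chooses
`kappa*` to minimise the misfit count

```
n1 + n2 + n3 + n4
```

where `n1` counts class-A means above `U`, `n3` counts class-NA means
below `L`, and `n2`, `n4` count means of either class strictly inside the
interval. Feasibility requires `L < U`, i.e.
`kappa < kappa_max = (mu_NA - mu_A) / (sigma_A + sigma_NA)`.

At prediction time the three-rule procedure applies per vital: a test
mean in the AHE region votes A, in the non-AHE region votes NA, and in
the uncertainty region the squared deviation of `z` from *all stored
training coordinates* of each class decides. That sum has the closed form

```
d = n * ((z - mu)^2 + nu)
```

per class, so classification needs only the 7-tuple
`[n_A, n_NA, mu_A, sigma_A, mu_NA, sigma_NA, kappa*]` (plus the
variances), never the raw coordinates. The vote is NA iff `d_A > d_NA`;
exact ties go to A, the conservative choice for an alerting system. With
several vitals, majority voting decides and MAP breaks exact ties.

### How `kappa*` is searched

The misfit count is piecewise constant in `kappa`: it can only change
where one boundary crosses a training coordinate, i.e. at the breakpoints
`(x - mu_A)/sigma_A` and `(mu_NA - x)/sigma_NA` for coordinates `x`.
`fit_kappa()` therefore evaluates the objective at `kappa = 0` and at the
midpoint of every interval between consecutive breakpoints inside
`[0, kappa_max)`, which is equivalent to an arbitrarily fine grid, and
returns the global minimiser, breaking ties toward the smallest `kappa`
(a narrow uncertainty region defers borderline cases to the distance
rule). Two deliberate subtleties:

* An equally spaced scan (`method = "grid"`) is also provided, but a
  fixed grid can step over count plateaus narrower than its spacing — in
  simulation roughly 5–8% of random Gaussian class pairs have a 201-point
  grid minimum one count above the true minimum — so the breakpoint
  method is the default.
* The objective is evaluated on plateau *interiors*, not at breakpoints
  themselves: with strict inequalities the count dips at the knife-edge
  `kappa` where a boundary touches a coordinate, an artifact of measure
  zero that no boundary placement away from the data reproduces.

When `mu_A >= mu_NA` no feasible `kappa` exists. The model is then
flagged `all_uncertainty` and every test value takes the distance path;
this keeps every `[O, P, T]` setting well defined even when the windows
carry no class signal. When both standard deviations are zero any
`kappa` is feasible and `kappa_max` is capped at `1e6`; the flat
objective then yields `kappa* = 0` by the tie-break.

### Online updating

The online protocol proceeds in rounds: predict for a newly arrived
patient from its test-window mean, then reveal the label and fold the
patient's observation-window mean into its class. Counts, means and
population variances advance one coordinate at a time by the streaming
recurrences

```
mu_n = mu_{n-1} + (x - mu_{n-1}) / n
nu_n = ((n-1) nu_{n-1} + (x - mu_{n-1})(x - mu_n)) / n
```

so raw patient series are never retained, and the result equals the
single-batch statistics of all coordinates seen so far to floating-point
accuracy (the suite checks 1e-9 over random partitions into up to 10
rounds). Refitting `kappa*` does, however, need the misfit counts, which
the 7-tuple cannot reproduce; the model therefore retains the multiset of
observation-window means (one number per patient per round, not the
series) and recomputes the counts over it after every update, using the
incrementally maintained class statistics for the boundaries.

### The distance rule's class-size factor

The sum-form distance `n * ((z - mu)^2 + nu)` grows with the class size,
so under imbalance the uncertainty-region vote leans toward the *smaller*
class (typically A). This is kept as the primary rule because the closed
form is exactly the total squared deviation from all stored training
points; a count-free variant `((z - mu)^2 + nu)` is available via
`distance = "mean"`. The bias has a visible consequence worth knowing:
in a degenerate `all_uncertainty` model fitted on windows with no class
signal (for example, prediction horizons longer than the pre-episode
deterioration), every case takes the distance path and the smaller class
wins almost every vote — sensitivity 1, specificity 0 on an imbalanced
cohort. That behaviour is deliberate and documented rather than patched,
since any patch would silently change the published rule.

## Windowing, cohort rules and degenerate inputs

* Intervals are half-open `[start, end)` in 0-based minutes; AHE onset is
  the start of the earliest complete 30-minute qualifying window under a
  stride-1 scan.
* Only complete 30-minute windows can fire the detector; a window with a
  missing minute is skipped so "27 of 30" keeps its exact meaning.
* Records are truncated strictly before the first onset; cohort filters
  keep records with at least 360 minutes of MAP measurements and, for
  positive records, onset at minute 300 or later.
* Window means require at least 90% of minutes present
  (`coverage_floor = 0.9`, mirroring the 90% spirit of the episode
  definition); sparser windows are treated as absent, never imputed.
* Class-NA records have no onset; their anchor defaults to the end of the
  usable record (deterministic), with a seeded-random alternative at
  least 360 minutes into the record for simulation studies.
* Multi-round use of a single patient steps *backward* in time (the
  round-`r` window ends `(r-1)*O` minutes before the round-1 window):
  positive records hold no data after `anchor - P`, so successive
  non-overlapping windows can only extend into earlier history.
* Population variance (divisor `n`) is used throughout, matching the
  streaming recurrence; boundary membership is strict, so a test value
  exactly on a boundary goes to the distance rule.

## The synthetic cohort generator

`generate_cohort()` exists so that training, online updating and the full
`[O, P, T]` grid are testable with known ground truth. It emulates the
qualitative structure the classifier exploits, not ICU physiology:

* **Class balance** defaults to `1307/4593` (~0.285), the class ratio of
  the 4,593-record ICU cohort the method was designed around.
* **Class-NA records**: Gaussian noise (SD 6 mmHg) around a per-patient
  baseline (85 ± 4 mmHg between patients, truncated at ±3 SD); 12-hour
  records.
* **Class-A records**: the same baseline until minute 420, then a linear
  drift (0.5 mmHg/min) down to a 45 mmHg plateau whose realised values
  are capped at 58 mmHg, guaranteeing the sustained sub-60 episode; the
  detected onset lands well after minute 300, so every generated positive
  passes the 5-hour filter. Drift onset at 420 of 720 minutes leaves room
  for observation windows both inside the deterioration (short P) and
  before it (long P).
* **Fluctuators** (default 10% of records): a sinusoid (amplitude 18
  mmHg, period 60 min) centred at `60 + 0.9 * amplitude`, so troughs
  cross 60 mmHg for a few minutes per cycle without ever satisfying
  27-of-30, and window means land near the decision boundaries.
* **Auxiliary vitals** are class-uninformative noise by default, so the
  finding that adding vitals does not improve MAP-only prediction can be
  reproduced qualitatively; an `aux_shift` knob creates the opposite
  regime.

What passing tests on this generator do *not* show: robustness to
measurement artifacts, non-stationary baselines, therapy-driven
reversals, or the heavy-tailed missingness of real monitors. The
generator's deterioration is a clean ramp; real pre-episode trajectories
are noisier and the real-data performance of the method cannot be
inferred from synthetic recovery rates.

One geometric property of the generator is worth stating because it is
the opposite of naive intuition: the class gap in observation-window
means *shrinks* as the drift steepens. Windows anchor at the detected
onset, and a steeper drift reaches 27-of-30 sooner, leaving a shallower
pre-onset footprint inside the window. Separation is therefore controlled
jointly by drift rate and prediction horizon, and the test suite asserts
the monotone trend in the direction the window geometry dictates.

## Problem sizes and evaluation choices

The packaged experiments use cohorts of 200–500 synthetic patients —
large enough for stable fold-wise class statistics (each class keeps at
least two patients per fold at 5 folds) and small enough that the full
864-setting grid evaluates in about a minute on one CPU. The online
protocol defaults to an initial training fraction of 0.2 at the cohort's
own class ratio (explicit per-class counts can be supplied instead, e.g.
260:650 of 4,593 leaves 3,683 prediction patients), batch size 1, and a
seeded arrival order. Grid dispersion is reported across settings and
labelled as such; dispersion across patients or folds is a different
quantity. All randomness — generator, folds, initial split, arrival
order, random anchors — flows from user-supplied seeds, and rerunning
any entry point with the same seed reproduces results exactly.

## Known limitations

* The mixed-integer programming formulation of the boundary fit is out of
  scope; only the one-dimensional search is implemented.
* No probability calibration: votes are hard labels, and there is no
  tunable operating point between sensitivity and specificity.
* Region attribution for the breakdown uses the MAP vital's region, since
  a patient-level region is undefined under multi-vital voting.
* The per-vital models are independent; features combining vitals are not
  supported.
* Real-data ingestion is limited to the two CSV dialects; waveform-level
  preprocessing and artifact cleaning are out of scope.
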