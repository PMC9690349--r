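---
title: "Recurrence analysis of diurnal skin temperature: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recurrence analysis of diurnal skin temperature: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermorqa)
```

## The problem

Skin temperature from a wearable sensor is a fast-responding interface
between core thermoregulation and the ambient environment. Sampled every
minute over a day it forms a long, oscillatory, noisy series whose
*temporal organisation* — not its mean level — carries the physiological
signal: how persistently the system retraces previous trajectories, how
often it lingers in near-constant (laminar) states, how rich its
deterministic structure is. Recurrence quantification analysis (RQA)
measures exactly that, without assuming stationarity, linearity or any
functional form. This package implements the full chain for a paired
cross-over design: per-record eligibility filtering, RQA, paired setting
comparisons, a principal-component composite, and mixed-effects models
linking the recurrence descriptors to urinary hormones.

## The recurrence model

A series $x_1,\dots,x_N$ is delay-embedded into vectors
$X_i = (x_i, x_{i+\tau}, \dots, x_{i+(p-1)\tau})$; only complete windows
are kept, giving $N-(p-1)\tau$ embedded states. Two states recur when
their Euclidean distance is at most $r$. Defining $r$ as a *fraction* of
the mean over all $n(n-1)/2$ distinct pairwise distances makes the binary
recurrence matrix — and therefore every metric — invariant to rescaling
the temperature units, and adapts the threshold to each record's own
variability.

From the matrix we extract maximal runs of recurrent cells along
diagonals (deterministic lines: stretches where the trajectory shadows an
earlier stretch) and along columns (vertical lines: laminar dwelling),
and assemble REC, DET, LAM, ENT, DIV, TRE, Lmean, Vmean as summarised in
the README.

### Parameters and defaults

| parameter | default | units | why |
|---|---|---|---|
| embedding dimension `dim` | 2 | – | standard for slow scalar physiological records; higher dimensions sparsify recurrences on day-length series |
| delay `lag` | 1 | samples (min) | the 1-min sampling already smooths faster dynamics |
| `radius_frac` | 0.1 | fraction of mean pairwise distance | keeps REC low (~0.05–0.1) while DET stays stable; 0.01 is the conventional stress test of conclusions (`sensitivity_radius_frac`) |
| `lmin` | 2 | cells | shortest run that counts as a line |
| `border` | 2 | cells | edge cells sit on truncated diagonals/columns; ignoring a 2-cell rim removes that censoring |
| `entropy_base` | natural | – | ENT in nats; base-2 available |

### Numerical and convention choices

Several conventions are genuinely open in the RQA literature; the ones
used here are:

* **Line of identity (LOI).** The main diagonal recurs by definition and
  is excluded from the recurrence count and from diagonal lines —
  counting it would add the same constant to every record. REC's
  denominator stays $n^2$, the printed convention for this analysis
  family. In *vertical* runs the LOI cell does participate in run
  formation (`loi_vertical = TRUE`; a trajectory passing through a
  laminar episode is physically part of it) but is never counted as a
  laminar cell, so LAM remains a fraction of true recurrences and cannot
  exceed 1.
* **ENT sign.** Shannon entropy is the *negative* sum
  $-\sum p(l)\log p(l)$; a positive-sum convention would be negative for
  any non-degenerate distribution.
* **TRE.** Defined here as the least-squares slope of per-diagonal
  recurrence *density* (count divided by diagonal length $n-k$) against
  the offset $k = 1,\dots,n-1-\mathrm{border}$. Raw counts trend downward
  mechanically because diagonals shorten with $k$; density isolates
  genuine drift. Units: recurrence fraction per time step.
* **Symmetry.** Each off-diagonal diagonal run is counted with its mirror
  image; horizontal structures are identical to vertical ones by symmetry
  and are stored once.
* **Degenerate outputs.** A constant series has zero mean distance and is
  rejected. A matrix with no recurrences or no lines yields `NA` with a
  warning — never silent zeros — so downstream log transforms fail loudly
  rather than quietly absorbing `log(0)`.
* **Exact dual paths.** The dense route
  (`recurrence_plot()` → `line_distributions()` → `rqa_metrics()`) and
  the streaming compiled route inside `rqa()` agree *bit for bit*: the
  compiled mean-pairwise-distance replicates the two-pass long-double
  accumulation of R's `mean()` over `dist()`'s storage order, and all
  line statistics are integer counts. The test suite asserts exact
  equality on 200 random series.
* **Memory.** The streaming scans visit one diagonal or column at a time,
  so peak memory is $O(n)$: a 27,000-point multi-day record needs no
  recurrence matrix at all. The dense constructor is guarded at 8000
  vectors and is meant for plots and audits.

## Preprocessing

A record is *eligible* only if fewer than 80% of its values lie below
30 °C (a mostly-cold armpit sensor was detached, not measuring skin);
values below 30 °C are then dropped and the retained sequence is analysed
as contiguous, with drop positions reported for audit. Re-embedding with
time-aware lags across gaps was considered and rejected: the dropped
values are measurement failures, not missing states, and the simplest
contiguous reading keeps the recurrence structure interpretable. The gap
counts in the filter report let a user exclude heavily gapped records
instead. Subjects must be eligible in *both* settings to enter paired
analyses.

## Statistical layer

All strictly positive metrics are analysed on the natural-log scale. TRE
is signed and within rounding distance of zero, so a log transform is
undefined for it; TRE enters paired tests and models untransformed (a
signed-log option exists for sensitivity checks). Since DIV $= 1/$Lmax,
log DIV $= -\log$ Lmax: a positive setting effect on log Lmax appears as
an equal negative effect on log DIV, a useful internal consistency check.

The setting model is
`log(metric) ~ setting + age + sex + (1 | subject)`, REML, urban
reference. With one measurement per subject-setting, the general
repeated-measures covariance reduces to exactly one random-intercept
variance, which is what is fitted. The hormone model is
`log(analyte/creatinine) ~ metric + sample_type + age + (1 | subject)`
with the night sample as reference; hormone values below the limit of
detection are imputed to LOD/2 before adjustment. The metric enters
log-transformed and z-scored (per-SD effects) by default; raw-scale entry
is available (`standardize = FALSE`) because the reporting scale of such
models is a genuine ambiguity across analyses. Covariates without
variation in the supplied cohort (e.g. a single-sex subgroup) are dropped
from the fixed effects rather than producing a rank-deficient design.

Confidence intervals default to Satterthwaite $t$ critical values
(via `lmerTest`): at 14 subjects, normal-quantile (Wald) intervals are
anticonservative by construction (roughly 93% realised coverage for a
nominal 95%), while Satterthwaite intervals hold the nominal level — the
package's recovery simulations assert 94–96% coverage at 1,000
replicates. `ci = "wald"` reproduces the ±1.96·SE convention used in
many published tables. P-values are reported raw and two-sided at
α = 0.05 with no multiplicity correction, matching the exploratory
posture of this analysis family; the nine metrics are strongly
inter-correlated (hence the PC1 composite), so a Bonferroni-type
correction would be badly miscalibrated anyway.

The PCA standardises the log-scale metrics (TRE raw) and decomposes the
correlation structure; PC1's sign is oriented so its DET loading is
positive, making larger PC1 mean "more deterministic". PC1 scores enter
subsequent models untransformed (they are centred and can be negative).

## What the generator emulates — and what it does not

`simulation_config()` encodes the study conditions: 14 subjects, two
settings per subject, one day (1,440 min) per record at 1-minute
sampling. Each series is

$$T(t) = \text{baseline} + A\sin\!\big(2\pi (t-\phi)/1440\big) + \text{AR}(1)
\;+\; \text{pulses},$$

then overlaid with laminar episodes (the value held constant for an
exponentially distributed duration — a zero-order hold, which is what
vertical-line metrics respond to), and quantised to 0.01 °C (sensor
resolution). The acrophase $\phi = 840$ puts the crest near 20:00 and the
trough in the early morning, the observed diurnal shape. The two presets
differ in persistence and perturbation: the urban preset has weaker AR
persistence (0.90 vs 0.97), larger innovations (0.06 vs 0.025 °C), fewer
and shorter laminar holds, and many more, larger pulses (40/day at 0.7 °C
vs 6/day at 0.4 °C) — the "busy microenvironment" reading of urban
exposure. These defaults place simulated records in the empirically
reported regime (DET > 0.5, REC < 0.2, mountainous exceeding urban on
Lmean, Vmean, DET, LAM, ENT, with DIV reversed) without being fitted to
any published number.

Hormones follow
$\log(\text{analyte}/\text{creatinine}) = \alpha + \beta z(\text{metric})
+ b_\text{subject} + \gamma\,\text{first morning} + \varepsilon$, two
samples per subject-setting, exponentiated and multiplied by log-normal
creatinine; the generator's true parameters ride along as an attribute so
recovery studies are self-contained. Default slopes are weakly positive
for adiponectin (0.25 per SD) and near zero elsewhere.

Every draw comes from a private stream keyed by (seed, subject, setting,
channel), so adding subjects never perturbs existing ones and all output
is a pure function of configuration and seed.

What the generator does *not* emulate: multi-day records (the default is
one day to keep analyses quick; lengths up to the multi-day range are a
config field and the streaming core handles them), activity-driven
temperature excursions correlated across subjects (weather), sensor
drift, clock gaps, or hormone assay heteroscedasticity. Passing tests on
synthetic cohorts therefore demonstrates the *machinery* — correctness of
the metrics, calibration of the models, direction and recoverability of
planted effects — not the physiological claims themselves, which require
the real sensor records.

## Problem sizes in the test suite

The suite verifies oracle equivalence on 200 series of 20–200 points
(exact), model calibration on 1,000 replicate fits per model family
(94–96% coverage band), directionality on 20 replicate 14-subject
cohorts, and one study-scale record of 12,240 points through the
streaming core. These sizes were chosen to give tight Monte Carlo error
on the calibration checks while keeping a full run in a few minutes.

## Known limitations

* With `dim = 2`, records differing only by an additive offset embed into
  translated point clouds; the radius rule neutralises *scale*, not
  offset–shape interactions. Comparisons should use records of the same
  measurement type.
* Lmax (hence DIV) is an extreme-value statistic and noisy at short
  series lengths; treat DIV contrasts at day-length records with care.
* The eligibility filter concatenates retained values across dropped
  segments; records with many large gaps acquire spurious adjacency at
  the seams. The filter report's `n_gaps` is the audit hook.
* Satterthwaite p-values are approximate at very small cohorts; at three
  or four subjects treat model output as descriptive.
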