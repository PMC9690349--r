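# thermorqa

Recurrence quantification analysis (RQA) of diurnal wearable-sensor
skin-temperature time series, with the statistical machinery of a paired
cross-over field study comparing two exposure settings (urban vs
mountainous) and linking recurrence structure to urinary metabolic
hormones.

## Who this is for

Environmental epidemiologists and physiologists working with continuous
1-minute skin- or personal-air-temperature records from wearable sensors,
who want to move beyond daily means and regressions to the *temporal
dynamics* of thermoregulation: how often the system revisits previous
states, how predictable its trajectories are, and how often it gets stuck
in laminar (near-constant) episodes — and then to relate those dynamical
descriptors to biomarkers under a repeated-measures design.

## The method

A scalar series x₁…x_N is delay-embedded (Takens reconstruction) into
p-dimensional vectors X_i = (x_i, x_{i+τ}, …, x_{i+(p−1)τ}) with p = 2 and
τ = 1 by default. Two time points recur when their embedded states are
close:

    R_ij = 1  iff  ‖X_i − X_j‖ ≤ r,      r = 0.1 × mean pairwise distance

The binary matrix R is the recurrence plot. Its line structures yield
eight descriptors (lmin = 2; cells within 2 of the matrix border ignored;
the main diagonal excluded):

| metric | definition | reading |
|---|---|---|
| REC | Σ R_ij / N² | recurrence density |
| DET | recurrences on diagonal lines / all recurrences | predictability |
| LAM | recurrences on vertical lines / all recurrences | intermittency |
| ENT | −Σ p(l) log p(l) over diagonal line lengths | complexity |
| DIV | 1 / Lmax | instability (Lyapunov-like) |
| TRE | slope of per-diagonal recurrence density vs distance from diagonal | non-stationarity |
| Lmean, Vmean | mean diagonal / vertical line length | cycle persistence |

The statistical layer log-transforms the metrics, compares settings with
paired t-tests and mixed-effects models (`metric ~ setting + age + sex +
(1 | subject)`), condenses the metrics into a PC1 composite, and models
LOD/2-imputed, creatinine-adjusted, log-transformed hormones as
`log(hormone/creatinine) ~ metric + sample_type + age + (1 | subject)`.

A synthetic cohort generator reproduces the study's structure — diurnal
sinusoid (morning trough, evening crest), AR(1) physiological noise,
zero-order-hold laminar episodes, short perturbation pulses (more frequent
in the urban preset) — so the full pipeline runs with no sensor data.

## Worked example

```r
library(thermorqa)

cfg <- simulation_config(seed = 1)       # 14 subjects, 1440-min series
s   <- simulate_series(cfg, 1, "urban")
s
#> Temperature series: 1440 points at 1-min nominal spacing (subject S01, urban)
#>   range 32.84-37.00 degC; 0 spacing irregularities

rqa(s)
#> Recurrence quantification analysis
#>   series: subject S01, urban setting
#>   1439 embedded vectors (dim = 2, lag = 1), radius = 0.1 x mean distance
#>   REC = 0.05985  DET = 0.8823  LAM = 0.9234  ENT = 1.865
#>   DIV = 0.01961  TRE = -6.836e-05  Lmean = 3.904  Vmean = 4.937  Lmax = 51

rqa(simulate_series(cfg, 1, "mountainous"), keep_matrix = "never")
#>   REC = 0.08545  DET = 0.9847  LAM = 0.9905  ENT = 3.268
#>   DIV = 0.00274  TRE = -0.0001355  Lmean = 11.72  Vmean = 17.83  Lmax = 365
```

Only ~6% of urban point pairs recur (REC), yet 88% of those recurrences
sit on diagonal lines (DET): a sparse but highly ordered dynamics. The
same subject's mountainous series is more deterministic (DET 0.98), more
laminar (LAM 0.99), richer (ENT 3.27 vs 1.87) and more persistent (Lmean
11.7 vs 3.9) — the directional pattern the paired analysis quantifies.
TRE near zero says both series are stationary over the day.

Cohort-level, from files on disk:

```r
cfg <- default_pipeline_config(input_dir = "in", output_dir = "out", seed = 1)
pipeline_simulate(cfg)   # or point input_dir at your own CSVs
pipeline_rqa(cfg)        # metrics.csv + filter_reports.csv
pipeline_analyze(cfg)    # paired tests, PCA, setting & hormone models
```

A shell entry point wrapping the same functions ships in
`inst/cli/rqa-pipeline.R` (`Rscript rqa-pipeline.R all --seed 1`).

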