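# run expr with a private RNG stream, leaving the caller's RNG state intact
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# independent stream per (subject, setting, channel): adding subjects never
# perturbs existing ones. Kept below 2^31 - 1.
.stream_seed <- function(seed, subject, setting, channel) {
  si <- match(setting, c("urban", "mountainous"))
  as.integer((as.numeric(seed) * 48271 + subject * 16807 + si * 69621 + channel * 75) %%
               2147483587)
}

.default_setting_params <- function() {
  list(
    urban = list(
      baseline = 34.6,        # degC, median skin temperature level
      amplitude = 0.9,        # degC, diurnal half-range
      acrophase = 840,        # minutes; peak at acrophase + 360 = 20:00
      ar_coef = 0.90,         # AR(1) persistence of physiological noise
      innovation_sd = 0.06,   # degC
      laminar_rate = 15,      # held-value episodes per day
      laminar_mean_duration = 6,   # minutes
      pulse_rate = 40,        # short perturbation pulses per day
      pulse_magnitude = 0.7,  # degC
      pulse_mean_duration = 4 # minutes
    ),
    mountainous = list(
      baseline = 34.8, amplitude = 1.1, acrophase = 840,
      ar_coef = 0.97, innovation_sd = 0.025,
      laminar_rate = 30, laminar_mean_duration = 12,
      pulse_rate = 6, pulse_magnitude = 0.4, pulse_mean_duration = 4
    ))
}

.default_hormone_params <- function() {
  list(
    metric = "LAM",           # driver metric (log scale, z-scored)
    log_metric = TRUE,
    alpha = c(leptin = 5.5, adiponectin = 3.0, cortisol = 4.0),
    beta = c(leptin = 0.12, adiponectin = 0.25, cortisol = 0.07),
    sample_effect = c(leptin = 0.2, adiponectin = 0.1, cortisol = 0.5),
    subject_sd = 0.5,
    resid_sd = 0.35,
    creatinine_meanlog = log(1.2), creatinine_sdlog = 0.4,
    lod = c(leptin = 1, adiponectin = 0.1, cortisol = 0.5))
}

#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: a 14-subject paired
#' cross-over cohort, one day of 1-minute skin-temperature readings per
#' subject and setting, a diurnal sinusoid (trough in the morning, peak
#' towards the night) with AR(1) physiological noise, zero-order-hold
#' laminar episodes, short perturbation pulses (more frequent and larger in
#' the urban preset, making urban series less deterministic and less
#' laminar), and urinary hormones with a linear dependence on a chosen RQA
#' metric plus subject random intercepts.
#'
#' @param n_subjects number of subjects (default 14).
#' @param series_length series length in minutes (default 1440, one day).
#' @param seed master seed; all generator output is a pure function of the
#'   configuration and this seed.
#' @param settings named list (`urban`, `mountainous`) of per-setting
#'   dynamics parameters; partial lists are merged over the defaults. See
#'   the source of `.default_setting_params` for the fields and units.
#' @param hormones hormone-model parameters, merged over defaults: driver
#'   `metric`, per-analyte intercepts `alpha`, slopes `beta`, first-morning
#'   contrasts `sample_effect`, `subject_sd`, `resid_sd`, creatinine
#'   log-normal parameters, and per-analyte `lod`.
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 14L, series_length = 1440L,
                              seed = 1L, settings = list(), hormones = list()) {
  n_subjects <- as.integer(n_subjects)
  series_length <- as.integer(series_length)
  if (is.na(n_subjects) || n_subjects < 1L) stop("n_subjects must be >= 1")
  if (is.na(series_length) || series_length < 2L) stop("series_length must be >= 2")
  base <- .default_setting_params()
  for (s in names(settings)) {
    if (!s %in% names(base)) stop(sprintf("unknown setting: %s", s))
    base[[s]] <- modifyList(base[[s]], settings[[s]])
  }
  for (s in names(base)) {
    p <- base[[s]]
    if (abs(p$ar_coef) >= 1) stop("ar_coef must be in (-1, 1)")
    if (p$innovation_sd < 0 || p$amplitude < 0) stop("SDs and amplitudes must be >= 0")
    if (p$laminar_rate < 0 || p$pulse_rate < 0) stop("rates must be >= 0")
    if (p$laminar_mean_duration <= 0 || p$pulse_mean_duration <= 0)
      stop("durations must be > 0")
  }
  h <- modifyList(.default_hormone_params(), hormones)
  if (h$subject_sd <= 0 || h$resid_sd <= 0) stop("hormone SDs must be > 0")
  structure(list(n_subjects = n_subjects, series_length = series_length,
                 seed = as.integer(seed), settings = base, hormones = h),
            class = "simulation_config")
}

#' Simulate one diurnal skin-temperature series
#'
#' Generates `T(t) = baseline + amplitude * sin(2 pi (t - acrophase) / 1440)
#' + AR(1) noise`, adds short perturbation pulses (rectangular offsets of
#' random sign and exponential duration), overlays laminar episodes in which
#' the value is held constant (zero-order hold), and quantises to 0.01 degC
#' (sensor resolution). Output is deterministic given
#' `(config seed, subject, setting)` and independent across subjects.
#'
#' @param config a [simulation_config].
#' @param subject subject index (1-based integer).
#' @param setting `"urban"` or `"mountainous"`.
#' @return a [temperature_series] with subject id `S<subject>`.
#' @export
simulate_series <- function(config, subject, setting = c("urban", "mountainous")) {
  stopifnot(inherits(config, "simulation_config"))
  setting <- match.arg(setting)
  subject <- as.integer(subject)
  p <- config$settings[[setting]]
  L <- config$series_length
  t <- seq_len(L) - 1

  circ <- p$baseline + p$amplitude * sin(2 * pi * (t - p$acrophase) / 1440)

  noise <- .with_seed(.stream_seed(config$seed, subject, setting, 1L), {
    e <- numeric(L)
    innov <- rnorm(L, sd = p$innovation_sd)
    for (i in seq_len(L)) {
      e[i] <- if (i == 1L) innov[1] else p$ar_coef * e[i - 1L] + innov[i]
    }
    e
  })
  x <- circ + noise

  # perturbation pulses: rectangular offsets
  x <- .with_seed(.stream_seed(config$seed, subject, setting, 2L), {
    n_p <- rpois(1, p$pulse_rate * L / 1440)
    if (n_p > 0) {
      starts <- sample.int(L, n_p, replace = TRUE)
      durs <- pmax(1L, as.integer(ceiling(rexp(n_p, 1 / p$pulse_mean_duration))))
      signs <- ifelse(runif(n_p) < 0.5, -1, 1)
      for (q in seq_len(n_p)) {
        idx <- starts[q]:min(L, starts[q] + durs[q] - 1L)
        x[idx] <- x[idx] + signs[q] * p$pulse_magnitude
      }
    }
    x
  })

  # laminar episodes: zero-order hold
  x <- .with_seed(.stream_seed(config$seed, subject, setting, 3L), {
    n_e <- rpois(1, p$laminar_rate * L / 1440)
    if (n_e > 0) {
      starts <- sample.int(L, n_e, replace = TRUE)
      durs <- pmax(2L, as.integer(ceiling(rexp(n_e, 1 / p$laminar_mean_duration))))
      for (q in seq_len(n_e)) {
        idx <- starts[q]:min(L, starts[q] + durs[q] - 1L)
        x[idx] <- x[starts[q]]
      }
    }
    x
  })

  temperature_series(round(x, 2), subject_id = sprintf("S%02d", subject),
                     setting = setting)
}

#' Simulate urinary hormone measurements from RQA metrics
#'
#' Two diurnal samples (night and first morning) per subject-setting, drawn
#' from `log(analyte/creatinine) = alpha + beta * metric_z + b_subject +
#' gamma * first_morning + eps`, exponentiated and multiplied by a simulated
#' creatinine concentration. Values below the per-analyte LOD are flagged.
#' The true parameters are attached as the `truth` attribute so recovery
#' studies are self-contained.
#'
#' @param config a [simulation_config].
#' @param metrics metrics table with `subject_id`, `setting` and the driver
#'   metric column.
#' @return hormone data frame in the layout of [read_hormone_table()].
#' @export
simulate_hormones <- function(config, metrics) {
  stopifnot(inherits(config, "simulation_config"))
  h <- config$hormones
  metric <- h$metric
  if (!metric %in% names(metrics))
    stop(sprintf("metrics table lacks driver metric %s", metric))
  mx <- if (h$log_metric) log(metrics[[metric]]) else metrics[[metric]]
  if (sd(mx) == 0) stop("driver metric is constant; cannot standardise")
  z <- (mx - mean(mx)) / sd(mx)

  analytes <- names(h$alpha)
  subjects <- unique(metrics$subject_id)
  b <- .with_seed(.stream_seed(config$seed, 0L, "urban", 4L),
                  stats::setNames(rnorm(length(subjects), sd = h$subject_sd),
                                  subjects))

  rows <- vector("list", nrow(metrics) * 2L)
  ri <- 0L
  for (i in seq_len(nrow(metrics))) {
    sid <- metrics$subject_id[i]
    set <- metrics$setting[i]
    sidx <- match(sid, subjects)
    draws <- .with_seed(.stream_seed(config$seed, sidx, set, 5L), {
      list(eps = matrix(rnorm(2L * length(analytes), sd = h$resid_sd),
                        nrow = 2L),
           creat = rlnorm(2L, meanlog = h$creatinine_meanlog,
                          sdlog = h$creatinine_sdlog))
    })
    for (k in 1:2) {
      stype <- c("night", "first_morning")[k]
      rec <- list(subject_id = sid, setting = set, sample_type = stype,
                  creatinine = draws$creat[k])
      for (ai in seq_along(analytes)) {
        a <- analytes[ai]
        la <- h$alpha[[a]] + h$beta[[a]] * z[i] + b[[sid]] +
          h$sample_effect[[a]] * (stype == "first_morning") +
          draws$eps[k, ai]
        val <- exp(la) * draws$creat[k]
        rec[[a]] <- val
        rec[[paste0(a, "_below_lod")]] <- val < h$lod[[a]]
        rec[[paste0(a, "_lod")]] <- h$lod[[a]]
      }
      ri <- ri + 1L
      rows[[ri]] <- as.data.frame(rec, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[seq_len(ri)])
  rownames(out) <- NULL
  attr(out, "truth") <- h
  out
}

#' Simulate cohort demographics
#'
#' Ages drawn around the study profile (mean 42, SD 9, truncated to 20-60),
#' sex with the observed female predominance, and alternating cross-over
#' group assignment. Deterministic per config seed.
#'
#' @param config a [simulation_config].
#' @return manifest data frame: `subject_id`, `group`, `age`, `sex`.
#' @export
simulate_manifest <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_subjects
  .with_seed(.stream_seed(config$seed, 0L, "urban", 6L), {
    age <- round(pmin(60, pmax(20, rnorm(n, mean = 42, sd = 9))))
    sex <- ifelse(runif(n) < 0.214, "male", "female")
    data.frame(subject_id = sprintf("S%02d", seq_len(n)),
               group = rep(c("first_urban", "first_mountainous"), length.out = n),
               age = age, sex = sex, stringsAsFactors = FALSE)
  })
}

#' Simulate a complete cohort in memory
#'
#' @param config a [simulation_config].
#' @return list with `manifest`, `series` (named list of
#'   [temperature_series], names `<subject>_<setting>`), and the config.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  manifest <- simulate_manifest(config)
  series <- list()
  for (i in seq_len(config$n_subjects)) {
    for (s in c("urban", "mountainous")) {
      series[[sprintf("S%02d_%s", i, s)]] <- simulate_series(config, i, s)
    }
  }
  list(manifest = manifest, series = series, config = config)
}

#' Write a miniature synthetic study to disk
#'
#' Emits one series CSV per subject-setting, a cohort manifest (with file
#' columns), and a hormone table, in exactly the dialects the readers
#' expect. Byte-identical across runs with the same configuration.
#'
#' @param dir output directory (created if needed).
#' @param config a [simulation_config].
#' @param rqa_args arguments passed to [rqa()] when computing the driver
#'   metric for hormone simulation.
#' @return invisibly, the manifest path.
#' @export
make_fixture_cohort <- function(dir, config = simulation_config(),
                                rqa_args = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(config)
  manifest <- cohort$manifest
  manifest$urban_file <- sprintf("%s_urban.csv", manifest$subject_id)
  manifest$mountainous_file <- sprintf("%s_mountainous.csv", manifest$subject_id)
  for (nm in names(cohort$series)) {
    write_temperature_series(cohort$series[[nm]],
                             file.path(dir, paste0(nm, ".csv")))
  }
  metrics <- do.call(rbind, lapply(cohort$series, function(s)
    as.data.frame(do.call(rqa, c(list(x = s, keep_matrix = "never"), rqa_args)))))
  rownames(metrics) <- NULL
  hormones <- simulate_hormones(config, metrics)
  write_result_table(manifest, file.path(dir, "manifest.csv"))
  write_result_table(hormones, file.path(dir, "hormones.csv"))
  invisible(file.path(dir, "manifest.csv"))
}
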