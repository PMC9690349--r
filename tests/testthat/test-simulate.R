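test_that("the generator is a pure function of configuration and seed", {
  cfg <- simulation_config(seed = 3)
  a <- simulate_series(cfg, 2, "mountainous")
  b <- simulate_series(cfg, 2, "mountainous")
  expect_identical(a$values, b$values)

  # independent streams: other subjects and the caller's RNG state do not
  # perturb a subject's series
  set.seed(999)
  invisible(simulate_series(cfg, 7, "urban"))
  c2 <- simulate_series(cfg, 2, "mountainous")
  expect_identical(a$values, c2$values)

  d <- simulate_series(simulation_config(seed = 4), 2, "mountainous")
  expect_false(identical(a$values, d$values))
})

test_that("degenerate limits collapse to a constant series", {
  cfg <- simulation_config(seed = 1, settings = list(
    urban = list(amplitude = 0, ar_coef = 0, innovation_sd = 0,
                 pulse_rate = 0, laminar_rate = 0)))
  s <- simulate_series(cfg, 1, "urban")
  expect_true(all(s$values == cfg$settings$urban$baseline))
})

test_that("configuration validation rejects impossible dynamics", {
  expect_error(simulation_config(settings = list(urban = list(ar_coef = 1.2))),
               "ar_coef")
  expect_error(simulation_config(n_subjects = 0), "n_subjects")
  expect_error(simulation_config(settings = list(beach = list())), "unknown setting")
  expect_error(simulation_config(hormones = list(subject_sd = -1)), "SDs")
})

test_that("default presets live in the diurnal recurrence regime", {
  cfg <- simulation_config(seed = 11)
  mets <- lapply(1:4, function(i) {
    u <- rqa(simulate_series(cfg, i, "urban"), keep_matrix = "never")$metrics
    m <- rqa(simulate_series(cfg, i, "mountainous"), keep_matrix = "never")$metrics
    list(u = u, m = m)
  })
  det <- unlist(lapply(mets, function(x) c(x$u$DET, x$m$DET)))
  rec <- unlist(lapply(mets, function(x) c(x$u$REC, x$m$REC)))
  expect_true(all(det > 0.5))
  expect_true(all(rec < 0.2))
  # diurnal shape: afternoon/evening crest above the morning trough
  s <- simulate_series(cfg, 1, "mountainous")
  evening <- mean(s$values[1140:1260])   # around 19:00-21:00
  morning <- mean(s$values[300:420])     # around 05:00-07:00
  expect_gt(evening, morning)
})

test_that("hormone simulation exposes its truth and honours the LOD", {
  cfg <- simulation_config(seed = 21)
  n <- 14
  metrics <- data.frame(subject_id = sprintf("S%02d", rep(1:n, 2)),
                        setting = rep(c("urban", "mountainous"), each = n),
                        LAM = exp(rnorm(2 * n, -0.1, 0.4)))
  h <- simulate_hormones(cfg, metrics)
  expect_equal(nrow(h), 4 * n)   # two samples per subject-setting
  expect_equal(attr(h, "truth")$beta[["adiponectin"]], 0.25)
  expect_true(all(h$sample_type %in% c("night", "first_morning")))

  # a null slope stays null across replicates
  cfg0 <- simulation_config(seed = 50, hormones = list(beta = c(
    leptin = 0, adiponectin = 0, cortisol = 0)))
  manifest <- data.frame(subject_id = sprintf("S%02d", 1:n),
                         age = 40, sex = "female", stringsAsFactors = FALSE)
  ests <- vapply(1:20, function(r) {
    cfgr <- simulation_config(seed = 50 + r, hormones = list(beta = c(
      leptin = 0, adiponectin = 0, cortisol = 0)))
    hr <- simulate_hormones(cfgr, metrics)
    fit_hormone_model(hr, metrics, manifest, "adiponectin", "LAM")$estimate
  }, numeric(1))
  expect_lt(abs(mean(ests)), 0.1)

  # LOD above every simulated value flags every record
  cfgL <- simulation_config(seed = 21, hormones = list(lod = c(
    leptin = 1e9, adiponectin = 1e9, cortisol = 1e9)))
  hL <- simulate_hormones(cfgL, metrics)
  expect_true(all(hL$leptin_below_lod))
  prep <- prepare_hormones(hL)
  expect_true(all(prep$leptin_adj == (1e9 / 2) / prep$creatinine))
})

test_that("fixture cohorts are complete and byte-stable", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- simulation_config(n_subjects = 3, series_length = 240, seed = 9)
  make_fixture_cohort(dir1, cfg)
  make_fixture_cohort(dir2, cfg)
  files <- sort(list.files(dir1))
  expect_length(grep("_(urban|mountainous)\\.csv$", files), 6L)
  expect_true(all(c("manifest.csv", "hormones.csv") %in% files))
  expect_identical(sort(list.files(dir2)), files)
  for (f in files) {
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)),
                     label = f)
  }
  m <- read_cohort_manifest(file.path(dir1, "manifest.csv"))
  expect_equal(nrow(m), 3L)
})
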