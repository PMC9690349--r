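test_that("log transform handles each metric as specified", {
  m <- data.frame(subject_id = "S01", setting = "urban",
                  REC = 0.06, DET = 1, LAM = 0.94, ENT = 1.5,
                  DIV = 0.005, TRE = -5e-05, Lmean = 6.7, Vmean = 7.92)
  out <- log_transform_metrics(m)
  expect_equal(out$DET, 0)
  expect_equal(out$DIV, log(0.005))
  expect_equal(out$TRE, -5e-05)           # untransformed, flagged
  expect_equal(attr(out, "tre_transform"), "none")

  m$DET <- 0
  expect_error(log_transform_metrics(m), "DET.*S01")

  m$DET <- 0.9
  sl <- log_transform_metrics(m, tre_transform = "signed_log", tre_scale = 1e-4)
  expect_equal(sl$TRE, -log(1.5))
})

test_that("paired t-test matches the closed-form statistic", {
  # hand-computable 5-pair dataset
  mnt <- c(4.2, 5.1, 3.9, 4.8, 5.5)
  urb <- c(3.6, 4.4, 4.1, 4.0, 4.9)
  metrics <- data.frame(
    subject_id = rep(sprintf("S%02d", 1:5), 2),
    setting = rep(c("mountainous", "urban"), each = 5),
    Lmean = exp(c(mnt, urb)))
  res <- paired_metric_test(metrics, "Lmean")
  d <- mnt - urb
  t_ref <- mean(d) / (sd(d) / sqrt(5))
  p_ref <- 2 * pt(-abs(t_ref), df = 4)
  expect_equal(res$t, t_ref)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, p_ref)
  expect_equal(res$mean_diff, mean(d))
  expect_true(res$conf_low < mean(d) && mean(d) < res$conf_high)

  # swapping setting labels negates t and the difference, p unchanged
  swapped <- metrics
  swapped$setting <- ifelse(metrics$setting == "urban", "mountainous", "urban")
  res2 <- paired_metric_test(swapped, "Lmean")
  expect_equal(res2$t, -res$t)
  expect_equal(res2$mean_diff, -res$mean_diff)
  expect_equal(res2$p_value, res$p_value)

  # null case by construction: symmetric noise, no setting effect
  set.seed(8)
  noise <- rnorm(10, 0, 0.05)
  nullm <- data.frame(subject_id = rep(sprintf("S%02d", 1:10), 2),
                      setting = rep(c("mountainous", "urban"), each = 10),
                      DET = exp(c(noise, rev(noise))))
  resn <- paired_metric_test(nullm, "DET")
  expect_gt(resn$p_value, 0.05)

  # degenerate: all differences identical
  const <- data.frame(subject_id = rep(sprintf("S%02d", 1:4), 2),
                      setting = rep(c("mountainous", "urban"), each = 4),
                      DET = exp(c(1:4 + 0.5, 1:4)))
  expect_error(paired_metric_test(const, "DET"), "zero variance")
})

test_that("PCA composite matches an independent eigendecomposition", {
  set.seed(12)
  n <- 40
  base <- rnorm(n)
  metrics <- data.frame(
    subject_id = sprintf("S%02d", rep(1:20, 2)),
    setting = rep(c("urban", "mountainous"), each = 20),
    DET = exp(base), LAM = exp(0.8 * base + 0.2 * rnorm(n)),
    ENT = exp(rnorm(n)), Lmean = exp(2 + 0.5 * base + 0.3 * rnorm(n)))
  cols <- c("DET", "LAM", "ENT", "Lmean")
  pca <- metrics_pca(metrics, columns = cols)
  expect_equal(sum(pca$prop_var), 1)
  expect_true(all(diff(pca$eigenvalues) <= 1e-12))
  expect_gt(pca$loadings["DET", 1], 0)

  # oracle: eigendecomposition of the correlation matrix of the logs
  X <- scale(log(as.matrix(metrics[, cols])))
  eig <- eigen(stats::cor(log(as.matrix(metrics[, cols]))))
  expect_equal(pca$eigenvalues, eig$values, tolerance = 1e-10)
  ref_scores <- X %*% eig$vectors[, 1]
  if (ref_scores[1] * pca$scores$PC1[1] < 0) ref_scores <- -ref_scores
  expect_equal(pca$scores$PC1, as.numeric(ref_scores), tolerance = 1e-10)

  # column order does not matter
  pca2 <- metrics_pca(metrics, columns = rev(cols))
  expect_equal(sort(abs(pca$loadings[, 1])), sort(abs(pca2$loadings[, 1])),
               tolerance = 1e-10)
  expect_equal(pca2$scores$PC1, pca$scores$PC1, tolerance = 1e-10)

  # two perfectly correlated columns: PC1 carries all the variance
  twin <- data.frame(a = exp(base), b = 3 * exp(base))
  p2 <- metrics_pca(twin, columns = c("a", "b"))
  expect_equal(p2$prop_var[1], 1)

  twin$b <- 1
  expect_error(metrics_pca(twin, columns = c("a", "b")), "constant column: b")
})

test_that("hormone preparation imputes, adjusts and logs", {
  h <- data.frame(subject_id = c("S01", "S01"), setting = "urban",
                  sample_type = c("night", "first_morning"),
                  leptin = c(0.4, 10), adiponectin = c(5, 6),
                  cortisol = c(40, 80), creatinine = c(1, 2),
                  leptin_below_lod = c(TRUE, FALSE),
                  leptin_lod = c(1, 1), stringsAsFactors = FALSE)
  out <- prepare_hormones(h)
  expect_equal(out$leptin_adj[1], 0.5)        # LOD/2 = 0.5, creatinine 1
  expect_equal(out$leptin_adj[2], 5)          # 10 / 2
  expect_equal(out$log_leptin_adj[2], log(5))
  # doubling creatinine halves the adjusted value: shift of -log 2
  h2 <- h
  h2$creatinine <- 2 * h$creatinine
  out2 <- prepare_hormones(h2)
  expect_equal(out2$log_adiponectin_adj, out$log_adiponectin_adj - log(2))

  h$creatinine[1] <- 0
  expect_error(prepare_hormones(h), "creatinine")
})

test_that("setting model reduces to OLS without repeated measures", {
  set.seed(33)
  n <- 16
  manifest <- data.frame(subject_id = sprintf("S%02d", 1:n),
                         age = round(runif(n, 25, 55)),
                         sex = rep(c("female", "male"), each = n / 2),
                         stringsAsFactors = FALSE)
  metrics <- data.frame(subject_id = manifest$subject_id,
                        setting = rep(c("urban", "mountainous"), n / 2),
                        Lmean = exp(rnorm(n, 2, 0.4)))
  # at this boundary the random-intercept variance sits at zero, which the
  # fitter flags; the fixed effects are still the OLS solution
  res <- suppressWarnings(fit_setting_model(metrics, manifest, "Lmean"))
  dat <- merge(metrics, manifest)
  dat$setting <- factor(dat$setting, levels = c("urban", "mountainous"))
  ols <- lm(log(Lmean) ~ setting + age + factor(sex), data = dat)
  expect_equal(res$estimate, unname(coef(ols)["settingmountainous"]),
               tolerance = 1e-6)
})

test_that("hormone model detects a planted slope and not a broken one", {
  set.seed(44)
  cfg <- simulation_config(seed = 44, hormones = list(beta = c(
    leptin = 0, adiponectin = 0.4, cortisol = 0)))
  n <- 14
  metrics <- data.frame(subject_id = sprintf("S%02d", rep(1:n, 2)),
                        setting = rep(c("urban", "mountainous"), each = n),
                        LAM = exp(rnorm(2 * n, -0.1, 0.5)))
  manifest <- data.frame(subject_id = sprintf("S%02d", 1:n),
                         age = round(runif(n, 25, 55)),
                         sex = "female", stringsAsFactors = FALSE)
  h <- simulate_hormones(cfg, metrics)
  res <- fit_hormone_model(h, metrics, manifest, "adiponectin", "LAM")
  expect_true(res$lower < 0.4 + 0.3 && res$upper > 0.4 - 0.3)
  expect_lt(res$p_value, 0.05)

  # permuting the metric across subject-settings breaks the association
  set.seed(45)
  broken <- metrics
  broken$LAM <- sample(broken$LAM)
  resb <- fit_hormone_model(h, broken, manifest, "adiponectin", "LAM")
  expect_gt(resb$p_value, 0.01)
  expect_lt(abs(resb$estimate), abs(res$estimate))
})
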