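#' @keywords internal
.rqa_metric_names <- c("REC", "DET", "LAM", "ENT", "DIV", "TRE", "Lmean", "Vmean")

# metrics analysed on the log scale; TRE (signed, near zero) and the PC1
# composite (centred) are used untransformed
.log_metric_names <- c("REC", "DET", "LAM", "ENT", "DIV", "Lmean", "Vmean")

.log_metric <- function(values, metric, subject_id = NULL, setting = NULL) {
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad)) {
    who <- if (!is.null(subject_id))
      sprintf(" (subject %s, %s)", subject_id[bad[1]], setting[bad[1]]) else ""
    stop(sprintf("non-positive or missing %s%s cannot be log-transformed",
                 metric, who))
  }
  log(values)
}

#' Log-transform RQA metric columns
#'
#' Applies the natural log to the strictly positive descriptors (REC, DET,
#' LAM, ENT, DIV, Lmean, Vmean). TRE, which is signed and typically within
#' rounding distance of zero, is passed through untransformed and the choice
#' is recorded in the `tre_transform` attribute; a signed-log option
#' (`sign(x) * log(1 + |x|/scale)`) is available for sensitivity checks.
#'
#' @param metrics data frame with RQA metric columns and (optionally)
#'   `subject_id`, `setting` for error messages.
#' @param columns columns to log-transform.
#' @param tre_transform `"none"` (default) or `"signed_log"`.
#' @param tre_scale scale for the signed log.
#' @return the data frame with transformed columns, attribute
#'   `tre_transform` set.
#' @export
log_transform_metrics <- function(metrics, columns = .log_metric_names,
                                  tre_transform = c("none", "signed_log"),
                                  tre_scale = 1e-4) {
  tre_transform <- match.arg(tre_transform)
  out <- metrics
  for (cl in intersect(columns, names(out))) {
    out[[cl]] <- .log_metric(out[[cl]], cl, out$subject_id, out$setting)
  }
  if ("TRE" %in% names(out) && tre_transform == "signed_log") {
    out$TRE <- sign(out$TRE) * log(1 + abs(out$TRE) / tre_scale)
  }
  attr(out, "tre_transform") <- tre_transform
  out
}

# pair up urban and mountainous rows per subject; drop incomplete subjects
.pair_settings <- function(metrics, metric) {
  need <- c("subject_id", "setting", metric)
  miss <- setdiff(need, names(metrics))
  if (length(miss))
    stop(sprintf("metrics table missing column(s) %s", paste(miss, collapse = ", ")))
  u <- metrics[metrics$setting == "urban", c("subject_id", metric)]
  m <- metrics[metrics$setting == "mountainous", c("subject_id", metric)]
  if (anyDuplicated(u$subject_id) || anyDuplicated(m$subject_id))
    stop("more than one row per subject-setting")
  merged <- merge(m, u, by = "subject_id", suffixes = c("_mountainous", "_urban"))
  merged[order(merged$subject_id), , drop = FALSE]
}

#' Paired comparison of an RQA metric between settings
#'
#' Classical paired t-test on per-subject differences
#' (mountainous - urban) of the (by default log-transformed) metric,
#' matching the within-subject logic of a cross-over design: each subject is
#' its own control.
#'
#' @param metrics metrics table with `subject_id`, `setting` and metric
#'   columns (one row per subject-setting).
#' @param metric metric name.
#' @param log analyse on the log scale? Default: yes except for TRE and PC1.
#' @return one-row data frame: `metric`, `n_pairs`, `mean_diff` (mountainous
#'   minus urban), `t`, `df`, `p_value`, `conf_low`, `conf_high`, `log_scale`.
#' @export
paired_metric_test <- function(metrics, metric,
                               log = !(metric %in% c("TRE", "PC1"))) {
  pairs <- .pair_settings(metrics, metric)
  if (nrow(pairs) < 2L) stop("need at least 2 complete subject pairs")
  xm <- pairs[[paste0(metric, "_mountainous")]]
  xu <- pairs[[paste0(metric, "_urban")]]
  if (log) {
    xm <- .log_metric(xm, metric, pairs$subject_id, rep("mountainous", nrow(pairs)))
    xu <- .log_metric(xu, metric, pairs$subject_id, rep("urban", nrow(pairs)))
  }
  d <- xm - xu
  if (sd(d) == 0) stop("zero variance of paired differences; t-test undefined")
  tt <- t.test(xm, xu, paired = TRUE)
  data.frame(metric = metric, n_pairs = nrow(pairs),
             mean_diff = unname(tt$estimate), t = unname(tt$statistic),
             df = unname(tt$parameter), p_value = tt$p.value,
             conf_low = tt$conf.int[1], conf_high = tt$conf.int[2],
             log_scale = log, stringsAsFactors = FALSE)
}

#' Principal-component composite of the RQA metrics
#'
#' Standardises the (log-transformed, except TRE) metric columns to zero
#' mean and unit variance and performs an eigendecomposition of their
#' correlation structure. The first component (PC1) serves as a composite
#' recurrence-structure score; its sign is oriented so that the loading on
#' DET is positive, making higher PC1 mean "more deterministic".
#'
#' @param metrics metrics table (one row per subject-setting).
#' @param columns metric columns entering the PCA.
#' @param log log-transform positive metrics first (default TRUE).
#' @return an object of class `metrics_pca`: list with `eigenvalues`,
#'   `prop_var` (explained-variance proportions, summing to 1), `loadings`,
#'   and `scores` (data frame with `subject_id`, `setting`, `PC1`, ...).
#' @export
metrics_pca <- function(metrics, columns = .rqa_metric_names, log = TRUE) {
  miss <- setdiff(columns, names(metrics))
  if (length(miss))
    stop(sprintf("metrics table missing column(s) %s", paste(miss, collapse = ", ")))
  if (nrow(metrics) < 2L) stop("need at least 2 rows for a PCA")
  dat <- metrics[, columns, drop = FALSE]
  if (log) dat <- log_transform_metrics(dat)[, columns, drop = FALSE]
  if (anyNA(dat)) stop("missing metric values; PCA requires complete rows")
  sds <- vapply(dat, sd, numeric(1))
  if (any(sds == 0))
    stop(sprintf("constant column: %s", columns[which(sds == 0)[1]]))
  pc <- prcomp(as.matrix(dat), center = TRUE, scale. = TRUE)
  eig <- pc$sdev^2
  if ("DET" %in% columns && pc$rotation["DET", 1] < 0) {
    pc$rotation[, 1] <- -pc$rotation[, 1]
    pc$x[, 1] <- -pc$x[, 1]
  }
  scores <- as.data.frame(pc$x)
  if (all(c("subject_id", "setting") %in% names(metrics))) {
    scores <- cbind(metrics[, c("subject_id", "setting")], scores)
  }
  rownames(scores) <- NULL
  structure(list(eigenvalues = eig, prop_var = eig / sum(eig),
                 loadings = pc$rotation, scores = scores,
                 columns = columns, log = log),
            class = "metrics_pca")
}

#' @export
print.metrics_pca <- function(x, ...) {
  cat(sprintf("PCA of %d RQA metrics (%d rows)\n", length(x$columns),
              nrow(x$scores)))
  cat("  explained variance: ",
      paste(sprintf("%.1f%%", 100 * x$prop_var), collapse = " "), "\n")
  invisible(x)
}

#' Prepare urinary hormone measurements for modelling
#'
#' Per analyte: values flagged below the limit of detection are imputed to
#' LOD/2, the concentration is divided by creatinine to correct for urine
#' dilution, and the natural log is taken. Adds `<analyte>_adj` and
#' `log_<analyte>_adj` columns.
#'
#' @param hormones hormone table (see [read_hormone_table()]).
#' @param analytes analyte column names.
#' @return the augmented data frame.
#' @export
prepare_hormones <- function(hormones,
                             analytes = c("leptin", "adiponectin", "cortisol")) {
  h <- hormones
  if (any(!is.finite(h$creatinine) | h$creatinine <= 0))
    stop("creatinine must be positive for creatinine adjustment")
  for (a in analytes) {
    v <- h[[a]]
    flag <- paste0(a, "_below_lod")
    lodc <- paste0(a, "_lod")
    if (flag %in% names(h) && lodc %in% names(h)) {
      idx <- which(as.logical(h[[flag]]))
      v[idx] <- h[[lodc]][idx] / 2
    }
    if (any(!is.finite(v) | v <= 0))
      stop(sprintf("non-positive %s after LOD/2 imputation", a))
    adj <- v / h$creatinine
    h[[paste0(a, "_adj")]] <- adj
    h[[paste0("log_", a, "_adj")]] <- log(adj)
  }
  h
}

# allow the degenerate one-observation-per-subject design, where the random
# intercept variance collapses to zero and the fixed effects reduce to OLS
.lmer_control <- function() {
  lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                    check.nobs.vs.nRE = "ignore",
                    check.conv.singular = lme4::.makeCC(action = "ignore",
                                                        tol = 1e-4))
}

.check_convergence <- function(fit) {
  msgs <- fit@optinfo$conv$lme4$messages
  if (!is.null(msgs) && any(grepl("failed to converge", msgs, fixed = TRUE)))
    stop(sprintf("mixed model failed to converge: %s", paste(msgs, collapse = "; ")))
  invisible(fit)
}

.extract_term <- function(fit, term, outcome, ci = c("satterthwaite", "wald"),
                          level = 0.95) {
  ci <- match.arg(ci)
  ct <- stats::coef(summary(fit))
  if (!term %in% rownames(ct))
    stop(sprintf("term %s not found in model", term))
  est <- ct[term, "Estimate"]
  se <- ct[term, "Std. Error"]
  if (ci == "satterthwaite") {
    df <- ct[term, "df"]
    p <- ct[term, "Pr(>|t|)"]
    crit <- qt(1 - (1 - level) / 2, df)
  } else {
    df <- NA_real_
    z <- est / se
    p <- 2 * stats::pnorm(-abs(z))
    crit <- qnorm(1 - (1 - level) / 2)
  }
  data.frame(outcome = outcome, term = term, estimate = est, std_error = se,
             df = df, p_value = p, lower = est - crit * se,
             upper = est + crit * se, ci_method = ci,
             stringsAsFactors = FALSE)
}

#' Mixed-effects model of an RQA metric on setting
#'
#' Fits `metric ~ setting + age + sex + (1 | subject_id)` by REML, with the
#' metric log-transformed by default (except TRE and PC1) and urban as the
#' reference setting, so the reported estimate is the adjusted
#' mountainous-vs-urban contrast on the log scale. The subject random
#' intercept absorbs the repeated (cross-over) measurements. Confidence
#' intervals use Satterthwaite t critical values by default, which hold
#' their nominal level at small cohort sizes; `ci = "wald"` gives the
#' plus/minus 1.96 SE convention.
#'
#' @param metrics metrics table (`subject_id`, `setting`, metric columns).
#' @param manifest cohort manifest with `subject_id`, `age`, `sex`.
#' @param metric metric name.
#' @param log analyse the metric on the log scale? Default: yes except TRE
#'   and PC1.
#' @param ci `"satterthwaite"` (default) or `"wald"`.
#' @return one-row data frame (the setting term): `outcome`, `term`,
#'   `estimate`, `std_error`, `df`, `p_value`, `lower`, `upper`, `ci_method`,
#'   plus `n_subjects` and `n_obs`.
#' @export
fit_setting_model <- function(metrics, manifest, metric,
                              log = !(metric %in% c("TRE", "PC1")),
                              ci = c("satterthwaite", "wald")) {
  ci <- match.arg(ci)
  dat <- merge(metrics[, c("subject_id", "setting", metric)],
               manifest[, c("subject_id", "age", "sex")], by = "subject_id")
  if (length(unique(dat$subject_id)) < 3L)
    stop("need at least 3 subjects to fit a mixed model")
  if (any(table(dat$subject_id) > 2L))
    stop("more than 2 rows per subject")
  dat$value <- if (log) .log_metric(dat[[metric]], metric, dat$subject_id,
                                    dat$setting) else dat[[metric]]
  dat$setting <- factor(dat$setting, levels = c("urban", "mountainous"))
  dat$sex <- factor(dat$sex)
  # covariates without variation (e.g. a single-sex subgroup) are dropped
  rhs <- c("setting",
           if (length(unique(dat$age)) > 1L) "age",
           if (nlevels(droplevels(dat$sex)) > 1L) "sex",
           "(1 | subject_id)")
  fit <- lmerTest::lmer(as.formula(paste("value ~", paste(rhs, collapse = " + "))),
                        data = dat, REML = TRUE, control = .lmer_control())
  .check_convergence(fit)
  out <- .extract_term(fit, "settingmountainous", outcome = metric, ci = ci)
  out$log_scale <- log
  out$n_subjects <- length(unique(dat$subject_id))
  out$n_obs <- nrow(dat)
  out
}

#' Mixed-effects model of a urinary hormone on an RQA metric
#'
#' Fits `log(analyte/creatinine) ~ metric + sample_type + age +
#' (1 | subject_id)` by REML, where the hormone outcome has been LOD/2
#' imputed, creatinine adjusted and log transformed
#' ([prepare_hormones()]), the two diurnal samples per subject-setting
#' (night reference, first-morning contrast) are handled by the sample-type
#' term, and the subject random intercept absorbs repeated measurements.
#' The metric enters log-transformed (except TRE and PC1) and, by default,
#' standardised to unit variance across the analysis set, so the estimate is
#' the expected change in the log hormone outcome per SD of the metric.
#'
#' @param hormones hormone table; prepared with [prepare_hormones()] if the
#'   log-adjusted column is absent.
#' @param metrics metrics table (`subject_id`, `setting`, metric columns).
#' @param manifest cohort manifest with `subject_id`, `age`.
#' @param analyte analyte name (e.g. `"adiponectin"`).
#' @param metric metric name (e.g. `"LAM"`).
#' @param standardize z-score the (transformed) metric? Default TRUE.
#' @param log_metric log-transform the metric first? Default: yes except TRE
#'   and PC1.
#' @param ci `"satterthwaite"` (default) or `"wald"`.
#' @return one-row data frame (the metric term), as [fit_setting_model()].
#' @export
fit_hormone_model <- function(hormones, metrics, manifest, analyte, metric,
                              standardize = TRUE,
                              log_metric = !(metric %in% c("TRE", "PC1")),
                              ci = c("satterthwaite", "wald")) {
  ci <- match.arg(ci)
  logcol <- paste0("log_", analyte, "_adj")
  if (!logcol %in% names(hormones)) hormones <- prepare_hormones(hormones, analyte)
  met <- metrics[, c("subject_id", "setting", metric)]
  met$metric_x <- if (log_metric)
    .log_metric(met[[metric]], metric, met$subject_id, met$setting) else
      met[[metric]]
  if (standardize) {
    if (sd(met$metric_x) == 0) stop(sprintf("constant metric: %s", metric))
    met$metric_x <- (met$metric_x - mean(met$metric_x)) / sd(met$metric_x)
  }
  dat <- merge(hormones[, c("subject_id", "setting", "sample_type", logcol)],
               met[, c("subject_id", "setting", "metric_x")],
               by = c("subject_id", "setting"))
  dat <- merge(dat, manifest[, c("subject_id", "age")], by = "subject_id")
  if (length(unique(dat$subject_id)) < 3L)
    stop("need at least 3 subjects to fit a mixed model")
  dat$sample_type <- factor(dat$sample_type, levels = c("night", "first_morning"))
  dat$value <- dat[[logcol]]
  rhs <- c("metric_x",
           if (nlevels(droplevels(dat$sample_type)) > 1L) "sample_type",
           if (length(unique(dat$age)) > 1L) "age",
           "(1 | subject_id)")
  fit <- lmerTest::lmer(as.formula(paste("value ~", paste(rhs, collapse = " + "))),
                        data = dat, REML = TRUE, control = .lmer_control())
  .check_convergence(fit)
  out <- .extract_term(fit, "metric_x", outcome = paste(analyte, "~", metric),
                       ci = ci)
  out$analyte <- analyte
  out$metric <- metric
  out$standardized <- standardize
  out$n_subjects <- length(unique(dat$subject_id))
  out$n_obs <- nrow(dat)
  out
}
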