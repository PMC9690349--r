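#' Recurrence quantification analysis of a time series
#'
#' The package's central estimator. Delay-embeds a scalar series
#' ([takens_embed()]), sets the recurrence radius to `radius_frac` times the
#' mean pairwise phase-space distance, and summarises the implied recurrence
#' matrix with the eight standard descriptors (see [rqa_metrics()]).
#' The recurrence structure is measured by streaming per-diagonal and
#' per-column scans in compiled code, so peak memory is linear in the series
#' length and a full multi-day 1-minute sensor record (tens of thousands of
#' points) is analysed without materialising the matrix. The result is
#' identical, cell for cell, to thresholding the dense distance matrix.
#'
#' @param x numeric vector or [temperature_series]. A series that has passed
#'   the eligibility filter ([apply_inclusion_filter()]) for sensor records.
#' @param dim embedding dimension (default 2).
#' @param lag embedding delay in samples (default 1).
#' @param radius_frac recurrence radius as a fraction of the mean pairwise
#'   distance (default 0.1; 0.01 for sensitivity analyses).
#' @param lmin minimal diagonal/vertical line length (default 2).
#' @param border cells within this distance of the matrix edge are ignored
#'   in all counts (default 2).
#' @param loi_vertical see [line_distributions()].
#' @param entropy_base log base for ENT (`"natural"` or `"base2"`).
#' @param keep_matrix `"auto"` stores the dense recurrence matrix for
#'   plotting when the embedding has at most 2000 vectors; `"always"` forces
#'   it (subject to the dense-path guard); `"never"` stores none.
#' @return an object of class `rqa`: a list with `metrics` (one-row data
#'   frame, see [rqa_metrics()]), `radius`, `mean_distance`, `n_vectors`,
#'   `lines` (the [line_distributions]), `config`, optionally `rp` (a
#'   [recurrence_plot]), and `series_info` (subject/setting for sensor
#'   records).
#' @examples
#' x <- sin(2 * pi * (0:719) / 360) + rnorm(720, sd = 0.05)
#' fit <- rqa(x)
#' fit
#' summary(fit)
#' @seealso [recurrence_plot()], [line_distributions()], [rqa_metrics()] for
#'   the explicit dense-matrix route, which yields the same numbers.
#' @export
rqa <- function(x, dim = 2L, lag = 1L, radius_frac = 0.1, lmin = 2L,
                border = 2L, loi_vertical = TRUE,
                entropy_base = c("natural", "base2"),
                keep_matrix = c("auto", "always", "never")) {
  entropy_base <- match.arg(entropy_base)
  keep_matrix <- match.arg(keep_matrix)
  series_info <- NULL
  if (inherits(x, "temperature_series")) {
    series_info <- list(subject_id = x$subject_id, setting = x$setting)
  }
  em <- takens_embed(x, dim = dim, lag = lag)
  n <- nrow(em)
  if (n < 2L) stop("need at least 2 embedded vectors")
  if (!is.numeric(radius_frac) || length(radius_frac) != 1L || radius_frac <= 0)
    stop("radius_frac must be a single positive number")
  lmin <- as.integer(lmin)
  border <- as.integer(border)
  if (lmin < 2L) stop("lmin must be >= 2")
  if (border < 0L) stop("border must be >= 0")

  md <- cpp_mean_pair_dist(em)
  if (md == 0) stop("degenerate series: zero mean distance")
  r <- radius_frac * md

  cnt <- cpp_rqa_counts(em, r, lmin, border, loi_vertical)

  metrics <- .metrics_from_counts(
    rec = cnt$rec,
    diag_len = cnt$diag_len, diag_count = cnt$diag_count,
    vert_len = cnt$vert_len, vert_count = cnt$vert_count,
    det_cells = cnt$det_cells, lam_cells = cnt$lam_cells,
    diag_rec_k = cnt$diag_rec_k, lmax = cnt$lmax,
    n = n, border = border, entropy_base = entropy_base)

  lines <- structure(
    list(diagonal = data.frame(length = cnt$diag_len, count = cnt$diag_count),
         vertical = data.frame(length = cnt$vert_len, count = cnt$vert_count),
         lmax = cnt$lmax, det_cells = cnt$det_cells, lam_cells = cnt$lam_cells,
         diag_rec_k = cnt$diag_rec_k, rec = cnt$rec,
         lmin = lmin, border = border, loi_vertical = loi_vertical),
    class = "line_distributions")

  rp <- NULL
  if (keep_matrix == "always" ||
      (keep_matrix == "auto" && n <= 2000L)) {
    rp <- recurrence_plot(em, radius_frac = radius_frac)
  }

  structure(list(metrics = metrics, radius = r, mean_distance = md,
                 n_vectors = n, lines = lines,
                 config = list(dim = dim, lag = lag, radius_frac = radius_frac,
                               lmin = lmin, border = border,
                               loi_vertical = loi_vertical,
                               entropy_base = entropy_base),
                 rp = rp, series_info = series_info,
                 call = match.call()),
            class = "rqa")
}

#' @export
print.rqa <- function(x, digits = 4, ...) {
  cat("Recurrence quantification analysis\n")
  if (!is.null(x$series_info))
    cat(sprintf("  series: subject %s, %s setting\n",
                x$series_info$subject_id, x$series_info$setting))
  cfg <- x$config
  cat(sprintf("  %d embedded vectors (dim = %d, lag = %d), radius = %.3g x mean distance\n",
              x$n_vectors, cfg$dim, cfg$lag, cfg$radius_frac))
  m <- x$metrics
  cat(sprintf("  REC = %s  DET = %s  LAM = %s  ENT = %s\n",
              format(m$REC, digits = digits), format(m$DET, digits = digits),
              format(m$LAM, digits = digits), format(m$ENT, digits = digits)))
  cat(sprintf("  DIV = %s  TRE = %s  Lmean = %s  Vmean = %s  Lmax = %d\n",
              format(m$DIV, digits = digits), format(m$TRE, digits = digits),
              format(m$Lmean, digits = digits), format(m$Vmean, digits = digits),
              m$Lmax))
  invisible(x)
}

#' @export
summary.rqa <- function(object, ...) {
  structure(list(fit = object), class = "summary.rqa")
}

#' @export
print.summary.rqa <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("\n  mean pairwise distance: %.6g; absolute radius: %.6g\n",
              f$mean_distance, f$radius))
  d <- f$lines$diagonal
  v <- f$lines$vertical
  cat(sprintf("  diagonal lines: %s runs over %d distinct lengths\n",
              format(if (nrow(d)) sum(d$count) else 0), nrow(d)))
  cat(sprintf("  vertical lines: %s runs over %d distinct lengths\n",
              format(if (nrow(v)) sum(v$count) else 0), nrow(v)))
  invisible(x)
}

#' @export
as.data.frame.rqa <- function(x, ...) {
  out <- x$metrics
  cfg <- x$config
  out$radius_frac <- cfg$radius_frac
  out$dim <- cfg$dim
  out$lag <- cfg$lag
  out$lmin <- cfg$lmin
  out$border <- cfg$border
  if (!is.null(x$series_info)) {
    out <- cbind(data.frame(subject_id = x$series_info$subject_id,
                            setting = x$series_info$setting,
                            stringsAsFactors = FALSE), out)
  }
  out
}

#' Plot method for rqa fits
#'
#' Renders the recurrence matrix as a square raster (dark cells mark
#' recurrences) when the fit kept it; see [plot.recurrence_plot()].
#'
#' @param x an `rqa` fit with a stored recurrence matrix
#'   (`keep_matrix != "never"` and a short enough series).
#' @param ... passed to [plot.recurrence_plot()].
#' @export
plot.rqa <- function(x, ...) {
  if (is.null(x$rp))
    stop("no stored recurrence matrix; refit with keep_matrix = \"always\" or plot a recurrence_plot directly")
  plot(x$rp, ...)
}
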