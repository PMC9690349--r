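# max-pool a logical matrix by an integer factor: a block is dark if any
# cell in it recurs, so sparse structures stay visible after downsampling
.pool_matrix <- function(M, factor) {
  if (factor <= 1L) return(M)
  n <- nrow(M)
  nb <- ceiling(n / factor)
  out <- matrix(FALSE, nb, nb)
  for (bi in seq_len(nb)) {
    ri <- ((bi - 1L) * factor + 1L):min(n, bi * factor)
    sub <- M[ri, , drop = FALSE]
    cs <- colSums(sub) > 0
    out[bi, ] <- vapply(seq_len(nb), function(bj) {
      ci <- ((bj - 1L) * factor + 1L):min(n, bj * factor)
      any(cs[ci])
    }, logical(1))
  }
  out
}

#' Plot a recurrence plot
#'
#' Square raster in the conventional orientation: both axes are time, dark
#' pixels mark recurrences, the main diagonal runs bottom-left to top-right.
#'
#' @param x a [recurrence_plot].
#' @param downsample integer block size for max-pooling (>= 1).
#' @param axis_unit `"minutes"` or `"index"` for axis labels.
#' @param ... further arguments passed to [graphics::image()].
#' @export
plot.recurrence_plot <- function(x, downsample = 1L,
                                 axis_unit = c("minutes", "index"), ...) {
  axis_unit <- match.arg(axis_unit)
  downsample <- as.integer(downsample)
  if (downsample < 1L) stop("downsample must be >= 1")
  M <- .pool_matrix(x$R, downsample)
  n <- nrow(M)
  ax <- (seq_len(n) - 0.5) * downsample
  lab <- if (axis_unit == "minutes") "time (min)" else "sample index"
  graphics::image(ax, ax, t(M[, , drop = FALSE]) * 1,
                  col = c("white", "black"), xlab = lab, ylab = lab,
                  useRaster = TRUE, ...)
  invisible(x)
}

#' Render a recurrence plot to a PNG file
#'
#' One pixel block per (downsampled) matrix cell; dark iff any cell in the
#' block recurs. Refuses to rasterise matrices beyond `max_pixels` on a side
#' without downsampling.
#'
#' @param rp a [recurrence_plot].
#' @param path output PNG path.
#' @param downsample max-pooling factor (>= 1).
#' @param max_pixels pixel budget per side (default 2000).
#' @param width_px image side length in device pixels.
#' @return invisibly, `path`.
#' @export
render_recurrence_plot <- function(rp, path, downsample = 1L,
                                   max_pixels = 2000L, width_px = 800L) {
  stopifnot(inherits(rp, "recurrence_plot"))
  n_out <- ceiling(rp$n_vectors / downsample)
  if (n_out > max_pixels)
    stop(sprintf("matrix is %d cells per side after downsampling; increase downsample to at least %d",
                 n_out, ceiling(rp$n_vectors / max_pixels)))
  grDevices::png(path, width = width_px, height = width_px)
  on.exit(grDevices::dev.off())
  plot(rp, downsample = downsample)
  invisible(path)
}

#' Write a recurrence plot as plain-text PBM
#'
#' Portable bitmap (P1) output: headless, diffable rendering of the binary
#' recurrence matrix, row 1 at the top.
#'
#' @inheritParams render_recurrence_plot
#' @return invisibly, `path`.
#' @export
write_pbm <- function(rp, path, downsample = 1L) {
  stopifnot(inherits(rp, "recurrence_plot"))
  M <- .pool_matrix(rp$R, as.integer(downsample))
  n <- nrow(M)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P1", sprintf("%d %d", n, n)), con)
  for (i in seq_len(n)) writeLines(paste(as.integer(M[i, ]), collapse = " "), con)
  invisible(path)
}

#' Render a temperature trace to a PNG file
#'
#' Conventional line plot of the diurnal temperature signal against time in
#' minutes.
#'
#' @param series a [temperature_series].
#' @param path output PNG path.
#' @param width_px,height_px device size in pixels.
#' @return invisibly, `path`.
#' @export
render_series <- function(series, path, width_px = 900L, height_px = 300L) {
  stopifnot(inherits(series, "temperature_series"))
  grDevices::png(path, width = width_px, height = height_px)
  on.exit(grDevices::dev.off())
  graphics::plot(series$time, series$values, type = "l",
                 xlab = "time (min)", ylab = "temperature (°C)",
                 main = if (!is.na(series$subject_id))
                   sprintf("%s (%s)", series$subject_id, series$setting) else "")
  invisible(path)
}
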