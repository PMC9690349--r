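#' Build a recurrence plot from an embedded series
#'
#' Computes all pairwise Euclidean distances between embedded vectors and
#' thresholds them at `radius_frac` times the mean of the n(n-1)/2 distinct
#' pairwise distances. Cell (i, j) of the resulting binary matrix is 1 when
#' vectors i and j lie within that radius of each other; the matrix is
#' symmetric and its main diagonal (the line of identity, LOI) is 1 by
#' construction.
#'
#' This dense constructor materialises the full matrix and is intended for
#' series up to a few thousand embedded vectors (plotting, audits, small
#' studies). [rqa()] computes the same quantities by streaming scans and
#' handles full multi-day sensor records without building the matrix.
#'
#' @param x numeric vector, [temperature_series], or an embedding matrix from
#'   [takens_embed()].
#' @param radius_frac recurrence radius as a fraction of the mean pairwise
#'   phase-space distance. Default 0.1; 0.01 is the conventional
#'   sensitivity-analysis value.
#' @param dim,lag embedding parameters, used when `x` is not already an
#'   embedding matrix.
#' @param max_size refuse to materialise matrices larger than
#'   `max_size` x `max_size` (memory guard); use [rqa()] for longer series.
#' @return an object of class `recurrence_plot`: a list with the logical
#'   matrix `R`, the absolute `radius` used, the `mean_distance` it was
#'   derived from, `radius_frac`, `n_vectors`, and the embedding parameters.
#' @examples
#' rp <- recurrence_plot(sin(2 * pi * (1:200) / 50) + rnorm(200, sd = 0.05))
#' rp
#' @export
recurrence_plot <- function(x, radius_frac = 0.1, dim = 2L, lag = 1L,
                            max_size = 8000L) {
  em <- if (is.matrix(x)) x else takens_embed(x, dim = dim, lag = lag)
  if (!is.numeric(radius_frac) || length(radius_frac) != 1L || radius_frac <= 0)
    stop("radius_frac must be a single positive number")
  n <- nrow(em)
  if (n < 2L) stop("need at least 2 embedded vectors")
  if (n > max_size)
    stop(sprintf("embedding has %d vectors, above the dense-matrix guard (%d); use rqa() for long series",
                 n, max_size))
  d <- dist(em)
  md <- mean(d)
  if (md == 0) stop("degenerate series: zero mean distance")
  r <- radius_frac * md
  R <- as.matrix(d) <= r
  diag(R) <- TRUE
  dimnames(R) <- NULL
  structure(list(R = R, radius = r, mean_distance = md,
                 radius_frac = radius_frac, n_vectors = n,
                 dim = attr(em, "embedding_dim") %||% ncol(em),
                 lag = attr(em, "embedding_lag") %||% NA_integer_),
            class = "recurrence_plot")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.recurrence_plot <- function(x, ...) {
  off <- sum(x$R) - x$n_vectors
  cat(sprintf("Recurrence plot: %d x %d, radius %.6g (%.3g x mean distance %.6g)\n",
              x$n_vectors, x$n_vectors, x$radius, x$radius_frac, x$mean_distance))
  cat(sprintf("  off-diagonal recurrent cells (untrimmed): %d (%.4f of pairs)\n",
              off, off / (x$n_vectors * (x$n_vectors - 1))))
  invisible(x)
}

#' @export
as.matrix.recurrence_plot <- function(x, ...) x$R

# border mask: TRUE for cells kept by the distance-to-border rule.
# 1-indexed: keep i, j in (border+1) .. (n-border).
.border_range <- function(n, border) {
  if (n - 2L * border < 1L) return(integer(0))
  seq.int(border + 1L, n - border)
}

#' Diagonal and vertical line-length distributions of a recurrence plot
#'
#' Extracts maximal runs of recurrent cells along super-/sub-diagonals
#' (deterministic lines) and along columns (laminar/vertical lines).
#' Runs shorter than `lmin` are discarded, cells closer than `border` to any
#' matrix edge are ignored, and the main diagonal is excluded from diagonal
#' lines. Because the matrix is symmetric, each off-diagonal run is counted
#' together with its mirror image, and horizontal structures are identical to
#' the vertical ones, which are counted once.
#'
#' @param rp a [recurrence_plot].
#' @param lmin minimal run length to count (>= 2). Default 2.
#' @param border number of cells at each matrix edge to ignore. Default 2.
#' @param loi_vertical should the main-diagonal cell participate in vertical
#'   runs (it recurs by definition, and joining it to a vertical run reflects
#'   tangential motion)? Default TRUE. It is never counted towards laminar
#'   cells, so laminarity stays a fraction of true recurrences.
#' @return an object of class `line_distributions`: data frames `diagonal`
#'   and `vertical` (columns `length`, `count`), the longest diagonal run
#'   `lmax`, counted-run cell totals `det_cells` and `lam_cells`, the
#'   per-super-diagonal recurrence counts `diag_rec_k`, the trimmed
#'   off-diagonal recurrence total `rec`, and the parameters used.
#' @export
line_distributions <- function(rp, lmin = 2L, border = 2L, loi_vertical = TRUE) {
  stopifnot(inherits(rp, "recurrence_plot"))
  lmin <- as.integer(lmin)
  border <- as.integer(border)
  if (lmin < 2L) stop("lmin must be >= 2")
  if (border < 0L) stop("border must be >= 0")
  M <- rp$R
  n <- nrow(M)
  keep <- .border_range(n, border)

  dhist <- new.env(parent = emptyenv())
  det_cells <- 0
  lmax <- 0L
  diag_rec_k <- if (n > 1L) numeric(n - 1L) else numeric(0)

  add_run <- function(env, len, times) {
    key <- as.character(len)
    env[[key]] <- (env[[key]] %||% 0) + times
  }

  # diagonal scans, upper triangle (k = offset from LOI)
  for (k in seq_len(n - 1L)) {
    i0 <- border + 1L
    i1 <- n - k - border
    if (i1 < i0) next
    idx <- seq.int(i0, i1)
    cells <- M[cbind(idx, idx + k)]
    diag_rec_k[k] <- sum(cells)
    rl <- rle(cells)
    runs <- rl$lengths[rl$values]
    runs <- runs[runs >= lmin]
    for (len in runs) {
      add_run(dhist, len, 2)      # run + mirror in the lower triangle
      det_cells <- det_cells + 2 * len
      if (len > lmax) lmax <- as.integer(len)
    }
  }

  # vertical scans, full trimmed columns
  vhist <- new.env(parent = emptyenv())
  lam_cells <- 0
  for (j in keep) {
    v <- M[keep, j]
    v[keep == j] <- loi_vertical
    rl <- rle(v)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    for (q in seq_along(rl$lengths)) {
      if (!rl$values[q] || rl$lengths[q] < lmin) next
      len <- rl$lengths[q]
      # does this run include the LOI cell of column j?
      loi_pos <- match(j, keep)
      has_loi <- loi_pos >= starts[q] && loi_pos <= ends[q]
      add_run(vhist, len, 1)
      lam_cells <- lam_cells + len - as.integer(has_loi)
    }
  }

  rec <- if (length(keep)) sum(M[keep, keep]) - length(keep) else 0

  env_to_df <- function(env) {
    keys <- as.integer(ls(env))
    if (!length(keys)) return(data.frame(length = integer(0), count = numeric(0)))
    keys <- sort(keys)
    data.frame(length = keys,
               count = vapply(as.character(keys), function(k) env[[k]], numeric(1),
                              USE.NAMES = FALSE))
  }

  structure(list(diagonal = env_to_df(dhist), vertical = env_to_df(vhist),
                 lmax = lmax, det_cells = det_cells, lam_cells = lam_cells,
                 diag_rec_k = diag_rec_k, rec = rec,
                 lmin = lmin, border = border, loi_vertical = loi_vertical),
            class = "line_distributions")
}

#' @export
print.line_distributions <- function(x, ...) {
  cat(sprintf("Line distributions (lmin = %d, border = %d): %d diagonal lengths, %d vertical lengths, Lmax = %d\n",
              x$lmin, x$border, nrow(x$diagonal), nrow(x$vertical), x$lmax))
  invisible(x)
}

# Assemble the eight scalar descriptors from recurrence counts.
# All arguments are plain counts so the dense and streaming paths share the
# same arithmetic (and therefore agree exactly).
.metrics_from_counts <- function(rec, diag_len, diag_count, vert_len, vert_count,
                                 det_cells, lam_cells, diag_rec_k, lmax, n,
                                 border, entropy_base = c("natural", "base2")) {
  entropy_base <- match.arg(entropy_base)
  logf <- if (entropy_base == "natural") log else log2

  REC <- rec / (n * n)

  if (rec == 0) {
    warning("no off-diagonal recurrences: DET and LAM are undefined and reported as NA")
    DET <- NA_real_
    LAM <- NA_real_
  } else {
    DET <- det_cells / rec
    LAM <- lam_cells / rec
  }

  if (length(diag_len) == 0L) {
    if (rec > 0)
      warning("no diagonal lines of minimal length: ENT, DIV and Lmean reported as NA")
    ENT <- NA_real_
    Lmean <- NA_real_
    DIV <- NA_real_
  } else {
    p <- diag_count / sum(diag_count)
    ENT <- -sum(p * logf(p))
    Lmean <- sum(diag_len * diag_count) / sum(diag_count)
    DIV <- 1 / lmax
  }

  Vmean <- if (length(vert_len) == 0L) NA_real_ else
    sum(vert_len * vert_count) / sum(vert_count)

  kmax <- n - 1L - border
  if (kmax < 2L) {
    TRE <- NA_real_
  } else {
    ks <- seq_len(kmax)
    dk <- diag_rec_k[ks] / (n - ks)
    mk <- mean(ks)
    md <- mean(dk)
    TRE <- sum((ks - mk) * (dk - md)) / sum((ks - mk)^2)
  }

  data.frame(REC = REC, DET = DET, LAM = LAM, ENT = ENT, DIV = DIV, TRE = TRE,
             Lmean = Lmean, Vmean = Vmean, Lmax = as.integer(lmax),
             n_vectors = as.integer(n))
}

#' Scalar RQA descriptors from a recurrence plot and its line distributions
#'
#' Computes the eight standard recurrence quantification metrics:
#' \describe{
#'   \item{REC}{recurrence rate: trimmed off-diagonal recurrent cells / n^2.}
#'   \item{DET}{determinism: fraction of recurrent cells lying on counted
#'     diagonal lines.}
#'   \item{LAM}{laminarity: fraction of recurrent cells lying on counted
#'     vertical lines.}
#'   \item{ENT}{Shannon entropy of the diagonal line-length distribution
#'     (negative sum of p log p).}
#'   \item{DIV}{divergence, 1 / Lmax.}
#'   \item{TRE}{trend: least-squares slope of per-diagonal recurrence density
#'     against distance from the main diagonal.}
#'   \item{Lmean, Vmean}{mean diagonal / vertical line lengths.}
#' }
#' Degenerate structures (no recurrences, no lines) yield `NA` with a
#' warning rather than zeros, so downstream log transforms fail loudly.
#'
#' @param rp a [recurrence_plot].
#' @param ld matching [line_distributions]; computed if omitted.
#' @inheritParams line_distributions
#' @param entropy_base log base for ENT: `"natural"` (nats, default) or
#'   `"base2"` (bits).
#' @return a one-row data frame with columns REC, DET, LAM, ENT, DIV, TRE,
#'   Lmean, Vmean, Lmax, n_vectors.
#' @export
rqa_metrics <- function(rp, ld = NULL, lmin = 2L, border = 2L,
                        loi_vertical = TRUE,
                        entropy_base = c("natural", "base2")) {
  stopifnot(inherits(rp, "recurrence_plot"))
  if (is.null(ld)) ld <- line_distributions(rp, lmin = lmin, border = border,
                                            loi_vertical = loi_vertical)
  stopifnot(inherits(ld, "line_distributions"))
  .metrics_from_counts(rec = ld$rec,
                       diag_len = ld$diagonal$length, diag_count = ld$diagonal$count,
                       vert_len = ld$vertical$length, vert_count = ld$vertical$count,
                       det_cells = ld$det_cells, lam_cells = ld$lam_cells,
                       diag_rec_k = ld$diag_rec_k, lmax = ld$lmax,
                       n = rp$n_vectors, border = ld$border,
                       entropy_base = entropy_base)
}
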