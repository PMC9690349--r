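#' Takens delay embedding of a scalar series
#'
#' Reconstructs a phase space from a scalar time series by stacking lagged
#' copies: row i of the result is (x\[i\], x\[i + lag\], ..., x\[i + (dim-1) lag\]).
#' Only complete rows are kept, so a series of length N yields
#' N - (dim - 1) * lag embedded vectors ("epochs").
#'
#' @param x numeric vector, or a [temperature_series] object.
#' @param dim embedding dimension (number of lagged copies), a positive
#'   integer. Default 2, the value used for diurnal skin-temperature records.
#' @param lag delay between copies, in samples. Default 1.
#' @return a numeric matrix with `dim` columns and `length(x) - (dim-1)*lag`
#'   rows, with attributes `dim` and `lag`.
#' @examples
#' takens_embed(c(10, 11, 21, 32, 41, 35, 40, 19), dim = 3)
#' @export
takens_embed <- function(x, dim = 2L, lag = 1L) {
  if (inherits(x, "temperature_series")) x <- x$values
  x <- as.numeric(x)
  dim <- as.integer(dim)
  lag <- as.integer(lag)
  if (is.na(dim) || dim < 1L) stop("embedding dimension must be a positive integer")
  if (is.na(lag) || lag < 1L) stop("lag must be a positive integer")
  n <- length(x)
  min_n <- (dim - 1L) * lag + 1L
  if (n < min_n) {
    stop(sprintf("series too short for embedding: length %d, need at least %d for dim = %d, lag = %d",
                 n, min_n, dim, lag))
  }
  if (anyNA(x) || any(!is.finite(x))) stop("series contains missing or non-finite values")
  nv <- n - (dim - 1L) * lag
  em <- matrix(NA_real_, nrow = nv, ncol = dim)
  for (d in seq_len(dim)) {
    em[, d] <- x[seq.int(1L + (d - 1L) * lag, length.out = nv)]
  }
  attr(em, "embedding_dim") <- dim
  attr(em, "embedding_lag") <- lag
  em
}
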