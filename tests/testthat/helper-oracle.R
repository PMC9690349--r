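# Naive reference implementation of the recurrence analysis, written
# directly from the definitions with explicit loops over the full matrix.
# Kept deliberately independent of the package internals: it builds the
# dense distance matrix, masks the border cell by cell, and walks every
# diagonal and column one element at a time.

oracle_embed <- function(x, dim = 2, lag = 1) {
  nv <- length(x) - (dim - 1) * lag
  out <- matrix(0, nv, dim)
  for (i in seq_len(nv)) {
    for (d in seq_len(dim)) out[i, d] <- x[i + (d - 1) * lag]
  }
  out
}

oracle_rqa <- function(x, dim = 2, lag = 1, radius_frac = 0.1, lmin = 2,
                       border = 2, loi_vertical = TRUE,
                       entropy_base = "natural") {
  em <- oracle_embed(x, dim, lag)
  n <- nrow(em)
  md <- mean(dist(em))
  r <- radius_frac * md
  D <- as.matrix(dist(em))
  M <- D <= r
  diag(M) <- TRUE

  valid <- function(i, j) min(i - 1, j - 1, n - i, n - j) >= border

  # trimmed off-LOI recurrence count
  rec <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && valid(i, j) && M[i, j]) rec <- rec + 1
  }

  # diagonal runs, upper triangle, doubled for the mirror image
  dhist <- integer(0)
  det_cells <- 0
  lmax <- 0
  diag_rec_k <- numeric(max(n - 1, 0))
  for (k in seq_len(n - 1)) {
    run <- 0
    cells <- 0
    for (i in seq_len(n - k)) {
      j <- i + k
      hit <- valid(i, j) && M[i, j]
      if (hit) {
        cells <- cells + 1
        run <- run + 1
      }
      if ((!hit || i == n - k) && run > 0) {
        if (run >= lmin) {
          dhist[as.character(run)] <- (if (is.na(dhist[as.character(run)])) 0
                                       else dhist[as.character(run)]) + 2
          det_cells <- det_cells + 2 * run
          if (run > lmax) lmax <- run
        }
        run <- 0
      }
    }
    diag_rec_k[k] <- cells
  }

  # vertical runs over trimmed columns; LOI cell joins runs but never
  # counts as a laminar cell
  vhist <- integer(0)
  lam_cells <- 0
  for (j in seq_len(n)) {
    if (min(j - 1, n - j) < border) next
    run <- 0
    run_rows <- integer(0)
    for (i in seq_len(n)) {
      if (min(i - 1, n - i) < border) next
      hit <- if (i == j) loi_vertical else M[i, j]
      if (hit) {
        run <- run + 1
        run_rows <- c(run_rows, i)
      }
      last_row <- n - border
      if ((!hit || i == last_row) && run > 0) {
        if (run >= lmin) {
          vhist[as.character(run)] <- (if (is.na(vhist[as.character(run)])) 0
                                       else vhist[as.character(run)]) + 1
          lam_cells <- lam_cells + run - sum(run_rows == j)
        }
        run <- 0
        run_rows <- integer(0)
      }
    }
  }

  logf <- if (entropy_base == "natural") log else log2
  REC <- rec / (n * n)
  DET <- if (rec == 0) NA_real_ else det_cells / rec
  LAM <- if (rec == 0) NA_real_ else lam_cells / rec
  dlens <- as.integer(names(dhist))
  ord <- order(dlens)
  dlens <- dlens[ord]
  dcnts <- as.numeric(dhist)[ord]
  if (length(dlens)) {
    p <- dcnts / sum(dcnts)
    ENT <- -sum(p * logf(p))
    Lmean <- sum(dlens * dcnts) / sum(dcnts)
    DIV <- 1 / lmax
  } else {
    ENT <- NA_real_; Lmean <- NA_real_; DIV <- NA_real_
  }
  vlens <- as.integer(names(vhist))
  ordv <- order(vlens)
  vlens <- vlens[ordv]
  vcnts <- as.numeric(vhist)[ordv]
  Vmean <- if (length(vlens)) sum(vlens * vcnts) / sum(vcnts) else NA_real_
  kmax <- n - 1 - border
  if (kmax < 2) {
    TRE <- NA_real_
  } else {
    ks <- seq_len(kmax)
    dk <- diag_rec_k[ks] / (n - ks)
    mk <- mean(ks)
    mdk <- mean(dk)
    TRE <- sum((ks - mk) * (dk - mdk)) / sum((ks - mk)^2)
  }
  list(metrics = data.frame(REC = REC, DET = DET, LAM = LAM, ENT = ENT,
                            DIV = DIV, TRE = TRE, Lmean = Lmean,
                            Vmean = Vmean, Lmax = as.integer(lmax),
                            n_vectors = as.integer(n)),
       diag_hist = data.frame(length = dlens, count = dcnts),
       vert_hist = data.frame(length = vlens, count = vcnts),
       mean_distance = md, radius = r)
}

# short synthetic series with genuine line structure: slow oscillation,
# mild noise, occasional held values
gen_test_series <- function(n, seed) {
  set.seed(seed)
  x <- sin(2 * pi * seq_len(n) / (n / runif(1, 2, 6))) + rnorm(n, sd = 0.15)
  if (n > 20) {
    holds <- sample.int(n - 6, 2)
    for (h in holds) x[h:(h + 5)] <- x[h]
  }
  x
}
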