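test_that("recurrence plot construction follows the radius rule", {
  # constant series: zero mean distance is degenerate
  expect_error(recurrence_plot(rep(5, 20)), "zero mean distance")
  expect_error(rqa(rep(5, 20)), "zero mean distance")

  # two embedded points at distance d: radius 0.1 d scores no off-diagonal
  # recurrence
  rp <- recurrence_plot(c(0, 0, 1, 1), dim = 2)  # 3 vectors
  expect_true(all(diag(rp$R)))
  expect_equal(rp$radius, 0.1 * rp$mean_distance)

  # dense matrix equals an all-pairs distance scan entry by entry
  set.seed(21)
  x <- gen_test_series(50, 21)
  rp <- recurrence_plot(x)
  em <- oracle_embed(x)
  D <- as.matrix(dist(em))
  ref <- D <= 0.1 * mean(dist(em))
  diag(ref) <- TRUE
  expect_identical(unname(rp$R), unname(ref))
  expect_true(isSymmetric(rp$R * 1))
})

test_that("line extraction counts maximal runs with border trimming", {
  # hand-built plot: one off-diagonal run of length 5 appears with its mirror
  n <- 12
  M <- diag(n) == 1
  for (i in 3:7) { M[i, i + 3] <- TRUE; M[i + 3, i] <- TRUE }
  rp <- structure(list(R = M, radius = 1, mean_distance = 10,
                       radius_frac = 0.1, n_vectors = n, dim = 2, lag = 1),
                  class = "recurrence_plot")
  ld <- line_distributions(rp, lmin = 2, border = 2)
  expect_equal(ld$diagonal$length, 5L)
  expect_equal(ld$diagonal$count, 2)
  expect_equal(ld$lmax, 5L)

  # isolated recurrences (no two adjacent in any direction): no lines at all
  cb <- outer(1:12, 1:12, function(i, j) i %% 3 == 0 & j %% 3 == 0)
  diag(cb) <- TRUE
  rpc <- structure(list(R = cb | t(cb), radius = 1, mean_distance = 10,
                        radius_frac = 0.1, n_vectors = 12, dim = 2, lag = 1),
                   class = "recurrence_plot")
  ldc <- line_distributions(rpc, lmin = 2, border = 2, loi_vertical = FALSE)
  expect_equal(nrow(ldc$diagonal), 0L)
  expect_equal(ldc$lmax, 0L)

  # border rule: a run hugging the matrix edge is invisible
  nE <- 10
  ME <- diag(nE) == 1
  for (i in 1:4) { ME[i, i + 1] <- TRUE; ME[i + 1, i] <- TRUE }
  rpe <- structure(list(R = ME, radius = 1, mean_distance = 10,
                        radius_frac = 0.1, n_vectors = nE, dim = 2, lag = 1),
                   class = "recurrence_plot")
  lde0 <- line_distributions(rpe, border = 0)
  lde2 <- line_distributions(rpe, border = 2)
  expect_equal(lde0$diagonal$length, 4L)
  expect_equal(lde2$diagonal$length, 2L)  # only rows 3,4 survive the trim
})

test_that("metric formulas hold on constructed structures", {
  # all diagonal lines sharing one length drive ENT to zero
  n <- 16
  M <- diag(n) == 1
  for (s in c(3, 7)) for (i in s:(s + 2)) {
    M[i, i + 4] <- TRUE
    M[i + 4, i] <- TRUE
  }
  rp <- structure(list(R = M, radius = 1, mean_distance = 10,
                       radius_frac = 0.1, n_vectors = n, dim = 2, lag = 1),
                  class = "recurrence_plot")
  m <- rqa_metrics(rp)
  expect_equal(m$ENT, 0)
  expect_equal(m$Lmean, 3)
  # DIV is the reciprocal of the longest diagonal line
  expect_equal(m$DIV * m$Lmax, 1)
  expect_equal(m$DET, 1)  # every off-diagonal recurrence lies in a counted run

  # TRE is zero when per-diagonal density is constant by construction
  nf <- 20
  Mf <- matrix(TRUE, nf, nf)
  rpf <- structure(list(R = Mf, radius = 1, mean_distance = 10,
                        radius_frac = 0.1, n_vectors = nf, dim = 2, lag = 1),
                   class = "recurrence_plot")
  ldf <- line_distributions(rpf, border = 0)
  mf <- rqa_metrics(rpf, ldf)
  expect_equal(mf$TRE, 0, tolerance = 1e-12)
  expect_equal(mf$REC, (nf * nf - nf) / nf^2)
  expect_equal(mf$LAM, 1)  # laminar cells exactly exhaust the recurrences

  # no recurrences at all: NA with a warning, not 0/0
  nd <- 10
  Md <- diag(nd) == 1
  rpd <- structure(list(R = Md, radius = 1, mean_distance = 10,
                        radius_frac = 0.1, n_vectors = nd, dim = 2, lag = 1),
                   class = "recurrence_plot")
  expect_warning(md <- rqa_metrics(rpd, line_distributions(rpd, loi_vertical = FALSE)),
                 "no off-diagonal recurrences")
  expect_true(is.na(md$DET) && is.na(md$LAM) && is.na(md$DIV))
})

test_that("streaming and dense paths agree exactly", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(30:150, 1)
    x <- gen_test_series(n, 31 + rep)
    f <- rqa(x, keep_matrix = "never")
    rp <- recurrence_plot(x)
    ld <- line_distributions(rp)
    m <- rqa_metrics(rp, ld)
    expect_identical(unlist(f$metrics), unlist(m))
    expect_identical(f$lines$diagonal$length, ld$diagonal$length)
    expect_identical(f$lines$diagonal$count, ld$diagonal$count)
    expect_identical(as.numeric(f$lines$vertical$count),
                     as.numeric(ld$vertical$count))
  }
})

test_that("recurrence structure is symmetric and scale invariant", {
  x <- gen_test_series(80, 77)
  rp <- recurrence_plot(x)
  expect_identical(rp$R, t(rp$R))

  # transposing changes no line statistics (LAM on rows equals LAM on columns)
  rpt <- rp
  rpt$R <- t(rp$R)
  expect_identical(unlist(rqa_metrics(rp)), unlist(rqa_metrics(rpt)))

  # rescaling the series rescales the radius with the mean distance,
  # leaving the binary matrix and all metrics unchanged
  for (c in c(0.2, 3, 1000)) {
    rps <- recurrence_plot(c * x)
    expect_identical(rps$R, rp$R)
    expect_identical(unlist(rqa_metrics(rps)), unlist(rqa_metrics(rp)))
  }
})

test_that("recurrence rate is monotone in the radius fraction", {
  x <- gen_test_series(90, 55)
  fracs <- c(0.01, 0.05, 0.1, 0.2, 0.5)
  recs <- vapply(fracs, function(rf)
    suppressWarnings(rqa(x, radius_frac = rf, keep_matrix = "never")$metrics$REC),
    numeric(1))
  expect_true(all(diff(recs) >= 0))
})

test_that("periodic signals are more deterministic than white noise", {
  set.seed(99)
  per <- sin(2 * pi * (0:1439) / 360) + rnorm(1440, sd = 0.05)
  wn <- rnorm(1440)
  fp <- rqa(per, keep_matrix = "never")
  fw <- rqa(wn, keep_matrix = "never")
  expect_gt(fp$metrics$DET, 0.5)
  expect_gt(fp$metrics$DET, fp$metrics$REC)
  expect_gt(fp$metrics$DET, fw$metrics$DET)
  # matches the naive reference on the periodic series? covered by the
  # acceptance sweep at smaller n; here the pipeline must simply complete
  # deterministically
  expect_identical(unlist(fp$metrics),
                   unlist(rqa(per, keep_matrix = "never")$metrics))
})

test_that("long multi-day records run in linear memory", {
  # shortest study-scale record; the streaming core never forms the matrix
  set.seed(12240)
  x <- 34.5 + sin(2 * pi * (0:12239) / 1440) + rnorm(12240, sd = 0.05)
  f <- rqa(x, keep_matrix = "never")
  expect_equal(f$n_vectors, 12239L)
  expect_true(f$metrics$REC > 0 && f$metrics$REC < 1)
  expect_true(is.finite(f$metrics$DET))
  expect_null(f$rp)
})
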