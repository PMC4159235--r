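test_that("framewise displacement matches hand-computed values", {
  m <- matrix(0, 10, 6)
  expect_equal(framewise_displacement(motion_trace(m)), rep(0, 10))
  # single 0.1 mm x-translation step
  m1 <- m; m1[5:10, 1] <- 0.1
  fd1 <- framewise_displacement(motion_trace(m1))
  expect_equal(fd1[5], 0.1)
  expect_equal(fd1[-5], rep(0, 9))
  # single 0.002 rad rotation step -> arc length 0.002 * 50 = 0.1
  m2 <- m; m2[5:10, 5] <- 0.002
  expect_equal(framewise_displacement(motion_trace(m2))[5], 0.1)
  expect_equal(framewise_displacement(motion_trace(m2),
                                      head_radius_mm = 100)[5], 0.2)
})

test_that("FD is offset-invariant and linear in step size", {
  set.seed(3)
  m <- matrix(rnorm(60, sd = 0.05), 10, 6)
  fd <- framewise_displacement(motion_trace(m))
  expect_equal(fd[1], 0)
  expect_true(all(fd >= 0))
  shifted <- sweep(m, 2, rnorm(6), `+`)
  expect_equal(framewise_displacement(motion_trace(shifted)), fd,
               tolerance = 1e-12)
  expect_equal(framewise_displacement(motion_trace(3 * m)), 3 * fd,
               tolerance = 1e-12)
  m[2, 1] <- NA
  expect_error(framewise_displacement(motion_trace(m)), "finite")
})

test_that("exclusion applies all three criteria strictly", {
  mk <- function(trans = 0, rot_deg = 0, fd_step = 0) {
    m <- matrix(0, 20, 6)
    m[10, 1] <- trans
    m[10, 4] <- rot_deg * pi / 180
    m[, 2] <- rep(c(0, fd_step), 10)  # mean FD = fd_step * 19/20
    motion_trace(m)
  }
  rep_ok <- apply_exclusion(list(mk(0.5, 0.3, 0.1)))
  expect_true(rep_ok$included)
  expect_lt(rep_ok$mean_fd_mm, 0.30)
  expect_false(apply_exclusion(list(mk(1.6, 0.3, 0.01)))$included)
  expect_false(apply_exclusion(list(mk(0.5, 1.7, 0.01)))$included)
  expect_false(apply_exclusion(list(mk(0.5, 0.3, 0.35)))$included)
  # mean FD 0.31 excluded (strict <0.30); 1.5 exactly is excluded too
  expect_false(apply_exclusion(list(mk(1.5, 0, 0)))$included)
  rep2 <- apply_exclusion(list(a = mk(), b = mk(2)))
  expect_equal(rep2$subject, c("a", "b"))
  expect_equal(rep2$included, c(TRUE, FALSE))
})

test_that("despike winsorizes only samples beyond the robust threshold", {
  set.seed(4)
  x <- rnorm(50)
  x <- (x - median(x)) / mad(x) * 2  # everything within ~2 robust z
  x_in <- x * 0.5
  expect_identical(despike(x_in), x_in)
  y <- x_in
  y[10] <- median(x_in) + 10 * mad(x_in)
  out <- despike(y)
  expect_equal(out[-10], y[-10])
  expect_equal((out[10] - median(y)) / mad(y), 3, tolerance = 1e-12)
  y[10] <- median(x_in) - 10 * mad(x_in)
  expect_equal((despike(y)[10] - median(y)) / mad(y), -3, tolerance = 1e-12)
  expect_warning(z <- despike(rep(1, 10)), "MAD")
  expect_identical(z, rep(1, 10))
  expect_error(despike(1:3), "5")
})

test_that("CompCor components recover shared noise sources", {
  set.seed(5)
  T_n <- 60
  s <- rnorm(T_n)
  X <- outer(rnorm(12, 1, 0.2), s)  # rank-1 pool
  comp <- suppressWarnings(compcor_components(X, 5))
  expect_equal(abs(cor(comp[, 1], s - fitted(lm(s ~ seq_len(T_n))))), 1,
               tolerance = 1e-8)
  # orthonormal columns
  expect_equal(crossprod(comp), diag(ncol(comp)), tolerance = 1e-8,
               ignore_attr = TRUE)

  # two orthogonal sources in disjoint halves, equal power: the top two
  # components span the two sources
  s1 <- rnorm(T_n); s2 <- rnorm(T_n)
  s1 <- resid(lm(s1 ~ seq_len(T_n))); s1 <- s1 / sd(s1)
  s2 <- resid(lm(s2 ~ s1 + seq_len(T_n))); s2 <- s2 / sd(s2)
  X2 <- rbind(outer(rep(1, 10), s1), outer(rep(1, 10), s2))
  comp2 <- suppressWarnings(compcor_components(X2, 2))
  proj <- lm(comp2 ~ s1 + s2)
  expect_lt(max(abs(resid(proj))), 1e-8)

  w <- testthat::capture_warnings(
    c3 <- compcor_components(matrix(rnorm(3 * 30), 3), 5))
  expect_match(w, "rank|voxels", all = FALSE)
  expect_lte(ncol(c3), 3)
})

test_that("nuisance design has exactly 23 named columns with the right structure", {
  set.seed(6)
  T_n <- 40
  mot <- motion_trace(matrix(rnorm(T_n * 6, sd = 0.1), T_n, 6))
  wm <- matrix(rnorm(T_n * 5), T_n, 5)
  csf <- matrix(rnorm(T_n * 5), T_n, 5)
  X <- nuisance_design(mot, wm, csf)
  expect_equal(ncol(X), 23L)
  expect_equal(nrow(X), T_n)
  # derivative columns: first entry zero, backward differences elsewhere
  expect_equal(unname(X[1, 7:12]), rep(0, 6))
  expect_equal(unname(X[-1, 7]), diff(unclass(mot)[, 1]))
  # trend strictly monotone
  expect_true(all(diff(X[, "trend"]) > 0))
  expect_error(nuisance_design(mot, wm[, 1:4], csf))
})

test_that("band-pass keeps in-band amplitude and kills out-of-band power", {
  tr <- 3.5; T_n <- 112
  tt <- (0:(T_n - 1)) * tr
  s05 <- sin(2 * pi * 0.05 * tt)
  s13 <- sin(2 * pi * 0.13 * tt)
  trend <- matrix(seq_len(T_n), ncol = 1)
  out05 <- bandpass_regress(matrix(s05, 1), trend, tr_seconds = tr)
  out13 <- bandpass_regress(matrix(s13, 1), trend, tr_seconds = tr)
  expect_gte(sd(out05[1, ]) / sd(s05), 0.9)
  expect_lte(sd(out13[1, ]) / sd(s13), 0.1)
  # band edge above Nyquist rejected (Nyquist = 1/7 Hz here)
  expect_error(bandpass_regress(matrix(s05, 1), NULL,
                                band = c(0.009, 0.2), tr_seconds = tr),
               "Nyquist")
})

test_that("cleaned series are orthogonal to every filtered design column", {
  set.seed(7)
  tr <- 3.5; T_n <- 112
  mot <- motion_trace(matrix(cumsum(rnorm(T_n * 6, sd = 0.01)), T_n, 6))
  wm <- matrix(rnorm(T_n * 5), T_n, 5)
  csf <- matrix(rnorm(T_n * 5), T_n, 5)
  X <- nuisance_design(mot, wm, csf)
  tt <- (0:(T_n - 1)) * tr
  sig <- sin(2 * pi * 0.05 * tt)
  Y <- rbind(2 * unclass(mot)[, 1] + sig,
             matrix(rnorm(3 * T_n), 3))
  out <- bandpass_regress(Y, X, tr_seconds = tr)
  Xf <- t(fft_bandpass(t(X), c(0.009, 0.1), tr))
  dots <- abs(out %*% Xf)
  expect_lt(max(dots) / max(abs(out)) / max(abs(Xf)), 1e-8)
  # correlation with the (filtered) motion column is negligible
  expect_lt(abs(cor(out[1, ], Xf[, 1])), 0.02)
  expect_error(bandpass_regress(Y, X[-1, ], tr_seconds = tr), "row count")
})

test_that("initial-frame removal leaves T - n frames everywhere", {
  d <- small_dataset(n_subjects = 1, rng_seed = 9)
  sub <- drop_initial_frames(d$subjects[[1]], 4)
  expect_equal(ncol(sub$roi_series), 116 - 4)
  expect_equal(ncol(sub$target_series), 116 - 4)
  expect_equal(sub$roi_series, d$subjects[[1]]$roi_series[, -(1:4)])
  mot <- drop_initial_frames(d$motion[[1]], 4)
  expect_equal(nrow(mot), 116 - 4)
  expect_equal(ncol(drop_initial_frames(d$wm_series[[1]], 4)), 112)
})
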