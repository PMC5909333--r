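paper_te <- c(12, 20, 30, 45, 60, 75, 90, 105)

test_that("noiseless mono-exponential data is refit exactly", {
  y <- 1000 * exp(-paper_te / 57)
  f <- fit_monoexp(y, paper_te)
  expect_equal(f$si0, 1000, tolerance = 1e-9)
  expect_equal(f$t2_ms, 57, tolerance = 1e-9)
  expect_identical(f$flag, "ok")
})

test_that("the fit matches the two-point closed form on exact data", {
  # exact data at TE = 12 and 105 plus a consistent midpoint:
  # T2 = (105 - 12) / ln(SI1/SI2)
  for (t2_true in c(35, 57, 94, 140)) {
    te <- c(12, 60, 105)
    y <- 820 * exp(-te / t2_true)
    closed_form <- (105 - 12) / log(y[1] / y[3])
    f <- fit_monoexp(y, te)
    expect_equal(f$t2_ms, closed_form, tolerance = 1e-9)
    expect_equal(closed_form, t2_true, tolerance = 1e-12)
  }
})

test_that("degenerate inputs are flagged, never silently fitted", {
  # constant signal: no decay, T2 runs into the documented cap
  f <- fit_monoexp(rep(500, 8), paper_te)
  expect_true(f$flag != "ok")
  expect_lte(f$t2_ms, 2000)
  # all-zero signal: failure flag, not an exception
  f0 <- fit_monoexp(rep(0, 8), paper_te)
  expect_identical(f0$flag, "insufficient-signal")
  expect_error(fit_monoexp(c(1, 2), c(10, 20)), "at least 3")
  expect_error(fit_monoexp(c(1, 2, 3), c(30, 20, 10)), "increasing")
})

test_that("the nonlinear fit agrees with an independent optimiser on noisy data", {
  skip_if_not_installed("minpack.lm")
  set.seed(31)
  for (i in 1:20) {
    t2_true <- runif(1, 30, 150)
    y <- 1000 * exp(-paper_te / t2_true) + rnorm(8, 0, 30)
    y <- pmax(y, 1)
    f <- fit_monoexp(y, paper_te)
    ref <- minpack.lm::nlsLM(y ~ a * exp(-paper_te / b),
                             start = list(a = f$si0 * 1.1, b = f$t2_ms * 0.9))
    expect_equal(f$t2_ms, coef(ref)[["b"]], tolerance = 1e-4)
    expect_equal(f$si0, coef(ref)[["a"]], tolerance = 1e-4)
  }
})

test_that("the nonlinear fit never has a larger SSE than its log-linear initialiser", {
  set.seed(32)
  sse <- function(a, b, y) sum((y - a * exp(-paper_te / b))^2)
  for (i in 1:30) {
    y <- pmax(800 * exp(-paper_te / runif(1, 20, 200)) + rnorm(8, 0, 60), 0.5)
    # independent log-linear initialiser
    co <- coef(lm(log(y) ~ paper_te))
    a0 <- exp(co[[1]]); b0 <- -1 / co[[2]]
    f <- fit_monoexp(y, paper_te)
    if (f$flag == "ok" && b0 > 0)
      expect_lte(sse(f$si0, f$t2_ms, y), sse(a0, b0, y) + 1e-9)
  }
})

test_that("the fit is invariant to echo ordering when TEs stay paired", {
  set.seed(33)
  y <- 900 * exp(-paper_te / 80) + rnorm(8, 0, 20)
  perm <- sample(8)
  a <- nfquant:::fit_monoexp_engine(matrix(y, 1), paper_te)
  b <- nfquant:::fit_monoexp_engine(matrix(y[perm], 1), paper_te[perm])
  expect_equal(a$t2_ms, b$t2_ms, tolerance = 1e-9)
  expect_equal(a$si0, b$si0, tolerance = 1e-9)
})

test_that("pixel-wise mapping respects the mask and validates geometry", {
  te <- c(12, 30, 60, 105)
  vox <- array(0, dim = c(4, 4, 1, 4))
  t2s <- matrix(c(50, 80, 120, 40), 2, 2)
  for (e in seq_along(te))
    vox[1:2, 1:2, 1, e] <- 1000 * exp(-te[e] / t2s)
  ser <- image_series(vox, c(1, 1), 10, kind = "t2-multi-echo",
                      echo_times_ms = te)
  mask <- array(FALSE, dim = c(4, 4, 1)); mask[1:2, 1:2, 1] <- TRUE
  m <- compute_t2_map(ser, mask)
  expect_equal(m$t2_ms[1:2, 1:2, 1], t2s, tolerance = 1e-8)
  expect_true(all(is.na(m$t2_ms[3:4, , 1])))    # untouched outside the mask
  expect_error(compute_t2_map(ser, mask[, , 1]), "geometry")
  lge <- image_series(array(vox[, , , 1], dim = c(4, 4, 1)), c(1, 1), 10,
                      kind = "ir-lge", ti_ms = 500, post_contrast_min = 2)
  expect_error(compute_t2_map(lge, mask), "multi-echo")
})

test_that("regional statistics use sample SD over unflagged pixels only", {
  te <- c(12, 30, 60, 105)
  vox <- array(0, dim = c(2, 2, 1, 4))
  for (e in seq_along(te)) {
    vox[1, 1, 1, e] <- 1000 * exp(-te[e] / 50)
    vox[1, 2, 1, e] <- 1000 * exp(-te[e] / 70)
    # [2,1] stays all-zero: a flagged pixel that must be excluded
    vox[2, 2, 1, e] <- 1000 * exp(-te[e] / 60)
  }
  ser <- image_series(vox, c(1, 1), 10, kind = "t2-multi-echo",
                      echo_times_ms = te)
  mask <- array(TRUE, dim = c(2, 2, 1))
  m <- compute_t2_map(ser, mask)
  region <- array(c(TRUE, TRUE, TRUE, FALSE), dim = c(2, 2, 1))
  st <- region_t2(m, region)
  expect_equal(st$n, 2L)                       # the flagged pixel is dropped
  expect_equal(st$mean_ms, 60, tolerance = 1e-6)
  expect_equal(st$sd_ms, sd(c(50, 70)), tolerance = 1e-6)
  expect_equal(round(st$sd_ms, 3), 14.142)
  uniform <- array(c(TRUE, FALSE, FALSE, FALSE), dim = c(2, 2, 1))
  expect_equal(region_t2(m, uniform)$n, 1L)
  none <- array(FALSE, dim = c(2, 2, 1))
  expect_error(region_t2(m, none), "no successfully fitted")
  outside <- array(TRUE, dim = c(2, 2, 1))
  m2 <- compute_t2_map(ser, array(c(TRUE, FALSE, FALSE, FALSE), dim = c(2, 2, 1)))
  expect_error(region_t2(m2, outside), "outside")
})

test_that("regional T2 bias stays under 1% at SNR 40 and 2% at SNR 20", {
  te <- paper_te
  set.seed(34)
  for (cfg in list(list(snr = 40, tol = 1), list(snr = 20, tol = 2))) {
    for (t2_true in c(57, 94)) {
      s <- 1000 * exp(-te / t2_true)
      sigma <- s[1] / cfg$snr
      n <- 3000
      Y <- sqrt(sweep(matrix(rnorm(n * 8, 0, sigma), n, 8), 2, s, "+")^2 +
                  matrix(rnorm(n * 8, 0, sigma), n, 8)^2)
      f <- nfquant:::fit_monoexp_engine(Y, te)
      bias_pct <- 100 * abs(mean(f$t2_ms[f$flag == "ok"]) / t2_true - 1)
      expect_lt(bias_pct, cfg$tol)
    }
  }
})
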