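test_that("myocardium rasterisation matches a pixel-centre counting oracle", {
  ctr <- c(50, 50)
  cs <- contour_set(list(list(endo = circle_polygon(ctr, 20, n = 720),
                              epi = circle_polygon(ctr, 30, n = 720))))
  m <- myocardium_mask(cs, c(100, 100, 1), c(1, 1))
  # oracle: count pixel centres with 20 < r < 30 directly
  cx <- (seq_len(100) - 0.5)
  R <- sqrt(outer((cx - ctr[2])^2, (cx - ctr[1])^2, "+"))
  oracle <- sum(R > 20 & R < 30)
  expect_lte(abs(sum(m) - oracle), 1)
  # and the count sits near the analytic annulus area (rasterisation noise
  # of a few boundary pixels)
  expect_lt(abs(sum(m) - pi * (30^2 - 20^2)), 10)
})

test_that("degenerate or missing contours are rejected with the slice named", {
  ctr <- c(50, 50)
  poly <- circle_polygon(ctr, 20, n = 64)
  cs <- contour_set(list(list(endo = poly, epi = poly)), validate = FALSE)
  expect_identical(sum(myocardium_mask(cs, c(100, 100, 1), c(1, 1))), 0L)
  cs2 <- contour_set(list(list(epi = poly)), validate = FALSE)
  expect_error(myocardium_mask(cs2, c(100, 100, 1), c(1, 1)), "slice 1")
})

test_that("remote statistics enforce the 100-pixel floor and match direct summation", {
  img <- matrix(100, 20, 20)
  mask <- matrix(FALSE, 20, 20); mask[1:10, 1:10] <- TRUE
  st <- remote_stats(img, mask)
  expect_equal(st$mean, 100); expect_equal(st$sd, 0); expect_equal(st$n, 100L)
  mask99 <- mask; mask99[10, 10] <- FALSE
  expect_error(remote_stats(img, mask99), "at least 100")
  set.seed(41)
  img2 <- matrix(rnorm(400, 80, 9), 20, 20)
  st2 <- remote_stats(img2, mask)
  oracle <- direct_mean_sd(img2[mask])
  expect_equal(st2$mean, oracle$mean, tolerance = 1e-12)
  expect_equal(st2$sd, oracle$sd, tolerance = 1e-12)
})

test_that("the n-SD threshold is remote mean + k SD", {
  expect_equal(enhancement_threshold(100, 10, 5), 150)
  expect_equal(enhancement_threshold(100, 0, 5), 100)
  expect_equal(enhancement_threshold(57.3, 4.2, 5), 78.3)
  expect_error(enhancement_threshold(100, -1, 5), "sd")
  expect_error(enhancement_threshold(100, 1, 0), "k")
})

test_that("enhanced classification is strictly over-threshold", {
  set.seed(42)
  img <- matrix(runif(400, 0, 200), 20, 20)
  myo <- matrix(sample(c(TRUE, FALSE), 400, TRUE), 20, 20)
  thr <- 120
  img[3, 3] <- thr; myo[3, 3] <- TRUE       # exactly at threshold
  enh <- classify_enhanced(img, myo, thr)
  expect_false(enh[3, 3])
  # brute-force per-pixel oracle
  oracle <- matrix(FALSE, 20, 20)
  for (r in 1:20) for (c in 1:20)
    oracle[r, c] <- myo[r, c] && img[r, c] > thr
  expect_identical(enh, oracle)
  expect_identical(sum(classify_enhanced(img, myo, 1e9)), 0L)
})

test_that("NF detection returns enclosed sub-threshold islands only", {
  # enhanced annulus with a sub-threshold hole inside a myocardial disc
  n <- 40
  img <- matrix(0, n, n)
  cx <- 20.5
  R <- sqrt(outer(((1:n) - cx)^2, ((1:n) - cx)^2, "+"))
  myo <- R < 15
  img[myo] <- 50                              # sub-threshold myocardium
  ring <- R >= 5 & R < 12
  img[ring] <- 500                            # enhanced ring
  thr <- 200
  enh <- classify_enhanced(img, myo, thr)
  nf <- detect_nf(img, myo, enh, thr)
  hole <- myo & R < 5
  expect_identical(nf, hole)                  # the hole and only the hole
  # open the ring: the core becomes contiguous with remote myocardium
  img2 <- img; img2[ring & row(img) == 20] <- 50
  enh2 <- classify_enhanced(img2, myo, thr)
  nf2 <- detect_nf(img2, myo, enh2, thr)
  expect_identical(sum(nf2), 0L)
  expect_error(detect_nf(img, !myo, enh, thr), "outside the myocardium")
})

test_that("phantom segmentation recovers the true infarct and NF volumes", {
  tr <- small_truth()
  ser <- render_lge_series(tr, 2)
  seg <- segment_series(ser, tr$contours)
  q <- quantify_masks(seg, tr$pixel_spacing_mm, tr$slice_thickness_mm)
  expect_lt(abs(q$mi_volume_ml / tr$volumes$mi_ml - 1), 0.05)
  expect_lt(abs(q$nf_volume_ml / tr$volumes$nf_ml_by_time[["2"]] - 1), 0.05)
  # indirect NF measurement identity: total minus enhanced equals NF exactly
  expect_identical(sum(seg$total_mi) - sum(seg$enhanced), sum(seg$nf))
  # mask algebra invariants
  expect_false(any(seg$enhanced & seg$nf))
  expect_identical(seg$total_mi, seg$enhanced | seg$nf)
  expect_false(any(seg$remote & seg$total_mi))
})

test_that("raising the threshold multiplier never grows the enhanced mask", {
  tr <- small_truth()
  ser <- render_lge_series(tr, 2)
  prev <- NULL
  for (k in c(2, 5, 8, 12)) {
    seg <- segment_series(ser, tr$contours, k = k)
    if (!is.null(prev))
      expect_false(any(seg$enhanced & !prev))  # set inclusion
    prev <- seg$enhanced
  }
})

test_that("the manual NF contour path agrees with automatic detection at the boundary band", {
  tr <- small_truth()
  ser <- render_lge_series(tr, 2)
  auto <- segment_series(ser, tr$contours)
  manual <- segment_series(ser, tr$contours, manual_nf = TRUE)
  # mismatches are confined to a one-pixel band around the truth boundary
  truth_nf <- tr$masks$nf_by_time[["2"]]
  for (s in seq_len(dim(truth_nf)[3])) {
    m <- truth_nf[, , s]
    er <- as.matrix(EBImage::erode(m * 1, EBImage::makeBrush(3, "box"))) > 0
    di <- as.matrix(EBImage::dilate(m * 1, EBImage::makeBrush(3, "box"))) > 0
    band <- di & !er
    mism <- xor(auto$nf[, , s], manual$nf[, , s])
    expect_true(all(!mism | band))
  }
  # both paths quantify the same NF volume within the band's worth of pixels
  expect_lt(abs(sum(manual$nf) - sum(auto$nf)) / max(sum(auto$nf), 1), 0.1)
})

test_that("manual NF overlapping enhanced tissue is clipped to NF with a warning", {
  # one-slice synthetic scene with a drawn NF contour that overlaps the rim
  n <- 60
  img <- array(0, dim = c(n, n, 1))
  ctr <- c(30, 30)
  R <- sqrt(outer(((1:n) - 30.5)^2, ((1:n) - 30.5)^2, "+"))
  myo2 <- R >= 8 & R < 25
  img[, , 1][myo2] <- 10
  rim <- myo2 & R >= 12 & R < 20 & outer(rep(TRUE, n), (1:n) > 30, "&")
  img[, , 1][rim] <- 800
  core <- myo2 & R >= 14 & R < 18 & outer(rep(TRUE, n), (1:n) > 38, "&")
  img[, , 1][core] <- 20
  cs <- contour_set(list(list(
    endo = circle_polygon(ctr, 8, n = 90),
    epi = circle_polygon(ctr, 25, n = 90),
    remote = nfquant:::annular_sector_polygon(ctr, 9, 24, pi * 0.6, pi * 1.4),
    nf = circle_polygon(c(46, 30), 6, n = 45))), validate = FALSE)
  ser <- image_series(img, c(1, 1), 10, kind = "ir-lge",
                      ti_ms = 300, post_contrast_min = 15)
  expect_warning(seg <- segment_series(ser, cs, manual_nf = TRUE),
                 "assigned to NF")
  expect_false(any(seg$enhanced & seg$nf))
  expect_gt(sum(seg$nf), 0)
  expect_identical(seg$total_mi, seg$enhanced | seg$nf)
})

test_that("mask assembly rejects invariant violations by name", {
  a <- array(FALSE, dim = c(4, 4, 1))
  myo <- a; myo[2:3, 2:3, 1] <- TRUE
  enh <- a; enh[1, 1, 1] <- TRUE              # outside myocardium
  expect_error(assemble_masks(myo, a, enh, a, 0, 0, 0),
               "enhanced subset of myocardium")
  nf_bad <- a; nf_bad[2, 2, 1] <- TRUE
  enh2 <- a; enh2[2, 2, 1] <- TRUE
  expect_error(assemble_masks(myo, a, enh2, nf_bad, 0, 0, 0),
               "disjoint")
  expect_error(assemble_masks(myo, a, a, a, 0, 0, 0),
               ">= 100 pixels")
})
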