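test_that("phantom masks hit the configured volumes to within one voxel", {
  tr <- small_truth()
  sp <- tr$spec
  vox <- tr$voxel_ml
  expect_lt(abs(tr$volumes$mi_ml - sp$target_mi_volume_ml), vox + 1e-9)
  for (tp in names(sp$target_nf_volume_ml_by_time))
    expect_lt(abs(tr$volumes$nf_ml_by_time[[tp]] -
                    sp$target_nf_volume_ml_by_time[[tp]]), vox + 1e-9)
  # mask-derived volumes equal stored volumes exactly
  expect_equal(sum(tr$masks$mi) * vox, tr$volumes$mi_ml)
  expect_equal(lv_mass(sum(tr$masks$myocardium) * vox), tr$volumes$lvm_g)
})

test_that("phantom region algebra holds: infarct in myocardium, NF in infarct, blood disjoint", {
  tr <- small_truth()
  expect_false(any(tr$masks$mi & !tr$masks$myocardium))
  expect_false(any(tr$masks$blood & tr$masks$myocardium))
  expect_false(any(tr$masks$remote_roi & tr$masks$mi))
  for (nf in tr$masks$nf_by_time)
    expect_false(any(nf & !tr$masks$mi))
})

test_that("NF masks are nested and non-increasing over post-contrast time", {
  tr <- small_truth()
  nfs <- tr$masks$nf_by_time
  for (j in seq_len(length(nfs) - 1L)) {
    expect_false(any(nfs[[j + 1L]] & !nfs[[j]]))  # NF(t2) subset of NF(t1)
    expect_lte(sum(nfs[[j + 1L]]), sum(nfs[[j]]))
  }
})

test_that("a zero NF target yields an empty mask and oversized targets fail loudly", {
  tp <- c(2, 45)
  sched <- c("2" = 1.5, "45" = 0)
  sp <- small_spec(timepoints_min = tp, target_nf_volume_ml_by_time = sched)
  tr <- build_phantom(sp)
  expect_identical(sum(tr$masks$nf_by_time[["45"]]), 0L)
  expect_gt(sum(tr$masks$nf_by_time[["2"]]), 0L)

  expect_error(small_spec(target_mi_volume_ml = 70, target_lvm_g = 69.4),
               "target MI volume exceeds")
  big <- small_spec(sector_halfwidth = 0.3)
  expect_error(build_phantom(big), "target_mi_volume_ml")
})

test_that("noiseless T2 render refits every tissue class exactly", {
  tr <- small_truth()
  ser <- render_t2_series(tr, noise_sigma = 0)
  m <- compute_t2_map(ser, tr$masks$myocardium)
  regions <- list(remote = tr$masks$myocardium & !tr$masks$mi,
                  mi = tr$masks$mi & !tr$masks$nf_by_time[[1]],
                  nf = tr$masks$nf_by_time[[1]])
  for (nm in names(regions)) {
    st <- region_t2(m, regions[[nm]])
    expect_lt(abs(st$mean_ms - tr$regional_t2_ms[[nm]]), 1e-6)
    expect_lt(st$sd_ms, 1e-6)
  }
  # background carries no signal in the noiseless render (the logical
  # spatial mask recycles across the echo dimension)
  bg <- !(tr$masks$myocardium | tr$masks$blood)
  expect_true(all(ser$voxels[bg] == 0))
})

test_that("noiseless LGE renders order the classes as the contrast model dictates", {
  tr <- small_truth()
  sp <- tr$spec
  for (tp in c(2, 20, 45)) {
    ser <- render_lge_series(tr, tp, noise_sigma = 0)
    nf <- tr$masks$nf_by_time[[as.character(tp)]]
    rim <- tr$masks$mi & !nf
    remote <- tr$masks$myocardium & !tr$masks$mi
    rim_mean <- mean(ser$voxels[rim])
    expect_lt(mean(ser$voxels[remote]), 0.05 * rim_mean)
    expect_lt(mean(ser$voxels[nf]), rim_mean)     # rim brighter than NF core
    expect_gte(min(ser$voxels[rim]), mean(ser$voxels[nf]))
  }
  # EGE: while the true NF is unchanged, the rendered core equals the EGE core
  expect_identical(tr$masks$nf_by_time[["2"]], tr$masks$nf_by_time[["10"]])
})

test_that("renders are reproducible for a fixed seed and differ across seeds", {
  tr <- small_truth()
  a <- render_lge_series(tr, 2, seed = 99L)
  b <- render_lge_series(tr, 2, seed = 99L)
  c <- render_lge_series(tr, 2, seed = 100L)
  expect_identical(a$voxels, b$voxels)
  expect_false(identical(a$voxels, c$voxels))
})

test_that("phantom truth table and contours are consistent with the masks", {
  tr <- small_truth()
  tt <- truth_table(tr)
  expect_equal(tt$volume_ml[tt$region == "mi_total"], tr$volumes$mi_ml)
  nf_rows <- tt[tt$region == "nf", ]
  expect_equal(nf_rows$volume_ml[order(nf_rows$timepoint_min)],
               unname(tr$volumes$nf_ml_by_time))
  # same rasteriser: contour-derived myocardium reproduces the truth mask
  myo <- myocardium_mask(tr$contours, dim(tr$masks$myocardium),
                         tr$pixel_spacing_mm)
  expect_identical(myo, tr$masks$myocardium)
})
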