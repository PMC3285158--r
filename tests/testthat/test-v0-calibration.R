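test_that("threshold segmentation removes isolated voxels", {
  vol <- high_res_volume(array(1, c(4, 4, 4)))
  expect_warning(m <- segment_vessels(vol, 5), "outside")
  expect_equal(sum(m$mask), 0)
  expect_equal(m$n_removed, 0)

  # a single bright voxel with dim neighbors is noise
  a <- array(0, c(5, 5, 5)); a[3, 3, 3] <- 10
  m1 <- segment_vessels(high_res_volume(a), 5)
  expect_equal(sum(m1$mask), 0)
  expect_equal(m1$n_removed, 1)

  # a 3-voxel straight bright segment survives intact
  b <- array(0, c(5, 5, 5)); b[2:4, 3, 3] <- 10
  m2 <- segment_vessels(high_res_volume(b), 5)
  expect_equal(sum(m2$mask), 3)
  expect_equal(m2$n_removed, 0)
  expect_equal(which(m2$mask == 1), which(b == 10))

  # a diagonal pair touches under 26- but not 6-connectivity
  d <- array(0, c(4, 4, 4)); d[2, 2, 2] <- 10; d[3, 3, 3] <- 10
  expect_equal(sum(segment_vessels(high_res_volume(d), 5, 26)$mask), 2)
  m6 <- segment_vessels(high_res_volume(d), 5, connectivity = 6)
  expect_equal(sum(m6$mask), 0)
  expect_equal(m6$n_removed, 2)
})

test_that("vessel fractions come from exact subvoxel counting", {
  # empty mask
  lam0 <- vessel_fraction(array(0L, c(8, 8, 8)), c(2, 2, 2))
  expect_true(all(lam0 == 0))

  # one fully-vessel block, one with 16/64
  m <- array(0L, c(8, 8, 8))
  m[1:4, 1:4, 1:4] <- 1L                      # block (1,1,1) full
  m[5:8, 1:4, 5:8][1:16] <- 1L                # 16 subvoxels in block (2,1,2)
  lam <- vessel_fraction(m, c(2, 2, 2))
  expect_equal(lam[1, 1, 1], 1)
  expect_equal(lam[2, 1, 2], 0.25)
  expect_equal(lam[2, 2, 2], 0)

  # brute-force oracle on a random mask: per-block triple loop
  set.seed(11)
  r <- array(rbinom(6 * 4 * 8, 1, 0.3), c(6, 4, 8))
  lam_r <- vessel_fraction(r, c(3, 2, 2))
  f <- c(2, 2, 4)
  for (i in 1:3) for (j in 1:2) for (k in 1:2) {
    blk <- r[(i - 1) * f[1] + 1:f[1], (j - 1) * f[2] + 1:f[2],
             (k - 1) * f[3] + 1:f[3]]
    expect_identical(lam_r[i, j, k], sum(blk) / prod(f))
  }
  # exact conservation of the vessel count
  expect_identical(sum(lam_r) * prod(f), as.numeric(sum(r)))
  expect_error(vessel_fraction(r, c(4, 2, 2)), "integer multiples")
})

test_that("the mixture formula maps fractions to V0 with correct bounds", {
  lam <- array(c(0, 0.25, 1, 0.5), c(2, 2, 1))
  v0 <- compute_v0_map(lam, v_tissue = 0.02, v_blood = 1.0)
  expect_equal(v0$values[1, 1, 1], 0.02)   # no-vessel special case
  expect_equal(v0$values[2, 1, 1], 0.265)  # 0.25*1 + 0.75*0.02
  expect_equal(v0$values[1, 2, 1], 1.0)    # pure vessel
  expect_true(all(v0$values >= 0.02 & v0$values <= 1))
  expect_error(compute_v0_map(lam, v_tissue = 0.5, v_blood = 0.3),
               "v_tissue")
})

test_that("ROI extraction averages the center and in-slice edge neighbors", {
  arr <- array(0, c(5, 5, 3, 4))
  # distinct constant series on the 5 members of an interior ROI
  vals <- c(1, 2, 3, 4, 5)
  members <- rbind(c(3, 3, 2), c(2, 3, 2), c(4, 3, 2), c(3, 2, 2),
                   c(3, 4, 2))
  for (r in 1:5) arr[members[r, 1], members[r, 2], members[r, 3], ] <- vals[r]
  roi <- extract_roi_series(arr, c(3, 3, 2))
  expect_equal(nrow(roi$members), 5)
  expect_equal(roi$series$mean_bold, rep(3, 4))
  # corner center keeps only in-volume members
  roi2 <- extract_roi_series(arr, c(1, 1, 1))
  expect_equal(nrow(roi2$members), 3)
  expect_error(extract_roi_series(arr, c(9, 1, 1)), "outside")
})

test_that("volumes and V0 maps round-trip through NIfTI with sidecar", {
  ph <- make_vessel_phantom(vessel_phantom_spec(functional_dim = c(4, 4, 2),
                                                seed = 3))
  path <- tempfile(fileext = ".nii.gz")
  write_volume_nifti(ph$volume, path)
  back <- read_volume_nifti(path)
  expect_equal(back$intensities, ph$volume$intensities, tolerance = 1e-6)

  mask <- segment_vessels(ph$volume, ph$threshold)
  v0 <- compute_v0_map(vessel_fraction(mask, c(4, 4, 2)))
  vpath <- tempfile(fileext = ".nii.gz")
  write_v0_nifti(v0, vpath, mask = mask)
  meta <- jsonlite::read_json(paste0(vpath, ".json"))
  expect_equal(meta$v_tissue, 0.02)
  expect_equal(meta$n_removed, mask$n_removed)
  img <- read_volume_nifti(vpath)
  expect_equal(img$intensities, v0$values, tolerance = 1e-6)
  unlink(c(path, vpath, paste0(vpath, ".json")))
})
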