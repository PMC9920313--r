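test_that("volumes round-trip through every supported format", {
  set.seed(1)
  v <- volume3d(rand_vol(c(4, 5, 6)), spacing = c(1.2695, 1.2695, 3),
                origin = c(10, -20, 30))
  td <- withr::local_tempdir()
  for (ext in c(".nii.gz", ".nii", ".nrrd", ".mha", ".mhd")) {
    p <- file.path(td, paste0("vol", ext))
    write_volume(v, p)
    r <- read_volume(p)
    expect_equal(r$data, v$data, tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(r$spacing, c(1.2695, 1.2695, 3))
    expect_equal(r$origin, c(10, -20, 30))
    expect_identical(r$scale_tag, "hu")
  }
})

test_that("reader rejects missing files, bad extensions and non-3D images", {
  expect_error(read_volume(file.path(tempdir(), "nope.nrrd")), "no such file")
  td <- withr::local_tempdir()
  bad <- file.path(td, "x.txt")
  writeLines("not a volume", bad)
  expect_error(read_volume(bad), "unsupported extension")
  # 2D and 4D NIfTI images are not volumes
  p2 <- file.path(td, "flat.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(matrix(0, 4, 4)), p2)
  expect_error(read_volume(p2), "3D")
  p4 <- file.path(td, "hyper.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(3, 3, 3, 2))), p4)
  expect_error(read_volume(p4), "3D")
})

test_that("writing to a nonexistent directory fails with a clear error", {
  v <- volume3d(array(0, c(2, 2, 2)))
  expect_error(write_volume(v, file.path(tempdir(), "no_dir_here", "v.nrrd")),
               "does not exist")
})

test_that("volume3d enforces its invariants", {
  expect_error(volume3d(matrix(0, 3, 3)), "3D")
  expect_error(volume3d(array(0, c(2, 2, 2)), spacing = c(1, 0, 1)),
               "positive")
  expect_error(volume3d(array(2, c(2, 2, 2)), scale_tag = "normalized"),
               "\\[-1, 1\\]")
  ok <- volume3d(array(0.5, c(2, 2, 2)), scale_tag = "normalized")
  expect_s3_class(ok, "volume3d")
})

test_that("resampling follows the shape formula and preserves constants", {
  set.seed(2)
  v <- volume3d(rand_vol(c(10, 10, 10)), spacing = c(1, 1, 1))
  half <- resample_to_spacing(v, c(2, 2, 2))
  expect_identical(dim(half$data), c(5L, 5L, 5L))
  expect_equal(half$spacing, c(2, 2, 2))
  # identity resample is voxel-exact
  expect_identical(resample_to_spacing(v, c(1, 1, 1))$data, v$data)
  # a constant volume stays constant under any linear resampling
  cst <- volume3d(array(7, c(6, 6, 6)))
  r <- resample_to_spacing(cst, c(1.3, 0.7, 2.1))
  expect_true(all(r$data == 7))
  # linear interpolation never escapes the input range
  r2 <- resample_to_spacing(v, c(0.6, 1.7, 0.9))
  expect_gte(min(r2$data), min(v$data))
  expect_lte(max(r2$data), max(v$data))
  expect_error(resample_to_spacing(v, c(1, -1, 1)), "positive")
})

test_that("nearest-neighbour resampling keeps label values intact", {
  lab <- volume3d(array(sample(0:3, 8^3, TRUE), c(8, 8, 8)))
  r <- resample_to_spacing(lab, c(1.5, 1.5, 1.5), interpolation = "nearest")
  expect_true(all(r$data %in% 0:3))
})

test_that("body mask recovers the phantom body and rejects empty input", {
  p <- small_phantom_pair()
  m <- compute_body_mask(p$ct)
  truth <- p$labels > 0L
  expect_gt(dice(m$data, truth), 0.98)
  # lungs (deep inside the body) must be filled in, not holes
  expect_true(all(m$data[p$labels == 2L | p$labels == 3L]))
  air <- volume3d(array(-1000, c(4, 4, 4)))
  expect_error(compute_body_mask(air), "empty")
  solid <- volume3d(array(100, c(4, 4, 4)))
  expect_true(all(compute_body_mask(solid)$data))
  norm <- clip_and_scale(solid, -1000, 2000, "to_normalized")
  expect_error(compute_body_mask(norm), "HU scale")
})

test_that("apply_mask fills outside voxels and validates shapes", {
  v <- volume3d(array(100, c(4, 4, 4)))
  all_true <- body_mask(array(TRUE, c(4, 4, 4)))
  expect_identical(apply_mask(v, all_true)$data, v$data)
  all_false <- body_mask(array(FALSE, c(4, 4, 4)))
  expect_true(all(apply_mask(v, all_false)$data == -1000))
  half <- array(FALSE, c(4, 4, 4)); half[1:2, , ] <- TRUE
  expect_equal(mean(apply_mask(v, body_mask(half))$data), (100 - 1000) / 2)
  small <- body_mask(array(TRUE, c(2, 2, 2)))
  expect_error(apply_mask(v, small), "shape")
})

test_that("field-of-view truncation matches physical-extent arithmetic", {
  set.seed(3)
  ct <- volume3d(rand_vol(c(20, 8, 8)), spacing = c(1, 1, 1),
                 origin = c(0, 0, 0))
  # CBCT covering the middle 10 slices, same in-plane extent
  cbct <- volume3d(array(0, c(10, 8, 8)), spacing = c(1, 1, 1),
                   origin = c(0, 0, 5))
  tr <- truncate_fov(ct, cbct)
  expect_identical(dim(tr$data), c(10L, 8L, 8L))
  expect_identical(tr$data, ct$data[6:15, , ], ignore_attr = TRUE)
  ext <- freqgan:::volume_extent(tr)
  ext_cb <- freqgan:::volume_extent(cbct)
  expect_true(all(abs(ext - ext_cb) <= 0.5 * rep(ct$spacing, each = 2)))
  # equal extents: identity crop
  same <- truncate_fov(ct, ct)
  expect_identical(same$data, ct$data)
  # air padding where the CBCT extends beyond the CT
  wide <- volume3d(array(0, c(24, 8, 8)), spacing = c(1, 1, 1),
                   origin = c(0, 0, -2))
  padded <- truncate_fov(ct, wide)
  expect_identical(dim(padded$data), c(24L, 8L, 8L))
  expect_true(all(padded$data[1:2, , ] == -1000))
  # disjoint extents
  far <- volume3d(array(0, c(4, 8, 8)), spacing = c(1, 1, 1),
                  origin = c(0, 0, 100))
  expect_error(truncate_fov(ct, far), "overlap")
})

test_that("HU windowing maps endpoints exactly and inverts in range", {
  v <- volume3d(array(c(-1000, 500, 2000, 2500, -1500), c(5, 1, 1)))
  n <- clip_and_scale(v, -1000, 2000, "to_normalized")
  expect_equal(as.vector(n$data), c(-1, 0, 1, 1, -1))
  expect_identical(n$scale_tag, "normalized")
  back <- clip_and_scale(n, -1000, 2000, "to_hu")
  expect_equal(as.vector(back$data), c(-1000, 500, 2000, 2000, -1000))
  # round trip on in-range data is the identity
  set.seed(4)
  w <- volume3d(array(stats::runif(60, -1000, 2000), c(3, 4, 5)))
  rt <- clip_and_scale(clip_and_scale(w, -1000, 2000, "to_normalized"),
                       -1000, 2000, "to_hu")
  expect_equal(rt$data, w$data, tolerance = 1e-6)
  expect_error(clip_and_scale(v, 100, 100, "to_normalized"), "clip_lo")
  out_of_range <- volume3d(array(1.5, c(2, 2, 2)))
  expect_error(clip_and_scale(out_of_range, -1000, 2000, "to_hu"),
               "\\[-1, 1\\]")
})
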