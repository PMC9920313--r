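test_that("phantom organs hit their HU targets and nest inside the body", {
  sp <- phantom_spec(shape = c(16L, 48L, 48L), spacing = c(5, 5, 6),
                     seed = 4L)
  ph <- make_phantom_ct(sp)
  labs <- phantom_labels()
  for (organ in c("body", "lung_left", "lung_right", "heart", "bone",
                  "tumor")) {
    sel <- ph$labels == labs[[organ]]
    expect_gt(sum(sel), 0)
    target <- switch(organ, lung_left = , lung_right = sp$hu[["lung"]],
                     sp$hu[[sub("_.*", "", organ)]])
    expect_lt(abs(mean(ph$ct$data[sel]) - target), 2 * sp$texture_sd)
  }
  # organs nested inside the body; lungs disjoint
  organs <- ph$labels >= 2L
  body_or_organ <- ph$labels >= 1L
  expect_true(all(body_or_organ[organs]))
  expect_identical(sum(ph$labels == 2L & ph$labels == 3L), 0L)
  # air outside the body
  expect_lt(mean(ph$ct$data[ph$labels == 0L]), -900)
})

test_that("the phantom is a deterministic function of spec and seed", {
  sp <- phantom_spec(shape = c(12L, 32L, 32L), seed = 9L)
  p1 <- make_phantom_ct(sp)
  p2 <- make_phantom_ct(sp)
  expect_identical(p1$ct$data, p2$ct$data)
  expect_identical(p1$labels, p2$labels)
  p3 <- make_phantom_ct(phantom_spec(shape = c(12L, 32L, 32L), seed = 10L))
  expect_false(identical(p1$ct$data, p3$ct$data))
})

test_that("a zero-radius tumor leaves no trace in the label map", {
  sp <- phantom_spec(shape = c(12L, 32L, 32L),
                     tumor = list(center = c(0, -0.1, 0.45), radius = 0))
  ph <- make_phantom_ct(sp)
  expect_identical(sum(ph$labels == phantom_labels()[["tumor"]]), 0L)
  sp2 <- phantom_spec(shape = c(12L, 32L, 32L), tumor = NULL)
  expect_identical(sum(make_phantom_ct(sp2)$labels == 6L), 0L)
  expect_error(phantom_spec(tumor = list(center = c(0, 0, 0), radius = 0.9)),
               "tumor")
})

test_that("the zero degradation is the identity map", {
  p <- small_phantom_pair()
  id_spec <- degradation_spec(hu_shift = 0, hu_scale = 1,
                              streak_amplitude = 0, blur_sigma = 0,
                              noise_sigma = 0, deform_amplitude = 0)
  out <- degrade_to_cbct(p$ct, id_spec)
  expect_identical(out$data, p$ct$data)
})

test_that("a pure HU shift moves the mean by exactly that shift", {
  p <- small_phantom_pair()
  sh <- degradation_spec(hu_shift = 100, hu_scale = 1, streak_amplitude = 0,
                         blur_sigma = 0, noise_sigma = 0,
                         deform_amplitude = 0)
  out <- degrade_to_cbct(p$ct, sh)
  expect_equal(mean(out$data - p$ct$data), 100, tolerance = 1e-9)
})

test_that("each degradation knob increases the error against the clean CT", {
  p <- small_phantom_pair()
  base <- degradation_spec(hu_shift = 0, hu_scale = 1, streak_amplitude = 0,
                           blur_sigma = 0, noise_sigma = 0,
                           deform_amplitude = 0)
  err_with <- function(field, values) {
    vapply(values, function(v) {
      d <- base; d[[field]] <- v
      mean(vapply(1:3, function(s) {
        d$seed <- s
        mae(p$ct$data, degrade_to_cbct(p$ct, d)$data)
      }, numeric(1)))
    }, numeric(1))
  }
  expect_true(all(diff(err_with("noise_sigma", c(0, 20, 80))) > 0))
  expect_true(all(diff(err_with("streak_amplitude", c(0, 30, 90))) > 0))
  expect_true(all(diff(err_with("hu_shift", c(0, 50, 150))) > 0))
  expect_true(all(diff(err_with("blur_sigma", c(0, 2, 6))) > 0))
})

test_that("degradation is deterministic given its seed", {
  p <- small_phantom_pair()
  d <- degradation_spec(seed = 33L, deform_amplitude = 3)
  expect_identical(degrade_to_cbct(p$ct, d)$data,
                   degrade_to_cbct(p$ct, d)$data)
})

test_that("the frequency loss separates CT from CBCT on synthetic data", {
  # the discriminative property the training signal relies on: distances
  # across domains exceed distances within the CT domain
  set.seed(60)
  cts <- lapply(1:3, function(i)
    make_phantom_ct(phantom_spec(shape = c(8L, 24L, 24L), spacing = c(5, 5, 6),
                                 seed = 100L + i))$ct)
  cbs <- lapply(cts, function(ct)
    degrade_to_cbct(ct, degradation_spec(seed = 7L)))
  # distances are taken on the windowed network scale, as during training
  win <- function(v) clip_and_scale(v, -1000, 2000, "to_normalized")$data
  cross <- outer(1:3, 1:3, Vectorize(function(i, j)
    frequency_distance(win(cts[[i]]), win(cbs[[j]]))))
  within <- c(frequency_distance(win(cts[[1]]), win(cts[[2]])),
              frequency_distance(win(cts[[1]]), win(cts[[3]])),
              frequency_distance(win(cts[[2]]), win(cts[[3]])))
  expect_gt(mean(cross), mean(within))
})

test_that("make_dataset writes the promised files and metadata", {
  td <- withr::local_tempdir()
  meta <- make_dataset(td, n_patients = 2, cts_per_patient = 1,
                       cbcts_per_patient = 2, shape = c(8L, 24L, 24L),
                       spacing = c(5, 5, 6), seed = 3)
  expect_identical(nrow(meta), 6L)                 # 2 x (1 CT + 2 CBCT)
  vols <- list.files(td, pattern = "\\.nii\\.gz$")
  expect_length(vols, 8)                           # 6 scans + phantom pair
  expect_true(all(c("phantom_CT.nii.gz", "phantom_CBCT.nii.gz") %in% vols))
  expect_true(file.exists(file.path(td, "scan_metadata.csv")))
  recs <- read_scan_metadata(file.path(td, "scan_metadata.csv"))
  expect_identical(nrow(recs), 6L)
  # the metadata feeds the weak-pair logic and yields one pair per patient
  wp <- select_weak_pairs(recs)
  expect_identical(nrow(wp), 2L)
  expect_true(all(wp$delta_days <= 1))
  # the CSV is byte-identical across runs with the same seed
  td2 <- withr::local_tempdir()
  make_dataset(td2, n_patients = 2, cts_per_patient = 1,
               cbcts_per_patient = 2, shape = c(8L, 24L, 24L),
               spacing = c(5, 5, 6), seed = 3)
  c1 <- readLines(file.path(td, "scan_metadata.csv"))
  c2 <- readLines(file.path(td2, "scan_metadata.csv"))
  expect_identical(gsub(td, "", c1, fixed = TRUE),
                   gsub(td2, "", c2, fixed = TRUE))
})
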