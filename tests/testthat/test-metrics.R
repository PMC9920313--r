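test_that("error metrics match hand-computed values", {
  ref <- array(c(0, 100), c(2, 1, 1))
  pred <- array(c(10, 90), c(2, 1, 1))
  expect_equal(mae(ref, pred), 10)
  expect_equal(mse(ref, pred), 100)
  expect_equal(nmse(ref, pred), 200 / 10000)
  expect_identical(mae(ref, ref), 0)
  expect_identical(mse(ref, ref), 0)
  # a zero prediction gives NMSE exactly 1 for any nonzero reference
  expect_equal(nmse(ref, array(0, c(2, 1, 1))), 1)
  expect_error(nmse(array(0, c(2, 2, 2)), array(1, c(2, 2, 2))),
               "signal power")
  expect_error(mae(ref, array(0, c(3, 1, 1))), "shape")
})

test_that("PSNR matches its closed form and signals perfection as Inf", {
  set.seed(50)
  ref <- array(stats::runif(4^3, 0, 255), c(4, 4, 4))
  ref[1] <- 255
  pred <- ref + sqrt(25) * (2 * (seq_along(ref) %% 2) - 1)  # MSE 25 exactly
  expect_equal(psnr(ref, pred), 20 * log10(255) - 10 * log10(25),
               tolerance = 1e-9)
  expect_equal(20 * log10(255) - 10 * log10(25), 34.1514, tolerance = 1e-4)
  ref2 <- array(100, c(2, 2, 2))
  pred2 <- ref2 + 1
  expect_equal(psnr(ref2, pred2), 40)
  expect_identical(psnr(ref, ref), Inf)
})

test_that("SSIM satisfies its identity, symmetry and sign properties", {
  set.seed(51)
  x <- array(stats::runif(10^3, 0, 3000), c(10, 10, 10))
  expect_equal(ssim(x, x), 1, tolerance = 1e-9)
  expect_equal(ssim(x, x, mode = "global"), 1, tolerance = 1e-9)
  y <- array(stats::runif(10^3, 0, 3000), c(10, 10, 10))
  expect_equal(ssim(x, y), ssim(y, x), tolerance = 1e-12)
  # intensity inversion about the mean drives the covariance negative
  inv <- -x + 2 * mean(x)
  expect_lt(ssim(x, inv, mode = "global", data_range = 3000), 0)
  # global mode agrees with a direct evaluation of the formula
  a <- array(c(10, 30, 20, 40, 50, 70, 60, 80), c(2, 2, 2))
  b <- array(c(12, 28, 24, 38, 52, 66, 64, 78), c(2, 2, 2))
  mu_x <- mean(a); mu_y <- mean(b)
  vx <- mean((a - mu_x)^2); vy <- mean((b - mu_y)^2)
  cxy <- mean((a - mu_x) * (b - mu_y))
  R <- 3000; c1 <- (0.01 * R)^2; c2 <- (0.03 * R)^2
  direct <- ((2 * mu_x * mu_y + c1) * (2 * cxy + c2)) /
    ((mu_x^2 + mu_y^2 + c1) * (vx + vy + c2))
  expect_equal(ssim(a, b, mode = "global"), direct, tolerance = 1e-12)
  expect_error(ssim(a, array(0, c(3, 3, 3))), "shape")
})

test_that("Dice matches hand examples and is symmetric", {
  d <- c(10, 10, 10)
  A <- array(FALSE, d); A[1:5, , ] <- TRUE       # |A| = 500
  B <- array(FALSE, d); B[3:7, , ] <- TRUE       # |B| = 500, overlap 300
  expect_equal(dice(A, B), 2 * 300 / 1000)
  expect_equal(dice(A, B), dice(B, A))
  expect_equal(dice(A, A), 1)
  C <- array(FALSE, d); C[8:10, , ] <- TRUE
  expect_equal(dice(A, C), 0)
  expect_equal(dice(array(FALSE, d), array(FALSE, d)), 1)
  # growing overlap at fixed sizes increases Dice
  B2 <- array(FALSE, d); B2[2:6, , ] <- TRUE     # overlap 400
  expect_gt(dice(A, B2), dice(A, B))
})

test_that("squared-error dominance mae^2 <= mse holds universally", {
  set.seed(52)
  for (rep in 1:200) {
    a <- rand_vol(c(4, 4, 4), sd = stats::runif(1, 1, 500))
    b <- rand_vol(c(4, 4, 4), sd = stats::runif(1, 1, 500))
    expect_lte(mae(a, b)^2, mse(a, b) + 1e-12)
  }
})

test_that("NMSE is invariant to joint rescaling", {
  set.seed(53)
  a <- array(stats::runif(60, 10, 100), c(3, 4, 5))
  b <- array(stats::runif(60, 10, 100), c(3, 4, 5))
  expect_equal(nmse(a, b), nmse(3.7 * a, 3.7 * b), tolerance = 1e-12)
})

test_that("HU histograms conserve in-range counts", {
  v <- volume3d(array(0, c(4, 4, 4)))
  h <- hu_histogram(v, -500, 500, bins = 11)
  expect_identical(sum(h$counts), 64L)
  expect_identical(h$counts[6], 64L)  # middle bin holds the constant
  set.seed(54)
  w <- volume3d(array(stats::runif(1000, -800, 800), c(10, 10, 10)))
  h2 <- hu_histogram(w, -500, 500, bins = 20)
  expect_identical(sum(h2$counts), sum(w$data >= -500 & w$data < 500))
  expect_error(hu_histogram(w, 500, -500), "lo < hi")
  expect_error(hu_histogram(w, -500, 500, bins = 0), "bin")
})

test_that("line profiles interpolate across axial slices", {
  v <- volume3d(array(7, c(4, 10, 10)))
  p <- line_profile(v, 2, c(1, 5), c(10, 5), n_samples = 25)
  expect_length(p, 25)
  expect_true(all(p == 7))
  # step image: monotone transition between the two plateaus
  s <- array(0, c(2, 8, 8)); s[, , 5:8] <- 100
  p2 <- line_profile(volume3d(s), 1, c(1, 4), c(8, 4), n_samples = 30)
  expect_equal(p2[1], 0); expect_equal(p2[30], 100)
  expect_true(all(diff(p2) >= -1e-9))
  # coincident endpoints repeat one value
  p3 <- line_profile(volume3d(s), 1, c(3, 3), c(3, 3), n_samples = 5)
  expect_true(all(p3 == p3[1]))
  expect_error(line_profile(v, 99, c(1, 1), c(2, 2)), "out of bounds")
  expect_error(line_profile(v, 1, c(0, 1), c(2, 2)), "bounds")
})

test_that("evaluate_pair applies one recorded convention to all metrics", {
  p <- small_phantom_pair()
  rep <- evaluate_pair(p$ct, p$cbct)
  expect_s3_class(rep, "metric_report")
  expect_equal(rep$clip_range, c(0, 3000))
  expect_false(rep$mask_used)
  expect_true(all(is.finite(c(rep$mae, rep$mse, rep$nmse, rep$psnr,
                              rep$ssim))))
  expect_lte(rep$ssim, 1)
  # identical inputs: zero errors, unit similarity, infinite PSNR
  perfect <- evaluate_pair(p$ct, p$ct)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$mse, 0)
  expect_equal(perfect$nmse, 0)
  expect_identical(perfect$psnr, Inf)
  expect_equal(perfect$ssim, 1, tolerance = 1e-9)
  # masked evaluation is recorded and differs from unmasked
  m <- compute_body_mask(p$ct)
  repm <- evaluate_pair(p$ct, p$cbct, mask = m)
  expect_true(repm$mask_used)
  expect_false(isTRUE(all.equal(rep$mae, repm$mae)))
  # optional Dice entries
  repd <- evaluate_pair(p$ct, p$cbct,
                        dice_masks = list(body = list(m, m)))
  expect_equal(unname(repd$dice_per_label["body"]), 1)
})

test_that("MAE grows with the noise level corrupting the prediction", {
  set.seed(55)
  ref <- array(stats::runif(8^3, 0, 1000), c(8, 8, 8))
  sigmas <- c(10, 50, 150)
  mae_at <- vapply(sigmas, function(s) {
    mean(vapply(1:5, function(r)
      mae(ref, ref + array(stats::rnorm(length(ref), 0, s), dim(ref))),
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mae_at) > 0))
})
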