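test_that("the learning-rate schedule is flat then decays linearly to zero", {
  expect_equal(lr_schedule(10000, 30000, 4e-4), 4e-4)
  expect_equal(lr_schedule(15000, 30000, 4e-4), 4e-4)
  expect_equal(lr_schedule(22500, 30000, 4e-4), 2e-4)
  expect_equal(lr_schedule(30000, 30000, 4e-4), 0)
  expect_error(lr_schedule(30001, 30000, 4e-4), "\\[0, total\\]")
  # discrete sum over the full run: 15,000 flat + decay averaging base/2
  s <- sum(lr_schedule(1:30000, 30000, 4e-4))
  expect_equal(s, 4e-4 * 22500, tolerance = 1e-4)
})

test_that("the default configuration echoes the published recipe", {
  cfg <- train_config()
  expect_equal(cfg$lr_discriminator, 0.0002)
  expect_equal(cfg$lr_generator, 0.0004)
  expect_identical(cfg$batch_size, 1L)
  expect_equal(cfg$optimizer_betas, c(0.5, 0.999))
  expect_identical(cfg$total_iterations, 30000L)
  expect_identical(cfg$patch_size, c(16L, 320L, 320L))
  expect_equal(cfg$weights$lambda_A, 5)
  expect_equal(cfg$weights$lambda_B, 5)
  expect_equal(cfg$weights$lambda_fA, 5)
  expect_equal(cfg$weights$lambda_fB, 5)
  expect_identical(cfg$generator$norm, "instance")
  expect_error(train_config(lr_generator = 0), "positive")
  expect_error(train_config(patch_size = c(15, 320, 320)), "divisible")
  expect_error(train_config(batch_size = 2), "batch size 1")
})

test_that("scan selection is uniform over the pool", {
  set.seed(30)
  draws <- replicate(10000, freqgan:::sample_pool_idx(2L))
  n1 <- sum(draws == 1L)
  expect_gt(n1, 4800)   # 4-sigma binomial band around 5000
  expect_lt(n1, 5200)
})

test_that("patch sampling honours pools, masks and padding", {
  td <- withr::local_tempdir()
  meta <- make_dataset(td, n_patients = 1, shape = c(16L, 48L, 48L),
                       spacing = c(5, 5, 6), seed = 3)
  cb_pool <- meta[meta$modality == "CBCT", , drop = FALSE]
  ct_pool <- meta[meta$modality == "CT", , drop = FALSE]
  cache <- new.env(parent = emptyenv())
  set.seed(31)
  s <- sample_unpaired_patch_pair(cb_pool, ct_pool,
                                  patch_size = c(8L, 32L, 32L),
                                  cache = cache)
  expect_identical(dim(s$cbct$data), c(8L, 32L, 32L))
  expect_identical(dim(s$ct$data), c(8L, 32L, 32L))
  # single-record pools always select those scans
  expect_identical(attr(s, "ct_record")$path, ct_pool$path[1])
  # a patch the size of the whole scan is the whole (masked) scan
  s2 <- sample_unpaired_patch_pair(cb_pool, ct_pool,
                                   patch_size = c(16L, 48L, 48L),
                                   cache = cache)
  masked_ct <- apply_mask(read_volume(ct_pool$path[1]),
                          compute_body_mask(read_volume(ct_pool$path[1])))
  expect_equal(s2$ct$data, masked_ct$data, tolerance = 1e-6)
  expect_error(sample_unpaired_patch_pair(cb_pool[0, ], ct_pool), "non-empty")
})

test_that("a training step updates every network and is deterministic", {
  patches <- smoke_patches()
  cfg <- smoke_config(iterations = 10L)
  set.seed(cfg$seed)
  state0 <- freqgan:::init_train_state(cfg)
  res <- train_step(state0, list(cbct = patches$cbct, ct = patches$ct))
  expect_true(all(vapply(res$losses, is.finite, logical(1))))
  # at least one parameter of each of the four networks changed
  for (net in c("G", "F", "DX", "DY")) {
    before <- freqgan:::collect_params(state0[[net]]$net)
    after <- freqgan:::collect_params(res$state[[net]]$net)
    expect_false(identical(before, after))
  }
  # the breakdown decomposes exactly
  w <- cfg$weights
  expect_equal(res$losses$total,
               res$losses$adv_G + res$losses$adv_F +
                 w$lambda_A * res$losses$cycle_A +
                 w$lambda_B * res$losses$cycle_B +
                 w$lambda_fA * res$losses$freq_A +
                 w$lambda_fB * res$losses$freq_B, tolerance = 1e-6)
  # identical state and batch give identical results
  set.seed(cfg$seed)
  state1 <- freqgan:::init_train_state(cfg)
  res1 <- train_step(state1, list(cbct = patches$cbct, ct = patches$ct))
  expect_identical(unlist(res$losses), unlist(res1$losses))
})

test_that("baseline and frequency runs share all non-frequency terms at step one", {
  patches <- smoke_patches()
  step1 <- function(structure) {
    cfg <- smoke_config(structure = structure, iterations = 5L)
    set.seed(cfg$seed)
    state <- freqgan:::init_train_state(cfg)
    train_step(state, list(cbct = patches$cbct, ct = patches$ct))$losses
  }
  lf <- step1("frequency_l1")
  l0 <- step1("none")
  # identical initialization: the first-step losses differ only in the
  # frequency terms (and hence the weighted total)
  expect_identical(l0$adv_G, lf$adv_G)
  expect_identical(l0$adv_F, lf$adv_F)
  expect_identical(l0$cycle_A, lf$cycle_A)
  expect_identical(l0$cycle_B, lf$cycle_B)
  expect_identical(l0$freq_A, 0)
  expect_gt(lf$freq_A, 0)
})

test_that("training runs end-to-end, checkpoints and resumes", {
  td <- withr::local_tempdir()
  meta <- make_dataset(td, n_patients = 1, shape = c(16L, 48L, 48L),
                       spacing = c(5, 5, 6), seed = 3)
  cfg <- train_config(patch_size = c(8L, 32L, 32L),
                      generator = generator_spec(base_filters = 2L),
                      discriminator = discriminator_spec(base_filters = 4L),
                      total_iterations = 6L, checkpoint_every = 3L,
                      seed = 9L)
  run_dir <- file.path(td, "run"); dir.create(run_dir)
  fit <- train_cyclegan(cfg, meta, out_dir = run_dir, quiet = TRUE)
  expect_s3_class(fit, "cyclegan")
  expect_identical(nrow(fit$log), 6L)
  expect_true(all(is.finite(as.matrix(fit$log))))
  expect_true(file.exists(file.path(run_dir, "checkpoint_latest.rds")))
  expect_true(file.exists(file.path(run_dir, "loss_log.csv")))
  log_csv <- utils::read.csv(file.path(run_dir, "loss_log.csv"))
  expect_identical(names(log_csv),
                   c("iteration", "lr", "adv_G", "adv_F", "cycle_A",
                     "cycle_B", "freq_A", "freq_B", "total"))
  # an interrupted run (3 of 6 iterations) resumes to completion
  cfg_half <- cfg; cfg_half$total_iterations <- 3L
  half_dir <- file.path(td, "half"); dir.create(half_dir)
  train_cyclegan(cfg_half, meta, out_dir = half_dir, quiet = TRUE)
  fit2 <- train_cyclegan(cfg, meta, out_dir = NULL,
                         resume = file.path(half_dir,
                                            "checkpoint_latest.rds"),
                         quiet = TRUE)
  expect_identical(fit2$state$iteration, 6L)
  expect_identical(nrow(fit2$log), 6L)
  # the schedule is a pure function of the iteration, so a resumed run sees
  # the same learning rate at the same iteration
  expect_equal(lr_schedule(5, cfg$total_iterations, cfg$lr_generator),
               fit$log$lr[fit$log$iteration == 5])
  # summary and plot methods work on the fit
  s <- summary(fit)
  expect_s3_class(s, "summary.cyclegan")
  pdf(NULL); on.exit(dev.off(), add = TRUE)
  expect_silent(plot(fit))
})

test_that("the historical image pool swaps deterministically under seed", {
  img <- array(1, c(2, 2, 2, 1))
  p0 <- freqgan:::pool_query(list(), img, 0L)
  expect_identical(p0$img, img)
  expect_length(p0$pool, 0)
  p1 <- freqgan:::pool_query(list(), img, 2L)
  expect_length(p1$pool, 1)
  set.seed(1)
  p2 <- freqgan:::pool_query(list(array(2, c(2, 2, 2, 1))), img, 1L)
  expect_true(length(p2$pool) == 1)
})
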