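#' Training configuration
#'
#' All knobs of the training recipe. The defaults are the published operating
#' point: discriminator learning rate 0.0002, generator 0.0004, batch size 1,
#' Adam with betas (0.5, 0.999), 30,000 iterations, patch size
#' (16, 320, 320) in (z, x, y), cycle weights `lambda_A = lambda_B = 5` and
#' frequency weights `lambda_fA = lambda_fB = 5`, learning rate fixed for the
#' first half of training then decayed linearly to zero.
#'
#' @param lr_discriminator,lr_generator base learning rates.
#' @param batch_size batch size; this engine trains with batch 1.
#' @param total_iterations number of training steps.
#' @param patch_size integer length-3 `(z, x, y)` patch shape; z must be
#'   divisible by 4 and the in-plane sizes by 16.
#' @param optimizer_betas Adam `(beta1, beta2)`.
#' @param weights a [loss_weights()].
#' @param seed integer seed controlling initialization and sampling.
#' @param image_pool_size size of the historical fake-image pool used for
#'   discriminator updates; 0 disables it.
#' @param adversarial `"least_squares"` (default) or `"vanilla"`.
#' @param structure structure loss: `"frequency_l1"` (default),
#'   `"frequency_l2"` or `"none"` (plain CycleGAN baseline).
#' @param freq_reduction reduction of the training-time frequency term:
#'   `"mean"` (default; keeps the balance implied by `lambda_f = 5`
#'   independent of patch size) or `"sum"` (the literal summed form).
#' @param clip HU window mapped onto `[-1, 1]` for network input.
#' @param generator a [generator_spec()].
#' @param discriminator a [discriminator_spec()].
#' @param checkpoint_every checkpoint cadence in iterations.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr_discriminator = 2e-4, lr_generator = 4e-4,
                         batch_size = 1L, total_iterations = 30000L,
                         patch_size = c(16L, 320L, 320L),
                         optimizer_betas = c(0.5, 0.999),
                         weights = loss_weights(), seed = 1L,
                         image_pool_size = 50L,
                         adversarial = c("least_squares", "vanilla"),
                         structure = c("frequency_l1", "frequency_l2", "none"),
                         freq_reduction = c("mean", "sum"),
                         clip = c(-1000, 2000),
                         generator = generator_spec(),
                         discriminator = discriminator_spec(),
                         checkpoint_every = 1000L) {
  adversarial <- match.arg(adversarial)
  structure_name <- match.arg(structure)
  freq_reduction <- match.arg(freq_reduction)
  if (lr_discriminator <= 0 || lr_generator <= 0)
    stop("train_config: learning rates must be positive", call. = FALSE)
  if (total_iterations < 1L)
    stop("train_config: total_iterations must be >= 1", call. = FALSE)
  if (batch_size != 1L)
    stop("train_config: this engine trains with batch size 1", call. = FALSE)
  patch_size <- as.integer(patch_size)
  if (length(patch_size) != 3L || patch_size[1] %% 4L != 0L ||
      any(patch_size[2:3] %% 16L != 0L))
    stop("train_config: patch_size (z, x, y) must have z divisible by 4 and ",
         "x, y divisible by 16", call. = FALSE)
  stopifnot(inherits(weights, "loss_weights"),
            inherits(generator, "generator_spec"),
            inherits(discriminator, "discriminator_spec"))
  structure(list(lr_discriminator = lr_discriminator,
                 lr_generator = lr_generator,
                 batch_size = as.integer(batch_size),
                 total_iterations = as.integer(total_iterations),
                 patch_size = patch_size,
                 optimizer_betas = as.numeric(optimizer_betas),
                 weights = weights, seed = as.integer(seed),
                 image_pool_size = as.integer(image_pool_size),
                 adversarial = adversarial, structure = structure_name,
                 freq_reduction = freq_reduction, clip = as.numeric(clip),
                 generator = generator, discriminator = discriminator,
                 checkpoint_every = as.integer(checkpoint_every)),
            class = "train_config")
}

#' @export
print.train_config <- function(x, ...) {
  cat("<train_config>\n")
  cat("  lr D/G:", x$lr_discriminator, "/", x$lr_generator,
      " Adam betas (", paste(x$optimizer_betas, collapse = ", "), ")\n")
  cat("  batch", x$batch_size, ", iterations", x$total_iterations,
      ", patch (z,x,y) (", paste(x$patch_size, collapse = ","), ")\n")
  cat("  lambda A/B:", x$weights$lambda_A, "/", x$weights$lambda_B,
      "  lambda fA/fB:", x$weights$lambda_fA, "/", x$weights$lambda_fB, "\n")
  cat("  adversarial:", x$adversarial, " structure:", x$structure, "\n")
  invisible(x)
}

#' Scan metadata record(s)
#'
#' @param patient_id patient identifier.
#' @param modality `"CT"` or `"CBCT"`.
#' @param acquisition_date calendar date (coerced with `as.Date`).
#' @param path path to the volume file.
#' @return A one-row data frame with class `scan_record` semantics; bind
#'   rows to build a pool.
#' @export
scan_record <- function(patient_id, modality, acquisition_date, path) {
  modality <- toupper(modality)
  if (!modality %in% c("CT", "CBCT"))
    stop("scan_record: modality must be CT or CBCT", call. = FALSE)
  date <- tryCatch(as.Date(acquisition_date),
                   error = function(e) stop("scan_record: unparseable date '",
                                            acquisition_date, "'",
                                            call. = FALSE))
  if (is.na(date))
    stop("scan_record: unparseable date '", acquisition_date, "'",
         call. = FALSE)
  data.frame(patient_id = as.character(patient_id), modality = modality,
             date = date, path = as.character(path),
             stringsAsFactors = FALSE)
}

#' Read a scan-metadata table
#'
#' Expects columns `patient_id`, `modality`, `date` (ISO-8601) and `path`.
#'
#' @param csv path to the metadata CSV.
#' @return A data frame of scan records.
#' @export
read_scan_metadata <- function(csv) {
  df <- utils::read.csv(csv, stringsAsFactors = FALSE)
  need <- c("patient_id", "modality", "date", "path")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_scan_metadata: missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$date <- as.Date(df$date)
  if (any(is.na(df$date)))
    stop("read_scan_metadata: unparseable date in row(s) ",
         paste(which(is.na(df$date)), collapse = ", "), call. = FALSE)
  df$patient_id <- as.character(df$patient_id)
  df$modality <- toupper(df$modality)
  df
}

#' Learning-rate schedule: fixed for 50%, linear decay for 50%
#'
#' Returns `base_lr` for iterations up to half of `total`, then decays
#' linearly so the rate is exactly half the base three quarters of the way
#' through and 0 at iteration `total`.
#'
#' @param iteration current iteration, `0 <= iteration <= total`.
#' @param total total number of iterations.
#' @param base_lr base learning rate.
#' @return The learning rate for `iteration`.
#' @export
lr_schedule <- function(iteration, total, base_lr) {
  if (any(iteration < 0) || any(iteration > total))
    stop("lr_schedule: iteration must be in [0, total]", call. = FALSE)
  half <- total / 2
  base_lr * pmin(1, (total - iteration) / (total - half))
}

# uniform scan selection from a pool (kept separate so uniformity is testable
# without touching volume I/O)
sample_pool_idx <- function(n) sample.int(n, 1L)

# extract a (z, y, x) patch of `size_zyx` centred near `center` (1-based,
# z,y,x), clamped so the patch stays inside the volume where possible and
# air-padded where the volume is smaller than the patch
extract_patch <- function(vol, center, size_zyx, fill = -1000) {
  d <- dim(vol$data)
  out <- array(fill, size_zyx)
  start <- integer(3)
  for (a in 1:3) {
    s <- center[a] - size_zyx[a] %/% 2L
    s <- max(1L, min(s, d[a] - size_zyx[a] + 1L))
    start[a] <- as.integer(s)
  }
  lo_out <- pmax(1L, 2L - start)
  hi_out <- pmin(size_zyx, d - start + 1L)
  lo_in <- start + lo_out - 1L
  hi_in <- start + hi_out - 1L
  out[lo_out[1]:hi_out[1], lo_out[2]:hi_out[2], lo_out[3]:hi_out[3]] <-
    vol$data[lo_in[1]:hi_in[1], lo_in[2]:hi_in[2], lo_in[3]:hi_in[3]]
  volume3d(out, spacing = vol$spacing, origin = vol$origin,
           scale_tag = vol$scale_tag)
}

# load a volume, with optional per-path cache (environment)
load_cached <- function(path, cache = NULL) {
  if (!is.null(cache)) {
    hit <- cache[[path]]
    if (!is.null(hit)) return(hit)
  }
  vol <- read_volume(path)
  mask <- compute_body_mask(vol)
  out <- list(vol = apply_mask(vol, mask), mask = mask)
  if (!is.null(cache)) cache[[path]] <- out
  out
}

#' Sample an unpaired CBCT/CT patch pair
#'
#' Draws one scan uniformly from each pool (so a CT may come from the same
#' patient as the CBCT or a different one), applies the online preprocessing
#' chain — body masking, truncation of the CT field of view to the CBCT's —
#' and extracts one patch from each volume whose centre lies inside the
#' body mask (uniformly over such positions); volumes smaller than the patch
#' are air-padded.
#'
#' @param cbct_pool,ct_pool data frames of scan records (see
#'   [scan_record()]); must be non-empty.
#' @param patch_size integer `(z, x, y)` patch shape.
#' @param cache optional environment caching loaded/masked volumes by path.
#' @return A list with elements `cbct` and `ct` ([volume3d]s on the HU
#'   scale) and the chosen records as attributes `cbct_record`/`ct_record`.
#' @export
sample_unpaired_patch_pair <- function(cbct_pool, ct_pool,
                                       patch_size = c(16L, 320L, 320L),
                                       cache = NULL) {
  if (is.null(cbct_pool) || nrow(cbct_pool) == 0L ||
      is.null(ct_pool) || nrow(ct_pool) == 0L)
    stop("sample_unpaired_patch_pair: scan pools must be non-empty",
         call. = FALSE)
  size_zyx <- as.integer(c(patch_size[1], patch_size[3], patch_size[2]))
  rec_cb <- cbct_pool[sample_pool_idx(nrow(cbct_pool)), , drop = FALSE]
  rec_ct <- ct_pool[sample_pool_idx(nrow(ct_pool)), , drop = FALSE]
  cb <- load_cached(rec_cb$path, cache)
  ct <- load_cached(rec_ct$path, cache)
  ct_vol <- truncate_fov(ct$vol, cb$vol)
  mask_vol <- volume3d(array(as.numeric(ct$mask$data), dim(ct$mask$data)),
                       spacing = ct$vol$spacing, origin = ct$vol$origin)
  ct_mask_arr <- truncate_fov(mask_vol, cb$vol, fill_value = 0)$data > 0.5
  patch_center <- function(mask_arr) {
    cand <- which(mask_arr)
    arrayInd(cand[sample_pool_idx(length(cand))], dim(mask_arr))[1, ]
  }
  cb_patch <- extract_patch(cb$vol, patch_center(cb$mask$data), size_zyx)
  ct_patch <- extract_patch(ct_vol, patch_center(ct_mask_arr), size_zyx)
  out <- list(cbct = cb_patch, ct = ct_patch)
  attr(out, "cbct_record") <- rec_cb
  attr(out, "ct_record") <- rec_ct
  out
}

# ---- training state --------------------------------------------------------

init_train_state <- function(config) {
  set.seed(config$seed)
  list(G = build_generator(config$generator),
       F = build_generator(config$generator),
       DX = build_discriminator(config$discriminator),
       DY = build_discriminator(config$discriminator),
       optG = adam_state(), optF = adam_state(),
       optDX = adam_state(), optDY = adam_state(),
       poolA = list(), poolB = list(),
       iteration = 0L, config = config)
}

# historical image pool (standard CycleGAN trick): returns the image to show
# the discriminator and the updated pool
pool_query <- function(pool, img, size) {
  if (size <= 0L) return(list(img = img, pool = pool))
  if (length(pool) < size) {
    pool[[length(pool) + 1L]] <- img
    return(list(img = img, pool = pool))
  }
  if (stats::runif(1) < 0.5) {
    j <- sample.int(length(pool), 1L)
    out <- pool[[j]]
    pool[[j]] <- img
    return(list(img = out, pool = pool))
  }
  list(img = img, pool = pool)
}

# adversarial loss value and d(loss)/d(raw scores) for the generator side
gen_adv_terms <- function(scores, variant) {
  n <- length(scores)
  if (variant == "least_squares") {
    list(loss = mean((scores - 1)^2), grad = 2 * (scores - 1) / n)
  } else {
    p <- 1 / (1 + exp(-scores))
    list(loss = -mean(log(p)), grad = -(1 - p) / n)
  }
}

# adversarial loss value and gradients for the discriminator side
disc_adv_terms <- function(s_real, s_fake, variant) {
  n_r <- length(s_real); n_f <- length(s_fake)
  if (variant == "least_squares") {
    list(loss = mean((s_real - 1)^2) + mean(s_fake^2),
         g_real = 2 * (s_real - 1) / n_r, g_fake = 2 * s_fake / n_f)
  } else {
    pr <- 1 / (1 + exp(-s_real)); pf <- 1 / (1 + exp(-s_fake))
    list(loss = -mean(log(pr)) - mean(log(1 - pf)),
         g_real = -(1 - pr) / n_r, g_fake = pf / n_f)
  }
}

#' One CycleGAN training step
#'
#' Performs one generator update (both mappings jointly, on the adversarial,
#' cycle-consistency and frequency terms) followed by one update of both
#' discriminators (using pooled historical fakes), with each optimizer's
#' learning rate taken from [lr_schedule()]. Deterministic given the state
#' and batch.
#'
#' @param state a training state from `init_train_state()` or a previous
#'   [train_step()] call.
#' @param batch list with elements `cbct` and `ct`: shape-congruent
#'   normalized patches ([volume3d]s with `scale_tag = "normalized"` or
#'   arrays in `[-1, 1]`).
#' @return A list with the updated `state` and the `losses`
#'   ([total_objective()] breakdown).
#' @export
train_step <- function(state, batch) {
  cfg <- state$config
  w <- cfg$weights
  variant <- cfg$adversarial
  realA <- as_feature_map(batch$cbct)  # domain X
  realB <- as_feature_map(batch$ct)    # domain Y
  nvox <- length(realA)

  # --- forward pass through both cycles ---
  g1 <- gen_fwd(state$G, realA); fakeB <- g1$y
  f1 <- gen_fwd(state$F, fakeB); recA <- f1$y
  f2 <- gen_fwd(state$F, realB); fakeA <- f2$y
  g2 <- gen_fwd(state$G, fakeA); recB <- g2$y
  dy <- disc_fwd(state$DY, fakeB)
  dx <- disc_fwd(state$DX, fakeA)

  advG <- gen_adv_terms(dy$y, variant)
  advF <- gen_adv_terms(dx$y, variant)
  cycle_A <- mean(abs(recA - realA))
  cycle_B <- mean(abs(recB - realB))
  a3 <- array(realA, dim(realA)[1:3]); b3 <- array(realB, dim(realB)[1:3])
  fb3 <- array(fakeB, dim(fakeB)[1:3]); fa3 <- array(fakeA, dim(fakeA)[1:3])
  freq_A <- structure_loss(cfg$structure, a3, fb3,
                           reduction = cfg$freq_reduction)
  freq_B <- structure_loss(cfg$structure, b3, fa3,
                           reduction = cfg$freq_reduction)
  losses <- total_objective(adv_G = advG$loss, adv_F = advF$loss,
                            cycle_A = cycle_A, cycle_B = cycle_B,
                            freq_A = freq_A, freq_B = freq_B, weights = w)
  if (!all(vapply(losses, is.finite, logical(1)))) {
    bad <- names(losses)[!vapply(losses, is.finite, logical(1))]
    stop("train_step: non-finite loss term(s) at iteration ",
         state$iteration + 1L, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
  }

  # --- generator backward ---
  g_fakeB <- disc_bwd(state$DY, dy$cache,
                      array(advG$grad, dim(dy$y)))$gx
  g_recA <- array(w$lambda_A * sign(recA - realA) / nvox, dim(recA))
  fb_cyc <- gen_bwd(state$F, f1$cache, g_recA)
  g_fakeB <- g_fakeB + fb_cyc$gx
  if (w$lambda_fA > 0 && cfg$structure != "none") {
    gfreq <- structure_loss_grad(cfg$structure, a3, fb3,
                                 reduction = cfg$freq_reduction)
    g_fakeB <- g_fakeB + array(w$lambda_fA * gfreq, dim(g_fakeB))
  }
  gG1 <- gen_bwd(state$G, g1$cache, g_fakeB)

  g_recB <- array(w$lambda_B * sign(recB - realB) / nvox, dim(recB))
  gG2 <- gen_bwd(state$G, g2$cache, g_recB)
  g_fakeA <- disc_bwd(state$DX, dx$cache,
                      array(advF$grad, dim(dx$y)))$gx
  g_fakeA <- g_fakeA + gG2$gx
  if (w$lambda_fB > 0 && cfg$structure != "none") {
    gfreq <- structure_loss_grad(cfg$structure, b3, fa3,
                                 reduction = cfg$freq_reduction)
    g_fakeA <- g_fakeA + array(w$lambda_fB * gfreq, dim(g_fakeA))
  }
  gF2 <- gen_bwd(state$F, f2$cache, g_fakeA)

  gradsG <- grads_add(gG1$grads, gG2$grads)
  gradsF <- grads_add(fb_cyc$grads, gF2$grads)

  it <- state$iteration + 1L
  lrG <- lr_schedule(it, cfg$total_iterations, cfg$lr_generator)
  lrD <- lr_schedule(it, cfg$total_iterations, cfg$lr_discriminator)
  up <- adam_update(state$G$net, gradsG, state$optG, lrG,
                    cfg$optimizer_betas)
  state$G$net <- up$net; state$optG <- up$state
  up <- adam_update(state$F$net, gradsF, state$optF, lrG,
                    cfg$optimizer_betas)
  state$F$net <- up$net; state$optF <- up$state

  # --- discriminator updates with pooled (detached) fakes ---
  pb <- pool_query(state$poolB, fakeB, cfg$image_pool_size)
  state$poolB <- pb$pool
  pa <- pool_query(state$poolA, fakeA, cfg$image_pool_size)
  state$poolA <- pa$pool

  upd_disc <- function(disc, opt, real, fake) {
    fr <- disc_fwd(disc, real)
    ff <- disc_fwd(disc, fake)
    terms <- disc_adv_terms(fr$y, ff$y, variant)
    gr <- disc_bwd(disc, fr$cache, array(terms$g_real, dim(fr$y)))
    gf <- disc_bwd(disc, ff$cache, array(terms$g_fake, dim(ff$y)))
    up <- adam_update(disc$net, grads_add(gr$grads, gf$grads), opt, lrD,
                      cfg$optimizer_betas)
    disc$net <- up$net
    list(disc = disc, opt = up$state, loss = terms$loss)
  }
  uy <- upd_disc(state$DY, state$optDY, realB, pb$img)
  state$DY <- uy$disc; state$optDY <- uy$opt
  ux <- upd_disc(state$DX, state$optDX, realA, pa$img)
  state$DX <- ux$disc; state$optDX <- ux$opt

  state$iteration <- it
  list(state = state, losses = losses,
       d_losses = c(D_Y = uy$loss, D_X = ux$loss))
}

#' Train a frequency-loss CycleGAN
#'
#' Drives unpaired patch-based training: at each iteration a CBCT and a CT
#' scan are drawn uniformly from their pools, preprocessed online (body
#' masking, CT field-of-view truncation, patch extraction, HU windowing to
#' `[-1, 1]`), and one [train_step()] is taken. The learning rate follows
#' [lr_schedule()]. Checkpoints are written periodically and a structured
#' loss log (one row per iteration) is kept; training is resumable from a
#' checkpoint with identical continuation of the schedule.
#'
#' @param config a [train_config()].
#' @param records data frame of scan records (CT and CBCT rows; see
#'   [scan_record()] / [read_scan_metadata()]).
#' @param out_dir directory for checkpoints and the loss log CSV; `NULL`
#'   disables writing.
#' @param resume path to a checkpoint RDS to resume from.
#' @param quiet suppress progress messages.
#' @return An object of class `cyclegan`: the trained networks, config and
#'   loss log. Methods: `print`, `summary`, `predict` (whole-volume
#'   translation), `plot` (loss curves).
#' @export
train_cyclegan <- function(config = train_config(), records, out_dir = NULL,
                           resume = NULL, quiet = FALSE) {
  cbct_pool <- records[records$modality == "CBCT", , drop = FALSE]
  ct_pool <- records[records$modality == "CT", , drop = FALSE]
  if (nrow(cbct_pool) == 0L || nrow(ct_pool) == 0L)
    stop("train_cyclegan: need at least one CT and one CBCT record",
         call. = FALSE)
  if (!is.null(resume)) {
    ck <- readRDS(resume)
    state <- ck$state
    state$config <- config  # the caller's config governs the continuation
    log <- ck$log
    if (!is.null(ck$rng)) assign(".Random.seed", ck$rng, envir = globalenv())
  } else {
    state <- init_train_state(config)
    log <- NULL
  }
  cache <- new.env(parent = emptyenv())
  logs <- list()
  start_it <- state$iteration
  for (i in seq_len(config$total_iterations - start_it)) {
    batch <- sample_unpaired_patch_pair(cbct_pool, ct_pool,
                                        patch_size = config$patch_size,
                                        cache = cache)
    norm <- function(v) clip_and_scale(v, config$clip[1], config$clip[2],
                                       "to_normalized")
    res <- train_step(state, list(cbct = norm(batch$cbct),
                                  ct = norm(batch$ct)))
    state <- res$state
    it <- state$iteration
    row <- data.frame(iteration = it,
                      lr = lr_schedule(it, config$total_iterations,
                                       config$lr_generator),
                      adv_G = res$losses$adv_G, adv_F = res$losses$adv_F,
                      cycle_A = res$losses$cycle_A,
                      cycle_B = res$losses$cycle_B,
                      freq_A = res$losses$freq_A, freq_B = res$losses$freq_B,
                      total = res$losses$total)
    logs[[length(logs) + 1L]] <- row
    if (!quiet && (it %% 10L == 0L || it == config$total_iterations))
      message(sprintf("iter %d/%d  total %.4g  cycle %.4g/%.4g", it,
                      config$total_iterations, res$losses$total,
                      res$losses$cycle_A, res$losses$cycle_B))
    if (!is.null(out_dir) &&
        (it %% config$checkpoint_every == 0L ||
           it == config$total_iterations)) {
      full_log <- do.call(rbind, c(list(log), logs))
      save_checkpoint(state, full_log,
                      file.path(out_dir, "checkpoint_latest.rds"))
    }
  }
  log <- do.call(rbind, c(list(log), logs))
  if (!is.null(out_dir))
    utils::write.csv(log, file.path(out_dir, "loss_log.csv"),
                     row.names = FALSE)
  structure(list(state = state, config = config, log = log),
            class = "cyclegan")
}

save_checkpoint <- function(state, log, path) {
  rng <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  saveRDS(list(state = state, log = log, rng = rng), path)
  invisible(path)
}

#' Load a training checkpoint as a `cyclegan` object
#'
#' @param path checkpoint RDS written during [train_cyclegan()].
#' @return A `cyclegan` object.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  structure(list(state = ck$state, config = ck$state$config, log = ck$log),
            class = "cyclegan")
}
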