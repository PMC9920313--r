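# Independent oracles and shared fixtures for the test suite.

# Naive 3D DFT written independently of the package implementation: a direct
# evaluation of the transform definition, one output bin at a time, with the
# same normalization and DC-centering conventions.
naive_dft3d <- function(x, convention = "orthonormal") {
  d <- dim(x)
  L <- d[1]; M <- d[2]; N <- d[3]
  a <- rep(0:(L - 1), times = M * N)
  b <- rep(rep(0:(M - 1), each = L), times = N)
  cc <- rep(0:(N - 1), each = L * M)
  xv <- as.vector(x)
  out <- array(complex(real = 0), d)
  for (u in 0:(L - 1)) for (v in 0:(M - 1)) for (w in 0:(N - 1))
    out[u + 1, v + 1, w + 1] <-
      sum(xv * exp(-2i * pi * (u * a / L + v * b / M + w * cc / N)))
  scale <- if (convention == "orthonormal") sqrt(L * M * N) else L * M * N
  out <- out / scale
  # recentre: DC moves to floor(n/2)+1 along each axis
  ix <- lapply(d, function(n) {
    h <- floor(n / 2)
    if (h == 0L) seq_len(n) else c((n - h + 1):n, seq_len(n - h))
  })
  out[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
}

# circular shift of a 3D array by integer offsets (dz, dy, dx)
circshift3d <- function(a, s) {
  d <- dim(a)
  a[((seq_len(d[1]) - 1 + s[1]) %% d[1]) + 1,
    ((seq_len(d[2]) - 1 + s[2]) %% d[2]) + 1,
    ((seq_len(d[3]) - 1 + s[3]) %% d[3]) + 1, drop = FALSE]
}

rand_vol <- function(d, sd = 1) array(stats::rnorm(prod(d), sd = sd), d)

# small CT/CBCT phantom pair used across training-related tests (memoised)
.fixture_env <- new.env(parent = emptyenv())

small_phantom_pair <- function() {
  hit <- .fixture_env$pair
  if (!is.null(hit)) return(hit)
  ph <- make_phantom_ct(phantom_spec(shape = c(16L, 48L, 48L),
                                     spacing = c(5, 5, 6), seed = 4L))
  cb <- degrade_to_cbct(ph$ct, degradation_spec(seed = 5L))
  out <- list(ct = ph$ct, cbct = cb, labels = ph$labels)
  .fixture_env$pair <- out
  out
}

# normalized (8, 32, 32) training patches cut from the phantom pair
smoke_patches <- function() {
  p <- small_phantom_pair()
  norm <- function(v) clip_and_scale(v, -1000, 2000, "to_normalized")
  list(ct = norm(volume3d(p$ct$data[5:12, 9:40, 9:40])),
       cbct = norm(volume3d(p$cbct$data[5:12, 9:40, 9:40])))
}

smoke_config <- function(structure = "frequency_l1", seed = 11L,
                         iterations = 50L) {
  train_config(patch_size = c(8L, 32L, 32L),
               generator = generator_spec(base_filters = 4L),
               discriminator = discriminator_spec(base_filters = 8L),
               total_iterations = iterations, seed = seed,
               structure = structure)
}

# run `iterations` identical-batch training steps; returns the per-step loss
# log and the final state
run_smoke_training <- function(structure, seed = 11L, iterations = 50L) {
  cfg <- smoke_config(structure = structure, seed = seed,
                      iterations = iterations)
  patches <- smoke_patches()
  set.seed(seed)
  state <- freqgan:::init_train_state(cfg)
  rows <- vector("list", iterations)
  for (i in seq_len(iterations)) {
    res <- train_step(state, list(cbct = patches$cbct, ct = patches$ct))
    state <- res$state
    rows[[i]] <- unlist(res$losses)
  }
  list(log = do.call(rbind, rows), state = state, patches = patches)
}
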