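#' @export
print.cyclegan <- function(x, ...) {
  cat("<cyclegan> trained for ", x$state$iteration, "/",
      x$config$total_iterations, " iterations\n", sep = "")
  cat("  structure loss:", x$config$structure, "\n")
  cat("  generator:", n_params(x$state$G$net), "parameters;",
      "discriminator:", n_params(x$state$DY$net), "parameters\n")
  invisible(x)
}

#' Summarize a trained translation model
#'
#' @param object a `cyclegan` fit.
#' @param last average the loss terms over the last `last` logged iterations.
#' @param ... unused.
#' @export
summary.cyclegan <- function(object, last = 50L, ...) {
  log <- object$log
  tail_log <- utils::tail(log, last)
  out <- list(iterations = object$state$iteration,
              config = object$config,
              recent_means = colMeans(tail_log[, setdiff(names(tail_log),
                                                         "iteration")]))
  class(out) <- "summary.cyclegan"
  out
}

#' @export
print.summary.cyclegan <- function(x, ...) {
  cat("CycleGAN with", x$config$structure, "structure loss —",
      x$iterations, "iterations\n")
  cat("mean losses over recent iterations:\n")
  print(round(x$recent_means, 5))
  invisible(x)
}

#' @export
plot.cyclegan <- function(x, terms = c("cycle_A", "cycle_B", "freq_A",
                                       "freq_B"), ...) {
  log <- x$log
  terms <- intersect(terms, names(log))
  ylim <- range(unlist(log[terms]), finite = TRUE)
  graphics::plot(log$iteration, log[[terms[1]]], type = "l", ylim = ylim,
                 xlab = "iteration", ylab = "loss", col = 1, ...)
  if (length(terms) > 1)
    for (i in seq_along(terms)[-1])
      graphics::lines(log$iteration, log[[terms[i]]], col = i)
  graphics::legend("topright", legend = terms, col = seq_along(terms),
                   lty = 1, bty = "n")
  invisible(x)
}

#' @export
predict.cyclegan <- function(object, newdata,
                             direction = c("cbct_to_ct", "ct_to_cbct"), ...) {
  translate(newdata, object, direction = match.arg(direction), ...)
}

# separable raised-cosine tile weight, strictly positive
tile_weight <- function(size_zyx) {
  w1 <- function(n) {
    if (n == 1L) return(1)
    0.05 + 0.95 * sin(pi * (seq_len(n) - 0.5) / n)^2
  }
  wz <- w1(size_zyx[1]); wy <- w1(size_zyx[2]); wx <- w1(size_zyx[3])
  array(outer(outer(wz, wy), wx), size_zyx)
}

# tile start positions covering [1, n] with patches of length p, overlap ov
tile_starts <- function(n, p, ov) {
  if (p >= n) return(1L)
  step <- max(1L, p - ov)
  s <- seq(1L, n - p, by = step)
  unique(c(s, n - p + 1L))
}

#' Translate a whole volume through a trained generator
#'
#' Applies the generator to overlapping sliding-window patches and blends
#' the results with smooth per-tile weights normalized to sum to one at
#' every voxel (a partition of unity). The input is windowed to `[-1, 1]`
#' with the model's HU clip window before the network, and the output is
#' mapped back to the HU scale; spacing and origin are copied from the
#' input.
#'
#' @param vol a [volume3d] on the HU scale.
#' @param model a trained `cyclegan` fit, or (for testing pipelines) a plain
#'   function mapping a normalized 3D patch array to a same-shape array.
#' @param direction `"cbct_to_ct"` (apply G) or `"ct_to_cbct"` (apply F).
#' @param patch_size integer `(z, x, y)` tile shape; defaults to the model's
#'   training patch, capped to the volume size (rounded to admissible
#'   multiples).
#' @param overlap integer overlap between neighbouring tiles, in voxels.
#' @param clip HU window; defaults to the model's training window.
#' @return A [volume3d] on the HU scale with the input's metadata.
#' @export
translate <- function(vol, model, direction = c("cbct_to_ct", "ct_to_cbct"),
                      patch_size = NULL, overlap = 4L, clip = NULL) {
  direction <- match.arg(direction)
  vol <- as_volume3d(vol)
  if (inherits(model, "cyclegan")) {
    net <- if (direction == "cbct_to_ct") model$state$G else model$state$F
    fun <- function(p) network_forward(net, p)
    if (is.null(clip)) clip <- model$config$clip
    if (is.null(patch_size)) patch_size <- model$config$patch_size
  } else if (is.function(model)) {
    fun <- model
    if (is.null(clip)) clip <- c(-1000, 2000)
  } else {
    stop("translate: `model` must be a cyclegan fit or a function",
         call. = FALSE)
  }
  d <- dim(vol$data)  # (z, y, x)
  if (is.null(patch_size)) patch_size <- c(d[1], d[3], d[2])
  size_zyx <- pmin(as.integer(c(patch_size[1], patch_size[3],
                                patch_size[2])), d)
  if (inherits(model, "cyclegan")) {
    # keep tile shape admissible for the generator
    size_zyx[1] <- max(4L, (size_zyx[1] %/% 4L) * 4L)
    size_zyx[2:3] <- pmax(16L, (size_zyx[2:3] %/% 16L) * 16L)
    if (any(size_zyx > d))
      stop("translate: volume (", paste(d, collapse = "x"),
           ") smaller than the minimal admissible tile (",
           paste(size_zyx, collapse = "x"), ")", call. = FALSE)
  }
  norm <- clip_and_scale(vol, clip[1], clip[2], "to_normalized")
  acc <- array(0, d)
  wacc <- array(0, d)
  w <- tile_weight(size_zyx)
  sz <- tile_starts(d[1], size_zyx[1], overlap)
  sy <- tile_starts(d[2], size_zyx[2], overlap)
  sx <- tile_starts(d[3], size_zyx[3], overlap)
  for (iz in sz) for (iy in sy) for (ix in sx) {
    rz <- iz:(iz + size_zyx[1] - 1L)
    ry <- iy:(iy + size_zyx[2] - 1L)
    rx <- ix:(ix + size_zyx[3] - 1L)
    patch <- norm$data[rz, ry, rx, drop = FALSE]
    out <- fun(patch)
    out <- array(out, size_zyx)
    acc[rz, ry, rx] <- acc[rz, ry, rx] + w * out
    wacc[rz, ry, rx] <- wacc[rz, ry, rx] + w
  }
  blended <- acc / wacc
  blended <- pmin(pmax(blended, -1), 1)
  res <- clip_and_scale(volume3d(array(blended, d), spacing = vol$spacing,
                                 origin = vol$origin,
                                 scale_tag = "normalized"),
                        clip[1], clip[2], "to_hu")
  res
}

# normalized blending weights at every voxel (they sum to one by
# construction); exposed for validation of the tiling scheme
blend_weight_sum <- function(dims, patch_zyx, overlap = 4L) {
  wacc <- array(0, dims)
  w <- tile_weight(patch_zyx)
  sz <- tile_starts(dims[1], patch_zyx[1], overlap)
  sy <- tile_starts(dims[2], patch_zyx[2], overlap)
  sx <- tile_starts(dims[3], patch_zyx[3], overlap)
  for (iz in sz) for (iy in sy) for (ix in sx) {
    rz <- iz:(iz + patch_zyx[1] - 1L)
    ry <- iy:(iy + patch_zyx[2] - 1L)
    rx <- ix:(ix + patch_zyx[3] - 1L)
    wacc[rz, ry, rx] <- wacc[rz, ry, rx] + w
  }
  # each tile's effective weight at a voxel is w / wacc; summed over tiles
  # covering the voxel this is exactly 1 wherever wacc > 0
  wacc
}
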