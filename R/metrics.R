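metric_arrays <- function(ref, pred, mask = NULL, what = "metric") {
  a <- if (is_volume3d(ref)) ref$data else ref
  b <- if (is_volume3d(pred)) pred$data else pred
  if (!identical(dim(a), dim(b)))
    stop(what, ": shape mismatch: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), call. = FALSE)
  if (!is.null(mask)) {
    m <- if (inherits(mask, "body_mask")) mask$data else mask
    if (!identical(dim(m), dim(a)))
      stop(what, ": mask shape mismatch", call. = FALSE)
    if (!any(m))
      stop(what, ": mask is empty", call. = FALSE)
    a <- a[m]; b <- b[m]
  }
  list(ref = as.numeric(a), pred = as.numeric(b))
}

#' Mean absolute error
#'
#' `(1/N) * sum(|ref - pred|)` over all (in-mask) voxels, in HU when the
#' inputs are HU.
#'
#' @param ref,pred shape-congruent [volume3d]s or 3D arrays; `ref` is the
#'   ground-truth CT by convention.
#' @param mask optional [body_mask] restricting the voxels considered.
#' @return A scalar.
#' @export
mae <- function(ref, pred, mask = NULL) {
  v <- metric_arrays(ref, pred, mask, "mae")
  mean(abs(v$ref - v$pred))
}

#' Mean squared error
#'
#' `(1/N) * sum((ref - pred)^2)`, in HU squared.
#'
#' @inheritParams mae
#' @return A scalar.
#' @export
mse <- function(ref, pred, mask = NULL) {
  v <- metric_arrays(ref, pred, mask, "mse")
  mean((v$ref - v$pred)^2)
}

#' Normalized mean squared error
#'
#' `sum((ref - pred)^2) / sum(ref^2)` — the squared error normalized by the
#' signal power (note the numerator is not divided by N). Invariant to
#' simultaneous rescaling of both inputs; equals 1 when `pred` is all zero.
#'
#' @inheritParams mae
#' @return A dimensionless scalar.
#' @export
nmse <- function(ref, pred, mask = NULL) {
  v <- metric_arrays(ref, pred, mask, "nmse")
  denom <- sum(v$ref^2)
  if (denom == 0)
    stop("nmse: reference has zero signal power", call. = FALSE)
  sum((v$ref - v$pred)^2) / denom
}

#' Peak signal-to-noise ratio
#'
#' `20*log10(ref_max) - 10*log10(MSE)` in dB, with `ref_max` the maximum of
#' the (masked) reference. A perfect prediction (zero MSE) yields `Inf`.
#'
#' @inheritParams mae
#' @return A scalar in dB (possibly `Inf`).
#' @export
psnr <- function(ref, pred, mask = NULL) {
  v <- metric_arrays(ref, pred, mask, "psnr")
  m <- mean((v$ref - v$pred)^2)
  ref_max <- max(v$ref)
  if (m == 0) return(Inf)
  if (ref_max <= 0)
    stop("psnr: reference maximum must be positive", call. = FALSE)
  20 * log10(ref_max) - 10 * log10(m)
}

# box-filtered local means over valid windows, separable cumsum per axis
box_mean3d <- function(a, w) {
  for (axis in 1:3) {
    d <- dim(a)
    if (d[axis] < w)
      stop("ssim: window (", w, ") larger than volume axis (", d[axis], ")",
           call. = FALSE)
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    b <- aperm(a, perm)
    db <- dim(b)
    m <- matrix(b, db[1], db[2] * db[3])
    cs <- rbind(0, apply(m, 2, cumsum))
    sm <- (cs[(w + 1):(db[1] + 1), , drop = FALSE] -
             cs[1:(db[1] - w + 1), , drop = FALSE]) / w
    b <- array(sm, c(db[1] - w + 1, db[2], db[3]))
    a <- aperm(b, order(perm))
  }
  a
}

#' Structural similarity index
#'
#' Evaluates the SSIM formula
#' `((2*mu_x*mu_y + c1) * (2*sigma_xy + c2)) /
#'  ((mu_x^2 + mu_y^2 + c1) * (sigma_x^2 + sigma_y^2 + c2))`
#' with `c1 = (0.01*R)^2`, `c2 = (0.03*R)^2` for data range `R`.
#' `mode = "global"` computes it once from whole-volume moments;
#' `mode = "windowed"` (default) averages the local SSIM map over sliding
#' cubic windows, the common IQA practice for volumes. In windowed mode an
#' optional mask restricts the average to windows centred in the mask.
#'
#' @inheritParams mae
#' @param mode `"windowed"` (default) or `"global"`.
#' @param data_range dynamic range `R`; default 3000 (the evaluation clip
#'   width).
#' @param window cubic window side for windowed mode (default 7).
#' @return A scalar `<= 1`.
#' @export
ssim <- function(ref, pred, mask = NULL, mode = c("windowed", "global"),
                 data_range = 3000, window = 7L) {
  mode <- match.arg(mode)
  a <- if (is_volume3d(ref)) ref$data else ref
  b <- if (is_volume3d(pred)) pred$data else pred
  if (!identical(dim(a), dim(b)))
    stop("ssim: shape mismatch", call. = FALSE)
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  if (mode == "global") {
    v <- metric_arrays(a, b, mask, "ssim")
    mu_x <- mean(v$ref); mu_y <- mean(v$pred)
    vx <- mean((v$ref - mu_x)^2); vy <- mean((v$pred - mu_y)^2)
    cxy <- mean((v$ref - mu_x) * (v$pred - mu_y))
    return(((2 * mu_x * mu_y + c1) * (2 * cxy + c2)) /
             ((mu_x^2 + mu_y^2 + c1) * (vx + vy + c2)))
  }
  w <- as.integer(window)
  mu_x <- box_mean3d(a, w); mu_y <- box_mean3d(b, w)
  xx <- box_mean3d(a * a, w); yy <- box_mean3d(b * b, w)
  xy <- box_mean3d(a * b, w)
  vx <- xx - mu_x^2; vy <- yy - mu_y^2; cxy <- xy - mu_x * mu_y
  smap <- ((2 * mu_x * mu_y + c1) * (2 * cxy + c2)) /
    ((mu_x^2 + mu_y^2 + c1) * (vx + vy + c2))
  if (!is.null(mask)) {
    m <- if (inherits(mask, "body_mask")) mask$data else mask
    off <- (w - 1L) %/% 2L
    d <- dim(smap)
    centres <- m[off + seq_len(d[1]), off + seq_len(d[2]),
                 off + seq_len(d[3]), drop = FALSE]
    if (!any(centres)) stop("ssim: mask covers no window centres",
                            call. = FALSE)
    return(mean(smap[centres]))
  }
  mean(smap)
}

#' Dice overlap between two masks
#'
#' `2|A intersect B| / (|A| + |B|)`; 1 when both masks are empty.
#'
#' @param mask_a,mask_b shape-congruent [body_mask]s or logical arrays.
#' @return A scalar in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  a <- if (inherits(mask_a, "body_mask")) mask_a$data else mask_a
  b <- if (inherits(mask_b, "body_mask")) mask_b$data else mask_b
  if (!identical(dim(a), dim(b)))
    stop("dice: shape mismatch", call. = FALSE)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' HU intensity histogram
#'
#' Counts voxels over uniform bins on `[lo, hi)`; out-of-range voxels are
#' excluded, so the counts sum to the number of in-range (in-mask) voxels.
#' The default range (-500, 500) is the soft-tissue window used for
#' distribution comparisons between CT, CBCT and translated scans.
#'
#' @param vol a [volume3d].
#' @param lo,hi histogram range in HU, `lo < hi`.
#' @param bins number of bins (>= 1).
#' @param mask optional [body_mask].
#' @return A list with `breaks` (length `bins + 1`), `mids` and `counts`.
#' @export
hu_histogram <- function(vol, lo = -500, hi = 500, bins = 100L,
                         mask = NULL) {
  if (lo >= hi) stop("hu_histogram: need lo < hi", call. = FALSE)
  if (bins < 1L) stop("hu_histogram: need at least one bin", call. = FALSE)
  x <- if (is_volume3d(vol)) vol$data else vol
  if (!is.null(mask)) {
    m <- as_mask_array(mask)
    x <- x[m]
  }
  x <- x[x >= lo & x < hi]
  breaks <- seq(lo, hi, length.out = bins + 1L)
  counts <- tabulate(pmin(findInterval(x, breaks), bins), nbins = bins)
  list(breaks = breaks, mids = (breaks[-1] + breaks[-(bins + 1L)]) / 2,
       counts = counts)
}

#' HU line profile across an axial slice
#'
#' Samples HU values at `n_samples` equally spaced points along the segment
#' from `start` to `end` (in-plane `(x, y)` voxel coordinates, 1-based) of
#' one axial slice, with bilinear in-plane interpolation — e.g. a line
#' passing through heart, lung, muscle and bone for calibration inspection.
#'
#' @param vol a [volume3d].
#' @param axial_slice z index of the slice (1-based).
#' @param start,end numeric length-2 `(x, y)` endpoints inside the slice.
#' @param n_samples number of samples (>= 2, or 1 if start equals end).
#' @return Numeric vector of sampled intensities.
#' @export
line_profile <- function(vol, axial_slice, start, end, n_samples = 100L) {
  x <- if (is_volume3d(vol)) vol$data else vol
  d <- dim(x)
  if (axial_slice < 1 || axial_slice > d[1])
    stop("line_profile: axial_slice out of bounds", call. = FALSE)
  pts <- rbind(start, end)
  if (any(pts[, 1] < 1 | pts[, 1] > d[3] | pts[, 2] < 1 | pts[, 2] > d[2]))
    stop("line_profile: endpoints outside slice bounds", call. = FALSE)
  t <- if (n_samples == 1L) 0 else seq(0, 1, length.out = n_samples)
  px <- start[1] + t * (end[1] - start[1])
  py <- start[2] + t * (end[2] - start[2])
  slice <- x[axial_slice, , ]  # (y, x)
  x0 <- pmin(floor(px), d[3] - 1); y0 <- pmin(floor(py), d[2] - 1)
  fx <- px - x0; fy <- py - y0
  v00 <- slice[cbind(y0, x0)]; v01 <- slice[cbind(y0, x0 + 1)]
  v10 <- slice[cbind(y0 + 1, x0)]; v11 <- slice[cbind(y0 + 1, x0 + 1)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

#' Evaluate a reference/prediction pair with one consistent convention
#'
#' Clips both volumes to the evaluation range (default `[0, 3000]` HU),
#' optionally applies a mask, and computes MAE, MSE, NMSE, PSNR and SSIM.
#' The clipping and masking convention is recorded in the report so results
#' from different runs are comparable.
#'
#' @inheritParams mae
#' @param clip_range evaluation HU window, default `c(0, 3000)`.
#' @param ssim_mode,ssim_window passed to [ssim()]; the SSIM data range is
#'   the clip width.
#' @param dice_masks optional named list of `(a, b)` mask pairs; each
#'   contributes a Dice entry.
#' @return An object of class `metric_report`.
#' @export
evaluate_pair <- function(ref, pred, mask = NULL, clip_range = c(0, 3000),
                          ssim_mode = "windowed", ssim_window = 7L,
                          dice_masks = NULL) {
  clipv <- function(v) {
    x <- if (is_volume3d(v)) v$data else v
    array(pmin(pmax(x, clip_range[1]), clip_range[2]), dim(x))
  }
  a <- clipv(ref); b <- clipv(pred)
  rep <- list(mae = mae(a, b, mask), mse = mse(a, b, mask),
              nmse = nmse(a, b, mask), psnr = psnr(a, b, mask),
              ssim = ssim(a, b, mask, mode = ssim_mode,
                          data_range = diff(clip_range),
                          window = ssim_window),
              clip_range = clip_range, mask_used = !is.null(mask),
              ssim_mode = ssim_mode)
  if (!is.null(dice_masks))
    rep$dice_per_label <- vapply(dice_masks,
                                 function(p) dice(p[[1]], p[[2]]),
                                 numeric(1))
  structure(rep, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>  clip [", x$clip_range[1], ", ", x$clip_range[2],
      "] HU, mask ", if (x$mask_used) "applied" else "not applied",
      ", SSIM ", x$ssim_mode, "\n", sep = "")
  cat(sprintf("  MAE %.4g  MSE %.4g  NMSE %.4g  PSNR %.4g dB  SSIM %.4g\n",
              x$mae, x$mse, x$nmse, x$psnr, x$ssim))
  if (!is.null(x$dice_per_label)) {
    cat("  Dice:", paste(names(x$dice_per_label),
                         round(x$dice_per_label, 4), collapse = "  "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.metric_report <- function(x, ...) {
  data.frame(mae = x$mae, mse = x$mse, nmse = x$nmse, psnr = x$psnr,
             ssim = x$ssim, clip_lo = x$clip_range[1],
             clip_hi = x$clip_range[2], mask_used = x$mask_used)
}
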