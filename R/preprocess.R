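#' Resample a volume to a target voxel spacing
#'
#' Resamples onto a new grid whose shape is
#' `round(old_shape * old_spacing / target_spacing)` (at least 1 per axis),
#' sampling at output voxel centres. Intensity volumes use trilinear
#' interpolation; masks and label maps should use nearest-neighbour to avoid
#' label bleeding. Resampling to the volume's own spacing is voxel-exact.
#'
#' @param vol a [volume3d].
#' @param target_spacing numeric length-3, `(x, y, z)` mm, strictly positive.
#' @param interpolation `"linear"` (default) or `"nearest"`.
#' @return A [volume3d] on the new grid; origin is preserved.
#' @export
resample_to_spacing <- function(vol, target_spacing,
                                interpolation = c("linear", "nearest")) {
  vol <- as_volume3d(vol)
  interpolation <- match.arg(interpolation)
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(!is.finite(target_spacing)) ||
      any(target_spacing <= 0))
    stop("resample_to_spacing: target spacing must be 3 positive numbers",
         call. = FALSE)
  d <- dim(vol$data)                         # (z, y, x)
  n_in <- c(d[3], d[2], d[1])                # (x, y, z)
  n_out <- pmax(1L, as.integer(round(n_in * vol$spacing / target_spacing)))
  # fractional input index (0-based) of each output voxel centre, per axis
  idx <- lapply(1:3, function(a) {
    pos <- (seq_len(n_out[a]) - 1) * target_spacing[a]  # mm from first centre
    pmin(pmax(pos / vol$spacing[a], 0), n_in[a] - 1)
  })
  arr <- resample_grid(vol$data, idx_x = idx[[1]], idx_y = idx[[2]],
                       idx_z = idx[[3]], interpolation = interpolation)
  volume3d(arr, spacing = target_spacing, origin = vol$origin,
           scale_tag = vol$scale_tag)
}

# Sample `data` (z,y,x) at the grid given by 0-based fractional indices along
# each axis; returns array of dim (length(idx_z), length(idx_y), length(idx_x)).
resample_grid <- function(data, idx_x, idx_y, idx_z,
                          interpolation = "linear") {
  d <- dim(data)
  if (interpolation == "nearest") {
    iz <- as.integer(round(idx_z)) + 1L
    iy <- as.integer(round(idx_y)) + 1L
    ix <- as.integer(round(idx_x)) + 1L
    return(data[iz, iy, ix, drop = FALSE])
  }
  f <- function(idx, n) {
    lo <- pmin(floor(idx), n - 1)
    list(lo = as.integer(lo) + 1L, hi = as.integer(pmin(lo + 1, n - 1)) + 1L,
         w = idx - lo)
  }
  z <- f(idx_z, d[1]); y <- f(idx_y, d[2]); x <- f(idx_x, d[3])
  nz <- length(idx_z); ny <- length(idx_y); nx <- length(idx_x)
  wz <- array(z$w, c(nz, ny, nx))
  wy <- array(rep(y$w, each = nz), c(nz, ny, nx))
  wx <- array(rep(x$w, each = nz * ny), c(nz, ny, nx))
  g <- function(zi, yi, xi) data[zi, yi, xi, drop = FALSE]
  c000 <- g(z$lo, y$lo, x$lo); c100 <- g(z$hi, y$lo, x$lo)
  c010 <- g(z$lo, y$hi, x$lo); c110 <- g(z$hi, y$hi, x$lo)
  c001 <- g(z$lo, y$lo, x$hi); c101 <- g(z$hi, y$lo, x$hi)
  c011 <- g(z$lo, y$hi, x$hi); c111 <- g(z$hi, y$hi, x$hi)
  (1 - wx) * ((1 - wy) * ((1 - wz) * c000 + wz * c100) +
                wy * ((1 - wz) * c010 + wz * c110)) +
    wx * ((1 - wy) * ((1 - wz) * c001 + wz * c101) +
            wy * ((1 - wz) * c011 + wz * c111))
}

#' Derive a patient body mask from a CT-scale volume
#'
#' Thresholds the volume above `air_threshold`, keeps the largest
#' 26-connected 3D component, and fills holes slice-by-slice in the axial
#' plane (holes are background regions not reachable from the slice border).
#' This is the standard CT body-masking heuristic.
#'
#' @param vol a [volume3d] on the HU scale.
#' @param air_threshold HU threshold separating body from air; default -300.
#' @return A [body_mask].
#' @export
compute_body_mask <- function(vol, air_threshold = -300) {
  vol <- as_volume3d(vol)
  if (vol$scale_tag != "hu")
    stop("compute_body_mask: volume must be on the HU scale", call. = FALSE)
  fg <- vol$data > air_threshold
  if (!any(fg))
    stop("compute_body_mask: no voxel above ", air_threshold,
         " HU; mask would be empty", call. = FALSE)
  comp <- largest_component_26(fg)
  body_mask(fill_holes_axial(comp))
}

# shift a 3D logical/numeric array by (dz, dy, dx), padding with `fill`
shift3d <- function(a, dz, dy, dx, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  src_z <- seq_len(d[1]) - dz; src_y <- seq_len(d[2]) - dy
  src_x <- seq_len(d[3]) - dx
  okz <- src_z >= 1 & src_z <= d[1]; oky <- src_y >= 1 & src_y <= d[2]
  okx <- src_x >= 1 & src_x <= d[3]
  if (!any(okz) || !any(oky) || !any(okx)) return(out)
  out[which(okz), which(oky), which(okx)] <-
    a[src_z[okz], src_y[oky], src_x[okx], drop = FALSE]
  out
}

# vectorized-frontier BFS over the TRUE voxels of `fg` from linear-index
# seeds, using the given (dz, dy, dx) neighbourhood offsets; returns a
# logical vector over linear indices marking reached voxels
flood_reach <- function(fg, seeds, offs) {
  d <- dim(fg)
  v <- as.vector(fg)
  seeds <- seeds[v[seeds]]
  reached <- logical(length(v))
  reached[seeds] <- TRUE
  # 0-based coordinates of every voxel, computed once
  idx0 <- seq_along(v) - 1L
  zc <- idx0 %% d[1]
  yc <- (idx0 %/% d[1]) %% d[2]
  xc <- idx0 %/% (d[1] * d[2])
  frontier <- seeds
  lin_off <- offs[, 1] + d[1] * offs[, 2] + d[1] * d[2] * offs[, 3]
  while (length(frontier)) {
    nxt <- integer(0)
    for (k in seq_len(nrow(offs))) {
      ok <- zc[frontier] + offs[k, 1] >= 0L & zc[frontier] + offs[k, 1] < d[1] &
            yc[frontier] + offs[k, 2] >= 0L & yc[frontier] + offs[k, 2] < d[2] &
            xc[frontier] + offs[k, 3] >= 0L & xc[frontier] + offs[k, 3] < d[3]
      cand <- frontier[ok] + lin_off[k]
      cand <- cand[v[cand] & !reached[cand]]
      if (length(cand)) {
        reached[cand] <- TRUE
        nxt <- c(nxt, cand)
      }
    }
    frontier <- unique(nxt)
  }
  reached
}

offsets_26 <- local({
  g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
})

offsets_4_inplane <- matrix(c(0L, 1L, 0L,  0L, -1L, 0L,
                              0L, 0L, 1L,  0L, 0L, -1L),
                            ncol = 3, byrow = TRUE)

# largest 26-connected component of a logical 3D array
largest_component_26 <- function(fg) {
  v <- as.vector(fg)
  remaining <- which(v)
  best <- integer(0)
  seen <- logical(length(v))
  while (length(remaining)) {
    seed <- remaining[1]
    comp <- flood_reach(fg, seed, offsets_26)
    members <- which(comp)
    if (length(members) > length(best)) best <- members
    seen[members] <- TRUE
    remaining <- remaining[!seen[remaining]]
  }
  keep <- array(FALSE, dim(fg))
  keep[best] <- TRUE
  keep
}

# fill holes per axial (z) slice: background 4-connected (in-plane) to the
# slice border stays background, enclosed background becomes foreground
fill_holes_axial <- function(mask) {
  d <- dim(mask)
  bg <- !mask
  border <- array(FALSE, d)
  border[, 1, ] <- TRUE; border[, d[2], ] <- TRUE
  border[, , 1] <- TRUE; border[, , d[3]] <- TRUE
  seeds <- which(as.vector(border & bg))
  reach <- flood_reach(bg, seeds, offsets_4_inplane)
  out <- mask
  out[as.vector(bg) & !reach] <- TRUE
  out
}

#' Mask a volume, filling outside voxels
#'
#' @param vol a [volume3d].
#' @param mask a [body_mask] shape-congruent with `vol`.
#' @param fill_value intensity assigned outside the mask; default -1000 HU
#'   (air).
#' @return A [volume3d] with out-of-mask voxels set to `fill_value`.
#' @export
apply_mask <- function(vol, mask, fill_value = -1000) {
  vol <- as_volume3d(vol)
  m <- as_mask_array(mask, ref = vol)
  out <- vol$data
  out[!m] <- fill_value
  volume3d(out, spacing = vol$spacing, origin = vol$origin,
           scale_tag = vol$scale_tag)
}

#' Truncate a CT's field of view to match a CBCT's
#'
#' Crops (and air-pads where the CBCT grid extends beyond the CT) the CT so
#' that its physical extent equals the CBCT's, using
#' `origin + spacing * shape` arithmetic in millimetres. Both volumes are
#' expected on a common spacing; the output lies on the CT grid shifted to
#' the CBCT's extent.
#'
#' @param ct reference [volume3d] to be truncated.
#' @param cbct [volume3d] whose field of view defines the target extent.
#' @param fill_value padding intensity where the CBCT extends beyond the CT;
#'   default -1000 HU.
#' @return A [volume3d] whose physical extent equals the CBCT's within half a
#'   voxel per axis.
#' @export
truncate_fov <- function(ct, cbct, fill_value = -1000) {
  ct <- as_volume3d(ct); cbct <- as_volume3d(cbct)
  ext_ct <- volume_extent(ct); ext_cb <- volume_extent(cbct)
  if (any(ext_cb["lo", ] >= ext_ct["hi", ] | ext_cb["hi", ] <= ext_ct["lo", ]))
    stop("truncate_fov: CT and CBCT extents do not overlap", call. = FALSE)
  d_cb <- dim(cbct$data)
  n_out_xyz <- as.integer(round(c(d_cb[3], d_cb[2], d_cb[1]) *
                                  cbct$spacing / ct$spacing))
  i0_xyz <- as.integer(round((cbct$origin - ct$origin) / ct$spacing))  # 0-based
  d_ct <- dim(ct$data)
  n_ct_xyz <- c(d_ct[3], d_ct[2], d_ct[1])
  out <- array(fill_value, c(n_out_xyz[3], n_out_xyz[2], n_out_xyz[1]))
  # overlap range per axis, 0-based in output coords
  lo <- pmax(0L, -i0_xyz)
  hi <- pmin(n_out_xyz, n_ct_xyz - i0_xyz) - 1L
  if (any(hi < lo))
    stop("truncate_fov: CT and CBCT extents do not overlap", call. = FALSE)
  oz <- (lo[3]:hi[3]) + 1L; oy <- (lo[2]:hi[2]) + 1L; ox <- (lo[1]:hi[1]) + 1L
  out[oz, oy, ox] <- ct$data[oz + i0_xyz[3], oy + i0_xyz[2], ox + i0_xyz[1],
                             drop = FALSE]
  volume3d(out, spacing = ct$spacing,
           origin = ct$origin + i0_xyz * ct$spacing,
           scale_tag = ct$scale_tag)
}

#' Window HU intensities and map to/from the network range
#'
#' `to_normalized` clips intensities to `[clip_lo, clip_hi]` and maps that
#' window linearly onto `[-1, 1]` (the range expected by the tanh-bounded
#' generator). `to_hu` inverts the map exactly on in-range data.
#'
#' @param vol a [volume3d].
#' @param clip_lo,clip_hi HU window; `clip_lo < clip_hi`. Defaults
#'   `[-1000, 2000]`, the training window.
#' @param direction `"to_normalized"` or `"to_hu"`.
#' @return A [volume3d] with the matching `scale_tag`.
#' @export
clip_and_scale <- function(vol, clip_lo = -1000, clip_hi = 2000,
                           direction = c("to_normalized", "to_hu")) {
  vol <- as_volume3d(vol)
  direction <- match.arg(direction)
  if (!is.finite(clip_lo) || !is.finite(clip_hi) || clip_lo >= clip_hi)
    stop("clip_and_scale: need clip_lo < clip_hi", call. = FALSE)
  if (direction == "to_normalized") {
    x <- pmin(pmax(vol$data, clip_lo), clip_hi)
    y <- 2 * (x - clip_lo) / (clip_hi - clip_lo) - 1
    volume3d(array(y, dim(vol$data)), spacing = vol$spacing,
             origin = vol$origin, scale_tag = "normalized")
  } else {
    r <- range(vol$data)
    if (r[1] < -1 - 1e-6 || r[2] > 1 + 1e-6)
      stop("clip_and_scale: to_hu input must lie in [-1, 1]; range is [",
           signif(r[1], 6), ", ", signif(r[2], 6), "]", call. = FALSE)
    x <- pmin(pmax(vol$data, -1), 1)
    y <- (x + 1) / 2 * (clip_hi - clip_lo) + clip_lo
    volume3d(array(y, dim(vol$data)), spacing = vol$spacing,
             origin = vol$origin, scale_tag = "hu")
  }
}
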