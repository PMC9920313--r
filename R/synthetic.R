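#' Specification of the synthetic anthropomorphic phantom
#'
#' Describes a CT-like thorax phantom: an ellipsoidal body containing two
#' ellipsoidal lungs, a heart ellipsoid, rib-like bone arcs plus a spine
#' column, and an optional spherical tumor inside the right lung. Voxel
#' intensities are the HU target of the deepest enclosing structure plus a
#' small Gaussian texture.
#'
#' Default organ HU targets follow standard tissue ranges: body (soft
#' tissue) 40, lung -750, bone 700, heart 50, tumor 30, air -1000.
#'
#' @param shape integer `(z, y, x)` voxel grid (default `c(48, 96, 96)`).
#' @param spacing `(x, y, z)` mm (default `c(3, 3, 4)`, a coarse thorax
#'   field of view of roughly 288 x 288 x 192 mm).
#' @param hu named numeric vector of organ HU targets with entries `body`,
#'   `lung`, `bone`, `heart`, `tumor`, `air`.
#' @param tumor `NULL` for no tumor, or a list with `center` (normalized
#'   `(z, y, x)` position in `[-1, 1]` body coordinates) and `radius`
#'   (fraction of the in-plane body semi-axis; 0 disables the tumor).
#' @param texture_sd HU standard deviation of the texture noise (default 10).
#' @param seed integer seed; the phantom is a deterministic function of
#'   `(spec, seed)`.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(48L, 96L, 96L), spacing = c(3, 3, 4),
                         hu = c(body = 40, lung = -750, bone = 700,
                                heart = 50, tumor = 30, air = -1000),
                         tumor = list(center = c(0, -0.1, 0.45),
                                      radius = 0.12),
                         texture_sd = 10, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L))
    stop("phantom_spec: shape must be 3 integers >= 8", call. = FALSE)
  need <- c("body", "lung", "bone", "heart", "tumor", "air")
  if (!all(need %in% names(hu)))
    stop("phantom_spec: hu must name ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(hu < -1000) || any(hu > 3000))
    stop("phantom_spec: HU targets must lie in [-1000, 3000]", call. = FALSE)
  if (!is.null(tumor) && tumor$radius > 0) {
    if (tumor$radius > 0.35)
      stop("phantom_spec: tumor radius too large to fit inside a lung",
           call. = FALSE)
    if (any(abs(tumor$center) > 0.9))
      stop("phantom_spec: tumor center outside the body", call. = FALSE)
  }
  structure(list(shape = shape, spacing = as.numeric(spacing), hu = hu,
                 tumor = tumor, texture_sd = texture_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Structure ids of the phantom label map
#'
#' @return Named integer vector: air 0, body 1, lung_left 2, lung_right 3,
#'   heart 4, bone 5, tumor 6.
#' @export
phantom_labels <- function() {
  c(air = 0L, body = 1L, lung_left = 2L, lung_right = 3L, heart = 4L,
    bone = 5L, tumor = 6L)
}

#' Generate a CT-like phantom volume and its label map
#'
#' @param spec a [phantom_spec()].
#' @return A list with `ct` (a [volume3d] on the HU scale) and `labels`
#'   (integer array of structure ids, see [phantom_labels()]).
#' @export
make_phantom_ct <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  # normalized coordinates in [-1, 1] per axis
  zc <- (seq_len(d[1]) - (d[1] + 1) / 2) / (d[1] / 2)
  yc <- (seq_len(d[2]) - (d[2] + 1) / 2) / (d[2] / 2)
  xc <- (seq_len(d[3]) - (d[3] + 1) / 2) / (d[3] / 2)
  Z <- array(zc, d)
  Y <- array(rep(yc, each = d[1]), d)
  X <- array(rep(xc, each = d[1] * d[2]), d)
  ell <- function(cz, cy, cx, rz, ry, rx)
    ((Z - cz) / rz)^2 + ((Y - cy) / ry)^2 + ((X - cx) / rx)^2 <= 1
  body <- ell(0, 0, 0, 0.95, 0.72, 0.88)
  lung_l <- ell(0, -0.05, -0.42, 0.70, 0.42, 0.30)
  lung_r <- ell(0, -0.05, 0.42, 0.70, 0.42, 0.30)
  heart <- ell(-0.05, 0.12, -0.05, 0.35, 0.28, 0.24)
  # bone: rib-like arcs (a thin shell near the body surface present on
  # alternating z bands) plus a posterior spine column
  rho <- (Z / 0.95)^2 + (Y / 0.72)^2 + (X / 0.88)^2
  shell <- rho <= 1 & rho >= 0.78
  rib_band <- (floor((Z + 1) / 0.22) %% 2L) == 0L
  ribs <- shell & rib_band & Y < 0.45  # open posteriorly toward the spine
  spine <- (Y - 0.52)^2 / 0.12^2 + X^2 / 0.14^2 <= 1 & body
  lung_l <- lung_l & !heart
  lung_r <- lung_r & !heart
  labels <- array(0L, d)
  labels[body] <- 1L
  labels[ribs & body] <- 5L
  labels[spine] <- 5L
  labels[lung_l] <- 2L
  labels[lung_r] <- 3L
  labels[heart & body] <- 4L
  if (!is.null(spec$tumor) && spec$tumor$radius > 0) {
    tc <- spec$tumor$center
    tum <- ell(tc[1], tc[2], tc[3], spec$tumor$radius, spec$tumor$radius,
               spec$tumor$radius)
    tum <- tum & (labels == 2L | labels == 3L)
    labels[tum] <- 6L
  }
  hu_of <- c(spec$hu[["air"]], spec$hu[["body"]], spec$hu[["lung"]],
             spec$hu[["lung"]], spec$hu[["heart"]], spec$hu[["bone"]],
             spec$hu[["tumor"]])
  set.seed(spec$seed)
  vals <- hu_of[labels + 1L] + stats::rnorm(length(labels), 0,
                                            spec$texture_sd)
  vals <- pmax(vals, -1000)
  list(ct = volume3d(array(vals, d), spacing = spec$spacing),
       labels = labels)
}

#' Specification of the CBCT-like degradation
#'
#' The degradation chain emulating cone-beam characteristics relative to a
#' CT: affine HU miscalibration (scale then shift), in-plane radial streaks
#' (scatter/motion-artifact analogue), Gaussian blur, additive Gaussian
#' noise, and an optional smooth random deformation (set-up difference
#' analogue). A zero-everything spec is the identity.
#'
#' @param hu_shift additive HU offset (default 80).
#' @param hu_scale multiplicative factor (default 1.05).
#' @param streak_amplitude HU amplitude of the radial streak pattern
#'   (default 60).
#' @param streak_count number of angular streak periods (default 24).
#' @param blur_sigma Gaussian blur width in mm (default 1.5).
#' @param noise_sigma additive noise standard deviation in HU (default 40).
#' @param deform_amplitude maximum smooth-deformation displacement in mm
#'   (default 0).
#' @param seed integer seed; the degradation is deterministic given
#'   `(spec, seed)`.
#' @return An object of class `degradation_spec`.
#' @export
degradation_spec <- function(hu_shift = 80, hu_scale = 1.05,
                             streak_amplitude = 60, streak_count = 24L,
                             blur_sigma = 1.5, noise_sigma = 40,
                             deform_amplitude = 0, seed = 1L) {
  if (streak_amplitude < 0 || blur_sigma < 0 || noise_sigma < 0 ||
      deform_amplitude < 0 || streak_count < 0)
    stop("degradation_spec: magnitudes must be >= 0", call. = FALSE)
  structure(list(hu_shift = hu_shift, hu_scale = hu_scale,
                 streak_amplitude = streak_amplitude,
                 streak_count = as.integer(streak_count),
                 blur_sigma = blur_sigma, noise_sigma = noise_sigma,
                 deform_amplitude = deform_amplitude,
                 seed = as.integer(seed)),
            class = "degradation_spec")
}

# identity when the spec carries no degradation at all
is_identity_degradation <- function(spec)
  spec$hu_shift == 0 && spec$hu_scale == 1 && spec$streak_amplitude == 0 &&
  spec$blur_sigma == 0 && spec$noise_sigma == 0 && spec$deform_amplitude == 0

# separable 1D Gaussian convolution along each axis, sigma in voxels
gaussian_blur3d <- function(a, sigma_vox) {
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 1e-8) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r):r)^2 / (2 * s^2))
    k <- k / sum(k)
    d <- dim(a)
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    b <- aperm(a, perm)
    db <- dim(b)
    m <- matrix(b, db[1], db[2] * db[3])
    # replicate-pad then filter
    mp <- rbind(m[rep(1L, r), , drop = FALSE], m,
                m[rep(db[1], r), , drop = FALSE])
    out <- matrix(0, db[1], ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * mp[(j):(j + db[1] - 1L), , drop = FALSE]
    a <- aperm(array(out, db), order(perm))
  }
  a
}

#' Degrade a CT-like volume into a CBCT-like one
#'
#' Applies, in order: HU scale, HU shift, radial in-plane streaks, Gaussian
#' blur, additive Gaussian noise, and an optional smooth deformation.
#'
#' @param ct a [volume3d] on the HU scale.
#' @param spec a [degradation_spec()].
#' @return A [volume3d] with the same grid and metadata.
#' @export
degrade_to_cbct <- function(ct, spec = degradation_spec()) {
  ct <- as_volume3d(ct)
  stopifnot(inherits(spec, "degradation_spec"))
  if (is_identity_degradation(spec)) return(ct)
  set.seed(spec$seed)
  d <- dim(ct$data)
  x <- ct$data * spec$hu_scale + spec$hu_shift
  if (spec$streak_amplitude > 0 && spec$streak_count > 0) {
    yc <- (seq_len(d[2]) - (d[2] + 1) / 2)
    xc <- (seq_len(d[3]) - (d[3] + 1) / 2)
    ang <- atan2(outer(yc, rep(1, d[3])), outer(rep(1, d[2]), xc))
    rad <- sqrt(outer(yc^2, rep(1, d[3])) + outer(rep(1, d[2]), xc^2))
    rad <- rad / max(rad)
    phase <- stats::runif(1, 0, 2 * pi)
    streak2d <- spec$streak_amplitude *
      sin(spec$streak_count * ang + phase) * rad
    x <- x + array(rep(as.vector(streak2d), each = d[1]), d)
  }
  if (spec$blur_sigma > 0) {
    sig_vox <- spec$blur_sigma / c(ct$spacing[3], ct$spacing[2],
                                   ct$spacing[1])
    x <- gaussian_blur3d(x, sig_vox)
  }
  if (spec$noise_sigma > 0)
    x <- x + stats::rnorm(length(x), 0, spec$noise_sigma)
  if (spec$deform_amplitude > 0) {
    # low-frequency displacement field: coarse random grids upsampled
    coarse <- c(4L, 6L, 6L)
    up <- function() {
      g <- array(stats::runif(prod(coarse), -1, 1), coarse)
      resample_grid(g,
                    idx_x = seq(0, coarse[3] - 1, length.out = d[3]),
                    idx_y = seq(0, coarse[2] - 1, length.out = d[2]),
                    idx_z = seq(0, coarse[1] - 1, length.out = d[1]))
    }
    disp_mm <- list(z = up(), y = up(), x = up())
    vox <- c(ct$spacing[3], ct$spacing[2], ct$spacing[1])  # (z,y,x) mm
    iz <- array(seq_len(d[1]) - 1, d) +
      disp_mm$z * spec$deform_amplitude / vox[1]
    iy <- array(rep(seq_len(d[2]) - 1, each = d[1]), d) +
      disp_mm$y * spec$deform_amplitude / vox[2]
    ix <- array(rep(seq_len(d[3]) - 1, each = d[1] * d[2]), d) +
      disp_mm$x * spec$deform_amplitude / vox[3]
    iz <- pmin(pmax(iz, 0), d[1] - 1)
    iy <- pmin(pmax(iy, 0), d[2] - 1)
    ix <- pmin(pmax(ix, 0), d[3] - 1)
    x <- trilinear_scatter_free(x, iz, iy, ix)
  }
  volume3d(array(x, d), spacing = ct$spacing, origin = ct$origin)
}

# trilinear sampling of `a` at per-voxel fractional coordinates (full warp)
trilinear_scatter_free <- function(a, iz, iy, ix) {
  d <- dim(a)
  z0 <- pmin(floor(iz), d[1] - 2); y0 <- pmin(floor(iy), d[2] - 2)
  x0 <- pmin(floor(ix), d[3] - 2)
  z0 <- pmax(z0, 0); y0 <- pmax(y0, 0); x0 <- pmax(x0, 0)
  fz <- iz - z0; fy <- iy - y0; fx <- ix - x0
  lin <- function(z, y, x) a[1 + z + d[1] * (y + d[2] * x)]
  v000 <- lin(z0, y0, x0); v100 <- lin(z0 + 1, y0, x0)
  v010 <- lin(z0, y0 + 1, x0); v110 <- lin(z0 + 1, y0 + 1, x0)
  v001 <- lin(z0, y0, x0 + 1); v101 <- lin(z0 + 1, y0, x0 + 1)
  v011 <- lin(z0, y0 + 1, x0 + 1); v111 <- lin(z0 + 1, y0 + 1, x0 + 1)
  out <- (1 - fx) * ((1 - fy) * ((1 - fz) * v000 + fz * v100) +
                       fy * ((1 - fz) * v010 + fz * v110)) +
    fx * ((1 - fy) * ((1 - fz) * v001 + fz * v101) +
            fy * ((1 - fz) * v011 + fz * v111))
  array(out, d)
}

#' Write a synthetic CBCT/CT dataset to disk
#'
#' Generates `n_patients` phantom variants (organ geometry jittered per
#' patient), writes one or more CT and CBCT volumes per patient with
#' acquisition dates arranged so the weak-pairing logic sees both
#' qualifying (<= 1 day) and non-qualifying (> 1 day) cases, and writes a
#' scan-metadata CSV in the format [read_scan_metadata()] consumes. A
#' held-out phantom CT/CBCT pair (not listed in the CSV) is written for
#' out-of-distribution evaluation.
#'
#' @param out_dir output directory (created if missing).
#' @param n_patients number of patients (>= 1).
#' @param cts_per_patient,cbcts_per_patient scans per patient.
#' @param shape,spacing phantom grid passed to [phantom_spec()].
#' @param degradation a [degradation_spec()] template; the per-scan seed is
#'   varied.
#' @param format file extension, one of `".nii.gz"`, `".nii"`, `".nrrd"`,
#'   `".mha"`.
#' @param seed master seed; output is a deterministic function of it.
#' @return Invisibly, the metadata data frame (also written to
#'   `scan_metadata.csv` in `out_dir`).
#' @export
make_dataset <- function(out_dir, n_patients = 2L, cts_per_patient = 1L,
                         cbcts_per_patient = 2L,
                         shape = c(48L, 96L, 96L), spacing = c(3, 3, 4),
                         degradation = degradation_spec(),
                         format = ".nii.gz", seed = 1L) {
  if (n_patients < 1L)
    stop("make_dataset: need at least one patient", call. = FALSE)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("make_dataset: cannot create output directory '", out_dir, "'",
         call. = FALSE)
  rows <- list()
  base_date <- as.Date("2021-01-04")
  for (p in seq_len(n_patients)) {
    pseed <- seed * 1000L + p
    set.seed(pseed)
    jit <- stats::runif(1, 0.95, 1.05)
    pspec <- phantom_spec(shape = shape, spacing = spacing,
                          tumor = list(center = c(0, -0.1, 0.45),
                                       radius = 0.12 * jit),
                          seed = pseed)
    ph <- make_phantom_ct(pspec)
    pid <- sprintf("P%03d", p)
    pdate <- base_date + 30 * (p - 1)
    for (k in seq_len(cts_per_patient)) {
      path <- file.path(out_dir, paste0(pid, "_CT_", k, format))
      write_volume(ph$ct, path)
      rows[[length(rows) + 1L]] <- scan_record(pid, "CT",
                                               pdate + 14 * (k - 1), path)
    }
    # CBCT dates: first on the CT date (delta 0), second 5 days later
    # (> 1 day, excluded from weak pairs), further ones weekly
    cb_offsets <- c(0L, 5L, 7L * seq_len(max(0L, cbcts_per_patient - 2L)))
    for (k in seq_len(cbcts_per_patient)) {
      dspec <- degradation
      dspec$seed <- pseed * 10L + k
      cb <- degrade_to_cbct(ph$ct, dspec)
      path <- file.path(out_dir, paste0(pid, "_CBCT_", k, format))
      write_volume(cb, path)
      rows[[length(rows) + 1L]] <- scan_record(pid, "CBCT",
                                               pdate + cb_offsets[k], path)
    }
  }
  # held-out phantom pair for out-of-distribution evaluation
  hspec <- phantom_spec(shape = shape, spacing = spacing,
                        seed = seed * 1000L + 999L)
  hph <- make_phantom_ct(hspec)
  hdeg <- degradation
  hdeg$seed <- seed * 1000L + 998L
  write_volume(hph$ct, file.path(out_dir, paste0("phantom_CT", format)))
  write_volume(degrade_to_cbct(hph$ct, hdeg),
               file.path(out_dir, paste0("phantom_CBCT", format)))
  meta <- do.call(rbind, rows)
  meta$date <- format(meta$date, "%Y-%m-%d")
  utils::write.csv(meta, file.path(out_dir, "scan_metadata.csv"),
                   row.names = FALSE)
  invisible(meta)
}
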