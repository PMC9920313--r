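#' 3D medical volume with spatial metadata
#'
#' A `volume3d` is the universal currency of the package: a 3D numeric array
#' in `(z, y, x)` index order together with voxel spacing and origin given as
#' `(x, y, z)` in millimetres (the order used by medical-image file headers),
#' and a tag recording whether intensities are on the Hounsfield-unit scale
#' or normalized to `[-1, 1]` for network consumption.
#'
#' @param data 3D numeric array, index order `(z, y, x)`.
#' @param spacing numeric length-3, voxel size in mm as `(x, y, z)`; all
#'   components must be strictly positive.
#' @param origin numeric length-3, position of the first voxel centre in mm
#'   as `(x, y, z)`.
#' @param scale_tag `"hu"` or `"normalized"`. Normalized volumes must have
#'   all intensities in `[-1, 1]`.
#' @return An object of class `volume3d`.
#' @examples
#' v <- volume3d(array(0, c(4, 5, 6)), spacing = c(1, 1, 3))
#' dim(v$data)
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     scale_tag = c("hu", "normalized")) {
  scale_tag <- match.arg(scale_tag)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume3d: `data` must be a 3D array, got ",
         paste(dim(data), collapse = "x"), call. = FALSE)
  if (any(dim(data) < 1L))
    stop("volume3d: every dimension must be >= 1", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("volume3d: spacing must be 3 strictly positive numbers", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("volume3d: origin must be 3 finite numbers", call. = FALSE)
  if (scale_tag == "normalized") {
    r <- range(data)
    if (r[1] < -1 - 1e-9 || r[2] > 1 + 1e-9)
      stop("volume3d: normalized volumes must lie in [-1, 1]; range is [",
           signif(r[1], 6), ", ", signif(r[2], 6), "]", call. = FALSE)
  }
  structure(list(data = data, spacing = spacing, origin = origin,
                 scale_tag = scale_tag),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat("<volume3d> ", d[1], " x ", d[2], " x ", d[3], " (z,y,x), scale: ",
      x$scale_tag, "\n", sep = "")
  cat("  spacing (x,y,z) mm:", paste(signif(x$spacing, 6), collapse = " x "), "\n")
  cat("  origin  (x,y,z) mm:", paste(signif(x$origin, 6), collapse = ", "), "\n")
  cat("  intensity range: [", signif(min(x$data), 6), ", ",
      signif(max(x$data), 6), "]\n", sep = "")
  invisible(x)
}

is_volume3d <- function(x) inherits(x, "volume3d")

as_volume3d <- function(x) {
  if (is_volume3d(x)) return(x)
  if (is.array(x) && length(dim(x)) == 3L) return(volume3d(x))
  stop("expected a volume3d or a 3D array", call. = FALSE)
}

stopifnot_congruent <- function(a, b, what = "volumes") {
  if (!identical(dim(a$data), dim(b$data)))
    stop("shape mismatch between ", what, ": ",
         paste(dim(a$data), collapse = "x"), " vs ",
         paste(dim(b$data), collapse = "x"), call. = FALSE)
  invisible(TRUE)
}

#' Binary body mask companion to a volume
#'
#' @param data 3D logical array, `(z, y, x)` order, shape-congruent with the
#'   volume it masks.
#' @return An object of class `body_mask`.
#' @export
body_mask <- function(data) {
  if (is.numeric(data)) data <- array(data != 0, dim(data))
  if (!is.array(data) || length(dim(data)) != 3L || !is.logical(data))
    stop("body_mask: `data` must be a 3D logical array", call. = FALSE)
  structure(list(data = data), class = "body_mask")
}

#' @export
print.body_mask <- function(x, ...) {
  d <- dim(x$data)
  cat("<body_mask> ", d[1], " x ", d[2], " x ", d[3], " (z,y,x), ",
      sum(x$data), "/", length(x$data), " voxels set\n", sep = "")
  invisible(x)
}

as_mask_array <- function(mask, ref = NULL) {
  m <- if (inherits(mask, "body_mask")) mask$data else mask
  if (is.numeric(m)) m <- array(m != 0, dim(m))
  if (!is.array(m) || length(dim(m)) != 3L || !is.logical(m))
    stop("mask must be a body_mask or a 3D logical array", call. = FALSE)
  if (!is.null(ref) && !identical(dim(m), dim(ref$data)))
    stop("mask shape ", paste(dim(m), collapse = "x"),
         " does not match volume shape ", paste(dim(ref$data), collapse = "x"),
         call. = FALSE)
  m
}

# physical extent [lo, hi] per axis (x,y,z) in mm, measured at voxel edges
volume_extent <- function(vol) {
  d <- dim(vol$data)           # (z, y, x)
  n <- c(d[3], d[2], d[1])     # (x, y, z)
  lo <- vol$origin - vol$spacing / 2
  hi <- vol$origin + (n - 0.5) * vol$spacing
  rbind(lo = lo, hi = hi)
}
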