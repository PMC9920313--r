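#' Orthonormal, zero-centred 3D discrete Fourier transform
#'
#' Computes the full complex 3D DFT of a volume, scaled to the orthonormal
#' convention `1/sqrt(L*M*N)` (under which Parseval's identity holds:
#' total spectral energy equals total signal energy), then cyclically shifted
#' so the zero-frequency (DC) component sits at the centre index
#' `(floor(L/2)+1, floor(M/2)+1, floor(N/2)+1)`.
#'
#' The alternative `"strict"` convention scales by `1/(L*M*N)` instead; it is
#' provided because the two normalizations appear interchangeably in the
#' literature, but it does not conserve energy.
#'
#' @param vol a [volume3d] or 3D numeric array.
#' @param convention `"orthonormal"` (default) or `"strict"`.
#' @return A complex 3D array of the same shape as the input, DC-centred.
#' @seealso [frequency_representation()], [frequency_distance()]
#' @export
orthonormal_dft3d <- function(vol, convention = c("orthonormal", "strict")) {
  convention <- match.arg(convention)
  x <- if (is_volume3d(vol)) vol$data else vol
  if (!is.array(x) || length(dim(x)) != 3L || length(x) < 1L)
    stop("orthonormal_dft3d: input must be a non-empty 3D volume",
         call. = FALSE)
  n <- length(x)
  scale <- if (convention == "orthonormal") sqrt(n) else n
  fftshift3d(stats::fft(x) / scale)
}

# cyclic shift placing index 1 (DC) at floor(n/2)+1 along every axis
fftshift3d <- function(x) {
  d <- dim(x)
  ix <- lapply(d, function(n) {
    h <- floor(n / 2)
    if (h == 0L) seq_len(n) else c((n - h + 1):n, seq_len(n - h))
  })
  x[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
}

ifftshift3d <- function(x) {
  d <- dim(x)
  ix <- lapply(d, function(n) {
    h <- floor(n / 2)
    c((h + 1):n, seq_len(h))
  })
  x[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
}

#' Generalized frequency representation of a volume
#'
#' The tanh-compressed magnitude spectrum: the elementwise modulus of the
#' orthonormal, DC-centred 3D DFT passed through `tanh`, giving values in
#' `[0, 1)`. Phase is discarded entirely, which makes the representation
#' insensitive to circular spatial translation of the input, and the tanh
#' dampens large magnitudes so that the distribution of spectral values,
#' rather than their raw scale, dominates.
#'
#' @inheritParams orthonormal_dft3d
#' @return An object of class `spectral_rep` with fields `rep` (3D array in
#'   `[0, 1)`), `shape`, and `convention_tag`.
#' @export
frequency_representation <- function(vol,
                                     convention = c("orthonormal", "strict")) {
  convention <- match.arg(convention)
  spec <- orthonormal_dft3d(vol, convention = convention)
  structure(list(rep = tanh(Mod(spec)), shape = dim(spec),
                 convention_tag = convention),
            class = "spectral_rep")
}

#' @export
print.spectral_rep <- function(x, ...) {
  cat("<spectral_rep> ", paste(x$shape, collapse = " x "),
      ", convention: ", x$convention_tag,
      ", range [", signif(min(x$rep), 4), ", ", signif(max(x$rep), 4), "]\n",
      sep = "")
  invisible(x)
}

#' Generalized frequency loss between two volumes
#'
#' The distance between the frequency representations of two shape-congruent
#' volumes: `sum(|Frep(a) - Frep(b)|)` for the L1 norm (the published form of
#' the structure loss, with `reduction = "sum"`) or
#' `sum((Frep(a) - Frep(b))^2)` for L2. It is non-negative, symmetric, zero
#' for identical inputs, and — because the magnitude spectrum is
#' translation-insensitive — zero between a volume and any circular shift of
#' it. With `reduction = "mean"` the sum is divided by the voxel count.
#'
#' @param a,b shape-congruent [volume3d]s or 3D arrays.
#' @param norm `"l1"` (default) or `"l2"`.
#' @param reduction `"sum"` (default) or `"mean"`.
#' @inheritParams orthonormal_dft3d
#' @return A non-negative scalar.
#' @export
frequency_distance <- function(a, b, norm = c("l1", "l2"),
                               reduction = c("sum", "mean"),
                               convention = c("orthonormal", "strict")) {
  norm <- match.arg(norm); reduction <- match.arg(reduction)
  convention <- match.arg(convention)
  xa <- if (is_volume3d(a)) a$data else a
  xb <- if (is_volume3d(b)) b$data else b
  if (!identical(dim(xa), dim(xb)))
    stop("frequency_distance: shape mismatch: ",
         paste(dim(xa), collapse = "x"), " vs ",
         paste(dim(xb), collapse = "x"), call. = FALSE)
  ra <- frequency_representation(xa, convention = convention)$rep
  rb <- frequency_representation(xb, convention = convention)$rep
  diff <- ra - rb
  s <- if (norm == "l1") sum(abs(diff)) else sum(diff^2)
  if (reduction == "mean") s <- s / length(xa)
  s
}

# Gradient of frequency_distance(a, b, ...) with respect to `b` (a 3D array).
# The loss depends on b through r = tanh(|F b|) with F the scaled DFT; the
# chain rule through the modulus gives, for real b,
#   dL/db = Re( F^H ( dL/dr * (1 - r^2) * Fb / |Fb| ) )
# with F^H the adjoint (inverse FFT with the same scale factor). Zero-
# magnitude bins have a well-defined subgradient of 0. Used by the trainer.
frequency_distance_grad <- function(a, b, norm = "l1", reduction = "sum",
                                    convention = "orthonormal") {
  xa <- if (is_volume3d(a)) a$data else a
  xb <- if (is_volume3d(b)) b$data else b
  n <- length(xb)
  scale <- if (convention == "orthonormal") sqrt(n) else n
  Fa <- stats::fft(xa) / scale
  Fb <- stats::fft(xb) / scale
  ma <- Mod(Fa); mb <- Mod(Fb)
  ra <- tanh(ma); rb <- tanh(mb)
  dldr <- if (norm == "l1") -sign(ra - rb) else -2 * (ra - rb)
  if (reduction == "mean") dldr <- dldr / n
  dldm <- dldr * (1 - rb^2)
  phase <- Fb
  nz <- mb > 0
  phase[nz] <- phase[nz] / mb[nz]
  phase[!nz] <- 0
  g <- stats::fft(dldm * phase, inverse = TRUE) / scale
  array(Re(g), dim(xb))
}
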