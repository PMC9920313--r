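#' Loss weights for the CycleGAN + frequency objective
#'
#' Holds the cycle-consistency weights (`lambda_A`, `lambda_B`) and the
#' frequency-structure-loss weights (`lambda_fA`, `lambda_fB`). All default
#' to 5, the published operating point.
#'
#' @param lambda_A,lambda_B non-negative cycle-consistency weights.
#' @param lambda_fA,lambda_fB non-negative frequency-loss weights (set both
#'   to 0 to recover the plain CycleGAN objective).
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(lambda_A = 5, lambda_B = 5,
                         lambda_fA = 5, lambda_fB = 5) {
  w <- c(lambda_A = lambda_A, lambda_B = lambda_B,
         lambda_fA = lambda_fA, lambda_fB = lambda_fB)
  if (any(!is.finite(w)) || any(w < 0))
    stop("loss_weights: all weights must be finite and >= 0", call. = FALSE)
  structure(as.list(w), class = "loss_weights")
}

#' Adversarial GAN loss
#'
#' Minimization-form adversarial losses for either side of the game, in the
#' log ("vanilla") or least-squares (LSGAN) variant. The vanilla
#' discriminator loss is the negation of the classic GAN objective
#' `E[log D(x)] + E[log(1 - D(G(z)))]`, so that all losses are minimized;
#' the vanilla generator uses the non-saturating form `-E[log D(G(z))]`.
#' Least-squares: discriminator `mean((d_real - 1)^2) + mean(d_fake^2)`,
#' generator `mean((d_fake - 1)^2)`.
#'
#' @param d_real discriminator outputs on real samples (any numeric array);
#'   ignored (may be `NULL`) when `side = "generator"`.
#' @param d_fake discriminator outputs on generated samples.
#' @param variant `"least_squares"` (default) or `"vanilla"`. Vanilla
#'   requires outputs strictly inside (0, 1) (probabilities).
#' @param side `"discriminator"` or `"generator"`.
#' @return A scalar loss value.
#' @export
adversarial_loss <- function(d_real = NULL, d_fake,
                             variant = c("least_squares", "vanilla"),
                             side = c("discriminator", "generator")) {
  variant <- match.arg(variant); side <- match.arg(side)
  d_fake <- as.numeric(d_fake)
  if (side == "discriminator") d_real <- as.numeric(d_real)
  vals <- c(d_fake, if (side == "discriminator") d_real)
  if (any(!is.finite(vals)))
    stop("adversarial_loss: discriminator outputs must be finite",
         call. = FALSE)
  if (variant == "vanilla") {
    if (any(vals <= 0 | vals >= 1))
      stop("adversarial_loss: vanilla variant requires outputs in (0, 1)",
           call. = FALSE)
    if (side == "discriminator")
      return(-mean(log(d_real)) - mean(log(1 - d_fake)))
    return(-mean(log(d_fake)))
  }
  if (side == "discriminator")
    return(mean((d_real - 1)^2) + mean(d_fake^2))
  mean((d_fake - 1)^2)
}

#' Cycle-consistency loss
#'
#' Mean absolute difference over voxels between an original volume and its
#' reconstruction through the two mappings (X to Y and back). Unweighted;
#' the `lambda` weights are applied in [total_objective()].
#'
#' @param original,reconstructed shape-congruent [volume3d]s or 3D arrays.
#' @return A non-negative scalar.
#' @export
cycle_consistency_loss <- function(original, reconstructed) {
  a <- if (is_volume3d(original)) original$data else original
  b <- if (is_volume3d(reconstructed)) reconstructed$data else reconstructed
  if (!identical(dim(a), dim(b)))
    stop("cycle_consistency_loss: shape mismatch: ",
         paste(dim(a), collapse = "x"), " vs ", paste(dim(b), collapse = "x"),
         call. = FALSE)
  mean(abs(a - b))
}

#' Assemble the full training objective
#'
#' Combines the six raw loss terms into the weighted total
#' `adv_G + adv_F + lambda_A * cycle_A + lambda_B * cycle_B +
#'  lambda_fA * freq_A + lambda_fB * freq_B`.
#' With `lambda_fA = lambda_fB = 0` this reduces exactly to the plain
#' CycleGAN objective.
#'
#' @param adv_G,adv_F generator-side adversarial terms for the two mappings.
#' @param cycle_A,cycle_B raw (unweighted) cycle-consistency terms.
#' @param freq_A,freq_B raw frequency-structure terms.
#' @param weights a [loss_weights].
#' @return An object of class `loss_breakdown`: the six raw terms plus
#'   `total`.
#' @export
total_objective <- function(adv_G = 0, adv_F = 0, cycle_A = 0, cycle_B = 0,
                            freq_A = 0, freq_B = 0,
                            weights = loss_weights()) {
  parts <- c(adv_G = adv_G, adv_F = adv_F, cycle_A = cycle_A,
             cycle_B = cycle_B, freq_A = freq_A, freq_B = freq_B)
  bad <- names(parts)[!is.finite(parts)]
  if (length(bad))
    stop("total_objective: non-finite loss term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  total <- adv_G + adv_F + weights$lambda_A * cycle_A +
    weights$lambda_B * cycle_B + weights$lambda_fA * freq_A +
    weights$lambda_fB * freq_B
  structure(c(as.list(parts), list(total = total)), class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat("<loss_breakdown>\n")
  for (k in c("adv_G", "adv_F", "cycle_A", "cycle_B", "freq_A", "freq_B",
              "total"))
    cat(sprintf("  %-8s %g\n", k, x[[k]]))
  invisible(x)
}

#' Pluggable structure loss between a generator input and its translation
#'
#' The structure-loss slot of the objective: `"none"` (plain CycleGAN
#' baseline, always 0), `"frequency_l1"` or `"frequency_l2"` (the
#' generalized frequency loss with the matching norm). The loss operates
#' directly between a generator's input and its translated output,
#' constraining anatomy without requiring spatial alignment.
#'
#' @param name one of `"none"`, `"frequency_l1"`, `"frequency_l2"`.
#' @param a,b shape-congruent [volume3d]s or 3D arrays (input, translation).
#' @param reduction passed to [frequency_distance()].
#' @return A non-negative scalar.
#' @export
structure_loss <- function(name = c("none", "frequency_l1", "frequency_l2"),
                           a, b, reduction = "sum") {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("none", "frequency_l1", "frequency_l2"))
    stop("structure_loss: unknown structure loss '", paste(name, collapse = ","),
         "'; expected none, frequency_l1 or frequency_l2", call. = FALSE)
  if (name == "none") return(0)
  frequency_distance(a, b, norm = sub("frequency_", "", name),
                     reduction = reduction)
}

# gradient of structure_loss with respect to `b`
structure_loss_grad <- function(name, a, b, reduction = "sum") {
  if (name == "none") {
    xb <- if (is_volume3d(b)) b$data else b
    return(array(0, dim(xb)))
  }
  frequency_distance_grad(a, b, norm = sub("frequency_", "", name),
                          reduction = reduction)
}
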