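#' Specification of the 3D VNet generator
#'
#' Architecture contract for the generator: an input block (kernel-5
#' convolution, instance norm, PReLU), four down-sampling blocks with
#' 1, 2, 3 and 2 convolutional blocks respectively (each stage ending in a
#' strided convolution that doubles the channel count), four up-sampling
#' blocks with 2, 2, 1 and 1 convolutional blocks (nearest-neighbour
#' upsampling plus convolution, with U-Net-style skip connections joining
#' matching-resolution stages), and an output block of two convolutions, the
#' second followed by a tanh so outputs are bounded in (-1, 1).
#'
#' In-plane dimensions halve at all four down stages (factor 16 total);
#' z-axis striding is disabled in the last two stages (factor 4 total), so a
#' 16-slice patch remains valid.
#'
#' @param in_channels input channel count (default 1).
#' @param base_filters channel count after the input block; doubles per down
#'   stage (default 16).
#' @param down_block_convs,up_block_convs convolutions per down/up stage.
#' @param norm,activation,final_activation fixed to `"instance"`, `"prelu"`,
#'   `"tanh"`; listed for the record.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(in_channels = 1L, base_filters = 16L,
                           down_block_convs = c(1L, 2L, 3L, 2L),
                           up_block_convs = c(2L, 2L, 1L, 1L),
                           norm = "instance", activation = "prelu",
                           final_activation = "tanh") {
  stopifnot(length(down_block_convs) == 4L, length(up_block_convs) == 4L,
            all(down_block_convs >= 1L), all(up_block_convs >= 1L),
            base_filters >= 1L, in_channels >= 1L)
  if (!identical(norm, "instance") || !identical(activation, "prelu") ||
      !identical(final_activation, "tanh"))
    stop("generator_spec: supported configuration is instance norm, PReLU, ",
         "tanh output", call. = FALSE)
  structure(list(in_channels = as.integer(in_channels),
                 base_filters = as.integer(base_filters),
                 down_block_convs = as.integer(down_block_convs),
                 up_block_convs = as.integer(up_block_convs),
                 norm = norm, activation = activation,
                 final_activation = final_activation),
            class = "generator_spec")
}

#' Specification of the 3D PatchGAN discriminator
#'
#' A 3D version of the PatchGAN: a stack of strided convolutions with
#' instance norm and LeakyReLU(0.2) ending in a 1-channel convolution that
#' emits a 3D grid of patch scores (raw, unsquashed — suitable for the
#' least-squares adversarial loss). Its receptive field covers a local patch,
#' not the whole input.
#'
#' @param in_channels input channel count (default 1).
#' @param n_layers number of in-plane-strided convolution layers (default 3).
#' @param base_filters filters in the first layer, doubling per layer
#'   (default 64).
#' @return An object of class `discriminator_spec`.
#' @export
discriminator_spec <- function(in_channels = 1L, n_layers = 3L,
                               base_filters = 64L) {
  stopifnot(in_channels >= 1L, n_layers >= 1L, base_filters >= 1L)
  structure(list(in_channels = as.integer(in_channels),
                 n_layers = as.integer(n_layers),
                 base_filters = as.integer(base_filters)),
            class = "discriminator_spec")
}

# conv + instance norm + PReLU block
cb_new <- function(cin, cout, k = 3L, stride = 1L) {
  list(conv = conv3d_layer(cin, cout, k = k, stride = stride),
       norm = instnorm_layer(cout),
       act = prelu_layer(cout))
}

cb_fwd <- function(blk, x) {
  c1 <- conv3d_fwd(blk$conv, x)
  n1 <- instnorm_fwd(blk$norm, c1$y)
  a1 <- prelu_fwd(blk$act, n1$y)
  list(y = a1$y, cache = list(conv = c1$cache, norm = n1$cache,
                              act = a1$cache))
}

cb_bwd <- function(blk, cache, gy) {
  a <- prelu_bwd(blk$act, cache$act, gy)
  n <- instnorm_bwd(blk$norm, cache$norm, a$gx)
  c <- conv3d_bwd(blk$conv, cache$conv, n$gx)
  list(gx = c$gx, grads = list(conv = c$grads, norm = n$grads,
                               act = a$grads))
}

# per-stage strides/upsampling factors (z, y, x)
gen_down_strides <- list(c(2L, 2L, 2L), c(2L, 2L, 2L),
                         c(1L, 2L, 2L), c(1L, 2L, 2L))
gen_up_factors <- rev(gen_down_strides)

#' Build a 3D VNet generator
#'
#' Instantiates the network described by a [generator_spec()] with
#' normal(0, 0.02) weight initialization. Construction is deterministic
#' given `seed`.
#'
#' @param spec a [generator_spec()].
#' @param seed optional integer seed for weight initialization.
#' @return An object of class `fg_generator`.
#' @seealso [network_forward()]
#' @export
build_generator <- function(spec = generator_spec(), seed = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  if (!is.null(seed)) set.seed(seed)
  nf <- spec$base_filters
  ch <- nf * 2L^(0:4)  # channels at resolution levels 0..4
  net <- list()
  net$inb <- cb_new(spec$in_channels, ch[1], k = 5L)
  net$down <- vector("list", 4L)
  for (i in 1:4) {
    convs <- lapply(seq_len(spec$down_block_convs[i]),
                    function(j) cb_new(ch[i], ch[i]))
    net$down[[i]] <- list(convs = convs,
                          down = cb_new(ch[i], ch[i + 1], k = 3L,
                                        stride = gen_down_strides[[i]]))
  }
  net$up <- vector("list", 4L)
  for (j in 1:4) {
    lvl <- 5L - j  # from level lvl down to lvl-1
    upconv <- cb_new(ch[lvl + 1L], ch[lvl])
    n_convs <- spec$up_block_convs[j]
    convs <- vector("list", n_convs)
    convs[[1]] <- cb_new(2L * ch[lvl], ch[lvl])  # first conv sees the concat
    if (n_convs > 1L)
      for (m in 2:n_convs) convs[[m]] <- cb_new(ch[lvl], ch[lvl])
    net$up[[j]] <- list(upconv = upconv, convs = convs)
  }
  net$outb <- list(conv1 = cb_new(ch[1], ch[1]),
                   conv2 = conv3d_layer(ch[1], 1L, k = 3L))
  structure(list(spec = spec, net = net), class = "fg_generator")
}

check_gen_input <- function(d) {
  if (d[1] %% 4L != 0L || d[2] %% 16L != 0L || d[3] %% 16L != 0L)
    stop("generator input shape (", paste(d, collapse = ", "),
         ") must be divisible by 4 in z and 16 in-plane", call. = FALSE)
  invisible(TRUE)
}

gen_fwd <- function(gen, x) {
  d <- dim(x)
  check_gen_input(d[1:3])
  net <- gen$net
  cache <- list()
  h <- cb_fwd(net$inb, x); cache$inb <- h$cache; h <- h$y
  skips <- vector("list", 4L)
  cache$down <- vector("list", 4L)
  for (i in 1:4) {
    cc <- vector("list", length(net$down[[i]]$convs))
    for (m in seq_along(cc)) {
      s <- cb_fwd(net$down[[i]]$convs[[m]], h); cc[[m]] <- s$cache; h <- s$y
    }
    skips[[i]] <- h  # level i-1 resolution
    s <- cb_fwd(net$down[[i]]$down, h)
    cache$down[[i]] <- list(convs = cc, down = s$cache)
    h <- s$y
  }
  cache$up <- vector("list", 4L)
  for (j in 1:4) {
    f <- gen_up_factors[[j]]
    u <- upsample_fwd(h, f)
    s <- cb_fwd(net$up[[j]]$upconv, u$y)
    skip <- skips[[5L - j]]
    h2 <- concat_channels(s$y, skip)
    cc <- vector("list", length(net$up[[j]]$convs))
    h <- h2
    for (m in seq_along(cc)) {
      t <- cb_fwd(net$up[[j]]$convs[[m]], h); cc[[m]] <- t$cache; h <- t$y
    }
    cache$up[[j]] <- list(upsample = u$cache, upconv = s$cache, convs = cc,
                          c1 = dim(s$y)[4])
  }
  o1 <- cb_fwd(net$outb$conv1, h)
  o2 <- conv3d_fwd(net$outb$conv2, o1$y)
  ot <- tanh_fwd(o2$y)
  cache$outb <- list(conv1 = o1$cache, conv2 = o2$cache, tanh = ot$cache)
  list(y = ot$y, cache = cache)
}

gen_bwd <- function(gen, cache, gy) {
  net <- gen$net
  grads <- list()
  g <- tanh_bwd(cache$outb$tanh, gy)
  o2 <- conv3d_bwd(net$outb$conv2, cache$outb$conv2, g)
  o1 <- cb_bwd(net$outb$conv1, cache$outb$conv1, o2$gx)
  grads$outb <- list(conv1 = o1$grads, conv2 = o2$grads)
  g <- o1$gx
  gskips <- vector("list", 4L)
  grads$up <- vector("list", 4L)
  for (j in 4:1) {
    cu <- cache$up[[j]]
    gc <- vector("list", length(net$up[[j]]$convs))
    for (m in rev(seq_along(gc))) {
      s <- cb_bwd(net$up[[j]]$convs[[m]], cu$convs[[m]], g)
      gc[[m]] <- s$grads; g <- s$gx
    }
    sp <- split_channels(g, cu$c1)
    gskips[[5L - j]] <- sp$b
    s <- cb_bwd(net$up[[j]]$upconv, cu$upconv, sp$a)
    g <- upsample_bwd(cu$upsample, s$gx, gen_up_factors[[j]])
    grads$up[[j]] <- list(upconv = s$grads, convs = gc)
  }
  grads$down <- vector("list", 4L)
  for (i in 4:1) {
    cd <- cache$down[[i]]
    s <- cb_bwd(net$down[[i]]$down, cd$down, g)
    g <- s$gx + gskips[[i]]
    gc <- vector("list", length(net$down[[i]]$convs))
    for (m in rev(seq_along(gc))) {
      t <- cb_bwd(net$down[[i]]$convs[[m]], cd$convs[[m]], g)
      gc[[m]] <- t$grads; g <- t$gx
    }
    grads$down[[i]] <- list(convs = gc, down = s$grads)
  }
  s <- cb_bwd(net$inb, cache$inb, g)
  grads$inb <- s$grads
  list(gx = s$gx, grads = grads)
}

#' Build a 3D PatchGAN discriminator
#'
#' @param spec a [discriminator_spec()].
#' @param seed optional integer seed for weight initialization.
#' @return An object of class `fg_discriminator`.
#' @export
build_discriminator <- function(spec = discriminator_spec(), seed = NULL) {
  stopifnot(inherits(spec, "discriminator_spec"))
  if (!is.null(seed)) set.seed(seed)
  nf <- spec$base_filters
  k <- c(3L, 4L, 4L)
  layers <- list()
  cin <- spec$in_channels
  cout <- nf
  for (i in seq_len(spec$n_layers)) {
    stride <- if (i == 1L) c(2L, 2L, 2L) else c(1L, 2L, 2L)
    layers[[i]] <- list(conv = conv3d_layer(cin, cout, k = k, stride = stride,
                                            pad = 1L),
                        norm = if (i > 1L) instnorm_layer(cout))
    cin <- cout
    cout <- min(cout * 2L, 8L * nf)
  }
  layers[[spec$n_layers + 1L]] <-
    list(conv = conv3d_layer(cin, cout, k = k, stride = 1L, pad = 1L),
         norm = instnorm_layer(cout))
  layers[[spec$n_layers + 2L]] <-
    list(conv = conv3d_layer(cout, 1L, k = k, stride = 1L, pad = 1L),
         norm = NULL)
  structure(list(spec = spec, net = list(layers = layers)),
            class = "fg_discriminator")
}

disc_fwd <- function(disc, x) {
  layers <- disc$net$layers
  nl <- length(layers)
  cache <- vector("list", nl)
  h <- x
  for (i in seq_len(nl)) {
    if (any((dim(h)[1:3] + 2L * layers[[i]]$conv$pad) < layers[[i]]$conv$k))
      stop("discriminator input smaller than its receptive field at layer ",
           i, " (shape ", paste(dim(h)[1:3], collapse = "x"), ")",
           call. = FALSE)
    cv <- conv3d_fwd(layers[[i]]$conv, h)
    h <- cv$y
    nc <- NULL
    if (!is.null(layers[[i]]$norm)) {
      nm <- instnorm_fwd(layers[[i]]$norm, h)
      h <- nm$y; nc <- nm$cache
    }
    ac <- NULL
    if (i < nl) {
      lr <- lrelu_fwd(h)
      h <- lr$y; ac <- lr$cache
    }
    cache[[i]] <- list(conv = cv$cache, norm = nc, act = ac)
  }
  list(y = h, cache = cache)
}

disc_bwd <- function(disc, cache, gy) {
  layers <- disc$net$layers
  nl <- length(layers)
  grads <- vector("list", nl)
  g <- gy
  for (i in nl:1) {
    if (!is.null(cache[[i]]$act)) g <- lrelu_bwd(cache[[i]]$act, g)
    gn <- NULL
    if (!is.null(layers[[i]]$norm)) {
      nb <- instnorm_bwd(layers[[i]]$norm, cache[[i]]$norm, g)
      g <- nb$gx; gn <- nb$grads
    }
    cb <- conv3d_bwd(layers[[i]]$conv, cache[[i]]$conv, g)
    g <- cb$gx
    grads[[i]] <- list(conv = cb$grads, norm = gn)
  }
  list(gx = g, grads = list(layers = grads))
}

as_feature_map <- function(x) {
  if (is_volume3d(x)) x <- x$data
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}

#' Run a network forward
#'
#' Applies a built generator or discriminator to a single-channel volume
#' patch. Generators return a same-shape array with values in (-1, 1);
#' discriminators return a 3D grid of raw patch scores.
#'
#' @param network an `fg_generator` or `fg_discriminator`.
#' @param x a [volume3d] or 3D array (a `(z, y, x, c)` array is also
#'   accepted).
#' @return A numeric array.
#' @export
network_forward <- function(network, x) {
  x <- as_feature_map(x)
  if (inherits(network, "fg_generator")) {
    y <- gen_fwd(network, x)$y
    return(array(y, dim(y)[1:3]))
  }
  if (inherits(network, "fg_discriminator")) {
    y <- disc_fwd(network, x)$y
    return(array(y, dim(y)[1:3]))
  }
  stop("network_forward: not a built network", call. = FALSE)
}

#' @export
print.fg_generator <- function(x, ...) {
  cat("<fg_generator> 3D VNet, base filters ", x$spec$base_filters,
      ", down blocks (", paste(x$spec$down_block_convs, collapse = ","),
      "), up blocks (", paste(x$spec$up_block_convs, collapse = ","),
      "), ", n_params(x$net), " parameters\n", sep = "")
  invisible(x)
}

#' @export
print.fg_discriminator <- function(x, ...) {
  cat("<fg_discriminator> 3D PatchGAN, ", x$spec$n_layers,
      " strided layers, base filters ", x$spec$base_filters, ", ",
      n_params(x$net), " parameters\n", sep = "")
  invisible(x)
}
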