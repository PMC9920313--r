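# ---------------------------------------------------------------------------
# Minimal 3D convolutional-network engine.
#
# Feature maps are numeric arrays of dim (Z, Y, X, C), batch size 1.
# Convolutions are evaluated as im2col gathers followed by BLAS matrix
# multiplies; backward passes are written by hand. This keeps the whole
# training stack in plain R while remaining fast enough for patch-sized
# volumes on one CPU.
# ---------------------------------------------------------------------------

.idx_cache <- new.env(parent = emptyenv())

# im2col gather-index matrix for a padded input of dims `pd` = (Pz,Py,Px,C):
# rows index output voxels (z fastest), columns index (kz, ky, kx, c) with kz
# fastest — matching the conv weight layout. Cached per configuration.
im2col_idx <- function(pd, k, stride) {
  key <- paste(c(pd, k, stride), collapse = "_")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  od <- (pd[1:3] - k) %/% stride + 1L
  oz <- (seq_len(od[1]) - 1L) * stride[1]
  oy <- (seq_len(od[2]) - 1L) * stride[2]
  ox <- (seq_len(od[3]) - 1L) * stride[3]
  base <- rep(oz, times = od[2] * od[3]) +
    pd[1] * rep(rep(oy, each = od[1]), times = od[3]) +
    pd[1] * pd[2] * rep(ox, each = od[1] * od[2])
  C <- pd[4]
  kz <- rep(seq_len(k[1]) - 1L, times = k[2] * k[3] * C)
  ky <- rep(rep(seq_len(k[2]) - 1L, each = k[1]), times = k[3] * C)
  kx <- rep(rep(seq_len(k[3]) - 1L, each = k[1] * k[2]), times = C)
  cc <- rep(seq_len(C) - 1L, each = k[1] * k[2] * k[3])
  offs <- kz + pd[1] * ky + pd[1] * pd[2] * kx + pd[1] * pd[2] * pd[3] * cc
  idx <- outer(as.integer(base), as.integer(offs), `+`) + 1L
  storage.mode(idx) <- "integer"
  out <- list(idx = idx, od = od)
  .idx_cache[[key]] <- out
  out
}

pad4d <- function(x, pad) {
  if (all(pad == 0L)) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * pad[1], d[2] + 2L * pad[2],
                    d[3] + 2L * pad[3], d[4]))
  out[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]),
      pad[3] + seq_len(d[3]), ] <- x
  out
}

unpad4d <- function(x, pad, d) {
  if (all(pad == 0L)) return(x)
  x[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]),
    pad[3] + seq_len(d[3]), , drop = FALSE]
}

# conv layer: weight matrix (prod(k)*cin) x cout, bias cout
conv3d_layer <- function(cin, cout, k = c(3L, 3L, 3L), stride = c(1L, 1L, 1L),
                         pad = NULL, init_sd = 0.02) {
  k <- as.integer(rep(k, length.out = 3L))
  stride <- as.integer(rep(stride, length.out = 3L))
  if (is.null(pad)) pad <- k %/% 2L
  pad <- as.integer(rep(pad, length.out = 3L))
  list(type = "conv", cin = cin, cout = cout, k = k, stride = stride,
       pad = pad,
       par = list(W = matrix(stats::rnorm(prod(k) * cin * cout, 0, init_sd),
                             prod(k) * cin, cout),
                  b = numeric(cout)))
}

conv3d_fwd <- function(layer, x) {
  d <- dim(x)
  xp <- pad4d(x, layer$pad)
  pd <- dim(xp)
  ic <- im2col_idx(pd, layer$k, layer$stride)
  col <- xp[ic$idx]
  dim(col) <- dim(ic$idx)
  out <- col %*% layer$par$W
  out <- out + rep(layer$par$b, each = nrow(out))
  y <- array(out, c(ic$od, layer$cout))
  list(y = y, cache = list(col = col, pd = pd, d = d))
}

conv3d_bwd <- function(layer, cache, gy) {
  n_out <- nrow(cache$col)
  Go <- gy
  dim(Go) <- c(n_out, layer$cout)
  dW <- crossprod(cache$col, Go)
  db <- colSums(Go)
  dcol <- tcrossprod(Go, layer$par$W)
  ic <- im2col_idx(cache$pd, layer$k, layer$stride)
  dpad <- numeric(prod(cache$pd))
  # scatter-add column by column: within one kernel-offset column the gather
  # indices are distinct, so a vectorized indexed add is exact
  for (j in seq_len(ncol(ic$idx))) {
    ii <- ic$idx[, j]
    dpad[ii] <- dpad[ii] + dcol[, j]
  }
  dim(dpad) <- cache$pd
  gx <- unpad4d(dpad, layer$pad, cache$d)
  list(gx = gx, grads = list(W = dW, b = db))
}

instnorm_layer <- function(c, eps = 1e-5) {
  list(type = "instnorm", c = c, eps = eps,
       par = list(g = rep(1, c), b = numeric(c)))
}

instnorm_fwd <- function(layer, x) {
  d <- dim(x)
  n <- prod(d[1:3])
  xm <- matrix(x, n, d[4])
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = n)
  v <- colSums(xc^2) / n
  invstd <- 1 / sqrt(v + layer$eps)
  xhat <- xc * rep(invstd, each = n)
  ym <- xhat * rep(layer$par$g, each = n) + rep(layer$par$b, each = n)
  list(y = array(ym, d),
       cache = list(xhat = xhat, invstd = invstd, d = d, n = n))
}

instnorm_bwd <- function(layer, cache, gy) {
  d <- cache$d; n <- cache$n
  gym <- matrix(gy, n, d[4])
  dg <- colSums(gym * cache$xhat)
  db <- colSums(gym)
  dxhat <- gym * rep(layer$par$g, each = n)
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * cache$xhat)
  dx <- (dxhat - rep(m1, each = n) - cache$xhat * rep(m2, each = n)) *
    rep(cache$invstd, each = n)
  list(gx = array(dx, d), grads = list(g = dg, b = db))
}

prelu_layer <- function(c, init = 0.25) {
  list(type = "prelu", c = c, par = list(a = rep(init, c)))
}

prelu_fwd <- function(layer, x) {
  d <- dim(x)
  n <- prod(d[1:3])
  a <- rep(layer$par$a, each = n)
  neg <- x < 0
  y <- x
  y[neg] <- a[neg] * x[neg]
  list(y = y, cache = list(x = x, neg = neg, n = n, d = d))
}

prelu_bwd <- function(layer, cache, gy) {
  n <- cache$n; d <- cache$d
  a <- rep(layer$par$a, each = n)
  gx <- gy
  gx[cache$neg] <- gy[cache$neg] * a[cache$neg]
  contrib <- gy * cache$x
  contrib[!cache$neg] <- 0
  da <- colSums(matrix(contrib, n, d[4]))
  list(gx = gx, grads = list(a = da))
}

lrelu_fwd <- function(x, slope = 0.2) {
  neg <- x < 0
  y <- x
  y[neg] <- slope * x[neg]
  list(y = y, cache = neg)
}

lrelu_bwd <- function(cache, gy, slope = 0.2) {
  gx <- gy
  gx[cache] <- slope * gy[cache]
  gx
}

tanh_fwd <- function(x) {
  y <- tanh(x)
  list(y = y, cache = y)
}

tanh_bwd <- function(cache, gy) gy * (1 - cache^2)

# nearest-neighbour upsampling by integer factors f = (fz, fy, fx)
upsample_fwd <- function(x, f) {
  d <- dim(x)
  y <- x[rep(seq_len(d[1]), each = f[1]), rep(seq_len(d[2]), each = f[2]),
         rep(seq_len(d[3]), each = f[3]), , drop = FALSE]
  list(y = y, cache = d)
}

upsample_bwd <- function(cache, gy, f) {
  d <- cache
  gx <- array(0, d)
  for (az in seq_len(f[1])) for (ay in seq_len(f[2])) for (ax in seq_len(f[3]))
    gx <- gx + gy[seq(az, by = f[1], length.out = d[1]),
                  seq(ay, by = f[2], length.out = d[2]),
                  seq(ax, by = f[3], length.out = d[3]), , drop = FALSE]
  gx
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

split_channels <- function(g, c1) {
  d <- dim(g)
  list(a = g[, , , seq_len(c1), drop = FALSE],
       b = g[, , , c1 + seq_len(d[4] - c1), drop = FALSE])
}

# ---- parameter-tree utilities ---------------------------------------------
# Networks are nested lists whose leaves are layer lists carrying $par.
# Gradients mirror the same structure with $par replaced by grad lists.

# child keys of a tree node: element names where present, indices otherwise
tree_keys <- function(x) {
  nm <- names(x)
  if (is.null(nm)) nm <- rep("", length(x))
  ifelse(nm == "", as.character(seq_along(x)), nm)
}

collect_params <- function(net) {
  out <- list()
  walk <- function(x, path) {
    if (is.list(x) && !is.null(x$par)) {
      for (nm in names(x$par))
        out[[paste0(path, "/", nm)]] <<- x$par[[nm]]
      return(invisible())
    }
    if (is.list(x)) {
      keys <- tree_keys(x)
      for (i in seq_along(x))
        if (is.list(x[[i]])) walk(x[[i]], paste0(path, "/", keys[i]))
    }
  }
  walk(net, "")
  out
}

n_params <- function(net) sum(vapply(collect_params(net), length, integer(1)))

# flatten any nested list (e.g. a gradient tree) into its numeric leaves
collect_leaves <- function(tree) {
  out <- list()
  walk <- function(x, path) {
    if (is.numeric(x)) {
      out[[path]] <<- x
      return(invisible())
    }
    if (is.list(x)) {
      keys <- tree_keys(x)
      for (i in seq_along(x))
        walk(x[[i]], paste0(path, "/", keys[i]))
    }
  }
  walk(tree, "")
  out
}

# elementwise sum of two structurally identical gradient trees (matched by
# position, since both come from the same backward-pass construction)
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.numeric(a)) return(a + b)
  out <- a
  for (i in seq_along(b))
    out[[i]] <- grads_add(a[[i]], b[[i]])
  out
}

# ---- Adam ------------------------------------------------------------------

adam_state <- function() list(t = 0L, m = list(), v = list())

# Applies one Adam update to every $par leaf of `net` using the matching
# leaves of the gradient tree `grads`. Returns list(net, state).
adam_update <- function(net, grads, state, lr, betas = c(0.5, 0.999),
                        eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  b1 <- betas[1]; b2 <- betas[2]
  walk <- function(x, g, path) {
    if (is.list(x) && !is.null(x$par)) {
      for (nm in names(x$par)) {
        key <- paste0(path, "/", nm)
        gv <- g[[nm]]
        if (is.null(gv)) next
        m <- state$m[[key]]; v <- state$v[[key]]
        if (is.null(m)) { m <- gv * 0; v <- gv * 0 }
        m <- b1 * m + (1 - b1) * gv
        v <- b2 * v + (1 - b2) * gv^2
        state$m[[key]] <<- m
        state$v[[key]] <<- v
        mhat <- m / (1 - b1^t)
        vhat <- v / (1 - b2^t)
        x$par[[nm]] <- x$par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
      return(x)
    }
    if (is.list(x)) {
      keys <- tree_keys(x)
      gkeys <- if (is.list(g)) tree_keys(g) else character(0)
      for (i in seq_along(x)) {
        j <- match(keys[i], gkeys)
        if (is.list(x[[i]]) && !is.na(j) && !is.null(g[[j]]))
          x[[i]] <- walk(x[[i]], g[[j]], paste0(path, "/", keys[i]))
      }
    }
    x
  }
  net <- walk(net, grads, "")
  list(net = net, state = state)
}
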