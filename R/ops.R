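# ---------------------------------------------------------------------------
# Differentiable operations on [C, D, H, W] feature volumes (channel fastest).
# Bias addition and channel-wise broadcasts exploit column-major recycling:
# a length-C vector recycles exactly along the channel axis.
# ---------------------------------------------------------------------------

vol_dim <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 4L) stop("expected a [C, D, H, W] array")
  d
}

# Dense 3D convolution (cubic kernel, isotropic stride/pad).
# w: [Cout, Cin, k, k, k]; b: length Cout.
op_conv3d <- function(ctx, x, w, b, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  xd <- vol_dim(x$value)
  cout <- dim(w$value)[1L]
  if (dim(w$value)[2L] != xd[1L]) {
    stop("channel mismatch: input has ", xd[1L], " channels, kernel expects ",
         dim(w$value)[2L])
  }
  y <- cpp_conv3d_fwd(x$value, as.integer(xd), w$value,
                      cout, as.integer(k), as.integer(stride), as.integer(pad))
  os <- (xd[2:4] + 2L * pad - k) %/% stride + 1L
  if (!is.null(b)) y <- y + b$value
  dim(y) <- c(cout, os)
  trk <- x$track || w$track || (!is.null(b) && b$track)
  ad_node(ctx$tape, y, track = trk, backward = function(g) {
    gm <- matrix(g, nrow = cout)
    if (w$track) {
      dw <- cpp_conv3d_bwd_weight(g, x$value,
                                  as.integer(xd), cout, as.integer(k),
                                  as.integer(stride), as.integer(pad))
      dim(dw) <- dim(w$value)
      ad_accum(w, dw)
    }
    if (!is.null(b) && b$track) ad_accum(b, rowSums(gm))
    if (x$track) {
      dx <- cpp_conv3d_bwd_input(g, as.integer(xd),
                                 w$value, cout, as.integer(k),
                                 as.integer(stride), as.integer(pad))
      dim(dx) <- xd
      ad_accum(x, dx)
    }
  })
}

# Depthwise 3D convolution, stride 1, "same" padding.  w: [C, k^3].
op_dwconv3d <- function(ctx, x, w, b, k) {
  xd <- vol_dim(x$value)
  if (dim(w$value)[1L] != xd[1L]) {
    stop("channel mismatch: input has ", xd[1L], " channels, kernel expects ",
         dim(w$value)[1L])
  }
  y <- cpp_dwconv3d_fwd(x$value, as.integer(xd), w$value,
                        as.integer(k))
  if (!is.null(b)) y <- y + b$value
  dim(y) <- xd
  trk <- x$track || w$track || (!is.null(b) && b$track)
  ad_node(ctx$tape, y, track = trk, backward = function(g) {
    if (w$track) {
      dw <- cpp_dwconv3d_bwd_weight(g, x$value,
                                    as.integer(xd), as.integer(k))
      dim(dw) <- dim(w$value)
      ad_accum(w, dw)
    }
    if (!is.null(b) && b$track) ad_accum(b, rowSums(matrix(g, nrow = xd[1L])))
    if (x$track) {
      dx <- cpp_dwconv3d_bwd_input(g, as.integer(xd),
                                   w$value, as.integer(k))
      dim(dx) <- xd
      ad_accum(x, dx)
    }
  })
}

# Pointwise (1x1x1) convolution as a channel-mixing GEMM.  w: [Cout, Cin].
op_pw <- function(ctx, x, w, b) {
  xd <- vol_dim(x$value)
  cin <- dim(w$value)[2L]
  cout <- dim(w$value)[1L]
  if (cin != xd[1L]) {
    stop("channel mismatch: input has ", xd[1L], " channels, kernel expects ",
         cin)
  }
  X <- matrix(x$value, nrow = xd[1L])
  y <- w$value %*% X
  if (!is.null(b)) y <- y + b$value
  dim(y) <- c(cout, xd[2:4])
  trk <- x$track || w$track || (!is.null(b) && b$track)
  ad_node(ctx$tape, y, track = trk, backward = function(g) {
    gm <- matrix(g, nrow = cout)
    if (w$track) ad_accum(w, tcrossprod(gm, X))
    if (!is.null(b) && b$track) ad_accum(b, rowSums(gm))
    if (x$track) {
      dx <- crossprod(w$value, gm)
      dim(dx) <- xd
      ad_accum(x, dx)
    }
  })
}

# Transpose convolution, kernel 2x2x2, stride 2 (non-overlapping blocks).
# w: [Cout, Cin, 2, 2, 2].
op_convtrans2 <- function(ctx, x, w, b) {
  xd <- vol_dim(x$value)
  cin <- dim(w$value)[2L]
  cout <- dim(w$value)[1L]
  if (cin != xd[1L]) {
    stop("channel mismatch: input has ", xd[1L], " channels, kernel expects ",
         cin)
  }
  X <- matrix(x$value, nrow = cin)
  od <- 2L * xd[2:4]
  y <- array(0, c(cout, od))
  taps <- expand.grid(a = 0:1, bb = 0:1, cc = 0:1)
  for (t in seq_len(nrow(taps))) {
    a <- taps$a[t]; bb <- taps$bb[t]; cc <- taps$cc[t]
    Wt <- matrix(w$value[, , a + 1L, bb + 1L, cc + 1L], cout, cin)
    Yt <- Wt %*% X
    dim(Yt) <- c(cout, xd[2:4])
    y[, seq(a + 1L, od[1L], 2L), seq(bb + 1L, od[2L], 2L),
      seq(cc + 1L, od[3L], 2L)] <- Yt
  }
  y <- y + b$value
  ad_node(ctx$tape, y, track = x$track || w$track || b$track, backward = function(g) {
    dim(g) <- c(cout, od)
    dX <- if (x$track) matrix(0, cin, ncol(X)) else NULL
    dW <- if (w$track) array(0, dim(w$value)) else NULL
    for (t in seq_len(nrow(taps))) {
      a <- taps$a[t]; bb <- taps$bb[t]; cc <- taps$cc[t]
      Gt <- g[, seq(a + 1L, od[1L], 2L), seq(bb + 1L, od[2L], 2L),
              seq(cc + 1L, od[3L], 2L), drop = FALSE]
      Gt <- matrix(Gt, nrow = cout)
      Wt <- matrix(w$value[, , a + 1L, bb + 1L, cc + 1L], cout, cin)
      if (!is.null(dW)) dW[, , a + 1L, bb + 1L, cc + 1L] <- tcrossprod(Gt, X)
      if (!is.null(dX)) dX <- dX + crossprod(Wt, Gt)
    }
    if (w$track) ad_accum(w, dW)
    if (b$track) ad_accum(b, rowSums(matrix(g, nrow = cout)))
    if (x$track) {
      dim(dX) <- xd
      ad_accum(x, dX)
    }
  })
}

# Layer normalisation over the channel axis, per voxel, learnable affine.
op_ln <- function(ctx, x, gamma, beta, eps = 1e-6) {
  xd <- vol_dim(x$value)
  C <- xd[1L]
  X <- matrix(x$value, nrow = C)
  mu <- colMeans(X)
  Xc <- X - rep(mu, each = C)
  istd <- 1 / sqrt(colMeans(Xc * Xc) + eps)
  xhat <- Xc * rep(istd, each = C)
  y <- xhat * gamma$value + beta$value
  dim(y) <- xd
  ad_node(ctx$tape, y, track = x$track || gamma$track || beta$track,
          backward = function(g) {
    gm <- matrix(g, nrow = C)
    if (gamma$track) ad_accum(gamma, rowSums(gm * xhat))
    if (beta$track) ad_accum(beta, rowSums(gm))
    if (x$track) {
      dxh <- gm * gamma$value
      m1 <- colMeans(dxh)
      m2 <- colMeans(dxh * xhat)
      dx <- (dxh - rep(m1, each = C) - xhat * rep(m2, each = C)) *
        rep(istd, each = C)
      dim(dx) <- xd
      ad_accum(x, dx)
    }
  })
}

# Exact GELU: x * Phi(x).
op_gelu <- function(ctx, x) {
  v <- x$value
  y <- cpp_gelu_fwd(v)
  dim(y) <- dim(v)
  ad_node(ctx$tape, y, track = x$track, backward = function(g) {
    dx <- cpp_gelu_bwd(g, v)
    dim(dx) <- dim(v)
    ad_accum(x, dx)
  })
}

op_sigmoid <- function(ctx, x) {
  y <- 1 / (1 + exp(-x$value))
  ad_node(ctx$tape, y, track = x$track, backward = function(g) {
    ad_accum(x, g * y * (1 - y))
  })
}

op_add <- function(ctx, a, b) {
  ad_node(ctx$tape, a$value + b$value, track = a$track || b$track,
          backward = function(g) {
    ad_accum(a, g)
    ad_accum(b, g)
  })
}

op_scale <- function(ctx, x, s) {
  ad_node(ctx$tape, x$value * s, track = x$track, backward = function(g) {
    ad_accum(x, g * s)
  })
}

# Channel concatenation.
op_cat <- function(ctx, a, b) {
  da <- vol_dim(a$value)
  db <- vol_dim(b$value)
  if (!all(da[2:4] == db[2:4])) {
    stop("spatial mismatch in channel concatenation: [",
         paste(da[2:4], collapse = "x"), "] vs [",
         paste(db[2:4], collapse = "x"), "]")
  }
  y <- array(0, c(da[1L] + db[1L], da[2:4]))
  y[seq_len(da[1L]), , , ] <- a$value
  y[da[1L] + seq_len(db[1L]), , , ] <- b$value
  ad_node(ctx$tape, y, track = a$track || b$track, backward = function(g) {
    if (a$track) ad_accum(a, g[seq_len(da[1L]), , , , drop = FALSE])
    if (b$track) ad_accum(b, g[da[1L] + seq_len(db[1L]), , , , drop = FALSE])
  })
}

# Per-channel weighting: x * r, r broadcast over space.  r: length-C vector.
op_mul_ch <- function(ctx, x, r) {
  xd <- vol_dim(x$value)
  if (length(r$value) != xd[1L]) {
    stop("channel mismatch: input has ", xd[1L],
         " channels, weighting vector has ", length(r$value))
  }
  y <- x$value * r$value
  ad_node(ctx$tape, y, track = x$track || r$track, backward = function(g) {
    if (x$track) ad_accum(x, g * r$value)
    if (r$track) ad_accum(r, rowSums(matrix(g * x$value, nrow = xd[1L])))
  })
}

# --- trilinear x2 upsampling (half-pixel convention), separable per axis ----

up2_weights <- function(L) {
  # output o (0-based) samples input at o/2 - 0.25
  m <- 0:(L - 1L)
  lo_e <- pmax(m - 1L, 0L) + 1L          # even outputs o = 2m
  hi_e <- m + 1L
  lo_o <- m + 1L                         # odd outputs o = 2m + 1
  hi_o <- pmin(m + 1L, L - 1L) + 1L
  idx_lo <- integer(2L * L); idx_hi <- integer(2L * L)
  w_lo <- numeric(2L * L); w_hi <- numeric(2L * L)
  idx_lo[seq(1L, 2L * L, 2L)] <- lo_e; idx_hi[seq(1L, 2L * L, 2L)] <- hi_e
  idx_lo[seq(2L, 2L * L, 2L)] <- lo_o; idx_hi[seq(2L, 2L * L, 2L)] <- hi_o
  w_lo[seq(1L, 2L * L, 2L)] <- 0.25; w_hi[seq(1L, 2L * L, 2L)] <- 0.75
  w_lo[seq(2L, 2L * L, 2L)] <- 0.75; w_hi[seq(2L, 2L * L, 2L)] <- 0.25
  list(lo = idx_lo, hi = idx_hi, wlo = w_lo, whi = w_hi)
}

up2_axis <- function(v, dims, ax) {
  P <- prod(dims[seq_len(ax - 1L)])
  L <- dims[ax]
  Q <- prod(dims[seq_len(length(dims))[-seq_len(ax)]])
  dim(v) <- c(P, L, Q)
  wt <- up2_weights(L)
  y <- v[, wt$lo, , drop = FALSE] * rep(wt$wlo, each = P) +
    v[, wt$hi, , drop = FALSE] * rep(wt$whi, each = P)
  dims[ax] <- 2L * L
  dim(y) <- dims
  y
}

# Adjoint of up2_axis: scatter output-axis gradients back to input length L.
up2_axis_adj <- function(g, dims_in, ax) {
  P <- prod(dims_in[seq_len(ax - 1L)])
  L <- dims_in[ax]
  Q <- prod(dims_in[seq_len(length(dims_in))[-seq_len(ax)]])
  dim(g) <- c(P, 2L * L, Q)
  E <- g[, seq(1L, 2L * L, 2L), , drop = FALSE]  # even outputs
  O <- g[, seq(2L, 2L * L, 2L), , drop = FALSE]  # odd outputs
  dx <- 0.75 * (E + O)
  if (L > 1L) {
    dx[, seq_len(L - 1L), ] <- dx[, seq_len(L - 1L), , drop = FALSE] +
      0.25 * E[, 2:L, , drop = FALSE]
    dx[, 2:L, ] <- dx[, 2:L, , drop = FALSE] +
      0.25 * O[, seq_len(L - 1L), , drop = FALSE]
  }
  # clamped boundary taps fall onto the edge voxels
  dx[, 1L, ] <- dx[, 1L, , drop = FALSE] + 0.25 * E[, 1L, , drop = FALSE]
  dx[, L, ] <- dx[, L, , drop = FALSE] + 0.25 * O[, L, , drop = FALSE]
  dim(dx) <- dims_in
  dx
}

up2_arr <- function(v) {
  d <- vol_dim(v)
  y <- cpp_up2_fwd(v, as.integer(d))
  dim(y) <- c(d[1L], 2L * d[2:4])
  y
}

# Pure-R separable reference of the same upsampler (kept as the independent
# oracle for the C++ kernel in the tests).
up2_arr_ref <- function(v) {
  for (ax in 2:4) {
    v <- up2_axis(v, dim(v), ax)
  }
  v
}

op_up2 <- function(ctx, x) {
  xd <- vol_dim(x$value)
  y <- up2_arr(x$value)
  ad_node(ctx$tape, y, track = x$track, backward = function(g) {
    dx <- cpp_up2_bwd(g, as.integer(xd))
    dim(dx) <- xd
    ad_accum(x, dx)
  })
}

op_sum <- function(ctx, x) {
  xd <- dim(x$value)
  ad_node(ctx$tape, sum(x$value), track = x$track, backward = function(g) {
    dx <- array(g, xd)
    ad_accum(x, dx)
  })
}

# --- losses -----------------------------------------------------------------

# Soft Dice loss over region channels; masks is a plain 0/1 array.
op_soft_dice <- function(ctx, probs, masks, eps = 1e-5) {
  pd <- vol_dim(probs$value)
  R <- pd[1L]
  P <- matrix(probs$value, nrow = R)
  G <- matrix(masks, nrow = R)
  psum <- rowSums(P)
  gsum <- rowSums(G)
  inter <- rowSums(P * G)
  num <- 2 * inter + eps
  den <- psum + gsum + eps
  loss <- 1 - mean(num / den)
  ad_node(ctx$tape, loss, track = probs$track, backward = function(g) {
    dp <- -(g / R) * (2 * G * rep(den, times = ncol(P)) -
                        rep(num, times = ncol(P))) / rep(den^2, times = ncol(P))
    dim(dp) <- pd
    ad_accum(probs, dp)
  })
}

# Mean binary cross-entropy over all voxels and region channels.
op_bce <- function(ctx, probs, masks, clamp = 1e-7) {
  pd <- vol_dim(probs$value)
  p <- pmin(pmax(probs$value, clamp), 1 - clamp)
  n <- length(p)
  loss <- -mean(masks * log(p) + (1 - masks) * log(1 - p))
  ad_node(ctx$tape, loss, track = probs$track, backward = function(g) {
    dp <- g * (p - masks) / (p * (1 - p)) / n
    dim(dp) <- pd
    ad_accum(probs, dp)
  })
}
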