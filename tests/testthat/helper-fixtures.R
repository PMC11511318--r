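# Shared fixtures: tiny volumes, scaled-down model configs, and brute-force
# oracles used across the unit tests.

rand_vol <- function(C, D, H = D, W = D, seed = 1L) {
  set.seed(seed)
  array(rnorm(C * D * H * W), c(C, D, H, W))
}

tiny_config <- function(...) {
  ehff_config(base_width = 4L, hfw_hidden = c(3L, 4L, 5L, 6L, 7L), seed = 7L,
              ...)
}

# Direct (brute-force) dense 3D convolution used as the independent oracle.
naive_conv3d <- function(x, w, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  d <- dim(x)
  cout <- dim(w)[1L]
  os <- (d[2:4] + 2L * pad - k) %/% stride + 1L
  y <- array(0, c(cout, os))
  for (od in 1:os[1]) for (oh in 1:os[2]) for (ow in 1:os[3]) {
    for (kd in 1:k) for (kh in 1:k) for (kw in 1:k) {
      id <- (od - 1L) * stride - pad + kd
      ih <- (oh - 1L) * stride - pad + kh
      iw <- (ow - 1L) * stride - pad + kw
      if (id >= 1 && id <= d[2] && ih >= 1 && ih <= d[3] &&
          iw >= 1 && iw <= d[4]) {
        for (co in 1:cout) {
          y[co, od, oh, ow] <- y[co, od, oh, ow] +
            sum(w[co, , kd, kh, kw] * x[, id, ih, iw])
        }
      }
    }
  }
  y
}

# Depthwise convolution expressed through the dense oracle.
naive_dwconv3d <- function(x, wd, k) {
  C <- dim(x)[1L]
  wfull <- array(0, c(C, C, k, k, k))
  for (cc in seq_len(C)) wfull[cc, cc, , , ] <- array(wd[cc, ], c(k, k, k))
  naive_conv3d(x, wfull, k)
}

zero_block_params <- function(module) {
  module$params <- lapply(module$params, function(p) p * 0)
  module
}

# Set every convolution weight/bias to zero but leave norm affines at
# identity, exposing the pure residual path.
zero_convs_identity_norms <- function(params) {
  for (nm in names(params)) {
    if (grepl("\\.(w|b)$", nm)) params[[nm]] <- params[[nm]] * 0
  }
  params
}
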