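test_that("macro-perception preserves shape and matches the direct convolution oracle", {
  cfg <- block_config(channels = 3L, lk_kernel = 7L, seed = 11L)
  blk <- mp_block(cfg)
  x <- rand_vol(3, 15, seed = 2L)
  y <- forward(blk, x)
  expect_identical(dim(y), dim(x))

  ref <- naive_dwconv3d(x, blk$params[["mp.w"]], 7L) + blk$params[["mp.b"]]
  expect_equal(y, ref, tolerance = 1e-12)

  # single-voxel impulse: support confined to the 7^3 neighbourhood
  imp <- array(0, c(3, 15, 15, 15))
  imp[2, 8, 8, 8] <- 1
  blk0 <- blk
  blk0$params[["mp.b"]] <- blk0$params[["mp.b"]] * 0
  yi <- forward(blk0, imp)
  nz <- which(yi != 0, arr.ind = TRUE)
  expect_true(all(abs(nz[, 2:4] - 8L) <= 3L))

  # zeroed weights and bias give the zero map
  expect_true(all(forward(zero_block_params(blk), x) == 0))

  expect_error(forward(blk, rand_vol(5, 8)), "channel mismatch.*5.*3")
})

test_that("micro-focus is voxel-wise: shape preserving and permutation equivariant", {
  cfg <- block_config(channels = 6L, mf_expansion = 3L, seed = 5L)
  blk <- mf_block(cfg)
  x <- rand_vol(6, 4, seed = 3L)
  y <- forward(blk, x)
  expect_identical(dim(y), dim(x))

  # permuting voxel positions of the input permutes the output identically
  set.seed(4)
  perm <- sample(4 * 4 * 4)
  xp <- array(matrix(x, nrow = 6)[, perm], dim(x))
  yp <- forward(blk, xp)
  expect_equal(array(matrix(y, nrow = 6)[, perm], dim(y)), yp,
               tolerance = 1e-12)

  # zeroed final projection gives the zero map
  blk$params[["mf.pw2.w"]] <- blk$params[["mf.pw2.w"]] * 0
  blk$params[["mf.pw2.b"]] <- blk$params[["mf.pw2.b"]] * 0
  expect_true(all(forward(blk, x) == 0))
})

test_that("AFL equals the manual composition of its four residual sub-steps", {
  cfg <- block_config(channels = 5L, lk_kernel = 3L, mf_expansion = 2L,
                      seed = 9L)
  blk <- afl_block(cfg)
  x <- rand_vol(5, 6, seed = 6L)
  y <- forward(blk, x)
  expect_identical(dim(y), dim(x))

  # independent re-composition in plain R
  p <- blk$params
  ln <- function(v, g, b) {
    X <- matrix(v, nrow = dim(v)[1])
    mu <- colMeans(X)
    Xc <- sweep(X, 2, mu)
    istd <- 1 / sqrt(colMeans(Xc^2) + 1e-6)
    array(sweep(Xc, 2, istd, `*`) * g + b, dim(v))
  }
  gelu <- function(v) v * pnorm(v)
  mp <- function(v, pfx) naive_dwconv3d(v, p[[paste0(pfx, ".w")]], 3L) +
    p[[paste0(pfx, ".b")]]
  mf <- function(v, pfx) {
    h <- p[[paste0(pfx, ".pw1.w")]] %*% matrix(v, nrow = dim(v)[1]) +
      p[[paste0(pfx, ".pw1.b")]]
    o <- p[[paste0(pfx, ".pw2.w")]] %*% gelu(h) + p[[paste0(pfx, ".pw2.b")]]
    array(o, dim(v))
  }
  z <- x
  for (it in 1:2) {
    pre <- paste0("afl.it", it)
    z <- mp(ln(z, p[[paste0(pre, ".ln1.gm")]], p[[paste0(pre, ".ln1.bt")]]),
            paste0(pre, ".mp")) + z
    z <- mf(ln(z, p[[paste0(pre, ".ln2.gm")]], p[[paste0(pre, ".ln2.bt")]]),
            paste0(pre, ".mf")) + z
  }
  expect_equal(y, z, tolerance = 1e-10)
})

test_that("AFL with zeroed convolutions is the bit-exact identity", {
  cfg <- block_config(channels = 4L, lk_kernel = 3L, seed = 2L)
  blk <- afl_block(cfg)
  for (nm in names(blk$params)) {
    if (grepl("\\.(w|b)$", nm)) blk$params[[nm]] <- blk$params[[nm] ] * 0
  }
  x <- rand_vol(4, 5, seed = 8L)
  expect_identical(forward(blk, x), x)
})

test_that("down-sampler halves spatial extents or changes channels only", {
  blk <- downsample_block(3L, 6L, spatial_halving = TRUE, seed = 1L)
  x <- rand_vol(3, 8, 6, 4, seed = 9L)
  y <- forward(blk, x)
  expect_identical(dim(y), c(6L, 4L, 3L, 2L))
  ref <- naive_conv3d(x, blk$params[["down.w"]], 2L, stride = 2L, pad = 0L) +
    blk$params[["down.b"]]
  expect_equal(y, ref, tolerance = 1e-12)

  blk2 <- downsample_block(3L, 6L, spatial_halving = FALSE, seed = 1L)
  expect_identical(dim(forward(blk2, x)), c(6L, 8L, 6L, 4L))

  xodd <- rand_vol(3, 7, 8, 8, seed = 10L)
  expect_error(forward(blk, xodd), "axis 0.*7.*odd")
})

test_that("block forward passes are deterministic and finite", {
  cfg <- block_config(channels = 4L, lk_kernel = 3L, seed = 3L)
  blk <- afl_block(cfg)
  x <- rand_vol(4, 6, seed = 12L)
  y1 <- forward(blk, x)
  y2 <- forward(blk, x)
  expect_identical(y1, y2)
  expect_true(all(is.finite(y1)))
})
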