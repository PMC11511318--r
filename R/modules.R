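#' Configuration for a single network building block
#'
#' @param channels Number of feature channels the block operates on.
#' @param lk_kernel Odd cubic kernel extent of the macro-perception (large
#'   kernel) convolution. Default 7.
#' @param mf_expansion Hidden-width multiplier of the micro-focus pointwise
#'   pair (channels -> channels * mf_expansion -> channels). Default 4.
#' @param mp_form `"depthwise"` (one 7x7x7 kernel per channel, the default)
#'   or `"dense"` (full channel-mixing large kernel).
#' @param seed Integer seed for weight initialisation.
#' @return A `block_config` list.
#' @export
block_config <- function(channels, lk_kernel = 7L, mf_expansion = 4L,
                         mp_form = c("depthwise", "dense"), seed = 42L) {
  mp_form <- match.arg(mp_form)
  stopifnot(channels >= 1L, mf_expansion >= 1L)
  if (lk_kernel %% 2L != 1L) {
    stop("lk_kernel must be odd for symmetric same padding, got ", lk_kernel)
  }
  structure(list(channels = as.integer(channels),
                 lk_kernel = as.integer(lk_kernel),
                 mf_expansion = as.integer(mf_expansion),
                 mp_form = mp_form, seed = as.integer(seed)),
            class = "block_config")
}

new_module <- function(params, fwd, channels) {
  structure(list(params = params, fwd = fwd, channels = channels),
            class = "ehff_module")
}

check_block_input <- function(x, channels) {
  d <- vol_dim(x)
  if (!is.double(x)) stop("input must be a double-precision array")
  if (d[1L] != channels) {
    stop("channel mismatch: input has ", d[1L], " channels, block expects ",
         channels)
  }
  invisible(d)
}

#' Macro-perception block: large-kernel 3D convolution at constant width
#'
#' Stride-1, same-padding convolution whose per-voxel receptive field is
#' `lk_kernel^3`; depthwise by default.
#'
#' @param cfg A [block_config()].
#' @return An `ehff_module`.
#' @export
mp_block <- function(cfg) {
  pm <- new_param_store()
  with_seed(cfg$seed, mk_mp(pm, "mp", cfg$channels, cfg$lk_kernel, cfg$mp_form))
  new_module(pm$params,
             function(ctx, x) f_mp(ctx, "mp", x, cfg$lk_kernel, cfg$mp_form),
             cfg$channels)
}

#' Micro-focus block: voxel-wise channel mixing
#'
#' Two 1x1x1 linear maps (widths C -> C * mf_expansion -> C) with a GELU
#' between; purely voxel-local, so spatial permutations commute with it.
#'
#' @inheritParams mp_block
#' @return An `ehff_module`.
#' @export
mf_block <- function(cfg) {
  pm <- new_param_store()
  with_seed(cfg$seed, mk_mf(pm, "mf", cfg$channels, cfg$mf_expansion))
  new_module(pm$params, function(ctx, x) f_mf(ctx, "mf", x), cfg$channels)
}

#' Adaptive feature learning block
#'
#' Two residual macro-perception + micro-focus iterations with channel-wise
#' layer normalisation before each sub-step; shape preserving.
#'
#' @inheritParams mp_block
#' @return An `ehff_module`.
#' @export
afl_block <- function(cfg) {
  pm <- new_param_store()
  with_seed(cfg$seed,
            mk_afl(pm, "afl", cfg$channels, cfg$lk_kernel, cfg$mf_expansion,
                   cfg$mp_form))
  new_module(pm$params,
             function(ctx, x) f_afl(ctx, "afl", x, cfg$lk_kernel, cfg$mp_form),
             cfg$channels)
}

#' Inter-stage down-sampling block
#'
#' With `spatial_halving`, a 2x2x2 stride-2 convolution that halves every
#' spatial extent while changing the channel count; without it, a 1x1x1
#' convolution that changes channels only (the deepest-stage case).
#'
#' @param in_channels,out_channels Channel counts before and after.
#' @param spatial_halving Halve the spatial extents?
#' @param seed Integer seed for weight initialisation.
#' @return An `ehff_module`.
#' @export
downsample_block <- function(in_channels, out_channels, spatial_halving = TRUE,
                             seed = 42L) {
  pm <- new_param_store()
  with_seed(seed, mk_down(pm, "down", in_channels, out_channels,
                          spatial_halving))
  new_module(pm$params, function(ctx, x) f_down(ctx, "down", x, spatial_halving),
             in_channels)
}

#' Run a building block forward
#'
#' @param module An `ehff_module` from [mp_block()], [mf_block()],
#'   [afl_block()] or [downsample_block()].
#' @param x A `[C, D, H, W]` numeric array.
#' @return The output feature volume as a numeric array.
#' @export
forward <- function(module, x) {
  UseMethod("forward")
}

#' @export
forward.ehff_module <- function(module, x) {
  check_block_input(x, module$channels)
  ctx <- ad_ctx(module$params, tape = NULL)
  module$fwd(ctx, ad_leaf(NULL, x))$value
}

# --- hierarchical feature weighting as a standalone module ------------------

#' Create a hierarchical feature weighting (HFW) state
#'
#' Refines a skip feature through a compression 1x1x1 projection, two
#' residual refinement units (two dense 3x3x3 convolutions, layer norm and a
#' closing 1x1x1 each), multiplies the refined feature E by a learnable
#' per-channel weighting vector R (bridged by a residual, i.e. E + E * R),
#' applies one more refinement unit and expands back to the input width.
#'
#' @param channels Channel count of the skip feature this state refines.
#' @param hidden Width of the compressed refinement path (default
#'   `max(4, channels %/% 2)`).
#' @param r_init `"uniform"` (U(0,1), default) or `"normal"` for R.
#' @param seed Integer seed.
#' @return An `hfw_state`.
#' @export
hfw_state <- function(channels, hidden = max(4L, channels %/% 2L),
                      r_init = c("uniform", "normal"), seed = 42L) {
  r_init <- match.arg(r_init)
  pm <- new_param_store()
  with_seed(seed, mk_hfw(pm, "hfw", channels, hidden, r_init))
  structure(list(params = pm$params, channels = as.integer(channels),
                 hidden = as.integer(hidden)),
            class = "hfw_state")
}

#' Apply an HFW state to a skip feature
#'
#' @param state An [hfw_state()].
#' @param z A `[C, D, H, W]` numeric array with `C == state$channels`.
#' @return The weighted feature, same shape as `z`.
#' @export
hfw_forward <- function(state, z) {
  check_block_input(z, state$channels)
  ctx <- ad_ctx(state$params, tape = NULL)
  f_hfw(ctx, "hfw", ad_leaf(NULL, z))$value
}

#' Finite-difference check of the gradient of the weighting vector R
#'
#' Defines the scalar loss `sum(hfw_forward(state, z))`, computes the
#' analytic gradient of R by backpropagation, and compares it against
#' central finite differences.
#'
#' @param state An [hfw_state()].
#' @param z Input feature volume.
#' @param eps Finite-difference step (default 1e-4).
#' @return A list with `analytic`, `numeric`, and `max_rel_error` (the
#'   maximum relative error over the entries of R).
#' @export
hfw_gradient_check <- function(state, z, eps = 1e-4) {
  check_block_input(z, state$channels)
  tape <- ad_tape()
  ctx <- ad_ctx(state$params, tape = tape)
  out <- f_hfw(ctx, "hfw", ad_leaf(tape, z))
  loss <- op_sum(ctx, out)
  ad_backward(tape, loss)
  analytic <- ctx$leaves[["hfw.r"]]$grad
  r0 <- state$params[["hfw.r"]]
  numeric <- vapply(seq_along(r0), function(i) {
    pp <- state$params
    pp[["hfw.r"]][i] <- r0[i] + eps
    up <- sum(f_hfw(ad_ctx(pp, NULL), "hfw", ad_leaf(NULL, z))$value)
    pp[["hfw.r"]][i] <- r0[i] - eps
    dn <- sum(f_hfw(ad_ctx(pp, NULL), "hfw", ad_leaf(NULL, z))$value)
    (up - dn) / (2 * eps)
  }, numeric(1))
  denom <- pmax(abs(analytic), abs(numeric), 1e-8)
  list(analytic = analytic, numeric = numeric,
       max_rel_error = max(abs(analytic - numeric) / denom))
}
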