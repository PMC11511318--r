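# ---------------------------------------------------------------------------
# Parameter construction and forward passes for the network building blocks.
#
# Parameters live in a flat named list ("enc.stage1.afl1.it1.mp.w", ...);
# every block is a pair of functions: mk_* adds freshly initialised arrays to
# a parameter accumulator, f_* runs the block inside an autodiff context.
# ---------------------------------------------------------------------------

# Truncated-normal(sd, cut at 2 sd) initialisation for convolution weights.
init_tn <- function(n, sd = 0.02) {
  qnorm(runif(n, pnorm(-2), pnorm(2))) * sd
}

new_param_store <- function() {
  pm <- new.env(parent = emptyenv())
  pm$params <- list()
  pm
}

mk_par <- function(pm, name, value) {
  pm$params[[name]] <- value
  invisible(NULL)
}

# --- primitive layers -------------------------------------------------------

mk_ln <- function(pm, pfx, C) {
  mk_par(pm, paste0(pfx, ".gm"), rep(1, C))
  mk_par(pm, paste0(pfx, ".bt"), rep(0, C))
}

f_ln <- function(ctx, pfx, x) {
  op_ln(ctx, x, ctx_param(ctx, paste0(pfx, ".gm")),
        ctx_param(ctx, paste0(pfx, ".bt")))
}

mk_conv <- function(pm, pfx, cin, cout, k, bias = TRUE) {
  mk_par(pm, paste0(pfx, ".w"),
         array(init_tn(cout * cin * k^3), c(cout, cin, k, k, k)))
  if (bias) mk_par(pm, paste0(pfx, ".b"), rep(0, cout))
}

# bias leaf, or NULL for bias-free layers (convolutions feeding a norm)
ctx_bias <- function(ctx, name) {
  if (is.null(ctx$params[[name]])) NULL else ctx_param(ctx, name)
}

f_conv <- function(ctx, pfx, x, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  op_conv3d(ctx, x, ctx_param(ctx, paste0(pfx, ".w")),
            ctx_bias(ctx, paste0(pfx, ".b")), k, stride, pad)
}

mk_dw <- function(pm, pfx, C, k, bias = TRUE) {
  mk_par(pm, paste0(pfx, ".w"), array(init_tn(C * k^3), c(C, k^3)))
  if (bias) mk_par(pm, paste0(pfx, ".b"), rep(0, C))
}

f_dw <- function(ctx, pfx, x, k) {
  op_dwconv3d(ctx, x, ctx_param(ctx, paste0(pfx, ".w")),
              ctx_bias(ctx, paste0(pfx, ".b")), k)
}

mk_pw <- function(pm, pfx, cin, cout, bias = TRUE) {
  mk_par(pm, paste0(pfx, ".w"), matrix(init_tn(cout * cin), cout, cin))
  if (bias) mk_par(pm, paste0(pfx, ".b"), rep(0, cout))
}

f_pw <- function(ctx, pfx, x) {
  op_pw(ctx, x, ctx_param(ctx, paste0(pfx, ".w")),
        ctx_bias(ctx, paste0(pfx, ".b")))
}

mk_ct2 <- function(pm, pfx, cin, cout) {
  mk_par(pm, paste0(pfx, ".w"),
         array(init_tn(cout * cin * 8), c(cout, cin, 2, 2, 2)))
  mk_par(pm, paste0(pfx, ".b"), rep(0, cout))
}

f_ct2 <- function(ctx, pfx, x) {
  op_convtrans2(ctx, x, ctx_param(ctx, paste0(pfx, ".w")),
                ctx_param(ctx, paste0(pfx, ".b")))
}

# --- macro-perception / micro-focus / AFL -----------------------------------

mk_mp <- function(pm, pfx, C, k, form = "depthwise") {
  if (form == "depthwise") mk_dw(pm, pfx, C, k) else mk_conv(pm, pfx, C, C, k)
}

f_mp <- function(ctx, pfx, x, k, form = "depthwise") {
  if (form == "depthwise") f_dw(ctx, pfx, x, k) else f_conv(ctx, pfx, x, k)
}

mk_mf <- function(pm, pfx, C, expansion) {
  mk_pw(pm, paste0(pfx, ".pw1"), C, C * expansion)
  mk_pw(pm, paste0(pfx, ".pw2"), C * expansion, C)
}

f_mf <- function(ctx, pfx, x) {
  h <- f_pw(ctx, paste0(pfx, ".pw1"), x)
  h <- op_gelu(ctx, h)
  f_pw(ctx, paste0(pfx, ".pw2"), h)
}

# One AFL block: two residual macro-perception + micro-focus iterations,
# each sub-step preceded by channel-wise layer normalisation.
mk_afl <- function(pm, pfx, C, k, expansion, form = "depthwise") {
  for (it in 1:2) {
    p <- paste0(pfx, ".it", it)
    mk_ln(pm, paste0(p, ".ln1"), C)
    mk_mp(pm, paste0(p, ".mp"), C, k, form)
    mk_ln(pm, paste0(p, ".ln2"), C)
    mk_mf(pm, paste0(p, ".mf"), C, expansion)
  }
}

f_afl <- function(ctx, pfx, x, k, form = "depthwise") {
  for (it in 1:2) {
    p <- paste0(pfx, ".it", it)
    h <- f_ln(ctx, paste0(p, ".ln1"), x)
    h <- f_mp(ctx, paste0(p, ".mp"), h, k, form)
    x <- op_add(ctx, h, x)
    h <- f_ln(ctx, paste0(p, ".ln2"), x)
    h <- f_mf(ctx, paste0(p, ".mf"), h)
    x <- op_add(ctx, h, x)
  }
  x
}

# --- inter-stage down-sampler ----------------------------------------------

mk_down <- function(pm, pfx, cin, cout, halve) {
  if (halve) mk_conv(pm, pfx, cin, cout, 2L) else mk_pw(pm, pfx, cin, cout)
}

f_down <- function(ctx, pfx, x, halve) {
  if (halve) {
    xd <- vol_dim(x$value)
    odd <- which(xd[2:4] %% 2L != 0L)
    if (length(odd) > 0L) {
      stop("cannot halve spatial axis ", odd[1L] - 1L, ": extent ",
           xd[1L + odd[1L]], " is odd")
    }
    f_conv(ctx, pfx, x, 2L, stride = 2L, pad = 0L)
  } else {
    f_pw(ctx, pfx, x)
  }
}

# --- depthwise-separable conv block (skip projections, decoder fusion) ------

mk_scb <- function(pm, pfx, C) {
  for (u in 1:2) {
    p <- paste0(pfx, ".u", u)
    mk_dw(pm, paste0(p, ".dw"), C, 3L, bias = FALSE)
    mk_pw(pm, paste0(p, ".pw"), C, C, bias = FALSE)
    mk_ln(pm, paste0(p, ".ln"), C)
  }
}

f_scb <- function(ctx, pfx, x) {
  h <- x
  for (u in 1:2) {
    p <- paste0(pfx, ".u", u)
    h <- f_dw(ctx, paste0(p, ".dw"), h, 3L)
    h <- f_pw(ctx, paste0(p, ".pw"), h)
    h <- f_ln(ctx, paste0(p, ".ln"), h)
    h <- op_gelu(ctx, h)
  }
  op_add(ctx, h, x)
}

# --- hierarchical feature weighting (HFW) -----------------------------------

# Refinement unit: two dense 3x3x3 convolutions with layer norm and GELU,
# closed by a 1x1x1 projection; bridged by a residual connection.
mk_hfw_unit <- function(pm, pfx, h) {
  mk_conv(pm, paste0(pfx, ".c1"), h, h, 3L, bias = FALSE)
  mk_ln(pm, paste0(pfx, ".ln1"), h)
  mk_conv(pm, paste0(pfx, ".c2"), h, h, 3L, bias = FALSE)
  mk_ln(pm, paste0(pfx, ".ln2"), h)
  mk_pw(pm, paste0(pfx, ".pw"), h, h)
}

f_hfw_unit <- function(ctx, pfx, x) {
  h <- f_conv(ctx, paste0(pfx, ".c1"), x, 3L)
  h <- f_ln(ctx, paste0(pfx, ".ln1"), h)
  h <- op_gelu(ctx, h)
  h <- f_conv(ctx, paste0(pfx, ".c2"), h, 3L)
  h <- f_ln(ctx, paste0(pfx, ".ln2"), h)
  h <- op_gelu(ctx, h)
  h <- f_pw(ctx, paste0(pfx, ".pw"), h)
  op_add(ctx, h, x)
}

# Final stack: same convolution/norm body, but its closing 1x1x1 is the
# expansion back to the skip width, applied outside the residual bridge.
mk_hfw_final <- function(pm, pfx, h) {
  mk_conv(pm, paste0(pfx, ".c1"), h, h, 3L, bias = FALSE)
  mk_ln(pm, paste0(pfx, ".ln1"), h)
  mk_conv(pm, paste0(pfx, ".c2"), h, h, 3L, bias = FALSE)
  mk_ln(pm, paste0(pfx, ".ln2"), h)
}

f_hfw_final <- function(ctx, pfx, x) {
  h <- f_conv(ctx, paste0(pfx, ".c1"), x, 3L)
  h <- f_ln(ctx, paste0(pfx, ".ln1"), h)
  h <- op_gelu(ctx, h)
  h <- f_conv(ctx, paste0(pfx, ".c2"), h, 3L)
  h <- f_ln(ctx, paste0(pfx, ".ln2"), h)
  h <- op_gelu(ctx, h)
  op_add(ctx, h, x)
}

mk_hfw <- function(pm, pfx, C, hidden, r_init = "uniform") {
  mk_pw(pm, paste0(pfx, ".compress"), C, hidden, bias = FALSE)
  mk_ln(pm, paste0(pfx, ".cln"), hidden)
  mk_hfw_unit(pm, paste0(pfx, ".ref1"), hidden)
  mk_hfw_unit(pm, paste0(pfx, ".ref2"), hidden)
  r <- if (r_init == "uniform") runif(hidden) else rnorm(hidden)
  mk_par(pm, paste0(pfx, ".r"), r)
  mk_hfw_final(pm, paste0(pfx, ".final"), hidden)
  mk_pw(pm, paste0(pfx, ".expand"), hidden, C)
}

f_hfw <- function(ctx, pfx, z) {
  e <- f_pw(ctx, paste0(pfx, ".compress"), z)
  e <- f_ln(ctx, paste0(pfx, ".cln"), e)
  e <- op_gelu(ctx, e)
  e <- f_hfw_unit(ctx, paste0(pfx, ".ref1"), e)
  e <- f_hfw_unit(ctx, paste0(pfx, ".ref2"), e)
  w <- op_add(ctx, op_mul_ch(ctx, e, ctx_param(ctx, paste0(pfx, ".r"))), e)
  o <- f_hfw_final(ctx, paste0(pfx, ".final"), w)
  f_pw(ctx, paste0(pfx, ".expand"), o)
}
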