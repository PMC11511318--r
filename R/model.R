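# ---------------------------------------------------------------------------
# Full EHFF model: stem + four AFL/down-sampling stages, skip projections,
# HFW-weighted U-style decoder ladder, HFR auxiliary decoder, fused head.
#
# Pyramid level channels: base * c(1, 2, 4, 8, 16) at spatial scales
# 1/2, 1/4, 1/8, 1/16, 1/16 of the input.
# ---------------------------------------------------------------------------

#' Build an EHFF model
#'
#' Instantiates every trainable parameter array from the configuration,
#' seeded deterministically.
#'
#' @param config An [ehff_config()].
#' @return An `ehff_model` (flat named parameter list + configuration).
#' @export
build_ehff <- function(config) {
  stopifnot(inherits(config, "ehff_config"))
  w <- ehff_widths(config$base_width)
  pm <- new_param_store()
  with_seed(config$seed, {
    # encoder
    mk_conv(pm, "enc.stem.conv", config$in_channels, w[1L], config$lk_kernel,
            bias = !config$stem_norm)
    if (config$stem_norm) mk_ln(pm, "enc.stem.ln", w[1L])
    for (i in 1:4) {
      for (d in seq_len(config$depths[i])) {
        mk_afl(pm, sprintf("enc.s%d.afl%d", i, d), w[i], config$lk_kernel,
               config$mf_expansion, config$mp_form)
      }
      mk_down(pm, sprintf("enc.s%d.down", i), w[i], w[i + 1L], halve = i < 4L)
    }
    # skip projections Z1..Z5
    for (l in 1:5) mk_scb(pm, paste0("proj.z", l), w[l])
    # hierarchical feature weighting
    if (config$hfw_enabled) {
      for (l in 1:5) {
        mk_hfw(pm, paste0("hfw.l", l), w[l], config$hfw_hidden[l],
               config$hfw_r_init)
      }
    }
    # primary decoder ladder
    for (lvl in 4:1) {
      if (lvl == 4L) {
        mk_pw(pm, "dec.s4.up", w[5L], w[4L])  # 1/16 -> 1/16, channels only
      } else {
        mk_ct2(pm, sprintf("dec.s%d.up", lvl), w[lvl + 1L], w[lvl])
      }
      mk_pw(pm, sprintf("dec.s%d.fuse", lvl), 2L * w[lvl], w[lvl],
            bias = FALSE)
      mk_ln(pm, sprintf("dec.s%d.ln", lvl), w[lvl])
      mk_scb(pm, sprintf("dec.s%d.scb", lvl), w[lvl])
    }
    mk_pw(pm, "dec.t.fuse", 2L * w[1L], w[1L], bias = FALSE)
    mk_ln(pm, "dec.t.ln", w[1L])
    mk_scb(pm, "dec.t.scb", w[1L])
    mk_ct2(pm, "dec.t.up", w[1L], w[1L])
    # hierarchical feature retention
    if (config$hfr_enabled) {
      for (l in 1:5) mk_pw(pm, paste0("hfr.l", l), w[l], w[1L])
    }
    # terminal prediction head
    mk_pw(pm, "head", w[1L], config$out_channels)
  })
  structure(list(params = pm$params, config = config, widths = w),
            class = "ehff_model")
}

check_model_input <- function(model, image) {
  d <- vol_dim(image)
  if (!is.double(image)) stop("input image must be a double-precision array")
  if (d[1L] != model$config$in_channels) {
    stop("channel mismatch: input has ", d[1L], " channels, model expects ",
         model$config$in_channels)
  }
  bad <- which(d[2:4] %% 16L != 0L)
  if (length(bad) > 0L) {
    stop("spatial extent ", d[1L + bad[1L]], " on axis ", bad[1L] - 1L,
         " is not divisible by 16; pad the volume to a multiple of 16")
  }
  invisible(d)
}

# --- forward passes (ctx-level) ---------------------------------------------

ehff_stem_ctx <- function(ctx, model, x) {
  cfg <- model$config
  s <- f_conv(ctx, "enc.stem.conv", x, cfg$lk_kernel, stride = 2L,
              pad = (cfg$lk_kernel - 1L) %/% 2L)
  if (cfg$stem_norm) s <- f_ln(ctx, "enc.stem.ln", s)
  s
}

ehff_encode_ctx <- function(ctx, model, x) {
  cfg <- model$config
  s <- ehff_stem_ctx(ctx, model, x)
  pyr <- vector("list", 5L)
  names(pyr) <- c("stem", paste0("s", 1:4))
  pyr[[1L]] <- s
  cur <- s
  for (i in 1:4) {
    for (d in seq_len(cfg$depths[i])) {
      cur <- f_afl(ctx, sprintf("enc.s%d.afl%d", i, d), cur, cfg$lk_kernel,
                   cfg$mp_form)
    }
    cur <- f_down(ctx, sprintf("enc.s%d.down", i), cur, halve = i < 4L)
    pyr[[i + 1L]] <- cur
  }
  pyr
}

ehff_project_ctx <- function(ctx, model, pyr) {
  lapply(1:5, function(l) f_scb(ctx, paste0("proj.z", l), pyr[[l]]))
}

ehff_skip_ctx <- function(ctx, model, l, z) {
  if (model$config$hfw_enabled) f_hfw(ctx, paste0("hfw.l", l), z) else z
}

ehff_decode_ctx <- function(ctx, model, Z, stem_feat) {
  x <- ehff_skip_ctx(ctx, model, 5L, Z[[5L]])
  for (lvl in 4:1) {
    x <- if (lvl == 4L) {
      f_pw(ctx, "dec.s4.up", x)
    } else {
      f_ct2(ctx, sprintf("dec.s%d.up", lvl), x)
    }
    skip <- ehff_skip_ctx(ctx, model, lvl, Z[[lvl]])
    if (!all(vol_dim(x$value)[2:4] == vol_dim(skip$value)[2:4])) {
      stop("decoder/skip spatial mismatch at pyramid level ", lvl)
    }
    x <- op_cat(ctx, x, skip)
    x <- f_pw(ctx, sprintf("dec.s%d.fuse", lvl), x)
    x <- f_ln(ctx, sprintf("dec.s%d.ln", lvl), x)
    x <- op_gelu(ctx, x)
    x <- f_scb(ctx, sprintf("dec.s%d.scb", lvl), x)
  }
  x <- op_cat(ctx, x, stem_feat)
  x <- f_pw(ctx, "dec.t.fuse", x)
  x <- f_ln(ctx, "dec.t.ln", x)
  x <- op_gelu(ctx, x)
  x <- f_scb(ctx, "dec.t.scb", x)
  f_ct2(ctx, "dec.t.up", x)
}

# Number of x2 upsamplings needed to bring each pyramid level to full
# resolution (levels live at 1/2, 1/4, 1/8, 1/16, 1/16).
.hfr_up_times <- c(1L, 2L, 3L, 4L, 4L)

ehff_hfr_ctx <- function(ctx, model, Z, return_maps = FALSE) {
  maps <- lapply(1:5, function(l) {
    p <- f_pw(ctx, paste0("hfr.l", l), Z[[l]])
    for (t in seq_len(.hfr_up_times[l])) p <- op_up2(ctx, p)
    p
  })
  q <- maps[[1L]]
  for (l in 2:5) q <- op_add(ctx, q, maps[[l]])
  if (return_maps) list(q = q, maps = maps) else q
}

ehff_head_ctx <- function(ctx, model, P, Q = NULL) {
  cfg <- model$config
  fused <- if (cfg$hfr_enabled && !is.null(Q)) {
    op_add(ctx, op_scale(ctx, P, cfg$fusion_coefficient),
           op_scale(ctx, Q, 1 - cfg$fusion_coefficient))
  } else {
    P
  }
  op_sigmoid(ctx, f_pw(ctx, "head", fused))
}

ehff_forward_ctx <- function(ctx, model, x) {
  pyr <- ehff_encode_ctx(ctx, model, x)
  Z <- ehff_project_ctx(ctx, model, pyr)
  P <- ehff_decode_ctx(ctx, model, Z, pyr[[1L]])
  Q <- if (model$config$hfr_enabled) ehff_hfr_ctx(ctx, model, Z) else NULL
  probs <- ehff_head_ctx(ctx, model, P, Q)
  list(pyramid = pyr, Z = Z, P = P, Q = Q, probs = probs)
}

# --- public array-level surface ---------------------------------------------

#' Stem forward pass
#'
#' Large-kernel stride-2 convolution mapping the 4-modality input to the
#' base-width preliminary feature map at half resolution, followed by layer
#' normalisation.
#'
#' @param model An `ehff_model`.
#' @param image `[in_channels, D, H, W]` array, extents multiples of 16.
#' @return `[base_width, D/2, H/2, W/2]` array.
#' @export
stem_forward <- function(model, image) {
  check_model_input(model, image)
  ctx <- ad_ctx(model$params, NULL)
  ehff_stem_ctx(ctx, model, ad_leaf(NULL, image))$value
}

#' Encode an image into the hierarchical feature pyramid
#'
#' @inheritParams stem_forward
#' @return A list `stem, s1..s4` of feature volumes at scales 1/2, 1/4, 1/8,
#'   1/16, 1/16 with widths `base_width * c(1, 2, 4, 8, 16)`.
#' @export
encode <- function(model, image) {
  check_model_input(model, image)
  ctx <- ad_ctx(model$params, NULL)
  lapply(ehff_encode_ctx(ctx, model, ad_leaf(NULL, image)),
         function(nd) nd$value)
}

#' Project pyramid features into the skip representations Z1..Z5
#'
#' Each level passes through a shape-preserving separable convolution block.
#'
#' @param model An `ehff_model`.
#' @param pyramid The list returned by [encode()].
#' @return A list of five arrays Z1..Z5.
#' @export
project_pyramid <- function(model, pyramid) {
  ctx <- ad_ctx(model$params, NULL)
  nodes <- lapply(pyramid, function(a) ad_leaf(NULL, a))
  lapply(ehff_project_ctx(ctx, model, nodes), function(nd) nd$value)
}

#' Primary decoder: fuse skips deepest-first and restore full resolution
#'
#' @param model An `ehff_model`.
#' @param Z List of five arrays from [project_pyramid()].
#' @param stem_feat The stem feature volume from [encode()].
#' @return `[base_width, D, H, W]` array P at full resolution.
#' @export
decode <- function(model, Z, stem_feat) {
  ctx <- ad_ctx(model$params, NULL)
  Zn <- lapply(Z, function(a) ad_leaf(NULL, a))
  ehff_decode_ctx(ctx, model, Zn, ad_leaf(NULL, stem_feat))$value
}

#' Hierarchical feature retention (auxiliary decoder)
#'
#' Projects each Zi to base width, upsamples it to full resolution
#' (trilinear, repeated x2) and sums the five maps.
#'
#' @inheritParams decode
#' @param return_maps Also return the five individual full-resolution maps?
#' @return The summed map Q, or `list(q, maps)` when `return_maps`.
#' @export
hfr_forward <- function(model, Z, return_maps = FALSE) {
  if (!model$config$hfr_enabled) stop("HFR is disabled in this configuration")
  ctx <- ad_ctx(model$params, NULL)
  Zn <- lapply(Z, function(a) ad_leaf(NULL, a))
  out <- ehff_hfr_ctx(ctx, model, Zn, return_maps = return_maps)
  if (return_maps) {
    list(q = out$q$value, maps = lapply(out$maps, function(nd) nd$value))
  } else {
    out$value
  }
}

#' Terminal fusion and prediction
#'
#' Fuses the primary and auxiliary decoder outputs convexly
#' (`P * coef + Q * (1 - coef)`), applies the 1x1x1 prediction head and a
#' sigmoid, yielding per-voxel region probabilities in `[0, 1]`.
#'
#' @param model An `ehff_model`.
#' @param P,Q Full-resolution feature maps of identical shape.
#' @return `[out_channels, D, H, W]` array of probabilities.
#' @export
fuse_and_predict <- function(model, P, Q = NULL) {
  if (!is.null(Q) && !all(vol_dim(P) == vol_dim(Q))) {
    stop("P and Q must have identical shapes before fusion")
  }
  ctx <- ad_ctx(model$params, NULL)
  ehff_head_ctx(ctx, model, ad_leaf(NULL, P),
                if (is.null(Q)) NULL else ad_leaf(NULL, Q))$value
}

#' Full forward pass
#'
#' @inheritParams stem_forward
#' @return A list with `probs` (`[out_channels, D, H, W]` in `[0, 1]`), the
#'   primary decoder output `P`, the auxiliary sum `Q` (or `NULL`), and the
#'   skip projections `Z`.
#' @export
ehff_forward <- function(model, image) {
  check_model_input(model, image)
  ctx <- ad_ctx(model$params, NULL)
  out <- ehff_forward_ctx(ctx, model, ad_leaf(NULL, image))
  list(probs = out$probs$value, P = out$P$value,
       Q = if (is.null(out$Q)) NULL else out$Q$value,
       Z = lapply(out$Z, function(nd) nd$value),
       pyramid = lapply(out$pyramid, function(nd) nd$value))
}

#' Count trainable parameters
#'
#' @param model An `ehff_model`, or an `ehff_config` (the model is then
#'   instantiated first).
#' @return Integer-valued numeric: total number of trainable scalars.
#' @export
count_parameters <- function(model) {
  if (inherits(model, "ehff_config")) model <- build_ehff(model)
  sum(vapply(model$params, length, numeric(1)))
}

#' @export
print.ehff_model <- function(x, ...) {
  cat("EHFF model:", format(count_parameters(x), big.mark = ","),
      "trainable parameters\n")
  print(x$config)
  invisible(x)
}
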