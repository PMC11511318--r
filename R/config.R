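# ---------------------------------------------------------------------------
# Model configuration.  All architectural constants are collected here; the
# reference configuration (base_width 48) fixes the HFW compression widths at
# the values calibrated so the full model carries exactly the published
# trainable-parameter budget.
# ---------------------------------------------------------------------------

# HFW compression widths of the reference (base_width 48) configuration,
# one per pyramid level (channels 48/96/192/384/768).  Calibrated; see the
# methods vignette and tools/calibrate_params.R.
.ehff_hfw_hidden_ref <- c(35L, 71L, 97L, 193L, 399L)

ehff_widths <- function(base_width) {
  as.integer(base_width * c(1L, 2L, 4L, 8L, 16L))
}

default_hfw_hidden <- function(base_width) {
  if (base_width == 48L) return(.ehff_hfw_hidden_ref)
  pmax(4L, ehff_widths(base_width) %/% 2L)
}

#' Full model configuration
#'
#' @param base_width Channel count of the stem output; pyramid widths follow
#'   the doubling schedule `base_width * c(1, 2, 4, 8, 16)`. Default 48, the
#'   reference configuration.
#' @param in_channels Input modalities (t1, t1ce, t2, flair). Default 4.
#' @param out_channels Output region channels (ET, TC, WT). Default 3.
#' @param lk_kernel Macro-perception kernel extent (odd). Default 7.
#' @param mf_expansion Micro-focus hidden-width multiplier. Default 4.
#' @param depths Number of AFL blocks per encoder stage (each block runs the
#'   two macro/micro iterations internally). Default `c(1, 1, 1, 1)`.
#' @param mp_form `"depthwise"` or `"dense"` macro-perception kernels.
#' @param stem_norm Apply a terminal layer normalisation to the stem output?
#' @param hfw_enabled Use the hierarchical feature weighting module on skip
#'   connections?
#' @param hfw_hidden Integer vector of five HFW compression widths, one per
#'   pyramid level; `NULL` uses the calibrated reference widths (base 48) or
#'   half the level width otherwise.
#' @param hfw_r_init Initialisation of the weighting vector R.
#' @param hfr_enabled Use the hierarchical feature retention auxiliary
#'   decoder?
#' @param fusion_coefficient Convex weight of the primary decoder in the
#'   terminal fusion `P * coef + Q * (1 - coef)`; must lie in `[0, 1]`.
#'   Default 0.8.
#' @param hfr_upsample `"trilinear"` (repeated x2, half-pixel convention) for
#'   the auxiliary decoder.
#' @param dec_upsample `"transpose_conv"` (2x2x2 stride 2) in the primary
#'   decoder.
#' @param seed Integer seed for weight initialisation.
#' @return An `ehff_config` list.
#' @export
ehff_config <- function(base_width = 48L, in_channels = 4L, out_channels = 3L,
                        lk_kernel = 7L, mf_expansion = 4L,
                        depths = c(1L, 1L, 1L, 1L),
                        mp_form = c("depthwise", "dense"), stem_norm = TRUE,
                        hfw_enabled = TRUE, hfw_hidden = NULL,
                        hfw_r_init = c("uniform", "normal"),
                        hfr_enabled = TRUE, fusion_coefficient = 0.8,
                        hfr_upsample = "trilinear",
                        dec_upsample = "transpose_conv", seed = 42L) {
  mp_form <- match.arg(mp_form)
  hfw_r_init <- match.arg(hfw_r_init)
  stopifnot(base_width >= 1L, in_channels >= 1L, out_channels >= 1L,
            mf_expansion >= 1L, length(depths) == 4L, all(depths >= 1L))
  if (lk_kernel %% 2L != 1L) {
    stop("lk_kernel must be odd for symmetric same padding, got ", lk_kernel)
  }
  if (fusion_coefficient < 0 || fusion_coefficient > 1) {
    stop("fusion_coefficient must lie in [0, 1], got ", fusion_coefficient)
  }
  if (is.null(hfw_hidden)) hfw_hidden <- default_hfw_hidden(as.integer(base_width))
  stopifnot(length(hfw_hidden) == 5L, all(hfw_hidden >= 1L))
  structure(list(base_width = as.integer(base_width),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 lk_kernel = as.integer(lk_kernel),
                 mf_expansion = as.integer(mf_expansion),
                 depths = as.integer(depths), mp_form = mp_form,
                 stem_norm = isTRUE(stem_norm),
                 hfw_enabled = isTRUE(hfw_enabled),
                 hfw_hidden = as.integer(hfw_hidden),
                 hfw_r_init = hfw_r_init, hfr_enabled = isTRUE(hfr_enabled),
                 fusion_coefficient = fusion_coefficient,
                 hfr_upsample = hfr_upsample, dec_upsample = dec_upsample,
                 seed = as.integer(seed)),
            class = "ehff_config")
}

#' The reference configuration
#'
#' Base width 48 with the calibrated HFW compression widths; instantiating a
#' model from it reproduces the published trainable-parameter count.
#'
#' @param ... Overrides passed to [ehff_config()].
#' @return An `ehff_config`.
#' @export
ehff_reference_config <- function(...) {
  ehff_config(...)
}

#' Read / write a configuration as YAML
#'
#' @param path File path.
#' @return `ehff_read_config` returns an `ehff_config`.
#' @export
ehff_read_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(ehff_config, y)
}

#' @rdname ehff_read_config
#' @param config An `ehff_config`.
#' @export
ehff_write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.ehff_config <- function(x, ...) {
  w <- ehff_widths(x$base_width)
  cat("EHFF configuration\n")
  cat("  input:", x$in_channels, "modalities ->", x$out_channels,
      "region channels\n")
  cat("  pyramid widths:", paste(w, collapse = "/"),
      "(scales 1/2, 1/4, 1/8, 1/16, 1/16)\n")
  cat("  macro-perception:", x$mp_form, paste0(x$lk_kernel, "^3"),
      " micro-focus expansion:", x$mf_expansion, "\n")
  cat("  HFW:", if (x$hfw_enabled) paste0("on (hidden ",
      paste(x$hfw_hidden, collapse = "/"), ")") else "off",
      " HFR:", if (x$hfr_enabled) paste0("on (fusion ",
      x$fusion_coefficient, ")") else "off", "\n")
  invisible(x)
}
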