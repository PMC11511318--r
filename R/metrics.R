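# ---------------------------------------------------------------------------
# BraTS region semantics and Dice-based evaluation.
#
# Label convention: 0 background, 1 necrotic/non-enhancing core, 2 edema,
# 4 enhancing tumor.  Evaluation regions are nested and overlapping:
# ET = {4}, TC = {1, 4}, WT = {1, 2, 4}.
# ---------------------------------------------------------------------------

#' Validate a label volume
#'
#' @param lab Integer array with entries in `{0, 1, 2, 4}`.
#' @return `lab`, invisibly.
#' @export
validate_labels <- function(lab) {
  bad <- setdiff(unique(as.vector(lab)), c(0L, 1L, 2L, 4L))
  if (length(bad) > 0L) {
    stop("invalid label values {", paste(sort(bad), collapse = ", "),
         "}; expected only 0, 1, 2, 4")
  }
  invisible(lab)
}

#' Derive the nested ET/TC/WT region masks from a label volume
#'
#' ET = label 4; TC = labels 1 and 4; WT = labels 1, 2 and 4.  Nesting
#' (ET within TC within WT) holds by construction.
#'
#' @param lab `[D, H, W]` integer array with entries in `{0, 1, 2, 4}`.
#' @return A `region_masks` list of three binary arrays `et`, `tc`, `wt`.
#' @export
remap_labels <- function(lab) {
  validate_labels(lab)
  et <- (lab == 4L) * 1L
  tc <- (lab == 1L | lab == 4L) * 1L
  wt <- (lab == 1L | lab == 2L | lab == 4L) * 1L
  structure(list(et = et, tc = tc, wt = wt), class = "region_masks")
}

#' Invert region masks back to a BraTS label volume
#'
#' Region-nesting inversion: ET voxels get label 4, TC outside ET label 1,
#' WT outside TC label 2.
#'
#' @param masks A `region_masks` list.
#' @return Integer label array.
#' @export
masks_to_labels <- function(masks) {
  lab <- array(0L, dim(masks$wt))
  lab[masks$wt > 0L] <- 2L
  lab[masks$tc > 0L] <- 1L
  lab[masks$et > 0L] <- 4L
  lab
}

#' Dice similarity coefficient between two binary masks
#'
#' `2 |S n G| / (|S| + |G|)`.  If both masks are empty the score is 1
#' (perfect agreement on absence); if exactly one is empty it is 0.
#'
#' @param S,G Binary arrays of identical shape.
#' @return A value in `[0, 1]`.
#' @export
dice <- function(S, G) {
  if (!identical(dim(S), dim(G)) || length(S) != length(G)) {
    stop("shape mismatch between segmentation and reference masks")
  }
  s <- sum(S != 0)
  g <- sum(G != 0)
  if (s + g == 0) return(1)
  2 * sum(S != 0 & G != 0) / (s + g)
}

stack_masks <- function(masks) {
  if (inherits(masks, "region_masks")) {
    d <- dim(masks$et)
    m <- array(0, c(3L, d))
    m[1L, , , ] <- masks$et
    m[2L, , , ] <- masks$tc
    m[3L, , , ] <- masks$wt
    m
  } else {
    masks
  }
}

#' Soft Dice loss over the three region channels
#'
#' `1 - mean_r (2 sum(p g) + eps) / (sum p + sum g + eps)`; differentiable
#' in the probabilities and bounded in `[0, 1]` up to epsilon effects.
#'
#' @param probs `[3, D, H, W]` array of probabilities.
#' @param masks A `region_masks` list or a `[3, D, H, W]` binary array.
#' @param eps Smoothing constant (default 1e-5).
#' @return Scalar loss.
#' @export
soft_dice_loss <- function(probs, masks, eps = 1e-5) {
  m <- stack_masks(masks)
  if (!identical(dim(probs), dim(m))) {
    stop("probability and mask arrays must share one shape")
  }
  R <- dim(probs)[1L]
  P <- matrix(probs, nrow = R)
  G <- matrix(m, nrow = R)
  num <- 2 * rowSums(P * G) + eps
  den <- rowSums(P) + rowSums(G) + eps
  1 - mean(num / den)
}

#' Binarize probabilities into region masks
#'
#' @param probs `[3, D, H, W]` array.
#' @param threshold Cut at which a voxel counts as inside (default 0.5).
#' @return A `region_masks` list (channels in ET, TC, WT order).
#' @export
probs_to_masks <- function(probs, threshold = 0.5) {
  structure(list(et = (probs[1L, , , ] >= threshold) * 1L,
                 tc = (probs[2L, , , ] >= threshold) * 1L,
                 wt = (probs[3L, , , ] >= threshold) * 1L),
            class = "region_masks")
}

#' Per-case Dice report
#'
#' @param case_id Character vector of case identifiers.
#' @param dice_et,dice_tc,dice_wt Numeric vectors of per-case scores.
#' @return A `dice_report` data frame with a `per_region_mean` attribute.
#' @export
dice_report <- function(case_id, dice_et, dice_tc, dice_wt) {
  df <- data.frame(case_id = case_id, dice_et = dice_et, dice_tc = dice_tc,
                   dice_wt = dice_wt, stringsAsFactors = FALSE)
  structure(df, class = c("dice_report", "data.frame"))
}

#' Per-region mean of a Dice report
#'
#' @param report A `dice_report`.
#' @return Named numeric vector (et, tc, wt).
#' @export
report_means <- function(report) {
  c(et = mean(report$dice_et), tc = mean(report$dice_tc),
    wt = mean(report$dice_wt))
}

#' Aggregate per-fold results across a cross-validation
#'
#' Takes one set of per-region fold means per fold (either `dice_report`
#' objects or numeric vectors `c(et, tc, wt)`), and returns the per-region
#' mean across folds together with the across-fold spread of the fold means
#' (population standard deviation and population variance).
#'
#' @param folds A list of `dice_report`s or of numeric `c(et, tc, wt)`
#'   vectors, one per fold.
#' @return A `fold_summary` list with `fold_means` (matrix, folds x regions),
#'   `per_region_mean`, `mean_of_means`, `per_region_sd` and
#'   `per_region_var` (population statistics across the fold means).
#' @export
aggregate_folds <- function(folds) {
  if (length(folds) < 2L) {
    stop("need at least two folds to compute an across-fold spread")
  }
  fm <- t(vapply(folds, function(f) {
    if (inherits(f, "dice_report")) report_means(f) else {
      stats::setNames(as.numeric(f[1:3]), c("et", "tc", "wt"))
    }
  }, numeric(3)))
  n <- nrow(fm)
  pm <- colMeans(fm)
  pvar <- colMeans(fm^2) - pm^2
  pvar <- pmax(pvar, 0)
  structure(list(fold_means = fm, per_region_mean = pm,
                 mean_of_means = mean(pm), per_region_sd = sqrt(pvar),
                 per_region_var = pvar, n_folds = n),
            class = "fold_summary")
}

#' Serialize a Dice report / fold summary
#'
#' @param report A `dice_report`.
#' @param path Output CSV path.
#' @export
write_dice_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dice_report
#' @param summary A `fold_summary`.
#' @export
write_fold_summary <- function(summary, path) {
  jsonlite::write_json(list(per_region_mean = as.list(summary$per_region_mean),
                            mean_of_means = summary$mean_of_means,
                            per_region_sd = as.list(summary$per_region_sd),
                            per_region_var = as.list(summary$per_region_var),
                            n_folds = summary$n_folds),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
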