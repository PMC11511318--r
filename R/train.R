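# ---------------------------------------------------------------------------
# Optimization loop (Adam, batch size 1), sliding-window inference and
# per-fold evaluation.
# ---------------------------------------------------------------------------

# Zero state with the same shape attributes as each parameter, so updates
# never change a parameter's dim.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Convert a case to a training sample
#'
#' @param case A `brats_case` (labeled).
#' @param target_shape Crop/pad target, multiple of 16.
#' @return A list `x` (`[4, D, H, W]`), `masks` (`[3, D, H, W]`), `case_id`.
#' @export
case_to_sample <- function(case, target_shape = c(128L, 128L, 128L)) {
  s <- preprocess_case(case, target_shape)
  if (is.null(s$masks)) stop("case ", case$case_id, " carries no label")
  s
}

#' Train an EHFF model
#'
#' Adam (default learning rate 0.001) on the soft Dice loss (optionally soft
#' Dice + binary cross-entropy), batch size 1, fully seeded: weight
#' initialisation comes from the model's configuration seed and sample
#' shuffling from `seed`.
#'
#' @param model An `ehff_model` from [build_ehff()].
#' @param samples List of samples from [case_to_sample()].
#' @param epochs Training epochs (each epoch visits every sample once).
#' @param lr Learning rate (default 0.001).
#' @param loss `"soft_dice"` or `"dice_ce"` (soft Dice plus BCE).
#' @param seed Shuffling seed.
#' @param max_steps Optional cap on total optimization steps.
#' @param eval_every If set (with `target_dice`), evaluate mean training
#'   Dice every this many steps and stop early once every region exceeds
#'   `target_dice`.
#' @param target_dice Early-stopping threshold on the per-region training
#'   Dice.
#' @param verbose Print per-epoch losses?
#' @return A list with the trained `model`, `loss_trace` (per step),
#'   `epoch_loss` (per epoch mean), and `steps`.
#' @export
train_ehff <- function(model, samples, epochs = 300L, lr = 1e-3,
                       loss = c("soft_dice", "dice_ce"), seed = 1L,
                       max_steps = NULL, eval_every = NULL,
                       target_dice = NULL, verbose = FALSE) {
  loss <- match.arg(loss)
  stopifnot(length(samples) >= 1L)
  params <- model$params
  state <- adam_init(params)
  trace <- numeric(0)
  epoch_loss <- numeric(0)
  step <- 0L
  done <- FALSE
  orders <- with_seed(seed, lapply(seq_len(epochs), function(e) {
    sample(seq_along(samples))
  }))
  for (ep in seq_len(epochs)) {
    losses_ep <- numeric(0)
    for (idx in orders[[ep]]) {
      sm <- samples[[idx]]
      tape <- ad_tape()
      ctx <- ad_ctx(params, tape)
      out <- ehff_forward_ctx(ctx, model, ad_leaf(tape, sm$x))
      l <- op_soft_dice(ctx, out$probs, sm$masks)
      if (loss == "dice_ce") {
        l <- op_add(ctx, l, op_bce(ctx, out$probs, sm$masks))
      }
      if (!is.finite(l$value)) {
        stop("non-finite loss at step ", step + 1L, " (epoch ", ep,
             ", sample ", sm$case_id %||% idx, ")")
      }
      ad_backward(tape, l)
      upd <- adam_step(params, ctx_grads(ctx), state, lr = lr)
      params <- upd$params
      state <- upd$state
      step <- step + 1L
      trace <- c(trace, l$value)
      losses_ep <- c(losses_ep, l$value)
      model$params <- params
      if (!is.null(eval_every) && !is.null(target_dice) &&
          step %% eval_every == 0L) {
        ds <- training_dice(model, samples)
        if (all(ds > target_dice)) { done <- TRUE; break }
      }
      if (!is.null(max_steps) && step >= max_steps) { done <- TRUE; break }
    }
    epoch_loss <- c(epoch_loss, mean(losses_ep))
    if (verbose) {
      message(sprintf("epoch %d/%d  mean loss %.4f", ep, epochs,
                      mean(losses_ep)))
    }
    if (done) break
  }
  model$params <- params
  list(model = model, loss_trace = trace, epoch_loss = epoch_loss,
       steps = step)
}

# Mean per-region hard Dice of the model on a list of samples.
training_dice <- function(model, samples) {
  per <- vapply(samples, function(sm) {
    probs <- ehff_forward(model, sm$x)$probs
    pred <- probs_to_masks(probs)
    c(dice(pred$et, sm$masks[1L, , , ]),
      dice(pred$tc, sm$masks[2L, , , ]),
      dice(pred$wt, sm$masks[3L, , , ]))
  }, numeric(3))
  rowMeans(per)
}

#' Checkpoint helpers
#'
#' A checkpoint bundles the parameter arrays, the configuration and the
#' seeds, serialized as an RDS file.
#'
#' @param model Trained `ehff_model`.
#' @param path Output path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(params = model$params, config = unclass(model$config)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(ehff_config, ck$config[setdiff(names(ck$config), NULL)])
  model <- build_ehff(cfg)
  model$params <- ck$params
  model
}

# --- sliding-window inference ----------------------------------------------

window_starts <- function(extent, win, stride) {
  if (extent <= win) return(1L)
  st <- seq(1L, extent - win + 1L, by = stride)
  if (st[length(st)] != extent - win + 1L) st <- c(st, extent - win + 1L)
  st
}

#' Sliding-window prediction over a full volume
#'
#' Tiles the volume with windows of the training crop size at the given
#' overlap, predicts each tile, and mean-blends the overlapping
#' probabilities.  Volumes smaller than the window are zero-padded and the
#' result cropped back.
#'
#' @param model An `ehff_model`.
#' @param x `[4, D, H, W]` preprocessed input array.
#' @param window Length-3 window shape (multiple of 16); default 128^3.
#' @param overlap Fractional overlap between neighbouring windows
#'   (default 0.5).
#' @return `[out_channels, D, H, W]` array of blended probabilities.
#' @export
predict_probs <- function(model, x, window = c(128L, 128L, 128L),
                          overlap = 0.5) {
  window <- as.integer(window)
  if (any(window %% 16L != 0L)) {
    stop("window must be a multiple of 16 on every axis")
  }
  xd <- vol_dim(x)
  shp <- xd[2:4]
  pad_to <- pmax(shp, window)
  padded <- !all(pad_to == shp)
  if (padded) {
    xp <- array(0, c(xd[1L], pad_to))
    xp[, seq_len(shp[1L]), seq_len(shp[2L]), seq_len(shp[3L])] <- x
    x <- xp
    shp_eff <- pad_to
  } else {
    shp_eff <- shp
  }
  stride <- pmax(1L, as.integer(round(window * (1 - overlap))))
  acc <- array(0, c(model$config$out_channels, shp_eff))
  cnt <- array(0, shp_eff)
  for (sd_ in window_starts(shp_eff[1L], window[1L], stride[1L])) {
    for (sh in window_starts(shp_eff[2L], window[2L], stride[2L])) {
      for (sw in window_starts(shp_eff[3L], window[3L], stride[3L])) {
        ix <- sd_:(sd_ + window[1L] - 1L)
        iy <- sh:(sh + window[2L] - 1L)
        iz <- sw:(sw + window[3L] - 1L)
        tile <- x[, ix, iy, iz, drop = FALSE]
        probs <- ehff_forward(model, tile)$probs
        acc[, ix, iy, iz] <- acc[, ix, iy, iz, drop = FALSE] + probs
        cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
      }
    }
  }
  out <- acc / rep(cnt, each = model$config$out_channels)
  if (padded) {
    out <- out[, seq_len(shp[1L]), seq_len(shp[2L]), seq_len(shp[3L]),
               drop = FALSE]
  }
  out
}

#' Evaluate a model on labeled cases
#'
#' Sliding-window inference, binarization at the threshold, and hard Dice
#' per region per case.
#'
#' @param model A trained `ehff_model`.
#' @param cases List of labeled `brats_case` objects (or preprocessed
#'   samples with `x`, `label`, `case_id`).
#' @param window Inference window (default 128^3).
#' @param overlap Window overlap (default 0.5).
#' @param threshold Binarization cut (default 0.5).
#' @return A [dice_report()].
#' @export
evaluate_cases <- function(model, cases, window = c(128L, 128L, 128L),
                           overlap = 0.5, threshold = 0.5) {
  rows <- lapply(cases, function(cs) {
    if (inherits(cs, "brats_case")) {
      if (is.null(cs$label)) {
        stop("case ", cs$case_id, " is unlabeled and cannot be evaluated")
      }
      shp0 <- dim(cs$label)
      target <- as.integer(ceiling(shp0 / 16) * 16L)
      sm <- preprocess_case(cs, target)
    } else {
      if (is.null(cs$label)) {
        stop("case ", cs$case_id, " is unlabeled and cannot be evaluated")
      }
      sm <- cs
    }
    truth <- remap_labels(sm$label)
    probs <- predict_probs(model, sm$x, window = window, overlap = overlap)
    pred <- probs_to_masks(probs, threshold)
    data.frame(case_id = sm$case_id,
               dice_et = dice(pred$et, truth$et),
               dice_tc = dice(pred$tc, truth$tc),
               dice_wt = dice(pred$wt, truth$wt),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  dice_report(df$case_id, df$dice_et, df$dice_tc, df$dice_wt)
}

#' @rdname evaluate_cases
#' @param folds A `fold_split` from [make_folds()].
#' @param fold Which fold index to evaluate.
#' @export
evaluate_fold <- function(model, cases, folds, fold,
                          window = c(128L, 128L, 128L), overlap = 0.5,
                          threshold = 0.5) {
  ids <- vapply(cases, function(cs) cs$case_id, character(1))
  keep <- ids %in% names(folds)[unclass(folds) == fold]
  if (!any(keep)) stop("no cases assigned to fold ", fold)
  evaluate_cases(model, cases[keep], window = window, overlap = overlap,
                 threshold = threshold)
}
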