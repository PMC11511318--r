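small_phantom_sample <- function(seed) {
  sp <- phantom_spec(shape = c(32L, 32L, 32L), wt_radius = 10, tc_radius = 7,
                     et_radius = 4, seed = seed)
  case_to_sample(generate_phantom(sp, paste0("ph", seed)), c(32L, 32L, 32L))
}

test_that("parameter counting matches closed forms and is input-size invariant", {
  # a single 1x1x1 convolution 2 -> 3 with bias: 2*3 + 3 = 9
  blk <- downsample_block(2L, 3L, spatial_halving = FALSE)
  expect_equal(sum(vapply(blk$params, length, numeric(1))), 9)

  model <- build_ehff(tiny_config())
  n0 <- count_parameters(model)
  invisible(ehff_forward(model, rand_vol(4, 16, seed = 1L)))
  invisible(ehff_forward(model, rand_vol(4, 32, seed = 1L)))
  expect_identical(count_parameters(model), n0)

  # doubling the micro-focus expansion strictly increases the count
  n_e2 <- count_parameters(tiny_config(mf_expansion = 2L))
  n_e4 <- count_parameters(tiny_config(mf_expansion = 4L))
  expect_gt(n_e4, n_e2)
})

test_that("module toggles give four distinct architectures with ordered counts", {
  n00 <- count_parameters(tiny_config(hfw_enabled = FALSE, hfr_enabled = FALSE))
  n01 <- count_parameters(tiny_config(hfw_enabled = FALSE, hfr_enabled = TRUE))
  n10 <- count_parameters(tiny_config(hfw_enabled = TRUE, hfr_enabled = FALSE))
  n11 <- count_parameters(tiny_config(hfw_enabled = TRUE, hfr_enabled = TRUE))
  expect_true(n00 < n01 && n01 < n10 && n10 < n11)
  expect_length(unique(c(n00, n01, n10, n11)), 4L)
})

test_that("a zero learning rate leaves the weights bit-identical", {
  model <- build_ehff(tiny_config())
  sm <- small_phantom_sample(21L)
  res <- train_ehff(model, list(sm), epochs = 1L, lr = 0, seed = 1L)
  expect_identical(res$model$params, model$params)
})

test_that("training is deterministic under a fixed seed", {
  sm <- small_phantom_sample(22L)
  r1 <- train_ehff(build_ehff(tiny_config()), list(sm), epochs = 2L, seed = 3L)
  r2 <- train_ehff(build_ehff(tiny_config()), list(sm), epochs = 2L, seed = 3L)
  expect_identical(r1$loss_trace, r2$loss_trace)
  expect_identical(r1$model$params, r2$model$params)
})

test_that("training reduces the loss and aborts on non-finite values", {
  model <- build_ehff(tiny_config())
  sm <- small_phantom_sample(23L)
  res <- train_ehff(model, list(sm), epochs = 8L, seed = 2L)
  expect_lt(res$loss_trace[res$steps], res$loss_trace[1L])

  bad <- build_ehff(tiny_config())
  bad$params[["head.w"]][1L] <- NaN
  expect_error(train_ehff(bad, list(sm), epochs = 1L, seed = 1L),
               "non-finite loss")
})

test_that("the dice_ce loss variant trains and differs from pure soft Dice", {
  sm <- small_phantom_sample(24L)
  r1 <- train_ehff(build_ehff(tiny_config()), list(sm), epochs = 1L, seed = 1L,
                   loss = "soft_dice")
  r2 <- train_ehff(build_ehff(tiny_config()), list(sm), epochs = 1L, seed = 1L,
                   loss = "dice_ce")
  expect_gt(r2$loss_trace[1L], r1$loss_trace[1L])  # BCE adds a positive term
})

test_that("sliding-window inference blends tiles consistently", {
  model <- build_ehff(tiny_config())
  x <- rand_vol(4, 32, seed = 9L)
  # volume equal to the window: identical to a direct forward pass
  direct <- ehff_forward(model, x)$probs
  slid <- predict_probs(model, x, window = c(32L, 32L, 32L))
  expect_equal(slid, direct, tolerance = 1e-12)

  # tiled volume: valid probabilities of the right shape
  x2 <- rand_vol(4, 48, 32, 32, seed = 10L)
  p2 <- predict_probs(model, x2, window = c(32L, 32L, 32L), overlap = 0.5)
  expect_identical(dim(p2), c(3L, 48L, 32L, 32L))
  expect_true(all(p2 >= 0 & p2 <= 1))

  # a constant-output model stays constant under blending
  cmodel <- model
  cmodel$params[["head.w"]] <- cmodel$params[["head.w"]] * 0
  cmodel$params[["head.b"]] <- c(2, 0, -2)
  p3 <- predict_probs(cmodel, x2, window = c(32L, 32L, 32L))
  expect_equal(unique(as.vector(p3[1, , , ])), 1 / (1 + exp(-2)),
               tolerance = 1e-12)
  expect_error(predict_probs(model, x2, window = c(20L, 32L, 32L)),
               "multiple of 16")
})

test_that("evaluation scores forced predictions correctly and rejects unlabeled cases", {
  sp <- phantom_spec(shape = c(32L, 32L, 32L), wt_radius = 10, tc_radius = 7,
                     et_radius = 4, seed = 31L)
  cs <- generate_phantom(sp, "ph31")
  truth <- remap_labels(cs$label)

  # prediction forced to the ground truth -> Dice 1 per region
  m <- ehff:::stack_masks(truth)
  pred <- probs_to_masks(m)
  expect_equal(dice(pred$et, truth$et), 1)
  expect_equal(dice(pred$tc, truth$tc), 1)
  expect_equal(dice(pred$wt, truth$wt), 1)
  # empty prediction against nonempty truth -> 0
  expect_equal(dice(truth$et * 0L, truth$et), 0)

  model <- build_ehff(tiny_config())
  rep1 <- evaluate_cases(model, list(cs), window = c(32L, 32L, 32L))
  expect_s3_class(rep1, "dice_report")
  expect_identical(nrow(rep1), 1L)
  expect_true(all(unlist(rep1[, 2:4]) >= 0 & unlist(rep1[, 2:4]) <= 1))

  unlabeled <- cs
  unlabeled$label <- NULL
  expect_error(evaluate_cases(model, list(unlabeled), window = c(32L, 32L, 32L)),
               "unlabeled")

  folds <- make_folds(c("ph31", "x1", "x2", "x3", "x4"), seed = 1L)
  fold_of <- unclass(folds)[["ph31"]]
  repf <- evaluate_fold(model, list(cs), folds, fold_of,
                        window = c(32L, 32L, 32L))
  expect_identical(repf$case_id, "ph31")
  expect_error(evaluate_fold(model, list(cs), folds,
                             setdiff(0:4, fold_of)[1L],
                             window = c(32L, 32L, 32L)),
               "no cases assigned")
})
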