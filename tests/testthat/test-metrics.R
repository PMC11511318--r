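test_that("label remapping yields the nested ET/TC/WT regions", {
  lab <- array(0L, c(2, 2, 2))
  lab[1, 1, 1] <- 4L
  lab[2, 1, 1] <- 2L
  lab[1, 2, 1] <- 1L
  m <- remap_labels(lab)
  expect_identical(c(m$et[1, 1, 1], m$tc[1, 1, 1], m$wt[1, 1, 1]),
                   c(1L, 1L, 1L))
  expect_identical(c(m$et[2, 1, 1], m$tc[2, 1, 1], m$wt[2, 1, 1]),
                   c(0L, 0L, 1L))
  expect_identical(c(m$et[1, 2, 1], m$tc[1, 2, 1], m$wt[1, 2, 1]),
                   c(0L, 1L, 1L))
  expect_identical(c(m$et[2, 2, 2], m$tc[2, 2, 2], m$wt[2, 2, 2]),
                   c(0L, 0L, 0L))

  lab[2, 2, 2] <- 3L
  expect_error(remap_labels(lab), "invalid label values \\{3\\}")

  # nesting invariant over random label volumes
  set.seed(1)
  for (i in 1:10) {
    rl <- array(sample(c(0L, 1L, 2L, 4L), 125, TRUE), c(5, 5, 5))
    mm <- remap_labels(rl)
    expect_true(all(mm$et <= mm$tc))
    expect_true(all(mm$tc <= mm$wt))
    # region-nesting inversion restores the labels exactly
    expect_identical(masks_to_labels(mm), rl)
  }
})

test_that("Dice agrees with the brute-force voxel-count oracle", {
  a <- array(0L, c(3, 3, 3)); a[1:3, 1, 1] <- 1L          # |S| = 3
  b <- array(0L, c(3, 3, 3)); b[2:3, 1, 1] <- 1L; b[, 2, 1] <- 1L  # |G| = 5
  expect_equal(dice(a, b), 2 * 2 / (3 + 5))               # overlap 2 -> 0.5

  expect_equal(dice(b, b), 1)
  d <- array(0L, c(3, 3, 3)); d[1, 3, 3] <- 1L
  expect_equal(dice(a, d), 0)

  # conventions on empty masks
  z <- array(0L, c(3, 3, 3))
  expect_equal(dice(z, z), 1)
  expect_equal(dice(z, a), 0)

  set.seed(2)
  for (i in 1:20) {
    S <- array(rbinom(64, 1, 0.4), c(4, 4, 4))
    G <- array(rbinom(64, 1, 0.4), c(4, 4, 4))
    inter <- 0; ns <- 0; ng <- 0
    for (v in seq_along(S)) {
      inter <- inter + (S[v] == 1 && G[v] == 1)
      ns <- ns + (S[v] == 1); ng <- ng + (G[v] == 1)
    }
    ref <- if (ns + ng == 0) 1 else 2 * inter / (ns + ng)
    expect_equal(dice(S, G), ref)
    expect_equal(dice(S, G), dice(G, S))
    expect_gte(dice(S, G), 0); expect_lte(dice(S, G), 1)
  }
  expect_error(dice(a, array(0L, c(2, 2, 2))), "shape mismatch")
})

test_that("soft Dice loss matches its closed form and is bounded", {
  set.seed(3)
  d <- c(3L, 4L, 4L, 4L)
  masks <- array(rbinom(prod(d), 1, 0.5), d)

  # perfect probabilities: loss ~ 0
  expect_lt(soft_dice_loss(masks + 0.0, masks), 1e-4)
  # complementary probabilities: loss ~ 1
  expect_gt(soft_dice_loss(1 - masks, masks), 0.999)

  # probs = 0.5 everywhere against half-full masks, hand evaluation
  probs <- array(0.5, d)
  eps <- 1e-5
  n <- prod(d[2:4])
  per_ch <- vapply(1:3, function(r) {
    g <- sum(masks[r, , , ])
    (2 * 0.5 * g + eps) / (0.5 * n + g + eps)
  }, numeric(1))
  expect_equal(soft_dice_loss(probs, masks), 1 - mean(per_ch),
               tolerance = 1e-12)

  expect_error(soft_dice_loss(probs, masks[, 1:2, , ]), "share one shape")
})

test_that("fold aggregation reproduces the published cross-validation means", {
  folds <- list(c(87.63, 90.39, 92.45),
                c(89.68, 92.45, 93.47),
                c(88.29, 91.24, 92.98),
                c(88.52, 91.64, 93.12),
                c(88.74, 91.91, 93.45))
  s <- aggregate_folds(folds)
  expect_equal(unname(s$per_region_mean), c(88.572, 91.526, 93.094),
               tolerance = 1e-9)
  # printed to two decimals these are the published 88.57 / 91.53 / 93.09
  expect_equal(round(unname(s$per_region_mean), 2), c(88.57, 91.53, 93.09))

  # identical folds have zero spread
  same <- aggregate_folds(rep(list(c(80, 85, 90)), 5))
  expect_equal(unname(same$per_region_sd), c(0, 0, 0))

  two <- aggregate_folds(list(c(0, 0, 0), c(1, 1, 1)))
  expect_equal(unname(two$per_region_mean), c(0.5, 0.5, 0.5))

  expect_error(aggregate_folds(folds[1]), "at least two folds")

  # dice_report objects aggregate through their per-region means
  rep1 <- dice_report(c("a", "b"), c(0.8, 0.9), c(0.7, 0.9), c(0.9, 1.0))
  rep2 <- dice_report(c("c", "d"), c(0.6, 0.8), c(0.8, 0.8), c(0.8, 0.9))
  s2 <- aggregate_folds(list(rep1, rep2))
  expect_equal(unname(s2$per_region_mean[1]), mean(c(0.85, 0.7)))
})

test_that("probability binarization produces region masks at the threshold", {
  probs <- array(0, c(3, 2, 2, 2))
  probs[1, 1, 1, 1] <- 0.6
  probs[2, 1, 1, 1] <- 0.5
  probs[3, , , ] <- 0.4
  m <- probs_to_masks(probs, 0.5)
  expect_identical(m$et[1, 1, 1], 1L)
  expect_identical(m$tc[1, 1, 1], 1L)   # >= threshold counts as inside
  expect_true(all(m$wt == 0L))
})
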