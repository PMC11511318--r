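test_that("the phantom is deterministic, nested, and piecewise-constant without noise", {
  sp <- phantom_spec(shape = c(32L, 32L, 32L), wt_radius = 11, tc_radius = 7,
                     et_radius = 4, noise_sigma = 0, seed = 5L)
  c1 <- generate_phantom(sp)
  c2 <- generate_phantom(sp)
  expect_identical(c1$modalities, c2$modalities)
  expect_identical(c1$label, c2$label)

  m <- remap_labels(c1$label)
  expect_true(all(m$et <= m$tc) && all(m$tc <= m$wt))

  # distinct contrasts, no noise: exactly 4 intensity levels per modality
  for (mod in c1$modalities) expect_length(unique(as.vector(mod)), 4L)

  # noise changes voxel values but never the label
  spn <- phantom_spec(shape = c(32L, 32L, 32L), wt_radius = 11, tc_radius = 7,
                      et_radius = 4, noise_sigma = 0.1, seed = 5L)
  cn <- generate_phantom(spn)
  expect_identical(cn$label, c1$label)
  expect_gt(stats::sd(cn$modalities$t1 - c1$modalities$t1), 0.05)

  expect_error(phantom_spec(wt_radius = 5, tc_radius = 7, et_radius = 4),
               "et_radius < tc_radius < wt_radius")
})

test_that("the enhancing-core voxel count matches the analytic ellipsoid volume", {
  sp <- phantom_spec(shape = c(64L, 64L, 64L), wt_radius = 12, tc_radius = 8,
                     et_radius = 4, center_jitter = 0, noise_sigma = 0,
                     seed = 2L)
  lab <- generate_phantom(sp)$label
  vol_et <- sum(lab == 4L)
  expect_lt(abs(vol_et - 4 / 3 * pi * 4^3) / (4 / 3 * pi * 4^3), 0.15)
})

test_that("write_case / read_case round-trips voxel data bit-exactly", {
  sp <- phantom_spec(shape = c(32L, 32L, 32L), wt_radius = 10, tc_radius = 7,
                     et_radius = 4, seed = 3L)
  cs <- generate_phantom(sp, case_id = "ph003")
  dir <- file.path(tempdir(), "ph003")
  write_case(cs, dir)
  back <- read_case(dir)
  expect_identical(back$case_id, "ph003")
  for (m in names(cs$modalities)) {
    expect_identical(dim(back$modalities[[m]]), dim(cs$modalities[[m]]))
    expect_equal(back$modalities[[m]], cs$modalities[[m]], tolerance = 0,
                 ignore_attr = TRUE)
  }
  expect_true(all(back$label == cs$label))
  unlink(dir, recursive = TRUE)
})

test_that("read_case reports missing modalities and invalid labels", {
  sp <- phantom_spec(shape = c(32L, 32L, 32L), wt_radius = 10, tc_radius = 7,
                     et_radius = 4, seed = 4L)
  cs <- generate_phantom(sp, case_id = "bad")
  dir <- file.path(tempdir(), "bad")
  write_case(cs, dir)
  file.remove(file.path(dir, "bad_flair.nii.gz"))
  expect_error(read_case(dir), "missing modality.*flair")
  unlink(dir, recursive = TRUE)

  cs2 <- cs
  cs2$case_id <- "bad3"
  cs2$label[1, 1, 1] <- 3L
  dir2 <- file.path(tempdir(), "bad3")
  dir.create(dir2, showWarnings = FALSE)
  for (m in names(cs2$modalities)) {
    RNifti::writeNifti(RNifti::asNifti(cs2$modalities[[m]]),
                       file.path(dir2, paste0("bad3_", m, ".nii.gz")))
  }
  RNifti::writeNifti(RNifti::asNifti(cs2$label),
                     file.path(dir2, "bad3_seg.nii.gz"))
  expect_error(read_case(dir2), "invalid label values \\{3\\}")
  unlink(dir2, recursive = TRUE)
})

test_that("preprocessing z-scores brain voxels and pads symmetrically", {
  # five-voxel toy: hand-computed z-scores over the nonzero voxels
  a <- array(0, c(4, 4, 4))
  vals <- c(2, 4, 7, 9, 14)
  a[1:5] <- vals
  cs <- structure(list(case_id = "toy",
                       modalities = list(t1 = a, t1ce = a, t2 = a, flair = a),
                       label = array(0L, c(4, 4, 4)), reference = NULL),
                  class = "brats_case")
  s <- preprocess_case(cs, c(16L, 16L, 16L))
  mu <- mean(vals); sdv <- stats::sd(vals)
  got <- s$x[1, , , ][s$x[1, , , ] != 0]
  expect_equal(sort(got), sort((vals - mu) / sdv), tolerance = 1e-12)
  # constant-zero background stays zero
  expect_equal(sum(s$x[1, , , ] != 0), 5L)
  # symmetric zero padding of (16 - 4) / 2 = 6 voxels per side
  expect_identical(s$offset, c(6L, 6L, 6L))
  expect_identical(dim(s$x), c(4L, 16L, 16L, 16L))

  expect_error(preprocess_case(cs, c(15L, 16L, 16L)), "multiple of 16")

  # crop keeps the center: phantom label extents survive a crop + uncrop
  sp <- phantom_spec(shape = c(32L, 32L, 32L), wt_radius = 8, tc_radius = 6,
                     et_radius = 3, center_jitter = 0, seed = 6L)
  ph <- generate_phantom(sp)
  s2 <- preprocess_case(ph, c(16L, 16L, 16L))
  expect_identical(s2$offset, c(-8L, -8L, -8L))
  expect_identical(s2$label, ph$label[9:24, 9:24, 9:24])
})

test_that("five-fold splitting is balanced, deterministic, and validated", {
  ids <- sprintf("case%04d", seq_len(1251))
  f <- make_folds(ids, seed = 42L)
  expect_identical(sort(as.vector(table(unclass(f))), decreasing = TRUE),
                   c(251L, 250L, 250L, 250L, 250L))
  expect_identical(unclass(make_folds(ids, seed = 42L)),
                   unclass(f))
  expect_false(identical(unclass(make_folds(ids, seed = 43L)), unclass(f)))

  f5 <- make_folds(sprintf("c%d", 1:5))
  expect_identical(sort(as.integer(unclass(f5))), 0:4)

  expect_error(make_folds(c("a", "b")), "at least 5")

  # JSON round trip
  path <- file.path(tempdir(), "folds.json")
  write_folds(f5, path)
  back <- read_folds(path)
  expect_identical(unname(unclass(back)[names(f5)]),
                   unname(as.integer(unclass(f5))))
  expect_equal(attr(back, "seed"), attr(f5, "seed"))
  unlink(path)
})
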