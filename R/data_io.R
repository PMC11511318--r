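# ---------------------------------------------------------------------------
# BraTS-style case handling: NIfTI reading/writing, preprocessing,
# five-fold splitting, and the synthetic multi-modal phantom generator.
# Internal axis convention is (D, H, W) in the order NIfTI stores the voxel
# grid; the affine of the first modality is retained for write-back and no
# reorientation is applied.
# ---------------------------------------------------------------------------

.ehff_modalities <- c("t1", "t1ce", "t2", "flair")

#' Read a BraTS-style case directory
#'
#' Expects the four modality files `<id>_<modality>.nii(.gz)` and optionally
#' a segmentation `<id>_seg.nii(.gz)`; label values are validated against
#' `{0, 1, 2, 4}`.
#'
#' @param directory Case directory.
#' @param case_id Case identifier; defaults to the directory name.
#' @param pattern Filename pattern with `%s` placeholders for id and
#'   modality.
#' @return A `brats_case`: `case_id`, `modalities` (named list of four
#'   `[D, H, W]` arrays), `label` (or `NULL`), `reference` (NIfTI header for
#'   write-back).
#' @export
read_case <- function(directory, case_id = basename(normalizePath(directory)),
                      pattern = "%s_%s.nii.gz") {
  find_file <- function(mod) {
    f <- file.path(directory, sprintf(pattern, case_id, mod))
    if (!file.exists(f)) {
      alt <- sub("\\.gz$", "", f)
      if (file.exists(alt)) return(alt)
      return(NA_character_)
    }
    f
  }
  paths <- vapply(.ehff_modalities, find_file, character(1))
  missing <- .ehff_modalities[is.na(paths)]
  if (length(missing) > 0L) {
    stop("missing modality file(s) in ", directory, ": ",
         paste(missing, collapse = ", "))
  }
  modalities <- lapply(paths, function(p) {
    img <- RNifti::readNifti(p)
    a <- as.array(img)
    dim(a) <- dim(img)
    a
  })
  names(modalities) <- .ehff_modalities
  shp <- dim(modalities[[1L]])
  for (m in .ehff_modalities) {
    if (!identical(dim(modalities[[m]]), shp)) {
      stop("modality ", m, " is not co-registered: shape [",
           paste(dim(modalities[[m]]), collapse = "x"), "] vs [",
           paste(shp, collapse = "x"), "]")
    }
  }
  seg_path <- find_file("seg")
  label <- NULL
  if (!is.na(seg_path)) {
    lab_img <- RNifti::readNifti(seg_path)
    label <- array(as.integer(round(as.array(lab_img))), dim(lab_img))
    validate_labels(label)
    if (!identical(dim(label), shp)) {
      stop("segmentation shape [", paste(dim(label), collapse = "x"),
           "] does not match the modalities")
    }
  }
  structure(list(case_id = case_id, modalities = modalities, label = label,
                 reference = RNifti::niftiHeader(RNifti::readNifti(paths[1L]))),
            class = "brats_case")
}

#' Write a case back to a BraTS-style directory
#'
#' @param case A `brats_case`.
#' @param directory Output directory (created if needed).
#' @param pattern Filename pattern, as in [read_case()].
#' @return The directory, invisibly.
#' @export
write_case <- function(case, directory, pattern = "%s_%s.nii.gz") {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  ref <- case$reference
  as_img <- function(a, datatype) {
    if (is.null(ref)) {
      RNifti::asNifti(a, datatype = datatype)
    } else {
      RNifti::asNifti(a, reference = ref, datatype = datatype)
    }
  }
  for (m in .ehff_modalities) {
    RNifti::writeNifti(as_img(case$modalities[[m]], "double"),
                       file.path(directory,
                                 sprintf(pattern, case$case_id, m)))
  }
  if (!is.null(case$label)) {
    RNifti::writeNifti(as_img(case$label, "int16"),
                       file.path(directory,
                                 sprintf(pattern, case$case_id, "seg")))
  }
  invisible(directory)
}

#' Write a predicted label volume as NIfTI
#'
#' @param labels Integer `[D, H, W]` array with values in `{0, 1, 2, 4}`.
#' @param path Output path.
#' @param reference Optional NIfTI header to copy geometry from.
#' @export
write_prediction <- function(labels, path, reference = NULL) {
  validate_labels(labels)
  img <- if (is.null(reference)) {
    RNifti::asNifti(labels, datatype = "int16")
  } else {
    RNifti::asNifti(labels, reference = reference, datatype = "int16")
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Center crop-or-pad a (D, H, W) array to a target shape; returns the array
# and the per-axis offset of the original volume inside the result
# (positive: padding added; negative: voxels cropped away at the front).
crop_or_pad <- function(a, target, fill = 0) {
  src <- dim(a)
  if (is.integer(a)) fill <- as.integer(fill)
  out <- array(fill, target)
  src_from <- integer(3); src_to <- integer(3)
  dst_from <- integer(3); dst_to <- integer(3)
  off <- integer(3)
  for (ax in 1:3) {
    if (src[ax] >= target[ax]) {
      start <- (src[ax] - target[ax]) %/% 2L
      src_from[ax] <- start + 1L; src_to[ax] <- start + target[ax]
      dst_from[ax] <- 1L; dst_to[ax] <- target[ax]
      off[ax] <- -start
    } else {
      start <- (target[ax] - src[ax]) %/% 2L
      src_from[ax] <- 1L; src_to[ax] <- src[ax]
      dst_from[ax] <- start + 1L; dst_to[ax] <- start + src[ax]
      off[ax] <- start
    }
  }
  out[dst_from[1]:dst_to[1], dst_from[2]:dst_to[2], dst_from[3]:dst_to[3]] <-
    a[src_from[1]:src_to[1], src_from[2]:src_to[2], src_from[3]:src_to[3]]
  list(array = out, offset = off)
}

#' Preprocess a case into a model-ready sample
#'
#' Each modality is z-scored over its nonzero (brain) voxels, then all
#' channels and the label are center-cropped or zero-padded to
#' `target_shape` (a multiple of 16 on every axis).
#'
#' @param case A `brats_case`.
#' @param target_shape Length-3 integer vector, default `c(128, 128, 128)`.
#' @return A list with `x` (`[4, D, H, W]` array), `masks` (stacked
#'   `[3, D, H, W]` region masks, or `NULL` if unlabeled), `label` (cropped
#'   label volume or `NULL`), `offset` (crop/pad offset for inverse
#'   mapping), and `case_id`.
#' @export
preprocess_case <- function(case, target_shape = c(128L, 128L, 128L)) {
  target_shape <- as.integer(target_shape)
  if (any(target_shape %% 16L != 0L)) {
    stop("target_shape must be a multiple of 16 on every axis")
  }
  x <- array(0, c(4L, target_shape))
  off <- NULL
  for (i in seq_along(.ehff_modalities)) {
    a <- case$modalities[[.ehff_modalities[i]]]
    nz <- a != 0
    if (any(nz)) {
      mu <- mean(a[nz])
      sdv <- stats::sd(a[nz])
      if (!is.finite(sdv) || sdv == 0) sdv <- 1
      a[nz] <- (a[nz] - mu) / sdv
    }
    cp <- crop_or_pad(a, target_shape)
    x[i, , , ] <- cp$array
    off <- cp$offset
  }
  label <- NULL
  masks <- NULL
  if (!is.null(case$label)) {
    label <- crop_or_pad(case$label, target_shape)$array
    masks <- stack_masks(remap_labels(label))
  }
  list(x = x, masks = masks, label = label, offset = off,
       case_id = case$case_id)
}

#' Deterministic five-fold split
#'
#' Shuffles the case ids under the seed and assigns them round-robin, so
#' fold sizes differ by at most one.
#'
#' @param case_ids Character vector (at least `n_folds` entries).
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed (default 42).
#' @return A `fold_split`: named integer vector of fold indices in
#'   `0..n_folds-1`, with the seed as an attribute.
#' @export
make_folds <- function(case_ids, n_folds = 5L, seed = 42L) {
  if (length(case_ids) < n_folds) {
    stop("need at least ", n_folds, " cases to build ", n_folds,
         " folds, got ", length(case_ids))
  }
  shuffled <- with_seed(seed, sample(case_ids))
  assignment <- stats::setNames(rep_len(seq_len(n_folds) - 1L,
                                        length(shuffled)), shuffled)
  structure(assignment[case_ids], seed = seed, class = "fold_split")
}

#' @rdname make_folds
#' @param folds A `fold_split`.
#' @param path JSON output path.
#' @export
write_folds <- function(folds, path) {
  jsonlite::write_json(list(seed = attr(folds, "seed"),
                            fold_assignments = as.list(unclass(folds))),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname make_folds
#' @export
read_folds <- function(path) {
  j <- jsonlite::read_json(path)
  fa <- unlist(j$fold_assignments)
  structure(as.integer(fa), names = names(fa), seed = j$seed,
            class = "fold_split")
}

# --- synthetic phantom ------------------------------------------------------

.default_contrasts <- function() {
  m <- rbind(t1    = c(0.70, 0.45, 0.35, 0.60),
             t1ce  = c(0.70, 0.50, 0.30, 1.00),
             t2    = c(0.50, 0.80, 0.90, 0.60),
             flair = c(0.50, 1.00, 0.70, 0.60))
  colnames(m) <- c("healthy", "edema", "necrotic", "enhancing")
  m
}

#' Specification of a synthetic BraTS-like phantom
#'
#' A nested-ellipsoid lesion (enhancing core inside tumor core inside a
#' whole-tumor edema shell) embedded in homogeneous healthy tissue, imaged
#' under four modality-dependent contrast lookups with additive Gaussian
#' noise.  The label volume uses the BraTS convention (0 healthy, 2 edema
#' shell, 1 core shell, 4 enhancing core), so the derived ET/TC/WT regions
#' nest by construction.
#'
#' @param shape Volume shape, multiples of 16 (default 64^3).
#' @param wt_radius,tc_radius,et_radius Nested radii in voxels
#'   (`et < tc < wt < min(shape)/2`).
#' @param center_jitter Uniform jitter of the lesion center, voxels.
#' @param axis_ratios Per-axis radius multipliers (default spherical).
#' @param modality_contrasts 4x4 matrix, modality x tissue class
#'   (healthy, edema, necrotic, enhancing).
#' @param noise_sigma Additive Gaussian noise level (default 0.1).
#' @param seed Integer seed.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 64L), wt_radius = 20,
                         tc_radius = 13, et_radius = 7, center_jitter = 3,
                         axis_ratios = c(1, 1, 1),
                         modality_contrasts = .default_contrasts(),
                         noise_sigma = 0.1, seed = 1L) {
  shape <- as.integer(shape)
  if (any(shape %% 16L != 0L)) {
    stop("phantom shape must be a multiple of 16 on every axis")
  }
  if (!(et_radius < tc_radius && tc_radius < wt_radius &&
        wt_radius < min(shape) / 2)) {
    stop("phantom radii must satisfy et_radius < tc_radius < wt_radius < ",
         "min(shape)/2 (got ", et_radius, ", ", tc_radius, ", ", wt_radius,
         ")")
  }
  stopifnot(noise_sigma >= 0, all(dim(modality_contrasts) == c(4L, 4L)))
  structure(list(shape = shape, wt_radius = wt_radius, tc_radius = tc_radius,
                 et_radius = et_radius, center_jitter = center_jitter,
                 axis_ratios = axis_ratios,
                 modality_contrasts = modality_contrasts,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic phantom case
#'
#' Fully deterministic given the spec (including its seed).
#'
#' @param spec A [phantom_spec()].
#' @param case_id Identifier for the generated case.
#' @return A `brats_case` with label present.
#' @export
generate_phantom <- function(spec, case_id = "phantom") {
  stopifnot(inherits(spec, "phantom_spec"))
  shp <- spec$shape
  with_seed(spec$seed, {
    center <- shp / 2 + runif(3, -spec$center_jitter, spec$center_jitter)
    dist2 <- function(radius) {
      r <- radius * spec$axis_ratios
      dx <- (seq_len(shp[1L]) - center[1L]) / r[1L]
      dy <- (seq_len(shp[2L]) - center[2L]) / r[2L]
      dz <- (seq_len(shp[3L]) - center[3L]) / r[3L]
      outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
    }
    lab <- array(0L, shp)
    lab[dist2(spec$wt_radius) <= 1] <- 2L
    lab[dist2(spec$tc_radius) <= 1] <- 1L
    lab[dist2(spec$et_radius) <= 1] <- 4L
    class_idx <- array(1L, shp)
    class_idx[lab == 2L] <- 2L
    class_idx[lab == 1L] <- 3L
    class_idx[lab == 4L] <- 4L
    modalities <- lapply(seq_len(4L), function(m) {
      v <- spec$modality_contrasts[m, class_idx]
      if (spec$noise_sigma > 0) {
        v <- v + rnorm(length(v), sd = spec$noise_sigma)
      }
      array(v, shp)
    })
    names(modalities) <- .ehff_modalities
    structure(list(case_id = case_id, modalities = modalities, label = lab,
                   reference = NULL),
              class = "brats_case")
  })
}
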