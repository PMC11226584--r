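#' Write a volume set to NIfTI files plus a manifest
#'
#' One `.nii.gz` per subject and a manifest CSV with columns `subject_id`,
#' `path`, `age`, `cohort` — the on-disk interchange format between the
#' simulation and modelling stages.
#'
#' @param vols A `bg_volumes` object.
#' @param dir Output directory (created if needed).
#' @param cohort Cohort label written to the manifest.
#' @return The manifest tibble, invisibly written to `dir/manifest.csv`.
#' @export
write_volumes <- function(vols, dir, cohort = "cohort") {
  stopifnot(inherits(vols, "bg_volumes"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(vols$subject_id, ".nii.gz"))
  for (i in seq_along(vols$subject_id)) {
    RNifti::writeNifti(RNifti::asNifti(vols$data[, , , i]), paths[i])
  }
  manifest <- tibble::tibble(subject_id = vols$subject_id, path = paths,
                             age = vols$age, cohort = cohort)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Read registered GM volumes listed in a manifest
#'
#' Loads NIfTI volumes in manifest order and attaches subject ages. All
#' volumes must share the grid shape and voxel-to-world affine (tolerance
#' 1e-4); a mismatching file is reported by name.
#'
#' @param manifest A data frame with columns `subject_id`, `path`, `age`, or
#'   the path of a manifest CSV.
#' @return A `bg_volumes` object.
#' @export
read_volumes <- function(manifest) {
  if (is.character(manifest)) {
    manifest <- readr::read_csv(manifest, show_col_types = FALSE)
  }
  check_df_cols(manifest, c("subject_id", "path", "age"), "manifest")
  if (any(is.na(manifest$age))) {
    abort(sprintf("missing age for subject(s): %s",
                  paste(manifest$subject_id[is.na(manifest$age)],
                        collapse = ", ")))
  }
  imgs <- lapply(manifest$path, function(p) {
    if (!file.exists(p)) abort(sprintf("volume file not found: %s", p))
    RNifti::readNifti(p)
  })
  d0 <- dim(imgs[[1]])
  a0 <- RNifti::xform(imgs[[1]])
  for (i in seq_along(imgs)) {
    if (!identical(dim(imgs[[i]]), d0)) {
      abort(sprintf("grid shape mismatch in %s (expected %s, got %s)",
                    manifest$path[i], paste(d0, collapse = "x"),
                    paste(dim(imgs[[i]]), collapse = "x")))
    }
    if (max(abs(RNifti::xform(imgs[[i]]) - a0)) > 1e-4) {
      abort(sprintf("affine mismatch in %s", manifest$path[i]))
    }
  }
  data <- array(0, c(d0, length(imgs)))
  for (i in seq_along(imgs)) data[, , , i] <- as.array(imgs[[i]])
  gm_volumes(data, manifest$subject_id, manifest$age, affine = a0)
}

#' Build a brain mask from a template
#'
#' A voxel is included iff its template value exceeds `threshold`. The mask
#' stores both the boolean volume and the ordered list of included linear
#' indices (ascending, column-major — R's native array order), which fixes
#' the design-matrix column order for serialized models.
#'
#' @param template Template volume.
#' @param threshold Inclusion threshold in `[0, 1)`; default 0.1 excludes
#'   near-zero background voxels.
#' @return An object of class `bg_mask` with fields `volume`, `index`,
#'   `grid`, `threshold`.
#' @export
build_mask <- function(template, threshold = 0.1) {
  stopifnot(is.array(template), length(dim(template)) == 3L)
  if (threshold < 0 || threshold >= 1) abort("threshold must be in [0, 1)")
  keep <- template > threshold
  idx <- which(keep)  # ascending linear index, column-major
  if (length(idx) == 0L) abort("mask is empty: threshold excludes every voxel")
  structure(list(volume = keep, index = idx, grid = dim(template),
                 threshold = threshold, order = "column-major"),
            class = "bg_mask")
}

#' @export
print.bg_mask <- function(x, ...) {
  cat(sprintf("<bg_mask> %d / %d voxels (threshold %g, %s order)\n",
              length(x$index), prod(x$grid), x$threshold, x$order))
  invisible(x)
}

#' Vectorize volumes into a subjects-by-voxels design matrix
#'
#' Row i, column k holds subject i's value at the k-th masked voxel; column
#' order is the mask's ascending linear index.
#'
#' @param vols A `bg_volumes` object on the mask's grid.
#' @param mask A `bg_mask`.
#' @return An object of class `bg_design`: `values` (n x p matrix),
#'   `subject_id`, `age`, `voxel_index`, `grid`.
#' @export
vectorize <- function(vols, mask) {
  stopifnot(inherits(vols, "bg_volumes"), inherits(mask, "bg_mask"))
  if (!identical(as.integer(vols$grid), as.integer(mask$grid))) {
    abort(sprintf("grid mismatch: volumes %s vs mask %s",
                  paste(vols$grid, collapse = "x"),
                  paste(mask$grid, collapse = "x")))
  }
  n <- length(vols$subject_id)
  flat <- matrix(vols$data, nrow = prod(vols$grid), ncol = n)
  values <- t(flat[mask$index, , drop = FALSE])
  rownames(values) <- vols$subject_id
  structure(list(values = values, subject_id = vols$subject_id,
                 age = vols$age, voxel_index = mask$index,
                 grid = mask$grid),
            class = "bg_design")
}

#' @export
print.bg_design <- function(x, ...) {
  cat(sprintf("<bg_design> %d subjects x %d voxels (grid %s)\n",
              nrow(x$values), ncol(x$values), paste(x$grid, collapse = "x")))
  invisible(x)
}

#' Place a voxel-weight vector back onto the template grid
#'
#' Inverse of [vectorize()] on the mask support: weights land at the mask's
#' linear indices, all other voxels are zero.
#'
#' @param weights Numeric vector, length equal to the mask size.
#' @param mask A `bg_mask`.
#' @param file Optional path; when given the volume is also written as NIfTI.
#' @return A 3-D array on the mask grid.
#' @export
unvectorize <- function(weights, mask, file = NULL) {
  stopifnot(inherits(mask, "bg_mask"))
  if (length(weights) != length(mask$index)) {
    abort(sprintf("weights length (%d) must equal mask size (%d)",
                  length(weights), length(mask$index)))
  }
  vol <- array(0, mask$grid)
  vol[mask$index] <- weights
  if (!is.null(file)) RNifti::writeNifti(RNifti::asNifti(vol), file)
  vol
}
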