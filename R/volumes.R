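#' Container for a set of registered gray-matter volumes
#'
#' Holds per-subject 3-D GM probability volumes on a shared grid as one 4-D
#' array (x, y, z, subject) together with subject identifiers and
#' chronological ages.
#'
#' @param data 4-D numeric array, last dimension indexes subjects.
#' @param subject_id Character vector of unique subject identifiers.
#' @param age Numeric vector of chronological ages (years).
#' @param affine 4x4 voxel-to-world matrix (defaults to identity).
#' @return An object of class `bg_volumes`.
#' @export
gm_volumes <- function(data, subject_id, age, affine = diag(4)) {
  stopifnot(is.array(data), length(dim(data)) == 4L)
  n <- dim(data)[4]
  if (length(subject_id) != n || length(age) != n) {
    abort("subject_id and age must match the number of volumes")
  }
  if (anyDuplicated(subject_id)) abort("subject_id values must be unique")
  if (any(!is.finite(age))) abort("ages must be finite")
  structure(
    list(data = data, subject_id = as.character(subject_id),
         age = as.numeric(age), grid = dim(data)[1:3], affine = affine),
    class = "bg_volumes"
  )
}

#' @export
print.bg_volumes <- function(x, ...) {
  cat(sprintf("<bg_volumes> %d subjects on a %s grid; ages %.1f-%.1f\n",
              length(x$subject_id), paste(x$grid, collapse = "x"),
              min(x$age), max(x$age)))
  invisible(x)
}

#' @export
length.bg_volumes <- function(x) length(x$subject_id)

#' Extract one subject's volume
#' @param vols A `bg_volumes` object.
#' @param i Subject index or id.
#' @return A 3-D array.
#' @export
get_volume <- function(vols, i) {
  stopifnot(inherits(vols, "bg_volumes"))
  if (is.character(i)) i <- match(i, vols$subject_id)
  vols$data[, , , i]
}
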