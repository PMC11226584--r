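#' Generate a synthetic gray-matter template volume
#'
#' Builds a smooth pseudo-anatomical template on a voxel grid: an ellipsoidal
#' "brain" with a soft edge profile plus spatially autocorrelated texture,
#' clipped to GM-probability range. The contiguous region with values above
#' 0.1 occupies roughly 30-70% of the grid, standing in for a population
#' template that registered GM maps share.
#'
#' @param grid_shape Integer length-3 vector, all dimensions >= 8.
#' @param seed Integer seed; identical inputs reproduce the volume
#'   bit-identically.
#' @return A 3-D array in `[0, 1]` with attribute `brain_frac`, the fraction
#'   of voxels above 0.1.
#' @export
#' @examples
#' tpl <- make_template(c(16, 16, 16), seed = 1)
#' range(tpl)
make_template <- function(grid_shape, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L)) {
    abort("grid_shape must be three dimensions, each >= 8")
  }
  d <- grid_shape
  set.seed(stage_seed(seed, "template"))
  # normalized radial coordinate of an ellipsoid filling ~42% of each axis
  ax <- lapply(d, function(n) (seq_len(n) - (n + 1) / 2) / (0.42 * n))
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  edge <- 1 / (1 + exp((sqrt(r2) - 1) * 12))   # soft shell
  texture <- gaussian_smooth3d(array(rnorm(prod(d)), d), fwhm = max(2, d[1] / 8))
  texture <- texture / max(sd(texture), 1e-12)
  vol <- clip01(0.65 * edge + 0.12 * texture * edge + 0.02)
  structure(vol, brain_frac = mean(vol > 0.1))
}

#' Plant a sparse atrophy signal map inside a template
#'
#' Places `n_clusters` non-overlapping spherical clusters of age-related GM
#' loss within the template brain. Inside each sphere the per-year effect is
#' negative (gray matter decreases with age) with peak magnitude
#' `effect_scale` and a cosine taper to zero at the sphere edge; the map is
#' exactly zero elsewhere. These clusters are the ground truth the fitted
#' voxel-weight map should recover.
#'
#' @param template Template volume from [make_template()].
#' @param n_clusters Number of spheres (>= 1).
#' @param effect_scale Peak GM-probability change per year; 0 gives an
#'   all-zero map.
#' @param seed Integer seed.
#' @return A 3-D array of per-voxel effects (GM units per year), `<= 0`
#'   everywhere.
#' @export
make_signal_map <- function(template, n_clusters, effect_scale, seed = 1L) {
  stopifnot(is.array(template), length(dim(template)) == 3L)
  n_clusters <- as.integer(n_clusters)
  if (n_clusters < 1L) abort("n_clusters must be >= 1")
  d <- dim(template)
  w <- array(0, d)
  if (effect_scale == 0) return(w)
  set.seed(stage_seed(seed, "signal"))
  radius <- max(2, round(min(d) / 10))
  interior <- which(template > 0.3, arr.ind = TRUE)
  # keep sphere fully inside the grid
  ok <- rowSums(sweep(interior, 2, radius + 1L, `<`)) == 0 &
    rowSums(sweep(sweep(interior, 2, d), 2, -(radius + 1L), `>`)) == 0
  interior <- interior[ok, , drop = FALSE]
  # placement can wedge itself (an early central sphere blocks the rest),
  # so restart from scratch rather than sampling around a bad partial set
  centers <- NULL
  for (restart in seq_len(100L)) {
    cand_set <- matrix(0, 0, 3)
    for (try in seq_len(500L)) {
      if (nrow(interior) == 0L) break
      cand <- interior[sample.int(nrow(interior), 1L), ]
      if (nrow(cand_set) == 0L ||
          all(sqrt(rowSums(sweep(cand_set, 2, cand)^2)) > 2 * radius + 2)) {
        cand_set <- rbind(cand_set, cand)
      }
      if (nrow(cand_set) == n_clusters) break
    }
    if (nrow(cand_set) == n_clusters) {
      centers <- cand_set
      break
    }
  }
  if (is.null(centers)) {
    abort(sprintf(
      "could not place %d non-overlapping clusters of radius %d in this template",
      n_clusters, radius))
  }
  for (i in seq_len(nrow(centers))) {
    ctr <- centers[i, ]
    rng <- lapply(1:3, function(k) (ctr[k] - radius):(ctr[k] + radius))
    dist2 <- outer(outer((rng[[1]] - ctr[1])^2, (rng[[2]] - ctr[2])^2, `+`),
                   (rng[[3]] - ctr[3])^2, `+`)
    prof <- ifelse(dist2 <= radius^2,
                   cos(pi / 2 * sqrt(dist2) / radius), 0)
    w[rng[[1]], rng[[2]], rng[[3]]] <-
      w[rng[[1]], rng[[2]], rng[[3]]] - abs(effect_scale) * prof
  }
  w
}
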