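# internal helpers shared across modules

# Deterministic per-stage seed derived from a global seed, so stages can be
# re-run individually and still reproduce a full-pipeline run. Kept < 2^31.
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 1009L + h) %% 2147483587L)
}

# Separable 3-D Gaussian smoothing; fwhm in voxels. fwhm <= 0 is a no-op.
# Kernel is truncated at 3 sigma and renormalized, so the filter preserves a
# constant field (edge effects damp variance but not the mean).
gaussian_smooth3d <- function(vol, fwhm) {
  if (fwhm <= 0) return(vol)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(vol)
  conv1 <- function(m, kern) {
    # convolve each column of matrix m with kern, zero-padded, renormalized
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    wt <- numeric(n)
    for (j in seq_along(kern)) {
      off <- j - r - 1L
      src <- seq_len(n) + off
      ok <- src >= 1L & src <= n
      out[ok, ] <- out[ok, ] + kern[j] * m[src[ok], , drop = FALSE]
      wt[ok] <- wt[ok] + kern[j]
    }
    out / wt
  }
  # axis 1
  vol <- array(conv1(matrix(vol, d[1]), k), d)
  # axis 2
  vol <- aperm(array(conv1(matrix(aperm(vol, c(2, 1, 3)), d[2]), k),
                     d[c(2, 1, 3)]), c(2, 1, 3))
  # axis 3
  vol <- aperm(array(conv1(matrix(aperm(vol, c(3, 1, 2)), d[3]), k),
                     d[c(3, 1, 2)]), c(2, 3, 1))
  vol
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_df_cols <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(data)
}
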