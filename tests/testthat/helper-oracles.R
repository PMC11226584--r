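# Independent reference implementations used to cross-check the package.
# These are deliberately naive (loops, normal equations, step-up by hand)
# and never call the code paths they validate.

# cyclic coordinate descent for (1/2n)||y - a0 - Xb||^2 +
# lambda * (alpha ||b||_1 + (1-alpha)/2 ||b||_2^2)
oracle_enet <- function(x, y, alpha, lambda, tol = 1e-13, maxit = 1e5) {
  n <- nrow(x)
  p <- ncol(x)
  b <- numeric(p)
  a0 <- mean(y)
  xx <- colSums(x^2) / n
  r <- y - a0
  for (it in seq_len(maxit)) {
    b_old <- b
    for (j in seq_len(p)) {
      zj <- sum(x[, j] * r) / n + xx[j] * b[j]
      bj <- sign(zj) * max(abs(zj) - lambda * alpha, 0) /
        (xx[j] + lambda * (1 - alpha))
      r <- r - x[, j] * (bj - b[j])
      b[j] <- bj
    }
    a0_new <- a0 + mean(r)
    r <- r - (a0_new - a0)
    a0 <- a0_new
    if (max(abs(b - b_old)) < tol) break
  }
  list(beta = b, a0 = a0)
}

# 6-connected flood fill counting connected components of a 3-D logical array
oracle_components <- function(mask3d) {
  d <- dim(mask3d)
  seen <- array(FALSE, d)
  comps <- 0L
  idx_all <- which(mask3d)
  for (start in idx_all) {
    if (seen[start]) next
    comps <- comps + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue) > 0) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      co <- arrayInd(v, d)
      for (ax in 1:3) for (dl in c(-1L, 1L)) {
        nb <- co
        nb[ax] <- nb[ax] + dl
        if (nb[ax] < 1L || nb[ax] > d[ax]) next
        li <- nb[1] + d[1] * (nb[2] - 1L) + d[1] * d[2] * (nb[3] - 1L)
        if (mask3d[li] && !seen[li]) {
          seen[li] <- TRUE
          queue <- c(queue, li)
        }
      }
    }
  }
  comps
}

# Benjamini-Hochberg step-up, written out from the definition
oracle_bh <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  passed <- which(p[ord] <= alpha * seq_len(m) / m)
  flags <- rep(FALSE, m)
  if (length(passed) > 0) flags[ord[seq_len(max(passed))]] <- TRUE
  flags
}

# LS means and pairwise contrasts by explicit normal equations:
# model bag ~ group + covariates with treatment coding; LS mean of group g
# is the fit evaluated at covariate sample means.
oracle_lsmeans <- function(data, outcome, group, covariates) {
  g <- factor(data[[group]])
  X <- stats::model.matrix(~ g)
  for (cv in covariates) X <- cbind(X, data[[cv]])
  y <- data[[outcome]]
  beta <- solve(crossprod(X), crossprod(X, y))
  sigma2 <- sum((y - X %*% beta)^2) / (nrow(X) - ncol(X))
  XtXinv <- solve(crossprod(X))
  lev <- levels(g)
  pred_row <- function(l) {
    r <- c(1, as.numeric(lev[-1] == l))
    c(r, vapply(covariates, function(cv) mean(data[[cv]]), 0))
  }
  means <- vapply(lev, function(l) sum(pred_row(l) * beta), 0)
  contrast <- function(l1, l2) {
    cvec <- pred_row(l1) - pred_row(l2)
    est <- sum(cvec * beta)
    se <- sqrt(sigma2 * drop(t(cvec) %*% XtXinv %*% cvec))
    c(est = est, se = se)
  }
  list(means = means, contrast = contrast)
}
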