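# Regularized canonical correlation analysis: classical CCA with ridge
# constants added to the within-block covariance matrices, which keeps the
# problem well-posed when variables are nearly collinear or outnumber
# samples.

# Core computation on centered (optionally scaled) matrices. Returns NULL
# when a block has a zero-variance column (caller decides how to react).
# rho_i are the singular values of Rx^-T Cxy Ry^-1 with C.. + lambda I =
# R^T R, i.e. the square roots of the eigenvalues of
# (Cxx + lx I)^-1 Cxy (Cyy + ly I)^-1 Cyx.
.rccaCore <- function(X, Y, lambda_x, lambda_y, standardize = TRUE,
                      want_weights = TRUE) {
  n <- nrow(X)
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- X - rep(xm, each = n)
  Yc <- Y - rep(ym, each = n)
  if (standardize) {
    xs <- sqrt(colSums(Xc^2) / (n - 1))
    ys <- sqrt(colSums(Yc^2) / (n - 1))
    if (any(xs < 1e-12) || any(ys < 1e-12)) return(NULL)
    Xc <- Xc / rep(xs, each = n)
    Yc <- Yc / rep(ys, each = n)
  } else if (any(colSums(Xc^2) < 1e-24) || any(colSums(Yc^2) < 1e-24)) {
    return(NULL)
  }
  Cxx <- crossprod(Xc) / (n - 1)
  Cyy <- crossprod(Yc) / (n - 1)
  Cxy <- crossprod(Xc, Yc) / (n - 1)
  Rx <- tryCatch(chol(Cxx + diag(lambda_x, ncol(X))), error = function(e) NULL)
  Ry <- tryCatch(chol(Cyy + diag(lambda_y, ncol(Y))), error = function(e) NULL)
  if (is.null(Rx) || is.null(Ry)) return(structure(list(), class = "singular"))
  A <- backsolve(Rx, Cxy, transpose = TRUE)       # Rx^-T Cxy
  K <- t(backsolve(Ry, t(A), transpose = TRUE))   # A Ry^-1
  if (!want_weights) {
    d <- svd(K, nu = 0, nv = 0)$d
    return(list(rho = pmin(pmax(d, 0), 1)))
  }
  sv <- svd(K)
  m <- min(ncol(X), ncol(Y))
  list(rho = pmin(pmax(sv$d[seq_len(m)], 0), 1),
       wx = backsolve(Rx, sv$u[, seq_len(m), drop = FALSE]),
       wy = backsolve(Ry, sv$v[, seq_len(m), drop = FALSE]))
}

#' Fit a regularized canonical correlation analysis
#'
#' Computes the canonical correlations between two sample-aligned blocks as
#' the square roots of the eigenvalues of
#' `(Cxx + lambda_x I)^-1 Cxy (Cyy + lambda_y I)^-1 Cyx`, where the `C` are
#' sample covariance matrices of the internally centered (and, by default,
#' unit-variance scaled) columns. With `lambda = 0` on full-rank blocks
#' this is classical CCA; positive constants shrink the within-block
#' covariances and keep the fit defined when a block is rank-deficient,
#' e.g. more variables than samples. Correlations are clipped to \[0, 1\]
#' and `min(p, q)` of them are reported.
#'
#' Standardizing the columns first (the default) makes the ridge constants
#' comparable across blocks; `standardize = FALSE` penalizes the raw
#' covariances instead, which is not scale-equivariant.
#'
#' @param X,Y numeric matrices with the same rows (samples).
#' @param lambda_x,lambda_y ridge constants, >= 0.
#' @param standardize scale columns to unit variance before penalization.
#' @return an [RccaResult].
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(20), 10, 2)
#' Y <- cbind(X[, 1] + rnorm(10, 0, 0.1), rnorm(10))
#' canonicalCorrelations(rccaFit(X, Y, 0, 0))
#' @export
rccaFit <- function(X, Y, lambda_x = 0.1, lambda_y = 0.1,
                    standardize = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) .stopf("X and Y must have the same sample rows")
  if (nrow(X) < 3L) .stopf("need at least 3 samples")
  if (lambda_x < 0 || lambda_y < 0) .stopf("ridge constants must be >= 0")
  core <- .rccaCore(X, Y, lambda_x, lambda_y, standardize)
  if (is.null(core))
    .stopf("zero-variance column in X or Y")
  if (inherits(core, "singular"))
    .stopf(paste("singular within-block covariance at lambda = 0;",
                 "use a positive ridge constant"))
  new("RccaResult", lambda_x = lambda_x, lambda_y = lambda_y,
      rho = core$rho, x_weights = core$wx, y_weights = core$wy,
      n = nrow(X), standardized = standardize)
}

#' Choose ridge constants by leave-one-out cross-validation
#'
#' Scores every pair on a grid of ridge constants by the leave-one-out
#' cross-validated first canonical correlation: for each held-out sample
#' the first pair of canonical variates is computed from the remaining
#' samples (sign-aligned to the full-data fit) and evaluated on the
#' held-out row; the score is the Pearson correlation of the n held-out
#' variate pairs. The procedure is deterministic.
#'
#' @param X,Y sample-aligned blocks (n >= 3).
#' @param grid_x,grid_y candidate ridge constants.
#' @param standardize passed to the internal fits.
#' @return a list with `lambda_x`, `lambda_y` (the argmax pair) and
#'   `scores`, the CV score surface (`grid_x` by `grid_y`).
#' @export
chooseLambda <- function(X, Y, grid_x = c(0.001, 0.01, 0.1, 1),
                         grid_y = grid_x, standardize = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (n < 3L) .stopf("need at least 3 samples for cross-validation")
  if (nrow(Y) != n) .stopf("X and Y must have the same sample rows")
  scores <- matrix(NA_real_, length(grid_x), length(grid_y),
                   dimnames = list(format(grid_x), format(grid_y)))
  loo_score <- function(lx, ly) {
    full <- .rccaCore(X, Y, lx, ly, standardize)
    if (is.null(full) || inherits(full, "singular")) return(NA_real_)
    u <- v <- numeric(n)
    for (i in seq_len(n)) {
      Xi <- X[-i, , drop = FALSE]; Yi <- Y[-i, , drop = FALSE]
      fit <- .rccaCore(Xi, Yi, lx, ly, standardize)
      if (is.null(fit) || inherits(fit, "singular")) return(NA_real_)
      sgn <- sign(sum(fit$wx[, 1] * full$wx[, 1]))
      if (sgn == 0) sgn <- 1
      ctr_x <- colMeans(Xi); ctr_y <- colMeans(Yi)
      sx <- if (standardize) apply(Xi, 2, sd) else rep(1, ncol(Xi))
      sy <- if (standardize) apply(Yi, 2, sd) else rep(1, ncol(Yi))
      u[i] <- sum((X[i, ] - ctr_x) / sx * fit$wx[, 1]) * sgn
      v[i] <- sum((Y[i, ] - ctr_y) / sy * fit$wy[, 1]) * sgn
    }
    if (sd(u) < 1e-12 || sd(v) < 1e-12) return(NA_real_)
    cor(u, v)
  }
  for (a in seq_along(grid_x)) for (b in seq_along(grid_y))
    scores[a, b] <- loo_score(grid_x[a], grid_y[b])
  if (all(is.na(scores)))
    .stopf("no grid pair produced a computable cross-validation score")
  best <- which(scores == max(scores, na.rm = TRUE), arr.ind = TRUE)[1, ]
  list(lambda_x = grid_x[best[1]], lambda_y = grid_y[best[2]],
       scores = scores)
}
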