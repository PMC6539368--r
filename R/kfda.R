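## Kernel Fisher discriminant analysis, solved in the dual: discriminant
## directions w = sum_i alpha_i phi(x_i) are found from the generalized
## eigenproblem K_B a = lambda (K_W + sigma I) a, where K_B and K_W are the
## between- and within-class scatters of the kernel columns.

#' RBF kernel value
#'
#' \eqn{k(x, z) = \exp(-\|x - z\|^2 / \delta^2)}.
#'
#' @param x,z numeric vectors of equal length.
#' @param delta positive kernel width.
#' @return kernel value in (0, 1].
#' @export
#' @examples
#' rbfKernel(c(0, 0), c(1, 0), delta = 1)  # exp(-1)
rbfKernel <- function(x, z, delta) {
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0)
    stop("delta must be a single positive number")
  exp(-sum((x - z)^2) / delta^2)
}

## Cross-kernel matrix k(x_i, z_j): N x M.
kernelCross <- function(X, Z, delta, kernel = "rbf") {
  if (kernel == "linear") return(X %*% t(Z))
  d2 <- outer(rowSums(X^2), rowSums(Z^2), "+") - 2 * X %*% t(Z)
  d2[d2 < 0] <- 0
  exp(-d2 / delta^2)
}

#' Median-heuristic RBF width
#'
#' Median pairwise Euclidean distance between rows of `X`; the customary
#' starting point for RBF width grids.
#'
#' @param X numeric matrix.
#' @return positive scalar.
#' @export
medianHeuristic <- function(X) {
  m <- stats::median(stats::dist(X))
  if (!is.finite(m) || m <= 0) 1 else m
}

#' Fit a kernel Fisher discriminant model
#'
#' Builds the dual between-class scatter
#' \eqn{K_B = \frac{1}{C(C-1)}\sum_{i \ne j} (\mu_i - \mu_j)(\mu_i - \mu_j)^T}
#' from the per-class mean kernel columns \eqn{\mu_i}, and the dual
#' within-class scatter
#' \eqn{K_W = \frac{1}{C}\sum_i \frac{1}{N_i}\sum_{j \in G_i}
#'   (\xi_j - \mu_i)(\xi_j - \mu_i)^T}
#' from the per-sample kernel columns \eqn{\xi_j}; then solves the
#' ridge-regularized eigenproblem of \eqn{(K_W + \sigma I)^{-1} K_B} (via
#' Cholesky whitening of the symmetrized matrices, so all eigenvalues are
#' real) and keeps the top `d` eigenvectors as dual coefficients, unit-norm,
#' sign fixed so each column's largest-magnitude entry is positive.
#'
#' Features are z-scored per column before the kernel by default (the RBF
#' distance is scale-sensitive and the feature set mixes units);
#' standardization parameters are learned here and reapplied by
#' [projectFeatures()].
#'
#' @param X N x p numeric feature matrix.
#' @param y length-N class labels (at least 2 classes, each with at least 2
#'   samples).
#' @param delta RBF width; `NULL` (default) uses [medianHeuristic()] on the
#'   standardized features.
#' @param sigma ridge regularizer (default 1e-7).
#' @param d number of discriminant dimensions; default and maximum `C - 1`.
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @param standardize z-score columns before the kernel (default TRUE).
#' @return a [KFDAModel-class].
#' @export
#' @examples
#' X <- rbind(matrix(rnorm(40), ncol = 2), matrix(rnorm(40, 4), ncol = 2))
#' y <- rep(c("a", "b"), each = 20)
#' m <- fitKFDA(X, y)
#' m
fitKFDA <- function(X, y, delta = NULL, sigma = 1e-7, d = NULL,
                    kernel = c("rbf", "linear"), standardize = TRUE) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  y <- as.character(y)
  stopifnot(nrow(X) == length(y))
  classes <- sort(unique(y))
  C <- length(classes)
  if (C < 2) stop("need at least 2 classes")
  Ni <- table(factor(y, levels = classes))
  if (any(Ni < 2)) stop("every class needs at least 2 samples")
  N <- nrow(X)

  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2L, stats::sd)
    scl[scl < .Machine$double.eps] <- 1
    Xs <- scale(X, center = ctr, scale = scl)
  } else {
    ctr <- numeric(0); scl <- numeric(0); Xs <- X
  }
  Xs <- matrix(as.numeric(Xs), nrow(X), ncol(X))  # strip names/attributes

  if (kernel == "rbf" && is.null(delta)) delta <- medianHeuristic(Xs)
  if (kernel == "linear" && is.null(delta)) delta <- 1
  if (kernel == "rbf" && delta <= 0) stop("delta must be positive")

  if (is.null(d)) d <- C - 1L
  if (d > C - 1L) {
    warning("d clipped to C - 1")
    d <- C - 1L
  }
  d <- as.integer(d)

  K <- kernelCross(Xs, Xs, delta, kernel)

  ## per-class mean kernel columns mu_i (N x C) and dual scatters
  mu <- matrix(0, N, C)
  KW <- matrix(0, N, N)
  for (i in seq_len(C)) {
    idx <- which(y == classes[i])
    Ki <- K[, idx, drop = FALSE]
    mu[, i] <- rowMeans(Ki)
    Ei <- Ki - mu[, i]
    KW <- KW + tcrossprod(Ei) / length(idx)
  }
  KW <- KW / C
  KB <- matrix(0, N, N)
  for (i in seq_len(C - 1L)) for (j in (i + 1L):C) {
    dmu <- mu[, i] - mu[, j]
    KB <- KB + tcrossprod(dmu)
  }
  KB <- 2 * KB / (C * (C - 1))

  KW <- (KW + t(KW)) / 2
  KB <- (KB + t(KB)) / 2

  U <- tryCatch(chol(KW + sigma * diag(N)), error = function(e)
    stop("within-class dual scatter is singular even after regularization: ",
         conditionMessage(e)))
  ## whitened symmetric problem: C0 = U^{-T} K_B U^{-1}
  C0 <- backsolve(U, t(backsolve(U, KB, transpose = TRUE)), transpose = TRUE)
  C0 <- (C0 + t(C0)) / 2
  es <- eigen(C0, symmetric = TRUE)
  vals <- es$values[seq_len(d)]
  alpha <- backsolve(U, es$vectors[, seq_len(d), drop = FALSE])
  ## unit-norm columns, largest-|entry| positive
  for (r in seq_len(d)) {
    a <- alpha[, r]
    a <- a / sqrt(sum(a^2))
    if (a[which.max(abs(a))] < 0) a <- -a
    alpha[, r] <- a
  }
  vals[vals < 0 & vals > -1e-8] <- pmax(vals[vals < 0 & vals > -1e-8], -1e-8)

  methods::new("KFDAModel",
    supportSamples = Xs, alpha = alpha, eigenvalues = vals,
    delta = as.numeric(delta), sigma = as.numeric(sigma), d = d,
    kernel = kernel, classList = classes,
    center = as.numeric(ctr), scale = as.numeric(scl))
}

#' @describeIn fitKFDA project new samples into the discriminant subspace:
#'   row j of the result is \eqn{\alpha^T (k(x_1, z_j), \ldots, k(x_N, z_j))}.
#' @param object a fitted [KFDAModel-class].
#' @param newdata M x p numeric matrix on the original feature scale.
#' @param ... unused.
#' @export
setMethod("projectFeatures", "KFDAModel", function(object, newdata, ...) {
  Z <- as.matrix(newdata)
  if (ncol(Z) != ncol(object@supportSamples))
    stop("newdata has ", ncol(Z), " columns; model expects ",
         ncol(object@supportSamples))
  if (length(object@center))
    Z <- scale(Z, center = object@center, scale = object@scale)
  Z <- unname(as.matrix(Z))
  Kc <- kernelCross(object@supportSamples, Z, object@delta, object@kernel)
  out <- t(Kc) %*% object@alpha
  colnames(out) <- paste0("kfda", seq_len(object@d))
  out
})

## Nearest-class-centroid classifier in a projected space (used for the
## delta cross-validation score and handy as a sanity baseline).
nearestCentroidPredict <- function(Ptrain, ytrain, Ptest) {
  classes <- sort(unique(ytrain))
  cent <- matrix(0, length(classes), ncol(Ptrain))
  for (i in seq_along(classes))
    cent[i, ] <- colMeans(Ptrain[ytrain == classes[i], , drop = FALSE])
  d2 <- outer(rowSums(Ptest^2), rowSums(cent^2), "+") -
    2 * Ptest %*% t(cent)
  classes[max.col(-d2, ties.method = "first")]
}

## Stratified fold assignment: within each class, cycle fold ids over a
## seeded permutation of the class's rows.
stratifiedFolds <- function(y, folds, seed) {
  assign <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' Choose the RBF width by stratified cross-validation
#'
#' For each candidate width, fits KFDA on the training folds and scores the
#' held-out fold with a nearest-class-centroid classifier in the projected
#' space; returns the width with the highest mean held-out accuracy (ties:
#' smallest width). If some class has fewer samples than `folds`, the fold
#' count is reduced with a warning.
#'
#' @param X,y training features and labels.
#' @param grid numeric vector of candidate widths. The default policy
#'   elsewhere in the package is `2^k * medianHeuristic(X)`.
#' @param folds number of CV folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @param sigma,standardize passed to [fitKFDA()].
#' @return the chosen width (scalar).
#' @export
selectDelta <- function(X, y, grid, folds = 5, seed = 1, sigma = 1e-7,
                        standardize = TRUE) {
  stopifnot(length(grid) >= 1, folds >= 2)
  y <- as.character(y)
  minClass <- min(table(y))
  if (minClass < folds) {
    warning("reducing folds to smallest class size (", minClass, ")")
    folds <- max(2L, as.integer(minClass))
  }
  if (length(grid) == 1L) return(grid[1L])
  fold <- stratifiedFolds(y, folds, seed)
  acc <- vapply(grid, function(delta) {
    mean(vapply(seq_len(folds), function(f) {
      tr <- fold != f
      m <- fitKFDA(X[tr, , drop = FALSE], y[tr], delta = delta,
                   sigma = sigma, standardize = standardize)
      Ptr <- projectFeatures(m, X[tr, , drop = FALSE])
      Pte <- projectFeatures(m, X[!tr, , drop = FALSE])
      mean(nearestCentroidPredict(Ptr, y[tr], Pte) == y[!tr])
    }, numeric(1)))
  }, numeric(1))
  ord <- order(-acc, grid)
  grid[ord[1L]]
}
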