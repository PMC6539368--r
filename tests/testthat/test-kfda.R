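# Kernel Fisher discriminant analysis: kernel identities, eigen-solution
# against a dense generalized-eigenproblem oracle, equivalence with primal
# FDA under a linear kernel, projection contracts and width selection.

# 3-class Gaussian toy in 2-D, 10 samples per class.
makeToy <- function(seed = 1, n = 10, sep = 4) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(2 * n), ncol = 2),
               matrix(rnorm(2 * n, mean = sep), ncol = 2),
               cbind(rnorm(n, sep), rnorm(n, -sep)))
    y <- rep(c("a", "b", "c"), each = n)
    list(X = X, y = y)
  })
}

# Dual scatters built independently (plain loops over definitions).
oracleDualScatters <- function(K, y) {
  classes <- sort(unique(y))
  C <- length(classes); N <- nrow(K)
  mu <- sapply(classes, function(cl) rowMeans(K[, y == cl, drop = FALSE]))
  KB <- matrix(0, N, N)
  for (i in 1:C) for (j in 1:C) if (i != j)
    KB <- KB + tcrossprod(mu[, i] - mu[, j])
  KB <- KB / (C * (C - 1))
  KW <- matrix(0, N, N)
  for (i in 1:C) {
    idx <- which(y == classes[i])
    for (jj in idx) KW <- KW + tcrossprod(K[, jj] - mu[, i]) / length(idx)
  }
  KW <- KW / C
  list(KB = KB, KW = KW)
}

test_that("RBF kernel obeys its pointwise identities", {
  x <- c(1, 2, 3); z <- c(2, 0, 3)
  expect_equal(rbfKernel(x, x, 2), 1)
  expect_equal(rbfKernel(x, z, 2), rbfKernel(z, x, 2))
  # ||x-z||^2 = delta^2 -> exp(-1)
  d <- sqrt(sum((x - z)^2))
  expect_equal(rbfKernel(x, z, delta = d), exp(-1))
  expect_error(rbfKernel(x, z, -1), "positive")
  # cross-check the Gram against kernlab's rbfdot (sigma = 1/delta^2)
  X <- matrix(rnorm(20), 5)
  G1 <- harensemble:::kernelCross(X, X, delta = 1.7)
  G2 <- kernlab::kernelMatrix(kernlab::rbfdot(sigma = 1 / 1.7^2), X)
  expect_equal(unname(G1), unname(G2@.Data), tolerance = 1e-12)
})

test_that("eigen-solution matches the dense generalized-eigenproblem oracle", {
  toy <- makeToy()
  delta <- 3; sigma <- 1e-7
  m <- fitKFDA(toy$X, toy$y, delta = delta, sigma = sigma,
               standardize = FALSE)
  K <- harensemble:::kernelCross(toy$X, toy$X, delta)
  sc <- oracleDualScatters(K, toy$y)
  # brute-force: eigen of (KW + sigma I)^{-1} KB, non-symmetric solve
  E <- eigen(solve(sc$KW + sigma * diag(nrow(K))) %*% sc$KB)
  vals <- Re(E$values)[1:2]
  expect_equal(fisherValues(m), vals, tolerance = 1e-6)
  for (r in 1:2) {
    a <- alphaCoefficients(m)[, r]
    b <- Re(E$vectors[, r]); b <- b / sqrt(sum(b^2))
    expect_gt(abs(sum(a * b)), 1 - 1e-6)  # collinear up to sign
  }
  # C = 2 gives exactly one non-negligible eigenvalue
  two <- makeToy(seed = 2)
  m2 <- fitKFDA(two$X[1:20, ], two$y[1:20], delta = 3, standardize = FALSE)
  ev <- fisherValues(m2)
  expect_gt(ev[1], 1e3 * max(abs(ev[-1]), .Machine$double.eps))
})

test_that("linear-kernel KFDA projections match primal FDA directions", {
  toy <- makeToy(seed = 3)
  m <- fitKFDA(toy$X, toy$y, kernel = "linear", sigma = 1e-9,
               standardize = FALSE)
  P <- projectFeatures(m, toy$X)
  # primal FDA with matching class weights (1/C within, pairwise between)
  classes <- sort(unique(toy$y))
  C <- length(classes); p <- ncol(toy$X)
  xb <- sapply(classes, function(cl) colMeans(toy$X[toy$y == cl, , drop = FALSE]))
  SB <- matrix(0, p, p); SW <- matrix(0, p, p)
  for (i in 1:C) for (j in 1:C) if (i != j)
    SB <- SB + tcrossprod(xb[, i] - xb[, j])
  SB <- SB / (C * (C - 1))
  for (i in 1:C) {
    Xi <- toy$X[toy$y == classes[i], , drop = FALSE]
    SW <- SW + crossprod(sweep(Xi, 2, xb[, i])) / nrow(Xi)
  }
  SW <- SW / C
  W <- eigen(solve(SW) %*% SB)$vectors[, 1:2]
  Pfda <- toy$X %*% Re(W)
  for (r in 1:2) {
    cc <- abs(cor(P[, r], Pfda[, r]))
    expect_gt(cc, 1 - 1e-6)
  }
  # and the same subspace as MASS::lda (independent library cross-check)
  ld <- MASS::lda(toy$X, grouping = toy$y)
  Plda <- toy$X %*% ld$scaling
  for (r in 1:2) expect_gt(abs(cor(P[, r], Plda[, r])), 1 - 1e-4)
})

test_that("projection contracts: shapes, self-consistency, identity check", {
  toy <- makeToy(seed = 4)
  m <- fitKFDA(toy$X, toy$y, delta = 3, standardize = FALSE)
  P <- projectFeatures(m, toy$X)
  expect_equal(dim(P), c(30, 2))
  # projecting the support set equals K alpha
  K <- harensemble:::kernelCross(toy$X, toy$X, kernelWidth(m))
  expect_equal(unname(P), unname(K %*% alphaCoefficients(m)),
               tolerance = 1e-12)
  expect_identical(P, projectFeatures(m, toy$X))  # deterministic
  expect_error(projectFeatures(m, toy$X[, 1, drop = FALSE]), "columns")
})

test_that("projected classes separate cleanly in the near-linear regime", {
  withr::with_seed(6, {
    X <- matrix(c(rnorm(40, -5), rnorm(40, 5)), ncol = 1)
    y <- rep(c("a", "b"), each = 40)
  })
  m <- fitKFDA(X, y, delta = 100, standardize = FALSE)
  P <- projectFeatures(m, X)[, 1]
  mu <- tapply(P, y, mean)
  sdp <- sqrt(mean(tapply(P, y, var)))
  expect_gt(abs(diff(mu)), 4 * sdp)
})

test_that("projection improves the trace separability ratio", {
  sepRatio <- function(X, y) {
    classes <- unique(y)
    gm <- colMeans(X)
    within <- 0; between <- 0
    for (cl in classes) {
      Xi <- X[y == cl, , drop = FALSE]
      within <- within + sum(sweep(Xi, 2, colMeans(Xi))^2)
      between <- between + nrow(Xi) * sum((colMeans(Xi) - gm)^2)
    }
    between / within
  }
  wins <- 0
  for (s in 1:20) {
    withr::with_seed(s, {
      n <- 15
      X <- rbind(matrix(rnorm(2 * n, sd = 1.5), ncol = 2),
                 matrix(rnorm(2 * n, mean = 2.5, sd = 1.5), ncol = 2),
                 cbind(rnorm(n, 2.5, 1.5), rnorm(n, -2.5, 1.5)))
      y <- rep(c("a", "b", "c"), each = n)
    })
    m <- fitKFDA(X, y)
    P <- projectFeatures(m, X)
    raw <- sepRatio(scale(X), y)
    proj <- sepRatio(P, y)
    wins <- wins + (proj >= raw)
  }
  expect_equal(wins, 20)
})

test_that("delta selection is reproducible and finds the useful width", {
  # singleton grid short-circuits
  toy <- makeToy(seed = 8)
  expect_equal(selectDelta(toy$X, toy$y, grid = 2.5), 2.5)

  # XOR-style clusters at scale s: only the cluster-scale width separates
  # them (a huge width degenerates to a linear boundary, a tiny width
  # makes held-out kernel columns vanish)
  hits <- 0
  for (s in 1:20) {
    withr::with_seed(s, {
      n <- 10
      corner <- function(cx, cy) cbind(rnorm(n, cx, 0.5), rnorm(n, cy, 0.5))
      X <- rbind(corner(0, 0), corner(3, 3), corner(0, 3), corner(3, 0))
      y <- rep(c("a", "a", "b", "b"), each = n)
    })
    sc <- median(dist(X))
    grid <- c(0.01 * sc, sc, 100 * sc)
    chosen <- selectDelta(X, y, grid = grid, folds = 3, seed = s,
                          standardize = FALSE)
    hits <- hits + (chosen == grid[2])
  }
  expect_gte(hits, 18)

  expect_equal(selectDelta(toy$X, toy$y, grid = c(1, 3, 9), seed = 42),
               selectDelta(toy$X, toy$y, grid = c(1, 3, 9), seed = 42))
})

test_that("degenerate inputs are rejected or repaired as documented", {
  toy <- makeToy()
  expect_error(fitKFDA(toy$X, rep("a", 30)), "2 classes")
  expect_error(fitKFDA(toy$X, c("b", rep("a", 29))), "2 samples")
  expect_warning(m <- fitKFDA(toy$X, toy$y, d = 5), "clipped")
  expect_equal(nDimensions(m), 2L)
  sm <- makeToy(n = 3)
  expect_warning(selectDelta(sm$X, sm$y, grid = c(1, 2), folds = 5),
                 "reducing folds")
})
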