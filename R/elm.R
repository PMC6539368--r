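## Extreme learning machines: random input layer, closed-form output weights
## via the SVD pseudoinverse, plus bootstrap-resampled ensemble construction
## with per-member hidden-neuron selection.

#' Bootstrap resample indices
#'
#' Uniform i.i.d. draws with replacement from `1:n`, reproducible for a fixed
#' seed; the resample has the same cardinality as the original set.
#'
#' @param n training-set size (>= 1).
#' @param seed integer seed.
#' @return integer vector of n indices in `[1, n]`.
#' @export
#' @examples
#' idx <- bootstrapSample(10, seed = 1)
#' length(unique(bootstrapSample(1e4, 1))) / 1e4  # ~ 1 - 1/e
bootstrapSample <- function(n, seed) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be a positive integer")
  withr::with_seed(as.integer(seed), sample.int(as.integer(n), replace = TRUE))
}

elmActivation <- function(name) {
  switch(name,
         sigmoid = function(x) 1 / (1 + exp(-x)),
         tanh = tanh,
         stop("unknown activation: ", name))
}

## Hidden layer output matrix H = g(X W' + b).
elmHidden <- function(X, W, b, activation) {
  g <- elmActivation(activation)
  g(sweep(X %*% t(W), 2L, b, "+"))
}

## Moore-Penrose pseudoinverse solve via SVD, relative cutoff 1e-12.
pinvSolve <- function(H, T, rcond = 1e-12) {
  sv <- svd(H)
  keep <- sv$d > rcond * sv$d[1L]
  sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% T) / sv$d[keep])
}

#' Train a single extreme learning machine
#'
#' Input weights and hidden biases are drawn uniformly from `[-1, 1]` with
#' the given seed; the hidden output matrix \eqn{H = g(XW^T + b)} uses a
#' scalar activation (logistic sigmoid by default); class labels are one-hot
#' encoded (1 for the true class, 0 elsewhere) and the output weights are the
#' least-squares solution \eqn{\beta = H^\dagger T} via the SVD
#' pseudoinverse.
#'
#' @param X n x d numeric feature matrix (finite).
#' @param y length-n class labels.
#' @param L number of hidden neurons (>= 1).
#' @param seed integer seed for the random input layer.
#' @param activation `"sigmoid"` (default) or `"tanh"`.
#' @param classes optional fixed class-label order; defaults to
#'   `sort(unique(y))`.
#' @return an [ELMModel-class].
#' @export
trainELM <- function(X, y, L, seed, activation = "sigmoid", classes = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  stopifnot(L >= 1, nrow(X) >= 1, nrow(X) == length(y))
  if (!all(is.finite(X))) stop("non-finite features")
  if (is.null(classes)) classes <- sort(unique(y))
  L <- as.integer(L)
  seed <- as.integer(seed)
  d <- ncol(X)
  wb <- withr::with_seed(seed, stats::runif(L * d + L, -1, 1))
  W <- matrix(wb[seq_len(L * d)], nrow = L, ncol = d)
  b <- wb[L * d + seq_len(L)]
  H <- elmHidden(X, W, b, activation)
  Tm <- outer(y, classes, "==") * 1
  beta <- pinvSolve(H, Tm)
  methods::new("ELMModel",
    inputWeights = W, biases = b, outputWeights = beta,
    activation = activation, hiddenCount = L,
    classList = classes, seed = seed)
}

#' Predict with an extreme learning machine
#'
#' Scores are \eqn{g(XW^T + b)\beta}; the label is the argmax over classes,
#' ties resolved to the lexicographically first class. With
#' `type = "scores"` the raw score matrix is returned; `type = "prob"`
#' applies a softmax over the scores for probability-style reporting.
#'
#' @param object an [ELMModel-class].
#' @param newdata M x d numeric matrix.
#' @param type `"label"` (default), `"scores"` or `"prob"`.
#' @return character vector of labels, or an M x m numeric matrix.
#' @export
setMethod("predict", "ELMModel",
          function(object, newdata, type = c("label", "scores", "prob")) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (ncol(X) != ncol(object@inputWeights))
    stop("newdata has ", ncol(X), " columns; model expects ",
         ncol(object@inputWeights))
  S <- elmHidden(X, object@inputWeights, object@biases,
                 object@activation) %*% object@outputWeights
  colnames(S) <- object@classList
  if (type == "scores") return(S)
  if (type == "prob") {
    E <- exp(S - apply(S, 1L, max))
    return(E / rowSums(E))
  }
  ## classList is sorted, so the first maximal column is the
  ## lexicographically first tied class
  object@classList[max.col(S, ties.method = "first")]
})

#' Choose the hidden-neuron count by training accuracy
#'
#' Trains one ELM per candidate L (with a deterministic per-candidate seed
#' offset) and returns the candidate with the highest training accuracy;
#' ties go to the smallest L.
#'
#' @param X,y training data.
#' @param candidates integer vector of candidate hidden counts (default
#'   `5:30`).
#' @param seed integer base seed; candidate i uses `seed + i - 1`.
#' @param activation,classes passed to [trainELM()].
#' @return the chosen L (integer).
#' @export
chooseHiddenCount <- function(X, y, candidates = 5:30, seed = 1,
                              activation = "sigmoid", classes = NULL) {
  stopifnot(length(candidates) >= 1)
  y <- as.character(y)
  acc <- vapply(seq_along(candidates), function(i) {
    m <- trainELM(X, y, candidates[i], seed = seed + i - 1L,
                  activation = activation, classes = classes)
    mean(predict(m, X) == y)
  }, numeric(1))
  ord <- order(-acc, candidates)
  as.integer(candidates[ord[1L]])
}

#' Build a bootstrap-trained ELM ensemble
#'
#' For each of the T members: draw a bootstrap resample of the training rows
#' (same cardinality, member-specific derived seed), pick the hidden-neuron
#' count on the resampled set with [chooseHiddenCount()], and train the
#' member on the resample. Per-member seeds are `seed + t`, so any single
#' member is reproducible in isolation.
#'
#' @param X,y training data.
#' @param T number of base classifiers (default 20).
#' @param seed master integer seed.
#' @param candidates hidden-count candidates (default `5:30`).
#' @param activation scalar hidden activation name.
#' @param classes optional fixed class order shared by all members.
#' @return an [ELMEnsemble-class].
#' @export
buildEnsemble <- function(X, y, T = 20, seed = 1, candidates = 5:30,
                          activation = "sigmoid", classes = NULL) {
  stopifnot(T >= 1)
  X <- as.matrix(X)
  y <- as.character(y)
  if (is.null(classes)) classes <- sort(unique(y))
  n <- nrow(X)
  members <- vector("list", T)
  bseeds <- integer(T)
  bidx <- vector("list", T)
  tracc <- numeric(T)
  for (t in seq_len(T)) {
    st <- as.integer(seed) + t
    bseeds[t] <- st
    idx <- bootstrapSample(n, st)
    bidx[[t]] <- idx
    Xb <- X[idx, , drop = FALSE]
    yb <- y[idx]
    L <- chooseHiddenCount(Xb, yb, candidates = candidates,
                           seed = st * 131L, activation = activation,
                           classes = classes)
    m <- trainELM(Xb, yb, L, seed = st * 131L + match(L, candidates) - 1L,
                  activation = activation, classes = classes)
    members[[t]] <- m
    tracc[t] <- mean(predict(m, Xb) == yb)
  }
  methods::new("ELMEnsemble",
    members = members, bootstrapSeeds = bseeds, bootstrapIndices = bidx,
    trainAccuracy = tracc, masterSeed = as.integer(seed))
}

#' Per-member predictions of an ensemble
#'
#' @param ensemble an [ELMEnsemble-class].
#' @param newdata M x d numeric matrix.
#' @return T x M character matrix; row t holds member t's labels.
#' @export
predictMembers <- function(ensemble, newdata) {
  t(vapply(ensemble@members, function(m) predict(m, newdata),
           character(nrow(as.matrix(newdata)))))
}
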