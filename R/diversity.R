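## Ensemble diversity measures (pairwise disagreement, Cunningham entropy,
## coincident failure diversity), the combined-theta greedy ranking of base
## classifiers, and majority-vote fusion.

#' Correctness matrix of an ensemble on a validation set
#'
#' Binary T x N matrix: entry (t, i) is 1 iff member t labels validation
#' sample i correctly. All three diversity measures are functions of this
#' matrix only.
#'
#' @param ensemble an [ELMEnsemble-class] (or a T x N character matrix of
#'   per-member predicted labels).
#' @param Xval M x d validation features (ignored when predictions are given
#'   directly).
#' @param yval length-M true labels.
#' @return binary T x N matrix (rows: classifiers).
#' @export
correctnessMatrix <- function(ensemble, Xval, yval) {
  preds <- if (methods::is(ensemble, "ELMEnsemble")) {
    if (length(ensemble) == 0L) stop("empty ensemble")
    predictMembers(ensemble, Xval)
  } else {
    as.matrix(ensemble)
  }
  if (nrow(preds) < 1L) stop("empty ensemble")
  stopifnot(ncol(preds) == length(yval))
  (preds == matrix(yval, nrow(preds), length(yval), byrow = TRUE)) * 1L
}

checkBinary <- function(v) {
  stopifnot(is.numeric(v), all(v %in% c(0, 1)))
}

#' Pairwise disagreement measure
#'
#' Fraction of samples on which the two classifiers' correctness differs:
#' \eqn{(N^{01} + N^{10}) / (N^{00} + N^{01} + N^{10} + N^{11})}. Symmetric,
#' in `[0, 1]`.
#'
#' @param ci,ck binary correctness vectors of equal length.
#' @return scalar in `[0, 1]`.
#' @export
#' @examples
#' disagreementPair(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 0.5
disagreementPair <- function(ci, ck) {
  if (length(ci) != length(ck)) stop("correctness vectors differ in length")
  checkBinary(ci); checkBinary(ck)
  mean(ci != ck)
}

subsetRows <- function(C, subset) {
  C <- as.matrix(C)
  if (is.null(subset)) subset <- seq_len(nrow(C))
  C[subset, , drop = FALSE]
}

#' Average pairwise disagreement of a classifier subset
#'
#' Mean of [disagreementPair()] over all unordered pairs:
#' \eqn{\frac{2}{L(L-1)} \sum_{i<k} Dis_{ik}}. A singleton (or empty) subset
#' has no pairs; its diversity is defined as 0 (with a warning) so the
#' greedy ranking's bookkeeping is total.
#'
#' @param C binary T x N correctness matrix.
#' @param subset row indices of the subset (default: all rows).
#' @return scalar in `[0, 1]`.
#' @export
disagreementAvg <- function(C, subset = NULL) {
  M <- subsetRows(C, subset)
  L <- nrow(M)
  if (L < 2) {
    warning("diversity of a subset with fewer than 2 classifiers is 0")
    return(0)
  }
  tot <- 0
  for (i in seq_len(L - 1L)) for (k in (i + 1L):L)
    tot <- tot + mean(M[i, ] != M[k, ])
  2 * tot / (L * (L - 1))
}

#' Cunningham entropy of a classifier subset
#'
#' With \eqn{l(x_i)} the number of subset classifiers correct on sample i:
#' \eqn{Ent = \frac{1}{N} \sum_i \frac{\min(l(x_i), L - l(x_i))}
#' {L - \lceil L/2 \rceil}}. 0 when the subset is unanimous on every sample,
#' 1 at the most even achievable splits.
#'
#' @inheritParams disagreementAvg
#' @return scalar in `[0, 1]`.
#' @export
entropyMeasure <- function(C, subset = NULL) {
  M <- subsetRows(C, subset)
  L <- nrow(M)
  if (L < 2) {
    warning("diversity of a subset with fewer than 2 classifiers is 0")
    return(0)
  }
  l <- colSums(M)
  mean(pmin(l, L - l)) / (L - ceiling(L / 2))
}

#' Coincident failure diversity of a classifier subset
#'
#' With \eqn{P_i} the fraction of samples on which exactly i of the L subset
#' classifiers fail (and \eqn{P_0} the no-failure fraction):
#' \deqn{CFD = 0 \text{ if } P_0 = 1, \quad
#'   \frac{1}{1 - P_0} \sum_{i=1}^{L} \frac{L - i}{L - 1} P_i
#'   \text{ otherwise.}}
#' 1 when failures never coincide, 0 when all classifiers always fail
#' together.
#'
#' @inheritParams disagreementAvg
#' @return scalar in `[0, 1]`.
#' @export
cfd <- function(C, subset = NULL) {
  M <- subsetRows(C, subset)
  L <- nrow(M)
  if (L < 2) {
    warning("diversity of a subset with fewer than 2 classifiers is 0")
    return(0)
  }
  fails <- L - colSums(M)
  P0 <- mean(fails == 0)
  if (P0 >= 1) return(0)
  Pi <- vapply(seq_len(L), function(i) mean(fails == i), numeric(1))
  sum((L - seq_len(L)) / (L - 1) * Pi) / (1 - P0)
}

#' Combined diversity theta of a classifier subset
#'
#' \eqn{\theta = Dis_{av} + Ent + CFD}, the sum of the three set-level
#' measures; bounded in `[0, 3]`, 0 for identical classifiers.
#'
#' @inheritParams disagreementAvg
#' @return scalar in `[0, 3]`.
#' @export
combinedTheta <- function(C, subset = NULL) {
  disagreementAvg(C, subset) + entropyMeasure(C, subset) + cfd(C, subset)
}

#' Greedy diversity ranking of base classifiers
#'
#' Rank 1 is the classifier with the highest validation accuracy (its
#' recorded diversity is 0); thereafter the candidate e maximizing the
#' combined diversity \eqn{\theta(D \cup \{e\})} of the accumulated set D is
#' appended, with its theta-at-selection recorded. Ties at any step go to
#' the lowest classifier index. The result is a full permutation and is
#' deterministic for a fixed correctness matrix.
#'
#' @param C binary T x N correctness matrix.
#' @param valAccuracies length-T validation accuracies (used only to seed
#'   rank 1; defaults to the row means of `C`).
#' @return a data.frame with columns `classifier` (original row index),
#'   `rank`, `theta` (theta at selection; 0 for rank 1) and `valAccuracy`.
#' @export
rankClassifiers <- function(C, valAccuracies = NULL) {
  C <- as.matrix(C)
  T <- nrow(C)
  stopifnot(T >= 1)
  if (is.null(valAccuracies)) valAccuracies <- rowMeans(C)
  stopifnot(length(valAccuracies) == T)
  seedIdx <- which.max(valAccuracies)  # first max = lowest index on ties
  sel <- seedIdx
  theta <- 0
  remaining <- setdiff(seq_len(T), seedIdx)
  while (length(remaining) > 0L) {
    th <- vapply(remaining, function(e)
      suppressWarnings(combinedTheta(C, c(sel, e))), numeric(1))
    best <- remaining[order(-th, remaining)[1L]]
    sel <- c(sel, best)
    theta <- c(theta, th[match(best, remaining)])
    remaining <- setdiff(remaining, best)
  }
  data.frame(classifier = sel, rank = seq_len(T), theta = theta,
             valAccuracy = valAccuracies[sel])
}

#' Top-n classifiers of a diversity ranking
#'
#' @param ranking a data.frame from [rankClassifiers()].
#' @param n number of classifiers to keep, `1 <= n <= T`.
#' @return integer vector of classifier indices in rank order.
#' @export
selectTopN <- function(ranking, n) {
  T <- nrow(ranking)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n > T)
    stop("n must be in [1, ", T, "]")
  ranking$classifier[seq_len(as.integer(n))]
}

#' Majority-vote fusion of selected base classifiers
#'
#' Per sample, the class with the most votes among the selected classifiers
#' wins; when several classes tie, the vote of the highest-ranked selected
#' classifier whose vote is among the tied classes decides.
#'
#' @param predictions T x N character matrix of per-classifier labels.
#' @param selected ordered classifier indices (rank order; at least one).
#' @return length-N character vector of fused labels.
#' @export
#' @examples
#' p <- rbind(c("W", "R"), c("W", "W"), c("R", "R"))
#' majorityVote(p, selected = 1:3)
majorityVote <- function(predictions, selected) {
  predictions <- as.matrix(predictions)
  if (length(selected) < 1L) stop("no selected classifiers")
  P <- predictions[selected, , drop = FALSE]
  apply(P, 2L, function(v) {
    tab <- table(v)
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) return(top)
    v[v %in% top][1L]  # rows are in rank order
  })
}
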