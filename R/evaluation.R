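## Confusion matrices, accuracy/recall metrics, the leave-one-subject-out
## protocol, and the fused-all / selected-n / random-n strategy comparison.

#' Confusion matrix
#'
#' Rows are true classes, columns predicted classes, in the order given by
#' `classes` (default [activityClasses()] when all labels belong to it,
#' otherwise the sorted label union).
#'
#' @param yTrue,yPred equal-length label vectors.
#' @param classes class order for rows/columns.
#' @return C x C integer matrix with dimnames.
#' @export
confusionCounts <- function(yTrue, yPred, classes = NULL) {
  yTrue <- as.character(yTrue); yPred <- as.character(yPred)
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  if (is.null(classes)) {
    u <- unique(c(yTrue, yPred))
    classes <- if (all(u %in% activityClasses())) activityClasses()
               else sort(u)
  }
  if (!all(c(yTrue, yPred) %in% classes))
    stop("labels outside the class list")
  table(factor(yTrue, levels = classes),
        factor(yPred, levels = classes)) |>
    unclass() |> as.matrix()
}

#' Accuracy and recall metrics from a confusion matrix
#'
#' Per class c: TP is the diagonal cell, FN the rest of the row, FP the rest
#' of the column, TN the remainder. Reports per-class one-vs-rest accuracy
#' \eqn{(TP + TN) / (TP + TN + FP + FN)} and recall \eqn{TP / (TP + FN)},
#' their macro averages, and the overall accuracy trace/total. Classes with
#' an empty true row have undefined recall and are excluded from the macro
#' averages with a warning.
#'
#' @param cm a square counts matrix from [confusionCounts()].
#' @return list with `overallAccuracy`, `macroAccuracy`, `macroRecall`, and
#'   `perClass` (data.frame of TP/TN/FP/FN, accuracy, recall).
#' @export
classificationMetrics <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm), all(cm >= 0))
  if (is.null(rownames(cm)))
    rownames(cm) <- colnames(cm) <-
      if (!is.null(colnames(cm))) colnames(cm)
      else as.character(seq_len(nrow(cm)))
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix")
  TP <- diag(cm)
  FN <- rowSums(cm) - TP
  FP <- colSums(cm) - TP
  TN <- total - TP - FN - FP
  rec <- TP / (TP + FN)
  acc <- (TP + TN) / total
  present <- rowSums(cm) > 0
  if (any(!present))
    warning("recall undefined for empty class(es): ",
            paste(rownames(cm)[!present], collapse = ", "))
  list(
    overallAccuracy = sum(TP) / total,
    macroAccuracy = mean(acc[present]),
    macroRecall = mean(rec[present]),
    perClass = data.frame(class = rownames(cm), TP = TP, TN = TN, FP = FP,
                          FN = FN, accuracy = acc, recall = rec,
                          row.names = NULL)
  )
}

## Stratified train/validation split of window indices; returns logical
## "is validation" vector.
stratifiedHoldout <- function(y, fraction, seed) {
  val <- logical(length(y))
  withr::with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      k <- max(1L, round(length(idx) * fraction))
      val[sample(idx, k)] <- TRUE
    }
  })
  val
}

#' Leave-one-subject-out evaluation of the full pipeline
#'
#' For each held-out subject: features of the remaining subjects are split
#' into training and validation windows (stratified by class); the RBF width
#' is chosen by cross-validation on the training windows; KFDA is fitted on
#' the training windows and all sets are projected; a bootstrap ELM ensemble
#' is built on the projected training windows; members are ranked on the
#' validation windows by the combined diversity criterion; the top-n members
#' are fused by majority vote on the held-out subject's windows.
#'
#' @param recordings list of [AccelRecording-class], one (or more) per
#'   subject; at least 2 distinct subjects.
#' @param config a [runConfig()] list.
#' @return list with `folds` (per-subject results: test metrics of the
#'   selected-n ensemble, ranking, member predictions and accuracies) and
#'   `mean` (mean overall accuracy and macro recall of selected-n across
#'   folds).
#' @export
losoEvaluate <- function(recordings, config = runConfig()) {
  feats <- extractFeatures(recordings, windowLen = config$windowLen,
                           overlap = config$overlap)
  subjects <- unique(feats$subjects)
  if (length(subjects) < 2) stop("need at least 2 subjects")
  classes <- sort(unique(feats$labels))
  folds <- list()
  for (s in subjects) {
    test <- feats$subjects == s
    if (!any(test)) {
      warning("subject ", s, " has no windows; fold skipped")
      next
    }
    fseed <- as.integer(config$masterSeed) + match(s, subjects) * 1000L
    Xrest <- feats$features[!test, , drop = FALSE]
    yrest <- feats$labels[!test]
    isVal <- stratifiedHoldout(yrest, config$valFraction, fseed)
    Xtr <- Xrest[!isVal, , drop = FALSE]; ytr <- yrest[!isVal]
    Xva <- Xrest[isVal, , drop = FALSE]; yva <- yrest[isVal]
    Xte <- feats$features[test, , drop = FALSE]
    yte <- feats$labels[test]

    grid <- 2^config$deltaGridPowers * medianHeuristic(scale(Xtr))
    delta <- selectDelta(Xtr, ytr, grid = grid, folds = config$cvFolds,
                         seed = fseed + 1L, sigma = config$sigma)
    kf <- fitKFDA(Xtr, ytr, delta = delta, sigma = config$sigma)
    Ptr <- projectFeatures(kf, Xtr)
    Pva <- projectFeatures(kf, Xva)
    Pte <- projectFeatures(kf, Xte)

    ens <- buildEnsemble(Ptr, ytr, T = config$T, seed = fseed + 2L,
                         candidates = config$hiddenCandidates,
                         classes = classes)
    valPreds <- predictMembers(ens, Pva)
    C <- correctnessMatrix(valPreds, yval = yva)
    valAcc <- rowMeans(C)
    ranking <- rankClassifiers(C, valAcc)
    sel <- selectTopN(ranking, min(config$nSelect, config$T))
    testPreds <- predictMembers(ens, Pte)
    fused <- majorityVote(testPreds, sel)
    cm <- confusionCounts(yte, fused, classes = classes)
    met <- classificationMetrics(cm)
    folds[[s]] <- list(subject = s, delta = delta, ranking = ranking,
                       valAccuracy = valAcc, yTest = yte,
                       testPredictions = testPreds, selected = sel,
                       fusedPredictions = fused, confusion = cm,
                       metrics = met,
                       memberTestAccuracy = rowMeans(
                         correctnessMatrix(testPreds, yval = yte)))
  }
  if (!length(folds)) stop("no evaluable folds")
  list(folds = folds,
       mean = c(
         overallAccuracy = mean(vapply(folds, function(f)
           f$metrics$overallAccuracy, numeric(1))),
         macroRecall = mean(vapply(folds, function(f)
           f$metrics$macroRecall, numeric(1)))))
}

## Fuse a fixed selection on every fold and average overall accuracy /
## macro recall; selection is given per fold as ordered indices.
fuseFolds <- function(folds, selections, classes) {
  accs <- numeric(0); recs <- numeric(0)
  for (i in seq_along(folds)) {
    f <- folds[[i]]
    fused <- majorityVote(f$testPredictions, selections[[i]])
    met <- suppressWarnings(
      classificationMetrics(confusionCounts(f$yTest, fused, classes)))
    accs <- c(accs, met$overallAccuracy)
    recs <- c(recs, met$macroRecall)
  }
  c(accuracy = mean(accs), recall = mean(recs))
}

#' Compare fuse-all, diversity-selected and random selection strategies
#'
#' Runs [losoEvaluate()] once, then fuses three member subsets on identical
#' folds: all T members, the diversity-ranked top n, and `randomDraws`
#' random n-subsets (averaged; each draw is ordered by validation accuracy
#' for tie-breaking).
#'
#' @param recordings,config as in [losoEvaluate()].
#' @return list with `table` (strategy x accuracy/recall data.frame, on the
#'   0-1 scale), `meanSingleAccuracy` (mean member test accuracy), and the
#'   underlying `loso` result.
#' @export
compareStrategies <- function(recordings, config = runConfig()) {
  loso <- losoEvaluate(recordings, config)
  folds <- loso$folds
  classes <- sort(unique(unlist(lapply(folds, `[[`, "yTest"))))
  T <- config$T
  n <- min(config$nSelect, T)

  fuseAll <- fuseFolds(folds, lapply(folds, function(f)
    f$ranking$classifier), classes)
  selected <- fuseFolds(folds, lapply(folds, function(f)
    selectTopN(f$ranking, n)), classes)
  randAcc <- matrix(0, config$randomDraws, 2)
  for (r in seq_len(config$randomDraws)) {
    sels <- lapply(seq_along(folds), function(i) {
      f <- folds[[i]]
      ids <- withr::with_seed(
        as.integer(config$masterSeed) + 5000L + r * 97L + i,
        sample(seq_len(T), n))
      ids[order(-f$valAccuracy[ids], ids)]
    })
    randAcc[r, ] <- fuseFolds(folds, sels, classes)
  }
  random <- colMeans(randAcc)
  tab <- data.frame(
    strategy = c("fuse-all", "selected-n", "random-n"),
    n = c(T, n, n),
    accuracy = c(fuseAll["accuracy"], selected["accuracy"], random[1L]),
    recall = c(fuseAll["recall"], selected["recall"], random[2L]),
    row.names = NULL)
  meanSingle <- mean(unlist(lapply(folds, `[[`, "memberTestAccuracy")))
  list(table = tab, meanSingleAccuracy = meanSingle,
       randomDrawAccuracy = randAcc[, 1L], loso = loso)
}
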