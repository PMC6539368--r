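## Desk-scale end-to-end experiment: simulate a multi-subject scenario and
## run the leave-one-subject-out strategy comparison. The default problem
## size (10 subjects, one 6-second bout per activity, a 3-point RBF width
## grid with 3-fold CV) keeps a full run to seconds while preserving the
## study design shape: 8 activities, confusable dynamic classes, T = 20
## bootstrap members, top-11 selection.

#' Run the end-to-end comparison experiment on simulated data
#'
#' Simulates `nSubjects` subjects, then runs [compareStrategies()] under a
#' leave-one-subject-out protocol with T bootstrap ELM members per fold,
#' diversity-ranked selection of the top n, and the random-selection
#' baseline.
#'
#' @param seed master integer seed (drives the generator and every
#'   downstream stage).
#' @param nSubjects number of simulated subjects (default 10).
#' @param trials activity-sequence repetitions (default 1).
#' @param boutSeconds bout length in seconds (default 6, i.e. 5 windows per
#'   activity per trial).
#' @param T,nSelect ensemble size and selection size (defaults 20, 11).
#' @param randomDraws random-baseline repetitions (default 25).
#' @param deltaGridPowers,cvFolds RBF width search (defaults `-1:1`, 3).
#' @return the [compareStrategies()] result, plus a `summary` numeric
#'   vector with the headline accuracies on the 0-1 scale.
#' @export
runComparisonExperiment <- function(seed = 1, nSubjects = 10, trials = 1,
                                    boutSeconds = 6, T = 20, nSelect = 11,
                                    randomDraws = 25,
                                    deltaGridPowers = -1:1, cvFolds = 3) {
  recs <- simulateScenario(nSubjects = nSubjects, trials = trials,
                           boutSeconds = boutSeconds, seed = seed)
  config <- runConfig(T = T, nSelect = nSelect, randomDraws = randomDraws,
                      deltaGridPowers = deltaGridPowers, cvFolds = cvFolds,
                      masterSeed = seed)
  res <- compareStrategies(recs, config)
  tab <- res$table
  res$summary <- c(
    selectedAccuracy = tab$accuracy[tab$strategy == "selected-n"],
    selectedRecall = tab$recall[tab$strategy == "selected-n"],
    fuseAllAccuracy = tab$accuracy[tab$strategy == "fuse-all"],
    fuseAllRecall = tab$recall[tab$strategy == "fuse-all"],
    randomAccuracy = tab$accuracy[tab$strategy == "random-n"],
    randomRecall = tab$recall[tab$strategy == "random-n"],
    meanSingleAccuracy = res$meanSingleAccuracy)
  res
}
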