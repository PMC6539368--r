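## Run configuration and the command-style entry points wrapped by the
## Rscript wrappers under inst/cli/. All randomness fans out from a single
## master seed; resolved parameters are echoed to a log file next to the
## outputs.

#' Pipeline run configuration
#'
#' All tunables in one list, every field overridable. Defaults: 300-sample
#' windows with 50% overlap at 150 Hz; 20 base classifiers with hidden
#' neurons chosen from 5-30; top-11 selection; ridge 1e-7; RBF width grid
#' `2^powers * median heuristic` with 5-fold CV; 20% stratified validation
#' holdout within each training split.
#'
#' @param windowLen window length in samples.
#' @param overlap window overlap fraction.
#' @param rate sampling rate in Hz.
#' @param T number of base classifiers.
#' @param nSelect number of classifiers fused after ranking.
#' @param hiddenCandidates candidate hidden-neuron counts.
#' @param sigma KFDA ridge regularizer.
#' @param deltaGridPowers RBF width grid as powers of two times the median
#'   heuristic.
#' @param cvFolds folds for the width cross-validation.
#' @param valFraction stratified validation holdout fraction.
#' @param randomDraws repeat draws for the random-selection baseline.
#' @param masterSeed master integer seed.
#' @return named list.
#' @export
runConfig <- function(windowLen = 300, overlap = 0.5, rate = 150, T = 20,
                      nSelect = 11, hiddenCandidates = 5:30, sigma = 1e-7,
                      deltaGridPowers = -3:3, cvFolds = 5,
                      valFraction = 0.2, randomDraws = 25, masterSeed = 1) {
  list(windowLen = windowLen, overlap = overlap, rate = rate, T = T,
       nSelect = nSelect, hiddenCandidates = hiddenCandidates,
       sigma = sigma, deltaGridPowers = deltaGridPowers, cvFolds = cvFolds,
       valFraction = valFraction, randomDraws = randomDraws,
       masterSeed = masterSeed)
}

#' Read a flat key=value config file into a runConfig
#'
#' Lines of the form `key = value`; vector values are comma-separated;
#' unknown keys are an error. Missing keys keep their defaults.
#'
#' @param path config file path.
#' @return a [runConfig()] list.
#' @export
readConfigFile <- function(path) {
  cfg <- runConfig()
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("bad config line: ", ln)
    key <- trimws(kv[1L])
    if (!key %in% names(cfg)) stop("unknown config key: ", key)
    val <- as.numeric(strsplit(trimws(kv[2L]), ",")[[1L]])
    cfg[[key]] <- val
  }
  cfg
}

logParams <- function(params, path) {
  writeLines(vapply(names(params), function(k)
    paste0(k, " = ", paste(params[[k]], collapse = ",")), character(1)),
    path)
}

#' Simulate a scenario and write recording CSVs
#'
#' Writes one `<subject>.csv` recording file per simulated subject plus a
#' `simulate_log.txt` with all resolved parameters. Bit-identical for a
#' fixed seed.
#'
#' @param outDir output directory (created if missing).
#' @param nSubjects,trials,boutSeconds,seed scenario parameters (see
#'   [simulateScenario()]).
#' @param rate sampling rate.
#' @return invisibly, the written file paths.
#' @export
cmdSimulate <- function(outDir, nSubjects = 10, trials = 5,
                        boutSeconds = 20, rate = 150, seed = 1) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  recs <- simulateScenario(nSubjects = nSubjects, trials = trials,
                           boutSeconds = boutSeconds, rate = rate,
                           seed = seed)
  paths <- vapply(recs, function(r) {
    p <- file.path(outDir, paste0(r@subject, ".csv"))
    writeRecordingCSV(r, p)
    p
  }, character(1))
  logParams(list(nSubjects = nSubjects, trials = trials,
                 boutSeconds = boutSeconds, rate = rate, seed = seed),
            file.path(outDir, "simulate_log.txt"))
  invisible(paths)
}

#' Run the full pipeline on recording CSVs and write reports
#'
#' Reads every `*.csv` recording in `inDir`, runs the leave-one-subject-out
#' strategy comparison, and writes: `metrics.csv` (strategy table),
#' `metrics.txt` (human-readable summary), per-fold confusion matrices
#' (`confusion_<subject>.csv`), per-fold ranking reports
#' (`ranking_<subject>.csv`) and `run_log.txt` with the resolved
#' configuration. Reruns with the same master seed reproduce the outputs
#' exactly.
#'
#' @param inDir directory of recording CSVs.
#' @param outDir output directory.
#' @param config a [runConfig()] list.
#' @return invisibly, the [compareStrategies()] result.
#' @export
cmdRun <- function(inDir, outDir, config = runConfig()) {
  files <- list.files(inDir, pattern = "\\.csv$", full.names = TRUE)
  files <- files[!grepl("log", files)]
  if (!length(files)) stop("no recording CSVs in ", inDir)
  recs <- unlist(lapply(files, readRecordingCSV, rate = config$rate),
                 recursive = FALSE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  res <- compareStrategies(recs, config)
  utils::write.csv(res$table, file.path(outDir, "metrics.csv"),
                   row.names = FALSE, quote = FALSE)
  for (f in res$loso$folds) {
    utils::write.csv(f$confusion,
                     file.path(outDir, paste0("confusion_", f$subject,
                                              ".csv")))
    writeRankingCSV(f$ranking,
                    file.path(outDir, paste0("ranking_", f$subject,
                                             ".csv")))
  }
  con <- file(file.path(outDir, "metrics.txt"), "w")
  writeLines(c(
    sprintf("Leave-one-subject-out over %d subjects",
            length(res$loso$folds)),
    sprintf("%-12s n=%2d  accuracy %6.2f%%  recall %6.2f%%",
            res$table$strategy, res$table$n, 100 * res$table$accuracy,
            100 * res$table$recall),
    sprintf("mean single-member accuracy %6.2f%%",
            100 * res$meanSingleAccuracy)), con)
  close(con)
  logParams(config, file.path(outDir, "run_log.txt"))
  invisible(res)
}

#' Rank classifiers from a correctness-matrix CSV
#'
#' Reads a T x N binary correctness CSV (no header) and an optional
#' one-column validation-accuracy CSV, writes the ranking report, and
#' returns the ranking.
#'
#' @param correctnessCSV path to the binary matrix CSV.
#' @param outPath output ranking CSV path.
#' @param accuraciesCSV optional path to per-classifier validation
#'   accuracies (one per line); defaults to correctness row means.
#' @return the ranking data.frame, invisibly.
#' @export
cmdRank <- function(correctnessCSV, outPath, accuraciesCSV = NULL) {
  C <- as.matrix(utils::read.csv(correctnessCSV, header = FALSE))
  acc <- if (is.null(accuraciesCSV)) NULL
         else as.numeric(readLines(accuraciesCSV))
  ranking <- rankClassifiers(C, acc)
  writeRankingCSV(ranking, outPath)
  invisible(ranking)
}
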