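## Plain-text I/O: recording CSVs, feature tables, ranking reports, and
## flat-file model serialization with bit-exact numeric round-trips
## (numbers are written with 17 significant digits, which round-trips
## IEEE doubles exactly).

fmtNum <- function(x) sprintf("%.17g", x)

#' Read / write recording CSVs
#'
#' The recording format has one row per sample with header
#' `subject,activity,t,ax,ay,az`. A file may contain several subjects;
#' `readRecordingCSV()` returns one [AccelRecording-class] per subject.
#'
#' @param path CSV file path.
#' @param rate sampling rate to attach (default 150).
#' @return list of [AccelRecording-class].
#' @export
readRecordingCSV <- function(path, rate = 150) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "activity", "t", "ax", "ay", "az")
  if (!all(need %in% names(df)))
    stop("recording CSV must have columns ", paste(need, collapse = ","))
  lapply(split(df, df$subject), function(d) {
    d <- d[order(d$t), ]
    AccelRecording(d$subject[1L], as.matrix(d[, c("ax", "ay", "az")]),
                   d$activity, rate = rate)
  })
}

#' @rdname readRecordingCSV
#' @param recording an [AccelRecording-class].
#' @export
writeRecordingCSV <- function(recording, path) {
  n <- length(recording)
  df <- data.frame(
    subject = recording@subject,
    activity = recording@labels,
    t = (seq_len(n) - 1L) / recording@rate,
    ax = recording@samples[, 1L],
    ay = recording@samples[, 2L],
    az = recording@samples[, 3L])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a feature table CSV
#'
#' 43 named feature columns plus `label` and `subject`.
#'
#' @param feats result of [extractFeatures()].
#' @param path output path.
#' @export
writeFeatureCSV <- function(feats, path) {
  df <- as.data.frame(feats$features)
  df$label <- feats$labels
  df$subject <- feats$subjects
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a diversity-ranking report CSV
#'
#' Columns: classifier id, rank, theta at selection, validation accuracy.
#'
#' @param ranking data.frame from [rankClassifiers()].
#' @param path output path.
#' @export
writeRankingCSV <- function(ranking, path) {
  utils::write.csv(ranking, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## --- KFDA model serialization: single flat text file -----------------------

#' Save / load a KFDA model as a flat text file
#'
#' A single self-describing text file: `key value` header lines (kernel,
#' delta, sigma, d, classes, standardization parameters) followed by the
#' dual coefficients and support samples, all numerics at 17 significant
#' digits so the round-trip is bit-exact.
#'
#' @param model a [KFDAModel-class].
#' @param path file path.
#' @return `loadKFDAModel()` returns the reconstructed [KFDAModel-class].
#' @export
saveKFDAModel <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste(...), con)
  wl("kfda_model 1")
  wl("kernel", model@kernel)
  wl("delta", fmtNum(model@delta))
  wl("sigma", fmtNum(model@sigma))
  wl("d", model@d)
  wl("classes", paste(model@classList, collapse = ","))
  wl("standardize", as.integer(length(model@center) > 0))
  if (length(model@center)) {
    wl("center", paste(fmtNum(model@center), collapse = ","))
    wl("scale", paste(fmtNum(model@scale), collapse = ","))
  }
  wl("eigenvalues", paste(fmtNum(model@eigenvalues), collapse = ","))
  wl("dims", nrow(model@supportSamples), ncol(model@supportSamples))
  wl("alpha")
  utils::write.table(matrix(fmtNum(model@alpha), nrow(model@alpha)), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  wl("support")
  utils::write.table(
    matrix(fmtNum(model@supportSamples), nrow(model@supportSamples)), con,
    row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname saveKFDAModel
#' @export
loadKFDAModel <- function(path) {
  lines <- readLines(path)
  if (lines[1L] != "kfda_model 1") stop("not a KFDA model file")
  kv <- function(key) {
    ln <- lines[startsWith(lines, paste0(key, " "))][1L]
    sub(paste0("^", key, " "), "", ln)
  }
  std <- kv("standardize") == "1"
  dims <- as.integer(strsplit(kv("dims"), " ")[[1L]])
  d <- as.integer(kv("d"))
  ia <- which(lines == "alpha")
  is <- which(lines == "support")
  parseBlock <- function(from, nr, nc)
    matrix(as.numeric(unlist(strsplit(lines[from + seq_len(nr)], " "))),
           nrow = nr, ncol = nc, byrow = TRUE)
  methods::new("KFDAModel",
    supportSamples = parseBlock(is, dims[1L], dims[2L]),
    alpha = parseBlock(ia, dims[1L], d),
    eigenvalues = as.numeric(strsplit(kv("eigenvalues"), ",")[[1L]]),
    delta = as.numeric(kv("delta")),
    sigma = as.numeric(kv("sigma")),
    d = d,
    kernel = kv("kernel"),
    classList = strsplit(kv("classes"), ",")[[1L]],
    center = if (std) as.numeric(strsplit(kv("center"), ",")[[1L]])
             else numeric(0),
    scale = if (std) as.numeric(strsplit(kv("scale"), ",")[[1L]])
            else numeric(0))
}

## --- ELM ensemble serialization: directory of member files + manifest ------

saveELMModel <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste(...), con)
  wl("elm_model 1")
  wl("activation", model@activation)
  wl("L", model@hiddenCount)
  wl("seed", model@seed)
  wl("classes", paste(model@classList, collapse = ","))
  wl("dims", ncol(model@inputWeights), length(model@classList))
  wl("inputWeights")
  utils::write.table(matrix(fmtNum(model@inputWeights),
                            nrow(model@inputWeights)), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  wl("biases", paste(fmtNum(model@biases), collapse = ","))
  wl("outputWeights")
  utils::write.table(matrix(fmtNum(model@outputWeights),
                            nrow(model@outputWeights)), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

loadELMModel <- function(path) {
  lines <- readLines(path)
  if (lines[1L] != "elm_model 1") stop("not an ELM model file")
  kv <- function(key)
    sub(paste0("^", key, " "), "",
        lines[startsWith(lines, paste0(key, " "))][1L])
  L <- as.integer(kv("L"))
  dims <- as.integer(strsplit(kv("dims"), " ")[[1L]])
  iw <- which(lines == "inputWeights")
  ow <- which(lines == "outputWeights")
  parseBlock <- function(from, nr, nc)
    matrix(as.numeric(unlist(strsplit(lines[from + seq_len(nr)], " "))),
           nrow = nr, ncol = nc, byrow = TRUE)
  methods::new("ELMModel",
    inputWeights = parseBlock(iw, L, dims[1L]),
    biases = as.numeric(strsplit(kv("biases"), ",")[[1L]]),
    outputWeights = parseBlock(ow, L, dims[2L]),
    activation = kv("activation"),
    hiddenCount = L,
    classList = strsplit(kv("classes"), ",")[[1L]],
    seed = as.integer(kv("seed")))
}

#' Save / load an ELM ensemble as a directory of text files
#'
#' Writes `manifest.csv` (member id, bootstrap seed, hidden count, training
#' accuracy) plus one `member_###.txt` model file per base classifier and a
#' `bootstrap_###.txt` index file preserving resampling provenance.
#'
#' @param ensemble an [ELMEnsemble-class].
#' @param dir directory path (created if missing).
#' @return `loadEnsemble()` returns the reconstructed
#'   [ELMEnsemble-class].
#' @export
saveEnsemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  T <- length(ensemble)
  manifest <- data.frame(
    member = seq_len(T),
    bootstrapSeed = ensemble@bootstrapSeeds,
    hiddenCount = vapply(ensemble@members, function(m) m@hiddenCount,
                         integer(1)),
    trainAccuracy = fmtNum(ensemble@trainAccuracy),
    masterSeed = ensemble@masterSeed)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  for (t in seq_len(T)) {
    saveELMModel(ensemble@members[[t]],
                 file.path(dir, sprintf("member_%03d.txt", t)))
    writeLines(paste(ensemble@bootstrapIndices[[t]], collapse = ","),
               file.path(dir, sprintf("bootstrap_%03d.txt", t)))
  }
  invisible(dir)
}

#' @rdname saveEnsemble
#' @export
loadEnsemble <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  T <- nrow(manifest)
  members <- lapply(seq_len(T), function(t)
    loadELMModel(file.path(dir, sprintf("member_%03d.txt", t))))
  bidx <- lapply(seq_len(T), function(t)
    as.integer(strsplit(readLines(
      file.path(dir, sprintf("bootstrap_%03d.txt", t))), ",")[[1L]]))
  methods::new("ELMEnsemble",
    members = members,
    bootstrapSeeds = as.integer(manifest$bootstrapSeed),
    bootstrapIndices = bidx,
    trainAccuracy = as.numeric(manifest$trainAccuracy),
    masterSeed = as.integer(manifest$masterSeed[1L]))
}
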