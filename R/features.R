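## Sliding-window segmentation and the 43-dimensional feature vector:
## 18 per-axis time features + 1 signal magnitude area + 9 AR coefficients
## + 15 per-axis spectral features.

#' Names of the 43 window features, in matrix column order
#'
#' Layout: per-axis time features (mean, sd, max, min, mad, iqr) for x, y, z;
#' signal magnitude area (`sma`); per-axis AR(3) coefficients; per-axis
#' spectral features (mean, skewness, kurtosis, energy, entropy).
#'
#' @return character vector of length 43.
#' @export
featureNames <- function() {
  ax <- c("x", "y", "z")
  c(as.vector(t(outer(ax, c("mean", "sd", "max", "min", "mad", "iqr"),
                      paste, sep = "_"))),
    "sma",
    as.vector(t(outer(ax, paste0("ar", 1:3), paste, sep = "_"))),
    as.vector(t(outer(ax, c("fmean", "fskew", "fkurt", "fenergy", "fentropy"),
                      paste, sep = "_"))))
}

#' Segment a recording into fixed-length overlapping windows
#'
#' Windows advance by a stride of `windowLen * (1 - overlap)` samples. A
#' window is kept only when every sample in it carries the same activity
#' label; mixed-label windows (bout boundaries) and trailing partial windows
#' are dropped. A recording shorter than one window yields an empty list.
#'
#' @param recording an [AccelRecording-class].
#' @param windowLen window length in samples (default 300, i.e. 2 s at
#'   150 Hz).
#' @param overlap fraction of overlap between consecutive windows, in
#'   `[0, 1)` (default 0.5).
#' @return list of windows; each is a list with elements `data` (windowLen x
#'   3 matrix), `label` and `subject`.
#' @export
#' @examples
#' r <- AccelRecording("s1", matrix(rnorm(1800), ncol = 3), rep("W", 600))
#' length(segmentWindows(r))  # 3 windows at offsets 0, 150, 300
segmentWindows <- function(recording, windowLen = 300, overlap = 0.5) {
  stopifnot(methods::is(recording, "AccelRecording"),
            windowLen >= 2, overlap >= 0, overlap < 1)
  n <- nrow(recording@samples)
  stride <- max(1L, as.integer(round(windowLen * (1 - overlap))))
  if (n < windowLen) return(list())
  starts <- seq.int(1L, n - windowLen + 1L, by = stride)
  out <- vector("list", length(starts))
  keep <- logical(length(starts))
  for (i in seq_along(starts)) {
    idx <- starts[i]:(starts[i] + windowLen - 1L)
    lab <- recording@labels[idx]
    if (all(lab == lab[1L])) {
      keep[i] <- TRUE
      out[[i]] <- list(data = recording@samples[idx, , drop = FALSE],
                       label = lab[1L], subject = recording@subject)
    }
  }
  out[keep]
}

#' Time-domain window features
#'
#' Per axis: mean, standard deviation, maximum, minimum, median absolute
#' deviation (raw, no consistency constant) and interquartile range; plus the
#' cross-axis signal magnitude area
#' \eqn{SMA = \frac{1}{n}\sum_t (|a_x| + |a_y| + |a_z|)}.
#'
#' @param window a window as returned by [segmentWindows()], or a numeric
#'   n x 3 matrix.
#' @return named numeric vector of length 19.
#' @export
timeFeatures <- function(window) {
  d <- windowData(window)
  per <- apply(d, 2L, function(v) {
    c(mean = mean(v), sd = stats::sd(v), max = max(v), min = min(v),
      mad = stats::median(abs(v - stats::median(v))),
      iqr = stats::IQR(v))
  })
  out <- c(as.vector(per), mean(rowSums(abs(d))))
  names(out) <- c(as.vector(t(outer(c("x", "y", "z"),
                                    c("mean", "sd", "max", "min", "mad",
                                      "iqr"), paste, sep = "_"))), "sma")
  ## per is 6 x 3 (stats x axes); reorder axis-major
  out[featureNames()[1:19]]
}

#' Autoregressive window features
#'
#' Fits an AR(`order`) model per axis by the Yule-Walker method with biased
#' autocovariance estimates (the closed-form, always-stable estimator) and
#' returns the concatenated x, y, z coefficients. A zero-variance axis gets
#' zero coefficients (with a message, since there is nothing to fit).
#'
#' @param window a window or numeric n x 3 matrix.
#' @param order AR model order (default 3, giving 9 coefficients).
#' @return named numeric vector of length `3 * order`.
#' @export
arCoefficients <- function(window, order = 3) {
  d <- windowData(window)
  stopifnot(order >= 1, nrow(d) > order)
  out <- numeric(0)
  for (j in 1:3) {
    v <- d[, j]
    if (stats::var(v) < .Machine$double.eps * 100) {
      message("arCoefficients: zero-variance axis ", j,
              "; coefficients set to 0")
      cf <- rep(0, order)
    } else {
      cf <- stats::ar.yw(v, aic = FALSE, order.max = order,
                         demean = TRUE)$ar
    }
    out <- c(out, cf)
  }
  names(out) <- as.vector(t(outer(c("x", "y", "z"), paste0("ar", 1:order),
                                  paste, sep = "_")))
  out
}

## One-sided magnitude spectrum of the mean-removed signal, DC bin excluded,
## Nyquist included; n assumed even (windows are 300 samples).
onesidedSpectrum <- function(v) {
  n <- length(v)
  vc <- v - mean(v)
  Mod(stats::fft(vc))[2:(n %/% 2 + 1)]
}

#' Frequency-domain window features
#'
#' Per axis, from the one-sided magnitude spectrum of the mean-removed signal
#' (DC excluded — removing it stops the gravity offset from dominating):
#' spectral mean, skewness and kurtosis of the magnitudes; spectral energy,
#' Parseval-normalized so it equals the time-domain mean square of the
#' detrended signal (interior bins doubled, divided by n^2); and spectral
#' entropy, the Shannon entropy (natural log, 0 log 0 = 0) of the normalized
#' power spectrum. An all-zero axis yields zeros (flagged with a message).
#'
#' @param window a window or numeric n x 3 matrix (even row count).
#' @return named numeric vector of length 15.
#' @export
frequencyFeatures <- function(window) {
  d <- windowData(window)
  n <- nrow(d)
  out <- numeric(0)
  for (j in 1:3) {
    M <- onesidedSpectrum(d[, j])
    tot <- sum(M^2)
    if (tot < .Machine$double.eps * 100) {
      message("frequencyFeatures: zero signal on axis ", j,
              "; spectral features set to 0")
      f <- c(0, 0, 0, 0, 0)
    } else {
      p <- M^2 / tot
      ent <- -sum(ifelse(p > 0, p * log(p), 0))
      nyq <- M[length(M)]
      energy <- (2 * tot - nyq^2) / n^2  # Parseval: mean square of detrended v
      f <- c(mean(M), e1071::skewness(M), e1071::kurtosis(M), energy, ent)
    }
    out <- c(out, f)
  }
  names(out) <- as.vector(t(outer(c("x", "y", "z"),
                                  c("fmean", "fskew", "fkurt", "fenergy",
                                    "fentropy"), paste, sep = "_")))
  out
}

#' Full 43-dimensional feature vector of one window
#'
#' @param window a window or numeric n x 3 matrix.
#' @return named numeric vector of length 43 (see [featureNames()]).
#' @export
windowFeatures <- function(window) {
  c(timeFeatures(window), arCoefficients(window), frequencyFeatures(window))
}

#' Extract the feature matrix of a set of recordings
#'
#' Segments every recording with [segmentWindows()] and stacks the per-window
#' feature vectors. Row order follows the input recording order, windows in
#' temporal order within each recording. Deterministic.
#'
#' @param recordings a list of [AccelRecording-class] objects (a single
#'   recording is accepted).
#' @param windowLen,overlap passed to [segmentWindows()].
#' @return list with `features` (W x 43 matrix), `labels` (length-W
#'   character), `subjects` (length-W character).
#' @export
extractFeatures <- function(recordings, windowLen = 300, overlap = 0.5) {
  if (methods::is(recordings, "AccelRecording")) recordings <- list(recordings)
  stopifnot(length(recordings) > 0)
  wins <- unlist(lapply(recordings, segmentWindows,
                        windowLen = windowLen, overlap = overlap),
                 recursive = FALSE)
  if (length(wins) == 0L) stop("no usable windows")
  feats <- t(vapply(wins, function(w) windowFeatures(w$data),
                    numeric(length(featureNames()))))
  colnames(feats) <- featureNames()
  list(features = feats,
       labels = vapply(wins, `[[`, character(1), "label"),
       subjects = vapply(wins, `[[`, character(1), "subject"))
}

## Accept either a window list or a bare matrix.
windowData <- function(window) {
  d <- if (is.list(window)) window$data else window
  stopifnot(is.numeric(d), is.matrix(d), ncol(d) == 3L)
  d
}
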