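## Seeded synthetic accelerometer-signal generator. Each activity is a sum
## of harmonics riding on a (rotated) gravity vector plus AR(1) noise;
## subjects differ in amplitude scale, cadence scale and sensor-orientation
## jitter, emulating the large inter-individual differences seen in
## waist-worn recordings. Walk and the two stairs classes share cadences
## within 15% (confusable by construction); the three static postures differ
## only in orientation and noise.

#' Default activity signal profiles
#'
#' One profile per activity: gravity orientation (unit 3-vector of the
#' sensor's resting attitude), per-axis periodic amplitude in g,
#' fundamental cadence in Hz (0 for static postures), harmonic weights,
#' AR(1) noise coefficient and innovation SD in g.
#'
#' @return named list of profiles, one per [activityClasses()] entry.
#' @export
activityProfiles <- function() {
  prof <- function(orient, amp, freq, harm = c(1, 0.4, 0.15),
                   noiseSd = 0.35, arCoef = 0.5) {
    orient <- orient / sqrt(sum(orient^2))
    list(gravityOrientation = orient, periodicAmplitude = amp,
         fundamentalFreq = freq, harmonicWeights = harm,
         noiseSd = noiseSd, arCoefficient = arCoef)
  }
  list(
    ## dynamic: walk / stairs cadences within 15% of each other
    W  = prof(c(0, 0, 1), c(0.8, 0.5, 1.0), 1.9),
    GD = prof(c(0, 0, 1), c(0.9, 0.55, 1.15), 2.05),
    GU = prof(c(0, 0, 1), c(0.75, 0.5, 0.9), 1.75),
    ## jump / run: high-energy pair
    J  = prof(c(0, 0, 1), c(0.9, 0.7, 2.0), 2.6, harm = c(1, 0.6, 0.3)),
    R  = prof(c(0, 0, 1), c(1.1, 0.7, 1.6), 2.75, harm = c(1, 0.5, 0.2)),
    ## static postures: orientation + small noise only
    S  = prof(c(0, 0, 1), c(0, 0, 0), 0, noiseSd = 0.05, arCoef = 0.3),
    SC = prof(c(0, sin(25 * pi / 180), cos(25 * pi / 180)), c(0, 0, 0), 0,
              noiseSd = 0.07, arCoef = 0.3),
    L  = prof(c(1, 0, 0), c(0, 0, 0), 0, noiseSd = 0.05, arCoef = 0.3)
  )[activityClasses()]
}

#' Subject-level variation parameters
#'
#' Draws per-subject amplitude scale (uniform 0.7-1.6), cadence scale
#' (uniform 0.9-1.1) and sensor-orientation jitter (uniform 0-0.15 rad)
#' for the requested number of subjects.
#'
#' @param n number of subjects.
#' @param seed integer seed.
#' @return data.frame with columns `subject`, `amplitudeScale`,
#'   `freqScale`, `orientationJitter`.
#' @export
subjectParams <- function(n, seed = 1) {
  withr::with_seed(as.integer(seed), data.frame(
    subject = sprintf("S%02d", seq_len(n)),
    amplitudeScale = stats::runif(n, 0.7, 1.6),
    freqScale = stats::runif(n, 0.9, 1.1),
    orientationJitter = stats::runif(n, 0, 0.15)))
}

## Small rotation about a seeded random axis by `angle` radians.
jitterRotation <- function(angle, seed) {
  ax <- withr::with_seed(seed, stats::rnorm(3))
  ax <- ax / sqrt(sum(ax^2))
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

arNoise <- function(n, phi, sd) {
  if (sd <= 0) return(numeric(n))
  as.numeric(stats::arima.sim(list(ar = phi), n,
                              sd = sd * sqrt(1 - phi^2)))
}

#' Simulate one subject's labelled recording
#'
#' Per activity bout: the signal on each axis is the rotated gravity
#' component plus the subject-scaled sum of harmonics at the activity's
#' cadence (random phases per bout) plus AR(1) noise, clipped to the
#' sensor's +-6 g range. Bouts are concatenated in the order of
#' `activities`, each `boutSeconds` long.
#'
#' Real bouts are not stationary: gait amplitude and cadence wander and the
#' sensor shifts slightly between bouts. Each bout therefore gets its own
#' small orientation jitter and amplitude/cadence perturbation, and the
#' periodic component is modulated by a slow (0.05-0.2 Hz) amplitude
#' envelope, so windows cut from the same bout differ.
#'
#' @param subject one row of [subjectParams()] (or a list with the same
#'   fields).
#' @param activities activity labels to perform, default
#'   [activityClasses()].
#' @param boutSeconds duration of each activity bout (default 20).
#' @param rate sampling rate in Hz (default 150).
#' @param seed integer seed.
#' @param profiles activity profiles, default [activityProfiles()].
#' @param trials number of repetitions of the full activity sequence
#'   (default 1).
#' @return an [AccelRecording-class].
#' @export
simulateRecording <- function(subject, activities = activityClasses(),
                              boutSeconds = 20, rate = 150, seed = 1,
                              profiles = activityProfiles(), trials = 1) {
  stopifnot(rate > 0, boutSeconds * rate >= 300)
  if (!all(activities %in% names(profiles)))
    stop("unknown activity in 'activities'")
  n <- as.integer(round(boutSeconds * rate))
  tt <- (seq_len(n) - 1L) / rate
  Rj <- jitterRotation(subject$orientationJitter, as.integer(seed) + 17L)
  segs <- list(); labs <- character(0)
  k <- 0L
  for (trial in seq_len(trials)) for (a in activities) {
    k <- k + 1L
    p <- profiles[[a]]
    seg <- withr::with_seed(as.integer(seed) + 101L * k, {
      ## per-bout sensor shift and gait perturbation
      Rb <- Rj %*% jitterRotation(stats::runif(1, 0, 0.08),
                                  as.integer(seed) + 101L * k + 1L)
      g <- as.numeric(Rb %*% p$gravityOrientation)
      ampBout <- stats::runif(1, 0.85, 1.15)
      f <- p$fundamentalFreq * subject$freqScale * stats::runif(1, 0.95, 1.05)
      ## slow amplitude envelope: windows within a bout differ
      env <- 1 + 0.25 * sin(2 * pi * stats::runif(1, 0.05, 0.2) * tt +
                              stats::runif(1, 0, 2 * pi))
      sig <- matrix(0, n, 3)
      for (axis in 1:3) {
        periodic <- 0
        if (f > 0 && p$periodicAmplitude[axis] > 0) {
          for (h in seq_along(p$harmonicWeights)) {
            periodic <- periodic +
              p$harmonicWeights[h] *
              sin(2 * pi * f * h * tt + stats::runif(1, 0, 2 * pi))
          }
          periodic <- subject$amplitudeScale * ampBout *
            p$periodicAmplitude[axis] * env * periodic
        }
        sig[, axis] <- g[axis] + periodic +
          arNoise(n, p$arCoefficient, p$noiseSd)
      }
      pmin(pmax(sig, -6), 6)  # sensor saturation
    })
    segs[[k]] <- seg
    labs <- c(labs, rep(a, n))
  }
  AccelRecording(subject$subject, do.call(rbind, segs), labs, rate = rate)
}

#' Simulate a multi-subject scenario
#'
#' The default scenario mirrors a 10-subject lab protocol: each subject
#' performs every activity for `boutSeconds`, repeated over `trials`
#' passes.
#'
#' @param nSubjects number of subjects (default 10).
#' @param trials activity-sequence repetitions per subject (default 5).
#' @param boutSeconds bout length in seconds (default 20).
#' @param rate sampling rate (default 150).
#' @param seed master integer seed.
#' @param activities,profiles as in [simulateRecording()].
#' @return list of [AccelRecording-class], one per subject.
#' @export
simulateScenario <- function(nSubjects = 10, trials = 5, boutSeconds = 20,
                             rate = 150, seed = 1,
                             activities = activityClasses(),
                             profiles = activityProfiles()) {
  sp <- subjectParams(nSubjects, seed = seed)
  lapply(seq_len(nSubjects), function(i)
    simulateRecording(sp[i, ], activities = activities,
                      boutSeconds = boutSeconds, rate = rate,
                      seed = as.integer(seed) + 7919L * i,
                      profiles = profiles, trials = trials))
}

#' Simulate a correctness matrix with planted accuracies and correlation
#'
#' Gaussian-copula thresholding: member t is correct on sample i iff
#' \eqn{\sqrt{\rho} Z_i + \sqrt{1 - \rho}\, e_{ti} \le \Phi^{-1}(a_t)}
#' with standard-normal latents, so marginal correct-rates match the
#' requested accuracies and dependence between members grows with rho
#' (identical rows at rho = 1 for equal accuracies).
#'
#' @param T number of classifiers.
#' @param N number of validation samples.
#' @param accuracies length-T accuracies in (0, 1).
#' @param rho latent equicorrelation in `[0, 1]`.
#' @param seed integer seed.
#' @return binary T x N matrix.
#' @export
simulateCorrectness <- function(T, N, accuracies, rho, seed = 1) {
  stopifnot(T >= 1, N >= 1, length(accuracies) == T)
  if (any(accuracies <= 0 | accuracies >= 1))
    stop("accuracies must lie strictly in (0, 1)")
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  withr::with_seed(as.integer(seed), {
    Z <- stats::rnorm(N)
    M <- matrix(0L, T, N)
    for (t in seq_len(T)) {
      lat <- sqrt(rho) * Z + sqrt(1 - rho) * stats::rnorm(N)
      M[t, ] <- as.integer(lat <= stats::qnorm(accuracies[t]))
    }
    M
  })
}
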