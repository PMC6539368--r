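#' Activity classes recognised by the pipeline
#'
#' The eight activities, in the fixed reporting order used throughout:
#' walk (W), stand (S), jump (J), go down stairs (GD), go up stairs (GU),
#' sit on a chair (SC), run (R), lie (L).
#'
#' @return character vector of length 8.
#' @export
#' @examples
#' activityClasses()
activityClasses <- function() c("W", "S", "J", "GD", "GU", "SC", "R", "L")

## ---------------------------------------------------------------------------
## AccelRecording: labelled tri-axial acceleration time series for one subject
## ---------------------------------------------------------------------------

#' Labelled tri-axial accelerometer recording
#'
#' Container for one subject's acceleration time series: an n x 3 matrix of
#' (ax, ay, az) samples in g-units, a per-sample activity label, and the
#' sampling rate in Hz.
#'
#' @slot subject character scalar, subject identifier.
#' @slot rate numeric scalar, sampling rate in Hz.
#' @slot samples numeric n x 3 matrix, columns x/y/z acceleration in g.
#' @slot labels character vector of per-sample activity labels.
#'
#' @seealso [AccelRecording()], [segmentWindows()], [simulateRecording()]
#' @export
setClass("AccelRecording",
  representation(
    subject = "character",
    rate = "numeric",
    samples = "matrix",
    labels = "character"
  )
)

setValidity("AccelRecording", function(object) {
  msg <- character()
  if (length(object@subject) != 1L || !nzchar(object@subject))
    msg <- c(msg, "subject must be a single non-empty string")
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    msg <- c(msg, "rate must be a single positive number")
  if (!is.numeric(object@samples) || ncol(object@samples) != 3L)
    msg <- c(msg, "samples must be a numeric matrix with 3 columns")
  if (nrow(object@samples) != length(object@labels))
    msg <- c(msg, "samples and labels must have equal length")
  if (length(msg)) msg else TRUE
})

#' Construct an AccelRecording
#'
#' @param subject subject identifier.
#' @param samples numeric n x 3 matrix of (ax, ay, az) in g-units.
#' @param labels character vector of per-sample activity labels (length n).
#' @param rate sampling rate in Hz (default 150).
#' @return an [AccelRecording-class] object.
#' @export
#' @examples
#' r <- AccelRecording("s1", matrix(rnorm(900), ncol = 3), rep("W", 300))
#' r
AccelRecording <- function(subject, samples, labels, rate = 150) {
  samples <- as.matrix(samples)
  colnames(samples) <- c("ax", "ay", "az")
  methods::new("AccelRecording",
    subject = as.character(subject), rate = as.numeric(rate),
    samples = samples, labels = as.character(labels))
}

#' @rdname AccelRecording-class
#' @param object object to display
#' @export
setMethod("show", "AccelRecording", function(object) {
  cat(sprintf(
    "AccelRecording '%s': %d samples @ %g Hz (%.1f s), activities: %s\n",
    object@subject, nrow(object@samples), object@rate,
    nrow(object@samples) / object@rate,
    paste(unique(object@labels), collapse = ", ")))
})

#' @describeIn AccelRecording number of samples
#' @param x an AccelRecording.
#' @export
setMethod("length", "AccelRecording", function(x) nrow(x@samples))

#' Accessors for AccelRecording
#'
#' @param object an [AccelRecording-class].
#' @return `recordingSubject()` the subject id, `recordingSamples()` the
#'   n x 3 sample matrix, `recordingLabels()` the label vector,
#'   `samplingRate()` the rate in Hz.
#' @export
recordingSubject <- function(object) object@subject

#' @rdname recordingSubject
#' @export
recordingSamples <- function(object) object@samples

#' @rdname recordingSubject
#' @export
recordingLabels <- function(object) object@labels

#' @rdname recordingSubject
#' @export
samplingRate <- function(object) object@rate

## ---------------------------------------------------------------------------
## KFDAModel
## ---------------------------------------------------------------------------

#' Kernel Fisher discriminant analysis model
#'
#' Fitted KFDA projection in dual form: discriminant directions are stored as
#' dual coefficient vectors alpha over the (optionally standardized) training
#' samples, so projecting a new point z computes
#' \eqn{y_r = \sum_i \alpha_{ir} k(x_i, z)}.
#'
#' @slot supportSamples N x p matrix of training features (after the model's
#'   own standardization, if any).
#' @slot alpha N x d dual coefficient matrix, unit-norm columns, sign fixed so
#'   each column's largest-magnitude entry is positive.
#' @slot eigenvalues d Fisher criterion values, non-increasing.
#' @slot delta RBF kernel width (irrelevant for the linear kernel).
#' @slot sigma ridge regularizer added to the within-class dual scatter.
#' @slot d number of discriminant dimensions (at most C - 1).
#' @slot kernel "rbf" or "linear".
#' @slot classList class labels seen in training.
#' @slot center,scale column standardization parameters (length p, or length 0
#'   when standardize = FALSE).
#'
#' @seealso [fitKFDA()], [projectFeatures()], [selectDelta()]
#' @export
setClass("KFDAModel",
  representation(
    supportSamples = "matrix",
    alpha = "matrix",
    eigenvalues = "numeric",
    delta = "numeric",
    sigma = "numeric",
    d = "integer",
    kernel = "character",
    classList = "character",
    center = "numeric",
    scale = "numeric"
  )
)

setValidity("KFDAModel", function(object) {
  msg <- character()
  if (nrow(object@alpha) != nrow(object@supportSamples))
    msg <- c(msg, "alpha must have one row per support sample")
  if (ncol(object@alpha) != object@d)
    msg <- c(msg, "alpha must have d columns")
  if (object@d > length(object@classList) - 1L)
    msg <- c(msg, "d must be at most C - 1")
  if (is.unsorted(rev(object@eigenvalues), strictly = FALSE))
    msg <- c(msg, "eigenvalues must be non-increasing")
  if (any(object@eigenvalues < -1e-8))
    msg <- c(msg, "eigenvalues must be >= -1e-8")
  if (!object@kernel %in% c("rbf", "linear"))
    msg <- c(msg, "kernel must be 'rbf' or 'linear'")
  if (object@kernel == "rbf" && object@delta <= 0)
    msg <- c(msg, "delta must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname KFDAModel-class
#' @param object object to display
#' @export
setMethod("show", "KFDAModel", function(object) {
  cat(sprintf(
    "KFDAModel: %d support samples, %d features, %d classes -> %d dims\n",
    nrow(object@supportSamples), ncol(object@supportSamples),
    length(object@classList), object@d))
  cat(sprintf("  kernel: %s (delta = %.4g), sigma = %.3g\n",
              object@kernel, object@delta, object@sigma))
  cat("  Fisher values:", paste(sprintf("%.3g", object@eigenvalues),
                                collapse = " "), "\n")
})

#' @describeIn KFDAModel number of discriminant dimensions
#' @export
setMethod("nDimensions", "KFDAModel", function(object) object@d)

#' @describeIn KFDAModel class labels seen in training
#' @export
setMethod("classLabels", "KFDAModel", function(object) object@classList)

#' Dual coefficients of a KFDA model
#'
#' @param object a [KFDAModel-class].
#' @return `alphaCoefficients()` the N x d dual coefficient matrix;
#'   `fisherValues()` the d Fisher criterion eigenvalues;
#'   `kernelWidth()` the RBF width delta.
#' @export
alphaCoefficients <- function(object) object@alpha

#' @rdname alphaCoefficients
#' @export
fisherValues <- function(object) object@eigenvalues

#' @rdname alphaCoefficients
#' @export
kernelWidth <- function(object) object@delta

## ---------------------------------------------------------------------------
## ELMModel and ELMEnsemble
## ---------------------------------------------------------------------------

#' Extreme learning machine classifier
#'
#' Single-hidden-layer feed-forward network with random input weights and
#' biases (uniform in [-1, 1]) and closed-form output weights
#' \eqn{\beta = H^\dagger T} obtained from the SVD pseudoinverse of the hidden
#' layer output matrix H against one-hot class targets T.
#'
#' @slot inputWeights L x d matrix of input weights (rows are hidden neurons).
#' @slot biases length-L hidden biases.
#' @slot outputWeights L x m output weight matrix beta.
#' @slot activation name of the scalar hidden activation ("sigmoid" or
#'   "tanh").
#' @slot hiddenCount number of hidden neurons L.
#' @slot classList the m class labels, in target-column order.
#' @slot seed integer seed the random weights were drawn with.
#'
#' @seealso [trainELM()], [predict,ELMModel-method], [buildEnsemble()]
#' @export
setClass("ELMModel",
  representation(
    inputWeights = "matrix",
    biases = "numeric",
    outputWeights = "matrix",
    activation = "character",
    hiddenCount = "integer",
    classList = "character",
    seed = "integer"
  )
)

setValidity("ELMModel", function(object) {
  msg <- character()
  if (nrow(object@inputWeights) != object@hiddenCount)
    msg <- c(msg, "inputWeights must have hiddenCount rows")
  if (length(object@biases) != object@hiddenCount)
    msg <- c(msg, "biases must have length hiddenCount")
  if (!all(dim(object@outputWeights) ==
           c(object@hiddenCount, length(object@classList))))
    msg <- c(msg, "outputWeights must be hiddenCount x nClasses")
  if (!object@activation %in% c("sigmoid", "tanh"))
    msg <- c(msg, "activation must be 'sigmoid' or 'tanh'")
  if (length(msg)) msg else TRUE
})

#' @rdname ELMModel-class
#' @param object object to display
#' @export
setMethod("show", "ELMModel", function(object) {
  cat(sprintf("ELMModel: %d hidden neurons (%s), %d inputs, %d classes\n",
              object@hiddenCount, object@activation,
              ncol(object@inputWeights), length(object@classList)))
})

#' @describeIn ELMModel number of hidden neurons
#' @export
setMethod("nDimensions", "ELMModel", function(object) object@hiddenCount)

#' @describeIn ELMModel class labels
#' @export
setMethod("classLabels", "ELMModel", function(object) object@classList)

#' Bootstrap-trained ELM ensemble
#'
#' A set of T ELM base classifiers, each trained on its own bootstrap
#' resample of the training set with a per-member hidden-neuron count chosen
#' by training accuracy. Provenance (bootstrap seed and indices, training
#' accuracy) is retained per member.
#'
#' @slot members list of [ELMModel-class] base classifiers.
#' @slot bootstrapSeeds integer seed per member.
#' @slot bootstrapIndices list of bootstrap index vectors (each the size of
#'   the training set).
#' @slot trainAccuracy per-member accuracy on its bootstrap training set.
#' @slot masterSeed the master seed the ensemble was derived from.
#'
#' @seealso [buildEnsemble()], [predictMembers()]
#' @export
setClass("ELMEnsemble",
  representation(
    members = "list",
    bootstrapSeeds = "integer",
    bootstrapIndices = "list",
    trainAccuracy = "numeric",
    masterSeed = "integer"
  )
)

setValidity("ELMEnsemble", function(object) {
  msg <- character()
  T <- length(object@members)
  if (!all(vapply(object@members, methods::is, TRUE, "ELMModel")))
    msg <- c(msg, "members must all be ELMModel objects")
  if (length(object@bootstrapSeeds) != T ||
      length(object@bootstrapIndices) != T ||
      length(object@trainAccuracy) != T)
    msg <- c(msg, "provenance slots must have one entry per member")
  if (length(msg)) msg else TRUE
})

#' @rdname ELMEnsemble-class
#' @param object object to display
#' @export
setMethod("show", "ELMEnsemble", function(object) {
  L <- vapply(object@members, function(m) m@hiddenCount, integer(1))
  cat(sprintf(
    "ELMEnsemble: %d members, hidden neurons %d-%d, master seed %d\n",
    length(object@members), min(L), max(L), object@masterSeed))
})

#' @describeIn ELMEnsemble number of members
#' @param x an ELMEnsemble.
#' @export
setMethod("length", "ELMEnsemble", function(x) length(x@members))

#' @describeIn ELMEnsemble list of member classifiers
#' @export
setMethod("ensembleMembers", "ELMEnsemble", function(object) object@members)

#' @describeIn ELMEnsemble class labels (shared by all members)
#' @export
setMethod("classLabels", "ELMEnsemble",
          function(object) object@members[[1L]]@classList)
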