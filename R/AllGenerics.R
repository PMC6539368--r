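#' @title Generics for harensemble model objects
#' @name harensemble-generics
#' @keywords internal
NULL

#' Project new feature vectors with a fitted discriminant model
#'
#' @param object a fitted model (e.g. a [KFDAModel-class]).
#' @param newdata numeric matrix with one row per sample.
#' @param ... further arguments passed to methods.
#' @return numeric matrix of projected coordinates, one row per sample.
#' @export
setGeneric("projectFeatures", function(object, newdata, ...)
  standardGeneric("projectFeatures"))

#' Number of discriminant dimensions / hidden neurons / members
#'
#' @param object a harensemble model object.
#' @return integer.
#' @export
setGeneric("nDimensions", function(object) standardGeneric("nDimensions"))

#' Class labels a classifier was trained on
#'
#' @param object a classifier or ensemble object.
#' @return character vector of class labels.
#' @export
setGeneric("classLabels", function(object) standardGeneric("classLabels"))

#' Ensemble members
#'
#' @param object an [ELMEnsemble-class].
#' @return list of [ELMModel-class] members.
#' @export
setGeneric("ensembleMembers", function(object) standardGeneric("ensembleMembers"))
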