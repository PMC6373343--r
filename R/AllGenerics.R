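#' @name accessors
#' @title Accessors for streamlmm objects
#' @description Read the components of parameter, fit, state and stream
#'   objects without touching slots directly.
#' @param object a streamlmm S4 object.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("fixedEffects", function(object) standardGeneric("fixedEffects"))

#' @rdname accessors
#' @export
setGeneric("ranefCovariance", function(object) standardGeneric("ranefCovariance"))

#' @rdname accessors
#' @export
setGeneric("residualVariance", function(object) standardGeneric("residualVariance"))

#' @rdname accessors
#' @export
setGeneric("nObs", function(object) standardGeneric("nObs"))

#' @rdname accessors
#' @export
setGeneric("nIndividuals", function(object) standardGeneric("nIndividuals"))

#' @rdname accessors
#' @export
setGeneric("modelParams", function(object) standardGeneric("modelParams"))

setMethod("fixedEffects", "MixedModelParams", function(object) object@beta)
setMethod("ranefCovariance", "MixedModelParams", function(object) object@phi)
setMethod("residualVariance", "MixedModelParams", function(object) object@sigma2)

setMethod("fixedEffects", "EmFit", function(object) object@params@beta)
setMethod("ranefCovariance", "EmFit", function(object) object@params@phi)
setMethod("residualVariance", "EmFit", function(object) object@params@sigma2)
setMethod("modelParams", "EmFit", function(object) object@params)

setMethod("fixedEffects", "SemaState", function(object) object@params@beta)
setMethod("ranefCovariance", "SemaState", function(object) object@params@phi)
setMethod("residualVariance", "SemaState", function(object) object@params@sigma2)
setMethod("modelParams", "SemaState", function(object) object@params)
setMethod("nObs", "SemaState", function(object) object@n)
setMethod("nIndividuals", "SemaState", function(object) object@J)

setMethod("modelParams", "PrequentialResult", function(object) object@finalParams)

setMethod("nObs", "BatchData", function(object) nrow(object@X))
setMethod("nIndividuals", "BatchData", function(object) length(unique(object@id)))

#' @rdname accessors
#' @export
setGeneric("predictionLog", function(object) standardGeneric("predictionLog"))
setMethod("predictionLog", "PrequentialResult", function(object) object@log)

#' @rdname accessors
#' @export
setGeneric("checkpoints", function(object) standardGeneric("checkpoints"))
setMethod("checkpoints", "PrequentialResult", function(object) object@checkpoints)

#' @rdname accessors
#' @export
setGeneric("streamHeader", function(object) standardGeneric("streamHeader"))
setMethod("streamHeader", "DataStream", function(object) object@header)

#' @rdname accessors
#' @export
setGeneric("streamData", function(object) standardGeneric("streamData"))
setMethod("streamData", "DataStream", function(object) object@data)

#' @rdname accessors
#' @export
setGeneric("individualSummary",
           function(object, id) standardGeneric("individualSummary"))
setMethod("individualSummary", "SemaState", function(object, id) {
  object@individuals[[as.character(id)]]
})

setMethod("show", "MixedModelParams", function(object) {
  cat("Linear mixed model parameters\n")
  cat("  fixed effects (p =", length(object@beta), "):",
      paste(signif(utils::head(object@beta, 5), 4), collapse = ", "),
      if (length(object@beta) > 5) "...", "\n")
  cat("  random-effect covariance (r =", nrow(object@phi), "), diag:",
      paste(signif(diag(object@phi), 4), collapse = ", "), "\n")
  cat("  residual variance:", signif(object@sigma2, 4), "\n")
})

setMethod("show", "EmFit", function(object) {
  cat("Batch EM fit:", object@iterations, "iterations,",
      if (object@converged) "converged" else "NOT converged", "\n")
  show(object@params)
})

setMethod("show", "SemaState", function(object) {
  cat("Streaming EM state: n =", object@n, ", J =", object@J,
      ", p =", object@p, ", r =", object@r, "\n")
  show(object@params)
})

setMethod("show", "SimulationCondition", function(object) {
  cat("Simulation condition", object@name, ": r =", nrow(object@phi),
      "random effects, J =", object@J, ", n =", object@nTotal, "\n")
})

setMethod("show", "PrequentialResult", function(object) {
  cat("Prequential run (", object@method, "): ",
      nrow(object@log), " evaluated predictions after a training set of ",
      object@trainN, "\n", sep = "")
  show(object@finalParams)
})

setMethod("show", "DataStream", function(object) {
  cat("Data stream: n =", nrow(object@data), ", p =", object@header$p,
      ", r =", object@header$r, "\n")
})
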