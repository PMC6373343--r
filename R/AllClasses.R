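## Central S4 containers.  Validity checks encode the model's invariants;
## accessors (see AllGenerics.R) are the supported way to read slots.

.symTol <- 1e-10

#' Model parameters of the linear multilevel model
#'
#' The triplet \eqn{(\beta, \Phi, \sigma^2)}: fixed-effect coefficients, the
#' random-effect covariance matrix, and the residual variance.
#'
#' @slot beta numeric vector of length p, fixed-effect coefficients.
#' @slot phi r x r symmetric positive semi-definite covariance matrix of the
#'   random effects.
#' @slot sigma2 positive residual variance.
#' @exportClass MixedModelParams
setClass("MixedModelParams",
  representation(beta = "numeric", phi = "matrix", sigma2 = "numeric"))

setValidity("MixedModelParams", function(object) {
  msg <- character()
  if (length(object@sigma2) != 1L || !is.finite(object@sigma2) ||
      object@sigma2 <= 0)
    msg <- c(msg, "sigma2 must be a single positive finite number")
  if (!all(is.finite(object@beta)))
    msg <- c(msg, "beta must be finite")
  phi <- object@phi
  if (nrow(phi) != ncol(phi) || !all(is.finite(phi))) {
    msg <- c(msg, "phi must be a finite square matrix")
  } else {
    if (max(abs(phi - t(phi))) > .symTol)
      msg <- c(msg, "phi must be symmetric (tolerance 1e-10)")
    ev <- eigen((phi + t(phi)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -.symTol)
      msg <- c(msg, "phi must be positive semi-definite")
  }
  if (length(msg)) msg else TRUE
})

#' Construct model parameters
#'
#' @param beta numeric vector of fixed-effect coefficients.
#' @param phi random-effect covariance matrix (a scalar is promoted to 1 x 1).
#' @param sigma2 positive residual variance.
#' @return A [MixedModelParams-class] object.
#' @examples
#' mixedModelParams(c(100, 0.1), matrix(50), 5)
#' @export
mixedModelParams <- function(beta, phi, sigma2) {
  if (!is.matrix(phi)) phi <- matrix(phi, length(phi) == 1L, 1L)
  new("MixedModelParams", beta = as.numeric(beta), phi = phi,
      sigma2 = as.numeric(sigma2))
}

#' Posterior of one individual's random effects
#'
#' The posterior mean \eqn{\hat b_j} together with the precision-like matrix
#' \eqn{C_j = Z_j'Z_j + \sigma^2 \Phi^{-1}} and its inverse, which quantifies
#' the uncertainty of the imputed random effects.
#'
#' @slot bHat numeric vector, posterior mean of the random effects.
#' @slot C r x r symmetric positive-definite matrix.
#' @slot Cinv inverse of \code{C}.
#' @exportClass RanefPosterior
setClass("RanefPosterior",
  representation(bHat = "numeric", C = "matrix", Cinv = "matrix"))

setValidity("RanefPosterior", function(object) {
  msg <- character()
  r <- length(object@bHat)
  if (!all(dim(object@C) == r) || !all(dim(object@Cinv) == r))
    msg <- c(msg, "C and Cinv must be r x r")
  else {
    if (max(abs(object@C - t(object@C))) > 1e-8)
      msg <- c(msg, "C must be symmetric")
    if (max(abs(object@Cinv %*% object@C - diag(r))) > 1e-8)
      msg <- c(msg, "Cinv must invert C to within 1e-8")
  }
  if (length(msg)) msg else TRUE
})

#' One streamed observation
#'
#' @slot id individual identifier (length-1 character).
#' @slot y response.
#' @slot x fixed-effect covariate vector (includes an explicit 1 for the
#'   intercept; there is no implicit intercept anywhere in the package).
#' @slot z random-effect covariate vector (includes an explicit 1 when a
#'   random intercept is modeled).
#' @exportClass DataPoint
setClass("DataPoint",
  representation(id = "character", y = "numeric", x = "numeric",
                 z = "numeric"))

setValidity("DataPoint", function(object) {
  if (!all(is.finite(c(object@y, object@x, object@z))))
    return("all fields of a data point must be finite")
  if (length(object@y) != 1L || length(object@id) != 1L)
    return("y and id must have length 1")
  TRUE
})

#' Construct a data point
#' @param id individual identifier.
#' @param y response value.
#' @param x fixed-effect covariates.
#' @param z random-effect covariates.
#' @return A [DataPoint-class] object.
#' @export
dataPoint <- function(id, y, x, z) {
  new("DataPoint", id = as.character(id), y = as.numeric(y),
      x = as.numeric(x), z = as.numeric(z))
}

#' Batch (in-memory) data for the multilevel model
#'
#' @slot X n x p fixed-effect design matrix.
#' @slot Z n x r random-effect design matrix.
#' @slot y response vector.
#' @slot id character vector of individual identifiers, one per row.
#' @exportClass BatchData
setClass("BatchData",
  representation(X = "matrix", Z = "matrix", y = "numeric", id = "character"))

setValidity("BatchData", function(object) {
  n <- nrow(object@X)
  if (nrow(object@Z) != n || length(object@y) != n || length(object@id) != n)
    return("X, Z, y and id must agree on the number of rows")
  if (n < 1L) return("data must be nonempty")
  if (!all(is.finite(object@X)) || !all(is.finite(object@Z)) ||
      !all(is.finite(object@y)))
    return("all entries must be finite")
  TRUE
})

#' Construct batch data
#' @param X fixed-effect design matrix (n x p).
#' @param Z random-effect design matrix (n x r).
#' @param y responses.
#' @param id individual identifiers (one per row).
#' @return A [BatchData-class] object.
#' @export
batchData <- function(X, Z, y, id) {
  new("BatchData", X = as.matrix(X), Z = as.matrix(Z), y = as.numeric(y),
      id = as.character(id))
}

#' Result of a batch EM fit
#'
#' @slot params final [MixedModelParams-class].
#' @slot trace matrix of per-iteration parameter values (columns: beta,
#'   lower-triangular phi, sigma2).
#' @slot iterations number of EM iterations performed.
#' @slot converged whether the parameter-change criterion was met.
#' @exportClass EmFit
setClass("EmFit",
  representation(params = "MixedModelParams", trace = "matrix",
                 iterations = "integer", converged = "logical"))

#' Streaming estimator state
#'
#' The global state of the streaming estimator: counts, global cross-products
#' and the maintained inverse of X'X, the running complete-data sufficient
#' statistic (CDSS) totals, the current parameters, and one summary per
#' individual seen so far (the only structure that grows, with J).
#'
#' @slot n total observations ingested.
#' @slot J number of distinct individuals seen.
#' @slot p,r covariate dimensions.
#' @slot XtX,XtXinv global fixed-effect cross-product and its maintained
#'   inverse.
#' @slot xy running \eqn{\sum x_{ij} y_{ij}}.
#' @slot t1,T2,t3 running CDSS totals.
#' @slot params current [MixedModelParams-class].
#' @slot individuals named list of per-individual summaries (cross-products,
#'   posterior, and CDSS contributions).
#' @slot config list of tuning constants (sweep cadence, re-inversion cadence,
#'   phi eigenvalue floor, warm-up policy).
#' @exportClass SemaState
setClass("SemaState",
  representation(n = "integer", J = "integer", p = "integer", r = "integer",
                 XtX = "matrix", XtXinv = "matrix", xy = "numeric",
                 t1 = "numeric", T2 = "matrix", t3 = "numeric",
                 params = "MixedModelParams", individuals = "list",
                 config = "list"))

setValidity("SemaState", function(object) {
  msg <- character()
  p <- object@p; r <- object@r
  if (length(object@t1) != p || !all(dim(object@T2) == r))
    msg <- c(msg, "CDSS dimensions inconsistent with p and r")
  if (length(object@individuals)) {
    t1s <- Reduce(`+`, lapply(object@individuals, `[[`, "t1j"))
    T2s <- Reduce(`+`, lapply(object@individuals, `[[`, "T2j"))
    t3s <- sum(vapply(object@individuals, `[[`, numeric(1), "t3j"))
    rel <- function(a, b) max(abs(a - b)) / max(1, max(abs(b)))
    if (rel(t1s, object@t1) > 1e-6 || rel(T2s, object@T2) > 1e-6 ||
        rel(t3s, object@t3) > 1e-6)
      msg <- c(msg, "CDSS totals do not match the sum of stored contributions")
  }
  if (object@n >= p && all(is.finite(object@XtXinv))) {
    if (max(abs(object@XtXinv %*% object@XtX - diag(p))) > 1e-6)
      msg <- c(msg, "maintained inverse of X'X has drifted beyond 1e-6")
  }
  if (length(msg)) msg else TRUE
})

#' Sliding window of recent data points
#'
#' FIFO buffer of the \code{m} most recent observations used by the
#' sliding-window EM comparator; eviction is strictly oldest-first.
#'
#' @slot capacity maximum number of retained points (m).
#' @slot records list of [DataPoint-class] objects in arrival order.
#' @exportClass WindowBuffer
setClass("WindowBuffer",
  representation(capacity = "integer", records = "list"))

setValidity("WindowBuffer", function(object) {
  if (object@capacity < 1L) return("capacity must be at least 1")
  if (length(object@records) > object@capacity)
    return("buffer holds more records than its capacity")
  TRUE
})

#' Construct a sliding-window buffer
#' @param capacity window size m.
#' @return An empty [WindowBuffer-class].
#' @export
windowBuffer <- function(capacity) {
  new("WindowBuffer", capacity = as.integer(capacity), records = list())
}

#' A named simulation condition
#'
#' Bundles the true generating values of one simulation condition: 15 fixed
#' effects, the random-effect covariance (a single random intercept in
#' condition A; intercept plus four slopes with exchangeable correlation 0,
#' .15 or .5 in conditions B, C, D), residual variance 5, J = 1000
#' individuals and a stream of 50,000 observations.
#'
#' @slot name one of "A", "B", "C", "D".
#' @slot beta true fixed effects (length 15).
#' @slot phi true random-effect covariance.
#' @slot sigma2 true residual variance.
#' @slot J number of individuals.
#' @slot nTotal stream length.
#' @slot zCols indices of the x columns that also carry random effects.
#' @exportClass SimulationCondition
setClass("SimulationCondition",
  representation(name = "character", beta = "numeric", phi = "matrix",
                 sigma2 = "numeric", J = "integer", nTotal = "integer",
                 zCols = "integer"))

setValidity("SimulationCondition", function(object) {
  ev <- eigen((object@phi + t(object@phi)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) <= 0) return("implied random-effect covariance is not positive definite")
  if (length(object@beta) != 15L) return("the design uses 15 fixed effects")
  TRUE
})

#' A simulated population of individuals
#'
#' @slot condition the [SimulationCondition-class] it was drawn under.
#' @slot id individual identifiers.
#' @slot level2 J x q matrix of level-2 covariates (constant within
#'   individual).
#' @slot b J x r matrix of true random-effect coefficients.
#' @exportClass Population
setClass("Population",
  representation(condition = "SimulationCondition", id = "character",
                 level2 = "matrix", b = "matrix"))

#' A data stream with its schema header
#'
#' @slot header list with fields \code{p}, \code{r}, \code{xCols},
#'   \code{zCols}, and optional condition metadata and seed.
#' @slot data data.frame with columns \code{id}, \code{y} and the covariate
#'   columns named in the header.
#' @exportClass DataStream
setClass("DataStream",
  representation(header = "list", data = "data.frame"))

setValidity("DataStream", function(object) {
  h <- object@header
  need <- c("p", "r", "xCols", "zCols")
  if (!all(need %in% names(h)))
    return("header must declare p, r, xCols and zCols")
  if (length(h$xCols) != h$p || length(h$zCols) != h$r)
    return("xCols/zCols lengths must match p and r")
  cols <- union(h$xCols, h$zCols)
  if (nrow(object@data) && !all(c("id", "y", cols) %in% names(object@data)))
    return("data is missing declared columns")
  TRUE
})

#' Result of a prequential run
#'
#' @slot method one of "sema", "sema_update", "em_batched", "swem".
#' @slot log data.frame with one row per evaluated stream point (columns
#'   \code{t}, \code{id}, \code{y}, \code{yhat}), in arrival order.
#' @slot checkpoints data.frame of parameter snapshots (long format: \code{n},
#'   \code{parameter}, \code{value}).
#' @slot finalParams parameters at the end of the stream.
#' @slot trainN size of the warm-up training set.
#' @exportClass PrequentialResult
setClass("PrequentialResult",
  representation(method = "character", log = "data.frame",
                 checkpoints = "data.frame", finalParams = "MixedModelParams",
                 trainN = "integer"))
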