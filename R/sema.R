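## Streaming EM: per-data-point E-step for the arriving individual plus an
## immediate closed-form M-step, all from stored summaries.  The fine-grained
## operations below are pure R and operate on a SemaState; semaStream() runs
## the same updates through the compiled kernel for long streams (the two
## paths agree to float reordering and are tested for it).

.semaConfig <- function(config = list()) {
  defaults <- list(sweepEvery = 1000L, reinvertEvery = 100000L,
                   phiFloorRel = 1e-8, minWarmup = NULL)
  defaults[names(config)] <- config
  defaults
}

.emptyIndividual <- function(p, r) {
  list(nj = 0L, ZtZ = matrix(0, r, r), XtZ = matrix(0, p, r),
       XtXj = matrix(0, p, p), Zty = numeric(r), Xtyj = numeric(p),
       yty = 0, bHat = numeric(r), Cinv = matrix(0, r, r),
       t1j = numeric(p), T2j = matrix(0, r, r), t3j = 0)
}

#' Initialize an empty streaming state
#'
#' Points fed to [semaProcessPoint()] are buffered until X'X has full rank and
#' at least \code{max(5p, minWarmup)} points have arrived; then a batch EM fit
#' of the buffer provides the start values and the state switches to
#' streaming.  Use [semaWarmStart()] instead when a training set is available
#' up front.
#'
#' @param p,r covariate dimensions.
#' @param config list of tuning constants; see [SemaState-class].
#' @return A [SemaState-class] in warm-up mode.
#' @export
semaInit <- function(p, r, config = list()) {
  cfg <- .semaConfig(config)
  cfg$warming <- TRUE
  cfg$buffer <- list()
  new("SemaState", n = 0L, J = 0L, p = as.integer(p), r = as.integer(r),
      XtX = matrix(0, p, p), XtXinv = matrix(NA_real_, p, p),
      xy = numeric(p), t1 = numeric(p), T2 = matrix(0, r, r), t3 = 0,
      params = mixedModelParams(numeric(p), diag(r), 1),
      individuals = list(), config = cfg)
}

#' Sherman-Morrison rank-one inverse update
#'
#' Given \code{inv} = \eqn{A^{-1}}, returns the exact inverse of
#' \eqn{A + xx'} without re-inverting:
#' \deqn{A^{-1} - \frac{A^{-1}xx'A^{-1}}{1 + x'A^{-1}x}.}
#'
#' @param inv current inverse (p x p, symmetric positive definite).
#' @param x update vector (length p).
#' @return the updated inverse.
#' @examples
#' shermanMorrisonUpdate(matrix(1 / 4), 2)  # 1/8
#' @export
shermanMorrisonUpdate <- function(inv, x) {
  x <- as.numeric(x)
  if (length(x) != nrow(inv)) stop("x has the wrong length")
  ax <- as.numeric(inv %*% x)
  denom <- 1 + sum(x * ax)
  if (denom <= 1e-12)
    stop("Sherman-Morrison update is numerically degenerate ",
         "(denominator <= 1e-12); re-invert the raw cross-product instead")
  inv - tcrossprod(ax) / denom
}

#' Ingest one data point into a streaming state
#'
#' Applies the exact rank-one accumulator updates (per-individual Z'Z, X'Z,
#' X'X, Z'y, X'y, sum of squared y; global X'X, its maintained inverse, and
#' x'y) for the arriving individual.  No CDSS or parameter changes happen
#' here.  A record with non-finite fields is rejected with a warning and the
#' state is returned unchanged.
#'
#' @param state a [SemaState-class].
#' @param point a [DataPoint-class].
#' @return the updated state.
#' @export
semaIngest <- function(state, point) {
  if (!all(is.finite(c(point@y, point@x, point@z)))) {
    warning("rejecting record with non-finite fields for individual '",
            point@id, "'")
    return(state)
  }
  if (length(point@x) != state@p || length(point@z) != state@r)
    stop("point dimensions do not match the stream (p = ", state@p,
         ", r = ", state@r, ")")
  x <- point@x; z <- point@z; y <- point@y
  key <- point@id
  ind <- state@individuals[[key]]
  if (is.null(ind)) {
    ind <- .emptyIndividual(state@p, state@r)
    state@J <- state@J + 1L
  }
  ind$nj <- ind$nj + 1L
  ind$ZtZ <- ind$ZtZ + tcrossprod(z)
  ind$XtZ <- ind$XtZ + outer(x, z)
  ind$XtXj <- ind$XtXj + tcrossprod(x)
  ind$Zty <- ind$Zty + z * y
  ind$Xtyj <- ind$Xtyj + x * y
  ind$yty <- ind$yty + y^2
  state@individuals[[key]] <- ind
  state@n <- state@n + 1L
  state@XtX <- state@XtX + tcrossprod(x)
  state@xy <- state@xy + x * y
  if (all(is.finite(state@XtXinv))) {
    state@XtXinv <- tryCatch(shermanMorrisonUpdate(state@XtXinv, x),
                             error = function(e) solve(state@XtX))
    reinv <- state@config$reinvertEvery
    if (!is.null(reinv) && reinv > 0 && state@n %% reinv == 0)
      state@XtXinv <- solve(state@XtX)
  }
  state
}

.estepIndividual <- function(ind, params, phiFloorRel) {
  phiInv <- .phiInvFloored(params@phi, phiFloorRel)
  C <- ind$ZtZ + params@sigma2 * phiInv
  C <- (C + t(C)) / 2
  Cinv <- tryCatch(solve(C), error = function(e) NULL)
  if (is.null(Cinv)) {
    phiInv <- .phiInvFloored(params@phi, max(phiFloorRel, 1e-6))
    C <- ind$ZtZ + params@sigma2 * phiInv
    Cinv <- tryCatch(solve(C), error = function(e) NULL)
    if (is.null(Cinv)) return(NULL)
  }
  Cinv <- (Cinv + t(Cinv)) / 2
  bHat <- as.numeric(Cinv %*% (ind$Zty - t(ind$XtZ) %*% params@beta))
  beta <- params@beta
  t3j <- ind$yty +
    as.numeric(t(beta) %*% ind$XtXj %*% beta) +
    as.numeric(t(bHat) %*% ind$ZtZ %*% bHat) -
    2 * sum(ind$Xtyj * beta) - 2 * sum(ind$Zty * bHat) +
    2 * as.numeric(t(beta) %*% ind$XtZ %*% bHat) +
    params@sigma2 * sum(diag(Cinv %*% ind$ZtZ))
  list(bHat = bHat, Cinv = Cinv,
       t1j = as.numeric(ind$XtZ %*% bHat),
       T2j = tcrossprod(bHat) + params@sigma2 * Cinv,
       t3j = t3j)
}

#' Online E-step for one individual
#'
#' Recomputes the posterior and CDSS contributions of a single individual at
#' the current parameters, then replaces that individual's contribution in the
#' running CDSS totals (subtract the old, add the new).  No other individual
#' is touched and no raw data are revisited.
#'
#' @param state a [SemaState-class].
#' @param id individual identifier (must exist in the state).
#' @return the updated state.
#' @export
semaEStepIndividual <- function(state, id) {
  key <- as.character(id)
  ind <- state@individuals[[key]]
  if (is.null(ind)) stop("unknown individual '", key, "'")
  es <- .estepIndividual(ind, state@params, state@config$phiFloorRel)
  if (is.null(es)) {
    warning("E-step for individual '", key,
            "' skipped: C_j singular even after regularizing phi")
    return(state)
  }
  state@t1 <- state@t1 - ind$t1j + es$t1j
  state@T2 <- state@T2 - ind$T2j + es$T2j
  state@T2 <- (state@T2 + t(state@T2)) / 2
  state@t3 <- state@t3 - ind$t3j + es$t3j
  ind[c("bHat", "Cinv", "t1j", "T2j", "t3j")] <-
    es[c("bHat", "Cinv", "t1j", "T2j", "t3j")]
  state@individuals[[key]] <- ind
  state
}

#' Online M-step
#'
#' Closed forms from the running CDSS totals:
#' \eqn{\beta = (X'X)^{-1}(xy - \tilde t_1)}, \eqn{\Phi = \tilde T_2/J}
#' (symmetrized), \eqn{\sigma^2 = \tilde t_3/n} (floored at 1e-10).
#'
#' @param state a [SemaState-class] with a valid maintained inverse.
#' @return the updated state.
#' @export
semaMStep <- function(state) {
  if (state@n < 1L || state@J < 1L) stop("no data ingested yet")
  if (!all(is.finite(state@XtXinv)))
    stop("warm-up incomplete: X'X has not been inverted yet")
  if (state@t3 < -1e-6)
    stop("t3 is negative beyond numerical slack: CDSS totals are corrupted")
  beta <- as.numeric(state@XtXinv %*% (state@xy - state@t1))
  phi <- state@T2 / state@J
  phi <- (phi + t(phi)) / 2
  state@params <- mixedModelParams(beta, phi, max(state@t3 / state@n, 1e-10))
  state
}

#' Process one streamed data point
#'
#' The full per-point cycle: emit the prequential prediction (using the
#' current parameters and the individual's stored posterior mean, or zero for
#' an unseen individual) \emph{before} any update, then ingest, run the online
#' E-step for this individual only, and run the online M-step.  During
#' warm-up (see [semaInit()]) points are buffered and the prediction is
#' \code{NA}; once X'X has full rank and enough points have arrived, a batch
#' EM fit of the buffer initializes the stream.
#'
#' @param state a [SemaState-class].
#' @param point a [DataPoint-class].
#' @return list with \code{prediction} (scalar) and \code{state}.
#' @export
semaProcessPoint <- function(state, point) {
  if (isTRUE(state@config$warming)) {
    state@config$buffer <- c(state@config$buffer, point)
    buf <- state@config$buffer
    minN <- max(5L * state@p,
                if (is.null(state@config$minWarmup)) 0L
                else state@config$minWarmup)
    if (length(buf) >= minN) {
      X <- do.call(rbind, lapply(buf, slot, "x"))
      if (qr(crossprod(X))$rank == state@p) {
        data <- batchData(X, do.call(rbind, lapply(buf, slot, "z")),
                          vapply(buf, slot, numeric(1), "y"),
                          vapply(buf, slot, character(1), "id"))
        cfg <- state@config
        cfg$warming <- NULL
        cfg$buffer <- NULL
        state <- semaWarmStart(data, config = cfg)
      }
    }
    return(list(prediction = NA_real_, state = state))
  }
  ind <- state@individuals[[point@id]]
  pred <- predictResponse(state@params, point,
                          bHat = if (is.null(ind)) NULL else ind$bHat)
  state <- semaIngest(state, point)
  state <- semaEStepIndividual(state, point@id)
  state <- semaMStep(state)
  list(prediction = pred, state = state)
}

#' Warm-start a streaming state from a training set
#'
#' Fits the model to the training data by batch EM (default tolerance 1e-4,
#' at most 800 iterations), builds every individual's summary from the
#' training rows, computes all CDSS contributions under the fitted
#' parameters, and inverts X'X once directly.
#'
#' @param data a [BatchData-class] training set; X'X must have full rank.
#' @param start optional EM start values (defaults to the OLS-based start).
#' @param tol,maxIter passed to [fitEM()].
#' @param config tuning constants for the resulting state.
#' @return A consistent [SemaState-class] ready for streaming.
#' @export
semaWarmStart <- function(data, start = NULL, tol = 1e-4, maxIter = 800L,
                          config = list()) {
  fit <- fitEM(data, start = start, tol = tol, maxIter = maxIter)
  .buildState(data, fit@params, .semaConfig(config))
}

# assemble a streaming state from raw rows at fixed parameters
.buildState <- function(data, params, config) {
  idf <- factor(data@id)
  cs <- cppBuildState(data@X, data@Z, data@y, as.integer(idf) - 1L,
                      nlevels(idf), params@beta, params@phi, params@sigma2,
                      config$phiFloorRel)
  .stateFromCpp(cs, levels(idf), config)
}

#' Sweep through all stored individuals
#'
#' Re-runs the online E-step for every stored individual (using only their
#' aggregated summaries, never raw data) and then performs one M-step.  This
#' is the periodic "update" pass that refreshes the contributions of
#' individuals who have not returned recently.
#'
#' @param state a [SemaState-class].
#' @return the updated state.
#' @export
semaSweep <- function(state) {
  for (key in names(state@individuals))
    state <- semaEStepIndividual(state, key)
  semaMStep(state)
}

## ---- conversions between the S4 state and the compiled parallel arrays ----

.stateFromCpp <- function(cs, levels, config) {
  p <- cs$p; r <- cs$r
  inds <- list()
  for (k in seq_along(levels)) {
    if (cs$seen[k] == 0L) next
    inds[[levels[k]]] <- list(
      nj = cs$nj[k],
      ZtZ = matrix(cs$ZtZ[, , k], r, r), XtZ = matrix(cs$XtZ[, , k], p, r),
      XtXj = matrix(cs$XtXj[, , k], p, p),
      Zty = cs$Zty[, k], Xtyj = cs$Xtyj[, k], yty = cs$yty[k],
      bHat = cs$bhat[, k], Cinv = matrix(cs$Cinv[, , k], r, r),
      t1j = cs$t1j[, k], T2j = matrix(cs$T2j[, , k], r, r), t3j = cs$t3j[k])
  }
  state <- new("SemaState", n = as.integer(cs$n), J = as.integer(cs$J),
               p = as.integer(p), r = as.integer(r),
               XtX = cs$XtX, XtXinv = cs$XtXinv, xy = as.numeric(cs$xy),
               t1 = as.numeric(cs$t1), T2 = cs$T2, t3 = as.numeric(cs$t3),
               params = mixedModelParams(cs$beta, cs$phi, cs$sigma2),
               individuals = inds, config = config)
  validObject(state)
  state
}

.stateToCpp <- function(state, levels) {
  p <- state@p; r <- state@r
  Jmax <- length(levels)
  cs <- list(n = state@n, J = state@J, p = p, r = r,
             XtX = state@XtX, XtXinv = state@XtXinv, xy = state@xy,
             t1 = state@t1, T2 = state@T2, t3 = state@t3,
             beta = state@params@beta, phi = state@params@phi,
             sigma2 = state@params@sigma2,
             nj = integer(Jmax), seen = integer(Jmax),
             ZtZ = array(0, c(r, r, Jmax)), XtZ = array(0, c(p, r, Jmax)),
             XtXj = array(0, c(p, p, Jmax)),
             Zty = matrix(0, r, Jmax), Xtyj = matrix(0, p, Jmax),
             yty = numeric(Jmax), bhat = matrix(0, r, Jmax),
             Cinv = array(0, c(r, r, Jmax)), t1j = matrix(0, p, Jmax),
             T2j = array(0, c(r, r, Jmax)), t3j = numeric(Jmax))
  for (key in names(state@individuals)) {
    k <- match(key, levels)
    ind <- state@individuals[[key]]
    cs$nj[k] <- ind$nj
    cs$seen[k] <- 1L
    cs$ZtZ[, , k] <- ind$ZtZ
    cs$XtZ[, , k] <- ind$XtZ
    cs$XtXj[, , k] <- ind$XtXj
    cs$Zty[, k] <- ind$Zty
    cs$Xtyj[, k] <- ind$Xtyj
    cs$yty[k] <- ind$yty
    cs$bhat[, k] <- ind$bHat
    cs$Cinv[, , k] <- ind$Cinv
    cs$t1j[, k] <- ind$t1j
    cs$T2j[, , k] <- ind$T2j
    cs$t3j[k] <- ind$t3j
  }
  cs
}

#' Run the streaming estimator over many points
#'
#' Processes the supplied points in order through the compiled kernel
#' (prediction before update, per-point E- and M-steps, optional periodic
#' sweeps) and returns the updated state, the prequential predictions, and
#' parameter snapshots at the requested global stream positions.
#'
#' @param state a warm-started [SemaState-class].
#' @param X,Z,y,id the points to stream, in arrival order (or pass a
#'   [DataStream-class] as \code{X}).
#' @param sweepEvery run a full sweep every this many points (0 = never; the
#'   "update" variant uses 1000).
#' @param checkpointAt integer vector of global n values at which to snapshot
#'   the parameters.
#' @return list with \code{state}, \code{predictions} and \code{checkpoints}
#'   (data.frame, one row per snapshot).
#' @export
semaStream <- function(state, X, Z = NULL, y = NULL, id = NULL,
                       sweepEvery = 0L, checkpointAt = integer()) {
  if (is(X, "DataStream")) {
    m <- streamMatrices(X)
    X <- m$X; Z <- m$Z; y <- m$y; id <- m$id
  }
  levels <- union(names(state@individuals), unique(as.character(id)))
  cs <- .stateToCpp(state, levels)
  res <- cppSemaStream(cs, as.matrix(X), as.matrix(Z), as.numeric(y),
                       match(as.character(id), levels) - 1L,
                       as.integer(sweepEvery),
                       as.integer(state@config$reinvertEvery),
                       state@config$phiFloorRel,
                       as.integer(checkpointAt))
  out <- .stateFromCpp(res$state, levels, state@config)
  cps <- .checkpointFrame(res$checkpointParams, checkpointAt, state@p, state@r)
  list(state = out, predictions = as.numeric(res$predictions),
       checkpoints = cps)
}

.checkpointFrame <- function(mat, at, p, r) {
  nms <- .paramNames(p, r)
  if (length(at) == 0L)
    return(data.frame(n = integer(), parameter = character(),
                      value = numeric()))
  data.frame(n = rep(as.integer(at), each = length(nms)),
             parameter = rep(nms, times = length(at)),
             value = as.numeric(t(mat)))
}
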