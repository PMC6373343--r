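## Prequential protocol and the summary statistics it reports.

#' Online (running) mean
#'
#' One step of the online mean update
#' \eqn{\bar x \leftarrow \bar x + (x_t - \bar x)/(n + 1)}.
#'
#' @param state numeric vector \code{c(n, mean)}.
#' @param x the new value.
#' @return updated \code{c(n, mean)}.
#' @examples
#' runningMean(c(0, 0), 7)  # c(1, 7)
#' @export
runningMean <- function(state, x) {
  n <- state[[1]] + 1
  c(n, state[[2]] + (x - state[[2]]) / n)
}

#' Prequential run of one estimator over a stream
#'
#' The first \code{trainN} points form the warm-up training set: batch EM is
#' run on them (start values from \code{start}, or the OLS-based default) and
#' the resulting parameters seed the streaming phase.  Every later point is
#' predicted \emph{before} it updates any state; parameter snapshots are taken
#' at \code{checkpointAt} (global stream positions).
#'
#' Methods: \code{"sema"} (per-point streaming EM), \code{"sema_update"}
#' (plus a sweep over all stored individuals every \code{sweepEvery} points),
#' \code{"em_batched"} (batch EM refit on all data so far every
#' \code{refitEvery} points, at most \code{refitMaxIter} iterations, run to
#' convergence at stream end), \code{"swem"} (same but on a sliding window of
#' the \code{window} most recent points, no final convergence run).
#'
#' @param stream a [DataStream-class] (or list with X, Z, y, id).
#' @param method one of "sema", "sema_update", "em_batched", "swem".
#' @param trainN training-set size (default 2000).
#' @param start optional [MixedModelParams-class] start for the warm-up EM.
#' @param checkpointAt global positions for parameter snapshots; defaults to
#'   every 1000 points plus 25,000 and the stream end.
#' @param sweepEvery sweep cadence for "sema_update" (default 1000).
#' @param refitEvery refit cadence for the EM comparators (default 1000).
#' @param refitMaxIter iteration cap per refit (default 20).
#' @param window sliding-window size m for "swem" (default 10,000).
#' @param tol EM convergence tolerance (default 1e-4).
#' @return A [PrequentialResult-class].
#' @export
prequentialRun <- function(stream,
                           method = c("sema", "sema_update", "em_batched",
                                      "swem"),
                           trainN = 2000L, start = NULL,
                           checkpointAt = NULL, sweepEvery = 1000L,
                           refitEvery = 1000L, refitMaxIter = 20L,
                           window = 10000L, tol = 1e-4) {
  method <- match.arg(method)
  m <- if (is(stream, "DataStream")) streamMatrices(stream) else stream
  nTotal <- length(m$y)
  if (trainN >= nTotal) stop("trainN must be smaller than the stream length")
  if (is.null(checkpointAt)) {
    checkpointAt <- seq(trainN, nTotal, by = 1000L)
    checkpointAt <- sort(unique(c(checkpointAt,
                                  if (nTotal >= 25000L) 25000L, nTotal)))
  }
  checkpointAt <- as.integer(checkpointAt)
  tr <- seq_len(trainN)
  train <- batchData(m$X[tr, , drop = FALSE], m$Z[tr, , drop = FALSE],
                     m$y[tr], m$id[tr])
  warm <- fitEM(train, start = start, tol = tol, maxIter = 800L)
  p <- ncol(m$X); r <- ncol(m$Z)

  if (method %in% c("sema", "sema_update")) {
    state <- .buildState(train, warm@params, .semaConfig(list()))
    rest <- setdiff(seq_len(nTotal), tr)
    run <- semaStream(state, m$X[rest, , drop = FALSE],
                      m$Z[rest, , drop = FALSE], m$y[rest], m$id[rest],
                      sweepEvery = if (method == "sema_update") sweepEvery
                                   else 0L,
                      checkpointAt = checkpointAt)
    final <- modelParams(run$state)
    preds <- run$predictions
    cps <- run$checkpoints
  } else {
    idf <- factor(m$id)
    res <- cppWindowStream(m$X, m$Z, m$y, as.integer(idf) - 1L,
                           nlevels(idf), as.integer(trainN),
                           if (method == "swem") as.integer(window) else 0L,
                           as.integer(refitEvery), as.integer(refitMaxIter),
                           tol, warm@params@beta, warm@params@phi,
                           warm@params@sigma2, 1e-8, checkpointAt,
                           method == "em_batched", 800L)
    final <- mixedModelParams(res$beta, res$phi, res$sigma2)
    preds <- as.numeric(res$predictions)
    cps <- .checkpointFrame(res$checkpointParams, checkpointAt, p, r)
  }
  # positions at or before the training set are snapshots of the warm fit
  early <- cps$n <= trainN
  if (any(early)) {
    packed <- c(warm@params@beta,
                warm@params@phi[lower.tri(warm@params@phi, diag = TRUE)],
                warm@params@sigma2)
    cps$value[early] <- rep(packed, times = length(unique(cps$n[early])))
  }
  post <- setdiff(seq_len(nTotal), tr)
  new("PrequentialResult", method = method,
      log = data.frame(t = post, id = m$id[post], y = m$y[post],
                       yhat = preds),
      checkpoints = cps, finalParams = final, trainN = as.integer(trainN))
}

.errors <- function(log) {
  if (is(log, "PrequentialResult")) log <- log@log
  if (!nrow(log)) stop("the prediction log is empty")
  log$yhat - log$y
}

#' Mean absolute prediction error
#' @param log a [PrequentialResult-class] or its log data.frame.
#' @return scalar MAE.
#' @export
mae <- function(log) mean(abs(.errors(log)))

#' Root-mean-squared prediction error
#' @param log a [PrequentialResult-class] or its log data.frame.
#' @return scalar RMSE.
#' @export
rmse <- function(log) sqrt(mean(.errors(log)^2))

#' Moving-window MAE
#'
#' MAE per window of \code{window} consecutive predictions, advancing by
#' \code{shift} points (100 in the simulation figures, 500 in the
#' application-style figures).
#'
#' @param log a [PrequentialResult-class] or its log data.frame.
#' @param window window length (default 1000).
#' @param shift step between consecutive windows (default 100).
#' @return data.frame with the window start and its MAE.
#' @export
movingMae <- function(log, window = 1000L, shift = 100L) {
  e <- abs(.errors(log))
  if (window > length(e)) stop("window is longer than the prediction log")
  starts <- seq(1L, length(e) - window + 1L, by = shift)
  data.frame(start = starts,
             mae = vapply(starts, function(s) mean(e[s:(s + window - 1L)]),
                          numeric(1)))
}

#' Empirical confidence interval
#'
#' Empirical quantiles (linear interpolation between order statistics,
#' \code{stats::quantile} type 7) at \code{(1 - level)/2} and
#' \code{1 - (1 - level)/2}.
#'
#' @param values numeric vector (at least 2 values).
#' @param level coverage (default 0.95).
#' @return named vector \code{c(low, high)}.
#' @export
empiricalCi <- function(values, level = 0.95) {
  if (length(values) < 2L) stop("need at least 2 values")
  a <- (1 - level) / 2
  q <- stats::quantile(values, probs = c(a, 1 - a), names = FALSE, type = 7)
  c(low = q[1], high = q[2])
}

#' Monte-Carlo standard error of an estimator
#'
#' \deqn{\sqrt{\tfrac1{S-1}\sum_s(\hat\theta_s - \theta)^2}\,/\,\sqrt S,}
#' centered on the \emph{true} value, not the sample mean.
#'
#' @param estimates estimates across S simulation runs.
#' @param truth the data-generating value.
#' @return scalar Monte-Carlo SE.
#' @export
mcSe <- function(estimates, truth) {
  S <- length(estimates)
  if (S < 2L) stop("need at least 2 runs")
  sqrt(sum((estimates - truth)^2) / (S - 1)) / sqrt(S)
}

#' Tidy summary table of a set of prequential runs
#'
#' The machine-readable analogue of a results table: one row per (condition,
#' method, replication, checkpoint, statistic).
#'
#' @param results named list: results[[condition]][[method]] is a list of
#'   [PrequentialResult-class], one per replication.
#' @return a long data.frame.
#' @export
resultTable <- function(results) {
  rows <- list()
  for (cond in names(results)) for (meth in names(results[[cond]])) {
    runs <- results[[cond]][[meth]]
    for (s in seq_along(runs)) {
      res <- runs[[s]]
      cp <- res@checkpoints
      rows[[length(rows) + 1L]] <- rbind(
        data.frame(condition = cond, method = meth, replication = s,
                   checkpoint = cp$n, statistic = cp$parameter,
                   value = cp$value),
        data.frame(condition = cond, method = meth, replication = s,
                   checkpoint = max(res@log$t),
                   statistic = c("mae", "rmse"),
                   value = c(mae(res), rmse(res))))
    }
  }
  do.call(rbind, rows)
}
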