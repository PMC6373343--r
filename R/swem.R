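## Sliding-window EM comparator: batch EM refit over only the m most recent
## data points.  The R-level buffer operations are exact and small-scale; the
## streaming comparator in prequentialRun() runs the same logic in compiled
## form with incremental add/evict of cross-products.

#' Push a point into a sliding window
#'
#' Appends the point; when the buffer exceeds its capacity the oldest point is
#' evicted (strictly FIFO, per data point, not per individual).
#'
#' @param buffer a [WindowBuffer-class].
#' @param point a [DataPoint-class].
#' @return the updated buffer.
#' @export
pushEvict <- function(buffer, point) {
  recs <- c(buffer@records, point)
  if (length(recs) > buffer@capacity)
    recs <- recs[-seq_len(length(recs) - buffer@capacity)]
  buffer@records <- recs
  buffer
}

#' Batch data held in a window
#'
#' @param buffer a [WindowBuffer-class] with at least one record.
#' @return A [BatchData-class] of the window contents, in arrival order.
#' @export
windowBatchData <- function(buffer) {
  if (!length(buffer@records)) stop("the window is empty")
  batchData(do.call(rbind, lapply(buffer@records, slot, "x")),
            do.call(rbind, lapply(buffer@records, slot, "z")),
            vapply(buffer@records, slot, numeric(1), "y"),
            vapply(buffer@records, slot, character(1), "id"))
}

#' Refit the model on the current window
#'
#' Batch EM over the window contents only, warm-started from the previous
#' estimates.  Individuals with no remaining rows in the window take no part
#' in the refit.  On a rank-deficient window the previous estimates are kept
#' and a warning is issued.
#'
#' @param buffer a [WindowBuffer-class].
#' @param start previous [MixedModelParams-class] estimates.
#' @param maxIter cap on EM iterations (default 20).
#' @param tol convergence tolerance.
#' @return A [MixedModelParams-class].
#' @export
refitWindow <- function(buffer, start, maxIter = 20L, tol = 1e-4) {
  data <- windowBatchData(buffer)
  if (qr(crossprod(data@X))$rank < ncol(data@X)) {
    warning("window X'X is rank deficient; keeping previous estimates")
    return(start)
  }
  fitEM(data, start = start, tol = tol, maxIter = maxIter)@params
}
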