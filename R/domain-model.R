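## Basic model computations: prediction and the two log-likelihoods.

#' Predict a response for one data point
#'
#' Returns \eqn{x'\beta + z'\hat b_j}.  For an individual that has never been
#' seen, pass \code{bHat = NULL} (or zeros): the prediction then falls back to
#' the fixed part \eqn{x'\beta} (the cold-start rule used throughout the
#' prequential protocol).
#'
#' @param params a [MixedModelParams-class].
#' @param x fixed-effect covariates (length p), or a [DataPoint-class].
#' @param z random-effect covariates (length r); ignored when \code{x} is a
#'   [DataPoint-class].
#' @param bHat posterior mean of the individual's random effects, or NULL.
#' @return the predicted response (scalar).
#' @examples
#' p <- mixedModelParams(100, matrix(50), 5)
#' predictResponse(p, x = 1, z = 1, bHat = NULL)  # new individual: 100
#' @export
predictResponse <- function(params, x, z = NULL, bHat = NULL) {
  if (is(x, "DataPoint")) {
    z <- x@z
    x <- x@x
  }
  if (length(x) != length(params@beta))
    stop("x has length ", length(x), " but the model has p = ",
         length(params@beta))
  r <- nrow(params@phi)
  if (length(z) != r)
    stop("z has length ", length(z), " but the model has r = ", r)
  if (is.null(bHat)) bHat <- numeric(r)
  if (length(bHat) != r)
    stop("bHat has length ", length(bHat), " but the model has r = ", r)
  sum(x * params@beta) + sum(z * bHat)
}

#' Complete-data log-likelihood
#'
#' The log-likelihood of the responses and the random effects jointly, as if
#' the \eqn{b_j} were observed:
#' \deqn{-\tfrac n2 \ln\sigma^2 - \tfrac1{2\sigma^2}\sum_{ij}(y_{ij}-x'\beta-z'b_j)^2
#'       - \tfrac J2 \ln|\Phi| - \tfrac12\sum_j b_j'\Phi^{-1}b_j.}
#' The additive \eqn{-\tfrac n2\ln 2\pi - \tfrac{Jr}2\ln 2\pi} constants are
#' deliberately omitted; do not compare this value against
#' [marginalLogLik()], which includes them.
#'
#' @param params a [MixedModelParams-class].
#' @param data a [BatchData-class].
#' @param b matrix (J x r) or named list of per-individual random-effect
#'   vectors, in the order of \code{unique(data@id)} when a matrix.
#' @return the complete-data log-likelihood (scalar).
#' @export
completeDataLogLik <- function(params, data, b) {
  ids <- unique(data@id)
  J <- length(ids)
  r <- nrow(params@phi)
  if (is.list(b)) b <- do.call(rbind, b[ids])
  b <- matrix(b, nrow = J)
  phiInv <- tryCatch(solve(params@phi), error = function(e)
    stop("phi is singular", call. = FALSE))
  ldphi <- determinant(params@phi, logarithm = TRUE)
  resid <- data@y - as.numeric(data@X %*% params@beta) -
    rowSums(data@Z * b[match(data@id, ids), , drop = FALSE])
  n <- length(data@y)
  -n / 2 * log(params@sigma2) - sum(resid^2) / (2 * params@sigma2) -
    J / 2 * as.numeric(ldphi$modulus) -
    sum(vapply(seq_len(J), function(j) {
      bj <- b[j, ]
      as.numeric(t(bj) %*% phiInv %*% bj)
    }, numeric(1))) / 2
}

#' Marginal (observed-data) log-likelihood
#'
#' Sums, over individuals, the multivariate-normal log density of \eqn{y_j}
#' with mean \eqn{X_j\beta} and covariance
#' \eqn{V_j = Z_j \Phi Z_j' + \sigma^2 I}.  Unlike [completeDataLogLik()],
#' the \eqn{2\pi} constants are included here; the function exists to verify
#' that EM iterations never decrease the observed-data likelihood.
#'
#' @param params a [MixedModelParams-class].
#' @param data a [BatchData-class].
#' @return the marginal log-likelihood (scalar).
#' @export
marginalLogLik <- function(params, data) {
  ids <- unique(data@id)
  total <- 0
  for (j in ids) {
    rows <- which(data@id == j)
    Zj <- data@Z[rows, , drop = FALSE]
    mu <- as.numeric(data@X[rows, , drop = FALSE] %*% params@beta)
    V <- Zj %*% params@phi %*% t(Zj) + diag(params@sigma2, length(rows))
    ch <- tryCatch(chol(V), error = function(e)
      stop("marginal covariance for individual '", j,
           "' is not positive definite", call. = FALSE))
    dev <- backsolve(ch, data@y[rows] - mu, transpose = TRUE)
    total <- total - length(rows) / 2 * log(2 * pi) -
      sum(log(diag(ch))) - sum(dev^2) / 2
  }
  total
}
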