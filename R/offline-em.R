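## Classical batch EM for the multilevel model.  The E-step imputes the
## posterior mean and uncertainty of each individual's random effects; the
## M-step then has closed forms in the complete-data sufficient statistics
## (CDSS) t1, T2, t3.

.phiInvFloored <- function(phi, floorRel = 1e-8) {
  r <- nrow(phi)
  eg <- eigen((phi + t(phi)) / 2, symmetric = TRUE)
  fl <- floorRel * max(sum(diag(phi)), 1e-4) / r
  vals <- pmax(eg$values, fl)
  eg$vectors %*% diag(1 / vals, r) %*% t(eg$vectors)
}

#' Posterior of one individual's random effects
#'
#' Computes \eqn{C_j = Z_j'Z_j + \sigma^2\Phi^{-1}} and
#' \eqn{\hat b_j = C_j^{-1}(Z_j'y_j - Z_j'X_j\beta)}.  An individual with no
#' rows gets the prior: \eqn{C_j = \sigma^2\Phi^{-1}}, \eqn{\hat b_j = 0}.
#'
#' @param params a [MixedModelParams-class].
#' @param X,Z,y that individual's design blocks and responses (possibly with
#'   zero rows).
#' @return A [RanefPosterior-class].
#' @export
ranefPosterior <- function(params, X, Z, y) {
  X <- matrix(X, ncol = length(params@beta))
  Z <- matrix(Z, ncol = nrow(params@phi))
  phiInv <- tryCatch(solve(params@phi), error = function(e)
    stop("phi is singular; regularize before the E-step", call. = FALSE))
  C <- crossprod(Z) + params@sigma2 * phiInv
  C <- (C + t(C)) / 2
  Cinv <- solve(C)
  Cinv <- (Cinv + t(Cinv)) / 2
  bHat <- as.numeric(Cinv %*% (crossprod(Z, y) - crossprod(Z, X %*% params@beta)))
  # name Class explicitly: a partially matched `C =` would capture it
  new(Class = "RanefPosterior", bHat = bHat, C = C, Cinv = Cinv)
}

#' Batch E-step
#'
#' One pass over all individuals: posteriors plus the CDSS
#' \deqn{t_1 = \sum_j X_j'Z_j\hat b_j,\quad
#'       T_2 = \sum_j \hat b_j\hat b_j' + \sigma^2\sum_j C_j^{-1},\quad
#'       t_3 = \sum_j u_j'u_j + \sigma^2\,\mathrm{tr}\big(\sum_j C_j^{-1}Z_j'Z_j\big),}
#' with \eqn{u_j = y_j - X_j\beta - Z_j\hat b_j}.
#'
#' @param params a [MixedModelParams-class] (the previous iteration's values).
#' @param data a [BatchData-class].
#' @return list with elements \code{cdss} (list \code{t1}, \code{T2},
#'   \code{t3}, \code{sumCinv}) and \code{posteriors} (named list of
#'   [RanefPosterior-class]).
#' @export
eStep <- function(params, data) {
  ids <- unique(data@id)
  p <- length(params@beta)
  r <- nrow(params@phi)
  t1 <- numeric(p)
  T2 <- matrix(0, r, r)
  t3 <- 0
  sumCinv <- matrix(0, r, r)
  posteriors <- vector("list", length(ids))
  names(posteriors) <- ids
  for (j in ids) {
    rows <- which(data@id == j)
    Xj <- data@X[rows, , drop = FALSE]
    Zj <- data@Z[rows, , drop = FALSE]
    yj <- data@y[rows]
    post <- ranefPosterior(params, Xj, Zj, yj)
    posteriors[[j]] <- post
    t1 <- t1 + as.numeric(crossprod(Xj, Zj) %*% post@bHat)
    T2 <- T2 + tcrossprod(post@bHat) + params@sigma2 * post@Cinv
    u <- yj - as.numeric(Xj %*% params@beta) - as.numeric(Zj %*% post@bHat)
    t3 <- t3 + sum(u^2) +
      params@sigma2 * sum(diag(post@Cinv %*% crossprod(Zj)))
    sumCinv <- sumCinv + post@Cinv
  }
  list(cdss = list(t1 = t1, T2 = (T2 + t(T2)) / 2, t3 = t3,
                   sumCinv = sumCinv),
       posteriors = posteriors)
}

#' Batch M-step
#'
#' Closed-form maximizers given the CDSS:
#' \eqn{\beta = (X'X)^{-1}(X'y - t_1)}, \eqn{\Phi = T_2/J},
#' \eqn{\sigma^2 = t_3/n}.
#'
#' @param cdss list with \code{t1}, \code{T2}, \code{t3} (as from [eStep()]).
#' @param XtX global p x p cross-product \eqn{\sum_j X_j'X_j}.
#' @param Xty global \eqn{\sum_j X_j'y_j}.
#' @param n total number of observations.
#' @param J number of individuals.
#' @return A [MixedModelParams-class].
#' @export
mStep <- function(cdss, XtX, Xty, n, J) {
  qrx <- qr(XtX)
  if (qrx$rank < ncol(XtX))
    stop("X'X is rank deficient (deficiency ", ncol(XtX) - qrx$rank, ")")
  beta <- as.numeric(solve(qrx, Xty - cdss$t1))
  phi <- cdss$T2 / J
  phi <- (phi + t(phi)) / 2
  mixedModelParams(beta, phi, max(cdss$t3 / n, 1e-10))
}

.olsStart <- function(data) {
  fit <- stats::lm.fit(data@X, data@y)
  s2 <- max(sum(fit$residuals^2) / max(length(data@y) - fit$rank, 1), 1e-6)
  r <- ncol(data@Z)
  mixedModelParams(ifelse(is.na(fit$coefficients), 0, fit$coefficients),
                   diag(s2, r), s2)
}

#' Fit the multilevel model by batch EM
#'
#' Alternates [eStep()] and [mStep()] (in compiled form) until the largest
#' absolute change over all parameters (beta entries, lower-triangular phi
#' entries, sigma2) drops below \code{tol}, or \code{maxIter} is reached.
#' When no start values are supplied, beta comes from pooled OLS, and phi and
#' sigma2 from the OLS residual variance.
#'
#' @param data a [BatchData-class].
#' @param start optional [MixedModelParams-class] start values.
#' @param tol convergence tolerance on the parameter change (default 1e-4).
#' @param maxIter maximum EM iterations (default 800).
#' @return An [EmFit-class] with the final parameters and the per-iteration
#'   parameter trace.
#' @examples
#' cond <- conditionPreset("A")
#' s <- simulateStream(cond, nTotal = 800, J = 40, seed = 1)
#' m <- streamMatrices(s)
#' fit <- fitEM(batchData(m$X, m$Z, m$y, m$id))
#' fixedEffects(fit)[1]
#' @export
fitEM <- function(data, start = NULL, tol = 1e-4, maxIter = 800L) {
  if (is.null(start)) start <- .olsStart(data)
  idf <- factor(data@id)
  suff <- cppBuildSuff(data@X, data@Z, data@y, as.integer(idf) - 1L,
                       nlevels(idf))
  res <- cppEmFit(suff, start@beta, start@phi, start@sigma2,
                  tol, as.integer(maxIter), 1e-8)
  params <- mixedModelParams(res$beta, res$phi, res$sigma2)
  tr <- res$trace
  colnames(tr) <- .paramNames(length(start@beta), nrow(start@phi))
  new("EmFit", params = params, trace = tr,
      iterations = as.integer(res$iterations), converged = res$converged)
}

# names matching the packing order used by the compiled code:
# beta, then lower-triangular phi by column, then sigma2
.paramNames <- function(p, r) {
  phiNames <- unlist(lapply(seq_len(r), function(cc)
    paste0("phi.", seq(cc, r), ".", cc)))
  c(paste0("beta.", seq_len(p)), phiNames, "sigma2")
}

#' Refit in incremental batches
#'
#' The batched comparator: refit by EM every \code{refitEvery} new points with
#' at most \code{maxIter} iterations, warm-started from the previous
#' estimates.  Used through [prequentialRun()] with
#' \code{method = "em_batched"}.
#'
#' @param data a [BatchData-class] (all data so far).
#' @param start previous estimates.
#' @param maxIter cap on EM iterations per refit (default 20).
#' @param tol convergence tolerance.
#' @return An [EmFit-class].
#' @export
refitBatch <- function(data, start, maxIter = 20L, tol = 1e-4) {
  fitEM(data, start = start, tol = tol, maxIter = maxIter)
}
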