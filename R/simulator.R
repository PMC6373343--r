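## Synthetic data-stream generator.  Four named conditions share 15 true
## fixed effects; condition A has a single random intercept with variance 50,
## conditions B-D add random slopes on the first four level-1 continuous
## covariates (variances 0.2, 0.6, 1.8, 5.0) with exchangeable correlation 0,
## .15 or .5.  Residual variance is 5 throughout.  Streams draw an individual
## uniformly at random per point, so each of the J = 1000 individuals has 50
## observations in expectation over a 50,000-point stream.

.condBeta <- c(100.0, 0.1, 0.5, 0.9, 1.3, 1.7, 2.1, 2.5, 2.9, 3.3, 3.7,
               4.1, 4.5, 4.9, 5.3)

#' Named simulation conditions
#'
#' @param name one of "A" (random intercept only), "B" (intercept + 4 slopes,
#'   uncorrelated), "C" (correlation .15), "D" (correlation .5).
#' @return A [SimulationCondition-class].
#' @examples
#' ranefCovariance(conditionPreset("A"))  # 1 x 1 matrix, value 50
#' @export
conditionPreset <- function(name) {
  name <- match.arg(name, c("A", "B", "C", "D"))
  if (name == "A") {
    phi <- matrix(50)
    zCols <- 1L
  } else {
    v <- c(50, 0.2, 0.6, 1.8, 5.0)
    cor <- c(B = 0, C = 0.15, D = 0.5)[[name]]
    phi <- cor * sqrt(outer(v, v))
    diag(phi) <- v
    zCols <- 1:5
  }
  new("SimulationCondition", name = name, beta = .condBeta, phi = phi,
      sigma2 = 5, J = 1000L, nTotal = 50000L, zCols = as.integer(zCols))
}

setMethod("ranefCovariance", "SimulationCondition", function(object) object@phi)
setMethod("fixedEffects", "SimulationCondition", function(object) object@beta)
setMethod("residualVariance", "SimulationCondition",
          function(object) object@sigma2)

# dummy coding with equiprobable categories, reference level dropped
.dummies <- function(k, n) {
  cat <- sample.int(k, n, replace = TRUE)
  m <- matrix(0, n, k - 1L)
  for (lev in 2:k) m[cat == lev, lev - 1L] <- 1
  m
}

#' Draw a population of individuals
#'
#' Level-2 covariates (3 standard-normal continuous variables, a 2-category
#' and a 3-category factor with equiprobable levels, dummy coded) and true
#' random-effect coefficients \eqn{b_j \sim MVN(0, \Phi)}, one row per
#' individual.
#'
#' @param cond a [SimulationCondition-class].
#' @param J number of individuals (defaults to the condition's).
#' @param seed optional integer seed for reproducibility.
#' @return A [Population-class].
#' @export
makePopulation <- function(cond, J = cond@J, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r <- nrow(cond@phi)
  l2 <- cbind(MASS::mvrnorm(J, mu = numeric(3), Sigma = diag(3)),
              .dummies(2L, J), .dummies(3L, J))
  colnames(l2) <- c(paste0("w", 1:3), "gender2", "edu2", "edu3")
  b <- MASS::mvrnorm(J, mu = numeric(r), Sigma = cond@phi)
  b <- matrix(b, nrow = J)
  new("Population", condition = cond, id = sprintf("id%04d", seq_len(J)),
      level2 = l2, b = b)
}

#' Draw a data stream from a population
#'
#' Each point picks an individual uniformly at random, draws fresh level-1
#' covariates (5 standard-normal continuous variables and a 4-category factor,
#' resampled per observation), and generates
#' \eqn{y = x'\beta + z'b_j + \epsilon}, \eqn{\epsilon \sim N(0, \sigma^2)}.
#' The fixed-effect vector x is, in order: intercept, the 5 level-1 continuous
#' covariates, 3 level-1 factor dummies, 3 level-2 continuous covariates, and
#' 3 level-2 factor dummies.  z comprises the x columns indexed by the
#' condition's \code{zCols}.
#'
#' @param pop a [Population-class].
#' @param nTotal stream length (defaults to the condition's 50,000).
#' @param seed optional integer seed.
#' @return A [DataStream-class].
#' @export
makeStream <- function(pop, nTotal = pop@condition@nTotal, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cond <- pop@condition
  J <- nrow(pop@b)
  idx <- sample.int(J, nTotal, replace = TRUE)
  l1c <- matrix(rnorm(nTotal * 5L), nTotal, 5L)
  X <- cbind(1, l1c, .dummies(4L, nTotal), pop@level2[idx, , drop = FALSE])
  xCols <- c("intercept", paste0("v", 1:5), paste0("f", 2:4),
             colnames(pop@level2))
  colnames(X) <- xCols
  Z <- X[, cond@zCols, drop = FALSE]
  b <- pop@b[idx, , drop = FALSE]
  y <- as.numeric(X %*% cond@beta) + rowSums(Z * b) +
    rnorm(nTotal, sd = sqrt(cond@sigma2))
  df <- data.frame(id = pop@id[idx], y = y, X, check.names = FALSE)
  header <- list(p = ncol(X), r = length(cond@zCols), xCols = xCols,
                 zCols = xCols[cond@zCols], condition = cond@name,
                 seed = seed)
  new("DataStream", header = header, data = df)
}

#' Simulate a condition end to end
#'
#' Convenience wrapper: [makePopulation()] then [makeStream()] under one seed.
#'
#' @param cond a [SimulationCondition-class] or a condition name.
#' @param nTotal stream length.
#' @param J number of individuals.
#' @param seed integer seed.
#' @return A [DataStream-class].
#' @export
simulateStream <- function(cond, nTotal = NULL, J = NULL, seed = NULL) {
  if (is.character(cond)) cond <- conditionPreset(cond)
  if (!is.null(seed)) set.seed(seed)
  pop <- makePopulation(cond, J = if (is.null(J)) cond@J else J)
  makeStream(pop, nTotal = if (is.null(nTotal)) cond@nTotal else nTotal)
}

#' Design matrices of a stream
#'
#' @param stream a [DataStream-class].
#' @return list with \code{X}, \code{Z}, \code{y}, \code{id}.
#' @export
streamMatrices <- function(stream) {
  h <- stream@header
  df <- stream@data
  list(X = as.matrix(df[, h$xCols, drop = FALSE]),
       Z = as.matrix(df[, h$zCols, drop = FALSE]),
       y = df$y, id = as.character(df$id))
}

#' Two-regime stream with an abrupt mean shift
#'
#' A condition-A-style stream whose true intercept jumps by \code{shift} at
#' \code{changeAt}; used to exercise the sliding-window comparator under
#' concept drift.
#'
#' @param cond a [SimulationCondition-class].
#' @param nTotal stream length.
#' @param changeAt point index at which the intercept changes.
#' @param shift added to the intercept from \code{changeAt} onward.
#' @param seed integer seed.
#' @return A [DataStream-class].
#' @export
makeShiftStream <- function(cond, nTotal, changeAt, shift, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pop <- makePopulation(cond)
  s <- makeStream(pop, nTotal = nTotal)
  post <- seq_len(nTotal) >= changeAt
  s@data$y[post] <- s@data$y[post] + shift
  s@header$shiftAt <- changeAt
  s
}
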