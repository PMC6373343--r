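test_that("random-effect posterior matches its closed form", {
  params <- trueParams("A")
  d <- smallBatch(seed = 5, n = 100, J = 10)
  j <- unique(d@id)[1]
  blk <- rowsOf(d, j)
  post <- ranefPosterior(params, blk$X, blk$Z, blk$y)
  C <- crossprod(blk$Z) + params@sigma2 * solve(params@phi)
  expect_equal(post@C, C, tolerance = 1e-12, ignore_attr = TRUE)
  bHat <- solve(C, crossprod(blk$Z, blk$y - blk$X %*% params@beta))
  expect_equal(post@bHat, as.numeric(bHat), tolerance = 1e-12)
})

test_that("an individual with no rows gets the prior", {
  params <- trueParams("A")
  post <- ranefPosterior(params, matrix(0, 0, 15), matrix(0, 0, 1),
                         numeric(0))
  expect_equal(post@bHat, 0)
  expect_equal(post@C, params@sigma2 * solve(params@phi),
               ignore_attr = TRUE)
  expect_error(ranefPosterior(mixedModelParams(params@beta, matrix(0), 5),
                              matrix(0, 0, 15), matrix(0, 0, 1), numeric(0)),
               "singular")
})

test_that("the M-step reproduces known closed forms", {
  # T2 = J * phi0 => phi = phi0;  beta = XtXinv (Xty - t1);  sigma2 = t3 / n
  phi0 <- matrix(c(2, 0.5, 0.5, 1), 2)
  cdss <- list(t1 = c(50, 0), T2 = 7 * phi0, t3 = 30)
  got <- mStep(cdss, XtX = diag(c(100, 10)), Xty = c(250, 5), n = 10, J = 7)
  expect_equal(fixedEffects(got), c(2, 0.5))
  expect_equal(ranefCovariance(got), phi0)
  expect_equal(residualVariance(got), 3)
  expect_error(mStep(cdss, XtX = matrix(0, 2, 2), Xty = c(0, 0), n = 10,
                     J = 7), "rank deficient \\(deficiency 2\\)")
})

test_that("EM is a fixed point at its own converged estimates", {
  d <- smallBatch(seed = 9, n = 800, J = 25)
  fit <- fitEM(d, tol = 1e-10, maxIter = 20000)
  expect_true(fit@converged)
  # one more iteration from the converged values moves nothing
  more <- fitEM(d, start = modelParams(fit), tol = 0, maxIter = 1L)
  expect_equal(fixedEffects(more), fixedEffects(fit), tolerance = 1e-8)
  expect_equal(ranefCovariance(more), ranefCovariance(fit),
               tolerance = 1e-8)
  expect_equal(residualVariance(more), residualVariance(fit),
               tolerance = 1e-8)
})

test_that("compiled EM agrees with the pure-R E/M steps", {
  d <- smallBatch(seed = 13, n = 300, J = 12)
  start <- trueParams("A")
  # one compiled iteration vs one R-level eStep + mStep
  es <- eStep(start, d)
  rstep <- mStep(es$cdss, crossprod(d@X), crossprod(d@X, d@y)[, 1],
                 length(d@y), length(unique(d@id)))
  cfit <- fitEM(d, start = start, tol = 0, maxIter = 1L)
  expect_equal(fixedEffects(cfit), fixedEffects(rstep), tolerance = 1e-10)
  expect_equal(ranefCovariance(cfit), ranefCovariance(rstep),
               tolerance = 1e-10)
  expect_equal(residualVariance(cfit), residualVariance(rstep),
               tolerance = 1e-10)
})

test_that("marginal log-likelihood never decreases along the EM trace", {
  for (seed in c(2, 4, 6)) {
    d <- smallBatch(seed = seed, n = 400, J = 16)
    fit <- fitEM(d, tol = 1e-6, maxIter = 400)
    tr <- fit@trace
    ll <- apply(tr, 1, function(row) {
      r <- ncol(d@Z)
      phi <- matrix(0, r, r)
      phi[lower.tri(phi, diag = TRUE)] <- row[grep("^phi\\.", colnames(tr))]
      phi <- phi + t(phi) - diag(diag(phi), r)
      marginalLogLik(mixedModelParams(row[grep("^beta\\.", colnames(tr))],
                                      phi, row[["sigma2"]]), d)
    })
    expect_true(all(diff(ll) > -1e-8))
  }
})

test_that("EM matches an established ML mixed-model fitter", {
  skip_if_not_installed("lme4")
  d <- smallBatch(seed = 17, n = 3000, J = 100)
  fit <- fitEM(d, tol = 1e-9, maxIter = 50000)
  df <- data.frame(y = d@y, d@X[, -1], id = d@id)
  form <- stats::as.formula(paste("y ~", paste(colnames(d@X)[-1],
                                               collapse = " + "),
                                  "+ (1 | id)"))
  lfit <- lme4::lmer(form, data = df, REML = FALSE,
                     control = lme4::lmerControl(calc.derivs = FALSE))
  expect_lt(max(abs(fixedEffects(fit) - lme4::fixef(lfit))), 1e-3)
  vc <- lme4::VarCorr(lfit)
  expect_lt(abs(ranefCovariance(fit)[1, 1] / as.numeric(vc$id[1, 1]) - 1),
            1e-2)
  expect_lt(abs(residualVariance(fit) /
                  attr(vc, "sc")^2 - 1), 1e-2)
})

test_that("EM estimates are equivariant under response rescaling", {
  d <- smallBatch(seed = 21, n = 500, J = 20)
  fit1 <- fitEM(d, tol = 1e-9, maxIter = 20000)
  c0 <- 2
  d2 <- batchData(d@X, d@Z, c0 * d@y, d@id)
  fit2 <- fitEM(d2, tol = 1e-9, maxIter = 20000)
  expect_equal(fixedEffects(fit2), c0 * fixedEffects(fit1),
               tolerance = 1e-4)
  expect_equal(ranefCovariance(fit2), c0^2 * ranefCovariance(fit1),
               tolerance = 1e-4)
  expect_equal(residualVariance(fit2), c0^2 * residualVariance(fit1),
               tolerance = 1e-4)
})

test_that("EM errors on rank-deficient designs and reports the deficiency", {
  d <- smallBatch(seed = 1, n = 200, J = 10)
  X <- cbind(d@X, d@X[, 2])  # duplicated column
  expect_error(fitEM(batchData(X, d@Z, d@y, d@id)),
               "rank deficient \\(deficiency 1\\)")
})

test_that("tightening the tolerance changes a small fit by less than 1e-3", {
  # moderate variance ratio so the default tolerance sits close to the limit
  set.seed(25)
  J <- 50; nj <- 5
  id <- rep(sprintf("s%02d", 1:J), each = nj)
  X <- cbind(1, rnorm(J * nj))
  Z <- X[, 1, drop = FALSE]
  b <- rnorm(J, sd = 1)
  y <- as.numeric(X %*% c(2, 1)) + b[match(id, unique(id))] +
    rnorm(J * nj)
  d <- batchData(X, Z, y, id)
  loose <- fitEM(d, tol = 1e-4, maxIter = 20000)
  tight <- fitEM(d, tol = 1e-9, maxIter = 50000)
  expect_lt(max(abs(fixedEffects(loose) - fixedEffects(tight))), 1e-3)
  expect_lt(max(abs(ranefCovariance(loose) - ranefCovariance(tight))), 2e-3)
})
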