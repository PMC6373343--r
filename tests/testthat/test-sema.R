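pointsOf <- function(m, idx = seq_along(m$y)) {
  lapply(idx, function(i) dataPoint(m$id[i], m$y[i], m$X[i, ], m$Z[i, ]))
}

test_that("Sherman-Morrison update matches direct inversion", {
  # scalar: A = 4, x = 2 => (4 + 4)^-1 = 1/8
  expect_equal(shermanMorrisonUpdate(matrix(1 / 4), 2), matrix(1 / 8))
  # 2 x 2: A = diag(2), x = (1,1) => inverse of [[3,1],[1,3]]
  got <- shermanMorrisonUpdate(solve(diag(c(2, 2))), c(1, 1))
  expect_equal(got, solve(matrix(c(3, 1, 1, 3), 2)), tolerance = 1e-12)
  # zero update leaves the inverse unchanged
  A <- crossprod(matrix(rnorm(9), 3))
  expect_equal(shermanMorrisonUpdate(solve(A), numeric(3)), solve(A))
  # random updates stay within 1e-8 of the direct inverse
  set.seed(8)
  inv <- solve(A)
  for (k in 1:50) {
    x <- rnorm(3)
    A <- A + tcrossprod(x)
    inv <- shermanMorrisonUpdate(inv, x)
  }
  expect_lt(max(abs(inv - solve(A))), 1e-8)
  expect_error(shermanMorrisonUpdate(matrix(-1), 1), "degenerate")
  expect_error(shermanMorrisonUpdate(matrix(1), c(1, 2)), "length")
})

test_that("ingest accumulates exactly what a from-scratch build produces", {
  s <- smallStream(seed = 31, n = 300, J = 12)
  m <- streamMatrices(s)
  tr <- 1:150
  d <- batchData(m$X[tr, , drop = FALSE], m$Z[tr, , drop = FALSE],
                 m$y[tr], m$id[tr])
  state <- semaWarmStart(d)
  for (pt in pointsOf(m, 151:300)) state <- semaIngest(state, pt)
  oracle <- rebuildState(state, m$X, m$Z, m$y, m$id)
  for (j in names(oracle@individuals))
    for (f in c("nj", "ZtZ", "XtZ", "XtXj", "Zty", "Xtyj", "yty"))
      expect_equal(state@individuals[[j]][[f]],
                   oracle@individuals[[j]][[f]], tolerance = 1e-10)
  expect_equal(state@XtX, oracle@XtX, tolerance = 1e-10)
  expect_equal(state@xy, oracle@xy, tolerance = 1e-10)
  expect_equal(state@n, oracle@n)
  expect_equal(state@J, oracle@J)
  # the maintained inverse tracks the direct inverse
  expect_lt(max(abs(state@XtXinv - solve(state@XtX))), 1e-8)
})

test_that("ingest order does not matter for the accumulators", {
  s <- smallStream(seed = 33, n = 200, J = 10)
  m <- streamMatrices(s)
  d <- batchData(m$X[1:100, ], m$Z[1:100, , drop = FALSE], m$y[1:100],
                 m$id[1:100])
  base <- semaWarmStart(d)
  set.seed(1)
  perm <- 100 + sample(100)
  s1 <- Reduce(semaIngest, pointsOf(m, 101:200), base)
  s2 <- Reduce(semaIngest, pointsOf(m, perm), base)
  expect_equal(s1@XtX, s2@XtX, tolerance = 1e-10)
  expect_equal(s1@xy, s2@xy, tolerance = 1e-10)
  for (j in names(s1@individuals))
    expect_equal(s1@individuals[[j]]$ZtZ, s2@individuals[[j]]$ZtZ,
                 tolerance = 1e-10)
})

test_that("ingest rejects non-finite records and mismatched dimensions", {
  s <- smallStream(seed = 2, n = 240, J = 12)
  state <- semaWarmStart(do.call(batchData, streamMatrices(s)))
  expect_error(dataPoint("x", NaN, rep(1, 15), 1), "finite")
  bad <- dataPoint("x", 1, rep(1, 15), 1)
  slot(bad, "y", check = FALSE) <- NaN  # bypass the constructor's own check
  expect_warning(s2 <- semaIngest(state, bad), "non-finite")
  expect_equal(s2@n, state@n)
  expect_error(semaIngest(state, dataPoint("x", 1, c(1, 2), 1)),
               "dimensions")
})

test_that("online E-step equals the offline E-step per individual", {
  params <- trueParams("A")
  d <- smallBatch(seed = 35, n = 250, J = 10)
  state <- streamlmm:::.buildState(d, params, streamlmm:::.semaConfig())
  off <- eStep(params, d)
  for (j in unique(d@id)) {
    ind <- individualSummary(state, j)
    post <- off$posteriors[[j]]
    expect_lt(max(abs(ind$bHat - post@bHat)), 1e-10)
    expect_lt(max(abs(ind$Cinv - post@Cinv)), 1e-10)
    blk <- rowsOf(d, j)
    expect_lt(max(abs(ind$t1j -
      as.numeric(crossprod(blk$X, blk$Z) %*% post@bHat))), 1e-10)
    expect_lt(max(abs(ind$T2j -
      (tcrossprod(post@bHat) + params@sigma2 * post@Cinv))), 1e-10)
  }
  # totals agree with the offline CDSS
  expect_lt(max(abs(state@t1 - off$cdss$t1)), 1e-8)
  expect_lt(max(abs(state@T2 - off$cdss$T2)), 1e-8)
  expect_lt(abs(state@t3 - off$cdss$t3), 1e-8)
})

test_that("the stored cross-product expansion equals the raw residual sum", {
  params <- trueParams("A")
  d <- smallBatch(seed = 37, n = 250, J = 10)
  state <- streamlmm:::.buildState(d, params, streamlmm:::.semaConfig())
  for (j in unique(d@id)) {
    ind <- individualSummary(state, j)
    blk <- rowsOf(d, j)
    u <- blk$y - as.numeric(blk$X %*% params@beta) -
      as.numeric(blk$Z %*% ind$bHat)
    raw <- sum(u^2) +
      params@sigma2 * sum(diag(ind$Cinv %*% crossprod(blk$Z)))
    expect_lt(abs(ind$t3j - raw) / max(1, abs(raw)), 1e-8)
  }
})

test_that("an individual with no data gets the prior contribution", {
  params <- trueParams("A")
  empty <- streamlmm:::.emptyIndividual(15L, 1L)
  es <- streamlmm:::.estepIndividual(empty, params, 1e-8)
  expect_equal(es$bHat, 0)
  expect_equal(es$t1j, numeric(15))
  # T2j = sigma2 * (sigma2 phi^-1)^-1 = phi
  expect_equal(es$T2j, params@phi, tolerance = 1e-10)
  expect_equal(es$t3j, 0, tolerance = 1e-12)
})

test_that("repeating the E-step at unchanged parameters changes nothing", {
  d <- smallBatch(seed = 39, n = 200, J = 8)
  state <- semaWarmStart(d)
  j <- unique(d@id)[3]
  once <- semaEStepIndividual(state, j)
  twice <- semaEStepIndividual(once, j)
  expect_equal(twice@t1, once@t1, tolerance = 1e-12)
  expect_equal(twice@T2, once@T2, tolerance = 1e-12)
  expect_equal(twice@t3, once@t3, tolerance = 1e-12)
  expect_error(semaEStepIndividual(state, "nobody"), "unknown individual")
})

test_that("the online M-step matches the offline closed forms", {
  d <- smallBatch(seed = 41, n = 300, J = 12)
  state <- semaWarmStart(d)
  stepped <- semaMStep(state)
  want <- mStep(list(t1 = state@t1, T2 = state@T2, t3 = state@t3),
                state@XtX, state@xy, state@n, state@J)
  expect_equal(fixedEffects(modelParams(stepped)), fixedEffects(want),
               tolerance = 1e-8)
  expect_equal(ranefCovariance(modelParams(stepped)),
               ranefCovariance(want), tolerance = 1e-10)
  expect_equal(residualVariance(modelParams(stepped)),
               residualVariance(want), tolerance = 1e-10)
})

test_that("M-step guards its preconditions", {
  fresh <- semaInit(15, 1)
  expect_error(semaMStep(fresh), "no data")
})

test_that("one sweep equals one exact batch EM iteration", {
  d <- smallBatch(seed = 43, n = 400, J = 16)
  start <- trueParams("A")
  state <- streamlmm:::.buildState(d, start, streamlmm:::.semaConfig())
  swept <- semaSweep(state)
  one <- fitEM(d, start = start, tol = 0, maxIter = 1L)
  expect_equal(fixedEffects(modelParams(swept)), fixedEffects(one),
               tolerance = 1e-10)
  expect_equal(ranefCovariance(modelParams(swept)), ranefCovariance(one),
               tolerance = 1e-10)
  expect_equal(residualVariance(modelParams(swept)),
               residualVariance(one), tolerance = 1e-10)
})

test_that("sweeping a converged state is a near fixed point", {
  d <- smallBatch(seed = 45, n = 500, J = 20)
  fit <- fitEM(d, tol = 1e-10, maxIter = 50000)
  state <- streamlmm:::.buildState(d, modelParams(fit),
                                   streamlmm:::.semaConfig())
  swept <- semaSweep(state)
  expect_lt(max(abs(fixedEffects(modelParams(swept)) - fixedEffects(fit))),
            1e-8)
  expect_lt(max(abs(ranefCovariance(modelParams(swept)) -
                      ranefCovariance(fit))), 1e-8)
})

test_that("processing a point predicts first and touches one individual", {
  s <- smallStream(seed = 47, n = 260, J = 10)
  m <- streamMatrices(s)
  tr <- 1:250
  state <- semaWarmStart(batchData(m$X[tr, ], m$Z[tr, , drop = FALSE],
                                   m$y[tr], m$id[tr]))
  before <- state
  pt <- pointsOf(m, 251)[[1]]
  out <- semaProcessPoint(state, pt)
  # the prediction uses the pre-update parameters and posterior
  expect_equal(out$prediction,
               predictResponse(before@params, pt,
                               bHat = individualSummary(before, pt@id)$bHat))
  expect_equal(out$state@n, before@n + 1L)
  # only the arriving individual's summary changed
  others <- setdiff(names(before@individuals), pt@id)
  for (j in others)
    expect_identical(out$state@individuals[[j]]$ZtZ,
                     before@individuals[[j]]$ZtZ)
  # a brand-new individual is predicted from the fixed part alone
  novel <- dataPoint("never-seen", 0, m$X[252, ], m$Z[252, ])
  out2 <- semaProcessPoint(out$state, novel)
  expect_equal(out2$prediction,
               sum(m$X[252, ] * fixedEffects(modelParams(out$state))))
  expect_equal(out2$state@J, out$state@J + 1L)
})

test_that("warm-up buffers points until the design has full rank", {
  s <- smallStream(seed = 49, n = 160, J = 25)
  m <- streamMatrices(s)
  state <- semaInit(15, 1)
  preds <- numeric(0)
  for (pt in pointsOf(m)) {
    out <- semaProcessPoint(state, pt)
    state <- out$state
    preds <- c(preds, out$prediction)
  }
  # at least 5p = 75 points are buffered (prediction NA); once X'X reaches
  # full rank the state switches to streaming and predicts every point
  last <- max(which(is.na(preds)))
  expect_gte(last, 75L)
  expect_lt(last, 160L)
  expect_true(all(is.na(preds[1:last])))
  expect_true(all(!is.na(preds[(last + 1):160])))
  expect_equal(nObs(state), 160L)
  expect_null(state@config$warming)
})

test_that("a warm start on all data reproduces the batch fit exactly", {
  d <- smallBatch(seed = 51, n = 400, J = 16)
  state <- semaWarmStart(d)
  fit <- fitEM(d)
  expect_equal(fixedEffects(modelParams(state)), fixedEffects(fit))
  expect_equal(ranefCovariance(modelParams(state)), ranefCovariance(fit))
  expect_equal(nObs(state), 400L)
  expect_equal(nIndividuals(state), 16L)
})

test_that("the R and compiled streaming paths agree", {
  s <- smallStream(seed = 53, n = 450, J = 15)
  m <- streamMatrices(s)
  tr <- 1:250
  warm <- semaWarmStart(batchData(m$X[tr, ], m$Z[tr, , drop = FALSE],
                                  m$y[tr], m$id[tr]))
  # R path, point by point
  stateR <- warm
  predsR <- numeric(0)
  for (pt in pointsOf(m, 251:450)) {
    out <- semaProcessPoint(stateR, pt)
    stateR <- out$state
    predsR <- c(predsR, out$prediction)
  }
  # compiled path over the same points
  run <- semaStream(warm, m$X[251:450, ], m$Z[251:450, , drop = FALSE],
                    m$y[251:450], m$id[251:450])
  expect_equal(run$predictions, predsR, tolerance = 1e-9)
  expect_equal(fixedEffects(modelParams(run$state)),
               fixedEffects(modelParams(stateR)), tolerance = 1e-9)
  expect_equal(ranefCovariance(modelParams(run$state)),
               ranefCovariance(modelParams(stateR)), tolerance = 1e-9)
  expect_equal(residualVariance(modelParams(run$state)),
               residualVariance(modelParams(stateR)), tolerance = 1e-9)
  expect_equal(nObs(run$state), nObs(stateR))
})

test_that("CDSS totals always equal the sum of stored contributions", {
  s <- smallStream(seed = 55, n = 500, J = 20)
  m <- streamMatrices(s)
  tr <- 1:200
  warm <- semaWarmStart(batchData(m$X[tr, ], m$Z[tr, , drop = FALSE],
                                  m$y[tr], m$id[tr]))
  run <- semaStream(warm, m$X[201:500, ], m$Z[201:500, , drop = FALSE],
                    m$y[201:500], m$id[201:500], sweepEvery = 100L)
  st <- run$state
  t1s <- Reduce(`+`, lapply(st@individuals, `[[`, "t1j"))
  T2s <- Reduce(`+`, lapply(st@individuals, `[[`, "T2j"))
  t3s <- sum(vapply(st@individuals, `[[`, numeric(1), "t3j"))
  expect_lt(relDiff(t1s, st@t1), 1e-9)
  expect_lt(relDiff(T2s, st@T2), 1e-9)
  expect_lt(relDiff(t3s, st@t3), 1e-9)
})

test_that("streaming checkpoints snapshot the parameters at the right n", {
  s <- smallStream(seed = 57, n = 300, J = 12)
  m <- streamMatrices(s)
  tr <- 1:150
  warm <- semaWarmStart(batchData(m$X[tr, ], m$Z[tr, , drop = FALSE],
                                  m$y[tr], m$id[tr]))
  run <- semaStream(warm, m$X[151:300, ], m$Z[151:300, , drop = FALSE],
                    m$y[151:300], m$id[151:300],
                    checkpointAt = c(200L, 300L))
  cps <- run$checkpoints
  expect_setequal(unique(cps$n), c(200L, 300L))
  # the final checkpoint equals the final parameters
  endB <- cps$value[cps$n == 300L & cps$parameter == "beta.1"]
  expect_equal(endB, fixedEffects(modelParams(run$state))[1],
               tolerance = 1e-12)
  expect_equal(nrow(cps), 2L * (15 + 1 + 1))
})
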