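## Shared fixtures.  Heavy objects (full-size replication sets) are built
## lazily and cached in this environment so several test files can share them.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache, inherits = FALSE))
    assign(key, force(expr), envir = .cache)
  get(key, envir = .cache, inherits = FALSE)
}

# a small condition-A-style stream for fast unit tests
smallStream <- function(seed = 1, n = 600, J = 30, cond = "A") {
  simulateStream(conditionPreset(cond), nTotal = n, J = J, seed = seed)
}

smallBatch <- function(seed = 1, n = 600, J = 30, cond = "A") {
  m <- streamMatrices(smallStream(seed, n, J, cond))
  batchData(m$X, m$Z, m$y, m$id)
}

trueParams <- function(cond = "A") {
  cnd <- conditionPreset(cond)
  mixedModelParams(cnd@beta, cnd@phi, cnd@sigma2)
}

# rebuild a SemaState from scratch at the state's own parameters; used as the
# oracle for the accumulator (ingest) path
rebuildState <- function(state, X, Z, y, id) {
  streamlmm:::.buildState(batchData(X, Z, y, id), state@params, state@config)
}

# per-individual raw design blocks
rowsOf <- function(data, j) {
  rows <- which(data@id == j)
  list(X = data@X[rows, , drop = FALSE], Z = data@Z[rows, , drop = FALSE],
       y = data@y[rows])
}

# elementwise relative difference against a reference
relDiff <- function(a, b) max(abs(a - b)) / max(1, max(abs(b)))

## ---- full-size replication set shared by the acceptance tests ----
## One replication = the simulation-design protocol for condition A:
## n = 50,000 points, J = 1000 individuals, EM warm start (tol 1e-4) on the
## first 2000 points from the true generating values, then the streaming
## estimator point by point, with parameter snapshots at n = 25,000 and the
## stream end.

replicationSeeds <- function() 1000L + seq_len(30L)

conditionAReplications <- function() cached("condA", {
  truth <- trueParams("A")
  lapply(replicationSeeds(), function(seed) {
    s <- simulateStream(conditionPreset("A"), seed = seed)
    res <- prequentialRun(s, method = "sema", trainN = 2000L, start = truth,
                          checkpointAt = c(25000L, 50000L))
    cp <- checkpoints(res)
    list(seed = seed,
         beta0Mid = cp$value[cp$n == 25000L & cp$parameter == "beta.1"],
         beta0End = cp$value[cp$n == 50000L & cp$parameter == "beta.1"],
         phi0Mid = cp$value[cp$n == 25000L & cp$parameter == "phi.1.1"],
         phi0End = cp$value[cp$n == 50000L & cp$parameter == "phi.1.1"],
         sigma2End = residualVariance(modelParams(res)),
         finalParams = modelParams(res),
         mae = mae(res), rmse = rmse(res))
  })
})

conditionDReplications <- function() cached("condD", {
  truth <- trueParams("D")
  lapply(replicationSeeds()[1:3], function(seed) {
    s <- simulateStream(conditionPreset("D"), seed = seed)
    res <- prequentialRun(s, method = "sema", trainN = 2000L, start = truth)
    list(seed = seed, mae = mae(res), rmse = rmse(res))
  })
})
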