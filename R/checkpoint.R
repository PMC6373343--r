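## Versioned state snapshots.  JSON at full precision so counts restore
## bit-equal and floats round-trip to <= 1e-12.

.checkpointVersion <- 1L

.packMat <- function(m) list(dim = dim(m), values = as.numeric(m))
.unpackMat <- function(x) matrix(as.numeric(x$values), x$dim[1], x$dim[2])

#' Save a streaming state to a checkpoint file
#'
#' @param state a [SemaState-class].
#' @param path output file (JSON).
#' @return \code{path}, invisibly.
#' @export
saveCheckpoint <- function(state, path) {
  inds <- lapply(state@individuals, function(ind) list(
    nj = ind$nj, ZtZ = .packMat(ind$ZtZ), XtZ = .packMat(ind$XtZ),
    XtXj = .packMat(ind$XtXj), Zty = ind$Zty, Xtyj = ind$Xtyj,
    yty = ind$yty, bHat = ind$bHat, Cinv = .packMat(ind$Cinv),
    t1j = ind$t1j, T2j = .packMat(ind$T2j), t3j = ind$t3j))
  cfg <- state@config
  cfg$buffer <- NULL
  obj <- list(version = .checkpointVersion, n = state@n, J = state@J,
              p = state@p, r = state@r,
              XtX = .packMat(state@XtX), XtXinv = .packMat(state@XtXinv),
              xy = state@xy, t1 = state@t1, T2 = .packMat(state@T2),
              t3 = state@t3,
              beta = state@params@beta, phi = .packMat(state@params@phi),
              sigma2 = state@params@sigma2,
              config = cfg, individuals = inds)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a streaming state from a checkpoint file
#'
#' Refuses to load a checkpoint written under a different format version.
#'
#' @param path a file written by [saveCheckpoint()].
#' @return A [SemaState-class].
#' @export
loadCheckpoint <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyMatrix = FALSE, simplifyDataFrame = FALSE)
  if (!identical(as.integer(obj$version), .checkpointVersion))
    stop("checkpoint version ", obj$version, " is not supported (expected ",
         .checkpointVersion, ")")
  inds <- lapply(obj$individuals, function(ind) list(
    nj = as.integer(ind$nj), ZtZ = .unpackMat(ind$ZtZ),
    XtZ = .unpackMat(ind$XtZ), XtXj = .unpackMat(ind$XtXj),
    Zty = as.numeric(ind$Zty), Xtyj = as.numeric(ind$Xtyj),
    yty = as.numeric(ind$yty), bHat = as.numeric(ind$bHat),
    Cinv = .unpackMat(ind$Cinv), t1j = as.numeric(ind$t1j),
    T2j = .unpackMat(ind$T2j), t3j = as.numeric(ind$t3j)))
  cfg <- obj$config
  cfg$sweepEvery <- as.integer(cfg$sweepEvery)
  cfg$reinvertEvery <- as.integer(cfg$reinvertEvery)
  state <- new("SemaState", n = as.integer(obj$n), J = as.integer(obj$J),
               p = as.integer(obj$p), r = as.integer(obj$r),
               XtX = .unpackMat(obj$XtX), XtXinv = .unpackMat(obj$XtXinv),
               xy = as.numeric(obj$xy), t1 = as.numeric(obj$t1),
               T2 = .unpackMat(obj$T2), t3 = as.numeric(obj$t3),
               params = mixedModelParams(obj$beta, .unpackMat(obj$phi),
                                         obj$sigma2),
               individuals = inds, config = cfg)
  validObject(state)
  state
}
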