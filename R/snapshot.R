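#' Snapshot and restore a running simulation
#'
#' `snapshot_state()` captures the complete simulation state -- grid,
#' holobionts, event log, archives, step counter -- together with the state
#' of R's random number generator and a format version tag.
#' `restore_state()` rebuilds the simulation and restores the RNG, so a
#' restored run continues bit-identically to an uninterrupted one with the
#' same seed stream.
#'
#' @param sim an `endo_sim`.
#' @param file path for the snapshot file.
#' @return `snapshot_state()` the file path, invisibly; `restore_state()`
#'   a rebuilt `endo_sim`.
#' @export
snapshot_state <- function(sim, file) {
  state <- list(
    format = "endocycle-snapshot",
    version = 1L,
    rng = get(".Random.seed", envir = globalenv()),
    fields = mget(ls(sim, all.names = TRUE), envir = sim),
    log = mget(ls(sim$log, all.names = TRUE), envir = sim$log),
    archive = mget(ls(sim$archive, all.names = TRUE), envir = sim$archive)
  )
  state$fields$log <- NULL
  state$fields$archive <- NULL
  saveRDS(state, file)
  invisible(file)
}

#' @rdname snapshot_state
#' @export
restore_state <- function(file) {
  state <- tryCatch(readRDS(file), error = function(e)
    stop("snapshot is unreadable or truncated: ", conditionMessage(e),
         call. = FALSE))
  if (!identical(state$format, "endocycle-snapshot"))
    stop("not an endocycle snapshot file", call. = FALSE)
  if (!identical(state$version, 1L))
    stop("snapshot version ", state$version,
         " not supported by this build (expected 1)", call. = FALSE)
  sim <- new.env(parent = emptyenv())
  for (nm in names(state$fields)) assign(nm, state$fields[[nm]], envir = sim)
  sim$log <- new.env(parent = emptyenv())
  for (nm in names(state$log)) assign(nm, state$log[[nm]], envir = sim$log)
  sim$archive <- new.env(parent = emptyenv())
  for (nm in names(state$archive)) assign(nm, state$archive[[nm]], envir = sim$archive)
  class(sim) <- "endo_sim"
  assign(".Random.seed", state$rng, envir = globalenv())
  sim
}
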