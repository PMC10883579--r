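#' Run configuration
#'
#' A nested list of every tunable parameter of the simulator, with defaults
#' matching the model's standard conditions: the Table of mutation rates,
#' leakage rate `l = 0.01`, transfer rate `mu_t = 2e-5`, an 11-sector
#' vertical nutrient gradient on a 45 x 110 grid, replication cost `rho = 5`
#' nutrient units per bead, and basal holobiont death `delta = 0.002` per
#' step. See `vignette("endocycle-methods")` for what each block controls.
#'
#' @param ... named overrides, as nested lists (e.g.
#'   `default_config(grid = list(width = 20, height = 22))`). Unknown keys
#'   are an error in [validate_config()].
#' @return a `endo_config` list.
#' @export
default_config <- function(...) {
  cfg <- config_defaults()
  overrides <- list(...)
  if (length(overrides)) cfg <- merge_config(cfg, overrides)
  validate_config(cfg)
}

config_defaults <- function() {
  list(
    B = 20L,
    affinity = list(c = 10, s = 0.5),
    ranges = list(weight = c(-3L, 3L), threshold = c(-2L, 5L)),
    stage_table = stage_table(),
    mutation = mutation_rates(),
    interference = interference_config(),
    grid = list(width = 45L, height = 110L, sectors = 11L,
                influx_min = 10, influx_max = 110),
    dynamics = list(rho = 5, delta = 0.002, timesteps = 10000L, seed = 1L),
    assay = list(T = 2000L, window = 0.2, grid_width = 20L, grid_height = 20L,
                 inoculum = 0.1, symbionts = 2L)
  )
}

merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Validate and normalize a configuration
#'
#' Fills defaults, coerces the stage table and rate blocks to their classes,
#' checks every range constraint and the grid geometry (height divisible by
#' the sector count), and attaches the derived per-sector influx values.
#' All problems are reported together.
#'
#' @param cfg a (possibly partial) configuration list.
#' @return the normalized `endo_config`, or an error listing every problem.
#' @export
validate_config <- function(cfg) {
  errs <- character(0)
  cfg <- merge_config(config_defaults(), unclass(cfg))  # fill defaults
  if (!inherits(cfg$stage_table, "stage_table")) {
    cfg$stage_table <- tryCatch(do.call(stage_table, as.list(cfg$stage_table)),
                                error = function(e) {
                                  errs <<- c(errs, conditionMessage(e)); stage_table()
                                })
  }
  if (!inherits(cfg$mutation, "mutation_rates")) {
    cfg$mutation <- tryCatch(do.call(mutation_rates, cfg$mutation),
                             error = function(e) {
                               errs <<- c(errs, conditionMessage(e)); mutation_rates()
                             })
  }
  bad_mu <- names(cfg$mutation)[vapply(cfg$mutation, function(x)
    !is.numeric(x) || x < 0 || x > 1, TRUE)]
  if (length(bad_mu))
    errs <- c(errs, paste0("mutation rates out of [0,1]: ",
                           paste(bad_mu, collapse = ", ")))
  if (!inherits(cfg$interference, "interference_config")) {
    cfg$interference <- tryCatch(do.call(interference_config, cfg$interference),
                                 error = function(e) {
                                   errs <<- c(errs, conditionMessage(e))
                                   interference_config()
                                 })
  }
  ic <- cfg$interference
  if (!is.null(ic)) {
    if (ic$l < 0 || ic$l > 1) errs <- c(errs, "leakage rate l outside [0,1]")
    if (ic$mu_t < 0 || ic$mu_t > 1) errs <- c(errs, "transfer rate mu_t outside [0,1]")
  }
  gr <- cfg$grid
  if (gr$height %% gr$sectors != 0L)
    errs <- c(errs, sprintf("grid height %d not divisible by %d sectors",
                            gr$height, gr$sectors))
  if (gr$influx_min > gr$influx_max)
    errs <- c(errs, "influx_min exceeds influx_max")
  if (cfg$dynamics$rho <= 0) errs <- c(errs, "rho must be positive")
  if (cfg$dynamics$delta < 0 || cfg$dynamics$delta > 1)
    errs <- c(errs, "delta outside [0,1]")
  if (cfg$B < 1 || cfg$B > 30) errs <- c(errs, "B must be in 1..30")
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  cfg$grid$sector_influx <- sector_influx(cfg$grid)
  class(cfg) <- "endo_config"
  cfg
}

# linearly spaced sector influx values, top row = influx_min
sector_influx <- function(grid) {
  seq(grid$influx_min, grid$influx_max, length.out = grid$sectors)
}

#' @export
print.endo_config <- function(x, ...) {
  cat(sprintf(
    "<endo_config> B=%d grid=%dx%d (%d sectors, influx %g..%g) l=%g mu_t=%g\n",
    x$B, x$grid$width, x$grid$height, x$grid$sectors,
    x$grid$influx_min, x$grid$influx_max,
    x$interference$l, x$interference$mu_t))
  invisible(x)
}

#' Read / write a configuration as YAML
#'
#' The stage table is serialized as four bit strings and the rate blocks as
#' plain named lists, so a round-tripped file reproduces the configuration
#' exactly.
#'
#' @param cfg an `endo_config`.
#' @param file path.
#' @return `read_config()` a validated `endo_config`.
#' @export
write_config <- function(cfg, file) {
  out <- unclass(cfg)
  out$stage_table <- as.list(vapply(seq_along(cfg$stage_table), function(i)
    mask_to_string(cfg$stage_table[[i]], 5L), ""))
  names(out$stage_table) <- names(cfg$stage_table)
  out$mutation <- unclass(cfg$mutation)
  out$interference <- unclass(cfg$interference)
  out$grid$sector_influx <- NULL
  yaml::write_yaml(out, file)
  invisible(file)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  raw <- yaml::read_yaml(file)
  merged <- merge_config(unclass(default_config()), raw)
  validate_config(merged)
}
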