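#' Clonal growth assay
#'
#' Measures the equilibrium grid density `N` of a single holobiont genotype
#' at a fixed nutrient level: a uniform-influx grid is inoculated with
#' clonal holobionts (all hosts identical, all symbionts identical),
#' mutation rates are forced to zero so the measured density reflects the
#' genotype alone, and the population is run for `T` steps under the given
#' interference toggles. `N_equilibrium` is the mean occupied fraction over
#' the final `window` fraction of the run. A nonviable clone simply reports
#' `N = 0`.
#'
#' @param host_genome,sym_genome the clonal genotype.
#' @param n_influx uniform nutrient influx (e.g. 90 for rich, 30 for
#'   intermediate conditions).
#' @param toggles interference overrides: an [interference_config()], or a
#'   list of overrides applied to the config's interference block.
#' @param T run length in timesteps; `window` the trailing fraction (or
#'   absolute number if > 1) of steps averaged.
#' @param config run configuration; the assay grid size and inoculum come
#'   from its `assay` block.
#' @param seed integer seed making the assay reproducible.
#' @return an `endo_assay` list: `N_equilibrium`, `toggles`, `trace` (tibble
#'   of step and occupied fraction), `extinct`, `sim`.
#' @export
clonal_growth_assay <- function(host_genome, sym_genome, n_influx = 90,
                                toggles = list(), T = NULL, window = NULL,
                                config = default_config(), seed = 1L) {
  T <- as.integer(T %||% config$assay$T)
  window <- window %||% config$assay$window
  win_steps <- if (window > 1) as.integer(window) else max(1L, as.integer(window * T))
  stopifnot(win_steps <= T)
  icfg <- if (inherits(toggles, "interference_config")) toggles
          else do.call(interference_config,
                       utils::modifyList(unclass(config$interference), toggles))
  acfg <- validate_config(merge_config(unclass(config), list(
    grid = list(width = config$assay$grid_width,
                height = config$assay$grid_height,
                sectors = 1L, influx_min = n_influx, influx_max = n_influx),
    mutation = zero_rates(),
    interference = icfg)))
  set.seed(seed)
  sim <- new_simulation(acfg)
  inoculate(sim, host_genome, sym_genome,
            fraction = acfg$assay$inoculum, n_sym = acfg$assay$symbionts)
  total <- sim$height * sim$width
  occ_frac <- numeric(T)
  for (t in seq_len(T)) {
    step_population(sim)
    occ_frac[t] <- length(alive_ids(sim)) / total
    if (occ_frac[t] == 0) { occ_frac[t:T] <- 0; break }
  }
  structure(list(
    N_equilibrium = mean(occ_frac[(T - win_steps + 1L):T]),
    toggles = icfg,
    trace = tibble::tibble(step = seq_len(T), N = occ_frac),
    extinct = occ_frac[T] == 0,
    n_influx = n_influx, T = T, seed = seed, sim = sim
  ), class = "endo_assay")
}

#' @export
print.endo_assay <- function(x, ...) {
  cat(sprintf("<endo_assay> n_influx=%g T=%d N_equilibrium=%.4f%s\n",
              x$n_influx, x$T, x$N_equilibrium,
              if (x$extinct) " (extinct)" else ""))
  invisible(x)
}

#' Interference knockout panel
#'
#' Runs [clonal_growth_assay()] for the baseline configuration plus six
#' knockouts -- leakage disabled host-to-symbiont, symbiont-to-host, or
#' both; targeting disabled in the same three ways -- and reports the
#' density change `delta_N = N(toggled) - N(baseline)` per knockout with a
#' Monte-Carlo standard error over `n_seeds` replicate seeds. A strongly
#' negative `delta_N` means the knocked-out channel was essential for
#' holobiont growth.
#'
#' @inheritParams clonal_growth_assay
#' @param n_seeds replicate seeds per condition (>= 3 for a standard
#'   error).
#' @param seed base seed; replicate r of every condition uses `seed + r`.
#' @return a tibble: `toggle`, `N_mean`, `delta_N`, `se`, `n_seeds`.
#' @export
knockout_panel <- function(host_genome, sym_genome, n_influx = 90, T = NULL,
                           config = default_config(), n_seeds = 3L, seed = 1L) {
  toggles <- list(
    baseline = list(),
    no_leakage_h_to_s = list(leakage_mode = "symbiont_to_host"),
    no_leakage_s_to_h = list(leakage_mode = "host_to_symbiont"),
    no_leakage = list(leakage_mode = "off"),
    no_targeting_h_to_s = list(targeting = list(host_to_symbiont = FALSE,
                                                symbiont_to_host = TRUE)),
    no_targeting_s_to_h = list(targeting = list(host_to_symbiont = TRUE,
                                                symbiont_to_host = FALSE)),
    no_targeting = list(targeting = list(host_to_symbiont = FALSE,
                                         symbiont_to_host = FALSE)))
  res <- lapply(names(toggles), function(nm) {
    Ns <- vapply(seq_len(n_seeds), function(r) {
      clonal_growth_assay(host_genome, sym_genome, n_influx,
                          toggles = toggles[[nm]], T = T, config = config,
                          seed = seed + r)$N_equilibrium
    }, 1)
    tibble::tibble(toggle = nm, N_mean = mean(Ns),
                   se = stats::sd(Ns) / sqrt(n_seeds), n_seeds = n_seeds)
  })
  out <- dplyr::bind_rows(res)
  base <- out$N_mean[out$toggle == "baseline"]
  out$delta_N <- out$N_mean - base
  out[, c("toggle", "N_mean", "delta_N", "se", "n_seeds")]
}

#' Competition between two populations
#'
#' Inoculates the left half of a fresh grid from population A and the right
#' half from population B (subsampled to equal initial densities), freezes
#' mutation, and runs until one lineage has taken over the grid or `T`
#' steps have elapsed.
#'
#' @param pop_A,pop_B source populations: `endo_sim` objects, or lists of
#'   holobionts (each a list with `host` and `syms` cells).
#' @param T maximum number of timesteps.
#' @param config configuration for the competition arena.
#' @param seed integer seed.
#' @param mutation optional [mutation_rates()]; defaults to all-zero.
#' @return a list: `winner` (`"A"`, `"B"` or `"coexistence"`),
#'   `final_densities`, `trace` (tibble of per-step lineage densities),
#'   `steps_run`.
#' @export
competition <- function(pop_A, pop_B, T = 10000L, config = default_config(),
                        seed = 1L, mutation = NULL) {
  holos_A <- extract_holobionts(pop_A)
  holos_B <- extract_holobionts(pop_B)
  stopifnot(length(holos_A) > 0L, length(holos_B) > 0L)
  ccfg <- validate_config(merge_config(unclass(config), list(
    mutation = mutation %||% zero_rates())))
  set.seed(seed)
  sim <- new_simulation(ccfg)
  half <- sim$width %/% 2L
  n_each <- min(length(holos_A), length(holos_B),
                floor(0.25 * sim$height * half))
  seed_half <- function(holos, cols, tag) {
    picks <- sample(seq_along(holos), n_each)
    free <- expand.grid(row = seq_len(sim$height), col = cols)
    spots <- free[sample.int(nrow(free), n_each), ]
    for (i in seq_len(n_each)) {
      h <- holos[[picks[i]]]
      host <- reset_cell(h$host, ccfg)
      syms <- lapply(h$syms, reset_cell, config = ccfg)
      id <- new_holobiont(sim, host, syms, spots$row[i], spots$col[i])
      h2 <- get_holo(sim, id)
      h2$lineage <- tag
      set_holo(sim, id, h2)
    }
  }
  seed_half(holos_A, seq_len(half), "A")
  seed_half(holos_B, (half + 1L):sim$width, "B")
  total <- sim$height * sim$width
  trace <- list()
  steps_run <- 0L
  for (t in seq_len(T)) {
    step_population(sim)
    steps_run <- t
    ids <- alive_ids(sim)
    lin <- vapply(holo_list(sim, ids), function(h) h$lineage %||% "?", "")
    dA <- sum(lin == "A") / total
    dB <- sum(lin == "B") / total
    trace[[t]] <- tibble::tibble(step = sim$step, A = dA, B = dB)
    if (dA == 0 || dB == 0) break
  }
  tr <- dplyr::bind_rows(trace)
  dA <- tr$A[nrow(tr)]; dB <- tr$B[nrow(tr)]
  winner <- if (dA > 0 && dB == 0) "A" else if (dB > 0 && dA == 0) "B" else "coexistence"
  list(winner = winner, final_densities = c(A = dA, B = dB),
       trace = tr, steps_run = steps_run)
}

extract_holobionts <- function(pop) {
  if (inherits(pop, "endo_sim")) {
    ids <- alive_ids(pop)
    return(lapply(holo_list(pop, ids), function(h) {
      h$host <- materialize_cell(h, 1L)
      for (s in seq_along(h$syms)) h$syms[[s]] <- materialize_cell(h, s + 1L)
      h
    }))
  }
  pop
}

# reset a cell's cycle state for inoculation into a new arena, keeping its
# genome and expression
reset_cell <- function(cell, config) {
  out <- new_cell(cell$genome, cell$role, config, expression = cell$expression)
  out
}

#' Reconstruct the ancestry of a population
#'
#' Computes, separately for the host (holobiont) lineage and the symbiont
#' lineage, the most recent common ancestor of all individuals alive at
#' the end of a recorded run, plus the ancestral path from the root to the
#' MRCA. Requires the run's event log; per-ancestor genomes are attached
#' when the run archived them (`record_genomes = TRUE`).
#'
#' @param sim an `endo_sim` after a run (or a list with `log` tibble from
#'   [event_log()], `alive` ids, and optionally `archive`).
#' @return a list with `host` and `symbiont`, each a list of `mrca` (id or
#'   `NA` if the alive set has no common ancestor), `path` (ids from root
#'   to MRCA), `genomes` (named list, possibly empty), `n_alive`.
#' @export
reconstruct_ancestry <- function(sim) {
  lg <- event_log(sim)
  births <- lg[lg$event %in% c("birth", "inoculate"), ]
  host_parent <- stats::setNames(births$parent, births$child)
  sym_births <- lg[lg$event == "sym_birth", ]
  sym_parent <- stats::setNames(sym_births$parent, sym_births$child)
  ids <- alive_ids(sim)
  if (length(ids) == 0L) stop("no holobionts alive; nothing to trace", call. = FALSE)
  sym_ids <- unlist(lapply(holo_list(sim, ids),
                           function(h) vapply(h$syms, `[[`, 1L, "sym_id")))
  host <- mrca_of(ids, host_parent)
  symb <- mrca_of(sym_ids, sym_parent)
  host$genomes <- fetch_genomes(sim, "h", host$path)
  symb$genomes <- fetch_genomes(sim, "s", symb$path)
  host$n_alive <- length(ids); symb$n_alive <- length(sym_ids)
  list(host = host, symbiont = symb)
}

fetch_genomes <- function(sim, prefix, ids) {
  if (!isTRUE(sim$record_genomes) || !length(ids)) return(list())
  out <- list()
  for (i in ids) {
    key <- paste0(prefix, i)
    if (exists(key, envir = sim$archive, inherits = FALSE))
      out[[key]] <- get(key, envir = sim$archive)
  }
  out
}

# MRCA by root-path intersection over a parent map (names = child id).
# Returns the deepest id common to every alive individual's root path.
mrca_of <- function(alive, parent_map) {
  root_path <- function(id) {
    path <- id
    repeat {
      j <- match(as.character(id), names(parent_map))
      if (is.na(j))
        stop(sprintf("broken parent link at id %s", id), call. = FALSE)
      p <- parent_map[[j]]
      if (is.na(p)) break  # root (inoculant)
      id <- p
      path <- c(p, path)
    }
    path # root .. leaf
  }
  paths <- lapply(unique(alive), root_path)
  ref <- paths[[1]]
  depth <- length(ref)
  for (p in paths[-1]) {
    m <- min(depth, length(p))
    eq <- ref[seq_len(m)] == p[seq_len(m)]
    depth <- match(FALSE, eq, nomatch = m + 1L) - 1L
    if (depth == 0L) break
  }
  if (depth == 0L)
    return(list(mrca = NA_integer_, path = integer(0)))
  list(mrca = ref[depth], path = ref[seq_len(depth)])
}

#' Export a recorded lineage forest as Newick
#'
#' Builds the holobiont birth forest from a run's event log (branch lengths
#' in timesteps) and writes one Newick line per root using `ape`.
#'
#' @param sim an `endo_sim` (or an [event_log()] tibble).
#' @param file optional output path.
#' @return character vector of Newick strings, invisibly if written.
#' @export
export_lineage_newick <- function(sim, file = NULL) {
  lg <- if (inherits(sim, "endo_sim")) event_log(sim) else sim
  births <- lg[lg$event %in% c("birth", "inoculate"), ]
  if (!nrow(births)) stop("event log records no births", call. = FALSE)
  birth_step <- stats::setNames(births$step, births$child)
  kids <- split(births$child[!is.na(births$parent)],
                births$parent[!is.na(births$parent)])
  end_step <- max(lg$step)
  deaths <- lg[lg$event == "death", ]
  death_step <- stats::setNames(deaths$step, deaths$holo)
  tip_end <- function(id) {
    j <- match(as.character(id), names(death_step))
    if (is.na(j)) end_step else death_step[[j]]
  }
  # A division replaces the parent with its daughters, so a parent's branch
  # runs from its own birth to the division step. Holobionts with a single
  # surviving daughter would create singleton internal nodes; those chains
  # are collapsed into the daughter's branch.
  render <- function(id, extra = 0L) {
    ch <- kids[[as.character(id)]]
    t0 <- birth_step[[as.character(id)]]
    if (is.null(ch) || !length(ch)) {
      sprintf("h%d:%d", id, tip_end(id) - t0 + extra)
    } else {
      div <- birth_step[[as.character(ch[1])]]
      len <- div - t0 + extra
      if (length(ch) == 1L) {
        render(ch, extra = len)
      } else {
        inner <- paste(vapply(ch, render, ""), collapse = ",")
        sprintf("(%s)h%d:%d", inner, id, len)
      }
    }
  }
  roots <- births$child[is.na(births$parent)]
  nwk <- vapply(roots, function(r) {
    s <- render(r)
    if (!startsWith(s, "(")) s <- paste0("(", s, ")")  # one-tip tree
    paste0(s, ";")
  }, "")
  if (!is.null(file)) {
    writeLines(nwk, file)
    return(invisible(nwk))
  }
  nwk
}
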