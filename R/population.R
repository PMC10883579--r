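#' Create a spatial holobiont simulation
#'
#' Builds an empty grid with the configured nutrient gradient: influx is
#' constant within each of the horizontal sector bands (default 11 sectors,
#' linearly spaced influx from `influx_min` in the top band to `influx_max`
#' in the bottom band), constant in time. The grid is toroidal in the
#' horizontal (width) dimension and bounded vertically. At most one
#' holobiont occupies a site.
#'
#' The simulation state is an environment (class `endo_sim`) mutated in
#' place by [step_population()]; use [snapshot_state()] to capture it. All
#' randomness is drawn from R's global RNG stream, so `set.seed()` before
#' [inoculate()]/[run_simulation()] makes a run bit-reproducible.
#'
#' @param config an `endo_config` from [default_config()].
#' @param record_genomes keep full genomes of every cell at birth (needed
#'   for ancestry reconstruction; off by default to bound memory in long
#'   runs -- genome hashes are always logged).
#' @return an `endo_sim` environment.
#' @export
new_simulation <- function(config = default_config(), record_genomes = FALSE) {
  sim <- new.env(parent = emptyenv())
  sim$config <- config
  sim$width <- as.integer(config$grid$width)
  sim$height <- as.integer(config$grid$height)
  rows_per_sector <- sim$height %/% config$grid$sectors
  sim$influx <- matrix(rep(config$grid$sector_influx, each = rows_per_sector),
                       nrow = sim$height, ncol = sim$width)
  sim$occ <- matrix(0L, nrow = sim$height, ncol = sim$width)
  sim$ncells <- matrix(0L, nrow = sim$height, ncol = sim$width)
  # holobionts live in an environment keyed by id: assignments never copy
  sim$holos <- new.env(parent = emptyenv())
  sim$next_holo_id <- 1L
  sim$next_sym_id <- 1L
  sim$step <- 0L
  sim$record_genomes <- isTRUE(record_genomes)
  sim$archive <- new.env(parent = emptyenv())
  sim$log <- new_event_log()
  class(sim) <- "endo_sim"
  sim
}

#' @export
print.endo_sim <- function(x, ...) {
  cat(sprintf("<endo_sim> %dx%d grid, step %d, %d holobiont(s)\n",
              x$height, x$width, x$step, length(alive_ids(x))))
  invisible(x)
}

# ---------------------------------------------------------------------------
# event log: preallocated parallel vectors grown by doubling

# The log accumulates fixed-size chunks so per-event writes only ever
# touch small vectors (growing a single long vector in place degenerates
# into full copies once it is referenced elsewhere).
log_chunk_size <- 4096L

new_event_log <- function() {
  lg <- new.env(parent = emptyenv())
  lg$chunks <- list()
  lg$n <- 0L
  reset_log_chunk(lg)
  lg
}

reset_log_chunk <- function(lg) {
  n <- log_chunk_size
  lg$cn <- 0L
  lg$c_step <- integer(n); lg$c_event <- character(n)
  lg$c_row <- integer(n); lg$c_col <- integer(n)
  lg$c_holo <- integer(n); lg$c_parent <- integer(n)
  lg$c_child <- integer(n); lg$c_extra <- character(n)
  invisible(lg)
}

flush_log_chunk <- function(lg) {
  i <- seq_len(lg$cn)
  lg$chunks[[length(lg$chunks) + 1L]] <-
    list(step = lg$c_step[i], event = lg$c_event[i], row = lg$c_row[i],
         col = lg$c_col[i], holo = lg$c_holo[i], parent = lg$c_parent[i],
         child = lg$c_child[i], extra = lg$c_extra[i])
  reset_log_chunk(lg)
}

log_event <- function(sim, event, row = NA_integer_, col = NA_integer_,
                      holo = NA_integer_, parent = NA_integer_,
                      child = NA_integer_, extra = NA_character_) {
  lg <- sim$log
  if (lg$cn == log_chunk_size) flush_log_chunk(lg)
  i <- lg$cn + 1L
  lg$c_step[i] <- sim$step; lg$c_event[i] <- event
  lg$c_row[i] <- row; lg$c_col[i] <- col
  lg$c_holo[i] <- holo; lg$c_parent[i] <- parent; lg$c_child[i] <- child
  lg$c_extra[i] <- extra
  lg$cn <- i
  lg$n <- lg$n + 1L
  invisible(NULL)
}

#' Extract the event log of a run
#'
#' @param sim an `endo_sim`.
#' @return a tibble with one row per event: `step`, `event`, grid `row` and
#'   `col`, the `holo`(biont) concerned, `parent` and `child` ids for birth
#'   events, and `extra` (genome hash at births, cause at deaths).
#' @export
event_log <- function(sim) {
  lg <- sim$log
  i <- seq_len(lg$cn)
  parts <- c(lg$chunks, list(
    list(step = lg$c_step[i], event = lg$c_event[i], row = lg$c_row[i],
         col = lg$c_col[i], holo = lg$c_holo[i], parent = lg$c_parent[i],
         child = lg$c_child[i], extra = lg$c_extra[i])))
  tibble::tibble(
    step = unlist(lapply(parts, `[[`, "step")),
    event = unlist(lapply(parts, `[[`, "event")),
    row = unlist(lapply(parts, `[[`, "row")),
    col = unlist(lapply(parts, `[[`, "col")),
    holo = unlist(lapply(parts, `[[`, "holo")),
    parent = unlist(lapply(parts, `[[`, "parent")),
    child = unlist(lapply(parts, `[[`, "child")),
    extra = unlist(lapply(parts, `[[`, "extra")))
}

genome_hash <- function(genome) rlang::hash(unclass(genome))

archive_genome <- function(sim, key, genome) {
  if (sim$record_genomes) assign(key, genome, envir = sim$archive)
}

alive_ids <- function(sim) {
  v <- as.integer(sim$occ)
  sort(unique(v[v > 0L]))
}

get_holo <- function(sim, id) get0(as.character(id), envir = sim$holos)

set_holo <- function(sim, id, h) assign(as.character(id), h, envir = sim$holos)

del_holo <- function(sim, id) rm(list = as.character(id), envir = sim$holos)

# alive holobionts in id order
holo_list <- function(sim, ids) mget(as.character(ids), envir = sim$holos)

# The per-step state of a holobiont's cells (expression, fork, stage
# progress) lives in flat arrays on the holobiont, consumed directly by the
# compiled step; the cell objects are synchronized lazily at division and
# death events.
sync_holo_state <- function(h) {
  nc <- length(h$syms) + 1L
  caches <- vector("list", nc)
  exprs <- vector("list", nc)
  forks <- integer(nc); progs <- integer(nc)
  stgs <- integer(nc); lens <- integer(nc)
  for (i in seq_len(nc)) {
    cl <- if (i == 1L) h$host else h$syms[[i - 1L]]
    caches[[i]] <- cl$cache
    exprs[[i]] <- cl$expression
    forks[i] <- cl$fork; progs[i] <- cl$prog
    stgs[i] <- cl$stg; lens[i] <- length(cl$genome$kind)
  }
  h$caches <- caches; h$exprs <- exprs; h$forks <- forks
  h$progs <- progs; h$stgs <- stgs; h$lens <- lens
  h
}

# copy the array state of slot i (1 = host) back into its cell object
materialize_cell <- function(h, i) {
  cl <- if (i == 1L) h$host else h$syms[[i - 1L]]
  cl$expression <- h$exprs[[i]]
  cl$fork <- h$forks[i]
  cl$prog <- h$progs[i]
  cl$stg <- h$stgs[i]
  cl
}

# ---------------------------------------------------------------------------
# holobionts

new_holobiont <- function(sim, host, syms, row, col, parent = NA_integer_) {
  row <- as.integer(row); col <- as.integer(col)
  id <- sim$next_holo_id
  sim$next_holo_id <- id + 1L
  for (s in seq_along(syms)) {
    if (is.null(syms[[s]]$sym_id)) {
      syms[[s]]$sym_id <- sim$next_sym_id
      sim$next_sym_id <- sim$next_sym_id + 1L
      archive_genome(sim, paste0("s", syms[[s]]$sym_id), syms[[s]]$genome)
      log_event(sim, "sym_birth", row, col, holo = id,
                parent = NA_integer_, child = syms[[s]]$sym_id)
    }
  }
  h <- list(id = id, host = host, syms = syms, row = row, col = col,
            birth_sym_count = length(syms), pending = FALSE)
  h <- sync_holo_state(h)
  set_holo(sim, id, h)
  sim$occ[row, col] <- id
  sim$ncells[row, col] <- 1L + length(syms)
  archive_genome(sim, paste0("h", id), host$genome)
  log_event(sim, if (is.na(parent)) "inoculate" else "birth",
            row, col, holo = id, parent = parent, child = id,
            extra = genome_hash(host$genome))
  id
}

#' Inoculate holobionts onto the grid
#'
#' Places clonal holobionts (one host plus `n_sym` symbionts, all built
#' from the given genomes) on the requested sites, or on a uniformly random
#' fraction of all sites.
#'
#' @param sim an `endo_sim`.
#' @param host_genome,sym_genome `endo_genome`s for hosts and symbionts.
#' @param sites a 2-column matrix of (row, col) positions, or `NULL`.
#' @param fraction if `sites` is `NULL`, the fraction of grid sites to
#'   occupy (sampled without replacement).
#' @param n_sym symbionts per holobiont at inoculation.
#' @return the sim, invisibly.
#' @export
inoculate <- function(sim, host_genome, sym_genome, sites = NULL,
                      fraction = 0.1, n_sym = 2L) {
  if (is.null(sites)) {
    total <- sim$height * sim$width
    picks <- sample.int(total, max(1L, round(fraction * total)))
    sites <- cbind((picks - 1L) %% sim$height + 1L,
                   (picks - 1L) %/% sim$height + 1L)
  }
  for (i in seq_len(nrow(sites))) {
    row <- sites[i, 1]; col <- sites[i, 2]
    if (sim$occ[row, col] != 0L) next
    host <- new_cell(host_genome, "host", sim$config)
    syms <- replicate(n_sym, new_cell(sym_genome, "symbiont", sim$config),
                      simplify = FALSE)
    new_holobiont(sim, host, syms, row, col)
  }
  invisible(sim)
}

# Moore neighborhood site list (toroidal width, bounded height), incl. own
moore_sites <- function(sim, row, col) {
  rows <- row + c(-1L, 0L, 1L)
  rows <- rows[rows >= 1L & rows <= sim$height]
  cols <- (col + c(-1L, 0L, 1L) - 1L) %% sim$width + 1L
  cbind(rep(rows, times = length(cols)), rep(cols, each = length(rows)))
}

#' Nutrient share and replication speed at a site
#'
#' The nutrient available to each cell at an occupied site is the site's
#' influx divided by the total number of cells (hosts plus symbionts) of
#' all holobionts in the 3x3 Moore neighborhood. The replication budget is
#' `k = max(1, floor(A / rho))` beads per timestep, so crowding and high
#' symbiont loads slow down genome replication.
#'
#' @param sim an `endo_sim`.
#' @param site `c(row, col)` of an occupied site.
#' @return list with `A` (available nutrient per cell) and `k` (beads per
#'   step).
#' @export
nutrient_share <- function(sim, site) {
  row <- site[1]; col <- site[2]
  if (sim$occ[row, col] == 0L) stop("site not occupied", call. = FALSE)
  rows <- max(1L, row - 1L):min(sim$height, row + 1L)
  cols <- (col + c(-2L, -1L, 0L)) %% sim$width + 1L
  C <- sum(sim$ncells[rows, cols])
  A <- sim$influx[row, col] / C
  # k = 0 under starvation: replication halts, which is the feedback that
  # keeps symbiont loads bounded in crowded neighbourhoods
  list(A = A, k = as.integer(floor(A / sim$config$dynamics$rho)))
}

#' Divide a holobiont
#'
#' The host divides via [divide_cell()]; each symbiont is assigned
#' independently to daughter A or B with probability 1/2. A daughter
#' receiving zero symbionts is dead on arrival. Newly divided cells receive
#' gene transfers from the partner compartment per the interference
#' configuration.
#'
#' @param h a holobiont (list with `host`, `syms`) whose host is
#'   divided-ready.
#' @param config run configuration.
#' @param rates mutation rates applied to dividing genomes.
#' @return list of two daughters, each either a list with `host`, `syms`,
#'   `birth_sym_count` or `NULL` if that daughter received no symbiont.
#' @export
divide_holobiont <- function(h, config = default_config(), rates = NULL) {
  if (is.null(rates)) rates <- config$mutation
  daughters_host <- divide_cell(h$host, rates)
  side <- stats::runif(length(h$syms)) < 0.5
  parts <- list(h$syms[side], h$syms[!side])
  out <- vector("list", 2L)
  for (i in 1:2) {
    if (length(parts[[i]]) == 0L) next  # dead on arrival
    host <- daughters_host[[i]]
    syms <- parts[[i]]
    # endosymbiotic gene transfer into the newly divided host
    tr <- gene_transfer(host$genome, lapply(syms, `[[`, "genome"),
                        config$interference)
    if (tr$n_transfers > 0L) {
      host <- new_cell(tr$recipient, "host", config,
                       expression = expression_after_resize(host, tr$recipient))
      for (s in seq_along(syms)) {
        if (!identical(syms[[s]]$genome, tr$donors[[s]])) {
          syms[[s]] <- replace_genome(syms[[s]], tr$donors[[s]], config)
        }
      }
    }
    out[[i]] <- list(host = host, syms = syms,
                     birth_sym_count = length(syms),
                     n_transfers = tr$n_transfers)
  }
  out
}

# crude expression carry-over when a genome changed length out-of-band
# (gene transfer): genes are matched by position order; new genes start off.
expression_after_resize <- function(cell, new_genome) {
  cache <- build_regulatory_cache(new_genome)
  ng <- length(cache$gene_pos)
  old <- cell$expression
  out <- rep(FALSE, ng)
  n <- min(ng, length(old))
  out[seq_len(n)] <- old[seq_len(n)]
  out
}

# ---------------------------------------------------------------------------

#' Advance the whole population by one timestep
#'
#' One timestep over all occupied sites, processed in randomized order. For
#' each holobiont: the local nutrient share sets the replication budget `k`;
#' signal-peptide targeting and then leakage build the foreign product pools
#' of host and symbionts; every cell performs one regulatory step; symbiont
#' divisions add a symbiont in place; a divided-ready host places one
#' daughter holobiont in a uniformly random empty Moore-neighborhood site
#' (stalling, and retrying next step, if there is none); deaths (premature
#' mitosis, symbiont loss, basal death at rate `delta`) free the site.
#'
#' @param sim an `endo_sim`; mutated in place.
#' @return the sim, invisibly.
#' @export
step_population <- function(sim) {
  sim$step <- sim$step + 1L
  ids <- alive_ids(sim)
  if (length(ids) == 0L) return(invisible(sim))
  ord <- if (length(ids) == 1L) ids else sample(ids)
  cfg <- sim$config
  icfg <- cfg$interference

  # one compiled pass over the whole grid: nutrient shares (from the
  # step-start cell counts), targeting, leakage, regulation, stage
  # bookkeeping and basal-death draws. Holobiont state arrays are updated
  # in place; only holobionts with an event need R-level handling below.
  res <- .grid_step(holo_list(sim, ord), seq_along(ord),
                    sim$influx, sim$ncells,
                    cfg$dynamics$rho, unclass(cfg$stage_table),
                    cfg$affinity$c, cfg$affinity$s,
                    icfg$l,
                    isTRUE(icfg$targeting$host_to_symbiont),
                    isTRUE(icfg$targeting$symbiont_to_host),
                    leak_enabled(icfg, "host_to_symbiont"),
                    leak_enabled(icfg, "symbiont_to_host"),
                    cfg$dynamics$delta)

  for (hi in which(res$att == 1L)) {
    id <- ord[hi]
    h <- get_holo(sim, id)
    if (is.null(h) || sim$occ[h$row, h$col] != id) next
    nc <- length(h$syms) + 1L
    ev <- res$events[res$offset[hi] + seq_len(nc)]

    died <- FALSE
    # --- host (frozen while waiting for space)
    if (!h$pending) {
      if (ev[1] == 2L) {
        h$host$alive <- FALSE
        died <- TRUE
      } else if (ev[1] == 1L) {
        host <- materialize_cell(h, 1L)
        host$ready <- TRUE
        host$stage <- "M"
        host$passed <- c("G1", "S", "G2")
        h$host <- host
        h$pending <- TRUE
      }
    }

    # --- symbionts: only touched when one divided or died this step
    if (!died && length(ev) > 1L && any(ev[-1L] != 0L)) {
      h$host <- materialize_cell(h, 1L)
      new_syms <- list()
      for (s in seq_along(h$syms)) {
        i <- s + 1L
        if (ev[i] == 2L) {
          log_event(sim, "sym_death", h$row, h$col, holo = id,
                    parent = h$syms[[s]]$sym_id)
          next
        }
        sym <- materialize_cell(h, i)
        if (ev[i] == 1L) {
          sym$ready <- TRUE
          sym$stage <- "M"
          sym$passed <- c("G1", "S", "G2")
          kids <- divide_cell(sym, cfg$mutation)
          # transfers from the host into each newly divided symbiont
          for (kk in 1:2) {
            tr <- gene_transfer(kids[[kk]]$genome, list(h$host$genome), icfg)
            if (tr$n_transfers > 0L) {
              kids[[kk]] <- new_cell(tr$recipient, "symbiont", cfg,
                                     expression = expression_after_resize(kids[[kk]], tr$recipient))
              h$host <- replace_genome(h$host, tr$donors[[1]], cfg)
              log_event(sim, "transfer", h$row, h$col, holo = id,
                        extra = "host_to_symbiont")
            }
          }
          for (kk in 1:2) {
            kids[[kk]]$sym_id <- sim$next_sym_id
            sim$next_sym_id <- sim$next_sym_id + 1L
            archive_genome(sim, paste0("s", kids[[kk]]$sym_id), kids[[kk]]$genome)
            log_event(sim, "sym_birth", h$row, h$col, holo = id,
                      parent = sym$sym_id, child = kids[[kk]]$sym_id)
            new_syms[[length(new_syms) + 1L]] <- kids[[kk]]
          }
          next
        }
        new_syms[[length(new_syms) + 1L]] <- sym
      }
      h$syms <- new_syms
      if (length(h$syms) == 0L) died <- TRUE else h <- sync_holo_state(h)
    }

    # --- host division into an empty neighbor site
    if (!died && h$pending) {
      nb <- moore_sites(sim, h$row, h$col)
      empty <- which(sim$occ[nb] == 0L)
      if (length(empty)) {
        pick <- nb[if (length(empty) == 1L) empty else sample(empty, 1L), , drop = FALSE]
        # bring every symbiont's array state back into its cell before the
        # daughters inherit them (the host cell was materialized at ready)
        for (s in seq_along(h$syms)) h$syms[[s]] <- materialize_cell(h, s + 1L)
        daughters <- divide_holobiont(h, cfg, cfg$mutation)
        # parent site keeps daughter 1, new site gets daughter 2
        sim$occ[h$row, h$col] <- 0L
        sim$ncells[h$row, h$col] <- 0L
        del_holo(sim, id)
        placed <- FALSE
        for (i in 1:2) {
          d <- daughters[[i]]
          if (is.null(d)) next
          tgt <- if (i == 1L) c(h$row, h$col) else c(pick[1], pick[2])
          did <- new_holobiont(sim, d$host, d$syms, tgt[1], tgt[2], parent = id)
          if (d$n_transfers > 0L)
            log_event(sim, "transfer", tgt[1], tgt[2], holo = did,
                      extra = "symbiont_to_host")
          placed <- TRUE
        }
        if (!placed)
          log_event(sim, "death", h$row, h$col, holo = id, extra = "no_viable_daughter")
        next
      }
      # no empty neighbor: stall in divided-ready, retry next step
    }

    # --- basal death (drawn in the compiled pass)
    if (!died && res$basal[hi] == 1L) died <- TRUE

    if (died) {
      sim$occ[h$row, h$col] <- 0L
      sim$ncells[h$row, h$col] <- 0L
      del_holo(sim, id)
      log_event(sim, "death", h$row, h$col, holo = id,
                extra = if (!h$host$alive) "host_death" else if (length(h$syms) == 0L) "symbiont_loss" else "basal")
    } else {
      set_holo(sim, id, h)
      sim$ncells[h$row, h$col] <- 1L + length(h$syms)
    }
  }
  invisible(sim)
}

replace_genome <- function(cell, genome, config) {
  out <- new_cell(genome, cell$role, config,
                  expression = expression_after_resize(cell, genome))
  out$sym_id <- cell$sym_id
  out$stage <- cell$stage; out$passed <- cell$passed
  out$prog <- cell$prog; out$stg <- cell$stg
  out$fork <- min(cell$fork, length(genome$kind))
  out$age <- cell$age
  out$ready <- cell$ready
  out$alive <- cell$alive
  out
}

#' Run a simulation for many steps
#'
#' @param sim an `endo_sim`.
#' @param steps number of timesteps.
#' @param summary_every collect [population_summary()] every this many
#'   steps (0 = never).
#' @return a tibble of collected summaries (zero rows if none), invisibly;
#'   the sim itself is mutated in place.
#' @export
run_simulation <- function(sim, steps, summary_every = 0L) {
  out <- list()
  for (t in seq_len(steps)) {
    step_population(sim)
    if (summary_every > 0L && sim$step %% summary_every == 0L)
      out[[length(out) + 1L]] <- population_summary(sim)
    if (length(alive_ids(sim)) == 0L) break
  }
  invisible(if (length(out)) dplyr::bind_rows(out) else tibble::tibble())
}

#' Population summary
#'
#' @param sim an `endo_sim`.
#' @return a one-row tibble: `step`, `N` (occupied fraction), `n_holos`,
#'   `mean_symbionts`, `S_H` (mean symbiont count at birth), means of `L`
#'   and `R` for hosts and symbionts, plus a nested `sectors` tibble with
#'   per-sector occupancy and genome-size means.
#' @export
population_summary <- function(sim) {
  ids <- alive_ids(sim)
  total <- sim$height * sim$width
  if (length(ids) == 0L) {
    return(tibble::tibble(step = sim$step, N = 0, n_holos = 0L,
                          mean_symbionts = NA_real_, S_H = NA_real_,
                          host_L = NA_real_, host_R = NA_real_,
                          sym_L = NA_real_, sym_R = NA_real_,
                          sectors = list(tibble::tibble())))
  }
  hs <- holo_list(sim, ids)
  nsym <- vapply(hs, function(h) length(h$syms), 1L)
  sh <- vapply(hs, function(h) h$birth_sym_count, 1L)
  hostL <- vapply(hs, function(h) length(h$host$genome$kind), 1L)
  hostR <- vapply(hs, function(h) sum(h$host$genome$kind != "H"), 1L)
  symL <- vapply(hs, function(h)
    mean(vapply(h$syms, function(s) length(s$genome$kind), 1L)), 1)
  symR <- vapply(hs, function(h)
    mean(vapply(h$syms, function(s) sum(s$genome$kind != "H"), 1L)), 1)
  rows <- vapply(hs, function(h) h$row, 1L)
  rows_per_sector <- sim$height %/% sim$config$grid$sectors
  sector <- (rows - 1L) %/% rows_per_sector + 1L
  sectors <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(sector = sector, hostL = hostL,
                                   symL = symL, nsym = nsym), sector),
    n = dplyr::n(), host_L = mean(hostL), sym_L = mean(symL),
    mean_symbionts = mean(nsym), .groups = "drop")
  sectors$N <- sectors$n / (rows_per_sector * sim$width)
  tibble::tibble(step = sim$step, N = length(ids) / total,
                 n_holos = length(ids),
                 mean_symbionts = mean(nsym), S_H = mean(sh),
                 host_L = mean(hostL), host_R = mean(hostR),
                 sym_L = mean(symL), sym_R = mean(symR),
                 sectors = list(sectors))
}
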