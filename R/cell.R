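#' Cells: staged cell-cycle state machines
#'
#' A cell couples a genome to an expression state, a cell-cycle stage, a
#' replication fork and a pool of foreign products received this timestep.
#' `passed` records the stages completed since the last division, in order;
#' it resets at division. `fork` counts beads replicated (0..L); a gene bead
#' at position `<= fork` has been replicated and its product carries double
#' dosage.
#'
#' @param genome an `endo_genome`.
#' @param role `"host"` or `"symbiont"`; decides which signal-peptide bit
#'   keeps a product in this cell's own compartment.
#' @param config a run configuration ([default_config()]); supplies the
#'   stage table and affinity constants.
#' @param expression initial expression state (logical over genes); default
#'   all off.
#' @return an object of class `endo_cell`.
#' @export
new_cell <- function(genome, role = c("host", "symbiont"),
                     config = default_config(), expression = NULL) {
  role <- match.arg(role)
  cache <- build_regulatory_cache(genome)
  cache$native <- sp_native_mask(cache, role)
  cache$stage_codes <- unclass(config$stage_table)
  cache$aff_c <- config$affinity$c
  cache$aff_s <- config$affinity$s
  ng <- length(cache$gene_pos)
  if (is.null(expression)) {
    # genomes can carry a canonical birth expression (the state of a freshly
    # divided cell); without one, start fully unexpressed
    init <- attr(genome, "init_expression")
    expression <- if (!is.null(init) && length(init) == ng) init else rep(FALSE, ng)
  }
  stopifnot(length(expression) == ng)
  structure(list(
    genome = genome, cache = cache, role = role,
    expression = as.logical(expression),
    stage = "G1", passed = character(0),
    prog = 0L, stg = 1L,   # integer mirrors of passed/stage for the
                           # batched population step
    fork = 0L, foreign = NULL,
    alive = TRUE, ready = FALSE,
    age = 0L, config = config
  ), class = "endo_cell")
}

#' @export
print.endo_cell <- function(x, ...) {
  cat(sprintf("<endo_cell %s> stage=%s passed=[%s] fork=%d/%d %s\n",
              x$role, x$stage, paste(x$passed, collapse = ","),
              x$fork, length(x$genome$kind),
              if (x$alive) "alive" else "dead"))
  invisible(x)
}

stage_successor <- c(G1 = "S", S = "G2", G2 = "M")

# native product pool of a cell given current expression and fork.
# sp filtering: a product is natively present iff its signal peptide keeps
# it in the cell's own compartment (own bit set, or no relocation "00").
native_pool <- function(cell) {
  cache <- cell$cache
  idx <- which(cell$expression & cache$native)
  if (!length(idx)) return(product_pool())
  copies <- 1 + (cache$gene_pos[idx] <= cell$fork)
  structure(list(origin = rep(cell$role, length(idx)),
                 type_id = cache$gene_type[idx],
                 seq = cache$gene_seq[idx],
                 weight = cache$gene_w[idx],
                 copies = as.numeric(copies),
                 localization = rep("native", length(idx))),
            class = "product_pool")
}

stage_codes <- c(G1 = 1L, S = 2L, G2 = 3L, M = 4L)

#' Advance a cell by one timestep
#'
#' One timestep of the single-cell dynamics: (1) native products are built
#' from the currently expressed genes, with dosage doubled for replicated
#' beads; (2) the foreign pool received this step is merged in; (3) every
#' binding site samples its occupant; (4) expression is updated against the
#' activation thresholds; (5) the core pattern is decoded against the stage
#' table. A decoded stage that is the successor of the last completed stage
#' advances the cycle; decoding M without having passed G1, S, G2 in order,
#' or with an unfinished replication fork, kills the cell; while the cell is
#' in S-phase the fork advances by up to `k` beads. The foreign pool is
#' cleared at the end of the step.
#'
#' @param cell an `endo_cell`.
#' @param k beads-per-step replication budget (nutrient-dependent).
#' @return a list with `cell` (updated) and `event`: one of `"none"`,
#'   `"divided-ready"`, `"died"`.
#' @export
step_cell <- function(cell, k) {
  if (!cell$alive) stop("step_cell() called on a dead cell", call. = FALSE)
  cache <- cell$cache

  fn <- cell$foreign
  if (is.null(fn))
    fn <- list(type_id = integer(0), seq = integer(0), weight = numeric(0),
               copies = numeric(0))
  res <- .cell_regulation(cache$site_seq, cache$site_gene, cache$gene_thr,
                          cache$gene_seq, cache$gene_type, cache$gene_w,
                          cache$gene_pos, cache$native, cell$expression,
                          cell$fork, fn$seq, as.numeric(fn$weight),
                          as.numeric(fn$copies), fn$type_id,
                          cache$stage_codes, cache$aff_c, cache$aff_s)
  cell$expression <- res$expr
  si <- res$stage_index

  event <- "none"
  L <- length(cell$genome$kind)
  if (si > 0L) {
    np <- length(cell$passed)  # passed is always the in-order stage prefix
    if (si == 4L) {
      if (np == 3L && cell$fork >= L) {
        cell$stage <- "M"
        cell$ready <- TRUE
        event <- "divided-ready"
      } else {
        cell$alive <- FALSE
        event <- "died"
      }
    } else if (si == np + 1L) {
      st <- names(stage_codes)[si]
      cell$stage <- st
      cell$passed <- c(cell$passed, st)
    } # any other match stalls
  }
  if (cell$alive && cell$stage == "S") {
    cell$fork <- cell$fork + min(k, L - cell$fork)
  }
  cell$foreign <- NULL  # foreign products live one timestep
  cell$age <- cell$age + 1L
  list(cell = cell, event = event)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Divide a cell into two daughters
#'
#' The parent must be divided-ready (M decoded legitimately: fork at L and
#' all stages passed in order). Each daughter receives an independently
#' mutated copy of the genome, a reset fork and stage history, an empty
#' foreign pool, and inherits the parent's expression state (mapped through
#' the structural mutations: duplicated beads inherit the source gene's
#' state, innovations start unexpressed).
#'
#' @param cell a divided-ready `endo_cell`.
#' @param rates a [mutation_rates()] set; use `zero_rates()` to copy
#'   genomes unchanged (clonal assays).
#' @return list of two `endo_cell` daughters.
#' @export
divide_cell <- function(cell, rates = NULL) {
  if (!isTRUE(cell$ready))
    stop("divide_cell() called on a cell that is not divided-ready", call. = FALSE)
  if (is.null(rates)) rates <- cell$config$mutation
  daughter <- function() {
    g <- mutate_genome(cell$genome, rates, config = cell$config)
    if (isTRUE(attr(g, "unchanged"))) {
      # no mutation events: the daughter shares the parent's genome and
      # regulatory cache (both treated as immutable)
      d <- cell
      d$passed <- character(0)
      d$stage <- "G1"
      d$prog <- 0L
      d$stg <- 1L
      d$fork <- 0L
      d$foreign <- NULL
      d$ready <- FALSE
      d$alive <- TRUE
      d$age <- 0L
      d$sym_id <- NULL
      return(d)
    }
    origin <- attr(g, "origin")
    cache <- build_regulatory_cache(g)
    # map parent's per-gene expression onto the daughter's genes
    parent_gene_of <- match(origin[cache$gene_pos], cell$cache$gene_pos)
    expr <- rep(FALSE, length(cache$gene_pos))
    known <- !is.na(parent_gene_of)
    expr[known] <- cell$expression[parent_gene_of[known]]
    d <- new_cell(g, role = cell$role, config = cell$config, expression = expr)
    d
  }
  list(daughter(), daughter())
}

#' Minimal cycle time and cell-cycle efficiency
#'
#' The fastest possible cycle for genome size `L` at replication speed `k`
#' spends one timestep in each of G1, G2 and M and `ceiling(L / k)` steps
#' replicating in S, so `tau_min = ceiling(L / k) + 3`. Efficiency compares
#' this floor with an observed cycle duration: `e = tau_min / tau`, in
#' (0, 1].
#'
#' @param L genome size (beads).
#' @param k beads replicated per timestep, `k >= 1`.
#' @param tau_min,tau minimal and observed cycle durations (timesteps).
#' @return `minimal_cycle_time()` an integer; `efficiency()` a numeric in
#'   (0, 1].
#' @export
minimal_cycle_time <- function(L, k) {
  stopifnot(k >= 1)
  as.integer(ceiling(L / k) + 3L)
}

#' @rdname minimal_cycle_time
#' @export
efficiency <- function(tau_min, tau) {
  if (any(tau < tau_min))
    stop("tau must be >= tau_min", call. = FALSE)
  tau_min / tau
}

#' Single-cell viability check
#'
#' Simulates one isolated cell (no leakage, no foreign products) at the
#' replication speed implied by `n_influx` for a lone cell
#' (`k = max(1, floor(n_influx / rho))`). After each division, the
#' simulation continues with the first daughter. Passes iff the cell
#' completes at least `need` divisions within the horizon `T` and never
#' dies; the check concludes as soon as the verdict is decided (at the
#' `need`-th division, at death, or at `T`). Set `need = Inf` to follow
#' the lineage for the full horizon (as [cycle_metrics()] does).
#'
#' @param genome an `endo_genome`.
#' @param n_influx nutrient influx available to the lone cell.
#' @param T horizon in timesteps.
#' @param config run configuration.
#' @param role compartment tag for signal-peptide filtering.
#' @param need divisions required for a pass.
#' @return a list with `pass`, `divisions`, `died`, and `taus` (observed
#'   cycle durations).
#' @export
viability_check <- function(genome, n_influx = 90, T = 2000,
                            config = default_config(), role = "host",
                            need = 5L) {
  k <- as.integer(floor(n_influx / config$dynamics$rho))
  stopifnot(k >= 1L)
  cell <- new_cell(genome, role = role, config = config)
  divisions <- 0L
  died <- FALSE
  taus <- integer(0)
  last_div <- 0L
  for (t in seq_len(T)) {
    res <- step_cell(cell, k)
    cell <- res$cell
    if (res$event == "died") { died <- TRUE; break }
    if (res$event == "divided-ready") {
      daughters <- divide_cell(cell, zero_rates())
      taus <- c(taus, t - last_div)
      last_div <- t
      divisions <- divisions + 1L
      if (divisions >= need) break
      cell <- daughters[[1]]
    }
  }
  list(pass = !died && divisions >= min(need, 5L), divisions = divisions,
       died = died, taus = taus)
}

#' Observed cell-cycle metrics of an isolated cell
#'
#' Convenience wrapper around [viability_check()] that reports the mean
#' observed cycle duration and the efficiency `e = tau_min / tau`.
#'
#' @inheritParams viability_check
#' @return a list with `tau` (mean), `tau_min` and `e`, or `NULL` if no
#'   division completed.
#' @export
cycle_metrics <- function(genome, n_influx = 90, T = 2000,
                          config = default_config(), role = "host") {
  v <- viability_check(genome, n_influx, T, config, role, need = Inf)
  if (!length(v$taus)) return(NULL)
  k <- as.integer(floor(n_influx / config$dynamics$rho))
  tau_min <- minimal_cycle_time(length(genome$kind), k)
  tau <- mean(v$taus)
  list(tau = tau, tau_min = tau_min, e = efficiency(tau_min, tau))
}
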