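#' Host--symbiont interference configuration
#'
#' The three coupling channels between the host and its symbionts: passive
#' product leakage at rate `l` per expressed gene per symbiont per timestep,
#' signal-peptide targeting (per-direction enable flags, used by the
#' knockout assays), and endosymbiotic gene transfer at a per-gene rate
#' `mu_t` applied to newly divided cells.
#'
#' @param l leakage probability per expressed gene per symbiont per step.
#' @param leakage_mode `"both"`, `"host_to_symbiont"`, `"symbiont_to_host"`
#'   or `"off"`.
#' @param targeting list of per-direction flags `host_to_symbiont`,
#'   `symbiont_to_host`; disabling a direction drops cross-compartment
#'   deliveries in that direction (native-compartment presence is kept).
#' @param mu_t per-gene transfer probability at division.
#' @param transfer_mode `"both"` or `"off"`.
#' @return an `interference_config` list.
#' @export
interference_config <- function(l = 0.01, leakage_mode = "both",
                                targeting = list(host_to_symbiont = TRUE,
                                                 symbiont_to_host = TRUE),
                                mu_t = 2.0e-5, transfer_mode = "both") {
  leakage_mode <- match.arg(leakage_mode,
                            c("both", "host_to_symbiont", "symbiont_to_host", "off"))
  transfer_mode <- match.arg(transfer_mode, c("both", "off"))
  stopifnot(is.numeric(l), is.numeric(mu_t))
  structure(list(l = l, leakage_mode = leakage_mode,
                 targeting = list(
                   host_to_symbiont = isTRUE(targeting$host_to_symbiont),
                   symbiont_to_host = isTRUE(targeting$symbiont_to_host)),
                 mu_t = mu_t, transfer_mode = transfer_mode),
            class = "interference_config")
}

leak_enabled <- function(cfg, direction) {
  cfg$l > 0 && cfg$leakage_mode %in% c("both", direction)
}

# products of the expressed genes of `cell`, each with 1 copy, tagged with
# the given localization; used for leakage and targeting deliveries.
expressed_products <- function(cell, localization, which_idx = NULL) {
  idx <- which(cell$expression)
  if (!is.null(which_idx)) idx <- idx[which_idx]
  cache <- cell$cache
  structure(list(origin = rep(cell$role, length(idx)),
                 type_id = cache$gene_type[idx],
                 seq = cache$gene_seq[idx],
                 weight = cache$gene_w[idx],
                 copies = rep(1, length(idx)),
                 localization = rep(localization, length(idx))),
            class = "product_pool")
}

#' Passive product leakage between host and symbionts
#'
#' Every expressed host gene leaks a one-copy product into each symbiont
#' independently with probability `l`, and every expressed symbiont gene
#' leaks into the host with probability `l` -- so the influx into a symbiont
#' is proportional to the number of expressed host genes, and the influx
#' into the host is proportional to the total number of expressed genes
#' across all symbionts. Directions can be gated for knockout assays.
#'
#' @param host an `endo_cell` with role `"host"`.
#' @param symbionts list of symbiont `endo_cell`s.
#' @param cfg an [interference_config()].
#' @return a list with `host`: pool of products leaked into the host, and
#'   `symbionts`: list of pools, one per symbiont.
#' @export
apply_leakage <- function(host, symbionts, cfg = interference_config()) {
  n_sym <- length(symbionts)
  sym_pools <- replicate(n_sym, product_pool(), simplify = FALSE)
  host_pool <- product_pool()
  if (leak_enabled(cfg, "host_to_symbiont") && n_sym > 0) {
    n_expr <- sum(host$expression)
    if (n_expr > 0) {
      for (s in seq_len(n_sym)) {
        hit <- which(stats::runif(n_expr) < cfg$l)
        if (length(hit))
          sym_pools[[s]] <- expressed_products(host, "leaked", hit)
      }
    }
  }
  if (leak_enabled(cfg, "symbiont_to_host") && n_sym > 0) {
    parts <- list()
    for (s in seq_len(n_sym)) {
      n_expr <- sum(symbionts[[s]]$expression)
      if (n_expr == 0) next
      hit <- which(stats::runif(n_expr) < cfg$l)
      if (length(hit))
        parts[[length(parts) + 1L]] <- expressed_products(symbionts[[s]], "leaked", hit)
    }
    if (length(parts)) host_pool <- do.call(pool_bind, parts)
  }
  list(host = host_pool, symbionts = sym_pools)
}

#' Signal-peptide targeting of expressed products
#'
#' Each expressed gene's product is delivered according to its 2-bit signal
#' peptide: `10` host only, `01` one copy-record into every symbiont, `00`
#' stays in the compartment of its encoding genome, `11` both. Deliveries
#' that cross compartments are tagged `"targeted"`; presence in the native
#' compartment is handled by the cell's own product construction, so this
#' function returns only the cross-compartment deliveries. Per-direction
#' knockout flags drop crossing deliveries.
#'
#' @inheritParams apply_leakage
#' @return a list with `host` (pool targeted into the host by symbionts)
#'   and `symbionts` (list of pools targeted into each symbiont by the
#'   host).
#' @export
apply_targeting <- function(host, symbionts, cfg = interference_config()) {
  n_sym <- length(symbionts)
  sym_pools <- replicate(n_sym, product_pool(), simplify = FALSE)
  host_pool <- product_pool()
  # host genes whose sp has the symbiont bit -> delivered to every symbiont
  if (isTRUE(cfg$targeting$host_to_symbiont) && n_sym > 0) {
    idx <- which(host$expression)
    cross <- which(bitwAnd(host$cache$gene_sp[idx], 1L) > 0L)
    if (length(cross)) {
      delivery <- expressed_products(host, "targeted", cross)
      for (s in seq_len(n_sym)) sym_pools[[s]] <- delivery
    }
  }
  # symbiont genes whose sp has the host bit -> delivered to the host
  if (isTRUE(cfg$targeting$symbiont_to_host) && n_sym > 0) {
    parts <- list()
    for (s in seq_len(n_sym)) {
      sym <- symbionts[[s]]
      idx <- which(sym$expression)
      cross <- which(bitwAnd(sym$cache$gene_sp[idx], 2L) > 0L)
      if (length(cross))
        parts[[length(parts) + 1L]] <- expressed_products(sym, "targeted", cross)
    }
    if (length(parts)) host_pool <- do.call(pool_bind, parts)
  }
  list(host = host_pool, symbionts = sym_pools)
}

# Fast combined targeting + leakage used by the population loop: returns
# minimal product records (type_id, seq, weight, copies) or NULL per cell.
# Semantics identical to apply_targeting() followed by apply_leakage().
build_foreign_pools <- function(host, syms, cfg) {
  n <- length(syms)
  sym_f <- vector("list", n)
  if (n == 0L ||
      (cfg$l <= 0 && !cfg$targeting$host_to_symbiont &&
       !cfg$targeting$symbiont_to_host))
    return(list(host = NULL, symbionts = sym_f))
  host_parts <- list()
  hc <- host$cache
  hidx <- which(host$expression)
  if (n && length(hidx) && isTRUE(cfg$targeting$host_to_symbiont)) {
    cross <- hidx[bitwAnd(hc$gene_sp[hidx], 1L) > 0L]
    if (length(cross)) {
      dl <- list(type_id = hc$gene_type[cross], seq = hc$gene_seq[cross],
                 weight = hc$gene_w[cross], copies = rep(1, length(cross)))
      for (s in seq_len(n)) sym_f[[s]] <- dl
    }
  }
  if (n && length(hidx) && leak_enabled(cfg, "host_to_symbiont")) {
    for (s in seq_len(n)) {
      hit <- hidx[stats::runif(length(hidx)) < cfg$l]
      if (length(hit)) {
        dl <- list(type_id = hc$gene_type[hit], seq = hc$gene_seq[hit],
                   weight = hc$gene_w[hit], copies = rep(1, length(hit)))
        sym_f[[s]] <- if (is.null(sym_f[[s]])) dl else
          Map(c, sym_f[[s]], dl)
      }
    }
  }
  t_sh <- isTRUE(cfg$targeting$symbiont_to_host)
  l_sh <- leak_enabled(cfg, "symbiont_to_host")
  if (n && (t_sh || l_sh)) {
    for (s in seq_len(n)) {
      sc <- syms[[s]]$cache
      sidx <- which(syms[[s]]$expression)
      if (!length(sidx)) next
      take <- integer(0)
      if (t_sh) take <- sidx[bitwAnd(sc$gene_sp[sidx], 2L) > 0L]
      if (l_sh) take <- c(take, sidx[stats::runif(length(sidx)) < cfg$l])
      if (length(take))
        host_parts[[length(host_parts) + 1L]] <-
          list(type_id = sc$gene_type[take], seq = sc$gene_seq[take],
               weight = sc$gene_w[take], copies = rep(1, length(take)))
    }
  }
  host_f <- if (length(host_parts) == 1L) host_parts[[1]]
            else if (length(host_parts)) Reduce(function(a, b) Map(c, a, b), host_parts)
            else NULL
  list(host = host_f, symbionts = sym_f)
}

#' Endosymbiotic gene transfer at division
#'
#' A newly divided host can receive gene beads from each of its symbionts,
#' and a newly divided symbiont from the host, each gene independently with
#' probability `mu_t`. A transfer is copy-and-paste or cut-and-paste with
#' probability 1/2 each; cut removes the bead from the donor. The
#' transferred unit is the gene bead alone (no flanking binding sites), and
#' it is inserted at a uniformly random position of the recipient genome.
#'
#' @param recipient an `endo_genome` of a newly divided cell.
#' @param donors list of `endo_genome`s (the partner compartment's genomes).
#' @param cfg an [interference_config()].
#' @return list with `recipient` (possibly extended genome), `donors`
#'   (possibly cut genomes) and `n_transfers`.
#' @export
gene_transfer <- function(recipient, donors, cfg = interference_config()) {
  n_tr <- 0L
  if (cfg$transfer_mode == "off" || cfg$mu_t <= 0)
    return(list(recipient = recipient, donors = donors, n_transfers = 0L))
  for (d in seq_along(donors)) {
    donor <- donors[[d]]
    gene_idx <- which(donor$kind == "G")
    hits <- gene_idx[which(stats::runif(length(gene_idx)) < cfg$mu_t)]
    cut_hits <- integer(0)
    for (i in hits) {
      bead <- list(kind = "G", type_id = donor$type_id[i], seq = donor$seq[i],
                   sp = donor$sp[i], weight = donor$weight[i],
                   threshold = donor$threshold[i])
      ins <- sample.int(length(recipient$kind) + 1L, 1L) - 1L
      gfields <- insert_bead(unclass(recipient), ins, bead)
      recipient <- structure(gfields, B = attr(recipient, "B"),
                             class = "endo_genome")
      if (stats::runif(1) < 0.5) cut_hits <- c(cut_hits, i) # cut-and-paste
      n_tr <- n_tr + 1L
    }
    if (length(cut_hits)) {
      keep <- setdiff(seq_along(donor$kind), cut_hits)
      donors[[d]] <- structure(lapply(unclass(donor), `[`, keep),
                               B = attr(donor, "B"), class = "endo_genome")
    }
  }
  list(recipient = recipient, donors = donors, n_transfers = n_tr)
}
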