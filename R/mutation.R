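#' Mutation rate set
#'
#' All per-division genome mutation rates. Defaults are the model's standard
#' values: per-bit binding-sequence flips (`mu_B`), per-bit signal-peptide
#' flips (`mu_S`), per-gene weight and threshold steps (`mu_w`, `mu_theta`),
#' per-bead duplication, deletion and relocation (`mu_dup`, `mu_del`,
#' `mu_rel`), and per-genome innovation of binding sites and regulatory
#' genes (`mu_b_in`, `mu_r_in`). The host--symbiont gene-transfer rate
#' `mu_t` lives in [interference_config()] because transfer crosses
#' genomes.
#'
#' @param mu_B,mu_S,mu_w,mu_theta,mu_dup,mu_del,mu_rel,mu_b_in,mu_r_in
#'   probabilities in `[0, 1]`.
#' @return a `mutation_rates` list.
#' @export
mutation_rates <- function(mu_B = 3.3e-5, mu_S = 1.0e-5,
                           mu_w = 1.67e-4, mu_theta = 1.67e-4,
                           mu_dup = 1.67e-4, mu_del = 1.67e-4,
                           mu_rel = 1.67e-4,
                           mu_b_in = 1.67e-3, mu_r_in = 1.67e-4) {
  r <- list(mu_B = mu_B, mu_S = mu_S, mu_w = mu_w, mu_theta = mu_theta,
            mu_dup = mu_dup, mu_del = mu_del, mu_rel = mu_rel,
            mu_b_in = mu_b_in, mu_r_in = mu_r_in)
  bad <- names(r)[vapply(r, function(x) !is.numeric(x) || x < 0 || x > 1, TRUE)]
  if (length(bad))
    stop("rates out of [0,1]: ", paste(bad, collapse = ", "), call. = FALSE)
  structure(r, class = "mutation_rates")
}

#' @rdname mutation_rates
#' @export
zero_rates <- function() {
  mutation_rates(0, 0, 0, 0, 0, 0, 0, 0, 0)
}

#' @rdname mutation_rates
#' @param rates a `mutation_rates` object.
#' @param factor multiplier applied to every rate (capped at 1).
#' @export
scale_rates <- function(rates, factor) {
  do.call(mutation_rates, lapply(unclass(rates), function(x) min(1, x * factor)))
}

#' Mutate a genome at division
#'
#' Applies, in fixed order: per-bead structural operators (duplication,
#' deletion, relocation; each Bernoulli per bead of the pre-mutation bead
#' list), per-genome innovations (a fresh random binding site and/or a fresh
#' regulatory gene with an unused type label), then per-element value
#' mutations (sequence bit flips at `mu_B` on every gene and site, signal
#' peptide bit flips at `mu_S`, weight steps of +/-1 at `mu_w` clamped to
#' the configured range, threshold steps at `mu_theta`). Household beads
#' undergo only the structural operators. Duplications insert the copy
#' immediately downstream of the original; relocations and innovations
#' insert at a uniformly random position.
#'
#' @param genome an `endo_genome`.
#' @param rates a [mutation_rates()] set.
#' @param config run configuration (weight/threshold ranges, `B`).
#' @return the mutated `endo_genome`. Attribute `"origin"` maps each output
#'   bead to its source position in the input (`NA` for innovations);
#'   attribute `"events"` counts the operator events that occurred.
#' @export
mutate_genome <- function(genome, rates, config = default_config()) {
  g <- unclass(genome)
  B <- attr(genome, "B")
  n0 <- length(g$kind)
  origin <- seq_len(n0)
  ev <- c(dup = 0L, del = 0L, rel = 0L, b_in = 0L, r_in = 0L,
          bit = 0L, sp = 0L, w = 0L, theta = 0L)

  # Event counts are drawn as Binomial(n, mu) and positions uniformly
  # without replacement -- identical in law to per-bead Bernoulli draws,
  # and cheap for the overwhelmingly common zero-event division.
  n_gene0 <- sum(g$kind == "G")
  n_seq0 <- n_gene0 + sum(g$kind == "B")
  cnt <- stats::rbinom(9L,
                       c(n0, n0, n0, 1L, 1L,
                         n_seq0 * B, n_gene0 * 2L, n_gene0, n_gene0),
                       c(rates$mu_dup, rates$mu_del, rates$mu_rel,
                         rates$mu_b_in, rates$mu_r_in,
                         rates$mu_B, rates$mu_S, rates$mu_w, rates$mu_theta))
  if (all(cnt == 0L)) {
    # untouched: return the input object itself (bead vectors stay shared
    # between parent and daughters, which keeps long runs lean)
    out <- genome
    attr(out, "origin") <- origin
    attr(out, "events") <- ev
    attr(out, "unchanged") <- TRUE
    return(out)
  }
  sc <- cnt[1:5]
  vc <- cnt[6:9]

  # --- structural operators, sampled on the pre-mutation bead list
  dup <- if (sc[1] > 0L) sample.int(n0, sc[1]) else integer(0)
  del <- if (sc[2] > 0L) sample.int(n0, sc[2]) else integer(0)
  rel <- if (sc[3] > 0L) sample.int(n0, sc[3]) else integer(0)
  if (length(dup) || length(del) || length(rel)) {
    # each operator samples the pre-mutation list independently: a deleted
    # or relocated bead still leaves its duplication copy in place, and a
    # bead hit by both deletion and relocation is simply deleted
    reloc <- setdiff(rel, del)
    order_out <- integer(0)
    for (i in seq_len(n0)) {
      if (!(i %in% del) && !(i %in% reloc)) order_out <- c(order_out, i)
      if (i %in% dup) order_out <- c(order_out, i)    # adjacent copy
    }
    ev["dup"] <- length(dup)
    ev["del"] <- length(del)
    ev["rel"] <- length(reloc)
    for (i in reloc) {
      slot <- sample.int(length(order_out) + 1L, 1L) - 1L
      order_out <- append(order_out, i, after = slot)
    }
    origin <- order_out
    g <- lapply(g, `[`, order_out)
  }

  # --- per-genome innovations
  n <- length(g$kind)
  if (sc[4] > 0L) {
    ins <- sample.int(n + 1L, 1L) - 1L
    g <- insert_bead(g, ins, list(kind = "B", type_id = NA_integer_,
                                  seq = random_mask(B), sp = NA_integer_,
                                  weight = NA_integer_, threshold = NA_integer_))
    origin <- append(origin, NA_integer_, after = ins)
    n <- n + 1L
    ev["b_in"] <- 1L
  }
  if (sc[5] > 0L) {
    gene <- innovate_gene(g, config)
    ins <- sample.int(n + 1L, 1L) - 1L
    g <- insert_bead(g, ins, list(kind = "G", type_id = gene$type_id,
                                  seq = gene$seq, sp = gene$sp,
                                  weight = gene$weight,
                                  threshold = gene$threshold))
    origin <- append(origin, NA_integer_, after = ins)
    n <- n + 1L
    ev["r_in"] <- 1L
  }

  # --- per-element value mutations (sizes follow the post-structural list;
  # redrawn if a structural or innovation event changed the bead counts)
  seq_idx <- which(g$kind != "H")
  gene_idx <- which(g$kind == "G")
  if (any(sc > 0L)) {
    vc <- stats::rbinom(4L,
                        c(length(seq_idx) * B, length(gene_idx) * 2L,
                          length(gene_idx), length(gene_idx)),
                        c(rates$mu_B, rates$mu_S, rates$mu_w, rates$mu_theta))
  }
  if (vc[1] > 0L) {
    for (h in sample.int(length(seq_idx) * B, vc[1])) {
      el <- seq_idx[((h - 1L) %/% B) + 1L]
      bit <- ((h - 1L) %% B)
      g$seq[el] <- bitwXor(g$seq[el], bitwShiftL(1L, bit))
    }
    ev["bit"] <- vc[1]
  }
  if (vc[2] > 0L) {
    for (h in sample.int(length(gene_idx) * 2L, vc[2])) {
      el <- gene_idx[((h - 1L) %/% 2L) + 1L]
      bit <- (h - 1L) %% 2L   # 0 = symbiont bit, 1 = host bit
      g$sp[el] <- bitwXor(g$sp[el], bitwShiftL(1L, bit))
    }
    ev["sp"] <- vc[2]
  }
  if (vc[3] > 0L) {
    wr <- config$ranges$weight
    for (el in gene_idx[sample.int(length(gene_idx), vc[3])]) {
      g$weight[el] <- clamp(g$weight[el] + sample(c(-1L, 1L), 1L), wr[1], wr[2])
    }
    ev["w"] <- vc[3]
  }
  if (vc[4] > 0L) {
    tr <- config$ranges$threshold
    for (el in gene_idx[sample.int(length(gene_idx), vc[4])]) {
      g$threshold[el] <- clamp(g$threshold[el] + sample(c(-1L, 1L), 1L), tr[1], tr[2])
    }
    ev["theta"] <- vc[4]
  }

  out <- structure(g, B = B, class = "endo_genome")
  attr(out, "origin") <- origin
  attr(out, "events") <- ev
  out
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

insert_bead <- function(g, after, bead) {
  idx <- seq_along(g$kind)
  pre <- idx[idx <= after]
  post <- idx[idx > after]
  lapply(stats::setNames(names(g), names(g)), function(f) {
    v <- g[[f]]
    c(v[pre], bead[[f]], v[post])
  })
}

#' Create a de novo regulatory gene
#'
#' Innovated genes get a fresh type label strictly greater than any label in
#' the genome (and never a core label 1--5), a uniform random sequence, a
#' uniform random weight and threshold within the configured ranges, and no
#' signal peptide (`"00"`), so cross-compartment targeting of new genes has
#' to evolve through signal-peptide mutations.
#'
#' @param genome an `endo_genome` (or its unclassed field list).
#' @param config run configuration.
#' @return a one-gene list with fields `type_id`, `seq`, `sp`, `weight`,
#'   `threshold`.
#' @export
innovate_gene <- function(genome, config = default_config()) {
  used <- genome$type_id
  top <- max(5L, used[!is.na(used)])
  wr <- config$ranges$weight
  tr <- config$ranges$threshold
  list(type_id = top + 1L,
       seq = random_mask(config$B),
       sp = 0L,
       weight = as.integer(sample(seq(wr[1], wr[2]), 1L)),
       threshold = as.integer(sample(seq(tr[1], tr[2]), 1L)))
}

#' Expected mutation events per division
#'
#' Closed-form expectations used as a Monte-Carlo oracle: `L * mu` for each
#' per-bead structural operator, total sequence bits times `mu_B`, gene
#' count times the per-gene rates, and the per-genome innovation rates
#' themselves.
#'
#' @param genome an `endo_genome`.
#' @param rates a [mutation_rates()] set.
#' @return named numeric vector of per-division expected event counts.
#' @export
expected_event_counts <- function(genome, rates) {
  L <- length(genome$kind)
  B <- attr(genome, "B")
  n_seq <- sum(genome$kind != "H")
  n_gene <- sum(genome$kind == "G")
  c(dup = L * rates$mu_dup, del = L * rates$mu_del, rel = L * rates$mu_rel,
    bit = n_seq * B * rates$mu_B, sp = n_gene * 2 * rates$mu_S,
    w = n_gene * rates$mu_w, theta = n_gene * rates$mu_theta,
    b_in = rates$mu_b_in, r_in = rates$mu_r_in)
}
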