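#' Regulatory products and product pools
#'
#' The products present in a cell during one timestep are held in a product
#' pool: a list of parallel vectors with one entry per product record.
#' `origin` tags the compartment the encoding gene lives in (`"host"` or
#' `"symbiont"`), `localization` distinguishes `"native"` products from
#' `"leaked"` and `"targeted"` foreign ones, and `copies` is the gene dosage
#' (doubled for gene beads already passed by the replication fork; foreign
#' deliveries carry one copy each). Binding affinity is linear in `copies`,
#' so multiple records of the same product are equivalent to one record with
#' summed copies.
#'
#' @param origin,type_id,seq,weight,copies,localization vectors (recycled)
#'   describing the product records; `seq` may be bit strings or masks.
#' @return a `product_pool` object.
#' @export
product_pool <- function(origin = character(), type_id = integer(),
                         seq = integer(), weight = integer(),
                         copies = numeric(), localization = "native") {
  if (is.character(seq) && length(seq)) seq <- vapply(seq, bits_to_mask, 1L)
  n <- max(length(origin), length(type_id), length(seq), length(weight),
           length(copies))
  if (length(type_id) == 0L) n <- 0L
  p <- list(origin = rep_len(as.character(origin), n),
            type_id = rep_len(as.integer(type_id), n),
            seq = rep_len(as.integer(seq), n),
            weight = rep_len(as.integer(weight), n),
            copies = rep_len(as.numeric(copies), n),
            localization = rep_len(as.character(localization), n))
  structure(p, class = "product_pool")
}

#' @rdname product_pool
#' @param ... pools to concatenate.
#' @export
pool_bind <- function(...) {
  ps <- Filter(function(p) length(p$type_id) > 0L, list(...))
  if (!length(ps)) return(product_pool())
  structure(
    list(origin = unlist(lapply(ps, `[[`, "origin"), use.names = FALSE),
         type_id = unlist(lapply(ps, `[[`, "type_id"), use.names = FALSE),
         seq = unlist(lapply(ps, `[[`, "seq"), use.names = FALSE),
         weight = unlist(lapply(ps, `[[`, "weight"), use.names = FALSE),
         copies = unlist(lapply(ps, `[[`, "copies"), use.names = FALSE),
         localization = unlist(lapply(ps, `[[`, "localization"), use.names = FALSE)),
    class = "product_pool")
}

pool_size <- function(pool) length(pool$type_id)

#' @export
print.product_pool <- function(x, ...) {
  cat(sprintf("<product_pool> %d record(s)\n", pool_size(x)))
  invisible(x)
}

#' Binding affinity between a product and a binding site
#'
#' The unnormalized binding mass is `a = c * s^d * copies` where `d` is the
#' Hamming distance between the product's sequence and the site's sequence:
#' strictly decreasing in `d`, linear in gene dosage. A site is occupied by
#' a given product with probability `a / (1 + sum of all masses)`, so even a
#' perfect-match product (`d = 0`) binds less than 100% of the time.
#'
#' @param product a one-record [product_pool()] (or any list with `seq` and
#'   `copies`).
#' @param site a binding site: a list with `seq` (mask or bit string), e.g.
#'   [site_bead()].
#' @param c,s affinity scale and per-mismatch decay (defaults 10 and 0.5).
#' @return nonnegative numeric affinity.
#' @export
binding_affinity <- function(product, site, c = 10, s = 0.5) {
  pseq <- as_mask(product$seq)
  sseq <- as_mask(site$seq)
  d <- hamming(pseq, sseq)
  copies <- if (is.null(product$copies)) 1 else product$copies
  c * s^d * copies
}

#' Sample the occupant of one binding site
#'
#' Draws one outcome from the categorical distribution with unnormalized
#' mass 1 for "none" and [binding_affinity()] for each product in the pool;
#' at most one product binds per site per timestep.
#'
#' @param site a binding site (list with `seq`).
#' @param pool a [product_pool()].
#' @param c,s affinity parameters.
#' @return the index (1-based) of the bound product in `pool`, or `0L` if
#'   the site stays unbound. Use `pool_slice(pool, i)` to extract the record.
#' @export
sample_site_occupancy <- function(site, pool, c = 10, s = 0.5) {
  if (pool_size(pool) == 0L) return(0L)
  .occupancy_draw(as_mask(site$seq), pool$seq, pool$copies, c, s)[1]
}

#' @rdname sample_site_occupancy
#' @param i record index.
#' @export
pool_slice <- function(pool, i) {
  structure(lapply(unclass(pool), `[`, i), class = "product_pool")
}

#' Boolean expression update
#'
#' A gene is expressed in the next timestep iff the summed regulatory
#' weights of the products bound to the sites of its upstream regulatory
#' region reach its activation threshold. Deterministic given the occupancy;
#' genes with an empty region compare 0 against their threshold.
#'
#' @param genome an `endo_genome`.
#' @param occupancy for each binding-site position of the genome (in
#'   increasing position order), the bound product as a one-record pool /
#'   list with a `weight` field, or `NULL` for an unbound site. Alternatively
#'   a numeric vector of bound weights with `NA` for unbound sites.
#' @return named logical vector over the genome's regulatory genes (names
#'   are bead positions).
#' @export
update_expression <- function(genome, occupancy) {
  cache <- build_regulatory_cache(genome)
  ns <- length(cache$site_pos)
  if (is.list(occupancy)) {
    if (length(occupancy) != ns)
      stop("occupancy must cover exactly the binding-site positions", call. = FALSE)
    w <- vapply(occupancy, function(o) {
      if (is.null(o)) NA_real_ else as.numeric(o$weight)
    }, numeric(1))
  } else {
    w <- as.numeric(occupancy)
    if (length(w) != ns)
      stop("occupancy must cover exactly the binding-site positions", call. = FALSE)
  }
  sums <- numeric(length(cache$gene_pos))
  ok <- !is.na(w) & cache$site_gene > 0L
  if (any(ok)) {
    agg <- rowsum(w[ok], cache$site_gene[ok])
    sums[as.integer(rownames(agg))] <- agg[, 1]
  }
  stats::setNames(sums >= cache$gene_thr, cache$gene_pos)
}

#' Stage table: the four core expression patterns
#'
#' The cell-cycle stage of a cell is defined by the joint expression pattern
#' of the five core gene types g1--g5. The four patterns (one per stage G1,
#' S, G2, M) must be pairwise distinct. Patterns are given as 5-character
#' bit strings, bit k corresponding to core type k.
#'
#' @param G1,S,G2,M 5-bit patterns.
#' @return a `stage_table` object (named integer codes).
#' @export
stage_table <- function(G1 = "11001", S = "01001", G2 = "01011", M = "01101") {
  pats <- c(G1 = G1, S = S, G2 = G2, M = M)
  stopifnot(all(nchar(pats) == 5L), all(grepl("^[01]{5}$", pats)))
  codes <- vapply(pats, bits_to_mask, 1L)
  if (anyDuplicated(codes)) stop("stage patterns must be pairwise distinct", call. = FALSE)
  structure(codes, class = "stage_table")
}

#' Core expression pattern of a cell
#'
#' Bit k (for the core types k = 1..5) is set iff a native gene of type k is
#' expressed, or a foreign product of type k in the pool is bit-identical in
#' sequence to at least one native type-k gene. Foreign products whose
#' sequence has diverged from every native copy of their type do not set the
#' bit, which is how diverged symbiont core genes resist takeover by host
#' products (and vice versa).
#'
#' @param expression logical vector over the genome's genes (gene-position
#'   order, as returned by [update_expression()]).
#' @param genome an `endo_genome`.
#' @param pool a [product_pool()]; only records with localization other than
#'   `"native"` are considered foreign.
#' @return integer 0/1 vector of length 5.
#' @export
core_pattern <- function(expression, genome, pool = product_pool()) {
  cache <- build_regulatory_cache(genome)
  core_pattern_cached(expression, cache, pool)
}

core_pattern_cached <- function(expression, cache, pool) {
  bits <- integer(5)
  on <- cache$gene_type[expression]
  on <- on[!is.na(on) & on <= 5L]
  bits[on] <- 1L
  if (pool_size(pool)) {
    foreign <- which(pool$localization != "native" & pool$type_id <= 5L)
    for (j in foreign) {
      k <- pool$type_id[j]
      if (bits[k]) next
      native <- cache$gene_seq[cache$gene_type == k]
      if (length(native) && any(native == pool$seq[j])) bits[k] <- 1L
    }
  }
  bits
}

#' Decode a cell-cycle stage from a core pattern
#'
#' @param bits integer 0/1 vector of length 5 (or a 5-bit string).
#' @param table a [stage_table()].
#' @return `"G1"`, `"S"`, `"G2"`, `"M"`, or `NA_character_` if the pattern
#'   matches no stage.
#' @export
decode_stage <- function(bits, table) {
  code <- if (is.character(bits)) bits_to_mask(bits) else bits_to_mask(as.integer(bits))
  i <- match(code, unclass(table))
  if (is.na(i)) NA_character_ else names(table)[i]
}
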