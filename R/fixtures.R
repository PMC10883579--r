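#' Generate the bootstrap host and symbiont genomes
#'
#' Builds the primitive ancestral genomes used to inoculate evolution runs:
#' 64 beads, 50 of them passive household genes, plus a 14-bead regulatory
#' repertoire (the five core genes g1--g5 and nine binding sites) wired so
#' that an isolated cell under rich nutrients (`n_influx = 90`) executes the
#' full G1-S-G2-M cycle and passes [viability_check()].
#'
#' The wiring implements a minimal stochastic cell-cycle oscillator:
#' \describe{
#'   \item{g5 ("clock")}{constitutively expressed, placed at the very end of
#'     the genome, so its product dosage doubles exactly when replication
#'     completes.}
#'   \item{g2 ("stage marker")}{constitutively expressed (empty region,
#'     threshold 0); present in all four stage patterns.}
#'   \item{g4 ("completion gate")}{requires all three of its low-affinity
#'     g5 sites bound at once -- rare at single g5 dosage, several-fold more
#'     likely after the terminal g5 bead has been replicated, so S-phase
#'     exit is coupled to replication completion.}
#'   \item{g3 ("mitosis relay")}{fires one step after the gate (perfect-match
#'     g4 sites), defining the M pattern; since nothing else can activate
#'     g3, the M pattern strictly requires a gate firing on the previous
#'     step.}
#'   \item{g1 ("restart reporter")}{fires one step after g3 (four
#'     perfect-match g3 sites), defining the G1 pattern of the daughters.}
#' }
#' The corresponding stage patterns are the package defaults:
#' G1 = 11001 is the post-division step (g1, g2, g5), S = 01001 the long
#' replicating phase (g2, g5), G2 = 01011 the gate step (g2, g4, g5) and
#' M = 01101 the relay step (g2, g3, g5).
#'
#' Host and symbiont genomes are identical except for their signal
#' peptides: every host gene carries `"10"` (host localization) and every
#' symbiont gene `"01"`, so initially all products stay in the compartment
#' encoding them. Both genomes carry a canonical birth expression state
#' (`g2`, `g3`, `g5` on -- the state of a freshly divided cell) in the
#' `init_expression` attribute.
#'
#' @param config run configuration (the wiring is laid out for the default
#'   `B = 20`).
#' @param gate_d Hamming distances (each 6 or 8) of the three
#'   completion-gate sites from the g5 sequence; larger distances make
#'   premature S-exit rarer but lengthen the post-replication wait.
#' @return list with `host` and `symbiont` `endo_genome`s.
#' @export
generate_bootstrap_genomes <- function(config = default_config(),
                                       gate_d = c(5, 6, 8)) {
  B <- config$B
  stopifnot(B == 20L)
  stopifnot(length(gate_d) == 3L, all(gate_d %in% 4:8))
  seqs <- core_seqs(B)
  gate_sites <- gate_site_masks(gate_d)
  build <- function(sp) {
    g <- function(type, weight, threshold)
      gene_bead(type, seqs[[type]], sp, weight, threshold)
    s <- function(type) site_bead(seqs[[type]])
    beads <- c(
      list(g(2, weight = 0, threshold = 0)),   # constitutive stage marker
      list(s(4), s(4)),                        # g3 region: the gate product
      list(g(3, weight = 3, threshold = 3)),
      list(s(3), s(3), s(3), s(3)),            # g1 region: mitosis relay
      list(g(1, weight = 0, threshold = 3)),
      lapply(gate_sites, site_bead),           # completion-gate region
      list(g(4, weight = 3, threshold = 5)),
      replicate(50, household_bead(), simplify = FALSE),
      list(g(5, weight = 2, threshold = 0))    # terminal clock gene
    )
    genome <- new_genome(beads, B = B)
    # birth state of a freshly divided cell: g2/g5 constitutive, g3 relay on
    # (gene order in the genome: g2, g3, g1, g4, g5)
    attr(genome, "init_expression") <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
    genome
  }
  list(host = build("10"), symbiont = build("01"))
}

# Core sequences (B = 20), chosen so that the products able to satisfy a
# threshold of 3 (g3, g4) lie at distance >= 12 from every site sequence
# they are not meant to bind, and so that the always-present weight-2 clock
# product g5 is 16 bits away from the mitosis-relay sites (two g5 products
# cross-bound there would sum to 4 >= 3 and fake the M relay, so this
# distance is the safety-critical one):
#   g5 = all zeros (clock), g4 = 1s at 1..16, g3 = 1s at 9..20,
#   g2 = 1s at {1-4, 13-16}, g1 = 1s at {5-8, 17-20}.
core_seqs <- function(B) {
  stopifnot(B == 20L)
  list(
    bits_to_mask(flip_positions(c(5:8, 17:20))),   # g1
    bits_to_mask(flip_positions(c(1:4, 13:16))),   # g2
    bits_to_mask(flip_positions(9:20)),            # g3
    bits_to_mask(flip_positions(1:16)),            # g4
    0L                                             # g5
  )
}

# 0/1 vector of length 20 with 1s at the given positions
flip_positions <- function(pos) {
  v <- integer(20L)
  v[pos] <- 1L
  v
}

# Completion-gate site sequences: g5 (all zeros) with d bits flipped,
# balanced between positions 5..8 and 17..20 so the flips stay at distance
# >= 11 from g3 and >= 16 from g4 (whose products carry weight 3 and must
# not be able to help fire the gate).
gate_site_masks <- function(gate_d) {
  flip_sets <- list(
    `4` = list(c(5, 6, 17, 18), c(7, 8, 19, 20)),
    `5` = list(c(5, 6, 17, 18, 19), c(7, 8, 18, 19, 20)),
    `6` = list(c(5, 6, 7, 17, 18, 19), c(5, 6, 8, 17, 18, 20),
               c(5, 7, 8, 17, 19, 20)),
    `7` = list(c(5, 6, 7, 17, 18, 19, 20), c(5, 6, 8, 17, 18, 19, 20)),
    `8` = list(c(5, 6, 7, 8, 17, 18, 19, 20))
  )
  used <- integer(length(flip_sets))
  names(used) <- names(flip_sets)
  lapply(gate_d, function(d) {
    key <- as.character(d)
    opts <- flip_sets[[key]]
    pick <- opts[[min(used[key] + 1L, length(opts))]]
    used[key] <<- used[key] + 1L
    bits_to_mask(flip_positions(pick))
  })
}

#' Synthetic test fixtures
#'
#' A small suite of hand-wired genomes exercising the simulator's edge
#' cases, used throughout the test suite:
#' \describe{
#'   \item{bootstrap}{the host/symbiont pair of
#'     [generate_bootstrap_genomes()].}
#'   \item{nonviable}{64 household beads, no regulation: never reaches M
#'     and never dies.}
#'   \item{constitutive_m}{expresses the M pattern from the first step and
#'     dies by the premature-mitosis rule.}
#'   \item{host_control}{a holobiont in which the symbiont's clock gene g5
#'     is natively silent and the host's g5 carries a dual-localization
#'     signal peptide (`"11"`); the symbiont cycle therefore requires
#'     host-to-symbiont targeting.}
#'   \item{symbiont_control}{the mirror image: the host's g5 is natively
#'     silent and the symbiont carries a second g5 copy targeted to the
#'     host (`"10"`), so host cycle progression (through to M) is gated by
#'     its symbionts.}
#' }
#'
#' @param config run configuration.
#' @return a nested list of `endo_genome`s.
#' @export
make_test_fixtures <- function(config = default_config()) {
  boot <- generate_bootstrap_genomes(config)
  B <- config$B
  seqs <- core_seqs(B)

  nonviable <- new_genome(replicate(64, household_bead(), simplify = FALSE), B = B)

  # constitutively expressed g2, g3, g5 = the M pattern every step
  const_m <- new_genome(c(
    list(gene_bead(2, seqs[[2]], "10", 3, -2),
         gene_bead(3, seqs[[3]], "10", 3, -2),
         gene_bead(5, seqs[[5]], "10", 2, -2),
         gene_bead(1, seqs[[1]], "10", 0, 5),
         gene_bead(4, seqs[[4]], "10", 3, 5)),
    replicate(59, household_bead(), simplify = FALSE)), B = B)

  # host control: symbiont g5 natively silent, host g5 targeted "11".
  # Deliveries arrive at single-copy dosage, so the dependent symbiont's
  # completion gate uses closer sites than the bootstrap's to keep its
  # (host-driven) cycle at a workable pace.
  hc_host <- edit_gene(boot$host, 5, sp = "11")
  hc_sym <- edit_gene(generate_bootstrap_genomes(config,
                                                 gate_d = c(5, 5, 6))$symbiont,
                      5, threshold = 5L)

  # symbiont control: host g5 natively silent; symbiont gains an extra g5
  # copy exported to the host
  sc_host <- edit_gene(boot$host, 5, threshold = 5L)
  sc_sym <- append_gene(boot$symbiont, gene_bead(5, seqs[[5]], "10", 2L, 0L),
                        init_expression = TRUE)

  list(bootstrap = boot,
       nonviable = nonviable,
       constitutive_m = const_m,
       host_control = list(host = hc_host, symbiont = hc_sym),
       symbiont_control = list(host = sc_host, symbiont = sc_sym))
}

# modify the first gene of the given core type
edit_gene <- function(genome, type, sp = NULL, threshold = NULL, weight = NULL) {
  i <- which(genome$kind == "G" & genome$type_id == type)[1]
  stopifnot(!is.na(i))
  if (!is.null(sp)) genome$sp[i] <- as_sp(sp)
  if (!is.null(threshold)) genome$threshold[i] <- as.integer(threshold)
  if (!is.null(weight)) genome$weight[i] <- as.integer(weight)
  genome
}

append_gene <- function(genome, bead, init_expression = FALSE) {
  fields <- insert_bead(unclass(genome), length(genome$kind), bead)
  out <- structure(fields, B = attr(genome, "B"), class = "endo_genome")
  init <- attr(genome, "init_expression")
  if (!is.null(init)) attr(out, "init_expression") <- c(init, init_expression)
  out
}
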