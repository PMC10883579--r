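# Shared fixtures and generators for the test suite. Everything is built
# in code; no data files.

test_config <- function(...) default_config(...)

# a random genome with roughly the requested bead mix
random_genome <- function(n_household = 5, n_sites = 4, n_genes = 3,
                          B = 20L, config = test_config()) {
  wr <- config$ranges$weight
  tr <- config$ranges$threshold
  beads <- c(
    replicate(n_household, household_bead(), simplify = FALSE),
    replicate(n_sites, site_bead(random_mask_(B)), simplify = FALSE),
    lapply(seq_len(n_genes), function(i) {
      gene_bead(sample(1:8, 1), random_mask_(B),
                sp = sample(0:3, 1),
                weight = sample(seq(wr[1], wr[2]), 1),
                threshold = sample(seq(tr[1], tr[2]), 1))
    })
  )
  beads <- beads[sample(length(beads))]
  new_genome(beads, B = B)
}

random_mask_ <- function(B) bits_to_mask(as.integer(stats::runif(B) < 0.5))

# the six parallel bead vectors, without incidental attributes
bead_fields <- function(g) {
  g <- unclass(g)
  attributes(g) <- list(names = names(g))
  g[c("kind", "type_id", "seq", "sp", "weight", "threshold")]
}

expect_same_beads <- function(a, b) {
  expect_identical(bead_fields(a), bead_fields(b))
}

# one-record product pool shorthand
one_product <- function(seq, weight = 1L, copies = 1, type_id = 1L,
                        origin = "host", localization = "native") {
  product_pool(origin = origin, type_id = type_id, seq = seq,
               weight = weight, copies = copies, localization = localization)
}

# a small uniform-influx arena configuration for population tests
arena_config <- function(width = 10L, height = 10L, influx = 90,
                         delta = 0, mutation = zero_rates(),
                         interference = list(l = 0, leakage_mode = "off",
                                             targeting = list(host_to_symbiont = FALSE,
                                                              symbiont_to_host = FALSE),
                                             mu_t = 0, transfer_mode = "off"),
                         ...) {
  default_config(grid = list(width = width, height = height, sectors = 1L,
                             influx_min = influx, influx_max = influx),
                 dynamics = list(delta = delta),
                 mutation = mutation,
                 interference = interference,
                 ...)
}

# a tiny sim with the bootstrap clone placed on every requested site
seeded_sim <- function(config, sites, n_sym = 2L, record_genomes = FALSE) {
  boot <- generate_bootstrap_genomes(config)
  sim <- new_simulation(config, record_genomes = record_genomes)
  inoculate(sim, boot$host, boot$symbiont, sites = sites, n_sym = n_sym)
  sim
}
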