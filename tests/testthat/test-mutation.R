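test_that("zero rates leave the genome untouched", {
  set.seed(21)
  g <- random_genome()
  out <- mutate_genome(g, zero_rates(), test_config())
  expect_same_beads(out, g)
  expect_identical(attr(out, "origin"), seq_along(g$kind))
  expect_true(all(attr(out, "events") == 0L))
})

test_that("default configuration carries the standard mutation rates", {
  cfg <- validate_config(list(grid = list(width = 45, height = 110,
                                          sectors = 11, influx_min = 10,
                                          influx_max = 110),
                              dynamics = list(rho = 5, delta = 0.002),
                              B = 20))
  expect_equal(cfg$mutation$mu_dup, 1.67e-4)
  expect_equal(cfg$mutation$mu_B, 3.3e-5)
  expect_equal(cfg$mutation$mu_S, 1.0e-5)
  expect_equal(cfg$mutation$mu_b_in, 1.67e-3)
  expect_equal(cfg$interference$l, 0.01)
  expect_equal(cfg$interference$mu_t, 2.0e-5)
})

test_that("expected event counts follow the closed forms", {
  boot <- generate_bootstrap_genomes(test_config())$host
  ex <- expected_event_counts(boot, mutation_rates())
  expect_equal(ex[["dup"]], 64 * 1.67e-4)        # 0.010688 per division
  expect_equal(ex[["b_in"]], 1.67e-3)

  empty <- parse_genome(character(0))
  ex0 <- expected_event_counts(empty, mutation_rates())
  expect_true(all(ex0[c("dup", "del", "rel", "bit", "sp", "w", "theta")] == 0))

  # 6 genes + 8 sites at B = 20: (6*20 + 8*20) bits at risk
  set.seed(22)
  g <- random_genome(n_household = 0, n_sites = 8, n_genes = 6)
  exg <- expected_event_counts(g, mutation_rates())
  expect_equal(exg[["bit"]], 280 * 3.3e-5)
})

test_that("empirical operator frequencies match expectation and scale linearly", {
  boot <- generate_bootstrap_genomes(test_config())$host
  run <- function(factor, n) {
    rates <- scale_rates(mutation_rates(), factor)
    ev <- matrix(0, nrow = n, ncol = 9)
    for (i in seq_len(n)) {
      ev[i, ] <- attr(mutate_genome(boot, rates, test_config()), "events")
    }
    colnames(ev) <- names(attr(mutate_genome(boot, zero_rates(),
                                             test_config()), "events"))
    colSums(ev)
  }
  set.seed(23)
  n <- 8000
  obs <- run(100, n)
  ex <- expected_event_counts(boot, scale_rates(mutation_rates(), 100)) * n
  for (op in c("dup", "del", "rel", "bit", "sp", "w", "theta", "b_in", "r_in")) {
    expect_lt(abs(obs[[op]] - ex[[op]]), 4 * sqrt(ex[[op]]) + 1,
              label = sprintf("operator %s: observed %d expected %.1f",
                              op, obs[[op]], ex[[op]]))
  }
  # linearity: 100x rates give ~10x the events of 10x rates
  obs10 <- run(10, n)
  ratio <- sum(obs[c("dup", "del", "rel")]) / sum(obs10[c("dup", "del", "rel")])
  expect_lt(abs(ratio - 10), 1.5)
})

test_that("duplication copies sit beside the original and lengths change by one", {
  g <- new_genome(list(household_bead(), site_bead(5L),
                       gene_bead(1, 9L)), B = 20)
  set.seed(24)
  dup_all <- mutate_genome(g, mutation_rates(mu_B = 0, mu_S = 0, mu_w = 0,
                                             mu_theta = 0, mu_dup = 1,
                                             mu_del = 0, mu_rel = 0,
                                             mu_b_in = 0, mu_r_in = 0),
                           test_config())
  expect_equal(length(dup_all$kind), 6L)
  expect_identical(attr(dup_all, "origin"), c(1L, 1L, 2L, 2L, 3L, 3L))

  del_all <- mutate_genome(g, mutation_rates(0, 0, 0, 0, 0, 1, 0, 0, 0),
                           test_config())
  expect_equal(length(del_all$kind), 0L)

  rel_all <- mutate_genome(g, mutation_rates(0, 0, 0, 0, 0, 0, 1, 0, 0),
                           test_config())
  expect_setequal(attr(rel_all, "origin"), 1:3)   # a permutation, no loss
})

test_that("weights and thresholds stay inside their ranges under heavy mutation", {
  cfg <- test_config()
  set.seed(25)
  g <- random_genome(n_genes = 5)
  rates <- mutation_rates(mu_B = 0, mu_S = 0, mu_w = 1, mu_theta = 1,
                          mu_dup = 0, mu_del = 0, mu_rel = 0,
                          mu_b_in = 0, mu_r_in = 0)
  for (i in 1:200) {
    g <- mutate_genome(g, rates, cfg)
    gw <- g$weight[g$kind == "G"]
    gt <- g$threshold[g$kind == "G"]
    expect_true(all(gw >= -3 & gw <= 3))
    expect_true(all(gt >= -2 & gt <= 5))
  }
})

test_that("L, R and household counts stay consistent under random mutation", {
  cfg <- test_config()
  set.seed(26)
  g <- generate_bootstrap_genomes(cfg)$host
  rates <- scale_rates(mutation_rates(), 500)
  bad <- 0L
  for (i in 1:2000) {
    g <- mutate_genome(g, rates, cfg)
    s <- genome_stats(g)
    if (s$L != length(g$kind) || s$L != s$R + s$household_count ||
        sum(s$type_counts) != sum(g$kind == "G")) bad <- bad + 1L
  }
  expect_equal(bad, 0L)
})

test_that("innovated genes get fresh non-core labels and uniform sequences", {
  cfg <- test_config()
  set.seed(27)
  boot <- generate_bootstrap_genomes(cfg)$host
  ids <- vapply(1:2000, function(i) innovate_gene(boot, cfg)$type_id, 1L)
  expect_true(all(ids > 5L))
  g1 <- innovate_gene(boot, cfg)
  g_with <- structure(lapply(unclass(boot), function(v) v),
                      B = 20L, class = "endo_genome")
  g_with$type_id[which(g_with$kind == "G")[1]] <- 12L
  expect_gt(innovate_gene(g_with, cfg)$type_id, 12L)

  ones <- vapply(1:5000, function(i)
    sum(mask_to_bits(innovate_gene(boot, cfg)$seq, 20)), 1L)
  p_hat <- sum(ones) / (5000 * 20)        # each bit is Bernoulli(1/2)
  expect_lt(abs(p_hat - 0.5), 4 * sqrt(0.25 / (5000 * 20)))
  expect_true(all(vapply(1:200, function(i)
    innovate_gene(boot, cfg)$sp, 1L) == 0L))   # no signal peptide at birth
})

test_that("signal peptides mutate bitwise through all four states", {
  cfg <- test_config()
  g <- new_genome(list(gene_bead(1, 0L, sp = "10")), B = 20)
  rates <- mutation_rates(0, 0.5, 0, 0, 0, 0, 0, 0, 0)
  set.seed(28)
  sps <- vapply(1:400, function(i)
    mutate_genome(g, rates, cfg)$sp[1], 1L)
  expect_setequal(sort(unique(sps)), 0:3)   # 00, 01, 10 and 11 all reachable
})
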