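test_that("binding affinity follows c * s^d * copies", {
  site <- site_bead(bits_to_mask(rep(0L, 20)))
  p0 <- one_product(seq = bits_to_mask(rep(0L, 20)))
  expect_equal(binding_affinity(p0, site), 10)

  p3 <- one_product(seq = bits_to_mask(c(1L, 1L, 1L, rep(0L, 17))))
  expect_equal(binding_affinity(p3, site), 10 * 0.5^3)      # 1.25
  p3$copies <- 2
  expect_equal(binding_affinity(p3, site), 2.5)             # dosage linear

  # strictly decreasing in Hamming distance over the full range
  affs <- vapply(0:20, function(d) {
    p <- one_product(seq = bits_to_mask(c(rep(1L, d), rep(0L, 20 - d))))
    binding_affinity(p, site)
  }, numeric(1))
  expect_true(all(diff(affs) < 0))

  expect_error(
    binding_affinity(one_product(seq = bits_to_mask("0101")), site),
    NA)  # masks carry no length; equal-B is the caller's contract
})

test_that("occupancy sampling matches the exact categorical distribution", {
  set.seed(11)
  site <- site_bead(0L)
  # pools of 1..4 products with a spread of affinities
  pools <- list(
    one_product(seq = 0L),                                     # a = 10
    pool_bind(one_product(seq = 0L),
              one_product(seq = bits_to_mask(c(1L, rep(0L, 19))))),
    pool_bind(one_product(seq = 0L, copies = 2),
              one_product(seq = bits_to_mask(c(1L, 1L, rep(0L, 18)))),
              one_product(seq = bits_to_mask(c(rep(1L, 5), rep(0L, 15))))),
    pool_bind(one_product(seq = 0L),
              one_product(seq = 0L),
              one_product(seq = bits_to_mask(c(rep(1L, 3), rep(0L, 17)))),
              one_product(seq = bits_to_mask(c(rep(1L, 8), rep(0L, 12)))))
  )
  n <- 20000
  for (pool in pools) {
    k <- length(pool$type_id)
    aff <- vapply(seq_len(k), function(i)
      binding_affinity(pool_slice(pool, i), site), numeric(1))
    probs <- c(1, aff) / (1 + sum(aff))     # exact enumeration: none + each
    draws <- vapply(seq_len(n), function(i)
      sample_site_occupancy(site, pool), integer(1))
    obs <- tabulate(draws + 1L, nbins = k + 1L)
    cs <- suppressWarnings(stats::chisq.test(obs, p = probs))
    expect_gt(cs$p.value, 0.001)
  }
})

test_that("empty pools never bind and perfect matches bind below 100%", {
  expect_identical(sample_site_occupancy(site_bead(0L), product_pool()), 0L)
  set.seed(12)
  pool <- one_product(seq = 0L)   # a = 10 -> P(bound) = 10/11
  n <- 20000
  hits <- sum(vapply(seq_len(n), function(i)
    sample_site_occupancy(site_bead(0L), pool), integer(1)) > 0L)
  p_hat <- hits / n
  se <- sqrt((10 / 11) * (1 / 11) / n)
  expect_lt(abs(p_hat - 10 / 11), 3 * se)
  expect_lt(p_hat, 1)
})

test_that("expression update thresholds the summed bound weights", {
  # [site, site, gene(theta = 1)] with controllable occupancy
  g <- new_genome(list(site_bead(1L), site_bead(2L),
                       gene_bead(1, 3L, threshold = 1L)), B = 20)
  w <- function(x) list(weight = x)
  expect_true(update_expression(g, list(w(2), w(-1)))[["3"]])    # 1 >= 1
  expect_false(update_expression(g, list(w(-1), NULL)))          # -1 < 1
  g2 <- new_genome(list(site_bead(1L), site_bead(2L),
                        gene_bead(1, 3L, threshold = 2L)), B = 20)
  expect_false(update_expression(g2, list(w(2), w(-1))))         # 1 < 2

  # empty regulatory region compares 0 against the threshold
  lone1 <- new_genome(list(gene_bead(1, 1L, threshold = 1L)), B = 20)
  lone0 <- new_genome(list(gene_bead(1, 1L, threshold = 0L)), B = 20)
  expect_false(update_expression(lone1, list()))
  expect_true(update_expression(lone0, list()))

  expect_error(update_expression(g, list(w(1))), "exactly the binding-site")
})

test_that("expression update is deterministic and monotone in activation", {
  set.seed(13)
  g <- random_genome(n_household = 2, n_sites = 5, n_genes = 3)
  ns <- sum(g$kind == "B")
  occ <- lapply(seq_len(ns), function(i)
    if (stats::runif(1) < 0.5) NULL else list(weight = sample(-3:3, 1)))
  expect_identical(update_expression(g, occ), update_expression(g, occ))

  # adding a positive-weight binding never switches a gene off
  base <- update_expression(g, occ)
  for (i in seq_len(ns)) {
    if (!is.null(occ[[i]])) next
    occ2 <- occ
    occ2[[i]] <- list(weight = 3)
    expect_true(all(update_expression(g, occ2) >= base))
  }
})

test_that("core pattern tracks native expression and identical foreign products", {
  boot <- generate_bootstrap_genomes(test_config())$host
  ng <- sum(boot$kind == "G")
  none <- core_pattern(rep(FALSE, ng), boot)
  expect_identical(none, integer(5))

  # foreign product bit-identical to the native g2 sets bit 2
  g2_seq <- boot$seq[boot$kind == "G" & boot$type_id == 2L]
  foreign <- one_product(seq = g2_seq, type_id = 2L, origin = "symbiont",
                         localization = "leaked")
  expect_identical(core_pattern(rep(FALSE, ng), boot, foreign),
                   c(0L, 1L, 0L, 0L, 0L))

  # one mismatching bit and the foreign product no longer defines the stage
  diverged <- one_product(seq = bitwXor(g2_seq, 1L), type_id = 2L,
                          origin = "symbiont", localization = "leaked")
  expect_identical(core_pattern(rep(FALSE, ng), boot, diverged), integer(5))

  # native products in the pool do not count as foreign
  native <- one_product(seq = g2_seq, type_id = 2L, localization = "native")
  expect_identical(core_pattern(rep(FALSE, ng), boot, native), integer(5))
})

test_that("stage decoding is an exact pattern lookup", {
  tab <- stage_table()
  expect_identical(decode_stage(mask_to_bits(tab[["G1"]], 5), tab), "G1")
  expect_identical(decode_stage(mask_to_bits(tab[["M"]], 5), tab), "M")
  expect_true(is.na(decode_stage(c(1L, 1L, 1L, 1L, 1L), tab)))
  expect_error(stage_table(G1 = "11001", S = "11001"), "distinct")
  expect_error(stage_table(G1 = "111"))
})
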