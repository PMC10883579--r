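test_that("nutrient share divides influx over the 3x3 neighbourhood cells", {
  cfg <- arena_config(width = 10, height = 10, influx = 90)
  set.seed(41)
  sim <- seeded_sim(cfg, sites = cbind(5, 5), n_sym = 2)
  ns <- nutrient_share(sim, c(5, 5))
  expect_equal(ns$A, 30)                  # 90 / (1 host + 2 symbionts)
  expect_equal(ns$k, 6L)                  # floor(30 / rho), rho = 5

  # a second holobiont (3 cells) in the neighbourhood halves the share
  boot <- generate_bootstrap_genomes(cfg)
  inoculate(sim, boot$host, boot$symbiont, sites = cbind(5, 6), n_sym = 2)
  ns2 <- nutrient_share(sim, c(5, 5))
  expect_equal(ns2$A, 15)
  expect_equal(ns2$k, 3L)

  # neighbourhood wraps horizontally but not vertically
  sim2 <- seeded_sim(cfg, sites = cbind(1, 1), n_sym = 2)
  inoculate(sim2, boot$host, boot$symbiont, sites = cbind(1, 10), n_sym = 2)
  expect_equal(nutrient_share(sim2, c(1, 1))$A, 15)

  expect_error(nutrient_share(sim, c(9, 9)), "not occupied")
})

test_that("starvation halts replication entirely", {
  cfg <- arena_config(width = 5, height = 5, influx = 2)
  set.seed(42)
  sim <- seeded_sim(cfg, sites = cbind(3, 3), n_sym = 2)
  expect_equal(nutrient_share(sim, c(3, 3))$k, 0L)   # A = 2/3 < rho
  # a starved cell in S-phase makes no replication progress
  boot <- generate_bootstrap_genomes(test_config())$host
  cell <- new_cell(boot, "host", test_config())
  cell$stage <- "S"
  cell$passed <- c("G1", "S")
  cell$fork <- 30L
  cell <- step_cell(cell, 0L)$cell
  expect_equal(cell$fork, 30L)
})

test_that("holobiont division partitions symbionts binomially", {
  cfg <- test_config()
  boot <- generate_bootstrap_genomes(cfg)
  ready_holobiont <- function(n_sym) {
    host <- new_cell(boot$host, "host", cfg)
    host$ready <- TRUE
    host$fork <- 64L
    host$passed <- c("G1", "S", "G2")
    syms <- replicate(n_sym, new_cell(boot$symbiont, "symbiont", cfg),
                      simplify = FALSE)
    list(host = host, syms = syms, birth_sym_count = n_sym)
  }

  set.seed(43)
  # a single symbiont: exactly one daughter survives
  for (i in 1:50) {
    d <- divide_holobiont(ready_holobiont(1), cfg, zero_rates())
    expect_equal(sum(vapply(d, is.null, TRUE)), 1L)
  }

  # four symbionts: Binomial(4, 1/2) split, totals conserved
  n <- 20000
  h4 <- ready_holobiont(4)
  first_counts <- integer(n)
  both <- 0L
  for (i in seq_len(n)) {
    d <- divide_holobiont(h4, cfg, zero_rates())
    c1 <- if (is.null(d[[1]])) 0L else length(d[[1]]$syms)
    c2 <- if (is.null(d[[2]])) 0L else length(d[[2]]$syms)
    expect_equal(c1 + c2, 4L)
    first_counts[i] <- c1
    if (c1 > 0L && c2 > 0L) both <- both + 1L
  }
  obs <- tabulate(first_counts + 1L, nbins = 5L)
  cs <- suppressWarnings(stats::chisq.test(obs, p = stats::dbinom(0:4, 4, 0.5)))
  expect_gt(cs$p.value, 0.001)
  p_both <- both / n
  expect_lt(abs(p_both - 7 / 8), 4 * sqrt((7 / 8) * (1 / 8) / n))
})

test_that("an empty grid steps to an empty grid", {
  sim <- new_simulation(arena_config(width = 6, height = 6))
  step_population(sim)
  expect_equal(length(event_log(sim)$event), 0L)
  expect_true(all(sim$occ == 0L))
})

test_that("divided-ready hosts stall until a neighbouring site frees up", {
  cfg <- arena_config(width = 4, height = 4, influx = 200)
  fx <- make_test_fixtures(test_config())
  set.seed(44)
  sim <- new_simulation(cfg)
  # fill the grid with inert holobionts (no genes: they never divide or die)
  inoculate(sim, fx$nonviable, fx$nonviable,
            sites = as.matrix(expand.grid(1:4, 1:4)), n_sym = 2)
  # force one host into the divided-ready state
  id <- sim$occ[2, 2]
  h <- endocycle:::get_holo(sim, id)
  h$host$ready <- TRUE
  h$host$fork <- 64L
  h$host$passed <- c("G1", "S", "G2")
  h$pending <- TRUE
  endocycle:::set_holo(sim, id, h)
  for (t in 1:10) step_population(sim)
  expect_equal(sum(event_log(sim)$event == "birth"), 0L)
  expect_true(endocycle:::get_holo(sim, sim$occ[2, 2])$pending)   # still waiting

  # free one neighbour: the stalled division goes through next step
  victim <- sim$occ[2, 3]
  sim$occ[2, 3] <- 0L
  sim$ncells[2, 3] <- 0L
  endocycle:::del_holo(sim, victim)
  for (t in 1:2) step_population(sim)
  lg <- event_log(sim)
  # the division happened (symbiont partitioning can lose one daughter)
  births <- sum(lg$event == "birth")
  expect_gte(births, 1L)
  expect_lte(births, 2L)
})

test_that("a nonviable genotype goes extinct by the premature-mitosis rule", {
  cfg <- arena_config(width = 6, height = 6, influx = 90, delta = 0)
  fx <- make_test_fixtures(test_config())
  set.seed(45)
  sim <- new_simulation(cfg)
  inoculate(sim, fx$constitutive_m, fx$constitutive_m,
            sites = as.matrix(expand.grid(2:5, 2:5)), n_sym = 2)
  for (t in 1:40) {
    step_population(sim)
    if (length(endocycle:::alive_ids(sim)) == 0L) break
  }
  expect_equal(length(endocycle:::alive_ids(sim)), 0L)
})

test_that("a viable clone expands and self-limits its symbiont load", {
  cfg <- arena_config(width = 15, height = 15, influx = 90, delta = 0)
  set.seed(46)
  sim <- new_simulation(cfg)
  boot <- generate_bootstrap_genomes(test_config())
  inoculate(sim, boot$host, boot$symbiont, fraction = 0.05, n_sym = 2)
  n0 <- length(endocycle:::alive_ids(sim))
  N <- integer(0)
  for (t in 1:600) {
    step_population(sim)
    N[t] <- length(endocycle:::alive_ids(sim))
  }
  expect_gt(N[600], 2 * n0)                # clear growth from the inoculum
  expect_gt(min(N), 0)                     # never collapses
  # the nutrient feedback keeps symbiont loads bounded: starved symbionts
  # eventually die, so the mean stays moderate instead of growing freely
  expect_lt(population_summary(sim)$mean_symbionts, 8)
  expect_gt(sum(event_log(sim)$event == "sym_death"), 0)
})

test_that("every alive holobiont keeps at least one symbiont and one site", {
  cfg <- arena_config(width = 8, height = 8, influx = 90, delta = 0.01)
  set.seed(47)
  sim <- seeded_sim(cfg, sites = as.matrix(expand.grid(3:6, 3:6)), n_sym = 2)
  bad <- 0L
  for (t in 1:150) {
    step_population(sim)
    ids <- endocycle:::alive_ids(sim)
    for (id in ids) {
      h <- endocycle:::get_holo(sim, id)
      if (length(h$syms) < 1L || !h$host$alive ||
          sim$occ[h$row, h$col] != id ||
          sim$ncells[h$row, h$col] != 1L + length(h$syms)) bad <- bad + 1L
    }
    if (sum(sim$occ > 0L) != length(ids)) bad <- bad + 1L
  }
  expect_equal(bad, 0L)
})

test_that("identical seeds give identical event logs", {
  cfg <- default_config(grid = list(width = 12, height = 22, sectors = 11))
  run <- function() {
    set.seed(48)
    sim <- seeded_sim(cfg, sites = as.matrix(expand.grid(seq(2, 20, 3),
                                                         seq(2, 10, 3))),
                      n_sym = 2)
    for (t in 1:120) step_population(sim)
    event_log(sim)
  }
  expect_identical(run(), run())
})

test_that("population summaries report occupancy and composition", {
  cfg <- arena_config(width = 5, height = 2, influx = 90)
  sim <- new_simulation(cfg)
  s0 <- population_summary(sim)
  expect_equal(s0$N, 0)
  expect_true(is.na(s0$S_H))

  set.seed(49)
  boot <- generate_bootstrap_genomes(cfg)
  inoculate(sim, boot$host, boot$symbiont, sites = cbind(1, 1), n_sym = 2)
  s1 <- population_summary(sim)
  expect_equal(s1$N, 0.1)                  # 1 of 10 sites
  expect_equal(s1$S_H, 2)                  # all born with two symbionts
  expect_equal(s1$host_L, 64)
  expect_equal(s1$sym_L, 64)
  expect_equal(nrow(s1$sectors[[1]]), 1L)
})
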