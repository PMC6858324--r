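test_that("energy is the clamped inverse deviation from the optimum", {
  expect_equal(compute_energy(c(3, 5, 2), c(3, 5, 2)), 1)
  expect_equal(compute_energy(7, 1), 0)
  expect_equal(compute_energy(c(4, 2), c(1, 2)), 0.75)
  expect_equal(compute_energy(rbind(c(1, 2), c(30, 2)), c(1, 2)), c(1, 0))
  expect_error(compute_energy(c(1, 2), c(1, 2, 3)), "length")
})

test_that("roulette weights give the best couple exactly a 1+s advantage", {
  expect_equal(roulette_weights(c(2, 4), 0.20), c(1, 1.2) / 2.2)
  expect_equal(roulette_weights(rep(1.3, 5), 0.20), rep(0.2, 5))
  expect_equal(roulette_weights(c(0.2, 0.9, 1.4), 0), rep(1 / 3, 3))
  set.seed(2)
  for (s in c(0.10, 0.15, 0.20)) {
    w <- roulette_weights(runif(50, 0.2, 1.8), s)
    expect_equal(max(w) / min(w), 1 + s)
    expect_equal(sum(w), 1)
  }
  expect_error(roulette_weights(numeric(0), 0.1), "couples")
})

test_that("reproduction inherits, mutates, and weights couples correctly", {
  # two couples whose pooled energies differ; affine map gives a 1.2 ratio
  p <- 4
  traits <- rbind(rep(4, p), rep(4.75, p), rep(4, p), rep(4.75, p))
  pop <- make_toy_pop(traits, traits, c("female", "female", "male", "male"),
                      optimum = rep(4, p),
                      mate_pairs = list(c(1, 3), c(2, 4)))
  expect_equal(pop$energy, c(1, 0.875, 1, 0.875))
  matching <- structure(data.frame(female = 1:2, male = 1:2,
                                   score = c(1, 1)),
                        class = c("mm_matching", "data.frame"))
  cfg <- sim_config("euclidean", n_agents = 4000L, n_traits = p,
                    mutation_sd = 1e-9, selection_strength = 0.2, seed = 1)
  set.seed(10)
  kids <- reproduce(matching, pop, cfg)
  expect_equal(length(kids$id), 4000L)
  expect_equal(sum(kids$sex == "female"), 2000L)
  # every child trait equals a parental value (mutation negligible)
  expect_true(all(abs(kids$traits - 4) < 1e-6 | abs(kids$traits - 4.75) < 1e-6))
  # offspring counts approach the 1.2 roulette ratio
  from_best <- mean(abs(kids$traits[, 1] - 4) < 1e-6)
  expect_equal(from_best / (1 - from_best), 1.2, tolerance = 0.08)
  expect_error(reproduce(matching[0, ], pop, cfg), "empty")
})

test_that("simulations are deterministic and respect the life-cycle contract", {
  cfg <- sim_config("euclidean", n_agents = 20, n_traits = 5,
                    generations = 10, seed = 42)
  a <- run_simulation(cfg); b <- run_simulation(cfg)
  expect_identical(a$final_population, b$final_population)
  expect_identical(a$summary, b$summary)
  expect_equal(nrow(a$summary), 10L)
  expect_equal(sum(a$final_population$sex == "female"), 10L)
  expect_true(all(!is.na(a$final_population$mate_id)))

  g1 <- run_simulation(sim_config("euclidean", n_agents = 12, n_traits = 3,
                                  generations = 1, seed = 5))
  expect_equal(nrow(g1$summary), 1L)
  expect_equal(g1$final_population$generation, 0L)  # initial cohort, paired
})

test_that("the cached implied ideal stays exact through inheritance", {
  for (rule in c("polynomial", "aspiration")) {
    cfg <- sim_config(rule, n_agents = 16, n_traits = 4, generations = 8,
                      seed = 9)
    fin <- run_simulation(cfg)$final_population
    expect_equal(fin$ideal, implied_ideal_all(fin$prefs, rule))
  }
})

test_that("choice-driven markets fulfill preferences better than random pairing", {
  # paired seeds at the canonical scale; the choice-driven market should beat
  # random pairing on fulfillment in both selection regimes
  diffs <- vapply(1:2, function(s) {
    eu <- run_simulation(sim_config("euclidean", seed = s))
    ra <- run_simulation(sim_config("random", seed = s))
    tail(eu$summary$mean_fulfillment, 1) - tail(ra$summary$mean_fulfillment, 1)
  }, numeric(1))
  expect_gt(mean(diffs), 0)

  eu_p <- run_simulation(sim_config("euclidean", selection = "proportional",
                                    mutate_prefs = TRUE, seed = 7))
  ra_p <- run_simulation(sim_config("random", selection = "proportional",
                                    mutate_prefs = TRUE, seed = 7))
  expect_gt(tail(eu_p$summary$mean_fulfillment, 1),
            tail(ra_p$summary$mean_fulfillment, 1))
})

test_that("selection raises mean energy while the neutral null drifts", {
  res <- vapply(1:3, function(s) {
    r <- run_simulation(sim_config("euclidean", n_agents = 100, n_traits = 10,
                                   generations = 40, selection = "proportional",
                                   mutate_prefs = TRUE, seed = 500 + s))
    mean(tail(r$summary$mean_energy, 5)) - mean(head(r$summary$mean_energy, 5))
  }, numeric(1))
  expect_gt(mean(res), 0.02)

  null_drift <- vapply(1:3, function(s) {
    r <- run_simulation(sim_config("random", n_agents = 100, n_traits = 10,
                                   generations = 40, selection_strength = 0,
                                   seed = 600 + s))
    mean(tail(r$summary$mean_energy, 5)) - mean(head(r$summary$mean_energy, 5))
  }, numeric(1))
  expect_lt(mean(null_drift), 0.02)  # no systematic climb without selection
})

test_that("sweeps enumerate the grid with independent, order-free substreams", {
  base <- sim_config("euclidean", n_agents = 12, n_traits = 3,
                     generations = 2, seed = 77)
  sw <- run_sweep(base, mutation_sds = c(0.06, 0.30),
                  selection_strengths = c(0.10, 0.20), runs = 2)
  expect_equal(length(sw), 8L)
  expect_equal(length(unique(vapply(sw, `[[`, integer(1), "seed"))), 8L)

  # re-running one cell directly reproduces the sweep's result
  cell <- sw[["euclidean.product_mu0.3_s0.2_run2"]]
  again <- run_simulation(cell$config)
  expect_identical(again$final_population, cell$final_population)
})

test_that("restricted search leaves some agents unmatched but still runs", {
  cfg <- sim_config("euclidean", n_agents = 20, n_traits = 4, generations = 4,
                    search_k = 2, seed = 21)
  fin <- run_simulation(cfg)$final_population
  expect_equal(length(fin$id), 20L)
  expect_true(sum(!is.na(fin$mate_id)) %% 2 == 0)
})
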