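test_that("fitness is the shifted payoff with floor delta", {
  ft <- compute_fitness(c(-3, 0, 5), delta = 1)
  expect_equal(ft$fitness, c(1, 4, 9))
  expect_equal(ft$tp_star, 3)
  ft <- compute_fitness(c(0, 2), delta = 1)
  expect_equal(ft$tp_star, 0)
  expect_equal(ft$fitness, c(1, 3))
  # the floor is hit exactly when the worst payoff is non-positive
  expect_equal(min(compute_fitness(c(-7, 2, 0), delta = 1)$fitness), 1)
  expect_true(all(compute_fitness(rnorm(50), delta = 1)$fitness >= 1))
})

test_that("parent selection is fitness-proportional in the right pool", {
  # singleton group with P = 1: parent is always self
  pop <- make_pop(trait = c(1, 2, 2), P = 1)
  fit <- compute_fitness(c(5, 1, 1))
  set.seed(1)
  expect_true(all(replicate(30, select_parent(1, pop, fit)) == 1))

  # in-group draw with group fitnesses 1, 4, 9 -> probabilities 1/14, 4/14, 9/14
  pop <- make_pop(trait = c(1, 1, 1, 2), P = 1, payoff = c(0, 3, 8, 50))
  fit <- compute_fitness(pop$payoff)
  layout <- prejsim:::group_layout(pop)
  set.seed(2)
  n_draws <- 30000
  draws <- replicate(n_draws, select_parent(1, pop, fit, layout))
  p_exp <- c(1, 4, 9) / 14
  for (j in 1:3) {
    expect_lt(abs(mean(draws == j) - p_exp[j]),
              3 * sqrt(p_exp[j] * (1 - p_exp[j]) / n_draws))
  }
  expect_false(any(draws == 4))  # out-group agent never selected in-group

  # P = 0: global draw matches population-wide fitness weights
  pop$P <- 0
  set.seed(3)
  draws <- replicate(n_draws, select_parent(1, pop, fit, layout))
  p_exp <- fit$fitness / sum(fit$fitness)
  for (j in 1:4) {
    expect_lt(abs(mean(draws == j) - p_exp[j]),
              3 * sqrt(p_exp[j] * (1 - p_exp[j]) / n_draws))
  }

  # equal payoffs -> uniform selection
  pop$payoff <- rep(2, 4)
  fit <- compute_fitness(pop$payoff)
  set.seed(4)
  draws <- replicate(n_draws, select_parent(1, pop, fit, layout))
  for (j in 1:4) {
    expect_lt(abs(mean(draws == j) - 0.25), 3 * sqrt(0.25 * 0.75 / n_draws))
  }
})

test_that("a closed reproduction gate leaves heuristics untouched", {
  set.seed(5)
  cfg <- tiny_config(reproduction_chance = 0)
  pop <- init_population(cfg)
  pop$payoff <- runif(nrow(pop))
  pop2 <- reproduce_population(pop, cfg)
  cols <- c("s", "u", "d", "alpha", "S", "P")
  expect_identical(pop2[cols], pop[cols])
  expect_equal(attr(pop2, "n_reproduced"), 0L)
  expect_true(all(pop2$payoff == 0) && all(pop2$rep_u == 0))
})

test_that("copying across traits adopts the heuristic but never the trait", {
  # trait-2 agents have much higher fitness; trait-1 copiers learn globally
  pop <- make_pop(trait = c(1, 1, 2, 2), alpha = c(0, 0, 1, 1), P = 0,
                  payoff = c(0, 0, 100, 100))
  cfg <- sim_config(n_agents = 4, n_traits = 2, generations = 1,
                    reproduction_chance = 1, mutation_rate = 0)
  set.seed(6)
  pop2 <- reproduce_population(pop, cfg)
  expect_identical(pop2$trait, pop$trait)
  # nearly all copies come from the high-fitness trait-2 group, so trait-1
  # agents can found a new (trait 1, alpha 1) group
  expect_true(any(pop2$alpha[pop2$trait == 1] == 1))
  expect_setequal(unlist(group_index(pop2)), pop2$id)
})

test_that("the 10% reproduction gate matches a binomial over many steps", {
  cfg <- sim_config(n_agents = 50, n_traits = 1, generations = 1,
                    mutation_rate = 0)
  pop <- make_pop(trait = rep(1, 50))
  set.seed(7)
  total <- 0
  n_steps <- 400
  for (k in seq_len(n_steps)) {
    total <- total + attr(reproduce_population(pop, cfg), "n_reproduced")
  }
  n_trials <- n_steps * 50
  expect_lt(abs(total / n_trials - 0.1), 3 * sqrt(0.1 * 0.9 / n_trials))
})

test_that("per-element mutation fires at the configured rate", {
  cfg <- sim_config(mutation_rate = 0.01)
  h0 <- list(s = 1L, u = 0L, d = 1L, alpha = 0.5, S = 0.3, P = 0.6)
  set.seed(8)
  n_trials <- 20000
  flips_s <- 0
  changes_a <- 0
  for (k in seq_len(n_trials)) {
    h <- mutate_heuristic(h0, cfg)
    if (h$s != h0$s) flips_s <- flips_s + 1
    if (h$alpha != h0$alpha) changes_a <- changes_a + 1
  }
  expect_lt(abs(flips_s / n_trials - 0.01), 3 * sqrt(0.01 * 0.99 / n_trials))
  # a resampled alpha lands on its old value 1/5 of the time
  p_a <- 0.01 * 4 / 5
  expect_lt(abs(changes_a / n_trials - p_a), 3 * sqrt(p_a * (1 - p_a) / n_trials))

  # boundary rates
  expect_identical(mutate_heuristic(h0, sim_config(mutation_rate = 0)), h0)
  set.seed(9)
  h <- mutate_heuristic(h0, sim_config(mutation_rate = 1))
  expect_identical(h$s, 0L)
  expect_identical(h$u, 1L)
  expect_identical(h$d, 0L)
})

test_that("elements fixed by the experiment are never mutated", {
  cfg <- sim_config(mutation_rate = 1, evolve_S = FALSE, evolve_P = FALSE,
                    fixed_S = 0.85, fixed_P = 0.15)
  h0 <- list(s = 1L, u = 0L, d = 1L, alpha = 0.5, S = 0.85, P = 0.15)
  set.seed(10)
  for (k in 1:20) {
    h <- mutate_heuristic(h0, cfg)
    expect_identical(h$S, 0.85)
    expect_identical(h$P, 0.15)
  }
})

test_that("neutral fitness gives an unbiased random walk in prejudice", {
  cfg <- sim_config(n_agents = 20, n_traits = 1, generations = 1,
                    mutation_rate = 0, fixed_S = 0.5, fixed_P = 0.5,
                    evolve_S = FALSE, evolve_P = FALSE)
  set.seed(11)
  n_reps <- 60
  drift <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    pop <- make_pop(trait = rep(1, 20), alpha = rep(c(0.25, 0.75), 10),
                    S = 0.5, P = 0.5)
    for (k in 1:30) pop <- reproduce_population(pop, cfg)
    drift[r] <- mean(pop$alpha) - 0.5
  }
  expect_lt(abs(mean(drift)), 3 * sd(drift) / sqrt(n_reps))
})
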