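test_that("effective reputation is exact quarter-unit arithmetic", {
  expect_identical(effective_reputation(3, 0, TRUE, 0), 12L)
  expect_identical(effective_reputation(0, 4, FALSE, 0.5), 8L)   # 2.0
  # discounting moves negative universal reputations toward zero
  expect_identical(effective_reputation(0, -4, FALSE, 0.75), -4L) # -1.0
  expect_identical(effective_reputation(0, -4, FALSE, 1), 0L)
})

test_that("donation decisions follow the social comparison rule", {
  # in-group similarity
  dec <- decide_donation(1, 1, 0, 2, effective_reputation(2, 0, TRUE, 0))
  expect_true(dec$donated)
  expect_equal(dec$outcome, "similarity")
  # out-group exact discounted tie: r_u = 4, alpha = 0.5 -> 2.0 == r_g
  dec <- decide_donation(1, 1, 0, 2, effective_reputation(0, 4, FALSE, 0.5))
  expect_true(dec$donated)
  expect_equal(dec$outcome, "similarity")
  # full prejudice turns an upward comparison into a downward defection
  dec <- decide_donation(1, 1, 0, 1, effective_reputation(0, 4, FALSE, 1))
  expect_false(dec$donated)
  expect_equal(dec$outcome, "downward")
  dec0 <- decide_donation(1, 1, 0, 1, effective_reputation(0, 4, FALSE, 0))
  expect_true(dec0$donated)  # the zero-prejudice counterfactual donates
  expect_equal(dec0$outcome, "upward")
})

test_that("decision matches the float oracle over the full state space", {
  grid <- expand.grid(rg_i = -5:5, rep_j = -5:5, lvl = 0:4,
                      s = 0:1, u = 0:1, d = 0:1, ing = c(TRUE, FALSE))
  eff <- effective_reputation(grid$rep_j, grid$rep_j, grid$ing, grid$lvl / 4)
  dec <- decide_donation(grid$s, grid$u, grid$d, grid$rg_i, eff)
  oracle <- lapply(seq_len(nrow(grid)), function(i) {
    oracle_decide(grid$s[i], grid$u[i], grid$d[i], grid$rg_i[i],
                  grid$rep_j[i], grid$rep_j[i], grid$ing[i], grid$lvl[i] / 4)
  })
  expect_identical(dec$donated,
                   vapply(oracle, function(o) o$donated, logical(1)))
  expect_identical(dec$outcome,
                   vapply(oracle, function(o) o$outcome, character(1)))
})

test_that("donation is non-increasing in prejudice for upward-rule donors", {
  for (rg_i in -5:5) {
    for (ru_j in 0:5) {
      decs <- sapply(c(0, 0.25, 0.5, 0.75, 1), function(a) {
        decide_donation(1, 1, 0, rg_i,
                        effective_reputation(0, ru_j, FALSE, a))$donated
      })
      expect_true(all(diff(as.integer(decs)) <= 0))
    }
  }
})

test_that("recipient scope follows S with null events at the boundaries", {
  pop <- make_pop(trait = c(1, 1, 1, 2, 2), alpha = 0, S = 1)
  layout <- prejsim:::group_layout(pop)
  set.seed(1)
  recs <- replicate(200, select_recipient(1, pop, layout))
  expect_true(all(recs %in% c(2, 3)))  # always in-group, never self

  # singleton group, S = 1: always a null event
  single <- build_fixture("singleton_group")
  lay <- prejsim:::group_layout(single)
  expect_true(all(is.na(replicate(50, select_recipient(1, single, lay)))))

  # S = 0: never in-group
  pop$S <- 0
  recs <- replicate(200, select_recipient(1, pop, layout))
  expect_true(all(recs %in% c(4, 5)))

  # empirical branch frequency at S = 0.3 within 3 sigma of binomial
  pop$S <- 0.3
  set.seed(2)
  n_draws <- 10000
  ing <- replicate(n_draws, select_recipient(1, pop, layout) %in% c(2, 3))
  expect_lt(abs(mean(ing) - 0.3), 3 * sqrt(0.3 * 0.7 / n_draws))
})

test_that("payoffs transfer b - c per donation and nothing on defection", {
  cfg <- tiny_config(n_agents = 4L, n_traits = 1L)
  coop <- build_fixture("all_cooperators")
  set.seed(1)
  res <- run_generation(coop, cfg)
  expect_equal(nrow(res$events), cfg$games_per_generation)
  non_null <- sum(res$events$scope != "none")
  expect_equal(sum(res$events$donated), non_null)  # full cooperators
  expect_equal(sum(res$pop$payoff), (cfg$b - cfg$cost) * non_null,
               tolerance = 1e-12)

  defect <- build_fixture("all_defectors")
  set.seed(1)
  res <- run_generation(defect, cfg)
  expect_equal(sum(res$events$donated), 0)
  expect_true(all(res$pop$payoff == 0))
})

test_that("payoff conservation holds on every generation of a full run", {
  run <- simulate_run(tiny_config(generations = 50), seed = 9)
  expect_true(all(abs(run$metrics$total_payoff -
                      0.3 * run$metrics$n_donated) < 1e-8))
})

test_that("degenerate generations behave as contracted", {
  pop <- make_pop(trait = 1, S = 0.5)  # N = 1: no possible partner
  cfg <- sim_config(n_agents = 1, n_traits = 1, generations = 5,
                    games_per_generation = 30)
  set.seed(4)
  res <- run_generation(pop, cfg)
  expect_true(all(res$events$scope == "none"))
  expect_true(all(!res$events$donated))

  cfg0 <- tiny_config(games_per_generation = 0L)
  set.seed(4)
  pop <- init_population(cfg0)
  res <- run_generation(pop, cfg0)
  expect_equal(nrow(res$events), 0)
})

test_that("counterfactual differs from the decision only out-group with alpha > 0", {
  pop <- make_pop(trait = rep(1:2, each = 4),
                  alpha = rep(c(0, 0.75), 4),
                  s = c(1, 0), u = c(1, 1, 0), d = 0,
                  S = 0.4,
                  rep_u = c(3, -2, 0, 5, -4, 1, 2, -1),
                  rep_g = c(1, 0, -3, 4, 2, -5, 0, 3))
  cfg <- sim_config(n_agents = 8, n_traits = 2, generations = 1,
                    games_per_generation = 800)
  set.seed(11)
  res <- run_generation(pop, cfg)
  ev <- res$events
  ev$donor_alpha <- pop$alpha[ev$donor]
  diff <- ev$counterfactual != ev$donated
  expect_true(all(ev$scope[diff] == "out-group"))
  expect_true(all(ev$donor_alpha[diff] > 0))
  expect_true(any(diff))  # the configuration does exercise the gap
  # in-group events always agree with their counterfactual
  expect_true(all(ev$counterfactual[ev$scope == "in-group"] ==
                  ev$donated[ev$scope == "in-group"]))
})
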