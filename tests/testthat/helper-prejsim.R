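# small configurations used across tests
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_agents = 12L, n_traits = 3L, generations = 20L,
                   games_per_generation = 150L, record_every = 1L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# hand-built population with full control over every field
make_pop <- function(trait, s = 1, u = 1, d = 0, alpha = 0, S = 0.5, P = 0.5,
                     rep_u = 0L, rep_g = 0L, payoff = 0) {
  n <- length(trait)
  pop <- data.frame(
    id = seq_len(n), trait = as.integer(trait),
    s = as.integer(rep(s, length.out = n)),
    u = as.integer(rep(u, length.out = n)),
    d = as.integer(rep(d, length.out = n)),
    alpha = rep(alpha, length.out = n),
    S = rep(S, length.out = n), P = rep(P, length.out = n),
    rep_u = as.integer(rep(rep_u, length.out = n)),
    rep_g = as.integer(rep(rep_g, length.out = n)),
    payoff = rep(payoff, length.out = n)
  )
  class(pop) <- c("population", "data.frame")
  rebuild_group_index(pop)
}

# independent plain-float oracle for the donation decision: compares the
# donor's in-group reputation against the (possibly prejudice-discounted)
# recipient reputation without any quarter-unit scaling
oracle_decide <- function(s, u, d, rg_i, rg_j, ru_j, in_group, alpha) {
  eff <- if (in_group) rg_j else ru_j * (1 - alpha)
  if (eff == rg_i) {
    list(donated = s == 1, outcome = "similarity")
  } else if (eff > rg_i) {
    list(donated = u == 1, outcome = "upward")
  } else {
    list(donated = d == 1, outcome = "downward")
  }
}

# independent oracle for the standing assessment updates
oracle_update <- function(ru_i, rg_i, rg_j, ru_j, donated, in_group, alpha) {
  clamp <- function(x) max(-5, min(5, x))
  if (donated) {
    return(list(ru = clamp(ru_i + 1), rg = clamp(rg_i + 1)))
  }
  ru <- if (ru_j < ru_i) ru_i else clamp(ru_i - 1)
  legit <- if (in_group) rg_j < rg_i else ru_j * (1 - alpha) < rg_i
  rg <- if (legit) rg_i else clamp(rg_i - 1)
  list(ru = ru, rg = rg)
}
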