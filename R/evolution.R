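#' Fitness from per-generation payoffs
#'
#' Fitness is the total payoff shifted so that every agent's fitness is
#' strictly positive: `f_i = tp* + tp_i + delta`, where `tp*` is the
#' magnitude of the most negative total payoff in the generation (0 if no
#' payoff is negative) and `delta > 0` is a small constant. The shift makes
#' fitness-proportional selection well defined; the minimum fitness equals
#' `delta` exactly when the worst payoff is non-positive.
#'
#' @param payoffs numeric vector of per-agent total payoffs `tp_i`.
#' @param delta additive fitness constant.
#' @return a `fitness_table` list with `payoffs`, `tp_star`, `delta` and
#'   `fitness`.
#' @examples
#' compute_fitness(c(-3, 0, 5), delta = 1)$fitness  # 1 4 9
#' @export
compute_fitness <- function(payoffs, delta = 1) {
  mn <- min(payoffs)
  tp_star <- if (mn < 0) -mn else 0
  structure(
    list(payoffs = payoffs, tp_star = tp_star, delta = delta,
         fitness = tp_star + payoffs + delta),
    class = "fitness_table"
  )
}

#' Select a parent to copy from (island model)
#'
#' With probability `P_i` (the copier's own in-group learning probability)
#' the parent is drawn from the copier's current prejudicial group with
#' probability proportional to fitness within the group; otherwise from the
#' whole population with probability proportional to fitness over all
#' agents. Self-selection is permitted (a no-op copy).
#'
#' Uses the session RNG; draw order matches the compiled engine.
#'
#' @param agent_id the copying agent.
#' @param pop the pre-reproduction population snapshot.
#' @param fit a [compute_fitness()] table for the same snapshot.
#' @param layout precomputed [group_layout()].
#' @return the parent's agent id.
#' @export
select_parent <- function(agent_id, pop, fit, layout = group_layout(pop)) {
  f <- fit$fitness
  if (runif(1) < pop$P[agent_id]) {
    gid <- layout$gid[agent_id]
    members <- layout$ord[(layout$gstart0[gid] + 1L):
                          (layout$gstart0[gid] + layout$gsize[gid])]
    cum <- Reduce(`+`, f[members], accumulate = TRUE)
    r <- runif(1) * cum[length(cum)]
    j <- which(cum >= r)[1]
    if (is.na(j)) j <- length(cum)
    members[j]
  } else {
    cum <- Reduce(`+`, f, accumulate = TRUE)
    r <- runif(1) * cum[length(cum)]
    j <- which(cum >= r)[1]
    if (is.na(j)) j <- length(f)
    j
  }
}

#' Mutate a social comparison heuristic
#'
#' Independently per element with probability `mutation_rate`: the binary
#' action rules flip; the prejudice level is resampled uniformly from its
#' 5-point grid; `S` and `P` are resampled uniformly from the 10-point
#' `{0, 0.1, ..., 0.9}` grid when they evolve (elements fixed by the
#' experiment are never mutated). Resampling may return the current value.
#'
#' @param h a list (or one-row data frame) with elements `s`, `u`, `d`,
#'   `alpha`, `S`, `P`.
#' @param cfg a [sim_config()].
#' @return the mutated heuristic.
#' @export
mutate_heuristic <- function(h, cfg) {
  mu <- cfg$mutation_rate
  if (runif(1) < mu) h$s <- 1L - h$s
  if (runif(1) < mu) h$u <- 1L - h$u
  if (runif(1) < mu) h$d <- 1L - h$d
  if (cfg$evolve_alpha && runif(1) < mu) {
    h$alpha <- ALPHA_GRID[min(floor(runif(1) * 5), 4) + 1L]
  }
  if (cfg$evolve_S && runif(1) < mu) {
    h$S <- 0.1 * min(floor(runif(1) * 10), 9)
  }
  if (cfg$evolve_P && runif(1) < mu) {
    h$P <- 0.1 * min(floor(runif(1) * 10), 9)
  }
  h
}

#' End-of-generation selection and reproduction
#'
#' Each agent independently passes the reproduction gate with probability
#' `reproduction_chance`; gated agents replace their entire heuristic
#' (`s, u, d, alpha` and, when evolving, `S, P`) with a parent's chosen by
#' [select_parent()] and then mutate per element. The trait is never
#' copied. Selection is fully synchronous: every parent choice is made
#' against the frozen pre-step snapshot of heuristics, groups and
#' fitnesses. Afterwards the group index is rebuilt and reputations and
#' payoffs are reset for the new generation.
#'
#' @param pop the population at the end of a generation (payoffs earned).
#' @param cfg a [sim_config()].
#' @return the next-generation population; the number of agents that
#'   reproduced is attached as attribute `n_reproduced`.
#' @export
reproduce_population <- function(pop, cfg) {
  pop0 <- pop                       # frozen snapshot
  layout <- group_layout(pop0)
  fit <- compute_fitness(pop0$payoff, cfg$delta)
  n <- nrow(pop)
  n_rep <- 0L
  for (i in seq_len(n)) {
    if (runif(1) < cfg$reproduction_chance) {
      n_rep <- n_rep + 1L
      parent <- select_parent(i, pop0, fit, layout)
      h <- list(s = pop0$s[parent], u = pop0$u[parent], d = pop0$d[parent],
                alpha = pop0$alpha[parent],
                S = if (cfg$evolve_S) pop0$S[parent] else pop$S[i],
                P = if (cfg$evolve_P) pop0$P[parent] else pop$P[i])
      h <- mutate_heuristic(h, cfg)
      pop$s[i] <- h$s
      pop$u[i] <- h$u
      pop$d[i] <- h$d
      pop$alpha[i] <- h$alpha
      pop$S[i] <- h$S
      pop$P[i] <- h$P
    }
  }
  pop$rep_u <- integer(n)
  pop$rep_g <- integer(n)
  pop$payoff <- numeric(n)
  pop <- rebuild_group_index(pop)
  attr(pop, "n_reproduced") <- n_rep
  pop
}
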