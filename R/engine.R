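#' @title Donation-game rules
#' @description
#' Pure functions implementing the social-comparison action rule and the
#' generalized-standing assessment rules. All reputation comparisons are
#' carried out in quarter-units (scaled by 4): prejudice levels are
#' multiples of 0.25 and reputations are integers, so the discounted
#' out-group reputation `r_j^U * (1 - alpha_i)` times 4 is an exact
#' integer and ties are never float-sensitive.
#' @name donation-rules
NULL

# CSR-style layout of the group partition; the member ordering (ascending
# group id, ascending agent id within group) is part of the engine contract
# shared with the compiled core.
group_layout <- function(pop) {
  gid <- group_id(pop)
  n_groups <- max(pop$trait) * 5L
  ord <- order(gid, pop$id)
  gsize <- tabulate(gid, nbins = n_groups)
  gstart0 <- cumsum(c(0L, gsize))[seq_len(n_groups)]
  pos0 <- integer(nrow(pop))
  pos0[ord] <- unlist(lapply(gsize[gsize > 0L], seq_len), use.names = FALSE) - 1L
  list(gid = gid, ord = pop$id[ord], gsize = gsize, gstart0 = gstart0,
       pos0 = pos0)
}

#' Effective recipient reputation in quarter-units
#'
#' The reputation the donor actually compares against: the recipient's
#' in-group reputation for in-group recipients, or the universal reputation
#' discounted by the donor's prejudice for out-group recipients. Returned
#' scaled by 4 so the value is always an exact integer.
#'
#' @param rep_g_j,rep_u_j recipient in-group / universal reputation
#'   (integers in \[-5, 5\]).
#' @param in_group logical; is the recipient in the donor's group?
#' @param alpha_donor the donor's prejudice level.
#' @return integer quarter-unit reputation(s): `4 * r_j^G` in-group,
#'   `4 * r_j^U * (1 - alpha)` out-group.
#' @examples
#' effective_reputation(3, 0, TRUE, 0)        # 12
#' effective_reputation(0, 4, FALSE, 0.5)     # 8, i.e. discounted 2.0
#' @export
effective_reputation <- function(rep_g_j, rep_u_j, in_group, alpha_donor) {
  lvl <- alpha_level(alpha_donor)
  as.integer(ifelse(in_group, 4L * rep_g_j, rep_u_j * (4L - lvl)))
}

#' Donation decision by social comparison
#'
#' Compares the donor's in-group reputation (in quarter-units) with the
#' effective recipient reputation and applies the donor's action rule:
#' donate on similarity if `s = 1`, on upward self-comparison (recipient
#' higher) if `u = 1`, on downward self-comparison if `d = 1`.
#'
#' @param s,u,d donor action-rule bits.
#' @param rep_g_i donor in-group reputation.
#' @param eff_q effective recipient reputation in quarter-units, from
#'   [effective_reputation()].
#' @return a list with `donated` (logical) and `outcome` (one of
#'   `"similarity"`, `"upward"`, `"downward"`); vectorized.
#' @export
decide_donation <- function(s, u, d, rep_g_i, eff_q) {
  L <- 4L * rep_g_i
  outcome <- ifelse(eff_q == L, "similarity",
                    ifelse(eff_q > L, "upward", "downward"))
  donated <- ifelse(outcome == "similarity", s == 1,
                    ifelse(outcome == "upward", u == 1, d == 1))
  list(donated = donated, outcome = outcome)
}

#' Universal-reputation update (generalized standing)
#'
#' Donations increment the donor's universal reputation; defection
#' decrements it unless the recipient's universal reputation is strictly
#' below the donor's (legitimate shirking). Equal standing is not
#' legitimate. Values saturate at the \[-5, 5\] bounds.
#'
#' @param rep_u_i donor universal reputation.
#' @param rep_u_j recipient universal reputation.
#' @param donated logical.
#' @return the donor's new universal reputation; vectorized.
#' @export
update_universal <- function(rep_u_i, rep_u_j, donated) {
  as.integer(ifelse(donated, pmin(rep_u_i + 1L, 5L),
                    ifelse(rep_u_j < rep_u_i, rep_u_i,
                           pmax(rep_u_i - 1L, -5L))))
}

#' In-group-reputation update (prejudice-aware standing)
#'
#' As [update_universal()] but from the in-group's perspective: for
#' in-group recipients legitimacy compares in-group reputations; for
#' out-group recipients the recipient's universal reputation is first
#' discounted by the donor's prejudice (exact quarter-unit comparison).
#'
#' @param rep_g_i donor in-group reputation.
#' @param rep_g_j,rep_u_j recipient reputations.
#' @param donated logical.
#' @param in_group logical; recipient in the donor's group?
#' @param alpha_donor donor prejudice level.
#' @return the donor's new in-group reputation; vectorized.
#' @export
update_ingroup <- function(rep_g_i, rep_g_j, rep_u_j, donated, in_group,
                           alpha_donor) {
  lvl <- alpha_level(alpha_donor)
  legit <- ifelse(in_group, rep_g_j < rep_g_i,
                  rep_u_j * (4L - lvl) < 4L * rep_g_i)
  as.integer(ifelse(donated, pmin(rep_g_i + 1L, 5L),
                    ifelse(legit, rep_g_i, pmax(rep_g_i - 1L, -5L))))
}

#' Select a recipient for a donation game
#'
#' With probability `S_i` (the donor's own value) the recipient is drawn
#' uniformly from the donor's prejudicial group excluding the donor;
#' otherwise uniformly from all agents outside the group. If the chosen
#' scope has no eligible agent (a singleton group, or an empty out-group
#' when the whole population shares one group) the game is a null event:
#' no cost is incurred and no donation is made.
#'
#' Uses the session RNG; draw order matches the compiled engine.
#'
#' @param donor_id donor agent id.
#' @param pop a population with a current group index.
#' @param layout precomputed [group_layout()] (internal fast path).
#' @return the recipient id, or `NA` for a null event.
#' @export
select_recipient <- function(donor_id, pop, layout = group_layout(pop)) {
  n <- nrow(pop)
  gid <- layout$gid[donor_id]
  gs <- layout$gsize[gid]
  if (runif(1) < pop$S[donor_id]) {
    m <- gs - 1L
    if (m < 1L) return(NA_integer_)
    k <- min(floor(runif(1) * m), m - 1L)
    if (k >= layout$pos0[donor_id]) k <- k + 1L
    layout$ord[layout$gstart0[gid] + k + 1L]
  } else {
    m <- n - gs
    if (m < 1L) return(NA_integer_)
    k <- min(floor(runif(1) * m), m - 1L)
    if (k >= layout$gstart0[gid]) k <- k + gs
    layout$ord[k + 1L]
  }
}

#' Play one donation game
#'
#' Selects a recipient for the given donor, makes the donation decision,
#' transfers payoffs (`-cost` to the donor, `+b` to the recipient) if the
#' donor donates, computes the zero-prejudice counterfactual decision for
#' out-group recipients, and updates the donor's two reputations under the
#' standing assessment rules. Null events change no state.
#'
#' @param donor_id donor agent id.
#' @param pop a population.
#' @param cfg a [sim_config()] (for `b` and `cost`).
#' @param layout precomputed [group_layout()].
#' @return list with the updated `pop` and an `event` list holding
#'   `donor`, `recipient`, `scope`, `outcome`, `donated`,
#'   `counterfactual`.
#' @export
play_game <- function(donor_id, pop, cfg, layout = group_layout(pop)) {
  rec <- select_recipient(donor_id, pop, layout)
  if (is.na(rec)) {
    return(list(pop = pop, event = list(
      donor = donor_id, recipient = NA_integer_, scope = "none",
      outcome = "none", donated = FALSE, counterfactual = FALSE)))
  }
  ing <- layout$gid[rec] == layout$gid[donor_id]
  eff <- effective_reputation(pop$rep_g[rec], pop$rep_u[rec], ing,
                              pop$alpha[donor_id])
  dec <- decide_donation(pop$s[donor_id], pop$u[donor_id], pop$d[donor_id],
                         pop$rep_g[donor_id], eff)
  cf <- dec$donated
  if (!ing) {
    dec0 <- decide_donation(pop$s[donor_id], pop$u[donor_id],
                            pop$d[donor_id], pop$rep_g[donor_id],
                            4L * pop$rep_u[rec])
    cf <- dec0$donated
  }
  if (dec$donated) {
    pop$payoff[donor_id] <- pop$payoff[donor_id] - cfg$cost
    pop$payoff[rec] <- pop$payoff[rec] + cfg$b
  }
  new_u <- update_universal(pop$rep_u[donor_id], pop$rep_u[rec], dec$donated)
  new_g <- update_ingroup(pop$rep_g[donor_id], pop$rep_g[rec],
                          pop$rep_u[rec], dec$donated, ing,
                          pop$alpha[donor_id])
  pop$rep_u[donor_id] <- new_u
  pop$rep_g[donor_id] <- new_g
  list(pop = pop, event = list(
    donor = donor_id, recipient = rec,
    scope = if (ing) "in-group" else "out-group",
    outcome = dec$outcome, donated = dec$donated, counterfactual = cf))
}

#' Run one generation of donation games (reference engine)
#'
#' Performs `games_per_generation` games with the donor drawn uniformly
#' (with replacement) from the whole population each time, and returns the
#' full event log. This is the pure-R reference implementation; it consumes
#' the RNG stream identically to the compiled engine used by
#' [simulate_run()], so both produce bit-identical trajectories.
#'
#' @param pop a population with reputations and payoffs zeroed at the
#'   generation start.
#' @param cfg a [sim_config()].
#' @return list with the updated `pop` and `events`, a data frame with one
#'   row per game (including null events).
#' @export
run_generation <- function(pop, cfg) {
  pop <- rebuild_group_index(pop)
  layout <- group_layout(pop)
  n <- nrow(pop)
  g <- cfg$games_per_generation
  ev <- list(
    donor = integer(g), recipient = integer(g), scope = character(g),
    outcome = character(g), donated = logical(g), counterfactual = logical(g)
  )
  for (k in seq_len(g)) {
    donor <- as.integer(min(floor(runif(1) * n), n - 1)) + 1L
    res <- play_game(donor, pop, cfg, layout)
    pop <- res$pop
    e <- res$event
    ev$donor[k] <- e$donor
    ev$recipient[k] <- e$recipient
    ev$scope[k] <- e$scope
    ev$outcome[k] <- e$outcome
    ev$donated[k] <- e$donated
    ev$counterfactual[k] <- e$counterfactual
  }
  list(pop = pop, events = as.data.frame(ev))
}
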