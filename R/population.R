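#' Initialize a population
#'
#' Creates the generation-zero population for a configuration: traits
#' assigned block-wise according to the configured sub-population sizes,
#' action rules `s, u, d` uniform random binary (unless fixed by
#' `init_sud`), `S` and `P` uniform on the `{0, 0.1, ..., 0.9}` grid when
#' evolving (otherwise the fixed exogenous values), prejudice per
#' `init_alpha`, and all reputations and payoffs at zero.
#'
#' Uses the session RNG; call `set.seed()` beforehand for reproducibility.
#'
#' @param cfg a [sim_config()].
#' @return a `population`: a data frame with one row per agent and columns
#'   `id`, `trait`, `s`, `u`, `d`, `alpha`, `S`, `P`, `rep_u`, `rep_g`,
#'   `payoff`, carrying the group index as an attribute (see
#'   [rebuild_group_index()]).
#' @examples
#' set.seed(1)
#' pop <- init_population(sim_config(n_traits = 5, generations = 10))
#' table(pop$trait)
#' @export
init_population <- function(cfg) {
  validate_config(cfg)
  n <- cfg$n_agents
  trait <- rep(seq_along(cfg$trait_sizes), times = cfg$trait_sizes)
  if (identical(cfg$init_sud, "random")) {
    s <- as.integer(runif(n) < 0.5)
    u <- as.integer(runif(n) < 0.5)
    d <- as.integer(runif(n) < 0.5)
  } else {
    s <- rep(as.integer(cfg$init_sud[1]), n)
    u <- rep(as.integer(cfg$init_sud[2]), n)
    d <- rep(as.integer(cfg$init_sud[3]), n)
  }
  S <- if (cfg$evolve_S) 0.1 * pmin(floor(runif(n) * 10), 9) else rep(cfg$fixed_S, n)
  P <- if (cfg$evolve_P) 0.1 * pmin(floor(runif(n) * 10), 9) else rep(cfg$fixed_P, n)
  alpha <- rep(cfg$init_alpha, length.out = n)
  pop <- data.frame(
    id = seq_len(n), trait = as.integer(trait),
    s = s, u = u, d = d, alpha = alpha, S = S, P = P,
    rep_u = integer(n), rep_g = integer(n), payoff = numeric(n)
  )
  class(pop) <- c("population", "data.frame")
  rebuild_group_index(pop)
}

#' Prejudice level as an integer 0..4
#' @param alpha prejudice values (multiples of 0.25 in \[0, 1\]).
#' @return integer levels `alpha * 4`.
#' @keywords internal
alpha_level <- function(alpha) as.integer(round(alpha * 4))

#' Group id of each agent
#'
#' A prejudicial group is identified by the pair (trait, alpha); internally
#' groups are numbered `(trait - 1) * 5 + alpha_level + 1`.
#'
#' @param pop a population.
#' @return integer group ids, one per agent.
#' @keywords internal
group_id <- function(pop) {
  (pop$trait - 1L) * 5L + alpha_level(pop$alpha) + 1L
}

#' Rebuild the group index of a population
#'
#' Prejudicial groups are the maximal sets of agents sharing both the
#' immutable trait and the prejudice level; they partition each
#' sub-population. The index is recomputed from scratch from the agent
#' table and stored as the `group_index` attribute: a named list
#' `"trait:alpha" -> member ids`, members in ascending id order.
#'
#' @param pop a population.
#' @return `pop` with a fresh `group_index` attribute.
#' @export
rebuild_group_index <- function(pop) {
  gid <- group_id(pop)
  key <- sprintf("%d:%s", pop$trait, as.character(pop$alpha))
  idx <- split(pop$id, factor(key, levels = unique(key[order(gid, pop$id)])))
  attr(pop, "group_index") <- lapply(idx, as.integer)
  pop
}

#' Retrieve the group index
#' @param pop a population.
#' @return named list mapping `"trait:alpha"` to member ids.
#' @export
group_index <- function(pop) attr(pop, "group_index")

#' Deterministic tiny populations for tests and examples
#'
#' @param name one of:
#'   \describe{
#'     \item{`all_cooperators`}{4 agents, one trait, `(s,u,d) = (1,1,1)`,
#'       `alpha = 0`: every game is a donation.}
#'     \item{`all_defectors`}{as above with `(0,0,0)`: never donates.}
#'     \item{`two_group_tie`}{4 agents in two prejudicial groups with preset
#'       reputations chosen so that one sweep of donor/recipient pairs hits
#'       the similarity, upward and downward branches both in-group and
#'       out-group, including the exact discounted tie.}
#'     \item{`singleton_group`}{3 agents, one of which is alone in its
#'       group, with `S = 1`: the singleton's in-group draws are null
#'       events (no cost, no donation).}
#'   }
#' @return a `population` with group index attached.
#' @export
build_fixture <- function(name) {
  mk <- function(trait, s, u, d, alpha, S, P, rep_u = 0L, rep_g = 0L) {
    n <- length(trait)
    pop <- data.frame(
      id = seq_len(n), trait = as.integer(trait),
      s = as.integer(s), u = as.integer(u), d = as.integer(d),
      alpha = alpha, S = S, P = P,
      rep_u = as.integer(rep(rep_u, length.out = n)),
      rep_g = as.integer(rep(rep_g, length.out = n)),
      payoff = numeric(n)
    )
    class(pop) <- c("population", "data.frame")
    rebuild_group_index(pop)
  }
  switch(name,
    all_cooperators = mk(rep(1L, 4), 1, 1, 1, 0, 0.5, 0.5),
    all_defectors = mk(rep(1L, 4), 0, 0, 0, 0, 0.5, 0.5),
    two_group_tie = mk(
      trait = c(1L, 1L, 1L, 1L),
      s = 1, u = 1, d = 0,
      alpha = c(0, 0, 0.5, 0.5),
      S = 0.5, P = 0.5,
      rep_u = c(0L, 4L, 2L, -2L),
      rep_g = c(0L, 2L, 2L, 2L)
    ),
    singleton_group = mk(
      trait = c(1L, 1L, 1L),
      s = 1, u = 1, d = 1,
      alpha = c(1, 0, 0),
      S = 1, P = 0.5
    ),
    stop("unknown fixture: ", name, call. = FALSE)
  )
}
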