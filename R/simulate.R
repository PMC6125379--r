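#' Run one simulation (compiled engine)
#'
#' Initializes a population and runs the full generational cycle — 5000
#' donation games (by default) followed by island-model selection, with
#' reputations and payoffs reset at each generation boundary — in the
#' compiled event loop. The R reference engine ([simulate_run_r()])
#' consumes the identical RNG stream and produces bit-identical output;
#' the compiled path is simply fast enough for full-length runs.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed for this run (sets the session RNG).
#' @param log_events if `TRUE`, also return the full per-game event log
#'   (one row per game; intended for short diagnostic runs — the log has
#'   `games_per_generation * generations` rows).
#' @return a `sim_run` list with `metrics` (one row per recorded
#'   generation), `final` (heuristics after the last reproductive step),
#'   `config`, `seed`, and optionally `events`.
#' @examples
#' cfg <- sim_config(n_agents = 20, n_traits = 2, generations = 50,
#'                   games_per_generation = 200)
#' run <- simulate_run(cfg, seed = 1)
#' tail(run$metrics[, c("gen", "coop_rate", "mean_alpha")], 3)
#' @export
simulate_run <- function(cfg, seed, log_events = FALSE) {
  validate_config(cfg)
  set.seed(seed)
  pop <- init_population(cfg)
  res <- .sim_core_run(
    pop$trait - 1L, pop$s, pop$u, pop$d, alpha_level(pop$alpha),
    pop$S, pop$P,
    cfg$games_per_generation, cfg$generations, cfg$b, cfg$cost,
    cfg$mutation_rate, cfg$reproduction_chance, cfg$delta,
    cfg$evolve_S, cfg$evolve_P, cfg$evolve_alpha,
    cfg$record_every, log_events
  )
  metrics <- as.data.frame(res$metrics)
  fin <- as.data.frame(res$final)
  fin$trait <- fin$trait + 1L
  fin$alpha <- fin$alpha_lvl / 4
  fin$alpha_lvl <- NULL
  fin$id <- seq_len(nrow(fin))
  out <- list(metrics = metrics, final = fin, config = cfg, seed = seed)
  if (log_events) out$events <- decode_events(res$events)
  class(out) <- "sim_run"
  out
}

# map the compiled engine's integer event codes onto the labels used by
# the reference engine
decode_events <- function(m) {
  df <- as.data.frame(m)
  df$scope <- c("in-group", "out-group", "none")[df$scope + 1L]
  df$outcome <- c("similarity", "upward", "downward", "none")[df$outcome + 1L]
  df$donated <- df$donated == 1L
  df$counterfactual <- df$counterfactual == 1L
  df
}

#' Run one simulation (pure-R reference engine)
#'
#' Slow, transparent implementation of the identical generational cycle,
#' used to cross-validate the compiled engine: from the same seed both
#' produce bit-identical metrics, final state and event logs. Intended for
#' small populations and short runs.
#'
#' @inheritParams simulate_run
#' @return a `sim_run` list as in [simulate_run()], with `events` always
#'   included.
#' @export
simulate_run_r <- function(cfg, seed, log_events = TRUE) {
  validate_config(cfg)
  set.seed(seed)
  pop <- init_population(cfg)
  rec <- list()
  evs <- list()
  for (gen in seq_len(cfg$generations)) {
    res <- run_generation(pop, cfg)
    pop <- res$pop
    record <- gen %% cfg$record_every == 0 || gen == cfg$generations
    row <- NULL
    if (record) row <- summarize_generation(pop, res$events, gen)
    if (log_events) evs[[gen]] <- cbind(gen = gen, res$events)
    pop <- reproduce_population(pop, cfg)
    if (record) {
      row$n_reproduced <- attr(pop, "n_reproduced")
      rec[[length(rec) + 1L]] <- row
    }
  }
  fin <- pop[c("trait", "s", "u", "d", "S", "P", "alpha", "id")]
  out <- list(metrics = do.call(rbind, rec), final = as.data.frame(fin),
              config = cfg, seed = seed)
  if (log_events) out$events <- do.call(rbind, evs)
  class(out) <- "sim_run"
  out
}

#' @export
print.sim_run <- function(x, ...) {
  m <- x$metrics
  last <- m[nrow(m), ]
  cat(sprintf("<sim_run> seed %d: %d agents, %d generations recorded\n",
              x$seed, x$config$n_agents, nrow(m)))
  cat(sprintf("  final gen %d: cooperation %.3f, mean prejudice %.3f\n",
              last$gen, last$coop_rate, last$mean_alpha))
  invisible(x)
}
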