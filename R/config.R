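#' Simulation configuration
#'
#' Builds and validates the full parameter set for one simulation scenario.
#' Defaults follow the standard study conditions: 100 agents, 5000 donation
#' games per generation, cost/benefit ratio `cost/b = 0.7`, 1% per-element
#' mutation, a 10% per-agent reproduction gate and fitness constant
#' `delta = 1`.
#'
#' @param n_agents population size.
#' @param n_traits number of equal-sized sub-populations. Ignored when
#'   `trait_sizes` is given.
#' @param trait_sizes optional integer vector of sub-population sizes (must
#'   sum to `n_agents`); use this for imbalanced splits such as `c(90, 10)`.
#' @param games_per_generation donation games played per generation.
#' @param generations number of generations per run.
#' @param runs default number of independently seeded replicates.
#' @param b,cost benefit received by the recipient and cost paid by the
#'   donor. Only the ratio matters for selection (payoffs are affine in the
#'   scale, up to the `delta` offset); the default scale sets `b = 1`.
#' @param mutation_rate per-element mutation probability applied to a newly
#'   copied heuristic.
#' @param reproduction_chance per-agent probability of reproducing at the
#'   end of a generation.
#' @param delta additive fitness constant keeping all fitnesses positive.
#' @param evolve_S,evolve_P whether `S` (in-group interaction probability)
#'   and `P` (in-group learning probability) evolve on the grid
#'   `{0, 0.1, ..., 0.9}`. When `FALSE`, `fixed_S` / `fixed_P` is applied to
#'   every agent and excluded from mutation.
#' @param fixed_S,fixed_P exogenous values in `[0, 1]` used when the
#'   corresponding element does not evolve.
#' @param evolve_alpha whether the prejudice level mutates. Setting this to
#'   `FALSE` with `init_alpha = 0` and a single trait reproduces the
#'   group-free social-comparison base model.
#' @param init_alpha initial prejudice level: a single grid value
#'   (multiple of 0.25 in `[0, 1]`) applied to all agents, or a vector of
#'   length `n_agents`.
#' @param init_sud `"random"` for uniform random binary action rules, or a
#'   length-3 binary vector `c(s, u, d)` applied to all agents.
#' @param record_every record metrics every this many generations (the final
#'   generation is always recorded).
#' @param master_seed optional integer seed attached to the config; used by
#'   [run_experiment()] to derive per-run child seeds.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @seealso [simulate_run()], [init_population()], [load_config()]
#' @examples
#' cfg <- sim_config(n_traits = 5, generations = 100)
#' cfg$trait_sizes
#' @export
sim_config <- function(n_agents = 100L,
                       n_traits = 5L,
                       trait_sizes = NULL,
                       games_per_generation = 5000L,
                       generations = 50000L,
                       runs = 10L,
                       b = 1.0,
                       cost = 0.7,
                       mutation_rate = 0.01,
                       reproduction_chance = 0.10,
                       delta = 1.0,
                       evolve_S = TRUE,
                       evolve_P = TRUE,
                       fixed_S = NULL,
                       fixed_P = NULL,
                       evolve_alpha = TRUE,
                       init_alpha = 0,
                       init_sud = "random",
                       record_every = 1L,
                       master_seed = NULL) {
  if (is.null(trait_sizes)) {
    if (n_traits < 1 || n_agents %% n_traits != 0) {
      stop("n_agents (", n_agents, ") is not divisible by n_traits (",
           n_traits, "); give explicit trait_sizes instead", call. = FALSE)
    }
    trait_sizes <- rep(n_agents / n_traits, n_traits)
  }
  cfg <- list(
    n_agents = as.integer(n_agents),
    trait_sizes = as.integer(trait_sizes),
    games_per_generation = as.integer(games_per_generation),
    generations = as.integer(generations),
    runs = as.integer(runs),
    b = as.numeric(b),
    cost = as.numeric(cost),
    mutation_rate = as.numeric(mutation_rate),
    reproduction_chance = as.numeric(reproduction_chance),
    delta = as.numeric(delta),
    evolve_S = isTRUE(evolve_S),
    evolve_P = isTRUE(evolve_P),
    fixed_S = if (is.null(fixed_S)) NULL else as.numeric(fixed_S),
    fixed_P = if (is.null(fixed_P)) NULL else as.numeric(fixed_P),
    evolve_alpha = isTRUE(evolve_alpha),
    init_alpha = as.numeric(init_alpha),
    init_sud = init_sud,
    record_every = as.integer(record_every),
    master_seed = if (is.null(master_seed)) NULL else as.integer(master_seed)
  )
  class(cfg) <- "sim_config"
  validate_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks every constraint and reports all violations together.
#'
#' @param cfg a `sim_config`.
#' @return `cfg`, invisibly, if valid; otherwise an error listing every
#'   violation.
#' @export
validate_config <- function(cfg) {
  err <- character(0)
  add <- function(msg) err <<- c(err, msg)

  if (cfg$n_agents < 1) add("n_agents must be >= 1")
  if (any(cfg$trait_sizes < 0)) add("trait_sizes must be non-negative")
  if (sum(cfg$trait_sizes) != cfg$n_agents) {
    add(sprintf("trait_sizes sum to %d, not n_agents = %d",
                sum(cfg$trait_sizes), cfg$n_agents))
  }
  if (cfg$games_per_generation < 0) add("games_per_generation must be >= 0")
  if (cfg$generations < 1) add("generations must be >= 1")
  if (cfg$runs < 1) add("runs must be >= 1")
  if (!(cfg$cost > 0 && cfg$cost < cfg$b)) add("need 0 < cost < b")
  if (cfg$mutation_rate < 0 || cfg$mutation_rate > 1) {
    add("mutation_rate must be in [0, 1]")
  }
  if (cfg$reproduction_chance < 0 || cfg$reproduction_chance > 1) {
    add("reproduction_chance must be in [0, 1]")
  }
  if (cfg$delta <= 0) add("delta must be > 0")
  if (!cfg$evolve_S && is.null(cfg$fixed_S)) {
    add("fixed_S is required when evolve_S = FALSE")
  }
  if (!cfg$evolve_P && is.null(cfg$fixed_P)) {
    add("fixed_P is required when evolve_P = FALSE")
  }
  for (nm in c("fixed_S", "fixed_P")) {
    v <- cfg[[nm]]
    if (!is.null(v) && (length(v) != 1 || v < 0 || v > 1)) {
      add(paste(nm, "must be a single value in [0, 1]"))
    }
  }
  ia <- cfg$init_alpha
  if (!length(ia) %in% c(1L, cfg$n_agents)) {
    add("init_alpha must have length 1 or n_agents")
  }
  if (any(!ia %in% ALPHA_GRID)) {
    add("init_alpha values must lie on the grid {0, 0.25, 0.5, 0.75, 1}")
  }
  if (!identical(cfg$init_sud, "random")) {
    sud <- cfg$init_sud
    if (length(sud) != 3 || !all(sud %in% c(0, 1))) {
      add("init_sud must be \"random\" or a length-3 binary vector")
    }
  }
  if (cfg$record_every < 1) add("record_every must be >= 1")

  if (length(err)) {
    stop("invalid sim_config:\n  - ", paste(err, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  agents: %d in %d sub-population(s) [%s]\n", x$n_agents,
              length(x$trait_sizes), paste(x$trait_sizes, collapse = "/")))
  cat(sprintf("  games/gen: %d, generations: %d, runs: %d\n",
              x$games_per_generation, x$generations, x$runs))
  cat(sprintf("  b = %g, cost = %g (cost/b = %g), delta = %g\n",
              x$b, x$cost, x$cost / x$b, x$delta))
  cat(sprintf("  mutation: %g/element, reproduction gate: %g\n",
              x$mutation_rate, x$reproduction_chance))
  sp <- function(ev, fx, nm) {
    if (ev) sprintf("%s evolving on {0,...,0.9}", nm)
    else sprintf("%s fixed at %g", nm, fx)
  }
  cat("  ", sp(x$evolve_S, x$fixed_S, "S"), "; ",
      sp(x$evolve_P, x$fixed_P, "P"), "\n", sep = "")
  cat(sprintf("  alpha: init %s, %s\n",
              paste(unique(x$init_alpha), collapse = ","),
              if (x$evolve_alpha) "evolving" else "frozen"))
  invisible(x)
}

# grids the evolving heuristic elements live on
ALPHA_GRID <- c(0, 0.25, 0.5, 0.75, 1)
SP_GRID <- seq(0, 0.9, by = 0.1)

#' Read a configuration from a JSON file
#'
#' The file is a flat JSON object whose keys are [sim_config()] argument
#' names. Unknown keys are an error; missing keys take the defaults. All
#' validation failures are reported together.
#'
#' @param path path to a JSON config file.
#' @return a validated `sim_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(sim_config, raw)
}

#' Write a configuration to a JSON file
#'
#' @param cfg a `sim_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  x <- unclass(cfg)
  x <- x[!vapply(x, is.null, logical(1))]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Stable short hash of a configuration
#'
#' FNV-1a over the canonical JSON serialization; used to tag result files so
#' runs can be matched back to the exact configuration that produced them.
#'
#' @param cfg a `sim_config`.
#' @return an 8-hex-digit character scalar.
#' @export
config_hash <- function(cfg) {
  x <- unclass(cfg)
  x <- x[!vapply(x, is.null, logical(1))]
  x <- x[order(names(x))]
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(js))
  h <- 2166136261
  for (bb in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(bb))
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Derive a reproducible child seed
#'
#' Deterministic integer mixing of a master seed with one or more indices
#' (config index, run index), so that adding configurations or runs never
#' perturbs the seeds of existing ones. Results stay within the 32-bit
#' signed-integer range R requires of `set.seed()`.
#'
#' @param master_seed integer master seed.
#' @param ... integer indices identifying the child stream.
#' @return a positive integer seed.
#' @export
child_seed <- function(master_seed, ...) {
  m <- 2147483647  # 2^31 - 1
  x <- as.numeric(master_seed) %% m
  for (idx in c(...)) {
    x <- (x * 48271 + as.numeric(idx) * 2246822519 + 1013904223) %% m
  }
  as.integer(x + 1)
}
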