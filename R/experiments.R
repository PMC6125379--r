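#' Preset scenario: full co-evolution
#'
#' The emergence scenario: 100 agents in 5 equal sub-populations, every
#' heuristic element — action rules, prejudice, in-group interaction `S`
#' and in-group learning `P` — subject to natural selection, starting from
#' a prejudice-free population with random action rules and random `S`,
#' `P` on the `{0, ..., 0.9}` grid. Default length 100,000 generations.
#'
#' @param generations,runs,... overrides passed to [sim_config()] (use
#'   these to run the scenario at reduced scale).
#' @return a `sim_config`.
#' @export
scenario_coevolution <- function(generations = 100000L, runs = 10L, ...) {
  sim_config(n_traits = 5L, generations = generations, runs = runs,
             evolve_S = TRUE, evolve_P = TRUE, evolve_alpha = TRUE,
             init_alpha = 0, ...)
}

#' Preset scenario: fixed interaction/learning grid
#'
#' One configuration per (S, P) pair with both values exogenously fixed
#' for all agents (and excluded from mutation), 5 equal sub-populations,
#' prejudice starting at zero. This is the pluralism sweep: `S` sets how
#' in-group the donation games are, `P` how in-group the strategy learning
#' is.
#'
#' @param S_values,P_values numeric vectors of fixed values in `[0, 1]`.
#' @param generations,runs,n_traits,... overrides passed to [sim_config()].
#' @return a list of `sim_config`, cross product in row-major order
#'   (`S` varying fastest).
#' @export
scenario_grid <- function(S_values, P_values, generations = 50000L,
                          runs = 10L, n_traits = 5L, ...) {
  out <- list()
  for (P in P_values) {
    for (S in S_values) {
      out[[length(out) + 1L]] <- sim_config(
        n_traits = n_traits, generations = generations, runs = runs,
        evolve_S = FALSE, evolve_P = FALSE, fixed_S = S, fixed_P = P,
        evolve_alpha = TRUE, init_alpha = 0, ...)
    }
  }
  out
}

#' Preset scenario: trait-count sweep from a fully prejudicial start
#'
#' How much does sub-population diversity help reverse entrenched
#' prejudice? Every agent starts fully prejudicial (`alpha = 1`), with
#' high out-group mixing (`S = 0.1`) and evenly split learning
#' (`P = 0.5`); the number of equal sub-populations is varied.
#'
#' @param trait_counts integer vector of sub-population counts (each must
#'   divide the population size).
#' @param generations,runs,... overrides passed to [sim_config()].
#' @return a list of `sim_config`, one per trait count.
#' @export
scenario_trait_sweep <- function(trait_counts, generations = 50000L,
                                 runs = 10L, ...) {
  lapply(trait_counts, function(k) {
    sim_config(n_traits = k, generations = generations, runs = runs,
               evolve_S = FALSE, evolve_P = FALSE,
               fixed_S = 0.1, fixed_P = 0.5,
               evolve_alpha = TRUE, init_alpha = 1, ...)
  })
}

#' Preset scenario: balanced vs imbalanced sub-populations
#'
#' Two traits with `S = P = 0.5` fixed and prejudice starting at zero,
#' once with a 50/50 split and once with a 90/10 split, to test whether
#' prejudice emerges more easily in the presence of a small minority
#' sub-population.
#'
#' @param generations,runs,... overrides passed to [sim_config()].
#' @return a named list of two `sim_config`s, `balanced` and `imbalanced`.
#' @export
scenario_imbalance <- function(generations = 50000L, runs = 10L, ...) {
  mk <- function(sizes) {
    sim_config(n_agents = sum(sizes), trait_sizes = sizes,
               generations = generations, runs = runs,
               evolve_S = FALSE, evolve_P = FALSE,
               fixed_S = 0.5, fixed_P = 0.5,
               evolve_alpha = TRUE, init_alpha = 0, ...)
  }
  list(balanced = mk(c(50L, 50L)), imbalanced = mk(c(90L, 10L)))
}

#' Run a set of configurations with replicate runs
#'
#' Executes `runs` independently seeded replicates of each configuration.
#' Child seeds are derived deterministically from the master seed and the
#' (configuration, run) indices, so adding configurations or runs never
#' perturbs existing ones, and the same master seed always reproduces
#' every output exactly.
#'
#' @param configs a single `sim_config` or a list of them.
#' @param runs number of replicates per configuration (default: each
#'   config's own `runs` field).
#' @param master_seed integer master seed.
#' @param out_dir if non-`NULL`, results are written there via
#'   [write_results()].
#' @param engine `"cpp"` (default) or `"r"` (reference engine; small runs
#'   only).
#' @return an `experiment_store`: a list with `master_seed` and `results`,
#'   one entry per configuration holding `config`, `seeds`, `runs` (list
#'   of per-generation metric tables) and `aggregate`
#'   (see [aggregate_runs()]).
#' @export
run_experiment <- function(configs, runs = NULL, master_seed = 1L,
                           out_dir = NULL, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (inherits(configs, "sim_config")) configs <- list(configs)
  results <- vector("list", length(configs))
  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    nr <- if (is.null(runs)) cfg$runs else as.integer(runs)
    seeds <- vapply(seq_len(nr), function(ri) child_seed(master_seed, ci, ri),
                    integer(1))
    run_metrics <- vector("list", nr)
    for (ri in seq_len(nr)) {
      sim <- if (engine == "cpp") simulate_run(cfg, seeds[ri])
             else simulate_run_r(cfg, seeds[ri], log_events = FALSE)
      run_metrics[[ri]] <- sim$metrics
    }
    results[[ci]] <- list(config = cfg, seeds = seeds, runs = run_metrics,
                          aggregate = aggregate_runs(run_metrics))
  }
  store <- structure(list(master_seed = as.integer(master_seed),
                          results = results),
                     class = "experiment_store")
  if (!is.null(out_dir)) write_results(store, out_dir)
  store
}

#' Grid summary of a fixed-(S, P) experiment
#'
#' Collapses an experiment over [scenario_grid()] configurations into one
#' row per (S, P) cell: across-run means (and standard deviations) of the
#' tail-window cooperation rate and mean prejudice.
#'
#' @param store an `experiment_store` whose configs all have fixed S and P.
#' @param frac tail fraction passed to [summarize_tail()].
#' @return a data frame with columns `S`, `P`, `coop_rate`,
#'   `coop_rate_sd`, `mean_alpha`, `mean_alpha_sd`.
#' @export
grid_summary <- function(store, frac = 0.1) {
  rows <- lapply(store$results, function(res) {
    if (res$config$evolve_S || res$config$evolve_P) {
      stop("grid_summary needs configurations with fixed S and P",
           call. = FALSE)
    }
    tails <- vapply(res$runs, function(m) {
      summarize_tail(m, frac)[c("coop_rate", "mean_alpha")]
    }, numeric(2))
    sd_or_0 <- function(x) if (length(x) > 1) sd(x) else 0
    data.frame(S = res$config$fixed_S, P = res$config$fixed_P,
               coop_rate = mean(tails["coop_rate", ]),
               coop_rate_sd = sd_or_0(tails["coop_rate", ]),
               mean_alpha = mean(tails["mean_alpha", ]),
               mean_alpha_sd = sd_or_0(tails["mean_alpha", ]))
  })
  do.call(rbind, rows)
}

#' Write an experiment store to disk
#'
#' One sub-directory per configuration (`cfg<i>_<hash>`) containing a
#' per-run metrics CSV (`run<j>.csv`), the across-run aggregate
#' (`aggregate.csv`) and a JSON summary (`summary.json`) with the config
#' echo, its hash, the seed tree and the tail-window means of each run.
#' All outputs are deterministic: stable key order, UTF-8, `.` decimal.
#'
#' @param store an `experiment_store` from [run_experiment()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(store, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (ci in seq_along(store$results)) {
    res <- store$results[[ci]]
    hash <- config_hash(res$config)
    sub <- file.path(out_dir, sprintf("cfg%d_%s", ci, hash))
    dir.create(sub, showWarnings = FALSE)
    for (ri in seq_along(res$runs)) {
      write.csv(res$runs[[ri]], file.path(sub, sprintf("run%d.csv", ri)),
                row.names = FALSE)
    }
    write.csv(res$aggregate, file.path(sub, "aggregate.csv"),
              row.names = FALSE)
    cfg <- unclass(res$config)
    cfg <- cfg[!vapply(cfg, is.null, logical(1))]
    summary <- list(
      config = cfg,
      config_hash = hash,
      master_seed = store$master_seed,
      seeds = res$seeds,
      tail_means = lapply(res$runs, function(m) as.list(summarize_tail(m)))
    )
    jsonlite::write_json(summary, file.path(sub, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out_dir)
}
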