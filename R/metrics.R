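#' Per-generation metrics
#'
#' Computes the aggregate quantities reported per generation from the
#' population state and the generation's event log: cooperation rate
#' (donations over non-null events; null events — singleton in-group draws
#' or an empty out-group — are excluded from the denominator and counted
#' separately), prejudice distribution, dominant-heuristic frequencies, the
#' share of out-group events that were prejudice-driven defections (the
#' donor defected but would have donated with prejudice forced to zero),
#' and per-trait prejudice distributions.
#'
#' @param pop the population as it played the generation.
#' @param events the event log from [run_generation()].
#' @param gen generation index to record.
#' @return a one-row data frame; columns match [simulate_run()] metrics.
#' @export
summarize_generation <- function(pop, events, gen = NA_integer_) {
  n <- nrow(pop)
  n_traits <- max(pop$trait)
  n_games <- nrow(events)
  n_null <- sum(events$scope == "none")
  n_don <- sum(events$donated)
  nn <- n_games - n_null
  is_out <- events$scope == "out-group"
  n_out <- sum(is_out)
  n_outdef <- sum(is_out & !events$donated)
  n_pd <- sum(is_out & !events$donated & events$counterfactual)
  lvl <- alpha_level(pop$alpha)
  adist <- tabulate(lvl + 1L, nbins = 5L) / n
  sb <- pmin(as.integer(pop$S * 10 + 0.5), 9L)
  pb <- pmin(as.integer(pop$P * 10 + 0.5), 9L)
  out <- data.frame(
    gen = gen, n_games = n_games, n_null = n_null, n_donated = n_don,
    coop_rate = if (nn > 0) n_don / nn else NA_real_,
    coop_rate_raw = if (n_games > 0) n_don / n_games else NA_real_,
    n_ingroup = sum(events$scope == "in-group"),
    n_outgroup = n_out, n_outgroup_def = n_outdef, n_prej_def = n_pd,
    prej_def_share = if (n_out > 0) n_pd / n_out else 0,
    mean_alpha = mean(pop$alpha)
  )
  out[paste0("alpha_", c(0, 25, 50, 75, 100))] <- as.list(adist)
  out$share_high_alpha <- sum(adist[4:5])
  out$freq_110 <- mean(pop$s == 1 & pop$u == 1 & pop$d == 0)
  out$freq_000 <- mean(pop$s == 0 & pop$u == 0 & pop$d == 0)
  out$mean_S <- mean(pop$S)
  out$mean_P <- mean(pop$P)
  out$total_payoff <- sum(pop$payoff)
  out$max_rep_gap <- max(abs(pop$rep_g - pop$rep_u))
  out$n_reproduced <- NA_real_
  out[paste0("S_", 0:9)] <- as.list(tabulate(sb + 1L, nbins = 10L) / n)
  out[paste0("P_", 0:9)] <- as.list(tabulate(pb + 1L, nbins = 10L) / n)
  for (t in seq_len(n_traits)) {
    sel <- pop$trait == t
    out[[paste0("trait", t, "_mean_alpha")]] <-
      if (any(sel)) mean(pop$alpha[sel]) else NA_real_
  }
  for (t in seq_len(n_traits)) {
    sel <- pop$trait == t
    td <- if (any(sel)) tabulate(lvl[sel] + 1L, nbins = 5L) / sum(sel)
          else rep(NA_real_, 5)
    out[paste0("trait", t, "_alpha_", c(0, 25, 50, 75, 100))] <- as.list(td)
  }
  out
}

#' Aggregate metrics across replicate runs
#'
#' Computes the across-run mean and standard deviation of every metric at
#' matching generations. All runs must come from the same configuration
#' (identical recorded generations and columns).
#'
#' @param runs a list of per-generation metric data frames, one per run.
#' @return a data frame with `gen` plus `<metric>_mean` and `<metric>_sd`
#'   columns.
#' @export
aggregate_runs <- function(runs) {
  if (length(runs) < 1) stop("need at least one run", call. = FALSE)
  ref <- runs[[1]]
  for (r in runs[-1]) {
    if (!identical(dim(r), dim(ref)) || !identical(names(r), names(ref)) ||
        !identical(r$gen, ref$gen)) {
      stop("runs have mismatched configurations (generations or columns differ)",
           call. = FALSE)
    }
  }
  cols <- setdiff(names(ref), "gen")
  arr <- vapply(runs, function(r) as.matrix(r[cols]),
                matrix(0, nrow(ref), length(cols)))
  dim(arr) <- c(nrow(ref), length(cols), length(runs))
  mean_m <- apply(arr, c(1, 2), mean)
  sd_m <- if (length(runs) > 1) apply(arr, c(1, 2), sd) else mean_m * 0
  out <- data.frame(gen = ref$gen)
  out[paste0(cols, "_mean")] <- as.data.frame(mean_m)
  out[paste0(cols, "_sd")] <- as.data.frame(sd_m)
  out
}

#' Tail-window summary of a metrics table
#'
#' Means of every metric over the final fraction of recorded generations —
#' the default end-of-run summary used when comparing long runs (the last
#' 10% of generations).
#'
#' @param metrics a per-generation metrics data frame.
#' @param frac fraction of recorded generations to average over.
#' @return a named numeric vector of column means.
#' @export
summarize_tail <- function(metrics, frac = 0.1) {
  k <- max(1L, ceiling(frac * nrow(metrics)))
  tail_rows <- metrics[(nrow(metrics) - k + 1L):nrow(metrics), , drop = FALSE]
  colMeans(as.matrix(tail_rows), na.rm = TRUE)
}

#' First generation of sustained prejudice emergence
#'
#' Finds the first recorded generation at which the given metric exceeds a
#' threshold and keeps exceeding it for a full window of generations
#' (default: the share of agents with `alpha >= 0.75` above 10% sustained
#' for 500 generations).
#'
#' @param metrics a per-generation metrics data frame (recorded every
#'   generation, or uniformly thinned).
#' @param threshold value the metric must exceed.
#' @param window number of generations the exceedance must be sustained.
#' @param col metric column to test.
#' @return the generation index, or `NA` if never sustained within the run.
#' @export
first_emergence_generation <- function(metrics, threshold = 0.10,
                                       window = 500L,
                                       col = "share_high_alpha") {
  x <- metrics[[col]] > threshold
  g <- metrics$gen
  step <- if (length(g) > 1) g[2] - g[1] else 1
  need <- max(1L, ceiling(window / step))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= need)
  if (!length(hit)) return(NA_real_)
  g[starts[hit[1]]]
}
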