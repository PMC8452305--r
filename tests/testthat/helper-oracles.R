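# Independent oracles and shared fixtures.
# Oracles deliberately use the dumbest correct formulation (O(n^2) loops,
# closed forms) so they stay independent of the implementation under test.

# Brute-force autocorrelogram: enumerate every ordered pair.
brute_force_acg <- function(times, bin_width_s = 0.005, max_lag_s = 1.0) {
  n_bins <- round(max_lag_s / bin_width_s)
  counts <- integer(n_bins)
  n <- length(times)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      lag <- times[j] - times[i]
      if (lag > max_lag_s) break
      b <- ceiling(lag / bin_width_s)
      if (b >= 1 && b <= n_bins) counts[b] <- counts[b] + 1L
    }
  }
  counts
}

# Brute-force complex-spike-train enumeration: scan all runs directly.
brute_force_cs_trains <- function(complex_times, max_gap_s) {
  runs <- list()
  cur <- c(complex_times[1])
  for (t in complex_times[-1]) {
    if (t - cur[length(cur)] <= max_gap_s) cur <- c(cur, t)
    else { runs[[length(runs) + 1]] <- cur; cur <- c(t) }
  }
  runs[[length(runs) + 1]] <- cur
  runs[lengths(runs) >= 3]
}

quick_series <- function(times, duration = NULL, amps = 1, spikelets = 0L) {
  spike_series(times, recording_duration_s = duration %||% (max(times) + 0.01),
               amplitudes = amps, spikelet_counts = spikelets)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shared cohort fixtures: generated once per test run and cached, since
# several test files (population, acceptance) need the same stated-world
# cohorts.
.cohort_cache <- new.env(parent = emptyenv())

cohort_features <- function(preset, n_cells, seed, group_label = preset) {
  key <- paste(preset, n_cells, seed, group_label, sep = "|")
  if (!is.null(.cohort_cache[[key]])) return(.cohort_cache[[key]])
  cells <- generate_cohort(preset, n_cells, seed = seed,
                           group_label = group_label)
  ft <- do.call(rbind, lapply(cells, function(s)
    extract_features(s, classify_events(s))))
  .cohort_cache[[key]] <- ft
  ft
}
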