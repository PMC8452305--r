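## The six per-cell simple-spike firing statistics:
## frequency, frequency mode, CV, CV2, pause percentage, rhythmicity index
## (the last lives in autocorrelogram.R).

#' Mean firing frequency
#'
#' Number of spikes divided by the total analyzed recording time.
#'
#' @param n_spikes Spike count.
#' @param recording_duration_s Analyzed recording time in seconds (> 0).
#' @return Frequency in Hz.
#' @export
compute_frequency <- function(n_spikes, recording_duration_s) {
  if (recording_duration_s <= 0)
    stop_validation("recording_duration_s must be > 0")
  n_spikes / recording_duration_s
}

#' Frequency mode (preferred instantaneous frequency)
#'
#' The inverse of every interspike interval is an instantaneous frequency;
#' these are histogrammed into half-open bins `[k*w, (k+1)*w)` Hz anchored
#' at 0 (default width 2.5 Hz) and the center of the fullest bin is
#' returned. Ties are broken toward the lowest-frequency bin.
#'
#' @param isis An `isi_seq` (or numeric vector of ISIs in seconds).
#' @param bin_width_hz Histogram bin width in Hz (default 2.5).
#' @return The mode bin center in Hz.
#' @export
#' @examples
#' compute_frequency_mode(compute_isis(seq(0, 1, by = 0.01)))  # 101.25
compute_frequency_mode <- function(isis, bin_width_hz = 2.5) {
  v <- isi_values(isis)
  if (!length(v)) stop_insufficient("at least one ISI is required")
  f <- 1 / v
  bins <- floor(f / bin_width_hz)
  counts <- table(bins)
  # table() orders numerically-named bins by value, so which.max takes the
  # lowest-frequency bin on ties
  ord <- order(as.numeric(names(counts)))
  counts <- counts[ord]
  k <- as.numeric(names(counts))[which.max(counts)]
  (k + 0.5) * bin_width_hz
}

#' Coefficient of variation of the interspike intervals
#'
#' `CV = sd(ISI) / mean(ISI)`, a global irregularity/burstiness measure.
#' The population (divide-by-N) standard deviation is used; the difference
#' from the sample convention is O(1/N).
#'
#' @param isis An `isi_seq` (or numeric vector of ISIs).
#' @return CV, dimensionless and non-negative.
#' @export
compute_cv <- function(isis) {
  v <- isi_values(isis)
  if (length(v) < 2L)
    stop_insufficient("at least 2 ISIs are required for CV")
  sqrt(mean((v - mean(v))^2)) / mean(v)
}

#' Local interspike-interval irregularity (CV2)
#'
#' `CV2 = mean(2 * |ISI_n - ISI_{n-1}| / (ISI_n + ISI_{n-1}))` over
#' adjacent interval pairs. Bounded in `[0, 2]`; insensitive to slow rate
#' drift, unlike CV.
#'
#' @param isis An `isi_seq` (or numeric vector of ISIs).
#' @return CV2, dimensionless.
#' @export
compute_cv2 <- function(isis) {
  v <- isi_values(isis)
  if (length(v) < 2L)
    stop_insufficient("at least 2 ISIs are required for CV2")
  a <- v[-1L]; b <- v[-length(v)]
  mean(2 * abs(a - b) / (a + b))
}

#' Pause percentage
#'
#' The fraction of the analyzed recording time spent in interspike
#' intervals strictly exceeding `threshold_multiple` times the mean ISI
#' of the cell (default 5x).
#'
#' @param isis An `isi_seq` (or numeric vector of ISIs).
#' @param recording_duration_s Analyzed recording time in seconds (> 0).
#' @param threshold_multiple Pause threshold as a multiple of the mean ISI
#'   (default 5).
#' @return Fraction of recording time in `[0, 1]`.
#' @export
compute_pause_percent <- function(isis, recording_duration_s,
                                  threshold_multiple = 5) {
  v <- isi_values(isis)
  if (length(v) < 2L)
    stop_insufficient("at least 2 ISIs are required for the pause percentage")
  if (recording_duration_s <= 0)
    stop_validation("recording_duration_s must be > 0")
  thr <- threshold_multiple * mean(v)
  sum(v[v > thr]) / recording_duration_s
}

isi_values <- function(isis) {
  if (inherits(isis, "isi_seq")) return(isis$isis_s)
  as.numeric(isis)
}

#' Extract the per-cell firing feature vector
#'
#' Computes the six simple-spike statistics on the simple-spike-only time
#' sequence (complex spikes, doublet primaries and doublet secondaries are
#' all removed; the interval between the simple spikes flanking a removed
#' event is retained as a single ISI, preserving total-time conservation),
#' then appends the complex-spike, doublet and combined frequencies from
#' the classification.
#'
#' @param series A validated [spike_series()].
#' @param classified The matching [classify_events()] result; computed
#'   with default parameters if `NULL`.
#' @param min_simple_spikes Minimum number of simple spikes required
#'   (default 10); fewer raises an insufficient-data error so the caller
#'   can flag (not silently drop) the cell.
#' @param frequency_mode_bin_hz Bin width for the frequency mode (2.5 Hz).
#' @param pause_threshold_multiple Pause threshold multiple (5).
#' @param acg_bin_width_s,acg_max_lag_s Autocorrelogram bin width (5 ms)
#'   and maximum lag (1 s).
#' @param ri_rule Peak/trough acceptance rule for the rhythmicity index;
#'   see [compute_rhythmicity_index()].
#' @return A one-row data.frame (class `firing_features`) with columns
#'   `cell_id`, `group_label`, `frequency_hz`, `frequency_mode_hz`, `cv`,
#'   `cv2`, `pause_percent`, `rhythmicity_index`, `cs_frequency_hz`,
#'   `doublet_frequency_hz`, `combined_cs_frequency_hz`,
#'   `heterogeneous_cs`.
#' @export
extract_features <- function(series, classified = NULL,
                             min_simple_spikes = 10L,
                             frequency_mode_bin_hz = 2.5,
                             pause_threshold_multiple = 5,
                             acg_bin_width_s = 0.005,
                             acg_max_lag_s = 1.0,
                             ri_rule = c("deviation", "sum")) {
  ri_rule <- match.arg(ri_rule)
  if (is.null(classified)) classified <- classify_events(series)
  st <- series$times[classified$labels == "simple"]
  if (length(st) < min_simple_spikes)
    stop_insufficient(sprintf(
      "cell %s: %d simple spikes < required minimum %d",
      series$cell_id, length(st), min_simple_spikes))
  T <- series$recording_duration_s
  isis <- compute_isis(st)
  acg <- compute_autocorrelogram(st, bin_width_s = acg_bin_width_s,
                                 max_lag_s = acg_max_lag_s,
                                 recording_duration_s = T)
  ri <- compute_rhythmicity_index(acg, isis$mean_isi_s, rule = ri_rule)
  cls <- event_class_frequencies(classified, T)
  out <- data.frame(
    cell_id = series$cell_id,
    group_label = series$group_label,
    frequency_hz = compute_frequency(length(st), T),
    frequency_mode_hz = compute_frequency_mode(isis, frequency_mode_bin_hz),
    cv = compute_cv(isis),
    cv2 = compute_cv2(isis),
    pause_percent = compute_pause_percent(isis, T, pause_threshold_multiple),
    rhythmicity_index = ri$rhythmicity_index,
    cs_frequency_hz = unname(cls["cs_frequency_hz"]),
    doublet_frequency_hz = unname(cls["doublet_frequency_hz"]),
    combined_cs_frequency_hz = unname(cls["combined_cs_frequency_hz"]),
    heterogeneous_cs = classified$heterogeneous,
    stringsAsFactors = FALSE)
  class(out) <- c("firing_features", class(out))
  out
}
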