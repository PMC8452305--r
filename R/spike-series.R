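#' Construct a per-cell spike event series
#'
#' The basic container for one extracellular recording: ordered event times
#' with per-event peak amplitude and spikelet count, plus the recording
#' metadata needed downstream (analyzed duration, group label, genotype).
#'
#' Times are kept in seconds. Two events closer than the time resolution
#' (1 microsecond) are treated as duplicates and rejected: the acquisition
#' chain cannot distinguish them and downstream interspike intervals would
#' be zero or negative.
#'
#' @param times Numeric vector of event times in seconds, strictly
#'   increasing, all within `[0, recording_duration_s]`.
#' @param recording_duration_s Total analyzed recording time in seconds.
#'   This is authoritative metadata: it is the denominator of every
#'   frequency and of the pause percentage. If `NA`, the spike span
#'   `max(times) - min(times)` is used as a fallback with a warning.
#' @param amplitudes Per-event peak amplitude in arbitrary units (> 0).
#'   Recycled if length 1.
#' @param spikelet_counts Per-event count of trailing spikelets (non-negative
#'   integers); the feature that identifies classical complex spikes.
#'   Recycled if length 1.
#' @param cell_id Identifier for the cell.
#' @param group_label Age-by-genotype group, e.g. `"control_P7-8"`.
#' @param genotype Genotype string.
#' @return An object of class `spike_series`.
#' @export
#' @examples
#' s <- spike_series(c(0.01, 0.02, 0.03), recording_duration_s = 1)
#' n_events(s)
spike_series <- function(times, recording_duration_s,
                         amplitudes = 1, spikelet_counts = 0L,
                         cell_id = "cell", group_label = "unknown",
                         genotype = "unknown") {
  times <- as.numeric(times)
  n <- length(times)
  amplitudes <- rep_len(as.numeric(amplitudes), n)
  spikelet_counts <- rep_len(as.integer(spikelet_counts), n)
  if (is.null(recording_duration_s) || is.na(recording_duration_s)) {
    if (n < 2L) stop_validation("recording duration missing and cannot be inferred from < 2 events")
    recording_duration_s <- max(times) - min(times)
    times <- times - min(times)  # rebase so the span covers the recording
    warning("recording_duration_s missing; falling back to the spike span (",
            format(recording_duration_s), " s), times rebased to 0")
  }
  recording_duration_s <- as.numeric(recording_duration_s)
  obj <- structure(
    list(times = times, amplitudes = amplitudes,
         spikelet_counts = spikelet_counts,
         recording_duration_s = recording_duration_s,
         cell_id = as.character(cell_id),
         group_label = as.character(group_label),
         genotype = as.character(genotype)),
    class = "spike_series")
  validate_spike_series(obj)
}

#' Validate a spike_series
#'
#' Enforces the container invariants: strictly increasing times (duplicates
#' at 1 microsecond resolution rejected), all times within the recording,
#' positive duration and amplitudes, non-negative spikelet counts.
#'
#' @param x A `spike_series`.
#' @return `x`, invisibly unchanged, if valid; otherwise a validation error.
#' @export
validate_spike_series <- function(x) {
  t <- x$times
  if (anyNA(t) || anyNA(x$amplitudes) || anyNA(x$spikelet_counts))
    stop_validation("spike series contains missing values")
  if (!is.numeric(x$recording_duration_s) || length(x$recording_duration_s) != 1L ||
      x$recording_duration_s <= 0)
    stop_validation("recording_duration_s must be a single positive number")
  if (length(t)) {
    if (is.unsorted(t, strictly = FALSE))
      stop_validation("event times must be non-decreasing; input is unordered")
    d <- diff(t)
    if (length(d) && any(d < 1e-6))
      stop_validation("event times must be strictly increasing; duplicate or near-duplicate times (< 1 us apart) found")
    if (t[1L] < 0 || t[length(t)] > x$recording_duration_s + 1e-9)
      stop_validation("event times must lie within [0, recording_duration_s]")
    if (any(x$amplitudes <= 0))
      stop_validation("amplitudes must be > 0")
    if (any(x$spikelet_counts < 0L))
      stop_validation("spikelet counts must be non-negative")
  }
  x
}

#' @export
print.spike_series <- function(x, ...) {
  cat("<spike_series> cell", x$cell_id, "\n")
  cat("  events:", length(x$times), "over", format(x$recording_duration_s), "s",
      sprintf("(%.2f events/s)", length(x$times) / x$recording_duration_s), "\n")
  cat("  group:", x$group_label, " genotype:", x$genotype, "\n")
  invisible(x)
}

#' Number of events in a spike series
#' @param x A `spike_series`.
#' @return Integer event count.
#' @export
n_events <- function(x) length(x$times)

#' Interspike intervals of an ordered spike-time sequence
#'
#' Successive differences of adjacent spike times, the basis of CV, CV2,
#' pause percentage and the frequency mode.
#'
#' @param times Numeric vector of strictly increasing spike times in
#'   seconds, or a `spike_series`.
#' @return An object of class `isi_seq` with fields `isis_s`, `mean_isi_s`
#'   and `n_spikes`.
#' @export
#' @examples
#' compute_isis(c(0, 0.01, 0.03))
compute_isis <- function(times) {
  if (inherits(times, "spike_series")) times <- times$times
  times <- as.numeric(times)
  if (length(times) < 2L)
    stop_insufficient("at least 2 spike times are required to form interspike intervals")
  if (is.unsorted(times, strictly = TRUE))
    stop_validation("spike times must be strictly increasing")
  isis <- diff(times)
  structure(list(isis_s = isis, mean_isi_s = mean(isis),
                 n_spikes = length(times)),
            class = "isi_seq")
}

#' @export
print.isi_seq <- function(x, ...) {
  cat("<isi_seq>", length(x$isis_s), "intervals, mean",
      sprintf("%.4f s (%.2f Hz)", x$mean_isi_s, 1 / x$mean_isi_s), "\n")
  invisible(x)
}

#' Recording-duration inclusion filter
#'
#' Cells are only analyzed when the stable recording is long enough for the
#' firing statistics to be meaningful; the default minimum is 75 s,
#' inclusive.
#'
#' @param series A `spike_series`.
#' @param min_duration_s Minimum analyzed duration in seconds (default 75).
#' @param quiet Suppress the decision message.
#' @return `TRUE` (accept) or `FALSE` (reject), with a `"reason"` attribute
#'   describing the decision.
#' @export
filter_by_duration <- function(series, min_duration_s = 75, quiet = TRUE) {
  d <- series$recording_duration_s
  ok <- d >= min_duration_s
  reason <- sprintf("cell %s: duration %.3f s %s minimum %.3f s -> %s",
                    series$cell_id, d, if (ok) ">=" else "<", min_duration_s,
                    if (ok) "accept" else "reject")
  if (!quiet) message(reason)
  structure(ok, reason = reason)
}
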