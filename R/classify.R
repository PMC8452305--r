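#' Classifier parameters for spike-type sorting
#'
#' Defaults encode the operational definitions of the three Purkinje-cell
#' spike types during the second postnatal week:
#' a classical complex spike carries a train of (typically three to five)
#' trailing spikelets; a doublet is an action potential followed within
#' 20 ms by one or more smaller action potentials; everything else is a
#' simple spike. A complex-spike train is three or more complex spikes in
#' close succession (the succession gap is not quantified in the
#' literature; 100 ms is this package's configurable default).
#'
#' @param doublet_window_s Window after a candidate primary within which a
#'   smaller event marks a doublet (default 0.020 s, inclusive).
#' @param doublet_ratio Maximum secondary/primary amplitude ratio for
#'   "smaller" (default 0.9, strict; exact equality is "not smaller").
#' @param cs_min_spikelets Minimum spikelet count marking a classical
#'   complex spike (default 3).
#' @param cs_train_max_gap_s Maximum gap between consecutive complex
#'   spikes inside a complex-spike train (default 0.100 s, inclusive).
#' @return An object of class `classifier_params`.
#' @export
classifier_params <- function(doublet_window_s = 0.020, doublet_ratio = 0.9,
                              cs_min_spikelets = 3L, cs_train_max_gap_s = 0.100) {
  if (doublet_window_s <= 0 || doublet_ratio <= 0 || cs_train_max_gap_s <= 0 ||
      cs_min_spikelets < 1)
    stop_validation("classifier parameters must be positive")
  structure(list(doublet_window_s = doublet_window_s,
                 doublet_ratio = doublet_ratio,
                 cs_min_spikelets = as.integer(cs_min_spikelets),
                 cs_train_max_gap_s = cs_train_max_gap_s),
            class = "classifier_params")
}

SPIKE_LABELS <- c("simple", "complex", "doublet_primary", "doublet_secondary")

#' Classify events into simple spikes, complex spikes and doublets
#'
#' Rules are applied with precedence complex > doublet > simple (a complex
#' spike also satisfies the doublet window pattern, so it is claimed
#' first):
#' 1. an event with `spikelet_count >= cs_min_spikelets` is `complex`;
#' 2. scanning in time order, an unlabeled event followed within
#'    `doublet_window_s` by one or more unlabeled events of strictly
#'    smaller amplitude (ratio < `doublet_ratio`) becomes
#'    `doublet_primary` and those followers `doublet_secondary`;
#' 3. all remaining events are `simple`.
#'
#' @param series A validated [spike_series()].
#' @param params A [classifier_params()].
#' @return An object of class `classified_events` with per-event `labels`,
#'   the event `times`, detected `cs_trains` (see [detect_cs_trains()]),
#'   a `heterogeneous` flag (the cell fires both complex spikes and
#'   doublets), and the parameters used.
#' @export
classify_events <- function(series, params = classifier_params()) {
  validate_spike_series(series)
  n <- length(series$times)
  if (n == 0L) stop_insufficient("cannot classify an empty event list")
  t <- series$times
  amp <- series$amplitudes
  labels <- rep(NA_character_, n)
  labels[series$spikelet_counts >= params$cs_min_spikelets] <- "complex"
  # window comparisons carry a 1 ns guard: times are stored at 1 us
  # resolution, so representation error far below that must not flip an
  # inclusive boundary
  eps <- 1e-9
  for (i in seq_len(n)) {
    if (!is.na(labels[i])) next
    j <- i + 1L
    followers <- integer(0)
    while (j <= n && t[j] - t[i] <= params$doublet_window_s + eps) {
      if (is.na(labels[j]) && amp[j] / amp[i] < params$doublet_ratio)
        followers <- c(followers, j)
      j <- j + 1L
    }
    if (length(followers)) {
      labels[i] <- "doublet_primary"
      labels[followers] <- "doublet_secondary"
    }
  }
  labels[is.na(labels)] <- "simple"
  out <- structure(list(labels = labels, times = t,
                        cs_trains = NULL,
                        heterogeneous = any(labels == "complex") &&
                                        any(labels == "doublet_primary"),
                        params = params),
                   class = "classified_events")
  out$cs_trains <- detect_cs_trains(out, max_gap_s = params$cs_train_max_gap_s)
  out
}

#' @export
print.classified_events <- function(x, ...) {
  tb <- table(factor(x$labels, levels = SPIKE_LABELS))
  cat("<classified_events>", length(x$labels), "events:",
      paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  cat("  complex-spike trains:", nrow(x$cs_trains),
      " heterogeneous:", x$heterogeneous, "\n")
  invisible(x)
}

#' Detect complex-spike trains
#'
#' A complex-spike train is a maximal run of three or more consecutive
#' complex-spike events whose successive gaps are all at most `max_gap_s`.
#'
#' @param classified A `classified_events` object (or a character label
#'   vector, in which case `times` must be supplied).
#' @param max_gap_s Maximum gap between consecutive complex spikes
#'   (default 0.100 s).
#' @param times Event times; only needed when `classified` is a bare
#'   label vector.
#' @return A data.frame with columns `start_s`, `end_s`,
#'   `n_complex_spikes` (one row per train; zero rows if none).
#' @export
detect_cs_trains <- function(classified, max_gap_s = 0.100, times = NULL) {
  if (inherits(classified, "classified_events")) {
    labels <- classified$labels
    times <- classified$times
  } else {
    labels <- classified
    if (is.null(times)) stop_validation("times must be supplied with a label vector")
  }
  ct <- times[labels == "complex"]
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_complex_spikes = integer(0))
  if (length(ct) < 3L) return(empty)
  breaks <- which(diff(ct) > max_gap_s + 1e-9)
  run_start <- c(1L, breaks + 1L)
  run_end <- c(breaks, length(ct))
  keep <- (run_end - run_start + 1L) >= 3L
  if (!any(keep)) return(empty)
  data.frame(start_s = ct[run_start[keep]], end_s = ct[run_end[keep]],
             n_complex_spikes = as.integer(run_end[keep] - run_start[keep] + 1L))
}

#' Per-class event frequencies
#'
#' Counts of complex spikes and doublets (each doublet counted once, by
#' its primary) divided by the analyzed recording time.
#'
#' @param classified A `classified_events` object.
#' @param recording_duration_s Analyzed recording time in seconds (> 0).
#' @return Named numeric vector: `cs_frequency_hz`, `doublet_frequency_hz`,
#'   `combined_cs_frequency_hz` (their sum).
#' @export
event_class_frequencies <- function(classified, recording_duration_s) {
  if (recording_duration_s <= 0)
    stop_validation("recording_duration_s must be > 0")
  n_cs <- sum(classified$labels == "complex")
  n_db <- sum(classified$labels == "doublet_primary")
  c(cs_frequency_hz = n_cs / recording_duration_s,
    doublet_frequency_hz = n_db / recording_duration_s,
    combined_cs_frequency_hz = (n_cs + n_db) / recording_duration_s)
}
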