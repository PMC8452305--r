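#' Binned spike-time autocorrelogram
#'
#' Histogram of all ordered spike-pair lags `t_j - t_i` (i < j) up to
#' `max_lag_s`, in bins `(b*delta, (b+1)*delta]`. The expected per-bin
#' pair count for a memoryless train of the same rate is
#' `baseline = N^2 / (T / delta)`, and the noise floor is estimated as the
#' standard deviation of the counts over the tail lags
#' `(max_lag_s - tail_window_s, max_lag_s]` (the last 8 bins at the 5 ms
#' default), where the autocorrelation of a cell whose rhythmicity has
#' damped out is flat.
#'
#' Pairs are accumulated by lag order rather than by O(n^2) enumeration,
#' but the result is exactly the brute-force pair count.
#'
#' @param times Strictly increasing spike times in seconds (at least 2),
#'   or a `spike_series` (all events are used; pass simple-spike times
#'   explicitly for simple-spike analyses).
#' @param bin_width_s Bin width in seconds (default 0.005).
#' @param max_lag_s Maximum lag in seconds (default 1.0).
#' @param recording_duration_s Analyzed recording time `T` for the
#'   baseline; defaults to the spike span if omitted.
#' @param tail_window_s Width of the tail window used for the noise SD
#'   (default 0.04 s, i.e. lags in (0.96, 1] at the default maximum lag).
#' @return An object of class `autocorrelogram`: `counts` (integer per
#'   bin), `lag_centers_s`, `bin_width_s`, `max_lag_s`, `baseline`,
#'   `tail_sd`, `n_spikes`, `recording_duration_s`.
#' @export
compute_autocorrelogram <- function(times, bin_width_s = 0.005,
                                    max_lag_s = 1.0,
                                    recording_duration_s = NULL,
                                    tail_window_s = 0.04) {
  if (inherits(times, "spike_series")) {
    if (is.null(recording_duration_s))
      recording_duration_s <- times$recording_duration_s
    times <- times$times
  }
  times <- as.numeric(times)
  n <- length(times)
  if (n < 2L) stop_insufficient("at least 2 spikes are required for an autocorrelogram")
  if (is.unsorted(times, strictly = TRUE))
    stop_validation("spike times must be strictly increasing")
  if (is.null(recording_duration_s))
    recording_duration_s <- times[n] - times[1L]
  n_bins <- as.integer(round(max_lag_s / bin_width_s))
  counts <- integer(n_bins)
  k <- 1L
  repeat {
    if (k >= n) break
    lags <- times[(k + 1L):n] - times[1L:(n - k)]
    lags <- lags[lags <= max_lag_s]
    if (!length(lags)) break
    idx <- ceiling(lags / bin_width_s)
    idx[idx < 1L] <- 1L  # a lag of exactly 0 cannot occur (strict ordering)
    counts <- counts + tabulate(idx, nbins = n_bins)
    k <- k + 1L
  }
  centers <- (seq_len(n_bins) - 0.5) * bin_width_s
  tail_bins <- centers > (max_lag_s - tail_window_s) & centers <= max_lag_s
  structure(list(counts = counts, lag_centers_s = centers,
                 bin_width_s = bin_width_s, max_lag_s = max_lag_s,
                 baseline = n^2 / (recording_duration_s / bin_width_s),
                 tail_sd = stats::sd(counts[tail_bins]),
                 n_spikes = n,
                 recording_duration_s = recording_duration_s),
            class = "autocorrelogram")
}

#' @export
print.autocorrelogram <- function(x, ...) {
  cat("<autocorrelogram>", length(x$counts), "bins of",
      x$bin_width_s * 1000, "ms;", x$n_spikes, "spikes\n")
  cat(sprintf("  baseline %.2f pairs/bin, tail SD %.2f\n", x$baseline, x$tail_sd))
  invisible(x)
}

#' Autocorrelogram rhythmicity index
#'
#' Quantifies damped oscillation in the autocorrelogram by an iterative
#' peak/trough search. The first peak is the highest bin at lags between
#' 10 ms and 1.5 times the mean ISI (its lag is `a1`); the first trough is
#' the lowest bin between the first peak and `a1 + a1`. Each subsequent
#' peak is the highest bin between the previous trough and
#' `a_n + a1 + 10 ms` (`a_n` = previous peak lag), and each subsequent
#' trough the lowest bin between that peak and `peak + a1`. A window
#' includes every bin whose center lies inside it; lags of peaks and
#' troughs are bin centers.
#'
#' Each (peak, trough) pair must pass an acceptance test against the tail
#' noise floor; iteration stops at the first rejected pair, when a search
#' window is empty, or when the next window's upper edge would exceed the
#' maximum lag. The index is the sum of accepted `peak - trough` count
#' differences divided by the baseline; 0 if no pair is accepted.
#'
#' Two forms of the first acceptance clause are available. The default,
#' `"deviation"`, accepts a pair when `peak - trough > 4 * tail_sd`: the
#' oscillation excursion must exceed four times the tail noise SD, which
#' correctly rejects flat (memoryless) autocorrelograms. The `"sum"` form
#' compares `peak + trough` to the same threshold; because two raw counts
#' of order baseline are compared against a dispersion, it accepts almost
#' any sufficiently active cell regardless of rhythmicity and makes the
#' index rate-dependent, so it is provided for comparison only (see the
#' methods vignette). Under either form a pair is also accepted when the
#' peak exceeds `baseline + 2 * tail_sd` and the trough falls below
#' `baseline - 2 * tail_sd`.
#'
#' @param acg An [compute_autocorrelogram()] result.
#' @param mean_isi_s Mean interspike interval of the analyzed (simple)
#'   spikes, in seconds (> 0); sets the first-peak search window.
#' @param rule Acceptance clause 1 form: `"deviation"` (default) or
#'   `"sum"` (see Details).
#' @return A list: `rhythmicity_index` (>= 0) and `accepted_pairs`, a
#'   data.frame with `peak_lag_s`, `peak_count`, `trough_lag_s`,
#'   `trough_count` for each accepted pair.
#' @export
compute_rhythmicity_index <- function(acg, mean_isi_s,
                                      rule = c("deviation", "sum")) {
  rule <- match.arg(rule)
  if (!inherits(acg, "autocorrelogram"))
    stop_validation("acg must be an autocorrelogram")
  if (mean_isi_s <= 0) stop_validation("mean_isi_s must be > 0")
  counts <- acg$counts
  centers <- acg$lag_centers_s
  empty <- data.frame(peak_lag_s = numeric(0), peak_count = numeric(0),
                      trough_lag_s = numeric(0), trough_count = numeric(0))
  if (all(counts == 0))
    return(list(rhythmicity_index = 0, accepted_pairs = empty))
  bins_in <- function(lo, hi) which(centers > lo & centers <= hi)
  tail_sd <- acg$tail_sd
  baseline <- acg$baseline
  a1 <- NA_real_
  prev_peak <- NA_real_
  prev_trough <- NA_real_
  acc <- empty
  total <- 0
  repeat {
    if (is.na(a1)) {
      w <- bins_in(0.010, min(1.5 * mean_isi_s, acg$max_lag_s))
    } else {
      upper <- prev_peak + a1 + 0.010
      if (upper > acg$max_lag_s) break
      w <- bins_in(prev_trough, upper)
    }
    if (!length(w)) break
    pk <- w[which.max(counts[w])]
    peak_lag <- centers[pk]
    span <- if (is.na(a1)) peak_lag else a1
    tw <- bins_in(peak_lag, peak_lag + span)
    if (!length(tw)) break
    tr <- tw[which.min(counts[tw])]
    peak_count <- counts[pk]
    trough_count <- counts[tr]
    clause1 <- if (rule == "deviation") {
      (peak_count - trough_count) > 4 * tail_sd
    } else {
      (peak_count + trough_count) > 4 * tail_sd
    }
    clause2 <- peak_count > baseline + 2 * tail_sd &&
               trough_count < baseline - 2 * tail_sd
    if (!(clause1 || clause2)) break
    total <- total + (peak_count - trough_count)
    acc <- rbind(acc, data.frame(peak_lag_s = peak_lag,
                                 peak_count = peak_count,
                                 trough_lag_s = centers[tr],
                                 trough_count = trough_count))
    if (is.na(a1)) a1 <- peak_lag
    prev_peak <- peak_lag
    prev_trough <- centers[tr]
  }
  list(rhythmicity_index = total / baseline, accepted_pairs = acc)
}
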