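#' Synthesize a raw extracellular voltage trace
#'
#' Builds a test trace at the recording sampling rate: Gaussian background
#' noise, a stereotyped negative-valley spike waveform at each requested spike
#' time, and a saturating stimulation artifact in a blanking window around
#' each stimulus onset. Spikes falling inside an artifact window are dropped
#' with a warning.
#'
#' @param spike_times_ms Numeric vector of spike times (ms).
#' @param stim_times_ms Numeric vector of stimulation onsets (ms).
#' @param duration_ms Total trace duration (ms).
#' @param noise_sd Background noise standard deviation (µV).
#' @param spike_amp Peak (negative) spike amplitude in multiples of
#'   `noise_sd`; the default plants -8 sigma valleys.
#' @param fs Sampling frequency (Hz); fixed at 25 kHz by the recording design.
#' @param artifact_window Blanked interval around each stimulus (ms, relative
#'   to onset).
#' @param sat_value Saturation amplitude of the artifact (µV).
#' @param seed Optional RNG seed for the noise.
#' @return An object of class `"voltage_trace"`: list with `samples` (µV),
#'   `fs`, `stim_times` (ms), `artifact_window`, and the planted
#'   `spike_times` actually used.
#' @export
synthesize_trace <- function(spike_times_ms, stim_times_ms = numeric(),
                             duration_ms = 1000, noise_sd = 4,
                             spike_amp = 8, fs = 25000,
                             artifact_window = c(-3, 3), sat_value = 1000,
                             seed = NULL) {
  n <- round(duration_ms * fs / 1000)
  keep <- rep(TRUE, length(spike_times_ms))
  for (st in stim_times_ms) {
    inside <- spike_times_ms >= st + artifact_window[1] &
      spike_times_ms <= st + artifact_window[2]
    keep <- keep & !inside
  }
  if (any(!keep)) {
    warning(sprintf("%d spike(s) inside an artifact window were dropped",
                    sum(!keep)), call. = FALSE)
  }
  spike_times_ms <- spike_times_ms[keep]

  v <- with_seed(seed, stats::rnorm(n, sd = noise_sd))

  # stereotyped waveform: sharp negative valley with a shallow rebound,
  # ~0.6 ms total support
  t_w <- seq(-0.3, 0.6, by = 1000 / fs)
  w <- -exp(-(t_w / 0.1)^2) + 0.3 * exp(-((t_w - 0.25) / 0.2)^2)
  w <- w / max(abs(w)) * spike_amp * noise_sd
  for (ts in spike_times_ms) {
    k0 <- round(ts * fs / 1000) + 1L
    idx <- k0 + seq_along(t_w) - 1L - round(0.3 * fs / 1000)
    ok <- idx >= 1L & idx <= n
    v[idx[ok]] <- v[idx[ok]] + w[ok]
  }
  for (st in stim_times_ms) {
    idx <- max(1L, round((st + artifact_window[1]) * fs / 1000) + 1L):
      min(n, round((st + artifact_window[2]) * fs / 1000) + 1L)
    v[idx] <- sat_value
  }
  structure(list(samples = v, fs = fs, stim_times = stim_times_ms,
                 artifact_window = artifact_window,
                 spike_times = spike_times_ms),
            class = "voltage_trace")
}

#' Remove stimulation artifacts and band-pass a raw trace
#'
#' Three-step procedure: (i) saturated samples are set to 0, (ii) a zero-phase
#' 4th-order Butterworth band-pass at 500--2000 Hz is applied, (iii) the
#' regions flagged in step (i) are set to 0 again (the filter rings through
#' them otherwise).
#'
#' @param trace A `"voltage_trace"` object at 25 kHz.
#' @param sat_threshold Absolute amplitude (µV) at or above which a sample is
#'   considered saturated.
#' @param band Band-pass edges (Hz).
#' @return The filtered `"voltage_trace"` with artifacts zeroed; the saturated
#'   mask is attached as `saturated`.
#' @export
remove_artifacts <- function(trace, sat_threshold = 1000,
                             band = c(500, 2000)) {
  stopifnot(inherits(trace, "voltage_trace"))
  if (trace$fs != 25000) stop("trace must be sampled at 25 kHz", call. = FALSE)
  v <- trace$samples
  sat <- abs(v) >= sat_threshold
  v[sat] <- 0
  if (all(sat)) {
    out <- rep(0, length(v))
  } else {
    bf <- signal::butter(2, band / (trace$fs / 2), type = "pass")
    # filtfilt applies the order-2 design forward and backward: zero phase,
    # effective 4th order
    out <- signal::filtfilt(bf, v)
    out[sat] <- 0
  }
  trace$samples <- out
  trace$saturated <- sat
  trace
}

#' Detect spikes by valley threshold crossing
#'
#' Computes the mean and standard deviation of the trace per non-overlapping
#' one-second block, then marks every local minimum (`v[k] < v[k-1]` and
#' `v[k] <= v[k+1]`) whose depth satisfies `v - mu < -5 sigma`. Within any
#' 0.25 ms, only the lowest valley is kept (refractory filtering).
#'
#' @param trace An artifact-removed `"voltage_trace"`.
#' @param threshold_sd Detection threshold in standard deviations (default 5).
#' @param refractory_ms Minimum spacing between kept spikes (ms).
#' @return An object of class `"spike_train"`: list with `times_ms` (strictly
#'   increasing) and `fs`. Traces shorter than 1 s use the available span for
#'   `mu` and `sigma`.
#' @export
detect_spikes <- function(trace, threshold_sd = 5, refractory_ms = 0.25) {
  stopifnot(inherits(trace, "voltage_trace"))
  v <- trace$samples
  n <- length(v)
  fs <- trace$fs
  block <- as.integer(pmin((seq_len(n) - 1L) %/% fs, max(0L, n %/% fs - 1L)))
  mu <- ave(v, block, FUN = mean)
  sigma <- ave(v, block, FUN = stats::sd)

  k <- 2:(n - 1L)
  is_min <- v[k] < v[k - 1L] & v[k] <= v[k + 1L]
  cand <- k[is_min & (v[k] - mu[k] < -threshold_sd * sigma[k])]
  if (length(cand) == 0L) {
    return(structure(list(times_ms = numeric(), fs = fs), class = "spike_train"))
  }
  # refractory: greedily accept valleys from deepest to shallowest
  ord <- cand[order(v[cand])]
  min_gap <- refractory_ms * fs / 1000
  accepted <- integer()
  for (idx in ord) {
    if (length(accepted) == 0L || all(abs(accepted - idx) >= min_gap)) {
      accepted <- c(accepted, idx)
    }
  }
  structure(list(times_ms = sort((accepted - 1L) / fs * 1000), fs = fs),
            class = "spike_train")
}

#' Count evoked spikes per stimulation event
#'
#' Counts spikes with latency in the half-open window `[10, 30)` ms after each
#' stimulation onset; spikes outside all windows are ignored. Earlier spikes
#' belong to the direct-response zone and are excluded by design.
#'
#' @param spikes A `"spike_train"` (or numeric vector of spike times, ms).
#' @param stim_times_ms Stimulation onsets (ms), in the same clock.
#' @param window_ms Response window relative to each onset (half-open).
#' @return Integer vector of counts, one per stimulation event.
#' @export
count_evoked <- function(spikes, stim_times_ms, window_ms = c(10, 30)) {
  times <- if (inherits(spikes, "spike_train")) spikes$times_ms else spikes
  if (length(stim_times_ms) > 1L) {
    gaps <- diff(sort(stim_times_ms))
    if (any(gaps < window_ms[2])) {
      stop("stimulation intervals shorter than the response window overlap",
           call. = FALSE)
    }
  }
  vapply(stim_times_ms, function(s0) {
    sum(times >= s0 + window_ms[1] & times < s0 + window_ms[2])
  }, integer(1))
}
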