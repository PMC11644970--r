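# Per-bout gait metrics and their per-subject aggregation.
#
# Conventions: population SD (divisor n) throughout; step regularity
# (1/sigma_T) is capped when sigma_T is numerically zero; harmonic ratio
# uses stride harmonics 1..20 on a Hann-windowed periodogram with
# band-integrated energy extraction.

.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Step-time intervals of a bout
#'
#' @param peak_times Times of consecutive step peaks, seconds.
#' @return Intervals `t[i+1] - t[i]` (empty, with a warning, for < 2 peaks).
#' @export
step_times <- function(peak_times) {
  if (length(peak_times) < 2) {
    warning("fewer than 2 peaks: no step intervals")
    return(numeric(0))
  }
  diff(peak_times)
}

#' Mean step time
#' @param intervals Step-time intervals, seconds.
#' @return Seconds.
#' @export
mean_step_time <- function(intervals) mean(intervals)

#' Step-time variability (coefficient of variation)
#'
#' Population SD of the intervals divided by their mean.
#' @param intervals Step-time intervals.
#' @return Dimensionless fraction.
#' @export
step_time_cv <- function(intervals) {
  m <- mean(intervals)
  if (m == 0) stop("zero mean step time")
  .pop_sd(intervals) / m
}

#' Step regularity
#'
#' Inverse of the population SD of the step times, capped at `cap` when the
#' SD is numerically zero (< 1e-6 s).
#' @param intervals Step-time intervals.
#' @param cap Cap applied for (near-)zero SD.
#' @return 1/s.
#' @export
step_regularity <- function(intervals, cap = 1e6) {
  s <- .pop_sd(intervals)
  if (s < 1e-6) cap else 1 / s
}

#' Step symmetry
#'
#' `1 - mean(|T[i+1] - T[i]|) / T_mean` over consecutive interval pairs;
#' equals 1 iff all intervals are equal.
#' @param intervals Step-time intervals (>= 2).
#' @return Dimensionless, <= 1.
#' @export
step_symmetry <- function(intervals) {
  stopifnot(length(intervals) >= 2)
  1 - mean(abs(diff(intervals))) / mean(intervals)
}

#' Stride regularity
#'
#' Normalised unbiased autocorrelation of the mean-removed vertical signal
#' at the stride lag (twice the mean step time), clamped to [-1, 1].
#'
#' @param x Filtered vertical-axis samples of the bout.
#' @param fs Sampling rate, Hz.
#' @param mean_step_time_s Mean step time of the bout, seconds.
#' @return Value in [-1, 1], or `NA` for a degenerate (zero-variance)
#'   signal or a lag beyond the bout.
#' @export
stride_regularity <- function(x, fs, mean_step_time_s) {
  lag <- round(2 * mean_step_time_s * fs)
  n <- length(x)
  if (lag < 1 || lag >= n) return(NA_real_)
  xc <- x - mean(x)
  v <- mean(xc^2)
  if (v < 1e-12) return(NA_real_)
  r <- sum(xc[1:(n - lag)] * xc[(lag + 1):n]) / (n - lag) / v
  max(-1, min(1, r))
}

#' Walking speed from step count
#'
#' `v = n_steps * step_length / total_time`, with a fixed average step
#' length (the study used 0.7 m for all participants) and total time the
#' summed duration of qualifying bouts.
#'
#' @param n_steps Total steps.
#' @param total_bout_time_s Summed bout duration, seconds (> 0 unless
#'   `n_steps` is 0).
#' @param step_length_m Constant step length, metres.
#' @return m/s.
#' @export
walking_speed <- function(n_steps, total_bout_time_s, step_length_m = 0.7) {
  if (n_steps == 0) return(0)
  if (total_bout_time_s <= 0) stop("total bout time must be positive")
  n_steps * step_length_m / total_bout_time_s
}

#' Root mean square of a signal
#' @param x Samples.
#' @return `sqrt(mean(x^2))`.
#' @export
rms <- function(x) {
  stopifnot(length(x) > 0)
  sqrt(mean(x^2))
}

#' Harmonic ratio
#'
#' Ratio of even- to odd-harmonic spectral energy at multiples of the
#' stride frequency (`1 / (2 * T_mean)`), from a Hann-windowed
#' periodogram over harmonics 1..`n_harmonics` (harmonics at or above
#' Nyquist are dropped). By default the energy of each harmonic is
#' integrated over a band of `band_frac` stride frequencies around it:
#' step-timing jitter broadens the spectral lines (increasingly so for
#' higher harmonics), and a strict nearest-bin lookup (`band_frac = 0`)
#' then measures only the fluctuating line centre, which makes short-bout
#' estimates unstable. The same even/odd orientation is used for every
#' axis; `invert = TRUE` flips it (the mediolateral convention in parts
#' of the gait literature).
#'
#' @param x Axis samples over the bout.
#' @param fs Sampling rate, Hz.
#' @param stride_frequency_hz Stride frequency, Hz.
#' @param n_harmonics Number of stride harmonics (default 20).
#' @param band_frac Half-width of the per-harmonic integration band as a
#'   fraction of the stride frequency; `0` = nearest bin only.
#' @param invert Swap even and odd energy (off by default).
#' @param cap Value returned when odd energy is numerically zero.
#' @return Dimensionless ratio (possibly `cap`, flagged with attribute
#'   `capped`).
#' @export
harmonic_ratio <- function(x, fs, stride_frequency_hz, n_harmonics = 20,
                           band_frac = 0.35, invert = FALSE, cap = 1e6) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))   # Hann
  X <- stats::fft((x - mean(x)) * w)
  mag2 <- Mod(X[seq_len(floor(n / 2) + 1)])^2
  freq <- (seq_len(floor(n / 2) + 1) - 1) * fs / n
  h <- seq_len(n_harmonics)
  fh <- h * stride_frequency_hz
  keep <- fh < fs / 2
  h <- h[keep]; fh <- fh[keep]
  e <- if (band_frac > 0) {
    vapply(fh, function(f)
      sum(mag2[abs(freq - f) <= band_frac * stride_frequency_hz]),
      numeric(1))
  } else {
    mag2[round(fh / (fs / n)) + 1]
  }
  even <- sum(e[h %% 2 == 0]); odd <- sum(e[h %% 2 == 1])
  if (invert) { tmp <- even; even <- odd; odd <- tmp }
  if (odd <= .Machine$double.eps * sum(e))
    return(structure(cap, capped = TRUE))
  structure(even / odd, capped = FALSE)
}

#' Histogram entropy
#'
#' Shannon entropy (natural log) of an equal-width histogram over
#' `[min(x), max(x)]`; empty bins contribute zero. A constant signal has
#' entropy 0.
#'
#' @param x Samples.
#' @param n_bins Number of bins (default 32).
#' @return Nats.
#' @export
entropy <- function(x, n_bins = 32) {
  stopifnot(length(x) > 0)
  rng <- range(x)
  if (rng[1] == rng[2]) return(0)
  bin <- pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L, n_bins)
  p <- tabulate(bin, n_bins) / length(x)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Gait feature names, in schema order
#' @export
gait_feature_names <- function() {
  c("n_steps", "mean_step_time_s", "step_time_cv", "step_regularity",
    "stride_regularity", "step_symmetry", "walking_speed_mps",
    "rms_vt", "rms_ml", "rms_ap", "hr_vt", "hr_ml", "hr_ap",
    "entropy_vt", "entropy_ml", "entropy_ap")
}

#' Compute gait features for one subject
#'
#' Computes each metric per walking bout on the band-pass-filtered axes
#' and averages unweighted across bouts; `n_steps` is summed and walking
#' speed uses the pooled step count over the pooled bout time. With no
#' qualifying bout an all-`NA` row (with `n_steps = 0`) is returned.
#'
#' @param signal An `accel_signal` (raw; filtering is applied internally
#'   unless `filtered` is supplied).
#' @param bouts Bout list from [segment_bouts()].
#' @param low,high,order Band-pass settings (see [bandpass()]).
#' @param step_length_m Constant step length for walking speed.
#' @param n_bins Entropy histogram bins.
#' @param filtered Optional pre-filtered `accel_signal` (avoids refiltering
#'   when the caller already band-passed the axes).
#' @return One-row data frame with columns [gait_feature_names()].
#' @export
compute_gait_features <- function(signal, bouts, low = 0.5, high = 20,
                                  order = 4, step_length_m = 0.7,
                                  n_bins = 32, filtered = NULL) {
  stopifnot(inherits(signal, "accel_signal"))
  empty <- as.data.frame(as.list(stats::setNames(
    rep(NA_real_, length(gait_feature_names())), gait_feature_names())))
  if (length(bouts) == 0) { empty$n_steps <- 0L; return(empty) }
  filt <- if (is.null(filtered)) bandpass(signal, low, high, order)
          else filtered
  fs <- signal$fs
  per_bout <- lapply(bouts, function(b) {
    # peaks are detected on the filtered axis, but the sub-sample vertex
    # is fitted on the raw axis: the band-pass mixes neighbouring-step
    # content into each apex and would bias refined step times
    tpk <- refine_peak_times(signal$vt, b$peak_indices, fs)
    iv <- step_times(tpk)
    tm <- mean_step_time(iv)
    idx <- b$start:(b$end - 1L)
    sf <- 1 / (2 * tm)
    row <- c(
      mean_step_time_s = tm,
      step_time_cv = step_time_cv(iv),
      step_regularity = step_regularity(iv),
      stride_regularity = stride_regularity(filt$vt[idx], fs, tm),
      step_symmetry = step_symmetry(iv),
      rms_vt = rms(filt$vt[idx]), rms_ml = rms(filt$ml[idx]),
      rms_ap = rms(filt$ap[idx]),
      hr_vt = as.numeric(harmonic_ratio(filt$vt[idx], fs, sf)),
      hr_ml = as.numeric(harmonic_ratio(filt$ml[idx], fs, sf)),
      hr_ap = as.numeric(harmonic_ratio(filt$ap[idx], fs, sf)),
      entropy_vt = entropy(filt$vt[idx], n_bins),
      entropy_ml = entropy(filt$ml[idx], n_bins),
      entropy_ap = entropy(filt$ap[idx], n_bins))
    list(row = row, n_steps = length(b$peak_indices),
         dur = (b$end - b$start) / fs)
  })
  mat <- do.call(rbind, lapply(per_bout, `[[`, "row"))
  n_steps <- as.integer(sum(vapply(per_bout, `[[`, 0, "n_steps")))
  total_t <- sum(vapply(per_bout, `[[`, 0, "dur"))
  out <- empty
  out$n_steps <- n_steps
  for (nm in colnames(mat)) out[[nm]] <- mean(mat[, nm])
  out$walking_speed_mps <- walking_speed(n_steps, total_t, step_length_m)
  out[, gait_feature_names(), drop = FALSE]
}
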