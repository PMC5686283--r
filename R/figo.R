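# FIGO-style macroscopic descriptors: baseline trend, acceleration and
# deceleration events, long-term variability.

# zero-phase FFT low-pass with mirror padding; cutoff in Hz
fft_lowpass <- function(x, fs, cutoff) {
  n <- length(x)
  if (n < 4L) return(x)
  pad <- min(n - 1L, max(16L, ceiling(fs / cutoff)))
  xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(n - pad):(n - 1)]))
  np <- length(xp)
  freqs <- (seq_len(np) - 1) / np * fs
  freqs <- pmin(freqs, fs - freqs) # two-sided
  X <- stats::fft(xp)
  X[freqs > cutoff] <- 0
  out <- Re(stats::fft(X, inverse = TRUE)) / np
  out[(pad + 1):(pad + n)]
}

#' Estimate the FHR baseline and macroscopic events
#'
#' A slowly varying baseline trend robust to acceleration/deceleration
#' excursions: iteratively low-pass filter (cutoff `cutoff_hz`), trim
#' samples deviating more than `trim_bpm` from the current trend
#' (replacing them by the trend), and refit, until the trend changes by
#' less than `tol_bpm` everywhere or `max_iter` passes. Events are then
#' detected against the converged baseline (see [detect_events()]).
#'
#' @param clean an `fhr_clean` object with at least one valid segment of
#'   `min_segment_s` seconds.
#' @param cutoff_hz low-pass cutoff in Hz for the trend.
#' @param trim_bpm deviation in bpm beyond which samples are treated as
#'   event excursions while fitting the trend.
#' @param tol_bpm convergence tolerance in bpm.
#' @param max_iter iteration cap.
#' @param min_segment_s minimum usable segment length in seconds.
#' @return An object of class `fhr_baseline`: list with `baseline` (bpm,
#'   full record length, clamped to \[50, 200\]), `accelerations` and
#'   `decelerations` (tibbles of half-open sample intervals), and the
#'   event counts `n_accel`, `n_decel`.
#' @export
estimate_baseline <- function(clean, cutoff_hz = 0.006, trim_bpm = 15,
                              tol_bpm = 0.5, max_iter = 10,
                              min_segment_s = 60) {
  stopifnot(inherits(clean, "fhr_clean"))
  segs <- valid_segments(clean, min_segment_s)
  if (nrow(segs) == 0L) {
    stop_fhr("no valid segment long enough for baseline estimation",
             class = "fhrbench_extraction_error")
  }
  fs <- clean$fs
  # fill masked samples for filtering purposes only
  x <- clean$fhr
  idx <- which(!is.na(x))
  x_full <- stats::approx(idx, x[idx], xout = seq_along(x), rule = 2)$y
  # robust initialization: a wide rolling median is insensitive to even
  # minute-long accel/decel excursions, so the trim step sees them
  k_med <- min(length(x_full) - 1 + length(x_full) %% 2,
               as.integer(300 * fs) %/% 2 * 2 + 1)
  trend <- fft_lowpass(stats::runmed(x_full, k_med, endrule = "median"),
                       fs, cutoff_hz)
  work <- x_full
  for (it in seq_len(max_iter)) {
    dev <- x_full - trend
    work <- ifelse(abs(dev) > trim_bpm, trend, x_full)
    new_trend <- fft_lowpass(work, fs, cutoff_hz)
    delta <- max(abs(new_trend - trend))
    trend <- new_trend
    if (delta < tol_bpm) break
  }
  baseline <- pmin(pmax(trend, 50), 200)
  ev <- detect_events(clean, baseline)
  structure(
    list(baseline = baseline,
         accelerations = ev$accelerations,
         decelerations = ev$decelerations,
         n_accel = nrow(ev$accelerations),
         n_decel = nrow(ev$decelerations)),
    class = "fhr_baseline"
  )
}

#' Detect accelerations and decelerations against a baseline
#'
#' FIGO-style event criteria: an acceleration is an excursion at least
#' `amp_bpm` above baseline lasting at least `dur_s` seconds; a
#' deceleration is the mirror image below baseline. Events cannot span
#' masked (long-gap) regions.
#'
#' @param clean an `fhr_clean` object.
#' @param baseline numeric baseline vector, same length as the signal.
#' @param amp_bpm excursion threshold in bpm.
#' @param dur_s duration threshold in seconds.
#' @param merge_gap_s same-direction excursions separated by less than
#'   this are one event (momentary dips from beat-to-beat variability do
#'   not split an event).
#' @return List with tibbles `accelerations` and `decelerations`, each
#'   with half-open `start`/`end` sample columns.
#' @export
detect_events <- function(clean, baseline, amp_bpm = 15, dur_s = 15,
                          merge_gap_s = 5) {
  stopifnot(inherits(clean, "fhr_clean"))
  if (length(baseline) != length(clean$fhr)) {
    stop_fhr("baseline length mismatch")
  }
  dev <- clean$fhr - baseline
  dev[!clean$valid_mask] <- 0
  dev[is.na(dev)] <- 0
  min_len <- dur_s * clean$fs
  max_merge <- merge_gap_s * clean$fs
  find_runs <- function(flag) {
    # events may not bridge masked regions
    flag[!clean$valid_mask] <- FALSE
    segs <- mask_segments(flag)
    if (nrow(segs) > 1L) {
      merged <- segs[1, ]
      for (i in 2:nrow(segs)) {
        gap_idx <- merged$end[nrow(merged)]:(segs$start[i] - 1L)
        bridged <- (segs$start[i] - merged$end[nrow(merged)]) < max_merge &&
          all(clean$valid_mask[gap_idx])
        if (bridged) {
          merged$end[nrow(merged)] <- segs$end[i]
        } else {
          merged <- rbind(merged, segs[i, ])
        }
      }
      segs <- merged
    }
    segs[(segs$end - segs$start) >= min_len, , drop = FALSE]
  }
  list(accelerations = find_runs(dev >= amp_bpm),
       decelerations = find_runs(dev <= -amp_bpm))
}

#' FIGO-domain feature set
#'
#' Baseline mean and SD over valid samples, event counts, and the
#' aggregated long-term variability `delta_total`: the sum over complete
#' minutes of the per-minute range (max minus min) of the detrended
#' (signal minus baseline) FHR.
#'
#' @param clean an `fhr_clean` object.
#' @param baseline an `fhr_baseline` object from [estimate_baseline()].
#' @return Named list: `baseline_mean`, `baseline_sd` (bpm), `n_accel`,
#'   `n_decel`, `delta_total` (bpm).
#' @export
figo_features <- function(clean, baseline) {
  stopifnot(inherits(clean, "fhr_clean"), inherits(baseline, "fhr_baseline"))
  ok <- clean$valid_mask & !is.na(clean$fhr)
  b <- baseline$baseline
  detr <- clean$fhr - b
  fs <- clean$fs
  n <- length(clean$fhr)
  min_len <- as.integer(60 * fs)
  n_min <- n %/% min_len
  deltas <- vapply(seq_len(n_min), function(k) {
    i <- ((k - 1L) * min_len + 1L):(k * min_len)
    v <- detr[i][ok[i]]
    if (length(v) < 2L) return(NA_real_)
    max(v) - min(v)
  }, numeric(1))
  list(
    baseline_mean = mean(b[ok]),
    baseline_sd = stats::sd(b[ok]),
    n_accel = baseline$n_accel,
    n_decel = baseline$n_decel,
    delta_total = sum(deltas, na.rm = TRUE)
  )
}
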