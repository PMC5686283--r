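# Welch power spectral density and band energies. FHR spectral analysis
# uses two band conventions; both are computed from one PSD estimate.

#' Gaussian analysis window
#'
#' `w[i] = exp(-0.5 ((i - (N-1)/2) / sigma_w)^2)` with
#' `sigma_w = shape * (N-1)/2`.
#'
#' @param n window length in samples.
#' @param shape relative width; 0.4 gives the conventional "Gaussian-like"
#'   taper.
#' @return Numeric window of length `n`.
#' @export
gaussian_window <- function(n, shape = 0.4) {
  i <- seq_len(n) - 1
  c0 <- (n - 1) / 2
  exp(-0.5 * ((i - c0) / (shape * c0))^2)
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodograms over overlapping windows. Each window is
#' mean-removed, tapered, and scaled so that the one-sided PSD integrates
#' to the windowed signal variance (density normalization by
#' `fs * sum(w^2)`).
#'
#' @param x numeric signal (a single contiguous segment).
#' @param fs sampling frequency in Hz.
#' @param n_window window length in samples.
#' @param overlap fractional window overlap in `[0, 1)`.
#' @param window taper vector of length `n_window`; defaults to the
#'   Gaussian window.
#' @return List with `freq` (Hz) and `psd` (power density, signal^2 / Hz),
#'   one-sided.
#' @export
welch_psd <- function(x, fs = 4, n_window = 1024, overlap = 0.8,
                      window = gaussian_window(n_window)) {
  n <- length(x)
  if (n < n_window) {
    stop_fhr("segment shorter than the analysis window",
             class = "fhrbench_extraction_error")
  }
  hop <- max(1L, as.integer(round(n_window * (1 - overlap))))
  starts <- seq(1L, n - n_window + 1L, by = hop)
  u <- sum(window^2)
  acc <- numeric(n_window %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + n_window - 1L)]
    seg <- (seg - mean(seg)) * window
    X <- stats::fft(seg)
    p <- Mod(X[seq_along(acc)])^2 / (fs * u)
    # one-sided: double everything except DC (and Nyquist for even n)
    p[2:(length(p) - 1L)] <- 2 * p[2:(length(p) - 1L)]
    acc <- acc + p
  }
  list(freq = (seq_along(acc) - 1) * fs / n_window,
       psd = acc / length(starts))
}

# trapezoid integral of psd over [lo, hi)
band_power <- function(freq, psd, lo, hi) {
  sel <- freq >= lo & freq < hi
  if (sum(sel) < 2L) return(0)
  f <- freq[sel]; p <- psd[sel]
  sum(diff(f) * (head(p, -1) + tail(p, -1)) / 2)
}

#' Spectral band edges
#'
#' Two conventions used in FHR analysis: `"sig"` — VLF \[0, 0.03), LF
#' \[0.03, 0.15), MF \[0.15, 0.5), HF \[0.5, 1\] Hz; `"alt"` — VLF
#' \[0, 0.03), LF \[0.03, 0.07), MF \[0.07, 0.13), HF \[0.13, 1\] Hz.
#'
#' @param system `"sig"` or `"alt"`.
#' @return Named list of `c(lo, hi)` band edges in Hz.
#' @export
spectral_bands <- function(system = c("sig", "alt")) {
  system <- match.arg(system)
  if (system == "sig") {
    list(vlf = c(0, 0.03), lf = c(0.03, 0.15), mf = c(0.15, 0.5),
         hf = c(0.5, 1.000001))
  } else {
    list(vlf = c(0, 0.03), lf = c(0.03, 0.07), mf = c(0.07, 0.13),
         hf = c(0.13, 1.000001))
  }
}

#' Frequency-domain feature set
#'
#' Welch PSD (Gaussian window, `n_window` samples, `overlap` fractional
#' overlap) over every valid segment at least `n_window` samples long,
#' with all windowed periodograms averaged; band powers integrated by the
#' trapezoid rule over both band systems, plus the LF/HF and LF/(MF+HF)
#' ratios and per-system relative (fraction-of-total) powers.
#'
#' @param clean an `fhr_clean` object (features run on the bpm signal).
#' @param n_window,overlap Welch parameters.
#' @return Named list of 18 features: absolute band powers and totals for
#'   both systems (`vlf_sig`, ..., `total_power_alt`), `lf_hf_sig`,
#'   `lf_mfhf_alt`, and relative powers `rel_*`.
#' @export
spectral_features <- function(clean, n_window = 1024, overlap = 0.8) {
  stopifnot(inherits(clean, "fhr_clean"))
  fs <- clean$fs
  segs <- clean$segments
  segs <- segs[(segs$end - segs$start) >= n_window, , drop = FALSE]
  if (nrow(segs) == 0L) {
    stop_fhr("no valid segment long enough for spectral analysis",
             class = "fhrbench_extraction_error")
  }
  win <- gaussian_window(n_window)
  hop <- max(1L, as.integer(round(n_window * (1 - overlap))))
  u <- sum(win^2)
  nb <- n_window %/% 2 + 1
  acc <- numeric(nb)
  n_win_total <- 0L
  for (i in seq_len(nrow(segs))) {
    x <- clean$fhr[segs$start[i]:(segs$end[i] - 1L)]
    starts <- seq(1L, length(x) - n_window + 1L, by = hop)
    for (s in starts) {
      seg <- x[s:(s + n_window - 1L)]
      seg <- (seg - mean(seg)) * win
      X <- stats::fft(seg)
      p <- Mod(X[seq_len(nb)])^2 / (fs * u)
      p[2:(nb - 1L)] <- 2 * p[2:(nb - 1L)]
      acc <- acc + p
      n_win_total <- n_win_total + 1L
    }
  }
  psd <- acc / n_win_total
  freq <- (seq_len(nb) - 1) * fs / n_window
  out <- list()
  for (sys in c("sig", "alt")) {
    bands <- spectral_bands(sys)
    pw <- lapply(bands, function(b) band_power(freq, psd, b[1], b[2]))
    tot <- sum(unlist(pw))
    out[[paste0("vlf_", sys)]] <- pw$vlf
    out[[paste0("lf_", sys)]] <- pw$lf
    out[[paste0("mf_", sys)]] <- pw$mf
    out[[paste0("hf_", sys)]] <- pw$hf
    out[[paste0("total_power_", sys)]] <- tot
    out[[paste0("rel_lf_", sys)]] <- if (tot > 0) pw$lf / tot else 0
    out[[paste0("rel_mf_", sys)]] <- if (tot > 0) pw$mf / tot else 0
    out[[paste0("rel_hf_", sys)]] <- if (tot > 0) pw$hf / tot else 0
  }
  out$lf_hf_sig <- if (out$hf_sig > 0) out$lf_sig / out$hf_sig else NA_real_
  out$lf_mfhf_alt <- if ((out$mf_alt + out$hf_alt) > 0) {
    out$lf_alt / (out$mf_alt + out$hf_alt)
  } else NA_real_
  out
}
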