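#' Remove non-physiological FHR values
#'
#' Samples strictly above `bpm_max` or strictly below `bpm_min` (zeroed
#' dropout included) are replaced by `NA`; all other samples pass through
#' bit-identical. The boundary values themselves are retained.
#'
#' @param fhr numeric bpm vector (may already contain `NA` markers).
#' @param bpm_min,bpm_max physiological range bounds in bpm.
#' @return Numeric vector with `NA` at removed samples.
#' @export
remove_extremes <- function(fhr, bpm_min = 50, bpm_max = 200) {
  if (length(fhr) == 0L) stop_fhr("empty input signal")
  bad <- !is.na(fhr) & (fhr > bpm_max | fhr < bpm_min)
  fhr[bad] <- NA_real_
  fhr
}

# runs of NA in a logical mask -> tibble(start, end) half-open, 0-based not
# used; returns 1-based inclusive starts/ends internally
na_runs <- function(miss) {
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Interpolate short gaps and mask long ones
#'
#' Missing runs lasting at most `max_gap_s` seconds are filled by monotone
#' (shape-preserving) piecewise-cubic Hermite interpolation through the
#' valid samples, which cannot overshoot the flanking anchor values.
#' Runs longer than `max_gap_s`, and any leading/trailing missing run
#' (which cannot be interpolated one-sidedly), are left unfilled and
#' excluded via the validity mask.
#'
#' @param fhr numeric bpm vector with `NA` at missing/removed samples.
#' @param fs sampling frequency in Hz.
#' @param max_gap_s longest gap, in seconds, that is still interpolated.
#' @return An object of class `fhr_clean`: list with
#'   \describe{
#'     \item{fhr}{the gap-filled signal (`NA` inside masked regions)}
#'     \item{valid_mask}{logical, `FALSE` inside long/edge gaps}
#'     \item{filled_mask}{logical, `TRUE` where a sample was interpolated}
#'     \item{segments}{tibble of half-open `[start, end)` valid runs
#'       (1-based start, exclusive end)}
#'     \item{fs, noise_fraction, long_gap_fraction}{scalars; the noise
#'       fraction counts interpolated (short-gap/artifact) samples, the
#'       long-gap fraction counts masked samples}
#'   }
#' @export
interpolate_gaps <- function(fhr, fs = 4, max_gap_s = 15) {
  if (length(fhr) == 0L) stop_fhr("empty input signal")
  if (fs <= 0) stop_fhr("`fs` must be positive")
  miss <- is.na(fhr)
  if (all(miss)) stop_fhr("all samples missing")
  n <- length(fhr)
  filled <- fhr
  valid_mask <- rep(TRUE, n)
  filled_mask <- rep(FALSE, n)
  runs <- na_runs(miss)
  if (nrow(runs) > 0L) {
    idx_valid <- which(!miss)
    interp_fun <- NULL
    for (i in seq_len(nrow(runs))) {
      s <- runs$start[i]; e <- runs$end[i]
      len_s <- (e - s + 1L) / fs
      edge <- s == 1L || e == n
      if (!edge && len_s <= max_gap_s) {
        if (is.null(interp_fun)) {
          interp_fun <- stats::splinefun(idx_valid, fhr[idx_valid],
                                         method = "monoH.FC")
        }
        filled[s:e] <- interp_fun(s:e)
        filled_mask[s:e] <- TRUE
      } else {
        valid_mask[s:e] <- FALSE
      }
    }
  }
  segs <- mask_segments(valid_mask)
  structure(
    list(fhr = filled, valid_mask = valid_mask, filled_mask = filled_mask,
         segments = segs, fs = fs,
         noise_fraction = sum(filled_mask) / n,
         long_gap_fraction = sum(!valid_mask) / n),
    class = "fhr_clean"
  )
}

#' @export
print.fhr_clean <- function(x, ...) {
  cat(sprintf(
    "<fhr_clean>  %d samples @ %g Hz | %d valid segment(s) | noise %.1f%% | long gaps %.1f%%\n",
    length(x$fhr), x$fs, nrow(x$segments), 100 * x$noise_fraction,
    100 * x$long_gap_fraction))
  invisible(x)
}

# maximal TRUE runs of a logical mask as half-open [start, end) intervals
mask_segments <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(start = starts[keep], end = ends[keep] + 1L)
}

#' Preprocess a raw FHR record
#'
#' Extreme-value removal followed by gap interpolation/masking; the
#' standard artifact-rejection pass applied before feature extraction.
#' Idempotent on already-clean signals.
#'
#' @param record an [fhr_record()].
#' @param bpm_min,bpm_max physiological range in bpm.
#' @param max_gap_s longest interpolated gap in seconds.
#' @return An `fhr_clean` object (see [interpolate_gaps()]).
#' @export
preprocess_record <- function(record, bpm_min = 50, bpm_max = 200,
                              max_gap_s = 15) {
  stopifnot(inherits(record, "fhr_record"))
  marked <- remove_extremes(record$fhr, bpm_min = bpm_min,
                            bpm_max = bpm_max)
  interpolate_gaps(marked, fs = record$fs, max_gap_s = max_gap_s)
}

#' Fraction of a record lost to short artifacts
#'
#' Counts samples that were extreme-removed or missing in runs short
#' enough to be interpolated (<= the gap threshold), as a fraction of the
#' total record length. Samples inside long (masked) gaps are reported by
#' `long_gap_fraction` on the clean object, not here.
#'
#' @param raw the raw bpm vector (zeros/extremes as recorded).
#' @param clean the `fhr_clean` object obtained from the same record.
#' @return A single fraction in `[0, 1]`.
#' @export
noise_fraction <- function(raw, clean) {
  stopifnot(inherits(clean, "fhr_clean"))
  if (length(raw) != length(clean$fhr)) {
    stop_fhr("raw and cleaned signals differ in length")
  }
  sum(clean$filled_mask) / length(raw)
}

#' Valid segments of a cleaned signal
#'
#' Maximal contiguous valid runs at least `min_len_s` seconds long,
#' ordered by start, half-open `[start, end)` indexing.
#'
#' @param clean an `fhr_clean` object.
#' @param min_len_s minimum duration in seconds.
#' @return Tibble with columns `start`, `end` (may have zero rows).
#' @export
valid_segments <- function(clean, min_len_s = 60) {
  stopifnot(inherits(clean, "fhr_clean"))
  segs <- clean$segments
  segs[(segs$end - segs$start) >= min_len_s * clean$fs, , drop = FALSE]
}
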