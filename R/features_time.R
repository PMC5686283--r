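# Beat-to-beat interval representation and classical short/long-term
# variability indices of the HRV tradition. All of these operate on RR
# intervals in milliseconds.

#' Convert bpm samples to RR intervals in milliseconds
#'
#' @param fhr numeric bpm vector; zero or negative rates are an error.
#' @return `60000 / fhr`, elementwise (ms).
#' @examples
#' rr_from_bpm(c(120, 150)) # 500, 400
#' @export
rr_from_bpm <- function(fhr) {
  if (any(!is.finite(fhr)) || any(fhr <= 0)) {
    stop_fhr("bpm values must be positive and finite")
  }
  60000 / fhr
}

# epoch means of consecutive `len`-sample windows (trailing partial epoch
# dropped)
epoch_means <- function(x, len) {
  n_ep <- length(x) %/% len
  if (n_ep == 0L) return(numeric(0))
  colMeans(matrix(x[seq_len(n_ep * len)], nrow = len))
}

#' Time-domain variability features of an RR series
#'
#' Classical short-term variability (STV) and long-term irregularity
#' indices computed on RR intervals (ms) sampled at `fs`:
#' \describe{
#'   \item{stv}{mean absolute successive difference of 2.5 s epoch means}
#'   \item{stv_haan}{interquartile range of successive RR differences
#'     (Haan-style short-term variation)}
#'   \item{stv_yeh}{Yeh's differential index: 1000 times the SD of
#'     (RR_i - RR_{i+1}) / (RR_i + RR_{i+1})}
#'   \item{sonicaid}{Dawes-Redman style STV: mean over complete minutes of
#'     the mean absolute successive difference of 3.75 s epoch means}
#'   \item{sdnn}{sample SD of the RR series}
#'   \item{delta}{mean over complete minutes of the per-minute RR range}
#'   \item{lti_haa}{Haan long-term irregularity: interquartile range of
#'     the modulus sqrt(RR_i^2 + RR_{i+1}^2) of successive pairs}
#'   \item{rmssd}{root mean square of successive RR differences}
#'   \item{mad_rr, iqr_rr}{median absolute deviation and interquartile
#'     range of the RR series}
#' }
#'
#' @param rr RR intervals in ms.
#' @param fs sampling frequency of the underlying trace in Hz.
#' @return Named list of the ten features above (ms except `stv_yeh`,
#'   which is dimensionless scaled by 1000).
#' @export
time_domain_features <- function(rr, fs = 4) {
  if (length(rr) < 60 * fs) {
    stop_fhr("record shorter than one minute of valid data",
             class = "fhrbench_extraction_error")
  }
  d <- diff(rr)
  ep_stv <- epoch_means(rr, max(1L, as.integer(round(2.5 * fs))))
  stv <- if (length(ep_stv) > 1L) mean(abs(diff(ep_stv))) else 0
  # Sonicaid-style: 3.75 s epochs, averaged per complete minute
  ep_len <- max(1L, as.integer(round(3.75 * fs)))
  ep_son <- epoch_means(rr, ep_len)
  per_min <- 60 %/% 3.75 # 16 epochs per minute
  n_min <- length(ep_son) %/% per_min
  sonicaid <- if (n_min >= 1L) {
    mean(vapply(seq_len(n_min), function(k) {
      e <- ep_son[((k - 1) * per_min + 1):(k * per_min)]
      mean(abs(diff(e)))
    }, numeric(1)))
  } else 0
  min_len <- as.integer(60 * fs)
  n_full_min <- length(rr) %/% min_len
  delta <- mean(vapply(seq_len(n_full_min), function(k) {
    v <- rr[((k - 1L) * min_len + 1L):(k * min_len)]
    max(v) - min(v)
  }, numeric(1)))
  yeh_d <- (rr[-length(rr)] - rr[-1]) / (rr[-length(rr)] + rr[-1])
  list(
    stv = stv,
    stv_haan = stats::IQR(d),
    stv_yeh = 1000 * stats::sd(yeh_d),
    sonicaid = sonicaid,
    sdnn = stats::sd(rr),
    delta = delta,
    lti_haa = stats::IQR(sqrt(rr[-length(rr)]^2 + rr[-1]^2)),
    rmssd = sqrt(mean(d^2)),
    mad_rr = stats::mad(rr),
    iqr_rr = stats::IQR(rr)
  )
}

#' Poincare plot dispersions SD1 and SD2
#'
#' Lag-1 return-map geometry of the RR series: SD1 is the dispersion
#' across the identity line, computed as the SD of successive differences
#' divided by sqrt(2); SD2 is the dispersion along it, obtained from the
#' identity SD2^2 = 2 SDNN^2 - SD1^2 (floored at zero). The ratio SD1/SD2
#' is also returned (0 for a constant series).
#'
#' @param rr RR intervals in ms (length >= 3).
#' @return Named list `sd1`, `sd2` (ms), `sd1_sd2_ratio`.
#' @export
poincare_sd <- function(rr) {
  if (length(rr) < 3L) stop_fhr("need at least 3 RR intervals")
  sd1 <- stats::sd(diff(rr)) / sqrt(2)
  sdnn <- stats::sd(rr)
  sd2 <- sqrt(max(2 * sdnn^2 - sd1^2, 0))
  ratio <- if (sd2 > 0) sd1 / sd2 else 0
  list(sd1 = sd1, sd2 = sd2, sd1_sd2_ratio = ratio)
}
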