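# Complexity and regularity estimators: approximate/sample entropy
# (compiled template counting), Lempel-Ziv complexity, four fractal
# dimension estimators, and detrended fluctuation analysis.

#' Approximate entropy (Pincus)
#'
#' ApEn(m, r) = Phi_m - Phi_{m+1} with self-matches included and Chebyshev
#' distance, the classical regularity statistic. The tolerance is
#' `r_factor` times the SD of the series (the HRV convention).
#'
#' @param x numeric series (length >= 100 recommended).
#' @param m template length, typically 2 or 3.
#' @param r_factor tolerance as a fraction of the series SD.
#' @return ApEn value; 0 for a zero-variance series (all templates match).
#' @export
approx_entropy <- function(x, m = 2, r_factor = 0.2) {
  if (length(x) < m + 2L) stop_fhr("series too short for ApEn")
  s <- stats::sd(x)
  if (s == 0) return(0)
  apen_cpp(as.numeric(x), as.integer(m), r_factor * s)
}

#' Sample entropy (Richman-Moorman)
#'
#' SampEn(m, r) = -ln(A/B) where B counts template pairs matching at
#' length m and A those still matching at m+1; self-matches excluded,
#' Chebyshev distance, tolerance `r_factor * sd(x)`. When no pairs match
#' (A or B zero) the value is undefined and `NA` is returned with
#' attribute `undefined = TRUE` so callers can flag the record.
#'
#' @inheritParams approx_entropy
#' @return SampEn value, 0 for a zero-variance series, or `NA` (flagged)
#'   when undefined.
#' @export
sample_entropy <- function(x, m = 2, r_factor = 0.2) {
  if (length(x) < m + 2L) stop_fhr("series too short for SampEn")
  s <- stats::sd(x)
  if (s == 0) return(0)
  cnt <- sampen_counts_cpp(as.numeric(x), as.integer(m), r_factor * s)
  if (cnt$B == 0 || cnt$A == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  -log(cnt$A / cnt$B)
}

#' Lempel-Ziv complexity of a quantized series
#'
#' The series is quantized (binary split at the median, or ternary split
#' at the tertiles), parsed with the LZ76 phrase-counting scheme, and
#' normalized by the asymptotic random-sequence rate: `c(n) * log_a(n) / n`
#' for an alphabet of size `a`, so an i.i.d. symbol stream scores near 1.
#'
#' @param x numeric series (length >= 2).
#' @param quantize `"median"` (binary) or `"tertile"` (ternary).
#' @return Normalized complexity (dimensionless).
#' @export
lempel_ziv_complexity <- function(x, quantize = c("median", "tertile")) {
  quantize <- match.arg(quantize)
  n <- length(x)
  if (n < 2L) stop_fhr("series too short for LZC")
  if (quantize == "median") {
    sym <- as.integer(x > stats::median(x))
    a <- 2
  } else {
    qs <- stats::quantile(x, c(1 / 3, 2 / 3), names = FALSE)
    sym <- as.integer(x > qs[1]) + as.integer(x > qs[2])
    a <- 3
  }
  c_n <- lz76_cpp(sym)
  c_n * (log(n) / log(a)) / n
}

#' LZ76 phrase count
#'
#' Raw phrase count of the exhaustive-history Lempel-Ziv parse of an
#' integer symbol sequence (exposed for verification against hand parses).
#'
#' @param symbols integer vector of symbols.
#' @return Integer phrase count.
#' @export
lz76_phrase_count <- function(symbols) {
  lz76_cpp(as.integer(symbols))
}

#' Fractal dimension estimators
#'
#' Four classical FD estimates of a sampled curve:
#' \describe{
#'   \item{fd_variance}{variance method: FD = 2 - H with H half the slope
#'     of log Var(x_{t+k} - x_t) against log k}
#'   \item{fd_boxcount}{box counting on the graph normalized to the unit
#'     square}
#'   \item{fd_sevcik}{Sevcik's normalized-length formula
#'     1 + ln(L) / ln(2 (n-1))}
#'   \item{fd_higuchi_k8, fd_higuchi_k16}{Higuchi's curve-length slope
#'     with k_max = 8 and 16}
#' }
#' Degenerate (constant) series return 1 by convention.
#'
#' @param x numeric series (length >= 128).
#' @return Named list of the five estimates.
#' @export
fractal_dimensions <- function(x) {
  n <- length(x)
  if (n < 128L) stop_fhr("series too short for fractal dimensions")
  if (stats::sd(x) == 0) {
    return(list(fd_variance = 1, fd_boxcount = 1, fd_sevcik = 1,
                fd_higuchi_k8 = 1, fd_higuchi_k16 = 1))
  }
  list(fd_variance = fd_variance(x),
       fd_boxcount = fd_boxcount(x),
       fd_sevcik = fd_sevcik(x),
       fd_higuchi_k8 = fd_higuchi(x, 8L),
       fd_higuchi_k16 = fd_higuchi(x, 16L))
}

fd_variance <- function(x, k_max = 10L) {
  ks <- seq_len(min(k_max, length(x) %/% 4))
  v <- vapply(ks, function(k) stats::var(diff(x, lag = k)), numeric(1))
  keep <- v > 0
  if (sum(keep) < 2L) return(1)
  h <- stats::coef(stats::lm(log(v[keep]) ~ log(ks[keep])))[[2]] / 2
  2 - max(min(h, 1), 0)
}

fd_boxcount <- function(x) {
  n <- length(x)
  t <- (seq_len(n) - 1) / (n - 1)
  y <- (x - min(x)) / (max(x) - min(x))
  ks <- 2:7
  counts <- vapply(ks, function(k) {
    nb <- 2^k
    ix <- pmin(floor(t * nb), nb - 1)
    iy <- pmin(floor(y * nb), nb - 1)
    # count boxes crossed, spanning the vertical extent within each column
    cells <- 0L
    for (col in unique(ix)) {
      ys <- iy[ix == col]
      cells <- cells + (max(ys) - min(ys) + 1L)
    }
    as.numeric(cells)
  }, numeric(1))
  stats::coef(stats::lm(log(counts) ~ log(2^ks)))[[2]]
}

fd_sevcik <- function(x) {
  n <- length(x)
  y <- (x - min(x)) / (max(x) - min(x))
  t <- (seq_len(n) - 1) / (n - 1)
  L <- sum(sqrt(diff(t)^2 + diff(y)^2))
  1 + log(L) / log(2 * (n - 1))
}

fd_higuchi <- function(x, k_max = 8L) {
  L <- higuchi_lengths_cpp(as.numeric(x), as.integer(k_max))
  ks <- seq_len(k_max)
  keep <- L > 0
  if (sum(keep) < 2L) return(1)
  stats::coef(stats::lm(log(L[keep]) ~ log(1 / ks[keep])))[[2]]
}

#' Detrended fluctuation analysis
#'
#' First-order DFA: integrate the mean-removed series, split into
#' non-overlapping boxes of size s (logarithmically spaced in
#' `[4, n/4]`), detrend each box linearly, and regress log RMS
#' fluctuation on log s. Returns the overall scaling exponent together
#' with the short-scale (boxes of 4-16 samples) and longer-scale (16-64)
#' exponents.
#'
#' @param x numeric series (length >= 512 recommended).
#' @param n_scales number of box sizes.
#' @return Named list `dfa_alpha`, `dfa_alpha1`, `dfa_alpha2`; `NA`
#'   (flagged) for a zero-variance series.
#' @export
dfa_alpha <- function(x, n_scales = 16) {
  n <- length(x)
  if (n < 64L) stop_fhr("series too short for DFA")
  if (stats::sd(x) == 0) {
    na <- structure(NA_real_, undefined = TRUE)
    return(list(dfa_alpha = na, dfa_alpha1 = na, dfa_alpha2 = na))
  }
  prof <- cumsum(x - mean(x))
  scales <- unique(round(exp(seq(log(4), log(n / 4), length.out = n_scales))))
  fl <- vapply(scales, function(s) {
    n_box <- n %/% s
    idx <- seq_len(n_box * s)
    m <- matrix(prof[idx], nrow = s)
    t <- seq_len(s)
    # linear detrend each column: residuals of lm(prof ~ t), vectorized
    tc <- t - mean(t)
    beta <- colSums(m * tc) / sum(tc^2)
    resid <- m - outer(tc, beta) - rep(colMeans(m), each = s)
    sqrt(mean(resid^2))
  }, numeric(1))
  fit_range <- function(lo, hi) {
    keep <- scales >= lo & scales <= hi & fl > 0
    if (sum(keep) < 2L) return(NA_real_)
    stats::coef(stats::lm(log(fl[keep]) ~ log(scales[keep])))[[2]]
  }
  list(dfa_alpha = fit_range(4, n / 4),
       dfa_alpha1 = fit_range(4, 16),
       dfa_alpha2 = fit_range(16, 64))
}
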