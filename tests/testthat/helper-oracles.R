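# Independent brute-force oracles and small fixture builders. These are
# deliberately naive O(n^2) / enumeration implementations, kept separate
# from the package code paths they check.

# pairwise-comparison AUC with half credit for ties
auc_oracle <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (q in neg) {
    if (p > q) wins <- wins + 1
    else if (p == q) wins <- wins + 0.5
  }
  wins / (length(pos) * length(neg))
}

# Pincus ApEn by direct template counting (self-matches included)
apen_oracle <- function(x, m, r) {
  phi <- function(mm) {
    nt <- length(x) - mm + 1
    templ <- sapply(seq_len(nt), function(i) x[i:(i + mm - 1)])
    templ <- matrix(templ, nrow = mm)
    cnt <- vapply(seq_len(nt), function(i) {
      sum(vapply(seq_len(nt), function(j) {
        max(abs(templ[, i] - templ[, j])) <= r
      }, logical(1)))
    }, numeric(1))
    mean(log(cnt / nt))
  }
  phi(m) - phi(m + 1)
}

# Richman-Moorman SampEn counts by direct pair enumeration
sampen_oracle <- function(x, m, r) {
  nt <- length(x) - m
  A <- 0; B <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  list(A = A, B = B,
       value = if (A > 0 && B > 0) -log(A / B) else NA_real_)
}

# LZ76 phrase count by literal definition: a new phrase ends as soon as
# the current substring does not occur starting before the phrase start
lz76_oracle <- function(s) {
  n <- length(s)
  if (n == 0) return(0)
  occurs_before <- function(start, stop) {
    # does s[start..stop] occur starting at any p < start?
    len <- stop - start + 1
    if (start == 1) return(FALSE)
    for (p in seq_len(start - 1)) {
      if (p + len - 1 > n) break
      if (all(s[p:(p + len - 1)] == s[start:stop])) return(TRUE)
    }
    FALSE
  }
  c_cnt <- 0
  i <- 1
  while (i <= n) {
    k <- i
    while (k <= n && occurs_before(i, k)) k <- k + 1
    # phrase is s[i..k] (first novel extension, or sequence end)
    c_cnt <- c_cnt + 1
    i <- k + 1
  }
  c_cnt
}

# spectrally shaped 1/f^alpha noise (alpha = 1 gives pink noise)
one_over_f_noise <- function(n, alpha = 1) {
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)
  X <- X / f^(alpha / 2)
  Re(stats::fft(X, inverse = TRUE)) / n
}

# Gaussian-feature table for protocol-level tests: `d` features, the
# first `n_informative` shifted by `effect` SDs in the positive class
toy_feature_table <- function(n_pos, n_neg, d = 3, n_informative = d,
                              effect = 2, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm((n_pos + n_neg) * d), ncol = d)
    X[seq_len(n_pos), seq_len(n_informative)] <-
      X[seq_len(n_pos), seq_len(n_informative)] + effect
    colnames(X) <- paste0("f", seq_len(d))
    tibble::as_tibble(X) |>
      dplyr::mutate(
        record_id = sprintf("r%03d", dplyr::row_number()),
        label = c(rep(1L, n_pos), rep(-1L, n_neg)),
        .before = 1
      )
  })
}

# wrap a bare numeric vector as an fhr_clean with everything valid
as_clean <- function(x, fs = 4) {
  interpolate_gaps(as.numeric(x), fs = fs)
}

# desk-scale generator settings used by pipeline-level tests: shorter
# records, lighter artifact load so every record supports the 1024-sample
# spectral window
desk_config <- function(...) {
  args <- list(duration_s = 768, gap_rate = 0.25, long_gap_prob = 0.05,
               spike_rate = 1)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(generator_config, args)
}
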