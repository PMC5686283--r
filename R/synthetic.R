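# Synthetic FHR generator: baseline wander within the physiological
# 110-160 bpm band, AR(2)-shaped broadband variability, narrowband
# VLF/LF/MF oscillations, trapezoidal acceleration/deceleration events,
# impulsive spike artifacts, and zeroed dropout gaps both below and above
# the interpolation threshold. Class structure (abnormal = acidotic
# outcome) enters through multiplicative effect ratios on variability,
# band amplitudes, and event rates.

#' Generator configuration
#'
#' Defaults emulate the clinical benchmark conditions: 30-minute records
#' at 4 Hz, baseline 110-160 bpm, and an artifact model (spikes plus
#' dropout gaps) whose short-artifact load averages about 14% of the
#' record, with roughly one dropout per minute of which a fifth exceed
#' the 15 s interpolation limit. Abnormal-class ratios encode reduced
#' variability and LF power, fewer accelerations, more decelerations,
#' and more very-low-frequency power; `effect_size` exponentiates all
#' ratios (0 = identical classes, 1 = the default separation).
#'
#' @param duration_s record length in seconds.
#' @param fs sampling rate in Hz.
#' @param baseline_range bpm interval the baseline level is drawn from.
#' @param baseline_drift_bpm SD of the slow baseline wander.
#' @param variability_sd_bpm SD of the AR(2) broadband variability
#'   (normal class).
#' @param vlf_amp_bpm,lf_amp_bpm,mf_amp_bpm narrowband component
#'   amplitudes (normal class).
#' @param vlf_freq,lf_freq,mf_freq frequency ranges (Hz) the component
#'   frequencies are drawn from.
#' @param accel_rate,decel_rate events per minute (normal class).
#' @param accel_amp_bpm,decel_amp_bpm event amplitude ranges (bpm,
#'   positive numbers; decelerations are applied downward).
#' @param event_dur_s event duration range in seconds (including ramps).
#' @param event_ramp_s linear ramp time at each end of an event.
#' @param n_accel,n_decel optional fixed event counts overriding the
#'   Poisson draws (used for deterministic recovery checks).
#' @param spike_rate spike artifacts per minute; each spans
#'   `spike_len_samples` and takes a non-physiological value, so
#'   preprocessing removes it.
#' @param spike_len_samples range of spike lengths.
#' @param gap_rate dropout gaps per minute (samples zeroed).
#' @param short_gap_s,long_gap_s gap-duration ranges (s) for the two
#'   mixture components.
#' @param long_gap_prob probability a gap is drawn from the long
#'   component.
#' @param between_sd_log SD (log scale) of the per-record lognormal
#'   jitter applied to variability, band amplitudes, event rates, and
#'   artifact rates — the between-subject physiological heterogeneity
#'   that sets how separable the classes can be (0.3 corresponds to a
#'   ~30% coefficient of variation between records).
#' @param variability_ratio,lf_ratio,vlf_ratio,accel_rate_ratio,
#'   decel_rate_ratio abnormal/normal multiplicative effects.
#' @param effect_size exponent applied to every class ratio.
#' @param ph_abnormal,ph_normal class-conditional pH ranges.
#' @return A list of class `fhr_gen_config`.
#' @export
generator_config <- function(duration_s = 1800, fs = 4,
                             baseline_range = c(110, 160),
                             baseline_drift_bpm = 3,
                             variability_sd_bpm = 6,
                             vlf_amp_bpm = 2, lf_amp_bpm = 3,
                             mf_amp_bpm = 1.5,
                             vlf_freq = c(0.01, 0.025),
                             lf_freq = c(0.04, 0.1),
                             mf_freq = c(0.18, 0.3),
                             accel_rate = 0.3, decel_rate = 0.1,
                             accel_amp_bpm = c(20, 30),
                             decel_amp_bpm = c(20, 35),
                             event_dur_s = c(25, 60),
                             event_ramp_s = 5,
                             n_accel = NULL, n_decel = NULL,
                             spike_rate = 3.6,
                             spike_len_samples = c(1, 3),
                             gap_rate = 1.1,
                             short_gap_s = c(2, 15),
                             long_gap_s = c(16, 40),
                             long_gap_prob = 0.1,
                             between_sd_log = 0.3,
                             variability_ratio = 0.75,
                             lf_ratio = 0.65,
                             vlf_ratio = 1.5,
                             accel_rate_ratio = 0.5,
                             decel_rate_ratio = 2.5,
                             effect_size = 1,
                             ph_abnormal = c(6.85, 7.05),
                             ph_normal = c(7.06, 7.35)) {
  cfg <- as.list(environment())
  n <- duration_s * fs
  if (abs(n - round(n)) > 1e-9) {
    stop_fhr("duration_s * fs must be an integer sample count")
  }
  if (duration_s <= 0 || fs <= 0) stop_fhr("invalid duration or fs")
  rates <- c(accel_rate, decel_rate, spike_rate, gap_rate)
  if (any(rates < 0)) stop_fhr("rates must be non-negative")
  structure(cfg, class = "fhr_gen_config")
}

runif1 <- function(range) stats::runif(1, range[1], range[2])

#' Generate one synthetic FHR record
#'
#' @param class_label +1 (abnormal) or -1 (normal).
#' @param config an [generator_config()].
#' @param seed RNG seed (record is a deterministic function of it).
#' @param record_id identifier.
#' @return List with `record` (an [fhr_record()] with a class-consistent
#'   pH attached) and `truth`: every injected parameter and event
#'   (baseline level, component amplitudes/frequencies, event table,
#'   spike/gap masks, counts).
#' @export
generate_record <- function(class_label, config = generator_config(),
                            seed = 1, record_id = NULL) {
  stopifnot(inherits(config, "fhr_gen_config"))
  if (!class_label %in% c(-1, 1)) stop_fhr("class_label must be +1 or -1")
  cfg <- config
  abn <- class_label == 1
  es <- cfg$effect_size
  eff <- function(ratio) if (abn) ratio^es else 1
  n <- as.integer(round(cfg$duration_s * cfg$fs))
  fs <- cfg$fs
  t <- (seq_len(n) - 1) / fs
  minutes <- cfg$duration_s / 60
  if (is.null(record_id)) {
    record_id <- sprintf("syn_%s_%d", if (abn) "abn" else "nor", seed)
  }
  with_seed(seed, {
    # per-record physiological heterogeneity: lognormal multipliers on
    # every rate/amplitude parameter (drawn first, so the record's
    # deterministic structure follows them)
    jit <- function() {
      if (cfg$between_sd_log > 0) exp(stats::rnorm(1, 0, cfg$between_sd_log))
      else 1
    }
    j_var <- jit(); j_vlf <- jit(); j_lf <- jit(); j_mf <- jit()
    j_acc <- jit(); j_dec <- jit(); j_spike <- jit(); j_gap <- jit()
    level <- runif1(cfg$baseline_range)
    drift <- if (cfg$baseline_drift_bpm > 0) {
      d <- fft_lowpass(stats::rnorm(n), fs, 0.003)
      if (stats::sd(d) > 0) d * (cfg$baseline_drift_bpm / stats::sd(d))
      else d
    } else numeric(n)
    baseline <- pmin(pmax(level + drift, cfg$baseline_range[1]),
                     cfg$baseline_range[2])

    var_sd <- cfg$variability_sd_bpm * eff(cfg$variability_ratio) * j_var
    broadband <- if (var_sd > 0) {
      b <- as.numeric(stats::arima.sim(list(ar = c(1.2, -0.45)), n))
      b * (var_sd / stats::sd(b))
    } else numeric(n)

    comp <- function(amp, freq_range) {
      if (amp <= 0) return(numeric(n))
      f <- runif1(freq_range)
      amp * sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
    }
    vlf <- comp(cfg$vlf_amp_bpm * eff(cfg$vlf_ratio) * j_vlf, cfg$vlf_freq)
    lf <- comp(cfg$lf_amp_bpm * eff(cfg$lf_ratio) * j_lf, cfg$lf_freq)
    mf <- comp(cfg$mf_amp_bpm * j_mf, cfg$mf_freq)

    draw_events <- function(rate, ratio, fixed, amp_range, sign) {
      k <- if (!is.null(fixed)) fixed
           else stats::rpois(1, rate * eff(ratio) * minutes)
      if (k == 0L) {
        return(tibble::tibble(type = character(0), start_s = numeric(0),
                              dur_s = numeric(0), amp_bpm = numeric(0)))
      }
      durs <- stats::runif(k, cfg$event_dur_s[1], cfg$event_dur_s[2])
      amps <- sign * stats::runif(k, amp_range[1], amp_range[2])
      tibble::tibble(type = if (sign > 0) "accel" else "decel",
                     start_s = rep(NA_real_, k), dur_s = durs,
                     amp_bpm = amps)
    }
    ev <- dplyr::bind_rows(
      draw_events(cfg$accel_rate * j_acc, cfg$accel_rate_ratio,
                  cfg$n_accel, cfg$accel_amp_bpm, +1),
      draw_events(cfg$decel_rate * j_dec, cfg$decel_rate_ratio,
                  cfg$n_decel, cfg$decel_amp_bpm, -1)
    )
    # greedy placement with a 10 s separation margin; overlaps allowed
    # only when the requested event load cannot fit
    if (nrow(ev) > 0L) {
      ev <- ev[sample.int(nrow(ev)), , drop = FALSE]
      placed <- numeric(0) # accepted (start, end) pairs, flat
      for (i in seq_len(nrow(ev))) {
        d <- ev$dur_s[i]
        ok_start <- NA_real_
        for (try in seq_len(50L)) {
          s0 <- stats::runif(1, 0, max(cfg$duration_s - d, 0))
          clash <- FALSE
          if (length(placed)) {
            m <- matrix(placed, ncol = 2, byrow = TRUE)
            clash <- any(s0 < m[, 2] + 10 & s0 + d > m[, 1] - 10)
          }
          if (!clash) { ok_start <- s0; break }
        }
        if (is.na(ok_start)) ok_start <- stats::runif(1, 0, max(cfg$duration_s - d, 0))
        ev$start_s[i] <- ok_start
        placed <- c(placed, ok_start, ok_start + d)
      }
    }
    events_sig <- numeric(n)
    if (nrow(ev) > 0L) {
      for (i in seq_len(nrow(ev))) {
        s0 <- ev$start_s[i]; d <- ev$dur_s[i]
        ramp <- min(cfg$event_ramp_s, d / 3)
        # trapezoid: linear ramps, flat plateau
        u <- (t - s0) / ramp
        v <- (s0 + d - t) / ramp
        shape <- pmin(pmax(pmin(u, v), 0), 1)
        events_sig <- events_sig + ev$amp_bpm[i] * shape
      }
    }

    fhr <- baseline + broadband + vlf + lf + mf + events_sig
    fhr <- pmin(pmax(fhr, 55), 198) # physiological saturation

    # impulsive spike artifacts: non-physiological values, removed later
    spike_mask <- rep(FALSE, n)
    n_spikes <- stats::rpois(1, cfg$spike_rate * j_spike * minutes)
    if (n_spikes > 0L) {
      for (s in seq_len(n_spikes)) {
        len <- sample(seq(cfg$spike_len_samples[1],
                          cfg$spike_len_samples[2]), 1L)
        at <- sample.int(n - len + 1L, 1L)
        idx <- at:(at + len - 1L)
        fhr[idx] <- if (stats::runif(1) < 0.5) stats::runif(1, 201, 240)
                    else stats::runif(1, 25, 49)
        spike_mask[idx] <- TRUE
      }
    }

    # dropout gaps: zeroed samples, mixture of short and long durations
    gap_mask <- rep(FALSE, n)
    gaps <- tibble::tibble(start_s = numeric(0), dur_s = numeric(0),
                           long = logical(0))
    n_gaps <- stats::rpois(1, cfg$gap_rate * j_gap * minutes)
    if (n_gaps > 0L) {
      for (g in seq_len(n_gaps)) {
        long <- stats::runif(1) < cfg$long_gap_prob
        d <- if (long) runif1(cfg$long_gap_s) else runif1(cfg$short_gap_s)
        d <- min(d, cfg$duration_s / 2)
        s0 <- stats::runif(1, 0, cfg$duration_s - d)
        idx <- (floor(s0 * fs) + 1L):min(n, floor((s0 + d) * fs))
        fhr[idx] <- 0
        gap_mask[idx] <- TRUE
        gaps <- dplyr::bind_rows(gaps, tibble::tibble(
          start_s = s0, dur_s = d, long = long))
      }
    }

    ph <- if (abn) runif1(cfg$ph_abnormal) else runif1(cfg$ph_normal)
    record <- fhr_record(fhr, fs = fs, record_id = record_id, ph = ph)
    truth <- list(
      class_label = class_label, baseline_level = level,
      baseline = baseline, variability_sd = var_sd,
      jitter = c(var = j_var, vlf = j_vlf, lf = j_lf, mf = j_mf,
                 accel = j_acc, decel = j_dec, spike = j_spike,
                 gap = j_gap),
      events = ev, n_accel = sum(ev$type == "accel"),
      n_decel = sum(ev$type == "decel"),
      spike_mask = spike_mask, gap_mask = gap_mask, gaps = gaps,
      n_spikes = n_spikes, n_gaps = n_gaps, ph = ph, seed = seed
    )
    list(record = record, truth = truth)
  })
}

#' Generate a labeled synthetic dataset
#'
#' @param n_normal,n_abnormal class sizes (benchmark imbalance is
#'   508:44; desk runs scale this down, e.g. 127:11).
#' @param config an [generator_config()].
#' @param seed master seed; per-record seeds are derived from it.
#' @return List with `records` (named list of [fhr_record()]s), `meta`
#'   (tibble `record_id`, `ph`, `label`), and `truths` (named list).
#' @export
generate_dataset <- function(n_normal, n_abnormal,
                             config = generator_config(), seed = 1) {
  if (n_normal + n_abnormal < 2L) stop_fhr("need at least 2 records")
  labels <- c(rep(-1, n_normal), rep(1, n_abnormal))
  out <- lapply(seq_along(labels), function(i) {
    generate_record(labels[i], config, seed = derive_seed(seed, i),
                    record_id = sprintf("syn%04d", i))
  })
  records <- lapply(out, `[[`, "record")
  names(records) <- vapply(records, `[[`, "", "record_id")
  truths <- lapply(out, `[[`, "truth")
  names(truths) <- names(records)
  meta <- tibble::tibble(
    record_id = names(records),
    ph = vapply(records, `[[`, 0, "ph"),
    label = labels
  )
  list(records = records, meta = meta, truths = truths)
}

#' Class composition of a labeled dataset
#'
#' Applies the pH <= 7.05 rule to a table of outcomes and tallies the
#' classes; the composition summary reported for any benchmark dataset.
#'
#' @param meta data frame with a `ph` column (a `label` column, if
#'   present, is cross-checked against the rule).
#' @return One-row tibble `n_records`, `n_abnormal`, `n_normal`.
#' @export
dataset_composition <- function(meta) {
  if (!is.data.frame(meta) || !"ph" %in% names(meta)) {
    stop_fhr("`meta` must be a data frame with a `ph` column")
  }
  lab <- label_from_ph(meta$ph)
  if ("label" %in% names(meta) && !all(lab == meta$label)) {
    stop_fhr("stored labels disagree with the pH <= 7.05 rule")
  }
  tibble::tibble(
    n_records = length(lab),
    n_abnormal = sum(lab == 1),
    n_normal = sum(lab == -1)
  )
}

#' Plot a synthetic or clinical record with its cleaned version
#'
#' @param record an [fhr_record()].
#' @param clean optional `fhr_clean`; computed if missing.
#' @return A ggplot of the raw and cleaned traces.
#' @export
plot_record <- function(record, clean = preprocess_record(record)) {
  n <- length(record$fhr)
  t <- (seq_len(n) - 1) / record$fs
  d <- tibble::tibble(
    time_s = rep(t, 2),
    bpm = c(record$fhr, ifelse(clean$valid_mask, clean$fhr, NA)),
    trace = rep(c("raw", "clean"), each = n)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$bpm,
                                  colour = .data$trace)) +
    ggplot2::geom_line(na.rm = TRUE, linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "FHR (bpm)",
                  title = record$record_id) +
    ggplot2::theme_minimal()
}
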