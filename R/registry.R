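# The canonical 54-variant feature bank. 21 base measures expanded by
# internal parameters (entropy r/m grid, two spectral band systems and
# relative powers, two Higuchi scales, DFA scale splits, two LZC
# quantizations, Poincare geometry and ratio). The registry order is fixed
# and defines the feature-vector layout everywhere downstream.

#' The canonical feature registry
#'
#' One row per feature variant: `name`, `domain` (`figo`, `time`, `freq`,
#' `nonlinear`), `representation` (the signal the feature is computed on:
#' `bpm` or `rr`), and a parameter description. 54 rows; the order defines
#' the feature-vector layout and the stable tie-break used in ranking.
#'
#' @return A 54-row tibble.
#' @export
feature_registry <- function() {
  reg <- list(
    # FIGO-based macroscopic descriptors (bpm)
    c("baseline_mean", "figo", "bpm", "mean of baseline trend"),
    c("baseline_sd", "figo", "bpm", "sd of baseline trend"),
    c("n_accel", "figo", "bpm", ">= +15 bpm for >= 15 s"),
    c("n_decel", "figo", "bpm", "<= -15 bpm for >= 15 s"),
    c("delta_total", "figo", "bpm", "sum of per-minute detrended range"),
    # time-domain variability (RR ms)
    c("stv", "time", "rr", "2.5 s epoch means"),
    c("stv_haan", "time", "rr", "IQR of successive differences"),
    c("stv_yeh", "time", "rr", "differential index x1000"),
    c("sonicaid", "time", "rr", "3.75 s epochs per minute"),
    c("sdnn", "time", "rr", "sample SD"),
    c("delta", "time", "rr", "mean per-minute range"),
    c("lti_haa", "time", "rr", "IQR of successive-pair modulus"),
    c("rmssd", "time", "rr", "RMS of successive differences"),
    c("mad_rr", "time", "rr", "median absolute deviation"),
    c("iqr_rr", "time", "rr", "interquartile range"),
    # frequency domain, band system "sig" (bpm)
    c("vlf_sig", "freq", "bpm", "0-0.03 Hz"),
    c("lf_sig", "freq", "bpm", "0.03-0.15 Hz"),
    c("mf_sig", "freq", "bpm", "0.15-0.5 Hz"),
    c("hf_sig", "freq", "bpm", "0.5-1 Hz"),
    c("lf_hf_sig", "freq", "bpm", "LF/HF ratio"),
    c("total_power_sig", "freq", "bpm", "0-1 Hz"),
    c("rel_lf_sig", "freq", "bpm", "LF / total"),
    c("rel_mf_sig", "freq", "bpm", "MF / total"),
    c("rel_hf_sig", "freq", "bpm", "HF / total"),
    # frequency domain, band system "alt" (bpm)
    c("vlf_alt", "freq", "bpm", "0-0.03 Hz"),
    c("lf_alt", "freq", "bpm", "0.03-0.07 Hz"),
    c("mf_alt", "freq", "bpm", "0.07-0.13 Hz"),
    c("hf_alt", "freq", "bpm", "0.13-1 Hz"),
    c("lf_mfhf_alt", "freq", "bpm", "LF/(MF+HF) ratio"),
    c("total_power_alt", "freq", "bpm", "0-1 Hz"),
    c("rel_lf_alt", "freq", "bpm", "LF / total"),
    c("rel_mf_alt", "freq", "bpm", "MF / total"),
    c("rel_hf_alt", "freq", "bpm", "HF / total"),
    # nonlinear (fractal/scaling on bpm; entropies and Poincare on RR)
    c("fd_variance", "nonlinear", "bpm", "variance-of-increments slope"),
    c("fd_boxcount", "nonlinear", "bpm", "box counting"),
    c("fd_sevcik", "nonlinear", "bpm", "normalized length"),
    c("fd_higuchi_k8", "nonlinear", "bpm", "k_max = 8"),
    c("fd_higuchi_k16", "nonlinear", "bpm", "k_max = 16"),
    c("dfa_alpha", "nonlinear", "bpm", "scales 4-n/4"),
    c("dfa_alpha1", "nonlinear", "bpm", "scales 4-16"),
    c("dfa_alpha2", "nonlinear", "bpm", "scales 16-64"),
    c("apen_r015_m2", "nonlinear", "rr", "r=0.15 sd, m=2"),
    c("apen_r015_m3", "nonlinear", "rr", "r=0.15 sd, m=3"),
    c("apen_r02_m2", "nonlinear", "rr", "r=0.2 sd, m=2"),
    c("apen_r02_m3", "nonlinear", "rr", "r=0.2 sd, m=3"),
    c("sampen_r015_m2", "nonlinear", "rr", "r=0.15 sd, m=2"),
    c("sampen_r015_m3", "nonlinear", "rr", "r=0.15 sd, m=3"),
    c("sampen_r02_m2", "nonlinear", "rr", "r=0.2 sd, m=2"),
    c("sampen_r02_m3", "nonlinear", "rr", "r=0.2 sd, m=3"),
    c("lzc_median", "nonlinear", "bpm", "binary at median"),
    c("lzc_tertile", "nonlinear", "bpm", "ternary at tertiles"),
    c("sd1", "nonlinear", "rr", "Poincare short axis"),
    c("sd2", "nonlinear", "rr", "Poincare long axis"),
    c("sd1_sd2_ratio", "nonlinear", "rr", "SD1/SD2")
  )
  tibble::tibble(
    name = vapply(reg, `[[`, "", 1),
    domain = vapply(reg, `[[`, "", 2),
    representation = vapply(reg, `[[`, "", 3),
    params = vapply(reg, `[[`, "", 4)
  )
}

#' Write / read the registry as YAML
#'
#' The canonical enumeration is serialized so a run can log exactly which
#' variants it used.
#'
#' @param registry a registry tibble (defaults to the canonical one).
#' @param path YAML path.
#' @return `path` invisibly; `read_feature_registry()` returns a tibble.
#' @export
write_feature_registry <- function(registry = feature_registry(), path) {
  yaml::write_yaml(lapply(seq_len(nrow(registry)), function(i) {
    as.list(registry[i, ])
  }), path)
  invisible(path)
}

#' @rdname write_feature_registry
#' @export
read_feature_registry <- function(path) {
  entries <- yaml::read_yaml(path)
  dplyr::bind_rows(lapply(entries, tibble::as_tibble))
}

#' Extract the full feature vector of one record
#'
#' Preprocesses the record (unless given an `fhr_clean` via `clean`),
#' concatenates valid segments, and evaluates every registry feature on
#' the appropriate representation: FIGO and spectral features on the bpm
#' signal (spectral ones per valid segment), HRV-tradition features on RR
#' intervals in ms. Extraction is fully deterministic.
#'
#' Features whose value is undefined on a record (e.g. sample entropy with
#' no template matches) are returned as `NA` and listed in the
#' `failed_features` attribute.
#'
#' @param record an [fhr_record()].
#' @param registry feature registry tibble.
#' @param min_segment_s minimum valid-segment duration used (seconds).
#' @param max_gap_s,bpm_min,bpm_max preprocessing parameters.
#' @return A one-row tibble `record_id`, `label`, then the 54 features in
#'   registry order; attribute `failed_features` names any undefined ones.
#' @export
extract_features <- function(record, registry = feature_registry(),
                             min_segment_s = 60, max_gap_s = 15,
                             bpm_min = 50, bpm_max = 200) {
  stopifnot(inherits(record, "fhr_record"))
  clean <- preprocess_record(record, bpm_min = bpm_min, bpm_max = bpm_max,
                             max_gap_s = max_gap_s)
  segs <- valid_segments(clean, min_segment_s)
  if (nrow(segs) == 0L) {
    stop_fhr("no valid segment long enough for feature extraction",
             class = "fhrbench_extraction_error")
  }
  bpm <- unlist(lapply(seq_len(nrow(segs)), function(i) {
    clean$fhr[segs$start[i]:(segs$end[i] - 1L)]
  }), use.names = FALSE)
  rr <- rr_from_bpm(pmin(pmax(bpm, bpm_min), bpm_max))
  fs <- clean$fs

  vals <- list()
  bl <- estimate_baseline(clean, min_segment_s = min_segment_s)
  vals <- c(vals, figo_features(clean, bl))
  vals <- c(vals, time_domain_features(rr, fs = fs))
  vals <- c(vals, spectral_features(clean))
  vals <- c(vals, fractal_dimensions(bpm))
  vals <- c(vals, dfa_alpha(bpm))
  for (r in c("015", "02")) {
    rf <- if (r == "015") 0.15 else 0.2
    for (m in c(2L, 3L)) {
      vals[[sprintf("apen_r%s_m%d", r, m)]] <-
        approx_entropy(rr, m = m, r_factor = rf)
      vals[[sprintf("sampen_r%s_m%d", r, m)]] <-
        sample_entropy(rr, m = m, r_factor = rf)
    }
  }
  vals$lzc_median <- lempel_ziv_complexity(bpm, "median")
  vals$lzc_tertile <- lempel_ziv_complexity(bpm, "tertile")
  vals <- c(vals, poincare_sd(rr))

  missing_names <- setdiff(registry$name, names(vals))
  if (length(missing_names)) {
    stop_fhr(paste("registry features not computed:",
                   paste(missing_names, collapse = ", ")))
  }
  v <- vapply(registry$name, function(nm) as.numeric(vals[[nm]]), numeric(1))
  failed <- registry$name[!is.finite(v)]
  out <- tibble::as_tibble(c(
    list(record_id = record$record_id,
         label = if (is.null(record$label)) NA_integer_
                 else as.integer(record$label)),
    as.list(v)
  ))
  attr(out, "failed_features") <- failed
  out
}

#' Extract a feature matrix from a set of records
#'
#' @param records list of [fhr_record()] objects.
#' @param registry feature registry tibble.
#' @param ... passed to [extract_features()].
#' @return Tibble with one row per record: `record_id`, `label`, then the
#'   features in registry order. Records with undefined features keep
#'   `NA` in those cells; the union of failures is attached as the
#'   `failed_features` attribute (named by record).
#' @export
extract_dataset <- function(records, registry = feature_registry(), ...) {
  rows <- lapply(records, extract_features, registry = registry, ...)
  fails <- lapply(rows, attr, "failed_features")
  names(fails) <- vapply(rows, function(r) r$record_id[1], "")
  fails <- fails[vapply(fails, length, 0L) > 0L]
  out <- dplyr::bind_rows(rows)
  attr(out, "failed_features") <- fails
  out
}
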