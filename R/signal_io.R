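#' Construct an FHR record
#'
#' The basic container for a uniformly sampled fetal heart rate trace in
#' beats per minute, optionally carrying the umbilical-artery pH outcome.
#' When `ph` is supplied and `label` is not, the label is derived by the
#' pH <= 7.05 rule (see [label_from_ph()]).
#'
#' @param fhr numeric vector of beats-per-minute samples. Zeros are legal
#'   here (signal dropout as distributed in clinical archives) and are
#'   flagged later by preprocessing.
#' @param fs sampling frequency in Hz; clinical CTG archives use 4 Hz.
#' @param record_id identifier string.
#' @param ph umbilical artery pH, or `NULL` if unknown.
#' @param label class label `+1` (abnormal) or `-1` (normal), or `NULL`.
#' @return An object of class `fhr_record`: a list with elements
#'   `record_id`, `fhr`, `fs`, `ph`, `label`.
#' @export
fhr_record <- function(fhr, fs = 4, record_id = "record", ph = NULL,
                       label = NULL) {
  fhr <- as.numeric(fhr)
  if (length(fhr) < 1L) stop_fhr("`fhr` must contain at least one sample")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop_fhr("`fs` must be a single positive number")
  }
  if (!is.null(ph)) {
    if (!is.numeric(ph) || length(ph) != 1L) {
      stop_fhr("`ph` must be a single numeric value")
    }
    if (is.null(label)) label <- label_from_ph(ph)
  }
  if (!is.null(label)) {
    if (!label %in% c(-1, 1)) stop_fhr("`label` must be +1 or -1")
    if (!is.null(ph) && label != label_from_ph_quiet(ph)) {
      stop_fhr("`label` inconsistent with `ph` under the pH <= 7.05 rule")
    }
  }
  structure(
    list(record_id = as.character(record_id), fhr = fhr, fs = fs,
         ph = ph, label = label),
    class = "fhr_record"
  )
}

#' @export
print.fhr_record <- function(x, ...) {
  dur <- length(x$fhr) / x$fs
  cat(sprintf("<fhr_record '%s'>  %d samples @ %g Hz (%.1f s)",
              x$record_id, length(x$fhr), x$fs, dur))
  if (!is.null(x$ph)) cat(sprintf("  pH %.2f", x$ph))
  if (!is.null(x$label)) {
    cat(sprintf("  [%s]", if (x$label > 0) "abnormal" else "normal"))
  }
  cat("\n")
  invisible(x)
}

label_from_ph_quiet <- function(ph) if (ph <= 7.05) 1 else -1

#' Label an outcome from umbilical-artery pH
#'
#' Abnormal (acidotic) iff pH <= 7.05, the single class boundary used by
#' this benchmark; the boundary value itself is abnormal. Values outside a
#' (6.5, 7.8) plausibility window raise a warning, not an error.
#'
#' @param ph numeric vector of pH values.
#' @return Integer vector of labels, `+1` abnormal, `-1` normal.
#' @examples
#' label_from_ph(c(7.05, 7.06, 6.90))
#' @export
label_from_ph <- function(ph) {
  if (!is.numeric(ph)) stop_fhr("`ph` must be numeric")
  if (any(!is.finite(ph))) stop_fhr("`ph` must be finite")
  if (any(ph <= 6.5 | ph >= 7.8)) {
    rlang::warn("pH value outside the (6.5, 7.8) plausibility window")
  }
  ifelse(ph <= 7.05, 1L, -1L)
}

#' Read an FHR record from a plain CSV file
#'
#' Accepts either a two-column numeric CSV `time,bpm` (time in seconds) or
#' a one-column CSV of bpm values. With a time column, uniform sampling at
#' `fs` is checked to within 1e-6 s.
#'
#' @param path CSV path (comma separator, `.` decimal, no header).
#' @param fs sampling frequency in Hz.
#' @param record_id identifier; defaults to the file stem.
#' @param ph optional pH value attached to the record.
#' @return An [fhr_record()].
#' @export
read_csv_record <- function(path, fs = 4, record_id = NULL, ph = NULL) {
  if (!file.exists(path)) stop_fhr(sprintf("file not found: %s", path))
  dat <- utils::read.csv(path, header = FALSE)
  if (!all(vapply(dat, is.numeric, logical(1)))) {
    stop_fhr("CSV must be numeric (no header row)")
  }
  if (ncol(dat) == 1L) {
    bpm <- dat[[1]]
  } else if (ncol(dat) == 2L) {
    t <- dat[[1]]
    bpm <- dat[[2]]
    if (length(t) > 1L) {
      dt <- diff(t)
      if (any(abs(dt - 1 / fs) > 1e-6)) {
        stop_fhr("timestamps are not uniform at the declared sampling rate",
                 class = "fhrbench_format_error")
      }
    }
  } else {
    stop_fhr("CSV must have one (bpm) or two (time,bpm) columns",
             class = "fhrbench_format_error")
  }
  if (is.null(record_id)) {
    record_id <- sub("\\.[^.]*$", "", basename(path))
  }
  fhr_record(bpm, fs = fs, record_id = record_id, ph = ph)
}

#' Write an FHR record to a plain CSV file
#'
#' Two columns `time,bpm`, the inverse of [read_csv_record()].
#'
#' @param record an [fhr_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_csv_record <- function(record, path) {
  stopifnot(inherits(record, "fhr_record"))
  n <- length(record$fhr)
  t <- (seq_len(n) - 1) / record$fs
  lines <- sprintf("%.12g,%.12g", t, record$fhr)
  writeLines(lines, path)
  invisible(path)
}

# ---- WFDB format 16 (.hea/.dat) ------------------------------------------
# Minimal reader/writer for the header + 16-bit little-endian signal layout
# used by open CTG archives. Only what the benchmark needs: sampling rate,
# channel count, per-channel gain/baseline and description, interleaved
# int16 samples. physical = (adc - baseline) / gain.

parse_hea <- function(header_path) {
  lines <- readLines(header_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop_fhr("malformed WFDB header",
                                   class = "fhrbench_format_error")
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 4L) stop_fhr("malformed WFDB header line",
                                 class = "fhrbench_format_error")
  n_sig <- as.integer(top[2])
  fs <- as.numeric(strsplit(top[3], "/")[[1]][1])
  n_samp <- as.integer(top[4])
  sig <- lapply(lines[1 + seq_len(n_sig)], function(l) {
    tok <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(tok) < 2L) stop_fhr("malformed WFDB signal line",
                                   class = "fhrbench_format_error")
    fmt <- sub("x.*$", "", tok[2])
    gb <- tok[3]
    gain <- 200; baseline <- 0
    if (!is.na(gb)) {
      m <- regmatches(gb, regexec("^([-0-9.eE+]+)(\\(([-0-9]+)\\))?", gb))[[1]]
      if (length(m) && nzchar(m[2])) gain <- as.numeric(m[2])
      if (length(m) >= 4 && nzchar(m[4])) baseline <- as.numeric(m[4])
    }
    desc <- if (length(tok) >= 9) paste(tok[9:length(tok)], collapse = " ")
            else ""
    list(file = tok[1], format = fmt, gain = gain, baseline = baseline,
         desc = desc)
  })
  list(record = top[1], n_sig = n_sig, fs = fs, n_samp = n_samp, sig = sig)
}

#' Read an FHR record from a WFDB header/signal pair
#'
#' Supports the format-16 (16-bit little-endian, interleaved) layout used
#' by open-access CTG archives. The FHR channel is located by its header
#' description (case-insensitive match on "FHR"); if none matches, the
#' first channel is used. Zeroed samples are preserved as-is and flagged
#' later by preprocessing.
#'
#' @param header_path path to the `.hea` file; the `.dat` file must sit
#'   alongside it.
#' @param ph optional pH value attached to the record.
#' @return An [fhr_record()] with `fs` taken from the header.
#' @export
read_wfdb_record <- function(header_path, ph = NULL) {
  if (!file.exists(header_path)) {
    stop_fhr(sprintf("file not found: %s", header_path))
  }
  hea <- parse_hea(header_path)
  descs <- toupper(vapply(hea$sig, `[[`, "", "desc"))
  ch <- which(grepl("FHR", descs))[1]
  if (is.na(ch)) {
    if (any(nzchar(descs))) {
      stop_fhr("no FHR channel in WFDB record",
               class = "fhrbench_format_error")
    }
    ch <- 1L
  }
  fmt <- hea$sig[[ch]]$format
  if (fmt != "16") {
    stop_fhr(sprintf("unsupported WFDB format '%s' (only 16)", fmt),
             class = "fhrbench_format_error")
  }
  dat_path <- file.path(dirname(header_path), hea$sig[[ch]]$file)
  if (!file.exists(dat_path)) {
    stop_fhr(sprintf("signal file not found: %s", dat_path))
  }
  need <- hea$n_samp * hea$n_sig
  raw <- readBin(dat_path, what = "integer", n = need, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < need) {
    stop_fhr("truncated WFDB signal file", class = "fhrbench_io_error")
  }
  adc <- matrix(raw, nrow = hea$n_sig)[ch, ]
  phys <- (adc - hea$sig[[ch]]$baseline) / hea$sig[[ch]]$gain
  fhr_record(phys, fs = hea$fs,
             record_id = sub("\\.hea$", "", basename(header_path)),
             ph = ph)
}

#' Write an FHR record as a WFDB header/signal pair
#'
#' Inverse of [read_wfdb_record()]: format 16, single FHR channel, values
#' quantized at the given gain.
#'
#' @param record an [fhr_record()].
#' @param dir output directory.
#' @param gain ADC units per bpm.
#' @return The header path, invisibly.
#' @export
write_wfdb_record <- function(record, dir, gain = 100) {
  stopifnot(inherits(record, "fhr_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- record$record_id
  n <- length(record$fhr)
  hea <- file.path(dir, paste0(id, ".hea"))
  dat <- paste0(id, ".dat")
  writeLines(c(
    sprintf("%s 1 %g %d", id, record$fs, n),
    sprintf("%s 16 %g(0)/bpm 16 0 0 0 0 FHR", dat, gain)
  ), hea)
  adc <- as.integer(round(record$fhr * gain))
  writeBin(adc, file.path(dir, dat), size = 2L, endian = "little")
  invisible(hea)
}

#' Read all FHR records in a directory
#'
#' @param dir directory containing `.hea`/`.dat` pairs or `.csv` records.
#' @param format `"wfdb"` or `"csv"`.
#' @param fs sampling rate for CSV records (WFDB headers carry their own).
#' @param ph_table optional data frame with columns `record_id` and `ph`
#'   used to attach outcomes.
#' @return A named list of [fhr_record()] objects. Duplicate record IDs
#'   are an error.
#' @export
read_record_dir <- function(dir, format = c("wfdb", "csv"), fs = 4,
                            ph_table = NULL) {
  format <- match.arg(format)
  paths <- list.files(dir, full.names = TRUE,
                      pattern = if (format == "wfdb") "\\.hea$" else "\\.csv$")
  if (length(paths) == 0L) stop_fhr("no records found in directory")
  ph_for <- function(id) {
    if (is.null(ph_table)) return(NULL)
    hit <- match(id, ph_table$record_id)
    if (is.na(hit)) NULL else ph_table$ph[hit]
  }
  recs <- lapply(paths, function(p) {
    id <- sub("\\.[^.]*$", "", basename(p))
    if (format == "wfdb") read_wfdb_record(p, ph = ph_for(id))
    else read_csv_record(p, fs = fs, ph = ph_for(id))
  })
  ids <- vapply(recs, `[[`, "", "record_id")
  if (anyDuplicated(ids)) stop_fhr("duplicate record IDs in dataset")
  names(recs) <- ids
  recs
}

# ---- feature tables -------------------------------------------------------

#' Write a feature table to CSV
#'
#' Header row `record_id,label,<feature names...>`; values round-trip to at
#' least 12 significant digits through [read_feature_table()].
#'
#' @param features tibble with columns `record_id`, `label`, and one
#'   numeric column per feature (all rows sharing the same layout).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  if (!is.data.frame(features)) stop_fhr("`features` must be a data frame")
  need <- c("record_id", "label")
  if (!all(need %in% names(features))) {
    stop_fhr("feature table must have record_id and label columns")
  }
  fcols <- setdiff(names(features), need)
  vals <- features[fcols]
  if (!all(vapply(vals, is.numeric, logical(1)))) {
    stop_fhr("feature columns must be numeric")
  }
  if (anyNA(vals)) stop_fhr("feature table contains missing values")
  out <- data.frame(
    record_id = as.character(features$record_id),
    label = as.integer(features$label),
    lapply(vals, function(v) sprintf("%.15g", v)),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return A tibble with `record_id`, `label`, and numeric feature columns.
#' @export
read_feature_table <- function(path) {
  dat <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  dat$record_id <- as.character(dat$record_id)
  dat$label <- as.integer(dat$label)
  tibble::as_tibble(dat)
}
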