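#' Read / write ECG records as CSV
#'
#' The CSV layout is samples x leads with a header row of lead names and a
#' leading comment line `# fs: <Hz>` stating the sampling rate. Amplitudes
#' are millivolts.
#'
#' @param record An `ecg_record`.
#' @param path Output path.
#' @export
write_ecg_csv <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs: %g", ecg_fs(record)), con)
  m <- ecg_matrix(record)
  utils::write.csv(as.data.frame(m), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ecg_csv
#' @param fs Sampling rate (Hz); overrides any `# fs:` comment line.
#' @export
read_ecg_csv <- function(path, fs = NULL) {
  first <- readLines(path, n = 1)
  if (grepl("^#\\s*fs:", first)) {
    if (is.null(fs)) fs <- as.numeric(sub("^#\\s*fs:\\s*", "", first))
  }
  if (is.null(fs)) stop("sampling rate not stated; pass fs=", call. = FALSE)
  d <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  as_ecg_record(d, fs = fs)
}

#' Write ground-truth fiducials and labels as a JSON sidecar
#'
#' Sample indices are written 0-based (stated in the file); in-memory tables
#' are 1-based.
#'
#' @param truth Truth tibble (see [ecg_truth()]).
#' @param path Output path.
#' @export
write_truth_json <- function(truth, path) {
  idx_cols <- intersect(c("i", "q", "r", "s", "j", "t_start", "t_peak",
                          "t_end", "p"), names(truth))
  out <- as.list(truth[, setdiff(names(truth), "leads")])
  for (cl in idx_cols) out[[cl]] <- out[[cl]] - 1L
  payload <- list(index_base = 0L, units = "samples", beats = out)
  if ("leads" %in% names(truth)) payload$affected_leads <- truth$leads
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- tibble::as_tibble(p$beats)
  idx_cols <- intersect(c("i", "q", "r", "s", "j", "t_start", "t_peak",
                          "t_end", "p"), names(tr))
  for (cl in idx_cols) tr[[cl]] <- tr[[cl]] + (p$index_base == 0L)
  tr
}

#' Write a per-beat fiducial annotation table (TSV, 0-based indices)
#' @param fiducials Tibble from [delineate_record()].
#' @param path Output path.
#' @export
write_fiducials_tsv <- function(fiducials, path) {
  out <- fiducials
  idx_cols <- intersect(c("i", "q", "r", "s", "j", "t_start", "t_peak",
                          "t_end", "p"), names(out))
  for (cl in idx_cols) out[[cl]] <- out[[cl]] - 1L
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a 12-lead record from a WFDB header/signal pair
#'
#' Minimal reader for WFDB format 16 (16-bit little-endian two's complement,
#' interleaved): parses the `.hea` header for the sampling rate, per-signal
#' gain (ADC units per mV), baseline and lead description, converts to
#' millivolts, and keeps exactly the 12 conventional leads by name (Frank
#' leads vx/vy/vz and any others are dropped).
#'
#' @param path Record path without extension (expects `path.hea` and
#'   `path.dat`).
#' @return An `ecg_record`.
#' @export
read_wfdb <- function(path) {
  hea <- readLines(paste0(path, ".hea"))
  hea <- hea[!grepl("^#", hea)]
  top <- strsplit(trimws(hea[1]), "\\s+")[[1]]
  nsig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(top[3]) else 250
  nsamp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  sig <- lapply(hea[1 + seq_len(nsig)], parse_hea_signal)
  fmts <- vapply(sig, function(s) s$format, character(1))
  if (!all(fmts == "16")) {
    stop("only WFDB format 16 is supported (got ",
         paste(unique(fmts), collapse = ","), ")", call. = FALSE)
  }
  dat <- paste0(path, ".dat")
  raw_n <- file.info(dat)$size / 2
  vals <- readBin(dat, "integer", n = raw_n, size = 2, endian = "little",
                  signed = TRUE)
  if (is.na(nsamp)) nsamp <- length(vals) %/% nsig
  m <- matrix(vals[seq_len(nsamp * nsig)], ncol = nsig, byrow = TRUE)
  mv <- vapply(seq_len(nsig), function(k) {
    (m[, k] - sig[[k]]$baseline) / sig[[k]]$gain
  }, numeric(nsamp))
  desc <- vapply(sig, function(s) s$desc, character(1))
  sel <- match(tolower(ECG_LEADS), tolower(desc))
  if (anyNA(sel)) {
    stop("missing conventional leads: ",
         paste(ECG_LEADS[is.na(sel)], collapse = ", "), call. = FALSE)
  }
  as_ecg_record(mv[, sel, drop = FALSE], fs = fs, leads = ECG_LEADS)
}

# One signal-spec line: file format[xN] gain[(baseline)][/units] adcres
# adczero initval checksum blocksize description...
parse_hea_signal <- function(line) {
  f <- strsplit(trimws(line), "\\s+")[[1]]
  gain_tok <- f[3]
  gain_part <- sub("/.*$", "", gain_tok)
  baseline <- NA_real_
  if (grepl("\\(", gain_part)) {
    baseline <- as.numeric(sub("^.*\\(([^)]*)\\).*$", "\\1", gain_part))
    gain_part <- sub("\\(.*$", "", gain_part)
  }
  gain <- as.numeric(gain_part)
  if (is.na(gain) || gain == 0) gain <- 200
  adczero <- if (length(f) >= 5) as.numeric(f[5]) else 0
  if (is.na(baseline)) baseline <- adczero
  desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else ""
  list(file = f[1], format = sub("x.*$", "", f[2]), gain = gain,
       baseline = baseline, desc = desc)
}

#' Write an `ecg_record` as a WFDB format-16 pair
#'
#' @param record An `ecg_record`.
#' @param path Record path without extension.
#' @param gain ADC units per mV (default 2000).
#' @export
write_wfdb <- function(record, path, gain = 2000) {
  m <- ecg_matrix(record)
  name <- basename(path)
  n <- nrow(m); nsig <- ncol(m)
  adc <- round(m * gain)
  stopifnot(all(abs(adc) < 32768))
  hea <- c(sprintf("%s %d %g %d", name, nsig, ecg_fs(record), n),
           sprintf("%s.dat 16 %g(0)/mV 16 0 0 0 0 %s", name, gain,
                   colnames(m)))
  writeLines(hea, paste0(path, ".hea"))
  inter <- as.integer(t(adc))
  writeBin(inter, paste0(path, ".dat"), size = 2, endian = "little")
  invisible(path)
}

#' Write a wide feature table as CSV (the feature/model contract file)
#' @param wide Wide feature tibble from [fuse_features()].
#' @param path Output path.
#' @export
write_features_csv <- function(wide, path) {
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
}

#' Write cross-validation metrics as JSON plus a per-class TSV report
#' @param cv An `mi_cv` object.
#' @param json_path,tsv_path,confusion_path Output paths (NULL to skip).
#' @export
write_metrics <- function(cv, json_path = NULL, tsv_path = NULL,
                          confusion_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(accuracy = cv$accuracy,
           mean_fold_accuracy = cv$mean_fold_accuracy,
           fold_accuracy = cv$fold_accuracy,
           per_class = cv$metrics),
      json_path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  if (!is.null(tsv_path)) {
    utils::write.table(cv_report(cv), tsv_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  if (!is.null(confusion_path)) {
    utils::write.csv(as.data.frame(unclass(cv$confusion)), confusion_path)
  }
  invisible(cv)
}
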