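# Recording, manifest and artifact I/O.
#
# Recordings travel as two-column CSV (header exactly `time_s,value`) with a
# JSON sidecar (<path>.json) holding the sampling rate, start time, patient
# id, generator metadata and the artifact mask as run-lengths, or as a
# minimal WFDB record: a .hea header plus format-16 (int16 little-endian)
# .dat, one signal channel and, when a mask is present, a second 0/1 MASK
# channel.  The WFDB support is deliberately scoped to what this package
# writes.

#' Write a recording to disk
#'
#' @param rec A \code{ppg_recording}.
#' @param path Output path: for CSV the file itself; for WFDB the record
#'   path without extension (writes \code{<path>.hea} and \code{<path>.dat}).
#' @param format \code{"csv"} or \code{"wfdb"}.
#' @return \code{path}, invisibly.
#' @export
write_recording <- function(rec, path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "ppg_recording"))
  if (format == "csv") {
    df <- data.frame(time_s = rec$start_time +
                       (seq_along(rec$samples) - 1) / rec$fs,
                     value = rec$samples)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    strip_classes <- function(x) {
      if (is.list(x)) lapply(unclass(x), strip_classes)
      else if (is.function(x)) NULL
      else x
    }
    sidecar <- list(fs = rec$fs, start_time = rec$start_time,
                    patient_id = rec$patient_id,
                    mask_runs = mask_to_runs(rec$artifact_mask),
                    n_samples = length(rec$samples),
                    meta = strip_classes(rec$meta))
    jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  } else {
    write_wfdb(rec, path)
  }
  invisible(path)
}

wfdb_gain <- 1000

write_wfdb <- function(rec, path) {
  record <- basename(path)
  has_mask <- any(rec$artifact_mask)
  nsig <- if (has_mask) 2L else 1L
  n <- length(rec$samples)
  # scale to int16 via fixed gain around the signal's own offset
  baseline <- round(mean(range(rec$samples)) * wfdb_gain)
  adc <- as.integer(round(rec$samples * wfdb_gain) - baseline)
  if (any(abs(adc) > 32767))
    stopf("signal amplitude too large for int16 WFDB encoding")
  hea <- c(sprintf("%s %d %g %d", record, nsig, rec$fs, n),
           sprintf("%s.dat 16 %g(%d)/au 16 0 %d 0 0 PPG", record, wfdb_gain,
                   baseline, adc[1]))
  mat <- rbind(adc)
  if (has_mask) {
    m <- as.integer(rec$artifact_mask)
    hea <- c(hea, sprintf("%s.dat 16 1(0)/bool 16 0 %d 0 0 MASK", record, m[1]))
    mat <- rbind(adc, m)
  }
  hea <- c(hea, sprintf("# patient_id: %s", rec$patient_id),
           sprintf("# start_time: %g", rec$start_time))
  writeLines(hea, paste0(path, ".hea"))
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.integer(mat), con, size = 2, endian = "little")
  invisible(path)
}

read_wfdb <- function(path) {
  hea_path <- paste0(path, ".hea")
  if (!file.exists(hea_path)) stopf("WFDB header not found: %s", hea_path)
  lines <- readLines(hea_path)
  meta_lines <- grep("^#", lines, value = TRUE)
  lines <- grep("^#", lines, invert = TRUE, value = TRUE)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) < 4) stopf("malformed WFDB header line: %s", lines[1])
  nsig <- as.integer(hdr[2])
  fs <- as.numeric(hdr[3])
  n <- as.integer(hdr[4])
  if (!is.finite(fs) || fs <= 0) stopf("missing or invalid sampling rate in %s",
                                       hea_path)
  sig <- lapply(seq_len(nsig), function(i) {
    tok <- strsplit(trimws(lines[1 + i]), "\\s+")[[1]]
    if (tok[2] != "16") stopf("unsupported WFDB format %s (only 16)", tok[2])
    gb <- regmatches(tok[3], regexec("^([0-9.eE+-]+)\\(([0-9-]+)\\)", tok[3]))[[1]]
    if (length(gb) < 3) stopf("cannot parse gain/baseline: %s", tok[3])
    list(gain = as.numeric(gb[2]), baseline = as.numeric(gb[3]),
         name = tok[length(tok)])
  })
  con <- file(paste0(path, ".dat"), "rb")
  on.exit(close(con))
  raw <- readBin(con, integer(), n = n * nsig, size = 2, endian = "little")
  mat <- matrix(raw, nrow = nsig)
  samples <- (mat[1, ] + sig[[1]]$baseline) / sig[[1]]$gain
  mask <- if (nsig >= 2 && sig[[2]]$name == "MASK") mat[2, ] > 0
          else logical(n)
  pid <- sub("^# patient_id: ", "",
             grep("^# patient_id:", meta_lines, value = TRUE)[1])
  st <- suppressWarnings(as.numeric(sub("^# start_time: ", "",
         grep("^# start_time:", meta_lines, value = TRUE)[1])))
  new_ppg_recording(samples, fs, if (is.finite(st)) st else 0, mask,
                    if (is.na(pid)) basename(path) else pid)
}

#' Read a recording from disk
#'
#' CSV files must have the exact header \code{time_s,value}; the sampling
#' rate is taken from the JSON sidecar when present and otherwise inferred
#' from the (required, regular) time column.  Malformed CSV lines raise a
#' parse error naming the line.
#'
#' @param path File path (CSV) or record path without extension (WFDB).
#' @param format \code{"csv"} or \code{"wfdb"}.
#' @return A \code{ppg_recording}; the artifact mask is all-false when no
#'   ground truth is available.
#' @export
read_recording <- function(path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  if (format == "wfdb") return(read_wfdb(path))
  if (!file.exists(path)) stopf("file not found: %s", path)
  fields <- count.fields(path, sep = ",")
  bad <- which(fields != 2)
  if (length(bad))
    stopf("parse error in %s: line %d has %d field(s), expected 2",
          path, bad[1], fields[bad[1]])
  df <- read.csv(path)
  if (!identical(names(df), c("time_s", "value")))
    stopf("CSV header must be exactly `time_s,value`, got `%s`",
          paste(names(df), collapse = ","))
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    mask <- runs_to_mask(as.data.frame(sc$mask_runs), nrow(df))
    new_ppg_recording(df$value, as.numeric(sc$fs), sc$start_time %||% 0, mask,
                      sc$patient_id %||% basename(path),
                      as.list(sc$meta %||% list()))
  } else {
    if (nrow(df) < 2) stopf("cannot infer sampling rate from %s", path)
    dt <- diff(df$time_s)
    if (diff(range(dt)) > 1e-6 * median(dt))
      stopf("irregular time column in %s; cannot infer sampling rate", path)
    new_ppg_recording(df$value, 1 / median(dt), df$time_s[1],
                      logical(nrow(df)), basename(path))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

manifest_schema_version <- "1"

#' Write / read a segment manifest
#'
#' The manifest is the tabular index of a segment store: one row per
#' segment with \code{segment_id}, \code{patient_id}, \code{t} (window start,
#' seconds from recording start), \code{y} (artifact fraction),
#' \code{source_path}, \code{offset} (element index within the source
#' container) and \code{schema_version}.
#'
#' @param manifest Data.frame with the columns above (\code{schema_version}
#'   added if absent).
#' @param path CSV file path.
#' @return \code{write_manifest}: \code{path} invisibly;
#'   \code{read_manifest}: the data.frame.
#' @export
write_manifest <- function(manifest, path) {
  if (is.null(manifest$schema_version))
    manifest$schema_version <- manifest_schema_version
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Validate a segment manifest
#'
#' Checks required columns, segment-id uniqueness, value ranges and the
#' existence of referenced source files.  Returns a report rather than
#' erroring; pipeline entry points fail on a non-empty error list.
#'
#' @param manifest A manifest data.frame.
#' @param check_files Whether to verify \code{source_path} existence.
#' @return List with character vectors \code{errors} and \code{warnings}.
#' @export
validate_manifest <- function(manifest, check_files = TRUE) {
  errors <- character()
  warnings <- character()
  req <- c("segment_id", "patient_id", "t", "y")
  miss <- setdiff(req, names(manifest))
  if (length(miss)) {
    errors <- c(errors, sprintf("missing column(s): %s",
                                paste(miss, collapse = ", ")))
    return(list(errors = errors, warnings = warnings))
  }
  dup <- manifest$segment_id[duplicated(manifest$segment_id)]
  if (length(dup))
    errors <- c(errors, sprintf("duplicated segment_id: %s",
                                paste(unique(dup), collapse = ", ")))
  bad_y <- which(!is.finite(manifest$y) | manifest$y < 0 | manifest$y > 1)
  if (length(bad_y))
    errors <- c(errors, sprintf("y out of [0,1] in row(s) %s (values %s)",
                                paste(bad_y, collapse = ", "),
                                paste(manifest$y[bad_y], collapse = ", ")))
  bad_t <- which(!is.finite(manifest$t) | manifest$t < 0)
  if (length(bad_t))
    errors <- c(errors, sprintf("negative or missing t in row(s) %s",
                                paste(bad_t, collapse = ", ")))
  if (is.null(manifest$schema_version))
    warnings <- c(warnings, "missing schema_version column")
  if (check_files && !is.null(manifest$source_path)) {
    missing_files <- setdiff(unique(manifest$source_path),
                             c("", NA))
    missing_files <- missing_files[!file.exists(missing_files)]
    if (length(missing_files))
      errors <- c(errors, sprintf("missing source file(s): %s",
                                  paste(missing_files, collapse = ", ")))
  }
  list(errors = errors, warnings = warnings)
}

#' Write / read a segment store
#'
#' A segment store is a directory with one sample-array container per
#' patient (\code{<patient>.rds}, a samples matrix plus per-segment fields)
#' and a \code{manifest.csv} indexing all segments.
#'
#' @param segments A \code{ppg_segments} collection.
#' @param dir Directory (created if needed).
#' @return \code{write_segment_store}: the manifest data.frame, invisibly;
#'   \code{read_segment_store}: the \code{ppg_segments} collection.
#' @export
write_segment_store <- function(segments, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- as.data.frame(segments)
  df$offset <- stats::ave(seq_len(nrow(df)), df$patient_id,
                          FUN = seq_along)
  df$source_path <- file.path(dir, paste0(df$patient_id, ".rds"))
  for (pid in unique(df$patient_id)) {
    idx <- which(df$patient_id == pid)
    sub <- segments[idx]
    saveRDS(list(samples = segment_matrix(sub),
                 segment_id = df$segment_id[idx], t = df$t[idx],
                 y = df$y[idx], fs = sub[[1]]$fs,
                 meta = lapply(unclass(sub), `[[`, "meta")),
            file.path(dir, paste0(pid, ".rds")))
  }
  manifest <- df[, c("segment_id", "patient_id", "t", "y", "source_path",
                     "offset")]
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' @rdname write_segment_store
#' @export
read_segment_store <- function(dir) {
  manifest <- read_manifest(file.path(dir, "manifest.csv"))
  rep_ <- validate_manifest(manifest)
  if (length(rep_$errors))
    stopf("invalid manifest in %s:\n%s", dir,
          paste(rep_$errors, collapse = "\n"))
  segs <- vector("list", nrow(manifest))
  for (pid in unique(manifest$patient_id)) {
    blob <- readRDS(file.path(dir, paste0(pid, ".rds")))
    rows <- which(manifest$patient_id == pid)
    for (r in rows) {
      k <- manifest$offset[r]
      segs[[r]] <- new_ppg_segment(blob$samples[, k], blob$y[k], blob$t[k],
                                   pid, blob$segment_id[k], blob$fs,
                                   meta = blob$meta[[k]])
    }
  }
  new_ppg_segments(segs)
}

#' Write / read a pairs manifest
#'
#' CSV with columns \code{good_id}, \code{bad_id}, \code{good_idx},
#' \code{bad_idx}, \code{patient_id}, \code{c}, plus a JSON config echo at
#' \code{<path>.json} for provenance.
#'
#' @param pairs A \code{quality_pairs} data.frame.
#' @param path CSV file path.
#' @return \code{write_pairs}: \code{path} invisibly; \code{read_pairs}: the
#'   \code{quality_pairs} data.frame.
#' @export
write_pairs <- function(pairs, path) {
  write.csv(as.data.frame(pairs), path, row.names = FALSE)
  cfg <- attr(pairs, "config")
  if (!is.null(cfg))
    jsonlite::write_json(unclass(cfg), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  pairs <- read.csv(path, stringsAsFactors = FALSE)
  class(pairs) <- c("quality_pairs", "data.frame")
  cfg_path <- paste0(path, ".json")
  if (file.exists(cfg_path)) {
    cfg <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
    attr(pairs, "config") <- structure(cfg, class = "pairing_config")
  }
  pairs
}
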