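## Readers and writers. Canonical containers: a minimal SNIRF (HDF5) subset
## via rhdf5 when available, and a self-describing CSV dialect (header
## comment lines carry acquisition metadata) that works everywhere. Vitals,
## annotations, features and reports are plain CSV.

## CSV writer at full double precision (17 significant digits) so that
## write -> read round trips are bit-exact.
write_csv_precise <- function(df, con) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
}

meta_header <- function(rec) {
  c(sprintf("# sample_rate_hz: %g", rec$sample_rate),
    sprintf("# wavelengths_nm: %s", paste(rec$wavelengths, collapse = ",")),
    sprintf("# distance_cm: %g", rec$distance_cm),
    if (!is.null(rec$i0)) sprintf("# i0: %s", paste(rec$i0, collapse = ",")))
}

#' Write a NIRS recording to the CSV dialect
#'
#' Columns `time_s`, `ch<j>_wl<nm>` per channel/wavelength and optional
#' `tsi_ch<j>`; acquisition metadata in `# key: value` header lines.
#'
#' @param rec a `nirs_recording`.
#' @param path output path (`.csv`).
#' @return `path`, invisibly.
#' @export
write_nirs_csv <- function(rec, path) {
  stopifnot(inherits(rec, "nirs_recording"))
  n <- nrow(rec$channels[[1L]])
  df <- data.frame(time_s = (seq_len(n) - 1) / rec$sample_rate)
  for (ch in seq_along(rec$channels)) {
    for (w in seq_along(rec$wavelengths)) {
      df[[sprintf("ch%d_wl%g", ch, rec$wavelengths[w])]] <- rec$channels[[ch]][, w]
    }
  }
  if (!is.null(rec$tsi)) {
    for (ch in seq_len(ncol(rec$tsi))) df[[sprintf("tsi_ch%d", ch)]] <- rec$tsi[, ch]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header(rec), con)
  write_csv_precise(df, con)
  invisible(path)
}

read_meta_lines <- function(path) {
  lines <- readLines(path, n = 10L)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (l in hdr) {
    m <- regmatches(l, regexec("^#\\s*([a-z0-9_]+):\\s*(.*)$", l))[[1L]]
    if (length(m) == 3L) kv[[m[2L]]] <- m[3L]
  }
  kv
}

#' Read a NIRS recording (CSV dialect or SNIRF)
#'
#' Dispatches on extension: `.snirf` via rhdf5, otherwise the CSV dialect.
#' Validates geometry, wavelength count (>= 2), timestamp monotonicity and
#' the declared sampling rate.
#'
#' @param path input file.
#' @return a `nirs_recording`.
#' @export
read_nirs <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (grepl("\\.snirf$", path, ignore.case = TRUE)) return(read_snirf(path))
  kv <- read_meta_lines(path)
  if (is.null(kv$sample_rate_hz) || is.null(kv$wavelengths_nm)) {
    stopf("%s: missing '# sample_rate_hz' / '# wavelengths_nm' header lines", path)
  }
  fs <- as.numeric(kv$sample_rate_hz)
  wl <- as.numeric(strsplit(kv$wavelengths_nm, ",")[[1L]])
  if (length(wl) < 2L) stopf("%s declares %d wavelength(s); Beer-Lambert needs >= 2", path, length(wl))
  df <- utils::read.csv(path, comment.char = "#")
  if (is.unsorted(df$time_s, strictly = TRUE)) stopf("%s: non-monotone timestamps", path)
  dt <- stats::median(diff(df$time_s))
  if (abs(dt * fs - 1) > 1e-3) {
    stopf("%s: timestamps imply %.3f Hz but %g Hz declared", path, 1 / dt, fs)
  }
  chs <- sort(unique(as.integer(sub("^ch(\\d+)_.*$", "\\1",
                                    grep("^ch\\d+_wl", names(df), value = TRUE)))))
  channels <- lapply(chs, function(ch) {
    m <- vapply(wl, function(w) df[[sprintf("ch%d_wl%g", ch, w)]], numeric(nrow(df)))
    colnames(m) <- as.character(wl)
    m
  })
  tsi_cols <- grep("^tsi_ch\\d+$", names(df), value = TRUE)
  tsi <- if (length(tsi_cols)) as.matrix(df[, tsi_cols, drop = FALSE]) else NULL
  i0 <- if (!is.null(kv$i0)) as.numeric(strsplit(kv$i0, ",")[[1L]]) else NULL
  nirs_recording(channels, fs, wl,
                 distance_cm = if (!is.null(kv$distance_cm)) as.numeric(kv$distance_cm) else 3.0,
                 i0 = i0, tsi = tsi)
}

need_rhdf5 <- function() {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stopf("SNIRF support needs the rhdf5 package; use the CSV dialect instead")
  }
}

#' Write a minimal SNIRF (HDF5) file
#'
#' Writes the SNIRF-1.0 subset this pipeline needs: `/formatVersion`,
#' `/nirs/data1/dataTimeSeries` + `time`, one `measurementList<k>` entry per
#' channel/wavelength, probe wavelengths and source/detector positions.
#' TSI (a derived device output, not part of core SNIRF) goes to
#' `/nirs/aux1`.
#'
#' @param rec a `nirs_recording`.
#' @param path output `.snirf` path.
#' @return `path`, invisibly.
#' @export
write_snirf <- function(rec, path) {
  need_rhdf5()
  stopifnot(inherits(rec, "nirs_recording"))
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  h5 <- function(name, value) rhdf5::h5write(value, path, name)
  h5("formatVersion", "1.0")
  rhdf5::h5createGroup(path, "nirs")
  rhdf5::h5createGroup(path, "nirs/data1")
  n <- nrow(rec$channels[[1L]])
  dts <- do.call(cbind, rec$channels)     # n x (channels*wavelengths)
  h5("nirs/data1/dataTimeSeries", dts)
  h5("nirs/data1/time", (seq_len(n) - 1) / rec$sample_rate)
  k <- 0L
  for (ch in seq_along(rec$channels)) {
    for (w in seq_along(rec$wavelengths)) {
      k <- k + 1L
      g <- sprintf("nirs/data1/measurementList%d", k)
      rhdf5::h5createGroup(path, g)
      h5(paste0(g, "/sourceIndex"), 1L)
      h5(paste0(g, "/detectorIndex"), as.integer(ch))
      h5(paste0(g, "/wavelengthIndex"), as.integer(w))
      h5(paste0(g, "/dataType"), 1L)
      h5(paste0(g, "/dataTypeIndex"), 1L)
    }
  }
  rhdf5::h5createGroup(path, "nirs/probe")
  h5("nirs/probe/wavelengths", rec$wavelengths)
  h5("nirs/probe/sourcePos2D", matrix(c(0, 0), 1L))
  h5("nirs/probe/detectorPos2D",
     matrix(c(rec$distance_cm, 0, rec$distance_cm + 0.5, 0), 2L, byrow = TRUE))
  if (!is.null(rec$tsi)) h5("nirs/aux1", rec$tsi)
  if (!is.null(rec$i0)) h5("nirs/i0", rec$i0)
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read the minimal SNIRF subset
#'
#' @param path a `.snirf` file written by [write_snirf()] or any SNIRF file
#'   carrying the same subset.
#' @return a `nirs_recording`.
#' @export
read_snirf <- function(path) {
  need_rhdf5()
  on.exit(rhdf5::h5closeAll())
  wl <- as.numeric(rhdf5::h5read(path, "nirs/probe/wavelengths"))
  if (length(wl) < 2L) stopf("%s declares %d wavelength(s); need >= 2", path, length(wl))
  dts <- as.matrix(rhdf5::h5read(path, "nirs/data1/dataTimeSeries"))
  tm <- as.numeric(rhdf5::h5read(path, "nirs/data1/time"))
  if (is.unsorted(tm, strictly = TRUE)) stopf("%s: non-monotone timestamps", path)
  fs <- 1 / stats::median(diff(tm))
  ls <- rhdf5::h5ls(path)
  ml <- grep("^measurementList\\d+$",
             ls$name[ls$group == "/nirs/data1"], value = TRUE)
  det <- integer(length(ml)); wli <- integer(length(ml))
  for (g in ml) {
    k <- as.integer(sub("measurementList", "", g))
    det[k] <- as.integer(rhdf5::h5read(path, sprintf("nirs/data1/%s/detectorIndex", g)))
    wli[k] <- as.integer(rhdf5::h5read(path, sprintf("nirs/data1/%s/wavelengthIndex", g)))
  }
  channels <- lapply(sort(unique(det)), function(ch) {
    m <- vapply(seq_along(wl), function(w) dts[, which(det == ch & wli == w)],
                numeric(nrow(dts)))
    colnames(m) <- as.character(wl)
    m
  })
  tsi <- tryCatch(as.matrix(rhdf5::h5read(path, "nirs/aux1")), error = function(e) NULL)
  i0 <- tryCatch(as.numeric(rhdf5::h5read(path, "nirs/i0")), error = function(e) NULL)
  dp <- tryCatch(rhdf5::h5read(path, "nirs/probe/detectorPos2D"), error = function(e) NULL)
  dist <- if (!is.null(dp)) as.numeric(dp[1L, 1L]) else 3.0
  nirs_recording(channels, round(fs, 6), wl, distance_cm = dist, i0 = i0, tsi = tsi)
}

#' Write / read one-minute sleep annotations
#'
#' CSV with columns `epoch_start_s`, `label` (AS/QS/Wake). Reading sorts
#' out-of-order epochs with a warning and rejects overlapping epochs and
#' unknown label tokens.
#'
#' @param timeline a `sleep_timeline`.
#' @param path CSV path.
#' @return `write_annotations`: `path` invisibly; `read_annotations`: a
#'   `sleep_timeline`.
#' @export
write_annotations <- function(timeline, path) {
  stopifnot(inherits(timeline, "sleep_timeline"))
  df <- data.frame(
    epoch_start_s = timeline$start_s + (seq_along(timeline$labels) - 1L) * timeline$epoch_s,
    label = timeline$labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, colClasses = c("numeric", "character"))
  if (!all(c("epoch_start_s", "label") %in% names(df))) {
    stopf("%s: need columns epoch_start_s, label", path)
  }
  bad <- setdiff(unique(df$label), SLEEP_STATES)
  if (length(bad)) {
    stopf("unknown label '%s' in %s; allowed tokens: %s", bad[1L], path,
          paste(SLEEP_STATES, collapse = ", "))
  }
  if (is.unsorted(df$epoch_start_s)) {
    warning("epochs out of order in ", path, "; sorting", call. = FALSE)
    df <- df[order(df$epoch_start_s), ]
  }
  if (any(diff(df$epoch_start_s) < 60)) stopf("%s: overlapping epochs", path)
  gaps <- which(diff(df$epoch_start_s) > 60)
  if (length(gaps)) {
    warning(sprintf("%d gap(s) in annotation coverage of %s", length(gaps), path),
            call. = FALSE)
  }
  sleep_timeline(df$label, start_s = df$epoch_start_s[1L])
}

#' Write / read reference monitor vitals
#'
#' CSV columns `time_s`, `hr_bpm`, `rr_epm` on the 0.4 Hz monitor grid.
#'
#' @param ref a `reference_vitals` object.
#' @param path CSV path.
#' @return `path` invisibly, or the `reference_vitals` on read.
#' @export
write_reference_vitals <- function(ref, path) {
  utils::write.csv(data.frame(time_s = ref$time_s, hr_bpm = ref$hr, rr_epm = ref$rr),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_vitals
#' @export
read_reference_vitals <- function(path) {
  df <- utils::read.csv(path)
  structure(list(time_s = df$time_s, hr = df$hr_bpm, rr = df$rr_epm,
                 rate_hz = 1 / stats::median(diff(df$time_s))),
            class = "reference_vitals")
}

#' Write extracted vitals (window level and 1 Hz)
#'
#' Long-format CSV: `grid` (window/1hz), `metric` (hr/rr), `time_s`,
#' `value`, `flagged`.
#'
#' @param v a `vitals_series`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_vitals <- function(v, path) {
  stopifnot(inherits(v, "vitals_series"))
  rows <- list(
    data.frame(grid = "window", metric = "hr", time_s = v$hr$time_s,
               value = v$hr$hr_bpm, flagged = v$hr$flagged),
    data.frame(grid = "window", metric = "rr", time_s = v$rr$time_s,
               value = v$rr$rr_epm, flagged = v$rr$flagged))
  if (!is.null(v$hr_1hz)) {
    rows <- c(rows, list(data.frame(grid = "1hz", metric = "hr",
                                    time_s = v$hr_1hz$time_s,
                                    value = v$hr_1hz$hr_bpm, flagged = FALSE)))
  }
  if (!is.null(v$rr_1hz)) {
    rows <- c(rows, list(data.frame(grid = "1hz", metric = "rr",
                                    time_s = v$rr_1hz$time_s,
                                    value = v$rr_1hz$rr_epm, flagged = FALSE)))
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write / read a modality table
#'
#' One row per second: `time_s` plus the eight modality columns.
#'
#' @param ms a [modality_set()].
#' @param path CSV path.
#' @return `path` invisibly, or the `modality_set` on read.
#' @export
write_modalities <- function(ms, path) {
  stopifnot(inherits(ms, "modality_set"))
  df <- cbind(data.frame(time_s = ms$time_s), as.data.frame(t(ms$mods)))
  con <- file(path, "w"); on.exit(close(con))
  write_csv_precise(df, con)
  invisible(path)
}

#' @rdname write_modalities
#' @export
read_modalities <- function(path) {
  df <- utils::read.csv(path)
  modality_set(t(as.matrix(df[, MODALITY_NAMES])), time_s = df$time_s)
}

#' Write / read labeled feature epochs
#'
#' Tensor as long CSV (`epoch`, `modality`, `t_s`, `value`) plus a label
#' sidecar (`epoch`, `epoch_start_s`, `label`, `recording_id`,
#' `subject_id`).
#'
#' @param es an [epoch_set()].
#' @param path tensor CSV path; sidecar gets suffix `_labels.csv`.
#' @return `path` invisibly, or the `epoch_set` on read.
#' @export
write_epochs <- function(es, path) {
  stopifnot(inherits(es, "epoch_set"))
  n <- length(es$label)
  long <- data.frame(
    epoch = rep(seq_len(n), each = 8L * 60L),
    modality = rep(MODALITY_NAMES, times = 60L * n),
    t_s = rep(rep(0:59, each = 8L), times = n),
    value = as.vector(es$x))
  con <- file(path, "w"); on.exit(close(con))
  write_csv_precise(long, con)
  side <- data.frame(epoch = seq_len(n), epoch_start_s = es$epoch_start_s,
                     label = as.character(es$label),
                     recording_id = es$recording_id, subject_id = es$subject_id)
  utils::write.csv(side, sub("\\.csv$", "_labels.csv", path), row.names = FALSE)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  long <- utils::read.csv(path)
  side <- utils::read.csv(sub("\\.csv$", "_labels.csv", path),
                          colClasses = c("integer", "numeric", "character",
                                         "character", "character"))
  n <- max(long$epoch)
  x <- array(long$value, dim = c(8L, 60L, n),
             dimnames = list(MODALITY_NAMES, NULL, NULL))
  epoch_set(x, side$label, side$epoch_start_s, side$recording_id, side$subject_id)
}

#' Write / read a cohort manifest
#'
#' One row per measurement: identifiers, gestational/postmenstrual age,
#' duration and file paths.
#'
#' @param manifest data.frame (see [example_cohort()] for the metadata
#'   columns); a `files_*` column per artifact is conventional.
#' @param path CSV path.
#' @return `path` invisibly, or the data.frame on read.
#' @export
write_manifest <- function(manifest, path) {
  if (any(duplicated(manifest$measurement_id))) stopf("duplicate measurement_id in manifest")
  if (any(manifest$duration_min <= 0)) stopf("durations must be positive")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, colClasses = "character")
  m$duration_min <- as.numeric(m$duration_min)
  if (any(duplicated(m$measurement_id))) stopf("duplicate measurement_id in %s", path)
  m
}
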