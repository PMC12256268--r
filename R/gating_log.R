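# Gating-session log I/O and the session-level data model.
#
# A gating log is the merged per-sample table a gating system records during
# delivery: time stamps, respiratory surrogate amplitudes on three orthogonal
# axes (z = anterior-posterior by convention) and the beam on/off flag, all on
# one clock. Vendor offline-review exports map onto this normalized
# representation; the on-disk dialect is a plain UTF-8 CSV documented in
# `read_gating_log()`.

GATING_HEADER <- "time_s,amp_x_cm,amp_y_cm,amp_z_cm,beam_on"

#' Construct a gating log table
#'
#' Builds and validates the in-memory representation of one gating session:
#' a tibble with columns `time_s`, `amp_x_cm`, `amp_y_cm`, `amp_z_cm`
#' (amplitudes in cm) and `beam_on` (logical), carrying the session id,
#' free-form metadata and the nominal sample period as attributes.
#'
#' Invariants enforced: at least 2 samples; strictly increasing time;
#' near-uniform sampling (every gap within 10% of the nominal sample period,
#' since phase times are later obtained by linear interpolation on this axis);
#' unique metadata keys.
#'
#' @param data Data frame with the five columns above (`beam_on` logical or
#'   0/1).
#' @param session_id Character scalar identifying the session.
#' @param metadata Named character vector of free-form key/value pairs
#'   (machine, date, planned MU, gating window, ...).
#' @param sample_period Nominal sample period in seconds; inferred from the
#'   median time step when `NULL`.
#' @return A `gating_log` tibble.
#' @export
gating_log <- function(data, session_id = "session", metadata = character(),
                       sample_period = NULL) {
  req <- c("time_s", "amp_x_cm", "amp_y_cm", "amp_z_cm", "beam_on")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0L) {
    abort_gatelog(
      sprintf("gating log is missing column(s): %s",
              paste(missing_cols, collapse = ", ")),
      "gatelog_format_error"
    )
  }
  out <- as_tibble(data)[req]
  if (nrow(out) < 2L) {
    abort_gatelog("a gating log needs at least 2 samples.",
                  "gatelog_validation_error")
  }
  if (is.numeric(out$beam_on)) {
    if (!all(out$beam_on %in% c(0, 1))) {
      abort_gatelog("`beam_on` must contain only 0 or 1.",
                    "gatelog_validation_error")
    }
    out$beam_on <- out$beam_on == 1
  }
  if (any(diff(out$time_s) <= 0)) {
    i <- which(diff(out$time_s) <= 0)[1]
    abort_gatelog(
      sprintf("`time_s` must be strictly increasing (violated at sample %d).",
              i + 1L),
      "gatelog_validation_error"
    )
  }
  if (is.null(sample_period)) sample_period <- infer_sample_period(out$time_s)
  check_number(sample_period, "sample_period", positive = TRUE)
  check_uniform_sampling(out$time_s, sample_period, what = "gating log")
  if (anyDuplicated(names(metadata))) {
    abort_gatelog("metadata keys must be unique.", "gatelog_validation_error")
  }
  structure(
    out,
    session_id = as.character(session_id)[1],
    metadata = metadata,
    sample_period = sample_period,
    class = c("gating_log", class(out))
  )
}

#' Read a gating-session log
#'
#' Parses the plain-text gating-log dialect: UTF-8 CSV where lines starting
#' with `#` are metadata comments of the form `# key: value`, the header row
#' is exactly `time_s,amp_x_cm,amp_y_cm,amp_z_cm,beam_on`, time is in seconds,
#' amplitudes in cm, and `beam_on` is 0 or 1. The file is validated on read:
#' malformed headers, non-monotone time, beam flags outside \{0,1\} and
#' sampling gaps beyond 10% of the nominal period are all rejected with
#' errors naming the offending line.
#'
#' @param path Path to a gating-log CSV file.
#' @param session_id Session identifier; defaults to the file name without
#'   extension (a `session_id` metadata key, if present, takes precedence).
#' @return A validated [gating_log()] tibble.
#' @export
read_gating_log <- function(path, session_id = NULL) {
  if (!file.exists(path)) {
    abort_gatelog(sprintf("gating log file not found: %s", path),
                  "gatelog_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8")
  is_comment <- grepl("^\\s*#", lines)
  is_blank <- grepl("^\\s*$", lines)

  metadata <- character()
  meta_lines <- lines[is_comment]
  m <- regmatches(meta_lines,
                  regexec("^\\s*#\\s*([^:]+?)\\s*:\\s*(.*)\\s*$", meta_lines))
  for (parts in m) {
    if (length(parts) == 3L) metadata[parts[2]] <- parts[3]
  }
  if (anyDuplicated(names(metadata))) {
    abort_gatelog("duplicate metadata key in gating log header.",
                  "gatelog_validation_error")
  }

  body_idx <- which(!is_comment & !is_blank)
  if (length(body_idx) < 1L) {
    abort_gatelog("gating log has no header row.", "gatelog_format_error")
  }
  header_line <- body_idx[1]
  if (trimws(lines[header_line]) != GATING_HEADER) {
    abort_gatelog(
      sprintf("malformed gating log header at line %d: expected \"%s\", got \"%s\".",
              header_line, GATING_HEADER, trimws(lines[header_line])),
      "gatelog_format_error"
    )
  }
  data_idx <- body_idx[-1]
  if (length(data_idx) < 2L) {
    abort_gatelog("gating log must contain at least 2 data rows.",
                  "gatelog_validation_error")
  }
  fields <- strsplit(trimws(lines[data_idx]), ",", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 5L)) {
    bad <- which(nf != 5L)[1]
    abort_gatelog(
      sprintf("line %d has %d fields; expected 5.", data_idx[bad], nf[bad]),
      "gatelog_format_error"
    )
  }
  mat <- do.call(rbind, fields)
  num <- suppressWarnings(apply(mat, 2, as.numeric))
  cols <- c("time_s", "amp_x_cm", "amp_y_cm", "amp_z_cm", "beam_on")
  for (j in seq_len(5L)) {
    if (anyNA(num[, j])) {
      bad <- which(is.na(num[, j]))[1]
      abort_gatelog(
        sprintf("non-numeric value \"%s\" at line %d, column %s.",
                mat[bad, j], data_idx[bad], cols[j]),
        "gatelog_format_error"
      )
    }
  }
  if (!all(num[, 5] %in% c(0, 1))) {
    bad <- which(!(num[, 5] %in% c(0, 1)))[1]
    abort_gatelog(
      sprintf("beam_on must be 0 or 1; found \"%s\" at line %d, column beam_on.",
              mat[bad, 5], data_idx[bad]),
      "gatelog_validation_error"
    )
  }
  df <- tibble(
    time_s = num[, 1], amp_x_cm = num[, 2], amp_y_cm = num[, 3],
    amp_z_cm = num[, 4], beam_on = num[, 5] == 1
  )
  if (is.null(session_id)) {
    session_id <- if ("session_id" %in% names(metadata)) {
      metadata[["session_id"]]
    } else {
      sub("\\.[^.]*$", "", basename(path))
    }
  }
  gating_log(df, session_id = session_id, metadata = metadata)
}

#' Write a gating-session log
#'
#' Serializes a [gating_log()] to the plain-text dialect read by
#' [read_gating_log()]: metadata as `# key: value` comment lines, the fixed
#' header row, then one CSV row per sample with times and amplitudes printed
#' at 6 decimal places and the beam flag as 0/1. Writing then re-reading a
#' log reproduces every numeric field at the printed precision, and a second
#' write of the re-read log is byte-identical.
#'
#' @param log A [gating_log()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gating_log <- function(log, path) {
  stopifnot(inherits(log, "gating_log"))
  metadata <- attr(log, "metadata")
  meta_lines <- if (length(metadata) > 0L) {
    sprintf("# %s: %s", names(metadata), unname(metadata))
  } else character()
  rows <- sprintf("%.6f,%.6f,%.6f,%.6f,%d",
                  log$time_s, log$amp_x_cm, log$amp_y_cm, log$amp_z_cm,
                  as.integer(log$beam_on))
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) {
                    abort_gatelog(sprintf("cannot open %s for writing.", path),
                                  "gatelog_io_error")
                  })
  on.exit(close(con))
  writeLines(c(meta_lines, GATING_HEADER, rows), con, sep = "\n")
  invisible(path)
}

#' @export
print.gating_log <- function(x, ...) {
  cat(sprintf("<gating_log> session \"%s\": %d samples, %.4f s period, %.2f-%.2f s\n",
              attr(x, "session_id"), nrow(x), attr(x, "sample_period"),
              x$time_s[1], x$time_s[nrow(x)]))
  NextMethod()
}
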