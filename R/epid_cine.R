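# Independent beam-timing verification from EPID cine frame stacks.
#
# The portal imager runs in cine mode (~25 fps, 0.04 s frames) during gated
# delivery. Beam-on frames are identified from the mean pixel intensity of a
# square ROI centred on the beam axis, thresholded at a fraction of the
# series maximum; segment durations are frame counts times the frame period,
# so every EPID duration is quantized to the frame period.
#
# Input is a frame-stack directory: a `sidecar.json` with the acquisition
# metadata (frame period, pixel spacing, SID/SAD, frame times) and a
# `frames.csv` holding one row-major flattened frame per row.

#' ROI specification for EPID analysis
#'
#' A square ROI defined at the isocenter plane and projected onto the imager
#' by the SID/SAD magnification (projected side = `side_cm_at_iso * sid/sad`).
#'
#' @param side_cm_at_iso Side of the square ROI at isocenter (default 5 cm).
#' @param center Frame-pixel `(row, col)` centre, or `NULL` for the beam
#'   axis (frame centre).
#' @param sad_cm Source-to-axis distance (default 100 cm).
#' @param sid_cm Source-to-imager distance (default 150 cm).
#' @return A `roi_spec` list.
#' @export
roi_spec <- function(side_cm_at_iso = 5, center = NULL,
                     sad_cm = 100, sid_cm = 150) {
  check_number(side_cm_at_iso, "side_cm_at_iso", positive = TRUE)
  check_number(sad_cm, "sad_cm", positive = TRUE)
  check_number(sid_cm, "sid_cm", positive = TRUE)
  if (sid_cm < sad_cm) {
    abort_gatelog("`sid_cm` must be >= `sad_cm`.", "gatelog_parameter_error")
  }
  structure(list(side_cm_at_iso = side_cm_at_iso, center = center,
                 sad_cm = sad_cm, sid_cm = sid_cm),
            class = "roi_spec")
}

new_epid_stack <- function(frames, frame_times, frame_period,
                           pixel_spacing_cm, sid_cm, sad_cm) {
  stopifnot(length(dim(frames)) == 3L, dim(frames)[3] == length(frame_times))
  check_uniform_sampling(frame_times, frame_period, what = "EPID frame")
  structure(list(frames = frames, frame_times = frame_times,
                 frame_period = frame_period,
                 pixel_spacing_cm = pixel_spacing_cm,
                 sid_cm = sid_cm, sad_cm = sad_cm),
            class = "epid_stack")
}

#' Write an EPID frame stack to a directory
#'
#' Serializes the stack as `sidecar.json` (frame period, frame times, pixel
#' spacing, SID/SAD, frame geometry) plus `frames.csv` with one row-major
#' flattened frame per row.
#'
#' @param stack An `epid_stack` (e.g. from [simulate_epid_cine()]).
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_epid_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "epid_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(stack$frames)
  sidecar <- list(
    frame_period_s = stack$frame_period,
    frame_times_s = stack$frame_times,
    pixel_spacing_cm = stack$pixel_spacing_cm,
    sid_cm = stack$sid_cm, sad_cm = stack$sad_cm,
    n_rows = d[1], n_cols = d[2], n_frames = d[3]
  )
  jsonlite::write_json(sidecar, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA)
  flat <- t(apply(stack$frames, 3, function(fr) as.vector(t(fr))))
  utils::write.table(flat, file.path(dir, "frames.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Load an EPID cine frame stack
#'
#' Reads a frame-stack directory written by [write_epid_stack()] /
#' [make_fixture_set()]. Frames are ordered by acquisition time. Geometry
#' (pixel spacing, SID/SAD) is taken from the sidecar when present, else
#' from the arguments (with a message). When the sidecar carries no frame
#' times, a uniform grid at `frame_period` is assumed; with neither timing
#' source the load fails.
#'
#' @param dir Directory containing `sidecar.json` and `frames.csv`.
#' @param frame_period,pixel_spacing_cm,sid_cm,sad_cm Fallback values used
#'   when absent from the sidecar.
#' @return An `epid_stack`.
#' @export
load_cine_frames <- function(dir, frame_period = NULL,
                             pixel_spacing_cm = NULL,
                             sid_cm = NULL, sad_cm = NULL) {
  sidecar_path <- file.path(dir, "sidecar.json")
  frames_path <- file.path(dir, "frames.csv")
  if (!file.exists(sidecar_path) || !file.exists(frames_path)) {
    abort_gatelog(sprintf("EPID stack directory %s must contain sidecar.json and frames.csv.",
                          dir), "gatelog_io_error")
  }
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  pick <- function(key, fallback, what) {
    if (!is.null(meta[[key]])) return(meta[[key]])
    if (is.null(fallback)) {
      abort_gatelog(sprintf("EPID sidecar lacks %s and no fallback was configured.",
                            what), "gatelog_configuration_error")
    }
    message(sprintf("EPID sidecar lacks %s; using configured value %s.",
                    what, format(fallback)))
    fallback
  }
  fp <- pick("frame_period_s", frame_period, "frame period")
  psp <- pick("pixel_spacing_cm", pixel_spacing_cm, "pixel spacing")
  sid <- pick("sid_cm", sid_cm, "SID")
  sad <- pick("sad_cm", sad_cm, "SAD")
  flat <- as.matrix(utils::read.table(frames_path, sep = ",", header = FALSE))
  nr <- meta$n_rows %||% as.integer(sqrt(ncol(flat)))
  nc <- meta$n_cols %||% nr
  if (nr * nc != ncol(flat)) {
    abort_gatelog("frame geometry in sidecar does not match frames.csv width.",
                  "gatelog_validation_error")
  }
  times <- meta$frame_times_s %||% ((seq_len(nrow(flat)) - 1L) * fp)
  ord <- order(times)
  times <- times[ord]; flat <- flat[ord, , drop = FALSE]
  frames <- array(0, dim = c(nr, nc, nrow(flat)))
  for (k in seq_len(nrow(flat))) {
    frames[, , k] <- matrix(flat[k, ], nrow = nr, byrow = TRUE)
  }
  new_epid_stack(frames, times, fp, psp, sid, sad)
}

# 3x3 median filter with edge replication; optional pre-averaging noise
# reduction for compute_roi_series.
median_filter_3x3 <- function(fr) {
  nr <- nrow(fr); nc <- ncol(fr)
  pad <- fr[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  out <- fr
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      out[i, j] <- stats::median(pad[i:(i + 2), j:(j + 2)])
    }
  }
  out
}

#' Per-frame ROI mean intensity series
#'
#' Projects the ROI onto the imager (pixel extent =
#' `round(side_cm * (sid/sad) / pixel_spacing_cm)`, centred), averages the
#' pixel block per frame, and normalizes by the series maximum so the peak
#' of `roi_mean_norm` is exactly 1.
#'
#' @param stack An `epid_stack`.
#' @param roi A [roi_spec()].
#' @param median_filter Apply a 3x3 median filter to each frame before
#'   averaging (noise reduction; default `FALSE`, so the documented pipeline
#'   is the default).
#' @return An `epid_series` tibble: `frame` (0-based), `time`, `roi_mean`,
#'   `roi_mean_norm`; attribute `frame_period`.
#' @export
compute_roi_series <- function(stack, roi = roi_spec(),
                               median_filter = FALSE) {
  stopifnot(inherits(stack, "epid_stack"))
  d <- dim(stack$frames)
  side_px <- round(roi$side_cm_at_iso * (roi$sid_cm / roi$sad_cm) /
                     stack$pixel_spacing_cm)
  center <- roi$center %||% c((d[1] + 1) / 2, (d[2] + 1) / 2)
  half <- (side_px - 1) / 2
  rows <- round(center[1] - half):round(center[1] + half)
  cols <- round(center[2] - half):round(center[2] + half)
  if (min(rows) < 1 || max(rows) > d[1] || min(cols) < 1 || max(cols) > d[2]) {
    abort_gatelog(
      sprintf("projected ROI (%d px) does not fit inside the %d x %d frame.",
              side_px, d[1], d[2]),
      "gatelog_parameter_error"
    )
  }
  roi_mean <- vapply(seq_len(d[3]), function(k) {
    fr <- stack$frames[, , k]
    if (median_filter) fr <- median_filter_3x3(fr)
    mean(fr[rows, cols])
  }, numeric(1))
  out <- tibble(
    frame = seq_len(d[3]) - 1L,
    time = stack$frame_times,
    roi_mean = roi_mean,
    roi_mean_norm = roi_mean / max(roi_mean)
  )
  attr(out, "frame_period") <- stack$frame_period
  class(out) <- c("epid_series", class(out))
  out
}

#' Threshold the ROI series into beam-on frames and segments
#'
#' A frame is beam-on iff its normalized ROI mean is *strictly above*
#' `threshold_fraction` of the series maximum (a frame exactly at the
#' threshold counts as off); contiguous on-runs become segments. Raising the
#' threshold can never increase the on-frame count.
#'
#' @param series An `epid_series` from [compute_roi_series()].
#' @param threshold_fraction Fraction of the series maximum (default 0.5).
#' @return List with `on` (logical per-frame mask) and `segments` (tibble:
#'   `segment`, `start_frame`, `end_frame` (0-based, inclusive),
#'   `n_frames`).
#' @export
detect_beam_on_frames <- function(series, threshold_fraction = 0.5) {
  on <- series$roi_mean_norm > threshold_fraction
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  segments <- tibble(
    segment = seq_along(idx),
    start_frame = series$frame[starts[idx]],
    end_frame = series$frame[ends[idx]],
    n_frames = r$lengths[idx]
  )
  list(on = on, segments = segments)
}

#' Beam-on durations from EPID segments
#'
#' Duration per segment = frame count x frame period, so every duration is
#' an exact integer multiple of the frame period and differs from the true
#' beam-on time by at most one frame period.
#'
#' @param segments Segment tibble from [detect_beam_on_frames()].
#' @param frame_period Frame period in seconds (default 0.04).
#' @return List with `durations` (seconds, possibly empty) and `stats`
#'   ([aggregate_stats()] row, or `NULL` when there are no segments).
#' @export
epid_beam_durations <- function(segments, frame_period = 0.04) {
  check_number(frame_period, "frame_period", positive = TRUE)
  durations <- segments$n_frames * frame_period
  stats <- if (length(durations) > 0L) aggregate_stats(durations) else NULL
  list(durations = durations, stats = stats)
}

#' Compare EPID-derived and log-derived beam-on durations
#'
#' When both sides report one duration per cycle (equal counts) the
#' comparison is paired by order and the per-cycle differences
#' (EPID - log) are aggregated; with unequal counts the difference of the
#' two means is reported instead.
#'
#' @param epid_durations Durations from [epid_beam_durations()].
#' @param log_durations Complete-interval durations from
#'   [detect_beam_intervals()].
#' @return One-row tibble: `mode` ("paired" or "mean"), `mean`, `sd`,
#'   `median`, `n` of the differences; attribute `diffs` in paired mode.
#' @export
compare_epid_vs_log <- function(epid_durations, log_durations) {
  if (length(epid_durations) == 0L || length(log_durations) == 0L) {
    abort_gatelog("both duration lists must be non-empty.",
                  "gatelog_empty_input_error")
  }
  if (length(epid_durations) == length(log_durations)) {
    diffs <- epid_durations - log_durations
    out <- bind_cols(tibble(mode = "paired"), aggregate_stats(diffs))
    attr(out, "diffs") <- diffs
  } else {
    out <- bind_cols(tibble(mode = "mean"),
                     aggregate_stats(mean(epid_durations) -
                                       mean(log_durations)))
  }
  out
}
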