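#' Segment stream container
#'
#' Time-ordered per-channel 1-s snapshots at a fixed cadence, the pipeline's
#' raw input. Samples are stored as an array `[sample, segment, channel]`;
#' masked segments carry `NA` samples and `mask = TRUE`.
#'
#' @param times_h Segment timestamps in hours (strictly increasing, constant
#'   spacing).
#' @param data Numeric array `[n_sample, n_segment, n_channel]`.
#' @param rate_hz Within-segment sampling rate.
#' @param cadence_min Spacing between segments in minutes.
#' @param mask Logical per-segment missing flag.
#' @param filter_history Character note of applied filters.
#' @return An object of class `segment_stream`.
#' @export
segment_stream <- function(times_h, data, rate_hz, cadence_min,
                           mask = rep(FALSE, length(times_h)),
                           filter_history = character(0)) {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            dim(data)[2] == length(times_h),
            length(mask) == length(times_h))
  if (length(times_h) > 1) {
    d <- diff(times_h)
    if (any(d <= 0)) stop("segment timestamps must be strictly increasing")
    if (max(d) - min(d) > 1e-9) stop("segment timestamps must be equally spaced")
  }
  structure(list(times_h = times_h, data = data, mask = mask,
                 rate_hz = rate_hz, cadence_min = cadence_min,
                 filter_history = filter_history),
            class = "segment_stream")
}

#' @export
print.segment_stream <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<segment_stream> %d segments x %d channels, %d samples @ %g Hz\n",
              d[2], d[3], d[1], x$rate_hz))
  cat(sprintf("  cadence %g min, span %.2f days, %.1f%% masked\n",
              x$cadence_min, diff(range(x$times_h)) / 24, 100 * mean(x$mask)))
  invisible(x)
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf("<synthetic_recording> %.0f days, %d channels, %d seizures, %d true spikes\n",
              x$config$duration_days, x$config$n_channels,
              nrow(x$seizure_catalog), nrow(x$spike_truth)))
  invisible(x)
}

#' Write / read a seizure catalog as CSV
#'
#' Columns `onset_time_iso` (UTC, fixed origin 2020-01-01), `onset_h` and
#' `duration_s`.
#'
#' @param catalog A seizure catalog data.frame (`onset_h`, `duration_s`).
#' @param path Output CSV path.
#' @export
write_seizure_catalog <- function(catalog, path) {
  origin <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")
  out <- data.frame(
    onset_time_iso = format(origin + catalog$onset_h * 3600,
                            "%Y-%m-%dT%H:%M:%OS1Z", tz = "UTC"),
    onset_h = catalog$onset_h,
    duration_s = catalog$duration_s)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_seizure_catalog
#' @export
read_seizure_catalog <- function(path) {
  x <- utils::read.csv(path)
  structure(data.frame(onset_h = x$onset_h, duration_s = x$duration_s),
            class = c("seizure_catalog", "data.frame"))
}
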