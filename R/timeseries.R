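#' Construct a BOLD time-series object
#'
#' @param data T x V numeric matrix (frames by vertices).
#' @param tr Repetition time in seconds.
#' @param mask Logical vector of length V marking in-brain vertices.
#' @param fd Optional per-frame framewise displacement (mm).
#'
#' @return An object of class `bold_ts`.
#' @export
bold_ts <- function(data, tr, mask = rep(TRUE, ncol(data)), fd = NULL) {
  data <- as.matrix(data)
  if (nrow(data) < 2) {
    abort("A time series needs at least 2 frames.", class = "netdax_error_argument")
  }
  if (length(mask) != ncol(data)) {
    abort("`mask` length must equal the number of vertices.",
          class = "netdax_error_shape")
  }
  if (any(!is.finite(data[, mask, drop = FALSE]))) {
    abort("Non-finite values inside the mask.", class = "netdax_error_argument")
  }
  if (!is.null(fd) && length(fd) != nrow(data)) {
    abort("`fd` length must equal the number of frames.", class = "netdax_error_shape")
  }
  structure(list(data = data, tr = tr, mask = as.logical(mask), fd = fd),
            class = "bold_ts")
}

#' @export
print.bold_ts <- function(x, ...) {
  cat(sprintf("<bold_ts> %d frames x %d vertices, TR = %gs%s\n",
              nrow(x$data), ncol(x$data), x$tr,
              if (is.null(x$fd)) "" else ", FD attached"))
  invisible(x)
}

#' Select the minimum-motion contiguous segment of a scan
#'
#' Scans all contiguous windows of `min_frames` frames and returns the one
#' with the lowest mean framewise displacement (earliest window on ties). If
#' even that window's mean FD exceeds `fd_threshold`, the scan is flagged for
#' exclusion rather than erroring: exclusion is a data-quality outcome, not a
#' usage error.
#'
#' @param fd Numeric vector of per-frame framewise displacement (mm).
#' @param min_frames Minimum segment length in frames (default 120).
#' @param fd_threshold Mean-FD exclusion threshold in mm (default 0.4).
#'
#' @return A one-row tibble with `start`, `end` (1-based, inclusive),
#'   `mean_fd`, and `excluded`.
#' @export
select_motion_segment <- function(fd, min_frames = 120L, fd_threshold = 0.4) {
  min_frames <- assert_positive_int(min_frames, "min_frames")
  if (length(fd) < min_frames) {
    abort("Series shorter than the minimum segment length.",
          class = "netdax_error_too_short")
  }
  # rolling mean over every window of length min_frames
  cs <- c(0, cumsum(fd))
  n_win <- length(fd) - min_frames + 1L
  means <- (cs[(min_frames + 1L):(min_frames + n_win)] - cs[1:n_win]) / min_frames
  best <- which.min(means)  # which.min takes the earliest on ties
  tibble(
    start = as.integer(best),
    end = as.integer(best + min_frames - 1L),
    mean_fd = means[best],
    excluded = means[best] > fd_threshold
  )
}
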