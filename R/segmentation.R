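#' Active-segment detection parameters
#'
#' Gesture repetitions are found on the channel-mean signal by framing it and
#' thresholding two frame statistics: short-term energy and variance. A frame
#' is *active* when its statistics exceed the thresholds (both by default);
#' a maximal run of active frames becomes one active segment.
#'
#' Thresholds may be given as absolute values; when left `NULL` they are
#' calibrated from the first `rest_frames` frames (assumed rest) as
#' `mean + 3 * sd` of each statistic, which is reproducible and needs no
#' manual tuning. The default uses 40 frames (4 s at the default framing),
#' matching the lead-in rest the recording protocol guarantees: a 3-sigma
#' rule needs that many frames for a stable standard-deviation estimate.
#'
#' Detection frames are non-overlapping by default (`hop = frame_len`):
#' segment boundaries are reported as the first/last sample of the
#' first/last active frame, so with non-overlapping frames the boundary
#' error against a true onset is bounded by one hop.
#'
#' @param frame_len Frame length in samples (100 = 100 ms at 1000 Hz).
#' @param hop Hop between frame starts in samples; defaults to `frame_len`.
#' @param energy_threshold,var_threshold Absolute thresholds in squared
#'   signal units, or `NULL` for rest-calibrated thresholds.
#' @param min_segment_frames Discard active runs shorter than this many frames.
#' @param expected_segments If set and more runs survive, keep this many runs
#'   with the highest total energy (temporal order preserved).
#' @param rest_frames Number of leading frames used for threshold calibration.
#' @param mode `"and"` (a frame must exceed both thresholds) or `"or"`.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(frame_len = 100, hop = frame_len,
                                energy_threshold = NULL, var_threshold = NULL,
                                min_segment_frames = 2,
                                expected_segments = NULL,
                                rest_frames = 40, mode = c("and", "or")) {
  mode <- match.arg(mode)
  stopifnot(frame_len >= 1, hop >= 1, hop <= frame_len,
            min_segment_frames >= 1, rest_frames >= 2)
  if (!is.null(energy_threshold)) stopifnot(energy_threshold >= 0)
  if (!is.null(var_threshold)) stopifnot(var_threshold >= 0)
  structure(list(frame_len = as.integer(frame_len), hop = as.integer(hop),
                 energy_threshold = energy_threshold,
                 var_threshold = var_threshold,
                 min_segment_frames = as.integer(min_segment_frames),
                 expected_segments = expected_segments,
                 rest_frames = as.integer(rest_frames), mode = mode),
            class = "segmentation_params")
}

#' Channel-mean signal
#'
#' Averages all channels sample-wise into a single series; detection runs on
#' this mean signal rather than per channel.
#'
#' @param rec A [recording()].
#' @return Numeric vector of length `n_samples(rec)`.
#' @export
mean_signal <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  colMeans(rec$data)
}

#' Frame a series with a sliding window
#'
#' Frame `i` (1-based) covers samples `[(i-1)*hop, (i-1)*hop + frame_len)`;
#' a trailing remainder shorter than `frame_len` is dropped, so the number of
#' frames is `floor((length(x) - frame_len) / hop) + 1`.
#'
#' @param x Numeric vector.
#' @param frame_len Frame length in samples; must not exceed `length(x)`.
#' @param hop Hop between frame starts in samples.
#' @return A `frame_len` x `n_frames` matrix, one frame per column.
#' @export
frame_series <- function(x, frame_len, hop) {
  stopifnot(frame_len >= 1, hop >= 1)
  if (frame_len > length(x)) {
    abort(sprintf("frame_len (%d) exceeds series length (%d).",
                  frame_len, length(x)))
  }
  n_frames <- (length(x) - frame_len) %/% hop + 1L
  starts <- (seq_len(n_frames) - 1L) * hop
  idx <- outer(seq_len(frame_len), starts, `+`)
  matrix(x[idx], nrow = frame_len)
}

#' Short-term energy of a frame
#'
#' Mean squared amplitude, `E = (1/l) * sum(x^2)` over the `l` samples of the
#' frame.
#'
#' @param frame Numeric vector (one frame).
#' @return Non-negative scalar.
#' @export
short_term_energy <- function(frame) {
  if (length(frame) < 1L) abort("Empty frame.")
  mean(frame^2)
}

#' Frame variance
#'
#' Population variance `Var = (1/l) * sum((x - mean(x))^2)` (divide-by-`l`
#' convention, so a constant frame has variance exactly 0).
#'
#' @inheritParams short_term_energy
#' @return Non-negative scalar.
#' @export
frame_variance <- function(frame) {
  if (length(frame) < 1L) abort("Empty frame.")
  mean((frame - mean(frame))^2)
}

#' Detect active segments on a single-channel series
#'
#' Frames the series, computes per-frame short-term energy and variance,
#' thresholds them (see [segmentation_params()]), and returns maximal runs of
#' active frames as half-open sample intervals. A segment starts at the first
#' sample of the run's first active frame and ends just past the last sample
#' of its final active frame. Runs shorter than `min_segment_frames` are
#' discarded; if `expected_segments` is set and more runs survive, the runs
#' with the highest total energy are kept (in temporal order).
#'
#' @param x Numeric vector (typically [mean_signal()] output).
#' @param params A [segmentation_params()].
#' @return Tibble with columns `start`, `end` (0-based, half-open, sorted,
#'   non-overlapping); zero rows when nothing is active.
#' @export
detect_active_segments <- function(x, params = segmentation_params()) {
  stopifnot(inherits(params, "segmentation_params"))
  frames <- frame_series(x, params$frame_len, params$hop)
  e <- colMeans(frames^2)
  v <- e - colMeans(frames)^2
  thr_e <- params$energy_threshold
  thr_v <- params$var_threshold
  if (is.null(thr_e) || is.null(thr_v)) {
    k <- min(params$rest_frames, length(e))
    if (is.null(thr_e)) thr_e <- mean(e[1:k]) + 3 * sd(e[1:k])
    if (is.null(thr_v)) thr_v <- mean(v[1:k]) + 3 * sd(v[1:k])
  }
  active <- if (params$mode == "and") (e > thr_e) & (v > thr_v)
            else (e > thr_e) | (v > thr_v)
  active[is.na(active)] <- FALSE
  r <- rle(active)
  ends_f <- cumsum(r$lengths)
  starts_f <- ends_f - r$lengths + 1L
  keep <- r$values & r$lengths >= params$min_segment_frames
  starts_f <- starts_f[keep]; ends_f <- ends_f[keep]
  if (length(starts_f) == 0L) {
    return(tibble(start = integer(), end = integer()))
  }
  if (!is.null(params$expected_segments) &&
      length(starts_f) > params$expected_segments) {
    tot_e <- vapply(seq_along(starts_f), function(i) {
      sum(e[starts_f[i]:ends_f[i]])
    }, numeric(1))
    sel <- sort(order(tot_e, decreasing = TRUE)[seq_len(params$expected_segments)])
    starts_f <- starts_f[sel]; ends_f <- ends_f[sel]
  }
  tibble(start = (starts_f - 1L) * params$hop,
         end = (ends_f - 1L) * params$hop + params$frame_len)
}

#' Extract multichannel slices for detected intervals
#'
#' Maps detection intervals found on the mean signal back onto all channels,
#' returning one `active_segment` per interval with the verbatim multichannel
#' slice.
#'
#' @param rec A [recording()].
#' @param intervals Tibble/data frame with `start`, `end` columns (0-based,
#'   half-open), e.g. from [detect_active_segments()].
#' @return List of `active_segment` objects (fields `start`, `end`, `data`,
#'   `fs`).
#' @export
extract_segments <- function(rec, intervals) {
  stopifnot(inherits(rec, "recording"))
  intervals <- as.data.frame(intervals)
  lapply(seq_len(nrow(intervals)), function(i) {
    s <- intervals$start[i]; e <- intervals$end[i]
    if (s < 0 || e > n_samples(rec) || s >= e) {
      abort(sprintf("Interval [%d, %d) is outside the recording (0, %d].",
                    s, e, n_samples(rec)))
    }
    structure(list(start = s, end = e,
                   data = rec$data[, (s + 1L):e, drop = FALSE],
                   fs = rec$fs),
              class = "active_segment")
  })
}

#' @export
print.active_segment <- function(x, ...) {
  cat(sprintf("<active_segment> [%d, %d) %d channels x %d samples\n",
              x$start, x$end, nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' Length-normalize a segment by linear interpolation
#'
#' Resamples each channel onto `target_len` equally spaced points over the
#' segment's original support using piecewise-linear interpolation; first and
#' last samples are preserved exactly. Used to bring every repetition to the
#' maximal active-segment length before feature extraction.
#'
#' @param seg An `active_segment` (length >= 2) from [extract_segments()].
#' @param target_len Desired number of samples (>= 2).
#' @return An `active_segment` whose every channel has `target_len` samples.
#' @export
resample_to_length <- function(seg, target_len) {
  stopifnot(inherits(seg, "active_segment"))
  n <- ncol(seg$data)
  if (n < 2L) abort("Segment must have at least 2 samples.")
  if (target_len < 2L) abort("target_len must be at least 2.")
  xout <- seq(1, n, length.out = target_len)
  seg$data <- t(apply(seg$data, 1L, function(ch) {
    approx(x = seq_len(n), y = ch, xout = xout)$y
  }))
  if (nrow(seg$data) == 1L) seg$data <- matrix(seg$data, nrow = 1)
  seg
}
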