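#' Multichannel sEMG recording
#'
#' A `recording` bundles a channels-by-samples signal matrix with its sampling
#' rate and optional metadata: channel names, a gesture-class label, a subject
#' identifier, and ground-truth active-segment annotations.
#'
#' Sample indices are 0-based and annotation intervals are half-open
#' `[start, end)`, so `start = 0, end = n_samples` covers the whole recording.
#'
#' @param data Numeric matrix, one row per channel, one column per time sample.
#'   A vector is taken as a single channel.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel_names Optional character vector, one name per channel.
#' @param label Optional gesture-class identifier (scalar).
#' @param subject_id Optional subject identifier (scalar string).
#' @param annotations Optional two-column matrix (or list of length-2 vectors)
#'   of 0-based half-open `[start, end)` ground-truth active segments; must be
#'   sorted and non-overlapping within `[0, n_samples]`.
#'
#' @return An object of class `recording`.
#' @examples
#' rec <- recording(matrix(rnorm(200), nrow = 2), fs = 1000)
#' n_channels(rec)
#' n_samples(rec)
#' @export
recording <- function(data, fs, channel_names = NULL, label = NULL,
                      subject_id = NULL, annotations = NULL) {
  if (is.vector(data) && is.numeric(data)) data <- matrix(data, nrow = 1)
  if (!is.matrix(data) || !is.numeric(data)) {
    abort("`data` must be a numeric matrix (channels x samples).")
  }
  if (nrow(data) < 1L || ncol(data) < 1L) {
    abort("A recording needs at least one channel and one sample.")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a positive scalar sampling rate in Hz.")
  }
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_names) != nrow(data)) {
    abort(sprintf("Got %d channel names for %d channels.",
                  length(channel_names), nrow(data)))
  }
  annotations <- validate_annotations(annotations, ncol(data))
  rownames(data) <- channel_names
  structure(
    list(data = data, fs = fs, channel_names = as.character(channel_names),
         label = label, subject_id = subject_id, annotations = annotations),
    class = "recording"
  )
}

validate_annotations <- function(annotations, n_samples) {
  if (is.null(annotations)) return(NULL)
  if (is.list(annotations)) {
    annotations <- do.call(rbind, lapply(annotations, function(x) x[1:2]))
  }
  ann <- matrix(as.numeric(annotations), ncol = 2)
  colnames(ann) <- c("start", "end")
  if (any(ann[, 1] < 0) || any(ann[, 2] > n_samples) ||
      any(ann[, 1] >= ann[, 2])) {
    abort("Annotations must satisfy 0 <= start < end <= n_samples.")
  }
  if (nrow(ann) > 1L) {
    ord <- order(ann[, 1])
    ann <- ann[ord, , drop = FALSE]
    if (any(ann[-1, 1] < ann[-nrow(ann), 2])) {
      abort("Annotation intervals must be non-overlapping.")
    }
  }
  ann
}

#' @rdname recording
#' @param x A `recording`.
#' @export
n_channels <- function(x) nrow(x$data)

#' @rdname recording
#' @export
n_samples <- function(x) ncol(x$data)

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channel%s x %d samples @ %g Hz (%.2f s)\n",
              n_channels(x), if (n_channels(x) == 1) "" else "s",
              n_samples(x), x$fs, n_samples(x) / x$fs))
  if (!is.null(x$label)) cat("  label:", x$label, "\n")
  if (!is.null(x$subject_id)) cat("  subject:", x$subject_id, "\n")
  if (!is.null(x$annotations)) {
    cat(sprintf("  annotations: %d active segment(s)\n", nrow(x$annotations)))
  }
  invisible(x)
}

#' Tidy a recording into a long tibble
#'
#' One row per (channel, sample): columns `time_s`, `sample`, `channel`,
#' `value`. Convenient for ggplot2.
#'
#' @param x A `recording`.
#' @param ... Unused.
#' @return A tibble.
#' @export
as_tibble.recording <- function(x, ...) {
  tibble(
    sample = rep(seq_len(n_samples(x)) - 1L, each = n_channels(x)),
    time_s = rep((seq_len(n_samples(x)) - 1L) / x$fs, each = n_channels(x)),
    channel = rep(x$channel_names, times = n_samples(x)),
    value = as.vector(x$data)
  )
}

#' Plot the channels of a recording
#'
#' Faceted line plot of every channel against time, with ground-truth
#' annotations (if present) shaded.
#'
#' @param object A `recording`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recording <- function(object, ...) {
  df <- as_tibble(object)
  df$channel <- factor(df$channel, levels = object$channel_names)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "time [s]", y = "amplitude")
  if (!is.null(object$annotations)) {
    ann <- as.data.frame(object$annotations)
    p <- p + ggplot2::annotate("rect",
      xmin = ann$start / object$fs, xmax = ann$end / object$fs,
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "orange")
  }
  p
}
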