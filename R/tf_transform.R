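#' Discrete Fourier transform of one frame
#'
#' Computes the full complex DFT
#' `X(k) = sum_{n=0}^{N-1} x(n) exp(-i 2 pi n k / N)`, `k = 0..N-1`.
#' Implemented with [stats::fft()]; the package test-suite checks it against
#' a direct cosine/sine summation on all lengths up to 64.
#'
#' @param frame Numeric vector of length `N >= 1`.
#' @return Complex vector of length `N`.
#' @export
dft_frame <- function(frame) {
  if (length(frame) < 1L) abort("Empty frame.")
  fft(frame)
}

#' Split a spectrum into real/imaginary/magnitude/phase components
#'
#' Takes the full complex spectrum of a real frame, truncates it to the
#' one-sided form (bins `0..floor(N/2)`, which lose no information for real
#' input), and returns the four component vectors. Phase uses the
#' full-quadrant two-argument arctangent; the phase of an exactly zero bin is
#' defined as 0.
#'
#' @param X Complex spectrum from [dft_frame()].
#' @param fs Sampling rate in Hz of the framed signal.
#' @return An object of class `spectrum_frame` with fields `x_real`,
#'   `x_imag`, `x_mag`, `x_phase` (vectors over the one-sided bins),
#'   `bin_hz` (bin center frequencies), `N`, and `fs`.
#' @export
spectrum_components <- function(X, fs) {
  N <- length(X)
  keep <- seq_len(N %/% 2 + 1L)
  Xk <- X[keep]
  re <- Re(Xk); im <- Im(Xk)
  phase <- atan2(im, re)
  phase[re == 0 & im == 0] <- 0
  structure(list(x_real = re, x_imag = im,
                 x_mag = sqrt(re^2 + im^2), x_phase = phase,
                 bin_hz = (keep - 1L) * fs / N, N = N, fs = fs),
            class = "spectrum_frame")
}

#' @export
print.spectrum_frame <- function(x, ...) {
  cat(sprintf("<spectrum_frame> N = %d, fs = %g Hz, %d one-sided bins\n",
              x$N, x$fs, length(x$x_mag)))
  invisible(x)
}

#' Sliding-window DFT of an active segment
#'
#' Frames each channel (frame length `frame_ms` milliseconds, hop
#' `round(frame_len * (1 - overlap_frac))` samples), transforms every frame
#' with [dft_frame()], and stacks the requested one-sided component into a
#' channels x frames x bins tensor. `component = "stacked"` concatenates
#' real, imaginary, magnitude, and phase as four channel groups.
#'
#' @param seg An `active_segment` (or a [recording()], transformed whole).
#' @param frame_ms Frame length in milliseconds.
#' @param overlap_frac Overlap between consecutive frames as a fraction of
#'   the frame length, in `[0, 1)`.
#' @param component One of `"magnitude"`, `"real"`, `"imag"`, `"phase"`,
#'   `"stacked"`.
#' @param window `"rectangular"` (plain framing, the default) or `"hann"`.
#' @return A `tf_tensor`: list with `values` (array channels x frames x
#'   bins), `component`, `frame_ms`, `overlap_frac`, `fs`, `frame_len`,
#'   `hop`, `bin_hz`.
#' @export
stft_tensor <- function(seg, frame_ms = 50, overlap_frac = 0.4,
                        component = c("magnitude", "real", "imag", "phase",
                                      "stacked"),
                        window = c("rectangular", "hann")) {
  component <- match.arg(component)
  window <- match.arg(window)
  stopifnot(overlap_frac >= 0, overlap_frac < 1)
  data <- if (inherits(seg, "recording")) seg$data else seg$data
  fs <- seg$fs
  frame_len <- max(1L, as.integer(round(frame_ms * fs / 1000)))
  hop <- max(1L, as.integer(round(frame_len * (1 - overlap_frac))))
  if (frame_len > ncol(data)) {
    abort(sprintf("Frame of %d samples exceeds segment length %d.",
                  frame_len, ncol(data)))
  }
  taper <- if (window == "hann") {
    0.5 - 0.5 * cos(2 * pi * (seq_len(frame_len) - 1) / frame_len)
  } else rep(1, frame_len)
  n_bins <- frame_len %/% 2 + 1L
  per_channel <- lapply(seq_len(nrow(data)), function(c) {
    frames <- frame_series(data[c, ], frame_len, hop) * taper
    X <- stats::mvfft(frames)[seq_len(n_bins), , drop = FALSE]
    list(re = t(Re(X)), im = t(Im(X)))   # frames x bins
  })
  stack <- function(extract) {
    out <- array(0, dim = c(length(per_channel), nrow(per_channel[[1]]$re),
                            n_bins))
    for (c in seq_along(per_channel)) out[c, , ] <- extract(per_channel[[c]])
    out
  }
  mag_of <- function(pc) sqrt(pc$re^2 + pc$im^2)
  phase_of <- function(pc) {
    ph <- atan2(pc$im, pc$re)
    ph[pc$re == 0 & pc$im == 0] <- 0
    ph
  }
  values <- switch(component,
    magnitude = stack(mag_of),
    real = stack(function(pc) pc$re),
    imag = stack(function(pc) pc$im),
    phase = stack(phase_of),
    stacked = {
      parts <- list(stack(function(pc) pc$re), stack(function(pc) pc$im),
                    stack(mag_of), stack(phase_of))
      out <- array(0, dim = c(4 * dim(parts[[1]])[1], dim(parts[[1]])[2:3]))
      for (i in 1:4) {
        rows <- (i - 1) * dim(parts[[1]])[1] + seq_len(dim(parts[[1]])[1])
        out[rows, , ] <- parts[[i]]
      }
      out
    })
  structure(list(values = values, component = component, frame_ms = frame_ms,
                 overlap_frac = overlap_frac, fs = fs, frame_len = frame_len,
                 hop = hop, bin_hz = (seq_len(n_bins) - 1L) * fs / frame_len),
            class = "tf_tensor")
}

#' @export
print.tf_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<tf_tensor> %s: %d channels x %d frames x %d bins (frame %g ms, overlap %g)\n",
    x$component, d[1], d[2], d[3], x$frame_ms, x$overlap_frac))
  invisible(x)
}

#' Flatten a time-frequency tensor into network input
#'
#' Per channel, frames are concatenated in temporal order with bins in
#' ascending frequency within each frame, giving a channels x
#' (frames * bins) matrix. The layout is reversible; see
#' [unflatten_model_input()].
#'
#' @param tensor A `tf_tensor`.
#' @return Numeric matrix `n_channels x (n_frames * n_bins)` with attributes
#'   `n_frames` and `n_bins`.
#' @export
flatten_for_model <- function(tensor) {
  stopifnot(inherits(tensor, "tf_tensor"))
  d <- dim(tensor$values)
  out <- matrix(0, nrow = d[1], ncol = d[2] * d[3])
  for (f in seq_len(d[2])) {
    out[, (f - 1) * d[3] + seq_len(d[3])] <- tensor$values[, f, ]
  }
  attr(out, "n_frames") <- d[2]
  attr(out, "n_bins") <- d[3]
  out
}

#' Invert [flatten_for_model()]
#'
#' @param mat Matrix from [flatten_for_model()].
#' @param n_frames,n_bins Tensor dimensions; taken from `mat`'s attributes
#'   when omitted.
#' @return Array channels x frames x bins.
#' @export
unflatten_model_input <- function(mat, n_frames = attr(mat, "n_frames"),
                                  n_bins = attr(mat, "n_bins")) {
  stopifnot(ncol(mat) == n_frames * n_bins)
  out <- array(0, dim = c(nrow(mat), n_frames, n_bins))
  for (f in seq_len(n_frames)) {
    out[, f, ] <- mat[, (f - 1) * n_bins + seq_len(n_bins)]
  }
  out
}
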