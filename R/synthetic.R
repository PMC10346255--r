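#' Acquisition-protocol configuration for the synthetic generator
#'
#' Describes the recording protocol the generator emulates: several subjects
#' each perform every gesture class as a block of repetitions separated by
#' rest intervals, recorded over multiple sEMG channels. Defaults mirror a
#' 7-channel, 1000 Hz sign-language protocol with 10 subjects, 10 gestures,
#' and 5 repetitions separated by 4 s of rest, with active durations of
#' 2-2.664 s.
#'
#' @param n_subjects,n_gestures,n_repetitions,n_channels Protocol counts.
#' @param fs Sampling rate in Hz.
#' @param active_duration_ms Length-2 range (min, max) of one repetition's
#'   active duration in ms; each repetition draws uniformly from it.
#' @param rest_duration_ms Rest before, between, and after repetitions (ms).
#' @param snr_db Activation-to-rest amplitude ratio in dB: the active
#'   carrier's amplitude is `10^(snr_db/20)` times the unit rest-noise
#'   standard deviation (before per-channel gains).
#' @param ramp_ms Raised-cosine rise/fall time of activation envelopes (ms).
#'   Emulates physiological force onset; kept no longer than one detection
#'   frame so that onset/offset ambiguity stays within a single frame.
#' @param dynamic_fraction Fraction of gesture classes given multi-phase
#'   (time-varying) envelopes; the rest hold a single plateau.
#' @param subject_sigma Standard deviation of the per-subject lognormal
#'   channel-gain jitter.
#' @param seed Integer seed; identical configurations generate identical
#'   datasets.
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(n_subjects = 10, n_gestures = 10,
                            n_repetitions = 5, n_channels = 7, fs = 1000,
                            active_duration_ms = c(2000, 2664),
                            rest_duration_ms = 4000, snr_db = 20,
                            ramp_ms = 100, dynamic_fraction = 0.3,
                            subject_sigma = 0.1, seed = 1L) {
  stopifnot(n_subjects >= 1, n_gestures >= 1, n_repetitions >= 1,
            n_channels >= 1, fs > 0, length(active_duration_ms) == 2,
            all(active_duration_ms > 0),
            active_duration_ms[1] <= active_duration_ms[2],
            rest_duration_ms > 0, ramp_ms >= 0,
            dynamic_fraction >= 0, dynamic_fraction <= 1,
            subject_sigma >= 0)
  structure(as.list(environment()), class = "protocol_config")
}

#' @export
print.protocol_config <- function(x, ...) {
  cat(sprintf(
    "<protocol_config> %d subjects x %d gestures x %d reps, %d channels @ %g Hz\n",
    x$n_subjects, x$n_gestures, x$n_repetitions, x$n_channels, x$fs))
  cat(sprintf("  active %g-%g ms, rest %g ms, snr %g dB, seed %d\n",
              x$active_duration_ms[1], x$active_duration_ms[2],
              x$rest_duration_ms, x$snr_db, x$seed))
  invisible(x)
}

#' Gesture activation template
#'
#' The per-class recipe the generator modulates: relative activation
#' amplitude of each channel and an envelope that is either a single plateau
#' (static gestures) or a sequence of 2-3 phases with phase-specific channel
#' gains (dynamic gestures composed of sub-movements).
#'
#' @param channel_gains Non-negative vector of relative channel amplitudes;
#'   at least one must be positive.
#' @param envelope_kind `"static"` or `"dynamic"`.
#' @param phase_gains For dynamic templates, a `n_phases x n_channels`
#'   matrix of per-phase multipliers on `channel_gains` (ignored for static).
#' @param phase_fracs For dynamic templates, positive fractions of the
#'   active duration given to each phase (normalized to sum 1).
#' @return An object of class `gesture_template`.
#' @export
gesture_template <- function(channel_gains,
                             envelope_kind = c("static", "dynamic"),
                             phase_gains = NULL, phase_fracs = NULL) {
  envelope_kind <- match.arg(envelope_kind)
  stopifnot(all(channel_gains >= 0), any(channel_gains > 0))
  if (envelope_kind == "dynamic") {
    stopifnot(is.matrix(phase_gains),
              ncol(phase_gains) == length(channel_gains),
              nrow(phase_gains) >= 2)
    if (is.null(phase_fracs)) phase_fracs <- rep(1, nrow(phase_gains))
    stopifnot(length(phase_fracs) == nrow(phase_gains), all(phase_fracs > 0))
    phase_fracs <- phase_fracs / sum(phase_fracs)
  }
  structure(list(channel_gains = channel_gains,
                 envelope_kind = envelope_kind,
                 phase_gains = phase_gains, phase_fracs = phase_fracs),
            class = "gesture_template")
}

# Evaluate code under a temporary RNG state, restoring the caller's.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Activation envelope for one channel, length n samples: per-phase plateau
# levels smoothed with a raised-cosine kernel of width ramp_n, which turns
# the edges and internal phase boundaries into soft ramps.
channel_envelope <- function(n, levels, fracs, ramp_n) {
  bounds <- round(cumsum(c(0, fracs)) * n)
  counts <- diff(bounds)
  counts[length(counts)] <- n - sum(head(counts, -1))
  env <- rep(levels, times = counts)
  if (ramp_n >= 2) {
    w <- 0.5 - 0.5 * cos(2 * pi * seq_len(ramp_n) / (ramp_n + 1))
    w <- w / sum(w)
    padded <- stats::filter(c(rep(0, ramp_n), env, rep(0, ramp_n)), w,
                            sides = 2)
    env <- as.numeric(padded[ramp_n + seq_len(n)])
    env[is.na(env)] <- 0
  }
  env
}

band_limited_noise <- function(n, fs, lo = 20, hi = 450) {
  co <- bandpass_coefs(filter_spec(band_low = lo, band_high = hi), fs)
  pad <- 200
  x <- signal::filtfilt(filt = co$b, a = co$a, rnorm(n + 2 * pad))
  x <- x[pad + seq_len(n)]
  x / sd(x)
}

#' Generate one protocol-structured recording
#'
#' Synthesizes a multichannel sEMG surrogate: unit-variance Gaussian
#' baseline noise everywhere, plus—during each of `n_repetitions` active
#' windows—a 20-450 Hz band-limited Gaussian carrier amplitude-modulated by
#' the template envelope and channel gains, scaled to `snr_db`. Ground-truth
#' active windows are stored in the recording's annotations. The same
#' `(protocol, template, seed)` triple always returns bit-identical output.
#'
#' @param protocol A [protocol_config()].
#' @param template A [gesture_template()] with `protocol$n_channels` gains.
#' @param seed Integer seed for this recording.
#' @param label,subject_id Optional metadata stored on the recording.
#' @return A [recording()] with annotations.
#' @export
generate_recording <- function(protocol, template, seed,
                               label = NULL, subject_id = NULL) {
  stopifnot(inherits(protocol, "protocol_config"),
            inherits(template, "gesture_template"),
            length(template$channel_gains) == protocol$n_channels)
  p <- protocol
  ms <- function(x) as.integer(round(x * p$fs / 1000))
  rest_n <- ms(p$rest_duration_ms)
  ramp_n <- ms(p$ramp_ms)
  amp <- 10^(p$snr_db / 20)
  with_seed(seed, {
    durs <- ms(runif(p$n_repetitions, p$active_duration_ms[1],
                     p$active_duration_ms[2]))
    starts <- rest_n + cumsum(c(0, head(durs, -1) + rest_n))
    total <- rest_n + sum(durs + rest_n)
    data <- matrix(rnorm(p$n_channels * total), nrow = p$n_channels)
    for (r in seq_len(p$n_repetitions)) {
      n <- durs[r]
      idx <- starts[r] + seq_len(n)
      for (c in seq_len(p$n_channels)) {
        levels <- if (template$envelope_kind == "static") {
          template$channel_gains[c]
        } else {
          template$channel_gains[c] * template$phase_gains[, c]
        }
        fracs <- template$phase_fracs %||% 1
        env <- channel_envelope(n, levels, fracs, ramp_n)
        data[c, idx] <- data[c, idx] +
          amp * env * band_limited_noise(n, p$fs)
      }
    }
    ann <- cbind(start = starts, end = starts + durs)
    recording(data, fs = p$fs, label = label, subject_id = subject_id,
              annotations = ann)
  })
}

#' Generate a full labeled, segmented, length-normalized dataset
#'
#' Draws one [gesture_template()] per gesture class (shared across subjects,
#' with per-subject lognormal gain jitter), generates one recording per
#' (subject, gesture) "basic structure", runs the detection pipeline
#' (optional denoising, channel-mean thresholding with
#' `expected_segments = n_repetitions`, extraction, linear-interpolation
#' length normalization to the maximal detected segment length), and
#' assembles the result. The manifest counts one sample per channel of one
#' repetition's active segment, so the default protocol yields
#' `10 x 10 = 100` structures and `100 x 5 x 7 = 3500` samples.
#'
#' @param protocol A [protocol_config()].
#' @param seg_params A [segmentation_params()]; `expected_segments` is set
#'   to the protocol's repetition count.
#' @param preprocess Apply [denoise()] before segmentation?
#' @param target_len Fixed normalization length in samples, or `NULL` to use
#'   the maximal detected segment length.
#' @return An `emg_dataset`: list with `segments` (array `n_channels x
#'   target_len x n_instances`), `labels` (factor of gesture classes),
#'   `subject`, `repetition`, `manifest` (one row per channel-sample),
#'   `n_structures`, `target_len`, and the protocol.
#' @export
generate_dataset <- function(protocol = protocol_config(),
                             seg_params = segmentation_params(),
                             preprocess = TRUE, target_len = NULL) {
  p <- protocol
  seg_params$expected_segments <- p$n_repetitions
  # calibrate thresholds on the lead-in rest the protocol guarantees
  lead_frames <- floor(p$rest_duration_ms * p$fs / 1000 / seg_params$hop)
  seg_params$rest_frames <- max(2L, min(seg_params$rest_frames,
                                        as.integer(lead_frames)))
  setup <- with_seed(p$seed, {
    dyn <- sample(p$n_gestures, round(p$dynamic_fraction * p$n_gestures))
    templates <- lapply(seq_len(p$n_gestures), function(g) {
      gains <- runif(p$n_channels, 0.3, 1.5)
      if (g %in% dyn) {
        n_phases <- sample(2:3, 1)
        gesture_template(gains, "dynamic",
                         phase_gains = matrix(runif(n_phases * p$n_channels,
                                                    0.3, 1.5),
                                              nrow = n_phases),
                         phase_fracs = runif(n_phases, 0.5, 1))
      } else {
        gesture_template(gains, "static")
      }
    })
    jitter <- array(exp(rnorm(p$n_subjects * p$n_gestures * p$n_channels,
                              0, p$subject_sigma)),
                    dim = c(p$n_subjects, p$n_gestures, p$n_channels))
    rec_seeds <- matrix(sample.int(.Machine$integer.max,
                                   p$n_subjects * p$n_gestures),
                        nrow = p$n_subjects)
    list(templates = templates, jitter = jitter, rec_seeds = rec_seeds)
  })
  fspec <- filter_spec()
  segments <- list(); meta <- list()
  for (s in seq_len(p$n_subjects)) {
    for (g in seq_len(p$n_gestures)) {
      tpl <- setup$templates[[g]]
      tpl$channel_gains <- tpl$channel_gains * setup$jitter[s, g, ]
      rec <- generate_recording(p, tpl, seed = setup$rec_seeds[s, g],
                                label = g, subject_id = sprintf("S%02d", s))
      if (preprocess) rec <- denoise(rec, fspec)
      iv <- detect_active_segments(mean_signal(rec), seg_params)
      if (nrow(iv) != p$n_repetitions) {
        abort(sprintf(
          "Segmentation found %d active segments (expected %d) for subject %d, gesture %d.",
          nrow(iv), p$n_repetitions, s, g))
      }
      segs <- extract_segments(rec, iv)
      for (r in seq_along(segs)) {
        segments[[length(segments) + 1L]] <- segs[[r]]
        meta[[length(meta) + 1L]] <-
          list(subject = s, gesture = g, repetition = r,
               start = segs[[r]]$start, end = segs[[r]]$end)
      }
    }
  }
  lens <- vapply(segments, function(x) ncol(x$data), integer(1))
  tl <- as.integer(target_len %||% max(lens))
  arr <- array(0, dim = c(p$n_channels, tl, length(segments)))
  for (i in seq_along(segments)) {
    arr[, , i] <- resample_to_length(segments[[i]], tl)$data
  }
  md <- dplyr::bind_rows(lapply(meta, tibble::as_tibble))
  manifest <- tidyr::expand_grid(md, channel = seq_len(p$n_channels)) |>
    dplyr::arrange(.data$subject, .data$gesture, .data$repetition,
                   .data$channel) |>
    dplyr::mutate(sample_id = dplyr::row_number(), .before = 1)
  structure(list(segments = arr,
                 labels = factor(md$gesture,
                                 levels = seq_len(p$n_gestures)),
                 subject = md$subject, repetition = md$repetition,
                 manifest = manifest,
                 n_structures = as.integer(p$n_subjects * p$n_gestures),
                 target_len = tl, protocol = p),
            class = "emg_dataset")
}

#' @export
print.emg_dataset <- function(x, ...) {
  d <- dim(x$segments)
  cat(sprintf(
    "<emg_dataset> %d structures, %d instances (%d channels x %d samples), %d manifest samples\n",
    x$n_structures, d[3], d[1], d[2], nrow(x$manifest)))
  invisible(x)
}

#' Spectral sanity report for generated recordings
#'
#' Checks that generated signals look like surface EMG in the frequency
#' domain: within annotated active windows, at least `threshold` of the
#' power (periodogram, one-sided) should fall in the EMG band; rest windows
#' should look like broadband noise (their band fraction sits near the
#' analytic flat-spectrum value, bandwidth / Nyquist).
#'
#' @param rec A [recording()] (annotations used when present; otherwise the
#'   whole recording is treated as one window).
#' @param band_low,band_high EMG band edges in Hz.
#' @param threshold Required active-window band-power fraction.
#' @return Tibble with one row per window type: `window` ("active"/"rest"),
#'   `band_fraction`, `expected_flat` (the flat-spectrum reference), and
#'   `pass` (active rows only).
#' @export
spectral_validity_check <- function(rec, band_low = 20, band_high = 450,
                                    threshold = 0.9) {
  stopifnot(inherits(rec, "recording"))
  frac <- function(cols) {
    mean(apply(rec$data[, cols, drop = FALSE], 1L, function(x) {
      P <- Mod(fft(x))^2
      n <- length(x)
      keep <- seq_len(n %/% 2 + 1)
      f <- (keep - 1) * rec$fs / n
      sum(P[keep][f >= band_low & f <= band_high]) / sum(P[keep])
    }))
  }
  n <- n_samples(rec)
  flat <- (band_high - band_low) / (rec$fs / 2)
  if (is.null(rec$annotations)) {
    return(tibble(window = "all", band_fraction = frac(seq_len(n)),
                  expected_flat = flat,
                  pass = frac(seq_len(n)) >= threshold))
  }
  act <- unlist(lapply(seq_len(nrow(rec$annotations)), function(i) {
    (rec$annotations[i, 1] + 1):rec$annotations[i, 2]
  }))
  rest <- setdiff(seq_len(n), act)
  fa <- frac(act)
  tibble(window = c("active", "rest"),
         band_fraction = c(fa, frac(rest)),
         expected_flat = flat,
         pass = c(fa >= threshold, NA))
}
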