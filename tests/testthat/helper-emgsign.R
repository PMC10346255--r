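# Shared fixtures and independent oracles for the test-suite.

# Direct cosine/sine summation DFT (O(N^2)), the independent oracle for the
# fft-backed implementation.
dft_direct <- function(x) {
  N <- length(x)
  vapply(0:(N - 1), function(k) {
    ang <- 2 * pi * (0:(N - 1)) * k / N
    complex(real = sum(x * cos(ang)), imaginary = -sum(x * sin(ang)))
  }, complex(1))
}

# Pointwise two-point linear interpolation oracle for resample_to_length.
lin_interp_direct <- function(y, target_len) {
  n <- length(y)
  xout <- seq(1, n, length.out = target_len)
  vapply(xout, function(x) {
    lo <- floor(x); hi <- ceiling(x)
    if (lo == hi) y[lo] else y[lo] + (x - lo) * (y[hi] - y[lo])
  }, numeric(1))
}

# Small, quickly generated protocol for end-to-end tests.
tiny_protocol <- function(seed = 11, n_gestures = 4, n_subjects = 2,
                          n_repetitions = 3, n_channels = 3) {
  protocol_config(n_subjects = n_subjects, n_gestures = n_gestures,
                  n_repetitions = n_repetitions, n_channels = n_channels,
                  active_duration_ms = c(400, 600),
                  rest_duration_ms = 1200, seed = seed)
}

# Tiny network configuration for training-path tests.
tiny_model_args <- function() {
  list(n_blocks_A = 1, n_blocks_B = 1, branch_kernels = c(4, 6, 8),
       filters_branch_A = 4, filters_branch_B = 8, filters_reduce_B = 4,
       stem_filters = 4, dropout_rate = 0.2)
}

# Nearest-centroid classifier on log mean per-channel energies: the
# template-matched linear baseline that certifies class separability.
energy_centroid_accuracy <- function(dataset, train_idx, test_idx) {
  feats <- t(apply(dataset$segments, 3, function(m) log(rowMeans(m^2))))
  centroids <- sapply(split(train_idx, dataset$labels[train_idx]),
                      function(ix) colMeans(feats[ix, , drop = FALSE]))
  pred <- apply(feats[test_idx, , drop = FALSE], 1, function(f) {
    colnames(centroids)[which.min(colSums((centroids - f)^2))]
  })
  mean(pred == as.character(dataset$labels[test_idx]))
}
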