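test_that("dft_frame matches analytic single-bin results", {
  expect_equal(dft_frame(c(1, 0, 0, 0)), rep(1 + 0i, 4))
  expect_equal(dft_frame(rep(3, 8)), c(24 + 0i, rep(0 + 0i, 7)))
  x <- cos(2 * pi * 3 * (0:31) / 32)
  X <- dft_frame(x)
  expect_equal(Mod(X[4]), 16)    # bin k = 3
  expect_equal(Mod(X[30]), 16)   # bin k = 29 = 32 - 3
  expect_lt(max(Mod(X[-c(4, 30)])), 1e-9)
})

test_that("dft_frame agrees with the direct summation oracle on lengths 1-64", {
  set.seed(17)
  worst <- 0
  for (N in 1:64) {
    x <- rnorm(N)
    worst <- max(worst, max(Mod(dft_frame(x) - dft_direct(x))))
  }
  expect_lt(worst, 1e-9)
})

test_that("real input gives Hermitian spectra and Parseval holds", {
  set.seed(18)
  for (N in c(2, 7, 16, 33)) {
    x <- rnorm(N)
    X <- dft_frame(x)
    k <- 1:(N - 1)
    expect_equal(X[k + 1], Conj(X[N - k + 1]), tolerance = 1e-9)
    expect_equal(sum(x^2), sum(Mod(X)^2) / N, tolerance = 1e-9)
  }
})

test_that("spectrum components decompose bins correctly", {
  sf <- spectrum_components(c(10 + 0i, 3 - 4i, 0 + 0i), fs = 10)
  # one-sided truncation of a length-3 spectrum keeps bins 0..1
  expect_equal(length(sf$x_mag), 2)
  expect_equal(sf$x_real[2], 3)
  expect_equal(sf$x_imag[2], -4)
  expect_equal(sf$x_mag[2], 5)
  expect_equal(sf$x_phase[2], atan2(-4, 3))

  sf0 <- spectrum_components(c(0 + 0i, 0 + 0i, 0 + 0i, 0 + 0i), fs = 8)
  expect_equal(sf0$x_mag, c(0, 0, 0))
  expect_equal(sf0$x_phase, c(0, 0, 0))

  set.seed(19)
  x <- rnorm(20)
  sf <- spectrum_components(dft_frame(x), fs = 100)
  expect_equal(sf$x_mag^2, sf$x_real^2 + sf$x_imag^2, tolerance = 1e-9)
  expect_equal(length(sf$x_mag), 11)
})

test_that("stft tensors have the closed-form frame and bin counts", {
  seg <- structure(list(data = matrix(rnorm(7 * 2664), nrow = 7), fs = 1000,
                        start = 0L, end = 2664L), class = "active_segment")
  tens <- stft_tensor(seg, frame_ms = 50, overlap_frac = 0.4)
  expect_equal(dim(tens$values), c(7, 88, 26))
  expect_equal(tens$hop, 30)

  # closed forms across a small sweep grid
  for (fm in c(20, 50, 100)) {
    for (ov in c(0, 0.4, 0.5)) {
      tt <- stft_tensor(seg, frame_ms = fm, overlap_frac = ov)
      fl <- round(fm * 1000 / 1000)
      hp <- round(fl * (1 - ov))
      expect_equal(dim(tt$values)[2], (2664 - fl) %/% hp + 1)
      expect_equal(dim(tt$values)[3], fl %/% 2 + 1)
    }
  }
  expect_error(stft_tensor(seg, frame_ms = 5000), "exceeds")
})

test_that("a pure tone lands in the right frequency bin of every frame", {
  t <- 0:2663
  seg <- structure(list(data = matrix(sin(2 * pi * 100 * t / 1000),
                                      nrow = 1), fs = 1000,
                        start = 0L, end = 2664L), class = "active_segment")
  tens <- stft_tensor(seg, frame_ms = 50, overlap_frac = 0.4)
  bin_width <- 1000 / tens$frame_len
  for (f in seq_len(dim(tens$values)[2])) {
    peak <- which.max(tens$values[1, f, ])
    expect_lte(abs(tens$bin_hz[peak] - 100), bin_width)
  }
  # constant segment: all energy in the DC bin
  segc <- structure(list(data = matrix(2, 1, 300), fs = 1000,
                         start = 0L, end = 300L), class = "active_segment")
  tc <- stft_tensor(segc, frame_ms = 50, overlap_frac = 0.4)
  expect_true(all(tc$values[1, , 1] > 0))
  expect_lt(max(tc$values[1, , -1]), 1e-9)
})

test_that("flattening is size-correct, reversible, and local", {
  seg <- structure(list(data = matrix(rnorm(7 * 2664), nrow = 7), fs = 1000,
                        start = 0L, end = 2664L), class = "active_segment")
  tens <- stft_tensor(seg)
  flat <- flatten_for_model(tens)
  expect_equal(dim(flat), c(7, 88 * 26))
  expect_equal(unflatten_model_input(flat), tens$values)

  tens2 <- tens
  tens2$values[, 5, ] <- tens2$values[, 5, ] + 1
  flat2 <- flatten_for_model(tens2)
  changed <- which(colSums(abs(flat2 - flat)) > 0)
  expect_equal(changed, 4 * 26 + seq_len(26))
})

test_that("the stacked component concatenates four channel groups", {
  seg <- structure(list(data = matrix(rnorm(2 * 500), nrow = 2), fs = 1000,
                        start = 0L, end = 500L), class = "active_segment")
  st <- stft_tensor(seg, component = "stacked")
  mg <- stft_tensor(seg, component = "magnitude")
  re <- stft_tensor(seg, component = "real")
  expect_equal(dim(st$values)[1], 8)
  expect_equal(st$values[1:2, , ], re$values)
  expect_equal(st$values[5:6, , ], mg$values)
})
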