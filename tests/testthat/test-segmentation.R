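test_that("mean_signal averages channels sample-wise", {
  expect_equal(mean_signal(recording(rbind(c(1, 1), c(3, 3)), fs = 1)),
               c(2, 2))
  x <- rnorm(10)
  expect_equal(mean_signal(recording(matrix(x, 1), fs = 1)), x)
  expect_equal(mean_signal(recording(rbind(c(1, -1), c(-1, 1)), fs = 1)),
               c(0, 0))
})

test_that("frame_series enumerates sliding windows exactly", {
  f <- frame_series(0:9, frame_len = 4, hop = 2)
  expect_equal(ncol(f), 4)
  expect_equal(f[1, ], c(0, 2, 4, 6))        # frame starts
  expect_equal(f[, 2], 2:5)
  expect_equal(ncol(frame_series(1:7, 7, 3)), 1)
  expect_equal(ncol(frame_series(rnorm(2664), 50, 30)), 88)
  expect_error(frame_series(1:5, 10, 2), "exceeds")
})

test_that("short-term energy and variance follow the divide-by-l forms", {
  expect_equal(short_term_energy(c(2, 2, 2, 2)), 4)
  expect_equal(short_term_energy(c(1, -1, 1, -1)), 1)
  expect_equal(short_term_energy(c(0, 0, 0)), 0)
  expect_equal(frame_variance(rep(7.3, 5)), 0)
  expect_equal(frame_variance(c(1, -1)), 1)
  expect_equal(frame_variance(c(0, 2)), 1)
  # quadratic scaling property
  set.seed(3)
  for (a in c(0.5, 2, -3)) {
    x <- rnorm(64)
    expect_equal(short_term_energy(a * x), a^2 * short_term_energy(x))
    expect_equal(frame_variance(a * x), a^2 * frame_variance(x))
  }
})

test_that("detection returns nothing on inactive series and filters blips", {
  prm <- segmentation_params(frame_len = 10, hop = 10,
                             energy_threshold = 0.5, var_threshold = 0.5)
  expect_equal(nrow(detect_active_segments(rep(0, 200), prm)), 0)
  blip <- rep(0, 200); blip[101:110] <- rep(c(5, -5), 5)
  prm2 <- segmentation_params(frame_len = 10, hop = 10,
                              energy_threshold = 0.5, var_threshold = 0.5,
                              min_segment_frames = 2)
  expect_equal(nrow(detect_active_segments(blip, prm2)), 0)
  prm1 <- segmentation_params(frame_len = 10, hop = 10,
                              energy_threshold = 0.5, var_threshold = 0.5,
                              min_segment_frames = 1)
  expect_equal(detect_active_segments(blip, prm1)$start, 100)
})

test_that("generator bursts are recovered within one hop of ground truth", {
  p <- tiny_protocol(seed = 5, n_gestures = 1, n_subjects = 1,
                     n_repetitions = 5, n_channels = 7)
  p$active_duration_ms <- c(2000, 2664)
  p$rest_duration_ms <- 4000
  tpl <- local({set.seed(5); gesture_template(runif(7, 0.5, 1.5))})
  rec <- generate_recording(p, tpl, seed = 123)
  prm <- segmentation_params(expected_segments = 5)
  iv <- detect_active_segments(mean_signal(rec), prm)
  expect_equal(nrow(iv), 5)
  expect_true(all(abs(iv$start - rec$annotations[, "start"]) <= prm$hop))
  expect_true(all(abs(iv$end - rec$annotations[, "end"]) <= prm$hop))
})

test_that("detection boundaries shift by at most one hop under small delays", {
  p <- tiny_protocol(seed = 6, n_gestures = 1, n_subjects = 1,
                     n_repetitions = 3, n_channels = 2)
  rec <- generate_recording(p, gesture_template(c(1, 1)), seed = 9)
  x <- mean_signal(rec)
  # calibrate on the 1.2 s lead-in rest this tiny protocol provides
  prm <- segmentation_params(expected_segments = 3, rest_frames = 12)
  base <- detect_active_segments(x, prm)
  set.seed(10)
  delayed <- detect_active_segments(c(rnorm(40), x), prm)
  expect_equal(nrow(delayed), 3)
  expect_true(all(abs((delayed$start - 40) - base$start) <= prm$hop))
})

test_that("extraction slices channels verbatim and checks bounds", {
  rec <- recording(matrix(rnorm(60), nrow = 3), fs = 100)
  whole <- extract_segments(rec, tibble::tibble(start = 0, end = 20))[[1]]
  expect_equal(whole$data, rec$data)
  two <- extract_segments(rec, tibble::tibble(start = c(0, 12),
                                              end = c(5, 20)))
  expect_equal(sum(vapply(two, function(s) ncol(s$data), integer(1))),
               (5 - 0) + (20 - 12))
  expect_error(extract_segments(rec, tibble::tibble(start = 10, end = 25)),
               "outside")
})

test_that("length normalization is exact linear interpolation", {
  rec <- recording(matrix(rnorm(40), nrow = 2), fs = 100)
  seg <- extract_segments(rec, tibble::tibble(start = 0, end = 20))[[1]]
  same <- resample_to_length(seg, 20)
  expect_equal(same$data, seg$data, tolerance = 1e-12)

  ramp <- extract_segments(recording(matrix(0:9, nrow = 1), fs = 10),
                           tibble::tibble(start = 0, end = 10))[[1]]
  up <- resample_to_length(ramp, 19)
  expect_equal(up$data[1, ], seq(0, 9, length.out = 19))

  set.seed(8)
  for (tl in c(7, 23, 61)) {
    out <- resample_to_length(seg, tl)
    expect_equal(dim(out$data), c(2L, tl))
    for (c in 1:2) {
      expect_equal(out$data[c, ], lin_interp_direct(seg$data[c, ], tl),
                   tolerance = 1e-9)
    }
    expect_equal(out$data[, 1], seg$data[, 1])
    expect_equal(out$data[, tl], seg$data[, 20])
  }
  expect_error(resample_to_length(seg, 1), "at least 2")
})

test_that("detect->extract->resample yields equal-length segments per run", {
  p <- tiny_protocol(seed = 21)
  ds <- generate_dataset(p)
  expect_equal(dim(ds$segments)[3],
               p$n_subjects * p$n_gestures * p$n_repetitions)
  expect_true(all(dim(ds$segments)[2] == ds$target_len))
})
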