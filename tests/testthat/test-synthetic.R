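test_that("generation is deterministic under a fixed seed", {
  p <- tiny_protocol(seed = 31)
  tpl <- gesture_template(runif(p$n_channels, 0.5, 1.5))
  a <- generate_recording(p, tpl, seed = 77)
  b <- generate_recording(p, tpl, seed = 77)
  expect_identical(a$data, b$data)
  expect_identical(a$annotations, b$annotations)
  c <- generate_recording(p, tpl, seed = 78)
  expect_false(identical(a$data, c$data))
})

test_that("recordings carry one annotation per repetition with rest between", {
  p <- protocol_config(n_subjects = 1, n_gestures = 1, n_repetitions = 5,
                       seed = 1)
  rec <- generate_recording(p, gesture_template(rep(1, 7)), seed = 2)
  ann <- rec$annotations
  expect_equal(nrow(ann), 5)
  expect_true(all(ann[-1, "start"] - ann[-5, "end"] == 4000))
  durs <- ann[, "end"] - ann[, "start"]
  expect_true(all(durs >= 2000 & durs <= 2664))
})

test_that("activation energy dominates rest energy at the configured SNR", {
  p <- tiny_protocol(seed = 41, n_channels = 7)
  p$snr_db <- 20
  rec <- generate_recording(p, gesture_template(runif(7, 0.8, 1.2)),
                            seed = 5)
  act <- unlist(lapply(seq_len(nrow(rec$annotations)), function(i) {
    (rec$annotations[i, 1] + 1):rec$annotations[i, 2]
  }))
  rest <- setdiff(seq_len(n_samples(rec)), act)
  e_act <- mean(rec$data[, act]^2)
  e_rest <- mean(rec$data[, rest]^2)
  expect_gte(e_act / e_rest, 10)
})

test_that("dataset assembly follows the per-channel counting convention", {
  p <- protocol_config(n_subjects = 1, n_gestures = 2, n_repetitions = 3,
                       n_channels = 2, active_duration_ms = c(400, 600),
                       rest_duration_ms = 1200, seed = 13)
  ds <- generate_dataset(p)
  expect_equal(ds$n_structures, 2)
  expect_equal(nrow(ds$manifest), 1 * 2 * 3 * 2)
  expect_equal(dim(ds$segments)[3], 6)
  expect_equal(levels(ds$labels), c("1", "2"))
  expect_equal(as.vector(table(ds$manifest$channel)), c(6, 6))
  # identical protocol => identical manifest
  ds2 <- generate_dataset(p)
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(ds$segments, ds2$segments)
})

test_that("generated spectra look like band-limited EMG", {
  p <- tiny_protocol(seed = 51, n_channels = 3)
  rec <- generate_recording(p, gesture_template(rep(1, 3)), seed = 6)
  rep_tbl <- spectral_validity_check(rec)
  expect_gte(rep_tbl$band_fraction[rep_tbl$window == "active"], 0.9)
  expect_true(rep_tbl$pass[rep_tbl$window == "active"])
  # rest windows sit near the flat-spectrum reference, below the EMG bar
  expect_equal(rep_tbl$band_fraction[rep_tbl$window == "rest"], 0.86,
               tolerance = 0.02)

  dc <- recording(matrix(1, 1, 500), fs = 1000)
  expect_false(spectral_validity_check(dc)$pass)

  set.seed(60)
  white <- recording(matrix(rnorm(3 * 4000), nrow = 3), fs = 1000)
  wf <- spectral_validity_check(white)
  expect_equal(wf$band_fraction, 430 / 500, tolerance = 0.02)
  expect_false(wf$pass)
})

test_that("per-channel energy patterns separate the classes linearly", {
  p <- protocol_config(n_subjects = 3, n_gestures = 10, n_repetitions = 5,
                       n_channels = 7, active_duration_ms = c(2000, 2664),
                       rest_duration_ms = 4000, seed = 71)
  ds <- generate_dataset(p)
  sp <- stratified_split(ds$labels, split_spec(seed = 72))
  acc <- energy_centroid_accuracy(ds, c(sp$train, sp$val), sp$test)
  expect_gte(acc, 0.9)
})
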