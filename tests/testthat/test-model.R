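test_that("built networks have the configured output width and block counts", {
  cfg <- model_config(n_classes = 10, input_channels = 7,
                      input_length = 2288, n_blocks_A = 2, n_blocks_B = 1)
  net <- build_irdc_net(cfg, seed = 1)
  tab <- net$layers
  expect_equal(tab$out_channels[tab$op == "dense"], 10)
  expect_equal(sum(grepl("^blockA\\d+_merge$", tab$name)), 2)
  expect_equal(sum(grepl("^blockB\\d+_merge$", tab$name)), 1)

  deep <- model_config(n_classes = 52, input_channels = 10,
                       input_length = 1000, n_blocks_A = 6, n_blocks_B = 2)
  dt <- layer_table(deep)
  expect_equal(dt$out_channels[dt$op == "dense"], 52)
  expect_equal(sum(grepl("^blockA\\d+_merge$", dt$name)), 6)
  expect_equal(sum(grepl("^blockB\\d+_merge$", dt$name)), 2)
})

test_that("forward passes return valid probability simplices", {
  cfg <- do.call(model_config,
                 c(list(n_classes = 5, input_channels = 3,
                        input_length = 120), tiny_model_args()))
  net <- build_irdc_net(cfg, seed = 2)
  set.seed(2)
  x <- array(rnorm(3 * 120 * 3), dim = c(3, 120, 3))
  p <- predict(net, x)
  expect_equal(dim(p), c(3L, 5L))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  expect_true(all(p >= 0))
})

test_that("the closed-form parameter count matches the layer formula", {
  conv <- tibble::tibble(op = "conv", filters = 16, kernel = 3,
                         in_channels = 8)
  expect_equal(count_parameters(conv), 16 * (3 * 8 + 1))
  dense <- tibble::tibble(op = "dense", filters = 10, kernel = NA,
                          in_channels = 100)
  expect_equal(count_parameters(dense), 1010)
})

test_that("counts match the instantiated models and ignore dilation", {
  cfg <- model_config(n_classes = 10, input_channels = 7,
                      input_length = 2288)
  for (v in c("baseline", "residual_only", "dilation_only", "full")) {
    net <- build_variant(cfg, v, seed = 3)
    expect_identical(count_parameters(net), net$n_params)
  }
  full <- build_variant(cfg, "full", seed = 3)
  res <- build_variant(cfg, "residual_only", seed = 3)
  dil <- build_variant(cfg, "dilation_only", seed = 3)
  expect_identical(res$n_params, full$n_params)
  expect_lte(dil$n_params, full$n_params)

  alt <- cfg; alt$dilation_A <- 1; alt$dilation_B <- 1
  expect_identical(count_parameters(alt), count_parameters(cfg))
  alt2 <- cfg; alt2$dilation_A <- 9
  expect_identical(count_parameters(alt2), count_parameters(cfg))
})

test_that("ablation variants change structure as advertised", {
  cfg <- model_config(n_classes = 10, input_channels = 7,
                      input_length = 2288)
  base <- build_variant(cfg, "baseline", seed = 0)
  expect_false(any(base$layers$op == "add"))
  convs <- base$layers[base$layers$op == "conv", ]
  expect_true(all(convs$dilation == 1))

  full <- build_variant(cfg, "full", seed = 0)
  expect_true(any(full$layers$op == "add"))
  fc <- full$layers[full$layers$op == "conv", ]
  expect_setequal(unique(fc$dilation[grepl("branch[123]_conv", fc$name)]),
                  c(5, 3))
  expect_error(build_variant(cfg, "bogus"), "arg")
})

test_that("leaky ReLU is identity for positives and scaled for negatives", {
  x <- c(-2, -0.5, 0, 0.5, 2)
  expect_equal(leaky_relu(x, slope = 0.3),
               c(-0.6, -0.15, 0, 0.5, 2))
  set.seed(4)
  v <- rnorm(100)
  out <- leaky_relu(v, slope = 0.1)
  expect_equal(out[v >= 0], v[v >= 0])
  expect_equal(out[v < 0], 0.1 * v[v < 0])
})

test_that("analytic gradients match finite differences", {
  cfg <- model_config(n_classes = 3, input_channels = 2, input_length = 80,
                      n_blocks_A = 1, n_blocks_B = 1,
                      branch_kernels = c(2, 3, 5), filters_branch_A = 3,
                      filters_branch_B = 4, filters_reduce_B = 3,
                      stem_filters = 3, dropout_rate = 0)
  net <- build_irdc_net(cfg, seed = 3)
  set.seed(5)
  x <- array(rnorm(2 * 80 * 4), dim = c(2, 80, 4))
  y <- c(0L, 1L, 2L, 0L)
  lg <- emgsign:::nn_loss_grads(net$ptr, x, y)
  th <- emgsign:::nn_params_get(net$ptr)
  eps <- 1e-6
  probe <- sample(length(th), 30)
  for (i in probe) {
    tp <- th; tp[i] <- tp[i] + eps
    emgsign:::nn_params_set(net$ptr, tp)
    lp <- emgsign:::nn_loss_grads(net$ptr, x, y)$loss
    tp[i] <- th[i] - eps
    emgsign:::nn_params_set(net$ptr, tp)
    lm <- emgsign:::nn_loss_grads(net$ptr, x, y)$loss
    expect_equal(lg$grads[i], (lp - lm) / (2 * eps), tolerance = 1e-5)
  }
  emgsign:::nn_params_set(net$ptr, th)
})

test_that("too-short inputs are rejected with the minimum length", {
  expect_error(
    build_irdc_net(model_config(n_classes = 4, input_channels = 2,
                                input_length = 2)),
    "too short")
})
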