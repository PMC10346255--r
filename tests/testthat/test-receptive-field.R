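test_that("effective kernel length accounts for dilation gaps", {
  expect_equal(effective_kernel(rf_layer(3, dilation = 1)), 3)
  expect_equal(effective_kernel(rf_layer(3, dilation = 2)), 5)
  expect_equal(effective_kernel(rf_layer(24, dilation = 1)), 24)
  expect_equal(effective_kernel(rf_layer(8, dilation = 5)), 36)
})

test_that("stacked receptive fields compose as expected", {
  expect_equal(stack_rf(list(rf_layer(3), rf_layer(2))), 4)
  expect_equal(stack_rf(list(rf_layer(5, dilation = 3))),
               effective_kernel(rf_layer(5, dilation = 3)))
  expect_equal(stack_rf(list(rf_layer(3, stride = 2), rf_layer(3))), 7)
  expect_error(stack_rf(list()), "at least one")
})

test_that("index tracing agrees with the recursion on random stacks", {
  expect_equal(rf_dependency_oracle(list(rf_layer(3), rf_layer(2)), 16), 4)
  expect_equal(rf_dependency_oracle(list(rf_layer(6, dilation = 4)), 64),
               effective_kernel(rf_layer(6, dilation = 4)))
  set.seed(99)
  for (i in 1:100) {
    layers <- lapply(seq_len(sample(1:4, 1)), function(j) {
      rf_layer(sample(1:5, 1), sample(1:2, 1), sample(1:3, 1))
    })
    expect_equal(rf_dependency_oracle(layers, 512), stack_rf(layers))
  }
})

test_that("receptive field is monotone and reduces to the classic formula", {
  base <- list(rf_layer(3), rf_layer(3, stride = 2), rf_layer(5))
  rf0 <- stack_rf(base)
  expect_gte(stack_rf(c(base, list(rf_layer(3)))), rf0)      # depth
  bigger <- base; bigger[[3]] <- rf_layer(7)
  expect_gte(stack_rf(bigger), rf0)                          # kernel
  dilated <- base; dilated[[1]] <- rf_layer(3, dilation = 4)
  expect_gte(stack_rf(dilated), rf0)                         # dilation

  # dilation 1: RF = 1 + sum (k_i - 1) * prod_{j<i} s_j
  set.seed(7)
  for (i in 1:20) {
    ks <- sample(1:6, 3, replace = TRUE)
    ss <- sample(1:3, 3, replace = TRUE)
    layers <- Map(function(k, s) rf_layer(k, s), ks, ss)
    classic <- 1 + sum((ks - 1) * cumprod(c(1, ss[-3])))
    expect_equal(stack_rf(layers), classic)
  }
})

test_that("the model RF table reports both kernel and effective kernel", {
  cfg <- model_config(n_classes = 10, input_channels = 7,
                      input_length = 2288)
  tab <- rf_table(cfg)
  branch <- tab[tab$layer == "blockA1_branch_conv", ]
  expect_equal(branch$kernel, 24)
  expect_equal(branch$effective_kernel, 24 + 23 * 4)
  expect_true(all(diff(tab$receptive_field) >= 0))
  # disabling dilation collapses effective kernels back to kernels
  cfg$use_dilation <- FALSE
  tab1 <- rf_table(cfg)
  expect_equal(tab1$effective_kernel, tab1$kernel)
})
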