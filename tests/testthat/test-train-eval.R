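test_that("stratified splits follow the 70/30 + 30%-validation arithmetic", {
  labels <- rep(letters[1:10], each = 50)
  sp <- stratified_split(labels, split_spec(seed = 1))
  expect_equal(length(sp$test), 150)
  expect_equal(length(sp$val), 105)
  expect_equal(length(sp$train), 245)
  per_class_test <- table(labels[sp$test])
  expect_true(all(per_class_test == 15))
  per_class_val <- table(labels[sp$val])
  expect_true(all(per_class_val %in% c(10, 11)))
  # partition: disjoint and exhaustive
  all_idx <- sort(c(sp$train, sp$val, sp$test))
  expect_equal(all_idx, seq_along(labels))
})

test_that("splits are deterministic and proportion-preserving", {
  set.seed(2)
  labels <- sample(rep(1:5, times = c(30, 40, 50, 60, 21)))
  a <- stratified_split(labels, split_spec(seed = 9))
  b <- stratified_split(labels, split_spec(seed = 9))
  expect_identical(a, b)
  d <- stratified_split(labels, split_spec(seed = 10))
  expect_false(identical(a, d))

  orig <- table(labels) / length(labels)
  for (part in a) {
    frac <- table(factor(labels[part], levels = 1:5)) / length(part)
    expect_true(all(abs(frac - orig) <= 1 / length(part) + 1e-9))
  }
  expect_error(stratified_split(c(1, 1, 1, 2), split_spec()), "'2'")
})

test_that("evaluation metrics match their defining formulas", {
  y <- rep(1:10, each = 5)
  perfect <- eval_metrics(y, y)
  expect_equal(perfect$accuracy, 1)
  expect_true(all(perfect$per_class$f1 == 1))
  expect_equal(unname(diag(perfect$confusion)), rep(5L, 10))

  constant <- eval_metrics(y, rep(1, 50), levels = as.character(1:10))
  expect_equal(constant$accuracy, 0.1)
  expect_equal(constant$macro$recall, 0.1)

  # printed 2x2 contingency: confusion [[8,2],[4,6]]
  truth <- c(rep("a", 10), rep("b", 10))
  pred <- c(rep("a", 8), rep("b", 2), rep("a", 4), rep("b", 6))
  rep2 <- eval_metrics(truth, pred)
  expect_equal(unname(rep2$confusion), rbind(c(8L, 2L), c(4L, 6L)))
  expect_equal(rep2$per_class$precision[1], 8 / 12)
  expect_equal(rep2$per_class$recall[1], 0.8)
  expect_equal(rep2$per_class$f1[1], 0.727, tolerance = 1e-3)
})

test_that("evaluation is permutation-invariant and consistent across routes", {
  set.seed(3)
  truth <- sample(1:4, 200, replace = TRUE)
  pred <- ifelse(runif(200) < 0.7, truth, sample(1:4, 200, replace = TRUE))
  a <- eval_metrics(truth, pred)
  perm <- sample(200)
  b <- eval_metrics(truth[perm], pred[perm])
  expect_equal(a$per_class, b$per_class)
  expect_equal(a$accuracy, b$accuracy)

  # macro F1 recomputed from the confusion matrix alone
  cm <- a$confusion
  prec <- diag(cm) / pmax(colSums(cm), 1)
  rec <- diag(cm) / pmax(rowSums(cm), 1)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  expect_equal(a$macro$f1, mean(f1))
  expect_equal(a$accuracy, sum(diag(cm)) / sum(cm))
})

test_that("a zero learning rate leaves weights untouched with flat history", {
  cfg <- do.call(model_config,
                 c(list(n_classes = 3, input_channels = 2,
                        input_length = 60), tiny_model_args()))
  net <- build_irdc_net(cfg, seed = 5)
  before <- emgsign:::nn_params_get(net$ptr)
  set.seed(6)
  x <- array(rnorm(2 * 60 * 12), dim = c(2, 60, 12))
  y <- rep(1:3, 4)
  net <- fit_network(net, x, y, train_idx = 1:9, val_idx = 10:12,
                     epochs = 3, learning_rate = 0, seed = 7)
  expect_identical(emgsign:::nn_params_get(net$ptr), before)
  expect_equal(length(unique(net$history$val_loss)), 1)
})

test_that("a single-class task is learned trivially", {
  cfg <- do.call(model_config,
                 c(list(n_classes = 2, input_channels = 1,
                        input_length = 40), tiny_model_args()))
  net <- build_irdc_net(cfg, seed = 8)
  set.seed(9)
  x <- array(rnorm(40 * 10), dim = c(1, 40, 10))
  y <- rep("only", 10)
  net <- fit_network(net, x, y, train_idx = 1:7, val_idx = 8:10,
                     epochs = 40, learning_rate = 0.05, seed = 10)
  expect_equal(tail(net$history$val_acc, 1), 1)
})

test_that("overlapping splits and empty training sets are rejected", {
  cfg <- do.call(model_config,
                 c(list(n_classes = 2, input_channels = 1,
                        input_length = 40), tiny_model_args()))
  net <- build_irdc_net(cfg, seed = 11)
  x <- array(rnorm(40 * 4), dim = c(1, 40, 4))
  expect_error(fit_network(net, x, c(1, 1, 2, 2), 1:3, 3:4), "overlap")
  expect_error(fit_network(net, x, c(1, 1, 2, 2), integer(), 3:4), "Empty")
})

test_that("report tidiers expose per-class and summary views", {
  y <- rep(1:3, each = 4)
  r <- eval_metrics(y, y)
  expect_equal(nrow(tidy(r)), 3)
  g <- glance(r)
  expect_equal(g$accuracy, 1)
  expect_equal(g$n, 12)
  p <- autoplot(r)
  expect_s3_class(p, "ggplot")
})
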