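#' Configuration of the dilated residual Inception network
#'
#' Describes the parallel 1-D convolutional classifier: a STEM block
#' (conv/pool dimensionality reduction), `n_blocks_A` Inception-ResNet A
#' blocks and `n_blocks_B` Inception-ResNet B blocks, a dropout layer, a
#' flattening layer, and a dense softmax output. Each Inception block runs
#' three parallel dilated-convolution branches with kernel lengths
#' `branch_kernels` merged by element-wise summation, plus a residual
#' shortcut (Branch 4) added onto the merge: identity when channel counts
#' match, otherwise a length-1 projection convolution. B-block branches use
#' `filters_branch_B` filters followed by a length-3 convolution with
#' `filters_reduce_B` filters to reduce dimensionality. All activations are
#' Leaky ReLU.
#'
#' @param n_classes Number of gesture classes (softmax width).
#' @param input_channels Number of input channels (e.g. 7 sEMG channels).
#' @param input_length Samples/features per channel at the network input.
#' @param n_blocks_A,n_blocks_B Counts of A and B Inception-ResNet blocks
#'   (not both zero). Defaults 2 and 1.
#' @param branch_kernels Kernel lengths of the three parallel branches.
#' @param dilation_A,dilation_B Dilation rates used in A-block and B-block
#'   branches (defaults 5 and 3).
#' @param filters_branch_A Filters per A-block branch (also the block output
#'   width).
#' @param filters_branch_B,filters_reduce_B Filters of the B-block branch
#'   convolution and of its length-3 reduction convolution.
#' @param dropout_rate Probability of dropping a unit in the dropout layer
#'   (set `dropout_is_keep_prob = TRUE` to reinterpret it as a keep
#'   probability).
#' @param leaky_slope Negative-slope coefficient of the Leaky ReLU.
#' @param use_residual Include the Branch-4 residual shortcuts?
#' @param use_dilation Apply the branch dilation rates? When `FALSE` every
#'   dilation is forced to 1.
#' @param stem_filters,stem_kernel1,stem_stride1,stem_kernel2,stem_pool
#'   STEM block sizes: first conv (filters/kernel/stride), second conv
#'   kernel, and the size( = stride) of both max-pooling layers.
#' @param reduce_kernel Kernel length of the B-block reduction convolution.
#' @param dropout_is_keep_prob Interpret `dropout_rate` as keep probability?
#' @return An object of class `model_config`.
#' @examples
#' model_config(n_classes = 10, input_channels = 7, input_length = 2288)
#' @export
model_config <- function(n_classes, input_channels, input_length,
                         n_blocks_A = 2, n_blocks_B = 1,
                         branch_kernels = c(8, 12, 24),
                         dilation_A = 5, dilation_B = 3,
                         filters_branch_A = 16,
                         filters_branch_B = 64, filters_reduce_B = 16,
                         dropout_rate = 0.8, leaky_slope = 0.3,
                         use_residual = TRUE, use_dilation = TRUE,
                         stem_filters = 32, stem_kernel1 = 7,
                         stem_stride1 = 2, stem_kernel2 = 3, stem_pool = 2,
                         reduce_kernel = 3, dropout_is_keep_prob = FALSE) {
  stopifnot(n_classes >= 2, input_channels >= 1, input_length >= 1,
            n_blocks_A >= 0, n_blocks_B >= 0, n_blocks_A + n_blocks_B > 0,
            length(branch_kernels) == 3, all(branch_kernels >= 1),
            dilation_A >= 1, dilation_B >= 1,
            dropout_rate >= 0, dropout_rate < 1, leaky_slope >= 0)
  structure(as.list(environment()), class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf(
    "<model_config> %d classes, input %d x %d; %dxA + %dxB blocks, kernels %s,\n",
    x$n_classes, x$input_channels, x$input_length, x$n_blocks_A, x$n_blocks_B,
    paste(x$branch_kernels, collapse = "/")))
  cat(sprintf("  dilation %d/%d%s, residual %s, dropout %g, leaky slope %g\n",
              x$dilation_A, x$dilation_B,
              if (x$use_dilation) "" else " (disabled)",
              if (x$use_residual) "on" else "off",
              x$dropout_rate, x$leaky_slope))
  invisible(x)
}

conv_out_len <- function(len, stride) (len + stride - 1L) %/% stride  # 'same'
pool_out_len <- function(len, size, stride) (len - size) %/% stride + 1L

# Build the network as a node graph plus a layer table used for parameter
# audits. Node 1 is the input; `inputs` reference earlier node ids.
irdc_graph <- function(config) {
  cfg <- config
  dil_a <- if (cfg$use_dilation) cfg$dilation_A else 1L
  dil_b <- if (cfg$use_dilation) cfg$dilation_B else 1L
  nodes <- list(list(op = "input", name = "input",
                     out_channels = cfg$input_channels,
                     out_length = cfg$input_length, inputs = integer()))
  add_node <- function(node) {
    nodes[[length(nodes) + 1L]] <<- node
    length(nodes)
  }
  conv <- function(name, input, filters, kernel, stride = 1L, dilation = 1L) {
    src <- nodes[[input]]
    add_node(list(op = "conv", name = name, kernel = as.integer(kernel),
                  stride = as.integer(stride), dilation = as.integer(dilation),
                  filters = as.integer(filters),
                  in_channels = src$out_channels, out_channels = filters,
                  out_length = conv_out_len(src$out_length, stride),
                  inputs = input))
  }
  pool <- function(name, input, size, stride) {
    src <- nodes[[input]]
    if (src$out_length < size) {
      abort(sprintf(
        "input_length %d is too short for the STEM pooling chain (layer '%s' sees %d < pool %d); minimum input length is %d.",
        cfg$input_length, name, src$out_length, size,
        min_input_length(cfg)))
    }
    add_node(list(op = "pool", name = name, kernel = as.integer(size),
                  stride = as.integer(stride),
                  in_channels = src$out_channels,
                  out_channels = src$out_channels,
                  out_length = pool_out_len(src$out_length, size, stride),
                  inputs = input))
  }
  lrelu <- function(name, input) {
    src <- nodes[[input]]
    add_node(list(op = "lrelu", name = name, slope = cfg$leaky_slope,
                  in_channels = src$out_channels,
                  out_channels = src$out_channels,
                  out_length = src$out_length, inputs = input))
  }
  sum_node <- function(op, name, inputs) {
    src <- nodes[[inputs[1]]]
    add_node(list(op = op, name = name,
                  in_channels = src$out_channels,
                  out_channels = src$out_channels,
                  out_length = src$out_length, inputs = inputs))
  }

  x <- 1L
  x <- conv("stem_conv1", x, cfg$stem_filters, cfg$stem_kernel1,
            cfg$stem_stride1)
  x <- lrelu("stem_act1", x)
  x <- pool("stem_pool1", x, cfg$stem_pool, cfg$stem_pool)
  x <- conv("stem_conv2", x, cfg$stem_filters, cfg$stem_kernel2)
  x <- lrelu("stem_act2", x)
  x <- pool("stem_pool2", x, cfg$stem_pool, cfg$stem_pool)

  inception_block <- function(x, tag, filters, dilation, reduce = NULL) {
    branches <- integer(3)
    for (b in 1:3) {
      v <- conv(sprintf("%s_branch%d_conv", tag, b), x, filters,
                cfg$branch_kernels[b], dilation = dilation)
      v <- lrelu(sprintf("%s_branch%d_act", tag, b), v)
      if (!is.null(reduce)) {
        v <- conv(sprintf("%s_branch%d_reduce", tag, b), v, reduce$filters,
                  reduce$kernel)
        v <- lrelu(sprintf("%s_branch%d_reduce_act", tag, b), v)
      }
      branches[b] <- v
    }
    out <- sum_node("merge", sprintf("%s_merge", tag), branches)
    if (cfg$use_residual) {
      out_ch <- nodes[[out]]$out_channels
      shortcut <- if (nodes[[x]]$out_channels == out_ch) x else
        conv(sprintf("%s_branch4_proj", tag), x, out_ch, 1L)
      out <- sum_node("add", sprintf("%s_branch4_add", tag),
                      c(out, shortcut))
    }
    lrelu(sprintf("%s_act", tag), out)
  }

  for (i in seq_len(cfg$n_blocks_A)) {
    x <- inception_block(x, sprintf("blockA%d", i), cfg$filters_branch_A,
                         dil_a)
  }
  for (i in seq_len(cfg$n_blocks_B)) {
    x <- inception_block(x, sprintf("blockB%d", i), cfg$filters_branch_B,
                         dil_b,
                         reduce = list(filters = cfg$filters_reduce_B,
                                       kernel = cfg$reduce_kernel))
  }
  rate <- if (cfg$dropout_is_keep_prob) 1 - cfg$dropout_rate else
    cfg$dropout_rate
  src <- nodes[[x]]
  x <- add_node(list(op = "dropout", name = "dropout", rate = rate,
                     in_channels = src$out_channels,
                     out_channels = src$out_channels,
                     out_length = src$out_length, inputs = x))
  src <- nodes[[x]]
  n_flat <- src$out_channels * src$out_length
  x <- add_node(list(op = "flatten", name = "flatten",
                     in_channels = src$out_channels, out_channels = n_flat,
                     out_length = 1L, inputs = x))
  x <- add_node(list(op = "dense", name = "dense", units = cfg$n_classes,
                     in_channels = n_flat, out_channels = cfg$n_classes,
                     out_length = 1L, inputs = x))
  list(nodes = nodes, output = x)
}

# Smallest input length the STEM chain accepts (both pools need >= pool
# samples after the preceding stride).
min_input_length <- function(cfg) {
  lo <- 1L
  repeat {
    l1 <- conv_out_len(lo, cfg$stem_stride1)
    ok <- l1 >= cfg$stem_pool
    if (ok) {
      l2 <- pool_out_len(l1, cfg$stem_pool, cfg$stem_pool)
      ok <- l2 >= cfg$stem_pool
    }
    if (ok) return(lo)
    lo <- lo + 1L
  }
}

#' Tabulate the layers of a network
#'
#' One row per node of the network graph with geometry, shapes, and the
#' parameter count of every trainable layer computed from the closed form
#' `filters * (kernel * input_channels + 1)` for convolutions (bias
#' included; dilation does not appear, so dilated layers cost the same as
#' standard ones) and `units * (n_in + 1)` for the dense layer.
#'
#' @param x A `model_config` or a built `irdc_net`.
#' @return Tibble with columns `name`, `op`, `kernel`, `stride`, `dilation`,
#'   `filters`, `in_channels`, `out_channels`, `out_length`, `params`.
#' @export
layer_table <- function(x) {
  nodes <- if (inherits(x, "irdc_net")) x$graph$nodes
           else irdc_graph(x)$nodes
  dplyr::bind_rows(lapply(nodes, function(nd) {
    tibble(name = nd$name, op = nd$op,
           kernel = nd$kernel %||% NA_integer_,
           stride = nd$stride %||% NA_integer_,
           dilation = nd$dilation %||% NA_integer_,
           filters = nd$filters %||% nd$units %||% NA_integer_,
           in_channels = nd$in_channels %||% NA_integer_,
           out_channels = nd$out_channels %||% NA_integer_,
           out_length = nd$out_length %||% NA_integer_,
           params = switch(nd$op,
             conv = nd$filters * (nd$kernel * nd$in_channels + 1),
             dense = nd$units * (nd$in_channels + 1),
             0))
  }))
}

#' Count trainable parameters
#'
#' Sums the closed-form per-layer parameter counts of [layer_table()]. For a
#' built network this is checked by the test-suite against the instantiated
#' model's own parameter vector length.
#'
#' @param x A `model_config`, a built `irdc_net`, or a layer table tibble
#'   with `op`/`filters`/`kernel`/`in_channels` columns.
#' @return Integer total.
#' @export
count_parameters <- function(x) {
  tab <- if (is.data.frame(x)) x else layer_table(x)
  if (!"params" %in% names(tab)) {
    tab$params <- ifelse(tab$op == "conv",
                         tab$filters * (tab$kernel * tab$in_channels + 1),
                         ifelse(tab$op == "dense",
                                tab$filters * (tab$in_channels + 1), 0))
  }
  as.integer(sum(tab$params))
}

#' Build the full network
#'
#' Instantiates the configured network with seeded uniform fan-in weight
#' initialization, ready for [fit_network()] and [predict()].
#'
#' @param config A [model_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `irdc_net` with fields `config`, `graph`,
#'   `layers` (the [layer_table()]), `n_params`, and the native network
#'   handle.
#' @export
build_irdc_net <- function(config, seed = 0L) {
  stopifnot(inherits(config, "model_config"))
  graph <- irdc_graph(config)
  cpp_nodes <- lapply(graph$nodes, function(nd) {
    list(op = nd$op, kernel = nd$kernel %||% 0L, stride = nd$stride %||% 1L,
         dilation = nd$dilation %||% 1L,
         filters = nd$filters %||% nd$units %||% 0L,
         in_channels = nd$in_channels %||% 0L,
         slope = nd$slope %||% 0, rate = nd$rate %||% 0,
         inputs = as.integer(nd$inputs - 1L))
  })
  ptr <- nn_build(cpp_nodes, as.integer(seed))
  tab <- layer_table_from_graph(graph)
  structure(list(config = config, graph = graph, layers = tab,
                 n_params = as.integer(nn_nparams(ptr)),
                 seed = as.integer(seed), ptr = ptr,
                 scaler = NULL),
            class = "irdc_net")
}

layer_table_from_graph <- function(graph) {
  layer_table(structure(list(graph = graph), class = "irdc_net"))
}

#' @export
print.irdc_net <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<irdc_net> %dxA + %dxB blocks, input %d x %d -> %d classes, %s parameters\n",
    cfg$n_blocks_A, cfg$n_blocks_B, cfg$input_channels, cfg$input_length,
    cfg$n_classes, format(x$n_params, big.mark = ",")))
  invisible(x)
}

#' Build an ablation variant of the network
#'
#' The ablation grid removes the two receptive-field mechanisms one at a
#' time: `baseline` disables the residual shortcuts and forces every
#' dilation to 1 (plain Inception), `residual_only` keeps the shortcuts but
#' removes dilation, `dilation_only` the reverse, and `full` builds the
#' unmodified network.
#'
#' @param config A [model_config()].
#' @param variant One of `"baseline"`, `"residual_only"`, `"dilation_only"`,
#'   `"full"`.
#' @param seed Integer seed for weight initialization.
#' @return An `irdc_net`.
#' @export
build_variant <- function(config,
                          variant = c("baseline", "residual_only",
                                      "dilation_only", "full"),
                          seed = 0L) {
  variant <- match.arg(variant)
  config$use_residual <- variant %in% c("residual_only", "full")
  config$use_dilation <- variant %in% c("dilation_only", "full")
  net <- build_irdc_net(config, seed = seed)
  net$variant <- variant
  net
}

#' Leaky rectified linear unit
#'
#' `x` for `x >= 0`, `slope * x` for `x < 0`. The activation used throughout
#' the network; exposed for inspection and testing.
#'
#' @param x Numeric vector/array.
#' @param slope Negative-slope coefficient.
#' @return Same shape as `x`.
#' @export
leaky_relu <- function(x, slope = 0.3) {
  ifelse(x >= 0, x, slope * x)
}

#' Class-probability predictions
#'
#' Runs the forward pass (dropout disabled) and returns softmax
#' probabilities.
#'
#' @param object An `irdc_net`.
#' @param x Input array `n_channels x input_length x n_samples` (a single
#'   `n_channels x input_length` matrix is accepted).
#' @param ... Unused.
#' @return Matrix `n_samples x n_classes` of probabilities (rows sum to 1).
#' @export
predict.irdc_net <- function(object, x, ...) {
  x <- as_input_array(object, x)
  if (!is.null(object$scaler)) {
    x <- (x - object$scaler$center) / object$scaler$scale
  }
  p <- nn_predict(object$ptr, x)
  colnames(p) <- object$class_levels %||% paste0("class", seq_len(ncol(p)))
  p
}

as_input_array <- function(object, x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  stopifnot(length(dim(x)) == 3,
            dim(x)[1] == object$config$input_channels,
            dim(x)[2] == object$config$input_length)
  x
}
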