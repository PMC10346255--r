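#' A 1-D layer for receptive-field arithmetic
#'
#' Geometry of one convolution or pooling layer: kernel length, stride, and
#' dilation (pooling is geometrically a kernel = pool-size layer). Padding is
#' irrelevant to receptive-field size, which measures tap reach, not output
#' length.
#'
#' @param kernel Kernel (or pool) length, >= 1.
#' @param stride Stride, >= 1.
#' @param dilation Dilation rate, >= 1 (1 = standard convolution).
#' @return An object of class `rf_layer`.
#' @examples
#' rf_layer(3)            # standard 1x3 conv
#' rf_layer(3, dilation = 2)
#' @export
rf_layer <- function(kernel, stride = 1, dilation = 1) {
  stopifnot(kernel >= 1, stride >= 1, dilation >= 1)
  structure(list(kernel = as.integer(kernel), stride = as.integer(stride),
                 dilation = as.integer(dilation)),
            class = "rf_layer")
}

#' Effective kernel length of a dilated convolution
#'
#' A kernel of length `k` with dilation `d` spans
#' `k + (k - 1) * (d - 1)` input samples: the taps keep their count (and
#' hence their parameters) but are spaced `d` apart.
#'
#' @param layer An [rf_layer()].
#' @return Integer effective kernel length.
#' @export
effective_kernel <- function(layer) {
  stopifnot(inherits(layer, "rf_layer"))
  layer$kernel + (layer$kernel - 1L) * (layer$dilation - 1L)
}

#' Receptive field of a layer stack
#'
#' Composes the classic receptive-field recursion over an input-to-output
#' ordered list of layers: starting from `RF = 1`, `jump = 1`, each layer
#' updates `RF <- RF + (k_eff - 1) * jump` and `jump <- jump * stride`,
#' where `k_eff` is [effective_kernel()]. The result is the number of input
#' samples that influence one element of the final feature map.
#'
#' @param layers List of [rf_layer()] objects, input-to-output order.
#' @return Integer receptive-field size in input samples.
#' @examples
#' # two stacked convs, kernels 3 then 2: each output taps 4 input samples
#' stack_rf(list(rf_layer(3), rf_layer(2)))
#' @export
stack_rf <- function(layers) {
  if (length(layers) == 0L) abort("Need at least one layer.")
  rf <- 1L; jump <- 1L
  for (ly in layers) {
    stopifnot(inherits(ly, "rf_layer"))
    rf <- rf + (effective_kernel(ly) - 1L) * jump
    jump <- jump * ly$stride
  }
  rf
}

#' Receptive field by explicit index tracing
#'
#' Independent oracle for [stack_rf()]: builds the exact set of input indices
#' that one central output element depends on, by composing per-layer tap
#' positions (`input index = position * stride + tap * dilation`) from the
#' output backwards, and returns the span `max - min + 1`.
#'
#' @param layers List of [rf_layer()] objects, input-to-output order.
#' @param input_len Input length in samples; must be long enough that the
#'   central output element's support fits inside.
#' @return Integer span of reached input indices.
#' @export
rf_dependency_oracle <- function(layers, input_len) {
  if (length(layers) == 0L) abort("Need at least one layer.")
  out_len <- input_len
  for (ly in layers) {
    stopifnot(inherits(ly, "rf_layer"))
    out_len <- (out_len - effective_kernel(ly)) %/% ly$stride + 1L
    if (out_len < 1L) {
      abort(sprintf(
        "Input of %d samples too short for this stack; provide a longer input.",
        input_len))
    }
  }
  idx <- as.integer(out_len %/% 2)   # a central output element (0-based)
  for (ly in rev(layers)) {
    idx <- unique(as.vector(outer(idx * ly$stride,
                                  (seq_len(ly$kernel) - 1L) * ly$dilation,
                                  `+`)))
  }
  if (min(idx) < 0L || max(idx) >= input_len) {
    abort("Support clipped by the input boundary; provide a longer input.")
  }
  max(idx) - min(idx) + 1L
}

#' Per-layer receptive-field table for a model configuration
#'
#' Walks the convolution/pooling chain of the network a [model_config()]
#' describes (along its longest branch path, using the largest branch kernel)
#' and reports, per layer, kernel, stride, dilation, effective kernel, and
#' cumulative receptive field in input samples. Branch convolutions are also
#' listed with their within-branch effective kernels, which differ from the
#' plain kernel sizes whenever dilation exceeds 1.
#'
#' @param config A [model_config()].
#' @return Tibble with one row per layer.
#' @export
rf_table <- function(config) {
  stopifnot(inherits(config, "model_config"))
  rows <- list()
  add <- function(name, kernel, stride, dilation) {
    rows[[length(rows) + 1L]] <<- list(layer = name, kernel = kernel,
                                       stride = stride, dilation = dilation)
  }
  add("stem_conv1", config$stem_kernel1, config$stem_stride1, 1L)
  add("stem_pool1", config$stem_pool, config$stem_pool, 1L)
  add("stem_conv2", config$stem_kernel2, 1L, 1L)
  add("stem_pool2", config$stem_pool, config$stem_pool, 1L)
  kmax <- max(config$branch_kernels)
  dil_a <- if (config$use_dilation) config$dilation_A else 1L
  dil_b <- if (config$use_dilation) config$dilation_B else 1L
  for (i in seq_len(config$n_blocks_A)) {
    add(sprintf("blockA%d_branch_conv", i), kmax, 1L, dil_a)
  }
  for (i in seq_len(config$n_blocks_B)) {
    add(sprintf("blockB%d_branch_conv", i), kmax, 1L, dil_b)
    add(sprintf("blockB%d_reduce_conv", i), 3L, 1L, 1L)
  }
  df <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  layers <- purrr::pmap(df[, c("kernel", "stride", "dilation")],
                        function(kernel, stride, dilation)
                          rf_layer(kernel, stride, dilation))
  df$effective_kernel <- vapply(layers, effective_kernel, integer(1))
  df$receptive_field <- vapply(seq_along(layers), function(i)
    stack_rf(layers[seq_len(i)]), integer(1))
  df
}
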