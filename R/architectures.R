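# Reference teacher/student architectures.
#
# The teacher family is residual-style (plain 3x3 conv stacks with identity
# skips); the student family is depthwise-separable inverted-bottleneck
# style (pointwise expand -> depthwise -> pointwise project, skip when the
# shapes allow). Desk-scale variants share the hidden dimension D so the
# hidden-vector transfer loss applies without an adapter.

ir_block <- function(in_ch, out_ch, expand, stride, prunable = TRUE) {
  # returns list(layers = list of layer_spec, skip, prune offsets)
  list(
    layers = list(
      layer_spec("pointwise_conv", expand, activation = "relu"),
      layer_spec("depthwise_conv", expand, kernel = 3, stride = stride,
                 activation = "relu"),
      layer_spec("pointwise_conv", out_ch, activation = "linear")
    ),
    skip = (stride == 1 && in_ch == out_ch),
    prunable = prunable, prune_offset = 1L, coupled_offset = 2L
  )
}

assemble_spec <- function(stem, body, hidden_dim, n_classes, input_size,
                          hidden_activation = "linear",
                          stem_prunable = FALSE) {
  layers <- list(stem)
  blocks <- list(list(layers = 1L, skip = FALSE, prunable = stem_prunable,
                      prune_layer = if (stem_prunable) 1L else NA_integer_,
                      coupled = integer(0)))
  nxt <- 2L
  for (bl in body) {
    idx <- seq.int(nxt, length.out = length(bl$layers))
    layers <- c(layers, bl$layers)
    blocks[[length(blocks) + 1L]] <- list(
      layers = idx, skip = bl$skip, prunable = isTRUE(bl$prunable),
      prune_layer = if (isTRUE(bl$prunable)) idx[bl$prune_offset] else NA_integer_,
      coupled = if (isTRUE(bl$prunable) && !is.null(bl$coupled_offset))
        idx[bl$coupled_offset] else integer(0))
    nxt <- nxt + length(bl$layers)
  }
  last_ch <- layers[[length(layers)]]$out_filters
  layers <- c(layers, list(
    layer_spec("fully_connected", hidden_dim, activation = hidden_activation),
    layer_spec("fully_connected", n_classes, activation = "linear")
  ))
  network_spec(layers, blocks, hidden_dim = hidden_dim, n_classes = n_classes,
               input_size = input_size)
}

res_block <- function(ch) {
  list(layers = list(
    layer_spec("conv", ch, kernel = 3, stride = 1, activation = "relu"),
    layer_spec("conv", ch, kernel = 3, stride = 1, activation = "linear")
  ), skip = TRUE, prunable = FALSE)
}

plain_block <- function(ch, kernel = 3, stride = 1, prunable = FALSE) {
  list(layers = list(layer_spec("conv", ch, kernel = kernel, stride = stride,
                                activation = "relu")),
       skip = FALSE, prunable = prunable, prune_offset = 1L,
       coupled_offset = NULL)
}

#' Desk-scale reference architectures
#'
#' `spec_desk_teacher()` is a residual-style network (identity-skip conv
#' pairs); `spec_desk_student()` is an inverted-bottleneck depthwise
#' separable network with `T = 3` prunable blocks (the expansion filters of
#' each bottleneck are cut, with the coupled depthwise channels; the
#' projection layers feed skip connections and are never cut). Both share
#' the hidden dimension so the transfer loss needs no adapter.
#'
#' `spec_tiny_teacher()`/`spec_tiny_student()` are still smaller variants
#' (input side 24, D = 24) for fast experiments; the student has T = 2.
#'
#' @param n_classes number of categories.
#' @param hidden_dim hidden vector dimension D.
#' @param input_size square input side the model is intended for.
#' @return a [network_spec()].
#' @export
spec_desk_student <- function(n_classes = 10, hidden_dim = 32, input_size = 32) {
  assemble_spec(
    layer_spec("conv", 8, kernel = 3, stride = 2),
    list(ir_block(8, 16, expand = 16, stride = 2),
         ir_block(16, 16, expand = 32, stride = 1),
         ir_block(16, 24, expand = 32, stride = 2)),
    hidden_dim, n_classes, input_size)
}

#' @rdname spec_desk_student
#' @export
spec_desk_teacher <- function(n_classes = 10, hidden_dim = 32, input_size = 32) {
  assemble_spec(
    layer_spec("conv", 16, kernel = 3, stride = 2),
    list(res_block(16),
         plain_block(32, stride = 2),
         res_block(32),
         plain_block(48, stride = 2)),
    hidden_dim, n_classes, input_size)
}

#' @rdname spec_desk_student
#' @export
spec_tiny_student <- function(n_classes = 10, hidden_dim = 24, input_size = 24) {
  assemble_spec(
    layer_spec("conv", 8, kernel = 3, stride = 2),
    list(ir_block(8, 12, expand = 16, stride = 2),
         ir_block(12, 12, expand = 16, stride = 1)),
    hidden_dim, n_classes, input_size)
}

#' @rdname spec_desk_student
#' @export
spec_tiny_teacher <- function(n_classes = 10, hidden_dim = 24, input_size = 24) {
  assemble_spec(
    layer_spec("conv", 12, kernel = 3, stride = 2),
    list(res_block(12),
         plain_block(24, stride = 2)),
    hidden_dim, n_classes, input_size)
}

#' Full-scale reference architectures
#'
#' `spec_student_full()` is an inverted-bottleneck separable network in the
#' mobile-classifier style with 17 prunable bottleneck blocks (T = 17) and
#' hidden dimension 1280. `spec_teacher_full()` is a residual bottleneck
#' network in the 50-layer style with hidden dimension 2048. These document
#' the full-scale shapes; desk work uses the desk variants.
#'
#' @inheritParams spec_desk_student
#' @return a [network_spec()].
#' @export
spec_student_full <- function(n_classes = 95, hidden_dim = 1280,
                              input_size = 224) {
  cfg <- list( # out_ch, expand_factor, stride, repeats
    c(16, 1, 1, 1), c(24, 6, 2, 2), c(32, 6, 2, 3), c(64, 6, 2, 4),
    c(96, 6, 1, 3), c(160, 6, 2, 3), c(320, 6, 1, 1))
  body <- list()
  in_ch <- 32
  for (st in cfg) {
    for (r in seq_len(st[4])) {
      stride <- if (r == 1) st[3] else 1
      body[[length(body) + 1L]] <-
        ir_block(in_ch, st[1], expand = max(in_ch * st[2], st[1]),
                 stride = stride)
      in_ch <- st[1]
    }
  }
  assemble_spec(layer_spec("conv", 32, kernel = 3, stride = 2), body,
                hidden_dim, n_classes, input_size)
}

bottleneck_block <- function(in_ch, mid, out_ch, stride) {
  list(layers = list(
    layer_spec("pointwise_conv", mid, activation = "relu"),
    layer_spec("conv", mid, kernel = 3, stride = stride, activation = "relu"),
    layer_spec("pointwise_conv", out_ch, activation = "linear")
  ), skip = (stride == 1 && in_ch == out_ch), prunable = FALSE)
}

#' @rdname spec_student_full
#' @export
spec_teacher_full <- function(n_classes = 95, hidden_dim = 2048,
                              input_size = 224) {
  stages <- list(c(64, 256, 3, 1), c(128, 512, 4, 2),
                 c(256, 1024, 6, 2), c(512, 2048, 3, 2))
  body <- list()
  in_ch <- 64
  for (st in stages) {
    for (r in seq_len(st[3])) {
      stride <- if (r == 1) st[4] else 1
      body[[length(body) + 1L]] <- bottleneck_block(in_ch, st[1], st[2], stride)
      in_ch <- st[2]
    }
  }
  # stride-2 stem stands in for the 7x7 conv + pooling stem
  assemble_spec(layer_spec("conv", 64, kernel = 5, stride = 4), body,
                hidden_dim, n_classes, input_size)
}
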