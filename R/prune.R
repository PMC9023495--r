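#' Cut (pruning) configuration
#'
#' @param alpha cut ratio in [0, 1): `ceiling(C_t * alpha)` filters are
#'   removed from a layer with `C_t` filters and `C_t - ceiling(C_t*alpha)`
#'   reserved. `alpha = 0` is a documented no-op (nothing cut, no retrain).
#' @param subset_size number M of images scored per layer (drawn once per
#'   compression run, reused across layers); defaults to `min(256, N)`.
#' @param subset_seed seed of the subset draw.
#' @param retrain a [transfer_config()] for the after-cut retraining; the
#'   published ladder is 0.001 for 5000 iterations then 0.0001 for 2000,
#'   the default here is that ladder shrunk 10x.
#' @return an object of class `cut_config`.
#' @export
cut_config <- function(alpha = 0.5, subset_size = NULL, subset_seed = 1,
                       retrain = transfer_config(
                         train = train_config(
                           lr_schedule = list(c(0.001, 500), c(0.0001, 200))))) {
  cn_assert(is.numeric(alpha) && length(alpha) == 1 && alpha >= 0 && alpha < 1,
            "config", "alpha must lie in [0, 1)")
  cn_assert(is.null(subset_size) || is_count(subset_size), "config",
            "subset_size must be a positive integer")
  cn_assert(inherits(retrain, "transfer_config"), "config",
            "retrain must be a transfer_config")
  structure(list(alpha = alpha, subset_size = subset_size,
                 subset_seed = as.integer(subset_seed), retrain = retrain,
                 layer_order = "top_down"),
            class = "cut_config")
}

#' Construct a filter score table
#'
#' @param layer prunable block index the scores belong to.
#' @param scores non-negative numeric vector, one entry per current filter;
#'   names default to the filter indices.
#' @return an object of class `filter_score_table`.
#' @export
filter_score_table <- function(layer, scores) {
  cn_assert(length(scores) > 0 && all(scores >= 0), "input",
            "scores must be a non-empty non-negative vector")
  if (is.null(names(scores))) names(scores) <- seq_along(scores)
  structure(list(layer = as.integer(layer), scores = scores),
            class = "filter_score_table")
}

prunable_block_indices <- function(spec)
  which(vapply(spec$blocks, `[[`, logical(1), "prunable"))

# The removal chain of a prunable block: the cut layer, any coupled
# depthwise layers, and the consumer whose input slices are removed with
# them. The consumer's pre-normalization output is the reference map
# (the nearest feature map whose size a cut leaves unchanged); for the
# deepest prunable layer this is the pre-activation hidden vector.
removal_chain <- function(spec, block) {
  cn_assert(is_count(block) && block <= length(spec$blocks), "input",
            "no such block: %s", format(block))
  b <- spec$blocks[[block]]
  cn_assert(b$prunable, "input", "block %d is not prunable", block)
  chain_end <- max(c(b$prune_layer, b$coupled))
  L <- length(spec$layers)
  consumer <- chain_end + 1L
  cn_assert(consumer <= L - 1L, "spec", "no reference layer after block %d", block)
  list(prune_layer = b$prune_layer, coupled = b$coupled,
       consumer = consumer,
       consumer_is_fc = spec$layers[[consumer]]$kind == "fully_connected")
}

#' Score filters by next-layer reconstruction error
#'
#' For each filter i of the block's cut layer, computes the mean squared
#' change in the reference map (the next layer's pre-normalization output;
#' the pre-activation hidden vector when the next layer is the hidden
#' fully connected layer) when the filter -- and its normalization
#' parameters, coupled depthwise channel and matching input slice of the
#' next layer -- is removed, averaged over M subset images. The model runs
#' in evaluation mode on deterministically preprocessed inputs, so scores
#' are reproducible.
#'
#' @param model a `model_state`.
#' @param block prunable block index t.
#' @param inputs preprocessed image tensor of dim (3, S, S, M), e.g. built
#'   with [test_transform()].
#' @return a [filter_score_table()].
#' @export
score_filters <- function(model, block, inputs) {
  d <- dim(inputs)
  cn_assert(length(d) == 4 && d[4] >= 1, "config",
            "inputs must be a (3,S,S,M) tensor with M >= 1")
  rc <- removal_chain(model$spec, block)
  M <- d[4]
  fp <- forward_pass(model, inputs, mode = "eval", keep_cache = TRUE)

  if (rc$consumer_is_fc) {
    # the consumer is the hidden FC: its input is the pooled final feature
    # map; rebuild that map (including a trailing skip add) from the caches
    last_block <- model$spec$blocks[[length(model$spec$blocks)]]
    cons_in <- fp$caches[[last_block$layers[length(last_block$layers)]]]$out
    if (last_block$skip)
      cons_in <- cons_in + fp$caches[[last_block$layers[1]]]$x
    hp <- model$params[[rc$consumer]]
    ref_full <- hp$W %*% gap_fwd(cons_in) + hp$b
    C_t <- dim(cons_in)[1]
    scores <- numeric(C_t)
    for (i in seq_len(C_t)) {
      masked <- cons_in
      masked[i, , , ] <- 0
      ref_i <- hp$W %*% gap_fwd(masked) + hp$b
      scores[i] <- sum((ref_i - ref_full)^2) / M
    }
  } else {
    cons_ls <- model$spec$layers[[rc$consumer]]
    cons_p <- model$params[[rc$consumer]]
    cons_in <- fp$caches[[rc$consumer]]$x
    ref_full <- fp$caches[[rc$consumer]]$z
    C_t <- dim(cons_in)[1]
    scores <- numeric(C_t)
    for (i in seq_len(C_t)) {
      masked <- cons_in
      masked[i, , , ] <- 0
      ref_i <- if (cons_ls$kind == "depthwise_conv")
        cpp_dwconv_fwd(masked, cons_p$W, cons_p$b %||% numeric(0), cons_ls$stride)
      else
        cpp_conv_fwd(masked, cons_p$W, cons_p$b %||% numeric(0), cons_ls$stride)
      scores[i] <- sum((ref_i - ref_full)^2) / M
    }
  }
  filter_score_table(block, scores)
}

#' Select the filters to remove
#'
#' Removes the `ceiling(C_t * alpha)` lowest-scoring filters; ties are
#' broken by ascending filter index. Selection is a pure function of the
#' scores and the ratio: the storage order of the table does not matter.
#'
#' @param scores a [filter_score_table()] (or bare numeric vector).
#' @param alpha cut ratio in [0, 1).
#' @return sorted integer vector of removal indices (possibly empty).
#' @export
select_filters <- function(scores, alpha) {
  s <- if (inherits(scores, "filter_score_table")) scores$scores else scores
  cn_assert(length(s) > 0, "input", "empty score table")
  ids <- as.integer(names(s) %||% seq_along(s))
  C_t <- length(s)
  n_cut <- as.integer(ceiling(C_t * alpha))
  if (n_cut == 0) return(integer(0))
  if (C_t - n_cut < 1)
    cn_stop("config", "removing %d of %d filters would leave none", n_cut, C_t)
  ord <- order(s, ids)
  sort(ids[ord[seq_len(n_cut)]])
}

# Update the architecture description after removing n filters from a
# block's cut layer (and its coupled depthwise layers); revalidates the
# whole chain.
cut_spec <- function(spec, block, n_removed) {
  if (n_removed == 0) return(spec)
  rc <- removal_chain(spec, block)
  layers <- spec$layers
  for (li in c(rc$prune_layer, rc$coupled))
    layers[[li]]$out_filters <- layers[[li]]$out_filters - as.integer(n_removed)
  network_spec(layers, spec$blocks, hidden_dim = spec$hidden_dim,
               n_classes = spec$n_classes, input_size = spec$input_size,
               in_channels = spec$in_channels)
}

#' Structurally remove filters from a layer
#'
#' Slices the cut layer's filter bank and normalization parameters, any
#' coupled depthwise channel (and its normalization), and the matching
#' input slices of the consumer layer; appends the cut to the model's
#' `cut_history`. Removing the empty set returns the model unchanged.
#'
#' @param model a `model_state`.
#' @param block prunable block index t.
#' @param idx integer indices of the filters to remove (1-based, relative
#'   to the layer's current filters).
#' @return the pruned `model_state`.
#' @export
remove_filters <- function(model, block, idx) {
  if (length(idx) == 0) return(model)
  rc <- removal_chain(model$spec, block)
  C_t <- model$spec$layers[[rc$prune_layer]]$out_filters
  idx <- as.integer(idx)
  cn_assert(all(idx >= 1 & idx <= C_t) && !anyDuplicated(idx), "input",
            "removal indices out of range for %d filters", C_t)
  cn_assert(length(idx) < C_t, "config", "cannot remove every filter")
  keep <- setdiff(seq_len(C_t), idx)

  slice_out <- function(p, keep) {
    nd <- length(dim(p$W) %||% 1)
    p$W <- if (nd == 4) p$W[keep, , , , drop = FALSE]
    else if (nd == 3) p$W[keep, , , drop = FALSE]
    else p$W[keep, , drop = FALSE]
    for (nm in c("b", "gamma", "beta", "running_mean", "running_var"))
      if (!is.null(p[[nm]])) p[[nm]] <- p[[nm]][keep]
    p
  }
  for (li in c(rc$prune_layer, rc$coupled))
    model$params[[li]] <- slice_out(model$params[[li]], keep)

  cp <- model$params[[rc$consumer]]
  if (rc$consumer_is_fc) {
    cp$W <- cp$W[, keep, drop = FALSE]
  } else if (model$spec$layers[[rc$consumer]]$kind == "depthwise_conv") {
    cn_stop("spec", "consumer of block %d is depthwise; it must be coupled, not sliced", block)
  } else {
    cp$W <- cp$W[, keep, , , drop = FALSE]
  }
  model$params[[rc$consumer]] <- cp

  model$spec <- cut_spec(model$spec, block, length(idx))
  model$cut_history[[length(model$cut_history) + 1L]] <-
    list(block = as.integer(block), removed = idx)
  validate_model_shapes(model)
  model
}

#' Retrain after cutting one layer
#'
#' Optimizes the same combined objective as [transfer_train()] (cross
#' entropy plus the hidden-vector penalty against the frozen teacher)
#' under the cut configuration's retrain schedule. A zero-iteration
#' schedule returns the cut model unchanged.
#'
#' @param model the freshly cut `model_state`.
#' @param teacher the frozen teacher.
#' @param data full training `labeled_dataset`.
#' @param aug an [aug_config()].
#' @param cfg a [cut_config()].
#' @param eval_data optional held-out data.
#' @return the retrained `model_state`.
#' @export
retrain_layer <- function(model, teacher, data, aug, cfg, eval_data = NULL) {
  cn_assert(inherits(cfg, "cut_config"), "config", "cfg must be a cut_config")
  transfer_train(model, teacher, data, aug, cfg$retrain, eval_data = eval_data)
}

#' Top-down layer-wise compression
#'
#' For every prunable block, from the deepest (t = T) down to the first
#' (t = 1): score the block's filters on the fixed image subset, select the
#' `ceiling(C_t * alpha)` lowest-scoring ones, remove them structurally,
#' and retrain with the transfer-regularized objective. Each stage starts
#' from the previous stage's output; scores are recomputed at every stage
#' because they depend on the current parameters. The same subset (drawn
#' once with `subset_seed`) is reused across layers for comparability.
#'
#' @param student the transfer-trained `model_state` (W_S^K).
#' @param teacher the frozen teacher.
#' @param data training `labeled_dataset`.
#' @param aug an [aug_config()].
#' @param cfg a [cut_config()].
#' @param eval_data optional held-out `labeled_dataset`; when supplied the
#'   report records the held-out macro top-1 after every stage.
#' @return list with `model` (W_S^1) and `report` (class
#'   `compression_report`): per-layer scores, removed indices, parameter
#'   counts and the held-out accuracy trace.
#' @export
compress <- function(student, teacher, data, aug, cfg = cut_config(),
                     eval_data = NULL) {
  cn_assert(inherits(cfg, "cut_config"), "config", "cfg must be a cut_config")
  n <- length(data$images)
  M <- min(cfg$subset_size %||% 256L, n)
  sub_idx <- with_seed(cfg$subset_seed, sample.int(n, M))
  inputs <- assemble_batch(lapply(data$images[sub_idx],
                                  function(im) test_transform(im, aug)))

  eval_top1 <- function(m) {
    if (is.null(eval_data)) return(NA_real_)
    topk_macro_accuracy(predict_logits(m, eval_data$images, aug),
                        eval_data$labels, 1)
  }

  model <- student
  stages <- list()
  acc0 <- eval_top1(model)
  order_t <- rev(prunable_block_indices(model$spec))
  for (t in order_t) {
    C_t <- model$spec$layers[[model$spec$blocks[[t]]$prune_layer]]$out_filters
    n_cut <- as.integer(ceiling(C_t * cfg$alpha))
    if (n_cut == 0) {
      stages[[length(stages) + 1L]] <- list(
        block = t, scores = NULL, removed = integer(0),
        reserved = C_t, params_after = parameter_count(model),
        test_top1 = acc0)
      next
    }
    st <- score_filters(model, t, inputs)
    rem <- select_filters(st, cfg$alpha)
    model <- remove_filters(model, t, rem)
    acc_cut <- eval_top1(model)
    rcfg <- cfg$retrain
    rcfg$train$seed <- derive_seed(rcfg$train$seed, t)
    model <- retrain_layer(model, teacher, data, aug,
                           cut_config(alpha = cfg$alpha,
                                      subset_seed = cfg$subset_seed,
                                      retrain = rcfg))
    stages[[length(stages) + 1L]] <- list(
      block = t, scores = st$scores, removed = rem,
      reserved = C_t - length(rem),
      params_after = parameter_count(model),
      test_top1_after_cut = acc_cut,
      test_top1 = eval_top1(model))
  }
  report <- structure(list(
    alpha = cfg$alpha, subset_size = M, subset_idx = sub_idx,
    initial_params = parameter_count(student),
    initial_test_top1 = acc0, stages = stages,
    final_params = parameter_count(model)), class = "compression_report")
  list(model = model, report = report)
}

#' @export
print.compression_report <- function(x, ...) {
  cat(sprintf("<compression_report> alpha=%.2f, %d stages, params %d -> %d\n",
              x$alpha, length(x$stages), x$initial_params, x$final_params))
  for (s in x$stages)
    cat(sprintf("  block %d: removed %d, reserved %d, held-out top1 %s\n",
                s$block, length(s$removed), s$reserved,
                ifelse(is.na(s$test_top1), "-", sprintf("%.1f", s$test_top1))))
  invisible(x)
}
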