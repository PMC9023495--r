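#' Training configuration
#'
#' Stochastic gradient descent with momentum and weight decay under a staged
#' step-decay learning-rate ladder. "Iterations" are optimizer steps (not
#' epochs); the data are cycled with reshuffling each pass.
#'
#' @param lr_schedule a list of `c(rate, iterations)` pairs (or a 2-column
#'   matrix/data.frame); rates must be strictly decreasing, iteration counts
#'   non-negative (a 0-iteration stage is a no-op).
#' @param batch mini-batch size B.
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty coefficient, applied to convolution and
#'   fully connected weights only (never to normalization parameters or
#'   biases).
#' @param seed integer seed for batch shuffling and augmentation draws.
#' @param eval_every if an evaluation set is supplied to the training call,
#'   held-out accuracy is recorded every this many iterations.
#' @return an object of class `train_config`.
#' @export
train_config <- function(lr_schedule = list(c(0.01, 1000), c(0.001, 1000),
                                            c(0.0001, 1000)),
                         batch = 32, momentum = 0.9, weight_decay = 5e-4,
                         seed = 1, eval_every = 200) {
  if (is.data.frame(lr_schedule) || is.matrix(lr_schedule))
    lr_schedule <- lapply(seq_len(nrow(lr_schedule)),
                          function(i) as.numeric(lr_schedule[i, ]))
  rates <- vapply(lr_schedule, `[`, numeric(1), 1)
  iters <- vapply(lr_schedule, `[`, numeric(1), 2)
  cn_assert(all(rates > 0) && all(diff(rates) < 0), "config",
            "learning rates must be positive and strictly decreasing")
  cn_assert(all(iters >= 0) && all(iters == floor(iters)), "config",
            "iteration counts must be non-negative integers")
  cn_assert(is_count(batch), "config", "batch must be a positive integer")
  structure(list(lr_schedule = Map(c, rates, iters), batch = as.integer(batch),
                 momentum = momentum, weight_decay = weight_decay,
                 seed = as.integer(seed), eval_every = as.integer(eval_every)),
            class = "train_config")
}

#' Named training presets
#'
#' `"published-herb-large"` / `"published-herb-small"` are the published
#' fine-tuning ladders for the large and small network (0.01 to 0.0001,
#' stepped by 10 every 5000 / 10000 iterations); `"published-pretrain"` is
#' the source-task ladder (0.1 to 0.0001); `"desk"` shrinks the
#' small-network ladder 10x for desk-scale synthetic tasks.
#'
#' @param name preset name.
#' @param seed seed stored in the returned config.
#' @return a [train_config()].
#' @export
train_preset <- function(name = c("desk", "published-herb-small",
                                  "published-herb-large",
                                  "published-pretrain"),
                         seed = 1) {
  name <- match.arg(name)
  sched <- switch(name,
    "published-herb-large" = list(c(0.01, 5000), c(0.001, 5000),
                                  c(0.0001, 5000)),
    "published-herb-small" = list(c(0.01, 10000), c(0.001, 10000),
                                  c(0.0001, 10000)),
    "published-pretrain" = list(c(0.1, 30), c(0.01, 30), c(0.001, 30),
                                c(0.0001, 30)),  # epochs at full scale
    "desk" = list(c(0.01, 1000), c(0.001, 1000), c(0.0001, 1000)))
  train_config(lr_schedule = sched, seed = seed)
}

#' Optimizer parameter groups
#'
#' Lists every trainable tensor with its weight-decay treatment: decay
#' applies to convolution/fully-connected weights only, never to biases or
#' normalization scale/shift.
#'
#' @param model a `model_state`.
#' @return data.frame with columns layer, tensor, n, decay.
#' @export
optimizer_param_groups <- function(model) {
  rows <- list()
  for (i in seq_along(model$params)) {
    for (nm in names(model$params[[i]])) {
      if (nm %in% c("running_mean", "running_var")) next
      rows[[length(rows) + 1L]] <- data.frame(
        layer = i, tensor = nm, n = length(model$params[[i]][[nm]]),
        decay = nm == "W")
    }
  }
  do.call(rbind, rows)
}

expand_schedule <- function(sched)
  unlist(lapply(sched, function(s) rep(s[1], s[2])))

# Shared SGD loop for plain cross-entropy training, transfer training and
# after-cut retraining. The teacher (if any) is run in evaluation mode on
# the SAME augmented batch as the student and is never modified. With
# lambda = 0 and identical seeds/schedules this reproduces plain training
# exactly: the teacher forward consumes no randomness.
run_training <- function(model, data, aug, cfg, teacher = NULL, lambda = 0,
                         eval_data = NULL) {
  cn_assert(inherits(cfg, "train_config"), "config", "cfg must be a train_config")
  cn_assert(inherits(data, "labeled_dataset"), "input", "data must be a labeled_dataset")
  C <- model$spec$n_classes
  cn_assert(length(data$class_names) == C, "spec",
            "model has %d classes but dataset declares %d",
            C, length(data$class_names))
  adapter <- model$adapter
  if (!is.null(teacher) && lambda > 0) {
    dS <- model$spec$hidden_dim; dT <- teacher$spec$hidden_dim
    if (dS != dT && is.null(adapter))
      cn_stop("spec", paste0("teacher hidden dim %d != student hidden dim %d",
                             " (enable the adapter to bridge them)"), dT, dS)
  }

  lrs <- expand_schedule(cfg$lr_schedule)
  n_iter <- length(lrs)
  if (n_iter == 0) {
    attr(model, "trace") <- empty_trace()
    return(model)
  }

  vel <- lapply(model$params, function(p) lapply(p, function(t) t * 0))
  vel_adapter <- if (!is.null(adapter)) adapter * 0

  n <- length(data$images)
  trace <- vector("list", n_iter)
  with_seed(derive_seed(cfg$seed, 104729L), {
    perm <- sample.int(n)
    ptr <- 1L
    for (it in seq_len(n_iter)) {
      take <- integer(0)
      while (length(take) < cfg$batch) {
        if (ptr > n) { perm <- sample.int(n); ptr <- 1L }
        k <- min(n - ptr + 1L, cfg$batch - length(take))
        take <- c(take, perm[ptr:(ptr + k - 1L)])
        ptr <- ptr + k
      }
      xb <- assemble_batch(lapply(data$images[take],
                                  function(im) train_transform(im, aug)))
      yb <- data$labels[take]

      t_hidden <- NULL
      if (!is.null(teacher) && lambda > 0) {
        t_hidden <- forward_pass(teacher, xb, mode = "eval")$hidden
        if (!is.null(adapter)) t_hidden_raw <- t_hidden
      }
      if (!is.null(adapter) && !is.null(t_hidden))
        t_hidden <- crossprod(adapter, t_hidden)  # project into student space

      lfb <- loss_forward_backward(model, xb, yb, teacher_hidden = t_hidden,
                                   lambda = lambda)
      if (!is.finite(lfb$loss)) {
        tr <- do.call(rbind, trace[seq_len(it - 1L)])
        cond <- structure(
          class = c("cn_divergence_error", "error", "condition"),
          list(message = sprintf("non-finite loss at iteration %d", it),
               call = sys.call(-1), trace = tr))
        stop(cond)
      }

      lr <- lrs[it]
      for (i in seq_along(model$params)) {
        for (nm in names(lfb$grads[[i]])) {
          g <- lfb$grads[[i]][[nm]]
          if (nm == "W") g <- g + cfg$weight_decay * model$params[[i]][[nm]]
          vel[[i]][[nm]] <- cfg$momentum * vel[[i]][[nm]] - lr * g
          model$params[[i]][[nm]] <- model$params[[i]][[nm]] + vel[[i]][[nm]]
        }
        ns <- lfb$new_stats[[i]]
        if (!is.null(ns)) {
          model$params[[i]]$running_mean <-
            (1 - BN_MOMENTUM) * model$params[[i]]$running_mean + BN_MOMENTUM * ns$mean
          model$params[[i]]$running_var <-
            (1 - BN_MOMENTUM) * model$params[[i]]$running_var + BN_MOMENTUM * ns$var
        }
      }
      if (!is.null(adapter) && !is.null(t_hidden)) {
        # adapter A maps teacher hidden into student space; trained jointly
        diffA <- lfb$hidden - t_hidden
        gA <- -(2 * lambda / ncol(diffA)) * t_hidden_raw %*% t(diffA)
        vel_adapter <- cfg$momentum * vel_adapter - lr * gA
        adapter <- adapter + vel_adapter
        model$adapter <- adapter
      }

      test_top1 <- NA_real_
      if (!is.null(eval_data) &&
          (it %% cfg$eval_every == 0 || it == n_iter)) {
        lg <- predict_logits(model, eval_data$images, aug)
        test_top1 <- topk_macro_accuracy(lg, eval_data$labels, 1)
      }
      trace[[it]] <- data.frame(iteration = it, lr = lr, loss = lfb$loss,
                                ce = lfb$ce, transfer = lfb$transfer,
                                batch_top1 = lfb$batch_top1,
                                test_top1 = test_top1)
    }
  })
  attr(model, "trace") <- do.call(rbind, trace)
  model
}

empty_trace <- function() {
  data.frame(iteration = integer(0), lr = numeric(0), loss = numeric(0),
             ce = numeric(0), transfer = numeric(0), batch_top1 = numeric(0),
             test_top1 = numeric(0))
}

#' Train a model with the cross-entropy objective
#'
#' Minimizes the mini-batch cross-entropy by SGD with momentum and weight
#' decay under the staged learning-rate ladder; every image in every batch
#' receives an independent [train_transform()] draw. The returned model
#' carries a per-iteration trace (`attr(model, "trace")`) with loss, rate
#' and batch accuracy.
#'
#' @param model a `model_state` (its class count must match the data).
#' @param data a `labeled_dataset`.
#' @param aug an [aug_config()] whose `train_out` matches the model input.
#' @param cfg a [train_config()].
#' @param eval_data optional held-out `labeled_dataset` for periodic
#'   accuracy logging.
#' @return the trained `model_state`.
#' @export
train_crossentropy <- function(model, data, aug, cfg, eval_data = NULL) {
  run_training(model, data, aug, cfg, teacher = NULL, lambda = 0,
               eval_data = eval_data)
}

#' Replace the classifier head
#'
#' Installs a fresh zero-initialized head for `n_classes` categories; all
#' other parameters are preserved bit-exactly.
#'
#' @param model a `model_state`.
#' @param n_classes new category count.
#' @return the modified `model_state`.
#' @export
replace_head <- function(model, n_classes) {
  L <- length(model$spec$layers)
  model$spec$layers[[L]] <- layer_spec("fully_connected", n_classes,
                                       activation = "linear")
  model$spec$n_classes <- as.integer(n_classes)
  model$spec$in_ch[L] <- model$spec$hidden_dim
  model$params[[L]] <- list(W = matrix(0, n_classes, model$spec$hidden_dim),
                            b = numeric(n_classes))
  model
}

#' Pre-train on a source task, then fine-tune on the target task
#'
#' Trains the model on the (larger, disjoint) source dataset, replaces the
#' classifier head with a fresh zero-initialized one sized for the target
#' classes, and fine-tunes on the target dataset. Either stage may have a
#' zero-iteration schedule, which degrades to plain fine-tuning (or plain
#' source training).
#'
#' @param model a `model_state` sized for the source class count.
#' @param source,target `labeled_dataset`s (class counts may differ).
#' @param pre_cfg,fine_cfg [train_config()]s for the two stages.
#' @param aug an [aug_config()] shared by both stages.
#' @param eval_data optional held-out target data for trace logging.
#' @return the fine-tuned `model_state`; the pre-train trace is kept in
#'   `attr(model, "pretrain_trace")`.
#' @export
pretrain_then_finetune <- function(model, source, target, pre_cfg, fine_cfg,
                                   aug, eval_data = NULL) {
  model <- run_training(model, source, aug, pre_cfg)
  pre_trace <- attr(model, "trace")
  model <- replace_head(model, length(target$class_names))
  model <- run_training(model, target, aug, fine_cfg, eval_data = eval_data)
  attr(model, "pretrain_trace") <- pre_trace
  model
}

#' Predict logits for a list of images
#'
#' Applies the deterministic [test_transform()] and runs the model in
#' evaluation mode, in batches.
#'
#' @param model a `model_state`.
#' @param images list of (H, W, 3) arrays.
#' @param aug an [aug_config()].
#' @param batch forward batch size.
#' @return an N x C logit matrix.
#' @export
predict_logits <- function(model, images, aug, batch = 64) {
  C <- model$spec$n_classes
  out <- matrix(0, length(images), C)
  i <- 1L
  while (i <= length(images)) {
    j <- min(i + batch - 1L, length(images))
    xb <- assemble_batch(lapply(images[i:j], function(im) test_transform(im, aug)))
    out[i:j, ] <- t(forward_pass(model, xb, mode = "eval")$logits)
    i <- j + 1L
  }
  out
}
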