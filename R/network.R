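#' Describe one parameter layer
#'
#' @param kind one of `"conv"`, `"depthwise_conv"`, `"pointwise_conv"`,
#'   `"fully_connected"`.
#' @param out_filters number of output filters/units `C_t`.
#' @param kernel odd kernel side `k_t` (forced to 1 for pointwise, ignored
#'   for fully connected layers).
#' @param stride positive integer stride `s`.
#' @param has_norm whether a normalization layer (scale, shift, running
#'   mean/variance) follows the convolution; normalized layers carry no
#'   convolution bias.
#' @param activation `"relu"` or `"linear"`.
#' @return an object of class `layer_spec`.
#' @export
layer_spec <- function(kind, out_filters, kernel = 3, stride = 1,
                       has_norm = TRUE, activation = "relu") {
  kind <- match.arg(kind, c("conv", "depthwise_conv", "pointwise_conv",
                            "fully_connected"))
  cn_assert(is_count(out_filters), "spec", "out_filters must be a positive integer")
  if (kind == "pointwise_conv") kernel <- 1
  if (kind == "fully_connected") { kernel <- 1; stride <- 1; has_norm <- FALSE }
  cn_assert(is_count(kernel) && kernel %% 2 == 1, "spec", "kernel must be odd")
  cn_assert(is_count(stride), "spec", "stride must be a positive integer")
  activation <- match.arg(activation, c("relu", "linear"))
  structure(list(kind = kind, out_filters = as.integer(out_filters),
                 kernel = as.integer(kernel), stride = as.integer(stride),
                 has_norm = isTRUE(has_norm), activation = activation),
            class = "layer_spec")
}

#' Describe a layered network
#'
#' A network is an ordered list of convolutional layers partitioned into
#' blocks, followed by global average pooling, one fully connected layer
#' producing the D-dimensional hidden vector H, and a fully connected
#' classifier head producing the C logits. Blocks may carry an identity
#' skip connection (input added to output) and may be marked prunable; a
#' prunable block names the layer whose filters are cut (`prune_layer`) and
#' any depthwise layers whose channels are coupled to those filters
#' (`coupled`).
#'
#' @param layers list of [layer_spec()]s: all convolutional layers in order,
#'   then the hidden fully connected layer, then the head.
#' @param blocks list of block descriptors, each a list with fields
#'   `layers` (indices into `layers`), `skip`, `prunable`, `prune_layer`,
#'   `coupled`. Blocks must partition the convolutional layers in order.
#' @param hidden_dim hidden vector dimension D.
#' @param n_classes number of categories C.
#' @param input_size expected square input side (informational; forward
#'   infers sizes from the data).
#' @param in_channels input channels, default 3 (RGB).
#' @return an object of class `network_spec` with element `n_prunable`, the
#'   number T of prunable blocks.
#' @export
network_spec <- function(layers, blocks, hidden_dim, n_classes,
                         input_size = 64, in_channels = 3) {
  cn_assert(length(layers) >= 3, "spec", "need at least one conv layer plus two FC layers")
  L <- length(layers)
  hidden <- layers[[L - 1]]; head <- layers[[L]]
  cn_assert(hidden$kind == "fully_connected" && head$kind == "fully_connected",
            "spec", "the last two layers must be fully_connected (hidden, head)")
  cn_assert(hidden$out_filters == hidden_dim, "spec",
            "hidden layer out_filters must equal hidden_dim")
  cn_assert(head$out_filters == n_classes, "spec",
            "head out_filters must equal n_classes")
  conv_idx <- seq_len(L - 2)
  for (i in conv_idx)
    cn_assert(layers[[i]]$kind != "fully_connected", "spec",
              "fully_connected layers may only appear as hidden and head")

  # channel chaining
  in_ch <- integer(L)
  cur <- as.integer(in_channels)
  for (i in conv_idx) {
    in_ch[i] <- cur
    if (layers[[i]]$kind == "depthwise_conv")
      cn_assert(layers[[i]]$out_filters == cur, "spec",
                "depthwise layer %d must keep its input channel count (%d)", i, cur)
    cur <- layers[[i]]$out_filters
  }
  in_ch[L - 1] <- cur           # hidden FC consumes pooled conv output
  in_ch[L] <- hidden$out_filters

  # blocks partition the conv layers in order
  blocks <- lapply(blocks, function(b) {
    list(layers = as.integer(b$layers), skip = isTRUE(b$skip),
         prunable = isTRUE(b$prunable),
         prune_layer = if (is.null(b$prune_layer)) NA_integer_ else as.integer(b$prune_layer),
         coupled = as.integer(b$coupled %||% integer(0)))
  })
  covered <- unlist(lapply(blocks, `[[`, "layers"))
  cn_assert(identical(covered, conv_idx), "spec",
            "blocks must partition the convolutional layers in order")
  for (b in blocks) {
    if (b$prunable) {
      cn_assert(!is.na(b$prune_layer) && b$prune_layer %in% b$layers, "spec",
                "prunable block must name a prune_layer inside the block")
      cn_assert(!b$skip || max(b$layers) > b$prune_layer, "spec",
                "a prunable block's cut filters must be consumed inside the block when it carries a skip")
    }
    if (b$skip) {
      first_in <- in_ch[b$layers[1]]
      last_out <- layers[[b$layers[length(b$layers)]]]$out_filters
      strides <- vapply(b$layers, function(i) layers[[i]]$stride, integer(1))
      cn_assert(first_in == last_out && all(strides == 1), "spec",
                "skip blocks need matching channels and stride 1 throughout")
    }
  }
  structure(list(layers = layers, blocks = blocks,
                 hidden_dim = as.integer(hidden_dim),
                 n_classes = as.integer(n_classes),
                 input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels),
                 in_ch = in_ch,
                 n_prunable = sum(vapply(blocks, `[[`, logical(1), "prunable"))),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> %d layers, %d blocks (T=%d prunable), D=%d, C=%d\n",
              length(x$layers), length(x$blocks), x$n_prunable,
              x$hidden_dim, x$n_classes))
  invisible(x)
}

init_layer_params <- function(ls, in_ch, zero_head = FALSE) {
  if (ls$kind == "fully_connected") {
    W <- if (zero_head) matrix(0, ls$out_filters, in_ch)
    else matrix(rnorm(ls$out_filters * in_ch, 0, sqrt(2 / in_ch)),
                ls$out_filters, in_ch)
    return(list(W = W, b = numeric(ls$out_filters)))
  }
  if (ls$kind == "depthwise_conv") {
    W <- array(rnorm(ls$out_filters * ls$kernel^2, 0, sqrt(2 / ls$kernel^2)),
               c(ls$out_filters, ls$kernel, ls$kernel))
  } else {
    fan_in <- in_ch * ls$kernel^2
    W <- array(rnorm(ls$out_filters * fan_in, 0, sqrt(2 / fan_in)),
               c(ls$out_filters, in_ch, ls$kernel, ls$kernel))
  }
  p <- list(W = W)
  if (ls$has_norm) {
    p$gamma <- rep(1, ls$out_filters); p$beta <- numeric(ls$out_filters)
    p$running_mean <- numeric(ls$out_filters)
    p$running_var <- rep(1, ls$out_filters)
  } else {
    p$b <- numeric(ls$out_filters)
  }
  p
}

#' Build a model from a network spec
#'
#' Parameters are drawn by a fan-in (He) scheme from a seeded stream, so the
#' same `(spec, seed)` always yields identical parameters. The classifier
#' head is initialized to zero, which makes a fresh model predict the
#' uniform distribution (initial cross-entropy `log(C)`).
#'
#' @param spec a [network_spec()].
#' @param seed integer seed.
#' @return an object of class `model_state` with fields `spec`, `params`
#'   (one parameter list per layer), `cut_history`.
#' @export
build_network <- function(spec, seed = 1) {
  cn_assert(inherits(spec, "network_spec"), "spec", "spec must be a network_spec")
  L <- length(spec$layers)
  params <- with_seed(seed, lapply(seq_len(L), function(i)
    init_layer_params(spec$layers[[i]], spec$in_ch[i], zero_head = (i == L))))
  structure(list(spec = spec, params = params, cut_history = list()),
            class = "model_state")
}

#' @export
print.model_state <- function(x, ...) {
  cat(sprintf("<model_state> %s params=%d, cuts=%d\n",
              format(x$spec$n_prunable), parameter_count(x),
              length(x$cut_history)))
  invisible(x)
}

#' Count scalar parameters
#'
#' @param model a `model_state`.
#' @param only_prunable if TRUE, count only the filter banks of prunable
#'   blocks (the cut layer and its coupled depthwise layers).
#' @return integer count.
#' @export
parameter_count <- function(model, only_prunable = FALSE) {
  if (!only_prunable)
    return(sum(vapply(model$params, function(p)
      sum(vapply(p, length, integer(1))), numeric(1))))
  tot <- 0
  for (b in model$spec$blocks) {
    if (!b$prunable) next
    for (li in c(b$prune_layer, b$coupled))
      tot <- tot + length(model$params[[li]]$W)
  }
  tot
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

relu <- function(x) { x[x < 0] <- 0; x }

# Forward through one conv-family layer. Returns output plus caches needed
# for the backward pass. `mask`: channel indices zeroed AFTER normalization
# (used by the pruning equivalence checks).
conv_layer_fwd <- function(ls, p, x, mode, mask = NULL) {
  z <- if (ls$kind == "depthwise_conv")
    cpp_dwconv_fwd(x, p$W, p$b %||% numeric(0), ls$stride)
  else
    cpp_conv_fwd(x, p$W, p$b %||% numeric(0), ls$stride)
  cache <- list(x = x, z = z)
  a <- z
  if (ls$has_norm) {
    C <- dim(z)[1]
    M <- matrix(z, nrow = C)
    if (mode == "train") {
      mu <- rowMeans(M)
      xc <- M - mu
      v <- rowMeans(xc * xc)
      xhat <- xc / sqrt(v + BN_EPS)
      cache$bn <- list(xhat = xhat, var = v)
      cache$new_stats <- list(mean = mu, var = v)
    } else {
      xhat <- (M - p$running_mean) / sqrt(p$running_var + BN_EPS)
    }
    a <- array(p$gamma * xhat + p$beta, dim(z))
  }
  if (!is.null(mask) && length(mask)) {
    a[mask, , , ] <- 0
    if (!is.null(cache$bn)) cache$mask <- mask
  }
  cache$pre_act <- a
  if (ls$activation == "relu") a <- relu(a)
  cache$a <- a
  cache$out <- a
  cache
}

conv_layer_bwd <- function(ls, p, cache, d_out, need_dx) {
  d <- d_out
  if (ls$activation == "relu") d <- d * (cache$pre_act > 0)
  if (!is.null(cache$mask)) d[cache$mask, , , ] <- 0
  grads <- list()
  if (ls$has_norm) {
    C <- dim(cache$z)[1]
    dM <- matrix(d, nrow = C)
    xhat <- cache$bn$xhat
    grads$gamma <- rowSums(dM * xhat)
    grads$beta <- rowSums(dM)
    dxhat <- dM * p$gamma
    dz <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) /
      sqrt(cache$bn$var + BN_EPS)
    dz <- array(dz, dim(cache$z))
  } else {
    dz <- d
  }
  bw <- if (ls$kind == "depthwise_conv")
    cpp_dwconv_bwd(cache$x, p$W, dz, ls$stride, need_dx)
  else
    cpp_conv_bwd(cache$x, p$W, dz, ls$stride, need_dx)
  grads$W <- bw$dw
  if (!ls$has_norm) grads$b <- bw$db
  list(grads = grads, dx = if (need_dx) bw$dx else NULL)
}

gap_fwd <- function(x) {
  d <- dim(x)
  matrix(colMeans(matrix(aperm(x, c(2, 3, 1, 4)), nrow = d[2] * d[3])),
         nrow = d[1])
}

gap_bwd <- function(dp, d) {
  hw <- d[2] * d[3]
  a <- array(rep(as.vector(dp) / hw, each = hw), c(d[2], d[3], d[1], d[4]))
  aperm(a, c(3, 1, 2, 4))
}

# Full forward pass. mode "eval" uses running normalization statistics and
# is deterministic; "train" uses batch statistics and returns their updates.
# capture: conv layer indices whose PRE-normalization convolution output is
# recorded (the reference maps of the pruning score), or the hidden layer
# index for the pre-activation hidden vector.
forward_pass <- function(model, x, mode = "eval", capture = integer(),
                         keep_cache = FALSE, mask = NULL) {
  spec <- model$spec
  L <- length(spec$layers)
  caches <- if (keep_cache) vector("list", L)
  fmaps <- list()
  new_stats <- if (mode == "train") vector("list", L)
  block_in <- if (keep_cache) vector("list", length(spec$blocks))

  cur <- x
  for (bi in seq_along(spec$blocks)) {
    b <- spec$blocks[[bi]]
    xb <- cur
    if (keep_cache) block_in[[bi]] <- xb
    for (li in b$layers) {
      cc <- conv_layer_fwd(spec$layers[[li]], model$params[[li]], cur, mode,
                           mask = mask[[as.character(li)]])
      if (li %in% capture) fmaps[[as.character(li)]] <- cc$z
      if (mode == "train" && !is.null(cc$new_stats))
        new_stats[[li]] <- cc$new_stats
      if (keep_cache) caches[[li]] <- cc else cc$x <- NULL
      cur <- cc$out
    }
    if (b$skip) cur <- cur + xb
  }
  dlast <- dim(cur)
  p <- gap_fwd(cur)
  hi <- L - 1L
  hp <- model$params[[hi]]
  h_pre <- hp$W %*% p + hp$b
  if (hi %in% capture) fmaps[[as.character(hi)]] <- h_pre
  h <- if (spec$layers[[hi]]$activation == "relu") relu(h_pre) else h_pre
  hd <- model$params[[L]]
  logits <- hd$W %*% h + hd$b

  list(logits = logits, hidden = h, hidden_pre = h_pre, pooled = p,
       feature_maps = fmaps, caches = caches, block_in = block_in,
       last_dim = dlast, new_stats = new_stats)
}

softmax_cols <- function(logits) {
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m))
  sweep(e, 2, colSums(e), "/")
}

#' Run a model forward
#'
#' @param model a `model_state`.
#' @param batch float image tensor of dim (3, S, S) or (3, S, S, N), already
#'   transformed/normalized.
#' @param capture integer conv-layer indices whose pre-normalization
#'   convolution outputs (the candidate reference maps) are returned.
#' @param mode `"eval"` (running statistics, deterministic) or `"train"`
#'   (batch statistics).
#' @return list with `logits` (N x C), `softmax` (N x C), `hidden` (N x D)
#'   and `feature_maps` (named list of (C, H, W, N) arrays).
#' @export
forward_network <- function(model, batch, capture = integer(), mode = "eval") {
  cn_assert(inherits(model, "model_state"), "input", "model must be a model_state")
  d <- dim(batch)
  if (length(d) == 3) { dim(batch) <- c(d, 1); d <- dim(batch) }
  cn_assert(length(d) == 4 && d[1] == model$spec$in_channels, "input",
            "batch must have %d channels", model$spec$in_channels)
  fp <- forward_pass(model, batch, mode = mode, capture = capture)
  list(logits = t(fp$logits), softmax = t(softmax_cols(fp$logits)),
       hidden = t(fp$hidden), feature_maps = fp$feature_maps)
}

# Combined loss forward/backward used by every training stage.
# labels: 0-based integer vector. teacher_hidden: D x N matrix or NULL.
# Returns loss components, gradients (same shape as params), and the batch
# normalization statistics updates.
loss_forward_backward <- function(model, x, labels, teacher_hidden = NULL,
                                  lambda = 0) {
  spec <- model$spec
  L <- length(spec$layers)
  N <- dim(x)[4]
  fp <- forward_pass(model, x, mode = "train", keep_cache = TRUE)
  P <- softmax_cols(fp$logits)
  idx <- cbind(labels + 1L, seq_len(N))
  logp <- log(pmax(P[idx], 1e-300))
  ce <- -mean(logp)
  tloss <- 0

  dlogits <- P
  dlogits[idx] <- dlogits[idx] - 1
  dlogits <- dlogits / N

  grads <- vector("list", L)
  hd <- model$params[[L]]
  grads[[L]] <- list(W = dlogits %*% t(fp$hidden), b = rowSums(dlogits))
  dh <- t(hd$W) %*% dlogits
  if (!is.null(teacher_hidden) && lambda > 0) {
    diff <- fp$hidden - teacher_hidden
    tloss <- lambda * sum(diff * diff) / N
    dh <- dh + (2 * lambda / N) * diff
  }
  hi <- L - 1L
  dh_pre <- if (spec$layers[[hi]]$activation == "relu") dh * (fp$hidden_pre > 0) else dh
  hp <- model$params[[hi]]
  grads[[hi]] <- list(W = dh_pre %*% t(fp$pooled), b = rowSums(dh_pre))
  dp <- t(hp$W) %*% dh_pre
  d <- gap_bwd(dp, fp$last_dim)

  for (bi in rev(seq_along(spec$blocks))) {
    b <- spec$blocks[[bi]]
    d_block_out <- if (b$skip) d else NULL
    for (j in rev(seq_along(b$layers))) {
      li <- b$layers[j]
      first_layer <- (bi == 1 && j == 1)
      bw <- conv_layer_bwd(spec$layers[[li]], model$params[[li]],
                           fp$caches[[li]], d, need_dx = !first_layer)
      grads[[li]] <- bw$grads
      d <- bw$dx
    }
    if (b$skip) d <- d + d_block_out
  }

  acc <- mean(max.col(t(fp$logits), ties.method = "first") == labels + 1L)
  list(loss = ce + tloss, ce = ce, transfer = tloss, batch_top1 = acc,
       grads = grads, new_stats = fp$new_stats, hidden = fp$hidden)
}
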