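# Shared fixtures: desk-scale augmentation configs, synthetic task builders,
# and pure-R oracles (explicit-loop convolution, eval-mode network replay,
# brute-force filter scoring) kept independent of the package's C++ path.

aug32 <- aug_config(train_out = 32, test_resize = 36, test_crop = 32)
aug24 <- aug_config(train_out = 24, test_resize = 27, test_crop = 24)
aug16 <- aug_config(train_out = 16, test_resize = 18, test_crop = 16)

# collapse every random augmentation choice: full-image crop, unit scale/ratio
aug_fixed <- function(out) {
  aug_config(scale_range = c(1, 1), ratio_range = c(1, 1),
             crop_frac_range = c(1, 1), train_out = out,
             test_resize = out, test_crop = out)
}

# train/eval pair drawn from the SAME class prototypes (shared
# prototype_seed) but disjoint noise/jitter streams
make_task <- function(n_classes, n_train, n_eval, image_size = 64,
                      noise_sd = 0.05, seed = 1, similarity = 0,
                      jitter = 1) {
  cfg <- synth_config(n_classes, n_train, image_size = image_size,
                      noise_sd = noise_sd, similarity = similarity,
                      jitter = jitter, seed = seed)
  ev_cfg <- synth_config(n_classes, n_eval, image_size = image_size,
                         noise_sd = noise_sd, similarity = similarity,
                         jitter = jitter, seed = seed + 5000L,
                         prototype_seed = cfg$prototype_seed)
  list(train = generate_dataset(cfg), eval = generate_dataset(ev_cfg),
       cfg = cfg)
}

test_batch <- function(ds, aug, idx = seq_along(ds$images)) {
  compressnet:::assemble_batch(
    lapply(ds$images[idx], function(im) test_transform(im, aug)))
}

sched <- function(...) {
  pairs <- list(...)
  lapply(pairs, function(p) c(p[[1]], p[[2]]))
}

# ---- pure-R oracles ------------------------------------------------------

# explicit-loop 2-D cross-correlation with zero padding (k-1)/2
oracle_conv <- function(x, w, b, stride) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  wd <- dim(w); Cout <- wd[1]; k <- wd[3]; pad <- (k - 1) / 2
  Ho <- (H + 2 * pad - k) %/% stride + 1
  Wo <- (W + 2 * pad - k) %/% stride + 1
  y <- array(0, c(Cout, Ho, Wo, N))
  for (n in seq_len(N)) for (co in seq_len(Cout))
    for (oy in seq_len(Ho)) for (ox in seq_len(Wo)) {
      acc <- if (length(b)) b[co] else 0
      for (ci in seq_len(C)) for (kr in seq_len(k)) for (kc in seq_len(k)) {
        iy <- (oy - 1) * stride - pad + kr
        ix <- (ox - 1) * stride - pad + kc
        if (iy >= 1 && iy <= H && ix >= 1 && ix <= W)
          acc <- acc + w[co, ci, kr, kc] * x[ci, iy, ix, n]
      }
      y[co, oy, ox, n] <- acc
    }
  y
}

oracle_bn_eval <- function(z, gamma, beta, rm, rv, eps = 1e-5) {
  a <- z
  for (c in seq_len(dim(z)[1]))
    a[c, , , ] <- gamma[c] * (z[c, , , ] - rm[c]) / sqrt(rv[c] + eps) + beta[c]
  a
}

# eval-mode replay of a plain conv chain (conv layers in order, then GAP,
# hidden FC, head); params given as the package's per-layer lists but the
# arithmetic is all explicit R
oracle_forward_chain <- function(layers, params, x, upto = length(layers)) {
  # returns list of per-layer pre-norm outputs (z) and activations (a)
  zs <- as <- vector("list", upto)
  cur <- x
  for (i in seq_len(upto)) {
    ls <- layers[[i]]; p <- params[[i]]
    z <- oracle_conv(cur, p$W, p$b %||% numeric(0), ls$stride)
    a <- if (ls$has_norm)
      oracle_bn_eval(z, p$gamma, p$beta, p$running_mean, p$running_var)
    else z
    if (ls$activation == "relu") a <- pmax(a, 0)
    zs[[i]] <- z; as[[i]] <- a
    cur <- a
  }
  list(z = zs, a = as)
}

`%||%` <- compressnet:::`%||%`

# brute-force reconstruction-error scores for a plain conv chain: for each
# filter i of conv layer t, physically rebuild the chain without that
# filter (dropping its normalization entries and the consumer's matching
# input slice) and recompute the reference map by explicit-loop convolution.
oracle_score_chain <- function(model, t, inputs) {
  layers <- model$spec$layers
  params <- model$params
  L <- length(layers)
  n_conv <- L - 2L
  M <- dim(inputs)[4]
  full <- oracle_forward_chain(layers, params, inputs, upto = min(t + 1L, n_conv))
  consumer_is_fc <- (t == n_conv)
  ref_full <- if (consumer_is_fc) {
    act <- full$a[[t]]
    hp <- params[[L - 1L]]
    pool <- apply(act, c(1, 4), mean)
    hp$W %*% pool + hp$b
  } else full$z[[t + 1L]]

  C_t <- dim(params[[t]]$W)[1]
  scores <- numeric(C_t)
  for (i in seq_len(C_t)) {
    keep <- setdiff(seq_len(C_t), i)
    p_cut <- params
    p_cut[[t]]$W <- params[[t]]$W[keep, , , , drop = FALSE]
    for (nm in c("b", "gamma", "beta", "running_mean", "running_var"))
      if (!is.null(p_cut[[t]][[nm]]))
        p_cut[[t]][[nm]] <- p_cut[[t]][[nm]][keep]
    if (consumer_is_fc) {
      p_cut[[L - 1L]]$W <- params[[L - 1L]]$W[, keep, drop = FALSE]
      red <- oracle_forward_chain(layers, p_cut, inputs, upto = t)
      pool <- apply(red$a[[t]], c(1, 4), mean)
      ref_i <- p_cut[[L - 1L]]$W %*% pool + p_cut[[L - 1L]]$b
    } else {
      p_cut[[t + 1L]]$W <- params[[t + 1L]]$W[, keep, , , drop = FALSE]
      red <- oracle_forward_chain(layers, p_cut, inputs, upto = t + 1L)
      ref_i <- red$z[[t + 1L]]
    }
    scores[i] <- sum((ref_i - ref_full)^2) / M
  }
  scores
}

# a small plain conv chain (singleton prunable blocks) with randomized
# normalization statistics, so eval mode is non-trivial
make_plain_chain <- function(filters = c(6, 8, 7), k = 3, n_classes = 4,
                             hidden_dim = 6, seed = 1) {
  layers <- lapply(filters, function(f)
    layer_spec("conv", f, kernel = k, activation = "relu"))
  layers <- c(layers, list(
    layer_spec("fully_connected", hidden_dim, activation = "linear"),
    layer_spec("fully_connected", n_classes, activation = "linear")))
  blocks <- lapply(seq_along(filters), function(i)
    list(layers = i, skip = FALSE, prunable = TRUE, prune_layer = i,
         coupled = integer(0)))
  spec <- network_spec(layers, blocks, hidden_dim = hidden_dim,
                       n_classes = n_classes, input_size = 10)
  model <- build_network(spec, seed)
  set.seed(seed + 100)
  for (i in seq_along(filters)) {
    f <- filters[i]
    model$params[[i]]$gamma <- runif(f, 0.5, 1.5)
    model$params[[i]]$beta <- rnorm(f, 0, 0.3)
    model$params[[i]]$running_mean <- rnorm(f, 0, 0.3)
    model$params[[i]]$running_var <- runif(f, 0.5, 1.5)
  }
  # give the zero-initialized head real values so logits are informative
  L <- length(model$params)
  model$params[[L]]$W <- matrix(rnorm(length(model$params[[L]]$W), 0, 0.5),
                                nrow = n_classes)
  model
}
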