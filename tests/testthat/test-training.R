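tiny_sched <- list(c(0.05, 25))

test_that("initial loss on a zero-headed model is log(C)", {
  t <- make_task(10, 4, 1, image_size = 32, seed = 1)
  m <- build_network(spec_tiny_student(n_classes = 10), 1)
  m2 <- train_crossentropy(m, t$train, aug24,
                           train_config(lr_schedule = list(c(0.01, 3)),
                                        batch = 8, seed = 1))
  tr <- attr(m2, "trace")
  expect_equal(tr$loss[1], log(10), tolerance = 1e-10)
  expect_equal(nrow(tr), 3)
})

test_that("training is deterministic for identical (data, cfg, seed)", {
  t <- make_task(5, 6, 1, image_size = 32, seed = 2)
  cfg <- train_config(lr_schedule = tiny_sched, batch = 8, seed = 7)
  m <- build_network(spec_tiny_student(n_classes = 5), 3)
  a <- train_crossentropy(m, t$train, aug24, cfg)
  b <- train_crossentropy(m, t$train, aug24, cfg)
  expect_identical(a$params, b$params)
  c <- train_crossentropy(m, t$train, aug24,
                          train_config(lr_schedule = tiny_sched, batch = 8,
                                       seed = 8))
  expect_false(identical(a$params, c$params))
})

test_that("weight decay is confined to convolution/FC weights", {
  m <- build_network(spec_tiny_student(n_classes = 4), 1)
  g <- optimizer_param_groups(m)
  expect_true(all(g$decay[g$tensor == "W"]))
  expect_false(any(g$decay[g$tensor %in% c("b", "gamma", "beta")]))
  expect_false(any(g$tensor %in% c("running_mean", "running_var")))
})

test_that("combined-loss gradients match finite differences (toy 2-layer net)", {
  # norm-free toy: conv + hidden FC + head, checked against central
  # differences; relative error < 1e-4
  layers <- list(layer_spec("conv", 4, has_norm = FALSE),
                 layer_spec("conv", 5, has_norm = FALSE),
                 layer_spec("fully_connected", 6, activation = "linear"),
                 layer_spec("fully_connected", 3, activation = "linear"))
  blocks <- list(list(layers = 1L, skip = FALSE, prunable = FALSE),
                 list(layers = 2L, skip = FALSE, prunable = FALSE))
  spec <- network_spec(layers, blocks, hidden_dim = 6, n_classes = 3,
                       input_size = 6)
  m <- build_network(spec, 5)
  L <- length(m$params)
  m$params[[L]]$W <- matrix(rnorm(18, 0, 0.5), 3)
  teach <- m
  teach$params[[3]]$W <- teach$params[[3]]$W + 0.1  # distinct hidden target
  set.seed(6)
  x <- array(rnorm(3 * 6 * 6 * 4), c(3, 6, 6, 4))
  y <- c(0L, 1L, 2L, 0L)
  th <- compressnet:::forward_pass(teach, x, mode = "eval")$hidden

  lfb <- compressnet:::loss_forward_backward(m, x, y, teacher_hidden = th,
                                             lambda = 0.5)
  eps <- 1e-6
  probes <- list(c(1, 7), c(2, 20), c(3, 11), c(4, 5))
  for (pr in probes) {
    li <- pr[1]
    for (nm in names(lfb$grads[[li]])) {
      j <- min(pr[2], length(m$params[[li]][[nm]]))
      up <- m; up$params[[li]][[nm]][j] <- up$params[[li]][[nm]][j] + eps
      dn <- m; dn$params[[li]][[nm]][j] <- dn$params[[li]][[nm]][j] - eps
      num <- (compressnet:::loss_forward_backward(up, x, y, th, 0.5)$loss -
                compressnet:::loss_forward_backward(dn, x, y, th, 0.5)$loss) /
        (2 * eps)
      ana <- lfb$grads[[li]][[nm]][j]
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4)
    }
  }
})

test_that("gradients through normalization and skips also check out", {
  m <- build_network(spec_tiny_teacher(n_classes = 4), 2)
  L <- length(m$params)
  m$params[[L]]$W <- matrix(rnorm(length(m$params[[L]]$W), 0, 0.3),
                            nrow = 4)
  set.seed(8)
  x <- array(rnorm(3 * 24 * 24 * 4), c(3, 24, 24, 4))
  y <- c(0L, 1L, 2L, 3L)
  lfb <- compressnet:::loss_forward_backward(m, x, y)
  eps <- 1e-5
  set.seed(9)
  for (rep in 1:12) {
    li <- sample(seq_along(m$params), 1)
    nm <- sample(names(lfb$grads[[li]]), 1)
    j <- sample(length(m$params[[li]][[nm]]), 1)
    up <- m; up$params[[li]][[nm]][j] <- up$params[[li]][[nm]][j] + eps
    dn <- m; dn$params[[li]][[nm]][j] <- dn$params[[li]][[nm]][j] - eps
    num <- (compressnet:::loss_forward_backward(up, x, y)$loss -
              compressnet:::loss_forward_backward(dn, x, y)$loss) / (2 * eps)
    ana <- lfb$grads[[li]][[nm]][j]
    expect_lt(abs(num - ana) / max(1e-4, abs(num) + abs(ana)), 2e-3)
  }
})

test_that("head replacement is bit-exact outside the head", {
  t <- make_task(6, 4, 1, image_size = 32, seed = 3)
  m <- build_network(spec_tiny_student(n_classes = 6), 4)
  m <- train_crossentropy(m, t$train, aug24,
                          train_config(lr_schedule = list(c(0.05, 10)),
                                       batch = 8, seed = 1))
  m2 <- replace_head(m, 3)
  L <- length(m$params)
  expect_identical(m2$params[seq_len(L - 1)], m$params[seq_len(L - 1)])
  expect_true(all(m2$params[[L]]$W == 0))
  expect_equal(m2$spec$n_classes, 3L)
})

test_that("a zero-iteration pre-train stage degrades to plain fine-tuning", {
  src <- make_task(4, 5, 1, image_size = 32, seed = 4)$train
  tgt <- make_task(3, 5, 1, image_size = 32, seed = 9)$train
  m0 <- build_network(spec_tiny_student(n_classes = 4), 6)
  fine <- train_config(lr_schedule = tiny_sched, batch = 8, seed = 2)
  a <- pretrain_then_finetune(m0, src, tgt,
                              train_config(lr_schedule = list(c(0.1, 0)),
                                           batch = 8, seed = 1),
                              fine, aug24)
  b <- train_crossentropy(replace_head(m0, 3), tgt, aug24, fine)
  expect_identical(a$params, b$params)
})

test_that("class-count mismatch and divergence raise typed errors", {
  t <- make_task(5, 3, 1, image_size = 32, seed = 5)
  m <- build_network(spec_tiny_student(n_classes = 4), 1)
  expect_error(train_crossentropy(m, t$train, aug24,
                                  train_config(lr_schedule = tiny_sched)),
               class = "cn_spec_error")

  m5 <- build_network(spec_tiny_student(n_classes = 5), 1)
  err <- tryCatch(
    train_crossentropy(m5, t$train, aug24,
                       train_config(lr_schedule = list(c(1e9, 20)),
                                    batch = 8, seed = 1)),
    cn_divergence_error = function(e) e,
    error = function(e) e)
  expect_s3_class(err, "cn_divergence_error")
  expect_true(!is.null(err$trace))
})

test_that("a small student fits an easy desk task quickly", {
  t <- make_task(5, 30, 1, image_size = 48, noise_sd = 0.05, seed = 6)
  m <- build_network(spec_tiny_student(n_classes = 5), 2)
  m <- train_crossentropy(m, t$train, aug24,
                          train_config(lr_schedule = list(c(0.05, 250),
                                                          c(0.005, 50)),
                                       batch = 16, seed = 3))
  tr <- attr(m, "trace")
  expect_gte(mean(tail(tr$batch_top1, 20)), 0.9)
})

test_that("named presets reproduce the published ladders", {
  p <- train_preset("published-herb-small")
  expect_equal(vapply(p$lr_schedule, `[`, numeric(1), 1),
               c(0.01, 0.001, 0.0001))
  expect_equal(vapply(p$lr_schedule, `[`, numeric(1), 2),
               rep(10000, 3))
  expect_equal(p$batch, 32L)
  expect_equal(p$momentum, 0.9)
  expect_equal(p$weight_decay, 5e-4)
  expect_equal(vapply(train_preset("published-pretrain")$lr_schedule,
                      `[`, numeric(1), 1), c(0.1, 0.01, 0.001, 0.0001))
})
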