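test_that("building is deterministic per (spec, seed) and head starts at zero", {
  spec <- spec_tiny_student(n_classes = 6)
  m1 <- build_network(spec, seed = 42)
  m2 <- build_network(spec, seed = 42)
  expect_identical(m1$params, m2$params)
  m3 <- build_network(spec, seed = 43)
  expect_false(identical(m1$params, m3$params))

  L <- length(spec$layers)
  expect_true(all(m1$params[[L]]$W == 0))
  x <- array(runif(3 * 24 * 24 * 2), c(3, 24, 24, 2))
  fr <- forward_network(m1, x)
  expect_equal(fr$softmax, matrix(1 / 6, 2, 6))  # zeroed head -> uniform
})

test_that("reference specs have the documented pruning structure", {
  expect_equal(spec_desk_student()$n_prunable, 3)
  expect_equal(spec_tiny_student()$n_prunable, 2)
  expect_equal(spec_desk_teacher()$n_prunable, 0)

  full <- spec_student_full()
  expect_equal(full$n_prunable, 17)
  expect_equal(full$hidden_dim, 1280)
  m <- build_network(full, seed = 1)   # ~ millions of parameters, still fast
  expect_gt(parameter_count(m), 1e6)
  expect_s3_class(spec_teacher_full(), "network_spec")
  expect_equal(spec_teacher_full()$hidden_dim, 2048)

  # desk teacher and student share D so the transfer loss needs no adapter
  expect_equal(spec_desk_teacher()$hidden_dim, spec_desk_student()$hidden_dim)
})

test_that("spec validation catches inconsistent channel chains", {
  layers <- list(layer_spec("conv", 8), layer_spec("depthwise_conv", 6),
                 layer_spec("fully_connected", 4, activation = "linear"),
                 layer_spec("fully_connected", 3, activation = "linear"))
  blocks <- list(list(layers = 1:2, skip = FALSE, prunable = FALSE))
  expect_error(network_spec(layers, blocks, hidden_dim = 4, n_classes = 3),
               class = "cn_spec_error")
})

test_that("tiny desk specs run forward on a 3x64x64 input", {
  m <- build_network(spec_desk_student(n_classes = 10, hidden_dim = 32), 1)
  fr <- forward_network(m, array(runif(3 * 64 * 64), c(3, 64, 64)))
  expect_equal(dim(fr$logits), c(1, 10))
  expect_equal(dim(fr$hidden), c(1, 32))
})

test_that("forward of a 1-layer conv net matches explicit-loop convolution", {
  layers <- list(layer_spec("conv", 4, kernel = 3, has_norm = FALSE,
                            activation = "linear"),
                 layer_spec("fully_connected", 3, activation = "linear"),
                 layer_spec("fully_connected", 2, activation = "linear"))
  blocks <- list(list(layers = 1L, skip = FALSE, prunable = FALSE))
  spec <- network_spec(layers, blocks, hidden_dim = 3, n_classes = 2,
                       input_size = 5)
  m <- build_network(spec, 9)
  m$params[[1]]$b <- rnorm(4)
  x <- array(rnorm(3 * 5 * 5 * 2), c(3, 5, 5, 2))
  got <- forward_network(m, x, capture = 1L)
  want <- oracle_conv(x, m$params[[1]]$W, m$params[[1]]$b, 1)
  expect_equal(got$feature_maps[["1"]], want, tolerance = 1e-12)

  # captured map shape is (C_t, H_t, W_t, N) as specified
  expect_equal(dim(got$feature_maps[["1"]]), c(4, 5, 5, 2))
})

test_that("softmax is normalized even for extreme logits", {
  lg <- matrix(c(1e4, -1e4, 0, 1e4, 1e4, -1e4), nrow = 3)
  sm <- compressnet:::softmax_cols(lg)
  expect_true(all(is.finite(sm)) && all(sm >= 0))
  expect_equal(colSums(sm), rep(1, 2), tolerance = 1e-6)
})

test_that("forward is deterministic in evaluation mode", {
  t <- make_task(4, 3, 1, image_size = 32, seed = 2)
  m <- build_network(spec_tiny_student(n_classes = 4), 5)
  xb <- test_batch(t$train, aug24)
  f1 <- forward_network(m, xb)
  f2 <- forward_network(m, xb)
  expect_identical(f1$logits, f2$logits)
})

test_that("parameter counting follows the filter-bank arithmetic", {
  # conv layer with C_t=8, C_{t-1}=4, k=3: filter bank holds 8*4*3*3 = 288
  layers <- list(layer_spec("conv", 4, has_norm = FALSE),
                 layer_spec("conv", 8, has_norm = FALSE),
                 layer_spec("conv", 5, has_norm = FALSE),
                 layer_spec("fully_connected", 4, activation = "linear"),
                 layer_spec("fully_connected", 3, activation = "linear"))
  blocks <- lapply(1:3, function(i)
    list(layers = i, skip = FALSE, prunable = TRUE, prune_layer = i,
         coupled = integer(0)))
  spec <- network_spec(layers, blocks, hidden_dim = 4, n_classes = 3,
                       input_size = 8)
  m <- build_network(spec, 1)
  expect_length(m$params[[2]]$W, 288)

  before <- parameter_count(m)
  pruned <- remove_filters(m, 2L, c(1L, 3L, 5L, 7L))
  expect_length(pruned$params[[2]]$W, 144)
  # drop: 144 weights + 4 biases of layer 2, plus the downstream input
  # slices of layer 3 (5 * 4 * 3 * 3)
  expect_equal(before - parameter_count(pruned), 144 + 4 + 5 * 4 * 9)

  expect_equal(parameter_count(m, only_prunable = TRUE),
               length(m$params[[1]]$W) + 288 + length(m$params[[3]]$W))
})

test_that("checkpoints round-trip and reject shape tampering", {
  dir <- withr::local_tempdir()
  m <- make_plain_chain(filters = c(5, 6), seed = 3)
  m <- remove_filters(m, 1L, c(2L, 4L))
  save_checkpoint(m, dir)
  back <- load_checkpoint(dir)
  expect_equal(back$params, m$params, tolerance = 1e-12)
  expect_equal(back$cut_history, m$cut_history)
  x <- array(rnorm(3 * 10 * 10 * 2), c(3, 10, 10, 2))
  expect_equal(forward_network(back, x)$logits, forward_network(m, x)$logits,
               tolerance = 1e-10)

  # tamper: drop a tensor from params.json
  pj <- file.path(dir, "params.json")
  flat <- jsonlite::read_json(pj, simplifyVector = FALSE)
  flat[[1]]$W <- NULL
  jsonlite::write_json(flat, pj, digits = NA, auto_unbox = FALSE)
  expect_error(load_checkpoint(dir), class = "cn_spec_error")
})

test_that("cut history replay reproduces the current shapes", {
  m0 <- make_plain_chain(filters = c(6, 8, 7), seed = 4)
  spec0 <- m0$spec
  m <- remove_filters(m0, 3L, c(1L, 2L))
  m <- remove_filters(m, 1L, c(5L))
  replayed <- compressnet:::replay_cut_history(spec0, m$cut_history)
  expect_equal(vapply(replayed$layers, `[[`, integer(1), "out_filters"),
               vapply(m$spec$layers, `[[`, integer(1), "out_filters"))
})

test_that("bad batches are rejected", {
  m <- build_network(spec_tiny_student(n_classes = 3), 1)
  expect_error(forward_network(m, array(0, c(4, 24, 24, 1))),
               class = "cn_input_error")
})
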