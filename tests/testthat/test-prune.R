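chain_inputs <- function(n = 4, size = 10, seed = 1) {
  set.seed(seed)
  array(rnorm(3 * size * size * n), c(3, size, size, n))
}

test_that("filter scores match the brute-force rebuild oracle", {
  m <- make_plain_chain(filters = c(5, 6, 4), seed = 2)
  x <- chain_inputs(3, 10, seed = 3)
  for (t in 1:3) {
    got <- score_filters(m, t, x)$scores
    want <- oracle_score_chain(m, t, x)
    expect_equal(unname(got), want, tolerance = 1e-6)
    expect_true(all(got >= 0))
  }
})

test_that("a filter with zero weights, shift and running mean scores zero", {
  m <- make_plain_chain(filters = c(6, 5), seed = 4)
  m$params[[1]]$W[3, , , ] <- 0
  m$params[[1]]$beta[3] <- 0
  m$params[[1]]$running_mean[3] <- 0
  st <- score_filters(m, 1L, chain_inputs(3, 8, seed = 5))
  expect_equal(unname(st$scores[3]), 0)
  expect_gt(min(st$scores[-3]), 0)
})

test_that("identical filters with identical downstream slices score equally", {
  m <- make_plain_chain(filters = c(6, 5), seed = 6)
  for (nm in c("gamma", "beta", "running_mean", "running_var"))
    m$params[[1]][[nm]][4] <- m$params[[1]][[nm]][2]
  m$params[[1]]$W[4, , , ] <- m$params[[1]]$W[2, , , ]
  m$params[[2]]$W[, 4, , ] <- m$params[[2]]$W[, 2, , ]
  st <- score_filters(m, 1L, chain_inputs(2, 8, seed = 7))
  expect_equal(unname(st$scores[2]), unname(st$scores[4]), tolerance = 1e-12)
})

test_that("selection follows the ceiling rule with index tie-breaks", {
  # scores 9,1,8,2,7,3,6,4 at alpha 0.5: the four smallest are at
  # positions 2,4,6,8 (scores 1,2,3,4)
  st <- filter_score_table(1, c(9, 1, 8, 2, 7, 3, 6, 4))
  expect_equal(select_filters(st, 0.5), c(2L, 4L, 6L, 8L))

  # C_t = 7, alpha = 0.5: ceiling(3.5) = 4 removed, 3 reserved
  expect_length(select_filters(filter_score_table(1, runif(7)), 0.5), 4)

  # all-equal scores, C_t = 4: tie rule removes the lowest indices
  expect_equal(select_filters(filter_score_table(1, rep(1, 4)), 0.5),
               c(1L, 2L))

  # selection must not depend on table storage order
  s <- c(5, 1, 4, 2, 3, 9, 8, 7)
  names(s) <- 1:8
  perm <- c(6, 2, 8, 1, 3, 7, 5, 4)
  expect_equal(select_filters(filter_score_table(1, s[perm]), 0.4),
               select_filters(filter_score_table(1, s), 0.4))

  # refusal when nothing would remain
  expect_error(select_filters(filter_score_table(1, runif(3)), 0.9),
               class = "cn_config_error")
  # alpha = 0 selects nothing
  expect_equal(select_filters(filter_score_table(1, runif(5)), 0), integer(0))
})

test_that("structural removal slices all coupled tensors", {
  m <- make_plain_chain(filters = c(4, 5), seed = 8)
  pr <- remove_filters(m, 1L, c(2L, 4L))
  expect_equal(dim(pr$params[[1]]$W), c(2, 3, 3, 3))
  expect_equal(dim(pr$params[[2]]$W), c(5, 2, 3, 3))
  expect_length(pr$params[[1]]$gamma, 2)
  expect_equal(pr$cut_history,
               list(list(block = 1L, removed = c(2L, 4L))))
  expect_error(remove_filters(m, 1L, c(1L, 9L)), class = "cn_input_error")

  # empty removal is the identity
  expect_identical(remove_filters(m, 1L, integer(0)), m)
})

test_that("pruned forward equals zero-masked forward (inverted bottlenecks)", {
  m <- build_network(spec_desk_student(n_classes = 6), 3)
  L <- length(m$params)
  m$params[[L]]$W <- matrix(rnorm(length(m$params[[L]]$W), 0, 0.4), nrow = 6)
  set.seed(10)
  x <- array(rnorm(3 * 32 * 32 * 5), c(3, 32, 32, 5))
  for (rep in 1:4) {
    blk <- sample(c(2L, 3L, 4L), 1)
    rc <- compressnet:::removal_chain(m$spec, blk)
    C_t <- m$spec$layers[[rc$prune_layer]]$out_filters
    idx <- sort(sample(C_t, sample(2:(C_t - 1), 1)))
    pr <- remove_filters(m, blk, idx)
    mask <- stats::setNames(rep(list(idx), 1 + length(rc$coupled)),
                            as.character(c(rc$prune_layer, rc$coupled)))
    f_m <- compressnet:::forward_pass(m, x, mode = "eval", mask = mask)
    f_p <- compressnet:::forward_pass(pr, x, mode = "eval")
    expect_lt(max(abs(f_m$logits - f_p$logits)), 1e-5)
  }
})

test_that("retraining with a zero-iteration schedule returns the model as cut", {
  t <- make_task(4, 5, 1, image_size = 32, seed = 9)
  teacher <- build_network(spec_tiny_teacher(n_classes = 4), 1)
  m <- build_network(spec_tiny_student(n_classes = 4), 2)
  m <- remove_filters(m, 2L, c(1L, 5L))
  cfg <- cut_config(retrain = transfer_config(train = train_config(
    lr_schedule = list(c(0.001, 0)))))
  out <- retrain_layer(m, teacher, t$train, aug24, cfg)
  expect_identical(out$params, m$params)
})

test_that("compress walks blocks top-down and cuts by the ceiling rule", {
  t <- make_task(4, 6, 2, image_size = 32, seed = 10)
  teacher <- build_network(spec_tiny_teacher(n_classes = 4), 3)
  student <- build_network(spec_tiny_student(n_classes = 4), 4)
  res <- compress(student, teacher, t$train, aug24,
                  cut_config(alpha = 0.5, subset_size = 6, subset_seed = 2,
                             retrain = transfer_config(train = train_config(
                               lr_schedule = list(c(0.005, 4)), batch = 6,
                               seed = 5))),
                  eval_data = t$eval)
  expect_equal(vapply(res$model$cut_history, `[[`, integer(1), "block"),
               c(3L, 2L))  # descending block order
  # both tiny-student expansions have 16 filters: 8 reserved at alpha 0.5
  expect_equal(vapply(res$report$stages, `[[`, numeric(1), "reserved"),
               c(8, 8))
  expect_lte(parameter_count(res$model, only_prunable = TRUE),
             0.55 * parameter_count(student, only_prunable = TRUE))
  expect_false(any(is.na(vapply(res$report$stages, `[[`, numeric(1),
                                "test_top1"))))
})

test_that("an alpha of zero leaves the model and its accuracy untouched", {
  t <- make_task(3, 4, 2, image_size = 32, seed = 11)
  teacher <- build_network(spec_tiny_teacher(n_classes = 3), 5)
  student <- build_network(spec_tiny_student(n_classes = 3), 6)
  res <- compress(student, teacher, t$train, aug24,
                  cut_config(alpha = 0, subset_size = 4), eval_data = t$eval)
  expect_identical(res$model$params, student$params)
  lg <- predict_logits(student, t$eval$images, aug24)
  expect_equal(res$report$stages[[1]]$test_top1,
               topk_macro_accuracy(lg, t$eval$labels, 1))
})
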