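#' Transfer (distillation) configuration
#'
#' @param lambda non-negative weight of the hidden-vector matching penalty;
#'   0 reduces transfer training to plain cross-entropy training.
#' @param train a [train_config()] for the optimization schedule. The
#'   published preset is rate 0.001 for 10000 iterations then 0.0001 for
#'   5000; the default here is that ladder shrunk 10x for desk scale.
#' @param adapter if TRUE and the teacher/student hidden dimensions differ,
#'   a learned linear map bridges the teacher hidden vector into the
#'   student's space and is trained jointly; if FALSE (default) a dimension
#'   mismatch is an error.
#' @return an object of class `transfer_config`.
#' @export
transfer_config <- function(lambda = 1, train = train_config(
                              lr_schedule = list(c(0.001, 1000), c(0.0001, 500))),
                            adapter = FALSE) {
  cn_assert(is.numeric(lambda) && length(lambda) == 1 && lambda >= 0,
            "config", "lambda must be a non-negative scalar")
  cn_assert(inherits(train, "train_config"), "config",
            "train must be a train_config")
  structure(list(lambda = lambda, train = train, adapter = isTRUE(adapter)),
            class = "transfer_config")
}

#' Transfer-train a student against a frozen teacher
#'
#' Minimizes the combined objective: mini-batch cross-entropy plus
#' `lambda` times the squared Euclidean distance between the student and
#' teacher hidden vectors, computed on the SAME augmented view of every
#' image. The teacher runs in evaluation mode and is never modified (an
#' internal assertion verifies this).
#'
#' @param student a `model_state` to be trained.
#' @param teacher a trained `model_state`; hidden dimension must equal the
#'   student's unless `cfg$adapter` is enabled.
#' @param data a `labeled_dataset`.
#' @param aug an [aug_config()].
#' @param cfg a [transfer_config()].
#' @param eval_data optional held-out data for trace logging.
#' @return the transfer-trained `model_state`; the per-iteration transfer
#'   penalty is the `transfer` column of `attr(, "trace")`.
#' @export
transfer_train <- function(student, teacher, data, aug, cfg = transfer_config(),
                           eval_data = NULL) {
  cn_assert(inherits(cfg, "transfer_config"), "config",
            "cfg must be a transfer_config")
  cn_assert(inherits(teacher, "model_state"), "input",
            "teacher must be a model_state")
  dS <- student$spec$hidden_dim; dT <- teacher$spec$hidden_dim
  if (cfg$lambda > 0 && dS != dT) {
    if (!cfg$adapter)
      cn_stop("spec", "hidden dims differ (teacher %d, student %d) and no adapter enabled",
              dT, dS)
    if (is.null(student$adapter))
      student$adapter <- with_seed(derive_seed(cfg$train$seed, 7207L),
                                   matrix(rnorm(dT * dS, 0, sqrt(1 / dT)), dT, dS))
  }
  teacher_before <- teacher$params
  out <- run_training(student, data, aug, cfg$train, teacher = teacher,
                      lambda = cfg$lambda, eval_data = eval_data)
  cn_assert(identical(teacher$params, teacher_before), "internal",
            "teacher parameters changed during transfer")
  out
}
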