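#' Macro-averaged top-k accuracy
#'
#' Per class: the fraction of that class's samples whose true label is
#' among the k highest-scoring classes; the reported value is the
#' unweighted mean over classes, times 100. Ties in the scores are broken
#' by ascending class index, so reports are deterministic. Classes absent
#' from the test set are excluded with a warning.
#'
#' @param logits N x C score matrix.
#' @param labels length-N 0-based integer labels.
#' @param k integer in [1, C].
#' @return percentage in [0, 100].
#' @export
topk_macro_accuracy <- function(logits, labels, k = 1) {
  C <- ncol(logits)
  cn_assert(is_count(k) && k <= C, "input", "k must lie in [1, %d]", C)
  cn_assert(nrow(logits) == length(labels), "input",
            "logits and labels disagree in length")
  cn_assert(all(labels >= 0 & labels < C), "input", "labels out of range")
  hit <- vapply(seq_len(nrow(logits)), function(i) {
    ord <- order(logits[i, ], decreasing = TRUE)  # stable: ties by index
    (labels[i] + 1L) %in% ord[seq_len(k)]
  }, logical(1))
  present <- sort(unique(labels))
  if (length(present) < C)
    warning(sprintf("%d of %d classes absent from the test set; excluded",
                    C - length(present), C))
  per_class <- vapply(present, function(c) mean(hit[labels == c]), numeric(1))
  100 * mean(per_class)
}

#' Confusion matrix
#'
#' @param preds,labels length-N 0-based predicted and true class ids.
#' @param C number of classes.
#' @return C x C integer matrix; entry (i, j) counts samples of true class
#'   i-1 predicted as class j-1.
#' @export
confusion_matrix <- function(preds, labels, C) {
  cn_assert(all(preds >= 0 & preds < C) && all(labels >= 0 & labels < C),
            "input", "class ids out of range [0, %d)", C)
  m <- matrix(0L, C, C)
  for (i in seq_along(preds))
    m[labels[i] + 1L, preds[i] + 1L] <- m[labels[i] + 1L, preds[i] + 1L] + 1L
  m
}

#' Stratified per-class 70/30 split
#'
#' Per class, `round_half_up(train_frac * n_c)` samples go to training and
#' the remainder to testing.
#'
#' @param labels 0-based integer labels.
#' @param train_frac training fraction.
#' @param seed split seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_frac = 0.7, seed = 1) {
  classes <- sort(unique(labels))
  cn_assert(all(table(labels) >= 2), "input",
            "every class needs at least 2 samples to split")
  with_seed(seed, {
    tr <- integer(0); te <- integer(0)
    for (c in classes) {
      idx <- which(labels == c)
      n_tr <- max(1L, min(length(idx) - 1L,
                          as.integer(round_half_up(train_frac * length(idx)))))
      pick <- sample(idx, n_tr)
      tr <- c(tr, pick); te <- c(te, setdiff(idx, pick))
    }
    list(train = sort(tr), test = sort(te))
  })
}

#' Repeated stratified split evaluation
#'
#' Runs the published accuracy protocol: `n_repeats` independent stratified
#' 70/30 splits; for each, the training recipe is run on the training part
#' and the held-out part is scored; macro top-k accuracies are aggregated
#' as mean and sample standard deviation over the repeats.
#'
#' @param dataset a `labeled_dataset` (every class needs >= 2 samples).
#' @param model_factory function `(train_ds, seed)` returning a fitted
#'   predictor: either a function `(images) -> N x C logits` or a
#'   `model_state` (then `aug` must be supplied for prediction).
#' @param n_repeats number of random splits.
#' @param train_frac training fraction per class.
#' @param seed master seed; repeat r uses a seed derived from it.
#' @param topk integer vector of k values to report.
#' @param aug an [aug_config()], required when the factory returns a
#'   `model_state`.
#' @return an `eval_report`: list with `topk` (per k: mean/sd in percent),
#'   `per_class_accuracy`, `confusion` (one C x C matrix per split) and
#'   `n_splits`.
#' @export
repeated_split_eval <- function(dataset, model_factory, n_repeats = 5,
                                train_frac = 0.7, seed = 1, topk = c(1, 5),
                                aug = NULL) {
  C <- length(dataset$class_names)
  topk <- topk[topk <= C]
  accs <- matrix(NA_real_, n_repeats, length(topk),
                 dimnames = list(NULL, as.character(topk)))
  confusion <- vector("list", n_repeats)
  per_class <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    sp <- stratified_split(dataset$labels, train_frac, derive_seed(seed, r))
    train_ds <- subset_dataset(dataset, sp$train)
    test_ds <- subset_dataset(dataset, sp$test)
    fit <- model_factory(train_ds, derive_seed(seed, r, 2L))
    logits <- if (is.function(fit)) fit(test_ds$images)
    else {
      cn_assert(!is.null(aug), "config",
                "aug is required when the factory returns a model_state")
      predict_logits(fit, test_ds$images, aug)
    }
    for (j in seq_along(topk))
      accs[r, j] <- topk_macro_accuracy(logits, test_ds$labels, topk[j])
    preds <- max.col(logits, ties.method = "first") - 1L
    confusion[[r]] <- confusion_matrix(preds, test_ds$labels, C)
    per_class[[r]] <- vapply(sort(unique(test_ds$labels)), function(c)
      100 * mean(preds[test_ds$labels == c] == c), numeric(1))
  }
  topk_out <- lapply(seq_along(topk), function(j)
    c(mean = mean(accs[, j]), sd = if (n_repeats > 1) sd(accs[, j]) else 0))
  names(topk_out) <- as.character(topk)
  structure(list(topk = topk_out, accuracies = accs,
                 per_class_accuracy = per_class, confusion = confusion,
                 n_splits = as.integer(n_repeats)), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d splits\n", x$n_splits))
  for (k in names(x$topk))
    cat(sprintf("  top%-2s macro accuracy: %.2f +/- %.2f %%\n",
                k, x$topk[[k]]["mean"], x$topk[[k]]["sd"]))
  invisible(x)
}
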