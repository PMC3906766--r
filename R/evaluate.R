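# Evaluation: MCC, rank-based AUC, stratified repeated cross-validation with
# per-class one-vs-rest metrics, and class balancing by subsampling.

#' Matthews correlation coefficient from confusion counts
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN))`, with the
#' convention that a zero denominator factor yields 0 (so the constant
#' majority classifier scores exactly 0).
#'
#' @param tp,fp,tn,fn Non-negative confusion counts.
#' @return MCC in \[-1, 1\].
#' @export
mcc <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn > 0)
  denom <- (tp + fn) * (tp + fp) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Rank-based AUC
#'
#' Area under the ROC curve via the Mann-Whitney statistic: the probability
#' that a random positive outscores a random negative, ties counting one
#' half. Constant scores therefore give exactly 0.5.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Logical (or 0/1, or two-level factor) class labels.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- labels == levels(labels)[2]
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to compute AUC", call. = FALSE)
  }
  r <- rank(scores) # midranks handle ties as 1/2
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold assignment: within each class, examples are shuffled and
# dealt round-robin into folds.
stratified_folds <- function(labels, folds, seed) {
  labels <- factor(labels)
  if (min(table(labels)) < folds) {
    stop("class '", names(which.min(table(labels))), "' has fewer than ",
         folds, " members; use fewer folds", call. = FALSE)
  }
  fold_id <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold_id
}

#' Balance classes by random subsampling
#'
#' Uniformly subsamples (without replacement) every class down to the size
#' of the smallest class.
#'
#' @param features Labeled feature tibble.
#' @param seed Seed for the subsample.
#' @return Subset tibble with equal class counts.
#' @export
balance_classes <- function(features, seed = 1L) {
  labels <- droplevels(factor(features$label))
  if (nlevels(labels) < 2L) stop("need at least 2 classes", call. = FALSE)
  m <- min(table(labels))
  keep <- withr::with_seed(seed, {
    unlist(lapply(levels(labels), function(cl) {
      sample(which(labels == cl), m)
    }))
  })
  features[sort(keep), , drop = FALSE]
}

#' Stratified repeated cross-validation
#'
#' Evaluates a classifier by stratified k-fold cross-validation repeated
#' `repeats` times. Accuracy and the per-class one-vs-rest AUC/MCC (using
#' the decoded pseudo-posterior of each class as its score) are computed on
#' held-out folds and summarized as mean +/- SD over all folds x repeats.
#' `shuffle_labels = TRUE` runs the randomized control: labels are permuted
#' (per repeat) before fold construction, which should drive AUC to 0.5 and
#' MCC to 0.
#'
#' @param features Labeled feature tibble.
#' @param config A [classifier_config()].
#' @param folds Number of folds (default 5).
#' @param repeats Number of repeats (default 5).
#' @param seed Seed controlling fold assignment and any shuffling.
#' @param shuffle_labels Run the label-shuffled control.
#' @return A `div_eval` object: accuracy mean/SD, per-class AUC/MCC
#'   mean/SD, pooled confusion matrix (rows = true, columns = predicted;
#'   counts pooled over all folds and repeats), and per-fold details.
#' @export
cross_validate <- function(features, config = classifier_config(),
                           folds = 5L, repeats = 5L, seed = 1L,
                           shuffle_labels = FALSE) {
  features <- as_tibble(features)
  labels0 <- droplevels(factor(features$label))
  if (anyNA(labels0)) stop("unlabeled examples in cross-validation input")
  classes <- levels(labels0)
  feat <- dplyr::select(features, -dplyr::any_of("id"))
  fold_rows <- list()
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(true = classes, predicted = classes))
  for (rep_i in seq_len(repeats)) {
    rep_seed <- seed + 104729L * (rep_i - 1L)
    labels <- labels0
    if (shuffle_labels) {
      labels <- withr::with_seed(rep_seed + 1L, sample(labels0))
    }
    fold_id <- stratified_folds(labels, folds, rep_seed)
    for (f in seq_len(folds)) {
      test_i <- which(fold_id == f)
      train <- feat[-test_i, , drop = FALSE]
      train$label <- labels[-test_i]
      test <- feat[test_i, , drop = FALSE]
      truth <- labels[test_i]
      model <- fit_classifier(train, config)
      pred <- predict(model, test, type = "class")
      pred <- factor(as.character(pred), levels = classes)
      post <- predict(model, test, type = "posterior")
      confusion <- confusion + table(true = factor(truth, classes),
                                     predicted = pred)
      acc <- mean(pred == truth)
      for (cl in classes) {
        is_pos <- truth == cl
        pr_pos <- pred == cl
        cl_auc <- auc(post[, cl], is_pos)
        cl_mcc <- mcc(tp = sum(pr_pos & is_pos), fp = sum(pr_pos & !is_pos),
                      tn = sum(!pr_pos & !is_pos), fn = sum(!pr_pos & is_pos))
        fold_rows[[length(fold_rows) + 1L]] <- tibble(
          repeat_i = rep_i, fold = f, class = cl,
          accuracy = acc, auc = cl_auc, mcc = cl_mcc
        )
      }
    }
  }
  per_fold <- dplyr::bind_rows(fold_rows)
  acc_by_fold <- dplyr::distinct(
    per_fold, .data$repeat_i, .data$fold, .data$accuracy)
  per_class <- per_fold |>
    dplyr::group_by(class = factor(.data$class, levels = classes)) |>
    dplyr::summarise(
      auc_sd = sd(.data$auc), auc = mean(.data$auc),
      mcc_sd = sd(.data$mcc), mcc = mean(.data$mcc),
      .groups = "drop"
    ) |>
    dplyr::select("class", "auc", "auc_sd", "mcc", "mcc_sd")
  structure(
    list(
      accuracy = 100 * mean(acc_by_fold$accuracy),
      accuracy_sd = 100 * sd(acc_by_fold$accuracy),
      per_class = per_class,
      confusion = confusion,
      folds = folds, repeats = repeats, seed = seed,
      n = nrow(features), classes = classes,
      classifier = config$kind, shuffled = shuffle_labels,
      per_fold = per_fold
    ),
    class = "div_eval"
  )
}

#' @export
print.div_eval <- function(x, ...) {
  cat("<div_eval> ", x$classifier, if (x$shuffled) " (label-shuffled control)",
      ": ", x$folds, "-fold x ", x$repeats, " repeats on n = ", x$n, "\n",
      sep = "")
  cat(sprintf("  accuracy: %.2f%% +/- %.2f\n", x$accuracy, x$accuracy_sd))
  pc <- x$per_class
  for (i in seq_len(nrow(pc))) {
    cat(sprintf("  %-14s AUC %.2f +/- %.2f   MCC %.2f +/- %.2f\n",
                pc$class[i], pc$auc[i], pc$auc_sd[i], pc$mcc[i], pc$mcc_sd[i]))
  }
  cat("  confusion (true x predicted):\n")
  print(x$confusion)
  invisible(x)
}

#' Tidy a cross-validation result
#'
#' @param x A `div_eval` object.
#' @param ... Unused.
#' @return `tidy()`: per-class tibble of AUC/MCC means and SDs.
#' @method tidy div_eval
#' @export
tidy.div_eval <- function(x, ...) {
  x$per_class
}

#' @rdname tidy.div_eval
#' @return `glance()`: one-row tibble with overall accuracy, macro-averaged
#'   AUC/MCC, and the evaluation setup.
#' @method glance div_eval
#' @export
glance.div_eval <- function(x, ...) {
  tibble(
    accuracy = x$accuracy, accuracy_sd = x$accuracy_sd,
    macro_auc = mean(x$per_class$auc), macro_mcc = mean(x$per_class$mcc),
    n = x$n, folds = x$folds, repeats = x$repeats,
    classifier = x$classifier, shuffled = x$shuffled
  )
}
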