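# Classifiers: majority-class baseline, decision tree, and the RBF SVM with
# one-vs-one pairwise machines. Pairwise decision scores are decoded into
# per-class pseudo-posteriors by exponential loss-based decoding, which also
# drives vote tie-breaking and the divergence-influence measure.

#' Classifier configuration
#'
#' @param kind `"svm"` (Gaussian RBF, one-vs-one), `"tree"` (information-gain
#'   decision tree) or `"majority"` (constant baseline).
#' @param cost SVM soft-margin cost parameter C (default 50).
#' @param gamma RBF kernel width; defaults to 1 / number of features.
#' @param standardize Z-score features on training statistics (default on
#'   for the SVM, whose `gamma = 1/d` presumes comparable feature scales).
#' @param tree_cp Complexity parameter controlling tree pruning.
#' @param seed Random seed recorded with the model.
#' @return List of class `classifier_config`.
#' @export
classifier_config <- function(kind = c("svm", "tree", "majority"),
                              cost = 50, gamma = NULL,
                              standardize = NULL, tree_cp = 0.01,
                              seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(cost > 0, is.null(gamma) || gamma > 0)
  standardize <- standardize %||% (kind == "svm")
  structure(list(kind = kind, cost = cost, gamma = gamma,
                 standardize = standardize, tree_cp = tree_cp,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

feature_matrix <- function(data, feature_names = NULL) {
  cols <- feature_names %||% setdiff(names(data), c("id", "label"))
  x <- as.matrix(data[, cols, drop = FALSE])
  storage.mode(x) <- "double"
  x
}

#' Majority-class baseline classifier
#'
#' Unconditionally predicts the most common training label; ties are broken
#' by the fixed class order MTS < SP < CTP < none. By convention its MCC is
#' identically zero and its AUC 0.5 (constant scores).
#'
#' @param train Feature tibble with a `label` column.
#' @return A fitted `div_model`.
#' @export
majority_classifier <- function(train) {
  fit_classifier(train, classifier_config("majority"))
}

#' Train a classifier on a labeled feature table
#'
#' @param train Feature tibble (`label` column plus numeric features; an
#'   `id` column is ignored).
#' @param config A [classifier_config()].
#' @return A fitted model of class `div_model` supporting
#'   `predict(type = "class" | "posterior" | "decision")`.
#' @export
fit_classifier <- function(train, config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  labels <- droplevels(factor(train$label))
  if (nrow(train) == 0L) stop("empty training set", call. = FALSE)
  feature_names <- setdiff(names(train), c("id", "label"))
  x <- feature_matrix(train, feature_names)
  if (config$kind != "majority" && nlevels(labels) < 2L) {
    stop("degenerate training set: only one class present", call. = FALSE)
  }
  fit <- switch(config$kind,
    majority = {
      counts <- table(factor(labels,
                             levels = intersect(SIGNAL_CLASSES,
                                                levels(labels))))
      names(counts)[which.max(counts)] # which.max: first max in class order
    },
    tree = {
      df <- as.data.frame(x)
      df$.label <- labels
      rpart::rpart(.label ~ ., data = df, method = "class",
                   parms = list(split = "information"),
                   control = rpart::rpart.control(cp = config$tree_cp,
                                                  xval = 0))
    },
    svm = {
      gamma <- config$gamma %||% (1 / ncol(x))
      withr::with_seed(config$seed, e1071::svm(
        x, labels, kernel = "radial", gamma = gamma, cost = config$cost,
        scale = config$standardize, fitted = FALSE
      ))
    }
  )
  structure(list(kind = config$kind, fit = fit, levels = levels(labels),
                 feature_names = feature_names, config = config),
            class = "div_model")
}

#' @export
print.div_model <- function(x, ...) {
  cat("<div_model> ", x$kind, " classifier over {",
      paste(x$levels, collapse = ", "), "}; ",
      length(x$feature_names), " features\n", sep = "")
  invisible(x)
}

#' Predict classes, pseudo-posteriors or pairwise decision scores
#'
#' For the SVM, `type = "decision"` returns the one-vs-one pairwise decision
#' scores (columns named `"A/B"`, positive favoring A); `"posterior"` returns
#' the exponential-loss-decoded pseudo-posteriors; `"class"` applies
#' one-vs-one majority voting with ties broken by smallest decoded loss.
#'
#' @param object A `div_model`.
#' @param newdata Feature tibble.
#' @param type Output type.
#' @param ... Unused.
#' @return Factor of predicted classes, or a numeric matrix of scores.
#' @export
predict.div_model <- function(object, newdata,
                              type = c("class", "posterior", "decision"),
                              ...) {
  type <- match.arg(type)
  x <- feature_matrix(newdata, object$feature_names)
  K <- length(object$levels)
  n <- nrow(x)
  if (object$kind == "majority") {
    if (type == "class") {
      return(factor(rep(object$fit, n), levels = object$levels))
    }
    if (type == "posterior") {
      return(matrix(1 / K, n, K, dimnames = list(NULL, object$levels)))
    }
    pairs <- utils::combn(object$levels, 2L, paste, collapse = "/")
    return(matrix(0, n, length(pairs), dimnames = list(NULL, pairs)))
  }
  if (object$kind == "tree") {
    if (type == "decision") {
      stop("pairwise decision scores are only available for the svm",
           call. = FALSE)
    }
    prob <- predict(object$fit, as.data.frame(x), type = "prob")
    prob <- prob[, object$levels, drop = FALSE]
    if (type == "posterior") return(prob)
    return(factor(object$levels[max.col(prob, ties.method = "first")],
                  levels = object$levels))
  }
  # svm
  pred <- predict(object$fit, x, decision.values = TRUE)
  dec <- attr(pred, "decision.values")
  if (type == "decision") return(dec)
  decoded <- loss_decode(dec, classes = object$levels)
  if (type == "posterior") return(decoded$posterior)
  vote_classes(dec, decoded, object$levels)
}

# One-vs-one majority voting from pairwise decision scores; ties broken by
# smallest decoded loss.
vote_classes <- function(dec, decoded, classes) {
  pairs <- strsplit(colnames(dec), "/", fixed = TRUE)
  votes <- matrix(0L, nrow(dec), length(classes),
                  dimnames = list(NULL, classes))
  for (p in seq_along(pairs)) {
    a <- pairs[[p]][1]; b <- pairs[[p]][2]
    win_a <- dec[, p] > 0
    votes[, a] <- votes[, a] + as.integer(win_a)
    votes[, b] <- votes[, b] + as.integer(!win_a)
  }
  out <- character(nrow(dec))
  for (i in seq_len(nrow(dec))) {
    top <- which(votes[i, ] == max(votes[i, ]))
    if (length(top) == 1L) {
      out[i] <- classes[top]
    } else {
      tied <- classes[top]
      out[i] <- tied[which.min(decoded$loss[i, tied])]
    }
  }
  factor(out, levels = classes)
}

#' Exponential loss-based decoding of one-vs-one scores
#'
#' With the one-vs-one coding matrix M (`M[c, (a,b)] = +1` if `c = a`, `-1`
#' if `c = b`, 0 otherwise), the loss of class c is
#' `loss(c) = sum over machines with M != 0 of exp(-M[c,.] * score)`.
#' Lower loss means more favored; normalized pseudo-posteriors
#' `p(c) proportional to 1/loss(c)` are also returned.
#'
#' @param scores Named numeric vector (one example) or matrix (examples x
#'   pairwise machines) with names/colnames of the form `"A/B"`; positive
#'   scores favor A.
#' @param classes Optional class vector (defaults to classes appearing in
#'   the pair names, in [SIGNAL_CLASSES] order where applicable).
#' @return List with `loss` and `posterior` matrices (examples x classes)
#'   and `label` (argmin-loss class factor).
#' @export
loss_decode <- function(scores, classes = NULL) {
  if (is.null(dim(scores))) {
    scores <- matrix(scores, nrow = 1L, dimnames = list(NULL, names(scores)))
  }
  pair_names <- colnames(scores)
  if (is.null(pair_names)) stop("scores must carry 'A/B' pair names")
  pairs <- strsplit(pair_names, "/", fixed = TRUE)
  seen <- unique(unlist(pairs))
  classes <- classes %||%
    c(intersect(SIGNAL_CLASSES, seen), setdiff(seen, SIGNAL_CLASSES))
  loss <- matrix(0, nrow(scores), length(classes),
                 dimnames = list(rownames(scores), classes))
  for (p in seq_along(pairs)) {
    a <- pairs[[p]][1]; b <- pairs[[p]][2]
    s <- scores[, p]
    loss[, a] <- loss[, a] + exp(-s)
    loss[, b] <- loss[, b] + exp(s)
  }
  inv <- 1 / loss
  posterior <- inv / rowSums(inv)
  label <- factor(classes[apply(loss, 1L, which.min)], levels = classes)
  list(loss = loss, posterior = posterior, label = label)
}

#' Influence of a feature set change on one prediction
#'
#' Compares two pairwise score sets for the same example (e.g. SVM scores
#' computed with and without divergence features): decodes both into
#' pseudo-posteriors and reports the total-variation distance between them,
#' together with the two decoded labels. Symmetric in its arguments.
#'
#' @param scores_with,scores_without Named pairwise score vectors or
#'   single-row matrices over the same classes.
#' @return One-row tibble: `influence` (in \[0, 1\]), `label_with`,
#'   `label_without`.
#' @export
influence_score <- function(scores_with, scores_without) {
  d1 <- loss_decode(scores_with)
  d2 <- loss_decode(scores_without)
  stopifnot(identical(colnames(d1$posterior), colnames(d2$posterior)))
  tibble(
    influence = 0.5 * sum(abs(d1$posterior[1, ] - d2$posterior[1, ])),
    label_with = as.character(d1$label[1]),
    label_without = as.character(d2$label[1])
  )
}

#' Rank examples by the influence of divergence features on their prediction
#'
#' Trains the SVM twice — once on the full feature table and once with the
#' divergence columns removed — under stratified cross-validation, collects
#' each example's held-out pairwise decision scores from both models, and
#' scores the per-example influence as the total-variation distance between
#' the decoded pseudo-posteriors. The returned table is ordered by
#' decreasing influence; `flipped` marks examples whose decoded label
#' changes.
#'
#' @param features Labeled feature tibble containing divergence columns.
#' @param config SVM [classifier_config()].
#' @param folds Number of stratified folds.
#' @param seed Seed for fold assignment.
#' @return Tibble: `id`, `influence`, `label_with`, `label_without`,
#'   `flipped`, sorted by decreasing influence.
#' @export
influence_ranking <- function(features, config = classifier_config("svm"),
                              folds = 5L, seed = 1L) {
  div_cols <- divergence_columns(features)
  if (length(div_cols) == 0L) {
    stop("feature table contains no divergence columns", call. = FALSE)
  }
  labels <- droplevels(factor(features$label))
  fold_id <- stratified_folds(labels, folds, seed)
  ids <- features$id %||% as.character(seq_len(nrow(features)))
  rows <- list()
  for (f in sort(unique(fold_id))) {
    test_i <- which(fold_id == f)
    train <- features[-test_i, , drop = FALSE]
    test <- features[test_i, , drop = FALSE]
    m_with <- fit_classifier(dplyr::select(train, -dplyr::any_of("id")), config)
    m_wo <- fit_classifier(
      dplyr::select(train, -dplyr::any_of(c("id", div_cols))), config)
    dec_with <- predict(m_with, test, type = "decision")
    dec_wo <- predict(m_wo, test, type = "decision")
    for (j in seq_along(test_i)) {
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble(id = ids[test_i[j]]),
        influence_score(dec_with[j, , drop = FALSE],
                        dec_wo[j, , drop = FALSE])
      )
    }
  }
  dplyr::bind_rows(rows) |>
    dplyr::mutate(flipped = .data$label_with != .data$label_without) |>
    dplyr::arrange(dplyr::desc(.data$influence))
}
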