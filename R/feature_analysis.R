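# Single-feature importance: Fayyad-Irani MDL discretization followed by
# information gain I(C;F) = H(C) - H(C|F), both in bits.

label_entropy <- function(labels) {
  p <- table(labels)
  p <- p[p > 0] / length(labels)
  -sum(p * log2(p))
}

# Candidate cut points: midpoints between adjacent distinct values whose
# value-groups are not both pure with the same class (boundary points; by
# Fayyad's theorem restricting to these preserves the optimum).
candidate_cuts <- function(values, labels) {
  ord <- order(values)
  v <- values[ord]
  l <- labels[ord]
  uv <- unique(v)
  if (length(uv) < 2L) return(numeric(0))
  cuts <- numeric(0)
  groups <- split(as.character(l), factor(match(v, uv), levels = seq_along(uv)))
  for (i in seq_len(length(uv) - 1L)) {
    g1 <- unique(groups[[i]])
    g2 <- unique(groups[[i + 1L]])
    if (length(g1) > 1L || length(g2) > 1L || g1 != g2) {
      cuts <- c(cuts, (uv[i] + uv[i + 1L]) / 2)
    }
  }
  cuts
}

# MDL acceptance test for a binary split of (values, labels) at threshold t.
mdl_accept <- function(values, labels, t) {
  n <- length(values)
  left <- labels[values <= t]
  right <- labels[values > t]
  ent_s <- label_entropy(labels)
  ent_1 <- label_entropy(left)
  ent_2 <- label_entropy(right)
  gain <- ent_s - (length(left) / n) * ent_1 - (length(right) / n) * ent_2
  k <- length(unique(labels))
  k1 <- length(unique(left))
  k2 <- length(unique(right))
  delta <- log2(3^k - 2) - (k * ent_s - k1 * ent_1 - k2 * ent_2)
  thresh <- (log2(n - 1) + delta) / n
  list(accept = gain > thresh, gain = gain)
}

fi_split <- function(values, labels) {
  cuts <- candidate_cuts(values, labels)
  if (length(cuts) == 0L) return(numeric(0))
  n <- length(values)
  # pick the cut minimizing the class-entropy of the partition
  went <- vapply(cuts, function(t) {
    left <- labels[values <= t]
    right <- labels[values > t]
    (length(left) / n) * label_entropy(left) +
      (length(right) / n) * label_entropy(right)
  }, numeric(1))
  best <- cuts[which.min(went)]
  if (!mdl_accept(values, labels, best)$accept) return(numeric(0))
  li <- values <= best
  c(fi_split(values[li], labels[li]), best,
    fi_split(values[!li], labels[!li]))
}

#' Fayyad-Irani MDL discretization of a continuous feature
#'
#' Recursively bisects the feature range at the entropy-minimizing boundary
#' midpoint, accepting a split only when its information gain exceeds the
#' minimum-description-length cost
#' `[log2(N-1) + log2(3^k - 2) - (k Ent(S) - k1 Ent(S1) - k2 Ent(S2))] / N`.
#' Identical feature values are never split apart.
#'
#' @param values Numeric feature values.
#' @param labels Class labels (same length).
#' @return Sorted numeric vector of cut points (possibly empty = single bin),
#'   of class `div_discretization`.
#' @export
mdl_discretize <- function(values, labels) {
  stopifnot(length(values) == length(labels), length(values) >= 1L)
  keep <- !is.na(values)
  cuts <- sort(fi_split(values[keep], droplevels(factor(labels[keep]))))
  structure(cuts, class = "div_discretization")
}

#' Information gain of a discretized feature
#'
#' `I(C;F) = H(C) - sum_b (n_b/N) H(C | bin b)` in bits, computed over the
#' bins induced by the cut points.
#'
#' @inheritParams mdl_discretize
#' @param discretization Cut points (e.g. from [mdl_discretize()]); computed
#'   automatically if omitted.
#' @return Information gain in bits, in `[0, H(C)]`.
#' @export
information_gain <- function(values, labels, discretization = NULL) {
  if (is.null(discretization)) discretization <- mdl_discretize(values, labels)
  labels <- factor(labels)
  bins <- findInterval(values, unclass(discretization))
  n <- length(values)
  hc <- label_entropy(labels)
  hcf <- sum(vapply(split(labels, bins), function(l) {
    (length(l) / n) * label_entropy(l)
  }, numeric(1)))
  max(0, hc - hcf)
}

#' Rank features by information gain
#'
#' For every feature column, discretizes with [mdl_discretize()] and scores
#' with [information_gain()]; returns the ranking sorted by decreasing gain
#' (ties broken by feature name).
#'
#' @param features Feature tibble with a `label` column and numeric feature
#'   columns.
#' @return Tibble of class `div_importance`: `feature`, `gain_bits`,
#'   `n_bins`, `cuts` (list-column).
#' @export
rank_features <- function(features) {
  stopifnot("label" %in% names(features))
  labels <- droplevels(factor(features$label))
  if (nlevels(labels) < 2L) stop("need at least 2 classes", call. = FALSE)
  feat_cols <- setdiff(names(features), c("id", "label"))
  feat_cols <- feat_cols[vapply(features[feat_cols], is.numeric, logical(1))]
  rows <- purrr::map(feat_cols, function(f) {
    d <- mdl_discretize(features[[f]], labels)
    tibble(
      feature = f,
      gain_bits = information_gain(features[[f]], labels, d),
      n_bins = length(d) + 1L,
      cuts = list(as.numeric(d))
    )
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::arrange(dplyr::desc(.data$gain_bits), .data$feature)
  class(out) <- c("div_importance", class(out))
  out
}
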