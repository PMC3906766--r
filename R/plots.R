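# ggplot2 views of the main result types.

#' Plot a divergence profile
#'
#' Column entropy against reference residue position, with the local
#' divergence curve (mean over a +/-10 window) overlaid.
#'
#' @param object A `div_profile`.
#' @param n_terminal Restrict the x-axis to the first `n_terminal` residues
#'   (`NULL` = full length).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot div_profile
#' @export
autoplot.div_profile <- function(object, n_terminal = NULL, ...) {
  df <- as_tibble(object)
  df$ld <- local_divergence(object, df$position)
  if (!is.null(n_terminal)) df <- df[df$position <= n_terminal, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$entropy),
                      fill = "grey70", width = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$ld), colour = "#2166ac",
                       linewidth = 0.8) +
    ggplot2::labs(x = "Reference residue position",
                  y = "Column entropy (bits)",
                  title = attr(object, "reference_id"),
                  subtitle = "bars: per-column entropy; line: local divergence") +
    ggplot2::theme_minimal()
}

#' Plot a feature-importance ranking
#'
#' @param object A `div_importance` from [rank_features()].
#' @param top Show only the `top` highest-gain features.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot div_importance
#' @export
autoplot.div_importance <- function(object, top = 30L, ...) {
  df <- head(as_tibble(object), top)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  df$divergence <- grepl("^(LD_|Nraw|mu|sigma|NCdiff|N20|N40|N80_99)",
                         df$feature)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gain_bits, y = .data$feature,
                                   fill = .data$divergence)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#67a9cf",
                                          `FALSE` = "#2166ac"),
                               labels = c(`TRUE` = "divergence",
                                          `FALSE` = "classical"),
                               name = NULL) +
    ggplot2::labs(x = "Information gain (bits)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a cross-validation confusion matrix
#'
#' @param object A `div_eval` from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot div_eval
#' @export
autoplot.div_eval <- function(object, ...) {
  df <- as.data.frame(object$confusion)
  names(df) <- c("true", "predicted", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_gradient(low = "#d1e5f0", high = "#2166ac",
                                 name = "count") +
    ggplot2::labs(x = "Predicted", y = "True",
                  title = sprintf("%s: accuracy %.1f%% +/- %.1f",
                                  object$classifier, object$accuracy,
                                  object$accuracy_sd)) +
    ggplot2::theme_minimal()
}
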