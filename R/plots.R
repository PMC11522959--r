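#' Plot the AUC distribution of a forest run
#'
#' @param object A `forest_run`.
#' @param ... Unused.
#' @return A ggplot: per-iteration test AUCs with their mean.
#' @export
autoplot.forest_run <- function(object, ...) {
  m <- tidy(object)
  ggplot2::ggplot(m, ggplot2::aes(x = .data$auc)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey60", colour = "grey30") +
    ggplot2::geom_vline(xintercept = mean(m$auc), linetype = 2) +
    ggplot2::labs(x = "test AUC", y = "iterations",
                  title = sprintf("%d iterations, mean AUC %.3f",
                                  nrow(m), mean(m$auc))) +
    ggplot2::theme_minimal()
}

#' Plot the top consensus KOs of a consensus report
#'
#' @param object A `consensus_report`.
#' @param n_top Number of KOs shown (by median importance).
#' @param ... Unused.
#' @return A ggplot bar chart of median permutation importance, consensus
#'   KOs filled.
#' @export
autoplot.consensus_report <- function(object, n_top = 20, ...) {
  df <- utils::head(
    tibble::as_tibble(object)[order(-object$median_importance), ], n_top)
  df$ko_id <- factor(df$ko_id, levels = rev(df$ko_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$median_importance,
                                   y = .data$ko_id,
                                   fill = .data$consensus)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "median permutation importance", y = NULL,
                  fill = "consensus") +
    ggplot2::theme_minimal()
}

#' Plot an association table as paired presence percentages
#'
#' The report layout mirrors the study's gene-level figure: for each KO, the
#' percent presence inside and outside the classified group.
#'
#' @param object An `association_table`.
#' @param n_top Number of KOs shown (table order).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.association_table <- function(object, n_top = 20, ...) {
  df <- utils::head(tibble::as_tibble(object), n_top)
  long <- tidyr::pivot_longer(
    df[, c("ko_id", "pct_in_class", "pct_out_class")],
    cols = c("pct_in_class", "pct_out_class"),
    names_to = "group", values_to = "pct")
  long$group <- ifelse(long$group == "pct_in_class", "in class",
                       "out of class")
  long$ko_id <- factor(long$ko_id, levels = rev(df$ko_id))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pct, y = .data$ko_id,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "% strains carrying the KO", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
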