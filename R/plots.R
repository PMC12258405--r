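# ggplot2 views of the two result types users inspect: Pareto fronts of
# route scores, and per-strategy benchmark metrics.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Plot Pareto fronts of route score vectors
#'
#' @param object `rp_pareto` from [pareto_fronts()].
#' @param xlab,ylab axis labels for the first two objectives.
#' @param ... ignored.
#' @return a ggplot.
#' @method autoplot rp_pareto
#' @export
autoplot.rp_pareto <- function(object, xlab = "state score",
                               ylab = "broken bonds score", ...) {
  df <- do.call(rbind, lapply(object, function(f)
    data.frame(x = f$points[, 1], y = f$points[, 2],
               rank = factor(f$rank))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$rank)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(data = df[order(df$rank, df$x), ],
                       linetype = "dashed", alpha = 0.6) +
    ggplot2::labs(x = xlab, y = ylab, colour = "Pareto rank") +
    ggplot2::theme_minimal()
}

#' Plot per-strategy benchmark metrics
#'
#' One panel per metric, one dot per batch, with the per-strategy mean as
#' a bar.
#'
#' @param object `rp_eval` from [evaluate_strategies()].
#' @param ... ignored.
#' @return a ggplot.
#' @method autoplot rp_eval
#' @export
autoplot.rp_eval <- function(object, ...) {
  long <- function(df, src) do.call(rbind, lapply(
    c("percent_solved", "percent_solved_and_constrained",
      "mean_constraint_satisfying_routes", "median_search_time"),
    function(m) data.frame(strategy = df$strategy, metric = m,
                           value = df[[m]], src = src)))
  ds <- long(object$per_strategy, "strategy")
  db <- long(object$per_batch, "batch")
  ggplot2::ggplot(ds, ggplot2::aes(x = .data$strategy, y = .data$value)) +
    ggplot2::geom_col(fill = "grey80") +
    ggplot2::geom_jitter(data = db, width = 0.1, height = 0,
                         colour = "steelblue", size = 1.5) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
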