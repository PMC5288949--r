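#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the stage-one relevance ranking
#'
#' Objective `J` against rank; lower `J` means a more relevant feature.
#' Infinite scores (constant features) are dropped from the panel.
#'
#' @param object an `smkl_scores` tibble from [score_features()].
#' @param top highlight the top-`top` features (default 20).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.smkl_scores <- function(object, top = 20L, ...) {
  df <- dplyr::filter(object, is.finite(.data$J))
  df$selected <- df$rank <= top
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$J)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected), size = 1) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#D55E00", `FALSE` = "grey50"),
                                 name = paste0("top ", top)) +
    ggplot2::labs(x = "rank (ascending J)", y = "single-feature objective J",
                  title = "Stage-one relevance ranking") +
    ggplot2::theme_minimal()
}

#' Plot a forward-selection trace
#'
#' The subset objective `J_Z` after each accepted feature; the strictly
#' decreasing staircase is the acceptance rule made visible.
#'
#' @param object an `smkl_trace` from [forward_select()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.smkl_trace <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$J)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$feature_id),
                       vjust = -0.8, size = 3) +
    ggplot2::scale_x_continuous(breaks = df$step) +
    ggplot2::labs(x = "features accepted", y = expression(J[Z]),
                  title = "Forward selection by objective reduction") +
    ggplot2::theme_minimal()
}

#' Plot per-k effectiveness of a nested feature chain
#'
#' @param object an `smkl_effectiveness` tibble from [effectiveness()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.smkl_effectiveness <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_features, y = .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = attr(object, "mean_effectiveness"),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_x_continuous(breaks = object$n_features) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "features in the nested set", y = "cross-validated accuracy",
                  title = "Effectiveness of the nested feature chain",
                  subtitle = "dashed line: mean effectiveness") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
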