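#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

#' Volcano-style plot of differential circuit activity
#'
#' @param object A `circuit_diff` from [differential_circuits()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot circuit_diff
#' @export
autoplot.circuit_diff <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$delta,
                                    y = -log10(pmax(.data$q, 1e-300)),
                                    colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(object$alpha),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = sprintf("mean activity difference (%s - %s)",
                              object$groups[1], object$groups[2]),
                  y = "-log10 FDR q",
                  title = "Differential circuit activity") +
    ggplot2::theme_minimal()
}

#' Bar chart of significant circuits per hallmark and group
#'
#' @param object A `hallmark_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hallmark_summary
#' @export
autoplot.hallmark_summary <- function(object, ...) {
  ggplot2::ggplot(object$counts,
                  ggplot2::aes(x = .data$hallmark, y = .data$n_significant,
                               fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "significant circuits",
                  title = "Cancer hallmarks of differentially active circuits") +
    ggplot2::theme_minimal()
}

#' Impact distribution of a simulated drug, split by responder label
#'
#' @param object A `perturbation_result` with responder labels (see
#'   [simulate_drug()]).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot perturbation_result
#' @export
autoplot.perturbation_result <- function(object, ...) {
  df <- if (!is.null(object$responders)) object$responders else object$impact
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$impact))
  if ("label" %in% names(df)) {
    p <- p + ggplot2::geom_histogram(ggplot2::aes(fill = .data$label),
                                     bins = 30, alpha = 0.8,
                                     position = "identity") +
      ggplot2::geom_vline(xintercept = attr(df, "threshold"),
                          linetype = "dashed")
  } else {
    p <- p + ggplot2::geom_histogram(bins = 30)
  }
  p + ggplot2::labs(x = "per-cell impact (mean |log2 FC| over target circuits)",
                    y = "cells",
                    title = paste0("Simulated perturbation",
                                   if (!is.null(object$drug))
                                     paste0(": ", object$drug))) +
    ggplot2::theme_minimal()
}

#' Heatmap of circuit activities
#'
#' @param object A `circuit_activity` matrix.
#' @param max_cells Downsample to at most this many cells for display.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot circuit_activity
#' @export
autoplot.circuit_activity <- function(object, max_cells = 200, ...) {
  m <- m_strip(unclass(object))
  if (ncol(m) > max_cells) {
    m <- m[, seq(1, ncol(m), length.out = max_cells), drop = FALSE]
  }
  df <- tidy.circuit_activity(structure(m, class = c("circuit_activity",
                                                     "matrix", "array")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell, y = .data$circuit_id,
                                   fill = .data$activity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank()) +
    ggplot2::labs(x = "cells", y = NULL, fill = "activity")
}
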