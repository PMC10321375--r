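#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a guide design into a flat tibble
#'
#' Drops the nested `hits` list-column, leaving one plain row per
#' guide, ready for dplyr/ggplot2 pipelines.
#'
#' @param x A `guide_design`.
#' @param ... Unused.
#' @return A plain tibble.
#' @method tidy guide_design
#' @export
tidy.guide_design <- function(x, ...) {
  out <- as_tibble(x)
  out$hits <- NULL
  out$gene_hits <- NULL
  out
}

#' One-row summary of a guide design
#'
#' @param x A `guide_design`.
#' @param ... Unused.
#' @return A one-row tibble: guide counts, unique/flagged tallies,
#'   mean specificity, total off-target sites.
#' @method glance guide_design
#' @export
glance.guide_design <- function(x, ...) {
  tibble(
    target_id = attr(x, "target_id"),
    target_length = attr(x, "target_length"),
    n_guides = nrow(x),
    n_unique = sum(x$is_unique),
    n_poly_ta = sum(x$poly_ta),
    n_hairpin = sum(x$hairpin),
    mean_specificity = if (nrow(x) == 0) NA_real_ else mean(x$specificity),
    total_offtargets = sum(x$n_offtargets)
  )
}

#' Plot guide positions on the target
#'
#' ggplot2 rendering of the position map: one arrow per guide, strand
#' by direction, uniqueness by fill.
#'
#' @param object A `guide_design`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot guide_design
#' @export
autoplot.guide_design <- function(object, ...) {
  tlen <- attr(object, "target_length")
  df <- tidy(object)
  df$y <- seq_len(nrow(df))
  df$xend <- ifelse(df$strand == "+", df$end, df$start)
  df$x <- ifelse(df$strand == "+", df$start, df$end)
  df$uniqueness <- ifelse(df$is_unique, "unique", "not_unique")
  ggplot2::ggplot(df) +
    ggplot2::annotate("segment", x = 0, xend = tlen, y = 0, yend = 0,
                      linewidth = 1) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y, yend = .data$y,
                   colour = .data$uniqueness),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"), type = "closed"),
      linewidth = 1.2
    ) +
    ggplot2::geom_text(
      ggplot2::aes(x = tlen, y = .data$y, label = .data$guide_id),
      hjust = -0.1, size = 3
    ) +
    ggplot2::scale_colour_manual(values = c(unique = "#2b6cb0",
                                            not_unique = "#c53030")) +
    ggplot2::coord_cartesian(xlim = c(0, tlen * 1.15)) +
    ggplot2::labs(x = sprintf("position on %s (nt)", attr(object, "target_id")),
                  y = NULL, colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
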