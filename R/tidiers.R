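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
NULL

#' Tidy switch results
#'
#' @param x An `"mp_switches"` tibble.
#' @param ... Unused.
#' @return A plain tibble ordered by ascending adjusted p then pair id.
#' @export
tidy.mp_switches <- function(x, ...) {
  tibble::as_tibble(x) |> dplyr::arrange(.data$adjusted_p, .data$pair_id)
}

#' One-row summary of a switch scan
#'
#' @param x An `"mp_switches"` tibble.
#' @param alpha Cutoff used for the significant count (default 0.05).
#' @param ... Unused.
#' @return Tibble with pair counts, test usage and the significant tally.
#' @export
glance.mp_switches <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    n_pairs = nrow(x),
    n_chi_square = sum(x$test_used == "chi_square"),
    n_fisher = sum(x$test_used == "fisher_exact"),
    n_permutation = sum(x$test_used == "permutation"),
    n_degenerate = sum(x$degenerate),
    n_significant = sum(x$adjusted_p < alpha),
    alpha = alpha
  )
}

#' Tidy a metabo-plastic network
#'
#' @param x An `"mp_network"` object.
#' @param ... Unused.
#' @return The node tibble in hub rank order.
#' @export
tidy.mp_network <- function(x, ...) hub_pathways(x)

#' One-row summary of a metabo-plastic network
#'
#' @param x An `"mp_network"` object.
#' @param ... Unused.
#' @export
glance.mp_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_cohorts = length(unique(x$edges$cohort)),
    max_degree = if (nrow(x$nodes) > 0) max(x$nodes$degree) else 0L
  )
}

#' Volcano-style plot of switch results
#'
#' Log2 odds ratio against -log10 adjusted p; points past `alpha` are
#' highlighted.
#'
#' @param object An `"mp_switches"` tibble.
#' @param alpha Highlight cutoff (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mp_switches <- function(object, alpha = 0.05, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(significant = .data$adjusted_p < alpha)
  ggplot2::ggplot(df, ggplot2::aes(x = log2(.data$odds_ratio),
                                   y = -log10(pmax(.data$adjusted_p, 1e-50)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 odds ratio (young vs old first-dominance)",
                  y = "-log10 adjusted p",
                  colour = paste0("adj p < ", alpha)) +
    ggplot2::theme_minimal()
}

#' Heatmap of pathway activity scores
#'
#' @param object An `"mp_activity"` tibble.
#' @param ... Unused.
#' @return A ggplot object (pathway-by-sample tile map).
#' @export
autoplot.mp_activity <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"pathway_id",
                              names_to = "sample_id", values_to = "score")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id,
                                     y = .data$pathway_id,
                                     fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "activity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Tile plot of Ro/e enrichment
#'
#' @param object An `"mp_roe"` tibble.
#' @param ... Unused.
#' @return A ggplot object; tiles above 1 mark enrichment.
#' @export
autoplot.mp_roe <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$group, y = .data$cell_type,
                               fill = .data$roe)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$roe)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(midpoint = 1, low = "steelblue",
                                  mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Ro/e") +
    ggplot2::theme_minimal()
}

#' QC scatter of UMI totals against detected genes
#'
#' @param object An `"mp_qc"` tibble (after [apply_qc_filters()] the points
#'   are coloured by verdict).
#' @param ... Unused.
#' @return A ggplot object on log10 axes.
#' @export
autoplot.mp_qc <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$umi_count,
                                        y = .data$gene_count))
  p <- if ("verdict" %in% names(df)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$verdict),
                            alpha = 0.4, size = 0.8) +
      ggplot2::scale_colour_manual(values = c(keep = "grey40",
                                              drop = "firebrick"))
  } else {
    p + ggplot2::geom_point(alpha = 0.4, size = 0.8)
  }
  p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "UMI count", y = "detected genes") +
    ggplot2::theme_minimal()
}
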