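#' Select the top-ranked switch events of one cohort
#'
#' Orders events by ascending `adjusted_p` with ties broken by `pair_id`
#' and keeps at most `k` (all of them when fewer exist). Idempotent and
#' independent of input row order.
#'
#' @param results Switch-result tibble carrying `adjusted_p`.
#' @param k Maximum number of events to keep (default 200).
#' @return The selected rows in rank order.
#' @export
select_top_events <- function(results, k = 200) {
  stopifnot(is.numeric(k), length(k) == 1, k >= 1)
  if (!"adjusted_p" %in% names(results)) stop("results lack `adjusted_p`")
  results |>
    dplyr::arrange(.data$adjusted_p, .data$pair_id) |>
    dplyr::slice_head(n = as.integer(k))
}

#' Build the metabo-plastic network from per-cohort top events
#'
#' Nodes are pathways; each cohort contributes one edge per selected event,
#' and the same pair recurring in several cohorts yields parallel edges, so
#' node degree reflects recurrence across cohorts. `weighted_degree` sums
#' `-log10(adjusted_p)` (clipped at 50) over incident edges. Betweenness is
#' exact Brandes centrality on the simple graph obtained by collapsing the
#' cohort multigraph, in unnormalized shortest-path-pair counts.
#'
#' @param event_lists Either a named list of event tibbles (name = cohort
#'   tag) or a single tibble with a `cohort` column. Each event needs
#'   `first`, `second`, `adjusted_p` and optionally `odds_ratio`,
#'   `direction`.
#' @return An object of class `"mp_network"`: a list with tibbles `nodes`
#'   (`pathway_id`, `degree`, `weighted_degree`, `betweenness`) and `edges`
#'   (`pathway_a`, `pathway_b`, `cohort`, `adjusted_p`, `odds_ratio`,
#'   `direction`).
#' @export
build_network <- function(event_lists) {
  if (is.data.frame(event_lists)) {
    edges <- tibble::as_tibble(event_lists)
    if (!"cohort" %in% names(edges)) edges$cohort <- "cohort1"
  } else {
    stopifnot(is.list(event_lists))
    if (length(event_lists) > 0 && is.null(names(event_lists))) {
      names(event_lists) <- paste0("cohort", seq_along(event_lists))
    }
    edges <- purrr::imap(event_lists, function(ev, tag) {
      dplyr::mutate(tibble::as_tibble(ev), cohort = tag)
    }) |> dplyr::bind_rows()
  }
  if (nrow(edges) == 0) {
    net <- list(
      nodes = tibble::tibble(pathway_id = character(), degree = integer(),
                             weighted_degree = numeric(),
                             betweenness = numeric()),
      edges = tibble::tibble(pathway_a = character(), pathway_b = character(),
                             cohort = character(), adjusted_p = numeric(),
                             odds_ratio = numeric(), direction = character())
    )
    class(net) <- "mp_network"
    return(net)
  }
  if (!all(c("first", "second", "adjusted_p") %in% names(edges))) {
    stop("events need `first`, `second`, `adjusted_p` columns")
  }
  if (any(edges$first == edges$second)) {
    stop("event with identical endpoints (self-edge) rejected")
  }
  if (!"odds_ratio" %in% names(edges)) edges$odds_ratio <- NA_real_
  if (!"direction" %in% names(edges)) edges$direction <- NA_character_
  edges <- tibble::tibble(
    pathway_a = pmin(edges$first, edges$second),
    pathway_b = pmax(edges$first, edges$second),
    cohort = edges$cohort, adjusted_p = edges$adjusted_p,
    odds_ratio = edges$odds_ratio, direction = edges$direction
  ) |> dplyr::arrange(.data$cohort, .data$pathway_a, .data$pathway_b)
  nodes_ids <- sort(unique(c(edges$pathway_a, edges$pathway_b)))
  w <- pmin(-log10(edges$adjusted_p), 50)  # clip; adjusted_p = 0 maps to 50
  incident <- c(edges$pathway_a, edges$pathway_b)
  deg <- table(factor(incident, levels = nodes_ids))
  wdeg <- tapply(c(w, w), factor(incident, levels = nodes_ids), sum,
                 default = 0)
  g <- igraph::graph_from_data_frame(
    unique(edges[c("pathway_a", "pathway_b")]),
    directed = FALSE, vertices = nodes_ids
  )
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  net <- list(
    nodes = tibble::tibble(
      pathway_id = nodes_ids,
      degree = as.integer(deg),
      weighted_degree = as.numeric(wdeg),
      betweenness = as.numeric(btw[nodes_ids])
    ),
    edges = edges
  )
  class(net) <- "mp_network"
  net
}

#' @export
print.mp_network <- function(x, ...) {
  cat("Metabo-plastic network:", nrow(x$nodes), "pathways,",
      nrow(x$edges), "events across",
      length(unique(x$edges$cohort)), "cohort(s)\n")
  invisible(x)
}

#' Rank hub pathways of a metabo-plastic network
#'
#' @param net An `"mp_network"` object.
#' @param top_n Number of hubs to return (default all nodes).
#' @return Node tibble ranked by descending degree, then weighted degree,
#'   then `pathway_id`; betweenness reported as an auxiliary attribute.
#' @export
hub_pathways <- function(net, top_n = Inf) {
  stopifnot(inherits(net, "mp_network"))
  if (nrow(net$nodes) == 0) stop("empty network")
  ranked <- net$nodes |>
    dplyr::arrange(dplyr::desc(.data$degree),
                   dplyr::desc(.data$weighted_degree), .data$pathway_id)
  utils::head(ranked, n = top_n)
}

#' Convert a metabo-plastic network to igraph
#'
#' @param net An `"mp_network"` object.
#' @param collapse Collapse parallel cohort edges into a simple graph
#'   (default FALSE keeps the multigraph).
#' @return An igraph object with node and edge attributes.
#' @export
as_igraph_network <- function(net, collapse = FALSE) {
  stopifnot(inherits(net, "mp_network"))
  ed <- net$edges
  if (collapse) ed <- dplyr::distinct(ed, .data$pathway_a, .data$pathway_b)
  igraph::graph_from_data_frame(ed, directed = FALSE,
                                vertices = net$nodes)
}

#' Export a network as GraphML plus node/edge TSV tables
#'
#' @param net An `"mp_network"` object.
#' @param dir Output directory (created if needed); writes `network.graphml`,
#'   `nodes.tsv`, `edges.tsv`.
#' @return `dir`, invisibly.
#' @export
write_network <- function(net, dir) {
  stopifnot(inherits(net, "mp_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ed <- net$edges
  ed$direction[is.na(ed$direction)] <- ""
  g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                     vertices = net$nodes)
  igraph::write_graph(g, file.path(dir, "network.graphml"),
                      format = "graphml")
  readr::write_tsv(net$nodes, file.path(dir, "nodes.tsv"), progress = FALSE)
  readr::write_tsv(net$edges, file.path(dir, "edges.tsv"), progress = FALSE)
  invisible(dir)
}
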