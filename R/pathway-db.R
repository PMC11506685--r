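#' Read gene sets from a GMT file
#'
#' Parses the standard GMT format (one gene set per line: id, description,
#' then member genes, all tab-separated) into a long pathway-database tibble.
#' Every gene starts with weight 1; [attach_ppi_weights()] can replace the
#' uniform weights with PPI-derived ones.
#'
#' @param path Path to a GMT file.
#' @return A tibble with one row per (pathway, gene): columns `pathway_id`,
#'   `name`, `gene`, `weight`. Genes are kept in canonical lexicographic
#'   order within each pathway. Carries class `"mp_pathway_db"`.
#' @details Duplicate genes within one line are collapsed with a warning.
#'   A line with fewer than three fields, a pathway with fewer than two
#'   distinct genes, or a duplicated pathway id is an error.
#' @seealso [write_gmt()], [attach_ppi_weights()], [enumerate_pairs()]
#' @export
read_gmt <- function(path) {
  stopifnot(is.character(path), length(path) == 1)
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty GMT file: ", path)
  rows <- purrr::imap(lines, function(line, i) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3) {
      stop("malformed GMT line ", i, ": fewer than 3 tab-separated fields")
    }
    genes <- fields[-(1:2)]
    if (anyDuplicated(genes)) {
      warning("duplicate genes in pathway '", fields[1], "' (GMT line ", i,
              ") collapsed", call. = FALSE)
      genes <- unique(genes)
    }
    tibble::tibble(pathway_id = fields[1], name = fields[2],
                   gene = sort(genes))
  })
  db <- dplyr::bind_rows(rows)
  db$weight <- 1
  validate_pathway_db(db)
}

#' Write a pathway database back to GMT
#'
#' @param db A pathway database tibble from [read_gmt()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(db, path) {
  db <- validate_pathway_db(db)
  lines <- db |>
    dplyr::group_by(.data$pathway_id, .data$name) |>
    dplyr::summarise(genes = paste(sort(.data$gene), collapse = "\t"),
                     .groups = "drop") |>
    dplyr::arrange(.data$pathway_id)
  writeLines(paste(lines$pathway_id, lines$name, lines$genes, sep = "\t"),
             path)
  invisible(path)
}

#' Validate a pathway database tibble
#'
#' Checks the invariants: gene symbols unique within a pathway, every gene
#' has exactly one nonnegative weight, every pathway has >= 2 genes and at
#' least one positive weight, pathway ids map to a single name.
#'
#' @param db A data frame with columns `pathway_id`, `name`, `gene`, `weight`.
#' @return The validated tibble with class `"mp_pathway_db"`.
#' @export
validate_pathway_db <- function(db) {
  db <- tibble::as_tibble(db)
  need <- c("pathway_id", "name", "gene", "weight")
  if (!all(need %in% names(db))) {
    stop("pathway database needs columns: ", paste(need, collapse = ", "))
  }
  if (any(duplicated(db[c("pathway_id", "gene")]))) {
    stop("duplicate gene within a pathway")
  }
  id_names <- unique(db[c("pathway_id", "name")])
  if (anyDuplicated(id_names$pathway_id)) {
    stop("duplicate pathway_id with conflicting names")
  }
  sizes <- table(db$pathway_id)
  if (any(sizes < 2)) {
    stop("pathways with fewer than 2 genes: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  if (any(!is.finite(db$weight)) || any(db$weight < 0)) {
    stop("weights must be finite and nonnegative")
  }
  wmax <- tapply(db$weight, db$pathway_id, max)
  if (any(wmax <= 0)) {
    stop("pathways with no positive weight: ",
         paste(names(wmax)[wmax <= 0], collapse = ", "))
  }
  class(db) <- unique(c("mp_pathway_db", class(db)))
  db
}

#' Read a protein-protein interaction edge list
#'
#' Reads a 2- or 3-column tab-separated file (`gene_a`, `gene_b`, optional
#' positive `weight`, default 1). Edges are undirected: records are
#' canonicalised so the lexicographically smaller gene comes first,
#' self-loops are dropped, and duplicate undirected edges are collapsed by
#' summing their weights.
#'
#' @param path Path to the edge-list TSV (a header line is detected and
#'   skipped when the third field is non-numeric).
#' @return A tibble with columns `gene_a`, `gene_b`, `weight`.
#' @export
read_ppi <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", fill = TRUE,
                           quote = "", comment.char = "")
  if (ncol(raw) < 2) stop("PPI edge list needs at least 2 columns")
  if (ncol(raw) == 2) raw$V3 <- "1"
  raw$V3[!nzchar(raw$V3)] <- "1"
  w <- suppressWarnings(as.numeric(raw$V3))
  if (is.na(w[1]) && nrow(raw) > 1) {  # header line
    raw <- raw[-1, , drop = FALSE]
    w <- w[-1]
  }
  if (any(is.na(w)) || any(w <= 0)) stop("PPI edge weights must be positive")
  ppi_edges(raw$V1, raw$V2, w)
}

#' Build a canonical undirected PPI edge tibble
#'
#' @param gene_a,gene_b Character vectors of endpoint gene symbols.
#' @param weight Positive edge weights (recycled; default 1).
#' @return A tibble `gene_a`, `gene_b`, `weight` with `gene_a < gene_b`,
#'   no self-loops, duplicates collapsed by summing weights.
#' @export
ppi_edges <- function(gene_a, gene_b, weight = 1) {
  ga <- as.character(gene_a)
  gb <- as.character(gene_b)
  tb <- tibble::tibble(
    gene_a = pmin(ga, gb),
    gene_b = pmax(ga, gb),
    weight = as.numeric(weight)
  )
  tb <- dplyr::filter(tb, .data$gene_a != .data$gene_b)
  tb |>
    dplyr::group_by(.data$gene_a, .data$gene_b) |>
    dplyr::summarise(weight = sum(.data$weight), .groups = "drop") |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
}

#' Attach PPI-derived gene weights to a pathway database
#'
#' For each pathway, takes the PPI subgraph induced by the pathway's genes
#' and sets each gene's weight to
#' `floor + weighted_degree / max(weighted_degree)`; genes with no
#' within-pathway edge get `floor`. A pathway whose induced subgraph has no
#' edges keeps uniform weight 1 for all genes. With the default `floor = 1`
#' a hub gene counts at most twice a peripheral gene.
#'
#' @param db A pathway database tibble ([read_gmt()]).
#' @param ppi A PPI edge tibble ([read_ppi()] / [ppi_edges()]).
#' @param floor Nonnegative baseline weight added to every connected
#'   pathway's genes (default 1).
#' @return The database with the `weight` column replaced.
#' @export
attach_ppi_weights <- function(db, ppi, floor = 1) {
  db <- validate_pathway_db(db)
  stopifnot(is.numeric(floor), length(floor) == 1)
  if (!is.finite(floor) || floor < 0) stop("`floor` must be >= 0")
  edges <- ppi_edges(ppi$gene_a, ppi$gene_b,
                     if ("weight" %in% names(ppi)) ppi$weight else 1)
  out <- db |>
    dplyr::group_by(.data$pathway_id) |>
    dplyr::group_modify(function(g, key) {
      sub <- edges[edges$gene_a %in% g$gene & edges$gene_b %in% g$gene, ]
      if (nrow(sub) == 0) {
        g$weight <- 1
        return(g)
      }
      deg <- tapply(c(sub$weight, sub$weight), c(sub$gene_a, sub$gene_b), sum)
      d <- deg[g$gene]
      d[is.na(d)] <- 0
      g$weight <- floor + as.numeric(d) / max(d)
      g
    }) |>
    dplyr::ungroup()
  validate_pathway_db(out[c("pathway_id", "name", "gene", "weight")])
}

#' Enumerate all unordered pathway pairs
#'
#' Emits each unordered pair of pathway ids once, lexicographically smaller
#' id first, in deterministic order. For `n` pathways this yields
#' `n * (n - 1) / 2` candidate pairs (84 pathways give 3486).
#'
#' @param db A pathway database tibble, or a character vector of pathway ids.
#' @return A tibble with columns `pair_id` (`"first|second"`), `first`,
#'   `second`.
#' @export
enumerate_pairs <- function(db) {
  ids <- if (is.character(db)) unique(db) else unique(db$pathway_id)
  ids <- sort(ids)
  n <- length(ids)
  if (n < 2) stop("need at least 2 pathways to form pairs")
  idx <- utils::combn(n, 2)
  tibble::tibble(
    pair_id = paste(ids[idx[1, ]], ids[idx[2, ]], sep = "|"),
    first = ids[idx[1, ]],
    second = ids[idx[2, ]]
  )
}

#' Summarise a pathway database as JSON
#'
#' @param db A pathway database tibble.
#' @param path Output JSON path.
#' @param source_tag Free-text provenance tag recorded in the summary.
#' @return `path`, invisibly.
#' @export
write_pathway_db_summary <- function(db, path, source_tag = "") {
  db <- validate_pathway_db(db)
  sizes <- db |>
    dplyr::count(.data$pathway_id, name = "n_genes") |>
    dplyr::arrange(.data$pathway_id)
  obj <- list(
    source_tag = source_tag,
    n_pathways = nrow(sizes),
    n_pairs = nrow(sizes) * (nrow(sizes) - 1) / 2,
    pathways = sizes
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
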