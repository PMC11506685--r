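#' Gene-coverage gate for pathway scoring
#'
#' A pathway is scored only when a sufficient fraction of its member genes
#' is expressed in the cohort. A gene counts as expressed when it is present
#' in the matrix and nonzero in at least `min_samples` samples.
#'
#' @param db Pathway database tibble.
#' @param expr Expression tibble ([as_expression()]).
#' @param min_fraction Minimum expressed fraction, inclusive (default 0.30:
#'   a 10-gene pathway with exactly 3 expressed genes is scored).
#' @param min_samples Minimum number of samples in which a gene must be
#'   nonzero to count as expressed (default 1).
#' @return A tibble `pathway_id`, `n_genes`, `n_expressed`, `coverage`,
#'   `scored`, one row per pathway, class `"mp_coverage"`.
#' @export
coverage_gate <- function(db, expr, min_fraction = 0.30, min_samples = 1) {
  db <- validate_pathway_db(db)
  expr <- as_expression(expr)
  if (!(min_fraction > 0 && min_fraction <= 1)) {
    stop("`min_fraction` must be in (0, 1]")
  }
  m <- expr_matrix(expr)
  if (nrow(m) == 0 || ncol(m) == 0) stop("empty expression matrix")
  nz <- rowSums(m != 0)
  expressed_genes <- rownames(m)[nz >= min_samples]
  out <- db |>
    dplyr::group_by(.data$pathway_id) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      n_expressed = sum(.data$gene %in% expressed_genes),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      coverage = .data$n_expressed / .data$n_genes,
      scored = .data$coverage >= min_fraction
    ) |>
    dplyr::arrange(.data$pathway_id)
  attr(out, "min_fraction") <- min_fraction
  attr(out, "min_samples") <- min_samples
  class(out) <- unique(c("mp_coverage", class(out)))
  out
}

#' PPI-weighted pathway activity scores
#'
#' For every pathway passing the coverage gate and every sample, the
#' activity score is the weighted mean of the expressed member genes'
#' log-scale expression:
#' \deqn{A_{P,s} = \sum_{g} w_g x_{g,s} / \sum_{g} w_g}
#' where `x = log2(v + 1)` for linear-scale input and the raw value for
#' log-scale input, and `w` are the (PPI-derived or uniform) gene weights.
#'
#' @param db Pathway database tibble (weights used as-is).
#' @param expr Expression tibble.
#' @param gate Optional precomputed [coverage_gate()] result for the same
#'   `db`/`expr`; computed with defaults when missing.
#' @return A wide tibble, class `"mp_activity"`: column `pathway_id`
#'   followed by one numeric column per sample, rows restricted to scored
#'   pathways; the gate tibble is attached as attribute `"gate"`.
#' @export
compute_activity <- function(db, expr, gate = NULL) {
  db <- validate_pathway_db(db)
  expr <- as_expression(expr)
  if (is.null(gate)) gate <- coverage_gate(db, expr)
  raw <- expr_matrix(expr)
  min_samples <- attr(gate, "min_samples") %||% 1
  expressed_genes <- rownames(raw)[rowSums(raw != 0) >= min_samples]
  m <- if (expr_scale(expr) == "linear") log2(raw + 1) else raw
  scored_ids <- gate$pathway_id[gate$scored]
  if (length(scored_ids) == 0) stop("no pathway passes the coverage gate")
  sub <- db[db$pathway_id %in% scored_ids & db$gene %in% expressed_genes, ]
  if (nrow(sub) == 0) stop("internal error: scored pathway with no expressed gene")
  # weighted mean via a sparse pathway-by-gene weight matrix
  pid <- factor(sub$pathway_id, levels = sort(scored_ids))
  gid <- factor(sub$gene, levels = rownames(m))
  W <- Matrix::sparseMatrix(i = as.integer(pid), j = as.integer(gid),
                            x = sub$weight,
                            dims = c(nlevels(pid), nrow(m)),
                            dimnames = list(levels(pid), rownames(m)))
  scores <- as.matrix(W %*% m) / as.numeric(Matrix::rowSums(W))
  out <- dplyr::bind_cols(tibble::tibble(pathway_id = rownames(scores)),
                          tibble::as_tibble(scores))
  attr(out, "gate") <- gate
  class(out) <- unique(c("mp_activity", class(out)))
  out
}

# internal: activity tibble -> pathway x sample matrix
activity_matrix <- function(act) {
  m <- as.matrix(act[-1])
  rownames(m) <- act$pathway_id
  m
}

#' Intra-sample pathway-pair dominance calls
#'
#' Reduces each pathway pair within each sample to a ternary call: `+1`
#' when the first pathway's activity exceeds the second's by more than
#' `tie_tol`, `-1` for the reverse, `0` for a tie. Because the comparison
#' is made entirely within one sample, any per-sample monotone rescaling of
#' all pathway scores (a sample-level batch effect) leaves every call
#' unchanged.
#'
#' @param act Activity tibble from [compute_activity()].
#' @param pairs Optional pair tibble ([enumerate_pairs()]); defaults to all
#'   pairs of scored pathways. Every referenced pathway must be scored.
#' @param tie_tol Absolute tie tolerance (default 1e-9).
#' @return A wide tibble, class `"mp_dominance"`: columns `pair_id`,
#'   `first`, `second`, then one integer column per sample.
#' @export
pairwise_dominance <- function(act, pairs = NULL, tie_tol = 1e-9) {
  stopifnot(inherits(act, "mp_activity") || is.data.frame(act))
  m <- activity_matrix(act)
  if (is.null(pairs)) pairs <- enumerate_pairs(rownames(m))
  missing <- setdiff(unique(c(pairs$first, pairs$second)), rownames(m))
  if (length(missing) > 0) {
    stop("pairs reference unscored pathways: ", paste(missing, collapse = ", "))
  }
  stopifnot(tie_tol >= 0)
  delta <- m[pairs$first, , drop = FALSE] - m[pairs$second, , drop = FALSE]
  calls <- sign(delta) * (abs(delta) > tie_tol)
  out <- dplyr::bind_cols(
    tibble::tibble(pair_id = pairs$pair_id, first = pairs$first,
                   second = pairs$second),
    tibble::as_tibble(matrix(as.integer(calls), nrow = nrow(calls),
                             dimnames = list(NULL, colnames(m))))
  )
  attr(out, "tie_tol") <- tie_tol
  class(out) <- unique(c("mp_dominance", class(out)))
  out
}

# internal: dominance tibble -> pair x sample integer matrix
dominance_matrix <- function(dom) {
  m <- as.matrix(dom[setdiff(names(dom), c("pair_id", "first", "second"))])
  rownames(m) <- dom$pair_id
  m
}

#' Export an activity or dominance tibble as TSV
#'
#' @param x An `"mp_activity"` or `"mp_dominance"` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(path)
}
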