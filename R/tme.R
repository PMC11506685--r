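#' Read immune (or any) signature gene sets
#'
#' Signatures use the same GMT format as pathways; weights are ignored.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (signature name -> genes).
#' @export
read_signatures <- function(path) {
  db <- read_gmt(path)
  split(db$gene, db$pathway_id)
}

#' Single-sample gene-set enrichment (ssGSEA) scores
#'
#' For each sample, genes are ranked by expression in descending order
#' (ties broken by gene id). Walking down the ranking, a running sum is
#' incremented at signature members by their rank weight
#' `r^alpha` (r = N at the top of the list down to 1), normalized over the
#' signature's members, and decremented by `1/(N - |S|)` at non-members;
#' the score is the sum of the running-sum deviations over all positions.
#' Being rank-based, scores are invariant to any strictly monotone
#' transform of a sample's expression vector.
#'
#' @param expr Expression tibble ([as_expression()]).
#' @param sigs Named list of gene sets, or a GMT path.
#' @param alpha Rank-weight exponent (default 0.25, the conventional
#'   ssGSEA choice).
#' @param rescale Linearly rescale the full score matrix to span \[0, 1\]
#'   (default TRUE).
#' @return A tibble: column `signature` then one numeric column per sample,
#'   class `"mp_ssgsea"`. Signatures with no gene present in the matrix are
#'   flagged `NA` across all samples.
#' @export
ssgsea_scores <- function(expr, sigs, alpha = 0.25, rescale = TRUE) {
  if (is.character(sigs) && length(sigs) == 1) sigs <- read_signatures(sigs)
  stopifnot(is.list(sigs), length(sigs) > 0)
  if (is.null(names(sigs)) || anyDuplicated(names(sigs))) {
    stop("signatures need unique names")
  }
  expr <- as_expression(expr)
  m <- expr_matrix(expr)
  genes <- rownames(m)
  n <- length(genes)
  present <- purrr::map(sigs, ~ intersect(unique(.x), genes))
  flagged <- lengths(present) == 0
  if (any(flagged)) {
    warning("signatures with no gene in the matrix flagged NA: ",
            paste(names(sigs)[flagged], collapse = ", "), call. = FALSE)
  }
  scores <- matrix(NA_real_, nrow = length(sigs), ncol = ncol(m),
                   dimnames = list(names(sigs), colnames(m)))
  rw <- (n:1)^alpha  # rank weight by descending-expression position
  # each step at position i persists in the running sum for (n - i + 1)
  # positions, so the deviation sum is a weighted dot product
  persist <- n:1
  for (s in seq_len(ncol(m))) {
    ord <- order(-m[, s], genes)
    ranked_genes <- genes[ord]
    for (k in seq_along(sigs)) {
      if (flagged[k]) next
      member <- ranked_genes %in% present[[k]]
      n_s <- sum(member)
      inc_norm <- sum(rw[member])
      step <- ifelse(member, rw / inc_norm, 0)
      if (n > n_s) step <- step - ifelse(member, 0, 1 / (n - n_s))
      scores[k, s] <- sum(step * persist)
    }
  }
  if (rescale) {
    rng <- range(scores, na.rm = TRUE)
    scores <- if (diff(rng) > 0) (scores - rng[1]) / diff(rng) else scores * 0
  }
  out <- dplyr::bind_cols(tibble::tibble(signature = rownames(scores)),
                          tibble::as_tibble(scores))
  class(out) <- unique(c("mp_ssgsea", class(out)))
  out
}

#' Observed/expected (Ro/e) cell-type enrichment by group
#'
#' Compares each cell type's observed count in each group with the count
#' expected under independence of type and group
#' (`row_total * col_total / grand_total`). A ratio above 1 marks
#' enrichment of that type in that group.
#'
#' @param cells A data frame with one row per cell and the type/group
#'   columns named below.
#' @param type_col,group_col Column names (defaults `"cell_type"`,
#'   `"group"`).
#' @return A long tibble of class `"mp_roe"`: `cell_type`, `group`,
#'   `observed`, `expected`, `roe`; the observed and expected matrices are
#'   attached as attributes.
#' @export
roe <- function(cells, type_col = "cell_type", group_col = "group") {
  cells <- tibble::as_tibble(cells)
  stopifnot(type_col %in% names(cells), group_col %in% names(cells))
  observed <- as.matrix(table(as.character(cells[[type_col]]),
                              as.character(cells[[group_col]])))
  roe_from_counts(observed)
}

#' Ro/e from an observed cell-type-by-group count matrix
#'
#' @param observed Nonnegative integer matrix, cell types in rows, groups
#'   in columns, with dimnames.
#' @return See [roe()].
#' @export
roe_from_counts <- function(observed) {
  observed <- as.matrix(observed)
  if (nrow(observed) < 2 || ncol(observed) < 2) {
    stop("need >= 2 cell types and >= 2 groups")
  }
  if (any(observed < 0) || sum(observed) == 0) stop("invalid count matrix")
  rt <- rowSums(observed); ct <- colSums(observed)
  if (any(rt == 0) || any(ct == 0)) {
    stop("every cell type and group needs a nonzero total")
  }
  expected <- outer(rt, ct) / sum(observed)
  values <- observed / expected
  out <- tibble::tibble(
    cell_type = rep(rownames(observed), times = ncol(observed)),
    group = rep(colnames(observed), each = nrow(observed)),
    observed = as.numeric(observed),
    expected = as.numeric(expected),
    roe = as.numeric(values)
  )
  attr(out, "observed") <- observed
  attr(out, "expected") <- expected
  class(out) <- unique(c("mp_roe", class(out)))
  out
}
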