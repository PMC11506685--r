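#' Per-cell QC metrics from a count matrix
#'
#' @param counts Gene-by-cell count matrix (sparse `dgCMatrix` or dense),
#'   nonnegative integers, with dimnames.
#' @param mito_genes Character vector of mitochondrial gene ids (may be
#'   empty).
#' @param ratio_mode `"log"` (default): gene-to-UMI ratio is the per-cell
#'   complexity score `log10(genes)/log10(UMIs)` (0 when either is <= 1);
#'   `"raw"`: plain `genes/UMIs`.
#' @return A tibble of class `"mp_qc"`, one row per cell: `cell_id`,
#'   `umi_count`, `gene_count`, `mito_pct`, `gene_umi_ratio`.
#' @export
compute_qc_metrics <- function(counts, mito_genes = character(),
                               ratio_mode = c("log", "raw")) {
  ratio_mode <- match.arg(ratio_mode)
  if (is.null(colnames(counts))) stop("counts need cell colnames")
  x <- if (inherits(counts, "sparseMatrix")) counts@x else as.numeric(counts)
  if (any(x < 0) || any(x != trunc(x))) {
    stop("counts must be nonnegative integers")
  }
  umi <- Matrix::colSums(counts)
  gene_count <- Matrix::colSums(counts != 0)
  mito <- intersect(mito_genes, rownames(counts))
  mito_sum <- if (length(mito) > 0) {
    Matrix::colSums(counts[mito, , drop = FALSE])
  } else rep(0, ncol(counts))
  mito_pct <- ifelse(umi > 0, 100 * mito_sum / umi, 0)
  ratio <- if (ratio_mode == "log") {
    ifelse(gene_count > 1 & umi > 1, log10(gene_count) / log10(umi), 0)
  } else {
    ifelse(umi > 0, gene_count / umi, 0)
  }
  out <- tibble::tibble(
    cell_id = colnames(counts),
    umi_count = as.numeric(umi),
    gene_count = as.numeric(gene_count),
    mito_pct = as.numeric(mito_pct),
    gene_umi_ratio = as.numeric(ratio)
  )
  attr(out, "ratio_mode") <- ratio_mode
  class(out) <- unique(c("mp_qc", class(out)))
  out
}

#' Default single-cell QC thresholds
#'
#' The five-rule filter: drop cells with fewer than 200 or more than
#' 20,000 UMIs, more than 4500 detected genes, mitochondrial percentage
#' above 10, or gene-to-UMI ratio below 0.8. All comparisons are strict,
#' so boundary cells (exactly 200 or 20,000 UMIs, 4500 genes, 10% mito,
#' ratio 0.8) are kept.
#'
#' @param umi_min,umi_max,genes_max,mito_max,ratio_min Rule thresholds.
#' @return A named list of thresholds.
#' @export
qc_thresholds <- function(umi_min = 200, umi_max = 20000, genes_max = 4500,
                          mito_max = 10, ratio_min = 0.8) {
  th <- list(umi_min = umi_min, umi_max = umi_max, genes_max = genes_max,
             mito_max = mito_max, ratio_min = ratio_min)
  if (any(unlist(th) <= 0)) stop("thresholds must be positive")
  if (th$umi_min >= th$umi_max) stop("umi_min must be below umi_max")
  th
}

#' Apply the five-rule QC filter to per-cell metrics
#'
#' A cell's verdict depends only on its own metrics. An optional doublet
#' flag column (from an external doublet caller) drops flagged cells after
#' the five rules.
#'
#' @param records Metrics tibble from [compute_qc_metrics()] (extra
#'   columns such as a doublet flag are carried through).
#' @param thresholds Threshold list from [qc_thresholds()].
#' @param doublet_col Optional name of a logical column marking doublets.
#' @return `records` with `failed_rules` (list-column of rule names among
#'   `umi_low`, `umi_high`, `genes_high`, `mito_high`, `ratio_low`,
#'   `doublet`) and `verdict` (`"keep"`/`"drop"`; drop iff any rule
#'   failed).
#' @export
apply_qc_filters <- function(records, thresholds = qc_thresholds(),
                             doublet_col = NULL) {
  records <- tibble::as_tibble(records)
  need <- c("cell_id", "umi_count", "gene_count", "mito_pct",
            "gene_umi_ratio")
  stopifnot(all(need %in% names(records)))
  th <- thresholds
  fails <- cbind(
    umi_low = records$umi_count < th$umi_min,
    umi_high = records$umi_count > th$umi_max,
    genes_high = records$gene_count > th$genes_max,
    mito_high = records$mito_pct > th$mito_max,
    ratio_low = records$gene_umi_ratio < th$ratio_min
  )
  if (!is.null(doublet_col)) {
    stopifnot(doublet_col %in% names(records))
    fails <- cbind(fails, doublet = isTRUE_vec(records[[doublet_col]]))
  }
  records$failed_rules <- apply(fails, 1, function(r) colnames(fails)[r],
                                simplify = FALSE)
  records$verdict <- ifelse(rowSums(fails) > 0, "drop", "keep")
  class(records) <- unique(c("mp_qc", class(records)))
  records
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Write a per-cell QC report as TSV
#'
#' @param records Filtered records from [apply_qc_filters()].
#' @param path Output path; `failed_rules` is serialised comma-separated.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(records, path) {
  out <- tibble::as_tibble(records)
  if (is.list(out$failed_rules)) {
    out$failed_rules <- purrr::map_chr(out$failed_rules, paste,
                                       collapse = ",")
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
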