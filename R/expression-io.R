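#' Read a dense expression matrix from TSV/CSV
#'
#' Genes in rows, first column gene ids, remaining columns one per sample.
#'
#' @param path Path to the table; delimiter inferred from the extension
#'   (`.csv` comma, otherwise tab).
#' @param scale Either `"linear"` (TPM/FPKM-like, nonnegative; log2(x+1) is
#'   applied during scoring) or `"log"` (already log-scale).
#' @return An expression tibble: column `gene` followed by one numeric
#'   column per sample, with attribute `scale_tag`.
#' @export
read_expression <- function(path, scale = c("linear", "log")) {
  scale <- match.arg(scale)
  stopifnot(file.exists(path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tb <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  names(tb)[1] <- "gene"
  as_expression(tb, scale = scale)
}

#' Coerce to a validated expression tibble
#'
#' @param x A data frame whose first column is the gene id (or a numeric
#'   matrix with gene rownames and sample colnames).
#' @param scale `"linear"` or `"log"`; defaults to an existing `scale_tag`
#'   attribute, else `"linear"`.
#' @return The expression tibble with attribute `scale_tag`.
#' @export
as_expression <- function(x, scale = NULL) {
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      stop("expression matrix needs gene rownames and sample colnames")
    }
    x <- dplyr::bind_cols(tibble::tibble(gene = rownames(x)),
                          tibble::as_tibble(x))
  }
  scale <- scale %||% attr(x, "scale_tag") %||% "linear"
  scale <- match.arg(scale, c("linear", "log"))
  tb <- tibble::as_tibble(x)
  names(tb)[1] <- "gene"
  tb$gene <- as.character(tb$gene)
  if (ncol(tb) < 2) stop("expression table has no sample columns")
  if (anyDuplicated(tb$gene)) stop("duplicate gene ids in expression table")
  if (anyDuplicated(names(tb))) stop("duplicate sample ids in expression table")
  vals <- as.matrix(tb[-1])
  if (!is.numeric(vals)) stop("sample columns must be numeric")
  if (scale == "linear" && any(vals < 0, na.rm = TRUE)) {
    stop("negative entries in a linear-scale expression matrix")
  }
  attr(tb, "scale_tag") <- scale
  tb
}

# internal: expression tibble -> numeric matrix (genes x samples)
expr_matrix <- function(expr) {
  m <- as.matrix(expr[-1])
  rownames(m) <- expr$gene
  m
}

# internal: scale_tag accessor with a safe default
expr_scale <- function(expr) attr(expr, "scale_tag") %||% "linear"

#' Read a sample metadata table
#'
#' @param path TSV with a mandatory `sample_id` column; `age` (years) and
#'   `group` are used downstream when present, other columns are carried as
#'   covariates.
#' @return A tibble.
#' @export
read_sample_metadata <- function(path) {
  stopifnot(file.exists(path))
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(tb)) stop("metadata needs a `sample_id` column")
  tb$sample_id <- as.character(tb$sample_id)
  if (anyDuplicated(tb$sample_id)) stop("duplicate sample_id in metadata")
  tb
}

#' Read sparse single-cell counts (MatrixMarket + sidecars)
#'
#' @param mtx Path to the MatrixMarket `.mtx` file (genes x cells).
#' @param features Path to a one-column (or first-column) gene id file.
#' @param barcodes Path to a one-column cell barcode file.
#' @return A sparse `dgCMatrix` with gene rownames and cell colnames.
#' @export
read_mtx_counts <- function(mtx, features, barcodes) {
  stopifnot(file.exists(mtx), file.exists(features), file.exists(barcodes))
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  feats <- utils::read.table(features, sep = "\t", header = FALSE,
                             colClasses = "character")[[1]]
  cells <- utils::read.table(barcodes, sep = "\t", header = FALSE,
                             colClasses = "character")[[1]]
  if (nrow(m) != length(feats) || ncol(m) != length(cells)) {
    stop("MTX dimensions do not match features/barcodes sidecars")
  }
  dimnames(m) <- list(feats, cells)
  m
}

#' Write sparse counts as MatrixMarket with sidecars
#'
#' @param counts A sparse or dense gene-by-cell matrix with dimnames.
#' @param dir Output directory (created if missing); writes `matrix.mtx`,
#'   `features.tsv`, `barcodes.tsv`.
#' @return `dir`, invisibly.
#' @export
write_mtx_counts <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Assign age groups to sample metadata
#'
#' Two modes mirror common cohort designs: `"quartile"` labels the lower
#' quartile of ages `young` (age <= Q1), the upper quartile `old`
#' (age >= Q3) and the rest `middle`; `"fixed"` uses two increasing
#' thresholds `(t1, t2)` and half-open intervals `[0, t1)` young,
#' `[t1, t2)` middle, `[t2, Inf)` old (so with thresholds (50, 65) an age
#' of exactly 50 is middle and 65 is old).
#'
#' @param meta Metadata tibble with an age column.
#' @param mode `"quartile"` or `"fixed"`.
#' @param thresholds Length-2 increasing numeric, required for fixed mode.
#' @param age_col Name of the age column (default `"age"`).
#' @return `meta` with a `group` factor column (`young` < `middle` < `old`).
#' @details Quartiles use linear interpolation between order statistics
#'   (type-7); samples exactly at a quartile fall in the extreme group.
#' @export
assign_age_groups <- function(meta, mode = c("quartile", "fixed"),
                              thresholds = NULL, age_col = "age") {
  mode <- match.arg(mode)
  meta <- tibble::as_tibble(meta)
  if (!age_col %in% names(meta)) stop("metadata lacks age column `", age_col, "`")
  age <- meta[[age_col]]
  if (any(is.na(age))) {
    bad <- meta$sample_id[is.na(age)]
    stop("missing ages for samples: ", paste(bad, collapse = ", "))
  }
  if (any(age < 0)) stop("negative ages")
  lv <- c("young", "middle", "old")
  if (mode == "quartile") {
    q <- stats::quantile(age, c(0.25, 0.75), type = 7, names = FALSE)
    grp <- ifelse(age <= q[1], "young", ifelse(age >= q[2], "old", "middle"))
  } else {
    if (is.null(thresholds) || length(thresholds) != 2 ||
        !is.numeric(thresholds) || diff(thresholds) <= 0) {
      stop("fixed mode needs two increasing numeric `thresholds`")
    }
    grp <- ifelse(age < thresholds[1], "young",
                  ifelse(age < thresholds[2], "middle", "old"))
  }
  meta$group <- factor(grp, levels = lv)
  meta
}

`%||%` <- function(a, b) if (is.null(a)) b else a
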