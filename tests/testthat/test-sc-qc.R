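counts_from_cells <- function(cells) {
  # cells: named list cell_id -> named integer vector of gene counts
  genes <- sort(unique(unlist(lapply(cells, names))))
  m <- sapply(cells, function(v) {
    out <- stats::setNames(rep(0, length(genes)), genes)
    out[names(v)] <- v
    out
  })
  Matrix::Matrix(m, sparse = TRUE)
}

test_that("per-cell metrics follow their definitions", {
  counts <- counts_from_cells(list(
    c1 = c(G1 = 3, G2 = 2),
    c2 = c(MT1 = 1, G1 = 9)
  ))
  rec <- compute_qc_metrics(counts, mito_genes = "MT1")
  expect_equal(rec$umi_count, c(5, 10))
  expect_equal(rec$gene_count, c(2, 2))
  expect_equal(rec$mito_pct, c(0, 10))

  big <- counts_from_cells(list(
    c1 = stats::setNames(c(rep(5, 1000)), paste0("g", 1:1000))))
  big@x <- big@x  # 1000 genes x 5 = 5000 umi
  r2 <- compute_qc_metrics(big)
  expect_equal(r2$gene_umi_ratio, log10(1000) / log10(5000),
               tolerance = 1e-12)
  expect_error(compute_qc_metrics(counts / 2), "integer")
})

test_that("raw ratio mode is available behind the same surface", {
  counts <- counts_from_cells(list(c1 = c(G1 = 4, G2 = 1)))
  r <- compute_qc_metrics(counts, ratio_mode = "raw")
  expect_equal(r$gene_umi_ratio, 2 / 5)
})

test_that("the five rules drop strictly past their thresholds", {
  rec <- tibble::tibble(
    cell_id = paste0("c", 1:7),
    umi_count = c(150, 200, 20000, 20001, 5000, 5000, 5000),
    gene_count = c(100, 180, 4500, 4000, 4501, 4000, 3000),
    mito_pct = c(0, 5, 10, 5, 5, 10.5, 2),
    gene_umi_ratio = c(0.95, 0.98, 0.9, 0.9, 0.95, 0.9, 0.79)
  )
  out <- apply_qc_filters(rec)
  expect_equal(out$verdict,
               c("drop", "keep", "keep", "drop", "drop", "drop", "drop"))
  expect_equal(out$failed_rules[[1]], "umi_low")
  expect_equal(out$failed_rules[[4]], "umi_high")
  expect_equal(out$failed_rules[[5]], "genes_high")
  expect_equal(out$failed_rules[[6]], "mito_high")
  expect_equal(out$failed_rules[[7]], "ratio_low")
  expect_equal(out$failed_rules[[2]], character(0))
})

test_that("verdict is drop iff some rule failed", {
  set.seed(5)
  rec <- tibble::tibble(
    cell_id = paste0("c", 1:200),
    umi_count = round(runif(200, 0, 30000)),
    gene_count = round(runif(200, 0, 6000)),
    mito_pct = runif(200, 0, 30),
    gene_umi_ratio = runif(200, 0.5, 1)
  )
  rec$gene_count <- pmin(rec$gene_count, rec$umi_count)
  out <- apply_qc_filters(rec)
  expect_equal(out$verdict == "drop", lengths(out$failed_rules) > 0)
})

test_that("tightening any threshold never converts a drop to a keep", {
  set.seed(6)
  rec <- tibble::tibble(
    cell_id = paste0("c", 1:300),
    umi_count = round(exp(runif(300, 4, 10.5))),
    gene_count = round(exp(runif(300, 3, 8.6))),
    mito_pct = runif(300, 0, 15),
    gene_umi_ratio = runif(300, 0.6, 1)
  )
  rec$gene_count <- pmin(rec$gene_count, rec$umi_count)
  base <- apply_qc_filters(rec)
  tighter <- list(
    qc_thresholds(umi_min = 400), qc_thresholds(umi_max = 10000),
    qc_thresholds(genes_max = 3000), qc_thresholds(mito_max = 5),
    qc_thresholds(ratio_min = 0.9)
  )
  for (th in tighter) {
    out <- apply_qc_filters(rec, th)
    expect_true(all(out$verdict[base$verdict == "drop"] == "drop"))
  }
})

test_that("verdicts are order-independent", {
  set.seed(7)
  rec <- tibble::tibble(
    cell_id = paste0("c", 1:50),
    umi_count = round(runif(50, 100, 25000)),
    gene_count = round(runif(50, 50, 5000)),
    mito_pct = runif(50, 0, 15),
    gene_umi_ratio = runif(50, 0.6, 1)
  )
  rec$gene_count <- pmin(rec$gene_count, rec$umi_count)
  out <- apply_qc_filters(rec)
  perm <- sample(50)
  out_perm <- apply_qc_filters(rec[perm, ])
  expect_equal(out_perm$verdict, out$verdict[perm])
})

test_that("the doublet hook drops flagged cells after the five rules", {
  rec <- tibble::tibble(
    cell_id = c("a", "b"), umi_count = c(5000, 5000),
    gene_count = c(2000, 2000), mito_pct = c(1, 1),
    gene_umi_ratio = c(0.9, 0.9), is_doublet = c(FALSE, TRUE))
  out <- apply_qc_filters(rec, doublet_col = "is_doublet")
  expect_equal(out$verdict, c("keep", "drop"))
  expect_equal(out$failed_rules[[2]], "doublet")
})

test_that("planted violators are recovered exactly on a small cohort", {
  sc <- simulate_sc_cohort(cells_per_group = 300,
                           qc_violation_fraction = c(umi_low = 0.02,
                                                     mito_high = 0.02,
                                                     ratio_low = 0.02),
                           seed = 19)
  rec <- apply_qc_filters(compute_qc_metrics(sc$counts, sc$mito_genes))
  dropped <- rec$cell_id[rec$verdict == "drop"]
  expect_setequal(dropped, sc$truth$cell_id)
  # each violator failed exactly its planted rule
  planted <- sc$truth$planted_rule
  names(planted) <- sc$truth$cell_id
  for (cid in sc$truth$cell_id) {
    expect_equal(rec$failed_rules[[which(rec$cell_id == cid)]],
                 unname(planted[cid]))
  }
  report <- withr::local_tempfile(fileext = ".tsv")
  write_qc_report(rec, report)
  back <- readr::read_tsv(report, show_col_types = FALSE)
  expect_equal(sum(back$verdict == "drop"), length(dropped))
})
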