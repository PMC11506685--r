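test_that("generators are pure functions of their seed", {
  ps <- plant_switches(2, 10, 1)
  s1 <- simulate_bulk_cohort(n_pathways = 10, genes_per_pathway = 5,
                             n_young = 8, n_old = 8,
                             planted_switches = ps, seed = 4)
  s2 <- simulate_bulk_cohort(n_pathways = 10, genes_per_pathway = 5,
                             n_young = 8, n_old = 8,
                             planted_switches = ps, seed = 4)
  expect_identical(s1$expr, s2$expr)
  expect_identical(s1$meta, s2$meta)
  s3 <- simulate_bulk_cohort(n_pathways = 10, genes_per_pathway = 5,
                             n_young = 8, n_old = 8,
                             planted_switches = ps, seed = 5)
  expect_false(identical(s1$expr, s3$expr))

  c1 <- simulate_sc_cohort(cells_per_group = 100, n_genes = 1000,
                           n_mito = 5, seed = 2)
  c2 <- simulate_sc_cohort(cells_per_group = 100, n_genes = 1000,
                           n_mito = 5, seed = 2)
  expect_identical(as.matrix(c1$counts), as.matrix(c2$counts))
})

test_that("invalid configurations fail before any sampling", {
  expect_error(simulate_bulk_cohort(), "mandatory")
  expect_error(simulate_bulk_cohort(
    planted_switches = tibble::tibble(first = "P001", second = "P001",
                                      delta = 1), seed = 1), "repeats")
  expect_error(simulate_bulk_cohort(
    planted_switches = tibble::tibble(first = "P001", second = "NOPE",
                                      delta = 1), seed = 1), "unknown")
  expect_error(simulate_sc_cohort(), "mandatory")
  expect_error(simulate_sc_cohort(
    freqs = tibble::tibble(cell_type = c("A", "B"), group = "g",
                           freq = c(0.5, 0.6)), seed = 1), "sum to 1")
  expect_error(simulate_sc_cohort(
    qc_violation_fraction = c(genes_high = 0.01), n_genes = 2000, seed = 1),
    "9100")
})

test_that("age bands make quartile grouping consistent with the truth", {
  sim <- simulate_bulk_cohort(n_pathways = 4, genes_per_pathway = 5,
                              n_young = 20, n_old = 20, seed = 12)
  relabelled <- assign_age_groups(sim$meta[c("sample_id", "age")],
                                  mode = "quartile")
  agree <- relabelled$group != "middle"
  expect_true(all(as.character(relabelled$group[agree]) ==
                    as.character(sim$meta$group[agree])))
})

test_that("a null cohort leaves pair dominance balanced in expectation", {
  sim <- simulate_bulk_cohort(n_pathways = 2, genes_per_pathway = 10,
                              n_young = 150, n_old = 150,
                              baseline_mean_range = c(5, 5), seed = 8)
  act <- compute_activity(sim$db, sim$expr)
  dom <- pairwise_dominance(act)
  calls <- as.integer(dom[1, -(1:3)])
  young <- sim$meta$group == "young"
  expect_lt(abs(mean(calls[young] == 1) - mean(calls[!young] == 1)), 0.2)
})

test_that("a large planted effect yields a near-diagonal table and OR >> 1", {
  sim <- simulate_bulk_cohort(n_pathways = 4, genes_per_pathway = 10,
                              n_young = 30, n_old = 30,
                              planted_switches = tibble::tibble(
                                first = "P001", second = "P002", delta = 3),
                              gene_noise_sd = 0.1,
                              baseline_mean_range = c(5, 5), seed = 21)
  act <- compute_activity(sim$db, sim$expr)
  dom <- pairwise_dominance(act)
  tab <- build_contingency(dom, sim$meta, "P001|P002")
  expect_gt(tab$counts["young", "first"], 27)
  expect_gt(tab$counts["old", "second"], 27)
  r <- test_switch(tab)
  expect_gt(r$odds_ratio, 50)
  expect_equal(r$direction, sim$truth$direction[1])
})

test_that("simulated covariates hit the requested correlation", {
  sim <- simulate_bulk_cohort(n_pathways = 4, genes_per_pathway = 10,
                              n_young = 50, n_old = 50, seed = 3)
  act <- compute_activity(sim$db, sim$expr)
  check_r <- function(target) {
    cv <- simulate_age_covariate(act, "P001|P002", target, seed = 5)
    meta <- dplyr::left_join(sim$meta, cv, by = "sample_id")
    pair_covariate_association(act, "P001|P002", meta, "covariate")$pearson_r
  }
  expect_equal(check_r(1), 1, tolerance = 1e-9)
  expect_lt(abs(check_r(0)), 0.2)
  r47 <- check_r(-0.47)
  expect_gte(r47, -0.57)
  expect_lte(r47, -0.37)
})

test_that("zero violation fraction keeps every simulated cell", {
  sc <- simulate_sc_cohort(cells_per_group = 250, seed = 6)
  rec <- apply_qc_filters(compute_qc_metrics(sc$counts, sc$mito_genes))
  expect_true(all(rec$verdict == "keep"))
  expect_equal(nrow(sc$truth), 0)
})

test_that("composition shifts surface as Ro/e enrichment", {
  fr <- tibble::tibble(
    cell_type = rep(c("T", "M", "O"), each = 2),
    group = rep(c("young", "old"), 3),
    freq = c(0.2, 0.6, 0.4, 0.2, 0.4, 0.2))
  sc <- simulate_sc_cohort(cell_types = c("T", "M", "O"), freqs = fr,
                           cells_per_group = 2000, seed = 13)
  r <- roe(sc$cells)
  expect_gt(r$roe[r$cell_type == "T" & r$group == "old"], 1)
  expect_lt(r$roe[r$cell_type == "T" & r$group == "young"], 1)
  expect_equal(unname(sc$composition["T", "old"]), 1200)
})
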