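test_that("contingency tables tally non-tie calls by group", {
  dom <- structure(
    tibble::tibble(pair_id = "A|B", first = "A", second = "B",
                   S1 = 1L, S2 = 1L, S3 = -1L, S4 = -1L, S5 = -1L, S6 = 1L),
    class = c("mp_dominance", class(tibble::tibble())))
  meta <- tibble::tibble(sample_id = paste0("S", 1:6),
                         group = rep(c("young", "old"), each = 3))
  tab <- build_contingency(dom, meta, "A|B")
  expect_equal(unname(tab$counts), matrix(c(2, 1, 1, 2), 2))
  expect_equal(tab$n_ties_excluded, 0)

  dom$S2 <- 0L
  tab2 <- build_contingency(dom, meta, "A|B")
  expect_equal(tab2$n_ties_excluded, 1)
  expect_equal(sum(tab2$counts), 5)
})

test_that("three-group contingency tables keep the group order", {
  dom <- structure(
    tibble::tibble(pair_id = "A|B", first = "A", second = "B",
                   S1 = 1L, S2 = -1L, S3 = 1L, S4 = -1L, S5 = 1L, S6 = -1L),
    class = c("mp_dominance", class(tibble::tibble())))
  meta <- tibble::tibble(sample_id = paste0("S", 1:6),
                         group = rep(c("young", "middle", "old"), each = 2))
  tab <- build_contingency(dom, meta, "A|B",
                           groups = c("young", "middle", "old"))
  expect_equal(dim(tab$counts), c(3L, 2L))
  expect_equal(rownames(tab$counts), c("young", "middle", "old"))
  expect_false(tab$degenerate)
})

test_that("balanced tables give a null result and crossed tables OR = 9", {
  r0 <- test_switch(toy_contingency(c(25, 25, 25, 25)))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_equal(r0$odds_ratio, 1)
  expect_equal(r0$direction, "none")
  expect_equal(r0$test_used, "chi_square")

  r9 <- test_switch(toy_contingency(c(30, 10, 10, 30)))
  expect_equal(r9$odds_ratio, 9)
  expect_equal(r9$test_used, "chi_square")
  expect_equal(r9$direction, "toward_second")
})

test_that("small tables take the Fisher path with Haldane-corrected OR", {
  r <- test_switch(toy_contingency(c(3, 0, 0, 3)))
  expect_equal(r$test_used, "fisher_exact")
  expect_equal(r$odds_ratio, (3.5 * 3.5) / (0.5 * 0.5))  # 49
  expect_equal(r$p_value, fisher2x2_oracle(matrix(c(3, 0, 0, 3), 2)),
               tolerance = 1e-12)
})

test_that("degenerate tables return p = 1 with no direction", {
  r <- test_switch(toy_contingency(c(0, 0, 10, 5)))  # empty young row
  expect_true(r$degenerate)
  expect_equal(r$p_value, 1)
  expect_equal(r$direction, "none")
})

test_that("swapping group rows keeps p, inverts OR and flips direction", {
  set.seed(42)
  for (i in 1:50) {
    cnt <- matrix(rpois(4, 15) + 1, 2)
    t1 <- test_switch(toy_contingency(cnt))
    t2 <- test_switch(toy_contingency(cnt[2:1, ]))
    expect_equal(t1$p_value, t2$p_value, tolerance = 1e-12)
    expect_equal(t1$odds_ratio, 1 / t2$odds_ratio, tolerance = 1e-12)
    if (t1$direction != "none") expect_true(t1$direction != t2$direction)
  }
})

test_that("chi-square, Fisher, OR and BH match brute-force oracles", {
  set.seed(7)
  for (i in 1:120) {
    cnt <- matrix(rpois(4, sample(c(2, 8, 30), 1)), 2)
    if (any(rowSums(cnt) == 0) || any(colSums(cnt) == 0)) next
    r <- test_switch(toy_contingency(cnt))
    expect_equal(r$odds_ratio, or_oracle(cnt), tolerance = 1e-12)
    exp_cnt <- outer(rowSums(cnt), colSums(cnt)) / sum(cnt)
    if (all(exp_cnt >= 5)) {
      o <- chisq_oracle(cnt)
      expect_equal(r$statistic, o$statistic, tolerance = 1e-12)
      expect_equal(r$p_value, o$p, tolerance = 1e-12)
    } else {
      expect_equal(r$p_value, fisher2x2_oracle(cnt), tolerance = 1e-9)
    }
  }
  for (i in 1:120) {
    p <- runif(sample(1:40, 1))
    expect_equal(stats::p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("Fisher converges to chi-square as table counts grow", {
  set.seed(3)
  # at moderate counts the exact test is visibly conservative ...
  mid <- replicate(40, {
    cnt <- matrix(50 + rpois(4, 40), 2)
    abs(chisq_oracle(cnt)$p - stats::fisher.test(cnt)$p.value)
  })
  expect_lt(max(mid), 0.15)
  # ... and the discreteness gap closes for large balanced tables
  for (i in 1:25) {
    cnt <- matrix(5000 + rpois(4, 1500), 2)
    expect_lt(abs(chisq_oracle(cnt)$p - stats::fisher.test(cnt)$p.value),
              0.01)
  }
})

test_that("BH adjustment reproduces the step-up worked examples", {
  r <- tibble::tibble(p_value = c(0.01, 0.02, 0.03))
  expect_equal(adjust_pvalues(r)$adjusted_p, rep(0.03, 3))
  expect_equal(adjust_pvalues(tibble::tibble(p_value = 0.04))$adjusted_p, 0.04)
  expect_equal(adjust_pvalues(tibble::tibble(p_value = rep(1, 5)))$adjusted_p,
               rep(1, 5))
  expect_true(all(adjust_pvalues(r)$adjusted_p >= r$p_value))
})

test_that("significance filtering is strict and deterministically ordered", {
  r <- tibble::tibble(pair_id = c("B|C", "A|B", "A|C"),
                      p_value = c(0.01, 0.01, 0.9),
                      adjusted_p = c(0.049, 0.049, 0.05))
  out <- significant_switches(r)
  expect_equal(out$pair_id, c("A|B", "B|C"))  # 0.05 dropped, ties by id
  expect_equal(nrow(significant_switches(r[0, ])), 0)
})

test_that("vectorised scan equals the per-pair route", {
  sim <- simulate_bulk_cohort(n_pathways = 8, genes_per_pathway = 5,
                              n_young = 12, n_old = 12,
                              planted_switches = plant_switches(2, 8, 1.5),
                              seed = 31)
  act <- compute_activity(sim$db, sim$expr)
  dom <- pairwise_dominance(act)
  fast <- detect_switches(dom, sim$meta, adjust = FALSE)
  slow <- purrr::map(dom$pair_id, function(pid) {
    test_switch(build_contingency(dom, sim$meta, pid))
  }) |> dplyr::bind_rows() |> dplyr::arrange(pair_id)
  expect_equal(fast$p_value, slow$p_value, tolerance = 1e-12)
  expect_equal(fast$odds_ratio, slow$odds_ratio, tolerance = 1e-12)
  expect_equal(fast$test_used, slow$test_used)
  expect_equal(fast$direction, slow$direction)
  expect_equal(fast$n_ties_excluded, slow$n_ties_excluded)
})

test_that("r x 2 small-count tables need a seed and are reproducible", {
  tab <- toy_contingency(c(4, 1, 2, 3, 1, 4),
                         groups = c("young", "middle", "old"))
  expect_error(test_switch(tab), "perm_seed")
  r1 <- test_switch(tab, perm_seed = 11)
  r2 <- test_switch(tab, perm_seed = 11)
  expect_equal(r1$test_used, "permutation")
  expect_equal(r1$p_value, r2$p_value)
})

test_that("pair-covariate association matches the Pearson oracle", {
  act <- structure(tibble::tibble(pathway_id = c("A", "B"),
                                  S1 = c(2, 1), S2 = c(3, 1),
                                  S3 = c(4, 1), S4 = c(5, 1)),
                   class = c("mp_activity", class(tibble::tibble())))
  meta <- tibble::tibble(sample_id = paste0("S", 1:4),
                         cov_up = c(1, 2, 3, 4), cov_dn = c(4, 3, 2, 1),
                         cov_const = rep(2, 4))
  up <- pair_covariate_association(act, "A|B", meta, "cov_up")
  expect_equal(up$pearson_r, 1)
  dn <- pair_covariate_association(act, "A|B", meta, "cov_dn")
  expect_equal(dn$pearson_r, -1)
  cst <- pair_covariate_association(act, "A|B", meta, "cov_const")
  expect_true(cst$degenerate)
  expect_true(is.na(cst$pearson_r))
  expect_equal(cst$p_value, 1)

  set.seed(8)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    o <- pearson_oracle(x, y)
    ct <- stats::cor.test(x, y)
    expect_equal(unname(ct$estimate), o$r, tolerance = 1e-12)
    expect_equal(ct$p.value, o$p, tolerance = 1e-12)
  }
})

test_that("single-pathway group contrast reports old-minus-young shifts", {
  act <- structure(tibble::tibble(pathway_id = c("A", "B"),
                                  S1 = c(1, 5), S2 = c(2, 6), S3 = c(3, 7),
                                  S4 = c(11, 5), S5 = c(12, 6), S6 = c(13, 7)),
                   class = c("mp_activity", class(tibble::tibble())))
  meta <- tibble::tibble(sample_id = paste0("S", 1:6),
                         group = rep(c("young", "old"), each = 3))
  r <- pathway_group_test(act, meta)
  expect_equal(r$mean_diff[r$pathway_id == "A"], 10)
  expect_equal(r$mean_diff[r$pathway_id == "B"], 0)
  expect_equal(r$p_value[r$pathway_id == "B"], 1)
  expect_error(pathway_group_test(act, meta[-(1:2), ]), "at least 2")
})

test_that("a planted single-pathway shift is detected across seeds", {
  hits <- vapply(1:20, function(s) {
    sim <- simulate_bulk_cohort(n_pathways = 4, genes_per_pathway = 20,
                                n_young = 30, n_old = 30, seed = 1000 + s)
    act <- compute_activity(sim$db, sim$expr)
    # shift pathway P001 by delta = 1 in the old group at the score level
    old <- sim$meta$sample_id[sim$meta$group == "old"]
    act[act$pathway_id == "P001", old] <-
      act[act$pathway_id == "P001", old] + 1
    r <- pathway_group_test(act, sim$meta)
    r$adjusted_p[r$pathway_id == "P001"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
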