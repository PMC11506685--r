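#' Group-by-dominance contingency table for one pathway pair
#'
#' Tallies non-tie dominance calls of one pair by sample group. Rows follow
#' the order of `groups` (youngest first); columns are first-dominant,
#' second-dominant. Tie calls carry no dominance information and are
#' excluded (counted in `n_ties_excluded`).
#'
#' @param dom Dominance tibble from [pairwise_dominance()].
#' @param meta Metadata with `sample_id` and `group`.
#' @param pair_id The pair to tabulate (`"first|second"`).
#' @param groups Group labels to include, ordered young to old; samples in
#'   other groups (e.g. `middle`) are excluded. Default `c("young", "old")`.
#' @return An object of class `"mp_contingency"`: a list with `counts`
#'   (group x {first, second} integer matrix), `pair_id`, `first`,
#'   `second`, `n_ties_excluded`, and `degenerate` (TRUE when some group
#'   has no non-tie sample).
#' @export
build_contingency <- function(dom, meta, pair_id,
                              groups = c("young", "old")) {
  stopifnot(length(pair_id) == 1)
  row <- dom[dom$pair_id == pair_id, , drop = FALSE]
  if (nrow(row) != 1) stop("pair not found in dominance table: ", pair_id)
  meta <- tibble::as_tibble(meta)
  if (!"group" %in% names(meta)) stop("metadata lacks a `group` column")
  if (any(is.na(meta$group))) stop("samples with missing group label")
  sample_cols <- setdiff(names(dom), c("pair_id", "first", "second"))
  meta <- meta[meta$sample_id %in% sample_cols &
                 as.character(meta$group) %in% groups, ]
  calls <- as.integer(row[1, meta$sample_id])
  grp <- factor(as.character(meta$group), levels = groups)
  counts <- matrix(0L, nrow = length(groups), ncol = 2,
                   dimnames = list(groups, c("first", "second")))
  keep <- calls != 0L
  tab <- table(grp[keep], factor(calls[keep], levels = c(1L, -1L)))
  counts[rownames(tab), ] <- as.integer(tab)
  structure(list(
    counts = counts,
    pair_id = pair_id, first = row$first[1], second = row$second[1],
    n_ties_excluded = sum(!keep),
    degenerate = any(rowSums(counts) == 0) || any(colSums(counts) == 0)
  ), class = "mp_contingency")
}

#' @export
print.mp_contingency <- function(x, ...) {
  cat("Pair ", x$pair_id, " (", x$first, " vs ", x$second, ")\n", sep = "")
  print(x$counts)
  cat("ties excluded:", x$n_ties_excluded,
      if (x$degenerate) " [degenerate]" else "", "\n")
  invisible(x)
}

# internal: odds ratio + direction from the young/old margin of a counts
# matrix (first and last rows). Haldane-Anscombe +0.5 when any cell is 0.
# Direction names the pathway gaining dominance in the OLD group.
or_direction <- function(counts) {
  yo <- counts[c(1, nrow(counts)), , drop = FALSE]
  a <- yo[1, 1]; b <- yo[1, 2]; c <- yo[2, 1]; d <- yo[2, 2]
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (b * c)
  direction <- if (or > 1) "toward_second" else if (or < 1) "toward_first" else "none"
  list(odds_ratio = or, direction = direction)
}

#' Test one pair's contingency table for a metabolic switch
#'
#' Chooses the test the table supports: the chi-square test of independence
#' (no continuity correction) when every expected count is at least
#' `min_expected`; otherwise Fisher's exact test for 2x2 tables, or a seeded
#' Monte-Carlo permutation p-value for r x 2 tables with r > 2.
#'
#' The odds ratio is the cross-product `(a d)/(b c)` of the young/old
#' margin (rows ordered young to old, columns first-/second-dominant), with
#' the Haldane-Anscombe +0.5 correction applied to all four cells when any
#' cell is zero. Since `OR = odds(first | young) / odds(first | old)`, an
#' OR above 1 means first-dominance is depleted with age, i.e. the switch
#' runs `toward_second`; below 1, `toward_first`.
#'
#' @param tab An `"mp_contingency"` object.
#' @param min_expected Minimum expected count for the chi-square path
#'   (default 5).
#' @param n_perm Monte-Carlo permutations for r x 2 small-count tables
#'   (default 10000).
#' @param perm_seed Integer seed, required whenever the permutation path is
#'   taken.
#' @return A one-row tibble: `pair_id`, `first`, `second`, `test_used`,
#'   `statistic`, `p_value`, `odds_ratio`, `direction`, `degenerate`,
#'   `n_used`, `n_ties_excluded`. Degenerate tables (an empty group or an
#'   empty dominance column) return `p_value = 1` and `direction = "none"`.
#' @export
test_switch <- function(tab, min_expected = 5, n_perm = 10000,
                        perm_seed = NULL) {
  stopifnot(inherits(tab, "mp_contingency"))
  counts <- tab$counts
  n <- sum(counts)
  od <- or_direction(counts)
  if (tab$degenerate || n == 0) {
    return(switch_result_row(tab, "chi_square", 0, 1, od$odds_ratio, "none"))
  }
  expected <- outer(rowSums(counts), colSums(counts)) / n
  if (all(expected >= min_expected)) {
    ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
    return(switch_result_row(tab, "chi_square",
                             unname(ct$statistic), ct$p.value,
                             od$odds_ratio, od$direction))
  }
  if (nrow(counts) == 2) {
    ft <- stats::fisher.test(counts)
    return(switch_result_row(tab, "fisher_exact", NA_real_, ft$p.value,
                             od$odds_ratio, od$direction))
  }
  if (is.null(perm_seed)) {
    stop("`perm_seed` is required for the Monte-Carlo permutation test")
  }
  ct <- withr_seed(perm_seed, suppressWarnings(
    stats::chisq.test(counts, simulate.p.value = TRUE, B = n_perm)))
  switch_result_row(tab, "permutation", unname(ct$statistic), ct$p.value,
                    od$odds_ratio, od$direction)
}

# internal: run expr under a local RNG seed without touching the caller's
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

switch_result_row <- function(tab, test_used, statistic, p_value,
                              odds_ratio, direction) {
  tibble::tibble(
    pair_id = tab$pair_id, first = tab$first, second = tab$second,
    test_used = test_used, statistic = statistic,
    p_value = p_value, odds_ratio = odds_ratio, direction = direction,
    degenerate = tab$degenerate, n_used = sum(tab$counts),
    n_ties_excluded = tab$n_ties_excluded
  )
}

#' Detect metabolic switches across all pathway pairs
#'
#' Builds every pair's group-by-dominance table, runs [test_switch()] on
#' each (with a vectorised fast path for the two-group chi-square case) and
#' applies Benjamini-Hochberg adjustment across all pairs of the cohort.
#'
#' @inheritParams build_contingency
#' @inheritParams test_switch
#' @param adjust Apply BH adjustment (default TRUE).
#' @return A tibble of class `"mp_switches"`, one row per pair, columns as
#'   in [test_switch()] plus `adjusted_p`, ordered by `pair_id`.
#' @export
detect_switches <- function(dom, meta, groups = c("young", "old"),
                            min_expected = 5, n_perm = 10000,
                            perm_seed = NULL, adjust = TRUE) {
  meta <- tibble::as_tibble(meta)
  if (!"group" %in% names(meta)) stop("metadata lacks a `group` column")
  sample_cols <- setdiff(names(dom), c("pair_id", "first", "second"))
  meta <- meta[meta$sample_id %in% sample_cols &
                 as.character(meta$group) %in% groups, ]
  if (nrow(meta) == 0) stop("no samples in the requested groups")
  M <- dominance_matrix(dom)[, meta$sample_id, drop = FALSE]
  grp <- factor(as.character(meta$group), levels = groups)

  if (length(groups) == 2) {
    res <- detect_switches_2g(dom, M, grp, min_expected)
  } else {
    res <- purrr::map(dom$pair_id, function(pid) {
      test_switch(build_contingency(dom, meta, pid, groups),
                  min_expected = min_expected, n_perm = n_perm,
                  perm_seed = perm_seed)
    }) |> dplyr::bind_rows()
  }
  res <- dplyr::arrange(res, .data$pair_id)
  if (adjust) res <- adjust_pvalues(res)
  class(res) <- unique(c("mp_switches", class(res)))
  res
}

# vectorised two-group path; must agree exactly with test_switch()
detect_switches_2g <- function(dom, M, grp, min_expected) {
  y <- M[, grp == levels(grp)[1], drop = FALSE]
  o <- M[, grp == levels(grp)[2], drop = FALSE]
  a <- unname(rowSums(y == 1L)); b <- unname(rowSums(y == -1L))
  c_ <- unname(rowSums(o == 1L)); d <- unname(rowSums(o == -1L))
  ties <- unname(rowSums(M == 0L))
  n <- a + b + c_ + d
  degen <- (a + b == 0) | (c_ + d == 0) | (a + c_ == 0) | (b + d == 0)
  # Haldane-Anscombe corrected cross-product odds ratio
  zero <- (a == 0) | (b == 0) | (c_ == 0) | (d == 0)
  h <- ifelse(zero, 0.5, 0)
  or <- ((a + h) * (d + h)) / ((b + h) * (c_ + h))
  direction <- ifelse(degen | or == 1, "none",
                      ifelse(or > 1, "toward_second", "toward_first"))
  # expected counts and test routing
  e_min <- pmin(
    (a + b) * (a + c_), (a + b) * (b + d),
    (c_ + d) * (a + c_), (c_ + d) * (b + d)
  ) / ifelse(n > 0, n, 1)
  chi_path <- !degen & e_min >= min_expected
  stat <- rep(NA_real_, length(a))
  p <- rep(1, length(a))
  stat[degen] <- 0
  # closed-form 2x2 Pearson chi-square (no continuity correction)
  i <- chi_path
  stat[i] <- n[i] * (a[i] * d[i] - b[i] * c_[i])^2 /
    ((a[i] + b[i]) * (c_[i] + d[i]) * (a[i] + c_[i]) * (b[i] + d[i]))
  p[i] <- stats::pchisq(stat[i], df = 1, lower.tail = FALSE)
  fisher_path <- !degen & !chi_path
  for (j in which(fisher_path)) {
    p[j] <- stats::fisher.test(matrix(c(a[j], c_[j], b[j], d[j]), 2))$p.value
  }
  tibble::tibble(
    pair_id = dom$pair_id, first = dom$first, second = dom$second,
    test_used = ifelse(fisher_path, "fisher_exact", "chi_square"),
    statistic = stat, p_value = p, odds_ratio = or,
    direction = direction, degenerate = degen,
    n_used = n, n_ties_excluded = ties
  )
}

#' Benjamini-Hochberg adjustment over a cohort's switch results
#'
#' @param results A switch-result tibble with a `p_value` column.
#' @param method Only `"BH"` is supported.
#' @return `results` with an `adjusted_p` column (step-up FDR over all
#'   rows). Empty input is returned unchanged with the column added.
#' @export
adjust_pvalues <- function(results, method = "BH") {
  method <- match.arg(method, "BH")
  results$adjusted_p <- stats::p.adjust(results$p_value, method = "BH")
  results
}

#' Filter switches significant after adjustment
#'
#' @param results Switch results carrying `adjusted_p`.
#' @param alpha Significance cutoff; strict (`adjusted_p < alpha`), so a
#'   pair at exactly `alpha` is dropped. Default 0.05.
#' @return The significant rows, ordered by ascending `adjusted_p` then
#'   `pair_id`.
#' @export
significant_switches <- function(results, alpha = 0.05) {
  if (!"adjusted_p" %in% names(results)) {
    stop("results lack `adjusted_p`; run adjust_pvalues() first")
  }
  results |>
    dplyr::filter(.data$adjusted_p < alpha) |>
    dplyr::arrange(.data$adjusted_p, .data$pair_id)
}

#' Correlate a pair's dominance signal with a continuous covariate
#'
#' The per-sample signal is the activity difference (first minus second
#' pathway); Pearson correlation with the covariate (e.g. methylation age,
#' RNA age, pseudotime) is tested two-sided on samples with a non-missing
#' covariate value.
#'
#' @param act Activity tibble.
#' @param pair A `pair_id` string (`"A|B"`) or length-2 character vector.
#' @param meta Metadata tibble with `sample_id` and the covariate column.
#' @param covariate Name of the covariate column.
#' @return One-row tibble: `pair_id`, `first`, `second`, `covariate`,
#'   `pearson_r`, `p_value`, `n_used`, `degenerate`. A zero-variance signal
#'   or covariate yields `pearson_r = NA`, `p_value = 1`,
#'   `degenerate = TRUE`.
#' @export
pair_covariate_association <- function(act, pair, meta, covariate) {
  if (length(pair) == 1) pair <- strsplit(pair, "|", fixed = TRUE)[[1]]
  stopifnot(length(pair) == 2)
  m <- activity_matrix(act)
  if (!all(pair %in% rownames(m))) stop("pair pathways not in activity matrix")
  meta <- tibble::as_tibble(meta)
  if (!covariate %in% names(meta)) stop("covariate not in metadata: ", covariate)
  meta <- meta[meta$sample_id %in% colnames(m) & !is.na(meta[[covariate]]), ]
  if (nrow(meta) < 3) stop("need >= 3 samples with a non-missing covariate")
  signal <- m[pair[1], meta$sample_id] - m[pair[2], meta$sample_id]
  x <- meta[[covariate]]
  base <- tibble::tibble(
    pair_id = paste(pair, collapse = "|"), first = pair[1], second = pair[2],
    covariate = covariate, n_used = length(x)
  )
  if (stats::sd(signal) == 0 || stats::sd(x) == 0) {
    return(dplyr::mutate(base, pearson_r = NA_real_, p_value = 1,
                         degenerate = TRUE))
  }
  ct <- stats::cor.test(signal, x, method = "pearson")
  dplyr::mutate(base, pearson_r = unname(ct$estimate),
                p_value = ct$p.value, degenerate = FALSE)
}

#' Per-pathway activity difference between two groups
#'
#' Complements the pairwise analysis with a conventional single-pathway
#' contrast: a two-sided Welch t-test of activity scores between the two
#' groups, BH-adjusted across pathways. Effect is the old-minus-young mean
#' difference.
#'
#' @param act Activity tibble.
#' @param meta Metadata with `sample_id` and `group`.
#' @param groups Two group labels, young first. Each group needs >= 2
#'   samples.
#' @return A tibble `pathway_id`, `mean_diff`, `statistic`, `p_value`,
#'   `adjusted_p`.
#' @export
pathway_group_test <- function(act, meta, groups = c("young", "old")) {
  stopifnot(length(groups) == 2)
  m <- activity_matrix(act)
  meta <- tibble::as_tibble(meta)
  meta <- meta[meta$sample_id %in% colnames(m) &
                 as.character(meta$group) %in% groups, ]
  gy <- meta$sample_id[as.character(meta$group) == groups[1]]
  go <- meta$sample_id[as.character(meta$group) == groups[2]]
  if (length(gy) < 2 || length(go) < 2) {
    stop("each group needs at least 2 samples")
  }
  res <- purrr::map(rownames(m), function(p) {
    y <- m[p, gy]; o <- m[p, go]
    diff <- mean(o) - mean(y)
    tt <- tryCatch(stats::t.test(o, y), error = function(e) NULL)
    if (is.null(tt)) {  # constant data
      tibble::tibble(pathway_id = p, mean_diff = diff,
                     statistic = NA_real_,
                     p_value = as.numeric(diff == 0))
    } else {
      tibble::tibble(pathway_id = p, mean_diff = diff,
                     statistic = unname(tt$statistic), p_value = tt$p.value)
    }
  }) |> dplyr::bind_rows()
  res$adjusted_p <- stats::p.adjust(res$p_value, "BH")
  res
}

#' Export switch results as TSV or JSON
#'
#' @param results Switch-result tibble.
#' @param path Output path; format chosen by extension (`.json` or TSV).
#' @return `path`, invisibly.
#' @export
write_switches <- function(results, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(results, path, auto_unbox = FALSE, digits = NA)
  } else {
    readr::write_tsv(tibble::as_tibble(results), path, progress = FALSE)
  }
  invisible(path)
}
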