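#' Default planted-switch table
#'
#' Pairs consecutive pathways (`P001`|`P002`, `P003`|`P004`, ...) so every
#' planted pair uses two pathways not shared with any other plant.
#'
#' @param n_planted Number of planted pairs.
#' @param n_pathways Total pathways available (needs `2 * n_planted`).
#' @param delta Log2-unit group effect applied per gene.
#' @return A tibble `first`, `second`, `delta`.
#' @export
plant_switches <- function(n_planted, n_pathways, delta = 1.0) {
  if (2 * n_planted > n_pathways) stop("not enough pathways for the plants")
  ids <- sprintf("P%03d", seq_len(n_pathways))
  tibble::tibble(
    first = ids[2 * seq_len(n_planted) - 1],
    second = ids[2 * seq_len(n_planted)],
    delta = delta
  )
}

#' Simulate a bulk expression cohort with planted metabolic switches
#'
#' Gene log2-expression is `baseline + group effect + Normal(0, sd)`. For a
#' planted switch `(A, B, delta)` every gene of pathway A gains `delta` in
#' young samples and every gene of B gains `delta` in old samples, so the
#' pair's within-sample dominance reverses between groups while both
#' pathways stay expressed. Effects enter at the gene level so the coverage
#' gate, weighting and scoring path are all exercised. Ages are drawn in
#' disjoint bands (young 35-49, old 66-80) so quartile-based grouping
#' assigns extreme-quartile samples to their true group.
#'
#' Planting a gene-level effect on pathway A perturbs every pair that
#' contains A, not only the designated partner pair; the truth table
#' therefore also records the full set of affected pathways, and
#' [score_switch_recovery()] counts as false positives only discoveries
#' among pairs of two unaffected pathways.
#'
#' @param n_pathways,genes_per_pathway Cohort dimensions (defaults 50, 20).
#' @param n_young,n_old Samples per group (defaults 30, 30).
#' @param planted_switches Tibble `first`, `second`, `delta`
#'   ([plant_switches()]), or `NULL` for a null cohort.
#' @param gene_noise_sd Per-gene, per-sample noise standard deviation in
#'   log2 units (default 0.5).
#' @param baseline_mean_range Range of per-gene baseline log2 means
#'   (default `c(2, 8)`).
#' @param seed Mandatory integer seed; the generator is a pure function of
#'   its arguments.
#' @return A list of class `"mp_bulk_sim"`: `expr` (log-scale expression
#'   tibble), `meta` (`sample_id`, `age`, `group`), `db` (uniform-weight
#'   pathway database), `truth` (planted pairs with `pair_id`, `delta`,
#'   `direction`, plus attribute `affected_pathways`).
#' @export
simulate_bulk_cohort <- function(n_pathways = 50, genes_per_pathway = 20,
                                 n_young = 30, n_old = 30,
                                 planted_switches = NULL,
                                 gene_noise_sd = 0.5,
                                 baseline_mean_range = c(2, 8),
                                 seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  stopifnot(n_pathways >= 2, genes_per_pathway >= 2,
            n_young >= 1, n_old >= 1, gene_noise_sd >= 0,
            length(baseline_mean_range) == 2,
            diff(baseline_mean_range) >= 0)
  pids <- sprintf("P%03d", seq_len(n_pathways))
  if (!is.null(planted_switches)) {
    ps <- tibble::as_tibble(planted_switches)
    stopifnot(all(c("first", "second", "delta") %in% names(ps)))
    if (any(ps$first == ps$second)) stop("a planted pair repeats a pathway")
    if (!all(c(ps$first, ps$second) %in% pids)) {
      stop("planted pairs reference unknown pathways")
    }
    if (any(!is.finite(ps$delta))) stop("non-finite planted delta")
  } else {
    ps <- tibble::tibble(first = character(), second = character(),
                         delta = numeric())
  }

  n_genes <- n_pathways * genes_per_pathway
  gids <- sprintf("G%05d", seq_len(n_genes))
  gene_pathway <- rep(pids, each = genes_per_pathway)
  sample_ids <- sprintf("S%03d", seq_len(n_young + n_old))
  group <- rep(c("young", "old"), c(n_young, n_old))

  sim <- withr_seed(seed, {
    baseline <- stats::runif(n_genes, baseline_mean_range[1],
                             baseline_mean_range[2])
    age <- c(stats::runif(n_young, 35, 49), stats::runif(n_old, 66, 80))
    vals <- matrix(baseline, n_genes, length(sample_ids)) +
      matrix(stats::rnorm(n_genes * length(sample_ids), 0, gene_noise_sd),
             n_genes)
    list(baseline = baseline, age = age, vals = vals)
  })
  vals <- sim$vals
  young_idx <- which(group == "young")
  old_idx <- which(group == "old")
  for (k in seq_len(nrow(ps))) {
    vals[gene_pathway == ps$first[k], young_idx] <-
      vals[gene_pathway == ps$first[k], young_idx] + ps$delta[k]
    vals[gene_pathway == ps$second[k], old_idx] <-
      vals[gene_pathway == ps$second[k], old_idx] + ps$delta[k]
  }
  dimnames(vals) <- list(gids, sample_ids)

  truth <- dplyr::mutate(
    ps,
    pair_id = paste(pmin(.data$first, .data$second),
                    pmax(.data$first, .data$second), sep = "|"),
    # direction of the switch with age: the old-boosted pathway wins
    direction = ifelse(.data$second == pmax(.data$first, .data$second),
                       "toward_second", "toward_first")
  )
  attr(truth, "affected_pathways") <-
    unique(c(ps$first[ps$delta != 0], ps$second[ps$delta != 0]))

  out <- list(
    expr = as_expression(vals, scale = "log"),
    meta = tibble::tibble(sample_id = sample_ids, age = sim$age,
                          group = factor(group,
                                         levels = c("young", "middle", "old"))),
    db = validate_pathway_db(tibble::tibble(
      pathway_id = gene_pathway, name = gene_pathway, gene = gids, weight = 1
    )),
    truth = truth
  )
  class(out) <- "mp_bulk_sim"
  out
}

#' Score planted-switch recovery of a pipeline run
#'
#' @param results Switch results ([detect_switches()]).
#' @param truth Truth table from [simulate_bulk_cohort()].
#' @param alpha BH significance cutoff (default 0.05).
#' @return One-row tibble: `n_planted`, `n_discovered`, `n_true_null_fp`,
#'   `sensitivity` (planted pairs recovered), `fdr` (fraction of
#'   discoveries among pairs of two unaffected pathways).
#' @export
score_switch_recovery <- function(results, truth, alpha = 0.05) {
  sig <- significant_switches(results, alpha = alpha)
  affected <- attr(truth, "affected_pathways") %||% character()
  null_pair <- !(sig$first %in% affected) & !(sig$second %in% affected)
  tibble::tibble(
    n_planted = nrow(truth),
    n_discovered = nrow(sig),
    n_true_null_fp = sum(null_pair),
    sensitivity = if (nrow(truth) > 0) {
      mean(truth$pair_id %in% sig$pair_id)
    } else NA_real_,
    fdr = if (nrow(sig) > 0) sum(null_pair) / nrow(sig) else 0
  )
}

#' Simulate an age-like covariate correlated with a pair's signal
#'
#' Builds a continuous covariate whose sample Pearson correlation with the
#' pair's activity difference equals `target_r` exactly, by combining the
#' standardized signal with seeded Gaussian noise orthogonalized against
#' it, then shifting to an age-like scale.
#'
#' @param act Activity tibble.
#' @param pair Pair id (`"A|B"`) or length-2 character vector.
#' @param target_r Target Pearson correlation in \[-1, 1\].
#' @param seed Integer seed for the noise component.
#' @return A tibble `sample_id`, `covariate`.
#' @export
simulate_age_covariate <- function(act, pair, target_r, seed) {
  stopifnot(abs(target_r) <= 1)
  if (length(pair) == 1) pair <- strsplit(pair, "|", fixed = TRUE)[[1]]
  m <- activity_matrix(act)
  if (!all(pair %in% rownames(m))) stop("pair pathways not in activity matrix")
  signal <- m[pair[1], ] - m[pair[2], ]
  if (stats::sd(signal) == 0) stop("zero-variance pair signal")
  z <- as.numeric(scale(signal))
  n <- length(z)
  e <- withr_seed(seed, stats::rnorm(n))
  e <- e - mean(e) - z * sum(e * z) / sum(z * z)  # orthogonalize
  if (abs(target_r) < 1) {
    if (stats::sd(e) == 0) stop("degenerate noise vector")
    e <- as.numeric(scale(e))
    cov <- target_r * z + sqrt(1 - target_r^2) * e
  } else {
    cov <- target_r * z
  }
  tibble::tibble(sample_id = colnames(m), covariate = 60 + 10 * cov)
}

#' Simulate a single-cell cohort with planted QC violations
#'
#' Baseline cells draw a per-cell UMI total from a negative binomial
#' (per cell type), clamped to a QC-safe band, and spread it over a
#' concentrated per-type gene-frequency profile by multinomial sampling, so
#' every baseline cell passes the five QC rules. Designated violator cells
#' are replaced by deterministic count vectors that break exactly one named
#' rule each with a wide margin (for example UMI total 80 for `umi_low`,
#' 9000 detected genes for `genes_high`, 30 percent mitochondrial reads for
#' `mito_high`). Cell-type composition per group follows the supplied
#' frequencies exactly (largest-remainder rounding).
#'
#' @param cell_types Character vector of type names.
#' @param freqs Tibble `cell_type`, `group`, `freq` (frequencies sum to 1
#'   within each group), or `NULL` for uniform composition over
#'   `c("young", "old")`.
#' @param cells_per_group Named integer vector of cells per group, or a
#'   single number applied to every group.
#' @param n_genes Genes in the matrix (default 10000; the first `n_mito`
#'   are mitochondrial, named `MT-*`).
#' @param n_mito Mitochondrial genes (default 13).
#' @param nb_mean,nb_size Negative-binomial mean and size of the per-cell
#'   UMI total, recycled over cell types (defaults 2000 and 10).
#' @param mito_frac Expected mitochondrial share of baseline reads
#'   (default 0.02).
#' @param qc_violation_fraction Named fractions of cells to convert into
#'   violators, names among `umi_low`, `umi_high`, `genes_high`,
#'   `mito_high`, `ratio_low` (default none).
#' @param seed Mandatory integer seed.
#' @return A list of class `"mp_sc_sim"`: `counts` (sparse gene-by-cell
#'   `dgCMatrix`), `cells` (`cell_id`, `cell_type`, `group`), `truth`
#'   (`cell_id`, `planted_rule` for every violator), and `composition`
#'   (type-by-group cell counts).
#' @export
simulate_sc_cohort <- function(cell_types = c("Tcell", "Macrophage", "Oligo"),
                               freqs = NULL, cells_per_group = 1000,
                               n_genes = 10000, n_mito = 13,
                               nb_mean = 2000, nb_size = 10,
                               mito_frac = 0.02,
                               qc_violation_fraction = numeric(),
                               seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  stopifnot(n_genes > n_mito, n_mito >= 1, all(nb_mean > 0),
            all(nb_size > 0), mito_frac >= 0, mito_frac < 1)
  if (is.null(freqs)) {
    groups <- c("young", "old")
    freqs <- tidyr::expand_grid(cell_type = cell_types, group = groups) |>
      dplyr::mutate(freq = 1 / length(cell_types))
  } else {
    freqs <- tibble::as_tibble(freqs)
    stopifnot(all(c("cell_type", "group", "freq") %in% names(freqs)))
    groups <- unique(freqs$group)
    cell_types <- unique(freqs$cell_type)
    sums <- tapply(freqs$freq, freqs$group, sum)
    if (any(abs(sums - 1) > 1e-8)) stop("frequencies must sum to 1 per group")
  }
  if (is.null(names(cells_per_group))) {
    cells_per_group <- stats::setNames(rep(cells_per_group[1],
                                           length(groups)), groups)
  }
  stopifnot(all(groups %in% names(cells_per_group)),
            all(cells_per_group > 0))
  rules <- c("umi_low", "umi_high", "genes_high", "mito_high", "ratio_low")
  if (length(qc_violation_fraction) > 0) {
    stopifnot(!is.null(names(qc_violation_fraction)),
              all(names(qc_violation_fraction) %in% rules),
              all(qc_violation_fraction >= 0),
              sum(qc_violation_fraction) < 1)
  }
  if (any(names(qc_violation_fraction) == "genes_high") && n_genes < 9100) {
    stop("genes_high violators need n_genes >= 9100")
  }
  nb_mean <- rep_len(nb_mean, length(cell_types))
  nb_size <- rep_len(nb_size, length(cell_types))
  names(nb_mean) <- names(nb_size) <- cell_types

  gids <- c(sprintf("MT-%d", seq_len(n_mito)),
            sprintf("G%05d", seq_len(n_genes - n_mito)))
  mito_idx <- seq_len(n_mito)

  # exact composition by largest-remainder rounding
  cells <- purrr::map(groups, function(g) {
    f <- freqs$freq[freqs$group == g][match(cell_types,
                                            freqs$cell_type[freqs$group == g])]
    f[is.na(f)] <- 0
    target <- f * cells_per_group[[g]]
    n <- floor(target)
    rem <- cells_per_group[[g]] - sum(n)
    if (rem > 0) {
      add <- order(target - n, decreasing = TRUE)[seq_len(rem)]
      n[add] <- n[add] + 1
    }
    tibble::tibble(cell_type = rep(cell_types, n), group = g)
  }) |> dplyr::bind_rows()
  n_cells <- nrow(cells)
  cells <- dplyr::mutate(cells, cell_id = sprintf("C%05d", seq_len(n_cells)),
                         .before = 1)

  withr_seed(seed, {
    # designate violators
    n_viol <- round(qc_violation_fraction * n_cells)
    n_viol <- n_viol[n_viol > 0]
    viol_cells <- sample.int(n_cells, sum(n_viol))
    truth <- tibble::tibble(
      cell_id = cells$cell_id[viol_cells],
      planted_rule = rep(names(n_viol), n_viol)
    )
    is_viol <- seq_len(n_cells) %in% viol_cells

    # concentrated per-type gene profiles with a fixed mitochondrial share
    profiles <- purrr::map(cell_types, function(ct) {
      p <- exp(stats::rnorm(n_genes, 0, 2.5))
      p_m <- p[mito_idx] / sum(p[mito_idx]) * mito_frac
      p_o <- p[-mito_idx] / sum(p[-mito_idx]) * (1 - mito_frac)
      c(p_m, p_o)
    })
    names(profiles) <- cell_types

    # baseline counts: one multinomial stream per cell type
    ii <- list(); jj <- list(); xx <- list()
    for (ct in cell_types) {
      idx <- which(cells$cell_type == ct & !is_viol)
      if (length(idx) == 0) next
      tot <- stats::rnbinom(length(idx), size = nb_size[[ct]],
                            mu = nb_mean[[ct]])
      tot <- pmin(pmax(tot, 500), 9000)  # QC-safe UMI band
      draws <- sample.int(n_genes, sum(tot), replace = TRUE,
                          prob = profiles[[ct]])
      ii <- c(ii, list(draws))
      jj <- c(jj, list(rep(idx, tot)))
      xx <- c(xx, list(rep(1, sum(tot))))
    }
    # deterministic violator count vectors (exactly one rule broken each)
    nonmito <- setdiff(seq_len(n_genes), mito_idx)
    viol_counts <- list(
      umi_low = {
        g <- nonmito[1:60]
        list(i = c(g, g[1:20]), x = rep(1, 80))
      },
      umi_high = {
        g <- nonmito[1:4400]
        list(i = c(rep(g, each = 1), g[1:3600]),
             x = c(rep(6, 4400), rep(1, 3600)))
      },
      genes_high = {
        g <- nonmito[1:9000]
        list(i = g, x = rep(1, 9000))
      },
      mito_high = {
        g <- nonmito[1:613]
        list(i = c(mito_idx, g, g[1:100]),
             x = c(rep(23, n_mito - 1), 300 - 23 * (n_mito - 1),
                   rep(1, 613), rep(1, 100)))
      },
      ratio_low = {
        g <- nonmito[1:100]
        list(i = g, x = rep(50, 100))
      }
    )
    for (k in seq_len(nrow(truth))) {
      vc <- viol_counts[[truth$planted_rule[k]]]
      j <- which(cells$cell_id == truth$cell_id[k])
      ii <- c(ii, list(vc$i)); jj <- c(jj, list(rep(j, length(vc$i))))
      xx <- c(xx, list(vc$x))
    }
    counts <- Matrix::sparseMatrix(
      i = unlist(ii), j = unlist(jj), x = unlist(xx),
      dims = c(n_genes, n_cells), dimnames = list(gids, cells$cell_id)
    )
    composition <- as.matrix(table(cells$cell_type, cells$group))
    out <- list(counts = counts, cells = cells, truth = truth,
                composition = composition,
                mito_genes = gids[mito_idx])
    class(out) <- "mp_sc_sim"
    out
  })
}
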