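#' Validate a pipeline run configuration
#'
#' A configuration is a YAML file or named list with input paths and stage
#' parameters. Required: `expression` (dense TSV/CSV), `metadata` (TSV with
#' `sample_id`), `gene_sets` (GMT), `out_dir`, `seed`. Optional: `ppi`
#' (edge-list TSV), `scale` (`"linear"`/`"log"`, default linear),
#' `age_mode` (`"quartile"`/`"fixed"`/`"none"`, default quartile; `"none"`
#' expects a `group` column in the metadata), `age_thresholds` (length 2,
#' fixed mode), `groups` (contrast labels, default `young`/`old`),
#' `min_fraction` (0.30), `tie_tol` (1e-9), `alpha` (0.05), `top_k` (200),
#' `n_perm` (10000), `ppi_floor` (1), `covariates` (metadata columns to
#' correlate significant pairs with).
#'
#' @param config Path to a YAML file or a named list.
#' @return The completed configuration list, with defaults filled in.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  for (field in c("expression", "metadata", "gene_sets", "out_dir", "seed")) {
    if (is.null(config[[field]])) stop("config field missing: ", field)
  }
  for (field in c("expression", "metadata", "gene_sets")) {
    if (!file.exists(config[[field]])) {
      stop("config field `", field, "`: file not found: ", config[[field]])
    }
  }
  if (!is.null(config[["ppi"]]) && !file.exists(config[["ppi"]])) {
    stop("config field `ppi`: file not found: ", config[["ppi"]])
  }
  defaults <- list(scale = "linear", age_mode = "quartile",
                   age_thresholds = NULL, groups = c("young", "old"),
                   min_fraction = 0.30, tie_tol = 1e-9, alpha = 0.05,
                   top_k = 200, n_perm = 10000, ppi_floor = 1,
                   covariates = character())
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  config$seed <- as.integer(config$seed)
  if (is.na(config$seed)) stop("config field `seed` must be an integer")
  if (!config$age_mode %in% c("quartile", "fixed", "none")) {
    stop("config field `age_mode` must be quartile, fixed or none")
  }
  if (config$age_mode == "fixed" && length(config$age_thresholds) != 2) {
    stop("config field `age_thresholds` must have 2 values in fixed mode")
  }
  config
}

#' Run the full switch-detection pipeline on one cohort
#'
#' Chains the stages score -> switches -> network -> associate: reads the
#' expression matrix, metadata and gene sets, attaches PPI weights when an
#' edge list is given, assigns age groups, scores pathway activity behind
#' the coverage gate, computes intra-sample pairwise dominance, tests every
#' pair for a group-wise switch with BH adjustment, selects the top events
#' into a single-cohort network, and correlates each significant pair's
#' signal with any configured covariates. All primary outputs are written
#' as TSV/JSON/GraphML under `out_dir` together with a manifest of content
#' hashes, so re-running with an identical configuration produces
#' byte-identical files.
#'
#' @param config Path to a YAML configuration or a named list
#'   ([validate_run_config()]).
#' @return Invisibly, a list with the in-memory results: `activity`,
#'   `dominance`, `switches`, `significant`, `network`, `associations`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  log_stage <- function(...) {
    message(sprintf("[%5.1fs] ", as.numeric(Sys.time() - t0, units = "secs")),
            ...)
  }

  db <- read_gmt(cfg$gene_sets)
  if (!is.null(cfg[["ppi"]])) {
    db <- attach_ppi_weights(db, read_ppi(cfg[["ppi"]]), floor = cfg$ppi_floor)
  }
  expr <- read_expression(cfg$expression, scale = cfg$scale)
  meta <- read_sample_metadata(cfg$metadata)
  if (cfg$age_mode != "none") {
    meta <- assign_age_groups(meta, mode = cfg$age_mode,
                              thresholds = cfg$age_thresholds)
  } else if (!"group" %in% names(meta)) {
    stop("age_mode `none` requires a `group` column in the metadata")
  }
  log_stage("inputs: ", length(unique(db$pathway_id)), " pathways, ",
            nrow(expr), " genes, ", ncol(expr) - 1, " samples")

  gate <- coverage_gate(db, expr, min_fraction = cfg$min_fraction)
  act <- compute_activity(db, expr, gate)
  dom <- pairwise_dominance(act, tie_tol = cfg$tie_tol)
  log_stage("score: ", sum(gate$scored), "/", nrow(gate),
            " pathways scored, ", nrow(dom), " pairs")

  switches <- detect_switches(dom, meta, groups = cfg$groups,
                              n_perm = cfg$n_perm, perm_seed = cfg$seed)
  sig <- significant_switches(switches, alpha = cfg$alpha)
  log_stage("switches: ", nrow(sig), " significant of ", nrow(switches))

  top <- select_top_events(sig, k = cfg$top_k)
  net <- build_network(list(cohort = top))
  log_stage("network: ", nrow(net$nodes), " nodes, ", nrow(net$edges),
            " edges")

  assoc <- purrr::map(cfg$covariates, function(cv) {
    purrr::map(sig$pair_id,
               ~ pair_covariate_association(act, .x, meta, cv)) |>
      dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  if (length(cfg$covariates) > 0) {
    log_stage("associate: ", nrow(assoc), " pair-covariate tests")
  }

  paths <- c(
    coverage = "coverage.tsv", activity = "activity.tsv",
    dominance = "dominance.tsv", switches = "switches.tsv",
    significant = "significant_switches.tsv",
    associations = "associations.tsv"
  )
  paths <- file.path(cfg$out_dir, paths)
  names(paths) <- c("coverage", "activity", "dominance", "switches",
                    "significant", "associations")
  readr::write_tsv(tibble::as_tibble(gate), paths["coverage"],
                   progress = FALSE)
  write_matrix_tsv(act, paths["activity"])
  write_matrix_tsv(dom, paths["dominance"])
  write_switches(switches, paths["switches"])
  write_switches(sig, paths["significant"])
  readr::write_tsv(assoc, paths["associations"], progress = FALSE)
  write_network(net, cfg$out_dir)
  out_files <- c(paths, file.path(cfg$out_dir,
                                  c("network.graphml", "nodes.tsv",
                                    "edges.tsv")))
  manifest <- tibble::tibble(
    file = basename(out_files),
    md5 = unname(tools::md5sum(out_files))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = FALSE, digits = NA)
  log_stage("done: ", length(out_files), " files in ", cfg$out_dir)

  invisible(list(activity = act, dominance = dom, switches = switches,
                 significant = sig, network = net, associations = assoc,
                 manifest = manifest))
}
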