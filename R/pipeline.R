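#' Run the full analysis pipeline
#'
#' Orchestrates the whole workflow in the fixed order: obtain data
#' (synthetic cohort or TSV inputs) -> preprocess (missingness filter, PQN,
#' log2, kNN imputation, duplicate averaging) -> diagnosis-contrast
#' differential analysis -> pathway filtering (when annotations are given)
#' -> GGM network inference with node annotation -> optional seed
#' subnetwork -> clinical panel and mortality signature. Every intermediate
#' artifact is written to `out_dir` as TSV/GraphML and a JSON manifest
#' records the configuration, its hash, and per-stage counts, so a run can
#' be reproduced from the manifest alone.
#'
#' @param config a named list, or path to a JSON (or YAML, if the `yaml`
#'   package is available) file. Recognized entries:
#'   \describe{
#'     \item{synthetic}{list of [synthetic_spec()] arguments — generate a
#'       cohort; or}
#'     \item{inputs}{list with `matrix_metabolites` and/or `matrix_proteins`
#'       (TSV paths), `samples` (TSV), optional `annotations` (TSV),
#'       optional `duplicate_map` (TSV: assay_id, canonical_id).}
#'     \item{out_dir}{output directory (required).}
#'     \item{max_missing_frac, knn_k}{preprocessing knobs (0.25, 10).}
#'     \item{fdr, lfc_threshold}{differential knobs (0.05, 2).}
#'     \item{min_significant}{pathway support threshold (3).}
#'     \item{edge_fdr, edge_fdr_method}{network knobs (0.05, "bh").}
#'     \item{subnetwork_seeds, subnetwork_depth}{optional seed extraction.}
#'     \item{run_clinical_panel}{logical, default TRUE when the outcome
#'       columns are present.}
#'   }
#' @return list with the processed matrix, results tables, networks and the
#'   manifest (also written to `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  config <- load_config(config)
  if (is.null(config$out_dir)) stop("config needs an out_dir", call. = FALSE)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               null = "null")
  cfg_path <- file.path(out_dir, "config.json")
  writeLines(cfg_json, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  counts <- list()
  log_stage <- function(stage, ...) {
    msg <- sprintf(...)
    message(sprintf("[momnet:%s] %s", stage, msg))
  }

  # --- stage: data ---------------------------------------------------------
  truth <- NULL
  if (!is.null(config$synthetic)) {
    spec <- do.call(synthetic_spec, config$synthetic)
    cohort <- generate_cohort(spec)
    m <- cohort$matrix; samples <- cohort$samples; truth <- cohort$truth
    write_cohort(cohort, file.path(out_dir, "synthetic"))
    duplicate_groups <- truth$duplicate_groups
    log_stage("simulate", "%d features x %d samples", nrow(m$values), ncol(m$values))
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    mats <- list()
    if (!is.null(inp$matrix_metabolites))
      mats$met <- read_matrix(inp$matrix_metabolites, "metabolite")
    if (!is.null(inp$matrix_proteins))
      mats$prot <- read_matrix(inp$matrix_proteins, "protein")
    if (length(mats) == 0) stop("inputs must name at least one matrix", call. = FALSE)
    vals <- do.call(rbind, lapply(mats, function(x) x$values))
    omics <- unlist(lapply(mats, function(x) unname(x$omics)))
    rownames(vals) <- unlist(lapply(mats, feature_ids))
    m <- omics_matrix(vals, omics, "raw")
    samples <- read_sample_table(inp$samples)
    duplicate_groups <- if (!is.null(inp$duplicate_map)) {
      dm <- utils::read.delim(inp$duplicate_map, sep = "\t",
                              stringsAsFactors = FALSE)
      stats::setNames(dm$canonical_id, dm$assay_id)
    } else NULL
    log_stage("load", "%d features x %d samples", nrow(m$values), ncol(m$values))
  } else stop("config needs either 'synthetic' or 'inputs'", call. = FALSE)
  validate_sample_table(samples, m)
  counts$n_features_raw <- nrow(m$values)
  counts$n_samples <- ncol(m$values)

  # --- stage: preprocess ---------------------------------------------------
  pp <- preprocess_pipeline(
    m,
    max_missing_frac = config$max_missing_frac %||% 0.25,
    k = config$knn_k %||% 10,
    duplicate_groups = duplicate_groups)
  proc <- pp$matrix
  counts$n_features_removed_missingness <- nrow(pp$qc$removed)
  counts$n_features_processed <- nrow(proc$values)
  write_matrix(proc, file.path(out_dir, "processed_matrix.tsv"))
  utils::write.table(
    data.frame(sample_id = names(pp$qc$quotient_medians),
               quotient_median = unname(pp$qc$quotient_medians)),
    file.path(out_dir, "qc_quotient_medians.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("preprocess", "removed %d features (>%.0f%% missing), %d kept",
            counts$n_features_removed_missingness,
            100 * (config$max_missing_frac %||% 0.25),
            counts$n_features_processed)

  fdr <- config$fdr %||% 0.05

  # --- stage: diagnosis differential --------------------------------------
  diag_res <- fit_association(proc, samples, "group")
  write_results(diag_res, file.path(out_dir, "differential_diagnosis.tsv"))
  sig <- diag_res[diag_res$p_adj < fdr, , drop = FALSE]
  counts$n_significant_diagnosis <- nrow(sig)
  counts$n_significant_diagnosis_metabolites <-
    sum(sig$omics_label == "metabolite")
  counts$n_significant_diagnosis_proteins <- sum(sig$omics_label == "protein")
  log_stage("associate", "%d significant molecules at FDR < %g (%d metabolites, %d proteins)",
            nrow(sig), fdr, counts$n_significant_diagnosis_metabolites,
            counts$n_significant_diagnosis_proteins)

  # --- stage: pathways -----------------------------------------------------
  pathways <- NULL
  ann_path <- if (!is.null(config$inputs)) config$inputs$annotations else NULL
  if (!is.null(ann_path)) {
    ann <- read_annotations(ann_path)
    pathways <- annotate_and_filter(diag_res, ann,
                                    min_significant = config$min_significant %||% 3,
                                    fdr = fdr)
    utils::write.table(pathways$pathways, file.path(out_dir, "pathways.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    counts$n_pathways_retained <- nrow(pathways$pathways)
    log_stage("pathways", "%d pathways retained", nrow(pathways$pathways))
  }

  # --- stage: network ------------------------------------------------------
  net <- infer_network(proc, results = diag_res,
                       fdr = config$edge_fdr %||% 0.05,
                       method = config$edge_fdr_method %||% "bh")
  counts$n_edges <- nrow(net$edges)
  counts$lambda_star <- net$lambda_star
  write_network(net, file.path(out_dir, "network.graphml"), "graphml")
  write_network(net, file.path(out_dir, "network_edges.tsv"), "edge_tsv")
  utils::write.table(net$nodes, file.path(out_dir, "network_nodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("network", "%d edges at FDR < %g (%s), lambda* = %.3f",
            nrow(net$edges), net$fdr, net$method, net$lambda_star)

  # --- stage: subnetwork ---------------------------------------------------
  subnet <- NULL
  if (!is.null(config$subnetwork_seeds)) {
    subnet <- extract_subnetwork(net, unlist(config$subnetwork_seeds),
                                 max_depth = config$subnetwork_depth %||% 2)
    counts$n_subnetwork_nodes <- nrow(subnet$nodes)
    counts$n_subnetwork_edges <- nrow(subnet$edges)
    write_network(subnet, file.path(out_dir, "subnetwork.graphml"), "graphml")
    write_network(subnet, file.path(out_dir, "subnetwork_edges.tsv"), "edge_tsv")
    log_stage("subnetwork", "%d nodes, %d edges", nrow(subnet$nodes),
              nrow(subnet$edges))
  }

  # --- stage: clinical panel + mortality signature -------------------------
  panel <- NULL; signature <- NULL
  outcome_cols <- c("aki", "mortality", "platelet_count", "pao2_fio2")
  do_panel <- config$run_clinical_panel %||% all(outcome_cols %in% names(samples))
  if (isTRUE(do_panel) && all(outcome_cols %in% names(samples))) {
    panel <- suppressWarnings(run_clinical_panel(proc, samples, fdr = fdr))
    utils::write.table(panel$hits, file.path(out_dir, "clinical_panel_hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    counts$clinical_hits <- stats::setNames(
      as.list(panel$hits$n_significant),
      paste(panel$hits$group, panel$hits$outcome, sep = "."))
    mort <- panel$results[["covid.mortality"]]
    if (!is.null(mort)) {
      signature <- extract_signature(mort, fdr = fdr,
                                     lfc_threshold = config$lfc_threshold %||% 2)
      write_results(signature, file.path(out_dir, "mortality_signature.tsv"))
      counts$n_signature <- nrow(signature)
      log_stage("signature", "%d molecules pass |log2FC| >= %g at FDR < %g",
                nrow(signature), config$lfc_threshold %||% 2, fdr)
    }
  }

  manifest <- list(
    package = "momnet",
    version = as.character(utils::packageVersion("momnet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = NULL,  # deliberately omitted: manifests must be byte-identical
    config = config,
    config_hash = cfg_hash,
    counts = counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(list(matrix = proc, samples = samples, truth = truth,
                 qc = pp$qc, differential = diag_res, pathways = pathways,
                 network = net, subnetwork = subnet, clinical_panel = panel,
                 signature = signature, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    ext <- tolower(tools::file_ext(config))
    config <- if (ext %in% c("yaml", "yml")) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("YAML configs need the 'yaml' package; use JSON instead", call. = FALSE)
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config)) stop("config must be a list or a file path", call. = FALSE)
  config
}
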