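#' Read a feature-by-sample abundance matrix from TSV
#'
#' Canonical dialect: tab-separated, UTF-8, '.' decimal, features as rows,
#' first column the feature id, remaining columns one per sample. Empty cells
#' and the literal string "NA" are read as missing.
#'
#' @param path TSV file path.
#' @param omics_label `"metabolite"` or `"protein"`, applied to all features.
#' @param scale_state scale state to stamp on the result (default `"raw"`).
#' @param transpose read samples-as-rows input (orientation is flipped after
#'   parsing; written output is always features-as-rows).
#' @return an [omics_matrix()].
#' @export
read_matrix <- function(path, omics_label, scale_state = "raw", transpose = FALSE) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          na.strings = c("NA", ""), colClasses = "character",
                          quote = "")
  if (ncol(df) < 2) stop("matrix TSV needs an id column plus >= 1 sample column", call. = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate feature id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  raw <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw),
                                  dimnames = list(ids, colnames(raw))))
  bad <- which(is.na(vals) & !is.na(raw), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric cell at feature '%s', sample '%s' in %s",
                 ids[bad[1, 1]], colnames(raw)[bad[1, 2]], path), call. = FALSE)
  if (transpose) vals <- t(vals)
  omics_matrix(vals, omics_label, scale_state)
}

#' Write an omics matrix as TSV
#'
#' Inverse of [read_matrix()]: features as rows, first column `feature_id`,
#' missing values written as "NA". Deterministic: preserves row/column order.
#'
#' @param m an `omics_matrix`.
#' @param path output file path.
#' @export
write_matrix <- function(m, path) {
  stopifnot(inherits(m, "omics_matrix"))
  df <- data.frame(feature_id = feature_ids(m), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read / write the sample metadata table
#'
#' TSV with columns `sample_id`, `group` and any of `aki`, `mortality`,
#' `platelet_count`, `pao2_fio2`; "NA"/empty means missing.
#'
#' @param path TSV file path.
#' @return a validated sample table data.frame.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          na.strings = c("NA", ""), quote = "",
                          stringsAsFactors = FALSE)
  validate_sample_table(df)
}

#' @rdname read_sample_table
#' @param samples sample table data.frame.
#' @export
write_sample_table <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a molecule-to-pathway annotation table
#'
#' Columns: `molecule_id`, `pathway_name`, `source`
#' (`metabolon_subpathway` or `kegg`) and `kegg_category` (may be NA for
#' non-KEGG rows; used to exclude disease pathways).
#'
#' @param path TSV file path.
#' @return data.frame of annotations.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          na.strings = c("NA", ""), quote = "",
                          stringsAsFactors = FALSE)
  need <- c("molecule_id", "pathway_name", "source")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(df$source %in% c("metabolon_subpathway", "kegg")))
    stop("annotation source must be 'metabolon_subpathway' or 'kegg'", call. = FALSE)
  if (!"kegg_category" %in% names(df)) df$kegg_category <- NA_character_
  if (anyDuplicated(df[, c("molecule_id", "pathway_name")]))
    stop("duplicate (molecule_id, pathway_name) pairs in annotation table", call. = FALSE)
  df
}

#' Write an inferred network to GraphML or edge-list TSV
#'
#' GraphML nodes carry `omics_label` and `p_score` attributes; edges carry
#' the partial correlation and raw/adjusted p-values. The edge TSV has
#' columns `source`, `target`, `pcor`, `p`, `p_adj`.
#'
#' @param network a `ggm_network` (see [edge_significance()]).
#' @param path output file path.
#' @param format `"graphml"` or `"edge_tsv"`.
#' @export
write_network <- function(network, path, format = c("graphml", "edge_tsv")) {
  stopifnot(inherits(network, "ggm_network"))
  format <- match.arg(format)
  if (format == "edge_tsv") {
    utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    return(invisible(path))
  }
  g <- as_igraph(network)
  # igraph's GraphML writer needs a file connection; attributes ride along
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Convert a ggm_network to an igraph object
#'
#' @param network a `ggm_network`.
#' @return an undirected `igraph` graph with node attributes `omics_label`
#'   and `p_score` and edge attributes `pcor`, `p`, `p_adj`.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "ggm_network"))
  nodes <- network$nodes
  # igraph requires the vertex id column first
  vdf <- data.frame(name = nodes$id,
                    omics_label = nodes$omics,
                    p_score = ifelse(is.na(nodes$p_score), NaN, nodes$p_score),
                    stringsAsFactors = FALSE)
  edf <- network$edges
  igraph::graph_from_data_frame(
    d = edf[, c("source", "target", "pcor", "p", "p_adj")],
    directed = FALSE, vertices = vdf)
}

#' Read an edge-list TSV back into edge form
#'
#' Companion to `write_network(format = "edge_tsv")`; used for round-trip
#' checks and downstream tooling.
#'
#' @param path TSV with columns source, target, pcor, p, p_adj.
#' @return data.frame of edges.
#' @export
read_edge_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          na.strings = c("NA", ""), quote = "",
                          stringsAsFactors = FALSE)
  need <- c("source", "target", "pcor", "p", "p_adj")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("edge TSV missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df
}

#' Write an association results table
#'
#' Mirrors the layout of supplementary differential-analysis tables:
#' molecule, omics label, outcome, estimate, statistic, p, adjusted p,
#' direction and the signed significance score.
#'
#' @param results an association results data.frame (see [fit_association()]).
#' @param path output TSV path.
#' @export
write_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
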