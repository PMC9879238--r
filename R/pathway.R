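#' Aggregate differential results to pathway level and filter
#'
#' Counts annotated and significant molecules per pathway and keeps the
#' pathways that are (a) eligible — a Metabolon-style sub-pathway whose name
#' contains "metabolism" (case-insensitive) or a KEGG pathway whose
#' `kegg_category` is not "Human Diseases" — and (b) supported by at least
#' `min_significant` significant molecules (`p_adj < fdr`).
#'
#' Annotations for molecules absent from `results` are dropped with a
#' warning; molecules with no annotation are reported separately.
#'
#' @param results data.frame from [fit_association()].
#' @param annotations annotation table (see [read_annotations()]).
#' @param min_significant minimum significant molecules per retained
#'   pathway, default 3.
#' @param fdr significance threshold, default 0.05.
#' @return list with `pathways` (retained summary table: pathway, source,
#'   n_annotated, n_significant, n_up, n_down), `all_pathways` (the same
#'   summary before eligibility/support filtering, with `eligible` flag) and
#'   `unannotated` (significant molecule ids with no annotation).
#' @export
annotate_and_filter <- function(results, annotations, min_significant = 3,
                                fdr = 0.05) {
  stopifnot(is.data.frame(results), is.data.frame(annotations))
  unknown <- !annotations$molecule_id %in% results$molecule_id
  if (any(unknown)) {
    warning(sum(unknown), " annotation row(s) reference molecules absent from",
            " the results; ignored", call. = FALSE)
    annotations <- annotations[!unknown, , drop = FALSE]
  }
  sig <- results$p_adj < fdr
  sig_ids <- results$molecule_id[sig]
  up_ids <- results$molecule_id[sig & results$d > 0]
  ann <- annotations
  key <- paste(ann$pathway_name, ann$source, sep = "\r")
  split_idx <- split(seq_len(nrow(ann)), key)
  rows <- lapply(split_idx, function(idx) {
    mols <- ann$molecule_id[idx]
    s <- intersect(mols, sig_ids)
    src <- ann$source[idx[1]]
    cat_ <- ann$kegg_category[idx[1]]
    eligible <- if (src == "metabolon_subpathway") {
      grepl("metabolism", ann$pathway_name[idx[1]], ignore.case = TRUE)
    } else {
      is.na(cat_) || cat_ != "Human Diseases"
    }
    data.frame(pathway = ann$pathway_name[idx[1]], source = src,
               kegg_category = cat_,
               n_annotated = length(unique(mols)),
               n_significant = length(s),
               n_up = length(intersect(s, up_ids)),
               n_down = length(setdiff(s, up_ids)),
               eligible = eligible,
               significant_molecules = paste(sort(s), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  all_pw <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(all_pw)) {
    all_pw <- data.frame(pathway = character(), source = character(),
                         kegg_category = character(), n_annotated = integer(),
                         n_significant = integer(), n_up = integer(),
                         n_down = integer(), eligible = logical(),
                         significant_molecules = character(),
                         stringsAsFactors = FALSE)
  }
  all_pw <- all_pw[order(-all_pw$n_significant, all_pw$pathway), , drop = FALSE]
  rownames(all_pw) <- NULL
  retained <- all_pw[all_pw$eligible & all_pw$n_significant >= min_significant, ,
                     drop = FALSE]
  rownames(retained) <- NULL
  unannot <- setdiff(sig_ids, annotations$molecule_id)
  list(pathways = retained, all_pathways = all_pw, unannotated = unannot)
}
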