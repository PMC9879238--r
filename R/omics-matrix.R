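#' Feature-by-sample abundance matrix with omics labels
#'
#' The central data container of the pipeline: a numeric matrix with features
#' (metabolites and/or proteins) as rows and samples as columns, a per-feature
#' omics label, and a `scale_state` that tracks where the object sits in the
#' preprocessing chain. Missing measurements are `NA`.
#'
#' `scale_state` may only advance along
#' `raw -> normalized -> log2 -> imputed`; each preprocessing step checks the
#' state of its input so the chain cannot be run out of order.
#'
#' @param values numeric matrix, features x samples, with rownames (feature
#'   ids) and colnames (sample ids). `NA` marks missing values.
#' @param omics character vector, one of `"metabolite"` or `"protein"` per
#'   feature (recycled if length 1).
#' @param scale_state one of `"raw"`, `"normalized"`, `"log2"`, `"imputed"`.
#' @return an object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, omics, scale_state = "raw") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "),
         call. = FALSE)
  omics <- rep_len(as.character(omics), nrow(values))
  if (!all(omics %in% c("metabolite", "protein")))
    stop("omics labels must be 'metabolite' or 'protein'", call. = FALSE)
  scale_state <- match.arg(scale_state, c("raw", "normalized", "log2", "imputed"))
  if (scale_state %in% c("raw", "normalized") && any(values <= 0, na.rm = TRUE))
    stop("raw/normalized abundances must be strictly positive", call. = FALSE)
  structure(
    list(values = values, omics = stats::setNames(omics, rownames(values)),
         scale_state = scale_state),
    class = "omics_matrix"
  )
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> %d features x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$scale_state))
  tab <- table(x$omics)
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  nmiss <- sum(is.na(x$values))
  cat(sprintf("   missing: %d (%.1f%%)\n", nmiss,
              100 * nmiss / length(x$values)))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

feature_ids <- function(m) rownames(m$values)
sample_ids  <- function(m) colnames(m$values)

#' Subset an omics matrix by feature and/or sample ids
#'
#' @param m an `omics_matrix`.
#' @param features,samples character vectors of ids to keep (default: all).
#' @return an `omics_matrix` in the same scale state.
#' @export
subset_omics <- function(m, features = NULL, samples = NULL) {
  stopifnot(inherits(m, "omics_matrix"))
  f <- if (is.null(features)) feature_ids(m) else features
  s <- if (is.null(samples)) sample_ids(m) else samples
  miss_f <- setdiff(f, feature_ids(m))
  if (length(miss_f)) stop("unknown features: ", paste(miss_f, collapse = ", "), call. = FALSE)
  miss_s <- setdiff(s, sample_ids(m))
  if (length(miss_s)) stop("unknown samples: ", paste(miss_s, collapse = ", "), call. = FALSE)
  out <- m
  out$values <- m$values[f, s, drop = FALSE]
  out$omics <- m$omics[f]
  out
}

assert_scale <- function(m, expected, op) {
  if (!inherits(m, "omics_matrix"))
    stop(op, "() expects an omics_matrix", call. = FALSE)
  if (!m$scale_state %in% expected)
    stop(sprintf("%s() requires scale_state %s, got '%s' (pipeline order is filter -> pqn -> log2 -> impute -> average)",
                 op, paste(sQuote(expected), collapse = " or "), m$scale_state),
         call. = FALSE)
  invisible(m)
}

#' Validate a sample metadata table
#'
#' Checks the clinical metadata table used throughout the pipeline: one row
#' per sample, a two-level diagnosis `group` (`"covid"` / `"bacterial"`),
#' binary outcomes `aki` and `mortality` (0/1 or `NA`) and non-negative
#' continuous outcomes `platelet_count` and `pao2_fio2`.
#'
#' @param samples data.frame with at least columns `sample_id` and `group`.
#' @param m optional `omics_matrix`; if given, sample ids must match exactly.
#' @return the validated data.frame, invisibly usable downstream.
#' @export
validate_sample_table <- function(samples, m = NULL) {
  stopifnot(is.data.frame(samples))
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("sample table missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in sample table", call. = FALSE)
  if (!all(samples$group %in% c("covid", "bacterial")))
    stop("group must be 'covid' or 'bacterial'", call. = FALSE)
  for (b in intersect(c("aki", "mortality"), names(samples))) {
    v <- samples[[b]]
    if (!all(is.na(v) | v %in% c(0, 1)))
      stop("binary outcome '", b, "' must be 0/1 or NA", call. = FALSE)
  }
  if ("platelet_count" %in% names(samples) &&
      any(samples$platelet_count < 0, na.rm = TRUE))
    stop("platelet_count must be >= 0", call. = FALSE)
  if ("pao2_fio2" %in% names(samples) &&
      any(samples$pao2_fio2 <= 0, na.rm = TRUE))
    stop("pao2_fio2 must be > 0", call. = FALSE)
  if (!is.null(m)) {
    if (!setequal(samples$sample_id, sample_ids(m)))
      stop("sample table and omics matrix sample ids differ", call. = FALSE)
  }
  samples
}
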