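#' Remove features with too many missing values
#'
#' Drops every feature whose missing fraction is strictly greater than
#' `max_missing_frac` (the boundary case "exactly 25% missing" is kept).
#' With 59 samples this removes a feature missing in 15 samples (25.4%) and
#' keeps one missing in 14 (23.7%).
#'
#' @param m raw `omics_matrix`.
#' @param max_missing_frac removal threshold; default 0.25.
#' @return the filtered matrix, with a `removed` attribute: a data.frame of
#'   dropped feature ids and their missing fractions.
#' @export
filter_missingness <- function(m, max_missing_frac = 0.25) {
  assert_scale(m, "raw", "filter_missingness")
  frac <- rowMeans(is.na(m$values))
  drop <- frac > max_missing_frac
  if (all(drop))
    stop("all features exceed the missingness threshold", call. = FALSE)
  report <- data.frame(feature_id = feature_ids(m)[drop],
                       missing_frac = unname(frac[drop]),
                       stringsAsFactors = FALSE)
  out <- subset_omics(m, features = feature_ids(m)[!drop])
  attr(out, "removed") <- report
  out
}

#' Probabilistic quotient normalization
#'
#' Corrects per-sample dilution (e.g. urine concentration): the reference
#' spectrum is the per-feature median across samples; each sample's quotients
#' are its values divided by the reference, and the sample is divided by the
#' median of its quotients. Missing values are ignored throughout
#' (pairwise-complete). After normalization every sample's median quotient
#' against the same reference is 1, so the operation is idempotent.
#'
#' @param m raw `omics_matrix` with strictly positive values.
#' @param reference optional per-feature reference spectrum (named numeric
#'   vector). Defaults to the median spectrum of `m` itself. Normalizing
#'   against a fixed reference is exactly idempotent: the median quotient of
#'   every normalized sample against that same reference is 1.
#' @return normalized `omics_matrix` with attributes `quotient_medians` (the
#'   per-sample scaling factors, estimates of relative dilution) and
#'   `reference` (the spectrum used).
#' @export
pqn_normalize <- function(m, reference = NULL) {
  assert_scale(m, "raw", "pqn_normalize")
  v <- m$values
  if (any(v <= 0, na.rm = TRUE))
    stop("PQN requires strictly positive abundances", call. = FALSE)
  ref <- if (is.null(reference)) {
    apply(v, 1, stats::median, na.rm = TRUE)
  } else {
    if (is.null(names(reference)) || !all(feature_ids(m) %in% names(reference)))
      stop("reference must be named and cover all features", call. = FALSE)
    reference[feature_ids(m)]
  }
  q <- v / ref
  n_shared <- colSums(!is.na(q))
  if (any(n_shared < 2))
    stop("sample(s) with < 2 features shared with the reference: ",
         paste(sample_ids(m)[n_shared < 2], collapse = ", "), call. = FALSE)
  qmed <- apply(q, 2, stats::median, na.rm = TRUE)
  out <- m
  out$values <- sweep(v, 2, qmed, "/")
  out$scale_state <- "normalized"
  attr(out, "quotient_medians") <- stats::setNames(qmed, sample_ids(m))
  attr(out, "reference") <- stats::setNames(ref, feature_ids(m))
  out
}

#' Log2-transform a normalized matrix
#'
#' @param m normalized `omics_matrix` with positive values.
#' @return `omics_matrix` in log2 scale; missing entries stay missing.
#' @export
log2_transform <- function(m) {
  assert_scale(m, "normalized", "log2_transform")
  if (any(m$values <= 0, na.rm = TRUE))
    stop("log2 requires strictly positive values", call. = FALSE)
  out <- m
  out$values <- log2(m$values)
  out$scale_state <- "log2"
  out
}

#' K-nearest-neighbor imputation of remaining missing values
#'
#' Operates in feature space (appropriate for p >> n omics): for a missing
#' entry (feature f, sample s), the k features nearest to f that are observed
#' at sample s are averaged. Distance between feature profiles is the
#' root-mean-square difference over samples observed in both (i.e. Euclidean
#' distance scaled by the number of shared samples), so features with few
#' shared samples are compared on an equal footing. Features with fewer than
#' k eligible neighbors use all eligible ones. Observed values are never
#' altered.
#'
#' @param m log2-scale `omics_matrix`; every feature must have at least one
#'   observed value.
#' @param k number of neighbors; default 10.
#' @return imputed `omics_matrix` (scale_state `"imputed"`).
#' @export
knn_impute <- function(m, k = 10) {
  assert_scale(m, "log2", "knn_impute")
  v <- m$values
  fully_missing <- rowSums(!is.na(v)) == 0
  if (any(fully_missing))
    stop("feature(s) entirely missing (should have been filtered): ",
         paste(feature_ids(m)[fully_missing], collapse = ", "), call. = FALSE)
  if (!anyNA(v)) {
    out <- m; out$scale_state <- "imputed"; return(out)
  }
  p <- nrow(v)
  obs <- !is.na(v)
  v0 <- v; v0[!obs] <- 0
  # pairwise RMS distance over shared observed samples, computed via
  # cross-products: sum over shared of (xi - xj)^2 = xi^2 + xj^2 - 2 xi xj
  sq <- v0^2
  shared <- obs %*% t(obs * 1)
  cross <- v0 %*% t(v0)
  si <- sq %*% t(obs * 1)     # sum of xi^2 over shared samples
  d2 <- si + t(si) - 2 * cross
  d2[d2 < 0] <- 0
  dist <- sqrt(d2 / pmax(shared, 1))
  dist[shared == 0] <- Inf
  diag(dist) <- Inf
  out_v <- v
  miss_feats <- which(rowSums(!obs) > 0)
  for (f in miss_feats) {
    ord <- order(dist[f, ])
    for (s in which(!obs[f, ])) {
      elig <- ord[obs[ord, s] & is.finite(dist[f, ord])]
      if (length(elig) == 0) {
        # no comparable feature observed here: fall back to the feature mean
        out_v[f, s] <- mean(v[f, ], na.rm = TRUE)
      } else {
        nn <- elig[seq_len(min(k, length(elig)))]
        out_v[f, s] <- mean(v[nn, s])
      }
    }
  }
  out <- m
  out$values <- out_v
  out$scale_state <- "imputed"
  out
}

#' Average duplicated assay copies of the same molecule
#'
#' Some targeted proteomics panels measure a protein on more than one panel;
#' each duplicate group is collapsed to a single feature whose per-sample
#' value is the arithmetic mean (in the current scale) of the group's
#' members. The canonical id is kept; the collapsed feature takes the row
#' position of the group's first member.
#'
#' @param m an `omics_matrix` (any scale; averaging in log2 space is the
#'   default pipeline position, after imputation).
#' @param duplicate_groups named character vector mapping assay feature ids
#'   to their canonical molecule id. See [default_duplicate_proteins()] for
#'   the conventional 10-protein Olink list.
#' @return `omics_matrix` with each group collapsed to one feature.
#' @export
average_duplicates <- function(m, duplicate_groups) {
  stopifnot(inherits(m, "omics_matrix"))
  if (length(duplicate_groups) == 0) return(m)
  if (is.null(names(duplicate_groups)))
    stop("duplicate_groups must be a named vector (assay id -> canonical id)",
         call. = FALSE)
  unknown <- setdiff(names(duplicate_groups), feature_ids(m))
  if (length(unknown))
    stop("duplicate_groups references unknown feature(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  v <- m$values
  omics <- m$omics
  keep_order <- feature_ids(m)
  drop_ids <- character()
  for (canon in unique(unname(duplicate_groups))) {
    members <- names(duplicate_groups)[duplicate_groups == canon]
    if (length(members) < 2 && canon %in% members) next
    avg <- colMeans(v[members, , drop = FALSE], na.rm = FALSE)
    anchor <- members[1]
    v[anchor, ] <- avg
    rownames(v)[rownames(v) == anchor] <- canon
    names(omics)[names(omics) == anchor] <- canon
    keep_order[keep_order == anchor] <- canon
    drop_ids <- c(drop_ids, setdiff(members, anchor))
  }
  keep <- setdiff(keep_order, drop_ids)
  out <- m
  out$values <- v[keep, , drop = FALSE]
  out$omics <- omics[keep]
  out
}

#' The ten Olink proteins conventionally assayed in duplicate
#'
#' @return named character vector mapping the two panel copies of each
#'   protein (suffixes `_a`, `_b`) to the canonical protein name.
#' @export
default_duplicate_proteins <- function() {
  prots <- c("CCL3", "CXCL1", "FGF-21", "FGF-23", "IL-18", "IL-6",
             "MCP-1", "OPG", "SCF", "uPA")
  stats::setNames(rep(prots, each = 2),
                  paste0(rep(prots, each = 2), c("_a", "_b")))
}

#' Run the full preprocessing chain
#'
#' filter (missingness > `max_missing_frac` removed) -> probabilistic
#' quotient normalization -> log2 -> kNN imputation -> duplicate averaging.
#' The order is fixed; each step checks its input's scale state.
#'
#' @param m raw `omics_matrix`.
#' @param max_missing_frac missingness threshold, default 0.25.
#' @param k imputation neighbors, default 10.
#' @param duplicate_groups optional named vector for [average_duplicates()].
#' @return list with `matrix` (processed, scale `"imputed"`) and `qc`:
#'   per-feature missingness of the input, removed features, per-sample
#'   quotient medians.
#' @export
preprocess_pipeline <- function(m, max_missing_frac = 0.25, k = 10,
                                duplicate_groups = NULL) {
  missing_frac <- rowMeans(is.na(m$values))
  filt <- filter_missingness(m, max_missing_frac)
  removed <- attr(filt, "removed")
  norm <- pqn_normalize(filt)
  qmed <- attr(norm, "quotient_medians")
  lg <- log2_transform(norm)
  imp <- knn_impute(lg, k = k)
  if (!is.null(duplicate_groups) && length(duplicate_groups) > 0)
    imp <- average_duplicates(imp, duplicate_groups)
  list(matrix = imp,
       qc = list(missing_frac = missing_frac, removed = removed,
                 quotient_medians = qmed))
}
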