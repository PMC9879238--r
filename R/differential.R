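#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up FDR correction: sort p-values ascending, multiply the
#' i-th by m/i, enforce monotone non-decreasing from the top rank down, cap
#' at 1, and restore the input order.
#'
#' @param pvalues numeric vector with all values in (0, 1].
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric())
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  m <- length(pvalues)
  ord <- order(pvalues)
  scaled <- pvalues[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Signed significance score
#'
#' `p_score = -log10(p_adj) * d`, where `d` in {-1, +1} is the direction of
#' the association. Used to annotate network nodes: magnitude is evidence,
#' sign is direction.
#'
#' @param p_adj adjusted p-value(s) in (0, 1]; exactly 0 is an error (the
#'   score would be infinite — floor upstream).
#' @param d direction(s), -1 or +1.
#' @return numeric score(s).
#' @export
compute_p_score <- function(p_adj, d) {
  if (any(is.na(p_adj)) || any(p_adj <= 0) || any(p_adj > 1))
    stop("p_adj must lie in (0, 1]; floor zero p-values before scoring",
         call. = FALSE)
  if (!all(d %in% c(-1, 1)))
    stop("direction d must be -1 or +1", call. = FALSE)
  -log10(p_adj) * d
}

#' Per-molecule linear-model association with an outcome
#'
#' For each molecule, ordinary least squares of abundance on an intercept
#' plus the outcome, over samples with a non-missing outcome. With a 0/1
#' outcome the coefficient is the difference of group means — the log2 fold
#' change when abundances are in log2 space — and the test is numerically
#' identical to a pooled-variance two-sample t-test. Two-sided p-values come
#' from the t distribution with `n_used - 2` degrees of freedom; BH
#' adjustment is applied across all molecules tested here (both omics
#' jointly). Constant molecules get estimate 0 and p 1 (flagged in
#' `degenerate`), not an error.
#'
#' @param m imputed `omics_matrix`.
#' @param samples sample table containing `outcome_name`.
#' @param outcome_name column of `samples` to test ("group" is recoded
#'   bacterial = 0, covid = 1, so positive estimates mean higher in covid).
#' @param subset_group optional: restrict to samples of this diagnosis group
#'   before testing (used for within-group clinical associations).
#' @param bh_scope `"joint"` (default): one BH correction across both omics
#'   layers; `"per_omics"`: correct metabolites and proteins separately.
#' @return data.frame with one row per molecule: `molecule_id`,
#'   `omics_label`, `outcome_name`, `estimate`, `t_statistic`, `p`, `p_adj`,
#'   `d`, `p_score`, `n_used`, `degenerate`.
#' @export
fit_association <- function(m, samples, outcome_name, subset_group = NULL,
                            bh_scope = c("joint", "per_omics")) {
  bh_scope <- match.arg(bh_scope)
  assert_scale(m, "imputed", "fit_association")
  samples <- validate_sample_table(samples)
  if (!outcome_name %in% c(names(samples), "group"))
    stop("unknown outcome: ", outcome_name, call. = FALSE)
  if (!is.null(subset_group)) {
    samples <- samples[samples$group == subset_group, , drop = FALSE]
  }
  samples <- samples[samples$sample_id %in% sample_ids(m), , drop = FALSE]
  y <- if (outcome_name == "group") {
    as.numeric(samples$group == "covid")
  } else {
    out <- samples[[outcome_name]]
    if (outcome_name %in% c("aki", "mortality")) as.numeric(out) else as.numeric(out)
  }
  keep <- !is.na(y)
  y <- y[keep]
  use_ids <- samples$sample_id[keep]
  if (length(unique(y)) < 2)
    stop("outcome '", outcome_name, "' is constant in the analyzed samples",
         call. = FALSE)
  x <- m$values[, use_ids, drop = FALSE]
  n <- length(y)
  yc <- y - mean(y)
  syy <- sum(yc^2)
  xm <- rowMeans(x)
  sxy <- as.vector(x %*% yc)              # row-wise sum of (x - xbar) * yc
  beta <- sxy / syy
  fitted_var <- beta^2 * syy              # SS explained
  sxx <- rowSums((x - xm)^2)
  rss <- pmax(sxx - fitted_var, 0)
  df <- n - 2
  sigma2 <- rss / df
  se <- sqrt(sigma2 / syy)
  tstat <- beta / se
  pval <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  degenerate <- sxx <= .Machine$double.eps * n | !is.finite(tstat)
  beta[degenerate] <- 0
  tstat[degenerate] <- 0
  pval[degenerate] <- 1
  pval <- pmax(pval, .Machine$double.xmin)  # guard exact zeros for log10
  if (bh_scope == "joint") {
    padj <- bh_adjust(pval)
  } else {
    padj <- pval
    for (lab in unique(m$omics)) {
      idx <- m$omics == lab
      padj[idx] <- bh_adjust(pval[idx])
    }
  }
  d <- ifelse(tstat >= 0, 1, -1)
  res <- data.frame(
    molecule_id = feature_ids(m),
    omics_label = unname(m$omics),
    outcome_name = outcome_name,
    estimate = unname(beta),
    t_statistic = unname(tstat),
    p = unname(pval),
    p_adj = unname(padj),
    d = unname(d),
    p_score = unname(compute_p_score(padj, d)),
    n_used = n,
    degenerate = unname(degenerate),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Extract a fold-change signature from a binary-outcome analysis
#'
#' Molecules significant at the given FDR (strict `p_adj < fdr`) with
#' absolute log2 fold change at least `lfc_threshold` (inclusive), sorted by
#' decreasing absolute fold change.
#'
#' @param results data.frame from [fit_association()] on a binary outcome.
#' @param fdr FDR cut, default 0.05.
#' @param lfc_threshold absolute log2 fold-change cut, default 2 (inclusive).
#' @return the filtered, sorted subset of `results`.
#' @export
extract_signature <- function(results, fdr = 0.05, lfc_threshold = 2) {
  if (lfc_threshold < 0) stop("lfc_threshold must be >= 0", call. = FALSE)
  hit <- results$p_adj < fdr & abs(results$estimate) >= lfc_threshold
  out <- results[hit, , drop = FALSE]
  out[order(-abs(out$estimate)), , drop = FALSE]
}

#' Per-group clinical-manifestation association panel
#'
#' Runs [fit_association()] separately within each diagnosis group for each
#' of the four clinical outcomes (AKI, mortality, platelet count,
#' PaO2/FiO2): eight analyses, each with its own BH correction. A
#' group-by-outcome cell with fewer than 3 usable samples (or a constant
#' outcome) is skipped with a warning.
#'
#' @param m imputed `omics_matrix`.
#' @param samples sample table with the four outcome columns.
#' @param fdr significance threshold for the hit counts, default 0.05.
#' @return list with `results` (named list `group.outcome` -> results
#'   data.frame) and `hits` (data.frame of significant-molecule counts per
#'   analysis, split by omics layer).
#' @export
run_clinical_panel <- function(m, samples, fdr = 0.05) {
  outcomes <- c("aki", "mortality", "platelet_count", "pao2_fio2")
  miss <- setdiff(outcomes, names(samples))
  if (length(miss)) stop("sample table missing outcome(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  groups <- c("covid", "bacterial")
  results <- list()
  hits <- list()
  for (g in groups) {
    for (oc in outcomes) {
      key <- paste(g, oc, sep = ".")
      sub <- samples[samples$group == g & !is.na(samples[[oc]]), , drop = FALSE]
      res <- NULL
      if (nrow(sub) < 3) {
        warning("skipping ", key, ": fewer than 3 usable samples", call. = FALSE)
      } else if (length(unique(sub[[oc]])) < 2) {
        warning("skipping ", key, ": constant outcome", call. = FALSE)
      } else {
        res <- fit_association(m, samples, oc, subset_group = g)
      }
      results[[key]] <- res
      sig <- if (is.null(res)) res else res[res$p_adj < fdr, , drop = FALSE]
      hits[[key]] <- data.frame(
        group = g, outcome = oc,
        n_significant = if (is.null(sig)) NA_integer_ else nrow(sig),
        n_metabolites = if (is.null(sig)) NA_integer_ else
          sum(sig$omics_label == "metabolite"),
        n_proteins = if (is.null(sig)) NA_integer_ else
          sum(sig$omics_label == "protein"),
        skipped = is.null(res),
        stringsAsFactors = FALSE)
    }
  }
  list(results = results, hits = do.call(rbind, c(hits, list(make.row.names = FALSE))))
}
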