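#' Specification for a synthetic two-group multi-omic cohort
#'
#' Bundles every knob of the generator. Defaults emulate an unbalanced
#' two-etiology ARDS cohort: 42 vs 17 samples, lognormal abundances on top of
#' a sparse Gaussian graphical model spanning both omics layers, per-sample
#' urine-style dilution, a planted differential feature subset, planted
#' mortality-associated features, completely-at-random missingness and
#' optional duplicated protein assays.
#'
#' @param n_group_a samples in group A ("covid"); default 42.
#' @param n_group_b samples in group B ("bacterial"); default 17.
#' @param p_metabolites,p_proteins features per omics layer. Defaults (150,
#'   50) are a scaled-down stand-in for a 708 + 266 feature panel, sized so
#'   the full pipeline runs in seconds.
#' @param frac_differential fraction of features given a group-mean shift.
#' @param effect_size_log2 magnitude of the planted group shift, log2 units.
#' @param edge_density probability that a feature pair carries a planted
#'   precision-matrix edge.
#' @param partial_cor_strength magnitude of planted off-diagonal precision
#'   entries, in (0,1).
#' @param dilution_sigma log-scale SD of per-sample dilution factors.
#' @param missing_rate MCAR missingness probability per cell, in [0,1).
#' @param n_overfiltered_features extra features constructed to exceed the
#'   25% missingness threshold (appended; not part of the latent model).
#' @param duplicate_protein_pairs number of proteins that receive a noisy
#'   duplicate assay copy (additive N(0, 0.1^2) in log2 space).
#' @param n_outcome_features number of proteins given a planted mortality
#'   association (generator needs a count; not tied to any reported value).
#' @param outcome_effect_log2 per-SD logistic effect of planted outcome
#'   features on mortality, log-odds scale.
#' @param missing_mechanism `"mcar"` (default) or `"censor"` (missing =
#'   lowest abundance quantile of each feature).
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the spec including this seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_group_a = 42, n_group_b = 17,
                           p_metabolites = 150, p_proteins = 50,
                           frac_differential = 0.1, effect_size_log2 = 2,
                           edge_density = 0.02, partial_cor_strength = 0.3,
                           dilution_sigma = 0.5, missing_rate = 0.05,
                           n_overfiltered_features = 0,
                           duplicate_protein_pairs = 0,
                           n_outcome_features = 10,
                           outcome_effect_log2 = 2,
                           missing_mechanism = c("mcar", "censor"),
                           seed = 1L) {
  spec <- list(n_group_a = n_group_a, n_group_b = n_group_b,
               p_metabolites = p_metabolites, p_proteins = p_proteins,
               frac_differential = frac_differential,
               effect_size_log2 = effect_size_log2,
               edge_density = edge_density,
               partial_cor_strength = partial_cor_strength,
               dilution_sigma = dilution_sigma, missing_rate = missing_rate,
               n_overfiltered_features = n_overfiltered_features,
               duplicate_protein_pairs = duplicate_protein_pairs,
               n_outcome_features = n_outcome_features,
               outcome_effect_log2 = outcome_effect_log2,
               missing_mechanism = match.arg(missing_mechanism),
               seed = as.integer(seed))
  counts <- c("n_group_a", "n_group_b", "p_metabolites", "p_proteins",
              "n_overfiltered_features", "duplicate_protein_pairs",
              "n_outcome_features")
  for (f in counts)
    if (spec[[f]] < 0) stop("spec field '", f, "' must be >= 0", call. = FALSE)
  if (spec$frac_differential < 0 || spec$frac_differential > 1)
    stop("frac_differential must be in [0,1]", call. = FALSE)
  if (spec$missing_rate < 0 || spec$missing_rate >= 1)
    stop("missing_rate must be in [0,1)", call. = FALSE)
  if (spec$dilution_sigma < 0) stop("dilution_sigma must be >= 0", call. = FALSE)
  if (spec$edge_density > 0) {
    if (spec$edge_density >= 1) stop("edge_density must be in (0,1) or 0", call. = FALSE)
    if (spec$p_metabolites + spec$p_proteins < 3)
      stop("need p_metabolites + p_proteins >= 3 when edge_density > 0", call. = FALSE)
    if (spec$partial_cor_strength <= 0 || spec$partial_cor_strength >= 1)
      stop("partial_cor_strength must be in (0,1)", call. = FALSE)
  }
  if (spec$duplicate_protein_pairs > spec$p_proteins)
    stop("duplicate_protein_pairs cannot exceed p_proteins", call. = FALSE)
  class(spec) <- "synthetic_spec"
  spec
}

# Run code under a given seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Plant a sparse symmetric positive-definite precision matrix
#'
#' Edges are placed by an Erdős–Rényi draw over the `p(p-1)/2` pairs; each
#' planted off-diagonal entry is `+/- strength` with random sign. The
#' diagonal (initially 1) is then loaded uniformly until the matrix is
#' positive definite with condition number at most 1e3, which leaves the
#' zero pattern — and hence the set of exactly-zero partial correlations —
#' untouched.
#'
#' @param p number of variables (>= 2).
#' @param edge_density probability of an edge per pair, in (0,1].
#' @param strength magnitude of planted entries, in (0,1).
#' @param seed integer seed.
#' @return list with `omega` (p x p precision matrix) and `true_edges`
#'   (two-column integer matrix of i < j planted pairs).
#' @export
plant_precision_matrix <- function(p, edge_density, strength, seed = 1L) {
  if (p < 2) stop("p must be >= 2", call. = FALSE)
  if (edge_density <= 0 || edge_density > 1)
    stop("edge_density must be in (0,1]", call. = FALSE)
  if (strength <= 0 || strength >= 1)
    stop("strength must be in (0,1)", call. = FALSE)
  with_seed(seed, {
    pairs <- which(upper.tri(diag(p)), arr.ind = TRUE)
    on_edge <- stats::runif(nrow(pairs)) < edge_density
    edges <- pairs[on_edge, , drop = FALSE]
    omega <- diag(p)
    if (nrow(edges) > 0) {
      signs <- sample(c(-1, 1), nrow(edges), replace = TRUE)
      omega[edges] <- signs * strength
      omega[edges[, c(2, 1), drop = FALSE]] <- signs * strength
    }
    ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
    kappa_max <- 1e3
    # (max+d)/(min+d) <= kappa_max  =>  d >= (max - kappa_max*min)/(kappa_max-1)
    d <- max(0, (max(ev) - kappa_max * min(ev)) / (kappa_max - 1))
    if (d > 0) omega <- omega + (d + 1e-8) * diag(p)
    colnames(edges) <- c("i", "j")
    list(omega = omega, true_edges = edges)
  })
}

#' Generate a synthetic multi-omic cohort with planted ground truth
#'
#' Draws latent log2 abundances from the multivariate normal implied by a
#' planted sparse precision matrix, shifts group-B means on a known feature
#' subset, attaches clinical outcomes (mortality via a logistic link on
#' planted protein features; AKI, platelet count and PaO2/FiO2 without
#' molecular signal by default), exponentiates to the abundance scale,
#' multiplies in per-sample dilution factors `exp(N(0, dilution_sigma^2))`,
#' punches MCAR holes, appends over-filtered features (missingness forced
#' above 25%) and duplicated protein assays.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `matrix` (raw `omics_matrix`), `samples` (sample
#'   table) and `truth` (planted ground truth: `differential_features` named
#'   vector of signed log2 shifts, `true_edges` data.frame of feature-id
#'   pairs, `dilution_factors`, `outcome_features`, `duplicate_groups`).
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) spec <- do.call(synthetic_spec, spec)
  pm <- spec$p_metabolites; pp <- spec$p_proteins
  p <- pm + pp
  if (p < 1) stop("need at least one feature", call. = FALSE)
  n <- spec$n_group_a + spec$n_group_b
  fid <- c(sprintf("met_%03d", seq_len(pm)), sprintf("prot_%03d", seq_len(pp)))
  omics <- c(rep("metabolite", pm), rep("protein", pp))
  sid <- sprintf("S%02d", seq_len(n))
  group <- c(rep("covid", spec$n_group_a), rep("bacterial", spec$n_group_b))

  if (spec$edge_density > 0 && p >= 2) {
    pl <- plant_precision_matrix(p, spec$edge_density,
                                 spec$partial_cor_strength,
                                 seed = spec$seed + 1L)
    omega <- pl$omega
    true_edges <- data.frame(a = fid[pl$true_edges[, 1]],
                             b = fid[pl$true_edges[, 2]],
                             stringsAsFactors = FALSE)
  } else {
    omega <- diag(p)
    true_edges <- data.frame(a = character(), b = character(),
                             stringsAsFactors = FALSE)
  }

  with_seed(spec$seed, {
    sigma <- chol2inv(chol(omega))
    latent <- matrix(stats::rnorm(n * p), n, p) %*% chol(sigma)

    n_diff <- round(spec$frac_differential * p)
    diff_idx <- if (n_diff > 0) sort(sample.int(p, n_diff)) else integer()
    shifts <- stats::setNames(numeric(length(diff_idx)), fid[diff_idx])
    if (n_diff > 0) {
      shifts[] <- sample(c(-1, 1), n_diff, replace = TRUE) * spec$effect_size_log2
      b_rows <- which(group == "bacterial")
      latent[b_rows, diff_idx] <- latent[b_rows, diff_idx] +
        rep(shifts, each = length(b_rows))
    }

    # clinical outcomes: mortality carries the planted molecular signal
    n_out <- min(spec$n_outcome_features, p)
    out_idx <- if (n_out > 0) sort(sample.int(p, n_out, prob = c(
      rep(1, pm), rep(4, pp))[seq_len(p)])) else integer()
    mortality <- if (n_out > 0) {
      score <- rowSums(latent[, out_idx, drop = FALSE]) / sqrt(max(1, n_out))
      eta <- -1 + spec$outcome_effect_log2 * score
      stats::rbinom(n, 1, stats::plogis(eta))
    } else stats::rbinom(n, 1, 0.27)
    samples <- data.frame(
      sample_id = sid, group = group,
      aki = stats::rbinom(n, 1, 0.46),
      mortality = mortality,
      platelet_count = round(stats::rlnorm(n, log(220), 0.4)),
      pao2_fio2 = round(stats::runif(n, 60, 300), 1),
      stringsAsFactors = FALSE)

    base_mean <- 10   # raw abundances around 2^10
    dilution <- exp(stats::rnorm(n, 0, spec$dilution_sigma))
    abund <- t(2^(latent + base_mean)) * rep(dilution, each = p)  # p x n
    dimnames(abund) <- list(fid, sid)

    # duplicated protein assays: noisy copies in log2 space, SD 0.1
    dup_groups <- character()
    if (spec$duplicate_protein_pairs > 0) {
      dup_of <- fid[pm + sort(sample.int(pp, spec$duplicate_protein_pairs))]
      dup_ids <- paste0(dup_of, "_dup")
      noise <- matrix(stats::rnorm(length(dup_of) * n, 0, 0.1),
                      length(dup_of), n)
      dup_vals <- abund[dup_of, , drop = FALSE] * 2^noise
      rownames(dup_vals) <- dup_ids
      abund <- rbind(abund, dup_vals)
      omics <- c(omics, rep("protein", length(dup_ids)))
      dup_groups <- stats::setNames(c(dup_of, dup_of), c(dup_of, dup_ids))
    }

    # over-filtered features: appended, built to fail the 25% rule
    if (spec$n_overfiltered_features > 0) {
      of_ids <- sprintf("overfilt_%03d", seq_len(spec$n_overfiltered_features))
      of_vals <- matrix(2^(stats::rnorm(spec$n_overfiltered_features * n,
                                        base_mean, 1)),
                        spec$n_overfiltered_features, n,
                        dimnames = list(of_ids, sid))
      abund <- rbind(abund, of_vals)
      omics <- c(omics, rep("metabolite", spec$n_overfiltered_features))
    }

    # missingness
    if (spec$missing_rate > 0) {
      if (spec$missing_mechanism == "mcar") {
        holes <- matrix(stats::runif(length(abund)) < spec$missing_rate,
                        nrow(abund), ncol(abund))
      } else {
        qcut <- apply(abund, 1, stats::quantile, probs = spec$missing_rate)
        holes <- abund <= qcut
      }
      # keep every feature observed at least once
      all_gone <- rowSums(!holes) == 0
      holes[all_gone, 1] <- FALSE
      abund[holes] <- NA_real_
    }
    if (spec$n_overfiltered_features > 0) {
      of_rows <- grep("^overfilt_", rownames(abund))
      thr <- floor(0.25 * n) + 1   # strictly more than 25% missing
      for (r in of_rows) {
        n_miss_extra <- min(n - 1, thr + stats::rpois(1, 2))
        abund[r, sample.int(n, n_miss_extra)] <- NA_real_
      }
    }

    truth <- list(differential_features = shifts,
                  true_edges = true_edges,
                  dilution_factors = stats::setNames(dilution, sid),
                  outcome_features = fid[out_idx],
                  duplicate_groups = dup_groups)
    list(matrix = omics_matrix(abund, omics, "raw"),
         samples = samples, truth = truth)
  })
}

#' Write a generated cohort to a directory as TSV
#'
#' Emits `matrix.tsv`, `samples.tsv` and plain-text truth tables
#' (`truth_differential.tsv`, `truth_edges.tsv`, `truth_dilution.tsv`,
#' `truth_outcome_features.tsv`, `truth_duplicates.tsv`).
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(cohort$matrix, file.path(dir, "matrix.tsv"))
  write_sample_table(cohort$samples, file.path(dir, "samples.tsv"))
  tr <- cohort$truth
  utils::write.table(
    data.frame(feature_id = names(tr$differential_features),
               shift_log2 = unname(tr$differential_features)),
    file.path(dir, "truth_differential.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tr$true_edges, file.path(dir, "truth_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(tr$dilution_factors),
               dilution = unname(tr$dilution_factors)),
    file.path(dir, "truth_dilution.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(feature_id = tr$outcome_features),
    file.path(dir, "truth_outcome_features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(assay_id = names(tr$duplicate_groups),
               canonical_id = unname(tr$duplicate_groups)),
    file.path(dir, "truth_duplicates.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
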