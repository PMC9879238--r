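#' Analytic shrinkage estimate of the correlation matrix
#'
#' Computes the sample correlation of the (feature-standardized) data and
#' shrinks it toward the identity with the analytic intensity
#' \deqn{\lambda^* = \sum_{i<j} \widehat{Var}(r_{ij}) / \sum_{i<j} r_{ij}^2,}
#' clipped to [0, 1], where the variance of each sample correlation is the
#' usual unbiased-moment estimate from the per-sample products of the
#' standardized variables. The shrunk matrix
#' `R* = (1 - lambda) R + lambda I` is positive definite whenever
#' `lambda > 0`, which makes the partial-correlation step well defined even
#' for p >> n.
#'
#' @param m imputed `omics_matrix` with no missing values, or a plain
#'   samples x features numeric matrix.
#' @param lambda optional fixed shrinkage intensity overriding the analytic
#'   value (0 disables shrinkage; only sensible for n > p).
#' @return object of class `shrinkage_estimate`: `correlation` (shrunk
#'   matrix `R*`), `sample_correlation`, `lambda_star`, `n`, and later
#'   `partial_cor` (see [partial_correlations()]).
#' @export
shrinkage_correlation <- function(m, lambda = NULL) {
  if (inherits(m, "omics_matrix")) {
    assert_scale(m, "imputed", "shrinkage_correlation")
    if (anyNA(m$values)) stop("matrix still contains missing values", call. = FALSE)
    x <- t(m$values)                      # samples x features
    omics <- m$omics
  } else {
    x <- as.matrix(m)
    omics <- NULL
  }
  n <- nrow(x); p <- ncol(x)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance feature(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  xs <- scale(x)                          # mean 0, sd 1 (denominator n-1)
  r <- crossprod(xs) / (n - 1)
  # Var-hat of each r_ij from the centered products w_k = x_ki * x_kj:
  #   Var(r_ij) = n / (n-1)^3 * sum_k (w_k - wbar)^2
  sw  <- crossprod(xs)                    # sum_k w_k  = (n-1) r
  sw2 <- crossprod(xs^2)                  # sum_k w_k^2
  varr <- n / (n - 1)^3 * (sw2 - sw^2 / n)
  off <- upper.tri(r)
  denom <- sum(r[off]^2)
  lambda_star <- if (is.null(lambda)) {
    if (denom <= 0) 1 else min(1, max(0, sum(varr[off]) / denom))
  } else {
    if (lambda < 0 || lambda > 1) stop("lambda must be in [0,1]", call. = FALSE)
    lambda
  }
  rstar <- (1 - lambda_star) * r
  diag(rstar) <- 1
  structure(list(correlation = rstar, sample_correlation = r,
                 lambda_star = lambda_star, n = n, p = p,
                 omics = omics, partial_cor = NULL),
            class = "shrinkage_estimate")
}

#' @export
print.shrinkage_estimate <- function(x, ...) {
  cat(sprintf("<shrinkage_estimate> p = %d, n = %d, lambda* = %.4f%s\n",
              x$p, x$n, x$lambda_star,
              if (is.null(x$partial_cor)) "" else ", partial correlations ready"))
  invisible(x)
}

#' Partial correlations from a (shrunk) correlation matrix
#'
#' Inverts the shrunk correlation matrix `R*` and scales the precision
#' matrix to partial correlations
#' `pcor[i, j] = -Omega[i, j] / sqrt(Omega[i, i] * Omega[j, j])`.
#' A pair's partial correlation is zero exactly when its precision entry is
#' zero, i.e. when the two variables are conditionally independent given all
#' others under the Gaussian model.
#'
#' @param est a `shrinkage_estimate` from [shrinkage_correlation()].
#' @return `est` with `partial_cor` filled (unit diagonal).
#' @export
partial_correlations <- function(est) {
  stopifnot(inherits(est, "shrinkage_estimate"))
  ch <- tryCatch(chol(est$correlation), error = function(e) NULL)
  if (is.null(ch))
    stop("shrunk correlation matrix is singular; use nonzero shrinkage ",
         "(lambda_star = 0 with p >= n cannot be inverted)", call. = FALSE)
  omega <- chol2inv(ch)
  dsq <- sqrt(diag(omega))
  pcor <- -omega / tcrossprod(dsq)
  diag(pcor) <- 1
  pcor <- (pcor + t(pcor)) / 2
  dimnames(pcor) <- dimnames(est$correlation)
  est$partial_cor <- pcor
  est
}

# Null density of a sample partial correlation with kappa effective df:
#   f0(r; kappa) = (1 - r^2)^((kappa - 3) / 2) / Beta(1/2, (kappa - 1)/2)
# so r^2 ~ Beta(1/2, (kappa - 1)/2) under the null.
dnull_pcor <- function(r, kappa, log = FALSE) {
  ld <- (kappa - 3) / 2 * log1p(-r^2) - lbeta(0.5, (kappa - 1) / 2)
  if (log) ld else exp(ld)
}

pnull_pcor <- function(r, kappa) {
  # two-sided tail P(|R| >= |r|)
  stats::pbeta(r^2, 0.5, (kappa - 1) / 2, lower.tail = FALSE)
}

# Fit the null width kappa (and null fraction eta0) by maximizing the
# likelihood of a two-component mixture: eta0 * f0(r; kappa) + (1-eta0)/2
# (uniform alternative on [-1, 1]). Deterministic nested bounded search,
# kappa bracketed in [3, 1e6].
fit_kappa <- function(pcors, bracket = c(3, 1e6)) {
  r <- pcors[abs(pcors) < 1]
  if (length(r) < 10)
    stop("too few partial correlations to fit the null (need >= 10)", call. = FALSE)
  prof <- function(log_kappa) {
    kappa <- exp(log_kappa)
    f0 <- dnull_pcor(r, kappa)
    nll <- function(eta0) -sum(log(eta0 * f0 + (1 - eta0) * 0.5))
    opt <- stats::optimize(nll, c(1e-6, 1))
    c(nll = opt$objective, eta0 = opt$minimum)
  }
  opt <- stats::optimize(function(lk) prof(lk)[["nll"]],
                         log(bracket))
  kappa <- exp(opt$minimum)
  eta0 <- prof(opt$minimum)[["eta0"]]
  if (!is.finite(kappa) || kappa < bracket[1])
    stop("kappa fit failed to converge (kappa = ", kappa, ")", call. = FALSE)
  list(kappa = kappa, eta0 = eta0)
}

#' FDR-controlled edge selection for the Gaussian graphical model
#'
#' Tests every unordered feature pair against the null distribution of
#' partial correlations, `f0(r; kappa) ~ (1 - r^2)^((kappa-3)/2)`, with the
#' effective degrees-of-freedom parameter `kappa` fitted by maximum
#' likelihood of a null + uniform-alternative mixture on the observed
#' partial-correlation distribution. Two-sided p-values are corrected either
#' by Benjamini-Hochberg (`method = "bh"`, default) or by an empirical
#' tail-area FDR (`method = "efdr"`: fitted null fraction times the null
#' tail probability over the empirical tail frequency, monotonized — the
#' flavor of q-value used by classic GGM packages). Pairs below the `fdr`
#' cut become edges.
#'
#' @param est a `shrinkage_estimate` with `partial_cor` filled.
#' @param fdr edge FDR threshold, default 0.05 (strict `<`).
#' @param method `"bh"` or `"efdr"`.
#' @return object of class `ggm_network`: `nodes` (id, omics, p_score --
#'   NA until [annotate_network()]), `edges` (source, target, pcor, p,
#'   p_adj, sorted by p), plus `fdr`, `method`, `kappa`, `eta0`,
#'   `lambda_star`.
#' @export
edge_significance <- function(est, fdr = 0.05, method = c("bh", "efdr")) {
  stopifnot(inherits(est, "shrinkage_estimate"))
  method <- match.arg(method)
  if (is.null(est$partial_cor))
    stop("call partial_correlations() first", call. = FALSE)
  pc <- est$partial_cor
  p <- ncol(pc)
  if (p * (p - 1) / 2 < 10)
    stop("need at least 10 feature pairs", call. = FALSE)
  idx <- which(upper.tri(pc), arr.ind = TRUE)
  r <- pc[idx]
  ids <- colnames(pc)
  if (is.null(ids)) ids <- sprintf("V%d", seq_len(p))
  if (all(abs(r) < 1e-12)) {
    pval <- rep(1, length(r)); padj <- pval
    kappa <- NA_real_; eta0 <- 1
  } else {
    fit <- fit_kappa(r)
    kappa <- fit$kappa; eta0 <- fit$eta0
    pval <- pnull_pcor(r, kappa)
    if (method == "bh") {
      padj <- bh_adjust(pmax(pval, .Machine$double.xmin))
    } else {
      # tail-area empirical FDR: eta0 * P0(|R| >= t) / Phat(|R| >= t)
      m_pairs <- length(r)
      ord <- order(abs(r), decreasing = TRUE)
      tailfrac <- seq_along(r) / m_pairs
      q <- eta0 * pval[ord] / tailfrac
      q <- rev(cummin(rev(pmin(q, 1))))   # monotone in |r|
      padj <- numeric(m_pairs)
      padj[ord] <- q
    }
  }
  sel <- padj < fdr
  edges <- data.frame(source = ids[idx[sel, 1]], target = ids[idx[sel, 2]],
                      pcor = r[sel], p = pval[sel], p_adj = padj[sel],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$p, edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  omics <- if (is.null(est$omics)) rep(NA_character_, p) else unname(est$omics[ids])
  nodes <- data.frame(id = ids, omics = omics, p_score = NA_real_,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, fdr = fdr, method = method,
                 kappa = kappa, eta0 = eta0, lambda_star = est$lambda_star),
            class = "ggm_network")
}

#' @export
print.ggm_network <- function(x, ...) {
  cat(sprintf("<ggm_network> %d nodes, %d edges (FDR < %g, %s)\n",
              nrow(x$nodes), nrow(x$edges), x$fdr, x$method))
  invisible(x)
}

#' Annotate network nodes with differential-analysis scores
#'
#' Attaches each molecule's signed significance score (`p_score`) from a
#' differential analysis to the corresponding node. Topology is unchanged;
#' nodes without a result keep a missing annotation.
#'
#' @param network a `ggm_network`.
#' @param results data.frame from [fit_association()] (typically the
#'   diagnosis contrast).
#' @return the annotated `ggm_network`.
#' @export
annotate_network <- function(network, results) {
  stopifnot(inherits(network, "ggm_network"))
  lookup <- stats::setNames(results$p_score, results$molecule_id)
  network$nodes$p_score <- unname(lookup[network$nodes$id])
  network
}

#' Infer the full multi-omic network in one call
#'
#' Convenience wrapper: shrinkage correlation, partial correlations, edge
#' selection and (optionally) node annotation.
#'
#' @param m imputed `omics_matrix`.
#' @param results optional differential results for node annotation.
#' @param fdr edge FDR threshold, default 0.05.
#' @param method edge FDR flavor, `"bh"` or `"efdr"`.
#' @param lambda optional fixed shrinkage intensity.
#' @return a `ggm_network`.
#' @export
infer_network <- function(m, results = NULL, fdr = 0.05,
                          method = c("bh", "efdr"), lambda = NULL) {
  est <- shrinkage_correlation(m, lambda = lambda)
  est <- partial_correlations(est)
  net <- edge_significance(est, fdr = fdr, method = match.arg(method))
  if (!is.null(results)) net <- annotate_network(net, results)
  net
}
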