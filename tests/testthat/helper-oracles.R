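# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own code paths.

# brute-force BH step-up: literal textbook procedure, O(m^2) monotonization
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    # adjusted value at rank i = min over j >= i of p_(j) * m / j, capped at 1
    js <- i:m
    adj[ord[i]] <- min(1, min(p[ord[js]] * m / js))
  }
  adj
}

# pooled-variance two-sample t-test returning (estimate, t, p)
pooled_t <- function(x0, x1) {
  n0 <- length(x0); n1 <- length(x1)
  sp2 <- ((n0 - 1) * stats::var(x0) + (n1 - 1) * stats::var(x1)) / (n0 + n1 - 2)
  est <- mean(x1) - mean(x0)
  tt <- est / sqrt(sp2 * (1 / n0 + 1 / n1))
  p <- 2 * stats::pt(abs(tt), n0 + n1 - 2, lower.tail = FALSE)
  c(estimate = est, t = tt, p = p)
}

# brute-force partial correlations by direct inversion of a covariance matrix
pcor_brute <- function(sigma) {
  om <- solve(sigma)
  pc <- -om / sqrt(outer(diag(om), diag(om)))
  diag(pc) <- 1
  pc
}

# tiny raw omics matrix with given values (features x samples)
toy_matrix <- function(values, omics = "metabolite", scale_state = "raw") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("f%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  omics_matrix(values, omics, scale_state)
}

# promote a plain matrix straight to "imputed" for association tests
toy_imputed <- function(values, omics = "metabolite") {
  m <- toy_matrix(2^values)          # positive on raw scale
  m$values <- values
  m$scale_state <- "imputed"
  m
}

# hand-built network from an edge list (no statistics needed)
toy_network <- function(edges, nodes = NULL) {
  k <- nrow(edges)
  e <- data.frame(source = as.character(edges[, 1]),
                  target = as.character(edges[, 2]),
                  pcor = rep(0.5, k), p = rep(1e-4, k), p_adj = rep(1e-3, k),
                  stringsAsFactors = FALSE)
  ids <- if (is.null(nodes)) sort(unique(c(e$source, e$target))) else nodes
  structure(list(
    nodes = data.frame(id = ids, omics = "metabolite", p_score = NA_real_,
                       stringsAsFactors = FALSE),
    edges = e, fdr = 0.05, method = "bh",
    kappa = NA_real_, eta0 = NA_real_, lambda_star = NA_real_),
    class = "ggm_network")
}

toy_samples <- function(n0, n1, seed = 1) {
  n <- n0 + n1
  set.seed(seed)
  data.frame(sample_id = sprintf("s%02d", seq_len(n)),
             group = c(rep("covid", n0), rep("bacterial", n1)),
             aki = rbinom(n, 1, 0.5), mortality = rbinom(n, 1, 0.3),
             platelet_count = round(rlnorm(n, log(200), 0.3)),
             pao2_fio2 = round(runif(n, 80, 300), 1),
             stringsAsFactors = FALSE)
}
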