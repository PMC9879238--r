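test_that("filter_missingness uses strict >25% semantics at n=59", {
  set.seed(1)
  v <- matrix(rlnorm(3 * 59), 3, 59,
              dimnames = list(c("removed15", "kept14", "complete"),
                              sprintf("s%02d", 1:59)))
  v["removed15", 1:15] <- NA   # 15/59 = 25.4% > 25%
  v["kept14", 1:14] <- NA      # 14/59 = 23.7%
  m <- omics_matrix(v, "metabolite")
  out <- filter_missingness(m)
  expect_setequal(rownames(out$values), c("kept14", "complete"))
  rem <- attr(out, "removed")
  expect_equal(rem$feature_id, "removed15")
  expect_equal(rem$missing_frac, 15 / 59)

  # exact boundary kept: 1/4 missing at threshold 0.25
  v2 <- matrix(rlnorm(8), 2, 4,
               dimnames = list(c("a", "b"), paste0("s", 1:4)))
  v2[1, 1] <- NA
  out2 <- filter_missingness(omics_matrix(v2, "protein"))
  expect_equal(nrow(out2$values), 2)

  # identity on complete matrices, and idempotence
  m3 <- toy_matrix(matrix(rlnorm(20), 4, 5))
  f1 <- filter_missingness(m3)
  expect_equal(f1$values, m3$values)
  # removing every feature is an explicit error
  v3 <- matrix(c(1, NA, NA, NA), 2, 2,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(filter_missingness(omics_matrix(v3, "metabolite")),
               "all features")
})

test_that("pqn_normalize matches hand computation and is idempotent", {
  # sample2 = 2 * sample1: median quotient of s2 must be 2
  v <- matrix(c(2, 4, 8, 4, 8, 16), 3, 2,
              dimnames = list(c("f1", "f2", "f3"), c("s1", "s2")))
  m <- omics_matrix(v, "metabolite")
  out <- pqn_normalize(m)
  qm <- attr(out, "quotient_medians")
  # reference = rowMedians = (3, 6, 12); quotients s1 = 2/3, s2 = 4/3
  expect_equal(unname(qm), c(2 / 3, 4 / 3))
  expect_equal(qm[["s2"]] / qm[["s1"]], 2)
  expect_equal(out$values[, "s1"], out$values[, "s2"])
  expect_equal(out$scale_state, "normalized")

  # idempotence against the same reference: quotient medians of exactly 1
  out$scale_state <- "raw"  # re-enter the chain for the check
  out2 <- pqn_normalize(out, reference = attr(out, "reference"))
  expect_equal(unname(attr(out2, "quotient_medians")), c(1, 1),
               tolerance = 1e-10)
  expect_equal(out2$values, out$values, tolerance = 1e-10)
  # without a fixed reference the toy is symmetric enough to stay put too
  out3 <- pqn_normalize(out)
  expect_equal(out3$values, out$values, tolerance = 1e-10)

  # missing values are ignored pairwise
  v[1, 2] <- NA
  outm <- pqn_normalize(omics_matrix(v, "metabolite"))
  expect_true(is.na(outm$values[1, 2]))

  expect_error(pqn_normalize(omics_matrix(
    matrix(c(1, 2), 1, 2, dimnames = list("f", c("a", "b"))), "metabolite")),
    "< 2 features")
})

test_that("pqn recovers planted dilution factors on synthetic data", {
  co <- generate_cohort(synthetic_spec(seed = 3, p_metabolites = 400,
                                       p_proteins = 100, dilution_sigma = 0.5,
                                       missing_rate = 0.05))
  norm <- pqn_normalize(filter_missingness(co$matrix))
  qm <- attr(norm, "quotient_medians")
  r <- stats::cor(qm, co$truth$dilution_factors[names(qm)])
  expect_gt(r, 0.99)
})

test_that("log2_transform is elementwise and guards the chain", {
  v <- matrix(c(8, 1, 0.5, NA), 2, 2,
              dimnames = list(c("a", "b"), c("x", "y")))
  m <- omics_matrix(v, "metabolite")
  expect_error(log2_transform(m), "scale_state")  # raw, not normalized
  m$scale_state <- "normalized"
  out <- log2_transform(m)
  expect_equal(out$values[1, 1], 3)
  expect_equal(out$values[2, 1], 0)
  expect_equal(out$values[1, 2], -1)
  expect_true(is.na(out$values[2, 2]))
  expect_equal(out$scale_state, "log2")
})

test_that("knn_impute: exact-neighbor case, preservation, and beats mean imputation", {
  # three identical features: the hole must be filled with their shared value
  v <- matrix(rep(c(1, 2, 3, 4), each = 3), 3, 4,
              dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
  v[1, 2] <- NA
  m <- toy_matrix(2^v); m$values <- v; m$scale_state <- "log2"
  out <- knn_impute(m, k = 2)
  expect_equal(out$values[1, 2], 2)
  expect_equal(out$values[-1, ], v[-1, ])  # observed untouched, bit-exact
  expect_equal(out$scale_state, "imputed")

  # identity on complete data
  m2 <- toy_matrix(2^v[, , drop = FALSE]); m2$values <- v; m2$values[1, 2] <- 2.5
  m2$scale_state <- "log2"
  expect_equal(knn_impute(m2)$values, m2$values)

  # correlated features, 5% MCAR: kNN beats per-feature mean imputation
  set.seed(42)
  p <- 60; n <- 40
  base <- matrix(rnorm(5 * n), 5, n)
  truth <- base[sample(5, p, replace = TRUE), ] + matrix(rnorm(p * n, 0, 0.3), p, n)
  dimnames(truth) <- list(sprintf("f%02d", 1:p), sprintf("s%02d", 1:n))
  holes <- matrix(runif(p * n) < 0.05, p, n)
  holes[rowSums(!holes) == 0, 1] <- FALSE
  obs <- truth; obs[holes] <- NA
  m3 <- toy_matrix(2^truth); m3$values <- obs; m3$scale_state <- "log2"
  imp <- knn_impute(m3, k = 10)
  rmse_knn <- sqrt(mean((imp$values[holes] - truth[holes])^2))
  mean_imp <- obs
  for (f in seq_len(p)) mean_imp[f, is.na(obs[f, ])] <- mean(obs[f, ], na.rm = TRUE)
  rmse_mean <- sqrt(mean((mean_imp[holes] - truth[holes])^2))
  expect_lt(rmse_knn, rmse_mean)

  # entirely-missing feature is an error
  v4 <- v; v4[1, ] <- NA
  m4 <- toy_matrix(2^v); m4$values <- v4; m4$scale_state <- "log2"
  expect_error(knn_impute(m4), "entirely missing")
})

test_that("average_duplicates collapses groups by arithmetic mean", {
  v <- matrix(c(4, 6, 10, 2, 8, 12), 3, 2,
              dimnames = list(c("IL-6_a", "IL-6_b", "CRP"), c("s1", "s2")))
  m <- omics_matrix(v, "protein", "raw")
  out <- average_duplicates(m, c("IL-6_a" = "IL-6", "IL-6_b" = "IL-6"))
  expect_setequal(rownames(out$values), c("IL-6", "CRP"))
  expect_equal(unname(out$values["IL-6", ]), c(5, 5))
  expect_equal(out$values["CRP", ], v["CRP", ])

  # group of one is renamed but unchanged
  out1 <- average_duplicates(m, c("CRP" = "CRP"))
  expect_equal(out1$values, v)

  expect_error(average_duplicates(m, c("nope" = "x")), "unknown feature")

  # the conventional duplicate panel covers 10 proteins
  dd <- default_duplicate_proteins()
  expect_equal(length(unique(unname(dd))), 10)
  expect_true(all(c("IL-6", "FGF-21", "uPA") %in% dd))
})

test_that("pipeline order is enforced and the full chain runs", {
  co <- generate_cohort(synthetic_spec(seed = 2, p_metabolites = 40,
                                       p_proteins = 20,
                                       duplicate_protein_pairs = 2,
                                       n_overfiltered_features = 3))
  expect_error(pqn_normalize(preprocess_pipeline(co$matrix)$matrix),
               "scale_state")
  expect_error(knn_impute(co$matrix), "scale_state")
  pp <- preprocess_pipeline(co$matrix,
                            duplicate_groups = co$truth$duplicate_groups)
  expect_equal(pp$matrix$scale_state, "imputed")
  expect_false(anyNA(pp$matrix$values))
  expect_equal(nrow(pp$matrix$values), 60)  # 63 kept - 3 collapsed? see below
  # 40 + 20 core + 2 dups + 3 overfiltered = 65 raw; 3 overfiltered removed;
  # 2 duplicate pairs collapse 4 rows to 2 -> 60
  expect_equal(nrow(pp$qc$removed), 3)
})
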