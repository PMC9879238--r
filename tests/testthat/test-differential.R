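test_that("bh_adjust matches hand examples and the brute-force oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.5, 7)), rep(0.5, 7))  # ties collapse to p*m/m
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(7)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_brute(p), tolerance = 1e-14)
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-14)
  }
})

test_that("compute_p_score follows the signed -log10 formula", {
  expect_equal(compute_p_score(0.01, 1), 2)
  expect_equal(compute_p_score(0.01, -1), -2)
  expect_equal(compute_p_score(1, 1), 0)
  expect_equal(compute_p_score(1, -1), 0)
  expect_error(compute_p_score(0, 1), "floor")
  expect_error(compute_p_score(0.5, 0), "-1 or \\+1")
})

test_that("fit_association on a 0/1 outcome equals the pooled-variance t-test", {
  # 6-sample toy with group means 4 and 6: estimate must be exactly 2
  v <- rbind(f1 = c(3.5, 4.0, 4.5, 5.5, 6.0, 6.5))
  colnames(v) <- sprintf("s%02d", 1:6)
  m <- toy_imputed(v)
  st <- data.frame(sample_id = colnames(v),
                   group = c(rep("bacterial", 3), rep("covid", 3)),
                   stringsAsFactors = FALSE)
  res <- fit_association(m, st, "group")
  orc <- pooled_t(v[1, 1:3], v[1, 4:6])
  expect_equal(res$estimate, unname(orc["estimate"]), tolerance = 1e-12)
  expect_equal(res$estimate, 2)
  expect_equal(res$t_statistic, unname(orc["t"]), tolerance = 1e-10)
  expect_equal(res$p, unname(orc["p"]), tolerance = 1e-10)
  expect_equal(res$d, sign(res$estimate))
  expect_equal(res$p_score, -log10(res$p_adj) * res$d)
  expect_equal(res$n_used, 6)

  # random toys, both directions, unequal group sizes
  set.seed(11)
  for (i in 1:10) {
    n0 <- sample(3:8, 1); n1 <- sample(3:8, 1)
    x <- rnorm(n0 + n1)
    v <- rbind(f1 = x); colnames(v) <- sprintf("s%02d", seq_len(n0 + n1))
    st <- data.frame(sample_id = colnames(v),
                     group = c(rep("bacterial", n0), rep("covid", n1)))
    res <- fit_association(toy_imputed(v), st, "group")
    orc <- pooled_t(x[1:n0], x[-(1:n0)])
    expect_equal(res$p, unname(orc["p"]), tolerance = 1e-10)
    expect_equal(res$estimate, unname(orc["estimate"]), tolerance = 1e-10)
  }
})

test_that("null molecules show nominal type-I error and constant ones p = 1", {
  set.seed(3)
  n <- 59; p <- 1000
  v <- matrix(rnorm(p * n), p, n,
              dimnames = list(sprintf("f%04d", 1:p), sprintf("s%02d", 1:n)))
  m <- toy_imputed(v)
  st <- data.frame(sample_id = colnames(v),
                   group = c(rep("covid", 42), rep("bacterial", 17)))
  res <- fit_association(m, st, "group")
  # binomial Monte-Carlo error at p = 1000 draws: 3 SE ~ 0.02
  expect_lt(abs(mean(res$p < 0.05) - 0.05), 0.02)
  expect_lt(abs(mean(res$p < 0.5) - 0.5), 0.05)

  v2 <- v; v2[1, ] <- 3  # constant molecule
  res2 <- fit_association(toy_imputed(v2), st, "group")
  expect_equal(res2$p[1], 1)
  expect_equal(res2$estimate[1], 0)
  expect_true(res2$degenerate[1])

  st$group <- "covid"
  expect_error(fit_association(m, st, "group"), "constant")
})

test_that("continuous outcomes use the regression slope and subsetting works", {
  set.seed(5)
  st <- toy_samples(8, 6)
  n <- nrow(st)
  v <- rbind(f1 = 0.02 * st$platelet_count + rnorm(n, 0, 0.1),
             f2 = rnorm(n))
  colnames(v) <- st$sample_id
  m <- toy_imputed(v)
  res <- fit_association(m, st, "platelet_count")
  lmfit <- summary(lm(v[1, ] ~ st$platelet_count))$coefficients
  expect_equal(res$estimate[1], lmfit[2, 1], tolerance = 1e-10)
  expect_equal(res$p[1], lmfit[2, 4], tolerance = 1e-10)

  sub <- fit_association(m, st, "platelet_count", subset_group = "covid")
  expect_equal(unique(sub$n_used), 8)

  # per-omics BH scope adjusts within layers
  m2 <- m; m2$omics[] <- c("metabolite", "protein")
  joint <- fit_association(m2, st, "platelet_count")
  per <- fit_association(m2, st, "platelet_count", bh_scope = "per_omics")
  expect_equal(per$p_adj, per$p)  # single molecule per layer -> no correction
  expect_equal(joint$p_adj, bh_brute(joint$p))
})

test_that("extract_signature applies strict FDR and inclusive LFC bounds", {
  res <- data.frame(molecule_id = c("a", "b", "c", "d"),
                    estimate = c(2.0, -5, 1.9, 3),
                    p_adj = c(0.01, 0.10, 0.01, 0.04))
  sig <- extract_signature(res)
  expect_equal(sig$molecule_id, c("d", "a"))  # b fails FDR, c fails LFC
  expect_error(extract_signature(res, lfc_threshold = -1), ">= 0")
})

test_that("planted differential features are recovered with controlled FDR", {
  sens <- fdp <- numeric(5)
  for (s in 1:5) {
    co <- generate_cohort(synthetic_spec(seed = 100 + s, effect_size_log2 = 3,
                                         frac_differential = 0.1))
    pp <- preprocess_pipeline(co$matrix)
    res <- fit_association(pp$matrix, co$samples, "group")
    hits <- res$molecule_id[res$p_adj < 0.05]
    truth <- names(co$truth$differential_features)
    sens[s] <- mean(truth %in% hits)
    fdp[s] <- if (length(hits)) mean(!hits %in% truth) else 0
  }
  expect_gt(mean(sens), 0.9)
  expect_lte(mean(fdp), 0.1)
})

test_that("run_clinical_panel runs eight analyses and recovers planted outcome signal", {
  co <- generate_cohort(synthetic_spec(seed = 21, outcome_effect_log2 = 3,
                                       n_outcome_features = 8))
  pp <- preprocess_pipeline(co$matrix)
  panel <- suppressWarnings(run_clinical_panel(pp$matrix, co$samples))
  expect_equal(nrow(panel$hits), 8)
  hits <- panel$hits
  mort_covid <- hits$n_significant[hits$group == "covid" &
                                   hits$outcome == "mortality"]
  plat_covid <- hits$n_significant[hits$group == "covid" &
                                   hits$outcome == "platelet_count"]
  expect_gt(mort_covid, 0)
  expect_lte(plat_covid, 2)  # no planted platelet signal

  # a cell with < 3 usable samples is skipped with a warning
  st <- co$samples
  st$aki[st$group == "bacterial"] <- NA
  expect_warning(run_clinical_panel(pp$matrix, st), "bacterial.aki")
})
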