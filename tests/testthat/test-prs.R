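test_that("race/ethnicity routing: Hispanic dominates, sparse groups fall back to NH White", {
  expect_equal(assign_prs_group("black", hispanic = TRUE), "hispanic")
  expect_equal(assign_prs_group("unknown", hispanic = FALSE), "nh_white")
  expect_equal(assign_prs_group("white", hispanic = FALSE), "nh_white")
  expect_equal(
    assign_prs_group(c("asian", "native_hawaiian", "pacific_islander",
                       "black", "american_indian_alaska_native", "other",
                       "mixed"), hispanic = FALSE),
    c("nh_asian", "nh_asian", "nh_asian", "nh_black", "nh_white",
      "nh_white", "nh_white"))
  expect_equal(assign_prs_group(NA, hispanic = FALSE), "nh_white")
  expect_error(assign_prs_group("martian", hispanic = FALSE), "martian")
  expect_equal(assign_prs_group("martian", hispanic = TRUE), "hispanic")
})

test_that("Hardy-Weinberg genotype distribution is the binomial expansion", {
  expect_equal(hwe_genotype_distribution(0), c(d0 = 1, d1 = 0, d2 = 0))
  expect_equal(hwe_genotype_distribution(0.3),
               c(d0 = 0.49, d1 = 0.42, d2 = 0.09))
  expect_equal(hwe_genotype_distribution(0.5),
               c(d0 = 0.25, d1 = 0.5, d2 = 0.25))
  p <- seq(0, 1, by = 0.05)
  expect_equal(unname(rowSums(hwe_genotype_distribution(p))), rep(1, length(p)))
  expect_error(hwe_genotype_distribution(1.2), "frequency")
})

test_that("per-SNP mean relative risk enumerates the three genotype classes", {
  expect_equal(snp_mean_relative_risk(1, 0.3), 1)
  expect_equal(snp_mean_relative_risk(1, 0.77), 1)
  expect_equal(snp_mean_relative_risk(2, 0.3), 1.69)
  expect_equal(snp_mean_relative_risk(0.8, 0.5), 0.81)
  # independent oracle: expectation of OR^g over the HWE distribution
  for (case in list(c(1.4, 0.12), c(0.7, 0.6), c(2.3, 0.91))) {
    pr <- hwe_genotype_distribution(case[2])
    expect_equal(snp_mean_relative_risk(case[1], case[2]),
                 sum(pr * case[1]^(0:2)))
  }
  expect_error(snp_mean_relative_risk(-1, 0.5), "odds ratio")
  expect_error(snp_mean_relative_risk(2, 0), "frequency")
})

test_that("normalized per-SNP factor is OR^g/mu with neutral missing fill", {
  expect_equal(snp_adjusted_risk(NA, 2, 1.69), 1)
  expect_equal(snp_adjusted_risk(0, 2, 1.69), 1 / 1.69, tolerance = 1e-12)
  expect_equal(snp_adjusted_risk(2, 2, 1.69), 4 / 1.69, tolerance = 1e-12)
  expect_equal(round(snp_adjusted_risk(0, 2, 1.69), 4), 0.5917)
  expect_equal(round(snp_adjusted_risk(2, 2, 1.69), 4), 2.3669)
})

test_that("PRS is the product of per-SNP factors, neutral panel gives exactly 1", {
  pan <- tiny_panel()
  expect_equal(compute_prs(c(2, 0), pan, "nh_white")$prs,
               (4 / 1.69) * (1 / 0.81), tolerance = 1e-12)
  expect_equal(round(compute_prs(c(2, 0), pan, "nh_white")$prs, 4), 2.9221)

  null_pan <- tiny_panel(ors = c(1, 1, 1), freqs = c(0.2, 0.5, 0.8))
  for (d in list(c(0, 0, 0), c(1, 2, 0), c(2, 2, 2))) {
    expect_equal(compute_prs(d, null_pan, "nh_black")$prs, 1)
  }
})

test_that("log-additivity: log PRS equals the sum of per-SNP log factors", {
  set.seed(42)
  pan <- simulate_panel(30)
  d <- simulate_genotypes(pan, "hispanic", 20)
  res <- compute_prs(d, pan, "hispanic")
  p <- panel_for_group(pan, "hispanic")
  mu <- snp_mean_relative_risk(p$or, p$freq)
  for (i in seq_len(nrow(d))) {
    logsum <- sum(log(snp_adjusted_risk(d[i, ], p$or, mu)))
    expect_equal(log(res$prs[i]), logsum, tolerance = 1e-10)
  }
})

test_that("PRS is invariant to consistent permutation of panel SNP order", {
  set.seed(7)
  pan <- simulate_panel(25)
  d <- simulate_genotypes(pan, "nh_asian", 10)
  perm <- sample(nrow(pan))
  pan2 <- as_snp_panel(as.data.frame(pan)[perm, ])
  expect_equal(compute_prs(d[, perm, drop = FALSE], pan2, "nh_asian")$prs,
               compute_prs(d, pan, "nh_asian")$prs)
})

test_that("exhaustive genotype enumeration gives E[PRS] = 1 for small panels", {
  pan <- tiny_panel(ors = c(2, 0.8, 1.3), freqs = c(0.3, 0.5, 0.12))
  p <- panel_for_group(pan, "nh_white")
  probs <- hwe_genotype_distribution(p$freq)
  e_prs <- 0
  for (g1 in 0:2) for (g2 in 0:2) for (g3 in 0:2) {
    g <- c(g1, g2, g3)
    w <- probs[1, g1 + 1] * probs[2, g2 + 1] * probs[3, g3 + 1]
    e_prs <- e_prs + w * compute_prs(g, pan, "nh_white")$prs
  }
  expect_equal(unname(e_prs), 1, tolerance = 1e-12)
})

test_that("raising a dosage moves the PRS in the direction of the odds ratio", {
  pan <- tiny_panel(ors = c(1.5, 0.7), freqs = c(0.4, 0.4))
  base <- compute_prs(c(1, 1), pan, "nh_white")$prs
  expect_gt(compute_prs(c(2, 1), pan, "nh_white")$prs, base)  # OR > 1
  expect_lt(compute_prs(c(1, 2), pan, "nh_white")$prs, base)  # OR < 1
})

test_that("missingness: neutral factors, scoreability threshold, no silent values", {
  pan <- tiny_panel()
  # default threshold 0: any missing SNP -> non-scoreable, NA score
  res <- compute_prs(c(NA, 0), pan, "nh_white")
  expect_false(res$scoreable)
  expect_true(is.na(res$prs))
  expect_equal(res$n_missing, 1)
  expect_equal(res$n_used + res$n_missing, 2)
  # tolerant threshold: missing SNP contributes the neutral factor 1
  res2 <- compute_prs(c(NA, 0), pan, "nh_white", max_missing_fraction = 0.5)
  expect_true(res2$scoreable)
  expect_equal(res2$prs, 1 / 0.81, tolerance = 1e-12)
  expect_error(compute_prs(c(1, 1, 1), pan, "nh_white"), "panel size")
  expect_error(compute_prs(c(3, 0), pan, "nh_white"), "dosages")
})

test_that("quintile cutpoints use linear-interpolation percentiles", {
  expect_equal(unname(quintile_cutpoints(1:5)), c(1.8, 2.6, 3.4, 4.2))
  expect_equal(unname(quintile_cutpoints(rep(3.2, 9))), rep(3.2, 4))
  expect_error(quintile_cutpoints(1:4), "at least 5")
  set.seed(99)
  u <- runif(100000)
  expect_equal(unname(quintile_cutpoints(u)), c(0.2, 0.4, 0.6, 0.8),
               tolerance = 0.01)
})
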