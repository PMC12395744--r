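test_that("cross-tabulation counts pairs and conserves marginals", {
  r3 <- data.frame(rec_bcsc = rep("biennial", 3),
                   rec_combined = rep("biennial", 3),
                   stringsAsFactors = FALSE)
  t3 <- cross_tabulate(r3)
  expect_equal(t3$counts["biennial", "biennial"], 3)
  expect_equal(t3$n_total, 3)

  set.seed(21)
  lv <- screening_levels(include_pv = FALSE)
  rec <- data.frame(rec_bcsc = sample(lv, 10, replace = TRUE),
                    rec_combined = sample(lv, 10, replace = TRUE),
                    stringsAsFactors = FALSE)
  tab <- cross_tabulate(rec)
  expect_equal(unclass(tab$counts),
               pair_count_oracle(rec$rec_bcsc, rec$rec_combined, lv))
  expect_equal(sum(tab$counts), nrow(rec))
  expect_equal(unname(rowSums(tab$counts)),
               as.numeric(table(factor(rec$rec_bcsc, lv))[lv]))
  expect_equal(unname(colSums(tab$counts)),
               as.numeric(table(factor(rec$rec_combined, lv))[lv]))
})

test_that("cross-tabulation filters PV carriers, non-scoreable and age strata", {
  rec <- data.frame(
    age = c(45, 45, 60, 45), pv = c(FALSE, TRUE, FALSE, FALSE),
    scoreable = c(TRUE, TRUE, TRUE, FALSE),
    rec_bcsc = c("biennial", "pv_guideline", "biennial", "biennial"),
    rec_combined = c("annual_risk", "pv_guideline", "biennial", "biennial"),
    stringsAsFactors = FALSE)
  tab <- cross_tabulate(rec, age_stratum = c(40, 49))
  expect_equal(tab$n_total, 1)
  expect_equal(tab$counts["biennial", "annual_risk"], 1)
  empty <- cross_tabulate(rec[0, ])
  expect_equal(empty$n_total, 0)
})

test_that("discordance is the off-diagonal share, identity table gives 0", {
  lv <- c("x", "y")
  ident <- reassignment_table(matrix(c(5, 0, 0, 7), 2,
                                     dimnames = list(lv, lv)))
  expect_equal(discordance_percentage(ident)$percent, 0)
  mixed <- reassignment_table(matrix(c(5, 1, 3, 7), 2,
                                     dimnames = list(lv, lv)))
  expect_equal(discordance_percentage(mixed)$percent, 100 * 4 / 16)
  expect_error(discordance_percentage(reassignment_table(
    matrix(0, 2, 2, dimnames = list(lv, lv)))), "empty")
})

test_that("row-conditional reassignment fractions match hand counting", {
  lv <- c("x", "y")
  tab <- reassignment_table(matrix(c(6, 0, 2, 0), 2,
                                   dimnames = list(lv, lv)))
  expect_equal(cell_reassignment_fraction(tab, "x", "y")$percent, 25)
  expect_equal(cell_reassignment_fraction(tab, "x", "x")$percent, 75)
  expect_error(cell_reassignment_fraction(tab, "y", "x"), "empty")
  expect_error(cell_reassignment_fraction(tab, "z", "x"), "unknown")
})

test_that("screening utilization averages the frequency map over records", {
  all_bien <- data.frame(rec_combined = rep("biennial", 8),
                         stringsAsFactors = FALSE)
  u <- mean_screens_per_woman_year(all_bien, "combined")
  expect_equal(u$mean_screens, 0.5)
  expect_equal(u$women_per_screen, 2)

  toy <- data.frame(rec_combined = c("none_or_stop", "none_or_stop",
                                     "annual_risk", "annual_risk"),
                    stringsAsFactors = FALSE)
  expect_equal(mean_screens_per_woman_year(toy, "combined")$mean_screens, 0.5)

  none <- data.frame(rec_combined = rep("none_or_stop", 4),
                     stringsAsFactors = FALSE)
  u0 <- mean_screens_per_woman_year(none, "combined")
  expect_equal(u0$mean_screens, 0)
  expect_true(is.na(u0$women_per_screen))

  # named counts interface agrees with the records interface
  u2 <- mean_screens_per_woman_year(c(none_or_stop = 2, annual_risk = 2))
  expect_equal(u2$mean_screens, 0.5)
})

test_that("Sankey flows enumerate nonzero cells and conserve counts", {
  rec <- data.frame(
    rec_bcsc = c("none_or_stop", "none_or_stop", "biennial", "biennial",
                 "annual_risk"),
    rec_combined = c("none_or_stop", "biennial", "biennial", "biennial",
                     "annual_risk"),
    rec_final = c("none_or_stop", "biennial", "biennial", "annual_risk",
                  "annual_risk"),
    stringsAsFactors = FALSE)
  fl <- sankey_flows(rec)
  s1 <- fl[fl$stage == "bcsc_to_combined", ]
  expect_equal(sum(s1$count), nrow(rec))
  # flow out of each source equals its marginal
  out_none <- sum(s1$count[s1$source == "none_or_stop"])
  expect_equal(out_none, sum(rec$rec_bcsc == "none_or_stop"))
  s2 <- fl[fl$stage == "combined_to_final", ]
  expect_equal(sum(s2$count), nrow(rec))
  expect_equal(sum(s2$count[s2$source == "biennial" &
                              s2$target == "annual_risk"]), 1)
  # single-cell table -> single flow
  fl1 <- sankey_flows(rec[rec$rec_bcsc == "annual_risk", ])
  expect_equal(nrow(fl1[fl1$stage == "bcsc_to_combined", ]), 1)
  # JSON export round-trips
  f <- tempfile(fileext = ".json")
  write_sankey_json(fl, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$count, fl$count)
})

test_that("two-group comparisons use the exact Wilcoxon null for small samples", {
  out <- rank_group_compare(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(out$method, "wilcoxon_rank_sum")
  expect_equal(out$p.value, 1 / 3, tolerance = 1e-12)
  # complete separation, n = 5 per group
  sep <- rank_group_compare(c(1:5, 11:15), rep(c("a", "b"), each = 5))
  expect_equal(sep$p.value, 2 / 252, tolerance = 1e-12)
  expect_error(rank_group_compare(1:4, rep("a", 4)), "two groups")
})

test_that("exact Wilcoxon p-values match full rank enumeration for n <= 8", {
  set.seed(17)
  for (rep in 1:6) {
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
    x <- sample(1:100, n1); y <- sample(setdiff(1:100, x), n2)
    got <- rank_group_compare(c(x, y), rep(c("a", "b"), c(n1, n2)))$p.value
    expect_equal(got, wilcox_enum_p(x, y), tolerance = 1e-12)
  }
})

test_that("three or more groups route to Kruskal-Wallis; null case is non-significant", {
  set.seed(5)
  v <- rnorm(600)
  g <- rep(c("a", "b", "c"), each = 200)
  out <- rank_group_compare(v, g)
  expect_equal(out$method, "kruskal_wallis")
  expect_gt(out$p.value, 0.001)
  expect_equal(out$statistic,
               unname(kruskal.test(v, factor(g))$statistic))
})

test_that("trend test: exact enumeration for tiny n, direction, and tie degeneracy", {
  inc <- trend_test(c(1, 2, 3), c("lo", "mid", "hi"))
  expect_equal(inc$statistic, 3)
  expect_equal(inc$p.value, 1 / 6, tolerance = 1e-12)
  expect_equal(inc$method, "jonckheere_terpstra_exact")

  rev <- trend_test(c(3, 2, 1), c("lo", "mid", "hi"))
  expect_gt(rev$p.value, 0.5)

  tied <- trend_test(rep(4, 30), rep(c("lo", "mid", "hi"), each = 10))
  expect_equal(tied$p.value, 0.5)
  expect_equal(tied$statistic, tied$null_mean)

  expect_error(trend_test(1:4, c("a", "a", "b", "b")), "3 ordered")
})

test_that("trend test normal approximation rejects a strong trend, not a null", {
  set.seed(31)
  g <- rep(c("g1", "g2", "g3", "g4"), each = 100)
  trend <- rnorm(400, mean = rep(c(0, 0.3, 0.6, 0.9), each = 100))
  expect_lt(trend_test(trend, g)$p.value, 1e-6)
  null <- rnorm(400)
  expect_gt(trend_test(null, g)$p.value, 0.001)
})

test_that("squared Pearson correlation matches hand computation", {
  out <- pearson_r2(c(1, 2, 3), c(2, 1, 3))
  expect_equal(out$r, 0.5, tolerance = 1e-12)
  expect_equal(out$r2, 0.25, tolerance = 1e-12)
  expect_equal(pearson_r2(1:10, 1:10)$r2, 1, tolerance = 1e-12)
  set.seed(8)
  x <- rnorm(1e4); y <- rnorm(1e4)
  expect_lt(pearson_r2(x, y)$r2, 0.001)
  expect_error(pearson_r2(c(1, 1, 1), 1:3), "variance")
})

test_that("group summaries report n, mean, sd and interpolated quartiles", {
  s <- summarize_prs_by_group(c(1, 2, 3), rep("g", 3))
  expect_equal(s$mean, 2); expect_equal(s$median, 2); expect_equal(s$sd, 1)
  s1 <- summarize_prs_by_group(5, "g")
  expect_true(is.na(s1$sd))
  two <- summarize_prs_by_group(c(1, 2, 3, 1, 2, 3),
                                rep(c("a", "b"), each = 3))
  expect_equal(two[two$group == "a", -1], two[two$group == "b", -1],
               ignore_attr = TRUE)
  expect_warning(
    summarize_prs_by_group(1:3, factor(rep("a", 3), levels = c("a", "b"))),
    "empty")
  q <- summarize_prs_by_group(1:5, rep("g", 5))
  expect_equal(c(q$q1, q$median, q$q3), c(2, 3, 4))
})

test_that("reporting percentages round half away from zero", {
  expect_equal(round_half_up(13.5), 14)
  expect_equal(round_half_up(10.5), 11)
  expect_equal(round_half_up(10.49), 10)
  expect_equal(round_half_up(-2.5), -3)
  expect_equal(round_half_up(64.593), 65)
})
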