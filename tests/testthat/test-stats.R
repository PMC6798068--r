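test_that("t-tests match their textbook closed forms to 1e-10", {
  set.seed(8)
  for (i in 1:1000) {
    n <- sample(3:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- paired_ttest(x, y)
    want <- paired_oracle(x, y)
    expect_lt(abs(got$t - want$t) / max(1, abs(want$t)), 1e-10)
    expect_equal(got$df, want$df)
    expect_lt(abs(got$p - want$p), 1e-10)
    a <- rnorm(sample(3:20, 1)); b <- rnorm(sample(3:20, 1), 0.3)
    got2 <- two_sample_ttest(a, b)
    want2 <- two_sample_oracle(a, b)
    expect_lt(abs(got2$t - want2$t) / max(1, abs(want2$t)), 1e-10)
    expect_equal(got2$df, want2$df)
    expect_lt(abs(got2$p - want2$p), 1e-10)
  }
})

test_that("degrees of freedom follow the design sizes", {
  set.seed(9)
  p29 <- paired_ttest(rnorm(29), rnorm(29))
  expect_equal(p29$df, 28)                    # 29 participants, paired
  g <- two_sample_ttest(rnorm(14), rnorm(7))
  expect_equal(g$df, 19)                      # 14 FD vs 7 FI, pooled
  same <- rnorm(10)
  expect_equal(paired_ttest(same + 0 * same, same + rnorm(10, 0, 1e-12))$df, 9)
  expect_error(paired_ttest(same, same), "zero difference variance")
  expect_error(two_sample_ttest(rep(1, 5), rep(1, 5)), "pooled variance")
})

test_that("paired t is antisymmetric in its arguments", {
  set.seed(10)
  x <- rnorm(12); y <- rnorm(12)
  a <- paired_ttest(x, y); b <- paired_ttest(y, x)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
})

test_that("Holm-Bonferroni reproduces the hand-executed step-down", {
  hb <- holm_bonferroni(c(0.01, 0.02, 0.20), 0.05)
  expect_equal(hb$reject, c(TRUE, TRUE, FALSE)) # thresholds 1/60, 1/40, 1/20
  expect_equal(holm_bonferroni(rep(1, 5))$reject, rep(FALSE, 5))
  one <- holm_bonferroni(0.001)
  expect_true(one$reject)
  expect_equal(one$p_adjusted, 0.001)
  set.seed(12)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    got <- holm_bonferroni(p, 0.05)
    want <- holm_oracle(p, 0.05)
    expect_equal(got$reject, want$reject)
    expect_equal(got$p_adjusted, want$p_adjusted)
  }
  expect_error(holm_bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Holm rejects at least as much as Bonferroni, at most as much as raw", {
  set.seed(13)
  for (i in 1:50) {
    p <- runif(sample(2:30, 1))^2
    holm <- sum(holm_bonferroni(p, 0.05)$reject)
    bonf <- sum(p <= 0.05 / length(p))
    raw <- sum(p <= 0.05)
    expect_gte(holm, bonf)
    expect_lte(holm, raw)
  }
})

test_that("the comparison matrix enumerates 30 locations per feature family", {
  feats <- rbind(
    fake_feature_rows(29, 1, "c1", seed = 1),
    fake_feature_rows(29, 1, "c2", mean = 0.5, seed = 2))
  cmp <- run_comparisons(feats, families = "condition")
  expect_equal(nrow(cmp), 30)
  expect_true(all(cmp$df == 28))              # 29 participants paired
  expect_true(all(cmp$p_holm >= cmp$p))
  # two-sample family: 14 FD vs 7 FI -> df 19 everywhere
  g <- rep(c("FD", "FI"), times = c(14, 7))
  feats2 <- fake_feature_rows(21, 12, "b2", groups = g, seed = 3)
  cmp2 <- run_comparisons(feats2, families = "group")
  expect_equal(nrow(cmp2), 30)
  expect_true(all(cmp2$df == 19))
  expect_true(all(cmp2$n_a == 14 & cmp2$n_b == 7))
  expect_error(run_comparisons(fake_feature_rows(
    6, 12, "b2", groups = rep("FD", 6)), families = "group"), "group")
})

test_that("report lists passing locations with t, df, p and both means", {
  g <- rep(c("FD", "FI"), times = c(6, 6))
  feats <- fake_feature_rows(12, 5, "c1", groups = g, seed = 4)
  # plant a large FD-FI difference at T8
  sel <- feats$location == "T8" & feats$group == "FD"
  feats$value[sel] <- feats$value[sel] + 50
  cmp <- run_comparisons(feats, families = "group")
  lines <- utils::capture.output(report_comparisons(cmp))
  hit <- grep("T8 \\[t\\(10\\) = ", lines, value = TRUE)
  expect_length(hit, 1)
  expect_match(hit, "p_holm")
  expect_match(hit, "m_FD")
  expect_match(hit, "m_FI")
})
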