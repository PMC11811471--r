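test_that("two-way mean squares match hand and loop ANOVA decompositions", {
  m0 <- matrix(5, 4, 3)
  ms0 <- two_way_mean_squares(m0)
  expect_equal(c(ms0$msr, ms0$msc, ms0$mse), c(0, 0, 0))
  m1 <- matrix(c(1, 3, 2, 4), 2, 2)     # [[1,2],[3,4]]
  ms1 <- two_way_mean_squares(m1)
  expect_equal(c(ms1$msr, ms1$msc, ms1$mse), c(4, 1, 0))
  set.seed(1)
  for (i in 1:20) {
    m <- matrix(rnorm(30), 10, 3)
    ms <- two_way_mean_squares(m)
    o <- o_two_way_ss(m)
    expect_equal(c(ms$msr, ms$msc, ms$mse), c(o$msr, o$msc, o$mse),
                 tolerance = 1e-9)
  }
  expect_error(two_way_mean_squares(matrix(1:3, 3, 1)), "at least 2")
  expect_error(two_way_mean_squares(matrix(c(1, NA, 3, 4), 2, 2)),
               "incomplete")
})

test_that("perfect agreement yields ICC 1 in every model", {
  m <- matrix(rep(c(1, 5, 9, 2, 7), 3), 5, 3)
  for (mod in c("icc2_1", "icc3_1", "icc2_k", "icc3_k")) {
    est <- icc(m, mod)
    expect_equal(est$icc, 1)
    expect_equal(est$category, "excellent")
    expect_equal(c(est$ci_lo, est$ci_hi), c(1, 1))
  }
})

test_that("a constant column shift leaves consistency invariant but lowers agreement", {
  set.seed(2)
  m <- matrix(rnorm(45), 15, 3) + rnorm(15) * 2
  m2 <- m
  m2[, 2] <- m2[, 2] + 10
  expect_equal(icc(m2, "icc3_1")$icc, icc(m, "icc3_1")$icc, tolerance = 1e-12)
  expect_lt(icc(m2, "icc2_1")$icc, icc(m, "icc2_1")$icc)
})

test_that("categorization uses the exact half-open thresholds", {
  expect_equal(icc_categorize(c(1, 0.95, 0.949999, 0.75, 0.7499, 0.5, 0.499,
                                0, -0.2)),
               c("excellent", "excellent", "good", "good", "moderate",
                 "moderate", "poor", "poor", "poor"))
})

test_that("all-constant tables are flagged degenerate, not scored", {
  est <- icc(matrix(3, 6, 3), "icc2_1")
  expect_true(est$degenerate)
  expect_true(is.na(est$icc))
})

test_that("estimates and CIs track the variance-components structure", {
  # parameter recovery: y_ij = mu + s_i + r_j + e_ij
  sim_icc <- function(ss, sr, se, n = 200, k = 3, reps = 50, seed = 1) {
    vals <- withr::with_seed(seed, vapply(seq_len(reps), function(i) {
      m <- outer(rnorm(n, sd = ss), rep(1, k)) +
        outer(rep(1, n), rnorm(k, sd = sr)) + matrix(rnorm(n * k, sd = se), n, k)
      icc(m, "icc2_1")$icc
    }, numeric(1)))
    mean(vals)
  }
  theo <- 2 / (2 + 0.25 + 1)
  expect_equal(sim_icc(sqrt(2), 0.5, 1), theo, tolerance = 0.02)
  # monotone: more error variance, lower expected ICC
  expect_gt(sim_icc(1, 0.3, 0.5, reps = 30, seed = 5),
            sim_icc(1, 0.3, 1.5, reps = 30, seed = 5))
})

test_that("screening removes exactly the zero-variance and non-finite features", {
  df <- data.frame(
    feature = rep(c("a_firstorder_X", "b_glcm_Y", "c_gldm_Z"), each = 4),
    value = c(rep(2, 4), rnorm(4), c(1, 2, NaN, 4)))
  scr <- screen_degenerate(df)
  expect_equal(scr$kept, "b_glcm_Y")
  expect_setequal(scr$excluded$feature, c("a_firstorder_X", "c_gldm_Z"))
  expect_equal(scr$excluded$reason[scr$excluded$feature == "a_firstorder_X"],
               "zero variance")
})

test_that("breakdowns tally categories per group and conserve totals", {
  feats <- c(paste0("original_glcm_F", 1:4), paste0("lbp-2D_gldm_G", 1:2))
  est <- data.frame(feature = feats,
                    icc = c(0.99, 0.8, 0.6, 0.2, 0.97, 0.3),
                    ci_lo = 0, ci_hi = 1,
                    category = icc_categorize(c(0.99, 0.8, 0.6, 0.2, 0.97, 0.3)),
                    stringsAsFactors = FALSE)
  bf <- reliability_breakdown(est, "filter")
  p <- bf$proportions
  for (g in unique(p$group))
    expect_equal(sum(p$proportion[p$group == g]), 1)
  expect_equal(p$count[p$group == "original" & p$category == "excellent"], 1)
  expect_equal(p$count[p$group == "lbp-2D" & p$category == "poor"], 1)
  # independent tally
  for (g in unique(p$group)) for (categ in icc_categories()) {
    manual <- sum(grepl(paste0("^", g, "_"), est$feature) &
                    est$category == categ)
    expect_equal(p$count[p$group == g & p$category == categ], manual)
  }
  # overall proportions equal group proportions weighted by group size
  ov <- reliability_breakdown(est, "overall")$proportions
  exc <- sum(p$count[p$category == "excellent"]) / nrow(est)
  expect_equal(ov$proportion[ov$category == "excellent"], exc)
  # top features
  top <- bf$top_features
  expect_equal(top$feature[top$group == "original"], "original_glcm_F1")
})

test_that("ICC point estimates agree with an aov variance-decomposition oracle", {
  set.seed(8)
  for (i in 1:15) {
    n <- sample(5:20, 1); k <- sample(2:4, 1)
    m <- matrix(rnorm(n * k), n, k) + rnorm(n)
    df <- data.frame(y = as.vector(m),
                     t = factor(rep(seq_len(n), k)),
                     r = factor(rep(seq_len(k), each = n)))
    a <- anova(stats::lm(y ~ t + r, data = df))
    msr <- a["t", "Mean Sq"]; msc <- a["r", "Mean Sq"]
    mse <- a["Residuals", "Mean Sq"]
    expect_equal(icc(m, "icc2_1")$icc,
                 (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse)),
                 tolerance = 1e-9)
    expect_equal(icc(m, "icc3_1")$icc, (msr - mse) / (msr + (k - 1) * mse),
                 tolerance = 1e-9)
    expect_equal(icc(m, "icc2_k")$icc, (msr - mse) / (msr + (msc - mse) / n),
                 tolerance = 1e-9)
    expect_equal(icc(m, "icc3_k")$icc, (msr - mse) / msr, tolerance = 1e-9)
  }
})

test_that("long tables round-trip through measurement_matrix and icc_by_feature", {
  set.seed(11)
  long <- expand.grid(target = paste0("t", 1:6), rater = paste0("r", 1:3),
                      feature = c("f1", "f2"), stringsAsFactors = FALSE)
  long$value <- rnorm(nrow(long)) + as.integer(factor(long$target))
  est <- icc_by_feature(long, "icc2_1")
  expect_equal(nrow(est), 2)
  m1 <- measurement_matrix(long[long$feature == "f1", ])
  expect_equal(est$icc[est$feature == "f1"], icc(m1, "icc2_1")$icc)
  f1 <- long[long$feature == "f1", ]
  expect_error(measurement_matrix(f1[-1, ]), "incomplete")
})
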