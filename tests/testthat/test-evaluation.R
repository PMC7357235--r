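test_that("LOOCV predictions equal an independent fold loop exactly", {
  set.seed(20)
  for (rep in 1:4) {
    n <- sample(8:14, 1)
    df <- data.frame(a = rnorm(n), b = rnorm(n),
                     sex = factor(sample(c("f", "m"), n, TRUE),
                                  levels = c("f", "m")))
    ds <- rs_dataset(df, rnorm(n, 400, 100))
    params <- svr_params(10^runif(1, 0, 2), runif(1, 1, 20),
                         10^runif(1, -2, 0))
    feats <- sample(c("a", "b", "sex"), sample(2:3, 1))
    cv <- loocv_predict(ds, feats, params)
    expect_identical(cv$predicted, loocv_loop_oracle(ds, feats, params))
    expect_equal(cv$residual, abs(cv$actual - cv$predicted))
    expect_length(cv$residual, n)
    expect_true(all(cv$residual >= 0))
  }
})

test_that("constant targets give zero LOOCV residuals", {
  df <- data.frame(a = c(1, 5, 9))
  ds <- rs_dataset(df, c(100, 100, 100))
  cv <- loocv_predict(ds, "a", svr_params(10, 0.5, 1))
  expect_equal(cv$predicted, rep(100, 3), tolerance = 1e-6)
  expect_equal(cv$residual, rep(0, 3), tolerance = 1e-6)
})

test_that("residual summaries use the sample standard deviation", {
  s <- summarize_residuals(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  s2 <- summarize_residuals(rep(4.2, 6))
  expect_equal(s2$mean, 4.2)
  expect_equal(s2$sd, 0)
  s3 <- summarize_residuals(7)
  expect_equal(s3$sd, 0)
  expect_true(s3$degenerate)
})

test_that("Wilcoxon signed-rank exact p equals full sign enumeration", {
  # all-positive differences 1..5: W = 0, two-sided p = 2/32
  w <- wilcoxon_signed_rank(c(2, 4, 6, 8, 10), c(1, 2, 3, 4, 5))
  expect_equal(w$statistic, 0)
  expect_equal(w$p_value, 0.0625)
  expect_equal(w$method, "exact")
  set.seed(31)
  for (m in c(3, 5, 8, 10)) {
    for (rep in 1:5) {
      a <- rnorm(m)
      b <- rnorm(m)
      # occasionally force ties and zeros
      if (rep > 3) {
        b[1] <- a[1]
        if (m > 3) b[2] <- a[2] + (a[3] - b[3])
      }
      for (alt in c("two.sided", "greater", "less")) {
        got <- wilcoxon_signed_rank(a, b, alternative = alt)
        expect_equal(got$p_value, wilcoxon_enum_oracle(a - b, alt),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("Wilcoxon agrees with the reference implementation when no ties", {
  set.seed(17)
  a <- rnorm(12); b <- rnorm(12)
  got <- wilcoxon_signed_rank(a, b)
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  # large-sample path matches the normal approximation reference
  set.seed(18)
  a2 <- rnorm(40); b2 <- rnorm(40)
  got2 <- wilcoxon_signed_rank(a2, b2)
  ref2 <- stats::wilcox.test(a2, b2, paired = TRUE, exact = FALSE,
                             correct = TRUE)
  expect_equal(got2$p_value, ref2$p.value, tolerance = 1e-9)
  expect_equal(got2$method, "normal approximation")
})

test_that("identical paired samples yield a flagged p of 1", {
  w <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3))
  expect_true(w$all_zero)
  expect_equal(w$p_value, 1)
  expect_equal(w$statistic, 0)
})

test_that("Kaplan-Meier matches the hand product-limit computation", {
  km <- kaplan_meier(c(1, 2, 3))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))
  # single subject
  km1 <- kaplan_meier(5)
  expect_equal(km1$survival, 0)
  # all censored: S stays 1
  km2 <- kaplan_meier(c(2, 4, 6), events = c(0, 0, 0))
  expect_true(all(km2$survival == 1))
  # no censoring: equals the empirical survival function (hand oracle)
  set.seed(40)
  tt <- sample(1:500, 25, replace = TRUE)
  km3 <- kaplan_meier(tt)
  hand <- km_hand_oracle(tt)
  expect_equal(km3$survival[km3$n_event > 0], hand$survival,
               tolerance = 1e-12)
  expect_error(kaplan_meier(c(1, -2)), "positive")
})

test_that("log-rank statistic matches the hand risk-table computation", {
  lr <- logrank_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(lr$statistic, logrank_hand_oracle(c(1, 2, 3), c(4, 5, 6)),
               tolerance = 1e-9)
  # identical groups: statistic 0, p = 1
  lr0 <- logrank_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1, tolerance = 1e-12)
  # doubling both groups scales consistently with the oracle
  ta <- c(1, 2, 3, 1, 2, 3); tb <- c(4, 5, 6, 4, 5, 6)
  lr2 <- logrank_test(ta, tb)
  expect_equal(lr2$statistic, logrank_hand_oracle(ta, tb),
               tolerance = 1e-9)
  expect_error(logrank_test(c(1, 2), c(3, 4), events_b = c(0, 0)),
               "degenerate")
})

test_that("median-split AUC equals brute-force pair counting", {
  expect_equal(median_split_auc(c(10, 20, 30, 40), c(10, 20, 30, 40)), 1)
  expect_equal(median_split_auc(c(10, 20, 30, 40),
                                -c(10, 20, 30, 40)), 0)
  set.seed(50)
  for (rep in 1:5) {
    actual <- sample(50:500, 10)
    predicted <- actual + rnorm(10, 0, 150)
    labels <- actual > median(actual)
    expect_equal(median_split_auc(actual, predicted),
                 auc_pair_oracle(labels, predicted), tolerance = 1e-12)
  }
  expect_error(median_split_auc(rep(5, 6), rnorm(6)), "single class")
})

test_that("feature-group comparison produces a coherent report", {
  set.seed(60)
  rec <- make_recovery_dataset(n_patients = 24, n_candidates = 12,
                               seed = 3)
  ds <- rec$dataset
  p <- svr_params(100, 10, 0.05)
  feats <- colnames(ds$x)
  sel <- list(clinical = list(mask = feats[1:4], params = p),
              dvh = list(mask = feats[5:8], params = p),
              combined = list(mask = feats[1:8], params = p))
  cmp <- compare_feature_groups(ds, sel)
  expect_equal(nrow(cmp$summary), 3)
  expect_true(all(cmp$summary$mean_residual >= 0))
  ps <- c(cmp$wilcoxon$combined_vs_clinical$p_value,
          cmp$wilcoxon$combined_vs_dvh$p_value, cmp$logrank$p_value)
  expect_true(all(ps >= 0 & ps <= 1))
  expect_true(cmp$auc >= 0 && cmp$auc <= 1)
  # degenerate equality: identical selections give flagged p = 1
  sel_same <- list(clinical = sel$combined, dvh = sel$combined,
                   combined = sel$combined)
  cmp2 <- compare_feature_groups(ds, sel_same)
  expect_true(cmp2$wilcoxon$combined_vs_clinical$all_zero)
  expect_equal(cmp2$wilcoxon$combined_vs_clinical$p_value, 1)
  expect_equal(cmp2$summary$mean_residual[1],
               cmp2$summary$mean_residual[3])
})
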