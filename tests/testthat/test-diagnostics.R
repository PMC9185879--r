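test_that("AUC equals the brute-force Mann-Whitney probability", {
  expect_equal(roc_auc(c(1, 2), c(3, 4))$auc, 1.0)
  expect_equal(roc_auc(c(1, 3), c(2, 4))$auc, 0.75)
  expect_equal(roc_auc(c(1, 2, 3), c(1, 2, 3))$auc, 0.5)

  set.seed(7)
  for (i in 1:60) {
    crt <- sample(1:6, sample(2:8, 1), replace = TRUE)   # ties likely
    nrt <- sample(1:6, sample(2:8, 1), replace = TRUE)
    r <- roc_auc(crt, nrt)
    expect_equal(r$auc, brute_auc(crt, nrt), tolerance = 1e-12)
    # trapezoid under the empirical curve reproduces the MW value
    expect_equal(trapezoid_auc(r), r$auc, tolerance = 1e-12)
    # swapping group roles maps AUC -> 1 - AUC
    expect_equal(roc_auc(nrt, crt)$auc, 1 - r$auc, tolerance = 1e-12)
    # curve is monotone from (0,0) to (1,1)
    cv <- r$curve
    expect_equal(c(cv$fpr[1], cv$tpr[1]), c(0, 0))
    expect_equal(c(cv$fpr[nrow(cv)], cv$tpr[nrow(cv)]), c(1, 1))
    expect_true(all(diff(cv$fpr) >= 0) && all(diff(cv$tpr) >= 0))
  }
  expect_error(roc_auc(numeric(0), 1:3), "non-empty")
})

test_that("Youden cutoff matches exhaustive search with the stated tie rule", {
  y <- youden_cutoff(roc_auc(c(1, 2), c(3, 4)))
  expect_equal(y$cutoff, 2.5)
  expect_equal(y$yi, 1)

  # frozen via brute_youden: max YI = 0.5 at cutoffs in (1,2] and (3,4];
  # smallest qualifying midpoint is 1.5 (Se 0.5, Sp 1)
  y2 <- youden_cutoff(roc_auc(c(1, 3), c(2, 4)))
  b2 <- brute_youden(c(1, 3), c(2, 4))
  expect_equal(y2$cutoff, b2$cutoff)
  expect_equal(y2$cutoff, 1.5)
  expect_equal(y2$yi, 0.5)

  set.seed(11)
  for (i in 1:40) {
    crt <- round(rnorm(sample(3:8, 1), 0, 2), 1)
    nrt <- round(rnorm(sample(3:8, 1), 2, 2), 1)
    y <- youden_cutoff(roc_auc(crt, nrt))
    b <- brute_youden(crt, nrt)
    expect_equal(y$yi, b$yi, tolerance = 1e-12)
    expect_equal(y$cutoff, b$cutoff)
  }
})

test_that("classification uses the strict < rule with NRT at the boundary", {
  expect_identical(classify(19.60, 19.61), "CRT")
  expect_identical(classify(19.61, 19.61), "NRT")
  expect_identical(classify(24.10, 24.05), "NRT")
  expect_identical(classify(c(1, 2, 3), 2), c("CRT", "NRT", "NRT"))
  expect_error(classify(c(1, NA), 2), "finite")
})

test_that("contingency metrics follow the 2x2 definitions and flag NA", {
  m <- contingency_metrics(36, 10, 5, 44)
  expect_equal(m$se, 36 / 41, tolerance = 1e-12)
  expect_equal(m$sp, 44 / 54, tolerance = 1e-12)
  expect_equal(m$pv_pos, 36 / 46, tolerance = 1e-12)
  expect_equal(m$yi, 36 / 41 + 44 / 54 - 1, tolerance = 1e-12)
  expect_equal(round(m$se, 2), 0.88)
  expect_equal(round(m$sp, 2), 0.81)
  expect_equal(round(m$pv_pos, 2), 0.78)
  expect_equal(round(m$yi, 2), 0.69)

  # zero denominators are flagged missing, never reported as 0
  m0 <- contingency_metrics(0, 3, 0, 7)
  expect_true(is.na(m0$se))
  expect_true(is.na(m0$yi))
  m1 <- contingency_metrics(5, 0, 1, 4)
  expect_true(is.na(m1$lr_pos))   # Sp = 1
  expect_error(contingency_metrics(-1, 0, 0, 0), ">= 0")
})

test_that("sample size formula reproduces the worked examples", {
  r <- sample_size(k = 1, alpha = 0.05, beta = 0.20, sigma = 1, delta = 1)
  expect_identical(r$n1, 16L)
  expect_identical(r$n2, 16L)
  # direct evaluation: ceil(2 * (1.959964 + 0.841621)^2) = ceil(15.70) = 16
  z <- qnorm(0.975) + qnorm(0.80)
  expect_identical(r$n1, as.integer(ceiling(2 * z^2)))

  r2 <- sample_size(k = 0.75, alpha = 0.05, beta = 0.20, sigma = 1.7171,
                    delta = 1)
  expect_identical(r2$n1, 54L)
  expect_identical(r2$n2, 41L)   # ceil(0.75 * 54) = ceil(40.5)

  # vanishing effect size guard: minimum 2 per group
  r3 <- sample_size(k = 1, sigma = 1, delta = 1e6)
  expect_identical(r3$n1, 2L)
  expect_identical(r3$n2, 2L)
  expect_error(sample_size(k = -1, sigma = 1, delta = 1), "k must")
})

test_that("ICC(2,1) behaves as a variance ratio", {
  x <- cbind(1:10, 1:10)
  expect_equal(icc(x), 1.0, tolerance = 1e-12)

  set.seed(5)
  subj <- rnorm(200, 50, 1)
  noisy <- cbind(subj + rnorm(200, 0, 3), subj + rnorm(200, 0, 3))
  expect_lt(icc(noisy), 0.5)   # oracle: 1 / (1 + 9) = 0.1

  subj2 <- rnorm(200, 50, 10)
  good <- cbind(subj2 + rnorm(200), subj2 + rnorm(200))
  expect_gt(icc(good), 0.8)    # oracle: 100 / 101
  expect_equal(icc(good), 100 / 101, tolerance = 0.05)

  expect_warning(v <- icc(cbind(rep(1, 5), rep(1, 5))), "undefined")
  expect_true(is.na(v))
  expect_error(icc(cbind(1:2, 1:2)), "3 subjects")
  expect_error(icc(matrix(1:9, 3, 3)), "2 measurement occasions")
})

test_that("measurement_error summarises test-retest agreement", {
  set.seed(8)
  o1 <- rnorm(50, 20, 2)
  o2 <- o1 + rnorm(50, 0, 0.1)
  me <- measurement_error(o1, o2)
  expect_gt(me$icc, 0.8)
  expect_gt(me$paired_t_p, 0.01)
  expect_equal(me$mean_values, (o1 + o2) / 2)
})

test_that("group comparison matches the pooled-variance formula", {
  g <- group_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(g$t_stat, 0)
  expect_equal(g$t_p, 1)

  g2 <- group_compare(c(1, 2, 3), c(101, 102, 103))
  expect_lt(g2$t_p, 0.01)
  # normal-approximation rank-sum floor at n = 3 per group is ~0.08
  expect_lt(g2$w_p, 0.1)
  g2b <- group_compare(1:6, 101:106)
  expect_lt(g2b$w_p, 0.01)

  a <- c(1.2, 2.4, 3.1, 4.8)
  b <- c(2.0, 4.1, 6.3)
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  g3 <- group_compare(a, b)
  expect_equal(g3$t_stat, t_hand, tolerance = 1e-12)
  expect_equal(g3$t_p, 2 * pt(-abs(t_hand), length(a) + length(b) - 2),
               tolerance = 1e-12)

  # zero pooled variance with unequal means: 0-limit flag
  g4 <- group_compare(c(1, 1, 1), c(2, 2, 2))
  expect_equal(g4$t_p, 0)
  expect_true(is.infinite(g4$t_stat))
})

test_that("diagnose_cohort assembles consistent tables", {
  set.seed(33)
  cohort <- generate_cohort(population_spec(seed = 33))
  rep <- diagnose_cohort(cohort)
  expect_setequal(rep$table_roc$parameter,
                  c("RL", "PRW", "RSA", "RV", "RSA_RL", "RV_RL"))
  # the discriminating parameters separate far better than RL
  aucs <- setNames(rep$table_roc$auc, rep$table_roc$parameter)
  expect_lt(aucs["RL"], 0.7)
  expect_gt(aucs["RV_RL"], 0.8)
  # YI consistency across tables
  acc <- rep$table_accuracy
  expect_equal(acc$yi, acc$se + acc$sp - 1, tolerance = 1e-12)
  # counts re-derive the accuracy metrics
  pp <- rep$per_parameter$RSA_RL
  cm <- contingency_metrics(pp$counts["tp"], pp$counts["fp"],
                            pp$counts["fn"], pp$counts["tn"])
  expect_equal(cm$se, pp$metrics$se)
  expect_error(diagnose_cohort(data.frame(group = c("A", "B"))), "NRT or CRT")
})
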