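test_that("ROC handles separation, ties and the rank identity", {
  roc <- roc_curve_auc(c(3, 4, 1, 2), c(1, 1, 0, 0))
  expect_equal(roc$auc, 1.0)
  expect_equal(roc$auc_rank, 1.0)

  set.seed(11)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(round(rnorm(n), 1))
    roc <- roc_curve_auc(scores, labels)
    expect_lt(abs(roc$auc - roc$auc_rank), 1e-12)
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    raw_pair_auc <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
    expect_equal(roc$auc, raw_pair_auc)
    # monotone curve
    expect_true(all(diff(1 - roc$specificity) >= -1e-12))
    expect_true(all(diff(roc$sensitivity) >= -1e-12))
  }

  # independent scores on a large sample: AUC near 1/2
  set.seed(12)
  lab <- rep(c(1, 0), each = 1000)
  roc <- roc_curve_auc(rnorm(2000), lab)
  se <- sqrt((2000 + 1) / (12 * 1000 * 1000))
  expect_lt(abs(roc$auc - 0.5), 3 * se)
})

test_that("response association reports ORR and switches tests sensibly", {
  # balanced table with identical proportions -> p = 1
  grp <- rep(c("high", "low"), each = 10)
  lab <- rep(c(1, 0, 1, 0), c(5, 5, 5, 5))
  res <- response_association(grp, lab)
  expect_equal(res$p_value, 1)
  expect_equal(unname(res$orr), c(0.5, 0.5))

  # strongly crossed 10+10 table, Fisher route agrees with enumeration
  grp <- rep(c("high", "low"), each = 10)
  lab <- rep(c(1, 0, 1, 0), c(9, 1, 1, 9))
  res <- response_association(grp, lab, test = "fisher")
  expect_equal(res$test_name, "fisher")
  expect_equal(res$p_value,
               oracle_fisher_p(matrix(c(9, 1, 1, 9), 2, byrow = TRUE)),
               tolerance = 1e-12)

  # sparse table auto-switches to Fisher and records it
  grp <- rep(c("high", "low"), c(4, 16))
  lab <- rep(c(1, 0, 1, 0), c(4, 0, 2, 14))
  expect_equal(response_association(grp, lab)$test_name, "fisher")

  expect_error(response_association(rep("high", 5), rep(0:1, c(2, 3))),
               "two non-empty groups")
})

test_that("Kaplan-Meier matches hand product-limit values", {
  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$curve$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$median, 2)

  km <- kaplan_meier(c(5, 6, 7), c(0, 0, 0))
  expect_true(all(km$curve$survival == 1))
  expect_true(is.na(km$median))

  # with no censoring the estimator is the empirical survival function
  set.seed(3)
  t <- rexp(40) + 0.1
  km <- kaplan_meier(t, rep(1, 40))
  emp <- vapply(km$curve$time, function(x) mean(t > x), numeric(1))
  expect_equal(km$curve$survival, emp, tolerance = 1e-12)
})

test_that("log-rank matches hand computation, symmetry and permutation null", {
  # identical groups -> statistic 0, p = 1
  lr <- log_rank(c(1, 2, 3, 1, 2, 3), rep(1, 6), rep(c("A", "B"), each = 3))
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)

  # toy table: times {1,2,3}, all events, groups {A,A,B}
  # O_A = 2, E_A = 2/3 + 1/2 = 7/6, V = 2/9 + 1/4 = 17/36
  lr <- log_rank(c(1, 2, 3), c(1, 1, 1), c("A", "A", "B"))
  expect_equal(lr$chisq, (5 / 6)^2 / (17 / 36), tolerance = 1e-9)

  expect_error(log_rank(c(1, 2), c(0, 0), c("A", "B")), "at least one event")

  # analytic p agrees with the label-permutation distribution (sample
  # large enough for the chi-square approximation to hold)
  set.seed(21)
  t <- c(rexp(30, 1 / 10), rexp(30, 1 / 15))
  ev <- rep(1, 60)
  g <- rep(c("A", "B"), each = 30)
  obs <- log_rank(t, ev, g)
  n_perm <- 2000
  perm <- replicate(n_perm, log_rank(t, ev, sample(g))$chisq)
  p_mc <- mean(perm >= obs$chisq - 1e-12)
  se <- sqrt(max(p_mc * (1 - p_mc), 1 / n_perm) / n_perm)
  expect_lt(abs(obs$p_value - p_mc), 3 * se + 1e-9)
})

test_that("Cox hazard ratios are symmetric, consistent and error on degeneracy", {
  set.seed(31)
  t <- c(rexp(60, 1 / 100), rexp(60, 1 / 40))
  ev <- rep(1, 120)
  g <- rep(c("slow", "fast"), each = 60)
  a <- cox_hr(t, ev, g, reference = "slow")
  b <- cox_hr(t, ev, g, reference = "fast")
  expect_lt(abs(a$hr - 1 / b$hr), 1e-9)
  expect_true(a$ci_lower < a$hr && a$hr < a$ci_upper)
  expect_error(cox_hr(t, ev, rep("same", 120)), "two levels")

  # consistency: spread of the estimate shrinks and the mean tightens with n
  est <- function(n, seeds) sapply(seeds, function(s) {
    set.seed(s)
    t <- c(rexp(n / 2, 0.4 / 100), rexp(n / 2, 1 / 100))
    cox_hr(t, rep(1, n), rep(c("x", "ref"), each = n / 2),
           reference = "ref")$hr
  })
  e100 <- est(100, 1:30)
  e1000 <- est(1000, 1:30)
  expect_lt(sd(e1000), sd(e100))
  expect_lt(abs(mean(e1000) - 0.4), abs(mean(e100) - 0.4) + 0.03)
  expect_true(mean(e1000) > 0.36 && mean(e1000) < 0.44)
})

test_that("the quantile biomarker screen flags degeneracy and finds real signal", {
  set.seed(41)
  n <- 150
  lab <- rbinom(n, 1, 0.6)
  t <- rexp(n, 1 / 100)
  ev <- rep(1, n)

  scr <- biomarker_cutoff_screen(rep(2.5, n), lab, t, ev)
  expect_true(all(scr$degenerate))

  # a biomarker that is the outcome plus small noise: median split is decisive
  strong <- lab + rnorm(n, 0, 0.2)
  scr <- biomarker_cutoff_screen(strong, lab, t, ev, quantiles = 0.5)
  expect_lt(scr$orr_p, 1e-3)
  expect_false(scr$degenerate)

  expect_error(biomarker_cutoff_screen(c(1, NA), c(0, 1), c(1, 2), c(1, 1)),
               "finite")
  expect_error(biomarker_cutoff_screen(1:4, rep(0:1, 2), 1:4, rep(1, 4),
                                       quantiles = 1.2), "quantiles")
})
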