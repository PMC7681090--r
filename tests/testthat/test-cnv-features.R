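test_that("CNV categorization applies strict thresholds", {
  expect_equal(categorize_cnv(0), "neutral")
  expect_equal(categorize_cnv(0.2, gain_thr = 0.2), "neutral")
  expect_equal(categorize_cnv(-0.2, loss_thr = -0.2), "neutral")
  expect_equal(categorize_cnv(c(-0.5, 0, 0.6)), c("loss", "neutral", "gain"))
  m <- matrix(c(-0.5, 0.5, 0, 0.1), 2, dimnames = list(c("a", "b"), c("g1", "g2")))
  cm <- categorize_cnv(m)
  expect_identical(dimnames(cm), dimnames(m))
  expect_error(categorize_cnv(0, gain_thr = -0.1), "loss_thr < 0 < gain_thr")
})

test_that("folded AUC matches its closed cases and brute-force pair counting", {
  expect_equal(feature_auc(c(0.8, 0.6, 0.3, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(feature_auc(c(1, 1, 1, 1), c(1, 1, 0, 0)), 0.5)
  # responders {2, 5} vs non-responders {3}: pair scores (0 + 1)/2
  expect_equal(feature_auc(c(2, 5, 3), c(1, 1, 0)), 0.5)
  expect_error(feature_auc(c(1, 2), c(1, 1)), "both")

  set.seed(101)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    values <- sample(round(rnorm(n), 1))  # rounding forces ties
    expect_equal(feature_auc(values, labels), oracle_auc(values, labels))
  }
})

test_that("mutual information matches the entropy identity and its edge cases", {
  # category identical to label, balanced n = 20 -> exactly 1 bit
  cats <- rep(c("gain", "loss"), each = 10)
  labs <- rep(c(1, 0), each = 10)
  mi <- feature_mutual_information(cats, labs, n_perm = 200, seed = 1)
  expect_equal(mi$mi_bits, 1.0)
  expect_lte(mi$perm_p, 1 / 201 + 1e-12)

  # constant category -> zero MI, permutation p = 1
  mi0 <- feature_mutual_information(rep("neutral", 20), labs, n_perm = 200,
                                    seed = 1)
  expect_equal(mi0$mi_bits, 0)
  expect_equal(mi0$perm_p, 1)

  # hand-specified joint: {(gain,1):4, (gain,0):1, (neutral,1):1, (neutral,0):4}
  cats <- rep(c("gain", "gain", "neutral", "neutral"), c(4, 1, 1, 4))
  labs <- rep(c(1, 0, 1, 0), c(4, 1, 1, 4))
  mi <- feature_mutual_information(cats, labs, n_perm = 200, seed = 2)
  expect_equal(mi$mi_bits, oracle_mi_bits(table(cats, labs)), tolerance = 1e-12)

  # exactly factorizing joint -> MI 0; relabeling categories leaves MI alone
  cats <- rep(c("gain", "neutral"), times = c(6, 9))
  labs <- c(rep(c(1, 0), c(2, 4)), rep(c(1, 0), c(3, 6)))
  expect_equal(feature_mutual_information(cats, labs, seed = 1)$mi_bits, 0)
  swapped <- ifelse(cats == "gain", "loss", "neutral")
  expect_equal(feature_mutual_information(swapped, labs, seed = 1)$mi_bits, 0)
})

test_that("MI is non-negative and matches the entropy identity on random draws", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(6:40, 1)
    cats <- sample(c("loss", "neutral", "gain"), n, replace = TRUE)
    labs <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    mi <- feature_mutual_information(cats, labs, seed = i)$mi_bits
    expect_gte(mi, 0)
    expect_equal(mi, oracle_mi_bits(table(factor(cats), labs)),
                 tolerance = 1e-12)
  }
})

test_that("the four tests agree with their identities and hand-computed table", {
  # identical value multisets in both groups -> all p-values 1
  v <- c(-0.5, 0, 0.5, -0.5, 0, 0.5)
  lab <- c(1, 1, 1, 0, 0, 0)
  ft <- feature_tests(v, categorize_cnv(v), lab)
  expect_equal(ft$p_chi2, 1)
  expect_equal(ft$p_wilcoxon, 1)
  expect_equal(ft$p_anova, 1)
  expect_equal(ft$p_ttest, 1)

  # [[10,0],[0,10]] contingency -> chi-square statistic 20, df 1
  v <- c(rep(0.5, 10), rep(-0.5, 10))
  lab <- rep(c(1, 0), each = 10)
  ft <- feature_tests(v, categorize_cnv(v), lab)
  expect_equal(ft$chi2_stat, 20.0)
  expect_equal(ft$chi2_df, 1)

  # F = t^2 identity on arbitrary two-group inputs
  set.seed(5)
  for (i in 1:50) {
    n <- sample(6:40, 1)
    v <- round(rnorm(n), 1)
    lab <- c(0, 0, 1, 1, sample(0:1, n - 4, replace = TRUE))
    ft <- feature_tests(v, categorize_cnv(v), lab)
    expect_lt(abs(ft$p_anova - ft$p_ttest), 1e-9)
  }

  expect_error(feature_tests(c(1, 2, 3), rep("gain", 3), c(1, 0, 0)),
               "t-test/ANOVA")
})

test_that("deviation is |Cohen's d| with (n-2)-pooled SD", {
  expect_equal(feature_deviation(c(1, 2, 1, 2), c(1, 1, 0, 0)), 0)
  expect_equal(feature_deviation(c(1, 2, 3, 0, 1, 2), c(1, 1, 1, 0, 0, 0)), 1.0)
  expect_error(feature_deviation(c(1, 1, 0, 0), c(1, 1, 0, 0)),
               "degenerate variance")
  # equal means with zero variance is still 0, not an error
  expect_equal(feature_deviation(c(1, 1, 1, 1), c(1, 1, 0, 0)), 0)
})

test_that("feature stats table is consistent and order-invariant", {
  coh <- simulate_cohort(quick_config(n_patients = 60, effect_size = 1.2,
                                      seed = 13))
  lab <- coh$truth$responder
  st <- compute_feature_stats(coh$cnv, lab, seed = 9)
  flag_cols <- grep("^pass_", names(st), value = TRUE)
  expect_length(flag_cols, 7)
  expect_identical(st$votes, as.integer(rowSums(st[flag_cols])))
  expect_true(all(st$auc >= 0.5))
  pcols <- c("mi_perm_p", "p_chi2", "p_wilcoxon", "p_anova", "p_ttest")
  for (pc in pcols)
    expect_true(all(is.na(st[[pc]]) | (st[[pc]] >= 0 & st[[pc]] <= 1)))

  # reordering samples changes nothing
  perm <- sample(nrow(coh$cnv))
  st2 <- compute_feature_stats(coh$cnv[perm, ], lab[perm], seed = 9)
  expect_equal(st2, st)
})

test_that("a constant gene column collects zero votes", {
  set.seed(44)
  m <- cbind(flat = rep(0, 40),
             informative = rep(c(1, -1), each = 20) + rnorm(40, 0, 0.05))
  rownames(m) <- sprintf("s%02d", 1:40)
  lab <- rep(c(1, 0), each = 20)
  st <- compute_feature_stats(m, lab, seed = 4)
  expect_equal(st$votes[st$gene == "flat"], 0L)
  expect_equal(st$votes[st$gene == "informative"], 7L)
})

test_that("a strong single-gene effect is selected with high probability", {
  votes <- sapply(1:50, function(s) {
    set.seed(s)
    lab <- rep(c(1, 0), c(90, 60))
    v <- rnorm(150, 0, 0.25) + ifelse(lab == 1, 1.2 * 0.25, 0)
    m <- matrix(v, ncol = 1, dimnames = list(sprintf("s%03d", 1:150), "g"))
    compute_feature_stats(m, lab, seed = s)$votes
  })
  expect_gte(mean(votes >= 4), 0.95)
})
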