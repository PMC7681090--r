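# Per-gene criterion statistics for the consensus feature filter: each
# candidate gene is scored by seven between-group criteria (deviation,
# mutual information, AUC, chi-square, Wilcoxon, ANOVA, t-test) and a gene
# "votes" once per criterion it passes.

#' Categorize log2 copy ratios into loss / neutral / gain
#'
#' Strict thresholding: values above `gain_thr` are gains, below `loss_thr`
#' losses, everything else (boundaries included) neutral.
#'
#' @param x Numeric vector or matrix of log2 ratios.
#' @param gain_thr Gain threshold (> 0).
#' @param loss_thr Loss threshold (< 0).
#' @return Character vector/matrix of `"loss"`, `"neutral"`, `"gain"` with
#'   the shape and dimnames of `x`.
#' @examples
#' categorize_cnv(c(-0.5, 0, 0.2, 0.6))
#' @export
categorize_cnv <- function(x, gain_thr = 0.2, loss_thr = -0.2) {
  if (!is.numeric(gain_thr) || !is.numeric(loss_thr) ||
      !(loss_thr < 0 && 0 < gain_thr))
    stop("thresholds must satisfy loss_thr < 0 < gain_thr", call. = FALSE)
  out <- ifelse(x > gain_thr, "gain", ifelse(x < loss_thr, "loss", "neutral"))
  if (is.matrix(x)) dimnames(out) <- dimnames(x)
  out
}

#' Folded per-feature AUC
#'
#' Mann-Whitney (rank) formulation with ties contributing 1/2, folded as
#' `max(A, 1 - A)` so the value is direction-agnostic and lies in
#' \[0.5, 1\].
#'
#' @param values Numeric vector, one value per sample.
#' @param labels Binary responder labels aligned with `values`.
#' @return Folded AUC.
#' @export
feature_auc <- function(values, labels) {
  labels <- as_binary_labels(labels)
  if (length(values) != length(labels))
    stop("values and labels differ in length", call. = FALSE)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  r <- rank(values)
  a <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  max(a, 1 - a)
}

# mutual information in bits from a 3 x 2 count vector (tabulate layout)
mi_bits_from_counts <- function(counts6) {
  m <- matrix(counts6, nrow = 3L)
  n <- sum(m)
  if (n == 0L) return(0)
  p <- m / n
  px <- rowSums(p)
  py <- colSums(p)
  e <- outer(px, py)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / e[nz]))
}

cat_to_int <- function(categories) {
  ci <- match(categories, c("loss", "neutral", "gain"))
  if (anyNA(ci))
    stop("categories must be 'loss', 'neutral' or 'gain'", call. = FALSE)
  ci
}

# Permutation null for the MI criterion. Shuffling labels leaves the
# category margins fixed, so the permuted joint table is a multivariate
# hypergeometric draw: sample the number of responders landing in each
# category directly (sequential rhyper) and evaluate MI on the resulting
# counts, fully vectorized over permutations. Equivalent in distribution
# to explicit label shuffling, and invariant to sample order.
mi_perm_count_ge <- function(ci, labels, n_perm, obs) {
  n <- length(ci)
  cts <- tabulate(ci, nbins = 3L)
  n1 <- sum(labels == 1L)
  n0 <- n - n1
  k1 <- stats::rhyper(n_perm, cts[1], n - cts[1], n1)
  k2 <- stats::rhyper(n_perm, cts[2], n - cts[1] - cts[2], n1 - k1)
  k3 <- n1 - k1 - k2
  term <- function(a, cmar, nlab) {
    out <- numeric(length(a))
    nz <- a > 0
    out[nz] <- a[nz] / n * log2(a[nz] * n / (cmar * nlab))
    out
  }
  mi <- term(k1, cts[1], n1) + term(k2, cts[2], n1) + term(k3, cts[3], n1) +
    term(cts[1] - k1, cts[1], n0) + term(cts[2] - k2, cts[2], n0) +
    term(cts[3] - k3, cts[3], n0)
  sum(mi >= obs - 1e-12)
}

#' Mutual information between a categorized feature and response
#'
#' Empirical mutual information (in bits) of the category x label joint
#' distribution, with a permutation p-value obtained by shuffling labels:
#' `p = (1 + #(MI_perm >= MI_obs)) / (n_perm + 1)`.
#'
#' @param categories Per-sample `"loss"`/`"neutral"`/`"gain"`.
#' @param labels Binary responder labels.
#' @param n_perm Number of label permutations (>= 100).
#' @param seed Seed for the permutation stream.
#' @return List with `mi_bits` and `perm_p`.
#' @export
feature_mutual_information <- function(categories, labels, n_perm = 200L,
                                       seed = 1L) {
  labels <- as_binary_labels(labels)
  if (n_perm < 100L) stop("n_perm must be at least 100", call. = FALSE)
  ci <- cat_to_int(categories)
  if (length(ci) != length(labels))
    stop("categories and labels differ in length", call. = FALSE)
  obs <- mi_bits_from_counts(tabulate(ci + 3L * labels, nbins = 6L))
  ge <- with_seed(seed, mi_perm_count_ge(ci, labels, n_perm, obs))
  list(mi_bits = obs, perm_p = (1 + ge) / (n_perm + 1))
}

#' Four classical two-group tests for one feature
#'
#' Chi-square (no continuity correction) on the category x label table after
#' dropping zero-margin categories; Wilcoxon rank-sum, two-sided, normal
#' approximation with midranks and tie-corrected variance; one-way ANOVA
#' over the two classes; and the pooled-variance two-sample t-test. With two
#' groups ANOVA and the t-test are the same test (F = t^2), so their
#' p-values coincide. Tests that are undefined on the input (e.g. a constant
#' feature) return `NA` rather than erroring.
#'
#' @param values Per-sample continuous values.
#' @param categories Per-sample loss/neutral/gain (for the chi-square).
#' @param labels Binary responder labels.
#' @return List: `p_chi2`, `p_wilcoxon`, `p_anova`, `p_ttest`, plus
#'   `chi2_stat` and `chi2_df`.
#' @export
feature_tests <- function(values, categories, labels) {
  labels <- as_binary_labels(labels)
  if (length(values) != length(labels) || length(categories) != length(labels))
    stop("values, categories and labels differ in length", call. = FALSE)
  if (min(table(labels)) < 2L)
    stop("t-test/ANOVA need at least 2 samples per class", call. = FALSE)
  g1 <- values[labels == 1L]
  g0 <- values[labels == 0L]

  tab <- table(factor(categories, levels = c("loss", "neutral", "gain")),
               labels)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) >= 2L && ncol(tab) >= 2L) {
    ch <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    p_chi2 <- unname(ch$p.value)
    chi2_stat <- unname(ch$statistic)
    chi2_df <- unname(ch$parameter)
  } else {
    p_chi2 <- NA_real_
    chi2_stat <- NA_real_
    chi2_df <- NA_real_
  }

  p_wilcoxon <- tryCatch(
    stats::wilcox.test(g1, g0, exact = FALSE, correct = FALSE)$p.value,
    error = function(e) NA_real_)
  if (!is.na(p_wilcoxon) && is.nan(p_wilcoxon)) p_wilcoxon <- NA_real_

  p_ttest <- tryCatch(
    stats::t.test(g1, g0, var.equal = TRUE)$p.value,
    error = function(e) NA_real_)
  p_anova <- tryCatch(
    stats::oneway.test(values ~ factor(labels), var.equal = TRUE)$p.value,
    error = function(e) NA_real_)
  if (!is.na(p_anova) && is.nan(p_anova)) p_anova <- NA_real_
  if (!is.na(p_ttest) && is.nan(p_ttest)) p_ttest <- NA_real_

  list(p_chi2 = p_chi2, p_wilcoxon = p_wilcoxon, p_anova = p_anova,
       p_ttest = p_ttest, chi2_stat = chi2_stat, chi2_df = chi2_df)
}

#' Absolute standardized mean difference (|Cohen's d|)
#'
#' `|mean_1 - mean_0| / s_pooled` with the (n - 2)-denominator pooled
#' standard deviation. Zero when the group means are equal; degenerate
#' variance with unequal means is an error.
#'
#' @param values Per-sample continuous values.
#' @param labels Binary responder labels.
#' @return Non-negative deviation.
#' @export
feature_deviation <- function(values, labels) {
  labels <- as_binary_labels(labels)
  if (length(values) != length(labels))
    stop("values and labels differ in length", call. = FALSE)
  g1 <- values[labels == 1L]
  g0 <- values[labels == 0L]
  if (length(g1) < 2L || length(g0) < 2L)
    stop("deviation needs at least 2 samples per class", call. = FALSE)
  md <- mean(g1) - mean(g0)
  if (md == 0) return(0)
  sp <- sqrt(((length(g1) - 1) * stats::var(g1) +
                (length(g0) - 1) * stats::var(g0)) / (length(values) - 2))
  if (sp == 0)
    stop("degenerate variance: pooled SD is 0 but group means differ",
         call. = FALSE)
  abs(md) / sp
}

#' Per-gene criterion statistics and consensus votes
#'
#' Computes, for every gene of a CNV matrix, the seven criterion statistics
#' and their pass flags: four p-value criteria at `alpha` (chi-square,
#' Wilcoxon, ANOVA, t-test — the latter two are one test in the two-group
#' setting), `deviation >= d_min`, folded `auc >= auc_min`, and the mutual
#' information permutation p at `alpha`. `votes` counts the true flags
#' (0-7). A gene on which a criterion is undefined (e.g. a constant column)
#' simply fails that criterion. The MI permutation null is drawn from
#' `seed`, gene by gene, as multivariate-hypergeometric joint tables
#' (equivalent in distribution to shuffling labels).
#'
#' @param matrix Samples x genes numeric CNV matrix (rownames = sample ids).
#' @param labels Binary responder labels, named by sample id or aligned with
#'   the matrix rows.
#' @param alpha Per-criterion significance level.
#' @param d_min Deviation (|Cohen's d|) pass threshold.
#' @param auc_min Folded AUC pass threshold.
#' @param gain_thr,loss_thr Categorization thresholds for the chi-square and
#'   MI criteria.
#' @param n_perm Label permutations for the MI p-value.
#' @param seed Seed for the permutation stream.
#' @return Data frame with one row per gene: the seven statistics, the MI
#'   permutation p, seven logical `pass_*` flags and `votes`.
#' @export
compute_feature_stats <- function(matrix, labels, alpha = 0.05, d_min = 0.5,
                                  auc_min = 0.6, gain_thr = 0.2,
                                  loss_thr = -0.2, n_perm = 200L, seed = 1L) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("matrix must be a numeric samples x genes matrix", call. = FALSE)
  if (!is.null(names(labels)) && !is.null(rownames(matrix))) {
    missing <- setdiff(rownames(matrix), names(labels))
    if (length(missing))
      stop("labels missing for sample(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    labels <- labels[rownames(matrix)]
  }
  labels <- as_binary_labels(labels)
  if (length(labels) != nrow(matrix))
    stop("labels length must equal the number of samples", call. = FALSE)
  genes <- colnames(matrix) %||% sprintf("gene%03d", seq_len(ncol(matrix)))

  rows <- with_seed(seed, lapply(seq_len(ncol(matrix)), function(j) {
    v <- matrix[, j]
    cats <- categorize_cnv(v, gain_thr, loss_thr)
    ci <- cat_to_int(cats)
    dev <- tryCatch(feature_deviation(v, labels), error = function(e) NA_real_)
    auc <- feature_auc(v, labels)
    tests <- feature_tests(v, cats, labels)
    mi <- mi_bits_from_counts(tabulate(ci + 3L * labels, nbins = 6L))
    ge <- mi_perm_count_ge(ci, labels, n_perm, mi)
    mi_p <- (1 + ge) / (n_perm + 1)
    data.frame(
      gene = genes[j],
      deviation = dev,
      mutual_info = mi,
      mi_perm_p = mi_p,
      auc = auc,
      p_chi2 = tests$p_chi2,
      p_wilcoxon = tests$p_wilcoxon,
      p_anova = tests$p_anova,
      p_ttest = tests$p_ttest,
      stringsAsFactors = FALSE
    )
  }))
  out <- do.call(rbind, rows)
  out$pass_chi2 <- !is.na(out$p_chi2) & out$p_chi2 < alpha
  out$pass_wilcoxon <- !is.na(out$p_wilcoxon) & out$p_wilcoxon < alpha
  out$pass_anova <- !is.na(out$p_anova) & out$p_anova < alpha
  out$pass_ttest <- !is.na(out$p_ttest) & out$p_ttest < alpha
  out$pass_deviation <- !is.na(out$deviation) & out$deviation >= d_min
  out$pass_auc <- out$auc >= auc_min
  out$pass_mi <- out$mi_perm_p < alpha
  flag_cols <- c("pass_chi2", "pass_wilcoxon", "pass_anova", "pass_ttest",
                 "pass_deviation", "pass_auc", "pass_mi")
  out$votes <- as.integer(rowSums(out[flag_cols]))
  rownames(out) <- NULL
  out
}
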