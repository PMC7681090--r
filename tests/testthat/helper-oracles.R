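# Independent brute-force oracles used by the property and acceptance
# tests. These deliberately re-derive each quantity from first principles
# (pair enumeration, exhaustive threshold search, hypergeometric
# enumeration, entropy identities) so they share no code with the package
# implementations they check.

# AUC by exhaustive pair counting, ties count 1/2, folded.
oracle_auc <- function(values, labels) {
  pos <- values[labels == 1]
  neg <- values[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  a <- s / (length(pos) * length(neg))
  max(a, 1 - a)
}

# Accuracy-optimal cutoff by exhaustive search over all midpoint/sentinel
# candidates; same tie-break chain (accuracy, Youden J, smallest cutoff).
oracle_cutoff <- function(scores, labels) {
  s <- sort(unique(scores))
  cand <- c(-Inf, if (length(s) > 1) (s[-length(s)] + s[-1]) / 2, Inf)
  stats <- t(vapply(cand, function(ct) {
    pred <- scores > ct
    acc <- mean(pred == (labels == 1))
    sens <- sum(pred & labels == 1) / sum(labels == 1)
    spec <- sum(!pred & labels == 0) / sum(labels == 0)
    c(acc = acc, youden = sens + spec - 1)
  }, numeric(2)))
  keep <- which(abs(stats[, "acc"] - max(stats[, "acc"])) <= 1e-12)
  keep <- keep[abs(stats[keep, "youden"] - max(stats[keep, "youden"])) <= 1e-12]
  list(cutoff = cand[min(keep)], accuracy = max(stats[, "acc"]))
}

# Two-sided Fisher p by direct enumeration of the hypergeometric support:
# sum the probabilities of all tables with the observed margins whose
# probability does not exceed the observed table's (R's convention, with
# its relative tolerance).
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Mutual information in bits via the entropy identity H(X)+H(Y)-H(X,Y).
oracle_mi_bits <- function(tab) {
  h <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  p <- tab / sum(tab)
  h(rowSums(p)) + h(colSums(p)) - h(as.vector(p))
}

# convenience: a small cohort config with trimmed gene/variant load for
# tests that do not exercise the CNV or variant arms at scale
quick_config <- function(..., seed) {
  sim_config(panel_genes = c(cnv_effect_genes, sprintf("NULL%03d", 1:20)),
             mean_variants = 2, seed = seed, ...)
}
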