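# Evaluation statistics: ROC/AUC, response-rate contingency tests,
# Kaplan-Meier, log-rank, Cox hazard ratios and quantile biomarker screens.
# Survival machinery is delegated to the survival package; the ROC and
# contingency conventions are implemented here.

#' ROC curve and AUC
#'
#' The curve is traced over all distinct score thresholds (positive call:
#' score >= threshold). The AUC is computed both by the trapezoid rule on
#' the curve and by the tie-aware rank (Mann-Whitney) statistic; the two
#' agree to numerical precision and both are returned.
#'
#' @param scores Per-sample continuous scores (higher = more responder-like).
#' @param labels Binary responder labels.
#' @return List of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc` (trapezoid), `auc_rank`.
#' @export
roc_curve_auc <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1))
  auc <- sum(diff(fpr) * (sens[-length(sens)] + sens[-1]) / 2)
  r <- rank(scores)
  n1 <- length(pos)
  n0 <- length(neg)
  auc_rank <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(list(thresholds = thr, sensitivity = sens, specificity = 1 - fpr,
                 auc = auc, auc_rank = auc_rank),
            class = "roc_result")
}

#' Response-rate association between two groups
#'
#' Builds the 2x2 group x responder table, reports the objective response
#' rate per group, and tests association with the chi-square test (no
#' continuity correction) or, when any expected count is below 5, Fisher's
#' exact test (two-sided); the rule actually applied is recorded in the
#' result.
#'
#' @param groups Two-level grouping (e.g. `"high"`/`"low"`), one per sample.
#' @param labels Binary responder labels.
#' @param test `"auto"` applies the expected-count rule; `"fisher"` or
#'   `"chi_square"` force the corresponding test.
#' @return List of class `contingency_result`: `table` (groups x
#'   responder), `orr` (named proportions), `test_name`, `statistic`
#'   (chi-square statistic, `NA` for Fisher), `p_value`.
#' @export
response_association <- function(groups, labels,
                                 test = c("auto", "fisher", "chi_square")) {
  test <- match.arg(test)
  labels <- as_binary_labels(labels)
  groups <- as.character(groups)
  if (length(groups) != length(labels))
    stop("groups and labels differ in length", call. = FALSE)
  lev <- unique(groups)
  if (length(lev) != 2L)
    stop("exactly two non-empty groups are required (got ",
         length(lev), ")", call. = FALSE)
  tab <- table(factor(groups, levels = sort(lev)),
               factor(labels, levels = c(1L, 0L),
                      labels = c("responder", "non_responder")))
  orr <- tab[, "responder"] / rowSums(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (test == "fisher" || (test == "auto" && any(expected < 5))) {
    ft <- stats::fisher.test(tab)
    res <- list(table = tab, orr = orr, test_name = "fisher",
                statistic = NA_real_, p_value = unname(ft$p.value))
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    res <- list(table = tab, orr = orr, test_name = "chi_square",
                statistic = unname(ct$statistic),
                p_value = unname(ct$p.value))
  }
  class(res) <- "contingency_result"
  res
}

#' Kaplan-Meier product-limit estimate for one group
#'
#' Censored observations tied with an event time are counted at risk for
#' that event (the standard event-before-censor convention). The median is
#' the first time at which the survival estimate drops to 0.5 or below,
#' `NA` if it never does.
#'
#' @param time Positive follow-up times (days).
#' @param event 1 = event observed, 0 = censored.
#' @return List of class `km_curve`: `curve` (data frame: time, n_risk,
#'   n_event, survival), `median`, `n`.
#' @export
kaplan_meier <- function(time, event) {
  if (any(!is.finite(time) | time <= 0))
    stop("times must be positive", call. = FALSE)
  if (!all(event %in% c(0, 1)))
    stop("event must be 0/1", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  curve <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, survival = fit$surv)
  below <- curve$time[curve$survival <= 0.5 & curve$n_event > 0]
  med <- if (length(below)) min(below) else NA_real_
  structure(list(curve = curve, median = med, n = length(time)),
            class = "km_curve")
}

#' Two-group log-rank test
#'
#' Observed-minus-expected statistic with hypergeometric variance summed
#' over distinct event times; p-value from the chi-square distribution with
#' one degree of freedom.
#'
#' @param time Positive follow-up times.
#' @param event 1 = event, 0 = censored.
#' @param group Two-level grouping.
#' @return List: `chisq`, `df`, `p_value`, `obs` and `exp` per group.
#' @export
log_rank <- function(time, event, group) {
  group <- as.character(group)
  if (length(unique(group)) != 2L)
    stop("exactly two non-empty groups are required", call. = FALSE)
  if (sum(event) < 1)
    stop("log-rank test requires at least one event", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(chisq = unname(sd$chisq), df = 1L,
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       obs = sd$obs, exp = sd$exp)
}

#' Cox proportional-hazards ratio for a binary covariate
#'
#' Single-covariate Cox model with Breslow tie handling. The hazard ratio
#' is `exp(beta)` for `level2` relative to `level1` (levels sorted unless
#' `reference` is given), with a Wald 95% CI and p-value. A monotone
#' partial likelihood (complete separation of event orders) is flagged
#' `unbounded` instead of silently reporting a huge finite HR. The crude
#' (O/E ratio) hazard-ratio estimate from the log-rank decomposition is
#' also reported for transparency.
#'
#' @param time Positive follow-up times.
#' @param event 1 = event, 0 = censored.
#' @param group Two-level covariate.
#' @param reference Optional level to use as the baseline.
#' @return List: `hr`, `ci_lower`, `ci_upper`, `p_value`, `beta`, `se`,
#'   `hr_oe`, `unbounded`, `reference`, `comparison`.
#' @export
cox_hr <- function(time, event, group, reference = NULL) {
  group <- as.character(group)
  lev <- sort(unique(group))
  if (length(lev) != 2L)
    stop("covariate must have exactly two levels (got ", length(lev), ")",
         call. = FALSE)
  if (!is.null(reference)) {
    if (!reference %in% lev) stop("unknown reference level: ", reference,
                                  call. = FALSE)
    lev <- c(reference, setdiff(lev, reference))
  }
  g <- factor(group, levels = lev)
  ev_per_level <- tapply(event, g, sum)
  if (any(ev_per_level < 1))
    stop("each covariate level needs at least one event", call. = FALSE)
  unbounded <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ g, ties = "breslow"),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w)))
        unbounded <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  oe <- (sd$obs[2] / sd$exp[2]) / (sd$obs[1] / sd$exp[1])
  list(hr = exp(beta),
       ci_lower = exp(beta - stats::qnorm(0.975) * se),
       ci_upper = exp(beta + stats::qnorm(0.975) * se),
       p_value = 2 * stats::pnorm(-abs(beta / se)),
       beta = beta, se = se, hr_oe = unname(oe),
       unbounded = unbounded,
       reference = lev[1], comparison = lev[2])
}

#' Quantile-cutoff biomarker screen
#'
#' For each requested quantile, dichotomizes the biomarker at its empirical
#' quantile (value > cutoff is "high") and reports the response-rate
#' association p-value and the log-rank p-value for the survival endpoint.
#' This is the negative-control pattern used for TMB, cfDNA concentration,
#' ctDNA fraction and maximum VAF: a biomarker with no predictive value
#' should yield uniform-looking p-values across cutoffs. A cutoff that
#' leaves one group empty is flagged degenerate rather than failing the
#' screen.
#'
#' @param values Finite biomarker values, one per sample.
#' @param labels Binary responder labels.
#' @param time,event Survival endpoint.
#' @param quantiles Probabilities in (0, 1).
#' @return Data frame: `quantile`, `cutoff`, `n_high`, `n_low`, `orr_p`,
#'   `logrank_p`, `degenerate`.
#' @export
biomarker_cutoff_screen <- function(values, labels, time, event,
                                    quantiles = c(0.25, 0.5, 0.75)) {
  if (any(!is.finite(values)))
    stop("biomarker values must be finite", call. = FALSE)
  if (any(quantiles <= 0 | quantiles >= 1))
    stop("quantiles must lie strictly in (0, 1)", call. = FALSE)
  labels <- as_binary_labels(labels)
  rows <- lapply(quantiles, function(q) {
    cut <- stats::quantile(values, q, names = FALSE)
    grp <- ifelse(values > cut, "high", "low")
    if (length(unique(grp)) < 2L) {
      return(data.frame(quantile = q, cutoff = cut,
                        n_high = sum(grp == "high"), n_low = sum(grp == "low"),
                        orr_p = NA_real_, logrank_p = NA_real_,
                        degenerate = TRUE))
    }
    orr_p <- response_association(grp, labels)$p_value
    lr_p <- tryCatch(log_rank(time, event, grp)$p_value,
                     error = function(e) NA_real_)
    data.frame(quantile = q, cutoff = cut, n_high = sum(grp == "high"),
               n_low = sum(grp == "low"), orr_p = orr_p, logrank_p = lr_p,
               degenerate = FALSE)
  })
  do.call(rbind, rows)
}
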