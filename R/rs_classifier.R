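# The response score (RS): consensus gene selection, L1-penalized logistic
# fitting with accuracy-driven cross-validation, per-sample scoring and
# accuracy-optimal dichotomization.

#' Consensus feature selection by criterion votes
#'
#' Genes whose vote count (see [compute_feature_stats()]) reaches
#' `min_votes`, in input order. An empty result is legal and left to the
#' caller to handle.
#'
#' @param stats Feature statistics table from [compute_feature_stats()].
#' @param min_votes Required number of passed criteria (1-7).
#' @return Character vector of selected gene symbols.
#' @export
consensus_select <- function(stats, min_votes = 4L) {
  if (!is.numeric(min_votes) || length(min_votes) != 1L ||
      min_votes < 1 || min_votes > 7)
    stop("min_votes must lie in 1..7", call. = FALSE)
  stats$gene[stats$votes >= min_votes]
}

#' Fit the L1-penalized response-score model
#'
#' Candidate gene columns are standardized to zero mean and unit SD on the
#' training data (the standardization is frozen into the model and reused
#' verbatim on any cohort scored later). An L1-penalized logistic regression
#' is fit over a lambda grid (default: the 50-value path glmnet computes on
#' the training data) and the penalty is chosen by stratified k-fold
#' cross-validated classification accuracy at probability 0.5; accuracy ties
#' are broken toward the larger (sparser) lambda among lambdas whose
#' full-data refit keeps at least one gene. The model's genes are the
#' nonzero-coefficient genes of the refit at the chosen penalty.
#'
#' @param matrix Samples x genes CNV matrix (training cohort).
#' @param labels Binary responder labels (named by sample id or row-aligned).
#' @param candidate_genes Genes to offer to the penalized fit (typically the
#'   [consensus_select()] output).
#' @param cv_folds Number of stratified folds.
#' @param lambda_grid Optional decreasing penalty grid.
#' @param seed Seed for fold assignment.
#' @return An object of class `rs_model`: `selected_genes`, `coefficients`
#'   (named, log2-ratio^-1 scale after standardization), `standardization`
#'   (`center`, `scale` for the selected genes), `lambda`, `cutoff`
#'   (`NA` until [select_cutoff()]), and `training_meta`.
#' @export
fit_rs_model <- function(matrix, labels, candidate_genes, cv_folds = 5L,
                         lambda_grid = NULL, seed = 1L) {
  if (length(candidate_genes) < 1L)
    stop("candidate_genes must contain at least one gene", call. = FALSE)
  missing <- setdiff(candidate_genes, colnames(matrix))
  if (length(missing))
    stop("matrix lacks candidate gene(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!is.null(names(labels)) && !is.null(rownames(matrix)))
    labels <- labels[rownames(matrix)]
  y <- as_binary_labels(labels)
  x <- matrix[, candidate_genes, drop = FALSE]
  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  if (any(scale_ == 0))
    stop("constant candidate column(s): ",
         paste(candidate_genes[scale_ == 0], collapse = ", "), call. = FALSE)
  xs <- scale(x, center = center, scale = scale_)

  if (is.null(lambda_grid)) {
    lambda_grid <- glmnet::glmnet(xs, y, family = "binomial", nlambda = 50,
                                  standardize = FALSE)$lambda
  }
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)

  n <- nrow(xs)
  folds <- integer(n)
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- which(y == cls)
      folds[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
    }
  })
  for (f in seq_len(cv_folds)) {
    if (length(unique(y[folds != f])) < 2L)
      stop("both classes must be present in every training fold", call. = FALSE)
  }

  correct <- numeric(length(lambda_grid))
  for (f in seq_len(cv_folds)) {
    train <- folds != f
    fit_f <- glmnet::glmnet(xs[train, , drop = FALSE], y[train],
                            family = "binomial", lambda = lambda_grid,
                            standardize = FALSE)
    prob <- stats::predict(fit_f, xs[!train, , drop = FALSE],
                           s = lambda_grid, type = "response")
    pred <- prob > 0.5
    correct <- correct + colSums(pred == y[!train])
  }
  cv_accuracy <- correct / n

  full_fit <- glmnet::glmnet(xs, y, family = "binomial",
                             lambda = lambda_grid, standardize = FALSE)
  nonzero <- full_fit$df > 0
  if (!any(nonzero))
    stop("empty model: every penalty in the grid zeroes all coefficients; ",
         "widen lambda_grid toward smaller values", call. = FALSE)
  eligible <- which(nonzero)
  best <- eligible[cv_accuracy[eligible] == max(cv_accuracy[eligible])]
  chosen <- min(best)  # grid is decreasing, so the smallest index = largest lambda
  lambda <- lambda_grid[chosen]

  beta <- as.matrix(stats::coef(full_fit, s = lambda))[, 1]
  intercept <- beta[["(Intercept)"]]
  beta <- beta[setdiff(names(beta), "(Intercept)")]
  selected <- names(beta)[beta != 0]
  model <- list(
    selected_genes = selected,
    coefficients = beta[selected],
    standardization = list(center = center[selected], scale = scale_[selected]),
    lambda = lambda,
    cutoff = NA_real_,
    training_meta = list(
      seed = as.integer(seed),
      cv_folds = as.integer(cv_folds),
      lambda_grid = lambda_grid,
      cv_accuracy = cv_accuracy,
      intercept = intercept,
      candidate_genes = candidate_genes,
      n_train = n
    )
  )
  class(model) <- "rs_model"
  model
}

#' @export
print.rs_model <- function(x, ...) {
  cat(sprintf("response-score model: %d gene(s), lambda = %.4g, cutoff = %s\n",
              length(x$selected_genes), x$lambda,
              if (is.na(x$cutoff)) "unset" else format(x$cutoff)))
  invisible(x)
}

#' Compute per-sample response scores
#'
#' Default (`mode = "weighted_sum"`):
#' `RS_i = sum_j beta_j * (x_ij - center_j) / scale_j` over the model's
#' selected genes — the linear predictor without intercept (the decision
#' cutoff absorbs the constant). The alternative reading of the score,
#' `mode = "altered_sum"`, adds each selected gene's coefficient only for
#' samples in which that gene is copy-number altered (outside the
#' neutral band of [categorize_cnv()]); it yields a coarser, step-valued
#' score. Genes outside the selected set never influence either score.
#'
#' @param model An `rs_model`.
#' @param matrix Samples x genes CNV matrix containing all selected genes.
#' @param mode Scoring rule; see Details.
#' @param gain_thr,loss_thr Neutral-band thresholds for `"altered_sum"`.
#' @return Named numeric vector of scores.
#' @export
compute_rs <- function(model, matrix, mode = c("weighted_sum", "altered_sum"),
                       gain_thr = 0.2, loss_thr = -0.2) {
  mode <- match.arg(mode)
  if (!inherits(model, "rs_model"))
    stop("model must be an rs_model", call. = FALSE)
  if (length(model$selected_genes) == 0L)
    return(stats::setNames(rep(0, nrow(matrix)), rownames(matrix)))
  missing <- setdiff(model$selected_genes, colnames(matrix))
  if (length(missing))
    stop("matrix lacks selected gene(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  x <- matrix[, model$selected_genes, drop = FALSE]
  if (mode == "weighted_sum") {
    xs <- sweep(sweep(x, 2, model$standardization$center), 2,
                model$standardization$scale, "/")
    rs <- as.vector(xs %*% model$coefficients)
  } else {
    altered <- categorize_cnv(x, gain_thr, loss_thr) != "neutral"
    rs <- as.vector(altered %*% model$coefficients)
  }
  stats::setNames(rs, rownames(matrix))
}

#' Accuracy-optimal response-score cutoff
#'
#' Candidate cutoffs are the midpoints of adjacent distinct sorted scores
#' plus -Inf/+Inf sentinels. The returned cutoff maximizes classification
#' accuracy under the rule "RS > cutoff predicts responder"; accuracy ties
#' are broken by maximal Youden J (sensitivity + specificity - 1), then by
#' the smallest cutoff. If the reversed rule would achieve strictly higher
#' accuracy, the result carries `inverted_separation = TRUE` rather than
#' silently flipping the direction.
#'
#' @param scores Per-sample response scores.
#' @param labels Binary responder labels.
#' @return List of class `rs_cutoff`: `cutoff`, `accuracy`, `sensitivity`,
#'   `specificity`, `youden`, `inverted_separation`.
#' @export
select_cutoff <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  s <- sort(unique(scores))
  cand <- c(-Inf, if (length(s) > 1L) (s[-length(s)] + s[-1L]) / 2, Inf)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  best <- NULL
  for (cut in cand) {
    pred <- scores > cut
    tp <- sum(pred & labels == 1L)
    tn <- sum(!pred & labels == 0L)
    acc <- (tp + tn) / length(labels)
    sens <- tp / n1
    spec <- tn / n0
    youden <- sens + spec - 1
    if (is.null(best) || acc > best$accuracy + 1e-12 ||
        (abs(acc - best$accuracy) <= 1e-12 && youden > best$youden + 1e-12)) {
      best <- list(cutoff = cut, accuracy = acc, sensitivity = sens,
                   specificity = spec, youden = youden)
    }
  }
  rev_acc <- max(vapply(cand, function(cut)
    mean((scores <= cut) == (labels == 1L)), numeric(1)))
  best$inverted_separation <- rev_acc > best$accuracy + 1e-12
  class(best) <- "rs_cutoff"
  best
}

#' Dichotomize response scores at a cutoff
#'
#' Strict rule: `RS > cutoff` is `"high"`; a score exactly at the cutoff is
#' `"low"`.
#'
#' @param scores Per-sample response scores.
#' @param cutoff Finite cutoff or a -Inf/+Inf sentinel.
#' @return Character vector of `"high"`/`"low"`, named like `scores`.
#' @export
classify_rs <- function(scores, cutoff) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || is.na(cutoff))
    stop("cutoff must be a single number (sentinels allowed)", call. = FALSE)
  out <- ifelse(scores > cutoff, "high", "low")
  if (!is.null(names(scores))) names(out) <- names(scores)
  out
}

#' Serialize a response-score model to JSON
#'
#' Stable, versioned field names so fitted models can be archived and
#' reloaded with [read_rs_model()].
#'
#' @param model An `rs_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_rs_model <- function(model, path) {
  obj <- list(
    format = "rs_model",
    format_version = 1L,
    selected_genes = model$selected_genes,
    coefficients = unname(model$coefficients),
    standardization_center = unname(model$standardization$center),
    standardization_scale = unname(model$standardization$scale),
    lambda = model$lambda,
    cutoff = model$cutoff,
    seed = model$training_meta$seed,
    cv_folds = model$training_meta$cv_folds,
    cv_accuracy = model$training_meta$cv_accuracy,
    intercept = model$training_meta$intercept,
    n_train = model$training_meta$n_train
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' Read a serialized response-score model
#'
#' @param path JSON file written by [write_rs_model()].
#' @return An `rs_model`.
#' @export
read_rs_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "rs_model"))
    stop(path, ": not an rs_model file", call. = FALSE)
  genes <- as.character(obj$selected_genes)
  model <- list(
    selected_genes = genes,
    coefficients = stats::setNames(as.numeric(obj$coefficients), genes),
    standardization = list(
      center = stats::setNames(as.numeric(obj$standardization_center), genes),
      scale = stats::setNames(as.numeric(obj$standardization_scale), genes)),
    lambda = obj$lambda,
    cutoff = if (is.null(obj$cutoff)) NA_real_ else obj$cutoff,
    training_meta = list(seed = obj$seed, cv_folds = obj$cv_folds,
                         cv_accuracy = obj$cv_accuracy,
                         intercept = obj$intercept, n_train = obj$n_train)
  )
  class(model) <- "rs_model"
  model
}
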