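# End-to-end driver: split -> feature stats -> consensus -> L1 fit -> score
# -> cutoff -> classify -> evaluation -> biomarker screens -> VAF
# monitoring, with every artifact written to a run directory and a
# deterministic manifest. All randomness flows from one root seed expanded
# per stage by fixed offsets.

responder_flag <- function(clinical) {
  stats::setNames(as.integer(clinical$best_response %in% c("CR", "PR")),
                  clinical$sample_id)
}

# stratified train/validation split by responder label
stratified_split <- function(labels, split_fraction, seed) {
  ids <- names(labels)
  with_seed(seed, {
    train <- character(0)
    for (cls in c(0L, 1L)) {
      cls_ids <- ids[labels == cls]
      n_tr <- round(split_fraction * length(cls_ids))
      train <- c(train, sample(cls_ids, n_tr))
    }
    train
  })
}

km_rows <- function(time, event, group) {
  out <- lapply(sort(unique(as.character(group))), function(g) {
    km <- kaplan_meier(time[group == g], event[group == g])
    data.frame(group = g, km$curve)
  })
  do.call(rbind, out)
}

eval_row <- function(cohort, endpoint, comparison, statistic = NA_real_,
                     p = NA_real_, hr = NA_real_, ci_lower = NA_real_,
                     ci_upper = NA_real_, note = "") {
  data.frame(cohort = cohort, endpoint = endpoint, comparison = comparison,
             statistic = statistic, p_value = p, hr = hr,
             ci_lower = ci_lower, ci_upper = ci_upper, note = note,
             stringsAsFactors = FALSE)
}

#' Run the full response-score and VAF-monitoring analysis
#'
#' Executes the complete analysis on a cohort: a stratified
#' train/validation split, per-gene criterion statistics on the training
#' set, consensus gene selection, L1-penalized model fitting,
#' response-score computation, accuracy-optimal cutoff selection on the
#' training set (frozen and reused on validation), evaluation (ROC/AUC,
#' ORR contingency tests, Kaplan-Meier/log-rank/Cox for PFS and OS),
#' quantile biomarker screens of the negative-control covariates, and VAF
#' monitoring (paired dynamics and cycle-2 detectability). All outputs are
#' written under `outdir`; a manifest records the configuration, seeds and
#' MD5 hash of every artifact, so a rerun with identical inputs and seed is
#' byte-identical.
#'
#' @param cohort A `cohort_data` object ([simulate_cohort()] or
#'   [read_cohort()]).
#' @param outdir Output directory (created if missing).
#' @param split_fraction Fraction of each response class assigned to
#'   training.
#' @param seed Root seed; stage seeds are fixed offsets from it.
#' @param min_votes Consensus vote threshold.
#' @param alpha,d_min,auc_min,gain_thr,loss_thr,n_perm Feature-filter
#'   settings ([compute_feature_stats()]).
#' @param cv_folds Cross-validation folds for the penalized fit.
#' @param lod,min_alt_reads,vaf_mode VAF detection settings.
#' @param quantiles Biomarker screen quantiles.
#' @return Invisibly, a list with the manifest, the fitted `rs_model`, the
#'   per-cohort results and the output paths.
#' @export
run_full_analysis <- function(cohort, outdir, split_fraction = 0.65,
                              seed = 1L, min_votes = 4L, alpha = 0.05,
                              d_min = 0.5, auc_min = 0.6, gain_thr = 0.2,
                              loss_thr = -0.2, n_perm = 200L, cv_folds = 5L,
                              lod = 0.001, min_alt_reads = 3L,
                              vaf_mode = "mean",
                              quantiles = c(0.25, 0.5, 0.75)) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  if (split_fraction <= 0 || split_fraction >= 1)
    stop_field("split_fraction", "must lie strictly in (0, 1)")
  seed <- as.integer(seed)
  stage_seeds <- c(split = seed + 101L, features = seed + 202L,
                   fit = seed + 303L)
  completed <- character(0)
  manifest_path <- file.path(outdir, "manifest.json")
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      partial <- list(status = "failed", failed_stage = name,
                      error = conditionMessage(e),
                      completed_stages = completed, seed = seed)
      jsonlite::write_json(partial, manifest_path, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      stop(sprintf("stage '%s': %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    completed <<- c(completed, name)
    res
  }

  labels <- responder_flag(cohort$clinical)
  clin <- cohort$clinical

  train_ids <- stage("split",
                     stratified_split(labels, split_fraction,
                                      stage_seeds[["split"]]))
  val_ids <- setdiff(names(labels), train_ids)

  stats_tab <- stage("features", compute_feature_stats(
    cohort$cnv[train_ids, , drop = FALSE], labels[train_ids],
    alpha = alpha, d_min = d_min, auc_min = auc_min,
    gain_thr = gain_thr, loss_thr = loss_thr, n_perm = n_perm,
    seed = stage_seeds[["features"]]))
  write_tsv_numeric(
    transform(stats_tab,
              pass_chi2 = as.integer(pass_chi2),
              pass_wilcoxon = as.integer(pass_wilcoxon),
              pass_anova = as.integer(pass_anova),
              pass_ttest = as.integer(pass_ttest),
              pass_deviation = as.integer(pass_deviation),
              pass_auc = as.integer(pass_auc),
              pass_mi = as.integer(pass_mi)),
    file.path(outdir, "feature_stats.tsv"))

  genes <- stage("consensus", {
    g <- consensus_select(stats_tab, min_votes)
    if (!length(g)) stop("empty feature set: no gene reached ", min_votes,
                         " votes")
    g
  })

  model <- stage("fit", fit_rs_model(
    cohort$cnv[train_ids, , drop = FALSE], labels[train_ids], genes,
    cv_folds = cv_folds, seed = stage_seeds[["fit"]]))

  rs_train <- stage("score", compute_rs(model, cohort$cnv[train_ids, , drop = FALSE]))
  rs_val <- compute_rs(model, cohort$cnv[val_ids, , drop = FALSE])

  cut_res <- stage("cutoff", select_cutoff(rs_train, labels[train_ids]))
  model$cutoff <- cut_res$cutoff
  write_rs_model(model, file.path(outdir, "rs_model.json"))

  grp_train <- stage("classify", classify_rs(rs_train, model$cutoff))
  grp_val <- classify_rs(rs_val, model$cutoff)
  scores_tab <- data.frame(
    sample_id = c(train_ids, val_ids),
    cohort = rep(c("training", "validation"),
                 c(length(train_ids), length(val_ids))),
    rs = c(rs_train, rs_val),
    rs_group = c(grp_train, grp_val),
    stringsAsFactors = FALSE
  )
  write_tsv_numeric(scores_tab, file.path(outdir, "rs_scores.tsv"))

  results <- stage("evaluate", {
    res <- list()
    rows <- list()
    km <- list()
    for (set in c("training", "validation")) {
      ids <- if (set == "training") train_ids else val_ids
      sc <- if (set == "training") rs_train else rs_val
      gr <- if (set == "training") grp_train else grp_val
      cl <- clin[match(ids, clin$sample_id), ]
      roc <- roc_curve_auc(sc, labels[ids])
      rows[[length(rows) + 1]] <- eval_row(set, "response", "RS continuous",
                                           statistic = roc$auc,
                                           note = "ROC AUC")
      orr <- tryCatch(response_association(gr, labels[ids]),
                      error = function(e) NULL)
      if (!is.null(orr)) {
        rows[[length(rows) + 1]] <- eval_row(
          set, "response", "RS high vs low", statistic = orr$statistic,
          p = orr$p_value,
          note = sprintf("ORR %.1f%% vs %.1f%% (%s)",
                         100 * orr$orr[["high"]], 100 * orr$orr[["low"]],
                         orr$test_name))
      } else {
        rows[[length(rows) + 1]] <- eval_row(set, "response",
                                             "RS high vs low",
                                             note = "single RS group")
      }
      for (ep in c("pfs", "os")) {
        tm <- cl[[paste0(ep, "_days")]]
        ev <- cl[[paste0(ep, "_event")]]
        lr <- tryCatch(log_rank(tm, ev, gr), error = function(e) NULL)
        cx <- tryCatch(cox_hr(tm, ev, gr, reference = "low"),
                       error = function(e) NULL)
        rows[[length(rows) + 1]] <- eval_row(
          set, toupper(ep), "RS high vs low",
          statistic = if (!is.null(lr)) lr$chisq else NA_real_,
          p = if (!is.null(lr)) lr$p_value else NA_real_,
          hr = if (!is.null(cx)) cx$hr else NA_real_,
          ci_lower = if (!is.null(cx)) cx$ci_lower else NA_real_,
          ci_upper = if (!is.null(cx)) cx$ci_upper else NA_real_,
          note = "log-rank; Cox HR high vs low")
        if (ep == "pfs" && length(unique(gr)) == 2L)
          km[[set]] <- cbind(cohort = set, km_rows(tm, ev, gr))
      }
      res[[set]] <- list(auc = roc$auc, orr = orr)
    }
    res$report <- do.call(rbind, rows)
    res$km <- if (length(km)) do.call(rbind, km) else NULL
    res
  })
  write_tsv_numeric(results$report, file.path(outdir, "evaluation_report.tsv"))
  if (!is.null(results$km))
    write_tsv_numeric(results$km, file.path(outdir, "km_curves.tsv"))

  screens <- stage("screen", {
    out <- list()
    biomarkers <- intersect(c("tmb", "cfdna_conc", "ctdna_fraction"),
                            names(clin))
    bl_max <- tapply(cohort$variants$vaf[cohort$variants$timepoint == "BL"],
                     cohort$variants$sample_id[cohort$variants$timepoint == "BL"],
                     max)
    extra <- list()
    if (length(bl_max)) {
      v <- stats::setNames(rep(0, nrow(clin)), clin$sample_id)
      v[names(bl_max)] <- bl_max
      extra$max_vaf <- v
    }
    for (b in biomarkers) {
      scr <- biomarker_cutoff_screen(clin[[b]], labels[clin$sample_id],
                                     clin$pfs_days, clin$pfs_event,
                                     quantiles)
      out[[b]] <- cbind(biomarker = b, scr)
    }
    for (b in names(extra)) {
      scr <- biomarker_cutoff_screen(extra[[b]], labels[clin$sample_id],
                                     clin$pfs_days, clin$pfs_event,
                                     quantiles)
      out[[b]] <- cbind(biomarker = b, scr)
    }
    do.call(rbind, out)
  })
  write_tsv_numeric(screens, file.path(outdir, "biomarker_screen.tsv"))

  vaf <- stage("monitor_vaf", {
    summaries <- summarize_vaf_cohort(cohort$variants,
                                      cohort$variant_manifest,
                                      lod = lod,
                                      min_alt_reads = min_alt_reads,
                                      mode = vaf_mode)
    paired <- paired_vaf_change(summaries, labels)
    c2 <- summaries[summaries$timepoint == "C2", ]
    det <- tryCatch(detectability_association(
      c2, labels,
      stats::setNames(clin$pfs_days, clin$sample_id),
      stats::setNames(clin$pfs_event, clin$sample_id)),
      error = function(e) NULL)
    list(summaries = summaries, paired = paired, detectability = det)
  })
  write_tsv_numeric(vaf$summaries, file.path(outdir, "vaf_summary.tsv"))
  vaf_report <- vaf$paired
  write_tsv_numeric(vaf_report, file.path(outdir, "vaf_monitoring_report.tsv"))

  summary_md <- c(
    "# Analysis summary",
    "",
    sprintf("- cohort: %d patients (%d training / %d validation)",
            nrow(clin), length(train_ids), length(val_ids)),
    sprintf("- consensus-selected genes (>= %d votes): %d", min_votes,
            length(genes)),
    sprintf("- model genes after L1 fit: %d (lambda = %.5g)",
            length(model$selected_genes), model$lambda),
    sprintf("- RS cutoff: %.5g (training accuracy %.3f)", model$cutoff,
            cut_res$accuracy),
    sprintf("- training ROC AUC: %.3f | validation ROC AUC: %.3f",
            results$training$auc, results$validation$auc),
    if (!is.null(results$training$orr))
      sprintf("- training ORR high vs low: %.1f%% vs %.1f%% (p = %.3g)",
              100 * results$training$orr$orr[["high"]],
              100 * results$training$orr$orr[["low"]],
              results$training$orr$p_value),
    if (!is.null(results$validation$orr))
      sprintf("- validation ORR high vs low: %.1f%% vs %.1f%% (p = %.3g)",
              100 * results$validation$orr$orr[["high"]],
              100 * results$validation$orr$orr[["low"]],
              results$validation$orr$p_value),
    if (!is.null(vaf$detectability))
      sprintf("- C2 undetectable vs detectable: ORR %.1f%% vs %.1f%%, PFS HR %.2f",
              100 * vaf$detectability$response$orr[["undetectable"]],
              100 * vaf$detectability$response$orr[["detectable"]],
              vaf$detectability$cox$hr)
  )
  writeLines(summary_md, file.path(outdir, "summary.md"))

  outputs <- c("feature_stats.tsv", "rs_model.json", "rs_scores.tsv",
               "evaluation_report.tsv", "biomarker_screen.tsv",
               "vaf_summary.tsv", "vaf_monitoring_report.tsv", "summary.md")
  if (!is.null(results$km)) outputs <- append(outputs, "km_curves.tsv", 4)
  hashes <- as.list(tools::md5sum(file.path(outdir, outputs)))
  names(hashes) <- outputs

  manifest <- list(
    status = "complete",
    package_version = as.character(utils::packageVersion("cfrs")),
    seed = seed,
    stage_seeds = as.list(stage_seeds),
    config = list(split_fraction = split_fraction, min_votes = min_votes,
                  alpha = alpha, d_min = d_min, auc_min = auc_min,
                  gain_thr = gain_thr, loss_thr = loss_thr,
                  n_perm = n_perm, cv_folds = cv_folds, lod = lod,
                  min_alt_reads = min_alt_reads, vaf_mode = vaf_mode,
                  quantiles = quantiles),
    train_ids = sort(train_ids),
    validation_ids = sort(val_ids),
    standardization = list(
      center = as.list(model$standardization$center),
      scale = as.list(model$standardization$scale)),
    cutoff = model$cutoff,
    completed_stages = completed,
    output_hashes = hashes
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(manifest = manifest, model = model, results = results,
                 screens = screens, vaf = vaf,
                 paths = stats::setNames(
                   file.path(outdir, c(outputs, "manifest.json")),
                   c(outputs, "manifest.json"))))
}
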