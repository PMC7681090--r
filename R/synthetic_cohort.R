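#' Configuration for the synthetic two-arm cohort generator
#'
#' Parameterizes [simulate_cohort()]. Defaults reproduce the structure of the
#' two-arm chemotherapy cohort the package models: 155 patients split ~80/75
#' across the LP and GP arms, a ~60% objective response rate, copy-number
#' signal concentrated in the 31-gene effect set ([cnv_effect_genes]) on a
#' background of null genes, exponential progression-free survival coupled to
#' response, and baseline/cycle-2 variant allele frequencies that shrink in
#' responders and grow in non-responders.
#'
#' @param n_patients Cohort size.
#' @param arm_fractions Named proportions for the LP and GP arms (sum to 1).
#' @param responder_rate Probability a patient is a responder (CR/PR).
#' @param panel_genes CNV panel gene symbols. Default: `effect_genes` plus
#'   `n_null_genes` synthetic null genes (`NULL001`, ...).
#' @param effect_genes Genes carrying the responder/non-responder shift; must
#'   be a subset of `panel_genes`.
#' @param n_null_genes Number of null genes appended when `panel_genes` is
#'   left `NULL`.
#' @param effect_size Standardized mean shift (Cohen's d) between responders
#'   and non-responders on effect genes, in units of `noise_sd`.
#' @param noise_sd Standard deviation of per-gene log2 copy ratios.
#' @param p_cr_given_responder Probability a responder is CR (rest PR).
#' @param p_sd_given_nonresponder Probability a non-responder is SD (rest PD).
#' @param median_pfs_responder,median_pfs_nonresponder Median PFS in days for
#'   each response group (exponential event times).
#' @param median_os_tail Median of the exponential tail added to PFS to form
#'   OS, days.
#' @param censoring_rate Probability a patient's follow-up is censored.
#' @param variant_panel Monitoring panel gene symbols ([vaf_panel_genes]).
#' @param mean_variants Mean of the zero-truncated Poisson count of baseline
#'   variants per patient.
#' @param mean_depth Mean sequencing depth at variant sites.
#' @param vaf_baseline_log_mean,vaf_baseline_log_sd Log-scale parameters of
#'   the lognormal baseline VAF distribution.
#' @param vaf_shrink_responder Multiplicative cycle-2 VAF factor in
#'   responders (< 1).
#' @param vaf_grow_nonresponder Multiplicative cycle-2 VAF factor in
#'   non-responders (> 1).
#' @param vaf_jitter_sd Log-scale SD of the per-variant lognormal jitter
#'   applied to the cycle-2 factor.
#' @param clear_prob_responder,clear_prob_nonresponder Per-patient probability
#'   that all cycle-2 variants fall below the detection limit.
#' @param lod VAF limit of detection used downstream; the generator records
#'   sub-LOD variants with their observed values (flagging is downstream).
#' @param seed Integer seed; the entire cohort is a deterministic function of
#'   the configuration.
#' @return A validated list of class `sim_config`.
#' @seealso [simulate_cohort()], [write_cohort()]
#' @export
sim_config <- function(n_patients = 155L,
                       arm_fractions = c(LP = 80 / 155, GP = 75 / 155),
                       responder_rate = 93 / 155,
                       panel_genes = NULL,
                       effect_genes = cnv_effect_genes,
                       n_null_genes = 100L,
                       effect_size = 1.0,
                       noise_sd = 0.25,
                       p_cr_given_responder = 0.02,
                       p_sd_given_nonresponder = 0.45,
                       median_pfs_responder = 230,
                       median_pfs_nonresponder = 95,
                       median_os_tail = 190,
                       censoring_rate = 0.2,
                       variant_panel = vaf_panel_genes,
                       mean_variants = 5,
                       mean_depth = 15000,
                       vaf_baseline_log_mean = log(0.02),
                       vaf_baseline_log_sd = 0.8,
                       vaf_shrink_responder = 0.3,
                       vaf_grow_nonresponder = 1.5,
                       vaf_jitter_sd = 0.4,
                       clear_prob_responder = 0.8,
                       clear_prob_nonresponder = 0.1,
                       lod = 0.001,
                       seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 2)
    stop_field("n_patients", "must be a single integer >= 2")
  n_patients <- as.integer(n_patients)
  if (is.list(arm_fractions)) arm_fractions <- unlist(arm_fractions)
  if (is.list(effect_genes)) effect_genes <- unlist(effect_genes)
  if (is.list(panel_genes)) panel_genes <- unlist(panel_genes)
  if (is.list(variant_panel)) variant_panel <- unlist(variant_panel)
  if (length(arm_fractions) != 2L || is.null(names(arm_fractions)) ||
      !setequal(names(arm_fractions), c("LP", "GP")))
    stop_field("arm_fractions", "must be a named length-2 vector for LP and GP")
  if (any(arm_fractions < 0) || abs(sum(arm_fractions) - 1) > 1e-8)
    stop_field("arm_fractions", "must be non-negative and sum to 1")
  check_prob(responder_rate, "responder_rate")
  check_prob(censoring_rate, "censoring_rate")
  check_prob(p_cr_given_responder, "p_cr_given_responder")
  check_prob(p_sd_given_nonresponder, "p_sd_given_nonresponder")
  check_prob(clear_prob_responder, "clear_prob_responder")
  check_prob(clear_prob_nonresponder, "clear_prob_nonresponder")
  if (is.null(panel_genes)) {
    if (n_null_genes < 0) stop_field("n_null_genes", "must be >= 0")
    panel_genes <- c(effect_genes,
                     if (n_null_genes > 0) sprintf("NULL%03d", seq_len(n_null_genes)))
  }
  if (anyDuplicated(panel_genes))
    stop_field("panel_genes", "contains duplicate gene symbols")
  if (!all(effect_genes %in% panel_genes))
    stop_field("effect_genes", "must be a subset of panel_genes")
  if (!is.numeric(effect_size) || length(effect_size) != 1L || effect_size < 0)
    stop_field("effect_size", "must be a single non-negative number")
  check_pos(noise_sd, "noise_sd")
  check_pos(median_pfs_responder, "median_pfs_responder")
  check_pos(median_pfs_nonresponder, "median_pfs_nonresponder")
  check_pos(median_os_tail, "median_os_tail")
  check_pos(mean_variants, "mean_variants")
  check_pos(mean_depth, "mean_depth")
  check_pos(vaf_baseline_log_sd, "vaf_baseline_log_sd")
  check_pos(vaf_jitter_sd, "vaf_jitter_sd")
  check_pos(lod, "lod")
  if (!is.numeric(vaf_baseline_log_mean) || length(vaf_baseline_log_mean) != 1L ||
      !is.finite(vaf_baseline_log_mean))
    stop_field("vaf_baseline_log_mean", "must be a single finite number")
  if (!(vaf_shrink_responder > 0 && vaf_shrink_responder < 1))
    stop_field("vaf_shrink_responder", "must lie in (0, 1)")
  if (!(vaf_grow_nonresponder > 1))
    stop_field("vaf_grow_nonresponder", "must exceed 1")
  if (anyDuplicated(variant_panel))
    stop_field("variant_panel", "contains duplicate gene symbols")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_field("seed", "must be a single integer")
  cfg <- list(
    n_patients = n_patients,
    arm_fractions = arm_fractions[c("LP", "GP")],
    responder_rate = responder_rate,
    panel_genes = panel_genes,
    effect_genes = effect_genes,
    effect_size = effect_size,
    noise_sd = noise_sd,
    p_cr_given_responder = p_cr_given_responder,
    p_sd_given_nonresponder = p_sd_given_nonresponder,
    median_pfs_responder = median_pfs_responder,
    median_pfs_nonresponder = median_pfs_nonresponder,
    median_os_tail = median_os_tail,
    censoring_rate = censoring_rate,
    variant_panel = variant_panel,
    mean_variants = mean_variants,
    mean_depth = mean_depth,
    vaf_baseline_log_mean = vaf_baseline_log_mean,
    vaf_baseline_log_sd = vaf_baseline_log_sd,
    vaf_shrink_responder = vaf_shrink_responder,
    vaf_grow_nonresponder = vaf_grow_nonresponder,
    vaf_jitter_sd = vaf_jitter_sd,
    clear_prob_responder = clear_prob_responder,
    clear_prob_nonresponder = clear_prob_nonresponder,
    lod = lod,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

# zero-truncated Poisson draw via the inverse CDF
rpois_trunc1 <- function(n, lambda) {
  stats::qpois(stats::runif(n, stats::ppois(0, lambda), 1), lambda)
}

# deterministic synthetic locus for a panel gene
gene_locus <- function(gene) {
  h <- vapply(gene, function(g) sum(utf8ToInt(g) * seq_along(utf8ToInt(g))),
              numeric(1), USE.NAMES = FALSE)
  list(chrom = paste0("chr", (h %% 22) + 1),
       pos = 1e6 + (h * 7919) %% 5e7)
}

#' Simulate a synthetic two-arm chemotherapy cohort
#'
#' Draws a complete cohort with the statistical coupling the downstream
#' analysis assumes: responder labels at `responder_rate`; effect genes'
#' log2 copy ratios shifted by `effect_size * noise_sd` in responders (sign
#' alternating per gene, so both gains and losses occur); exponential PFS with
#' group-specific medians and uniform censoring, OS = PFS plus an exponential
#' tail (so OS >= PFS always); lognormal baseline VAFs with binomial read
#' support at the sampled depth; and cycle-2 VAFs equal to baseline times the
#' group factor times per-variant lognormal jitter, with a per-patient
#' probability of full sub-LOD clearance. Variants whose sampled alt read
#' count is zero are not emitted, but every patient-timepoint is recorded in
#' the variant manifest.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `cohort_data` with elements `cnv` (samples x genes
#'   numeric matrix of log2 ratios), `clinical` (data frame: sample_id, arm,
#'   best_response, pfs_days, pfs_event, os_days, os_event, tmb, cfdna_conc,
#'   ctdna_fraction), `variants` (long data frame of calls), `variant_manifest`
#'   (all sample-timepoint pairs), `truth` (generative ground truth: responder
#'   flags, effect genes, cleared flags), and `config`.
#' @examples
#' coh <- simulate_cohort(sim_config(n_patients = 20, seed = 7))
#' dim(coh$cnv)
#' table(coh$clinical$arm)
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("config must be created by sim_config()", call. = FALSE)
  with_seed(config$seed, {
    n <- config$n_patients
    ids <- sprintf("P%04d", seq_len(n))

    n_lp <- as.integer(round(n * config$arm_fractions[["LP"]]))
    n_lp <- min(max(n_lp, 0L), n)
    arm <- sample(rep(c("LP", "GP"), c(n_lp, n - n_lp)))

    responder <- stats::rbinom(n, 1L, config$responder_rate)
    best_response <- ifelse(
      responder == 1L,
      ifelse(stats::runif(n) < config$p_cr_given_responder, "CR", "PR"),
      ifelse(stats::runif(n) < config$p_sd_given_nonresponder, "SD", "PD"))

    genes <- config$panel_genes
    cnv <- matrix(stats::rnorm(n * length(genes), 0, config$noise_sd),
                  nrow = n, dimnames = list(ids, genes))
    if (config$effect_size > 0 && any(responder == 1L)) {
      shift <- gene_effect_sign(config$effect_genes) *
        config$effect_size * config$noise_sd
      idx <- which(responder == 1L)
      cnv[idx, config$effect_genes] <-
        cnv[idx, config$effect_genes, drop = FALSE] +
        matrix(shift, nrow = length(idx), ncol = length(shift), byrow = TRUE)
    }

    med_pfs <- ifelse(responder == 1L, config$median_pfs_responder,
                      config$median_pfs_nonresponder)
    pfs_latent <- stats::rexp(n, rate = log(2) / med_pfs)
    censored <- stats::rbinom(n, 1L, config$censoring_rate) == 1L
    pfs_days <- ifelse(censored, stats::runif(n, 0, pfs_latent), pfs_latent)
    pfs_days <- pmax(pfs_days, 1)
    pfs_event <- as.integer(!censored)
    os_days <- pfs_days + stats::rexp(n, rate = log(2) / config$median_os_tail)
    os_event <- pfs_event

    clinical <- data.frame(
      sample_id = ids,
      arm = arm,
      best_response = best_response,
      pfs_days = pfs_days,
      pfs_event = pfs_event,
      os_days = os_days,
      os_event = os_event,
      tmb = stats::rlnorm(n, log(7), 0.5),
      cfdna_conc = stats::rlnorm(n, log(10), 0.6),
      ctdna_fraction = stats::rbeta(n, 2, 18),
      stringsAsFactors = FALSE
    )

    # variant calls: k baseline variants per patient on the monitoring panel
    k <- rpois_trunc1(n, config$mean_variants)
    k <- pmin(k, length(config$variant_panel))
    cleared <- stats::rbinom(n, 1L, ifelse(responder == 1L,
                                           config$clear_prob_responder,
                                           config$clear_prob_nonresponder)) == 1L
    factor_grp <- ifelse(responder == 1L, config$vaf_shrink_responder,
                         config$vaf_grow_nonresponder)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      vg <- sample(config$variant_panel, k[i])
      loc <- gene_locus(vg)
      pos <- as.integer(loc$pos + seq_len(k[i]))
      ref <- sample(c("A", "C", "G", "T"), k[i], replace = TRUE)
      alt <- vapply(ref, function(r)
        sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1),
        USE.NAMES = FALSE)
      vaf_bl <- pmin(stats::rlnorm(k[i], config$vaf_baseline_log_mean,
                                   config$vaf_baseline_log_sd), 0.5)
      if (cleared[i]) {
        vaf_c2 <- config$lod * stats::runif(k[i], 0.05, 0.3)
      } else {
        vaf_c2 <- pmin(vaf_bl * factor_grp[i] *
                         stats::rlnorm(k[i], 0, config$vaf_jitter_sd), 0.5)
      }
      depth_bl <- pmax(round(stats::rlnorm(k[i], log(config$mean_depth), 0.15)), 1000)
      depth_c2 <- pmax(round(stats::rlnorm(k[i], log(config$mean_depth), 0.15)), 1000)
      alt_bl <- stats::rbinom(k[i], depth_bl, vaf_bl)
      alt_c2 <- stats::rbinom(k[i], depth_c2, vaf_c2)
      rows[[i]] <- data.frame(
        sample_id = ids[i],
        timepoint = rep(c("BL", "C2"), each = k[i]),
        gene = c(vg, vg),
        chrom = c(loc$chrom, loc$chrom),
        pos = c(pos, pos),
        ref = c(ref, ref),
        alt = c(alt, alt),
        alt_reads = c(alt_bl, alt_c2),
        depth = c(depth_bl, depth_c2),
        stringsAsFactors = FALSE
      )
    }
    variants <- do.call(rbind, rows)
    variants <- variants[variants$alt_reads > 0, , drop = FALSE]
    variants$vaf <- variants$alt_reads / variants$depth
    rownames(variants) <- NULL

    manifest <- data.frame(
      sample_id = rep(ids, each = 2L),
      timepoint = rep(c("BL", "C2"), times = n),
      stringsAsFactors = FALSE
    )

    out <- list(
      cnv = cnv,
      clinical = clinical,
      variants = variants,
      variant_manifest = manifest,
      truth = list(responder = stats::setNames(responder, ids),
                   effect_genes = config$effect_genes,
                   cleared_c2 = stats::setNames(cleared, ids)),
      config = config
    )
    class(out) <- "cohort_data"
    out
  })
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d patients, %d CNV genes, %d variant calls\n",
              nrow(x$cnv), ncol(x$cnv), nrow(x$variants)))
  cat(sprintf("  arms: %s | responders: %d (%.1f%%)\n",
              paste(names(table(x$clinical$arm)),
                    table(x$clinical$arm), collapse = " / "),
              sum(x$truth$responder),
              100 * mean(x$truth$responder)))
  invisible(x)
}

#' Write a cohort to plain-text fixture files
#'
#' Emits `cnv_matrix.tsv`, `clinical.tsv`, `variants.tsv` and
#' `variant_manifest.tsv` in `directory`. Numeric values are written with
#' enough digits that reading them back ([read_cohort()]) reproduces the
#' cohort exactly.
#'
#' @param cohort A `cohort_data` object (or a list with the same elements).
#' @param directory Output directory; created if missing.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, directory) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(directory))
      stop("cannot create directory: ", directory, call. = FALSE)
  }
  paths <- c(
    cnv = file.path(directory, "cnv_matrix.tsv"),
    clinical = file.path(directory, "clinical.tsv"),
    variants = file.path(directory, "variants.tsv"),
    manifest = file.path(directory, "variant_manifest.tsv")
  )
  write_cnv_matrix(cohort$cnv, paths[["cnv"]])
  write_tsv_numeric(cohort$clinical, paths[["clinical"]])
  write_tsv_numeric(cohort$variants, paths[["variants"]])
  write_tsv_numeric(cohort$variant_manifest, paths[["manifest"]])
  invisible(paths)
}
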