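# ctDNA monitoring: per-sample VAF summarization at baseline and cycle 2,
# paired change testing within response groups, and cycle-2 detectability
# association with response and survival.

#' Summarize variant calls for one sample-timepoint
#'
#' A variant is detected iff `vaf >= lod` and `alt_reads >= min_alt_reads`.
#' The per-sample summary is the arithmetic mean (or maximum, with
#' `mode = "max"`) of detected variants' VAFs; with no detected variant the
#' sample is undetectable and the summary is 0.
#'
#' @param calls Data frame of calls sharing one sample and timepoint (may
#'   have zero rows).
#' @param lod VAF limit of detection.
#' @param min_alt_reads Minimum supporting reads.
#' @param mode Summary statistic over detected variants.
#' @param sample_id,timepoint Identifiers used when `calls` is empty.
#' @return One-row data frame: `sample_id`, `timepoint`,
#'   `n_variants_detected`, `summary_vaf`, `detectable`.
#' @export
summarize_vaf <- function(calls, lod = 0.001, min_alt_reads = 3L,
                          mode = c("mean", "max"),
                          sample_id = NULL, timepoint = NULL) {
  mode <- match.arg(mode)
  if (nrow(calls) > 0L) {
    if (length(unique(calls$sample_id)) != 1L ||
        length(unique(calls$timepoint)) != 1L)
      stop("calls must share a single sample and timepoint", call. = FALSE)
    sample_id <- calls$sample_id[1]
    timepoint <- calls$timepoint[1]
    detected <- calls$vaf >= lod & calls$alt_reads >= min_alt_reads
    n_det <- sum(detected)
    summary_vaf <- if (n_det > 0L) {
      if (mode == "mean") mean(calls$vaf[detected]) else max(calls$vaf[detected])
    } else 0
  } else {
    n_det <- 0L
    summary_vaf <- 0
  }
  data.frame(sample_id = sample_id %||% NA_character_,
             timepoint = timepoint %||% NA_character_,
             n_variants_detected = as.integer(n_det),
             summary_vaf = summary_vaf,
             detectable = n_det >= 1L,
             stringsAsFactors = FALSE)
}

#' Summarize VAFs for every sample-timepoint of a cohort
#'
#' Applies [summarize_vaf()] to each sample-timepoint listed in the
#' manifest, so timepoints with no reportable calls still yield an
#' (undetectable) summary row.
#'
#' @param variants Long variant table ([read_variants()] schema).
#' @param manifest Sample-timepoint manifest; defaults to the pairs present
#'   in `variants` (in which case empty timepoints are invisible).
#' @param lod,min_alt_reads,mode Passed to [summarize_vaf()].
#' @return Data frame, one row per manifest entry.
#' @export
summarize_vaf_cohort <- function(variants, manifest = NULL, lod = 0.001,
                                 min_alt_reads = 3L, mode = c("mean", "max")) {
  mode <- match.arg(mode)
  if (is.null(manifest)) {
    manifest <- unique(variants[c("sample_id", "timepoint")])
  }
  key_v <- paste(variants$sample_id, variants$timepoint, sep = "\r")
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    sel <- key_v == paste(manifest$sample_id[i], manifest$timepoint[i],
                          sep = "\r")
    summarize_vaf(variants[sel, , drop = FALSE], lod = lod,
                  min_alt_reads = min_alt_reads, mode = mode,
                  sample_id = manifest$sample_id[i],
                  timepoint = manifest$timepoint[i])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired VAF change between baseline and cycle 2, by response group
#'
#' Per patient, `delta = summary_vaf(C2) - summary_vaf(BL)`; within each
#' response group (responders CR/PR vs non-responders SD/PD) a two-sided
#' paired t-test (one-sample t on the deltas) is reported. Patients without
#' a detectable baseline signal are excluded (delta is undefined without a
#' baseline) and listed in the `dropped` attribute. A group whose deltas
#' are identically zero is reported with p = 1 and a degenerate flag; a
#' group with identical nonzero deltas is a degenerate-variance error.
#'
#' @param summaries Long summary table from [summarize_vaf_cohort()]
#'   containing both timepoints.
#' @param labels Binary responder labels named by sample id.
#' @return Data frame with one row per group: `group`, `n`, `mean_change`,
#'   `t`, `df`, `p_value`, `degenerate`; attribute `dropped` holds the
#'   excluded sample ids.
#' @export
paired_vaf_change <- function(summaries, labels) {
  bl <- summaries[summaries$timepoint == "BL", ]
  c2 <- summaries[summaries$timepoint == "C2", ]
  ids <- intersect(bl$sample_id, c2$sample_id)
  if (!length(ids))
    stop("no patients with both baseline and C2 summaries", call. = FALSE)
  bl <- bl[match(ids, bl$sample_id), ]
  c2 <- c2[match(ids, c2$sample_id), ]
  keep <- bl$detectable
  dropped <- ids[!keep]
  ids <- ids[keep]
  delta <- c2$summary_vaf[keep] - bl$summary_vaf[keep]
  lab <- as_binary_labels(labels[ids], require_both = FALSE)
  rows <- lapply(c(responder = 1L, non_responder = 0L), function(cls) {
    d <- delta[lab == cls]
    nm <- if (cls == 1L) "responder" else "non_responder"
    if (length(d) < 2L)
      stop("group '", nm, "' has fewer than 2 paired patients", call. = FALSE)
    if (stats::sd(d) == 0) {
      if (all(d == 0)) {
        return(data.frame(group = nm, n = length(d), mean_change = 0,
                          t = NA_real_, df = length(d) - 1L, p_value = 1,
                          degenerate = TRUE))
      }
      stop("group '", nm, "' has zero-variance nonzero deltas", call. = FALSE)
    }
    tt <- stats::t.test(d)
    data.frame(group = nm, n = length(d), mean_change = mean(d),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value, degenerate = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Cycle-2 detectability vs response and survival
#'
#' Splits patients by ctDNA detectability at cycle 2 and returns the
#' response-rate comparison ([response_association()]), the log-rank test
#' and the Cox hazard ratio (undetectable relative to detectable, so an
#' HR < 1 means undetectable patients progress later).
#'
#' @param c2_summaries Cycle-2 rows of [summarize_vaf_cohort()] output.
#' @param labels Binary responder labels named by sample id.
#' @param time,event Survival endpoint named by or aligned with
#'   `c2_summaries$sample_id`.
#' @return List: `response` (contingency result), `logrank`, `cox`,
#'   `groups` (named detectability assignment).
#' @export
detectability_association <- function(c2_summaries, labels, time, event) {
  stopifnot(all(c2_summaries$timepoint == "C2"))
  ids <- c2_summaries$sample_id
  grp <- ifelse(c2_summaries$detectable, "detectable", "undetectable")
  if (length(unique(grp)) < 2L)
    stop("both detectable and undetectable groups must be non-empty",
         call. = FALSE)
  if (!is.null(names(labels))) labels <- labels[ids]
  if (!is.null(names(time))) time <- time[ids]
  if (!is.null(names(event))) event <- event[ids]
  list(
    response = response_association(grp, labels),
    logrank = log_rank(time, event, grp),
    cox = cox_hr(time, event, grp, reference = "detectable"),
    groups = stats::setNames(grp, ids)
  )
}
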