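# Readers and writers for the pipeline's plain-text interchange formats.
# All readers validate strictly and report the offending file, line and
# column; no silent coercion or imputation.

write_tsv_numeric <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("failed to write: ", path, call. = FALSE)
  invisible(path)
}

#' Write a CNV matrix to TSV
#'
#' Header `sample_id` followed by gene symbols; one row per sample; values
#' are log2 copy ratios at full precision.
#'
#' @param cnv Numeric matrix, samples in rows (rownames = sample ids).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cnv_matrix <- function(cnv, path) {
  df <- data.frame(sample_id = rownames(cnv),
                   as.data.frame(cnv, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_numeric(df, path)
}

read_err <- function(path, line, column, msg) {
  stop(sprintf("%s: line %s, column '%s': %s", path, line, column, msg),
       call. = FALSE)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
}

#' Read a gene-level CNV matrix
#'
#' Expects the format written by [write_cnv_matrix()]: a `sample_id` column
#' followed by one numeric column per gene. Duplicate sample or gene
#' identifiers and non-finite cells are rejected (no imputation).
#'
#' @param path TSV file path.
#' @return Numeric matrix with sample rownames and gene colnames.
#' @export
read_cnv_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  require_columns(df, "sample_id", path)
  if (ncol(df) < 2L)
    stop(path, ": no gene columns found", call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop(path, ": duplicate sample_id: ",
         df$sample_id[duplicated(df$sample_id)][1], call. = FALSE)
  genes <- setdiff(names(df), "sample_id")
  if (anyDuplicated(genes))
    stop(path, ": duplicate gene column: ", genes[duplicated(genes)][1],
         call. = FALSE)
  for (g in genes) {
    v <- df[[g]]
    if (!is.numeric(v)) v <- suppressWarnings(as.numeric(v))
    bad <- which(!is.finite(v))
    if (length(bad))
      read_err(path, bad[1] + 1L, g, "non-finite or non-numeric CNV value")
    df[[g]] <- v
  }
  m <- as.matrix(df[genes])
  rownames(m) <- df$sample_id
  m
}

#' Read a clinical outcome table
#'
#' Required columns: `sample_id`, `arm` (LP|GP), `best_response`
#' (CR|PR|SD|PD), `pfs_days`, `pfs_event` (0|1), `os_days`, `os_event`
#' (0|1). Optional numeric columns `tmb`, `cfdna_conc`, `ctdna_fraction`
#' are kept when present. Any out-of-vocabulary category or non-positive
#' time is rejected with its line number.
#'
#' @param path TSV file path.
#' @return Validated data frame.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(df, c("sample_id", "arm", "best_response", "pfs_days",
                        "pfs_event", "os_days", "os_event"), path)
  if (anyDuplicated(df$sample_id))
    stop(path, ": duplicate sample_id: ",
         df$sample_id[duplicated(df$sample_id)][1], call. = FALSE)
  bad <- which(!df$arm %in% c("LP", "GP"))
  if (length(bad)) read_err(path, bad[1] + 1L, "arm", paste0(
    "unknown arm '", df$arm[bad[1]], "'"))
  bad <- which(!df$best_response %in% c("CR", "PR", "SD", "PD"))
  if (length(bad)) read_err(path, bad[1] + 1L, "best_response", paste0(
    "unknown best_response '", df$best_response[bad[1]], "'"))
  for (col in c("pfs_days", "os_days")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad)) read_err(path, bad[1] + 1L, col, "must be a positive number")
    df[[col]] <- v
  }
  for (col in c("pfs_event", "os_event")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(is.na(v) | !v %in% c(0L, 1L))
    if (length(bad)) read_err(path, bad[1] + 1L, col, "must be 0 or 1")
    df[[col]] <- v
  }
  for (col in intersect(c("tmb", "cfdna_conc", "ctdna_fraction"), names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad)) read_err(path, bad[1] + 1L, col, "must be a finite number")
    df[[col]] <- v
  }
  df
}

#' Read a per-timepoint variant call table
#'
#' Columns: `sample_id`, `timepoint` (BL|C2), `gene`, `chrom`, `pos`
#' (1-based), `ref`, `alt`, `alt_reads`, `depth`, `vaf`. Enforces
#' `0 <= alt_reads <= depth` and `vaf == alt_reads / depth` to within 1e-9.
#'
#' @param path TSV file path.
#' @return Validated data frame.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(df, c("sample_id", "timepoint", "gene", "chrom", "pos",
                        "ref", "alt", "alt_reads", "depth", "vaf"), path)
  bad <- which(!df$timepoint %in% c("BL", "C2"))
  if (length(bad)) read_err(path, bad[1] + 1L, "timepoint", paste0(
    "unknown timepoint '", df$timepoint[bad[1]], "'"))
  for (col in c("pos", "alt_reads", "depth")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v) | v < 0 | v != floor(v))
    if (length(bad)) read_err(path, bad[1] + 1L, col, "must be a non-negative integer")
    df[[col]] <- as.integer(v)
  }
  bad <- which(df$alt_reads > df$depth)
  if (length(bad)) read_err(path, bad[1] + 1L, "alt_reads", "exceeds depth")
  v <- suppressWarnings(as.numeric(df$vaf))
  bad <- which(!is.finite(v) | v < 0 | v > 1)
  if (length(bad)) read_err(path, bad[1] + 1L, "vaf", "must lie in [0, 1]")
  df$vaf <- v
  incons <- which(abs(df$vaf - df$alt_reads / df$depth) > 1e-9)
  if (length(incons))
    read_err(path, incons[1] + 1L, "vaf", "inconsistent with alt_reads/depth")
  df
}

#' Read a variant-timepoint manifest
#'
#' Two columns, `sample_id` and `timepoint` (BL|C2): the set of
#' sample-timepoint pairs that were assayed, including those with no
#' reportable variant calls.
#'
#' @param path TSV file path.
#' @return Validated data frame.
#' @export
read_variant_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(df, c("sample_id", "timepoint"), path)
  bad <- which(!df$timepoint %in% c("BL", "C2"))
  if (length(bad)) read_err(path, bad[1] + 1L, "timepoint", paste0(
    "unknown timepoint '", df$timepoint[bad[1]], "'"))
  if (anyDuplicated(df[c("sample_id", "timepoint")]))
    stop(path, ": duplicate sample-timepoint entry", call. = FALSE)
  df
}

#' Read a cohort fixture directory
#'
#' Inverse of [write_cohort()]: assembles the three data tables (plus the
#' manifest, when present) into a `cohort_data` list. Generative ground
#' truth is not recoverable from files, so `truth` is `NULL`.
#'
#' @param directory Directory containing `cnv_matrix.tsv`, `clinical.tsv`,
#'   `variants.tsv` and optionally `variant_manifest.tsv`.
#' @return A `cohort_data` list.
#' @export
read_cohort <- function(directory) {
  cnv <- read_cnv_matrix(file.path(directory, "cnv_matrix.tsv"))
  clinical <- read_clinical(file.path(directory, "clinical.tsv"))
  variants <- read_variants(file.path(directory, "variants.tsv"))
  mpath <- file.path(directory, "variant_manifest.tsv")
  manifest <- if (file.exists(mpath)) read_variant_manifest(mpath) else NULL
  ids <- rownames(cnv)
  if (!setequal(ids, clinical$sample_id))
    stop("sample sets of cnv_matrix.tsv and clinical.tsv differ", call. = FALSE)
  if (!all(variants$sample_id %in% ids))
    stop("variants.tsv contains sample_id absent from cnv_matrix.tsv",
         call. = FALSE)
  out <- list(cnv = cnv, clinical = clinical, variants = variants,
              variant_manifest = manifest, truth = NULL, config = NULL)
  class(out) <- "cohort_data"
  out
}

#' Read variant calls from a minimal single-sample VCF
#'
#' Accepts a VCF with per-sample `AD` (ref,alt allelic depths) or `AO`/`DP`
#' fields; `alt_reads` and `depth` are taken from `AD`, and VAF is computed
#' as alt_reads / depth. The sample id and timepoint default to the filename
#' convention `<sample>_<BL|C2>.vcf`.
#'
#' @param path VCF file path.
#' @param sample_id,timepoint Overrides for the filename convention.
#' @return Data frame in the [read_variants()] schema.
#' @export
read_vcf_calls <- function(path, sample_id = NULL, timepoint = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF input requires the 'vcfR' package", call. = FALSE)
  if (is.null(sample_id) || is.null(timepoint)) {
    stem <- sub("\\.vcf(\\.gz)?$", "", basename(path))
    m <- regmatches(stem, regexec("^(.+)_(BL|C2)$", stem))[[1]]
    if (length(m) != 3L)
      stop("cannot infer sample/timepoint from filename '", basename(path),
           "'; expected <sample>_<BL|C2>.vcf or explicit arguments",
           call. = FALSE)
    sample_id <- sample_id %||% m[2]
    timepoint <- timepoint %||% m[3]
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(vcfR::getFIX(v)),
                dimnames = list(NULL, colnames(vcfR::getFIX(v))))
  ad <- vcfR::extract.gt(v, element = "AD")[, 1]
  parts <- strsplit(ad, ",", fixed = TRUE)
  ref_reads <- as.integer(vapply(parts, `[`, character(1), 1L))
  alt_reads <- as.integer(vapply(parts, `[`, character(1), 2L))
  depth <- ref_reads + alt_reads
  ann <- vcfR::extract.info(v, element = "GENE")
  data.frame(
    sample_id = sample_id,
    timepoint = timepoint,
    gene = ifelse(is.na(ann), ".", ann),
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    alt_reads = alt_reads,
    depth = depth,
    vaf = alt_reads / depth,
    stringsAsFactors = FALSE
  )
}

#' Read a flat key:value simulation configuration file
#'
#' YAML document whose keys mirror the [sim_config()] arguments; unknown
#' keys are rejected.
#'
#' @param path YAML file path.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop(path, ": unknown configuration key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  do.call(sim_config, vals)
}
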