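# internal helpers shared across modules

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library functions never perturb user code.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop_field(field, "must be a probability in [0, 1]")
  invisible(x)
}

check_pos <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_field(field, "must be a single positive number")
  invisible(x)
}

# Coerce responder labels to a 0/1 integer vector; optionally require both
# classes. Accepts logical, numeric 0/1, or best-response strings.
as_binary_labels <- function(labels, require_both = TRUE) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    bad <- setdiff(unique(labels), c("CR", "PR", "SD", "PD"))
    if (length(bad))
      stop("unknown best_response value(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    labels <- as.integer(labels %in% c("CR", "PR"))
  }
  labels <- as.integer(labels)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
    stop("labels must be binary 0/1 (or CR/PR/SD/PD strings)", call. = FALSE)
  if (require_both && length(unique(labels)) < 2L)
    stop("both responder and non-responder classes must be present",
         call. = FALSE)
  labels
}

# Deterministic +1/-1 sign for a gene symbol (parity of summed code points);
# gives a reproducible mixed gain/loss pattern across the effect set.
gene_effect_sign <- function(gene) {
  vapply(gene, function(g) {
    if (sum(utf8ToInt(g)) %% 2L == 0L) 1 else -1
  }, numeric(1), USE.NAMES = FALSE)
}

# Full-precision numeric formatting so TSV round-trips are value-exact.
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (v == floor(v) && abs(v) < 1e15) return(sprintf("%.0f", v))
    sprintf("%.17g", v)
  }, character(1))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
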