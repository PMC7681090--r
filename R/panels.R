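#' Default effect gene set for the copy-number response classifier
#'
#' The 31 genes whose cfDNA copy-number pattern separates responders
#' (CR/PR) from non-responders (SD/PD) in the study the package models.
#' The synthetic cohort generator uses this set as ground truth: these
#' are the genes whose log2 copy ratios are shifted between response
#' groups, with a per-gene gain/loss direction fixed by hashing the
#' symbol (see [gene_effect_sign()] in the sources).
#'
#' @format Character vector of 31 gene symbols.
#' @export
cnv_effect_genes <- c(
  "CASP8", "PPHLN1", "PIGF", "KEAP1", "SDHC", "MOV10L1", "CCND3", "MTRR",
  "ID3", "STK11", "SEL1L3", "ARMC5", "MYCL", "SMARCA4", "BAT", "MYO10",
  "SMO", "TSHR", "IRF8", "SOX9", "CIC", "CCR4", "HSPA1B", "FLCN",
  "PRPF39", "RRP1B", "PRKCI", "ARPC2", "SOCS1", "ERCC2", "CEBPA"
)

#' Synthetic 29-gene ctDNA monitoring panel
#'
#' A stand-in panel of 29 prevalent tumor driver genes used by the
#' synthetic cohort generator for variant-allele-frequency monitoring.
#' The real monitoring panel's composition is not public, so this list
#' is a synthetic placeholder of the same size drawn from commonly
#' profiled lung cancer drivers; only its length and the per-gene
#' identity of calls matter to the analysis.
#'
#' @format Character vector of 29 gene symbols.
#' @export
vaf_panel_genes <- c(
  "TP53", "EGFR", "KRAS", "PIK3CA", "BRAF", "ALK", "MET", "ERBB2",
  "RET", "ROS1", "NRAS", "STK11", "KEAP1", "NF1", "RB1", "PTEN",
  "CDKN2A", "FGFR1", "FGFR3", "NOTCH1", "SMAD4", "CTNNB1", "MYC",
  "AKT1", "APC", "ATM", "BRCA2", "FBXW7", "IDH1"
)
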