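test_that("configuration invariants are enforced with the field named", {
  expect_error(sim_config(responder_rate = 1.5), "responder_rate")
  expect_error(sim_config(censoring_rate = -0.1), "censoring_rate")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(vaf_shrink_responder = 1.2), "vaf_shrink_responder")
  expect_error(sim_config(vaf_grow_nonresponder = 0.9), "vaf_grow_nonresponder")
  expect_error(sim_config(panel_genes = c("A", "B"),
                          effect_genes = c("A", "C")), "effect_genes")
  expect_error(sim_config(arm_fractions = c(LP = 0.7, GP = 0.7)),
               "arm_fractions")
})

test_that("the default cohort reproduces the 80/75 arm split", {
  coh <- simulate_cohort(sim_config(seed = 11))
  counts <- table(coh$clinical$arm)
  expect_equal(unname(counts[["LP"]]), 80)
  expect_equal(unname(counts[["GP"]]), 75)
  expect_equal(nrow(coh$cnv), 155)
})

test_that("the same seed yields byte-identical cohorts", {
  cfg <- quick_config(n_patients = 40, seed = 3)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c2 <- simulate_cohort(quick_config(n_patients = 40, seed = 4))
  expect_false(identical(a$cnv, c2$cnv))
})

test_that("simulated data satisfy their structural invariants", {
  coh <- simulate_cohort(quick_config(n_patients = 60, seed = 5))
  clin <- coh$clinical
  expect_true(all(clin$os_days >= clin$pfs_days))
  expect_true(all(clin$pfs_days > 0))
  expect_true(all(clin$pfs_event %in% 0:1))
  v <- coh$variants
  expect_true(all(v$alt_reads >= 1 & v$alt_reads <= v$depth))
  expect_true(all(abs(v$vaf - v$alt_reads / v$depth) < 1e-9))
  # manifest lists both timepoints for every patient regardless of calls
  expect_equal(nrow(coh$variant_manifest), 2 * 60)
  expect_setequal(unique(coh$variant_manifest$timepoint), c("BL", "C2"))
  # responder labels match best response coding
  expect_identical(unname(coh$truth$responder),
                   as.integer(clin$best_response %in% c("CR", "PR")))
})

test_that("with zero effect size per-gene t-tests reject at the nominal rate", {
  cfg <- sim_config(n_patients = 150, effect_size = 0,
                    panel_genes = sprintf("G%04d", 1:1000),
                    effect_genes = "G0001", mean_variants = 1, seed = 42)
  coh <- simulate_cohort(cfg)
  lab <- coh$truth$responder
  p <- apply(coh$cnv, 2, function(v)
    stats::t.test(v[lab == 1], v[lab == 0], var.equal = TRUE)$p.value)
  expect_gt(mean(p < 0.05), 0.03)
  expect_lt(mean(p < 0.05), 0.07)
})

test_that("effect genes are recoverable by t-tests at d >= 0.8, n >= 150", {
  hit <- sapply(1:20, function(s) {
    coh <- simulate_cohort(quick_config(n_patients = 150, effect_size = 0.8,
                                        seed = s))
    lab <- coh$truth$responder
    p <- apply(coh$cnv[, cnv_effect_genes], 2, function(v)
      stats::t.test(v[lab == 1], v[lab == 0], var.equal = TRUE)$p.value)
    mean(p < 0.05)
  })
  expect_gte(mean(hit), 0.90)
})

test_that("responders live longer and shifted genes gain or lose by hash sign", {
  longer <- sapply(1:100, function(s) {
    cfg <- sim_config(n_patients = 80, panel_genes = "G1", effect_genes = "G1",
                      mean_variants = 1, seed = s)
    clin <- simulate_cohort(cfg)$clinical
    resp <- clin$best_response %in% c("CR", "PR")
    median(clin$pfs_days[resp]) > median(clin$pfs_days[!resp])
  })
  expect_gte(mean(longer), 0.95)

  coh <- simulate_cohort(quick_config(n_patients = 300, effect_size = 1.5,
                                      seed = 8))
  lab <- coh$truth$responder
  shift <- colMeans(coh$cnv[lab == 1, cnv_effect_genes]) -
    colMeans(coh$cnv[lab == 0, cnv_effect_genes])
  hash_sign <- vapply(cnv_effect_genes, function(g)
    if (sum(utf8ToInt(g)) %% 2 == 0) 1 else -1, numeric(1))
  expect_true(all(sign(shift) == hash_sign))
})

test_that("cohorts round-trip losslessly through the fixture files", {
  coh <- simulate_cohort(quick_config(n_patients = 10, seed = 21))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_identical(back$cnv, coh$cnv)
  expect_equal(back$clinical, coh$clinical)
  expect_equal(back$variants, coh$variants)
  expect_equal(back$variant_manifest, coh$variant_manifest)
})

test_that("a patient with no reportable C2 calls keeps its manifest entry", {
  coh <- simulate_cohort(quick_config(n_patients = 10, seed = 21))
  pid <- coh$clinical$sample_id[1]
  coh$variants <- coh$variants[!(coh$variants$sample_id == pid &
                                   coh$variants$timepoint == "C2"), ]
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_true(any(back$variant_manifest$sample_id == pid &
                    back$variant_manifest$timepoint == "C2"))
  summaries <- summarize_vaf_cohort(back$variants, back$variant_manifest)
  row <- summaries[summaries$sample_id == pid & summaries$timepoint == "C2", ]
  expect_false(row$detectable)
  expect_equal(row$summary_vaf, 0)
})

test_that("the default cohort writes 155 CNV data rows", {
  coh <- simulate_cohort(sim_config(seed = 2))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  lines <- readLines(file.path(dir, "cnv_matrix.tsv"))
  expect_length(lines, 156)
})
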