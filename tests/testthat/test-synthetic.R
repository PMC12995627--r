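test_that("all generators are bit-reproducible under a fixed seed", {
  cfg <- synth_config(seed = 11, n_universal = 3, n_subtype_specific = 4,
                      n_null = 10)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth, b$truth)

  expect_identical(generate_ct_table(cfg), generate_ct_table(cfg))
  expect_identical(generate_longitudinal_panel(cfg),
                   generate_longitudinal_panel(cfg))
  expect_identical(generate_target_pairs(cfg, genes = c("A", "B")),
                   generate_target_pairs(cfg, genes = c("A", "B")))
})

test_that("truth table partitions the gene set and respects effect bounds", {
  cfg <- synth_config(seed = 2, n_universal = 5, n_subtype_specific = 6,
                      n_null = 20)
  truth <- generate_cohort(cfg)$truth
  expect_equal(nrow(truth), 31L)
  expect_equal(as.vector(table(truth$class)[c("universal", "subtype_specific", "null")]),
               c(5L, 6L, 20L))
  eff <- as.matrix(truth[truth$class == "universal", breast_subtypes()])
  expect_true(all(abs(eff) > 3))
  spec <- as.matrix(truth[truth$class == "subtype_specific", breast_subtypes()])
  expect_true(all(rowSums(spec != 0) == 1L))
  expect_true(all(truth[truth$class == "null", breast_subtypes()] == 0))
})

test_that("a null cohort yields no universal genes under the full screen", {
  cfg <- synth_config(seed = 5, n_universal = 0, n_subtype_specific = 0,
                      n_null = 300,
                      n_pairs_per_subtype = setNames(rep(10L, 5), breast_subtypes()))
  sim <- generate_cohort(cfg)
  res <- de_screen(sim$matrix)
  expect_length(res$venn$universal_set, 0L)
})

test_that("the screen recovers exactly the planted universal genes (seed 7)", {
  sim <- generate_cohort(recovery_config(7))
  res <- de_screen(sim$matrix)
  planted <- sim$truth$gene_symbol[sim$truth$class == "universal"]
  expect_setequal(res$venn$universal_set, planted)
})

test_that("too few pairs per subtype is an error", {
  cfg <- synth_config(seed = 1,
                      n_pairs_per_subtype = setNames(c(2L, 2L, 2L, 1L, 2L),
                                                     breast_subtypes()))
  expect_error(generate_cohort(cfg), "at least 2 pairs")
})

test_that("multi-probe mode shares the gene effect across probes", {
  cfg <- synth_config(seed = 4, n_universal = 2, n_subtype_specific = 0,
                      n_null = 3, probes_per_gene = 3L, noise_sd = 0.3,
                      n_pairs_per_subtype = setNames(rep(15L, 5), breast_subtypes()))
  sim <- generate_cohort(cfg)
  expect_equal(nrow(sim$matrix$values), 15L)
  fc <- estimate_log2fc(sim$matrix, "LumA")
  probes_of <- fc[paste0("UNIV001_p", 1:3)]
  expect_lt(max(probes_of) - min(probes_of), 1)  # shared effect, small offsets
})

test_that("noise-free Ct tables recover the planted fold changes exactly", {
  cfg <- synth_config(seed = 9, ct = list(log2fc = c(GENE1 = 2), noise_sd = 0))
  ct <- generate_ct_table(cfg)
  fc <- ddct_fold_change(ct, "GENE1", "tumor")
  expect_equal(unname(fc), rep(4, 20))
})

test_that("noisy Ct tables recover planted FC=4 within the expected window", {
  cfg <- synth_config(seed = 13, ct = list(log2fc = c(GENE1 = 2), noise_sd = 0.2,
                                           n_per_group = 20L))
  ct <- generate_ct_table(cfg)
  fc <- ddct_fold_change(ct, "GENE1", "tumor")
  expect_gt(mean(fc), 3.2)
  expect_lt(mean(fc), 5.0)
  # zero planted effect: FC about 1
  cfg0 <- synth_config(seed = 13, ct = list(log2fc = c(GENE1 = 0), noise_sd = 0.2))
  fc0 <- ddct_fold_change(generate_ct_table(cfg0), "GENE1", "tumor")
  expect_equal(mean(fc0), 1, tolerance = 0.2)
  # missing reference gene is rejected
  bad <- synth_config(seed = 1, ct = list(reference_gene = ""))
  expect_error(generate_ct_table(bad), "reference gene")
})

test_that("the kinetics pulse peaks at tau and is flat when A = 0", {
  hrs <- timepoint_hours()
  fc <- pulse_fc(hrs, amplitude = 1.1, tau = 10)
  expect_equal(unname(fc["T0"]), 1)
  expect_equal(names(which.max(fc[-1])), "T2")
  expect_equal(unname(fc["T2"]), 2.1)

  expect_equal(unname(pulse_fc(hrs, 0, 10)), rep(1, 7))
  expect_error(pulse_fc(hrs, -0.5, 10), "amplitude")
})

test_that("noisy replicate panels put the peak at T2 in nearly every run", {
  hits <- 0L
  for (seed in 1:100) {
    cfg <- synth_config(seed = seed,
                        kinetics = list(amplitudes = c(X = 1.1), tau = 10,
                                        noise_sd = 0.1, n_replicates = 34L))
    s <- generate_longitudinal_panel(cfg)$X
    if (detect_peak(s)$time == "T2") hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("target-pair scores follow the discrete-uniform tier masses", {
  cfg <- synth_config(seed = 21)
  pairs <- generate_target_pairs(cfg, genes = paste0("G", 1:200), n_per_gene = 5L)
  tiers <- table(tier_targets(pairs)$tier)
  n <- nrow(pairs)
  # closed-form masses on integers 50..99: 19/50 high, 21/50 mid, 10/50 cautious
  expect_equal(tiers[["high"]] / n, 19 / 50, tolerance = 0.1)
  expect_equal(tiers[["intermediate"]] / n, 21 / 50, tolerance = 0.1)
  expect_equal(tiers[["cautious"]] / n, 10 / 50, tolerance = 0.15)

  fix <- generate_target_pairs(cfg, fixture_mode = TRUE)
  expect_equal(fix$target_score[fix$gene_symbol == "CXCL8" &
                                  fix$mirna_id == "hsa-miR-140-3p"], 94L)
  expect_error(generate_target_pairs(cfg, genes = character(0)), "empty gene list")
})

test_that("log2FC estimates on generated cohorts are unbiased", {
  biases <- vapply(1:30, function(seed) {
    cfg <- synth_config(seed = seed, n_universal = 4, n_subtype_specific = 0,
                        n_null = 0,
                        n_pairs_per_subtype = setNames(rep(20L, 5), breast_subtypes()))
    sim <- generate_cohort(cfg)
    est <- estimate_log2fc(sim$matrix, "TNBC")
    mean(est[sim$truth$gene_symbol] - sim$truth$TNBC)
  }, 0)
  expect_lt(abs(mean(biases)), 0.05)
})
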