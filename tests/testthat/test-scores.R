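test_that("probe aggregation follows the chosen rule", {
  fc <- fixture_fc_table()
  casp1 <- fc$log2fc[fc$gene_symbol == "CASP1" & fc$subtype == "LumA"]
  expect_equal(casp1, c(3.91, 3.54, 3.81, 3.44, 3.87))

  expect_equal(aggregate_probes(fc, "first")["CASP1", "LumA"], 3.91)
  expect_equal(aggregate_probes(fc, "mean")["CASP1", "LumA"], mean(casp1))
  expect_equal(aggregate_probes(fc, "median")["CASP1", "LumA"], median(casp1))

  # single-probe gene: identical under every rule
  for (rule in c("first", "mean", "median")) {
    expect_equal(aggregate_probes(fc, rule)["MMP9", "TNBC"], 12.91)
  }
})

test_that("mean-difference PI reproduces the printed per-subtype values", {
  gene_fc <- aggregate_probes(fixture_fc_table(), "first")

  lb <- pyroptosis_index_published(gene_fc[, "LumB_HER2pos"], scope = "LumB_HER2pos")
  expect_equal(round(lb$value, 2), 3.33)
  tn <- pyroptosis_index_published(gene_fc[, "TNBC"], scope = "TNBC")
  expect_equal(round(tn$value, 2), 18.46)
  expect_equal(tn$value, tn$pro_mean - tn$anti_mean)

  # all nine genes equal: symmetric difference of means is 0
  flat <- setNames(rep(2.5, 9), gene_set_registry()$core9)
  expect_equal(pyroptosis_index_published(flat)$value, 0)

  # missing gene named in the error
  expect_error(pyroptosis_index_published(flat[-1]), "CXCL8")
})

test_that("PI is linear in its inputs and permutation-invariant within sets", {
  reg <- gene_set_registry()
  set.seed(12)
  x <- setNames(rnorm(9, 0, 4), reg$core9)
  base <- pyroptosis_index_published(x, reg)$value
  expect_equal(pyroptosis_index_published(3 * x, reg)$value, 3 * base)
  # constant added to every gene cancels in the mean difference
  expect_equal(pyroptosis_index_published(x + 7, reg)$value, base)
  # shuffling genes leaves the score unchanged
  expect_equal(pyroptosis_index_published(sample(x), reg)$value, base)
})

test_that("Z-score PI variant matches a step-by-step hand computation", {
  reg <- gene_set_registry()
  set.seed(5)
  vals <- matrix(rnorm(4 * 9, 2, 3), nrow = 4,
                 dimnames = list(paste0("s", 1:4), reg$core9))
  res <- pyroptosis_index_stated(vals, reg)

  # independent route: explicit loops
  s <- vals
  for (j in seq_len(ncol(s))) {
    for (i in seq_len(nrow(s))) {
      s[i, j] <- sign(vals[i, j]) * log2(1 + abs(vals[i, j]))
    }
  }
  z <- s
  for (j in seq_len(ncol(z))) z[, j] <- (s[, j] - mean(s[, j])) / sd(s[, j])
  manual <- sapply(seq_len(nrow(z)), function(i) {
    mean(z[i, reg$pro_pyroptotic]) - mean(z[i, reg$anti_pyroptotic])
  })
  expect_equal(res$pi, manual)

  # two samples mirrored about the per-gene mean: scores sum to zero
  two <- vals[1:2, ]
  expect_equal(sum(pyroptosis_index_stated(two, reg)$pi), 0)

  # identical samples: SD = 0 convention maps all Z (hence PI) to 0
  same <- vals[c(1, 1, 1), ]
  expect_equal(pyroptosis_index_stated(same, reg)$pi, rep(0, 3))

  expect_error(pyroptosis_index_stated(vals[1, , drop = FALSE], reg), ">= 2")
})

test_that("IAS is the arithmetic mean over the ten-gene panel", {
  reg <- gene_set_registry()
  zero <- setNames(rep(0, 10), reg$inflammasome_panel)
  expect_equal(inflammasome_activation_score(zero, reg)$value, 0)

  ten <- setNames(1:10, reg$inflammasome_panel)
  expect_equal(inflammasome_activation_score(ten, reg)$value, 5.5)
  expect_equal(inflammasome_activation_score(sample(ten), reg)$value, 5.5)

  # PYCARD accepted under its ASC alias
  aliased <- ten
  names(aliased)[names(aliased) == "PYCARD"] <- "ASC"
  expect_equal(inflammasome_activation_score(aliased, reg)$value, 5.5)

  expect_error(inflammasome_activation_score(ten[-3], reg), "NLRP3")
})

test_that("PI rises strictly from luminal A to TNBC on the packaged tables", {
  pi <- subtype_pyroptosis_index(fixture_fc_table())
  expect_equal(pi$subtype, breast_subtypes())
  expect_true(all(diff(pi$pi) > 0))
})
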