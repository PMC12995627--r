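test_that("log2 fold change equals the brute-force mean difference", {
  m <- toy_matrix(n_pairs = 3, shift = 0)
  expect_equal(unname(estimate_log2fc(m, "LumA")), rep(0, 3))

  m5 <- toy_matrix(n_pairs = 3, shift = 5)
  expect_equal(unname(estimate_log2fc(m5, "TNBC")), rep(5, 3))

  mr <- toy_matrix(n_pairs = 4, shift = 2, noise_sd = 1, seed = 42)
  meta <- mr$sample_meta
  ti <- meta$subtype == "LumB_HER2pos" & meta$group == "tumor"
  ci <- meta$subtype == "LumB_HER2pos" & meta$group == "control"
  manual <- rowMeans(mr$values[, ti]) - rowMeans(mr$values[, ci])
  expect_equal(estimate_log2fc(mr, "LumB_HER2pos"), manual)

  expect_error(estimate_log2fc(toy_matrix(n_pairs = 2), "NotASubtype"), ">= 2")
})

test_that("one-way F statistic matches hand computation and aov", {
  # Two subtypes, three pairs each. Tissue classes and values:
  #   control (pooled) {1,2,3,3,4,5}, LumA tumor {2,3,4}, TNBC tumor {3,4,5}
  # Hand computation: class means 3, 3, 4; grand mean 3.25;
  # SSB = 6(.0625) + 3(.0625) + 3(.5625) = 2.25, MSB = 1.125;
  # SSW = 10 + 2 + 2 = 14 on 9 df, MSW = 14/9; F = 1.125 / (14/9) = 0.7232143.
  meta <- data.frame(
    sample_id = paste0("s", 1:12), subject_id = paste0("s", 1:12),
    subtype = rep(c("LumA", "TNBC"), each = 6),
    group = rep(c("tumor", "control", "tumor", "control"), each = 3),
    pair_id = c(paste0("q", 1:3), paste0("q", 1:3),
                paste0("r", 1:3), paste0("r", 1:3)),
    stringsAsFactors = FALSE
  )
  v <- matrix(c(2, 3, 4, 1, 2, 3, 3, 4, 5, 3, 4, 5), nrow = 1,
              dimnames = list("pr1", meta$sample_id))
  em <- expression_matrix(v, meta)
  scr <- anova_screen(em)
  expect_equal(scr$F_stat, 1.125 / (14 / 9))
  expect_equal(scr$p_raw, stats::pf(1.125 / (14 / 9), 2, 9, lower.tail = FALSE))

  # independent route: aov on the same class structure
  cls <- ifelse(meta$group == "control", "control", meta$subtype)
  ref <- summary(stats::aov(as.vector(v) ~ factor(cls)))[[1]]
  expect_equal(scr$F_stat, ref[1, "F value"])
  expect_equal(scr$p_raw, ref[1, "Pr(>F)"])
})

test_that("identical class means give F near 0 and flagged zero-variance rows", {
  m <- toy_matrix(n_pairs = 3, shift = 0, noise_sd = 0.5, seed = 8)
  scr <- anova_screen(m)
  expect_true(all(scr$p_raw > 0.01))  # no planted effect

  m0 <- toy_matrix(n_pairs = 3, shift = 0, noise_sd = 0)
  scr0 <- anova_screen(m0)
  expect_true(all(scr0$flagged))
  expect_true(all(is.na(scr0$p_raw)))
})

test_that("BH adjustment reproduces the step-up formula by hand", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.001, 0.5)), c(0.002, 0.5))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH is monotone and dominating, with stable fixed points", {
  set.seed(99)
  for (i in 1:20) {
    p <- runif(50)^2
    adj <- adjust_bh(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= 0))  # p_raw order preserved
    # re-adjustment can only move values toward the cap, never below
    expect_true(all(adjust_bh(adj) >= adj))
  }
  # fixed points: constant vectors and the cap itself
  expect_equal(adjust_bh(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_bh(c(0, 0, 0)), c(0, 0, 0))
})

test_that("Tukey q reduces to sqrt(2)|t| with two groups and p is exact", {
  set.seed(3)
  a <- rnorm(8, 0, 1)
  b <- rnorm(10, 1, 1)
  res <- tukey_hsd(list(a = a, b = b))
  t_pooled <- stats::t.test(a, b, var.equal = TRUE)$statistic
  expect_equal(res$q, sqrt(2) * abs(unname(t_pooled)), tolerance = 1e-9)

  same <- tukey_hsd(list(x = c(1, 2, 3), y = c(1, 2, 3)))
  expect_equal(same$q, 0)
  expect_equal(same$p, 1)

  expect_error(tukey_hsd(list(x = c(1, 1), y = c(1, 1))), "MSW")
})

test_that("Tukey p-values agree with the aov/TukeyHSD reference", {
  set.seed(17)
  groups <- list(a = rnorm(6, 0), b = rnorm(7, 0.8), c = rnorm(5, 1.6))
  mine <- tukey_hsd(groups)
  df <- data.frame(y = unlist(groups),
                   g = rep(names(groups), lengths(groups)))
  ref <- stats::TukeyHSD(stats::aov(y ~ g, data = df))$g
  key <- paste(mine$group_j, mine$group_i, sep = "-")
  expect_equal(mine$p, unname(ref[key, "p adj"]), tolerance = 1e-3)
})

test_that("the DE filter uses strict thresholds and any-probe gene rule", {
  tab <- data.frame(
    probe_id = c("p1", "p2", "p3"),
    gene_symbol = c("G1", "G1", "G2"),
    subtype = "LumA",
    log2fc = c(3.0, 3.5, 10),     # 3.0 exactly must fail
    p_adj = c(0.01, 0.01, 0.05),  # 0.05 exactly must fail
    tukey_significant = TRUE,
    stringsAsFactors = FALSE
  )
  sets <- filter_de(tab, alpha = 0.05, fc_threshold = 3)
  expect_equal(sets$LumA, "G1")  # via p2; G2 fails on p_adj boundary

  # shrinkage: stricter thresholds never grow the sets
  wide <- filter_de(tab, alpha = 0.10, fc_threshold = 2)
  expect_true(all(sets$LumA %in% wide$LumA))
})

test_that("intersection is order-invariant with the expected degenerate cases", {
  s <- list(A = c("g1", "g2"), B = c("g2", "g3"), C = c("g2"),
            D = c("g2", "g4"), E = c("g2", "g1"))
  v <- intersect_subtypes(s)
  expect_equal(v$universal_set, "g2")
  expect_equal(sum(v$cell_counts), 4L)  # genes in union

  perm <- intersect_subtypes(s[c(3, 5, 1, 2, 4)])
  expect_equal(perm$universal_set, v$universal_set)

  disjoint <- intersect_subtypes(list(A = "a", B = "b", C = "c", D = "d", E = "e"))
  expect_length(disjoint$universal_set, 0L)

  same <- replicate(5, c("x", "y"), simplify = FALSE)
  names(same) <- letters[1:5]
  expect_setequal(intersect_subtypes(same)$universal_set, c("x", "y"))

  expect_error(intersect_subtypes(s[1:4]), "5")
})

test_that("universal set is contained in every per-subtype set on real screens", {
  sim <- generate_cohort(synth_config(seed = 31, n_universal = 4,
                                      n_subtype_specific = 10, n_null = 60,
                                      n_pairs_per_subtype = setNames(rep(12L, 5),
                                                                     breast_subtypes())))
  res <- de_screen(sim$matrix)
  for (s in names(res$sets)) {
    expect_true(all(res$venn$universal_set %in% res$sets[[s]]))
  }
  expect_true(all(res$fc_table$p_adj >= res$fc_table$p_raw, na.rm = TRUE))
})
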