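# Tissue-class labels for the joint ANOVA: one pooled control class plus the
# five tumor subtypes.
tissue_classes <- function(meta) {
  ifelse(meta$group == "control", "control", meta$subtype)
}

#' Per-probe log2 fold change for one subtype
#'
#' `log2FC = mean(log2 tumor) - mean(log2 control)` over that subtype's
#' samples (the matrix is assumed to hold log2 intensities).
#'
#' @param x An `expr_matrix`.
#' @param subtype One of [breast_subtypes()].
#' @return Named numeric vector, one value per probe.
#' @export
estimate_log2fc <- function(x, subtype) {
  m <- x$sample_meta
  ti <- m$subtype == subtype & m$group == "tumor"
  ci <- m$subtype == subtype & m$group == "control"
  if (sum(ti) < 2L || sum(ci) < 2L) {
    stop("need >= 2 tumor and >= 2 control samples for subtype ", subtype,
         call. = FALSE)
  }
  rowMeans(x$values[, ti, drop = FALSE]) - rowMeans(x$values[, ci, drop = FALSE])
}

#' One-way ANOVA across tissue classes, per probe
#'
#' Classical one-way F statistic over the six tissue classes (pooled control
#' plus five tumor subtypes), computed in closed form across all probes at
#' once; the upper-tail p comes from the F distribution with (k−1, N−k)
#' degrees of freedom. Probes with zero within-class variance are flagged
#' (`F`/`p` set to `NA`) and excluded downstream.
#'
#' @param x An `expr_matrix`.
#' @return data.frame with columns `probe_id`, `F_stat`, `p_raw`, `flagged`,
#'   plus attributes `msw`, `df_within`, `n_classes`, `class_sizes`,
#'   `class_means` reused by the Tukey contrasts.
#' @export
anova_screen <- function(x) {
  cls <- tissue_classes(x$sample_meta)
  classes <- sort(unique(cls))
  k <- length(classes)
  if (k < 2L) stop("need >= 2 tissue classes", call. = FALSE)
  n_g <- vapply(classes, function(g) sum(cls == g), 0L)
  if (any(n_g < 2L)) stop("each tissue class needs >= 2 samples", call. = FALSE)
  N <- sum(n_g)
  v <- x$values

  gm <- matrix(vapply(classes, function(g) rowMeans(v[, cls == g, drop = FALSE]),
                      numeric(nrow(v))),
               nrow = nrow(v), dimnames = list(rownames(v), classes))
  gss <- matrix(vapply(classes, function(g) rowSums(v[, cls == g, drop = FALSE]^2),
                       numeric(nrow(v))),
                nrow = nrow(v), dimnames = list(rownames(v), classes))
  grand <- as.vector(gm %*% n_g) / N
  ssb <- as.vector((gm - grand)^2 %*% n_g)
  ssw <- rowSums(gss) - as.vector(gm^2 %*% n_g)
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)

  flagged <- msw <= .Machine$double.eps * pmax(1, rowSums(gss))
  F_stat <- ifelse(flagged, NA_real_, msb / msw)
  p_raw <- stats::pf(F_stat, k - 1, N - k, lower.tail = FALSE)

  out <- data.frame(probe_id = rownames(v), F_stat = F_stat, p_raw = p_raw,
                    flagged = flagged, stringsAsFactors = FALSE)
  attr(out, "msw") <- msw
  attr(out, "df_within") <- N - k
  attr(out, "n_classes") <- k
  attr(out, "class_sizes") <- n_g
  attr(out, "class_means") <- gm
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up adjusted values returned in input order: after sorting ascending,
#' `p_adj(i) = min_{j >= i}(p(j) * m / j)`, capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (`NA` allowed, passed
#'   through).
#' @return Adjusted p-values, same order as input.
#' @export
adjust_bh <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric", call. = FALSE)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Tukey HSD pairwise comparisons
#'
#' For groups i, j the studentized-range statistic is
#' `q = |mean_i - mean_j| / sqrt(MSW/2 * (1/n_i + 1/n_j))` (Tukey-Kramer for
#' unequal sizes) with MSW the pooled within-group mean square; p-values come
#' from the studentized range distribution with k groups and N−k degrees of
#' freedom. In the two-group case `q = sqrt(2) * |t|` of the pooled-variance
#' two-sample test.
#'
#' @param groups List of >= 2 numeric vectors (>= 2 observations each).
#' @param alpha Significance level for the `significant` flag.
#' @return data.frame with one row per unordered pair: `group_i`, `group_j`,
#'   `diff`, `q`, `p`, `significant`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need a list of >= 2 groups", call. = FALSE)
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  n_g <- lengths(groups)
  if (any(n_g < 2L)) stop("each group needs >= 2 observations", call. = FALSE)
  k <- length(groups)
  N <- sum(n_g)
  means <- vapply(groups, mean, 0)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  msw <- ssw / (N - k)
  if (msw <= 0) stop("MSW is zero: no within-group variance", call. = FALSE)

  pairs <- utils::combn(k, 2L)
  d <- means[pairs[2L, ]] - means[pairs[1L, ]]
  se <- sqrt(msw / 2 * (1 / n_g[pairs[1L, ]] + 1 / n_g[pairs[2L, ]]))
  q <- abs(d) / se
  p <- stats::ptukey(q, nmeans = k, df = N - k, lower.tail = FALSE)
  data.frame(
    group_i = names(groups)[pairs[1L, ]],
    group_j = names(groups)[pairs[2L, ]],
    diff = unname(d), q = unname(q), p = unname(p),
    significant = unname(p < alpha),
    stringsAsFactors = FALSE
  )
}

# Vectorized subtype-vs-control Tukey contrasts for every probe, reusing the
# ANOVA decomposition. Returns matrices (probe x subtype) of q and p.
tukey_contrasts <- function(screen) {
  gm <- attr(screen, "class_means")
  n_g <- attr(screen, "class_sizes")
  msw <- attr(screen, "msw")
  k <- attr(screen, "n_classes")
  df <- attr(screen, "df_within")
  subtypes <- setdiff(colnames(gm), "control")
  q <- sapply(subtypes, function(s) {
    abs(gm[, s] - gm[, "control"]) /
      sqrt(msw / 2 * (1 / n_g[[s]] + 1 / n_g[["control"]]))
  })
  q <- matrix(q, nrow = nrow(gm), dimnames = list(rownames(gm), subtypes))
  p <- matrix(stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE),
              nrow = nrow(q), dimnames = dimnames(q))
  list(q = q, p = p)
}

#' Run the full differential-expression screen
#'
#' Pipeline: joint one-way ANOVA across the six tissue classes; BH adjustment
#' of the ANOVA p-values across probes (one family per subtype contrast);
#' Tukey post hoc subtype-vs-control contrasts; per-subtype log2 fold changes.
#' Flagged probes (zero within-class variance) are retained in the table but
#' never pass the filter.
#'
#' @param x An `expr_matrix`.
#' @param alpha Significance threshold applied to adjusted p (strict `<`).
#' @param fc_threshold Magnitude threshold on log2FC (strict `>`).
#' @param probe_gene Optional named character vector mapping probe id to gene
#'   symbol; defaults to probe id = gene symbol (single-probe designs).
#' @return List of class `de_screen`: `fc_table` (long data.frame keyed by
#'   probe and subtype with `log2fc`, `F_stat`, `p_raw`, `p_adj`,
#'   `tukey_significant`, `flagged`), `sets` (per-subtype significant gene
#'   sets), `venn` (a [intersect_subtypes()] partition), `alpha`,
#'   `fc_threshold`.
#' @export
#' @examples
#' sim <- generate_cohort(synth_config(seed = 7, n_null = 50,
#'                                     n_subtype_specific = 5))
#' res <- de_screen(sim$matrix)
#' res$venn$universal_set
de_screen <- function(x, alpha = 0.05, fc_threshold = 3, probe_gene = NULL) {
  screen <- anova_screen(x)
  contrasts <- tukey_contrasts(screen)
  subtypes <- breast_subtypes()
  if (is.null(probe_gene)) {
    probe_gene <- setNames(screen$probe_id, screen$probe_id)
  }
  fc_table <- do.call(rbind, lapply(subtypes, function(s) {
    data.frame(
      probe_id = screen$probe_id,
      gene_symbol = unname(probe_gene[screen$probe_id]),
      subtype = s,
      log2fc = unname(estimate_log2fc(x, s)[screen$probe_id]),
      F_stat = screen$F_stat,
      p_raw = screen$p_raw,
      p_adj = adjust_bh(screen$p_raw),
      tukey_significant = unname(contrasts$p[screen$probe_id, s] < alpha),
      flagged = screen$flagged,
      stringsAsFactors = FALSE
    )
  }))
  rownames(fc_table) <- NULL
  sets <- filter_de(fc_table, alpha = alpha, fc_threshold = fc_threshold)
  structure(list(fc_table = fc_table, sets = sets,
                 venn = intersect_subtypes(sets),
                 alpha = alpha, fc_threshold = fc_threshold),
            class = "de_screen")
}

#' Per-subtype significant gene sets
#'
#' A probe passes for a subtype iff `p_adj < alpha` AND `|log2fc| >
#' fc_threshold` AND its Tukey subtype-vs-control contrast is significant
#' (all inequalities strict, matching the printed operators); a gene passes
#' iff at least one of its probes passes. Direction of change is not
#' required to agree across subtypes.
#'
#' @param fc_table Long fold-change table with columns `probe_id`,
#'   `gene_symbol`, `subtype`, `log2fc`, `p_adj`, `tukey_significant` and
#'   optionally `flagged`.
#' @param alpha Adjusted-p threshold.
#' @param fc_threshold log2FC magnitude threshold.
#' @return Named list (one element per subtype present) of character vectors
#'   of gene symbols.
#' @export
filter_de <- function(fc_table, alpha = 0.05, fc_threshold = 3) {
  need <- c("probe_id", "gene_symbol", "subtype", "log2fc", "p_adj",
            "tukey_significant")
  if (!all(need %in% names(fc_table))) {
    stop("fc_table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  flagged <- if ("flagged" %in% names(fc_table)) fc_table$flagged else FALSE
  pass <- !is.na(fc_table$p_adj) & fc_table$p_adj < alpha &
    abs(fc_table$log2fc) > fc_threshold &
    fc_table$tukey_significant & !flagged
  subtypes <- unique(fc_table$subtype)
  sets <- lapply(subtypes, function(s) {
    sort(unique(fc_table$gene_symbol[pass & fc_table$subtype == s]))
  })
  names(sets) <- subtypes
  sets
}

#' Five-way intersection of per-subtype gene sets
#'
#' Builds the membership partition over the five subtype sets and the
#' universal intersection (genes significant in every subtype). Membership is
#' magnitude-based only: the direction of change need not agree across
#' subtypes.
#'
#' @param sets Named list of exactly 5 character vectors (per-subtype
#'   significant gene sets over a common gene universe).
#' @return List of class `venn_partition`: `membership` (data.frame, one row
#'   per gene in the union with a logical column per subtype),
#'   `universal_set` (sorted character vector), `cell_counts` (named integer
#'   vector over the 31 non-empty membership patterns).
#' @export
intersect_subtypes <- function(sets) {
  if (!is.list(sets) || length(sets) < 5L) {
    stop("need 5 per-subtype gene sets", call. = FALSE)
  }
  sets <- sets[seq_len(5L)]
  universe <- sort(unique(unlist(sets)))
  membership <- data.frame(gene_symbol = universe, stringsAsFactors = FALSE)
  for (nm in names(sets)) membership[[nm]] <- universe %in% sets[[nm]]
  memb_mat <- as.matrix(membership[, -1L, drop = FALSE])
  universal <- universe[rowSums(memb_mat) == 5L]
  pattern <- apply(memb_mat, 1L, function(r) paste(as.integer(r), collapse = ""))
  cell_counts <- if (length(pattern)) table(pattern) else table(character(0))
  structure(list(membership = membership,
                 universal_set = universal,
                 cell_counts = c(cell_counts)),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("Venn partition over", ncol(x$membership) - 1L, "subtype sets;",
      nrow(x$membership), "genes in union\n")
  cat("Universal set (", length(x$universal_set), "): ",
      paste(x$universal_set, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.de_screen <- function(x, ...) {
  cat("Differential-expression screen (alpha =", x$alpha,
      ", |log2FC| >", x$fc_threshold, ")\n")
  for (s in names(x$sets)) cat(" ", s, ":", length(x$sets[[s]]), "genes\n")
  cat("Universal:", length(x$venn$universal_set), "genes\n")
  invisible(x)
}
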