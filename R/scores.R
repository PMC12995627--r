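#' Collapse probe-level fold changes to gene level
#'
#' Microarray designs carry several probe sets per gene; the scores operate
#' on one value per gene. Rules: `"first"` takes the probe with
#' `list_rank == 1` (the first listed probe of the gene's block — the
#' default, and the rule under which the packaged fold-change fixture
#' reproduces the printed Pyroptosis Index exactly), `"mean"` and `"median"`
#' aggregate across a gene's probes.
#'
#' @param fc_table Long fold-change table with columns `gene_symbol`,
#'   `subtype`, `log2fc`, and (for `rule = "first"`) `list_rank`.
#' @param rule Aggregation rule.
#' @return Numeric matrix, genes in rows, subtypes in columns.
#' @export
#' @examples
#' fc <- fixture_fc_table()
#' gene_fc <- aggregate_probes(fc, "first")
#' gene_fc["CASP1", ]
aggregate_probes <- function(fc_table, rule = c("first", "mean", "median")) {
  rule <- match.arg(rule)
  need <- c("gene_symbol", "subtype", "log2fc")
  if (!all(need %in% names(fc_table))) {
    stop("fc_table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (rule == "first") {
    if (!"list_rank" %in% names(fc_table)) {
      stop("rule = 'first' requires a list_rank column", call. = FALSE)
    }
    fc_table <- fc_table[fc_table$list_rank == 1L, , drop = FALSE]
  }
  genes <- unique(fc_table$gene_symbol)
  subtypes <- unique(fc_table$subtype)
  agg <- switch(rule, first = function(v) v[1L], mean = mean, median = median)
  out <- matrix(NA_real_, length(genes), length(subtypes),
                dimnames = list(genes, subtypes))
  for (g in genes) {
    for (s in subtypes) {
      v <- fc_table$log2fc[fc_table$gene_symbol == g & fc_table$subtype == s]
      if (length(v) == 0L) stop("gene with no probes: ", g, " (", s, ")",
                                call. = FALSE)
      out[g, s] <- agg(v)
    }
  }
  out
}

check_genes_present <- function(gene_fc, wanted, registry) {
  names(gene_fc) <- resolve_symbols(names(gene_fc), registry)
  missing <- setdiff(wanted, names(gene_fc))
  if (length(missing)) {
    stop("missing gene(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  gene_fc
}

new_signature_score <- function(scope, score_type, value, aggregation_rule,
                                pro_mean = NA_real_, anti_mean = NA_real_) {
  structure(list(scope = scope, score_type = score_type, value = value,
                 pro_mean = pro_mean, anti_mean = anti_mean,
                 aggregation_rule = aggregation_rule),
            class = "signature_score")
}

#' @export
print.signature_score <- function(x, ...) {
  cat(sprintf("%s [%s] = %.4f\n", x$score_type, x$scope, x$value))
  if (!is.na(x$pro_mean)) {
    cat(sprintf("  pro mean %.4f  anti mean %.4f\n", x$pro_mean, x$anti_mean))
  }
  invisible(x)
}

#' Pyroptosis Index (mean-difference variant)
#'
#' `PI = mean(log2FC over the six pro-pyroptotic genes) - mean(log2FC over
#' the three anti-pyroptotic genes)`, applied to gene-level log2 fold changes
#' of one subtype-vs-control comparison. This direct arithmetic on gene-level
#' fold changes is the variant that reproduces the study's printed per-subtype
#' index values; see [pyroptosis_index_stated()] for the per-sample Z-score
#' formulation.
#'
#' @param gene_fc Named numeric vector of gene-level log2 fold changes
#'   containing all nine core genes.
#' @param registry A [gene_set_registry()].
#' @param scope Label for the comparison (e.g. the subtype).
#' @return A `signature_score` with `value`, `pro_mean`, `anti_mean`.
#' @export
#' @examples
#' gene_fc <- aggregate_probes(fixture_fc_table(), "first")
#' pyroptosis_index_published(gene_fc[, "TNBC"], scope = "TNBC")
pyroptosis_index_published <- function(gene_fc, registry = gene_set_registry(),
                                       scope = "subtype") {
  gene_fc <- check_genes_present(gene_fc, registry$core9, registry)
  pro_mean <- mean(gene_fc[registry$pro_pyroptotic])
  anti_mean <- mean(gene_fc[registry$anti_pyroptotic])
  new_signature_score(scope, "PI_published", pro_mean - anti_mean,
                      aggregation_rule = "mean-difference",
                      pro_mean = pro_mean, anti_mean = anti_mean)
}

#' Pyroptosis Index (per-sample Z-score variant)
#'
#' The per-sample formulation: each gene's fold-change values are transformed
#' with the signed extension `s(x) = sign(x) * log2(1 + |x|)` (the plain
#' `log2(1 + FC)` is undefined for FC <= -1), standardized to Z-scores across
#' samples (a zero-variance gene maps to Z = 0), and each sample's PI is
#' `mean Z(pro) - mean Z(anti)`. Being Z-based, the score is bounded by the
#' cohort size and centred near 0 across samples.
#'
#' @param values Numeric matrix of fold changes, samples in rows, genes in
#'   columns (all nine core genes required); >= 2 samples.
#' @param registry A [gene_set_registry()].
#' @return data.frame with columns `sample_id`, `pi`, `pro_mean`, `anti_mean`.
#' @export
pyroptosis_index_stated <- function(values, registry = gene_set_registry()) {
  if (!is.matrix(values) || nrow(values) < 2L) {
    stop("need a matrix with >= 2 samples (Z-scores require variance)",
         call. = FALSE)
  }
  colnames(values) <- resolve_symbols(colnames(values), registry)
  missing <- setdiff(registry$core9, colnames(values))
  if (length(missing)) {
    stop("missing gene(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  s <- sign(values) * log2(1 + abs(values))
  z <- apply(s, 2L, function(col) {
    sdev <- sd(col)
    if (sdev == 0) rep(0, length(col)) else (col - mean(col)) / sdev
  })
  pro <- rowMeans(z[, registry$pro_pyroptotic, drop = FALSE])
  anti <- rowMeans(z[, registry$anti_pyroptotic, drop = FALSE])
  data.frame(
    sample_id = if (is.null(rownames(values))) {
      paste0("sample", seq_len(nrow(values)))
    } else rownames(values),
    pi = pro - anti, pro_mean = pro, anti_mean = anti,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Inflammasome Activation Score
#'
#' Arithmetic mean of the log2 fold changes of the ten inflammasome-panel
#' genes (sensors, adaptors, cytokines, signalling regulators and effector
#' caspases). Higher values indicate stronger inflammasome signalling.
#'
#' @param gene_fc Named numeric vector of gene-level log2 fold changes
#'   containing all ten panel genes (the ASC alias for PYCARD is accepted).
#' @param registry A [gene_set_registry()].
#' @param scope Label for the comparison.
#' @return A `signature_score`.
#' @export
inflammasome_activation_score <- function(gene_fc,
                                          registry = gene_set_registry(),
                                          scope = "subtype") {
  gene_fc <- check_genes_present(gene_fc, registry$inflammasome_panel, registry)
  new_signature_score(scope, "IAS",
                      mean(gene_fc[registry$inflammasome_panel]),
                      aggregation_rule = "mean")
}

#' Pyroptosis Index per subtype from a probe-level fold-change table
#'
#' Convenience wrapper: aggregates probes to gene level and computes the
#' mean-difference Pyroptosis Index for every subtype column.
#'
#' @param fc_table Long fold-change table (see [aggregate_probes()]).
#' @param rule Probe aggregation rule.
#' @param registry A [gene_set_registry()].
#' @return data.frame with columns `subtype`, `pi`, `pro_mean`, `anti_mean`,
#'   in the column order of the aggregated matrix.
#' @export
#' @examples
#' subtype_pyroptosis_index(fixture_fc_table())
subtype_pyroptosis_index <- function(fc_table, rule = "first",
                                     registry = gene_set_registry()) {
  gene_fc <- aggregate_probes(fc_table, rule)
  rows <- lapply(colnames(gene_fc), function(s) {
    sc <- pyroptosis_index_published(gene_fc[, s], registry, scope = s)
    data.frame(subtype = s, pi = sc$value, pro_mean = sc$pro_mean,
               anti_mean = sc$anti_mean, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
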