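#' Tier predicted miRNA-mRNA pairs by target score
#'
#' Sequence-based target prediction scores (0-100) are binned into confidence
#' tiers: score > 80 is `high` (highly reliable), score < 60 is `cautious`
#' (interpret only with additional evidence), anything in \[60, 80\] is
#' `intermediate`. Tiering depends on the score alone and is idempotent.
#'
#' @param pairs data.frame with columns `mirna_id`, `gene_symbol`,
#'   `target_score`.
#' @return `pairs` with an added factor column `tier` (levels high,
#'   intermediate, cautious).
#' @export
#' @examples
#' p <- data.frame(mirna_id = "hsa-miR-140-3p", gene_symbol = "CXCL8",
#'                 target_score = 94)
#' tier_targets(p)$tier
tier_targets <- function(pairs) {
  need <- c("mirna_id", "gene_symbol", "target_score")
  if (!all(need %in% names(pairs))) {
    stop("pairs must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  s <- pairs$target_score
  if (any(is.na(s)) || any(s < 0 | s > 100)) {
    stop("target scores must lie in [0, 100]", call. = FALSE)
  }
  tier <- ifelse(s > 80, "high", ifelse(s < 60, "cautious", "intermediate"))
  pairs$tier <- factor(tier, levels = c("high", "intermediate", "cautious"))
  pairs
}

#' Annotate signature genes with high-tier regulators and expression patterns
#'
#' Joins predicted miRNA-mRNA pairs onto gene-level fold changes: one output
#' row per (gene, high-tier regulator), with a per-subtype `up`/`down`
#' pattern label from the sign of the gene's log2 fold change. No inverse-
#' correlation requirement is imposed — predicted interactions are evaluated
#' independently of expression directionality.
#'
#' @param pairs data.frame of predicted pairs (see [tier_targets()]; tiered
#'   automatically if the `tier` column is absent).
#' @param gene_fc Numeric matrix of gene-level log2 fold changes (genes in
#'   rows, subtypes in columns), e.g. from [aggregate_probes()].
#' @return data.frame with columns `gene_symbol`, `mirna_id`, `target_score`
#'   and one `pattern_<subtype>` column per subtype. Empty when no high-tier
#'   pair matches a gene in `gene_fc` (with a warning).
#' @export
join_signature_targets <- function(pairs, gene_fc) {
  if (!is.matrix(gene_fc) || is.null(rownames(gene_fc))) {
    stop("gene_fc must be a matrix with gene rownames", call. = FALSE)
  }
  if (!"tier" %in% names(pairs)) pairs <- tier_targets(pairs)
  hits <- pairs[pairs$tier == "high" &
                  pairs$gene_symbol %in% rownames(gene_fc), , drop = FALSE]
  if (nrow(hits) == 0L) {
    warning("no high-tier pairs match the supplied genes; empty annotation")
    out <- data.frame(gene_symbol = character(0), mirna_id = character(0),
                      target_score = numeric(0), stringsAsFactors = FALSE)
    for (s in colnames(gene_fc)) out[[paste0("pattern_", s)]] <- character(0)
    return(out)
  }
  out <- data.frame(gene_symbol = hits$gene_symbol, mirna_id = hits$mirna_id,
                    target_score = hits$target_score, stringsAsFactors = FALSE)
  for (s in colnames(gene_fc)) {
    out[[paste0("pattern_", s)]] <-
      ifelse(gene_fc[out$gene_symbol, s] >= 0, "up", "down")
  }
  rownames(out) <- NULL
  out
}
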