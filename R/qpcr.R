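#' Relative quantification by the 2^-ddCt method
#'
#' For each sample s in `group`: `dCt_s = Ct_gene,s - Ct_ref,s`;
#' `ddCt_s = dCt_s - mean(dCt over the calibrator group)`;
#' `FC_s = 2^(-ddCt_s)`. A fold change of 1 means the calibrator level;
#' values above 1 indicate upregulation. Shifting a sample's gene and
#' reference Ct together leaves its fold change unchanged.
#'
#' @param ct_table data.frame with columns `sample_id`, `group`,
#'   `gene_symbol`, `ct` (threshold cycles, > 0). Every sample needs a
#'   reference-gene row.
#' @param gene Target gene symbol.
#' @param group Group whose samples are quantified (e.g. `"tumor"`).
#' @param reference Endogenous control gene (default ACTB).
#' @param calibrator Calibrator group label (default `"control"`).
#' @return Named numeric vector of per-sample fold changes.
#' @export
#' @examples
#' ct <- data.frame(
#'   sample_id = rep(c("t1", "c1", "c2"), each = 2),
#'   group = rep(c("tumor", "control", "control"), each = 2),
#'   gene_symbol = rep(c("CXCL8", "ACTB"), 3),
#'   ct = c(20, 15, 22, 15, 22, 15)
#' )
#' ddct_fold_change(ct, "CXCL8", "tumor")  # ddCt = -2, FC = 4
ddct_fold_change <- function(ct_table, gene, group, reference = "ACTB",
                             calibrator = "control") {
  need <- c("sample_id", "group", "gene_symbol", "ct")
  if (!all(need %in% names(ct_table))) {
    stop("ct_table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(ct_table$ct <= 0)) stop("Ct values must be > 0", call. = FALSE)
  delta_ct <- function(grp) {
    ids <- unique(ct_table$sample_id[ct_table$group == grp])
    if (length(ids) == 0L) stop("no samples in group '", grp, "'", call. = FALSE)
    vapply(ids, function(id) {
      rows <- ct_table[ct_table$sample_id == id, , drop = FALSE]
      g <- rows$ct[rows$gene_symbol == gene]
      r <- rows$ct[rows$gene_symbol == reference]
      if (length(r) != 1L) stop("missing reference Ct (", reference,
                                ") for sample ", id, call. = FALSE)
      if (length(g) != 1L) stop("missing Ct for ", gene, " in sample ", id,
                                call. = FALSE)
      g - r
    }, 0)
  }
  cal <- delta_ct(calibrator)
  ddct <- delta_ct(group) - mean(cal)
  2^(-ddct)
}

#' Summarize per-sample fold changes against a baseline
#'
#' Mean and SD of the fold changes plus a two-sided one-sample t-test of
#' `log2(FC)` against `log2(baseline)` (the log scale makes x-fold up- and
#' down-regulation symmetric). When all log fold changes are identical the
#' test degenerates: p = 1 if they equal the baseline, 0 otherwise.
#'
#' @param fc Numeric vector of fold changes (> 0), length >= 2.
#' @param baseline Null fold change (default 1, the calibrator level).
#' @param alpha Threshold for the significance flag.
#' @return List: `mean`, `sd`, `p`, `significant`, `n`.
#' @export
summarize_fc <- function(fc, baseline = 1, alpha = 0.05) {
  if (length(fc) < 2L) stop("need >= 2 samples", call. = FALSE)
  if (any(fc <= 0)) stop("fold changes must be > 0", call. = FALSE)
  lx <- log2(fc)
  mu <- log2(baseline)
  if (sd(lx) == 0) {
    p <- if (isTRUE(all.equal(mean(lx), mu))) 1 else 0
  } else {
    p <- stats::t.test(lx, mu = mu)$p.value
  }
  list(mean = mean(fc), sd = sd(fc), p = p, significant = p < alpha,
       n = length(fc))
}
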