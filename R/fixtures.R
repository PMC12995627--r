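#' Load a packaged reference table
#'
#' The package ships the study's printed tables as plain-text TSV fixtures:
#'
#' * `table1` — qPCR primer sequences for the nine signature genes plus the
#'   ACTB endogenous control (metadata only; the CXCL8 reverse primer is
#'   stored as sequence letters, without the typographic prefix it carries
#'   in print).
#' * `table2` — probe-level log2 fold changes (tumor vs control) for the
#'   nine signature genes across the five subtypes; probe order defines
#'   `list_rank` within each gene block.
#' * `table3` — predicted miRNA-mRNA pairs with target scores and
#'   per-subtype expression (mean, SD, significance star) stored verbatim.
#' * `table4` — ELISA protein concentrations, control and five subtypes.
#' * `table5` — longitudinal mRNA fold changes (T1..T6 vs T0) after
#'   cryoablation of benign fibroadenoma.
#' * `table6` — longitudinal protein concentrations (T0..T6).
#' * `table7` — Pyroptosis Index per subtype.
#' * `table8` — Inflammasome Activation Score per subtype.
#'
#' Values are stored exactly as printed; any typographic minus (U+2212) is
#' normalized to ASCII `-` on load. Significance stars are kept verbatim in
#' `*_sig` character columns (`""`, `"*"`, `"**"`).
#'
#' @param name Fixture name, one of `"table1"` .. `"table8"`.
#' @return A data.frame of class `paper_fixture` with attribute
#'   `fixture_name`. Repeated calls return identical content.
#' @export
#' @examples
#' pi_tab <- load_paper_fixture("table7")
#' pi_tab$pyroptosis_index[pi_tab$subtype == "TNBC"]
load_paper_fixture <- function(name) {
  known <- paste0("table", 1:8)
  if (!is.character(name) || length(name) != 1L || !name %in% known) {
    stop("no such fixture: ", deparse(substitute(name)), call. = FALSE)
  }
  path <- system.file("extdata", paste0(name, ".tsv"),
                      package = "pyrosig", mustWork = TRUE)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL,
                           quote = "", comment.char = "")
  raw[] <- lapply(raw, function(col) gsub("−", "-", col, fixed = TRUE))
  num_re <- "^-?[0-9]+(\\.[0-9]+)?$"
  raw[] <- lapply(raw, function(col) {
    if (all(grepl(num_re, col))) as.numeric(col) else col
  })
  attr(raw, "fixture_name") <- name
  class(raw) <- c("paper_fixture", "data.frame")
  raw
}

#' Probe-level fold-change table from the packaged microarray fixture
#'
#' Reshapes the `table2` fixture (wide: one column per subtype) into the long
#' fold-change layout used by [aggregate_probes()] and [filter_de()]: one row
#' per (probe, subtype) with the probe's gene symbol and its `list_rank`
#' (order of appearance within the gene's probe block).
#'
#' @param fixture A `paper_fixture` as returned by
#'   `load_paper_fixture("table2")`. Loaded automatically when omitted.
#' @return data.frame with columns `probe_id`, `gene_symbol`, `list_rank`,
#'   `subtype`, `log2fc`.
#' @export
#' @examples
#' fc <- fixture_fc_table()
#' head(fc)
fixture_fc_table <- function(fixture = load_paper_fixture("table2")) {
  subtypes <- breast_subtypes()
  stopifnot(all(subtypes %in% names(fixture)))
  out <- do.call(rbind, lapply(subtypes, function(s) {
    data.frame(
      probe_id = fixture$probe_id,
      gene_symbol = fixture$gene_symbol,
      list_rank = as.integer(fixture$list_rank),
      subtype = s,
      log2fc = fixture[[s]],
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Longitudinal series from the packaged kinetics fixtures
#'
#' Builds a [longitudinal_series()] for one analyte from the `table5`
#' (mRNA fold change vs T0; baseline fixed at 1) or `table6` (protein
#' concentration; T0 measured) fixture. Significance stars are carried over
#' as logical flags (any star counts as significant, as printed).
#'
#' @param analyte Gene symbol (table5) or protein name (table6).
#' @param table Which fixture to read, `"table5"` or `"table6"`.
#' @return A `longitudinal_series` object.
#' @export
#' @examples
#' s <- fixture_series("CXCL8", "table5")
#' detect_peak(s)
fixture_series <- function(analyte, table = c("table5", "table6")) {
  table <- match.arg(table)
  fix <- load_paper_fixture(table)
  key <- if (table == "table5") "gene_symbol" else "protein"
  row <- fix[fix[[key]] == analyte, , drop = FALSE]
  if (nrow(row) != 1L) stop("analyte not in ", table, ": ", analyte, call. = FALSE)
  tp <- paste0("T", 0:6)
  if (table == "table5") {
    means <- c(1, as.numeric(row[paste0("T", 1:6, "_mean")]))
    sds <- c(0, as.numeric(row[paste0("T", 1:6, "_sd")]))
    sig <- c(FALSE, nzchar(trimws(as.character(row[paste0("T", 1:6, "_sig")]))))
    level <- "fc"
  } else {
    means <- as.numeric(row[paste0("T", 0:6, "_mean")])
    sds <- as.numeric(row[paste0("T", 0:6, "_sd")])
    sig <- c(FALSE, nzchar(trimws(as.character(row[paste0("T", 1:6, "_sig")]))))
    level <- "concentration"
  }
  longitudinal_series(
    analyte = analyte, time = tp, hours = timepoint_hours(),
    mean = means, sd = sds, significant = sig, level = level
  )
}

#' Hour coordinates of the post-cryoablation sampling grid
#'
#' T0 is the pre-procedure draw; T1..T6 use the midpoint of each printed
#' sampling window (30-60 min, 8-12 h, 48-72 h, 7 days, 1 month, 3 months).
#'
#' @return Named numeric vector of hours for T0..T6.
#' @export
timepoint_hours <- function() {
  c(T0 = 0, T1 = 0.75, T2 = 10, T3 = 60, T4 = 168, T5 = 720, T6 = 2160)
}
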