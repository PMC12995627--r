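#' Construct a validated expression matrix
#'
#' Container for probe-by-sample log2 intensities with per-sample metadata.
#' The analysis assumes values are already on the log2 scale.
#'
#' @param values Numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids). No missing values.
#' @param sample_meta data.frame with one row per sample (in column order of
#'   `values`) and columns `sample_id`, `subject_id`, `subtype`, `group`
#'   (`"tumor"` or `"control"`), `pair_id`. Each `pair_id` must occur in
#'   exactly one tumor and one control sample.
#' @return Object of class `expr_matrix`: list with elements `values` and
#'   `sample_meta`.
#' @export
expression_matrix <- function(values, sample_meta) {
  x <- structure(list(values = values, sample_meta = sample_meta),
                 class = "expr_matrix")
  validate_expression_matrix(x)
}

validate_expression_matrix <- function(x) {
  v <- x$values
  m <- x$sample_meta
  if (!is.matrix(v) || !is.numeric(v)) stop("values must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(v))) stop("values must have probe-id rownames", call. = FALSE)
  if (anyDuplicated(rownames(v))) stop("duplicate probe id", call. = FALSE)
  if (anyNA(v)) stop("missing values in expression matrix", call. = FALSE)
  need <- c("sample_id", "subject_id", "subtype", "group", "pair_id")
  if (!all(need %in% names(m))) {
    stop("sample metadata must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(m) != ncol(v)) stop("metadata rows must match sample columns", call. = FALSE)
  if (!identical(as.character(m$sample_id), colnames(v))) {
    stop("metadata sample order must match matrix columns", call. = FALSE)
  }
  if (anyNA(m$subtype) || any(!nzchar(m$subtype)) ||
      anyNA(m$group) || any(!nzchar(m$group))) {
    stop("sample without subtype/group", call. = FALSE)
  }
  if (!all(m$group %in% c("tumor", "control"))) {
    stop("group must be 'tumor' or 'control'", call. = FALSE)
  }
  tab <- table(m$pair_id, m$group)
  if (!all(tab == 1L)) {
    stop("each pair_id must occur in exactly one tumor and one control sample",
         call. = FALSE)
  }
  x
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("Expression matrix:", nrow(x$values), "probes x", ncol(x$values), "samples\n")
  cat("Subtypes:", paste(names(table(x$sample_meta$subtype)), collapse = ", "), "\n")
  invisible(x)
}

#' Read an expression matrix with embedded or side-car sample metadata
#'
#' The single-file layout carries sample metadata as `#meta` header lines
#' before the data header, one line per field:
#' \preformatted{#meta subject_id s1 s1 s2 s2
#' #meta subtype LumA LumA TNBC TNBC
#' #meta group tumor control tumor control
#' #meta pair_id p1 p1 p2 p2
#' probe_id A1 A2 B1 B2
#' 202859_x_at 8.1 5.0 9.2 5.1}
#' Alternatively pass `meta_path`, a TSV/CSV with columns `sample_id`,
#' `subject_id`, `subtype`, `group`, `pair_id`.
#'
#' @param path Path to the matrix file.
#' @param dialect Field separator convention, `"tsv"` (default) or `"csv"`.
#' @param meta_path Optional side-car metadata file (same dialect).
#' @return An `expr_matrix`. Probe and sample order is preserved.
#' @export
read_expression_matrix <- function(path, dialect = c("tsv", "csv"), meta_path = NULL) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  lines <- readLines(path)
  meta_lines <- grep("^#meta", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  if (length(body) < 2L) stop("no data rows in ", path, call. = FALSE)

  tab <- utils::read.delim(text = paste(body, collapse = "\n"), sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "")
  probe_ids <- tab[[1L]]
  if (anyDuplicated(probe_ids)) stop("duplicate probe: ",
                                     probe_ids[duplicated(probe_ids)][1L], call. = FALSE)
  cells <- as.matrix(tab[, -1L, drop = FALSE])
  cells[] <- gsub("−", "-", cells, fixed = TRUE)
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells),
                                 dimnames = list(probe_ids, colnames(cells))))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("non-numeric or missing cell at probe ", probe_ids[bad[1L]],
         ", sample ", colnames(num)[bad[2L]], call. = FALSE)
  }

  if (!is.null(meta_path)) {
    meta <- utils::read.delim(meta_path, sep = sep, check.names = FALSE,
                              colClasses = "character")
    meta <- meta[match(colnames(num), meta$sample_id), , drop = FALSE]
    if (anyNA(meta$sample_id)) stop("metadata missing for some samples", call. = FALSE)
  } else {
    if (length(meta_lines) == 0L) stop("no #meta header block and no meta_path", call. = FALSE)
    fields <- lapply(meta_lines, function(l) strsplit(sub("^#meta[ \t]+", "", l),
                                                      sep, fixed = TRUE)[[1L]])
    keys <- vapply(fields, `[`, "", 1L)
    vals <- lapply(fields, function(f) f[-1L])
    if (any(lengths(vals) != ncol(num))) {
      stop("#meta lines must carry one value per sample", call. = FALSE)
    }
    meta <- data.frame(sample_id = colnames(num), stringsAsFactors = FALSE)
    for (i in seq_along(keys)) meta[[keys[i]]] <- vals[[i]]
  }
  rownames(meta) <- NULL
  expression_matrix(num, meta)
}

#' Write an expression matrix in the single-file `#meta` layout
#'
#' Values are written at full double precision so that a write-read
#' round trip reproduces the matrix exactly.
#'
#' @param x An `expr_matrix`.
#' @param path Output file path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  m <- x$sample_meta
  con <- file(path, "w")
  on.exit(close(con))
  for (field in c("subject_id", "subtype", "group", "pair_id")) {
    writeLines(paste(c("#meta", field, as.character(m[[field]])), collapse = sep), con)
  }
  writeLines(paste(c("probe_id", colnames(x$values)), collapse = sep), con)
  body <- apply(x$values, 1L, function(r) paste(sprintf("%.17g", r), collapse = sep))
  writeLines(paste(rownames(x$values), body, sep = sep), con)
  invisible(path)
}

#' Read an undirected interaction graph from a two-column edge list
#'
#' Whitespace-separated node pairs, one edge per line; blank lines and lines
#' starting with `#` are skipped. Duplicate pairs and reversed duplicates are
#' collapsed; a self-loop is an error (reported with its line number).
#'
#' @param path Path to the edge-list file.
#' @return An undirected simple [igraph::graph] object.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  if (length(keep) == 0L) stop("empty edge list: ", path, call. = FALSE)
  pairs <- lapply(keep, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(f) < 2L) stop("malformed edge at line ", i, call. = FALSE)
    if (f[1L] == f[2L]) stop("self-loop at line ", i, ": ", f[1L], call. = FALSE)
    f[1:2]
  })
  el <- do.call(rbind, pairs)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write result tables as fixed-precision TSV reports
#'
#' Each element of `results` becomes one `<name>.tsv` under `path`. Numeric
#' columns are rendered at two decimals, except columns whose name starts
#' with `p_` or equals `p` (scientific notation, three significant digits),
#' so re-running on identical input produces byte-identical files.
#'
#' @param results Named list of non-empty data.frames.
#' @param path Output directory (created if needed).
#' @return data.frame manifest with columns `name`, `file`, `rows`.
#' @export
write_report <- function(results, path) {
  if (!is.list(results) || length(results) == 0L ||
      is.null(names(results)) || any(!nzchar(names(results)))) {
    stop("nothing to write: results must be a non-empty named list", call. = FALSE)
  }
  ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("unwritable path: ", path, call. = FALSE)
  files <- character(0)
  rows <- integer(0)
  for (nm in names(results)) {
    df <- results[[nm]]
    if (!is.data.frame(df) || nrow(df) == 0L) {
      stop("nothing to write for '", nm, "'", call. = FALSE)
    }
    out <- df
    for (j in seq_along(out)) {
      if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
        if (grepl("^p($|_)", names(out)[j])) {
          out[[j]] <- sprintf("%.3e", out[[j]])
        } else {
          out[[j]] <- sprintf("%.2f", out[[j]])
        }
      }
    }
    f <- file.path(path, paste0(nm, ".tsv"))
    utils::write.table(out, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
    rows <- c(rows, nrow(df))
  }
  data.frame(name = names(results), file = files, rows = rows,
             stringsAsFactors = FALSE)
}
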