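#' Breast cancer molecular subtype labels
#'
#' The five molecular subtypes used throughout the package, in order of
#' increasing clinical aggressiveness: luminal A, luminal B HER2-negative,
#' luminal B HER2-positive, non-luminal HER2-positive, and triple-negative
#' breast cancer.
#'
#' @return Character vector of five subtype codes.
#' @export
#' @examples
#' breast_subtypes()
breast_subtypes <- function() {
  c("LumA", "LumB_HER2neg", "LumB_HER2pos", "NonLum_HER2pos", "TNBC")
}

#' Registry of pyroptosis-related gene sets
#'
#' Named gene sets underlying the signature scores:
#'
#' * `pro_pyroptotic` (6 genes): CXCL8, BAX, CASP1, CASP9, TP53, MMP9 —
#'   promote inflammasome activation, caspase signalling and inflammatory
#'   cell death.
#' * `anti_pyroptotic` (3 genes): BCL2, CDKN1A, CDKN1B — restrain programmed
#'   cell death and maintain cell-cycle control.
#' * `inflammasome_panel` (10 genes): IL1B, IL18, NLRP3, PYCARD, TLR9, RIPK1,
#'   TNF, STING1, JAK3, CASP1 — sensors, adaptors, cytokines and effector
#'   caspases of inflammasome signalling.
#' * `core9`: union of the pro- and anti-pyroptotic sets, the
#'   subtype-independent signature.
#'
#' PYCARD is also known as ASC; the alias is resolved transparently by the
#' scoring functions.
#'
#' @return An object of class `gene_set_registry`: a list with elements
#'   `pro_pyroptotic`, `anti_pyroptotic`, `inflammasome_panel`, `core9`, and
#'   `aliases` (named character vector mapping alias to canonical symbol).
#' @export
#' @examples
#' reg <- gene_set_registry()
#' reg$core9
gene_set_registry <- function() {
  reg <- list(
    pro_pyroptotic = c("CXCL8", "BAX", "CASP1", "CASP9", "TP53", "MMP9"),
    anti_pyroptotic = c("BCL2", "CDKN1A", "CDKN1B"),
    inflammasome_panel = c("IL1B", "IL18", "NLRP3", "PYCARD", "TLR9",
                           "RIPK1", "TNF", "STING1", "JAK3", "CASP1"),
    aliases = c(ASC = "PYCARD")
  )
  reg$core9 <- c(reg$pro_pyroptotic, reg$anti_pyroptotic)
  stopifnot(
    length(intersect(reg$pro_pyroptotic, reg$anti_pyroptotic)) == 0L,
    length(reg$pro_pyroptotic) == 6L,
    length(reg$anti_pyroptotic) == 3L,
    length(reg$inflammasome_panel) == 10L
  )
  class(reg) <- "gene_set_registry"
  reg
}

# Map alias symbols (e.g. ASC) to their canonical registry symbol.
resolve_symbols <- function(x, registry) {
  hit <- x %in% names(registry$aliases)
  x[hit] <- unname(registry$aliases[x[hit]])
  x
}

#' @export
print.gene_set_registry <- function(x, ...) {
  cat("Gene-set registry\n")
  cat("  pro-pyroptotic:    ", paste(x$pro_pyroptotic, collapse = ", "), "\n")
  cat("  anti-pyroptotic:   ", paste(x$anti_pyroptotic, collapse = ", "), "\n")
  cat("  inflammasome panel:", paste(x$inflammasome_panel, collapse = ", "), "\n")
  invisible(x)
}
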