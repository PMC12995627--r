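# Shared builders for small, fully-specified test inputs.

# A minimal valid expression matrix: `n_pairs` tumor/control pairs for each of
# the five subtypes, `probes` rows. `shift` is added to tumor samples of every
# subtype (same for all probes) on top of i.i.d. noise.
toy_matrix <- function(n_pairs = 2L, probes = c("p1", "p2", "p3"),
                       shift = 0, noise_sd = 0, seed = 1L) {
  set.seed(seed)
  meta <- do.call(rbind, lapply(breast_subtypes(), function(s) {
    subj <- paste0(s, "_", seq_len(n_pairs))
    data.frame(
      sample_id = c(paste0(subj, "_T"), paste0(subj, "_C")),
      subject_id = rep(subj, 2L), subtype = s,
      group = rep(c("tumor", "control"), each = n_pairs),
      pair_id = rep(subj, 2L), stringsAsFactors = FALSE
    )
  }))
  v <- matrix(8 + rnorm(length(probes) * nrow(meta), 0, noise_sd),
              nrow = length(probes),
              dimnames = list(probes, meta$sample_id))
  v[, meta$group == "tumor"] <- v[, meta$group == "tumor"] + shift
  expression_matrix(v, meta)
}

# Study-condition synthetic config used by the recovery checks: nine universal
# genes, forty subtype-specific, five hundred null, twenty pairs per subtype.
recovery_config <- function(seed) {
  synth_config(
    seed = seed,
    n_pairs_per_subtype = setNames(rep(20L, 5L), breast_subtypes()),
    n_universal = 9L, n_subtype_specific = 40L, n_null = 500L,
    universal_effect = c(4, 6), noise_sd = 0.8
  )
}

# Write lines to a temp file and return its path.
tmpfile_with <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
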