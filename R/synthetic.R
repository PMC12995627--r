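#' Configuration for the synthetic cohort generator
#'
#' Defines the statistical structure the analysis assumes: a paired
#' tumor/control cohort over five molecular subtypes with planted
#' subtype-independent ("universal") effects, subtype-specific effects and
#' null genes; qPCR Ct structure consistent with the planted fold changes;
#' pulse-shaped post-intervention kinetics peaking at the T2 grid time; and
#' miRNA target-score tables.
#'
#' Default pair counts are the study's subtype sizes (130/100/96/36/43)
#' scaled down by a factor of five. Universal effects have magnitude drawn
#' uniformly from `universal_effect` with a random sign per (gene, subtype) —
#' the intersection criterion is magnitude-only, so signs are free to differ
#' across subtypes. Expression noise is additive on the log2 scale.
#'
#' @param seed Integer seed; fixed seed makes every generator deterministic.
#' @param n_pairs_per_subtype Named integer vector of tumor/control pair
#'   counts per subtype.
#' @param n_universal,n_subtype_specific,n_null Number of genes in each
#'   planted class.
#' @param universal_effect,specific_effect Length-2 numeric: magnitude range
#'   of planted log2 fold changes (universal effects must exceed 3 in every
#'   subtype).
#' @param noise_sd Per-sample log2 noise SD (> 0).
#' @param baseline_range Range of per-gene baseline log2 intensity.
#' @param probes_per_gene Probes per gene; when > 1 probes share the gene
#'   effect plus a small probe-level baseline offset.
#' @param kinetics List: `amplitudes` (named, per analyte), `tau` peak time
#'   in hours, `noise_sd` replicate-level lognormal SD, `n_replicates`.
#'   Default amplitudes follow the nine-gene fibroadenoma panel.
#' @param ct List: `log2fc` (named planted effects), `noise_sd` Ct noise SD,
#'   `reference_gene`, `reference_ct`, `base_ct`, `n_per_group`.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_pairs_per_subtype = c(LumA = 26L, LumB_HER2neg = 20L,
                                                 LumB_HER2pos = 19L,
                                                 NonLum_HER2pos = 7L, TNBC = 9L),
                         n_universal = 9L,
                         n_subtype_specific = 40L,
                         n_null = 500L,
                         universal_effect = c(4, 6),
                         specific_effect = c(4, 6),
                         noise_sd = 0.8,
                         baseline_range = c(6, 12),
                         probes_per_gene = 1L,
                         kinetics = list(),
                         ct = list()) {
  kin_def <- list(
    amplitudes = c(CXCL8 = 1.10, BCL2 = 0.10, BAX = 0.80, CASP1 = 0.95,
                   CASP9 = 0.70, TP53 = 0.55, CDKN1A = 0.35, CDKN1B = 0.25,
                   MMP9 = 1.00),
    tau = 10, noise_sd = 0.1, n_replicates = 34L
  )
  ct_def <- list(log2fc = c(CXCL8 = 2, BAX = 1, BCL2 = -1), noise_sd = 0.2,
                 reference_gene = "ACTB", reference_ct = 15, base_ct = 24,
                 n_per_group = 20L)
  kin <- utils::modifyList(kin_def, kinetics)
  ctl <- utils::modifyList(ct_def, ct)
  cfg <- list(seed = as.integer(seed),
              n_pairs_per_subtype = n_pairs_per_subtype,
              n_universal = as.integer(n_universal),
              n_subtype_specific = as.integer(n_subtype_specific),
              n_null = as.integer(n_null),
              universal_effect = universal_effect,
              specific_effect = specific_effect,
              noise_sd = noise_sd,
              baseline_range = baseline_range,
              probes_per_gene = as.integer(probes_per_gene),
              kinetics = kin, ct = ctl)
  if (!all(breast_subtypes() %in% names(cfg$n_pairs_per_subtype))) {
    stop("n_pairs_per_subtype must name all five subtypes", call. = FALSE)
  }
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (min(cfg$universal_effect) <= 3) {
    stop("universal effects must exceed the |log2FC| > 3 screen threshold",
         call. = FALSE)
  }
  class(cfg) <- "synth_config"
  cfg
}

#' Generate a paired tumor/control expression cohort with known truth
#'
#' Control expression per probe is the gene baseline plus log2 noise; tumor
#' expression adds the planted log2 fold change for the sample's subtype.
#' Gene classes partition the simulated gene set:
#' `universal` (effect magnitude in `universal_effect` in every subtype, sign
#' random per subtype), `subtype_specific` (one subtype affected), `null`
#' (no effect).
#'
#' @param config A [synth_config()].
#' @return List with elements `matrix` (an `expr_matrix`) and `truth`
#'   (data.frame: `gene_symbol`, `class`, one planted-log2FC column per
#'   subtype).
#' @export
#' @examples
#' sim <- generate_cohort(synth_config(seed = 7, n_null = 50,
#'                                     n_subtype_specific = 5))
#' sim$truth[sim$truth$class == "universal", "gene_symbol"]
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  subtypes <- breast_subtypes()
  n_pairs <- config$n_pairs_per_subtype[subtypes]
  if (any(n_pairs < 2L)) {
    stop("need at least 2 pairs per subtype (variance undefined otherwise)",
         call. = FALSE)
  }
  set.seed(config$seed)

  genes <- c(
    if (config$n_universal > 0) sprintf("UNIV%03d", seq_len(config$n_universal)),
    if (config$n_subtype_specific > 0) sprintf("SPEC%03d", seq_len(config$n_subtype_specific)),
    if (config$n_null > 0) sprintf("NULL%03d", seq_len(config$n_null))
  )
  classes <- rep(c("universal", "subtype_specific", "null"),
                 c(config$n_universal, config$n_subtype_specific, config$n_null))
  n_genes <- length(genes)
  if (n_genes == 0L) stop("no genes configured", call. = FALSE)

  effects <- matrix(0, n_genes, length(subtypes),
                    dimnames = list(genes, subtypes))
  iu <- which(classes == "universal")
  for (i in iu) {
    mag <- runif(1L, config$universal_effect[1L], config$universal_effect[2L])
    effects[i, ] <- mag * sample(c(-1, 1), length(subtypes), replace = TRUE)
  }
  is_ <- which(classes == "subtype_specific")
  for (i in is_) {
    s <- sample(subtypes, 1L)
    effects[i, s] <- runif(1L, config$specific_effect[1L], config$specific_effect[2L]) *
      sample(c(-1, 1), 1L)
  }

  baseline <- runif(n_genes, config$baseline_range[1L], config$baseline_range[2L])
  k <- config$probes_per_gene
  probe_offset <- if (k > 1L) rnorm(n_genes * k, 0, 0.3) else rep(0, n_genes)
  probe_gene <- rep(seq_len(n_genes), each = k)
  probe_ids <- if (k > 1L) {
    paste0(rep(genes, each = k), "_p", rep(seq_len(k), n_genes))
  } else genes

  meta <- do.call(rbind, lapply(subtypes, function(s) {
    np <- n_pairs[[s]]
    subj <- sprintf("%s_P%03d", s, seq_len(np))
    data.frame(
      sample_id = c(paste0(subj, "_T"), paste0(subj, "_C")),
      subject_id = rep(subj, 2L),
      subtype = s,
      group = rep(c("tumor", "control"), each = np),
      pair_id = rep(subj, 2L),
      stringsAsFactors = FALSE
    )
  }))
  n_samp <- nrow(meta)

  vals <- matrix(rnorm(length(probe_ids) * n_samp, 0, config$noise_sd),
                 nrow = length(probe_ids),
                 dimnames = list(probe_ids, meta$sample_id))
  vals <- vals + baseline[probe_gene] + probe_offset
  tumor_idx <- which(meta$group == "tumor")
  for (j in tumor_idx) {
    vals[, j] <- vals[, j] + effects[probe_gene, meta$subtype[j]]
  }

  truth <- data.frame(gene_symbol = genes, class = classes,
                      stringsAsFactors = FALSE)
  for (s in subtypes) truth[[s]] <- effects[, s]

  list(matrix = expression_matrix(vals, meta), truth = truth)
}

#' Generate a qPCR Ct table consistent with planted fold changes
#'
#' Ct values are constructed so that the implied 2^-ddCt fold changes equal
#' the planted effects up to Ct noise: tumor target Ct = base Ct − planted
#' log2FC + noise; the reference gene Ct is constant across groups up to
#' noise. With `ct$noise_sd = 0` in the config, [ddct_fold_change()] recovers
#' the planted fold changes exactly.
#'
#' @param config A [synth_config()]; fields under `config$ct` control the
#'   planted `log2fc`, Ct noise, reference gene and group size.
#' @return data.frame with columns `sample_id`, `group`, `gene_symbol`, `ct`,
#'   including reference-gene rows for every sample.
#' @export
generate_ct_table <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  ct <- config$ct
  if (is.null(ct$reference_gene) || !nzchar(ct$reference_gene)) {
    stop("missing reference gene in ct config", call. = FALSE)
  }
  if (is.null(ct$log2fc) || is.null(names(ct$log2fc))) {
    stop("ct$log2fc must be a named vector of planted log2 fold changes",
         call. = FALSE)
  }
  set.seed(config$seed)
  n <- ct$n_per_group
  samples <- data.frame(
    sample_id = c(sprintf("tumor_%03d", seq_len(n)),
                  sprintf("control_%03d", seq_len(n))),
    group = rep(c("tumor", "control"), each = n),
    stringsAsFactors = FALSE
  )
  genes <- names(ct$log2fc)
  rows <- lapply(seq_len(nrow(samples)), function(i) {
    shift <- if (samples$group[i] == "tumor") ct$log2fc else setNames(rep(0, length(genes)), genes)
    data.frame(
      sample_id = samples$sample_id[i],
      group = samples$group[i],
      gene_symbol = c(genes, ct$reference_gene),
      ct = c(ct$base_ct - shift + rnorm(length(genes), 0, ct$noise_sd),
             ct$reference_ct + rnorm(1L, 0, ct$noise_sd)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pulse-shaped fold-change trajectory
#'
#' The gamma-like pulse `FC(t) = 1 + A * (t/tau) * exp(1 - t/tau)`: baseline 1
#' at t = 0, a single maximum of `1 + A` at `t = tau`, smooth decay back to
#' baseline.
#'
#' @param hours Numeric vector of time points (hours).
#' @param amplitude Pulse amplitude A (>= 0).
#' @param tau Peak time in hours (> 0).
#' @return Numeric vector of fold changes.
#' @export
pulse_fc <- function(hours, amplitude, tau) {
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  1 + amplitude * (hours / tau) * exp(1 - hours / tau)
}

#' Generate replicate-level longitudinal panels
#'
#' One [longitudinal_series()] per analyte on the T0..T6 grid
#' ([timepoint_hours()]). Replicate fold changes are the noise-free pulse
#' trajectory times lognormal noise (`exp(rnorm(0, noise_sd))`), keeping fold
#' changes positive; replicate-level values are retained for significance
#' testing with [paired_vs_baseline()].
#'
#' @param config A [synth_config()]; `config$kinetics` supplies per-analyte
#'   amplitudes, `tau`, replicate noise SD and replicate count.
#' @return Named list of `longitudinal_series` objects.
#' @export
generate_longitudinal_panel <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  kin <- config$kinetics
  if (any(kin$amplitudes < 0)) stop("amplitude must be >= 0", call. = FALSE)
  set.seed(config$seed)
  hrs <- timepoint_hours()
  out <- lapply(names(kin$amplitudes), function(a) {
    fc <- pulse_fc(hrs, kin$amplitudes[[a]], kin$tau)
    reps <- matrix(rep(fc, each = kin$n_replicates) *
                     exp(rnorm(kin$n_replicates * length(hrs), 0, kin$noise_sd)),
                   nrow = kin$n_replicates,
                   dimnames = list(NULL, names(hrs)))
    longitudinal_series(
      analyte = a, time = names(hrs), hours = unname(hrs),
      mean = colMeans(reps), sd = apply(reps, 2L, sd),
      level = "fc", replicates = reps
    )
  })
  names(out) <- names(kin$amplitudes)
  out
}

#' Generate miRNA target-score pairs
#'
#' Scores are drawn uniformly from the integers 50..99, so the expected tier
#' mass is 19/50 high (81..99), 21/50 intermediate (60..80) and 10/50
#' cautious (50..59). With `fixture_mode = TRUE` the packaged predicted-pair
#' table is returned verbatim (known pairs keep their printed scores).
#'
#' @param config A [synth_config()] (seed).
#' @param genes Character vector of target gene symbols (required unless
#'   `fixture_mode`).
#' @param n_per_gene Number of simulated miRNA partners per gene.
#' @param fixture_mode Return the packaged predicted-pair fixture instead of
#'   simulating.
#' @return data.frame with columns `mirna_id`, `gene_symbol`, `target_score`.
#' @export
generate_target_pairs <- function(config, genes = NULL, n_per_gene = 3L,
                                  fixture_mode = FALSE) {
  stopifnot(inherits(config, "synth_config"))
  if (fixture_mode) {
    fix <- load_paper_fixture("table3")
    return(data.frame(mirna_id = fix$mirna_id, gene_symbol = fix$gene_symbol,
                      target_score = as.integer(fix$target_score),
                      stringsAsFactors = FALSE))
  }
  if (is.null(genes) || length(genes) == 0L) {
    stop("empty gene list", call. = FALSE)
  }
  set.seed(config$seed)
  n <- length(genes) * n_per_gene
  data.frame(
    mirna_id = sprintf("sim-miR-%04d", seq_len(n)),
    gene_symbol = rep(genes, each = n_per_gene),
    target_score = sample(50:99, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}
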