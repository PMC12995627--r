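#' Construct a longitudinal series
#'
#' One analyte's ordered time course: per-time-point mean (fold change vs T0
#' or absolute concentration), SD, optional significance flags, and optional
#' replicate-level values (replicates x time points) for recomputing
#' significance.
#'
#' @param analyte Analyte name (gene or protein).
#' @param time Character vector of ordered time-point labels; must start
#'   with `"T0"`.
#' @param hours Numeric time coordinates, strictly increasing.
#' @param mean Per-time-point means.
#' @param sd Per-time-point SDs (>= 0); optional.
#' @param significant Logical flags per time point; optional.
#' @param level `"fc"` (fold change vs T0, baseline 1) or `"concentration"`
#'   (baseline = T0 mean).
#' @param replicates Optional numeric matrix, replicates x time points
#'   (columns named as `time`).
#' @return Object of class `longitudinal_series`.
#' @export
longitudinal_series <- function(analyte, time, hours, mean, sd = NULL,
                                significant = NULL,
                                level = c("fc", "concentration"),
                                replicates = NULL) {
  level <- match.arg(level)
  n <- length(time)
  if (time[1L] != "T0") stop("series must start at T0", call. = FALSE)
  if (anyDuplicated(time)) stop("duplicate time points", call. = FALSE)
  if (length(hours) != n || is.unsorted(hours, strictly = TRUE)) {
    stop("hours must be strictly increasing, one per time point", call. = FALSE)
  }
  if (length(mean) != n) stop("one mean per time point required", call. = FALSE)
  if (!is.null(sd) && (length(sd) != n || any(sd < 0))) {
    stop("sd must be non-negative, one per time point", call. = FALSE)
  }
  if (!is.null(replicates)) {
    if (!is.matrix(replicates) || ncol(replicates) != n) {
      stop("replicates must be a matrix with one column per time point",
           call. = FALSE)
    }
    colnames(replicates) <- time
  }
  structure(list(analyte = analyte, level = level,
                 points = data.frame(time = time, hours = hours,
                                     mean = unname(mean),
                                     sd = if (is.null(sd)) NA_real_ else unname(sd),
                                     significant = if (is.null(significant)) NA else significant,
                                     stringsAsFactors = FALSE),
                 replicates = replicates),
            class = "longitudinal_series")
}

#' @export
print.longitudinal_series <- function(x, ...) {
  cat("Longitudinal series:", x$analyte, "(", x$level, ")\n")
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Peak of a post-baseline time course
#'
#' Argmax of the mean over the post-baseline points (T1 onward); ties break
#' to the earliest time point. Invariant under positive rescaling of the
#' series.
#'
#' @param series A [longitudinal_series()].
#' @return List: `time`, `hours`, `value`.
#' @export
#' @examples
#' detect_peak(fixture_series("CXCL8", "table5"))  # T2, 2.10
detect_peak <- function(series) {
  stopifnot(inherits(series, "longitudinal_series"))
  post <- series$points[series$points$time != "T0", , drop = FALSE]
  if (nrow(post) < 2L) stop("need >= 2 post-baseline points", call. = FALSE)
  i <- which.max(post$mean)
  list(time = post$time[i], hours = post$hours[i], value = post$mean[i])
}

#' Earliest durable return to baseline
#'
#' The earliest post-peak time point whose mean lies within a relative band
#' `|mean/baseline - 1| <= band` of the baseline (1 for fold-change series,
#' the T0 mean for concentrations) with every later point also inside the
#' band. Widening the band never yields a later return time.
#'
#' @param series A [longitudinal_series()].
#' @param band Relative tolerance delta (> 0), default 0.15.
#' @return List: `time` (label, or `NA` if the series never durably
#'   re-enters the band), `hours`, `baseline`.
#' @export
#' @examples
#' time_to_baseline(fixture_series("CXCL8", "table5"))$time  # "T5"
time_to_baseline <- function(series, band = 0.15) {
  stopifnot(inherits(series, "longitudinal_series"))
  if (band <= 0) stop("band must be > 0", call. = FALSE)
  baseline <- if (series$level == "fc") 1 else series$points$mean[1L]
  peak <- detect_peak(series)
  # candidates: the peak itself onward (a series already at baseline "returns"
  # at its first post-baseline point)
  post <- series$points[series$points$hours >= peak$hours &
                          series$points$time != "T0", , drop = FALSE]
  within <- abs(post$mean / baseline - 1) <= band
  stays <- rev(cumprod(rev(within))) == 1  # inside the band from here onward
  i <- which(stays)[1L]
  if (is.na(i)) {
    return(list(time = NA_character_, hours = NA_real_, baseline = baseline))
  }
  list(time = post$time[i], hours = post$hours[i], baseline = baseline)
}

#' Paired test of one time point against baseline
#'
#' Two-sided paired t-test on log-scale values versus T0 (logs make fold
#' rises and falls symmetric). If every within-subject log difference is
#' zero the test degenerates to p = 1.
#'
#' @param t0 Per-subject values at baseline (> 0).
#' @param tk Per-subject values at the later time point, same subjects, same
#'   order (> 0).
#' @param alpha Threshold for the significance flag.
#' @return List: `p`, `significant`, `n`.
#' @export
paired_vs_baseline <- function(t0, tk, alpha = 0.05) {
  if (length(t0) != length(tk)) stop("unpaired input: lengths differ", call. = FALSE)
  if (length(t0) < 2L) stop("need >= 2 paired subjects", call. = FALSE)
  if (any(t0 <= 0) || any(tk <= 0)) stop("values must be > 0 for the log scale",
                                         call. = FALSE)
  d <- log(tk) - log(t0)
  p <- if (sd(d) == 0) {
    if (all(d == 0)) 1 else 0
  } else {
    stats::t.test(d, mu = 0)$p.value
  }
  list(p = p, significant = p < alpha, n = length(t0))
}

#' Per-time-point significance of a replicate-level series
#'
#' Runs [paired_vs_baseline()] of every post-T0 time point against T0 using
#' the series' replicate matrix.
#'
#' @param series A [longitudinal_series()] carrying replicates.
#' @param alpha Significance threshold.
#' @return data.frame with columns `time`, `p`, `significant`.
#' @export
series_significance <- function(series, alpha = 0.05) {
  stopifnot(inherits(series, "longitudinal_series"))
  if (is.null(series$replicates)) {
    stop("series carries no replicate-level values", call. = FALSE)
  }
  reps <- series$replicates
  post <- setdiff(colnames(reps), "T0")
  rows <- lapply(post, function(tp) {
    r <- paired_vs_baseline(reps[, "T0"], reps[, tp], alpha)
    data.frame(time = tp, p = r$p, significant = r$significant,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
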