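#' Percent-of-reference trace for one islet
#'
#' Expresses an integrated-density series as a percentage of its value at
#' the reference time point: `P(t) = 100 * ID(t) / ID(t_ref)`.  100 means
#' unchanged; values above 100 (apparent content gain) are allowed, as
#' observed for some small islets.  The reference is the stimulation time
#' point: t15 for the in vitro protocol, t0 in vivo.
#'
#' @param id Numeric vector of integrated densities.
#' @param time_points Acquisition times (minutes), same length as `id`.
#' @param reference_time Reference time (must be in `time_points`).
#' @return Percent series; if the reference density is not positive, a
#'   vector of `NA` with attribute `reason = "zero_reference"` (the trace
#'   is excluded downstream, never a division error).
#' @export
percent_trace <- function(id, time_points, reference_time) {
  stopifnot(length(id) == length(time_points))
  k <- match(reference_time, time_points)
  if (is.na(k)) stop("reference_time not among time_points", call. = FALSE)
  if (!is.finite(id[k]) || id[k] <= 0) {
    out <- rep(NA_real_, length(id))
    attr(out, "reason") <- "zero_reference"
    return(out)
  }
  100 * id / id[k]
}

#' Summarize an experiment's secretion response
#'
#' Computes, over the retained (complete, unexcluded) traces, the per-islet
#' percent of reference at the end time, the per-islet declines, the
#' whole-experiment total response (percent change of the summed integrated
#' densities, identically the content-weighted mean of the per-islet
#' declines), and the heterogeneity SEM (standard error of the mean of the
#' per-islet percentages; the population-heterogeneity metric).
#'
#' @param traces An `islet_traces` object (after [apply_exclusions()]).
#' @param reference_time Reference/stimulation time point (minutes).
#' @param end_time End of the analysis window (minutes); defaults to
#'   15 minutes after the reference, when most of the insulin is secreted.
#' @return A `gsis_summary` list: `reference_time`, `end_time`, `n_islets`,
#'   `per_islet` (data frame: `islet_id`, `area_px`, `id_ref`, `id_end`,
#'   `percent`, `decline`, `log10_ratio`), `total_response_percent`,
#'   `heterogeneity_sem` (`NA` for a single islet: undefined, not 0),
#'   `percent_traces` (long data frame of P(t) for plotting).
#' @export
summarize_experiment <- function(traces, reference_time, end_time = NULL) {
  stopifnot(inherits(traces, "islet_traces"))
  if (is.null(end_time)) {
    avail <- traces$time_points
    end_time <- min(reference_time + 15, max(avail, na.rm = TRUE))
  }
  obj <- traces$objects
  info <- traces$info
  retained <- info$islet_id[!info$excluded & info$complete]
  rows_ref <- obj[obj$time_point == reference_time & obj$islet_id %in% retained, ]
  rows_end <- obj[obj$time_point == end_time & obj$islet_id %in% retained, ]
  if (nrow(rows_ref) == 0) {
    stop("no retained traces to summarize", call. = FALSE)
  }
  m <- match(rows_ref$islet_id, rows_end$islet_id)
  per <- data.frame(
    islet_id = rows_ref$islet_id,
    area_px = rows_ref$area_px,
    id_ref = rows_ref$integrated_density,
    id_end = rows_end$integrated_density[m]
  )
  # zero reference density: excluded with a reason, not a division error
  bad <- per$id_ref <= 0
  if (any(bad)) {
    drop_ids <- per$islet_id[bad]
    traces$info$excluded[traces$info$islet_id %in% drop_ids] <- TRUE
    traces$info$reason[traces$info$islet_id %in% drop_ids] <- "zero_reference"
    per <- per[!bad, ]
  }
  if (nrow(per) == 0) stop("no retained traces to summarize", call. = FALSE)
  per$percent <- 100 * per$id_end / per$id_ref
  per$decline <- 100 - per$percent
  per$log10_ratio <- log10(per$id_end / per$id_ref)

  total <- 100 * (sum(per$id_ref) - sum(per$id_end)) / sum(per$id_ref)
  sem <- if (nrow(per) >= 2) sd(per$percent) / sqrt(nrow(per)) else NA_real_

  # long percent traces for the retained islets (plotting / audit)
  keep <- obj$islet_id %in% per$islet_id
  po <- obj[keep, c("islet_id", "time_point", "integrated_density")]
  ref_id <- setNames(per$id_ref, per$islet_id)
  po$percent <- 100 * po$integrated_density /
    ref_id[as.character(po$islet_id)]

  structure(list(
    reference_time = reference_time,
    end_time = end_time,
    n_islets = nrow(per),
    per_islet = per,
    total_response_percent = total,
    heterogeneity_sem = sem,
    percent_traces = po
  ), class = "gsis_summary")
}

#' @export
print.gsis_summary <- function(x, ...) {
  cat(sprintf(
    "<gsis_summary> n = %d islets, t_ref = %g min, t_end = %g min\n",
    x$n_islets, x$reference_time, x$end_time
  ))
  cat(sprintf("  total response: %.2f%%  mean per-islet decline: %.2f%%  SEM of P_i: %s\n",
              x$total_response_percent, mean(x$per_islet$decline),
              ifelse(is.na(x$heterogeneity_sem), "NA",
                     sprintf("%.3f", x$heterogeneity_sem))))
  invisible(x)
}

#' Size-response relation
#'
#' Rank correlation (Spearman) between islet area and the log integrated-
#' density change ratio, with its two-sided p-value — a report only, no
#' thresholded verdict.  An absence of correlation is the size-independence
#' signature of the in vivo response.
#'
#' @param summary A `gsis_summary`.
#' @return List `rho`, `p_value`, `n`; `rho` is `NA` when areas are
#'   constant (correlation undefined, reported as missing).
#' @export
size_response_relation <- function(summary) {
  per <- summary$per_islet
  if (nrow(per) < 3) stop("need at least 3 islets", call. = FALSE)
  if (sd(per$area_px) == 0 || sd(per$log10_ratio) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = nrow(per)))
  }
  ct <- suppressWarnings(
    cor.test(per$area_px, per$log10_ratio, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(per))
}

#' Compare response heterogeneity between two groups of experiments
#'
#' Compares the heterogeneity SEM values of two groups (e.g. in vitro
#' culture wells vs in vivo pancreata).  Each group's values are checked
#' for normality (Shapiro-Wilk at alpha = 0.05); if both pass, an unpaired
#' t-test is used, otherwise a Mann-Whitney test.  Both test results are
#' reported alongside the chosen one.
#'
#' @param sem_a,sem_b Numeric vectors of per-experiment heterogeneity SEMs
#'   (each of length >= 2); alternatively lists of `gsis_summary` objects.
#' @return List: `test_used`, `statistic`, `p_value`, group means and
#'   medians, `shapiro_p`, and the full `t_test` / `mann_whitney` results.
#' @export
compare_heterogeneity <- function(sem_a, sem_b) {
  pick <- function(x) {
    if (is.list(x)) vapply(x, function(s) s$heterogeneity_sem, numeric(1))
    else as.numeric(x)
  }
  a <- pick(sem_a); b <- pick(sem_b)
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 experiments", call. = FALSE)
  }
  shapiro_safe <- function(x) {
    if (sd(x) == 0) return(0)  # degenerate: treat as failing normality
    shapiro.test(x)$p.value
  }
  pa <- shapiro_safe(a); pb <- shapiro_safe(b)
  tt <- tryCatch(t.test(a, b), error = function(e) NULL)
  mw <- suppressWarnings(wilcox.test(a, b))
  use_t <- pa > 0.05 && pb > 0.05 && !is.null(tt)
  chosen <- if (use_t) tt else mw
  list(
    test_used = if (use_t) "t" else "mann_whitney",
    statistic = unname(chosen$statistic),
    p_value = chosen$p.value,
    mean_a = mean(a), mean_b = mean(b),
    median_a = median(a), median_b = median(b),
    shapiro_p = c(a = pa, b = pb),
    t_test = tt,
    mann_whitney = mw
  )
}
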