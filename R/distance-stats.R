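## Within/between-class distance summaries and the study's two test
## statistics: one-sided two-sample Kolmogorov-Smirnov and pooled two-sample t.

#' Per-sample within/between-class distance summary
#'
#' For every sample, the mean Euclidean distance to all other samples of the
#' same evaluation class (`within_avg`; `NA` for samples whose class is a
#' singleton) and to all samples of different classes (`between_avg`). A
#' one-sided KS test of "between stochastically larger than within" is
#' attached.
#'
#' @param pset A [project_fisher()] result, or a coordinate matrix with
#'   `labels`.
#' @param labels Optional label vector when `pset` is a matrix.
#' @return A `distance_summary`: per-sample tibble plus `ks_D`, `ks_p`.
#' @export
class_distance_summary <- function(pset, labels = NULL) {
  if (inherits(pset, "projected_set")) {
    coords <- pset$coordinates
    labels <- eval_labels(pset)
  } else {
    coords <- as.matrix(pset)
    if (is.null(labels)) abort("labels are required when pset is a matrix")
    labels <- as.character(labels)
  }
  n <- nrow(coords)
  if (n < 2L) abort("need at least 2 samples")
  if (dplyr::n_distinct(labels) < 2L) abort("all samples are in one class")

  D <- as.matrix(dist(coords))
  same <- outer(labels, labels, `==`)
  diag(same) <- NA  # exclude self-distances from both averages
  within_avg <- vapply(seq_len(n), function(i) {
    v <- D[i, which(same[i, ])]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  between_avg <- vapply(seq_len(n), function(i) {
    mean(D[i, which(!same[i, ])])
  }, numeric(1))

  ks <- ks_between_gt_within(within_avg[!is.na(within_avg)], between_avg)
  structure(
    list(per_sample = tibble(sample = seq_len(n), label = labels,
                             within_avg = within_avg, between_avg = between_avg),
         ks_D = ks$ks_D, ks_p = ks$ks_p),
    class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  cat("<distance_summary> ", nrow(x$per_sample), " samples; KS D = ",
      signif(x$ks_D, 3), ", p = ", signif(x$ks_p, 3), "\n", sep = "")
  invisible(x)
}

#' One-sided two-sample KS test: between > within
#'
#' Statistic `D = max_x [ECDF_within(x) - ECDF_between(x)]`, the one-sided
#' two-sample Kolmogorov-Smirnov statistic for the alternative that the
#' between-class distances are stochastically larger than the within-class
#' distances. The p-value is the asymptotic one-sided bound
#' `exp(-2 n_eff D^2)` with effective sample size `n1 n2 / (n1 + n2)`.
#'
#' @param within_avg,between_avg Non-empty numeric samples.
#' @return One-row tibble: `ks_D`, `ks_p`, `n_within`, `n_between`.
#' @export
ks_between_gt_within <- function(within_avg, between_avg) {
  w <- as.numeric(within_avg)
  b <- as.numeric(between_avg)
  if (length(w) == 0L || length(b) == 0L) abort("both samples must be non-empty")
  grid <- sort(unique(c(w, b)))
  ecdf_w <- findInterval(grid, sort(w)) / length(w)
  ecdf_b <- findInterval(grid, sort(b)) / length(b)
  D <- max(ecdf_w - ecdf_b)
  if (D < 0) D <- 0
  n_eff <- length(w) * length(b) / (length(w) + length(b))
  p <- min(1, exp(-2 * n_eff * D^2))
  tibble(ks_D = D, ks_p = p,
         n_within = length(w), n_between = length(b))
}

#' Pooled two-sample t-test between condition score sets
#'
#' Student's pooled-variance two-sample t-test with `df = n1 + n2 - 2`;
#' positive `t` when the first condition's mean is larger. Degenerate inputs
#' with zero pooled variance give `t = 0, p = 1` when the means agree and an
#' error otherwise.
#'
#' @param perf_a,perf_b Numeric vectors of percent-correct values (length
#'   >= 2 each).
#' @return One-row tibble: `t`, `df`, `p`.
#' @export
compare_conditions_ttest <- function(perf_a, perf_b) {
  a <- as.numeric(perf_a)
  b <- as.numeric(perf_b)
  if (length(a) < 2L || length(b) < 2L) abort("each score list needs length >= 2")
  df <- as.integer(length(a) + length(b) - 2L)
  s2p <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) / df
  if (s2p == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      return(tibble(t = 0, df = df, p = 1))
    }
    abort("zero pooled variance with unequal means: t is undefined")
  }
  tt <- t.test(a, b, var.equal = TRUE)
  tibble(t = unname(tt$statistic), df = df, p = tt$p.value)
}
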