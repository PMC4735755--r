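## Figure layer: notched per-condition boxplots, face-space projections,
## within/between distance histograms.

#' Notched boxplots of DMS performance per condition
#'
#' One box per train:test condition over its sweep scores; non-overlapping
#' notch intervals differ at roughly the 5% level.
#'
#' @param results Results tibble from [run_sweep()] (omitted rows are dropped).
#' @return A ggplot object.
#' @export
plot_performance <- function(results) {
  results <- dplyr::filter(as_tibble(results), !.data$omitted)
  if (nrow(results) == 0L) abort("results table has no non-omitted rows")
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$condition, y = .data$percent_correct,
                               fill = .data$test_property)) +
    ggplot2::geom_boxplot(notch = TRUE) +
    ggplot2::facet_wrap(~ .data$dataset, scales = "free_x") +
    ggplot2::labs(x = "train:test condition", y = "percent correct (DMS)",
                  fill = "tested property") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Scatter of the first face-space components
#'
#' Projection coordinates coloured by evaluation class.
#'
#' @param pset A [project_fisher()] result.
#' @param dims Two component indices to display; one-dimensional spaces are
#'   shown against a jittered dummy axis.
#' @return A ggplot object.
#' @export
plot_face_space <- function(pset, dims = NULL) {
  stopifnot(inherits(pset, "projected_set"))
  d <- ncol(pset$coordinates)
  dims <- dims %||% seq_len(min(2L, d))
  if (max(dims) > d) {
    abort("requested components exceed the projected dimensionality")
  }
  df <- tibble(c1 = pset$coordinates[, dims[1]],
               c2 = if (length(dims) > 1L) pset$coordinates[, dims[2]] else
                 withr::with_seed(1L, runif(nrow(pset$coordinates), -1, 1)),
               class = eval_labels(pset))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$c1, y = .data$c2, colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = paste("component", dims[1]),
                  y = if (length(dims) > 1L) paste("component", dims[2]) else "jitter",
                  colour = pset$eval_property) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = if (dplyr::n_distinct(df$class) > 8) "none" else "right")
}

#' Histograms of per-sample within vs between class distances
#'
#' @param dsum A [class_distance_summary()].
#' @param bins Histogram bin count.
#' @return A ggplot object.
#' @export
plot_distance_hist <- function(dsum, bins = 30L) {
  stopifnot(inherits(dsum, "distance_summary"))
  df <- tidyr::pivot_longer(dsum$per_sample,
                            cols = c("within_avg", "between_avg"),
                            names_to = "kind", values_to = "distance")
  df <- dplyr::filter(df, !is.na(.data$distance))
  df$kind <- ifelse(df$kind == "within_avg", "within", "between")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance, fill = .data$kind)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.6, position = "identity") +
    ggplot2::labs(x = "average Euclidean distance", y = "samples", fill = NULL,
                  subtitle = sprintf("KS D = %.3g, p = %.3g", dsum$ks_D, dsum$ks_p)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.projected_set <- function(object, ...) plot_face_space(object, ...)

#' @export
autoplot.distance_summary <- function(object, ...) plot_distance_hist(object, ...)

#' @export
autoplot.transfer_study <- function(object, ...) plot_performance(object$results)

#' Write the study's figures as PNG files
#'
#' Performance boxplots, one face-space scatter and one distance histogram
#' per figure-scale condition; deterministic file names.
#'
#' @param study A [run_study_protocol()] result.
#' @param dir Output directory.
#' @return Character vector of written paths, invisibly.
#' @export
write_figures <- function(study, dir) {
  stopifnot(inherits(study, "transfer_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  save_one <- function(plot, name) {
    p <- file.path(dir, name)
    ggplot2::ggsave(p, plot, width = 7, height = 5, dpi = 120)
    paths <<- c(paths, p)
  }
  save_one(plot_performance(study$results), "performance_boxplots.png")
  for (key in names(study$projections)) {
    safe <- gsub("[^A-Za-z0-9]+", "_", key)
    save_one(plot_face_space(study$projections[[key]]),
             paste0("facespace_", safe, ".png"))
    save_one(plot_distance_hist(study$distances[[key]]),
             paste0("distances_", safe, ".png"))
  }
  invisible(paths)
}
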