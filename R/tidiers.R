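## broom-style tabular views of the fitted objects.

#' @export
tidy.eigen_model <- function(x, ...) {
  tibble(component = seq_along(x$eigenvalues),
         eigenvalue = x$eigenvalues,
         variance_share = x$eigenvalues / sum(x$eigenvalues))
}

#' @export
glance.eigen_model <- function(x, ...) {
  tibble(n_components = length(x$eigenvalues),
         n_samples = x$n_samples,
         n_pixels = ncol(x$components),
         total_variance = sum(x$eigenvalues))
}

#' @export
tidy.fisher_model <- function(x, ...) {
  m <- ncol(x$directions)
  p <- ncol(x$padding)
  tibble(direction = seq_len(m + p),
         type = rep(c("discriminant", "padding"), c(m, p)),
         eigenvalue = c(x$eigenvalues, rep(NA_real_, p)))
}

#' @export
glance.fisher_model <- function(x, ...) {
  tibble(trained_property = x$trained_property %||% NA_character_,
         n_classes = length(x$class_labels),
         n_discriminants = ncol(x$directions),
         n_padding = ncol(x$padding),
         k = x$k, ridge = x$ridge, normalization = x$normalization)
}

#' @export
tidy.projected_set <- function(x, ...) {
  coords <- as_tibble(x$coordinates, .name_repair = ~ paste0("dim", seq_along(.x)))
  dplyr::bind_cols(x$labels, coords)
}

#' @export
tidy.distance_summary <- function(x, ...) x$per_sample

#' @export
glance.distance_summary <- function(x, ...) {
  tibble(ks_D = x$ks_D, ks_p = x$ks_p,
         n_within = sum(!is.na(x$per_sample$within_avg)),
         n_between = nrow(x$per_sample))
}

#' @export
tidy.transfer_study <- function(x, ...) x$results

#' @export
glance.transfer_study <- function(x, ...) {
  ok <- dplyr::filter(x$results, !.data$omitted)
  tibble(n_rows = nrow(x$results),
         n_omitted = sum(x$results$omitted),
         n_conditions = dplyr::n_distinct(paste(ok$dataset, ok$condition)),
         mean_percent_correct = mean(ok$percent_correct))
}
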