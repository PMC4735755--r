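## Relabel-and-test transfer protocol and the delayed-match-to-sample
## (DMS) performance estimator.

#' Relabel a projected set with another facial property
#'
#' The coordinates are untouched; only the evaluation labelling changes. The
#' property the subspace was trained on stays recorded as
#' `source_property`.
#'
#' @param pset A [project_fisher()] result.
#' @param new_property Name of a column of the set's label table.
#' @return The projected set evaluating `new_property`.
#' @export
relabel <- function(pset, new_property) {
  stopifnot(inherits(pset, "projected_set"))
  if (!new_property %in% names(pset$labels)) {
    abort(paste0("unknown property '", new_property, "'; available: ",
                 paste(names(pset$labels), collapse = ", ")))
  }
  vals <- pset$labels[[new_property]]
  if (dplyr::n_distinct(vals) < 2L) {
    abort(paste0("property '", new_property,
                 "' has fewer than 2 distinct values in this set"))
  }
  pset$eval_property <- new_property
  pset
}

#' Score a single delayed-match-to-sample trial
#'
#' Two reference faces of distinct classes and a probe from one of the two
#' classes: the trial is correct iff the probe is strictly nearer (Euclidean)
#' to the same-class reference. Exact ties score 0.
#'
#' @param ref_a,ref_b Coordinate vectors of the two references.
#' @param probe Coordinate vector of the probe.
#' @param class_a,class_b Classes of the references (must differ).
#' @param probe_class Class of the probe; must be `class_a` or `class_b`.
#' @return 0 or 1.
#' @examples
#' dms_trial(0, 10, 1, "A", "B", "A")  # 1
#' dms_trial(0, 10, 9, "A", "B", "A")  # 0
#' dms_trial(0, 10, 5, "A", "B", "A")  # 0 (tie)
#' @export
dms_trial <- function(ref_a, ref_b, probe, class_a, class_b, probe_class) {
  if (identical(class_a, class_b)) abort("reference classes must differ")
  if (!probe_class %in% c(class_a, class_b)) {
    abort("probe class must be one of the two reference classes")
  }
  d_a <- sqrt(sum((probe - ref_a)^2))
  d_b <- sqrt(sum((probe - ref_b)^2))
  same_is_a <- identical(probe_class, class_a)
  d_same <- if (same_is_a) d_a else d_b
  d_other <- if (same_is_a) d_b else d_a
  as.integer(d_same < d_other)
}

# Per-pair triple count: for classes of sizes na, nb there are na*nb reference
# pairs and (na + nb - 2) valid probes each.
.pair_triples <- function(na, nb) as.double(na) * nb * (na + nb - 2)

#' Estimate DMS percent-correct over a projected set
#'
#' Enumerates every valid trial triple — an ordered pair of reference samples
#' from two distinct evaluation classes plus a probe sample (distinct from
#' both references) drawn from one of those two classes — and scores each
#' with the nearest-reference rule of [dms_trial()]. When the triple count
#' exceeds `max_trials`, a seeded uniform sample of triples is scored instead
#' (`mode = "auto"`). Classes with fewer than 2 samples cannot serve as a
#' probe's class and are excluded with a warning.
#'
#' @param pset A [project_fisher()] result (after [relabel()] if testing a
#'   different property), or a plain coordinate matrix if `labels` is given.
#' @param mode `"auto"`, `"exhaustive"` or `"sampled"`.
#' @param max_trials Trial cap for sampled mode / auto switch-over.
#' @param seed Integer seed for sampled mode.
#' @param labels Optional label vector when `pset` is a matrix.
#' @return One-row tibble: `percent_correct`, `n_correct`, `n_trials`,
#'   `mode`, `n_classes`, `n_dropped`.
#' @export
dms_performance <- function(pset, mode = c("auto", "exhaustive", "sampled"),
                            max_trials = 1e5, seed = 1L, labels = NULL) {
  mode <- match.arg(mode)
  if (inherits(pset, "projected_set")) {
    coords <- pset$coordinates
    labels <- eval_labels(pset)
  } else {
    coords <- as.matrix(pset)
    if (is.null(labels)) abort("labels are required when pset is a matrix")
    labels <- as.character(labels)
  }
  counts <- table(labels)
  small <- names(counts)[counts < 2L]
  n_dropped <- length(small)
  if (n_dropped > 0L) {
    warn(paste0(n_dropped, " evaluation class(es) with fewer than 2 samples excluded: ",
                paste(head(small, 8L), collapse = ", "),
                if (n_dropped > 8L) ", ..."),
         class = "facetransfer_dropped_classes")
    keep <- !labels %in% small
    coords <- coords[keep, , drop = FALSE]
    labels <- labels[keep]
    counts <- table(labels)
  }
  classes <- names(counts)
  if (length(classes) < 2L) {
    abort("fewer than 2 evaluation classes with >= 2 samples remain")
  }

  idx_by_class <- split(seq_along(labels), labels)
  pairs <- utils::combn(length(classes), 2L)
  triples <- apply(pairs, 2L, function(ij) {
    .pair_triples(counts[[ij[1]]], counts[[ij[2]]])
  })
  total <- sum(triples)
  if (mode == "auto") mode <- if (total <= max_trials) "exhaustive" else "sampled"

  if (mode == "exhaustive") {
    D <- as.matrix(dist(coords))
    n_correct <- 0
    for (q in seq_len(ncol(pairs))) {
      ia <- idx_by_class[[pairs[1L, q]]]
      ib <- idx_by_class[[pairs[2L, q]]]
      n_correct <- n_correct +
        .dms_exhaustive_block(D, ia, ib) + .dms_exhaustive_block(D, ib, ia)
    }
    n_trials <- total
  } else {
    draws <- with_seed(seed, .dms_sampled(coords, idx_by_class, pairs, triples,
                                          as.integer(max_trials)))
    n_correct <- draws$n_correct
    n_trials <- draws$n_trials
  }

  tibble(percent_correct = 100 * n_correct / n_trials,
         n_correct = n_correct, n_trials = n_trials, mode = mode,
         n_classes = length(classes), n_dropped = n_dropped)
}

# Correct-trial count for probes drawn from class A against references
# (ref_a in A, ref_b in B). For probe p and same-class reference i, the trial
# is correct iff D[p, i] < D[p, j] for the other-class reference j; ties lose.
# Summing the strict comparisons over all (p, i, j) including p == i, then
# removing the p == i diagonal (where D[p, p] = 0 beats every positive
# distance), gives the count without materializing the triples.
.dms_exhaustive_block <- function(D, ia, ib) {
  DA <- D[ia, ia, drop = FALSE]
  DAB <- D[ia, ib, drop = FALSE]
  nb <- length(ib)
  correct <- 0
  for (p in seq_along(ia)) {
    cs <- sort.int(DAB[p, ])
    correct <- correct + sum(nb - findInterval(DA[p, ], cs))
  }
  correct - sum(DAB > 0)
}

# Uniform sampling over valid triples: class pair with probability
# proportional to its triple count, then uniform references and probe.
.dms_sampled <- function(coords, idx_by_class, pairs, triples, max_trials) {
  qs <- sample.int(ncol(pairs), max_trials, replace = TRUE, prob = triples)
  n_correct <- 0
  for (q in unique(qs)) {
    nt <- sum(qs == q)
    ia <- idx_by_class[[pairs[1L, q]]]
    ib <- idx_by_class[[pairs[2L, q]]]
    ra <- ia[sample.int(length(ia), nt, replace = TRUE)]
    rb <- ib[sample.int(length(ib), nt, replace = TRUE)]
    pool <- c(ia, ib)
    probe <- pool[sample.int(length(pool), nt, replace = TRUE)]
    clash <- probe == ra | probe == rb
    while (any(clash)) {
      probe[clash] <- pool[sample.int(length(pool), sum(clash), replace = TRUE)]
      clash <- probe == ra | probe == rb
    }
    probe_in_a <- probe %in% ia
    d_ra <- sqrt(rowSums((coords[probe, , drop = FALSE] - coords[ra, , drop = FALSE])^2))
    d_rb <- sqrt(rowSums((coords[probe, , drop = FALSE] - coords[rb, , drop = FALSE])^2))
    d_same <- ifelse(probe_in_a, d_ra, d_rb)
    d_other <- ifelse(probe_in_a, d_rb, d_ra)
    n_correct <- n_correct + sum(d_same < d_other)
  }
  list(n_correct = n_correct, n_trials = max_trials)
}
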