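## Orchestration: stratified subsampling, one train:test condition at one grid
## point, grid sweeps with the omission rule, and the full study protocol.

#' Sweep grids for the transfer experiment
#'
#' @param components Vector of PCA component counts (strictly increasing).
#' @param faces_invariant,faces_expression Face-sample counts per dataset.
#' @param base_seed Seed from which every grid point derives its own stream.
#' @return A `sweep_config` list.
#' @export
sweep_config <- function(components = seq(6L, 42L, by = 2L),
                         faces_invariant = seq(20L, 120L, by = 10L),
                         faces_expression = seq(20L, 160L, by = 10L),
                         base_seed = 1L) {
  stopifnot(all(diff(components) > 0), all(diff(faces_invariant) > 0),
            all(diff(faces_expression) > 0))
  structure(list(components = as.integer(components),
                 faces_invariant = as.integer(faces_invariant),
                 faces_expression = as.integer(faces_expression),
                 base_seed = as.integer(base_seed)),
            class = "sweep_config")
}

# How many training classes a generic stratified subsample of n_faces holds.
# Every retained class needs at least `min_per_class` samples so that a 50/50
# split leaves >= 2 per class on both sides.
.plan_n_classes <- function(n_classes_avail, n_faces, min_per_class = 4L) {
  min(n_classes_avail, max(2L, n_faces %/% min_per_class))
}

# Both study databases are factorial: identity x replicate, where the
# replicate factor is viewpoint (invariant database) or expression
# (expression database). Detect that structure.
.dataset_design <- function(labels) {
  rep_col <- if (dplyr::n_distinct(labels$expression) > 1L) "expression" else "viewpoint"
  reps <- unique(labels[[rep_col]])
  counts <- table(labels$identity)
  ids <- dplyr::distinct(labels, .data$identity, .data$sex, .data$race)
  list(rep_col = rep_col, n_rep = length(reps), ids = ids,
       factorial = length(counts) * length(reps) == nrow(labels) &&
         all(counts == length(reps)))
}

.planned_n_id <- function(design, n_faces) {
  max(2L, min(nrow(design$ids), as.integer(round(n_faces / design$n_rep))))
}

# Number of training classes a subsample of n_faces will produce; used to fix
# the common projected dimensionality across a grid point's conditions.
.planned_class_count <- function(labels, property, n_faces) {
  design <- .dataset_design(labels)
  if (!design$factorial) {
    return(.plan_n_classes(dplyr::n_distinct(labels[[property]]), n_faces))
  }
  if (property == "identity") .planned_n_id(design, n_faces)
  else dplyr::n_distinct(labels[[property]])
}

#' Plan a stratified subsample with a 50/50 train/test split
#'
#' For the factorial study databases (identity crossed with viewpoint or
#' expression), the subsample keeps the design intact: it draws identities —
#' evenly across the sex x race cells, so group composition does not
#' fluctuate between grid points — and takes all their replicate images,
#' sizing the identity count so the total is close to `n_faces`. Non-factorial
#' face sets fall back to per-class stratified sampling over the training
#' property. The split is 50/50, stratified by the training property's
#' classes.
#'
#' @param labels Label table of the face set.
#' @param property Training property.
#' @param n_faces Target subsample size.
#' @param seed Integer seed.
#' @param min_per_class Minimum class size retained in the fallback path.
#' @return List with integer row indices `train` and `test`, and the retained
#'   training `classes`.
#' @export
plan_subsample <- function(labels, property, n_faces, seed, min_per_class = 4L) {
  vals <- as.character(labels[[property]])
  design <- .dataset_design(labels)
  if (design$factorial) {
    n_id <- .planned_n_id(design, n_faces)
    rows <- with_seed(seed, {
      cells <- split(design$ids$identity,
                     paste(design$ids$sex, design$ids$race))
      cells <- cells[order(vapply(cells, length, integer(1)))]
      chosen <- character(0)
      left <- n_id
      for (ci in seq_along(cells)) {
        take <- min(length(cells[[ci]]), ceiling(left / (length(cells) - ci + 1L)))
        chosen <- c(chosen, sample(cells[[ci]], take))
        left <- left - take
      }
      which(labels$identity %in% chosen)
    })
  } else {
    avail <- table(vals)
    eligible <- names(avail)[avail >= min_per_class]
    if (length(eligible) < 2L) {
      abort(paste0("fewer than 2 classes of '", property, "' have >= ",
                   min_per_class, " samples"))
    }
    n_cls <- .plan_n_classes(length(eligible), n_faces, min_per_class)
    rows <- with_seed(seed, {
      chosen <- sample(eligible, n_cls)
      quota <- rep(n_faces %/% n_cls, n_cls)
      extra <- n_faces %% n_cls
      if (extra > 0L) quota[seq_len(extra)] <- quota[seq_len(extra)] + 1L
      quota <- pmin(quota, as.vector(avail[chosen]))
      unlist(lapply(seq_along(chosen), function(ci) {
        sample(which(vals == chosen[ci]), quota[ci])
      }))
    })
  }
  cls <- vals[rows]
  if (dplyr::n_distinct(cls) < 2L) {
    abort(paste0("subsample holds fewer than 2 classes of '", property, "'"))
  }
  # 50/50 split stratified by training class. Within a class the rows are
  # ordered by the replicate factor (viewpoint angle / expression category)
  # and assigned alternately from a seeded phase, so both halves span the
  # replicate levels instead of leaving the within-class scatter estimate at
  # the mercy of an unlucky draw.
  rep_vals <- labels[[.dataset_design(labels)$rep_col]]
  with_seed(derive_seed(seed, 71L), {
    train <- integer(0)
    test <- integer(0)
    for (cv in unique(cls)) {
      r <- rows[cls == cv]
      r <- r[order(rep_vals[r], sample.int(length(r)))]
      phase <- sample.int(2L, 1L)
      to_train <- (seq_along(r) + phase) %% 2L == 0L
      if (sum(to_train) < 2L || sum(!to_train) < 2L) {
        to_train <- seq_along(r) <= length(r) %/% 2L
      }
      train <- c(train, r[to_train])
      test <- c(test, r[!to_train])
    }
    list(train = sort(train), test = sort(test), classes = unique(cls))
  })
}

.omitted_row <- function(dataset, train_property, test_property, n_components,
                         n_faces, seed, reason) {
  tibble(dataset = dataset,
         condition = condition_label(train_property, test_property),
         train_property = train_property, test_property = test_property,
         n_components = as.integer(n_components), n_faces = as.integer(n_faces),
         seed = as.integer(seed), omitted = TRUE, omit_reason = reason,
         mode = NA_character_, n_trials = NA_real_,
         percent_correct = NA_real_, ks_D = NA_real_, ks_p = NA_real_,
         n_train_classes = NA_integer_, n_eval_dropped = NA_integer_)
}

#' Run one trained subspace against its test properties at one grid point
#'
#' The full per-cell protocol: stratified subsample of `n_faces` samples over
#' the training property with a seeded 50/50 class-stratified train/test
#' split; Eigenface PCA (`n_components`) on the subsample; Fisher fit on the
#' training half's labels; optional orthogonal padding to `target_dim`;
#' projection of the held-out half. The same trained projection is then
#' relabelled to each entry of `test_property` in turn and scored with the
#' DMS estimator plus the within/between distance summary — training on
#' identity and testing on identity, sex and race are one trained system,
#' three evaluations. Grid points where the face count cannot support the
#' component count (`n_faces <= n_components`) are returned as omitted rows,
#' not errors.
#'
#' @param faceset A [face_set()] carrying the properties' labels.
#' @param train_property Facial property trained on (identity, sex, race,
#'   expression).
#' @param test_property Character vector of properties to evaluate.
#' @param n_components PCA components.
#' @param n_faces Face samples to draw (capped at availability).
#' @param seed Integer seed for this cell.
#' @param target_dim Optional common projected dimensionality (pads with
#'   random orthogonal directions up to it).
#' @param dataset Dataset tag recorded in the rows.
#' @param ridge,normalization Passed to [fit_lfd()].
#' @param max_trials DMS trial cap (see [dms_performance()]).
#' @param keep_projection Also return the projected held-out set.
#' @return List with `result` (one row per test property), `distances`
#'   (named list of [class_distance_summary()] objects) and `projection`
#'   (or NULL).
#' @export
run_condition <- function(faceset, train_property, test_property,
                          n_components, n_faces, seed = 1L, target_dim = NULL,
                          dataset = "dataset", ridge = 1e-8,
                          normalization = "sw", max_trials = 1e5,
                          keep_projection = FALSE) {
  stopifnot(inherits(faceset, "face_set"))
  for (p in c(train_property, test_property)) property_code(p)
  n_faces <- min(as.integer(n_faces), n_faces(faceset))

  if (n_faces <= n_components) {
    reason <- if (n_faces < n_components) "n_faces < n_components" else
      "covariance rank < n_components"
    rows <- dplyr::bind_rows(lapply(test_property, function(tp) {
      .omitted_row(dataset, train_property, tp, n_components, n_faces, seed, reason)
    }))
    return(list(result = rows, distances = NULL, projection = NULL))
  }

  plan <- plan_subsample(faceset$labels, train_property, n_faces,
                         derive_seed(seed, 11L))
  sub <- c(plan$train, plan$test)
  n_actual <- length(sub)
  sub_images <- faceset$images[sub, , drop = FALSE]
  pca <- fit_pca(sub_images, n_components)
  coords <- project_pca(pca, sub_images)
  is_train <- seq_len(n_actual) <= length(plan$train)

  model <- fit_lfd(coords[is_train, , drop = FALSE],
                   faceset$labels[[train_property]][plan$train],
                   ridge = ridge, normalization = normalization,
                   property = train_property)
  if (!is.null(target_dim)) {
    model <- pad_orthogonal(model, min(as.integer(target_dim), model$k),
                            seed = derive_seed(seed, 13L))
  }

  pset <- project_fisher(model, coords[!is_train, , drop = FALSE],
                         faceset$labels[plan$test, , drop = FALSE])

  rows <- list()
  distances <- list()
  for (tp in test_property) {
    eval_set <- relabel(pset, tp)
    n_eval_dropped <- 0L
    perf <- withCallingHandlers(
      dms_performance(eval_set, mode = "auto", max_trials = max_trials,
                      seed = derive_seed(seed, 17L, match(tp, test_property))),
      facetransfer_dropped_classes = function(w) {
        n_eval_dropped <<- n_eval_dropped + 1L
        rlang::cnd_muffle(w)
      })
    dsum <- class_distance_summary(eval_set)
    rows[[tp]] <- tibble(
      dataset = dataset,
      condition = condition_label(train_property, tp),
      train_property = train_property, test_property = tp,
      n_components = as.integer(n_components),
      n_faces = n_actual, seed = as.integer(seed),
      omitted = FALSE, omit_reason = NA_character_,
      mode = perf$mode, n_trials = perf$n_trials,
      percent_correct = perf$percent_correct,
      ks_D = dsum$ks_D, ks_p = dsum$ks_p,
      n_train_classes = length(plan$classes),
      n_eval_dropped = n_eval_dropped)
    distances[[tp]] <- dsum
  }
  list(result = dplyr::bind_rows(rows), distances = distances,
       projection = if (keep_projection) pset else NULL)
}

#' Sweep all conditions over the component x face-count grids
#'
#' One row per condition per grid point. At each grid point all conditions on
#' the same dataset are padded to a common projected dimensionality (the
#' maximum discriminant count any of them attains there, capped at the PCA
#' dimension) so Euclidean distances are comparable across class counts.
#' Rows violating the omission rule are emitted as `omitted = TRUE`.
#'
#' @param datasets Named list of [face_set()]s.
#' @param conditions Tibble with columns `dataset`, `train_property`,
#'   `test_property`.
#' @param config A [sweep_config()].
#' @param ... Passed on to [run_condition()].
#' @return Results tibble (one row per condition x grid point).
#' @export
run_sweep <- function(datasets, conditions, config = sweep_config(), ...) {
  stopifnot(inherits(config, "sweep_config"))
  conditions <- as_tibble(conditions)
  rows <- list()
  for (ds_name in unique(conditions$dataset)) {
    faceset <- datasets[[ds_name]]
    if (is.null(faceset)) abort(paste0("dataset '", ds_name, "' not supplied"))
    conds <- dplyr::filter(conditions, .data$dataset == ds_name)
    faces_grid <- if (grepl("expr", ds_name)) config$faces_expression else config$faces_invariant
    ds_idx <- match(ds_name, unique(conditions$dataset))
    train_props <- unique(conds$train_property)
    for (i in seq_along(config$components)) {
      k <- config$components[i]
      for (j in seq_along(faces_grid)) {
        nf <- min(faces_grid[j], n_faces(faceset))
        # common projected dimensionality across this grid point's conditions
        m_per_train <- vapply(train_props, function(pr) {
          min(.planned_class_count(faceset$labels, pr, nf) - 1L, k)
        }, integer(1))
        target_dim <- min(max(m_per_train), k)
        for (ti in seq_along(train_props)) {
          tests <- conds$test_property[conds$train_property == train_props[ti]]
          cell_seed <- derive_seed(config$base_seed, ds_idx, ti, i, j)
          res <- run_condition(faceset, train_props[ti], tests,
                               n_components = k, n_faces = faces_grid[j],
                               seed = cell_seed, target_dim = target_dim,
                               dataset = ds_name, ...)
          rows[[length(rows) + 1L]] <- res$result
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Default configuration of the full study protocol
#'
#' Desk-scale defaults: the two synthetic databases at their study sizes
#' (120 balanced identities x 5 viewpoints; 50 identities, half female, all
#' asian, x 6 expressions), reduced sweep grids (components 6/10/14, faces
#' 40/80/120), figure-scale runs at 10 components with 120 (invariant) and
#' 160 (expression) faces, and no morphology-expression coupling.
#'
#' @param seed Base seed.
#' @return Named list of protocol parameters.
#' @export
default_protocol_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    n_identities_invariant = 120L,
    n_identities_expression = 50L,
    kappa = 0,
    noise_sd = 0.02,
    effect_size = 2,
    expr_strength = 3,
    jitter_frac = 0.25,
    components = c(6L, 10L, 14L),
    faces_invariant = c(40L, 80L, 120L),
    faces_expression = c(40L, 80L, 120L),
    figure_components = 10L,
    figure_faces_invariant = 120L,
    figure_faces_expression = 160L,
    normalization = "sw",
    ridge = 1e-8,
    max_trials = 1e5,
    write_figures = FALSE)
}

#' Generate the two synthetic study databases
#'
#' @param config Protocol configuration (see [default_protocol_config()]).
#' @return Named list with `invariant` and `expression` [face_set()]s.
#' @export
study_datasets <- function(config = default_protocol_config()) {
  spec_inv <- attribute_spec(config$n_identities_invariant)
  bank_inv <- make_identity_bank(spec_inv, derive_seed(config$seed, 1L),
                                 effect_size = config$effect_size)
  invariant <- render_invariant_dataset(bank_inv, noise_sd = config$noise_sd,
                                        seed = derive_seed(config$seed, 2L))
  spec_exp <- attribute_spec(config$n_identities_expression, race_levels = "asian")
  bank_exp <- make_identity_bank(spec_exp, derive_seed(config$seed, 3L),
                                 effect_size = config$effect_size)
  expression <- render_expression_dataset(bank_exp, kappa = config$kappa,
                                          noise_sd = config$noise_sd,
                                          seed = derive_seed(config$seed, 4L),
                                          expr_strength = config$expr_strength,
                                          jitter_frac = config$jitter_frac)
  list(invariant = invariant, expression = expression)
}

#' Condition blocks of the study protocol
#'
#' ID:ID, SE:SE, RA:RA, ID:SE, ID:RA on the invariant database and EX:EX,
#' ID:EX, SE:EX, ID:ID, EX:ID, SE:SE, EX:SE on the expression database.
#'
#' @return Tibble with `dataset`, `train_property`, `test_property`.
#' @export
protocol_conditions <- function() {
  dplyr::bind_rows(
    tibble(dataset = "invariant",
           train_property = c("identity", "sex", "race", "identity", "identity"),
           test_property = c("identity", "sex", "race", "sex", "race")),
    tibble(dataset = "expression",
           train_property = c("expression", "identity", "sex", "identity",
                              "expression", "sex", "expression"),
           test_property = c("expression", "expression", "expression", "identity",
                             "identity", "sex", "sex")))
}

# The eight across-condition score comparisons reported by the protocol.
.protocol_comparisons <- function() {
  tibble(
    dataset = c(rep("invariant", 4L), rep("expression", 4L)),
    cond_a = c("ID:ID", "ID:ID", "SE:SE", "RA:RA", "EX:EX", "EX:EX", "ID:ID", "SE:SE"),
    cond_b = c("SE:SE", "RA:RA", "ID:SE", "ID:RA", "ID:EX", "SE:EX", "EX:ID", "EX:SE"))
}

#' Run the full cross-property transfer study
#'
#' Generates (or accepts) the two synthetic databases, sweeps every condition
#' block over the component/face grids with the omission rule, compares the
#' condition score sets with pooled two-sample t-tests, runs the figure-scale
#' conditions for the face-space projections and distance histograms, and
#' optionally writes `results.csv`, `stats.csv`, `ks_stats.csv`, `run.log`
#' and the figures under an output directory.
#'
#' @param config Protocol configuration list (missing entries filled from
#'   [default_protocol_config()]) or a path to a YAML file of the same shape.
#' @param output_dir Optional directory for CSV/figure/log output.
#' @param datasets Optional pre-generated dataset list (as from
#'   [study_datasets()]); by default generated from the config.
#' @return A `transfer_study` list: `results`, `stats`, `ks`, `projections`,
#'   `distances`, `config`.
#' @export
run_study_protocol <- function(config = NULL, output_dir = NULL, datasets = NULL) {
  if (is.character(config)) config <- read_config(config)
  config <- utils::modifyList(default_protocol_config(), config %||% list())
  datasets <- datasets %||% study_datasets(config)
  conditions <- protocol_conditions()

  cfg <- sweep_config(components = config$components,
                      faces_invariant = config$faces_invariant,
                      faces_expression = config$faces_expression,
                      base_seed = derive_seed(config$seed, 10L))
  results <- run_sweep(datasets, conditions, cfg,
                       ridge = config$ridge, normalization = config$normalization,
                       max_trials = config$max_trials)

  scores <- dplyr::filter(results, !.data$omitted)
  stats <- purrr::pmap_dfr(.protocol_comparisons(), function(dataset, cond_a, cond_b) {
    a <- scores$percent_correct[scores$dataset == dataset & scores$condition == cond_a]
    b <- scores$percent_correct[scores$dataset == dataset & scores$condition == cond_b]
    tt <- compare_conditions_ttest(a, b)
    tibble(dataset = dataset, comparison = paste(cond_a, "vs", cond_b),
           mean_a = mean(a), mean_b = mean(b), t = tt$t, df = tt$df, p = tt$p)
  })

  # figure-scale runs: fixed component count and face count per dataset
  projections <- list()
  distances <- list()
  ks_rows <- list()
  # Figure-scale runs describe each condition's native subspace (projections
  # and distance histograms); padding is only needed where scores are compared
  # across class counts, i.e. in the sweep above.
  fig_k <- config$figure_components
  fig_groups <- dplyr::summarise(
    dplyr::group_by(conditions, .data$dataset, .data$train_property),
    tests = list(.data$test_property), .groups = "drop")
  for (gi in seq_len(nrow(fig_groups))) {
    ds_name <- fig_groups$dataset[gi]
    nf <- if (ds_name == "expression") config$figure_faces_expression else config$figure_faces_invariant
    nf <- min(nf, n_faces(datasets[[ds_name]]))
    res <- run_condition(datasets[[ds_name]],
                         fig_groups$train_property[gi], fig_groups$tests[[gi]],
                         n_components = fig_k, n_faces = nf,
                         seed = derive_seed(config$seed, 20L, gi),
                         dataset = ds_name, ridge = config$ridge,
                         normalization = config$normalization,
                         max_trials = config$max_trials, keep_projection = TRUE)
    for (ri in seq_len(nrow(res$result))) {
      row <- res$result[ri, ]
      key <- paste0(ds_name, ".", row$condition)
      projections[[key]] <- relabel(res$projection, row$test_property)
      distances[[key]] <- res$distances[[row$test_property]]
      ks_rows[[key]] <- tibble(dataset = ds_name, condition = row$condition,
                               n_components = fig_k, n_faces = row$n_faces,
                               percent_correct = row$percent_correct,
                               ks_D = row$ks_D, ks_p = row$ks_p)
    }
  }
  ks <- dplyr::bind_rows(ks_rows)

  study <- structure(
    list(results = results, stats = stats, ks = ks,
         projections = projections, distances = distances, config = config),
    class = "transfer_study")

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_results(results, file.path(output_dir, "results.csv"))
    readr::write_csv(stats, file.path(output_dir, "stats.csv"))
    readr::write_csv(ks, file.path(output_dir, "ks_stats.csv"))
    log_lines <- c(
      paste0("facetransfer study protocol, base seed ", config$seed),
      paste0("components grid: ", paste(config$components, collapse = ", ")),
      paste0("faces grid (invariant): ", paste(config$faces_invariant, collapse = ", ")),
      paste0("faces grid (expression): ", paste(config$faces_expression, collapse = ", ")),
      paste0("rows: ", nrow(results), " (", sum(results$omitted), " omitted)"))
    writeLines(log_lines, file.path(output_dir, "run.log"))
    if (isTRUE(config$write_figures)) {
      write_figures(study, file.path(output_dir, "figures"))
    }
  }
  study
}

#' @export
print.transfer_study <- function(x, ...) {
  cat("<transfer_study> ", nrow(x$results), " sweep rows (",
      sum(x$results$omitted), " omitted), ", nrow(x$stats),
      " comparisons, ", length(x$projections), " figure-scale projections\n", sep = "")
  means <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(x$results, !.data$omitted),
                    .data$dataset, .data$condition),
    mean_pct = mean(.data$percent_correct), .groups = "drop")
  print(as.data.frame(means), digits = 4)
  invisible(x)
}
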