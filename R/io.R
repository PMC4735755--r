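## Readers/writers: image+label dataset layout, results tables, model
## containers (JSON) and YAML configuration.

.LABEL_COL_TYPES <- readr::cols(
  sample_id = readr::col_character(), identity = readr::col_character(),
  sex = readr::col_character(), race = readr::col_character(),
  expression = readr::col_character(), viewpoint = readr::col_double())

#' Write a face set as PNG files plus labels.csv
#'
#' One 8-bit grayscale PNG per sample, named after its zero-padded
#' `sample_id`, and a `labels.csv` with header
#' `sample_id,identity,sex,race,expression,viewpoint`.
#'
#' @param faceset A [face_set()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_faceset <- function(faceset, dir) {
  stopifnot(inherits(faceset, "face_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(faceset$images))) {
    img <- vector_to_image(faceset$images[i, ], faceset$width, faceset$height)
    png::writePNG(img, file.path(dir, paste0(faceset$labels$sample_id[i], ".png")))
  }
  readr::write_csv(faceset$labels, file.path(dir, "labels.csv"))
  invisible(dir)
}

#' Load a face set from a PNG + labels.csv directory
#'
#' Images are decoded to `[0, 1]` intensities in the row order of
#' `labels.csv`. Malformed datasets are rejected, naming the offending
#' sample or column: missing image files, non-grayscale images, resolution
#' mismatches and missing label columns are all errors.
#'
#' @param dir Dataset directory.
#' @param width,height Required image resolution.
#' @param labels_file Name of the label table inside `dir`.
#' @return A [face_set()].
#' @export
load_faceset <- function(dir, width = 90L, height = 90L, labels_file = "labels.csv") {
  path <- file.path(dir, labels_file)
  if (!file.exists(path)) abort(paste0("label file not found: ", path))
  labels <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(.REQUIRED_LABELS, names(labels))
  if (length(missing)) {
    abort(paste0("labels.csv is missing column(s): ", paste(missing, collapse = ", ")))
  }
  labels$viewpoint <- as.double(labels$viewpoint)
  images <- matrix(0, nrow(labels), width * height)
  for (i in seq_len(nrow(labels))) {
    f <- file.path(dir, paste0(labels$sample_id[i], ".png"))
    if (!file.exists(f)) {
      abort(paste0("no image file for sample_id '", labels$sample_id[i], "'"))
    }
    img <- png::readPNG(f)
    if (length(dim(img)) != 2L) {
      abort(paste0("image for sample_id '", labels$sample_id[i],
                   "' is not single-channel grayscale"))
    }
    if (nrow(img) != height || ncol(img) != width) {
      abort(paste0("image for sample_id '", labels$sample_id[i], "' is ",
                   nrow(img), "x", ncol(img), ", expected ", height, "x", width))
    }
    images[i, ] <- image_to_vector(img)
  }
  face_set(images, labels, width, height)
}

.RESULT_INT_COLS <- c("n_components", "n_faces", "seed", "n_train_classes",
                      "n_eval_dropped")
.RESULT_DBL_COLS <- c("n_trials", "percent_correct", "ks_D", "ks_p")

#' Write / read a sweep results table
#'
#' Comma-separated, UTF-8, `.` decimal, mandatory header; numeric fields
#' round-trip at full precision.
#'
#' @param results Results tibble from [run_sweep()].
#' @param path CSV path.
#' @return `path` invisibly for the writer; the results tibble for the
#'   reader.
#' @export
write_results <- function(results, path) {
  # doubles rendered at 17 significant digits so the round trip is exact
  out <- dplyr::mutate(as_tibble(results), dplyr::across(
    dplyr::where(is.double),
    ~ ifelse(is.na(.x), NA_character_, sprintf("%.17g", .x))))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) abort(paste0("results file not found: ", path))
  out <- readr::read_csv(path,
                         col_types = readr::cols(.default = readr::col_character()))
  probs <- readr::problems(out)
  if (nrow(probs) > 0L) {
    abort(paste0("malformed results CSV at line(s) ",
                 paste(unique(probs$row), collapse = ", ")))
  }
  # numeric conversion through strtod, so %.17g values round-trip exactly
  convert <- function(col, fun, what) {
    bad <- which(!is.na(col) & is.na(suppressWarnings(fun(col))))
    if (length(bad)) {
      abort(paste0("malformed ", what, " in results CSV at line(s) ",
                   paste(bad + 1L, collapse = ", ")))
    }
    fun(col)
  }
  for (cc in intersect(.RESULT_INT_COLS, names(out))) {
    out[[cc]] <- convert(out[[cc]], as.integer, "integer")
  }
  for (cc in intersect(.RESULT_DBL_COLS, names(out))) {
    out[[cc]] <- convert(out[[cc]], as.double, "number")
  }
  if ("omitted" %in% names(out)) out$omitted <- as.logical(out$omitted)
  out
}

#' Serialize a subspace model to JSON
#'
#' Stores every matrix at full double precision together with the metadata
#' (trained property, ridge, normalization, dimensions); [read_model()]
#' reconstructs the model object.
#'
#' @param model An `eigen_model` or `fisher_model`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "eigen_model")) {
    payload <- list(type = "eigen_model", mean_face = model$mean_face,
                    components = model$components, eigenvalues = model$eigenvalues,
                    n_samples = model$n_samples)
  } else if (inherits(model, "fisher_model")) {
    payload <- list(type = "fisher_model", directions = model$directions,
                    padding = model$padding, eigenvalues = model$eigenvalues,
                    trained_property = model$trained_property,
                    class_labels = model$class_labels, ridge = model$ridge,
                    normalization = model$normalization, sw = model$sw,
                    k = model$k)
  } else {
    abort("model must be an eigen_model or fisher_model")
  }
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) abort(paste0("model file not found: ", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(m) {
    if (is.null(m) || length(m) == 0L) return(matrix(0, x$k %||% 0L, 0L))
    as.matrix(m)
  }
  if (identical(x$type, "eigen_model")) {
    structure(list(mean_face = as.numeric(x$mean_face),
                   components = as_mat(x$components),
                   eigenvalues = as.numeric(x$eigenvalues),
                   n_samples = as.integer(x$n_samples)),
              class = "eigen_model")
  } else if (identical(x$type, "fisher_model")) {
    structure(list(directions = as_mat(x$directions),
                   padding = as_mat(x$padding),
                   eigenvalues = as.numeric(x$eigenvalues),
                   trained_property = x$trained_property,
                   class_labels = as.character(x$class_labels),
                   ridge = as.numeric(x$ridge),
                   normalization = x$normalization,
                   sw = if (is.null(x$sw)) NULL else as.matrix(x$sw),
                   k = as.integer(x$k)),
              class = "fisher_model")
  } else {
    abort(paste0("unknown model type in ", path))
  }
}

#' Read a protocol configuration from YAML
#'
#' Fields mirror [default_protocol_config()]; missing entries keep their
#' defaults.
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  utils::modifyList(default_protocol_config(), yaml::read_yaml(path))
}
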