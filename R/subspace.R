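## Eigenface PCA preprocessing and multi-class Fisher discriminant subspaces.

#' Vectorize a face set and subtract the mean face
#'
#' Each image becomes one row-major pixel vector; the global mean face is
#' subtracted from every vector and returned alongside.
#'
#' @param faceset A [face_set()] (or a plain sample-by-pixel matrix).
#' @return List with `matrix` (centered `n x p`) and `mean_face` (`p` vector).
#' @export
vectorize_and_center <- function(faceset) {
  X <- if (inherits(faceset, "face_set")) faceset$images else as.matrix(faceset)
  if (nrow(X) == 0L) abort("face set is empty")
  mean_face <- colMeans(X)
  list(matrix = sweep(X, 2L, mean_face), mean_face = mean_face)
}

#' Fit the Eigenface principal-component model
#'
#' Top eigenvectors of the sample covariance of the centered image vectors
#' (via SVD), unit norm, eigenvalues non-increasing, with a deterministic sign
#' convention (largest-magnitude loading positive).
#'
#' @param faceset A [face_set()] or sample-by-pixel matrix.
#' @param n_components Number of components to retain; must be at most
#'   `n_samples - 1` (the rank bound of the centered covariance).
#' @return An `eigen_model` with `mean_face`, `components` (`k x p` orthonormal
#'   rows) and `eigenvalues`.
#' @export
fit_pca <- function(faceset, n_components) {
  ctr <- vectorize_and_center(faceset)
  n <- nrow(ctr$matrix)
  k <- as.integer(n_components)
  if (k < 1L) abort("n_components must be >= 1")
  if (k > n - 1L) {
    abort(paste0("n_components (", k, ") exceeds n_samples - 1 (", n - 1L,
                 "); the centered covariance has at most rank n - 1"))
  }
  sv <- svd(ctr$matrix, nu = 0, nv = k)
  eigenvalues <- (sv$d^2 / (n - 1))[seq_len(k)]
  components <- fix_signs(sv$v[, seq_len(k), drop = FALSE])
  structure(
    list(mean_face = ctr$mean_face,
         components = t(components),          # k x p, orthonormal rows
         eigenvalues = eigenvalues,
         n_samples = n),
    class = "eigen_model")
}

#' @export
print.eigen_model <- function(x, ...) {
  cat("<eigen_model> ", nrow(x$components), " components over ",
      ncol(x$components), " pixels (", x$n_samples, " training samples)\n", sep = "")
  invisible(x)
}

#' Project faces onto the Eigenface components
#'
#' @param model An [fit_pca()] model.
#' @param faceset A [face_set()] or sample-by-pixel matrix with matching
#'   resolution.
#' @return `n x k` coordinate matrix in PCA space.
#' @export
project_pca <- function(model, faceset) {
  stopifnot(inherits(model, "eigen_model"))
  X <- if (inherits(faceset, "face_set")) faceset$images else as.matrix(faceset)
  if (ncol(X) != length(model$mean_face)) {
    abort(paste0("images have ", ncol(X), " pixels but the model was fitted on ",
                 length(model$mean_face)))
  }
  sweep(X, 2L, model$mean_face) %*% t(model$components)
}

#' Fit the multi-class Fisher discriminant in PCA space
#'
#' Builds the between-class scatter `S_B` (class means weighted by class
#' size) and the pooled within-class scatter `S_W` (plus a relative ridge on
#' its diagonal), then solves the generalized eigenproblem `S_B v = lambda S_W v`
#' by within-class whitening. At most `C - 1` informative directions exist for
#' `C` classes; `n_discriminants` is capped at `min(C - 1, k)`.
#'
#' Direction scaling is controlled by `normalization`:
#' * `"sw"` (default): directions satisfy `v' S_W v = 1`, the native scaling of
#'   a generalized eigensolver. Euclidean distances between projections are
#'   then within-class-whitened distances — directions along which the
#'   training classes vary internally are shrunk. This is the geometry the
#'   distance-based transfer readout relies on.
#' * `"euclidean"`: the directions are re-orthonormalized (QR) so the
#'   projection is an isometry of their span.
#'
#' @param coords `n x k` PCA coordinates.
#' @param labels Class label per row (>= 2 classes, each with >= 2 samples).
#' @param n_discriminants Requested number of directions (default `C - 1`).
#' @param ridge Relative ridge added to `S_W` as `ridge * trace(S_W)/k` on the
#'   diagonal.
#' @param normalization `"sw"` or `"euclidean"` (see Details).
#' @param property Optional name of the trained facial property, recorded in
#'   the model.
#' @return A `fisher_model` with `directions` (`k x m` columns), empty
#'   `padding`, generalized `eigenvalues`, class labels and metadata.
#' @export
fit_lfd <- function(coords, labels, n_discriminants = NULL, ridge = 1e-8,
                    normalization = c("sw", "euclidean"), property = NULL) {
  normalization <- match.arg(normalization)
  coords <- as.matrix(coords)
  k <- ncol(coords)
  if (k < 1L) abort("coords must have at least one column")
  labels <- as.character(labels)
  if (length(labels) != nrow(coords)) abort("labels must match rows of coords")
  counts <- table(labels)
  C <- length(counts)
  if (C < 2L) abort("all labels identical: need at least 2 classes")
  if (any(counts < 2L)) {
    abort(paste0("class(es) with fewer than 2 samples: ",
                 paste(names(counts)[counts < 2L], collapse = ", ")))
  }

  mu <- colMeans(coords)
  class_means <- rowsum(coords, labels) / as.vector(counts)
  dm <- sweep(class_means, 2L, mu)
  Sb <- crossprod(dm * sqrt(as.vector(counts)))          # sum_c n_c (mu_c-mu)(mu_c-mu)'
  resid <- coords - class_means[labels, , drop = FALSE]
  Sw <- crossprod(resid)

  lam <- ridge * sum(diag(Sw)) / k
  if (lam <= 0) lam <- ridge
  Swr <- Sw + diag(lam, k)

  # Whiten S_W on its numerical range only. With few samples per class the
  # within-class scatter is rank deficient (rank <= n - C); its null-space
  # directions separate the training classes perfectly but carry no
  # generalizable structure, so they are excluded from the solve rather than
  # amplified by 1/ridge.
  Wh <- .sw_whitener(Swr)
  A <- crossprod(Wh, Sb %*% Wh)
  A <- (A + t(A)) / 2
  eig <- eigen(A, symmetric = TRUE)

  m <- min(n_discriminants %||% (C - 1L), C - 1L, k, ncol(Wh))
  dirs <- Wh %*% eig$vectors[, seq_len(m), drop = FALSE]  # v' Swr v = I
  if (normalization == "euclidean") {
    qrd <- qr(dirs)
    Q <- qr.Q(qrd)
    # keep orientation stable: positive diagonal of R factor
    dsign <- sign(diag(qr.R(qrd)))
    dsign[dsign == 0] <- 1
    dirs <- sweep(Q, 2L, dsign, `*`)
  }
  dirs <- fix_signs(dirs)

  structure(
    list(directions = dirs,
         padding = matrix(0, k, 0L),
         eigenvalues = pmax(eig$values[seq_len(m)], 0),
         trained_property = property,
         class_labels = names(counts),
         ridge = ridge,
         normalization = normalization,
         sw = Swr,
         k = k),
    class = "fisher_model")
}

# Truncated inverse square root of a symmetric PSD matrix: columns span its
# numerical range (relative eigenvalue tolerance) and whiten it to identity.
.sw_whitener <- function(S, tol = 1e-6) {
  es <- eigen(S, symmetric = TRUE)
  keep <- es$values > tol * es$values[1]
  es$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(es$values[keep]), sum(keep))
}

#' @export
print.fisher_model <- function(x, ...) {
  cat("<fisher_model> ", ncol(x$directions), " discriminant + ",
      ncol(x$padding), " padded direction(s) in ", x$k, "-dim PCA space",
      if (!is.null(x$trained_property)) paste0(" [trained on ", x$trained_property, "]"),
      "\n", sep = "")
  invisible(x)
}

#' Number of discriminant directions of a Fisher model
#' @param model A [fit_lfd()] model.
#' @return Integer count (excluding padding).
#' @export
n_discriminants <- function(model) ncol(model$directions)

#' Pad a Fisher subspace with random orthogonal directions
#'
#' Subspaces trained on different class counts have different intrinsic
#' dimensionality (`C - 1` cap); to compare Euclidean distances across them,
#' class-uninformative random directions are appended until `target_dim`.
#' Padding directions are drawn i.i.d. normal in PCA space and
#' orthonormalized — against the discriminant directions and against each
#' other — in the metric the model projects with: the within-class (`S_W`)
#' metric for `normalization = "sw"` (every padded axis then has unit
#' within-training-class variance, like the discriminant axes), the Euclidean
#' metric for `normalization = "euclidean"` (Gram matrix of all rows is the
#' identity). Deterministic given `seed`; any previous padding is replaced.
#'
#' @param model A [fit_lfd()] model.
#' @param target_dim Total dimension wanted (`m <= target_dim <= k`).
#' @param seed Integer seed.
#' @return The model with `padding` set to a `k x (target_dim - m)` matrix.
#' @export
pad_orthogonal <- function(model, target_dim, seed = 1L) {
  stopifnot(inherits(model, "fisher_model"))
  m <- ncol(model$directions)
  target_dim <- as.integer(target_dim)
  if (target_dim > model$k) {
    abort(paste0("target_dim (", target_dim, ") exceeds the PCA dimensionality k = ",
                 model$k))
  }
  if (target_dim < m) {
    abort(paste0("target_dim (", target_dim, ") is below the number of discriminant ",
                 "directions m = ", m))
  }
  p <- target_dim - m
  if (p == 0L) {
    model$padding <- matrix(0, model$k, 0L)
    return(model)
  }
  if (model$normalization == "sw" && !is.null(model$sw)) {
    # Gram-Schmidt in the S_W inner product, in whitened coordinates on the
    # numerical range of S_W (the discriminants are already orthonormal
    # there). Padding cannot exceed that range; p is capped at its dimension.
    Wh <- .sw_whitener(model$sw)
    r <- ncol(Wh)
    p <- min(p, r - m)
    if (p <= 0L) {
      model$padding <- matrix(0, model$k, 0L)
      return(model)
    }
    rnd <- with_seed(seed, matrix(rnorm(r * p), r, p))
    Yf <- crossprod(Wh, model$sw %*% model$directions)  # whitened images, orthonormal
    rnd <- rnd - Yf %*% (t(Yf) %*% rnd)
    rnd <- qr.Q(qr(rnd))[, seq_len(p), drop = FALSE]
    pad <- Wh %*% rnd
  } else {
    rnd <- with_seed(seed, matrix(rnorm(model$k * p), model$k, p))
    Qf <- qr.Q(qr(model$directions))
    pad <- rnd - Qf %*% (t(Qf) %*% rnd)
    pad <- qr.Q(qr(pad))[, seq_len(p), drop = FALSE]
  }
  model$padding <- fix_signs(pad)
  model
}

#' Project PCA coordinates into the (padded) Fisher subspace
#'
#' @param model A [fit_lfd()] model, possibly after [pad_orthogonal()].
#' @param coords `n x k` PCA coordinates.
#' @param labels Optional label table (or vector) for the projected samples;
#'   needed downstream by [relabel()] and the distance summaries.
#' @return A `projected_set`: coordinates in the `m + p` dimensional space,
#'   the label table, and the evaluation labelling (initially the trained
#'   property).
#' @export
project_fisher <- function(model, coords, labels = NULL) {
  stopifnot(inherits(model, "fisher_model"))
  coords <- as.matrix(coords)
  if (ncol(coords) != model$k) {
    abort(paste0("coords have ", ncol(coords), " columns but the model lives in k = ",
                 model$k, " dimensions"))
  }
  W <- cbind(model$directions, model$padding)
  prop <- model$trained_property
  if (is.null(labels)) {
    labels <- tibble(.rows = nrow(coords))
  } else if (!is.data.frame(labels)) {
    if (is.null(prop)) prop <- "class"
    labels <- tibble(!!prop := as.character(labels))
  } else {
    labels <- as_tibble(labels)
  }
  if (nrow(labels) != nrow(coords)) abort("labels must match rows of coords")
  projected_set(coords %*% W, labels, eval_property = prop,
                source_property = prop,
                n_discriminants = ncol(model$directions),
                n_padding = ncol(model$padding))
}

#' Construct a projected set directly
#'
#' Usually produced by [project_fisher()]; the constructor is exported so
#' that coordinate sets from other sources can be scored with the same
#' estimators.
#'
#' @param coordinates `n x d` coordinate matrix.
#' @param labels Label table (or vector, stored under `eval_property`).
#' @param eval_property Column of `labels` evaluated by default.
#' @param source_property Property the space was built from.
#' @param n_discriminants,n_padding Dimension bookkeeping.
#' @return A `projected_set`.
#' @export
projected_set <- function(coordinates, labels, eval_property,
                          source_property = eval_property,
                          n_discriminants = ncol(coordinates),
                          n_padding = 0L) {
  coordinates <- as.matrix(coordinates)
  if (!is.data.frame(labels)) {
    labels <- tibble(!!eval_property := as.character(labels))
  }
  labels <- as_tibble(labels)
  if (nrow(labels) != nrow(coordinates)) {
    abort("labels must have one row per coordinate row")
  }
  # an unlabelled set (no columns) is allowed; eval_labels() errors until
  # labels are supplied via relabel()
  if (ncol(labels) > 0L && !is.null(eval_property) &&
      !eval_property %in% names(labels)) {
    abort(paste0("eval_property '", eval_property, "' not in the label table"))
  }
  structure(
    list(coordinates = coordinates, labels = labels,
         eval_property = eval_property, source_property = source_property,
         n_discriminants = n_discriminants, n_padding = n_padding),
    class = "projected_set")
}

#' @export
print.projected_set <- function(x, ...) {
  cat("<projected_set> ", nrow(x$coordinates), " samples in ",
      ncol(x$coordinates), " dims (", x$n_discriminants, " discriminant + ",
      x$n_padding, " padded); trained on ", x$source_property %||% "<?>",
      ", evaluating ", x$eval_property %||% "<?>", "\n", sep = "")
  invisible(x)
}

#' Evaluation labels of a projected set
#' @param pset A [project_fisher()] result.
#' @return Character vector of labels for the property under evaluation.
#' @export
eval_labels <- function(pset) {
  stopifnot(inherits(pset, "projected_set"))
  prop <- pset$eval_property
  if (is.null(prop) || !prop %in% names(pset$labels)) {
    abort("projected set has no evaluation labelling; supply labels or relabel()")
  }
  as.character(pset$labels[[prop]])
}
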