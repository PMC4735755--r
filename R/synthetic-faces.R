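## Synthetic face-image generator.
##
## Faces are points in a structured latent space with three mutually orthogonal
## coordinate blocks:
##   M (morphology, 16 dims): stable per-identity shape, i.i.d. standard
##     normal on all 16 dims; dims 15 and 16 additionally carry the sex and
##     race group offsets (+/- effect_size on top of the unit within-cell
##     identity variation).
##   E (expression, 8 dims): per-image expression deformation (prototype per
##     expression category + jitter), optionally coupled to identity.
##   V (viewpoint, 2 dims): deterministic latent shift per camera angle.
## A fixed seeded smooth rendering basis maps latent codes linearly to 90x90
## pixel images; pixel noise, clipping to [0,1] and 8-bit quantization follow.

.M_DIM <- 16L
.M_FREE <- 14L   # identity dims; 15 = sex axis, 16 = race axis
.E_DIM <- 8L
.V_DIM <- 2L
.LATENT_DIM <- .M_DIM + .E_DIM + .V_DIM

.m_cols <- function() seq_len(.M_DIM)
.e_cols <- function() .M_DIM + seq_len(.E_DIM)
.v_cols <- function() .M_DIM + .E_DIM + seq_len(.V_DIM)

#' Describe the attribute structure of a synthetic face database
#'
#' Captures the composition that the generator must realise: how many
#' identities, which sex/race levels they are balanced over, which expression
#' categories exist and which viewpoints are rendered.
#'
#' @param n_identities Number of distinct identities (>= 2).
#' @param sex_levels Character vector of sex levels (default female/male).
#' @param race_levels Character vector of race levels; a single level gives a
#'   race-constant database.
#' @param expression_levels Ordered character vector of expression categories;
#'   `"neutral"` renders as the undeformed face.
#' @param viewpoints Numeric camera angles in degrees.
#' @return An `attribute_spec` object.
#' @examples
#' attribute_spec(120)                       # balanced 2 x 2, 30 per cell
#' attribute_spec(50, race_levels = "asian") # half female, race constant
#' @export
attribute_spec <- function(n_identities,
                           sex_levels = c("female", "male"),
                           race_levels = c("asian", "caucasian"),
                           expression_levels = c("neutral", "anger", "fear",
                                                 "happiness", "sadness", "surprise"),
                           viewpoints = c(-10, 0, 10, 20, 30)) {
  if (length(n_identities) != 1L || !is.finite(n_identities) || n_identities < 2) {
    abort("n_identities must be a single number >= 2")
  }
  if (length(sex_levels) == 0L || length(race_levels) == 0L) {
    abort("sex_levels and race_levels must be non-empty")
  }
  if (length(expression_levels) == 0L || length(expression_levels) > 6L) {
    abort("expression_levels must contain between 1 and 6 category names")
  }
  if (length(viewpoints) == 0L) abort("viewpoints must be non-empty")
  structure(
    list(n_identities = as.integer(n_identities),
         sex_levels = as.character(sex_levels),
         race_levels = as.character(race_levels),
         expression_levels = as.character(expression_levels),
         viewpoints = as.numeric(viewpoints)),
    class = "attribute_spec")
}

#' Draw the latent identity bank for a database
#'
#' One latent morphology code per identity. Identities are assigned to the
#' sex x race cells in exact balance; the identity code is i.i.d. standard
#' normal on every morphology dimension, and the sex/race group offsets are
#' fixed unit axes scaled by `effect_size` (sign by level) added on top, so
#' the offset magnitude is expressed in units of the within-cell identity
#' standard deviation.
#'
#' @param spec An [attribute_spec()].
#' @param seed Integer seed; the bank is deterministic given `(spec, seed)`.
#' @param effect_size Offset magnitude on the sex and race axes, in units of
#'   the within-cell identity standard deviation (default 2).
#' @return An `identity_bank`: identity table plus the `n x 16` morphology
#'   code matrix.
#' @export
make_identity_bank <- function(spec, seed, effect_size = 2) {
  stopifnot(inherits(spec, "attribute_spec"))
  cells <- tidyr::expand_grid(sex = spec$sex_levels, race = spec$race_levels)
  n_cells <- nrow(cells)
  if (spec$n_identities %% n_cells != 0L) {
    abort(paste0("n_identities (", spec$n_identities, ") is not divisible by the ",
                 n_cells, " sex x race balance cells (",
                 length(spec$sex_levels), " sex x ", length(spec$race_levels),
                 " race levels)"))
  }
  per_cell <- spec$n_identities %/% n_cells
  ids <- tibble(
    identity = sprintf("id%03d", seq_len(spec$n_identities)),
    sex = rep(cells$sex, each = per_cell),
    race = rep(cells$race, each = per_cell))

  codes <- with_seed(derive_seed(seed, 101L),
                     matrix(rnorm(spec$n_identities * .M_DIM),
                            spec$n_identities, .M_DIM))
  sgn <- function(level, levels) if (match(level, levels) == 1L) -1 else 1
  codes[, .M_FREE + 1L] <- codes[, .M_FREE + 1L] + effect_size *
    vapply(ids$sex, sgn, numeric(1), levels = spec$sex_levels)
  codes[, .M_FREE + 2L] <- codes[, .M_FREE + 2L] + effect_size *
    vapply(ids$race, sgn, numeric(1), levels = spec$race_levels)

  structure(
    list(spec = spec, ids = ids, codes = codes,
         effect_size = effect_size, seed = as.integer(seed)),
    class = "identity_bank")
}

#' @export
print.identity_bank <- function(x, ...) {
  cat("<identity_bank> ", nrow(x$ids), " identities (",
      paste(table(x$ids$sex, x$ids$race), collapse = "/"),
      " per sex x race cell)\n", sep = "")
  invisible(x)
}

#' Build the fixed smooth rendering basis
#'
#' Each latent dimension maps to a smooth pixel pattern built from seeded
#' differences of 2-D Gaussian bumps; the patterns are then orthonormalized
#' (QR), so the map is an isometry from latent space into pixel space (times
#' `gain`) and the latent covariance design carries over to the images
#' undistorted. Patterns are low spatial frequency, so the principal
#' components of rendered sets look like the smooth eigen-images familiar
#' from appearance-based face models. A fixed base face (broad central blob
#' on a mid-grey field) anchors the affine pixel range.
#'
#' @param seed Integer seed fixing the basis.
#' @param width,height Image resolution in pixels.
#' @param d Latent dimensionality (defaults to the generator's 26).
#' @param gain Scalar applied to the latent contribution before clipping.
#' @return A `face_basis` with the `(width*height) x d` matrix, base face and
#'   gain.
#' @export
render_basis <- function(seed, width = 90L, height = 90L, d = .LATENT_DIM,
                         gain = 0.5) {
  px_row <- rep(seq_len(height), each = width)   # row-major pixel order
  px_col <- rep(seq_len(width), times = height)
  B <- with_seed(derive_seed(seed, 202L), {
    vapply(seq_len(d), function(j) {
      cx <- runif(2, 0.12 * width, 0.88 * width)
      cy <- runif(2, 0.12 * height, 0.88 * height)
      sg <- runif(2, 0.07 * width, 0.16 * width)
      b <- exp(-((px_col - cx[1])^2 + (px_row - cy[1])^2) / (2 * sg[1]^2)) -
        exp(-((px_col - cx[2])^2 + (px_row - cy[2])^2) / (2 * sg[2]^2))
      b / sqrt(sum(b^2))
    }, numeric(width * height))
  })
  B <- fix_signs(qr.Q(qr(B)))
  base <- 0.35 + 0.3 * exp(-((px_col - (width + 1) / 2)^2 / (2 * (0.24 * width)^2) +
                               (px_row - 0.47 * height)^2 / (2 * (0.31 * height)^2)))
  structure(list(B = B, base = base, width = as.integer(width),
                 height = as.integer(height), d = as.integer(d), gain = gain,
                 seed = as.integer(seed)),
            class = "face_basis")
}

#' Render one latent code to an image
#'
#' Linear map of the concatenated latent blocks through the smooth basis,
#' added to the base face, then clipped to `[0, 1]`. The zero code renders the
#' base face exactly; before clipping, `code` and `-code` are symmetric about
#' it.
#'
#' @param code Numeric latent vector of the basis' dimensionality.
#' @param basis A [render_basis()] object.
#' @param clip Clip intensities into `[0, 1]` (default TRUE).
#' @return A `height x width` intensity matrix.
#' @export
latent_to_image <- function(code, basis, clip = TRUE) {
  stopifnot(inherits(basis, "face_basis"))
  if (length(code) != basis$d) {
    abort(paste0("latent code has length ", length(code),
                 " but the rendering basis expects ", basis$d))
  }
  px <- basis$base + basis$gain * as.vector(basis$B %*% code)
  if (clip) px <- pmin(pmax(px, 0), 1)
  vector_to_image(px, width = basis$width, height = basis$height)
}

## ---- face sets ------------------------------------------------------------

.REQUIRED_LABELS <- c("sample_id", "identity", "sex", "race", "expression", "viewpoint")

#' Bundle face images with their attribute labels
#'
#' The unit of all training and testing: an `n x (width*height)` matrix of
#' row-major vectorized grayscale intensities in `[0, 1]`, paired with a label
#' table carrying `sample_id`, `identity`, `sex`, `race`, `expression` and
#' `viewpoint` for every sample.
#'
#' @param images Numeric matrix, one row per sample.
#' @param labels Data frame with the six label columns, one row per image.
#' @param width,height Image resolution.
#' @return A `face_set` object.
#' @export
face_set <- function(images, labels, width = 90L, height = 90L) {
  images <- as.matrix(images)
  labels <- as_tibble(labels)
  missing <- setdiff(.REQUIRED_LABELS, names(labels))
  if (length(missing)) {
    abort(paste0("label table is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(labels) != nrow(images)) {
    abort(paste0("label table has ", nrow(labels), " rows but there are ",
                 nrow(images), " images"))
  }
  if (ncol(images) != width * height) {
    abort(paste0("images have ", ncol(images), " pixels but width*height = ",
                 width * height))
  }
  structure(list(images = images, labels = labels,
                 width = as.integer(width), height = as.integer(height)),
            class = "face_set")
}

#' @export
print.face_set <- function(x, ...) {
  cat("<face_set> ", nrow(x$images), " images (", x$width, "x", x$height, "), ",
      dplyr::n_distinct(x$labels$identity), " identities\n", sep = "")
  invisible(x)
}

#' Number of samples in a face set
#' @param faceset A [face_set()].
#' @return Integer count.
#' @export
n_faces <- function(faceset) nrow(faceset$images)

#' @describeIn face_set Row-major vectorization of one image matrix.
#' @param img Image matrix (rows = pixel rows).
#' @export
image_to_vector <- function(img) as.vector(t(img))

#' @describeIn face_set Inverse of [image_to_vector()].
#' @param v Pixel vector.
#' @export
vector_to_image <- function(v, width, height) {
  matrix(v, nrow = height, ncol = width, byrow = TRUE)
}

# Shared rendering tail: latent matrix -> face_set (noise, clip, quantize).
render_images <- function(Z, basis, noise_sd, seed, quantize) {
  px <- matrix(rep(basis$base, each = nrow(Z)), nrow = nrow(Z)) +
    basis$gain * (Z %*% t(basis$B))
  if (noise_sd > 0) {
    noise <- with_seed(seed, matrix(rnorm(length(px), sd = noise_sd), nrow = nrow(px)))
    px <- px + noise
  }
  px <- pmin(pmax(px, 0), 1)
  if (quantize) px <- round(px * 255) / 255
  px
}

#' Render the invariant-property database (identity x viewpoint)
#'
#' Emulates a multi-viewpoint identity database: one image per identity per
#' viewpoint, balanced over sex and race, expression constant (neutral).
#' Viewpoint is modelled as a deterministic latent shift, adding
#' within-identity variance without carrying class information used anywhere
#' in the analysis.
#'
#' @param bank An [make_identity_bank()] result.
#' @param viewpoints Angles in degrees (default: the bank's spec).
#' @param noise_sd Additive Gaussian pixel noise sd on the `[0,1]` scale.
#' @param seed Integer seed (noise stream and basis, if not supplied).
#' @param basis Optional fixed [render_basis()]; generated from `seed` if NULL.
#' @param vp_scale Scale of the viewpoint latent shift.
#' @param quantize Snap intensities to 8-bit levels (default TRUE).
#' @return A [face_set()] with a `"latents"` attribute holding the latent
#'   code matrix.
#' @export
render_invariant_dataset <- function(bank, viewpoints = NULL, noise_sd = 0.02,
                                     seed = 1L, basis = NULL, vp_scale = 1.5,
                                     quantize = TRUE) {
  stopifnot(inherits(bank, "identity_bank"))
  if (nrow(bank$ids) == 0L) abort("identity bank is empty")
  viewpoints <- viewpoints %||% bank$spec$viewpoints
  if (length(viewpoints) == 0L) abort("viewpoint list is empty")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  basis <- basis %||% render_basis(derive_seed(seed, 301L))

  n_id <- nrow(bank$ids)
  grid <- tidyr::expand_grid(id_row = seq_len(n_id), viewpoint = as.numeric(viewpoints))
  Z <- matrix(0, nrow(grid), .LATENT_DIM)
  Z[, .m_cols()] <- bank$codes[grid$id_row, , drop = FALSE]
  th <- grid$viewpoint * pi / 180
  Z[, .v_cols()] <- vp_scale * cbind(sin(th), 1 - cos(th))

  labels <- tibble(
    sample_id = sprintf("s%05d", seq_len(nrow(grid))),
    identity = bank$ids$identity[grid$id_row],
    sex = bank$ids$sex[grid$id_row],
    race = bank$ids$race[grid$id_row],
    expression = "neutral",
    viewpoint = grid$viewpoint)

  px <- render_images(Z, basis, noise_sd, derive_seed(seed, 302L), quantize)
  out <- face_set(px, labels, basis$width, basis$height)
  attr(out, "latents") <- Z
  attr(out, "basis_seed") <- basis$seed
  out
}

#' Render the expression database (identity x expression, frontal)
#'
#' Emulates a frontal facial-expression database: one image per identity per
#' expression category. Expression is rendered as a category prototype
#' deformation in the expression latent block plus per-image jitter. The
#' coupling parameter `kappa` routes a fraction of the expression deformation
#' energy through an identity-derived component (a fixed orthonormal map of
#' the identity morphology into the expression block): at `kappa = 0` the
#' deformation is statistically independent of identity; at `kappa = 1` the
#' deformation direction is a deterministic function of identity.
#'
#' @param bank An [make_identity_bank()] result.
#' @param expressions Expression categories (default: the bank's spec).
#' @param kappa Coupling in `[0, 1]` between identity morphology and
#'   expression deformation.
#' @param noise_sd Additive Gaussian pixel noise sd.
#' @param seed Integer seed.
#' @param basis Optional fixed [render_basis()].
#' @param expr_strength Prototype deformation norm (latent units); the
#'   default 3 puts the per-dimension expression variance on a par with the
#'   per-dimension identity morphology variance, so neither family of
#'   directions crowds the other out of the leading principal components.
#' @param expr_manifold_dim Dimensionality of the prototype deformation
#'   manifold inside the expression block. The default spans the whole block,
#'   leaving the category prototypes in general position so that every
#'   discriminant of an expression-trained subspace carries genuine
#'   expression structure.
#' @param jitter_frac Per-image jitter sd as a fraction of the prototype norm.
#' @param quantize Snap intensities to 8-bit levels.
#' @return A [face_set()] with `"latents"` attribute.
#' @export
render_expression_dataset <- function(bank, expressions = NULL, kappa = 0,
                                      noise_sd = 0.02, seed = 1L, basis = NULL,
                                      expr_strength = 3, expr_manifold_dim = .E_DIM,
                                      jitter_frac = 0.25, quantize = TRUE) {
  stopifnot(inherits(bank, "identity_bank"))
  expressions <- expressions %||% bank$spec$expression_levels
  if (length(expressions) == 0L) abort("expression list is empty")
  if (length(kappa) != 1L || kappa < 0 || kappa > 1) abort("kappa must be in [0, 1]")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  basis <- basis %||% render_basis(derive_seed(seed, 301L))

  n_id <- nrow(bank$ids)
  n_ex <- length(expressions)

  # Fixed prototypes: neutral is the undeformed face, the others are seeded
  # directions of norm expr_strength lying on a low-dimensional deformation
  # manifold inside the expression block.
  q <- min(as.integer(expr_manifold_dim), .E_DIM)
  protos <- with_seed(derive_seed(seed, 401L), {
    Q <- qr.Q(qr(matrix(rnorm(.E_DIM * q), .E_DIM, q)))
    U <- matrix(rnorm(n_ex * q), n_ex, q)
    P <- (U / sqrt(rowSums(U^2)) * expr_strength) %*% t(Q)
    P[expressions == "neutral", ] <- 0
    P
  })
  # Fixed orthonormal map morphology -> expression block for the coupling.
  couple_map <- with_seed(derive_seed(seed, 402L), {
    qr.Q(qr(matrix(rnorm(.M_FREE * .E_DIM), .M_FREE, .E_DIM)))  # 14 x 8
  })
  couple_scale <- expr_strength / sqrt(.E_DIM)

  grid <- tidyr::expand_grid(id_row = seq_len(n_id), expr = expressions)
  jitter_sd <- jitter_frac * expr_strength / sqrt(.E_DIM)
  jitter <- with_seed(derive_seed(seed, 403L),
                      matrix(rnorm(nrow(grid) * .E_DIM, sd = jitter_sd),
                             nrow(grid), .E_DIM))

  e_free <- protos[match(grid$expr, expressions), , drop = FALSE] + jitter
  e_coupled <- couple_scale *
    (bank$codes[grid$id_row, seq_len(.M_FREE), drop = FALSE] %*% couple_map)
  Z <- matrix(0, nrow(grid), .LATENT_DIM)
  Z[, .m_cols()] <- bank$codes[grid$id_row, , drop = FALSE]
  Z[, .e_cols()] <- sqrt(1 - kappa) * e_free + sqrt(kappa) * e_coupled

  labels <- tibble(
    sample_id = sprintf("s%05d", seq_len(nrow(grid))),
    identity = bank$ids$identity[grid$id_row],
    sex = bank$ids$sex[grid$id_row],
    race = bank$ids$race[grid$id_row],
    expression = grid$expr,
    viewpoint = 0)

  px <- render_images(Z, basis, noise_sd, derive_seed(seed, 404L), quantize)
  out <- face_set(px, labels, basis$width, basis$height)
  attr(out, "latents") <- Z
  attr(out, "basis_seed") <- basis$seed
  out
}

#' Latent-block column indices of the generator
#'
#' Utility for inspecting the `"latents"` attribute of generated face sets.
#'
#' @return Named list of integer column index vectors (`morphology`,
#'   `expression`, `viewpoint`).
#' @export
latent_blocks <- function() {
  list(morphology = .m_cols(), expression = .e_cols(), viewpoint = .v_cols())
}
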