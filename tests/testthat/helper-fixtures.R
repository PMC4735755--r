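# Small fixture builders, all generated in code.

# A tiny labelled coordinate set wrapped as a projected_set.
make_pset <- function(coords, labels, property = "class") {
  projected_set(as.matrix(coords), labels, eval_property = property)
}

# Two Gaussian clusters in d dims separated by `sep` along the first axis.
two_cluster_coords <- function(n_per, d = 3, sep = 10, sd = 1, seed = 1) {
  withr::with_seed(seed, {
    rbind(cbind(rnorm(n_per, 0, sd), matrix(rnorm(n_per * (d - 1), 0, sd), n_per)),
          cbind(rnorm(n_per, sep, sd), matrix(rnorm(n_per * (d - 1), 0, sd), n_per)))
  })
}

two_cluster_labels <- function(n_per) rep(c("A", "B"), each = n_per)

# Toy face set of arbitrary resolution built from explicit image matrices.
toy_face_set <- function(imgs) {
  h <- nrow(imgs[[1]]); w <- ncol(imgs[[1]])
  mat <- do.call(rbind, lapply(imgs, image_to_vector))
  n <- length(imgs)
  face_set(mat,
           tibble::tibble(sample_id = sprintf("s%03d", seq_len(n)),
                          identity = sprintf("id%03d", seq_len(n)),
                          sex = rep_len(c("female", "male"), n),
                          race = "asian", expression = "neutral", viewpoint = 0),
           width = w, height = h)
}

# Small rendered datasets shared across tests (cached per session).
small_invariant <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- attribute_spec(16)
      bank <- make_identity_bank(spec, seed = 21)
      cache <<- render_invariant_dataset(bank, seed = 22)
    }
    cache
  }
})

small_expression <- local({
  cache <- NULL
  function(kappa = 0) {
    spec <- attribute_spec(12, race_levels = "asian")
    bank <- make_identity_bank(spec, seed = 31)
    render_expression_dataset(bank, kappa = kappa, seed = 32)
  }
})
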