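test_that("identity banks realise the requested sex x race balance exactly", {
  bank <- make_identity_bank(attribute_spec(120), seed = 1)
  tab <- table(bank$ids$sex, bank$ids$race)
  expect_true(all(tab == 30))

  bank2 <- make_identity_bank(attribute_spec(50, race_levels = "asian"), seed = 1)
  expect_equal(unname(table(bank2$ids$sex)), c(25L, 25L), ignore_attr = TRUE)
  expect_equal(unique(bank2$ids$race), "asian")

  expect_error(make_identity_bank(attribute_spec(50), seed = 1), "divisible")
})

test_that("generation is deterministic given spec and seed", {
  spec <- attribute_spec(8)
  b1 <- make_identity_bank(spec, seed = 5)
  b2 <- make_identity_bank(spec, seed = 5)
  expect_identical(b1$codes, b2$codes)

  d1 <- render_invariant_dataset(b1, seed = 9)
  d2 <- render_invariant_dataset(b2, seed = 9)
  expect_identical(d1$images, d2$images)
  expect_identical(d1$labels, d2$labels)

  d3 <- render_invariant_dataset(b1, seed = 10)
  expect_false(identical(d1$images, d3$images))
})

test_that("rendered datasets follow the factorial composition", {
  ds <- render_invariant_dataset(make_identity_bank(attribute_spec(120), 1), seed = 2)
  expect_equal(n_faces(ds), 600L)  # 120 identities x 5 viewpoints
  expect_equal(unique(ds$labels$expression), "neutral")
  expect_true(all(ds$images >= 0 & ds$images <= 1))

  bank <- make_identity_bank(attribute_spec(50, race_levels = "asian"), 1)
  de <- render_expression_dataset(bank, seed = 2)
  expect_equal(n_faces(de), 300L)  # 50 identities x 6 expressions
  expect_equal(unique(de$labels$viewpoint), 0)
  expect_equal(dplyr::n_distinct(de$labels$expression), 6L)

  expect_error(render_invariant_dataset(make_identity_bank(attribute_spec(4), 1),
                                        viewpoints = numeric(0)), "viewpoint")
  expect_error(render_expression_dataset(bank, expressions = character(0)),
               "expression")
  expect_error(render_expression_dataset(bank, kappa = 1.2), "kappa")
})

test_that("latent-to-image map is linear around the base face and clipped", {
  basis <- render_basis(seed = 3)
  base <- latent_to_image(rep(0, basis$d), basis)
  expect_equal(image_to_vector(base), basis$base)

  code <- withr::with_seed(4, rnorm(basis$d, sd = 0.1))
  up <- latent_to_image(code, basis, clip = FALSE)
  down <- latent_to_image(-code, basis, clip = FALSE)
  expect_equal((up + down) / 2, latent_to_image(rep(0, basis$d), basis, clip = FALSE),
               tolerance = 1e-12)

  big <- latent_to_image(rep(50, basis$d), basis)
  expect_true(all(big >= 0 & big <= 1))
  expect_error(latent_to_image(rep(0, basis$d - 1), basis), "length")
})

test_that("identical latent codes render pixel-identical images without noise", {
  bank <- make_identity_bank(attribute_spec(4), seed = 6)
  bank$codes[2, ] <- bank$codes[1, ]
  ds <- render_invariant_dataset(bank, noise_sd = 0, seed = 7)
  for (vp in unique(ds$labels$viewpoint)) {
    i1 <- which(ds$labels$identity == "id001" & ds$labels$viewpoint == vp)
    i2 <- which(ds$labels$identity == "id002" & ds$labels$viewpoint == vp)
    expect_identical(ds$images[i1, ], ds$images[i2, ])
  }
  # and two viewpoints of one identity differ only through the viewpoint block
  Z <- attr(ds, "latents")
  rows <- which(ds$labels$identity == "id001")
  blocks <- latent_blocks()
  expect_true(all(apply(Z[rows, c(blocks$morphology, blocks$expression)], 2,
                        function(col) diff(range(col))) == 0))
})

test_that("expression components are independent of identity when kappa = 0", {
  bank <- make_identity_bank(attribute_spec(20, race_levels = "asian"), seed = 8)
  ds <- render_expression_dataset(bank, kappa = 0, seed = 9)
  E <- attr(ds, "latents")[, latent_blocks()$expression]
  id <- ds$labels$identity
  expr <- ds$labels$expression
  # residual expression component after removing category prototypes
  resid <- E - rowsum(E, expr)[expr, ] / as.vector(table(expr)[expr])
  between_id_ss <- function(R, g) {
    means <- rowsum(R, g) / as.vector(table(g))
    sum(as.vector(table(g)) * rowSums(means^2))
  }
  obs <- between_id_ss(resid, id)
  null <- withr::with_seed(10, replicate(199, between_id_ss(resid, sample(id))))
  expect_lt(obs, quantile(null, 0.99))
})

test_that("kappa = 1 makes the deformation direction identity-specific", {
  bank <- make_identity_bank(attribute_spec(6, race_levels = "asian"), seed = 11)
  ds <- render_expression_dataset(bank, kappa = 1, noise_sd = 0, seed = 12)
  E <- attr(ds, "latents")[, latent_blocks()$expression]
  per_id <- rowsum(E, ds$labels$identity) / 6
  # distinct directions across identities ...
  cosines <- abs(stats::cor(t(per_id)))
  expect_lt(max(cosines[upper.tri(cosines)]), 0.999)
  # ... and no expression information left within an identity
  expect_lt(max(abs(E - per_id[ds$labels$identity, ])), 1e-12)
})

test_that("generated latents separate sex nearly perfectly", {
  bank <- make_identity_bank(attribute_spec(120), seed = 13)
  ds <- render_invariant_dataset(bank, seed = 14)
  M <- attr(ds, "latents")[, latent_blocks()$morphology]
  fit <- MASS::lda(M, grouping = ds$labels$sex)
  acc <- mean(stats::predict(fit)$class == ds$labels$sex)
  expect_gt(acc, 0.95)
})
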