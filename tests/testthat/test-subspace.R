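test_that("vectorization is row-major and centering removes the mean face", {
  img <- matrix(1:9, nrow = 3, byrow = TRUE)  # rows (1,2,3), (4,5,6), (7,8,9)
  expect_equal(image_to_vector(img), as.numeric(1:9))
  expect_equal(vector_to_image(1:9, 3, 3), img)

  fs <- toy_face_set(list(img / 10, img / 10))
  ctr <- vectorize_and_center(fs)
  expect_equal(ctr$matrix, matrix(0, 2, 9), ignore_attr = TRUE)
  expect_equal(ctr$mean_face, as.numeric(1:9) / 10, ignore_attr = TRUE)

  one <- vectorize_and_center(toy_face_set(list(img / 10)))
  expect_equal(as.vector(one$matrix), rep(0, 9))
})

test_that("PCA recovers rank, orthonormality and the eigenvalue identity", {
  # data on a known 5-dim basis: eigenvalues beyond 5 vanish
  X <- withr::with_seed(1, {
    B <- qr.Q(qr(matrix(rnorm(40 * 5), 40, 5)))
    matrix(rnorm(30 * 5), 30, 5) %*% t(B)
  })
  m <- fit_pca(X, 10)
  expect_lt(max(m$eigenvalues[6:10]), 1e-20)
  expect_equal(tcrossprod(m$components), diag(10), tolerance = 1e-8)
  expect_true(all(diff(m$eigenvalues) <= 1e-12))

  # per-component variance of training projections equals the eigenvalues
  proj <- project_pca(m, X)
  expect_equal(apply(proj, 2, var)[1:5], m$eigenvalues[1:5], tolerance = 1e-8)

  # copies of one image: all eigenvalues zero
  flat <- fit_pca(matrix(rep(runif(12), each = 6), nrow = 6), 3)
  expect_lt(max(flat$eigenvalues), 1e-20)

  expect_error(fit_pca(X, 30), "n_samples")
})

test_that("PCA reconstruction error is non-increasing in the component count", {
  X <- withr::with_seed(2, matrix(rnorm(25 * 12), 25, 12))
  errs <- vapply(1:8, function(k) {
    m <- fit_pca(X, k)
    ctr <- sweep(X, 2, m$mean_face)
    sum((ctr - project_pca(m, X) %*% m$components)^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
})

test_that("PCA projection honours the component geometry", {
  X <- withr::with_seed(3, matrix(rnorm(20 * 8), 20, 8))
  m <- fit_pca(X, 4)
  expect_equal(as.vector(project_pca(m, matrix(m$mean_face, 1))), rep(0, 4))
  probe <- matrix(m$mean_face + 2.5 * m$components[2, ], 1)
  expect_equal(as.vector(project_pca(m, probe)), c(0, 2.5, 0, 0), tolerance = 1e-8)
  expect_error(project_pca(m, matrix(0, 1, 5)), "pixels")
})

test_that("two-class Fisher direction matches the closed form", {
  res <- withr::with_seed(4, {
    k <- 6; n <- 300
    A <- matrix(rnorm(k * k), k); S <- crossprod(A) / k + diag(k)
    R <- chol(S)
    mu1 <- rnorm(k); mu2 <- rnorm(k)
    X <- rbind(matrix(rnorm(n * k), n) %*% R + matrix(mu1, n, k, byrow = TRUE),
               matrix(rnorm(n * k), n) %*% R + matrix(mu2, n, k, byrow = TRUE))
    lab <- rep(c("a", "b"), each = n)
    # oracle: pooled within-class scatter, closed-form direction
    Sw <- crossprod(X[1:n, ] - matrix(colMeans(X[1:n, ]), n, k, byrow = TRUE)) +
      crossprod(X[-(1:n), ] - matrix(colMeans(X[-(1:n), ]), n, k, byrow = TRUE))
    w_star <- solve(Sw, colMeans(X[1:n, ]) - colMeans(X[-(1:n), ]))
    model <- fit_lfd(X, lab)
    list(model = model, w_star = w_star)
  })
  v <- res$model$directions[, 1]
  cosine <- abs(sum(v * res$w_star)) / sqrt(sum(v^2) * sum(res$w_star^2))
  expect_gt(cosine, 0.999)
  expect_equal(ncol(res$model$directions), 1L)  # 2 classes: 1 direction only
})

test_that("discriminant count is capped at classes minus one", {
  k <- 8
  X <- withr::with_seed(5, matrix(rnorm(60 * k), 60, k))
  for (C in c(2L, 3L, 6L)) {
    lab <- rep_len(sprintf("c%d", seq_len(C)), 60)
    expect_equal(n_discriminants(fit_lfd(X, lab, n_discriminants = 99)),
                 min(C - 1L, k))
  }
})

test_that("degenerate labellings are rejected", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_lfd(X, rep("a", 10)), "at least 2 classes")
  expect_error(fit_lfd(X, c(rep("a", 9), "b")), "fewer than 2 samples")
})

test_that("label structure shows up in the generalized eigenvalues", {
  set.seed(6)
  k <- 5; n_per <- 30
  X <- rbind(matrix(rnorm(n_per * k), n_per),
             matrix(rnorm(n_per * k, mean = 3), n_per))
  lab <- rep(c("a", "b"), each = n_per)
  lambda_true <- fit_lfd(X, lab)$eigenvalues[1]
  lambda_perm <- replicate(30, fit_lfd(X, sample(lab))$eigenvalues[1])
  expect_gt(lambda_true, 5 * max(lambda_perm))
  # a random labelling sits inside its own permutation null
  lab_r <- sample(lab)
  lambda_r <- fit_lfd(X, lab_r)$eigenvalues[1]
  null_r <- replicate(30, fit_lfd(X, sample(lab_r))$eigenvalues[1])
  expect_lt(lambda_r, max(null_r) * 1.5)
  expect_gt(lambda_r, min(null_r) / 1.5)
})

test_that("Fisher directions are scale-equivariant", {
  X <- withr::with_seed(7, matrix(rnorm(80 * 6), 80, 6))
  lab <- rep(c("a", "b", "c", "d"), each = 20)
  d1 <- fit_lfd(X, lab)$directions
  d2 <- fit_lfd(7 * X, lab)$directions
  for (j in seq_len(ncol(d1))) {
    cosine <- abs(sum(d1[, j] * d2[, j])) / sqrt(sum(d1[, j]^2) * sum(d2[, j]^2))
    expect_gt(cosine, 1 - 1e-6)
  }
})

test_that("orthogonal padding yields an orthonormal frame in the model metric", {
  X <- withr::with_seed(8, matrix(rnorm(100 * 7), 100, 7))
  lab <- rep(c("a", "b", "c"), length.out = 100)

  eu <- fit_lfd(X, lab, normalization = "euclidean")
  eu_pad <- pad_orthogonal(eu, target_dim = 5, seed = 1)
  W <- cbind(eu_pad$directions, eu_pad$padding)
  expect_equal(crossprod(W), diag(5), tolerance = 1e-8)

  sw <- fit_lfd(X, lab, normalization = "sw")
  sw_pad <- pad_orthogonal(sw, target_dim = 5, seed = 1)
  Wsw <- cbind(sw_pad$directions, sw_pad$padding)
  expect_equal(t(Wsw) %*% sw_pad$sw %*% Wsw, diag(5), tolerance = 1e-8)

  # target equal to m leaves the model unchanged
  expect_identical(pad_orthogonal(sw, target_dim = 2)$directions, sw$directions)
  expect_equal(ncol(pad_orthogonal(sw, target_dim = 2)$padding), 0L)

  # only the padding depends on the seed
  p1 <- pad_orthogonal(sw, 6, seed = 1)
  p2 <- pad_orthogonal(sw, 6, seed = 2)
  expect_identical(p1$directions, p2$directions)
  expect_false(identical(p1$padding, p2$padding))

  expect_error(pad_orthogonal(sw, 9), "exceeds")
  expect_error(pad_orthogonal(sw, 1), "below")
})

test_that("Fisher projection separates classes and records the labelling", {
  set.seed(9)
  X <- rbind(matrix(rnorm(40 * 4, mean = 0), 40),
             matrix(rnorm(40 * 4, mean = 4), 40))
  lab <- rep(c("a", "b"), each = 40)
  model <- fit_lfd(X, lab, property = "sex")
  pset <- project_fisher(model, X, lab)
  expect_equal(pset$eval_property, "sex")
  expect_identical(eval_labels(pset), lab)

  mu_a <- colMeans(pset$coordinates[lab == "a", , drop = FALSE])
  mu_b <- colMeans(pset$coordinates[lab == "b", , drop = FALSE])
  gap <- sqrt(sum((mu_a - mu_b)^2))
  within <- max(dist(pset$coordinates[lab == "a", , drop = FALSE]))
  expect_gt(gap, within / 4)  # means separated on the scale of within spread

  expect_equal(as.vector(project_fisher(model, matrix(0, 1, 4))$coordinates),
               rep(0, ncol(model$directions)))
  expect_error(project_fisher(model, matrix(0, 1, 5)), "dimensions")
})
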