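test_that("relabelling swaps the evaluation labels and nothing else", {
  labels <- tibble::tibble(identity = rep(c("i1", "i2", "i3"), each = 4),
                           sex = rep(c("f", "m", "f"), each = 4),
                           constant = "x")
  pset <- projected_set(matrix(rnorm(24), 12, 2), labels, eval_property = "identity")
  re <- relabel(pset, "sex")
  expect_identical(re$coordinates, pset$coordinates)
  expect_identical(re$source_property, "identity")
  expect_identical(eval_labels(re), labels$sex)
  expect_identical(eval_labels(relabel(re, "identity")), labels$identity)

  expect_error(relabel(pset, "age"), "unknown property")
  expect_error(relabel(pset, "constant"), "fewer than 2 distinct")
})

test_that("single DMS trials follow the strict nearest-reference rule", {
  expect_equal(dms_trial(0, 10, 1, "A", "B", "A"), 1L)
  expect_equal(dms_trial(0, 10, 9, "A", "B", "A"), 0L)
  expect_equal(dms_trial(0, 10, 5, "A", "B", "A"), 0L)  # exact tie loses
  expect_error(dms_trial(0, 10, 1, "A", "A", "A"), "must differ")
  expect_error(dms_trial(0, 10, 1, "A", "B", "C"), "probe class")
})

test_that("exhaustive DMS equals the brute-force triple enumeration", {
  for (seed in 1:6) {
    fixture <- withr::with_seed(seed, {
      n <- sample(6:12, 1)
      n_cls <- sample(2:3, 1)
      coords <- matrix(rnorm(n * 2), n, 2)
      if (seed %% 2 == 0) coords[2, ] <- coords[1, ]  # duplicated point: ties
      list(coords = round(coords, 2),  # rounding creates further ties
           labels = sample(letters[seq_len(n_cls)], n, replace = TRUE))
    })
    counts <- table(fixture$labels)
    if (any(counts < 2) || length(counts) < 2) next
    got <- dms_performance(fixture$coords, labels = fixture$labels,
                           mode = "exhaustive")
    want <- dms_oracle(fixture$coords, fixture$labels)
    expect_equal(got$percent_correct, want$percent, tolerance = 1e-12)
    expect_equal(got$n_trials, want$n_trials)
  }
})

test_that("chance level and ceiling behave as a 2AFC should", {
  coords <- withr::with_seed(11, matrix(rnorm(60 * 5), 60, 5))
  labels <- withr::with_seed(12, sample(rep(c("A", "B"), each = 30)))
  perf <- dms_performance(coords, labels = labels, mode = "exhaustive")
  expect_gt(perf$n_trials, 10000)
  expect_lt(abs(perf$percent_correct - 50), 3)

  tight <- two_cluster_coords(8, sep = 100, sd = 0.01)
  perf2 <- dms_performance(tight, labels = two_cluster_labels(8), mode = "exhaustive")
  expect_equal(perf2$percent_correct, 100)
})

test_that("sampled mode agrees with exhaustive within binomial error", {
  coords <- two_cluster_coords(25, sep = 2.5, sd = 1, seed = 13)
  labels <- two_cluster_labels(25)
  ex <- dms_performance(coords, labels = labels, mode = "exhaustive")
  sa <- dms_performance(coords, labels = labels, mode = "sampled",
                        max_trials = 20000, seed = 14)
  se <- sqrt(ex$percent_correct * (100 - ex$percent_correct) / sa$n_trials)
  expect_lt(abs(sa$percent_correct - ex$percent_correct), 3 * se + 1e-9)
  expect_equal(sa$mode, "sampled")
  # auto switches to sampling above the trial cap
  au <- dms_performance(coords, labels = labels, max_trials = 100, seed = 15)
  expect_equal(au$mode, "sampled")
  expect_equal(au$n_trials, 100)
})

test_that("performance is invariant under rigid motions of the space", {
  coords <- two_cluster_coords(10, sep = 3, seed = 16)
  labels <- two_cluster_labels(10)
  Q <- qr.Q(qr(withr::with_seed(17, matrix(rnorm(9), 3, 3))))
  moved <- coords %*% Q + matrix(c(5, -2, 1), 20, 3, byrow = TRUE)
  a <- dms_performance(coords, labels = labels, mode = "exhaustive")
  b <- dms_performance(moved, labels = labels, mode = "exhaustive")
  expect_equal(a$percent_correct, b$percent_correct)
})

test_that("class-uninformative padded dimensions cannot beat chance", {
  percents <- vapply(1:8, function(s) {
    coords <- withr::with_seed(100 + s, matrix(rnorm(40 * 6), 40, 6))
    labels <- withr::with_seed(200 + s, sample(rep(c("A", "B"), each = 20)))
    dms_performance(coords, labels = labels, mode = "exhaustive")$percent_correct
  }, numeric(1))
  expect_lt(mean(percents), 53)
})

test_that("widening the between-class separation never hurts", {
  seps <- c(0.5, 1, 2, 4, 8)
  percents <- vapply(seps, function(s) {
    dms_performance(two_cluster_coords(12, sep = s, seed = 18),
                    labels = two_cluster_labels(12),
                    mode = "exhaustive")$percent_correct
  }, numeric(1))
  expect_true(all(diff(percents) >= 0))
})

test_that("undersized evaluation classes are dropped with a warning", {
  coords <- rbind(two_cluster_coords(5, sep = 6, seed = 19), c(99, 0, 0))
  labels <- c(two_cluster_labels(5), "C")
  expect_warning(perf <- dms_performance(coords, labels = labels),
                 class = "facetransfer_dropped_classes")
  expect_equal(perf$n_dropped, 1L)
  expect_equal(perf$n_classes, 2L)
  expect_error(suppressWarnings(
    dms_performance(matrix(rnorm(8), 4, 2), labels = c("a", "a", "b", "c"))),
    "fewer than 2")
})
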