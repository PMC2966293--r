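test_that("pooled-count estimation matches the hand-worked abstraction", {
  # class counts AA->A: 2, AB->B: 2 over {A,B}; one abstraction {AA, AB}
  d <- seq_dataset(c("a", "b", "c"), c("AAAA", "ABB", "ABB"),
                   c("c1", "c1", "c1"), alphabet = ab2())
  idx <- build_kgram_index(d, 2)
  ctx <- kgram_contexts(d, idx)
  h <- learn_hierarchy(ctx)
  cut <- extract_mcut(h, 1)
  fit <- fit_aamm(d, cut)
  # theta(A | a, c1) = (2 + 1) / (4 + 2)
  expect_equal(unname(fit$emission$c1[1, "A"]), 0.5)
  expect_equal(unname(rowSums(fit$emission$c1)), rep(1, cut$m))
  # exactly m * |X| emission entries per class
  expect_equal(length(fit$emission$c1), cut$m * 2L)
})

test_that("the singleton cut reduces the AAMM exactly to the Markov model", {
  for (seed in c(21, 22)) {
    gt <- make_ground_truth(seed = seed, length_range = c(10, 40))
    d <- sample_dataset(gt, 30, seed = seed + 100)
    idx <- build_kgram_index(d, 2)
    mm <- fit_mm(d, 2, index = idx)
    h <- learn_hierarchy(kgram_contexts(d, idx))
    aam <- fit_aamm(d, extract_mcut(h, idx$N))
    qry <- sample_dataset(gt, 25, seed = seed + 200)
    for (cl in mm$classes) {
      expect_equal(log_likelihood(aam, qry, cl), log_likelihood(mm, qry, cl),
                   tolerance = 1e-13)
    }
    expect_identical(classify(aam, qry), classify(mm, qry))
  }
})

test_that("the root cut is the class-conditional zero-memory model", {
  d <- random_dataset(n = 20, seed = 31)
  idx <- build_kgram_index(d, 2)
  h <- learn_hierarchy(kgram_contexts(d, idx))
  aam <- fit_aamm(d, extract_mcut(h, 1))
  cnt <- count_transitions(d, idx, per_class = TRUE)
  for (cl in aam$classes) {
    pooled <- colSums(cnt$next_count[[cl]][seq_len(idx$N), , drop = FALSE])
    direct <- (pooled + 1) / (sum(pooled) + 2)
    expect_equal(unname(aam$emission[[cl]][1, ]), unname(direct))
  }
})

test_that("coarsening the cut never increases training likelihood", {
  # data with real context structure, so the emission term dominates
  gt <- make_ground_truth(seed = 41, length_range = c(40, 80))
  d <- sample_dataset(gt, 25, seed = 42)
  idx <- build_kgram_index(d, 2)
  h <- learn_hierarchy(kgram_contexts(d, idx))
  leaf <- fit_aamm(d, extract_mcut(h, idx$N))
  root <- fit_aamm(d, extract_mcut(h, 1))
  ll <- function(model) {
    sum(vapply(seq_len(n_records(d)), function(i) {
      log_likelihood(model, d$seq[i], d$label[i])
    }, numeric(1)))
  }
  expect_gte(ll(leaf), ll(root))
})

test_that("semi-supervised fitting uses unlabeled data only for structure", {
  gt <- make_ground_truth(seed = 51, length_range = c(20, 60))
  bench <- make_benchmark(gt, 80, 10, 0.5, 0.4, seed = 52)
  full <- fit_semisupervised(bench$train$dataset, 2, m = 6)
  expect_s3_class(full$hierarchy, "abstraction_hierarchy")
  expect_s3_class(full$model, "aamm_params")

  # the hierarchy stage never reads labels: it matches the hierarchy
  # learned from the same sequences with every label stripped
  idx <- build_kgram_index(bench$train$dataset, 2)
  blind <- learn_hierarchy(kgram_contexts(strip_labels(bench$train$dataset), idx))
  expect_identical(full$hierarchy$merges, blind$merges)
  expect_identical(full$hierarchy$heights, blind$heights)

  # with no unlabeled records the fit equals AAMM(l)
  lab_only <- fit_semisupervised(bench$train$labeled, 2, m = 6)
  direct <- fit_semisupervised(subset_records(bench$train$dataset,
                                              !is.na(bench$train$dataset$label)),
                               2, m = 6)
  expect_equal(lab_only$model$emission, direct$model$emission)

  expect_warning(fit_semisupervised(bench$train$dataset, 2, m = 10000),
                 "clipped")
})

test_that("AAMM serialization round-trips exactly", {
  d <- random_dataset(n = 15, seed = 61)
  fit <- fit_semisupervised(d, 2, m = 2)
  path <- tempfile(fileext = ".json")
  write_model(fit$model, path)
  back <- read_model(path)
  expect_identical(back$map$assignment, fit$model$map$assignment)
  expect_equal(back$emission, fit$model$emission, tolerance = 0)
  expect_equal(back$initial, fit$model$initial, tolerance = 0)
  qry <- random_dataset(n = 5, seed = 62, labeled = FALSE)
  expect_equal(posterior(back, qry), posterior(fit$model, qry), tolerance = 0)
})
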