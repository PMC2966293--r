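test_that("k-gram contexts pool successors over all sequences, label-free", {
  d <- seq_dataset(c("a", "b"), c("AAA", "AAB"), c("c1", "c2"),
                   alphabet = ab2())
  idx <- build_kgram_index(d, 2)
  ctx <- kgram_contexts(d, idx, pseudocount = 0)
  expect_equal(unname(ctx$dist["AA", ]), c(0.5, 0.5))
  expect_equal(unname(ctx$weight[match("AA", ctx$kgrams)]), 2)

  stripped <- kgram_contexts(strip_labels(d), idx, pseudocount = 0)
  expect_identical(ctx$dist, stripped$dist)
  expect_identical(ctx$weight, stripped$weight)
})

test_that("JS divergence matches closed forms and its metric properties", {
  expect_equal(js_divergence(c(1, 0), c(0, 1), 0.5, 0.5), 1.0)
  # H(0.75, 0.25) - 0.5 * H(0.5, 0.5)
  expect_equal(js_divergence(c(1, 0), c(0.5, 0.5), 0.5, 0.5),
               0.3112781, tolerance = 1e-6)
  set.seed(1)
  for (i in 1:50) {
    p <- rand_dist(5); q <- rand_dist(5)
    w <- runif(1)
    expect_equal(js_divergence(p, q, w, 1 - w), js_divergence(q, p, 1 - w, w))
    expect_gte(js_divergence(p, q, w, 1 - w), 0)
    # bounded by the binary entropy of the weight split
    hsplit <- -w * log2(w) - (1 - w) * log2(1 - w)
    expect_lte(js_divergence(p, q, w, 1 - w), hsplit + 1e-12)
    expect_equal(js_divergence(p, p, w, 1 - w), 0)
  }
  expect_error(js_divergence(c(1, 0), c(0, 1), 0.7, 0.7), "sum to 1")
  expect_error(js_divergence(c(1, 0), c(0, 1), -0.5, 1.5), "non-negative")
})

test_that("abstraction distance scales JS by total weight", {
  expect_equal(abstraction_distance(c(1, 0), 1, c(0, 1), 1), 2.0)
  expect_equal(abstraction_distance(c(1, 0), 3, c(0, 1), 1),
               3.2451125, tolerance = 1e-6)
  expect_equal(abstraction_distance(c(0.3, 0.7), 5, c(0.3, 0.7), 2), 0)
  expect_equal(abstraction_distance(c(1, 0), 0, c(0, 1), 0), 0)
  expect_equal(abstraction_distance(c(1, 0), 3, c(0, 1), 1,
                                    scaling = "unscaled"),
               3.2451125 / 4, tolerance = 1e-6)
})

test_that("agglomeration makes N-1 merges and the root covers everything", {
  # nine 2-grams over a 3-letter alphabet
  set.seed(2)
  al <- make_alphabet(c("A", "B", "C"))
  kg <- sort(apply(expand.grid(al, al), 1, paste0, collapse = ""))
  ctx <- context_set(kg, t(replicate(9, rand_dist(3))), sample(1:20, 9), al)
  h <- learn_hierarchy(ctx)
  expect_equal(nrow(h$merges), 8L)
  root <- extract_mcut(h, 1)
  expect_equal(sort(unique(root$assignment)), 1L)
  three <- extract_mcut(h, 3)
  expect_equal(sort(unique(three$assignment)), 1:3)
  expect_equal(length(three$assignment), 9L)
})

test_that("every m-cut is a disjoint cover of the vocabulary", {
  set.seed(3)
  ctx <- context_set(sprintf("s%02d", 1:12), t(replicate(12, rand_dist(4))),
                     runif(12, 0, 30), make_alphabet(c("A", "B", "C", "D")))
  h <- learn_hierarchy(ctx)
  for (m in 1:12) {
    cut <- extract_mcut(h, m)
    expect_equal(length(cut$assignment), 12L)
    expect_equal(sort(unique(cut$assignment)), seq_len(m))
    # blocks are leaf sets of single hierarchy nodes: disjoint by
    # construction of the assignment; cover checked by totality
    expect_false(anyNA(cut$assignment))
  }
  expect_error(extract_mcut(h, 0), "m must be")
  expect_error(extract_mcut(h, 13), "m must be")
})

test_that("merged contexts equal the direct weighted aggregation of leaves", {
  set.seed(4)
  N <- 10
  P <- t(replicate(N, rand_dist(3)))
  w <- runif(N, 0.5, 10)
  ctx <- context_set(sprintf("s%02d", 1:N), P, w, make_alphabet(c("A", "B", "C")))
  h <- learn_hierarchy(ctx)
  for (m in c(1, 3, 5)) {
    cut <- extract_mcut(h, m)
    for (b in seq_len(m)) {
      leaves <- which(cut$assignment == b)
      direct <- colSums(P[leaves, , drop = FALSE] * w[leaves]) / sum(w[leaves])
      expect_equal(unname(cut$block_dist[b, ]), unname(direct), tolerance = 1e-12)
      expect_equal(cut$block_weight[b], sum(w[leaves]), tolerance = 1e-12)
    }
  }
})

test_that("hierarchies are label-invariant", {
  d <- random_dataset(n = 15, seed = 8)
  idx <- build_kgram_index(d, 2)
  h1 <- learn_hierarchy(kgram_contexts(d, idx))
  h2 <- learn_hierarchy(kgram_contexts(strip_labels(d), idx))
  expect_identical(h1$merges, h2$merges)
  expect_identical(h1$heights, h2$heights)
})

test_that("Newick export is parseable and preserves the leaf set", {
  skip_if_not_installed("ape")
  single <- learn_hierarchy(context_set("AAA", matrix(rep(1 / 20, 20), 1),
                                        5, aa_alphabet()))
  expect_equal(export_newick(single), "AAA;")

  two <- learn_hierarchy(context_set(c("AAA", "AAB"),
                                     rbind(rand_dist(20), rand_dist(20)),
                                     c(2, 3), aa_alphabet()))
  expect_match(export_newick(two), "^\\(AAA:[0-9.e+-]+,AAB:[0-9.e+-]+\\);$")

  set.seed(5)
  ctx <- context_set(sprintf("kg%02d", 1:9), t(replicate(9, rand_dist(3))),
                     runif(9, 1, 9), make_alphabet(c("A", "B", "C")))
  h <- learn_hierarchy(ctx)
  tree <- ape::read.tree(text = export_newick(h))
  expect_setequal(tree$tip.label, ctx$kgrams)
})

test_that("m-cut TSV export writes one row per k-gram", {
  set.seed(6)
  ctx <- context_set(sprintf("s%d", 1:5), t(replicate(5, rand_dist(2))),
                     1:5, ab2())
  cut <- extract_mcut(learn_hierarchy(ctx), 2)
  path <- tempfile()
  write_mcut(cut, path)
  tab <- read.delim(path, header = FALSE)
  expect_equal(nrow(tab), 5L)
  expect_equal(sort(unique(tab$V2)), 1:2)
})
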