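test_that("FASTA reading handles headers, cleaning and empty files", {
  path <- write_tmp_fasta(c(">p1 some description", "MKVL", "AEST",
                            ">p2", "GULW"))
  d <- read_fasta(path)
  expect_equal(d$id, c("p1", "p2"))
  expect_equal(d$seq[1], "MKVLAEST")
  # U is non-canonical and becomes the sentinel under the default policy
  expect_equal(d$seq[2], "G?LW")

  ext <- read_fasta(path, policy = "extend-alphabet")
  expect_equal(ext$seq[2], "GULW")
  expect_true("U" %in% dataset_alphabet(ext))

  empty <- read_fasta(write_tmp_fasta(character()))
  expect_equal(n_records(empty), 0L)
})

test_that("malformed FASTA is rejected with the offending line", {
  no_header <- write_tmp_fasta(c("MKVL", ">p1", "AEST"))
  expect_error(read_fasta(no_header), "line 1")
  empty_entry <- write_tmp_fasta(c(">p1", "MKVL", ">p2", ">p3", "AEST"))
  expect_error(read_fasta(empty_entry), "line 3")
})

test_that("label files attach by id and partition the dataset", {
  d <- seq_dataset(sprintf("p%d", 1:5), rep("MKVLAEST", 5))
  lab <- tempfile()
  writeLines(c("p1\tcytoplasm", "p3\tperiplasm", "p5\touter membrane"), lab)
  d2 <- read_labels(lab, d)
  expect_equal(n_records(labeled_subset(d2)), 3L)
  expect_equal(n_records(unlabeled_subset(d2)), 2L)

  empty <- tempfile(); writeLines(character(), empty)
  expect_equal(sum(!is.na(read_labels(empty, d)$label)), 0L)

  five_class <- tempfile()
  writeLines(paste(sprintf("p%d", 1:5),
                   c("cytoplasm", "cytoplasmic membrane", "periplasm",
                     "outer membrane", "extracellular"), sep = "\t"),
             five_class)
  expect_equal(dataset_classes(read_labels(five_class, d)),
               sort(c("cytoplasm", "cytoplasmic membrane", "periplasm",
                      "outer membrane", "extracellular")))

  orphan <- tempfile(); writeLines("zzz\tcytoplasm", orphan)
  expect_error(read_labels(orphan, d), "zzz")
  conflict <- tempfile(); writeLines(c("p1\ta", "p1\tb"), conflict)
  expect_error(read_labels(conflict, d), "conflict")
})

test_that("FASTA + label TSV round-trips ids, residues and labels", {
  d <- random_dataset(n = 8, seed = 42)
  d$label[c(2, 5)] <- NA
  fa <- tempfile(fileext = ".fasta"); tsv <- tempfile(fileext = ".tsv")
  write_fasta(d, fa); write_labels(d, tsv)
  back <- read_labels(tsv, read_fasta(fa, alphabet = dataset_alphabet(d)))
  expect_identical(back$id, d$id)
  expect_identical(back$seq, d$seq)
  expect_identical(back$label, d$label)
})

test_that("k-gram vocabulary contains exactly the clean parent windows", {
  al <- aa_alphabet()
  expect_equal(build_kgram_index(seq_dataset("s", "MKV", alphabet = al), 3)$N, 0L)

  d <- seq_dataset("s", "AABAA", alphabet = ab2())
  idx <- build_kgram_index(d, 2)
  expect_equal(idx$kgrams, c("AA", "AB", "BA"))

  # windows touching the sentinel are excluded both inside the window and
  # at the successor position
  ds <- seq_dataset("s", "AAUAA", alphabet = ab2()) # U -> sentinel
  expect_equal(build_kgram_index(ds, 2)$kgrams, character(0))

  # label-invariant
  d2 <- random_dataset(n = 10, seed = 3)
  expect_identical(build_kgram_index(d2, 2)$kgrams,
                   build_kgram_index(strip_labels(d2), 2)$kgrams)
})

test_that("transition counting matches hand counts and conserves mass", {
  d <- seq_dataset("s", "AABAA", alphabet = ab2())
  idx <- build_kgram_index(d, 2)
  cnt <- count_transitions(d, idx)
  expect_equal(cnt$next_count["AA", "B"], 1)
  expect_equal(cnt$next_count["AB", "A"], 1)
  expect_equal(cnt$next_count["BA", "A"], 1)
  expect_equal(unname(cnt$parent_count[c("AA", "AB", "BA")]), c(1, 1, 1))

  for (seed in 1:5) {
    dr <- random_dataset(n = 12, seed = seed)
    ir <- build_kgram_index(dr, 2)
    cr <- count_transitions(dr, ir, per_class = TRUE)
    for (cl in names(cr$next_count)) {
      expect_equal(rowSums(cr$next_count[[cl]]), cr$parent_count[[cl]])
    }
  }
})

test_that("fractional class weights scale counts linearly", {
  d <- seq_dataset("u", "AABAA", alphabet = ab2())
  idx <- build_kgram_index(d, 2)
  w <- matrix(c(0.3, 0.7), nrow = 1)
  cnt <- count_transitions(d, idx, weights = w, classes = c("c1", "c2"))
  full <- count_transitions(d, idx)$next_count
  expect_equal(cnt$next_count$c1, full * 0.3)
  expect_equal(cnt$next_count$c2, full * 0.7)
})

test_that("k-grams outside the index land in the unseen bucket", {
  base <- seq_dataset("a", "AABAA", alphabet = ab2())
  idx <- build_kgram_index(base, 2)
  other <- seq_dataset("b", "BBBB", alphabet = ab2()) # BB not in index
  cnt <- count_transitions(other, idx)
  expect_equal(unname(cnt$parent_count["<unseen>"]), 2)
  expect_equal(sum(cnt$next_count), 2) # nothing silently dropped
})
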