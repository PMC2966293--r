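# shared in-code fixtures; no data files

ab2 <- function() make_alphabet(c("A", "B"))

# the two-class toy with hand-computable parameters at k = 1
toy_mm_dataset <- function() {
  seq_dataset(c("x1", "x2"), c("AAAA", "BBBB"), c("c1", "c2"), alphabet = ab2())
}

# random dataset over a small alphabet with two labeled classes
random_dataset <- function(n = 20, seed = 1, alphabet = ab2(),
                           len = c(8, 20), labeled = TRUE) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(alphabet, sample(len[1]:len[2], 1), replace = TRUE),
          collapse = "")
  }, "")
  label <- if (labeled) sample(c("c1", "c2"), n, replace = TRUE) else NULL
  if (labeled) { label[1] <- "c1"; label[2] <- "c2" } # both classes present
  seq_dataset(sprintf("r%03d", seq_len(n)), seqs, label, alphabet = alphabet)
}

# random probability vector
rand_dist <- function(a, alpha = 1) {
  g <- rgamma(a, alpha)
  g / sum(g)
}

write_tmp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}
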