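#' Ground-truth generative model for benchmarking
#'
#' Builds a known abstraction-conditioned Markov model: the full set of
#' `alphabet_size^k` k-grams is split into `m_true` balanced random
#' blocks, and each (class, block) pair gets a next-symbol distribution
#' drawn from a symmetric Dirichlet. Sequences sampled from this model
#' have exactly the AAMM factorization, so fitted models can be compared
#' against known parameters.
#'
#' @param alphabet_size number of symbols (taken from the amino-acid
#'   alphabet).
#' @param k Markov order.
#' @param m_true number of ground-truth abstraction blocks
#'   (`<= alphabet_size^k`).
#' @param num_classes number of classes.
#' @param concentration symmetric Dirichlet concentration for the
#'   emission draws; small values (default 0.3) give well-separated
#'   blocks.
#' @param seed integer seed.
#' @param class_priors optional class prior weights (default uniform).
#' @param length_range inclusive sequence-length interval; the lower
#'   bound must be at least `k + 1`.
#' @return an object of class `aamm_ground_truth`.
#' @export
make_ground_truth <- function(alphabet_size = 4L, k = 2L, m_true = 6L,
                              num_classes = 2L, concentration = 0.3,
                              seed = 1L, class_priors = NULL,
                              length_range = c(50L, 200L)) {
  alphabet <- aa_alphabet()[seq_len(alphabet_size)]
  k <- as.integer(k)
  N <- alphabet_size^k
  if (m_true < 1L || m_true > N) stop("m_true must be in [1, ", N, "]")
  if (length_range[1] < k + 1L) stop("minimum length must be at least k + 1")
  classes <- paste0("c", seq_len(num_classes))
  if (is.null(class_priors)) class_priors <- rep(1 / num_classes, num_classes)
  class_priors <- class_priors / sum(class_priors)

  kgrams <- sort(apply(expand.grid(rep(list(alphabet), k),
                                   stringsAsFactors = FALSE),
                       1L, paste0, collapse = ""))
  set.seed(derive_seed(seed, "ground-truth"))
  partition <- sample(rep_len(seq_len(m_true), N))
  rdirichlet <- function(n, alpha, dim) {
    g <- matrix(rgamma(n * dim, shape = alpha), nrow = n)
    g / rowSums(g)
  }
  emission <- lapply(classes, function(cl) {
    e <- rdirichlet(m_true, concentration, alphabet_size)
    dimnames(e) <- list(NULL, alphabet)
    e
  })
  names(emission) <- classes
  # successor k-gram lookup: drop the first symbol, append the emitted one
  next_kgram <- matrix(0L, N, alphabet_size)
  for (a in seq_len(alphabet_size)) {
    nxt <- paste0(substr(kgrams, 2L, k), alphabet[a])
    next_kgram[, a] <- match(nxt, kgrams)
  }
  structure(list(alphabet = alphabet, k = k, m_true = as.integer(m_true),
                 classes = classes, class_priors = class_priors,
                 kgrams = kgrams, partition = partition,
                 emission = emission,
                 initial = rep(1 / N, N),
                 next_kgram = next_kgram,
                 length_range = as.integer(length_range),
                 concentration = concentration, seed = as.integer(seed)),
            class = "aamm_ground_truth")
}

#' @export
print.aamm_ground_truth <- function(x, ...) {
  cat(sprintf("aamm_ground_truth: |X| = %d, k = %d, %d blocks, %d classes, lengths [%d, %d]\n",
              length(x$alphabet), x$k, x$m_true, length(x$classes),
              x$length_range[1], x$length_range[2]))
  invisible(x)
}

#' Abstraction map of the true partition
#'
#' Wraps the generator's block structure as an `abstraction_map`, so a
#' model can be fitted with the exact ground-truth grouping (the oracle
#' for parameter-recovery checks). Block contexts are the class-prior
#' mixture of the true emissions.
#'
#' @param spec a [make_ground_truth()] model.
#' @return an `abstraction_map` over all of the generator's k-grams.
#' @export
ground_truth_map <- function(spec) {
  stopifnot(inherits(spec, "aamm_ground_truth"))
  mix <- Reduce(`+`, Map(`*`, spec$emission, spec$class_priors))
  structure(list(kgrams = spec$kgrams, m = spec$m_true,
                 assignment = as.integer(spec$partition),
                 block_nodes = seq_len(spec$m_true),
                 block_dist = mix,
                 block_weight = as.numeric(tabulate(spec$partition, spec$m_true)),
                 alphabet = spec$alphabet, k = spec$k),
            class = "abstraction_map")
}

#' Sample a labeled dataset from a ground-truth model
#'
#' Per sequence: a class from the priors, a length uniform in the model's
#' range, an initial k-gram from the initial distribution, then successive
#' symbols from the (class, block) emission of the current k-gram.
#'
#' @param spec a [make_ground_truth()] model.
#' @param n number of sequences.
#' @param seed integer seed.
#' @param prefix id prefix (ids are `<prefix>00001`, ...).
#' @return a labeled `seq_dataset`.
#' @export
sample_dataset <- function(spec, n, seed = 1L, prefix = "syn") {
  stopifnot(inherits(spec, "aamm_ground_truth"))
  set.seed(derive_seed(seed, "sample"))
  cls <- sample.int(length(spec$classes), n, replace = TRUE,
                    prob = spec$class_priors)
  lens <- sample.int(spec$length_range[2] - spec$length_range[1] + 1L, n,
                     replace = TRUE) + spec$length_range[1] - 1L
  seqs <- .sample_chain_cpp(lens, cls, spec$emission, spec$initial,
                            spec$partition, spec$next_kgram, spec$kgrams,
                            paste(spec$alphabet, collapse = ""), spec$k)
  seq_dataset(sprintf("%s%05d", prefix, seq_len(n)), seqs,
              spec$classes[cls], alphabet = spec$alphabet)
}

#' Train/test benchmark from a ground-truth model
#'
#' Samples disjoint train and test sets and applies the labeled-fraction
#' protocol ([subsample_labeled()]) to the training set.
#'
#' @param spec a [make_ground_truth()] model.
#' @param n_train,n_test sample sizes.
#' @param labeled_fraction,unlabeled_fraction passed to
#'   [subsample_labeled()].
#' @param seed integer seed.
#' @return list with `train` (the [subsample_labeled()] result) and
#'   `test` (a fully labeled `seq_dataset` with ids disjoint from train).
#' @export
make_benchmark <- function(spec, n_train, n_test, labeled_fraction,
                           unlabeled_fraction = 0, seed = 1L) {
  train <- sample_dataset(spec, n_train, seed = derive_seed(seed, "train"),
                          prefix = "trn")
  test <- sample_dataset(spec, n_test, seed = derive_seed(seed, "test"),
                         prefix = "tst")
  list(train = subsample_labeled(train, labeled_fraction, unlabeled_fraction,
                                 seed = seed),
       test = test)
}
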