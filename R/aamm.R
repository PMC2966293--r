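#' Fit an abstraction augmented Markov model
#'
#' Estimates per-class emission distributions conditioned on abstractions
#' instead of raw k-grams: per class, the raw successor counts of an
#' abstraction's constituent k-grams are pooled and then Laplace-smoothed
#' once, `theta(sigma | a, c) = (sum_s #[s sigma] + p) / (sum_s #[s] + p |X|)`.
#' Pooling raw counts (rather than averaging smoothed leaf estimates)
#' makes the model with singleton abstractions (`m = N`) reduce exactly to
#' the plain Markov model. The initial distribution is over abstractions
#' (`m + 1` slots including one pooled unseen slot) and priors are shared
#' with the MM formulation. Each class has exactly `m * |X|` emission
#' parameters.
#'
#' @param dataset a `seq_dataset`; only labeled records are used.
#' @param map an [extract_mcut()] abstraction map.
#' @param k Markov order; must match the map's k-gram length.
#' @param smoothing Laplace pseudocount.
#' @return an object of class `aamm_params`.
#' @export
fit_aamm <- function(dataset, map, k = map$k, smoothing = 1) {
  stopifnot(inherits(map, "abstraction_map"))
  if (as.integer(k) != map$k) stop("k does not match the abstraction map")
  labeled <- labeled_subset(dataset)
  if (!n_records(labeled)) stop("no labeled sequences to fit from")
  classes <- dataset_classes(labeled)
  n_c <- table(factor(labeled$label, levels = classes))
  if (any(n_c == 0)) stop("class with zero sequences: ",
                          paste(classes[n_c == 0], collapse = ", "))
  a <- smoothing
  A <- length(map$alphabet)
  N <- length(map$kgrams)
  m <- map$m
  index <- structure(list(k = map$k, kgrams = map$kgrams, N = N,
                          alphabet = map$alphabet), class = "kgram_index")
  cnt <- count_transitions(labeled, index, per_class = TRUE)
  grp <- factor(map$assignment, levels = seq_len(m))

  emission <- lapply(classes, function(cl) {
    nx <- cnt$next_count[[cl]][seq_len(N), , drop = FALSE]
    pooled <- rowsum(nx, grp) # one row per abstraction, ordered 1..m
    e <- (pooled + a) / (rowSums(pooled) + a * A)
    if (a == 0) { # pure-MLE fits: unobserved abstractions fall back to uniform
      zero <- rowSums(pooled) == 0
      if (any(zero)) e[zero, ] <- 1 / A
    }
    rownames(e) <- NULL
    e
  })
  initial <- lapply(classes, function(cl) {
    pc <- rowsum(cnt$parent_count[[cl]][seq_len(N)], grp)[, 1L]
    tot <- sum(pc)
    c(setNames((pc + a) / (tot + a * (m + 1)), paste0("a", seq_len(m))),
      "<unseen>" = a / (tot + a * (m + 1)))
  })
  names(emission) <- names(initial) <- classes
  prior <- setNames((as.numeric(n_c) + a) / (sum(n_c) + a * length(classes)), classes)

  params <- structure(list(k = map$k, map = map, classes = classes,
                           emission = emission, initial = initial,
                           prior = prior, smoothing = a),
                      class = "aamm_params")
  check_normalized(params)
  params
}

#' @export
print.aamm_params <- function(x, ...) {
  cat(sprintf("aamm_params: order %d, %d classes, %d k-grams -> %d abstractions (%d x %d emission entries per class)\n",
              x$k, length(x$classes), length(x$map$kgrams), x$map$m,
              x$map$m, length(x$map$alphabet)))
  invisible(x)
}

#' @rdname log_likelihood
#' @export
log_likelihood.aamm_params <- function(params, seqs, class, ...) {
  if (!class %in% params$classes) stop("unknown class: ", class)
  seqs <- .as_seqs(seqs)
  map <- params$map
  alphabet <- map$alphabet
  log_unif <- -log(length(alphabet))
  log_em <- log(params$emission[[class]])
  ini <- params$initial[[class]]
  log_ini <- log(ini[seq_len(map$m)])
  log_unseen_ini <- log(ini[["<unseen>"]])
  vapply(seqs, function(s) {
    w <- seq_walk(s, params$k, alphabet, map$kgrams)
    ll <- if (is.na(w$init)) log_unseen_ini else log_ini[map$assignment[w$init]]
    if (w$n_windows) {
      ok <- !is.na(w$parent) & !is.na(w$succ)
      block <- map$assignment[w$parent[ok]]
      ll <- ll + sum(log_em[cbind(block, w$succ[ok])]) + sum(!ok) * log_unif
    }
    ll
  }, numeric(1), USE.NAMES = FALSE)
}

#' @rdname posterior
#' @export
posterior.aamm_params <- function(params, seqs, ...) .posterior_from_ll(params, seqs)

#' @rdname classify
#' @export
classify.aamm_params <- function(params, seqs, ...) {
  p <- posterior(params, seqs)
  params$classes[max.col(p, ties.method = "first")]
}

#' Semi-supervised AAMM training
#'
#' The semi-supervised recipe: the k-gram vocabulary, contexts and
#' abstraction hierarchy are learned from **all** sequences with labels
#' ignored, an m-cut is extracted, and the AAMM parameters are then fitted
#' from the labeled subset only. With no unlabeled records this collapses
#' to the labeled-only variant, AAMM(l).
#'
#' @param dataset a `seq_dataset` with at least one labeled sequence per
#'   class; unlabeled records shape the hierarchy only.
#' @param k Markov order.
#' @param m cut size (default 1500, a compression that keeps most of the
#'   context structure for protein-scale 3-gram vocabularies); values above
#'   the vocabulary size are clipped with a warning.
#' @param smoothing Laplace pseudocount for the model parameters.
#' @param context_pseudocount pseudocount for the context estimates.
#' @param scaling distance scaling, see [abstraction_distance()].
#' @return a list with components `model` (`aamm_params`), `hierarchy`
#'   (`abstraction_hierarchy`) and `map` (`abstraction_map`).
#' @export
fit_semisupervised <- function(dataset, k, m = 1500, smoothing = 1,
                               context_pseudocount = 1,
                               scaling = c("weighted", "unscaled")) {
  scaling <- match.arg(scaling)
  index <- build_kgram_index(dataset, k)
  if (index$N < 1L) stop("no k-grams observed at order ", k)
  if (m > index$N) {
    warning("m = ", m, " exceeds the vocabulary size ", index$N, "; clipped")
    m <- index$N
  }
  contexts <- kgram_contexts(dataset, index, pseudocount = context_pseudocount)
  hierarchy <- learn_hierarchy(contexts, scaling = scaling)
  map <- extract_mcut(hierarchy, m)
  model <- fit_aamm(dataset, map, k = k, smoothing = smoothing)
  list(model = model, hierarchy = hierarchy, map = map)
}
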