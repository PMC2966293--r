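#' Fit a supervised k-th order Markov model
#'
#' Maximum-likelihood estimation with Laplace smoothing of one transition
#' table per class, a class-conditional initial k-gram distribution, and
#' class priors. With pseudocount `a` and alphabet size `|X|`:
#' `theta(sigma | s, c) = (#[s sigma] + a) / (#[s] + a |X|)`,
#' `theta(s | c) = (#[s] + a) / (#parents + a (N + 1))` over the `N`
#' observed k-grams plus one pooled "unseen" slot, and
#' `prior(c) = (n_c + a) / (|D_L| + a |C|)`. `#[s]` counts `s` at parent
#' positions only, so transition and initial counts share one conservation
#' law.
#'
#' @param dataset a `seq_dataset`; only its labeled records are used.
#' @param k Markov order.
#' @param smoothing Laplace pseudocount (default 1).
#' @param index optional [build_kgram_index()]; defaults to the index of
#'   the labeled subset.
#' @return an object of class `mm_params`.
#' @export
fit_mm <- function(dataset, k, smoothing = 1, index = NULL) {
  labeled <- labeled_subset(dataset)
  if (!n_records(labeled)) stop("no labeled sequences to fit from")
  classes <- dataset_classes(labeled)
  n_c <- table(factor(labeled$label, levels = classes))
  if (any(n_c == 0)) stop("class with zero sequences: ",
                          paste(classes[n_c == 0], collapse = ", "))
  if (is.null(index)) index <- build_kgram_index(labeled, k)
  stopifnot(index$k == as.integer(k))
  a <- smoothing
  A <- length(index$alphabet)
  N <- index$N

  cnt <- count_transitions(labeled, index, per_class = TRUE)
  transition <- lapply(classes, function(cl) {
    nx <- cnt$next_count[[cl]][seq_len(N), , drop = FALSE]
    pc <- cnt$parent_count[[cl]][seq_len(N)]
    tr <- (nx + a) / (pc + a * A)
    if (a == 0) { # pure-MLE fits: contexts unseen in this class -> uniform
      zero <- pc == 0
      if (any(zero)) tr[zero, ] <- 1 / A
    }
    tr
  })
  initial <- lapply(classes, function(cl) {
    pc <- cnt$parent_count[[cl]][seq_len(N)]
    tot <- sum(pc)
    c(setNames((pc + a) / (tot + a * (N + 1)), index$kgrams),
      "<unseen>" = a / (tot + a * (N + 1)))
  })
  names(transition) <- names(initial) <- classes
  prior <- setNames((as.numeric(n_c) + a) / (sum(n_c) + a * length(classes)), classes)

  params <- structure(list(k = index$k, index = index, classes = classes,
                           transition = transition, initial = initial,
                           prior = prior, smoothing = a),
                      class = "mm_params")
  check_normalized(params)
  params
}

# every fitted distribution must sum to 1 (asserted at fit time)
check_normalized <- function(params) {
  tol <- 1e-9
  tabs <- if (inherits(params, "mm_params")) params$transition else params$emission
  for (cl in params$classes) {
    if (any(abs(rowSums(tabs[[cl]]) - 1) > tol)) {
      stop("per-context distributions of class ", cl, " do not normalize")
    }
    if (abs(sum(params$initial[[cl]]) - 1) > tol) {
      stop("initial distribution of class ", cl, " does not normalize")
    }
  }
  if (abs(sum(params$prior) - 1) > tol) stop("class priors do not normalize")
  invisible(TRUE)
}

#' @export
print.mm_params <- function(x, ...) {
  cat(sprintf("mm_params: order %d, %d classes, %d k-grams, alphabet %d, pseudocount %g\n",
              x$k, length(x$classes), x$index$N, length(x$index$alphabet), x$smoothing))
  invisible(x)
}

# decompose one sequence into its initial k-gram id and its
# (parent id, successor id) windows; NA parent = unseen or sentinel window
seq_walk <- function(seq, k, alphabet, kgrams) {
  n <- nchar(seq)
  init <- NA_integer_
  if (n >= k) {
    s0 <- substr(seq, 1L, k)
    if (!grepl(.SENTINEL, s0, fixed = TRUE)) init <- match(s0, kgrams)
  }
  if (n < k + 1L) {
    return(list(init = init, parent = integer(), succ = integer(), n_windows = 0L))
  }
  starts <- seq_len(n - k)
  kg <- substring(seq, starts, starts + k - 1L)
  sc <- substring(seq, starts + k, starts + k)
  parent <- match(kg, kgrams)
  parent[grepl(.SENTINEL, kg, fixed = TRUE)] <- NA_integer_
  succ <- match(sc, alphabet)
  list(init = init, parent = parent, succ = succ, n_windows = length(starts))
}

.as_seqs <- function(seqs) {
  if (inherits(seqs, "seq_dataset")) seqs$seq else toupper(as.character(seqs))
}

#' Sequence log-likelihood under a Markov model
#'
#' Computed entirely in log space as the log initial-k-gram probability
#' plus the sum of log transition probabilities along the sequence.
#' Sequences shorter than `k` contribute only the unseen-initial mass;
#' windows touching the sentinel, or whose k-gram was never observed in
#' training, fall back to the uniform transition `1/|X|`.
#'
#' @param params fitted model (`mm_params` or `aamm_params`).
#' @param seqs a `seq_dataset` or character vector of sequences.
#' @param class a class name in `params$classes`.
#' @param ... unused.
#' @return numeric vector of log-probabilities (one per sequence).
#' @export
log_likelihood <- function(params, seqs, class, ...) UseMethod("log_likelihood")

#' @rdname log_likelihood
#' @export
log_likelihood.mm_params <- function(params, seqs, class, ...) {
  if (!class %in% params$classes) stop("unknown class: ", class)
  seqs <- .as_seqs(seqs)
  alphabet <- params$index$alphabet
  kgrams <- params$index$kgrams
  log_unif <- -log(length(alphabet))
  log_tr <- log(params$transition[[class]])
  ini <- params$initial[[class]]
  log_ini <- log(ini[seq_len(params$index$N)])
  log_unseen_ini <- log(ini[["<unseen>"]])
  vapply(seqs, function(s) {
    w <- seq_walk(s, params$k, alphabet, kgrams)
    ll <- if (is.na(w$init)) log_unseen_ini else log_ini[w$init]
    if (w$n_windows) {
      ok <- !is.na(w$parent) & !is.na(w$succ)
      ll <- ll + sum(log_tr[cbind(w$parent[ok], w$succ[ok])]) +
        sum(!ok) * log_unif
    }
    ll
  }, numeric(1), USE.NAMES = FALSE)
}

#' Class posterior probabilities
#'
#' Applies Bayes' rule to the class-conditional sequence likelihoods and
#' the class priors; computed via a log-sum-exp softmax.
#'
#' @inheritParams log_likelihood
#' @return numeric matrix (sequences x classes), rows summing to 1.
#' @export
posterior <- function(params, seqs, ...) UseMethod("posterior")

# shared: softmax of per-class log(prior) + log-likelihood
.posterior_from_ll <- function(params, seqs) {
  scores <- vapply(params$classes,
                   function(cl) log_likelihood(params, seqs, cl) + log(params$prior[[cl]]),
                   numeric(length(.as_seqs(seqs))))
  scores <- matrix(scores, ncol = length(params$classes),
                   dimnames = list(NULL, params$classes))
  mx <- apply(scores, 1L, max)
  p <- exp(scores - mx)
  p / rowSums(p)
}

#' @rdname posterior
#' @export
posterior.mm_params <- function(params, seqs, ...) .posterior_from_ll(params, seqs)

#' Classify sequences
#'
#' Assigns the class with the highest posterior probability; exact ties go
#' to the earlier class in the model's class order.
#'
#' @inheritParams log_likelihood
#' @return character vector of predicted class names.
#' @export
classify <- function(params, seqs, ...) UseMethod("classify")

#' @rdname classify
#' @export
classify.mm_params <- function(params, seqs, ...) {
  p <- posterior(params, seqs)
  params$classes[max.col(p, ties.method = "first")]
}

#' Prediction table
#'
#' Per-record predicted class plus the full posterior, in a TSV-writable
#' data frame.
#'
#' @param params a fitted model supporting [posterior()].
#' @param dataset a `seq_dataset`.
#' @return data frame with columns `id`, `predicted`, and one posterior
#'   column per class.
#' @export
predict_table <- function(params, dataset) {
  stopifnot(inherits(dataset, "seq_dataset"))
  if (!n_records(dataset)) {
    out <- data.frame(id = character(), predicted = character())
    for (cl in params$classes) out[[cl]] <- numeric()
    return(out)
  }
  p <- posterior(params, dataset)
  out <- data.frame(id = dataset$id,
                    predicted = params$classes[max.col(p, ties.method = "first")],
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(p))
}
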