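#' EM configuration
#'
#' @param max_iterations maximum number of E/M iterations (>= 1).
#' @param tolerance convergence threshold on the maximum absolute change
#'   of any probability parameter between iterations.
#' @param unlabeled_weight weight in `[0, 1]` applied to the fractional
#'   counts contributed by unlabeled sequences (1 = classic EM; 0 makes
#'   the fit identical to the supervised model).
#' @return a list of class `em_config`.
#' @export
em_config <- function(max_iterations = 100L, tolerance = 1e-6,
                      unlabeled_weight = 1) {
  if (max_iterations < 1L) stop("max_iterations must be >= 1")
  if (tolerance <= 0) stop("tolerance must be > 0")
  if (unlabeled_weight < 0 || unlabeled_weight > 1) {
    stop("unlabeled_weight must be in [0, 1]")
  }
  structure(list(max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, unlabeled_weight = unlabeled_weight),
            class = "em_config")
}

# refit MM tables from (possibly fractional) per-class weights over all
# records; vocabulary fixed by `index`; n_eff = effective per-class counts
.mm_from_weights <- function(dataset, index, classes, weights, n_eff, smoothing) {
  a <- smoothing
  A <- length(index$alphabet)
  N <- index$N
  cnt <- count_transitions(dataset, index, weights = weights, classes = classes)
  transition <- lapply(classes, function(cl) {
    nx <- cnt$next_count[[cl]][seq_len(N), , drop = FALSE]
    (nx + a) / (cnt$parent_count[[cl]][seq_len(N)] + a * A)
  })
  initial <- lapply(classes, function(cl) {
    pc <- cnt$parent_count[[cl]][seq_len(N)]
    tot <- sum(pc)
    c(setNames((pc + a) / (tot + a * (N + 1)), index$kgrams),
      "<unseen>" = a / (tot + a * (N + 1)))
  })
  names(transition) <- names(initial) <- classes
  prior <- setNames((n_eff + a) / (sum(n_eff) + a * length(classes)), classes)
  structure(list(k = index$k, index = index, classes = classes,
                 transition = transition, initial = initial,
                 prior = prior, smoothing = a),
            class = "mm_params")
}

# Dirichlet(1 + smoothing) log-prior over every parameter entry; reported
# alongside the observed log-likelihood as the penalized objective the
# Laplace-smoothed M-step targets
.mm_log_penalty <- function(params) {
  a <- params$smoothing
  if (a == 0) return(0)
  a * (sum(vapply(params$transition, function(m) sum(log(m)), numeric(1))) +
         sum(vapply(params$initial, function(v) sum(log(v)), numeric(1))) +
         sum(log(params$prior)))
}

#' Semi-supervised Markov model via expectation maximization
#'
#' Initializes from the labeled subset, then alternates an E-step
#' (posterior class memberships for each unlabeled sequence under the
#' current model) with an M-step (refit of all tables on the hard-labeled
#' data plus the fractionally weighted unlabeled data, unlabeled counts
#' scaled by `unlabeled_weight`). Stops when no parameter moves more than
#' `tolerance`, or at `max_iterations`. The k-gram vocabulary is built
#' from all sequences so unlabeled windows can contribute.
#'
#' The returned model carries attributes `loglik_trace` (per-iteration
#' observed-data log-likelihood: full labeled term plus the weighted
#' unlabeled mixture term), `objective_trace` (the same plus the
#' smoothing log-prior), `iterations` and `converged`. The observed trace
#' is non-decreasing up to tiny numerical wiggle near convergence; exact
#' monotonicity is not guaranteed because the initial-k-gram distribution
#' is estimated from all parent positions (the convention shared with
#' [fit_mm()]) rather than from first positions only, so the M-step is a
#' very close approximation to the surrogate maximizer rather than the
#' exact one.
#'
#' @param dataset a `seq_dataset` with at least one labeled sequence per
#'   class; unlabeled records are the EM pool.
#' @param k Markov order.
#' @param config an [em_config()].
#' @param smoothing Laplace pseudocount.
#' @return an `mm_params` model with EM attributes.
#' @export
fit_em_mm <- function(dataset, k, config = em_config(), smoothing = 1) {
  stopifnot(inherits(config, "em_config"))
  labeled <- labeled_subset(dataset)
  if (!n_records(labeled)) stop("no labeled sequences to initialize from")
  classes <- dataset_classes(labeled)
  if (any(table(factor(labeled$label, levels = classes)) == 0)) {
    stop("every class needs at least one labeled sequence")
  }
  index <- build_kgram_index(dataset, k)
  lam <- config$unlabeled_weight
  is_lab <- !is.na(dataset$label)
  lab_idx <- match(dataset$label, classes)

  hard <- matrix(0, n_records(dataset), length(classes),
                 dimnames = list(NULL, classes))
  hard[cbind(which(is_lab), lab_idx[is_lab])] <- 1
  n_lab <- colSums(hard)

  params <- .mm_from_weights(dataset, index, classes, hard, n_lab, smoothing)
  unl <- which(!is_lab)
  flat <- function(p) c(unlist(p$transition), unlist(p$initial), p$prior)

  ll_obs <- function(p, post_unl) {
    ll <- 0
    for (ci in seq_along(classes)) {
      li <- which(is_lab & lab_idx == ci)
      if (length(li)) {
        ll <- ll + sum(log(p$prior[[ci]]) +
                         log_likelihood(p, dataset$seq[li], classes[ci]))
      }
    }
    if (length(unl) && lam > 0) {
      scores <- vapply(classes, function(cl) {
        log(p$prior[[cl]]) + log_likelihood(p, dataset$seq[unl], cl)
      }, numeric(length(unl)))
      scores <- matrix(scores, ncol = length(classes))
      mx <- apply(scores, 1L, max)
      ll <- ll + lam * sum(mx + log(rowSums(exp(scores - mx))))
    }
    ll
  }

  trace_obs <- numeric(0)
  trace_obj <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # E-step: posterior memberships of unlabeled records
    W <- hard
    if (length(unl) && lam > 0) {
      post <- posterior(params, dataset$seq[unl])
      W[unl, ] <- post
    }
    trace_obs <- c(trace_obs, ll_obs(params, NULL))
    trace_obj <- c(trace_obj, trace_obs[iter] + .mm_log_penalty(params))
    # M-step: weighted refit (unlabeled mass scaled by lambda)
    W[unl, ] <- W[unl, , drop = FALSE] * lam
    n_eff <- n_lab + colSums(W[unl, , drop = FALSE])
    Wnorm <- W
    new_params <- .mm_from_weights(dataset, index, classes, Wnorm, n_eff, smoothing)
    delta <- max(abs(flat(new_params) - flat(params)))
    params <- new_params
    if (delta < config$tolerance) { converged <- TRUE; break }
    if (iter >= config$max_iterations) break
  }
  trace_obs <- c(trace_obs, ll_obs(params, NULL))
  trace_obj <- c(trace_obj, trace_obs[length(trace_obs)] + .mm_log_penalty(params))

  attr(params, "loglik_trace") <- trace_obs
  attr(params, "objective_trace") <- trace_obj
  attr(params, "iterations") <- iter
  attr(params, "converged") <- converged
  params
}

#' Co-training configuration
#'
#' @param pool_size size `u` of the working unlabeled pool (default 75).
#' @param growth_total total number of confident predictions each
#'   classifier promotes per round, apportioned across classes by the
#'   labeled class distribution (default: number of classes, so each class
#'   gains at least one).
#' @param view1_length prefix length of the first view (default 60).
#' @param view2_length suffix length of the second view (default 15).
#' @param max_iterations round cap; `Inf` iterates until the unlabeled
#'   data are exhausted.
#' @param replenish `"consumed"` draws as many fresh examples as were
#'   consumed in the round; `"blum-mitchell"` draws `2 * growth_total`.
#' @return a list of class `cotrain_config`.
#' @export
cotrain_config <- function(pool_size = 75L, growth_total = NULL,
                           view1_length = 60L, view2_length = 15L,
                           max_iterations = Inf,
                           replenish = c("consumed", "blum-mitchell")) {
  if (pool_size < 1L) stop("pool_size must be >= 1")
  structure(list(pool_size = as.integer(pool_size), growth_total = growth_total,
                 view1_length = as.integer(view1_length),
                 view2_length = as.integer(view2_length),
                 max_iterations = max_iterations,
                 replenish = match.arg(replenish)),
            class = "cotrain_config")
}

#' Two feature views of a dataset
#'
#' View 1 is the sequence prefix (first `view1_length` residues, clipped to
#' the sequence length); view 2 is the suffix (last `view2_length`
#' residues). Ids and labels are preserved.
#'
#' @param dataset a `seq_dataset`.
#' @param config a [cotrain_config()].
#' @return list with `view1` and `view2` datasets.
#' @export
make_views <- function(dataset, config = cotrain_config()) {
  n <- nchar(dataset$seq)
  v1 <- substr(dataset$seq, 1L, pmin(config$view1_length, n))
  v2 <- substring(dataset$seq, pmax(1L, n - config$view2_length + 1L), n)
  al <- dataset_alphabet(dataset)
  list(view1 = seq_dataset(dataset$id, v1, dataset$label, alphabet = al),
       view2 = seq_dataset(dataset$id, v2, dataset$label, alphabet = al))
}

# largest-remainder apportionment of `total` across classes by proportions
# p (every class gets at least 1)
.apportion <- function(p, total) {
  total <- max(total, length(p))
  quota <- total * p / sum(p)
  kj <- floor(quota)
  rem <- total - sum(kj)
  if (rem > 0) {
    ord <- order(quota - kj, decreasing = TRUE)
    kj[ord[seq_len(rem)]] <- kj[ord[seq_len(rem)]] + 1
  }
  under <- kj == 0
  kj[under] <- 1
  kj
}

#' Co-training of two Markov models on prefix/suffix views
#'
#' Blum-Mitchell style co-training: two Markov models are trained on the
#' labeled data, one per view; a working pool of `pool_size` unlabeled
#' examples is maintained; each round, each classifier promotes its most
#' confident per-class predictions (confidence = maximum posterior) into
#' the shared labeled set with the predicted label, the pool is
#' replenished from the remaining unlabeled data, and both models are
#' refitted. Iterates until the unlabeled data are exhausted or
#' `max_iterations` is reached.
#'
#' @param dataset a `seq_dataset` with at least one labeled sequence per
#'   class; unlabeled records feed the pool.
#' @param k Markov order.
#' @param config a [cotrain_config()].
#' @param seed integer seed for the pool draws.
#' @param smoothing Laplace pseudocount for the view models.
#' @return an object of class `cotrain_mm` with components `h1`, `h2`
#'   (view models), `config`, and `audit` (per-round promotion log:
#'   round, id, assigned label, promoting classifier).
#' @export
cotrain <- function(dataset, k, config = cotrain_config(), seed = 1,
                    smoothing = 1) {
  stopifnot(inherits(config, "cotrain_config"))
  labeled_ids <- dataset$id[!is.na(dataset$label)]
  if (!length(labeled_ids)) stop("no labeled sequences")
  classes <- dataset_classes(dataset)
  views <- make_views(dataset, config)
  G <- if (is.null(config$growth_total)) length(classes) else config$growth_total
  pick <- function(ids) match(ids, dataset$id)

  labels <- setNames(dataset$label, dataset$id) # working labels (grow over rounds)
  unlabeled_ids <- dataset$id[is.na(dataset$label)]
  set.seed(derive_seed(seed, "cotrain-pool"))
  pool <- sample(unlabeled_ids, min(config$pool_size, length(unlabeled_ids)))
  initial_pool <- pool
  reservoir <- setdiff(unlabeled_ids, pool)

  fit_view <- function(view) {
    d <- subset_records(view, pick(names(labels)[!is.na(labels)]))
    d$label <- labels[d$id]
    fit_mm(d, k, smoothing = smoothing)
  }
  h1 <- fit_view(views$view1)
  h2 <- fit_view(views$view2)

  audit <- data.frame(round = integer(), id = character(), label = character(),
                      classifier = character(), stringsAsFactors = FALSE)
  round <- 0L
  while (length(pool) && round < config$max_iterations) {
    round <- round + 1L
    # per-class quotas follow the current labeled class distribution
    dist_now <- table(factor(labels[!is.na(labels)], levels = classes))
    kj <- .apportion(as.numeric(dist_now), G)
    moved <- character(0)
    for (hname in c("h1", "h2")) {
      h <- if (hname == "h1") h1 else h2
      view <- if (hname == "h1") views$view1 else views$view2
      avail <- setdiff(pool, moved)
      if (!length(avail)) break
      p <- posterior(h, subset_records(view, pick(avail)))
      conf <- apply(p, 1L, max)
      pred <- h$classes[max.col(p, ties.method = "first")]
      for (ci in seq_along(classes)) {
        cand <- which(pred == classes[ci])
        if (!length(cand)) next
        # ties: higher confidence first, then id order
        ord <- cand[order(-conf[cand], avail[cand])]
        take <- utils::head(ord, kj[ci])
        ids <- avail[take]
        labels[ids] <- classes[ci]
        moved <- c(moved, ids)
        if (length(ids)) {
          audit <- rbind(audit, data.frame(round = round, id = ids,
                                           label = classes[ci],
                                           classifier = hname,
                                           stringsAsFactors = FALSE))
        }
      }
    }
    if (!length(moved)) break # no promotable predictions left
    pool <- setdiff(pool, moved)
    draw <- switch(config$replenish, consumed = length(moved),
                   "blum-mitchell" = 2L * G)
    draw <- min(draw, length(reservoir))
    if (draw > 0) {
      fresh <- sample(reservoir, draw)
      pool <- c(pool, fresh)
      reservoir <- setdiff(reservoir, fresh)
    }
    h1 <- fit_view(views$view1)
    h2 <- fit_view(views$view2)
  }
  structure(list(h1 = h1, h2 = h2, config = config, classes = h1$classes,
                 audit = audit, labels = labels, rounds = round,
                 initial_pool = initial_pool),
            class = "cotrain_mm")
}

#' @export
print.cotrain_mm <- function(x, ...) {
  cat(sprintf("cotrain_mm: %d rounds, %d promoted examples\n",
              x$rounds, nrow(x$audit)))
  invisible(x)
}

#' @rdname posterior
#' @export
posterior.cotrain_mm <- function(params, seqs, ...) {
  if (inherits(seqs, "seq_dataset")) {
    views <- make_views(seqs, params$config)
  } else {
    d <- seq_dataset(paste0("q", seq_along(seqs)), seqs,
                     alphabet = params$h1$index$alphabet)
    views <- make_views(d, params$config)
  }
  # average of the two view log-posteriors (normalized geometric mean of
  # the view posteriors): when the views and models coincide this is
  # exactly the single-view posterior, and when both views agree on the
  # top class the combination preserves it
  score <- vapply(params$classes, function(cl) {
    log(params$h1$prior[[cl]]) +
      0.5 * log_likelihood(params$h1, views$view1, cl) +
      0.5 * log_likelihood(params$h2, views$view2, cl)
  }, numeric(n_records(views$view1)))
  score <- matrix(score, ncol = length(params$classes),
                  dimnames = list(NULL, params$classes))
  mx <- apply(score, 1L, max)
  p <- exp(score - mx)
  p / rowSums(p)
}

#' @rdname classify
#' @export
classify.cotrain_mm <- function(params, seqs, ...) {
  p <- posterior(params, seqs)
  params$classes[max.col(p, ties.method = "first")]
}
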