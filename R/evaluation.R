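#' Stratified k-fold assignment
#'
#' Deterministic for a fixed seed; each class is shuffled and dealt
#' round-robin, so per-fold class counts differ from exact proportionality
#' by at most one example. Cross-validation operates on labeled data only;
#' semi-supervised splits are made inside each training fold afterwards.
#'
#' @param dataset a fully labeled `seq_dataset`.
#' @param folds number of folds.
#' @param seed integer seed.
#' @return named integer vector mapping record id to fold (1..folds).
#' @export
stratified_kfold <- function(dataset, folds = 5L, seed = 1L) {
  if (any(is.na(dataset$label))) {
    stop("cross-validation requires a fully labeled dataset")
  }
  folds <- as.integer(folds)
  sizes <- table(dataset$label)
  small <- names(sizes)[sizes < folds]
  if (length(small)) {
    stop("class with fewer members than folds: ", paste(small, collapse = ", "))
  }
  set.seed(derive_seed(seed, "kfold"))
  assignment <- integer(n_records(dataset))
  for (cl in sort(names(sizes))) {
    idx <- which(dataset$label == cl)
    idx <- idx[sample.int(length(idx))]
    assignment[idx] <- rep_len(seq_len(folds), length(idx))
  }
  setNames(assignment, dataset$id)
}

#' Labeled/unlabeled subsampling of a training set
#'
#' Emulates labeled-fraction experiments: per class, records are permuted
#' once (seeded); the labeled subset `D_L` is the per-class prefix of size
#' `ceiling(fraction * n_class)` and the unlabeled pool `D_U` is drawn
#' from the per-class suffix with labels stripped. Prefix allocation makes
#' the labeled subsets nested across growing fractions at a fixed seed,
#' and suffix allocation keeps `D_U` identical while the labeled subset
#' grows; per-class proportions stay within one example of the training
#' set's.
#'
#' @param train a fully labeled `seq_dataset`.
#' @param labeled_fraction fraction in (0, 1] for `D_L`.
#' @param unlabeled_fraction fraction in \[0, 1) for `D_U`.
#' @param seed integer seed.
#' @return list with `labeled` (`D_L`), `unlabeled` (`D_U`, labels
#'   stripped) and `dataset` (their union, labels present on `D_L` only).
#' @export
subsample_labeled <- function(train, labeled_fraction, unlabeled_fraction = 0,
                              seed = 1L) {
  if (any(is.na(train$label))) stop("train must be fully labeled")
  if (labeled_fraction <= 0 || labeled_fraction > 1) {
    stop("labeled_fraction must be in (0, 1]")
  }
  if (unlabeled_fraction < 0 || unlabeled_fraction >= 1) {
    stop("unlabeled_fraction must be in [0, 1)")
  }
  set.seed(derive_seed(seed, "subsample"))
  lab_idx <- integer(0)
  unl_idx <- integer(0)
  for (cl in sort(unique(train$label))) {
    idx <- which(train$label == cl)
    idx <- idx[sample.int(length(idx))]
    q <- min(length(idx), ceiling(labeled_fraction * length(idx) - 1e-9))
    u <- ceiling(unlabeled_fraction * length(idx) - 1e-9)
    if (q + u > length(idx)) {
      stop("fractions exceed availability for class ", cl)
    }
    lab_idx <- c(lab_idx, idx[seq_len(q)])
    if (u > 0) unl_idx <- c(unl_idx, idx[seq(length(idx) - u + 1L, length(idx))])
  }
  d_l <- subset_records(train, sort(lab_idx))
  d_u <- strip_labels(subset_records(train, sort(unl_idx)))
  combined <- subset_records(train, sort(c(lab_idx, unl_idx)))
  combined$label[combined$id %in% d_u$id] <- NA_character_
  list(labeled = d_l, unlabeled = d_u, dataset = combined)
}

#' Classification accuracy
#'
#' @param predictions a [predict_table()] data frame (or any data frame
#'   with `id` and `predicted` columns).
#' @param truth a labeled `seq_dataset`, or a data frame with `id` and
#'   `label` columns.
#' @return fraction of correct predictions.
#' @export
accuracy <- function(predictions, truth) {
  if (inherits(truth, "seq_dataset")) {
    truth <- data.frame(id = truth$id, label = truth$label,
                        stringsAsFactors = FALSE)
  }
  if (!setequal(predictions$id, truth$id)) {
    stop("prediction and truth id sets differ")
  }
  ref <- truth$label[match(predictions$id, truth$id)]
  mean(predictions$predicted == ref)
}

#' Relative reduction in classification error
#'
#' The absolute difference between two error rates divided by the larger
#' of the two; 0 when both errors are 0. Symmetric in its arguments and
#' always in \[0, 1\].
#'
#' @param acc_a,acc_b accuracies as fractions in \[0, 1\].
#' @return the relative error reduction as a fraction.
#' @export
relative_error_reduction <- function(acc_a, acc_b) {
  err_a <- 1 - acc_a
  err_b <- 1 - acc_b
  m <- pmax(err_a, err_b)
  ifelse(m == 0, 0, abs(err_a - err_b) / m)
}

#' Cross-validated paired t test on fold accuracies
#'
#' Paired by fold: `d_i = a_i - b_i`, `t = mean(d) sqrt(n) / sd(d)` with
#' the sample (n-1) standard deviation, `df = n - 1`, and the two-sided
#' Student-t critical value at the given level (2.776 for 5 folds at
#' 0.05). Zero variance with nonzero mean is reported as an infinite t
#' with rejection; zero variance and zero mean gives t = 0.
#'
#' @param acc_a,acc_b equal-length (>= 2) per-fold accuracy vectors.
#' @param level two-sided significance level (default 0.05).
#' @return list of class `cv_ttest`: `t_statistic`,
#'   `degrees_of_freedom`, `critical_value`, `reject`, `infinite`.
#' @export
cv_paired_t <- function(acc_a, acc_b, level = 0.05) {
  if (length(acc_a) != length(acc_b)) stop("fold vectors differ in length")
  n <- length(acc_a)
  if (n < 2L) stop("need at least 2 folds")
  d <- acc_a - acc_b
  s <- stats::sd(d)
  infinite <- FALSE
  if (s == 0) {
    if (mean(d) == 0) t_stat <- 0
    else { t_stat <- sign(mean(d)) * Inf; infinite <- TRUE }
  } else {
    t_stat <- mean(d) * sqrt(n) / s
  }
  crit <- qt(1 - level / 2, df = n - 1L)
  structure(list(t_statistic = t_stat, degrees_of_freedom = n - 1L,
                 critical_value = crit, reject = abs(t_stat) > crit,
                 infinite = infinite),
            class = "cv_ttest")
}

#' @export
print.cv_ttest <- function(x, ...) {
  cat(sprintf("paired t = %.4g on %d df (critical %.3f): %s\n",
              x$t_statistic, x$degrees_of_freedom, x$critical_value,
              if (x$reject) "reject equal accuracy" else "no significant difference"))
  invisible(x)
}
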