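#' Residue alphabets
#'
#' `aa_alphabet()` returns the 20 canonical amino-acid one-letter codes;
#' `make_alphabet()` builds an alphabet from arbitrary single-character
#' symbols. Symbol order is fixed and defines the stable symbol index used
#' throughout the package.
#'
#' @param symbols character vector of unique single-character symbols
#'   (at least two).
#' @return character vector of class symbols.
#' @export
aa_alphabet <- function() {
  strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
}

#' @rdname aa_alphabet
#' @export
make_alphabet <- function(symbols) {
  symbols <- as.character(symbols)
  if (length(symbols) < 2L) stop("alphabet needs at least 2 symbols")
  if (anyDuplicated(symbols)) stop("alphabet symbols must be unique")
  if (any(nchar(symbols) != 1L)) stop("alphabet symbols must be single characters")
  if (.SENTINEL %in% symbols) stop("alphabet must not contain the sentinel '", .SENTINEL, "'")
  symbols
}

#' Construct a sequence dataset
#'
#' A sequence dataset holds cleaned residue strings with optional class
#' labels. Records without a label form the unlabeled pool `D_U`; labeled
#' records form `D_L`. Characters outside the alphabet are replaced by the
#' sentinel `"?"` (policy `"sentinel"`) or appended to the alphabet
#' (policy `"extend-alphabet"`).
#'
#' @param id character vector of non-empty record ids.
#' @param seq character vector of residue strings (upper-cased internally).
#' @param label optional character vector of class names; `NA` = unlabeled.
#' @param alphabet residue alphabet (see [aa_alphabet()]).
#' @param policy how to treat out-of-alphabet characters.
#' @return an object of class `seq_dataset` with fields `id`, `seq`,
#'   `label` and attribute `alphabet`.
#' @export
seq_dataset <- function(id, seq, label = NULL, alphabet = aa_alphabet(),
                        policy = c("sentinel", "extend-alphabet")) {
  policy <- match.arg(policy)
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq)) stop("id and seq lengths differ")
  if (length(id) && (anyNA(id) || any(!nzchar(id)))) stop("record ids must be non-empty")
  if (anyDuplicated(id)) stop("duplicate record ids: ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  if (length(seq) && any(!nzchar(seq))) stop("residue strings must be non-empty")
  if (is.null(label)) label <- rep(NA_character_, length(id))
  label <- as.character(label)
  if (length(label) != length(id)) stop("label length differs from id length")

  if (policy == "extend-alphabet" && length(seq)) {
    extra <- setdiff(unique(unlist(strsplit(seq, ""), use.names = FALSE)), alphabet)
    if (length(extra)) alphabet <- c(alphabet, sort(extra))
  }
  seq <- clean_residues(seq, alphabet)

  structure(list(id = id, seq = seq, label = label),
            alphabet = alphabet, class = "seq_dataset")
}

# replace every character outside the alphabet by the sentinel
clean_residues <- function(seq, alphabet) {
  if (!length(seq)) return(seq)
  pattern <- paste0("[^", paste(gsub("([][^\\\\-])", "\\\\\\1", alphabet), collapse = ""), "]")
  gsub(pattern, .SENTINEL, seq)
}

#' @export
print.seq_dataset <- function(x, ...) {
  cat(sprintf("seq_dataset: %d records (%d labeled, %d unlabeled), alphabet size %d\n",
              length(x$id), sum(!is.na(x$label)), sum(is.na(x$label)),
              length(attr(x, "alphabet"))))
  cls <- dataset_classes(x)
  if (length(cls)) cat("classes:", paste(cls, collapse = ", "), "\n")
  invisible(x)
}

#' Dataset accessors
#'
#' @param dataset a `seq_dataset`.
#' @return `dataset_classes()` returns the sorted set of observed class
#'   names; `dataset_alphabet()` the alphabet; `n_records()` the number of
#'   records; `labeled_subset()` / `unlabeled_subset()` the `D_L` / `D_U`
#'   partitions; `subset_records()` the records at index `i`.
#' @export
dataset_classes <- function(dataset) {
  sort(unique(dataset$label[!is.na(dataset$label)]))
}

#' @rdname dataset_classes
#' @export
dataset_alphabet <- function(dataset) attr(dataset, "alphabet")

#' @rdname dataset_classes
#' @export
n_records <- function(dataset) length(dataset$id)

#' @rdname dataset_classes
#' @param i integer or logical index of records to keep.
#' @export
subset_records <- function(dataset, i) {
  structure(list(id = dataset$id[i], seq = dataset$seq[i], label = dataset$label[i]),
            alphabet = attr(dataset, "alphabet"), class = "seq_dataset")
}

#' @rdname dataset_classes
#' @export
labeled_subset <- function(dataset) subset_records(dataset, !is.na(dataset$label))

#' @rdname dataset_classes
#' @export
unlabeled_subset <- function(dataset) subset_records(dataset, is.na(dataset$label))

#' Strip all class labels from a dataset
#' @param dataset a `seq_dataset`.
#' @return the dataset with every label set to `NA`.
#' @export
strip_labels <- function(dataset) {
  dataset$label <- rep(NA_character_, length(dataset$id))
  dataset
}

#' Read sequences from a FASTA file
#'
#' One record per FASTA entry; the id is the header token before the first
#' whitespace; residues are upper-cased and characters outside the alphabet
#' are replaced by the sentinel (or the alphabet is extended, depending on
#' `policy`).
#'
#' @param path path to a FASTA file.
#' @inheritParams seq_dataset
#' @return a [seq_dataset()].
#' @export
read_fasta <- function(path, alphabet = aa_alphabet(),
                       policy = c("sentinel", "extend-alphabet")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (!length(nonempty)) {
    return(seq_dataset(character(), character(), alphabet = alphabet, policy = policy))
  }
  if (!startsWith(trimws(lines[nonempty[1]]), ">")) {
    stop("malformed FASTA: sequence data before any header at line ", nonempty[1])
  }
  headers <- nonempty[startsWith(trimws(lines[nonempty]), ">")]
  # an entry is empty when its header is immediately followed by another
  # header (or end of file) with no sequence line in between
  ends <- c(headers[-1], length(lines) + 1L)
  for (h in seq_along(headers)) {
    body <- setdiff(seq(headers[h] + 1L, length.out = max(0L, ends[h] - headers[h] - 1L)),
                    headers)
    if (!length(body) || !any(nzchar(trimws(lines[body])))) {
      stop("malformed FASTA: empty sequence for header at line ", headers[h])
    }
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seq_dataset(ids, as.character(set), alphabet = alphabet, policy = policy)
}

#' Write a dataset to FASTA and to a label TSV
#'
#' @param dataset a `seq_dataset`.
#' @param path output file path.
#' @return the path, invisibly. `write_labels()` writes one
#'   `id<TAB>class` row per labeled record, no header.
#' @export
write_fasta <- function(dataset, path) {
  set <- Biostrings::BStringSet(setNames(dataset$seq, dataset$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_labels <- function(dataset, path) {
  keep <- !is.na(dataset$label)
  write.table(data.frame(id = dataset$id[keep], label = dataset$label[keep]),
              path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Attach class labels from a tab-separated file
#'
#' The file has rows `id<TAB>class` with no header. Records without a row
#' remain unlabeled. Rows whose id is absent from the dataset, or duplicate
#' ids with conflicting classes, are errors.
#'
#' @param path path to the label TSV.
#' @param dataset a `seq_dataset`.
#' @return the dataset with labels attached.
#' @export
read_labels <- function(path, dataset) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(dataset)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) {
    stop("malformed label file: row without a tab separator")
  }
  ids <- vapply(parts, `[[`, "", 1L)
  labs <- vapply(parts, `[[`, "", 2L)
  orphan <- setdiff(ids, dataset$id)
  if (length(orphan)) {
    stop("label rows for ids absent from the dataset: ",
         paste(orphan, collapse = ", "))
  }
  conflict <- vapply(split(labs, ids), function(v) length(unique(v)) > 1L, logical(1))
  if (any(conflict)) {
    stop("conflicting duplicate label rows for ids: ",
         paste(names(conflict)[conflict], collapse = ", "))
  }
  dataset$label[match(ids, dataset$id)] <- labs
  dataset
}

#' Build the observed k-gram vocabulary of a dataset
#'
#' The vocabulary contains exactly the length-`k` substrings that occur at a
#' parent position (a window followed by at least one more residue) with no
#' sentinel character inside the window or at the successor position. Ids
#' are assigned in lexicographic order, so the index is deterministic and
#' label-invariant.
#'
#' @param dataset a `seq_dataset`.
#' @param k Markov order (k-gram length), `k >= 1`.
#' @return an object of class `kgram_index` with fields `k`, `kgrams`, `N`
#'   and `alphabet`.
#' @export
build_kgram_index <- function(dataset, k) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  win <- dataset_windows(dataset, k)
  kg <- sort(unique(win$kgram))
  structure(list(k = k, kgrams = kg, N = length(kg),
                 alphabet = dataset_alphabet(dataset)),
            class = "kgram_index")
}

#' @export
print.kgram_index <- function(x, ...) {
  cat(sprintf("kgram_index: %d observed %d-grams over %d symbols\n",
              x$N, x$k, length(x$alphabet)))
  invisible(x)
}

# every (parent k-gram, successor) window of the dataset, sentinel-free;
# record column indexes into dataset$id
dataset_windows <- function(dataset, k) {
  n <- nchar(dataset$seq)
  use <- which(n >= k + 1L)
  if (!length(use)) {
    return(data.frame(record = integer(), kgram = character(),
                      succ = character(), stringsAsFactors = FALSE))
  }
  pieces <- lapply(use, function(i) {
    ni <- n[i]
    starts <- seq_len(ni - k)
    kgram <- substring(dataset$seq[i], starts, starts + k - 1L)
    succ <- substring(dataset$seq[i], starts + k, starts + k)
    data.frame(record = i, kgram = kgram, succ = succ, stringsAsFactors = FALSE)
  })
  win <- do.call(rbind, pieces)
  clean <- !grepl(.SENTINEL, win$kgram, fixed = TRUE) & win$succ != .SENTINEL
  win[clean, , drop = FALSE]
}

#' Count k-gram to successor transitions
#'
#' Tabulates how often each alphabet symbol follows each vocabulary k-gram,
#' optionally split by class. Windows touching the sentinel are skipped.
#' K-grams absent from `index` (possible when the index was built on a
#' different dataset) are accumulated in an explicit `"<unseen>"` bucket
#' rather than dropped, so count conservation holds for every scope.
#'
#' @param dataset a `seq_dataset`.
#' @param index a [build_kgram_index()] result.
#' @param per_class if `TRUE`, one count table per observed class (labeled
#'   records only, unless `weights` is supplied).
#' @param weights optional numeric matrix (records x classes, rows summing
#'   to 1) of fractional class memberships; implies per-class counts over
#'   all weighted records.
#' @param classes class names defining the weight columns (required with
#'   `weights`; defaults to the dataset's observed classes).
#' @return an object of class `transition_counts`: either a single
#'   `next_count` matrix ((N+1) x |alphabet|) with its `parent_count`
#'   vector, or per-class lists of the same.
#' @export
count_transitions <- function(dataset, index, per_class = FALSE, weights = NULL,
                              classes = NULL) {
  stopifnot(inherits(index, "kgram_index"))
  A <- length(index$alphabet)
  N <- index$N
  win <- dataset_windows(dataset, index$k)
  parent <- match(win$kgram, index$kgrams)
  parent[is.na(parent)] <- N + 1L
  succ <- match(win$succ, index$alphabet)
  keep <- !is.na(succ) # successor outside alphabet only possible off-policy
  win <- win[keep, , drop = FALSE]; parent <- parent[keep]; succ <- succ[keep]
  cell <- (succ - 1L) * (N + 1L) + parent # column-major linear index
  rown <- c(index$kgrams, "<unseen>")

  tabulate_weighted <- function(wvec) {
    m <- matrix(0, nrow = N + 1L, ncol = A, dimnames = list(rown, index$alphabet))
    if (length(cell)) {
      agg <- rowsum(wvec, group = cell)
      m[as.integer(rownames(agg))] <- agg[, 1L]
    }
    m
  }

  if (!per_class && is.null(weights)) {
    m <- tabulate_weighted(rep(1, nrow(win)))
    return(structure(list(scope = "pooled", next_count = m,
                          parent_count = rowSums(m), index = index),
                     class = "transition_counts"))
  }

  if (is.null(classes)) classes <- dataset_classes(dataset)
  if (is.null(weights)) {
    weights <- matrix(0, n_records(dataset), length(classes),
                      dimnames = list(NULL, classes))
    lab <- match(dataset$label, classes)
    ok <- which(!is.na(lab))
    weights[cbind(ok, lab[ok])] <- 1
  } else {
    weights <- as.matrix(weights)
    if (nrow(weights) != n_records(dataset)) stop("weights must have one row per record")
    if (ncol(weights) != length(classes)) stop("weights must have one column per class")
    rs <- rowSums(weights)
    if (any(rs > 1e-12 & abs(rs - 1) > 1e-6)) {
      stop("weight rows must sum to 1 (or 0 for records carrying no mass)")
    }
  }
  nc <- lapply(seq_along(classes), function(ci) tabulate_weighted(weights[win$record, ci]))
  names(nc) <- classes
  structure(list(scope = "per-class", classes = classes, next_count = nc,
                 parent_count = lapply(nc, rowSums), index = index),
            class = "transition_counts")
}
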