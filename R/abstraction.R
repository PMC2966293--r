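#' Next-symbol contexts of k-grams
#'
#' The context of a k-gram is the conditional distribution of the next
#' symbol given the k-gram, pooled over **all** sequences regardless of
#' class label — this is what lets unlabeled data shape the abstraction
#' hierarchy. The context weight is the k-gram's total parent-occurrence
#' count.
#'
#' @param dataset a `seq_dataset` (labels, if any, are ignored).
#' @param index a [build_kgram_index()] result.
#' @param pseudocount Laplace pseudocount for the context estimates
#'   (default 1; 0 gives raw relative frequencies).
#' @return an object of class `context_set`.
#' @export
kgram_contexts <- function(dataset, index, pseudocount = 1) {
  cnt <- count_transitions(dataset, index)
  N <- index$N
  A <- length(index$alphabet)
  nx <- cnt$next_count[seq_len(N), , drop = FALSE]
  w <- cnt$parent_count[seq_len(N)]
  dist <- (nx + pseudocount) / (w + pseudocount * A)
  if (pseudocount == 0) {
    zero <- w == 0
    if (any(zero)) dist[zero, ] <- 1 / A
  }
  context_set(index$kgrams, dist, w, index$alphabet, k = index$k)
}

#' Construct a context set directly
#'
#' Mainly useful for simulation and benchmarking; [kgram_contexts()] is the
#' data-driven constructor.
#'
#' @param kgrams character vector of k-gram names.
#' @param dist numeric matrix (k-grams x alphabet) of next-symbol
#'   distributions; rows must sum to 1.
#' @param weight non-negative occurrence weights, one per k-gram.
#' @param alphabet the symbol alphabet.
#' @param k the k-gram order (defaults to the name length).
#' @return an object of class `context_set`.
#' @export
context_set <- function(kgrams, dist, weight, alphabet,
                        k = nchar(kgrams[1])) {
  dist <- as.matrix(dist)
  if (nrow(dist) != length(kgrams)) stop("one dist row per k-gram required")
  if (ncol(dist) != length(alphabet)) stop("one dist column per symbol required")
  if (length(weight) != length(kgrams)) stop("one weight per k-gram required")
  if (any(weight < 0)) stop("weights must be non-negative")
  if (length(kgrams) && any(abs(rowSums(dist) - 1) > 1e-9)) {
    stop("context distributions must sum to 1")
  }
  dimnames(dist) <- list(kgrams, alphabet)
  structure(list(kgrams = kgrams, dist = dist, weight = as.numeric(weight),
                 alphabet = alphabet, k = as.integer(k)),
            class = "context_set")
}

#' Weighted Jensen-Shannon divergence
#'
#' `H(w_p p + w_q q) - w_p H(p) - w_q H(q)` with base-2 entropies:
#' the entropy of the weighted mixture minus the weighted entropies.
#' Symmetric in `(p, w_p)` vs `(q, w_q)`, non-negative, bounded by the
#' binary entropy of the weight split, and zero iff `p == q`.
#'
#' @param p,q probability vectors over the same alphabet.
#' @param w_p,w_q non-negative mixture weights summing to 1.
#' @return divergence in bits.
#' @export
js_divergence <- function(p, q, w_p = 0.5, w_q = 0.5) {
  if (length(p) != length(q)) stop("p and q must have the same length")
  if (w_p < 0 || w_q < 0) stop("mixture weights must be non-negative")
  if (abs(w_p + w_q - 1) > 1e-9) stop("mixture weights must sum to 1")
  h2 <- function(x) {
    x <- x[x > 0]
    -sum(x * log2(x))
  }
  max(0, h2(w_p * p + w_q * q) - w_p * h2(p) - w_q * h2(q))
}

#' Distance between two abstractions
#'
#' The merge criterion of the hierarchy: the weighted Jensen-Shannon
#' divergence between two contexts with count-proportional mixture
#' weights, scaled (by default) by the total occurrence weight so that
#' rarely observed abstractions merge first. Two zero-weight contexts are
#' at distance 0.
#'
#' @param dist_a,dist_b next-symbol distributions.
#' @param weight_a,weight_b occurrence weights (non-negative).
#' @param scaling `"weighted"` multiplies the divergence by
#'   `weight_a + weight_b`; `"unscaled"` drops that factor.
#' @return non-negative distance.
#' @export
abstraction_distance <- function(dist_a, weight_a, dist_b, weight_b,
                                 scaling = c("weighted", "unscaled")) {
  scaling <- match.arg(scaling)
  tot <- weight_a + weight_b
  if (tot <= 0) return(0)
  js <- js_divergence(dist_a, dist_b, weight_a / tot, weight_b / tot)
  if (scaling == "weighted") tot * js else js
}

#' Learn an abstraction hierarchy over k-grams
#'
#' Greedy agglomeration: starting from one singleton abstraction per
#' k-gram, repeatedly merge the pair of active abstractions at minimal
#' [abstraction_distance()], recording the `N - 1` merges in creation
#' (LIFO) order. A merged node's context is the count-weighted mean of its
#' children's contexts and its weight their sum, so any node's context
#' equals the direct aggregation of its constituent leaves. Ties are broken
#' by the lexicographically smallest (min node id, max node id) pair;
#' leaves carry ids `1..N` and merge step `t` creates node `N + t`.
#'
#' @param contexts a [context_set()].
#' @param scaling distance scaling, see [abstraction_distance()].
#' @return an object of class `abstraction_hierarchy` with fields
#'   `kgrams`, `merges` (`(N-1) x 2` node ids), `heights` (merge
#'   distances), `node_dist`, `node_weight`, `alphabet`, `k`.
#' @export
learn_hierarchy <- function(contexts, scaling = c("weighted", "unscaled")) {
  scaling <- match.arg(scaling)
  stopifnot(inherits(contexts, "context_set"))
  N <- length(contexts$kgrams)
  if (N < 1L) stop("empty k-gram vocabulary: nothing to agglomerate")
  res <- .agglomerate_cpp(unname(contexts$dist), contexts$weight,
                          scaling == "weighted")
  structure(list(kgrams = contexts$kgrams, N = N,
                 merges = res$merges, heights = as.numeric(res$heights),
                 node_dist = res$node_dist, node_weight = res$node_weight,
                 alphabet = contexts$alphabet, k = contexts$k,
                 scaling = scaling),
            class = "abstraction_hierarchy")
}

#' @export
print.abstraction_hierarchy <- function(x, ...) {
  cat(sprintf("abstraction_hierarchy: %d leaves, %d merges (%s scaling)\n",
              x$N, nrow(x$merges), x$scaling))
  invisible(x)
}

# leaf ids under each node id (1-based; internal node N+t was made at step t)
.node_leaves <- function(hierarchy, node) {
  N <- hierarchy$N
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (nd <= N) out <- c(out, nd)
    else stack <- c(stack, hierarchy$merges[nd - N, ])
  }
  sort(out)
}

#' Extract an m-cut from an abstraction hierarchy
#'
#' Undoes the last `m - 1` merges from the top of the LIFO merge stack; the
#' remaining active nodes are the `m` abstractions, whose leaf sets
#' partition the k-gram vocabulary. `m = 1` gives the root (all k-grams in
#' one abstraction); `m = N` gives singleton abstractions.
#'
#' @param hierarchy an [learn_hierarchy()] result.
#' @param m cut size, `1 <= m <= N`.
#' @return an object of class `abstraction_map` with the total assignment
#'   of k-gram ids to abstraction ids `1..m`, and per-abstraction contexts.
#' @export
extract_mcut <- function(hierarchy, m) {
  stopifnot(inherits(hierarchy, "abstraction_hierarchy"))
  N <- hierarchy$N
  m <- as.integer(m)
  if (m < 1L || m > N) stop("m must be in [1, ", N, "]")
  active <- if (N == 1L) 1L else 2L * N - 1L
  if (N > 1L && m > 1L) {
    for (step in (N - 1L):(N - m + 1L)) {
      node <- N + step
      active <- c(setdiff(active, node), hierarchy$merges[step, ])
    }
  }
  active <- sort(active)
  assignment <- integer(N)
  for (b in seq_along(active)) assignment[.node_leaves(hierarchy, active[b])] <- b
  structure(list(kgrams = hierarchy$kgrams, m = m, assignment = assignment,
                 block_nodes = active,
                 block_dist = hierarchy$node_dist[active, , drop = FALSE],
                 block_weight = hierarchy$node_weight[active],
                 alphabet = hierarchy$alphabet, k = hierarchy$k),
            class = "abstraction_map")
}

#' @export
print.abstraction_map <- function(x, ...) {
  cat(sprintf("abstraction_map: %d k-grams -> %d abstractions\n",
              length(x$kgrams), x$m))
  invisible(x)
}

#' Write an m-cut assignment to TSV
#'
#' One `kgram<TAB>abstraction_id` row per k-gram, no header.
#'
#' @param map an [extract_mcut()] result.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_mcut <- function(map, path) {
  write.table(data.frame(kgram = map$kgrams, abstraction_id = map$assignment),
              path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a hierarchy as a Newick string
#'
#' Leaves are named by their k-grams; each child branch of an internal node
#' carries that node's merge distance as its branch length. The output is
#' parseable by standard tree readers (e.g. `ape::read.tree`).
#'
#' @param hierarchy an [learn_hierarchy()] result.
#' @return a single Newick string, terminated by `";"`.
#' @export
export_newick <- function(hierarchy) {
  N <- hierarchy$N
  if (N == 1L) return(paste0(hierarchy$kgrams, ";"))
  str <- character(2L * N - 1L)
  str[seq_len(N)] <- hierarchy$kgrams
  for (step in seq_len(N - 1L)) {
    l <- hierarchy$merges[step, 1L]
    r <- hierarchy$merges[step, 2L]
    d <- sprintf("%.10g", hierarchy$heights[step])
    str[N + step] <- paste0("(", str[l], ":", d, ",", str[r], ":", d, ")")
  }
  paste0(str[2L * N - 1L], ";")
}
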