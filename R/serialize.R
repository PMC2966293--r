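#' Save and load fitted models as JSON
#'
#' A single JSON document holds the model type, order, alphabet,
#' vocabulary, all probability tables and smoothing metadata; for AAMMs
#' the m-cut assignment array (one abstraction index per unique k-gram)
#' and block contexts are included. Numbers are written at full precision
#' so a round-trip reproduces the model exactly.
#'
#' @param params an `mm_params` or `aamm_params` model.
#' @param path output path.
#' @return `write_model()` the path, invisibly; `read_model()` the model.
#' @export
write_model <- function(params, path) {
  doc <- if (inherits(params, "mm_params")) {
    list(type = "mm", k = params$k, smoothing = params$smoothing,
         alphabet = params$index$alphabet, kgrams = params$index$kgrams,
         classes = params$classes,
         transition = lapply(params$transition, unname),
         initial = params$initial, prior = params$prior)
  } else if (inherits(params, "aamm_params")) {
    list(type = "aamm", k = params$k, smoothing = params$smoothing,
         alphabet = params$map$alphabet, kgrams = params$map$kgrams,
         classes = params$classes, m = params$map$m,
         assignment = params$map$assignment,
         block_nodes = params$map$block_nodes,
         block_dist = unname(params$map$block_dist),
         block_weight = params$map$block_weight,
         emission = lapply(params$emission, unname),
         initial = params$initial, prior = params$prior)
  } else stop("unsupported model type")
  # digits = I(17): shortest representation that reproduces each double
  # bit-exactly on re-read
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  classes <- doc$classes
  named_dists <- function(lst, names_) {
    out <- lapply(classes, function(cl) setNames(unlist(lst[[cl]]), names_))
    names(out) <- classes
    out
  }
  prior <- setNames(unlist(doc$prior), classes)
  if (doc$type == "mm") {
    index <- structure(list(k = doc$k, kgrams = doc$kgrams,
                            N = length(doc$kgrams), alphabet = doc$alphabet),
                       class = "kgram_index")
    transition <- lapply(classes, function(cl) {
      m <- as.matrix(doc$transition[[cl]])
      dimnames(m) <- list(doc$kgrams, doc$alphabet)
      m
    })
    names(transition) <- classes
    structure(list(k = doc$k, index = index, classes = classes,
                   transition = transition,
                   initial = named_dists(doc$initial, c(doc$kgrams, "<unseen>")),
                   prior = prior, smoothing = doc$smoothing),
              class = "mm_params")
  } else if (doc$type == "aamm") {
    bd <- as.matrix(doc$block_dist)
    dimnames(bd) <- list(NULL, doc$alphabet)
    map <- structure(list(kgrams = doc$kgrams, m = doc$m,
                          assignment = as.integer(doc$assignment),
                          block_nodes = as.integer(doc$block_nodes),
                          block_dist = bd,
                          block_weight = as.numeric(doc$block_weight),
                          alphabet = doc$alphabet, k = doc$k),
                     class = "abstraction_map")
    emission <- lapply(classes, function(cl) {
      m <- as.matrix(doc$emission[[cl]])
      dimnames(m) <- list(NULL, doc$alphabet)
      m
    })
    names(emission) <- classes
    structure(list(k = doc$k, map = map, classes = classes,
                   emission = emission,
                   initial = named_dists(doc$initial,
                                         c(paste0("a", seq_len(doc$m)), "<unseen>")),
                   prior = prior, smoothing = doc$smoothing),
              class = "aamm_params")
  } else stop("unknown model type: ", doc$type)
}
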