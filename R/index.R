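#' Build the capped kmer-to-isoform index over a reference transcriptome
#'
#' Sketches every reference isoform and inverts the sketches into an
#' occurrence map from each sketched kmer to the set of isoforms that
#' contain it. Kmers found in more than `cap_b` isoforms are dropped from
#' the map altogether ("common" kmers that would blow up the search
#' space); their occurrences still count inside each isoform's sketch
#' multiset, which keeps the similarity denominator a property of the
#' sequences rather than of the corpus.
#'
#' @param reference Named character vector of isoform sequences, or a
#'   `Biostrings::DNAStringSet`. Names are the isoform IDs and must be
#'   unique; the reference must be non-empty.
#' @param params A [sketch_params()] object.
#' @param cap_b Maximum number of isoforms a kmer may occur in and still
#'   be indexed (default 16).
#' @return An object of class `kmer_index` with fields `map` (an
#'   environment keyed by kmer hash, each value a sorted character vector
#'   of isoform IDs), `cap_b`, `params`, `sketches` (per-isoform
#'   `kmer_sketch` objects) and `lengths` (named integer, bp).
#' @examples
#' ref <- c(t1 = paste(rep("ACGT", 30), collapse = ""))
#' idx <- build_index(ref, sketch_params(k = 5, gamma = 1), cap_b = 4)
#' @export
build_index <- function(reference, params = sketch_params(), cap_b = 16) {
  if (inherits(reference, "DNAStringSet")) {
    reference <- stats::setNames(as.character(reference), names(reference))
  }
  reference <- unlist(reference)
  if (length(reference) == 0) stop("reference transcriptome is empty")
  ids <- names(reference)
  if (is.null(ids) || any(is.na(ids)) || any(ids == ""))
    stop("every reference isoform needs an ID (names of `reference`)")
  if (anyDuplicated(ids)) stop("duplicate isoform IDs in reference")
  stopifnot(inherits(params, "sketch_params"), cap_b >= 1)

  sketches <- lapply(seq_along(reference), function(i)
    sketch_sequence(reference[[i]], ids[[i]], params))
  names(sketches) <- ids

  # invert: distinct (kmer, isoform) pairs, then cap on occupancy
  kh <- lapply(sketches, function(s) unique(s$hash))
  pair_iso <- rep(ids, lengths(kh))
  pair_hash <- unlist(kh, use.names = FALSE)
  occ <- split(pair_iso, hash_key(pair_hash))
  occ <- occ[lengths(occ) <= cap_b]
  occ <- lapply(occ, sort)

  map <- list2env(occ, envir = new.env(parent = emptyenv()),
                  hash = TRUE, size = max(length(occ), 29L))
  structure(
    list(map = map, cap_b = as.integer(cap_b), params = params,
         sketches = sketches,
         lengths = stats::setNames(nchar(reference), ids)),
    class = "kmer_index"
  )
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("kmer_index: %d isoforms, %d indexed kmers (cap_b=%d, k=%d, gamma=%g)\n",
              length(x$sketches), length(x$map), x$cap_b,
              x$params$k, x$params$gamma))
  invisible(x)
}

#' Resolve the candidate isoform set of a query sketch
#'
#' Computes the search space `S(q)` (all isoforms sharing at least one
#' indexed sketched kmer with the query) and the best-match set `M(q)`
#' (the isoforms attaining the maximum number of distinct shared sketched
#' kmers; multiplicity is ignored at this stage).
#'
#' @param query_sketch A `kmer_sketch` of the query read.
#' @param index A `kmer_index`.
#' @return An object of class `candidate_set` with fields `query_id`,
#'   `search_space`, `best_matches` (both sorted character vectors) and
#'   `max_shared_unique`. Empty sets (and `max_shared_unique = 0`) when no
#'   query kmer is indexed.
#' @export
resolve_candidates <- function(query_sketch, index) {
  stopifnot(inherits(query_sketch, "kmer_sketch"),
            inherits(index, "kmer_index"))
  keys <- unique(hash_key(query_sketch$hash))
  hits <- if (length(keys))
    mget(keys, envir = index$map, ifnotfound = list(NULL)) else list()
  isos <- unlist(hits, use.names = FALSE)
  if (is.null(isos) || length(isos) == 0) {
    return(structure(
      list(query_id = query_sketch$sequence_id,
           search_space = character(0), best_matches = character(0),
           max_shared_unique = 0L),
      class = "candidate_set"))
  }
  # each hit list element holds distinct kmers' isoform sets, so counting
  # isoform multiplicity across elements counts distinct shared kmers
  counts <- table(isos)
  mx <- max(counts)
  structure(
    list(query_id = query_sketch$sequence_id,
         search_space = sort(names(counts)),
         best_matches = sort(names(counts)[counts == mx]),
         max_shared_unique = as.integer(mx)),
    class = "candidate_set"
  )
}

#' Serialize the occurrence map of an index to a plain-text table
#'
#' One row per indexed kmer: the hash value and the comma-separated,
#' sorted isoform IDs containing it. Intended for debugging and
#' round-trip checks, not a stable interchange format.
#'
#' @param index A `kmer_index`.
#' @param path Output TSV path.
#' @export
write_occurrence_map <- function(index, path) {
  stopifnot(inherits(index, "kmer_index"))
  keys <- sort(names(as.list(index$map)))
  vals <- vapply(keys, function(k) paste(get(k, envir = index$map),
                                         collapse = ","), character(1))
  utils::write.table(
    data.frame(kmer_hash = keys, isoforms = vals, stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load an occurrence map written by [write_occurrence_map()]
#'
#' @param path TSV path.
#' @return An environment keyed by kmer hash, values sorted character
#'   vectors of isoform IDs (same shape as `kmer_index$map`).
#' @export
read_occurrence_map <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  occ <- lapply(strsplit(tab$isoforms, ",", fixed = TRUE), sort)
  names(occ) <- tab$kmer_hash
  list2env(occ, envir = new.env(parent = emptyenv()),
           hash = TRUE, size = max(length(occ), 29L))
}
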