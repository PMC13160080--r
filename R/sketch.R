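#' Sketching parameters
#'
#' Bundle of the FracMinHash sketch settings: the kmer length `k` and the
#' sketch fraction `gamma`. The hash codomain is the 2k-bit integer range
#' `[0, M]` with `M = 4^k - 1`; a kmer occurrence is retained in the sketch
#' when its hash is at most `floor(gamma * M)`, so `gamma` is the expected
#' fraction of kmers kept.
#'
#' @param k Kmer length in bp (default 22). Must be in `[1, 26]` so that
#'   hash values remain exactly representable as R doubles.
#' @param gamma Sketch fraction in `(0, 1]` (default 0.1).
#' @return An object of class `sketch_params` with fields `k`, `gamma`,
#'   `hash_space_max` (M) and `threshold` (the retention cutoff).
#' @examples
#' p <- sketch_params(k = 5, gamma = 0.5)
#' p$threshold / p$hash_space_max  # ~0.5
#' @export
sketch_params <- function(k = 22, gamma = 0.1) {
  stopifnot(length(k) == 1, length(gamma) == 1)
  k <- as.integer(k)
  if (is.na(k) || k < 1 || k > 26) stop("k must be an integer in [1, 26]")
  if (!is.finite(gamma) || gamma <= 0 || gamma > 1)
    stop("gamma must be in (0, 1]")
  M <- 4^k - 1
  structure(
    list(k = k, gamma = gamma, hash_space_max = M,
         threshold = floor(gamma * M)),
    class = "sketch_params"
  )
}

#' @export
print.sketch_params <- function(x, ...) {
  cat(sprintf("sketch_params: k=%d gamma=%g (M=%.0f, keep hash <= %.0f)\n",
              x$k, x$gamma, x$hash_space_max, x$threshold))
  invisible(x)
}

#' Hash kmers with the invertible 2k-bit mixing function
#'
#' Applies the 64-bit integer mixing hash used by minimizer-based read
#' mappers, restricted to the low 2k bits of the kmer's 2-bit encoding.
#' Restricted this way the map is a bijection on the kmer domain, so two
#' distinct kmers of the same length can never collide.
#'
#' @param kmers Character vector of kmers, each of length `params$k` over
#'   `{A,C,G,T}` (case-insensitive). Kmers containing any other symbol are
#'   rejected and hash to `NA`.
#' @param params A [sketch_params()] object.
#' @return Numeric vector of hash values in `[0, hash_space_max]`
#'   (exact integers stored as doubles), `NA` for rejected kmers.
#' @examples
#' p <- sketch_params(k = 3)
#' hash_kmer(c("ACG", "TTT"), p)
#' @export
hash_kmer <- function(kmers, params = sketch_params()) {
  stopifnot(inherits(params, "sketch_params"))
  cpp_hash_kmers(as.character(kmers), params$k)
}

#' Invert a kmer hash back to its nucleotide string
#'
#' @param hashes Numeric vector of hash values produced by [hash_kmer()].
#' @param params The [sketch_params()] the hashes were computed under.
#' @return Character vector of kmers.
#' @export
unhash_kmer <- function(hashes, params = sketch_params()) {
  stopifnot(inherits(params, "sketch_params"))
  cpp_unhash_kmers(as.numeric(hashes), params$k)
}

#' Sketch a nucleotide sequence
#'
#' Computes the positional FracMinHash sketch of a sequence: every kmer
#' occurrence whose hash falls at or below `gamma * M` is kept together
#' with its 0-based start offset, so a kmer occurring t times contributes
#' t entries. Kmer windows containing a non-ACGT character are skipped.
#'
#' @param seq A single nucleotide string (anything coercible by
#'   `as.character`). Empty or shorter-than-k sequences yield an empty
#'   sketch.
#' @param sequence_id Identifier stored with the sketch.
#' @param params A [sketch_params()] object.
#' @return An object of class `kmer_sketch` with fields `sequence_id`,
#'   `length_bp`, `pos` (0-based starts, strictly increasing), `hash`
#'   (parallel to `pos`), `n_kmers` (count of valid kmer windows),
#'   `multiset_size` (number of retained occurrences) and `unique_count`
#'   (number of distinct retained kmers).
#' @examples
#' p <- sketch_params(k = 4, gamma = 0.25)
#' sk <- sketch_sequence("ACGTACGTACGT", "toy", p)
#' sk$multiset_size
#' @export
sketch_sequence <- function(seq, sequence_id = "", params = sketch_params()) {
  stopifnot(inherits(params, "sketch_params"))
  seq <- as.character(seq)
  stopifnot(length(seq) == 1)
  res <- cpp_sketch(seq, params$k, params$threshold)
  structure(
    list(sequence_id = as.character(sequence_id),
         length_bp = nchar(seq),
         pos = res$pos,
         hash = res$hash,
         n_kmers = res$n_kmers,
         multiset_size = length(res$pos),
         unique_count = length(unique(res$hash)),
         params = params),
    class = "kmer_sketch"
  )
}

#' @export
print.kmer_sketch <- function(x, ...) {
  cat(sprintf(
    "kmer_sketch '%s': %d bp, %d/%d kmer occurrences retained (%d distinct)\n",
    x$sequence_id, x$length_bp, x$multiset_size, x$n_kmers, x$unique_count))
  invisible(x)
}

#' Kmer strings of a sketch
#'
#' Decodes the retained kmers of a sketch back to nucleotide strings via
#' the inverse of the sketch hash.
#'
#' @param sketch A `kmer_sketch`.
#' @return Character vector parallel to `sketch$pos`.
#' @export
sketch_kmers <- function(sketch) {
  stopifnot(inherits(sketch, "kmer_sketch"))
  unhash_kmer(sketch$hash, sketch$params)
}

#' Reverse complement of a nucleotide string
#'
#' @param seq Character vector of sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  cpp_revcomp(as.character(seq))
}

# hash values as stable map keys (exact integers below 2^53)
hash_key <- function(h) sprintf("%.0f", h)
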