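# Shared fixtures and independent brute-force oracles for the test suite.

hash_key <- isosieve:::hash_key

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# every kmer of a sequence by direct substring extraction
all_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  vapply(seq_len(n - k + 1), function(i) substr(seq, i, i + k - 1),
         character(1))
}

# brute-force sketch: enumerate every kmer, hash each, apply the cutoff
brute_sketch_kmers <- function(seq, params) {
  km <- all_kmers(seq, params$k)
  if (length(km) == 0) return(character(0))
  h <- hash_kmer(km, params)
  km[!is.na(h) & h <= params$threshold]
}

# exhaustive chain oracle: enumerate every subset of anchors and keep the
# largest one that is strictly increasing in both coordinates
oracle_chain_exhaustive <- function(q_pos, r_pos) {
  n <- length(q_pos)
  stopifnot(n <= 15)
  best <- 0L
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    if (length(idx) <= best) next
    o <- idx[order(q_pos[idx], r_pos[idx])]
    if (all(diff(q_pos[o]) > 0) && all(diff(r_pos[o]) > 0))
      best <- length(idx)
  }
  best
}

# quadratic longest-colinear-subsequence oracle (independent of the
# banded two-track DP): after sorting by (q, r) any valid chain is a
# subsequence of the sorted order, so a plain LIS-style recursion over
# all predecessor pairs is exact
oracle_chain_quadratic <- function(q_pos, r_pos) {
  n <- length(q_pos)
  if (n == 0) return(0L)
  o <- order(q_pos, r_pos)
  q <- q_pos[o]; r <- r_pos[o]
  L <- rep(1L, n)
  for (i in seq_len(n)) {
    pred <- which(q < q[i] & r < r[i])
    if (length(pred)) L[i] <- 1L + max(L[pred])
  }
  max(L)
}

# random anchor table with possibly repeated coordinates
random_anchor_table <- function(n_max = 12, coord_max = 100) {
  n <- sample.int(n_max, 1)
  a <- data.frame(q_pos = sample.int(coord_max, n, replace = TRUE) - 1L,
                  r_pos = sample.int(coord_max, n, replace = TRUE) - 1L)
  a[order(a$q_pos, a$r_pos), , drop = FALSE]
}

# brute-force inverted index: kmer string -> isoforms containing it in
# their sketch, capped at cap_b
brute_occurrence_map <- function(reference, params, cap_b) {
  per_iso <- lapply(reference, function(s) unique(brute_sketch_kmers(s, params)))
  km <- unlist(per_iso, use.names = FALSE)
  iso <- rep(names(reference), lengths(per_iso))
  occ <- split(iso, km)
  occ <- occ[lengths(occ) <= cap_b]
  lapply(occ, sort)
}

# small reusable toy transcriptome (built once per test run)
toy_tx <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_transcriptome(n_genes = 8, seed = 42)
    cache
  }
})
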