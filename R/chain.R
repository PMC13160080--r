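#' Anchor table between a query sketch and a reference sketch
#'
#' Lists every exact sketched-kmer match between the two sequences as an
#' anchor `(q_pos, r_pos)`. A kmer occurring a times on the query and b
#' times on the reference contributes a*b anchors (the Cartesian product
#' of its occurrences). When an index is supplied, kmers dropped by its
#' occupancy cap contribute no anchors.
#'
#' @param query_sketch,ref_sketch `kmer_sketch` objects built with the
#'   same [sketch_params()].
#' @param index Optional `kmer_index`; restricts anchors to indexed kmers.
#' @return A data.frame with columns `q_pos`, `r_pos`, `hash`, sorted by
#'   `q_pos` then `r_pos`. Zero rows when nothing is shared.
#' @export
build_anchor_table <- function(query_sketch, ref_sketch, index = NULL) {
  stopifnot(inherits(query_sketch, "kmer_sketch"),
            inherits(ref_sketch, "kmer_sketch"))
  allowed <- NULL
  if (!is.null(index)) {
    stopifnot(inherits(index, "kmer_index"))
    qh <- unique(query_sketch$hash)
    if (length(qh)) {
      present <- vapply(hash_key(qh), exists, logical(1),
                        envir = index$map, inherits = FALSE)
      allowed <- qh[present]
    } else {
      allowed <- numeric(0)
    }
  }
  cpp_anchor_table(query_sketch$pos, query_sketch$hash,
                   ref_sketch$pos, ref_sketch$hash, allowed)
}

#' Banded two-track colinear chaining of an anchor table
#'
#' Finds the chain (subsequence of anchors strictly increasing in both
#' the query and reference coordinate) containing the most anchors, using
#' a two-track dynamic program: for each anchor the first track scores
#' the best chain that ends with it and the second the best chain that
#' omits it. Predecessors are scanned backwards inside a band that
#' stretches until at least `band_m` distinct query positions and
#' `band_m` distinct reference positions have been seen, so runs of
#' anchors from a repeated kmer are skipped over rather than exhausting
#' the band. Alongside the score the DP propagates the chain's first and
#' last anchors and the largest absolute diagonal gap
#' `|g| = |(q_i - q_j) - (r_i - r_j)|` between consecutive chain anchors;
#' a large `|g|` flags an insertion or deletion of sequence relative to
#' the reference (e.g. a retained or skipped exon).
#'
#' @param anchors Anchor data.frame from [build_anchor_table()].
#' @param band_m Band width in distinct kmers (default 3).
#' @return An object of class `chain_result`: `score` (anchors in the
#'   optimal chain; 0 iff the table is empty), `first_anchor` and
#'   `last_anchor` (each `c(q_pos, r_pos)`, NA when score is 0),
#'   `largest_gap`, and `track` ("a" or "n").
#' @examples
#' a <- data.frame(q_pos = c(0L, 10L, 50L), r_pos = c(0L, 10L, 110L))
#' chain_anchors(a)$largest_gap  # 60
#' @export
chain_anchors <- function(anchors, band_m = 3) {
  res <- cpp_chain(as.integer(anchors$q_pos), as.integer(anchors$r_pos),
                   as.integer(band_m))
  structure(
    list(score = res$score,
         first_anchor = c(q_pos = res$fp_q, r_pos = res$fp_r),
         last_anchor = c(q_pos = res$lp_q, r_pos = res$lp_r),
         largest_gap = res$largest_gap,
         track = res$track),
    class = "chain_result"
  )
}

#' @export
print.chain_result <- function(x, ...) {
  cat(sprintf("chain_result: score=%d largest_gap=%d [%s]\n",
              x$score, x$largest_gap,
              if (x$score > 0)
                sprintf("(%d,%d)..(%d,%d)", x$first_anchor[1],
                        x$first_anchor[2], x$last_anchor[1], x$last_anchor[2])
              else "empty"))
  invisible(x)
}

# multiset Jaccard-style similarity from a chain score and the two raw
# sketch multiset sizes
chain_similarity <- function(score, q_multiset, r_multiset) {
  if (score < 1) return(0)
  score / (r_multiset + q_multiset - score)
}

#' Similarity score over the best-match isoforms
#'
#' Given one chain per candidate isoform, computes the chain-based
#' multiset similarity `s / (|{F(r)}| + |{F(q)}| - s)` for each (s the
#' chain score, the denominators the raw sketch multiset sizes) and
#' returns the maximizing isoform and score. The denominator uses the
#' full sketches, including kmers the index cap dropped.
#'
#' @param query_sketch The query `kmer_sketch`.
#' @param chains Named list of `chain_result`s, one per isoform of M(q).
#' @param index The `kmer_index` (provides reference multiset sizes).
#' @return List with `isoform` (NA when `chains` is empty; ties broken
#'   toward the lexicographically smallest ID), `similarity` in `[0,1]`,
#'   and `per_isoform` (named numeric of all similarities).
#' @export
similarity_score <- function(query_sketch, chains, index) {
  if (length(chains) == 0)
    return(list(isoform = NA_character_, similarity = 0,
                per_isoform = numeric(0)))
  sims <- vapply(names(chains), function(r) {
    chain_similarity(chains[[r]]$score, query_sketch$multiset_size,
                     index$sketches[[r]]$multiset_size)
  }, numeric(1))
  ord <- order(-sims, names(chains))
  list(isoform = names(chains)[ord[1]], similarity = sims[[ord[1]]],
       per_isoform = sims)
}

#' Pseudo-align one read against the reference index
#'
#' Sketches the read in both orientations, resolves the candidate
#' isoforms of each, chains the anchor table against every best-match
#' isoform, keeps the orientation whose best chain score is higher (ties
#' go to the forward strand), and scores the winning orientation's
#' candidates with the multiset similarity. Reads sharing no indexed
#' kmer with any isoform in either orientation come back unmapped.
#'
#' @param seq Read sequence (character).
#' @param read_id Read identifier.
#' @param index A `kmer_index`.
#' @param band_m Chaining band width (default 3).
#' @return An object of class `pseudo_alignment`. When `mapped` is TRUE
#'   it carries `isoform_id`, `orientation` ("+"/"-"), `chain` (the
#'   winning isoform's `chain_result`), `similarity`, `chains` and
#'   `similarities` over all of M(q), `query_len_bp`, `ref_len_bp`,
#'   `q_multiset_size`, `r_multiset_size` and `n_candidates` (|S(q)|).
#' @export
pseudoalign <- function(seq, read_id, index, band_m = 3) {
  stopifnot(inherits(index, "kmer_index"))
  orientations <- list(
    "+" = sketch_sequence(seq, read_id, index$params),
    "-" = sketch_sequence(revcomp(seq), read_id, index$params)
  )
  best <- NULL
  for (ori in c("+", "-")) {
    sk <- orientations[[ori]]
    cand <- resolve_candidates(sk, index)
    if (length(cand$best_matches) == 0) next
    chains <- lapply(cand$best_matches, function(r) {
      anc <- build_anchor_table(sk, index$sketches[[r]], index)
      chain_anchors(anc, band_m)
    })
    names(chains) <- cand$best_matches
    top <- max(vapply(chains, `[[`, numeric(1), "score"))
    if (is.null(best) || top > best$top) {
      best <- list(ori = ori, sketch = sk, cand = cand, chains = chains,
                   top = top)
    }
  }
  if (is.null(best)) {
    return(structure(list(query_id = read_id, mapped = FALSE,
                          query_len_bp = nchar(seq)),
                     class = "pseudo_alignment"))
  }
  sc <- similarity_score(best$sketch, best$chains, index)
  iso <- sc$isoform
  structure(
    list(query_id = read_id, mapped = TRUE,
         isoform_id = iso, orientation = best$ori,
         chain = best$chains[[iso]],
         similarity = sc$similarity, similarities = sc$per_isoform,
         chains = best$chains,
         query_len_bp = nchar(seq), ref_len_bp = index$lengths[[iso]],
         q_multiset_size = best$sketch$multiset_size,
         r_multiset_size = index$sketches[[iso]]$multiset_size,
         n_candidates = length(best$cand$search_space)),
    class = "pseudo_alignment"
  )
}

#' @export
print.pseudo_alignment <- function(x, ...) {
  if (!x$mapped) {
    cat(sprintf("pseudo_alignment '%s': unmapped\n", x$query_id))
  } else {
    cat(sprintf(
      "pseudo_alignment '%s' -> %s (%s): score=%d I=%.3f gap=%d\n",
      x$query_id, x$isoform_id, x$orientation, x$chain$score,
      x$similarity, x$chain$largest_gap))
  }
  invisible(x)
}
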