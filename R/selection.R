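#' Read-selection parameters
#'
#' Thresholds driving the classification of pseudo-aligned reads.
#'
#' @param n Expected minimum exon length in bp (default 30); gaps or
#'   query overhangs longer than this flag a splicing event.
#' @param z 5'/3' first-match bound in bp (default 100): the distance
#'   within which ~90 percent of reads see their first sketched kmer
#'   match, used to separate truncation from terminal novelty.
#' @param B Expected maximum similarity score of a novel read (default
#'   0.98); read groups whose mean similarity reaches B are never
#'   selected as alternative start/stop candidates.
#' @param c Candidate scale factor (default 1.5): the expected ratio of
#'   non-AS novel reads to AS novel reads, which sets the alternative
#'   start/stop selection budget.
#' @param l Per-isoform subsample size for quantify mode (default 5).
#' @param e Assumed per-base sequencing error rate (default 0.002).
#' @param mode `"discovery"` or `"quantify"`.
#' @return An object of class `selection_params`.
#' @export
selection_params <- function(n = 30, z = 100, B = 0.98, c = 1.5, l = 5,
                             e = 0.002, mode = c("discovery", "quantify")) {
  mode <- match.arg(mode)
  stopifnot(n >= 1, z >= 0, B > 0, B <= 1, c >= 0, l >= 1, e >= 0, e < 1)
  structure(list(n = n, z = z, B = B, c = c, l = as.integer(l), e = e,
                 mode = mode),
            class = "selection_params")
}

#' Unmatched 5'/3' overhangs of a pseudo-alignment
#'
#' From the first and last anchors of the optimal chain, the lengths of
#' query sequence, respectively reference sequence, left unexplained at
#' either end:
#' `O(q) = max(0, FP_q - FP_r, (|q| - LP_q) - (|r| - LP_r))` and
#' `O(r) = max(0, FP_r - FP_q, (|r| - LP_r) - (|q| - LP_q))`.
#' A large `O(q)` means the read begins or ends with sequence absent
#' from the isoform (a terminal novel exon); `O(r) > 0` means the read
#' stops short of the isoform's end, from either a shorter terminal
#' exon or a truncated read.
#'
#' @param alignment A mapped `pseudo_alignment`.
#' @return Named numeric `c(O_q, O_r)`.
#' @export
overhangs <- function(alignment) {
  stopifnot(inherits(alignment, "pseudo_alignment"))
  if (!alignment$mapped || alignment$chain$score < 1)
    stop("overhangs are undefined for unmapped reads / empty chains")
  fp <- alignment$chain$first_anchor
  lp <- alignment$chain$last_anchor
  qlen <- alignment$query_len_bp
  rlen <- alignment$ref_len_bp
  O_q <- max(0, fp[["q_pos"]] - fp[["r_pos"]],
             (qlen - lp[["q_pos"]]) - (rlen - lp[["r_pos"]]))
  O_r <- max(0, fp[["r_pos"]] - fp[["q_pos"]],
             (rlen - lp[["r_pos"]]) - (qlen - lp[["q_pos"]]))
  c(O_q = O_q, O_r = O_r)
}

#' Distance bound for the first sketched kmer match
#'
#' By default returns the configured `z`. With `derive = TRUE`, solves
#' for the smallest number of leading query positions z such that the
#' probability at least one of them starts an error-free sketched kmer
#' reaches 90 percent, under a geometric model with per-position success
#' probability `p = gamma * (1 - e)^k`:
#' the smallest integer z with `1 - (1 - p)^z >= 0.9`.
#'
#' @param sketch A [sketch_params()] object (supplies `gamma`, `k`).
#' @param selection A [selection_params()] object (supplies `z`, `e`).
#' @param derive Derive z from the geometric model instead of returning
#'   the configured value.
#' @return The effective z in bp.
#' @export
truncation_bound <- function(sketch, selection, derive = FALSE) {
  if (!derive) return(selection$z)
  p <- sketch$gamma * (1 - selection$e)^sketch$k
  if (p <= 0) return(selection$z)  # model degenerate; keep configured z
  if (p >= 1) return(1)
  ceiling(log(0.1) / log(1 - p))
}

#' Classify one read from its pseudo-alignment
#'
#' Applies the selection rules in order: (1) a chain gap larger than the
#' minimum exon length n flags an alternative-splicing event (`AS`);
#' (2) a query overhang larger than n flags a terminal novel exon
#' (`NOVEL_EXON`); (3) a positive reference overhang whose unmatched
#' query end exceeds `z + n` is too long to be explained by truncation
#' and flags shorter-terminal-exon novelty (`TRUNC_NOVEL`); otherwise
#' the read is provisionally `ANNOTATED` (group-level selection may
#' later relabel it `ATSS`). Reads with no candidate isoform are
#' `UNMAPPED`.
#'
#' @param alignment A `pseudo_alignment`.
#' @param params A [selection_params()] object.
#' @return An object of class `selection_decision`: `read_id`, `label`,
#'   `assigned_isoform` (NA for unmapped), `similarity`, `largest_gap`,
#'   `overhang_q`, `overhang_r`.
#' @export
classify_read <- function(alignment, params = selection_params()) {
  stopifnot(inherits(alignment, "pseudo_alignment"),
            inherits(params, "selection_params"))
  if (!alignment$mapped || alignment$chain$score < 1) {
    return(structure(
      list(read_id = alignment$query_id, label = "UNMAPPED",
           assigned_isoform = NA_character_, similarity = 0,
           largest_gap = NA_integer_, overhang_q = NA_real_,
           overhang_r = NA_real_),
      class = "selection_decision"))
  }
  ov <- overhangs(alignment)
  fp_q <- alignment$chain$first_anchor[["q_pos"]]
  lp_q <- alignment$chain$last_anchor[["q_pos"]]
  gap <- alignment$chain$largest_gap
  label <-
    if (gap > params$n) "AS"
    else if (ov[["O_q"]] > params$n) "NOVEL_EXON"
    else if (ov[["O_r"]] > 0 &&
             (fp_q > params$z + params$n ||
              alignment$query_len_bp - lp_q > params$z + params$n))
      "TRUNC_NOVEL"
    else "ANNOTATED"
  structure(
    list(read_id = alignment$query_id, label = label,
         assigned_isoform = alignment$isoform_id,
         similarity = alignment$similarity, largest_gap = gap,
         overhang_q = ov[["O_q"]], overhang_r = ov[["O_r"]]),
    class = "selection_decision")
}

#' Classify a list of pseudo-alignments into a decisions table
#'
#' @param alignments List of `pseudo_alignment` objects.
#' @param params A [selection_params()] object.
#' @return A data.frame with one row per read: `read_id`, `label`,
#'   `assigned_isoform`, `similarity`, `largest_gap`, `overhang_q`,
#'   `overhang_r`.
#' @export
classify_reads <- function(alignments, params = selection_params()) {
  if (length(alignments) == 0)
    return(data.frame(read_id = character(0), label = character(0),
                      assigned_isoform = character(0),
                      similarity = numeric(0), largest_gap = integer(0),
                      overhang_q = numeric(0), overhang_r = numeric(0)))
  rows <- lapply(alignments, function(al) {
    d <- classify_read(al, params)
    data.frame(read_id = d$read_id, label = d$label,
               assigned_isoform = d$assigned_isoform,
               similarity = d$similarity,
               largest_gap = if (is.na(d$largest_gap)) NA_integer_
                             else as.integer(d$largest_gap),
               overhang_q = d$overhang_q, overhang_r = d$overhang_r,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Group-level alternative start/stop (ATSS) selection
#'
#' Discovery mode only. Reads left `ANNOTATED` are grouped by their
#' best-scoring isoform; groups are ranked ascending by the square of
#' their mean similarity (the lower the group's mean score, the more
#' likely it holds reads of an unannotated start/stop variant). Groups
#' whose mean similarity reaches `B` are ineligible. Whole groups are
#' relabeled `ATSS` until adding the next group would push the ATSS
#' count past the budget `max(0, floor(c * |AS|) - |NE|)`, where `|AS|`
#' counts AS reads and `|NE|` counts NOVEL_EXON plus TRUNC_NOVEL reads;
#' the overflowing group is not added and selection stops.
#'
#' @param decisions Decisions data.frame from [classify_reads()].
#' @param params A [selection_params()] object.
#' @return The decisions data.frame with selected rows relabeled `ATSS`.
#' @export
select_atss_groups <- function(decisions, params = selection_params()) {
  n_as <- sum(decisions$label == "AS")
  n_ne <- sum(decisions$label %in% c("NOVEL_EXON", "TRUNC_NOVEL"))
  budget <- max(0, floor(params$c * n_as) - n_ne)
  if (budget == 0) return(decisions)
  ann <- which(decisions$label == "ANNOTATED")
  if (length(ann) == 0) return(decisions)
  groups <- split(ann, decisions$assigned_isoform[ann])
  means <- vapply(groups, function(ix) mean(decisions$similarity[ix]),
                  numeric(1))
  eligible <- means < params$B
  groups <- groups[eligible]
  means <- means[eligible]
  ord <- order(means^2, names(groups))  # isoform ID breaks exact ties
  taken <- 0L
  for (gi in ord) {
    sz <- length(groups[[gi]])
    if (taken + sz > budget) break  # whole groups only; stop at overflow
    decisions$label[groups[[gi]]] <- "ATSS"
    taken <- taken + sz
  }
  decisions
}

# deterministic, order-independent per-isoform RNG stream: fold the
# isoform ID into a 31-bit offset of the global seed
string_seed <- function(seed, id) {
  h <- 0
  for (v in utf8ToInt(id)) h <- (h * 131 + v) %% 2147483647
  as.integer((seed + h) %% 2147483647)
}

#' Quantify-mode subsampling and scale factors
#'
#' For each isoform with mapped `ANNOTATED` reads, uniformly samples at
#' most `l` of them without replacement and records the scale factor
#' `n_mapped / n_sampled` that restores downstream abundance estimates.
#' Novel candidates (AS, NOVEL_EXON, TRUNC_NOVEL) and unmapped reads are
#' passed through untouched. Sampling draws a deterministic per-isoform
#' RNG stream from `(seed, isoform_id)`, so the result is independent of
#' isoform processing order.
#'
#' @param decisions Decisions data.frame from [classify_reads()].
#' @param params A [selection_params()] object (supplies `l`).
#' @param seed Integer seed.
#' @return List with `sampled_ids` (annotated reads kept), `candidate_ids`
#'   (novel + unmapped reads, input order), and `scale_table` (data.frame
#'   `isoform_id`, `n_mapped`, `n_sampled`, `scale_factor`).
#' @export
quantify_sample <- function(decisions, params = selection_params(mode = "quantify"),
                            seed = 1L) {
  ann <- which(decisions$label == "ANNOTATED")
  groups <- split(decisions$read_id[ann], decisions$assigned_isoform[ann])
  isoforms <- sort(names(groups))
  sampled <- character(0)
  rows <- lapply(isoforms, function(iso) {
    ids <- groups[[iso]]
    n_map <- length(ids)
    n_smp <- min(params$l, n_map)
    old <- .Random.seed_exists()
    set.seed(string_seed(seed, iso))
    keep <- sort(sample(sort(ids), n_smp))  # input-order independent
    .restore_seed(old)
    sampled <<- c(sampled, keep)
    data.frame(isoform_id = iso, n_mapped = n_map, n_sampled = n_smp,
               scale_factor = n_map / n_smp, stringsAsFactors = FALSE)
  })
  scale_table <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(scale_table))
    scale_table <- data.frame(isoform_id = character(0),
                              n_mapped = integer(0), n_sampled = integer(0),
                              scale_factor = numeric(0))
  cand <- decisions$read_id[decisions$label %in%
                              c("AS", "NOVEL_EXON", "TRUNC_NOVEL", "UNMAPPED")]
  list(sampled_ids = decisions$read_id[decisions$read_id %in% sampled],
       candidate_ids = cand, scale_table = scale_table)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Rescale downstream abundance estimates by quantify-mode scale factors
#'
#' Multiplies each isoform's abundance estimate by its scale factor;
#' isoforms absent from the scale table keep scale 1. Optionally
#' renormalizes the result to transcripts-per-million.
#'
#' @param estimates Named numeric vector of abundances, or a data.frame
#'   with columns `isoform_id` and `abundance`.
#' @param scale_table Scale table from [quantify_sample()].
#' @param tpm Renormalize rescaled values to sum to 1e6.
#' @return Named numeric vector of rescaled abundances.
#' @export
rescale_abundances <- function(estimates, scale_table, tpm = FALSE) {
  if (is.data.frame(estimates))
    estimates <- stats::setNames(estimates$abundance, estimates$isoform_id)
  if (any(estimates < 0)) stop("negative abundance estimate")
  sc <- stats::setNames(scale_table$scale_factor, scale_table$isoform_id)
  mult <- sc[names(estimates)]
  mult[is.na(mult)] <- 1
  out <- estimates * mult
  if (tpm) {
    tot <- sum(out)
    if (tot > 0) out <- out / tot * 1e6
  }
  out
}
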