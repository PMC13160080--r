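random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a toy multi-isoform transcriptome with ground-truth events
#'
#' Builds `n_genes` genes, each a bank of `n_exons` random exon blocks,
#' and derives per gene a set of isoforms as exon chains. A fraction
#' `novel_fraction` of all isoforms is held out as "novel": each novel
#' isoform is derived from the gene's full-length annotated isoform by
#' one event, cycling deterministically through
#' \describe{
#'   \item{skip}{an internal exon is removed (alternative splicing),}
#'   \item{retention}{a random intron-like block is inserted between two
#'     adjacent exons (alternative splicing),}
#'   \item{novel_exon}{a random exon block is attached at the 5' or 3'
#'     terminus,}
#'   \item{atss}{the first or last exon is removed (alternative
#'     transcription start/stop).}
#' }
#' Every isoform is at least 250 bp, every gene keeps at least one
#' annotated isoform, and no novel isoform's exon chain coincides with
#' an annotated chain.
#'
#' @param n_genes Number of genes (default 100).
#' @param n_exons Exons per gene (default 5; at least 3).
#' @param exon_len_range Length range of exon and event blocks in bp
#'   (default `c(80, 200)`).
#' @param isoforms_per_gene Total isoforms per gene (default 5).
#' @param novel_fraction Fraction of all isoforms held out as novel
#'   (default 0.2); must leave every gene at least one annotated isoform.
#' @param seed Integer seed; the output is a pure function of the
#'   arguments.
#' @return An object of class `toy_transcriptome`: `reference` (named
#'   character, annotated isoform sequences), `novel` (named character,
#'   novel isoform sequences), and `truth` (data.frame over all isoforms
#'   with `isoform_id`, `gene_id`, `class` in
#'   annotated/skip/retention/novel_exon/atss, `truth_label` in
#'   ANNOTATED/AS/NOVEL_EXON/ATSS, `event_size` in bp, `length_bp`).
#' @export
simulate_transcriptome <- function(n_genes = 100, n_exons = 5,
                                   exon_len_range = c(80, 200),
                                   isoforms_per_gene = 5,
                                   novel_fraction = 0.2, seed = 1L) {
  stopifnot(n_genes >= 1, n_exons >= 3, isoforms_per_gene >= 1,
            novel_fraction >= 0, novel_fraction < 1,
            length(exon_len_range) == 2, exon_len_range[1] >= 40)
  n_total <- n_genes * isoforms_per_gene
  n_novel <- round(novel_fraction * n_total)
  novel_per_gene <- rep(n_novel %/% n_genes, n_genes)
  extra <- n_novel %% n_genes
  if (extra > 0) novel_per_gene[seq_len(extra)] <- novel_per_gene[seq_len(extra)] + 1
  if (any(novel_per_gene >= isoforms_per_gene))
    stop("infeasible: a gene would keep no annotated isoform")

  old <- .Random.seed_exists()
  on.exit(.restore_seed(old))
  set.seed(as.integer(seed))

  event_cycle <- c("skip", "retention", "novel_exon", "atss")
  ref <- list(); nov <- list(); truth <- list()
  ev_i <- 0L

  for (g in seq_len(n_genes)) {
    gene_id <- sprintf("gene%03d", g)
    exlen <- sample(seq(exon_len_range[1], exon_len_range[2]), n_exons,
                    replace = TRUE)
    exons <- vapply(exlen, random_dna, character(1))

    n_ann <- isoforms_per_gene - novel_per_gene[g]
    # annotated chains: the full chain plus distinct proper sub-chains
    chains <- list(seq_len(n_exons))
    tries <- 0
    while (length(chains) < n_ann && tries < 500) {
      tries <- tries + 1
      sz <- sample(2:(n_exons - 1), 1)
      ch <- sort(sample(n_exons, sz))
      if (sum(exlen[ch]) < 250) next
      if (any(vapply(chains, identical, logical(1), ch))) next
      chains[[length(chains) + 1]] <- ch
    }
    if (length(chains) < n_ann)
      stop("infeasible: could not draw enough distinct annotated chains")
    for (i in seq_along(chains)) {
      id <- sprintf("%s.iso%d", gene_id, i)
      ref[[id]] <- paste(exons[chains[[i]]], collapse = "")
      truth[[id]] <- data.frame(
        isoform_id = id, gene_id = gene_id, class = "annotated",
        truth_label = "ANNOTATED", event_size = 0L,
        length_bp = nchar(ref[[id]]), stringsAsFactors = FALSE)
    }

    full <- seq_len(n_exons) # event base: the full-length isoform
    for (j in seq_len(novel_per_gene[g])) {
      ev_i <- ev_i + 1L
      class <- event_cycle[(ev_i - 1L) %% 4L + 1L]
      id <- sprintf("%s.nov%d", gene_id, j)
      res <- switch(class,
        skip = {
          drops <- sample(2:(n_exons - 1))
          ch <- NULL
          for (d in drops) {
            cand <- full[-d]
            if (!any(vapply(chains, identical, logical(1), cand))) {
              ch <- cand; size <- exlen[d]; break
            }
          }
          if (is.null(ch)) { # all skip chains annotated; retain instead
            class <- "retention"; NULL
          } else list(seq = paste(exons[ch], collapse = ""), size = size)
        },
        NULL)
      if (is.null(res)) res <- switch(class,
        retention = {
          at <- sample(n_exons - 1, 1)
          blk <- random_dna(sample(seq(exon_len_range[1], exon_len_range[2]), 1))
          list(seq = paste(c(exons[1:at], blk,
                             exons[(at + 1):n_exons]), collapse = ""),
               size = nchar(blk))
        },
        novel_exon = {
          blk <- random_dna(sample(seq(exon_len_range[1], exon_len_range[2]), 1))
          s <- if (stats::runif(1) < 0.5)
            paste(c(blk, exons), collapse = "")
          else paste(c(exons, blk), collapse = "")
          list(seq = s, size = nchar(blk))
        },
        atss = {
          ends <- sample(c(1L, n_exons))
          ch <- NULL
          for (d in ends) {
            cand <- full[-d]
            if (!any(vapply(chains, identical, logical(1), cand)) &&
                sum(exlen[cand]) >= 250) {
              ch <- cand; size <- exlen[d]; break
            }
          }
          if (is.null(ch)) { # fall back to an always-feasible event
            class <- "retention"
            at <- sample(n_exons - 1, 1)
            blk <- random_dna(sample(seq(exon_len_range[1],
                                         exon_len_range[2]), 1))
            list(seq = paste(c(exons[1:at], blk,
                               exons[(at + 1):n_exons]), collapse = ""),
                 size = nchar(blk))
          } else list(seq = paste(exons[ch], collapse = ""), size = size)
        })
      nov[[id]] <- res$seq
      truth[[id]] <- data.frame(
        isoform_id = id, gene_id = gene_id, class = class,
        truth_label = switch(class, skip = "AS", retention = "AS",
                             novel_exon = "NOVEL_EXON", atss = "ATSS"),
        event_size = as.integer(res$size), length_bp = nchar(res$seq),
        stringsAsFactors = FALSE)
    }
  }
  structure(
    list(reference = unlist(ref), novel = unlist(nov),
         truth = do.call(rbind, c(truth, list(make.row.names = FALSE)))),
    class = "toy_transcriptome")
}

#' @export
print.toy_transcriptome <- function(x, ...) {
  cat(sprintf("toy_transcriptome: %d annotated + %d novel isoforms, %d genes\n",
              length(x$reference), length(x$novel),
              length(unique(x$truth$gene_id))))
  invisible(x)
}

mutate_seq <- function(seq, error_rate) {
  len <- nchar(seq)
  n_err <- stats::rbinom(1, len, error_rate)
  if (n_err == 0) return(seq)
  pos <- sample.int(len, n_err)
  for (p in pos) {
    orig <- substr(seq, p, p)
    substr(seq, p, p) <- sample(setdiff(c("A", "C", "G", "T"), orig), 1)
  }
  seq
}

#' Simulate labeled long reads from a toy transcriptome
#'
#' Draws `depth` reads from every isoform (annotated and novel).
#' Errors are i.i.d. substitutions at `error_rate` per base — the
#' high-fidelity long-read regime this models is substitution-dominated.
#' Optionally, each read end is independently truncated with probability
#' `truncation_prob` by a uniform 1..`truncation_max` bp. Each read
#' carries the ground-truth event label of its source isoform.
#'
#' @param transcriptome A `toy_transcriptome` from
#'   [simulate_transcriptome()].
#' @param depth Reads per isoform (default 20).
#' @param error_rate Per-base substitution rate (default 0.002).
#' @param truncation_prob Per-end truncation probability (default 0).
#' @param truncation_max Maximum truncation in bp (default 100).
#' @param seed Integer seed.
#' @return A data.frame with one row per read: `read_id`, `sequence`,
#'   `truth_label`, `source_isoform`, `trunc5`, `trunc3`.
#' @export
simulate_reads <- function(transcriptome, depth = 20, error_rate = 0.002,
                           truncation_prob = 0, truncation_max = 100,
                           seed = 1L) {
  stopifnot(inherits(transcriptome, "toy_transcriptome"), depth >= 1,
            error_rate >= 0, error_rate < 1)
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  seqs <- c(transcriptome$reference, transcriptome$novel)
  labels <- stats::setNames(transcriptome$truth$truth_label,
                            transcriptome$truth$isoform_id)
  rows <- vector("list", length(seqs) * depth)
  i <- 0L
  for (iso in names(seqs)) {
    s0 <- seqs[[iso]]
    for (d in seq_len(depth)) {
      t5 <- if (truncation_prob > 0 && stats::runif(1) < truncation_prob)
        sample.int(truncation_max, 1) else 0L
      t3 <- if (truncation_prob > 0 && stats::runif(1) < truncation_prob)
        sample.int(truncation_max, 1) else 0L
      s <- substr(s0, t5 + 1, nchar(s0) - t3)
      s <- mutate_seq(s, error_rate)
      i <- i + 1L
      rows[[i]] <- data.frame(
        read_id = sprintf("%s_r%02d", iso, d), sequence = s,
        truth_label = labels[[iso]], source_isoform = iso,
        trunc5 = t5, trunc3 = t3, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write named sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path, width = 80L)
  invisible(path)
}
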