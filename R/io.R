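#' Read a FASTA or FASTQ file (plain or gzipped)
#'
#' The format is auto-detected from the first record character. Record
#' IDs are taken verbatim up to the first whitespace; sequences are
#' uppercased.
#'
#' @param path Input file.
#' @return A data.frame with columns `read_id`, `sequence`, `quality`
#'   (NA for FASTA), carrying the detected format in
#'   `attr(, "format")`. An empty file yields a warning and zero rows.
#' @export
read_fastx <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  con <- gzfile(path, "rt")
  first <- readLines(con, n = 1L)
  close(con)
  if (length(first) == 0 || !nzchar(trimws(first))) {
    warning("empty input file: ", path)
    out <- data.frame(read_id = character(0), sequence = character(0),
                      quality = character(0), stringsAsFactors = FALSE)
    attr(out, "format") <- "fasta"
    return(out)
  }
  fmt <- if (startsWith(first, ">")) "fasta"
         else if (startsWith(first, "@")) "fastq"
         else stop("cannot detect FASTA/FASTQ format of ", path,
                   " (record starts with '", substr(first, 1, 1), "')")
  if (fmt == "fasta") {
    ss <- Biostrings::readDNAStringSet(path, format = "fasta")
    qual <- rep(NA_character_, length(ss))
  } else {
    ss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                       with.qualities = TRUE)
    qual <- as.character(S4Vectors::mcols(ss)$qualities)
  }
  out <- data.frame(
    read_id = sub("\\s.*$", "", names(ss)),
    sequence = toupper(as.character(ss)),
    quality = qual, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "format") <- fmt
  out
}

#' Write records in FASTA or FASTQ
#'
#' @param records Data.frame with `read_id`, `sequence` and (for FASTQ)
#'   `quality` columns, as produced by [read_fastx()].
#' @param path Output path.
#' @param format `"fasta"` or `"fastq"`.
#' @export
write_fastx <- function(records, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "fasta") {
    lines <- if (nrow(records))
      as.vector(rbind(paste0(">", records$read_id), records$sequence))
    else character(0)
  } else {
    qual <- records$quality
    qual[is.na(qual)] <- vapply(nchar(records$sequence[is.na(qual)]),
                                function(n) strrep("I", n), character(1))
    lines <- if (nrow(records))
      as.vector(rbind(paste0("@", records$read_id), records$sequence,
                      "+", qual))
    else character(0)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Sieve a read set against a reference transcriptome (in memory)
#'
#' The full preprocessing computation on in-memory objects: build the
#' capped kmer index over the reference, pseudo-align every read in both
#' orientations, classify each read, then apply the mode's selection
#' step (group-level ATSS selection in discovery mode; per-isoform
#' subsampling with scale factors in quantify mode).
#'
#' @param reference Named character vector (or `DNAStringSet`) of
#'   reference isoform sequences.
#' @param reads Data.frame with `read_id` and `sequence` columns, or a
#'   named character vector.
#' @param sketch A [sketch_params()] object.
#' @param selection A [selection_params()] object (its `mode` picks the
#'   selection step).
#' @param cap_b Index occupancy cap (default 16).
#' @param band_m Chaining band width (default 3).
#' @param seed Integer seed (quantify-mode subsampling).
#' @return A list: `decisions` (per-read data.frame), `candidate_ids`
#'   (reads selected as novel candidates, input order), `scale_table`
#'   and `sampled_ids` (quantify mode; NULL otherwise), and `index`.
#' @export
sieve_reads <- function(reference, reads, sketch = sketch_params(),
                        selection = selection_params(), cap_b = 16,
                        band_m = 3, seed = 1L) {
  if (!is.data.frame(reads))
    reads <- data.frame(read_id = names(reads),
                        sequence = unname(unlist(reads)),
                        stringsAsFactors = FALSE)
  index <- build_index(reference, sketch, cap_b)
  alignments <- lapply(seq_len(nrow(reads)), function(i)
    pseudoalign(reads$sequence[[i]], reads$read_id[[i]], index, band_m))
  decisions <- classify_reads(alignments, selection)
  scale_table <- NULL
  sampled_ids <- NULL
  if (selection$mode == "discovery") {
    decisions <- select_atss_groups(decisions, selection)
    cand <- decisions$read_id[decisions$label != "ANNOTATED"]
  } else {
    qs <- quantify_sample(decisions, selection, seed)
    cand <- qs$candidate_ids
    scale_table <- qs$scale_table
    sampled_ids <- qs$sampled_ids
  }
  list(decisions = decisions, candidate_ids = cand,
       scale_table = scale_table, sampled_ids = sampled_ids, index = index)
}

#' Run the preprocessing pipeline on files
#'
#' Reads a reference transcriptome FASTA and a FASTA/FASTQ read set,
#' runs [sieve_reads()], and writes the mode's outputs to `out_dir`:
#' `decisions.tsv` (one row per input read), `candidates.fasta`/`.fastq`
#' (verbatim copies of the selected reads, original orientation; output
#' format mirrors the input), for quantify mode additionally
#' `sampled.fasta`/`.fastq` and `scale_factors.tsv`, and a
#' `manifest.json` recording all parameters, the seed and the package
#' version.
#'
#' @param reference_path Reference transcriptome FASTA (optionally
#'   gzipped).
#' @param reads_path Read set FASTA or FASTQ (optionally gzipped).
#' @param out_dir Output directory (created if missing).
#' @param mode `"discovery"` or `"quantify"`.
#' @param sketch,selection,cap_b,band_m,seed See [sieve_reads()];
#'   `selection$mode` is overridden by `mode`.
#' @return Invisibly, the [sieve_reads()] result plus `paths` of the
#'   written files.
#' @export
run_pipeline <- function(reference_path, reads_path, out_dir,
                         mode = c("discovery", "quantify"),
                         sketch = sketch_params(),
                         selection = NULL, cap_b = 16, band_m = 3,
                         seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(selection)) selection <- selection_params(mode = mode)
  selection$mode <- mode
  if (!file.exists(reference_path)) stop("reference not found: ", reference_path)
  if (!file.exists(reads_path)) stop("reads not found: ", reads_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, mode = 2) != 0)
    stop("output directory not writable: ", out_dir)

  ref <- read_fastx(reference_path)
  reads <- read_fastx(reads_path)
  fmt <- attr(reads, "format")
  ext <- if (fmt == "fastq") "fastq" else "fasta"

  res <- sieve_reads(stats::setNames(ref$sequence, ref$read_id), reads,
                     sketch, selection, cap_b, band_m, seed)

  dec_path <- file.path(out_dir, "decisions.tsv")
  dec <- res$decisions
  dec$similarity <- sprintf("%.6f", dec$similarity)
  utils::write.table(dec, dec_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cand_path <- file.path(out_dir, paste0("candidates.", ext))
  write_fastx(reads[reads$read_id %in% res$candidate_ids, , drop = FALSE],
              cand_path, fmt)
  paths <- c(decisions = dec_path, candidates = cand_path)
  if (mode == "quantify") {
    smp_path <- file.path(out_dir, paste0("sampled.", ext))
    write_fastx(reads[reads$read_id %in% res$sampled_ids, , drop = FALSE],
                smp_path, fmt)
    sc_path <- file.path(out_dir, "scale_factors.tsv")
    utils::write.table(res$scale_table, sc_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, sampled = smp_path, scale_factors = sc_path)
  }
  manifest <- list(
    version = as.character(utils::packageVersion("isosieve")),
    mode = mode, seed = seed,
    reference = reference_path, reads = reads_path,
    n_reads = nrow(reads), n_isoforms = nrow(ref),
    params = list(k = sketch$k, gamma = sketch$gamma, cap_b = cap_b,
                  band_m = band_m, n = selection$n, z = selection$z,
                  B = selection$B, c = selection$c, l = selection$l,
                  e = selection$e),
    label_counts = as.list(table(res$decisions$label)))
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, pretty = TRUE)
  res$paths <- c(paths, manifest = man_path)
  invisible(res)
}
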