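# minimal hand-built pseudo_alignment for rule-level tests
fake_alignment <- function(score = 10, fp = c(0, 0), lp = c(400, 400),
                           gap = 0, qlen = 450, rlen = 450, sim = 0.9,
                           iso = "isoA", id = "r1") {
  structure(
    list(query_id = id, mapped = TRUE, isoform_id = iso, orientation = "+",
         chain = structure(list(score = as.integer(score),
                                first_anchor = c(q_pos = fp[1], r_pos = fp[2]),
                                last_anchor = c(q_pos = lp[1], r_pos = lp[2]),
                                largest_gap = as.integer(gap), track = "a"),
                           class = "chain_result"),
         similarity = sim, query_len_bp = qlen, ref_len_bp = rlen,
         q_multiset_size = 40, r_multiset_size = 40, n_candidates = 1),
    class = "pseudo_alignment")
}

test_that("overhang formulas follow the first/last chain anchors", {
  # full diagonal: no overhangs
  expect_identical(overhangs(fake_alignment()), c(O_q = 0, O_r = 0))
  # 40 extra 5' bp on the query
  al <- fake_alignment(fp = c(40, 0), lp = c(440, 400), qlen = 490)
  expect_identical(overhangs(al)[["O_q"]], 40)
  # 25 extra 3' bp on the reference beyond the last anchor
  al <- fake_alignment(fp = c(0, 0), lp = c(400, 400), qlen = 450, rlen = 475)
  expect_identical(overhangs(al)[["O_r"]], 25)
  expect_error(overhangs(structure(list(mapped = FALSE),
                                   class = "pseudo_alignment")),
               "undefined")
})

test_that("truncation bound returns the configured z or derives it", {
  sk <- sketch_params()
  sel <- selection_params()
  expect_identical(truncation_bound(sk, sel), 100)
  # degenerate limit: every position starts a matching kmer
  expect_identical(truncation_bound(sketch_params(k = 22, gamma = 1),
                                    selection_params(e = 0), derive = TRUE),
                   1)
  # derived z equals the smallest integer satisfying the geometric CDF
  pr <- 0.1 * (1 - 0.002)^22
  zs <- which(1 - (1 - pr)^(1:1000) >= 0.9)[1]
  expect_identical(truncation_bound(sk, sel, derive = TRUE), as.numeric(zs))
})

test_that("classification rules fire in their stated order", {
  sel <- selection_params()  # n = 30, z = 100
  expect_identical(classify_read(fake_alignment(gap = 45), sel)$label, "AS")
  # gap rule fires before the overhang rule
  al <- fake_alignment(gap = 45, fp = c(60, 0), lp = c(460, 400), qlen = 520)
  expect_identical(classify_read(al, sel)$label, "AS")
  al <- fake_alignment(fp = c(40, 0), lp = c(440, 400), qlen = 490)
  expect_identical(classify_read(al, sel)$label, "NOVEL_EXON")
  # O_r = 10 and FP_q = 135 > z + n = 130
  al <- fake_alignment(fp = c(135, 145), lp = c(435, 445), qlen = 460,
                       rlen = 470)
  expect_identical(classify_read(al, sel)$label, "TRUNC_NOVEL")
  # same but within the truncation allowance -> annotated
  al <- fake_alignment(fp = c(90, 100), lp = c(435, 445), qlen = 460,
                       rlen = 470)
  expect_identical(classify_read(al, sel)$label, "ANNOTATED")
  expect_identical(
    classify_read(structure(list(query_id = "u", mapped = FALSE,
                                 query_len_bp = 100),
                            class = "pseudo_alignment"), sel)$label,
    "UNMAPPED")
})

test_that("exact substring reads of an indexed isoform stay annotated", {
  p <- sketch_params(k = 11, gamma = 0.4)
  set.seed(30)
  ref <- stats::setNames(replicate(3, random_seq(800)), c("a", "b", "c"))
  idx <- build_index(ref, p, 16)
  sel <- selection_params()
  for (i in 1:20) {
    src <- sample(names(ref), 1)
    st <- sample(1:60, 1)
    q <- substr(ref[[src]], st, nchar(ref[[src]]) - sample(0:60, 1))
    d <- classify_read(pseudoalign(q, "q", idx), sel)
    expect_identical(d$label, "ANNOTATED")
    expect_identical(d$assigned_isoform, src)
  }
})

make_decisions <- function(labels, isoforms, sims) {
  data.frame(read_id = sprintf("r%03d", seq_along(labels)), label = labels,
             assigned_isoform = isoforms, similarity = sims,
             largest_gap = 0L, overhang_q = 0, overhang_r = 0,
             stringsAsFactors = FALSE)
}

test_that("ATSS budget arithmetic matches the whole-group rule", {
  # |AS| = 10, |NE| = 15, c = 1.5 -> budget 0
  d <- make_decisions(c(rep("AS", 10), rep("NOVEL_EXON", 15),
                        rep("ANNOTATED", 5)),
                      c(rep(NA, 25), rep("g1", 5)),
                      c(rep(1, 25), rep(0.5, 5)))
  out <- select_atss_groups(d, selection_params())
  expect_identical(sum(out$label == "ATSS"), 0L)

  # |AS| = 20, |NE| = 5 -> budget 25; groups of 10 (0.7^2) and 20 (0.8^2):
  # only the first fits, the overflowing second is not added
  d <- make_decisions(
    c(rep("AS", 20), rep("NOVEL_EXON", 5), rep("ANNOTATED", 30)),
    c(rep(NA, 25), rep("g1", 10), rep("g2", 20)),
    c(rep(1, 25), rep(0.7, 10), rep(0.8, 20)))
  out <- select_atss_groups(d, selection_params())
  expect_identical(sum(out$label == "ATSS"), 10L)
  expect_true(all(out$label[out$assigned_isoform %in% "g1"] == "ATSS"))

  # groups at or above B are never selected regardless of budget
  d$similarity[d$assigned_isoform %in% c("g1", "g2")] <- 0.985
  out <- select_atss_groups(d, selection_params())
  expect_identical(sum(out$label == "ATSS"), 0L)
})

test_that("ATSS count always respects the budget bound", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(30:80, 1)
    labs <- sample(c("AS", "NOVEL_EXON", "TRUNC_NOVEL", "ANNOTATED"), n,
                   replace = TRUE, prob = c(0.2, 0.1, 0.05, 0.65))
    isos <- ifelse(labs == "ANNOTATED",
                   sample(paste0("g", 1:5), n, replace = TRUE), NA)
    d <- make_decisions(labs, isos, runif(n, 0.3, 1))
    out <- select_atss_groups(d, selection_params())
    budget <- max(0, floor(1.5 * sum(labs == "AS")) -
                    sum(labs %in% c("NOVEL_EXON", "TRUNC_NOVEL")))
    expect_lte(sum(out$label == "ATSS"), budget)
    # partition: labels only move ANNOTATED -> ATSS
    expect_identical(sum(out$label %in% c("AS", "NOVEL_EXON", "TRUNC_NOVEL")),
                     sum(labs != "ANNOTATED"))
    expect_identical(nrow(out), n)
  }
})

test_that("quantify subsampling conserves totals through scale factors", {
  set.seed(32)
  labs <- c(rep("ANNOTATED", 60), rep("AS", 8), rep("UNMAPPED", 2))
  isos <- c(sample(paste0("t", 1:9), 60, replace = TRUE,
                   prob = c(8, 1, 1, 1, 3, 3, 3, 20, 20) / 60), rep(NA, 10))
  d <- make_decisions(labs, isos, runif(70, 0.8, 1))
  qs <- quantify_sample(d, selection_params(mode = "quantify"), seed = 5)
  st <- qs$scale_table
  expect_true(all(st$n_sampled <= 5 & st$n_sampled >= 1))
  expect_true(all(st$n_sampled <= st$n_mapped))
  # exact conservation (integer check)
  expect_identical(sum(st$n_sampled * st$scale_factor), sum(st$n_mapped) + 0)
  expect_identical(sort(unique(d$assigned_isoform[labs == "ANNOTATED"])),
                   st$isoform_id)
  # isoforms with <= l reads keep them all at scale 1
  small <- st$n_mapped <= 5
  expect_true(all(st$scale_factor[small] == 1))
  # novel + unmapped reads pass through
  expect_identical(qs$candidate_ids, d$read_id[labs != "ANNOTATED"])
  # determinism in the seed, order-independence of the draw
  qs2 <- quantify_sample(d, selection_params(mode = "quantify"), seed = 5)
  expect_identical(qs$sampled_ids, qs2$sampled_ids)
  shuf <- d[sample(nrow(d)), ]
  qs3 <- quantify_sample(shuf, selection_params(mode = "quantify"), seed = 5)
  expect_identical(sort(qs3$sampled_ids), sort(qs$sampled_ids))
  qs4 <- quantify_sample(d, selection_params(mode = "quantify"), seed = 6)
  expect_identical(qs4$scale_table, qs$scale_table)
})

test_that("rescaling multiplies by scale factors and can renormalize to TPM", {
  st <- data.frame(isoform_id = c("a", "b"), n_mapped = c(12L, 3L),
                   n_sampled = c(5L, 3L), scale_factor = c(2.4, 1))
  est <- c(a = 10, b = 7, zzz = 4)
  out <- rescale_abundances(est, st)
  expect_identical(unname(out), c(24, 7, 4))
  tpm <- rescale_abundances(est, st, tpm = TRUE)
  expect_equal(sum(tpm), 1e6)
  expect_error(rescale_abundances(c(a = -1), st), "negative")
})
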