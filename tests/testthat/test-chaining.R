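chain_of <- function(q, r, band_m = 100) {
  chain_anchors(data.frame(q_pos = as.integer(q), r_pos = as.integer(r)),
                band_m)
}

test_that("hand-worked anchor tables chain to their known optima", {
  # perfect diagonal
  res <- chain_of(1:3, 1:3)
  expect_identical(res$score, 3L)
  expect_identical(res$largest_gap, 0L)
  expect_identical(unname(res$first_anchor), c(1L, 1L))
  expect_identical(unname(res$last_anchor), c(3L, 3L))
  # diagonal shift of 100 on the reference: same chain, same gap
  res2 <- chain_of(1:3, 101:103)
  expect_identical(res2$score, 3L)
  expect_identical(res2$largest_gap, 0L)
  # deletion-like diagonal jump: gap = |(50-10) - (110-10)| = 60
  res3 <- chain_of(c(0, 10, 50), c(0, 10, 110))
  expect_identical(res3$score, 3L)
  expect_identical(res3$largest_gap, 60L)
  # crossing anchors cannot co-chain
  res4 <- chain_of(c(1, 2), c(2, 1))
  expect_identical(res4$score, 1L)
  # empty table
  res5 <- chain_anchors(data.frame(q_pos = integer(0), r_pos = integer(0)))
  expect_identical(res5$score, 0L)
  expect_identical(res5$largest_gap, 0L)
  expect_true(is.na(res5$first_anchor[["q_pos"]]))
})

test_that("chain score equals exhaustive subset enumeration on small tables", {
  set.seed(20)
  for (i in 1:60) {
    a <- random_anchor_table(n_max = 9, coord_max = 25)
    got <- chain_anchors(a, band_m = nrow(a) + 1)$score
    expect_identical(got, oracle_chain_exhaustive(a$q_pos, a$r_pos),
                     info = paste("table", i))
  }
})

test_that("banded score never exceeds the unbanded optimum", {
  set.seed(21)
  for (i in 1:100) {
    a <- random_anchor_table(n_max = 12, coord_max = 40)
    full <- chain_anchors(a, band_m = nrow(a) + 1)$score
    for (m in c(1, 2, 3)) {
      expect_lte(chain_anchors(a, band_m = m)$score, full)
    }
  }
})

test_that("band width in distinct kmers skips repeated-position anchor runs", {
  # a repetitive kmer creates 4 anchors at the same q_pos; with band_m = 2
  # the distinct-position band must reach past them to the true predecessor
  a <- data.frame(q_pos = c(10L, 20L, 20L, 20L, 20L, 30L),
                  r_pos = c(10L, 90L, 95L, 97L, 99L, 30L))
  # optimum is (10,10),(30,30): reachable only if the band at (30,30)
  # looks past the four q=20 anchors, which share one distinct q value
  expect_identical(oracle_chain_exhaustive(a$q_pos, a$r_pos), 2L)
  expect_identical(chain_anchors(a, band_m = 2)$score, 2L)
})

test_that("chaining is invariant under constant reference offsets", {
  set.seed(22)
  for (i in 1:30) {
    a <- random_anchor_table(n_max = 10, coord_max = 60)
    base <- chain_anchors(a, band_m = 3)
    off <- sample(1:500, 1)
    shifted <- chain_anchors(
      data.frame(q_pos = a$q_pos, r_pos = a$r_pos + off), band_m = 3)
    expect_identical(shifted$score, base$score)
    expect_identical(shifted$largest_gap, base$largest_gap)
  }
})

test_that("anchor table enumerates occurrence pairs and respects the cap", {
  p <- sketch_params(k = 4, gamma = 1)
  # kmer occurring twice on the query, once on the reference -> 2 anchors
  q <- sketch_sequence("AAACGTTTTTAAACGTTT", "q", p)
  r <- sketch_sequence("GGGGAAACGTGGGG", "r", p)
  anc <- build_anchor_table(q, r)
  shared <- anc[anc$hash == hash_kmer("AACG", p), ]
  expect_identical(nrow(shared), 2L)
  expect_identical(shared$r_pos, c(5L, 5L))
  expect_true(all(diff(anc$q_pos) >= 0))
  # identical sequences with unique kmers -> the full diagonal
  set.seed(23)
  s <- random_seq(200)
  sk <- sketch_sequence(s, "s", sketch_params(k = 8, gamma = 1))
  diag_anc <- build_anchor_table(sk, sk)
  expect_true(all(diag_anc$q_pos == diag_anc$r_pos) ||
                any(duplicated(sk$hash)))
  res <- chain_anchors(diag_anc, 3)
  expect_identical(res$score, sk$multiset_size)
  # disjoint sketches -> empty table
  other <- sketch_sequence(paste(rep("C", 100), collapse = ""), "o",
                           sketch_params(k = 8, gamma = 1))
  expect_identical(nrow(build_anchor_table(sk, other)), 0L)
})

test_that("similarity identities hold and degrade with divergence", {
  p <- sketch_params(k = 11, gamma = 1)
  set.seed(24)
  ref <- c(t1 = random_seq(600))
  idx <- build_index(ref, p, 16)
  # self-alignment: I = m / (m + m - m) = 1
  self <- pseudoalign(ref[[1]], "self", idx)
  expect_identical(self$similarity, 1)
  expect_identical(self$chain$score, idx$sketches$t1$multiset_size)
  # direct arithmetic on the formula
  expect_identical(isosieve:::chain_similarity(5, 8, 7), 0.5)
  expect_identical(isosieve:::chain_similarity(0, 8, 7), 0)
  # rising substitution rates push the mean similarity down
  p2 <- sketch_params(k = 11, gamma = 0.3)
  idx2 <- build_index(ref, p2, 16)
  mean_I <- vapply(c(0.005, 0.03, 0.10), function(rate) {
    mean(vapply(1:25, function(i) {
      s <- isosieve:::mutate_seq(ref[[1]], rate)
      al <- pseudoalign(s, "m", idx2)
      if (al$mapped) al$similarity else 0
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_I) < 0))
})

test_that("antisense reads are rescued by orientation selection", {
  p <- sketch_params(k = 11, gamma = 0.5)
  set.seed(25)
  ref <- c(t1 = random_seq(500))
  idx <- build_index(ref, p, 16)
  al <- pseudoalign(revcomp(ref[[1]]), "rc", idx)
  expect_true(al$mapped)
  expect_identical(al$orientation, "-")
  expect_identical(al$similarity, 1)
})
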