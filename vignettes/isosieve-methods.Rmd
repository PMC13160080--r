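---
title: "Methods: sketch-based read sieving for isoform discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sketch-based read sieving for isoform discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isosieve)
```

## The problem

Novel isoform discovery from long RNA-seq reads is dominated by the cost
of base-level alignment, yet only the reads transcribed from *novel*
isoforms carry information a discovery pipeline needs. isosieve
pseudo-aligns every read to a reference transcriptome using exact kmer
matches only, decides from the pseudo-alignment structure whether the
read is consistent with an annotated isoform, and outputs either the
likely-novel subset (discovery mode) or a balanced per-isoform subsample
plus scale factors (quantify mode). Downstream aligners and discovery
tools then run on a fraction of the data, and — because annotated reads
can mask novel transcripts through read-support biases — often with
better accuracy than on the full sample.

## Kmer sketching

Each sequence is reduced to a positional FracMinHash sketch. With kmer
length $k$ and hash $h:\Sigma^k \to [0, M]$, $M = 4^k - 1$, the sketch of
a sequence $S$ is every kmer occurrence $w$ with
$h(w) \le \gamma M$, together with its 0-based offset. $\gamma$ is
therefore the expected fraction of kmers retained; `sketch_sequence()`
keeps occurrences (a kmer occurring $t$ times contributes $t$ entries),
and the multiset size $|\{F(S)\}|$ enters the similarity denominator
below.

The hash is the invertible 64-bit integer mixing function familiar from
minimizer-based mappers, restricted to the low $2k$ bits of the kmer's
2-bit encoding. Every step of the mix is a bijection modulo $2^{2k}$, so
*distinct kmers never collide*; `unhash_kmer()` implements the exact
inverse, which the test suite uses to verify bijectivity. We cap $k$ at
26 so hash values stay exactly representable as doubles. Kmer windows
containing a non-ACGT symbol are skipped entirely rather than encoded —
the standard convention, which keeps ambiguity codes out of the hash
domain. Kmers are *not* canonicalized: orientation is resolved per read
(below), and keeping the plain-strand kmer preserves the positional
colinearity the chaining step relies on.

Two readings of the retention rule are possible ("hash below $M\gamma$"
versus a top-fraction rule); we keep $h(w) \le \gamma M$, the only
reading under which $\gamma$ is the fraction of kmers chosen. The
threshold is computed once as $\lfloor \gamma M \rfloor$ and reused
everywhere, so retention is bit-reproducible across platforms.

Homopolymer compression is off: the high-fidelity reads this tool
targets do not need it, and compression would distort the gap geometry
the selector measures.

## Reference index and candidate resolution

`build_index()` sketches every reference isoform and inverts the
sketches into a map $\kappa$ from each sketched kmer to the isoforms
containing it. A kmer present in more than $b$ isoforms (`cap_b`,
default 16) is dropped from the map: such kmers are uninformative about
identity and would inflate the search space quadratically. Dropped
kmers still count inside the per-isoform sketch multisets, so the
similarity denominator remains a property of the sequences, not of the
corpus composition.

For a query sketch, `resolve_candidates()` returns the search space
$S(q)$ — the union of occurrence sets over the query's sketched kmers —
and the best-match set $M(q)$, the isoforms attaining the maximum number
of *distinct* shared sketched kmers. Multiplicity is deliberately
ignored here; it matters only in the chain score. All argmax ties are
retained and each tied isoform is chained. The index lives in memory:
desk-scale transcriptomes (hundreds of thousands of isoforms) fit
comfortably, and an on-disk database would buy nothing.

## Chaining

For each isoform $r \in M(q)$ an anchor table lists every exact
sketched-kmer match as $(q_\mathrm{pos}, r_\mathrm{pos})$, sorted by
query then reference position. A chain is a subsequence of anchors
strictly increasing in both coordinates; its score is simply the number
of anchors. No gap penalty is applied — the point of this chain is not a
seed for extension but a *diagnostic*: we track the largest absolute
diagonal gap

$$|g| = |(q_i - q_j) - (r_i - r_j)|$$

between consecutive chain anchors. An exon missing from the read
relative to the isoform (skipping) shifts the diagonal by the exon
length in one direction; a retained intron or novel internal exon shifts
it the other way. Taking $|g|$ makes both directions trigger selection.

The DP keeps two tracks per anchor $i$: $f_a[i]$, the best chain among
anchors $1..i$ that ends with anchor $i$, and $f_n[i]$, the best chain
that omits it. Extension tests precedence against the *last anchor* of
the predecessor chain (relevant on the omit track, where the chain's
end is not $x_j$ itself). Each track propagates the chain's first/last
anchors and its running largest gap. Predecessors are scanned backward
within a band that stretches until at least $m$ distinct query positions
*and* $m$ distinct reference positions have been seen (`band_m`, default
3): anchors of a repeated kmer share a coordinate, so counting distinct
positions lets the band skip over repetitive runs instead of being
exhausted by them. A kmer occurrence cannot be used twice in a chain
because coordinates increase strictly. With high-fidelity reads m = 3
is ample; noisier data warrants a wider band.

Ties in the DP prefer the end-track over the omit-track, then the
nearest predecessor; the overall optimum prefers the end-track, then the
earliest entry. These choices only pin down *which* optimal chain is
reported — the score is tie-free — and make every output byte
deterministic.

The test suite checks the DP against two independent oracles: exhaustive
subset enumeration on small tables, and a quadratic
longest-increasing-subsequence recursion on 1000 random tables (after
sorting by coordinates, any valid chain is a subsequence of the sorted
order, so the quadratic recursion is exact).

Both read orientations are sketched and chained; the orientation with
the higher best chain score wins (ties go forward). Long cDNA reads are
routinely antisense to the transcript, and per-read orientation
resolution is cheaper and cleaner than canonical kmers.

## Similarity

For each candidate isoform the chain score $s$ is turned into a
multiset-Jaccard-style similarity

$$I = \frac{s}{|\{F(r)\}| + |\{F(q)\}| - s},$$

and the read's similarity $I(q)$ is the maximum over $M(q)$ (ties to the
lexicographically smallest isoform ID). $I(q) = 1$ exactly for a read
identical to an isoform (every sketched occurrence chains on the
diagonal) and 0 when nothing chains; because
$s \le \min(|\{F(q)\}|, |\{F(r)\}|)$, $I$ always lies in $[0,1]$.
Unlike a plain Jaccard index on kmer sets, this score rewards kmers that
are *colinear and correctly repeated*, not merely shared.

## Read selection

The classifier sees, for the best isoform: the largest chain gap, and
the unmatched end lengths

$$O(q) = \max\{0,\ FP_q - FP_r,\ (|q| - LP_q) - (|r| - LP_r)\},$$
$$O(r) = \max\{0,\ FP_r - FP_q,\ (|r| - LP_r) - (|q| - LP_q)\},$$

with $FP$/$LP$ the first/last chain anchors. Rules fire in order:

1. **AS** — largest gap $> n$ (default $n = 30$ bp, the expected minimum
   exon length): an internal splicing discrepancy.
2. **NOVEL_EXON** — $O(q) > n$: the read begins or ends with sequence
   the isoform lacks.
3. **TRUNC_NOVEL** — $O(r) > 0$ and the unmatched query end exceeds
   $z + n$ (default $z = 100$ bp): the isoform continues past the read,
   and the read's own unmatched end is too long to blame on truncation,
   so a shorter terminal exon is likely. $z$ bounds where the first
   sketched match lands on an intact read; under a geometric model with
   per-position success $\gamma (1-e)^k$, 90% of reads match within
   $z$ positions. `truncation_bound(derive = TRUE)` solves
   $1 - (1 - \gamma(1-e)^k)^z \ge 0.9$ for the smallest such $z$; the
   printed form of this bound is ambiguous in its exponent, so the
   configured $z = 100$ is authoritative and the derivation is offered
   as an interpretation.
4. **ANNOTATED** otherwise; **UNMAPPED** when $M(q)$ is empty in both
   orientations.

Reads with alternative transcription start/stop sites (ATSS) match an
annotated isoform end-to-end *locally* — no internal gap, modest
overhangs — and are only distinguishable by their depressed similarity.
Because individual similarities are noisy (truncation from library
prep or degradation lowers honest annotated reads too), selection works
on *groups*: the remaining ANNOTATED reads are grouped by best isoform,
groups are ranked ascending by squared mean similarity, and whole
groups are relabeled ATSS until the budget
$\max(0, \lfloor c\,|AS|\rfloor - |NE|)$ is reached (default $c = 1.5$,
the assumed ratio of non-AS novel reads to AS novel reads; $|NE|$
counts NOVEL_EXON and TRUNC_NOVEL reads already selected). A group that
would overflow the budget is skipped and selection stops — partial
groups would defeat the group-level rationale. Groups with mean
similarity at or above $B = 0.98$ (the expected ceiling for a truly
novel read) are never selected; $B$ is applied as this group-level gate
only, not to individual reads, since single-read scores are exactly the
noisy quantity the grouping exists to avoid. Group means are computed
after AS/NOVEL_EXON reads have left the pool, i.e. over the reads the
group actually holds at selection time.

Unmapped reads are emitted as novel candidates in both modes: a read
sharing no indexed kmer with any known isoform is maximally novel.

In quantify mode, each isoform's ANNOTATED reads are subsampled to at
most $l$ (default 5) without replacement, and the scale factor
$n_\mathrm{mapped}/n_\mathrm{sampled}$ restores abundance estimates
downstream (`rescale_abundances()`, optionally renormalizing to TPM).
The subsample draws a deterministic RNG stream per isoform derived from
the global seed and the isoform ID, so results do not depend on read or
isoform processing order.

## The synthetic data generator

`simulate_transcriptome()` builds genes as banks of i.i.d. random exon
blocks (default 5 exons of 80–200 bp) and isoforms as distinct exon
chains of at least 250 bp, holding out a fraction (default 20%) as novel
via four event classes applied to the gene's full-length isoform: an
internal exon skipped, an intron-like block retained, a novel terminal
exon attached, or a terminal exon dropped (ATSS). Every gene keeps at
least one annotated isoform and no novel chain coincides with an
annotated one. `simulate_reads()` then draws a fixed depth of reads per
isoform with i.i.d. substitution errors (default 0.002/bp) and optional
end truncation.

What this emulates: the regime of high-fidelity long reads, where
errors are sparse substitutions; events at realistic exon scales; genes
whose isoforms share most of their sequence, which is precisely what
makes candidate resolution and assignment non-trivial. What it does
not: indels and homopolymer artifacts, GC and motif structure, splice
junction sequence signals, expression-level variation across isoforms,
and intron chains recombined across genes. Passing the end-to-end
checks therefore demonstrates the *selection logic* under the stated
noise model, not robustness to every artifact of a real sequencer; the
per-read primitives are exercised against brute-force oracles
independently of the generator.

Default validation sizes, chosen to exercise every code path while
keeping the whole suite quick on a laptop: 100 genes × 5 isoforms ×
depth 20 (10,000 reads) for the discovery check; 60 annotated-only
genes at uniform depth 20 for the quantification check; 1000 random
anchor tables and 10,000 random sketch pairs for the oracle checks.
On one core the discovery fixture runs in well under a minute.

## Numerical and interface conventions

* Coordinates are 0-based, intervals half-open; lengths in bp.
* Hash values are exact integers carried in doubles (hence $k \le 26$);
  map keys are their decimal strings.
* The retention threshold $\lfloor \gamma M \rfloor$ is computed once in
  one place; tests reuse it rather than re-deriving it.
* Record IDs are taken verbatim up to the first whitespace; sequences
  are uppercased on input; output candidate records are verbatim copies
  of input records in the input's format.
* Empty inputs are legal everywhere: empty sketches, empty anchor
  tables (score 0), empty candidate sets (UNMAPPED), and an empty read
  file produce empty, well-formed outputs.
* All randomness flows from explicit seeds; two runs with the same
  configuration and seed produce byte-identical files.

## Limitations

The method sees transcripts only through exact sketched kmers: events
shorter than the minimum exon length $n$, or events whose flanks happen
to carry no sketched kmer (probability $(1-\gamma)^{f-k+1}$ for a flank
of length $f$), are invisible. Similarity-based ATSS selection is
heuristic by construction — it trades annotated-read leakage against
ATSS recall through $c$ — and reads from novel ATSS isoforms that pool
with an annotated isoform's own reads drag that group's mean down,
so some annotated reads ride along whenever such a group is selected.
Quantify-mode counts inherit any misassignment between isoforms that
are sketched nearly identically. None of these affect the exactness of
the conservation identity $\sum n_\mathrm{sampled} \times
\mathrm{scale} = \sum n_\mathrm{mapped}$.

## A worked example

```{r example}
tx <- simulate_transcriptome(n_genes = 10, seed = 7)
rd <- simulate_reads(tx, depth = 5, error_rate = 0.002, seed = 8)
res <- sieve_reads(tx$reference, rd, sketch_params(), selection_params(),
                   seed = 1)
table(truth = rd$truth_label, called = res$decisions$label)
```
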