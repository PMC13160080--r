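#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
using namespace Rcpp;

// 2-bit encoding: A=0, C=1, G=2, T=3; anything else is invalid.
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Invertible integer mixing hash restricted to the low 2k bits
// (the classic 64-bit finalizer used by minimizer-based mappers).
// Every step is a bijection modulo 2^(2k), so distinct kmers can
// never collide within the 2k-bit domain.
static inline uint64_t hash_mix(uint64_t key, uint64_t mask) {
  key = (~key + (key << 21)) & mask;
  key = key ^ (key >> 24);
  key = ((key + (key << 3)) + (key << 8)) & mask; // key * 265
  key = key ^ (key >> 14);
  key = ((key + (key << 2)) + (key << 4)) & mask; // key * 21
  key = key ^ (key >> 28);
  key = (key + (key << 31)) & mask;
  return key;
}

// modular inverse of an odd constant modulo 2^64 (Newton iteration)
static inline uint64_t inv_odd(uint64_t c) {
  uint64_t x = c;
  for (int i = 0; i < 6; ++i) x *= 2 - c * x;
  return x;
}

// invert y = x ^ (x >> s) on a w-bit word
static inline uint64_t unxorshift(uint64_t y, int s, uint64_t mask) {
  uint64_t x = y;
  for (int i = 0; i < 64; i += s) x = (y ^ (x >> s)) & mask;
  return x;
}

static inline uint64_t hash_unmix(uint64_t key, uint64_t mask) {
  key = (key * inv_odd(1ULL + (1ULL << 31))) & mask;     // undo *(2^31+1)
  key = unxorshift(key, 28, mask);
  key = (key * inv_odd(21ULL)) & mask;                    // undo *21
  key = unxorshift(key, 14, mask);
  key = (key * inv_odd(265ULL)) & mask;                   // undo *265
  key = unxorshift(key, 24, mask);
  // undo key = (2^21 - 1)*x - 1  (mod 2^w)
  key = ((key + 1) * inv_odd((1ULL << 21) - 1ULL)) & mask;
  return key;
}

static inline uint64_t domain_mask(int k) {
  return (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string r(s.rbegin(), s.rend());
    for (char &c : r) {
      switch (c) {
      case 'A': c = 'T'; break; case 'a': c = 't'; break;
      case 'C': c = 'G'; break; case 'c': c = 'g'; break;
      case 'G': c = 'C'; break; case 'g': c = 'c'; break;
      case 'T': c = 'A'; break; case 't': c = 'a'; break;
      default: break; // N and friends complement to themselves
      }
    }
    out[i] = r;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_hash_kmers(CharacterVector kmers, int k) {
  if (k < 1 || k > 26) stop("k must be in [1, 26]");
  uint64_t mask = domain_mask(k);
  int n = kmers.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(kmers, i));
    uint64_t enc = 0;
    bool ok = ((int)strlen(s) == k);
    if (ok) {
      for (int j = 0; j < k; ++j) {
        int c = base_code(s[j]);
        if (c < 0) { ok = false; break; }
        enc = (enc << 2) | (uint64_t)c;
      }
    }
    out[i] = ok ? (double)hash_mix(enc, mask) : NA_REAL;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_unhash_kmers(NumericVector hashes, int k) {
  if (k < 1 || k > 26) stop("k must be in [1, 26]");
  uint64_t mask = domain_mask(k);
  int n = hashes.size();
  CharacterVector out(n);
  const char *alpha = "ACGT";
  std::vector<char> buf(k + 1);
  buf[k] = '\0';
  for (int i = 0; i < n; ++i) {
    if (NumericVector::is_na(hashes[i])) { out[i] = NA_STRING; continue; }
    uint64_t enc = hash_unmix((uint64_t)hashes[i], mask);
    for (int j = k - 1; j >= 0; --j) { buf[j] = alpha[enc & 3ULL]; enc >>= 2; }
    out[i] = std::string(buf.data());
  }
  return out;
}

// Positional FracMinHash sketch: every kmer occurrence whose hash falls
// at or below floor(gamma * M) is retained, with its 0-based offset.
// Windows containing a non-ACGT character are skipped entirely.
// [[Rcpp::export]]
List cpp_sketch(std::string seq, int k, double threshold) {
  uint64_t mask = domain_mask(k);
  uint64_t thr = (uint64_t)threshold;
  int n = seq.size();
  std::vector<int> pos;
  std::vector<double> hash;
  int total = 0; // valid (all-ACGT) kmer windows
  uint64_t enc = 0;
  int run = 0; // length of current run of valid bases
  for (int i = 0; i < n; ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { run = 0; enc = 0; continue; }
    enc = ((enc << 2) | (uint64_t)c) & mask;
    if (++run >= k) {
      ++total;
      uint64_t h = hash_mix(enc, mask);
      if (h <= thr) { pos.push_back(i - k + 1); hash.push_back((double)h); }
    }
  }
  return List::create(_["pos"] = wrap(pos), _["hash"] = wrap(hash),
                      _["n_kmers"] = total);
}

// Anchor table between two positional sketches: one anchor per
// (query occurrence, reference occurrence) pair of every shared kmer,
// optionally restricted to kmers surviving the index occupancy cap.
// Sorted by q_pos ascending, then r_pos ascending.
// [[Rcpp::export]]
DataFrame cpp_anchor_table(IntegerVector qpos, NumericVector qhash,
                           IntegerVector rpos, NumericVector rhash,
                           Nullable<NumericVector> allowed = R_NilValue) {
  std::unordered_map<uint64_t, std::vector<int> > rmap;
  for (int i = 0; i < rpos.size(); ++i)
    rmap[(uint64_t)rhash[i]].push_back(rpos[i]);
  std::unordered_set<uint64_t> keep;
  bool restrict_set = allowed.isNotNull();
  if (restrict_set) {
    NumericVector a(allowed);
    for (int i = 0; i < a.size(); ++i) keep.insert((uint64_t)a[i]);
  }
  std::vector<int> aq, ar;
  std::vector<double> ah;
  for (int i = 0; i < qpos.size(); ++i) {
    uint64_t h = (uint64_t)qhash[i];
    if (restrict_set && !keep.count(h)) continue;
    auto it = rmap.find(h);
    if (it == rmap.end()) continue;
    for (int rp : it->second) {
      aq.push_back(qpos[i]); ar.push_back(rp); ah.push_back((double)h);
    }
  }
  // sort by (q_pos, r_pos); query sketch is position-sorted already but
  // multi-occurrence kmers need the secondary key enforced
  int n = aq.size();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::stable_sort(idx.begin(), idx.end(), [&](int a, int b) {
    if (aq[a] != aq[b]) return aq[a] < aq[b];
    return ar[a] < ar[b];
  });
  IntegerVector oq(n), orr(n);
  NumericVector oh(n);
  for (int i = 0; i < n; ++i) {
    oq[i] = aq[idx[i]]; orr[i] = ar[idx[i]]; oh[i] = ah[idx[i]];
  }
  return DataFrame::create(_["q_pos"] = oq, _["r_pos"] = orr, _["hash"] = oh);
}

// Two-track banded colinear chaining.
//
// Track a: optimal chain among anchors 1..i that ends with anchor i.
// Track n: optimal chain among anchors 1..i that does not include i.
// The chain score is the number of anchors chained; precedence is
// strict increase in BOTH coordinates, tested against the last anchor
// (LP) of the predecessor chain.  The band for anchor i extends
// backward until at least band_m distinct q positions AND band_m
// distinct r positions have been seen, which skips over repeated-kmer
// anchor runs.  The largest absolute diagonal gap
//   |g| = |(q_i - q_prev) - (r_i - r_prev)|
// along the winning chain is propagated with it.
// Ties in the DP prefer track a over track n, then the nearest
// (largest-index) predecessor.
// [[Rcpp::export]]
List cpp_chain(IntegerVector qpos, IntegerVector rpos, int band_m) {
  int n = qpos.size();
  if (band_m < 1) stop("band_m must be >= 1");
  if (n == 0)
    return List::create(_["score"] = 0, _["fp_q"] = NA_INTEGER,
                        _["fp_r"] = NA_INTEGER, _["lp_q"] = NA_INTEGER,
                        _["lp_r"] = NA_INTEGER, _["largest_gap"] = 0,
                        _["track"] = NA_STRING);
  std::vector<int> fa(n), fn(n);
  // per-track chain metadata: first/last anchor coords and running max |gap|
  std::vector<int> fa_fpq(n), fa_fpr(n), fa_lpq(n), fa_lpr(n), fa_gap(n);
  std::vector<int> fn_fpq(n), fn_fpr(n), fn_lpq(n), fn_lpr(n), fn_gap(n);

  for (int i = 0; i < n; ++i) {
    int qi = qpos[i], ri = rpos[i];
    // --- track a: start a fresh chain at i, or extend a predecessor chain
    int best = 1, bfpq = qi, bfpr = ri, bgap = 0;
    bool best_from_a = true; // fresh start counts as track-a provenance
    // --- track n: best chain not using i
    int nbest = 0, nfpq = NA_INTEGER, nfpr = NA_INTEGER,
        nlpq = NA_INTEGER, nlpr = NA_INTEGER, ngap = 0;
    bool n_set = false, nbest_from_a = true;

    std::unordered_set<int> uq, ur;
    for (int j = i - 1; j >= 0; --j) {
      // candidate: extend chain ending at j (track a)
      if (fa_lpq[j] < qi && fa_lpr[j] < ri) {
        int cand = fa[j] + 1;
        if (cand > best || (cand == best && !best_from_a)) {
          best = cand;
          int g = (qi - fa_lpq[j]) - (ri - fa_lpr[j]);
          if (g < 0) g = -g;
          bgap = std::max(fa_gap[j], g);
          bfpq = fa_fpq[j]; bfpr = fa_fpr[j];
          best_from_a = true;
        }
      }
      // candidate: extend chain recorded on track n at j
      if (fn[j] >= 1 && fn_lpq[j] < qi && fn_lpr[j] < ri) {
        int cand = fn[j] + 1;
        if (cand > best) {
          best = cand;
          int g = (qi - fn_lpq[j]) - (ri - fn_lpr[j]);
          if (g < 0) g = -g;
          bgap = std::max(fn_gap[j], g);
          bfpq = fn_fpq[j]; bfpr = fn_fpr[j];
          best_from_a = false;
        }
      }
      // track n carries the best chain so far forward unchanged
      if (!n_set || fa[j] > nbest || (fa[j] == nbest && !nbest_from_a)) {
        nbest = fa[j]; nfpq = fa_fpq[j]; nfpr = fa_fpr[j];
        nlpq = fa_lpq[j]; nlpr = fa_lpr[j]; ngap = fa_gap[j];
        n_set = true; nbest_from_a = true;
      }
      if (fn[j] > nbest) {
        nbest = fn[j]; nfpq = fn_fpq[j]; nfpr = fn_fpr[j];
        nlpq = fn_lpq[j]; nlpr = fn_lpr[j]; ngap = fn_gap[j];
        n_set = true; nbest_from_a = false;
      }
      uq.insert(qpos[j]); ur.insert(rpos[j]);
      if ((int)uq.size() >= band_m && (int)ur.size() >= band_m) break;
    }
    fa[i] = best; fa_fpq[i] = bfpq; fa_fpr[i] = bfpr;
    fa_lpq[i] = qi; fa_lpr[i] = ri; fa_gap[i] = bgap;
    fn[i] = nbest; fn_fpq[i] = nfpq; fn_fpr[i] = nfpr;
    fn_lpq[i] = nlpq; fn_lpr[i] = nlpr; fn_gap[i] = ngap;
  }

  // overall optimum: max over every entry of both tracks; ties prefer
  // track a, then the earliest entry (deterministic endpoints)
  int score = 0, fpq = NA_INTEGER, fpr = NA_INTEGER,
      lpq = NA_INTEGER, lpr = NA_INTEGER, gap = 0;
  bool from_a = true;
  for (int i = 0; i < n; ++i) {
    if (fa[i] > score) {
      score = fa[i]; fpq = fa_fpq[i]; fpr = fa_fpr[i];
      lpq = fa_lpq[i]; lpr = fa_lpr[i]; gap = fa_gap[i]; from_a = true;
    }
    if (fn[i] > score) {
      score = fn[i]; fpq = fn_fpq[i]; fpr = fn_fpr[i];
      lpq = fn_lpq[i]; lpr = fn_lpr[i]; gap = fn_gap[i]; from_a = false;
    }
  }
  return List::create(_["score"] = score, _["fp_q"] = fpq, _["fp_r"] = fpr,
                      _["lp_q"] = lpq, _["lp_r"] = lpr,
                      _["largest_gap"] = gap,
                      _["track"] = from_a ? "a" : "n");
}
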