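#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// 2-bit encode; -1 marks any k-mer containing a non-ACGT residue.
static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

// codes[i] = integer code of the k-mer starting at 0-based position i, or -1.
static std::vector<int64_t> encode_kmers(const std::string& s, int k) {
  int n = (int)s.size();
  int m = n - k + 1;
  std::vector<int64_t> codes;
  if (m <= 0) return codes;
  codes.assign(m, -1);
  int64_t mask = (k >= 32) ? -1 : ((int64_t(1) << (2 * k)) - 1);
  int64_t cur = 0;
  int valid = 0; // number of consecutive valid bases ending at i
  for (int i = 0; i < n; ++i) {
    int b = base_code(s[i]);
    if (b < 0) {
      valid = 0;
      cur = 0;
    } else {
      cur = ((cur << 2) | b) & mask;
      ++valid;
    }
    if (i >= k - 1 && valid >= k) codes[i - k + 1] = cur;
  }
  return codes;
}

// Forward/backward match-distance score tracks.
// forward[p] = distance to nearest downstream identical k-mer within
// [min_dist, max_dist] (distance between start positions), else 0;
// backward[p] symmetric for upstream. Directions are independent.
// [[Rcpp::export(name = ".score_tracks_cpp")]]
List score_tracks_cpp(std::string seq, int k, int min_dist, int max_dist) {
  std::vector<int64_t> codes = encode_kmers(seq, k);
  int m = (int)codes.size();
  IntegerVector fwd(m, 0), bwd(m, 0);
  if (m == 0) return List::create(_["forward"] = fwd, _["backward"] = bwd);

  std::unordered_map<int64_t, std::vector<int> > pos;
  pos.reserve(m * 2);
  for (int i = 0; i < m; ++i)
    if (codes[i] >= 0) pos[codes[i]].push_back(i);

  for (auto& kv : pos) {
    const std::vector<int>& v = kv.second;
    int nv = (int)v.size();
    if (nv < 2) continue;
    for (int i = 0; i < nv; ++i) {
      int p = v[i];
      // forward: first occurrence >= p + min_dist
      {
        int lo = i + 1, hi = nv; // search in v[(i+1)..]
        int target = p + min_dist;
        while (lo < hi) {
          int mid = (lo + hi) / 2;
          if (v[mid] < target) lo = mid + 1; else hi = mid;
        }
        if (lo < nv && v[lo] - p <= max_dist) fwd[p] = v[lo] - p;
      }
      // backward: last occurrence <= p - min_dist
      {
        int lo = 0, hi = i; // search in v[0..(i-1)]
        int target = p - min_dist;
        while (lo < hi) {
          int mid = (lo + hi) / 2;
          if (v[mid] <= target) lo = mid + 1; else hi = mid;
        }
        if (hi > 0 && p - v[hi - 1] <= max_dist) bwd[p] = p - v[hi - 1];
      }
    }
  }
  return List::create(_["forward"] = fwd, _["backward"] = bwd);
}

// Repeat-content profile: per-position fold-over-expectation scores.
// Counts k-mer occurrences over the whole genome set, fits an order-2
// Markov background on the same sequences, and scores each k-mer start as
// max(0, observed / max(1, expected) - 1). Positions whose k-mer contains
// N score 0. Returns one numeric vector per sequence, each of length
// nchar(sequence) (trailing k-1 positions score 0).
// [[Rcpp::export(name = ".profile_scores_cpp")]]
List profile_scores_cpp(List seqs, int k) {
  int ns = seqs.size();
  std::vector<std::vector<int64_t> > codes(ns);
  std::unordered_map<int64_t, double> counts;
  double total_kmers = 0.0;

  // order-2 Markov: dinucleotide and trinucleotide counts
  double di[16] = {0.0}, tri[64] = {0.0};
  double di_total = 0.0;

  for (int s = 0; s < ns; ++s) {
    std::string sq = as<std::string>(seqs[s]);
    codes[s] = encode_kmers(sq, k);
    for (int64_t c : codes[s])
      if (c >= 0) { counts[c] += 1.0; total_kmers += 1.0; }
    int prev1 = -1, prev2 = -1;
    for (size_t i = 0; i < sq.size(); ++i) {
      int b = base_code(sq[i]);
      if (b >= 0 && prev1 >= 0) { di[prev1 * 4 + b] += 1.0; di_total += 1.0; }
      if (b >= 0 && prev1 >= 0 && prev2 >= 0)
        tri[prev2 * 16 + prev1 * 4 + b] += 1.0;
      prev2 = prev1;
      prev1 = b;
    }
  }

  // P(w) = P(w1 w2) * prod_i P(w_i | w_{i-2} w_{i-1}); add-one smoothing
  double p_di[16], p_tr[64];
  for (int i = 0; i < 16; ++i)
    p_di[i] = (di[i] + 1.0) / (di_total + 16.0);
  for (int ab = 0; ab < 16; ++ab) {
    double tot = tri[ab * 4] + tri[ab * 4 + 1] + tri[ab * 4 + 2] + tri[ab * 4 + 3];
    for (int c = 0; c < 4; ++c)
      p_tr[ab * 4 + c] = (tri[ab * 4 + c] + 1.0) / (tot + 4.0);
  }

  std::unordered_map<int64_t, double> score_cache;
  score_cache.reserve(counts.size() * 2);
  List out(ns);
  for (int s = 0; s < ns; ++s) {
    std::string sq = as<std::string>(seqs[s]);
    int n = (int)sq.size();
    NumericVector sc(n, 0.0);
    int m = (int)codes[s].size();
    for (int i = 0; i < m; ++i) {
      int64_t c = codes[s][i];
      if (c < 0) continue;
      auto it = score_cache.find(c);
      double val;
      if (it != score_cache.end()) {
        val = it->second;
      } else {
        // decode bases from the 2-bit code (most significant first)
        double logp = 0.0;
        int b[32];
        for (int j = k - 1; j >= 0; --j) {
          b[j] = (int)(c & 3);
          c >>= 2;
        }
        logp += std::log(p_di[b[0] * 4 + b[1]]);
        for (int j = 2; j < k; ++j)
          logp += std::log(p_tr[b[j - 2] * 16 + b[j - 1] * 4 + b[j]]);
        double expected = total_kmers * std::exp(logp);
        if (expected < 1.0) expected = 1.0;
        double obs = counts[codes[s][i]];
        val = obs / expected - 1.0;
        if (val < 0.0) val = 0.0;
        score_cache[codes[s][i]] = val;
      }
      sc[i] = val;
    }
    out[s] = sc;
  }
  return out;
}

// Fraction of valid k-mers of seq[src_start, src_end) (0-based half-open)
// having at least one exact copy among the k-mers of seq[tgt_start, tgt_end).
// [[Rcpp::export(name = ".kmer_fraction_shared_cpp")]]
double kmer_fraction_shared_cpp(std::string seq, int src_start, int src_end,
                                int tgt_start, int tgt_end, int k) {
  if (src_end - src_start < k || tgt_end - tgt_start < k) return 0.0;
  std::string src = seq.substr(src_start, src_end - src_start);
  std::string tgt = seq.substr(tgt_start, tgt_end - tgt_start);
  std::vector<int64_t> sc = encode_kmers(src, k);
  std::vector<int64_t> tc = encode_kmers(tgt, k);
  std::unordered_map<int64_t, char> tset;
  tset.reserve(tc.size() * 2);
  for (int64_t c : tc) if (c >= 0) tset[c] = 1;
  double total = 0.0, hit = 0.0;
  for (int64_t c : sc) {
    if (c < 0) continue;
    total += 1.0;
    if (tset.count(c)) hit += 1.0;
  }
  return total > 0.0 ? hit / total : 0.0;
}
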