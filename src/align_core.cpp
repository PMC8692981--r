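#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// 2-bit DNA encoding; -1 for anything that is not A/C/G/T
static inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char complement(char c) {
  switch (c) {
  case 'A': case 'a': return 'T';
  case 'C': case 'c': return 'G';
  case 'G': case 'g': return 'C';
  case 'T': case 't': return 'A';
  default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = complement(r[i]);
  return r;
}

struct Posting {
  int32_t seq;   // 0-based target index
  int32_t pos;   // 0-based position on the indexed strand
  char strand;   // '+' forward, '-' position is on the reverse complement
};

typedef std::unordered_map<uint64_t, std::vector<Posting> > KmerMap;

static void index_string(KmerMap& map, const std::string& s, int k,
                         int32_t seq, char strand) {
  const int n = (int)s.size();
  if (n < k) return;
  uint64_t code = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)b) & mask;
    if (++run >= k) {
      Posting p; p.seq = seq; p.pos = i - k + 1; p.strand = strand;
      map[code].push_back(p);
    }
  }
}

// Exact k-mer seed hits of `queries` (forward strand only) against both
// strands of `targets`. Reverse-strand postings carry positions on the
// reverse-complemented target. `exclude_self` drops the trivial identity
// diagonal when a sequence list is aligned against itself.
// [[Rcpp::export]]
DataFrame cpp_seed_hits(CharacterVector queries, CharacterVector targets,
                        int k, bool exclude_self = false) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  KmerMap map;
  for (int t = 0; t < targets.size(); ++t) {
    std::string s = as<std::string>(targets[t]);
    index_string(map, s, k, t, '+');
    index_string(map, revcomp(s), k, t, '-');
  }
  std::vector<int> qv, tv, qp, tp;
  std::vector<char> sv;
  for (int q = 0; q < queries.size(); ++q) {
    std::string s = as<std::string>(queries[q]);
    const int n = (int)s.size();
    if (n < k) continue;
    uint64_t code = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
    int run = 0;
    for (int i = 0; i < n; ++i) {
      int b = base2bits(s[i]);
      if (b < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++run < k) continue;
      KmerMap::const_iterator it = map.find(code);
      if (it == map.end()) continue;
      int qpos = i - k + 1;
      for (size_t j = 0; j < it->second.size(); ++j) {
        const Posting& p = it->second[j];
        if (exclude_self && p.strand == '+' && p.seq == q && p.pos == qpos)
          continue;
        qv.push_back(q + 1); tv.push_back(p.seq + 1);
        qp.push_back(qpos); tp.push_back(p.pos);
        sv.push_back(p.strand);
      }
    }
  }
  CharacterVector strand(sv.size());
  for (size_t i = 0; i < sv.size(); ++i)
    strand[i] = (sv[i] == '+') ? "+" : "-";
  return DataFrame::create(_["query"] = qv, _["target"] = tv,
                           _["qpos"] = qp, _["tpos"] = tp,
                           _["strand"] = strand,
                           _["stringsAsFactors"] = false);
}

// Enumerate all k-mer postings of a set of sequences (both strands), used
// by the introspectable seed index. Positions on '-' are on the reverse
// complement of the sequence.
// [[Rcpp::export]]
DataFrame cpp_kmer_postings(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  std::vector<int> sv, pv;
  std::vector<char> strv;
  std::vector<std::string> kv;
  for (int t = 0; t < seqs.size(); ++t) {
    std::string s = as<std::string>(seqs[t]);
    for (int pass = 0; pass < 2; ++pass) {
      std::string x = (pass == 0) ? s : revcomp(s);
      if ((int)x.size() < k) continue;
      for (int i = 0; i + k <= (int)x.size(); ++i) {
        bool ok = true;
        for (int j = i; j < i + k; ++j)
          if (base2bits(x[j]) < 0) { ok = false; break; }
        if (!ok) continue;
        sv.push_back(t + 1); pv.push_back(i);
        strv.push_back(pass == 0 ? '+' : '-');
        kv.push_back(x.substr(i, k));
      }
    }
  }
  CharacterVector kmer(kv.size()), strand(strv.size());
  for (size_t i = 0; i < kv.size(); ++i) {
    kmer[i] = kv[i];
    strand[i] = (strv[i] == '+') ? "+" : "-";
  }
  return DataFrame::create(_["kmer"] = kmer, _["seq"] = sv, _["pos"] = pv,
                           _["strand"] = strand,
                           _["stringsAsFactors"] = false);
}

static const double NEG = -1e18;

struct ExtResult {
  int qlen, tlen;
  double score;
  int matches, cols;
};

// One-directional x-drop DP extension of a vs b from their origins, with
// unit costs (match +1, mismatch -1, gap -2). Tracks matches and alignment
// columns along the optimal path.
static ExtResult xdrop_dir(const std::string& a, const std::string& b,
                           double xdrop) {
  const int n = (int)a.size(), m = (int)b.size();
  ExtResult best; best.qlen = 0; best.tlen = 0; best.score = 0;
  best.matches = 0; best.cols = 0;
  if (n == 0 || m == 0) return best;
  // rows over a; adaptive column window [lo, hi] over b
  int lo = 0, hi = 0;
  // row 0: gaps in a
  while (hi < m && -2.0 * (hi + 1) >= -xdrop) ++hi;
  std::vector<double> prev(hi - lo + 1);
  std::vector<int> prevM(hi - lo + 1), prevC(hi - lo + 1);
  for (int j = lo; j <= hi; ++j) {
    prev[j - lo] = -2.0 * j; prevM[j - lo] = 0; prevC[j - lo] = j;
  }
  double bestScore = 0;
  for (int i = 1; i <= n; ++i) {
    int nlo = lo, nhi = std::min(hi + 1, m);
    std::vector<double> cur(nhi - nlo + 1, NEG);
    std::vector<int> curM(nhi - nlo + 1, 0), curC(nhi - nlo + 1, 0);
    bool any = false;
    for (int j = nlo; j <= nhi; ++j) {
      double sc = NEG; int mm = 0, cc = 0;
      // diagonal
      if (j >= 1 && j - 1 >= lo && j - 1 <= hi && prev[j - 1 - lo] > NEG / 2) {
        bool isM = (base2bits(a[i - 1]) >= 0 &&
                    base2bits(a[i - 1]) == base2bits(b[j - 1]));
        double s = prev[j - 1 - lo] + (isM ? 1.0 : -1.0);
        if (s > sc) { sc = s; mm = prevM[j - 1 - lo] + (isM ? 1 : 0);
                      cc = prevC[j - 1 - lo] + 1; }
      }
      // up: gap in b (consume a)
      if (j >= lo && j <= hi && prev[j - lo] > NEG / 2) {
        double s = prev[j - lo] - 2.0;
        if (s > sc) { sc = s; mm = prevM[j - lo]; cc = prevC[j - lo] + 1; }
      }
      // left: gap in a (consume b)
      if (j - 1 >= nlo && cur[j - 1 - nlo] > NEG / 2) {
        double s = cur[j - 1 - nlo] - 2.0;
        if (s > sc) { sc = s; mm = curM[j - 1 - nlo];
                      cc = curC[j - 1 - nlo] + 1; }
      }
      if (sc < bestScore - xdrop) sc = NEG;
      cur[j - nlo] = sc; curM[j - nlo] = mm; curC[j - nlo] = cc;
      if (sc > NEG / 2) {
        any = true;
        if (sc > bestScore) {
          bestScore = sc;
          best.qlen = i; best.tlen = j;
          best.score = sc; best.matches = mm; best.cols = cc;
        }
      }
    }
    if (!any) break;
    // shrink window to live cells
    int s = nlo, e = nhi;
    while (s <= nhi && cur[s - nlo] < NEG / 2) ++s;
    while (e >= s && cur[e - nlo] < NEG / 2) --e;
    if (s > e) break;
    lo = s; hi = e;
    prev.assign(cur.begin() + (s - nlo), cur.begin() + (e - nlo) + 1);
    prevM.assign(curM.begin() + (s - nlo), curM.begin() + (e - nlo) + 1);
    prevC.assign(curC.begin() + (s - nlo), curC.begin() + (e - nlo) + 1);
    if (lo == m) break;
  }
  return best;
}

// Two-sided x-drop extension of an exact anchor point (qpos, tpos),
// 0-based. Returns 0-based half-open query/target intervals plus score,
// match count and alignment column count of the combined extension.
// [[Rcpp::export]]
List cpp_xdrop_extend(std::string q, std::string t, int qpos, int tpos,
                      double xdrop) {
  std::string qr(q.begin(), q.begin() + qpos); std::reverse(qr.begin(), qr.end());
  std::string tr(t.begin(), t.begin() + tpos); std::reverse(tr.begin(), tr.end());
  std::string qf(q.begin() + qpos, q.end());
  std::string tf(t.begin() + tpos, t.end());
  ExtResult L = xdrop_dir(qr, tr, xdrop);
  ExtResult R = xdrop_dir(qf, tf, xdrop);
  return List::create(
    _["qstart"] = qpos - L.qlen, _["qend"] = qpos + R.qlen,
    _["tstart"] = tpos - L.tlen, _["tend"] = tpos + R.tlen,
    _["score"] = L.score + R.score,
    _["matches"] = L.matches + R.matches,
    _["cols"] = L.cols + R.cols);
}

// Per-position depth of scaffolds from exact k-mer assignment of reads.
// A read k-mer matching n positions (over both scaffold strands)
// contributes 1/n coverage to each matched k-length window.
// [[Rcpp::export]]
List cpp_kmer_depth(CharacterVector scaffolds, CharacterVector reads, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  KmerMap map;
  std::vector<int> lens(scaffolds.size());
  for (int t = 0; t < scaffolds.size(); ++t) {
    std::string s = as<std::string>(scaffolds[t]);
    lens[t] = (int)s.size();
    index_string(map, s, k, t, '+');
  }
  std::vector<std::vector<double> > depth(scaffolds.size());
  for (int t = 0; t < scaffolds.size(); ++t)
    depth[t].assign(lens[t], 0.0);
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  const int shift = 2 * (k - 1);
  for (int r = 0; r < reads.size(); ++r) {
    std::string s = as<std::string>(reads[r]);
    const int n = (int)s.size();
    if (n < k) continue;
    uint64_t code = 0, rc = 0;
    int run = 0;
    for (int i = 0; i < n; ++i) {
      int b = base2bits(s[i]);
      if (b < 0) { run = 0; code = 0; rc = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      rc = (rc >> 2) | (((uint64_t)(3 - b)) << shift);
      if (++run < k) continue;
      KmerMap::const_iterator it1 = map.find(code);
      KmerMap::const_iterator it2 = (rc != code) ? map.find(rc) : map.end();
      size_t nhit = (it1 != map.end() ? it1->second.size() : 0) +
                    (it2 != map.end() ? it2->second.size() : 0);
      if (nhit == 0) continue;
      double w = 1.0 / (double)nhit;
      if (it1 != map.end())
        for (size_t j = 0; j < it1->second.size(); ++j) {
          const Posting& p = it1->second[j];
          for (int x = p.pos; x < p.pos + k; ++x) depth[p.seq][x] += w;
        }
      if (it2 != map.end())
        for (size_t j = 0; j < it2->second.size(); ++j) {
          const Posting& p = it2->second[j];
          for (int x = p.pos; x < p.pos + k; ++x) depth[p.seq][x] += w;
        }
    }
  }
  List out(scaffolds.size());
  for (int t = 0; t < scaffolds.size(); ++t)
    out[t] = NumericVector(depth[t].begin(), depth[t].end());
  out.names() = scaffolds.names();
  return out;
}

// Sequencing-error injection with a substitution:insertion:deletion mix.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
CharacterVector cpp_mutate_reads(CharacterVector seqs, double rate,
                                 double p_sub, double p_ins, double p_del) {
  static const char B[4] = {'A', 'C', 'G', 'T'};
  double tot = p_sub + p_ins + p_del;
  if (tot <= 0) tot = 1.0;
  double c1 = p_sub / tot, c2 = (p_sub + p_ins) / tot;
  CharacterVector out(seqs.size());
  for (int r = 0; r < seqs.size(); ++r) {
    std::string s = as<std::string>(seqs[r]);
    std::string o;
    o.reserve(s.size() + 16);
    for (size_t i = 0; i < s.size(); ++i) {
      if (rate > 0 && unif_rand() < rate) {
        double u = unif_rand();
        if (u < c1) {                       // substitution
          int b = base2bits(s[i]);
          int nb = (int)(unif_rand() * 3.0); if (nb > 2) nb = 2;
          if (b >= 0) { if (nb >= b) ++nb; o.push_back(B[nb]); }
          else o.push_back(B[nb]);
        } else if (u < c2) {                // insertion (base kept)
          int nb = (int)(unif_rand() * 4.0); if (nb > 3) nb = 3;
          o.push_back(s[i]);
          o.push_back(B[nb]);
        }                                    // deletion: drop base
      } else {
        o.push_back(s[i]);
      }
    }
    out[r] = o;
  }
  out.names() = seqs.names();
  return out;
}
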