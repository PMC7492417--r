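// Core dynamic-programming primitives: pairwise global/local alignment with
// per-column (linear) gap costs, exact cyclic alignment over all rotations,
// wraparound DP against a cyclic monomer (TRF-style scoring), k-mer seed
// scanning and k-mer sharing prescreens.
//
// Conventions shared with the R layer:
//  * scores are additive: match > 0, mismatch < 0, indel < 0 per gap column;
//  * 'N' never matches anything, including another 'N' (scores as mismatch);
//  * identity = matches / alignment columns, gap columns included;
//  * deterministic tie-breaking: prefer diagonal, then up (gap in b,
//    consuming a), then left (gap in a, consuming b); local alignments end at
//    the first-encountered maximal cell in row-major order.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>

using namespace Rcpp;

static inline bool base_match(char x, char y) {
  return x == y && x != 'N';
}

enum Dir : unsigned char { STOP = 0, DIAG = 1, UP = 2, LEFT = 3 };

// Fill + traceback for plain (non-cyclic) alignment. Returns everything the
// AlignmentResult contract needs.
// [[Rcpp::export]]
List cpp_align(std::string a, std::string b, int match, int mismatch,
               int indel, bool local) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  std::vector<unsigned char> dir((size_t)(n + 1) * (m + 1), STOP);

  auto D = [&](int i, int j) -> unsigned char& {
    return dir[(size_t)i * (m + 1) + j];
  };

  int best = local ? 0 : 0;
  int best_i = 0, best_j = 0;

  prev[0] = 0;
  for (int j = 1; j <= m; ++j) {
    prev[j] = local ? 0 : prev[j - 1] + indel;
    if (!local) D(0, j) = LEFT;
  }
  for (int i = 1; i <= n; ++i) {
    cur[0] = local ? 0 : prev[0] + indel;
    if (!local) D(i, 0) = UP;
    for (int j = 1; j <= m; ++j) {
      int sdiag = prev[j - 1] +
                  (base_match(a[i - 1], b[j - 1]) ? match : mismatch);
      int sup = prev[j] + indel;
      int sleft = cur[j - 1] + indel;
      int s = sdiag;
      unsigned char d = DIAG;
      if (sup > s) { s = sup; d = UP; }
      if (sleft > s) { s = sleft; d = LEFT; }
      if (local && s <= 0) { s = 0; d = STOP; }
      cur[j] = s;
      D(i, j) = d;
      if (local && s > best) { best = s; best_i = i; best_j = j; }
    }
    std::swap(prev, cur);
  }

  int score, ei, ej;
  if (local) {
    score = best; ei = best_i; ej = best_j;
  } else {
    score = prev[m]; ei = n; ej = m;
  }

  // traceback
  std::string tr;
  int i = ei, j = ej, matches = 0, cols = 0;
  while (i > 0 || j > 0) {
    unsigned char d = D(i, j);
    if (local && d == STOP) break;
    if (!local && i == 0) d = LEFT;
    if (!local && j == 0) d = UP;
    if (d == DIAG) {
      bool mt = base_match(a[i - 1], b[j - 1]);
      tr.push_back(mt ? '=' : 'X');
      matches += mt;
      --i; --j;
    } else if (d == UP) {
      tr.push_back('I');
      --i;
    } else if (d == LEFT) {
      tr.push_back('D');
      --j;
    } else break;
    ++cols;
  }
  std::reverse(tr.begin(), tr.end());
  double identity = cols > 0 ? (double)matches / cols : 0.0;

  return List::create(
      _["score"] = score, _["identity"] = identity, _["matches"] = matches,
      _["columns"] = cols, _["a_start"] = i + 1, _["a_end"] = ei,
      _["b_start"] = j + 1, _["b_end"] = ej, _["transcript"] = tr);
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break;
      case 'C': c = 'G'; break;
      case 'G': c = 'C'; break;
      case 'T': c = 'A'; break;
      default: c = 'N';
    }
  }
  return r;
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break;
      case 'C': c = 'G'; break;
      case 'G': c = 'C'; break;
      case 'T': c = 'A'; break;
      default: c = 'N';
    }
  }
  return r;
}

// identity of the optimal-score global alignment (needs traceback counts)
static void global_identity(const std::string& a, const std::string& b,
                            int match, int mismatch, int indel,
                            int& score, double& identity) {
  List r = cpp_align(a, b, match, mismatch, indel, false);
  score = as<int>(r["score"]);
  identity = as<double>(r["identity"]);
}

// Exact cyclic comparison: maximise the identity of the optimal-score global
// alignment over every rotation of b and both orientations. Ties: higher
// score, then forward orientation, then smallest rotation.
// [[Rcpp::export]]
List cpp_cyclic_best(std::string a, std::string b, int match, int mismatch,
                     int indel) {
  const int m = (int)b.size();
  double best_id = -1.0;
  int best_score = INT32_MIN, best_rot = 0, best_ori = 1;
  for (int ori = 1; ori >= -1; ori -= 2) {
    std::string bb = (ori == 1) ? b : revcomp_str(b);
    std::string bb2 = bb + bb;
    for (int r = 0; r < m; ++r) {
      std::string rot = bb2.substr(r, m);
      int sc; double id;
      global_identity(a, rot, match, mismatch, indel, sc, id);
      if (id > best_id + 1e-12 ||
          (std::abs(id - best_id) <= 1e-12 && sc > best_score)) {
        best_id = id; best_score = sc; best_rot = r; best_ori = ori;
      }
    }
  }
  return List::create(_["identity"] = best_id, _["score"] = best_score,
                      _["rotation"] = best_rot, _["orientation"] = best_ori);
}

// Wraparound DP of a region against the cyclic extension of a monomer.
// Global mode: the whole region is aligned, monomer phase free at both ends
// (row 0 all zero; answer = max over the last row). Local mode: additionally
// the region ends are free (Smith-Waterman style clamp at 0), which yields
// array boundaries. One extra left-to-right wrap pass per row suffices
// because chains of gap columns strictly decrease the score.
// [[Rcpp::export]]
List cpp_wraparound(std::string region, std::string monomer, int match,
                    int mismatch, int indel, bool local) {
  const int n = (int)region.size(), p = (int)monomer.size();
  if (p < 1) stop("monomer must be non-empty");
  std::vector<int> prev(p + 1), cur(p + 1);
  std::vector<unsigned char> dir((size_t)(n + 1) * (p + 1), STOP);
  std::vector<unsigned char> wrapflag((size_t)(n + 1) * (p + 1), 0);
  auto D = [&](int i, int j) -> unsigned char& {
    return dir[(size_t)i * (p + 1) + j];
  };
  auto W = [&](int i, int j) -> unsigned char& {
    return wrapflag[(size_t)i * (p + 1) + j];
  };

  for (int j = 0; j <= p; ++j) prev[j] = 0;  // free phase start
  int best = 0, best_i = 0, best_j = 1;
  bool have_best = false;

  for (int i = 1; i <= n; ++i) {
    // pass 1: j = 1..p, left refers to current row j-1 (j=1 uses previous
    // row's wrap handled in pass 2)
    for (int j = 1; j <= p; ++j) {
      int jm1 = j - 1;               // 0 means "wrap from p"
      int diag_prev = (jm1 == 0) ? prev[p] : prev[jm1];
      int sdiag = diag_prev +
                  (base_match(region[i - 1], monomer[j - 1]) ? match : mismatch);
      int sup = prev[j] + indel;     // gap in monomer (consume region)
      int sleft;                     // gap in region (consume monomer)
      unsigned char wl = 0;
      if (jm1 == 0) { sleft = INT32_MIN / 2; }
      else sleft = cur[jm1] + indel;
      int s = sdiag; unsigned char d = DIAG;
      unsigned char w = (jm1 == 0) ? 1 : 0;  // diagonal wrap marker
      if (sup > s) { s = sup; d = UP; w = 0; }
      if (sleft > s) { s = sleft; d = LEFT; w = wl; }
      if (local && s <= 0) { s = 0; d = STOP; w = 0; }
      cur[j] = s; D(i, j) = d; W(i, j) = w;
    }
    // pass 2: propagate the wrap for left moves (j=1 from j=p, then onward)
    for (int rep = 0; rep < 2; ++rep) {
      bool changed = false;
      for (int j = 1; j <= p; ++j) {
        int jm1 = (j == 1) ? p : j - 1;
        int sleft = cur[jm1] + indel;
        if (sleft > cur[j]) {
          cur[j] = sleft; D(i, j) = LEFT; W(i, j) = (j == 1) ? 1 : 0;
          changed = true;
        }
      }
      if (!changed) break;
    }
    for (int j = 1; j <= p; ++j) {
      if (local) {
        if (cur[j] > best) { best = cur[j]; best_i = i; best_j = j; have_best = true; }
      }
    }
    std::swap(prev, cur);
  }

  int score, ei, ej;
  if (local) {
    score = best; ei = best_i; ej = best_j;
    if (!have_best) {
      return List::create(_["score"] = 0, _["start"] = 0, _["end"] = -1,
                          _["matches"] = 0, _["columns"] = 0,
                          _["phase"] = 0);
    }
  } else {
    // prev holds row n
    score = prev[1]; ej = 1;
    for (int j = 2; j <= p; ++j)
      if (prev[j] > score) { score = prev[j]; ej = j; }
    ei = n;
  }

  // traceback to find aligned region span and match stats
  int i = ei, j = ej, matches = 0, cols = 0;
  while (i > 0) {
    unsigned char d = D(i, j);
    if (d == STOP) break;
    if (d == DIAG) {
      matches += base_match(region[i - 1], monomer[j - 1]);
      --i;
      j = W(i + 1, j) ? p : j - 1;
      if (j == 0) j = p;
    } else if (d == UP) {
      --i;
    } else {  // LEFT
      int newj = W(i, j) ? p : j - 1;
      j = newj;
    }
    ++cols;
    if (cols > (n + 1) * (p + 2)) break;  // safety
  }
  int start = local ? i + 1 : 1;
  int phase = j;  // monomer column where the alignment starts (1-based-ish)
  return List::create(_["score"] = score, _["start"] = start, _["end"] = ei,
                      _["matches"] = matches, _["columns"] = cols,
                      _["phase"] = phase);
}

static inline int base2bit(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

// k-mer self-match scan: emit (pos_earlier, distance) pairs, 1-based, for
// identical k-mers at distance within [dmin, dmax]. k <= 15. N-containing
// k-mers are skipped. For each position only matches against earlier
// occurrences still inside the dmax window are reported.
// [[Rcpp::export]]
IntegerMatrix cpp_seed_hits(std::string seq, int k, int dmin, int dmax) {
  const int n = (int)seq.size();
  std::vector<int> out_pos, out_d;
  if (n < k) return IntegerMatrix(0, 2);
  std::unordered_map<uint64_t, std::vector<int>> occ;
  occ.reserve(n * 2);
  uint64_t h = 0, mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int b = base2bit(seq[i]);
    if (b < 0) { valid = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)b) & mask;
    if (++valid < k) continue;
    int pos = i - k + 1;  // 0-based start of this k-mer
    auto& v = occ[h];
    // prune stale
    size_t keep = 0;
    for (size_t t = 0; t < v.size(); ++t)
      if (pos - v[t] <= dmax) v[keep++] = v[t];
    v.resize(keep);
    for (size_t t = 0; t < v.size(); ++t) {
      int d = pos - v[t];
      if (d >= dmin && d <= dmax) {
        out_pos.push_back(v[t] + 1);
        out_d.push_back(d);
      }
    }
    v.push_back(pos);
  }
  IntegerMatrix res((int)out_pos.size(), 2);
  for (int t = 0; t < (int)out_pos.size(); ++t) {
    res(t, 0) = out_pos[t];
    res(t, 1) = out_d[t];
  }
  colnames(res) = CharacterVector::create("pos", "dist");
  return res;
}

// fraction of a's k-mers present in b (caller doubles/revcomps b as needed)
// [[Rcpp::export]]
double cpp_kmer_share(std::string a, std::string b, int k) {
  if ((int)a.size() < k || (int)b.size() < k) return 0.0;
  uint64_t mask = (1ULL << (2 * k)) - 1;
  std::unordered_set<uint64_t> bs;
  uint64_t h = 0; int valid = 0;
  for (int i = 0; i < (int)b.size(); ++i) {
    int v = base2bit(b[i]);
    if (v < 0) { valid = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)v) & mask;
    if (++valid >= k) bs.insert(h);
  }
  int total = 0, found = 0;
  h = 0; valid = 0;
  for (int i = 0; i < (int)a.size(); ++i) {
    int v = base2bit(a[i]);
    if (v < 0) { valid = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)v) & mask;
    if (++valid >= k) {
      ++total;
      if (bs.count(h)) ++found;
    }
  }
  return total > 0 ? (double)found / total : 0.0;
}

// positions (1-based, 0-based offset list) in `hay` where the k-mer starting
// a seed match with `needle` occurs; used by the empty-site seeded search.
// Returns pairs (hay_pos, needle_pos), both 1-based.
// [[Rcpp::export]]
IntegerMatrix cpp_shared_kmer_positions(std::string hay, std::string needle,
                                        int k) {
  std::vector<int> hp, np;
  if ((int)hay.size() >= k && (int)needle.size() >= k) {
    uint64_t mask = (1ULL << (2 * k)) - 1;
    std::unordered_map<uint64_t, std::vector<int>> idx;
    uint64_t h = 0; int valid = 0;
    for (int i = 0; i < (int)needle.size(); ++i) {
      int v = base2bit(needle[i]);
      if (v < 0) { valid = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)v) & mask;
      if (++valid >= k) idx[h].push_back(i - k + 2);
    }
    h = 0; valid = 0;
    for (int i = 0; i < (int)hay.size(); ++i) {
      int v = base2bit(hay[i]);
      if (v < 0) { valid = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)v) & mask;
      if (++valid >= k) {
        auto it = idx.find(h);
        if (it != idx.end()) {
          for (int q : it->second) {
            hp.push_back(i - k + 2);
            np.push_back(q);
          }
        }
      }
    }
  }
  IntegerMatrix res((int)hp.size(), 2);
  for (int t = 0; t < (int)hp.size(); ++t) {
    res(t, 0) = hp[t];
    res(t, 1) = np[t];
  }
  colnames(res) = CharacterVector::create("hay_pos", "needle_pos");
  return res;
}

// Ungapped rotation scan: for both orientations of b, slide every rotation
// against a (overlap = min length) and report the top_n candidates by
// ungapped identity (matches / min length). Ties: forward orientation,
// then smaller rotation. Used as a sound accept shortcut and to propose
// rotation candidates for gapped evaluation during clustering.
// [[Rcpp::export]]
DataFrame cpp_rotation_candidates(std::string a, std::string b, int top_n) {
  const int la = (int)a.size(), lb = (int)b.size();
  const int lmin = std::min(la, lb);
  struct Cand { int ori, rot; double u; };
  std::vector<Cand> all;
  all.reserve(2 * lb);
  for (int ori = 1; ori >= -1; ori -= 2) {
    std::string bb = (ori == 1) ? b : revcomp_str(b);
    std::string b2 = bb + bb;
    for (int r = 0; r < lb; ++r) {
      int matches = 0;
      for (int t = 0; t < lmin; ++t)
        if (base_match(a[t], b2[r + t])) ++matches;
      all.push_back({ori, r, (double)matches / lmin});
    }
  }
  std::stable_sort(all.begin(), all.end(), [](const Cand& x, const Cand& y) {
    if (x.u != y.u) return x.u > y.u;
    if (x.ori != y.ori) return x.ori > y.ori;
    return x.rot < y.rot;
  });
  int n = std::min((int)all.size(), top_n);
  IntegerVector ori(n), rot(n);
  NumericVector u(n);
  for (int i = 0; i < n; ++i) {
    ori[i] = all[i].ori;
    rot[i] = all[i].rot;
    u[i] = all[i].u;
  }
  return DataFrame::create(_["orientation"] = ori, _["rotation"] = rot,
                           _["identity"] = u);
}

// All-pairs k-mer-share prescreen for clustering: for every ordered pair
// (i < j), the fraction of i's k-mers found in the doubled forward or
// reverse-complement of j. Pairs reaching min_share are returned sorted by
// share (descending), then (i, j). Low-complexity sequences (flagged by
// the caller) never pair.
// [[Rcpp::export]]
DataFrame cpp_candidate_pairs(CharacterVector seqs, LogicalVector lowc,
                              int k, double min_share) {
  const int n = seqs.size();
  uint64_t mask = (1ULL << (2 * k)) - 1;
  auto kmer_list = [&](const std::string& s) {
    std::vector<uint64_t> out;
    uint64_t h = 0; int valid = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int v = base2bit(s[i]);
      if (v < 0) { valid = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)v) & mask;
      if (++valid >= k) out.push_back(h);
    }
    return out;
  };
  std::vector<std::vector<uint64_t>> own(n);
  std::vector<std::unordered_set<uint64_t>> big(n);
  for (int i = 0; i < n; ++i) {
    if (lowc[i]) continue;
    std::string s = as<std::string>(seqs[i]);
    own[i] = kmer_list(s);
    std::string d = s + s;
    std::string rc = revcomp_str(s);
    std::string drc = rc + rc;
    for (uint64_t h : kmer_list(d)) big[i].insert(h);
    for (uint64_t h : kmer_list(drc)) big[i].insert(h);
  }
  std::vector<int> ii, jj;
  std::vector<double> sh;
  for (int i = 0; i < n - 1; ++i) {
    if (lowc[i] || own[i].empty()) continue;
    for (int j = i + 1; j < n; ++j) {
      if (lowc[j] || big[j].empty()) continue;
      int found = 0;
      for (uint64_t h : own[i])
        if (big[j].count(h)) ++found;
      double s = (double)found / own[i].size();
      if (s >= min_share) {
        ii.push_back(i + 1);
        jj.push_back(j + 1);
        sh.push_back(s);
      }
    }
  }
  std::vector<int> idx(ii.size());
  for (size_t t = 0; t < idx.size(); ++t) idx[t] = (int)t;
  std::stable_sort(idx.begin(), idx.end(), [&](int x, int y) {
    if (sh[x] != sh[y]) return sh[x] > sh[y];
    if (ii[x] != ii[y]) return ii[x] < ii[y];
    return jj[x] < jj[y];
  });
  IntegerVector oi(idx.size()), oj(idx.size());
  NumericVector os(idx.size());
  for (size_t t = 0; t < idx.size(); ++t) {
    oi[t] = ii[idx[t]];
    oj[t] = jj[idx[t]];
    os[t] = sh[idx[t]];
  }
  return DataFrame::create(_["i"] = oi, _["j"] = oj, _["share"] = os);
}
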