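// Alignment and EM kernels.
//
// Conventions shared with the R layer:
//   * bases are encoded 0=A, 1=C, 2=G, 3=T, 4=anything else (N etc.)
//   * all reference coordinates are 0-based half-open internally
//   * CIGAR strings use the extended alphabet =, X, I, D ("I" consumes read,
//     "D" consumes reference); the SAM writer collapses =/X to M
//   * DP scoring is match +1, mismatch -1, gap -2 (linear), everywhere
#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

static const int NEG_INF = -1000000000;

static inline int comp_base(int b) { return b < 4 ? 3 - b : 4; }

// pack a k-mer starting at pos into 2 bits/base; returns false if it
// contains an ambiguous base
static inline bool pack_kmer(const int* s, int pos, int k, uint64_t& out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int b = s[pos + i];
    if (b >= 4) return false;
    v = (v << 2) | (uint64_t)b;
  }
  out = v;
  return true;
}

static inline uint64_t revcomp_kmer(uint64_t v, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3 - (v & 3ULL));
    v >>= 2;
  }
  return r;
}

// canonical form: lexicographic min of k-mer and its reverse complement
static inline uint64_t canon_kmer(uint64_t v, int k) {
  uint64_t r = revcomp_kmer(v, k);
  return v < r ? v : r;
}

// ---------------------------------------------------------------------------
// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  int n = x.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(x[i]);
    std::string r(s.rbegin(), s.rend());
    for (size_t j = 0; j < r.size(); ++j) {
      switch (r[j]) {
      case 'A': r[j] = 'T'; break; case 'C': r[j] = 'G'; break;
      case 'G': r[j] = 'C'; break; case 'T': r[j] = 'A'; break;
      case 'a': r[j] = 't'; break; case 'c': r[j] = 'g'; break;
      case 'g': r[j] = 'c'; break; case 't': r[j] = 'a'; break;
      default: break;                      // N and friends stay
      }
    }
    out[i] = r;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_encode(CharacterVector x) {
  int n = x.size();
  List out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(x[i]);
    IntegerVector v(s.size());
    for (size_t j = 0; j < s.size(); ++j) {
      switch (s[j]) {
      case 'A': case 'a': v[j] = 0; break;
      case 'C': case 'c': v[j] = 1; break;
      case 'G': case 'g': v[j] = 2; break;
      case 'T': case 't': v[j] = 3; break;
      default: v[j] = 4; break;
      }
    }
    out[i] = v;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Global (end-to-end) Needleman-Wunsch with traceback.  Returns the optimal
// score, the number of identical columns, the total number of alignment
// columns, and the per-column indices into a and b (-1 where gapped).
// Tie order in traceback: diagonal, then gap-in-b (consume a), then gap-in-a.
// [[Rcpp::export]]
List cpp_nw_align(IntegerVector a, IntegerVector b,
                  int match = 1, int mismatch = -1, int gap = -2) {
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence in global alignment");
  std::vector<int> S((size_t)(n + 1) * (m + 1));
  for (int j = 0; j <= m; ++j) S[j] = j * gap;
  for (int i = 1; i <= n; ++i) {
    S[(size_t)i * (m + 1)] = i * gap;
    const int ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      int sc = (ai == b[j - 1] && ai < 4) ? match : mismatch;
      int d = S[(size_t)(i - 1) * (m + 1) + (j - 1)] + sc;
      int u = S[(size_t)(i - 1) * (m + 1) + j] + gap;
      int l = S[(size_t)i * (m + 1) + (j - 1)] + gap;
      int v = d >= u ? d : u;
      if (l > v) v = l;
      S[(size_t)i * (m + 1) + j] = v;
    }
  }
  // traceback
  std::vector<int> acol, bcol;
  int i = n, j = m, matches = 0;
  while (i > 0 || j > 0) {
    int cur = S[(size_t)i * (m + 1) + j];
    if (i > 0 && j > 0) {
      int ai = a[i - 1], bj = b[j - 1];
      int sc = (ai == bj && ai < 4) ? match : mismatch;
      if (cur == S[(size_t)(i - 1) * (m + 1) + (j - 1)] + sc) {
        if (ai == bj && ai < 4) ++matches;
        acol.push_back(i - 1); bcol.push_back(j - 1);
        --i; --j; continue;
      }
    }
    if (i > 0 && cur == S[(size_t)(i - 1) * (m + 1) + j] + gap) {
      acol.push_back(i - 1); bcol.push_back(-1); --i; continue;
    }
    acol.push_back(-1); bcol.push_back(j - 1); --j;
  }
  std::reverse(acol.begin(), acol.end());
  std::reverse(bcol.begin(), bcol.end());
  int cols = (int)acol.size();
  return List::create(_["score"] = S[(size_t)n * (m + 1) + m],
                      _["matches"] = matches,
                      _["columns"] = cols,
                      _["identity"] = (double)matches / cols,
                      _["acol"] = IntegerVector(acol.begin(), acol.end()),
                      _["bcol"] = IntegerVector(bcol.begin(), bcol.end()));
}

// ---------------------------------------------------------------------------
// Banded semi-global alignment: the read is consumed end-to-end, reference
// ends are free, and DP cells are restricted to |(ref_pos - read_pos) - diag|
// <= band.  Returns ref_start (0-based), extended CIGAR, edit distance, score
// and the number of read bases in aligned (=/X) columns.
struct SemiResult {
  bool ok; int score, ref_start, nm, alen;
  std::string cigar;
};

static SemiResult semiglobal_banded(const int* rd, int m, const int* rf, int n,
                                    int diag, int band,
                                    int match, int mismatch, int gap) {
  SemiResult res; res.ok = false;
  int W = 2 * band + 1;
  // cell (i, c): i read prefix length 0..m, ref prefix length j = diag + i - band + c
  std::vector<int> S((size_t)(m + 1) * W, NEG_INF);
  std::vector<signed char> P((size_t)(m + 1) * W, 0); // 1 diag, 2 up(I), 3 left(D)
  for (int c = 0; c < W; ++c) {
    int j = diag - band + c;
    if (j >= 0 && j <= n) S[c] = 0;  // free reference prefix
  }
  for (int i = 1; i <= m; ++i) {
    const int ri = rd[i - 1];
    for (int c = 0; c < W; ++c) {
      int j = diag + i - band + c;
      if (j < 0 || j > n) continue;
      int best = NEG_INF; signed char ptr = 0;
      // diagonal: (i-1, j-1) is same banded column c
      if (j >= 1 && S[(size_t)(i - 1) * W + c] > NEG_INF / 2) {
        int sc = (ri == rf[j - 1] && ri < 4) ? match : mismatch;
        int v = S[(size_t)(i - 1) * W + c] + sc;
        if (v > best) { best = v; ptr = 1; }
      }
      // up: (i-1, j) is banded column c+1
      if (c + 1 < W && S[(size_t)(i - 1) * W + c + 1] > NEG_INF / 2) {
        int v = S[(size_t)(i - 1) * W + c + 1] + gap;
        if (v > best) { best = v; ptr = 2; }
      }
      // left: (i, j-1) is banded column c-1
      if (c - 1 >= 0 && S[(size_t)i * W + c - 1] > NEG_INF / 2) {
        int v = S[(size_t)i * W + c - 1] + gap;
        if (v > best) { best = v; ptr = 3; }
      }
      S[(size_t)i * W + c] = best;
      P[(size_t)i * W + c] = ptr;
    }
  }
  // free reference suffix: best cell in the last row (smallest j on ties)
  int bestc = -1, best = NEG_INF;
  for (int c = 0; c < W; ++c) {
    int j = diag + m - band + c;
    if (j < 0 || j > n) continue;
    if (S[(size_t)m * W + c] > best) { best = S[(size_t)m * W + c]; bestc = c; }
  }
  if (bestc < 0 || best <= NEG_INF / 2) return res;
  // traceback
  std::string ops; ops.reserve(m + 8);
  int i = m, c = bestc, nm = 0, alen = 0;
  while (i > 0) {
    signed char ptr = P[(size_t)i * W + c];
    if (ptr == 0) break; // reached free row 0 region
    int j = diag + i - band + c;
    if (ptr == 1) {
      int ri = rd[i - 1];
      bool eq = (ri == rf[j - 1] && ri < 4);
      ops.push_back(eq ? '=' : 'X');
      if (!eq) ++nm;
      ++alen; --i; // c unchanged
    } else if (ptr == 2) {
      ops.push_back('I'); ++nm; --i; ++c;
    } else {
      ops.push_back('D'); ++nm; --c;
    }
  }
  if (i > 0) return res; // band exhausted before consuming the read
  int ref_start = diag + i - band + c;
  if (ref_start < 0) return res;
  std::reverse(ops.begin(), ops.end());
  // run-length encode
  std::string cig;
  size_t p = 0;
  while (p < ops.size()) {
    size_t q = p;
    while (q < ops.size() && ops[q] == ops[p]) ++q;
    cig += std::to_string(q - p); cig.push_back(ops[p]);
    p = q;
  }
  res.ok = true; res.score = best; res.ref_start = ref_start;
  res.nm = nm; res.alen = alen; res.cigar = cig;
  return res;
}

// [[Rcpp::export]]
List cpp_semiglobal(IntegerVector read, IntegerVector ref, int diag, int band,
                    int match = 1, int mismatch = -1, int gap = -2) {
  SemiResult r = semiglobal_banded(INTEGER(read), read.size(), INTEGER(ref),
                                   ref.size(), diag, band, match, mismatch, gap);
  return List::create(_["ok"] = r.ok, _["score"] = r.score,
                      _["ref_start"] = r.ref_start, _["nm"] = r.nm,
                      _["alen"] = r.alen, _["cigar"] = r.cigar);
}

// ---------------------------------------------------------------------------
// Map every read against every reference sharing >= 1 canonical k-mer, on
// both strands; keep, per (read, reference), the better strand's alignment
// when its edit distance passes max_err_rate * read_length.
// [[Rcpp::export]]
DataFrame cpp_map_reads(List reads, List refs, int k, int band,
                        double max_err_rate,
                        int match = 1, int mismatch = -1, int gap = -2) {
  int R = refs.size(), N = reads.size();
  std::vector<std::vector<int>> refv(R);
  for (int r = 0; r < R; ++r) refv[r] = as<std::vector<int>>(refs[r]);
  // k-mer index over references (forward orientation, canonical keys)
  std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> idx;
  for (int r = 0; r < R; ++r) {
    const std::vector<int>& s = refv[r];
    for (int p = 0; p + k <= (int)s.size(); ++p) {
      uint64_t v;
      if (!pack_kmer(s.data(), p, k, v)) continue;
      idx[canon_kmer(v, k)].push_back(std::make_pair(r, p));
    }
  }
  std::vector<int> o_read, o_ref, o_start, o_nm, o_score, o_alen;
  std::vector<std::string> o_cigar, o_strand;

  for (int i = 0; i < N; ++i) {
    std::vector<int> rd = as<std::vector<int>>(reads[i]);
    int m = (int)rd.size();
    if (m < k) continue;
    int max_nm = (int)std::floor(max_err_rate * m);
    std::vector<int> rc(m);
    for (int t = 0; t < m; ++t) rc[t] = comp_base(rd[m - 1 - t]);
    // per reference: best alignment over both strands
    std::unordered_map<int, SemiResult> best;
    std::unordered_map<int, char> best_strand;
    for (int s = 0; s < 2; ++s) {
      const std::vector<int>& q = s == 0 ? rd : rc;
      // diagonal votes per (ref, diag)
      std::unordered_map<int64_t, int> votes;
      for (int p = 0; p + k <= m; ++p) {
        uint64_t v;
        if (!pack_kmer(q.data(), p, k, v)) continue;
        auto it = idx.find(canon_kmer(v, k));
        if (it == idx.end()) continue;
        for (auto& hit : it->second) {
          int d = hit.second - p;
          votes[((int64_t)hit.first << 32) | (uint32_t)(d + 1000000)] += 1;
        }
      }
      // best diagonal per ref (max votes; tie -> smaller diagonal)
      std::unordered_map<int, std::pair<int,int>> bestdiag; // ref -> (votes, diag)
      for (auto& kv : votes) {
        int r = (int)(kv.first >> 32);
        int d = (int)(uint32_t)(kv.first & 0xffffffffULL) - 1000000;
        auto it = bestdiag.find(r);
        if (it == bestdiag.end() || kv.second > it->second.first ||
            (kv.second == it->second.first && d < it->second.second))
          bestdiag[r] = std::make_pair(kv.second, d);
      }
      for (auto& kv : bestdiag) {
        int r = kv.first, d = kv.second.second;
        SemiResult a = semiglobal_banded(q.data(), m, refv[r].data(),
                                         (int)refv[r].size(), d, band,
                                         match, mismatch, gap);
        if (!a.ok || a.nm > max_nm) continue;
        auto it = best.find(r);
        if (it == best.end() || a.score > it->second.score) {
          best[r] = a; best_strand[r] = s == 0 ? '+' : '-';
        }
      }
    }
    std::vector<int> keys;
    for (auto& kv : best) keys.push_back(kv.first);
    std::sort(keys.begin(), keys.end());
    for (int r : keys) {
      const SemiResult& a = best[r];
      o_read.push_back(i + 1); o_ref.push_back(r + 1);
      o_start.push_back(a.ref_start); o_nm.push_back(a.nm);
      o_score.push_back(a.score); o_alen.push_back(a.alen);
      o_cigar.push_back(a.cigar);
      o_strand.push_back(std::string(1, best_strand[r]));
    }
  }
  return DataFrame::create(_["read"] = o_read, _["gsc"] = o_ref,
                           _["strand"] = o_strand, _["ref_start"] = o_start,
                           _["cigar"] = o_cigar, _["nm"] = o_nm,
                           _["score"] = o_score, _["alen"] = o_alen,
                           _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Walk one alignment's extended CIGAR, calling back per column.  Read
// orientation: for strand '-', oriented base t is the complement of
// read[m-1-t] and carries qual[m-1-t].
template <class FAln, class FIns, class FDel>
static void walk_cigar(const std::string& cig, const int* rd, const int* qu,
                       int m, bool minus, int ref_start,
                       FAln faln, FIns fins, FDel fdel) {
  int rpos = 0, tpos = ref_start;
  size_t p = 0;
  while (p < cig.size()) {
    int len = 0;
    while (p < cig.size() && isdigit((unsigned char)cig[p]))
      len = len * 10 + (cig[p++] - '0');
    char op = cig[p++];
    for (int t = 0; t < len; ++t) {
      if (op == '=' || op == 'X' || op == 'M') {
        int src = minus ? m - 1 - rpos : rpos;
        int b = rd[src]; if (minus) b = comp_base(b);
        faln(tpos, b, qu[src]);
        ++rpos; ++tpos;
      } else if (op == 'I') {
        fins(); ++rpos;
      } else if (op == 'D') {
        fdel(); ++tpos;
      } else {
        stop("unsupported CIGAR op '%s'", std::string(1, op).c_str());
      }
    }
  }
}

// log P(read | GSC) under the per-position base-probability model:
// aligned column t with observed base o, qual q:
//   P = sum_x probs[t, x] * M(o | x, q),  M = (1 - eps) if o == x else eps/3
// each inserted or deleted column contributes gap_factor.  N columns skipped.
// [[Rcpp::export]]
NumericVector cpp_loglik(List reads, List quals,
                         IntegerVector read_idx, IntegerVector gsc_idx,
                         CharacterVector strand, IntegerVector ref_start,
                         CharacterVector cigar, List probs,
                         double gap_factor = 1e-3, double eps_max = 0.75) {
  int A = read_idx.size();
  NumericVector out(A);
  double lgap = std::log(gap_factor);
  for (int a = 0; a < A; ++a) {
    IntegerVector rd = reads[read_idx[a] - 1];
    IntegerVector qu = quals[read_idx[a] - 1];
    NumericMatrix pm = probs[gsc_idx[a] - 1];
    int L = pm.nrow();
    bool minus = (as<std::string>(strand[a]) == "-");
    double ll = 0.0;
    walk_cigar(as<std::string>(cigar[a]), INTEGER(rd), INTEGER(qu), rd.size(),
               minus, ref_start[a],
               [&](int t, int b, int q) {
                 if (b >= 4 || t < 0 || t >= L) return;
                 double eps = std::pow(10.0, -q / 10.0);
                 if (eps > eps_max) eps = eps_max;
                 double p = 0.0;
                 for (int x = 0; x < 4; ++x)
                   p += pm(t, x) * (x == b ? 1.0 - eps : eps / 3.0);
                 ll += std::log(p);
               },
               [&]() { ll += lgap; },
               [&]() { ll += lgap; });
    out[a] = ll;
  }
  return out;
}

// M-step accumulation of the posterior-weighted base counts:
// counts[t, x] += w * ((1 - eps) if x == obs else eps/3); depth[t] += w.
// New row = (alpha + counts) / rowsum; rows with depth < depth_keep keep the
// previous probabilities.  Returns per-GSC lists of probs and depth.
// [[Rcpp::export]]
List cpp_mstep(List reads, List quals,
               IntegerVector read_idx, IntegerVector gsc_idx,
               CharacterVector strand, IntegerVector ref_start,
               CharacterVector cigar, NumericVector w, List probs_prev,
               double alpha = 0.1, double depth_keep = 1.0,
               double eps_max = 0.75) {
  int K = probs_prev.size(), A = read_idx.size();
  std::vector<std::vector<double>> counts(K), depth(K);
  std::vector<int> L(K);
  for (int g = 0; g < K; ++g) {
    NumericMatrix pm = probs_prev[g];
    L[g] = pm.nrow();
    counts[g].assign((size_t)L[g] * 4, 0.0);
    depth[g].assign(L[g], 0.0);
  }
  for (int a = 0; a < A; ++a) {
    if (w[a] <= 0) continue;
    IntegerVector rd = reads[read_idx[a] - 1];
    IntegerVector qu = quals[read_idx[a] - 1];
    int g = gsc_idx[a] - 1;
    bool minus = (as<std::string>(strand[a]) == "-");
    double wa = w[a];
    walk_cigar(as<std::string>(cigar[a]), INTEGER(rd), INTEGER(qu), rd.size(),
               minus, ref_start[a],
               [&](int t, int b, int q) {
                 if (b >= 4 || t < 0 || t >= L[g]) return;
                 double eps = std::pow(10.0, -q / 10.0);
                 if (eps > eps_max) eps = eps_max;
                 for (int x = 0; x < 4; ++x)
                   counts[g][(size_t)t * 4 + x] +=
                     wa * (x == b ? 1.0 - eps : eps / 3.0);
                 depth[g][t] += wa;
               },
               []() {}, []() {});
  }
  List out_probs(K), out_depth(K);
  for (int g = 0; g < K; ++g) {
    NumericMatrix prev = probs_prev[g];
    NumericMatrix pm(L[g], 4);
    for (int t = 0; t < L[g]; ++t) {
      if (depth[g][t] < depth_keep) {
        for (int x = 0; x < 4; ++x) pm(t, x) = prev(t, x);
      } else {
        double rs = 0.0;
        for (int x = 0; x < 4; ++x) rs += alpha + counts[g][(size_t)t * 4 + x];
        for (int x = 0; x < 4; ++x)
          pm(t, x) = (alpha + counts[g][(size_t)t * 4 + x]) / rs;
      }
    }
    out_probs[g] = pm;
    out_depth[g] = NumericVector(depth[g].begin(), depth[g].end());
  }
  return List::create(_["probs"] = out_probs, _["depth"] = out_depth);
}

// ---------------------------------------------------------------------------
// Number of canonical k-mers each read shares with the union of reference
// k-mer sets (k-mers containing ambiguous bases are skipped).
// [[Rcpp::export]]
IntegerVector cpp_prescreen(List reads, List refs, int k) {
  std::unordered_set<uint64_t> kmers;
  for (int r = 0; r < refs.size(); ++r) {
    std::vector<int> s = as<std::vector<int>>(refs[r]);
    for (int p = 0; p + k <= (int)s.size(); ++p) {
      uint64_t v;
      if (pack_kmer(s.data(), p, k, v)) kmers.insert(canon_kmer(v, k));
    }
  }
  int N = reads.size();
  IntegerVector out(N);
  for (int i = 0; i < N; ++i) {
    std::vector<int> s = as<std::vector<int>>(reads[i]);
    int shared = 0;
    for (int p = 0; p + k <= (int)s.size(); ++p) {
      uint64_t v;
      if (pack_kmer(s.data(), p, k, v) && kmers.count(canon_kmer(v, k)))
        ++shared;
    }
    out[i] = shared;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Phase the minor haplotype of a mixed cluster by read linkage.
// At every variant position the two candidate alleles are the cluster's two
// most probable bases (major, second); the anchor position is seeded with
// its second allele.  Alternating passes (a) classify each alignment as a
// minor-carrier when, over already-phased positions, its observed alleles
// match the current minor haplotype more often than the alternative allele,
// and (b) re-vote every variant position's minor allele by posterior weight
// over the carriers, marking voted positions as phased.  Linkage propagates
// outward through reads straddling phased and unphased positions, so
// complementary chimeras cannot lock in.
// [[Rcpp::export]]
IntegerVector cpp_phase_minor(List reads, IntegerVector read_idx,
                              CharacterVector strand,
                              IntegerVector ref_start, CharacterVector cigar,
                              NumericVector w, IntegerVector vi,
                              IntegerVector major, IntegerVector second,
                              int anchor_idx, int L, int n_pass = 16) {
  int V = vi.size(), A = read_idx.size();
  std::vector<int> posmap(L, -1);
  for (int k = 0; k < V; ++k)
    if (vi[k] >= 0 && vi[k] < L) posmap[vi[k]] = k;
  // sparse per-alignment observations at variant positions
  std::vector<std::vector<std::pair<int,int>>> obs(A);
  for (int a = 0; a < A; ++a) {
    if (w[a] <= 0) continue;
    IntegerVector rd = reads[read_idx[a] - 1];
    bool minus = (as<std::string>(strand[a]) == "-");
    walk_cigar(as<std::string>(cigar[a]), INTEGER(rd), INTEGER(rd), rd.size(),
               minus, ref_start[a],
               [&](int t, int b, int) {
                 if (t >= 0 && t < L && b < 4 && posmap[t] >= 0)
                   obs[a].push_back(std::make_pair(posmap[t], b));
               },
               []() {}, []() {});
  }
  std::vector<int> minor(major.begin(), major.end());
  std::vector<bool> phased(V, false);
  minor[anchor_idx] = second[anchor_idx];
  phased[anchor_idx] = true;
  for (int pass = 0; pass < n_pass; ++pass) {
    std::vector<double> counts((size_t)V * 4, 0.0);
    for (int a = 0; a < A; ++a) {
      if (obs[a].empty()) continue;
      double s = 0.0;
      for (auto& pk : obs[a]) {
        int k = pk.first;
        if (!phased[k]) continue;
        int alt = (minor[k] == major[k]) ? second[k] : major[k];
        if (pk.second == minor[k]) s += 1.0;
        else if (pk.second == alt) s -= 1.0;
      }
      if (s <= 0) continue;                                // not a carrier
      for (auto& pk : obs[a])
        counts[(size_t)pk.first * 4 + pk.second] += w[a];
    }
    for (int k = 0; k < V; ++k) {
      double tot = 0.0; int best = -1; double bestc = -1.0;
      for (int x = 0; x < 4; ++x) {
        tot += counts[(size_t)k * 4 + x];
        if (counts[(size_t)k * 4 + x] > bestc) {
          bestc = counts[(size_t)k * 4 + x]; best = x;
        }
      }
      if (tot > 0) { minor[k] = best; phased[k] = true; }
    }
    minor[anchor_idx] = second[anchor_idx];  // the anchor stays pinned
    phased[anchor_idx] = true;
  }
  return IntegerVector(minor.begin(), minor.end());
}
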