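// Core tandem-repeat search engine.
//
// Model: a hit of unit size p is anchored -- it begins with a perfect,
// fully matching copy of its unit u = s[start .. start+p), which is not
// scored.  Subsequent columns align the sequence against the continued
// perfect tiling of u and score match +1, mismatch -5, gap -5, N 0
// (configurable).  Edit columns (mismatch / insertion / deletion) may run
// at most `recursion_depth` in a row before a match or N column resumes;
// runs of consumed sequence Ns are capped at `max_successive_ns`
// (deletion columns do not reset the N-run counter, so an N run can never
// be bridged by interleaving gaps).  The first scored column and the last
// column of a hit are matches.  A hit qualifies when its score reaches
// max(min_score_floor, p).
//
// Two search routes are provided:
//   * detect_scan_cpp  -- seed and extend: maximal perfect tandem
//     stretches seed a bidirectional frontier DP (X-drop pruned when the
//     maximum score reduction is finite).
//   * oracle_scan_cpp  -- exhaustive enumeration of every anchor, forward
//     DP only; reference implementation for testing, no X-drop support.
// align_stats_cpp recomputes the optimal alignment of a fixed interval
// with full traceback, yielding column counts and the consensus unit.

#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <climits>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

static const int NEG = INT_MIN / 4;

struct Scheme {
  int match, mismatch, gap, nscore;
  int min_floor, max_ns, depth;
  bool xdrop_on;
  int xdrop;
  int unit_min, unit_max;
};

static Scheme scheme_from_list(List sl) {
  Scheme sc;
  sc.match = as<int>(sl["match_score"]);
  sc.mismatch = as<int>(sl["mismatch_score"]);
  sc.gap = as<int>(sl["gap_score"]);
  sc.nscore = as<int>(sl["n_score"]);
  sc.min_floor = as<int>(sl["min_score_floor"]);
  sc.max_ns = as<int>(sl["max_successive_ns"]);
  sc.depth = as<int>(sl["recursion_depth"]);
  double mr = as<double>(sl["max_score_reduction"]);
  sc.xdrop_on = R_finite(mr);
  sc.xdrop = sc.xdrop_on ? (int)mr : 0;
  sc.unit_min = as<int>(sl["unit_min"]);
  sc.unit_max = as<int>(sl["unit_max"]);
  return sc;
}

static inline int min_score_for(const Scheme& sc, int p) {
  return std::max(sc.min_floor, p);
}

static inline bool base_ok(char c) { return c != 'N'; }

// true unless u = d-mer repeated (primitive period < p)
static bool is_primitive(const char* u, int p) {
  for (int d = 1; d <= p / 2; ++d) {
    if (p % d) continue;
    bool per = true;
    for (int t = d; t < p && per; ++t)
      if (u[t] != u[t - d]) { per = false; break; }
    if (per) return false;
  }
  return true;
}

static bool unit_clean(const char* u, int p) {
  for (int t = 0; t < p; ++t)
    if (u[t] == 'N') return false;
  return true;
}

// ---------------------------------------------------------------------------
// Frontier DP used by the seed-and-extend detector.
//
// State: (k, e, m) = tiling phase of the next reference base, current run of
// consecutive edit columns, current run of consumed sequence Ns.

struct Frontier {
  int p, D, M, S;
  std::vector<int> cur, nxt;
  Frontier(int p_, int D_, int M_)
      : p(p_), D(D_), M(M_), S(p_ * (D_ + 1) * (M_ + 1)),
        cur(S, NEG), nxt(S, NEG) {}
  inline int idx(int k, int e, int m) const {
    return (k * (D + 1) + e) * (M + 1) + m;
  }
  void reset() { std::fill(cur.begin(), cur.end(), NEG); }
  // deletion closure: consume reference bases only
  void closure(int gap) {
    for (int e = 0; e < D; ++e)
      for (int k = 0; k < p; ++k)
        for (int m = 0; m <= M; ++m) {
          int v = cur[idx(k, e, m)];
          if (v <= NEG / 2) continue;
          int& t = cur[idx((k + 1) % p, e + 1, m)];
          if (v + gap > t) t = v + gap;
        }
  }
  int maxval() const {
    int mv = NEG;
    for (int i = 0; i < S; ++i) mv = std::max(mv, cur[i]);
    return mv;
  }
  void prune_below(int cutoff) {
    for (int i = 0; i < S; ++i)
      if (cur[i] < cutoff) cur[i] = NEG;
  }
};

// Extend rightwards from anchor a (unit = s[a..a+p), s[a+p] == s[a]
// guaranteed by the caller).  Returns the best (score, end) with ties on
// the score broken towards the smallest end.
static void forward_scan(const std::string& s, int a, int p, const Scheme& sc,
                         int& best_score, int& best_j) {
  const int n = (int)s.size();
  const char* u = s.data() + a;
  Frontier F(p, sc.depth, sc.max_ns);
  // forced first scored column: match consuming s[a+p]
  best_score = sc.match;
  best_j = a + p + 1;
  F.cur[F.idx(1 % p, 0, 0)] = sc.match;
  for (int pos = a + p + 1; pos < n; ++pos) {
    F.closure(sc.gap);
    std::fill(F.nxt.begin(), F.nxt.end(), NEG);
    const char c = s[pos];
    bool any = false;
    for (int k = 0; k < p; ++k)
      for (int e = 0; e <= sc.depth; ++e)
        for (int m = 0; m <= sc.max_ns; ++m) {
          int v = F.cur[F.idx(k, e, m)];
          if (v <= NEG / 2) continue;
          if (c == 'N') {
            if (m < sc.max_ns) {
              int& t = F.nxt[F.idx((k + 1) % p, 0, m + 1)];
              if (v + sc.nscore > t) t = v + sc.nscore;
              any = true;
            }
          } else {
            if (c == u[k]) {
              int w = v + sc.match;
              int& t = F.nxt[F.idx((k + 1) % p, 0, 0)];
              if (w > t) t = w;
              if (w > best_score) { best_score = w; best_j = pos + 1; }
              any = true;
            } else if (e < sc.depth) {
              int& t = F.nxt[F.idx((k + 1) % p, e + 1, 0)];
              if (v + sc.mismatch > t) t = v + sc.mismatch;
              any = true;
            }
            if (e < sc.depth) {  // insertion in the sequence
              int& t = F.nxt[F.idx(k, e + 1, 0)];
              if (v + sc.gap > t) t = v + sc.gap;
              any = true;
            }
          }
        }
    F.cur.swap(F.nxt);
    if (!any) break;
    int mv = F.maxval();
    if (mv <= NEG / 2) break;
    if (sc.xdrop_on) {
      F.prune_below(best_score - sc.xdrop);
      if (F.maxval() <= NEG / 2) break;
    }
    // futility: even all-match continuation cannot beat the current best
    if (mv + (n - pos - 1) <= best_score) break;
  }
}

// Extend leftwards from anchor a.  A valid stop at position i requires the
// p + 1 sequence positions [i, i + p] to match the tiling (they become the
// new perfect first unit plus the first scored match column).  Returns the
// score delta (sum of all columns in [i, a), counting the old first unit
// which becomes scored) and the new start; delta ties prefer the leftmost
// start, consistent with overlap resolution.
static void backward_scan(const std::string& s, int a, int p, const Scheme& sc,
                          int& best_delta, int& best_i) {
  const char* u = s.data() + a;
  best_delta = 0;
  best_i = a;
  if (a == 0) return;
  Frontier F(p, sc.depth, sc.max_ns);
  F.cur[F.idx(0, 0, 0)] = 0;  // nothing consumed yet; k = refs consumed mod p
  for (int pos = a - 1; pos >= 0; --pos) {
    F.closure(sc.gap);
    std::fill(F.nxt.begin(), F.nxt.end(), NEG);
    const char c = s[pos];
    bool any = false;
    for (int k = 0; k < p; ++k) {
      const char ref = u[p - 1 - k];  // next reference base, walking left
      for (int e = 0; e <= sc.depth; ++e)
        for (int m = 0; m <= sc.max_ns; ++m) {
          int v = F.cur[F.idx(k, e, m)];
          if (v <= NEG / 2) continue;
          if (c == 'N') {
            if (m < sc.max_ns) {
              int& t = F.nxt[F.idx((k + 1) % p, 0, m + 1)];
              if (v + sc.nscore > t) t = v + sc.nscore;
              any = true;
            }
          } else {
            if (c == ref) {
              int& t = F.nxt[F.idx((k + 1) % p, 0, 0)];
              if (v + sc.match > t) t = v + sc.match;
              any = true;
            } else if (e < sc.depth) {
              int& t = F.nxt[F.idx((k + 1) % p, e + 1, 0)];
              if (v + sc.mismatch > t) t = v + sc.mismatch;
              any = true;
            }
            if (e < sc.depth) {
              int& t = F.nxt[F.idx(k, e + 1, 0)];
              if (v + sc.gap > t) t = v + sc.gap;
              any = true;
            }
          }
        }
    }
    F.cur.swap(F.nxt);
    if (!any) break;
    // candidate stops: state (k, 0, 0) whose trailing p+1 positions match
    for (int k = 0; k < p; ++k) {
      int v = F.cur[F.idx(k, 0, 0)];
      if (v <= NEG / 2 || v < best_delta) continue;
      int phase = (p - k) % p;  // forward tiling phase at position pos
      bool ok = true;
      for (int t2 = 0; t2 <= p; ++t2) {
        char cc = s[pos + t2];
        if (cc == 'N' || cc != u[(phase + t2) % p]) { ok = false; break; }
      }
      if (ok && (v > best_delta || pos < best_i)) {
        best_delta = v;
        best_i = pos;
      }
    }
    int mv = F.maxval();
    if (mv <= NEG / 2) break;
    if (sc.xdrop_on) {
      F.prune_below(best_delta - sc.xdrop);
      if (F.maxval() <= NEG / 2) break;
    }
    if (mv + pos < best_delta) break;
  }
}

// ---------------------------------------------------------------------------
// Seed-and-extend detector.  Seeds are maximal perfect tandem stretches
// (lag-p autocorrelation runs) of length >= p + min(p, 4).

// [[Rcpp::export]]
DataFrame detect_scan_cpp(std::string seq, List scheme) {
  Scheme sc = scheme_from_list(scheme);
  const int n = (int)seq.size();
  std::vector<int> out_start, out_end, out_p, out_score;
  int pmax = std::min(sc.unit_max, n / 2);
  for (int p = sc.unit_min; p <= pmax; ++p) {
    if (n - p < min_score_for(sc, p)) continue;  // cannot reach the threshold
    const int need = std::min(p, 4);
    int j = 0;
    while (j < n - p) {
      if (!(base_ok(seq[j]) && seq[j] == seq[j + p])) { ++j; continue; }
      int rs = j;
      while (j < n - p && base_ok(seq[j]) && seq[j] == seq[j + p]) ++j;
      int runlen = j - rs;
      if (runlen < need) continue;
      const char* u = seq.data() + rs;
      if (!unit_clean(u, p) || !is_primitive(u, p)) continue;
      int fs, fj, bd, bi;
      forward_scan(seq, rs, p, sc, fs, fj);
      backward_scan(seq, rs, p, sc, bd, bi);
      int score = fs + bd;
      if (score >= min_score_for(sc, p)) {
        out_start.push_back(bi);
        out_end.push_back(fj);
        out_p.push_back(p);
        out_score.push_back(score);
      }
    }
  }
  return DataFrame::create(_["start0"] = out_start, _["end0"] = out_end,
                           _["unit_size"] = out_p, _["score"] = out_score);
}

// ---------------------------------------------------------------------------
// Exhaustive oracle: every position is tried as an anchor for every unit
// size; a plain full forward DP (no X-drop, no seeding) finds the best end
// per anchor.  Kept deliberately simple; used as the reference in tests.

// [[Rcpp::export]]
DataFrame oracle_scan_cpp(std::string seq, List scheme) {
  Scheme sc = scheme_from_list(scheme);
  const int n = (int)seq.size();
  const int D = sc.depth, M = sc.max_ns;
  std::vector<int> out_start, out_end, out_p, out_score;
  int pmax = std::min(sc.unit_max, n / 2);
  for (int p = sc.unit_min; p <= pmax; ++p) {
    const int thr = min_score_for(sc, p);
    const int S = p * (D + 1) * (M + 1);
    std::vector<int> cur(S), nxt(S);
    auto idx = [&](int k, int e, int m) { return (k * (D + 1) + e) * (M + 1) + m; };
    for (int i = 0; i + p < n; ++i) {
      if (n - i - p < thr) break;  // shorter suffixes cannot qualify
      const char* u = seq.data() + i;
      if (seq[i + p] != seq[i] || !base_ok(seq[i])) continue;
      if (!unit_clean(u, p) || !is_primitive(u, p)) continue;
      std::fill(cur.begin(), cur.end(), NEG);
      cur[idx(1 % p, 0, 0)] = sc.match;  // forced first scored match
      int best = sc.match, bestj = i + p + 1;
      for (int pos = i + p + 1; pos < n; ++pos) {
        // deletion closure
        for (int e = 0; e < D; ++e)
          for (int k = 0; k < p; ++k)
            for (int m = 0; m <= M; ++m) {
              int v = cur[idx(k, e, m)];
              if (v <= NEG / 2) continue;
              int& t = cur[idx((k + 1) % p, e + 1, m)];
              if (v + sc.gap > t) t = v + sc.gap;
            }
        std::fill(nxt.begin(), nxt.end(), NEG);
        const char c = seq[pos];
        int mv = NEG;
        for (int k = 0; k < p; ++k)
          for (int e = 0; e <= D; ++e)
            for (int m = 0; m <= M; ++m) {
              int v = cur[idx(k, e, m)];
              if (v <= NEG / 2) continue;
              if (c == 'N') {
                if (m < M) {
                  int& t = nxt[idx((k + 1) % p, 0, m + 1)];
                  if (v + sc.nscore > t) t = v + sc.nscore;
                }
              } else {
                if (c == u[k]) {
                  int w = v + sc.match;
                  int& t = nxt[idx((k + 1) % p, 0, 0)];
                  if (w > t) t = w;
                  if (w > best) { best = w; bestj = pos + 1; }
                } else if (e < D) {
                  int& t = nxt[idx((k + 1) % p, e + 1, 0)];
                  if (v + sc.mismatch > t) t = v + sc.mismatch;
                }
                if (e < D) {
                  int& t = nxt[idx(k, e + 1, 0)];
                  if (v + sc.gap > t) t = v + sc.gap;
                }
              }
            }
        cur.swap(nxt);
        for (int x = 0; x < S; ++x) mv = std::max(mv, cur[x]);
        if (mv <= NEG / 2) break;
        if (mv + (n - pos - 1) <= best) break;
      }
      if (best >= thr) {
        out_start.push_back(i);
        out_end.push_back(bestj);
        out_p.push_back(p);
        out_score.push_back(best);
      }
    }
  }
  return DataFrame::create(_["start0"] = out_start, _["end0"] = out_end,
                           _["unit_size"] = out_p, _["score"] = out_score);
}

// ---------------------------------------------------------------------------
// Optimal alignment of a fixed interval against the tiling of its anchor
// unit, with traceback.  Value maximizes score, then minimizes alignment
// columns, then gap columns; traceback prefers match > N > mismatch >
// deletion > insertion.  Returns column counts (including the anchored
// first unit, counted as matches) and the majority-vote consensus unit.

// [[Rcpp::export]]
List align_stats_cpp(std::string seq, int start0, int end0, int p, List scheme) {
  Scheme sc = scheme_from_list(scheme);
  const int n = (int)seq.size();
  if (start0 < 0 || end0 > n || end0 - start0 < 2 * p)
    stop("interval too short for unit size %d", p);
  const char* u = seq.data() + start0;
  if (!unit_clean(u, p)) stop("anchor unit contains N");
  const int L = end0 - start0 - p;  // scored sequence bases
  const int D = sc.depth, M = sc.max_ns;
  const int S = p * (D + 1) * (M + 1);
  // packed value: score major, then -columns, then -gap columns
  if ((double)(L + 1) * S > 1.2e7) stop("interval too large for alignment statistics");
  if (L > 40000) stop("interval too long");
  const int64_t NEGV = INT64_MIN / 4;
  const int64_t CB = ((int64_t)1) << 20;  // per-column bit budget
  auto pack = [&](int score, int cols, int gaps) {
    return ((int64_t)score * CB - cols) * CB - gaps;
  };
  // value[pos][state], move[pos][state]; pos = scored bases consumed
  std::vector<int64_t> val((size_t)(L + 1) * S, NEGV);
  std::vector<int8_t> mv((size_t)(L + 1) * S, -1);  // 0=M 1=N 2=X 3=D 4=I
  auto idx = [&](int k, int e, int m) { return (k * (D + 1) + e) * (M + 1) + m; };
  auto at = [&](int pos, int st) -> int64_t& { return val[(size_t)pos * S + st]; };
  auto mo = [&](int pos, int st) -> int8_t& { return mv[(size_t)pos * S + st]; };
  at(0, idx(0, 0, 0)) = pack(0, 0, 0);
  for (int pos = 0; pos <= L; ++pos) {
    // deletion closure within this pos
    for (int e = 0; e < D; ++e)
      for (int k = 0; k < p; ++k)
        for (int m = 0; m <= M; ++m) {
          int64_t v = at(pos, idx(k, e, m));
          if (v <= NEGV / 2) continue;
          int64_t w = v + pack(sc.gap, 1, 1) - pack(0, 0, 0);
          int st = idx((k + 1) % p, e + 1, m);
          if (w > at(pos, st)) { at(pos, st) = w; mo(pos, st) = 3; }
        }
    if (pos == L) break;
    const char c = seq[start0 + p + pos];
    for (int k = 0; k < p; ++k)
      for (int e = 0; e <= D; ++e)
        for (int m = 0; m <= M; ++m) {
          int64_t v = at(pos, idx(k, e, m));
          if (v <= NEGV / 2) continue;
          if (c == 'N') {
            if (m < M) {
              int64_t w = v + pack(sc.nscore, 1, 0) - pack(0, 0, 0);
              int st = idx((k + 1) % p, 0, m + 1);
              if (w > at(pos + 1, st)) { at(pos + 1, st) = w; mo(pos + 1, st) = 1; }
            }
          } else {
            if (c == u[k]) {
              int64_t w = v + pack(sc.match, 1, 0) - pack(0, 0, 0);
              int st = idx((k + 1) % p, 0, 0);
              if (w > at(pos + 1, st)) { at(pos + 1, st) = w; mo(pos + 1, st) = 0; }
            } else if (e < D) {
              int64_t w = v + pack(sc.mismatch, 1, 0) - pack(0, 0, 0);
              int st = idx((k + 1) % p, e + 1, 0);
              if (w > at(pos + 1, st)) { at(pos + 1, st) = w; mo(pos + 1, st) = 2; }
            }
            if (e < D) {
              int64_t w = v + pack(sc.gap, 1, 1) - pack(0, 0, 0);
              int st = idx(k, e + 1, 0);
              if (w > at(pos + 1, st)) { at(pos + 1, st) = w; mo(pos + 1, st) = 4; }
            }
          }
        }
  }
  // best final state (trailing deletions excluded: closure at pos == L was
  // applied above -- drop it by scanning only states whose move != 3 chain?
  // simpler: trailing deletions only lower the packed value, so the best
  // final state never ends in one.)
  int best_st = -1;
  int64_t best_v = NEGV;
  for (int st = 0; st < S; ++st)
    if (at(L, st) > best_v) { best_v = at(L, st); best_st = st; }
  if (best_st < 0) stop("no valid alignment for the interval");
  // traceback
  int n_match = p, n_mis = 0, n_gap = 0, n_ncol = 0, cols = p;
  std::array<int, 4> zero = {{0, 0, 0, 0}};
  std::vector<std::array<int, 4> > tally(p, zero);  // A C G T votes
  auto vote = [&](int phase, char c) {
    int b = (c == 'A') ? 0 : (c == 'C') ? 1 : (c == 'G') ? 2 : (c == 'T') ? 3 : -1;
    if (b >= 0) tally[phase][b]++;
  };
  for (int t = 0; t < p; ++t) vote(t, u[t]);  // anchor copy
  {
    int pos = L, st = best_st;
    while (!(pos == 0 && st == idx(0, 0, 0))) {
      int8_t m8 = mo(pos, st);
      int k = st / ((D + 1) * (M + 1));
      int e = (st / (M + 1)) % (D + 1);
      int mm = st % (M + 1);
      int pk = (k + p - 1) % p;  // phase before ref-consuming moves
      if (m8 == 0) {  // match
        ++n_match; ++cols;
        vote(pk, seq[start0 + p + pos - 1]);
        --pos; st = -2;
        // predecessor: any (pk, e', m') that produced this; we re-derive by
        // scanning because counters reset on match
        int64_t need = at(pos + 1, idx(k, 0, 0));
        for (int e2 = 0; e2 <= D && st == -2; ++e2)
          for (int m2 = 0; m2 <= M; ++m2) {
            int cand = idx(pk, e2, m2);
            if (at(pos, cand) + pack(sc.match, 1, 0) - pack(0, 0, 0) == need) {
              st = cand; break;
            }
          }
      } else if (m8 == 1) {  // N column
        ++n_ncol; ++cols;
        int64_t need = at(pos, st);
        --pos; st = -2;
        for (int e2 = 0; e2 <= D && st == -2; ++e2) {
          int cand = idx(pk, e2, mm - 1);
          if (at(pos, cand) + pack(sc.nscore, 1, 0) - pack(0, 0, 0) == need)
            st = cand;
        }
      } else if (m8 == 2) {  // mismatch (resets the N counter)
        ++n_mis; ++cols;
        vote(pk, seq[start0 + p + pos - 1]);
        int64_t need = at(pos, st);
        --pos;
        st = -2;
        for (int m2 = 0; m2 <= M && st == -2; ++m2) {
          int c2 = idx(pk, e - 1, m2);
          if (at(pos, c2) + pack(sc.mismatch, 1, 0) - pack(0, 0, 0) == need)
            st = c2;
        }
      } else if (m8 == 3) {  // deletion (ref only, same pos)
        ++n_gap; ++cols;
        int64_t need = at(pos, st);
        st = -2;
        int c2 = idx(pk, e - 1, mm);
        if (at(pos, c2) + pack(sc.gap, 1, 1) - pack(0, 0, 0) == need) st = c2;
      } else if (m8 == 4) {  // insertion (sequence only)
        ++n_gap; ++cols;
        int64_t need = at(pos, st);
        --pos;
        st = -2;
        for (int m2 = 0; m2 <= M && st == -2; ++m2) {
          int c2 = idx(k, e - 1, m2);
          if (at(pos, c2) + pack(sc.gap, 1, 1) - pack(0, 0, 0) == need) st = c2;
        }
      } else {
        stop("traceback failed");
      }
      if (st == -2) stop("traceback failed");
    }
  }
  // consensus: majority vote, ties towards the alphabetically first base
  std::string cons(p, 'N');
  const char bases[4] = {'A', 'C', 'G', 'T'};
  for (int t = 0; t < p; ++t) {
    int bi = -1, bc = 0;
    for (int b = 0; b < 4; ++b)
      if (tally[t][b] > bc) { bc = tally[t][b]; bi = b; }
    if (bi >= 0) cons[t] = bases[bi];
  }
  // score recomputed from the column counts (the anchored first unit is
  // not scored)
  int score = (n_match - p) * sc.match + n_mis * sc.mismatch +
              n_gap * sc.gap + n_ncol * sc.nscore;
  return List::create(_["score"] = score, _["n_match"] = n_match,
                      _["n_mismatch"] = n_mis, _["n_gap"] = n_gap,
                      _["n_ncol"] = n_ncol, _["cols"] = cols,
                      _["consensus"] = cons);
}
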