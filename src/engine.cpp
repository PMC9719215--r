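// Seed-and-extend local homology search engine and profile-profile aligner.
//
// The search follows the classic word-seeded HSP model: exact (nt) or
// score-neighbourhood (aa) k-mer seeds, optional two-hit triggering on a
// diagonal, ungapped X-drop extension, then adaptive-band gapped X-drop
// extension with affine gaps. Scores, match counts and alignment column
// counts are propagated through the DP so identity is exact for the
// reported path without a traceback.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <climits>
#include <cstdint>

using namespace Rcpp;

static const long NEG = LLONG_MIN / 4;

struct SearchParams {
  std::string letters;   // residue order of the scoring matrix
  int charmap[256];
  std::vector<int> S;    // flattened scoring matrix (nl x nl)
  std::vector<int> sortedLetters;  // per residue: indexable letters, score-descending
  int nl;                // number of letters in matrix
  int index_letters;     // words are built from codes < index_letters
  int seed_k;
  int neighbor_min;      // <=0: exact seeds only
  int max_neighbors;
  bool two_hit;
  int two_hit_window;
  int ungapped_xdrop;
  int gapped_xdrop;
  int ungapped_trigger;
  int gap_open;          // positive penalty
  int gap_ext;           // positive penalty
  int max_band;
  long min_score;
  double min_identity;
  int min_alnlen;
  int max_candidates;
};

static SearchParams parse_params(List params) {
  SearchParams p;
  p.letters = as<std::string>(params["letters"]);
  IntegerMatrix S = params["submat"];
  p.nl = S.nrow();
  p.S.assign(p.nl * p.nl, 0);
  for (int i = 0; i < p.nl; ++i)
    for (int j = 0; j < p.nl; ++j) p.S[i * p.nl + j] = S(i, j);
  std::string fb = as<std::string>(params["fallback"]);
  int fbcode = 0;
  for (size_t i = 0; i < p.letters.size(); ++i)
    if (p.letters[i] == fb[0]) fbcode = (int)i;
  for (int i = 0; i < 256; ++i) p.charmap[i] = fbcode;
  for (size_t i = 0; i < p.letters.size(); ++i)
    p.charmap[(unsigned char)p.letters[i]] = (int)i;
  p.index_letters = as<int>(params["index_letters"]);
  p.seed_k = as<int>(params["seed_k"]);
  p.neighbor_min = as<int>(params["neighbor_min"]);
  p.max_neighbors = as<int>(params["max_neighbors"]);
  p.two_hit = as<bool>(params["two_hit"]);
  p.two_hit_window = as<int>(params["two_hit_window"]);
  p.ungapped_xdrop = as<int>(params["ungapped_xdrop"]);
  p.gapped_xdrop = as<int>(params["gapped_xdrop"]);
  p.ungapped_trigger = as<int>(params["ungapped_trigger"]);
  p.gap_open = as<int>(params["gap_open"]);
  p.gap_ext = as<int>(params["gap_ext"]);
  p.max_band = as<int>(params["max_band"]);
  p.min_score = (long)as<double>(params["min_score"]);
  p.min_identity = as<double>(params["min_identity"]);
  p.min_alnlen = as<int>(params["min_alnlen"]);
  p.max_candidates = as<int>(params["max_candidates"]);
  // letters of each matrix row sorted by substitution score (descending,
  // ties by letter index) over the indexable alphabet, for best-first
  // neighbourhood enumeration
  const int A = p.index_letters;
  p.sortedLetters.assign((size_t)p.nl * A, 0);
  for (int r = 0; r < p.nl; ++r) {
    std::vector<int> ord(A);
    for (int a = 0; a < A; ++a) ord[a] = a;
    const int* row = &p.S[r * p.nl];
    std::sort(ord.begin(), ord.end(), [row](int a, int b) {
      if (row[a] != row[b]) return row[a] > row[b];
      return a < b;
    });
    for (int a = 0; a < A; ++a) p.sortedLetters[r * A + a] = ord[a];
  }
  return p;
}

static std::vector<uint8_t> encode(const std::string& s, const SearchParams& p) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = (uint8_t)p.charmap[(unsigned char)s[i]];
  return v;
}

// ---- subject k-mer index -------------------------------------------------

struct KmerIndex {
  long W;
  std::vector<int> starts;     // W+1 offsets
  std::vector<int> positions;  // positions grouped by word
};

static void build_index(const std::vector<uint8_t>& s, const SearchParams& p, KmerIndex& idx) {
  const int k = p.seed_k, A = p.index_letters;
  long W = 1;
  for (int i = 0; i < k; ++i) W *= A;
  idx.W = W;
  std::vector<int> counts((size_t)W + 1, 0);
  const int n = (int)s.size();
  long pw = W / A;  // A^(k-1)
  // rolling word with reset on non-indexable code
  long w = 0; int run = 0;
  std::vector<long> words(n >= k ? n - k + 1 : 0, -1);
  for (int i = 0; i < n; ++i) {
    if (s[i] < A) { w = (w % pw) * A + s[i]; run++; } else { run = 0; w = 0; }
    if (run >= k) words[i - k + 1] = w;
  }
  for (size_t i = 0; i < words.size(); ++i)
    if (words[i] >= 0) counts[words[i] + 1]++;
  idx.starts.assign((size_t)W + 1, 0);
  for (long i = 0; i < W; ++i) idx.starts[i + 1] = idx.starts[i] + counts[i + 1];
  idx.positions.assign(idx.starts[W], 0);
  std::vector<int> cur(idx.starts.begin(), idx.starts.end() - 1);
  for (size_t i = 0; i < words.size(); ++i)
    if (words[i] >= 0) idx.positions[cur[words[i]]++] = (int)i;
}

// ---- neighbourhood enumeration ------------------------------------------

// Best-first capped enumeration of the word neighbourhood: at each
// position candidate letters are tried in descending substitution-score
// order, branches whose optimistic bound falls below the threshold are
// cut, and enumeration stops at max_neighbors words. Deterministic.
static void enum_neighbors(const uint8_t* qw, const SearchParams& p,
                           std::vector<long>& out) {
  const int k = p.seed_k, A = p.index_letters, nl = p.nl;
  std::vector<int> suffmax(k + 1, 0);
  for (int i = k - 1; i >= 0; --i) {
    int best = p.S[qw[i] * nl + p.sortedLetters[qw[i] * A]];
    suffmax[i] = suffmax[i + 1] + best;
  }
  out.clear();
  std::vector<int> choice(k, -1);
  std::vector<int> acc(k + 1, 0);
  int depth = 0;
  while (depth >= 0) {
    if (depth == k) {
      long w = 0;
      for (int i = 0; i < k; ++i) w = w * A + p.sortedLetters[qw[i] * A + choice[i]];
      out.push_back(w);
      if ((int)out.size() >= p.max_neighbors) return;
      depth--;
      continue;
    }
    int ci = ++choice[depth];
    if (ci >= A) { choice[depth] = -1; depth--; continue; }
    int a = p.sortedLetters[qw[depth] * A + ci];
    int sc = acc[depth] + p.S[qw[depth] * nl + a];
    if (sc + suffmax[depth + 1] < p.neighbor_min) {
      // letters are score-sorted: nothing further at this depth can pass
      choice[depth] = -1; depth--; continue;
    }
    acc[depth + 1] = sc;
    depth++;
  }
}

// ---- ungapped X-drop extension ------------------------------------------

struct Ungapped { int qb, qe, sb, se; long score; };

static Ungapped ungapped_extend(const std::vector<uint8_t>& q, const std::vector<uint8_t>& s,
                                int qp, int sp, const SearchParams& p) {
  const int nl = p.nl, k = p.seed_k, X = p.ungapped_xdrop;
  long sc = 0;
  for (int i = 0; i < k; ++i) sc += p.S[q[qp + i] * nl + s[sp + i]];
  // right
  long best = sc, run = sc; int qe = qp + k, se = sp + k, bqe = qe;
  while (qe < (int)q.size() && se < (int)s.size()) {
    run += p.S[q[qe] * nl + s[se]];
    ++qe; ++se;
    if (run > best) { best = run; bqe = qe; }
    else if (run < best - X) break;
  }
  // left
  long runl = 0, bestl = 0; int qb = qp, sb = sp, bqb = qp;
  while (qb > 0 && sb > 0) {
    --qb; --sb;
    runl += p.S[q[qb] * nl + s[sb]];
    if (runl > bestl) { bestl = runl; bqb = qb; }
    else if (runl < bestl - X) break;
  }
  Ungapped u;
  u.qb = bqb; u.qe = bqe; u.sb = sp - (qp - bqb); u.se = sp + (bqe - qp);
  u.score = best + bestl;
  return u;
}

// ---- gapped X-drop extension with stats propagation ----------------------

struct GExt { int qi, sj; long score, matches, cols; };

// Reusable DP workspace: cells are never initialised globally; every read
// is guarded by the written-column ranges, so stale values are never seen.
struct XWork {
  std::vector<long> Hs, Fs, Hm, Hc, Fm, Fc, pHs, pHm, pHc;
  void ensure(size_t cap) {
    if (Hs.size() >= cap) return;
    size_t nc = std::max(cap + 64, Hs.size() * 2);
    Hs.resize(nc); Fs.resize(nc); Hm.resize(nc); Hc.resize(nc);
    Fm.resize(nc); Fc.resize(nc); pHs.resize(nc); pHm.resize(nc); pHc.resize(nc);
  }
};

// DIR = +1: q/s point at the first residue of the forward extension.
// DIR = -1: q/s point at the residue just before the anchor; the DP walks
// leftwards without copying (element i of the conceptual prefix is
// q[-(i-1)]).
template <int DIR>
static GExt xdrop_gapped(const uint8_t* q, int m, const uint8_t* s, int n,
                         const SearchParams& p, XWork& w) {
  GExt bestc; bestc.qi = 0; bestc.sj = 0; bestc.score = 0; bestc.matches = 0; bestc.cols = 0;
  if (m <= 0 || n <= 0) return bestc;
  const int nl = p.nl, go = p.gap_open, ge = p.gap_ext, X = p.gapped_xdrop;
  const int maxb = p.max_band;
  w.ensure((size_t)std::min(n, maxb + X + 8) + 2);
  long* Hs = w.Hs.data(); long* Fs = w.Fs.data();
  long* Hm = w.Hm.data(); long* Hc = w.Hc.data();
  long* Fm = w.Fm.data(); long* Fc = w.Fc.data();
  long* pHs = w.pHs.data(); long* pHm = w.pHm.data(); long* pHc = w.pHc.data();
  long best = 0;
  // row 0: leading gaps in subject (consume s only)
  Hs[0] = 0; Hm[0] = 0; Hc[0] = 0;
  int lo = 0;
  int pwlo = 0, pwhi = 0;  // column range written in the previous row
  Fs[0] = NEG;
  for (int j = 1; j <= n; ++j) {
    long v = -(long)go - (long)(j - 1) * ge;
    if (v < best - X || j > maxb) break;
    Hs[j] = v; Hm[j] = 0; Hc[j] = j;
    Fs[j] = NEG;
    pwhi = j;
  }
  for (int i = 1; i <= m; ++i) {
    // grow the workspace for the furthest column this row can touch,
    // then (re)bind raw pointers and swap current/previous rows
    w.ensure((size_t)std::min(n, pwhi + maxb + X + 8) + 2);
    std::swap(w.Hs, w.pHs); std::swap(w.Hm, w.pHm); std::swap(w.Hc, w.pHc);
    Hs = w.Hs.data(); Hm = w.Hm.data(); Hc = w.Hc.data();
    pHs = w.pHs.data(); pHm = w.pHm.data(); pHc = w.pHc.data();
    Fs = w.Fs.data(); Fm = w.Fm.data(); Fc = w.Fc.data();
    int rlo = lo;
    int newlo = -1, lastWritten = -1;
    long Ecur = NEG, EcurM = 0, EcurC = 0;  // E for current row, carried left->right
    long Hleft = NEG, HleftM = 0, HleftC = 0;
    int jstart = rlo;
    int wlo = rlo;
    if (rlo == 0) {
      // j == 0: leading gaps in query (consume q only)
      long v = -(long)go - (long)(i - 1) * ge;
      if (v >= best - X) {
        Hs[0] = v; Hm[0] = 0; Hc[0] = i;
        Fs[0] = v; Fm[0] = 0; Fc[0] = i;
        newlo = 0;
        Hleft = v; HleftM = 0; HleftC = i;
      } else {
        Hs[0] = NEG; Fs[0] = NEG;
      }
      jstart = 1; wlo = 0; lastWritten = 0;
    }
    for (int j = jstart; j <= n; ++j) {
      if (newlo >= 0 && j - newlo > maxb) break;
      // F: vertical (consume q), valid only where the previous row wrote
      long f = NEG, fm = 0, fc = 0;
      if (j >= pwlo && j <= pwhi) {
        long fo = (pHs[j] == NEG) ? NEG : pHs[j] - go;
        long fe = (Fs[j] == NEG) ? NEG : Fs[j] - ge;
        if (fo >= fe) { if (fo != NEG) { f = fo; fm = pHm[j]; fc = pHc[j] + 1; } }
        else { f = fe; fm = Fm[j]; fc = Fc[j] + 1; }
      }
      // E: horizontal (consume s), from current row previous column
      long eo = (Hleft == NEG) ? NEG : Hleft - go;
      long ee = (Ecur == NEG) ? NEG : Ecur - ge;
      long e = NEG, em = 0, ec = 0;
      if (eo >= ee) { if (eo != NEG) { e = eo; em = HleftM; ec = HleftC + 1; } }
      else { e = ee; em = EcurM; ec = EcurC + 1; }
      // diagonal
      long d = NEG, dm = 0, dc = 0;
      if (j - 1 >= pwlo && j - 1 <= pwhi && pHs[j - 1] != NEG) {
        uint8_t qc = (DIR > 0) ? q[i - 1] : q[-(i - 1)];
        uint8_t sc = (DIR > 0) ? s[j - 1] : s[-(j - 1)];
        d = pHs[j - 1] + p.S[qc * nl + sc];
        dm = pHm[j - 1] + (qc == sc ? 1 : 0);
        dc = pHc[j - 1] + 1;
      }
      long h = NEG, hm = 0, hc = 0;
      if (d >= e && d >= f) { h = d; hm = dm; hc = dc; }
      else if (e >= f) { h = e; hm = em; hc = ec; }
      else { h = f; hm = fm; hc = fc; }
      bool viable = (h != NEG) && (h >= best - X);
      Fs[j] = (f != NEG && f >= best - X) ? f : NEG; Fm[j] = fm; Fc[j] = fc;
      Ecur = (e != NEG && e >= best - X) ? e : NEG; EcurM = em; EcurC = ec;
      lastWritten = j;
      if (!viable) {
        Hs[j] = NEG;
        Hleft = NEG; HleftM = 0; HleftC = 0;
        if (j > pwhi + 1 && Ecur == NEG) break;  // nothing can revive further right
        continue;
      }
      Hs[j] = h; Hm[j] = hm; Hc[j] = hc;
      Hleft = h; HleftM = hm; HleftC = hc;
      if (newlo < 0) newlo = j;
      if (h > best) {
        best = h;
        bestc.qi = i; bestc.sj = j; bestc.score = h; bestc.matches = hm; bestc.cols = hc;
      }
    }
    if (newlo < 0) break;  // row extinguished
    lo = newlo;
    pwlo = wlo; pwhi = lastWritten;
    if (pwhi < pwlo) break;
  }
  return bestc;
}

// ---- per-pair search ------------------------------------------------------

struct GHit {
  int qb, qe, sb, se;
  long score, matches, cols;
};

static double ivOverlap(int a1, int a2, int b1, int b2) {
  int o = std::min(a2, b2) - std::max(a1, b1);
  if (o <= 0) return 0.0;
  return (double)o / (double)(a2 - a1);
}

static bool coveredByAccepted(int qb, int qe, int sb, int se,
                              const std::vector<GHit>& acc, int band) {
  for (size_t i = 0; i < acc.size(); ++i) {
    const GHit& h = acc[i];
    if (ivOverlap(qb, qe, h.qb, h.qe) >= 0.9 && ivOverlap(sb, se, h.sb, h.se) >= 0.9) {
      // require diagonal compatibility so off-diagonal self-repeat hits survive
      int dlo = std::min(sb - qb, se - qe) - band, dhi = std::max(sb - qb, se - qe) + band;
      int hdlo = std::min(h.sb - h.qb, h.se - h.qe) - band, hdhi = std::max(h.sb - h.qb, h.se - h.qe) + band;
      if (dlo <= hdhi && hdlo <= dhi) return true;
    }
  }
  return false;
}

static void search_pair(const std::vector<uint8_t>& q, const std::vector<uint8_t>& s,
                        const KmerIndex& idx, const SearchParams& p,
                        std::vector<int>& lastSeed, std::vector<int>& extent,
                        std::vector<uint32_t>& stamp, uint32_t epoch,
                        std::vector<GHit>& out) {
  const int k = p.seed_k;
  const int qlen = (int)q.size(), slen = (int)s.size();
  if (qlen < k || slen < k) return;
  std::vector<Ungapped> cands;
  std::vector<long> nwords;
  const int A = p.index_letters;
  long pw = 1; for (int i = 0; i < k - 1; ++i) pw *= A;
  long w = 0; int run = 0;
  for (int qp = 0; qp + k <= qlen; ++qp) {
    // rolling query word at position qp
    if (qp == 0) {
      run = 0; w = 0;
      for (int i = 0; i < k; ++i) {
        if (q[i] < A) { w = w * A + q[i]; run++; } else { run = 0; w = 0; }
      }
    } else {
      if (q[qp + k - 1] < A) { w = (w % pw) * A + q[qp + k - 1]; run++; }
      else { run = 0; w = 0; }
    }
    if (run < k) continue;
    const long* words; int nw;
    long single = w;
    if (p.neighbor_min > 0) {
      enum_neighbors(&q[qp], p, nwords);
      words = nwords.data(); nw = (int)nwords.size();
    } else { words = &single; nw = 1; }
    for (int wi = 0; wi < nw; ++wi) {
      long ww = words[wi];
      int from = idx.starts[ww], to = idx.starts[ww + 1];
      for (int t = from; t < to; ++t) {
        int sp = idx.positions[t];
        int dg = sp - qp + qlen;  // >= 0
        if (stamp[dg] != epoch) { stamp[dg] = epoch; lastSeed[dg] = INT_MIN; extent[dg] = INT_MIN; }
        if (qp <= extent[dg]) continue;
        if (p.two_hit) {
          int lp = lastSeed[dg];
          if (lp == INT_MIN) { lastSeed[dg] = qp; continue; }
          int dist = qp - lp;
          if (dist < k) continue;  // overlapping seeds: keep the earlier one
          lastSeed[dg] = qp;
          if (dist > p.two_hit_window) continue;
        }
        Ungapped u = ungapped_extend(q, s, qp, sp, p);
        extent[dg] = u.qe - 1;
        if (u.score >= p.ungapped_trigger) {
          cands.push_back(u);
          if ((int)cands.size() >= p.max_candidates) { qp = qlen; wi = nw; break; }
        }
      }
    }
  }
  std::sort(cands.begin(), cands.end(), [](const Ungapped& a, const Ungapped& b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.qb != b.qb) return a.qb < b.qb;
    return a.sb < b.sb;
  });
  std::vector<GHit> accepted;
  XWork xw;
  for (size_t ci = 0; ci < cands.size(); ++ci) {
    const Ungapped& u = cands[ci];
    if (coveredByAccepted(u.qb, u.qe, u.sb, u.se, accepted, p.max_band)) continue;
    int qa = (u.qb + u.qe) / 2;
    int sa = u.sb + (qa - u.qb);
    if (qa >= qlen || sa >= slen) continue;
    // forward: suffixes starting at the anchor
    GExt fw = xdrop_gapped<1>(&q[qa], qlen - qa, &s[sa], slen - sa, p, xw);
    // backward: prefixes ending just before the anchor, walked leftwards
    GExt bw = xdrop_gapped<-1>(qa > 0 ? &q[qa - 1] : q.data(),
                               qa,
                               sa > 0 ? &s[sa - 1] : s.data(),
                               sa, p, xw);
    GHit h;
    h.qb = qa - bw.qi; h.qe = qa + fw.qi;
    h.sb = sa - bw.sj; h.se = sa + fw.sj;
    h.score = fw.score + bw.score;
    h.matches = fw.matches + bw.matches;
    h.cols = fw.cols + bw.cols;
    if (h.qe <= h.qb || h.se <= h.sb || h.cols < 1) continue;
    if (h.score < p.min_score) continue;
    double ident = 100.0 * (double)h.matches / (double)h.cols;
    if (ident < p.min_identity) continue;
    if (h.cols < p.min_alnlen) continue;
    if (coveredByAccepted(h.qb, h.qe, h.sb, h.se, accepted, p.max_band)) continue;
    accepted.push_back(h);
  }
  for (size_t i = 0; i < accepted.size(); ++i) out.push_back(accepted[i]);
}

// [[Rcpp::export]]
DataFrame cpp_search(CharacterVector qseqs, CharacterVector sseqs, List params) {
  SearchParams p = parse_params(params);
  std::vector<int> qi_out, si_out, qb_out, qe_out, sb_out, se_out;
  std::vector<double> score_out, ident_out;
  std::vector<int> match_out, alen_out;
  int nq = qseqs.size(), ns = sseqs.size();
  std::vector<std::vector<uint8_t> > qcodes(nq);
  for (int i = 0; i < nq; ++i) qcodes[i] = encode(as<std::string>(qseqs[i]), p);
  KmerIndex idx;
  uint32_t epoch = 0;
  std::vector<int> lastSeed, extent;
  std::vector<uint32_t> stamp;
  for (int sj = 0; sj < ns; ++sj) {
    std::vector<uint8_t> sc = encode(as<std::string>(sseqs[sj]), p);
    if ((int)sc.size() < p.seed_k) continue;
    build_index(sc, p, idx);
    for (int qi = 0; qi < nq; ++qi) {
      const std::vector<uint8_t>& qc = qcodes[qi];
      size_t need = qc.size() + sc.size() + 1;
      if (lastSeed.size() < need) {
        lastSeed.resize(need); extent.resize(need); stamp.resize(need, 0);
      }
      ++epoch;
      std::vector<GHit> hits;
      search_pair(qc, sc, idx, p, lastSeed, extent, stamp, epoch, hits);
      for (size_t h = 0; h < hits.size(); ++h) {
        qi_out.push_back(qi + 1); si_out.push_back(sj + 1);
        qb_out.push_back(hits[h].qb); qe_out.push_back(hits[h].qe);
        sb_out.push_back(hits[h].sb); se_out.push_back(hits[h].se);
        score_out.push_back((double)hits[h].score);
        match_out.push_back((int)hits[h].matches);
        alen_out.push_back((int)hits[h].cols);
        ident_out.push_back(100.0 * (double)hits[h].matches / (double)hits[h].cols);
      }
    }
  }
  return DataFrame::create(
    _["qi"] = qi_out, _["si"] = si_out,
    _["q_start"] = qb_out, _["q_end"] = qe_out,
    _["s_start"] = sb_out, _["s_end"] = se_out,
    _["score"] = score_out, _["matches"] = match_out,
    _["aln_len"] = alen_out, _["identity_pct"] = ident_out,
    _["stringsAsFactors"] = false);
}

// ---- profile-profile global alignment (progressive MSA merge) ------------

// profA, profB: (nl x LA/LB) residue frequency profiles (gap mass excluded,
// columns need not sum to 1). Returns op codes per merged column:
// 0 = column from both, 1 = column from A only (gap in B), 2 = B only.
// [[Rcpp::export]]
IntegerVector cpp_profile_align(NumericMatrix profA, NumericMatrix profB,
                                NumericMatrix submat, double gap_open, double gap_ext) {
  const int nl = submat.nrow();
  const int la = profA.ncol(), lb = profB.ncol();
  // premultiply: VA[ , i] = submat %*% profA[, i]
  std::vector<double> VA((size_t)nl * la, 0.0);
  for (int i = 0; i < la; ++i)
    for (int a = 0; a < nl; ++a) {
      double fa = profA(a, i);
      if (fa != 0.0) {
        for (int b = 0; b < nl; ++b) VA[(size_t)i * nl + b] += fa * submat(a, b);
      }
    }
  const double INF = 1e18;
  std::vector<double> M((size_t)(la + 1) * (lb + 1), -INF);
  std::vector<double> X((size_t)(la + 1) * (lb + 1), -INF);  // gap in B (consume A)
  std::vector<double> Y((size_t)(la + 1) * (lb + 1), -INF);  // gap in A (consume B)
  std::vector<uint8_t> tbM((size_t)(la + 1) * (lb + 1), 0), tbX((size_t)(la + 1) * (lb + 1), 0),
      tbY((size_t)(la + 1) * (lb + 1), 0);
  auto id = [lb](int i, int j) { return (size_t)i * (lb + 1) + j; };
  M[id(0, 0)] = 0.0;
  for (int i = 1; i <= la; ++i) {
    X[id(i, 0)] = -gap_open - gap_ext * (i - 1);
    tbX[id(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= lb; ++j) {
    Y[id(0, j)] = -gap_open - gap_ext * (j - 1);
    tbY[id(0, j)] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= la; ++i) {
    const double* va = &VA[(size_t)(i - 1) * nl];
    for (int j = 1; j <= lb; ++j) {
      double sc = 0.0;
      for (int b = 0; b < nl; ++b) {
        double fb = profB(b, j - 1);
        if (fb != 0.0) sc += fb * va[b];
      }
      double m0 = M[id(i - 1, j - 1)], x0 = X[id(i - 1, j - 1)], y0 = Y[id(i - 1, j - 1)];
      double bestp = m0; uint8_t tb = 0;
      if (x0 > bestp) { bestp = x0; tb = 1; }
      if (y0 > bestp) { bestp = y0; tb = 2; }
      M[id(i, j)] = bestp + sc; tbM[id(i, j)] = tb;
      double xo = M[id(i - 1, j)] - gap_open, xe = X[id(i - 1, j)] - gap_ext;
      if (xo >= xe) { X[id(i, j)] = xo; tbX[id(i, j)] = 0; }
      else { X[id(i, j)] = xe; tbX[id(i, j)] = 1; }
      double yo = M[id(i, j - 1)] - gap_open, ye = Y[id(i, j - 1)] - gap_ext;
      if (yo >= ye) { Y[id(i, j)] = yo; tbY[id(i, j)] = 0; }
      else { Y[id(i, j)] = ye; tbY[id(i, j)] = 2; }
    }
  }
  // traceback from best end state
  int i = la, j = lb;
  double m = M[id(i, j)], x = X[id(i, j)], y = Y[id(i, j)];
  int state = 0;
  if (x > m && x >= y) state = 1;
  else if (y > m && y > x) state = 2;
  std::vector<int> ops;
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i == 0) { state = 2; continue; }
      if (j == 0) { state = 1; continue; }
      ops.push_back(0);
      state = tbM[id(i, j)];
      --i; --j;
    } else if (state == 1) {
      ops.push_back(1);
      state = tbX[id(i, j)];
      --i;
    } else {
      ops.push_back(2);
      state = tbY[id(i, j)];
      --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return wrap(ops);
}
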