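// Seed-and-extend local alignment engine.
//
// The index stores forward-strand k-mers of every catalog sequence. Queries
// are scanned on both orientations by the R wrapper (the reverse complement
// is scanned as a plus-strand query and coordinates are mirrored back).
// Seed chains are built greedily on near-constant diagonals and extended by
// a banded affine-gap Smith-Waterman whose band follows the interpolated
// chain diagonal; when query x subject is small the band covers the whole
// matrix, so the result is the exact local optimum.
//
// Gap cost convention: a gap of length L costs gap_open + L * gap_extend
// (both negative), i.e. opening a gap costs gap_open + gap_extend.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

static const int NEG_INF = -1000000000;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return 4;
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  case 'a': return 't';
  case 'c': return 'g';
  case 'g': return 'c';
  case 't': return 'a';
  default:  return 'N';
  }
}

// [[Rcpp::export(name = ".rc_cpp")]]
std::string rc_cpp(std::string s) {
  std::string out(s.size(), 'N');
  size_t n = s.size();
  for (size_t i = 0; i < n; ++i) out[i] = comp_base(s[n - 1 - i]);
  return out;
}

// ---------------------------------------------------------------------------
// Seed index
// ---------------------------------------------------------------------------

struct SeedIndexC {
  int k;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  double total_len;
  std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t> > > tab;
};

static void collect_kmers(const std::string& s, int k,
                          std::vector<uint64_t>& kmers,
                          std::vector<int>& positions) {
  kmers.clear(); positions.clear();
  int n = (int)s.size();
  if (n < k) return;
  uint64_t mask = (k < 32) ? ((uint64_t(1) << (2 * k)) - 1) : ~uint64_t(0);
  uint64_t cur = 0;
  int run = 0;  // valid bases accumulated
  for (int i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c > 3) { run = 0; cur = 0; continue; }
    cur = ((cur << 2) | (uint64_t)c) & mask;
    if (++run >= k) {
      kmers.push_back(cur);
      positions.push_back(i - k + 1);
    }
  }
}

// [[Rcpp::export(name = ".build_seed_index_cpp")]]
SEXP build_seed_index_cpp(CharacterVector seqs, CharacterVector names, int k) {
  SeedIndexC* idx = new SeedIndexC();
  idx->k = k;
  idx->total_len = 0;
  std::vector<uint64_t> km; std::vector<int> pos;
  for (int j = 0; j < seqs.size(); ++j) {
    std::string s = as<std::string>(seqs[j]);
    idx->names.push_back(as<std::string>(names[j]));
    idx->total_len += (double)s.size();
    collect_kmers(s, k, km, pos);
    for (size_t t = 0; t < km.size(); ++t)
      idx->tab[km[t]].push_back(std::make_pair((int32_t)j, (int32_t)pos[t]));
    idx->seqs.push_back(s);
  }
  XPtr<SeedIndexC> xp(idx, true);
  return xp;
}

// [[Rcpp::export(name = ".index_info_cpp")]]
List index_info_cpp(SEXP xp_) {
  XPtr<SeedIndexC> xp(xp_);
  IntegerVector lens(xp->names.size());
  for (size_t j = 0; j < xp->seqs.size(); ++j) lens[j] = (int)xp->seqs[j].size();
  return List::create(_["k"] = xp->k,
                      _["names"] = wrap(xp->names),
                      _["lengths"] = lens,
                      _["total_len"] = xp->total_len,
                      _["n_kmers"] = (double)xp->tab.size());
}

// [[Rcpp::export(name = ".index_lookup_cpp")]]
DataFrame index_lookup_cpp(SEXP xp_, std::string kmer) {
  XPtr<SeedIndexC> xp(xp_);
  std::vector<uint64_t> km; std::vector<int> pos;
  collect_kmers(kmer, xp->k, km, pos);
  std::vector<std::string> subj; std::vector<int> spos;
  if (km.size() == 1 && pos[0] == 0) {
    std::unordered_map<uint64_t, std::vector<std::pair<int32_t,int32_t> > >::iterator it =
      xp->tab.find(km[0]);
    if (it != xp->tab.end()) {
      for (size_t t = 0; t < it->second.size(); ++t) {
        subj.push_back(xp->names[it->second[t].first]);
        spos.push_back(it->second[t].second);
      }
    }
  }
  return DataFrame::create(_["subject_id"] = wrap(subj), _["pos"] = wrap(spos),
                           _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Banded affine local alignment with traceback
// ---------------------------------------------------------------------------

struct Aln {
  int score, qs, qe, ss, se, matches, alen, diag_cols;
  bool ok;
};

// Rows i = 1..n correspond to q[q0 + i - 1]; allowed subject columns for row i
// are [lo[i], hi[i]) (absolute coordinates within [s0, s1)).
static Aln band_sw(const std::string& q, const std::string& s,
                   int q0, int q1, int s0, int s1,
                   const std::vector<int>& lo, const std::vector<int>& hi,
                   int ma, int mi, int go, int ge) {
  Aln res; res.ok = false; res.score = 0;
  int n = q1 - q0;
  if (n <= 0 || s1 <= s0) return res;

  // ragged traceback storage; cell (i, j) at tb[row_off[i-1] + (j - lo[i])]
  std::vector<size_t> row_off(n + 1, 0);
  for (int i = 1; i <= n; ++i)
    row_off[i] = row_off[i - 1] + (size_t)std::max(0, hi[i] - lo[i]);
  std::vector<uint8_t> tb(row_off[n], 0);

  // base codes for the touched ranges
  std::vector<int8_t> qc(n), sc(s1 - s0);
  for (int i = 0; i < n; ++i) qc[i] = (int8_t)base_code(q[q0 + i]);
  for (int j = s0; j < s1; ++j) sc[j - s0] = (int8_t)base_code(s[j]);

  // arrays are indexed by absolute col - s0 + 1 (slot 0 = left sentinel)
  int width = s1 - s0 + 2;
  std::vector<int> Hp(width, 0), Fp(width, NEG_INF);
  std::vector<int> Hc(width, NEG_INF), Fc(width, NEG_INF);
  Hp[0] = NEG_INF;  // outside-matrix left sentinel for diag reads at j == s0
  int plo = s0, phi = s1;  // validity range of Hp/Fp (row 0 fully valid)

  int best = 0, bi = 0, bj = 0;
  int open_cost = go + ge;

  for (int i = 1; i <= n; ++i) {
    int l = lo[i], h = hi[i];
    if (l >= h) { plo = 0; phi = 0; continue; }
    // invalidate previous-row cells the current band reads but the previous
    // band did not compute (reads cover [l-1, h))
    for (int j = l - 1; j < h; ++j)
      if (j < plo || j >= phi) { Hp[j - s0 + 1] = NEG_INF; Fp[j - s0 + 1] = NEG_INF; }
    if (i == 1) {  // top matrix boundary: row 0 is all zero
      for (int j = l - 1; j < h; ++j)
        if (j >= s0) { Hp[j - s0 + 1] = 0; Fp[j - s0 + 1] = NEG_INF; }
    }
    // virtual column -1 of the matrix (H boundary) when it is in reach
    if (s0 == 0 && l == 0) Hp[0] = 0;
    int cq = qc[i - 1];
    int E = NEG_INF, Hleft = NEG_INF;
    uint8_t* trow = &tb[row_off[i - 1]] - l;
    int* hp = &Hp[1 - s0];  // hp[j] = H[i-1][j]
    int* fp = &Fp[1 - s0];
    int* hc = &Hc[1 - s0];
    int* fc = &Fc[1 - s0];
    const int8_t* scp = &sc[-s0];
    for (int j = l; j < h; ++j) {
      int f_open = hp[j] + open_cost;
      int f_ext = fp[j] + ge;
      int F; uint8_t fbit;
      if (f_open >= f_ext) { F = f_open; fbit = 8; } else { F = f_ext; fbit = 0; }
      int e_open = Hleft + open_cost;
      int e_ext = E + ge;
      uint8_t ebit;
      if (e_open >= e_ext) { E = e_open; ebit = 4; } else { E = e_ext; ebit = 0; }
      int cs = scp[j];
      int sub = (cq == cs && cq < 4) ? ma : mi;
      int dscore = hp[j - 1] + sub;
      int H = 0; uint8_t dir = 0;
      if (dscore > H) { H = dscore; dir = 1; }
      if (F > H) { H = F; dir = 2; }
      if (E > H) { H = E; dir = 3; }
      trow[j] = dir | ebit | fbit;
      hc[j] = H; fc[j] = F;
      Hleft = H;
      if (H > best) { best = H; bi = i; bj = j; }
    }
    hc[l - 1] = NEG_INF; fc[l - 1] = NEG_INF;  // left sentinel of this row
    std::swap(Hp, Hc); std::swap(Fp, Fc);
    plo = l; phi = h;
  }

  if (best <= 0) return res;

  // traceback from (bi, bj)
  int i = bi, j = bj, matches = 0, alen = 0, diag_cols = 0;
  while (i >= 1) {
    if (j < lo[i] || j >= hi[i]) break;
    uint8_t b = tb[row_off[i - 1] + (j - lo[i])];
    uint8_t dir = b & 3;
    if (dir == 0) break;
    if (dir == 1) {
      int cq = base_code(q[q0 + i - 1]), cs = base_code(s[j]);
      if (cq == cs && cq < 4) ++matches;
      ++alen; ++diag_cols; --i; --j;
    } else if (dir == 2) { // F: gap in subject, consume query chars upward
      while (i >= 1) {
        uint8_t bb = (j >= lo[i] && j < hi[i]) ? tb[row_off[i - 1] + (j - lo[i])] : 8;
        ++alen; --i;
        if (bb & 8) break; // F was opened from H at (i-1, j)
      }
    } else { // E: gap in query, consume subject chars leftward
      while (j >= s0) {
        uint8_t bb = (i >= 1 && j >= lo[i] && j < hi[i]) ? tb[row_off[i - 1] + (j - lo[i])] : 4;
        ++alen; --j;
        if (bb & 4) break;
      }
    }
  }
  res.ok = true;
  res.score = best;
  res.qs = q0 + i;       // 0-based inclusive start in query
  res.qe = q0 + bi;      // half-open end
  res.ss = j + 1;        // after last decrement, j is one left of the start col
  res.se = bj + 1;
  res.matches = matches;
  res.alen = alen;
  res.diag_cols = diag_cols;
  return res;
}

static Aln full_sw(const std::string& q, const std::string& s,
                   int ma, int mi, int go, int ge) {
  int n = (int)q.size(), m = (int)s.size();
  std::vector<int> lo(n + 1, 0), hi(n + 1, m);
  return band_sw(q, s, 0, n, 0, m, lo, hi, ma, mi, go, ge);
}

// [[Rcpp::export(name = ".sw_local_cpp")]]
List sw_local_cpp(std::string q, std::string s,
                  int match, int mismatch, int gap_open, int gap_extend) {
  double cells = (double)q.size() * (double)s.size();
  if (cells > 6e8) stop("sequence pair too large for full local alignment");
  Aln a = full_sw(q, s, match, mismatch, gap_open, gap_extend);
  if (!a.ok)
    return List::create(_["score"] = 0, _["q_start"] = NA_INTEGER,
                        _["q_end"] = NA_INTEGER, _["s_start"] = NA_INTEGER,
                        _["s_end"] = NA_INTEGER, _["matches"] = 0, _["aln_len"] = 0,
                        _["diag_cols"] = 0);
  return List::create(_["score"] = a.score, _["q_start"] = a.qs, _["q_end"] = a.qe,
                      _["s_start"] = a.ss, _["s_end"] = a.se,
                      _["matches"] = a.matches, _["aln_len"] = a.alen,
                      _["diag_cols"] = a.diag_cols);
}

// Cheap pre-alignment screen: how much of the query is covered by index
// seed matches (either strand), and over which query range. Used to skip
// banded extension for reads that clearly match nowhere or clearly match
// end to end.
// [[Rcpp::export(name = ".seed_screen_cpp")]]
List seed_screen_cpp(SEXP xp_, std::string qseq) {
  XPtr<SeedIndexC> xp(xp_);
  int k = xp->k;
  int nq = (int)qseq.size();
  std::vector<uint64_t> km; std::vector<int> pos;
  int n_pos = 0, qmin = nq, qmax = -1;
  for (int strand = 0; strand < 2; ++strand) {
    std::string qs = (strand == 0) ? qseq : rc_cpp(qseq);
    collect_kmers(qs, k, km, pos);
    for (size_t t = 0; t < km.size(); ++t) {
      if (xp->tab.find(km[t]) == xp->tab.end()) continue;
      int p = (strand == 0) ? pos[t] : nq - pos[t] - k;
      ++n_pos;
      if (p < qmin) qmin = p;
      if (p + k > qmax) qmax = p + k;
    }
  }
  double denom = std::max(1, nq - k + 1);
  return List::create(_["n_anchors"] = n_pos,
                      _["frac"] = n_pos / denom,
                      _["q_lo"] = (qmax < 0) ? NA_INTEGER : qmin,
                      _["q_hi"] = (qmax < 0) ? NA_INTEGER : qmax);
}

// ---------------------------------------------------------------------------
// Seed chaining + extension
// ---------------------------------------------------------------------------

struct Chain {
  std::vector<int> aq, as;  // anchor positions (query, subject), qpos ascending
  int last_q, last_s;
  long diag() const { return (long)last_s - (long)last_q; }
};

// [[Rcpp::export(name = ".scan_hits_cpp")]]
DataFrame scan_hits_cpp(SEXP xp_, std::string qseq,
                        int match, int mismatch, int gap_open, int gap_extend,
                        double exact_cells, int max_chain_gap, int diag_tol,
                        int band_min, int band_max, int pad, int max_chains) {
  XPtr<SeedIndexC> xp(xp_);
  int k = xp->k;
  int nq = (int)qseq.size();
  int nsub = (int)xp->seqs.size();

  std::vector<Aln> hits;
  std::vector<int> hit_subj;

  std::vector<bool> exact(nsub, false);
  for (int j = 0; j < nsub; ++j) {
    double cells = (double)nq * (double)xp->seqs[j].size();
    if (cells <= exact_cells) {
      exact[j] = true;
      Aln a = full_sw(qseq, xp->seqs[j], match, mismatch, gap_open, gap_extend);
      if (a.ok && a.score > 0) { hits.push_back(a); hit_subj.push_back(j); }
    }
  }

  // anchors per subject
  std::vector<uint64_t> km; std::vector<int> pos;
  collect_kmers(qseq, k, km, pos);
  std::vector<std::vector<std::pair<int,int> > > anchors(nsub);
  for (size_t t = 0; t < km.size(); ++t) {
    std::unordered_map<uint64_t, std::vector<std::pair<int32_t,int32_t> > >::iterator it =
      xp->tab.find(km[t]);
    if (it == xp->tab.end()) continue;
    const std::vector<std::pair<int32_t,int32_t> >& v = it->second;
    for (size_t u = 0; u < v.size(); ++u) {
      int j = v[u].first;
      if (!exact[j]) anchors[j].push_back(std::make_pair(pos[t], (int)v[u].second));
    }
  }

  for (int j = 0; j < nsub; ++j) {
    if (anchors[j].empty()) continue;
    const std::string& sseq = xp->seqs[j];
    int ns = (int)sseq.size();
    // greedy chaining: anchors arrive in ascending query position
    std::vector<Chain> chains;
    for (size_t t = 0; t < anchors[j].size(); ++t) {
      int qp = anchors[j][t].first, sp = anchors[j][t].second;
      long d = (long)sp - (long)qp;
      int bestc = -1; long bestdd = diag_tol + 1;
      for (size_t c = 0; c < chains.size(); ++c) {
        Chain& ch = chains[c];
        if (qp < ch.last_q) continue;
        if (qp - ch.last_q > max_chain_gap) continue;
        if (sp < ch.last_s - k) continue;
        long dd = d - ch.diag(); if (dd < 0) dd = -dd;
        if (dd <= diag_tol && dd < bestdd) { bestdd = dd; bestc = (int)c; }
      }
      if (bestc >= 0) {
        chains[bestc].aq.push_back(qp); chains[bestc].as.push_back(sp);
        chains[bestc].last_q = qp; chains[bestc].last_s = sp;
      } else {
        Chain ch; ch.aq.push_back(qp); ch.as.push_back(sp);
        ch.last_q = qp; ch.last_s = sp;
        chains.push_back(ch);
      }
    }
    // filter: tiny subjects (where random anchors are rare) may be hit by a
    // single seed; anything larger needs two co-linear seeds
    int min_seeds = (ns <= 2000) ? 1 : 2;
    std::vector<int> keep;
    for (size_t c = 0; c < chains.size(); ++c)
      if ((int)chains[c].aq.size() >= min_seeds) keep.push_back((int)c);
    // cap extension work: prefer chains with most anchors
    if ((int)keep.size() > max_chains) {
      std::sort(keep.begin(), keep.end(), [&](int a, int b) {
        if (chains[a].aq.size() != chains[b].aq.size())
          return chains[a].aq.size() > chains[b].aq.size();
        return chains[a].aq[0] < chains[b].aq[0];
      });
      keep.resize(max_chains);
    }

    // merge co-linear chains split by anchor droughts: gradual indel drift
    // can move the diagonal past diag_tol across a seed-free stretch,
    // fragmenting one true alignment into overlapping pieces
    std::sort(keep.begin(), keep.end(), [&](int a, int b) {
      return chains[a].aq[0] < chains[b].aq[0];
    });
    std::vector<Chain> merged;
    for (size_t t = 0; t < keep.size(); ++t) {
      Chain& c = chains[keep[t]];
      bool joined = false;
      // find a compatible open chain (closest diagonal wins)
      int best_m = -1; long best_dd = 401;
      for (size_t mi = 0; mi < merged.size(); ++mi) {
        Chain& m = merged[mi];
        long d1 = (long)m.as.back() - (long)m.aq.back();
        long d2 = (long)c.as[0] - (long)c.aq[0];
        long dd = d2 - d1; if (dd < 0) dd = -dd;
        if (c.aq[0] - m.aq.back() <= max_chain_gap + k && dd <= 400 &&
            c.as[0] >= m.as[0] && dd < best_dd) { best_dd = dd; best_m = (int)mi; }
      }
      if (best_m >= 0) {
        Chain& m = merged[best_m];
        {
          std::vector<int> aq, as;
          aq.reserve(m.aq.size() + c.aq.size());
          as.reserve(aq.capacity());
          size_t u = 0, v = 0;
          while (u < m.aq.size() || v < c.aq.size()) {
            bool from_m = (v >= c.aq.size()) ||
              (u < m.aq.size() && m.aq[u] <= c.aq[v]);
            if (from_m) { aq.push_back(m.aq[u]); as.push_back(m.as[u]); ++u; }
            else { aq.push_back(c.aq[v]); as.push_back(c.as[v]); ++v; }
          }
          m.aq.swap(aq); m.as.swap(as);
          m.last_q = m.aq.back(); m.last_s = m.as.back();
          joined = true;
        }
      }
      if (!joined) merged.push_back(c);
    }

    for (size_t ci = 0; ci < merged.size(); ++ci) {
      Chain& ch = merged[ci];
      int na = (int)ch.aq.size();
      int q_lo = ch.aq[0], q_hi = ch.aq[na - 1] + k;
      int s_lo = ch.as[0], s_hi = ch.as[na - 1] + k;
      for (int t = 0; t < na; ++t) {
        if (ch.as[t] < s_lo) s_lo = ch.as[t];
        if (ch.as[t] + k > s_hi) s_hi = ch.as[t] + k;
      }
      int q0 = std::max(0, q_lo - pad), q1 = std::min(nq, q_hi + pad);
      int s0 = std::max(0, s_lo - pad), s1 = std::min(ns, s_hi + pad);
      int span = q_hi - q_lo;
      int halfW = span / 5;
      if (halfW < band_min) halfW = band_min;
      if (halfW > band_max) halfW = band_max;
      int n = q1 - q0;
      std::vector<int> lo(n + 1, 0), hi(n + 1, 0);
      int t = 0;
      for (int i = 1; i <= n; ++i) {
        int qp = q0 + i - 1;
        long center;
        if (qp <= ch.aq[0]) center = (long)ch.as[0] + (qp - ch.aq[0]);
        else if (qp >= ch.aq[na - 1]) center = (long)ch.as[na - 1] + (qp - ch.aq[na - 1]);
        else {
          while (t + 1 < na && ch.aq[t + 1] <= qp) ++t;
          int t2 = t + 1;
          if (t2 >= na) t2 = na - 1;
          if (ch.aq[t2] == ch.aq[t]) center = ch.as[t];
          else center = ch.as[t] + (long)(ch.as[t2] - ch.as[t]) * (qp - ch.aq[t]) /
                        (ch.aq[t2] - ch.aq[t]);
        }
        int l = (int)center - halfW, h = (int)center + halfW + 1;
        if (l < s0) l = s0;
        if (h > s1) h = s1;
        if (l > h) l = h;
        lo[i] = l; hi[i] = h;
      }
      Aln a = band_sw(qseq, sseq, q0, q1, s0, s1, lo, hi,
                      match, mismatch, gap_open, gap_extend);
      if (a.ok && a.score > 0) { hits.push_back(a); hit_subj.push_back(j); }
    }
  }

  int nh = (int)hits.size();
  IntegerVector subj(nh), qs(nh), qe(nh), ss(nh), se(nh), score(nh), matches(nh), alen(nh);
  for (int t = 0; t < nh; ++t) {
    subj[t] = hit_subj[t] + 1;  // 1-based subject index
    qs[t] = hits[t].qs; qe[t] = hits[t].qe;
    ss[t] = hits[t].ss; se[t] = hits[t].se;
    score[t] = hits[t].score; matches[t] = hits[t].matches; alen[t] = hits[t].alen;
  }
  return DataFrame::create(_["subject"] = subj, _["q_start"] = qs, _["q_end"] = qe,
                           _["s_start"] = ss, _["s_end"] = se, _["score"] = score,
                           _["matches"] = matches, _["aln_len"] = alen,
                           _["stringsAsFactors"] = false);
}
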