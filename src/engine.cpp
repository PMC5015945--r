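// Core sequence kernels: seeded local alignment search, Nussinov base-pair
// maximization, and the permutation statistic of the conserved-ORF test.
#include <Rcpp.h>
#include <vector>
#include <string>
#include <unordered_map>
#include <algorithm>
#include <random>
using namespace Rcpp;

static inline int base2bit(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1; // N and friends: never match
  }
}

static std::string revcomp_str(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) {
    switch (c) {
    case 'A': case 'a': c = 'T'; break;
    case 'C': case 'c': c = 'G'; break;
    case 'G': case 'g': c = 'C'; break;
    case 'T': case 't': c = 'A'; break;
    default: c = 'N';
    }
  }
  return r;
}

struct Hit {
  int qidx; int cidx; char strand;
  int sstart, send, qstart, qend; int score;
};

// k-mer index of one chromosome: counting-sort layout.
struct KmerIndex {
  int k;
  std::vector<int> start;  // 4^k + 1 offsets
  std::vector<int> pos;    // positions sorted by bucket
  void build(const std::string &s, int k_) {
    k = k_;
    int nb = 1 << (2 * k);
    start.assign(nb + 1, 0);
    int n = (int)s.size();
    std::vector<int> codes(std::max(0, n - k + 1), -1);
    int code = 0, valid = 0;
    for (int i = 0; i < n; ++i) {
      int b = base2bit(s[i]);
      if (b < 0) { valid = 0; code = 0; }
      else { code = ((code << 2) | b) & (nb - 1); ++valid; }
      if (i >= k - 1 && valid >= k) codes[i - k + 1] = code;
    }
    for (int c : codes) if (c >= 0) ++start[c + 1];
    for (int b = 0; b < nb; ++b) start[b + 1] += start[b];
    pos.assign(start[nb], 0);
    std::vector<int> fill(start.begin(), start.end() - 1);
    for (int i = 0; i < (int)codes.size(); ++i)
      if (codes[i] >= 0) pos[fill[codes[i]]++] = i;
  }
};

static std::vector<int8_t> encode_seq(const std::string &s) {
  std::vector<int8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = (int8_t)base2bit(s[i]);
  return v;
}

// Ungapped X-drop extension of a seed on encoded sequences.
static int xdrop_extend(const std::vector<int8_t> &q,
                        const std::vector<int8_t> &s,
                        int qi, int si, int k, int match, int mismatch,
                        int xdrop, int &qlo, int &qhi, int &slo, int &shi) {
  int score = 0;
  for (int j = 0; j < k; ++j) {
    int bq = q[qi + j], bs = s[si + j];
    score += (bq >= 0 && bq == bs) ? match : -mismatch;
  }
  qlo = qi; slo = si; qhi = qi + k; shi = si + k;
  int best = score, cur = score, bq2 = qhi, bs2 = shi;
  int qn = (int)q.size(), sn = (int)s.size();
  for (int a = qhi, b = shi; a < qn && b < sn; ++a, ++b) {
    int x = q[a], y = s[b];
    cur += (x >= 0 && x == y) ? match : -mismatch;
    if (cur > best) { best = cur; bq2 = a + 1; bs2 = b + 1; }
    if (best - cur > xdrop) break;
  }
  qhi = bq2; shi = bs2;
  cur = best;
  int bq1 = qlo, bs1 = slo;
  for (int a = qlo - 1, b = slo - 1; a >= 0 && b >= 0; --a, --b) {
    int x = q[a], y = s[b];
    cur += (x >= 0 && x == y) ? match : -mismatch;
    if (cur > best) { best = cur; bq1 = a; bs1 = b; }
    if (best - cur > xdrop) break;
  }
  qlo = bq1; slo = bs1;
  return best;
}

// Smith-Waterman with affine gaps over a subject window; gap of length L
// costs gap_open + L * gap_extend. Returns best score + spans.
static int sw_window(const std::vector<int8_t> &qb,
                     const std::vector<int8_t> &s,
                     int w0, int w1, int match, int mismatch,
                     int gap_open, int gap_extend,
                     int &qstart, int &qend, int &sstart, int &send) {
  int m = (int)qb.size(), n = w1 - w0;
  const int NEG = -1000000000;
  int open_first = gap_open + gap_extend;
  std::vector<int> H(n + 2, 0), E(n + 2, NEG);
  // origin tracking: cell (i,j) stores start coords of its local alignment
  std::vector<int> Hqo(n + 2, 0), Hso(n + 2, 0), Eqo(n + 2, 0), Eso(n + 2, 0);
  int best = 0, bqs = 0, bqe = 0, bss = 0, bse = 0;
  // band around the window diagonal for long alignments; small problems
  // are solved in full
  bool banded = (m >= 256 && n >= 384);
  int band = 128;
  for (int i = 1; i <= m; ++i) {
    int jlo = 1, jhi = n;
    if (banded) {
      // the alignment maps query i near subject j = i + t for some
      // offset t in [-(m-n), (n-m)] depending on which side overhangs
      jlo = std::max(1, i - band - std::max(0, m - n));
      jhi = std::min(n, i + band + std::max(0, n - m));
      if (jhi < jlo) continue;
    }
    int diagH = H[jlo - 1], diagQo = Hqo[jlo - 1], diagSo = Hso[jlo - 1];
    // left boundary of the band is an empty cell for this row
    H[jlo - 1] = 0; E[jlo - 1] = NEG; Hqo[jlo - 1] = i; Hso[jlo - 1] = jlo - 1;
    int F = NEG, Fqo = 0, Fso = 0;
    for (int j = jlo; j <= jhi; ++j) {
      int sb = s[w0 + j - 1];
      int sub = (qb[i - 1] >= 0 && qb[i - 1] == sb) ? match : -mismatch;
      int diagScore = diagH + sub, dq = diagQo, ds = diagSo;
      if (diagH == 0 && diagScore == sub) { dq = i - 1; ds = j - 1; }
      // E: gap in query (consume subject)
      int eo = H[j - 1] - open_first, ee = E[j - 1] - gap_extend;
      if (eo >= ee) { E[j] = eo; Eqo[j] = Hqo[j - 1]; Eso[j] = Hso[j - 1]; }
      else { E[j] = ee; Eqo[j] = Eqo[j - 1]; Eso[j] = Eso[j - 1]; }
      // F: gap in subject (consume query)
      int fo = H[j] - open_first, fe = F - gap_extend;
      int nFqo, nFso, nF;
      if (fo >= fe) { nF = fo; nFqo = Hqo[j]; nFso = Hso[j]; }
      else { nF = fe; nFqo = Fqo; nFso = Fso; }
      diagH = H[j]; diagQo = Hqo[j]; diagSo = Hso[j];
      int h = diagScore, hq = dq, hs = ds;
      if (E[j] > h) { h = E[j]; hq = Eqo[j]; hs = Eso[j]; }
      if (nF > h) { h = nF; hq = nFqo; hs = nFso; }
      if (h < 0) { h = 0; hq = i; hs = j; }
      H[j] = h; Hqo[j] = hq; Hso[j] = hs;
      F = nF; Fqo = nFqo; Fso = nFso;
      if (h > best) { best = h; bqs = hq; bss = hs; bqe = i; bse = j; }
    }
    if (banded && jhi + 1 <= n) { // right boundary: empty for the next row
      H[jhi + 1] = 0; E[jhi + 1] = NEG; Hqo[jhi + 1] = i; Hso[jhi + 1] = jhi + 1;
    }
  }
  qstart = bqs; qend = bqe; sstart = w0 + bss; send = w0 + bse;
  return best;
}

// [[Rcpp::export]]
DataFrame cpp_search(CharacterVector query_seqs, CharacterVector chrom_seqs,
                     int k, int match, int mismatch, int gap_open,
                     int gap_extend, int xdrop, int trigger,
                     int max_cand_per_chrom = 64) {
  int nq = query_seqs.size(), nc = chrom_seqs.size();
  std::vector<Hit> hits;
  // pre-encode queries (both strands)
  int max_qlen = 0;
  std::vector<std::vector<int8_t>> qfwd_enc(nq), qrev_enc(nq);
  for (int qi = 0; qi < nq; ++qi) {
    std::string qs = as<std::string>(query_seqs[qi]);
    qfwd_enc[qi] = encode_seq(qs);
    qrev_enc[qi] = encode_seq(revcomp_str(qs));
    max_qlen = std::max(max_qlen, (int)qs.size());
  }
  for (int ci = 0; ci < nc; ++ci) {
    std::string chrom_str = as<std::string>(chrom_seqs[ci]);
    if ((int)chrom_str.size() < k) continue;
    KmerIndex idx; idx.build(chrom_str, k);
    std::vector<int8_t> chrom = encode_seq(chrom_str);
    int nb = 1 << (2 * k);
    // generation-stamped diagonal coverage (diag = spos - qpos + max_qlen)
    std::vector<int> cov((int)chrom.size() + max_qlen + 1, 0);
    std::vector<int> cov_gen((int)chrom.size() + max_qlen + 1, -1);
    int gen = 0;
    for (int qi = 0; qi < nq; ++qi) {
      int qlen = (int)qfwd_enc[qi].size();
      if (qlen < k) continue;
      for (int strand = 0; strand < 2; ++strand) {
        const std::vector<int8_t> &q = strand == 0 ? qfwd_enc[qi] : qrev_enc[qi];
        ++gen;
        struct Cand { int qlo, qhi, slo, shi, score; };
        std::vector<Cand> cands;
        int code = 0, valid = 0;
        for (int i = 0; i < qlen; ++i) {
          int b = q[i];
          if (b < 0) { valid = 0; code = 0; continue; }
          code = ((code << 2) | b) & (nb - 1);
          ++valid;
          if (valid < k) continue;
          int qpos = i - k + 1;
          for (int t = idx.start[code]; t < idx.start[code + 1]; ++t) {
            int spos = idx.pos[t];
            int d = spos - qpos + max_qlen;
            if (cov_gen[d] == gen && spos < cov[d]) continue;
            int qlo, qhi, slo, shi;
            int sc = xdrop_extend(q, chrom, qpos, spos, k, match, mismatch,
                                  xdrop, qlo, qhi, slo, shi);
            cov_gen[d] = gen; cov[d] = shi;
            if (sc >= trigger) cands.push_back({qlo, qhi, slo, shi, sc});
          }
        }
        if (cands.empty()) continue;
        // merge overlapping/nearby candidate subject regions
        std::sort(cands.begin(), cands.end(),
                  [](const Cand &a, const Cand &b) { return a.slo < b.slo; });
        std::vector<Cand> merged;
        for (auto &c : cands) {
          if (!merged.empty() && c.slo <= merged.back().shi + 2 * k) {
            merged.back().shi = std::max(merged.back().shi, c.shi);
            merged.back().qlo = std::min(merged.back().qlo, c.qlo);
            merged.back().qhi = std::max(merged.back().qhi, c.qhi);
            merged.back().score = std::max(merged.back().score, c.score);
          } else merged.push_back(c);
        }
        if ((int)merged.size() > max_cand_per_chrom) {
          std::sort(merged.begin(), merged.end(),
                    [](const Cand &a, const Cand &b) { return a.score > b.score; });
          merged.resize(max_cand_per_chrom);
          std::sort(merged.begin(), merged.end(),
                    [](const Cand &a, const Cand &b) { return a.slo < b.slo; });
        }
        for (auto &c : merged) {
          // window: candidate span plus the uncovered query ends and slack
          int w0 = std::max(0, c.slo - c.qlo - 64);
          int w1 = std::min((int)chrom.size(), c.shi + (qlen - c.qhi) + 64);
          int qs, qe, ss, se;
          int sc = sw_window(q, chrom, w0, w1, match, mismatch, gap_open,
                             gap_extend, qs, qe, ss, se);
          if (sc <= 0 || se - ss < k) continue;
          // report query span in original orientation
          int oqs = qs, oqe = qe;
          if (strand == 1) { oqs = qlen - qe; oqe = qlen - qs; }
          hits.push_back({qi, ci, strand == 0 ? '+' : '-', ss, se, oqs, oqe, sc});
        }
      }
    }
  }
  int n = (int)hits.size();
  IntegerVector qidx(n), cidx(n), sstart(n), send(n), qstart(n), qend(n), score(n);
  CharacterVector strand(n);
  for (int i = 0; i < n; ++i) {
    qidx[i] = hits[i].qidx + 1; cidx[i] = hits[i].cidx + 1;
    strand[i] = std::string(1, hits[i].strand);
    sstart[i] = hits[i].sstart; send[i] = hits[i].send;
    qstart[i] = hits[i].qstart; qend[i] = hits[i].qend;
    score[i] = hits[i].score;
  }
  return DataFrame::create(_["qidx"] = qidx, _["cidx"] = cidx,
                           _["strand"] = strand, _["sstart"] = sstart,
                           _["send"] = send, _["qstart"] = qstart,
                           _["qend"] = qend, _["score"] = score,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
int cpp_nussinov(std::string seq, int min_loop = 3) {
  int n = (int)seq.size();
  if (n == 0) return 0;
  auto pairs = [](char a, char b) {
    a = toupper(a); b = toupper(b);
    return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
           (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
           (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
  };
  std::string s = seq;
  for (auto &c : s) { c = toupper(c); if (c == 'T') c = 'U'; }
  std::vector<std::vector<int>> M(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[i + 1][j - 1] + (pairs(s[i], s[j]) && j - i > min_loop ? 1 : 0);
      best = std::max(best, M[i + 1][j]);
      best = std::max(best, M[i][j - 1]);
      for (int t = i + 1; t < j; ++t)
        best = std::max(best, M[i][t] + M[t + 1][j]);
      M[i][j] = best;
    }
  }
  return M[0][n - 1];
}

static const char *CODON_AA =
  // indexed by 16*b1 + 4*b2 + b3 with A=0,C=1,G=2,T=3
  "KNKNTTTTRSRSIIMIQHQHPPPPRRRRLLLLEDEDAAAAGGGGVVVV*Y*YSSSS*CWCLFLF";

static inline char translate_codon(int b1, int b2, int b3) {
  if (b1 < 0 || b2 < 0 || b3 < 0) return 'X';
  return CODON_AA[16 * b1 + 4 * b2 + b3];
}

// T statistic of the conserved-ORF test for one frame and column order.
// rows: aligned sequences (focal first, no gaps in focal); perm: 0-based
// column order; frame: 0..2 offset into the permuted columns.
static double coding_T(const std::vector<std::string> &rows,
                       const std::vector<int> &perm, int frame) {
  int L = (int)perm.size(), nr = (int)rows.size();
  int syn = 0, nonsyn = 0, disrupt = 0;
  for (int c0 = frame; c0 + 2 < L; c0 += 3) {
    int i1 = perm[c0], i2 = perm[c0 + 1], i3 = perm[c0 + 2];
    char f1 = rows[0][i1], f2 = rows[0][i2], f3 = rows[0][i3];
    int fb1 = base2bit(f1), fb2 = base2bit(f2), fb3 = base2bit(f3);
    if (fb1 < 0 || fb2 < 0 || fb3 < 0) continue;
    char faa = translate_codon(fb1, fb2, fb3);
    for (int r = 1; r < nr; ++r) {
      char m1 = rows[r][i1], m2 = rows[r][i2], m3 = rows[r][i3];
      int gaps = (m1 == '-') + (m2 == '-') + (m3 == '-');
      if (gaps == 3) continue;          // clean codon deletion, frame kept
      if (gaps > 0) { ++disrupt; continue; } // partial gap: frameshift
      if (m1 == f1 && m2 == f2 && m3 == f3) continue;
      int b1 = base2bit(m1), b2 = base2bit(m2), b3 = base2bit(m3);
      if (b1 < 0 || b2 < 0 || b3 < 0) continue;
      char aa = translate_codon(b1, b2, b3);
      if (aa == '*') { ++disrupt; continue; }
      if (faa == '*') { ++disrupt; continue; }
      if (aa == faa) ++syn; else ++nonsyn;
    }
  }
  return (double)syn - (double)nonsyn - 3.0 * (double)disrupt;
}

// [[Rcpp::export]]
List cpp_coding_test(CharacterVector aln, int n_perm, int seed) {
  int nr = aln.size();
  std::vector<std::string> rows(nr);
  for (int i = 0; i < nr; ++i) rows[i] = as<std::string>(aln[i]);
  int L = (int)rows[0].size();
  std::vector<int> ident(L);
  for (int i = 0; i < L; ++i) ident[i] = i;
  double tobs = coding_T(rows, ident, 0);
  for (int f = 1; f < 3; ++f) tobs = std::max(tobs, coding_T(rows, ident, f));
  std::mt19937 rng((unsigned)seed);
  NumericVector tperm(n_perm);
  std::vector<int> perm = ident;
  for (int p = 0; p < n_perm; ++p) {
    for (int i = L - 1; i > 0; --i) {
      std::uniform_int_distribution<int> u(0, i);
      std::swap(perm[i], perm[u(rng)]);
    }
    double t = coding_T(rows, perm, 0);
    for (int f = 1; f < 3; ++f) t = std::max(t, coding_T(rows, perm, f));
    tperm[p] = t;
  }
  return List::create(_["t_obs"] = tobs, _["t_perm"] = tperm);
}
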