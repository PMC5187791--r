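#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// shared helpers
// ---------------------------------------------------------------------------

static inline int base_idx(char c) {
  switch (c) {
    case 'T': return 0; case 'C': return 1; case 'A': return 2; case 'G': return 3;
  }
  return -1;
}

// standard genetic code, TCAG order, index = 16*b1 + 4*b2 + b3
static const char CODON_AA[] =
  "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG";

static inline char translate_codon(char a, char b, char c) {
  int i1 = base_idx(a), i2 = base_idx(b), i3 = base_idx(c);
  if (i1 < 0 || i2 < 0 || i3 < 0) return 'X';
  return CODON_AA[16 * i1 + 4 * i2 + i3];
}

// 128x128 score lookup built from a named substitution matrix; characters
// absent from the matrix score 0 (the 'X'-vs-anything convention)
struct ScoreTable {
  std::vector<double> tab;
  explicit ScoreTable(const NumericMatrix& mat) : tab(128 * 128, 0.0) {
    CharacterVector rn = rownames(mat), cn = colnames(mat);
    for (int i = 0; i < mat.nrow(); ++i) {
      char a = Rcpp::as<std::string>(rn[i])[0];
      for (int j = 0; j < mat.ncol(); ++j) {
        char b = Rcpp::as<std::string>(cn[j])[0];
        tab[(size_t)(a & 127) * 128 + (b & 127)] = mat(i, j);
      }
    }
  }
  inline double s(char a, char b) const {
    return tab[(size_t)(a & 127) * 128 + (b & 127)];
  }
};

// [[Rcpp::export(name = ".translate_cpp")]]
std::string translate_cpp(std::string dna) {
  size_t n = dna.size() / 3;
  std::string out(n, 'X');
  for (size_t i = 0; i < n; ++i)
    out[i] = translate_codon(dna[3 * i], dna[3 * i + 1], dna[3 * i + 2]);
  return out;
}

// ---------------------------------------------------------------------------
// Smith-Waterman local alignment (affine gaps; gap of length L costs
// gap_open + L * gap_extend), with traceback
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string q, std::string t, NumericMatrix mat,
                  double gap_open, double gap_extend) {
  const ScoreTable S(mat);
  const int m = (int)q.size(), n = (int)t.size();
  const double NEG = -1e18, go = gap_open + gap_extend, ge = gap_extend;
  const size_t W = (size_t)n + 1;
  std::vector<double> H((size_t)(m + 1) * W, 0.0), E((size_t)(m + 1) * W, NEG),
      F((size_t)(m + 1) * W, NEG);
  std::vector<signed char> PH((size_t)(m + 1) * W, 0), PE((size_t)(m + 1) * W, 0),
      PF((size_t)(m + 1) * W, 0);
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      size_t id = (size_t)i * W + j;
      double e_open = H[id - 1] - go, e_ext = E[id - 1] - ge;
      E[id] = std::max(e_open, e_ext); PE[id] = (e_ext > e_open) ? 1 : 0;
      double f_open = H[id - W] - go, f_ext = F[id - W] - ge;
      F[id] = std::max(f_open, f_ext); PF[id] = (f_ext > f_open) ? 1 : 0;
      double diag = H[id - W - 1] + S.s(q[i - 1], t[j - 1]);
      double h = 0.0; signed char ph = 0;
      if (diag > h) { h = diag; ph = 1; }
      if (E[id] > h) { h = E[id]; ph = 2; }
      if (F[id] > h) { h = F[id]; ph = 3; }
      H[id] = h; PH[id] = ph;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  int qs = 0, qe = 0, ts = 0, te = 0, nid = 0, ncol = 0;
  if (best > 0) {
    int i = bi, j = bj;
    qe = bi; te = bj;
    while (i > 0 && j > 0 && H[(size_t)i * W + j] > 0 && PH[(size_t)i * W + j] != 0) {
      size_t id = (size_t)i * W + j;
      signed char c = PH[id];
      if (c == 1) {
        ++ncol; if (q[i - 1] == t[j - 1]) ++nid;
        --i; --j;
      } else if (c == 2) {  // gap in query, consume target
        while (true) {
          signed char ec = PE[(size_t)i * W + j];
          ++ncol; --j;
          if (ec == 0) break;
        }
      } else {              // gap in target, consume query
        while (true) {
          signed char fc = PF[(size_t)i * W + j];
          ++ncol; --i;
          if (fc == 0) break;
        }
      }
    }
    qs = i + 1; ts = j + 1;
  }
  return List::create(_["score"] = best, _["q_start"] = qs, _["q_end"] = qe,
                      _["t_start"] = ts, _["t_end"] = te,
                      _["n_ident"] = nid, _["n_cols"] = ncol);
}

// ---------------------------------------------------------------------------
// seeded translated search of one protein query against one translated frame:
// exact k-mer seeds -> diagonal clustering -> windowed SW, iterated with
// masking so multiple copies in one window are all reported
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".seeded_search_cpp")]]
DataFrame seeded_search_cpp(std::string q, std::string t, int k, NumericMatrix mat,
                            double gap_open, double gap_extend, double min_score,
                            int diag_slack, int max_seed_gap, int window_pad,
                            int max_iter, int min_seeds) {
  const int m = (int)q.size(), n = (int)t.size();
  std::vector<double> score_v; std::vector<int> qs_v, qe_v, ts_v, te_v, nid_v, ncol_v;
  if (m >= k && n >= k) {
    std::unordered_map<std::string, std::vector<int> > idx;
    for (int i = 0; i + k <= m; ++i) {
      std::string w = q.substr(i, k);
      if (w.find('X') != std::string::npos || w.find('*') != std::string::npos) continue;
      idx[w].push_back(i);
    }
    // seeds as (diag, i, j)
    std::vector<std::array<int, 3> > seeds;
    for (int j = 0; j + k <= n; ++j) {
      std::string w = t.substr(j, k);
      std::unordered_map<std::string, std::vector<int> >::iterator it = idx.find(w);
      if (it == idx.end()) continue;
      for (size_t u = 0; u < it->second.size(); ++u) {
        int i = it->second[u];
        seeds.push_back({j - i, i, j});
      }
    }
    if (!seeds.empty()) {
      std::sort(seeds.begin(), seeds.end());
      // cluster seeds along diagonals, derive target windows
      std::vector<std::pair<int, int> > wins;
      int c_lo = 0;
      for (size_t s = 1; s <= seeds.size(); ++s) {
        bool brk = (s == seeds.size()) ||
          (seeds[s][0] - seeds[s - 1][0] > diag_slack) ||
          (seeds[s][0] == seeds[s - 1][0] && seeds[s][1] - seeds[s - 1][1] > max_seed_gap);
        if (brk) {
          if ((int)(s - c_lo) < min_seeds) { c_lo = (int)s; continue; }
          int min_j = seeds[c_lo][2], max_j = seeds[c_lo][2] + k;
          int min_i = seeds[c_lo][1], max_i = seeds[c_lo][1];
          for (size_t u = c_lo; u < s; ++u) {
            min_j = std::min(min_j, seeds[u][2]);
            max_j = std::max(max_j, seeds[u][2] + k);
            min_i = std::min(min_i, seeds[u][1]);
            max_i = std::max(max_i, seeds[u][1]);
          }
          int lo = std::max(0, min_j - min_i - window_pad);
          int hi = std::min(n, max_j + (m - max_i) + window_pad);
          wins.push_back(std::make_pair(lo, hi));
          c_lo = (int)s;
        }
      }
      std::sort(wins.begin(), wins.end());
      std::vector<std::pair<int, int> > merged;
      for (size_t u = 0; u < wins.size(); ++u) {
        if (!merged.empty() && wins[u].first <= merged.back().second)
          merged.back().second = std::max(merged.back().second, wins[u].second);
        else merged.push_back(wins[u]);
      }
      for (size_t u = 0; u < merged.size(); ++u) {
        int lo = merged[u].first, hi = merged[u].second;
        std::string win = t.substr(lo, hi - lo);
        for (int iter = 0; iter < max_iter; ++iter) {
          List al = sw_align_cpp(q, win, mat, gap_open, gap_extend);
          double sc = as<double>(al["score"]);
          if (sc < min_score) break;
          int ats = as<int>(al["t_start"]), ate = as<int>(al["t_end"]);
          score_v.push_back(sc);
          qs_v.push_back(as<int>(al["q_start"])); qe_v.push_back(as<int>(al["q_end"]));
          ts_v.push_back(lo + ats); te_v.push_back(lo + ate);
          nid_v.push_back(as<int>(al["n_ident"])); ncol_v.push_back(as<int>(al["n_cols"]));
          for (int p = ats - 1; p < ate; ++p) win[p] = 'X';  // mask and re-search
        }
      }
    }
  }
  return DataFrame::create(_["raw_score"] = score_v, _["q_start"] = qs_v,
                           _["q_end"] = qe_v, _["t_start"] = ts_v, _["t_end"] = te_v,
                           _["n_ident"] = nid_v, _["n_cols"] = ncol_v);
}

// ---------------------------------------------------------------------------
// frameshift-, stop- and intron-aware protein-to-DNA alignment.
// Moves into the aligned state H[i][j] (i aa consumed, j nt consumed):
//   codon match/substitution  (i-1, j-3), stop codons scored stop_penalty
//   frameshift codons of 1/2/4/5 nt for one aa, scored frameshift_penalty
//   codon gap in the genome   E (3 nt, affine)    [insertion in pseudogene]
//   codon gap in the protein  F (1 aa, affine)    [deletion in pseudogene]
//   intron skip of >= min_intron nt, scored intron_open (negative), free
//     extension,
//     splice_bonus/2 each for a GT donor and an AG acceptor
// Alignment is local at both ends (floor at 0); unaligned protein ends are
// reported by the caller as 5'/3' truncation.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".glocal_align_cpp")]]
List glocal_align_cpp(std::string prot, std::string dna, NumericMatrix mat,
                      double gap_open, double gap_extend, double fs_penalty,
                      double stop_penalty, double intron_open, int min_intron,
                      double splice_bonus) {
  const ScoreTable S(mat);
  const int m = (int)prot.size(), L = (int)dna.size();
  const double NEG = -1e18, go = gap_open + gap_extend, ge = gap_extend;
  const size_t W = (size_t)L + 1;
  std::vector<double> H((size_t)(m + 1) * W, 0.0), E((size_t)(m + 1) * W, NEG),
      F((size_t)(m + 1) * W, NEG);
  std::vector<signed char> PH((size_t)(m + 1) * W, 0), PE((size_t)(m + 1) * W, 0),
      PF((size_t)(m + 1) * W, 0);
  std::vector<int> JI((size_t)(m + 1) * W, 0);
  std::vector<double> Arow(W, NEG);   // running max_j' (H[i][j'] + donor bonus)
  std::vector<int> Aarg(W, 0);
  const int steps[4] = {1, 2, 4, 5};

  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    // reset row-local intron bookkeeping
    double amax = NEG; int aarg = 0;
    for (int j = 0; j <= L; ++j) {
      size_t id = (size_t)i * W + j;
      // gap matrices
      if (j >= 3) {
        double e_open = H[id - 3] - go, e_ext = E[id - 3] - ge;
        E[id] = std::max(e_open, e_ext); PE[id] = (e_ext > e_open) ? 1 : 0;
      }
      double f_open = H[id - W] - go, f_ext = F[id - W] - ge;
      F[id] = std::max(f_open, f_ext); PF[id] = (f_ext > f_open) ? 1 : 0;
      // maintain running donor max for position j - min_intron of this row
      if (j - min_intron >= 0) {
        int jp = j - min_intron;
        double db = 0.0;
        if (jp + 1 < L && dna[jp] == 'G' && dna[jp + 1] == 'T') db = splice_bonus / 2.0;
        double cand = H[(size_t)i * W + jp] + db;
        if (cand > amax) { amax = cand; aarg = jp; }
      }
      double h = 0.0; signed char ph = 0;
      if (j >= 3) {
        char aa = translate_codon(dna[j - 3], dna[j - 2], dna[j - 1]);
        double sc = (aa == '*') ? stop_penalty : S.s(prot[i - 1], aa);
        double diag = H[id - W - 3] + sc;
        if (diag > h) { h = diag; ph = 1; }
      }
      for (int s = 0; s < 4; ++s) {
        int st = steps[s];
        if (j >= st) {
          double c = H[id - W - st] + fs_penalty;
          if (c > h) { h = c; ph = (signed char)(2 + s); }
        }
      }
      if (E[id] > h) { h = E[id]; ph = 6; }
      if (F[id] > h) { h = F[id]; ph = 7; }
      if (j >= min_intron && amax > NEG / 2) {
        double ab = 0.0;
        if (j >= 2 && dna[j - 2] == 'A' && dna[j - 1] == 'G') ab = splice_bonus / 2.0;
        double c = amax + intron_open + ab;
        if (c > h) { h = c; ph = 8; JI[id] = aarg; }
      }
      H[id] = h; PH[id] = ph;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  // traceback
  std::vector<int> type_v, qpos_v, tstart_v, tend_v;
  std::vector<std::string> aa_v, codon_v;
  std::vector<bool> ident_v, stop_v;
  int n_indel = 0;
  int i = bi, j = bj;
  if (best > 0) {
    while (H[(size_t)i * W + j] > 0 && PH[(size_t)i * W + j] != 0) {
      size_t id = (size_t)i * W + j;
      signed char c = PH[id];
      if (c == 1) {
        char aa = translate_codon(dna[j - 3], dna[j - 2], dna[j - 1]);
        type_v.push_back(1); qpos_v.push_back(i);
        tstart_v.push_back(j - 2); tend_v.push_back(j);
        aa_v.push_back(std::string(1, aa));
        codon_v.push_back(dna.substr(j - 3, 3));
        ident_v.push_back(aa == prot[i - 1]); stop_v.push_back(aa == '*');
        --i; j -= 3;
      } else if (c >= 2 && c <= 5) {
        int st = steps[c - 2];
        type_v.push_back(2); qpos_v.push_back(i);
        tstart_v.push_back(j - st + 1); tend_v.push_back(j);
        aa_v.push_back("!"); codon_v.push_back("");
        ident_v.push_back(false); stop_v.push_back(false);
        --i; j -= st;
      } else if (c == 6) {
        ++n_indel;
        while (true) {
          signed char ec = PE[(size_t)i * W + j];
          type_v.push_back(3); qpos_v.push_back(NA_INTEGER);
          tstart_v.push_back(j - 2); tend_v.push_back(j);
          aa_v.push_back("-"); codon_v.push_back("");
          ident_v.push_back(false); stop_v.push_back(false);
          j -= 3;
          if (ec == 0) break;
        }
      } else if (c == 7) {
        ++n_indel;
        while (true) {
          signed char fc = PF[(size_t)i * W + j];
          type_v.push_back(4); qpos_v.push_back(i);
          tstart_v.push_back(NA_INTEGER); tend_v.push_back(NA_INTEGER);
          aa_v.push_back("-"); codon_v.push_back("");
          ident_v.push_back(false); stop_v.push_back(false);
          --i;
          if (fc == 0) break;
        }
      } else {  // intron
        int jp = JI[id];
        type_v.push_back(5); qpos_v.push_back(i);
        tstart_v.push_back(jp + 1); tend_v.push_back(j);
        aa_v.push_back("~"); codon_v.push_back("");
        ident_v.push_back(false); stop_v.push_back(false);
        j = jp;
      }
    }
  }
  std::reverse(type_v.begin(), type_v.end()); std::reverse(qpos_v.begin(), qpos_v.end());
  std::reverse(tstart_v.begin(), tstart_v.end()); std::reverse(tend_v.begin(), tend_v.end());
  std::reverse(aa_v.begin(), aa_v.end()); std::reverse(ident_v.begin(), ident_v.end());
  std::reverse(stop_v.begin(), stop_v.end()); std::reverse(codon_v.begin(), codon_v.end());

  DataFrame cols = DataFrame::create(
      _["type"] = type_v, _["q_pos"] = qpos_v, _["t_start"] = tstart_v,
      _["t_end"] = tend_v, _["aa"] = aa_v, _["codon"] = codon_v,
      _["ident"] = ident_v, _["stop"] = stop_v,
      _["stringsAsFactors"] = false);
  return List::create(_["score"] = best,
                      _["q_start"] = (best > 0) ? i + 1 : 0,
                      _["q_end"] = (best > 0) ? bi : 0,
                      _["t_start"] = (best > 0) ? j + 1 : 0,
                      _["t_end"] = (best > 0) ? bj : 0,
                      _["n_indel_events"] = n_indel, _["columns"] = cols);
}
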