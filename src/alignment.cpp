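#include <Rcpp.h>
#include <cstring>
#include <string>
#include <vector>

using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh). A gap of length L costs
// gap_open + L * gap_extend. 'N' never matches, not even another 'N'.

namespace {

inline int subst(char a, char b, int match, int mismatch) {
  if (a == b && a != 'N') return match;
  return mismatch;
}

const int NEG = -1000000000;

struct Trace {
  // per-cell traceback states for H, E (gap consuming query), F (gap
  // consuming subject)
  std::vector<unsigned char> h, e, f;
  int m;
  Trace(int n, int mm) : h((size_t)(n + 1) * (mm + 1), 0),
                         e((size_t)(n + 1) * (mm + 1), 0),
                         f((size_t)(n + 1) * (mm + 1), 0), m(mm) {}
  size_t idx(int i, int j) const { return (size_t)i * (m + 1) + j; }
};

// H states: 0 = stop/origin, 1 = diagonal, 2 = from E, 3 = from F
// E/F states: 0 = opened from H, 1 = extended

std::string cigar_from_ops(const std::vector<char>& ops) {
  std::string out;
  size_t i = 0;
  while (i < ops.size()) {
    size_t j = i;
    while (j < ops.size() && ops[j] == ops[i]) ++j;
    out += std::to_string(j - i);
    out += ops[i];
    i = j;
  }
  return out;
}

} // namespace

// Local (Smith-Waterman) alignment with affine gaps and full traceback.
// Returns score 0 / empty cigar when no positive-scoring alignment exists.
// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string query, std::string subject,
                  int match, int mismatch, int gap_open, int gap_extend) {
  int n = (int)query.size(), m = (int)subject.size();
  if (n == 0 || m == 0) {
    return List::create(_["score"] = 0, _["query_start"] = 0,
                        _["query_end"] = -1, _["subject_start"] = 0,
                        _["subject_end"] = -1, _["cigar"] = "",
                        _["n_match"] = 0, _["n_aligned_cols"] = 0);
  }
  std::vector<int> Hprev(m + 1, 0), Hcur(m + 1, 0);
  std::vector<int> Eprev(m + 1, NEG), Ecur(m + 1, NEG);
  std::vector<int> Fcur(m + 1, NEG);
  Trace tr(n, m);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    Hcur[0] = 0; Ecur[0] = NEG; Fcur[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      // E: gap consuming query (vertical)
      int e_open = Hprev[j] + gap_open + gap_extend;
      int e_ext  = Eprev[j] + gap_extend;
      if (e_open >= e_ext) { Ecur[j] = e_open; tr.e[tr.idx(i, j)] = 0; }
      else                 { Ecur[j] = e_ext;  tr.e[tr.idx(i, j)] = 1; }
      // F: gap consuming subject (horizontal)
      int f_open = Hcur[j - 1] + gap_open + gap_extend;
      int f_ext  = Fcur[j - 1] + gap_extend;
      if (f_open >= f_ext) { Fcur[j] = f_open; tr.f[tr.idx(i, j)] = 0; }
      else                 { Fcur[j] = f_ext;  tr.f[tr.idx(i, j)] = 1; }
      int diag = Hprev[j - 1] + subst(query[i - 1], subject[j - 1],
                                      match, mismatch);
      int h = 0; unsigned char st = 0;
      if (diag >= h)    { h = diag;    st = 1; }
      if (Ecur[j] > h)  { h = Ecur[j]; st = 2; }
      if (Fcur[j] > h)  { h = Fcur[j]; st = 3; }
      if (h <= 0) { h = 0; st = 0; }
      Hcur[j] = h; tr.h[tr.idx(i, j)] = st;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }
  if (best == 0) {
    return List::create(_["score"] = 0, _["query_start"] = 0,
                        _["query_end"] = -1, _["subject_start"] = 0,
                        _["subject_end"] = -1, _["cigar"] = "",
                        _["n_match"] = 0, _["n_aligned_cols"] = 0);
  }
  // traceback from (bi, bj)
  std::vector<char> ops;
  int i = bi, j = bj, state = 0; // 0 = in H
  int n_match = 0, n_cols = 0;
  while (i > 0 && j > 0) {
    if (state == 0) {
      unsigned char st = tr.h[tr.idx(i, j)];
      if (st == 0) break;
      if (st == 1) {
        ops.push_back('M');
        ++n_cols;
        if (query[i - 1] == subject[j - 1] && query[i - 1] != 'N') ++n_match;
        --i; --j;
      } else if (st == 2) state = 2;
      else state = 3;
    } else if (state == 2) { // E: gap consuming query
      ops.push_back('I');
      if (tr.e[tr.idx(i, j)] == 0) state = 0;
      --i;
    } else { // F: gap consuming subject
      ops.push_back('D');
      if (tr.f[tr.idx(i, j)] == 0) state = 0;
      --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = best,
                      _["query_start"] = i + 1, _["query_end"] = bi,
                      _["subject_start"] = j + 1, _["subject_end"] = bj,
                      _["cigar"] = cigar_from_ops(ops),
                      _["n_match"] = n_match, _["n_aligned_cols"] = n_cols);
}

// Global (Needleman-Wunsch) alignment with affine gaps; end gaps are
// penalized. Used for the center-star consensus MSA.
// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string query, std::string subject,
                  int match, int mismatch, int gap_open, int gap_extend) {
  int n = (int)query.size(), m = (int)subject.size();
  if (n == 0 && m == 0)
    return List::create(_["score"] = 0, _["cigar"] = "");
  if (n == 0)
    return List::create(_["score"] = gap_open + m * gap_extend,
                        _["cigar"] = std::to_string(m) + "D");
  if (m == 0)
    return List::create(_["score"] = gap_open + n * gap_extend,
                        _["cigar"] = std::to_string(n) + "I");
  std::vector<int> Hprev(m + 1), Hcur(m + 1);
  std::vector<int> Eprev(m + 1), Ecur(m + 1);
  std::vector<int> Fcur(m + 1);
  Trace tr(n, m);
  Hprev[0] = 0; Eprev[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    Hprev[j] = gap_open + j * gap_extend;
    Eprev[j] = NEG;
    tr.h[tr.idx(0, j)] = 3; tr.f[tr.idx(0, j)] = (j == 1) ? 0 : 1;
  }
  for (int i = 1; i <= n; ++i) {
    Hcur[0] = gap_open + i * gap_extend;
    Ecur[0] = Hcur[0]; Fcur[0] = NEG;
    tr.h[tr.idx(i, 0)] = 2; tr.e[tr.idx(i, 0)] = (i == 1) ? 0 : 1;
    for (int j = 1; j <= m; ++j) {
      int e_open = Hprev[j] + gap_open + gap_extend;
      int e_ext  = Eprev[j] + gap_extend;
      if (e_open >= e_ext) { Ecur[j] = e_open; tr.e[tr.idx(i, j)] = 0; }
      else                 { Ecur[j] = e_ext;  tr.e[tr.idx(i, j)] = 1; }
      int f_open = Hcur[j - 1] + gap_open + gap_extend;
      int f_ext  = Fcur[j - 1] + gap_extend;
      if (f_open >= f_ext) { Fcur[j] = f_open; tr.f[tr.idx(i, j)] = 0; }
      else                 { Fcur[j] = f_ext;  tr.f[tr.idx(i, j)] = 1; }
      int diag = Hprev[j - 1] + subst(query[i - 1], subject[j - 1],
                                      match, mismatch);
      int h = diag; unsigned char st = 1;
      if (Ecur[j] > h) { h = Ecur[j]; st = 2; }
      if (Fcur[j] > h) { h = Fcur[j]; st = 3; }
      Hcur[j] = h; tr.h[tr.idx(i, j)] = st;
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }
  int score = Hprev[m];
  std::vector<char> ops;
  int i = n, j = m, state = 0;
  while (i > 0 || j > 0) {
    if (state == 0) {
      unsigned char st = tr.h[tr.idx(i, j)];
      if (st == 1) { ops.push_back('M'); --i; --j; }
      else if (st == 2) state = 2;
      else state = 3;
    } else if (state == 2) {
      ops.push_back('I');
      if (tr.e[tr.idx(i, j)] == 0) state = 0;
      --i;
    } else {
      ops.push_back('D');
      if (tr.f[tr.idx(i, j)] == 0) state = 0;
      --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = score, _["cigar"] = cigar_from_ops(ops));
}

// Score-only local alignment (two-row DP, no traceback): used to rank
// candidate germline segments before computing the full alignment for the
// winner only.
// [[Rcpp::export(name = ".sw_score_multi_cpp")]]
IntegerVector sw_score_multi_cpp(std::string query, CharacterVector subjects,
                                 int match, int mismatch, int gap_open,
                                 int gap_extend) {
  int n = (int)query.size();
  int ns = subjects.size();
  IntegerVector out(ns);
  std::vector<int> H, E;
  for (int s = 0; s < ns; ++s) {
    std::string subject = as<std::string>(subjects[s]);
    int m = (int)subject.size();
    if (n == 0 || m == 0) { out[s] = 0; continue; }
    H.assign(m + 1, 0);
    E.assign(m + 1, NEG);
    int best = 0;
    for (int i = 1; i <= n; ++i) {
      int diag = 0;        // H[i-1][j-1]
      int f = NEG;         // F[i][j-1] running horizontal gap
      char qc = query[i - 1];
      for (int j = 1; j <= m; ++j) {
        int e = std::max(H[j] + gap_open, E[j]) + gap_extend;
        f = std::max(H[j - 1] + gap_open, f) + gap_extend;
        int h = diag + ((qc == subject[j - 1] && qc != 'N') ? match
                                                            : mismatch);
        if (e > h) h = e;
        if (f > h) h = f;
        if (h < 0) h = 0;
        diag = H[j];
        H[j] = h;
        E[j] = e;
        if (h > best) best = h;
      }
    }
    out[s] = best;
  }
  return out;
}

// Hamming-distance tag search. Offsets are scanned outward from the read
// end (0-based offsets returned); at the first offset where any tag lies
// within max_mismatch, the tag with the fewest mismatches there is the hit
// ('tie' flags two *distinct* tags sharing that minimum). Preferring the
// proximal-most acceptable offset prevents background sequence deeper in
// the window from outcompeting a slightly errored true tag, which is what
// causes cross-well misassignment. When no offset yields an acceptable hit
// the overall minimum-mismatch hit is reported for diagnostics (the caller
// rejects it against max_mismatch).
// [[Rcpp::export(name = ".tag_scan_dir_cpp")]]
DataFrame tag_scan_dir_cpp(CharacterVector windows, CharacterVector tags,
                           int max_mismatch, bool from_end) {
  int nw = windows.size(), nt = tags.size();
  std::vector<std::string> tg(nt);
  for (int t = 0; t < nt; ++t) tg[t] = as<std::string>(tags[t]);
  IntegerVector best_tag(nw), best_off(nw), best_mm(nw);
  LogicalVector tie(nw);
  for (int w = 0; w < nw; ++w) {
    std::string win = as<std::string>(windows[w]);
    int bm = INT_MAX, bt = -1, bo = -1; // global minimum (diagnostics)
    bool amb = false;
    bool found = false;
    int L = nt ? (int)tg[0].size() : 0;
    int maxoff = (int)win.size() - L;
    std::vector<int> offsets;
    if (from_end) { for (int o = maxoff; o >= 0; --o) offsets.push_back(o); }
    else          { for (int o = 0; o <= maxoff; ++o) offsets.push_back(o); }
    for (size_t oi = 0; oi < offsets.size() && !found; ++oi) {
      int off = offsets[oi];
      int off_bm = INT_MAX, off_bt = -1;
      bool off_amb = false;
      for (int t = 0; t < nt; ++t) {
        const std::string& tag = tg[t];
        int mm = 0;
        int lim = std::min(bm, max_mismatch + 1);
        for (int k = 0; k < (int)tag.size() && mm <= lim; ++k)
          if (win[off + k] != tag[k]) ++mm;
        if (mm < bm) { bm = mm; bt = t; bo = off; }
        if (mm <= max_mismatch) {
          if (mm < off_bm) { off_bm = mm; off_bt = t; off_amb = false; }
          else if (mm == off_bm && t != off_bt) off_amb = true;
        }
      }
      if (off_bt >= 0) {
        bm = off_bm; bt = off_bt; bo = off; amb = off_amb;
        found = true;
      }
    }
    best_tag[w] = (bt < 0) ? NA_INTEGER : bt + 1;
    best_off[w] = (bt < 0) ? NA_INTEGER : bo;
    best_mm[w]  = (bt < 0) ? NA_INTEGER : bm;
    tie[w] = found && amb;
  }
  return DataFrame::create(_["tag_index"] = best_tag, _["offset"] = best_off,
                           _["mismatches"] = best_mm, _["tie"] = tie);
}
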