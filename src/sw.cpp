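// Smith-Waterman local alignment with affine gaps (gap of length L costs
// gap_open + L * gap_extend), full traceback for identity accounting.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// qi, sj: 1-based row/column indices into the substitution matrix
// [[Rcpp::export]]
List sw_align_cpp(IntegerVector qi, IntegerVector sj, NumericMatrix sub,
                  double gap_open, double gap_extend) {
  const int n = qi.size(), m = sj.size();
  const double NEG = -1e18;
  // flat copy of the substitution matrix for fast access
  const int nr = sub.nrow();
  std::vector<double> S(sub.begin(), sub.end());
  const double go = gap_open + gap_extend;  // cost of opening a 1-gap
  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0);
  // traceback pointers: H: 0 stop, 1 diag, 2 E, 3 F; E/F: 0 open, 1 extend
  std::vector<signed char> tbH((n + 1) * (m + 1), 0);
  std::vector<signed char> tbE((n + 1) * (m + 1), 0);
  std::vector<signed char> tbF((n + 1) * (m + 1), 0);

  double best = 0.0;
  int bi = 0, bj = 0;

  std::vector<double> Fcol(m + 1, NEG);  // F of the previous row, per column

  for (int i = 1; i <= n; ++i) {
    Hcur[0] = 0.0;
    double Eleft = NEG;  // E[i][j-1]
    for (int j = 1; j <= m; ++j) {
      const size_t at = (size_t)i * (m + 1) + j;
      // E: gap in query (consume subject)
      double e_open = Hcur[j - 1] - go;
      double e_ext = Eleft - gap_extend;
      double E = e_open >= e_ext ? e_open : e_ext;
      tbE[at] = e_open >= e_ext ? 0 : 1;
      // F: gap in subject (consume query), uses row i-1
      double f_open = Hprev[j] - go;
      double f_ext = Fcol[j] - gap_extend;
      double F = f_open >= f_ext ? f_open : f_ext;
      tbF[at] = f_open >= f_ext ? 0 : 1;
      double diag = Hprev[j - 1] + S[(size_t)(sj[j - 1] - 1) * nr + (qi[i - 1] - 1)];
      double h = 0.0;
      signed char ptr = 0;
      if (diag > h) { h = diag; ptr = 1; }
      if (E > h) { h = E; ptr = 2; }
      if (F > h) { h = F; ptr = 3; }
      Hcur[j] = h;
      tbH[at] = ptr;
      Eleft = E;
      Fcol[j] = F;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
  }

  // traceback
  int i = bi, j = bj, qend = bi, send = bj, qstart = bi, sstart = bj;
  int ncols = 0, nident = 0;
  int state = 0;  // 0 = H
  if (best > 0) {
    while (i > 0 && j > 0) {
      const size_t at = (size_t)i * (m + 1) + j;
      if (state == 0) {
        signed char ptr = tbH[at];
        if (ptr == 0) break;
        if (ptr == 1) {
          ++ncols;
          if (qi[i - 1] == sj[j - 1]) ++nident;
          qstart = i; sstart = j;
          --i; --j;
        } else if (ptr == 2) {
          state = 2;
        } else {
          state = 3;
        }
      } else if (state == 2) {  // in E: consume subject
        ++ncols;
        sstart = j;
        signed char ptr = tbE[at];
        --j;
        if (ptr == 0) state = 0;
      } else {  // in F: consume query
        ++ncols;
        qstart = i;
        signed char ptr = tbF[at];
        --i;
        if (ptr == 0) state = 0;
      }
    }
  } else {
    qstart = qend = sstart = send = 0;
  }

  return List::create(
    _["score"] = best, _["q_start"] = qstart, _["q_end"] = qend,
    _["s_start"] = sstart, _["s_end"] = send,
    _["aligned_cols"] = ncols, _["identical_cols"] = nident
  );
}
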