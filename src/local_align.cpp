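#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Smith-Waterman-Gotoh local alignment with affine gaps.
// Gap of length k costs gap_open + k * gap_ext (so a length-1 gap costs
// gap_open + gap_ext). Traceback is deterministic: at equal scores prefer
// diagonal, then up (gap in target / query residue consumed), then left.

// [[Rcpp::export(name = ".sw_align")]]
List sw_align(std::string q, std::string t, NumericMatrix mat,
              std::string alphabet, double gap_open, double gap_ext) {
  const int m = q.size(), n = t.size();
  std::vector<int> code(256, -1);
  for (size_t k = 0; k < alphabet.size(); ++k)
    code[(unsigned char)alphabet[k]] = (int)k;
  int xcode = code[(unsigned char)'X'];
  std::vector<int> qi(m), ti(n);
  for (int i = 0; i < m; ++i) {
    int c = code[(unsigned char)q[i]];
    qi[i] = (c >= 0) ? c : xcode;
  }
  for (int j = 0; j < n; ++j) {
    int c = code[(unsigned char)t[j]];
    ti[j] = (c >= 0) ? c : xcode;
  }

  const double NEG = -1e30;
  const double open_cost = gap_open + gap_ext;
  // matrices are (m+1) x (n+1), row-major
  std::vector<double> H((m + 1) * (n + 1), 0.0);
  std::vector<double> E((m + 1) * (n + 1), NEG); // gap in query (left moves)
  std::vector<double> F((m + 1) * (n + 1), NEG); // gap in target (up moves)
  // pointers: H: 0 stop, 1 diag, 2 from F(up), 3 from E(left)
  //           E: 0 opened from H, 1 extended ; F likewise
  std::vector<unsigned char> pH((m + 1) * (n + 1), 0), pE((m + 1) * (n + 1), 0),
      pF((m + 1) * (n + 1), 0);

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int idx = i * (n + 1) + j;
      const int up = (i - 1) * (n + 1) + j;
      const int left = idx - 1;
      const int diag = up - 1;
      // E: gap in query, consume target residue (left)
      double e_open = H[left] - open_cost;
      double e_ext = E[left] - gap_ext;
      if (e_open >= e_ext) { E[idx] = e_open; pE[idx] = 0; }
      else { E[idx] = e_ext; pE[idx] = 1; }
      // F: gap in target, consume query residue (up)
      double f_open = H[up] - open_cost;
      double f_ext = F[up] - gap_ext;
      if (f_open >= f_ext) { F[idx] = f_open; pF[idx] = 0; }
      else { F[idx] = f_ext; pF[idx] = 1; }
      double sub = H[diag] + mat(qi[i - 1], ti[j - 1]);
      // preference at ties: diagonal, then up (F), then left (E), then stop
      double h = 0.0; unsigned char p = 0;
      if (sub >= h) { h = sub; p = 1; }
      if (F[idx] > h) { h = F[idx]; p = 2; }
      if (E[idx] > h) { h = E[idx]; p = 3; }
      if (sub >= h && p != 1) { h = sub; p = 1; } // diag wins ties
      H[idx] = h; pH[idx] = (h > 0.0) ? p : 0;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["qstart"] = NA_INTEGER,
                        _["qend"] = NA_INTEGER, _["tstart"] = NA_INTEGER,
                        _["tend"] = NA_INTEGER, _["n_ident"] = 0,
                        _["n_cols"] = 0, _["q_aln"] = "", _["t_aln"] = "");
  }

  // traceback
  std::string qa, ta;
  int i = bi, j = bj;
  int state = 0; // 0 = H, 1 = E, 2 = F
  while (true) {
    int idx = i * (n + 1) + j;
    if (state == 0) {
      unsigned char p = pH[idx];
      if (p == 0) break;
      if (p == 1) {
        qa.push_back(q[i - 1]); ta.push_back(t[j - 1]);
        --i; --j;
      } else if (p == 2) {
        state = 2;
      } else {
        state = 1;
      }
    } else if (state == 1) { // E: gap in query, consume target
      qa.push_back('-'); ta.push_back(t[j - 1]);
      unsigned char p = pE[idx];
      --j;
      if (p == 0) state = 0;
    } else { // F: gap in target, consume query
      qa.push_back(q[i - 1]); ta.push_back('-');
      unsigned char p = pF[idx];
      --i;
      if (p == 0) state = 0;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(ta.begin(), ta.end());
  int n_ident = 0;
  for (size_t k = 0; k < qa.size(); ++k)
    if (qa[k] == ta[k] && qa[k] != '-') ++n_ident;

  return List::create(_["score"] = best, _["qstart"] = i + 1, _["qend"] = bi,
                      _["tstart"] = j + 1, _["tend"] = bj,
                      _["n_ident"] = n_ident, _["n_cols"] = (int)qa.size(),
                      _["q_aln"] = qa, _["t_aln"] = ta);
}
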