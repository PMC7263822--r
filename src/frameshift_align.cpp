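#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>
using namespace Rcpp;

// Frameshift-tolerant alignment of a retrocopy nucleotide sequence to a
// parent protein (with its terminal '*' appended by the caller).
//
// Local on both axes (one best block): unaligned retrocopy overhangs
// (UTRs, mid-codon truncation remainders) and parent prefix/suffix codons
// are free.  The block may start at any codon (fresh start into M) and
// ends at the best-scoring M cell.  Three Gotoh states:
//   M  - codon aligned to a parent residue, entered by
//          diag3 (3 nt, ordinary codon),
//          fs4   (4 nt, one inserted nt -> frameshift_ins, scored on the
//                 last 3 nt minus the frameshift penalty),
//          fs2   (2 nt, one deleted nt  -> frameshift_del, penalty only);
//   X  - extra retrocopy codon (gap in parent), affine at codon granularity;
//   Y  - missing parent codon (gap in retrocopy), affine at codon granularity.
// Ties resolved match > frameshift > gap, then leftmost, by strict-greater
// updates in a fixed evaluation order.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline int base_idx(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
  }
}

// [[Rcpp::export]]
List cpp_align_frameshift(std::string nt, std::string prot,
                          IntegerVector codon_aa, IntegerVector prot_col,
                          NumericMatrix submat, double gap_open3,
                          double gap_ext3, double fs_penalty) {
  const int n = (int)nt.size();
  const int m = (int)prot.size();
  const int W = m + 1;

  std::vector<int> nti(n);
  for (int i = 0; i < n; ++i) {
    nti[i] = base_idx(nt[i]);
    if (nti[i] < 0) stop("non-ACGT base in retrocopy sequence");
  }
  // codon index ending at nt position i (1-based consumed count): uses
  // nt[i-3..i-1]
  auto codon_at = [&](int i) {
    return 16 * nti[i - 3] + 4 * nti[i - 2] + nti[i - 1];
  };

  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  // traceback: move code and predecessor state per cell per state
  // M moves: 1 diag3, 2 fs4, 3 fs2 ; X: 1 from M, 2 from X ; Y likewise
  std::vector<signed char> tbM((n + 1) * W, 0), tbMs((n + 1) * W, 0),
      tbX((n + 1) * W, 0), tbY((n + 1) * W, 0);

  for (int j = 0; j <= m; ++j) M[j] = 0.0;  // free parent prefix at i = 0

  for (int i = 1; i <= n; ++i) {
    for (int j = 0; j <= m; ++j) {
      const int c = i * W + j;
      // ---- M ----
      if (j >= 1) {
        double best = NEG_INF;
        signed char mv = 0, ps = 0;
        const int aa = prot_col[j - 1];
        // diag3 (also the only fresh-start move of a local block)
        if (i >= 3) {
          const int p = (i - 3) * W + (j - 1);
          const int ci = codon_aa[codon_at(i)];
          const double sc = submat(ci, aa);
          const double preds[4] = {M[p], X[p], Y[p], 0.0};
          for (int s = 0; s < 4; ++s) {
            if (preds[s] != NEG_INF && preds[s] + sc > best) {
              best = preds[s] + sc;
              mv = 1;
              ps = (signed char)s;  // 3 = fresh start
            }
          }
        }
        // fs4: 4 nt consumed, scored on last 3
        if (i >= 4) {
          const int p = (i - 4) * W + (j - 1);
          const int ci = codon_aa[codon_at(i)];
          const double sc = submat(ci, aa) - fs_penalty;
          const double preds[3] = {M[p], X[p], Y[p]};
          for (int s = 0; s < 3; ++s) {
            if (preds[s] != NEG_INF && preds[s] + sc > best) {
              best = preds[s] + sc;
              mv = 2;
              ps = (signed char)s;
            }
          }
        }
        // fs2: 2 nt consumed, penalty only
        if (i >= 2) {
          const int p = (i - 2) * W + (j - 1);
          const double preds[3] = {M[p], X[p], Y[p]};
          for (int s = 0; s < 3; ++s) {
            if (preds[s] != NEG_INF && preds[s] - fs_penalty > best) {
              best = preds[s] - fs_penalty;
              mv = 3;
              ps = (signed char)s;
            }
          }
        }
        if (mv) {
          M[c] = best;
          tbM[c] = mv;
          tbMs[c] = ps;
        }
      }
      // ---- X: extra retrocopy codon (3 nt, no parent residue) ----
      if (i >= 3) {
        const int p = (i - 3) * W + j;
        double a = (M[p] == NEG_INF) ? NEG_INF : M[p] - gap_open3;
        double b = (X[p] == NEG_INF) ? NEG_INF : X[p] - gap_ext3;
        if (a >= b && a != NEG_INF) {
          X[c] = a;
          tbX[c] = 1;
        } else if (b != NEG_INF) {
          X[c] = b;
          tbX[c] = 2;
        }
      }
      // ---- Y: missing parent codon ----
      if (j >= 1) {
        const int p = i * W + (j - 1);
        double a = (M[p] == NEG_INF) ? NEG_INF : M[p] - gap_open3;
        double b = (Y[p] == NEG_INF) ? NEG_INF : Y[p] - gap_ext3;
        if (a >= b && a != NEG_INF) {
          Y[c] = a;
          tbY[c] = 1;
        } else if (b != NEG_INF) {
          Y[c] = b;
          tbY[c] = 2;
        }
      }
    }
  }

  // final: the local block ends at the best M cell anywhere; strict-greater
  // scan => leftmost (smallest i, then smallest j) preferred on ties
  double best = NEG_INF;
  int bi = -1, bj = -1;
  for (int i = 0; i <= n; ++i) {
    for (int j = 0; j <= m; ++j) {
      const int c = i * W + j;
      if (M[c] != NEG_INF && M[c] > best) { best = M[c]; bi = i; bj = j; }
    }
  }
  if (bi < 0) {
    return List::create(_["score"] = NA_REAL, _["aligned"] = false);
  }

  // traceback
  std::vector<int> ev_type;  // 1 premature_stop, 2 frameshift_ins, 3 frameshift_del
  std::vector<int> ev_codon;
  int i = bi, j = bj, s = 0;
  int jmin = m + 1, jmax = 0;
  const int star_col = prot_col[m - 1];  // terminal '*' column index
  while (i > 0) {
    const int c = i * W + j;
    if (s == 0) {
      const int mv = tbM[c];
      const int ps = tbMs[c];
      if (j < jmin) jmin = j;
      if (j > jmax) jmax = j;
      if (mv == 1 || mv == 2) {
        const int ci = codon_aa[codon_at(i)];
        // premature stop: codon translates to '*' before the terminal codon
        if (ci == star_col && j < m) {
          ev_type.push_back(1);
          ev_codon.push_back(j);
        }
        if (mv == 2) {
          ev_type.push_back(2);
          ev_codon.push_back(j);
        }
        i -= (mv == 1) ? 3 : 4;
      } else {  // fs2
        ev_type.push_back(3);
        ev_codon.push_back(j);
        i -= 2;
      }
      j -= 1;
      if (ps == 3) break;  // fresh start: block begins here
      s = ps;
    } else if (s == 1) {
      const int ps = tbX[c];
      i -= 3;
      s = (ps == 1) ? 0 : 1;
    } else {
      const int ps = tbY[c];
      j -= 1;
      s = (ps == 1) ? 0 : 2;
    }
  }

  // events were collected right-to-left
  const int ne = (int)ev_type.size();
  IntegerVector types(ne), codons(ne);
  for (int k = 0; k < ne; ++k) {
    types[k] = ev_type[ne - 1 - k];
    codons[k] = ev_codon[ne - 1 - k];
  }
  return List::create(_["score"] = best, _["aligned"] = true,
                      _["event_type"] = types, _["parent_codon"] = codons,
                      _["parent_start"] = (jmin <= m ? jmin : NA_INTEGER),
                      _["parent_end"] = (jmax >= 1 ? jmax : NA_INTEGER));
}
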