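// Affine-gap Smith-Waterman (Gotoh). Sequences arrive as 0-based integer
// codes into the rows/cols of the scoring matrix (code 20 = X, scored 0).
// A gap of length k costs open + k * extend (NCBI convention, so the
// published BLOSUM62 11/1 Karlin-Altschul parameters apply).

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Best local alignment score only; O(|q|) memory, used for the all-vs-all
// scan where most pairs never reach the E-value ceiling.
static int sw_score(const int* q, int nq, const int* s, int ns,
                    const int* mat, int na, int open, int extend) {
  std::vector<int> H(nq + 1, 0), E(nq + 1, 0);
  int best = 0;
  const int ginit = open + extend;
  for (int j = 1; j <= ns; ++j) {
    int diag = 0;       // H[i-1][j-1]
    int F = 0;          // gap in subject (vertical)
    const int* srow = mat + (size_t)s[j - 1] * na;
    for (int i = 1; i <= nq; ++i) {
      int h = diag + srow[q[i - 1]];
      diag = H[i];
      E[i] = std::max(H[i] - ginit, E[i] - extend);
      F = std::max(H[i - 1] - ginit, F - extend);
      h = std::max(h, std::max(E[i], F));
      if (h < 0) h = 0;
      H[i] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".cpp_sw_score_batch")]]
IntegerVector cpp_sw_score_batch(IntegerVector q, List db, IntegerMatrix smat,
                                 int gap_open, int gap_extend) {
  int n = db.size();
  IntegerVector out(n);
  int na = smat.nrow();
  std::vector<int> mat(smat.begin(), smat.end());
  // smat is column-major; transpose-free access needs row-major copy
  std::vector<int> rm((size_t)na * na);
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < na; ++j) rm[(size_t)i * na + j] = smat(i, j);
  for (int k = 0; k < n; ++k) {
    IntegerVector s = db[k];
    out[k] = sw_score(q.begin(), q.size(), s.begin(), s.size(),
                      rm.data(), na, gap_open, gap_extend);
  }
  return out;
}

// Full DP with traceback. Ties on the optimum are broken toward the
// smallest query end coordinate, then smallest subject end coordinate,
// with diagonal moves preferred during traceback (shortest alignment).
// [[Rcpp::export(name = ".cpp_sw_align")]]
List cpp_sw_align(IntegerVector qv, IntegerVector sv, IntegerMatrix smat,
                  int gap_open, int gap_extend) {
  const int nq = qv.size(), ns = sv.size(), na = smat.nrow();
  const int ginit = gap_open + gap_extend;
  std::vector<int> rm((size_t)na * na);
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < na; ++j) rm[(size_t)i * na + j] = smat(i, j);

  std::vector<int> H((size_t)(nq + 1) * (ns + 1), 0);
  std::vector<int> E((size_t)(nq + 1) * (ns + 1), 0);
  std::vector<int> F((size_t)(nq + 1) * (ns + 1), 0);
  auto at = [&](std::vector<int>& M, int i, int j) -> int& {
    return M[(size_t)i * (ns + 1) + j];
  };
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= nq; ++i) {
    const int* qrow = rm.data() + (size_t)qv[i - 1] * na;
    for (int j = 1; j <= ns; ++j) {
      at(E, i, j) = std::max(at(H, i, j - 1) - ginit, at(E, i, j - 1) - gap_extend);
      at(F, i, j) = std::max(at(H, i - 1, j) - ginit, at(F, i - 1, j) - gap_extend);
      int h = at(H, i - 1, j - 1) + qrow[sv[j - 1]];
      h = std::max(h, std::max(at(E, i, j), at(F, i, j)));
      if (h < 0) h = 0;
      at(H, i, j) = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0)
    return List::create(_["score"] = 0);

  // traceback
  int i = bi, j = bj;
  int identities = 0, mismatches = 0, gap_opens = 0, align_len = 0;
  while (i > 0 && j > 0 && at(H, i, j) > 0) {
    int h = at(H, i, j);
    const int sub = rm[(size_t)qv[i - 1] * na + sv[j - 1]];
    if (h == at(H, i - 1, j - 1) + sub) {
      if (qv[i - 1] == sv[j - 1]) ++identities; else ++mismatches;
      ++align_len; --i; --j;
    } else if (h == at(E, i, j)) {
      // gap in query (consumes subject): walk the whole gap run
      ++gap_opens;
      while (j > 0) {
        ++align_len;
        bool opened = (at(E, i, j) == at(H, i, j - 1) - ginit);
        --j;
        if (opened) break;
      }
    } else {
      ++gap_opens;
      while (i > 0) {
        ++align_len;
        bool opened = (at(F, i, j) == at(H, i - 1, j) - ginit);
        --i;
        if (opened) break;
      }
    }
  }
  return List::create(
    _["score"] = best,
    _["qstart"] = i + 1, _["qend"] = bi,
    _["sstart"] = j + 1, _["send"] = bj,
    _["align_len"] = align_len,
    _["identities"] = identities,
    _["mismatches"] = mismatches,
    _["gap_opens"] = gap_opens);
}
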