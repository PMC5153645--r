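#include <Rcpp.h>
using namespace Rcpp;

// Exact affine-gap Smith-Waterman local alignment.
// Gap of length g costs gap_open + gap_extend * g (BLAST convention),
// so the first gapped position is charged gap_open + gap_extend.
// Traceback ties: diagonal, then up (gap in subject), then left.

static inline int idx_of(char c, const std::vector<int>& lut) {
  int k = lut[static_cast<unsigned char>(c)];
  return k; // -1 means unknown -> caller maps to X
}

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string query, std::string subject,
                  IntegerMatrix submat, int gap_open, int gap_extend) {
  const int m = query.size(), n = subject.size();
  if (m == 0 || n == 0) stop("empty sequence");

  // residue -> matrix row lookup from dimnames; unknowns use the X column
  CharacterVector rn = rownames(submat);
  std::vector<int> lut(256, -1);
  int xcol = -1;
  for (int i = 0; i < rn.size(); ++i) {
    char c = CHAR(STRING_ELT(rn, i))[0];
    lut[static_cast<unsigned char>(c)] = i;
    if (c == 'X') xcol = i;
  }
  if (xcol < 0) stop("substitution matrix lacks an X column");
  std::vector<int> qi(m), sj(n);
  for (int i = 0; i < m; ++i) {
    int k = idx_of(query[i], lut);
    qi[i] = (k < 0) ? xcol : k;
  }
  for (int j = 0; j < n; ++j) {
    int k = idx_of(subject[j], lut);
    sj[j] = (k < 0) ? xcol : k;
  }

  const int NEG = INT_MIN / 4;
  const int gfirst = gap_open + gap_extend;
  // H: best ending in match; U: gap in subject (consumes query, moves up);
  // L: gap in query (consumes subject, moves left)
  std::vector<int> H((m + 1) * (n + 1), 0), U((m + 1) * (n + 1), NEG),
      L((m + 1) * (n + 1), NEG);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int s = submat(qi[i - 1], sj[j - 1]);
      int diag = std::max(H[at(i - 1, j - 1)],
                          std::max(U[at(i - 1, j - 1)], L[at(i - 1, j - 1)]));
      int h = diag + s;
      if (h < 0) h = 0;
      H[at(i, j)] = h;
      int u = std::max(H[at(i - 1, j)] - gfirst, U[at(i - 1, j)] - gap_extend);
      U[at(i, j)] = u;
      int l = std::max(H[at(i, j - 1)] - gfirst, L[at(i, j - 1)] - gap_extend);
      L[at(i, j)] = l;
      if (h > best) { best = h; bi = i; bj = j; } // first max kept (row-major)
    }
  }

  if (best == 0) {
    return List::create(_["score"] = 0, _["q_start"] = NA_INTEGER,
                        _["q_end"] = NA_INTEGER, _["s_start"] = NA_INTEGER,
                        _["s_end"] = NA_INTEGER, _["aligned_query"] = "",
                        _["aligned_subject"] = "");
  }

  // traceback from (bi,bj) in state H until the running H hits 0
  std::string aq, as;
  int i = bi, j = bj;
  char state = 'H';
  while (i > 0 && j > 0) {
    if (state == 'H') {
      if (H[at(i, j)] == 0) break;
      int s = submat(qi[i - 1], sj[j - 1]);
      int prev = H[at(i, j)] - s;
      aq.push_back(query[i - 1]);
      as.push_back(subject[j - 1]);
      // prefer diagonal (H), then up (U), then left (L)
      if (H[at(i - 1, j - 1)] == prev || prev == 0) {
        state = 'H';
      } else if (U[at(i - 1, j - 1)] == prev) {
        state = 'U';
      } else {
        state = 'L';
      }
      --i; --j;
      if (prev == 0) break;
    } else if (state == 'U') {
      aq.push_back(query[i - 1]);
      as.push_back('-');
      if (H[at(i - 1, j)] - gfirst == U[at(i, j)]) state = 'H';
      --i;
    } else { // L
      aq.push_back('-');
      as.push_back(subject[j - 1]);
      if (H[at(i, j - 1)] - gfirst == L[at(i, j)]) state = 'H';
      --j;
    }
  }
  std::reverse(aq.begin(), aq.end());
  std::reverse(as.begin(), as.end());
  return List::create(_["score"] = best, _["q_start"] = i + 1,
                      _["q_end"] = bi, _["s_start"] = j + 1, _["s_end"] = bj,
                      _["aligned_query"] = aq, _["aligned_subject"] = as);
}
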