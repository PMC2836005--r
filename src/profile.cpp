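#include <Rcpp.h>
using namespace Rcpp;

// Profile-profile global alignment with linear gap penalty, used by the
// progressive aligner. Column score = average substitution score over all
// residue pairs drawn from the two columns; gap characters contribute 0.

// [[Rcpp::export]]
List cpp_profile_align(CharacterVector prof1, CharacterVector prof2,
                       std::string alphabet, NumericMatrix submat,
                       double gap) {
  const int K = (int)alphabet.size();
  int map[256];
  for (int i = 0; i < 256; ++i) map[i] = -1;
  for (int i = 0; i < K; ++i) map[(unsigned char)alphabet[i]] = i;

  std::vector<std::string> p1, p2;
  for (int i = 0; i < prof1.size(); ++i) p1.push_back(as<std::string>(prof1[i]));
  for (int i = 0; i < prof2.size(); ++i) p2.push_back(as<std::string>(prof2[i]));
  const int L1 = p1.empty() ? 0 : (int)p1[0].size();
  const int L2 = p2.empty() ? 0 : (int)p2[0].size();
  for (auto& s : p1) if ((int)s.size() != L1) stop("profile 1 rows differ in length");
  for (auto& s : p2) if ((int)s.size() != L2) stop("profile 2 rows differ in length");
  const int n1 = (int)p1.size(), n2 = (int)p2.size();

  // column frequency counts (gaps excluded)
  std::vector<double> f1((size_t)L1 * K, 0.0), f2((size_t)L2 * K, 0.0);
  for (int r = 0; r < n1; ++r)
    for (int c = 0; c < L1; ++c) {
      int a = map[(unsigned char)p1[r][c]];
      if (a >= 0) f1[(size_t)c * K + a] += 1.0;
    }
  for (int r = 0; r < n2; ++r)
    for (int c = 0; c < L2; ++c) {
      int a = map[(unsigned char)p2[r][c]];
      if (a >= 0) f2[(size_t)c * K + a] += 1.0;
    }
  // precompute M * f2 for each column of profile 2
  std::vector<double> Mf2((size_t)L2 * K, 0.0);
  for (int c = 0; c < L2; ++c)
    for (int a = 0; a < K; ++a) {
      double acc = 0.0;
      for (int b = 0; b < K; ++b) acc += submat(a, b) * f2[(size_t)c * K + b];
      Mf2[(size_t)c * K + a] = acc;
    }
  const double denom = (double)n1 * (double)n2;

  std::vector<float> H((size_t)(L1 + 1) * (L2 + 1));
  std::vector<unsigned char> tr((size_t)(L1 + 1) * (L2 + 1), 0);
#define IDX(i, j) ((size_t)(i) * (L2 + 1) + (j))
  H[IDX(0, 0)] = 0.0f;
  for (int j = 1; j <= L2; ++j) { H[IDX(0, j)] = (float)(-gap * j); tr[IDX(0, j)] = 3; }
  for (int i = 1; i <= L1; ++i) { H[IDX(i, 0)] = (float)(-gap * i); tr[IDX(i, 0)] = 2; }
  for (int i = 1; i <= L1; ++i) {
    const double* fi = &f1[(size_t)(i - 1) * K];
    for (int j = 1; j <= L2; ++j) {
      const double* mj = &Mf2[(size_t)(j - 1) * K];
      double s = 0.0;
      for (int a = 0; a < K; ++a) s += fi[a] * mj[a];
      s /= denom;
      double diag = H[IDX(i - 1, j - 1)] + s;
      double up = H[IDX(i - 1, j)] - gap;
      double left = H[IDX(i, j - 1)] - gap;
      double h = diag; unsigned char src = 1;
      if (up > h) { h = up; src = 2; }
      if (left > h) { h = left; src = 3; }
      H[IDX(i, j)] = (float)h;
      tr[IDX(i, j)] = src;
    }
  }
  // traceback -> merged alignment
  std::vector<std::pair<int, int>> cols; // (col in p1 or 0, col in p2 or 0), 1-based
  int i = L1, j = L2;
  while (i > 0 || j > 0) {
    unsigned char src = tr[IDX(i, j)];
    if (src == 1) { cols.push_back({i, j}); --i; --j; }
    else if (src == 2) { cols.push_back({i, 0}); --i; }
    else { cols.push_back({0, j}); --j; }
  }
  std::reverse(cols.begin(), cols.end());
  const int L = (int)cols.size();
  CharacterVector out(n1 + n2);
  for (int r = 0; r < n1; ++r) {
    std::string s(L, '-');
    for (int c = 0; c < L; ++c) if (cols[c].first > 0) s[c] = p1[r][cols[c].first - 1];
    out[r] = s;
  }
  for (int r = 0; r < n2; ++r) {
    std::string s(L, '-');
    for (int c = 0; c < L; ++c) if (cols[c].second > 0) s[c] = p2[r][cols[c].second - 1];
    out[n1 + r] = s;
  }
  double score = H[IDX(L1, L2)];
#undef IDX
  return List::create(_["alignment"] = out, _["score"] = score);
}
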