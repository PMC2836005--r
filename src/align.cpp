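#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh). A gap of length k costs
// gap_open + k * gap_extend (both passed as positive magnitudes).
// Traceback ties are broken diagonal > up > left.

static const float NEG = -1e30f;

struct AlnResult {
  double score;
  int q_start, q_end, t_start, t_end; // 1-based inclusive; 0 if empty
  std::string q_aln, t_aln;
  int n_match, n_cols;
};

static void encode(const std::string& s, const std::string& alphabet,
                   std::vector<int>& out, const char* what) {
  int map[256];
  for (int i = 0; i < 256; ++i) map[i] = -1;
  for (size_t i = 0; i < alphabet.size(); ++i)
    map[(unsigned char)alphabet[i]] = (int)i;
  out.resize(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int c = map[(unsigned char)s[i]];
    if (c < 0) stop("unknown residue '%c' in %s (position %d)", s[i], what, (int)i + 1);
    out[i] = c;
  }
}

static AlnResult gotoh(const std::string& q, const std::string& t,
                       const std::string& alphabet, const NumericMatrix& submat,
                       double gap_open, double gap_ext, bool local) {
  std::vector<int> qe, te;
  encode(q, alphabet, qe, "query");
  encode(t, alphabet, te, "target");
  const int n = (int)qe.size(), m = (int)te.size();
  const int K = (int)alphabet.size();
  if (submat.nrow() != K || submat.ncol() != K)
    stop("substitution matrix must be %d x %d", K, K);
  if ((double)(n + 1) * (double)(m + 1) > 4e8)
    stop("alignment problem too large (%d x %d)", n, m);

  const double go = gap_open, ge = gap_ext;

  std::vector<float> H((size_t)(n + 1) * (m + 1), NEG),
      E((size_t)(n + 1) * (m + 1), NEG), F((size_t)(n + 1) * (m + 1), NEG);
  // trace flags per cell: bits 0-1 H source (0 stop/origin, 1 diag, 2 F(up), 3 E(left));
  // bit 2: E came from E (extend); bit 3: F came from F (extend)
  std::vector<unsigned char> tr((size_t)(n + 1) * (m + 1), 0);

#define IDX(i, j) ((size_t)(i) * (m + 1) + (j))

  H[IDX(0, 0)] = 0.0f;
  for (int j = 1; j <= m; ++j) {
    if (local) { H[IDX(0, j)] = 0.0f; }
    else {
      E[IDX(0, j)] = (float)(-(go + j * ge));
      H[IDX(0, j)] = E[IDX(0, j)];
      tr[IDX(0, j)] = 3 | (j > 1 ? 4 : 0);
    }
  }
  for (int i = 1; i <= n; ++i) {
    if (local) { H[IDX(i, 0)] = 0.0f; }
    else {
      F[IDX(i, 0)] = (float)(-(go + i * ge));
      H[IDX(i, 0)] = F[IDX(i, 0)];
      tr[IDX(i, 0)] = 2 | (i > 1 ? 8 : 0);
    }
  }

  // flat substitution matrix for fast row access
  const int K2 = K;
  std::vector<float> sub((size_t)K2 * K2);
  for (int a = 0; a < K2; ++a)
    for (int b = 0; b < K2; ++b) sub[(size_t)a * K2 + b] = (float)submat(a, b);

  double best = local ? 0.0 : NEG;
  int bi = 0, bj = 0;
  const float open = (float)(go + ge), ext = (float)ge;
  for (int i = 1; i <= n; ++i) {
    const float* srow = &sub[(size_t)qe[i - 1] * K2];
    float* Hc = &H[(size_t)i * (m + 1)];
    float* Ec = &E[(size_t)i * (m + 1)];
    float* Fc = &F[(size_t)i * (m + 1)];
    const float* Hp = &H[(size_t)(i - 1) * (m + 1)];
    const float* Fp = &F[(size_t)(i - 1) * (m + 1)];
    unsigned char* tc = &tr[(size_t)i * (m + 1)];
    for (int j = 1; j <= m; ++j) {
      unsigned char fl = 0;
      // E: gap consuming target (left)
      float e = Hc[j - 1] - open;
      float e_ext = Ec[j - 1] - ext;
      if (e_ext > e) { e = e_ext; fl |= 4; }
      Ec[j] = e;
      // F: gap consuming query (up)
      float f = Hp[j] - open;
      float f_ext = Fp[j] - ext;
      if (f_ext > f) { f = f_ext; fl |= 8; }
      Fc[j] = f;
      // H
      float h = Hp[j - 1] + srow[te[j - 1]];
      unsigned char src = 1;
      if (f > h) { h = f; src = 2; }
      if (e > h) { h = e; src = 3; }
      if (local && h < 0.0f) { h = 0.0f; src = 0; }
      Hc[j] = h;
      tc[j] = fl | src;
      if (local && h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (!local) { best = H[IDX(n, m)]; bi = n; bj = m; }

  AlnResult res;
  res.score = best;
  res.n_match = 0; res.n_cols = 0;
  if (local && best <= 0.0) {
    res.q_start = res.q_end = res.t_start = res.t_end = 0;
    res.score = 0.0;
    return res;
  }
  // traceback
  std::string qa, ta;
  int i = bi, j = bj;
  int state = 0; // 0 in H, 1 in E, 2 in F
  while (i > 0 || j > 0) {
    unsigned char fl = tr[IDX(i, j)];
    if (state == 0) {
      unsigned char src = fl & 3;
      if (src == 0) break; // local origin
      if (src == 1) {
        qa.push_back(q[i - 1]); ta.push_back(t[j - 1]);
        if (qe[i - 1] == te[j - 1]) res.n_match++;
        --i; --j;
      } else if (src == 2) state = 2;
      else state = 1;
    } else if (state == 1) { // E: gap in query, consume target
      qa.push_back('-'); ta.push_back(t[j - 1]);
      bool ext = (fl & 4) != 0;
      --j;
      if (!ext) state = 0;
    } else { // F: gap in target, consume query
      qa.push_back(q[i - 1]); ta.push_back('-');
      bool ext = (fl & 8) != 0;
      --i;
      if (!ext) state = 0;
    }
    if (local && i >= 0 && j >= 0 && state == 0 && H[IDX(i, j)] == 0.0f &&
        (tr[IDX(i, j)] & 3) == 0)
      break;
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(ta.begin(), ta.end());
  res.q_aln = qa; res.t_aln = ta;
  res.n_cols = (int)qa.size();
  res.q_start = i + 1; res.q_end = bi;
  res.t_start = j + 1; res.t_end = bj;
  if (qa.empty()) { res.q_start = res.t_start = 0; res.q_end = res.t_end = 0; }
  return res;
#undef IDX
}

static List as_list(const AlnResult& r) {
  return List::create(
      _["score"] = r.score, _["q_start"] = r.q_start, _["q_end"] = r.q_end,
      _["t_start"] = r.t_start, _["t_end"] = r.t_end, _["q_aln"] = r.q_aln,
      _["t_aln"] = r.t_aln, _["n_match"] = r.n_match, _["n_cols"] = r.n_cols);
}

// [[Rcpp::export]]
List cpp_align(std::string q, std::string t, std::string alphabet,
               NumericMatrix submat, double gap_open, double gap_ext,
               bool local) {
  return as_list(gotoh(q, t, alphabet, submat, gap_open, gap_ext, local));
}

// [[Rcpp::export]]
DataFrame cpp_align_many(CharacterVector qs, std::string t, std::string alphabet,
                         NumericMatrix submat, double gap_open, double gap_ext,
                         bool local) {
  int n = qs.size();
  NumericVector score(n);
  IntegerVector qs1(n), qe1(n), ts1(n), te1(n), nm(n), nc(n);
  for (int k = 0; k < n; ++k) {
    AlnResult r = gotoh(as<std::string>(qs[k]), t, alphabet, submat, gap_open,
                        gap_ext, local);
    score[k] = r.score; qs1[k] = r.q_start; qe1[k] = r.q_end;
    ts1[k] = r.t_start; te1[k] = r.t_end; nm[k] = r.n_match; nc[k] = r.n_cols;
  }
  return DataFrame::create(_["score"] = score, _["q_start"] = qs1,
                           _["q_end"] = qe1, _["t_start"] = ts1,
                           _["t_end"] = te1, _["n_match"] = nm,
                           _["n_cols"] = nc);
}
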