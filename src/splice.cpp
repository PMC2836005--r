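#include <Rcpp.h>
using namespace Rcpp;

// Spliced alignment of a genomic region against a homologous protein.
// Exons are consumed codon-by-codon and scored against the protein with a
// substitution matrix; introns may open between any two exon nucleotides
// (any phase) provided they start with a donor (GT; GC when noncanonical
// splice sites are allowed) and end with an acceptor (AG; TG for GT-TG
// introns when allowed) and are at least min_intron long. The alignment is
// global in the protein and local in the genome.
//
// DP state: (i = genomic nucleotides processed, j = protein residues
// matched, st = partial-codon content). st encodes 0 empty, 1..5 one stored
// base (A,C,G,T,other), 6..30 two stored bases.

static const float NEG = -1e30f;
static const int NST = 31;

// [[Rcpp::export]]
List cpp_spliced_align(std::string dna, std::string protein,
                       std::string alphabet, NumericMatrix submat,
                       IntegerVector codon2aa, double gap_protein,
                       double gap_codon, double stop_penalty,
                       double intron_penalty, int min_intron,
                       bool allow_noncanonical) {
  const int n = (int)dna.size();
  const int K = (int)alphabet.size();
  int amap[256];
  for (int i = 0; i < 256; ++i) amap[i] = -1;
  for (int i = 0; i < K; ++i) amap[(unsigned char)alphabet[i]] = i;
  std::vector<int> prot(protein.size());
  for (size_t i = 0; i < protein.size(); ++i) {
    int c = amap[(unsigned char)protein[i]];
    if (c < 0) stop("unknown residue '%c' in protein", protein[i]);
    prot[i] = c;
  }
  const int m = (int)prot.size();
  if (m == 0) stop("empty protein");
  if (codon2aa.size() != 125) stop("codon table must have 125 entries");
  int star = -1;
  for (int i = 0; i < K; ++i) if (alphabet[i] == '*') star = i;

  std::vector<int> nt(n);
  for (int i = 0; i < n; ++i) {
    switch (dna[i]) {
      case 'A': nt[i] = 0; break;
      case 'C': nt[i] = 1; break;
      case 'G': nt[i] = 2; break;
      case 'T': nt[i] = 3; break;
      default: nt[i] = 4;
    }
  }
  const size_t slab = (size_t)(m + 1) * NST;
  const size_t total = (size_t)(n + 1) * slab;
  if (total * 5 > 2e9) stop("spliced-alignment problem too large (%d nt x %d aa)", n, m);

  std::vector<float> S(total, NEG);
  std::vector<unsigned char> par(total, 0);
  if (min_intron < 4) min_intron = 4;
  std::vector<float> ring((size_t)min_intron * 2 * slab, NEG);
  std::vector<char> ring_has((size_t)min_intron * 2, 0);
  std::vector<float> pend(2 * slab, NEG);

#define SI(i, j, st) ((size_t)(i) * slab + (size_t)(j) * NST + (st))

  auto donor_ch = [&](int pos) -> int {
    // intron starting at pos: dinucleotide dna[pos], dna[pos+1]
    if (pos + 1 >= n) return -1;
    if (nt[pos] == 2 && nt[pos + 1] == 3) return 0;                      // GT
    if (allow_noncanonical && nt[pos] == 2 && nt[pos + 1] == 1) return 1; // GC
    return -1;
  };

  for (int i = 0; i <= n; ++i) {
    // (a) make donor contributions from position i - min_intron available
    int a = i - min_intron;
    if (a >= 0) {
      int slot = a % min_intron;
      for (int ch = 0; ch < 2; ++ch) {
        if (!ring_has[(size_t)slot * 2 + ch]) continue;
        float* rp = &ring[((size_t)slot * 2 + ch) * slab];
        float* pp = &pend[(size_t)ch * slab];
        for (size_t k = 0; k < slab; ++k)
          if (rp[k] > pp[k]) pp[k] = rp[k];
      }
    }
    // (b) acceptor landing: intron ends at i-1 with dna[i-2], dna[i-1]
    if (i >= 2) {
      bool ag = (nt[i - 2] == 0 && nt[i - 1] == 2);
      bool tg = allow_noncanonical && (nt[i - 2] == 3 && nt[i - 1] == 2);
      if (ag || tg) {
        for (int ch = 0; ch < 2; ++ch) {
          if (ch == 1 && !ag) continue; // GC donor pairs only with AG
          if (ch == 1 && !allow_noncanonical) continue;
          float* pp = &pend[(size_t)ch * slab];
          for (size_t k = 0; k < slab; ++k) {
            if (pp[k] > S[(size_t)i * slab + k]) {
              S[(size_t)i * slab + k] = pp[k];
              par[(size_t)i * slab + k] = (unsigned char)(5 + ch);
            }
          }
        }
      }
    }
    // (c) free start
    if (S[SI(i, 0, 0)] < 0.0f) { S[SI(i, 0, 0)] = 0.0f; par[SI(i, 0, 0)] = 1; }
    // (d) protein deletions
    for (int j = 1; j <= m; ++j) {
      float v = S[SI(i, j - 1, 0)];
      if (v > NEG / 2 && v - (float)gap_protein > S[SI(i, j, 0)]) {
        S[SI(i, j, 0)] = v - (float)gap_protein;
        par[SI(i, j, 0)] = 4;
      }
    }
    // (e) record donor contributions opening at position i
    {
      int ch = donor_ch(i);
      int slot = i % min_intron;
      ring_has[(size_t)slot * 2 + 0] = 0;
      ring_has[(size_t)slot * 2 + 1] = 0;
      if (ch >= 0) {
        float* rp = &ring[((size_t)slot * 2 + ch) * slab];
        const float* sp = &S[(size_t)i * slab];
        for (size_t k = 0; k < slab; ++k)
          rp[k] = (sp[k] > NEG / 2) ? sp[k] - (float)intron_penalty : NEG;
        ring_has[(size_t)slot * 2 + ch] = 1;
      }
    }
    // (f) consume nucleotide i
    if (i < n) {
      int c = nt[i];
      for (int j = 0; j <= m; ++j) {
        const float* sp = &S[SI(i, j, 0)];
        // empty -> one base
        if (sp[0] > NEG / 2) {
          int st2 = 1 + c;
          if (sp[0] > S[SI(i + 1, j, st2)]) {
            S[SI(i + 1, j, st2)] = sp[0];
            par[SI(i + 1, j, st2)] = 2;
          }
        }
        // one base -> two bases
        for (int b = 0; b < 5; ++b) {
          float v = sp[1 + b];
          if (v <= NEG / 2) continue;
          int st2 = 6 + 5 * b + c;
          if (v > S[SI(i + 1, j, st2)]) {
            S[SI(i + 1, j, st2)] = v;
            par[SI(i + 1, j, st2)] = 2;
          }
        }
        // two bases -> codon complete
        for (int st = 6; st < NST; ++st) {
          float v = sp[st];
          if (v <= NEG / 2) continue;
          int b1 = (st - 6) / 5, b2 = (st - 6) % 5;
          int aa = codon2aa[25 * b1 + 5 * b2 + c];
          // match to next protein residue
          if (j < m && aa >= 0) {
            float sc = v + (float)submat(aa, prot[j]);
            if (sc > S[SI(i + 1, j + 1, 0)]) {
              S[SI(i + 1, j + 1, 0)] = sc;
              par[SI(i + 1, j + 1, 0)] = (unsigned char)(10 + (st - 6));
            }
          }
          // unmatched codon (insertion in the genome)
          float pen = (aa == star) ? (float)stop_penalty : (float)gap_codon;
          float sc = v - pen;
          if (sc > S[SI(i + 1, j, 0)]) {
            S[SI(i + 1, j, 0)] = sc;
            par[SI(i + 1, j, 0)] = (unsigned char)(40 + (st - 6));
          }
        }
      }
    }
  }

  // best end: all protein matched, no partial codon
  double best = NEG; int bi = -1;
  for (int i = 0; i <= n; ++i) {
    float v = S[SI(i, m, 0)];
    if (v > best) { best = v; bi = i; }
  }
  if (bi < 0 || best <= NEG / 2)
    return List::create(_["score"] = R_NegInf);

  // traceback
  std::vector<int> consumed;            // genomic nt positions in exons
  std::vector<std::pair<int, int>> introns; // [a, b] inclusive
  int i = bi, j = m, st = 0;
  while (true) {
    unsigned char p = par[SI(i, j, st)];
    if (p == 1 && j == 0 && st == 0) break;
    if (p == 0) break;
    if (p == 2) {
      consumed.push_back(i - 1);
      if (st >= 6) st = 1 + (st - 6) / 5;
      else st = 0;
      --i;
    } else if (p >= 10 && p < 40) {
      consumed.push_back(i - 1);
      st = 6 + (p - 10);
      --i; --j;
    } else if (p >= 40) {
      consumed.push_back(i - 1);
      st = 6 + (p - 40);
      --i;
    } else if (p == 4) {
      --j;
    } else if (p == 5 || p == 6) {
      int ch = p - 5;
      float target = S[SI(i, j, st)];
      int found = -1;
      for (int a2 = i - min_intron; a2 >= 0; --a2) {
        if (donor_ch(a2) != ch) continue;
        float v = S[SI(a2, j, st)];
        if (v > NEG / 2 && std::fabs((v - (float)intron_penalty) - target) < 1e-3) {
          found = a2; break;
        }
      }
      if (found < 0) stop("internal error: intron donor not recovered");
      introns.push_back({found, i - 1});
      i = found;
    } else {
      break;
    }
  }
  std::reverse(consumed.begin(), consumed.end());
  std::reverse(introns.begin(), introns.end());

  // exons = maximal contiguous runs of consumed positions
  std::vector<std::pair<int, int>> exons; // 0-based half-open
  for (size_t k = 0; k < consumed.size(); ++k) {
    if (k == 0 || consumed[k] != consumed[k - 1] + 1)
      exons.push_back({consumed[k], consumed[k] + 1});
    else
      exons.back().second = consumed[k] + 1;
  }
  IntegerMatrix ex(exons.size(), 2), in(introns.size(), 2);
  for (size_t k = 0; k < exons.size(); ++k) {
    ex(k, 0) = exons[k].first; ex(k, 1) = exons[k].second;
  }
  for (size_t k = 0; k < introns.size(); ++k) {
    in(k, 0) = introns[k].first; in(k, 1) = introns[k].second + 1; // half-open
  }
  return List::create(_["score"] = best, _["exons"] = ex, _["introns"] = in);
}
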