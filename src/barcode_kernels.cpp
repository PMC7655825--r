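#include <Rcpp.h>
using namespace Rcpp;

// Watson-Crick pair weight: A-T = 2/3, C-G = 1, N pairs with anything at 2/3
// (conservative worst case at the weaker affinity), otherwise 0.
// Pair-weight lookup over raw characters: A-T = 2/3, C-G = 1, N pairs with
// anything at 2/3 (conservative worst case at the weaker affinity).
static double WEIGHT[256][256];
static bool weight_ready = false;

static void init_weights() {
  if (weight_ready) return;
  for (int a = 0; a < 256; ++a)
    for (int b = 0; b < 256; ++b) WEIGHT[a][b] = 0.0;
  const unsigned char A = 'A', C = 'C', G = 'G', T = 'T', N = 'N';
  WEIGHT[A][T] = WEIGHT[T][A] = 2.0 / 3.0;
  WEIGHT[C][G] = WEIGHT[G][C] = 1.0;
  const unsigned char all[5] = {A, C, G, T, N};
  for (int k = 0; k < 5; ++k) {
    WEIGHT[N][all[k]] = WEIGHT[all[k]][N] = 2.0 / 3.0;
  }
  weight_ready = true;
}

// Max weighted length of a contiguous self-complementary stretch: the oligo
// is aligned antiparallel against itself at every offset (every anti-diagonal
// i + j = c); a stretch is a maximal run of consecutive complementary pairs
// along one diagonal and its score is the sum of per-pair weights.
static double selfdimer_score_one(const char *s, int L) {
  init_weights();
  double best = 0.0;
  for (int c = 0; c <= 2 * L - 2; ++c) {
    int i0 = c - L + 1; if (i0 < 0) i0 = 0;
    int i1 = c; if (i1 > L - 1) i1 = L - 1;
    double run = 0.0;
    for (int i = i0; i <= i1; ++i) {
      double w = WEIGHT[(unsigned char)s[i]][(unsigned char)s[c - i]];
      if (w > 0.0) {
        run += w;
        if (run > best) best = run;
      } else {
        run = 0.0;
      }
    }
  }
  return best;
}

// [[Rcpp::export]]
NumericVector cpp_selfdimer_scores(CharacterVector oligos) {
  int n = oligos.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    const char *s = CHAR(STRING_ELT(oligos, k));
    out[k] = selfdimer_score_one(s, (int)LENGTH(STRING_ELT(oligos, k)));
  }
  return out;
}

// Plain Levenshtein distance between two short sequences.
static int lev(const std::string &a, const std::string &b) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      cur[j] = std::min(std::min(prev[j] + 1, cur[j - 1] + 1), sub);
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// TRUE iff `cand` is at Levenshtein distance >= min_dist from every accepted
// sequence (early exit on the first violation).
// [[Rcpp::export]]
bool cpp_lev_clear(std::string cand, CharacterVector accepted, int min_dist) {
  for (int k = 0; k < accepted.size(); ++k) {
    std::string a = as<std::string>(accepted[k]);
    if (lev(cand, a) < min_dist) return false;
  }
  return true;
}

// Minimum pairwise Levenshtein distance over a set of sequences.
// [[Rcpp::export]]
int cpp_lev_pairwise_min(CharacterVector seqs) {
  int n = seqs.size();
  if (n < 2) return NA_INTEGER;
  int best = INT_MAX;
  std::vector<std::string> v(n);
  for (int i = 0; i < n; ++i) v[i] = as<std::string>(seqs[i]);
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      int d = lev(v[i], v[j]);
      if (d < best) best = d;
    }
  return best;
}
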