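#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch / Gotoh) alignment with an affine gap model.
// Gap run of length L costs gap_open + (L-1) * gap_extend, so a linear model
// (gap_open == gap_extend) charges L * gap_extend exactly.
// Traceback tie-break: diagonal (match/mismatch) > deletion (gap in b)
// > insertion (gap in a), making the returned alignment deterministic.

static const double NEG_INF = -1e18;

// [[Rcpp::export(name = ".align_global_cpp")]]
List align_global_cpp(std::string a, std::string b,
                      double match, double mismatch,
                      double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  // state matrices: M diag, X gap-in-b (consumes a, deletion),
  // Y gap-in-a (consumes b, insertion)
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) X[at(i, 0)] = gap_open + (i - 1) * gap_extend;
  for (int j = 1; j <= m; ++j) Y[at(0, j)] = gap_open + (j - 1) * gap_extend;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double dM = M[at(i - 1, j - 1)], dX = X[at(i - 1, j - 1)],
             dY = Y[at(i - 1, j - 1)];
      M[at(i, j)] = std::max(dM, std::max(dX, dY)) + s;

      double xo = std::max(M[at(i - 1, j)], Y[at(i - 1, j)]) + gap_open;
      double xe = X[at(i - 1, j)] + gap_extend;
      X[at(i, j)] = std::max(xo, xe);

      double yo = std::max(M[at(i, j - 1)], X[at(i, j - 1)]) + gap_open;
      double ye = Y[at(i, j - 1)] + gap_extend;
      Y[at(i, j)] = std::max(yo, ye);
    }
  }

  double best = std::max(M[at(n, m)], std::max(X[at(n, m)], Y[at(n, m)]));

  // traceback; state 0 = M, 1 = X, 2 = Y, preference M > X > Y throughout
  std::string ga, gb;
  int i = n, j = m;
  int state;
  if (M[at(n, m)] == best) state = 0;
  else if (X[at(n, m)] == best) state = 1;
  else state = 2;

  while (i > 0 || j > 0) {
    if (state == 0) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double need = M[at(i, j)] - s;
      ga += a[i - 1]; gb += b[j - 1];
      --i; --j;
      if (i == 0 && j == 0) break;
      if (M[at(i, j)] == need) state = 0;
      else if (X[at(i, j)] == need) state = 1;
      else state = 2;
    } else if (state == 1) {
      ga += a[i - 1]; gb += '-';
      double cur = X[at(i, j)];
      --i;
      if (M[at(i, j)] + gap_open == cur) state = 0;
      else if (X[at(i, j)] + gap_extend == cur) state = 1;
      else state = 2;
    } else {
      ga += '-'; gb += b[j - 1];
      double cur = Y[at(i, j)];
      --j;
      if (M[at(i, j)] + gap_open == cur) state = 0;
      else if (X[at(i, j)] + gap_open == cur) state = 1;
      else state = 2;
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  return List::create(_["aligned_a"] = ga, _["aligned_b"] = gb,
                      _["score"] = best);
}

static inline int base_index(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// PSAM sliding-window scan: product of per-position weights over each window,
// forward strand and the reverse complement of each window. weights is k x 4
// (columns A, C, G, T). Returns fwd/rev vectors of length L - k + 1.
// [[Rcpp::export(name = ".psam_scan_cpp")]]
List psam_scan_cpp(std::string seq, NumericMatrix weights) {
  const int L = seq.size(), k = weights.nrow();
  const int nw = L - k + 1;
  if (nw <= 0)
    return List::create(_["fwd"] = NumericVector(0), _["rev"] = NumericVector(0));
  std::vector<int> idx(L);
  for (int i = 0; i < L; ++i) {
    idx[i] = base_index(seq[i]);
    if (idx[i] < 0) stop("invalid base in sequence at position %d", i + 1);
  }
  NumericVector fwd(nw), rev(nw);
  for (int s = 0; s < nw; ++s) {
    double f = 1.0, r = 1.0;
    for (int p = 0; p < k; ++p) {
      f *= weights(p, idx[s + p]);
      // reverse complement of the window read 3'->5'
      r *= weights(p, 3 - idx[s + k - 1 - p]);
    }
    fwd[s] = f; rev[s] = r;
  }
  return List::create(_["fwd"] = fwd, _["rev"] = rev);
}

// Batch raw affinity of many equal-length k-mers encoded as an n x k integer
// matrix (0=A,1=C,2=G,3=T); used by the random-k-mer normalizer.
// [[Rcpp::export(name = ".psam_score_kmers_cpp")]]
NumericVector psam_score_kmers_cpp(IntegerMatrix kmers, NumericMatrix weights) {
  const int n = kmers.nrow(), k = weights.nrow();
  if (kmers.ncol() != k) stop("k-mer width does not match motif width");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double f = 1.0;
    for (int p = 0; p < k; ++p) f *= weights(p, kmers(i, p));
    out[i] = f;
  }
  return out;
}
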