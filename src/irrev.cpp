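#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Two-sample Kolmogorov-Smirnov: statistic D and asymptotic p-value
// (Kolmogorov distribution evaluated at sqrt(n_e) * D, n_e = nx*ny/(nx+ny)).
// [[Rcpp::export]]
NumericVector cpp_ks2(NumericVector x, NumericVector y) {
  std::vector<double> a(x.begin(), x.end()), b(y.begin(), y.end());
  std::sort(a.begin(), a.end());
  std::sort(b.begin(), b.end());
  const size_t nx = a.size(), ny = b.size();
  size_t i = 0, j = 0;
  double d = 0.0;
  while (i < nx && j < ny) {
    double v = std::min(a[i], b[j]);
    while (i < nx && a[i] <= v) ++i;
    while (j < ny && b[j] <= v) ++j;
    double diff = std::fabs((double)i / nx - (double)j / ny);
    if (diff > d) d = diff;
  }
  double ne = (double)nx * ny / (nx + ny);
  double t = std::sqrt(ne) * d;
  // Kolmogorov tail: p = 2 * sum_{k>=1} (-1)^{k-1} exp(-2 k^2 t^2)
  double p;
  if (t < 0.2) {
    p = 1.0;
  } else {
    p = 0.0;
    for (int k = 1; k <= 101; ++k) {
      double term = 2.0 * std::pow(-1.0, k - 1) * std::exp(-2.0 * k * k * t * t);
      p += term;
      if (std::fabs(term) < 1e-12) break;
    }
    if (p < 0) p = 0;
    if (p > 1) p = 1;
  }
  return NumericVector::create(_["D"] = d, _["p"] = p);
}

// BDS building blocks: correlation integrals C_1 and C_m (sup norm over
// m-dimensional delay vectors, pairs i<j among the n-m+1 vectors) and the
// triple-count K, all with the indicator |.| <= eps.
// [[Rcpp::export]]
List cpp_bds_integrals(NumericVector x, int m, double eps) {
  const int n = x.size();
  const int M = n - m + 1;  // number of embedded vectors
  if (M < 3) stop("series too short for embedding dimension m");
  std::vector<long long> r(M, 0);  // per-vector neighbour counts at dim 1
  long long c1 = 0, cm = 0;
  for (int i = 0; i < M; ++i) {
    for (int j = i + 1; j < M; ++j) {
      bool within1 = std::fabs(x[i] - x[j]) <= eps;
      if (within1) {
        ++c1;
        ++r[i];
        ++r[j];
      }
      // sup-norm over the m components
      bool withinm = within1;
      if (within1 && m > 1) {
        for (int l = 1; l < m; ++l) {
          if (std::fabs(x[i + l] - x[j + l]) > eps) { withinm = false; break; }
        }
      }
      if (withinm) ++cm;
    }
  }
  const double pairs = (double)M * (M - 1) / 2.0;
  double C1 = c1 / pairs;
  double Cm = cm / pairs;
  long double ksum = 0.0;
  for (int i = 0; i < M; ++i) ksum += (long double)r[i] * (r[i] - 1);
  double K = (double)(ksum / ((long double)M * (M - 1) * (M - 2)));
  return List::create(_["C1"] = C1, _["Cm"] = Cm, _["K"] = K, _["M"] = M);
}

// Kernel two-sample U-statistic between the delay-vector cloud of a series
// and its time-reversed counterpart, with a sign-flip randomisation null.
// Rows of X are the forward delay vectors a_i; the reversed cloud holds
// b_i = reverse(a_i). Gaussian kernel K(u) = exp(-|u|^2 / (2 h^2)). Because
// |a_i - a_j| = |b_i - b_j| exactly, the symmetric pair kernel reduces to
//   h_ij = 2 A_ij - B_ij - C_ij
// with A_ij = K(a_i,a_j), B_ij = K(a_i,b_j), C_ij = K(a_j,b_i).
//
// Under reversibility each pair (a_i, b_i) is exchangeable, so the null is
// sampled by swapping a_i <-> b_i with independent fair coin flips eps_i:
//   both or neither swapped: h'_ij = 2A - B - C
//   only i swapped:          h'_ij = 2C - 2A
//   only j swapped:          h'_ij = 2B - 2A
// (the kernel U-statistic is degenerate under the null, so the usual normal
// approximation is invalid; the randomisation null is exact). Returns the
// observed Q and the B randomised replicates. Uses R's RNG.
// [[Rcpp::export]]
List cpp_diks(NumericMatrix X, double h, int B) {
  const int M = X.nrow(), m = X.ncol();
  if (M < 4) stop("too few delay vectors");
  const double inv2h2 = 1.0 / (2.0 * h * h);
  std::vector<double> A((size_t)M * M), Bm((size_t)M * M), Cm((size_t)M * M);
  long double total = 0.0;
  for (int i = 0; i < M; ++i) {
    for (int j = i + 1; j < M; ++j) {
      double daa = 0.0, dab = 0.0, dba = 0.0;
      for (int l = 0; l < m; ++l) {
        double u = X(i, l) - X(j, l);
        daa += u * u;
        double v = X(i, l) - X(j, m - 1 - l);  // a_i vs b_j
        dab += v * v;
        double w = X(j, l) - X(i, m - 1 - l);  // a_j vs b_i
        dba += w * w;
      }
      const size_t idx = (size_t)i * M + j;
      A[idx] = std::exp(-daa * inv2h2);
      Bm[idx] = std::exp(-dab * inv2h2);
      Cm[idx] = std::exp(-dba * inv2h2);
      total += 2.0 * A[idx] - Bm[idx] - Cm[idx];
    }
  }
  const double pairs = (double)M * (M - 1) / 2.0;
  double Q = (double)(total / pairs);
  NumericVector Qnull(B);
  GetRNGstate();
  std::vector<int> eps(M);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < M; ++i) eps[i] = (unif_rand() < 0.5) ? 1 : 0;
    long double tb = 0.0;
    for (int i = 0; i < M; ++i) {
      for (int j = i + 1; j < M; ++j) {
        const size_t idx = (size_t)i * M + j;
        if (eps[i] == eps[j]) {
          tb += 2.0 * A[idx] - Bm[idx] - Cm[idx];
        } else if (eps[i]) {
          tb += 2.0 * Cm[idx] - 2.0 * A[idx];
        } else {
          tb += 2.0 * Bm[idx] - 2.0 * A[idx];
        }
      }
    }
    Qnull[b] = (double)(tb / pairs);
  }
  PutRNGstate();
  return List::create(_["Q"] = Q, _["Qnull"] = Qnull, _["M"] = M);
}
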