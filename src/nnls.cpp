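#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Solve the symmetric positive (semi-)definite system A z = b restricted to
// the index set P, by Gaussian elimination with partial pivoting.  A tiny
// ridge is added if a pivot collapses (duplicate design columns in an
// under-determined passive set).  Returns false only if the system is
// irrecoverably singular.
static bool solveSubset(const std::vector<double>& A,
                        const std::vector<double>& b, int n,
                        const std::vector<int>& P, std::vector<double>& z) {
  int np = (int)P.size();
  std::vector<double> M(np * np), r(np);
  for (int ridgePass = 0; ridgePass < 2; ++ridgePass) {
    double ridge = ridgePass == 0 ? 0.0 : 1e-10;
    for (int i = 0; i < np; ++i) {
      r[i] = b[P[i]];
      for (int j = 0; j < np; ++j)
        M[i + j * np] = A[P[i] + P[j] * n] + (i == j ? ridge : 0.0);
    }
    bool ok = true;
    for (int col = 0; col < np && ok; ++col) {
      int piv = col;
      double best = std::fabs(M[col + col * np]);
      for (int i = col + 1; i < np; ++i) {
        double v = std::fabs(M[i + col * np]);
        if (v > best) { best = v; piv = i; }
      }
      if (best < 1e-12) { ok = false; break; }
      if (piv != col) {
        for (int j = 0; j < np; ++j) std::swap(M[col + j * np], M[piv + j * np]);
        std::swap(r[col], r[piv]);
      }
      for (int i = col + 1; i < np; ++i) {
        double f = M[i + col * np] / M[col + col * np];
        if (f == 0.0) continue;
        for (int j = col; j < np; ++j) M[i + j * np] -= f * M[col + j * np];
        r[i] -= f * r[col];
      }
    }
    if (!ok) continue;
    z.assign(np, 0.0);
    for (int i = np - 1; i >= 0; --i) {
      double s = r[i];
      for (int j = i + 1; j < np; ++j) s -= M[i + j * np] * z[j];
      z[i] = s / M[i + i * np];
    }
    return true;
  }
  return false;
}

// Lawson-Hanson active-set non-negative least squares on the normal
// equations: minimizes ||y - X g||^2 subject to g >= 0.  Design matrices
// here are small (tree-branch indicator systems), so normal equations with
// dense elimination are accurate and fast.
// [[Rcpp::export(name = ".nnlsCpp")]]
List nnlsCpp(NumericMatrix X, NumericVector y, int maxIter = 0) {
  int m = X.nrow(), n = X.ncol();
  if (y.size() != m) stop("dimension mismatch between X and y");
  if (maxIter <= 0) maxIter = 30 * (n + 1);

  std::vector<double> A(n * n, 0.0), b(n, 0.0);
  double yty = 0.0;
  for (int i = 0; i < m; ++i) yty += y[i] * y[i];
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < m; ++i) b[j] += X(i, j) * y[i];
    for (int k = j; k < n; ++k) {
      double s = 0.0;
      for (int i = 0; i < m; ++i) s += X(i, j) * X(i, k);
      A[j + k * n] = A[k + j * n] = s;
    }
  }
  double bmax = 0.0;
  for (int j = 0; j < n; ++j) bmax = std::max(bmax, std::fabs(b[j]));
  double tol = 1e-10 * (1.0 + bmax);

  std::vector<double> g(n, 0.0), w(n), z;
  std::vector<bool> inP(n, false);
  std::vector<int> P;
  int iter = 0;

  while (true) {
    // gradient of 0.5*||y - Xg||^2 is A g - b; w = b - A g
    int jbest = -1;
    double wbest = tol;
    for (int j = 0; j < n; ++j) {
      if (inP[j]) continue;
      double wj = b[j];
      for (int k = 0; k < n; ++k) wj -= A[j + k * n] * g[k];
      if (wj > wbest) { wbest = wj; jbest = j; }
    }
    if (jbest < 0) break;
    inP[jbest] = true;
    P.push_back(jbest);

    while (true) {
      if (++iter > maxIter)
        stop("NNLS failed to converge within %d iterations", maxIter);
      if (!solveSubset(A, b, n, P, z))
        stop("NNLS passive-set system is singular");
      bool allPos = true;
      for (size_t i = 0; i < P.size(); ++i)
        if (z[i] <= 0.0) { allPos = false; break; }
      if (allPos) {
        for (int j = 0; j < n; ++j) g[j] = 0.0;
        for (size_t i = 0; i < P.size(); ++i) g[P[i]] = z[i];
        break;
      }
      double alpha = 1.0;
      for (size_t i = 0; i < P.size(); ++i) {
        if (z[i] <= 0.0) {
          double gi = g[P[i]];
          double a = gi / (gi - z[i]);
          if (a < alpha) alpha = a;
        }
      }
      for (size_t i = 0; i < P.size(); ++i)
        g[P[i]] += alpha * (z[i] - g[P[i]]);
      std::vector<int> Pnew;
      for (size_t i = 0; i < P.size(); ++i) {
        if (g[P[i]] > 1e-14) Pnew.push_back(P[i]);
        else { g[P[i]] = 0.0; inP[P[i]] = false; }
      }
      P.swap(Pnew);
      if (P.empty()) break;
    }
  }

  // residual sum of squares: ||y||^2 - 2 g'b + g'A g
  double quad = 0.0, lin = 0.0;
  for (int j = 0; j < n; ++j) {
    lin += g[j] * b[j];
    double s = 0.0;
    for (int k = 0; k < n; ++k) s += A[j + k * n] * g[k];
    quad += g[j] * s;
  }
  double rss = yty - 2.0 * lin + quad;
  if (rss < 0.0) rss = 0.0;

  return List::create(_["gamma"] = NumericVector(g.begin(), g.end()),
                      _["rss"] = rss, _["iterations"] = iter);
}
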