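#include <Rcpp.h>
using namespace Rcpp;

// Gaussian kernel CDF estimate per column across samples.
// F(x_ij) = (1/n) * sum_l Phi((x_ij - x_lj) / h_j), h_j = sd_j / 4 (n-1 denom).
// Uses the antisymmetry Phi(d) + Phi(-d) = 1 to halve the pnorm calls.
// [[Rcpp::export]]
NumericMatrix cpp_gauss_kcdf(NumericMatrix X) {
  const int n = X.nrow(), m = X.ncol();
  NumericMatrix out(n, m);
  for (int j = 0; j < m; ++j) {
    double mean = 0.0;
    for (int i = 0; i < n; ++i) mean += X(i, j);
    mean /= n;
    double ss = 0.0;
    for (int i = 0; i < n; ++i) {
      const double d = X(i, j) - mean;
      ss += d * d;
    }
    const double sdj = std::sqrt(ss / (n - 1));
    if (!(sdj > 0.0))
      stop("zero-variance metabolite at column %d: kernel bandwidth is 0", j + 1);
    const double h = sdj / 4.0;
    std::vector<double> acc(n, 0.5); // diagonal term Phi(0) = 0.5 for each i
    for (int i = 0; i < n; ++i) {
      for (int l = i + 1; l < n; ++l) {
        const double p = R::pnorm((X(i, j) - X(l, j)) / h, 0.0, 1.0, 1, 0);
        acc[i] += p;
        acc[l] += 1.0 - p;
      }
    }
    for (int i = 0; i < n; ++i) out(i, j) = acc[i] / n;
  }
  return out;
}

// Weighted Kolmogorov-Smirnov-like random walk enrichment scores.
//
// ord: n x m integer matrix, ord(i, t) = 1-based column index of the
//      metabolite at walk position t for sample i (walk order, typically by
//      decreasing abundance/statistic).
// w:   n x m non-negative weights aligned to original column indices; in-set
//      steps climb by w/sum(w in set), out-set steps fall by 1/(m - Mk).
// sets: list of 1-based integer index vectors (pathway member columns).
// mode: 0 = integrated running sum (ssGSEA convention),
//       1 = max positive deviation + min negative deviation (GSVA max-diff),
//       2 = signed maximum |deviation| (GSEA convention).
// If a sample's in-set weights sum to zero the in-set steps fall back to
// equal weights 1/Mk.
// [[Rcpp::export]]
NumericMatrix cpp_es_walk(IntegerMatrix ord, NumericMatrix w, List sets,
                          int mode) {
  const int n = ord.nrow(), m = ord.ncol();
  const int P = sets.size();
  NumericMatrix out(n, P);
  std::vector<char> member(m);
  for (int k = 0; k < P; ++k) {
    IntegerVector idx = sets[k];
    const int Mk = idx.size();
    if (Mk < 1) stop("empty pathway index set");
    if (Mk >= m)
      stop("pathway covers all metabolites: in-set and out-set walk undefined");
    std::fill(member.begin(), member.end(), 0);
    for (int a = 0; a < Mk; ++a) {
      const int j = idx[a] - 1;
      if (j < 0 || j >= m) stop("pathway member index out of range");
      member[j] = 1;
    }
    const double dec = 1.0 / (m - Mk);
    for (int i = 0; i < n; ++i) {
      double W = 0.0;
      for (int a = 0; a < Mk; ++a) W += w(i, idx[a] - 1);
      const bool flat = !(W > 0.0);
      double cum = 0.0, maxdev = 0.0, mindev = 0.0, integral = 0.0;
      for (int t = 0; t < m; ++t) {
        const int j = ord(i, t) - 1;
        if (member[j])
          cum += flat ? (1.0 / Mk) : (w(i, j) / W);
        else
          cum -= dec;
        if (cum > maxdev) maxdev = cum;
        if (cum < mindev) mindev = cum;
        integral += cum;
      }
      double es;
      if (mode == 0)      es = integral;
      else if (mode == 1) es = maxdev + mindev;
      else                es = (maxdev > -mindev) ? maxdev : mindev;
      out(i, k) = es;
    }
  }
  return out;
}

// Leading eigenpair of a symmetric PSD matrix by power iteration with a
// deterministic start vector. Convergence is declared when successive unit
// vectors agree to 1 - dot < tol. Returns value, vector, converged flag.
// [[Rcpp::export]]
List cpp_power_eig(NumericMatrix K, double tol, int max_iter) {
  const int n = K.nrow();
  std::vector<double> v(n), w(n);
  double nv = 0.0;
  for (int i = 0; i < n; ++i) v[i] = (i + 1.0) / n;
  double mean = 0.0;
  for (int i = 0; i < n; ++i) mean += v[i];
  mean /= n;
  for (int i = 0; i < n; ++i) { v[i] -= mean; nv += v[i] * v[i]; }
  nv = std::sqrt(nv);
  for (int i = 0; i < n; ++i) v[i] /= nv;
  double lambda = 0.0;
  bool converged = false;
  for (int it = 0; it < max_iter; ++it) {
    double wn = 0.0;
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int j = 0; j < n; ++j) acc += K(i, j) * v[j];
      w[i] = acc;
      wn += acc * acc;
    }
    wn = std::sqrt(wn);
    if (!(wn > 0.0)) { lambda = 0.0; converged = true; break; }
    double dot = 0.0;
    for (int i = 0; i < n; ++i) { w[i] /= wn; dot += w[i] * v[i]; }
    std::swap(v, w);
    lambda = wn; // ||K v|| -> lambda_1 for a unit eigenvector of a PSD matrix
    if (std::fabs(1.0 - std::fabs(dot)) < tol) { converged = true; break; }
  }
  return List::create(Named("value") = lambda,
                      Named("vector") = NumericVector(v.begin(), v.end()),
                      Named("converged") = converged);
}
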