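// Compute-heavy kernels: all-pairs shortest paths, the null-model efficiency
// loop, and the windowed singular-spectrum entropy sweep. R-level reference
// implementations of each step are exported from R/ and the test suite pins
// these kernels against them.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double CLIP_HI = 1.0 - 1e-10;

// weight -> path length: -log(w) for w in (0,1); w<=0 removed (+Inf);
// w>=1 clipped just below 1. Diagonal is 0.
static void weightsToDist(const arma::mat& W, arma::mat& D) {
  const arma::uword n = W.n_rows;
  const double inf = arma::datum::inf;
  D.set_size(n, n);
  for (arma::uword j = 0; j < n; ++j) {
    for (arma::uword i = 0; i < n; ++i) {
      if (i == j) { D(i, j) = 0.0; continue; }
      double w = W(i, j);
      if (w <= 0.0) D(i, j) = inf;
      else D(i, j) = -std::log(w < CLIP_HI ? w : CLIP_HI);
    }
  }
}

// column-major sweep: for fixed (k, j) relax the whole column j against
// column k, which keeps both memory streams contiguous and branchless
static void floyd(arma::mat& D) {
  const arma::uword n = D.n_rows;
  for (arma::uword k = 0; k < n; ++k) {
    const double* Dk = D.colptr(k);
    for (arma::uword j = 0; j < n; ++j) {
      const double dkj = D(k, j);
      if (!std::isfinite(dkj)) continue;
      double* Dj = D.colptr(j);
      for (arma::uword i = 0; i < n; ++i) {
        const double alt = Dk[i] + dkj;
        Dj[i] = alt < Dj[i] ? alt : Dj[i];
      }
    }
  }
}

// mean of 1/d over pairs selected by mask (1/Inf counted as 0)
static double effFromDist(const arma::mat& D, const arma::umat& mask) {
  double s = 0.0;
  arma::uword m = 0;
  for (arma::uword j = 0; j < D.n_cols; ++j) {
    for (arma::uword i = 0; i < D.n_rows; ++i) {
      if (i == j || !mask(i, j)) continue;
      ++m;
      const double d = D(i, j);
      if (std::isfinite(d)) s += (d > 0.0) ? 1.0 / d : arma::datum::inf;
    }
  }
  return m ? s / m : NA_REAL;
}

// [[Rcpp::export(.floydWarshallCpp)]]
NumericMatrix floydWarshallCpp(NumericMatrix dist) {
  arma::mat D(dist.begin(), dist.nrow(), dist.ncol());
  floyd(D);
  return wrap(D);
}

// Raw efficiency of W over masked pairs plus nNull weight-shuffled null
// realizations. Shuffling permutes the upper-triangular weight multiset
// (Fisher-Yates on R's RNG) and mirrors it, so set.seed() reproduces runs.
// [[Rcpp::export(.effNormCpp)]]
List effNormCpp(NumericMatrix w, LogicalMatrix mask, int nNull) {
  const arma::uword n = w.nrow();
  arma::mat W(w.begin(), n, n);
  arma::umat M(n, n);
  for (arma::uword j = 0; j < n; ++j)
    for (arma::uword i = 0; i < n; ++i)
      M(i, j) = mask(i, j) ? 1u : 0u;

  arma::mat D;
  weightsToDist(W, D);
  floyd(D);
  const double eg = effFromDist(D, M);

  // upper-triangle weight pool
  const arma::uword m = n * (n - 1) / 2;
  std::vector<double> pool(m);
  {
    arma::uword k = 0;
    for (arma::uword j = 1; j < n; ++j)
      for (arma::uword i = 0; i < j; ++i) pool[k++] = W(i, j);
  }

  NumericVector egRand(nNull);
  arma::mat Ws(n, n, arma::fill::zeros);
  std::vector<double> v;
  for (int r = 0; r < nNull; ++r) {
    v = pool;
    for (arma::uword i = m; i > 1; --i) {
      arma::uword j = static_cast<arma::uword>(unif_rand() * i);
      if (j >= i) j = i - 1;
      std::swap(v[i - 1], v[j]);
    }
    arma::uword k = 0;
    for (arma::uword j = 1; j < n; ++j)
      for (arma::uword i = 0; i < j; ++i) {
        Ws(i, j) = v[k];
        Ws(j, i) = v[k];
        ++k;
      }
    Ws.diag() = W.diag();
    weightsToDist(Ws, D);
    floyd(D);
    egRand[r] = effFromDist(D, M);
  }
  return List::create(_["eg"] = eg, _["egRand"] = egRand);
}

// entropy of a singular-value vector normalized by log2(K); K may exceed
// the number of entries in s (implicit zeros contribute nothing)
static double entropyFromSv(const arma::vec& s, double K) {
  const double tot = arma::accu(s);
  if (!(tot > 0.0)) return NA_REAL; // all-zero matrix: undefined, caller skips
  double h = 0.0;
  for (arma::uword k = 0; k < s.n_elem; ++k) {
    const double p = s[k] / tot;
    if (p > 0.0) h -= p * std::log2(p);
  }
  return h / std::log2(K);
}

// Normalized singular-value entropy of the centered interaction matrix
// M = X1' X2 - mean, without forming M when the sets are large: the centered
// cross-product factors as C' D with C = [X1; 1'] and D = [X2; -mbar 1']
// ((T+1) x n each), so its nonzero singular values equal those of the
// (T+1) x (T+1) core R_C Q R_D' obtained from economy SVDs of C and D.
static double svEntropyWindow(const arma::mat& X1, const arma::mat& X2,
                              double K) {
  const arma::uword T = X1.n_rows;
  const double mbar =
      arma::accu(X1.t() * arma::sum(X2, 1)) / (X1.n_cols * X2.n_cols);
  // direct path for small interaction matrices
  if (std::min(X1.n_cols, X2.n_cols) <= 4 * (T + 1)) {
    arma::mat M = X1.t() * X2;
    M -= arma::accu(M) / M.n_elem;
    arma::vec s;
    if (!arma::svd(s, M)) return NA_REAL;
    return entropyFromSv(s, K);
  }
  arma::mat C(T + 1, X1.n_cols), D(T + 1, X2.n_cols);
  C.rows(0, T - 1) = X1;
  C.row(T).ones();
  D.rows(0, T - 1) = X2;
  D.row(T).fill(-mbar);
  arma::mat Uc, Vc, Ud, Vd;
  arma::vec sc, sd;
  // economy SVD of the (T+1) x n factors; with C = Uc Sc Vc' and
  // D = Ud Sd Vd', C'D = Vc [Sc Uc'Ud Sd] Vd' and the bracket carries
  // every nonzero singular value of M
  if (!arma::svd_econ(Uc, sc, Vc, C, "left") ||
      !arma::svd_econ(Ud, sd, Vd, D, "left"))
    return NA_REAL;
  arma::mat core = arma::diagmat(sc) * (Uc.t() * Ud) * arma::diagmat(sd);
  arma::vec s;
  if (!arma::svd(s, core)) return NA_REAL;
  return entropyFromSv(s, K);
}

// Window-averaged interaction complexity for a list of (set1, set2) column
// specs over non-overlapping windows of `width` frames (remainder dropped).
// x: frames x ROIs. Sets are 1-based column indices. All-zero windows are
// skipped; a spec with no valid window yields NA.
// [[Rcpp::export(.windowComplexityCpp)]]
NumericVector windowComplexityCpp(NumericMatrix x, List set1, List set2,
                                  int width) {
  const arma::mat X(x.begin(), x.nrow(), x.ncol());
  const int nSpec = set1.size();
  const arma::uword nWin = X.n_rows / width;
  NumericVector out(nSpec);
  for (int s = 0; s < nSpec; ++s) {
    arma::uvec s1 = as<arma::uvec>(set1[s]) - 1;
    arma::uvec s2 = as<arma::uvec>(set2[s]) - 1;
    double acc = 0.0;
    int nValid = 0;
    const double K = static_cast<double>(std::min(s1.n_elem, s2.n_elem));
    for (arma::uword wdx = 0; wdx < nWin; ++wdx) {
      const arma::uword a = wdx * width, b = a + width - 1;
      arma::mat X1 = X.submat(arma::regspace<arma::uvec>(a, b), s1);
      arma::mat X2 = X.submat(arma::regspace<arma::uvec>(a, b), s2);
      const double c = svEntropyWindow(X1, X2, K);
      if (std::isfinite(c)) { acc += c; ++nValid; }
    }
    out[s] = nValid ? acc / nValid : NA_REAL;
  }
  return out;
}
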