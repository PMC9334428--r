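// Voxel-block ICC statistics and the Fourier phase-randomization surrogate
// null. Data are passed as an n x (M*K) matrix: K voxels, each a contiguous
// block of M subject columns with n time points. Population (divide-by-count)
// moments throughout, matching the single-voxel R reference.
#include <RcppArmadillo.h>
using namespace arma;

// Per-voxel scalar aggregates -> A_hat, var_A, t_A (and C_hat, Gamma).
// The delta-method quadratic form is evaluated as the closed trace form
// 2/n * c^2 (t^2 s^2 - 2tsu + s^2 v), identical to
// eta' K (S (x) S) K' eta with K the Moore-Penrose elimination transform.
static void icc_block(const mat& X, const int M, mat& out) {
  const int n = X.n_rows;
  const int K = X.n_cols / M;
  const double dn = (double)n, dM = (double)M;
  for (int k = 0; k < K; ++k) {
    mat Xv = X.cols((uword)k * M, (uword)k * M + M - 1);
    rowvec cm = mean(Xv, 0);
    Xv.each_row() -= cm;
    const mat S = (Xv.t() * Xv) / dn;
    const double t = trace(S), s = accu(S);
    const vec rs = sum(S, 1);
    const double u = dot(rs, rs), v = accu(S % S);
    const double g = mean(cm);
    double q1V = 0.0;
    for (int i = 0; i < M; ++i) { const double d = cm[i] - g; q1V += d * d; }
    q1V /= dM;
    const double Gamma = q1V * dM * dM / s;
    const double C = (dM / (dM - 1)) * (s - t) / s;
    const double A = (dM / (dM - 1)) * (s - t) /
      (s * (1 + (dn - 1) * Gamma / (dn * (dM - 1)) -
            (dM / (dn * (dM - 1))) * (t / s) + 1 / (dn * (dM - 1))));
    const double cc = dM / ((dM - 1) * s * s);
    double vC = 2 / dn * cc * cc *
      (t * t * s * s - 2 * t * s * u + s * s * v);
    if (vC < 0) vC = 0;
    const double shrink = (dM - 1) / ((dM - 1) + Gamma);
    const double vA = vC * shrink * shrink;
    out(k, 0) = A;
    out(k, 1) = vA;
    out(k, 2) = (vA > 0) ? A / std::sqrt(vA) : NA_REAL;
    out(k, 3) = C;
    out(k, 4) = Gamma;
  }
}

// [[Rcpp::export]]
arma::mat cpp_icc_block(const arma::mat& X, const int M) {
  mat out(X.n_cols / M, 5);
  icc_block(X, M, out);
  return out;
}

// Phase-randomize every column of X independently (phases from R's RNG so a
// set.seed() in R fixes the whole stream), recompute the voxelwise t_A for
// each of n_surr surrogate replicates.
// [[Rcpp::export]]
arma::mat cpp_surrogate_t(const arma::mat& X, const int M, const int n_surr) {
  const int n = X.n_rows, nc = X.n_cols;
  const int K = nc / M;
  const cx_mat F = fft(conv_to<cx_mat>::from(X));
  const int half = (n - 2 + n % 2) / 2;
  mat tsurr(K, n_surr);
  cx_mat Fs(n, nc);
  mat Xs(n, nc), stats(K, 5);
  Rcpp::RNGScope scope;
  for (int r = 0; r < n_surr; ++r) {
    Fs = F;
    for (int j = 0; j < nc; ++j) {
      for (int f = 1; f <= half; ++f) {
        const double ph = unif_rand() * 2.0 * M_PI;
        Fs(f, j) *= std::complex<double>(std::cos(ph), std::sin(ph));
        Fs(n - f, j) = std::conj(Fs(f, j));
      }
      if (n % 2 == 0) Fs(n / 2, j) *= (unif_rand() < 0.5 ? -1.0 : 1.0);
      Xs.col(j) = real(ifft(Fs.col(j)));
    }
    icc_block(Xs, M, stats);
    tsurr.col(r) = stats.col(2);
    Rcpp::checkUserInterrupt();
  }
  return tsurr;
}

// Mean surrogate A_hat per voxel (used by diagnostics on synchronized
// fixtures: surrogates must destroy synchronization).
// [[Rcpp::export]]
arma::mat cpp_surrogate_A(const arma::mat& X, const int M, const int n_surr) {
  const int n = X.n_rows, nc = X.n_cols;
  const int K = nc / M;
  const cx_mat F = fft(conv_to<cx_mat>::from(X));
  const int half = (n - 2 + n % 2) / 2;
  mat Asurr(K, n_surr);
  cx_mat Fs(n, nc);
  mat Xs(n, nc), stats(K, 5);
  Rcpp::RNGScope scope;
  for (int r = 0; r < n_surr; ++r) {
    Fs = F;
    for (int j = 0; j < nc; ++j) {
      for (int f = 1; f <= half; ++f) {
        const double ph = unif_rand() * 2.0 * M_PI;
        Fs(f, j) *= std::complex<double>(std::cos(ph), std::sin(ph));
        Fs(n - f, j) = std::conj(Fs(f, j));
      }
      if (n % 2 == 0) Fs(n / 2, j) *= (unif_rand() < 0.5 ? -1.0 : 1.0);
      Xs.col(j) = real(ifft(Fs.col(j)));
    }
    icc_block(Xs, M, stats);
    Asurr.col(r) = stats.col(0);
    Rcpp::checkUserInterrupt();
  }
  return Asurr;
}
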