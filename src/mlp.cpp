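#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Single-pass IIR filter, transposed direct form II, with initial state zi.
// Coefficients must already be normalized (a[0] == 1).
// [[Rcpp::export]]
NumericVector df2t_filter_cpp(NumericVector b, NumericVector a,
                              NumericVector x, NumericVector zi) {
  int nb = b.size(), na = a.size(), n = x.size();
  int nz = std::max(na, nb) - 1;
  std::vector<double> z(nz, 0.0);
  for (int i = 0; i < std::min((int)zi.size(), nz); ++i) z[i] = zi[i];
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + z[0];
    for (int k = 0; k < nz - 1; ++k)
      z[k] = bb[k + 1] * xi + z[k + 1] - aa[k + 1] * yi;
    if (nz > 0) z[nz - 1] = bb[nz] * xi - aa[nz] * yi;
    y[i] = yi;
  }
  return y;
}

static arma::mat relu(const arma::mat& z) { return arma::clamp(z, 0.0, arma::datum::inf); }

// Train a fully connected feed-forward network for binary classification:
// ReLU hidden layers, sigmoid output, binary cross-entropy loss, plain
// mini-batch SGD. All randomness (weight init, epoch shuffling) comes from
// R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List mlp_train_cpp(const arma::mat& X, const arma::vec& y,
                   IntegerVector hidden, double lr, int epochs,
                   int batch_size) {
  const int n = X.n_rows, d = X.n_cols;
  const int nh = hidden.size();
  std::vector<int> sizes;
  sizes.push_back(d);
  for (int i = 0; i < nh; ++i) sizes.push_back(hidden[i]);
  sizes.push_back(1);
  const int nl = (int)sizes.size() - 1;  // number of weight layers

  std::vector<arma::mat> W(nl);
  std::vector<arma::rowvec> bvec(nl);
  for (int l = 0; l < nl; ++l) {
    double sd = (l < nl - 1) ? std::sqrt(2.0 / sizes[l])                 // He (ReLU)
                             : std::sqrt(2.0 / (sizes[l] + sizes[l + 1]));  // Glorot
    W[l].set_size(sizes[l], sizes[l + 1]);
    for (arma::uword j = 0; j < W[l].n_elem; ++j) W[l](j) = R::norm_rand() * sd;
    bvec[l] = arma::rowvec(sizes[l + 1], arma::fill::zeros);
  }

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  std::vector<arma::mat> A(nl + 1), Z(nl);
  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle driven by R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(R::unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }
    for (int start = 0; start < n; start += batch_size) {
      int stop = std::min(start + batch_size, n);
      int m = stop - start;
      arma::uvec rows(m);
      for (int i = 0; i < m; ++i) rows[i] = idx[start + i];
      A[0] = X.rows(rows);
      arma::vec yb = y.elem(rows);

      for (int l = 0; l < nl; ++l) {
        Z[l] = A[l] * W[l];
        Z[l].each_row() += bvec[l];
        A[l + 1] = (l < nl - 1) ? relu(Z[l]) : 1.0 / (1.0 + arma::exp(-Z[l]));
      }

      // output delta for sigmoid + BCE, averaged over the batch
      arma::mat delta = (A[nl] - arma::mat(yb)) / (double)m;
      for (int l = nl - 1; l >= 0; --l) {
        arma::mat gW = A[l].t() * delta;
        arma::rowvec gb = arma::sum(delta, 0);
        if (l > 0)
          delta = (delta * W[l].t()) % arma::conv_to<arma::mat>::from(Z[l - 1] > 0.0);
        W[l] -= lr * gW;
        bvec[l] -= lr * gb;
      }
    }
  }

  List weights(nl), biases(nl);
  for (int l = 0; l < nl; ++l) {
    weights[l] = W[l];
    biases[l] = NumericVector(bvec[l].begin(), bvec[l].end());
  }
  return List::create(Named("weights") = weights, Named("biases") = biases,
                      Named("sizes") = IntegerVector(sizes.begin(), sizes.end()));
}
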