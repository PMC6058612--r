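// Two-means under correlation distance, the inner step of the bisecting
// k-means segmentation. Points are pixel feature vectors; the centroid of a
// cluster is the plain mean of its members' raw vectors, and the distance of
// a point to a centroid is 1 - Pearson(point, centroid). Zero-variance
// vectors (point or centroid) have correlation 0 with everything, i.e.
// distance 1.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Row-standardize to centered unit norm; all-constant rows become zero rows.
static arma::rowvec standardize_row(const arma::rowvec& v) {
  arma::rowvec c = v - arma::mean(v);
  double n = arma::norm(c, 2);
  if (n > 0) c /= n; else c.zeros();
  return c;
}

// [[Rcpp::export(name = ".kmeans2_cor")]]
List kmeans2_cor(const arma::mat& X, const arma::mat& Z,
                 const arma::umat& inits, int max_iter) {
  const arma::uword n = X.n_rows;
  arma::uvec best_assign(n, arma::fill::zeros);
  double best_obj = arma::datum::inf;
  bool any_valid = false;

  for (arma::uword r = 0; r < inits.n_rows; ++r) {
    arma::rowvec c0 = X.row(inits(r, 0) - 1);
    arma::rowvec c1 = X.row(inits(r, 1) - 1);
    arma::uvec assign(n, arma::fill::zeros);
    arma::uvec prev(n); prev.fill(2);
    arma::vec d0(n), d1(n);

    for (int it = 0; it < max_iter; ++it) {
      arma::vec s0 = Z * standardize_row(c0).t();
      arma::vec s1 = Z * standardize_row(c1).t();
      d0 = 1.0 - s0;
      d1 = 1.0 - s1;
      assign = arma::conv_to<arma::uvec>::from(d1 < d0);
      // re-seed an emptied centroid at the point farthest from the other
      if (arma::accu(assign) == 0) {
        arma::uword far = d0.index_max();
        assign(far) = 1;
      } else if (arma::accu(assign) == n) {
        arma::uword far = d1.index_max();
        assign(far) = 0;
      }
      if (arma::all(assign == prev)) break;
      prev = assign;
      arma::uvec i0 = arma::find(assign == 0), i1 = arma::find(assign == 1);
      c0 = arma::mean(X.rows(i0), 0);
      c1 = arma::mean(X.rows(i1), 0);
    }

    // objective at the final assignment, against final member centroids
    arma::uvec i0 = arma::find(assign == 0), i1 = arma::find(assign == 1);
    if (i0.n_elem == 0 || i1.n_elem == 0) continue;
    arma::rowvec z0 = standardize_row(arma::mean(X.rows(i0), 0));
    arma::rowvec z1 = standardize_row(arma::mean(X.rows(i1), 0));
    double obj = arma::accu(1.0 - Z.rows(i0) * z0.t()) +
                 arma::accu(1.0 - Z.rows(i1) * z1.t());
    any_valid = true;
    if (obj < best_obj) {
      best_obj = obj;
      best_assign = assign;
    }
  }

  return List::create(_["assign"] = best_assign,
                      _["objective"] = best_obj,
                      _["valid"] = any_valid);
}

// Sum of correlation distances of rows to their mean-vector centroid.
// [[Rcpp::export(name = ".cluster_scatter")]]
double cluster_scatter(const arma::mat& X, const arma::mat& Z) {
  if (X.n_rows < 2) return 0.0;
  arma::rowvec zc = standardize_row(arma::mean(X, 0));
  return arma::accu(1.0 - Z * zc.t());
}
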