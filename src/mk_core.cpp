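#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// closed form for binary chains, Pade scaling-and-squaring otherwise
static arma::mat prob_mat(const arma::mat& Q, double t) {
  if (Q.n_rows == 2) {
    const double a = Q(0, 1), b = Q(1, 0), s = a + b;
    arma::mat P(2, 2);
    if (s <= 0.0) { P.eye(); return P; }
    const double e = std::exp(-s * t);
    P(0, 0) = (b + a * e) / s; P(0, 1) = (a - a * e) / s;
    P(1, 0) = (b - b * e) / s; P(1, 1) = (a + b * e) / s;
    return P;
  }
  return arma::expmat(Q * t);
}

// P(t) = exp(Qt)
// [[Rcpp::export]]
arma::mat expm_cpp(const arma::mat& Q, double t) {
  return prob_mat(Q, t);
}

// Felsenstein pruning log-likelihood for one discrete character on one tree.
//
// edge: 2-column (parent, child) integer matrix in *postorder* (ape
//   node numbering: tips 1..n_tip, root n_tip+1). edge_len aligned.
// tip_partials: n_tip x k matrix of conditional likelihoods at the tips
//   (one-hot for observed states, all-ones for missing/inapplicable).
// root_prior: length-k probability vector.
// Per-node rescaling by the row maximum keeps partials in range on
// trees with hundreds of tips; the log factors are accumulated.
// [[Rcpp::export]]
double mk_loglik_cpp(const arma::imat& edge,
                     const arma::vec& edge_len,
                     int n_tip,
                     const arma::mat& tip_partials,
                     const arma::mat& Q,
                     const arma::vec& root_prior) {
  const int k = Q.n_rows;
  const int n_edge = edge.n_rows;
  const int n_node = n_tip + (edge.max() - n_tip); // total nodes referenced
  arma::mat part(n_node, k, arma::fill::ones);
  part.rows(0, n_tip - 1) = tip_partials;
  double log_scale = 0.0;

  int i = 0;
  while (i < n_edge) {
    int parent = edge(i, 0) - 1;
    // all edges sharing a parent are contiguous in ape postorder
    while (i < n_edge && edge(i, 0) - 1 == parent) {
      int child = edge(i, 1) - 1;
      arma::mat P = prob_mat(Q, edge_len(i));
      arma::rowvec msg = part.row(child) * P.t(); // sum_j P(i,j) L_child(j)
      part.row(parent) %= msg;
      ++i;
    }
    double mx = part.row(parent).max();
    if (mx <= 0.0) return -std::numeric_limits<double>::infinity();
    part.row(parent) /= mx;
    log_scale += std::log(mx);
  }

  int root = edge(n_edge - 1, 0) - 1;
  double lik = arma::dot(part.row(root).t(), root_prior);
  if (lik <= 0.0) return -std::numeric_limits<double>::infinity();
  return std::log(lik) + log_scale;
}

// Downward (tip-to-root) partial likelihoods for every node, with the
// per-node log scale factors; used by the marginal-reconstruction pass.
// [[Rcpp::export]]
List mk_partials_cpp(const arma::imat& edge,
                     const arma::vec& edge_len,
                     int n_tip,
                     const arma::mat& tip_partials,
                     const arma::mat& Q) {
  const int k = Q.n_rows;
  const int n_edge = edge.n_rows;
  const int n_node = n_tip + (edge.max() - n_tip);
  arma::mat part(n_node, k, arma::fill::ones);
  part.rows(0, n_tip - 1) = tip_partials;
  arma::vec logsc(n_node, arma::fill::zeros);
  arma::cube P(k, k, n_edge);

  int i = 0;
  while (i < n_edge) {
    int parent = edge(i, 0) - 1;
    while (i < n_edge && edge(i, 0) - 1 == parent) {
      int child = edge(i, 1) - 1;
      P.slice(i) = prob_mat(Q, edge_len(i));
      part.row(parent) %= part.row(child) * P.slice(i).t();
      ++i;
    }
    double mx = part.row(parent).max();
    part.row(parent) /= mx;
    // child scales fold upward so logsc(root) is the full correction
    logsc(parent) += std::log(mx);
  }
  return List::create(_["partials"] = part, _["P"] = P, _["log_scale"] = logsc);
}
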