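// Codon pruning-likelihood kernel.
//
// Per-site penalized ML estimation of 20 amino-acid fitnesses calls the
// likelihood thousands of times per site, so the generator construction,
// its symmetric eigendecomposition and Felsenstein pruning live here.
// Reversibility of the nucleotide mutation model is assumed (the R side
// falls back to matrix exponentials otherwise).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// neighbor table columns (0-based): from, to, from_base, to_base, syn,
// aa_from, aa_to -- stop-gaining rows already removed on the R side.
static mat build_q(const mat& mu, const vec& F, const imat& nb) {
  mat Q(61, 61, fill::zeros);
  for (uword k = 0; k < nb.n_rows; ++k) {
    double m = mu(nb(k, 2), nb(k, 3));
    double rate;
    if (nb(k, 4) == 1) {
      rate = m;
    } else {
      double dF = F(nb(k, 6)) - F(nb(k, 5));
      if (std::abs(dF) < 1e-8) rate = m;
      else if (dF < -500.0) rate = 0.0;
      else rate = m * dF / (-std::expm1(-dF));
    }
    Q(nb(k, 0), nb(k, 1)) = rate;
  }
  Q.diag() = -sum(Q, 1);
  return Q;
}

struct Decomp {
  vec d;      // sqrt(pi)
  vec eval;
  mat evec;
};

static Decomp decompose(const mat& Q, const vec& pi) {
  Decomp dec;
  dec.d = sqrt(pi);
  mat B = Q;
  B.each_col() %= dec.d;
  B.each_row() /= dec.d.t();
  B = 0.5 * (B + B.t());            // symmetric up to round-off
  eig_sym(dec.eval, dec.evec, B);
  return dec;
}

static mat transition(const Decomp& dec, double t) {
  mat P = dec.evec * diagmat(exp(dec.eval * t)) * dec.evec.t();
  P.each_col() /= dec.d;
  P.each_row() %= dec.d.t();
  P.elem(find(P < 0)).zeros();      // clip round-off negatives
  return P;
}

// Pruning over one site. edges: postorder (parent, child) 0-based;
// states: per-tip codon index, -1 for missing; root weighted by pi.
static double prune_site(const mat& Q, const vec& pi, const imat& edges,
                         const vec& blen, const ivec& states, int nnode) {
  Decomp dec = decompose(Q, pi);
  int nstate = Q.n_rows;
  mat part(nstate, nnode, fill::ones);
  for (uword i = 0; i < states.n_elem; ++i) {
    if (states(i) >= 0) {
      part.col(i).zeros();
      part(states(i), i) = 1.0;
    }
  }
  double logscale = 0.0;
  for (uword e = 0; e < edges.n_rows; ++e) {
    int par = edges(e, 0), ch = edges(e, 1);
    vec msg = transition(dec, blen(e)) * part.col(ch);
    part.col(par) %= msg;
    double mx = part.col(par).max();
    if (mx <= 0) return -datum::inf;
    part.col(par) /= mx;
    logscale += std::log(mx);
  }
  int root = edges(edges.n_rows - 1, 0);
  double lik = dot(pi, part.col(root));
  if (lik <= 0) return -datum::inf;
  return std::log(lik) + logscale;
}

// [[Rcpp::export]]
double cpp_prune_site(const arma::mat& Q, const arma::vec& pi,
                      const arma::imat& edges, const arma::vec& blen,
                      const arma::ivec& states, int nnode) {
  return prune_site(Q, pi, edges, blen, states, nnode);
}

// Same decomposition shared across sites (one Q for the whole alignment).
// states: ntip x nsites, -1 missing.  Returns per-site log-likelihoods.
// [[Rcpp::export]]
arma::vec cpp_prune_alignment(const arma::mat& Q, const arma::vec& pi,
                              const arma::imat& edges, const arma::vec& blen,
                              const arma::imat& states, int nnode) {
  Decomp dec = decompose(Q, pi);
  int nstate = Q.n_rows;
  uword ntip = states.n_rows, S = states.n_cols;
  std::vector<mat> part(nnode);
  for (int v = 0; v < nnode; ++v) part[v] = mat(nstate, S, fill::ones);
  for (uword i = 0; i < ntip; ++i) {
    part[i].zeros();
    for (uword s = 0; s < S; ++s) {
      if (states(i, s) >= 0) part[i](states(i, s), s) = 1.0;
      else part[i].col(s).ones();
    }
  }
  rowvec logscale(S, fill::zeros);
  for (uword e = 0; e < edges.n_rows; ++e) {
    int par = edges(e, 0), ch = edges(e, 1);
    mat msg = transition(dec, blen(e)) * part[ch];
    part[par] %= msg;
    rowvec mx = max(part[par], 0);
    part[par].each_row() /= mx;
    logscale += log(mx);
  }
  int root = edges(edges.n_rows - 1, 0);
  rowvec lik = pi.t() * part[root];
  return (log(lik) + logscale).t();
}

// Penalized negative log-likelihood for one site's fitness vector.
// psi: 61-vector of codon-position base-frequency products;
// aa: 0-based amino-acid index per codon.
// [[Rcpp::export]]
double cpp_profile_negloglik(const arma::vec& F, const arma::mat& mu,
                             const arma::vec& psi, const arma::ivec& aa,
                             const arma::imat& nb, const arma::imat& edges,
                             const arma::vec& blen, const arma::ivec& states,
                             int nnode, double penalty) {
  vec Fc = F - mean(F);
  mat Q = build_q(mu, Fc, nb);
  vec w = psi % exp(Fc(conv_to<uvec>::from(aa)) - Fc.max());
  vec pi = w / accu(w);
  double ll = prune_site(Q, pi, edges, blen, states, nnode);
  return -ll + penalty * dot(Fc, Fc);
}
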