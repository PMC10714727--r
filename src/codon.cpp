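// Felsenstein pruning for reversible codon (and general state) models.
// R supplies the 61-state structure (transition/transversion and
// synonymous/nonsynonymous masks over sense codons); this file builds the
// per-omega rate matrices, exponentiates them via symmetric eigendecomposition
// (the models are time-reversible) and computes per-class per-site
// log-likelihoods over a postorder edge list.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Build the GY94-style rate matrix for one omega, scaled by normConst.
// mult_ij = kappa^[ts] * omega^[nonsyn] for single-nt-change pairs, else 0.
static arma::mat build_q(const arma::mat& ts, const arma::mat& tv,
                         const arma::mat& nonsyn, const arma::vec& pi,
                         double kappa, double omega, double normConst) {
  arma::uword n = pi.n_elem;
  arma::mat mult = kappa * ts + tv;           // zero where >1 nt differs
  arma::mat omult = mult % (1.0 + (omega - 1.0) * nonsyn);
  arma::mat Q = omult;
  Q.each_row() %= pi.t();                      // q_ij = mult_ij * pi_j
  for (arma::uword i = 0; i < n; ++i) {
    Q(i, i) = 0.0;
    Q(i, i) = -arma::accu(Q.row(i));
  }
  return Q / normConst;
}

// mean substitution rate -sum_i pi_i q_ii of the unscaled matrix
static double mean_rate(const arma::mat& ts, const arma::mat& tv,
                        const arma::mat& nonsyn, const arma::vec& pi,
                        double kappa, double omega) {
  arma::mat Q = build_q(ts, tv, nonsyn, pi, kappa, omega, 1.0);
  return -arma::dot(pi, Q.diag());
}

struct EigQ {
  arma::mat L;   // diag(1/sqrt(pi)) * V
  arma::mat R;   // V' * diag(sqrt(pi))
  arma::vec lam;
};

static EigQ eig_reversible(const arma::mat& Q, const arma::vec& pi) {
  arma::vec s = arma::sqrt(pi);
  arma::mat B = Q;
  B.each_col() %= s;          // diag(s) * Q
  B.each_row() /= s.t();      // ... * diag(1/s)
  B = 0.5 * (B + B.t());      // symmetrize against rounding
  EigQ e;
  arma::mat V;
  arma::eig_sym(e.lam, V, B);
  e.L = V;
  e.L.each_col() /= s;
  e.R = V.t();
  e.R.each_row() %= s.t();
  return e;
}

static arma::mat pmat(const EigQ& e, double t) {
  arma::mat Ld = e.L;
  Ld.each_row() %= arma::exp(e.lam.t() * t);
  arma::mat P = Ld * e.R;
  P.transform([](double x) { return x < 0.0 ? 0.0 : x; });
  return P;
}

// [[Rcpp::export(name = ".cpp_mean_rate")]]
double cpp_mean_rate(const arma::mat& ts, const arma::mat& tv,
                     const arma::mat& nonsyn, const arma::vec& pi,
                     double kappa, double omega) {
  return mean_rate(ts, tv, nonsyn, pi, kappa, omega);
}

// [[Rcpp::export(name = ".cpp_codon_pmat")]]
arma::mat cpp_codon_pmat(const arma::mat& ts, const arma::mat& tv,
                         const arma::mat& nonsyn, const arma::vec& pi,
                         double kappa, double omega, double normConst,
                         double t) {
  arma::mat Q = build_q(ts, tv, nonsyn, pi, kappa, omega, normConst);
  return pmat(eig_reversible(Q, pi), t);
}

// Per-class per-pattern log-likelihoods of the branch-site mixture.
//
// tipStates: ntip x npat (0-based states, -1 = missing)
// edge: nedge x 2 (ape numbering, postorder: children before parents)
// blen: per-edge lengths (expected substitutions per codon at omega = 1)
// foreground: per-edge 0/1
// omegaBg, omegaFg: per-class background/foreground omega
// kappa, pi: shared across classes
// The matrices are normalized jointly so a branch length of 1 equals one
// expected substitution per codon for an omega = 1 site.
// [[Rcpp::export(name = ".cpp_branchsite_loglik")]]
arma::mat cpp_branchsite_loglik(const arma::imat& tipStates,
                                const arma::imat& edge,
                                const arma::vec& blen,
                                const arma::ivec& foreground,
                                const arma::vec& omegaBg,
                                const arma::vec& omegaFg,
                                double kappa,
                                const arma::vec& pi,
                                const arma::mat& ts, const arma::mat& tv,
                                const arma::mat& nonsyn) {
  const arma::uword ntip = tipStates.n_rows;
  const arma::uword npat = tipStates.n_cols;
  const arma::uword nedge = edge.n_rows;
  const arma::uword nstate = pi.n_elem;
  const arma::uword nclass = omegaBg.n_elem;
  const double normC = mean_rate(ts, tv, nonsyn, pi, kappa, 1.0);

  // distinct omegas -> eigensystems and per-edge P matrices
  std::vector<double> omegas;
  for (arma::uword c = 0; c < nclass; ++c) {
    for (double w : {omegaBg(c), omegaFg(c)}) {
      bool seen = false;
      for (double o : omegas) if (std::abs(o - w) < 1e-14) { seen = true; break; }
      if (!seen) omegas.push_back(w);
    }
  }
  std::vector<std::vector<arma::mat>> P(omegas.size());
  for (size_t oi = 0; oi < omegas.size(); ++oi) {
    arma::mat Q = build_q(ts, tv, nonsyn, pi, kappa, omegas[oi], normC);
    EigQ e = eig_reversible(Q, pi);
    P[oi].resize(nedge);
    for (arma::uword k = 0; k < nedge; ++k) P[oi][k] = pmat(e, blen(k));
  }
  auto omega_index = [&](double w) {
    for (size_t oi = 0; oi < omegas.size(); ++oi)
      if (std::abs(omegas[oi] - w) < 1e-14) return oi;
    return size_t(0);
  };

  arma::uword nnode = ntip + nedge + 1;  // upper bound on node ids
  arma::mat out(nclass, npat);

  for (arma::uword c = 0; c < nclass; ++c) {
    std::vector<arma::mat> partial(nnode + 1);
    std::vector<bool> init(nnode + 1, false);
    arma::rowvec logscale(npat, arma::fill::zeros);
    size_t oiBg = omega_index(omegaBg(c));
    size_t oiFg = omega_index(omegaFg(c));

    for (arma::uword k = 0; k < nedge; ++k) {
      arma::uword par = edge(k, 0);
      arma::uword ch  = edge(k, 1);
      const arma::mat& Pk = P[foreground(k) ? oiFg : oiBg][k];
      arma::mat contrib;
      if (ch <= ntip) {  // tip child
        contrib.set_size(nstate, npat);
        for (arma::uword j = 0; j < npat; ++j) {
          int st = tipStates(ch - 1, j);
          if (st < 0) contrib.col(j).ones();
          else contrib.col(j) = Pk.col(st);
        }
      } else {
        contrib = Pk * partial[ch];
      }
      if (!init[par]) { partial[par] = contrib; init[par] = true; }
      else partial[par] %= contrib;
      if (partial[par].max() < 1e-120) {   // guard against underflow
        arma::rowvec m = arma::max(partial[par], 0);
        m.transform([](double x) { return x > 0.0 ? x : 1.0; });
        partial[par].each_row() /= m;
        logscale += arma::log(m);
      }
    }
    // root = parent of the last postorder edge
    arma::uword root = edge(nedge - 1, 0);
    arma::rowvec lik = pi.t() * partial[root];
    out.row(c) = arma::log(lik) + logscale;
  }
  return out;
}
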