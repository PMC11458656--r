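// Linear compartmental solver for the MPA model: a chain of n_abs
// first-order absorption compartments (all at rate ktr) feeding a
// two-compartment disposition block, plus a cumulative-elimination state
// used for mass-balance checks.  The system is propagated between dose and
// observation times with the matrix exponential, which is exact for this
// constant-coefficient linear ODE and robust to the repeated eigenvalue
// (-ktr, multiplicity n_abs) that a distinct-eigenvalue analytic formula
// would not tolerate.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

static arma::mat rate_matrix(double cl, double vc, double vp, double q,
                             double ktr, int n_abs) {
  // states: a_1..a_{n_abs}, central, peripheral, eliminated
  int n = n_abs + 3;
  arma::mat A(n, n, arma::fill::zeros);
  for (int i = 0; i < n_abs; ++i) {
    A(i, i) = -ktr;
    A(i + 1, i) = ktr; // last chain state feeds central
  }
  int ic = n_abs, ip = n_abs + 1, ie = n_abs + 2;
  double kel = cl / vc, kcp = q / vc, kpc = q / vp;
  A(ic, ic) += -(kel + kcp);
  A(ip, ic) = kcp;
  A(ic, ip) = kpc;
  A(ip, ip) = -kpc;
  A(ie, ic) = kel;
  return A;
}

// Propagate the system through a merged timeline of dose and observation
// events.  Doses (amounts already scaled by occasion bioavailability) are
// bolus inputs into the first absorption state.  An observation coinciding
// with a dose time is read *before* the dose is applied (pre-dose sample).
// Returns a matrix with one row per observation time: full state vector.
// [[Rcpp::export]]
arma::mat profile_states_cpp(double cl, double vc, double vp, double q,
                             double ktr, int n_abs,
                             const arma::vec& dose_time,
                             const arma::vec& dose_amt,
                             const arma::vec& obs_time) {
  int n = n_abs + 3;
  arma::mat A = rate_matrix(cl, vc, vp, q, ktr, n_abs);
  arma::vec state(n, arma::fill::zeros);
  arma::mat out(obs_time.n_elem, n, arma::fill::zeros);

  arma::uword id = 0, io = 0;
  double t = 0.0;
  // assumes dose_time and obs_time each sorted non-decreasing, all >= 0
  while (io < obs_time.n_elem || id < dose_time.n_elem) {
    bool take_obs;
    double tnext;
    if (io < obs_time.n_elem &&
        (id >= dose_time.n_elem || obs_time(io) <= dose_time(id))) {
      take_obs = true;
      tnext = obs_time(io);
    } else {
      take_obs = false;
      tnext = dose_time(id);
    }
    double dt = tnext - t;
    if (dt > 0) {
      state = arma::expmat(A * dt) * state;
      t = tnext;
    }
    if (take_obs) {
      out.row(io) = state.t();
      ++io;
    } else {
      state(0) += dose_amt(id);
      ++id;
    }
  }
  return out;
}

// Concentration (central amount / vc) at the observation times.
// [[Rcpp::export]]
arma::vec profile_conc_cpp(double cl, double vc, double vp, double q,
                           double ktr, int n_abs,
                           const arma::vec& dose_time,
                           const arma::vec& dose_amt,
                           const arma::vec& obs_time) {
  arma::mat st = profile_states_cpp(cl, vc, vp, q, ktr, n_abs,
                                    dose_time, dose_amt, obs_time);
  return st.col(n_abs) / vc;
}
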