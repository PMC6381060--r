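// Forward-Euler integration of the recurrent V1-MT circuit over a segment
// with a constant driving direction signal. Mirrors the single-step update
// in R/circuit.R step() exactly; kept in compiled code because the long
// adaptation protocols integrate millions of 1-ms steps.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline void clip_checked(vec& x, double lo, double hi,
                                const char* what, double tol) {
  if (x.min() < lo - tol || x.max() > hi + tol)
    Rcpp::stop("Euler update pushed %s outside [%g, %g] by more than %g; reduce dt",
               what, lo, hi, tol);
  x = clamp(x, lo, hi);
}

// [[Rcpp::export]]
Rcpp::List cpp_run_segment(arma::vec v1, arma::vec vmt,
                           arma::vec yff, arma::vec yfb, double t0,
                           const arma::mat& K, const arma::vec& r,
                           int n_steps, double dt,
                           double tau, double tau_syn, double lam,
                           double a_ff, double b_ff, double a_fb, double b_fb,
                           double clip_tol, int stride) {
  const double kv = dt / tau;
  const double ks = dt / tau_syn;
  const vec Kr = K * r;  // constant over the segment

  vec mean_v1(v1.n_elem, fill::zeros);
  vec mean_mt(v1.n_elem, fill::zeros);
  double v_min = std::min(v1.min(), vmt.min());
  double v_max = std::max(v1.max(), vmt.max());
  double y_min = std::min(yff.min(), yfb.min());
  double y_max = std::max(yff.max(), yfb.max());

  int n_rec = (stride > 0) ? (n_steps / stride) : 0;
  mat traj;
  if (n_rec > 0) traj.set_size(n_rec, 1 + 4 * v1.n_elem);
  int rec = 0;

  for (int s = 0; s < n_steps; ++s) {
    const vec v1p = clamp(v1, 0.0, datum::inf);
    const vec vmtp = clamp(vmt, 0.0, datum::inf);
    const vec i_ex_v1 = Kr % (1.0 + lam * (yfb % vmtp));
    const vec i_ex_mt = yff % (K * v1p);
    const double i_inh_v1 = mean(i_ex_v1);
    const double i_inh_mt = mean(i_ex_mt);

    v1 += kv * (-v1 + (1.0 - v1) % i_ex_v1 - (1.0 + v1) * i_inh_v1);
    vmt += kv * (-vmt + (1.0 - vmt) % i_ex_mt - (1.0 + vmt) * i_inh_mt);
    yff += ks * (a_ff * (1.0 - yff) - b_ff * (yff % v1p));
    yfb += ks * (a_fb * (1.0 - yfb) - b_fb * (yfb % vmtp));

    clip_checked(v1, -1.0, 1.0, "v_v1", clip_tol);
    clip_checked(vmt, -1.0, 1.0, "v_mt", clip_tol);
    clip_checked(yff, 0.0, 1.0, "y_ff", clip_tol);
    clip_checked(yfb, 0.0, 1.0, "y_fb", clip_tol);

    mean_v1 += clamp(v1, 0.0, datum::inf);
    mean_mt += clamp(vmt, 0.0, datum::inf);
    v_min = std::min(v_min, std::min(v1.min(), vmt.min()));
    v_max = std::max(v_max, std::max(v1.max(), vmt.max()));
    y_min = std::min(y_min, std::min(yff.min(), yfb.min()));
    y_max = std::max(y_max, std::max(yff.max(), yfb.max()));

    if (stride > 0 && ((s + 1) % stride == 0) && rec < n_rec) {
      traj(rec, 0) = t0 + (s + 1) * dt;
      for (uword i = 0; i < v1.n_elem; ++i) {
        traj(rec, 1 + i) = v1(i);
        traj(rec, 1 + v1.n_elem + i) = vmt(i);
        traj(rec, 1 + 2 * v1.n_elem + i) = yff(i);
        traj(rec, 1 + 3 * v1.n_elem + i) = yfb(i);
      }
      ++rec;
    }
  }

  mean_v1 /= n_steps;
  mean_mt /= n_steps;

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("v_v1") = v1, Rcpp::Named("v_mt") = vmt,
    Rcpp::Named("y_ff") = yff, Rcpp::Named("y_fb") = yfb,
    Rcpp::Named("t") = t0 + n_steps * dt,
    Rcpp::Named("mean_v1") = mean_v1, Rcpp::Named("mean_mt") = mean_mt,
    Rcpp::Named("v_min") = v_min, Rcpp::Named("v_max") = v_max,
    Rcpp::Named("y_min") = y_min, Rcpp::Named("y_max") = y_max);
  if (n_rec > 0) out["trajectory"] = traj;
  return out;
}
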