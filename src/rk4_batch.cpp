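#include <Rcpp.h>
using namespace Rcpp;

// Per-agent ODE right-hand side for the Bnip3 dual-domain network.
//
// State layout (matches the R-side MitoState ordering):
//   0 bnip3_i   1 bnip3_a   2 bnip3_av  3 bcl2_free 4 bcl2_bnip3
//   5 bcl2_bax  6 bax_i     7 bax_a     8 cytc_m    9 casp3_i   10 casp3_a
// Two bookkeeping states are appended inside the integrator:
//  11 av (local autophagosome pool, consumed by LIR binding and caspase
//     inactivation), 12 ros_prod (cumulative ROS emitted, k_ros_bax * bax_a).
// ROS and tBid are held constant over the interval (quasi-static environment).
static inline void rhs(const double *y, double ros, double tbid,
                       const double *p, double *dy) {
  const double r_f = p[0], r_r = p[1], r_lir = p[2], k_ros_bax = p[3],
               k_cas_av = p[4], k_momp = p[5], alpha_bcl2 = p[6];
  const double v1f = r_f * y[0] * ros;        // ROS activation of Bnip3
  const double v1r = r_r * y[1];
  const double v2f = r_f * y[1] * y[3];       // BH3 sequestration of Bcl2
  const double v2r = r_r * y[4];
  const double v3f = r_f * y[7] * y[3];       // Bcl2 neutralizes active Bax
  const double v3r = r_r * y[5];
  const double v4  = r_f * tbid * y[6];       // tBid-catalyzed Bax activation
  const double v5  = k_momp * y[7] * y[8];    // MOMP cytochrome c release
  const double v6  = r_f * (1.0 - y[8]) * y[9]; // caspase tracks total release
  const double v7f = r_lir * (1.0 + alpha_bcl2 * y[4]) * y[1] * y[11]; // LIR-AV
  const double v7r = r_r * y[2];
  const double v8  = k_cas_av * y[10] * y[11]; // caspase inactivates AV

  dy[0]  = -v1f + v1r;
  // BH3 engagement of Bcl2 does not deplete LIR-competent Bnip3: the two
  // domains of one molecule act independently, so v2 terms are absent here.
  dy[1]  = v1f - v1r - v7f + v7r;
  dy[2]  = v7f - v7r;
  dy[3]  = -v2f + v2r - v3f + v3r;
  dy[4]  = v2f - v2r;
  dy[5]  = v3f - v3r;
  dy[6]  = -v4;
  dy[7]  = v4 - v3f + v3r;
  dy[8]  = -v5;
  dy[9]  = -v6;
  dy[10] = v6;
  dy[11] = -v7f + v7r - v8;
  dy[12] = k_ros_bax * y[7];
}

// Classical fixed-step RK4 over [0, duration] for every agent (rows of
// `state`). Returns the advanced states plus per-agent bookkeeping outputs.
// [[Rcpp::export]]
List rk4_batch_cpp(NumericMatrix state, NumericVector av, NumericVector ros,
                   NumericVector tbid, NumericVector params, double duration,
                   double dt) {
  const int n = state.nrow();
  if (state.ncol() != 11)
    stop("state must have 11 columns");
  if (av.size() != n || ros.size() != n || tbid.size() != n)
    stop("av/ros/tbid must have one entry per agent");
  if (params.size() != 7)
    stop("params must be length 7");
  NumericMatrix out(n, 11);
  NumericVector av_out(n), ros_prod(n), cytc_released(n);
  if (duration <= 0.0) {
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < 11; ++j) out(i, j) = state(i, j);
    av_out = clone(av);
    return List::create(_["state"] = out, _["av"] = av_out,
                        _["ros_produced"] = ros_prod,
                        _["cytc_released"] = cytc_released);
  }
  const int nstep = (int)std::ceil(duration / dt);
  const double h = duration / nstep;
  const double *p = params.begin();
  double y[13], yt[13], k1[13], k2[13], k3[13], k4[13];
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < 11; ++j) y[j] = state(i, j);
    y[11] = av[i];
    y[12] = 0.0;
    const double cytc0 = y[8];
    const double ro = ros[i], tb = tbid[i];
    for (int s = 0; s < nstep; ++s) {
      rhs(y, ro, tb, p, k1);
      for (int j = 0; j < 13; ++j) yt[j] = y[j] + 0.5 * h * k1[j];
      rhs(yt, ro, tb, p, k2);
      for (int j = 0; j < 13; ++j) yt[j] = y[j] + 0.5 * h * k2[j];
      rhs(yt, ro, tb, p, k3);
      for (int j = 0; j < 13; ++j) yt[j] = y[j] + h * k3[j];
      rhs(yt, ro, tb, p, k4);
      for (int j = 0; j < 13; ++j)
        y[j] += h / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
    }
    for (int j = 0; j < 13; ++j)
      if (y[j] < 0.0) y[j] = 0.0; // clamp solver round-off at output
    for (int j = 0; j < 11; ++j) out(i, j) = y[j];
    av_out[i] = y[11];
    ros_prod[i] = y[12];
    cytc_released[i] = cytc0 - y[8] > 0.0 ? cytc0 - y[8] : 0.0;
  }
  return List::create(_["state"] = out, _["av"] = av_out,
                      _["ros_produced"] = ros_prod,
                      _["cytc_released"] = cytc_released);
}
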