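#include <Rcpp.h>
using namespace Rcpp;

// State layout: y[0]=H (free HSPA1A), y[1]=HF (HSPA1A.HSF1 complex),
// y[2]=F (free/active HSF1), y[3]=M (misfolded protein), y[4]=C (CHIP).
//
// Parameter layout (par): 0:k 1:Kd 2:k2 3:k4 4:k5 5:k7 6:k1 7:k6 8:a_chip
// 9:r_HC 10:eta (CHIP titration relaxation rate; only used when titrate=true)

static inline double chip_phi(double M, double H, double a) {
  double den = a * M + H;
  if (den <= 0.0) return 0.0;
  return a * M / den;
}

// Seven-process rate law; Fd is the delayed active-HSF1 value F(t - tau).
static inline void rates(const double *y, double Fd, const double *par,
                         bool stress, bool titrate, double s, double *dy) {
  double H = y[0], HF = y[1], F = y[2], M = y[3], C = y[4];
  double phi = chip_phi(M, H, par[8]);
  double syn = (Fd > 0.0) ? par[0] * Fd / (par[1] + Fd) : 0.0;
  double gen = par[6] * (stress ? s : 1.0);
  double assoc = par[7] * H * F;   // HSF1 inactivation (forms HF)
  double rel = par[5] * M * HF;    // MFP-driven HSF1 release
  dy[3] = gen - par[2] * H * M - par[3] * C * phi * M;
  dy[1] = assoc - rel;
  dy[0] = syn - par[4] * C * (1.0 - phi) * H - assoc + rel;
  dy[2] = -dy[1];
  dy[4] = titrate ? par[10] * (H / par[9] - C) : 0.0;
}

// Fixed-step RK4 method of steps for the single-constant-lag system.
// The lag must be an exact multiple of the step: tau = lag_steps * h.
// Delayed F at off-node stage times is cubic-Hermite interpolated from the
// stored node values and node derivatives. History before t0 is the
// constant value F_hist (pre-equilibrated baseline).
// Stress is active for node indices in [stress_start_idx, stress_end_idx).
// [[Rcpp::export]]
NumericMatrix hsr_integrate_cpp(NumericVector y0, NumericVector par,
                                double t0, int n_steps, double h,
                                int lag_steps, int stress_start_idx,
                                int stress_end_idx, double s,
                                double F_hist, int stride, bool titrate) {
  if (y0.size() != 5) stop("y0 must have 5 components (H, HF, F, M, C)");
  if (lag_steps < 1) stop("lag must be at least one step");
  std::vector<double> Fn(n_steps + 1), dFn(n_steps + 1);
  double y[5], yt[5], k1[5], k2[5], k3[5], k4[5];
  for (int i = 0; i < 5; ++i) y[i] = y0[i];
  Fn[0] = y[2];
  int n_out = n_steps / stride + 1;
  NumericMatrix out(n_out, 7);
  int row = 0;

  auto node_F = [&](int j) { return j < 0 ? F_hist : Fn[j]; };
  auto mid_F = [&](int j) {
    // F(t_j + h/2) via Hermite on [j, j+1]; constant history before t0
    if (j < -1) return F_hist;
    if (j == -1) return 0.5 * (F_hist + Fn[0]) + h * (0.0 - dFn[0]) / 8.0;
    return 0.5 * (Fn[j] + Fn[j + 1]) + h * (dFn[j] - dFn[j + 1]) / 8.0;
  };

  for (int n = 0; n <= n_steps; ++n) {
    bool stress = (n >= stress_start_idx && n < stress_end_idx);
    rates(y, node_F(n - lag_steps), &par[0], stress, titrate, s, k1);
    dFn[n] = k1[2];
    if (n % stride == 0) {
      out(row, 0) = t0 + n * h;
      for (int i = 0; i < 5; ++i) out(row, i + 1) = y[i];
      out(row, 6) = stress ? 1.0 : 0.0;
      ++row;
    }
    if (n == n_steps) break;
    for (int i = 0; i < 5; ++i) {
      if (!R_finite(y[i])) stop("non-finite state at t = %f", t0 + n * h);
    }
    double Fmid = mid_F(n - lag_steps);
    double Fend = node_F(n + 1 - lag_steps);
    for (int i = 0; i < 5; ++i) yt[i] = y[i] + 0.5 * h * k1[i];
    rates(yt, Fmid, &par[0], stress, titrate, s, k2);
    for (int i = 0; i < 5; ++i) yt[i] = y[i] + 0.5 * h * k2[i];
    rates(yt, Fmid, &par[0], stress, titrate, s, k3);
    for (int i = 0; i < 5; ++i) yt[i] = y[i] + h * k3[i];
    rates(yt, Fend, &par[0], stress, titrate, s, k4);
    for (int i = 0; i < 5; ++i)
      y[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    Fn[n + 1] = y[2];
  }
  colnames(out) = CharacterVector::create("time", "H", "HF", "F", "M", "C",
                                          "stress_on");
  return out;
}
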