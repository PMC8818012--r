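#include <Rcpp.h>
using namespace Rcpp;

// Epileptor neural-field right-hand side and Heun integrator.
//
// State per vertex: u1, u2, v, q1, q2, g.  The memory integral of the
// original formulation is differentiated into the auxiliary state g:
//   dg/dt = a12*u1 + gamma12*(w12 * S(u1, theta12)) - g/(tau_s*tau_12).
// Spatial coupling is a sparse kernel in CSC form (Matrix::dgCMatrix
// slots) applied to Heaviside-thresholded activity; S(u, theta) = 1 for
// u >= theta (threshold included).

struct Params {
  double tau_s, tau_0, tau_2, tau_12;
  double I1, I2, a12;
  double g11, g12, g22;
  double th11, th12, th22;
};

static inline void spmv_indicator(const IntegerVector &p, const IntegerVector &i,
                                  const NumericVector &x, const NumericVector &u,
                                  double theta, std::vector<double> &out) {
  // out = K %*% (u >= theta); K in CSC (column j scattered into rows)
  std::fill(out.begin(), out.end(), 0.0);
  const int n = u.size();
  for (int j = 0; j < n; ++j) {
    if (u[j] >= theta) {
      for (int k = p[j]; k < p[j + 1]; ++k) out[i[k]] += x[k];
    }
  }
}

static inline double f1(double u1, double q1, double v) {
  if (u1 < 0.0) return u1 * u1 * u1 - 3.0 * u1 * u1;
  double d = v - 4.0;
  return (q1 - 0.6 * d * d) * u1;
}

static inline double f2(double q1) {
  return (q1 < -0.25) ? 0.0 : 6.0 * (q1 + 0.25);
}

static void rhs(const std::vector<double> &u1, const std::vector<double> &u2,
                const std::vector<double> &v, const std::vector<double> &q1,
                const std::vector<double> &q2, const std::vector<double> &g,
                const NumericVector &u0, const Params &pr, bool coupled,
                const IntegerVector &kp, const IntegerVector &ki, const NumericVector &kx,
                std::vector<double> &c11, std::vector<double> &c12, std::vector<double> &c22,
                std::vector<double> &du1, std::vector<double> &du2, std::vector<double> &dv,
                std::vector<double> &dq1, std::vector<double> &dq2, std::vector<double> &dg) {
  const int n = u1.size();
  if (coupled) {
    NumericVector u1v(u1.begin(), u1.end());
    NumericVector q1v(q1.begin(), q1.end());
    spmv_indicator(kp, ki, kx, u1v, pr.th11, c11);
    if (pr.th12 == pr.th11) c12 = c11;
    else spmv_indicator(kp, ki, kx, u1v, pr.th12, c12);
    spmv_indicator(kp, ki, kx, q1v, pr.th22, c22);
  }
  for (int m = 0; m < n; ++m) {
    double k11 = coupled ? pr.g11 * c11[m] : 0.0;
    double k12 = coupled ? pr.g12 * c12[m] : 0.0;
    double k22 = coupled ? pr.g22 * c22[m] : 0.0;
    du1[m] = (u2[m] - f1(u1[m], q1[m], v[m]) - v[m] + pr.I1 + k11) / pr.tau_s;
    du2[m] = (1.0 - 5.0 * u1[m] * u1[m] - u2[m]) / pr.tau_s;
    dv[m]  = (4.0 * (u1[m] - u0[m]) - v[m]) / (pr.tau_s * pr.tau_0);
    dq1[m] = (-q2[m] + q1[m] - q1[m] * q1[m] * q1[m] + pr.I2 + 0.002 * g[m]
              - 0.3 * (v[m] - 3.5) + k22) / pr.tau_s;
    dq2[m] = (-q2[m] + f2(q1[m])) / (pr.tau_s * pr.tau_2);
    dg[m]  = pr.a12 * u1[m] + k12 - g[m] / (pr.tau_s * pr.tau_12);
  }
}

static Params unpack(const List &params) {
  Params pr;
  pr.tau_s = params["tau_s"]; pr.tau_0 = params["tau_0"];
  pr.tau_2 = params["tau_2"]; pr.tau_12 = params["tau_12"];
  pr.I1 = params["I_1"]; pr.I2 = params["I_2"]; pr.a12 = params["a_12"];
  pr.g11 = params["gamma_11"]; pr.g12 = params["gamma_12"]; pr.g22 = params["gamma_22"];
  pr.th11 = params["theta_11"]; pr.th12 = params["theta_12"]; pr.th22 = params["theta_22"];
  return pr;
}

// [[Rcpp::export(name = ".heun_field_cpp")]]
List heun_field_cpp(NumericMatrix state0, NumericVector u0, List params,
                    double dt, double n_steps_d, int record_every,
                    Nullable<List> kernel, bool record_u1, bool record_q1,
                    IntegerVector stop_vertices, double stop_threshold,
                    double stop_extra_ms) {
  const int n = state0.nrow();
  const R_xlen_t n_steps = (R_xlen_t)n_steps_d;
  Params pr = unpack(params);

  bool coupled = kernel.isNotNull();
  IntegerVector kp, ki; NumericVector kx;
  if (coupled) {
    List kl(kernel);
    kp = kl["p"]; ki = kl["i"]; kx = kl["x"];
  }

  std::vector<double> u1(n), u2(n), v(n), q1(n), q2(n), g(n);
  for (int m = 0; m < n; ++m) {
    u1[m] = state0(m, 0); u2[m] = state0(m, 1); v[m] = state0(m, 2);
    q1[m] = state0(m, 3); q2[m] = state0(m, 4); g[m] = state0(m, 5);
  }

  std::vector<double> c11(n), c12(n), c22(n);
  std::vector<double> du1(n), du2(n), dv(n), dq1(n), dq2(n), dg(n);
  std::vector<double> pu1(n), pu2(n), pv(n), pq1(n), pq2(n), pg(n);
  std::vector<double> e1(n), e2(n), e3(n), e4(n), e5(n), e6(n);

  R_xlen_t n_rec = n_steps / record_every + 1;
  NumericMatrix s_rec(n_rec, n);
  NumericMatrix u1_rec(record_u1 ? n_rec : 0, record_u1 ? n : 0);
  NumericMatrix q1_rec(record_q1 ? n_rec : 0, record_q1 ? n : 0);
  NumericVector t_rec(n_rec);

  R_xlen_t irec = 0;
  for (int m = 0; m < n; ++m) s_rec(0, m) = q1[m] - u1[m];
  if (record_u1) for (int m = 0; m < n; ++m) u1_rec(0, m) = u1[m];
  if (record_q1) for (int m = 0; m < n; ++m) q1_rec(0, m) = q1[m];
  t_rec[0] = 0.0; irec = 1;

  bool stopping = stop_vertices.size() > 0;
  R_xlen_t stop_at = -1;  // step index after which to halt (set once triggered)
  R_xlen_t step_done = 0;

  for (R_xlen_t step = 1; step <= n_steps; ++step) {
    // predictor
    rhs(u1, u2, v, q1, q2, g, u0, pr, coupled, kp, ki, kx,
        c11, c12, c22, du1, du2, dv, dq1, dq2, dg);
    for (int m = 0; m < n; ++m) {
      pu1[m] = u1[m] + dt * du1[m]; pu2[m] = u2[m] + dt * du2[m];
      pv[m] = v[m] + dt * dv[m];    pq1[m] = q1[m] + dt * dq1[m];
      pq2[m] = q2[m] + dt * dq2[m]; pg[m] = g[m] + dt * dg[m];
    }
    // corrector
    rhs(pu1, pu2, pv, pq1, pq2, pg, u0, pr, coupled, kp, ki, kx,
        c11, c12, c22, e1, e2, e3, e4, e5, e6);
    for (int m = 0; m < n; ++m) {
      u1[m] += 0.5 * dt * (du1[m] + e1[m]);
      u2[m] += 0.5 * dt * (du2[m] + e2[m]);
      v[m]  += 0.5 * dt * (dv[m] + e3[m]);
      q1[m] += 0.5 * dt * (dq1[m] + e4[m]);
      q2[m] += 0.5 * dt * (dq2[m] + e5[m]);
      g[m]  += 0.5 * dt * (dg[m] + e6[m]);
    }
    step_done = step;

    if (step % record_every == 0 && irec < n_rec) {
      for (int m = 0; m < n; ++m) s_rec(irec, m) = q1[m] - u1[m];
      if (record_u1) for (int m = 0; m < n; ++m) u1_rec(irec, m) = u1[m];
      if (record_q1) for (int m = 0; m < n; ++m) q1_rec(irec, m) = q1[m];
      t_rec[irec] = step * dt;
      ++irec;
    }

    if (step % 1000 == 0) {
      double mx = 0.0;
      for (int m = 0; m < n; ++m) if (std::fabs(u1[m]) > mx) mx = std::fabs(u1[m]);
      if (mx > 50.0) stop("simulation diverged (|u1| > 50) at t = %f ms", step * dt);
      if (!(u1[0] == u1[0])) stop("non-finite state at t = %f ms", step * dt);
      if (stopping && stop_at < 0) {
        bool all_cross = true;
        for (int k = 0; k < stop_vertices.size(); ++k) {
          if (u1[stop_vertices[k]] < stop_threshold) { all_cross = false; break; }
        }
        if (all_cross) stop_at = step + (R_xlen_t)(stop_extra_ms / dt);
      }
      if (stop_at >= 0 && step >= stop_at) break;
    }
  }

  return List::create(
    _["s"] = s_rec, _["u1"] = u1_rec, _["q1"] = q1_rec, _["t_ms"] = t_rec,
    _["n_recorded"] = (double)irec, _["n_steps_done"] = (double)step_done);
}

// [[Rcpp::export(name = ".heun_fast_subsystem_cpp")]]
List heun_fast_subsystem_cpp(double u1_0, double u2_0, double q1_f, double v_f,
                             List params, double dt, double n_steps_d,
                             int record_every) {
  Params pr = unpack(params);
  const R_xlen_t n_steps = (R_xlen_t)n_steps_d;
  double u1 = u1_0, u2 = u2_0;
  R_xlen_t n_rec = n_steps / record_every + 1;
  NumericVector u1_rec(n_rec), t_rec(n_rec);
  u1_rec[0] = u1; t_rec[0] = 0.0;
  R_xlen_t irec = 1;
  for (R_xlen_t step = 1; step <= n_steps; ++step) {
    double d1 = (u2 - f1(u1, q1_f, v_f) - v_f + pr.I1) / pr.tau_s;
    double d2 = (1.0 - 5.0 * u1 * u1 - u2) / pr.tau_s;
    double pu1 = u1 + dt * d1, pu2 = u2 + dt * d2;
    double e1 = (pu2 - f1(pu1, q1_f, v_f) - v_f + pr.I1) / pr.tau_s;
    double e2 = (1.0 - 5.0 * pu1 * pu1 - pu2) / pr.tau_s;
    u1 += 0.5 * dt * (d1 + e1);
    u2 += 0.5 * dt * (d2 + e2);
    if (step % record_every == 0 && irec < n_rec) {
      u1_rec[irec] = u1; t_rec[irec] = step * dt; ++irec;
    }
    if (u1 != u1 || std::fabs(u1) > 1e3)
      stop("fast-subsystem integration diverged at t = %f ms", step * dt);
  }
  return List::create(_["u1"] = u1_rec, _["t_ms"] = t_rec,
                      _["n_recorded"] = (double)irec);
}
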