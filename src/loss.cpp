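// Fused evaluation of the data, physics, and scale-regularization losses of
// the delay-distribution estimator, together with analytic gradients with
// respect to the per-trace decoder outputs (omega, omega', s, lambda_b,
// lambda_d).  All kernel quantities use the closed-form shifted Rayleigh
// pdf/cdf, so the physics residual needs no numerical integration; the time
// derivative of the reconstruction is the closed-form mixture density.
//
//   yhat_i(t)   = sum_j omega'_ij F(t; c_j, s_ij)
//   r_i(t)      = sum_j omega'_ij f(t) - lb_i sum_j omega_ij F(t)
//                 + ld_i sum_j omega'_ij F(t)
//   L_data      = 1/(N d) sum |yhat - y|
//   L_phys      = 1/(N C) sum |r|
//   L_scale     = 1/(N M) sum |s - starget|
//
// Gradients are for the weighted sum wd*L_data + wp*L_phys + ws*L_scale.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline void kernel_eval(double t, double c, double s,
                               double& F, double& f) {
  double u = t - c;
  if (u <= 0.0) { F = 0.0; f = 0.0; return; }
  double q = u * u / (2.0 * s * s);
  double E = std::exp(-q);
  F = 1.0 - E;
  f = u / (s * s) * E;
}

// [[Rcpp::export(name = ".dpinn_loss_cpp")]]
List dpinn_loss_cpp(NumericMatrix y,        // N x d (internal scale)
                    NumericVector tgrid,    // d
                    NumericVector centers,  // M
                    NumericVector coll,     // C collocation points
                    NumericMatrix omega,    // N x M
                    NumericMatrix omegap,   // N x M
                    NumericMatrix s,        // N x M
                    NumericVector lb,       // N
                    NumericVector ld,       // N
                    NumericMatrix starget,  // N x M
                    double wd, double wp, double ws,
                    bool fixed_ld) {
  const int N = y.nrow(), d = y.ncol(), M = centers.size(), C = coll.size();
  if (omega.nrow() != N || omega.ncol() != M) stop("omega shape mismatch");
  if (omegap.nrow() != N || omegap.ncol() != M) stop("omega' shape mismatch");
  if (s.nrow() != N || s.ncol() != M) stop("s shape mismatch");
  if (starget.nrow() != N || starget.ncol() != M) stop("starget shape mismatch");
  if (lb.size() != N || ld.size() != N) stop("rate vector length mismatch");

  NumericMatrix yhat(N, d);
  NumericMatrix g_omega(N, M), g_omegap(N, M), g_s(N, M);
  NumericVector g_lb(N), g_ld(N);
  double L_data = 0.0, L_phys = 0.0, L_scale = 0.0;

  std::vector<double> Fg(M * d), fc(M * C), Fc(M * C);

  for (int i = 0; i < N; ++i) {
    // kernel tables for trace i
    for (int j = 0; j < M; ++j) {
      double cj = centers[j], sij = s(i, j);
      for (int l = 0; l < d; ++l) {
        double F, f;
        kernel_eval(tgrid[l], cj, sij, F, f);
        Fg[j * d + l] = F;
      }
      for (int p = 0; p < C; ++p) {
        double F, f;
        kernel_eval(coll[p], cj, sij, F, f);
        Fc[j * C + p] = F;
        fc[j * C + p] = f;
      }
    }
    // ---- data loss on the observation grid
    for (int l = 0; l < d; ++l) {
      double yh = 0.0;
      for (int j = 0; j < M; ++j) yh += omegap(i, j) * Fg[j * d + l];
      yhat(i, l) = yh;
      double e = yh - y(i, l);
      L_data += std::fabs(e);
      if (e != 0.0) {
        double sg = (e > 0 ? 1.0 : -1.0) * wd / (double)(N * d);
        for (int j = 0; j < M; ++j) {
          double u = tgrid[l] - centers[j];
          if (u <= 0.0) continue;
          double F = Fg[j * d + l], sij = s(i, j);
          double dFds = -(1.0 - F) * u * u / (sij * sij * sij);
          g_omegap(i, j) += sg * F;
          g_s(i, j) += sg * omegap(i, j) * dFds;
        }
      }
    }
    // ---- physics loss at collocation points
    for (int p = 0; p < C; ++p) {
      double P = 0.0, Q = 0.0, Yc = 0.0;
      for (int j = 0; j < M; ++j) {
        P += omegap(i, j) * fc[j * C + p];
        Q += omega(i, j) * Fc[j * C + p];
        Yc += omegap(i, j) * Fc[j * C + p];
      }
      double r = P - lb[i] * Q + ld[i] * Yc;
      L_phys += std::fabs(r);
      if (r != 0.0) {
        double sg = (r > 0 ? 1.0 : -1.0) * wp / (double)(N * C);
        g_lb[i] -= sg * Q;
        if (!fixed_ld) g_ld[i] += sg * Yc;
        for (int j = 0; j < M; ++j) {
          double u = coll[p] - centers[j];
          double F = Fc[j * C + p], f = fc[j * C + p], sij = s(i, j);
          g_omegap(i, j) += sg * (f + ld[i] * F);
          g_omega(i, j) -= sg * lb[i] * F;
          if (u > 0.0) {
            double dFds = -(1.0 - F) * u * u / (sij * sij * sij);
            double dfds = (f / sij) * (u * u / (sij * sij) - 2.0);
            g_s(i, j) += sg * (omegap(i, j) * dfds +
                               (ld[i] * omegap(i, j) - lb[i] * omega(i, j)) * dFds);
          }
        }
      }
    }
    // ---- scale regularization
    for (int j = 0; j < M; ++j) {
      double e = s(i, j) - starget(i, j);
      L_scale += std::fabs(e);
      if (e != 0.0)
        g_s(i, j) += (e > 0 ? 1.0 : -1.0) * ws / (double)(N * M);
    }
  }
  L_data /= (double)(N * d);
  L_phys /= (double)(N * C);
  L_scale /= (double)(N * M);

  return List::create(_["data"] = L_data, _["physics"] = L_phys,
                      _["scale_reg"] = L_scale, _["yhat"] = yhat,
                      _["g_omega"] = g_omega, _["g_omegap"] = g_omegap,
                      _["g_s"] = g_s, _["g_lb"] = g_lb, _["g_ld"] = g_ld);
}
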