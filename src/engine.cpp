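// Overdamped (Brownian) dynamics engine with uniform potential scaling,
// Ratchet&Pawl bias and well-tempered metadynamics on a coordinate or on
// path collective variables.  Potential kinds mirror the R-side
// model_potential() constructors; parameters arrive packed in a numeric
// vector so the inner loop never calls back into R.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double KB = 0.0019872041; // kcal/mol/K

// ---- potential dispatch ----------------------------------------------------
// kind 1 harmonic  : params = [d, k_1..k_d, c_1..c_d]
// kind 2 dwell1d   : params = [h, a, eps]; U = h*((x^2-a^2)/a^2)^2 + eps*x/(2a)
// kind 3 mueller   : params = [scale, A1..A4, a1..a4, b1..b4, c1..c4,
//                              x01..x04, y01..y04]
// kind 4 egress    : params = [r_b, kappa, D, r_w, b_base, n_ch,
//                              (theta_j, amp_j) x n_ch]
static double pot_energy(int kind, const double* p, const double* x, int dim) {
  if (kind == 1) {
    int d = (int)p[0];
    double u = 0.0;
    for (int i = 0; i < d; ++i) {
      double dx = x[i] - p[1 + d + i];
      u += 0.5 * p[1 + i] * dx * dx;
    }
    return u;
  } else if (kind == 2) {
    double h = p[0], a = p[1], eps = p[2];
    double q = (x[0] * x[0] - a * a) / (a * a);
    return h * q * q + eps * x[0] / (2.0 * a);
  } else if (kind == 3) {
    double u = 0.0;
    for (int j = 0; j < 4; ++j) {
      double A = p[1 + j], aa = p[5 + j], bb = p[9 + j], cc = p[13 + j];
      double dx = x[0] - p[17 + j], dy = x[1] - p[21 + j];
      u += A * std::exp(aa * dx * dx + bb * dx * dy + cc * dy * dy);
    }
    return p[0] * u;
  } else if (kind == 4) {
    double r_b = p[0], kappa = p[1], D = p[2], r_w = p[3], b_base = p[4];
    int n_ch = (int)p[5];
    double r2 = x[0] * x[0] + x[1] * x[1];
    double r = std::sqrt(r2);
    double u_r = r2 / (r_b * r_b);
    double f = u_r * std::exp(1.0 - u_r);
    double B = b_base;
    if (r > 1e-12) {
      double theta = std::atan2(x[1], x[0]);
      for (int j = 0; j < n_ch; ++j)
        B -= p[7 + 2 * j] * std::exp(kappa * (std::cos(theta - p[6 + 2 * j]) - 1.0));
    }
    double W = 0.0;
    if (r < r_w) {
      double q = 1.0 - r2 / (r_w * r_w);
      W = -D * q * q;
    }
    return B * f + W;
  }
  return NA_REAL;
}

static void pot_gradient(int kind, const double* p, const double* x, int dim,
                         double* g) {
  if (kind == 1) {
    int d = (int)p[0];
    for (int i = 0; i < d; ++i) g[i] = p[1 + i] * (x[i] - p[1 + d + i]);
  } else if (kind == 2) {
    double h = p[0], a = p[1], eps = p[2];
    double q = (x[0] * x[0] - a * a) / (a * a);
    g[0] = h * 2.0 * q * (2.0 * x[0] / (a * a)) + eps / (2.0 * a);
  } else if (kind == 3) {
    g[0] = 0.0; g[1] = 0.0;
    for (int j = 0; j < 4; ++j) {
      double A = p[1 + j], aa = p[5 + j], bb = p[9 + j], cc = p[13 + j];
      double dx = x[0] - p[17 + j], dy = x[1] - p[21 + j];
      double e = A * std::exp(aa * dx * dx + bb * dx * dy + cc * dy * dy);
      g[0] += e * (2.0 * aa * dx + bb * dy);
      g[1] += e * (bb * dx + 2.0 * cc * dy);
    }
    g[0] *= p[0]; g[1] *= p[0];
  } else if (kind == 4) {
    double r_b = p[0], kappa = p[1], D = p[2], r_w = p[3], b_base = p[4];
    int n_ch = (int)p[5];
    double r2 = x[0] * x[0] + x[1] * x[1];
    double r = std::sqrt(r2);
    g[0] = 0.0; g[1] = 0.0;
    if (r < 1e-12) return; // smooth stationary point at the origin
    double u_r = r2 / (r_b * r_b);
    double ex = std::exp(1.0 - u_r);
    double f = u_r * ex;
    double fp = ex * (2.0 * r / (r_b * r_b)) * (1.0 - u_r); // df/dr
    double theta = std::atan2(x[1], x[0]);
    double B = b_base, Bp = 0.0;
    for (int j = 0; j < n_ch; ++j) {
      double e = std::exp(kappa * (std::cos(theta - p[6 + 2 * j]) - 1.0));
      B -= p[7 + 2 * j] * e;
      Bp += p[7 + 2 * j] * e * kappa * std::sin(theta - p[6 + 2 * j]);
    }
    double Wp = 0.0;
    if (r < r_w) {
      double q = 1.0 - r2 / (r_w * r_w);
      Wp = D * q * (4.0 * r / (r_w * r_w)); // dW/dr
    }
    double dUdr = B * fp + Wp;
    double cx = x[0] / r, cy = x[1] / r;
    // dtheta/dx = -y/r^2, dtheta/dy = x/r^2
    g[0] = dUdr * cx + Bp * f * (-x[1] / r2);
    g[1] = dUdr * cy + Bp * f * (x[0] / r2);
  }
}

// [[Rcpp::export]]
double pot_energy_cpp(int kind, NumericVector params, NumericVector x) {
  return pot_energy(kind, params.begin(), x.begin(), x.size());
}

// [[Rcpp::export]]
NumericVector pot_gradient_cpp(int kind, NumericVector params, NumericVector x) {
  NumericVector g(x.size());
  pot_gradient(kind, params.begin(), x.begin(), x.size(), g.begin());
  return g;
}

// ---- path collective variables --------------------------------------------
// msd(x, X_i) = |x - X_i|^2 / dim ; weights w_i = exp(-lambda msd_i) (log-sum-
// exp guarded); s = sum i w_i / sum w_i in [1, N]; z = -(1/lambda) log sum.
struct PathCVOut {
  double s, z;
  std::vector<double> ds, dz;
};

static void pathcv_eval(const double* x, int dim, const double* ref, int nref,
                        double lambda, PathCVOut& out, bool want_grad) {
  std::vector<double> msd(nref);
  double mmin = R_PosInf;
  for (int i = 0; i < nref; ++i) {
    double acc = 0.0;
    for (int d = 0; d < dim; ++d) {
      double dv = x[d] - ref[i + (size_t)nref * d];
      acc += dv * dv;
    }
    msd[i] = acc / dim;
    if (msd[i] < mmin) mmin = msd[i];
  }
  double sw = 0.0, siw = 0.0;
  std::vector<double> w(nref);
  for (int i = 0; i < nref; ++i) {
    w[i] = std::exp(-lambda * (msd[i] - mmin));
    sw += w[i];
    siw += (i + 1.0) * w[i];
  }
  out.s = siw / sw;
  out.z = mmin - std::log(sw) / lambda;
  if (!want_grad) return;
  out.ds.assign(dim, 0.0);
  out.dz.assign(dim, 0.0);
  for (int i = 0; i < nref; ++i) {
    double wi = w[i] / sw;
    for (int d = 0; d < dim; ++d) {
      double dmsd = 2.0 * (x[d] - ref[i + (size_t)nref * d]) / dim;
      out.ds[d] += -lambda * ((i + 1.0) - out.s) * wi * dmsd;
      out.dz[d] += wi * dmsd;
    }
  }
}

// [[Rcpp::export]]
List pathcv_eval_cpp(NumericVector x, NumericMatrix ref, double lambda) {
  PathCVOut out;
  pathcv_eval(x.begin(), x.size(), ref.begin(), ref.nrow(), lambda, out, true);
  return List::create(_["s"] = out.s, _["z"] = out.z,
                      _["ds"] = NumericVector(out.ds.begin(), out.ds.end()),
                      _["dz"] = NumericVector(out.dz.begin(), out.dz.end()));
}

// ---- metadynamics bias grid ------------------------------------------------
// The bias and its CV-gradient are accumulated on a regular grid (6 sigma
// deposit cutoff, bilinear interpolation) so the per-step cost is O(1); the
// deposition height itself uses the exact analytic sum over the ledger, so
// recorded hill heights obey the well-tempered recursion exactly.
struct MetadGrid {
  int ncv;
  int n1, n2;
  double lo1, hi1, d1, lo2, hi2, d2;
  std::vector<double> V, dV1, dV2;
  void init(int ncv_, double lo1_, double hi1_, int n1_, double lo2_,
            double hi2_, int n2_) {
    ncv = ncv_; n1 = n1_; lo1 = lo1_; hi1 = hi1_;
    d1 = (hi1 - lo1) / (n1 - 1);
    if (ncv == 2) {
      n2 = n2_; lo2 = lo2_; hi2 = hi2_; d2 = (hi2 - lo2) / (n2 - 1);
    } else { n2 = 1; lo2 = 0; hi2 = 0; d2 = 1; }
    V.assign((size_t)n1 * n2, 0.0);
    dV1.assign((size_t)n1 * n2, 0.0);
    dV2.assign((size_t)n1 * n2, 0.0);
  }
  void deposit(double c1, double c2, double s1, double s2, double h) {
    int i_lo = std::max(0, (int)std::floor((c1 - 6.0 * s1 - lo1) / d1));
    int i_hi = std::min(n1 - 1, (int)std::ceil((c1 + 6.0 * s1 - lo1) / d1));
    int j_lo = 0, j_hi = 0;
    if (ncv == 2) {
      j_lo = std::max(0, (int)std::floor((c2 - 6.0 * s2 - lo2) / d2));
      j_hi = std::min(n2 - 1, (int)std::ceil((c2 + 6.0 * s2 - lo2) / d2));
    }
    for (int i = i_lo; i <= i_hi; ++i) {
      double u1 = (lo1 + i * d1 - c1) / s1;
      double g1 = std::exp(-0.5 * u1 * u1);
      for (int j = j_lo; j <= j_hi; ++j) {
        double g = g1, u2 = 0.0;
        if (ncv == 2) {
          u2 = (lo2 + j * d2 - c2) / s2;
          g *= std::exp(-0.5 * u2 * u2);
        }
        size_t idx = (size_t)j * n1 + i;
        V[idx] += h * g;
        dV1[idx] += h * g * (-u1 / s1);
        if (ncv == 2) dV2[idx] += h * g * (-u2 / s2);
      }
    }
  }
  // bilinear interpolation; clamped outside the grid
  void query(double c1, double c2, double& v, double& g1, double& g2) const {
    double t1 = (c1 - lo1) / d1;
    int i = std::max(0, std::min(n1 - 2, (int)std::floor(t1)));
    double f1 = std::max(0.0, std::min(1.0, t1 - i));
    int j = 0; double f2 = 0.0;
    if (ncv == 2) {
      double t2 = (c2 - lo2) / d2;
      j = std::max(0, std::min(n2 - 2, (int)std::floor(t2)));
      f2 = std::max(0.0, std::min(1.0, t2 - j));
    }
    size_t i00 = (size_t)j * n1 + i;
    size_t i10 = i00 + 1;
    size_t i01 = (ncv == 2) ? i00 + n1 : i00;
    size_t i11 = (ncv == 2) ? i10 + n1 : i10;
    double w00 = (1 - f1) * (1 - f2), w10 = f1 * (1 - f2);
    double w01 = (1 - f1) * f2, w11 = f1 * f2;
    v  = w00 * V[i00] + w10 * V[i10] + w01 * V[i01] + w11 * V[i11];
    g1 = w00 * dV1[i00] + w10 * dV1[i10] + w01 * dV1[i01] + w11 * dV1[i11];
    g2 = (ncv == 2)
       ? w00 * dV2[i00] + w10 * dV2[i10] + w01 * dV2[i01] + w11 * dV2[i11]
       : 0.0;
  }
};

// ---- main engine -----------------------------------------------------------
// [[Rcpp::export]]
List engine_run(int pot_kind, NumericVector pot_params, NumericVector x0,
                NumericMatrix domain,
                double dt, double temperature, double friction,
                double beta_scale, int n_steps, int save_stride,
                bool use_rpp, double rpp_k, NumericVector rpp_dir,
                NumericVector rpp_origin, double rpp_target, bool rpp_radial,
                int stop_kind, NumericVector stop_normal, double stop_offset,
                int stop_grace,
                bool use_metad, int cv_kind, int cv_index,
                NumericMatrix cv_ref, double cv_lambda,
                double omega0, double sigma1, double sigma2, double bias_factor,
                int hill_stride, NumericVector grid_lo, NumericVector grid_hi) {
  int dim = x0.size();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> g(dim), gb(dim);
  int n_saved_max = n_steps / save_stride + 1;
  NumericMatrix frames(n_saved_max, dim);
  NumericVector times(n_saved_max);
  int ncv = 0;
  if (use_metad) ncv = (cv_kind == 2) ? 2 : 1;
  // colvar log per saved frame: [cv1, cv2, metad bias, rpp s, rho, rho_best, rpp V]
  NumericMatrix clog(n_saved_max, 7);
  std::fill(clog.begin(), clog.end(), NA_REAL);

  double kT = KB * temperature;
  double noise_amp = std::sqrt(2.0 * kT * dt / friction);
  double mob = dt / friction;

  // RPP state
  double rho_best = R_PosInf;
  double rpp_work = 0.0;

  // metad state
  MetadGrid grid;
  std::vector<double> h_time, h_c1, h_c2, h_height;
  double dT = (bias_factor - 1.0) * temperature;
  if (use_metad) {
    int n1 = std::max(2, (int)std::ceil((grid_hi[0] - grid_lo[0]) / (sigma1 / 5.0))) + 1;
    int n2 = 2;
    if (ncv == 2)
      n2 = std::max(2, (int)std::ceil((grid_hi[1] - grid_lo[1]) / (sigma2 / 5.0))) + 1;
    grid.init(ncv, grid_lo[0], grid_hi[0], n1,
              ncv == 2 ? grid_lo[1] : 0.0, ncv == 2 ? grid_hi[1] : 0.0, n2);
  }

  int saved = 0;
  bool exited = false;
  int exit_step = NA_INTEGER;
  int pending_stop = -1; // step at which predicate first held (grace logic)
  PathCVOut cv;

  auto eval_cv = [&](bool want_grad) {
    if (cv_kind == 2) {
      pathcv_eval(x.data(), dim, cv_ref.begin(), cv_ref.nrow(), cv_lambda, cv,
                  want_grad);
    } else {
      cv.s = x[cv_index - 1];
      cv.z = 0.0;
      if (want_grad) {
        cv.ds.assign(dim, 0.0);
        cv.ds[cv_index - 1] = 1.0;
        cv.dz.assign(dim, 0.0);
      }
    }
  };

  auto exact_bias_at = [&](double c1, double c2) {
    double v = 0.0;
    for (size_t k = 0; k < h_height.size(); ++k) {
      double u1 = (c1 - h_c1[k]) / sigma1;
      double e = -0.5 * u1 * u1;
      if (ncv == 2) {
        double u2 = (c2 - h_c2[k]) / sigma2;
        e += -0.5 * u2 * u2;
      }
      v += h_height[k] * std::exp(e);
    }
    return v;
  };

  double rpp_s = NA_REAL, rho = NA_REAL, rpp_V = NA_REAL;
  double mbias = NA_REAL;

  for (int step = 0; step <= n_steps; ++step) {
    // forces at current position
    pot_gradient(pot_kind, pot_params.begin(), x.data(), dim, g.data());
    double U = pot_energy(pot_kind, pot_params.begin(), x.data(), dim);
    if (!std::isfinite(U)) stop("non-finite potential energy at step %d", step);
    for (int d = 0; d < dim; ++d) g[d] *= beta_scale;

    // Ratchet&Pawl (pawl update after force evaluation)
    if (use_rpp) {
      if (rpp_radial) {
        double acc = 0.0;
        for (int d = 0; d < dim; ++d) {
          double dv = x[d] - rpp_origin[d];
          acc += dv * dv;
        }
        rpp_s = std::sqrt(acc);
      } else {
        rpp_s = 0.0;
        for (int d = 0; d < dim; ++d) rpp_s += (x[d] - rpp_origin[d]) * rpp_dir[d];
      }
      double dd = rpp_s - rpp_target;
      rho = dd * dd;
      if (step == 0 && !std::isfinite(rho_best)) rho_best = rho;
      rpp_V = 0.0;
      if (rho > rho_best) {
        double dr = rho - rho_best;
        rpp_V = 0.5 * rpp_k * dr * dr;
        double dVds = rpp_k * dr * 2.0 * dd; // dV/ds via chain rule
        if (rpp_radial) {
          double r = std::max(rpp_s, 1e-12);
          for (int d = 0; d < dim; ++d)
            g[d] += dVds * (x[d] - rpp_origin[d]) / r;
        } else {
          for (int d = 0; d < dim; ++d) g[d] += dVds * rpp_dir[d];
        }
        rpp_work += rpp_V;
      }
      if (rho < rho_best) rho_best = rho;
    }

    // metadynamics
    if (use_metad) {
      eval_cv(true);
      if (step > 0 && step % hill_stride == 0) {
        double Vh = exact_bias_at(cv.s, cv.z);
        double h = omega0 * std::exp(-Vh / (KB * dT));
        h_time.push_back(step * dt);
        h_c1.push_back(cv.s);
        h_c2.push_back(cv.z);
        h_height.push_back(h);
        grid.deposit(cv.s, ncv == 2 ? cv.z : 0.0, sigma1, sigma2, h);
      }
      double gv1, gv2;
      grid.query(cv.s, ncv == 2 ? cv.z : 0.0, mbias, gv1, gv2);
      for (int d = 0; d < dim; ++d) {
        g[d] += gv1 * cv.ds[d];
        if (ncv == 2) g[d] += gv2 * cv.dz[d];
      }
    }

    // record
    if (step % save_stride == 0) {
      for (int d = 0; d < dim; ++d) frames(saved, d) = x[d];
      times[saved] = step * dt;
      if (use_metad) { clog(saved, 0) = cv.s; clog(saved, 1) = cv.z; clog(saved, 2) = mbias; }
      if (use_rpp) {
        clog(saved, 3) = rpp_s; clog(saved, 4) = rho;
        clog(saved, 5) = rho_best; clog(saved, 6) = rpp_V;
      }
      ++saved;
    }

    // stop predicate with one-step grace confirmation
    if (stop_kind > 0) {
      bool hold;
      if (stop_kind == 1) { // halfspace
        double s = 0.0;
        for (int d = 0; d < dim; ++d) s += x[d] * stop_normal[d];
        hold = s > stop_offset;
      } else { // radius from origin of rpp (or 0)
        double acc = 0.0;
        for (int d = 0; d < dim; ++d) {
          double dv = x[d] - (use_rpp ? rpp_origin[d] : 0.0);
          acc += dv * dv;
        }
        hold = std::sqrt(acc) > stop_offset;
      }
      if (hold) {
        if (pending_stop < 0) pending_stop = step;
        if (step - pending_stop >= stop_grace) {
          exited = true;
          exit_step = step;
          break;
        }
      } else {
        pending_stop = -1;
      }
    }

    if (step == n_steps) break;

    // Euler-Maruyama update with reflective domain boundaries
    for (int d = 0; d < dim; ++d) {
      x[d] += -mob * g[d] + noise_amp * norm_rand();
      double lo = domain(0, d), hi = domain(1, d);
      if (x[d] < lo) x[d] = 2.0 * lo - x[d];
      if (x[d] > hi) x[d] = 2.0 * hi - x[d];
      if (x[d] < lo) x[d] = lo; // pathological large step
      if (x[d] > hi) x[d] = hi;
    }
  }

  NumericMatrix hills(h_height.size(), 4);
  for (size_t k = 0; k < h_height.size(); ++k) {
    hills(k, 0) = h_time[k];
    hills(k, 1) = h_c1[k];
    hills(k, 2) = h_c2[k];
    hills(k, 3) = h_height[k];
  }

  return List::create(
      _["frames"] = frames(Range(0, saved - 1), _),
      _["times"] = times[Range(0, saved - 1)],
      _["colvar"] = clog(Range(0, saved - 1), _),
      _["exited"] = exited, _["exit_step"] = exit_step,
      _["hills"] = hills, _["rpp_work"] = rpp_work,
      _["rho_best"] = rho_best, _["n_saved"] = saved);
}
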