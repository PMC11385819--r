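#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Sample a von Mises(0, kappa) angle by the Best & Fisher (1979) rejection
// scheme, using R's uniform stream so set.seed() governs everything.
static double rvonmises0(double kappa) {
  if (kappa < 1e-8) return unif_rand() * 2.0 * M_PI - M_PI;
  double a = 1.0 + std::sqrt(1.0 + 4.0 * kappa * kappa);
  double b = (a - std::sqrt(2.0 * a)) / (2.0 * kappa);
  double r = (1.0 + b * b) / (2.0 * b);
  for (;;) {
    double u1 = unif_rand();
    double z = std::cos(M_PI * u1);
    double f = (1.0 + r * z) / (r + z);
    double c = kappa * (r - f);
    double u2 = unif_rand();
    if (c * (2.0 - c) - u2 > 0.0 || std::log(c / u2) + 1.0 - c >= 0.0) {
      double u3 = unif_rand();
      return (u3 > 0.5 ? 1.0 : -1.0) * std::acos(f);
    }
  }
}

// One depletion/regeneration update. Occupied cells lose a fraction
// `consumption` of their current value; every cell then relaxes toward its
// baseline at rate `regen`; values stay in [0, baseline].
static void resource_step(std::vector<double> &v, const std::vector<double> &base,
                          const std::vector<int> &occupied,
                          double consumption, double regen) {
  for (size_t k = 0; k < occupied.size(); ++k) {
    int i = occupied[k];
    if (i >= 0) v[i] -= consumption * v[i];
  }
  for (size_t i = 0; i < v.size(); ++i) {
    v[i] += regen * (base[i] - v[i]);
    if (v[i] < 0.0) v[i] = 0.0;
    if (v[i] > base[i]) v[i] = base[i];
  }
}

// [[Rcpp::export]]
NumericVector resource_step_cpp(NumericVector values, NumericVector baseline,
                                IntegerVector occupied, double consumption,
                                double regen) {
  std::vector<double> v(values.begin(), values.end());
  std::vector<double> b(baseline.begin(), baseline.end());
  std::vector<int> occ(occupied.begin(), occupied.end());
  resource_step(v, b, occ, consumption, regen);
  return NumericVector(v.begin(), v.end());
}

// Place a predator encounter relative to a forager at (x, y).
// variant 0 (elusive): uniform position within the perception disc.
// variant 1 (stalking): a resource cell near the forager, drawn with
// probability proportional to current resource value (falls back to the whole
// landscape when no valued cell is nearby).
static void place_encounter(int variant, double x, double y,
                            const std::vector<double> &rx,
                            const std::vector<double> &ry,
                            const std::vector<double> &v,
                            double perception, double stalk_radius,
                            double *ex, double *ey) {
  if (variant == 0) {
    double ang = unif_rand() * 2.0 * M_PI;
    double rad = perception * std::sqrt(unif_rand());
    *ex = x + rad * std::cos(ang);
    *ey = y + rad * std::sin(ang);
    return;
  }
  double r2 = stalk_radius * stalk_radius;
  double tot = 0.0;
  for (size_t i = 0; i < rx.size(); ++i) {
    double dx = rx[i] - x, dy = ry[i] - y;
    if (dx * dx + dy * dy <= r2) tot += v[i];
  }
  bool local = tot > 0.0;
  if (!local) { for (size_t i = 0; i < v.size(); ++i) tot += v[i]; }
  if (tot <= 0.0) { *ex = x; *ey = y; return; }
  double u = unif_rand() * tot, acc = 0.0;
  for (size_t i = 0; i < rx.size(); ++i) {
    if (local) {
      double dx = rx[i] - x, dy = ry[i] - y;
      if (dx * dx + dy * dy > r2) continue;
    }
    acc += v[i];
    if (acc >= u) { *ex = rx[i]; *ey = ry[i]; return; }
  }
  *ex = rx.back(); *ey = ry.back();
}

// [[Rcpp::export]]
NumericVector place_encounter_cpp(int variant, double x, double y,
                                  NumericVector rx, NumericVector ry,
                                  NumericVector values, double perception,
                                  double stalk_radius) {
  std::vector<double> rxx(rx.begin(), rx.end());
  std::vector<double> ryy(ry.begin(), ry.end());
  std::vector<double> v(values.begin(), values.end());
  double ex, ey;
  place_encounter(variant, x, y, rxx, ryy, v, perception, stalk_radius, &ex, &ey);
  return NumericVector::create(ex, ey);
}

struct Forager {
  double x, y, theta;
  std::vector<double> mem;               // remembered value per resource cell
  std::vector<double> ax, ay;            // avoided locations
  std::vector<int> aexp;                 // their expiry steps
  std::vector<double> sx, sy;            // own scent marks
  std::vector<int> sexp;
};

static void reflect(double *x, double *theta_cos_sign, double lo, double hi) {
  // single reflection suffices for speed <= domain size
  if (*x < lo) { *x = 2.0 * lo - *x; *theta_cos_sign = -*theta_cos_sign; }
  if (*x >= hi) { *x = 2.0 * hi - *x; *theta_cos_sign = -*theta_cos_sign; }
  if (*x < lo) *x = lo;                  // guard against double overshoot
  if (*x >= hi) *x = hi - 1e-9;
}

// Continuous correlated biased random walk over a depletable resource grid.
// process: 0 = F (foraging only), 1 = F+Pe (elusive predator),
//          2 = F+Ps (stalking predator), 3 = F+T (territorial foragers).
// Returns one (step, x, y) matrix per forager covering the recorded window
// (positions at steps burn_in .. burn_in + n_record - 1, step re-indexed
// from 0).
// [[Rcpp::export]]
List simulate_cbrw_cpp(NumericVector res_x, NumericVector res_y,
                       NumericVector res_baseline,
                       IntegerVector res_cell_of, int nrows, int ncols,
                       int process, List params, int n_record, int burn_in,
                       NumericVector init_x, NumericVector init_y,
                       NumericVector init_theta) {
  const int nres = res_x.size();
  const int nf = init_x.size();
  const double speed = as<double>(params["speed"]);
  const double kappa = as<double>(params["kappa"]);
  const double mem_decay = as<double>(params["mem_decay"]);
  const double mem_dist = as<double>(params["mem_dist"]);
  const double mem_w = as<double>(params["mem_w"]);
  const double persist_w = as<double>(params["persist_w"]);
  const double perception = as<double>(params["perception_radius"]);
  const double consumption = as<double>(params["consumption"]);
  const double regen = as<double>(params["regen"]);
  const double p_enc = as<double>(params["p_encounter"]);
  const int avoid_duration = as<int>(params["avoid_duration"]);
  const double avoid_w = as<double>(params["avoid_w"]);
  const double avoid_dist = as<double>(params["avoid_dist"]);
  const double flee_dist = as<double>(params["flee_dist"]);
  const int mark_interval = as<int>(params["mark_interval"]);
  const int mark_lifetime = as<int>(params["mark_lifetime"]);
  const double scent_w = as<double>(params["scent_w"]);
  const double scent_dist = as<double>(params["scent_dist"]);

  std::vector<double> rx(res_x.begin(), res_x.end());
  std::vector<double> ry(res_y.begin(), res_y.end());
  std::vector<double> base(res_baseline.begin(), res_baseline.end());
  std::vector<double> v(base);           // current resource values
  // res_cell_of maps a 0-based cell index (col-major, row fastest) to the
  // resource-cell index, or -1 for matrix cells.
  std::vector<int> cellmap(res_cell_of.begin(), res_cell_of.end());

  std::vector<Forager> ff(nf);
  for (int f = 0; f < nf; ++f) {
    ff[f].x = init_x[f]; ff[f].y = init_y[f]; ff[f].theta = init_theta[f];
    ff[f].mem = base;                    // start with knowledge of the field
  }

  const int total = burn_in + n_record;  // recorded positions incl. t = 0
  std::vector<NumericMatrix> out;
  for (int f = 0; f < nf; ++f) out.push_back(NumericMatrix(n_record, 3));
  std::vector<int> occupied(nf);

  for (int t = 0; t < total; ++t) {
    for (int f = 0; f < nf; ++f) {
      Forager &fo = ff[f];
      if (t >= burn_in) {
        int row = t - burn_in;
        out[f](row, 0) = row; out[f](row, 1) = fo.x; out[f](row, 2) = fo.y;
      }
      if (t == total - 1) continue;      // last recorded position: no move

      // predator encounter (before moving), F+Pe / F+Ps only
      if ((process == 1 || process == 2) && unif_rand() < p_enc) {
        double ex, ey;
        place_encounter(process == 1 ? 0 : 1, fo.x, fo.y, rx, ry, v,
                        perception, 2.0 * perception, &ex, &ey);
        fo.ax.push_back(ex); fo.ay.push_back(ey);
        fo.aexp.push_back(t + avoid_duration);
        // flee straight away from the encounter
        double dx = fo.x - ex, dy = fo.y - ey;
        double d = std::sqrt(dx * dx + dy * dy);
        double ang = (d > 1e-12) ? std::atan2(dy, dx)
                                 : unif_rand() * 2.0 * M_PI;
        fo.x += flee_dist * std::cos(ang);
        fo.y += flee_dist * std::sin(ang);
        double dummy = 1.0;
        reflect(&fo.x, &dummy, 0.0, (double)ncols);
        reflect(&fo.y, &dummy, 0.0, (double)nrows);
        fo.theta = ang;
      }

      // scent marking (F+T)
      if (process == 3 && t % mark_interval == 0) {
        fo.sx.push_back(fo.x); fo.sy.push_back(fo.y);
        fo.sexp.push_back(t + mark_lifetime);
      }

      // memory: refresh within perception, then decay
      double p2 = perception * perception;
      for (int i = 0; i < nres; ++i) {
        double dx = rx[i] - fo.x, dy = ry[i] - fo.y;
        if (dx * dx + dy * dy <= p2) fo.mem[i] = v[i];
        fo.mem[i] *= (1.0 - mem_decay);
      }

      // attraction toward remembered resources: weighted resultant of unit
      // vectors (magnitude in [0,1] reflects directional consensus, so a
      // forager surrounded symmetrically by memories feels no net pull)
      double bx = 0.0, by = 0.0, bw = 0.0;
      for (int i = 0; i < nres; ++i) {
        if (fo.mem[i] <= 0.0) continue;
        double dx = rx[i] - fo.x, dy = ry[i] - fo.y;
        double d = std::sqrt(dx * dx + dy * dy);
        if (d < 0.5) continue;           // current cell exerts no pull
        double w = fo.mem[i] * std::exp(-d / mem_dist);
        bx += w * dx / d; by += w * dy / d; bw += w;
      }
      if (bw > 1e-300) { bx /= bw; by /= bw; } else { bx = by = 0.0; }

      // repulsion from avoided encounter locations
      double vx = 0.0, vy = 0.0, vw = 0.0;
      for (size_t j = 0; j < fo.ax.size(); ++j) {
        if (fo.aexp[j] <= t) continue;
        double dx = fo.x - fo.ax[j], dy = fo.y - fo.ay[j];
        double d = std::sqrt(dx * dx + dy * dy);
        if (d < 1e-9) continue;
        double w = std::exp(-d / avoid_dist);
        vx += w * dx / d; vy += w * dy / d; vw += w;
      }
      if (vw > 1e-300) { vx /= vw; vy /= vw; } else { vx = vy = 0.0; }

      // repulsion from conspecific scent marks (F+T)
      double sxv = 0.0, syv = 0.0, sw = 0.0;
      if (process == 3) {
        for (int g = 0; g < nf; ++g) {
          if (g == f) continue;
          Forager &fg = ff[g];
          for (size_t j = 0; j < fg.sx.size(); ++j) {
            if (fg.sexp[j] <= t) continue;
            double dx = fo.x - fg.sx[j], dy = fo.y - fg.sy[j];
            double d = std::sqrt(dx * dx + dy * dy);
            if (d < 1e-9 || d > scent_dist * 3.0) continue;
            double w = std::exp(-d / scent_dist);
            sxv += w * dx / d; syv += w * dy / d; sw += w;
          }
        }
        if (sw > 1e-300) { sxv /= sw; syv /= sw; } else { sxv = syv = 0.0; }
      }

      double wx = persist_w * std::cos(fo.theta) + mem_w * bx +
                  avoid_w * vx + scent_w * sxv;
      double wy = persist_w * std::sin(fo.theta) + mem_w * by +
                  avoid_w * vy + scent_w * syv;
      double des = (std::fabs(wx) + std::fabs(wy) > 1e-12)
                       ? std::atan2(wy, wx) : fo.theta;
      double th = des + rvonmises0(kappa);
      double cs = std::cos(th), sn2 = std::sin(th);
      double nx = fo.x + speed * cs, ny = fo.y + speed * sn2;
      reflect(&nx, &cs, 0.0, (double)ncols);
      reflect(&ny, &sn2, 0.0, (double)nrows);
      fo.x = nx; fo.y = ny;
      fo.theta = std::atan2(sn2, cs);
    }

    if (t == total - 1) break;

    // resource dynamics after all foragers moved
    for (int f = 0; f < nf; ++f) {
      int c = (int)std::floor(ff[f].x);
      int r = (int)std::floor(ff[f].y);
      occupied[f] = cellmap[c * nrows + r];
    }
    resource_step(v, base, occupied, consumption, regen);

    // drop expired avoidance / scent entries now and then
    if (t % 200 == 199) {
      for (int f = 0; f < nf; ++f) {
        Forager &fo = ff[f];
        size_t k = 0;
        for (size_t j = 0; j < fo.ax.size(); ++j)
          if (fo.aexp[j] > t) {
            fo.ax[k] = fo.ax[j]; fo.ay[k] = fo.ay[j]; fo.aexp[k] = fo.aexp[j];
            ++k;
          }
        fo.ax.resize(k); fo.ay.resize(k); fo.aexp.resize(k);
        k = 0;
        for (size_t j = 0; j < fo.sx.size(); ++j)
          if (fo.sexp[j] > t) {
            fo.sx[k] = fo.sx[j]; fo.sy[k] = fo.sy[j]; fo.sexp[k] = fo.sexp[j];
            ++k;
          }
        fo.sx.resize(k); fo.sy.resize(k); fo.sexp.resize(k);
      }
    }
  }

  List res(nf);
  for (int f = 0; f < nf; ++f) res[f] = out[f];
  return res;
}

// [[Rcpp::export]]
double rvonmises_cpp(double kappa) { return rvonmises0(kappa); }
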