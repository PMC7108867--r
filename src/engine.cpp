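#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Internal engine for the pressurized mass-spring cross-section.
//
// Point layout: all loop tissues first (contiguous blocks, counterclockwise
// order), then the immobile yolk chain as the last group. Springs exist only
// within loop groups; inter-group interactions use the piecewise
// repulsion/adhesion law. Adhesion stiffness is looked up per group pair so
// that single interfaces can be weakened (unilateral perturbations).

struct Engine {
  int n;                 // total points
  int G;                 // number of loop tissues (yolk = group G)
  std::vector<double> x, y;
  std::vector<int> grp;
  std::vector<int> start, len;   // per loop tissue
  std::vector<double> ks;        // per spring (global point index = spring index)
  std::vector<double> kadh;      // (G+1)*(G+1)
  double l0, P, krep, rrep, radh, cdrag, dt;

  // Verlet neighbour list
  double skin;
  std::vector<std::pair<int,int> > pairs;
  std::vector<double> bx, by;    // positions at last build

  Engine() : skin(0.1) {}

  inline double kadh_at(int a, int b) const { return kadh[a * (G + 1) + b]; }

  void build_pairs() {
    pairs.clear();
    const double cut = radh + skin;
    const double cut2 = cut * cut;
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        if (grp[i] == grp[j]) continue;
        if (grp[i] >= G && grp[j] >= G) continue; // yolk-yolk
        const double dx = x[i] - x[j], dy = y[i] - y[j];
        if (dx * dx + dy * dy < cut2) pairs.push_back(std::make_pair(i, j));
      }
    }
    bx = x; by = y;
  }

  bool need_rebuild() const {
    const double lim = 0.25 * skin * skin; // (skin/2)^2
    for (int i = 0; i < n; ++i) {
      const double dx = x[i] - bx[i], dy = y[i] - by[i];
      if (dx * dx + dy * dy > lim) return true;
    }
    return false;
  }

  // net forces; throws on degenerate springs or non-finite values
  void forces(std::vector<double>& fx, std::vector<double>& fy) const {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);

    // surface springs + pressure, per loop tissue
    for (int t = 0; t < G; ++t) {
      const int s0 = start[t], m = len[t];
      for (int i = 0; i < m; ++i) {
        const int p = s0 + i;
        const int q = s0 + (i + 1) % m;     // spring p: p -> q
        const double dx = x[q] - x[p], dy = y[q] - y[p];
        const double l = std::sqrt(dx * dx + dy * dy);
        if (l <= 0.0)
          stop("degenerate spring (zero length) at tissue %d point %d", t + 1, i + 1);
        const double f = ks[p] * (l - l0) / l; // tension along spring
        fx[p] += f * dx; fy[p] += f * dy;
        fx[q] -= f * dx; fy[q] -= f * dy;
        // pressure: outward normal of edge (dx,dy) for CCW loop is (dy,-dx)/l
        const double pf = 0.5 * P * l0 / l;
        fx[p] += pf * dy; fy[p] -= pf * dx;
        fx[q] += pf * dy; fy[q] -= pf * dx;
      }
    }

    // inter-tissue interactions over the neighbour list
    const double radh2 = radh * radh;
    for (size_t k = 0; k < pairs.size(); ++k) {
      const int i = pairs[k].first, j = pairs[k].second;
      const double dx = x[i] - x[j], dy = y[i] - y[j];
      const double r2 = dx * dx + dy * dy;
      if (r2 >= radh2) continue;
      const double r = std::sqrt(r2);
      if (r <= 0.0)
        stop("coincident points %d and %d of different tissues", i + 1, j + 1);
      double f;
      if (r < rrep) {
        f = krep * (rrep - r) / r;            // repulsive, along +r_ij
      } else {
        f = -kadh_at(grp[i], grp[j]) * (r - rrep) / r; // attractive
      }
      fx[i] += f * dx; fy[i] += f * dy;
      fx[j] -= f * dx; fy[j] -= f * dy;
    }
  }
};

static Engine make_engine(NumericMatrix pos, IntegerVector grp,
                          IntegerVector start, IntegerVector len,
                          NumericVector ks, NumericMatrix kadh,
                          List par) {
  Engine e;
  e.n = pos.nrow();
  e.G = start.size();
  e.x.resize(e.n); e.y.resize(e.n); e.grp.resize(e.n);
  for (int i = 0; i < e.n; ++i) {
    e.x[i] = pos(i, 0); e.y[i] = pos(i, 1); e.grp[i] = grp[i];
  }
  e.start.assign(start.begin(), start.end());
  e.len.assign(len.begin(), len.end());
  e.ks.assign(ks.begin(), ks.end());
  e.kadh.resize((e.G + 1) * (e.G + 1));
  for (int a = 0; a <= e.G; ++a)
    for (int b = 0; b <= e.G; ++b)
      e.kadh[a * (e.G + 1) + b] = kadh(a, b);
  e.l0   = as<double>(par["l0"]);
  e.P    = as<double>(par["P"]);
  e.krep = as<double>(par["K_rep"]);
  e.rrep = as<double>(par["R_rep"]);
  e.radh = as<double>(par["R_adh"]);
  e.cdrag = as<double>(par["c"]);
  e.dt   = as<double>(par["dt"]);
  e.skin = 0.5 * e.radh;
  e.build_pairs();
  return e;
}

// [[Rcpp::export]]
NumericMatrix lj_net_forces(NumericMatrix pos, IntegerVector grp,
                            IntegerVector start, IntegerVector len,
                            NumericVector ks, NumericMatrix kadh, List par) {
  Engine e = make_engine(pos, grp, start, len, ks, kadh, par);
  std::vector<double> fx(e.n), fy(e.n);
  e.forces(fx, fy);
  NumericMatrix out(e.n, 2);
  for (int i = 0; i < e.n; ++i) { out(i, 0) = fx[i]; out(i, 1) = fy[i]; }
  return out;
}

// [[Rcpp::export]]
List lj_run(NumericMatrix pos, IntegerVector grp,
            IntegerVector start, IntegerVector len,
            NumericVector ks, NumericMatrix kadh, List par,
            LogicalVector mobile, double tol, double max_steps,
            int window, int check_every) {
  Engine e = make_engine(pos, grp, start, len, ks, kadh, par);
  std::vector<double> fx(e.n), fy(e.n);
  std::vector<double> sx(e.n, 0.0), sy(e.n, 0.0);   // window accumulators
  std::vector<double> mxp(e.n), myp(e.n);           // previous window means
  // ring buffer of window means, for the long-horizon drift criterion
  const int HORIZON = 10;
  std::vector<std::vector<double> > ringx, ringy;
  int ring_n = 0;
  bool have_prev_mean = false;
  const double scale = e.dt / e.cdrag;

  double resid_win = R_PosInf, resid_inst = R_PosInf;
  double resid_prev = R_PosInf;
  bool converged = false;
  double steps_done = 0;
  long in_window = 0;

  for (long s = 1; s <= (long)max_steps; ++s) {
    if (e.need_rebuild()) e.build_pairs();
    e.forces(fx, fy);
    for (int i = 0; i < e.n; ++i) {
      if (!mobile[i]) continue;
      if (!std::isfinite(fx[i]) || !std::isfinite(fy[i]))
        stop("non-finite force on point %d at step %ld", i + 1, s);
      e.x[i] += scale * fx[i];
      e.y[i] += scale * fy[i];
      sx[i] += e.x[i]; sy[i] += e.y[i];
    }
    ++in_window;
    steps_done = (double)s;

    if (s % check_every == 0) {
      double mf = 0.0;
      for (int i = 0; i < e.n; ++i) {
        if (!mobile[i]) continue;
        const double m = fx[i] * fx[i] + fy[i] * fy[i];
        if (m > mf) mf = m;
      }
      resid_inst = std::sqrt(mf);
    }

    if (in_window >= window) {
      // block-averaged residual: drag times the drift velocity of the
      // window-mean positions, which cancels the small repulsion-zone
      // limit cycle of the explicit scheme and measures true relaxation
      if (have_prev_mean) {
        double md = 0.0;
        for (int i = 0; i < e.n; ++i) {
          if (!mobile[i]) continue;
          const double dx = sx[i] / in_window - mxp[i];
          const double dy = sy[i] / in_window - myp[i];
          const double d = dx * dx + dy * dy;
          if (d > md) md = d;
        }
        resid_win = e.cdrag * std::sqrt(md) / ((double)window * e.dt);
      }
      std::vector<double> curx(e.n), cury(e.n);
      for (int i = 0; i < e.n; ++i) {
        curx[i] = sx[i] / in_window; cury[i] = sy[i] / in_window;
        mxp[i] = curx[i]; myp[i] = cury[i];
        sx[i] = 0.0; sy[i] = 0.0;
      }
      have_prev_mean = true;
      in_window = 0;
      // drift over HORIZON windows: non-decaying boundary-toggling
      // oscillations (the adhesion cutoff is a force discontinuity)
      // average out, genuine relaxation does not
      double resid_long = R_PosInf;
      if (ring_n >= HORIZON) {
        const std::vector<double>& ox = ringx[ring_n % HORIZON];
        const std::vector<double>& oy = ringy[ring_n % HORIZON];
        double md = 0.0;
        for (int i = 0; i < e.n; ++i) {
          if (!mobile[i]) continue;
          const double dx = curx[i] - ox[i], dy = cury[i] - oy[i];
          const double d = dx * dx + dy * dy;
          if (d > md) md = d;
        }
        resid_long = e.cdrag * std::sqrt(md) /
          ((double)HORIZON * (double)window * e.dt);
      }
      if (ring_n < HORIZON) {
        ringx.push_back(curx); ringy.push_back(cury);
      } else {
        ringx[ring_n % HORIZON] = curx; ringy[ring_n % HORIZON] = cury;
      }
      ++ring_n;
      if (resid_win < tol || resid_long < tol) {
        converged = true;
        if (resid_long < resid_win) resid_win = resid_long;
        break;
      }
      if (std::isfinite(resid_prev) && resid_win > 10.0 * resid_prev &&
          resid_win > 1e3)
        stop("simulation diverging: windowed residual grew from %g to %g",
             resid_prev, resid_win);
      resid_prev = resid_win;
    }
  }

  NumericMatrix out(e.n, 2);
  for (int i = 0; i < e.n; ++i) { out(i, 0) = e.x[i]; out(i, 1) = e.y[i]; }
  return List::create(_["pos"] = out,
                      _["steps"] = steps_done,
                      _["converged"] = converged,
                      _["resid_window"] = resid_win,
                      _["resid_inst"] = resid_inst);
}

// 4/8-connected component labelling for binary masks (row-major R matrix)
// [[Rcpp::export]]
IntegerMatrix lj_label_components(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<std::pair<int,int> > stack;
  int next = 0;
  const int dr8[8] = {-1,-1,-1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1,-1, 1,-1, 0, 1};
  const int dr4[4] = {-1, 1, 0, 0};
  const int dc4[4] = { 0, 0,-1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0)) continue;
      ++next;
      stack.push_back(std::make_pair(r0, c0));
      lab(r0, c0) = next;
      while (!stack.empty()) {
        const int r = stack.back().first, c = stack.back().second;
        stack.pop_back();
        for (int k = 0; k < nn; ++k) {
          const int rr = r + dr[k], cc = c + dc[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && !lab(rr, cc)) {
            lab(rr, cc) = next;
            stack.push_back(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  return lab;
}
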