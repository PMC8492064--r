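#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Uniform-grid neighbor lists over agent positions (counting sort into bins).
// All distances are in the caller's length unit (micrometres throughout the
// package); bin size must be >= the largest interaction radius so that a
// 3x3 bin neighborhood covers every candidate pair.
struct Grid {
  double x0, y0, h;
  int nx, ny;
  std::vector<int> start;   // bin -> first index into order
  std::vector<int> order;   // agent indices grouped by bin
  Grid(const NumericVector& x, const NumericVector& y, double bin) {
    int n = x.size();
    h = bin;
    x0 = R_PosInf; y0 = R_PosInf;
    double x1 = R_NegInf, y1 = R_NegInf;
    for (int i = 0; i < n; ++i) {
      if (x[i] < x0) x0 = x[i];
      if (y[i] < y0) y0 = y[i];
      if (x[i] > x1) x1 = x[i];
      if (y[i] > y1) y1 = y[i];
    }
    if (n == 0) { x0 = y0 = 0.0; x1 = y1 = 0.0; }
    nx = std::max(1, (int)std::floor((x1 - x0) / h) + 1);
    ny = std::max(1, (int)std::floor((y1 - y0) / h) + 1);
    std::vector<int> bin_of(n), count(nx * ny + 1, 0);
    for (int i = 0; i < n; ++i) {
      int bx = std::min(nx - 1, (int)std::floor((x[i] - x0) / h));
      int by = std::min(ny - 1, (int)std::floor((y[i] - y0) / h));
      bin_of[i] = by * nx + bx;
      count[bin_of[i] + 1]++;
    }
    start.resize(nx * ny + 1);
    start[0] = 0;
    for (int b = 0; b < nx * ny; ++b) start[b + 1] = start[b] + count[b + 1];
    std::vector<int> cursor(start.begin(), start.end() - 1);
    order.resize(n);
    for (int i = 0; i < n; ++i) order[cursor[bin_of[i]]++] = i;
  }
  inline int bx_of(double x) const {
    return std::min(nx - 1, std::max(0, (int)std::floor((x - x0) / h)));
  }
  inline int by_of(double y) const {
    return std::min(ny - 1, std::max(0, (int)std::floor((y - y0) / h)));
  }
};

// One synchronous position update of the biased random walk.
//
// Candidate displacement = speed*dt*(cos a, sin a) + dt * interaction bias,
// where the bias (a velocity, micron/h) sums, over neighbors within r_adh:
//   - hard-core repulsion inside r_core:   f_core * (1 - r/r_core) away
//   - fate-pair adhesion in (r_core,r_adh]: f_adh * A[s_i,s_j] *
//         adh_scale_i * adh_scale_j * (r - r_core)/(r_adh - r_core) toward
//         the neighbor (adh_scale carries the per-cell Sox2-level coupling)
//   - cross-fate (non-mixing) repulsion:    f_adh * Rm[s_i,s_j] *
//         (1 - (r - r_core)/(r_adh - r_core)) away
// A candidate is rejected (the cell stays put) if it crosses the anterior
// wall y < y_min, a lateral wall, or would have more than n_max neighbors
// within r_pack (counted against current positions). Moves that do not
// increase the cell's own neighbor count are always admissible, so
// overcrowded regions (e.g. after cap-exempt birth placements) can relax
// outward instead of jamming; this packing pressure is what pushes the
// growing tissue into the open posterior space.
// [[Rcpp::export]]
NumericMatrix step_positions_cpp(NumericVector x, NumericVector y,
                                 IntegerVector state, NumericVector speed,
                                 NumericVector angle, NumericVector adh_scale,
                                 double dt,
                                 double r_core, double r_adh, double r_pack,
                                 int n_max, double f_core, double f_adh,
                                 NumericMatrix attract, NumericMatrix repel,
                                 double y_min, double x_min, double x_max,
                                 bool motility_on, bool interactions_on) {
  int n = x.size();
  NumericMatrix out(n, 2);
  double bin = std::max(r_adh, r_pack);
  if (bin <= 0) bin = 1.0;
  Grid g(x, y, bin);
  double span = r_adh - r_core;
  if (span <= 0) span = 1e-9;

  std::vector<double> cx(n), cy(n);
  for (int i = 0; i < n; ++i) {
    double dx = 0.0, dy = 0.0;
    if (motility_on) {
      dx = speed[i] * dt * std::cos(angle[i]);
      dy = speed[i] * dt * std::sin(angle[i]);
    }
    if (interactions_on) {
      double bxv = 0.0, byv = 0.0;
      int bx = g.bx_of(x[i]), by = g.by_of(y[i]);
      for (int ddy = -1; ddy <= 1; ++ddy) {
        int yy = by + ddy;
        if (yy < 0 || yy >= g.ny) continue;
        for (int ddx = -1; ddx <= 1; ++ddx) {
          int xx = bx + ddx;
          if (xx < 0 || xx >= g.nx) continue;
          int b = yy * g.nx + xx;
          for (int k = g.start[b]; k < g.start[b + 1]; ++k) {
            int j = g.order[k];
            if (j == i) continue;
            double ux = x[j] - x[i], uy = y[j] - y[i];
            double r = std::sqrt(ux * ux + uy * uy);
            if (r >= r_adh) continue;
            if (r < 1e-12) continue;  // coincident: no defined direction
            ux /= r; uy /= r;
            int si = state[i], sj = state[j];
            if (r < r_core) {
              double f = f_core * (1.0 - r / r_core);
              bxv -= f * ux; byv -= f * uy;
            } else {
              double t = (r - r_core) / span;
              double fa = f_adh * attract(si, sj) * adh_scale[i] * adh_scale[j] * t;
              double fr = f_adh * repel(si, sj) * (1.0 - t);
              bxv += (fa - fr) * ux;
              byv += (fa - fr) * uy;
            }
          }
        }
      }
      // cap the bias displacement at r_core per step: keeps the stiff
      // core repulsion numerically stable at dt without limiting the
      // direction of the packing pressure
      double bx_d = bxv * dt, by_d = byv * dt;
      double norm = std::sqrt(bx_d * bx_d + by_d * by_d);
      if (norm > r_core) { bx_d *= r_core / norm; by_d *= r_core / norm; }
      dx += bx_d;
      dy += by_d;
    }
    cx[i] = x[i] + dx;
    cy[i] = y[i] + dy;
  }

  // rejection pass against current positions
  for (int i = 0; i < n; ++i) {
    bool ok = (cy[i] >= y_min) && (cx[i] >= x_min) && (cx[i] <= x_max);
    if (ok && n_max > 0 && (cx[i] != x[i] || cy[i] != y[i])) {
      double r2 = r_pack * r_pack;
      auto count_at = [&](double px, double py) {
        int cnt = 0;
        int bx = g.bx_of(px), by = g.by_of(py);
        for (int ddy = -1; ddy <= 1; ++ddy) {
          int yy = by + ddy;
          if (yy < 0 || yy >= g.ny) continue;
          for (int ddx = -1; ddx <= 1; ++ddx) {
            int xx = bx + ddx;
            if (xx < 0 || xx >= g.nx) continue;
            int b = yy * g.nx + xx;
            for (int k = g.start[b]; k < g.start[b + 1]; ++k) {
              int j = g.order[k];
              if (j == i) continue;
              double ux = x[j] - px, uy = y[j] - py;
              if (ux * ux + uy * uy <= r2) ++cnt;
            }
          }
        }
        return cnt;
      };
      int cand = count_at(cx[i], cy[i]);
      if (cand > n_max && cand > count_at(x[i], y[i])) ok = false;
    }
    out(i, 0) = ok ? cx[i] : x[i];
    out(i, 1) = ok ? cy[i] : y[i];
  }
  return out;
}

// Iterative hard-core packing: Gauss-Seidel sweeps that project any pair
// closer than d_min apart to exactly d_min (each cell moved half the
// deficit along the pair axis), clamped to the walls. Contact chains
// transmit packing pressure through the tissue within a few sweeps, which
// is what lets proliferation drive expansion into the open posterior space
// at the observed tissue scale; soft pairwise forces alone would only relax
// compression diffusively. Deterministic (no RNG): fixed sweep order.
// [[Rcpp::export]]
NumericMatrix resolve_overlaps_cpp(NumericVector x0, NumericVector y0,
                                   double d_min, int n_sweeps,
                                   double y_min, double x_min, double x_max,
                                   double omega = 1.0) {
  int n = x0.size();
  std::vector<double> x(x0.begin(), x0.end()), y(y0.begin(), y0.end());
  double d2min = d_min * d_min;
  std::vector<int> rank(n);
  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    NumericVector xv(x.begin(), x.end()), yv(y.begin(), y.end());
    Grid g(xv, yv, d_min);
    // process cells anterior-to-posterior (grid bins are y-major): each
    // sweep then propagates a compression wave toward the open posterior
    for (int k = 0; k < n; ++k) rank[g.order[k]] = k;
    bool any = false;
    for (int ord = 0; ord < n; ++ord) {
      int i = g.order[ord];
      int bx = g.bx_of(x[i]), by = g.by_of(y[i]);
      for (int ddy = -1; ddy <= 1; ++ddy) {
        int yy = by + ddy;
        if (yy < 0 || yy >= g.ny) continue;
        for (int ddx = -1; ddx <= 1; ++ddx) {
          int xx = bx + ddx;
          if (xx < 0 || xx >= g.nx) continue;
          int b = yy * g.nx + xx;
          for (int k = g.start[b]; k < g.start[b + 1]; ++k) {
            int j = g.order[k];
            if (rank[j] <= ord) continue;
            double ux = x[j] - x[i], uy = y[j] - y[i];
            double r2 = ux * ux + uy * uy;
            if (r2 >= d2min) continue;
            double r = std::sqrt(r2);
            if (r < 1e-9) continue;  // coincident: leave to random motion
            double push = 0.5 * omega * (d_min - r) / r;  // SOR-accelerated
            x[i] -= push * ux; y[i] -= push * uy;
            x[j] += push * ux; y[j] += push * uy;
            // walls: clamp back inside
            if (y[i] < y_min) y[i] = y_min;
            if (y[j] < y_min) y[j] = y_min;
            if (x[i] < x_min) x[i] = x_min; else if (x[i] > x_max) x[i] = x_max;
            if (x[j] < x_min) x[j] = x_min; else if (x[j] > x_max) x[j] = x_max;
            any = true;
          }
        }
      }
    }
    if (!any) break;
  }
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) { out(i, 0) = x[i]; out(i, 1) = y[i]; }
  return out;
}

// Number of neighbors within `radius` of each agent (self excluded).
// [[Rcpp::export]]
IntegerVector count_neighbors_cpp(NumericVector x, NumericVector y,
                                  double radius) {
  int n = x.size();
  IntegerVector out(n);
  Grid g(x, y, radius > 0 ? radius : 1.0);
  double r2 = radius * radius;
  for (int i = 0; i < n; ++i) {
    int cnt = 0;
    int bx = g.bx_of(x[i]), by = g.by_of(y[i]);
    for (int ddy = -1; ddy <= 1; ++ddy) {
      int yy = by + ddy;
      if (yy < 0 || yy >= g.ny) continue;
      for (int ddx = -1; ddx <= 1; ++ddx) {
        int xx = bx + ddx;
        if (xx < 0 || xx >= g.nx) continue;
        int b = yy * g.nx + xx;
        for (int k = g.start[b]; k < g.start[b + 1]; ++k) {
          int j = g.order[k];
          if (j == i) continue;
          double ux = x[j] - x[i], uy = y[j] - y[i];
          if (ux * ux + uy * uy <= r2) ++cnt;
        }
      }
    }
    out[i] = cnt;
  }
  return out;
}

// For each agent: 1 if a strict majority of its neighbors within `radius`
// share its fate, 0 otherwise; isolated agents (no neighbors) count as 1.
// [[Rcpp::export]]
IntegerVector majority_same_fate_cpp(NumericVector x, NumericVector y,
                                     IntegerVector state, double radius) {
  int n = x.size();
  IntegerVector out(n);
  Grid g(x, y, radius > 0 ? radius : 1.0);
  double r2 = radius * radius;
  for (int i = 0; i < n; ++i) {
    int same = 0, tot = 0;
    int bx = g.bx_of(x[i]), by = g.by_of(y[i]);
    for (int ddy = -1; ddy <= 1; ++ddy) {
      int yy = by + ddy;
      if (yy < 0 || yy >= g.ny) continue;
      for (int ddx = -1; ddx <= 1; ++ddx) {
        int xx = bx + ddx;
        if (xx < 0 || xx >= g.nx) continue;
        int b = yy * g.nx + xx;
        for (int k = g.start[b]; k < g.start[b + 1]; ++k) {
          int j = g.order[k];
          if (j == i) continue;
          double ux = x[j] - x[i], uy = y[j] - y[i];
          if (ux * ux + uy * uy <= r2) {
            ++tot;
            if (state[j] == state[i]) ++same;
          }
        }
      }
    }
    out[i] = (tot == 0) ? 1 : (2 * same > tot ? 1 : 0);
  }
  return out;
}
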