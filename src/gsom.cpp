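// Growing Self-Organizing Map training core.
//
// The map starts as a 2x2 grid and grows during the growing phase: each
// sample is assigned to its best-matching node (shortest distance, ties to
// the lexicographically smallest grid coordinate), the winner and its grid
// neighborhood move toward the sample with a decaying learning rate, and the
// winner accumulates quantization error. When a node's accumulated error
// exceeds the growth threshold GT = -D * ln(SF), a boundary node spawns new
// nodes at all free von Neumann neighbors while an interior node spreads its
// error to its neighbors. The smoothing phase continues the updates at a
// reduced rate without growth. The core is RNG-free: sample presentation
// orders are drawn in R and passed in.

#include <Rcpp.h>
#include <map>
#include <vector>
#include <cmath>
using namespace Rcpp;

typedef std::pair<int, int> Coord;

static inline double node_dist(const std::vector<double>& w,
                               const double* x, int D, int metric) {
  if (metric == 1) { // Jaccard distance on non-negative data
    double mn = 0.0, mx = 0.0;
    for (int d = 0; d < D; d++) {
      double a = w[d], b = x[d];
      mn += (a < b) ? a : b;
      mx += (a > b) ? a : b;
    }
    return (mx <= 0.0) ? 0.0 : 1.0 - mn / mx;
  }
  double s = 0.0; // squared Euclidean: same argmin, canonical error unit
  for (int d = 0; d < D; d++) {
    double diff = w[d] - x[d];
    s += diff * diff;
  }
  return s;
}

// [[Rcpp::export]]
List gsom_train_cpp(NumericMatrix X, double gt, double lr0, double radius0,
                    int grow_epochs, int smooth_epochs, IntegerMatrix orders,
                    double smooth_lr_factor, double error_spread,
                    int max_nodes, int metric, int initial_nodes) {
  const int n = X.nrow(), D = X.ncol();
  std::vector<int> gx, gy;
  std::vector<std::vector<double> > W;
  std::vector<double> err;
  std::map<Coord, int> pos;

  // column means for the initial 2x2 map, with a tiny deterministic
  // perturbation so the four nodes can differentiate
  std::vector<double> mu(D, 0.0);
  for (int j = 0; j < D; j++) {
    double s = 0.0;
    for (int i = 0; i < n; i++) s += X(i, j);
    mu[j] = s / n;
  }
  int n_init = (initial_nodes == 1) ? 1 : 4;
  for (int k = 0; k < n_init; k++) {
    int cx = k % 2, cy = k / 2;
    std::vector<double> w(D);
    for (int j = 0; j < D; j++) {
      unsigned int h = (unsigned int)(k * 2654435761u + j * 97u);
      w[j] = mu[j] + 0.02 * (((double)(h % 1000)) / 1000.0 - 0.5);
    }
    gx.push_back(cx); gy.push_back(cy);
    W.push_back(w); err.push_back(0.0);
    pos[Coord(cx, cy)] = k;
  }

  const int dx4[4] = {-1, 1, 0, 0};
  const int dy4[4] = {0, 0, -1, 1};
  const int total_epochs = grow_epochs + smooth_epochs;

  // data range for clamping extrapolated new-node weights
  double dmin = X(0, 0), dmax = X(0, 0);
  for (int j = 0; j < D; j++)
    for (int i = 0; i < n; i++) {
      double v = X(i, j);
      if (v < dmin) dmin = v;
      if (v > dmax) dmax = v;
    }

  for (int e = 0; e < total_epochs; e++) {
    bool growing = e < grow_epochs;
    // accumulated error is cleared at the start of each growing pass so
    // map size tracks the per-pass quantization error against GT instead
    // of growing with training length
    if (growing)
      for (size_t k = 0; k < err.size(); k++) err[k] = 0.0;
    double lr, radius;
    if (growing) {
      double frac = grow_epochs > 1 ? (double)e / (grow_epochs - 1) : 0.0;
      lr = lr0 * (1.0 - 0.8 * frac);          // linear decay to 20%
      radius = radius0 - (radius0 - 1.0) * frac;
    } else {
      double frac = smooth_epochs > 1 ?
        (double)(e - grow_epochs) / (smooth_epochs - 1) : 0.0;
      lr = lr0 * smooth_lr_factor * (1.0 - 0.5 * frac);
      radius = 1.0;
    }
    double sigma2 = 2.0 * (radius / 2.0) * (radius / 2.0);
    if (sigma2 <= 0) sigma2 = 0.5;

    for (int s = 0; s < n; s++) {
      int i = orders(e, s);
      const double* x = &X(i, 0); // column-major: need row copy instead
      // Rcpp matrices are column-major; copy the row once
      std::vector<double> xi(D);
      for (int d = 0; d < D; d++) xi[d] = X(i, d);

      // best-matching node, ties to smallest (x, y)
      int bmu = 0;
      double best = R_PosInf;
      for (size_t k = 0; k < W.size(); k++) {
        double dist = node_dist(W[k], &xi[0], D, metric);
        if (dist < best - 1e-12 ||
            (std::fabs(dist - best) <= 1e-12 &&
             (gx[k] < gx[bmu] || (gx[k] == gx[bmu] && gy[k] < gy[bmu])))) {
          best = dist; bmu = (int)k;
        }
      }
      (void)x;

      // neighborhood update on the grid
      int r_int = (int)std::ceil(radius);
      for (size_t k = 0; k < W.size(); k++) {
        int ddx = gx[k] - gx[bmu], ddy = gy[k] - gy[bmu];
        if (std::abs(ddx) > r_int || std::abs(ddy) > r_int) continue;
        double g2 = (double)(ddx * ddx + ddy * ddy);
        if (g2 > (double)(r_int * r_int)) continue;
        double theta = std::exp(-g2 / sigma2);
        double step = lr * theta;
        for (int d = 0; d < D; d++)
          W[k][d] += step * (xi[d] - W[k][d]);
      }

      err[bmu] += best;

      if (growing && err[bmu] > gt && (int)W.size() < max_nodes) {
        // locate free von Neumann neighbors of the winner
        std::vector<int> free_dir;
        for (int t = 0; t < 4; t++) {
          Coord c(gx[bmu] + dx4[t], gy[bmu] + dy4[t]);
          if (pos.find(c) == pos.end()) free_dir.push_back(t);
        }
        if (!free_dir.empty()) {
          // boundary node: grow into every free position
          for (size_t f = 0; f < free_dir.size(); f++) {
            if ((int)W.size() >= max_nodes) break;
            int t = free_dir[f];
            int nx = gx[bmu] + dx4[t], ny = gy[bmu] + dy4[t];
            std::vector<double> w(D);
            std::map<Coord, int>::iterator opp =
              pos.find(Coord(gx[bmu] - dx4[t], gy[bmu] - dy4[t]));
            if (opp != pos.end()) {
              // extrapolate across the winner, clamped to the data range
              for (int d = 0; d < D; d++) {
                double wd = 2.0 * W[bmu][d] - W[opp->second][d];
                if (wd < dmin) wd = dmin;
                if (wd > dmax) wd = dmax;
                w[d] = wd;
              }
            } else {
              // average the winner with its existing neighbors
              int cnt = 1;
              for (int d = 0; d < D; d++) w[d] = W[bmu][d];
              for (int t2 = 0; t2 < 4; t2++) {
                std::map<Coord, int>::iterator nb =
                  pos.find(Coord(gx[bmu] + dx4[t2], gy[bmu] + dy4[t2]));
                if (nb != pos.end()) {
                  for (int d = 0; d < D; d++) w[d] += W[nb->second][d];
                  cnt++;
                }
              }
              for (int d = 0; d < D; d++) w[d] /= cnt;
            }
            int idx = (int)W.size();
            gx.push_back(nx); gy.push_back(ny);
            W.push_back(w); err.push_back(0.0);
            pos[Coord(nx, ny)] = idx;
          }
          err[bmu] = 0.0;
        } else {
          // interior node: spread the error to the neighbors
          double e0 = err[bmu];
          for (int t = 0; t < 4; t++) {
            std::map<Coord, int>::iterator nb =
              pos.find(Coord(gx[bmu] + dx4[t], gy[bmu] + dy4[t]));
            if (nb != pos.end()) err[nb->second] += error_spread * e0;
          }
          err[bmu] = gt / 2.0;
        }
      }
    }
  }

  NumericMatrix Wout((int)W.size(), D);
  for (size_t k = 0; k < W.size(); k++)
    for (int d = 0; d < D; d++) Wout((int)k, d) = W[k][d];
  return List::create(_["x"] = wrap(gx), _["y"] = wrap(gy),
                      _["weights"] = Wout, _["error"] = wrap(err));
}
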