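#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Constant-step rediscretization (chord method): starting from the first
// vertex, repeatedly find the first point along the remaining polyline at
// Euclidean distance `step` from the last emitted point.  Every emitted step
// has length exactly `step`; the trailing piece shorter than `step` is
// discarded.
// [[Rcpp::export]]
NumericMatrix cpp_rediscretize(NumericMatrix xy, double step) {
  const int n = xy.nrow();
  std::vector<double> rx, ry;
  double qx = xy(0, 0), qy = xy(0, 1);
  rx.push_back(qx); ry.push_back(qy);
  // current position along the polyline: segment index `seg`, point (cx, cy)
  int seg = 0;
  double cx = qx, cy = qy;
  while (seg < n - 1) {
    double bx = xy(seg + 1, 0), by = xy(seg + 1, 1);
    double db = std::hypot(bx - qx, by - qy);
    if (db < step) {
      // whole remaining segment is inside the circle: advance to its end
      cx = bx; cy = by; ++seg;
      continue;
    }
    // circle of radius `step` about (qx,qy) intersects segment (cx,cy)-(bx,by)
    double ux = cx - qx, uy = cy - qy;
    double vx = bx - cx, vy = by - cy;
    double a = vx * vx + vy * vy;
    if (a == 0.0) { ++seg; continue; }
    double b = ux * vx + uy * vy;
    double c = ux * ux + uy * uy - step * step;
    double disc = b * b - a * c;
    if (disc < 0.0) disc = 0.0;
    double t = (-b + std::sqrt(disc)) / a;
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
    qx = cx + t * vx; qy = cy + t * vy;
    rx.push_back(qx); ry.push_back(qy);
    cx = qx; cy = qy;  // stay on this segment
  }
  NumericMatrix out(rx.size(), 2);
  for (size_t i = 0; i < rx.size(); ++i) { out(i, 0) = rx[i]; out(i, 1) = ry[i]; }
  return out;
}

static double perp_dist(double px, double py,
                        double ax, double ay, double bx, double by) {
  double dx = bx - ax, dy = by - ay;
  double len = std::hypot(dx, dy);
  if (len == 0.0) return std::hypot(px - ax, py - ay);
  return std::fabs(dy * (px - ax) - dx * (py - ay)) / len;
}

// Ramer-Douglas-Peucker: which vertices survive simplification at epsilon.
// Iterative (explicit stack); the first point of maximal perpendicular
// distance is split on ties.
// [[Rcpp::export]]
LogicalVector cpp_rdp_keep(NumericMatrix xy, double eps) {
  const int n = xy.nrow();
  LogicalVector keep(n, false);
  keep[0] = true; keep[n - 1] = true;
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int lo = stack.back().first, hi = stack.back().second;
    stack.pop_back();
    if (hi - lo < 2) continue;
    double dmax = -1.0; int imax = -1;
    for (int i = lo + 1; i < hi; ++i) {
      double d = perp_dist(xy(i, 0), xy(i, 1),
                           xy(lo, 0), xy(lo, 1), xy(hi, 0), xy(hi, 1));
      if (d > dmax) { dmax = d; imax = i; }
    }
    if (dmax > eps) {
      keep[imax] = true;
      stack.push_back(std::make_pair(lo, imax));
      stack.push_back(std::make_pair(imax, hi));
    }
  }
  return keep;
}

// Greedy place centers: the first sample is a center; each later sample
// farther than r from every existing center opens a new one.  Returns
// 1-based sample indices of the centers.
// [[Rcpp::export]]
IntegerVector cpp_greedy_centers(NumericMatrix xy, double r) {
  const int n = xy.nrow();
  const double r2 = r * r;
  std::vector<int> centers;
  centers.push_back(0);
  for (int i = 1; i < n; ++i) {
    bool covered = false;
    for (size_t k = 0; k < centers.size(); ++k) {
      double dx = xy(i, 0) - xy(centers[k], 0);
      double dy = xy(i, 1) - xy(centers[k], 1);
      if (dx * dx + dy * dy <= r2) { covered = true; break; }
    }
    if (!covered) centers.push_back(i);
  }
  IntegerVector out(centers.size());
  for (size_t k = 0; k < centers.size(); ++k) out[k] = centers[k] + 1;
  return out;
}

// Entry events into radius-r discs: for each center, the 1-based sample
// indices at which the trajectory transitions from outside to inside its
// disc (a first sample already inside counts as an entry).
// [[Rcpp::export]]
List cpp_disc_entries(NumericMatrix xy, NumericMatrix centers, double r) {
  const int n = xy.nrow(), m = centers.nrow();
  const double r2 = r * r;
  List out(m);
  for (int k = 0; k < m; ++k) {
    std::vector<int> entries;
    bool inside_prev = false;
    for (int i = 0; i < n; ++i) {
      double dx = xy(i, 0) - centers(k, 0);
      double dy = xy(i, 1) - centers(k, 1);
      bool inside = dx * dx + dy * dy <= r2;
      if (inside && !inside_prev) entries.push_back(i + 1);
      inside_prev = inside;
    }
    out[k] = wrap(entries);
  }
  return out;
}

static double wrap_angle(double a) {
  while (a > M_PI) a -= 2.0 * M_PI;
  while (a < -M_PI) a += 2.0 * M_PI;
  return a;
}

// Correlated random walk with pauses, reversal events, return trips to
// previously visited positions, and attraction to unvisited landmarks.
// Uses R's RNG (set.seed() upstream makes it reproducible).  bounds is
// (xmin, ymin, xmax, ymax); movement reflects at the walls.
// [[Rcpp::export]]
NumericMatrix cpp_simulate_agent(int n, double step,
                                 double activity, double tortuosity,
                                 double turnaround_rate, double revisit_bias,
                                 double landmark_attraction,
                                 NumericMatrix landmarks, double landmark_radius,
                                 NumericVector bounds,
                                 double x0, double y0, double heading0) {
  NumericMatrix out(n, 2);
  const double xmin = bounds[0], ymin = bounds[1];
  const double xmax = bounds[2], ymax = bounds[3];
  const int n_lm = landmarks.nrow();
  const double lm_r2 = landmark_radius * landmark_radius;
  std::vector<bool> lm_visited(n_lm, false);
  double x = x0, y = y0, heading = heading0;
  out(0, 0) = x; out(0, 1) = y;
  bool target_active = false;
  double tx = 0.0, ty = 0.0;
  // a return trip heads back to the most recent position at least
  // `trip_dist` away: a flight-scale reversal of the net heading whose
  // length is controlled, so excursions mark efficiency without dominating
  // the time budget
  const double trip_dist = 25.0;
  const int scan_cap = 1000;
  const double omega = 0.2;        // max steering correction, rad per step
  const double margin = 6.0;       // wall-repulsion margin, vm
  const double capture = 3.0;      // trip ends within this distance of target
  const int trip_max_age = (int)(3.0 * trip_dist / step);
  int trip_age = 0;
  for (int i = 1; i < n; ++i) {
    // landmark visit bookkeeping on the current position
    for (int k = 0; k < n_lm; ++k) {
      if (lm_visited[k]) continue;
      double dx = x - landmarks(k, 0), dy = y - landmarks(k, 1);
      if (dx * dx + dy * dy <= lm_r2) lm_visited[k] = true;
    }
    if (R::runif(0.0, 1.0) < activity) {  // pause: zero-length step
      out(i, 0) = x; out(i, 1) = y;
      continue;
    }
    if (!target_active && revisit_bias > 0.0 &&
        R::runif(0.0, 1.0) < revisit_bias) {
      int lo = i - scan_cap; if (lo < 0) lo = 0;
      for (int j = i - 1; j >= lo; --j) {
        double dx = out(j, 0) - x, dy = out(j, 1) - y;
        if (dx * dx + dy * dy >= trip_dist * trip_dist) {
          tx = out(j, 0); ty = out(j, 1);
          target_active = true;
          trip_age = 0;
          break;
        }
      }
    }
    if (target_active) {
      double d = std::hypot(tx - x, ty - y);
      ++trip_age;
      if (d < capture || trip_age > trip_max_age) target_active = false;
    }
    // turning noise (damped while steering back: the excursion is a flight)
    heading += R::rnorm(0.0, target_active ? 0.25 * tortuosity : tortuosity);
    if (!target_active && turnaround_rate > 0.0 &&
        R::runif(0.0, 1.0) < turnaround_rate)
      heading += M_PI;
    // desired direction: trip target or landmark pull, then wall repulsion;
    // steering toward it is rate-limited so turns are smooth arcs that stay
    // below the flight-simplification scale instead of step-scale spikes
    double want = heading;
    if (target_active) {
      want = std::atan2(ty - y, tx - x);
    } else if (landmark_attraction > 0.0) {
      int best = -1; double best_d2 = 0.0;
      for (int k = 0; k < n_lm; ++k) {
        if (lm_visited[k]) continue;
        double dx = landmarks(k, 0) - x, dy = landmarks(k, 1) - y;
        double d2 = dx * dx + dy * dy;
        if (best < 0 || d2 < best_d2) { best = k; best_d2 = d2; }
      }
      if (best >= 0) {
        double lm_dir = std::atan2(landmarks(best, 1) - y,
                                   landmarks(best, 0) - x);
        want = heading + landmark_attraction * wrap_angle(lm_dir - heading);
      }
    }
    double vx = std::cos(want), vy = std::sin(want);
    if (x - xmin < margin) vx += 1.5 * (1.0 - (x - xmin) / margin);
    if (xmax - x < margin) vx -= 1.5 * (1.0 - (xmax - x) / margin);
    if (y - ymin < margin) vy += 1.5 * (1.0 - (y - ymin) / margin);
    if (ymax - y < margin) vy -= 1.5 * (1.0 - (ymax - y) / margin);
    want = std::atan2(vy, vx);
    double corr = wrap_angle(want - heading);
    if (corr > omega) corr = omega;
    if (corr < -omega) corr = -omega;
    heading = wrap_angle(heading + corr);
    double nx = x + step * std::cos(heading);
    double ny = y + step * std::sin(heading);
    for (int rep = 0; rep < 8; ++rep) {  // safety net: reflect at the walls
      bool moved = false;
      if (nx < xmin) { nx = 2.0 * xmin - nx; heading = M_PI - heading; moved = true; }
      if (nx > xmax) { nx = 2.0 * xmax - nx; heading = M_PI - heading; moved = true; }
      if (ny < ymin) { ny = 2.0 * ymin - ny; heading = -heading; moved = true; }
      if (ny > ymax) { ny = 2.0 * ymax - ny; heading = -heading; moved = true; }
      if (!moved) break;
    }
    x = nx; y = ny;
    out(i, 0) = x; out(i, 1) = y;
  }
  return out;
}
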