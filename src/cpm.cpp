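#include <Rcpp.h>
using namespace Rcpp;

// Type codes shared with R/constants.R
#define T_CELL   1
#define T_FIBRIN 2
#define T_PATCH  3
#define T_BORDER 4
#define T_MEDIUM 5

// 8-neighborhood offsets in cyclic (ring) order: consecutive entries are
// themselves lattice neighbours, which the local connectivity test relies on.
static const int RING_DY[8] = { 1, 1, 0, -1, -1, -1, 0, 1 };
static const int RING_DX[8] = { 0, 1, 1, 1, 0, -1, -1, -1 };

static inline int type_of(const IntegerVector& type, int id) {
  return type[id - 1];
}

// Total interfacial (contact) energy: sum of J(tau,tau') over all unordered
// 8-adjacent site pairs with differing identifiers.
// [[Rcpp::export]]
double cpp_interfacial_energy(const IntegerMatrix& sigma,
                              const IntegerVector& type,
                              const NumericMatrix& J) {
  const int H = sigma.nrow(), W = sigma.ncol();
  // half of the 8-neighborhood so each pair is visited once
  static const int DY[4] = { 0, 1, 1, 1 };
  static const int DX[4] = { 1, 0, 1, -1 };
  double e = 0.0;
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      const int s = sigma(y, x);
      for (int k = 0; k < 4; ++k) {
        const int yy = y + DY[k], xx = x + DX[k];
        if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
        const int s2 = sigma(yy, xx);
        if (s2 != s)
          e += J(type_of(type, s) - 1, type_of(type, s2) - 1);
      }
    }
  }
  return e;
}

// Area-constraint energy: lambda * (A - a)^2 summed over type-cell identifiers.
// [[Rcpp::export]]
double cpp_size_energy(const IntegerVector& type,
                       const IntegerVector& area,
                       const NumericVector& target_area,
                       double lambda) {
  double e = 0.0;
  for (int i = 0; i < type.size(); ++i) {
    if (type[i] == T_CELL) {
      const double d = target_area[i] - area[i];
      e += lambda * d * d;
    }
  }
  return e;
}

// Local Hamiltonian change for copying sigma(src) into the target site.
// Coordinates are 0-based here; R wrappers convert.
static double delta_h_local(const IntegerMatrix& sigma,
                            const IntegerVector& type,
                            const IntegerVector& area,
                            const NumericVector& target_area,
                            const NumericMatrix& J, double lambda,
                            int ys, int xs, int yt, int xt) {
  const int H = sigma.nrow(), W = sigma.ncol();
  const int s_new = sigma(ys, xs);
  const int s_old = sigma(yt, xt);
  if (s_new == s_old) return 0.0;  // copying an identifier onto itself
  const int tau_new = type_of(type, s_new);
  const int tau_old = type_of(type, s_old);
  double dh = 0.0;
  for (int k = 0; k < 8; ++k) {
    const int yy = yt + RING_DY[k], xx = xt + RING_DX[k];
    if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
    const int sn = sigma(yy, xx);
    const int taun = type_of(type, sn);
    if (sn != s_new) dh += J(tau_new - 1, taun - 1);
    if (sn != s_old) dh -= J(tau_old - 1, taun - 1);
  }
  if (tau_old == T_CELL) {
    const double a = area[s_old - 1], A = target_area[s_old - 1];
    dh += lambda * ((A - (a - 1)) * (A - (a - 1)) - (A - a) * (A - a));
  }
  if (tau_new == T_CELL) {
    const double a = area[s_new - 1], A = target_area[s_new - 1];
    dh += lambda * ((A - (a + 1)) * (A - (a + 1)) - (A - a) * (A - a));
  }
  return dh;
}

// [[Rcpp::export]]
double cpp_delta_hamiltonian(const IntegerMatrix& sigma,
                             const IntegerVector& type,
                             const IntegerVector& area,
                             const NumericVector& target_area,
                             const NumericMatrix& J, double lambda,
                             int ys, int xs, int yt, int xt) {
  return delta_h_local(sigma, type, area, target_area, J, lambda,
                       ys - 1, xs - 1, yt - 1, xt - 1);
}

// Local ring test: would removing the target site from its cell leave the
// cell's sites in the surrounding 8-ring in more than one arc?  A cheap,
// conservative stand-in for a full connectivity check (the standard CPM
// practice); a BFS audit runs in the test suite.
static bool would_fragment(const IntegerMatrix& sigma, int yt, int xt, int s_old) {
  const int H = sigma.nrow(), W = sigma.ncol();
  bool belongs[8];
  int n_same = 0;
  for (int k = 0; k < 8; ++k) {
    const int yy = yt + RING_DY[k], xx = xt + RING_DX[k];
    belongs[k] = (yy >= 0 && yy < H && xx >= 0 && xx < W &&
                  sigma(yy, xx) == s_old);
    if (belongs[k]) ++n_same;
  }
  if (n_same == 0) return false;  // stray single pixel; removal cannot fragment
  int arcs = 0;
  for (int k = 0; k < 8; ++k)
    if (belongs[k] && !belongs[(k + 7) % 8]) ++arcs;
  return arcs > 1;
}

struct CopyOutcome { bool evaluated; bool accepted; };

// Core of one copy attempt (0-based coordinates).  Returns whether the
// proposal passed the static-type rules and whether it was accepted;
// mutates sigma/area in place on acceptance.
static CopyOutcome attempt_copy_core(IntegerMatrix& sigma,
                                     const IntegerVector& type,
                                     IntegerVector& area,
                                     const NumericVector& target_area,
                                     const NumericMatrix& J,
                                     double lambda, double mu,
                                     double h_conn,
                                     const NumericMatrix& fibrin_total,
                                     bool has_fibrin,
                                     double inv_p, double inv_E,
                                     double inv_m, double inv_theta,
                                     int ys, int xs, int yt, int xt) {
  CopyOutcome out = { false, false };
  const int s_new = sigma(ys, xs);
  const int s_old = sigma(yt, xt);
  if (s_new == s_old) return out;
  const int tau_src = type_of(type, s_new);
  const int tau_tgt = type_of(type, s_old);
  // static-type rules: only cells and medium move; fibrin may only be a
  // target (invasion); cell patch and border never change.
  if (tau_src != T_CELL && tau_src != T_MEDIUM) return out;
  if (tau_tgt != T_CELL && tau_tgt != T_MEDIUM && tau_tgt != T_FIBRIN) return out;

  double h0 = 0.0;
  if (tau_tgt == T_FIBRIN && has_fibrin) {
    const double f = fibrin_total(yt, xt);
    if (f > inv_theta)
      h0 += inv_p / (1.0 + std::exp(-inv_E * (f - inv_m)));
  }
  if (tau_tgt == T_CELL) {
    if (area[s_old - 1] <= 1 || would_fragment(sigma, yt, xt, s_old))
      h0 += h_conn;
  }
  const double dh = delta_h_local(sigma, type, area, target_area, J, lambda,
                                  ys, xs, yt, xt);
  out.evaluated = true;
  const double tot = dh + h0;
  bool accept = tot < 0.0;
  if (!accept) accept = (unif_rand() < std::exp(-tot / mu));
  if (accept) {
    sigma(yt, xt) = s_new;
    area[s_old - 1] -= 1;
    area[s_new - 1] += 1;
    out.accepted = true;
  }
  return out;
}

// Single copy attempt at a chosen source/target pair (1-based coordinates).
// [[Rcpp::export]]
List cpp_attempt_copy_at(IntegerMatrix sigma, const IntegerVector& type,
                         IntegerVector area, const NumericVector& target_area,
                         const NumericMatrix& J, double lambda, double mu,
                         double h_conn, Nullable<NumericMatrix> fibrin_total,
                         double inv_p, double inv_E, double inv_m,
                         double inv_theta,
                         int ys, int xs, int yt, int xt) {
  NumericMatrix fib;
  bool has_fib = fibrin_total.isNotNull();
  if (has_fib) fib = NumericMatrix(fibrin_total);
  CopyOutcome out = attempt_copy_core(sigma, type, area, target_area, J,
                                      lambda, mu, h_conn, fib, has_fib,
                                      inv_p, inv_E, inv_m, inv_theta,
                                      ys - 1, xs - 1, yt - 1, xt - 1);
  return List::create(_["evaluated"] = out.evaluated,
                      _["accepted"] = out.accepted);
}

// One Monte Carlo step: as many copy attempts as lattice sites.  Mutates
// sigma and area in place; draws from R's RNG stream.
// [[Rcpp::export]]
List cpp_monte_carlo_step(IntegerMatrix sigma, const IntegerVector& type,
                          IntegerVector area, const NumericVector& target_area,
                          const NumericMatrix& J, double lambda, double mu,
                          double h_conn, Nullable<NumericMatrix> fibrin_total,
                          double inv_p, double inv_E, double inv_m,
                          double inv_theta) {
  const int H = sigma.nrow(), W = sigma.ncol();
  const int n_attempts = H * W;
  NumericMatrix fib;
  bool has_fib = fibrin_total.isNotNull();
  if (has_fib) fib = NumericMatrix(fibrin_total);
  int n_eval = 0, n_acc = 0;
  for (int i = 0; i < n_attempts; ++i) {
    const int idx = (int)(unif_rand() * n_attempts);
    const int ys = idx % H, xs = idx / H;
    const int k = (int)(unif_rand() * 8);
    const int yt = ys + RING_DY[k], xt = xs + RING_DX[k];
    if (yt < 0 || yt >= H || xt < 0 || xt >= W) continue;
    CopyOutcome out = attempt_copy_core(sigma, type, area, target_area, J,
                                        lambda, mu, h_conn, fib, has_fib,
                                        inv_p, inv_E, inv_m, inv_theta,
                                        ys, xs, yt, xt);
    if (out.evaluated) ++n_eval;
    if (out.accepted) ++n_acc;
  }
  return List::create(_["attempts"] = n_attempts,
                      _["evaluated"] = n_eval,
                      _["accepted"] = n_acc);
}

// Per-identifier membrane statistics for the contact-inhibition rule:
// counts of boundary site-pairs (8-neighborhood) and of those pairs whose
// opposite site belongs to another type-cell identifier.
// [[Rcpp::export]]
List cpp_contact_ratio(const IntegerMatrix& sigma, const IntegerVector& type) {
  const int H = sigma.nrow(), W = sigma.ncol();
  const int n_ids = type.size();
  IntegerVector total(n_ids), cellcell(n_ids);
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      const int s = sigma(y, x);
      if (type_of(type, s) != T_CELL) continue;
      for (int k = 0; k < 8; ++k) {
        const int yy = y + RING_DY[k], xx = x + RING_DX[k];
        if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
        const int s2 = sigma(yy, xx);
        if (s2 == s) continue;
        total[s - 1] += 1;
        // the static side patch mimics the continuing monolayer, so
        // contact with it counts as cell-cell contact
        const int t2 = type_of(type, s2);
        if (t2 == T_CELL || t2 == T_PATCH) cellcell[s - 1] += 1;
      }
    }
  }
  return List::create(_["total"] = total, _["cell_contact"] = cellcell);
}

// Split a cell over its short principal axis: sites whose projection on the
// long axis is positive are reassigned to new_id (ties stay with the
// parent).  Returns the two daughter areas; performs no split (both zero)
// when the geometry is degenerate.
// [[Rcpp::export]]
List cpp_split_cell(IntegerMatrix sigma, int id, int new_id) {
  const int H = sigma.nrow(), W = sigma.ncol();
  std::vector<int> ys, xs;
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y)
      if (sigma(y, x) == id) { ys.push_back(y); xs.push_back(x); }
  const int n = (int)ys.size();
  if (n < 2) return List::create(_["parent"] = 0, _["daughter"] = 0);
  double my = 0.0, mx = 0.0;
  for (int i = 0; i < n; ++i) { my += ys[i]; mx += xs[i]; }
  my /= n; mx /= n;
  double sxx = 0.0, syy = 0.0, sxy = 0.0;
  for (int i = 0; i < n; ++i) {
    const double dy = ys[i] - my, dx = xs[i] - mx;
    sxx += dx * dx; syy += dy * dy; sxy += dx * dy;
  }
  // long-axis direction: eigenvector of the larger eigenvalue of the
  // second-moment tensor [[sxx, sxy], [sxy, syy]]
  const double tr = sxx + syy;
  const double det = sxx * syy - sxy * sxy;
  const double lam = 0.5 * tr + std::sqrt(std::max(0.0, 0.25 * tr * tr - det));
  double vx, vy;
  if (std::abs(sxy) > 1e-12) { vx = lam - syy; vy = sxy; }
  else if (sxx >= syy)       { vx = 1.0; vy = 0.0; }
  else                       { vx = 0.0; vy = 1.0; }
  const double nrm = std::sqrt(vx * vx + vy * vy);
  vx /= nrm; vy /= nrm;
  int n_new = 0;
  for (int i = 0; i < n; ++i) {
    const double proj = (xs[i] - mx) * vx + (ys[i] - my) * vy;
    if (proj > 0.0) ++n_new;
  }
  if (n_new == 0 || n_new == n)
    return List::create(_["parent"] = 0, _["daughter"] = 0);
  for (int i = 0; i < n; ++i) {
    const double proj = (xs[i] - mx) * vx + (ys[i] - my) * vy;
    if (proj > 0.0) sigma(ys[i], xs[i]) = new_id;
  }
  return List::create(_["parent"] = n - n_new, _["daughter"] = n_new);
}

// Full BFS connectivity audit used by the test suite: number of 8-connected
// components of the given identifier.
// [[Rcpp::export]]
int cpp_n_components(const IntegerMatrix& sigma, int id) {
  const int H = sigma.nrow(), W = sigma.ncol();
  std::vector<char> seen((size_t)H * W, 0);
  int n_comp = 0;
  std::vector<int> stack;
  for (int x0 = 0; x0 < W; ++x0) {
    for (int y0 = 0; y0 < H; ++y0) {
      const size_t i0 = (size_t)x0 * H + y0;
      if (seen[i0] || sigma(y0, x0) != id) continue;
      ++n_comp;
      stack.clear();
      stack.push_back((int)i0);
      seen[i0] = 1;
      while (!stack.empty()) {
        const int cur = stack.back(); stack.pop_back();
        const int y = cur % H, x = cur / H;
        for (int k = 0; k < 8; ++k) {
          const int yy = y + RING_DY[k], xx = x + RING_DX[k];
          if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
          const size_t ii = (size_t)xx * H + yy;
          if (!seen[ii] && sigma(yy, xx) == id) {
            seen[ii] = 1;
            stack.push_back((int)ii);
          }
        }
      }
    }
  }
  return n_comp;
}
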