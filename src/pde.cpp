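#include <Rcpp.h>
using namespace Rcpp;

#define T_CELL 1

static const int NB_DY[8] = { 1, 1, 0, -1, -1, -1, 0, 1 };
static const int NB_DX[8] = { 0, 1, 1, 1, 0, -1, -1, -1 };

// Mean of a field over each site and its existing 8-neighbors (9 sites in
// the interior, fewer at the domain edge).
// [[Rcpp::export]]
NumericMatrix cpp_nb8_mean(const NumericMatrix& f) {
  const int H = f.nrow(), W = f.ncol();
  NumericMatrix out(H, W);
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      double s = f(y, x);
      int n = 1;
      for (int k = 0; k < 8; ++k) {
        const int yy = y + NB_DY[k], xx = x + NB_DX[k];
        if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
        s += f(yy, xx);
        ++n;
      }
      out(y, x) = s / n;
    }
  }
  return out;
}

// One forward-Euler update of all reaction terms of the
// plasminogen-plasmin-TGFbeta1 network (no transport).  Field matrices are
// updated in place.  `upar_field` is the projected per-cell uPAR; the uPAR
// level driving plasmin activation at a site is the 9-site neighborhood
// mean of that field.  Returns the most negative value reached by any field
// (diagnostic for too-large time steps; no clipping is applied).
// [[Rcpp::export]]
double cpp_reaction_step(NumericMatrix F, NumericMatrix PLG,
                         NumericMatrix LTGF, NumericMatrix TGF,
                         NumericMatrix PAI, NumericMatrix FPLG,
                         NumericMatrix FLTGF, NumericMatrix FPLGL,
                         NumericMatrix FPLS, NumericMatrix FPLSL,
                         const NumericMatrix& upar_field,
                         const LogicalMatrix& cell_mask,
                         const List& par, double dt) {
  if (dt < 0) stop("negative time step");
  const double kf1 = par["k_f1"], kr1 = par["k_r1"];
  const double kf2 = par["k_f2"], kr2 = par["k_r2"];
  const double ku1 = par["k_u1"], km1 = par["k_m1"];
  const double ku2 = par["k_u2"], km2 = par["k_m2"];
  const double h = par["h"], d = par["d"];
  const double kf3 = par["k_f3"], alpha = par["alpha"];
  const double ePLG = par["eps_plg"], eLTGF = par["eps_ltgf"];
  const double eTGF = par["eps_tgf"], ePAI = par["eps_pai"];
  const double eFPLG = par["eps_fplg"], eFLTGF = par["eps_fltgf"];
  const double eFPLGL = par["eps_fplgl"], eFPLS = par["eps_fpls"];
  const double eFPLSL = par["eps_fplsl"];
  const int H = F.nrow(), W = F.ncol();
  NumericMatrix U = cpp_nb8_mean(upar_field);
  double min_val = 0.0, tot = 0.0;
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      const double f = F(y, x), plg = PLG(y, x), ltgf = LTGF(y, x);
      const double tgf = TGF(y, x), pai = PAI(y, x);
      const double fplg = FPLG(y, x), fltgf = FLTGF(y, x);
      const double fplgl = FPLGL(y, x), fpls = FPLS(y, x);
      const double fplsl = FPLSL(y, x);
      const double u = U(y, x);
      const double pls_tot = fpls + fplsl;
      // reversible binding (positive = binding direction)
      const double r1A = kf1 * plg * f - kr1 * fplg;
      const double r1B = kf1 * plg * fltgf - kr1 * fplgl;
      const double r2A = kf2 * ltgf * f - kr2 * fltgf;
      const double r2B = kf2 * ltgf * fplg - kr2 * fplgl;
      const double r2C = kf2 * ltgf * fpls - kr2 * fplsl;
      // plasmin-mediated TGF release (Michaelis-Menten in the substrate);
      // a zero substrate gives zero flux even if the half-saturation
      // constant is zero
      const double r3A = fltgf > 0 ? ku2 * fltgf * pls_tot / (km2 + fltgf) : 0;
      const double r3B = fplgl > 0 ? ku2 * fplgl * pls_tot / (km2 + fplgl) : 0;
      const double r3C = fplsl > 0 ? ku2 * fplsl * pls_tot / (km2 + fplsl) : 0;
      // uPAR-mediated plasmin activation
      const double r4A = fplg > 0 ? ku1 * u * fplg / (km1 + fplg) : 0;
      const double r4B = fplgl > 0 ? ku1 * u * fplgl / (km1 + fplgl) : 0;
      // fibrinolysis (Hill, exponent 2)
      const double r5A = fpls > 0 ? h * fpls * fpls / (d + fpls * fpls) : 0;
      const double r5B = fplsl > 0 ? h * fplsl * fplsl / (d + fplsl * fplsl) : 0;

      F(y, x)     = f     + dt * (-r1A - r2A + r3A);
      PLG(y, x)   = plg   + dt * (-ePLG * plg - r1A - r1B);
      LTGF(y, x)  = ltgf  + dt * (-eLTGF * ltgf - r2A - r2B - r2C + r5B);
      TGF(y, x)   = tgf   + dt * (-eTGF * tgf + r3A + r3B + r3C);
      PAI(y, x)   = pai   + dt * (-ePAI * pai
                                  - upar_field(y, x) * pai * kf3
                                  + (cell_mask(y, x) ? alpha : 0.0));
      FPLG(y, x)  = fplg  + dt * (-eFPLG * fplg + r1A - r2B - r4A + r3B);
      FLTGF(y, x) = fltgf + dt * (-eFLTGF * fltgf - r1B + r2A - r3A);
      FPLGL(y, x) = fplgl + dt * (-eFPLGL * fplgl + r1B + r2B - r4B - r3B);
      FPLS(y, x)  = fpls  + dt * (-eFPLS * fpls + r4A - r5A - r2C + r3C);
      FPLSL(y, x) = fplsl + dt * (-eFPLSL * fplsl + r4B - r5B + r2C - r3C);
      const double m = std::min({ F(y, x), PLG(y, x), LTGF(y, x), TGF(y, x),
                                  PAI(y, x), FPLG(y, x), FLTGF(y, x),
                                  FPLGL(y, x), FPLS(y, x), FPLSL(y, x) });
      if (m < min_val) min_val = m;
      tot += F(y, x) + PLG(y, x) + LTGF(y, x) + TGF(y, x) + PAI(y, x) +
             FPLG(y, x) + FLTGF(y, x) + FPLGL(y, x) + FPLS(y, x) + FPLSL(y, x);
    }
  }
  if (!R_finite(tot)) stop("non-finite concentration after reaction step");
  return min_val;
}

// Explicit 5-point Laplacian update with zero-flux boundaries, in place.
// [[Rcpp::export]]
void cpp_diffusion_step(NumericMatrix f, double D, double dt, double dx) {
  const int H = f.nrow(), W = f.ncol();
  const double nu = D * dt / (dx * dx);
  if (nu >= 0.25) stop("diffusion number D*dt/dx^2 must be below 0.25");
  NumericMatrix old = clone(f);
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      const double c = old(y, x);
      double lap = 0.0;
      if (y > 0)     lap += old(y - 1, x) - c;
      if (y < H - 1) lap += old(y + 1, x) - c;
      if (x > 0)     lap += old(y, x - 1) - c;
      if (x < W - 1) lap += old(y, x + 1) - c;
      f(y, x) = c + nu * lap;
    }
  }
}

// Per-cell sums feeding the uPAR ODE: total PAI over each cell's occupied
// sites C(s) and total TGF over its boundary sites P(s) (sites with at
// least one 8-neighbor of a different identifier).
// [[Rcpp::export]]
List cpp_cell_sums(const IntegerMatrix& sigma, const IntegerVector& type,
                   const NumericMatrix& TGF, const NumericMatrix& PAI) {
  const int H = sigma.nrow(), W = sigma.ncol();
  const int n_ids = type.size();
  NumericVector pai_sum(n_ids), tgf_sum(n_ids);
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      const int s = sigma(y, x);
      if (type[s - 1] != T_CELL) continue;
      pai_sum[s - 1] += PAI(y, x);
      bool boundary = false;
      for (int k = 0; k < 8; ++k) {
        const int yy = y + NB_DY[k], xx = x + NB_DX[k];
        if (yy < 0 || yy >= H || xx < 0 || xx >= W) { boundary = true; break; }
        if (sigma(yy, xx) != s) { boundary = true; break; }
      }
      if (boundary) tgf_sum[s - 1] += TGF(y, x);
    }
  }
  return List::create(_["pai_sum"] = pai_sum, _["tgf_sum"] = tgf_sum);
}

// Copy each cell's uPAR level into every site it occupies; zero elsewhere.
// [[Rcpp::export]]
void cpp_project_upar(const IntegerMatrix& sigma, const IntegerVector& type,
                      const NumericVector& upar, NumericMatrix upar_field) {
  const int H = sigma.nrow(), W = sigma.ncol();
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      const int s = sigma(y, x);
      upar_field(y, x) = (type[s - 1] == T_CELL) ? upar[s - 1] : 0.0;
    }
  }
}
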