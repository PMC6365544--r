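// Hot paths: explicit Euler stepping of the four-field peatland PDE system on a
// periodic grid, and toroidal connected-component labelling with winding
// detection. Fields are R matrices (ny rows = y, nx cols = x), column-major,
// so linear index = y + ny*x.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdio>

#if defined(__GNUC__) || defined(__clang__)
#define RESTRICT __restrict__
#else
#define RESTRICT
#endif

using namespace Rcpp;

struct Params {
  double rB, d, b, DB, cBS, kBS, HB;
  double rS, Smax, kSB, HS, DS;
  double p, tv, e, k, theta;
  double Nin, u, r, DN;
  double h1, h2, z, g;
};

static Params unpack(const NumericVector& pv) {
  Params P;
  P.rB = pv["r_B"];   P.d  = pv["d"];    P.b   = pv["b"];
  P.DB = pv["D_B"];   P.cBS = pv["c_BS"]; P.kBS = pv["k_BS"];
  P.HB = pv["H_B"];   P.rS = pv["r_S"];  P.Smax = pv["S_max"];
  P.kSB = pv["k_SB"]; P.HS = pv["H_S"];  P.DS  = pv["D_S"];
  P.p  = pv["p"];     P.tv = pv["t_v"];  P.e   = pv["e"];
  P.k  = pv["k"];     P.theta = pv["theta"];
  P.Nin = pv["N_in"]; P.u  = pv["u"];    P.r   = pv["r"];
  P.DN = pv["D_N"];   P.h1 = pv["h1"];   P.h2  = pv["h2"];
  P.z  = pv["z"];     P.g  = pv["g_conv"];
  return P;
}

static inline double fH(double H, const Params& P) {
  double f = (H - P.z - P.h2) / (P.h1 - P.h2);
  if (f < 0.0) f = 0.0;
  if (f > 1.0) f = 1.0;
  return f;
}

// One Euler step. Tendencies per Eqs. of the model with conservative face-flux
// transport. Returns clamp counts (B,S,N floored at 0; H floored at h_floor,
// optionally capped at h_cap when h_cap > 0).
static void do_step(std::vector<double>& B, std::vector<double>& S,
                    std::vector<double>& H, std::vector<double>& N,
                    std::vector<double>& Bn, std::vector<double>& Sn,
                    std::vector<double>& Hn, std::vector<double>& Nn,
                    std::vector<double>& Nc, std::vector<double>& HNc,
                    int ny, int nx, double dx, double dt,
                    const Params& P, double p_eff, double e_eff, double tv_eff,
                    double h_floor, double h_cap,
                    long long clamps[5], int& bad_field) {
  const double inv_dx2 = 1.0 / (dx * dx);
  const double inv_theta = 1.0 / P.theta;
  const double inv_ramp = 1.0 / (P.h1 - P.h2);
  const double f_off = P.z + P.h2;
  const double k_theta = P.k * inv_theta;
  const double thDN = P.theta * P.DN;
  const double db_loss = P.d + P.b;
  const double recyc = P.d * P.u / P.g;
  const double inv_Smax = 1.0 / P.Smax;
  const double inv_Htheta = 1.0 / P.theta;
  const int n = ny * nx;
  for (int i = 0; i < n; ++i) {
    Nc[i] = N[i] * inv_Htheta / H[i];
    HNc[i] = H[i] * Nc[i];
  }

  for (int x = 0; x < nx; ++x) {
    const int xe = (x + 1 == nx) ? 0 : x + 1;
    const int xw = (x == 0) ? nx - 1 : x - 1;
    const double* RESTRICT Bc = &B[ny * x];
    const double* RESTRICT Sc = &S[ny * x];
    const double* RESTRICT Hc = &H[ny * x];
    const double* RESTRICT Ncc = &Nc[ny * x];
    const double* RESTRICT HNcc = &HNc[ny * x];
    const double* RESTRICT Be = &B[ny * xe], * RESTRICT Bw = &B[ny * xw];
    const double* RESTRICT Se = &S[ny * xe], * RESTRICT Sw = &S[ny * xw];
    const double* RESTRICT He = &H[ny * xe], * RESTRICT Hw = &H[ny * xw];
    const double* RESTRICT Nce = &Nc[ny * xe], * RESTRICT Ncw = &Nc[ny * xw];
    const double* RESTRICT HNce = &HNc[ny * xe], * RESTRICT HNcw = &HNc[ny * xw];
    for (int y = 0; y < ny; ++y) {
      const int yn = (y == 0) ? ny - 1 : y - 1;
      const int ys = (y + 1 == ny) ? 0 : y + 1;
      const int i = y + ny * x;

      double f = (Hc[y] - f_off) * inv_ramp;
      if (f < 0.0) f = 0.0; else if (f > 1.0) f = 1.0;

      // linear diffusion (5-point Laplacian)
      const double lapB = (Be[y] + Bw[y] + Bc[yn] + Bc[ys] - 4.0 * Bc[y]) * inv_dx2;
      const double lapS = (Se[y] + Sw[y] + Sc[yn] + Sc[ys] - 4.0 * Sc[y]) * inv_dx2;

      // Darcy: div( (k/theta) H grad H ), face coef = arithmetic mean
      const double darcy = k_theta * 0.5 * inv_dx2 *
        ((Hc[y] + He[y]) * (He[y] - Hc[y]) +
         (Hc[y] + Hw[y]) * (Hw[y] - Hc[y]) +
         (Hc[y] + Hc[yn]) * (Hc[yn] - Hc[y]) +
         (Hc[y] + Hc[ys]) * (Hc[ys] - Hc[y]));

      // nutrient diffusion: div( theta D_N H grad Nc )
      const double ndif = thDN * 0.5 * inv_dx2 *
        ((Hc[y] + He[y]) * (Nce[y] - Ncc[y]) +
         (Hc[y] + Hw[y]) * (Ncw[y] - Ncc[y]) +
         (Hc[y] + Hc[yn]) * (Ncc[yn] - Ncc[y]) +
         (Hc[y] + Hc[ys]) * (Ncc[ys] - Ncc[y]));

      // nutrient advection with groundwater: div( k H Nc grad H )
      const double nadv = P.k * 0.5 * inv_dx2 *
        ((HNcc[y] + HNce[y]) * (He[y] - Hc[y]) +
         (HNcc[y] + HNcw[y]) * (Hw[y] - Hc[y]) +
         (HNcc[y] + HNcc[yn]) * (Hc[yn] - Hc[y]) +
         (HNcc[y] + HNcc[ys]) * (Hc[ys] - Hc[y]));

      const double dB = P.rB * Ncc[y] * Bc[y] * f - db_loss * Bc[y]
        - P.cBS * Sc[y] - P.kBS * Sc[y] * Bc[y] / (P.HB + Bc[y]) + P.DB * lapB;
      const double dS = P.rS * Sc[y] * (1.0 - Sc[y] * inv_Smax)
        - P.kSB * Sc[y] * Bc[y] / (P.HS + Sc[y]) + P.DS * lapS;
      const double dH = (p_eff - e_eff * f - tv_eff * f * Bc[y]) * inv_theta + darcy;
      const double dN = P.Nin - P.u * Ncc[y] * Bc[y] * f + recyc * Bc[y]
        - P.r * N[i] + ndif + nadv;

      double b2 = B[i] + dt * dB;
      double s2 = S[i] + dt * dS;
      double h2v = H[i] + dt * dH;
      double n2 = N[i] + dt * dN;
      // a clamp *event* is an overshoot through zero from a live cell;
      // holding an extinct cell (value exactly 0) at the boundary is the
      // constrained dynamics, not an integration artefact, and is not counted
      if (b2 < 0.0) { if (B[i] > 0.0) ++clamps[0]; b2 = 0.0; }
      if (s2 < 0.0) { if (S[i] > 0.0) ++clamps[1]; s2 = 0.0; }
      if (n2 < 0.0) { if (N[i] > 0.0) ++clamps[2]; n2 = 0.0; }
      if (h2v < h_floor) { if (H[i] > h_floor) ++clamps[3]; h2v = h_floor; }
      if (h_cap > 0.0 && h2v > h_cap) { h2v = h_cap; ++clamps[4]; }
      if (bad_field == 0) {
        if (!std::isfinite(b2)) bad_field = 1;
        else if (!std::isfinite(s2)) bad_field = 2;
        else if (!std::isfinite(h2v)) bad_field = 3;
        else if (!std::isfinite(n2)) bad_field = 4;
      }
      Bn[i] = b2; Sn[i] = s2; Hn[i] = h2v; Nn[i] = n2;
    }
  }
}

static const char* field_name(int code) {
  switch (code) {
    case 1: return "B"; case 2: return "S"; case 3: return "H"; default: return "N";
  }
}

static std::vector<double> as_vec(const NumericMatrix& m) {
  return std::vector<double>(m.begin(), m.end());
}

static NumericMatrix as_mat(const std::vector<double>& v, int ny, int nx) {
  NumericMatrix m(ny, nx);
  std::copy(v.begin(), v.end(), m.begin());
  return m;
}

// [[Rcpp::export]]
List cpp_step(NumericMatrix B0, NumericMatrix S0, NumericMatrix H0,
              NumericMatrix N0, NumericVector pv,
              double p_eff, double e_eff, double tv_eff,
              double dx, double dt, double h_floor, double h_cap) {
  const Params P = unpack(pv);
  const int ny = B0.nrow(), nx = B0.ncol(), n = ny * nx;
  std::vector<double> B = as_vec(B0), S = as_vec(S0), H = as_vec(H0), N = as_vec(N0);
  std::vector<double> Bn(n), Sn(n), Hn(n), Nn(n), Nc(n), HNc(n);
  long long clamps[5] = {0, 0, 0, 0, 0};
  int bad = 0;
  do_step(B, S, H, N, Bn, Sn, Hn, Nn, Nc, HNc, ny, nx, dx, dt, P,
          p_eff, e_eff, tv_eff, h_floor, h_cap, clamps, bad);
  if (bad != 0)
    stop("integration blow-up: non-finite values in field %s after one step",
         field_name(bad));
  return List::create(
    _["B"] = as_mat(Bn, ny, nx), _["S"] = as_mat(Sn, ny, nx),
    _["H"] = as_mat(Hn, ny, nx), _["N"] = as_mat(Nn, ny, nx),
    _["clamps"] = NumericVector::create(
      _["B"] = (double)clamps[0], _["S"] = (double)clamps[1],
      _["N"] = (double)clamps[2], _["H_floor"] = (double)clamps[3],
      _["H_cap"] = (double)clamps[4]));
}

// Integrate `years` whole years with piecewise-constant yearly forcing.
// precip/etf have length >= years. Yearly spatial means are recorded at the
// end of each year; snapshots every snap_every years (0 = none beyond final).
// [[Rcpp::export]]
List cpp_run(NumericMatrix B0, NumericMatrix S0, NumericMatrix H0,
             NumericMatrix N0, NumericVector pv,
             NumericVector precip, NumericVector etf,
             double t0, int years, int steps_per_year,
             double dt, double dx, int snap_every,
             double h_floor, double h_cap) {
  const Params P = unpack(pv);
  const int ny = B0.nrow(), nx = B0.ncol(), n = ny * nx;
  std::vector<double> B = as_vec(B0), S = as_vec(S0), H = as_vec(H0), N = as_vec(N0);
  std::vector<double> Bn(n), Sn(n), Hn(n), Nn(n), Nc(n), HNc(n);
  long long clamps[5] = {0, 0, 0, 0, 0};

  NumericMatrix yearly(years, 8); // year meanB meanS meanH meanN meanET precip etf
  List snaps;
  IntegerVector snap_years;

  for (int yr = 0; yr < years; ++yr) {
    const double pe = precip[yr], fe = etf[yr];
    const double e_eff = P.e * fe, tv_eff = P.tv * fe;
    for (int st = 0; st < steps_per_year; ++st) {
      int bad = 0;
      do_step(B, S, H, N, Bn, Sn, Hn, Nn, Nc, HNc, ny, nx, dx, dt, P,
              pe, e_eff, tv_eff, h_floor, h_cap, clamps, bad);
      if (bad != 0) {
        double t_fail = t0 + yr + (st + 1) * dt;
        stop("integration blow-up: non-finite values in field %s at t = %.6f yr "
             "(year %d, step %d)", field_name(bad), t_fail, yr + 1, st + 1);
      }
      B.swap(Bn); S.swap(Sn); H.swap(Hn); N.swap(Nn);
    }
    double mB = 0, mS = 0, mH = 0, mN = 0, mf = 0, mfB = 0;
    for (int i = 0; i < n; ++i) {
      mB += B[i]; mS += S[i]; mH += H[i]; mN += N[i];
      const double f = fH(H[i], P);
      mf += f; mfB += f * B[i];
    }
    mB /= n; mS /= n; mH /= n; mN /= n; mf /= n; mfB /= n;
    yearly(yr, 0) = t0 + yr + 1;
    yearly(yr, 1) = mB; yearly(yr, 2) = mS;
    yearly(yr, 3) = mH; yearly(yr, 4) = mN;
    yearly(yr, 5) = e_eff * mf + tv_eff * mfB;
    yearly(yr, 6) = pe; yearly(yr, 7) = fe;
    const bool last = (yr + 1 == years);
    if ((snap_every > 0 && (yr + 1) % snap_every == 0) || last) {
      snaps.push_back(List::create(
        _["B"] = as_mat(B, ny, nx), _["S"] = as_mat(S, ny, nx),
        _["H"] = as_mat(H, ny, nx), _["N"] = as_mat(N, ny, nx),
        _["time"] = t0 + yr + 1));
      snap_years.push_back(yr + 1);
    }
    Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["B"] = as_mat(B, ny, nx), _["S"] = as_mat(S, ny, nx),
    _["H"] = as_mat(H, ny, nx), _["N"] = as_mat(N, ny, nx),
    _["time"] = t0 + years,
    _["yearly"] = yearly,
    _["snapshots"] = snaps,
    _["snapshot_years"] = snap_years,
    _["clamps"] = NumericVector::create(
      _["B"] = (double)clamps[0], _["S"] = (double)clamps[1],
      _["N"] = (double)clamps[2], _["H_floor"] = (double)clamps[3],
      _["H_cap"] = (double)clamps[4]));
}

// Toroidal connected-component labelling with winding detection. BFS assigns
// each visited cell unwrapped coordinates; re-visiting a cell through a path
// whose unwrapped coordinates disagree with the stored ones by a multiple of
// the lattice size marks a nonzero winding number (torus percolation) in that
// direction.
// [[Rcpp::export]]
List cpp_label_torus(IntegerMatrix mask, int connectivity) {
  const int ny = mask.nrow(), nx = mask.ncol(), n = ny * nx;
  IntegerMatrix labels(ny, nx);
  std::vector<int> ux(n, 0), uy(n, 0);
  std::vector<int> areas;
  std::vector<int> wx, wy;

  int ndir = (connectivity == 8) ? 8 : 4;
  const int DY[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int DX[8] = {0, 0, -1, 1, -1, 1, -1, 1};

  std::queue<int> q;
  int next_label = 0;
  for (int x0 = 0; x0 < nx; ++x0) {
    for (int y0 = 0; y0 < ny; ++y0) {
      const int i0 = y0 + ny * x0;
      if (!mask[i0] || labels[i0] != 0) continue;
      ++next_label;
      int area = 0;
      bool wrapx = false, wrapy = false;
      labels[i0] = next_label;
      ux[i0] = x0; uy[i0] = y0;
      q.push(i0);
      while (!q.empty()) {
        const int i = q.front(); q.pop();
        ++area;
        const int y = i % ny, x = i / ny;
        for (int dir = 0; dir < ndir; ++dir) {
          int y2 = y + DY[dir], x2 = x + DX[dir];
          if (y2 < 0) y2 += ny; else if (y2 >= ny) y2 -= ny;
          if (x2 < 0) x2 += nx; else if (x2 >= nx) x2 -= nx;
          const int j = y2 + ny * x2;
          if (!mask[j]) continue;
          const int ex = ux[i] + DX[dir], ey = uy[i] + DY[dir];
          if (labels[j] == 0) {
            labels[j] = next_label;
            ux[j] = ex; uy[j] = ey;
            q.push(j);
          } else {
            if (ux[j] != ex) wrapx = true;
            if (uy[j] != ey) wrapy = true;
          }
        }
      }
      areas.push_back(area);
      wx.push_back(wrapx ? 1 : 0);
      wy.push_back(wrapy ? 1 : 0);
    }
  }

  return List::create(
    _["labels"] = labels,
    _["area_cells"] = IntegerVector(areas.begin(), areas.end()),
    _["wraps_x"] = LogicalVector(wx.begin(), wx.end()),
    _["wraps_y"] = LogicalVector(wy.begin(), wy.end()));
}
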