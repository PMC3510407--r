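#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Semi-discrete right-hand side of the two-phenotype + necrosis + oxygen
// system on a 1-D vertex-centred grid.
//
// State packing: y = (u_n[0..N-1], u_h[...], u_d[...], O2[...]).
// Densities are fractions of the carrying capacity; O2 is mmHg.
// All lengths in cm, times in s.
//
// par layout (kept in step with .pack_params in R/parameters.R):
//  0 D_n  1 D_h  2 D_O2  3 tau_n  4 tau_h  5 tau_nh  6 tau_hn  7 tau_hd
//  8 O2_S 9 O2_D 10 O2_T 11 delta_O2 12 A_n 13 uptake_ratio
//  14 switch_form (0 = tanh, 1 = hard step)
// vessel spec (each side): (O2_v, J, occlusion_time, occluded_mode)
//  occluded_mode: 0 = zero-flux after occlusion, 1 = Robin toward O2_v = 0

static inline double s_down(double O2, double centre, double width, int form) {
  if (form == 1) return O2 < centre ? 1.0 : (O2 > centre ? 0.0 : 0.5);
  const double z = (O2 - centre) / width;
  // tanh saturates to +/-1 within double precision beyond |z| ~ 19
  if (z > 19.0) return 0.0;
  if (z < -19.0) return 1.0;
  return 0.5 * (1.0 - std::tanh(z));
}

static void rhs_core(const double *y, double *dy, double t, int N, double dx,
                     const double *par, const double *vleft,
                     const double *vright) {
  const double Dn = par[0], Dh = par[1], DO2 = par[2];
  const double tn = par[3], th = par[4], tnh = par[5], thn = par[6],
               thd = par[7];
  const double O2S = par[8], O2D = par[9], O2T = par[10], dO2w = par[11];
  const double An = par[12], ur = par[13];
  const int form = (int)par[14];
  const double idx2 = 1.0 / (dx * dx);

  const double *un = y, *uh = y + N, *ud = y + 2 * N, *o2 = y + 3 * N;
  double *dn = dy, *dh = dy + N, *dd = dy + 2 * N, *doo = dy + 3 * N;

  for (int i = 0; i < N; ++i) {
    // Laplacians: interior central stencil, reflecting ghost nodes at walls
    double lun, luh, lo2;
    if (i == 0) {
      lun = 2.0 * (un[1] - un[0]) * idx2;
      luh = 2.0 * (uh[1] - uh[0]) * idx2;
      lo2 = 2.0 * (o2[1] - o2[0]) * idx2;
    } else if (i == N - 1) {
      lun = 2.0 * (un[N - 2] - un[N - 1]) * idx2;
      luh = 2.0 * (uh[N - 2] - uh[N - 1]) * idx2;
      lo2 = 2.0 * (o2[N - 2] - o2[N - 1]) * idx2;
    } else {
      lun = (un[i - 1] - 2.0 * un[i] + un[i + 1]) * idx2;
      luh = (uh[i - 1] - 2.0 * uh[i] + uh[i + 1]) * idx2;
      lo2 = (o2[i - 1] - 2.0 * o2[i] + o2[i + 1]) * idx2;
    }

    const double Snh = s_down(o2[i], O2S, dO2w, form);
    const double Shn = 1.0 - Snh;
    const double Shd = s_down(o2[i], O2D, dO2w, form);
    const double room = 1.0 - (un[i] + uh[i] + ud[i]);

    const double sw_nh = Snh * un[i] / tnh;
    const double sw_hn = Shn * uh[i] / thn;
    const double death = Shd * uh[i] / thd;

    dn[i] = Dn * lun + un[i] * room / tn - sw_nh + sw_hn;
    dh[i] = Dh * luh + uh[i] * room / th + sw_nh - sw_hn - death;
    dd[i] = death;
    doo[i] = DO2 * lo2 - An * (un[i] + ur * uh[i]) * o2[i] / (O2T + o2[i]);
  }

  // transmural oxygen exchange at the vessel walls (ghost-node Robin);
  // an occluded vessel degrades to the reflecting wall already applied
  if (!(vleft[2] <= t)) {
    doo[0] += 2.0 * DO2 / (vleft[1] * dx) * (vleft[0] - o2[0]);
  } else if (vleft[3] == 1.0) {
    doo[0] += 2.0 * DO2 / (vleft[1] * dx) * (0.0 - o2[0]);
  }
  if (!(vright[2] <= t)) {
    doo[N - 1] += 2.0 * DO2 / (vright[1] * dx) * (vright[0] - o2[N - 1]);
  } else if (vright[3] == 1.0) {
    doo[N - 1] += 2.0 * DO2 / (vright[1] * dx) * (0.0 - o2[N - 1]);
  }
}

// [[Rcpp::export(name = ".rhs_kernel")]]
NumericVector rhs_kernel(NumericVector y, double t, int N, double dx,
                         NumericVector par, NumericVector vleft,
                         NumericVector vright) {
  if (y.size() != 4 * N) stop("state length must be 4 * N");
  NumericVector dy(4 * N);
  rhs_core(&y[0], &dy[0], t, N, dx, &par[0], &vleft[0], &vright[0]);
  return dy;
}

// Fixed-step classical RK4 over the same kernel, storing snapshots at the
// requested times.  Returns a (4N) x length(snap_times) matrix.
// [[Rcpp::export(name = ".rk4_integrate")]]
NumericMatrix rk4_integrate(NumericVector y0, int N, double dx,
                            NumericVector par, NumericVector vleft,
                            NumericVector vright, double dt,
                            NumericVector snap_times) {
  const int n = y0.size(), nsnap = snap_times.size();
  NumericMatrix out(n, nsnap);
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(n), k2(n), k3(n), k4(n), tmp(n);
  const double *pp = &par[0], *vl = &vleft[0], *vr = &vright[0];
  double t = 0.0;
  int isnap = 0;
  auto store = [&](int k) {
    for (int j = 0; j < n; ++j) out(j, k) = y[j];
  };
  while (isnap < nsnap && snap_times[isnap] <= 1e-9 * dt) store(isnap++);

  const double t_end = snap_times[nsnap - 1];
  long step = 0;
  while (t < t_end - 1e-9 * dt) {
    double h = dt;
    if (t + h > t_end) h = t_end - t;
    rhs_core(y.data(), k1.data(), t, N, dx, pp, vl, vr);
    for (int j = 0; j < n; ++j) tmp[j] = y[j] + 0.5 * h * k1[j];
    rhs_core(tmp.data(), k2.data(), t + 0.5 * h, N, dx, pp, vl, vr);
    for (int j = 0; j < n; ++j) tmp[j] = y[j] + 0.5 * h * k2[j];
    rhs_core(tmp.data(), k3.data(), t + 0.5 * h, N, dx, pp, vl, vr);
    for (int j = 0; j < n; ++j) tmp[j] = y[j] + h * k3[j];
    rhs_core(tmp.data(), k4.data(), t + h, N, dx, pp, vl, vr);
    for (int j = 0; j < n; ++j)
      y[j] += h / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
    t += h;
    if ((++step & 2047) == 0) {
      Rcpp::checkUserInterrupt();
      for (int j = 0; j < n; ++j)
        if (std::isnan(y[j]))
          stop("NaN detected at t = %f s (state index %d)", t, j + 1);
    }
    while (isnap < nsnap && snap_times[isnap] <= t + 1e-6 * dt) store(isnap++);
  }
  while (isnap < nsnap) store(isnap++);
  return out;
}
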