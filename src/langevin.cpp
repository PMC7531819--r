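// Euler-Maruyama integration of the two-variable working-memory circuit.
// Noise is injected isotropically in current space (diffusion D) and
// mapped to gating space through the inverse coupling matrix each step;
// the gating state is mirror-reflected into [0,1]^2, matching the
// zero-flux boundary of the Fokker-Planck solver.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Circuit {
  double a, b, d, gamma, tauS;
  double J11, J12, J21, J22, I0;
  double Mi11, Mi12, Mi21, Mi22;  // inverse coupling matrix
  double rg1, rg2;                // conormal reflection ratios G21/G11, G12/G22
};

static Circuit make_circuit(const NumericVector& p) {
  // p = (a, b, d, gamma, tauS, J11, J12, J21, J22, I0)
  Circuit c;
  c.a = p[0]; c.b = p[1]; c.d = p[2]; c.gamma = p[3]; c.tauS = p[4];
  c.J11 = p[5]; c.J12 = p[6]; c.J21 = p[7]; c.J22 = p[8]; c.I0 = p[9];
  double det = c.J11 * c.J22 - c.J12 * c.J21;
  c.Mi11 =  c.J22 / det; c.Mi12 =  c.J12 / det;
  c.Mi21 =  c.J21 / det; c.Mi22 =  c.J11 / det;
  // G = Minv Minv^T is proportional to the gating-frame diffusion tensor;
  // reflection at the gating-box walls follows the conormal direction G n,
  // i.e. the plain mirror image in current space where noise is isotropic
  double G11 = c.Mi11 * c.Mi11 + c.Mi12 * c.Mi12;
  double G12 = c.Mi11 * c.Mi21 + c.Mi12 * c.Mi22;
  double G22 = c.Mi21 * c.Mi21 + c.Mi22 * c.Mi22;
  c.rg1 = G12 / G11;  // S2 shift per unit S1 reflection
  c.rg2 = G12 / G22;  // S1 shift per unit S2 reflection
  return c;
}

static inline double fi(double I, const Circuit& c) {
  double x = c.a * I - c.b, z = c.d * x, r;
  if (std::fabs(z) < 1e-8) r = 1.0 / c.d + x / 2 + c.d * x * x / 12;
  else r = x / (1.0 - std::exp(-z));
  return r > 0 ? r : 0;
}

// conormal (current-space mirror) reflection into the gating box
static inline void reflect(double& S1, double& S2, const Circuit& c) {
  for (int it = 0; it < 8; ++it) {
    bool moved = false;
    if (S1 < 0.0) { S2 -= 2.0 * S1 * c.rg1; S1 = -S1; moved = true; }
    else if (S1 > 1.0) { double e = S1 - 1.0; S2 -= 2.0 * e * c.rg1; S1 = 1.0 - e; moved = true; }
    if (S2 < 0.0) { S1 -= 2.0 * S2 * c.rg2; S2 = -S2; moved = true; }
    else if (S2 > 1.0) { double e = S2 - 1.0; S1 -= 2.0 * e * c.rg2; S2 = 1.0 - e; moved = true; }
    if (!moved) return;
  }
  // pathological corner case: clamp
  if (S1 < 0.0) S1 = 0.0; if (S1 > 1.0) S1 = 1.0;
  if (S2 < 0.0) S2 = 0.0; if (S2 > 1.0) S2 = 1.0;
}

// one EM step; noise (n1, n2) are N(0, 1) draws scaled outside
static inline void em_step(double& S1, double& S2, double Ie1, double Ie2,
                           double dt, double amp, const Circuit& c) {
  double I1 = c.J11 * S1 - c.J12 * S2 + c.I0 + Ie1;
  double I2 = c.J22 * S2 - c.J21 * S1 + c.I0 + Ie2;
  double F1 = -S1 / c.tauS + (1.0 - S1) * c.gamma * fi(I1, c);
  double F2 = -S2 / c.tauS + (1.0 - S2) * c.gamma * fi(I2, c);
  double n1 = amp * norm_rand(), n2 = amp * norm_rand();
  S1 += F1 * dt + c.Mi11 * n1 + c.Mi12 * n2;
  S2 += F2 * dt + c.Mi21 * n1 + c.Mi22 * n2;
  reflect(S1, S2, c);
}

// [[Rcpp::export]]
List cpp_simulate(NumericVector pars, NumericMatrix phases,
                  double S1_0, double S2_0,
                  double D, double dt, int stride) {
  Circuit c = make_circuit(pars);
  double amp = std::sqrt(2.0 * D * dt);
  double S1 = S1_0, S2 = S2_0;
  std::vector<double> ts, s1, s2;
  std::vector<int> ph;
  double t = 0.0;
  ts.push_back(t); s1.push_back(S1); s2.push_back(S2); ph.push_back(1);
  long step = 0;
  for (int p = 0; p < phases.nrow(); ++p) {
    long n = (long)std::lround(phases(p, 0) / dt);
    double Ie1 = phases(p, 1), Ie2 = phases(p, 2);
    for (long k = 0; k < n; ++k) {
      em_step(S1, S2, Ie1, Ie2, dt, amp, c);
      t += dt; ++step;
      if (step % stride == 0) {
        ts.push_back(t); s1.push_back(S1); s2.push_back(S2);
        ph.push_back(p + 1);
      }
      if (!R_FINITE(S1) || !R_FINITE(S2))
        stop("non-finite state at t = %g; reduce dt", t);
    }
  }
  return List::create(_["time"] = ts, _["S1"] = s1, _["S2"] = s2,
                      _["phase"] = ph);
}

// [[Rcpp::export]]
NumericMatrix cpp_simulate_positions(NumericVector pars,
                                     double Ie1, double Ie2,
                                     NumericVector S0, double D, double dt,
                                     long n_steps, int stride) {
  Circuit c = make_circuit(pars);
  double amp = std::sqrt(2.0 * D * dt);
  double S1 = S0[0], S2 = S0[1];
  long n_out = n_steps / stride + 1;
  NumericMatrix out(n_out, 2);
  out(0, 0) = S1; out(0, 1) = S2;
  long row = 1;
  for (long k = 1; k <= n_steps; ++k) {
    em_step(S1, S2, Ie1, Ie2, dt, amp, c);
    if (k % stride == 0 && row < n_out) {
      out(row, 0) = S1; out(row, 1) = S2; ++row;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_first_passage(NumericVector pars,
                                double Ie1, double Ie2,
                                NumericVector start, NumericVector dest,
                                double dest_r, int n_trials,
                                double D, double dt, double horizon) {
  Circuit c = make_circuit(pars);
  double amp = std::sqrt(2.0 * D * dt);
  double r2 = dest_r * dest_r;
  long max_steps = (long)(horizon / dt);
  NumericVector times(n_trials, NA_REAL);
  for (int tr = 0; tr < n_trials; ++tr) {
    double S1 = start[0], S2 = start[1];
    double dx = S1 - dest[0], dy = S2 - dest[1];
    if (dx * dx + dy * dy <= r2) { times[tr] = 0.0; continue; }
    for (long k = 1; k <= max_steps; ++k) {
      em_step(S1, S2, Ie1, Ie2, dt, amp, c);
      dx = S1 - dest[0]; dy = S2 - dest[1];
      if (dx * dx + dy * dy <= r2) { times[tr] = k * dt; break; }
    }
    if (tr % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return times;
}

// Occupancy histogram of switching segments: positions between the last
// exit from the start disk and the first entry into the destination disk.
// [[Rcpp::export]]
NumericMatrix cpp_path_histogram(NumericVector pars,
                                 double Ie1, double Ie2,
                                 NumericVector start, double start_r,
                                 NumericVector dest, double dest_r,
                                 int n_events, double D, double dt,
                                 double horizon, int nx, int ny) {
  Circuit c = make_circuit(pars);
  double amp = std::sqrt(2.0 * D * dt);
  double rs2 = start_r * start_r, rd2 = dest_r * dest_r;
  long max_steps = (long)(horizon / dt);
  NumericMatrix H(nx, ny);
  std::vector<int> buf;
  int events = 0;
  for (int tr = 0; tr < n_events * 50 && events < n_events; ++tr) {
    double S1 = start[0], S2 = start[1];
    buf.clear();
    bool done = false;
    for (long k = 1; k <= max_steps && !done; ++k) {
      em_step(S1, S2, Ie1, Ie2, dt, amp, c);
      double dxs = S1 - start[0], dys = S2 - start[1];
      double dxd = S1 - dest[0], dyd = S2 - dest[1];
      if (dxs * dxs + dys * dys <= rs2) {
        buf.clear();                     // back in the start basin
      } else {
        int i = (int)(S1 * nx); if (i >= nx) i = nx - 1; if (i < 0) i = 0;
        int j = (int)(S2 * ny); if (j >= ny) j = ny - 1; if (j < 0) j = 0;
        buf.push_back(i + j * nx);
        if (dxd * dxd + dyd * dyd <= rd2) {
          for (size_t m = 0; m < buf.size(); ++m)
            H[buf[m]] += 1.0;
          ++events;
          done = true;
        }
      }
      if (buf.size() > 50000000) stop("switching segment buffer overflow");
    }
    Rcpp::checkUserInterrupt();
  }
  if (events == 0)
    stop("no switching events observed within the horizon");
  H.attr("events") = events;
  return H;
}
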