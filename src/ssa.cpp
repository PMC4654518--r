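// Stochastic simulation (exact SSA and fixed-step tau-leaping) for the
// package's reaction-network oscillators. Rate laws are evaluated on
// concentrations X / Omega and multiplied by Omega (system-size convention
// for Hill/Michaelis-Menten propensities). Uses R's RNG stream, so results
// are reproducible from set.seed() on the R side.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ---- model definitions -----------------------------------------------------

// 8-state circadian feedback loop: species p, c1, c2, P, C1, C2, C1N, C2N.
// 26 reactions (18 kinetic + 8 first-order dilution); parameter order:
//  0 vtp  1 vtc1  2 vtc2  3 knp  4 knc  5 vdp  6 vdc1  7 vdc2  8 kdp  9 kdc
// 10 ktlnp 11 ktlnc 12 vdP 13 kdP 14 vdC1 15 vdC2 16 kdC 17 vaC1P 18 vaC2P
// 19 vdC1P 20 vdC2P 21 vdCn 22 mc 23 kdCn 24 kdil
static const int CLOCK8_NSP = 8;
static const int CLOCK8_NRX = 26;
static const int clock8_stoich[CLOCK8_NRX][CLOCK8_NSP] = {
  { 1, 0, 0, 0, 0, 0, 0, 0},   // transcription p
  { 0, 1, 0, 0, 0, 0, 0, 0},   // transcription c1
  { 0, 0, 1, 0, 0, 0, 0, 0},   // transcription c2
  {-1, 0, 0, 0, 0, 0, 0, 0},   // degradation p
  { 0,-1, 0, 0, 0, 0, 0, 0},   // degradation c1
  { 0, 0,-1, 0, 0, 0, 0, 0},   // degradation c2
  { 0, 0, 0, 1, 0, 0, 0, 0},   // translation P
  { 0, 0, 0, 0, 1, 0, 0, 0},   // translation C1
  { 0, 0, 0, 0, 0, 1, 0, 0},   // translation C2
  { 0, 0, 0,-1, 0, 0, 0, 0},   // degradation P
  { 0, 0, 0, 0,-1, 0, 0, 0},   // degradation C1
  { 0, 0, 0, 0, 0,-1, 0, 0},   // degradation C2
  { 0, 0, 0,-1,-1, 0, 1, 0},   // association P + C1 -> C1N
  { 0, 0, 0,-1, 0,-1, 0, 1},   // association P + C2 -> C2N
  { 0, 0, 0, 1, 1, 0,-1, 0},   // dissociation C1N -> P + C1
  { 0, 0, 0, 1, 0, 1, 0,-1},   // dissociation C2N -> P + C2
  { 0, 0, 0, 0, 0, 0,-1, 0},   // nuclear degradation C1N
  { 0, 0, 0, 0, 0, 0, 0,-1},   // nuclear degradation C2N
  {-1, 0, 0, 0, 0, 0, 0, 0},   // dilution p
  { 0,-1, 0, 0, 0, 0, 0, 0},   // dilution c1
  { 0, 0,-1, 0, 0, 0, 0, 0},   // dilution c2
  { 0, 0, 0,-1, 0, 0, 0, 0},   // dilution P
  { 0, 0, 0, 0,-1, 0, 0, 0},   // dilution C1
  { 0, 0, 0, 0, 0,-1, 0, 0},   // dilution C2
  { 0, 0, 0, 0, 0, 0,-1, 0},   // dilution C1N
  { 0, 0, 0, 0, 0, 0, 0,-1}    // dilution C2N
};

static inline void clock8_prop(const double* x, const double* th,
                               double omega, double* a) {
  const double p = x[0] / omega, c1 = x[1] / omega, c2 = x[2] / omega,
               P = x[3] / omega, C1 = x[4] / omega, C2 = x[5] / omega,
               C1N = x[6] / omega, C2N = x[7] / omega;
  const double cn = C1N + C2N;
  const double knp3 = th[3] * th[3] * th[3];
  const double knc3 = th[4] * th[4] * th[4];
  const double cn3 = cn * cn * cn;
  a[0]  = omega * th[0] * knp3 / (knp3 + cn3);
  a[1]  = omega * th[1] * knc3 / (knc3 + cn3);
  a[2]  = omega * th[2] * knc3 / (knc3 + cn3);
  a[3]  = omega * th[5] * p / (th[8] + p);
  a[4]  = omega * th[6] * c1 / (th[9] + c1);
  a[5]  = omega * th[7] * c2 / (th[9] + c2);
  a[6]  = omega * th[10] * p;
  a[7]  = omega * th[11] * c1;
  a[8]  = omega * th[11] * c2;
  a[9]  = omega * th[12] * P / (th[13] + P);
  a[10] = omega * th[14] * C1 / (th[16] + C1 + C2);
  a[11] = omega * th[15] * C2 / (th[16] + C1 + C2);
  a[12] = omega * th[17] * P * C1;
  a[13] = omega * th[18] * P * C2;
  a[14] = omega * th[19] * C1N;
  a[15] = omega * th[20] * C2N;
  a[16] = omega * th[21] * C1N / (th[23] + C1N + C2N);
  a[17] = omega * th[21] * th[22] * C2N / (th[23] + C1N + C2N);
  for (int s = 0; s < 8; ++s) a[18 + s] = th[24] * x[s];
}

// 3-state Goodwin-type transcription-translation oscillator with
// Michaelis-Menten degradation: species M, Pc, PN. 6 reactions; parameters:
//  0 v1  1 K1  2 hill  3 v2  4 K2  5 k3  6 v4  7 K4  8 k5  9 v6  10 K6
static const int GW3_NSP = 3;
static const int GW3_NRX = 6;
static const int gw3_stoich[GW3_NRX][GW3_NSP] = {
  { 1, 0, 0},   // transcription
  {-1, 0, 0},   // mRNA degradation
  { 0, 1, 0},   // translation
  { 0,-1, 0},   // cytosolic degradation
  { 0,-1, 1},   // nuclear import
  { 0, 0,-1}    // nuclear degradation
};

static inline void gw3_prop(const double* x, const double* th,
                            double omega, double* a) {
  const double M = x[0] / omega, Pc = x[1] / omega, PN = x[2] / omega;
  const double kh = std::pow(th[1], th[2]);
  const double ph = std::pow(PN, th[2]);
  a[0] = omega * th[0] * kh / (kh + ph);
  a[1] = omega * th[3] * M / (th[4] + M);
  a[2] = omega * th[5] * M;
  a[3] = omega * th[6] * Pc / (th[7] + Pc);
  a[4] = omega * th[8] * Pc;
  a[5] = omega * th[9] * PN / (th[10] + PN);
}

// ---- simulator -------------------------------------------------------------

// Simulate n_cells independent realizations; returns the population mean
// trajectory for every species (n_out x n_sp), and optionally the per-cell
// trajectories of one tracked species (n_out x n_cells).
// [[Rcpp::export]]
List simulate_cells_cpp(int model_id, NumericVector params, double omega,
                        NumericVector x0_counts, double t_end, double dt_out,
                        int n_cells, double tau, NumericVector cell_scale,
                        bool exact, int track_species) {
  const int n_sp = (model_id == 1) ? CLOCK8_NSP : GW3_NSP;
  const int n_rx = (model_id == 1) ? CLOCK8_NRX : GW3_NRX;
  if (x0_counts.size() != n_sp) stop("x0 has wrong length for this model");
  const int n_out = (int)std::floor(t_end / dt_out + 1e-9) + 1;

  NumericMatrix mean_traj(n_out, n_sp);
  NumericMatrix cells_out(track_species > 0 ? n_out : 1,
                          track_species > 0 ? n_cells : 1);
  std::vector<double> x(n_sp), a(n_rx);
  const double* th = REAL(params);

  RNGScope rngScope;
  for (int c = 0; c < n_cells; ++c) {
    const double scale = (cell_scale.size() == n_cells) ? cell_scale[c]
                         : (cell_scale.size() == 1 ? cell_scale[0] : 1.0);
    for (int s = 0; s < n_sp; ++s) x[s] = std::floor(x0_counts[s] + 0.5);
    double t = 0.0;
    int iout = 0;

    auto record = [&](int idx) {
      for (int s = 0; s < n_sp; ++s) mean_traj(idx, s) += x[s];
      if (track_species > 0) cells_out(idx, c) = x[track_species - 1];
    };

    if (exact) {
      record(iout++);
      while (iout < n_out) {
        if (model_id == 1) clock8_prop(x.data(), th, omega, a.data());
        else gw3_prop(x.data(), th, omega, a.data());
        double a0 = 0.0;
        for (int j = 0; j < n_rx; ++j) {
          if (a[j] < 0) a[j] = 0;
          a0 += a[j] * scale;
        }
        if (a0 <= 0) {           // absorbing state: hold
          while (iout < n_out) record(iout++);
          break;
        }
        t += R::exp_rand() / a0;
        while (iout < n_out && t > iout * dt_out) record(iout++);
        if (iout >= n_out) break;
        double r = unif_rand() * a0;
        int j = 0;
        for (double acc = a[0] * scale; j < n_rx - 1 && r > acc;
             acc += a[++j] * scale) {}
        const int* st = (model_id == 1) ? clock8_stoich[j] : gw3_stoich[j];
        for (int s = 0; s < n_sp; ++s) x[s] += st[s];
      }
    } else {
      record(iout++);
      const int sub = std::max(1, (int)std::ceil(dt_out / tau - 1e-9));
      const double h = dt_out / sub;
      for (; iout < n_out; ++iout) {
        for (int k = 0; k < sub; ++k) {
          if (model_id == 1) clock8_prop(x.data(), th, omega, a.data());
          else gw3_prop(x.data(), th, omega, a.data());
          for (int j = 0; j < n_rx; ++j) {
            if (a[j] <= 0) continue;
            const double nk = R::rpois(a[j] * scale * h);
            if (nk == 0) continue;
            const int* st = (model_id == 1) ? clock8_stoich[j] : gw3_stoich[j];
            for (int s = 0; s < n_sp; ++s) x[s] += nk * st[s];
          }
          for (int s = 0; s < n_sp; ++s) if (x[s] < 0) x[s] = 0;
        }
        record(iout);
      }
    }
  }
  for (int i = 0; i < n_out; ++i)
    for (int s = 0; s < n_sp; ++s) mean_traj(i, s) /= n_cells;
  if (track_species > 0)
    return List::create(_["mean"] = mean_traj, _["cells"] = cells_out);
  return List::create(_["mean"] = mean_traj, _["cells"] = R_NilValue);
}
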