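// Fixed-step RK4 integrator for the cortex-basal ganglia-thalamus network.
//
// Eight populations: eCTX, iCTX (Izhikevich), dSTR, idSTR (HH striatal),
// STN, GPe, GPi (HH pallidal), TH (HH thalamocortical relay). Synapses are
// delayed alpha kernels implemented as a pair of linear filter states (z, s)
// per postsynaptic neuron per projection; a presynaptic spike increments z
// by 1 after the transmission delay, which reproduces the kernel
// ((t - ts - td)/tau) exp(-(t - ts - td)/tau) by superposition.
//
// Voltage-dependent gating functions are evaluated through dense lookup
// tables (0.02 mV grid, linear interpolation) built once per process.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
#include <cstdint>
using namespace Rcpp;

namespace {

const int P_ECTX = 0, P_ICTX = 1, P_DSTR = 2, P_IDSTR = 3,
          P_STN = 4, P_GPE = 5, P_GPI = 6, P_TH = 7, NPOP = 8;

const int NGATE[NPOP] = {0, 0, 4, 4, 11, 3, 3, 2};

const double VMIN = -200.0, VMAX = 100.0, DV = 0.02;
const int NT = (int)((VMAX - VMIN) / DV) + 2;

// Counter-based RNG (splitmix64 + Box-Muller), keyed by (seed, absolute
// step, draw index): the noise realization is a pure function of the seed
// and simulation time, so segmenting a run does not change its trajectory.
inline uint64_t sm64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}
inline double u01(uint64_t x) {
  return ((x >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}
inline double norm_draw(uint64_t base, int j) {
  double u1 = u01(sm64(base + (uint64_t)(2 * j)));
  double u2 = u01(sm64(base + (uint64_t)(2 * j + 1)));
  return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
}

inline double sexp(double x) {
  if (x > 500.0) x = 500.0;
  if (x < -500.0) x = -500.0;
  return std::exp(x);
}
inline double sigm(double v, double w, double s) {
  return 1.0 / (1.0 + sexp(-(v + w) / s));
}
// x / (1 - exp(-x/k)) with the removable singularity filled in
inline double rate(double x, double k) {
  if (std::fabs(x) < 1e-7) return k + x / 2.0;
  return x / (1.0 - sexp(-x / k));
}

struct Tab {
  std::vector<double> A, B;
  Tab() : A(NT), B(NT) {}
  inline void get(double v, double &a, double &b) const {
    double x = (v - VMIN) / DV;
    if (x < 0.0) x = 0.0;
    if (x > NT - 2.0) x = NT - 2.0;
    int i = (int)x;
    double f = x - i;
    a = A[i] + f * (A[i + 1] - A[i]);
    b = B[i] + f * (B[i + 1] - B[i]);
  }
  inline double getA(double v) const {
    double x = (v - VMIN) / DV;
    if (x < 0.0) x = 0.0;
    if (x > NT - 2.0) x = NT - 2.0;
    int i = (int)x;
    double f = x - i;
    return A[i] + f * (A[i + 1] - A[i]);
  }
};

// sigmoid_tau tables: A = Xinf, B = tau/lambda. alpha_beta: A = alpha, B = beta.
struct Gates {
  Tab stn[11];                // m h n p q r a b c d1 d2
  Tab gp[3];                  // h n r
  Tab gp_minf, gp_ainf, gp_sinf;
  Tab th[2];                  // h r
  Tab th_minf, th_pinf;
  Tab str[4];                 // m h n p (alpha/beta)
  bool built = false;
};

Gates G;

void fill_sig(Tab &t, double w, double s, double lambda,
              double (*tauf)(double)) {
  for (int i = 0; i < NT; ++i) {
    double v = VMIN + i * DV;
    t.A[i] = sigm(v, w, s);
    t.B[i] = tauf(v) / lambda;
  }
}
void fill_inf(Tab &t, double w, double s) {
  for (int i = 0; i < NT; ++i) t.A[i] = sigm(VMIN + i * DV, w, s);
}

double tau_stn_m(double v) { return 0.2 + 3.0 / (1.0 + sexp((v + 53.0) / 0.7)); }
double tau_stn_h(double v) { return 24.5 / (sexp((v + 50.0) / 15.0) + sexp((v + 50.0) / 16.0)); }
double tau_stn_n(double v) { return 11.0 / (sexp(-(v + 40.0) / 14.0) + sexp(-(v + 40.0) / 50.0)); }
double tau_stn_p(double v) { return 5.0 + 0.33 / (sexp((v + 27.0) / 10.0) + sexp(-(v + 102.0) / 15.0)); }
double tau_stn_q(double v) { return 400.0 / (sexp((v + 50.0) / 15.0) + sexp(-(v + 50.0) / 16.0)); }
double tau_stn_r(double)   { return 2.0; }
double tau_stn_a(double v) { return 1.0 + 1.0 / (1.0 + sexp((v + 40.0) / 0.5)); }
double tau_stn_b(double v) { return 200.0 / (sexp((v + 60.0) / 30.0) + sexp(-(v + 40.0) / 10.0)); }
double tau_stn_c(double v) { return 45.0 + 10.0 / (sexp((v + 27.0) / 20.0) + sexp(-(v + 50.0) / 15.0)); }
double tau_stn_d1(double v){ return 400.0 + 500.0 / (sexp((v + 40.0) / 15.0) + sexp(-(v + 20.0) / 20.0)); }
double tau_stn_d2(double)  { return 130.0; }
double tau_gp_hn(double v) { return 0.05 + 0.27 / (1.0 + sexp((v + 40.0) / 12.0)); }
double tau_gp_r(double)    { return 15.0; }
double tau_th_h(double v)  {
  return 1.0 / (0.128 * sexp(-(v + 46.0) / 18.0) + 4.0 / (1.0 + sexp(-(v + 23.0) / 5.0)));
}
double tau_th_r(double v)  { return 0.15 * (28.0 + sexp(-(v + 25.0) / 10.5)); }

void build_tables() {
  if (G.built) return;
  fill_sig(G.stn[0], 40.0, 8.0, 1.0, tau_stn_m);
  fill_sig(G.stn[1], 45.5, -6.4, 1.0, tau_stn_h);
  fill_sig(G.stn[2], 41.0, 14.0, 1.0, tau_stn_n);
  fill_sig(G.stn[3], 56.0, 6.7, 1.0, tau_stn_p);
  fill_sig(G.stn[4], 85.0, -5.8, 1.0, tau_stn_q);
  fill_sig(G.stn[5], -0.17, 0.08, 1.0, tau_stn_r);
  fill_sig(G.stn[6], 45.0, 14.7, 1.0, tau_stn_a);
  fill_sig(G.stn[7], 90.0, -7.5, 1.0, tau_stn_b);
  fill_sig(G.stn[8], 30.6, 5.0, 1.0, tau_stn_c);
  fill_sig(G.stn[9], 60.0, -7.5, 1.0, tau_stn_d1);
  fill_sig(G.stn[10], -0.1, -0.02, 1.0, tau_stn_d2);
  fill_sig(G.gp[0], 58.0, -12.0, 0.05, tau_gp_hn);
  fill_sig(G.gp[1], 50.0, 14.0, 0.1, tau_gp_hn);
  fill_sig(G.gp[2], 70.0, -2.0, 1.0, tau_gp_r);
  fill_inf(G.gp_minf, 37.0, 10.0);
  fill_inf(G.gp_ainf, 57.0, 2.0);
  fill_inf(G.gp_sinf, 35.0, 2.0);
  fill_sig(G.th[0], 41.0, -4.0, 1.0, tau_th_h);
  fill_sig(G.th[1], 84.0, -4.0, 1.0, tau_th_r);
  fill_inf(G.th_minf, 37.0, 7.0);
  fill_inf(G.th_pinf, 60.0, 6.2);
  for (int i = 0; i < NT; ++i) {
    double v = VMIN + i * DV;
    G.str[0].A[i] = 0.32 * rate(v + 54.0, 4.0);
    G.str[0].B[i] = 0.28 * rate(-(v + 27.0), 5.0);
    G.str[1].A[i] = 0.128 * sexp(-(v + 50.0) / 18.0);
    G.str[1].B[i] = 4.0 / (1.0 + sexp(-(v + 27.0) / 5.0));
    G.str[2].A[i] = 0.032 * rate(v + 52.0, 5.0);
    G.str[2].B[i] = 0.5 * sexp(-(v + 57.0) / 40.0);
    G.str[3].A[i] = 3.209e-4 * rate(v + 30.0, 9.0);
    G.str[3].B[i] = 3.209e-4 * rate(-(v + 30.0), 9.0);
  }
  G.built = true;
}

struct Conn {
  int pre, post, delay_steps, L, head;
  double g, E, tau;
  std::vector<int> wpre, wpost;   // 0-based wiring pairs
  std::vector<double> buf;        // n_post x L pending arrival counts
};

struct Net {
  int n;
  double dt, gm;
  std::vector<Conn> conn;
  double bias[NPOP][64];
  double noise_sd[NPOP];
  double izh_a[2], izh_d[2], izh_b, izh_reset, izh_peak;
  double v_thre, refractory;
};

// Flat-state offsets
struct Layout {
  int off_v[NPOP], off_u[2], off_g[NPOP], off_ca[2];
  std::vector<int> off_z, off_s;
  int M;
  void build(int n, int ncon) {
    int o = 0;
    for (int p = 0; p < NPOP; ++p) { off_v[p] = o; o += n; }
    off_u[0] = o; o += n; off_u[1] = o; o += n;
    for (int p = 0; p < NPOP; ++p) { off_g[p] = o; o += NGATE[p] * n; }
    off_ca[0] = o; o += n; off_ca[1] = o; o += n;
    off_z.resize(ncon); off_s.resize(ncon);
    for (int c = 0; c < ncon; ++c) {
      off_z[c] = o; o += n;
      off_s[c] = o; o += n;
    }
    M = o;
  }
};

void deriv(const Net &net, const Layout &L, const double *y, double *dy,
           const double (*noise)[64], double stim) {
  const int n = net.n;
  static thread_local std::vector<double> isyn;
  isyn.assign(NPOP * n, 0.0);

  // synaptic currents and filter dynamics
  for (size_t c = 0; c < net.conn.size(); ++c) {
    const Conn &cn = net.conn[c];
    const double *z = y + L.off_z[c];
    const double *s = y + L.off_s[c];
    const double *vp = y + L.off_v[cn.post];
    double *dz = dy + L.off_z[c];
    double *ds = dy + L.off_s[c];
    double *acc = &isyn[cn.post * n];
    for (int i = 0; i < n; ++i) {
      acc[i] += cn.g * (vp[i] - cn.E) * s[i];
      dz[i] = -z[i] / cn.tau;
      ds[i] = (z[i] - s[i]) / cn.tau;
    }
  }

  // cortex (Izhikevich)
  for (int p = 0; p < 2; ++p) {
    const double *v = y + L.off_v[p];
    const double *u = y + L.off_u[p];
    double *dv = dy + L.off_v[p];
    double *du = dy + L.off_u[p];
    const double a = net.izh_a[p], b = net.izh_b;
    for (int i = 0; i < n; ++i) {
      dv[i] = 0.04 * v[i] * v[i] + 5.0 * v[i] + 140.0 - u[i]
              - isyn[p * n + i] + net.bias[p][i] + noise[p][i];
      du[i] = a * (b * v[i] - u[i]);
    }
  }

  // striatum
  for (int p = P_DSTR; p <= P_IDSTR; ++p) {
    const double *v = y + L.off_v[p];
    const double *g = y + L.off_g[p];
    double *dv = dy + L.off_v[p];
    double *dg = dy + L.off_g[p];
    for (int i = 0; i < n; ++i) {
      double vi = v[i];
      double m = g[0 * n + i], h = g[1 * n + i], nn = g[2 * n + i],
             pp = g[3 * n + i];
      double ina = 100.0 * m * m * m * h * (vi - 50.0);
      double ik = 80.0 * nn * nn * nn * nn * (vi + 100.0);
      double il = 0.1 * (vi + 67.0);
      double im = net.gm * pp * (vi + 100.0);
      dv[i] = -il - ik - ina - im - isyn[p * n + i] + net.bias[p][i]
              + noise[p][i];
      for (int k = 0; k < 4; ++k) {
        double al, be;
        G.str[k].get(vi, al, be);
        dg[k * n + i] = al * (1.0 - g[k * n + i]) - be * g[k * n + i];
      }
    }
  }

  // STN
  {
    const int p = P_STN;
    const double *v = y + L.off_v[p];
    const double *g = y + L.off_g[p];
    double *dv = dy + L.off_v[p];
    double *dg = dy + L.off_g[p];
    for (int i = 0; i < n; ++i) {
      double vi = v[i];
      double gt[11];
      for (int k = 0; k < 11; ++k) {
        double inf, tf;
        G.stn[k].get(vi, inf, tf);
        gt[k] = g[k * n + i];
        dg[k * n + i] = (inf - gt[k]) / tf;
      }
      double m = gt[0], h = gt[1], nn = gt[2], pp = gt[3], q = gt[4],
             r = gt[5], a = gt[6], b = gt[7], c = gt[8], d1 = gt[9],
             d2 = gt[10];
      double ina = 49.0 * m * m * m * h * (vi - 60.0);
      double ik = 57.0 * nn * nn * nn * nn * (vi + 90.0);
      double il = 0.35 * (vi + 60.0);
      double it = 5.0 * pp * pp * q * (vi - 165.0);
      double icak = r * r * (vi + 90.0);
      double ia = 5.0 * a * a * b * (vi + 90.0);
      double iL = 15.0 * c * c * d1 * d2 * (vi - 165.0);
      dv[i] = -ina - ik - il - it - icak - ia - iL - isyn[p * n + i]
              + net.bias[p][i] + noise[p][i];
    }
  }

  // GPe / GPi
  for (int p = P_GPE; p <= P_GPI; ++p) {
    const double *v = y + L.off_v[p];
    const double *g = y + L.off_g[p];
    const double *ca = y + L.off_ca[p - P_GPE];
    double *dv = dy + L.off_v[p];
    double *dg = dy + L.off_g[p];
    double *dca = dy + L.off_ca[p - P_GPE];
    double st = (p == P_GPI) ? stim : 0.0;
    for (int i = 0; i < n; ++i) {
      double vi = v[i];
      double h = g[0 * n + i], nn = g[1 * n + i], r = g[2 * n + i];
      for (int k = 0; k < 3; ++k) {
        double inf, tf;
        G.gp[k].get(vi, inf, tf);
        dg[k * n + i] = (inf - g[k * n + i]) / tf;
      }
      double minf = G.gp_minf.getA(vi), ainf = G.gp_ainf.getA(vi),
             sinf = G.gp_sinf.getA(vi);
      double ina = 120.0 * minf * minf * minf * h * (vi - 55.0);
      double ik = 30.0 * nn * nn * nn * nn * (vi + 80.0);
      double il = 0.1 * (vi + 65.0);
      double it = 0.5 * ainf * ainf * ainf * r * vi;
      double ica = 0.15 * sinf * sinf * (vi - 120.0);
      double iahp = 10.0 * (vi + 80.0) * ca[i] / (ca[i] + 10.0);
      dv[i] = -ina - ik - il - it - ica - iahp - isyn[p * n + i]
              + net.bias[p][i] + noise[p][i] + st;
      dca[i] = 1e-4 * (-ica - it - 15.0 * ca[i]);
    }
  }

  // TH
  {
    const int p = P_TH;
    const double *v = y + L.off_v[p];
    const double *g = y + L.off_g[p];
    double *dv = dy + L.off_v[p];
    double *dg = dy + L.off_g[p];
    for (int i = 0; i < n; ++i) {
      double vi = v[i];
      double h = g[0 * n + i], r = g[1 * n + i];
      for (int k = 0; k < 2; ++k) {
        double inf, tf;
        G.th[k].get(vi, inf, tf);
        dg[k * n + i] = (inf - g[k * n + i]) / tf;
      }
      double minf = G.th_minf.getA(vi), pinf = G.th_pinf.getA(vi);
      double ina = 3.0 * minf * minf * minf * h * (vi - 50.0);
      double kh = 0.75 * (1.0 - h);
      double ik = 5.0 * kh * kh * kh * kh * (vi + 75.0);
      double il = 0.05 * (vi + 70.0);
      double it = 5.0 * pinf * pinf * r * vi;
      dv[i] = -ina - ik - il - it - isyn[p * n + i] + net.bias[p][i]
              + noise[p][i];
    }
  }
}

} // namespace

// [[Rcpp::export(name = ".cbgt_sim_cpp")]]
List cbgt_sim_cpp(List state, List net_in, int n_steps, double dt,
                  NumericVector i_sti, int record_stride, int noise_seed) {
  build_tables();
  Net net;
  net.n = as<int>(net_in["n"]);
  const int n = net.n;
  if (n > 64) stop("population size above 64 is not supported");
  net.dt = dt;
  net.gm = as<double>(net_in["gm"]);
  List bias = net_in["bias"];
  for (int p = 0; p < NPOP; ++p) {
    NumericVector b = bias[p];
    for (int i = 0; i < n; ++i) net.bias[p][i] = b[i];
  }
  NumericVector nsd = net_in["noise_sd"];
  for (int p = 0; p < NPOP; ++p) net.noise_sd[p] = nsd[p];
  List izh = net_in["izh"];
  NumericVector ia = izh["a"], id = izh["d"];
  net.izh_a[0] = ia[0]; net.izh_a[1] = ia[1];
  net.izh_d[0] = id[0]; net.izh_d[1] = id[1];
  net.izh_b = as<double>(izh["b"]);
  net.izh_reset = as<double>(izh["reset"]);
  net.izh_peak = as<double>(izh["peak"]);
  net.v_thre = as<double>(net_in["v_thre"]);
  net.refractory = as<double>(net_in["refractory"]);

  List conn_in = net_in["conn"];
  List syn_state = state["syn"];
  const int ncon = conn_in.size();
  net.conn.resize(ncon);
  for (int c = 0; c < ncon; ++c) {
    List ci = conn_in[c];
    Conn &cn = net.conn[c];
    cn.pre = as<int>(ci["pre"]);
    cn.post = as<int>(ci["post"]);
    cn.g = as<double>(ci["g"]);
    cn.E = as<double>(ci["E"]);
    cn.tau = as<double>(ci["tau"]);
    cn.delay_steps = as<int>(ci["delay_steps"]);
    if (cn.delay_steps < 1) cn.delay_steps = 1;
    IntegerVector wp = ci["wpre"], wq = ci["wpost"];
    cn.wpre.assign(wp.begin(), wp.end());
    cn.wpost.assign(wq.begin(), wq.end());
    cn.L = cn.delay_steps + 1;
    List ss = syn_state[c];
    NumericVector buf = ss["buf"];
    cn.head = as<int>(ss["head"]);
    cn.buf.assign(n * cn.L, 0.0);
    if (buf.size() == (R_xlen_t)(n * cn.L))
      std::copy(buf.begin(), buf.end(), cn.buf.begin());
    else if (buf.size() != 0)
      stop("synapse buffer size does not match delay (dt changed mid-run?)");
  }

  Layout L;
  L.build(n, ncon);
  std::vector<double> y(L.M, 0.0), k1(L.M), k2(L.M), k3(L.M), k4(L.M),
      ytmp(L.M);

  // unpack state
  List v_in = state["v"], u_in = state["u"], g_in = state["gates"],
       ca_in = state["ca"], ls_in = state["last_spike"];
  for (int p = 0; p < NPOP; ++p) {
    NumericVector v = v_in[p];
    for (int i = 0; i < n; ++i) y[L.off_v[p] + i] = v[i];
    if (NGATE[p] > 0) {
      NumericMatrix gm = g_in[p]; // NGATE x n
      for (int k = 0; k < NGATE[p]; ++k)
        for (int i = 0; i < n; ++i)
          y[L.off_g[p] + k * n + i] = gm(k, i);
    }
  }
  for (int p = 0; p < 2; ++p) {
    NumericVector u = u_in[p];
    for (int i = 0; i < n; ++i) y[L.off_u[p] + i] = u[i];
  }
  for (int p = 0; p < 2; ++p) {
    NumericVector ca = ca_in[p];
    for (int i = 0; i < n; ++i) y[L.off_ca[p] + i] = ca[i];
  }
  for (int c = 0; c < ncon; ++c) {
    List ss = syn_state[c];
    NumericVector z = ss["z"], s = ss["s"];
    for (int i = 0; i < n; ++i) {
      y[L.off_z[c] + i] = z[i];
      y[L.off_s[c] + i] = s[i];
    }
  }
  std::vector<double> last_spike(NPOP * n);
  for (int p = 0; p < NPOP; ++p) {
    NumericVector ls = ls_in[p];
    for (int i = 0; i < n; ++i) last_spike[p * n + i] = ls[i];
  }
  double step0 = as<double>(state["step0"]);

  const bool has_sti = i_sti.size() > 0;
  if (has_sti && i_sti.size() < n_steps)
    stop("stimulus vector shorter than the number of steps");

  const uint64_t seed64 = sm64((uint64_t)(uint32_t)noise_seed);
  double noise[NPOP][64];
  std::memset(noise, 0, sizeof(noise));
  const double inv_sqrt_dt = 1.0 / std::sqrt(dt);

  // recording
  int n_rec = 0;
  if (record_stride > 0)
    for (int k = 1; k <= n_steps; ++k)
      if ((long long)(step0 + k) % record_stride == 0) ++n_rec;
  std::vector<NumericMatrix> vrec;
  NumericVector trec(n_rec);
  for (int p = 0; p < NPOP; ++p) vrec.push_back(NumericMatrix(n, n_rec));
  std::vector<std::vector<std::vector<double>>> spikes(
      NPOP, std::vector<std::vector<double>>(n));

  std::vector<double> vprev(NPOP * n);
  int irec = 0;
  const double h = dt;

  for (int k = 0; k < n_steps; ++k) {
    // deliver delayed spike arrivals, advance ring buffers
    for (int c = 0; c < ncon; ++c) {
      Conn &cn = net.conn[c];
      for (int i = 0; i < n; ++i) {
        double a = cn.buf[i * cn.L + cn.head];
        if (a != 0.0) {
          y[L.off_z[c] + i] += a;
          cn.buf[i * cn.L + cn.head] = 0.0;
        }
      }
      cn.head = (cn.head + 1) % cn.L;
    }
    // noise currents, frozen for the step
    {
      uint64_t base = sm64(seed64 ^ sm64((uint64_t)(step0 + k)));
      int j = 0;
      for (int p = 0; p < NPOP; ++p)
        if (net.noise_sd[p] > 0.0)
          for (int i = 0; i < n; ++i)
            noise[p][i] = net.noise_sd[p] * norm_draw(base, j++) * inv_sqrt_dt;
    }
    double stim = has_sti ? i_sti[k] : 0.0;

    for (int p = 0; p < NPOP; ++p)
      for (int i = 0; i < n; ++i)
        vprev[p * n + i] = y[L.off_v[p] + i];

    deriv(net, L, y.data(), k1.data(), noise, stim);
    for (int j = 0; j < L.M; ++j) ytmp[j] = y[j] + 0.5 * h * k1[j];
    deriv(net, L, ytmp.data(), k2.data(), noise, stim);
    for (int j = 0; j < L.M; ++j) ytmp[j] = y[j] + 0.5 * h * k2[j];
    deriv(net, L, ytmp.data(), k3.data(), noise, stim);
    for (int j = 0; j < L.M; ++j) ytmp[j] = y[j] + h * k3[j];
    deriv(net, L, ytmp.data(), k4.data(), noise, stim);
    for (int j = 0; j < L.M; ++j)
      y[j] += h / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);

    // keep gates in [0,1], calcium nonnegative
    for (int p = 0; p < NPOP; ++p)
      for (int j = 0; j < NGATE[p] * n; ++j) {
        double &g = y[L.off_g[p] + j];
        if (g < 0.0) g = 0.0;
        else if (g > 1.0) g = 1.0;
      }
    for (int p = 0; p < 2; ++p)
      for (int i = 0; i < n; ++i)
        if (y[L.off_ca[p] + i] < 0.0) y[L.off_ca[p] + i] = 0.0;

    const double t_now = (step0 + k + 1) * dt;
    bool spiked[NPOP][64];
    std::memset(spiked, 0, sizeof(spiked));

    // Izhikevich peak-reset rule
    for (int p = 0; p < 2; ++p)
      for (int i = 0; i < n; ++i) {
        double &v = y[L.off_v[p] + i];
        if (v > net.izh_peak) {
          v = net.izh_reset;
          y[L.off_u[p] + i] += net.izh_d[p];
          spiked[p][i] = true;
          spikes[p][i].push_back(t_now);
          last_spike[p * n + i] = t_now;
        }
      }
    // HH threshold crossing with refractory lockout
    for (int p = 2; p < NPOP; ++p)
      for (int i = 0; i < n; ++i) {
        double v = y[L.off_v[p] + i];
        if (v >= net.v_thre && vprev[p * n + i] < net.v_thre &&
            t_now - last_spike[p * n + i] >= net.refractory) {
          spiked[p][i] = true;
          spikes[p][i].push_back(t_now);
          last_spike[p * n + i] = t_now;
        }
        if (!std::isfinite(v))
          stop("integration diverged at t = %f ms (population %d, neuron %d)",
               t_now, p + 1, i + 1);
      }
    // queue delayed arrivals
    for (int c = 0; c < ncon; ++c) {
      Conn &cn = net.conn[c];
      const bool *sp = spiked[cn.pre];
      int slot = (cn.head + cn.delay_steps - 1) % cn.L;
      for (size_t w = 0; w < cn.wpre.size(); ++w)
        if (sp[cn.wpre[w]])
          cn.buf[cn.wpost[w] * cn.L + slot] += 1.0;
    }
    // record
    if (record_stride > 0 && (long long)(step0 + k + 1) % record_stride == 0) {
      trec[irec] = t_now;
      for (int p = 0; p < NPOP; ++p)
        for (int i = 0; i < n; ++i)
          vrec[p](i, irec) = y[L.off_v[p] + i];
      ++irec;
    }
  }

  // repack state
  List v_out(NPOP), g_out(NPOP), u_out(2), ca_out(2), ls_out(NPOP),
      syn_out(ncon);
  for (int p = 0; p < NPOP; ++p) {
    NumericVector v(n);
    for (int i = 0; i < n; ++i) v[i] = y[L.off_v[p] + i];
    v_out[p] = v;
    NumericMatrix gm(NGATE[p], n);
    for (int k2_ = 0; k2_ < NGATE[p]; ++k2_)
      for (int i = 0; i < n; ++i) gm(k2_, i) = y[L.off_g[p] + k2_ * n + i];
    g_out[p] = gm;
    NumericVector ls(n);
    for (int i = 0; i < n; ++i) ls[i] = last_spike[p * n + i];
    ls_out[p] = ls;
  }
  for (int p = 0; p < 2; ++p) {
    NumericVector u(n), ca(n);
    for (int i = 0; i < n; ++i) {
      u[i] = y[L.off_u[p] + i];
      ca[i] = y[L.off_ca[p] + i];
    }
    u_out[p] = u;
    ca_out[p] = ca;
  }
  for (int c = 0; c < ncon; ++c) {
    Conn &cn = net.conn[c];
    NumericVector z(n), s(n), buf(cn.buf.size());
    for (int i = 0; i < n; ++i) {
      z[i] = y[L.off_z[c] + i];
      s[i] = y[L.off_s[c] + i];
    }
    std::copy(cn.buf.begin(), cn.buf.end(), buf.begin());
    syn_out[c] = List::create(_["z"] = z, _["s"] = s, _["buf"] = buf,
                              _["head"] = cn.head);
  }
  List state_out = List::create(
      _["v"] = v_out, _["u"] = u_out, _["gates"] = g_out, _["ca"] = ca_out,
      _["syn"] = syn_out, _["last_spike"] = ls_out,
      _["step0"] = step0 + n_steps);

  List spk(NPOP);
  for (int p = 0; p < NPOP; ++p) {
    List sp(n);
    for (int i = 0; i < n; ++i)
      sp[i] = NumericVector(spikes[p][i].begin(), spikes[p][i].end());
    spk[p] = sp;
  }
  List vout(NPOP);
  for (int p = 0; p < NPOP; ++p) vout[p] = vrec[p];
  return List::create(_["state"] = state_out, _["t"] = trec, _["v"] = vout,
                      _["spikes"] = spk);
}
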