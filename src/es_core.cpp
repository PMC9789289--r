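// Forward-Euler integration of the two-point-neuron adaptive exponential
// integrate-and-fire model for electric stimulation of an auditory nerve
// fiber.  Internal units: time us, potential mV, current uA, conductance mS,
// capacitance nF (so dV = dt * I / C holds without scale factors).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct EsParams {
  double C_per, C_cen, gL_per, gL_cen, dT_per, dT_cen;
  double EL, vthr, vpeak, vreset;
  double tau_sub, a_sub, tau_supra_per, tau_supra_cen, a_supra, b;
  double t_dead;  // us
};

struct EsState {
  double Vp, Vc, Isub_p, Isub_c, Isup_p, Isup_c;
  double refr_until;  // us; external drive zeroed while t < refr_until
};

static inline double hfun(double V, double gL, double dT, double EL,
                          double vthr) {
  double ex = (V - vthr) / dT;
  if (ex > 60.0) ex = 60.0;  // clamp: value is hugely suprathreshold anyway
  return -gL * (V - EL) + gL * dT * std::exp(ex);
}

// one Euler step over samples [0, n); spike sample indices (1-based) and
// the neuron that crossed first (1 = peripheral, 2 = central, 3 = both)
// are appended to `spikes` / `who`.  t_offset shifts the refractory clock
// so that a state carried across calls stays consistent.
static void integrate_span(const double* drive_per, const double* drive_cen,
                           const double* noise_per, const double* noise_cen,
                           int n, double dt, const EsParams& P, EsState& S,
                           std::vector<int>& spikes, std::vector<int>& who) {
  for (int i = 0; i < n; ++i) {
    double t = i * dt;
    bool refr = t < S.refr_until;
    double sp = refr ? 0.0 : drive_per[i];
    double sc = refr ? 0.0 : drive_cen[i];

    double dVp = dt / P.C_per *
      (hfun(S.Vp, P.gL_per, P.dT_per, P.EL, P.vthr) - S.Isub_p - S.Isup_p +
       noise_per[i] + sp);
    double dVc = dt / P.C_cen *
      (hfun(S.Vc, P.gL_cen, P.dT_cen, P.EL, P.vthr) - S.Isub_c - S.Isup_c +
       noise_cen[i] + sc);
    double dIsub_p = dt / P.tau_sub * (P.a_sub * (S.Vp - P.EL) - S.Isub_p);
    double dIsub_c = dt / P.tau_sub * (P.a_sub * (S.Vc - P.EL) - S.Isub_c);
    double dIsup_p =
      dt / P.tau_supra_per * (P.a_supra * (S.Vp - P.EL) - S.Isup_p);
    double dIsup_c =
      dt / P.tau_supra_cen * (P.a_supra * (S.Vc - P.EL) - S.Isup_c);

    S.Vp += dVp;  S.Vc += dVc;
    S.Isub_p += dIsub_p;  S.Isub_c += dIsub_c;
    S.Isup_p += dIsup_p;  S.Isup_c += dIsup_c;

    if (S.Vp >= P.vpeak || S.Vc >= P.vpeak) {
      int w = (S.Vp >= P.vpeak ? 1 : 0) + (S.Vc >= P.vpeak ? 2 : 0);
      spikes.push_back(i + 1);
      who.push_back(w);
      S.Vp = P.vreset;  S.Vc = P.vreset;
      S.Isup_p += P.b;  S.Isup_c += P.b;
      S.refr_until = (i + 1) * dt + P.t_dead;
    }
  }
  // keep the refractory clock relative to the *end* of this span so that a
  // subsequent span (t restarting at 0) sees the remaining dead time
  S.refr_until -= n * dt;
  if (S.refr_until < 0) S.refr_until = 0;
}

static EsParams make_params(List par) {
  EsParams P;
  P.C_per = par["C_per"];  P.C_cen = par["C_cen"];
  P.gL_per = par["gL_per"];  P.gL_cen = par["gL_cen"];
  P.dT_per = par["dT_per"];  P.dT_cen = par["dT_cen"];
  P.EL = par["EL"];  P.vthr = par["vthr"];
  P.vpeak = par["vpeak"];  P.vreset = par["vreset"];
  P.tau_sub = par["tau_sub"];  P.a_sub = par["a_sub"];
  P.tau_supra_per = par["tau_supra_per"];
  P.tau_supra_cen = par["tau_supra_cen"];
  P.a_supra = par["a_supra"];  P.b = par["b"];
  P.t_dead = par["t_dead"];
  return P;
}

static EsState make_state(NumericVector s0) {
  EsState S;
  S.Vp = s0[0];  S.Vc = s0[1];
  S.Isub_p = s0[2];  S.Isub_c = s0[3];
  S.Isup_p = s0[4];  S.Isup_c = s0[5];
  S.refr_until = s0.size() > 6 ? s0[6] : 0.0;
  return S;
}

static NumericVector state_vec(const EsState& S) {
  return NumericVector::create(S.Vp, S.Vc, S.Isub_p, S.Isub_c, S.Isup_p,
                               S.Isup_c, S.refr_until);
}

// [[Rcpp::export]]
List es_integrate_cpp(NumericVector drive_per, NumericVector drive_cen,
                      NumericVector noise_per, NumericVector noise_cen,
                      double dt_us, List par, NumericVector state0) {
  int n = drive_per.size();
  if (drive_cen.size() != n || noise_per.size() != n || noise_cen.size() != n)
    stop("all drive/noise traces must share one time grid");
  EsParams P = make_params(par);
  EsState S = make_state(state0);
  std::vector<int> spikes, who;
  integrate_span(&drive_per[0], &drive_cen[0], &noise_per[0], &noise_cen[0],
                 n, dt_us, P, S, spikes, who);
  return List::create(_["spike_idx"] = wrap(spikes), _["neuron"] = wrap(who),
                      _["state"] = state_vec(S));
}

// Batch of independent trials sharing the deterministic drives; noise (and
// optionally an extra peripheral drive, e.g. synaptic release currents)
// differs per trial (one column per trial).  state0 has one column per
// trial, or a single column shared by all trials.
// [[Rcpp::export]]
List es_integrate_batch_cpp(NumericVector drive_per, NumericVector drive_cen,
                            NumericMatrix noise_per, NumericMatrix noise_cen,
                            double dt_us, List par, NumericMatrix state0,
                            Nullable<NumericMatrix> extra_per = R_NilValue) {
  int n = drive_per.size();
  int ntrial = noise_per.ncol();
  if (noise_per.nrow() != n || noise_cen.nrow() != n ||
      noise_cen.ncol() != ntrial)
    stop("noise matrices must be n_samples x n_trials");
  if (state0.ncol() != 1 && state0.ncol() != ntrial)
    stop("state0 must have 1 or n_trials columns");
  EsParams P = make_params(par);
  bool has_extra = extra_per.isNotNull();
  NumericMatrix X;
  if (has_extra) {
    X = NumericMatrix(extra_per);
    if (X.nrow() != n || X.ncol() != ntrial)
      stop("extra_per must be n_samples x n_trials");
  }
  std::vector<double> dp(n);
  List out_sp(ntrial), out_who(ntrial);
  for (int k = 0; k < ntrial; ++k) {
    NumericVector s0 = state0(_, state0.ncol() == 1 ? 0 : k);
    EsState S = make_state(s0);
    std::vector<int> spikes, who;
    const double* dper = &drive_per[0];
    if (has_extra) {
      for (int i = 0; i < n; ++i) dp[i] = drive_per[i] + X(i, k);
      dper = dp.data();
    }
    integrate_span(dper, &drive_cen[0], &noise_per[0] + (size_t)k * n,
                   &noise_cen[0] + (size_t)k * n, n, dt_us, P, S, spikes, who);
    out_sp[k] = wrap(spikes);
    out_who[k] = wrap(who);
  }
  return List::create(_["spike_idx"] = out_sp, _["neuron"] = out_who);
}

// Long single-trial integration that snapshots the state vector at the
// requested (1-based, post-update) sample indices; used to build a
// stationary ensemble of initial states for trial batches.
// [[Rcpp::export]]
List es_collect_states_cpp(NumericVector drive_per, NumericVector drive_cen,
                           NumericVector noise_per, NumericVector noise_cen,
                           double dt_us, List par, NumericVector state0,
                           IntegerVector at_idx) {
  int n = drive_per.size();
  EsParams P = make_params(par);
  EsState S = make_state(state0);
  int nout = at_idx.size();
  NumericMatrix states(7, nout);
  std::vector<int> spikes, who;
  int j = 0;
  // integrate step by step (same scheme as integrate_span), snapshotting
  for (int i = 0; i < n; ++i) {
    double t = i * dt_us;
    bool refr = t < S.refr_until;
    double sp = refr ? 0.0 : drive_per[i];
    double sc = refr ? 0.0 : drive_cen[i];
    double dVp = dt_us / P.C_per *
      (hfun(S.Vp, P.gL_per, P.dT_per, P.EL, P.vthr) - S.Isub_p - S.Isup_p +
       noise_per[i] + sp);
    double dVc = dt_us / P.C_cen *
      (hfun(S.Vc, P.gL_cen, P.dT_cen, P.EL, P.vthr) - S.Isub_c - S.Isup_c +
       noise_cen[i] + sc);
    double dIsub_p = dt_us / P.tau_sub * (P.a_sub * (S.Vp - P.EL) - S.Isub_p);
    double dIsub_c = dt_us / P.tau_sub * (P.a_sub * (S.Vc - P.EL) - S.Isub_c);
    double dIsup_p =
      dt_us / P.tau_supra_per * (P.a_supra * (S.Vp - P.EL) - S.Isup_p);
    double dIsup_c =
      dt_us / P.tau_supra_cen * (P.a_supra * (S.Vc - P.EL) - S.Isup_c);
    S.Vp += dVp;  S.Vc += dVc;
    S.Isub_p += dIsub_p;  S.Isub_c += dIsub_c;
    S.Isup_p += dIsup_p;  S.Isup_c += dIsup_c;
    if (S.Vp >= P.vpeak || S.Vc >= P.vpeak) {
      int w = (S.Vp >= P.vpeak ? 1 : 0) + (S.Vc >= P.vpeak ? 2 : 0);
      spikes.push_back(i + 1);
      who.push_back(w);
      S.Vp = P.vreset;  S.Vc = P.vreset;
      S.Isup_p += P.b;  S.Isup_c += P.b;
      S.refr_until = (i + 1) * dt_us + P.t_dead;
    }
    while (j < nout && at_idx[j] == i + 1) {
      states(0, j) = S.Vp;  states(1, j) = S.Vc;
      states(2, j) = S.Isub_p;  states(3, j) = S.Isub_c;
      states(4, j) = S.Isup_p;  states(5, j) = S.Isup_c;
      double rem = S.refr_until - (i + 1) * dt_us;
      states(6, j) = rem > 0 ? rem : 0.0;
      ++j;
    }
  }
  return List::create(_["states"] = states, _["spike_idx"] = wrap(spikes),
                      _["neuron"] = wrap(who));
}

// Random spectra for 1/f^alpha noise synthesis: each column packs two
// independent Hermitian-symmetric spectra into real and imaginary parts,
// so Re() and Im() of the inverse FFT are two independent real noise
// traces with the prescribed magnitude profile.  mag has length m with
// mag[0] = 0 (DC removed).  Uses R's RNG.
// Box-Muller pairs from R's uniform stream (much cheaper than the
// inversion-based normal sampler for bulk synthesis).
static inline void bm_pair(double& g1, double& g2) {
  double u1 = R::unif_rand(), u2 = R::unif_rand();
  while (u1 <= 1e-300) u1 = R::unif_rand();
  double r = std::sqrt(-2.0 * std::log(u1));
  g1 = r * std::cos(2.0 * M_PI * u2);
  g2 = r * std::sin(2.0 * M_PI * u2);
}

// [[Rcpp::export]]
ComplexMatrix noise_spectra_cpp(int m, int ncol, NumericVector mag) {
  ComplexMatrix z(m, ncol);
  int K = (m - 1) / 2;
  double a1, b1, a2, b2;
  for (int c = 0; c < ncol; ++c) {
    z(0, c).r = 0.0;  z(0, c).i = 0.0;
    for (int k = 1; k <= K; ++k) {
      bm_pair(a1, b1);
      bm_pair(a2, b2);
      z(k, c).r = mag[k] * (a1 - b2);
      z(k, c).i = mag[k] * (b1 + a2);
      z(m - k, c).r = mag[k] * (a1 + b2);
      z(m - k, c).i = mag[k] * (a2 - b1);
    }
    if (m % 2 == 0) {  // Nyquist bin: both Hermitian parts are real there
      int h = m / 2;
      bm_pair(a1, a2);
      z(h, c).r = mag[h] * a1;
      z(h, c).i = mag[h] * a2;
    }
  }
  return z;
}

// Split the inverse FFT of packed Hermitian spectra into the two real
// traces (first n rows), centering each column and scaling it to unit
// sample variance.
// [[Rcpp::export]]
List split_unit_cpp(ComplexMatrix x, int n) {
  int ncol = x.ncol();
  NumericMatrix A(n, ncol), B(n, ncol);
  for (int c = 0; c < ncol; ++c) {
    double ma = 0, mb = 0;
    for (int i = 0; i < n; ++i) {
      A(i, c) = x(i, c).r;  B(i, c) = x(i, c).i;
      ma += A(i, c);  mb += B(i, c);
    }
    ma /= n;  mb /= n;
    double sa = 0, sb = 0;
    for (int i = 0; i < n; ++i) {
      A(i, c) -= ma;  B(i, c) -= mb;
      sa += A(i, c) * A(i, c);  sb += B(i, c) * B(i, c);
    }
    sa = std::sqrt(sa / (n - 1));  sb = std::sqrt(sb / (n - 1));
    for (int i = 0; i < n; ++i) { A(i, c) /= sa;  B(i, c) /= sb; }
  }
  return List::create(_["A"] = A, _["B"] = B);
}

// Alternative coupling variant: the acoustic pathway keeps its own
// release-driven spike generator, and the two models exchange spike
// occurrences at runtime -- every spike (either source) resets the membrane
// model AND restarts the acoustic refractory clock (absolute period t_abs
// followed by an exponentially distributed relative period, mean t_rel).
// release_idx: 1-based sample indices of neurotransmitter release events.
// Returns the merged spike train; a release and a membrane crossing in the
// same integration step are collapsed into a single spike.
// [[Rcpp::export]]
List eas_alt_integrate_cpp(NumericVector drive_per, NumericVector drive_cen,
                           NumericMatrix noise_per, NumericMatrix noise_cen,
                           IntegerVector release_idx, List release_trial,
                           double dt_us, double t_abs_us, double t_rel_us,
                           List par, NumericMatrix state0) {
  int n = drive_per.size();
  int ntrial = noise_per.ncol();
  if (state0.ncol() != 1 && state0.ncol() != ntrial)
    stop("state0 must have 1 or n_trials columns");
  EsParams P = make_params(par);
  List out_sp(ntrial), out_src(ntrial);
  for (int k = 0; k < ntrial; ++k) {
    NumericVector s0 = state0(_, state0.ncol() == 1 ? 0 : k);
    EsState S = make_state(s0);
    IntegerVector rel = release_trial.size() > 0
      ? as<IntegerVector>(release_trial[k]) : release_idx;
    int nrel = rel.size(), ri = 0;
    double as_refr_until = 0.0;
    const double* np_ = &noise_per[0] + (size_t)k * n;
    const double* nc_ = &noise_cen[0] + (size_t)k * n;
    std::vector<int> spikes, src;  // src: 1 = membrane (ES), 2 = acoustic
    for (int i = 0; i < n; ++i) {
      double t = i * dt_us;
      bool as_spike = false;
      // acoustic spike generator: a release fires unless refractory
      while (ri < nrel && rel[ri] - 1 == i) {
        if (t >= as_refr_until) as_spike = true;
        ++ri;
      }
      bool refr = t < S.refr_until;
      double sp = refr ? 0.0 : drive_per[i];
      double sc = refr ? 0.0 : drive_cen[i];
      double dVp = dt_us / P.C_per *
        (hfun(S.Vp, P.gL_per, P.dT_per, P.EL, P.vthr) - S.Isub_p - S.Isup_p +
         np_[i] + sp);
      double dVc = dt_us / P.C_cen *
        (hfun(S.Vc, P.gL_cen, P.dT_cen, P.EL, P.vthr) - S.Isub_c - S.Isup_c +
         nc_[i] + sc);
      double dIsub_p = dt_us / P.tau_sub * (P.a_sub * (S.Vp - P.EL) - S.Isub_p);
      double dIsub_c = dt_us / P.tau_sub * (P.a_sub * (S.Vc - P.EL) - S.Isub_c);
      double dIsup_p =
        dt_us / P.tau_supra_per * (P.a_supra * (S.Vp - P.EL) - S.Isup_p);
      double dIsup_c =
        dt_us / P.tau_supra_cen * (P.a_supra * (S.Vc - P.EL) - S.Isup_c);
      S.Vp += dVp;  S.Vc += dVc;
      S.Isub_p += dIsub_p;  S.Isub_c += dIsub_c;
      S.Isup_p += dIsup_p;  S.Isup_c += dIsup_c;
      bool es_spike = (S.Vp >= P.vpeak || S.Vc >= P.vpeak);
      if (es_spike || as_spike) {
        spikes.push_back(i + 1);
        src.push_back(es_spike && as_spike ? 3 : (es_spike ? 1 : 2));
        // reset membrane model
        S.Vp = P.vreset;  S.Vc = P.vreset;
        S.Isup_p += P.b;  S.Isup_c += P.b;
        S.refr_until = (i + 1) * dt_us + P.t_dead;
        // restart acoustic refractory clock (uses R's RNG)
        as_refr_until = (i + 1) * dt_us + t_abs_us + R::rexp(t_rel_us);
      }
    }
    out_sp[k] = wrap(spikes);
    out_src[k] = wrap(src);
  }
  return List::create(_["spike_idx"] = out_sp, _["source"] = out_src);
}
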