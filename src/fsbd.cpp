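// Production integrator for the coupled membrane Langevin / bond Monte Carlo
// dynamics.  The R level owns all conventions (grid layout, transform
// normalisation, parameter validation); this file only advances the state.
//
// Transform convention (must match R/grid.R):
//   h_q = (L/N)^2 * DFT(h)          (continuum transform of the height field)
//   h   = Re(unnormalised IDFT(h_q)) / L^2
//
// The 2-D DFT is evaluated as W X W (W the dense DFT matrix) via BLAS zgemm
// for small grids, which beats the generic FFT well past the N = 24 grids
// the scaled experiments use; large grids fall back to arma::fft2.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

namespace {

// xoshiro256++ with splitmix64 seeding; Marsaglia polar normals.
// A self-contained stream keeps trajectories reproducible from the R seed
// independently of the C++ standard library's distribution internals.
struct Rng {
  uint64_t s[4];
  bool has_spare = false;
  double spare = 0.0;

  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // uniform on [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }
  inline double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f;
    has_spare = true;
    return u * f;
  }
};

struct DftPlan {
  int N;
  bool use_mm;
  arma::cx_mat W, Wc;  // forward DFT matrix and its conjugate

  explicit DftPlan(int N_) : N(N_), use_mm(N_ <= 48) {
    if (use_mm) {
      W.set_size(N, N);
      for (int j = 0; j < N; ++j)
        for (int k = 0; k < N; ++k)
          W(j, k) = std::polar(1.0, -2.0 * arma::datum::pi * double(j) * k / N);
      Wc = arma::conj(W);
    }
  }
  // unnormalised forward DFT
  inline arma::cx_mat fwd(const arma::cx_mat& x) const {
    return use_mm ? arma::cx_mat(W * x * W) : arma::cx_mat(arma::fft2(x));
  }
  // real part of the unnormalised inverse DFT
  inline arma::mat inv_real(const arma::cx_mat& x) const {
    if (use_mm) return arma::real(Wc * x * Wc);
    return arma::real(arma::ifft2(x)) * double(N) * N;
  }
};

}  // namespace

// [[Rcpp::export]]
Rcpp::List fsbd_run_cpp(const arma::cx_mat& hq0,
                        const arma::imat& bonds0,
                        const arma::imat& site_ix,  // 0-based grid x-index per site
                        const arma::imat& site_iy,  // 0-based grid y-index per site
                        double L, double dt, int n_steps,
                        double B, double eta, double kBT,
                        double sigma_w, double eps_w, double h_sub,
                        double k, double h_L, double R_RL,
                        double kon0, double koff0, double x_b, double p,
                        bool en_bend, bool en_wall, bool en_link, bool en_press,
                        bool en_noise, bool en_kinetics,
                        int sample_stride, int spectrum_stride,
                        double seed1, double seed2) {
  const int N = hq0.n_rows;
  const double dx = L / N;
  const double dx2 = dx * dx;
  const double qunit = 2.0 * arma::datum::pi / L;
  const DftPlan plan(N);

  arma::vec a(N);
  for (int i = 0; i < N; ++i) a(i) = (i < N / 2) ? i : i - N;
  arma::mat q4(N, N), qmag(N, N);
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < N; ++i) {
      double qx = qunit * a(i), qy = qunit * a(j);
      double m2 = qx * qx + qy * qy;
      q4(i, j) = m2 * m2;
      qmag(i, j) = std::sqrt(m2);
    }

  // Oseen-level mobility 1/(4 eta q); zero mode regularised at the box scale
  arma::mat lambda(N, N);
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < N; ++i) {
      double q = (i == 0 && j == 0) ? qunit : qmag(i, j);
      lambda(i, j) = 1.0 / (4.0 * eta * q);
    }
  // per-mode noise amplitude: Var(xi_q) = 2 kBT L^2 Lambda_q dt over the
  // mode's real + imaginary parts; no thermal kick on the centre of mass
  arma::mat namp = arma::sqrt(2.0 * kBT * L * L * lambda * dt);
  namp(0, 0) = 0.0;

  // Hermitian pairing of the mode set (column-major linear indices):
  // self-conjugate modes get one real draw, each (q, -q) pair two.
  std::vector<int> self_idx;
  std::vector<std::pair<int, int>> pair_idx;
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < N; ++i) {
      int idx = i + N * j;
      int pidx = ((N - i) % N) + N * ((N - j) % N);
      if (pidx == idx) {
        if (idx != 0) self_idx.push_back(idx);
      } else if (idx < pidx) {
        pair_idx.emplace_back(idx, pidx);
      }
    }

  uint64_t seed = (static_cast<uint64_t>(seed1) << 31) ^ static_cast<uint64_t>(seed2);
  Rng rng(seed ^ 0x5bd1e995u);

  arma::cx_mat hq = hq0;
  arma::imat bonds = bonds0;
  const int Nb = bonds.n_rows;
  const bool have_sites = Nb > 0;

  arma::mat h = plan.inv_real(hq) / (L * L);
  arma::cx_mat F(N, N), preal(N, N);
  const double inv_sqrt2 = 1.0 / std::sqrt(2.0);

  const int n_samp = (sample_stride > 0) ? n_steps / sample_stride : 0;
  arma::vec s_time(n_samp), s_mean(n_samp), s_rms(n_samp), s_phi(n_samp),
      s_ebend(n_samp), s_elink(n_samp);
  arma::ivec s_closed(n_samp);
  const int n_spec = (spectrum_stride > 0) ? n_steps / spectrum_stride : 0;
  arma::cube spec(spectrum_stride > 0 ? N : 0, spectrum_stride > 0 ? N : 0,
                  n_spec);

  std::string error = "";
  int error_step = -1;
  long n_bind = 0, n_unbind = 0, n_clamp = 0;
  int isamp = 0, ispec = 0;

  for (int step = 1; step <= n_steps; ++step) {
    // deterministic force on the current (hq, h) state
    F.zeros();
    if (en_bend)
      for (int j = 0; j < N; ++j)
        for (int i = 0; i < N; ++i) F(i, j) = -B * q4(i, j) * hq(i, j);

    bool need_real = false;
    if (en_wall || (en_link && have_sites)) preal.zeros();
    if (en_wall) {
      for (int j = 0; j < N && error.empty(); ++j)
        for (int i = 0; i < N; ++i) {
          double hv = h(i, j);
          if (hv <= h_sub) {
            double u = hv + sigma_w - h_sub;
            if (u <= 0.0) {
              error = "membrane reached the wall singularity "
                      "(h <= h_sub - sigma_w); reduce dt";
              error_step = step;
              break;
            }
            double r = sigma_w / u;
            double r3 = r * r * r;
            preal(i, j) += dx2 * 8.0 * (eps_w / sigma_w) * r3 * r3 * r3;
            need_real = true;
          }
        }
      if (!error.empty()) break;
    }
    if (en_link && have_sites) {
      for (int m = 0; m < Nb; ++m)
        for (int n = 0; n < Nb; ++n)
          if (bonds(m, n) == 1) {
            int gi = site_ix(m, n), gj = site_iy(m, n);
            // point force: no area factor
            preal(gi, gj) -= k * (h(gi, gj) - h_L);
            need_real = true;
          }
    }
    if (need_real) F += plan.fwd(preal);
    if (en_press) F(0, 0) -= L * L * p;

    // Euler-Maruyama update
    for (int j = 0; j < N; ++j)
      for (int i = 0; i < N; ++i) hq(i, j) += dt * lambda(i, j) * F(i, j);
    if (en_noise && kBT > 0.0) {
      for (int idx : self_idx) hq(idx) += namp(idx) * rng.norm();
      for (const auto& pr : pair_idx) {
        double s = namp(pr.first) * inv_sqrt2;
        std::complex<double> z(s * rng.norm(), s * rng.norm());
        hq(pr.first) += z;
        hq(pr.second) += std::conj(z);
      }
    }
    h = plan.inv_real(hq) / (L * L);

    // bond kinetics, one sweep per step, fixed row-major site order
    if (en_kinetics && have_sites) {
      for (int m = 0; m < Nb; ++m)
        for (int n = 0; n < Nb; ++n) {
          double g = h(site_ix(m, n), site_iy(m, n));
          if (bonds(m, n) == 0) {
            if (std::fabs(g - h_L) <= R_RL && rng.unif() < kon0 * dt) {
              bonds(m, n) = 1;
              ++n_bind;
            }
          } else {
            double f = k * std::max(g - h_L, 0.0);
            double poff = koff0 * std::exp(f * x_b / kBT) * dt;
            if (poff > 1.0) { poff = 1.0; ++n_clamp; }
            if (rng.unif() < poff) {
              bonds(m, n) = 0;
              ++n_unbind;
            }
          }
        }
    }

    if (sample_stride > 0 && step % sample_stride == 0 && isamp < n_samp) {
      if (!hq.is_finite()) {
        error = "non-finite mode amplitude";
        error_step = step;
        break;
      }
      s_time(isamp) = step * dt;
      s_mean(isamp) = arma::mean(arma::vectorise(h));
      s_rms(isamp) = std::sqrt(arma::mean(arma::square(arma::vectorise(h))));
      int nc = have_sites ? int(arma::accu(bonds)) : 0;
      s_closed(isamp) = nc;
      s_phi(isamp) = have_sites ? double(nc) / (Nb * Nb) : NA_REAL;
      s_ebend(isamp) =
          0.5 * B / (L * L) * arma::accu(q4 % arma::square(arma::abs(hq)));
      double el = 0.0;
      if (have_sites)
        for (int m = 0; m < Nb; ++m)
          for (int n = 0; n < Nb; ++n)
            if (bonds(m, n) == 1) {
              double e = h(site_ix(m, n), site_iy(m, n)) - h_L;
              el += 0.5 * k * e * e;
            }
      s_elink(isamp) = el;
      ++isamp;
    }
    if (spectrum_stride > 0 && step % spectrum_stride == 0 && ispec < n_spec) {
      spec.slice(ispec) = arma::square(arma::abs(hq));
      ++ispec;
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("time") = s_time.head(isamp),
      Rcpp::Named("mean_height") = s_mean.head(isamp),
      Rcpp::Named("rms_height") = s_rms.head(isamp),
      Rcpp::Named("phi") = s_phi.head(isamp),
      Rcpp::Named("n_closed") = s_closed.head(isamp),
      Rcpp::Named("E_bend") = s_ebend.head(isamp),
      Rcpp::Named("E_link") = s_elink.head(isamp),
      Rcpp::Named("spectrum") = spec,
      Rcpp::Named("n_spectrum") = ispec,
      Rcpp::Named("final_hq") = hq,
      Rcpp::Named("final_bonds") = bonds,
      Rcpp::Named("n_bind") = double(n_bind),
      Rcpp::Named("n_unbind") = double(n_unbind),
      Rcpp::Named("n_clamp") = double(n_clamp),
      Rcpp::Named("error") = error,
      Rcpp::Named("error_step") = error_step);
}
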