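// First-order k-space pseudospectral time-domain solver for linear acoustics
// in heterogeneous lossy fluid media (split-field formulation, staggered
// spatial grids, k-space temporal correction at a reference sound speed).
//
// Conventions:
//   * the cube index order is (x, y, z); z is the propagation axis,
//     degenerate axes (size 1) are skipped, so 1D and 2D runs reuse the
//     identical stepping code;
//   * the transverse axes (x, y) are periodic; a split-field absorbing layer
//     (quartic ramp) is applied at both z ends only;
//   * absorption follows a frequency power law with exponent fixed at 2 by
//     the caller, for which the dispersion correction vanishes and the loss
//     operator reduces to tau * rho0 * div(u) inside the equation of state;
//   * spatial spectra are real-to-complex (half-spectrum along one axis),
//     with FFTW_MEASURE plans cached per grid geometry.
#include <RcppArmadillo.h>
#include <fftw3.h>
#include <map>
#include <array>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// 1D complex DFT through FFTW (O(n log n) at any length, including primes),
// unnormalized in both directions to match stats::fft semantics
// [[Rcpp::export]]
arma::cx_vec fft1_cpp(const arma::cx_vec& x, const bool inverse) {
  static std::map<std::array<long, 2>, fftw_plan> cache;
  const long n = x.n_elem;
  const int sign = inverse ? FFTW_BACKWARD : FFTW_FORWARD;
  cx_vec y = x;
  const std::array<long, 2> key = { n, sign };
  fftw_plan& pl = cache[key];
  fftw_complex* ptr = reinterpret_cast<fftw_complex*>(y.memptr());
  if (pl == nullptr) {
    pl = fftw_plan_dft_1d(int(n), ptr, ptr, sign,
                          FFTW_ESTIMATE | FFTW_UNALIGNED);
    if (pl == nullptr) Rcpp::stop("FFTW plan creation failed");
  }
  fftw_execute_dft(pl, ptr, ptr);
  return y;
}

// ---------------------------------------------------------------------------
// cached real<->half-spectrum transforms over an (nx, ny, nz) cube;
// the first non-degenerate axis carries the halved spectrum
struct RealFFT {
  long nx, ny, nz;        // real-grid dims
  long cx_, cy_, cz_;     // half-spectrum dims
  int halved;             // axis index of the halved dimension
  fftw_plan fw = nullptr, bw = nullptr;

  static RealFFT& get(const long nx, const long ny, const long nz) {
    static std::map<std::array<long, 3>, RealFFT> cache;
    RealFFT& p = cache[{ nx, ny, nz }];
    if (p.fw == nullptr) p.init(nx, ny, nz);
    return p;
  }

  void init(const long nx_, const long ny_, const long nz_) {
    nx = nx_; ny = ny_; nz = nz_;
    const long n[3] = { nx, ny, nz };
    halved = (nx > 1) ? 0 : (ny > 1) ? 1 : 2;
    long c[3] = { nx, ny, nz };
    c[halved] = n[halved] / 2 + 1;
    cx_ = c[0]; cy_ = c[1]; cz_ = c[2];
    const long sr[3] = { 1, nx, nx * ny };
    const long sc[3] = { 1, c[0], c[0] * c[1] };
    // transform dims: non-halved active axes first, halved axis last
    fftw_iodim dims[3];
    int rank = 0;
    for (int a = 0; a < 3; ++a)
      if (a != halved && n[a] > 1) {
        dims[rank].n = int(n[a]);
        dims[rank].is = int(sr[a]); dims[rank].os = int(sc[a]);
        ++rank;
      }
    dims[rank].n = int(n[halved]);
    dims[rank].is = int(sr[halved]); dims[rank].os = int(sc[halved]);
    ++rank;
    cube r_scratch(nx, ny, nz, fill::zeros);
    cx_cube c_scratch(cx_, cy_, cz_, fill::zeros);
    double* rp = r_scratch.memptr();
    fftw_complex* cp = reinterpret_cast<fftw_complex*>(c_scratch.memptr());
    fw = fftw_plan_guru_dft_r2c(rank, dims, 0, nullptr, rp, cp,
                                FFTW_MEASURE | FFTW_UNALIGNED);
    fftw_iodim dimsb[3];
    for (int a = 0; a < rank; ++a) {
      dimsb[a].n = dims[a].n;
      dimsb[a].is = dims[a].os; dimsb[a].os = dims[a].is;
    }
    bw = fftw_plan_guru_dft_c2r(rank, dimsb, 0, nullptr, cp, rp,
                                FFTW_MEASURE | FFTW_UNALIGNED);
    if (fw == nullptr || bw == nullptr)
      Rcpp::stop("FFTW plan creation failed");
  }

  void forward(const cube& X, cx_cube& F) const {
    fftw_execute_dft_r2c(fw, const_cast<double*>(X.memptr()),
                         reinterpret_cast<fftw_complex*>(F.memptr()));
  }
  // destroys F (multidimensional c2r transforms overwrite their input)
  void backward(cx_cube& F, cube& X) const {
    fftw_execute_dft_c2r(bw, reinterpret_cast<fftw_complex*>(F.memptr()),
                         X.memptr());
    X /= double(nx * ny * nz);
  }
};

// circular shift so that out(i) = X(i + 1) along dim (for staggered-grid
// interpolation of the density)
static cube shift_up(const cube& X, const int dim) {
  cube Y(size(X));
  if (dim == 2) {
    for (uword s = 0; s < X.n_slices; ++s)
      Y.slice(s) = X.slice((s + 1) % X.n_slices);
  } else {
    for (uword s = 0; s < X.n_slices; ++s)
      Y.slice(s) = shift(X.slice(s), -1, dim);
  }
  return Y;
}

static double sinc(const double x) {
  return (std::abs(x) < 1e-12) ? 1.0 : std::sin(x) / x;
}

// signed wavenumber of bin i (negative Nyquist convention)
static double k_of_bin(const long i, const long n, const double dx) {
  const double dk = 2.0 * datum::pi / (double(n) * dx);
  const double m = (i <= (n - 1) / 2) ? double(i) : double(i) - double(n);
  return m * dk;
}

// [[Rcpp::export]]
Rcpp::List kspace_run_cpp(const arma::cube& c0, const arma::cube& rho0,
                          const arma::cube& tau,
                          const double dx, const double dt, const int n_steps,
                          const arma::vec& source, const arma::mat& source_amp,
                          const int z_src, const int z_rec,
                          const double c_ref,
                          const int pml_size, const double pml_alpha,
                          const bool track_energy) {
  const long nx = c0.n_rows, ny = c0.n_cols, nz = c0.n_slices;
  const bool ax[3] = { nx > 1, ny > 1, nz > 1 };
  int n_active = 0;
  for (int d = 0; d < 3; ++d) if (ax[d]) ++n_active;
  if (n_active == 0) Rcpp::stop("grid must have at least one non-degenerate axis");

  RealFFT& F = RealFFT::get(nx, ny, nz);
  const long cx_ = F.cx_, cy_ = F.cy_, cz_ = F.cz_;
  const long nfull[3] = { nx, ny, nz };

  // half-spectrum spectral operators: i k_d * kappa * exp(+/- i k_d dx / 2);
  // at a Nyquist bin the staggered derivative of a real field reduces to the
  // operator's real part, -/+ |k_N| * kappa (the half-voxel shift makes the
  // Nyquist derivative well defined, an advantage of staggered grids)
  std::vector<cx_cube> op_pos(3), op_neg(3);
  for (int d = 0; d < 3; ++d)
    if (ax[d]) {
      op_pos[d].set_size(cx_, cy_, cz_);
      op_neg[d].set_size(cx_, cy_, cz_);
    }
  for (long s = 0; s < cz_; ++s)
    for (long j = 0; j < cy_; ++j)
      for (long i = 0; i < cx_; ++i) {
        const long bin[3] = { i, j, s };
        double kk[3] = { 0, 0, 0 };
        bool nyq[3] = { false, false, false };
        for (int d = 0; d < 3; ++d) {
          if (!ax[d]) continue;
          const long n = nfull[d];
          if (d == F.halved) kk[d] = bin[d] * 2.0 * datum::pi / (n * dx);
          else kk[d] = k_of_bin(bin[d], n, dx);
          nyq[d] = (n % 2 == 0) && (bin[d] == n / 2);
        }
        const double km = std::sqrt(kk[0] * kk[0] + kk[1] * kk[1] +
                                    kk[2] * kk[2]);
        const double kap = sinc(0.5 * c_ref * km * dt);
        for (int d = 0; d < 3; ++d) {
          if (!ax[d]) continue;
          if (nyq[d]) {
            const double kN = std::abs(kk[d]);
            op_pos[d](i, j, s) = cx_double(-kN * kap, 0.0);
            op_neg[d](i, j, s) = cx_double(+kN * kap, 0.0);
            continue;
          }
          const cx_double ik(0.0, kk[d]);
          const cx_double sh = std::exp(cx_double(0.0, 0.5 * kk[d] * dx));
          op_pos[d](i, j, s) = ik * kap * sh;
          op_neg[d](i, j, s) = ik * kap * std::conj(sh);
        }
      }

  // z-axis absorbing layer, quartic ramp over pml_size voxels at both ends,
  // applied twice per update (split-field exponential damping)
  cube pml(nx, ny, nz, fill::ones), pml_sg(nx, ny, nz, fill::ones);
  if (pml_size > 0) {
    auto prof = [&](const double pos) {
      double xi = 0.0;
      if (pos < pml_size) xi = (double(pml_size) - pos) / double(pml_size);
      else if (pos > double(nz - 1 - pml_size))
        xi = (pos - double(nz - 1 - pml_size)) / double(pml_size);
      xi = std::min(std::max(xi, 0.0), 1.0);
      const double sigma = pml_alpha * c_ref / dx * std::pow(xi, 4);
      return std::exp(-0.5 * sigma * dt);
    };
    for (long s = 0; s < nz; ++s) {
      pml.slice(s).fill(prof(double(s)));
      pml_sg.slice(s).fill(prof(double(s) + 0.5));
    }
  }

  // precomputed coefficient maps
  const cube c2 = square(c0);
  const cube dtrho0 = dt * rho0;
  const cube tau_rho0 = tau % rho0;
  cube dt_invrho_sg[3];
  for (int d = 0; d < 3; ++d)
    if (ax[d]) dt_invrho_sg[d] = dt / (0.5 * (rho0 + shift_up(rho0, d)));

  // additive plane pressure source, split equally across active axes
  const mat inj = source_amp / c2.slice(z_src) / double(n_active);

  cube p(nx, ny, nz, fill::zeros);
  cube u[3], rho[3], dpd[3], dud[3];
  for (int d = 0; d < 3; ++d)
    if (ax[d]) {
      u[d] = cube(nx, ny, nz, fill::zeros);
      rho[d] = cube(nx, ny, nz, fill::zeros);
      dpd[d] = cube(nx, ny, nz, fill::zeros);
      dud[d] = cube(nx, ny, nz, fill::zeros);
    }
  cx_cube Fp(cx_, cy_, cz_), G(cx_, cy_, cz_);
  cube rho_sum(nx, ny, nz), divu(nx, ny, nz);

  cube record(nx, ny, (uword)n_steps);
  vec energy;
  cube u_prev[3];
  if (track_energy) {
    energy.zeros(n_steps);
    for (int d = 0; d < 3; ++d)
      if (ax[d]) u_prev[d] = cube(nx, ny, nz, fill::zeros);
  }

  for (int n = 0; n < n_steps; ++n) {
    // conserved leapfrog energy: potential from p at time n, kinetic from
    // the time-staggered product u(n-1/2) u(n+1/2) (filled in post-update)
    if (track_energy) {
      energy(n) = 0.5 * accu(square(p) / (rho0 % c2));
      for (int d = 0; d < 3; ++d)
        if (ax[d]) u_prev[d] = u[d];
    }
    // pressure gradient on the staggered grids
    F.forward(p, Fp);
    for (int d = 0; d < 3; ++d) {
      if (!ax[d]) continue;
      G = Fp % op_pos[d];
      F.backward(G, dpd[d]);
    }
    // momentum conservation (z axis carries the absorbing layer)
    for (int d = 0; d < 3; ++d) {
      if (!ax[d]) continue;
      if (d == 2) u[d] = pml_sg % (pml_sg % u[d] - dt_invrho_sg[d] % dpd[d]);
      else        u[d] -= dt_invrho_sg[d] % dpd[d];
    }
    if (track_energy)
      for (int d = 0; d < 3; ++d)
        if (ax[d]) energy(n) += 0.5 * accu(rho0 % (u_prev[d] % u[d]));
    // velocity divergence on the regular grid
    for (int d = 0; d < 3; ++d) {
      if (!ax[d]) continue;
      F.forward(u[d], G);
      G %= op_neg[d];
      F.backward(G, dud[d]);
    }
    // mass conservation with split density
    for (int d = 0; d < 3; ++d) {
      if (!ax[d]) continue;
      if (d == 2) rho[d] = pml % (pml % rho[d] - dtrho0 % dud[d]);
      else        rho[d] -= dtrho0 % dud[d];
    }
    // source injection
    const double s_n = source(n);
    if (s_n != 0.0)
      for (int d = 0; d < 3; ++d)
        if (ax[d]) rho[d].slice(z_src) += s_n * inj;
    // equation of state, power-law exponent 2 (non-dispersive loss term)
    rho_sum.zeros(); divu.zeros();
    for (int d = 0; d < 3; ++d)
      if (ax[d]) { rho_sum += rho[d]; divu += dud[d]; }
    p = c2 % (rho_sum + tau_rho0 % divu);

    record.slice(n) = p.slice(z_rec);
    if ((n & 0x1FF) == 0x1FF && !p.is_finite())
      Rcpp::stop("numerical instability: non-finite pressure at step %d", n + 1);
  }
  if (!p.is_finite())
    Rcpp::stop("numerical instability: non-finite pressure at step %d", n_steps);

  return Rcpp::List::create(
    Rcpp::Named("record") = record,
    Rcpp::Named("energy") = track_energy ? Rcpp::wrap(energy) : R_NilValue);
}
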