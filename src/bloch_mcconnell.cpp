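// Two-state Bloch-McConnell propagation for 15N CEST.
//
// State vector: (Mx, My, Mz) of the major conformer followed by
// (Mx, My, Mz) of the minor conformer.  Decay-only convention: no
// thermal-recovery inhomogeneous term, so dM/dt = L M and
// M(t) = expm(L t) M(0).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat bm_generator(double p_minor, double k_ex,
                              double omega_a, double omega_b, double w1,
                              double r1, double r2a, double r2b) {
  // detailed balance by construction
  const double k_ab = p_minor * k_ex;          // major -> minor
  const double k_ba = (1.0 - p_minor) * k_ex;  // minor -> major

  arma::mat L(6, 6, arma::fill::zeros);

  // major conformer block: precession about z, nutation about x
  L(0, 0) = -r2a - k_ab; L(0, 1) = -omega_a;
  L(1, 0) =  omega_a;    L(1, 1) = -r2a - k_ab; L(1, 2) = -w1;
  L(2, 1) =  w1;         L(2, 2) = -r1  - k_ab;

  // minor conformer block
  L(3, 3) = -r2b - k_ba; L(3, 4) = -omega_b;
  L(4, 3) =  omega_b;    L(4, 4) = -r2b - k_ba; L(4, 5) = -w1;
  L(5, 4) =  w1;         L(5, 5) = -r1  - k_ba;

  // exchange coupling between corresponding components
  for (int i = 0; i < 3; ++i) {
    L(i, i + 3) = k_ba;
    L(i + 3, i) = k_ab;
  }
  return L;
}

// [[Rcpp::export]]
arma::mat bm_generator_cpp(double p_minor, double k_ex,
                           double omega_a, double omega_b, double w1,
                           double r1, double r2a, double r2b) {
  return bm_generator(p_minor, k_ex, omega_a, omega_b, w1, r1, r2a, r2b);
}

// I/I0 CEST profile for one residue over an offset grid at several B1
// fields.  Offsets and shifts in ppm; nu_n_mhz converts ppm to Hz.
// Returns a matrix with one row per offset and one column per B1 field.
// [[Rcpp::export]]
arma::mat bm_profile_cpp(double p_minor, double k_ex,
                         double shift_major_ppm, double delta_shift_ppm,
                         double r1, double r2a, double r2b,
                         double nu_n_mhz,
                         const arma::vec& b1_hz,
                         const arma::vec& offsets_ppm,
                         double t_ex) {
  const double twopi = 2.0 * M_PI;
  arma::mat out(offsets_ppm.n_elem, b1_hz.n_elem);
  arma::vec m0 = {0.0, 0.0, 1.0 - p_minor, 0.0, 0.0, p_minor};

  for (arma::uword j = 0; j < b1_hz.n_elem; ++j) {
    const double w1 = twopi * b1_hz(j);
    for (arma::uword i = 0; i < offsets_ppm.n_elem; ++i) {
      const double omega_a =
        twopi * (shift_major_ppm - offsets_ppm(i)) * nu_n_mhz;
      const double omega_b =
        twopi * (shift_major_ppm + delta_shift_ppm - offsets_ppm(i)) * nu_n_mhz;
      arma::mat L = bm_generator(p_minor, k_ex, omega_a, omega_b, w1,
                                 r1, r2a, r2b);
      arma::vec m = arma::expmat(L * t_ex) * m0;
      out(i, j) = m(2) / (1.0 - p_minor);  // I0 slice omits t_ex entirely
    }
  }
  return out;
}
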