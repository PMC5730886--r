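#' Two-state exchange parameters
#'
#' Describes a protein exchanging between a visible major conformer and a
#' sparsely populated minor conformer: global occupancy and exchange rate
#' plus per-residue 15N shifts.  Detailed balance holds by construction
#' (`k_major_to_minor = p_minor * k_ex`,
#' `k_minor_to_major = (1 - p_minor) * k_ex`).
#'
#' @param residues Data frame with columns `residue` (number),
#'   `shift_major_n` (major-state 15N shift, ppm) and `delta_shift_n`
#'   (minor minus major 15N shift, ppm).
#' @param p_minor Minor-state occupancy, in `[0, 1)`.
#' @param k_ex Exchange rate (sum of forward and reverse rates), s^-1.
#' @param r1 Longitudinal relaxation rate shared by both states, s^-1.
#' @param r2_major,r2_minor Transverse relaxation rates, s^-1.
#' @param spectrometer_h_mhz Spectrometer 1H frequency, MHz.
#' @param temperature_c Sample temperature, deg C.
#' @return An `exchange_params` object.
#' @export
exchange_params <- function(residues, p_minor, k_ex,
                            r1 = 1.2, r2_major = 10, r2_minor = 14,
                            spectrometer_h_mhz = 700,
                            temperature_c = 25) {
  residues <- as_tibble(residues)
  stopifnot(all(c("residue", "shift_major_n", "delta_shift_n") %in%
                  names(residues)))
  if (p_minor < 0 || p_minor >= 1) abort("p_minor must be in [0, 1)")
  if (k_ex <= 0) abort("k_ex must be > 0")
  if (r1 <= 0 || r2_major <= 0 || r2_minor <= 0) {
    abort("relaxation rates must be > 0")
  }
  structure(
    list(residues = residues, p_minor = p_minor, k_ex = k_ex,
         r1 = r1, r2_major = r2_major, r2_minor = r2_minor,
         spectrometer_h_mhz = spectrometer_h_mhz,
         larmor_n_mhz = larmor_n_mhz(spectrometer_h_mhz),
         temperature_c = temperature_c),
    class = "exchange_params")
}

#' @export
#' @method print exchange_params
print.exchange_params <- function(x, ...) {
  cat(sprintf(
    "Two-state exchange: p_minor = %.4g, k_ex = %.4g /s, %d residue(s), %g MHz (1H)\n",
    x$p_minor, x$k_ex, nrow(x$residues), x$spectrometer_h_mhz))
  invisible(x)
}

#' CEST saturation scheme
#'
#' The acquisition schedule of a pseudo-2D 15N CEST experiment: the weak
#' B1 saturation fields, the offset grid over which the carrier is
#' stepped, and the exchange (saturation) period.  The reference slice
#' (`I0`) omits the exchange period entirely.
#'
#' @param b1_fields_hz B1 amplitudes in Hz.
#' @param offsets_ppm Strictly increasing saturation offsets, ppm.
#' @param t_ex Exchange period, s.
#' @param reference Whether a zero-saturation reference slice is part of
#'   the scheme.
#' @return A `cest_scheme` object.
#' @export
cest_scheme <- function(b1_fields_hz = c(12.5, 20, 25, 37.5, 50),
                        offsets_ppm = seq(102, 134, length.out = 184),
                        t_ex = 0.4, reference = TRUE) {
  if (t_ex <= 0) abort("t_ex must be > 0")
  if (any(diff(offsets_ppm) <= 0)) {
    abort("offsets_ppm must be strictly increasing")
  }
  structure(list(b1_fields_hz = b1_fields_hz, offsets_ppm = offsets_ppm,
                 t_ex = t_ex, reference = reference),
            class = "cest_scheme")
}

#' Bloch-McConnell evolution matrix
#'
#' Builds the 6x6 real generator of the two-state Bloch-McConnell
#' equations for the magnetization vector
#' `(Mx, My, Mz)_major + (Mx, My, Mz)_minor` in the rotating frame of the
#' saturation carrier: precession at `2*pi*(shift - offset)*larmor`
#' (rad/s), nutation `2*pi*b1_hz` about x, decay-only relaxation (`-r2`
#' transverse, `-r1` longitudinal) and exchange coupling obeying detailed
#' balance.
#'
#' @param params An [exchange_params()] object.
#' @param residue Residue number (must appear in `params$residues`).
#' @param b1_hz B1 amplitude, Hz.
#' @param offset_ppm Saturation carrier position, ppm.
#' @return A 6x6 numeric matrix.
#' @export
evolution_matrix <- function(params, residue, b1_hz, offset_ppm) {
  row <- params$residues[params$residues$residue == residue, ]
  if (nrow(row) != 1) abort(paste0("residue ", residue, " not in params"))
  omega_a <- 2 * pi * (row$shift_major_n - offset_ppm) * params$larmor_n_mhz
  omega_b <- 2 * pi * (row$shift_major_n + row$delta_shift_n - offset_ppm) *
    params$larmor_n_mhz
  w1 <- 2 * pi * b1_hz
  k_ab <- params$p_minor * params$k_ex
  k_ba <- (1 - params$p_minor) * params$k_ex
  block <- function(omega, r2, k_out) {
    matrix(c(-r2 - k_out, -omega, 0,
             omega, -r2 - k_out, -w1,
             0, w1, -params$r1 - k_out),
           nrow = 3, byrow = TRUE)
  }
  L <- matrix(0, 6, 6)
  L[1:3, 1:3] <- block(omega_a, params$r2_major, k_ab)
  L[4:6, 4:6] <- block(omega_b, params$r2_minor, k_ba)
  L[1:3, 4:6] <- diag(k_ba, 3)
  L[4:6, 1:3] <- diag(k_ab, 3)
  L
}

#' Propagate magnetization under a Bloch-McConnell generator
#'
#' Evolves a 6-component magnetization vector for `t_ex` seconds via the
#' matrix exponential `expm(L * t_ex) %*% m0` (scaling-and-squaring).
#' `t_ex = 0` returns `m0` exactly.
#'
#' @param m0 Numeric length-6 start vector.
#' @param L 6x6 generator from [evolution_matrix()].
#' @param t_ex Evolution time, s (`>= 0`).
#' @return Numeric length-6 vector.
#' @export
propagate <- function(m0, L, t_ex) {
  stopifnot(length(m0) == 6, all(dim(L) == c(6, 6)), t_ex >= 0)
  if (t_ex == 0) return(m0)
  out <- as.numeric(Matrix::expm(Matrix::Matrix(L * t_ex)) %*% m0)
  if (any(!is.finite(out))) {
    abort(paste0("non-finite propagation result (t_ex = ", t_ex, ")"))
  }
  out
}

#' Simulate a CEST profile for one residue
#'
#' Starting magnetization is the equilibrium longitudinal state
#' `(0, 0, 1 - p_minor, 0, 0, p_minor)`.  For each offset, `I` is the
#' major-state Mz after the exchange period; `I0` is the reference with
#' the exchange period omitted, i.e. `1 - p_minor`.  Far off resonance
#' the profile approaches `exp(-r1 * t_ex)`.
#'
#' @param params An [exchange_params()] object.
#' @param scheme A [cest_scheme()].
#' @param residue Residue number.
#' @return Tibble with columns `residue`, `b1_hz`, `offset_ppm`,
#'   `i_over_i0`.
#' @export
cest_profile <- function(params, scheme, residue) {
  row <- params$residues[params$residues$residue == residue, ]
  if (nrow(row) != 1) abort(paste0("residue ", residue, " not in params"))
  prof <- bm_profile_cpp(
    params$p_minor, params$k_ex, row$shift_major_n, row$delta_shift_n,
    params$r1, params$r2_major, params$r2_minor, params$larmor_n_mhz,
    scheme$b1_fields_hz, scheme$offsets_ppm, scheme$t_ex)
  tidyr::expand_grid(b1_hz = scheme$b1_fields_hz,
                     offset_ppm = scheme$offsets_ppm) |>
    dplyr::mutate(residue = residue,
                  i_over_i0 = as.vector(prof),
                  .before = 1) |>
    dplyr::select("residue", "b1_hz", "offset_ppm", "i_over_i0")
}

#' Locate saturation dips in a CEST profile
#'
#' Finds local minima that fall below `baseline - threshold * noise`,
#' returned sorted by depth (deepest first).  The baseline defaults to
#' the off-resonance plateau (maximum of the profile edges).  Minima on
#' the shoulder of a deeper dip are suppressed by a prominence rule:
#' between any two reported dips the profile must rise above the
#' shallower one by at least `min_prominence` times its depth.
#'
#' @param profile Data frame with `offset_ppm` and `i_over_i0` for a
#'   single residue and B1 field, on a monotone offset grid.
#' @param noise Noise level on I/I0 used to scale the threshold.
#' @param threshold Detection threshold in noise units.
#' @param min_prominence Fraction of a dip's depth by which the profile
#'   must recover between it and any deeper dip.
#' @param min_separation_ppm Minimum offset separation between reported
#'   dips; closer minima (e.g. coherent-oscillation sidelobes at the
#'   foot of a deep dip) are merged into the deeper one.
#' @return Tibble with `offset_ppm` and `depth` (baseline minus profile
#'   value); zero rows for a flat profile.
#' @export
detect_dips <- function(profile, noise = 0.002, threshold = 3,
                        min_prominence = 0.1, min_separation_ppm = 0.5) {
  stopifnot(all(c("offset_ppm", "i_over_i0") %in% names(profile)))
  profile <- profile[order(profile$offset_ppm), ]
  y <- profile$i_over_i0
  n <- length(y)
  if (n < 3) return(tibble(offset_ppm = numeric(0), depth = numeric(0)))
  baseline <- max(y[c(1, n)])
  is_min <- vapply(2:(n - 1), function(i) {
    y[i] <= y[i - 1] && y[i] <= y[i + 1] && (y[i] < y[i - 1] || y[i] < y[i + 1])
  }, logical(1))
  idx <- which(is_min) + 1
  depth <- baseline - y[idx]
  keep <- depth > threshold * noise
  idx <- idx[keep]; depth <- depth[keep]
  o <- order(-depth)
  idx <- idx[o]; depth <- depth[o]
  kept <- integer(0)
  for (j in seq_along(idx)) {
    i <- idx[j]
    ok <- all(vapply(kept, function(kk) {
      ridge <- max(y[seq(min(i, kk), max(i, kk))])
      ridge - y[i] >= min_prominence * depth[j] &&
        abs(profile$offset_ppm[i] - profile$offset_ppm[kk]) >=
          min_separation_ppm
    }, logical(1)))
    if (ok) kept <- c(kept, i)
  }
  sel <- match(kept, idx)
  tibble(offset_ppm = profile$offset_ppm[kept], depth = depth[sel])
}

#' Two-point van't Hoff extrapolation of a minor-state occupancy
#'
#' Treats `ln K` with `K = p / (1 - p)` as linear in `1/T` between two
#' measured (temperature, occupancy) pairs and evaluates the line at a
#' target temperature.  With a positive transition enthalpy the
#' occupancy increases with temperature.
#'
#' @param point_a,point_b Length-2 numeric vectors `c(temperature_K, p)`.
#' @param target_t_k Target temperature, K.
#' @return Extrapolated occupancy at `target_t_k`.
#' @examples
#' # occupancy at a colder temperature given a hot/cold pair
#' extrapolate_occupancy(c(318.15, 0.045), c(298.15, 0.013), 288.15)
#' @export
extrapolate_occupancy <- function(point_a, point_b, target_t_k) {
  stopifnot(length(point_a) == 2, length(point_b) == 2)
  ta <- point_a[1]; pa <- point_a[2]
  tb <- point_b[1]; pb <- point_b[2]
  if (any(c(pa, pb) <= 0) || any(c(pa, pb) >= 1)) {
    abort("occupancies must lie in (0, 1)")
  }
  if (ta == tb) abort("temperatures must differ")
  lka <- log(pa / (1 - pa))
  lkb <- log(pb / (1 - pb))
  slope <- (lkb - lka) / (1 / tb - 1 / ta)
  lk <- lka + slope * (1 / target_t_k - 1 / ta)
  exp(lk) / (1 + exp(lk))
}
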