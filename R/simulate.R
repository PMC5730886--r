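#' Intensity noise model for the synthetic-data generators
#'
#' Noise is Gaussian and multiplicative on raw intensities (a fraction of
#' the noiseless value), applied before any ratioing, so the fitted
#' ratios inherit realistic correlated noise from the reference slice.
#' Identical seeds produce identical draws.
#'
#' @param kind `"none"` or `"gaussian"`.
#' @param sigma_fraction Standard deviation as a fraction of the
#'   noiseless intensity (`0.01` = 1\% noise).
#' @param seed Optional integer seed; the generator's draws are made
#'   under this seed without disturbing the global RNG stream.
#' @return A `noise_model` object.
#' @export
noise_model <- function(kind = c("none", "gaussian"), sigma_fraction = 0,
                        seed = NULL) {
  kind <- match.arg(kind)
  if (sigma_fraction < 0) abort("sigma_fraction must be >= 0")
  structure(list(kind = kind, sigma_fraction = sigma_fraction, seed = seed),
            class = "noise_model")
}

# Evaluate code under a seed, restoring the caller's RNG state after.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

apply_noise <- function(x, noise) {
  if (noise$kind == "none" || noise$sigma_fraction == 0) return(x)
  x * (1 + rnorm(length(x), sd = noise$sigma_fraction))
}

#' Draw a synthetic residue table for CEST fixtures
#'
#' Major-state 15N shifts are placed uniformly over the central portion
#' of the offset window; minor-state shift differences are drawn
#' uniformly from 0.5-4 ppm with random sign, mimicking the spread seen
#' across exchanging amides and exercising sign handling in the fitter.
#'
#' @param n_residues Number of residues.
#' @param seed Integer seed.
#' @param shift_range Range (ppm) for major-state shifts.
#' @param dw_range Range (ppm) for the magnitude of the minor-state
#'   shift difference.
#' @return Tibble with `residue`, `shift_major_n`, `delta_shift_n`.
#' @export
draw_cest_residues <- function(n_residues = 7, seed = 1,
                               shift_range = c(108, 128),
                               dw_range = c(0.5, 4)) {
  with_local_seed(seed, {
    tibble(
      residue = seq_len(n_residues),
      shift_major_n = runif(n_residues, shift_range[1], shift_range[2]),
      delta_shift_n = runif(n_residues, dw_range[1], dw_range[2]) *
        sample(c(-1, 1), n_residues, replace = TRUE)
    )
  })
}

#' Simulate a CEST dataset
#'
#' Computes noiseless I/I0 profiles from the shared Bloch-McConnell
#' forward model ([cest_profile()]) for every residue and B1 field, then
#' applies multiplicative intensity noise to the saturated slices and to
#' the per-(residue, B1) reference slice before ratioing.
#'
#' @param params An [exchange_params()] object.
#' @param scheme A [cest_scheme()].
#' @param noise A [noise_model()].
#' @return A `cest_dataset`: tibble with `residue`, `b1_hz`,
#'   `offset_ppm`, `i_over_i0` plus scheme/residue metadata attributes.
#' @export
simulate_cest_dataset <- function(params, scheme,
                                  noise = noise_model("none")) {
  shifts <- params$residues$shift_major_n
  rng <- range(scheme$offsets_ppm)
  if (any(shifts < rng[1] | shifts > rng[2])) {
    warn("offset grid excludes a major-state resonance; fit will be ill-posed")
  }
  clean <- purrr::map_dfr(params$residues$residue,
                          function(r) cest_profile(params, scheme, r))
  data <- with_local_seed(noise$seed, {
    i0_true <- 1 - params$p_minor
    clean |>
      dplyr::group_by(.data$residue, .data$b1_hz) |>
      dplyr::mutate(
        i_over_i0 = apply_noise(.data$i_over_i0 * i0_true, noise) /
          apply_noise(i0_true, noise)[1]
      ) |>
      dplyr::ungroup()
  })
  new_cest_dataset(data, scheme = scheme, residues = params$residues,
                   larmor_n_mhz = params$larmor_n_mhz,
                   temperature_c = params$temperature_c)
}

new_cest_dataset <- function(data, scheme, residues, larmor_n_mhz,
                             temperature_c) {
  structure(as_tibble(data),
            scheme = scheme, residues = residues,
            larmor_n_mhz = larmor_n_mhz, temperature_c = temperature_c,
            class = c("cest_dataset", class(as_tibble(data))))
}

#' Simulate a CEST dataset from a packaged preset
#'
#' Convenience wrapper combining [get_preset()], [draw_cest_residues()]
#' and [simulate_cest_dataset()].
#'
#' @param preset Name of a `kind == "cest"` preset (see [ub_presets()]).
#' @param n_residues Number of synthetic residues.
#' @param seed Seed for the residue draw.
#' @param scheme A [cest_scheme()].
#' @param spectrometer_h_mhz Spectrometer 1H frequency, MHz.
#' @param noise A [noise_model()].
#' @inheritParams exchange_params
#' @return A `cest_dataset`.
#' @export
simulate_cest_from_preset <- function(preset, n_residues = 7, seed = 1,
                                      scheme = cest_scheme(),
                                      spectrometer_h_mhz = 950,
                                      noise = noise_model("none"),
                                      r1 = 1.2, r2_major = 10,
                                      r2_minor = 14) {
  p <- get_preset(preset)
  if (p$kind != "cest") abort(paste0("'", preset, "' is not a CEST preset"))
  residues <- draw_cest_residues(n_residues, seed = seed)
  params <- exchange_params(residues, p_minor = p$p_minor, k_ex = p$k_ex,
                            r1 = r1, r2_major = r2_major,
                            r2_minor = r2_minor,
                            spectrometer_h_mhz = spectrometer_h_mhz,
                            temperature_c = p$temperature_c)
  simulate_cest_dataset(params, scheme, noise)
}

#' CLEANEX buildup closed form
#'
#' Solvent-exchange buildup of amide intensity with mixing time:
#' `I(tau)/I0 = k / (r1_amide + k - r1_water) *
#' (exp(-r1_water * tau) - exp(-(r1_amide + k) * tau))`.
#' Shared by the simulator and the fitter, so noiseless recovery is
#' exact to optimizer tolerance.
#'
#' @param tau_s Mixing time, s.
#' @param k Solvent-exchange rate, s^-1.
#' @param r1_amide Amide longitudinal relaxation rate, s^-1.
#' @param r1_water Water longitudinal relaxation rate, s^-1.
#' @return Relative intensity I/I0.
#' @export
cleanex_buildup <- function(tau_s, k, r1_amide, r1_water) {
  if (k == 0) return(rep(0, length(tau_s)))
  denom <- r1_amide + k - r1_water
  if (abs(denom) < 1e-10) {
    # degenerate limit r1_amide + k -> r1_water
    return(k * tau_s * exp(-r1_water * tau_s))
  }
  k / denom * (exp(-r1_water * tau_s) - exp(-(r1_amide + k) * tau_s))
}

#' Simulate CLEANEX buildup series
#'
#' @param k Per-residue solvent-exchange rates, s^-1 (named or unnamed
#'   vector; names become residue numbers, otherwise 1..n).
#' @param r1_amide Amide R1, s^-1.
#' @param r1_water Water R1, s^-1.
#' @param mixing_times_ms Mixing times, ms.
#' @param reference Reference intensity I0 (arbitrary units).
#' @param noise A [noise_model()].
#' @return Tibble with `residue`, `mixing_time_ms`, `intensity`,
#'   `reference`.
#' @export
simulate_cleanex_series <- function(k, r1_amide = 2, r1_water = 0.6,
                                    mixing_times_ms =
                                      c(5.2, 10.4, 20.8, 41.6, 83.2, 166.4),
                                    reference = 1e6,
                                    noise = noise_model("none")) {
  if (any(k < 0)) abort("exchange rates must be >= 0")
  if (any(mixing_times_ms <= 0)) abort("mixing times must be > 0")
  residues <- if (!is.null(names(k))) as.integer(names(k)) else seq_along(k)
  with_local_seed(noise$seed, {
    purrr::map2_dfr(residues, k, function(res, ki) {
      clean <- reference * cleanex_buildup(mixing_times_ms / 1000, ki,
                                           r1_amide, r1_water)
      tibble(residue = res,
             mixing_time_ms = mixing_times_ms,
             intensity = apply_noise(clean, noise),
             reference = reference)
    })
  })
}

#' Simulate a real-time phosphorylation time course
#'
#' Serial peak heights for a first-order substrate-to-product
#' conversion: disappearing peaks decay as `exp(-k_phos * t)`, appearing
#' peaks grow as `1 - exp(-k_phos * t)`.  Each resonance carries its own
#' multiplicative intensity scale (drawn once per resonance), and
#' Gaussian intensity noise is applied per point.  The first time point
#' is acquired before any conversion (t = 0).
#'
#' @param k_phos First-order rate, min^-1.
#' @param t_step Acquisition increment, min.
#' @param n_steps Number of serial spectra.
#' @param n_resonances Number of monitored resonances.
#' @param noise A [noise_model()].
#' @return Tibble with `residue`, `species`
#'   (`"disappearing"`/`"appearing"`), `time_min`, `height`.
#' @export
simulate_phospho_timecourse <- function(k_phos, t_step = 4, n_steps = 16,
                                        n_resonances = 9,
                                        noise = noise_model("none")) {
  if (k_phos < 0) abort("k_phos must be >= 0")
  if (n_resonances < 1) abort("n_resonances must be >= 1")
  times <- (seq_len(n_steps) - 1) * t_step
  with_local_seed(noise$seed, {
    scales <- tibble(
      residue = seq_len(n_resonances),
      scale_dis = runif(n_resonances, 0.5, 2),
      scale_app = runif(n_resonances, 0.5, 2)
    )
    purrr::pmap_dfr(scales, function(residue, scale_dis, scale_app) {
      frac <- 1 - exp(-k_phos * times)
      dplyr::bind_rows(
        tibble(residue = residue, species = "disappearing",
               time_min = times,
               height = apply_noise(scale_dis * (1 - frac), noise)),
        tibble(residue = residue, species = "appearing",
               time_min = times,
               height = apply_noise(scale_app * frac, noise))
      )
    })
  })
}

#' Simulate a DSC endotherm
#'
#' Baseline-corrected excess heat capacity from the independent
#' van't Hoff transition model ([model_cp()]) plus optional Gaussian
#' noise scaled to the peak height.
#'
#' @param t_m_c Melting temperature, deg C.
#' @param dh_cal Calorimetric enthalpy, kJ/mol.
#' @param dh_vh van't Hoff enthalpy, kJ/mol.
#' @param t_grid_c Temperature grid, deg C; should span `t_m_c` by at
#'   least 20 deg C on both sides (warning otherwise).
#' @param noise A [noise_model()]; `sigma_fraction` scales the peak Cp.
#' @return Tibble with `temp_c`, `cp` (kJ mol^-1 K^-1).
#' @export
simulate_dsc_endotherm <- function(t_m_c, dh_cal = 300, dh_vh = 300,
                                   t_grid_c = seq(40, 110, by = 0.1),
                                   noise = noise_model("none")) {
  if (min(t_grid_c) > t_m_c - 20 || max(t_grid_c) < t_m_c + 20) {
    warn("temperature grid does not span t_m by 20 deg C on both sides")
  }
  cp <- model_cp(t_grid_c, t_m_c, dh_cal, dh_vh)
  cp <- with_local_seed(noise$seed, {
    if (noise$kind == "gaussian" && noise$sigma_fraction > 0) {
      cp + rnorm(length(cp), sd = noise$sigma_fraction * max(cp))
    } else cp
  })
  tibble(temp_c = t_grid_c, cp = cp)
}
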