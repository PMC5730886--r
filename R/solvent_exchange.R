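#' Fit CLEANEX solvent-exchange rates
#'
#' Fits the amide-water exchange rate `k` per residue from a CLEANEX
#' buildup series.  `mode = "full_model"` fits the two-exponential
#' closed form ([cleanex_buildup()]) for `k` and `r1_amide` with the
#' water R1 fixed; `mode = "initial_rate"` fits the early-mixing-time
#' slope of `I/I0` through the origin, whose limit is `k`.  Rates are
#' constrained non-negative, and estimates are invariant to the global
#' intensity scale.  If the full model fails to converge for a residue
#' the initial-rate estimate is returned with `flag = "initial_rate_fallback"`;
#' an all-zero series returns `k = 0` with `flag = "zero_signal"`.
#'
#' @param series Data frame with `residue`, `mixing_time_ms`,
#'   `intensity`, `reference` (I0 from the reference spectrum).
#' @param r1_water Fixed water longitudinal relaxation rate, s^-1.
#' @param mode `"full_model"` or `"initial_rate"`.
#' @param r1_amide_init Starting value for the amide R1, s^-1.
#' @return A `cleanex_fit` tibble: `residue`, `k`, `k_se`, `r1_amide`,
#'   `flag`.
#' @export
fit_exchange_rate <- function(series, r1_water = 0.6,
                              mode = c("full_model", "initial_rate"),
                              r1_amide_init = 2) {
  mode <- match.arg(mode)
  stopifnot(all(c("residue", "mixing_time_ms", "intensity", "reference") %in%
                  names(series)))
  min_pts <- if (mode == "full_model") 3 else 2
  out <- series |>
    dplyr::group_by(.data$residue) |>
    dplyr::group_map(function(d, key) {
      if (nrow(d) < min_pts) {
        abort(paste0("residue ", key$residue, ": need >= ", min_pts,
                     " mixing times"))
      }
      tau <- d$mixing_time_ms / 1000
      y <- d$intensity / d$reference
      if (all(d$intensity == 0)) {
        return(tibble(residue = key$residue, k = 0, k_se = 0,
                      r1_amide = NA_real_, flag = "zero_signal"))
      }
      slope0 <- initial_rate_slope(tau, y)
      if (mode == "initial_rate") {
        return(tibble(residue = key$residue, k = max(slope0, 0),
                      k_se = NA_real_, r1_amide = NA_real_,
                      flag = "initial_rate"))
      }
      fit <- tryCatch(
        minpack.lm::nls.lm(
          par = c(k = max(slope0, 0.1), r1_amide = r1_amide_init),
          lower = c(0, 1e-3), upper = c(1e4, 1e3),
          fn = function(par) cleanex_buildup(tau, par[1], par[2],
                                             r1_water) - y,
          control = minpack.lm::nls.lm.control(maxiter = 200,
                                               ftol = 1e-14,
                                               ptol = 1e-14)),
        error = function(e) NULL)
      if (is.null(fit) || !fit$info %in% 1:4) {
        return(tibble(residue = key$residue, k = max(slope0, 0),
                      k_se = NA_real_, r1_amide = NA_real_,
                      flag = "initial_rate_fallback"))
      }
      se <- tryCatch({
        dof <- max(nrow(d) - 2, 1)
        sqrt(diag(solve(fit$hessian) * fit$deviance / dof))
      }, error = function(e) rep(NA_real_, 2))
      tibble(residue = key$residue, k = fit$par[[1]], k_se = se[1],
             r1_amide = fit$par[[2]], flag = "ok")
    }) |>
    dplyr::bind_rows()
  structure(out, class = c("cleanex_fit", class(out)))
}

# slope of I/I0 vs tau through the origin on the earliest points;
# d(I/I0)/dtau at 0 equals k
initial_rate_slope <- function(tau, y) {
  n <- min(3, length(tau))
  o <- order(tau)[seq_len(n)]
  sum(tau[o] * y[o]) / sum(tau[o]^2)
}

#' Solvent-protection analysis upon complex formation
#'
#' Compares per-residue solvent-exchange rates between apo and bound
#' samples.  A residue is flagged protected when its bound rate drops
#' below `fraction_threshold` of the apo rate; residues that exchange in
#' the apo form but are absent from (or silent in) the bound table are
#' flagged `"fully_protected"`.
#'
#' @param apo,bound `cleanex_fit` tables from [fit_exchange_rate()].
#' @param fraction_threshold Protection threshold on `k_bound / k_apo`.
#' @return Tibble with `residue`, `k_apo`, `k_bound`, `delta_k`,
#'   `protection`.
#' @export
protection_analysis <- function(apo, bound, fraction_threshold = 0.5) {
  a <- as_tibble(apo)[, c("residue", "k")]
  b <- as_tibble(bound)[, c("residue", "k", "flag")]
  joined <- dplyr::left_join(a, b, by = "residue",
                             suffix = c("_apo", "_bound"))
  joined |>
    dplyr::mutate(
      k_bound = dplyr::coalesce(.data$k_bound, 0),
      delta_k = .data$k_apo - .data$k_bound,
      protection = dplyr::case_when(
        .data$k_apo > 0 &
          (is.na(.data$flag) | .data$flag == "zero_signal" |
             .data$k_bound == 0) ~ "fully_protected",
        .data$k_apo > 0 &
          .data$k_bound < fraction_threshold * .data$k_apo ~ "protected",
        TRUE ~ "none"
      )
    ) |>
    dplyr::select("residue", "k_apo", "k_bound", "delta_k", "protection")
}

#' Heteronuclear NOE from saturated/unsaturated peak pairs
#'
#' Computes the 15N(1H) heteronuclear NOE per residue as the intensity
#' ratio `I_on / I_off`, with first-order error propagation from the
#' per-spectrum noise floors:
#' `sigma = |value| * sqrt((noise_on / i_on)^2 + (noise_off / i_off)^2)`.
#' Residues with zero off-resonance intensity are excluded with a
#' warning.
#'
#' @param on,off [peak_list()]s from the saturated and reference
#'   experiments.
#' @param noise_on,noise_off Per-spectrum noise floors (intensity
#'   units).
#' @return Tibble with `residue_number`, `i_on`, `i_off`, `value`,
#'   `sigma`.
#' @export
compute_hetnoe <- function(on, off, noise_on = 0, noise_off = 0) {
  a <- as_tibble(on)[, c("residue_number", "height")]
  b <- as_tibble(off)[, c("residue_number", "height")]
  joined <- dplyr::inner_join(a, b, by = "residue_number",
                              suffix = c("_on", "_off"))
  if (nrow(joined) == 0) abort("peak lists share no residues")
  zero_off <- joined$height_off == 0
  if (any(zero_off)) {
    warn(paste0("excluding ", sum(zero_off),
                " residue(s) with zero off-resonance intensity"))
    joined <- joined[!zero_off, ]
  }
  value <- joined$height_on / joined$height_off
  term_on <- if (noise_on == 0) 0 else (noise_on / joined$height_on)^2
  term_off <- if (noise_off == 0) 0 else (noise_off / joined$height_off)^2
  sigma <- abs(value) * sqrt(term_on + term_off)
  tibble(residue_number = joined$residue_number,
         i_on = joined$height_on, i_off = joined$height_off,
         value = value, sigma = sigma)
}
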