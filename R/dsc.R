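# gas constant in kJ mol^-1 K^-1 (enthalpies are kept in kJ/mol)
R_KJ <- 8.314462618e-3

#' Excess heat capacity of an independent van't Hoff transition
#'
#' The non-two-state unfolding model in which the calorimetric enthalpy
#' (peak area) and the van't Hoff enthalpy (peak sharpness) vary
#' independently:
#' `K(T) = exp((dh_vh / R) * (1/T_m - 1/T))` and
#' `Cp(T) = dh_cal * dh_vh * K / (R * T^2 * (1 + K)^2)`
#' with temperatures in Kelvin internally.  At `T = T_m`, `K = 1` and
#' `Cp = dh_cal * dh_vh / (4 R T_m^2)`; the ratio `dh_vh / dh_cal`
#' close to 1 diagnoses two-state unfolding without intermediates.
#'
#' @param temp_c Temperature grid, deg C.
#' @param t_m_c Transition midpoint, deg C.
#' @param dh_cal Calorimetric enthalpy, kJ/mol.
#' @param dh_vh van't Hoff enthalpy, kJ/mol.
#' @return Excess Cp, kJ mol^-1 K^-1.
#' @export
model_cp <- function(temp_c, t_m_c, dh_cal, dh_vh) {
  if (dh_cal <= 0 || dh_vh <= 0) abort("enthalpies must be > 0")
  t_k <- temp_c + 273.15
  t_m_k <- t_m_c + 273.15
  K <- exp(dh_vh / R_KJ * (1 / t_m_k - 1 / t_k))
  dh_cal * dh_vh * K / (R_KJ * t_k^2 * (1 + K)^2)
}

#' Fit a DSC endotherm
#'
#' Least-squares fit of the independent van't Hoff transition model
#' ([model_cp()]) to a baseline-corrected endotherm, with `T_m`,
#' calorimetric and van't Hoff enthalpies free.  With
#' `baseline = "progress"` the intrinsic protein baseline is first
#' removed by iterating a sigmoidal interpolation between linear pre-
#' and post-transition baselines (fitted on the outer 15\% of the grid),
#' weighted by the fractional unfolding from the running integral, until
#' the correction changes by less than 1e-6 (at most 10 iterations).
#'
#' @param data Data frame with `temp_c` and `cp` columns.
#' @param baseline `"none"` (data already baseline-corrected) or
#'   `"progress"`.
#' @param edge_fraction Fraction of the grid on each side used for the
#'   pre/post-transition baselines.
#' @return A `dsc_fit` object with `t_m_c`, `dh_cal`, `dh_vh`, standard
#'   errors, the enthalpy ratio and the corrected trace.
#' @export
fit_endotherm <- function(data, baseline = c("none", "progress"),
                          edge_fraction = 0.15) {
  baseline <- match.arg(baseline)
  stopifnot(all(c("temp_c", "cp") %in% names(data)))
  d <- dplyr::arrange(as_tibble(data), .data$temp_c)
  if (multi_peaked(d$cp)) {
    abort("endotherm appears multi-peaked; restrict the temperature range to one transition")
  }
  cp <- d$cp
  if (baseline == "progress") {
    cp <- progress_baseline(d$temp_c, d$cp, edge_fraction)
  }
  t_c <- d$temp_c
  tm0 <- t_c[which.max(cp)]
  area <- trapz(t_c, cp)
  if (area <= 0) abort("endotherm has non-positive area")
  dhvh0 <- max(4 * R_KJ * (tm0 + 273.15)^2 * max(cp) / area, 10)
  fit <- minpack.lm::nls.lm(
    par = c(t_m_c = tm0, dh_cal = area, dh_vh = dhvh0),
    lower = c(min(t_c), 1, 1), upper = c(max(t_c), 1e5, 1e5),
    fn = function(par) model_cp(t_c, par[1], par[2], par[3]) - cp,
    control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-14,
                                         ptol = 1e-14))
  if (!fit$info %in% 1:4) {
    abort(paste0("endotherm fit did not converge: ", fit$message))
  }
  se <- tryCatch({
    dof <- max(length(t_c) - 3, 1)
    sqrt(diag(solve(fit$hessian) * fit$deviance / dof))
  }, error = function(e) rep(NA_real_, 3))
  structure(list(
    t_m_c = fit$par[[1]], dh_cal = fit$par[[2]], dh_vh = fit$par[[3]],
    t_m_se = se[1], dh_cal_se = se[2], dh_vh_se = se[3],
    vh_cal_ratio = fit$par[[3]] / fit$par[[2]],
    residual_norm = sqrt(fit$deviance),
    corrected = tibble(temp_c = t_c, cp = cp),
    baseline = baseline
  ), class = "dsc_fit")
}

multi_peaked <- function(cp, min_height = 0.3, min_dip = 0.5) {
  # two peaks count as separate only when both exceed min_height of the
  # global maximum and the valley between them drops below min_dip of
  # the smaller one
  n <- length(cp)
  if (n < 11) return(FALSE)
  w <- max(5, round(n / 50))
  sm <- as.numeric(stats::filter(cp, rep(1 / w, w), sides = 2))
  sm[is.na(sm)] <- cp[is.na(sm)]
  peak <- max(sm)
  cand <- which(diff(sign(diff(sm))) == -2) + 1
  cand <- cand[sm[cand] > min_height * peak]
  if (length(cand) < 2) return(FALSE)
  cand <- cand[order(-sm[cand])]
  kept <- cand[1]
  for (i in cand[-1]) {
    seps <- vapply(kept, function(j)
      min(sm[seq(min(i, j), max(i, j))]), numeric(1))
    if (all(seps < min_dip * sm[i])) kept <- c(kept, i)
  }
  length(kept) > 1
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

progress_baseline <- function(t_c, cp, edge_fraction) {
  n <- length(t_c)
  k <- max(3, round(edge_fraction * n))
  pre_idx <- seq_len(k)
  post_idx <- seq(n - k + 1, n)
  pre <- stats::lm(cp[pre_idx] ~ t_c[pre_idx])
  post <- stats::lm(cp[post_idx] ~ t_c[post_idx])
  pre_line <- coef(pre)[1] + coef(pre)[2] * t_c
  post_line <- coef(post)[1] + coef(post)[2] * t_c
  corrected <- cp
  for (i in seq_len(10)) {
    cum <- cumsum(c(0, diff(t_c) * (head(corrected, -1) +
                                      tail(corrected, -1)) / 2))
    alpha <- cum / cum[n]
    base <- (1 - alpha) * pre_line + alpha * post_line
    new_corrected <- cp - base
    delta <- max(abs(new_corrected - corrected)) /
      max(abs(corrected), 1e-12)
    corrected <- new_corrected
    if (delta < 1e-6) break
  }
  corrected
}

#' @export
#' @method print dsc_fit
print.dsc_fit <- function(x, ...) {
  cat(sprintf(
    "DSC fit: T_m = %.2f degC, dH_cal = %.1f kJ/mol, dH_vH = %.1f kJ/mol (ratio %.3f)\n",
    x$t_m_c, x$dh_cal, x$dh_vh, x$vh_cal_ratio))
  invisible(x)
}

#' @rdname fit_endotherm
#' @param x A `dsc_fit`.
#' @param ... Unused.
#' @export
tidy.dsc_fit <- function(x, ...) {
  tibble(term = c("t_m_c", "dh_cal", "dh_vh"),
         estimate = c(x$t_m_c, x$dh_cal, x$dh_vh),
         std.error = c(x$t_m_se, x$dh_cal_se, x$dh_vh_se))
}

#' @rdname fit_endotherm
#' @export
glance.dsc_fit <- function(x, ...) {
  tibble(t_m_c = x$t_m_c, dh_cal = x$dh_cal, dh_vh = x$dh_vh,
         vh_cal_ratio = x$vh_cal_ratio, residual_norm = x$residual_norm,
         baseline = x$baseline)
}
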