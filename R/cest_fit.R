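#' Global two-state fit of CEST profiles
#'
#' Fits all residues and B1 fields of a CEST dataset simultaneously with
#' the two-state Bloch-McConnell model: the minor-state occupancy
#' `p_minor` and exchange rate `k_ex` are global, the 15N shift
#' difference `delta_shift_n` is per residue, and relaxation rates are
#' shared across residues (`r1` shared between states, `r2` per state).
#' Major-state shifts are taken as known from the peak list and held
#' fixed.
#'
#' Initialisation is two-staged.  A per-residue brute-force scan over
#' occupancy, exchange rate and signed shift difference (evaluated on a
#' thinned copy of the data) seeds `delta_shift_n` for every residue; a
#' coarse grid search over the global occupancy and exchange rate then
#' ranks candidate starts for the Levenberg-Marquardt refinement.  The
#' objective has a strong spurious attractor at full minor-state
#' occupancy which the scan stage avoids.  The first start whose
#' residual reaches the estimated noise floor short-circuits the rest.
#' Approximate standard errors come from the residual curvature at the
#' optimum.
#'
#' @param data A `cest_dataset` from [simulate_cest_dataset()], or any
#'   data frame with columns `residue`, `b1_hz`, `offset_ppm`,
#'   `i_over_i0` (plus optional `sigma`).
#' @param residues Residue table with `residue` and `shift_major_n`;
#'   defaults to the dataset attribute.
#' @param scheme A [cest_scheme()]; defaults to the dataset attribute.
#' @param larmor_mhz 15N Larmor frequency (MHz); defaults to the dataset
#'   attribute.
#' @param p_grid,kex_grid Candidate grids for the coarse start search.
#' @param n_starts Number of top-ranked grid candidates refined by
#'   Levenberg-Marquardt.
#' @param r1_init,r2_major_init,r2_minor_init Relaxation starting
#'   values, s^-1; by default `r1` is seeded from the off-resonance
#'   baseline level (`I/I0 ~ exp(-r1 t_ex)` far from both dips).
#' @param max_iter Maximum Levenberg-Marquardt iterations per start.
#' @return A `cest_fit` object; see [tidy.cest_fit()] and
#'   [glance.cest_fit()].
#' @export
fit_cest <- function(data, residues = attr(data, "residues"),
                     scheme = attr(data, "scheme"),
                     larmor_mhz = attr(data, "larmor_n_mhz"),
                     p_grid = c(0.002, 0.005, 0.01, 0.02, 0.05, 0.1, 0.2,
                                0.35, 0.5, 0.65, 0.8, 0.9, 0.95, 0.98,
                                0.99, 0.995),
                     kex_grid = c(20, 30, 45, 65, 90, 120, 170, 240, 300),
                     n_starts = 3,
                     r1_init = NULL, r2_major_init = 8, r2_minor_init = 8,
                     max_iter = 200) {
  df <- as_tibble(data)
  stopifnot(all(c("residue", "b1_hz", "offset_ppm", "i_over_i0") %in%
                  names(df)))
  if (is.null(residues)) abort("supply a residue table with shift_major_n")
  if (is.null(larmor_mhz)) abort("supply the 15N Larmor frequency")
  res_ids <- sort(unique(df$residue))
  n_res <- length(res_ids)
  shift_major <- setNames(residues$shift_major_n, residues$residue)
  if (!all(as.character(res_ids) %in% names(shift_major))) {
    abort("residue table does not cover all residues in the data")
  }
  t_ex <- if (!is.null(scheme)) scheme$t_ex else 0.4

  df <- dplyr::arrange(df, .data$residue, .data$b1_hz, .data$offset_ppm)
  by_res <- split(df, df$residue)[as.character(res_ids)]
  b1 <- sort(unique(df$b1_hz))
  offsets <- sort(unique(df$offset_ppm))
  obs <- lapply(by_res, function(d) d$i_over_i0)
  wts <- lapply(by_res, function(d) {
    if ("sigma" %in% names(d) && all(is.finite(d$sigma)) &&
        all(d$sigma > 0)) 1 / d$sigma else rep(1, nrow(d))
  })
  if (min(offsets) > min(shift_major[as.character(res_ids)]) ||
      max(offsets) < max(shift_major[as.character(res_ids)])) {
    warn("offset grid may not cover all major-state resonances")
  }

  # robust noise floor from point-to-point differences, excluding the
  # dips themselves via the median absolute deviation
  sigma_hat <- stats::median(vapply(
    split(df, interaction(df$residue, df$b1_hz, drop = TRUE)),
    function(d) stats::mad(diff(d$i_over_i0)) / sqrt(2), numeric(1)))
  sigma_hat <- max(sigma_hat, 1e-8)

  # the far-off-resonance plateau decays as exp(-r1 * t_ex); seed r1
  # from the upper decile of the profiles unless given explicitly
  if (is.null(r1_init)) {
    plateau <- stats::median(vapply(obs, function(o)
      stats::quantile(o, 0.9, names = FALSE), numeric(1)))
    r1_init <- min(max(-log(min(max(plateau, 1e-3), 0.999)) / t_ex, 0.2), 8)
  }

  # Per-residue brute-force scan: for each residue, evaluate the
  # single-residue model over a coarse occupancy x exchange-rate x
  # shift-difference grid on thinned data.  The shift-difference
  # minimising the residual seeds the global fit; dip detection alone is
  # not robust once intensity noise approaches the minor-dip depth.
  b1_thin_idx <- unique(c(1L, length(b1)))
  off_thin <- seq(1L, length(offsets), by = 2L)
  obs_thin <- lapply(obs, function(o) {
    m <- matrix(o, nrow = length(offsets))
    as.vector(m[off_thin, b1_thin_idx])
  })
  dw_scan <- c(seq(-4.5, -0.4, by = 0.25), seq(0.4, 4.5, by = 0.25))
  p_scan <- c(0.005, 0.02, 0.05, 0.15, 0.4, 0.7, 0.95, 0.99)
  kex_scan <- c(25, 60, 120, 250)
  scan <- purrr::map_dfr(seq_len(n_res), function(i) {
    sA <- shift_major[[as.character(res_ids[i])]]
    # score away from the major resonance so that mismatch in the
    # (still uncalibrated) relaxation rates around the deep major dip
    # cannot drown out the shallow minor dip
    mask <- rep(abs(offsets[off_thin] - sA) > 0.7, length(b1_thin_idx))
    if (sum(mask) < 10) mask <- rep(TRUE, length(mask))
    y <- obs_thin[[i]][mask]
    best_i <- NULL
    for (p0 in p_scan) for (k0 in kex_scan) for (d0 in dw_scan) {
      prof <- bm_profile_cpp(p0, k0, sA, d0, r1_init, r2_major_init,
                             r2_minor_init, larmor_mhz, b1[b1_thin_idx],
                             offsets[off_thin], t_ex)
      ssr <- sum((as.vector(prof)[mask] - y)^2)
      if (is.null(best_i) || ssr < best_i$ssr) {
        best_i <- list(p = p0, kex = k0, dw = d0, ssr = ssr)
      }
    }
    tibble(residue = res_ids[i], p = best_i$p, kex = best_i$kex,
           dw = best_i$dw)
  })
  init <- scan[, c("residue", "dw")]

  lower <- c(1e-7, 0.5, rep(-12, n_res), 0.05, 0.2, 0.2)
  upper <- c(1 - 1e-7, 3000, rep(12, n_res), 20, 200, 400)
  w_all <- unlist(wts)
  make_resid <- function(b1_use, off_use, obs_use, w_use) {
    function(par) {
      p <- par[1]; kex <- par[2]
      dw <- par[3:(2 + n_res)]
      r1 <- par[3 + n_res]; r2a <- par[4 + n_res]; r2b <- par[5 + n_res]
      r <- unlist(lapply(seq_len(n_res), function(i) {
        prof <- bm_profile_cpp(p, kex,
                               shift_major[[as.character(res_ids[i])]],
                               dw[i], r1, r2a, r2b, larmor_mhz,
                               b1_use, offsets[off_use], t_ex)
        as.vector(prof) - obs_use[[i]]
      }))
      r * w_use
    }
  }
  resid_fun <- make_resid(b1, seq_along(offsets), obs,
                          w_all)

  # coarse grid over the global parameters on thinned data; the spurious
  # p -> 1 attractor loses to the true basin at this resolution
  resid_thin <- make_resid(b1[b1_thin_idx], off_thin, obs_thin,
                           rep(1, length(off_thin) * length(b1_thin_idx) *
                                 n_res))
  grid <- tidyr::expand_grid(p = p_grid, kex = kex_grid)
  grid$ssr <- vapply(seq_len(nrow(grid)), function(i) {
    sum(resid_thin(c(grid$p[i], grid$kex[i], init$dw, r1_init,
                     r2_major_init, r2_minor_init))^2)
  }, numeric(1))
  grid <- grid[order(grid$ssr), ]
  cand <- utils::head(grid[!duplicated(grid$p), ], n_starts)

  starts <- list(c(stats::median(scan$p), stats::median(scan$kex),
                   init$dw, r1_init, r2_major_init, r2_minor_init))
  for (i in seq_len(nrow(cand))) {
    starts[[length(starts) + 1]] <-
      c(cand$p[i], cand$kex[i], init$dw, r1_init, r2_major_init,
        r2_minor_init)
  }

  ctrl <- minpack.lm::nls.lm.control(maxiter = max_iter, ftol = 1e-11,
                                     ptol = 1e-11,
                                     maxfev = 600 * (n_res + 6))
  n_obs <- length(w_all)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                         fn = resid_fun, control = ctrl),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
    if (sqrt(best$deviance / n_obs) <= max(1e-8, sigma_hat) &&
        best$par[1] > lower[1] * 1.01) break
  }
  if (is.null(best)) {
    abort("CEST fit failed to converge from any start")
  }
  at_noise_floor <- sqrt(best$deviance / n_obs) <= 2 * max(sigma_hat, 1e-8)
  if (!best$info %in% 1:4 && !at_noise_floor) {
    abort(paste0("CEST fit did not converge (best residual norm ",
                 signif(sqrt(best$deviance), 4), "): ", best$message))
  }

  par <- best$par
  np <- length(par)
  se <- rep(NA_real_, np)
  dof <- max(n_obs - np, 1)
  cov_try <- tryCatch(solve(best$hessian) * best$deviance / dof,
                      error = function(e) NULL)
  if (!is.null(cov_try)) {
    d <- diag(cov_try)
    se <- ifelse(d > 0, sqrt(d), 0)
  }
  at_bound <- par[1] <= lower[1] * 1.01 || par[1] >= 1 - 1e-6

  structure(list(
    p_minor = par[1], p_minor_se = se[1],
    k_ex = par[2], k_ex_se = se[2],
    residues = tibble(
      residue = res_ids,
      shift_major_n = unname(shift_major[as.character(res_ids)]),
      delta_shift_n = par[3:(2 + n_res)],
      se = se[3:(2 + n_res)]
    ),
    r1 = par[3 + n_res], r2_major = par[4 + n_res],
    r2_minor = par[5 + n_res],
    residual_norm = sqrt(best$deviance),
    convergence = best$info, message = best$message,
    n_residues_fit = n_res, n_points = n_obs,
    p_at_bound = at_bound,
    b1_fields_hz = b1, offsets_ppm = offsets, t_ex = t_ex,
    larmor_n_mhz = larmor_mhz
  ), class = "cest_fit")
}

#' @export
#' @method print cest_fit
print.cest_fit <- function(x, ...) {
  cat(sprintf(
    "Two-state CEST fit: p_minor = %.4g +/- %.2g (%.3g%%), k_ex = %.4g +/- %.2g /s\n",
    x$p_minor, x$p_minor_se, 100 * x$p_minor, x$k_ex, x$k_ex_se))
  cat(sprintf("  %d residue(s), %d points, residual norm %.3g%s\n",
              x$n_residues_fit, x$n_points, x$residual_norm,
              if (x$p_at_bound) " [p_minor at bound]" else ""))
  invisible(x)
}

#' Tidy per-residue CEST fit results
#'
#' @param x A `cest_fit`.
#' @param ... Unused.
#' @return Tibble with one row per residue: fitted minor-state 15N shift
#'   difference and its standard error.
#' @export
tidy.cest_fit <- function(x, ...) {
  dplyr::rename(x$residues, estimate = "delta_shift_n", std.error = "se")
}

#' One-row summary of a CEST fit
#'
#' @param x A `cest_fit`.
#' @param ... Unused.
#' @return One-row tibble with the global parameters and diagnostics.
#' @export
glance.cest_fit <- function(x, ...) {
  tibble(p_minor = x$p_minor, p_minor_se = x$p_minor_se,
         k_ex = x$k_ex, k_ex_se = x$k_ex_se,
         r1 = x$r1, r2_major = x$r2_major, r2_minor = x$r2_minor,
         residual_norm = x$residual_norm, n_residues = x$n_residues_fit,
         n_points = x$n_points, converged = x$convergence %in% 1:4,
         p_at_bound = x$p_at_bound)
}

#' Model profiles from a fitted CEST model
#'
#' Evaluates the fitted two-state model on the fitted grid, for overlay
#' plots and residual checks.
#'
#' @param object A `cest_fit`.
#' @param ... Unused.
#' @return Tibble with `residue`, `b1_hz`, `offset_ppm`, `fitted`.
#' @export
fitted_cest_profiles <- function(object, ...) {
  purrr::map_dfr(seq_len(nrow(object$residues)), function(i) {
    r <- object$residues[i, ]
    prof <- bm_profile_cpp(object$p_minor, object$k_ex, r$shift_major_n,
                           r$delta_shift_n, object$r1, object$r2_major,
                           object$r2_minor, object$larmor_n_mhz,
                           object$b1_fields_hz, object$offsets_ppm,
                           object$t_ex)
    tidyr::expand_grid(b1_hz = object$b1_fields_hz,
                       offset_ppm = object$offsets_ppm) |>
      dplyr::mutate(residue = r$residue, fitted = as.vector(prof),
                    .before = 1)
  })
}
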