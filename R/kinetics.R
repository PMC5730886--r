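#' Normalise a phosphorylation time course
#'
#' Anchors each resonance's trace to single-spectrum references:
#' disappearing (substrate) peaks are divided by their first-time-point
#' height (no conversion yet, trace starts at 1), appearing (product)
#' peaks by their last-time-point height (full conversion, trace ends
#' at 1).  The per-residue fraction phosphorylated is the appearing
#' value, or `1 - disappearing`, averaged when both species are
#' monitored.  Residues with a zero anchor are excluded with a warning.
#' An optional plateau-average anchor (mean of the last `plateau_n`
#' points for appearing, first `plateau_n` for disappearing) trades the
#' single-spectrum rule for lower anchor noise.
#'
#' @param raw Data frame with `residue`, `species`
#'   (`"disappearing"`/`"appearing"`), `time_min`, `height`.
#' @param anchor `"single"` (first/last spectrum, the default rule) or
#'   `"plateau"` (average of `plateau_n` edge points).
#' @param plateau_n Number of edge points averaged when
#'   `anchor = "plateau"`.
#' @return Tibble like `raw` plus `norm_height` and `fraction`
#'   (fraction phosphorylated).
#' @export
normalize_timecourse <- function(raw, anchor = c("single", "plateau"),
                                 plateau_n = 3) {
  anchor <- match.arg(anchor)
  stopifnot(all(c("residue", "species", "time_min", "height") %in%
                  names(raw)))
  if (dplyr::n_distinct(raw$time_min) < 3) {
    abort("need at least 3 time points")
  }
  normed <- raw |>
    dplyr::group_by(.data$residue, .data$species) |>
    dplyr::arrange(.data$time_min, .by_group = TRUE) |>
    dplyr::mutate(
      anchor_height = {
        n <- dplyr::n()
        idx <- if (.data$species[1] == "disappearing") {
          if (anchor == "single") 1L else seq_len(min(plateau_n, n))
        } else {
          if (anchor == "single") n else seq(max(1L, n - plateau_n + 1L), n)
        }
        mean(.data$height[idx])
      },
      norm_height = .data$height / .data$anchor_height,
      fraction = dplyr::if_else(.data$species == "disappearing",
                                1 - .data$norm_height, .data$norm_height)
    ) |>
    dplyr::ungroup()
  bad <- unique(normed$residue[!is.finite(normed$norm_height)])
  if (length(bad) > 0) {
    warn(paste0("excluding residue(s) with zero anchor height: ",
                paste(bad, collapse = ", ")))
    normed <- normed[!normed$residue %in% bad, ]
  }
  dplyr::select(normed, -"anchor_height")
}

#' Aggregate per-residue fractions into a progress curve
#'
#' Averages the fraction phosphorylated across resonances at each time
#' point (residues with both species contribute their per-residue mean),
#' with the standard deviation across resonances as the spread.
#'
#' @param normalized Output of [normalize_timecourse()].
#' @param min_resonances Minimum number of resonances required.
#' @return A `progress_curve` tibble: `time_min`, `fraction`, `sd`, `n`.
#' @export
aggregate_progress <- function(normalized, min_resonances = 9) {
  per_res <- normalized |>
    dplyr::group_by(.data$residue, .data$time_min) |>
    dplyr::summarise(fraction = mean(.data$fraction), .groups = "drop")
  n_res <- dplyr::n_distinct(per_res$residue)
  if (n_res < min_resonances) {
    abort(paste0("only ", n_res, " resonance(s) available; need >= ",
                 min_resonances))
  }
  curve <- per_res |>
    dplyr::group_by(.data$time_min) |>
    dplyr::summarise(
      # population standard deviation across resonances
      sd = sqrt(mean((.data$fraction - mean(.data$fraction))^2)),
      fraction = mean(.data$fraction),
      n = dplyr::n(), .groups = "drop") |>
    dplyr::select("time_min", "fraction", "sd", "n")
  structure(curve, n_resonances = n_res,
            class = c("progress_curve", class(curve)))
}

#' Spectrum time stamps from acquisition increments
#'
#' Serial spectra integrate signal over their acquisition increment; by
#' default each spectrum is stamped at the midpoint of its increment,
#' configurable to the increment start.
#'
#' @param n_steps Number of spectra.
#' @param t_step Increment length, min.
#' @param stamp `"midpoint"` or `"start"`.
#' @return Numeric vector of time stamps, min.
#' @export
increment_times <- function(n_steps, t_step, stamp = c("midpoint", "start")) {
  stamp <- match.arg(stamp)
  start <- (seq_len(n_steps) - 1) * t_step
  if (stamp == "midpoint") start + t_step / 2 else start
}

#' First-order rate fit of a progress curve
#'
#' Weighted least squares of `fraction(t) = 1 - exp(-k * t)` (weights
#' `1/sd^2` where available), reporting `t50 = ln(2) / k` alongside a
#' model-free half-time from linear interpolation of the 50\% crossing
#' as a cross-check against model misfit.
#'
#' @param curve A `progress_curve` from [aggregate_progress()] (any data
#'   frame with `time_min` and `fraction` works; `sd` used as weights
#'   when present and positive).
#' @return A `rate_fit` object with `k_phos`, `k_se`, `t50`,
#'   `t50_interp`, `model`.
#' @export
fit_rate <- function(curve) {
  stopifnot(all(c("time_min", "fraction") %in% names(curve)))
  t <- curve$time_min
  y <- curve$fraction
  w <- if ("sd" %in% names(curve) && all(is.finite(curve$sd)) &&
           all(curve$sd > 0)) 1 / curve$sd^2 else rep(1, length(t))
  t50_interp <- interp_crossing(t, y, 0.5)
  crosses <- !is.na(t50_interp)
  k0 <- if (crosses) log(2) / t50_interp else
    max(-coef(stats::lm(log(pmax(1 - y, 1e-6)) ~ t + 0))[[1]], 1e-4)
  fit <- minpack.lm::nls.lm(
    par = c(k = k0), lower = 1e-8, upper = 1e4,
    fn = function(par) sqrt(w) * (1 - exp(-par[1] * t) - y),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14))
  if (!fit$info %in% 1:4 && !crosses) {
    abort("no 50% crossing and the exponential fit failed; acquire a longer time course")
  }
  if (!crosses) {
    warn("curve does not span the 50% crossing; t50 is a model extrapolation")
  }
  k <- fit$par[[1]]
  se <- tryCatch(sqrt(solve(fit$hessian)[1, 1] * fit$deviance /
                        max(length(t) - 1, 1)),
                 error = function(e) NA_real_)
  structure(list(k_phos = k, k_se = se, t50 = log(2) / k,
                 t50_interp = t50_interp,
                 model = "first_order", extrapolated = !crosses,
                 residual_norm = sqrt(fit$deviance), n_times = length(t)),
            class = "rate_fit")
}

interp_crossing <- function(t, y, level) {
  o <- order(t)
  t <- t[o]; y <- y[o]
  i <- which(y >= level)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1) return(t[1])
  t[i - 1] + (level - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
}

#' @export
#' @method print rate_fit
print.rate_fit <- function(x, ...) {
  cat(sprintf(
    "First-order phosphorylation fit: k = %.4g /min, t50 = %.4g min (interpolated %.4g min)\n",
    x$k_phos, x$t50, x$t50_interp))
  invisible(x)
}

#' @rdname fit_rate
#' @param x A `rate_fit`.
#' @param ... Unused.
#' @export
tidy.rate_fit <- function(x, ...) {
  tibble(term = "k_phos", estimate = x$k_phos, std.error = x$k_se)
}

#' @rdname fit_rate
#' @export
glance.rate_fit <- function(x, ...) {
  tibble(k_phos = x$k_phos, k_se = x$k_se, t50 = x$t50,
         t50_interp = x$t50_interp, extrapolated = x$extrapolated,
         residual_norm = x$residual_norm, n_times = x$n_times)
}

#' Fold-acceleration between two phosphorylation rates
#'
#' Ratio of half-times `t50_slow / t50_fast`, equal to `k_fast / k_slow`
#' under the first-order model.  `fold_acceleration(a, b) *
#' fold_acceleration(b, a) = 1`.
#'
#' @param fast,slow `rate_fit` objects (or lists with a `t50` element).
#' @return Dimensionless fold-acceleration.
#' @export
fold_acceleration <- function(fast, slow) {
  if (fast$t50 <= 0 || slow$t50 <= 0) abort("half-times must be positive")
  slow$t50 / fast$t50
}
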