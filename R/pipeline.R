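#' Run the simulate-and-fit pipeline from a configuration
#'
#' Orchestrates every stage present in the configuration in dependency
#' order (simulate, then fit), writes per-stage tables and summaries
#' under `output_dir` via [write_results()], and returns a run manifest
#' of output files with checksums.  The same configuration and seed
#' always yield identical checksums; stages never mutate each other's
#' inputs, so reruns are idempotent.
#'
#' Recognised stage blocks (all optional):
#'
#' * `cest`: `preset`, `n_residues`, `b1_fields_hz`, `offsets`
#'   (`from`/`to`/`n`), `t_ex`, `noise` (`sigma_fraction`), `fit`
#' * `cleanex`: `k` (vector), `r1_amide`, `r1_water`, `noise`, `fit`
#' * `kinetics`: `preset` (or `t50_min`), `n_resonances`, `n_steps`,
#'   `t_step_min`, `noise`, `min_resonances`, `fit`
#' * `dsc`: `preset` (or `t_m_c`/`dh_cal`/`dh_vh`), `noise`, `fit`
#'
#' @param config A configuration list (see [read_config()]) or the path
#'   to a YAML file.
#' @param output_dir Output directory; overrides `config$output_dir`.
#' @return A `run_manifest` tibble (`stage`, `file`, `md5`) with the
#'   config snapshot and seed attached as attributes.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- if (is.character(config)) read_config(config)
         else validate_config(config)
  out_dir <- output_dir %||% cfg$output_dir %||%
    abort("no output directory given")
  seed <- as.integer(cfg$seed)
  manifest <- list()
  stage_noise <- function(block, default_seed) {
    nz <- block$noise
    if (is.null(nz)) return(noise_model("none"))
    noise_model(nz$kind %||% "gaussian",
                sigma_fraction = nz$sigma_fraction %||% 0,
                seed = as.integer(nz$seed %||% default_seed))
  }

  if (!is.null(cfg$cest)) {
    b <- cfg$cest
    offs <- if (!is.null(b$offsets)) {
      seq(b$offsets$from, b$offsets$to, length.out = b$offsets$n)
    } else seq(102, 134, length.out = 184)
    scheme <- cest_scheme(b1_fields_hz = b$b1_fields_hz %||%
                            c(12.5, 20, 25, 37.5, 50),
                          offsets_ppm = offs, t_ex = b$t_ex %||% 0.4)
    ds <- simulate_cest_from_preset(
      b$preset %||% "wt_ub_45C", n_residues = b$n_residues %||% 7,
      seed = seed, scheme = scheme,
      spectrometer_h_mhz = cfg$spectrometer_h_mhz,
      noise = stage_noise(b, seed + 101L))
    results <- list(cest_profiles = as_tibble(ds))
    if (isTRUE(b$fit)) {
      fit <- fit_cest(ds)
      results$cest_fit <- tidy(fit)
      results$cest_global <- as.list(glance(fit))
    }
    manifest$cest <- write_results(results, file.path(out_dir, "cest"))
  }

  if (!is.null(cfg$cleanex)) {
    b <- cfg$cleanex
    series <- simulate_cleanex_series(
      k = unlist(b$k %||% c(5, 2, 0.5)),
      r1_amide = b$r1_amide %||% 2, r1_water = b$r1_water %||% 0.6,
      noise = stage_noise(b, seed + 202L))
    results <- list(cleanex_series = series)
    if (isTRUE(b$fit)) {
      results$cleanex_fit <- as_tibble(
        fit_exchange_rate(series, r1_water = b$r1_water %||% 0.6))
    }
    manifest$cleanex <- write_results(results, file.path(out_dir, "cleanex"))
  }

  if (!is.null(cfg$kinetics)) {
    b <- cfg$kinetics
    t50 <- b$t50_min %||% get_preset(b$preset %||% "phospho_tvln")$t50_min
    t_step <- b$t_step_min %||%
      get_preset(b$preset %||% "phospho_tvln")$t_step_min
    tc <- simulate_phospho_timecourse(
      k_phos = log(2) / t50, t_step = t_step,
      n_steps = b$n_steps %||% 16,
      n_resonances = b$n_resonances %||% 9,
      noise = stage_noise(b, seed + 303L))
    results <- list(timecourse = tc)
    if (isTRUE(b$fit)) {
      curve <- tc |> normalize_timecourse() |>
        aggregate_progress(min_resonances = b$min_resonances %||% 9)
      results$progress_curve <- as_tibble(curve)
      results$rate <- as.list(glance(fit_rate(curve)))
    }
    manifest$kinetics <- write_results(results,
                                       file.path(out_dir, "kinetics"))
  }

  if (!is.null(cfg$dsc)) {
    b <- cfg$dsc
    p <- if (!is.null(b$preset)) get_preset(b$preset) else
      list(t_m_c = b$t_m_c, dh_cal = b$dh_cal %||% 300,
           dh_vh = b$dh_vh %||% 300)
    endo <- simulate_dsc_endotherm(
      t_m_c = p$t_m_c, dh_cal = p$dh_cal, dh_vh = p$dh_vh,
      noise = stage_noise(b, seed + 404L))
    results <- list(endotherm = endo)
    if (isTRUE(b$fit)) {
      results$dsc_fit <- as.list(glance(fit_endotherm(endo))[
        , c("t_m_c", "dh_cal", "dh_vh", "vh_cal_ratio")])
    }
    manifest$dsc <- write_results(results, file.path(out_dir, "dsc"))
  }

  if (length(manifest) == 0) abort("config contains no stage blocks")
  out <- dplyr::bind_rows(
    purrr::imap(manifest, function(m, nm) dplyr::mutate(m, stage = nm,
                                                        .before = 1)))
  structure(out, config = cfg, seed = seed,
            class = c("run_manifest", class(out)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Configuration replaying the packaged study conditions
#'
#' Returns the configuration list for an end-to-end run over the
#' packaged presets: a noiseless CEST simulate-and-fit block, a CLEANEX
#' block at the standard six mixing times, a noisy nine-resonance
#' phosphorylation time course, and a DSC block.  Pass it (optionally
#' modified) to [run_pipeline()].
#'
#' @param seed Integer seed used by every stochastic stage.
#' @param cest_preset,kinetics_preset,dsc_preset Preset names.
#' @return A configuration list.
#' @export
replay_config <- function(seed = 1, cest_preset = "wt_ub_45C",
                          kinetics_preset = "phospho_tvln",
                          dsc_preset = "dsc_l67s_tvln") {
  list(
    spectrometer_h_mhz = 950,
    seed = seed,
    cest = list(preset = cest_preset, n_residues = 7, fit = TRUE),
    cleanex = list(k = c(5, 2, 0.5), fit = TRUE),
    kinetics = list(preset = kinetics_preset, n_resonances = 9,
                    n_steps = 16,
                    noise = list(kind = "gaussian", sigma_fraction = 0.05),
                    fit = TRUE),
    dsc = list(preset = dsc_preset, fit = TRUE)
  )
}
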