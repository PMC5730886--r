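#' Packaged ubiquitin study presets
#'
#' The generator presets bundle the fitted quantities for wild-type
#' ubiquitin and its conformer-shifting point mutants, grouped by assay:
#'
#' * `kind == "cest"` -- two-state exchange between the common and the
#'   C-terminally retracted (Ub-CR) conformation: minor-state occupancy
#'   `p_minor` and exchange rate `k_ex` (s^-1) at the stated temperature.
#' * `kind == "kinetics"` -- first-order Ser65-phosphorylation half-times
#'   `t50_min` (min) under a fixed kinase regime, with the acquisition
#'   increment `t_step_min` used for the corresponding time course.
#' * `kind == "dsc"` -- thermal unfolding midpoint `t_m_c` (deg C) with
#'   calorimetric and van't Hoff enthalpies (kJ/mol).  The enthalpies are
#'   set equal (two-state unfolding, consistent with the absence of
#'   intermediates) at a value typical for ubiquitin-fold proteins.
#'
#' @return A tibble with columns `name`, `kind`, `temperature_c` and the
#'   assay-specific parameter columns (`NA` where not applicable).
#' @examples
#' ub_presets()
#' get_preset("wt_ub_45C")
#' @export
ub_presets <- function() {
  dplyr::bind_rows(
    tibble(name = "wt_ub_45C",  kind = "cest", temperature_c = 45,
           p_minor = 0.0068, k_ex = 63),
    tibble(name = "tvln_45C",   kind = "cest", temperature_c = 45,
           p_minor = 0.99,   k_ex = 120),
    tibble(name = "f4a_45C",    kind = "cest", temperature_c = 45,
           p_minor = 0.045,  k_ex = 83),
    tibble(name = "f4a_25C",    kind = "cest", temperature_c = 25,
           p_minor = 0.013,  k_ex = 46),
    tibble(name = "phospho_wt", kind = "kinetics", temperature_c = 25,
           t50_min = 90,  t_step_min = 8),
    tibble(name = "phospho_l71y", kind = "kinetics", temperature_c = 25,
           t50_min = 275, t_step_min = 8),
    tibble(name = "phospho_f4a",  kind = "kinetics", temperature_c = 25,
           t50_min = 5,   t_step_min = 4),
    tibble(name = "phospho_tvln", kind = "kinetics", temperature_c = 25,
           t50_min = 2,   t_step_min = 4),
    tibble(name = "phospho_ubl",  kind = "kinetics", temperature_c = 25,
           t50_min = 2,   t_step_min = 4),
    tibble(name = "dsc_wt",        kind = "dsc", t_m_c = 97,
           dh_cal = 300, dh_vh = 300),
    tibble(name = "dsc_phospho_wt", kind = "dsc", t_m_c = 87,
           dh_cal = 300, dh_vh = 300),
    tibble(name = "dsc_l67s_tvln", kind = "dsc", t_m_c = 83,
           dh_cal = 300, dh_vh = 300),
    tibble(name = "dsc_f4a",       kind = "dsc", t_m_c = 89,
           dh_cal = 300, dh_vh = 300),
    tibble(name = "dsc_l71y",      kind = "dsc", t_m_c = 96,
           dh_cal = 300, dh_vh = 300)
  )
}

#' @rdname ub_presets
#' @param name Preset name, one of `ub_presets()$name`.
#' @export
get_preset <- function(name) {
  p <- ub_presets()
  row <- p[p$name == name, ]
  if (nrow(row) != 1) {
    abort(paste0("unknown preset '", name, "'; see ub_presets()"))
  }
  out <- as.list(row)
  out[!vapply(out, function(x) all(is.na(x)), logical(1))]
}
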