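#' Weighted amide chemical shift perturbation
#'
#' Combines 1H and 15N shift changes into a single ppm-scale value,
#' down-weighting the wider 15N dispersion by a factor of 5:
#' `sqrt(delta_h^2 + (delta_n / 5)^2)`.
#'
#' @param delta_h,delta_n Shift differences in ppm (vectorised).
#' @return Weighted CSP in ppm (non-negative).
#' @examples
#' weighted_csp(0, 1)    # 0.2
#' weighted_csp(0.3, 0)  # 0.3
#' @export
weighted_csp <- function(delta_h, delta_n) {
  stopifnot(length(delta_h) == length(delta_n))
  sqrt(delta_h^2 + (delta_n / 5)^2)
}

#' Per-residue chemical shift perturbation map
#'
#' Compares two assigned peak lists of the same protein in different
#' states and returns per-residue shift differences (`b - a`) and the
#' weighted CSP.  Residues present in only one list are kept and
#' flagged (`status` `"only_a"` / `"only_b"`, e.g. broadened beyond
#' detection), mirroring the grey entries of a CSP heat map; matched
#' residues have `status` `"matched"`.
#'
#' @param list_a,list_b [peak_list()]s (reference and comparison state).
#' @return Tibble with `residue_number`, `delta_h`, `delta_n`,
#'   `weighted_csp`, `status`.
#' @export
csp_map <- function(list_a, list_b) {
  a <- as_tibble(list_a)[, c("residue_number", "shift_h", "shift_n")]
  b <- as_tibble(list_b)[, c("residue_number", "shift_h", "shift_n")]
  a <- a[!is.na(a$residue_number), ]
  b <- b[!is.na(b$residue_number), ]
  joined <- dplyr::full_join(a, b, by = "residue_number",
                             suffix = c("_a", "_b"))
  if (!any(!is.na(joined$shift_h_a) & !is.na(joined$shift_h_b))) {
    abort("peak lists share no assigned residues")
  }
  joined |>
    dplyr::mutate(
      status = dplyr::case_when(
        is.na(.data$shift_h_b) ~ "only_a",
        is.na(.data$shift_h_a) ~ "only_b",
        TRUE ~ "matched"
      ),
      delta_h = .data$shift_h_b - .data$shift_h_a,
      delta_n = .data$shift_n_b - .data$shift_n_a,
      weighted_csp = dplyr::if_else(
        .data$status == "matched",
        weighted_csp(.data$delta_h, .data$delta_n),
        NA_real_)
    ) |>
    dplyr::select("residue_number", "delta_h", "delta_n", "weighted_csp",
                  "status") |>
    dplyr::arrange(.data$residue_number)
}

#' Differential line-broadening binding footprint
#'
#' Computes per-residue bound/free intensity ratios and classifies
#' residues by how far their ratio falls below the mean: `"strong"` if
#' `ratio < mean - stdv`, `"moderate"` if `mean - stdv <= ratio <
#' mean - 0.5 * stdv`, else `"none"`.  The population standard deviation
#' is used, and the classes are invariant under global rescaling of
#' either spectrum.  Residues that vanish in the bound spectrum are
#' assigned ratio 0 and class `"strong"` (complete exchange broadening
#' is itself interface evidence); residues with zero free height are
#' excluded with a warning.
#'
#' @param free,bound [peak_list()]s for the apo and complex samples.
#' @return A `broadening_footprint` tibble (`residue_number`,
#'   `intensity_ratio`, `class`) with the ratio mean and population
#'   stdv as attributes `mean` and `stdv`.
#' @export
broadening_footprint <- function(free, bound) {
  f <- as_tibble(free)[, c("residue_number", "height")]
  b <- as_tibble(bound)[, c("residue_number", "height")]
  f <- f[!is.na(f$residue_number), ]
  b <- b[!is.na(b$residue_number), ]
  joined <- dplyr::left_join(f, b, by = "residue_number",
                             suffix = c("_free", "_bound"))
  zero_free <- joined$height_free == 0
  if (any(zero_free)) {
    warn(paste0("excluding ", sum(zero_free),
                " residue(s) with zero free-state height"))
    joined <- joined[!zero_free, ]
  }
  if (nrow(joined) < 3) abort("need at least 3 shared residues")
  joined$height_bound[is.na(joined$height_bound)] <- 0
  ratio <- joined$height_bound / joined$height_free
  m <- mean(ratio)
  s <- sqrt(mean((ratio - m)^2))  # population stdv
  cls <- dplyr::case_when(
    ratio < m - s ~ "strong",
    ratio < m - 0.5 * s ~ "moderate",
    TRUE ~ "none"
  )
  # a vanished bound peak is interface evidence regardless of the spread
  cls[joined$height_bound == 0] <- "strong"
  structure(
    tibble(residue_number = joined$residue_number,
           intensity_ratio = ratio, class = cls),
    mean = m, stdv = s,
    class = c("broadening_footprint", class(tibble())))
}

#' Minor-species fraction from peak intensities
#'
#' @param height_minor,height_major Non-negative peak heights of the two
#'   species (vectorised; not both zero).
#' @return `height_minor / (height_minor + height_major)`.
#' @examples
#' minor_fraction(12, 88)  # 0.12
#' @export
minor_fraction <- function(height_minor, height_major) {
  if (any(height_minor < 0 | height_major < 0)) {
    abort("heights must be >= 0")
  }
  if (any(height_minor + height_major == 0)) {
    abort("heights must not both be zero")
  }
  height_minor / (height_minor + height_major)
}
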