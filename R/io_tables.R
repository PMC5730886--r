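#' Read and write stage tables
#'
#' All pipeline stages exchange plain column-oriented text tables with a
#' single header line.  These helpers read and write each dialect:
#'
#' * CEST profile CSV: `residue, b1_hz, offset_ppm, i_over_i0`
#' * CLEANEX series TSV: `residue, mixing_time_ms, intensity, reference`
#' * Time-course TSV: `residue, species, time_min, height`
#' * Endotherm TSV: `temp_c, cp`
#'
#' ppm values are stored as-is; conversion to angular frequencies happens
#' only inside the Bloch-McConnell layer.
#'
#' @param path File path.
#' @param x Data frame to write.
#' @return Readers return a tibble; writers return `path` invisibly.
#' @name stage_tables
NULL

read_table_checked <- function(path, required, reader) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- reader(path)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0(path, " is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  as_tibble(df)
}

#' @rdname stage_tables
#' @export
read_cest_table <- function(path) {
  read_table_checked(path, c("residue", "b1_hz", "offset_ppm", "i_over_i0"),
                     function(p) readr::read_csv(p, show_col_types = FALSE,
                                                 progress = FALSE))
}

#' @rdname stage_tables
#' @export
write_cest_table <- function(x, path) {
  readr::write_csv(as_tibble(x), path)
  invisible(path)
}

#' @rdname stage_tables
#' @export
read_cleanex_table <- function(path) {
  read_table_checked(path, c("residue", "mixing_time_ms", "intensity",
                             "reference"),
                     function(p) readr::read_tsv(p, show_col_types = FALSE,
                                                 progress = FALSE))
}

#' @rdname stage_tables
#' @export
read_timecourse_table <- function(path) {
  read_table_checked(path, c("residue", "species", "time_min", "height"),
                     function(p) readr::read_tsv(p, show_col_types = FALSE,
                                                 progress = FALSE))
}

#' @rdname stage_tables
#' @export
read_endotherm_table <- function(path) {
  read_table_checked(path, c("temp_c", "cp"),
                     function(p) readr::read_tsv(p, show_col_types = FALSE,
                                                 progress = FALSE))
}

#' @rdname stage_tables
#' @export
write_stage_tsv <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}

#' Read a run configuration
#'
#' Configurations are structured YAML: global acquisition conditions
#' (`spectrometer_h_mhz`, `temperature_c`, optional
#' `gyromagnetic_ratio_n_over_h`) plus optional per-stage blocks
#' (`cest`, `cleanex`, `kinetics`, `dsc`) holding schedules, bounds and
#' seeds.  Used by [run_pipeline()].
#'
#' @param path Path to a YAML file.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config not found: ", path))
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (is.null(cfg$spectrometer_h_mhz)) cfg$spectrometer_h_mhz <- 700
  if (cfg$spectrometer_h_mhz <= 0) abort("spectrometer_h_mhz must be > 0")
  if (is.null(cfg$gyromagnetic_ratio_n_over_h)) {
    cfg$gyromagnetic_ratio_n_over_h <- GAMMA_N_OVER_H
  }
  if (is.null(cfg$temperature_c)) cfg$temperature_c <- 25
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg
}

#' Write stage results to a directory with a checksummed manifest
#'
#' Serialises any collection of stage outputs (data frames become TSV
#' tables, scalar-valued lists become a flat `key\tvalue` summary file)
#' and writes a `manifest.tsv` listing every file with its MD5 checksum.
#' Re-running on identical inputs yields identical checksums.
#'
#' @param results Named list; data-frame elements are written as
#'   `<name>.tsv`, list/scalar elements as `<name>_summary.tsv`.
#' @param path Output directory (created if needed).
#' @return The manifest as a tibble (`file`, `md5`), invisibly written to
#'   `manifest.tsv`.
#' @export
write_results <- function(results, path) {
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(path)) abort(paste0("cannot create ", path))
  }
  files <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.data.frame(x)) {
      f <- file.path(path, paste0(nm, ".tsv"))
      write_stage_tsv(x, f)
    } else {
      f <- file.path(path, paste0(nm, "_summary.tsv"))
      flat <- unlist(x)
      utils::write.table(
        data.frame(key = names(flat),
                   value = vapply(flat, function(v)
                     if (is.numeric(v)) sprintf("%.17g", v) else as.character(v),
                     character(1))),
        f, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    files <- c(files, f)
  }
  manifest <- tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files))
  )
  readr::write_tsv(manifest, file.path(path, "manifest.tsv"))
  invisible(manifest)
}
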