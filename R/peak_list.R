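#' Assigned amide peak lists
#'
#' A peak list holds assigned backbone-amide (H-N) peak positions and
#' heights for one sample state (e.g. apo vs. kinase-bound, or
#' unphosphorylated vs. phosphorylated).  It is an ordinary tibble with
#' one row per peak and columns:
#'
#' * `residue_number`, `residue_code` -- 1-based sequence position and
#'   one-letter amino-acid code,
#' * `atom_pair` -- `"H-N"` (backbone amides only),
#' * `conformer_tag` -- `"major"`, `"minor"` or `"unassigned"`,
#' * `shift_n`, `shift_h` -- 15N and 1H chemical shifts (ppm),
#' * `height` -- peak height (arbitrary intensity units),
#' * `noise` -- optional per-peak noise estimate.
#'
#' @param peaks Data frame with at least `residue_number`, `residue_code`,
#'   `shift_n`, `shift_h` and `height` columns.
#' @param sample_label,condition Free-text labels carried as attributes.
#' @return A `peak_list` tibble.
#' @export
peak_list <- function(peaks, sample_label = "", condition = "") {
  peaks <- as_tibble(peaks)
  if (!"atom_pair" %in% names(peaks)) peaks$atom_pair <- "H-N"
  if (!"conformer_tag" %in% names(peaks)) peaks$conformer_tag <- "major"
  if (!"noise" %in% names(peaks)) peaks$noise <- NA_real_
  required <- c("residue_number", "residue_code", "shift_n", "shift_h",
                "height")
  missing <- setdiff(required, names(peaks))
  if (length(missing) > 0) {
    abort(paste0("peak list is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  peaks <- peaks[, c("residue_number", "residue_code", "atom_pair",
                     "conformer_tag", "shift_n", "shift_h", "height",
                     "noise")]
  assigned <- peaks$conformer_tag != "unassigned"
  if (any(!is.finite(peaks$height))) {
    abort("peak heights must be finite")
  }
  if (any(assigned & peaks$residue_number < 1, na.rm = TRUE)) {
    abort("residue numbers must be >= 1")
  }
  key <- paste(peaks$residue_number, peaks$atom_pair, peaks$conformer_tag)
  dup <- duplicated(key) & assigned
  if (any(dup)) {
    abort(paste0("duplicate assignment for residue ",
                 paste(unique(peaks$residue_number[dup]), collapse = ", ")))
  }
  out_of_band <- assigned & is.finite(peaks$shift_n) &
    (peaks$shift_n < 95 | peaks$shift_n > 140)
  if (any(out_of_band)) {
    warn(paste0(sum(out_of_band),
                " peak(s) have 15N shifts outside 95-140 ppm"))
  }
  structure(peaks,
            sample_label = sample_label,
            condition = condition,
            class = c("peak_list", class(peaks)))
}

# Parse assignment strings of the grammar
# "<one-letter code><residue number><atom>-<atom>", e.g. "K11N-H".
# Sparky-style unassigned labels ("?-?", "?") are tagged, not dropped.
parse_assignment <- function(x) {
  x <- trimws(x)
  n <- length(x)
  out <- tibble(
    residue_number = rep(NA_integer_, n),
    residue_code = rep(NA_character_, n),
    atom_pair = rep("H-N", n),
    conformer_tag = rep("major", n)
  )
  unassigned <- grepl("^\\?", x)
  out$conformer_tag[unassigned] <- "unassigned"
  m <- regmatches(x, regexec("^([A-Za-z])([0-9]+)([A-Za-z0-9]+)-([A-Za-z0-9]+)$", x))
  ok <- vapply(m, length, integer(1)) == 5
  bad <- !ok & !unassigned
  if (any(bad)) {
    abort(paste0("malformed assignment string(s): ",
                 paste(utils::head(x[bad], 5), collapse = ", "),
                 " (row ", paste(utils::head(which(bad), 5), collapse = ", "),
                 ")"))
  }
  for (i in which(ok)) {
    out$residue_number[i] <- as.integer(m[[i]][3])
    out$residue_code[i] <- toupper(m[[i]][2])
    # stored atom order is 1H first regardless of input order
    atoms <- sort(c(toupper(m[[i]][4]), toupper(m[[i]][5])))
    out$atom_pair[i] <- paste(atoms, collapse = "-")
  }
  out
}

#' Read an assigned peak list
#'
#' Reads a peak list either from the package's native tab-separated
#' dialect (header `assignment  w1_ppm  w2_ppm  height [noise]`, with
#' `w1` the 15N and `w2` the 1H dimension) or from a Sparky `.list`
#' export (read-only).  Assignment strings such as `"K11N-H"` are parsed
#' into residue number, residue code and atom pair; unassigned rows
#' (`"?-?"`) are kept and tagged, malformed rows raise an error naming
#' the offending line.
#'
#' @param path Path to the file.
#' @param dialect `"simple_tsv"` (native) or `"sparky_list"`.
#' @param sample_label,condition Labels attached to the result.
#' @return A [peak_list()] tibble.
#' @export
read_peak_list <- function(path, dialect = c("simple_tsv", "sparky_list"),
                           sample_label = "", condition = "") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (dialect == "simple_tsv") {
    # base reader: correctly rounded doubles so write/read round-trips
    # are bit-identical
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("assignment", "w1_ppm", "w2_ppm", "height")
    if (!all(need %in% names(df))) {
      abort(paste0("simple_tsv header must contain: ",
                   paste(need, collapse = ", ")))
    }
    parsed <- parse_assignment(df$assignment)
    peaks <- dplyr::bind_cols(
      parsed,
      tibble(shift_n = as.numeric(df$w1_ppm),
             shift_h = as.numeric(df$w2_ppm),
             height = as.numeric(df$height),
             noise = if ("noise" %in% names(df)) as.numeric(df$noise)
                     else NA_real_)
    )
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    # Sparky header: "Assignment  w1  w2  [Data Height]"
    header <- grepl("^\\s*Assignment", lines[1], ignore.case = TRUE)
    body <- if (header) lines[-1] else lines
    fields <- strsplit(trimws(body), "\\s+")
    nf <- vapply(fields, length, integer(1))
    if (any(nf < 3)) {
      abort(paste0("malformed Sparky row at line ",
                   which(nf < 3)[1] + as.integer(header)))
    }
    parsed <- parse_assignment(vapply(fields, `[[`, character(1), 1))
    peaks <- dplyr::bind_cols(
      parsed,
      tibble(
        shift_n = vapply(fields, function(f) as.numeric(f[2]), numeric(1)),
        shift_h = vapply(fields, function(f) as.numeric(f[3]), numeric(1)),
        height = vapply(fields, function(f)
          if (length(f) >= 4) as.numeric(f[4]) else NA_real_, numeric(1)),
        noise = NA_real_
      )
    )
  }
  peak_list(peaks, sample_label = sample_label, condition = condition)
}

#' Write a peak list in the native TSV dialect
#'
#' The written file round-trips bit-identically through
#' [read_peak_list()]: shifts and heights are serialised at full double
#' precision.
#'
#' @param x A [peak_list()] (or compatible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_list <- function(x, path) {
  x <- as_tibble(x)
  assignment <- ifelse(
    x$conformer_tag == "unassigned" | is.na(x$residue_number),
    "?-?",
    paste0(x$residue_code, x$residue_number,
           # native order: 15N atom first to mirror w1 = 15N
           vapply(strsplit(x$atom_pair, "-"), function(a)
             paste(rev(a), collapse = "-"), character(1)))
  )
  out <- data.frame(
    assignment = assignment,
    w1_ppm = sprintf("%.17g", x$shift_n),
    w2_ppm = sprintf("%.17g", x$shift_h),
    height = sprintf("%.17g", x$height),
    noise = ifelse(is.na(x$noise), "NA", sprintf("%.17g", x$noise)),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
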