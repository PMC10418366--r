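# Reading chi1 dihedral time series and circular "doubling and stacking"
# normalization onto a contiguous 360-degree window.

#' Construct a chi1 dihedral time series
#'
#' Container for one residue's chi1 torsion-angle trajectory from one MD
#' replicate.  Residue numbering follows the precursor (zymogen) convention,
#' i.e. the numbering under which the catalytic triad of a papain-family
#' protease sits at Cys 138 / His 275 / Asn 295.
#'
#' @param times numeric vector of frame times, ns; strictly increasing.
#' @param angles numeric vector of chi1 angles, degrees; same length as
#'   `times`.  Raw angles may come in either the `[-180, 180)` or the
#'   `[0, 360)` convention; the convention found is recorded.
#' @param residue_id integer residue label (precursor numbering).
#' @param residue_name three-letter amino-acid code.
#' @param chi_index which side-chain torsion this is (1 for chi1).
#' @return an object of class `dihedral_series` with fields `times`,
#'   `angles`, `residue_id`, `residue_name`, `chi_index`, `angle_range`.
#' @export
dihedral_series <- function(times, angles, residue_id = NA_integer_,
                            residue_name = NA_character_, chi_index = 1L) {
  times <- as.numeric(times)
  angles <- as.numeric(angles)
  if (length(times) == 0L)
    stop_chisno("dihedral series has no frames", "chisno_empty_input")
  if (length(times) != length(angles))
    stop_chisno("times and angles differ in length", "chisno_invalid_series")
  if (anyNA(times) || anyNA(angles))
    stop_chisno("times/angles contain missing values", "chisno_invalid_series")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop_chisno("times must be strictly increasing", "chisno_invalid_series")
  angle_range <- if (min(angles) < 0) "[-180,180)" else "[0,360)"
  structure(
    list(times = times, angles = angles,
         residue_id = as.integer(residue_id),
         residue_name = as.character(residue_name),
         chi_index = as.integer(chi_index),
         angle_range = angle_range),
    class = "dihedral_series"
  )
}

#' @export
print.dihedral_series <- function(x, ...) {
  cat(sprintf("<dihedral_series> chi%d %s%s: %d frames, %.3g-%.3g ns, raw range %s\n",
              x$chi_index, x$residue_name, x$residue_id, length(x$times),
              min(x$times), max(x$times), x$angle_range))
  invisible(x)
}

#' @export
as.data.frame.dihedral_series <- function(x, ...) {
  data.frame(time = x$times, angle = x$angles)
}

# gmx chi names its per-residue output e.g. "chi1HIS275.xvg"
parse_chi_filename <- function(path) {
  m <- regmatches(basename(path),
                  regexec("chi([0-9]+)([A-Za-z]{3})([0-9]+)", basename(path)))[[1]]
  if (length(m) == 4L)
    list(chi_index = as.integer(m[2]), residue_name = toupper(m[3]),
         residue_id = as.integer(m[4]))
  else
    list(chi_index = 1L, residue_name = NA_character_, residue_id = NA_integer_)
}

#' Read a GROMACS chi-utility xvg dihedral file
#'
#' Parses the two-column (time, angle) dialect written by the GROMACS `chi`
#' analysis tool.  Lines beginning with `#` or `@` are metadata and skipped;
#' data fields may be separated by whitespace or commas.  Residue identity is
#' taken from the `chi1HIS275.xvg`-style filename convention unless supplied
#' explicitly.
#'
#' @param path path to the xvg file.
#' @param residue_id,residue_name,chi_index optional overrides for the
#'   filename-derived residue metadata.
#' @return a [dihedral_series()].
#' @export
read_chi_xvg <- function(path, residue_id = NULL, residue_name = NULL,
                         chi_index = NULL) {
  if (!file.exists(path))
    stop_chisno(sprintf("file not found: %s", path), "chisno_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- gsub("−", "-", lines)  # tolerate typographic minus
  trimmed <- trimws(lines)
  is_data <- nzchar(trimmed) & !grepl("^[#@]", trimmed)
  if (!any(is_data))
    stop_chisno(sprintf("no data rows in %s", path), "chisno_empty_input")
  rows <- trimmed[is_data]
  lineno <- which(is_data)
  fields <- strsplit(rows, "[,;[:space:]]+")
  nf <- lengths(fields)
  if (any(nf < 2L))
    stop_chisno(sprintf("malformed data row at line %d of %s (need >= 2 columns)",
                        lineno[which(nf < 2L)[1]], path), "chisno_parse_error")
  t_raw <- vapply(fields, `[`, character(1), 1L)
  a_raw <- vapply(fields, `[`, character(1), 2L)
  times <- suppressWarnings(as.numeric(t_raw))
  angles <- suppressWarnings(as.numeric(a_raw))
  bad <- which(is.na(times) | is.na(angles))
  if (length(bad))
    stop_chisno(sprintf("non-numeric value at line %d of %s",
                        lineno[bad[1]], path), "chisno_parse_error")
  meta <- parse_chi_filename(path)
  dihedral_series(times, angles,
                  residue_id = residue_id %||% meta$residue_id,
                  residue_name = residue_name %||% meta$residue_name,
                  chi_index = chi_index %||% meta$chi_index)
}

#' Write a dihedral series in the chi xvg dialect
#'
#' Serializes with full double precision so that a write/read round trip
#' reproduces the values.
#'
#' @param series a [dihedral_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chi_xvg <- function(series, path) {
  header <- c(
    sprintf("# chi%d time series for %s%s", series$chi_index,
            series$residue_name, series$residue_id),
    "@    xaxis  label \"Time (ns)\"",
    "@    yaxis  label \"Angle (degrees)\""
  )
  body <- sprintf("%.12g %.12g", series$times, series$angles)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a delimited time/angle table
#'
#' Generic reader for plain delimited tables with a header line, for angle
#' series not produced by the GROMACS chi tool.  The delimiter is sniffed
#' (comma vs whitespace/tab) unless given.
#'
#' @param path path to the table.
#' @param time_col,angle_col names of the time and angle columns.
#' @param sep field separator; `NULL` to auto-detect.
#' @param residue_id,residue_name,chi_index residue metadata.
#' @return a [dihedral_series()].
#' @export
read_angle_table <- function(path, time_col = "time", angle_col = "angle",
                             sep = NULL, residue_id = NA_integer_,
                             residue_name = NA_character_, chi_index = 1L) {
  if (!file.exists(path))
    stop_chisno(sprintf("file not found: %s", path), "chisno_io_error")
  if (is.null(sep)) {
    first <- readLines(path, n = 1L, warn = FALSE)
    sep <- if (grepl(",", first)) "," else ""
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(c(time_col, angle_col), names(df))
  if (length(missing_cols))
    stop_chisno(sprintf("column(s) %s not found in %s",
                        paste(missing_cols, collapse = ", "), path),
                "chisno_schema_error")
  dihedral_series(df[[time_col]], df[[angle_col]],
                  residue_id = residue_id, residue_name = residue_name,
                  chi_index = chi_index)
}

#' Write a dihedral series as a CSV time/angle table
#'
#' @param series a [dihedral_series()].
#' @param path output path.
#' @param time_col,angle_col column names to write.
#' @return `path`, invisibly.
#' @export
write_angle_table <- function(series, path, time_col = "time",
                              angle_col = "angle") {
  df <- data.frame(series$times, series$angles)
  names(df) <- c(time_col, angle_col)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Cut point for stacking: the centre of the widest empty arc of the data on
# the mod-360 circle, so the dominant mode is never split by the window edge.
stack_cut <- function(angles_mod360) {
  u <- sort(unique(angles_mod360))
  if (length(u) == 1L) return((u + 180) %% 360)
  gaps <- diff(c(u, u[1] + 360))
  k <- which.max(gaps)
  (u[k] + gaps[k] / 2) %% 360
}

#' Stack circular chi1 angles onto a contiguous 360-degree window
#'
#' Circular chi1 data recorded in `[-180, 180)` suffer an artificial jump at
#' the +/-180 boundary when a rotamer well straddles it.  Stacking duplicates
#' each angle at `a` and `a + 360` and keeps the contiguous 360-degree window
#' whose boundary falls at the centre of the widest empty arc of the data, so
#' every well stays contiguous.  Each stacked angle is congruent (mod 360) to
#' its source angle, and re-stacking an already stacked series reproduces it
#' exactly.
#'
#' @param series a [dihedral_series()] or `stacked_series`.
#' @param window_start optional explicit window start, degrees.  When two
#'   series must share a binning (as in [sno()]), compute the cut from their
#'   pooled angles and pass it to both; no further normalization is applied
#'   to an explicit window.
#' @return an object of class `stacked_series`: fields `times`, `angles`
#'   (all within `[window_start, window_start + 360)`), `window_start`, and
#'   the residue metadata of the source.
#' @export
stack_angles <- function(series, window_start = NULL) {
  a <- series$angles %% 360
  if (is.null(window_start)) {
    ws <- stack_cut(a)
    stacked <- ws + (a - ws) %% 360
    # canonical representative: smallest stacked angle lies in [0, 360)
    shift <- 360 * floor(min(stacked) / 360)
    stacked <- stacked - shift
    ws <- ws - shift
  } else {
    ws <- window_start
    stacked <- ws + (a - ws) %% 360
  }
  structure(
    list(times = series$times, angles = stacked, window_start = ws,
         residue_id = series$residue_id, residue_name = series$residue_name,
         chi_index = series$chi_index),
    class = "stacked_series"
  )
}

#' @export
print.stacked_series <- function(x, ...) {
  cat(sprintf("<stacked_series> chi%d %s%s: %d frames on [%.1f, %.1f) deg\n",
              x$chi_index, x$residue_name, x$residue_id, length(x$angles),
              x$window_start, x$window_start + 360))
  invisible(x)
}
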