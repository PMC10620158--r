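#' Read a line intensity profile from CSV
#'
#' Profiles are stored the way an image viewer's plot-profile export writes
#' them: a header plus two numeric columns, position (micrometres, strictly
#' increasing from the wound-edge end of the line) and intensity (a.u.).
#' Lines starting with `#` are treated as comments; extra columns beyond the
#' first two are ignored with a warning.
#'
#' @param path CSV path.
#' @return A tibble with columns `position_um` and `intensity`.
#' @export
read_profile_csv <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("No such file: '%s'", path))
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (ncol(df) < 2L) rlang::abort(sprintf("'%s' needs >= 2 columns (position_um, intensity).", path))
  if (ncol(df) > 2L) {
    rlang::warn(sprintf("'%s': ignoring %d extra column(s): %s", path,
                        ncol(df) - 2L, paste(names(df)[-(1:2)], collapse = ", ")))
    df <- df[, 1:2]
  }
  names(df) <- c("position_um", "intensity")
  if (!is.numeric(df$position_um) || !is.numeric(df$intensity)) {
    rlang::abort(sprintf("'%s': both profile columns must be numeric.", path))
  }
  if (nrow(df) < 5L) {
    rlang::abort(sprintf("'%s': a profile needs at least 5 samples, got %d.", path, nrow(df)))
  }
  bad <- which(diff(df$position_um) <= 0)
  if (length(bad) > 0L) {
    rlang::abort(sprintf(
      "'%s': positions must be strictly increasing; first violation at data row %d (%.6g -> %.6g).",
      path, bad[1] + 1L, df$position_um[bad[1]], df$position_um[bad[1] + 1L]))
  }
  new_profile(df$position_um, df$intensity)
}

#' Read line ROIs from CSV or JSON
#'
#' ROI endpoints come from an image viewer and are therefore in pixels
#' (0-based row/col, origin top-left). `wound_end` names the endpoint that
#' abuts the wound: `"start"` or `"end"`.
#'
#' CSV needs columns `start_row, start_col, end_row, end_col, wound_end` (plus
#' optional grouping columns such as `animal`, `wound`, `line`); JSON is an
#' array of objects with the same fields.
#'
#' @param path ROI file path, `.csv` or `.json`.
#' @return A tibble, one row per line ROI.
#' @export
read_line_rois <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("No such file: '%s'", path))
  ext <- tolower(tools::file_ext(path))
  df <- switch(ext,
    csv = readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    json = tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE)),
    rlang::abort(sprintf("Unsupported ROI format '.%s' (use .csv or .json).", ext)))
  need <- c("start_row", "start_col", "end_row", "end_col", "wound_end")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    rlang::abort(sprintf("'%s' lacks ROI column(s): %s", path,
                         paste(missing, collapse = ", ")))
  }
  if (!all(df$wound_end %in% c("start", "end"))) {
    rlang::abort("`wound_end` must be 'start' or 'end' for every ROI.")
  }
  tibble::as_tibble(df)
}

#' Read a wound-area time series CSV
#'
#' Expected columns: `frame`, `area_mm2`, plus optional `wound_id`, `animal`,
#' `treatment`, `time_s`. When `time_s` is absent it is derived as
#' `frame * frame_interval_s`.
#'
#' @param path CSV path.
#' @param frame_interval_s Acquisition interval used when `time_s` is absent
#'   (default 11 s, the time-lapse interval of the assay).
#' @return Tidy tibble of areas.
#' @export
read_area_csv <- function(path, frame_interval_s = 11) {
  if (!file.exists(path)) rlang::abort(sprintf("No such file: '%s'", path))
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  need <- c("frame", "area_mm2")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    rlang::abort(sprintf("'%s' lacks column(s): %s", path, paste(missing, collapse = ", ")))
  }
  if (!"time_s" %in% names(df)) {
    check_positive_scalar(frame_interval_s, "frame_interval_s")
    df$time_s <- df$frame * frame_interval_s
  }
  tibble::as_tibble(df)
}

#' Write a tidy results table as CSV
#'
#' One row per observational unit (line, image, wound or animal depending on
#' the stage); stable column order as given; numeric columns printed at 6
#' significant digits so values round-trip within print precision.
#'
#' @param records A non-empty data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    rlang::abort("`records` must be a data frame with at least one row.")
  }
  out <- records
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) signif(x, 6))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
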