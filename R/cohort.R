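cohort_cols <- c("subject_id", "group", "time_h", "feature", "value")

#' Parse zeitgeber-time labels into hours
#'
#' Accepts plain numbers and `ZT`-prefixed tokens (`"ZT2"`, `"zt14"`);
#' ZT0 is lights-on in a 12:12 light:dark cycle.
#'
#' @param x Character or numeric vector of timepoint labels.
#' @return Numeric hours.
#' @examples
#' parse_zt(c("ZT2", "ZT22", "6"))
#' @export
parse_zt <- function(x) {
  if (is.numeric(x)) return(x)
  out <- suppressWarnings(as.numeric(sub("^[Zz][Tt]\\s*", "", trimws(x))))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    stop("unparseable timepoint labels: ",
         paste(utils::head(x[bad], 5), collapse = ", "), call. = FALSE)
  }
  out
}

#' Read a long-format cohort table
#'
#' Reads a UTF-8 tab-separated file with header
#' `subject_id  group  time_h  feature  value` ('.' decimal separator).
#' Rows with a blank/missing value are dropped with a message giving the
#' count; `time_h` may use `ZT` tokens. Malformed lines are reported with
#' their line numbers.
#'
#' @param path Path to the TSV file.
#' @return A tibble with the five schema columns.
#' @seealso [write_cohort()], [cohort_design()], [cosinor_rhythms()]
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  hdr <- names(readr::read_tsv(path, n_max = 0, show_col_types = FALSE,
                               progress = FALSE))
  # schema columns read as text; value goes through strtod below so that
  # written doubles round-trip exactly
  ctypes <- rep(list(readr::col_character()),
                length(intersect(cohort_cols, hdr)))
  names(ctypes) <- intersect(cohort_cols, hdr)
  tab <- readr::read_tsv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = do.call(readr::cols,
                        c(ctypes, .default = readr::col_guess()))
  )
  missing_cols <- setdiff(cohort_cols, names(tab))
  if (length(missing_cols)) {
    stop("cohort file is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  probs <- readr::problems(tab)
  if (nrow(probs)) {
    warning("malformed cells at lines: ",
            paste(utils::head(unique(probs$row), 10), collapse = ", "),
            call. = FALSE)
  }
  if (nrow(tab) == 0) stop("cohort file is empty: ", path, call. = FALSE)
  tab <- dplyr::select(tab, dplyr::all_of(cohort_cols))
  tab$time_h <- parse_zt(tab$time_h)
  blank <- is.na(tab$value) | !nzchar(trimws(tab$value))
  num <- suppressWarnings(as.numeric(tab$value))
  malformed <- which(!blank & is.na(num))
  if (length(malformed)) {
    warning("non-numeric value cells at data line(s): ",
            paste(utils::head(malformed, 10), collapse = ", "),
            call. = FALSE)
  }
  tab$value <- num
  n0 <- nrow(tab)
  tab <- dplyr::filter(tab, !is.na(.data$value))
  if (nrow(tab) < n0) {
    message("dropped ", n0 - nrow(tab), " row(s) with missing value")
  }
  tab
}

#' Write a cohort table to TSV
#'
#' Inverse of [read_cohort()]: tab-separated, `.` decimal, blank for
#' missing values, full numeric precision so a round trip is lossless.
#'
#' @param cohort A cohort tibble (schema of [read_cohort()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(all(cohort_cols %in% names(cohort)))
  readr::write_tsv(cohort[, cohort_cols], path, na = "", progress = FALSE)
  invisible(path)
}

#' Summarize the sampling design of a cohort
#'
#' Counts observations per feature, group and timepoint — the `n` per cell
#' of the cross-sectional design — and flags strata (feature x group) with
#' fewer than three distinct timepoints, which cannot support a cosinor
#' fit.
#'
#' @param cohort A cohort tibble.
#' @param period Period in hours used to identify timepoints modulo the
#'   cycle (default 24).
#' @return A tibble with one row per (feature, group): `n`, `n_timepoints`,
#'   `fittable`.
#' @export
cohort_design <- function(cohort, period = 24) {
  cohort |>
    dplyr::group_by(.data$feature, .data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_timepoints = dplyr::n_distinct(round(.data$time_h %% period, 9)),
      .groups = "drop"
    ) |>
    dplyr::mutate(fittable = .data$n >= 4 & .data$n_timepoints >= 3)
}
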