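#' Per-feature cosinor rhythm analysis of a cohort
#'
#' Runs the full single-cosinor analysis over a long-format cohort: per
#' (feature, group) an OLS cosinor fit and zero-amplitude F-test; when the
#' cohort holds exactly two groups, Wald F comparisons of MESOR, amplitude
#' and acrophase between them; Benjamini-Hochberg adjustment across
#' features within each test family (zero-amplitude across feature x group
#' rows; each comparison family across features). Strata with fewer than
#' three distinct timepoints or fewer than four observations are reported
#' with `note = "insufficient_design"` and `NA` statistics rather than
#' dropped; the pipeline continues.
#'
#' @param cohort A cohort tibble (schema of [read_cohort()]).
#' @param period Fixed cosinor period in hours (default 24).
#' @param alpha Significance threshold used for the `rhythmic` flag on the
#'   unadjusted zero-amplitude p (default 0.05).
#' @return A tibble with one row per (feature, group): sample size, fitted
#'   `mesor`/`amplitude`/`acrophase_h` each with `_se`, the zero-amplitude
#'   `p` and BH-adjusted `q`, a `rhythmic` flag, and — when two groups are
#'   present — `mesor_test_p`, `amplitude_test_p`, `acrophase_test_p`
#'   (identical within a feature) with their `_q` counterparts.
#' @seealso [cohort_timepoint_tests()], [write_rhythm_table()]
#' @export
cosinor_rhythms <- function(cohort, period = 24, alpha = 0.05) {
  stopifnot(all(cohort_cols %in% names(cohort)))
  if (nrow(cohort) == 0) stop("empty cohort.", call. = FALSE)
  groups <- sort(unique(cohort$group))

  strata <- cohort |>
    dplyr::group_by(.data$feature, .data$group) |>
    tidyr::nest() |>
    dplyr::ungroup()

  fit_one <- function(df) {
    n_times <- dplyr::n_distinct(round(df$time_h %% period, 9))
    if (nrow(df) < 4 || n_times < 3) return(NULL)
    fit_cosinor(df, period = period)
  }
  strata$fit <- purrr::map(strata$data, fit_one)

  row_of <- function(fit, df) {
    if (is.null(fit)) {
      return(tibble::tibble(
        n = nrow(df), mesor = NA_real_, mesor_se = NA_real_,
        amplitude = NA_real_, amplitude_se = NA_real_,
        acrophase_h = NA_real_, acrophase_se_h = NA_real_,
        zero_amplitude_p = NA_real_, note = "insufficient_design"
      ))
    }
    zt <- zero_amplitude_test(fit)
    tibble::tibble(
      n = fit$n, mesor = fit$mesor, mesor_se = fit$mesor_se,
      amplitude = fit$amplitude, amplitude_se = fit$amplitude_se,
      acrophase_h = fit$acrophase_h, acrophase_se_h = fit$acrophase_se_h,
      zero_amplitude_p = zt$p, note = NA_character_
    )
  }
  rows <- dplyr::bind_cols(
    strata[, c("feature", "group")],
    purrr::map2_dfr(strata$fit, strata$data, row_of)
  )
  rows$zero_amplitude_q <- adjust_bh(rows$zero_amplitude_p)
  rows$rhythmic <- !is.na(rows$zero_amplitude_p) &
    rows$zero_amplitude_p < alpha

  if (length(groups) == 2) {
    cmp_one <- function(fits) {
      f1 <- fits[[groups[1]]]
      f2 <- fits[[groups[2]]]
      if (is.null(f1) || is.null(f2)) {
        return(tibble::tibble(mesor_test_p = NA_real_,
                              amplitude_test_p = NA_real_,
                              acrophase_test_p = NA_real_))
      }
      cmp <- compare_cosinor(f1, f2)
      tibble::tibble(
        mesor_test_p = cmp$p[cmp$kind == "mesor"],
        amplitude_test_p = cmp$p[cmp$kind == "amplitude"],
        acrophase_test_p = cmp$p[cmp$kind == "acrophase"]
      )
    }
    by_feature <- split(
      stats::setNames(strata$fit, strata$group), strata$feature)
    cmp <- dplyr::bind_cols(
      tibble::tibble(feature = names(by_feature)),
      purrr::map_dfr(by_feature, cmp_one)
    )
    cmp$mesor_test_q <- adjust_bh(cmp$mesor_test_p)
    cmp$amplitude_test_q <- adjust_bh(cmp$amplitude_test_p)
    cmp$acrophase_test_q <- adjust_bh(cmp$acrophase_test_p)
    rows <- dplyr::left_join(rows, cmp, by = "feature")
  }
  dplyr::arrange(rows, .data$feature, .data$group)
}

#' Per-timepoint two-group t-tests for each feature
#'
#' The companion analysis to [cosinor_rhythms()]: at every timepoint of
#' every feature, a pooled-variance Student's t-test between the two
#' groups' values ([timepoint_t_test()]), with Benjamini-Hochberg
#' adjustment across timepoints within each feature.
#'
#' @param cohort A cohort tibble holding exactly two groups.
#' @param var_equal Pool variances (default TRUE, classical Student's t).
#' @return A tibble: `feature`, `time_h`, `n1`, `n2`, `t`, `df`, `p`,
#'   `p_adj`, `note`. Timepoints where either group has fewer than two
#'   values are flagged `"insufficient_n"`.
#' @export
cohort_timepoint_tests <- function(cohort, var_equal = TRUE) {
  stopifnot(all(cohort_cols %in% names(cohort)))
  groups <- sort(unique(cohort$group))
  if (length(groups) != 2) {
    stop("per-timepoint tests need exactly two groups, found ",
         length(groups), ".", call. = FALSE)
  }
  out <- cohort |>
    dplyr::group_by(.data$feature, .data$time_h) |>
    dplyr::group_modify(function(df, key) {
      v1 <- df$value[df$group == groups[1]]
      v2 <- df$value[df$group == groups[2]]
      if (length(v1) < 2 || length(v2) < 2) {
        return(tibble::tibble(n1 = length(v1), n2 = length(v2),
                              t = NA_real_, df = NA_real_, p = NA_real_,
                              note = "insufficient_n"))
      }
      tt <- timepoint_t_test(v1, v2, var_equal = var_equal)
      tibble::tibble(n1 = length(v1), n2 = length(v2),
                     t = tt$statistic, df = tt$df2, p = tt$p, note = tt$note)
    }) |>
    dplyr::ungroup()
  out |>
    dplyr::group_by(.data$feature) |>
    dplyr::mutate(p_adj = adjust_bh(.data$p)) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(c("feature", "time_h", "n1", "n2",
                                  "t", "df", "p", "p_adj", "note")))
}

#' Write / read a rhythm table as TSV
#'
#' Fixed column order mirroring the publication-style cosinor table
#' (zero-amplitude test, MESOR, amplitude, acrophase, between-group tests)
#' plus adjusted-p columns; estimates and their standard errors are
#' separate numeric columns. Undefined values are written as empty cells,
#' never `"NaN"`/`"NA"` strings. Full numeric precision, so
#' `read_rhythm_table(write_rhythm_table(x, f))` reproduces `x`.
#'
#' @param rows Result tibble from [cosinor_rhythms()] (nonempty).
#' @param path Output path.
#' @return `path` invisibly (writer); a tibble (reader).
#' @export
write_rhythm_table <- function(rows, path) {
  if (!is.data.frame(rows) || nrow(rows) == 0) {
    stop("no rhythm rows to write.", call. = FALSE)
  }
  lead <- intersect(
    c("feature", "group", "n", "zero_amplitude_p", "zero_amplitude_q",
      "mesor", "mesor_se", "amplitude", "amplitude_se",
      "acrophase_h", "acrophase_se_h",
      "mesor_test_p", "mesor_test_q", "amplitude_test_p", "amplitude_test_q",
      "acrophase_test_p", "acrophase_test_q", "rhythmic", "note"),
    names(rows))
  rows <- rows[, c(lead, setdiff(names(rows), lead))]
  readr::write_tsv(rows, path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_rhythm_table
#' @export
read_rhythm_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
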