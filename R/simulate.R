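#' Ground-truth parameter rows for cohort simulation
#'
#' Convenience constructor for the per-feature, per-group parameter table
#' consumed by [simulate_cohort()]. The default noise scale,
#' `noise_sd = amplitude / 4`, is the package's convention for a clearly
#' detectable rhythm when no dispersion estimate is available.
#'
#' @param feature,group Labels (recycled to a common length).
#' @param mesor,amplitude,acrophase_h,noise_sd Cosinor ground truth:
#'   rhythm-adjusted mean, half peak-to-trough extent (>= 0), clock time of
#'   the peak in hours within \[0, period), and Gaussian noise SD (>= 0).
#' @return A tibble with one row per parameter set.
#' @export
cohort_params <- function(feature, group, mesor, amplitude, acrophase_h,
                          noise_sd = amplitude / 4) {
  tibble::tibble(feature = feature, group = group, mesor = mesor,
                 amplitude = amplitude, acrophase_h = acrophase_h,
                 noise_sd = noise_sd)
}

validate_cohort_params <- function(params, period) {
  req <- c("feature", "group", "mesor", "amplitude", "acrophase_h",
           "noise_sd")
  missing_cols <- setdiff(req, names(params))
  if (length(missing_cols)) {
    stop("params is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- character(0)
  if (any(params$amplitude < 0)) bad <- c(bad, "amplitude < 0")
  if (any(params$noise_sd < 0)) bad <- c(bad, "noise_sd < 0")
  if (any(params$acrophase_h < 0 | params$acrophase_h >= period)) {
    bad <- c(bad, "acrophase_h outside [0, period)")
  }
  if (any(!stats::complete.cases(params[, req]))) bad <- c(bad, "missing values")
  if (length(bad)) {
    stop("invalid simulation parameters: ", paste(bad, collapse = "; "),
         call. = FALSE)
  }
  invisible(params)
}

#' Simulate a cross-sectional circadian cohort
#'
#' Generates the study design the analysis assumes: two (or more) groups,
#' each necropsied at fixed zeitgeber timepoints (default ZT 2, 6, ...,
#' 22, i.e. 4-h intervals over 24 h), with `n` subjects per group per
#' timepoint and each subject measured once. Values follow
#' \eqn{Y(t) = M + A\cos(2\pi t/\tau + \phi) + \varepsilon},
#' \eqn{\varepsilon \sim N(0, \sigma^2)} — additive homoscedastic Gaussian
#' noise, the error model implied by the OLS cosinor. The output is a pure
#' function of `(params, design, seed)`; the caller's RNG state is left
#' untouched.
#'
#' Subject IDs are shared across features within a (group, timepoint) cell,
#' mirroring one animal yielding all measurements; feature noise is drawn
#' independently.
#'
#' @param params Parameter tibble from [cohort_params()] (one row per
#'   feature x group).
#' @param timepoints Sampling times in hours (distinct modulo `period`).
#' @param n_per_cell Subjects per (group, timepoint) cell: a single fixed
#'   n, or a vector of candidate n values sampled uniformly per cell
#'   (default `3:6`, the typical group sizes of small-animal circadian
#'   necropsy studies).
#' @param period Rhythm period in hours (default 24).
#' @param seed Integer seed; required, for the reproducibility contract.
#' @return A cohort tibble (schema of [read_cohort()]).
#' @examples
#' truth <- cohort_params("lacz", "KO", 141.511, 251.811, 19.3)
#' cohort <- simulate_cohort(truth, n_per_cell = 8, seed = 42)
#' fit_cosinor(cohort)
#' @export
simulate_cohort <- function(params, timepoints = c(2, 6, 10, 14, 18, 22),
                            n_per_cell = 3:6, period = 24, seed) {
  if (missing(seed)) stop("`seed` is required.", call. = FALSE)
  if (!is.numeric(period) || period <= 0) {
    stop("`period` must be positive.", call. = FALSE)
  }
  if (dplyr::n_distinct(round(timepoints %% period, 9)) < length(timepoints)) {
    stop("timepoints must be distinct modulo the period.", call. = FALSE)
  }
  if (any(n_per_cell < 1)) stop("`n_per_cell` must be >= 1.", call. = FALSE)
  validate_cohort_params(params, period)

  withr::with_seed(as.integer(seed), {
    groups <- unique(params$group)
    cells <- tidyr::expand_grid(group = groups, time_h = timepoints)
    cells$n <- if (length(n_per_cell) == 1) {
      rep(n_per_cell, nrow(cells))
    } else {
      sample(n_per_cell, nrow(cells), replace = TRUE)
    }
    subjects <- cells |>
      dplyr::mutate(subject_id = purrr::map2(
        .data$group, seq_len(nrow(cells)),
        function(g, i) sprintf("%s_c%02d_m%02d", g, i, seq_len(cells$n[i]))
      )) |>
      tidyr::unnest("subject_id")

    per_feature <- function(feature) {
      p <- params[params$feature == feature, ]
      df <- dplyr::inner_join(subjects, p, by = "group")
      phi <- -2 * pi * df$acrophase_h / period
      mu <- df$mesor + df$amplitude * cos(2 * pi * df$time_h / period + phi)
      df$value <- mu + stats::rnorm(nrow(df), 0, df$noise_sd)
      df$feature <- feature
      df[, cohort_cols]
    }
    dplyr::bind_rows(lapply(unique(params$feature), per_feature))
  })
}

#' Simulate a rhythm-free (null) cohort
#'
#' [simulate_cohort()] with every amplitude forced to zero: values are
#' `mesor` plus Gaussian noise, the null of the zero-amplitude test.
#' Used for type-I-error calibration.
#'
#' @inheritParams simulate_cohort
#' @return A cohort tibble.
#' @export
simulate_null_cohort <- function(params, timepoints = c(2, 6, 10, 14, 18, 22),
                                 n_per_cell = 3:6, period = 24, seed) {
  params$amplitude <- 0
  params$acrophase_h <- 0
  simulate_cohort(params, timepoints = timepoints, n_per_cell = n_per_cell,
                  period = period, seed = seed)
}

#' Ground-truth rows for community simulation
#'
#' @param taxon_id Taxon labels.
#' @param lineage Semicolon-separated rank strings
#'   (`"Bacteria;Bacteroidota;...;Bacteroides"`).
#' @param baseline Baseline proportions (will be checked to sum to 1).
#' @param amplitude Oscillation amplitude in proportion units (>= 0 and
#'   strictly below `baseline` so expected proportions stay positive).
#' @param acrophase_h Peak clock time in hours.
#' @param group Optional group label for group-specific parameters.
#' @return A tibble with one row per taxon (x group).
#' @export
community_params <- function(taxon_id, lineage, baseline, amplitude = 0,
                             acrophase_h = 0, group = NA_character_) {
  tibble::tibble(taxon_id = taxon_id, lineage = lineage, baseline = baseline,
                 amplitude = amplitude, acrophase_h = acrophase_h,
                 group = group)
}

#' Simulate 16S-like compositional counts with oscillating taxa
#'
#' Per sample at time `t`, expected proportions are the renormalized
#' perturbation \eqn{p_i(t) \propto b_i + A_i\cos(2\pi t/\tau + \phi_i)};
#' a Dirichlet draw with concentration `concentration * p(t)` adds
#' compositional overdispersion, and multinomial sampling at a
#' lognormally drawn library size yields integer counts. Sequencing-error
#' structure (chimeras, copy-number variation) is not modeled.
#'
#' @param community Tibble from [community_params()]. If its `group`
#'   column is filled, each group uses its own rows (taxon sets must
#'   match); otherwise the same parameters apply to every `groups` entry.
#' @param groups Group labels of the design.
#' @param timepoints,n_per_cell,period Sampling design, as in
#'   [simulate_cohort()].
#' @param concentration Dirichlet concentration; larger = less
#'   overdispersion; `Inf` disables the Dirichlet stage (pure multinomial).
#' @param lib_median,lib_sdlog Lognormal library-size parameters (median
#'   scale and log-SD; `lib_sdlog = 0` fixes the size at `lib_median`).
#' @param seed Integer seed (required).
#' @return A [taxa_table()] in counts mode, with metadata
#'   (`sample_id`, `group`, `time_h`) and per-taxon taxonomy.
#' @export
simulate_microbiome <- function(community, groups = "WT",
                                timepoints = c(2, 6, 10, 14, 18, 22),
                                n_per_cell = 3:6, period = 24,
                                concentration = 200,
                                lib_median = 20000, lib_sdlog = 0.25, seed) {
  if (missing(seed)) stop("`seed` is required.", call. = FALSE)
  has_groups <- "group" %in% names(community) && !all(is.na(community$group))
  if (!has_groups) {
    community <- dplyr::bind_rows(lapply(groups, function(g) {
      dplyr::mutate(community, group = g)
    }))
  }
  community <- dplyr::filter(community, .data$group %in% groups)
  taxa <- unique(community$taxon_id)

  for (g in groups) {
    cg <- community[community$group == g, ]
    if (!setequal(cg$taxon_id, taxa) || nrow(cg) != length(taxa)) {
      stop("group '", g, "' does not define every taxon exactly once.",
           call. = FALSE)
    }
    tot <- sum(cg$baseline)
    if (abs(tot - 1) > 1e-6) {
      stop("baseline proportions for group '", g, "' sum to ", tot,
           ", not 1.", call. = FALSE)
    }
    low <- cg$baseline - cg$amplitude
    if (any(low <= 0)) {
      stop("amplitudes drive expected proportions of ",
           paste(cg$taxon_id[low <= 0], collapse = ", "),
           " to <= 0; reduce the amplitude or raise the baseline.",
           call. = FALSE)
    }
  }

  withr::with_seed(as.integer(seed), {
    cells <- tidyr::expand_grid(group = groups, time_h = timepoints)
    cells$n <- if (length(n_per_cell) == 1) {
      rep(n_per_cell, nrow(cells))
    } else {
      sample(n_per_cell, nrow(cells), replace = TRUE)
    }
    meta <- cells |>
      dplyr::mutate(rep = purrr::map(.data$n, seq_len)) |>
      tidyr::unnest("rep") |>
      dplyr::mutate(sample_id = sprintf("%s_ZT%02g_%02d", .data$group,
                                        .data$time_h, .data$rep)) |>
      dplyr::select(dplyr::all_of(c("sample_id", "group", "time_h")))

    counts <- matrix(0L, nrow = nrow(meta), ncol = length(taxa),
                     dimnames = list(meta$sample_id, taxa))
    for (i in seq_len(nrow(meta))) {
      cg <- community[community$group == meta$group[i], ]
      cg <- cg[match(taxa, cg$taxon_id), ]
      phi <- -2 * pi * cg$acrophase_h / period
      e <- cg$baseline +
        cg$amplitude * cos(2 * pi * meta$time_h[i] / period + phi)
      e <- e / sum(e)
      p <- if (is.infinite(concentration)) e else {
        g <- stats::rgamma(length(e), shape = concentration * e)
        if (sum(g) == 0) e else g / sum(g)
      }
      L <- if (lib_sdlog == 0) round(lib_median) else {
        max(1, round(stats::rlnorm(1, log(lib_median), lib_sdlog)))
      }
      counts[i, ] <- stats::rmultinom(1, size = L, prob = p)[, 1]
    }
    lineage <- community$lineage[match(taxa, community$taxon_id)]
    taxa_table(counts,
               taxonomy = tibble::tibble(taxon_id = taxa, lineage = lineage),
               metadata = meta)
  })
}

#' Read a simulation spec from YAML
#'
#' Two schemas are recognized. A cohort spec has top-level `period`,
#' `timepoints`, `n_per_cell` and a `features` list of
#' `{feature, group, mesor, amplitude, acrophase_h, noise_sd}` entries
#' (`noise_sd` defaults to `amplitude / 4`). A community spec has the same
#' design keys plus `groups`, `concentration`, `lib_median`, `lib_sdlog`
#' and a `taxa` list of
#' `{taxon_id, lineage, baseline, amplitude, acrophase_h[, group]}`.
#' A worked cohort example reproducing a published plasma-choline scenario
#' ships as `system.file("extdata", "choline_cohort.yaml",
#' package = "rhythmr")`.
#'
#' @param path Path to the YAML file.
#' @return A list with class `rhythm_sim_spec` and `$type` `"cohort"` or
#'   `"community"`; pass to [simulate_from_spec()].
#' @export
read_simulation_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  type <- if (!is.null(raw$taxa)) "community" else "cohort"
  spec <- list(
    type = type,
    period = raw$period %||% 24,
    timepoints = unlist(raw$timepoints) %||% c(2, 6, 10, 14, 18, 22),
    n_per_cell = unlist(raw$n_per_cell) %||% 3:6
  )
  if (type == "cohort") {
    if (is.null(raw$features)) stop("spec has no `features`.", call. = FALSE)
    spec$params <- purrr::map_dfr(raw$features, function(f) {
      cohort_params(f$feature, f$group, f$mesor, f$amplitude, f$acrophase_h,
                    noise_sd = f$noise_sd %||% (f$amplitude / 4))
    })
    validate_cohort_params(spec$params, spec$period)
  } else {
    spec$community <- purrr::map_dfr(raw$taxa, function(f) {
      community_params(f$taxon_id, f$lineage, f$baseline,
                       f$amplitude %||% 0, f$acrophase_h %||% 0,
                       f$group %||% NA_character_)
    })
    spec$groups <- unlist(raw$groups) %||% "WT"
    spec$concentration <- raw$concentration %||% 200
    spec$lib_median <- raw$lib_median %||% 20000
    spec$lib_sdlog <- raw$lib_sdlog %||% 0.25
  }
  structure(spec, class = "rhythm_sim_spec")
}

#' Run the simulator described by a YAML spec
#'
#' @param spec A [read_simulation_spec()] result (or a path to one).
#' @param seed Integer seed.
#' @return A cohort tibble or a [taxa_table()], by spec type.
#' @export
simulate_from_spec <- function(spec, seed) {
  if (is.character(spec)) spec <- read_simulation_spec(spec)
  stopifnot(inherits(spec, "rhythm_sim_spec"))
  if (spec$type == "cohort") {
    simulate_cohort(spec$params, timepoints = spec$timepoints,
                    n_per_cell = spec$n_per_cell, period = spec$period,
                    seed = seed)
  } else {
    simulate_microbiome(spec$community, groups = spec$groups,
                        timepoints = spec$timepoints,
                        n_per_cell = spec$n_per_cell, period = spec$period,
                        concentration = spec$concentration,
                        lib_median = spec$lib_median,
                        lib_sdlog = spec$lib_sdlog, seed = seed)
  }
}
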