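default_ranks <- c("kingdom", "phylum", "class", "order", "family",
                   "genus", "species")

#' Taxon count table with taxonomy and sample metadata
#'
#' Light container tying together a samples-by-taxa count (or proportion)
#' matrix, a taxonomy map (semicolon-separated lineages, kingdom outward),
#' and per-sample metadata (`sample_id`, `group`, `time_h`). Every sample
#' in the matrix must have metadata; taxa without taxonomy get an `NA`
#' lineage and fall into `unclassified` buckets on aggregation.
#'
#' @param counts Numeric matrix, samples as rows, taxa as columns, with
#'   dimnames; nonnegative.
#' @param taxonomy Tibble with `taxon_id` and `lineage`.
#' @param metadata Tibble with `sample_id`, `group`, `time_h`.
#' @param mode `"counts"` or `"proportions"`.
#' @return An object of class `taxa_table`.
#' @seealso [read_taxa_table()], [aggregate_rank()], [relative_abundance()]
#' @export
taxa_table <- function(counts, taxonomy, metadata, mode = "counts") {
  mode <- match.arg(mode, c("counts", "proportions"))
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (any(counts < 0)) stop("counts must be nonnegative.", call. = FALSE)
  stopifnot(all(c("taxon_id", "lineage") %in% names(taxonomy)),
            all(c("sample_id", "group", "time_h") %in% names(metadata)))
  metadata$time_h <- parse_zt(metadata$time_h)
  orphans <- setdiff(rownames(counts), metadata$sample_id)
  if (length(orphans)) {
    stop("samples without metadata: ", paste(orphans, collapse = ", "),
         call. = FALSE)
  }
  extra_meta <- setdiff(metadata$sample_id, rownames(counts))
  if (length(extra_meta)) {
    message("metadata rows without counts ignored: ",
            paste(extra_meta, collapse = ", "))
    metadata <- metadata[metadata$sample_id %in% rownames(counts), ]
  }
  no_tax <- setdiff(colnames(counts), taxonomy$taxon_id)
  if (length(no_tax)) {
    message(length(no_tax), " taxa without taxonomy assigned NA lineage")
    taxonomy <- dplyr::bind_rows(
      taxonomy, tibble::tibble(taxon_id = no_tax, lineage = NA_character_))
  }
  taxonomy <- taxonomy[match(colnames(counts), taxonomy$taxon_id), ]
  metadata <- metadata[match(rownames(counts), metadata$sample_id), ]
  if (mode == "proportions") {
    tot <- rowSums(counts)
    if (any(abs(tot - 1) > 1e-9)) {
      stop("proportion rows must sum to 1.", call. = FALSE)
    }
  }
  structure(list(counts = counts, taxonomy = taxonomy, metadata = metadata,
                 mode = mode),
            class = "taxa_table")
}

#' @export
print.taxa_table <- function(x, ...) {
  cat("taxa_table (", x$mode, "): ", nrow(x$counts), " samples x ",
      ncol(x$counts), " taxa\n", sep = "")
  cat("  groups:", paste(unique(x$metadata$group), collapse = ", "), "\n")
  cat("  timepoints (h):",
      paste(sort(unique(x$metadata$time_h)), collapse = ", "), "\n")
  invisible(x)
}

#' Read a taxa table from its three TSV files
#'
#' `counts_path`: taxa as rows, first column `taxon_id`, one column per
#' sample. `taxonomy_path`: `taxon_id <TAB> lineage` with
#' semicolon-separated ranks. `metadata_path`:
#' `sample_id <TAB> group <TAB> time_h`. Sample IDs must be consistent:
#' a counts sample without metadata is a hard error naming the offenders.
#'
#' @param counts_path,taxonomy_path,metadata_path File paths.
#' @return A [taxa_table()] in counts mode.
#' @export
read_taxa_table <- function(counts_path, taxonomy_path, metadata_path) {
  raw <- readr::read_tsv(counts_path, show_col_types = FALSE,
                         progress = FALSE)
  if (names(raw)[1] != "taxon_id") {
    stop("counts file must have `taxon_id` as its first column.",
         call. = FALSE)
  }
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- raw$taxon_id
  taxonomy <- readr::read_tsv(taxonomy_path, show_col_types = FALSE,
                              progress = FALSE,
                              col_types = readr::cols(.default = "c"))
  metadata <- readr::read_tsv(metadata_path, show_col_types = FALSE,
                              progress = FALSE)
  taxa_table(t(m), taxonomy = taxonomy, metadata = metadata)
}

#' Write a taxa table to its three TSV files
#'
#' @param tt A [taxa_table()].
#' @param counts_path,taxonomy_path,metadata_path Output paths.
#' @return `counts_path`, invisibly.
#' @export
write_taxa_table <- function(tt, counts_path, taxonomy_path, metadata_path) {
  stopifnot(inherits(tt, "taxa_table"))
  counts <- tibble::as_tibble(t(tt$counts), rownames = "taxon_id")
  readr::write_tsv(counts, counts_path, progress = FALSE)
  readr::write_tsv(tt$taxonomy, taxonomy_path, progress = FALSE)
  readr::write_tsv(tt$metadata, metadata_path, progress = FALSE)
  invisible(counts_path)
}

# Rank label per taxon; unassigned ranks fall into "unclassified_<parent>".
rank_labels <- function(tt, rank, ranks = default_ranks) {
  rank <- match.arg(rank, ranks)
  idx <- match(rank, ranks)
  vapply(tt$taxonomy$lineage, function(lin) {
    if (is.na(lin) || !nzchar(lin)) return("unclassified")
    parts <- trimws(strsplit(lin, ";", fixed = TRUE)[[1]])
    if (length(parts) >= idx && nzchar(parts[idx])) return(parts[idx])
    above <- parts[seq_len(min(idx - 1, length(parts)))]
    above <- above[nzchar(above)]
    if (length(above)) paste0("unclassified_", above[length(above)])
    else "unclassified"
  }, character(1), USE.NAMES = FALSE)
}

#' Aggregate taxa at a taxonomic rank
#'
#' Sums counts over taxa sharing the label at `rank` (e.g. all genera of
#' one phylum); per-sample totals are conserved exactly. Taxa lacking the
#' rank are pooled as `unclassified_<nearest named parent>`.
#'
#' @param tt A [taxa_table()].
#' @param rank One of kingdom, phylum, class, order, family, genus,
#'   species.
#' @return A [taxa_table()] whose taxa are the rank labels (lineages
#'   truncated at `rank`).
#' @export
aggregate_rank <- function(tt, rank) {
  stopifnot(inherits(tt, "taxa_table"))
  rank <- match.arg(rank, default_ranks)
  labels <- rank_labels(tt, rank)
  idx <- match(rank, default_ranks)
  agg <- t(rowsum(t(tt$counts), group = labels))
  lineage <- vapply(split(tt$taxonomy$lineage, labels), function(lins) {
    lin <- lins[!is.na(lins)][1]
    if (is.na(lin)) return(NA_character_)
    parts <- trimws(strsplit(lin, ";", fixed = TRUE)[[1]])
    paste(parts[seq_len(min(idx, length(parts)))], collapse = ";")
  }, character(1))
  taxa_table(agg,
             taxonomy = tibble::tibble(taxon_id = colnames(agg),
                                       lineage = unname(lineage[colnames(agg)])),
             metadata = tt$metadata, mode = tt$mode)
}

#' Convert counts to per-sample relative abundances
#'
#' Divides each sample's counts by its total so rows sum to 1. A
#' zero-total sample cannot be normalized and is a hard error naming it.
#'
#' @param tt A [taxa_table()] in counts mode.
#' @return A [taxa_table()] in proportions mode.
#' @export
relative_abundance <- function(tt) {
  stopifnot(inherits(tt, "taxa_table"))
  if (tt$mode == "proportions") {
    stop("table is already in proportions mode.", call. = FALSE)
  }
  tot <- rowSums(tt$counts)
  if (any(tot == 0)) {
    stop("zero-total sample(s): ",
         paste(rownames(tt$counts)[tot == 0], collapse = ", "),
         call. = FALSE)
  }
  taxa_table(tt$counts / tot, taxonomy = tt$taxonomy,
             metadata = tt$metadata, mode = "proportions")
}

#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{BC(u, v) = \sum_i |u_i - v_i| / \sum_i (u_i + v_i)}, computed by
#' `vegan::vegdist(method = "bray")` on the sample-by-taxon matrix.
#' Entries lie in \[0, 1\]: 0 for identical samples, 1 for disjoint
#' supports. All-zero samples have no defined dissimilarity and raise an
#' error.
#'
#' @param tt A [taxa_table()] (counts or proportions).
#' @return A `dist` object labeled by sample ID.
#' @export
bray_curtis <- function(tt) {
  stopifnot(inherits(tt, "taxa_table"))
  tot <- rowSums(tt$counts)
  if (any(tot == 0)) {
    stop("Bray-Curtis undefined for all-zero sample(s): ",
         paste(rownames(tt$counts)[tot == 0], collapse = ", "),
         call. = FALSE)
  }
  vegan::vegdist(tt$counts, method = "bray")
}

#' PERMANOVA on a dissimilarity matrix
#'
#' One-way permutational multivariate analysis of variance: the pseudo-F
#' compares among-group to within-group sums of squared dissimilarities,
#' \eqn{F = (SS_A/(a-1)) / (SS_W/(n-a))} with
#' \eqn{SS_T = \frac{1}{n}\sum_{i<j} d_{ij}^2} and
#' \eqn{SS_W = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d_{ij}^2}. The p-value
#' is \eqn{(1 + \#\{F^* \ge F\}) / (1 + n_{perm})} over seeded random
#' relabelings, so it is never exactly zero and is bit-reproducible given
#' `(dist, labels, n_perm, seed)`.
#'
#' @param dist A `dist` object or square symmetric matrix.
#' @param labels Group labels, one per sample, in `dist` order; at least
#'   two groups with two samples each.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed driving the permutation stream.
#' @return A one-row tibble: `kind = "permanova"`, `statistic` (pseudo-F),
#'   `df1`, `df2`, `p`, `n_perm`.
#' @export
permanova_test <- function(dist, labels, n_perm = 999, seed = 1) {
  d2 <- as.matrix(dist)^2
  n <- nrow(d2)
  labels <- as.character(labels)
  if (length(labels) != n) {
    stop("`labels` must have one entry per sample.", call. = FALSE)
  }
  tab <- table(labels)
  if (length(tab) < 2 || any(tab < 2)) {
    stop("need >= 2 groups with >= 2 samples each.", call. = FALSE)
  }
  if (n_perm < 1) stop("`n_perm` must be >= 1.", call. = FALSE)
  a <- length(tab)

  sst <- sum(d2[upper.tri(d2)]) / n
  ssw_of <- function(lab) {
    sum(vapply(unique(lab), function(g) {
      idx <- which(lab == g)
      sum(d2[idx, idx][upper.tri(d2[idx, idx, drop = FALSE])]) / length(idx)
    }, numeric(1)))
  }
  pseudo_f <- function(lab) {
    ssw <- ssw_of(lab)
    ((sst - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- pseudo_f(labels)
  f_perm <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(i) pseudo_f(sample(labels)), numeric(1))
  })
  res <- test_result("permanova", f_obs, a - 1, n - a,
                     (1 + sum(f_perm >= f_obs)) / (1 + n_perm))
  res$n_perm <- n_perm
  res
}

#' Per-taxon cosinor rhythm analysis of a community
#'
#' Converts counts to relative abundances (optionally after aggregation at
#' a rank), melts the proportions into a long cohort with the taxon as the
#' feature, and runs [cosinor_rhythms()]: per-group cosinor fits and
#' zero-amplitude tests, two-group comparisons when applicable, and BH
#' adjustment across taxa. Working on proportions makes the analysis
#' invariant to library-size differences. Cosinor runs on the raw
#' proportion scale by default; `transform = "asinsqrt"` applies the
#' variance-stabilizing arcsine-square-root first.
#'
#' @param tt A [taxa_table()].
#' @param period Cosinor period in hours (default 24).
#' @param alpha Threshold for the `rhythmic` flag on unadjusted p
#'   (default 0.05).
#' @param rank Optional rank to aggregate at first (e.g. `"genus"`).
#' @param flag_alpha Threshold on BH-adjusted p for the stringent
#'   `flagged` column (default 0.01, the usual cutoff for compositional
#'   16S screens).
#' @param transform `"none"` (default) or `"asinsqrt"`.
#' @return The [cosinor_rhythms()] tibble (feature = taxon) plus a
#'   `flagged` column (`zero_amplitude_q < flag_alpha`).
#' @export
taxa_rhythms <- function(tt, period = 24, alpha = 0.05, rank = NULL,
                         flag_alpha = 0.01,
                         transform = c("none", "asinsqrt")) {
  stopifnot(inherits(tt, "taxa_table"))
  transform <- match.arg(transform)
  if (!is.null(rank)) tt <- aggregate_rank(tt, rank)
  if (tt$mode == "counts") tt <- relative_abundance(tt)
  cohort <- tibble::as_tibble(tt$counts, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "feature",
                        values_to = "value") |>
    dplyr::inner_join(tt$metadata, by = "sample_id") |>
    dplyr::rename(subject_id = "sample_id") |>
    dplyr::select(dplyr::all_of(cohort_cols))
  if (transform == "asinsqrt") cohort$value <- asin(sqrt(cohort$value))
  res <- cosinor_rhythms(cohort, period = period, alpha = alpha)
  res$flagged <- !is.na(res$zero_amplitude_q) &
    res$zero_amplitude_q < flag_alpha
  res
}
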