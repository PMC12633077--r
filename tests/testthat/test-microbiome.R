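small_taxa_table <- function() {
  counts <- matrix(c(5, 7, 0, 3,
                     2, 3, 5, 0,
                     1, 1, 1, 1), nrow = 3, byrow = TRUE,
                   dimnames = list(c("s1", "s2", "s3"),
                                   c("taxA", "taxB", "taxC", "taxD")))
  taxonomy <- tibble::tibble(
    taxon_id = c("taxA", "taxB", "taxC", "taxD"),
    lineage = c("Bacteria;Bacteroidota;Bacteroidia;Bacteroidales;Bacteroidaceae;Bacteroides",
                "Bacteria;Bacteroidota;Bacteroidia;Bacteroidales;Bacteroidaceae;Bacteroides",
                "Bacteria;Bacillota;Clostridia;Eubacteriales;Lachnospiraceae",
                "Bacteria;Pseudomonadota"))
  metadata <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                             group = c("WT", "WT", "KO"),
                             time_h = c(2, 14, 2))
  taxa_table(counts, taxonomy, metadata)
}

test_that("taxa_table joins counts, taxonomy and metadata", {
  tt <- small_taxa_table()
  expect_equal(dim(tt$counts), c(3, 4))
  expect_equal(tt$metadata$sample_id, rownames(tt$counts))
  expect_equal(tt$taxonomy$taxon_id, colnames(tt$counts))
})

test_that("a counts sample without metadata is a hard error naming it", {
  tt <- small_taxa_table()
  expect_error(
    taxa_table(tt$counts, tt$taxonomy, tt$metadata[-2, ]),
    "samples without metadata: s2")
  expect_error(taxa_table(-tt$counts, tt$taxonomy, tt$metadata),
               "nonnegative")
})

test_that("three-file round trip preserves counts exactly", {
  comm <- demo_community(6, osc_taxon = 1, osc_amp = 0.05)
  tt <- simulate_microbiome(comm, groups = c("WT", "KO"), n_per_cell = 3,
                            seed = 21)
  fc <- withr::local_tempfile(fileext = ".tsv")
  ft <- withr::local_tempfile(fileext = ".tsv")
  fm <- withr::local_tempfile(fileext = ".tsv")
  write_taxa_table(tt, fc, ft, fm)
  back <- read_taxa_table(fc, ft, fm)
  expect_equal(back$counts[rownames(tt$counts), colnames(tt$counts)],
               tt$counts)
  expect_equal(back$taxonomy, tt$taxonomy)
})

test_that("rank aggregation is additive and conserves sample totals", {
  tt <- small_taxa_table()
  gen <- aggregate_rank(tt, "genus")
  # two Bacteroides taxa with counts 5 and 7 in s1 pool to 12
  expect_equal(gen$counts["s1", "Bacteroides"], 12)
  # missing genus ranks bucket under the nearest named parent
  expect_true("unclassified_Lachnospiraceae" %in% colnames(gen$counts))
  expect_true("unclassified_Pseudomonadota" %in% colnames(gen$counts))
  expect_equal(rowSums(gen$counts), rowSums(tt$counts))
  phy <- aggregate_rank(tt, "phylum")
  expect_setequal(colnames(phy$counts),
                  c("Bacteroidota", "Bacillota", "Pseudomonadota"))
  expect_error(aggregate_rank(tt, "serovar"))
})

test_that("aggregation at the finest present rank is near-identity and random fixtures conserve", {
  comm <- demo_community(8)
  tt <- simulate_microbiome(comm, n_per_cell = 3, seed = 22)
  gen <- aggregate_rank(tt, "genus")   # lineages end at genus
  expect_equal(sort(colnames(gen$counts)), sort(colnames(tt$counts)))
  expect_equal(gen$counts[, colnames(tt$counts)], tt$counts)
  for (rank in c("phylum", "family")) {
    agg <- aggregate_rank(tt, rank)
    expect_identical(unname(rowSums(agg$counts)),
                     unname(rowSums(tt$counts)))
  }
})

test_that("relative abundance normalizes rows and is invertible", {
  tt <- small_taxa_table()
  ra <- relative_abundance(tt)
  expect_equal(unname(ra$counts["s1", ]), c(5, 7, 0, 3) / 15)
  expect_equal(unname(rowSums(ra$counts)), rep(1, 3))
  expect_identical(ra$mode, "proportions")
  back <- ra$counts * rowSums(tt$counts)
  expect_equal(back, tt$counts)
  expect_error(relative_abundance(ra), "already")
  zero <- tt
  zero$counts["s2", ] <- 0
  expect_error(relative_abundance(zero), "zero-total sample\\(s\\): s2")
})

test_that("Bray-Curtis matches the hand formula and is a bounded semimetric", {
  counts <- rbind(s1 = c(2, 1), s2 = c(1, 1), s3 = c(2, 1),
                  s4 = c(0, 5))
  colnames(counts) <- c("t1", "t2")
  tt <- taxa_table(counts,
                   tibble::tibble(taxon_id = c("t1", "t2"),
                                  lineage = c("B;P1", "B;P2")),
                   tibble::tibble(sample_id = rownames(counts),
                                  group = "WT", time_h = c(2, 6, 10, 14)))
  d <- as.matrix(bray_curtis(tt))
  expect_equal(d["s1", "s2"], 0.2)            # sum|diff|=1, sum=5
  expect_equal(d["s1", "s3"], 0)              # identical samples
  dm <- matrix(c(4, 0, 0, 9), nrow = 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("t1", "t2")))
  disjoint <- taxa_table(dm,
                         tibble::tibble(taxon_id = c("t1", "t2"),
                                        lineage = c("B;P1", "B;P2")),
                         tibble::tibble(sample_id = c("a", "b"),
                                        group = "WT", time_h = c(2, 6)))
  expect_equal(as.matrix(bray_curtis(disjoint))["a", "b"], 1)
  # semimetric properties + invariance to joint taxon permutation
  comm <- demo_community(7)
  big <- simulate_microbiome(comm, n_per_cell = 3, seed = 23)
  m <- as.matrix(bray_curtis(big))
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, nrow(m)))
  expect_true(all(m >= 0 & m <= 1))
  perm <- sample(ncol(big$counts))
  shuf <- big
  shuf$counts <- big$counts[, perm]
  shuf$taxonomy <- big$taxonomy[perm, ]
  expect_equal(as.matrix(bray_curtis(shuf)), m)
  zero <- big
  zero$counts[3, ] <- 0
  expect_error(bray_curtis(zero), "all-zero")
})

test_that("PERMANOVA pseudo-F matches vegan and enumeration on 3+3", {
  comm <- demo_community(5)
  tt <- simulate_microbiome(comm, groups = c("WT", "KO"),
                            timepoints = c(2, 14), n_per_cell = 2,
                            concentration = 30, seed = 24)
  # perturb one group so the statistic is not degenerate
  tt$counts[tt$metadata$group == "KO", 1] <-
    tt$counts[tt$metadata$group == "KO", 1] + 500L
  keep <- c(which(tt$metadata$group == "WT")[1:3],
            which(tt$metadata$group == "KO")[1:3])
  d <- stats::as.dist(as.matrix(bray_curtis(tt))[keep, keep])
  labels <- tt$metadata$group[keep]

  res <- permanova_test(d, labels, n_perm = 19999, seed = 1)
  f_vegan <- vegan::adonis2(d ~ g,
                            data = data.frame(g = labels))$F[1]
  expect_equal(res$statistic, f_vegan, tolerance = 1e-10)
  expect_equal(res$statistic, oracle_pseudo_f(d, labels), tolerance = 1e-10)

  p_enum <- oracle_perm_enum_p(d, labels)
  expect_lt(abs(res$p - p_enum), 0.01)
  # bit-reproducibility of the permutation stream
  expect_identical(permanova_test(d, labels, n_perm = 99, seed = 7)$p,
                   permanova_test(d, labels, n_perm = 99, seed = 7)$p)
  expect_error(permanova_test(d, c(labels[-1], "X"), 99, 1), ">= 2")
})

test_that("PERMANOVA p is uniform under a random-label null", {
  comm <- demo_community(5)
  ps <- vapply(1:400, function(i) {
    tt <- simulate_microbiome(comm, groups = "WT",
                              timepoints = c(2, 8, 14, 20), n_per_cell = 3,
                              concentration = 50, seed = 80000 + i)
    d <- bray_curtis(tt)
    labels <- withr::with_seed(90000 + i,
                               sample(rep(c("A", "B"), each = 6)))
    permanova_test(d, labels, n_perm = 99, seed = i)$p
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("strongly separated groups saturate the permutation p", {
  comm <- dplyr::bind_rows(
    dplyr::mutate(demo_community(5), group = "WT"),
    dplyr::mutate(demo_community(5),
                  baseline = rev(baseline), group = "KO")
  )
  tt <- simulate_microbiome(comm, groups = c("WT", "KO"), n_per_cell = 3,
                            concentration = 500, seed = 26)
  res <- permanova_test(bray_curtis(tt), tt$metadata$group,
                        n_perm = 999, seed = 2)
  expect_equal(res$p, 1 / (1 + 999))
})

test_that("a spiked oscillating genus is ranked first among flat taxa", {
  comm <- demo_community(21, osc_taxon = 3, osc_amp = 0.05, osc_acro = 19)
  hits <- vapply(1:100, function(i) {
    tt <- simulate_microbiome(comm, n_per_cell = 4, concentration = 300,
                              seed = 100000 + i)
    res <- taxa_rhythms(tt)
    res$feature[which.min(res$zero_amplitude_p)] == "genus_03"
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("an all-flat community rejects at close to the nominal rate", {
  comm <- demo_community(20)
  rate <- mean(vapply(1:100, function(i) {
    tt <- simulate_microbiome(comm, n_per_cell = 4, concentration = 300,
                              seed = 110000 + i)
    res <- taxa_rhythms(tt)
    mean(res$zero_amplitude_p < 0.05)
  }, numeric(1)))
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("a 12-h acrophase shift in one genus survives BH flagging", {
  base <- demo_community(12, osc_taxon = 3, osc_amp = 0.06, osc_acro = 19)
  comm <- dplyr::bind_rows(
    dplyr::mutate(base, group = "WT"),
    dplyr::mutate(base, group = "KO",
                  acrophase_h = ifelse(taxon_id == "genus_03", 7,
                                       acrophase_h))
  )
  hits <- vapply(1:60, function(i) {
    tt <- simulate_microbiome(comm, groups = c("WT", "KO"), n_per_cell = 4,
                              concentration = 300, seed = 120000 + i)
    res <- taxa_rhythms(tt)
    q <- res$acrophase_test_q[res$feature == "genus_03"][1]
    !is.na(q) && q < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.80)
})

test_that("taxa rhythms are invariant to library-size rescaling", {
  comm <- demo_community(6, osc_taxon = 2, osc_amp = 0.04)
  tt <- simulate_microbiome(comm, groups = c("WT", "KO"), n_per_cell = 3,
                            concentration = 200, lib_sdlog = 0, seed = 27)
  scaled <- tt
  scaled$counts <- tt$counts * 17
  r1 <- taxa_rhythms(tt)
  r2 <- taxa_rhythms(scaled)
  expect_equal(as.data.frame(r2), as.data.frame(r1), tolerance = 1e-12)
})
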