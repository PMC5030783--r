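test_that("common-OTU filter keeps exactly the everywhere-present OTUs", {
  tab <- toy_otu_dataset()
  f <- filter_common_otus(tab)
  # OTU4 has a zero in S01.T0
  expect_setequal(colnames(f$counts), c("OTU1", "OTU2", "OTU3"))
  expect_equal(rownames(f$counts), rownames(tab$counts))

  # brute-force scan on a simulated table
  sim <- generate_paired_otu_table(otu_sim_params(n_subjects = 8, seed = 5))
  f2 <- filter_common_otus(sim)
  brute <- colnames(sim$counts)[vapply(seq_len(ncol(sim$counts)), function(j) {
    min(sim$counts[, j]) > 0
  }, logical(1))]
  expect_setequal(colnames(f2$counts), brute)

  # independent of OTU and sample ordering
  perm <- sim
  o <- sample(ncol(perm$counts)); s <- sample(nrow(perm$counts))
  perm <- otu_dataset(perm$counts[s, o], perm$taxonomy[o],
                      perm$metadata[s, ])
  f3 <- filter_common_otus(perm)
  expect_setequal(colnames(f3$counts), colnames(f2$counts))
})

test_that("relative abundance normalizes each sample to 100", {
  tab <- toy_otu_dataset()
  rel <- relative_abundance(tab)
  expect_equal(unname(rel["S01.T0", ]), c(20, 30, 50, 0))
  expect_equal(unname(rowSums(rel)), rep(100, 4), tolerance = 1e-9)

  zero <- tab
  zero$counts["S01.T0", ] <- 0L
  expect_error(relative_abundance(zero), "S01.T0")
})

test_that("taxonomy collapse sums counts and conserves totals", {
  tab <- toy_otu_dataset()
  ph <- collapse_taxonomy(tab, "phylum")
  expect_setequal(colnames(ph$counts), c("Actinobacteria", "Firmicutes", "Other"))
  # two Firmicutes OTUs summed
  expect_equal(unname(ph$counts[, "Firmicutes"]),
               unname(tab$counts[, "OTU1"] + tab$counts[, "OTU2"]))
  # unassigned-at-rank pools into Other
  expect_equal(unname(ph$counts[, "Other"]), unname(tab$counts[, "OTU4"]))
  # conservation at every rank
  for (rank in c("phylum", "class", "order", "family", "genus")) {
    col <- collapse_taxonomy(tab, rank)
    expect_equal(rowSums(col$counts), rowSums(tab$counts))
  }
})

test_that("malformed taxonomy routes to Other with a warning, not dropped", {
  tab <- toy_otu_dataset()
  tab$taxonomy["OTU3"] <- "not a lineage"
  expect_warning(ph <- collapse_taxonomy(tab, "phylum"), "malformed")
  expect_equal(rowSums(ph$counts), rowSums(tab$counts))
  expect_equal(unname(ph$counts[, "Other"]),
               unname(tab$counts[, "OTU3"] + tab$counts[, "OTU4"]))
})

test_that("paired Wilcoxon matches enumeration and handles degenerate input", {
  # n = 6, all differences positive, no ties
  expect_equal(paired_wilcoxon(rep(0, 6), c(1, 2, 3, 4, 5, 6)), 2 / 64)
  # all-zero differences
  expect_warning(p <- paired_wilcoxon(c(1, 2), c(1, 2)), "zero")
  expect_equal(p, 1)
  # antisymmetry of the two-sided p
  d <- c(0.3, -1.2, 2.5, 0.7, -0.4, 1.9, 0.05, -2.2)
  expect_equal(paired_wilcoxon(rep(0, 8), d), paired_wilcoxon(rep(0, 8), -d))
  # unpaired subjects are skipped by name
  t0 <- c(S1 = 1, S2 = 2, S3 = 3)
  t3 <- c(S1 = 4, S2 = 0, S4 = 9)
  expect_warning(p2 <- paired_wilcoxon(t0, t3), "unpaired")
  expect_equal(p2, paired_wilcoxon(c(1, 2), c(4, 0)))
})

test_that("exact p agrees with the independent exact reference", {
  set.seed(19)
  for (i in 1:25) {
    n <- sample(3:10, 1)
    d <- round(runif(n, -5, 5), 3)
    d <- d[d != 0]
    if (length(d) < 2 || any(duplicated(abs(d)))) next
    ours <- paired_wilcoxon(rep(0, length(d)), d)
    ref <- stats::wilcox.test(d, exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("approximate path uses the tie-corrected normal without continuity", {
  set.seed(23)
  d <- c(rep(1.5, 4), rep(-2.5, 3), round(runif(13, -4, 4), 1))
  d <- d[d != 0]
  ours <- paired_wilcoxon(rep(0, length(d)), d, exact_max = 0)
  ref <- stats::wilcox.test(d, exact = FALSE, correct = FALSE)$p.value
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("Bonferroni adjustment multiplies, caps and preserves order", {
  expect_equal(bonferroni_adjust(0.0007, m = 6), 0.0042)
  expect_equal(bonferroni_adjust(0.5, m = 6), 1)
  expect_equal(bonferroni_adjust(c(0.2, 0.03)), c(0.4, 0.06))
  p <- c(0.001, 0.04, 0.2, 0.9)
  adj <- bonferroni_adjust(p, m = 4)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj) >= 0))
  expect_error(bonferroni_adjust(1.4), "0, 1")
})

test_that("log2 fold change excludes zero-mean OTUs and is antisymmetric", {
  tab <- toy_otu_dataset()
  fc <- log2_fold_change(tab)
  # OTU4 mean at T0 is (0 + 2)/2 = 1 > 0, so everything is retained here
  expect_equal(nrow(fc$excluded), 0)
  otu1 <- fc$result[fc$result$otu_id == "OTU1", ]
  expect_equal(otu1$log2fc, log2(mean(c(4, 6)) / mean(c(2, 1))))

  # force a zero mean at T3
  tab$counts[c("S01.T3", "S02.T3"), "OTU3"] <- 0L
  fc2 <- log2_fold_change(tab)
  expect_equal(fc2$excluded$otu_id, "OTU3")
  expect_match(fc2$excluded$reason, "T3")

  # swapping labels negates every retained value
  swapped <- tab
  swapped$metadata$timepoint <- ifelse(swapped$metadata$timepoint == "T0",
                                       "T3", "T0")
  fc3 <- log2_fold_change(swapped)
  both <- merge(fc2$result, fc3$result, by = "otu_id")
  expect_equal(both$log2fc.x, -both$log2fc.y)

  # identical means give exactly zero
  same <- toy_otu_dataset()
  same$counts["S01.T3", ] <- same$counts["S01.T0", ]
  same$counts["S02.T3", ] <- same$counts["S02.T0", ]
  fc4 <- log2_fold_change(same)
  expect_true(all(fc4$result$log2fc == 0))
})

test_that("shift summary applies the stated quantile convention", {
  expect_equal(unname(quantile(1:5, c(0.25, 0.75), type = 6)), c(1.5, 4.5))
  sim <- generate_paired_otu_table(otu_sim_params(n_subjects = 9, seed = 2))
  s <- summarize_shifts(sim, "phylum")
  expect_true(all(s$q25_t0 <= s$median_t0 & s$median_t0 <= s$q75_t0))
  expect_true(all(s$p_adjusted == pmin(1, s$m * s$p_raw)))
  expect_equal(attr(s, "quantile_type"), 6L)
  expect_equal(attr(s, "m"), nrow(s))
  # the quartiles are those of the per-subject relative abundances
  rel <- relative_abundance(collapse_taxonomy(sim, "phylum"))
  v0 <- rel[sim$metadata$timepoint == "T0", "Firmicutes"]
  expect_equal(s$median_t0[s$taxon == "Firmicutes"],
               unname(quantile(v0, 0.5, type = 6)))
})

test_that("identical T0 and T3 matrices give p = 1 everywhere", {
  tab <- toy_otu_dataset()
  tab$counts["S01.T3", ] <- tab$counts["S01.T0", ]
  tab$counts["S02.T3", ] <- tab$counts["S02.T0", ]
  s <- summarize_shifts(tab, "phylum")
  expect_true(all(s$p_raw == 1))
})

test_that("a strong compositional shift is detected with high power", {
  taxa <- tiny_taxa(p_t0 = c(98, 1), p_t3 = c(88, 9))
  hits <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    sim <- generate_paired_otu_table(
      otu_sim_params(n_subjects = 25, taxa = taxa, concentration = 300,
                     otus_per_taxon = 1, seed = 100 + r))
    s <- summarize_shifts(sim, "genus")
    if (s$p_adjusted[s$taxon == "Streptococcus"] < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("heat-map matrix pairs each subject's T0 and T3 columns", {
  sim <- generate_paired_otu_table(otu_sim_params(n_subjects = 2, seed = 4))
  hm <- heatmap_matrix(sim, min_relative_abundance = 2)
  expect_equal(hm$column_order,
               c("S01.T0", "S01.T3", "S02.T0", "S02.T3"))
  # logarithmic scaling of percentages
  rel <- relative_abundance(collapse_taxonomy(sim, "genus"))
  g <- hm$genera[1]
  expect_equal(hm$matrix[g, "S01.T0"], log10(1 + rel["S01.T0", g]))
  # threshold 0 keeps every genus; impossible threshold empties the matrix
  hm0 <- heatmap_matrix(sim, min_relative_abundance = 0)
  expect_equal(length(hm0$genera),
               ncol(collapse_taxonomy(sim, "genus")$counts))
  expect_warning(hm100 <- heatmap_matrix(sim, min_relative_abundance = 100),
                 "threshold")
  expect_equal(nrow(hm100$matrix), 0)
})
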