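# Paired T0-vs-T3 compositional-shift analysis of OTU count tables.

#' Retain OTUs present in every sample
#'
#' The common-OTU filter: keeps exactly the OTUs with a non-zero count in
#' every sample of the table; the sample set is unchanged. The result does
#' not depend on OTU or sample ordering.
#'
#' @param table An [otu_dataset()].
#' @return The filtered `otu_dataset`.
#' @export
filter_common_otus <- function(table) {
  stopifnot(is.otu_dataset(table))
  if (nrow(table$counts) == 0) stop("table has no samples")
  keep <- apply(table$counts > 0, 2, all)
  otu_dataset(table$counts[, keep, drop = FALSE], table$taxonomy[keep],
              table$metadata)
}

#' Relative abundance matrix in percent
#'
#' `100 * count / sample total` per cell; each sample's values sum to 100.
#'
#' @param table An [otu_dataset()].
#' @return Numeric matrix (samples x OTUs) of percentages.
#' @export
relative_abundance <- function(table) {
  stopifnot(is.otu_dataset(table))
  totals <- rowSums(table$counts)
  zero <- totals == 0
  if (any(zero)) {
    stop("sample(s) with zero total counts: ",
         paste(rownames(table$counts)[zero], collapse = ", "))
  }
  sweep(table$counts, 1, totals, "/") * 100
}

#' Collapse an OTU table to a taxonomic rank
#'
#' Sums counts over OTUs sharing the same label at `rank`. OTUs without an
#' assignment at that rank (empty field, e.g. `p__`) pool into a taxon named
#' `"Other"`; OTUs with malformed taxonomy strings are routed to `"Other"`
#' with a warning, never dropped, so per-sample totals are conserved at
#' every rank.
#'
#' @param table An [otu_dataset()].
#' @param rank One of `"phylum"`, `"class"`, `"order"`, `"family"`,
#'   `"genus"`.
#' @return An `otu_dataset` whose columns are taxa at the requested rank
#'   (taxonomy strings reduced to the rank label).
#' @export
collapse_taxonomy <- function(table, rank) {
  stopifnot(is.otu_dataset(table))
  rank <- match.arg(rank, c("phylum", "class", "order", "family", "genus"))
  labels <- vapply(table$taxonomy, taxon_at_rank, character(1), rank = rank)
  malformed <- is.na(labels)
  if (any(malformed)) {
    warning(sprintf("%d OTU(s) with malformed taxonomy routed to 'Other'",
                    sum(malformed)))
  }
  labels[malformed | labels == ""] <- "Other"
  taxa <- unique(labels)
  # deterministic order: alphabetical with "Other" last
  taxa <- c(sort(setdiff(taxa, "Other")), intersect("Other", taxa))
  collapsed <- vapply(taxa, function(tx) {
    rowSums(table$counts[, labels == tx, drop = FALSE])
  }, numeric(nrow(table$counts)))
  collapsed <- matrix(as.integer(collapsed), nrow = nrow(table$counts),
                      dimnames = list(rownames(table$counts), taxa))
  otu_dataset(collapsed, structure(taxa, names = taxa), table$metadata)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on per-subject T0-vs-T3 differences. Zero
#' differences are discarded before ranking (classic zero-handling, not
#' Pratt); ties receive average ranks. When the number of non-zero
#' differences is at most `exact_max` and there are no ties in their
#' absolute values, the exact null distribution of the rank sum is computed
#' by convolution over the sign assignments; otherwise a normal
#' approximation with tie-corrected variance (and no continuity correction)
#' is used.
#'
#' @param t0,t3 Numeric vectors of per-subject values. Pairing is by the
#'   vectors' names when both are named, otherwise by position.
#' @param exact_max Largest number of non-zero differences for which the
#'   exact distribution is enumerated (default 12).
#' @return The two-sided p-value. All-zero differences give `p = 1` with a
#'   warning; subjects present in only one vector are skipped with a
#'   warning.
#' @export
#' @examples
#' paired_wilcoxon(rep(0, 6), 1:6) # all differences positive: 0.03125
paired_wilcoxon <- function(t0, t3, exact_max = 12L) {
  if (!is.null(names(t0)) && !is.null(names(t3))) {
    common <- intersect(names(t0), names(t3))
    skipped <- length(t0) + length(t3) - 2 * length(common)
    if (skipped > 0) {
      warning(sprintf("skipping %d unpaired subject value(s)", skipped))
    }
    t0 <- t0[common]; t3 <- t3[common]
  } else if (length(t0) != length(t3)) {
    stop("unnamed t0/t3 vectors must have equal length")
  }
  if (length(t0) < 1) stop("at least one complete pair is required")
  d <- t3 - t0
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; p = 1")
    return(1)
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= exact_max && !ties) {
    # exact distribution of W+ by convolution over the 2^n sign assignments
    m <- n * (n + 1) / 2
    f <- numeric(m + 1)
    f[1] <- 1
    for (ri in seq_len(n)) {
      g <- f
      g[(ri + 1):(m + 1)] <- g[(ri + 1):(m + 1)] + f[1:(m + 1 - ri)]
      f <- g
    }
    f <- f / 2^n
    p_le <- sum(f[seq_len(w + 1)])
    p_ge <- sum(f[(w + 1):(m + 1)])
    return(min(1, 2 * min(p_le, p_ge)))
  }
  tie_counts <- table(r)
  mu <- n * (n + 1) / 4
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_counts^3 - tie_counts) / 48
  z <- (w - mu) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

#' Bonferroni correction
#'
#' `min(1, m * p)` for each raw p-value; order-preserving and capped at 1.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @param m Number of tests (default `length(p)`).
#' @return Adjusted p-values.
#' @export
#' @examples
#' bonferroni_adjust(0.0007, m = 6) # 0.0042
bonferroni_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (m < 1) stop("m must be >= 1")
  pmin(1, m * p)
}

#' Log2 fold change of mean absolute abundance, T3 over T0
#'
#' Per OTU, the arithmetic mean of raw counts across T0 samples and across
#' T3 samples; OTUs whose mean is zero at either time point are excluded
#' (and listed), since their ratio is undefined. Retained OTUs get
#' `log2(mean_t3 / mean_t0)`, labeled by genus for display. A
#' relative-abundance mode is available; raw counts ("absolute abundances")
#' are the default.
#'
#' @param table An [otu_dataset()] with both time points.
#' @param mode `"counts"` (default) or `"relative"`.
#' @return List with `result` (data.frame: `otu_id`, `genus`, `mean_t0`,
#'   `mean_t3`, `log2fc`) and `excluded` (data.frame: `otu_id`, `reason`).
#' @export
log2_fold_change <- function(table, mode = c("counts", "relative")) {
  stopifnot(is.otu_dataset(table))
  mode <- match.arg(mode)
  tp <- table$metadata$timepoint
  if (!all(c("T0", "T3") %in% tp)) {
    stop("table must contain both T0 and T3 samples")
  }
  mat <- if (mode == "counts") table$counts else relative_abundance(table)
  mean_t0 <- colMeans(mat[tp == "T0", , drop = FALSE])
  mean_t3 <- colMeans(mat[tp == "T3", , drop = FALSE])
  zero <- mean_t0 == 0 | mean_t3 == 0
  genus <- vapply(table$taxonomy, function(tx) {
    g <- taxon_at_rank(tx, "genus")
    if (is.na(g) || g == "") "Other" else g
  }, character(1))
  result <- data.frame(
    otu_id = colnames(mat)[!zero], genus = unname(genus[!zero]),
    mean_t0 = unname(mean_t0[!zero]), mean_t3 = unname(mean_t3[!zero]),
    log2fc = log2(unname(mean_t3[!zero]) / unname(mean_t0[!zero])),
    stringsAsFactors = FALSE)
  excluded <- data.frame(
    otu_id = colnames(mat)[zero],
    reason = ifelse(mean_t0[zero] == 0 & mean_t3[zero] == 0,
                    "zero mean at both time points",
                    ifelse(mean_t0[zero] == 0, "zero mean at T0",
                           "zero mean at T3")),
    stringsAsFactors = FALSE)
  rownames(excluded) <- NULL
  list(result = result, excluded = excluded, mode = mode)
}

#' Median/quartile summaries and paired tests per taxon
#'
#' Collapses the table to `rank`, converts to relative abundance (percent),
#' and reports per taxon the 25th percentile, median and 75th percentile of
#' per-subject abundances at T0 and at T3, the raw two-sided
#' [paired_wilcoxon()] p-value, and the Bonferroni-adjusted p-value with
#' `m` = the number of taxa tested at this rank. Quantiles use linear
#' interpolation of order statistics with `p(k) = k / (n + 1)`
#' ([stats::quantile()] type 6, the convention of common commercial
#' statistics packages, under which `{1,...,5}` has quartiles 1.5 and 4.5);
#' the convention is recorded in the result's attributes.
#'
#' @param table An [otu_dataset()] with T0 and T3 samples.
#' @param rank Taxonomic rank to collapse to.
#' @return data.frame with one row per taxon: `taxon`, `q25_t0`,
#'   `median_t0`, `q75_t0`, `q25_t3`, `median_t3`, `q75_t3`, `p_raw`,
#'   `p_adjusted`, `m`. Attributes `quantile_type` (6), `zero_handling`
#'   (`"discard"`) and `m` record the conventions.
#' @export
summarize_shifts <- function(table, rank = "phylum") {
  stopifnot(is.otu_dataset(table))
  collapsed <- collapse_taxonomy(table, rank)
  rel <- relative_abundance(collapsed)
  meta <- collapsed$metadata
  taxa <- colnames(rel)
  m <- length(taxa)
  q <- function(v) quantile(v, c(0.25, 0.5, 0.75), type = 6, names = FALSE)
  rows <- lapply(taxa, function(tx) {
    v0 <- structure(rel[meta$timepoint == "T0", tx],
                    names = meta$subject[meta$timepoint == "T0"])
    v3 <- structure(rel[meta$timepoint == "T3", tx],
                    names = meta$subject[meta$timepoint == "T3"])
    q0 <- q(v0); q3 <- q(v3)
    p <- withCallingHandlers(
      paired_wilcoxon(v0, v3),
      warning = function(w) invokeRestart("muffleWarning"))
    data.frame(taxon = tx, q25_t0 = q0[1], median_t0 = q0[2], q75_t0 = q0[3],
               q25_t3 = q3[1], median_t3 = q3[2], q75_t3 = q3[3],
               p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bonferroni_adjust(out$p_raw, m)
  out$m <- m
  rownames(out) <- NULL
  attr(out, "quantile_type") <- 6L
  attr(out, "zero_handling") <- "discard"
  attr(out, "m") <- m
  out
}

#' Subject-paired heat-map matrix of genus-level relative abundance
#'
#' Rows are genera whose overall mean relative abundance exceeds
#' `min_relative_abundance` percent; columns are ordered subject by subject
#' with each subject's T0 immediately left of its T3. Cell values are
#' `log10(1 + relative abundance)` — a logarithmic scaling that tolerates
#' zeros.
#'
#' @param table An [otu_dataset()] with paired samples.
#' @param min_relative_abundance Display threshold in percent (default 2).
#' @return List with `matrix` (genera x samples, log-scaled), `column_order`
#'   (sample IDs as ordered), and `genera`. A threshold no genus passes
#'   gives an empty matrix with a warning.
#' @export
heatmap_matrix <- function(table, min_relative_abundance = 2) {
  stopifnot(is.otu_dataset(table))
  collapsed <- collapse_taxonomy(table, "genus")
  rel <- relative_abundance(collapsed)
  keep <- colMeans(rel) > min_relative_abundance
  meta <- collapsed$metadata
  subjects <- sort(unique(meta$subject))
  col_order <- unlist(lapply(subjects, function(s) {
    meta$sample[meta$subject == s][order(meta$timepoint[meta$subject == s])]
  }))
  if (!any(keep)) {
    warning("no genus exceeds the relative-abundance threshold")
    return(list(matrix = matrix(numeric(0), nrow = 0, ncol = length(col_order),
                                dimnames = list(NULL, col_order)),
                column_order = col_order, genera = character(0)))
  }
  mat <- t(log10(1 + rel[col_order, keep, drop = FALSE]))
  list(matrix = mat, column_order = col_order, genera = rownames(mat))
}
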