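# Paired T0/T3 OTU-count simulator.
#
# Emulates the sequencing arm of the study design: each subject contributes
# one sample directly after removal from the mouth (T0) and one after 48 h
# of reactor incubation (T3). Counts are Dirichlet-multinomial around
# time-point-specific base proportions, with per-sample read depths drawn
# uniformly from the observed depth range.

#' Default genus-level base composition for the OTU simulator
#'
#' Median phylum-level relative abundances of the supragingival biofilm at
#' T0 and T3, with the dominant phylum Firmicutes split into its leading
#' genera (Streptococcus and Veillonella together make up about two thirds
#' of the community) and the unclassifiable remainder pooled as "Other".
#' Proportions are in percent per time point; each column's shortfall from
#' 100 is added to "Other".
#'
#' @return data.frame with columns `taxon`, `lineage`, `p_t0`, `p_t3`
#'   (percent).
#' @export
default_base_composition <- function() {
  data.frame(
    taxon = c("Streptococcus", "Veillonella", "Gemella", "Lactobacillus",
              "Actinomyces", "Porphyromonas", "Fusobacterium", "Neisseria",
              "Other"),
    lineage = c(
      "k__Bacteria; p__Firmicutes; c__Bacilli; o__Lactobacillales; f__Streptococcaceae; g__Streptococcus; s__",
      "k__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales; f__Veillonellaceae; g__Veillonella; s__",
      "k__Bacteria; p__Firmicutes; c__Bacilli; o__Gemellales; f__Gemellaceae; g__Gemella; s__",
      "k__Bacteria; p__Firmicutes; c__Bacilli; o__Lactobacillales; f__Lactobacillaceae; g__Lactobacillus; s__",
      "k__Bacteria; p__Actinobacteria; c__Actinobacteria; o__Actinomycetales; f__Actinomycetaceae; g__Actinomyces; s__",
      "k__Bacteria; p__Bacteroidetes; c__Bacteroidia; o__Bacteroidales; f__Porphyromonadaceae; g__Porphyromonas; s__",
      "k__Bacteria; p__Fusobacteria; c__Fusobacteriia; o__Fusobacteriales; f__Fusobacteriaceae; g__Fusobacterium; s__",
      "k__Bacteria; p__Proteobacteria; c__Betaproteobacteria; o__Neisseriales; f__Neisseriaceae; g__Neisseria; s__",
      "k__Bacteria; p__; c__; o__; f__; g__; s__"),
    # Firmicutes phylum medians 98.67 (T0) and 87.71 (T3); genus shares kept
    # proportional across time points
    p_t0 = c(60.83, 13.38, 12.46, 12.00, 0.11, 0.01, 0.00, 0.00, 1.07),
    p_t3 = c(54.07, 11.89, 12.75, 9.00, 0.99, 3.20, 0.26, 2.06, 1.69),
    stringsAsFactors = FALSE)
}

#' Parameters for the paired OTU-table simulator
#'
#' @param n_subjects Number of subjects (>= 1); the cohort size of the study
#'   design is 25.
#' @param taxa data.frame with columns `taxon`, `lineage`, `p_t0`, `p_t3`
#'   (base relative abundances in percent; per time point the shortfall from
#'   100 is added to the `Other` row, which is created if absent).
#' @param concentration Dirichlet concentration controlling between-sample
#'   overdispersion; `Inf` gives pure multinomial sampling at the base
#'   proportions.
#' @param depth_range Integer range of per-sample read depths, drawn
#'   uniformly; default matches the observed per-sample OTU-level counts
#'   (1841 to 3863 reads).
#' @param otus_per_taxon OTUs per taxon; each taxon's proportion is split
#'   across its OTUs by fixed Dirichlet weights shared between time points.
#' @param seed Integer seed.
#' @return A validated `otu_sim_params` list.
#' @export
otu_sim_params <- function(n_subjects = 25L,
                           taxa = default_base_composition(),
                           concentration = 200,
                           depth_range = c(1841L, 3863L),
                           otus_per_taxon = 3L,
                           seed = 1L) {
  stopifnot(n_subjects >= 1)
  need <- c("taxon", "lineage", "p_t0", "p_t3")
  if (!all(need %in% names(taxa))) {
    stop("taxa must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(taxa) == 0) stop("taxon set must not be empty")
  if (any(taxa$p_t0 < 0 | taxa$p_t0 > 100 | taxa$p_t3 < 0 | taxa$p_t3 > 100)) {
    stop("base proportions must lie in [0, 100] percent")
  }
  if (sum(taxa$p_t0) > 100 + 1e-9 || sum(taxa$p_t3) > 100 + 1e-9) {
    stop("base proportions must sum to at most 100 percent per time point")
  }
  if (depth_range[1] > depth_range[2] || depth_range[1] < 1) {
    stop("depth_range must satisfy 1 <= min <= max")
  }
  if (otus_per_taxon < 1) stop("otus_per_taxon must be >= 1")
  if (concentration <= 0) stop("concentration must be positive (or Inf)")
  # route the per-time-point remainder to "Other"
  if (!"Other" %in% taxa$taxon) {
    taxa <- rbind(taxa, data.frame(
      taxon = "Other", lineage = "k__Bacteria; p__; c__; o__; f__; g__; s__",
      p_t0 = 0, p_t3 = 0, stringsAsFactors = FALSE))
  }
  i <- match("Other", taxa$taxon)
  taxa$p_t0[i] <- taxa$p_t0[i] + (100 - sum(taxa$p_t0))
  taxa$p_t3[i] <- taxa$p_t3[i] + (100 - sum(taxa$p_t3))
  structure(list(n_subjects = as.integer(n_subjects), taxa = taxa,
                 concentration = concentration,
                 depth_range = as.integer(depth_range),
                 otus_per_taxon = as.integer(otus_per_taxon),
                 seed = as.integer(seed)),
            class = "otu_sim_params")
}

rdirichlet1 <- function(alpha) {
  g <- vapply(alpha, function(a) if (a > 0) rgamma(1, a) else 0, numeric(1))
  s <- sum(g)
  if (s == 0) rep(0, length(alpha)) else g / s
}

#' Generate a paired T0/T3 OTU count table
#'
#' One T0 and one T3 sample per subject. Per sample, the read depth is
#' uniform on `depth_range`; OTU proportions are Dirichlet-distributed
#' around the time point's base proportions (concentration
#' `params$concentration`); counts are a multinomial draw. Taxa with base
#' proportion zero at both time points yield all-zero counts. Deterministic
#' for a fixed seed.
#'
#' @param params An [otu_sim_params()] object.
#' @return An [otu_dataset()] with `2 * n_subjects` samples.
#' @export
generate_paired_otu_table <- function(params = otu_sim_params()) {
  stopifnot(inherits(params, "otu_sim_params"))
  with_seed(params$seed, {
    taxa <- params$taxa
    n_tax <- nrow(taxa)
    k <- params$otus_per_taxon
    # fixed within-taxon OTU weights, shared between time points so each OTU
    # keeps its identity across the pairing
    weights <- lapply(seq_len(n_tax), function(i) rdirichlet1(rep(5, k)))
    otu_ids <- unlist(lapply(seq_len(n_tax), function(i) {
      sprintf("OTU_%s_%02d", gsub("[^A-Za-z0-9]", "", taxa$taxon[i]), seq_len(k))
    }))
    taxonomy <- structure(rep(taxa$lineage, each = k), names = otu_ids)
    base <- function(col) {
      p <- unlist(lapply(seq_len(n_tax), function(i) taxa[[col]][i] * weights[[i]]))
      p / 100
    }
    base_t0 <- base("p_t0"); base_t3 <- base("p_t3")

    subjects <- sprintf("S%02d", seq_len(params$n_subjects))
    sample_ids <- as.vector(t(outer(subjects, c("T0", "T3"), paste, sep = ".")))
    counts <- matrix(0L, nrow = length(sample_ids), ncol = length(otu_ids),
                     dimnames = list(sample_ids, otu_ids))
    meta <- data.frame(sample = sample_ids,
                       subject = rep(subjects, each = 2),
                       timepoint = rep(c("T0", "T3"), params$n_subjects),
                       stringsAsFactors = FALSE)
    for (i in seq_len(nrow(meta))) {
      p0 <- if (meta$timepoint[i] == "T0") base_t0 else base_t3
      depth <- if (params$depth_range[1] == params$depth_range[2]) {
        params$depth_range[1]
      } else {
        sample(seq(params$depth_range[1], params$depth_range[2]), 1)
      }
      p <- if (is.finite(params$concentration)) {
        rdirichlet1(params$concentration * p0)
      } else p0
      counts[i, ] <- as.integer(rmultinom(1, depth, if (sum(p) > 0) p else rep(1, length(p))))
    }
    otu_dataset(counts, taxonomy, meta)
  })
}
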