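# Independent oracles and fixture builders used across the suite.

# Exhaustive 1-D k-means oracle: minimum within-cluster SSE over all
# contiguous partitions of the sorted distinct values (optimal 1-D clusters
# are contiguous intervals). Weighted by value multiplicities.
brute_kmeans1d_sse <- function(values, k) {
  tab <- table(values)
  vals <- as.numeric(names(tab))
  w <- as.numeric(tab)
  d <- length(vals)
  k <- min(k, d)
  block_sse <- function(i, j) {
    v <- vals[i:j]; wt <- w[i:j]
    mu <- sum(wt * v) / sum(wt)
    sum(wt * (v - mu)^2)
  }
  if (k == d) return(0)
  best <- Inf
  cuts <- utils::combn(d - 1, k - 1)
  for (c in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, c], d)
    sse <- sum(vapply(seq_len(k), function(i) block_sse(b[i] + 1, b[i + 1]),
                      numeric(1)))
    best <- min(best, sse)
  }
  best
}

# Brute-force Wilcoxon signed-rank oracle: two-sided p by enumerating all
# 2^n sign assignments of the ranked absolute differences.
brute_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  m <- n * (n + 1) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mean(abs(w_all - m / 2) >= abs(w_obs - m / 2))
}

# quiet scene: zero noise, no bleed, uniform class intensities, so that the
# estimated fraction must equal the ground truth exactly
quiet_stack_params <- function(n_live = 80L, n_dead = 20L, n_double = 0L,
                               n_yeast = 0L, n_chains = 0L, seed = 1L, ...) {
  stack_sim_params(n_live = n_live, n_dead = n_dead, n_double = n_double,
                   n_yeast = n_yeast, n_chains = n_chains,
                   live_intensity = c(5000, 5000),
                   dead_intensity = c(5000, 5000),
                   double_intensity = c(5000, 5000),
                   noise_rate = 0, bleed_through = 0, seed = seed, ...)
}

# tiny two-taxon composition for fast OTU-table fixtures
tiny_taxa <- function(p_t0 = c(60, 30), p_t3 = c(40, 50)) {
  data.frame(
    taxon = c("Streptococcus", "Veillonella"),
    lineage = c(
      "k__Bacteria; p__Firmicutes; c__Bacilli; o__Lactobacillales; f__Streptococcaceae; g__Streptococcus; s__",
      "k__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales; f__Veillonellaceae; g__Veillonella; s__"),
    p_t0 = p_t0, p_t3 = p_t3, stringsAsFactors = FALSE)
}

# hand-built 2-subject dataset for exact composition checks
toy_otu_dataset <- function() {
  counts <- matrix(
    c(2, 3, 5, 0,
      4, 4, 2, 1,
      1, 1, 8, 2,
      6, 2, 2, 3),
    nrow = 4, byrow = TRUE,
    dimnames = list(c("S01.T0", "S01.T3", "S02.T0", "S02.T3"),
                    c("OTU1", "OTU2", "OTU3", "OTU4")))
  taxonomy <- c(
    OTU1 = "k__Bacteria; p__Firmicutes; c__Bacilli; o__Lactobacillales; f__Streptococcaceae; g__Streptococcus; s__",
    OTU2 = "k__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales; f__Veillonellaceae; g__Veillonella; s__",
    OTU3 = "k__Bacteria; p__Actinobacteria; c__Actinobacteria; o__Actinomycetales; f__Actinomycetaceae; g__Actinomyces; s__",
    OTU4 = "k__Bacteria; p__; c__; o__; f__; g__; s__")
  metadata <- data.frame(
    sample = rownames(counts),
    subject = c("S01", "S01", "S02", "S02"),
    timepoint = c("T0", "T3", "T0", "T3"),
    stringsAsFactors = FALSE)
  otu_dataset(counts, taxonomy, metadata)
}
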