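#' Construct an OTU dataset (counts + taxonomy + sample metadata)
#'
#' Container for a samples-by-OTUs integer count matrix with QIIME-style
#' semicolon-delimited taxonomy strings per OTU and per-sample metadata
#' (subject and time point). Subjects may contribute at most one sample per
#' time point.
#'
#' @param counts Integer matrix, samples in rows (rownames = sample IDs),
#'   OTUs in columns (colnames = OTU IDs).
#' @param taxonomy Character vector of taxonomy strings, one per OTU, named
#'   by OTU ID (or in column order).
#' @param metadata data.frame with columns `sample`, `subject`, `timepoint`.
#' @return An object of class `otu_dataset`.
#' @export
otu_dataset <- function(counts, taxonomy, metadata) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have sample rownames and OTU colnames")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (is.null(names(taxonomy))) names(taxonomy) <- colnames(counts)
  if (!identical(sort(names(taxonomy)), sort(colnames(counts)))) {
    stop("taxonomy must cover exactly the OTUs in counts")
  }
  taxonomy <- taxonomy[colnames(counts)]
  need <- c("sample", "subject", "timepoint")
  if (!all(need %in% names(metadata))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  }
  missing_meta <- setdiff(rownames(counts), metadata$sample)
  if (length(missing_meta)) {
    stop("samples without metadata: ", paste(missing_meta, collapse = ", "))
  }
  metadata <- metadata[match(rownames(counts), metadata$sample), , drop = FALSE]
  rownames(metadata) <- NULL
  dup <- duplicated(metadata[, c("subject", "timepoint")])
  if (any(dup)) {
    stop("subjects must have at most one sample per time point")
  }
  structure(list(counts = counts, taxonomy = taxonomy, metadata = metadata),
            class = "otu_dataset")
}

#' @export
print.otu_dataset <- function(x, ...) {
  cat(sprintf("<otu_dataset> %d samples x %d OTUs; time points: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(sort(unique(x$metadata$timepoint)), collapse = ", ")))
  invisible(x)
}

#' @rdname otu_dataset
#' @param x Object to test.
#' @export
is.otu_dataset <- function(x) inherits(x, "otu_dataset")

QIIME_RANKS <- c(kingdom = "k__", phylum = "p__", class = "c__",
                 order = "o__", family = "f__", genus = "g__",
                 species = "s__")

# label of `rank` from a semicolon-delimited taxonomy string; "" when
# unassigned at that rank, NA when the string is malformed
taxon_at_rank <- function(tax, rank) {
  prefix <- QIIME_RANKS[[rank]]
  parts <- trimws(strsplit(tax, ";", fixed = TRUE)[[1]])
  hit <- parts[startsWith(parts, prefix)]
  if (length(hit) == 0) return(NA_character_)
  sub(paste0("^", prefix), "", hit[1])
}

#' Read / write OTU tables as TSV
#'
#' The on-disk layout has OTUs as rows: first column `otu_id`, one integer
#' column per sample, last column `taxonomy`. Sample metadata is a second
#' TSV with columns `sample`, `subject`, `timepoint`.
#'
#' @param counts_path,metadata_path Paths of the two TSV files.
#' @return [read_otu_table()] returns an `otu_dataset`.
#' @export
read_otu_table <- function(counts_path, metadata_path) {
  raw <- read.delim(counts_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(raw)[1] != "otu_id" || names(raw)[ncol(raw)] != "taxonomy") {
    stop("OTU TSV must have first column 'otu_id' and last column 'taxonomy'")
  }
  sample_cols <- names(raw)[-c(1, ncol(raw))]
  counts <- t(as.matrix(raw[, sample_cols, drop = FALSE]))
  colnames(counts) <- raw$otu_id
  taxonomy <- structure(raw$taxonomy, names = raw$otu_id)
  metadata <- read.delim(metadata_path, stringsAsFactors = FALSE)
  otu_dataset(counts, taxonomy, metadata)
}

#' @rdname read_otu_table
#' @param table An `otu_dataset`.
#' @export
write_otu_table <- function(table, counts_path, metadata_path) {
  stopifnot(is.otu_dataset(table))
  df <- data.frame(otu_id = colnames(table$counts),
                   t(table$counts), check.names = FALSE,
                   stringsAsFactors = FALSE)
  df$taxonomy <- unname(table$taxonomy)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(table$metadata, metadata_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(counts_path, metadata_path))
}
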