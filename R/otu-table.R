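#' OTU count table with sample metadata and taxonomy
#'
#' Container for a samples x OTUs matrix of nonnegative integer counts,
#' per-sample metadata (mouse, genotype, sex, week, diagnosis) and a
#' per-OTU taxonomic lineage.  All analysis stages consume and return this
#' class.
#'
#' @param counts integer matrix, samples in rows (rownames are sample IDs),
#'   OTUs in columns (colnames are OTU IDs).
#' @param sample_meta data.frame with columns `sample_id`, `mouse_id`,
#'   `genotype` (`"WT"`/`"KO"`), `sex` (`"M"`/`"F"`), `week` (integer) and
#'   `diagnosis` (`"ED/CIS"`/`"OSCC"`); one row per sample.
#' @param taxonomy data.frame with columns `otu`, `size` and `lineage`
#'   (semicolon-separated ranks, domain through genus; unclassified ranks
#'   allowed); one row per OTU.
#'
#' @return An object of class `otu_count_table`.
#' @export
otu_count_table <- function(counts, sample_meta, taxonomy) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (nrow(counts) > 0 && is.null(rownames(counts)))
    stop("counts must have sample IDs as rownames")
  if (is.null(colnames(counts))) stop("counts must have OTU IDs as colnames")
  if (anyDuplicated(rownames(counts))) stop("sample IDs must be unique")
  sample_meta <- as.data.frame(sample_meta)
  req <- c("sample_id", "mouse_id", "genotype", "sex", "week", "diagnosis")
  miss <- setdiff(req, names(sample_meta))
  if (length(miss)) stop("sample_meta missing columns: ", paste(miss, collapse = ", "))
  if (!all(rownames(counts) %in% sample_meta$sample_id))
    stop("every sample must have metadata")
  sample_meta <- sample_meta[match(rownames(counts), sample_meta$sample_id), , drop = FALSE]
  rownames(sample_meta) <- NULL
  taxonomy <- as.data.frame(taxonomy)
  if (!all(c("otu", "lineage") %in% names(taxonomy)))
    stop("taxonomy needs columns 'otu' and 'lineage'")
  if (!all(colnames(counts) %in% taxonomy$otu))
    stop("every OTU must have a taxonomy lineage")
  taxonomy <- taxonomy[match(colnames(counts), taxonomy$otu), , drop = FALSE]
  rownames(taxonomy) <- NULL
  structure(list(counts = counts, sample_meta = sample_meta, taxonomy = taxonomy),
            class = "otu_count_table")
}

#' @export
print.otu_count_table <- function(x, ...) {
  cat("OTU count table:", nrow(x$counts), "samples x", ncol(x$counts), "OTUs\n")
  cat("  total reads:", sum(x$counts),
      " median depth:", stats::median(rowSums(x$counts)), "\n")
  wk <- sort(unique(x$sample_meta$week))
  cat("  weeks:", paste(wk, collapse = ", "),
      " mice:", length(unique(x$sample_meta$mouse_id)), "\n")
  invisible(x)
}

#' @export
dim.otu_count_table <- function(x) dim(x$counts)

# Subset samples (and optionally OTUs) keeping metadata aligned.
subset_table <- function(table, samples = NULL, otus = NULL) {
  counts <- table$counts
  if (!is.null(samples)) counts <- counts[samples, , drop = FALSE]
  if (!is.null(otus)) counts <- counts[, otus, drop = FALSE]
  otu_count_table(counts,
                  table$sample_meta[table$sample_meta$sample_id %in% rownames(counts), ],
                  table$taxonomy[table$taxonomy$otu %in% colnames(counts), ])
}
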