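# Compositional preprocessing: half-minimum zero replacement, centered
# log-ratio transform, prevalence filtering, rarefaction and taxonomy
# aggregation.

#' Replace zeros by half the smallest nonzero count of the sample
#'
#' @param x nonnegative numeric vector (one sample's counts over retained
#'   OTUs); must contain at least one nonzero entry.
#' @return Strictly positive vector with zeros replaced by
#'   `min(x[x > 0]) / 2`; nonzero entries are unchanged.
#' @export
replace_zeros_half_min <- function(x) {
  if (any(x < 0)) stop("counts must be nonnegative")
  nz <- x[x > 0]
  if (!length(nz)) stop("all-zero sample: half-minimum replacement undefined")
  x[x == 0] <- min(nz) / 2
  x
}

#' Per-OTU prevalence
#'
#' Fraction of all samples in which an OTU has a count greater than zero.
#'
#' @param table an [otu_count_table()] or a counts matrix.
#' @param otu optional OTU id(s) or indices; default all OTUs.
#' @return Named numeric vector of prevalences in `[0, 1]`.
#' @export
prevalence <- function(table, otu = NULL) {
  counts <- if (inherits(table, "otu_count_table")) table$counts else as.matrix(table)
  p <- colMeans(counts > 0)
  if (is.null(otu)) p else {
    if (is.character(otu) && !all(otu %in% colnames(counts))) stop("unknown OTU")
    p[otu]
  }
}

#' Centered log-ratio transform with prevalence filter and half-minimum
#' zero replacement
#'
#' OTUs with prevalence strictly below `prevalence_min` are removed first;
#' zeros are then replaced per sample by half the smallest nonzero count of
#' the retained submatrix; finally each row is log-transformed and centered
#' (`log x - mean(log x)`), so rows sum to zero.  Samples that are all-zero
#' after filtering are dropped with a warning.
#'
#' @param table an [otu_count_table()] or counts matrix.
#' @param prevalence_min prevalence threshold in `[0, 1)`; the filter rule
#'   is strict ("below"), so an OTU exactly at the threshold is retained.
#' @return An object of class `clr_matrix`: list with `values` (samples x
#'   retained OTUs), `retained_otus`, `replacement_record` (per-sample
#'   half-minimum used), `dropped_samples` and `prevalence` (pre-filter).
#' @export
clr_transform <- function(table, prevalence_min = 0.05) {
  if (prevalence_min < 0 || prevalence_min >= 1) stop("prevalence_min must be in [0, 1)")
  counts <- if (inherits(table, "otu_count_table")) table$counts else as.matrix(table)
  if (!nrow(counts) || !ncol(counts)) stop("empty table")
  prev <- colMeans(counts > 0)
  keep <- prev >= prevalence_min
  sub <- counts[, keep, drop = FALSE]
  degenerate <- rowSums(sub) == 0
  dropped <- rownames(sub)[degenerate] %||% character(0)
  if (any(degenerate)) {
    warning("dropping ", sum(degenerate), " all-zero sample(s) after filtering: ",
            paste(dropped, collapse = ", "))
    sub <- sub[!degenerate, , drop = FALSE]
  }
  repl <- apply(sub, 1, function(r) min(r[r > 0]) / 2)
  filled <- sub
  zero <- which(sub == 0, arr.ind = TRUE)
  if (nrow(zero)) filled[zero] <- repl[zero[, 1]]
  lv <- log(filled)
  values <- lv - rowMeans(lv)
  structure(list(values = values,
                 retained_otus = colnames(counts)[keep],
                 replacement_record = repl,
                 dropped_samples = dropped,
                 prevalence = prev),
            class = "clr_matrix")
}

#' @export
print.clr_matrix <- function(x, ...) {
  cat("CLR matrix:", nrow(x$values), "samples x", ncol(x$values), "retained OTUs\n")
  cat("  max |row sum| =", format(max(abs(rowSums(x$values))), digits = 3), "\n")
  invisible(x)
}

#' Rarefy samples to a common depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads; samples with fewer total reads are dropped (with a warning).
#'
#' @param table an [otu_count_table()].
#' @param depth target depth (reads per sample), >= 1.
#' @param seed integer seed; a single draw per sample.
#' @return A rarefied [otu_count_table()].
#' @export
rarefy <- function(table, depth = 9484L, seed = 1L) {
  stopifnot(inherits(table, "otu_count_table"))
  if (depth < 1) stop("depth must be >= 1")
  counts <- table$counts
  totals <- rowSums(counts)
  keep <- totals >= depth
  if (!any(keep)) {
    warning("all samples below rarefaction depth; returning empty table")
    empty <- counts[0, , drop = FALSE]
    return(otu_count_table(empty, table$sample_meta[0, ], table$taxonomy))
  }
  if (any(!keep))
    warning("dropping ", sum(!keep), " sample(s) below depth ", depth)
  set.seed(derive_seed(seed, 3L))
  out <- counts[keep, , drop = FALSE]
  K <- ncol(out)
  for (i in seq_len(nrow(out))) {
    if (totals[keep][i] == depth) next
    reads <- rep.int(seq_len(K), out[i, ])
    out[i, ] <- tabulate(sample(reads, depth), nbins = K)
  }
  meta <- table$sample_meta[table$sample_meta$sample_id %in% rownames(out), ]
  otu_count_table(out, meta, table$taxonomy)
}

.rank_index <- c(domain = 1L, phylum = 2L, class = 3L, order = 4L,
                 family = 5L, genus = 6L)

#' Aggregate OTU counts at a taxonomic rank
#'
#' Counts are summed over OTUs sharing the lineage prefix up to `rank`;
#' OTUs unclassified at that rank are pooled under
#' `"unclassified_<parent>"`.  Sample totals are conserved.
#'
#' @param table an [otu_count_table()].
#' @param rank one of `"phylum"`, `"class"`, `"order"`, `"family"`,
#'   `"genus"`.
#' @return An [otu_count_table()] whose "OTUs" are rank-level taxa.
#' @export
aggregate_taxonomy <- function(table, rank = c("phylum", "class", "order", "family", "genus")) {
  rank <- match.arg(rank)
  ri <- .rank_index[[rank]]
  stopifnot(inherits(table, "otu_count_table"))
  parts <- strsplit(table$taxonomy$lineage, ";", fixed = TRUE)
  label <- vapply(parts, function(p) {
    v <- if (length(p) >= ri) p[ri] else "unclassified"
    if (identical(v, "unclassified") || v == "") {
      parent <- rev(p[seq_len(min(ri - 1, length(p)))])
      parent <- parent[parent != "unclassified" & parent != ""]
      paste0("unclassified_", if (length(parent)) parent[1] else "root")
    } else v
  }, character(1))
  agg <- rowsum(t(table$counts), label)  # taxa x samples
  counts <- t(agg)
  lin <- vapply(split(seq_along(label), label), function(ix) {
    p <- parts[[ix[1]]]
    paste(p[seq_len(min(ri, length(p)))], collapse = ";")
  }, character(1))
  taxonomy <- data.frame(otu = rownames(agg), size = rowSums(agg),
                         lineage = lin[rownames(agg)], stringsAsFactors = FALSE)
  otu_count_table(counts, table$sample_meta, taxonomy)
}

#' Write a CLR matrix and its filter report
#'
#' @param clr a `clr_matrix`.
#' @param dir output directory.
#' @param stem file stem.
#' @return Named vector of written paths (CLR TSV, retained-OTU TSV,
#'   filter-report JSON).
#' @export
write_clr <- function(clr, dir, stem = "clr") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(values = file.path(dir, paste0(stem, ".values.tsv")),
             otus = file.path(dir, paste0(stem, ".retained_otus.tsv")),
             report = file.path(dir, paste0(stem, ".filter_report.json")))
  write.table(data.frame(sample_id = rownames(clr$values), clr$values,
                         check.names = FALSE),
              paths["values"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(otu = clr$retained_otus,
                         prevalence = clr$prevalence[clr$retained_otus]),
              paths["otus"], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(n_retained = length(clr$retained_otus),
                            n_dropped_samples = length(clr$dropped_samples),
                            dropped_samples = clr$dropped_samples),
                       paths["report"], auto_unbox = TRUE)
  invisible(paths)
}
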