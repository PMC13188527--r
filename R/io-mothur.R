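# Readers and writers for the mothur .shared / .cons.taxonomy dialect and
# the per-sample metadata TSV.

#' Read a mothur-dialect .shared OTU count file
#'
#' Expects the tab-separated layout `label  Group  numOtus  Otu0001 ...`,
#' one row per sample.
#'
#' @param path path to the `.shared` file.
#' @return Integer count matrix, samples in rows (Group column as
#'   rownames), OTUs in columns.
#' @export
read_shared <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("label", "Group", "numOtus")
  if (!all(req %in% names(df))) stop("not a .shared file: missing ", paste(setdiff(req, names(df)), collapse = ", "))
  otu_cols <- setdiff(names(df), req)
  counts <- as.matrix(df[, otu_cols, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$Group
  if (any(df$numOtus != length(otu_cols)))
    warning("numOtus column disagrees with the number of OTU columns")
  counts
}

#' Write a mothur-dialect .shared file
#'
#' @param counts samples x OTUs integer matrix with dimnames.
#' @param path output path.
#' @param label distance label written in the first column (default "0.03",
#'   the 97%-identity OTU level).
#' @export
write_shared <- function(counts, path, label = "0.03") {
  df <- data.frame(label = label, Group = rownames(counts),
                   numOtus = ncol(counts), check.names = FALSE)
  df <- cbind(df, as.data.frame(counts, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a mothur consensus taxonomy file
#'
#' Parses the `OTU  Size  Taxonomy` layout; bootstrap-support parentheses
#' (e.g. `Bacteria(100)`) and the trailing semicolon are stripped from the
#' lineage.
#'
#' @param path path to the `.cons.taxonomy` file.
#' @return data.frame with columns `otu`, `size`, `lineage`.
#' @export
read_cons_taxonomy <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("otu", "taxonomy") %in% names(df)))
    stop("not a .cons.taxonomy file")
  lineage <- gsub("\\([0-9]+\\)", "", df$taxonomy)
  lineage <- sub(";+$", "", lineage)
  data.frame(otu = df$otu, size = df$size %||% NA_integer_,
             lineage = lineage, stringsAsFactors = FALSE)
}

#' Write a mothur consensus taxonomy file
#'
#' @param taxonomy data.frame with columns `otu`, `size`, `lineage`.
#' @param path output path.
#' @param support bootstrap support annotated on every rank (cosmetic;
#'   readers strip it).
#' @export
write_cons_taxonomy <- function(taxonomy, path, support = 100) {
  ranks <- strsplit(taxonomy$lineage, ";", fixed = TRUE)
  tax <- vapply(ranks, function(r)
    paste0(paste0(r, "(", support, ")", collapse = ";"), ";"), character(1))
  df <- data.frame(OTU = taxonomy$otu,
                   Size = taxonomy$size %||% 0L,
                   Taxonomy = tax)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the per-sample metadata TSV
#'
#' @param path TSV with columns `sample_id`, `mouse_id`, `genotype`, `sex`,
#'   `week`, `diagnosis`.
#' @return data.frame of sample metadata.
#' @export
read_sample_metadata <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "mouse_id", "genotype", "sex", "week", "diagnosis")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  df$week <- as.integer(df$week)
  bad <- setdiff(unique(df$genotype), c("WT", "KO"))
  if (length(bad)) stop("unknown genotype levels: ", paste(bad, collapse = ", "))
  df
}

#' Read an OTU table from mothur-dialect files
#'
#' Convenience wrapper assembling [otu_count_table()] from a `.shared`
#' file, a consensus taxonomy file and a metadata TSV.
#'
#' @param shared,taxonomy,metadata file paths.
#' @return An [otu_count_table()].
#' @export
read_otu_table <- function(shared, taxonomy, metadata) {
  otu_count_table(read_shared(shared), read_sample_metadata(metadata),
                  read_cons_taxonomy(taxonomy))
}
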