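#' Sample-by-taxon abundance table with sample metadata
#'
#' The package's central container: an integer count matrix (rows = samples,
#' columns = taxa) paired with a metadata frame mapping each sample to its
#' group, replicate animal ("mouse") and sampling day.
#'
#' @param counts non-negative integer matrix, samples x taxa, with row and
#'   column names.
#' @param metadata data.frame with columns `sample`, `group`, `mouse`, `day`;
#'   one row per sample.
#' @return object of class `abundance_table`.
#' @export
abundance_table <- function(counts, metadata) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort("'counts' needs sample row names and taxon column names")
  if (any(counts < 0)) abort("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8)) abort("counts must be integers")
  storage.mode(counts) <- "integer"
  if (anyDuplicated(rownames(counts))) abort("sample IDs must be unique")
  need <- c("sample", "group", "mouse", "day")
  if (!is.data.frame(metadata) || !all(need %in% names(metadata)))
    abort("'metadata' must be a data.frame with columns %s",
          paste(need, collapse = ", "))
  missing <- setdiff(rownames(counts), metadata$sample)
  if (length(missing))
    abort("metadata is missing sample(s): %s",
          paste(missing, collapse = ", "))
  metadata <- metadata[match(rownames(counts), metadata$sample), , drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(counts = counts, metadata = metadata,
                 samples = rownames(counts), taxa = colnames(counts)),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance table: %d samples x %d taxa (groups: %s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$metadata$group), collapse = ", ")))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$counts)

#' Write an abundance table as a mothur shared-style TSV plus metadata TSV
#'
#' The shared file has columns `label`, `Group` (the sample ID), `numOtus`,
#' then one column per taxon; metadata is a four-column TSV
#' (sample, group, mouse, day).
#'
#' @param x an [abundance_table()].
#' @param shared_path,metadata_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_abundance_table <- function(x, shared_path, metadata_path) {
  stopifnot(inherits(x, "abundance_table"))
  shared <- data.frame(label = "genus", Group = x$samples,
                       numOtus = ncol(x$counts), check.names = FALSE,
                       stringsAsFactors = FALSE)
  shared <- cbind(shared, as.data.frame(x$counts, check.names = FALSE))
  utils::write.table(shared, shared_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$metadata, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(shared = shared_path, metadata = metadata_path))
}

#' Read a mothur shared-style TSV plus metadata TSV
#'
#' Inverse of [write_abundance_table()]; a write-then-read round trip
#' reproduces the table exactly. Ragged rows raise a parse error naming the
#' line; a sample absent from the metadata raises an error naming it. Taxa
#' with zero total count are allowed and reported via `message()`.
#'
#' @param shared_path,metadata_path input file paths.
#' @return an [abundance_table()].
#' @export
read_abundance_table <- function(shared_path, metadata_path) {
  for (p in c(shared_path, metadata_path))
    if (!file.exists(p)) abort("file not found: %s", p)
  nf <- utils::count.fields(shared_path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1L)
    abort("ragged shared file: line %d has %d fields, expected %d",
          which(nf != nf[1])[1], nf[nf != nf[1]][1], nf[1])
  shared <- utils::read.delim(shared_path, check.names = FALSE,
                              stringsAsFactors = FALSE)
  need <- c("label", "Group", "numOtus")
  if (!all(need %in% names(shared)))
    abort("shared file must have columns %s", paste(need, collapse = ", "))
  taxa <- setdiff(names(shared), need)
  counts <- as.matrix(shared[, taxa, drop = FALSE])
  rownames(counts) <- shared$Group
  meta <- utils::read.delim(metadata_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  empty <- colSums(counts) == 0
  if (any(empty))
    message("taxa with zero total count: ", paste(taxa[empty], collapse = ", "))
  abundance_table(counts, meta)
}

#' Convert counts to per-sample relative abundances
#'
#' @param x an [abundance_table()] or a sample x taxon count matrix.
#' @return matrix of fractions; each row sums to 1 (within 1e-12).
#' @export
to_relative <- function(x) {
  counts <- if (inherits(x, "abundance_table")) x$counts else as.matrix(x)
  tot <- rowSums(counts)
  if (any(tot <= 0))
    abort("sample '%s' has zero total count",
          rownames(counts)[which(tot <= 0)[1]] %||% which(tot <= 0)[1])
  sweep(counts, 1, tot, "/")
}

#' Subset an abundance table to one group
#' @param x an [abundance_table()].
#' @param group group label present in the metadata.
#' @return an [abundance_table()] with that group's samples.
#' @export
subset_group <- function(x, group) {
  stopifnot(inherits(x, "abundance_table"))
  keep <- x$metadata$group == group
  if (!any(keep)) abort("no samples for group '%s' (available: %s)", group,
                        paste(unique(x$metadata$group), collapse = ", "))
  abundance_table(x$counts[keep, , drop = FALSE],
                  x$metadata[keep, , drop = FALSE])
}
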