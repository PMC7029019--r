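#' Taxa-by-samples count table
#'
#' The compositional container used by all microbiome operations: an integer
#' matrix of taxa (rows) by samples (columns) together with per-sample library
#' sizes (column sums). This is the object that cumulative sum scaling,
#' rarefaction, the centered log-ratio transform and ANCOM operate on.
#'
#' @param counts non-negative integer matrix, taxa in rows, samples in columns.
#' @param taxa_ids,sample_ids optional character vectors; default to the
#'   dimnames of `counts` or generated `taxon_i` / `sample_j` labels.
#' @return an object of class `count_table` with elements `counts`,
#'   `taxa_ids`, `sample_ids` and `library_size`.
#' @examples
#' ct <- count_table(matrix(c(5L, 0L, 3L, 2L, 1L, 0L), nrow = 3))
#' ct$library_size
#' @export
count_table <- function(counts, taxa_ids = NULL, sample_ids = NULL) {
  counts <- as.matrix(counts)
  if (any(!is.finite(counts))) stop("counts must be finite")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8)) stop("counts must be integers")
  storage.mode(counts) <- "integer"
  if (is.null(taxa_ids)) {
    taxa_ids <- rownames(counts)
    if (is.null(taxa_ids)) taxa_ids <- paste0("taxon_", seq_len(nrow(counts)))
  }
  if (is.null(sample_ids)) {
    sample_ids <- colnames(counts)
    if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(ncol(counts)))
  }
  if (length(taxa_ids) != nrow(counts)) stop("taxa_ids length must match rows")
  if (length(sample_ids) != ncol(counts)) stop("sample_ids length must match columns")
  if (anyDuplicated(taxa_ids)) {
    stop("duplicate taxa ids: ", paste(unique(taxa_ids[duplicated(taxa_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ", paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  dimnames(counts) <- list(taxa_ids, sample_ids)
  structure(
    list(
      counts = counts,
      taxa_ids = taxa_ids,
      sample_ids = sample_ids,
      library_size = colSums(counts)
    ),
    class = "count_table"
  )
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x$counts), "taxa x", ncol(x$counts), "samples\n")
  cat("library sizes:", paste(utils::head(x$library_size, 6), collapse = ", "),
      if (ncol(x$counts) > 6) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

# internal: samples x taxa orientation used by distance/ordination code
.samples_by_taxa <- function(table) t(table$counts)
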