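# Count-matrix and poly(A) table I/O.

#' Read a gene x sample count matrix
#'
#' Reads a tab-delimited expression matrix in the style of long-read
#' quantifier output: a `gene_id` column followed by one numeric column per
#' sample. Gene ids must be unique and every count cell numeric and
#' non-negative.
#'
#' @param path Path to the TSV file.
#' @return A numeric matrix (genes x samples) with gene ids as row names.
#' @export
read_counts <- function(path) {
  df <- read_tsv(path)
  if (!"gene_id" %in% names(df)) {
    stop_msg("count matrix '%s' must have a 'gene_id' column", path)
  }
  if (anyDuplicated(df$gene_id)) {
    stop_msg("duplicate gene_id in count matrix '%s'", path)
  }
  vals <- df[setdiff(names(df), "gene_id")]
  for (cn in names(vals)) {
    v <- suppressWarnings(as.numeric(vals[[cn]]))
    if (anyNA(v)) {
      stop_msg("non-numeric count for gene '%s', sample '%s' in '%s'",
               df$gene_id[which(is.na(v))[1]], cn, path)
    }
    vals[[cn]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- df$gene_id
  if (any(m < 0)) stop_msg("negative count entries in '%s'", path)
  m
}

#' Write a gene x sample count matrix
#'
#' @param counts Numeric matrix with gene ids as row names.
#' @param path Output path.
#' @seealso [read_counts()]
#' @export
write_counts <- function(counts, path) {
  if (is.null(rownames(counts)) && nrow(counts)) {
    stop_msg("count matrix must carry gene ids as row names")
  }
  df <- data.frame(gene_id = rownames(counts) %||% character(0),
                   as.data.frame(counts), check.names = FALSE)
  write_tsv(df, path)
}

#' Read a per-read poly(A) tail-length table
#'
#' Expects tab-delimited columns `gene_id`, `sample_id`, `tail_length`
#' (nucleotides); a `read_id` column is carried through when present.
#' Negative tail lengths are an error.
#'
#' @param path Path to the TSV file.
#' @return A data frame with one row per read.
#' @export
read_polya <- function(path) {
  df <- read_tsv(path)
  need <- c("gene_id", "sample_id", "tail_length")
  if (!all(need %in% names(df))) {
    stop_msg("poly(A) table '%s' must have columns: %s", path,
             paste(need, collapse = ", "))
  }
  tl <- suppressWarnings(as.numeric(df$tail_length))
  if (anyNA(tl)) stop_msg("non-numeric tail_length in '%s'", path)
  if (any(tl < 0)) stop_msg("negative tail_length in '%s'", path)
  df$tail_length <- tl
  df
}
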