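# Readers/writers for per-site m6A call tables and BED export.

SITE_COLUMNS <- c("chromosome", "position", "strand", "motif",
                  "modified_reads", "total_reads")

#' Read a per-site m6A call table
#'
#' Reads the tab-delimited per-site output of a nanopore m6A caller
#' (chromosome, position, strand, 5-mer motif, modified read count, total
#' read count) and normalizes it to the package's internal convention:
#' 0-based site positions and a `ratio` column equal to
#' `modified_reads / total_reads`.
#'
#' Sites with `total_reads == 0` carry no stoichiometry information and are
#' dropped with a warning (callers can emit uncovered positions). Rows with
#' `modified_reads > total_reads`, non-numeric counts, or a duplicated
#' (chromosome, position, strand) key are hard errors naming the offending
#' line.
#'
#' @param path Path to a tab-delimited file with a header line naming the
#'   columns `chromosome`, `position`, `strand`, `motif`, `modified_reads`,
#'   `total_reads`.
#' @param dialect Position convention of the input file: `"one-based"`
#'   (default, the common per-site caller convention) or `"zero-based"`.
#' @param sample_id Sample identifier attached to the table; defaults to the
#'   file name without extension.
#' @param fasta Optional reference, either a path to a FASTA file or a
#'   [Biostrings::DNAStringSet]. When supplied, the 5-mer motif centered on
#'   each site is recomputed from the reference (strand-aware) and replaces
#'   the motif column; disagreements with the input motif are reported with
#'   a warning. See [extract_motif()].
#'
#' @return A `site_calls` data frame with columns `chrom`, `pos` (0-based),
#'   `strand`, `motif`, `modified`, `total`, `ratio`, the sample id in
#'   `attr(, "sample_id")` and the number of zero-coverage rows dropped in
#'   `attr(, "n_dropped_zero_coverage")`.
#' @seealso [write_bed()], [site_calls()]
#' @export
read_site_calls <- function(path, dialect = c("one-based", "zero-based"),
                            sample_id = NULL, fasta = NULL) {
  dialect <- match.arg(dialect)
  raw <- read_tsv(path, colClasses = "character")
  if (!all(SITE_COLUMNS %in% names(raw))) {
    stop_msg("site call file '%s' must have columns: %s", path,
             paste(SITE_COLUMNS, collapse = ", "))
  }
  raw <- raw[SITE_COLUMNS]
  pos <- suppressWarnings(as.numeric(raw$position))
  modified <- suppressWarnings(as.numeric(raw$modified_reads))
  total <- suppressWarnings(as.numeric(raw$total_reads))
  bad <- which(is.na(pos) | is.na(modified) | is.na(total) |
                 !raw$strand %in% c("+", "-"))
  if (length(bad)) {
    stop_msg("malformed row at line %d of '%s'", bad[1] + 1L, path)
  }
  over <- which(modified > total)
  if (length(over)) {
    stop_msg("modified_reads > total_reads at line %d of '%s'",
             over[1] + 1L, path)
  }
  neg <- which(modified < 0 | total < 0)
  if (length(neg)) {
    stop_msg("negative read count at line %d of '%s'", neg[1] + 1L, path)
  }
  if (dialect == "one-based") pos <- pos - 1
  tab <- site_calls(
    chrom = raw$chromosome, pos = as.integer(pos), strand = raw$strand,
    motif = toupper(chartr("U", "T", raw$motif)),
    modified = as.integer(round(modified)), total = as.integer(round(total)),
    sample_id = sample_id %||% sub("\\.[^.]*$", "", basename(path)),
    source = path
  )
  if (!is.null(fasta)) tab <- recompute_motifs(tab, fasta)
  tab
}

#' Construct a site-call table from vectors
#'
#' Validates and assembles the internal `site_calls` representation used by
#' every downstream stage: unique (chromosome, position, strand) keys,
#' counts with `0 <= modified <= total`, and `ratio = modified / total`.
#' Zero-coverage sites are dropped with a warning.
#'
#' @param chrom,pos,strand,motif,modified,total Parallel vectors describing
#'   one site per element; `pos` is the 0-based index of the site base.
#' @param sample_id Sample identifier.
#' @param source Optional provenance string used in messages.
#' @return A `site_calls` data frame (see [read_site_calls()]).
#' @export
site_calls <- function(chrom, pos, strand, motif, modified, total,
                       sample_id = "sample", source = "<memory>") {
  df <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    strand = as.character(strand), motif = as.character(motif),
    modified = as.integer(modified), total = as.integer(total),
    stringsAsFactors = FALSE
  )
  zero <- df$total == 0L
  if (any(zero)) {
    warning(sprintf("dropping %d zero-coverage site(s) from %s",
                    sum(zero), source), call. = FALSE)
    df <- df[!zero, , drop = FALSE]
  }
  if (any(df$modified > df$total) || any(df$modified < 0L)) {
    stop_msg("invalid read counts in %s: need 0 <= modified <= total", source)
  }
  key <- site_key(df$chrom, df$pos, df$strand)
  if (anyDuplicated(key)) {
    stop_msg("duplicate site key '%s' in %s", key[duplicated(key)][1], source)
  }
  df$ratio <- df$modified / df$total
  rownames(df) <- NULL
  structure(df,
            sample_id = sample_id,
            n_dropped_zero_coverage = sum(zero),
            class = c("site_calls", "data.frame"))
}

#' @export
print.site_calls <- function(x, ...) {
  cat(sprintf("m6A site calls for sample '%s': %d sites on %d sequence(s)\n",
              attr(x, "sample_id"), nrow(x), length(unique(x$chrom))))
  if (nrow(x)) {
    cat(sprintf("  mean ratio %.3f; high-level (>0.5) sites: %d\n",
                mean(x$ratio), sum(x$ratio > 0.5)))
    print.data.frame(head(as.data.frame(x), 6L))
    if (nrow(x) > 6L) cat(sprintf("  ... and %d more rows\n", nrow(x) - 6L))
  }
  invisible(x)
}

#' Write a site-call table in the package's TSV dialect
#'
#' Inverse of [read_site_calls()]: emits the tab-delimited layout
#' (chromosome, position, strand, motif, modified_reads, total_reads) in the
#' requested position dialect.
#'
#' @inheritParams read_site_calls
#' @param sites A `site_calls` table.
#' @export
write_site_calls <- function(sites, path, dialect = c("one-based", "zero-based")) {
  dialect <- match.arg(dialect)
  pos <- sites$pos + if (dialect == "one-based") 1L else 0L
  out <- data.frame(chromosome = sites$chrom, position = pos,
                    strand = sites$strand, motif = sites$motif,
                    modified_reads = sites$modified, total_reads = sites$total)
  write_tsv(out, path)
}

#' Export sites as BED6
#'
#' Emits 0-based half-open BED6: each site becomes the single-base interval
#' `[pos, pos + 1)`. The name column carries the motif and the m6A ratio as
#' `motif;ratio=<r>`, and the score column the ratio rescaled to 0-1000.
#'
#' @param sites A `site_calls` data frame, or any data frame with columns
#'   `chrom`, `pos`, `strand` and optionally `motif` and `ratio`.
#' @param path Output path.
#' @export
write_bed <- function(sites, path) {
  ratio <- if ("ratio" %in% names(sites)) sites$ratio else rep(0, nrow(sites))
  motif <- if ("motif" %in% names(sites)) sites$motif else rep(".", nrow(sites))
  bed <- data.frame(
    chrom = sites$chrom,
    start = sites$pos,
    end = sites$pos + 1L,
    name = sprintf("%s;ratio=%.6f", motif, ratio),
    score = as.integer(round(1000 * ratio)),
    strand = sites$strand
  )
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
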