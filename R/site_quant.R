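# Site-level m6A stoichiometry, RRACH motif analysis, and genome-wide
# distribution summaries.

#' m6A ratio of a site
#'
#' The site-level m6A stoichiometry: the number of modified reads divided by
#' the total number of reads covering the site.
#'
#' @param modified Modified read count(s), `0 <= modified <= total`.
#' @param total Total read count(s), strictly positive.
#' @return `modified / total`, in \[0, 1\]. Vectorized.
#' @examples
#' compute_ratio(5, 10)
#' @export
compute_ratio <- function(modified, total) {
  if (any(total <= 0)) stop_msg("total read count must be positive")
  if (any(modified < 0) || any(modified > total)) {
    stop_msg("need 0 <= modified <= total")
  }
  modified / total
}

#' Classify a site as having a high m6A level
#'
#' A site is "high" when its ratio is strictly greater than the threshold
#' (by default 0.5, i.e. more than half the reads are modified).
#'
#' @param ratio m6A ratio(s) in \[0, 1\].
#' @param threshold High-level cutoff; strict inequality is used.
#' @return Logical vector.
#' @export
is_high_m6a <- function(ratio, threshold = 0.5) {
  if (any(ratio < 0 | ratio > 1, na.rm = TRUE)) {
    stop_msg("ratio must lie in [0, 1]")
  }
  ratio > threshold
}

#' Extract the 5-mer sequence context of a site
#'
#' Returns the reference 5-mer centered on a site, reverse-complemented for
#' minus-strand sites so the motif reads in transcript orientation.
#' Uppercase DNA alphabet; U is mapped to T.
#'
#' @param fasta Path to a FASTA file or a [Biostrings::DNAStringSet].
#' @param chromosome,position,strand Parallel vectors: sequence name,
#'   0-based site position, and strand (`"+"`/`"-"`).
#' @return Character vector of 5-mers.
#' @export
extract_motif <- function(fasta, chromosome, position, strand) {
  seqs <- load_fasta(fasta)
  chromosome <- as.character(chromosome)
  missing_chrom <- setdiff(unique(chromosome), names(seqs))
  if (length(missing_chrom)) {
    stop_msg("chromosome '%s' absent from reference", missing_chrom[1])
  }
  lens <- Biostrings::width(seqs)[match(chromosome, names(seqs))]
  if (any(position < 2L | position > lens - 3L)) {
    stop_msg("motif window out of chromosome bounds")
  }
  # 0-based site p -> 1-based window [p - 1, p + 3].
  views <- Biostrings::subseq(seqs[chromosome],
                              start = position - 1L, width = 5L)
  out <- as.character(views)
  neg <- strand == "-"
  if (any(neg)) {
    out[neg] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(out[neg])))
  }
  unname(toupper(out))
}

load_fasta <- function(fasta) {
  if (inherits(fasta, "DNAStringSet")) return(fasta)
  Biostrings::readDNAStringSet(fasta)
}

#' All 12 RRACH motif variants
#'
#' The RRACH consensus (R = A/G, A = methylated adenosine, C, H = A/C/T)
#' expands to 12 concrete 5-mers, returned in lexicographic order.
#'
#' @return Character vector of length 12.
#' @export
rrach_variants <- function() {
  v <- as.vector(outer(
    as.vector(outer(c("A", "G"), c("A", "G"), paste0)),
    paste0("AC", c("A", "C", "T")), paste0))
  sort(v)
}

#' Classify a 5-mer against the RRACH consensus
#'
#' @param motif Character vector of 5-mers over A/C/G/T/N.
#' @return A data frame with columns `motif`, `is_rrach` and `variant`
#'   (the motif itself when it matches RRACH, otherwise `NA`).
#' @export
classify_rrach <- function(motif) {
  motif <- toupper(chartr("U", "T", as.character(motif)))
  ok <- nchar(motif) == 5L &
    substr(motif, 1, 1) %in% c("A", "G") &
    substr(motif, 2, 2) %in% c("A", "G") &
    substr(motif, 3, 3) == "A" &
    substr(motif, 4, 4) == "C" &
    substr(motif, 5, 5) %in% c("A", "C", "T")
  data.frame(motif = motif, is_rrach = ok,
             variant = ifelse(ok, motif, NA_character_),
             stringsAsFactors = FALSE)
}

# Recompute motifs from the reference and reconcile with the input column.
recompute_motifs <- function(sites, fasta) {
  if (!nrow(sites)) return(sites)
  ref_motif <- extract_motif(fasta, sites$chrom, sites$pos, sites$strand)
  mismatch <- !is.na(sites$motif) & nzchar(sites$motif) &
    sites$motif != ref_motif
  if (any(mismatch)) {
    warning(sprintf(
      "%d site motif(s) disagree with the reference; using reference sequence",
      sum(mismatch)), call. = FALSE)
  }
  sites$motif <- ref_motif
  sites
}

#' Motif composition of a site collection
#'
#' Tallies the RRACH variant of every site across one or more site-call
#' tables and builds the position-wise base-frequency (sequence-logo)
#' matrix of the 5-mer contexts. Sites whose center base is not A (after
#' strand handling) or whose window contains N are excluded from the motif
#' summary with a warning; they remain valid sites elsewhere.
#'
#' @param tables A `site_calls` table or list of them.
#' @param fasta Optional reference; when given, motifs are recomputed from
#'   sequence instead of trusting the motif column.
#' @return A list of class `motif_summary`:
#'   \describe{
#'     \item{variants}{data frame `variant`, `count`, `fraction` over the 12
#'       RRACH variants (fractions sum to 1).}
#'     \item{logo}{5 x 4 base-frequency matrix (positions x A/C/G/T), each
#'       row summing to 1.}
#'     \item{n_sites,n_excluded}{bookkeeping counts.}
#'   }
#' @export
motif_proportions <- function(tables, fasta = NULL) {
  tables <- as_table_list(tables)
  motifs <- unlist(lapply(tables, function(t) {
    if (!is.null(fasta)) extract_motif(fasta, t$chrom, t$pos, t$strand)
    else t$motif
  }), use.names = FALSE)
  if (!length(motifs)) stop_msg("no sites provided")
  valid <- !grepl("N", motifs, fixed = TRUE) & substr(motifs, 3, 3) == "A" &
    nchar(motifs) == 5L
  if (any(!valid)) {
    warning(sprintf("excluding %d site(s) from the motif summary (center not A or ambiguous base)",
                    sum(!valid)), call. = FALSE)
  }
  motifs <- motifs[valid]
  cls <- classify_rrach(motifs)
  n_rrach <- sum(cls$is_rrach)
  if (n_rrach == 0L) stop_msg("no RRACH sites to summarize")
  counts <- table(factor(cls$variant[cls$is_rrach], levels = rrach_variants()))
  variants <- data.frame(variant = names(counts),
                         count = as.integer(counts),
                         fraction = as.integer(counts) / n_rrach,
                         stringsAsFactors = FALSE)
  bases <- c("A", "C", "G", "T")
  logo <- t(vapply(1:5, function(i) {
    b <- substr(motifs, i, i)
    as.vector(table(factor(b, levels = bases))) / length(motifs)
  }, numeric(4)))
  dimnames(logo) <- list(position = paste0("pos", 1:5), base = bases)
  structure(list(variants = variants, logo = logo,
                 n_sites = n_rrach, n_excluded = sum(!valid)),
            class = "motif_summary")
}

#' @export
print.motif_summary <- function(x, ...) {
  cat(sprintf("RRACH motif summary over %d sites (%d excluded)\n",
              x$n_sites, x$n_excluded))
  v <- x$variants[order(-x$variants$fraction), ]
  cat(sprintf("  most abundant: %s (%.1f%%); least: %s (%.1f%%)\n",
              v$variant[1], 100 * v$fraction[1],
              v$variant[nrow(v)], 100 * v$fraction[nrow(v)]))
  invisible(x)
}

as_table_list <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  if (!length(tables)) stop_msg("no site tables provided")
  tables
}

#' Per-chromosome distribution of m6A sites
#'
#' @param table A `site_calls` table (or any data frame with a `chrom`
#'   column).
#' @return Data frame `chrom`, `count`, `fraction`; fractions sum to 1.
#'   Chromosomes without sites are absent.
#' @export
chromosome_distribution <- function(table) {
  if (!nrow(table)) stop_msg("empty site table")
  counts <- table(table$chrom)
  data.frame(chrom = names(counts), count = as.integer(counts),
             fraction = as.integer(counts) / nrow(table),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare global m6A load between two sample groups
#'
#' Quantifies the group-level difference the way a pre/post comparison is
#' usually summarized: the relative number of distinct m6A sites in group B
#' versus group A, and a two-sided Mann-Whitney U test comparing the
#' per-site ratio distributions of the two groups.
#'
#' @param group_a_tables,group_b_tables `site_calls` tables (or lists of
#'   them) for the two groups; group A is the reference (pre-treatment).
#' @return A list of class `m6a_group_comparison`: `n_sites_a`, `n_sites_b`
#'   (distinct site keys per group), `relative_site_count` (B / A),
#'   `ratios_a`, `ratios_b`, `statistic` and `p_value`.
#' @export
global_level_comparison <- function(group_a_tables, group_b_tables) {
  ga <- as_table_list(group_a_tables)
  gb <- as_table_list(group_b_tables)
  keys_a <- unique(unlist(lapply(ga, function(t) site_key(t$chrom, t$pos, t$strand))))
  keys_b <- unique(unlist(lapply(gb, function(t) site_key(t$chrom, t$pos, t$strand))))
  if (!length(keys_a) || !length(keys_b)) {
    stop_msg("both groups must contain at least one site")
  }
  ra <- unlist(lapply(ga, `[[`, "ratio"), use.names = FALSE)
  rb <- unlist(lapply(gb, `[[`, "ratio"), use.names = FALSE)
  wt <- suppressWarnings(wilcox.test(ra, rb, alternative = "two.sided"))
  structure(list(
    n_sites_a = length(keys_a), n_sites_b = length(keys_b),
    relative_site_count = length(keys_b) / length(keys_a),
    ratios_a = ra, ratios_b = rb,
    statistic = unname(wt$statistic), p_value = wt$p.value
  ), class = "m6a_group_comparison")
}

#' @export
print.m6a_group_comparison <- function(x, ...) {
  cat(sprintf(
    "group m6A comparison: %d vs %d distinct sites (relative count %.3f)\n",
    x$n_sites_a, x$n_sites_b, x$relative_site_count))
  cat(sprintf("  mean ratio %.3f vs %.3f; Mann-Whitney p = %.3g\n",
              mean(x$ratios_a), mean(x$ratios_b), x$p_value))
  invisible(x)
}
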