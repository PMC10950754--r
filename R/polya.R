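# Per-gene poly(A) tail-length comparison between groups, used as a proxy
# for mRNA stability (longer tails ~ more stable transcripts).

#' Compare poly(A) tail lengths of one gene between two groups
#'
#' Two-sided Mann-Whitney U test on per-read tail lengths (nanopore tail
#' estimates are per read, and tail-length distributions are skewed, so a
#' rank test is used). The shift direction is the sign of the median
#' difference (post vs pre). When every read in both groups has the same
#' tail length the test is degenerate and `p = 1` with direction `none`.
#'
#' @param table A poly(A) table (see [read_polya()]).
#' @param gene_id Gene to test.
#' @param group_map Named character vector mapping `sample_id` to group;
#'   must have exactly two distinct groups. The first group value
#'   encountered is the reference (pre-treatment).
#' @param min_reads Minimum reads required per group (default 3); genes
#'   below it are refused with an informative error (use
#'   [batch_compare_polya()] to skip them silently).
#' @return One-row data frame: `gene_id`, `n_pre`, `n_post`, `median_pre`,
#'   `median_post`, `statistic` (U for the post group), `p_value`,
#'   `direction` (`"shorter"`, `"longer"`, `"none"` — post relative to
#'   pre).
#' @export
compare_polya <- function(table, gene_id, group_map, min_reads = 3) {
  rows <- table[table$gene_id == gene_id, , drop = FALSE]
  grp <- group_map[rows$sample_id]
  if (anyNA(grp)) {
    stop_msg("sample '%s' missing from group_map",
             rows$sample_id[which(is.na(grp))[1]])
  }
  lv <- unique(unname(group_map))
  if (length(lv) != 2L) stop_msg("group_map must define exactly two groups")
  a <- rows$tail_length[grp == lv[1]]
  b <- rows$tail_length[grp == lv[2]]
  if (length(a) < min_reads || length(b) < min_reads) {
    stop_msg("gene '%s': fewer than %d reads in a group (%d vs %d)",
             gene_id, min_reads, length(a), length(b))
  }
  if (length(unique(c(a, b))) == 1L) {
    return(data.frame(gene_id = gene_id, n_pre = length(a),
                      n_post = length(b), median_pre = median(a),
                      median_post = median(b),
                      statistic = length(a) * length(b) / 2,
                      p_value = 1, direction = "none",
                      stringsAsFactors = FALSE))
  }
  wt <- suppressWarnings(wilcox.test(b, a, alternative = "two.sided"))
  md <- median(b) - median(a)
  data.frame(gene_id = gene_id, n_pre = length(a), n_post = length(b),
             median_pre = median(a), median_post = median(b),
             statistic = unname(wt$statistic), p_value = wt$p.value,
             direction = if (md < 0) "shorter" else if (md > 0) "longer"
             else "none",
             stringsAsFactors = FALSE)
}

#' Batch poly(A) comparison with BH correction
#'
#' Runs [compare_polya()] over a gene list, skipping genes with too few
#' reads (reasons recorded), and appends Benjamini-Hochberg adjusted
#' q-values.
#'
#' @inheritParams compare_polya
#' @param gene_list Genes to test; defaults to every gene in the table.
#' @return An object of class `polya_test`: data frame of per-gene results
#'   plus a `q_value` column; skipped genes in `attr(, "skipped")`.
#' @export
batch_compare_polya <- function(table, gene_list = NULL, group_map,
                                min_reads = 3) {
  gene_list <- gene_list %||% sort(unique(table$gene_id))
  rows <- list()
  skipped <- character(0)
  for (g in gene_list) {
    res <- tryCatch(compare_polya(table, g, group_map, min_reads),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) skipped[g] <- res else rows[[g]] <- res
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), n_pre = integer(0),
               n_post = integer(0), median_pre = numeric(0),
               median_post = numeric(0), statistic = numeric(0),
               p_value = numeric(0), direction = character(0),
               stringsAsFactors = FALSE)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  structure(out, skipped = skipped,
            class = c("polya_test", "data.frame"))
}

#' @export
print.polya_test <- function(x, ...) {
  cat(sprintf("poly(A) tail comparison: %d gene(s) tested, %d skipped\n",
              nrow(x), length(attr(x, "skipped"))))
  sig <- x$q_value < 0.05
  if (nrow(x)) {
    cat(sprintf("  q < 0.05: %d (shorter after treatment: %d)\n",
                sum(sig), sum(sig & x$direction == "shorter")))
    print.data.frame(head(as.data.frame(x[order(x$p_value), ]), 6L),
                     row.names = FALSE)
  }
  invisible(x)
}
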