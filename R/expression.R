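# Expression normalization, DEG calling at fold-change/p-value thresholds,
# and the methylome x transcriptome intersection.

#' Counts-per-million normalization
#'
#' Scales each sample (column) to one million, so already-normalized input
#' is unchanged. Library sizes are kept in `attr(, "library_sizes")`.
#'
#' @param counts Numeric matrix, genes x samples, non-negative.
#' @return CPM matrix of the same shape.
#' @export
normalize_counts <- function(counts) {
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop_msg("zero library size for sample '%s'",
             colnames(counts)[which(lib == 0)[1]] %||% "?")
  }
  cpm <- sweep(counts, 2, lib, "/") * 1e6
  attr(cpm, "library_sizes") <- lib
  cpm
}

#' Call differentially expressed genes
#'
#' Compares two groups of samples on `log2(CPM + 1)`. The log2 fold change
#' is `mean(post) - mean(pre)`; the p-value comes from a paired t-test on
#' the per-patient log differences when `paired = TRUE` (samples matched by
#' order of appearance within each group), and from Welch's t-test
#' otherwise. A gene's status is `up` when `log2_fc > log2(fc_threshold)`
#' and `p < alpha`, `down` when `log2_fc < -log2(fc_threshold)` and
#' `p < alpha`, else `unchanged`. Genes with zero variance of the test
#' contrast get `p = NA` and stay `unchanged`.
#'
#' A BH-adjusted p-value column is included for reference; status uses raw
#' p-values per the fold-change/p-value rule.
#'
#' @param counts Genes x samples count (or CPM) matrix.
#' @param group_labels Two-level factor/character vector over samples.
#' @param reference Label of the reference (pre-treatment) group; defaults
#'   to the first label encountered.
#' @param paired Paired t-test on matched samples (default) or Welch.
#' @param fc_threshold Fold-change threshold on the natural scale
#'   (default 2, i.e. |log2 FC| > 1).
#' @param alpha Raw p-value threshold (default 0.05).
#' @return An object of class `deg_fit` whose `genes` component has one row
#'   per gene: `gene_id`, `mean_log2_pre`, `mean_log2_post`, `log2_fc`,
#'   `t`, `p_value`, `p_adj`, `status`.
#' @export
call_degs <- function(counts, group_labels, paired = TRUE,
                      fc_threshold = 2, alpha = 0.05, reference = NULL) {
  group_labels <- as.character(group_labels)
  if (length(group_labels) != ncol(counts)) {
    stop_msg("group_labels must have one entry per sample column")
  }
  lv <- unique(group_labels)
  if (length(lv) != 2L) stop_msg("exactly two groups are required")
  reference <- reference %||% lv[1]
  if (!reference %in% lv) stop_msg("reference '%s' is not a group label",
                                   reference)
  lv <- c(reference, setdiff(lv, reference))
  pre_idx <- which(group_labels == lv[1])
  post_idx <- which(group_labels == lv[2])
  if (length(pre_idx) < 2L || length(post_idx) < 2L) {
    stop_msg("each group needs at least 2 samples")
  }
  if (paired && length(pre_idx) != length(post_idx)) {
    stop_msg("paired analysis requires equal group sizes")
  }
  x <- log2(normalize_counts(counts) + 1)
  pre <- x[, pre_idx, drop = FALSE]
  post <- x[, post_idx, drop = FALSE]
  m_pre <- rowMeans(pre)
  m_post <- rowMeans(post)
  lfc <- m_post - m_pre

  if (paired) {
    d <- post - pre
    n <- ncol(d)
    s <- apply(d, 1, sd)
    t <- ifelse(s == 0, NA_real_, rowMeans(d) / (s / sqrt(n)))
    p <- 2 * pt(-abs(t), n - 1L)
  } else {
    n1 <- ncol(pre)
    n2 <- ncol(post)
    v1 <- apply(pre, 1, stats::var)
    v2 <- apply(post, 1, stats::var)
    se2 <- v1 / n1 + v2 / n2
    t <- ifelse(se2 == 0, NA_real_, (m_post - m_pre) / sqrt(se2))
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * pt(-abs(t), df)
  }
  lthr <- log2(fc_threshold)
  status <- rep("unchanged", nrow(x))
  status[!is.na(p) & p < alpha & lfc > lthr] <- "up"
  status[!is.na(p) & p < alpha & lfc < -lthr] <- "down"

  genes <- data.frame(
    gene_id = rownames(counts), mean_log2_pre = m_pre,
    mean_log2_post = m_post, log2_fc = lfc, t = t, p_value = p,
    p_adj = p.adjust(p, method = "BH"), status = status,
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(genes = genes, groups = lv, paired = paired,
                 fc_threshold = fc_threshold, alpha = alpha),
            class = "deg_fit")
}

#' @export
print.deg_fit <- function(x, ...) {
  g <- x$genes
  cat(sprintf(
    "differential expression (%s): %d genes, %s vs %s\n",
    if (x$paired) "paired t" else "Welch t", nrow(g), x$groups[2], x$groups[1]))
  cat(sprintf("  DEGs at |log2FC| > %.2f and p < %g: %d up, %d down\n",
              log2(x$fc_threshold), x$alpha,
              sum(g$status == "up"), sum(g$status == "down")))
  invisible(x)
}

#' @export
summary.deg_fit <- function(object, ...) {
  g <- object$genes
  out <- list(n_genes = nrow(g), n_up = sum(g$status == "up"),
              n_down = sum(g$status == "down"),
              groups = object$groups, paired = object$paired,
              fc_threshold = object$fc_threshold, alpha = object$alpha)
  class(out) <- "summary.deg_fit"
  out
}

#' @export
print.summary.deg_fit <- function(x, ...) {
  cat(sprintf("%d genes tested (%s vs %s, %s test)\n", x$n_genes,
              x$groups[2], x$groups[1], if (x$paired) "paired" else "Welch"))
  cat(sprintf("%d up / %d down at FC > %g, p < %g\n", x$n_up, x$n_down,
              x$fc_threshold, x$alpha))
  invisible(x)
}

#' Volcano plot of a DEG analysis
#'
#' @param x A `deg_fit` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.deg_fit <- function(x, ...) {
  g <- x$genes
  col <- ifelse(g$status == "up", "firebrick",
                ifelse(g$status == "down", "steelblue", "grey60"))
  plot(g$log2_fc, -log10(g$p_value), col = col, pch = 16, cex = 0.6,
       xlab = expression(log[2]~fold~change),
       ylab = expression(-log[10]~p), ...)
  abline(v = c(-1, 1) * log2(x$fc_threshold), h = -log10(x$alpha), lty = 2)
  invisible(x)
}

#' Gene-level m6A direction rollup
#'
#' Aggregates called differential sites to genes: a gene is `down` when it
#' owns at least one called-down site and no called-up site, `up`
#' symmetrically, `mixed` when it owns called sites in both directions
#' (mixed genes are excluded from both direction sets), and `none`
#' otherwise.
#'
#' @param diff_results An `m6a_diff` object.
#' @param annotations A `site_annotation` object covering the tested sites.
#' @return Data frame with one row per gene owning at least one tested
#'   site: `gene_id`, `n_sites`, `n_up_sites`, `n_down_sites` (called
#'   counts), `mean_delta` (over called sites, else all sites),
#'   `direction`.
#' @export
gene_level_m6a_direction <- function(diff_results, annotations) {
  s <- diff_results$sites
  skey <- site_key(s$chrom, s$pos, s$strand)
  hits <- attr(annotations, "hits")
  hits <- hits[hits$key %in% skey, , drop = FALSE]
  if (!nrow(hits)) {
    return(data.frame(gene_id = character(0), n_sites = integer(0),
                      n_up_sites = integer(0), n_down_sites = integer(0),
                      mean_delta = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE))
  }
  i <- match(hits$key, skey)
  per_gene <- split(i, hits$gene_id)
  rows <- lapply(names(per_gene), function(gid) {
    idx <- unique(per_gene[[gid]])
    called <- s$called[idx]
    dirs <- s$direction[idx]
    n_up <- sum(called & dirs == "up")
    n_down <- sum(called & dirs == "down")
    direction <- if (n_up > 0L && n_down > 0L) "mixed"
    else if (n_down > 0L) "down"
    else if (n_up > 0L) "up"
    else "none"
    md <- if (any(called)) mean(s$mean_delta[idx][called])
    else mean(s$mean_delta[idx])
    data.frame(gene_id = gid, n_sites = length(idx), n_up_sites = n_up,
               n_down_sites = n_down, mean_delta = md, direction = direction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Intersect differential-methylation and differential-expression gene sets
#'
#' Builds the four gene sets (m6A up/down from the gene-level rollup, DEG
#' up/down from the expression analysis), their pairwise intersection
#' counts, and the concordantly down-regulated genes (m6A down AND
#' expression down) that form the candidate-biomarker class.
#'
#' @param m6a_gene_directions Output of [gene_level_m6a_direction()].
#' @param deg_fit A `deg_fit` object (or its `genes` data frame).
#' @return An object of class `m6a_integration`: list with `sets` (the four
#'   gene-id vectors), `venn` (named intersection counts satisfying
#'   inclusion-exclusion), `concordant_down` (data frame `gene_id`,
#'   `log2_fc`, `p_expression`, `mean_m6a_delta`) and `concordant_up`.
#' @export
intersect_gene_sets <- function(m6a_gene_directions, deg_fit) {
  degs <- if (inherits(deg_fit, "deg_fit")) deg_fit$genes else deg_fit
  sets <- list(
    m6a_up = m6a_gene_directions$gene_id[m6a_gene_directions$direction == "up"],
    m6a_down = m6a_gene_directions$gene_id[m6a_gene_directions$direction == "down"],
    deg_up = degs$gene_id[degs$status == "up"],
    deg_down = degs$gene_id[degs$status == "down"]
  )
  venn <- c(
    m6a_up = length(sets$m6a_up), m6a_down = length(sets$m6a_down),
    deg_up = length(sets$deg_up), deg_down = length(sets$deg_down),
    m6a_up_deg_up = length(intersect(sets$m6a_up, sets$deg_up)),
    m6a_up_deg_down = length(intersect(sets$m6a_up, sets$deg_down)),
    m6a_down_deg_up = length(intersect(sets$m6a_down, sets$deg_up)),
    m6a_down_deg_down = length(intersect(sets$m6a_down, sets$deg_down))
  )
  conc <- function(m6a_set, deg_set) {
    ids <- sort(intersect(m6a_set, deg_set))
    data.frame(
      gene_id = ids,
      log2_fc = degs$log2_fc[match(ids, degs$gene_id)],
      p_expression = degs$p_value[match(ids, degs$gene_id)],
      mean_m6a_delta = m6a_gene_directions$mean_delta[
        match(ids, m6a_gene_directions$gene_id)],
      stringsAsFactors = FALSE
    )
  }
  structure(list(
    sets = sets, venn = venn,
    concordant_down = conc(sets$m6a_down, sets$deg_down),
    concordant_up = conc(sets$m6a_up, sets$deg_up),
    mixed_genes = m6a_gene_directions$gene_id[
      m6a_gene_directions$direction == "mixed"]
  ), class = "m6a_integration")
}

#' @export
print.m6a_integration <- function(x, ...) {
  cat("methylome x transcriptome integration\n")
  cat(sprintf("  m6A genes: %d up / %d down (%d mixed, quarantined)\n",
              x$venn["m6a_up"], x$venn["m6a_down"], length(x$mixed_genes)))
  cat(sprintf("  DEGs: %d up / %d down\n", x$venn["deg_up"], x$venn["deg_down"]))
  cat(sprintf("  concordant down (m6A down & expression down): %d gene(s)\n",
              nrow(x$concordant_down)))
  if (nrow(x$concordant_down)) {
    cat("   ", paste(x$concordant_down$gene_id, collapse = ", "), "\n")
  }
  invisible(x)
}
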