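# Interval-intersection annotation of m6A sites to genes, functional
# regions, biotypes, and per-gene site maps.

REGION_PRECEDENCE <- c("three_prime_utr", "five_prime_utr", "cds",
                       "noncoding_exon", "intron")

#' Intersect m6A sites with gene spans
#'
#' Assigns every site to each gene whose span contains it (half-open
#' containment: `start <= pos < end`), strand-aware by default since
#' direct-RNA reads are stranded. Within each hit gene the site receives a
#' functional-region label (see [assign_functional_region()]); across
#' genes/transcripts the site-level label is resolved by the precedence
#' 3'UTR > 5'UTR > CDS > non-coding exon > intron. Sites hitting no gene
#' (including sites on chromosomes absent from the annotation) are labeled
#' `intergenic`.
#'
#' The overlap step is backed by [GenomicRanges::findOverlaps()].
#'
#' @param sites A `site_calls` table or any data frame with `chrom`, `pos`
#'   (0-based), `strand` columns.
#' @param gene_models A `gene_models` object from [read_gene_models()].
#' @param ignore_strand Intersect without strand matching (plain
#'   BEDTools-default behavior).
#' @return An object of class `site_annotation`: a data frame with one row
#'   per input site (`chrom`, `pos`, `strand`, `key`, `n_genes`,
#'   `gene_ids` comma-separated, `region`), with the per-(site, gene) hit
#'   table in `attr(, "hits")`.
#' @export
intersect_sites_genes <- function(sites, gene_models, ignore_strand = FALSE) {
  genes <- gene_models$genes
  site_gr <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(start = sites$pos + 1L, width = 1L),
    strand = if (ignore_strand) "*" else sites$strand)
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = if (ignore_strand) "*" else genes$strand)
  ov <- suppressWarnings(GenomicRanges::findOverlaps(site_gr, gene_gr))
  qi <- queryHits(ov)
  si <- subjectHits(ov)

  hit_region <- character(length(qi))
  if (length(qi)) {
    for (h in seq_along(qi)) {
      hit_region[h] <- region_in_gene(sites$pos[qi[h]],
                                      genes$gene_id[si[h]], gene_models)
    }
  }
  hits <- data.frame(
    key = site_key(sites$chrom[qi], sites$pos[qi], sites$strand[qi]),
    gene_id = genes$gene_id[si], region = hit_region,
    stringsAsFactors = FALSE
  )

  key <- site_key(sites$chrom, sites$pos, sites$strand)
  region <- rep("intergenic", nrow(sites))
  gene_ids <- rep("", nrow(sites))
  n_genes <- integer(nrow(sites))
  if (nrow(hits)) {
    spl <- split(seq_len(nrow(hits)), hits$key)
    idx <- match(names(spl), key)
    for (g in seq_along(spl)) {
      rows <- spl[[g]]
      gene_ids[idx[g]] <- paste(sort(unique(hits$gene_id[rows])), collapse = ",")
      n_genes[idx[g]] <- length(unique(hits$gene_id[rows]))
      region[idx[g]] <- best_region(hits$region[rows])
    }
  }
  out <- data.frame(chrom = sites$chrom, pos = sites$pos,
                    strand = sites$strand, key = key, n_genes = n_genes,
                    gene_ids = gene_ids, region = region,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, hits = hits, ignore_strand = ignore_strand,
            class = c("site_annotation", "data.frame"))
}

best_region <- function(labels) {
  labels <- labels[labels %in% REGION_PRECEDENCE]
  if (!length(labels)) return("intron")
  REGION_PRECEDENCE[min(match(labels, REGION_PRECEDENCE))]
}

# Region of one position within one gene, resolved across the gene's
# transcripts by the exon-before-intron precedence.
region_in_gene <- function(pos, gene_id, gene_models) {
  f <- gene_models$features
  f <- f[f$gene_id == gene_id, , drop = FALSE]
  g <- gene_models$genes
  coding_gene <- g$biotype[match(gene_id, g$gene_id)] == "protein_coding"
  if (!nrow(f)) return("intron")
  labels <- character(0)
  for (tx in unique(f$transcript_id)) {
    ft <- f[f$transcript_id == tx, , drop = FALSE]
    in_type <- function(type) {
      sel <- ft$type == type
      any(sel) && pos_in_intervals(pos, ft$start[sel], ft$end[sel])
    }
    if (in_type("exon")) {
      lab <- if (in_type("three_prime_utr")) "three_prime_utr"
      else if (in_type("five_prime_utr")) "five_prime_utr"
      else if (in_type("cds")) "cds"
      else "noncoding_exon"
    } else {
      lab <- "intron"
    }
    labels <- c(labels, lab)
  }
  best_region(labels)
}

#' Functional region of a site within a gene
#'
#' Exported convenience around the per-gene region logic: the label of a
#' single position within one gene, with the transcript-level precedence
#' 3'UTR > 5'UTR > CDS > non-coding exon > intron (a position exonic in any
#' transcript is exonic before it is intronic; positions inside the gene
#' span but outside all transcript features fall back to `intron`).
#'
#' @param pos 0-based position (must lie within the gene span).
#' @param gene_id Gene identifier.
#' @param gene_models A `gene_models` object.
#' @return One of `"three_prime_utr"`, `"five_prime_utr"`, `"cds"`,
#'   `"noncoding_exon"`, `"intron"`.
#' @export
assign_functional_region <- function(pos, gene_id, gene_models) {
  g <- gene_models$genes
  i <- match(gene_id, g$gene_id)
  if (is.na(i)) stop_msg("gene '%s' absent from annotation", gene_id)
  if (pos < g$start[i] || pos >= g$end[i]) {
    stop_msg("position %d outside span of gene '%s'", pos, gene_id)
  }
  region_in_gene(pos, gene_id, gene_models)
}

#' Functional-region composition of annotated sites
#'
#' @param annotations A `site_annotation` object.
#' @return Data frame `region`, `count`, `fraction` over sites assigned to
#'   at least one gene; fractions sum to 1. Intergenic sites are excluded
#'   (their count is reported in `attr(, "n_intergenic")`).
#' @export
region_distribution <- function(annotations) {
  ann <- annotations[annotations$region != "intergenic", , drop = FALSE]
  if (!nrow(ann)) stop_msg("no annotated sites")
  counts <- table(factor(ann$region, levels = REGION_PRECEDENCE))
  counts <- counts[counts > 0]
  out <- data.frame(region = names(counts), count = as.integer(counts),
                    fraction = as.integer(counts) / nrow(ann),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_intergenic") <- sum(annotations$region == "intergenic")
  out
}

#' Biotype composition of a gene set
#'
#' @param gene_ids Character vector of gene ids (duplicates collapsed).
#' @param gene_models A `gene_models` object.
#' @return Data frame `biotype`, `count`, `fraction` over the unique genes,
#'   with biotypes not among the common classes bucketed as `"other"`; the
#'   verbatim per-gene table is kept in `attr(, "detail")`.
#' @export
biotype_summary <- function(gene_ids, gene_models) {
  ids <- unique(gene_ids[!is.na(gene_ids) & nzchar(gene_ids)])
  g <- gene_models$genes
  i <- match(ids, g$gene_id)
  if (anyNA(i)) stop_msg("gene '%s' absent from annotation", ids[is.na(i)][1])
  detail <- data.frame(gene_id = ids, biotype = g$biotype[i],
                       stringsAsFactors = FALSE)
  common <- c("protein_coding", "lncRNA", "lincRNA", "miRNA", "snRNA",
              "snoRNA", "rRNA", "pseudogene")
  bucket <- ifelse(detail$biotype %in% common, detail$biotype, "other")
  counts <- sort(table(bucket), decreasing = TRUE)
  out <- data.frame(biotype = names(counts), count = as.integer(counts),
                    fraction = as.integer(counts) / length(ids),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "detail") <- detail
  out
}

#' Per-gene m6A site profile
#'
#' Maps every tested site of a gene with its functional region and a
#' per-pair significance class, mirroring how per-gene site maps are drawn
#' for genes of interest: a site is `consistent` when its pre/post read
#' counts differ significantly (two-sided Fisher's exact test, p < 0.05) in
#' *every* pair, `partial` when in some but not all pairs, and `stable`
#' otherwise.
#'
#' @param gene_id Gene of interest.
#' @param diff_results An `m6a_diff` object.
#' @param gene_models A `gene_models` object.
#' @param pair_alpha Per-pair significance level for the Fisher test.
#' @return A list of class `gene_site_profile` with `sites` (one row per
#'   site: position, region, per-pair significance count, class, called
#'   flag) and `class_counts`.
#' @export
gene_site_profile <- function(gene_id, diff_results, gene_models,
                              pair_alpha = 0.05) {
  g <- gene_models$genes
  i <- match(gene_id, g$gene_id)
  if (is.na(i)) stop_msg("gene '%s' absent from annotation", gene_id)
  s <- diff_results$sites
  inside <- s$chrom == g$chrom[i] & s$pos >= g$start[i] & s$pos < g$end[i] &
    s$strand == g$strand[i]
  s <- s[inside, , drop = FALSE]
  idx <- which(inside)
  n_sig <- integer(nrow(s))
  for (r in seq_len(nrow(s))) {
    for (pc in diff_results$pair_counts) {
      cnt <- pc[idx[r], ]
      if (anyNA(cnt)) next
      ft <- stats::fisher.test(matrix(c(cnt["pre_mod"],
                                        cnt["pre_tot"] - cnt["pre_mod"],
                                        cnt["post_mod"],
                                        cnt["post_tot"] - cnt["post_mod"]),
                                      2, 2))
      if (ft$p.value < pair_alpha) n_sig[r] <- n_sig[r] + 1L
    }
  }
  cls <- ifelse(n_sig == diff_results$n_pairs, "consistent",
                ifelse(n_sig > 0L, "partial", "stable"))
  region <- vapply(s$pos, region_in_gene, "", gene_id = gene_id,
                   gene_models = gene_models)
  sites <- data.frame(chrom = s$chrom, pos = s$pos, strand = s$strand,
                      region = region, mean_delta = s$mean_delta,
                      p_value = s$p_value, called = s$called,
                      n_pairs_significant = n_sig, class = cls,
                      stringsAsFactors = FALSE)
  counts <- table(factor(cls, levels = c("consistent", "partial", "stable")))
  structure(list(gene_id = gene_id, sites = sites,
                 class_counts = counts),
            class = "gene_site_profile")
}

#' @export
print.gene_site_profile <- function(x, ...) {
  cat(sprintf("m6A site profile of %s: %d tested site(s)\n",
              x$gene_id, nrow(x$sites)))
  print(x$class_counts)
  invisible(x)
}
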