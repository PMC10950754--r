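# Fixture builders and independent oracles shared across the suite.

# Closed-form two-sided p for a t statistic at 2 degrees of freedom:
# P(T > t) = 0.5 * (1 - t / sqrt(t^2 + 2)).
oracle_p_df2 <- function(t) {
  2 * 0.5 * (1 - abs(t) / sqrt(t^2 + 2))
}

# Exhaustive Mann-Whitney oracle for tie-free samples: the U null
# distribution is enumerated over all choose(n + m, m) group assignments
# of the pooled observations.
oracle_mw_p <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  nb <- length(b)
  u_of <- function(idx) {
    bb <- pooled[idx]
    aa <- pooled[-idx]
    sum(outer(bb, aa, ">"))
  }
  u_null <- apply(utils::combn(length(pooled), nb), 2, u_of)
  u_obs <- sum(outer(b, a, ">"))
  p1 <- if (u_obs > length(a) * nb / 2) mean(u_null >= u_obs) else
    mean(u_null <= u_obs)
  min(2 * p1, 1)
}

# Minimal two-exon coding transcript as GTF text:
# exons [0,100) and [200,300), CDS [50,250); no explicit UTR features, so
# the reader must infer 5'UTR [0,50) and 3'UTR [250,300) on "+".
toy_gtf <- function(strand = "+", biotype = "protein_coding",
                    with_cds = TRUE) {
  at <- sprintf('gene_id "g1"; transcript_id "t1"; gene_biotype "%s";',
                biotype)
  lines <- c(
    sprintf('chr1\ttoy\tgene\t1\t300\t.\t%s\t.\tgene_id "g1"; gene_biotype "%s";',
            strand, biotype),
    sprintf("chr1\ttoy\ttranscript\t1\t300\t.\t%s\t.\t%s", strand, at),
    sprintf("chr1\ttoy\texon\t1\t100\t.\t%s\t.\t%s", strand, at),
    sprintf("chr1\ttoy\texon\t201\t300\t.\t%s\t.\t%s", strand, at))
  if (with_cds) {
    lines <- c(lines,
               sprintf("chr1\ttoy\tCDS\t51\t100\t.\t%s\t.\t%s", strand, at),
               sprintf("chr1\ttoy\tCDS\t201\t250\t.\t%s\t.\t%s", strand, at))
  }
  f <- tempfile(fileext = ".gtf")
  writeLines(lines, f)
  f
}

# Gene-models object built directly (span-only genes, no features), for
# intersection tests that do not need region structure.
span_models <- function(gene_id, chrom, start, end, strand,
                        biotype = "protein_coding") {
  structure(list(
    genes = data.frame(gene_id = gene_id, gene_name = gene_id,
                       biotype = biotype, chrom = chrom, strand = strand,
                       start = start, end = end, stringsAsFactors = FALSE),
    features = data.frame(gene_id = character(0),
                          transcript_id = character(0),
                          type = character(0), chrom = character(0),
                          strand = character(0), start = integer(0),
                          end = integer(0))
  ), class = "gene_models")
}

# Paired site tables with given per-sample ratios at shared positions.
pair_from_ratios <- function(patient, pre_ratio, post_ratio, coverage = 100,
                             chrom = "chr1", strand = "+") {
  n <- length(pre_ratio)
  mk <- function(r, tag) {
    site_calls(chrom = rep(chrom, n), pos = seq_len(n) * 10L,
               strand = rep(strand, n), motif = rep("AAACA", n),
               modified = as.integer(round(r * coverage)),
               total = rep(as.integer(coverage), n),
               sample_id = paste0(patient, "_", tag))
  }
  sample_pair(patient, mk(pre_ratio, "pre"), mk(post_ratio, "post"))
}

# Binomial-sampled paired tables around true stoichiometries.
pairs_from_truth <- function(p_pre, p_post, n_pairs = 3, coverage = 100) {
  n <- length(p_pre)
  lapply(seq_len(n_pairs), function(k) {
    mk <- function(p, tag) {
      site_calls(chrom = rep("chr1", n), pos = seq_len(n) * 10L,
                 strand = rep("+", n), motif = rep("AAACA", n),
                 modified = rbinom(n, coverage, p),
                 total = rep(as.integer(coverage), n),
                 sample_id = sprintf("P%d_%s", k, tag))
    }
    sample_pair(sprintf("P%d", k), mk(p_pre, "pre"), mk(p_post, "post"))
  })
}
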