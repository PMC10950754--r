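# Study-design container for the synthetic-data generator.

#' Design of a synthetic paired m6A study
#'
#' Describes a synthetic study emulating a paired pre/post-treatment
#' direct-RNA experiment: a small genome with gene models, per-site m6A
#' calls for each patient and condition, a gene expression count matrix,
#' and a per-read poly(A) table — all with planted, recorded ground truth.
#'
#' The defaults mirror the paired-bone-marrow study structure this package
#' targets: 3 patients sampled before and after treatment, binomial
#' per-read modification sampling around a per-site stoichiometry,
#' negative-binomial expression counts, and log-normal tail lengths.
#' Planted effects use an m6A ratio shift of 0.4 at ~100x coverage and
#' strong (32-fold) expression changes with low count dispersion, so that
#' every planted label is recoverable by the corresponding pipeline stage
#' at its default thresholds; 13 genes are planted as concordantly
#' down-regulated (m6A down and expression down), three of which
#' additionally carry a halved poly(A) tail median.
#'
#' @param seed Master seed. Each generator stage derives its own stream
#'   from it (fixed offsets), so adding a stage never perturbs the others.
#' @param n_patients Number of pre/post pairs.
#' @param n_chromosomes,n_genes Genome shape.
#' @param coding_fraction Fraction of genes with `protein_coding` biotype.
#' @param rrach_freqs Named sampling frequencies over the 12 RRACH
#'   variants (normalized internally).
#' @param region_probs Planting probabilities of site functional regions
#'   within coding genes (3'UTR-dominant by default).
#' @param n_m6a_down_genes,n_m6a_up_genes Genes with planted m6A shifts;
#'   every site of such a gene is shifted.
#' @param sites_per_m6a_gene Integer range of planted sites per m6A gene.
#' @param n_null_sites,n_null_site_genes Unshifted sites and the gene pool
#'   carrying them.
#' @param n_intergenic_sites Sites planted outside any gene.
#' @param delta Planted m6A ratio shift (post - pre is `-delta` for down
#'   genes, `+delta` for up genes).
#' @param coverage_mean,coverage_size,coverage_min Negative-binomial read
#'   coverage per site and sample (`coverage_size = Inf` gives fixed
#'   coverage `coverage_mean`), floored at `coverage_min`.
#' @param post_retention Fraction of null sites retained in post-treatment
#'   tables (1 keeps all; lower values emulate global site loss after
#'   treatment).
#' @param n_deg_down,n_deg_up,n_concordant_down Planted expression-change
#'   genes; the concordant genes are a subset of both the m6A-down and
#'   expression-down sets by construction.
#' @param deg_log2fc Magnitude of planted log2 fold changes.
#' @param dispersion Negative-binomial dispersion of counts (0 gives
#'   counts exactly equal to their means).
#' @param expr_meanlog,expr_sdlog,expr_min_mean Log-normal distribution of
#'   baseline gene expression means, with a floor.
#' @param n_polya_genes,n_polya_shortened,polya_reads Genes with poly(A)
#'   reads, how many of the concordant genes get shortened tails, and
#'   reads per gene per sample.
#' @param tail_meanlog,tail_sdlog,polya_shrink Log-normal tail-length
#'   parameters; shortened genes have their post-treatment median
#'   multiplied by `polya_shrink`.
#' @return A validated list of class `study_design`.
#' @seealso [simulate_study()]
#' @export
study_design <- function(seed = 1,
                         n_patients = 3,
                         n_chromosomes = 5,
                         n_genes = 300,
                         coding_fraction = 0.87,
                         rrach_freqs = c(
                           AAACA = 0.16, AAACC = 0.09, AAACT = 0.09,
                           AGACA = 0.05, AGACC = 0.07, AGACT = 0.07,
                           GAACA = 0.11, GAACC = 0.08, GAACT = 0.08,
                           GGACA = 0.07, GGACC = 0.06, GGACT = 0.07),
                         region_probs = c(three_prime_utr = 0.55,
                                          cds = 0.25,
                                          five_prime_utr = 0.10,
                                          intron = 0.10),
                         n_m6a_down_genes = 40,
                         n_m6a_up_genes = 8,
                         sites_per_m6a_gene = c(3, 6),
                         n_null_sites = 1200,
                         n_null_site_genes = 110,
                         n_intergenic_sites = 15,
                         delta = 0.4,
                         coverage_mean = 100,
                         coverage_size = 10,
                         coverage_min = 20,
                         post_retention = 1,
                         n_deg_down = 30,
                         n_deg_up = 15,
                         n_concordant_down = 13,
                         deg_log2fc = 5,
                         dispersion = 0.05,
                         expr_meanlog = log(300),
                         expr_sdlog = 1,
                         expr_min_mean = 30,
                         n_polya_genes = 50,
                         n_polya_shortened = 3,
                         polya_reads = 60,
                         tail_meanlog = log(120),
                         tail_sdlog = 0.35,
                         polya_shrink = 0.5) {
  d <- as.list(environment())
  if (!setequal(names(d$rrach_freqs), rrach_variants())) {
    stop_msg("rrach_freqs must be named by the 12 RRACH variants")
  }
  d$rrach_freqs <- d$rrach_freqs / sum(d$rrach_freqs)
  d$region_probs <- d$region_probs / sum(d$region_probs)
  if (d$n_concordant_down > min(d$n_m6a_down_genes, d$n_deg_down)) {
    stop_msg("concordant genes must fit inside both down sets")
  }
  n_role <- d$n_m6a_down_genes + d$n_m6a_up_genes +
    (d$n_deg_down - d$n_concordant_down) + d$n_deg_up + d$n_null_site_genes
  if (n_role > d$n_genes) stop_msg("n_genes too small for the planted sets")
  stopifnot(d$delta > 0, d$delta <= 0.5,
            d$post_retention > 0, d$post_retention <= 1,
            d$dispersion >= 0, d$coverage_min >= 1,
            d$n_patients >= 2, d$n_polya_shortened <= d$n_concordant_down)
  structure(d, class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(
    "synthetic paired m6A study design (seed %d)\n", x$seed))
  cat(sprintf("  %d patients x pre/post; %d genes on %d chromosomes (%.0f%% coding)\n",
              x$n_patients, x$n_genes, x$n_chromosomes,
              100 * x$coding_fraction))
  cat(sprintf("  planted: %d m6A-down / %d m6A-up genes (delta %.2f), %d DEG-down / %d DEG-up (|log2FC| %g), %d concordant-down, %d poly(A)-shortened\n",
              x$n_m6a_down_genes, x$n_m6a_up_genes, x$delta,
              x$n_deg_down, x$n_deg_up, x$deg_log2fc,
              x$n_concordant_down, x$n_polya_shortened))
  invisible(x)
}
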