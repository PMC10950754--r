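# End-to-end orchestration: sites -> differential -> annotation ->
# expression -> integration -> poly(A), with a structured results
# directory and a deterministic report.json.

#' Run the full paired differential m6A pipeline
#'
#' Drives every stage over a samplesheet of paired site-call tables plus
#' reference, annotation, and (optionally) expression and poly(A) inputs,
#' writing a structured results directory:
#' \describe{
#'   \item{sites/}{chromosome distribution, RRACH motif proportions and
#'     logo matrix, pre-vs-post group comparison.}
#'   \item{differential/}{full per-site test table, BED files of called
#'     sites split by direction.}
#'   \item{annotation/}{per-site annotations, functional-region
#'     distribution of called-down sites, biotype summary of m6A-down
#'     genes.}
#'   \item{expression/}{DEG table; integration gene sets, Venn counts and
#'     concordantly down-regulated genes.}
#'   \item{polya/}{per-gene tail-length comparisons.}
#'   \item{report.json}{the funnel of record counts through every filter,
#'     with every threshold echoed for provenance.}
#' }
#' The analysis path contains no randomness: re-running on identical
#' inputs reproduces `report.json` byte for byte.
#'
#' @param samplesheet Path to a TSV with columns `patient_id`, `pre_path`,
#'   `post_path`, `pre_sample`, `post_sample` (>= 2 rows), or an
#'   equivalent data frame.
#' @param fasta,gtf Reference genome and annotation paths.
#' @param counts Optional count-matrix TSV (columns named like the
#'   samplesheet's sample ids); expression and integration stages are
#'   skipped when absent.
#' @param polya Optional poly(A) TSV; the tail stage is skipped when
#'   absent.
#' @param outdir Output directory.
#' @param min_coverage Per-sample coverage floor for testable sites.
#' @param alpha_m6a Raw p-value gate of the differential m6A caller.
#' @param high_threshold High-m6A-level ratio cutoff (strict).
#' @param fc_threshold,alpha_deg DEG thresholds.
#' @param two_sided Sidedness of the paired t-test.
#' @param paired Paired (default) or Welch DEG test.
#' @param ignore_strand Strand-blind site-gene intersection.
#' @param dialect Position dialect of the site-call TSVs.
#' @return The report, invisibly (also written as `report.json`).
#' @export
run_full <- function(samplesheet, fasta, gtf, counts = NULL, polya = NULL,
                     outdir, min_coverage = 10, alpha_m6a = 0.1,
                     high_threshold = 0.5, fc_threshold = 2,
                     alpha_deg = 0.05, two_sided = TRUE, paired = TRUE,
                     ignore_strand = FALSE,
                     dialect = c("one-based", "zero-based")) {
  dialect <- match.arg(dialect)
  sheet <- if (is.data.frame(samplesheet)) samplesheet else {
    sh <- read_tsv(samplesheet)
    # Relative table paths are resolved against the samplesheet location.
    for (col in c("pre_path", "post_path")) {
      rel <- !file.exists(sh[[col]])
      sh[[col]][rel] <- file.path(dirname(samplesheet), sh[[col]][rel])
    }
    sh
  }
  need <- c("patient_id", "pre_path", "post_path", "pre_sample",
            "post_sample")
  if (!all(need %in% names(sheet))) {
    stop_msg("samplesheet must have columns: %s", paste(need, collapse = ", "))
  }
  if (nrow(sheet) < 2L) {
    stop_msg("at least 2 complete sample pairs are required")
  }
  for (sub in c("sites", "differential", "annotation", "expression",
                "polya")) {
    dir.create(file.path(outdir, sub), recursive = TRUE,
               showWarnings = FALSE)
  }
  report <- list(thresholds = list(
    min_coverage = min_coverage, alpha_m6a = alpha_m6a,
    high_m6a_threshold = high_threshold, fc_threshold = fc_threshold,
    alpha_deg = alpha_deg, two_sided = two_sided, paired = paired,
    ignore_strand = ignore_strand, dialect = dialect))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_msg("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  # --- sites ---------------------------------------------------------
  ref <- stage("sites", load_fasta(fasta))
  tables <- stage("sites", {
    out <- list()
    for (i in seq_len(nrow(sheet))) {
      out[[sheet$pre_sample[i]]] <- read_site_calls(
        sheet$pre_path[i], dialect, sheet$pre_sample[i], fasta = ref)
      out[[sheet$post_sample[i]]] <- read_site_calls(
        sheet$post_path[i], dialect, sheet$post_sample[i], fasta = ref)
    }
    out
  })
  pre_tabs <- tables[sheet$pre_sample]
  post_tabs <- tables[sheet$post_sample]
  report$sites <- list(
    n_samples = length(tables),
    sites_loaded = setNames(lapply(tables, nrow), names(tables)),
    high_level = setNames(lapply(tables, function(t) {
      sum(is_high_m6a(t$ratio, high_threshold))
    }), names(tables))
  )
  stage("sites", {
    pooled_pre <- do.call(rbind, lapply(pre_tabs, as.data.frame))
    write_tsv(chromosome_distribution(pooled_pre),
              file.path(outdir, "sites", "chromosome_distribution_pre.tsv"))
    mot <- motif_proportions(pre_tabs)
    write_tsv(mot$variants,
              file.path(outdir, "sites", "motif_proportions_pre.tsv"))
    write_tsv(as.data.frame(mot$logo),
              file.path(outdir, "sites", "logo_matrix_pre.tsv"))
    cmp <- global_level_comparison(pre_tabs, post_tabs)
    report$sites$group_comparison <- list(
      n_sites_pre = cmp$n_sites_a, n_sites_post = cmp$n_sites_b,
      relative_site_count = cmp$relative_site_count,
      mannwhitney_p = cmp$p_value)
  })

  # --- differential --------------------------------------------------
  diff <- stage("differential", {
    pairs <- lapply(seq_len(nrow(sheet)), function(i) {
      sample_pair(sheet$patient_id[i], tables[[sheet$pre_sample[i]]],
                  tables[[sheet$post_sample[i]]])
    })
    call_differential_sites(pairs, alpha = alpha_m6a,
                            min_coverage = min_coverage,
                            two_sided = two_sided)
  })
  s <- diff$sites
  write_tsv(s, file.path(outdir, "differential", "sites.tsv"))
  for (dirn in c("up", "down")) {
    write_bed(s[s$called & s$direction == dirn, , drop = FALSE],
              file.path(outdir, "differential", paste0(dirn, ".bed")))
  }
  report$differential <- list(
    sites_tested = nrow(s), degenerate_excluded = diff$n_degenerate,
    called = sum(s$called),
    called_up = sum(s$called & s$direction == "up"),
    called_down = sum(s$called & s$direction == "down"))

  # --- annotation ----------------------------------------------------
  models <- stage("annotation", read_gene_models(gtf))
  ann <- stage("annotation",
               intersect_sites_genes(s, models,
                                     ignore_strand = ignore_strand))
  write_tsv(as.data.frame(ann),
            file.path(outdir, "annotation", "site_annotations.tsv"))
  gdir <- stage("annotation", gene_level_m6a_direction(diff, ann))
  write_tsv(gdir, file.path(outdir, "annotation", "gene_directions.tsv"))
  down_called <- ann[s$called & s$direction == "down", , drop = FALSE]
  if (nrow(down_called[down_called$region != "intergenic", ])) {
    rd <- region_distribution(down_called)
    write_tsv(rd, file.path(outdir, "annotation",
                            "region_distribution_down.tsv"))
    report$annotation$region_distribution_down <-
      setNames(as.list(rd$fraction), rd$region)
  }
  down_genes <- gdir$gene_id[gdir$direction == "down"]
  if (length(down_genes)) {
    bt <- biotype_summary(down_genes, models)
    write_tsv(bt, file.path(outdir, "annotation", "biotype_down_genes.tsv"))
    pc <- bt$fraction[bt$biotype == "protein_coding"]
    report$annotation$protein_coding_fraction_down <-
      if (length(pc)) pc else 0
  }
  report$annotation$genes_m6a_up <- sum(gdir$direction == "up")
  report$annotation$genes_m6a_down <- sum(gdir$direction == "down")
  report$annotation$genes_m6a_mixed <- sum(gdir$direction == "mixed")

  # --- expression + integration -------------------------------------
  if (!is.null(counts)) {
    degs <- stage("expression", {
      cm <- read_counts(counts)
      samp <- c(sheet$pre_sample, sheet$post_sample)
      missing <- setdiff(samp, colnames(cm))
      if (length(missing)) {
        stop_msg("count matrix lacks sample column(s): %s",
                 paste(missing, collapse = ", "))
      }
      cm <- cm[, samp, drop = FALSE]
      call_degs(cm, rep(c("pre", "post"), each = nrow(sheet)),
                paired = paired, fc_threshold = fc_threshold,
                alpha = alpha_deg)
    })
    write_tsv(degs$genes, file.path(outdir, "expression", "degs.tsv"))
    integration <- stage("integration", intersect_gene_sets(gdir, degs))
    write_tsv(integration$concordant_down,
              file.path(outdir, "expression", "concordant_down.tsv"))
    report$expression <- list(
      genes_tested = nrow(degs$genes),
      deg_up = sum(degs$genes$status == "up"),
      deg_down = sum(degs$genes$status == "down"))
    report$integration <- list(
      venn = as.list(integration$venn),
      concordant_down_genes = integration$concordant_down$gene_id,
      concordant_up_genes = integration$concordant_up$gene_id)
  }

  # --- poly(A) -------------------------------------------------------
  if (!is.null(polya)) {
    pres <- stage("polya", {
      tab <- read_polya(polya)
      gm <- setNames(rep(c("pre", "post"), each = nrow(sheet)),
                     c(sheet$pre_sample, sheet$post_sample))
      batch_compare_polya(tab, group_map = gm)
    })
    write_tsv(as.data.frame(pres),
              file.path(outdir, "polya", "tail_comparisons.tsv"))
    report$polya <- list(
      genes_tested = nrow(pres),
      genes_skipped = length(attr(pres, "skipped")),
      shorter_q05 = sum(pres$q_value < 0.05 & pres$direction == "shorter"))
  }

  report_path <- file.path(outdir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(report)
}
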