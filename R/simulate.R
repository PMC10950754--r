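# Ground-truth synthetic data: reference genome + annotation with planted
# RRACH sites, per-sample site-call tables, expression counts, poly(A)
# reads. All randomness lives here; the analysis path is deterministic.

# Uniform integer in [lo, hi] drawn from the R RNG stream.
rint <- function(n, lo, hi) lo + floor(runif(n) * (hi - lo + 1L))

#' Generate the synthetic reference genome, annotation, and site truth
#'
#' Builds chromosomes of random sequence carrying non-overlapping genes
#' (1-3 transcripts each, explicit UTR/CDS features, biotypes at the
#' designed coding fraction), plants RRACH 5-mers at recorded positions
#' with the designed variant frequencies, and assigns every planted site
#' its true pre/post stoichiometry according to the gene's role.
#'
#' @param design A [study_design()].
#' @return A list of class `m6a_reference`: `sequences`
#'   ([Biostrings::DNAStringSet]), `gtf` (character vector of GTF lines),
#'   `truth_sites` (one row per site: position, strand, motif, gene, true
#'   region, role, true pre/post stoichiometry), `truth_genes` (per-gene
#'   roles: biotype, m6A label, true log2 fold change, poly(A) label), and
#'   the `design`.
#' @export
generate_reference <- function(design) {
  set.seed(design$seed + 101L)
  d <- design
  ids <- sprintf("G%04d", seq_len(d$n_genes))

  # Role blocks (gene placement is randomized across chromosomes anyway).
  m6a_down <- ids[seq_len(d$n_m6a_down_genes)]
  concordant <- m6a_down[seq_len(d$n_concordant_down)]
  m6a_up <- ids[d$n_m6a_down_genes + seq_len(d$n_m6a_up_genes)]
  off <- d$n_m6a_down_genes + d$n_m6a_up_genes
  deg_down_only <- ids[off + seq_len(d$n_deg_down - d$n_concordant_down)]
  off <- off + d$n_deg_down - d$n_concordant_down
  deg_up <- ids[off + seq_len(d$n_deg_up)]
  off <- off + d$n_deg_up
  null_site_genes <- ids[off + seq_len(d$n_null_site_genes)]
  deg_down <- c(concordant, deg_down_only)

  # Planted-role genes must be coding (their sites live in UTR/CDS).
  role_genes <- c(m6a_down, m6a_up, deg_down_only, deg_up)
  n_noncoding <- round((1 - d$coding_fraction) * d$n_genes)
  eligible <- setdiff(ids, role_genes)
  noncoding <- sort(sample(eligible, n_noncoding))
  biotype <- ifelse(ids %in% noncoding, "lncRNA", "protein_coding")

  polya_pool <- setdiff(ids, c(role_genes, noncoding))
  polya_genes <- c(concordant,
                   sample(polya_pool, d$n_polya_genes - d$n_concordant_down))
  polya_short <- concordant[seq_len(d$n_polya_shortened)]

  # Build gene structures chromosome by chromosome.
  cursor <- rep(300L, d$n_chromosomes)
  genes <- vector("list", d$n_genes)
  feats <- vector("list", d$n_genes)
  for (gi in seq_len(d$n_genes)) {
    chrom_i <- ((gi - 1L) %% d$n_chromosomes) + 1L
    st <- if (runif(1) < 0.5) "+" else "-"
    k <- rint(1L, 2L, 4L)
    ex_len <- c(rint(1L, 200L, 300L),
                if (k > 2L) rint(k - 2L, 150L, 400L),
                rint(1L, 400L, 550L))
    in_len <- rint(k - 1L, 100L, 300L)
    gstart <- cursor[chrom_i]
    ex_start <- gstart + cumsum(c(0L, head(ex_len, -1L) + in_len))
    ex_end <- ex_start + ex_len
    gend <- ex_end[k]
    cursor[chrom_i] <- gend + 300L
    coding <- biotype[gi] == "protein_coding"
    if (coding) {
      # Margin sizes: 3'UTR side gets the larger room for site planting.
      m5 <- rint(1L, 50L, 100L)
      m3 <- rint(1L, 200L, 300L)
      left <- if (st == "+") m5 else m3
      right <- if (st == "+") m3 else m5
      cds_s <- gstart + left
      cds_e <- gend - right
    } else {
      cds_s <- cds_e <- NA_integer_
    }
    n_tx <- sample(1:3, 1L, prob = c(0.6, 0.3, 0.1))
    txf <- vector("list", n_tx)
    for (ti in seq_len(n_tx)) {
      keep <- seq_len(k)
      if (ti > 1L && k > 2L) keep <- keep[-rint(1L, 2L, k - 1L)]
      txf[[ti]] <- transcript_features(
        sprintf("%s.t%d", ids[gi], ti), ids[gi], ex_start[keep],
        ex_end[keep], cds_s, cds_e, st)
    }
    genes[[gi]] <- data.frame(
      gene_id = ids[gi], biotype = biotype[gi],
      chrom = sprintf("chr%d", chrom_i), strand = st,
      start = gstart, end = gend, stringsAsFactors = FALSE)
    feats[[gi]] <- do.call(rbind, txf)
  }
  genes <- do.call(rbind, genes)
  features <- do.call(rbind, feats)
  chrom_len <- cursor + 200L
  names(chrom_len) <- sprintf("chr%d", seq_len(d$n_chromosomes))

  # Plant sites.
  site_rows <- list()
  plant_gene_sites <- function(gid, n, role) {
    g <- genes[genes$gene_id == gid, ]
    f <- features[features$gene_id == gid &
                    features$transcript_id == sprintf("%s.t1", gid), ]
    probs <- if (g$biotype == "protein_coding") d$region_probs else
      c(noncoding_exon = 1)
    ex <- f[f$type == "exon", , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    gaps <- interval_gaps(ex$start, ex$end)
    ivs <- list(
      three_prime_utr = f[f$type == "three_prime_utr", c("start", "end")],
      five_prime_utr = f[f$type == "five_prime_utr", c("start", "end")],
      cds = f[f$type == "CDS", c("start", "end")],
      noncoding_exon = ex[c("start", "end")],
      intron = data.frame(start = gaps$start, end = gaps$end)
    )
    taken <- integer(0)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(200L)) {
        region <- sample(names(probs), 1L, prob = probs)
        iv <- ivs[[region]]
        iv <- iv[iv$end - iv$start >= 10L, , drop = FALSE]
        if (!nrow(iv)) next
        r <- rint(1L, 1L, nrow(iv))
        pos <- rint(1L, iv$start[r] + 3L, iv$end[r] - 4L)
        if (length(taken) && min(abs(taken - pos)) < 8L) next
        taken <- c(taken, pos)
        out[[i]] <- data.frame(chrom = g$chrom, pos = pos, strand = g$strand,
                               gene_id = gid, region = region, role = role,
                               stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed) {
        stop_msg("infeasible design: cannot place %d site(s) in gene %s",
                 n, gid)
      }
    }
    do.call(rbind, out)
  }

  for (gid in m6a_down) {
    site_rows[[gid]] <- plant_gene_sites(
      gid, rint(1L, d$sites_per_m6a_gene[1], d$sites_per_m6a_gene[2]), "down")
  }
  for (gid in m6a_up) {
    site_rows[[gid]] <- plant_gene_sites(
      gid, rint(1L, 2L, 4L), "up")
  }
  n_per_null_gene <- stats::rmultinom(
    1, d$n_null_sites, rep(1, d$n_null_site_genes))[, 1]
  for (i in seq_along(null_site_genes)) {
    if (n_per_null_gene[i] == 0L) next
    gid <- null_site_genes[i]
    site_rows[[gid]] <- plant_gene_sites(gid, n_per_null_gene[i], "null")
  }
  if (d$n_intergenic_sites > 0L) {
    # The first 250 bases of every chromosome are gene-free by
    # construction; an 8-base grid keeps motif windows disjoint.
    cand <- expand.grid(chrom = sprintf("chr%d", seq_len(d$n_chromosomes)),
                        pos = seq(10L, 240L, by = 8L),
                        stringsAsFactors = FALSE)
    pick <- cand[sample(nrow(cand), min(d$n_intergenic_sites, nrow(cand))), ]
    site_rows[["intergenic"]] <- data.frame(
      chrom = pick$chrom, pos = pick$pos,
      strand = ifelse(runif(nrow(pick)) < 0.5, "+", "-"),
      gene_id = "", region = "intergenic", role = "null",
      stringsAsFactors = FALSE)
  }
  truth_sites <- do.call(rbind, site_rows)
  rownames(truth_sites) <- NULL

  # Motifs and stoichiometries.
  nsite <- nrow(truth_sites)
  truth_sites$motif <- sample(names(d$rrach_freqs), nsite, replace = TRUE,
                              prob = d$rrach_freqs)
  p_pre <- numeric(nsite)
  role <- truth_sites$role
  p_pre[role == "down"] <- runif(sum(role == "down"), 0.5, 0.9)
  p_pre[role == "up"] <- runif(sum(role == "up"), 0.1, 0.5)
  p_pre[role == "null"] <- pmin(pmax(rbeta(sum(role == "null"), 2, 2),
                                     0.02), 0.98)
  p_post <- p_pre
  p_post[role == "down"] <- pmin(pmax(p_pre[role == "down"] - d$delta, 0), 1)
  p_post[role == "up"] <- pmin(pmax(p_pre[role == "up"] + d$delta, 0), 1)
  truth_sites$p_pre <- p_pre
  truth_sites$p_post <- p_post

  # Chromosome sequences with motifs stamped in.
  bases <- c("A", "C", "G", "T")
  seqs <- lapply(chrom_len, function(L) sample(bases, L, replace = TRUE))
  for (i in seq_len(nsite)) {
    chrom <- truth_sites$chrom[i]
    pos <- truth_sites$pos[i]
    mot <- truth_sites$motif[i]
    if (truth_sites$strand[i] == "-") mot <- revcomp(mot)
    seqs[[chrom]][(pos - 1L):(pos + 3L)] <- strsplit(mot, "")[[1]]
  }
  sequences <- Biostrings::DNAStringSet(vapply(seqs, paste, "", collapse = ""))
  names(sequences) <- names(chrom_len)

  truth_genes <- data.frame(
    gene_id = genes$gene_id, biotype = genes$biotype,
    chrom = genes$chrom, strand = genes$strand,
    m6a_label = ifelse(genes$gene_id %in% m6a_down, "down",
                       ifelse(genes$gene_id %in% m6a_up, "up", "none")),
    deg_label = ifelse(genes$gene_id %in% deg_down, "down",
                       ifelse(genes$gene_id %in% deg_up, "up", "none")),
    concordant_down = genes$gene_id %in% concordant,
    polya_label = ifelse(genes$gene_id %in% polya_short, "shortened",
                         ifelse(genes$gene_id %in% polya_genes, "null",
                                "none")),
    stringsAsFactors = FALSE)
  # Baseline expression means. Planted-down genes get moderate-to-high
  # baselines so their post-treatment counts are still quantifiable;
  # planted-up genes start lowly expressed (transcripts switched on by
  # treatment), which also keeps the post-treatment library-size shift --
  # and hence the compositional bias of per-million scaling -- small.
  mu <- pmax(rlnorm(d$n_genes, d$expr_meanlog, d$expr_sdlog), d$expr_min_mean)
  mu[truth_genes$deg_label == "down"] <- pmin(
    pmax(mu[truth_genes$deg_label == "down"], 200), 400)
  mu[truth_genes$deg_label == "up"] <- runif(sum(truth_genes$deg_label == "up"),
                                             30, 60)
  truth_genes$expr_mean <- mu
  truth_genes$log2fc_true <- ifelse(truth_genes$deg_label == "down",
                                    -d$deg_log2fc,
                                    ifelse(truth_genes$deg_label == "up",
                                           d$deg_log2fc, 0))

  structure(list(
    sequences = sequences,
    gtf = build_gtf_lines(genes, features),
    genes = genes, features = features,
    truth_sites = truth_sites, truth_genes = truth_genes,
    design = d
  ), class = "m6a_reference")
}

revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# Feature set of one transcript (0-based half-open): exons, and for coding
# transcripts the CDS pieces plus explicit UTRs flanking the CDS span.
transcript_features <- function(tx_id, gene_id, ex_start, ex_end,
                                cds_s, cds_e, strand) {
  row <- function(type, s, e) {
    if (!length(s)) return(NULL)
    data.frame(gene_id = gene_id, transcript_id = tx_id, type = type,
               start = as.integer(s), end = as.integer(e), strand = strand,
               stringsAsFactors = FALSE)
  }
  out <- list(row("exon", ex_start, ex_end))
  if (!is.na(cds_s)) {
    cs <- pmax(ex_start, cds_s)
    ce <- pmin(ex_end, cds_e)
    keep <- cs < ce
    out <- c(out, list(row("CDS", cs[keep], ce[keep])))
    nonc <- interval_subtract(ex_start, ex_end, cds_s, cds_e)
    left <- nonc$end <= cds_s
    lab_left <- if (strand == "+") "five_prime_utr" else "three_prime_utr"
    lab_right <- if (strand == "+") "three_prime_utr" else "five_prime_utr"
    out <- c(out, list(row(lab_left, nonc$start[left], nonc$end[left]),
                       row(lab_right, nonc$start[!left], nonc$end[!left])))
  }
  do.call(rbind, Filter(Negate(is.null), out))
}

# Deterministic GTF text (1-based closed coordinates on output).
build_gtf_lines <- function(genes, features) {
  gl <- sprintf(
    '%s\tm6adiff_sim\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_biotype "%s";',
    genes$chrom, genes$start + 1L, genes$end, genes$strand,
    genes$gene_id, genes$biotype)
  chrom <- genes$chrom[match(features$gene_id, genes$gene_id)]
  biot <- genes$biotype[match(features$gene_id, genes$gene_id)]
  tx_first <- !duplicated(features$transcript_id)
  tx_span <- do.call(rbind, lapply(
    split(seq_len(nrow(features)), features$transcript_id), function(i) {
      data.frame(i1 = i[1], s = min(features$start[i]),
                 e = max(features$end[i]))
    }))
  tl <- sprintf(
    '%s\tm6adiff_sim\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
    chrom[tx_span$i1], tx_span$s + 1L, tx_span$e,
    features$strand[tx_span$i1], features$gene_id[tx_span$i1],
    features$transcript_id[tx_span$i1], biot[tx_span$i1])
  fl <- sprintf(
    '%s\tm6adiff_sim\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
    chrom, features$type, features$start + 1L, features$end,
    features$strand, features$gene_id, features$transcript_id, biot)
  c("##gff-version 2", gl, tl, fl)
}

#' Generate per-sample site-call tables from a synthetic reference
#'
#' For every patient and condition, draws per-site coverage from the
#' designed distribution and modified-read counts from
#' `Binomial(coverage, true stoichiometry)`. When `post_retention < 1`, a
#' fixed random subset of null sites is removed from all post-treatment
#' tables, emulating global site loss after treatment.
#'
#' @param design A [study_design()].
#' @param ref The matching [generate_reference()] output.
#' @return Named list of `site_calls` tables (`P1_pre`, `P1_post`, ...).
#' @export
generate_site_calls <- function(design, ref) {
  set.seed(design$seed + 202L)
  ts <- ref$truth_sites
  n <- nrow(ts)
  dropped_post <- rep(FALSE, n)
  if (design$post_retention < 1) {
    null_idx <- which(ts$role == "null")
    n_drop <- round((1 - design$post_retention) * length(null_idx))
    dropped_post[sample(null_idx, n_drop)] <- TRUE
  }
  draw_cov <- function(n) {
    if (is.infinite(design$coverage_size)) {
      rep(as.integer(design$coverage_mean), n)
    } else {
      pmax(rnbinom(n, mu = design$coverage_mean,
                   size = design$coverage_size),
           as.integer(design$coverage_min))
    }
  }
  out <- list()
  for (p in seq_len(design$n_patients)) {
    for (cond in c("pre", "post")) {
      keep <- if (cond == "post") !dropped_post else rep(TRUE, n)
      truth_p <- if (cond == "post") ts$p_post else ts$p_pre
      cov <- draw_cov(sum(keep))
      mod <- rbinom(sum(keep), cov, truth_p[keep])
      sid <- sprintf("P%d_%s", p, cond)
      out[[sid]] <- site_calls(
        chrom = ts$chrom[keep], pos = ts$pos[keep], strand = ts$strand[keep],
        motif = ts$motif[keep], modified = mod, total = cov,
        sample_id = sid, source = sid)
    }
  }
  out
}

#' Generate the expression count matrix
#'
#' Counts are negative binomial around each gene's baseline mean, with the
#' planted log2 fold change applied to post-treatment samples. With
#' `dispersion = 0` the counts equal their means exactly.
#'
#' @inheritParams generate_site_calls
#' @return Numeric matrix, genes x (2 * n_patients) samples.
#' @export
generate_counts <- function(design, ref) {
  set.seed(design$seed + 303L)
  tg <- ref$truth_genes
  samples <- as.vector(t(outer(seq_len(design$n_patients), c("pre", "post"),
                               function(p, cond) sprintf("P%d_%s", p, cond))))
  m <- matrix(0, nrow = nrow(tg), ncol = length(samples),
              dimnames = list(tg$gene_id, samples))
  for (j in seq_along(samples)) {
    post <- grepl("_post$", samples[j])
    mu <- tg$expr_mean * 2^(if (post) tg$log2fc_true else 0)
    m[, j] <- if (design$dispersion == 0) mu else
      rnbinom(nrow(tg), mu = mu, size = 1 / design$dispersion)
  }
  m
}

#' Generate the per-read poly(A) table
#'
#' Log-normal tail lengths per read; genes planted as shortened have their
#' post-treatment scale multiplied by `polya_shrink`.
#'
#' @inheritParams generate_site_calls
#' @return Data frame `read_id`, `gene_id`, `sample_id`, `tail_length`.
#' @export
generate_polya <- function(design, ref) {
  set.seed(design$seed + 404L)
  tg <- ref$truth_genes
  genes <- tg$gene_id[tg$polya_label != "none"]
  rows <- list()
  for (p in seq_len(design$n_patients)) {
    for (cond in c("pre", "post")) {
      sid <- sprintf("P%d_%s", p, cond)
      for (g in genes) {
        short <- cond == "post" &&
          tg$polya_label[tg$gene_id == g] == "shortened"
        ml <- design$tail_meanlog + if (short) log(design$polya_shrink) else 0
        tl <- rlnorm(design$polya_reads, ml, design$tail_sdlog)
        rows[[paste(sid, g)]] <- data.frame(
          read_id = sprintf("%s_%s_r%03d", sid, g,
                            seq_len(design$polya_reads)),
          gene_id = g, sample_id = sid, tail_length = round(tl, 2),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a full synthetic study and write its input files
#'
#' Runs all generator stages under the design's master seed and writes
#' every pipeline input into `dir`: `reference.fa`, `annotation.gtf`, one
#' site-call TSV per sample under `sites/`, `counts.tsv`, `polya.tsv`, a
#' `samplesheet.tsv` pairing the samples, and the planted truth
#' (`truth_sites.tsv`, `truth_genes.tsv`). Output is byte-deterministic
#' for a fixed design.
#'
#' @param design A [study_design()].
#' @param dir Output directory (created if needed).
#' @return An object of class `m6a_study` with the file `paths`, the
#'   in-memory tables, the `truth`, and the `design`.
#' @export
simulate_study <- function(design, dir) {
  dir.create(file.path(dir, "sites"), recursive = TRUE, showWarnings = FALSE)
  ref <- generate_reference(design)
  calls <- generate_site_calls(design, ref)
  counts <- generate_counts(design, ref)
  polya <- generate_polya(design, ref)

  paths <- list(
    fasta = file.path(dir, "reference.fa"),
    gtf = file.path(dir, "annotation.gtf"),
    counts = file.path(dir, "counts.tsv"),
    polya = file.path(dir, "polya.tsv"),
    samplesheet = file.path(dir, "samplesheet.tsv"),
    truth_sites = file.path(dir, "truth_sites.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv"),
    sites = setNames(file.path(dir, "sites", paste0(names(calls), ".tsv")),
                     names(calls))
  )
  Biostrings::writeXStringSet(ref$sequences, paths$fasta, width = 80L)
  writeLines(ref$gtf, paths$gtf)
  for (sid in names(calls)) write_site_calls(calls[[sid]], paths$sites[[sid]])
  write_counts(counts, paths$counts)
  write_tsv(polya, paths$polya)
  write_tsv(ref$truth_sites, paths$truth_sites)
  write_tsv(ref$truth_genes, paths$truth_genes)
  # Paths in the samplesheet are relative to its own directory, so the
  # simulated tree is portable and byte-identical across output locations.
  sheet <- data.frame(
    patient_id = sprintf("P%d", seq_len(design$n_patients)),
    pre_path = sprintf("sites/P%d_pre.tsv", seq_len(design$n_patients)),
    post_path = sprintf("sites/P%d_post.tsv", seq_len(design$n_patients)),
    pre_sample = sprintf("P%d_pre", seq_len(design$n_patients)),
    post_sample = sprintf("P%d_post", seq_len(design$n_patients)),
    stringsAsFactors = FALSE)
  write_tsv(sheet, paths$samplesheet)

  structure(list(paths = paths, site_calls = calls, counts = counts,
                 polya = polya,
                 truth = list(sites = ref$truth_sites,
                              genes = ref$truth_genes),
                 reference = ref, design = design),
            class = "m6a_study")
}

#' @export
print.m6a_study <- function(x, ...) {
  print(x$design)
  cat(sprintf("  %d planted sites; files under %s\n",
              nrow(x$truth$sites), dirname(x$paths$fasta)))
  invisible(x)
}
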