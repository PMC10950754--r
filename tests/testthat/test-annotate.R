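test_that("site-gene intersection uses half-open containment", {
  gm <- span_models("g1", "chr1", 100L, 200L, "+")
  sites <- data.frame(chrom = "chr1", pos = c(150L, 200L, 99L, 100L, 199L),
                      strand = "+")
  ann <- intersect_sites_genes(sites, gm)
  expect_equal(ann$n_genes, c(1L, 0L, 0L, 1L, 1L))
  expect_equal(ann$region[2], "intergenic")
})

test_that("intersection is strand-aware by default and blind on request", {
  gm <- span_models("g1", "chr1", 100L, 200L, "+")
  sites <- data.frame(chrom = "chr1", pos = c(150L, 150L),
                      strand = c("+", "-"))
  ann <- intersect_sites_genes(sites, gm)
  expect_equal(ann$n_genes, c(1L, 0L))
  ann2 <- intersect_sites_genes(sites, gm, ignore_strand = TRUE)
  expect_equal(ann2$n_genes, c(1L, 1L))
})

test_that("intersection matches a brute-force containment oracle", {
  set.seed(61)
  n_sites <- 1000
  n_genes <- 100
  chroms <- sprintf("chr%d", 1:3)
  g_start <- sample(0:5000, n_genes, TRUE)
  genes <- data.frame(gene_id = sprintf("g%03d", seq_len(n_genes)),
                      chrom = sample(chroms, n_genes, TRUE),
                      start = g_start, end = g_start + sample(50:800, n_genes, TRUE),
                      strand = sample(c("+", "-"), n_genes, TRUE))
  gm <- span_models(genes$gene_id, genes$chrom, genes$start, genes$end,
                    genes$strand)
  sites <- data.frame(chrom = sample(chroms, n_sites, TRUE),
                      pos = sample(0:6000, n_sites, TRUE),
                      strand = sample(c("+", "-"), n_sites, TRUE))
  # force half-open boundary cases into the fixture
  sites$pos[1:20] <- genes$start[1:20]
  sites$chrom[1:20] <- genes$chrom[1:20]
  sites$strand[1:20] <- genes$strand[1:20]
  sites$pos[21:40] <- genes$end[1:20]
  sites$chrom[21:40] <- genes$chrom[1:20]
  sites$strand[21:40] <- genes$strand[1:20]

  ann <- intersect_sites_genes(sites, gm)
  hits <- attr(ann, "hits")
  got <- sort(paste(hits$key, hits$gene_id))

  # brute-force all-pairs oracle
  want <- character(0)
  for (i in seq_len(n_sites)) {
    for (j in seq_len(n_genes)) {
      if (sites$chrom[i] == genes$chrom[j] &&
          sites$strand[i] == genes$strand[j] &&
          genes$start[j] <= sites$pos[i] && sites$pos[i] < genes$end[j]) {
        want <- c(want, paste(sites$chrom[i], ":", sites$pos[i], ":",
                              sites$strand[i], " ", genes$gene_id[j],
                              sep = ""))
      }
    }
  }
  expect_equal(got, sort(want))

  # permutation invariance of the hit set
  perm <- sample(n_sites)
  ann_p <- intersect_sites_genes(sites[perm, ], gm)
  hp <- attr(ann_p, "hits")
  expect_equal(sort(paste(hp$key, hp$gene_id)), got)
})

test_that("functional regions follow the documented precedence", {
  gm <- read_gene_models(toy_gtf("+"))
  expect_equal(assign_functional_region(270L, "g1", gm), "three_prime_utr")
  expect_equal(assign_functional_region(20L, "g1", gm), "five_prime_utr")
  expect_equal(assign_functional_region(60L, "g1", gm), "cds")
  expect_equal(assign_functional_region(150L, "g1", gm), "intron")
  expect_error(assign_functional_region(150L, "nope", gm), "absent")
  expect_error(assign_functional_region(500L, "g1", gm), "outside")
})

test_that("a site exonic in any transcript is exonic before intronic", {
  at <- function(tx) sprintf(
    'gene_id "g1"; transcript_id "%s"; gene_biotype "protein_coding";', tx)
  lines <- c(
    'chr1\ttoy\tgene\t1\t400\t.\t+\t.\tgene_id "g1"; gene_biotype "protein_coding";',
    sprintf("chr1\ttoy\texon\t1\t100\t.\t+\t.\t%s", at("tA")),
    sprintf("chr1\ttoy\texon\t151\t250\t.\t+\t.\t%s", at("tA")),
    sprintf("chr1\ttoy\texon\t301\t400\t.\t+\t.\t%s", at("tA")),
    sprintf("chr1\ttoy\tCDS\t51\t350\t.\t+\t.\t%s", at("tA")),
    sprintf("chr1\ttoy\texon\t1\t100\t.\t+\t.\t%s", at("tB")),
    sprintf("chr1\ttoy\texon\t301\t400\t.\t+\t.\t%s", at("tB")),
    sprintf("chr1\ttoy\tCDS\t51\t350\t.\t+\t.\t%s", at("tB")))
  f <- tempfile(fileext = ".gtf")
  writeLines(lines, f)
  gm <- read_gene_models(f)
  # position 200 (0-based) is CDS-exonic in tA but intronic in tB
  expect_equal(assign_functional_region(200L, "g1", gm), "cds")
  # position 120 is intronic in both transcripts
  expect_equal(assign_functional_region(120L, "g1", gm), "intron")
})

test_that("region distribution recovers planted proportions and sums to one", {
  set.seed(8)
  regions <- sample(c("three_prime_utr", "cds", "five_prime_utr", "intron"),
                    5000, TRUE, prob = c(0.6, 0.2, 0.1, 0.1))
  ann <- structure(
    data.frame(chrom = "chr1", pos = seq_len(5000), strand = "+",
               key = sprintf("chr1:%d:+", seq_len(5000)),
               n_genes = 1L, gene_ids = "g1", region = regions,
               stringsAsFactors = FALSE),
    class = c("site_annotation", "data.frame"))
  rd <- region_distribution(ann)
  expect_equal(sum(rd$fraction), 1, tolerance = 1e-12)
  expect_equal(rd$fraction[rd$region == "three_prime_utr"], 0.6,
               tolerance = 0.04)
  ann$region <- "intergenic"
  expect_error(region_distribution(ann), "no annotated sites")
})

test_that("biotype fractions are exact deterministic counts", {
  gm <- span_models(sprintf("g%03d", 1:100), "chr1",
                    (0:99) * 1000L, (0:99) * 1000L + 500L, "+",
                    biotype = rep(c("protein_coding", "lncRNA", "weird_type"),
                                  c(87, 10, 3)))
  bt <- biotype_summary(gm$genes$gene_id, gm)
  expect_equal(bt$fraction[bt$biotype == "protein_coding"], 0.87)
  expect_equal(sum(bt$fraction), 1)
  # unknown biotypes are bucketed as "other" but preserved in the detail
  expect_equal(bt$count[bt$biotype == "other"], 3L)
  detail <- attr(bt, "detail")
  expect_true("weird_type" %in% detail$biotype)
  # duplicated ids collapse to unique genes
  bt2 <- biotype_summary(rep(gm$genes$gene_id[1], 5), gm)
  expect_equal(bt2$fraction, 1)
})

test_that("per-gene site profiles classify sites by per-pair significance", {
  gm <- read_gene_models(toy_gtf("+"))
  # three strongly shifted 3'UTR sites + one stable CDS site
  pos <- c(255L, 270L, 285L, 60L)
  mk <- function(p, tag, k) {
    site_calls("chr1", pos, "+", "AAACA",
               modified = as.integer(round(p * 100)), total = 100L,
               sample_id = sprintf("P%d_%s", k, tag))
  }
  wiggle <- c(0, 0.02, -0.02)
  pairs <- lapply(1:3, function(k) {
    sample_pair(sprintf("P%d", k),
                mk(c(0.8, 0.85, 0.75, 0.5), "pre", k),
                mk(c(0.3, 0.35, 0.3, 0.5) + wiggle[k], "post", k))
  })
  diff <- call_differential_sites(pairs)
  prof <- gene_site_profile("g1", diff, gm)
  expect_equal(unname(prof$class_counts["consistent"]), 3L)
  expect_equal(unname(prof$class_counts["stable"]), 1L)
  expect_equal(prof$sites$region[prof$sites$class == "consistent"],
               rep("three_prime_utr", 3))
  expect_error(gene_site_profile("missing", diff, gm), "absent")
})
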