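test_that("ratio computation follows the modified/total definition", {
  expect_equal(compute_ratio(5, 10), 0.5)
  expect_equal(compute_ratio(0, 25), 0)
  expect_equal(compute_ratio(7, 7), 1)
  expect_error(compute_ratio(1, 0), "positive")
  expect_error(compute_ratio(11, 10), "modified <= total")
})

test_that("high-level classification uses a strict threshold", {
  expect_true(is_high_m6a(0.51))
  expect_false(is_high_m6a(0.50))
  expect_false(is_high_m6a(0))
  expect_error(is_high_m6a(1.2), "\\[0, 1\\]")
})

test_that("ratio is an unbiased estimate of site stoichiometry", {
  set.seed(31)
  p_true <- 0.7
  ratios <- compute_ratio(rbinom(1000, 100, p_true), 100)
  expect_lt(abs(mean(ratios) - p_true), 0.01)
})

test_that("motif extraction is strand-aware and windows are validated", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "GGAAACAGG"))
  # plus strand: site at the middle A of AAACA (0-based position 4)
  expect_equal(extract_motif(ref, "chr1", 4L, "+"), "AAACA")
  # minus strand at the mirrored locus reads the reverse complement
  expect_equal(extract_motif(ref, "chr1", 4L, "-"), "TGTTT")
  rc <- Biostrings::DNAStringSet(c(chr1 = "CCTGTTTCC"))
  expect_equal(extract_motif(rc, "chr1", 4L, "-"), "AAACA")
  expect_error(extract_motif(ref, "chr1", 1L, "+"), "bounds")
  expect_error(extract_motif(ref, "chr1", 7L, "+"), "bounds")
  expect_error(extract_motif(ref, "chr9", 4L, "+"), "absent")
})

test_that("minus-strand extraction equals the reverse complement of plus", {
  set.seed(7)
  seq <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  ref <- Biostrings::DNAStringSet(c(chrX = seq))
  pos <- sample(2:496, 50)
  plus <- extract_motif(ref, rep("chrX", 50), pos, rep("+", 50))
  minus <- extract_motif(ref, rep("chrX", 50), pos, rep("-", 50))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(plus)))
  expect_equal(minus, unname(rc))
})

test_that("RRACH classification matches brute-force enumeration of all 1024 5-mers", {
  bases <- c("A", "C", "G", "T")
  all5 <- do.call(paste0, expand.grid(bases, bases, bases, bases, bases))
  # independent oracle: explicit set expansion of R x R x A x C x H
  oracle_set <- as.vector(outer(
    as.vector(outer(c("A", "G"), c("A", "G"), paste0)),
    paste0("AC", c("A", "C", "T")), paste0))
  expect_length(oracle_set, 12L)
  cls <- classify_rrach(all5)
  expect_equal(sum(cls$is_rrach), 12L)
  expect_setequal(cls$motif[cls$is_rrach], oracle_set)
  expect_setequal(rrach_variants(), oracle_set)
  expect_true(all(is.na(cls$variant[!cls$is_rrach])))
})

test_that("motif proportions recover planted variant frequencies", {
  tab <- site_calls("chr1", seq_len(100) * 10L, "+", rep("AAACA", 100),
                    rep(5L, 100), rep(10L, 100))
  ms <- motif_proportions(tab)
  expect_equal(ms$variants$fraction[ms$variants$variant == "AAACA"], 1)
  expect_equal(sum(ms$variants$fraction), 1)
  # center of the logo is the methylated A by construction
  expect_equal(unname(ms$logo[3, "A"]), 1)
  expect_equal(unname(rowSums(ms$logo)), rep(1, 5), tolerance = 1e-9)

  set.seed(12)
  freqs <- c(0.3, 0.2, 0.15, 0.1, 0.1, 0.05, 0.04, 0.03, 0.01, 0.01,
             0.005, 0.005)
  names(freqs) <- rrach_variants()
  motifs <- sample(names(freqs), 10000, TRUE, prob = freqs)
  tab2 <- site_calls("chr1", seq_len(10000) * 10L, "+", motifs,
                     rep(5L, 10000), rep(10L, 10000))
  ms2 <- motif_proportions(tab2)
  expect_lt(max(abs(ms2$variants$fraction[match(names(freqs),
                                                ms2$variants$variant)] -
                      freqs)), 0.02)
})

test_that("non-A-centered or ambiguous windows are excluded from motif summaries", {
  tab <- site_calls("chr1", c(10L, 20L, 30L), "+",
                    c("AAACA", "AACCA", "AANCA"),
                    c(5L, 5L, 5L), c(10L, 10L, 10L))
  expect_warning(ms <- motif_proportions(tab), "excluding 2")
  expect_equal(ms$n_sites, 1L)
  expect_error(suppressWarnings(
    motif_proportions(site_calls("chr1", 10L, "+", "AACCA", 5L, 10L))),
    "no RRACH")
})

test_that("chromosome distribution sums to one and drops empty chromosomes", {
  tab <- site_calls(rep("chr1", 3), c(1L, 2L, 3L) * 10L, "+",
                    rep("AAACA", 3), rep(5L, 3), rep(10L, 3))
  cd <- chromosome_distribution(tab)
  expect_equal(cd$fraction, 1)
  expect_equal(cd$chrom, "chr1")

  set.seed(4)
  n <- 22000
  chroms <- sample(sprintf("chr%d", 1:22), n, TRUE)
  tab2 <- site_calls(chroms, seq_len(n), "+", "AAACA", 5L, 10L)
  cd2 <- chromosome_distribution(tab2)
  expect_equal(sum(cd2$fraction), 1)
  expect_lt(max(abs(cd2$fraction - 1 / 22)), 0.01)
})

test_that("group-level comparison detects site loss and ratio shifts", {
  set.seed(9)
  n <- 1000
  p <- pmin(pmax(rbeta(n, 2, 2), 0.31), 0.95)
  mk <- function(idx, pvec, id) {
    site_calls("chr1", idx * 10L, "+", "AAACA",
               rbinom(length(idx), 100, pvec[idx]), 100L, sample_id = id)
  }
  a <- mk(seq_len(n), p, "a")
  # identical groups: null case
  null_cmp <- global_level_comparison(a, a)
  expect_equal(null_cmp$relative_site_count, 1)
  expect_gt(null_cmp$p_value, 0.05)

  # 25% downsampling of sites
  keep <- sort(sample(n, 250))
  b <- mk(keep, p, "b")
  cmp <- global_level_comparison(a, b)
  expect_equal(cmp$relative_site_count, 0.25)

  # ratios shifted down by 0.3
  b2 <- mk(seq_len(n), pmax(p - 0.3, 0), "b2")
  cmp2 <- global_level_comparison(a, b2)
  expect_lt(cmp2$p_value, 0.001)
  expect_error(global_level_comparison(a, list()), "no site tables")
})
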