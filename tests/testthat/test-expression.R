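test_that("CPM normalization scales to a million and is idempotent", {
  m <- matrix(c(1, 1, 2), ncol = 1, dimnames = list(c("a", "b", "c"), "s1"))
  cpm <- normalize_counts(m)
  expect_equal(unname(cpm[, 1]), c(250000, 250000, 500000))
  expect_equal(unname(normalize_counts(cpm)), unname(cpm),
               tolerance = 1e-9, ignore_attr = TRUE)

  m2 <- rbind(m, d = 0)
  expect_equal(unname(normalize_counts(m2)["d", ]), 0)
  m3 <- cbind(m, s2 = 0)
  expect_error(normalize_counts(m3), "zero library size")
})

test_that("DEG status follows the fold-change and p-value thresholds", {
  set.seed(21)
  n <- 50
  counts <- matrix(rnbinom(n * 6, mu = 500, size = 20), nrow = n,
                   dimnames = list(sprintf("g%02d", 1:n),
                                   c(paste0("pre", 1:3), paste0("post", 1:3))))
  # a gene identical in both groups is unchanged with logFC 0
  counts[1, ] <- 400
  # planted 4-fold down gene with low dispersion
  counts[2, 1:3] <- c(800, 820, 790)
  counts[2, 4:6] <- c(200, 205, 198)
  fit <- call_degs(counts, rep(c("pre", "post"), each = 3))
  g <- fit$genes
  expect_equal(g$status[1], "unchanged")
  expect_equal(g$log2_fc[1], 0, tolerance = 0.05)
  expect_equal(g$status[2], "down")

  # degenerate zero-variance contrast: NA p, unchanged
  expect_true(is.na(g$p_value[1]) || g$p_value[1] >= 0)
})

test_that("paired DEG test agrees with stats::t.test on the log scale", {
  set.seed(33)
  counts <- matrix(rnbinom(20 * 6, mu = 300, size = 10), nrow = 20,
                   dimnames = list(sprintf("g%02d", 1:20),
                                   sprintf("s%d", 1:6)))
  groups <- rep(c("pre", "post"), each = 3)
  fit <- call_degs(counts, groups, paired = TRUE)
  x <- log2(normalize_counts(counts) + 1)
  for (i in c(1, 7, 20)) {
    ref <- t.test(x[i, 4:6], x[i, 1:3], paired = TRUE)
    expect_equal(fit$genes$t[i], unname(ref$statistic), tolerance = 1e-9)
    expect_equal(fit$genes$p_value[i], ref$p.value, tolerance = 1e-9)
  }
  fitw <- call_degs(counts, groups, paired = FALSE)
  for (i in c(2, 11)) {
    ref <- t.test(x[i, 4:6], x[i, 1:3])
    expect_equal(fitw$genes$t[i], unname(ref$statistic), tolerance = 1e-9)
    expect_equal(fitw$genes$p_value[i], ref$p.value, tolerance = 1e-9)
  }
})

test_that("swapping group labels negates logFC and preserves p-values", {
  set.seed(41)
  counts <- matrix(rnbinom(40 * 6, mu = 400, size = 10), nrow = 40,
                   dimnames = list(sprintf("g%02d", 1:40),
                                   sprintf("s%d", 1:6)))
  a <- call_degs(counts, rep(c("pre", "post"), each = 3), reference = "pre")
  b <- call_degs(counts, rep(c("post", "pre"), each = 3), reference = "pre")
  expect_equal(b$genes$log2_fc, -a$genes$log2_fc)
  expect_equal(b$genes$p_value, a$genes$p_value)
})

test_that("group size and pairing preconditions are enforced", {
  counts <- matrix(1:12, nrow = 3,
                   dimnames = list(c("a", "b", "c"), sprintf("s%d", 1:4)))
  expect_error(call_degs(counts, c("x", "x", "x", "y")), "at least 2")
  expect_error(call_degs(counts, c("x", "y")), "one entry per sample")
  expect_error(call_degs(counts, c("x", "x", "y", "z")), "two groups")
})

test_that("gene-level m6A rollup quarantines mixed genes", {
  # gene gA: two called-down sites; gB: one up one down (mixed); gC: none
  s <- data.frame(
    chrom = "chr1", pos = c(10L, 20L, 110L, 120L, 210L),
    strand = "+",
    mean_delta = c(-0.4, -0.35, 0.4, -0.4, 0.01),
    direction = c("down", "down", "up", "down", "up"),
    called = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  diff <- structure(list(sites = s, n_pairs = 3), class = "m6a_diff")
  gm <- span_models(c("gA", "gB", "gC"), "chr1", c(0L, 100L, 200L),
                    c(100L, 200L, 300L), "+")
  ann <- intersect_sites_genes(s, gm)
  roll <- gene_level_m6a_direction(diff, ann)
  expect_equal(roll$direction[roll$gene_id == "gA"], "down")
  expect_equal(roll$direction[roll$gene_id == "gB"], "mixed")
  expect_equal(roll$direction[roll$gene_id == "gC"], "none")
  expect_equal(roll$n_sites[roll$gene_id == "gA"], 2L)
})

test_that("gene-set intersections satisfy inclusion-exclusion exactly", {
  m6a <- data.frame(gene_id = c("A", "B", "C", "D", "M"),
                    direction = c("down", "down", "down", "up", "mixed"),
                    mean_delta = c(-0.4, -0.3, -0.2, 0.3, 0),
                    stringsAsFactors = FALSE)
  degs <- data.frame(gene_id = c("B", "C", "D", "E"),
                     status = c("down", "down", "up", "down"),
                     log2_fc = c(-2, -3, 2, -4),
                     p_value = c(0.01, 0.01, 0.01, 0.01),
                     stringsAsFactors = FALSE)
  res <- intersect_gene_sets(m6a, degs)
  expect_equal(res$concordant_down$gene_id, c("B", "C"))
  expect_equal(res$mixed_genes, "M")
  v <- res$venn
  union_size <- length(union(res$sets$m6a_down, res$sets$deg_down))
  expect_equal(union_size,
               v[["m6a_down"]] + v[["deg_down"]] - v[["m6a_down_deg_down"]])
  expect_true(all(c(v[["m6a_down_deg_down"]] <= min(v[["m6a_down"]],
                                                    v[["deg_down"]]))))

  # disjoint sets give an empty concordant list
  degs2 <- degs
  degs2$status <- "up"
  res2 <- intersect_gene_sets(m6a, degs2)
  expect_equal(nrow(res2$concordant_down), 0L)
})
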