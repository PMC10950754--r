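test_that("pair deltas are post minus pre over jointly covered sites", {
  pair <- pair_from_ratios("P1", pre_ratio = c(0.8, 0.5),
                           post_ratio = c(0.3, 0.5))
  d <- build_pair_deltas(pair)
  expect_equal(d$delta, c(-0.5, 0))

  # a site absent in post yields no delta
  pre <- site_calls("chr1", c(10L, 20L), "+", "AAACA", c(8L, 5L),
                    c(10L, 10L), sample_id = "pre")
  post <- site_calls("chr1", 10L, "+", "AAACA", 3L, 10L, sample_id = "post")
  d2 <- build_pair_deltas(sample_pair("P1", pre, post))
  expect_equal(nrow(d2), 1L)
  expect_equal(attr(d2, "n_skipped"), 1L)

  # under-covered sites are filtered out
  post2 <- site_calls("chr1", c(10L, 20L), "+", "AAACA", c(3L, 1L),
                      c(10L, 5L), sample_id = "post2")
  d3 <- build_pair_deltas(sample_pair("P1", pre, post2), min_coverage = 10)
  expect_equal(nrow(d3), 1L)
})

test_that("paired t-test matches the df=2 closed form and stats::t.test", {
  d <- c(-0.30, -0.25, -0.35)
  res <- paired_t_test(d)
  expect_equal(res$statistic, -10.392305, tolerance = 1e-6)
  expect_equal(res$p_value, oracle_p_df2(res$statistic), tolerance = 1e-9)

  # generic-oracle agreement for n up to 10
  set.seed(2)
  for (n in 2:10) {
    x <- rnorm(n, sd = 0.1)
    mine <- paired_t_test(x)
    ref <- t.test(x)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  }

  # symmetric deltas give t = 0, p = 1
  sym <- paired_t_test(c(-0.1, 0, 0.1))
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p_value, 1)

  # zero variance is degenerate, not significant
  deg <- paired_t_test(c(-0.2, -0.2, -0.2))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p_value))
  expect_error(paired_t_test(0.1), "at least 2")
})

test_that("sites are called only with p < alpha and all-pairs sign consistency", {
  mk3 <- function(deltas) {
    lapply(1:3, function(k) {
      pair_from_ratios(sprintf("P%d", k), pre_ratio = c(0.6, 0.6),
                       post_ratio = c(0.6 + deltas[k], 0.6))
    })
  }
  res <- call_differential_sites(mk3(c(-0.30, -0.25, -0.35)))
  s1 <- res$sites[res$sites$pos == 10L, ]
  expect_true(s1$called)
  expect_equal(s1$direction, "down")
  expect_equal(s1$p_value, oracle_p_df2(-10.392305), tolerance = 1e-6)
  # the constant site is degenerate (all three deltas zero) and excluded
  expect_equal(res$n_degenerate, 1L)

  # sign inconsistency: never called
  res2 <- call_differential_sites(mk3(c(-0.30, -0.25, 0.05)))
  s2 <- res2$sites[res2$sites$pos == 10L, ]
  expect_false(s2$called)
  expect_false(s2$consistent)

  expect_error(call_differential_sites(mk3(c(0, 0, 0))[1]), "at least 2")
})

test_that("with three pairs, mixed-sign deltas can never reach |t| = 2.92", {
  # supremum of |t| over mixed-sign triples is 2 (limit of (-a,-a,0)),
  # below the two-sided p<0.1 critical value qt(0.95, 2) = 2.92; hence at
  # alpha = 0.1 the consistency filter is implied by the p-gate for n = 3.
  set.seed(55)
  for (i in 1:500) {
    x <- rnorm(3)
    if (length(unique(sign(x))) > 1) {
      expect_lt(abs(mean(x)) / (sd(x) / sqrt(3)), 2)
    }
  }
})

test_that("the consistency filter binds with four or more pairs", {
  mk4 <- function(deltas) {
    lapply(seq_along(deltas), function(k) {
      pair_from_ratios(sprintf("P%d", k), pre_ratio = c(0.6, 0.3),
                       post_ratio = c(0.6 + deltas[k], 0.35))
    })
  }
  # p < 0.1 at df = 3 but one pair moves the other way: rejected
  res <- call_differential_sites(mk4(c(-0.5, -0.5, -0.5, 0.01)))
  s <- res$sites[res$sites$pos == 10L, ]
  expect_lt(s$p_value, 0.1)
  expect_false(s$consistent)
  expect_false(s$called)
})

test_that("swapping pre and post flips every delta and exchanges calls", {
  set.seed(77)
  p_pre <- runif(200, 0.3, 0.9)
  p_post <- pmin(pmax(p_pre + sample(c(-0.4, 0, 0.4), 200, TRUE), 0), 1)
  pairs <- pairs_from_truth(p_pre, p_post)
  swapped <- lapply(pairs, function(pr) {
    sample_pair(pr$patient_id, pr$post, pr$pre)
  })
  a <- call_differential_sites(pairs)
  b <- call_differential_sites(swapped)
  expect_equal(b$sites$mean_delta, -a$sites$mean_delta)
  expect_equal(b$sites$p_value, a$sites$p_value)
  up_a <- a$sites$pos[a$sites$called & a$sites$direction == "up"]
  down_b <- b$sites$pos[b$sites$called & b$sites$direction == "down"]
  expect_setequal(up_a, down_b)
})

test_that("direction summaries report proportions that sum to one", {
  set.seed(3)
  p_pre <- runif(120, 0.45, 0.9)
  eff <- rep(c(-0.4, 0.4, 0), c(100, 20, 0))
  pairs <- pairs_from_truth(p_pre, pmin(pmax(p_pre + eff, 0), 1))
  res <- call_differential_sites(pairs)
  ds <- summarize_direction(res)
  expect_false(ds$empty)
  expect_equal(sum(ds$sites$proportion), 1)
  # planted 100 down / 20 up recovered within binomial error
  expect_equal(ds$sites$proportion[ds$sites$direction == "down"],
               100 / 120, tolerance = 0.1)

  null_res <- call_differential_sites(
    pairs_from_truth(rep(0.5, 3), rep(0.5, 3)), alpha = 1e-9)
  dn <- summarize_direction(null_res)
  expect_true(dn$empty)
  expect_equal(dn$sites$count, c(0L, 0L))
})
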