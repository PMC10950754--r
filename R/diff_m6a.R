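# The paired differential m6A caller: per-pair ratio deltas, a merged
# paired t-test across patients, a raw-P gate, and the all-pairs
# direction-consistency intersection.

#' Bundle one patient's pre/post site tables
#'
#' @param patient_id Patient identifier.
#' @param pre,post `site_calls` tables for the pre-treatment (e.g. AML) and
#'   post-treatment (e.g. complete remission) samples.
#' @return A list of class `sample_pair`.
#' @export
sample_pair <- function(patient_id, pre, post) {
  if (identical(attr(pre, "sample_id"), attr(post, "sample_id"))) {
    stop_msg("pre and post tables of pair '%s' have the same sample_id",
             patient_id)
  }
  structure(list(patient_id = patient_id, pre = pre, post = post),
            class = "sample_pair")
}

#' Per-pair m6A ratio differences
#'
#' For one patient pair, computes `delta = post_ratio - pre_ratio` at every
#' site that passes the coverage filter in *both* members of the pair; a
#' positive delta indicates up-regulation of m6A after treatment. Sites
#' absent (or under-covered) in either member are skipped and counted.
#'
#' @param pair A [sample_pair()].
#' @param min_coverage Minimum total read count required in each member.
#' @return Data frame `chrom`, `pos`, `strand`, `patient_id`, `pre_ratio`,
#'   `post_ratio`, `delta`, with the number of skipped sites in
#'   `attr(, "n_skipped")`.
#' @export
build_pair_deltas <- function(pair, min_coverage = 10) {
  pre <- pair$pre[pair$pre$total >= min_coverage, , drop = FALSE]
  post <- pair$post[pair$post$total >= min_coverage, , drop = FALSE]
  kp <- site_key(pre$chrom, pre$pos, pre$strand)
  kq <- site_key(post$chrom, post$pos, post$strand)
  common <- intersect(kp, kq)
  n_skipped <- (length(kp) - length(common)) + (length(kq) - length(common))
  i <- match(common, kp)
  j <- match(common, kq)
  out <- data.frame(
    chrom = pre$chrom[i], pos = pre$pos[i], strand = pre$strand[i],
    patient_id = rep(pair$patient_id, length(common)),
    pre_ratio = pre$ratio[i], post_ratio = post$ratio[j],
    delta = post$ratio[j] - pre$ratio[i],
    stringsAsFactors = FALSE
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

#' One-sample paired t-test on ratio deltas
#'
#' Tests the mean of the per-pair deltas against zero:
#' `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees of freedom.
#' With all deltas identical the statistic is undefined; such sites are
#' flagged degenerate rather than given an artificial p-value.
#'
#' @param deltas Numeric vector of per-pair deltas (length >= 2).
#' @param two_sided Two-sided p-value (default) or one-sided in the
#'   direction of the observed mean.
#' @return List with `statistic`, `df`, `p_value`, `mean_delta`,
#'   `degenerate`.
#' @export
paired_t_test <- function(deltas, two_sided = TRUE) {
  if (length(deltas) < 2L) stop_msg("need at least 2 deltas")
  s <- sd(deltas)
  m <- mean(deltas)
  if (s == 0) {
    return(list(statistic = NA_real_, df = length(deltas) - 1L,
                p_value = NA_real_, mean_delta = m, degenerate = TRUE))
  }
  t <- m / (s / sqrt(length(deltas)))
  df <- length(deltas) - 1L
  p <- pt(-abs(t), df) * if (two_sided) 2 else 1
  list(statistic = t, df = df, p_value = p, mean_delta = m,
       degenerate = FALSE)
}

#' Call differential m6A sites across patient pairs
#'
#' The merged paired analysis: sites covered (at `min_coverage`) in every
#' sample of every pair enter a one-sample t-test of their per-pair deltas
#' against zero. A site is called *up* when `p < alpha` and its delta is
#' strictly positive in every pair, and *down* when `p < alpha` and its
#' delta is strictly negative in every pair (the all-pairs
#' direction-consistency filter). All tested sites are reported. Sites with
#' identical deltas in every pair have an undefined t statistic and are
#' excluded as degenerate, with a count kept.
#'
#' A Benjamini-Hochberg adjusted p-value column is reported for
#' transparency but plays no role in calling, which uses the raw p-value
#' gate.
#'
#' @param pairs List of [sample_pair()] objects (>= 2).
#' @param alpha Raw p-value threshold for calling (default 0.1).
#' @param min_coverage Per-sample coverage floor (default 10).
#' @param two_sided Sidedness of the t-test (default two-sided).
#' @return An object of class `m6a_diff`; its `sites` component is a data
#'   frame with one row per tested site: the site key columns, one
#'   `delta_<patient>` column per pair, `mean_delta`, `t`, `p_value`,
#'   `p_adj`, `direction` (`"up"`/`"down"` by sign of the mean delta),
#'   `consistent` (same strict sign in every pair) and `called`.
#' @seealso [summarize_direction()], [gene_level_m6a_direction()]
#' @export
call_differential_sites <- function(pairs, alpha = 0.1, min_coverage = 10,
                                    two_sided = TRUE) {
  if (length(pairs) < 2L) stop_msg("need at least 2 sample pairs")
  deltas <- lapply(pairs, build_pair_deltas, min_coverage = min_coverage)
  patient_ids <- vapply(pairs, `[[`, "", "patient_id")
  keys <- lapply(deltas, function(d) site_key(d$chrom, d$pos, d$strand))
  common <- Reduce(intersect, keys)
  n_pairs <- length(pairs)

  first <- deltas[[1]][match(common, keys[[1]]), c("chrom", "pos", "strand")]
  D <- vapply(seq_len(n_pairs),
              function(k) deltas[[k]]$delta[match(common, keys[[k]])],
              numeric(length(common)))
  D <- matrix(D, nrow = length(common), ncol = n_pairs)
  colnames(D) <- paste0("delta_", patient_ids)

  m <- rowMeans(D)
  s <- apply(D, 1, sd)
  degenerate <- s == 0
  t <- ifelse(degenerate, NA_real_, m / (s / sqrt(n_pairs)))
  p <- pt(-abs(t), n_pairs - 1L) * if (two_sided) 2 else 1
  all_up <- rowSums(D > 0) == n_pairs
  all_down <- rowSums(D < 0) == n_pairs
  direction <- ifelse(m > 0, "up", ifelse(m < 0, "down", "none"))
  called <- !degenerate & !is.na(p) & p < alpha &
    ((direction == "up" & all_up) | (direction == "down" & all_down))

  sites <- data.frame(first, D, mean_delta = m, t = t, p_value = p,
                      p_adj = p.adjust(p, method = "BH"),
                      direction = direction,
                      consistent = all_up | all_down,
                      called = called,
                      stringsAsFactors = FALSE)
  sites <- sites[!degenerate, , drop = FALSE]
  rownames(sites) <- NULL

  # Per-pair read counts kept for per-gene site profiles.
  counts <- lapply(seq_len(n_pairs), function(k) {
    pr <- pairs[[k]]$pre
    po <- pairs[[k]]$post
    kp <- site_key(pr$chrom, pr$pos, pr$strand)
    kq <- site_key(po$chrom, po$pos, po$strand)
    keep <- site_key(sites$chrom, sites$pos, sites$strand)
    i <- match(keep, kp)
    j <- match(keep, kq)
    cbind(pre_mod = pr$modified[i], pre_tot = pr$total[i],
          post_mod = po$modified[j], post_tot = po$total[j])
  })
  names(counts) <- patient_ids

  structure(list(
    sites = sites, patient_ids = patient_ids, alpha = alpha,
    min_coverage = min_coverage, two_sided = two_sided,
    n_pairs = n_pairs, n_degenerate = sum(degenerate),
    pair_counts = counts
  ), class = "m6a_diff")
}

#' @export
print.m6a_diff <- function(x, ...) {
  s <- x$sites
  cat(sprintf("paired differential m6A analysis: %d pairs, %d tested sites\n",
              x$n_pairs, nrow(s)))
  cat(sprintf("  called at p < %g with all-pairs consistency: %d up, %d down",
              x$alpha, sum(s$called & s$direction == "up"),
              sum(s$called & s$direction == "down")))
  if (x$n_degenerate) {
    cat(sprintf(" (%d degenerate site(s) excluded)", x$n_degenerate))
  }
  cat("\n")
  invisible(x)
}

#' @export
summary.m6a_diff <- function(object, ...) {
  s <- object$sites
  out <- list(
    n_pairs = object$n_pairs,
    n_tested = nrow(s),
    n_called = sum(s$called),
    n_up = sum(s$called & s$direction == "up"),
    n_down = sum(s$called & s$direction == "down"),
    n_degenerate = object$n_degenerate,
    alpha = object$alpha,
    mean_delta_called = if (any(s$called)) mean(s$mean_delta[s$called]) else NA_real_
  )
  class(out) <- "summary.m6a_diff"
  out
}

#' @export
print.summary.m6a_diff <- function(x, ...) {
  cat(sprintf(
    "%d sites tested across %d pairs; %d called (up %d / down %d) at p < %g\n",
    x$n_tested, x$n_pairs, x$n_called, x$n_up, x$n_down, x$alpha))
  if (x$n_degenerate) cat(sprintf("%d degenerate site(s) excluded\n",
                                  x$n_degenerate))
  if (!is.na(x$mean_delta_called)) {
    cat(sprintf("mean delta among called sites: %.3f\n", x$mean_delta_called))
  }
  invisible(x)
}

#' Volcano-style plot of a differential m6A analysis
#'
#' @param x An `m6a_diff` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.m6a_diff <- function(x, ...) {
  s <- x$sites
  col <- ifelse(!s$called, "grey60",
                ifelse(s$direction == "up", "firebrick", "steelblue"))
  plot(s$mean_delta, -log10(s$p_value), col = col, pch = 16, cex = 0.5,
       xlab = "mean m6A ratio delta (post - pre)",
       ylab = expression(-log[10]~p), ...)
  abline(h = -log10(x$alpha), lty = 2)
  legend("topleft", legend = c("up", "down", "not called"),
         col = c("firebrick", "steelblue", "grey60"), pch = 16, bty = "n")
  invisible(x)
}

#' Up/down composition of called differential sites (and genes)
#'
#' @param results An `m6a_diff` object.
#' @param annotations Optional `site_annotation` object (see
#'   [intersect_sites_genes()]); when given, gene-level up/down proportions
#'   (via [gene_level_m6a_direction()]) are included.
#' @return List of class `m6a_direction_summary` with `sites` (and
#'   optionally `genes`) data frames of counts and proportions, plus an
#'   `empty` flag when nothing was called.
#' @export
summarize_direction <- function(results, annotations = NULL) {
  s <- results$sites
  called <- s[s$called, , drop = FALSE]
  empty <- nrow(called) == 0L
  tab <- function(dirs) {
    n <- c(up = sum(dirs == "up"), down = sum(dirs == "down"))
    data.frame(direction = names(n), count = as.integer(n),
               proportion = if (sum(n)) as.integer(n) / sum(n) else c(0, 0),
               stringsAsFactors = FALSE)
  }
  out <- list(sites = tab(called$direction), empty = empty)
  if (!is.null(annotations)) {
    gl <- gene_level_m6a_direction(results, annotations)
    out$genes <- tab(gl$direction[gl$direction %in% c("up", "down")])
  }
  structure(out, class = "m6a_direction_summary")
}

#' @export
print.m6a_direction_summary <- function(x, ...) {
  if (x$empty) {
    cat("no sites called\n")
    return(invisible(x))
  }
  cat("called sites by direction:\n")
  print.data.frame(x$sites, row.names = FALSE)
  if (!is.null(x$genes)) {
    cat("genes by direction:\n")
    print.data.frame(x$genes, row.names = FALSE)
  }
  invisible(x)
}
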