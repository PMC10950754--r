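# Internal helpers shared across modules.

# Site identity used for joins throughout: one genomic base on one strand.
site_key <- function(chrom, pos, strand) {
  paste(chrom, pos, strand, sep = ":")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Interval arithmetic on parallel start/end vectors, 0-based half-open.
# Tiny by design: per-transcript feature sets hold a handful of intervals.

# Gaps between sorted disjoint intervals (the introns of an exon chain).
interval_gaps <- function(start, end) {
  if (length(start) < 2L) {
    return(list(start = integer(0), end = integer(0)))
  }
  o <- order(start)
  start <- start[o]
  end <- end[o]
  list(start = end[-length(end)], end = start[-1L])
}

# Set difference a \ b for interval lists; both assumed sorted, disjoint.
interval_subtract <- function(a_start, a_end, b_start, b_end) {
  out_s <- integer(0)
  out_e <- integer(0)
  for (i in seq_along(a_start)) {
    segs <- list(c(a_start[i], a_end[i]))
    for (j in seq_along(b_start)) {
      nxt <- list()
      for (seg in segs) {
        s <- seg[1]
        e <- seg[2]
        bs <- b_start[j]
        be <- b_end[j]
        if (be <= s || bs >= e) {
          nxt[[length(nxt) + 1L]] <- c(s, e)
        } else {
          if (bs > s) nxt[[length(nxt) + 1L]] <- c(s, bs)
          if (be < e) nxt[[length(nxt) + 1L]] <- c(be, e)
        }
      }
      segs <- nxt
    }
    for (seg in segs) {
      out_s <- c(out_s, seg[1])
      out_e <- c(out_e, seg[2])
    }
  }
  list(start = out_s, end = out_e)
}

# Containment of single positions in half-open intervals: start <= pos < end.
pos_in_intervals <- function(pos, start, end) {
  any(start <= pos & pos < end)
}

stop_msg <- function(...) stop(sprintf(...), call. = FALSE)

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Deterministic TSV writer used for every result table.
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE, ...)
}
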