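# Gene models from GTF/GFF3: spans, per-transcript features, derived
# introns and (where absent) UTRs inferred from CDS boundaries.

#' Read gene models from a GTF/GFF3 annotation
#'
#' Parses an annotation with `gene`, `transcript`, `exon`, `CDS` and
#' (optionally) UTR features into the package's gene-model representation,
#' with all intervals converted to 0-based half-open coordinates. Introns
#' are derived as the gaps between consecutive exons of each transcript.
#' When a transcript carries no explicit UTR features but has a CDS, the
#' exonic sequence outside the CDS span is split into 5' and 3' UTR by
#' strand; explicit and inferred UTRs are never mixed within a transcript.
#'
#' @param path Path to a GTF or GFF3 file. Every feature must carry a
#'   `gene_id` attribute; gene biotypes are taken from `gene_biotype` (GTF)
#'   or `biotype` (GFF3) and default to `"unknown"`.
#' @return An object of class `gene_models`: a list with
#'   \describe{
#'     \item{genes}{data frame: `gene_id`, `gene_name`, `biotype`, `chrom`,
#'       `strand`, `start`, `end` (0-based half-open span).}
#'     \item{features}{data frame: `gene_id`, `transcript_id`, `type`
#'       (one of `exon`, `cds`, `five_prime_utr`, `three_prime_utr`,
#'       `intron`), `chrom`, `strand`, `start`, `end`.}
#'   }
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  mc <- S4Vectors::mcols(gr)
  if (!"gene_id" %in% names(mc) || anyNA(mc$gene_id)) {
    stop_msg("annotation '%s': every feature needs a gene_id attribute", path)
  }
  type <- tolower(as.character(mc$type))
  type[type %in% c("five_prime_utr", "5utr", "five_prime_UTR")] <- "five_prime_utr"
  type[type %in% c("three_prime_utr", "3utr")] <- "three_prime_utr"
  biotype <- as.character(mc$gene_biotype %||% mc$biotype %||%
                            rep(NA_character_, length(gr)))
  biotype[is.na(biotype)] <- "unknown"
  gene_name <- as.character(mc$gene_name %||% mc$Name %||% mc$gene_id)
  gene_name[is.na(gene_name)] <- as.character(mc$gene_id)[is.na(gene_name)]

  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    # GTF/GFF are 1-based closed; internal convention is 0-based half-open.
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = type,
    gene_id = as.character(mc$gene_id),
    transcript_id = as.character(mc$transcript_id %||%
                                   rep(NA_character_, length(gr))),
    biotype = biotype,
    gene_name = gene_name,
    stringsAsFactors = FALSE
  )

  gdf <- df[df$type == "gene", , drop = FALSE]
  if (!nrow(gdf)) {
    # No explicit gene features: synthesize spans from the other records.
    spl <- split(df, df$gene_id)
    gdf <- do.call(rbind, lapply(spl, function(d) {
      data.frame(chrom = d$chrom[1], start = min(d$start), end = max(d$end),
                 strand = d$strand[1], type = "gene", gene_id = d$gene_id[1],
                 transcript_id = NA_character_, biotype = d$biotype[1],
                 gene_name = d$gene_name[1], stringsAsFactors = FALSE)
    }))
  }
  genes <- data.frame(
    gene_id = gdf$gene_id, gene_name = gdf$gene_name, biotype = gdf$biotype,
    chrom = gdf$chrom, strand = gdf$strand,
    start = gdf$start, end = gdf$end, stringsAsFactors = FALSE
  )
  if (anyDuplicated(genes$gene_id)) {
    stop_msg("annotation '%s': duplicated gene feature for gene '%s'", path,
             genes$gene_id[duplicated(genes$gene_id)][1])
  }

  fdf <- df[df$type %in% c("exon", "cds", "five_prime_utr", "three_prime_utr") &
              !is.na(df$transcript_id), , drop = FALSE]
  feats <- lapply(split(fdf, fdf$transcript_id), derive_transcript_features)
  features <- if (length(feats)) do.call(rbind, feats) else
    data.frame(gene_id = character(0), transcript_id = character(0),
               type = character(0), chrom = character(0),
               strand = character(0), start = integer(0), end = integer(0))
  rownames(features) <- NULL
  structure(list(genes = genes, features = features), class = "gene_models")
}

# One transcript's exon/CDS/UTR records -> full feature set incl. derived
# introns and, when explicit UTRs are absent, UTRs inferred from the CDS.
derive_transcript_features <- function(d) {
  if (length(unique(d$strand)) > 1L) {
    stop_msg("transcript '%s' has exons on mixed strands", d$transcript_id[1])
  }
  strand <- d$strand[1]
  base <- function(type, start, end) {
    if (!length(start)) return(NULL)
    data.frame(gene_id = d$gene_id[1], transcript_id = d$transcript_id[1],
               type = type, chrom = d$chrom[1], strand = strand,
               start = as.integer(start), end = as.integer(end),
               stringsAsFactors = FALSE)
  }
  ex <- d[d$type == "exon", , drop = FALSE]
  ex <- ex[order(ex$start), , drop = FALSE]
  cds <- d[d$type == "cds", , drop = FALSE]
  utr5 <- d[d$type == "five_prime_utr", , drop = FALSE]
  utr3 <- d[d$type == "three_prime_utr", , drop = FALSE]

  out <- list(base("exon", ex$start, ex$end), base("cds", cds$start, cds$end))
  gaps <- interval_gaps(ex$start, ex$end)
  out <- c(out, list(base("intron", gaps$start, gaps$end)))

  if (nrow(utr5) || nrow(utr3)) {
    out <- c(out, list(base("five_prime_utr", utr5$start, utr5$end),
                       base("three_prime_utr", utr3$start, utr3$end)))
  } else if (nrow(cds) && nrow(ex)) {
    cs <- min(cds$start)
    ce <- max(cds$end)
    nonc <- interval_subtract(ex$start, ex$end, cs, ce)
    left <- nonc$end <= cs
    lab_left <- if (strand == "+") "five_prime_utr" else "three_prime_utr"
    lab_right <- if (strand == "+") "three_prime_utr" else "five_prime_utr"
    out <- c(out, list(base(lab_left, nonc$start[left], nonc$end[left]),
                       base(lab_right, nonc$start[!left], nonc$end[!left])))
  }
  do.call(rbind, Filter(Negate(is.null), out))
}

#' @export
print.gene_models <- function(x, ...) {
  bt <- sort(table(x$genes$biotype), decreasing = TRUE)
  cat(sprintf("gene models: %d genes, %d transcript features on %d sequence(s)\n",
              nrow(x$genes), nrow(x$features), length(unique(x$genes$chrom))))
  cat("  biotypes:", paste(sprintf("%s (%d)", names(bt), bt), collapse = ", "),
      "\n")
  invisible(x)
}
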