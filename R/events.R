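#' Discover alternative internal exons
#'
#' An alternative exon is an internal exon that is entirely included in
#' some reads and entirely excluded (spanned by a single intron) in
#' others. Candidates are the union of (a) annotated internal exons from
#' the gene models and (b) observed exons — maximal aligned segments
#' between two junctions in a read's intron chain (cryptic exons). A
#' candidate is reported when it is bounded by splice junctions on both
#' sides in at least one read (at least `minObservedReads` reads for
#' unannotated candidates, to suppress artifacts) and is spanned by a
#' single intron in at least one other read of the same gene. Exons are
#' deduplicated by coordinates; when an observed exon coincides with an
#' annotated one, the annotated source wins.
#'
#' @param x A [ReadTable] (after [dedupUmis()] and [filterRareChains()]).
#' @param geneModels A [GeneModels] object.
#' @param minObservedReads Minimum number of distinct reads that must
#'   contain an unannotated exon in flanked form (default 2).
#' @return A `GRanges` of alternative exons with metadata columns
#'   `gene_id` and `source` (`"annotated"` or `"observed"`).
#' @export
discoverAlternativeExons <- function(x, geneModels, minObservedReads = 2L) {
  df <- readData(x)
  empty <- GenomicRanges::GRanges()
  if (nrow(df) == 0) return(empty)
  introns <- parseIntronChains(df$intron_chain)
  if (nrow(introns) == 0) return(empty)
  introns$gene_id <- df$gene_id[introns$row]

  gene_id <- row <- start <- end <- seg_start <- seg_end <- n_reads <- NULL
  # Observed segments: exonic stretches between consecutive introns of a chain.
  segs <- introns[, if (.N >= 2)
                      .(seg_start = end[-.N] + 1L,
                        seg_end = start[-1] - 1L, gene_id = gene_id[1]),
                  by = row]
  ann <- internalExons(geneModels)
  ann_dt <- if (length(ann) == 0) {
    data.table::data.table(gene_id = character(), chrom = character(),
                           start = integer(), end = integer(),
                           strand = character())
  } else {
    data.table::data.table(gene_id = S4Vectors::mcols(ann)$gene_id,
      chrom = as.character(GenomeInfoDb::seqnames(ann)),
      start = GenomicRanges::start(ann), end = GenomicRanges::end(ann),
      strand = as.character(GenomicRanges::strand(ann)))
  }

  seg_support <- if (nrow(segs)) {
    segs[, .(n_reads = .N), by = .(gene_id, seg_start, seg_end)]
  } else {
    data.table::data.table(gene_id = character(), seg_start = integer(),
                           seg_end = integer(), n_reads = integer())
  }

  # Candidate exons: annotated internal exons plus observed segments.
  cand <- unique(rbind(
    ann_dt[, .(gene_id, start, end, source = "annotated")],
    seg_support[, .(gene_id, start = seg_start, end = seg_end,
                    source = "observed")]))
  cand <- cand[!(duplicated(cand[, c("gene_id", "start", "end")]))]

  gene_meta <- data.table::data.table(
    gene_id = unique(df$gene_id),
    chrom = df$chrom[match(unique(df$gene_id), df$gene_id)],
    strand = df$strand[match(unique(df$gene_id), df$gene_id)])

  # Inclusion support per candidate (flanked form seen in reads).
  cand <- merge(cand,
    seg_support[, .(gene_id, start = seg_start, end = seg_end, n_reads)],
    by = c("gene_id", "start", "end"), all.x = TRUE)
  cand$n_reads[is.na(cand$n_reads)] <- 0L
  min_support <- ifelse(cand$source == "annotated", 1L,
                        as.integer(minObservedReads))
  cand <- cand[cand$n_reads >= min_support]
  if (nrow(cand) == 0) return(empty)

  # Exclusion support: any intron of the same gene covering the candidate.
  i_start <- i_end <- NULL
  data.table::setnames(introns, c("start", "end"), c("i_start", "i_end"))
  excl <- merge(cand[, c("gene_id", "start", "end")],
                introns[, .(gene_id, i_start, i_end)],
                by = "gene_id", allow.cartesian = TRUE)
  excl <- excl[i_start <= start & i_end >= end]
  excl_key <- unique(excl[, c("gene_id", "start", "end")])
  cand <- merge(cand, cbind(excl_key, skipped = TRUE),
                by = c("gene_id", "start", "end"), all.x = TRUE)
  cand <- cand[!is.na(cand$skipped)]
  if (nrow(cand) == 0) return(empty)

  cand <- merge(cand, gene_meta, by = "gene_id")
  data.table::setorder(cand, gene_id, start, end)
  out <- GenomicRanges::GRanges(cand$chrom,
           IRanges::IRanges(cand$start, cand$end), strand = cand$strand)
  S4Vectors::mcols(out)$gene_id <- cand$gene_id
  S4Vectors::mcols(out)$source <- cand$source
  out
}

#' Classify reads against one alternative exon
#'
#' Classifies each read of the exon's gene as an inclusion event, an
#' exclusion event, uninformative, or non-overlapping:
#' \itemize{
#'   \item \strong{inclusion}: the read covers the entire exon and its
#'     chain contains junctions matching both exon boundaries; or the read
#'     starts (or ends) strictly inside the exon and its chain contains a
#'     junction matching the one exon boundary internal to the read
#'     (truncated reads vote only when the adjacent junction supports the
#'     covered splice site).
#'   \item \strong{exclusion}: the read has aligned bases on both sides of
#'     the exon and exactly one junction overlaps the flanked interval,
#'     with that junction's intron covering
#'     `[start - flank, end + flank]`. A read skipping the exon via two
#'     stacked junctions within the flank is uninformative.
#'   \item \strong{non_overlapping}: the read's span does not intersect
#'     the exon interval.
#'   \item \strong{uninformative}: anything else overlapping the exon.
#' }
#'
#' @param x A [ReadTable] or `data.frame` of reads.
#' @param exon A length-1 `GRanges` (with `gene_id` metadata) or a list
#'   with `gene_id`, `start`, `end`.
#' @param flank Required intronic flank for exclusion events, in bases
#'   (default 50).
#' @return A character vector, one label per read of the exon's gene (in
#'   input order); reads of other genes raise an error.
#' @export
classifyReads <- function(x, exon, flank = 50L) {
  df <- if (is(x, "ReadTable")) readData(x) else as.data.frame(x)
  ex <- normalizeExon(exon)
  if (!all(df$gene_id == ex$gene_id))
    stop("classifyReads: reads from gene(s) other than ", ex$gene_id)
  classifyChains(df$read_start, df$read_end, df$intron_chain,
                 ex$start, ex$end, flank)
}

normalizeExon <- function(exon) {
  if (is(exon, "GRanges")) {
    stopifnot(length(exon) == 1)
    list(gene_id = S4Vectors::mcols(exon)$gene_id,
         start = GenomicRanges::start(exon),
         end = GenomicRanges::end(exon))
  } else {
    stopifnot(all(c("gene_id", "start", "end") %in% names(exon)))
    exon[c("gene_id", "start", "end")]
  }
}

# Vectorized classification core over parallel read vectors.
classifyChains <- function(read_start, read_end, chains, s, e, flank) {
  n <- length(read_start)
  introns <- parseIntronChains(chains)
  has_left <- has_right <- ov_exon <- logical(n)
  n_ov_flank <- integer(n)
  covers_flank <- logical(n)
  if (nrow(introns)) {
    row <- start <- end <- NULL
    agg <- introns[, .(
      has_left = any(end == s - 1L),
      has_right = any(start == e + 1L),
      ov_exon = any(start <= e & end >= s),
      n_ov_flank = sum(start <= e + flank & end >= s - flank),
      covers_flank = any(start <= s - flank & end >= e + flank)), by = row]
    has_left[agg$row] <- agg$has_left
    has_right[agg$row] <- agg$has_right
    ov_exon[agg$row] <- agg$ov_exon
    n_ov_flank[agg$row] <- agg$n_ov_flank
    covers_flank[agg$row] <- agg$covers_flank
  }
  non_ov <- read_end < s | read_start > e
  starts_in <- read_start > s & read_start <= e
  ends_in <- read_end >= s & read_end < e
  incl_full <- read_start <= s & read_end >= e & has_left & has_right & !ov_exon
  incl_trunc <- (starts_in & !ends_in & has_right & !ov_exon) |
                (ends_in & !starts_in & has_left & !ov_exon)
  excl <- read_start < s & read_end > e &
          n_ov_flank == 1L & covers_flank
  out <- rep("uninformative", n)
  out[non_ov] <- "non_overlapping"
  out[incl_full | incl_trunc] <- "inclusion"
  out[excl] <- "exclusion"
  out
}

#' Count inclusion / exclusion / total events per group
#'
#' Tallies, for each alternative exon and each requested grouping of the
#' reads, the number of inclusion events, exclusion events, and the total
#' number of reads overlapping the exon location (inclusion, exclusion,
#' or uninformative; non-overlapping reads are not counted). Groups
#' observed anywhere in the read table are reported for every exon, with
#' zero counts where no read of the exon's gene falls in the group.
#'
#' @param x A [ReadTable].
#' @param exons `GRanges` of alternative exons (from
#'   [discoverAlternativeExons()]) with a `gene_id` metadata column.
#' @param groupBy Character vector of grouping columns, default
#'   `c("cell_type", "condition")`; add `"sample_id"` for per-sample
#'   counts or use `"subtype"` to stratify by annotated subtypes.
#' @param flank Flank passed to the classification rule (default 50).
#' @return A `data.frame` with columns `gene_id`, `chrom`, `exon_start`,
#'   `exon_end`, `strand`, `source`, the grouping columns, and
#'   `inclusion`, `exclusion`, `total`.
#' @export
countEvents <- function(x, exons, groupBy = c("cell_type", "condition"),
                        flank = 50L) {
  df <- readData(x)
  stopifnot(length(exons) > 0, all(groupBy %in% colnames(df)))
  ex_dt <- data.table::data.table(
    gene_id = S4Vectors::mcols(exons)$gene_id,
    chrom = as.character(GenomeInfoDb::seqnames(exons)),
    exon_start = GenomicRanges::start(exons),
    exon_end = GenomicRanges::end(exons),
    strand = as.character(GenomicRanges::strand(exons)),
    source = if (!is.null(S4Vectors::mcols(exons)$source))
               S4Vectors::mcols(exons)$source else "annotated")
  groups <- unique(data.table::as.data.table(df)[, groupBy, with = FALSE])
  data.table::setorderv(groups, groupBy)
  res <- vector("list", nrow(ex_dt))
  dt <- data.table::as.data.table(df)
  gene_id <- NULL
  dt_by_gene <- split(dt, dt$gene_id)
  for (i in seq_len(nrow(ex_dt))) {
    g <- ex_dt$gene_id[i]
    gdf <- dt_by_gene[[g]]
    base <- data.table::copy(groups)
    if (is.null(gdf) || nrow(gdf) == 0) {
      base[, c("inclusion", "exclusion", "total") := 0L]
    } else {
      cls <- classifyChains(gdf$read_start, gdf$read_end, gdf$intron_chain,
                            ex_dt$exon_start[i], ex_dt$exon_end[i], flank)
      gdf <- gdf[cls != "non_overlapping"]
      cls <- cls[cls != "non_overlapping"]
      if (nrow(gdf) == 0) {
        base[, c("inclusion", "exclusion", "total") := 0L]
      } else {
        gdf$.cls <- cls
        .cls <- NULL
        tal <- gdf[, .(inclusion = sum(.cls == "inclusion"),
                       exclusion = sum(.cls == "exclusion"),
                       total = .N), by = groupBy]
        base <- merge(base, tal, by = groupBy, all.x = TRUE)
        for (cc in c("inclusion", "exclusion", "total"))
          base[[cc]][is.na(base[[cc]])] <- 0L
      }
    }
    res[[i]] <- cbind(ex_dt[i, ], base)
  }
  out <- as.data.frame(data.table::rbindlist(res))
  rownames(out) <- NULL
  out
}

#' Write event counts to TSV
#'
#' @param counts Output of [countEvents()].
#' @param path Output path.
#' @param header Optional `#`-prefixed comment lines.
#' @return `path`, invisibly.
#' @export
writeEventCounts <- function(counts, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(counts, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
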