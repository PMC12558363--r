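#' Enumerate junction-spanning probe windows
#'
#' For every exon-exon junction of every transcript, selects up to 140
#' spliced-transcript bases spanning the junction — 70 exonic bases on
#' either side, walking across additional exons of the same transcript
#' when an adjacent exon is shorter than 70 bases. When fewer than 140
#' transcript bases are available (junction close to the transcript
#' start or end) the maximal window is emitted if it reaches 130 bases;
#' shorter windows are discarded. Candidates are deduplicated by
#' sequence content within each gene (the first transcript providing a
#' sequence wins).
#'
#' @param geneModels A [GeneModels] object.
#' @param genome A named [Biostrings::DNAStringSet] (one entry per
#'   chromosome) providing sequence for all exon intervals.
#' @param side Bases per side (default 70).
#' @param minWindow Minimum retained window length (default 130).
#' @return `data.frame`, one row per candidate: `gene_id`, `chrom`,
#'   `strand`, `junction_start`, `junction_end` (the intron), `blocks`
#'   (genomic exonic blocks `start-end;...`), `window_length`,
#'   `breakpoint` (1-based position in `window_seq` of the last base
#'   before the junction), `window_seq` (transcript orientation).
#' @export
enumerateJunctionWindows <- function(geneModels, genome, side = 70L,
                                     minWindow = 130L) {
  stopifnot(is(geneModels, "GeneModels"), is(genome, "DNAStringSet"))
  ex <- geneModels@exons
  dt <- data.table::data.table(
    gene_id = S4Vectors::mcols(ex)$gene_id,
    transcript_id = S4Vectors::mcols(ex)$transcript_id,
    chrom = as.character(GenomeInfoDb::seqnames(ex)),
    start = GenomicRanges::start(ex), end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)))
  data.table::setorder(dt, gene_id, transcript_id, start)
  out <- list()
  for (tx in unique(dt$transcript_id)) {
    e <- dt[dt$transcript_id == tx, ]
    if (nrow(e) < 2) next
    if (!e$chrom[1] %in% names(genome))
      stop("genome lacks sequence for chromosome ", e$chrom[1])
    for (j in seq_len(nrow(e) - 1)) {
      left <- walkExonBases(e$start[seq_len(j)], e$end[seq_len(j)],
                            side, from_right = TRUE)
      ridx <- seq(j + 1, nrow(e))
      right <- walkExonBases(e$start[ridx], e$end[ridx], side,
                             from_right = FALSE)
      wlen <- sum(left$end - left$start + 1) +
              sum(right$end - right$start + 1)
      if (wlen < minWindow) next
      blocks <- rbind(left, right)
      blocks <- blocks[order(blocks$start), , drop = FALSE]
      seqs <- as.character(Biostrings::subseq(
        rep(genome[e$chrom[1]], nrow(blocks)),
        start = blocks$start, end = blocks$end))
      window_plus <- paste(seqs, collapse = "")
      left_len <- sum(left$end - left$start + 1)
      if (e$strand[1] == "-") {
        window_seq <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(window_plus)))
        breakpoint <- wlen - left_len
      } else {
        window_seq <- window_plus
        breakpoint <- left_len
      }
      out[[length(out) + 1]] <- data.frame(
        gene_id = e$gene_id[1], chrom = e$chrom[1],
        strand = e$strand[1],
        junction_start = e$end[j] + 1L,
        junction_end = e$start[j + 1] - 1L,
        blocks = encodeIntronChain(blocks$start, blocks$end),
        window_length = wlen, breakpoint = breakpoint,
        window_seq = window_seq, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(), chrom = character(),
                      strand = character(), junction_start = integer(),
                      junction_end = integer(), blocks = character(),
                      window_length = integer(), breakpoint = integer(),
                      window_seq = character()))
  res <- do.call(rbind, out)
  res <- res[!duplicated(paste(res$gene_id, res$window_seq)), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

# Collect up to `n` exonic bases walking away from a junction across the
# given exon chain. from_right = TRUE walks leftwards starting at the
# last exon's right end (upstream side in genomic orientation).
walkExonBases <- function(starts, ends, n, from_right) {
  blocks <- data.frame(start = integer(), end = integer())
  idx <- if (from_right) rev(seq_along(starts)) else seq_along(starts)
  left <- n
  for (i in idx) {
    len <- ends[i] - starts[i] + 1
    take <- min(len, left)
    if (from_right) {
      blocks <- rbind(data.frame(start = ends[i] - take + 1L,
                                 end = ends[i]), blocks)
    } else {
      blocks <- rbind(blocks, data.frame(start = starts[i],
                                         end = starts[i] + take - 1L))
    }
    left <- left - take
    if (left == 0) break
  }
  blocks
}

#' Count exact genomic occurrences of probe sequences
#'
#' Default mappability oracle: the number of exact matches of each
#' sequence (or its reverse complement) across the supplied genome.
#'
#' @param seqs Character vector of probe sequences.
#' @param genome A named [Biostrings::DNAStringSet].
#' @return Integer vector of hit counts.
#' @export
genomicHitCounts <- function(seqs, genome) {
  stopifnot(is(genome, "DNAStringSet"))
  vapply(seqs, function(s) {
    pat <- Biostrings::DNAString(s)
    rc <- Biostrings::reverseComplement(pat)
    fwd <- sum(Biostrings::vcountPattern(pat, genome))
    rev_ <- sum(Biostrings::vcountPattern(rc, genome))
    as.integer(fwd + rev_)
  }, integer(1), USE.NAMES = FALSE)
}

#' Filter candidates and select final 120-mers
#'
#' Within each retained window a 120-mer containing the junction
#' breakpoint is chosen by a hybridization-proxy score: 1 when the GC
#' fraction lies in `[0.30, 0.70]`, else 0; ties are broken by junction
#' centrality (breakpoint closest to the probe middle), then by the
#' leftmost offset. Candidates whose final 120-mer has more than
#' `maxHits` exact genomic matches are discarded, and genes left with
#' fewer than `minProbesPerGene` candidates are dropped entirely. The
#' multimapping filter is applied to the final 120-mer; the window's own
#' hit count is reported alongside.
#'
#' @param candidates Output of [enumerateJunctionWindows()].
#' @param genome A named `DNAStringSet`, used by the default mappability
#'   oracle; may be `NULL` when `mappability` is supplied.
#' @param mappability Function mapping a character vector of sequences to
#'   integer genomic hit counts; defaults to exact-match counting on
#'   `genome`. Supplying neither is an error.
#' @param minProbesPerGene Minimum surviving probes per gene (default 5).
#' @param maxHits Maximum allowed genomic hits (default 5).
#' @param probeLength Final probe length (default 120).
#' @param scorer Optional replacement scoring function
#'   `function(seqs) numeric` for the 120-mer selection.
#' @return `data.frame` of retained probes: candidate columns plus
#'   `probe_seq`, `probe_offset` (0-based within the window),
#'   `n_hits_probe`, `n_hits_window`.
#' @export
filterAndSelectProbes <- function(candidates, genome = NULL,
                                  mappability = NULL,
                                  minProbesPerGene = 5L, maxHits = 5L,
                                  probeLength = 120L, scorer = NULL) {
  if (is.null(mappability)) {
    if (is.null(genome))
      stop("mappability oracle unavailable: supply `genome` or `mappability`")
    mappability <- function(seqs) genomicHitCounts(seqs, genome)
  }
  if (is.null(scorer)) scorer <- gcWindowScore
  if (nrow(candidates) == 0) return(cbind(candidates,
    probe_seq = character(), probe_offset = integer(),
    n_hits_probe = integer(), n_hits_window = integer()))
  sel <- t(mapply(select120mer, candidates$window_seq,
                  candidates$breakpoint,
                  MoreArgs = list(probeLength = probeLength,
                                  scorer = scorer)))
  candidates$probe_seq <- as.character(sel[, 1])
  candidates$probe_offset <- as.integer(sel[, 2])
  candidates$n_hits_probe <- mappability(candidates$probe_seq)
  candidates$n_hits_window <- mappability(candidates$window_seq)
  keep <- candidates$n_hits_probe <= maxHits
  candidates <- candidates[keep, , drop = FALSE]
  n_per_gene <- table(candidates$gene_id)
  candidates <- candidates[
    n_per_gene[candidates$gene_id] >= minProbesPerGene, , drop = FALSE]
  rownames(candidates) <- NULL
  candidates
}

# Default hybridization-proxy score: GC fraction within [0.30, 0.70].
gcWindowScore <- function(seqs) {
  gc <- Biostrings::letterFrequency(Biostrings::DNAStringSet(seqs),
                                    "GC", as.prob = TRUE)[, 1]
  as.numeric(gc >= 0.30 & gc <= 0.70)
}

# Choose the 120-mer within a window: junction breakpoint strictly
# inside, maximize score, tie-break by centrality then leftmost offset.
select120mer <- function(window_seq, breakpoint, probeLength, scorer) {
  L <- nchar(window_seq)
  offsets <- 0:(L - probeLength)
  # breakpoint (last base before the junction) must be inside the probe
  # with at least one base on each side
  ok <- offsets + 1 <= breakpoint & breakpoint + 1 <= offsets + probeLength
  offsets <- offsets[ok]
  subs <- substring(window_seq, offsets + 1, offsets + probeLength)
  sc <- scorer(subs)
  centrality <- abs((breakpoint - offsets) - probeLength / 2)
  ord <- order(-sc, centrality, offsets)
  list(subs[ord[1]], offsets[ord[1]])
}

#' Write probes as FASTA and BED12
#'
#' FASTA names follow `gene|chrom:junction_start-junction_end`; the
#' BED12 blocks are the exonic pieces of each probe window converted to
#' BED's 0-based half-open convention.
#'
#' @param probes Output of [filterAndSelectProbes()].
#' @param fastaPath,bedPath Output paths (either may be `NULL`).
#' @return Invisibly, a list of the paths written.
#' @export
writeProbes <- function(probes, fastaPath = NULL, bedPath = NULL) {
  nm <- paste0(probes$gene_id, "|", probes$chrom, ":",
               probes$junction_start, "-", probes$junction_end)
  if (!is.null(fastaPath)) {
    ss <- Biostrings::DNAStringSet(probes$probe_seq)
    names(ss) <- nm
    Biostrings::writeXStringSet(ss, fastaPath)
  }
  if (!is.null(bedPath)) {
    lines <- vapply(seq_len(nrow(probes)), function(i) {
      bl <- parseIntronChains(probes$blocks[i])
      chromStart <- min(bl$start) - 1L
      chromEnd <- max(bl$end)
      sizes <- bl$end - bl$start + 1L
      starts0 <- bl$start - 1L - chromStart
      paste(probes$chrom[i], chromStart, chromEnd, nm[i], 0,
            probes$strand[i], chromStart, chromEnd, "0,0,0",
            nrow(bl), paste0(paste(sizes, collapse = ","), ","),
            paste0(paste(starts0, collapse = ","), ","), sep = "\t")
    }, character(1))
    writeLines(lines, bedPath)
  }
  invisible(list(fasta = fastaPath, bed = bedPath))
}
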