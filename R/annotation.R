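#' Load exon-level gene models from a GTF annotation
#'
#' Reads a GENCODE-dialect GTF and reconstructs, for every gene, the exon
#' chains of its transcripts. Only `exon` features are used; CDS/UTR
#' features are ignored, since splicing analysis needs exon chains only.
#' Coordinates are kept 1-based inclusive as in the GTF.
#'
#' @param path Path to a GTF file.
#' @param proteinCodingOnly If `TRUE` and the annotation carries a
#'   transcript biotype attribute, restrict to protein-coding transcripts.
#'   Default `FALSE`: all transcripts of a gene are modelled.
#' @return A [GeneModels] object.
#' @examples
#' gtf <- system.file("extdata", "toy.gtf", package = "snSplice")
#' gm <- loadGeneModels(gtf)
#' gm
#' @export
loadGeneModels <- function(path, proteinCodingOnly = FALSE) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (file.size(path) == 0)
    return(newGeneModels(GenomicRanges::GRanges()))
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("GTF parse error in '", path, "': ",
                                          conditionMessage(e)))
  exons <- gr[gr$type == "exon"]
  if (length(exons) == 0) return(newGeneModels(exons))
  if (is.null(exons$gene_id) || anyNA(exons$gene_id))
    stop("exon feature without gene_id attribute")
  if (is.null(exons$transcript_id) || anyNA(exons$transcript_id))
    stop("exon feature without transcript parent (transcript_id)")
  if (proteinCodingOnly) {
    bt_col <- intersect(c("transcript_type", "transcript_biotype"),
                        colnames(S4Vectors::mcols(exons)))
    if (length(bt_col))
      exons <- exons[S4Vectors::mcols(exons)[[bt_col[1]]] == "protein_coding"]
  }
  newGeneModels(exons)
}

#' Construct a GeneModels object from an exon table
#'
#' Programmatic constructor used by the simulator and tests: builds gene
#' models from a plain table of exons instead of a GTF file.
#'
#' @param exon_df `data.frame` with columns `gene_id`, `transcript_id`,
#'   `chrom`, `start`, `end`, `strand`, and optionally `gene_name`.
#' @return A [GeneModels] object.
#' @export
geneModelsFromExons <- function(exon_df) {
  stopifnot(all(c("gene_id", "transcript_id", "chrom", "start", "end",
                  "strand") %in% colnames(exon_df)))
  gr <- GenomicRanges::GRanges(exon_df$chrom,
          IRanges::IRanges(exon_df$start, exon_df$end),
          strand = exon_df$strand)
  S4Vectors::mcols(gr)$gene_id <- exon_df$gene_id
  S4Vectors::mcols(gr)$transcript_id <- exon_df$transcript_id
  if ("gene_name" %in% colnames(exon_df))
    S4Vectors::mcols(gr)$gene_name <- exon_df$gene_name
  newGeneModels(gr)
}

# Shared construction/validation path: sorts exons within transcripts and
# enforces the model invariants (>=1 exon, no overlap within a transcript,
# one chrom/strand per gene).
newGeneModels <- function(exons) {
  if (length(exons) == 0) {
    empty_ex <- GenomicRanges::GRanges()
    S4Vectors::mcols(empty_ex)$gene_id <- character()
    S4Vectors::mcols(empty_ex)$transcript_id <- character()
    gm <- new("GeneModels", exons = empty_ex,
              genes = data.frame(gene_id = character(),
                                 gene_name = character(),
                                 chrom = character(), strand = character(),
                                 stringsAsFactors = FALSE))
    return(gm)
  }
  ord <- order(S4Vectors::mcols(exons)$gene_id,
               S4Vectors::mcols(exons)$transcript_id,
               GenomicRanges::start(exons))
  exons <- exons[ord]
  dt <- data.table::data.table(
    gene_id = S4Vectors::mcols(exons)$gene_id,
    transcript_id = S4Vectors::mcols(exons)$transcript_id,
    chrom = as.character(GenomeInfoDb::seqnames(exons)),
    start = GenomicRanges::start(exons),
    end = GenomicRanges::end(exons),
    strand = as.character(GenomicRanges::strand(exons)))
  start <- end <- chrom <- strand <- gene_id <- transcript_id <- NULL
  bad <- dt[, .(overlap = any(start[-1] <= cummax(end)[-.N])),
            by = .(gene_id, transcript_id)]
  if (any(bad$overlap))
    stop("overlapping exons within transcript(s): ",
         paste(head(bad$transcript_id[bad$overlap], 3), collapse = ", "))
  per_gene <- dt[, .(n_chrom = length(unique(chrom)),
                     n_strand = length(unique(strand)),
                     chrom = chrom[1], strand = strand[1]), by = gene_id]
  if (any(per_gene$n_chrom > 1 | per_gene$n_strand > 1))
    stop("gene(s) with exons on multiple chromosomes or strands: ",
         paste(head(per_gene$gene_id[per_gene$n_chrom > 1 |
                                     per_gene$n_strand > 1], 3),
               collapse = ", "))
  gene_name <- S4Vectors::mcols(exons)$gene_name
  if (is.null(gene_name)) gene_name <- S4Vectors::mcols(exons)$gene_id
  genes <- data.frame(gene_id = per_gene$gene_id,
    gene_name = gene_name[match(per_gene$gene_id,
                                S4Vectors::mcols(exons)$gene_id)],
    chrom = per_gene$chrom, strand = per_gene$strand,
    stringsAsFactors = FALSE)
  new("GeneModels", exons = exons, genes = genes)
}

#' Internal exons of gene models
#'
#' An internal exon is one that is neither first nor last in at least one
#' transcript, hence flanked by two splice junctions. Exons are
#' deduplicated by coordinates within each gene; an exon terminal in one
#' transcript but internal in another is reported.
#'
#' @param x A [GeneModels] object.
#' @param gene Optional gene identifier(s) to restrict to.
#' @return A `GRanges` of internal exons with a `gene_id` metadata column.
#' @rdname internalExons
#' @export
setMethod("internalExons", "GeneModels", function(x, gene = NULL) {
  ex <- x@exons
  if (!is.null(gene))
    ex <- ex[S4Vectors::mcols(ex)$gene_id %in% gene]
  if (length(ex) == 0) return(GenomicRanges::GRanges(gene_id = character()))
  dt <- data.table::data.table(
    gene_id = S4Vectors::mcols(ex)$gene_id,
    transcript_id = S4Vectors::mcols(ex)$transcript_id,
    chrom = as.character(GenomeInfoDb::seqnames(ex)),
    start = GenomicRanges::start(ex), end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)))
  gene_id <- transcript_id <- start <- NULL
  internal <- dt[, .SD[order(start)][seq_len(.N) > 1 & seq_len(.N) < .N],
                 by = .(gene_id, transcript_id)]
  if (nrow(internal) == 0) return(GenomicRanges::GRanges(gene_id = character()))
  uniq <- unique(internal[, c("gene_id", "chrom", "start", "end", "strand")])
  data.table::setorder(uniq, gene_id, start, end)
  out <- GenomicRanges::GRanges(uniq$chrom,
           IRanges::IRanges(uniq$start, uniq$end), strand = uniq$strand)
  S4Vectors::mcols(out)$gene_id <- uniq$gene_id
  out
})

#' Exon-exon junction catalog of gene models
#'
#' Enumerates every intron (junction between adjacent exons) present in at
#' least one transcript, deduplicated by coordinates within each gene.
#' Donor and acceptor coordinates are strand-aware: the donor is the first
#' intronic base at the intron's 5' end in transcription order, the
#' acceptor the last intronic base at its 3' end.
#'
#' @param x A [GeneModels] object.
#' @param gene Optional gene identifier(s) to restrict to.
#' @return A `GRanges` of introns with metadata columns `gene_id`,
#'   `donor_pos`, `acceptor_pos`.
#' @rdname junctionCatalog
#' @export
setMethod("junctionCatalog", "GeneModels", function(x, gene = NULL) {
  ex <- x@exons
  if (!is.null(gene))
    ex <- ex[S4Vectors::mcols(ex)$gene_id %in% gene]
  empty <- GenomicRanges::GRanges()
  if (length(ex) == 0) return(empty)
  dt <- data.table::data.table(
    gene_id = S4Vectors::mcols(ex)$gene_id,
    transcript_id = S4Vectors::mcols(ex)$transcript_id,
    chrom = as.character(GenomeInfoDb::seqnames(ex)),
    start = GenomicRanges::start(ex), end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)))
  gene_id <- transcript_id <- start <- end <- NULL
  jx <- dt[order(start),
           if (.N >= 2) .(i_start = end[-.N] + 1L, i_end = start[-1] - 1L,
                          chrom = chrom[1], strand = strand[1]),
           by = .(gene_id, transcript_id)]
  if (nrow(jx) == 0) return(empty)
  if (any(jx$i_start > jx$i_end))
    stop("zero-length intron between adjacent exons")
  uniq <- unique(jx[, c("gene_id", "chrom", "i_start", "i_end", "strand")])
  data.table::setorder(uniq, gene_id, i_start, i_end)
  out <- GenomicRanges::GRanges(uniq$chrom,
           IRanges::IRanges(uniq$i_start, uniq$i_end), strand = uniq$strand)
  S4Vectors::mcols(out)$gene_id <- uniq$gene_id
  plus <- uniq$strand != "-"
  S4Vectors::mcols(out)$donor_pos <- ifelse(plus, uniq$i_start, uniq$i_end)
  S4Vectors::mcols(out)$acceptor_pos <- ifelse(plus, uniq$i_end, uniq$i_start)
  out
})

#' Write gene models back to GTF
#'
#' Emits one `exon` feature per modelled exon with `gene_id` and
#' `transcript_id` attributes, 1-based inclusive. Re-loading the file with
#' [loadGeneModels()] reproduces the models.
#'
#' @param x A [GeneModels] object.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
writeGeneModelsGTF <- function(x, path) {
  stopifnot(is(x, "GeneModels"))
  ex <- x@exons
  S4Vectors::mcols(ex)$type <- "exon"
  S4Vectors::mcols(ex)$source <- "snSplice"
  rtracklayer::export(ex, path, format = "gtf")
  invisible(path)
}

#' Write internal exons as BED6
#'
#' Converts from the package's 1-based inclusive coordinates to BED's
#' 0-based half-open convention at the boundary.
#'
#' @param x A [GeneModels] object.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
writeInternalExonsBed <- function(x, path) {
  ie <- internalExons(x)
  names(ie) <- S4Vectors::mcols(ie)$gene_id
  rtracklayer::export(ie, path, format = "bed")
  invisible(path)
}
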