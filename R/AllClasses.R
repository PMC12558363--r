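#' @import methods
#' @import data.table
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom utils head
NULL

#' GeneModels: exon-level gene models from a GTF annotation
#'
#' Holds the exon structure of a set of genes as a single
#' \link[GenomicRanges]{GRanges} of exons annotated with `gene_id` and
#' `transcript_id`, plus a per-gene summary table. Coordinates are 1-based
#' inclusive (GTF convention) throughout.
#'
#' @slot exons A `GRanges` of exon features; `mcols()` must carry
#'   `gene_id` and `transcript_id`. Within a transcript, exons are
#'   non-overlapping and share chromosome and strand.
#' @slot genes A `data.frame` with one row per gene: `gene_id`,
#'   `gene_name`, `chrom`, `strand`.
#'
#' @seealso [loadGeneModels()], [internalExons()], [junctionCatalog()]
#' @exportClass GeneModels
setClass("GeneModels",
  representation(exons = "GRanges", genes = "data.frame"))

setValidity("GeneModels", function(object) {
  msg <- character()
  mc <- S4Vectors::mcols(object@exons)
  if (!all(c("gene_id", "transcript_id") %in% colnames(mc)))
    msg <- c(msg, "exons must carry gene_id and transcript_id metadata columns")
  if (!all(c("gene_id", "gene_name", "chrom", "strand") %in% colnames(object@genes)))
    msg <- c(msg, "genes table must have gene_id, gene_name, chrom, strand")
  if (length(object@exons) > 0 &&
      anyNA(mc$transcript_id))
    msg <- c(msg, "exon feature without a transcript parent")
  if (length(msg)) msg else TRUE
})

#' ReadTable: per-read records for single-nucleus long reads
#'
#' One row per (deduplicated or raw) long read, carrying the sample,
#' condition, cell-type and barcode labels, the UMI, the assigned gene, the
#' aligned genomic span, and the read's intron chain. The intron chain is
#' encoded as `start-end` pairs (1-based inclusive intronic coordinates)
#' joined by `";"`; the empty string denotes a mono-exonic read.
#'
#' @slot reads A `data.frame` with columns `read_id`, `sample_id`,
#'   `condition` (one of `"case"`, `"control"`), `cell_type`, `subtype`,
#'   `barcode`, `umi`, `gene_id`, `chrom`, `read_start`, `read_end`,
#'   `strand`, `intron_chain`.
#'
#' @seealso [readTable()], [parseReadTable()], [dedupUmis()],
#'   [filterRareChains()]
#' @exportClass ReadTable
setClass("ReadTable", representation(reads = "data.frame"))

READ_TABLE_COLUMNS <- c("read_id", "sample_id", "condition", "cell_type",
  "subtype", "barcode", "umi", "gene_id", "chrom", "read_start",
  "read_end", "strand", "intron_chain")

setValidity("ReadTable", function(object) {
  msg <- character()
  df <- object@reads
  missing_cols <- setdiff(READ_TABLE_COLUMNS, colnames(df))
  if (length(missing_cols))
    msg <- c(msg, paste0("missing column(s): ",
                         paste(missing_cols, collapse = ", ")))
  if (!length(msg) && nrow(df) > 0) {
    if (!all(df$condition %in% c("case", "control")))
      msg <- c(msg, "condition must be 'case' or 'control'")
    if (any(!nzchar(df$cell_type)))
      msg <- c(msg, "cell_type must be non-empty")
    if (any(df$read_start > df$read_end))
      msg <- c(msg, "read_start must be <= read_end")
  }
  if (length(msg)) msg else TRUE
})

#' SimTruth: planted ground truth of a simulated dataset
#'
#' @slot exonTruth `data.frame`: one row per (alternative exon, cell type)
#'   with planted `psi_case`, `psi_control` and `delta_psi`
#'   (= psi_case − psi_control).
#' @slot siteTruth `data.frame`: planted splice-site usage per group and
#'   condition (empty when no site shifts were planted).
#' @slot umiTruth `data.frame`: `read_id`, `true_umi` — UMIs before error
#'   injection, for dedup validation.
#'
#' @seealso [simulateDataset()]
#' @exportClass SimTruth
setClass("SimTruth",
  representation(exonTruth = "data.frame", siteTruth = "data.frame",
                 umiTruth = "data.frame"))

setValidity("SimTruth", function(object) {
  et <- object@exonTruth
  if (nrow(et) > 0 &&
      max(abs(et$delta_psi - (et$psi_case - et$psi_control))) > 1e-12)
    return("delta_psi must equal psi_case - psi_control")
  TRUE
})

#' @describeIn GeneModels Compact display.
#' @param object A `GeneModels` object.
#' @export
setMethod("show", "GeneModels", function(object) {
  cat("GeneModels with", nrow(object@genes), "gene(s),",
      length(unique(S4Vectors::mcols(object@exons)$transcript_id)),
      "transcript(s),", length(object@exons), "exon feature(s)\n")
})

#' @describeIn ReadTable Compact display.
#' @param object A `ReadTable` object.
#' @export
setMethod("show", "ReadTable", function(object) {
  df <- object@reads
  cat("ReadTable with", nrow(df), "read(s)")
  if (nrow(df) > 0)
    cat(";", length(unique(df$gene_id)), "gene(s),",
        length(unique(df$sample_id)), "sample(s),",
        length(unique(df$cell_type)), "cell type(s)")
  cat("\n")
})

#' @describeIn SimTruth Compact display.
#' @param object A `SimTruth` object.
#' @export
setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", nrow(object@exonTruth), "planted exon record(s),",
      nrow(object@siteTruth), "site-usage record(s),",
      nrow(object@umiTruth), "true UMI(s)\n")
})

#' Accessors for the core classes
#'
#' `readData()` returns the underlying per-read `data.frame` of a
#' `ReadTable`; `nReads()` its row count; `exonStructure()` the exon
#' `GRanges` of a `GeneModels`; `geneIds()` its gene identifiers;
#' `exonTruth()`, `siteTruth()` and `umiTruth()` the planted-truth tables
#' of a `SimTruth`.
#'
#' @param x The object.
#' @return See the individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
readData <- function(x) {
  stopifnot(is(x, "ReadTable"))
  x@reads
}

#' @rdname accessors
#' @export
nReads <- function(x) nrow(readData(x))

#' @rdname accessors
#' @export
exonStructure <- function(x) {
  stopifnot(is(x, "GeneModels"))
  x@exons
}

#' @rdname accessors
#' @export
geneIds <- function(x) {
  stopifnot(is(x, "GeneModels"))
  x@genes$gene_id
}

#' @rdname accessors
#' @export
exonTruth <- function(x) {
  stopifnot(is(x, "SimTruth"))
  x@exonTruth
}

#' @rdname accessors
#' @export
siteTruth <- function(x) {
  stopifnot(is(x, "SimTruth"))
  x@siteTruth
}

#' @rdname accessors
#' @export
umiTruth <- function(x) {
  stopifnot(is(x, "SimTruth"))
  x@umiTruth
}
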