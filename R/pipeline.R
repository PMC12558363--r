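#' Run the full case-control splicing pipeline
#'
#' Executes UMI deduplication, rare-chain filtering, alternative-exon
#' discovery, event counting, the exon test per cell type and in
#' pseudobulk (cell types merged, sample identity kept so the support
#' and ordering filters still apply), splice-site testing, and the
#' cross-stratum analyses (masking, ΔΨ correlations, and — when a DE
#' table is supplied — the splicing-versus-expression overlap). All
#' result tables are written to `outDir` with a header recording the
#' seed and a configuration hash, plus a `manifest.yaml` with row counts
#' per stage.
#'
#' @param reads A [ReadTable] (raw; dedup and chain filtering are
#'   applied here).
#' @param geneModels A [GeneModels].
#' @param outDir Output directory (created if needed).
#' @param config A [testConfig()].
#' @param sampleAges Optional named ages per sample for the age-matched
#'   robustness check.
#' @param deTable Optional per-gene DE table (`gene_id`, `log2FC`,
#'   `fdr`) for the overlap analysis; requesting the overlap without it
#'   aborts naming the stage.
#' @param runOverlap Run the expression-overlap stage (default: only
#'   when `deTable` is supplied).
#' @param dedupMaxDistance,minChainCount Read-processing thresholds
#'   (defaults 3 and 5).
#' @param seed Seed recorded in output headers (the pipeline itself is
#'   deterministic).
#' @return Invisibly, a list with the in-memory results:
#'   `celltype_results`, `pseudobulk_results`, `site_results`,
#'   `masking`, `correlations`, `overlap`, `manifest`.
#' @export
runPipeline <- function(reads, geneModels, outDir,
                        config = testConfig(), sampleAges = NULL,
                        deTable = NULL, runOverlap = !is.null(deTable),
                        dedupMaxDistance = 3L, minChainCount = 5L,
                        seed = NA_integer_) {
  stopifnot(is(reads, "ReadTable"), is(geneModels, "GeneModels"))
  if (runOverlap && is.null(deTable))
    stop("stage 'overlap' requested but no DE table supplied")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(paste0("seed=", seed),
           paste0("config_md5=", configHash(config)),
           paste0("snSplice=", as.character(utils::packageVersion("snSplice"))))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  manifest <- list(seed = seed, config = unclass(config),
                   n_reads_input = nReads(reads))

  reads <- stage("dedup", dedupUmis(reads, maxDistance = dedupMaxDistance))
  manifest$n_reads_dedup <- nReads(reads)
  reads <- stage("filter-chains", filterRareChains(reads, minChainCount))
  manifest$n_reads_chain_filtered <- nReads(reads)

  exons <- stage("discover-exons",
                 discoverAlternativeExons(reads, geneModels))
  manifest$n_alt_exons <- length(exons)
  counts <- stage("count-events",
    countEvents(reads, exons,
                groupBy = c("cell_type", "condition", "sample_id"),
                flank = config$flank))
  writeEventCounts(counts, file.path(outDir, "event_counts.tsv"), hdr)

  ct_res <- stage("test-exons", testExons(counts, config))
  if (!is.null(sampleAges))
    ct_res <- stage("age-match",
                    ageMatchedCheck(ct_res, counts, sampleAges, config))
  writeTestResults(ct_res, file.path(outDir, "exon_tests.tsv"), hdr)
  manifest$n_exon_tests <- nrow(ct_res)
  manifest$n_significant_exons <- sum(ct_res$significant)

  pb_counts <- pseudobulkCounts(counts)
  pb_res <- stage("test-exons-pseudobulk", testExons(pb_counts, config))
  if (!is.null(sampleAges))
    pb_res <- ageMatchedCheck(pb_res, pb_counts, sampleAges, config)
  writeTestResults(pb_res, file.path(outDir, "exon_tests_pseudobulk.tsv"),
                   hdr)

  site_res <- stage("test-sites",
                    testSiteGroups(groupSpliceSites(intronCounts(reads))))
  writeTestResults(site_res, file.path(outDir, "site_tests.tsv"), hdr)
  manifest$n_site_groups <- nrow(site_res)

  cts <- sort(unique(ct_res$cell_type))
  masking <- stage("masking", do.call(rbind, lapply(cts, function(ct)
    pseudobulkMasking(ct_res[ct_res$cell_type == ct, ], pb_res))))
  writeTestResults(masking, file.path(outDir, "masking.tsv"), hdr)

  correlations <- NULL
  if (length(cts) >= 2) {
    pairs <- utils::combn(cts, 2, simplify = FALSE)
    correlations <- stage("correlate", do.call(rbind, lapply(pairs,
      function(p) cbind(cell_type_a = p[1], cell_type_b = p[2],
        deltaPsiCorrelation(ct_res[ct_res$cell_type == p[1], ],
                            ct_res[ct_res$cell_type == p[2], ])))))
    writeTestResults(correlations, file.path(outDir, "correlations.tsv"),
                     hdr)
  }

  overlap <- NULL
  if (runOverlap) {
    overlap <- stage("overlap", do.call(rbind, lapply(cts, function(ct) {
      sub <- ct_res[ct_res$cell_type == ct, ]
      universe <- intersect(unique(sub$gene_id[sub$eligible]),
                            unique(deTable$gene_id))
      cbind(cell_type = ct,
            expressionOverlap(sub$gene_id[sub$significant], deTable,
                              universe))
    })))
    writeTestResults(overlap, file.path(outDir, "overlap.tsv"), hdr)
  }

  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  invisible(list(celltype_results = ct_res, pseudobulk_results = pb_res,
                 site_results = site_res, masking = masking,
                 correlations = correlations, overlap = overlap,
                 manifest = manifest))
}

#' Collapse per-sample event counts to pseudobulk
#'
#' Sums the inclusion / exclusion / total counts over cell types within
#' each (exon, condition, sample), keeping sample identity, and labels
#' the single resulting stratum `"pseudobulk"`.
#'
#' @param counts Per-sample counts from [countEvents()] with
#'   `cell_type` in the grouping.
#' @return A counts `data.frame` with one `cell_type` level,
#'   `"pseudobulk"`.
#' @export
pseudobulkCounts <- function(counts) {
  dt <- data.table::as.data.table(counts)
  inclusion <- exclusion <- total <- NULL
  out <- dt[, .(inclusion = sum(inclusion), exclusion = sum(exclusion),
                total = sum(total)),
            by = c("gene_id", "chrom", "exon_start", "exon_end", "strand",
                   "source", "condition", "sample_id")]
  out$cell_type <- "pseudobulk"
  as.data.frame(out)
}

# Stable hash of a configuration for output headers.
configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}
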