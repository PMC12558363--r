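#' Wilson score confidence interval for a binomial fraction
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return Named numeric vector `c(estimate, lower, upper)`.
#' @export
wilsonCI <- function(x, n, conf = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(estimate = p, lower = max(0, center - half),
    upper = min(1, center + half))
}

#' Pseudobulk masking of cell-type-specific splicing calls
#'
#' A cell-type-significant exon is masked when it is not significant in
#' the pseudobulk analysis (all cell types pooled per condition, tested
#' under identical criteria). Exons absent from the pseudobulk table
#' (untested there) are counted as masked and also reported separately.
#'
#' @param celltypeResults [testExons()] output for one cell type (rows of
#'   one stratum).
#' @param pseudobulkResults [testExons()] output of the pseudobulk run.
#' @return `data.frame` with one row: `cell_type`, `n_significant`,
#'   `n_masked`, `n_untested_pseudobulk`, `fraction_masked`, and Wilson
#'   95% CI bounds.
#' @export
pseudobulkMasking <- function(celltypeResults, pseudobulkResults) {
  sig <- celltypeResults[celltypeResults$significant %in% TRUE, ,
                         drop = FALSE]
  ct <- if ("cell_type" %in% colnames(celltypeResults) &&
            nrow(celltypeResults))
    as.character(celltypeResults$cell_type[1]) else NA_character_
  n_sig <- nrow(sig)
  if (n_sig == 0)
    return(data.frame(cell_type = ct, n_significant = 0L, n_masked = 0L,
                      n_untested_pseudobulk = 0L,
                      fraction_masked = NA_real_, ci_lower = NA_real_,
                      ci_upper = NA_real_))
  key <- function(d) paste(d$gene_id, d$exon_start, d$exon_end, sep = "\r")
  pb_key <- key(pseudobulkResults)
  m <- match(key(sig), pb_key)
  untested <- is.na(m)
  masked <- untested | !(pseudobulkResults$significant[m] %in% TRUE)
  ci <- wilsonCI(sum(masked), n_sig)
  data.frame(cell_type = ct, n_significant = n_sig,
             n_masked = sum(masked),
             n_untested_pseudobulk = sum(untested),
             fraction_masked = unname(ci["estimate"]),
             ci_lower = unname(ci["lower"]),
             ci_upper = unname(ci["upper"]))
}

#' ΔΨ correlation between two strata
#'
#' Pearson correlation of ΔΨ values for exons quantifiable (tested, with
#' defined ΔΨ) in both strata, with a 95% confidence interval by the
#' Fisher z-transform. By default restricted to exons significant in at
#' least one of the two strata.
#'
#' @param resultsA,resultsB [testExons()] outputs for the two strata.
#' @param selection `"significant_any"` (default) or `"all"` tested
#'   exons.
#' @return `data.frame` with `n_pairs`, `r`, `ci_lower`, `ci_upper`, and
#'   a `reason` column (`NA` when defined; otherwise why undefined).
#' @export
deltaPsiCorrelation <- function(resultsA, resultsB,
                                selection = c("significant_any", "all")) {
  selection <- match.arg(selection)
  key <- function(d) paste(d$gene_id, d$exon_start, d$exon_end, sep = "\r")
  a <- resultsA[!is.na(resultsA$delta_psi), , drop = FALSE]
  b <- resultsB[!is.na(resultsB$delta_psi), , drop = FALSE]
  m <- match(key(a), key(b))
  paired <- !is.na(m)
  da <- a$delta_psi[paired]
  db <- b$delta_psi[m[paired]]
  if (selection == "significant_any") {
    keep <- a$significant[paired] %in% TRUE |
            b$significant[m[paired]] %in% TRUE
    da <- da[keep]; db <- db[keep]
  }
  undef <- function(reason, n)
    data.frame(n_pairs = n, r = NA_real_, ci_lower = NA_real_,
               ci_upper = NA_real_, reason = reason)
  if (length(da) < 3) return(undef("fewer than 3 pairs", length(da)))
  if (stats::sd(da) == 0 || stats::sd(db) == 0)
    return(undef("zero variance in a stratum", length(da)))
  ct <- stats::cor.test(da, db, method = "pearson", conf.level = 0.95)
  data.frame(n_pairs = length(da), r = unname(ct$estimate),
             ci_lower = ct$conf.int[1], ci_upper = ct$conf.int[2],
             reason = NA_character_)
}

#' Overlap between splicing dysregulation and differential expression
#'
#' Builds, over the universe of genes tested for both splicing and
#' expression, the 2x2 table of (spliced and DE, spliced only, DE only,
#' neither), applies Fisher's exact two-sided test, and reports the
#' sample odds ratio `(a * d) / (b * c)`. When any cell is zero, the
#' Haldane-Anscombe corrected odds ratio (+0.5 per cell) is also
#' reported and flagged.
#'
#' @param splicedGenes Character vector: genes with at least one
#'   significantly dysregulated exon.
#' @param deTable `data.frame` with columns `gene_id`, `log2FC`, `fdr` —
#'   per-gene differential-expression results produced elsewhere.
#' @param testedUniverse Character vector: genes tested for both splicing
#'   and expression; gene lists are restricted to it before tabulation.
#' @param lfcMin Minimum |log2FC| to call a gene DE (default 0.1).
#' @param fdrMax Maximum DE FDR (default 0.05).
#' @return `data.frame` with the four cells, `odds_ratio`,
#'   `odds_ratio_corrected`, `zero_cell` flag, and `p`.
#' @export
expressionOverlap <- function(splicedGenes, deTable, testedUniverse,
                              lfcMin = 0.1, fdrMax = 0.05) {
  universe <- unique(testedUniverse)
  if (length(universe) == 0) stop("empty tested universe")
  stopifnot(all(c("gene_id", "log2FC", "fdr") %in% colnames(deTable)))
  de_genes <- deTable$gene_id[abs(deTable$log2FC) >= lfcMin &
                              deTable$fdr <= fdrMax]
  spliced <- intersect(unique(splicedGenes), universe)
  de <- intersect(unique(de_genes), universe)
  a <- length(intersect(spliced, de))
  b <- length(setdiff(spliced, de))
  c_ <- length(setdiff(de, spliced))
  d <- length(universe) - a - b - c_
  or <- (a * d) / (b * c_)
  zero <- any(c(a, b, c_, d) == 0)
  or_corr <- if (zero)
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5)) else NA_real_
  p <- stats::fisher.test(rbind(c(a, b), c(c_, d)))$p.value
  data.frame(n_both = a, n_spliced_only = b, n_de_only = c_,
             n_neither = d, odds_ratio = or,
             odds_ratio_corrected = or_corr, zero_cell = zero, p = p)
}
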