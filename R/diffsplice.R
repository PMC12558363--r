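#' Test configuration for the exon filter cascade
#'
#' Bundles the thresholds of the case-control exon test. Defaults follow
#' the standard cascade: |ΔΨ| at least 20 percentage points and FDR 0.05
#' for a call, pooled Ψ within [5%, 95%], at least 10 informative reads
#' per condition, informative/total coverage at least 0.8, two-thirds
#' per-sample support and ordering rules, 50% ΔΨ retention in the
#' age-matched subset, and a 50-base exclusion flank.
#'
#' @param deltaPsiMin Minimum |ΔΨ| for significance (fraction; default 0.20).
#' @param fdr BY-adjusted q-value cutoff (default 0.05).
#' @param psiBounds Pooled-Ψ eligibility bounds (default `c(0.05, 0.95)`).
#' @param minReadsPerCondition Minimum informative reads (inclusion +
#'   exclusion) per condition (default 10).
#' @param coverageMin Minimum (inclusion + exclusion) / total ratio,
#'   pooled over conditions (default 0.8).
#' @param supportFraction Fraction of samples per group that must
#'   contribute an informative read (default 2/3; ceiling rule).
#' @param orderingFraction Fraction for the per-sample Ψ ordering rule
#'   (default 2/3; ceiling rule, ties count against).
#' @param ageMatchRetention Minimum |ΔΨ| retention (same sign) in the
#'   age-matched subset (default 0.5).
#' @param ageSubsetSize Samples per group in the age-matched subset
#'   (default 4).
#' @param flank Exclusion flank in bases (default 50).
#' @return A named list of class `TestConfig`.
#' @export
testConfig <- function(deltaPsiMin = 0.20, fdr = 0.05,
                       psiBounds = c(0.05, 0.95),
                       minReadsPerCondition = 10L, coverageMin = 0.8,
                       supportFraction = 2 / 3, orderingFraction = 2 / 3,
                       ageMatchRetention = 0.5, ageSubsetSize = 4L,
                       flank = 50L) {
  stopifnot(deltaPsiMin >= 0, deltaPsiMin <= 1,
            fdr > 0, fdr <= 1,
            length(psiBounds) == 2, psiBounds[1] <= psiBounds[2],
            psiBounds[1] >= 0, psiBounds[2] <= 1,
            minReadsPerCondition >= 0, coverageMin >= 0, coverageMin <= 1,
            supportFraction > 0, supportFraction <= 1,
            orderingFraction > 0, orderingFraction <= 1,
            ageMatchRetention >= 0, ageMatchRetention <= 1, flank >= 0)
  structure(list(deltaPsiMin = deltaPsiMin, fdr = fdr,
                 psiBounds = psiBounds,
                 minReadsPerCondition = as.integer(minReadsPerCondition),
                 coverageMin = coverageMin,
                 supportFraction = supportFraction,
                 orderingFraction = orderingFraction,
                 ageMatchRetention = ageMatchRetention,
                 ageSubsetSize = as.integer(ageSubsetSize),
                 flank = as.integer(flank)),
            class = "TestConfig")
}

#' Percent spliced in (Ψ)
#'
#' Ψ = inclusion / (inclusion + exclusion). With zero informative reads
#' Ψ is undefined and `NA` is returned (such exons are flagged, not
#' tested). ΔΨ is formed as case Ψ minus control Ψ, so a negative ΔΨ
#' means more skipping in the case condition.
#'
#' @param inclusion,exclusion Non-negative event counts (vectorized).
#' @return Fraction in `[0, 1]`, or `NA` when both counts are zero.
#' @examples
#' psi(83, 17) - psi(90, 10)   # a -7 percentage-point shift
#' @export
psi <- function(inclusion, exclusion) {
  stopifnot(all(inclusion >= 0), all(exclusion >= 0))
  tot <- inclusion + exclusion
  ifelse(tot == 0, NA_real_, inclusion / tot)
}

#' ΔΨ: case Ψ minus control Ψ
#'
#' @param psiCase,psiControl Ψ fractions in `[0, 1]`.
#' @return ΔΨ in `[-1, 1]`.
#' @export
deltaPsi <- function(psiCase, psiControl) psiCase - psiControl

#' Fisher's exact test on a 2x2 table with chi-squared gating
#'
#' Computes the exact two-sided p-value (sum of hypergeometric
#' probabilities no larger than that of the observed table, margins
#' fixed) and evaluates Cochran's validity criterion: the gate passes iff
#' all four expected counts (row total x column total / grand total) are
#' at least 5. When the gate fails the p-value is still reported, but the
#' exon is excluded from the multiple-testing family. A zero margin makes
#' p undefined (`NA`) and fails the gate.
#'
#' @param tab 2x2 matrix of non-negative integer counts,
#'   `rbind(c(incl_case, excl_case), c(incl_ctrl, excl_ctrl))`.
#' @return List with elements `p` (two-sided p-value) and `gate`
#'   (logical).
#' @export
fisherExact2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2), all(tab >= 0))
  storage.mode(tab) <- "integer"
  n <- sum(tab)
  if (n == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(p = NA_real_, gate = FALSE))
  expected <- outer(rowSums(tab), colSums(tab)) / n
  gate <- all(expected >= 5)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  list(p = min(p, 1), gate = gate)
}

#' Benjamini-Yekutieli adjustment
#'
#' Step-up adjusted values `p_(i) * m * c(m) / i` with
#' `c(m) = sum_{k=1..m} 1/k`, enforced monotone non-increasing from the
#' largest rank down, capped at 1, and returned in input order. Valid
#' under arbitrary dependence of the tests.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA`s propagate and do
#'   not count toward the family size).
#' @return Adjusted q-values in input order.
#' @export
byAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BY")
}

#' Per-sample support filter
#'
#' Passes iff in each group at least `ceiling(fraction * group size)`
#' samples contribute at least one informative read.
#'
#' @param nInformativeCase,nInformativeControl Number of samples with >= 1
#'   informative read, per group.
#' @param nCase,nControl Group sizes (all samples).
#' @param fraction Required fraction (default 2/3).
#' @return Logical.
#' @export
sampleSupportFilter <- function(nInformativeCase, nCase,
                                nInformativeControl, nControl,
                                fraction = 2 / 3) {
  nInformativeCase >= ceiling(fraction * nCase) &
    nInformativeControl >= ceiling(fraction * nControl)
}

#' Per-sample Ψ ordering filter
#'
#' When the pooled control Ψ exceeds the pooled case Ψ, the filter passes
#' iff at least `ceiling(fraction * n)` of the informative control
#' samples each have a Ψ strictly greater than the Ψ of at least
#' `ceiling(fraction * m)` of the informative case samples; roles are
#' swapped when the pooled case Ψ is higher. Ties count against passing;
#' a pooled tie, or a group with no informative samples, fails.
#'
#' @param psiCase,psiControl Per-sample Ψ values, informative samples
#'   only (samples with zero informative reads are excluded on both sides
#'   of the rule).
#' @param pooledDirection Sign of pooled control Ψ minus pooled case Ψ.
#' @param fraction Required fraction (default 2/3).
#' @return Logical.
#' @export
sampleOrderingFilter <- function(psiCase, psiControl, pooledDirection,
                                 fraction = 2 / 3) {
  psiCase <- psiCase[!is.na(psiCase)]
  psiControl <- psiControl[!is.na(psiControl)]
  if (length(psiCase) == 0 || length(psiControl) == 0) return(FALSE)
  if (pooledDirection == 0) return(FALSE)
  hi <- if (pooledDirection > 0) psiControl else psiCase
  lo <- if (pooledDirection > 0) psiCase else psiControl
  need_lo <- ceiling(fraction * length(lo))
  need_hi <- ceiling(fraction * length(hi))
  n_beating <- vapply(hi, function(v) sum(v > lo), integer(1))
  sum(n_beating >= need_lo) >= need_hi
}

#' Coverage filter
#'
#' Passes iff (inclusion + exclusion) / total >= threshold, with counts
#' pooled over both conditions; a zero total fails.
#'
#' @param inclusion,exclusion,total Pooled event counts.
#' @param threshold Minimum informative fraction (default 0.8).
#' @return Logical (vectorized).
#' @export
coverageFilter <- function(inclusion, exclusion, total, threshold = 0.8) {
  total > 0 & (inclusion + exclusion) / total >= threshold
}

#' Case-control exon test with the full filter cascade
#'
#' For each stratum (by default each cell type) and each alternative
#' exon: (1) eligibility — pooled Ψ within `psiBounds`, at least
#' `minReadsPerCondition` informative reads in each condition, coverage
#' ratio at least `coverageMin`; (2) Fisher's exact test on the pooled
#' 2x2 inclusion/exclusion table, gated by Cochran's chi-squared
#' criterion; (3) Benjamini-Yekutieli adjustment across the stratum's
#' gated exons; (4) per-sample support and ordering flags; (5) an exon is
#' significant iff q <= `fdr`, |ΔΨ| >= `deltaPsiMin`, and every filter
#' passes. The full table is returned, including ineligible and
#' non-significant exons with their per-filter flags.
#'
#' @param counts Per-sample event counts from
#'   [countEvents()] with `groupBy = c(groupVar, "condition",
#'   "sample_id")`.
#' @param config A [testConfig()].
#' @param groupVar Stratifying column (default `"cell_type"`; use
#'   `"subtype"` for subtype-resolved tests, or a constant column for
#'   pseudobulk).
#' @return A `data.frame`, one row per exon x stratum: counts per
#'   condition, `psi_case`, `psi_control`, `delta_psi`, `p_raw`, `q_by`,
#'   logical flag columns `pass_*`, and `significant`.
#' @export
testExons <- function(counts, config = testConfig(),
                      groupVar = "cell_type") {
  stopifnot(inherits(config, "TestConfig"))
  need <- c("gene_id", "chrom", "exon_start", "exon_end", "strand",
            "source", groupVar, "condition", "sample_id",
            "inclusion", "exclusion", "total")
  stopifnot(all(need %in% colnames(counts)))
  dt <- data.table::as.data.table(counts)
  data.table::setnames(dt, groupVar, ".stratum")
  exon_cols <- c("gene_id", "chrom", "exon_start", "exon_end", "strand",
                 "source")
  # Group sizes: all samples observed per condition in the counts table.
  samp <- unique(dt[, c("condition", "sample_id")])
  n_case <- sum(samp$condition == "case")
  n_ctrl <- sum(samp$condition == "control")

  inclusion <- exclusion <- total <- condition <- .stratum <- NULL
  pooled <- dt[, .(
    incl_case = sum(inclusion[condition == "case"]),
    excl_case = sum(exclusion[condition == "case"]),
    total_case = sum(total[condition == "case"]),
    incl_ctrl = sum(inclusion[condition == "control"]),
    excl_ctrl = sum(exclusion[condition == "control"]),
    total_ctrl = sum(total[condition == "control"]),
    n_inf_samples_case = sum(condition == "case" &
                             inclusion + exclusion > 0),
    n_inf_samples_ctrl = sum(condition == "control" &
                             inclusion + exclusion > 0)),
    by = c(".stratum", exon_cols)]

  pooled$psi_case <- psi(pooled$incl_case, pooled$excl_case)
  pooled$psi_control <- psi(pooled$incl_ctrl, pooled$excl_ctrl)
  pooled$delta_psi <- deltaPsi(pooled$psi_case, pooled$psi_control)
  psi_pooled <- psi(pooled$incl_case + pooled$incl_ctrl,
                    pooled$excl_case + pooled$excl_ctrl)
  pooled$pass_psi_range <- !is.na(psi_pooled) &
    psi_pooled >= config$psiBounds[1] & psi_pooled <= config$psiBounds[2]
  pooled$pass_min_reads <-
    pooled$incl_case + pooled$excl_case >= config$minReadsPerCondition &
    pooled$incl_ctrl + pooled$excl_ctrl >= config$minReadsPerCondition
  pooled$pass_coverage <- coverageFilter(
    pooled$incl_case + pooled$incl_ctrl,
    pooled$excl_case + pooled$excl_ctrl,
    pooled$total_case + pooled$total_ctrl, config$coverageMin)
  pooled$pass_sample_support <- sampleSupportFilter(
    pooled$n_inf_samples_case, n_case,
    pooled$n_inf_samples_ctrl, n_ctrl, config$supportFraction)

  ft <- mapply(function(a, b, c_, d) {
      r <- fisherExact2x2(rbind(c(a, b), c(c_, d)))
      c(r$p, r$gate)
    }, pooled$incl_case, pooled$excl_case, pooled$incl_ctrl,
       pooled$excl_ctrl)
  pooled$p_raw <- ft[1, ]
  pooled$pass_chi2_gate <- as.logical(ft[2, ])

  # Ordering flag from per-sample Ψ of informative samples.
  key <- do.call(paste, c(pooled[, c(".stratum", exon_cols), with = FALSE],
                          sep = "\r"))
  dkey <- do.call(paste, c(dt[, c(".stratum", exon_cols), with = FALSE],
                           sep = "\r"))
  dt$.psi <- psi(dt$inclusion, dt$exclusion)
  split_dt <- split(dt[, c("condition", ".psi")], dkey)
  pooled$pass_sample_ordering <- vapply(seq_along(key), function(i) {
    sub <- split_dt[[key[i]]]
    dir <- pooled$psi_control[i] - pooled$psi_case[i]
    if (is.na(dir)) return(FALSE)
    sampleOrderingFilter(sub$.psi[sub$condition == "case"],
                         sub$.psi[sub$condition == "control"],
                         sign(dir), config$orderingFraction)
  }, logical(1))

  # BY family per stratum: only exons passing eligibility and the gate.
  pooled$eligible <- pooled$pass_psi_range & pooled$pass_min_reads &
    pooled$pass_coverage & pooled$pass_chi2_gate
  pooled$q_by <- NA_real_
  for (st in unique(pooled$.stratum)) {
    idx <- which(pooled$.stratum == st & pooled$eligible)
    if (length(idx))
      pooled$q_by[idx] <- byAdjust(pooled$p_raw[idx])
  }
  pooled$pass_age_match <- NA  # set by ageMatchedCheck()
  pooled$significant <- !is.na(pooled$q_by) &
    pooled$q_by <= config$fdr &
    !is.na(pooled$delta_psi) &
    abs(pooled$delta_psi) >= config$deltaPsiMin &
    pooled$pass_sample_support & pooled$pass_sample_ordering
  data.table::setnames(pooled, ".stratum", groupVar)
  out_cols <- c(groupVar, exon_cols,
                "incl_case", "excl_case", "total_case",
                "incl_ctrl", "excl_ctrl", "total_ctrl",
                "psi_case", "psi_control", "delta_psi", "p_raw", "q_by",
                "pass_psi_range", "pass_min_reads", "pass_coverage",
                "pass_chi2_gate", "pass_sample_support",
                "pass_sample_ordering", "pass_age_match", "eligible",
                "significant")
  out <- as.data.frame(pooled[, out_cols, with = FALSE])
  data.table::setorderv(out, c(groupVar, "gene_id", "exon_start"))
  rownames(out) <- NULL
  out
}

#' Age-matched robustness check
#'
#' Selects, once, the `subsetSize` samples per group whose group mean
#' ages are closest, recomputes ΔΨ on that subset for every result row,
#' and flags the row as passing iff the subset ΔΨ has the same sign as
#' the full ΔΨ and a magnitude of at least `ageMatchRetention` times the
#' full |ΔΨ|. Rows failing the flag lose significance; with fewer than
#' `subsetSize` samples in a group the flag is left undefined (`NA`) and
#' significance is unchanged.
#'
#' @param results Output of [testExons()].
#' @param counts The per-sample counts the results were computed from.
#' @param sampleAges Named numeric vector: age per `sample_id`.
#' @param config The same [testConfig()].
#' @param groupVar Stratifying column used in [testExons()].
#' @return `results` with `pass_age_match`, `delta_psi_agematched`, and
#'   updated `significant`.
#' @export
ageMatchedCheck <- function(results, counts, sampleAges,
                            config = testConfig(),
                            groupVar = "cell_type") {
  dt <- data.table::as.data.table(counts)
  samp <- unique(dt[, c("condition", "sample_id")])
  pick <- ageMatchedSubset(samp, sampleAges, config$ageSubsetSize)
  if (is.null(pick)) {
    results$delta_psi_agematched <- NA_real_
    return(results)
  }
  sub <- dt[dt$sample_id %in% pick, ]
  inclusion <- exclusion <- condition <- NULL
  key_cols <- c(groupVar, "gene_id", "exon_start", "exon_end")
  agg <- sub[, .(
    psi_case_sub = psi(sum(inclusion[condition == "case"]),
                       sum(exclusion[condition == "case"])),
    psi_ctrl_sub = psi(sum(inclusion[condition == "control"]),
                       sum(exclusion[condition == "control"]))),
    by = key_cols]
  agg$delta_sub <- deltaPsi(agg$psi_case_sub, agg$psi_ctrl_sub)
  rk <- do.call(paste, c(results[, key_cols], sep = "\r"))
  ak <- do.call(paste, c(agg[, key_cols, with = FALSE], sep = "\r"))
  delta_sub <- agg$delta_sub[match(rk, ak)]
  full <- results$delta_psi
  flag <- ifelse(is.na(delta_sub) | is.na(full), NA,
                 sign(delta_sub) == sign(full) &
                 abs(delta_sub) >= config$ageMatchRetention * abs(full))
  results$pass_age_match <- flag
  results$delta_psi_agematched <- delta_sub
  results$significant <- results$significant & !(flag %in% FALSE)
  results
}

# Pick the subsetSize samples per group minimizing the absolute
# difference in group mean ages; NULL when a group is too small.
ageMatchedSubset <- function(samples, ages, subsetSize) {
  case_ids <- samples$sample_id[samples$condition == "case"]
  ctrl_ids <- samples$sample_id[samples$condition == "control"]
  if (length(case_ids) < subsetSize || length(ctrl_ids) < subsetSize)
    return(NULL)
  if (!all(c(case_ids, ctrl_ids) %in% names(ages)))
    stop("sampleAges must name every sample")
  case_sets <- utils::combn(case_ids, subsetSize, simplify = FALSE)
  ctrl_sets <- utils::combn(ctrl_ids, subsetSize, simplify = FALSE)
  best <- NULL
  best_diff <- Inf
  for (cs in case_sets) {
    m_case <- mean(ages[cs])
    for (ks in ctrl_sets) {
      d <- abs(m_case - mean(ages[ks]))
      if (d < best_diff) {
        best_diff <- d
        best <- c(cs, ks)
      }
    }
  }
  best
}

#' Write exon test results to TSV
#'
#' @param results Output of [testExons()].
#' @param path Output path.
#' @param header Optional `#`-prefixed comment lines.
#' @return `path`, invisibly.
#' @export
writeTestResults <- function(results, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(results, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
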