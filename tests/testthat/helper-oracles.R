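# Independent oracles and fixture builders used across the test files.

# Exact two-sided Fisher p for a 2x2 table by full hypergeometric
# enumeration over all tables with the observed margins. Probabilities
# are computed from log-binomial coefficients (not dhyper) so the route
# is independent of the implementation under test. Tables whose
# probability is within a 1e-7 relative tolerance of the observed one
# count as "as extreme" (the standard convention for floating-point
# ties).
fisherOracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  logp <- function(x) {
    lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
  }
  p_obs <- exp(logp(a))
  xs <- lo:hi
  sum(exp(logp(xs))[exp(logp(xs)) <= p_obs * (1 + 1e-7)])
}

# Hand application of the Benjamini-Yekutieli step-up formula.
byOracle <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  ord <- order(p)
  q_sorted <- p[ord] * m * cm / seq_len(m)
  # step-up: enforce monotone non-increasing from the largest rank down
  q_sorted <- rev(cummin(rev(pmin(q_sorted, 1))))
  out <- numeric(m)
  out[ord] <- q_sorted
  out
}

# Brute-force UMI dedup oracle: precompute the full O(n^2) pairwise
# Levenshtein matrix, then apply the rank-order greedy rule (count
# descending, ties lexicographic; discard when within maxd of any
# already-retained UMI).
dedupOracle <- function(umis, maxd = 3) {
  cnt <- table(umis)
  u <- names(cnt)[order(-as.integer(cnt), names(cnt))]
  D <- utils::adist(u)
  kept_idx <- integer()
  for (i in seq_along(u)) {
    if (length(kept_idx) == 0 || min(D[i, kept_idx]) > maxd)
      kept_idx <- c(kept_idx, i)
  }
  sort(u[kept_idx])
}

# Build read-table rows with sensible defaults.
mkReads <- function(n = 1, read_id = sprintf("r%03d", seq_len(n)),
                    sample_id = "case_1",
                    condition = ifelse(grepl("^case", sample_id),
                                       "case", "control"),
                    cell_type = "neuron", subtype = cell_type,
                    barcode = "BC001", umi = sprintf("UMI%07d", seq_len(n)),
                    gene_id = "G1", chrom = "chr1",
                    read_start = 1L, read_end = 5000L, strand = "+",
                    intron_chain = "") {
  data.frame(read_id = read_id, sample_id = sample_id,
             condition = condition, cell_type = cell_type,
             subtype = subtype, barcode = barcode, umi = umi,
             gene_id = gene_id, chrom = chrom,
             read_start = read_start, read_end = read_end,
             strand = strand, intron_chain = intron_chain,
             stringsAsFactors = FALSE)
}

# A three-exon gene on chr1 used by the classification tests:
# exons 1000-1199, 1500-1699 (the alternative exon), 2100-2299.
threeExonGene <- function() {
  geneModelsFromExons(data.frame(
    gene_id = "G1", transcript_id = "G1.t1", chrom = "chr1",
    start = c(1000L, 1500L, 2100L), end = c(1199L, 1699L, 2299L),
    strand = "+"))
}

threeExonAlt <- function() list(gene_id = "G1", start = 1500L, end = 1699L)

# Chains for the three-exon gene.
CH_INCL <- "1200-1499;1700-2099"   # both flanking junctions
CH_SKIP <- "1200-2099"             # one intron covering exon + flanks

# Random 2x2 tables with margins bounded by mmax.
randomTables <- function(n, mmax = 40) {
  lapply(seq_len(n), function(i) {
    repeat {
      t <- matrix(sample(0:mmax, 4, replace = TRUE), 2)
      t <- matrix(pmin(t, mmax %/% 2), 2)
      if (sum(t) > 0 && all(rowSums(t) <= mmax) && all(colSums(t) <= mmax))
        return(t)
    }
  })
}

# Full small pipeline on a simulated config (shared by several tests).
runSimPipeline <- function(cfg, groupBy = c("cell_type", "condition",
                                            "sample_id")) {
  sim <- simulateDataset(cfg)
  rt <- filterRareChains(dedupUmis(sim$reads))
  ae <- discoverAlternativeExons(rt, cfg$genes$models)
  cnt <- countEvents(rt, ae, groupBy = groupBy)
  list(sim = sim, reads = rt, exons = ae, counts = cnt,
       results = testExons(cnt))
}
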