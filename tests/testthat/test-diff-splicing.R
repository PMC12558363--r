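test_that("psi and delta-psi reproduce the worked percentage shifts", {
  # excitatory neurons: 90% control, 83% case -> -7 percentage points
  expect_equal(deltaPsi(psi(83, 17), psi(90, 10)), -0.07)
  # inhibitory neurons: 90% control, 37% case -> -53 percentage points
  expect_equal(deltaPsi(psi(37, 63), psi(90, 10)), -0.53)
  expect_equal(psi(0, 10), 0)
  expect_true(is.na(psi(0, 0)))
})

test_that("Fisher p matches hypergeometric enumeration, gate follows Cochran", {
  r <- fisherExact2x2(rbind(c(5, 5), c(5, 5)))
  expect_equal(r$p, 1.0)
  expect_true(r$gate)
  r <- fisherExact2x2(rbind(c(3, 0), c(0, 3)))
  expect_equal(r$p, 0.1, tolerance = 1e-12)
  expect_false(r$gate)   # expected counts are all 1.5
  r <- fisherExact2x2(rbind(c(10, 0), c(0, 10)))
  expect_equal(r$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_true(r$gate)    # expected counts are all 5
  # zero margin: undefined p, failed gate
  r <- fisherExact2x2(rbind(c(0, 0), c(3, 4)))
  expect_true(is.na(r$p))
  expect_false(r$gate)
})

test_that("Fisher p agrees with the enumeration oracle on random tables", {
  set.seed(202)
  for (tab in randomTables(300, mmax = 40)) {
    if (sum(tab) == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      next
    p <- fisherExact2x2(tab)$p
    expect_equal(p, fisherOracle(tab[1, 1], tab[1, 2], tab[2, 1],
                                 tab[2, 2]),
                 tolerance = 1e-10)
  }
})

test_that("Fisher p is monotone under integer scaling of the evidence", {
  tab <- rbind(c(8, 2), c(2, 8))
  ps <- vapply(1:4, function(k) fisherExact2x2(tab * k)$p, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("BY adjustment matches the hand step-up formula", {
  # hand case with c(3) = 11/6
  expect_equal(byAdjust(c(0.01, 0.02, 0.9)), c(0.055, 0.055, 1.0),
               tolerance = 1e-12)
  expect_equal(byAdjust(0.2), 0.2)  # c(1) = 1
  set.seed(303)
  for (i in 1:20) {
    p <- runif(sample(2:50, 1))
    q <- byAdjust(p)
    expect_equal(q, byOracle(p), tolerance = 1e-12)
    expect_true(all(q >= p))   # c(m) * m / i >= 1
    # dominates BH elementwise; permutation-invariant after mapping back
    expect_true(all(q >= p.adjust(p, "BH") - 1e-12))
    perm <- sample(length(p))
    expect_equal(byAdjust(p[perm])[order(perm)], q, tolerance = 1e-12)
  }
  expect_error(byAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("sample support filter uses the ceiling two-thirds rule", {
  expect_true(sampleSupportFilter(4, 6, 4, 6))    # 4 = ceiling(2*6/3)
  expect_false(sampleSupportFilter(4, 6, 3, 6))
  expect_true(sampleSupportFilter(6, 6, 6, 6))
})

test_that("sample ordering filter handles direction, swap, and ties", {
  # complete separation, pooled control higher
  expect_true(sampleOrderingFilter(c(0.3, 0.2, 0.1), c(0.9, 0.8, 0.7), 1))
  # pooled control lower: roles swap; each of the 3 cases beats 2 controls
  expect_true(sampleOrderingFilter(c(0.8, 0.7, 0.6), c(0.9, 0.2, 0.1), -1))
  # all ties: strict comparison fails
  expect_false(sampleOrderingFilter(rep(0.5, 3), rep(0.5, 3), 0))
  expect_false(sampleOrderingFilter(rep(0.5, 3), rep(0.5, 3), 1))
  # a group with no informative samples fails
  expect_false(sampleOrderingFilter(numeric(0), c(0.9, 0.8), 1))
})

test_that("coverage filter at the 0.8 boundary", {
  expect_true(coverageFilter(4, 4, 10))    # exactly 0.8
  expect_false(coverageFilter(4, 3, 10))   # 0.7
  expect_true(coverageFilter(5, 5, 10))
  expect_false(coverageFilter(0, 0, 0))    # zero total
})

test_that("testExons applies the full cascade with reasons", {
  # two samples per condition won't matter: build explicit counts
  grid <- expand.grid(condition = c("case", "control"),
                      sample_id = 1:6, stringsAsFactors = FALSE)
  grid$sample_id <- paste0(substr(grid$condition, 1, 4), grid$sample_id)
  mk <- function(gene, incl_case, excl_case, incl_ctrl, excl_ctrl,
                 extra_total = 0) {
    g <- grid
    g$gene_id <- gene; g$chrom <- "chr1"; g$exon_start <- 100L
    g$exon_end <- 200L; g$strand <- "+"; g$source <- "annotated"
    g$cell_type <- "neuron"
    is_case <- g$condition == "case"
    g$inclusion <- ifelse(is_case, incl_case, incl_ctrl) %/% 6
    g$exclusion <- ifelse(is_case, excl_case, excl_ctrl) %/% 6
    g$total <- g$inclusion + g$exclusion + extra_total
    g
  }
  counts <- rbind(
    mk("GBIG", 120, 30, 30, 120),        # strong effect, delta = +0.6
    mk("GSMALL", 66, 54, 54, 66),        # delta = +0.1 < 0.2
    mk("GPOOR", 120, 30, 30, 120, extra_total = 40))  # coverage 0.79
  res <- testExons(counts)
  big <- res[res$gene_id == "GBIG", ]
  expect_true(big$significant)
  expect_equal(big$delta_psi, 0.6, tolerance = 1e-12)
  small <- res[res$gene_id == "GSMALL", ]
  expect_false(small$significant)       # q may pass but delta fails
  expect_true(small$eligible)
  poor <- res[res$gene_id == "GPOOR", ]
  expect_false(poor$pass_coverage)
  expect_false(poor$eligible)           # excluded from the BY family
  expect_true(is.na(poor$q_by))
  # BY family = eligible exons only
  expect_equal(sum(!is.na(res$q_by)), 2)
})

test_that("pooled psi bounds and minimum reads gate eligibility", {
  grid <- expand.grid(condition = c("case", "control"),
                      sample_id = paste0("s", 1:6),
                      stringsAsFactors = FALSE)
  base <- cbind(grid, gene_id = "G", chrom = "chr1", exon_start = 1L,
                exon_end = 2L, strand = "+", source = "annotated",
                cell_type = "neuron")
  # psi pooled ~0.97: outside [0.05, 0.95]
  hi <- base; hi$inclusion <- 20L; hi$exclusion <- 0L
  hi$exclusion[1] <- 4L; hi$total <- hi$inclusion + hi$exclusion
  res <- testExons(hi)
  expect_false(res$pass_psi_range)
  # fewer than 10 informative reads per condition
  lo <- base; lo$inclusion <- 0L; lo$exclusion <- 0L; lo$total <- 0L
  lo$inclusion[lo$condition == "case"] <- 1L
  lo$exclusion[lo$condition == "control"] <- 1L
  lo$total <- lo$inclusion + lo$exclusion
  res2 <- testExons(lo)
  expect_false(res2$pass_min_reads)
  expect_false(res2$significant)
})

test_that("age-matched check retains, fails, and flags sign flips", {
  grid <- expand.grid(condition = c("case", "control"),
                      sample_id = 1:6, stringsAsFactors = FALSE)
  grid$sample_id <- paste0(substr(grid$condition, 1, 4), grid$sample_id)
  ages <- setNames(c(56, 62, 66, 70, 74, 77, 71, 75, 78, 80, 84, 85),
                   c(paste0("case", 1:6), paste0("cont", 1:6)))
  mkc <- function(incl_case_per_sample) {
    g <- grid
    g$gene_id <- "G"; g$chrom <- "chr1"; g$exon_start <- 1L
    g$exon_end <- 2L; g$strand <- "+"; g$source <- "annotated"
    g$cell_type <- "neuron"
    is_case <- g$condition == "case"
    g$inclusion <- ifelse(is_case, incl_case_per_sample, 10L)
    g$exclusion <- ifelse(is_case, 20L - incl_case_per_sample, 10L)
    g$total <- g$inclusion + g$exclusion
    g
  }
  # uniform counts: subset delta equals full delta -> pass
  counts <- mkc(16L)     # case psi 0.8, control 0.5, delta +0.3
  res <- testExons(counts)
  res2 <- ageMatchedCheck(res, counts, ages)
  expect_true(res2$pass_age_match)
  expect_equal(res2$delta_psi_agematched, res2$delta_psi,
               tolerance = 1e-12)

  # effect carried only by samples far from the matched ages: the
  # age-matched subset (cases aged 66-77) loses most of the signal
  g <- mkc(10L)
  young <- g$sample_id %in% c("case1", "case2") & g$condition == "case"
  g$inclusion[young] <- 20L; g$exclusion[young] <- 0L
  res3 <- testExons(g)
  res4 <- ageMatchedCheck(res3, g, ages)
  expect_true(abs(res4$delta_psi_agematched) <
              0.5 * abs(res4$delta_psi))
  expect_false(res4$pass_age_match)
})

test_that("age-match retention boundary sits at exactly 50%", {
  # with these ages the matched subset is cases 3-6 (mean 71.75) and
  # controls 1-4 (mean 76): construct counts whose subset delta is
  # exactly half the full delta (0.15 vs 0.30) -> boundary pass
  grid <- expand.grid(condition = c("case", "control"),
                      sample_id = 1:6, stringsAsFactors = FALSE)
  grid$sample_id <- paste0(substr(grid$condition, 1, 4), grid$sample_id)
  ages <- setNames(c(56, 62, 66, 70, 74, 77, 71, 75, 78, 80, 84, 85),
                   c(paste0("case", 1:6), paste0("cont", 1:6)))
  mk_counts <- function(incl_sub) {
    g <- grid
    g$gene_id <- "G"; g$chrom <- "chr1"; g$exon_start <- 1L
    g$exon_end <- 2L; g$strand <- "+"; g$source <- "annotated"
    g$cell_type <- "neuron"
    g$inclusion <- 8L                                   # controls: psi 0.4
    g$inclusion[g$condition == "case"] <- incl_sub      # subset cases
    g$inclusion[g$sample_id %in% c("case1", "case2")] <- 20L
    g$exclusion <- 20L - g$inclusion
    g$total <- 20L
    g
  }
  counts <- mk_counts(11L)   # full delta 0.30, subset delta 0.15
  res <- ageMatchedCheck(testExons(counts), counts, ages)
  expect_equal(res$delta_psi, 0.30, tolerance = 1e-12)
  expect_equal(res$delta_psi_agematched, 0.15, tolerance = 1e-12)
  expect_true(res$pass_age_match)
  counts2 <- mk_counts(10L)  # subset delta 0.10 < half of 0.30
  res2 <- ageMatchedCheck(testExons(counts2), counts2, ages)
  expect_false(res2$pass_age_match)
  counts3 <- mk_counts(4L)   # subset delta -0.20 against a positive full
  res3 <- ageMatchedCheck(testExons(counts3), counts3, ages)
  expect_equal(res3$delta_psi_agematched, -0.20, tolerance = 1e-12)
  expect_false(res3$pass_age_match)  # sign flip
})
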