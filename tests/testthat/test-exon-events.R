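# The three-exon fixture gene: alternative exon 1500-1699, flanking
# introns 1200-1499 and 1700-2099.

test_that("read classification follows the inclusion/exclusion rules", {
  exon <- threeExonAlt()
  # full-length read with both flanking junctions -> inclusion
  expect_equal(classifyReads(mkReads(1, intron_chain = CH_INCL), exon),
               "inclusion")
  # single junction spanning exon plus >= 50 bases both sides -> exclusion
  expect_equal(classifyReads(mkReads(1, intron_chain = CH_SKIP), exon),
               "exclusion")
  # skipping intron starting only 30 bases upstream of the exon:
  # flank rule violated -> uninformative
  expect_equal(classifyReads(mkReads(1, intron_chain = "1470-2099"), exon),
               "uninformative")
  # read not reaching the exon
  expect_equal(classifyReads(
    mkReads(1, read_end = 1300L, intron_chain = ""), exon),
    "non_overlapping")
  # truncated read starting inside the exon, supporting the downstream
  # splice site -> inclusion (clause ii)
  expect_equal(classifyReads(
    mkReads(1, read_start = 1600L, intron_chain = "1700-2099"), exon),
    "inclusion")
  # truncated read ending inside the exon with no adjacent junction:
  # degraded end must not vote
  expect_equal(classifyReads(
    mkReads(1, read_start = 1600L, read_end = 3000L, intron_chain = ""),
    exon),
    "uninformative")
  # skipping via two stacked junctions (an intervening exon inside the
  # downstream flank) -> uninformative
  expect_equal(classifyReads(
    mkReads(1, intron_chain = "1200-1710;1740-2099"), exon),
    "uninformative")
  # gene mismatch is an error
  expect_error(classifyReads(mkReads(1, gene_id = "G2"), exon),
               "gene")
})

test_that("classification is mutually exclusive and exhaustive", {
  set.seed(11)
  exon <- threeExonAlt()
  chains <- c("", CH_INCL, CH_SKIP, "1200-1499", "1700-2099",
              "1200-1760;1790-2099", "1470-2099", "1200-2400")
  starts <- sample(c(1L, 1300L, 1550L, 1701L), 40, replace = TRUE)
  ends <- starts + sample(c(200L, 1000L, 4000L), 40, replace = TRUE)
  for (ch in chains) {
    df <- mkReads(length(starts), read_start = starts,
                  read_end = pmax(ends, starts + 1L), intron_chain = ch)
    df <- suppressWarnings(readTable(df, lenient = TRUE))
    if (nReads(df) == 0) next
    cls <- classifyReads(df, exon)
    expect_true(all(cls %in% c("inclusion", "exclusion", "uninformative",
                               "non_overlapping")))
  }
})

test_that("event counting tallies totals and respects grouping", {
  exon_gr <- internalExons(threeExonGene())
  df <- rbind(
    mkReads(4, read_id = sprintf("i%d", 1:4), intron_chain = CH_INCL),
    mkReads(4, read_id = sprintf("e%d", 1:4), intron_chain = CH_SKIP),
    mkReads(2, read_id = sprintf("u%d", 1:2), intron_chain = "1470-2099"),
    mkReads(3, read_id = sprintf("n%d", 1:3), read_end = 1300L,
            sample_id = "ctrl_1"))
  cnt <- countEvents(readTable(df), exon_gr)
  case_row <- cnt[cnt$condition == "case", ]
  expect_equal(case_row$inclusion, 4)
  expect_equal(case_row$exclusion, 4)
  expect_equal(case_row$total, 10)   # uninformative counted in total
  # group with no overlapping reads still reported, all-zero
  ctrl_row <- cnt[cnt$condition == "control", ]
  expect_equal(nrow(ctrl_row), 1)
  expect_equal(ctrl_row$total, 0)
  # per-sample counts sum to per-condition counts
  cnt_s <- countEvents(readTable(df), exon_gr,
                       groupBy = c("cell_type", "condition", "sample_id"))
  agg <- aggregate(cbind(inclusion, exclusion, total) ~ condition,
                   cnt_s, sum)
  expect_equal(agg$total[agg$condition == "case"], 10)
  expect_true(all(cnt$inclusion + cnt$exclusion <= cnt$total))
})

test_that("alternative-exon discovery needs both behaviors", {
  gm <- threeExonGene()
  # all reads include the middle exon: never excluded -> not alternative
  rt_incl <- readTable(mkReads(6, intron_chain = CH_INCL))
  expect_equal(length(discoverAlternativeExons(rt_incl, gm)), 0)
  # 50/50 split: reported as annotated
  rt_mix <- readTable(mkReads(6, intron_chain = rep(c(CH_INCL, CH_SKIP), 3)))
  ae <- discoverAlternativeExons(rt_mix, gm)
  expect_equal(length(ae), 1)
  expect_equal(S4Vectors::mcols(ae)$source, "annotated")
  expect_equal(GenomicRanges::start(ae), 1500L)
})

test_that("unannotated (cryptic) exons are discovered from read chains", {
  gm <- threeExonGene()
  # a cryptic exon 1800-1899 inside the downstream intron, seen flanked in
  # two reads and skipped in the others
  ch_cryptic <- "1200-1499;1700-1799;1900-2099"
  df <- rbind(
    mkReads(2, read_id = c("c1", "c2"), intron_chain = ch_cryptic),
    mkReads(4, read_id = sprintf("k%d", 1:4), intron_chain = CH_INCL))
  ae <- discoverAlternativeExons(readTable(df), gm)
  obs <- ae[S4Vectors::mcols(ae)$source == "observed"]
  expect_equal(GenomicRanges::start(obs), 1800L)
  expect_equal(GenomicRanges::end(obs), 1899L)
  # with only one supporting read the candidate is suppressed
  ae1 <- discoverAlternativeExons(readTable(df[-1, ]), gm)
  expect_equal(sum(S4Vectors::mcols(ae1)$source == "observed"), 0)
})

test_that("psi estimates converge to the planted inclusion probability", {
  cfg <- simConfig(genes = simGenes(nGenes = 1),
                   cellTypes = c(neuron = 15L),
                   plantedPsi = data.frame(gene_id = "G0001",
                     cell_type = "neuron", psi_case = 0.5,
                     psi_control = 0.5),
                   readsPerCellMean = 12, psiJitterConc = 1e6, seed = 21)
  out <- runSimPipeline(cfg)
  res <- out$results
  n <- res$incl_case + res$excl_case
  expect_gte(n, 1000)
  # 99% binomial interval around the planted 0.5
  half <- qnorm(0.995) * sqrt(0.25 / n)
  expect_lt(abs(res$psi_case - 0.5), half)
})
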