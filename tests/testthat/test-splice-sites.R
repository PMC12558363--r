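# Hand-built intron-count fixtures: donor groups share an acceptor and
# differ in donor; counts carry (condition, sample) labels.
mkIntronCounts <- function(sites, counts_case, counts_ctrl,
                           fixed_acceptor = 2000L, gene = "G1",
                           strand = "+") {
  rows <- list()
  for (i in seq_along(sites)) {
    rows[[length(rows) + 1]] <- data.frame(gene_id = gene, chrom = "chr1",
      intron_start = if (strand == "+") sites[i] else fixed_acceptor,
      intron_end = if (strand == "+") fixed_acceptor else sites[i],
      strand = strand, cell_type = "neuron", condition = "case",
      sample_id = "case_1", count = counts_case[i])
    rows[[length(rows) + 1]] <- data.frame(gene_id = gene, chrom = "chr1",
      intron_start = if (strand == "+") sites[i] else fixed_acceptor,
      intron_end = if (strand == "+") fixed_acceptor else sites[i],
      strand = strand, cell_type = "neuron", condition = "control",
      sample_id = "ctrl_1", count = counts_ctrl[i])
  }
  df <- do.call(rbind, rows)
  df[df$count > 0, ]
}

test_that("site grouping collects alternatives sharing the fixed end", {
  ic <- mkIntronCounts(c(1000L, 1200L), c(30, 10), c(20, 20))
  gr <- groupSpliceSites(ic)
  expect_setequal(unique(gr$kind[gr$fixed_pos == 2000]), "donor")
  expect_equal(length(unique(gr$site_pos[gr$kind == "donor"])), 2)
  # a unique intron forms no group
  solo <- mkIntronCounts(1000L, 5, 5)
  expect_equal(nrow(groupSpliceSites(solo)), 0)
  # three donors for one acceptor: one group with 3 sites
  tri <- mkIntronCounts(c(1000L, 1200L, 1400L), c(30, 10, 5), c(20, 20, 5))
  g3 <- groupSpliceSites(tri)
  expect_equal(length(unique(g3$site_pos[g3$kind == "donor"])), 3)
  # strand-awareness: on the minus strand the donor is the intron end
  neg <- mkIntronCounts(c(3000L, 3200L), c(10, 10), c(10, 10),
                        fixed_acceptor = 2000L, strand = "-")
  gn <- groupSpliceSites(neg)
  expect_setequal(gn$site_pos[gn$kind == "donor"], c(3000L, 3200L))
})

test_that("site test computes top-two psi and the discard rules", {
  # top = 1000 (total 50), second = 1200 (total 30); case psi 30/40
  ic <- mkIntronCounts(c(1000L, 1200L), c(30, 10), c(20, 20))
  res <- testSiteGroups(groupSpliceSites(ic))
  donor <- res[res$kind == "donor", ]
  expect_equal(donor$top_site, 1000L)
  expect_equal(donor$psi_case, 0.75)
  expect_equal(donor$psi_control, 0.5)
  expect_true(donor$retained)

  # totals {40, 30, 20, 10}: top-two table total 70 < 0.8 * 100 -> discard
  ic2 <- mkIntronCounts(c(1000L, 1200L, 1400L, 1600L),
                        c(20, 15, 10, 5), c(20, 15, 10, 5))
  res2 <- testSiteGroups(groupSpliceSites(ic2))
  expect_false(res2$retained[res2$kind == "donor"])

  # no counts for cases in the top-two table -> discard
  ic3 <- mkIntronCounts(c(1000L, 1200L), c(0, 0), c(20, 20))
  res3 <- testSiteGroups(groupSpliceSites(ic3))
  expect_false(res3$retained[res3$kind == "donor"])
})

test_that("equal site totals break ties toward the lower coordinate", {
  ic <- mkIntronCounts(c(1500L, 1100L), c(10, 12), c(12, 10))
  res <- testSiteGroups(groupSpliceSites(ic))
  donor <- res[res$kind == "donor", ]
  expect_equal(donor$top_site, 1100L)
})

test_that("planted donor-usage shifts are recovered from reads", {
  g <- simGenes(nGenes = 3)
  su <- data.frame(gene_id = g$genes$gene_id, usage_case = 0.8,
                   usage_control = 0.5)
  cfg <- simConfig(genes = g, cellTypes = c(neuron = 10L), siteUsage = su,
                   readsPerCellMean = 10, seed = 17)
  sim <- simulateDataset(cfg)
  rt <- filterRareChains(dedupUmis(sim$reads))
  res <- testSiteGroups(groupSpliceSites(intronCounts(rt)))
  donors <- res[res$kind == "donor" &
                res$fixed_pos %in% g$genes$donor_fixed_acceptor, ]
  expect_equal(nrow(donors), 3)
  expect_true(all(donors$top_site == g$genes$donor_main[
    match(donors$gene_id, g$genes$gene_id)]))
  # planted usage shift 0.3 shows up as delta psi near 0.3
  expect_true(all(abs(donors$delta_psi - 0.3) < 0.08))
  expect_true(all(donors$significant))
})

test_that("null site usage stays largely non-significant", {
  g <- simGenes(nGenes = 10)
  su <- data.frame(gene_id = g$genes$gene_id, usage_case = 0.6,
                   usage_control = 0.6)
  cfg <- simConfig(genes = g, cellTypes = c(neuron = 8L), siteUsage = su,
                   readsPerCellMean = 4, seed = 19)
  sim <- simulateDataset(cfg)
  rt <- filterRareChains(dedupUmis(sim$reads))
  res <- testSiteGroups(groupSpliceSites(intronCounts(rt)))
  keep <- res[res$retained, ]
  expect_lte(mean(keep$significant), 0.05)
})
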