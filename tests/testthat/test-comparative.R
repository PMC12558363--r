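mkRes <- function(gene, delta, sig, cell_type = "neuron",
                  eligible = TRUE) {
  data.frame(cell_type = cell_type, gene_id = gene, chrom = "chr1",
             exon_start = seq_along(gene) * 100L,
             exon_end = seq_along(gene) * 100L + 50L, strand = "+",
             delta_psi = delta, significant = sig, eligible = eligible,
             stringsAsFactors = FALSE)
}

test_that("Wilson interval matches the closed form", {
  ci <- wilsonCI(2, 10)
  z <- qnorm(0.975)
  denom <- 1 + z^2 / 10
  center <- (0.2 + z^2 / 20) / denom
  half <- z * sqrt(0.2 * 0.8 / 10 + z^2 / 400) / denom
  expect_equal(unname(ci["estimate"]), 0.2)
  expect_equal(unname(ci["lower"]), center - half, tolerance = 1e-12)
  expect_equal(unname(ci["upper"]), center + half, tolerance = 1e-12)
  expect_true(ci["lower"] <= ci["estimate"] &&
              ci["estimate"] <= ci["upper"])
})

test_that("masking counts cell-type calls missing from pseudobulk", {
  ct <- mkRes(sprintf("g%d", 1:10), rep(0.5, 10), rep(TRUE, 10))
  pb <- mkRes(sprintf("g%d", 1:9), rep(0.5, 9),
              c(rep(TRUE, 8), FALSE), cell_type = "pseudobulk")
  mk <- pseudobulkMasking(ct, pb)
  # g9 not significant in pseudobulk, g10 untested there: both masked
  expect_equal(mk$n_significant, 10)
  expect_equal(mk$n_masked, 2)
  expect_equal(mk$n_untested_pseudobulk, 1)
  expect_equal(mk$fraction_masked, 0.2)
  wc <- wilsonCI(2, 10)
  expect_equal(mk$ci_lower, unname(wc["lower"]))
  # all significant in both -> fraction 0
  mk0 <- pseudobulkMasking(ct, mkRes(sprintf("g%d", 1:10), rep(0.5, 10),
                                     rep(TRUE, 10), "pseudobulk"))
  expect_equal(mk0$n_masked, 0)
  # row order does not matter
  mk_shuf <- pseudobulkMasking(ct[sample(10), ], pb[sample(9), ])
  expect_equal(mk_shuf$n_masked, mk$n_masked)
})

test_that("pseudobulk over a single cell type reproduces its calls", {
  cfg <- simConfig(genes = simGenes(nGenes = 8),
                   cellTypes = c(neuron = 8L),
                   plantedPsi = data.frame(gene_id = "G0001",
                     cell_type = "neuron", psi_case = 0.8,
                     psi_control = 0.2),
                   readsPerCellMean = 4, seed = 23)
  out <- runSimPipeline(cfg)
  pb <- testExons(pseudobulkCounts(out$counts))
  key <- function(d) paste(d$gene_id, d$exon_start)
  m <- match(key(out$results), key(pb))
  expect_equal(pb$significant[m], out$results$significant)
  expect_equal(pb$delta_psi[m], out$results$delta_psi)
  mk <- pseudobulkMasking(out$results, pb)
  if (mk$n_significant > 0) expect_equal(mk$fraction_masked, 0)
})

test_that("delta-psi correlation handles identity and degenerate input", {
  a <- mkRes(sprintf("g%d", 1:6), c(0.5, -0.3, 0.2, 0.4, -0.1, 0.25),
             rep(TRUE, 6))
  expect_equal(deltaPsiCorrelation(a, a)$r, 1)
  b <- a; b$delta_psi <- rep(0.2, 6)
  expect_true(is.na(deltaPsiCorrelation(a, b)$r))
  expect_match(deltaPsiCorrelation(a, b)$reason, "variance")
  expect_true(is.na(deltaPsiCorrelation(a[1:2, ], a[1:2, ])$r))
})

test_that("correlation estimates cover the generating coefficient", {
  set.seed(404)
  rho <- 0.75
  n <- 200
  cover <- replicate(250, {
    z <- matrix(rnorm(2 * n), ncol = 2)
    x <- z[, 1]
    y <- rho * z[, 1] + sqrt(1 - rho^2) * z[, 2]
    a <- mkRes(sprintf("g%d", 1:n), x, rep(TRUE, n))
    b <- mkRes(sprintf("g%d", 1:n), y, rep(TRUE, n))
    r <- deltaPsiCorrelation(a, b)
    r$ci_lower <= rho && rho <= r$ci_upper
  })
  expect_gte(mean(cover), 0.93)
})

test_that("expression overlap builds the table over the tested universe", {
  # table [[5,5],[10,80]] -> OR 8
  universe <- sprintf("g%d", 1:100)
  spliced <- sprintf("g%d", 1:10)
  de <- data.frame(gene_id = c(sprintf("g%d", 1:5),
                               sprintf("g%d", 11:20), "outside1"),
                   log2FC = 1, fdr = 0.01)
  ov <- expressionOverlap(spliced, de, universe)
  expect_equal(c(ov$n_both, ov$n_spliced_only, ov$n_de_only,
                 ov$n_neither), c(5, 5, 10, 80))
  expect_equal(ov$odds_ratio, 8)
  expect_false(ov$zero_cell)
  # DE thresholds |log2FC| >= 0.1 and FDR <= 0.05 are enforced
  de2 <- data.frame(gene_id = sprintf("g%d", 11:20),
                    log2FC = c(rep(0.05, 5), rep(-0.2, 5)),
                    fdr = c(rep(0.01, 5), rep(0.2, 5)))
  ov2 <- expressionOverlap(spliced, de2, universe)
  expect_equal(ov2$n_de_only, 0)
  # zero cell: corrected OR reported and flagged
  ov3 <- expressionOverlap(character(0), de, universe)
  expect_true(is.na(ov3$odds_ratio) || ov3$odds_ratio == 0)
  expect_true(ov3$zero_cell)
  expect_false(is.na(ov3$odds_ratio_corrected))
  expect_error(expressionOverlap(spliced, de, character(0)), "universe")
})

test_that("overlap odds ratio is centered near 1 for independent sets", {
  set.seed(505)
  universe <- sprintf("g%d", 1:500)
  ors <- replicate(200, {
    spliced <- sample(universe, 50)
    de_genes <- sample(universe, 100)
    de <- data.frame(gene_id = de_genes, log2FC = 1, fdr = 0.01)
    expressionOverlap(spliced, de, universe)$odds_ratio
  })
  expect_true(median(ors) >= 0.8 && median(ors) <= 1.25)
})
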