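#' Build a synthetic gene set for simulation
#'
#' Creates `nGenes` plus-strand genes on one chromosome, each with
#' `exonsPerGene` exons; the middle exon (`altExonIndex`) is the
#' alternative exon whose inclusion is planted per (cell type,
#' condition). Introns are long enough (default 400 bases) that the
#' skipping intron always covers the exon plus at least 50 bases of
#' flank. Optionally the first intron carries an alternative donor site
#' (`altDonorShift` bases downstream of the canonical donor) so that
#' splice-site usage can be planted.
#'
#' @param nGenes Number of genes.
#' @param exonsPerGene Exons per gene (>= 3; default 5).
#' @param exonLength,intronLength Exon and intron sizes in bases
#'   (defaults 150 and 400).
#' @param altExonIndex Index of the alternative exon (default 3).
#' @param altDonorShift Offset of the alternative donor of intron 1
#'   (default 12 bases).
#' @return A list of class `simGenes`: `models` ([GeneModels]), `genes`
#'   (`data.frame` with per-gene structure: alt-exon coordinates, the
#'   flanking/skipping introns, and donor-site coordinates).
#' @export
simGenes <- function(nGenes = 20L, exonsPerGene = 5L, exonLength = 150L,
                     intronLength = 400L, altExonIndex = 3L,
                     altDonorShift = 12L) {
  stopifnot(exonsPerGene >= 3, altExonIndex > 1,
            altExonIndex < exonsPerGene, intronLength >= 150)
  gene_span <- exonsPerGene * exonLength +
    (exonsPerGene - 1) * intronLength
  gap <- 10000L
  rows <- list()
  info <- list()
  for (g in seq_len(nGenes)) {
    gid <- sprintf("G%04d", g)
    gstart <- (g - 1L) * (gene_span + gap) + 1L
    ex_start <- gstart + (seq_len(exonsPerGene) - 1L) *
      (exonLength + intronLength)
    ex_end <- ex_start + exonLength - 1L
    rows[[g]] <- data.frame(gene_id = gid, transcript_id = paste0(gid, ".t1"),
      chrom = "chrS", start = ex_start, end = ex_end, strand = "+",
      stringsAsFactors = FALSE)
    k <- altExonIndex
    info[[g]] <- data.frame(gene_id = gid, chrom = "chrS", strand = "+",
      gene_start = ex_start[1], gene_end = ex_end[exonsPerGene],
      alt_start = ex_start[k], alt_end = ex_end[k],
      skip_intron_start = ex_end[k - 1] + 1L,
      skip_intron_end = ex_start[k + 1] - 1L,
      donor_main = ex_end[1] + 1L,
      donor_alt = ex_end[1] + 1L + altDonorShift,
      donor_fixed_acceptor = ex_start[2] - 1L,
      stringsAsFactors = FALSE)
  }
  exons <- do.call(rbind, rows)
  structure(list(models = geneModelsFromExons(exons),
                 genes = do.call(rbind, info),
                 exonsPerGene = exonsPerGene),
            class = "simGenes")
}

#' Simulation configuration
#'
#' Describes a synthetic case-control single-nucleus long-read dataset
#' emulating a 6-case / 6-control, multi-cell-type design: per-sample
#' cell counts per cell type, per-(gene, cell type, condition) planted
#' exon-inclusion probabilities, optional planted donor-site usage,
#' negative-binomial read depth per (cell, gene), per-sample Ψ jitter,
#' and UMI noise.
#'
#' @param genes A [simGenes()] gene set.
#' @param nCaseSamples,nControlSamples Samples per group (defaults 6/6).
#' @param cellTypes Named integer vector: cells per sample per cell type.
#' @param plantedPsi `data.frame` with columns `gene_id`, `cell_type`,
#'   `psi_case`, `psi_control`; genes/cell types not listed default to
#'   0.5 / 0.5 (no planted effect).
#' @param siteUsage Optional `data.frame` with columns `gene_id`,
#'   `usage_case`, `usage_control`: probability that a read uses the
#'   canonical donor of intron 1 (the rest use the alternative donor).
#'   Empty by default.
#' @param readsPerCellMean,readsPerCellSize Negative-binomial mean and
#'   dispersion (size) of the read count per (cell, gene); defaults 2 and
#'   2.
#' @param psiJitterConc Beta concentration of the per-sample deviation
#'   around the planted group Ψ (sample Ψ ~ Beta(c·Ψ, c·(1−Ψ));
#'   default 300, i.e. sd ≈ 0.03 at Ψ = 0.5).
#' @param umiLength UMI length in bases (default 10).
#' @param umiErrorRate Per-read probability that the UMI is mutated
#'   (default 0; see [injectUmiNoise()]).
#' @param ages Optional named numeric vector of per-sample ages; defaults
#'   emulate an older control group (means 67.5 case / 78.8 control).
#' @param seed Random seed; a fixed seed makes the output byte-identical.
#' @return A named list of class `SimConfig`.
#' @export
simConfig <- function(genes = simGenes(),
                      nCaseSamples = 6L, nControlSamples = 6L,
                      cellTypes = c(excitatory = 30L, inhibitory = 15L,
                                    astrocyte = 15L,
                                    oligodendrocyte = 10L, microglia = 5L),
                      plantedPsi = NULL, siteUsage = NULL,
                      readsPerCellMean = 2, readsPerCellSize = 2,
                      psiJitterConc = 300, umiLength = 10L,
                      umiErrorRate = 0, ages = NULL, seed = 1L) {
  stopifnot(inherits(genes, "simGenes"), nCaseSamples >= 1,
            nControlSamples >= 1, length(cellTypes) >= 1,
            !is.null(names(cellTypes)),
            readsPerCellMean > 0, readsPerCellSize > 0,
            psiJitterConc > 0, umiLength >= 4,
            umiErrorRate >= 0, umiErrorRate <= 1)
  samples <- data.frame(
    sample_id = c(sprintf("case_%d", seq_len(nCaseSamples)),
                  sprintf("ctrl_%d", seq_len(nControlSamples))),
    condition = rep(c("case", "control"),
                    c(nCaseSamples, nControlSamples)),
    stringsAsFactors = FALSE)
  if (is.null(ages)) {
    age_case <- c(56, 62, 66, 70, 74, 77)
    age_ctrl <- c(71, 75, 78, 80, 84, 85)
    ages <- c(rep_len(age_case, nCaseSamples),
              rep_len(age_ctrl, nControlSamples))
    names(ages) <- samples$sample_id
  }
  grid <- expand.grid(gene_id = genes$genes$gene_id,
                      cell_type = names(cellTypes),
                      stringsAsFactors = FALSE)
  grid$psi_case <- 0.5
  grid$psi_control <- 0.5
  if (!is.null(plantedPsi)) {
    stopifnot(all(c("gene_id", "cell_type", "psi_case", "psi_control")
                  %in% colnames(plantedPsi)))
    if (any(plantedPsi$psi_case < 0 | plantedPsi$psi_case > 1 |
            plantedPsi$psi_control < 0 | plantedPsi$psi_control > 1))
      stop("planted inclusion probabilities must lie in [0, 1]")
    m <- match(paste(grid$gene_id, grid$cell_type),
               paste(plantedPsi$gene_id, plantedPsi$cell_type))
    hit <- !is.na(m)
    grid$psi_case[hit] <- plantedPsi$psi_case[m[hit]]
    grid$psi_control[hit] <- plantedPsi$psi_control[m[hit]]
  }
  if (!is.null(siteUsage)) {
    stopifnot(all(c("gene_id", "usage_case", "usage_control")
                  %in% colnames(siteUsage)))
    if (any(siteUsage$usage_case < 0 | siteUsage$usage_case > 1 |
            siteUsage$usage_control < 0 | siteUsage$usage_control > 1))
      stop("site-usage probabilities must lie in [0, 1]")
  }
  structure(list(genes = genes, samples = samples,
                 cellTypes = cellTypes, plantedPsi = grid,
                 siteUsage = siteUsage,
                 readsPerCellMean = readsPerCellMean,
                 readsPerCellSize = readsPerCellSize,
                 psiJitterConc = psiJitterConc,
                 umiLength = as.integer(umiLength),
                 umiErrorRate = umiErrorRate,
                 ages = ages, seed = as.integer(seed)),
            class = "SimConfig")
}

#' Read a simulation configuration from YAML
#'
#' Scalar fields map directly to [simConfig()] arguments; `genes` is a
#' mapping of [simGenes()] arguments; `cellTypes` a mapping of cell type
#' to cells per sample; `plantedPsi` and `siteUsage` lists of records.
#'
#' @param path YAML file.
#' @return A `SimConfig`.
#' @export
readSimConfigYaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$genes)) args$genes <- do.call(simGenes, y$genes)
  for (f in c("nCaseSamples", "nControlSamples", "readsPerCellMean",
              "readsPerCellSize", "psiJitterConc", "umiLength",
              "umiErrorRate", "seed"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  if (!is.null(y$cellTypes)) args$cellTypes <- unlist(y$cellTypes)
  if (!is.null(y$plantedPsi))
    args$plantedPsi <- do.call(rbind, lapply(y$plantedPsi, as.data.frame))
  if (!is.null(y$siteUsage))
    args$siteUsage <- do.call(rbind, lapply(y$siteUsage, as.data.frame))
  if (!is.null(y$ages)) args$ages <- unlist(y$ages)
  do.call(simConfig, args)
}

#' Simulate a read table with planted ground truth
#'
#' For every cell of every sample and cell type, read counts per gene are
#' drawn from a negative binomial; each read either includes the gene's
#' alternative exon (with the per-sample jittered planted probability for
#' its cell type and condition) or carries the skipping junction whose
#' intron covers the exon plus both flanks. Genes with planted donor
#' usage emit the canonical or alternative donor of intron 1 per read.
#' Every read receives a UMI unique within its (barcode, gene) group
#' (pairwise Levenshtein distance > 3, so noise-free data survive
#' deduplication unchanged); UMI noise is then injected at
#' `umiErrorRate`.
#'
#' @param config A [simConfig()].
#' @return A list with elements `reads` (a [ReadTable]) and `truth` (a
#'   [SimTruth]).
#' @export
simulateDataset <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  gi <- config$genes$genes
  n_genes <- nrow(gi)
  samples <- config$samples
  ct_names <- names(config$cellTypes)

  # Chain templates per gene: inclusion / skipping x canonical / alt donor.
  chains <- geneChainTemplates(config$genes)

  # Per-(sample, cell type, gene) jittered inclusion probability.
  planted <- config$plantedPsi
  pk <- paste(planted$gene_id, planted$cell_type)

  blocks <- list()
  for (si in seq_len(nrow(samples))) {
    cond <- samples$condition[si]
    for (ct in ct_names) {
      n_cells <- config$cellTypes[[ct]]
      if (n_cells < 1) next
      p_group <- planted[[if (cond == "case") "psi_case" else
                          "psi_control"]][
        match(paste(gi$gene_id, ct), pk)]
      p_sample <- jitterPsi(p_group, config$psiJitterConc)
      n_rc <- stats::rnbinom(n_cells * n_genes,
                             mu = config$readsPerCellMean,
                             size = config$readsPerCellSize)
      if (sum(n_rc) == 0) next
      cell_idx <- rep(rep(seq_len(n_cells), each = n_genes), n_rc)
      gene_idx <- rep(rep(seq_len(n_genes), times = n_cells), n_rc)
      n_reads <- length(gene_idx)
      incl <- stats::rbinom(n_reads, 1, p_sample[gene_idx]) == 1
      alt_donor <- rep(FALSE, n_reads)
      if (!is.null(config$siteUsage)) {
        su <- config$siteUsage
        mu_ <- match(gi$gene_id[gene_idx], su$gene_id)
        has <- !is.na(mu_)
        u <- su[[if (cond == "case") "usage_case" else
                 "usage_control"]][mu_[has]]
        alt_donor[has] <- stats::rbinom(sum(has), 1, 1 - u) == 1
      }
      chain_col <- 1L + (!incl) * 1L + alt_donor * 2L
      blocks[[length(blocks) + 1]] <- data.table::data.table(
        sample_id = samples$sample_id[si], condition = cond,
        cell_type = ct, subtype = ct,
        barcode = sprintf("%s.%s.BC%04d", samples$sample_id[si], ct,
                          cell_idx),
        gene_id = gi$gene_id[gene_idx], chrom = gi$chrom[gene_idx],
        read_start = gi$gene_start[gene_idx],
        read_end = gi$gene_end[gene_idx],
        strand = gi$strand[gene_idx],
        intron_chain = chains[cbind(gene_idx, chain_col)])
    }
  }
  dt <- data.table::rbindlist(blocks)
  if (nrow(dt) == 0) stop("simulation produced no reads; increase depth")
  dt$read_id <- sprintf("r%08d", seq_len(nrow(dt)))
  umi <- barcode <- gene_id <- NULL
  dt[, umi := groupUniqueUmis(.N, config$umiLength),
     by = .(barcode, gene_id)]
  truth_umi <- data.frame(read_id = dt$read_id, true_umi = dt$umi,
                          stringsAsFactors = FALSE)
  rt <- readTable(as.data.frame(dt)[, READ_TABLE_COLUMNS],
                  validateChains = FALSE)
  if (config$umiErrorRate > 0)
    rt <- injectUmiNoise(rt, config$umiErrorRate)

  exon_truth <- merge(planted,
    gi[, c("gene_id", "chrom", "strand", "alt_start", "alt_end")],
    by = "gene_id")
  exon_truth$delta_psi <- exon_truth$psi_case - exon_truth$psi_control
  site_truth <- if (is.null(config$siteUsage)) {
    data.frame()
  } else {
    st <- merge(config$siteUsage,
      gi[, c("gene_id", "donor_main", "donor_alt",
             "donor_fixed_acceptor")], by = "gene_id")
    st$delta_usage <- st$usage_case - st$usage_control
    st
  }
  truth <- new("SimTruth", exonTruth = exon_truth,
               siteTruth = site_truth, umiTruth = truth_umi)
  list(reads = rt, truth = truth)
}

# The four chain templates per gene: columns are (inclusion, skip) x
# (canonical donor, alternative donor of intron 1).
geneChainTemplates <- function(simgenes) {
  gi <- simgenes$genes
  ex <- data.table::as.data.table(data.frame(
    gene_id = S4Vectors::mcols(simgenes$models@exons)$gene_id,
    start = GenomicRanges::start(simgenes$models@exons),
    end = GenomicRanges::end(simgenes$models@exons)))
  data.table::setorder(ex, gene_id, start)
  out <- matrix("", nrow = nrow(gi), ncol = 4)
  for (g in seq_len(nrow(gi))) {
    e <- ex[ex$gene_id == gi$gene_id[g], ]
    i_start <- e$end[-nrow(e)] + 1L
    i_end <- e$start[-1] - 1L
    k <- which(e$start == gi$alt_start[g])
    incl <- encodeIntronChain(i_start, i_end)
    skip_start <- i_start[-(k - 1)]
    skip_end <- i_end[-(k - 1)]
    skip_start[k - 1] <- gi$skip_intron_start[g]
    skip_end[k - 1] <- gi$skip_intron_end[g]
    skip <- encodeIntronChain(skip_start, skip_end)
    alt1 <- function(ch_start, ch_end) {
      ch_start[1] <- gi$donor_alt[g]
      encodeIntronChain(ch_start, ch_end)
    }
    out[g, ] <- c(incl, skip, alt1(i_start, i_end),
                  alt1(skip_start, skip_end))
  }
  out
}

# Per-sample jitter of a planted group-level inclusion probability.
jitterPsi <- function(p, conc) {
  fixed <- p <= 0 | p >= 1
  out <- p
  if (any(!fixed))
    out[!fixed] <- stats::rbeta(sum(!fixed), conc * p[!fixed],
                                conc * (1 - p[!fixed]))
  out
}

# Draw n UMIs with pairwise Levenshtein distance > 3 within the group.
groupUniqueUmis <- function(n, len) {
  draw <- function(k) {
    m <- matrix(sample(c("A", "C", "G", "T"), k * len, replace = TRUE),
                nrow = k)
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  }
  u <- draw(n)
  if (n == 1) return(u)
  for (tries in 1:50) {
    d <- utils::adist(u)
    diag(d) <- Inf
    bad <- which(apply(d, 1, min) <= 3)
    # keep the first member of each close pair, redraw the rest
    bad <- bad[bad > vapply(bad, function(i) which(d[i, ] <= 3)[1],
                            integer(1))]
    if (!length(bad)) break
    u[bad] <- draw(length(bad))
  }
  u
}

#' Inject UMI sequencing noise
#'
#' Independently for each read, with probability `rate`, applies
#' `nEdits` random substitutions (distinct positions, base changed) to
#' the UMI, producing a noisy UMI within edit distance `nEdits` (at most
#' 3) of the truth.
#'
#' @param x A [ReadTable].
#' @param rate Per-UMI mutation probability in `[0, 1]`.
#' @param nEdits Substitutions per mutated UMI (1-3; default 1).
#' @param seed Optional seed for reproducible injection.
#' @return A [ReadTable] with mutated UMIs.
#' @export
injectUmiNoise <- function(x, rate, nEdits = 1L, seed = NULL) {
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]")
  stopifnot(nEdits >= 1, nEdits <= 3)
  if (!is.null(seed)) set.seed(seed)
  df <- readData(x)
  if (nrow(df) == 0 || rate == 0) return(x)
  hit <- which(stats::runif(nrow(df)) < rate)
  if (length(hit)) {
    len <- nchar(df$umi[hit[1]])
    df$umi[hit] <- vapply(df$umi[hit], function(u) {
      pos <- sample.int(len, nEdits)
      for (p in pos) {
        cur <- substr(u, p, p)
        substr(u, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
      }
      u
    }, character(1), USE.NAMES = FALSE)
  }
  new("ReadTable", reads = df)
}

#' Write the planted truth tables
#'
#' @param truth A [SimTruth].
#' @param path Output TSV for the exon truth (one row per alternative
#'   exon and cell type with planted Ψ values).
#' @return `path`, invisibly.
#' @export
writeSimTruth <- function(truth, path) {
  stopifnot(is(truth, "SimTruth"))
  utils::write.table(exonTruth(truth), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
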