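#' Derive per-intron counts from read chains
#'
#' Counts, for every intron appearing in a read's chain, the number of
#' reads per (gene, intron, cell type, condition, sample). This is the
#' internal route to splice-site testing; [importIntronCounts()] accepts
#' the same table from an external transcript-quantification tool.
#'
#' @param x A [ReadTable].
#' @return `data.frame` with columns `gene_id`, `chrom`, `intron_start`,
#'   `intron_end`, `strand`, `cell_type`, `condition`, `sample_id`,
#'   `count`.
#' @export
intronCounts <- function(x) {
  df <- readData(x)
  introns <- parseIntronChains(df$intron_chain)
  if (nrow(introns) == 0)
    return(data.frame(gene_id = character(), chrom = character(),
                      intron_start = integer(), intron_end = integer(),
                      strand = character(), cell_type = character(),
                      condition = character(), sample_id = character(),
                      count = integer()))
  tab <- data.table::data.table(
    gene_id = df$gene_id[introns$row],
    chrom = df$chrom[introns$row],
    intron_start = introns$start, intron_end = introns$end,
    strand = df$strand[introns$row],
    cell_type = df$cell_type[introns$row],
    condition = df$condition[introns$row],
    sample_id = df$sample_id[introns$row])
  out <- tab[, .(count = .N),
             by = c("gene_id", "chrom", "intron_start", "intron_end",
                    "strand", "cell_type", "condition", "sample_id")]
  data.table::setorder(out, gene_id, intron_start, intron_end, cell_type,
                       condition, sample_id)
  as.data.frame(out)
}

#' Import an external per-intron count table
#'
#' @param path TSV with columns `gene_id`, `chrom`, `intron_start`,
#'   `intron_end`, `strand`, `cell_type`, `condition`, `sample_id`,
#'   `count`.
#' @return `data.frame` in the [intronCounts()] layout.
#' @export
importIntronCounts <- function(path) {
  need <- c("gene_id", "chrom", "intron_start", "intron_end", "strand",
            "cell_type", "condition", "sample_id", "count")
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  missing_cols <- setdiff(need, colnames(df))
  if (length(missing_cols))
    stop("intron-count table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df[, need]
}

#' Group introns into alternative donor / acceptor site groups
#'
#' A donor group collects introns of one gene (and cell type) that share
#' the acceptor coordinate but differ in donor coordinate; an acceptor
#' group is symmetric. Donor/acceptor identity is strand-aware: on the
#' plus strand the donor is the intron start, on the minus strand the
#' intron end. Groups with fewer than two observed sites are omitted.
#'
#' @param counts Per-intron counts from [intronCounts()] or
#'   [importIntronCounts()].
#' @return Long-format `data.frame`: `group_id`, `kind` (`"donor"` or
#'   `"acceptor"`), `gene_id`, `chrom`, `strand`, `cell_type`,
#'   `fixed_pos`, `site_pos`, `condition`, `sample_id`, `count`.
#' @export
groupSpliceSites <- function(counts) {
  dt <- data.table::as.data.table(counts)
  if (nrow(dt) == 0) return(emptySiteGroups())
  plus <- dt$strand != "-"
  donor <- ifelse(plus, dt$intron_start, dt$intron_end)
  acceptor <- ifelse(plus, dt$intron_end, dt$intron_start)
  long <- rbind(
    data.table::data.table(kind = "donor", dt[, c("gene_id", "chrom",
      "strand", "cell_type", "condition", "sample_id", "count")],
      fixed_pos = acceptor, site_pos = donor),
    data.table::data.table(kind = "acceptor", dt[, c("gene_id", "chrom",
      "strand", "cell_type", "condition", "sample_id", "count")],
      fixed_pos = donor, site_pos = acceptor))
  site_pos <- NULL
  gcols <- c("kind", "gene_id", "chrom", "strand", "cell_type",
             "fixed_pos")
  nsites <- long[, .(n_sites = length(unique(site_pos))), by = gcols]
  keep <- nsites[nsites$n_sites >= 2, gcols, with = FALSE]
  if (nrow(keep) == 0) return(emptySiteGroups())
  out <- merge(long, keep, by = gcols)
  out$group_id <- do.call(paste, c(out[, c("kind", "gene_id", "cell_type",
                                           "fixed_pos")], sep = ":"))
  data.table::setorder(out, kind, gene_id, cell_type, fixed_pos, site_pos,
                       condition, sample_id)
  as.data.frame(out[, c("group_id", "kind", "gene_id", "chrom", "strand",
                        "cell_type", "fixed_pos", "site_pos", "condition",
                        "sample_id", "count")])
}

emptySiteGroups <- function() {
  data.frame(group_id = character(), kind = character(),
             gene_id = character(), chrom = character(),
             strand = character(), cell_type = character(),
             fixed_pos = integer(), site_pos = integer(),
             condition = character(), sample_id = character(),
             count = integer())
}

#' Case-control test of alternative splice-site usage
#'
#' For each site group, the two sites with the highest total count across
#' all samples are selected (ties broken by ascending genomic
#' coordinate) and a 2x2 table of (top site, second site) x (case,
#' control) is built. The group is discarded (`retained = FALSE`) when
#' either condition has zero total in the table or when the table's
#' grand total is less than `groupTotalFraction` of the group's
#' all-sites grand total. Fisher's exact two-sided test is applied to
#' retained groups and Benjamini-Yekutieli adjustment is performed per
#' (cell type, kind) family. The site-level Ψ is top / (top + second)
#' per condition; a group is significant iff q <= `fdr` and
#' |ΔΨ| >= `deltaPsiMin`.
#'
#' @param groups Output of [groupSpliceSites()].
#' @param deltaPsiMin Minimum |ΔΨ| (default 0.10).
#' @param fdr BY q cutoff (default 0.05).
#' @param groupTotalFraction Minimum fraction of the group total captured
#'   by the top-two table (default 0.8).
#' @return `data.frame`, one row per group: top/second site coordinates
#'   and counts per condition, `psi_case`, `psi_control`, `delta_psi`,
#'   `p_raw`, `q_by`, `retained`, `significant`.
#' @export
testSiteGroups <- function(groups, deltaPsiMin = 0.10, fdr = 0.05,
                           groupTotalFraction = 0.8) {
  dt <- data.table::as.data.table(groups)
  if (nrow(dt) == 0)
    return(data.frame(group_id = character()))
  count <- site_pos <- condition <- NULL
  site_tot <- dt[, .(tot = sum(count)),
                 by = c("group_id", "site_pos")]
  data.table::setorder(site_tot, group_id, -tot, site_pos)
  top2 <- site_tot[, .(top_site = site_pos[1], second_site = site_pos[2],
                       group_total_all = sum(tot)), by = "group_id"]
  d2 <- merge(dt, top2, by = "group_id")
  d2 <- d2[site_pos == d2$top_site | site_pos == d2$second_site]
  res <- d2[, .(
    kind = kind[1], gene_id = gene_id[1], chrom = chrom[1],
    strand = strand[1], cell_type = cell_type[1], fixed_pos = fixed_pos[1],
    top_site = top_site[1], second_site = second_site[1],
    top_case = sum(count[site_pos == top_site & condition == "case"]),
    second_case = sum(count[site_pos == second_site &
                            condition == "case"]),
    top_ctrl = sum(count[site_pos == top_site & condition == "control"]),
    second_ctrl = sum(count[site_pos == second_site &
                            condition == "control"]),
    group_total_all = group_total_all[1]), by = "group_id"]
  table_total <- res$top_case + res$second_case + res$top_ctrl +
    res$second_ctrl
  res$retained <- (res$top_case + res$second_case > 0) &
    (res$top_ctrl + res$second_ctrl > 0) &
    table_total >= groupTotalFraction * res$group_total_all
  res$psi_case <- psi(res$top_case, res$second_case)
  res$psi_control <- psi(res$top_ctrl, res$second_ctrl)
  res$delta_psi <- deltaPsi(res$psi_case, res$psi_control)
  res$p_raw <- NA_real_
  idx <- which(res$retained)
  res$p_raw[idx] <- vapply(idx, function(i)
    stats::fisher.test(rbind(c(res$top_case[i], res$second_case[i]),
                             c(res$top_ctrl[i], res$second_ctrl[i])))$p.value,
    numeric(1))
  # BY family per (cell type, kind), retained groups only.
  res$q_by <- NA_real_
  fam <- paste(res$cell_type, res$kind, sep = "\r")
  for (f in unique(fam[res$retained])) {
    i <- which(fam == f & res$retained)
    res$q_by[i] <- byAdjust(res$p_raw[i])
  }
  res$significant <- res$retained & !is.na(res$q_by) & res$q_by <= fdr &
    !is.na(res$delta_psi) & abs(res$delta_psi) >= deltaPsiMin
  out <- as.data.frame(res)
  data.table::setorderv(out, c("cell_type", "kind", "gene_id",
                               "fixed_pos"))
  rownames(out) <- NULL
  out
}
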