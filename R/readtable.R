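#' Construct a ReadTable from a data.frame
#'
#' Validates the per-read table: required columns, condition labels, and
#' (when `validateChains = TRUE`) that every read's intron chain parses,
#' is sorted by genomic start, non-overlapping, and lies within the
#' aligned span.
#'
#' @param df `data.frame` with the ReadTable columns (see
#'   [ReadTable-class]).
#' @param validateChains Check chain invariants per record (default `TRUE`).
#' @param lenient If `TRUE`, records violating chain invariants are dropped
#'   with a warning instead of raising an error.
#' @return A [ReadTable].
#' @export
readTable <- function(df, validateChains = TRUE, lenient = FALSE) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(READ_TABLE_COLUMNS, colnames(df))
  if (length(missing_cols))
    stop("read table format error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  df <- df[, READ_TABLE_COLUMNS]
  df$read_start <- as.integer(df$read_start)
  df$read_end <- as.integer(df$read_end)
  df$intron_chain[is.na(df$intron_chain)] <- ""
  if (validateChains && nrow(df) > 0) {
    bad <- badChainRows(df)
    if (length(bad)) {
      if (!lenient)
        stop("invalid intron chain in row(s): ",
             paste(head(bad, 5), collapse = ", "),
             " (unsorted, overlapping, or outside the aligned span)")
      warning(length(bad), " record(s) with invalid intron chains dropped")
      df <- df[-bad, , drop = FALSE]
    }
  }
  new("ReadTable", reads = df)
}

# Row indices whose chain violates the invariants (sorted, non-overlapping,
# within span, parseable).
badChainRows <- function(df) {
  ch <- parseIntronChains(df$intron_chain)
  if (nrow(ch) == 0) return(integer())
  row <- start <- end <- NULL
  chk <- ch[, .(ok = !anyNA(start) && !anyNA(end) && all(start <= end) &&
                  !is.unsorted(start, strictly = TRUE) &&
                  all(start[-1] > end[-.N]) &&
                  start[1] > df$read_start[row[1]] &&
                  end[.N] < df$read_end[row[1]]),
            by = row]
  chk$row[!chk$ok]
}

#' Parse intron-chain strings into a long table
#'
#' Decodes `"start-end;start-end"` chain strings (1-based inclusive
#' intronic coordinates) into one row per intron.
#'
#' @param chains Character vector of chain strings; `""` denotes a
#'   mono-exonic read and yields no rows.
#' @return A `data.table` with columns `row` (index into `chains`),
#'   `start`, `end`.
#' @export
parseIntronChains <- function(chains) {
  chains[is.na(chains)] <- ""
  has <- nzchar(chains)
  if (!any(has))
    return(data.table::data.table(row = integer(), start = integer(),
                                  end = integer()))
  idx <- which(has)
  parts <- strsplit(chains[idx], ";", fixed = TRUE)
  n_per <- lengths(parts)
  flat <- unlist(parts, use.names = FALSE)
  se <- data.table::tstrsplit(flat, "-", fixed = TRUE)
  data.table::data.table(row = rep(idx, n_per),
                         start = suppressWarnings(as.integer(se[[1]])),
                         end = suppressWarnings(as.integer(se[[2]])))
}

# Inverse of parseIntronChains for a matrix/data.frame of introns.
encodeIntronChain <- function(starts, ends) {
  if (length(starts) == 0) return("")
  paste(paste0(starts, "-", ends), collapse = ";")
}

#' Read / write the per-read TSV
#'
#' `parseReadTable()` reads the tab-separated per-read table (header
#' required; columns as documented in [ReadTable-class]) and validates
#' every record. `writeReadTable()` writes a `ReadTable` back to TSV,
#' optionally with `#`-prefixed header comment lines.
#'
#' @param path TSV path.
#' @param lenient Drop (with a warning) records whose intron chains violate
#'   the invariants instead of failing.
#' @return `parseReadTable()`: a [ReadTable]. `writeReadTable()`: `path`,
#'   invisibly.
#' @export
parseReadTable <- function(path, lenient = FALSE) {
  if (!file.exists(path)) stop("read table not found: ", path)
  # skip leading "# " comment lines (seed/config headers)
  n_skip <- 0L
  con <- file(path, "r")
  while (length(l <- readLines(con, 1)) && startsWith(l, "#"))
    n_skip <- n_skip + 1L
  close(con)
  df <- data.table::fread(path, sep = "\t", header = TRUE, skip = n_skip,
                          colClasses = list(character = c("umi", "barcode",
                                                          "intron_chain",
                                                          "subtype")),
                          na.strings = NULL, data.table = FALSE)
  readTable(df, validateChains = TRUE, lenient = lenient)
}

#' @rdname parseReadTable
#' @param x A [ReadTable].
#' @param header Optional character vector of comment lines written with a
#'   leading `"# "` before the column header.
#' @export
writeReadTable <- function(x, path, header = NULL) {
  stopifnot(is(x, "ReadTable"))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(readData(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Deduplicate UMIs by edit distance
#'
#' Within each deduplication group (by default one group per
#' (barcode, gene) pair), UMIs are ranked by read count in decreasing
#' order, ties broken lexicographically by UMI string. Scanning in rank
#' order, a UMI — together with all its reads — is discarded when its
#' Levenshtein distance to any already-retained UMI of the group is at
#' most `maxDistance` (i.e. strictly less than `maxDistance + 1`);
#' retained UMIs survive. This removes sequencing-error satellites of
#' more frequent UMIs while keeping genuinely distinct molecules.
#'
#' The comparison is against the retained set (not all input UMIs), so a
#' chain of mutually close low-count UMIs cannot eliminate one another
#' after their attractor is removed. The deterministic ranking makes the
#' result invariant to input row order.
#'
#' @param x A [ReadTable].
#' @param maxDistance Discard threshold: discard at Levenshtein distance
#'   `<= maxDistance` from a retained, more frequent UMI. Default 3
#'   (distance less than 4).
#' @param scope Grouping within which UMIs are compared: `"barcode-gene"`
#'   (default; collisions are only meaningful within a cell-and-gene
#'   context), `"barcode"`, or `"global"`.
#' @return A [ReadTable] containing the surviving reads (a subset of the
#'   input; idempotent).
#' @rdname dedupUmis
#' @export
setMethod("dedupUmis", "ReadTable",
  function(x, maxDistance = 3L,
           scope = c("barcode-gene", "barcode", "global")) {
  scope <- match.arg(scope)
  df <- readData(x)
  if (nrow(df) == 0) return(x)
  dt <- data.table::as.data.table(df)
  key <- switch(scope,
    "barcode-gene" = paste(df$barcode, df$gene_id, sep = "\r"),
    "barcode" = df$barcode,
    "global" = rep("all", nrow(df)))
  dt$.group <- key
  umi <- .group <- .keep <- .multi <- NULL
  # groups with a single distinct UMI are kept as-is; only multi-UMI
  # groups need the greedy distance scan
  dt[, .multi := length(unique(umi)) > 1, by = .group]
  multi <- dt[.multi == TRUE]
  if (nrow(multi)) {
    kept <- multi[, .(umi = keptUmis(umi, maxDistance)), by = .group]
    drop_key <- setdiff(paste(multi$.group, multi$umi, sep = "\r"),
                        paste(kept$.group, kept$umi, sep = "\r"))
    keep_row <- !(paste(dt$.group, dt$umi, sep = "\r") %in% drop_key)
  } else {
    keep_row <- rep(TRUE, nrow(dt))
  }
  out <- as.data.frame(dt[keep_row, !c(".group", ".multi"), with = FALSE])
  new("ReadTable", reads = out)
})

# Greedy retained-set scan for one dedup group: rank by count desc then
# UMI asc; keep a UMI iff its edit distance to every kept UMI exceeds maxd.
keptUmis <- function(umis, maxd) {
  cnt <- table(umis)
  u <- names(cnt)[order(-as.integer(cnt), names(cnt))]
  if (length(u) == 1) return(u)
  keep <- u[1]
  for (cand in u[-1]) {
    if (min(utils::adist(cand, keep)) > maxd) keep <- c(keep, cand)
  }
  keep
}

#' Discard reads with rare intron chains
#'
#' A read is kept iff its exact intron chain — gene-scoped,
#' coordinate-exact, with the empty (mono-exonic) chain forming its own
#' class per gene — occurs at least `minCount` times across all samples
#' pooled. Apply after [dedupUmis()].
#'
#' @param x A [ReadTable].
#' @param minCount Minimum dataset-wide chain occurrence (default 5).
#' @return A [ReadTable] (a subset of the input; idempotent).
#' @rdname filterRareChains
#' @export
setMethod("filterRareChains", "ReadTable", function(x, minCount = 5L) {
  df <- readData(x)
  if (nrow(df) == 0 || minCount <= 1) return(x)
  key <- paste(df$gene_id, df$intron_chain, sep = "\r")
  n <- table(key)
  new("ReadTable", reads = df[n[key] >= minCount, , drop = FALSE])
})
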