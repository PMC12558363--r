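# Toy probe-design fixture: three plus-strand genes on one synthetic
# chromosome.
#   GENE_A: 7 exons of 100 b  -> 6 junctions, all 140-base windows
#   GENE_B: exons 80/40/100/100/100 -> 4 junctions; the 40-base exon
#           forces walking across adjacent exons
#   GENE_C: exons 55/100/100 -> junction 1 yields a 125-base window
#           (discarded); junction 2 yields 140
probeFixture <- function(seed = 1) {
  set.seed(seed)
  mk_gene <- function(gene, lens, offset, gap = 400L) {
    starts <- integer(length(lens))
    pos <- offset
    rows <- list()
    for (i in seq_along(lens)) {
      starts[i] <- pos
      rows[[i]] <- data.frame(gene_id = gene,
        transcript_id = paste0(gene, ".t1"), chrom = "chrP",
        start = pos, end = pos + lens[i] - 1L, strand = "+")
      pos <- pos + lens[i] + gap
    }
    do.call(rbind, rows)
  }
  exons <- rbind(mk_gene("GENE_A", rep(100L, 7), 1000L),
                 mk_gene("GENE_B", c(80L, 40L, 100L, 100L, 100L), 8000L),
                 mk_gene("GENE_C", c(55L, 100L, 100L), 14000L))
  genome_len <- 20000L
  seq <- paste(sample(c("A", "C", "G", "T"), genome_len, replace = TRUE),
               collapse = "")
  list(models = geneModelsFromExons(exons),
       genome = Biostrings::DNAStringSet(c(chrP = seq)),
       exons = exons)
}
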