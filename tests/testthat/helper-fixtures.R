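library(data.table)

# Write a GTF from a list of transcripts:
#   list(tx = , gene = , strand = , exons = list(c(start, end), ...),
#        gene_name = optional, contig = optional)
make_gtf <- function(transcripts, path = tempfile(fileext = ".gtf")) {
  lines <- unlist(lapply(transcripts, function(t) {
    contig <- t$contig %||% "chr1"
    gname <- t$gene_name %||% t$gene
    vapply(t$exons, function(e) {
      sprintf('%s\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; gene_name "%s";',
              contig, e[1], e[2], t$strand, t$gene, t$tx, gname)
    }, "")
  }))
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Standard small fixture: two + strand genes and one - strand gene.
#   gA/tA: exons 101-200, 301-400, 501-600 (+)
#   gB/tB: exons 2001-2100, 2301-2400     (+)
#   gC/tC: exons 5001-5100, 5301-5400     (-)
fixture_index <- function(include_single_exon = FALSE, extra = list()) {
  txs <- c(list(
    list(tx = "tA", gene = "gA", strand = "+",
         exons = list(c(101, 200), c(301, 400), c(501, 600))),
    list(tx = "tB", gene = "gB", strand = "+",
         exons = list(c(2001, 2100), c(2301, 2400))),
    list(tx = "tC", gene = "gC", strand = "-",
         exons = list(c(5001, 5100), c(5301, 5400)))
  ), extra)
  parse_gtf(make_gtf(txs), include_single_exon = include_single_exon)
}

# Minimal single-sample VCF.
make_vcf <- function(variants, path = tempfile(fileext = ".vcf"),
                     contig = "chr1", contig_len = 100000L) {
  v <- as.data.table(variants)
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", contig, contig_len),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    if (nrow(v)) sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                         v$seqnames %||% contig, v$pos, v$ref, v$alt)
  ), path)
  path
}

# Minimal coordinate-sorted single-end SAM.
make_sam <- function(reads, path = tempfile(fileext = ".sam"),
                     contig = "chr1", contig_len = 1000000L) {
  r <- as.data.table(reads)
  setorder(r, pos)
  body <- if (nrow(r)) sprintf(
    "%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*%s",
    r$qname %||% sprintf("r%05d", seq_len(nrow(r))),
    r$flag %||% rep(0L, nrow(r)), contig, r$pos, r$cigar,
    r$seq %||% strrep("A", 1L),
    if (!is.null(r$xs)) sprintf("\tXS:A:%s", r$xs) else ""
  ) else character()
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", contig, contig_len), body), path)
  path
}

# Random transcript structures for property tests (one contig).
random_transcripts <- function(n, seed, contig = "chr1") {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      ne <- sample(2:5, 1)
      pos <- sample(1:500000, 1)
      exons <- list()
      for (k in seq_len(ne)) {
        len <- sample(50:200, 1)
        exons[[k]] <- c(pos, pos + len - 1L)
        pos <- pos + len + sample(80:400, 1)
      }
      list(tx = sprintf("t%04d", i), gene = sprintf("g%04d", (i + 1L) %/% 2L),
           strand = sample(c("+", "-"), 1), exons = exons, contig = contig)
    })
  })
}
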