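## ---- junction classification ----------------------------------------------

# DA > NDA > D = A > N, used to resolve unknown-strand junctions.
junction_type_rank <- c(N = 1L, D = 2L, A = 2L, NDA = 3L, DA = 4L)

classify_junction_stranded <- function(index, seqnames, start, end, strand) {
  chr_q <- seqnames; s_q <- as.integer(start); e_q <- as.integer(end)
  str_q <- strand
  dpos <- if (str_q == "+") s_q else e_q
  apos <- if (str_q == "+") e_q else s_q
  kd <- nrow(index$donors[list(chr_q, dpos, str_q),
                          on = c("seqnames", "pos", "strand"),
                          nomatch = NULL]) > 0L
  ka <- nrow(index$acceptors[list(chr_q, apos, str_q),
                             on = c("seqnames", "pos", "strand"),
                             nomatch = NULL]) > 0L
  kj <- nrow(index$introns[list(chr_q, s_q, e_q, str_q),
                           on = c("seqnames", "start", "end", "strand"),
                           nomatch = NULL]) > 0L
  type <- if (kj) "DA" else if (kd && ka) "NDA" else if (kd) "D" else
    if (ka) "A" else "N"
  tx <- overlapping_transcripts(index, chr_q, s_q, e_q)
  genes_same <- unique(tx[strand == str_q]$gene_id)
  # skipped-site counts: distinct annotated positions strictly inside the
  # intron, per same-strand gene, reported as the max across genes
  ds <- as_ <- es <- 0L
  for (g in genes_same) {
    gi <- index$tx_introns[list(g), nomatch = NULL][seqnames == chr_q]
    ge <- index$gene_exons[list(g), nomatch = NULL][seqnames == chr_q]
    d_in <- data.table::uniqueN(gi[donor_pos > s_q & donor_pos < e_q, donor_pos])
    a_in <- data.table::uniqueN(gi[acceptor_pos > s_q & acceptor_pos < e_q,
                                   acceptor_pos])
    e_in <- nrow(unique(ge[start > s_q & end < e_q, .(start, end)]))
    ds <- max(ds, d_in); as_ <- max(as_, a_in); es <- max(es, e_in)
  }
  list(strand = str_q, known_donor = kd, known_acceptor = ka,
       known_junction = kj, junction_type = type,
       donors_skipped = ds, acceptors_skipped = as_, exons_skipped = es,
       genes = sort(unique(tx$gene_name)),
       transcripts = sort(unique(tx$transcript_id)))
}

#' Classify a junction against the reference transcriptome
#'
#' The donor is the 5' intron boundary with respect to the transcribed
#' strand and the acceptor the 3' boundary; both are matched exactly
#' (to the base) against the annotated site catalogs. Junction types:
#' `DA` (annotated intron), `NDA` (both sites known but never paired),
#' `D` / `A` (only the donor / acceptor known), `N` (neither known).
#' Skipped counts are distinct annotated donor/acceptor positions strictly
#' inside the intron and distinct annotated exons fully contained in it,
#' computed per overlapping same-strand gene with the maximum reported.
#'
#' Junctions with unknown strand (`"."`) are evaluated on both strands and
#' the strand yielding the higher class (DA > NDA > D = A > N) is adopted,
#' ties resolving to `+`. A junction on a contig absent from the index is
#' typed `N` with empty gene lists, with a warning.
#'
#' @param index A `transcriptome_index`.
#' @param seqnames,start,end Junction intron interval (1-based inclusive:
#'   first to last intronic base).
#' @param strand `"+"`, `"-"` or `"."`.
#' @return A list: adopted `strand`, `known_donor`, `known_acceptor`,
#'   `known_junction`, `junction_type`, `donors_skipped`,
#'   `acceptors_skipped`, `exons_skipped`, `genes`, `transcripts`.
#' @export
classify_junction <- function(index, seqnames, start, end, strand = ".") {
  if (!seqnames %in% index$transcripts$seqnames) {
    warning("junction contig ", seqnames, " absent from index")
    return(list(strand = if (strand == ".") "+" else strand,
                known_donor = FALSE, known_acceptor = FALSE,
                known_junction = FALSE, junction_type = "N",
                donors_skipped = 0L, acceptors_skipped = 0L,
                exons_skipped = 0L, genes = character(),
                transcripts = character()))
  }
  if (strand %in% c("+", "-")) {
    return(classify_junction_stranded(index, seqnames, start, end, strand))
  }
  plus <- classify_junction_stranded(index, seqnames, start, end, "+")
  minus <- classify_junction_stranded(index, seqnames, start, end, "-")
  if (junction_type_rank[minus$junction_type] >
      junction_type_rank[plus$junction_type]) minus else plus
}

#' Splice-site dinucleotides of a junction
#'
#' Returns the first two intronic bases at the donor and the last two at the
#' acceptor, reverse-complemented for `-` strand junctions, joined
#' donor-to-acceptor (e.g. `"GT-AG"`).
#'
#' @param genome An [Rsamtools::FaFile] or FASTA path.
#' @param seqnames,start,end Intron interval (1-based inclusive).
#' @param strand `"+"` or `"-"` (unknown strand is reported on `+`).
#' @return A 5-character motif string, e.g. `"GT-AG"`.
#' @export
splice_site_sequence <- function(genome, seqnames, start, end, strand = "+") {
  if (end - start + 1L < 4L) {
    stop("intron shorter than 4 bases: cannot read both splice sites")
  }
  left <- genome_seq(genome, seqnames, start, start + 1L)
  right <- genome_seq(genome, seqnames, end - 1L, end)
  if (strand == "-") {
    rc <- function(x) as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(x)))
    paste0(rc(right), "-", rc(left))
  } else {
    paste0(left, "-", right)
  }
}

#' Annotate a table of junctions against transcriptome and genome
#'
#' Produces one output row per junction with its splice-site motif,
#' skipped-feature counts, junction type (column `anchor`), known-site
#' flags, and the overlapping genes and transcripts. Annotation is
#' independent of input order and idempotent; output rows are sorted by
#' coordinate.
#'
#' @param junctions A junction data.table (from [aggregate_junctions()],
#'   [read_junctions_bed()], or a BED12 path).
#' @param index A `transcriptome_index`.
#' @param genome An [Rsamtools::FaFile] or FASTA path, for splice-site
#'   motifs; `NULL` leaves the `splice_site` column `NA`.
#' @param out Optional TSV output path (header always written).
#' @return A data.table with columns `chrom`, `start`, `end` (1-based
#'   intron bounds), `name`, `score`, `strand`, `splice_site`,
#'   `acceptors_skipped`, `donors_skipped`, `exons_skipped`, `anchor`
#'   (junction type), `known_donor`, `known_acceptor`, `known_junction`,
#'   `genes`, `transcripts`.
#' @export
annotate_junctions <- function(junctions, index, genome = NULL, out = NULL) {
  if (is.character(junctions)) junctions <- read_junctions_bed(junctions)
  j <- as.data.table(junctions)
  if (!is.null(genome) && is.character(genome)) genome <- genome_open(genome)
  rows <- vector("list", nrow(j))
  for (i in seq_len(nrow(j))) {
    cl <- classify_junction(index, j$seqnames[i], j$start[i], j$end[i],
                            j$strand[i])
    ss <- if (is.null(genome)) NA_character_ else
      splice_site_sequence(genome, j$seqnames[i], j$start[i], j$end[i],
                           cl$strand)
    rows[[i]] <- data.table(
      chrom = j$seqnames[i], start = j$start[i], end = j$end[i],
      name = j$name[i], score = j$score[i], strand = cl$strand,
      splice_site = ss, acceptors_skipped = cl$acceptors_skipped,
      donors_skipped = cl$donors_skipped, exons_skipped = cl$exons_skipped,
      anchor = cl$junction_type,
      known_donor = as.integer(cl$known_donor),
      known_acceptor = as.integer(cl$known_acceptor),
      known_junction = as.integer(cl$known_junction),
      genes = paste(cl$genes, collapse = ","),
      transcripts = paste(cl$transcripts, collapse = ",")
    )
  }
  ann <- if (length(rows)) rbindlist(rows) else data.table(
    chrom = character(), start = integer(), end = integer(),
    name = character(), score = integer(), strand = character(),
    splice_site = character(), acceptors_skipped = integer(),
    donors_skipped = integer(), exons_skipped = integer(),
    anchor = character(), known_donor = integer(),
    known_acceptor = integer(), known_junction = integer(),
    genes = character(), transcripts = character()
  )
  setorder(ann, chrom, start, end, strand)
  if (!is.null(out)) fwrite(ann, out, sep = "\t", quote = FALSE)
  ann[]
}
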