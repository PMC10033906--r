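#' @importFrom data.table data.table as.data.table setkey setkeyv setorder
#'   setorderv rbindlist fread fwrite setnames copy := .N .SD foverlaps J
#'   %chin% CJ
#' @import methods
NULL

utils::globalVariables(c(
  ".", "J", "transcript_id", "gene_id", "gene_name", "seqnames", "start",
  "end", "strand", "exon_rank", "n_exons", "pos", "intron_start", "intron_end",
  "left_anchor", "right_anchor", "record", "op", "len", "ref_before", "g_after",
  "ref_len", "score", "thick_start", "thick_end", "max_left", "max_right",
  "name", "variant_id", "variant_type", "distance", "exon_index",
  "splice_relevant", "region_start", "region_end", "junction_type", "p_value",
  "p_adjusted", "significant", "total_variant_reads", "mean_norm_score",
  "n_variant_samples", "variant_samples", "gene", "ref", "alt", "sample_id",
  "anchor_pos", "donor_pos", "acceptor_pos", "binom_p", "fraction",
  "i.anchor", "anchor", "i.variant_samples", "i.variants", "i.junction_type",
  "junc_name", "junc_start", "junc_end", "junc_strand", "variants",
  "blocksizes", "blockstarts", "thickstart", "chromstart", "chromend",
  "chrom", "known_junction", "splice_site", "norm_scores", "role",
  "effect_fraction", "xs", "cigar", "qname", "V1", "n_chr", "n_str",
  "n_sig", "k", "s", "expected_type", "g"
))

## ---- transcriptome index ---------------------------------------------------

#' Parse a GTF file into a transcriptome index
#'
#' Reads exon features from a GTF (1-based, inclusive coordinates) and builds
#' the indexed structures used throughout the package: transcript models,
#' the catalog of annotated splice donors and acceptors, and the set of
#' annotated introns (exon-exon junctions). Transcripts are assembled from
#' `exon` feature lines only; `transcript` lines are optional. Exact duplicate
#' exon lines are deduplicated silently. Single-exon transcripts are excluded
#' unless `include_single_exon = TRUE`, since they carry no splice sites.
#'
#' Donor and acceptor positions are stored as the first and last intronic
#' base of each annotated intron with respect to the transcribed strand:
#' on `+` the donor is the intron start and the acceptor the intron end;
#' mirrored on `-`.
#'
#' @param gtf Path to a GTF file.
#' @param include_single_exon Keep single-exon transcripts? Default `FALSE`.
#' @return An object of class `transcriptome_index`: a list with data.tables
#'   `exons`, `transcripts`, `tx_introns` (per-transcript introns with donor
#'   and acceptor positions), the deduplicated site sets `donors`, `acceptors`,
#'   `introns`, and `tx_gr`, a [GenomicRanges::GRanges] of transcript spans
#'   used for interval queries.
#' @export
parse_gtf <- function(gtf, include_single_exon = FALSE) {
  lines <- readLines(gtf)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("no records in GTF: ", gtf)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    stop("malformed GTF line ", lineno[which(nf != 9L)[1]],
         ": expected 9 tab-separated fields, found ", nf[which(nf != 9L)[1]])
  }
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  is_exon <- m[, 3] == "exon"
  m <- m[is_exon, , drop = FALSE]
  lineno <- lineno[is_exon]
  if (nrow(m) == 0L) stop("GTF contains no exon features: ", gtf)
  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(start) | is.na(end) | start < 1L | start > end)
  if (length(bad)) {
    stop("malformed GTF line ", lineno[bad[1]], ": invalid exon coordinates")
  }
  attr_field <- m[, 9]
  get_attr <- function(key) {
    pat <- paste0('(^|;)\\s*', key, '\\s+"([^"]*)"')
    out <- rep(NA_character_, length(attr_field))
    hit <- regexpr(pat, attr_field, perl = TRUE)
    has <- hit > 0L
    out[has] <- sub(paste0('.*', key, '\\s+"([^"]*)".*'), "\\1",
                    attr_field[has], perl = TRUE)
    out
  }
  tx <- get_attr("transcript_id")
  gid <- get_attr("gene_id")
  gname <- get_attr("gene_name")
  no_tx <- is.na(tx) | !nzchar(tx)
  if (any(no_tx)) {
    warning(sum(no_tx), " exon record(s) without transcript_id rejected ",
            "(first at line ", lineno[no_tx][1], ")")
  }
  exons <- data.table(
    seqnames = m[, 1], start = start, end = end, strand = m[, 7],
    transcript_id = tx, gene_id = gid, gene_name = gname
  )[!no_tx]
  exons[is.na(gene_id) | !nzchar(gene_id), gene_id := transcript_id]
  exons[is.na(gene_name) | !nzchar(gene_name), gene_name := gene_id]
  exons <- unique(exons)
  if (any(!exons$strand %in% c("+", "-"))) {
    stop("exon with strand other than +/- in GTF: ", gtf)
  }
  build_transcriptome_index(exons, include_single_exon = include_single_exon)
}

# Assemble the index from a clean exon table (seqnames, start, end, strand,
# transcript_id, gene_id, gene_name). Shared by parse_gtf() and the simulator.
build_transcriptome_index <- function(exons, include_single_exon = FALSE) {
  exons <- copy(as.data.table(exons))
  chk <- exons[, .(n_chr = data.table::uniqueN(seqnames),
                   n_str = data.table::uniqueN(strand)), by = transcript_id]
  if (any(chk$n_chr > 1L) || any(chk$n_str > 1L)) {
    stop("transcript spanning multiple contigs or strands: ",
         chk[n_chr > 1L | n_str > 1L, transcript_id][1])
  }
  setorder(exons, seqnames, transcript_id, start, end)
  exons[, exon_rank := seq_len(.N), by = transcript_id]
  ovl <- exons[, any(start[-1L] <= end[-.N] & .N > 1L), by = transcript_id]
  if (any(ovl$V1)) {
    stop("transcript with overlapping exons: ", ovl[V1 == TRUE, transcript_id][1])
  }
  transcripts <- exons[, .(
    gene_id = gene_id[1], gene_name = gene_name[1], seqnames = seqnames[1],
    strand = strand[1], start = min(start), end = max(end), n_exons = .N
  ), by = transcript_id]
  if (!include_single_exon) {
    multi <- transcripts[n_exons > 1L, transcript_id]
    exons <- exons[transcript_id %in% multi]
    transcripts <- transcripts[n_exons > 1L]
  }
  if (nrow(transcripts) == 0L) {
    stop("no transcripts in index (all single-exon and include_single_exon = FALSE?)")
  }
  setorder(transcripts, transcript_id)
  tx_introns <- exons[, {
    if (.N > 1L) {
      is <- end[-.N] + 1L
      ie <- start[-1L] - 1L
      if (any(ie < is)) stop("abutting or overlapping exons leave no intron in ",
                             transcript_id[1])
      .(seqnames = seqnames[-.N], start = is, end = ie, strand = strand[1],
        gene_id = gene_id[1], gene_name = gene_name[1])
    } else {
      .(seqnames = character(), start = integer(), end = integer(),
        strand = character(), gene_id = character(), gene_name = character())
    }
  }, by = transcript_id]
  tx_introns[, donor_pos := ifelse(strand == "+", start, end)]
  tx_introns[, acceptor_pos := ifelse(strand == "+", end, start)]
  donors <- unique(tx_introns[, .(seqnames, pos = donor_pos, strand)])
  acceptors <- unique(tx_introns[, .(seqnames, pos = acceptor_pos, strand)])
  introns <- unique(tx_introns[, .(seqnames, start, end, strand)])
  gene_exons <- unique(exons[, .(gene_id, seqnames, start, end)])
  setkey(gene_exons, gene_id)
  setkey(tx_introns, gene_id)
  setkey(donors, seqnames, pos, strand)
  setkey(acceptors, seqnames, pos, strand)
  setkey(introns, seqnames, start, end, strand)
  setkey(exons, transcript_id)
  setkey(transcripts, transcript_id)
  tx_gr <- GenomicRanges::GRanges(
    transcripts$seqnames,
    IRanges::IRanges(transcripts$start, transcripts$end),
    strand = transcripts$strand
  )
  names(tx_gr) <- transcripts$transcript_id
  structure(
    list(exons = exons, transcripts = transcripts, tx_introns = tx_introns,
         gene_exons = gene_exons, donors = donors, acceptors = acceptors,
         introns = introns, tx_gr = tx_gr,
         include_single_exon = include_single_exon),
    class = "transcriptome_index"
  )
}

#' @export
print.transcriptome_index <- function(x, ...) {
  cat("transcriptome_index:", nrow(x$transcripts), "transcripts,",
      data.table::uniqueN(x$transcripts$gene_id), "genes,",
      nrow(x$introns), "annotated introns\n")
  invisible(x)
}

#' Write the transcripts of an index back to GTF
#'
#' Emits one `exon` feature line per exon with `gene_id`, `transcript_id`
#' and `gene_name` attributes. Re-parsing the output with [parse_gtf()]
#' reconstructs an identical index.
#'
#' @param index A `transcriptome_index`.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(index, path) {
  ex <- copy(index$exons)
  setorder(ex, seqnames, start, end, transcript_id)
  lines <- sprintf(
    '%s\tcisplice\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; gene_name "%s";',
    ex$seqnames, ex$start, ex$end, ex$strand, ex$gene_id, ex$transcript_id,
    ex$gene_name
  )
  writeLines(lines, path)
  invisible(path)
}

#' Transcripts overlapping a genomic interval
#'
#' Returns every transcript whose span (minimum exon start to maximum exon
#' end) intersects the query interval, ordered by `transcript_id`. A contig
#' absent from the index yields an empty result, not an error.
#'
#' @param index A `transcriptome_index`.
#' @param seqnames Contig name.
#' @param start,end 1-based inclusive interval bounds; `start <= end` required.
#' @return A data.table of matching rows from `index$transcripts`.
#' @export
overlapping_transcripts <- function(index, seqnames, start, end) {
  if (!is.numeric(start) || !is.numeric(end) || start < 1 || start > end) {
    stop("invalid interval: require 1 <= start <= end")
  }
  chr_q <- seqnames; s_q <- start; e_q <- end
  hit <- index$transcripts[seqnames == chr_q & start <= e_q & end >= s_q]
  setorder(hit, transcript_id)
  hit
}

# Exon table (genomic order) for one transcript.
transcript_exons <- function(index, txid) {
  ex <- index$exons[list(txid), on = "transcript_id", nomatch = NULL]
  if (nrow(ex) == 0L) stop("unknown transcript: ", txid)
  setorder(ex, start)
  ex
}

## ---- genome sequence -------------------------------------------------------

#' Open an indexed reference genome
#'
#' Opens a FASTA file for random access via its `.fai` sidecar index,
#' creating the index if absent.
#'
#' @param fasta Path to a FASTA file.
#' @return An [Rsamtools::FaFile] handle.
#' @export
genome_open <- function(fasta) {
  if (!file.exists(paste0(fasta, ".fai"))) Rsamtools::indexFa(fasta)
  Rsamtools::FaFile(fasta)
}

#' Fetch genome sequence for an interval
#'
#' @param genome An [Rsamtools::FaFile] from [genome_open()] (a path is
#'   accepted and opened on the fly).
#' @param seqnames Contig.
#' @param start,end 1-based inclusive bounds.
#' @param strand `"+"` (default) or `"-"`; minus returns the reverse
#'   complement.
#' @return A character scalar of length `end - start + 1`.
#' @export
genome_seq <- function(genome, seqnames, start, end, strand = "+") {
  if (is.character(genome)) genome <- genome_open(genome)
  gr <- GenomicRanges::GRanges(seqnames, IRanges::IRanges(start, end))
  seq <- Rsamtools::scanFa(genome, gr)[[1]]
  if (strand == "-") seq <- Biostrings::reverseComplement(seq)
  as.character(seq)
}
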