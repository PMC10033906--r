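## ---- splice variant window -------------------------------------------------

#' Define a splice-variant window
#'
#' The splice-variant window is the distance band around exon edges within
#' which a variant is considered potentially splice-associated: `intronic_bases`
#' (`-i`) into the intron from each exon edge and `exonic_bases` (`-e`) into
#' the exon. The defaults (`i = 2`, `e = 3`) capture the splice-site
#' dinucleotides plus the terminal exonic bases. Alternatively `all_intronic`
#' (`-I`) or `all_exonic` (`-E`) treat every intronic or exonic position as
#' splice-relevant; these flags leave the variant-type labels at plain
#' `"intronic"` / `"exonic"` and may be combined with a finite window on the
#' other side.
#'
#' Distances are counted from the exon edge: the exon-edge base itself has
#' exonic distance 1 (so `e = 3` covers exactly 3 exonic bases per edge) and
#' the first intronic base has intronic distance 1 (so `i = 2` covers the
#' canonical GT / AG dinucleotides).
#'
#' @param intronic_bases Intronic window size in bases (>= 0). Ignored with a
#'   warning when `all_intronic = TRUE`.
#' @param exonic_bases Exonic window size in bases (>= 0). Ignored with a
#'   warning when `all_exonic = TRUE`.
#' @param all_intronic Treat all intronic positions as splice-relevant.
#' @param all_exonic Treat all exonic positions as splice-relevant.
#' @param include_single_exon Keep single-exon transcripts in the index.
#' @return An object of class `splice_variant_window`.
#' @export
splice_variant_window <- function(intronic_bases = 2L, exonic_bases = 3L,
                                  all_intronic = FALSE, all_exonic = FALSE,
                                  include_single_exon = FALSE) {
  if (all_intronic && !missing(intronic_bases)) {
    warning("all_intronic = TRUE: intronic_bases ignored")
  }
  if (all_exonic && !missing(exonic_bases)) {
    warning("all_exonic = TRUE: exonic_bases ignored")
  }
  intronic_bases <- as.integer(intronic_bases)
  exonic_bases <- as.integer(exonic_bases)
  stopifnot(intronic_bases >= 0L, exonic_bases >= 0L)
  structure(
    list(intronic_bases = if (all_intronic) NA_integer_ else intronic_bases,
         exonic_bases = if (all_exonic) NA_integer_ else exonic_bases,
         all_intronic = all_intronic, all_exonic = all_exonic,
         include_single_exon = include_single_exon),
    class = "splice_variant_window"
  )
}

#' @export
print.splice_variant_window <- function(x, ...) {
  cat("splice_variant_window: intronic =",
      if (x$all_intronic) "all" else x$intronic_bases,
      "| exonic =", if (x$all_exonic) "all" else x$exonic_bases,
      "| single-exon:", x$include_single_exon, "\n")
  invisible(x)
}

## ---- per-transcript classification ----------------------------------------

#' Classify a variant position against one transcript
#'
#' Assigns one of the variant types `splicing_exonic`, `splicing_intronic`,
#' `exonic` or `intronic` to a genomic position inside a transcript span,
#' under a splice-variant window. The reported `distance` is the minimum over
#' the two edges of the associated exon: for exonic positions the edge base
#' counts as distance 1; for intronic positions the first intronic base
#' counts as distance 1. The associated exon of an intronic position is the
#' exon with the nearest edge (ties resolve to the upstream-in-genome exon).
#'
#' @param pos 1-based genomic position; must lie within the transcript span.
#' @param exons A data.frame of the transcript's exons with `start`/`end`
#'   columns (1-based inclusive), sorted by `start`, non-overlapping.
#' @param window A [splice_variant_window()].
#' @return A list with `variant_type`, `distance`, `exon_index` (genomic
#'   order) and `splice_relevant` (includes the `-E`/`-I` readings).
#' @export
classify_variant <- function(pos, exons, window = splice_variant_window()) {
  starts <- as.integer(exons$start)
  ends <- as.integer(exons$end)
  n <- length(starts)
  if (pos < starts[1] || pos > ends[n]) {
    stop("position ", pos, " outside transcript span [", starts[1], ", ",
         ends[n], "]")
  }
  k <- findInterval(pos, starts)           # last exon with start <= pos
  if (pos <= ends[k]) {                    # exonic
    d <- min(pos - starts[k], ends[k] - pos) + 1L
    if (window$all_exonic) {
      type <- "exonic"; relevant <- TRUE
    } else if (d <= window$exonic_bases) {
      type <- "splicing_exonic"; relevant <- TRUE
    } else {
      type <- "exonic"; relevant <- FALSE
    }
    list(variant_type = type, distance = d, exon_index = k,
         splice_relevant = relevant)
  } else {                                 # intronic, between exon k and k+1
    d_up <- pos - ends[k]
    d_down <- starts[k + 1L] - pos
    d <- min(d_up, d_down)
    exon_index <- if (d_up <= d_down) k else k + 1L
    if (window$all_intronic) {
      type <- "intronic"; relevant <- TRUE
    } else if (d <= window$intronic_bases) {
      type <- "splicing_intronic"; relevant <- TRUE
    } else {
      type <- "intronic"; relevant <- FALSE
    }
    list(variant_type = type, distance = d, exon_index = exon_index,
         splice_relevant = relevant)
  }
}

## ---- VCF annotation --------------------------------------------------------

# Anchor position for window tests: SNVs and insertions at POS, deletions /
# MNV-style records whose REF extends beyond a shared leading base at POS + 1
# (inputs are required to be left-aligned and decomposed, which makes this
# deterministic).
variant_anchor <- function(pos, ref, alt) {
  del <- nchar(ref) > 1L & nchar(alt) <= nchar(ref) &
    substr(ref, 1L, 1L) == substr(alt, 1L, 1L)
  as.integer(pos + ifelse(del, 1L, 0L))
}

# Read a VCF into a sites-only variant table (one row per record);
# CHROM/POS/REF/ALT are all the cohort engine needs, so the reader stays
# deliberately minimal (gzip accepted). Multi-allelic records are rejected;
# symbolic/structural alleles dropped with a warning.
read_variant_table <- function(vcf) {
  con <- gzfile(vcf, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L) {
    return(data.table(seqnames = character(), pos = integer(),
                      ref = character(), alt = character()))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(fields) < 8L)) {
    stop("malformed VCF record (fewer than 8 fields) in ", vcf)
  }
  m <- vapply(fields, `[`, character(5L), 1:5)
  if (any(grepl(",", m[5, ], fixed = TRUE))) {
    stop("multi-allelic record in ", vcf,
         ": decompose (left-align, trim, decompose) the VCF first")
  }
  dt <- data.table(
    seqnames = m[1, ],
    pos = as.integer(m[2, ]),
    ref = m[4, ],
    alt = m[5, ]
  )
  symbolic <- grepl("[<>\\[\\]]", dt$alt) | !nzchar(dt$alt) |
    grepl("[^ACGTNacgtn]", dt$alt)
  if (any(symbolic)) {
    warning(sum(symbolic), " symbolic/structural allele(s) dropped from ", vcf)
    dt <- dt[!symbolic]
  }
  unsorted <- dt[, is.unsorted(pos), by = seqnames]
  blocks <- rle(dt$seqnames)$values
  if (any(unsorted$V1) || anyDuplicated(blocks)) {
    stop("VCF not sorted by contig/position: ", vcf)
  }
  dt
}

# Core annotation over a variant table; returns one row per
# (variant, overlapping transcript).
annotate_variant_table <- function(vars, index, window = splice_variant_window()) {
  vars <- copy(as.data.table(vars))
  vars[, variant_id := paste0(seqnames, ":", pos, ":", ref, ">", alt)]
  vars[, anchor_pos := variant_anchor(pos, ref, alt)]
  out <- vector("list", nrow(vars))
  if (nrow(vars)) {
    gr <- GenomicRanges::GRanges(vars$seqnames,
                                 IRanges::IRanges(vars$anchor_pos, vars$anchor_pos))
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(gr, index$tx_gr, ignore.strand = TRUE))
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    for (i in seq_along(qh)) {
      vi <- qh[i]
      txid <- names(index$tx_gr)[sh[i]]
      ex <- transcript_exons(index, txid)
      cls <- classify_variant(vars$anchor_pos[vi], ex, window)
      out[[i]] <- data.table(
        variant_id = vars$variant_id[vi], seqnames = vars$seqnames[vi],
        pos = vars$pos[vi], anchor_pos = vars$anchor_pos[vi],
        ref = vars$ref[vi], alt = vars$alt[vi], transcript_id = txid,
        gene_id = ex$gene_id[1], gene_name = ex$gene_name[1],
        variant_type = cls$variant_type, distance = cls$distance,
        exon_index = cls$exon_index, splice_relevant = cls$splice_relevant
      )
    }
  }
  ann <- rbindlist(out[lengths(out) > 0L])
  if (nrow(ann) == 0L) {
    ann <- data.table(
      variant_id = character(), seqnames = character(), pos = integer(),
      anchor_pos = integer(), ref = character(), alt = character(),
      transcript_id = character(), gene_id = character(),
      gene_name = character(), variant_type = character(),
      distance = integer(), exon_index = integer(), splice_relevant = logical()
    )
  }
  setorder(ann, seqnames, pos, ref, alt, transcript_id)
  data.table::setattr(ann, "variants", vars)
  ann
}

#' Annotate a VCF of variants with per-transcript splice relevance
#'
#' Classifies each variant against every overlapping transcript under a
#' splice-variant window. Optionally writes an annotated VCF whose INFO field
#' gains four parallel comma-separated lists (`genes`, `transcripts`,
#' `distances`, `variant_types`), one entry per overlapping transcript;
#' records overlapping no indexed transcript pass through unannotated.
#'
#' Input VCFs must be sorted by contig/position and decomposed
#' (left-aligned, trimmed, one ALT per record); multi-allelic records raise
#' an error instructing decomposition.
#'
#' @param vcf Path to a VCF file (plain or bgzip-compressed).
#' @param index A `transcriptome_index` from [parse_gtf()].
#' @param window A [splice_variant_window()].
#' @param vcf_out Optional path for the annotated VCF.
#' @return A data.table with one row per (variant, overlapping transcript):
#'   `variant_id`, coordinates, alleles, `transcript_id`, `gene_id`,
#'   `gene_name`, `variant_type`, `distance`, `exon_index`,
#'   `splice_relevant`. The full variant table (including records with no
#'   overlap) is attached as attribute `"variants"`.
#' @export
annotate_variants <- function(vcf, index, window = splice_variant_window(),
                              vcf_out = NULL) {
  vars <- read_variant_table(vcf)
  ann <- annotate_variant_table(vars, index, window)
  if (!is.null(vcf_out)) {
    write_annotated_vcf(vcf, ann, vcf_out)
  }
  ann
}

# Re-read the source VCF and emit it with the four INFO lists populated.
write_annotated_vcf <- function(vcf, ann, vcf_out) {
  v <- VariantAnnotation::readVcf(vcf)
  rr <- SummarizedExperiment::rowRanges(v)
  key <- paste0(as.character(GenomicRanges::seqnames(rr)), ":",
                GenomicRanges::start(rr), ":",
                as.character(VariantAnnotation::ref(v)), ">",
                as.character(unlist(VariantAnnotation::alt(v))))
  lists <- ann[, .(
    genes = paste(gene_name, collapse = ","),
    transcripts = paste(transcript_id, collapse = ","),
    distances = paste(distance, collapse = ","),
    variant_types = paste(variant_type, collapse = ",")
  ), by = variant_id]
  idx <- match(key, lists$variant_id)
  hdr <- VariantAnnotation::header(v)
  newinfo <- S4Vectors::DataFrame(
    Number = rep(".", 4), Type = rep("String", 4),
    Description = c("Variant-overlapping gene names",
                    "Variant-overlapping transcripts",
                    "Distance to the associated exon edge per transcript",
                    "Splice variant type per transcript"),
    row.names = c("genes", "transcripts", "distances", "variant_types")
  )
  VariantAnnotation::info(hdr) <- rbind(VariantAnnotation::info(hdr), newinfo)
  VariantAnnotation::header(v) <- hdr
  VariantAnnotation::info(v)$genes <- lists$genes[idx]
  VariantAnnotation::info(v)$transcripts <- lists$transcripts[idx]
  VariantAnnotation::info(v)$distances <- lists$distances[idx]
  VariantAnnotation::info(v)$variant_types <- lists$variant_types[idx]
  VariantAnnotation::writeVcf(v, vcf_out)
  invisible(vcf_out)
}
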