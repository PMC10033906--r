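## ---- splice junction region ------------------------------------------------

#' Compute the splice-junction region for one variant annotation
#'
#' The splice-junction region is the genomic span within which observed
#' junctions are associated with a variant. For `splicing_exonic`,
#' `splicing_intronic` and `exonic` annotations it extends from the 3' end
#' of the exon directly upstream (in genomic orientation) of the
#' variant-associated exon to the 5' end of the exon directly downstream,
#' clamped to the transcript span when the associated exon is terminal. For
#' plain `intronic` annotations it is exactly the intron containing the
#' variant. For `splicing_intronic` variants the associated exon is the one
#' whose edge window captured the variant. A fixed-size override
#' (`window_size`) replaces the rule with a window of that total size
#' centered on the variant.
#'
#' @param pos Variant (anchor) position, 1-based.
#' @param variant_type One of `splicing_exonic`, `splicing_intronic`,
#'   `exonic`, `intronic`.
#' @param exon_index Genomic-order index of the associated exon.
#' @param exons The transcript's exon table (`start`/`end`, sorted).
#' @param window_size Optional total region size in bases (>= 2) centered
#'   on the variant, replacing the exon-flank rule.
#' @return `c(start, end)`, 1-based inclusive.
#' @export
splice_junction_region <- function(pos, variant_type, exon_index, exons,
                                   window_size = NULL) {
  if (!is.null(window_size)) {
    if (window_size < 2L) stop("configuration error: window_size must be >= 2")
    half <- window_size %/% 2L
    return(c(max(1L, pos - half), pos - half + as.integer(window_size) - 1L))
  }
  starts <- as.integer(exons$start)
  ends <- as.integer(exons$end)
  n <- length(starts)
  if (variant_type %in% c("splicing_exonic", "splicing_intronic", "exonic")) {
    k <- exon_index
    rs <- if (k > 1L) ends[k - 1L] + 1L else starts[1L]
    re <- if (k < n) starts[k + 1L] - 1L else ends[n]
    c(rs, re)
  } else if (variant_type == "intronic") {
    k <- findInterval(pos, starts)  # intron between exon k and k+1
    if (k < 1L || k >= n || pos <= ends[k]) {
      stop("position ", pos, " is not intronic in this transcript")
    }
    c(ends[k] + 1L, starts[k + 1L] - 1L)
  } else {
    stop("no splice junction region for variant_type ", variant_type)
  }
}

# Per-variant regions from an annotation table: one row per variant with the
# union span over its splice-relevant transcript annotations.
variant_regions <- function(ann, index, window_size = NULL) {
  rel <- ann[splice_relevant == TRUE]
  if (nrow(rel) == 0L) {
    return(data.table(variant_id = character(), seqnames = character(),
                      pos = integer(), ref = character(), alt = character(),
                      gene = character(), region_start = integer(),
                      region_end = integer()))
  }
  spans <- rel[, {
    reg <- splice_junction_region(
      anchor_pos, variant_type, exon_index,
      transcript_exons(index, transcript_id), window_size)
    .(region_start = reg[1], region_end = reg[2])
  }, by = .(variant_id, transcript_id)]
  meta <- rel[, .(seqnames = seqnames[1], pos = pos[1], ref = ref[1],
                  alt = alt[1],
                  gene = paste(sort(unique(gene_name)), collapse = ",")),
              by = variant_id]
  out <- spans[, .(region_start = min(region_start),
                   region_end = max(region_end)), by = variant_id]
  out <- meta[out, on = "variant_id"]
  setorder(out, seqnames, pos, ref, alt)
  out[]
}

## ---- association -----------------------------------------------------------

#' Associate junctions with variants through their splice-junction regions
#'
#' Emits one event per (variant, junction) pair whose region and intron span
#' intersect. Output ordering is deterministic: by variant coordinate, then
#' junction coordinate.
#'
#' @param regions Per-variant region table (internally from the annotation
#'   step): columns `variant_id`, `seqnames`, `pos`, `ref`, `alt`, `gene`,
#'   `region_start`, `region_end`.
#' @param junctions Junction table ([aggregate_junctions()] /
#'   [read_junctions_bed()]).
#' @return A data.table of events: the variant columns plus `junc_start`,
#'   `junc_end`, `junc_strand`, `junc_name`, `score`.
#' @export
associate_events <- function(regions, junctions) {
  empty <- data.table(
    variant_id = character(), seqnames = character(), pos = integer(),
    ref = character(), alt = character(), gene = character(),
    region_start = integer(), region_end = integer(),
    junc_start = integer(), junc_end = integer(), junc_strand = character(),
    junc_name = character(), score = integer())
  if (nrow(regions) == 0L || nrow(junctions) == 0L) return(empty)
  j <- as.data.table(junctions)[, .(seqnames, start, end, strand, name, score)]
  r <- as.data.table(regions)[, .(variant_id, seqnames, start = region_start,
                                  end = region_end)]
  setkey(j, seqnames, start, end)
  ov <- foverlaps(r, j, type = "any", nomatch = NULL)
  if (nrow(ov) == 0L) return(empty)
  ev <- ov[, .(variant_id, junc_start = start, junc_end = end,
               junc_strand = strand, junc_name = name, score)]
  ev <- regions[ev, on = "variant_id"]
  setorder(ev, seqnames, pos, ref, alt, junc_start, junc_end, junc_strand)
  ev[]
}

## ---- integrated pipeline ---------------------------------------------------

cse_result <- function(events, junction_table, variants, regions) {
  structure(list(events = events, junctions = junction_table,
                 variants = variants, regions = regions),
            class = "cse_result")
}

#' @export
print.cse_result <- function(x, ...) {
  cat("cis-splice-effects result:", nrow(x$regions), "splice-relevant",
      "variant(s),", nrow(x$junctions), "associated junction(s),",
      nrow(x$events), "event(s)\n")
  invisible(x)
}

# Shared tail of identify/associate: annotate junctions, associate, build
# the junction-centric TSV with its variants column.
cse_finish <- function(ann, regions, junctions, index, genome, out) {
  junctions <- copy(as.data.table(junctions))
  events <- associate_events(regions, junctions)
  # keep associated junctions only, renamed canonically so that identify and
  # the manual extract -> annotate -> associate chain agree byte for byte
  jsub <- junctions[name %in% unique(events$junc_name)]
  if (nrow(jsub)) {
    setorder(jsub, seqnames, start, end, strand)
    renames <- data.table(old = jsub$name,
                          new = sprintf("JUNC%06d", seq_len(nrow(jsub))))
    jsub[, name := renames$new]
    events[renames, junc_name := i.new, on = c(junc_name = "old")]
  }
  jt <- annotate_junctions(jsub, index, genome)
  jt[, variants := NA_character_]
  vlists <- events[, .(variants = paste(unique(variant_id), collapse = ",")),
                   by = junc_name]
  jt[vlists, variants := i.variants, on = c(name = "junc_name")]
  ann_j <- jt[, .(junc_name = name, junction_type = anchor, known_junction,
                  splice_site)]
  events <- ann_j[events, on = "junc_name"]
  data.table::setcolorder(events, c(
    "variant_id", "seqnames", "pos", "ref", "alt", "gene", "region_start",
    "region_end", "junc_start", "junc_end", "junc_strand", "junc_name",
    "score", "junction_type", "known_junction", "splice_site"))
  setorder(events, seqnames, pos, ref, alt, junc_start, junc_end, junc_strand)
  if (!is.null(out)) fwrite(jt, out, sep = "\t", quote = FALSE)
  cse_result(events, jt, ann, regions)
}

#' Identify cis-splice-effect events from variants plus RNA-seq alignments
#'
#' The integrated pipeline: annotate variants under the splice-variant
#' window, compute per-variant splice-junction regions, extract junctions
#' from the alignment restricted to those regions (an optimization that does
#' not change results), annotate the junctions, and associate junctions with
#' variants. The output TSV has one row per associated junction (the
#' [annotate_junctions()] columns plus a comma-separated `variants` list).
#'
#' @param vcf Path to a sorted, decomposed VCF.
#' @param alignment SAM/BAM path with aligned RNA-seq reads.
#' @param gtf A GTF path or a prebuilt `transcriptome_index`.
#' @param fasta Reference genome FASTA path (or [Rsamtools::FaFile]);
#'   `NULL` skips splice-site motifs.
#' @param window A [splice_variant_window()].
#' @param window_size Optional fixed region size (`-w`), see
#'   [splice_junction_region()].
#' @param min_anchor,min_intron,max_intron,strandness Extraction parameters,
#'   see [extract_junctions()].
#' @param out,vcf_out,bed_out Optional paths for the event TSV, the
#'   annotated VCF, and the extracted-junction BED12.
#' @return A `cse_result`: list with `events` (one row per variant-junction
#'   pair), `junctions` (annotated junction table with `variants` column),
#'   `variants` (annotation table), `regions`.
#' @export
cse_identify <- function(vcf, alignment, gtf, fasta = NULL,
                         window = splice_variant_window(), window_size = NULL,
                         min_anchor = 8L, min_intron = 70L,
                         max_intron = 500000L, strandness = 0L,
                         out = NULL, vcf_out = NULL, bed_out = NULL) {
  index <- if (inherits(gtf, "transcriptome_index")) gtf else
    parse_gtf(gtf, include_single_exon = window$include_single_exon)
  ann <- annotate_variants(vcf, index, window, vcf_out = vcf_out)
  regions <- variant_regions(ann, index, window_size)
  junctions <- if (nrow(regions)) {
    extract_junctions(
      alignment,
      region = GenomicRanges::GRanges(
        regions$seqnames, IRanges::IRanges(regions$region_start,
                                           regions$region_end)),
      min_anchor = min_anchor, min_intron = min_intron,
      max_intron = max_intron, strandness = strandness)
  } else empty_junction_table()
  if (!is.null(bed_out)) write_junctions_bed(junctions, bed_out)
  cse_finish(ann, regions, junctions, index, fasta, out)
}

#' Identify cis-splice-effect events from variants plus pre-extracted junctions
#'
#' Same as [cse_identify()] but takes the BED12 output of
#' [extract_junctions()] in lieu of an alignment file; results are limited
#' to the junctions provided.
#'
#' @inheritParams cse_identify
#' @param junctions_bed BED12 path (extract dialect) or junction data.table.
#' @return A `cse_result`, see [cse_identify()].
#' @export
cse_associate <- function(vcf, junctions_bed, gtf, fasta = NULL,
                          window = splice_variant_window(), window_size = NULL,
                          out = NULL, vcf_out = NULL) {
  index <- if (inherits(gtf, "transcriptome_index")) gtf else
    parse_gtf(gtf, include_single_exon = window$include_single_exon)
  ann <- annotate_variants(vcf, index, window, vcf_out = vcf_out)
  regions <- variant_regions(ann, index, window_size)
  junctions <- if (is.character(junctions_bed)) read_junctions_bed(junctions_bed)
    else as.data.table(junctions_bed)
  cse_finish(ann, regions, junctions, index, fasta, out)
}
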