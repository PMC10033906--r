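## ---- CIGAR walk ------------------------------------------------------------

#' Junction observations from CIGAR strings
#'
#' Walks each CIGAR along the reference and emits one junction observation
#' per `N` (skipped region) operator. Reference-consuming operators are
#' `M`, `D`, `N`, `=` and `X`; insertions and clips consume no reference.
#' The anchors are the reference-consuming span between the read end (or the
#' adjacent `N`) and the `N` operator; deletions therefore count toward the
#' anchor. Records whose CIGAR places an `N` at either extremity (anchor
#' would be 0, including `N` adjacent to another `N`) are skipped with a
#' warning.
#'
#' @param cigar Character vector of CIGAR strings.
#' @param pos Integer vector of 1-based leftmost mapping positions.
#' @param seqnames Optional character vector of contigs (recycled into the
#'   result).
#' @return A data.table with one row per junction observation: `record`
#'   (index into the input), `seqnames` (if given), `intron_start`,
#'   `intron_end` (1-based, inclusive), `left_anchor`, `right_anchor`.
#' @export
cigar_junctions <- function(cigar, pos, seqnames = NULL) {
  stopifnot(length(cigar) == length(pos))
  if (length(cigar) == 0L) {
    return(data.table(record = integer(), seqnames = character(),
                      intron_start = integer(), intron_end = integer(),
                      left_anchor = integer(), right_anchor = integer()))
  }
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))
  if (any(vapply(toks, function(x) sum(nchar(x)), 0L) != nchar(cigar))) {
    stop("invalid CIGAR string: ",
         cigar[which(vapply(toks, function(x) sum(nchar(x)), 0L) != nchar(cigar))[1]])
  }
  nops <- lengths(toks)
  flat <- unlist(toks, use.names = FALSE)
  dt <- data.table(
    record = rep(seq_along(cigar), nops),
    len = as.integer(sub("[MIDNSHP=X]$", "", flat)),
    op = sub("^\\d+", "", flat)
  )
  dt[, ref_len := len * (op %chin% c("M", "D", "N", "=", "X"))]
  dt[, ref_before := cumsum(data.table::shift(ref_len, fill = 0L)), by = record]
  # anchor segment index: ops between the (g)th and (g+1)th N get g_after = g
  dt[, g_after := cumsum(op == "N") - (op == "N"), by = record]
  anchors <- dt[op != "N",
                .(anchor = sum(ref_len)), by = .(record, g = g_after)]
  ns <- dt[op == "N", .(record, g_after, ref_before, len)]
  if (nrow(ns) == 0L) {
    out <- data.table(record = integer(), intron_start = integer(),
                      intron_end = integer(), left_anchor = integer(),
                      right_anchor = integer())
    if (!is.null(seqnames)) out[, seqnames := character()]
    return(out[])
  }
  # the j-th N of a record (g_after = j - 1) is flanked by non-N segments
  # j - 1 (left) and j (right)
  ns[anchors, left_anchor := i.anchor, on = c("record", g_after = "g")]
  ns[anchors[, .(record, g = g - 1L, anchor)], right_anchor := i.anchor,
     on = c("record", g_after = "g")]
  ns[is.na(left_anchor), left_anchor := 0L]
  ns[is.na(right_anchor), right_anchor := 0L]
  bad <- unique(ns[left_anchor == 0L | right_anchor == 0L, record])
  if (length(bad)) {
    warning(length(bad), " record(s) skipped: CIGAR N operator at a read ",
            "extremity (zero-length anchor)")
    ns <- ns[!record %in% bad]
  }
  out <- ns[, .(
    record,
    intron_start = pos[record] + ref_before,
    intron_end = pos[record] + ref_before + len - 1L,
    left_anchor, right_anchor
  )]
  if (!is.null(seqnames)) out[, seqnames := seqnames[record]]
  setorder(out, record, intron_start)
  out[]
}

## ---- strand inference ------------------------------------------------------

#' Infer the transcription strand of a junction-bearing read
#'
#' @param flag Integer vector of SAM flags.
#' @param xs Optional character vector of aligner `XS`-style strand tags
#'   (`"+"`, `"-"`, or `NA`).
#' @param strandness Library strandness: `0` unstranded (use the `XS` tag,
#'   else unknown), `1` first-strand/RF (transcription strand is opposite the
#'   orientation of read 1 and equal to read 2's), `2` second-strand/FR (the
#'   reverse mapping). Single-end reads are treated as read 1.
#' @return Character vector of `"+"`, `"-"` or `"."` (unknown).
#' @export
infer_strand <- function(flag, xs = NULL, strandness = 0L) {
  if (!strandness %in% 0:2) stop("strandness must be 0, 1 or 2")
  if (strandness == 0L) {
    if (is.null(xs)) return(rep(".", length(flag)))
    out <- ifelse(is.na(xs) | !xs %in% c("+", "-"), ".", xs)
    return(out)
  }
  is_read2 <- bitwAnd(flag, 128L) > 0L
  reverse <- bitwAnd(flag, 16L) > 0L
  orient <- ifelse(reverse, "-", "+")
  flip <- ifelse(orient == "+", "-", "+")
  if (strandness == 1L) ifelse(is_read2, orient, flip)
  else ifelse(is_read2, flip, orient)
}

## ---- aggregation and filtering --------------------------------------------

#' Aggregate junction observations and apply anchor/intron-length filters
#'
#' Observations are grouped by `(seqnames, intron_start, intron_end, strand)`
#' (junctions on different strands, or with unknown strand, are distinct).
#' The score is the number of supporting reads; the thick bounds are the
#' union of the supporting anchors. A junction is kept iff its maximum left
#' and right anchors both reach `min_anchor` and its intron length (number of
#' skipped bases) lies in `[min_intron, max_intron]`.
#'
#' @param obs A data.table of observations: `seqnames`, `intron_start`,
#'   `intron_end`, `strand`, `left_anchor`, `right_anchor`.
#' @param min_anchor Minimum anchor length on each side (default 8).
#' @param min_intron,max_intron Intron length bounds (default 70 / 500000).
#' @return A data.table of junctions sorted by coordinate: `seqnames`,
#'   `start`, `end` (1-based intron bounds), `strand`, `score`,
#'   `thick_start`, `thick_end`, `max_left`, `max_right`, `name`
#'   (`JUNC<serial>`).
#' @export
aggregate_junctions <- function(obs, min_anchor = 8L, min_intron = 70L,
                                max_intron = 500000L) {
  if (min_intron > max_intron) {
    stop("configuration error: min_intron > max_intron")
  }
  obs <- as.data.table(obs)
  if (nrow(obs) == 0L) return(empty_junction_table())
  j <- obs[, .(score = .N, max_left = max(left_anchor),
               max_right = max(right_anchor)),
           by = .(seqnames, start = intron_start, end = intron_end, strand)]
  j[, `:=`(thick_start = start - max_left, thick_end = end + max_right)]
  j <- j[max_left >= min_anchor & max_right >= min_anchor &
           (end - start + 1L) >= min_intron & (end - start + 1L) <= max_intron]
  setorder(j, seqnames, start, end, strand)
  j[, name := sprintf("JUNC%06d", seq_len(.N))]
  data.table::setcolorder(j, c("seqnames", "start", "end", "strand", "score",
                               "thick_start", "thick_end", "max_left",
                               "max_right", "name"))
  j[]
}

empty_junction_table <- function() {
  data.table(seqnames = character(), start = integer(), end = integer(),
             strand = character(), score = integer(), thick_start = integer(),
             thick_end = integer(), max_left = integer(),
             max_right = integer(), name = character())
}

## ---- alignment-file extraction --------------------------------------------

# Ensure a coordinate-sorted, indexed BAM; SAM input is converted on the fly.
as_indexed_bam <- function(alignment) {
  ext <- tolower(tools::file_ext(alignment))
  if (ext == "sam") {
    dest <- tempfile(fileext = "")
    alignment <- Rsamtools::asBam(alignment, destination = dest,
                                  overwrite = TRUE, indexDestination = TRUE)
  } else if (!file.exists(paste0(alignment, ".bai"))) {
    Rsamtools::indexBam(alignment)
  }
  alignment
}

#' Extract splice junctions from an alignment file
#'
#' Infers exon-exon junctions from the `N` (skipped region) CIGAR operators
#' of mapped reads, aggregates read support per junction, and applies the
#' anchor and intron-length filters of [aggregate_junctions()]. Unmapped,
#' secondary and supplementary records are ignored; duplicate-flagged and
#' QC-fail reads are excluded by default.
#'
#' When `region` is supplied, the output equals the coordinate-restricted
#' subset of whole-file extraction: junctions whose intron span overlaps the
#' region (reads are fetched from the index; every read supporting such a
#' junction necessarily overlaps the region).
#'
#' @param alignment Path to a SAM or BAM file (SAM is converted on the fly).
#' @param region Optional [GenomicRanges::GRanges] (or `"chr:start-stop"`
#'   string) restricting extraction.
#' @param min_anchor,min_intron,max_intron Filters, see
#'   [aggregate_junctions()].
#' @param strandness Library strandness passed to [infer_strand()].
#' @param keep_duplicates,keep_qcfail Include duplicate-flagged / QC-fail
#'   reads (default `FALSE`).
#' @return A junction data.table as returned by [aggregate_junctions()].
#' @export
extract_junctions <- function(alignment, region = NULL, min_anchor = 8L,
                              min_intron = 70L, max_intron = 500000L,
                              strandness = 0L, keep_duplicates = FALSE,
                              keep_qcfail = FALSE) {
  if (min_intron > max_intron) {
    stop("configuration error: min_intron > max_intron")
  }
  bam <- as_indexed_bam(alignment)
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE,
    isDuplicate = if (keep_duplicates) NA else FALSE,
    isNotPassingQualityControls = if (keep_qcfail) NA else FALSE
  )
  if (is.character(region)) {
    region <- GenomicRanges::GRanges(region)
  }
  what <- c("qname", "flag", "rname", "pos", "cigar")
  param <- if (is.null(region)) {
    Rsamtools::ScanBamParam(what = what, tag = "XS", flag = flag)
  } else {
    Rsamtools::ScanBamParam(what = what, tag = "XS", flag = flag,
                            which = GenomicRanges::reduce(region,
                                                          ignore.strand = TRUE))
  }
  chunks <- Rsamtools::scanBam(bam, param = param)
  reads <- rbindlist(lapply(chunks, function(ch) {
    data.table(qname = ch$qname, flag = ch$flag,
               seqnames = as.character(ch$rname), pos = ch$pos,
               cigar = ch$cigar,
               xs = if (!is.null(ch$tag$XS)) as.character(ch$tag$XS)
                    else rep(NA_character_, length(ch$pos)))
  }))
  if (nrow(reads)) {
    reads <- unique(reads, by = c("qname", "flag", "seqnames", "pos", "cigar"))
    reads <- reads[!is.na(cigar) & grepl("N", cigar, fixed = TRUE)]
  }
  if (nrow(reads) == 0L) return(empty_junction_table())
  obs <- cigar_junctions(reads$cigar, reads$pos, reads$seqnames)
  obs[, strand := infer_strand(reads$flag, reads$xs, strandness)[record]]
  j <- aggregate_junctions(obs, min_anchor, min_intron, max_intron)
  if (!is.null(region) && nrow(j)) {
    rdt <- data.table(seqnames = as.character(GenomicRanges::seqnames(region)),
                      start = GenomicRanges::start(region),
                      end = GenomicRanges::end(region))
    setkey(rdt, seqnames, start, end)
    ov <- foverlaps(j[, .(seqnames, start, end)], rdt,
                    type = "any", which = TRUE, nomatch = NULL)
    j <- j[sort(unique(ov$xid))]
    j[, name := sprintf("JUNC%06d", seq_len(.N))]
  }
  j[]
}

## ---- BED12 dialect ---------------------------------------------------------

#' Write junctions as BED12
#'
#' In this dialect (the `junctions extract` output format) `chromStart` /
#' `chromEnd` are the thick bounds (outermost anchor union), the two block
#' sizes are the maximum anchors, and the intron is
#' `[chromStart + blockSize1, chromEnd - blockSize2)` in 0-based half-open
#' coordinates.
#'
#' @param junctions A junction data.table from [aggregate_junctions()].
#' @param path Output path (or `""` for stdout).
#' @return `path`, invisibly.
#' @export
write_junctions_bed <- function(junctions, path) {
  j <- as.data.table(junctions)
  lines <- if (nrow(j) == 0L) character() else sprintf(
    "%s\t%d\t%d\t%s\t%d\t%s\t%d\t%d\t255,0,0\t2\t%d,%d\t0,%d",
    j$seqnames, j$thick_start - 1L, j$thick_end, j$name, j$score,
    ifelse(j$strand %in% c("+", "-"), j$strand, "."),
    j$thick_start - 1L, j$thick_end,
    j$max_left, j$max_right, j$end - j$thick_start + 1L
  )
  writeLines(lines, if (nzchar(path)) path else stdout())
  invisible(path)
}

#' Read junctions from BED12 in the extract dialect
#'
#' @param path A BED12 file written by [write_junctions_bed()] (or any BED12
#'   whose two blocks are the junction anchors).
#' @return A junction data.table as produced by [aggregate_junctions()].
#' @export
read_junctions_bed <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) return(empty_junction_table())
  if (length(strsplit(first, "\t", fixed = TRUE)[[1]]) != 12L) {
    stop("malformed BED12 (", length(strsplit(first, "\t", fixed = TRUE)[[1]]),
         " columns) in ", path)
  }
  dt <- fread(path, header = FALSE, sep = "\t",
              colClasses = list(character = c(1, 4, 6, 9, 11, 12)))
  if (ncol(dt) != 12L) {
    stop("malformed BED12 (", ncol(dt), " columns) in ", path)
  }
  setnames(dt, c("seqnames", "chromstart", "chromend", "name", "score",
                 "strand", "thickstart", "thickend", "rgb", "blockcount",
                 "blocksizes", "blockstarts"))
  sizes <- strsplit(dt$blocksizes, ",", fixed = TRUE)
  if (any(lengths(sizes) < 2L)) {
    stop("malformed BED12 row ", which(lengths(sizes) < 2L)[1], " in ", path,
         ": expected 2 blocks")
  }
  b1 <- as.integer(vapply(sizes, `[`, "", 1L))
  b2 <- as.integer(vapply(sizes, `[`, "", 2L))
  out <- data.table(
    seqnames = dt$seqnames,
    start = dt$chromstart + b1 + 1L,          # 1-based first intronic base
    end = dt$chromend - b2,                   # 1-based last intronic base
    strand = ifelse(dt$strand %in% c("+", "-"), dt$strand, "."),
    score = as.integer(dt$score),
    thick_start = dt$chromstart + 1L,
    thick_end = dt$chromend,
    max_left = b1, max_right = b2,
    name = dt$name
  )
  if (any(out$end < out$start)) {
    stop("malformed BED12 row ", which(out$end < out$start)[1], " in ", path,
         ": blocks leave no intron")
  }
  out[]
}
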