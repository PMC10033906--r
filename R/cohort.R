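## ---- primitive statistics --------------------------------------------------

#' Normalized junction usage within a splice-junction region
#'
#' A junction's norm_score in one sample is its read count divided by the
#' summed read counts of all junctions overlapping the splice-junction
#' region in that sample (0 when the region has no reads). This is a
#' PSI-like usage fraction measured on whole junctions.
#'
#' @param junction_reads Reads supporting the junction of interest.
#' @param region_reads Summed reads over all junctions overlapping the
#'   region in the same sample (including `junction_reads`).
#' @return A ratio in `[0, 1]`.
#' @export
norm_score <- function(junction_reads, region_reads) {
  ifelse(region_reads > 0, junction_reads / region_reads, 0)
}

#' Empirical event statistic across a cohort
#'
#' The mean_norm_score is the mean of the norm_scores over the
#' variant-containing samples (equal to the single norm_score when only one
#' sample carries the variant). The empirical p-value is the fraction of
#' non-variant samples whose norm_score is at least as high as the
#' mean_norm_score (ties count). Non-variant samples with no reads in the
#' region contribute norm_score 0; they are part of the null distribution.
#'
#' @param variant_scores Numeric norm_scores of the variant-containing
#'   samples (length >= 1).
#' @param nonvariant_scores Numeric norm_scores of the remaining samples;
#'   empty yields an undefined (`NA`) p-value.
#' @return A list with `mean_norm_score` and `p_value`.
#' @export
event_statistic <- function(variant_scores, nonvariant_scores) {
  stopifnot(length(variant_scores) >= 1L)
  m <- mean(variant_scores)
  p <- if (length(nonvariant_scores) == 0L) NA_real_
       else mean(nonvariant_scores >= m)
  list(mean_norm_score = m, p_value = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment with monotonicity enforcement,
#' order-preserving with the input (a thin validated wrapper around
#' [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs preserved).
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

## ---- cohort handling -------------------------------------------------------

#' Read a cohort manifest
#'
#' A cohort manifest is a TSV with columns `sample_id`, `junctions`
#' (BED12 path in the extract dialect, or a SAM/BAM alignment to extract
#' from), and `vcf` (the sample's variant calls). Sample ids must be
#' unique. Treating each cell of a single-cell experiment as an individual
#' sample uses the same manifest format.
#'
#' @param path Manifest TSV path.
#' @return A data.table with the three columns.
#' @export
read_cohort_manifest <- function(path) {
  m <- fread(path, sep = "\t", header = TRUE, colClasses = "character")
  need <- c("sample_id", "junctions", "vcf")
  if (!all(need %in% names(m))) {
    stop("cohort manifest must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(m$sample_id)) stop("duplicate sample_id in manifest")
  m[]
}

load_sample_junctions <- function(path, ...) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("sam", "bam", "cram")) extract_junctions(path, ...)
  else read_junctions_bed(path)
}

#' Score variant-junction events across a cohort
#'
#' The cohort statistical engine. Variants are pooled across all sample
#' VCFs (a sample "contains" a variant on an exact contig/pos/ref/alt
#' match), annotated under the splice-variant window, and given
#' splice-junction regions. An event is a (variant, junction) pair where
#' the junction was observed in at least one variant-containing sample and
#' its intron overlaps the variant's region. Events are filtered to the
#' requested junction classes (`N` junctions, which use no known splice
#' site, are never tested) and to those with at least `min_reads` reads of
#' evidence summed across variant-containing samples. Remaining events get
#' the empirical statistic of [event_statistic()], Benjamini-Hochberg
#' adjustment within this analysis, and a significance call at
#' `p_adjusted <= alpha`.
#'
#' Separate analyses for known junctions (`classes = "DA"`) and
#' non-reference junctions using at least one known splice site
#' (`classes = c("D", "A", "NDA")`, the default) mirror the two-track
#' analysis design; BH is applied per call to this function.
#'
#' @param manifest A manifest path or data.table from
#'   [read_cohort_manifest()].
#' @param gtf GTF path or prebuilt `transcriptome_index`.
#' @param fasta Optional genome FASTA for splice-site motifs.
#' @param classes Junction classes to test: subset of
#'   `c("DA", "NDA", "D", "A")`.
#' @param window A [splice_variant_window()].
#' @param window_size Optional fixed region size, see
#'   [splice_junction_region()].
#' @param min_reads Minimum summed reads across variant-containing samples
#'   (default 5).
#' @param alpha Significance threshold on the adjusted p-value (default
#'   0.05).
#' @param out Optional TSV output path.
#' @param ... Extraction parameters forwarded to [extract_junctions()] for
#'   alignment-backed samples.
#' @return A data.table with one row per tested event: variant columns,
#'   junction coordinates and type, `gene`, `variant_samples`,
#'   `n_variant_samples`, `total_variant_reads`, `mean_norm_score`,
#'   `p_value`, `p_adjusted`, `significant`, plus a `norm_scores` list
#'   column holding the per-sample scores (named by sample; dropped when
#'   writing TSV).
#' @export
compare_junctions <- function(manifest, gtf, fasta = NULL,
                              classes = c("D", "A", "NDA"),
                              window = splice_variant_window(),
                              window_size = NULL, min_reads = 5L,
                              alpha = 0.05, out = NULL, ...) {
  if (is.character(manifest)) manifest <- read_cohort_manifest(manifest)
  manifest <- as.data.table(manifest)
  if (nrow(manifest) == 0L) stop("empty cohort")
  stopifnot(all(classes %in% c("DA", "NDA", "D", "A")))
  index <- if (inherits(gtf, "transcriptome_index")) gtf else
    parse_gtf(gtf, include_single_exon = window$include_single_exon)
  if (!is.null(fasta) && is.character(fasta)) fasta <- genome_open(fasta)

  samples <- manifest$sample_id
  n_samples <- length(samples)

  ## per-sample variant calls, pooled
  vtabs <- lapply(seq_len(n_samples), function(i) {
    vt <- read_variant_table(manifest$vcf[i])
    if (nrow(vt)) vt[, sample_id := samples[i]]
    vt
  })
  all_vars <- rbindlist(vtabs, fill = TRUE)
  if (nrow(all_vars) == 0L) stop("no variants in any cohort sample")
  var_samples <- all_vars[, .(variant_samples = list(sort(unique(sample_id)))),
                          by = .(seqnames, pos, ref, alt)]
  uniq_vars <- var_samples[, .(seqnames, pos, ref, alt)]

  ## annotation + regions for the distinct variants
  ann <- annotate_variant_table(uniq_vars, index, window)
  regions <- variant_regions(ann, index, window_size)
  if (nrow(regions) == 0L) return(empty_event_table())
  regions[var_samples, variant_samples := i.variant_samples,
          on = c("seqnames", "pos", "ref", "alt")]

  ## per-sample junction tables, pooled with a sample_id column
  allj <- rbindlist(lapply(seq_len(n_samples), function(i) {
    j <- load_sample_junctions(manifest$junctions[i], ...)
    j <- j[, .(seqnames, start, end, strand, score)]
    j[, sample_id := samples[i]]
    j
  }))
  if (nrow(allj) == 0L) return(empty_event_table())
  setkey(allj, seqnames, start, end)

  ## junction observations inside each variant's region
  ## (foverlaps returns allj's columns plus the region's, i.-prefixed)
  reg_iv <- regions[, .(variant_id, seqnames, start = region_start,
                        end = region_end)]
  ov <- foverlaps(reg_iv, allj, type = "any", nomatch = NULL)
  if (nrow(ov) == 0L) return(empty_event_table())
  denom_dt <- ov[, .(denom = sum(score)), by = .(variant_id, sample_id)]
  vs_long <- regions[, .(sample_id = variant_samples[[1]]), by = variant_id]

  ## candidate junctions: observed in at least one variant-containing sample
  cand <- unique(ov[vs_long, on = c("variant_id", "sample_id"),
                    nomatch = NULL][, .(variant_id, seqnames, start, end,
                                        strand)])
  if (nrow(cand) == 0L) return(empty_event_table())

  ## per-(event, sample) grid of reads, denominators, norm_scores
  grid <- cand[, .(sample_id = samples),
               by = .(variant_id, seqnames, start, end, strand)]
  grid[ov, score := i.score,
       on = c("variant_id", "seqnames", "start", "end", "strand", "sample_id")]
  grid[is.na(score), score := 0L]
  grid[denom_dt, denom := i.denom, on = c("variant_id", "sample_id")]
  grid[is.na(denom), denom := 0L]
  grid[, ns := norm_score(score, denom)]
  grid[, is_vs := FALSE]
  grid[vs_long, is_vs := TRUE, on = c("variant_id", "sample_id")]
  events <- grid[, {
    m <- mean(ns[is_vs])
    nv <- ns[!is_vs]
    .(junc_strand = strand[1],
      total_variant_reads = sum(score[is_vs]),
      mean_norm_score = m,
      p_value = if (length(nv)) mean(nv >= m) else NA_real_,
      norm_scores = list(stats::setNames(ns, sample_id)))
  }, by = .(variant_id, junc_start = start, junc_end = end, strand)]
  events[, strand := NULL]
  meta <- regions[, .(variant_id, seqnames, pos, ref, alt, gene, region_start,
                      region_end,
                      variant_samples = vapply(variant_samples, paste, "",
                                               collapse = ","),
                      n_variant_samples = lengths(variant_samples))]
  events <- meta[events, on = "variant_id"]

  ## classify junctions once per distinct key
  keys <- unique(events[, .(seqnames, start = junc_start, end = junc_end,
                            strand = junc_strand)])
  keys[, junction_type := vapply(seq_len(.N), function(i) {
    classify_junction(index, seqnames[i], start[i], end[i], strand[i])$junction_type
  }, "")]
  events[keys, junction_type := i.junction_type,
         on = c("seqnames", junc_start = "start", junc_end = "end",
                junc_strand = "strand")]

  ## class + evidence filters, then BH within this analysis
  events <- events[junction_type %in% classes &
                     total_variant_reads >= min_reads]
  if (nrow(events) == 0L) return(empty_event_table())
  events[, p_adjusted := bh_adjust(p_value)]
  events[, significant := !is.na(p_adjusted) & p_adjusted <= alpha]
  setorder(events, seqnames, pos, ref, alt, junc_start, junc_end, junc_strand)
  if (!is.null(out)) {
    fwrite(events[, !"norm_scores"], out, sep = "\t", quote = FALSE)
  }
  events[]
}

empty_event_table <- function() {
  data.table(
    variant_id = character(), seqnames = character(), pos = integer(),
    ref = character(), alt = character(), gene = character(),
    region_start = integer(), region_end = integer(),
    junc_start = integer(), junc_end = integer(), junc_strand = character(),
    variant_samples = character(), n_variant_samples = integer(),
    total_variant_reads = numeric(), mean_norm_score = numeric(),
    p_value = numeric(), junction_type = character(),
    p_adjusted = numeric(), significant = logical(),
    norm_scores = list()
  )
}
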