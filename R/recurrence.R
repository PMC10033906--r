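## ---- splice-variant-window footprint ---------------------------------------

# All splice-variant-window intervals for the indexed transcripts:
# per intron-adjacent exon edge, exonic_bases into the exon and
# intronic_bases into the intron (whole exons / introns under -E / -I),
# clamped to the feature, one row per interval with its gene_id.
splice_window_intervals <- function(index, window = splice_variant_window()) {
  ex <- index$exons
  tx_in <- index$tx_introns
  parts <- list()
  if (window$all_exonic) {
    parts$ex_all <- ex[, .(seqnames, start, end, gene_id)]
  } else if (window$exonic_bases > 0L) {
    e <- window$exonic_bases
    # exon edges that abut an intron: donor-side end of exon k (k < n),
    # acceptor-side start of exon k+1 (k > 1), in genomic orientation
    left <- ex[exon_rank < n_exons_tx(index, transcript_id),
               .(seqnames, start = pmax(start, end - e + 1L), end, gene_id)]
    right <- ex[exon_rank > 1L,
                .(seqnames, start, end = pmin(end, start + e - 1L), gene_id)]
    parts$ex_edges <- rbindlist(list(left, right))
  }
  if (window$all_intronic) {
    parts$in_all <- tx_in[, .(seqnames, start, end, gene_id)]
  } else if (window$intronic_bases > 0L) {
    i <- window$intronic_bases
    up <- tx_in[, .(seqnames, start, end = pmin(end, start + i - 1L), gene_id)]
    down <- tx_in[, .(seqnames, start = pmax(start, end - i + 1L), end, gene_id)]
    parts$in_edges <- rbindlist(list(up, down))
  }
  out <- rbindlist(parts)
  if (is.null(out) || nrow(out) == 0L) {
    out <- data.table(seqnames = character(), start = integer(),
                      end = integer(), gene_id = character())
  }
  out
}

# exon counts aligned to the exon table rows
n_exons_tx <- function(index, transcript_ids) {
  index$transcripts[J(transcript_ids), on = "transcript_id", n_exons]
}

#' Gene footprint: base positions inside splice-variant windows
#'
#' Counts the distinct genomic positions lying in any of a gene's
#' splice-variant windows: for every intron-adjacent exon edge of every
#' transcript, `exonic_bases` into the exon plus `intronic_bases` into the
#' intron (under `-E` / `-I`, all exonic / intronic gene positions).
#' Positions are deduplicated across transcripts and edges. With
#' `gene = NULL` the union across all genes is returned (the denominator of
#' the joint-probability estimator).
#'
#' @param index A `transcriptome_index`.
#' @param window A [splice_variant_window()].
#' @param gene A `gene_id` (or vector of them); `NULL` for the genome-wide
#'   union footprint.
#' @return Named integer vector of footprints (or a single total for
#'   `gene = NULL`). A gene with no indexed transcript yields 0.
#' @export
gene_footprint <- function(index, window = splice_variant_window(),
                           gene = NULL) {
  iv <- splice_window_intervals(index, window)
  width_union <- function(d) {
    if (nrow(d) == 0L) return(0L)
    sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(d$start, d$end))))
  }
  if (is.null(gene)) {
    # union across genes, per contig
    return(sum(vapply(split(iv, iv$seqnames), width_union, 0L)))
  }
  vapply(stats::setNames(gene, gene), function(g) {
    sum(vapply(split(iv[gene_id == g], iv[gene_id == g]$seqnames),
               width_union, 0L))
  }, 0L)
}

## ---- binomial recurrence model ---------------------------------------------

#' Joint probability that a window position harbors a significant variant
#'
#' Estimated by dividing the number of significant splice-associated
#' variants summed over cohort samples (a variant present in three samples
#' counts three times) by the total number of base positions residing in
#' any splice-variant window across all genes.
#'
#' @param n_variants Significant splice-associated variant count, summed
#'   over samples.
#' @param total_footprint Genome-wide window footprint
#'   ([gene_footprint()] with `gene = NULL`); must be positive.
#' @return A probability, clamped to `[0, 1]` with a warning if the ratio
#'   exceeds 1.
#' @export
estimate_joint_probability <- function(n_variants, total_footprint) {
  if (total_footprint <= 0) stop("total_footprint must be positive")
  p <- n_variants / total_footprint
  if (p > 1) {
    warning("joint probability estimate exceeds 1; clamped")
    p <- 1
  }
  p
}

#' Per-sample null probability of a splice-associated variant in a gene
#'
#' Evaluates `1 - (1 - pr_va)^s` in log space
#' (`-expm1(s * log1p(-pr_va))`), numerically stable for small `pr_va`
#' and large `s`; monotone nondecreasing in both arguments.
#'
#' @param pr_va Joint probability in `[0, 1]` (vectorized).
#' @param s Gene footprint in base positions (>= 0, vectorized).
#' @return Probabilities in `[0, 1]`.
#' @export
p_null <- function(pr_va, s) {
  stopifnot(all(pr_va >= 0 & pr_va <= 1), all(s >= 0))
  out <- -expm1(s * log1p(-pr_va))
  out[pr_va == 0 | s == 0] <- 0
  out[pr_va == 1 & s > 0] <- 1
  pmin(pmax(out, 0), 1)
}

#' Gene recurrence test over a cohort's significant events
#'
#' For each gene, a sample counts as a success when it carries at least one
#' significant splice-associated variant in that gene (the variant's gene
#' assignment comes from the annotation step). The one-tailed binomial
#' p-value is the upper tail `P(X >= k | n, p_null)` with the cohort size
#' as the number of attempts and `p_null = 1 - (1 - Pr(V and A))^s`. The
#' fraction of samples, `k / n`, is reported alongside as the second
#' ranking metric.
#'
#' @param events An event table from [compare_junctions()] (only rows with
#'   `significant == TRUE` enter the model).
#' @param index The `transcriptome_index` the events were computed against.
#' @param n_samples Number of samples in the cohort.
#' @param window The [splice_variant_window()] used for the analysis (the
#'   footprint denominator uses the same window preset).
#' @param genes Genes (gene_id) to report; default: all genes carrying at
#'   least one significant splice-associated variant.
#' @return A data.table ranked by `binom_p` (ties by decreasing
#'   `fraction`): `gene`, `n`, `k`, `s`, `pr_va`, `p_null`, `binom_p`,
#'   `fraction`.
#' @export
gene_recurrence <- function(events, index, n_samples,
                            window = splice_variant_window(), genes = NULL) {
  ev <- as.data.table(events)[significant == TRUE]
  gene_map <- unique(index$exons[, .(gene_id, gene_name)])
  # one row per (variant, gene, sample): gene labels in events are
  # comma-joined gene names from the annotation step
  if (nrow(ev)) {
    long <- ev[, {
      gs <- unlist(strsplit(gene[1], ",", fixed = TRUE))
      ss <- unlist(strsplit(variant_samples[1], ",", fixed = TRUE))
      data.table::CJ(gene_name = gs, sample_id = ss, unique = TRUE)
    }, by = variant_id]
    long <- unique(long)
    long <- gene_map[long, on = "gene_name", allow.cartesian = TRUE]
  } else {
    long <- data.table(gene_id = character(), gene_name = character(),
                       variant_id = character(), sample_id = character())
  }
  if (is.null(genes)) genes <- sort(unique(long$gene_id))
  if (length(genes) == 0L) {
    return(data.table(gene = character(), gene_name = character(),
                      n = integer(), k = integer(), s = integer(),
                      pr_va = numeric(), p_null = numeric(),
                      binom_p = numeric(), fraction = numeric()))
  }
  if (!all(genes %in% index$transcripts$gene_id)) {
    stop("gene absent from annotation: ",
         setdiff(genes, index$transcripts$gene_id)[1])
  }
  n_sig_variants <- nrow(unique(long[, .(variant_id, sample_id)]))
  total_fp <- gene_footprint(index, window, gene = NULL)
  pr_va <- estimate_joint_probability(n_sig_variants, total_fp)
  s <- gene_footprint(index, window, gene = genes)
  k <- vapply(genes, function(g)
    data.table::uniqueN(long[gene_id == g, sample_id]), 0L)
  pn <- p_null(pr_va, s)
  out <- data.table(
    gene = genes,
    gene_name = gene_map$gene_name[match(genes, gene_map$gene_id)],
    n = as.integer(n_samples), k = as.integer(k), s = as.integer(s),
    pr_va = pr_va, p_null = pn,
    binom_p = stats::pbinom(k - 1L, n_samples, pn, lower.tail = FALSE),
    fraction = k / n_samples
  )
  setorder(out, binom_p, -fraction, gene)
  out[]
}

#' Pooled gene recurrence across cohorts
#'
#' Pools the samples of several cohorts into one and recomputes both
#' metrics: the binomial p-value with `n = sum of cohort sizes` and
#' successes summed across cohorts, and the fraction of samples over the
#' pooled total. Sample ids are namespaced by cohort so identical ids in
#' different cohorts stay distinct. A single cohort pools to itself.
#'
#' @param events_list Named list of event tables (one per cohort) from
#'   [compare_junctions()].
#' @param n_samples_list Integer vector of cohort sizes, aligned with
#'   `events_list`.
#' @param index,window,genes See [gene_recurrence()].
#' @return A ranked gene table as in [gene_recurrence()].
#' @export
pooled_recurrence <- function(events_list, n_samples_list, index,
                              window = splice_variant_window(), genes = NULL) {
  stopifnot(length(events_list) >= 1L,
            length(events_list) == length(n_samples_list))
  if (is.null(names(events_list))) {
    names(events_list) <- paste0("cohort", seq_along(events_list))
  }
  tagged <- lapply(names(events_list), function(nm) {
    ev <- copy(as.data.table(events_list[[nm]]))
    if (nrow(ev)) {
      ev[, variant_samples := vapply(variant_samples, function(x)
        paste(paste0(nm, "/", strsplit(x, ",", fixed = TRUE)[[1]]),
              collapse = ","), "")]
      # variants must also stay distinct across cohorts in the tally
      ev[, variant_id := paste0(nm, "/", variant_id)]
    }
    ev
  })
  pooled <- rbindlist(tagged, fill = TRUE)
  gene_recurrence(pooled, index, sum(n_samples_list), window, genes)
}
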