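## ---- simulation configuration ----------------------------------------------

#' Configuration for the synthetic splicing cohort generator
#'
#' Defines the reference layout and the cohort conditions emulated by
#' [sim_reference()] and [sim_cohort()]: multi-exon genes with canonical
#' GT-AG introns, reads spanning canonical and cryptic junctions, and a
#' cohort in which a subset of samples carries a variant that reroutes a
#' stated fraction of reads from the canonical junction(s) to a
#' non-reference junction. All randomness flows from `seed` (the cohort
#' stage uses a fixed offset of the same seed); no global RNG state leaks.
#'
#' The default cohort conditions are 20 samples of which 5 carry the
#' variant, a per-junction read depth of 50, and an effect fraction of 0.5
#' (half the affected reads reroute to the cryptic junction).
#'
#' @param seed Master seed (integer).
#' @param contig Contig name for the synthetic genome.
#' @param n_genes,exons_per_gene Gene count and exons per gene (>= 2; exon
#'   skipping needs >= 3).
#' @param exon_length,intron_length,intergenic Integer ranges
#'   (`c(min, max)`) for feature lengths in bases. Intron lengths should
#'   stay within the extraction filters (70 to 500000).
#' @param minus_strand_fraction Fraction of genes placed on `-`.
#' @param n_samples,n_variant_samples Cohort size and number of
#'   variant-carrying samples per effect gene.
#' @param read_depth Mean junction-spanning read depth per junction.
#' @param effect_fraction Fraction of reads rerouted to the cryptic
#'   junction in variant samples (in `[0, 1]`; 0 gives a null cohort).
#' @param n_effect_genes Genes carrying the planted effect (the first genes
#'   in the reference).
#' @param n_null_variant_genes Additional genes given a variant with no
#'   splicing effect (effect fraction 0), to provide null events.
#' @param null_variant_samples Variant-carrying samples per null gene.
#' @param baseline_alt_mean,baseline_alt_concentration Cross-sample
#'   baseline usage of the cryptic junction in all samples, drawn per
#'   sample and gene from a Beta distribution with this mean and
#'   concentration (mean 0 disables the baseline junction).
#' @param cryptic_type `"exon_skip"` (skips the middle exon; both splice
#'   sites annotated, junction type NDA) or `"cryptic_acceptor"` (a splice
#'   site inside the downstream exon; type D on `+` genes, A on `-`).
#' @param cryptic_shift Bases into the exon for `cryptic_acceptor`.
#' @param read_length Read length for SAM output (single-end, error-free).
#' @param output `"sam"` (reads with aM bN cM CIGARs) or `"bed"`
#'   (per-sample junction BED12 with aggregated counts).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, contig = "chr1", n_genes = 5L,
                       exons_per_gene = 3L, exon_length = c(120L, 200L),
                       intron_length = c(90L, 250L),
                       intergenic = c(300L, 600L),
                       minus_strand_fraction = 0.25,
                       n_samples = 20L, n_variant_samples = 5L,
                       read_depth = 50L, effect_fraction = 0.5,
                       n_effect_genes = 1L, n_null_variant_genes = 0L,
                       null_variant_samples = 2L,
                       baseline_alt_mean = 0,
                       baseline_alt_concentration = 30,
                       cryptic_type = c("exon_skip", "cryptic_acceptor"),
                       cryptic_shift = 17L, read_length = 100L,
                       output = c("sam", "bed")) {
  cryptic_type <- match.arg(cryptic_type)
  output <- match.arg(output)
  stopifnot(effect_fraction >= 0, effect_fraction <= 1,
            n_variant_samples <= n_samples, exons_per_gene >= 2L,
            n_effect_genes + n_null_variant_genes <= n_genes,
            exon_length[1] <= exon_length[2],
            intron_length[1] <= intron_length[2])
  if (cryptic_type == "exon_skip" && exons_per_gene < 3L) {
    stop("exon skipping requires exons_per_gene >= 3")
  }
  if (exon_length[1] < 2L * 10L || intron_length[1] < 4L) {
    stop("infeasible length ranges")
  }
  structure(as.list(environment()), class = "sim_config")
}

rint <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(range[1]:range[2], n, replace = TRUE)
}

## ---- reference generator ---------------------------------------------------

#' Generate a synthetic reference genome and transcriptome
#'
#' Builds a random genome carrying `n_genes` multi-exon genes whose introns
#' all have canonical GT-AG dinucleotides on their transcribed strand, and
#' plants, per gene, one candidate splice-disrupting variant (at the last
#' intronic base before the affected exon) together with the cryptic
#' junction it would activate. Deterministic under `config$seed`: the same
#' seed yields byte-identical FASTA and GTF.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if missing).
#' @return A `sim_reference` list: `fasta` / `gtf` paths, `index`
#'   (parsed back from the GTF), `genes`, `exons`, and `truth` — one row
#'   per gene with the planted variant, cryptic junction coordinates and
#'   expected junction type.
#' @export
sim_reference <- function(config = sim_config(), dir = tempfile("simref")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  withr::with_seed(config$seed, {
    ng <- config$n_genes
    ne <- config$exons_per_gene
    strand <- ifelse(stats::runif(ng) < config$minus_strand_fraction, "-", "+")
    exon_rows <- vector("list", ng)
    truth_rows <- vector("list", ng)
    cursor <- 0L
    append_bases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)
    genome <- character(0)
    for (g in seq_len(ng)) {
      gap <- rint(1L, config$intergenic)
      genome <- c(genome, append_bases(gap))
      cursor <- cursor + gap
      exl <- rint(ne, config$exon_length)
      inl <- rint(ne - 1L, config$intron_length)
      starts <- integer(ne); ends <- integer(ne)
      p <- cursor + 1L
      for (k in seq_len(ne)) {
        starts[k] <- p; ends[k] <- p + exl[k] - 1L
        p <- ends[k] + 1L
        if (k < ne) p <- p + inl[k]
      }
      glen <- p - 1L - cursor
      genome <- c(genome, append_bases(glen))
      # canonical dinucleotides on the transcribed strand
      for (k in seq_len(ne - 1L)) {
        is <- ends[k] + 1L; ie <- starts[k + 1L] - 1L
        if (strand[g] == "+") {
          genome[c(is, is + 1L)] <- c("G", "T")
          genome[c(ie - 1L, ie)] <- c("A", "G")
        } else {
          genome[c(is, is + 1L)] <- c("C", "T")   # AG read on minus
          genome[c(ie - 1L, ie)] <- c("A", "C")   # GT read on minus
        }
      }
      cursor <- cursor + glen
      gid <- sprintf("G%03d", g)
      exon_rows[[g]] <- data.table(
        seqnames = config$contig, start = starts, end = ends,
        strand = strand[g], transcript_id = paste0("TX", substring(gid, 2)),
        gene_id = gid, gene_name = paste0("GENE", substring(gid, 2))
      )
      ## planted variant and cryptic junction
      skip_k <- 2L  # affected exon (genomic order)
      vpos <- starts[skip_k] - 1L  # last intronic base of intron 1
      if (config$cryptic_type == "exon_skip") {
        js <- ends[1L] + 1L; je <- starts[3L] - 1L
        etype <- "NDA"
      } else {
        js <- ends[1L] + 1L
        je <- starts[skip_k] + config$cryptic_shift - 1L
        etype <- if (strand[g] == "+") "D" else "A"
      }
      truth_rows[[g]] <- data.table(
        gene_id = gid, gene_name = paste0("GENE", substring(gid, 2)),
        seqnames = config$contig, pos = vpos, junc_start = js, junc_end = je,
        strand = strand[g], expected_type = etype
      )
    }
    genome <- c(genome, append_bases(rint(1L, config$intergenic)))
    truth <- rbindlist(truth_rows)
    truth[, ref := genome[pos]]
    alt_of <- c(A = "C", C = "A", G = "T", T = "G")
    truth[, alt := alt_of[ref]]
    truth[, variant_id := paste0(seqnames, ":", pos, ":", ref, ">", alt)]
    exons <- rbindlist(exon_rows)
    fasta <- file.path(dir, "reference.fa")
    gtf <- file.path(dir, "reference.gtf")
    dna <- Biostrings::DNAStringSet(paste(genome, collapse = ""))
    names(dna) <- config$contig
    Biostrings::writeXStringSet(dna, fasta)
    idx0 <- build_transcriptome_index(exons)
    write_gtf(idx0, gtf)
    structure(list(config = config, dir = dir, fasta = fasta, gtf = gtf,
                   index = parse_gtf(gtf), exons = exons,
                   genome = paste(genome, collapse = ""), truth = truth),
              class = "sim_reference")
  })
}

#' @export
print.sim_reference <- function(x, ...) {
  cat("sim_reference:", x$config$n_genes, "genes on", x$config$contig,
      "(", nchar(x$genome), "bp ) in", x$dir, "\n")
  invisible(x)
}

## ---- cohort generator -------------------------------------------------------

# per-(sample, gene) junction count table under the rerouting model
sim_gene_counts <- function(ref, gene_truth, theta, depth) {
  ex <- ref$exons[gene_id == gene_truth$gene_id]
  setorder(ex, start)
  ne <- nrow(ex)
  introns <- data.table(start = ex$end[-ne] + 1L, end = ex$start[-1L] - 1L)
  t_mol <- stats::rbinom(1L, 2L * depth, 0.5)
  s_alt <- stats::rbinom(1L, t_mol, theta)
  affected <- if (ref$config$cryptic_type == "exon_skip") c(1L, 2L) else 1L
  cnt <- integer(ne - 1L)
  for (k in seq_len(ne - 1L)) {
    cnt[k] <- if (k %in% affected) t_mol - s_alt
              else stats::rbinom(1L, 2L * depth, 0.5)
  }
  out <- data.table(seqnames = gene_truth$seqnames, start = introns$start,
                    end = introns$end, strand = gene_truth$strand,
                    score = cnt)
  if (s_alt > 0L) {
    out <- rbind(out, data.table(
      seqnames = gene_truth$seqnames, start = gene_truth$junc_start,
      end = gene_truth$junc_end, strand = gene_truth$strand, score = s_alt))
  }
  out[score > 0L]
}

# spliced single-end reads (aM bN cM) for a junction count table
sim_reads <- function(ref, counts, read_length) {
  rows <- vector("list", nrow(counts))
  genome <- ref$genome
  for (i in seq_len(nrow(counts))) {
    n <- counts$score[i]
    a <- sample(10:(read_length - 10L), n, replace = TRUE)
    b <- read_length - a
    js <- counts$start[i]; je <- counts$end[i]
    pos <- js - a
    cigar <- sprintf("%dM%dN%dM", a, je - js + 1L, b)
    seq <- vapply(seq_len(n), function(r) {
      paste0(substr(genome, pos[r], js - 1L),
             substr(genome, je + 1L, je + b[r]))
    }, "")
    flag <- sample(c(0L, 16L), n, replace = TRUE)
    rows[[i]] <- data.table(pos = pos, flag = flag, cigar = cigar, seq = seq,
                            xs = counts$strand[i])
  }
  rbindlist(rows)
}

#' Simulate a cohort of samples over a synthetic reference
#'
#' Emits, per sample, a junction source (SAM reads with correct spliced
#' CIGARs, or aggregated junction counts as BED12) and a VCF of the
#' sample's variants, plus a cohort manifest and a truth table of the
#' planted events. The first `n_effect_genes` genes carry their variant in
#' `n_variant_samples` samples, which reroute `effect_fraction` of the
#' affected reads to the cryptic junction; the next `n_null_variant_genes`
#' genes carry a variant with no splicing effect. All samples express the
#' cryptic junction at a Beta-distributed baseline (`baseline_alt_mean`;
#' 0 disables it), and canonical junction depths carry binomial noise.
#'
#' @param ref A [sim_reference()].
#' @param dir Output directory; defaults to the reference's.
#' @return A `sim_cohort` list: `manifest` (data.table and `manifest_path`),
#'   `truth` (planted events with their variant samples), and the
#'   per-sample file paths.
#' @export
sim_cohort <- function(ref, dir = ref$dir) {
  config <- ref$config
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  withr::with_seed(config$seed + 1000003L, {
    ns <- config$n_samples
    samples <- sprintf("S%02d", seq_len(ns))
    roles <- rep("none", config$n_genes)
    roles[seq_len(config$n_effect_genes)] <- "effect"
    if (config$n_null_variant_genes > 0L) {
      roles[config$n_effect_genes + seq_len(config$n_null_variant_genes)] <-
        "null"
    }
    truth <- copy(ref$truth)
    truth[, role := roles]
    vs_list <- lapply(seq_len(config$n_genes), function(g) {
      if (roles[g] == "effect") sort(sample(samples, config$n_variant_samples))
      else if (roles[g] == "null") sort(sample(samples,
                                               config$null_variant_samples))
      else character(0)
    })
    truth[, variant_samples := vapply(vs_list, paste, "", collapse = ",")]
    truth[, effect_fraction :=
            ifelse(role == "effect", config$effect_fraction, 0)]
    bm <- config$baseline_alt_mean
    bc <- config$baseline_alt_concentration
    if (config$read_depth * max(config$effect_fraction, bm) < 1 &&
        config$n_effect_genes > 0L && config$effect_fraction > 0) {
      warning("read depth too low to realize the configured effect fraction")
    }
    junc_paths <- character(ns); vcf_paths <- character(ns)
    contig_len <- nchar(ref$genome)
    for (si in seq_len(ns)) {
      s <- samples[si]
      per_gene <- vector("list", config$n_genes)
      for (g in seq_len(config$n_genes)) {
        has_var <- s %in% vs_list[[g]]
        theta <- if (has_var && roles[g] == "effect") config$effect_fraction
                 else if (bm > 0) stats::rbeta(1L, bm * bc, (1 - bm) * bc)
                 else 0
        per_gene[[g]] <- sim_gene_counts(ref, truth[g], theta,
                                         config$read_depth)
      }
      counts <- rbindlist(per_gene)
      setorder(counts, seqnames, start, end)
      if (config$output == "bed") {
        j <- counts[, .(seqnames, start, end, strand, score,
                        thick_start = pmax(1L, start - 50L),
                        thick_end = end + 50L,
                        max_left = pmin(start - 1L, 50L),
                        max_right = 50L)]
        j[, name := sprintf("JUNC%06d", seq_len(.N))]
        junc_paths[si] <- file.path(dir, paste0(s, ".bed"))
        write_junctions_bed(j, junc_paths[si])
      } else {
        reads <- sim_reads(ref, counts, config$read_length)
        setorder(reads, pos)
        lines <- c(
          "@HD\tVN:1.6\tSO:coordinate",
          sprintf("@SQ\tSN:%s\tLN:%d", config$contig, contig_len),
          sprintf("r%06d\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*\tXS:A:%s",
                  seq_len(nrow(reads)), reads$flag, config$contig, reads$pos,
                  reads$cigar, reads$seq, reads$xs)
        )
        junc_paths[si] <- file.path(dir, paste0(s, ".sam"))
        writeLines(lines, junc_paths[si])
      }
      ## per-sample VCF of planted variants
      vg <- which(vapply(vs_list, function(v) s %in% v, TRUE))
      vrows <- truth[vg][order(pos)]
      vcf_paths[si] <- file.path(dir, paste0(s, ".vcf"))
      writeLines(c(
        "##fileformat=VCFv4.2",
        sprintf("##contig=<ID=%s,length=%d>", config$contig, contig_len),
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
        if (nrow(vrows)) sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                                 vrows$seqnames, vrows$pos, vrows$ref,
                                 vrows$alt)
      ), vcf_paths[si])
    }
    manifest <- data.table(sample_id = samples, junctions = junc_paths,
                           vcf = vcf_paths)
    manifest_path <- file.path(dir, "manifest.tsv")
    fwrite(manifest, manifest_path, sep = "\t", quote = FALSE)
    truth_path <- file.path(dir, "truth.tsv")
    fwrite(truth, truth_path, sep = "\t", quote = FALSE)
    structure(list(manifest = manifest, manifest_path = manifest_path,
                   truth = truth, truth_path = truth_path, dir = dir,
                   config = config),
              class = "sim_cohort")
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("sim_cohort:", nrow(x$manifest), "samples (",
      sum(x$truth$role == "effect"), "effect gene(s),",
      sum(x$truth$role == "null"), "null-variant gene(s) ) in", x$dir, "\n")
  invisible(x)
}
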