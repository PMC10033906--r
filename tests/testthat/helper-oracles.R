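# Independent oracles used to freeze or cross-check expected values.

# Reference-walk junction oracle built on GenomicAlignments block extraction:
# blocks are the reference-aligned segments split at N; junctions lie between
# consecutive blocks, anchors are the flanking block widths.
oracle_cigar_junctions <- function(cigar, pos) {
  blocks <- GenomicAlignments::extractAlignmentRangesOnReference(cigar, pos)
  out <- lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    if (length(b) < 2L) return(NULL)
    data.table(
      record = i,
      intron_start = IRanges::end(b)[-length(b)] + 1L,
      intron_end = IRanges::start(b)[-1L] - 1L,
      left_anchor = IRanges::width(b)[-length(b)],
      right_anchor = IRanges::width(b)[-1L]
    )
  })
  res <- rbindlist(out[!vapply(out, is.null, TRUE)])
  if (nrow(res) == 0L) {
    res <- data.table(record = integer(), intron_start = integer(),
                      intron_end = integer(), left_anchor = integer(),
                      right_anchor = integer())
  }
  setorder(res, record, intron_start)
  res[]
}

# Textbook Benjamini-Hochberg step-up oracle (explicit loop formulation).
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- Inf
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  pmin(adj, 1)
}

# Direct-summation binomial upper tail P(X >= k | n, p).
oracle_binom_upper <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i), 0))
}

# Per-base variant labeler: walks every position of a transcript span and
# labels it by explicit interval membership (independent of classify_variant).
oracle_label_positions <- function(exons, i_bases, e_bases) {
  starts <- vapply(exons, `[`, 0, 1)
  ends <- vapply(exons, `[`, 0, 2)
  span <- seq(min(starts), max(ends))
  vapply(span, function(p) {
    inx <- which(starts <= p & p <= ends)
    if (length(inx)) {
      d <- min(p - starts[inx], ends[inx] - p) + 1L
      if (d <= e_bases) "splicing_exonic" else "exonic"
    } else {
      dl <- min(p - ends[ends < p])
      dr <- min(starts[starts > p] - p)
      if (min(dl, dr) <= i_bases) "splicing_intronic" else "intronic"
    }
  }, "")
}

# Quadratic overlap scan for transcript interval queries.
oracle_overlap_scan <- function(transcripts, qstart, qend) {
  hits <- vapply(transcripts, function(t) {
    s <- min(vapply(t$exons, `[`, 0, 1))
    e <- max(vapply(t$exons, `[`, 0, 2))
    s <= qend && e >= qstart
  }, TRUE)
  sort(vapply(transcripts[hits], function(t) t$tx, ""))
}
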