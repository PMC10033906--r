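test_that("CIGAR walk turns N operators into junction observations", {
  # single junction, pure matches
  j <- cigar_junctions("50M100N50M", 1000L)
  expect_equal(j$intron_start, 1050L)
  expect_equal(j$intron_end, 1149L)
  expect_equal(j$left_anchor, 50L)
  expect_equal(j$right_anchor, 50L)
  # insertions consume no reference; the left anchor spans both M runs
  j2 <- cigar_junctions("20M10I30M200N25M", 1000L)
  expect_equal(j2$left_anchor, 50L)
  expect_equal(j2$intron_start, 1050L)
  expect_equal(j2$right_anchor, 25L)
  # two junctions share the middle segment as right/left anchor
  j3 <- cigar_junctions("30M100N30M100N30M", 500L)
  expect_equal(nrow(j3), 2L)
  expect_equal(j3$right_anchor[1], 30L)
  expect_equal(j3$left_anchor[2], 30L)
  expect_equal(j3$intron_start, c(530L, 660L))
  # deletions consume reference and extend the anchor
  j4 <- cigar_junctions("20M5D25M100N50M", 1000L)
  expect_equal(j4$left_anchor, 50L)
  expect_equal(j4$intron_start, 1050L)
  # soft clips do not
  j5 <- cigar_junctions("10S40M100N40M10S", 1000L)
  expect_equal(j5$left_anchor, 40L)
  expect_equal(j5$intron_start, 1040L)
})

test_that("records with an N at a read extremity are skipped with a warning", {
  expect_warning(j <- cigar_junctions(c("100N50M", "50M100N50M"), c(1L, 1L)),
                 "extremity")
  expect_equal(unique(j$record), 2L)
  expect_warning(cigar_junctions("50M100N", 1L), "extremity")
  expect_warning(cigar_junctions("10S100N50M", 1L), "extremity")
  expect_warning(cigar_junctions("50M100N100N50M", 1L), "extremity")
})

test_that("strand inference follows the XS tag and the RF/FR truth table", {
  # mode 0: tag or unknown
  expect_equal(infer_strand(0L, "+", 0L), "+")
  expect_equal(infer_strand(0L, NA_character_, 0L), ".")
  expect_equal(infer_strand(0L, NULL, 0L), ".")
  # all 8 (mode, mate, orientation) cases against the RF/FR truth table
  cases <- expand.grid(mode = 1:2, read2 = c(FALSE, TRUE),
                       rev = c(FALSE, TRUE))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    flag <- 0L + 128L * cs$read2 + 16L * cs$rev
    got <- infer_strand(flag, strandness = cs$mode)
    orient <- if (cs$rev) "-" else "+"
    want <- if (cs$mode == 1) {
      if (cs$read2) orient else setdiff(c("+", "-"), orient)
    } else {
      if (cs$read2) setdiff(c("+", "-"), orient) else orient
    }
    expect_equal(got, want,
                 info = sprintf("mode=%d read2=%s rev=%s", cs$mode,
                                cs$read2, cs$rev))
  }
  # spec spot checks: mode 2 read1 forward -> +; mode 1 read2 forward -> +
  expect_equal(infer_strand(0L, strandness = 2L), "+")
  expect_equal(infer_strand(128L, strandness = 1L), "+")
  expect_error(infer_strand(0L, strandness = 3L), "strandness")
})

test_that("aggregation takes the anchor union and filters on printed bounds", {
  obs <- data.table(
    seqnames = "chr1", intron_start = 1000L, intron_end = 1099L,
    strand = "+", left_anchor = c(5L, 20L), right_anchor = c(20L, 5L))
  j <- aggregate_junctions(obs)
  expect_equal(nrow(j), 1L)
  expect_equal(j$score, 2L)
  expect_equal(j$thick_start, 980L)
  expect_equal(j$thick_end, 1119L)
  # 69-base intron filtered; 70 kept; 500000 kept; 500001 filtered
  mk <- function(len) data.table(seqnames = "chr1", intron_start = 1000L,
                                 intron_end = 1000L + len - 1L, strand = "+",
                                 left_anchor = 10L, right_anchor = 10L)
  expect_equal(nrow(aggregate_junctions(mk(69L))), 0L)
  expect_equal(nrow(aggregate_junctions(mk(70L))), 1L)
  expect_equal(nrow(aggregate_junctions(mk(500000L))), 1L)
  expect_equal(nrow(aggregate_junctions(mk(500001L))), 0L)
  # junctions on different strands are distinct aggregation keys
  obs2 <- rbind(copy(obs)[, strand := "+"], copy(obs)[, strand := "-"])
  expect_equal(nrow(aggregate_junctions(obs2)), 2L)
  expect_error(aggregate_junctions(obs, min_intron = 100, max_intron = 10),
               "configuration")
})

test_that("extraction matches the reference-walk oracle on randomized reads", {
  withr::with_seed(101, {
    n <- 1200L
    reads <- lapply(seq_len(n), function(i) {
      nj <- sample(0:3, 1, prob = c(0.15, 0.45, 0.3, 0.1))
      pos <- sample(1:100000, 1)
      ops <- character()
      seg <- function() {
        # anchor segment mixing M/I/D, starting and usually ending in M
        parts <- sprintf("%dM", sample(1:60, 1))
        if (stats::runif(1) < 0.3) parts <- c(parts, sprintf("%dI", sample(1:5, 1)))
        if (stats::runif(1) < 0.3) parts <- c(parts, sprintf("%dD", sample(1:5, 1)))
        if (stats::runif(1) < 0.6) parts <- c(parts, sprintf("%dM", sample(1:30, 1)))
        paste(parts, collapse = "")
      }
      cig <- seg()
      if (stats::runif(1) < 0.2) cig <- paste0(sample(1:10, 1), "S", cig)
      for (k in seq_len(nj)) {
        cig <- paste0(cig, sample(70:5000, 1), "N", seg())
      }
      if (stats::runif(1) < 0.2) cig <- paste0(cig, sample(1:10, 1), "S")
      list(pos = pos, cigar = cig)
    })
    cig <- vapply(reads, `[[`, "", "cigar")
    pos <- vapply(reads, `[[`, 0L, "pos")
    got <- cigar_junctions(cig, pos)
    want <- oracle_cigar_junctions(cig, pos)
    expect_equal(as.data.frame(got[, .(record, intron_start, intron_end,
                                       left_anchor, right_anchor)]),
                 as.data.frame(want))
    # end-to-end through SAM: aggregated scores/anchors match an independent
    # aggregation of the oracle observations (no filtering)
    sam <- make_sam(data.table(pos = pos, cigar = cig,
                               seq = vapply(cig, function(cc) {
                                 ops <- regmatches(cc, gregexpr("\\d+[MIS]", cc))[[1]]
                                 strrep("A", sum(as.integer(sub("[MIS]", "", ops))))
                               }, "")),
                    contig_len = 2000000L)
    j <- extract_junctions(sam, min_anchor = 1L, min_intron = 1L,
                           max_intron = 10000000L)
    want[, key := paste(intron_start, intron_end)]
    agg <- want[, .(score = .N, max_left = max(left_anchor),
                    max_right = max(right_anchor)),
                by = .(intron_start, intron_end)]
    setorder(agg, intron_start, intron_end)
    expect_equal(j$start, agg$intron_start)
    expect_equal(j$end, agg$intron_end)
    expect_equal(j$score, agg$score)
    expect_equal(j$max_left, agg$max_left)
    expect_equal(j$max_right, agg$max_right)
    # score conservation: emitted support equals total N operators
    expect_equal(sum(j$score), nrow(want))
  })
})

test_that("region-restricted extraction equals the coordinate-restricted subset", {
  ref <- sim_reference(sim_config(seed = 5, n_genes = 3, output = "sam"),
                       dir = tempfile())
  co <- sim_cohort(ref)
  sam <- co$manifest$junctions[1]
  whole <- extract_junctions(sam)
  reg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1L, 1500L))
  sub <- extract_junctions(sam, region = reg)
  expected <- whole[start <= 1500L]
  expect_equal(sub$start, expected$start)
  expect_equal(sub$end, expected$end)
  expect_equal(sub$score, expected$score)
  # "chr:start-stop" string form
  sub2 <- extract_junctions(sam, region = "chr1:1-1500")
  expect_equal(sub2, sub)
})

test_that("BED12 round trip preserves junction coordinates, anchors and scores", {
  ref <- sim_reference(sim_config(seed = 6, n_genes = 2, output = "sam"),
                       dir = tempfile())
  co <- sim_cohort(ref)
  j <- extract_junctions(co$manifest$junctions[2])
  path <- tempfile(fileext = ".bed")
  write_junctions_bed(j, path)
  back <- read_junctions_bed(path)
  expect_equal(as.data.frame(back), as.data.frame(j[, names(back), with = FALSE]))
  # malformed rows are reported
  writeLines("chr1\t10\t20\tx\t1\t+", tempfile(fileext = ".bed") -> badpath)
  expect_error(read_junctions_bed(badpath), "malformed")
})
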