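test_that("norm_score divides junction reads by region reads", {
  expect_equal(norm_score(10, 10), 1.0)
  expect_equal(norm_score(5, 20), 0.25)
  expect_equal(norm_score(0, 20), 0.0)
  expect_equal(norm_score(0, 0), 0.0)  # junction absent, empty region
})

test_that("the empirical p-value counts ties and handles degenerate means", {
  st <- event_statistic(0.5, c(0.1, 0.2, 0.5, 0.6))
  expect_equal(st$mean_norm_score, 0.5)
  expect_equal(st$p_value, 0.5)  # 0.5 and 0.6 are >= the mean
  # mean of several variant samples
  st2 <- event_statistic(c(0.4, 0.6), c(0.1, 0.2, 0.5, 0.6))
  expect_equal(st2$mean_norm_score, 0.5)
  expect_equal(st2$p_value, 0.5)
  # zero mean: every norm_score qualifies
  expect_equal(event_statistic(0, c(0, 0.3, 0.9))$p_value, 1)
  # single variant sample: mean equals its norm_score
  expect_equal(event_statistic(0.73, c(0.1))$mean_norm_score, 0.73)
  # no non-variant samples: statistic undefined
  expect_true(is.na(event_statistic(0.5, numeric(0))$p_value))
})

test_that("empirical p-values match brute-force counting on random cohorts", {
  withr::with_seed(71, {
    for (rep in 1:40) {
      nv <- sample(1:5, 1); m <- sample(1:30, 1)
      v <- round(stats::runif(nv), 2)
      nvv <- round(stats::runif(m), 2)
      p <- event_statistic(v, nvv)$p_value
      cnt <- 0L
      for (x in nvv) if (x >= mean(v)) cnt <- cnt + 1L
      expect_equal(p, cnt / m)
      expect_true(p %in% ((0:m) / m))
    }
  })
})

test_that("BH adjustment matches the textbook step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  withr::with_seed(73, {
    for (rep in 1:100) {
      p <- stats::runif(sample(1:50, 1))
      adj <- bh_adjust(p)
      expect_equal(adj, oracle_bh(p))
      expect_true(all(adj >= p - 1e-15))          # never below raw p
      perm <- sample(length(p))
      expect_equal(bh_adjust(p[perm]), adj[perm]) # permutation-invariant
    }
  })
})

make_cohort <- function(seed, ...) {
  ref <- sim_reference(sim_config(seed = seed, ...), dir = tempfile())
  list(ref = ref, co = sim_cohort(ref))
}

test_that("compare_junctions recovers a strongly rerouted planted event", {
  cx <- make_cohort(14, n_genes = 4, n_effect_genes = 1,
                    n_null_variant_genes = 2, null_variant_samples = 2,
                    baseline_alt_mean = 0.05, output = "bed")
  ev <- compare_junctions(cx$co$manifest, cx$ref$index)
  tr <- cx$co$truth[role == "effect"]
  hit <- ev[variant_id == tr$variant_id & junc_start == tr$junc_start &
              junc_end == tr$junc_end]
  expect_equal(nrow(hit), 1L)
  expect_true(hit$significant)
  expect_equal(hit$variant_samples, tr$variant_samples)
  expect_equal(hit$n_variant_samples, 5L)
  # mean_norm_score is the mean over exactly the variant-containing samples
  scores <- hit$norm_scores[[1]]
  vs <- strsplit(tr$variant_samples, ",")[[1]]
  expect_equal(hit$mean_norm_score, mean(scores[vs]))
  expect_equal(hit$p_value,
               mean(scores[setdiff(names(scores), vs)] >= hit$mean_norm_score))
})

test_that("junction class and minimum-evidence filters gate testing", {
  cx <- make_cohort(15, n_genes = 3, n_effect_genes = 1,
                    baseline_alt_mean = 0.05, output = "bed")
  # DA analysis excludes the planted NDA junction and vice versa
  ev_da <- compare_junctions(cx$co$manifest, cx$ref$index, classes = "DA")
  expect_true(all(ev_da$junction_type == "DA"))
  ev_nda <- compare_junctions(cx$co$manifest, cx$ref$index)
  expect_true(all(ev_nda$junction_type %in% c("D", "A", "NDA")))
  # an extreme evidence threshold removes every event
  ev_none <- compare_junctions(cx$co$manifest, cx$ref$index,
                               min_reads = 10000L)
  expect_equal(nrow(ev_none), 0L)
  expect_error(compare_junctions(cx$co$manifest[0], cx$ref$index), "empty")
})

test_that("norm_scores sum to 1 per region for samples with reads, else 0", {
  cx <- make_cohort(16, n_genes = 3, n_effect_genes = 1,
                    baseline_alt_mean = 0.1, output = "bed")
  ev <- compare_junctions(cx$co$manifest, cx$ref$index,
                          classes = c("DA", "D", "A", "NDA"))
  # reconstruct each region's per-sample totals from all events in it
  for (vid in unique(ev$variant_id)) {
    sub <- ev[variant_id == vid]
    mat <- do.call(rbind, sub$norm_scores)
    tot <- colSums(mat)
    # all junctions of the region appear here because all classes were kept
    expect_true(all(abs(tot - 1) < 1e-9 | tot == 0))
  }
})

test_that("N junctions are never tested", {
  # hand-built cohort around fixture gene gA with an unannotated junction
  idx <- fixture_index()
  dir <- tempfile(); dir.create(dir)
  jset <- data.table(seqnames = "chr1", start = c(211L, 201L), end = c(290L, 300L),
                     strand = "+", score = c(30L, 30L),
                     thick_start = c(161L, 151L), thick_end = c(340L, 350L),
                     max_left = 50L, max_right = 50L,
                     name = c("JUNC000001", "JUNC000002"))
  beds <- vcfs <- character(6)
  for (i in 1:6) {
    beds[i] <- file.path(dir, sprintf("s%d.bed", i))
    write_junctions_bed(jset, beds[i])
    vcfs[i] <- make_vcf(
      if (i <= 2) data.table(pos = 202L, ref = "A", alt = "T")
      else data.table(pos = integer(), ref = character(), alt = character()),
      path = file.path(dir, sprintf("s%d.vcf", i)))
  }
  manifest <- data.table(sample_id = sprintf("s%d", 1:6), junctions = beds,
                         vcf = vcfs)
  ev <- compare_junctions(manifest, idx, classes = c("DA", "D", "A", "NDA"))
  expect_false(any(ev$junction_type == "N"))
  expect_true(nrow(ev) >= 1L)  # the DA junction is tested
})

test_that("an N-only cohort and the read-count filter yield no tested events", {
  idx <- fixture_index()
  dir <- tempfile(); dir.create(dir)
  # unannotated junction only, 4 reads total across variant samples
  jn <- data.table(seqnames = "chr1", start = 211L, end = 290L, strand = "+",
                   score = 2L, thick_start = 161L, thick_end = 340L,
                   max_left = 50L, max_right = 50L, name = "JUNC000001")
  jda <- data.table(seqnames = "chr1", start = 201L, end = 300L, strand = "+",
                    score = 2L, thick_start = 151L, thick_end = 350L,
                    max_left = 50L, max_right = 50L, name = "JUNC000002")
  beds <- vcfs <- character(4)
  for (i in 1:4) {
    beds[i] <- file.path(dir, sprintf("s%d.bed", i))
    write_junctions_bed(rbind(jn, jda), beds[i])
    vcfs[i] <- make_vcf(
      if (i <= 2) data.table(pos = 202L, ref = "A", alt = "T")
      else data.table(pos = integer(), ref = character(), alt = character()),
      path = file.path(dir, sprintf("s%d.vcf", i)))
  }
  manifest <- data.table(sample_id = sprintf("s%d", 1:4), junctions = beds,
                         vcf = vcfs)
  # 2 variant samples x 2 reads = 4 reads < 5: filtered before testing
  ev <- compare_junctions(manifest, idx, classes = c("DA", "D", "A", "NDA"))
  expect_equal(nrow(ev), 0L)
})
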