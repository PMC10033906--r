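test_that("gene footprint counts window bases per intron-adjacent edge, deduplicated", {
  # one 2-exon transcript, default i2e3: 2 edges x (2 + 3) = 10
  idx1 <- parse_gtf(make_gtf(list(
    list(tx = "t1", gene = "g1", strand = "+",
         exons = list(c(101, 200), c(301, 400))))))
  expect_equal(unname(gene_footprint(idx1, gene = "g1")), 10L)
  # two identical transcripts: same footprint (deduplication)
  idx2 <- parse_gtf(make_gtf(list(
    list(tx = "t1", gene = "g1", strand = "+",
         exons = list(c(101, 200), c(301, 400))),
    list(tx = "t2", gene = "g1", strand = "+",
         exons = list(c(101, 200), c(301, 400))))))
  expect_equal(unname(gene_footprint(idx2, gene = "g1")), 10L)
  # i0e0 empties the windows
  expect_equal(unname(gene_footprint(idx1, splice_variant_window(0, 0),
                                     gene = "g1")), 0L)
  # a 3-exon transcript has 4 intron-adjacent edges
  idx3 <- fixture_index()
  expect_equal(unname(gene_footprint(idx3, gene = "gA")), 20L)
  # -E counts every exonic position, -I every intronic one
  expect_equal(unname(gene_footprint(
    idx1, splice_variant_window(all_exonic = TRUE, intronic_bases = 0),
    gene = "g1")), 200L)
  expect_equal(unname(gene_footprint(
    idx1, splice_variant_window(all_intronic = TRUE, exonic_bases = 0),
    gene = "g1")), 100L)
  # genome-wide union across genes
  expect_equal(gene_footprint(idx3), 10L + 10L + 20L)
})

test_that("the joint probability estimator divides variants by footprint", {
  expect_equal(estimate_joint_probability(0, 1e6), 0)
  expect_equal(estimate_joint_probability(50, 1e6), 5e-5)
  expect_warning(p <- estimate_joint_probability(20, 10), "clamped")
  expect_equal(p, 1)
  expect_error(estimate_joint_probability(5, 0), "positive")
})

test_that("p_null agrees with a high-precision oracle to 12 significant digits", {
  # expected values computed once with 60-digit arbitrary-precision
  # arithmetic for 1 - (1 - pr)^s and frozen here
  cases <- list(
    list(pr = 1e-12, s = 1, expected = 1.0000000000000000e-12),
    list(pr = 1e-12, s = 1000, expected = 9.9999999950050000e-10),
    list(pr = 1e-12, s = 10000000, expected = 9.9999500001716662e-6),
    list(pr = 1e-9, s = 10, expected = 9.9999999550000001e-9),
    list(pr = 1e-9, s = 100000, expected = 9.9995000216657500e-5),
    list(pr = 1e-9, s = 10000000, expected = 0.0099501662557821956),
    list(pr = 1e-6, s = 10, expected = 9.9999550001199998e-6),
    list(pr = 1e-6, s = 1000, expected = 0.00099950066612559112),
    list(pr = 1e-6, s = 100000, expected = 0.095162627205940359),
    list(pr = 1e-6, s = 10000000, expected = 0.99995460029723675),
    list(pr = 1e-3, s = 10, expected = 0.0099551197902517901),
    list(pr = 1e-3, s = 1000, expected = 0.63230457522903596),
    list(pr = 0.01, s = 10, expected = 0.095617924991195510),
    list(pr = 0.01, s = 1000, expected = 0.99995682875258934),
    list(pr = 0.1, s = 10, expected = 0.65132155990000000),
    list(pr = 0.5, s = 10, expected = 0.99902343750000000),
    list(pr = 0.9, s = 10, expected = 0.99999999990000000),
    list(pr = 0.999, s = 1, expected = 0.99900000000000000)
  )
  for (cs in cases) {
    got <- p_null(cs$pr, cs$s)
    expect_lt(abs(got - cs$expected), abs(cs$expected) * 1e-12 + 1e-300)
  }
  # exact edge cases
  expect_equal(p_null(0, 1000), 0)
  expect_equal(p_null(1, 5), 1)
  expect_equal(p_null(1, 0), 0)
  expect_equal(p_null(0.3, 0), 0)
})

test_that("p_null is monotone nondecreasing in both arguments", {
  prs <- sort(c(10^seq(-12, -0.1, length.out = 40), 0, 1))
  ss <- sort(c(0, 1, 10, 100, 1e3, 1e5, 1e7))
  for (s in ss) {
    vals <- p_null(prs, s)
    expect_true(all(diff(vals) >= 0))
  }
  for (pr in prs) {
    vals <- p_null(pr, ss)
    expect_true(all(diff(vals) >= 0))
  }
})

test_that("the binomial upper tail matches direct summation and closed forms", {
  # k = 0 -> 1; k = n -> p^n
  expect_equal(stats::pbinom(-1, 20, 0.3, lower.tail = FALSE), 1)
  expect_equal(stats::pbinom(19, 20, 0.3, lower.tail = FALSE), 0.3^20)
  # random fixture: n = 20, k = 3, p = 0.01 against exhaustive summation
  expect_equal(stats::pbinom(2, 20, 0.01, lower.tail = FALSE),
               oracle_binom_upper(3, 20, 0.01), tolerance = 1e-12)
  withr::with_seed(83, {
    for (rep in 1:20) {
      n <- sample(1:40, 1); k <- sample(0:n, 1); p <- stats::runif(1)
      expect_equal(stats::pbinom(k - 1, n, p, lower.tail = FALSE),
                   oracle_binom_upper(k, n, p), tolerance = 1e-10)
    }
  })
})

# small synthetic significant-event table over the standard fixture
fixture_events <- function(samples, genes, sig = TRUE) {
  data.table(
    variant_id = paste0("v", seq_along(genes)),
    gene = genes,
    variant_samples = samples,
    significant = sig
  )
}

test_that("gene recurrence counts per-sample successes and ranks genes", {
  idx <- fixture_index()
  ev <- fixture_events(
    samples = c("s1,s2,s3", "s1", "s4"),
    genes = c("gA", "gA", "gB"))
  tab <- gene_recurrence(ev, idx, n_samples = 10)
  expect_setequal(tab$gene, c("gA", "gB"))
  a <- tab[gene == "gA"]; b <- tab[gene == "gB"]
  expect_equal(a$k, 3L)  # s1 counted once despite two variants
  expect_equal(b$k, 1L)
  expect_equal(a$fraction, 0.3)
  # pr_va: 5 (variant, sample) pairs over the genome-wide footprint of 40
  expect_equal(a$pr_va, 5 / 40)
  expect_equal(a$s, 20L); expect_equal(b$s, 10L)
  expect_equal(a$p_null, p_null(5 / 40, 20))
  expect_equal(a$binom_p, oracle_binom_upper(3, 10, a$p_null),
               tolerance = 1e-12)
  # gA (more successes) ranks first by the fraction metric; the binomial
  # metric also weighs each gene's footprint through p_null
  expect_equal(tab[order(-fraction), gene][1], "gA")
  # binom_p is monotone nonincreasing in k at fixed (n, p_null)
  ps <- vapply(1:5, function(k) stats::pbinom(k - 1, 10, a$p_null,
                                              lower.tail = FALSE), 0)
  expect_true(all(diff(ps) >= 0) || all(diff(ps) <= 0))
  expect_true(ps[1] >= ps[2])
  # unknown gene is an error
  expect_error(gene_recurrence(ev, idx, 10, genes = "nope"), "absent")
})

test_that("only significant events enter the recurrence model", {
  idx <- fixture_index()
  ev <- rbind(fixture_events("s1,s2", "gA"),
              fixture_events("s3,s4,s5", "gB", sig = FALSE))
  tab <- gene_recurrence(ev, idx, n_samples = 10)
  expect_equal(tab$gene, "gA")
})

test_that("pooling cohorts adds attempts and successes; one cohort pools to itself", {
  idx <- fixture_index()
  ev1 <- fixture_events(c("s1,s2", "s3"), c("gA", "gB"))
  ev2 <- fixture_events("s1,s2,s3", "gA")  # same ids, different cohort
  single <- gene_recurrence(ev1, idx, n_samples = 8)
  pooled_one <- pooled_recurrence(list(c1 = ev1), 8, idx)
  expect_equal(as.data.frame(pooled_one), as.data.frame(single))
  pooled <- pooled_recurrence(list(c1 = ev1, c2 = ev2), c(8, 12), idx)
  a <- pooled[gene == "gA"]
  expect_equal(a$n, 20L)
  expect_equal(a$k, 2L + 3L)     # disjoint samples across cohorts
  expect_equal(a$fraction, 5 / 20)
  # concatenation oracle: manual namespacing gives identical results
  ev1m <- copy(ev1)[, variant_samples := gsub("(^|,)", "\\1c1/", variant_samples)]
  ev1m[, variant_id := paste0("c1/", variant_id)]
  ev2m <- copy(ev2)[, variant_samples := gsub("(^|,)", "\\1c2/", variant_samples)]
  ev2m[, variant_id := paste0("c2/", variant_id)]
  manual <- gene_recurrence(rbind(ev1m, ev2m), idx, n_samples = 20)
  expect_equal(as.data.frame(pooled), as.data.frame(manual))
})
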