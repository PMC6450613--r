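make_callset <- function(calls, sex = NULL, group = "g",
                         call_rate = NULL) {
  n <- ncol(calls)
  if (is.null(colnames(calls))) colnames(calls) <- sprintf("s%02d", 1:n)
  samples <- data.frame(sample_id = colnames(calls),
                        sex = sex %||% rep(NA_character_, n),
                        call_rate = call_rate %||% colMeans(!is.na(calls)),
                        stringsAsFactors = FALSE)
  genotype_callset(group, samples, calls)
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("sample QC applies strict call-rate thresholds", {
  calls <- matrix("aa", nrow = 10, ncol = 4,
                  dimnames = list(sprintf("m%02d", 1:10), sprintf("s%d", 1:4)))
  cs <- make_callset(calls, call_rate = c(0.97, 0.99, 0.975, 0.96))
  qc <- apply_sample_qc(cs)
  # 0.97 exactly and 0.96 are removed (must exceed the threshold)
  expect_equal(qc$report$pass, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(ncol(qc$callset$calls), 2)
  # passing mean (0.99 + 0.975)/2 = 0.9825 > 0.98 -> run passes
  expect_true(qc$run_passed)

  cs2 <- make_callset(calls, call_rate = c(0.975, 0.975, 0.975, 0.975))
  qc2 <- apply_sample_qc(cs2)
  expect_false(qc2$run_passed)  # mean 0.975 <= 0.98

  cs3 <- make_callset(calls, call_rate = rep(0.99, 4))
  expect_true(apply_sample_qc(cs3)$run_passed)
})

test_that("marker classification covers the Axiom-style categories", {
  expect_equal(classify_marker(c(rep("aa", 10), rep("ab", 5), rep("bb", 2))),
               "PolyHighRes")
  expect_equal(classify_marker(c(rep("aa", 15), rep("ab", 5))), "NoMinorHom")
  expect_equal(classify_marker(rep("aa", 20)), "MonoHighRes")
  expect_equal(classify_marker(rep("bb", 20)), "MonoHighRes")
  expect_equal(classify_marker(c(rep("aa", 6), rep(NA, 4))),
               "CallRateBelowThreshold")
  # both homozygote classes present counts as fully resolved
  expect_equal(classify_marker(c(rep("aa", 5), rep("bb", 5))), "PolyHighRes")

  # partition: derived flags are mutually consistent
  cls <- marker_classification(data.frame(
    marker = sprintf("m%d", 1:4),
    category = c("PolyHighRes", "NoMinorHom", "MonoHighRes",
                 "CallRateBelowThreshold")))
  expect_equal(cls$polymorphic, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(cls$recommended, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(sum(cls$recommended),
               sum(cls$polymorphic) +
                 sum(cls$recommended & !cls$polymorphic))
})

test_that("group summaries reproduce recommended/polymorphic arithmetic", {
  # the published Nauyuk-scale proportion: 45,174 of 70,325 -> 64.2%
  cls <- marker_classification(data.frame(
    marker = sprintf("m%06d", 1:70325),
    category = c(rep("PolyHighRes", 45174), rep("MonoHighRes", 25151))))
  s <- summarize_group(cls)
  expect_equal(s$recommended, 70325)
  expect_equal(s$polymorphic, 45174)
  expect_equal(s$pct_polymorphic, 64.2)

  toy <- marker_classification(data.frame(
    marker = sprintf("t%d", 1:12),
    category = c(rep("PolyHighRes", 4), rep("MonoHighRes", 6),
                 rep("CallRateBelowThreshold", 2))))
  expect_equal(summarize_group(toy)$pct_polymorphic, 40.0)

  none <- marker_classification(data.frame(
    marker = "x", category = "CallRateBelowThreshold"))
  expect_true(is.na(summarize_group(none)$pct_polymorphic))
})

test_that("venn sharing matches brute-force set algebra", {
  # two identical sets: no uniques, everything in the intersection region
  s <- sprintf("m%d", 1:50)
  vs <- venn_sharing(list(A = s, B = s))
  expect_equal(vs$per_group$unique, c(0, 0))
  expect_equal(vs$regions$count[vs$regions$region == "A&B"], 50)
  expect_equal(vs$union_polymorphic, 50)

  set.seed(8)
  for (k in 1:10) {
    n_groups <- sample(3:4, 1)
    ids <- sprintf("x%03d", 1:80)
    sets <- setNames(lapply(seq_len(n_groups),
                            function(i) sample(ids, sample(10:60, 1))),
                     LETTERS[seq_len(n_groups)])
    vs <- venn_sharing(sets)
    # brute-force enumeration over all membership patterns
    union_ids <- unique(unlist(sets))
    pat <- vapply(union_ids, function(id) {
      paste(names(sets)[vapply(sets, function(s) id %in% s, logical(1))],
            collapse = "&")
    }, character(1))
    brute <- table(pat)
    for (r in seq_len(nrow(vs$regions))) {
      want <- if (vs$regions$region[r] %in% names(brute)) {
        as.integer(brute[[vs$regions$region[r]]])
      } else 0L
      expect_equal(vs$regions$count[r], want)
    }
    # conservation: regions sum to the union
    expect_equal(sum(vs$regions$count), length(union_ids))
    # per group: unique + shared = total
    expect_equal(vs$per_group$unique + vs$per_group$shared,
                 vs$per_group$total)
  }
})

test_that("pairwise sharing reports the share of the pair union", {
  a <- sprintf("m%d", 1:30)
  b <- sprintf("m%d", 16:40)
  ps <- pairwise_sharing(list(A = a, B = b), c("A", "B"))
  expect_equal(ps$shared, 15)
  expect_equal(ps$union, 40)
  expect_equal(ps$pct_shared, round(100 * 15 / 40, 1))

  expect_equal(pairwise_sharing(list(A = a, B = sprintf("z%d", 1:5)),
                                c("A", "B"))$pct_shared, 0)
  nested <- pairwise_sharing(list(A = a[1:10], B = a), c("A", "B"))
  expect_equal(nested$pct_shared, round(100 * 10 / 30, 1))
})

test_that("coverage reports per-chromosome density, windows and genes", {
  si <- data.frame(seqname = c("chrA", "ctg1", "ctg2"),
                   length = c(3e6, 50000, 30000),
                   is_chromosome = c(TRUE, FALSE, FALSE))
  panel <- data.frame(seqname = c("chrA", "chrA", "ctg1"),
                      pos = c(500000, 2500000, 100))
  cov <- coverage_report(panel, si)
  pc <- cov$per_chromosome
  expect_equal(pc$n_markers, 2)
  expect_equal(pc$markers_per_mb, round(2 / 3, 1))
  # middle megabase [1,000,001 - 2,000,000] holds no marker
  expect_equal(nrow(cov$empty_windows), 1)
  expect_equal(cov$empty_windows$window_start, 1000001)
  expect_equal(cov$empty_windows$window_end, 2000000)
  expect_equal(cov$n_windows, 3)
  # contig representation: 1 of 2 contigs, 50k of 80k sequence
  expect_equal(cov$unplaced$n_with_marker, 1)
  expect_equal(cov$unplaced$pct_with_marker, 50.0)
  expect_equal(cov$unplaced$pct_length_represented, round(100 * 5 / 8, 1))

  ann <- gene_annotation(data.frame(gene_id = c("g1", "g2"), seqname = "chrA",
                                    start = c(100L, 600000L),
                                    end = c(200L, 700000L), strand = "+"))
  cov2 <- coverage_report(data.frame(seqname = "chrA", pos = c(150, 201)),
                          si, ann)
  expect_equal(cov2$genes$n_represented, 1)  # 150 in g1; 201 just outside
  expect_equal(cov2$genes$represented_ids, "g1")

  expect_error(coverage_report(data.frame(seqname = "nope", pos = 1), si),
               "unknown sequence")
})

test_that("coverage conservation: windows and sequences sum to the panel", {
  g <- generate_genome(3, 80000, n_contigs = 4,
                       contig_length_range = c(2000, 8000), seed = 40)
  tv <- generate_true_variants(g, 1, groups = "a", seed = 40)
  panel <- data.frame(seqname = tv$seqname, pos = tv$pos)
  cov <- coverage_report(panel, g, window = 10000)
  expect_equal(sum(cov$per_chromosome$n_markers), cov$n_on_chromosomes)
  expect_equal(cov$n_on_chromosomes + cov$unplaced$n_markers, nrow(panel))
})

test_that("sdY sex prediction is exact without assay failures and degrades with them", {
  sdy_ids <- sprintf("sdy%d", 1:6)
  other <- sprintf("m%02d", 1:20)
  panel <- data.frame(marker_id = c(sdy_ids, other))
  afs <- matrix(0.4, nrow = 26, ncol = 1,
                dimnames = list(panel$marker_id, "g"))
  sex <- rep(c("M", "F"), each = 25)
  run <- simulate_array_run(panel, afs, c(g = 50), marker_failure_rate = 0,
                            sdy_markers = sdy_ids, sex_per_sample = sex,
                            sample_call_rate_distribution =
                              list(name = "point", value = 1),
                            seed = 50)
  ps <- predict_sex(run$g, sdy_ids)
  expect_equal(ps$concordance, 1.0)
  expect_equal(ps$n_known_sex, 50)
  expect_length(ps$discordant_samples, 0)
  # males carry 6/6 sdY calls, females 0/6
  expect_true(all(ps$predictions$n_sdy_called[sex == "M"] == 6))
  expect_true(all(ps$predictions$n_sdy_called[sex == "F"] == 0))

  conc <- vapply(c(0, 0.7, 0.95), function(fr) {
    r <- simulate_array_run(panel, afs, c(g = 50), marker_failure_rate = 0,
                            sdy_markers = sdy_ids, sex_per_sample = sex,
                            sdy_failure_rate = fr, seed = 51)
    predict_sex(r$g, sdy_ids)$concordance
  }, numeric(1))
  expect_true(all(diff(conc) <= 0))  # monotone degradation
  expect_lt(conc[3], 1.0)

  expect_error(predict_sex(run$g, c(sdy_ids, "ghost")), "absent")
})

test_that("markers with zero group AF are never called polymorphic", {
  panel <- data.frame(marker_id = sprintf("m%03d", 1:200))
  afs <- matrix(c(rep(0, 100), runif(100, 0.2, 0.5)), ncol = 1,
                dimnames = list(panel$marker_id, "g"))
  run <- simulate_array_run(panel, afs, c(g = 200), marker_failure_rate = 0,
                            sample_call_rate_distribution =
                              list(name = "point", value = 1),
                            seed = 52)
  cls <- classify_markers(run$g)
  zero_af <- cls$marker %in% panel$marker_id[1:100]
  expect_false(any(cls$polymorphic[zero_af]))
  # high-AF markers are nearly all polymorphic at n = 200
  expect_gt(mean(cls$polymorphic[!zero_af]), 0.95)
})

test_that("conversion rates divide array counts by candidate counts", {
  cs <- conversion_summary(c(a = 50, b = 25), c(a = 80, b = 100))
  expect_equal(cs$conversion_pct, c(62.5, 25.0, round(100 * 75 / 180, 1)))
  expect_equal(cs$source[3], "total")
})
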