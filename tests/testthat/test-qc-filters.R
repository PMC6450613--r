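test_that("missingness filter uses a strict >50% rule and the all-families rule", {
  fam <- make_family(c("aa", "aa"), c("ab", "ab"),
                     list(c(aa = 2, ab = 2), c(aa = 3, ab = 2)),
                     n_progeny = 10)
  # marker 1: 6/10 missing -> fail; marker 2: 5/10 missing -> pass
  rep1 <- filter_missingness(fam)
  expect_false(rep1$pass[rep1$marker == "m01"])
  expect_true(rep1$pass[rep1$marker == "m02"])

  # failing in family 1 but passing in family 2 -> retained overall
  famA <- make_family("aa", "ab", list(c(aa = 2, ab = 2)), n_progeny = 10,
                      family_id = "A")
  famB <- make_family("aa", "ab", list(c(aa = 5, ab = 5)), family_id = "B")
  both <- filter_missingness(list(famA, famB))
  expect_true(both$pass[both$marker == "m01"])
  expect_equal(both$n_families_failed[both$marker == "m01"], 1)
})

test_that("Mendelian-error detection matches transmission enumeration", {
  # the canonical example: aa x ab parents cannot produce bb progeny
  fam <- make_family(c("aa", "ab", "aa"), c("ab", "ab", "aa"),
                     list(c(aa = 4, ab = 3, bb = 1),
                          c(aa = 2, ab = 4, bb = 2),
                          c(aa = 6, ab = 2, bb = 0)))
  rep_m <- detect_mendelian_errors(fam)
  expect_false(rep_m$pass[rep_m$marker == "m01"])  # bb under aa x ab
  expect_true(rep_m$pass[rep_m$marker == "m02"])   # ab x ab allows all
  expect_false(rep_m$pass[rep_m$marker == "m03"])  # ab under aa x aa
  expect_equal(rep_m$n_errors, c(1, 0, 2))

  # exhaustive check of all parent-pair x progeny combinations against an
  # independent allele-transmission oracle
  combos <- expand.grid(p1 = c("aa", "ab", "bb"), p2 = c("aa", "ab", "bb"),
                        prog = c("aa", "ab", "bb"),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    fam_i <- make_family(combos$p1[i], combos$p2[i],
                         list(setNames(1L, combos$prog[i])))
    flagged <- attr(detect_mendelian_errors(fam_i), "error_cells")[[1]][1, 1]
    expect_equal(flagged,
                 !oracle_consistent(combos$p1[i], combos$p2[i],
                                    combos$prog[i]),
                 info = paste(combos[i, ], collapse = " x "))
  }

  # missing progeny genotypes never count as errors
  fam_na <- make_family("aa", "ab", list(c(aa = 1, ab = 1)), n_progeny = 5)
  expect_equal(detect_mendelian_errors(fam_na)$n_errors, 0)
})

test_that("injected-error recovery: full sensitivity on detectable cells, no false flags", {
  g <- generate_genome(1, 150000, seed = 8)
  tv <- generate_true_variants(g, 2, groups = "a", seed = 8)
  fam <- simulate_family(tv, n_progeny = 20, mendelian_error_rate = 0.05,
                         missing_rate = 0, distorted_fraction = 0, seed = 9)
  expect_gt(length(fam$geno), 5000)
  flags <- attr(detect_mendelian_errors(fam), "error_cells")[["fam1"]]
  # detectable = injected and inconsistent with the parents (oracle view)
  detectable <- fam$truth$error_cells
  for (i in seq_len(nrow(fam$geno))) {
    cons <- oracle_consistent(fam$parents$parent1[i], fam$parents$parent2[i],
                              fam$geno[i, ])
    detectable[i, ] <- fam$truth$error_cells[i, ] & !cons
  }
  expect_true(all(flags[detectable]))       # sensitivity 1.0
  expect_true(all(!flags[!detectable]))     # zero false flags
  expect_gt(sum(detectable), 50)
})

test_that("segregation-distortion chi-square matches hand arithmetic", {
  fam0 <- make_family("ab", "ab", list(c(aa = 25, ab = 50, bb = 25)))
  r0 <- test_segregation_distortion(fam0)
  expect_equal(r0$chisq, 0)
  expect_equal(r0$p_value, 1)
  expect_true(r0$pass)

  fam1 <- make_family("ab", "ab", list(c(aa = 40, ab = 40, bb = 20)))
  r1 <- test_segregation_distortion(fam1, alpha = 0.01)
  expect_equal(r1$chisq, 12.0)
  expect_equal(r1$df, 2)
  expect_equal(r1$p_value, pchisq(12, 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_false(r1$pass)

  # uninformative crosses are not testable
  fam2 <- make_family(c("aa", "aa"), c("aa", "bb"),
                      list(c(aa = 10), c(ab = 10)))
  expect_true(all(is.na(test_segregation_distortion(fam2)$pass)))
})

test_that("segregation test is calibrated under the null and powered under tilting", {
  g <- generate_genome(1, 1000000, seed = 10)
  tv <- generate_true_variants(g, 2, groups = "a", seed = 10)
  null_fam <- simulate_family(tv, n_progeny = 100, mendelian_error_rate = 0,
                              missing_rate = 0, distorted_fraction = 0,
                              seed = 11)
  rep_null <- test_segregation_distortion(null_fam, alpha = 0.01)
  tested <- !is.na(rep_null$pass)
  n_tested <- sum(tested)
  expect_gt(n_tested, 1000)
  type1 <- mean(!rep_null$pass[tested])
  expect_lt(abs(type1 - 0.01), 3 * sqrt(0.01 * 0.99 / n_tested))

  # power on ab x ab crosses at the default tilting strength log(2)
  cross <- data.frame(marker = sprintf("d%03d", 1:300), parent1 = "ab",
                      parent2 = "ab", stringsAsFactors = FALSE)
  dist_fam <- simulate_family(tv, cross = cross, n_progeny = 100,
                              mendelian_error_rate = 0, missing_rate = 0,
                              distorted_fraction = 1, seed = 12)
  rep_dist <- test_segregation_distortion(dist_fam, alpha = 0.01)
  expect_gt(mean(!rep_dist$pass), 0.9)
})

test_that("population MAF is inclusive at the threshold and matches allele counting", {
  # 10 samples: 3 ab + 7 aa -> MAF 3/20 = 0.15
  pop <- make_population(list(c(ab = 3, aa = 7)))
  r <- filter_population_maf(pop)
  expect_equal(r$maf, 0.15)
  expect_true(r$pass)

  # MAF exactly 0.05 passes (inclusive >=)
  pop2 <- make_population(list(c(ab = 10, aa = 90)))
  r2 <- filter_population_maf(pop2)
  expect_equal(r2$maf, 0.05)
  expect_true(r2$pass)

  # monomorphic -> MAF 0 -> fail; all-missing -> not testable
  pop3 <- population_genotypes("p", matrix(c(rep("aa", 4), rep(NA, 4)),
                                           nrow = 2, byrow = TRUE,
                                           dimnames = list(c("m1", "m2"),
                                                           NULL)))
  r3 <- filter_population_maf(pop3)
  expect_equal(r3$maf[1], 0)
  expect_false(r3$pass[1])
  expect_true(is.na(r3$pass[2]))

  # random matrices vs an independent allele-count oracle
  set.seed(99)
  for (k in 1:20) {
    geno <- matrix(sample(c("aa", "ab", "bb", NA), 60, replace = TRUE),
                   nrow = 6, dimnames = list(sprintf("m%d", 1:6), NULL))
    got <- filter_population_maf(population_genotypes("r", geno))$maf
    want <- apply(geno, 1, function(row) {
      counts <- table(factor(unlist(strsplit(row[!is.na(row)], "")),
                             levels = c("a", "b")))
      if (sum(counts) == 0) return(NA_real_)
      min(counts) / sum(counts)
    })
    expect_equal(got, unname(want))
  }
})

test_that("high-coverage record filters apply printed inclusive boundaries", {
  at_bound <- make_cand(dp = 45, qual = 20, gq = 20, mq = 30)
  expect_true(filter_highcov_record(at_bound, "design")$pass)

  over <- make_cand(dp = 46)
  r <- filter_highcov_record(over, "design")
  expect_false(r$pass)
  expect_equal(r$reason, "depth")

  # DP=3 passes the initial calling stage (1<=DP<=100) but fails design
  low_dp <- make_cand(dp = 3)
  expect_true(filter_highcov_record(low_dp, "initial")$pass)
  r2 <- filter_highcov_record(low_dp, "design")
  expect_false(r2$pass)
  expect_equal(r2$reason, "depth")

  # lower boundaries of the two stages
  expect_true(filter_highcov_record(make_cand(dp = 1), "initial")$pass)
  expect_false(filter_highcov_record(make_cand(dp = 101), "initial")$pass)
  expect_true(filter_highcov_record(make_cand(dp = 5), "design")$pass)
  expect_false(filter_highcov_record(make_cand(dp = 4), "design")$pass)
  expect_false(filter_highcov_record(make_cand(qual = 19.9), "design")$pass)
  expect_false(filter_highcov_record(make_cand(gq = 19), "design")$pass)
  expect_false(filter_highcov_record(make_cand(mq = 29.9), "design")$pass)

  # missing required field -> explicit not-testable, never a silent pass
  nofield <- make_cand(mq = NA)
  r3 <- filter_highcov_record(nofield, "design")
  expect_true(is.na(r3$pass))
  expect_equal(r3$reason, "not_testable:mq")
})

test_that("strand ambiguity and flank length rules", {
  expect_true(is_strand_ambiguous("A", "T"))
  expect_true(is_strand_ambiguous("G", "C"))
  expect_true(is_strand_ambiguous("C", "G"))
  expect_false(is_strand_ambiguous("A", "C"))
  expect_equal(is_strand_ambiguous(c("A", "A"), c("T", "G")), c(TRUE, FALSE))
  expect_error(is_strand_ambiguous("A", "N"), "single bases")

  expect_true(check_flank_length(make_cand(flank_left = strrep("A", 35),
                                           flank_right = strrep("C", 35))))
  expect_false(check_flank_length(make_cand(flank_left = strrep("A", 34),
                                            flank_right = strrep("C", 80))))
  expect_false(check_flank_length(make_cand(flank_left = "", flank_right = "")))
})

test_that("genome placement counting agrees with an independent scan", {
  # a toy genome with a planted duplicated segment (fwd + revcomp copy)
  set.seed(7)
  base <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
                collapse = "")
  # chr2 re-uses base[1..2000]; plant the duplicated segment from beyond it
  seg <- substr(base, 2501, 2560)
  seg_rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seg)))
  chr2 <- paste0(substr(base, 1, 1000), seg_rc, substr(base, 1001, 2000))
  g <- genome_assembly(c(chr01 = base, chr02 = chr2),
                       c(chr01 = TRUE, chr02 = TRUE))
  expect_equal(count_genome_placements(seg, g), 2)
  expect_equal(count_genome_placements(strrep("A", 25), g),
               count_genome_placements(strrep("T", 25), g))
  absent <- paste0(strrep("ACGT", 10))
  if (!grepl(absent, base) && !grepl(absent, chr2)) {
    expect_equal(count_genome_placements(absent, g), 0)
  }

  # 1,000 random queries vs a brute-force overlap-aware oracle
  g100 <- generate_genome(2, 50000, seed = 13)
  seqs <- g100$sequences
  queries <- vapply(1:1000, function(i) {
    sq <- seqs[[sample(2, 1)]]
    start <- sample(nchar(sq) - 40, 1)
    q <- substr(sq, start, start + 39)
    if (i %% 5 == 0) {  # mutate some so absence is exercised
      substr(q, 20, 20) <- sample(c("A", "C", "G", "T"), 1)
    }
    if (i %% 7 == 0) {
      q <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(q)))
    }
    q
  }, character(1))
  got <- count_genome_placements(queries, g100)
  oracle <- vapply(queries, function(q) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(q)))
    n <- sum(stringi::stri_count_fixed(seqs, q, overlap = TRUE))
    if (rc != q) {
      n <- n + sum(stringi::stri_count_fixed(seqs, rc, overlap = TRUE))
    }
    as.integer(n)
  }, integer(1), USE.NAMES = FALSE)
  expect_identical(got, oracle)
})

test_that("deduplication keeps one copy per tag and is idempotent", {
  t85 <- make_cand(2, id = c("t85_1", "t85_2"),
                   flank_left = c(strrep("G", 40), strrep("T", 40)))
  # t40's first record re-emits the t85_1 tag (same flanks and alleles)
  t40 <- make_cand(2, id = c("t40_1", "t40_2"), pos = c(100L, 900L),
                   flank_left = c(strrep("G", 40), strrep("GA", 20)))
  dd <- deduplicate_candidates(list(t85, t40))
  expect_equal(nrow(dd$candidates), 3)
  expect_setequal(dd$candidates$id, c("t85_1", "t85_2", "t40_2"))
  expect_equal(dd$duplicate_map,
               data.frame(kept_id = "t85_1", dropped_id = "t40_1",
                          stringsAsFactors = FALSE))

  # disjoint sets pass through unchanged
  a <- make_cand(2, flank_left = c(strrep("G", 40), strrep("T", 40)))
  b <- make_cand(2, id = c("b1", "b2"),
                 flank_left = c(strrep("AG", 20), strrep("TC", 20)))
  dd2 <- deduplicate_candidates(list(a, b))
  expect_equal(nrow(dd2$candidates), 4)

  dd3 <- deduplicate_candidates(dd2$candidates)
  expect_identical(dd3$candidates, dd2$candidates)
})

test_that("transcript ambiguity excludes multi-contig transcripts only", {
  cands <- make_cand(5, seqname = c("c1", "c2", "c3", "c3", "c4"),
                     transcript_id = c("T1", "T1", "T2", "T2", NA))
  r <- exclude_transcript_ambiguity(cands)
  expect_equal(r$pass, c(FALSE, FALSE, TRUE, TRUE, TRUE))
  # no transcript labels at all -> vacuous pass
  r2 <- exclude_transcript_ambiguity(make_cand(3))
  expect_true(all(r2$pass))
})

test_that("independent filter rules compose order-independently", {
  set.seed(42)
  n <- 50
  cands <- make_cand(n, pos = seq_len(n) * 50L,
                     ref = sample(c("A", "C"), n, TRUE),
                     alt = sample(c("T", "G"), n, TRUE),
                     flank_left = strrep("A", sample(30:40, n, TRUE)),
                     flank_right = strrep("C", 40),
                     dp = sample(1:60, n, TRUE))
  apply_rules <- function(df, order) {
    keep <- rep(TRUE, nrow(df))
    for (rule in order) {
      keep <- keep & switch(rule,
        flank = check_flank_length(df),
        strand = !is_strand_ambiguous(df$ref, df$alt),
        record = filter_highcov_record(df, "design")$pass %in% TRUE)
    }
    df$id[keep]
  }
  o1 <- apply_rules(cands, c("flank", "strand", "record"))
  o2 <- apply_rules(cands, c("record", "flank", "strand"))
  o3 <- apply_rules(cands, c("strand", "record", "flank"))
  expect_identical(o1, o2)
  expect_identical(o1, o3)
})
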