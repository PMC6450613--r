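#' Filter report constructor
#'
#' One row per marker (or record) with a `pass` column; `pass = NA` means
#' the rule was not testable for that marker (e.g. missing annotations,
#' uninformative cross). The rule name is carried as an attribute.
#' @noRd
new_filter_report <- function(df, rule) {
  stopifnot("pass" %in% names(df))
  attr(df, "rule") <- rule
  class(df) <- c("filter_report", "data.frame")
  df
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report '%s': %d markers | pass %d, fail %d, not testable %d\n",
              attr(x, "rule"), nrow(x), sum(x$pass %in% TRUE),
              sum(x$pass %in% FALSE), sum(is.na(x$pass))))
  NextMethod()
}

as_family_list <- function(fam) {
  if (inherits(fam, "family_genotypes")) list(fam) else fam
}

#' Combine per-family verdicts under the all-families removal rule
#'
#' A marker is removed only if it fails the criterion in every family in
#' which it is testable; markers untestable everywhere stay `NA`.
#' @noRd
all_families_pass <- function(fail_by_family) {
  # fail_by_family: logical matrix markers x families, NA = not testable
  tested <- rowSums(!is.na(fail_by_family)) > 0
  all_fail <- apply(fail_by_family, 1, function(r) {
    r <- r[!is.na(r)]
    length(r) > 0 && all(r)
  })
  pass <- !all_fail
  pass[!tested] <- NA
  pass
}

#' Family missingness filter
#'
#' A marker fails in a family when the fraction of progeny with missing
#' genotypes is strictly greater than `max_missing`; with several families
#' it is removed only when it fails in all families carrying it.
#'
#' @param fam a [family_genotypes()] or list of them.
#' @param max_missing maximum tolerated missing fraction (default 0.5,
#'   i.e. ">50% missing" fails).
#' @return `filter_report` with columns `marker`, `frac_missing` (worst
#'   family), `n_families_failed`, `n_families`, `pass`.
#' @export
filter_missingness <- function(fam, max_missing = 0.5) {
  stopifnot(max_missing >= 0, max_missing <= 1)
  fams <- as_family_list(fam)
  markers <- unique(unlist(lapply(fams, function(f) rownames(f$geno))))
  frac <- fail <- matrix(NA_real_, length(markers), length(fams),
                         dimnames = list(markers, NULL))
  for (j in seq_along(fams)) {
    g <- fams[[j]]$geno
    if (ncol(g) == 0) stop("family has an empty progeny set")
    fr <- rowMeans(is.na(g))
    frac[rownames(g), j] <- fr
    fail[rownames(g), j] <- fr > max_missing
  }
  fail <- fail > 0  # to logical, keeps NA
  new_filter_report(data.frame(
    marker = markers,
    frac_missing = apply(frac, 1, max, na.rm = TRUE),
    n_families_failed = rowSums(fail, na.rm = TRUE),
    n_families = rowSums(!is.na(fail)),
    pass = all_families_pass(fail),
    stringsAsFactors = FALSE), "missingness")
}

#' Progeny genotypes compatible with a parent pair
#' @noRd
consistent_genotypes <- function(p1, p2) {
  names(which(mendelian_probs(p1, p2) > 0))
}

#' Detect Mendelian-inheritance errors in family genotypes
#'
#' Flags every progeny genotype that cannot be composed from one allele of
#' each recorded parent (e.g. `bb` progeny under an `aa x ab` cross).
#' Missing progeny genotypes are never errors. A marker fails when more
#' than `tolerance` progeny cells are flagged (in every family, under the
#' all-families rule).
#'
#' @param fam a [family_genotypes()] or list of them.
#' @param tolerance flagged-cell count a marker may carry before failing
#'   (default 0: any detected error fails the marker).
#' @return `filter_report` with columns `marker`, `n_errors` (summed over
#'   families), `pass`; attribute `error_cells` holds one logical
#'   markers x progeny matrix per family.
#' @export
detect_mendelian_errors <- function(fam, tolerance = 0) {
  fams <- as_family_list(fam)
  markers <- unique(unlist(lapply(fams, function(f) rownames(f$geno))))
  fail <- matrix(NA, length(markers), length(fams),
                 dimnames = list(markers, NULL))
  nerr_total <- setNames(numeric(length(markers)), markers)
  cell_flags <- list()
  for (j in seq_along(fams)) {
    f <- fams[[j]]
    assert_genotype_codes(f$parents$parent1, "parent")
    if (anyNA(f$parents$parent1) || anyNA(f$parents$parent2)) {
      stop("parent genotypes must be known for every marker")
    }
    ok_sets <- Map(consistent_genotypes, f$parents$parent1, f$parents$parent2)
    flags <- matrix(FALSE, nrow(f$geno), ncol(f$geno),
                    dimnames = dimnames(f$geno))
    for (i in seq_len(nrow(f$geno))) {
      g <- f$geno[i, ]
      flags[i, ] <- !is.na(g) & !(g %in% ok_sets[[i]])
    }
    ne <- rowSums(flags)
    nerr_total[rownames(f$geno)] <- nerr_total[rownames(f$geno)] + ne
    fail[rownames(f$geno), j] <- ne > tolerance
    cell_flags[[f$family_id]] <- flags
  }
  rep <- new_filter_report(data.frame(
    marker = markers, n_errors = unname(nerr_total),
    pass = all_families_pass(fail), stringsAsFactors = FALSE),
    "mendelian_errors")
  attr(rep, "error_cells") <- cell_flags
  rep
}

#' Chi-square test for segregation distortion
#'
#' Tests non-missing progeny counts in each family against the Mendelian
#' expectation of the marker's cross type (`aa x ab`: 1:1 over aa/ab;
#' `ab x ab`: 1:2:1; `ab x bb`: 1:1 over ab/bb). Uninformative crosses
#' (both parents homozygous) are reported as not testable. Progeny
#' genotypes outside the expected classes are Mendelian errors, not
#' distortion, and are excluded from the counts.
#'
#' @param fam a [family_genotypes()] or list of them.
#' @param alpha significance level (default 0.01); a marker fails when
#'   `p < alpha` in every testable family (all-families rule).
#' @param pooled if `TRUE`, counts are summed across families whose cross
#'   type (expected class distribution) is identical before testing.
#' @param bonferroni if `TRUE`, alpha is divided by the number of testable
#'   markers.
#' @return `filter_report` with columns `marker`, `chisq`, `df`, `p_value`
#'   (worst = largest-statistic family, or the pooled test), `pass`.
#' @export
test_segregation_distortion <- function(fam, alpha = 0.01, pooled = FALSE,
                                        bonferroni = FALSE) {
  fams <- as_family_list(fam)
  markers <- unique(unlist(lapply(fams, function(f) rownames(f$geno))))
  count_tab <- function(f, i, classes) {
    g <- f$geno[i, ]
    vapply(classes, function(cl) sum(g == cl, na.rm = TRUE), numeric(1))
  }
  per_marker <- lapply(markers, function(mk) {
    # collect (counts, probs) per family where the marker is informative
    obs <- list()
    for (f in fams) {
      i <- match(mk, rownames(f$geno))
      if (is.na(i)) next
      pr <- mendelian_probs(f$parents$parent1[i], f$parents$parent2[i])
      classes <- names(pr)[pr > 0]
      if (length(classes) < 2) next
      obs[[length(obs) + 1]] <- list(counts = count_tab(f, i, classes),
                                     probs = pr[classes])
    }
    obs
  })
  names(per_marker) <- markers
  run_test <- function(counts, probs) {
    if (sum(counts) == 0) return(c(NA, NA, NA))
    ct <- suppressWarnings(chisq.test(counts, p = probs / sum(probs)))
    c(unname(ct$statistic), unname(ct$parameter), unname(ct$p.value))
  }
  n_testable <- sum(vapply(per_marker, length, integer(1)) > 0)
  alpha_eff <- if (bonferroni && n_testable > 0) alpha / n_testable else alpha
  res <- t(vapply(markers, function(mk) {
    obs <- per_marker[[mk]]
    if (length(obs) == 0) return(c(NA, NA, NA, NA))
    if (pooled) {
      sig <- vapply(obs, function(o) paste(names(o$probs), round(o$probs, 6),
                                           collapse = "|"), character(1))
      tests <- lapply(split(obs, sig), function(grp) {
        run_test(Reduce(`+`, lapply(grp, `[[`, "counts")), grp[[1]]$probs)
      })
    } else {
      tests <- lapply(obs, function(o) run_test(o$counts, o$probs))
    }
    tests <- tests[!vapply(tests, function(t) anyNA(t), logical(1))]
    if (length(tests) == 0) return(c(NA, NA, NA, NA))
    pvals <- vapply(tests, `[`, numeric(1), 3)
    fail <- all(pvals < alpha_eff)
    worst <- tests[[which.max(vapply(tests, `[`, numeric(1), 1))]]
    c(worst, as.numeric(!fail))
  }, numeric(4)))
  new_filter_report(data.frame(
    marker = markers, chisq = res[, 1], df = res[, 2], p_value = res[, 3],
    pass = as.logical(res[, 4]), stringsAsFactors = FALSE),
    "segregation_distortion")
}

#' Population minor-allele-frequency filter
#'
#' MAF is computed by allele counting over non-missing genotypes; a marker
#' passes when MAF >= `min_maf` (inclusive).
#'
#' @param pop a [population_genotypes()].
#' @param min_maf inclusive MAF threshold (default 0.05).
#' @return `filter_report` with columns `marker`, `maf`, `n_called`, `pass`
#'   (`NA` for all-missing markers).
#' @export
filter_population_maf <- function(pop, min_maf = 0.05) {
  stopifnot(inherits(pop, "population_genotypes"))
  g <- pop$geno
  n_aa <- rowSums(g == "aa", na.rm = TRUE)
  n_ab <- rowSums(g == "ab", na.rm = TRUE)
  n_bb <- rowSums(g == "bb", na.rm = TRUE)
  n_called <- n_aa + n_ab + n_bb
  b_count <- n_ab + 2 * n_bb
  maf <- ifelse(n_called > 0,
                pmin(b_count, 2 * n_called - b_count) / (2 * n_called), NA)
  pass <- maf >= min_maf
  new_filter_report(data.frame(
    marker = rownames(g), maf = maf, n_called = n_called, pass = pass,
    stringsAsFactors = FALSE), "population_maf")
}

#' Quality filters for high-coverage sequencing records
#'
#' Two stages, both with inclusive boundaries: the variant-calling stage
#' (`"initial"`: QUAL >= 20, MQ >= 30, GQ >= 20, 1 <= DP <= 100) and the
#' stricter array-design stage (`"design"`: 5 <= DP <= 45, QUAL >= 20,
#' GQ >= 20, MQ >= 30). Records missing a required field are reported as
#' not testable with an explicit reason, never silently passed.
#'
#' @param candidates candidate table (see [simulate_platform_callset()]).
#' @param stage `"initial"` or `"design"`.
#' @return `filter_report` with columns `id`, `pass`, `reason` (first
#'   failing rule, or `not_testable:<field>`).
#' @export
filter_highcov_record <- function(candidates, stage = c("initial", "design")) {
  stage <- match.arg(stage)
  rules <- if (stage == "initial") {
    list(depth = function(x) x$dp >= 1 & x$dp <= 100,
         qual = function(x) x$qual >= 20,
         genotype_quality = function(x) x$gq >= 20,
         mapping_quality = function(x) x$mq >= 30)
  } else {
    list(depth = function(x) x$dp >= 5 & x$dp <= 45,
         qual = function(x) x$qual >= 20,
         genotype_quality = function(x) x$gq >= 20,
         mapping_quality = function(x) x$mq >= 30)
  }
  fields <- c(depth = "dp", qual = "qual", genotype_quality = "gq",
              mapping_quality = "mq")
  n <- nrow(candidates)
  pass <- rep(TRUE, n)
  reason <- rep(NA_character_, n)
  for (rule in names(rules)) {
    fld <- candidates[[fields[[rule]]]]
    missing_fld <- if (is.null(fld)) rep(TRUE, n) else is.na(fld)
    ok <- if (is.null(fld)) rep(NA, n) else rules[[rule]](candidates)
    nt <- missing_fld & is.na(reason)
    reason[nt] <- paste0("not_testable:", fields[[rule]])
    pass[nt] <- NA
    fails <- !missing_fld & !ok & !is.na(pass) & pass
    reason[fails] <- rule
    pass[fails] <- FALSE
  }
  new_filter_report(data.frame(
    id = candidates$id, pass = pass, reason = reason,
    stringsAsFactors = FALSE), paste0("highcov_", stage))
}

#' Is an allele pair strand-ambiguous (A/T or C/G)?
#'
#' A/T and C/G SNPs read identically on both strands and need twice as many
#' assays on hybridisation arrays; designs usually drop them.
#'
#' @param ref,alt single-base allele vectors.
#' @return logical vector.
#' @export
is_strand_ambiguous <- function(ref, alt) {
  if (any(!ref %in% DNA_BASES) || any(!alt %in% DNA_BASES)) {
    stop("alleles must be single bases in A/C/G/T")
  }
  pair <- paste(pmin(ref, alt), pmax(ref, alt))
  pair %in% c("A T", "C G")
}

#' Flank-length requirement for probe design
#'
#' @param candidates candidate table with `flank_left`/`flank_right`.
#' @param min_flank minimum flank on each side (bp, default 35).
#' @return logical vector: `TRUE` when both flanks are long enough.
#' @export
check_flank_length <- function(candidates, min_flank = 35) {
  nchar(candidates$flank_left) >= min_flank &
    nchar(candidates$flank_right) >= min_flank
}

#' Count exact genome placements of a query sequence
#'
#' Counts exact, possibly overlapping occurrences of each query and of its
#' reverse complement across all assembly sequences. A palindromic query
#' (equal to its own reverse complement) is counted once per physical
#' locus. Callers keep candidates whose flank-with-allele sequence places
#' exactly once.
#'
#' @param query character vector of DNA queries (each >= 20 bp).
#' @param genome a [genome_assembly()].
#' @return integer vector of placement counts.
#' @export
count_genome_placements <- function(query, genome) {
  stopifnot(inherits(genome, "genome_assembly"))
  if (any(nchar(query) < 20)) stop("queries must be >= 20 bp")
  assert_dna(query, "query")
  subject <- Biostrings::DNAStringSet(genome$sequences)
  vapply(query, function(q) {
    n <- sum(Biostrings::vcountPattern(q, subject))
    rc <- revcomp(q)
    if (rc != q) n <- n + sum(Biostrings::vcountPattern(rc, subject))
    as.integer(n)
  }, integer(1), USE.NAMES = FALSE)
}

#' Deduplicate candidates across call sets
#'
#' Two candidates are duplicates when their flank+allele sequences and
#' unordered allele pairs are identical (e.g. the same GBS tag emitted by
#' two trim-parameter runs). The earliest occurrence in the supplied order
#' is retained; the operation is idempotent.
#'
#' @param sets a list of candidate tables (earliest has priority), or a
#'   single table.
#' @return list with `candidates` (the retained table) and `duplicate_map`
#'   (data.frame `kept_id`, `dropped_id`).
#' @export
deduplicate_candidates <- function(sets) {
  if (is.data.frame(sets)) sets <- list(sets)
  shared_cols <- Reduce(intersect, lapply(sets, names))
  all_c <- do.call(rbind, lapply(sets, function(s) {
    as.data.frame(s)[, shared_cols, drop = FALSE]
  }))
  if (nrow(all_c) == 0) {
    return(list(candidates = all_c,
                duplicate_map = data.frame(kept_id = character(0),
                                           dropped_id = character(0))))
  }
  key <- paste(all_c$flank_left, pmin(all_c$ref, all_c$alt),
               pmax(all_c$ref, all_c$alt), all_c$flank_right, sep = "|")
  first <- !duplicated(key)
  kept_for <- all_c$id[first][match(key, key[first])]
  dup_map <- data.frame(kept_id = kept_for[!first],
                        dropped_id = all_c$id[!first],
                        stringsAsFactors = FALSE)
  kept <- all_c[first, , drop = FALSE]
  rownames(kept) <- NULL
  list(candidates = kept, duplicate_map = dup_map)
}

#' Exclude transcript-ambiguous candidates
#'
#' When candidates originating from two or more distinct source sequences
#' (contigs) claim the same transcript, the transcript's placement is
#' ambiguous and all its candidates are excluded. Candidates without a
#' transcript label pass vacuously.
#'
#' @param candidates candidate table with `transcript_id` populated where
#'   applicable (NA elsewhere) and `seqname` as the source contig.
#' @return `filter_report` with columns `id`, `transcript_id`, `pass`,
#'   `reason`.
#' @export
exclude_transcript_ambiguity <- function(candidates) {
  tid <- candidates$transcript_id
  ambiguous <- character(0)
  has_t <- !is.na(tid)
  if (any(has_t)) {
    n_contigs <- tapply(candidates$seqname[has_t], tid[has_t],
                        function(x) length(unique(x)))
    ambiguous <- names(n_contigs)[n_contigs >= 2]
  }
  bad <- has_t & tid %in% ambiguous
  new_filter_report(data.frame(
    id = candidates$id, transcript_id = tid, pass = !bad,
    reason = ifelse(bad, "transcript_ambiguity", NA_character_),
    stringsAsFactors = FALSE), "transcript_ambiguity")
}
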