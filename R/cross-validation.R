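#' Cross-validate candidate SNPs between two platforms
#'
#' Two candidates match when they share the genome sequence, the 1-based
#' position and the unordered allele pair. Candidates lacking a genome
#' placement are skipped; positions carried by several candidates with
#' different alternate alleles within one set (multi-allelic collisions)
#' are excluded from matching and logged.
#'
#' @param set_a,set_b candidate tables placed on the same assembly.
#' @return object of class `cross_validation`: list with `pairs`
#'   (data.frame `id_a`, `id_b`, `platform_a`, `platform_b`),
#'   `matched_ids` (ids from both sets), `n_unplaced_skipped`,
#'   `n_multiallelic_excluded`.
#' @export
cross_validate <- function(set_a, set_b) {
  prep <- function(s) {
    placed <- !is.na(s$seqname) & !is.na(s$pos)
    s <- s[placed, , drop = FALSE]
    poskey <- paste(s$seqname, s$pos, sep = ":")
    allele <- paste(pmin(s$ref, s$alt), pmax(s$ref, s$alt), sep = "/")
    fullkey <- paste(poskey, allele, sep = ":")
    # drop exact duplicates, then positions with conflicting allele pairs
    keep <- !duplicated(fullkey)
    s <- s[keep, , drop = FALSE]
    poskey <- poskey[keep]; fullkey <- fullkey[keep]
    multi <- poskey %in% poskey[duplicated(poskey)]
    list(s = s[!multi, , drop = FALSE], key = fullkey[!multi],
         n_unplaced = sum(!placed), n_multi = sum(multi))
  }
  a <- prep(set_a); b <- prep(set_b)
  i <- match(a$key, b$key)
  hit <- !is.na(i)
  pairs <- data.frame(id_a = a$s$id[hit], id_b = b$s$id[i[hit]],
                      platform_a = a$s$platform[hit],
                      platform_b = b$s$platform[i[hit]],
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs,
                 matched_ids = unique(c(pairs$id_a, pairs$id_b)),
                 n_unplaced_skipped = a$n_unplaced + b$n_unplaced,
                 n_multiallelic_excluded = a$n_multi + b$n_multi),
            class = "cross_validation")
}

#' @export
print.cross_validation <- function(x, ...) {
  cat(sprintf("cross_validation: %d matched pairs (%d unplaced skipped, %d multi-allelic excluded)\n",
              nrow(x$pairs), x$n_unplaced_skipped, x$n_multiallelic_excluded))
  invisible(x)
}

#' GBS priority criteria
#'
#' A GBS candidate qualifies for the high-priority tier when it meets at
#' least one of: (a) detected in the call sets of two or more populations;
#' (b) minor allele frequency strictly greater than `maf_threshold` in at
#' least one population; (c) segregating (a parent heterozygous, marker
#' passing family QC) in two or more families.
#'
#' @param population_maf_reports named list of `filter_report`s from
#'   [filter_population_maf()], one per population (a marker's presence in
#'   a report records its presence in that population's call set).
#' @param family_segregation named list (one per family) of data.frames
#'   with columns `marker`, `segregating`, `pass_qc` (see
#'   [family_segregation_status()]).
#' @param maf_threshold strict lower bound for criterion (b) (default 0.05;
#'   note the discovery-stage population filter uses an inclusive bound).
#' @return data.frame `marker`, `crit_a`, `crit_b`, `crit_c`, `selected`,
#'   `criteria` (comma-joined labels).
#' @export
gbs_priority_select <- function(population_maf_reports, family_segregation,
                                maf_threshold = 0.05) {
  pop_markers <- lapply(population_maf_reports, function(r) r$marker)
  markers <- unique(c(unlist(pop_markers),
                      unlist(lapply(family_segregation, function(f) f$marker))))
  n_pops <- if (length(pop_markers) == 0) {
    rep(0L, length(markers))
  } else {
    presence <- vapply(pop_markers, function(mk) markers %in% mk,
                       logical(length(markers)))
    rowSums(matrix(presence, nrow = length(markers)))
  }
  crit_a <- n_pops >= 2
  maf_ok <- rep(FALSE, length(markers))
  for (r in population_maf_reports) {
    i <- match(r$marker, markers)
    maf_ok[i] <- maf_ok[i] | (!is.na(r$maf) & r$maf > maf_threshold)
  }
  n_seg <- rep(0L, length(markers))
  for (f in family_segregation) {
    i <- match(f$marker, markers)
    seg <- f$segregating & f$pass_qc
    n_seg[i] <- n_seg[i] + as.integer(seg %in% TRUE)
  }
  crit_c <- n_seg >= 2
  selected <- crit_a | maf_ok | crit_c
  lab <- function(a, b, c) {
    paste(c("a", "b", "c")[c(a, b, c)], collapse = ",")
  }
  data.frame(marker = markers, crit_a = crit_a, crit_b = maf_ok,
             crit_c = crit_c, selected = selected,
             criteria = mapply(lab, crit_a, maf_ok, crit_c),
             stringsAsFactors = FALSE)
}

#' Per-family segregation status for the GBS criteria
#'
#' A marker is segregating in a family when at least one parent is
#' heterozygous; `pass_qc` combines the missingness, Mendelian-error and
#' segregation-distortion reports for that family when supplied.
#'
#' @param fam a [family_genotypes()].
#' @param reports optional list of `filter_report`s for this family.
#' @return data.frame `marker`, `segregating`, `pass_qc`.
#' @export
family_segregation_status <- function(fam, reports = list()) {
  stopifnot(inherits(fam, "family_genotypes"))
  seg <- fam$parents$parent1 == "ab" | fam$parents$parent2 == "ab"
  pass <- rep(TRUE, nrow(fam$parents))
  for (r in reports) {
    i <- match(fam$parents$marker, r$marker)
    p <- r$pass[i]
    pass <- pass & !(p %in% FALSE)
  }
  data.frame(marker = fam$parents$marker, segregating = seg, pass_qc = pass,
             stringsAsFactors = FALSE)
}

#' Assemble the high-priority (tier 1) candidate list
#'
#' Takes the set union of cross-platform-validated candidates, GBS
#' criterion-selected candidates and family-cross-validated candidates
#' (duplicates counted once, cross-platform evidence recorded first), then
#' removes strand-ambiguous (A/T, C/G) candidates unless their source
#' platform is exempted.
#'
#' @param candidates master candidate table covering all ids.
#' @param cross_platform a [cross_validate()] result, or a character vector
#'   of cross-platform-validated ids.
#' @param gbs_selected ids selected by [gbs_priority_select()].
#' @param family_cross_validated ids validated between families of
#'   different populations.
#' @param ambiguity_exempt_sources platforms whose A/T-G/C candidates are
#'   retained (e.g. a source whose samples the design must maximise).
#' @return list with `tier1` (candidate table + `provenance` column),
#'   `n_ambiguous_removed`, `removed_ids`.
#' @export
build_high_priority_tier <- function(candidates, cross_platform,
                                     gbs_selected = character(0),
                                     family_cross_validated = character(0),
                                     ambiguity_exempt_sources = character(0)) {
  cp_ids <- if (inherits(cross_platform, "cross_validation")) {
    cross_platform$matched_ids
  } else {
    cross_platform
  }
  ids <- unique(c(cp_ids, gbs_selected, family_cross_validated))
  tier1 <- candidates[match(intersect(ids, candidates$id), candidates$id), ,
                      drop = FALSE]
  prov <- function(id) {
    src <- c("cross_platform", "gbs_criteria", "family_cross_validation")[
      c(id %in% cp_ids, id %in% gbs_selected, id %in% family_cross_validated)]
    paste(src, collapse = "+")
  }
  tier1$provenance <- vapply(tier1$id, prov, character(1), USE.NAMES = FALSE)
  # the same physical SNP may enter under ids from several platforms;
  # keep the first (cross-platform evidence is recorded first)
  placed <- !is.na(tier1$seqname) & !is.na(tier1$pos)
  poskey <- ifelse(placed, paste(tier1$seqname, tier1$pos), tier1$id)
  tier1 <- tier1[!duplicated(poskey), , drop = FALSE]
  ambiguous <- is_strand_ambiguous(tier1$ref, tier1$alt) &
    !(tier1$platform %in% ambiguity_exempt_sources)
  removed <- tier1$id[ambiguous]
  tier1 <- tier1[!ambiguous, , drop = FALSE]
  tier1$tier <- 1L
  rownames(tier1) <- NULL
  list(tier1 = tier1, n_ambiguous_removed = length(removed),
       removed_ids = removed)
}
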