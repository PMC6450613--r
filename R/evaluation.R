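MARKER_CATEGORIES <- c("PolyHighRes", "NoMinorHom", "MonoHighRes",
                       "CallRateBelowThreshold", "Other")

#' Sample-level quality control for an array run
#'
#' Removes samples whose call rate is not strictly greater than
#' `min_sample_call_rate` and flags the run as failed when the mean call
#' rate of the passing samples is not strictly greater than
#' `min_mean_passing_call_rate`. A pre-supplied per-sample dish-QC boolean
#' (`samples$dish_qc_pass`) is honoured when present, otherwise skipped.
#'
#' @param callset a [genotype_callset()].
#' @param min_sample_call_rate exclusive lower bound on sample call rate
#'   (default 0.97).
#' @param min_mean_passing_call_rate exclusive lower bound on the mean call
#'   rate of passing samples (default 0.98).
#' @return list with `callset` (filtered), `report` (per-sample data.frame
#'   `sample_id`, `call_rate`, `dish_qc_pass`, `pass`), `run_passed`,
#'   `mean_passing_call_rate`.
#' @export
apply_sample_qc <- function(callset, min_sample_call_rate = 0.97,
                            min_mean_passing_call_rate = 0.98) {
  stopifnot(inherits(callset, "genotype_callset"))
  if (ncol(callset$calls) == 0) stop("empty call set")
  s <- callset$samples
  cr <- s$call_rate
  if (anyNA(cr)) cr[is.na(cr)] <- colMeans(!is.na(callset$calls))[is.na(cr)]
  dish <- s$dish_qc_pass %||% rep(TRUE, nrow(s))
  pass <- cr > min_sample_call_rate & dish
  mean_cr <- if (any(pass)) mean(cr[pass]) else NA_real_
  run_passed <- isTRUE(mean_cr > min_mean_passing_call_rate)
  filtered <- genotype_callset(callset$group, s[pass, , drop = FALSE],
                               callset$calls[, pass, drop = FALSE])
  list(callset = filtered,
       report = data.frame(sample_id = s$sample_id, call_rate = cr,
                           dish_qc_pass = dish, pass = pass,
                           stringsAsFactors = FALSE),
       run_passed = run_passed, mean_passing_call_rate = mean_cr)
}

#' Classify one marker's call vector (Axiom-style surrogate)
#'
#' Uses only the call rate and the observed genotype classes:
#' `CallRateBelowThreshold` when the non-missing fraction is below the
#' threshold; otherwise `MonoHighRes` when a single allele is observed,
#' `NoMinorHom` when heterozygotes are present without the minor-allele
#' homozygote, and `PolyHighRes` when both homozygote classes appear.
#'
#' @param calls character vector of calls (`aa`/`ab`/`bb`/`NA`).
#' @param min_marker_call_rate inclusive call-rate threshold (default 0.97).
#' @return one of `"PolyHighRes"`, `"NoMinorHom"`, `"MonoHighRes"`,
#'   `"CallRateBelowThreshold"`.
#' @export
classify_marker <- function(calls, min_marker_call_rate = 0.97) {
  stopifnot(length(calls) >= 1)
  if (mean(!is.na(calls)) < min_marker_call_rate) {
    return("CallRateBelowThreshold")
  }
  n_aa <- sum(calls == "aa", na.rm = TRUE)
  n_ab <- sum(calls == "ab", na.rm = TRUE)
  n_bb <- sum(calls == "bb", na.rm = TRUE)
  if (n_aa > 0 && n_bb > 0) return("PolyHighRes")
  if (n_ab > 0) return("NoMinorHom")
  "MonoHighRes"
}

#' Classify every marker in a call set
#'
#' @param callset a [genotype_callset()] (ideally after
#'   [apply_sample_qc()]).
#' @param min_marker_call_rate see [classify_marker()].
#' @return data.frame of class `marker_classification`: `marker`,
#'   `category`, `recommended`, `polymorphic`. Categories are mutually
#'   exclusive; `polymorphic` is `PolyHighRes` or `NoMinorHom`;
#'   `recommended` excludes `CallRateBelowThreshold` and `Other`.
#' @export
classify_markers <- function(callset, min_marker_call_rate = 0.97) {
  stopifnot(inherits(callset, "genotype_callset"))
  cat_ <- apply(callset$calls, 1, classify_marker,
                min_marker_call_rate = min_marker_call_rate)
  marker_classification(data.frame(marker = rownames(callset$calls),
                                   category = unname(cat_),
                                   stringsAsFactors = FALSE))
}

#' Validate/derive a marker classification table
#' @param df data.frame with `marker` and `category`.
#' @return `marker_classification` with derived `recommended` and
#'   `polymorphic` flags.
#' @export
marker_classification <- function(df) {
  stopifnot(all(c("marker", "category") %in% names(df)))
  if (!all(df$category %in% MARKER_CATEGORIES)) {
    stop("unknown marker category: ",
         paste(setdiff(df$category, MARKER_CATEGORIES), collapse = ", "))
  }
  df$recommended <- !df$category %in% c("CallRateBelowThreshold", "Other")
  df$polymorphic <- df$category %in% c("PolyHighRes", "NoMinorHom")
  class(df) <- c("marker_classification", "data.frame")
  df
}

#' Per-group classification summary
#'
#' @param classifications a [marker_classification()] table.
#' @return list with `recommended`, `polymorphic`, `monomorphic` counts and
#'   `pct_polymorphic` (share of recommended markers, 1-decimal,
#'   round-half-even; `NA` when nothing is recommended).
#' @export
summarize_group <- function(classifications) {
  stopifnot(inherits(classifications, "marker_classification"))
  rec <- sum(classifications$recommended)
  poly <- sum(classifications$polymorphic)
  mono <- sum(classifications$recommended & !classifications$polymorphic)
  list(recommended = rec, polymorphic = poly, monomorphic = mono,
       pct_polymorphic = if (rec == 0) NA_real_ else pct1(poly, rec))
}

#' Cross-group sharing of polymorphic markers
#'
#' Exact set algebra over marker ids: per-group unique/shared counts with
#' percentages and all `2^k - 1` Venn region counts.
#'
#' @param per_group named list of polymorphic marker-id vectors, one per
#'   group.
#' @return list of class `sharing_report`: `per_group` (data.frame `group`,
#'   `total`, `unique`, `shared`, `pct_unique`), `regions` (data.frame
#'   `region`, `count`), `union_polymorphic` (size of the union),
#'   `n_unique_to_one_group`.
#' @export
venn_sharing <- function(per_group) {
  stopifnot(length(per_group) >= 1, !is.null(names(per_group)))
  per_group <- lapply(per_group, unique)
  groups <- names(per_group)
  all_ids <- unique(unlist(per_group))
  member <- vapply(per_group, function(s) all_ids %in% s,
                   logical(length(all_ids)))
  if (length(all_ids) == 1) member <- matrix(member, nrow = 1,
                                             dimnames = list(NULL, groups))
  n_groups_per_id <- rowSums(member)
  per_g <- data.frame(
    group = groups,
    total = colSums(member),
    unique = colSums(member & n_groups_per_id == 1),
    shared = colSums(member & n_groups_per_id > 1),
    stringsAsFactors = FALSE, row.names = NULL)
  per_g$pct_unique <- mapply(pct1, per_g$unique, per_g$total)
  pattern <- apply(member, 1, function(r) paste(groups[r], collapse = "&"))
  combos <- unlist(lapply(seq_along(groups), function(k) {
    apply(utils::combn(groups, k), 2, paste, collapse = "&")
  }))
  counts <- table(factor(pattern, levels = combos))
  regions <- data.frame(region = combos, count = as.integer(counts),
                        stringsAsFactors = FALSE)
  structure(list(per_group = per_g, regions = regions,
                 union_polymorphic = length(all_ids),
                 n_unique_to_one_group = sum(n_groups_per_id == 1)),
            class = "sharing_report")
}

#' @export
print.sharing_report <- function(x, ...) {
  cat(sprintf("sharing_report: %d polymorphic markers across %d groups (%d unique to one group)\n",
              x$union_polymorphic, nrow(x$per_group),
              x$n_unique_to_one_group))
  print(x$per_group)
  invisible(x)
}

#' Pairwise sharing between two groups
#'
#' @param per_group named list of polymorphic marker-id sets.
#' @param pair character vector of two group names.
#' @return list with `shared` (`|A intersect B|`), `union` (`|A union B|`)
#'   and `pct_shared` (share of the pair union, 1-decimal).
#' @export
pairwise_sharing <- function(per_group, pair) {
  stopifnot(length(pair) == 2, all(pair %in% names(per_group)))
  a <- unique(per_group[[pair[1]]]); b <- unique(per_group[[pair[2]]])
  shared <- length(intersect(a, b))
  un <- length(union(a, b))
  list(shared = shared, union = un, pct_shared = pct1(shared, un))
}

#' Conversion-rate summary for an array design audit
#'
#' The conversion rate of a data source is the fraction of its submitted
#' candidates that became working assays on the final array, reported to
#' 1 decimal (a totals row is appended).
#'
#' @param n_on_array named integer vector: markers on the array per source.
#' @param n_candidates named integer vector: candidates submitted per
#'   source (same names).
#' @return data.frame `source`, `n_on_array`, `n_candidates`,
#'   `conversion_pct`.
#' @export
conversion_summary <- function(n_on_array, n_candidates) {
  stopifnot(identical(names(n_on_array), names(n_candidates)))
  out <- data.frame(source = c(names(n_on_array), "total"),
                    n_on_array = c(unname(n_on_array), sum(n_on_array)),
                    n_candidates = c(unname(n_candidates), sum(n_candidates)),
                    stringsAsFactors = FALSE)
  out$conversion_pct <- mapply(pct1, out$n_on_array, out$n_candidates)
  out
}

#' Predict genotypic sex from sdY markers
#'
#' sdY is male-specific in salmonids: a sample is predicted male when at
#' least `min_called` of the sdY sexing assays yield a call, female
#' otherwise. Concordance is the fraction of samples with known phenotypic
#' sex whose prediction matches.
#'
#' @param callset a [genotype_callset()] or list of them (combined).
#' @param sdy_marker_ids sdY marker ids present in the call set.
#' @param min_called calls required to predict male (default 1).
#' @return list with `predictions` (data.frame `sample_id`, `group`,
#'   `n_sdy_called`, `predicted_sex`, `phenotypic_sex`, `concordant`),
#'   `concordance` (fraction, `NA` if no known-sex samples),
#'   `n_known_sex`, `discordant_samples`.
#' @export
predict_sex <- function(callset, sdy_marker_ids, min_called = 1) {
  callsets <- if (inherits(callset, "genotype_callset")) list(callset)
              else callset
  preds <- lapply(callsets, function(cs) {
    missing_ids <- setdiff(sdy_marker_ids, rownames(cs$calls))
    if (length(missing_ids) > 0 || length(sdy_marker_ids) == 0) {
      stop("sdY marker(s) absent from the call set: ",
           paste(missing_ids, collapse = ", "))
    }
    sdy <- cs$calls[sdy_marker_ids, , drop = FALSE]
    n_called <- colSums(!is.na(sdy))
    data.frame(sample_id = cs$samples$sample_id, group = cs$group,
               n_sdy_called = unname(n_called),
               predicted_sex = ifelse(n_called >= min_called, "M", "F"),
               phenotypic_sex = cs$samples$sex, stringsAsFactors = FALSE)
  })
  preds <- do.call(rbind, preds)
  preds$concordant <- ifelse(is.na(preds$phenotypic_sex), NA,
                             preds$predicted_sex == preds$phenotypic_sex)
  known <- !is.na(preds$concordant)
  list(predictions = preds,
       concordance = if (any(known)) mean(preds$concordant[known]) else NA_real_,
       n_known_sex = sum(known),
       discordant_samples = preds$sample_id[known & !preds$concordant])
}
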