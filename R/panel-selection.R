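#' Panel selection configuration
#'
#' Holds the tunable design parameters: array budget, the allele-frequency
#' strata (rare `[0.05, 0.15)`, common `[0.15, 0.85]`), the spacing targets
#' for the rare (~900 kb) and common intergenic (~62 kb) interval
#' selections, and the probe geometry (71-mer with the SNP at bp 36; long
#' form 101-mer with the SNP at bp 51 for transcript comparison).
#'
#' @param budget maximum marker count on the array.
#' @param rare_bounds numeric length 2: `[lower, upper)` of the rare stratum.
#' @param common_bounds numeric length 2: `[lower, upper]` of the common
#'   stratum; its lower bound must equal the rare upper bound.
#' @param rare_spacing,common_spacing spacing targets in bp.
#' @param probe_length,snp_offset probe geometry (1-based SNP offset).
#' @param long_probe_length,long_snp_offset long-probe geometry.
#' @return list of class `selection_config`.
#' @export
selection_config <- function(budget = 1000,
                             rare_bounds = c(0.05, 0.15),
                             common_bounds = c(0.15, 0.85),
                             rare_spacing = 900000, common_spacing = 62000,
                             probe_length = 71, snp_offset = 36,
                             long_probe_length = 101, long_snp_offset = 51) {
  if (!isTRUE(all.equal(rare_bounds[2], common_bounds[1]))) {
    stop("rare upper bound must equal common lower bound")
  }
  if (any(c(rare_bounds, common_bounds) < 0) ||
      any(c(rare_bounds, common_bounds) > 1)) {
    stop("AF bounds must lie in [0, 1]")
  }
  if (snp_offset < 1 || snp_offset > probe_length ||
      long_snp_offset < 1 || long_snp_offset > long_probe_length) {
    stop("SNP offsets must lie within the probe length")
  }
  structure(list(budget = budget, rare_bounds = rare_bounds,
                 common_bounds = common_bounds, rare_spacing = rare_spacing,
                 common_spacing = common_spacing, probe_length = probe_length,
                 snp_offset = snp_offset,
                 long_probe_length = long_probe_length,
                 long_snp_offset = long_snp_offset),
            class = "selection_config")
}

#' Classify an allele frequency into the design strata
#'
#' Interval membership exactly as designed: rare is left-closed/right-open
#' `[0.05, 0.15)`, common is closed `[0.15, 0.85]`; anything else
#' (including a missing AF) is excluded.
#'
#' @param af numeric vector of allele frequencies (NA allowed).
#' @param config a [selection_config()].
#' @return character vector: `"rare"`, `"common"` or `"excluded"`.
#' @export
classify_af <- function(af, config = selection_config()) {
  if (any(!is.na(af) & (af < 0 | af > 1))) stop("af must lie in [0, 1]")
  out <- rep("excluded", length(af))
  rb <- config$rare_bounds; cb <- config$common_bounds
  out[!is.na(af) & af >= rb[1] & af < rb[2]] <- "rare"
  out[!is.na(af) & af >= cb[1] & af <= cb[2]] <- "common"
  out
}

#' Label candidates by transcript presence
#'
#' Sets `in_transcript` to `TRUE` when the SNP position falls inside any
#' gene's `[start, end]` interval (1-based inclusive) and records the
#' comma-joined gene ids of all overlapping genes.
#'
#' @param candidates candidate table placed on the annotated assembly.
#' @param annotation a [gene_annotation()] table.
#' @return the candidate table with `in_transcript` and `transcript_id` set.
#' @export
label_in_transcript <- function(candidates, annotation) {
  if (nrow(candidates) == 0) {
    candidates$in_transcript <- logical(0)
    return(candidates)
  }
  snp <- GenomicRanges::GRanges(candidates$seqname,
                                IRanges::IRanges(candidates$pos,
                                                 candidates$pos))
  genes <- GenomicRanges::GRanges(annotation$seqname,
                                  IRanges::IRanges(annotation$start,
                                                   annotation$end))
  hits <- GenomicRanges::findOverlaps(snp, genes)
  candidates$in_transcript <- seq_len(nrow(candidates)) %in%
    S4Vectors::queryHits(hits)
  tid <- tapply(annotation$gene_id[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits),
                paste, collapse = ",")
  candidates$transcript_id <- NA_character_
  candidates$transcript_id[as.integer(names(tid))] <- unname(tid)
  candidates
}

#' Deterministic candidate ranking for spacing and filler selection
#'
#' Orders by external conversion score (descending, missing last), then
#' `|AF - 0.5|` ascending (missing last), then position, then id.
#' @noRd
rank_candidates <- function(df) {
  score <- df$score %||% rep(NA_real_, nrow(df))
  af_dist <- abs((df$af %||% rep(NA_real_, nrow(df))) - 0.5)
  order(is.na(score), -ifelse(is.na(score), 0, score),
        is.na(af_dist), ifelse(is.na(af_dist), 1, af_dist),
        df$pos, df$id)
}

#' Interval-spacing marker selection
#'
#' Windowed greedy rule: each sequence is partitioned into consecutive
#' windows of `target_interval` bp starting at bp 1 and the best-ranked
#' candidate in each nonempty window is selected, so consecutive picks are
#' less than twice the target apart whenever intervening windows hold
#' candidates. The alternative `"greedy"` method takes the next candidate
#' at least `target_interval` past the previous pick.
#'
#' @param candidates candidate table, sorted by position within each
#'   sequence (an unsorted input is an error).
#' @param target_interval spacing target in bp (> 0).
#' @param method `"window"` (default) or `"greedy"`.
#' @return the selected subset of `candidates`.
#' @export
select_spaced <- function(candidates, target_interval,
                          method = c("window", "greedy")) {
  method <- match.arg(method)
  stopifnot(target_interval > 0)
  if (nrow(candidates) == 0) return(candidates)
  by_seq <- split(seq_len(nrow(candidates)), candidates$seqname)
  picks <- integer(0)
  for (idx in by_seq) {
    pos <- candidates$pos[idx]
    if (is.unsorted(pos)) stop("candidates must be sorted by position")
    if (method == "window") {
      win <- (pos - 1) %/% target_interval
      for (w in unique(win)) {
        sub <- idx[win == w]
        best <- sub[rank_candidates(candidates[sub, , drop = FALSE])[1]]
        picks <- c(picks, best)
      }
    } else {
      last <- -Inf
      for (i in idx) {
        if (candidates$pos[i] - last >= target_interval) {
          picks <- c(picks, i)
          last <- candidates$pos[i]
        }
      }
    }
  }
  out <- candidates[sort(picks), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Include sdY sexing markers as tier 2
#'
#' All sdY-derived candidates are included unconditionally, bypassing AF
#' and spacing rules; candidates that would fail the flank-length check
#' are still included but flagged in the audit.
#'
#' @param sdy_candidates candidate table with `platform == "sdy"`.
#' @param min_flank flank length used only for audit flagging.
#' @return list with `records` (tier set to 2) and `audit` (data.frame
#'   `id`, `flank_ok`).
#' @export
include_sdy_markers <- function(sdy_candidates, min_flank = 35) {
  if (nrow(sdy_candidates) == 0) {
    warning("no sdY candidates supplied; genotypic sexing will be unavailable")
    return(list(records = sdy_candidates,
                audit = data.frame(id = character(0), flank_ok = logical(0))))
  }
  sdy_candidates$tier <- 2L
  list(records = sdy_candidates,
       audit = data.frame(id = sdy_candidates$id,
                          flank_ok = check_flank_length(sdy_candidates,
                                                        min_flank),
                          stringsAsFactors = FALSE))
}

#' Assemble the array manifest
#'
#' Deterministic fill order: tier 1 (high-priority, entirely), tier 2
#' (sdY, entirely), tier 3 (spacing selections: rare pool at the rare
#' target, then common intergenic pool at the common target), tier 4
#' (filler by rank) until the budget is reached or pools are exhausted.
#' When external conversion scores are supplied, candidates labelled
#' `"not_recommended"` are dropped from the optional pools before filling
#' and a top-up pass from the remaining common intergenic pool emulates a
#' design resubmission.
#'
#' @param tier1 high-priority candidate table (see
#'   [build_high_priority_tier()]).
#' @param sdy sdY candidate table.
#' @param highcov_pools list with elements `rare_all` (rare SNPs, genic and
#'   intergenic) and `common_intergenic` (common SNPs outside transcripts),
#'   each sorted by position within sequence.
#' @param filler_pool lowest-priority putative candidates.
#' @param config a [selection_config()].
#' @param conversion_scores optional data.frame `id`, `score`, `label`
#'   (`recommended`/`neutral`/`not_recommended`).
#' @param genome optional [genome_assembly()] used to build probes; when a
#'   candidate cannot be placed, its stored flanks are used instead.
#' @return list with `manifest` (a `panel_manifest` data.frame) and
#'   `audit` (data.frame `id`, `status`, `reason`; every input candidate
#'   appears exactly once).
#' @export
assemble_panel <- function(tier1, sdy, highcov_pools = list(),
                           filler_pool = NULL, config = selection_config(),
                           conversion_scores = NULL, genome = NULL) {
  n_mandatory <- nrow(tier1) + nrow(sdy)
  if (config$budget < n_mandatory) {
    stop("budget smaller than the mandatory tiers (tier 1 + sdY)")
  }
  rare_pool <- highcov_pools$rare_all %||% empty_candidates()
  common_pool <- highcov_pools$common_intergenic %||% empty_candidates()
  filler_pool <- filler_pool %||% empty_candidates()
  score_of <- function(df) {
    if (is.null(conversion_scores) || nrow(df) == 0) {
      return(rep(NA_real_, nrow(df)))
    }
    conversion_scores$score[match(df$id, conversion_scores$id)]
  }
  label_of <- function(df) {
    if (is.null(conversion_scores) || nrow(df) == 0) {
      return(rep(NA_character_, nrow(df)))
    }
    conversion_scores$label[match(df$id, conversion_scores$id)]
  }
  audit <- list()
  drop_not_recommended <- function(df, pool_name) {
    lab <- label_of(df)
    bad <- !is.na(lab) & lab == "not_recommended"
    if (any(bad)) {
      audit[[length(audit) + 1]] <<- data.frame(
        id = df$id[bad], status = "dropped",
        reason = paste0("not_recommended:", pool_name),
        stringsAsFactors = FALSE)
    }
    df[!bad, , drop = FALSE]
  }
  rare_pool <- drop_not_recommended(rare_pool, "rare")
  common_pool <- drop_not_recommended(common_pool, "common_intergenic")
  filler_pool <- drop_not_recommended(filler_pool, "filler")
  rare_pool$score <- score_of(rare_pool)
  common_pool$score <- score_of(common_pool)
  filler_pool$score <- score_of(filler_pool)

  sel3_rare <- select_spaced(rare_pool, config$rare_spacing)
  sel3_common <- select_spaced(common_pool, config$common_spacing)
  room3 <- config$budget - n_mandatory
  truncate_ranked <- function(df, room) {
    if (nrow(df) <= room) return(df)
    kept <- df[rank_candidates(df), , drop = FALSE][seq_len(max(0, room)), ,
                                                    drop = FALSE]
    cut <- df[!df$id %in% kept$id, , drop = FALSE]
    audit[[length(audit) + 1]] <<- data.frame(
      id = cut$id, status = "dropped", reason = "budget_exceeded",
      stringsAsFactors = FALSE)
    kept[order(kept$seqname, kept$pos), , drop = FALSE]
  }
  sel3_rare <- truncate_ranked(sel3_rare, room3)
  sel3_common <- truncate_ranked(sel3_common, room3 - nrow(sel3_rare))
  taken <- c(tier1$id, sdy$id, sel3_rare$id, sel3_common$id)
  room <- config$budget - length(taken)
  filler_pool <- filler_pool[!filler_pool$id %in% taken, , drop = FALSE]
  filler_sorted <- filler_pool[rank_candidates(filler_pool), , drop = FALSE]
  sel4 <- utils::head(filler_sorted, max(0, room))
  room <- room - nrow(sel4)
  # top-up pass: remaining common intergenic SNPs fill what is left
  topup <- common_pool[!common_pool$id %in% c(taken, sel4$id), , drop = FALSE]
  topup <- topup[rank_candidates(topup), , drop = FALSE]
  sel_topup <- utils::head(topup, max(0, room))

  add_tier <- function(df, tier, reason) {
    if (nrow(df) == 0) return(NULL)
    df$tier <- tier
    df$reason <- reason
    df
  }
  parts <- list(
    add_tier(tier1, 1L, paste0("high_priority:",
                               tier1$provenance %||% "tier1")),
    add_tier(sdy, 2L, "sdy_sexing"),
    add_tier(sel3_rare, 3L, "spaced_rare"),
    add_tier(sel3_common, 3L, "spaced_common_intergenic"),
    add_tier(sel4, 4L, "filler"),
    add_tier(sel_topup, 4L, "common_intergenic_topup"))
  parts <- parts[!vapply(parts, is.null, logical(1))]
  cols <- c("id", "platform", "seqname", "pos", "ref", "alt", "flank_left",
            "flank_right", "af", "in_transcript", "tier", "reason")
  manifest <- do.call(rbind, lapply(parts, function(p) {
    p <- as_candidates_keep(p, cols)
    p
  }))
  manifest <- manifest[!duplicated(manifest$id), , drop = FALSE]
  manifest$score <- score_of(manifest)
  manifest$probe <- make_probe(manifest, genome = genome,
                               length = config$probe_length,
                               snp_offset = config$snp_offset,
                               source = "auto", on_short = "na")
  no_probe <- is.na(manifest$probe) & manifest$tier != 2L
  if (any(no_probe)) {
    audit[[length(audit) + 1]] <- data.frame(
      id = manifest$id[no_probe], status = "dropped",
      reason = "insufficient_flank_for_probe", stringsAsFactors = FALSE)
    manifest <- manifest[!no_probe, , drop = FALSE]
  }
  names(manifest)[names(manifest) == "id"] <- "marker_id"
  rownames(manifest) <- NULL
  class(manifest) <- c("panel_manifest", "data.frame")
  if (nrow(manifest) > config$budget) {
    stop("internal error: manifest exceeds budget")  # guarded by fill logic
  }
  if (nrow(manifest) < config$budget) {
    message(sprintf("panel shortfall: %d of %d budgeted markers filled",
                    nrow(manifest), config$budget))
  }
  audit[[length(audit) + 1]] <- data.frame(
    id = manifest$marker_id, status = "selected", reason = manifest$reason,
    stringsAsFactors = FALSE)
  all_in <- unique(c(tier1$id, sdy$id, rare_pool$id, common_pool$id,
                     filler_pool$id))
  audit_df <- do.call(rbind, audit)
  leftover <- setdiff(all_in, audit_df$id)
  if (length(leftover) > 0) {
    audit_df <- rbind(audit_df,
                      data.frame(id = leftover, status = "dropped",
                                 reason = "not_selected",
                                 stringsAsFactors = FALSE))
  }
  list(manifest = manifest, audit = audit_df)
}

#' Keep a fixed column set, padding absent columns with NA
#' @noRd
as_candidates_keep <- function(df, cols) {
  for (cl in setdiff(cols, names(df))) df[[cl]] <- NA
  df[, cols, drop = FALSE]
}
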