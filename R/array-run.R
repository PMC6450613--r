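#' Post-genotyping call set for one group
#'
#' @param group group name.
#' @param samples data.frame with columns `sample_id`, `sex` (`"M"`/`"F"`/`NA`
#'   phenotypic sex), `call_rate` (observed, in `[0,1]`), optionally
#'   `dish_qc_pass`.
#' @param calls character matrix markers x samples (codes `aa`/`ab`/`bb`,
#'   `NA` = no-call), rownames = marker ids, colnames = sample ids.
#' @return object of class `genotype_callset`.
#' @export
genotype_callset <- function(group, samples, calls) {
  stopifnot(all(c("sample_id", "sex", "call_rate") %in% names(samples)),
            identical(colnames(calls), samples$sample_id))
  assert_genotype_codes(calls, "array calls")
  cr <- samples$call_rate
  if (any(!is.na(cr) & (cr < 0 | cr > 1))) stop("call rates must be in [0,1]")
  structure(list(group = group, samples = samples, calls = calls),
            class = "genotype_callset")
}

#' @export
print.genotype_callset <- function(x, ...) {
  cat(sprintf("genotype_callset '%s': %d markers x %d samples (mean call rate %.3f)\n",
              x$group, nrow(x$calls), ncol(x$calls),
              mean(x$samples$call_rate, na.rm = TRUE)))
  invisible(x)
}

#' Simulate a post-design array genotyping run
#'
#' For each group, genotypes are drawn Hardy-Weinberg from the group's
#' per-marker allele frequency. A random subset of markers fails per group
#' and emits no-calls at an elevated rate; per-sample no-calls follow a
#' sample-specific call-rate draw. sdY sexing markers behave as
#' presence/absence assays: called in males (hom calls), no-call in females.
#'
#' @param panel a `panel_manifest` (or data.frame with `marker_id`).
#' @param group_afs numeric matrix markers x groups of alternate-allele
#'   frequencies (rownames = marker ids matching the panel).
#' @param n_samples_per_group named integer vector, samples per group.
#' @param marker_failure_rate probability a marker fails in a given group.
#' @param failed_nocall_rate no-call probability for failed markers.
#' @param sample_call_rate_distribution list(name = "beta", shape1, shape2)
#'   or list(name = "point", value): target per-sample call rate.
#' @param sdy_markers character vector of sdY marker ids (must be in the
#'   panel); may be empty.
#' @param sex_per_sample character vector (`"M"`/`"F"`/`NA`) of phenotypic
#'   sexes for all samples in group order, or `NULL` to draw 1:1.
#' @param sdy_failure_rate extra per-cell no-call rate applied to sdY
#'   markers in males (0 = sexing assays never fail).
#' @param seed integer seed.
#' @return named list of [genotype_callset()] objects, one per group.
#' @export
simulate_array_run <- function(panel, group_afs, n_samples_per_group,
                               marker_failure_rate = 0.02,
                               failed_nocall_rate = 0.85,
                               sample_call_rate_distribution =
                                 list(name = "beta", shape1 = 120, shape2 = 2),
                               sdy_markers = character(0),
                               sex_per_sample = NULL,
                               sdy_failure_rate = 0, seed) {
  marker_ids <- if (is.data.frame(panel)) panel$marker_id else panel
  if (!all(rownames(group_afs) %in% marker_ids)) {
    stop("every marker in group_afs must exist in the panel")
  }
  if (length(sdy_markers) > 0 && !all(sdy_markers %in% marker_ids)) {
    stop("unknown sdY marker id(s): ",
         paste(setdiff(sdy_markers, marker_ids), collapse = ", "))
  }
  groups <- colnames(group_afs)
  if (is.null(names(n_samples_per_group))) {
    names(n_samples_per_group) <- groups
  }
  total_n <- sum(n_samples_per_group[groups])
  draw_cr <- function(n, d) {
    switch(d$name,
           beta = rbeta(n, d$shape1, d$shape2),
           point = rep(d$value, n),
           stop("unknown call-rate distribution: ", d$name))
  }
  with_seed(seed, {
    if (is.null(sex_per_sample)) {
      sex_per_sample <- sample(c("M", "F"), total_n, replace = TRUE)
    }
    if (length(sex_per_sample) != total_n) {
      stop("sex_per_sample must have one entry per sample across all groups")
    }
    markers <- rownames(group_afs)
    is_sdy <- markers %in% sdy_markers
    offset <- 0L
    out <- list()
    for (g in groups) {
      n <- n_samples_per_group[[g]]
      sex <- sex_per_sample[offset + seq_len(n)]
      offset <- offset + n
      p <- group_afs[, g]
      m <- length(markers)
      alt_copies <- matrix(rbinom(m * n, 2, rep(p, n)), m, n)
      calls <- matrix(GENOTYPE_CODES[alt_copies + 1L], m, n)
      # sdY presence/absence: males give a call, females never do
      if (any(is_sdy)) {
        calls[is_sdy, ] <- "aa"
        calls[is_sdy, sex != "M" | is.na(sex)] <- NA_character_
        if (sdy_failure_rate > 0) {
          male_cols <- which(sex == "M")
          if (length(male_cols) > 0) {
            fail <- matrix(runif(sum(is_sdy) * length(male_cols)) < sdy_failure_rate,
                           sum(is_sdy), length(male_cols))
            block <- calls[is_sdy, male_cols, drop = FALSE]
            block[fail] <- NA_character_
            calls[is_sdy, male_cols] <- block
          }
        }
      }
      failed <- runif(m) < marker_failure_rate & !is_sdy
      target_cr <- draw_cr(n, sample_call_rate_distribution)
      nocall_p <- outer(rep(1, m), 1 - target_cr)
      nocall_p[failed, ] <- pmax(nocall_p[failed, ], failed_nocall_rate)
      nocall_p[is_sdy, ] <- 0  # sdY no-calls are sex-driven, handled above
      calls[matrix(runif(m * n), m, n) < nocall_p] <- NA_character_
      sample_ids <- sprintf("%s_t%03d", g, seq_len(n))
      dimnames(calls) <- list(markers, sample_ids)
      observed_cr <- colMeans(!is.na(calls[!is_sdy, , drop = FALSE]))
      if (all(is_sdy)) observed_cr <- colMeans(!is.na(calls))
      out[[g]] <- genotype_callset(
        g,
        data.frame(sample_id = sample_ids, sex = sex,
                   call_rate = unname(observed_cr), stringsAsFactors = FALSE),
        calls)
    }
    out
  })
}
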