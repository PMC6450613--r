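#' Discovery-platform profile
#'
#' Describes how one discovery platform (high-coverage whole-genome
#' sequencing, GBS, RAD-seq or RNA-seq) observes true SNPs: its per-SNP
#' detection probability, false-positive rate, emitted flank length, sample
#' size available for allele-frequency estimation, and the distributions of
#' the per-record quality annotations DP/QUAL/GQ/MQ.
#'
#' @param platform one of `"highcov"`, `"gbs"`, `"rad"`, `"rnaseq"`, `"sdy"`.
#' @param detect_prob probability a true SNP appears in the call set.
#' @param fp_per_kb expected platform-private false positives per kb.
#' @param flank_bp flank length emitted with each record (bp, >= 0).
#' @param af_n diploid individuals used for AF estimation (0 disables the
#'   AF annotation, as for single-family RNA-seq contigs).
#' @param dp_mean Poisson mean of reported depth.
#' @param qual_mean,qual_sd,gq_mean,gq_sd,mq_mean,mq_sd normal parameters of
#'   the reported QUAL/GQ/MQ (floored at 0).
#' @param fp_af allele frequency used when simulating estimated AFs of false
#'   positives (they are artefacts, so kept low).
#' @return a list of class `platform_profile`.
#' @export
platform_profile <- function(platform = c("highcov", "gbs", "rad", "rnaseq", "sdy"),
                             detect_prob = 0.8, fp_per_kb = 0.05,
                             flank_bp = 50, af_n = 8,
                             dp_mean = 25, qual_mean = 60, qual_sd = 20,
                             gq_mean = 50, gq_sd = 15, mq_mean = 50, mq_sd = 8,
                             fp_af = 0.05) {
  platform <- match.arg(platform)
  if (detect_prob < 0 || detect_prob > 1) stop("detect_prob must be in [0,1]")
  if (fp_per_kb < 0) stop("fp_per_kb must be >= 0")
  if (flank_bp < 0) stop("flank_bp must be >= 0")
  structure(list(platform = platform, detect_prob = detect_prob,
                 fp_per_kb = fp_per_kb, flank_bp = flank_bp, af_n = af_n,
                 dp_mean = dp_mean, qual_mean = qual_mean, qual_sd = qual_sd,
                 gq_mean = gq_mean, gq_sd = gq_sd, mq_mean = mq_mean,
                 mq_sd = mq_sd, fp_af = fp_af),
            class = "platform_profile")
}

#' Default profiles for the four discovery platforms
#'
#' Encodes the qualitative contrast between sources: high-coverage
#' sequencing sees most of the genome but estimates AF from few individuals;
#' the reduced-representation platforms (GBS, RAD) see a minority of sites
#' with better AF resolution; RNA-seq sees transcribed sites only
#' (approximated here by a lower detection probability).
#'
#' @return named list of [platform_profile()] objects.
#' @export
default_platform_profiles <- function() {
  list(
    highcov = platform_profile("highcov", detect_prob = 0.90, fp_per_kb = 0.10,
                               flank_bp = 60, af_n = 8),
    gbs = platform_profile("gbs", detect_prob = 0.25, fp_per_kb = 0.02,
                           flank_bp = 40, af_n = 48, dp_mean = 15),
    rad = platform_profile("rad", detect_prob = 0.20, fp_per_kb = 0.02,
                           flank_bp = 45, af_n = 60, dp_mean = 15),
    rnaseq = platform_profile("rnaseq", detect_prob = 0.15, fp_per_kb = 0.01,
                              flank_bp = 50, af_n = 18, dp_mean = 40)
  )
}

#' Simulate a platform's candidate call set
#'
#' Each true SNP is detected with the profile's detection probability;
#' platform-private false positives are placed uniformly at non-variant
#' positions with a random alternate allele. Every record carries flanks cut
#' from the genome (truncated at sequence ends), an estimated AF from a
#' binomial draw of `2 * af_n` allele copies, DP/QUAL/GQ/MQ draws, and the
#' platform name as provenance.
#'
#' @param truth a `true_variants` table from [generate_true_variants()].
#' @param genome the [genome_assembly()] the truth was generated on.
#' @param profile a [platform_profile()].
#' @param group group name whose true AF drives detection-set AF estimates;
#'   defaults to the first AF column in `truth`.
#' @param seed integer seed.
#' @return candidate table (class `candidate_snps`): columns `id`,
#'   `platform`, `seqname`, `pos`, `ref`, `alt`, `flank_left`, `flank_right`,
#'   `af`, `dp`, `qual`, `gq`, `mq`, `in_transcript`, `transcript_id`,
#'   `tier`, `is_true` (simulation truth label).
#' @export
simulate_platform_callset <- function(truth, genome, profile, group = NULL,
                                      seed) {
  stopifnot(inherits(profile, "platform_profile"),
            inherits(genome, "genome_assembly"))
  afm <- true_af_matrix(truth)
  group <- group %||% colnames(afm)[1]
  lens <- seq_lengths(genome)
  with_seed(seed, {
    detected <- truth[runif(nrow(truth)) < profile$detect_prob, , drop = FALSE]
    det <- data.frame(seqname = detected$seqname, pos = detected$pos,
                      ref = detected$ref, alt = detected$alt,
                      true_af = detected[[paste0("af_", group)]],
                      is_true = rep(TRUE, nrow(detected)),
                      stringsAsFactors = FALSE)
    fp <- lapply(names(lens), function(sq) {
      n_fp <- rpois(1, profile$fp_per_kb * lens[[sq]] / 1000)
      if (n_fp == 0) return(NULL)
      taken <- truth$pos[truth$seqname == sq]
      open <- setdiff(seq_len(lens[[sq]]), taken)
      n_fp <- min(n_fp, length(open))
      pos <- sort(sample(open, n_fp))
      ref <- strsplit(genome$sequences[[sq]], "")[[1]][pos]
      data.frame(seqname = sq, pos = pos, ref = ref,
                 alt = random_other_base(ref), true_af = profile$fp_af,
                 is_true = FALSE, stringsAsFactors = FALSE)
    })
    calls <- rbind(det, do.call(rbind, fp))
    if (is.null(calls) || nrow(calls) == 0) {
      out <- as_candidates(empty_candidates())
      out$is_true <- logical(0)
      class(out) <- c("candidate_snps", "data.frame")
      return(out)
    }
    calls <- calls[order(calls$seqname, calls$pos), , drop = FALSE]
    n <- nrow(calls)
    fl <- profile$flank_bp
    left_start <- pmax(1L, calls$pos - fl)
    right_end <- pmin(lens[calls$seqname], calls$pos + fl)
    calls$flank_left <- substr(genome$sequences[calls$seqname],
                               left_start, calls$pos - 1L)
    calls$flank_right <- substr(genome$sequences[calls$seqname],
                                calls$pos + 1L, right_end)
    if (profile$af_n > 0) {
      calls$af <- rbinom(n, 2L * profile$af_n, calls$true_af) / (2 * profile$af_n)
    } else {
      calls$af <- NA_real_
    }
    calls$dp <- rpois(n, profile$dp_mean)
    calls$qual <- round(pmax(0, rnorm(n, profile$qual_mean, profile$qual_sd)), 1)
    calls$gq <- round(pmax(0, rnorm(n, profile$gq_mean, profile$gq_sd)))
    calls$mq <- round(pmax(0, rnorm(n, profile$mq_mean, profile$mq_sd)), 1)
    calls$platform <- profile$platform
    calls$id <- sprintf("%s_%s_%d", profile$platform, calls$seqname, calls$pos)
    is_true <- calls$is_true
    out <- as_candidates(calls)
    out$is_true <- is_true
    class(out) <- c("candidate_snps", "data.frame")
    out
  })
}
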