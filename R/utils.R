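DNA_BASES <- c("A", "C", "G", "T")
GENOTYPE_CODES <- c("aa", "ab", "bb")
MISSING_CODE <- "--"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Run an expression under a fixed seed without touching the global RNG
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

#' Derive a child seed deterministically from a parent seed
#'
#' Keeps derived seeds inside the 32-bit integer range.
#' @noRd
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 2003L + as.integer(offset)
}

assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(sprintf("%s contains non-ACGT characters (first offender: '%s')",
                 what, x[bad][1]), call. = FALSE)
  }
  invisible(x)
}

#' Reverse complement of DNA strings
#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Draw a random base different from `base` for each element
#' @noRd
random_other_base <- function(base) {
  vapply(base, function(b) sample(setdiff(DNA_BASES, b), 1L), character(1),
         USE.NAMES = FALSE)
}

assert_genotype_codes <- function(x, what = "genotypes") {
  vals <- x[!is.na(x)]
  bad <- setdiff(unique(vals), GENOTYPE_CODES)
  if (length(bad) > 0) {
    stop(sprintf("invalid %s code(s): %s (expected aa/ab/bb or missing)",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Round-half-even percentage, 1 decimal (the convention used in reports)
#' @noRd
pct1 <- function(num, den) {
  if (den == 0) return(NA_real_)
  round(100 * num / den, 1)
}

#' Empty candidate table with the canonical column layout
#' @noRd
empty_candidates <- function() {
  data.frame(
    id = character(0), platform = character(0), seqname = character(0),
    pos = integer(0), ref = character(0), alt = character(0),
    flank_left = character(0), flank_right = character(0),
    af = numeric(0), dp = numeric(0), qual = numeric(0), gq = numeric(0),
    mq = numeric(0), in_transcript = logical(0), transcript_id = character(0),
    tier = integer(0), stringsAsFactors = FALSE
  )
}

#' Coerce/complete a data.frame into the canonical candidate layout
#' @noRd
as_candidates <- function(df) {
  template <- empty_candidates()
  for (col in names(template)) {
    if (is.null(df[[col]])) {
      na_of <- switch(class(template[[col]])[1],
                      character = NA_character_, integer = NA_integer_,
                      numeric = NA_real_, logical = NA)
      df[[col]] <- rep(na_of, nrow(df))
    }
  }
  rownames(df) <- NULL
  df[, names(template), drop = FALSE]
}
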