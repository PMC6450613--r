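#' Build array submission probes
#'
#' Constructs the bracket-notation probe `FLANK[REF/ALT]FLANK` with the
#' SNP at 1-based position `snp_offset` of a `length`-mer (defaults: 71-mer,
#' SNP at bp 36, i.e. 35 bp of flank on each side). Flanks are taken from
#' the forward strand of the genome; alleles are written in REF/ALT order.
#'
#' @param candidates candidate (or manifest) table with `seqname`, `pos`,
#'   `ref`, `alt` and, for `source = "flank"`, `flank_left`/`flank_right`.
#' @param genome a [genome_assembly()] (required for `source = "genome"`).
#' @param length probe length in bp.
#' @param snp_offset 1-based position of the SNP within the probe.
#' @param source `"genome"` (cut flanks from the assembly), `"flank"` (use
#'   the candidate's stored flanks) or `"auto"` (genome when placed, flanks
#'   otherwise).
#' @param on_short `"error"` (default; the message names the deficient
#'   side) or `"na"` (emit `NA` for candidates with insufficient flank).
#' @return character vector of probes, e.g. `"ACGT...[A/C]...ACGT"`.
#' @export
make_probe <- function(candidates, genome = NULL, length = 71, snp_offset = 36,
                       source = c("genome", "flank", "auto"),
                       on_short = c("error", "na")) {
  source <- match.arg(source)
  on_short <- match.arg(on_short)
  need_left <- snp_offset - 1L
  need_right <- length - snp_offset
  n <- nrow(candidates)
  if (n == 0) return(character(0))
  lens <- if (!is.null(genome)) seq_lengths(genome) else NULL
  out <- character(n)
  for (i in seq_len(n)) {
    use_genome <- switch(source,
                         genome = TRUE,
                         flank = FALSE,
                         auto = !is.null(genome) &&
                           !is.na(candidates$seqname[i]) &&
                           candidates$seqname[i] %in% names(lens))
    if (use_genome) {
      sq <- candidates$seqname[i]; p <- candidates$pos[i]
      left_avail <- p - 1L
      right_avail <- lens[[sq]] - p
      if (left_avail < need_left || right_avail < need_right) {
        if (on_short == "error") {
          side <- if (left_avail < need_left) "left" else "right"
          stop(sprintf("candidate %s: insufficient %s flank (%d < %d bp)",
                       candidates$id[i] %||% i, side,
                       if (side == "left") left_avail else right_avail,
                       if (side == "left") need_left else need_right))
        }
        out[i] <- NA_character_
        next
      }
      lf <- substr(genome$sequences[[sq]], p - need_left, p - 1L)
      rf <- substr(genome$sequences[[sq]], p + 1L, p + need_right)
    } else {
      lf_full <- candidates$flank_left[i]
      rf_full <- candidates$flank_right[i]
      if (is.na(lf_full) || is.na(rf_full) ||
          nchar(lf_full) < need_left || nchar(rf_full) < need_right) {
        if (on_short == "error") {
          side <- if (is.na(lf_full) || nchar(lf_full) < need_left) "left"
                  else "right"
          stop(sprintf("candidate %s: insufficient %s flank for a %d-mer probe",
                       candidates$id[i] %||% i, side, length))
        }
        out[i] <- NA_character_
        next
      }
      lf <- substr(lf_full, nchar(lf_full) - need_left + 1L, nchar(lf_full))
      rf <- substr(rf_full, 1L, need_right)
    }
    out[i] <- sprintf("%s[%s/%s]%s", lf, candidates$ref[i],
                      candidates$alt[i], rf)
  }
  out
}

#' Plain-sequence form of a bracket probe
#'
#' Replaces `[REF/ALT]` with the reference allele, giving the `length`-bp
#' genomic sequence with the SNP base at the configured offset; used for
#' placement checks.
#'
#' @param probe character vector of bracket-notation probes.
#' @return character vector of plain sequences.
#' @export
probe_plain <- function(probe) {
  sub("\\[([ACGT])/[ACGT]\\]", "\\1", probe)
}
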