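VCF_INFO_KEYS <- c(AF = "estimated allele frequency",
                   DP = "read depth", MQ = "RMS mapping quality",
                   SOURCE = "discovery platform",
                   LF = "left flanking sequence",
                   RF = "right flanking sequence",
                   PROBE = "71-mer probe with the SNP in bracket notation")

#' Write candidates (or a panel manifest) as VCF 4.2
#'
#' One record per candidate with the pipeline's annotations in INFO
#' (`AF`, `DP`, `MQ`, `SOURCE`, flanks, and for manifests the bracket
#' `PROBE`) and a single genotype column carrying `GT:GQ`.
#'
#' @param candidates candidate table or `panel_manifest`.
#' @param path output path (plain text).
#' @param genome optional [genome_assembly()]: records are validated
#'   against sequence bounds and contig lines are emitted.
#' @export
write_vcf <- function(candidates, path, genome = NULL) {
  df <- as.data.frame(candidates)
  if ("marker_id" %in% names(df)) names(df)[names(df) == "marker_id"] <- "id"
  if (!is.null(genome)) {
    lens <- seq_lengths(genome)
    bad <- which(!df$seqname %in% names(lens) | df$pos > lens[df$seqname] |
                   df$pos < 1)
    if (length(bad) > 0) {
      stop(sprintf("record %d (%s): position outside the assembly", bad[1],
                   df$id[bad[1]]))
    }
  }
  info_field <- function(key, val, quote_ok = TRUE) {
    ifelse(is.na(val) | val == "", NA, paste0(key, "=", val))
  }
  parts <- cbind(info_field("AF", df$af), info_field("DP", df$dp),
                 info_field("MQ", df$mq), info_field("SOURCE", df$platform),
                 info_field("LF", df$flank_left),
                 info_field("RF", df$flank_right),
                 info_field("PROBE", df$probe %||% rep(NA, nrow(df))))
  info <- apply(parts, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) == 0) "." else paste(r, collapse = ";")
  })
  gq <- df$gq %||% rep(NA, nrow(df))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=charrpanel",
    if (!is.null(genome)) {
      sprintf("##contig=<ID=%s,length=%d>", names(seq_lengths(genome)),
              unname(seq_lengths(genome)))
    },
    sprintf("##INFO=<ID=%s,Number=1,Type=%s,Description=\"%s\">",
            names(VCF_INFO_KEYS),
            c("Float", "Integer", "Float", "String", "String", "String",
              "String"),
            unname(VCF_INFO_KEYS)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "sample1"), collapse = "\t"))
  body <- paste(df$seqname, df$pos, df$id, df$ref, df$alt,
                ifelse(is.na(df$qual %||% rep(NA, nrow(df))), ".", df$qual),
                ".", info, "GT:GQ",
                paste0("0/1:", ifelse(is.na(gq), ".", gq)),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read candidates from a VCF file
#'
#' Restores the pipeline annotations written by [write_vcf()]; unknown
#' INFO keys are ignored. Malformed records are rejected with their line
#' reported by the parser; positions are validated against `genome` when
#' supplied.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param genome optional [genome_assembly()] for bounds validation.
#' @return candidate table.
#' @export
read_vcf <- function(path, genome = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) {  # single-record files drop to a bare vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  n <- nrow(fix)
  if (n == 0) return(as_candidates(empty_candidates()))
  get_info <- function(key, as_num = FALSE) {
    x <- vcfR::extract.info(v, element = key)
    if (as_num) suppressWarnings(as.numeric(x)) else x
  }
  gq <- tryCatch(
    suppressWarnings(as.numeric(vcfR::extract.gt(v, element = "GQ")[, 1])),
    error = function(e) rep(NA_real_, n))
  out <- data.frame(
    id = fix$ID, platform = get_info("SOURCE"),
    seqname = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    flank_left = get_info("LF"), flank_right = get_info("RF"),
    af = get_info("AF", as_num = TRUE), dp = get_info("DP", as_num = TRUE),
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    gq = gq, mq = get_info("MQ", as_num = TRUE),
    stringsAsFactors = FALSE)
  probe <- get_info("PROBE")
  if (any(!is.na(probe))) out$probe <- probe
  if (!is.null(genome)) {
    lens <- seq_lengths(genome)
    bad <- which(!out$seqname %in% names(lens) | out$pos > lens[out$seqname])
    if (length(bad) > 0) {
      stop(sprintf("VCF record %d (%s:%d) lies outside the assembly",
                   bad[1], out$seqname[bad[1]], out$pos[bad[1]]))
    }
  }
  out <- as_candidates(out)
  if (any(!is.na(probe))) out$probe <- probe
  class(out) <- c("candidate_snps", "data.frame")
  out
}
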