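#' Write a genome assembly to FASTA
#'
#' Headers carry the sequence role (`chromosome` or `contig`) so the
#' assembly round-trips through [read_fasta()].
#'
#' @param genome a [genome_assembly()].
#' @param path output path.
#' @export
write_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "genome_assembly"))
  x <- Biostrings::DNAStringSet(genome$sequences)
  names(x) <- paste(names(genome$sequences),
                    ifelse(genome$is_chromosome, "chromosome", "contig"))
  Biostrings::writeXStringSet(x, path, width = 70)
  invisible(path)
}

#' Read a genome assembly from FASTA
#'
#' Lowercase bases are uppercased on load. Sequence role is taken from the
#' header token (`chromosome`/`contig`); without one, names starting with
#' `chr` are treated as chromosomes.
#'
#' @param path FASTA file.
#' @return a [genome_assembly()].
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  header <- names(x)
  nm <- sub("\\s.*$", "", header)
  token <- ifelse(grepl("\\schromosome\\b", header), "chromosome",
                  ifelse(grepl("\\scontig\\b", header), "contig", NA))
  is_chr <- ifelse(!is.na(token), token == "chromosome", grepl("^chr", nm))
  seqs <- toupper(as.character(x))
  names(seqs) <- nm
  genome_assembly(seqs, setNames(is_chr, nm))
}

#' Write a gene annotation to GFF3
#' @param annotation a [gene_annotation()] table.
#' @param path output path.
#' @export
write_annotation <- function(annotation, path) {
  if (nrow(annotation) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(annotation$seqname,
                               IRanges::IRanges(annotation$start,
                                                annotation$end),
                               strand = annotation$strand,
                               type = "gene", ID = annotation$gene_id,
                               source = "charrpanel")
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a gene annotation from GFF3
#'
#' Keeps `gene` records; gene ids come from the `ID` attribute. Invalid
#' coordinates are rejected with the offending record named.
#'
#' @param path GFF3 file.
#' @param genome optional [genome_assembly()] for bounds checking.
#' @return a [gene_annotation()] table.
#' @export
read_annotation <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[which(gr$type == "gene")]
  ids <- gr$ID
  if (length(gr) > 0 && (is.null(ids) || anyNA(ids))) {
    ids <- as.character(seq_along(gr))
    warning("GFF3 gene records without ID attribute; synthesised gene ids")
  }
  gene_annotation(data.frame(
    gene_id = as.character(ids),
    seqname = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE), genome = genome)
}

#' Write family or population genotypes to TSV
#'
#' Markers x samples layout with genotypes coded `aa`/`ab`/`bb`/`--`;
#' family files carry the parents as the first two genotype columns
#' (`parent1`, `parent2`).
#'
#' @param x a [family_genotypes()] or [population_genotypes()].
#' @param path output path.
#' @export
write_genotypes <- function(x, path) {
  if (inherits(x, "family_genotypes")) {
    tab <- data.frame(marker = x$parents$marker, parent1 = x$parents$parent1,
                      parent2 = x$parents$parent2, x$geno,
                      check.names = FALSE, stringsAsFactors = FALSE)
  } else if (inherits(x, "population_genotypes")) {
    tab <- data.frame(marker = rownames(x$geno), x$geno, check.names = FALSE,
                      stringsAsFactors = FALSE)
  } else {
    stop("x must be family_genotypes or population_genotypes")
  }
  tab[is.na(tab)] <- MISSING_CODE
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotypes from TSV
#'
#' @param path TSV written by [write_genotypes()] (or matching its layout).
#' @param type `"family"` (expects `parent1`/`parent2` columns) or
#'   `"population"`.
#' @param id family id or group name for the returned object.
#' @return a [family_genotypes()] or [population_genotypes()].
#' @export
read_genotypes <- function(path, type = c("family", "population"),
                           id = "unnamed") {
  type <- match.arg(type)
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"marker" %in% names(tab)) stop("genotype TSV must have a 'marker' column")
  to_code <- function(x, what, col) {
    x[x == MISSING_CODE] <- NA
    bad <- which(!is.na(x) & !x %in% GENOTYPE_CODES)
    if (length(bad) > 0) {
      stop(sprintf("invalid genotype code '%s' at row %d of column '%s'",
                   x[bad[1]], bad[1], col))
    }
    x
  }
  for (cl in setdiff(names(tab), "marker")) {
    tab[[cl]] <- to_code(as.character(tab[[cl]]), "genotype", cl)
  }
  if (type == "family") {
    if (!all(c("parent1", "parent2") %in% names(tab))) {
      stop("family genotype TSV needs parent1/parent2 columns")
    }
    prog_cols <- setdiff(names(tab), c("marker", "parent1", "parent2"))
    geno <- as.matrix(tab[, prog_cols, drop = FALSE])
    rownames(geno) <- tab$marker
    family_genotypes(id,
                     data.frame(marker = tab$marker, parent1 = tab$parent1,
                                parent2 = tab$parent2,
                                stringsAsFactors = FALSE),
                     geno)
  } else {
    geno <- as.matrix(tab[, setdiff(names(tab), "marker"), drop = FALSE])
    rownames(geno) <- tab$marker
    population_genotypes(id, geno)
  }
}

#' Write a call set to TSV (markers x samples, plus a sample sheet)
#' @param callset a [genotype_callset()].
#' @param path genotype TSV path; the sample sheet goes to
#'   `<path>.samples.tsv`.
#' @export
write_callset <- function(callset, path) {
  tab <- data.frame(marker = rownames(callset$calls), callset$calls,
                    check.names = FALSE, stringsAsFactors = FALSE)
  tab[is.na(tab)] <- MISSING_CODE
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(callset$samples, paste0(path, ".samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a call set written by [write_callset()]
#' @param path genotype TSV path (expects `<path>.samples.tsv` beside it).
#' @param group group name.
#' @return a [genotype_callset()].
#' @export
read_callset <- function(path, group = "unnamed") {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  geno <- as.matrix(tab[, setdiff(names(tab), "marker"), drop = FALSE])
  geno[geno == MISSING_CODE] <- NA
  rownames(geno) <- tab$marker
  samples <- read.delim(paste0(path, ".samples.tsv"), stringsAsFactors = FALSE)
  samples$sex[samples$sex %in% c("NA", "")] <- NA
  genotype_callset(group, samples, geno)
}

#' Write a filter report (one row per marker/rule) and its count summary
#' @param report a `filter_report`.
#' @param path TSV output path; per-rule pass/fail/not-testable counts go
#'   to `<path>.summary.tsv`.
#' @export
write_filter_report <- function(report, path) {
  df <- as.data.frame(report)
  df$rule <- attr(report, "rule")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- data.frame(rule = attr(report, "rule"),
                        n_markers = nrow(df),
                        n_pass = sum(df$pass %in% TRUE),
                        n_fail = sum(df$pass %in% FALSE),
                        n_not_testable = sum(is.na(df$pass)))
  write.table(summary, paste0(path, ".summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a panel manifest as TSV
#' @param manifest a `panel_manifest`.
#' @param path TSV output path.
#' @export
write_manifest <- function(manifest, path) {
  write.table(as.data.frame(manifest), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
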