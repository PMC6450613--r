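#' Genome coverage report for a panel
#'
#' Summarises marker placement over an assembly: per-chromosome marker
#' counts with average gap (chromosome length / marker count, in kb) and
#' marker density (markers per Mb); empty fixed-width windows (consecutive
#' `[k*window + 1, (k+1)*window]` segments anchored at bp 1, final window
#' truncated); unplaced-contig representation (contigs carrying a marker,
#' and the fraction of contig sequence they account for); and gene
#' representation (genes with at least one marker inside `[start, end]`).
#'
#' @param panel a `panel_manifest` or data.frame with `seqname` and `pos`.
#' @param genome a [genome_assembly()] or a seqinfo-style data.frame
#'   (`seqname`, `length`, `is_chromosome`) when only lengths are known.
#' @param annotation optional [gene_annotation()] table.
#' @param window window size in bp (default 1 Mb).
#' @return list of class `coverage_report`: `per_chromosome` (data.frame
#'   `seqname`, `n_markers`, `avg_gap_kb`, `length_kb`, `markers_per_mb`),
#'   `empty_windows` (data.frame `seqname`, `window_start`, `window_end`),
#'   `n_windows`, `unplaced` (list `n_contigs`, `n_with_marker`,
#'   `pct_with_marker`, `pct_length_represented`, `n_markers`), `genes`
#'   (list `n_genes`, `n_represented`, `pct_represented`, or `NULL`).
#' @export
coverage_report <- function(panel, genome, annotation = NULL,
                            window = 1000000) {
  si <- seq_info(genome)
  pos <- data.frame(seqname = panel$seqname, pos = panel$pos,
                    stringsAsFactors = FALSE)
  pos <- pos[!is.na(pos$seqname) & !is.na(pos$pos), , drop = FALSE]
  unknown <- setdiff(unique(pos$seqname), si$seqname)
  if (length(unknown) > 0) {
    stop("marker(s) on unknown sequence: ", paste(unknown, collapse = ", "))
  }
  chr <- si[si$is_chromosome, , drop = FALSE]
  counts <- table(factor(pos$seqname, levels = si$seqname))
  per_chr <- data.frame(
    seqname = chr$seqname,
    n_markers = as.integer(counts[chr$seqname]),
    stringsAsFactors = FALSE)
  per_chr$avg_gap_kb <- ifelse(per_chr$n_markers > 0,
                               round((chr$length / 1000) / per_chr$n_markers, 1),
                               NA)
  per_chr$length_kb <- round(chr$length / 1000)
  per_chr$markers_per_mb <- round(per_chr$n_markers / (chr$length / 1e6), 1)

  empties <- list()
  n_windows <- 0L
  for (i in seq_len(nrow(chr))) {
    L <- chr$length[i]
    k <- ceiling(L / window)
    n_windows <- n_windows + k
    p <- pos$pos[pos$seqname == chr$seqname[i]]
    occupied <- unique((p - 1) %/% window)
    empty_k <- setdiff(seq_len(k) - 1L, occupied)
    if (length(empty_k) > 0) {
      empties[[length(empties) + 1]] <- data.frame(
        seqname = chr$seqname[i],
        window_start = empty_k * window + 1,
        window_end = pmin((empty_k + 1) * window, L),
        stringsAsFactors = FALSE)
    }
  }
  empty_windows <- if (length(empties) > 0) do.call(rbind, empties) else
    data.frame(seqname = character(0), window_start = numeric(0),
               window_end = numeric(0))

  ctg <- si[!si$is_chromosome, , drop = FALSE]
  with_marker <- ctg$seqname %in% pos$seqname
  unplaced <- list(
    n_contigs = nrow(ctg),
    n_with_marker = sum(with_marker),
    pct_with_marker = if (nrow(ctg) > 0) pct1(sum(with_marker), nrow(ctg))
                      else NA_real_,
    pct_length_represented = if (nrow(ctg) > 0)
      pct1(sum(ctg$length[with_marker]), sum(ctg$length)) else NA_real_,
    n_markers = sum(pos$seqname %in% ctg$seqname))

  genes <- NULL
  if (!is.null(annotation) && nrow(annotation) > 0) {
    snp <- GenomicRanges::GRanges(pos$seqname,
                                  IRanges::IRanges(pos$pos, pos$pos))
    gr <- GenomicRanges::GRanges(annotation$seqname,
                                 IRanges::IRanges(annotation$start,
                                                  annotation$end))
    hit <- GenomicRanges::countOverlaps(gr, snp) > 0
    genes <- list(n_genes = nrow(annotation), n_represented = sum(hit),
                  pct_represented = pct1(sum(hit), nrow(annotation)),
                  represented_ids = annotation$gene_id[hit])
  }
  structure(list(per_chromosome = per_chr, empty_windows = empty_windows,
                 n_windows = n_windows, unplaced = unplaced, genes = genes,
                 n_on_chromosomes = sum(pos$seqname %in% chr$seqname),
                 n_placed = nrow(pos)),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("coverage_report: %d placed markers (%d on chromosomes, %d on contigs); %d of %d windows empty\n",
              x$n_placed, x$n_on_chromosomes, x$unplaced$n_markers,
              nrow(x$empty_windows), x$n_windows))
  invisible(x)
}
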