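#' Genome assembly container
#'
#' Holds named uppercase DNA sequences split into chromosomes and unplaced
#' contigs. This is the coordinate frame for every downstream object
#' (candidates, annotation, panel, coverage).
#'
#' @param sequences named character vector of uppercase DNA sequences.
#' @param is_chromosome named logical vector (same names) flagging
#'   chromosomes; unplaced contigs are `FALSE`.
#' @return an object of class `genome_assembly` with elements `sequences`
#'   and `is_chromosome`.
#' @export
genome_assembly <- function(sequences, is_chromosome) {
  if (length(sequences) == 0) stop("assembly must contain at least one sequence")
  nm <- names(sequences)
  if (is.null(nm) || anyDuplicated(nm) || any(nm == "")) {
    stop("sequence names must be unique and nonempty")
  }
  if (any(nchar(sequences) == 0)) stop("sequences must be nonempty")
  assert_dna(sequences, "genome sequence")
  if (is.null(names(is_chromosome))) names(is_chromosome) <- nm
  is_chromosome <- is_chromosome[nm]
  if (anyNA(is_chromosome)) stop("is_chromosome must cover every sequence")
  structure(list(sequences = sequences, is_chromosome = is_chromosome),
            class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  n_chr <- sum(x$is_chromosome)
  cat(sprintf("genome_assembly: %d chromosome(s), %d unplaced contig(s), %s bp total\n",
              n_chr, length(x$sequences) - n_chr,
              format(sum(nchar(x$sequences)), big.mark = ",")))
  invisible(x)
}

#' Sequence lengths of an assembly
#' @param genome a `genome_assembly`.
#' @return named integer vector of sequence lengths (bp).
#' @export
seq_lengths <- function(genome) {
  stopifnot(inherits(genome, "genome_assembly"))
  setNames(nchar(genome$sequences), names(genome$sequences))
}

#' A seqinfo-style table (name, length, is_chromosome) for an assembly
#' @param genome a `genome_assembly`, or a data.frame already in this layout.
#' @return data.frame with columns `seqname`, `length`, `is_chromosome`.
#' @export
seq_info <- function(genome) {
  if (is.data.frame(genome)) {
    stopifnot(all(c("seqname", "length") %in% names(genome)))
    if (is.null(genome$is_chromosome)) genome$is_chromosome <- TRUE
    return(genome[, c("seqname", "length", "is_chromosome")])
  }
  data.frame(seqname = names(genome$sequences),
             length = unname(nchar(genome$sequences)),
             is_chromosome = unname(genome$is_chromosome),
             stringsAsFactors = FALSE)
}

#' Generate a random genome assembly
#'
#' Simulates a small multi-chromosome genome with optional unplaced contigs.
#' Chromosome names (`chr01`, `chr02`, ...) sort lexically in karyotype
#' order; contigs are named `contig00001`, ... and flagged as unplaced.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chromosome_length length of each chromosome (bp, >= 100).
#' @param n_contigs number of unplaced contigs (may be 0).
#' @param contig_length_range length-2 numeric, inclusive bp range for contig
#'   lengths (each >= 100).
#' @param seed integer seed; identical seeds give byte-identical assemblies.
#' @return a [genome_assembly()].
#' @examples
#' g <- generate_genome(2, 10000, n_contigs = 3,
#'                      contig_length_range = c(500, 1500), seed = 1)
#' seq_lengths(g)
#' @export
generate_genome <- function(n_chromosomes, chromosome_length,
                            n_contigs = 0, contig_length_range = c(1000, 10000),
                            seed) {
  if (n_chromosomes < 1 && n_contigs < 1) {
    stop("invalid input: need at least one chromosome or contig")
  }
  if (n_chromosomes >= 1 && chromosome_length < 100) {
    stop("chromosome_length must be >= 100 bp")
  }
  if (n_contigs >= 1 && (length(contig_length_range) != 2 ||
                         min(contig_length_range) < 100)) {
    stop("contig_length_range must be two values >= 100 bp")
  }
  with_seed(seed, {
    seqs <- character(0)
    if (n_chromosomes >= 1) {
      chr_names <- sprintf("chr%02d", seq_len(n_chromosomes))
      seqs <- setNames(
        vapply(seq_len(n_chromosomes), function(i) random_dna(chromosome_length),
               character(1)),
        chr_names)
    }
    if (n_contigs >= 1) {
      lens <- sample(seq(contig_length_range[1], contig_length_range[2]),
                     n_contigs, replace = TRUE)
      ctg <- setNames(vapply(lens, random_dna, character(1)),
                      sprintf("contig%05d", seq_len(n_contigs)))
      seqs <- c(seqs, ctg)
    }
    genome_assembly(seqs, grepl("^chr", names(seqs)))
  })
}

#' Generate a non-overlapping gene annotation for an assembly
#'
#' Places `genes_per_mb` genes per megabase on each sequence, uniformly and
#' without overlap, with lengths drawn uniformly from `gene_length_range`.
#'
#' @param genome a [genome_assembly()].
#' @param genes_per_mb mean gene density (genes per Mb).
#' @param gene_length_range inclusive bp range of gene lengths.
#' @param seed integer seed.
#' @return data.frame of class `gene_annotation` with columns `gene_id`,
#'   `seqname`, `start`, `end`, `strand` (1-based inclusive coordinates).
#' @export
generate_annotation <- function(genome, genes_per_mb = 20,
                                gene_length_range = c(500, 5000), seed) {
  stopifnot(inherits(genome, "genome_assembly"), genes_per_mb > 0)
  lens <- seq_lengths(genome)
  with_seed(seed, {
    out <- lapply(names(lens), function(sq) {
      L <- lens[[sq]]
      n <- rpois(1, genes_per_mb * L / 1e6)
      if (n == 0) return(NULL)
      glen <- sample(seq(gene_length_range[1], min(gene_length_range[2], L)),
                     n, replace = TRUE)
      # lay genes left to right in disjoint slots; drop those that no longer fit
      starts <- sort(sample.int(L, n))
      keep_start <- integer(0); keep_end <- integer(0); cursor <- 0L
      for (i in seq_len(n)) {
        s <- max(starts[i], cursor + 1L)
        e <- s + glen[i] - 1L
        if (e > L) next
        keep_start <- c(keep_start, s); keep_end <- c(keep_end, e)
        cursor <- e
      }
      if (length(keep_start) == 0) return(NULL)
      data.frame(seqname = sq, start = keep_start, end = keep_end,
                 strand = sample(c("+", "-"), length(keep_start), replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    ann <- do.call(rbind, out)
    if (is.null(ann)) {
      ann <- data.frame(seqname = character(0), start = integer(0),
                        end = integer(0), strand = character(0))
    }
    ann <- cbind(gene_id = sprintf("gene%05d", seq_len(nrow(ann))), ann,
                 stringsAsFactors = FALSE)
    gene_annotation(ann)
  })
}

#' Validate and classify a gene annotation table
#' @param df data.frame with columns gene_id, seqname, start, end, strand.
#' @param genome optional [genome_assembly()] to bounds-check against.
#' @return the validated data.frame with class `gene_annotation`.
#' @export
gene_annotation <- function(df, genome = NULL) {
  stopifnot(all(c("gene_id", "seqname", "start", "end", "strand") %in% names(df)))
  if (anyDuplicated(df$gene_id)) stop("gene_ids must be unique")
  bad <- which(df$start < 1 | df$end < df$start)
  if (length(bad) > 0) {
    stop(sprintf("annotation record %d ('%s') has end < start or start < 1",
                 bad[1], df$gene_id[bad[1]]))
  }
  if (!is.null(genome)) {
    lens <- seq_lengths(genome)
    if (!all(df$seqname %in% names(lens))) stop("annotation on unknown sequence")
    over <- which(df$end > lens[df$seqname])
    if (length(over) > 0) {
      stop(sprintf("gene '%s' extends past the end of %s",
                   df$gene_id[over[1]], df$seqname[over[1]]))
    }
  }
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Generate true variants on an assembly
#'
#' Places true SNPs uniformly at unique positions at the requested density
#' and draws a true alternate-allele frequency per population group.
#'
#' @param genome a [genome_assembly()].
#' @param density SNPs per kb (> 0; at most 1000, i.e. one per bp).
#' @param af_distribution list with element `name` (`"uniform"`, `"beta"` or
#'   `"point"`) and its parameters (`min`/`max`, `shape1`/`shape2`, `value`).
#' @param groups character vector of group names; one AF column
#'   (`af_<group>`) is drawn independently per group.
#' @param seed integer seed.
#' @return data.frame of class `true_variants`: `seqname`, `pos`, `ref`,
#'   `alt`, plus one `af_<group>` column per group.
#' @export
generate_true_variants <- function(genome, density,
                                   af_distribution = list(name = "uniform",
                                                          min = 0.05, max = 0.5),
                                   groups = "pop1", seed) {
  stopifnot(inherits(genome, "genome_assembly"), density > 0)
  if (density > 1000) stop("density too high: cannot place unique positions")
  lens <- seq_lengths(genome)
  draw_af <- function(n) {
    switch(af_distribution$name,
           uniform = runif(n, af_distribution$min, af_distribution$max),
           beta = rbeta(n, af_distribution$shape1, af_distribution$shape2),
           point = rep(af_distribution$value, n),
           stop("unknown af_distribution: ", af_distribution$name))
  }
  with_seed(seed, {
    per_seq <- lapply(names(lens), function(sq) {
      L <- lens[[sq]]
      n <- rbinom(1, L, min(1, density / 1000))
      if (n == 0) return(NULL)
      pos <- sort(sample.int(L, n))
      ref <- strsplit(genome$sequences[[sq]], "")[[1]][pos]
      data.frame(seqname = sq, pos = pos, ref = ref,
                 alt = random_other_base(ref), stringsAsFactors = FALSE)
    })
    tv <- do.call(rbind, per_seq)
    if (is.null(tv)) {
      tv <- data.frame(seqname = character(0), pos = integer(0),
                       ref = character(0), alt = character(0))
    }
    for (g in groups) tv[[paste0("af_", g)]] <- draw_af(nrow(tv))
    rownames(tv) <- NULL
    class(tv) <- c("true_variants", "data.frame")
    tv
  })
}

#' Extract the AF matrix (variants x groups) from a true-variant table
#' @noRd
true_af_matrix <- function(truth) {
  af_cols <- grep("^af_", names(truth), value = TRUE)
  m <- as.matrix(truth[, af_cols, drop = FALSE])
  colnames(m) <- sub("^af_", "", af_cols)
  m
}
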