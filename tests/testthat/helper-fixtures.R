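# Shared in-code fixtures; everything deterministic via explicit seeds.

# Minimal candidate row(s) with sensible defaults, overridable per field.
make_cand <- function(n = 1, id = sprintf("c%02d", seq_len(n)),
                      platform = "highcov", seqname = "chr01",
                      pos = seq_len(n) * 100L, ref = "A", alt = "G",
                      flank_left = strrep("A", 40),
                      flank_right = strrep("C", 40),
                      af = 0.3, dp = 20, qual = 50, gq = 40, mq = 45,
                      in_transcript = NA, transcript_id = NA_character_) {
  if (n == 0) {
    return(make_cand(1)[0, , drop = FALSE])
  }
  df <- data.frame(id = id, platform = platform, seqname = seqname,
                   pos = pos, ref = ref, alt = alt,
                   flank_left = flank_left, flank_right = flank_right,
                   af = af, dp = dp, qual = qual, gq = gq, mq = mq,
                   in_transcript = in_transcript,
                   transcript_id = transcript_id,
                   tier = NA_integer_, stringsAsFactors = FALSE)
  df
}

# A family with explicit parent genotypes and a progeny matrix given as
# counts of each genotype class per marker; rows are padded with missing
# genotypes up to n_progeny (default: the largest class-count sum).
make_family <- function(parent1, parent2, progeny_counts, n_progeny = NULL,
                        family_id = "famX") {
  m <- length(parent1)
  markers <- sprintf("m%02d", seq_len(m))
  n_prog <- n_progeny %||%
    max(vapply(progeny_counts, sum, numeric(1)))
  geno <- t(vapply(seq_len(m), function(i) {
    cnt <- progeny_counts[[i]]
    c(rep(names(cnt), cnt), rep(NA_character_, n_prog - sum(cnt)))
  }, character(n_prog)))
  rownames(geno) <- markers
  colnames(geno) <- sprintf("p%02d", seq_len(ncol(geno)))
  family_genotypes(family_id,
                   data.frame(marker = markers, parent1 = parent1,
                              parent2 = parent2, stringsAsFactors = FALSE),
                   geno)
}

# Population genotypes from per-marker genotype counts.
make_population <- function(counts_list, group = "popX") {
  markers <- sprintf("m%02d", seq_along(counts_list))
  n <- sum(counts_list[[1]])
  geno <- t(vapply(counts_list, function(cnt) {
    c(rep(names(cnt), cnt))
  }, character(n)))
  rownames(geno) <- markers
  population_genotypes(group, geno)
}

# Independent brute-force oracle for Mendelian consistency: enumerate the
# four allele transmissions of a parent pair.
oracle_consistent <- function(p1, p2, progeny) {
  a1 <- strsplit(p1, "")[[1]]
  a2 <- strsplit(p2, "")[[1]]
  poss <- unique(unlist(lapply(a1, function(x) {
    vapply(a2, function(y) paste(sort(c(x, y)), collapse = ""), character(1))
  })))
  progeny %in% poss
}
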