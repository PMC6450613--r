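#' Family genotype container
#'
#' Genotypes for one cross: the two parents and a progeny matrix. Genotypes
#' use two-symbol coding (`aa`/`ab`/`bb`, `a` = reference allele); missing
#' values are `NA` in memory and `--` on disk.
#'
#' @param family_id family identifier.
#' @param parents data.frame with columns `marker`, `parent1`, `parent2`.
#' @param geno character matrix, markers x progeny, rownames = marker ids.
#' @param truth optional list of simulation truth labels (see
#'   [simulate_family()]).
#' @return object of class `family_genotypes`.
#' @export
family_genotypes <- function(family_id, parents, geno, truth = NULL) {
  stopifnot(all(c("marker", "parent1", "parent2") %in% names(parents)))
  if (ncol(geno) < 1) stop("family must have at least 1 progeny")
  assert_genotype_codes(parents$parent1, "parent")
  assert_genotype_codes(parents$parent2, "parent")
  assert_genotype_codes(geno, "progeny")
  if (!identical(rownames(geno), parents$marker)) {
    stop("progeny matrix rownames must match parents$marker")
  }
  structure(list(family_id = family_id, parents = parents, geno = geno,
                 truth = truth),
            class = "family_genotypes")
}

#' Population genotype container
#' @param group group name.
#' @param geno character matrix markers x samples (codes `aa`/`ab`/`bb`/`NA`).
#' @return object of class `population_genotypes`.
#' @export
population_genotypes <- function(group, geno) {
  assert_genotype_codes(geno, "population genotypes")
  structure(list(group = group, geno = geno), class = "population_genotypes")
}

#' Mendelian progeny-class probabilities for a parent pair
#'
#' @param p1,p2 parent genotype codes (`aa`/`ab`/`bb`).
#' @return numeric vector of probabilities over classes `c(aa, ab, bb)`.
#' @export
mendelian_probs <- function(p1, p2) {
  gamete <- function(g) switch(g, aa = c(a = 1, b = 0), ab = c(a = .5, b = .5),
                               bb = c(a = 0, b = 1),
                               stop("unknown parent genotype code: ", g))
  g1 <- gamete(p1); g2 <- gamete(p2)
  c(aa = g1["a"] * g2["a"],
    ab = g1["a"] * g2["b"] + g1["b"] * g2["a"],
    bb = g1["b"] * g2["b"]) |> unname() |> setNames(GENOTYPE_CODES)
}

#' Exponentially tilted progeny-class probabilities
#'
#' Distortion is modeled as exponential tilting of the Mendelian class
#' probabilities by the number of `b` alleles: class weights
#' `exp(strength * n_b)`. Strength 0 recovers the Mendelian null.
#'
#' @param p1,p2 parent genotype codes.
#' @param strength tilting strength (log scale per `b` allele).
#' @return tilted probability vector over `c(aa, ab, bb)`.
#' @export
tilted_probs <- function(p1, p2, strength) {
  p <- mendelian_probs(p1, p2)
  w <- exp(strength * c(0, 1, 2))
  pw <- p * w
  pw / sum(pw)
}

#' Simulate a genotyped family with injected error modes
#'
#' Progeny genotypes are drawn from the (possibly tilted) Mendelian class
#' distribution of each marker's parent pair. A labeled fraction of
#' informative markers is distorted by exponential tilting; Mendelian errors
#' and missingness are then injected independently per progeny cell. Truth
#' labels (distorted markers, error cells) are returned for test oracles.
#'
#' @param truth a `true_variants` table (marker ids are taken as
#'   `<seqname>_<pos>`); parents are drawn Hardy-Weinberg from the group AF
#'   unless `cross` is supplied.
#' @param cross optional data.frame `marker`, `parent1`, `parent2` fixing the
#'   cross design per marker.
#' @param n_progeny number of progeny (>= 1).
#' @param mendelian_error_rate per-cell probability of replacing the drawn
#'   genotype with a different random genotype.
#' @param missing_rate per-cell missingness probability.
#' @param distorted_fraction fraction of informative markers distorted.
#' @param distortion_strength tilting strength for distorted markers
#'   (default `log(2)`: each `b` allele doubles its class weight, a strong
#'   but realistic transmission-ratio distortion).
#' @param group AF column used to draw parents (default first).
#' @param family_id identifier for the returned family.
#' @param seed integer seed.
#' @return [family_genotypes()] whose `truth` element lists
#'   `distorted_markers`, `error_cells` (logical matrix, pre-missingness)
#'   and `pre_error_geno` (the clean drawn genotypes).
#' @export
simulate_family <- function(truth, cross = NULL, n_progeny,
                            mendelian_error_rate = 0.01, missing_rate = 0.05,
                            distorted_fraction = 0.05,
                            distortion_strength = log(2),
                            group = NULL, family_id = "fam1", seed) {
  if (n_progeny < 1) stop("n_progeny must be >= 1")
  stopifnot(mendelian_error_rate >= 0, mendelian_error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1,
            distorted_fraction >= 0, distorted_fraction <= 1)
  with_seed(seed, {
    if (is.null(cross)) {
      afm <- true_af_matrix(truth)
      group <- group %||% colnames(afm)[1]
      p <- truth[[paste0("af_", group)]]
      draw_parent <- function(p) {
        probs <- cbind((1 - p)^2, 2 * p * (1 - p), p^2)
        GENOTYPE_CODES[apply(probs, 1, function(pr) sample.int(3, 1, prob = pr))]
      }
      cross <- data.frame(marker = paste(truth$seqname, truth$pos, sep = "_"),
                          parent1 = draw_parent(p), parent2 = draw_parent(p),
                          stringsAsFactors = FALSE)
    }
    m <- nrow(cross)
    informative <- vapply(seq_len(m), function(i) {
      sum(mendelian_probs(cross$parent1[i], cross$parent2[i]) > 0) > 1
    }, logical(1))
    n_dist <- round(distorted_fraction * sum(informative))
    distorted <- sort(sample(which(informative), n_dist))
    geno <- matrix(NA_character_, m, n_progeny,
                   dimnames = list(cross$marker,
                                   sprintf("%s_p%03d", family_id,
                                           seq_len(n_progeny))))
    for (i in seq_len(m)) {
      pr <- if (i %in% distorted) {
        tilted_probs(cross$parent1[i], cross$parent2[i], distortion_strength)
      } else {
        mendelian_probs(cross$parent1[i], cross$parent2[i])
      }
      geno[i, ] <- sample(GENOTYPE_CODES, n_progeny, replace = TRUE, prob = pr)
    }
    pre_error <- geno
    err <- matrix(runif(m * n_progeny) < mendelian_error_rate, m, n_progeny)
    if (any(err)) {
      idx <- which(err)
      geno[idx] <- vapply(geno[idx],
                          function(g) sample(setdiff(GENOTYPE_CODES, g), 1L),
                          character(1), USE.NAMES = FALSE)
    }
    miss <- matrix(runif(m * n_progeny) < missing_rate, m, n_progeny)
    geno[miss] <- NA_character_
    family_genotypes(family_id, cross, geno,
                     truth = list(distorted_markers = cross$marker[distorted],
                                  error_cells = err & !miss,
                                  pre_error_geno = pre_error))
  })
}

#' Simulate population genotypes under Hardy-Weinberg equilibrium
#'
#' @param truth a `true_variants` table.
#' @param group AF column to use.
#' @param n_samples diploid individuals.
#' @param missing_rate per-cell missingness probability.
#' @param seed integer seed.
#' @return [population_genotypes()].
#' @export
simulate_population <- function(truth, group, n_samples, missing_rate = 0.02,
                                seed) {
  stopifnot(n_samples >= 1)
  p <- truth[[paste0("af_", group)]]
  if (is.null(p)) stop("no AF column for group ", group)
  markers <- paste(truth$seqname, truth$pos, sep = "_")
  with_seed(seed, {
    m <- length(p)
    alt_copies <- matrix(rbinom(m * n_samples, 2, rep(p, n_samples)),
                         m, n_samples)
    geno <- matrix(GENOTYPE_CODES[alt_copies + 1L], m, n_samples,
                   dimnames = list(markers,
                                   sprintf("%s_s%03d", group, seq_len(n_samples))))
    geno[matrix(runif(m * n_samples) < missing_rate, m, n_samples)] <- NA_character_
    population_genotypes(group, geno)
  })
}
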