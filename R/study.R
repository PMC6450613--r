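#' Simulate a complete array-design study
#'
#' Generates every pipeline input with seeded statistical structure and
#' writes it under `out_dir/inputs`: a multi-chromosome genome with
#' unplaced contigs and a dedicated sdY contig, a gene annotation, true
#' SNPs with per-group allele frequencies, four platform call sets (two
#' GBS trim-parameter runs sharing true SNPs plus platform-private false
#' positives), GBS family and population genotype matrices, and sdY
#' candidates. It then assembles the panel once (design stage only),
#' simulates a post-design array genotyping run across the test groups,
#' writes the call sets, and returns a ready [pipeline_config()] for the
#' full run.
#'
#' False-positive candidates have true allele frequency 0 in every group,
#' so a designed panel carrying them yields monomorphic assays - the
#' mechanism behind realistic (sub-100%) conversion-to-polymorphic rates.
#'
#' @param out_dir directory for inputs and outputs.
#' @param seed integer master seed; all stage seeds derive from it.
#' @param n_chromosomes,chromosome_length,n_contigs,contig_length_range
#'   genome shape (defaults: 3 chromosomes x 200 kb, 12 contigs of
#'   5-20 kb).
#' @param snp_density true SNPs per kb.
#' @param groups test-group names.
#' @param n_families,n_progeny GBS family structure.
#' @param n_population_samples samples per GBS population.
#' @param n_samples_per_group named vector of array-test sample counts.
#' @param budget array budget (markers).
#' @param profiles named list of [platform_profile()]s.
#' @param sdy_failure_rate per-cell no-call rate on sdY assays in males.
#' @param seed_offset added to the derived stage seeds (lets callers draw
#'   independent replicate studies from one master seed).
#' @return a [pipeline_config()] whose `out_dir` is `out_dir/results`.
#' @export
simulate_study <- function(out_dir, seed,
                           n_chromosomes = 3, chromosome_length = 200000,
                           n_contigs = 12, contig_length_range = c(5000, 20000),
                           snp_density = 2,
                           groups = c("fraser", "nauyuk", "treeriver",
                                      "iceland"),
                           n_families = 2, n_progeny = 30,
                           n_population_samples = 24,
                           n_samples_per_group = c(fraser = 30, nauyuk = 40,
                                                   treeriver = 20,
                                                   iceland = 60),
                           budget = 800,
                           profiles = default_platform_profiles(),
                           sdy_failure_rate = 0, seed_offset = 0) {
  in_dir <- file.path(out_dir, "inputs")
  dir.create(in_dir, recursive = TRUE, showWarnings = FALSE)
  sd <- function(k) derive_seed(seed, k + seed_offset)

  genome <- generate_genome(n_chromosomes, chromosome_length, n_contigs,
                            contig_length_range, seed = sd(1))
  # dedicated sdY contig: male-specific gene sequence the sexing markers sit on
  sdy_seq <- with_seed(sd(2), random_dna(2000))
  genome <- genome_assembly(c(genome$sequences, sdY_contig = sdy_seq),
                            c(genome$is_chromosome, sdY_contig = FALSE))
  annotation <- generate_annotation(genome, genes_per_mb = 20, seed = sd(3))
  truth <- generate_true_variants(
    genome, density = snp_density,
    af_distribution = list(name = "uniform", min = 0.02, max = 0.6),
    groups = groups, seed = sd(4))
  truth <- truth[truth$seqname != "sdY_contig", , drop = FALSE]

  callsets <- list(
    highcov = simulate_platform_callset(truth, genome, profiles$highcov,
                                        group = groups[2], seed = sd(5)),
    gbs = NULL, rad = simulate_platform_callset(truth, genome, profiles$rad,
                                                group = groups[2],
                                                seed = sd(6)),
    rnaseq = simulate_platform_callset(truth, genome, profiles$rnaseq,
                                       group = groups[1], seed = sd(7)))
  gbs_runs <- list(
    t85 = simulate_platform_callset(truth, genome, profiles$gbs,
                                    group = groups[1], seed = sd(8)),
    t40 = simulate_platform_callset(truth, genome, profiles$gbs,
                                    group = groups[1], seed = sd(9)))
  callsets$gbs <- deduplicate_candidates(gbs_runs)$candidates

  # sdY candidates: six presence/absence markers on the sdY contig
  sdy_pos <- seq(300, 1800, length.out = 6)
  sdy_ref <- substring(sdy_seq, sdy_pos, sdy_pos)
  sdy <- with_seed(sd(10), data.frame(
    id = sprintf("sdy_%02d", 1:6), platform = "sdy", seqname = "sdY_contig",
    pos = as.integer(sdy_pos), ref = sdy_ref,
    alt = random_other_base(sdy_ref),
    flank_left = substring(sdy_seq, sdy_pos - 50, sdy_pos - 1),
    flank_right = substring(sdy_seq, sdy_pos + 1, sdy_pos + 50),
    stringsAsFactors = FALSE))
  sdy <- as_candidates(sdy)

  paths <- list(genome = file.path(in_dir, "genome.fasta"),
                annotation = file.path(in_dir, "genes.gff3"))
  write_fasta(genome, paths$genome)
  write_annotation(annotation, paths$annotation)
  cand_paths <- list()
  for (pf in c("highcov", "rad", "rnaseq")) {
    cand_paths[[pf]] <- file.path(in_dir, paste0(pf, ".vcf"))
    write_vcf(callsets[[pf]], cand_paths[[pf]], genome)
  }
  cand_paths$gbs <- c(file.path(in_dir, "gbs_t85.vcf"),
                      file.path(in_dir, "gbs_t40.vcf"))
  write_vcf(gbs_runs$t85, cand_paths$gbs[1], genome)
  write_vcf(gbs_runs$t40, cand_paths$gbs[2], genome)
  cand_paths$sdy <- file.path(in_dir, "sdy.vcf")
  write_vcf(sdy, cand_paths$sdy, genome)

  # families and populations are genotyped at the GBS-detected true SNPs
  gbs_true <- callsets$gbs[callsets$gbs$is_true %in% TRUE, , drop = FALSE]
  truth_gbs <- truth[match(marker_key(gbs_true$seqname, gbs_true$pos),
                           marker_key(truth$seqname, truth$pos)), ,
                     drop = FALSE]
  fam_paths <- list()
  for (i in seq_len(n_families)) {
    fam <- simulate_family(truth_gbs, n_progeny = n_progeny,
                           group = groups[1],
                           family_id = paste0("fam", i), seed = sd(20 + i))
    fam_paths[[paste0("fam", i)]] <- file.path(in_dir,
                                               sprintf("family%d.tsv", i))
    write_genotypes(fam, fam_paths[[paste0("fam", i)]])
  }
  pop_paths <- list()
  for (i in 1:2) {
    pop <- simulate_population(truth_gbs, groups[min(i + 1, length(groups))],
                               n_population_samples, seed = sd(30 + i))
    pop$group <- paste0("pop", i)
    pop_paths[[paste0("pop", i)]] <- file.path(in_dir,
                                               sprintf("population%d.tsv", i))
    write_genotypes(pop, pop_paths[[paste0("pop", i)]])
  }

  base_cfg <- pipeline_config(
    genome = paths$genome, annotation = paths$annotation,
    candidates = cand_paths, families = fam_paths, populations = pop_paths,
    ambiguity_exempt_sources = "gbs",
    selection = selection_config(budget = budget, rare_spacing = 50000,
                                 common_spacing = 10000),
    seed = seed, out_dir = file.path(out_dir, "design"))
  design <- run_pipeline(base_cfg)
  panel <- design$panel

  # post-design genotyping run: group AFs from truth, 0 for false positives
  key <- marker_key(panel$seqname, panel$pos)
  tkey <- marker_key(truth$seqname, truth$pos)
  afm <- matrix(0, nrow(panel), length(groups),
                dimnames = list(panel$marker_id, groups))
  hit <- match(key, tkey)
  for (g in groups) {
    afm[!is.na(hit), g] <- truth[[paste0("af_", g)]][hit[!is.na(hit)]]
  }
  sdy_ids <- panel$marker_id[panel$tier == 2L]
  run <- simulate_array_run(panel, afm,
                            n_samples_per_group = n_samples_per_group,
                            sdy_markers = sdy_ids,
                            sdy_failure_rate = sdy_failure_rate,
                            seed = sd(40))
  callset_paths <- list()
  for (g in names(run)) {
    callset_paths[[g]] <- file.path(in_dir, paste0("callset_", g, ".tsv"))
    write_callset(run[[g]], callset_paths[[g]])
  }

  pipeline_config(
    genome = paths$genome, annotation = paths$annotation,
    candidates = cand_paths, families = fam_paths, populations = pop_paths,
    callsets = callset_paths, ambiguity_exempt_sources = "gbs",
    selection = base_cfg$selection, sdy_marker_ids = sdy_ids,
    seed = seed, out_dir = file.path(out_dir, "results"))
}
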