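#' Pipeline configuration
#'
#' Declarative description of one end-to-end run: input paths, QC
#' thresholds, the [selection_config()] and the seed. CLI flags override
#' config values; the effective config is echoed into the output directory.
#'
#' @param genome path to the assembly FASTA.
#' @param annotation path to the gene annotation GFF3 (optional).
#' @param candidates named list of candidate VCF paths; names are the
#'   platforms (`highcov`, `gbs`, `rad`, `rnaseq`, `sdy`). `gbs` may be a
#'   character vector (e.g. the two trim-parameter runs, deduplicated on
#'   load).
#' @param families named list of family genotype TSV paths (GBS families).
#' @param populations named list of population genotype TSV paths.
#' @param callsets optional named list of post-genotyping call-set TSV
#'   paths (one per test group); enables the evaluation stage.
#' @param scores optional TSV path with columns `id`, `score`, `label`
#'   (externally supplied conversion scores).
#' @param max_missing,alpha,min_maf QC thresholds (see
#'   [filter_missingness()], [test_segregation_distortion()],
#'   [filter_population_maf()]).
#' @param ambiguity_exempt_sources platforms whose A/T-G/C candidates are
#'   retained.
#' @param selection a [selection_config()].
#' @param sdy_marker_ids optional sdY panel ids for the evaluation stage
#'   (defaults to the tier-2 markers of the assembled panel).
#' @param seed integer seed.
#' @param out_dir output directory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome, annotation = NULL, candidates = list(),
                            families = list(), populations = list(),
                            callsets = list(), scores = NULL,
                            max_missing = 0.5, alpha = 0.01, min_maf = 0.05,
                            ambiguity_exempt_sources = character(0),
                            selection = selection_config(),
                            sdy_marker_ids = NULL, seed = 1, out_dir) {
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  paths <- c(cfg$genome, cfg$annotation, unlist(cfg$candidates),
             unlist(cfg$families), unlist(cfg$populations),
             unlist(cfg$callsets), cfg$scores)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("pipeline_config: missing input file(s): ",
         paste(missing, collapse = ", "))
  }
  stopifnot(cfg$max_missing >= 0, cfg$max_missing <= 1,
            cfg$alpha > 0, cfg$alpha < 1, cfg$min_maf >= 0, cfg$min_maf <= 1,
            inherits(cfg$selection, "selection_config"))
  invisible(cfg)
}

log_stage <- function(log, stage, n_in, n_dropped, n_out, note = "") {
  rbind(log, data.frame(stage = stage, n_in = n_in, n_dropped = n_dropped,
                        n_out = n_out, note = note, stringsAsFactors = FALSE))
}

marker_key <- function(seqname, pos) paste(seqname, pos, sep = "_")

#' Run the full design (and optionally evaluation) pipeline
#'
#' Reads every configured input, applies the discovery QC filters,
#' cross-validates candidates between platforms, assembles the tiered
#' panel with probes, and - when post-genotyping call sets are supplied -
#' classifies markers, summarises cross-group sharing, genome coverage and
#' genotypic sex. All stage outputs and an audit log (one line per stage
#' with in/dropped/out counts) are written to `out_dir`; the run is fully
#' deterministic given the config.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with the main in-memory results: `panel`,
#'   `audit`, `log`, and when call sets are present `classifications`,
#'   `sharing`, `coverage`, `sex`.
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- data.frame()

  genome <- read_fasta(config$genome)
  annotation <- if (!is.null(config$annotation)) {
    read_annotation(config$annotation, genome)
  }
  scores <- if (!is.null(config$scores)) {
    read.delim(config$scores, stringsAsFactors = FALSE)
  }
  cands <- lapply(config$candidates, function(p) {
    if (length(p) == 1) return(read_vcf(p, genome))
    dedup <- deduplicate_candidates(lapply(p, read_vcf, genome = genome))
    dedup$candidates
  })

  # --- GBS family/population QC -------------------------------------------
  fams <- Map(function(p, id) read_genotypes(p, "family", id),
              config$families, names(config$families) %||%
                paste0("fam", seq_along(config$families)))
  pops <- Map(function(p, id) read_genotypes(p, "population", id),
              config$populations, names(config$populations) %||%
                paste0("pop", seq_along(config$populations)))
  fam_reports <- list()
  if (length(fams) > 0) {
    fam_reports$missingness <- filter_missingness(fams, config$max_missing)
    fam_reports$mendelian <- detect_mendelian_errors(fams)
    fam_reports$segregation <- test_segregation_distortion(fams, config$alpha)
    for (nm in names(fam_reports)) {
      write_filter_report(fam_reports[[nm]],
                          file.path(config$out_dir,
                                    paste0("qc_family_", nm, ".tsv")))
    }
  }
  pop_maf <- lapply(pops, filter_population_maf, min_maf = config$min_maf)
  for (nm in names(pop_maf)) {
    write_filter_report(pop_maf[[nm]],
                        file.path(config$out_dir,
                                  paste0("qc_population_maf_", nm, ".tsv")))
  }
  fam_pass <- NULL
  if (length(fam_reports) > 0) {
    fam_pass <- Reduce(function(acc, r) {
      p <- r$pass[match(acc$marker, r$marker)]
      acc$pass <- acc$pass & !(p %in% FALSE)
      acc
    }, fam_reports[-1],
    data.frame(marker = fam_reports[[1]]$marker,
               pass = !(fam_reports[[1]]$pass %in% FALSE)))
  }

  # --- high coverage record QC and stratification -------------------------
  highcov <- cands$highcov %||% empty_candidates()
  n0 <- nrow(highcov)
  if (n0 > 0) {
    ok_i <- filter_highcov_record(highcov, "initial")$pass %in% TRUE
    highcov <- highcov[ok_i, , drop = FALSE]
    ok_d <- filter_highcov_record(highcov, "design")$pass %in% TRUE
    highcov <- highcov[ok_d, , drop = FALSE]
    log <- log_stage(log, "highcov_record_qc", n0, n0 - nrow(highcov),
                     nrow(highcov))
    if (!is.null(annotation)) {
      highcov <- label_in_transcript(highcov, annotation)
      amb <- exclude_transcript_ambiguity(highcov)
      highcov <- highcov[amb$pass, , drop = FALSE]
    }
    n1 <- nrow(highcov)
    highcov <- highcov[check_flank_length(highcov), , drop = FALSE]
    keep <- !is_strand_ambiguous(highcov$ref, highcov$alt) |
      highcov$platform %in% config$ambiguity_exempt_sources
    highcov <- highcov[keep, , drop = FALSE]
    log <- log_stage(log, "highcov_flank_ambiguity", n1, n1 - nrow(highcov),
                     nrow(highcov))
  }
  # --- cross-platform validation ------------------------------------------
  small_sets <- cands[intersect(c("gbs", "rad", "rnaseq"), names(cands))]
  cv <- lapply(small_sets, function(s) cross_validate(cands$highcov, s))
  cp_ids <- unique(unlist(lapply(cv, function(x) x$pairs$id_a)))

  # high-coverage pools hold only SNPs not already taken by cross validation
  stratum <- classify_af(highcov$af, config$selection)
  in_tx <- highcov$in_transcript %in% TRUE
  not_cv <- !highcov$id %in% cp_ids
  pools <- list(
    rare_all = highcov[stratum == "rare" & not_cv, , drop = FALSE],
    common_intergenic = highcov[stratum == "common" & !in_tx & not_cv, ,
                                drop = FALSE])
  cv_counts <- vapply(cv, function(x) nrow(x$pairs), integer(1))
  if (length(cv) > 0) {
    write.table(data.frame(platform_pair = paste0("highcov&", names(cv)),
                           matches = cv_counts),
                file.path(config$out_dir, "cross_validation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    log <- log_stage(log, "cross_validation", sum(cv_counts), 0,
                     length(cp_ids))
  }

  # --- GBS priority criteria ----------------------------------------------
  gbs_sel_ids <- character(0)
  if (!is.null(cands$gbs)) {
    fam_status <- lapply(fams, family_segregation_status,
                         reports = fam_reports)
    sel <- gbs_priority_select(pop_maf, fam_status)
    sel_markers <- sel$marker[sel$selected]
    if (!is.null(fam_pass)) {
      drop <- fam_pass$marker[fam_pass$pass %in% FALSE]
      sel_markers <- setdiff(sel_markers, drop)
    }
    gbs_key <- marker_key(cands$gbs$seqname, cands$gbs$pos)
    gbs_sel_ids <- cands$gbs$id[gbs_key %in% sel_markers]
    log <- log_stage(log, "gbs_priority", nrow(sel), 0, length(gbs_sel_ids))
  }

  # --- assemble panel ------------------------------------------------------
  all_cands <- do.call(rbind, lapply(cands, as_candidates))
  tier1 <- build_high_priority_tier(
    all_cands, cp_ids, gbs_selected = gbs_sel_ids,
    ambiguity_exempt_sources = config$ambiguity_exempt_sources)
  sdy <- cands$sdy %||% empty_candidates()
  filler_ids <- setdiff(
    unlist(lapply(cands[intersect(c("gbs", "rnaseq"), names(cands))],
                  function(x) x$id)),
    c(tier1$tier1$id, cp_ids))
  filler <- all_cands[all_cands$id %in% filler_ids, , drop = FALSE]
  filler <- filler[check_flank_length(filler), , drop = FALSE]
  keep <- !is_strand_ambiguous(filler$ref, filler$alt) |
    filler$platform %in% config$ambiguity_exempt_sources
  filler <- filler[keep, , drop = FALSE]
  panel <- assemble_panel(tier1$tier1, sdy, pools, filler,
                          config = config$selection,
                          conversion_scores = scores, genome = genome)
  log <- log_stage(log, "panel_assembly",
                   nrow(tier1$tier1) + nrow(sdy) + nrow(pools$rare_all) +
                     nrow(pools$common_intergenic) + nrow(filler),
                   sum(panel$audit$status == "dropped"),
                   nrow(panel$manifest))
  write_manifest(panel$manifest, file.path(config$out_dir, "panel.tsv"))
  write_vcf(panel$manifest, file.path(config$out_dir, "panel.vcf"),
            genome = genome)
  write.table(panel$audit, file.path(config$out_dir, "panel_audit.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  results <- list(panel = panel$manifest, audit = panel$audit)

  # --- evaluation ----------------------------------------------------------
  if (length(config$callsets) > 0) {
    callsets <- Map(function(p, g) read_callset(p, g),
                    config$callsets, names(config$callsets))
    qc <- lapply(callsets, apply_sample_qc)
    classifications <- lapply(qc, function(x) classify_markers(x$callset))
    for (g in names(classifications)) {
      write.table(as.data.frame(classifications[[g]]),
                  file.path(config$out_dir,
                            paste0("classification_", g, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    poly_sets <- lapply(classifications,
                        function(cl) cl$marker[cl$polymorphic])
    sharing <- venn_sharing(poly_sets)
    write.table(sharing$per_group,
                file.path(config$out_dir, "sharing_groups.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(sharing$regions,
                file.path(config$out_dir, "sharing_regions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cov <- coverage_report(panel$manifest, genome, annotation)
    write.table(cov$per_chromosome,
                file.path(config$out_dir, "coverage_chromosomes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    sdy_ids <- config$sdy_marker_ids %||%
      panel$manifest$marker_id[panel$manifest$tier == 2L]
    sex <- NULL
    if (length(sdy_ids) > 0 &&
        all(sdy_ids %in% rownames(callsets[[1]]$calls))) {
      sex <- predict_sex(callsets, sdy_ids)
      write.table(sex$predictions,
                  file.path(config$out_dir, "sex_report.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    log <- log_stage(log, "evaluation", nrow(panel$manifest),
                     nrow(panel$manifest) - sharing$union_polymorphic,
                     sharing$union_polymorphic,
                     "panel markers in / polymorphic in >=1 group out")
    results <- c(results, list(classifications = classifications,
                               sharing = sharing, coverage = cov, sex = sex))
  }

  write.table(log, file.path(config$out_dir, "audit_log.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  # echo the effective config with paths reduced to basenames so the file
  # is invariant to where the run was staged
  cfg_echo <- config[setdiff(names(config), "out_dir")]
  for (fld in c("genome", "annotation", "scores", "candidates", "families",
                "populations", "callsets")) {
    if (!is.null(cfg_echo[[fld]])) {
      cfg_echo[[fld]] <- rapply(as.list(cfg_echo[fld]), basename,
                                how = "unlist")
    }
  }
  writeLines(utils::capture.output(utils::str(cfg_echo, give.attr = FALSE)),
             file.path(config$out_dir, "effective_config.txt"))
  results$log <- log
  invisible(results)
}
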