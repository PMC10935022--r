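#' Pipeline configuration
#'
#' Aggregates every stage's tunable parameters with the reference defaults
#' (QC thresholds 25/30/20/10/2x/5%, group-polymorphism threshold 0.1,
#' tiling thresholds 0.818/0.69, probe call-rate threshold 0.97, error
#' rates 0/3/5%) plus the simulation configuration, stage seeds, and the
#' downselection targets.
#'
#' @param seed master seed; per-stage seeds are derived from it.
#' @param sim a [sim_config()] for the synthetic cohort (its own seed is
#'   overridden by `seed`).
#' @param qc a [qc_thresholds()].
#' @param group_threshold strict alt-allele frequency bound for group
#'   polymorphism.
#' @param tile_hi,tile_lo strand-tiling thresholds.
#' @param call_rate_threshold,min_minor_count probe classification
#'   parameters.
#' @param target_total,chloroplast_target downselection targets; `NULL`
#'   target_total defaults to half the validated candidates (the array is
#'   smaller than the candidate list by construction).
#' @param n_bootstrap bootstrap replicates for the tree (default 100 at
#'   pipeline scale; the reference analysis used 1000).
#' @param ld_r2 LD pruning threshold.
#' @param error_rates injected genotyping-error rates.
#' @param n_error_targets number of divergent samples receiving injected
#'   errors.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = sim_config(seed = seed),
                            qc = qc_thresholds(),
                            group_threshold = 0.1,
                            tile_hi = 0.818, tile_lo = 0.69,
                            call_rate_threshold = 0.97, min_minor_count = 2,
                            target_total = NULL, chloroplast_target = NULL,
                            n_bootstrap = 100,
                            ld_r2 = 1,
                            error_rates = c(0, 0.03, 0.05),
                            n_error_targets = 2) {
  sim$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), sim = sim, qc = qc,
                 group_threshold = group_threshold, tile_hi = tile_hi,
                 tile_lo = tile_lo,
                 call_rate_threshold = call_rate_threshold,
                 min_minor_count = min_minor_count,
                 target_total = target_total,
                 chloroplast_target = chloroplast_target,
                 n_bootstrap = n_bootstrap, ld_r2 = ld_r2,
                 error_rates = error_rates,
                 n_error_targets = n_error_targets),
            class = "pipeline_config")
}

#' Run the full array-design pipeline on a simulated cohort
#'
#' Executes simulate -> write/read fixture -> quality control -> group
#' assignment and part-1 filtering -> strand tiling -> simulated array
#' runs -> probe classification and two-run consistency -> best-probe
#' selection -> downselection -> genotype metrics -> LD pruning, PCA and
#' bootstrapped neighbor-joining tree -> genotyping-error robustness, and
#' writes each stage's outputs plus a JSON manifest of per-stage counts and
#' file hashes under `out_dir`. All randomness derives from `config$seed`,
#' so two runs with the same configuration are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if absent).
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- config$seed
  stage_seed <- function(k) (seed + k) %% .Machine$integer.max
  # stage failures halt with a stage-named error
  with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  ## stage 1: simulate and round-trip the fixture
  cohort <- with_stage("simulate", simulate_cohort(config$sim))
  fix_dir <- file.path(out_dir, "fixture")
  paths <- write_fixture_bundle(cohort, fix_dir)
  vs <- read_vcf(paths[["vcf"]])
  counts <- list(input_sites = nrow(vs$sites))

  ## stage 2: post-calling QC
  qc <- with_stage("qc", apply_qc(vs, config$qc))
  counts$qc_retained <- length(qc$report$retained)
  write_tsv(qc$report$stages, file.path(out_dir, "qc_stages.tsv"))

  ## stage 3: group assignment + part-1 filtering
  vs_qc <- qc$variants
  assignments <- assign_groups(vs_qc$gt, cohort$samples,
                               threshold = config$group_threshold,
                               ploidy = vs_qc$sites$ploidy)
  windows <- build_genic_windows(paths[["gff3"]],
                                 flank_bp = config$sim$flank_bp)
  p1 <- with_stage("select", filter_part1(vs_qc$sites, assignments, windows))
  counts$part1_retained <- length(p1$retained)
  write_tsv(p1$stages, file.path(out_dir, "part1_stages.tsv"))

  ## stage 4: strand-tiling decisions
  sc <- cohort$scores[cohort$scores$locus_id %in% p1$retained, ]
  tiles <- with_stage("tiling", tile_decisions(sc, vs_qc$sites, hi = config$tile_hi,
                                               lo = config$tile_lo))
  tiled <- tiles$locus_id[tiles$decision != "reject"]
  counts$tiled <- length(tiled)
  write_tsv(tiles, file.path(out_dir, "tiling_decisions.tsv"))

  ## stage 5: simulated array runs on the tiled loci
  best_score <- do.call(rbind, lapply(split(sc, sc$locus_id), function(x) {
    x[which.max(x$pconvert), c("locus_id", "pconvert")]
  }))
  truth_tiled <- cohort$truth[tiled, , drop = FALSE]
  ploidy_tiled <- vs_qc$sites$ploidy[match(tiled, vs_qc$sites$locus_id)]
  runs <- with_stage("array_runs",
    simulate_array_runs(truth_tiled, cohort$samples, best_score,
                        ploidy = ploidy_tiled, seed = stage_seed(5)))
  write_call_matrix(runs$analysis1, file.path(fix_dir, "calls_analysis1.tsv"))
  write_call_matrix(runs$analysis2, file.path(fix_dir, "calls_analysis2.tsv"))

  ## stage 6: probe classification + two-run consistency
  cls <- classify_probes(runs$analysis1, config$call_rate_threshold,
                         config$min_minor_count, ploidy_tiled)
  phr <- cls$locus_id[cls$category == "PolyHighResolution"]
  counts$phr <- length(phr)
  cons <- with_stage("validate", call_consistency(runs$analysis1, runs$analysis2, phr))
  consistent <- cons$locus_id[cons$consistent]
  counts$consistent <- length(consistent)

  ## stage 7: best probe per locus by sequence concordance
  seq_gt <- vs_qc$gt
  probes <- do.call(rbind, lapply(consistent, function(l) {
    strands <- sc[sc$locus_id == l & sc$buildable, "strand"]
    if (!length(strands)) strands <- "fwd"
    data.frame(locus_id = l, strand = strands,
               probe_id = paste0(l, "_", strands),
               concordance = concordance(runs$analysis1[l, ], seq_gt[l, ]),
               stringsAsFactors = FALSE)
  }))
  best <- select_best_probes(probes)
  counts$validated <- nrow(best)

  ## stage 8: downselection
  cand <- vs_qc$sites[match(best$locus_id, vs_qc$sites$locus_id), ]
  n_cp <- sum(cand$ploidy == 1L)
  cp_target <- if (is.null(config$chloroplast_target)) {
    floor(n_cp / 2)
  } else config$chloroplast_target
  total <- if (is.null(config$target_total)) {
    floor(nrow(cand) / 2)
  } else config$target_total
  ds <- with_stage("downselect", downselect(cand, total, cp_target, seed = stage_seed(8)))
  counts$downselected <- length(ds$selected)
  write_tsv(ds$report, file.path(out_dir, "downselect_report.tsv"))
  write_tsv(data.frame(locus_id = ds$selected),
            file.path(out_dir, "selected_snps.tsv"))

  ## stage 9: genotype metrics on the selected array content
  array_calls <- runs$analysis1[ds$selected, , drop = FALSE]
  sel_ploidy <- cand$ploidy[match(ds$selected, cand$locus_id)]
  het <- vapply(colnames(array_calls), function(s) {
    heterozygosity(array_calls, s, sel_ploidy)
  }, numeric(1))
  conc <- vapply(colnames(array_calls), function(s) {
    concordance(array_calls[, s], seq_gt[ds$selected, s])
  }, numeric(1))
  metrics <- data.frame(sample_id = colnames(array_calls),
                        heterozygosity_pct = round(het, 2),
                        seq_array_concordance_pct = round(conc, 2),
                        stringsAsFactors = FALSE)
  write_tsv(metrics, file.path(out_dir, "sample_metrics.tsv"))
  clonal <- with_stage("metrics", clonal_identity_report(array_calls, cohort$samples))
  write_tsv(clonal$groups, file.path(out_dir, "clonal_identity.tsv"))

  ## stage 10: population analyses on diploid selected loci
  dip <- ds$selected[sel_ploidy == 2L]
  pruned <- ld_prune(array_calls[dip, , drop = FALSE],
                     vs_qc$sites, r2_threshold = config$ld_r2)
  counts$ld_pruned <- length(pruned)
  pa_calls <- array_calls[pruned, , drop = FALSE]
  fit <- genotype_pca(pa_calls)
  write_tsv(cbind(data.frame(sample_id = rownames(fit$scores)),
                  round(as.data.frame(fit$scores[, 1:3]), 6)),
            file.path(out_dir, "pca_scores.tsv"))
  bs <- with_stage("tree", bootstrap_support(pa_calls, n_replicates = config$n_bootstrap,
                                             seed = stage_seed(10)))
  ape::write.tree(bs$tree, file.path(out_dir, "nj_tree.nwk"))
  write_tsv(bs$support, file.path(out_dir, "bootstrap_support.tsv"))

  ## stage 11: genotyping-error robustness
  targets <- head(cohort$samples$sample_id[cohort$samples$group == "3"],
                  config$n_error_targets)
  universe <- with_stage("errorsim", build_error_universe(pa_calls,
                                     seq_gt[pruned, , drop = FALSE], targets))
  stability <- lapply(config$error_rates, function(rate) {
    inj <- inject_errors(pa_calls, targets, rate, universe,
                         seed = stage_seed(11))
    rep <- stability_report(pa_calls, inj$matrix, targets, cohort$samples)
    data.frame(rate = rate, n_flipped = floor(rate * length(universe)),
               rf = rep$rf,
               assignments_unchanged = all(rep$assignments$unchanged),
               max_displacement = rep$max_displacement,
               stringsAsFactors = FALSE)
  })
  stab <- do.call(rbind, stability)
  write_tsv(stab, file.path(out_dir, "error_stability.tsv"))
  counts$error_universe <- length(universe)

  ## manifest
  files <- sort(list.files(out_dir, recursive = TRUE))
  files <- files[files != "manifest.json"]
  manifest <- list(
    seed = seed,
    counts = counts,
    thresholds = list(qc = unclass(config$qc),
                      group_threshold = config$group_threshold,
                      tile_hi = config$tile_hi, tile_lo = config$tile_lo,
                      call_rate_threshold = config$call_rate_threshold,
                      ld_r2 = config$ld_r2,
                      error_rates = config$error_rates),
    stability = stab,
    files = data.frame(
      path = files,
      md5 = unname(tools::md5sum(file.path(out_dir, files))),
      stringsAsFactors = FALSE)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
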