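#' Simulation configuration for a citrus-like genotyping cohort
#'
#' Defines the cohort the simulator emulates: three divergence groups of
#' founders (mandarins/pummelos and hybrids; citrons; citrus relatives and
#' papedas in the real panel), interspecific hybrids with known parents,
#' clonal duplicates differing only by rare somatic mutations, a haploid
#' chloroplast track, per-call read-level evidence, and per-strand probe
#' convertibility scores.
#'
#' Group allele frequencies follow a Balding-Nichols model: for ancestral
#' frequency p and group differentiation F, the group frequency is drawn from
#' Beta(p(1-F)/F, (1-p)(1-F)/F), so F plays the role of a per-group FST.
#'
#' @param seed integer seed; the same seed yields byte-identical outputs.
#' @param n_chromosomes number of nuclear chromosomes.
#' @param chromosome_lengths lengths in bp, one per chromosome.
#' @param n_loci number of simulated variant loci per chromosome.
#' @param group_sizes founder counts for groups 1/2/3.
#' @param divergence per-group differentiation F in [0, 1).
#' @param n_hybrids number of F1 hybrid samples.
#' @param hybrid_parent_groups list of length-2 integer vectors giving the
#'   parental group of each hybrid; default pairs group 1 with group 2.
#' @param n_clone_pairs number of founder/clone pairs (sources drawn from
#'   group 1).
#' @param somatic_mutation_rate per-locus probability that a clone's nuclear
#'   genotype differs from its source.
#' @param mean_depth expected reads per site per sample (Poisson).
#' @param base_error per-read miscall probability.
#' @param missing_rate probability a call is missing (in addition to sites
#'   with zero simulated reads).
#' @param indel_rate fraction of nuclear loci simulated as insertions.
#' @param gene_density genes per Mb used to lay out the annotation track.
#' @param mean_gene_length mean gene length in bp.
#' @param flank_bp genic flank used when labelling loci genic for the
#'   convertibility-score model.
#' @param pconvert_params list with Beta shape pairs `genic` and
#'   `intergenic`, `equal_prob` (probability the two strand scores tie),
#'   `unbuildable_prob` (probability a strand probe cannot be built), and
#'   `recommend_min` (minimum score for a strand to be recommended).
#' @param chloroplast_n_loci number of haploid chloroplast loci.
#' @param chloroplast_length chloroplast genome length in bp.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 9L,
                       chromosome_lengths = rep(5e6, n_chromosomes),
                       n_loci = rep(200L, n_chromosomes),
                       group_sizes = c(29L, 4L, 8L),
                       divergence = c(0.3, 0.3, 0.3),
                       n_hybrids = 4L,
                       hybrid_parent_groups = NULL,
                       n_clone_pairs = 2L,
                       somatic_mutation_rate = 1e-4,
                       mean_depth = 30,
                       base_error = 0.01,
                       missing_rate = 0.02,
                       indel_rate = 0.1,
                       gene_density = 80,
                       mean_gene_length = 1300,
                       flank_bp = 5000,
                       pconvert_params = list(genic = c(8, 2),
                                              intergenic = c(2, 2),
                                              equal_prob = 0.1,
                                              unbuildable_prob = 0.005,
                                              recommend_min = 0.4),
                       chloroplast_n_loci = 50L,
                       chloroplast_length = 160000) {
  if (is.null(hybrid_parent_groups)) {
    hybrid_parent_groups <- rep(list(c(1L, 2L)), n_hybrids)
  }
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chromosome_lengths = chromosome_lengths, n_loci = as.integer(n_loci),
              group_sizes = as.integer(group_sizes), divergence = divergence,
              n_hybrids = as.integer(n_hybrids),
              hybrid_parent_groups = hybrid_parent_groups,
              n_clone_pairs = as.integer(n_clone_pairs),
              somatic_mutation_rate = somatic_mutation_rate,
              mean_depth = mean_depth, base_error = base_error,
              missing_rate = missing_rate, indel_rate = indel_rate,
              gene_density = gene_density, mean_gene_length = mean_gene_length,
              flank_bp = flank_bp, pconvert_params = pconvert_params,
              chloroplast_n_loci = as.integer(chloroplast_n_loci),
              chloroplast_length = chloroplast_length)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$somatic_mutation_rate, cfg$base_error, cfg$missing_rate,
             cfg$indel_rate, cfg$pconvert_params$equal_prob,
             cfg$pconvert_params$unbuildable_prob)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (any(cfg$divergence < 0 | cfg$divergence >= 1)) {
    stop("divergence parameters must lie in [0, 1)")
  }
  if (length(cfg$chromosome_lengths) != cfg$n_chromosomes ||
      length(cfg$n_loci) != cfg$n_chromosomes) {
    stop("chromosome_lengths and n_loci must have one entry per chromosome")
  }
  if (any(cfg$n_loci < 1) || any(cfg$group_sizes < 1) ||
      cfg$chloroplast_n_loci < 1) {
    stop("counts must be positive")
  }
  if (any(cfg$chromosome_lengths < 10 * cfg$n_loci)) {
    stop("chromosome_lengths too short for the requested locus counts")
  }
  if (length(cfg$hybrid_parent_groups) != cfg$n_hybrids) {
    stop("hybrid_parent_groups must list one parent-group pair per hybrid")
  }
  if (cfg$n_hybrids > 0) {
    pg <- unlist(cfg$hybrid_parent_groups)
    if (any(!pg %in% 1:3)) stop("hybrid parent groups must be in 1..3")
  }
  if (cfg$n_clone_pairs > cfg$group_sizes[1]) {
    stop("n_clone_pairs exceeds the number of group-1 founders available as clone sources")
  }
  invisible(cfg)
}

balding_nichols <- function(p0, f) {
  if (f < 1e-9) return(p0)
  rbeta(length(p0), p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
}

#' Simulate a citrus-like genotyping cohort
#'
#' Generates the sample table, true genotypes, read-level evidence, gene
#' annotation track, and per-strand probe convertibility scores for a cohort
#' of three divergence groups plus hybrids and clone pairs, together with a
#' haploid chloroplast track.
#'
#' Founder genotypes are Binomial(ploidy, p_g) draws from group frequencies
#' under the Balding-Nichols model; hybrids receive one allele sampled from
#' each parent's genotype; clones copy their source and then mutate each
#' nuclear locus independently at `somatic_mutation_rate`. Chloroplast
#' alleles are haploid, copied maternally (first parent) in hybrids and
#' copied exactly in clones. Read depth is Poisson(`mean_depth`); alternate
#' read counts are Binomial(depth, mu) with mu = `base_error`, 0.5, or
#' 1 - `base_error` by true genotype; genotype/base/map qualities are emitted
#' consistently with that evidence. Calls equal the true genotype except that
#' zero-depth sites and a `missing_rate` fraction are missing.
#'
#' @param config a [sim_config()].
#' @return A list of class `sim_cohort` with elements `samples` (data.frame),
#'   `variants` ([variant_set()]), `truth` (loci x samples dosage matrix with
#'   no missing values), `genes` (annotation data.frame), `scores`
#'   (per locus-strand convertibility table), and `config`.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  cfg <- config

  ## ---- samples -------------------------------------------------------
  groups <- rep(1:3, cfg$group_sizes)
  founder_ids <- sprintf("G%d_%02d", groups,
                         unlist(lapply(cfg$group_sizes, seq_len)))
  samples <- data.frame(
    sample_id = founder_ids,
    group = as.character(groups),
    role = "founder",
    clone_of = NA_character_,
    parent1 = NA_character_,
    parent2 = NA_character_,
    label = sprintf("founder_group%d", groups),
    stringsAsFactors = FALSE
  )
  if (cfg$n_hybrids > 0) {
    for (i in seq_len(cfg$n_hybrids)) {
      pg <- cfg$hybrid_parent_groups[[i]]
      p1 <- sample(founder_ids[groups == pg[1]], 1L)
      p2 <- sample(setdiff(founder_ids[groups == pg[2]], p1), 1L)
      samples <- rbind(samples, data.frame(
        sample_id = sprintf("HYB_%02d", i), group = "hybrid", role = "hybrid",
        clone_of = NA_character_, parent1 = p1, parent2 = p2,
        label = sprintf("hybrid_g%dxg%d", pg[1], pg[2]),
        stringsAsFactors = FALSE))
    }
  }
  if (cfg$n_clone_pairs > 0) {
    sources <- sample(founder_ids[groups == 1], cfg$n_clone_pairs)
    for (i in seq_len(cfg$n_clone_pairs)) {
      samples <- rbind(samples, data.frame(
        sample_id = sprintf("%s_clone", sources[i]), group = "1",
        role = "clone", clone_of = sources[i], parent1 = NA_character_,
        parent2 = NA_character_, label = "clonal_accession",
        stringsAsFactors = FALSE))
    }
  }
  n_samp <- nrow(samples)

  ## ---- loci ----------------------------------------------------------
  chroms <- sprintf("chr%d", seq_len(cfg$n_chromosomes))
  site_list <- lapply(seq_len(cfg$n_chromosomes), function(i) {
    pos <- sort(sample.int(cfg$chromosome_lengths[i], cfg$n_loci[i]))
    data.frame(chrom = chroms[i], pos = pos, stringsAsFactors = FALSE)
  })
  nuc <- do.call(rbind, site_list)
  bases <- c("A", "C", "G", "T")
  nuc$ref <- sample(bases, nrow(nuc), replace = TRUE)
  alt_snp <- vapply(nuc$ref,
                    function(r) sample(setdiff(bases, r), 1L), "")
  ins <- runif(nrow(nuc)) < cfg$indel_rate
  nuc$alt <- ifelse(ins, paste0(nuc$ref, sample(bases, nrow(nuc), TRUE)),
                    alt_snp)
  cp <- data.frame(chrom = "chrCP",
                   pos = sort(sample.int(cfg$chloroplast_length,
                                         cfg$chloroplast_n_loci)),
                   stringsAsFactors = FALSE)
  cp$ref <- sample(bases, nrow(cp), replace = TRUE)
  cp$alt <- vapply(cp$ref, function(r) sample(setdiff(bases, r), 1L), "")
  sites <- rbind(nuc, cp)
  sites$ploidy <- rep(c(2L, 1L), c(nrow(nuc), nrow(cp)))
  sites$locus_id <- sprintf("%s_%d", sites$chrom, sites$pos)
  sites$mq <- round(pmin(60, pmax(20, rnorm(nrow(sites), 55, 4))), 2)
  sites <- sites[, c("locus_id", "chrom", "pos", "ref", "alt", "mq", "ploidy")]
  n_loci <- nrow(sites)

  ## ---- annotation track ---------------------------------------------
  genes <- do.call(rbind, lapply(seq_len(cfg$n_chromosomes), function(i) {
    len <- cfg$chromosome_lengths[i]
    n_genes <- max(1L, round(cfg$gene_density * len / 1e6))
    glen <- pmax(500L, round(rexp(n_genes, 1 / cfg$mean_gene_length)))
    start <- sort(sample.int(len, n_genes))
    end <- pmin(start + glen - 1L, len)
    data.frame(chrom = chroms[i], start = start, end = end,
               gene_id = sprintf("gene_%s_%03d", chroms[i], seq_len(n_genes)),
               stringsAsFactors = FALSE)
  }))

  genic <- loci_in_windows(
    sites$chrom, sites$pos,
    data.frame(chrom = genes$chrom,
               start = pmax(1L, genes$start - cfg$flank_bp),
               end = genes$end + cfg$flank_bp))
  genic[sites$chrom == "chrCP"] <- TRUE  # chloroplast scored as genic

  ## ---- allele frequencies and true genotypes -------------------------
  p0 <- runif(n_loci, 0.05, 0.95)
  pg <- sapply(1:3, function(g) balding_nichols(p0, cfg$divergence[g]))

  truth <- matrix(NA_integer_, n_loci, n_samp,
                  dimnames = list(sites$locus_id, samples$sample_id))
  for (j in seq_len(n_samp)) {
    if (samples$role[j] != "founder") next
    g <- as.integer(samples$group[j])
    truth[, j] <- rbinom(n_loci, sites$ploidy, pg[, g])
  }
  for (j in which(samples$role == "hybrid")) {
    g1 <- truth[, samples$parent1[j]]
    g2 <- truth[, samples$parent2[j]]
    dip <- sites$ploidy == 2L
    gt <- rbinom(n_loci, 1L, g1 / 2) + rbinom(n_loci, 1L, g2 / 2)
    gt[!dip] <- g1[!dip]  # chloroplast maternally inherited from parent1
    truth[, j] <- gt
  }
  for (j in which(samples$role == "clone")) {
    gt <- truth[, samples$clone_of[j]]
    mut <- runif(n_loci) < cfg$somatic_mutation_rate & sites$ploidy == 2L
    if (any(mut)) {
      # mutate to one of the two other dosage states, uniformly
      shift <- 1L + (runif(sum(mut)) > 0.5)
      gt[mut] <- (gt[mut] + shift) %% 3L
    }
    truth[, j] <- gt
  }

  ## ---- read-level evidence ------------------------------------------
  ncell <- n_loci * n_samp
  dp <- matrix(rpois(ncell, cfg$mean_depth), n_loci, n_samp,
               dimnames = dimnames(truth))
  mu_dip <- c(cfg$base_error, 0.5, 1 - cfg$base_error)
  mu <- matrix(mu_dip[truth + 1L], n_loci, n_samp)
  hap <- sites$ploidy == 1L
  mu[hap, ] <- c(cfg$base_error, 1 - cfg$base_error)[truth[hap, ] + 1L]
  ad_alt <- matrix(rbinom(ncell, as.vector(dp), as.vector(mu)),
                   n_loci, n_samp, dimnames = dimnames(truth))
  ad_ref <- dp - ad_alt
  gq <- matrix(pmin(99L, pmax(1L, round(3 * dp + rnorm(ncell, 0, 5)))),
               n_loci, n_samp, dimnames = dimnames(truth))
  bq <- matrix(round(pmin(45, pmax(20, rnorm(ncell, 36, 2))), 1),
               n_loci, n_samp, dimnames = dimnames(truth))
  gt <- truth
  gt[dp == 0 | matrix(runif(ncell) < cfg$missing_rate, n_loci, n_samp)] <-
    NA_integer_

  ## ---- convertibility scores ----------------------------------------
  pp <- cfg$pconvert_params
  draw_scores <- function() {
    s <- numeric(n_loci)
    s[genic] <- rbeta(sum(genic), pp$genic[1], pp$genic[2])
    s[!genic] <- rbeta(sum(!genic), pp$intergenic[1], pp$intergenic[2])
    round(s, 4)
  }
  fwd <- draw_scores()
  rev_ <- draw_scores()
  tie <- runif(n_loci) < pp$equal_prob
  rev_[tie] <- fwd[tie]
  buildable <- matrix(runif(2 * n_loci) >= pp$unbuildable_prob, n_loci, 2)
  scores <- data.frame(
    locus_id = rep(sites$locus_id, 2),
    strand = rep(c("fwd", "rev"), each = n_loci),
    pconvert = c(fwd, rev_),
    buildable = c(buildable[, 1], buildable[, 2]),
    stringsAsFactors = FALSE
  )
  scores$recommended <- scores$buildable & scores$pconvert > pp$recommend_min

  structure(
    list(samples = samples,
         variants = variant_set(sites, gt, dp, ad_ref, ad_alt, gq, bq),
         truth = truth, genes = genes, scores = scores, genic = genic,
         config = cfg),
    class = "sim_cohort"
  )
}

#' @exportS3Method base::print
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "sim_cohort: %d samples (%d founders, %d hybrids, %d clones); %d loci (%d chloroplast)\n",
    nrow(x$samples), sum(x$samples$role == "founder"),
    sum(x$samples$role == "hybrid"), sum(x$samples$role == "clone"),
    nrow(x$variants$sites), sum(x$variants$sites$ploidy == 1L)))
  invisible(x)
}

#' Simulate two array analysis runs from true genotypes
#'
#' Produces the "analysis 1" and "analysis 2" call sets used by the two-run
#' call-consistency filter. Calls equal the true genotype except for NoCalls
#' at `missing_rate` and miscalls at a per-locus rate that grows as probe
#' convertibility falls; analysis 2 additionally inflates the miscall rate
#' for divergent-group samples (groups 2 and 3), emulating an analysis at
#' lowered sample-QC thresholds that admits noisier samples.
#'
#' Per cell, the miscall probability is
#' `miscall_rate * (1 + conv_weight * (1 - pconvert))`, times
#' `divergent_multiplier` in run 2 for divergent-group samples. A miscalled
#' diploid dosage moves to one of the two other states with equal
#' probability; a haploid dosage flips.
#'
#' @param truth loci x samples dosage matrix (no missing values).
#' @param samples sample table with `sample_id` and `group` columns.
#' @param locus_scores data.frame with `locus_id` and `pconvert` (one row per
#'   locus; use the tiled probe's score). Must cover every truth locus.
#' @param ploidy integer vector of per-locus ploidy (1 or 2); default all 2.
#' @param run1,run2 lists with elements `miscall_rate` and `missing_rate`;
#'   `run2` may add `divergent_multiplier` (default 3).
#' @param conv_weight weight of the convertibility penalty on the miscall
#'   rate.
#' @param seed integer seed for the two runs.
#' @return list with matrices `analysis1` and `analysis2` (NA = NoCall).
#' @export
simulate_array_runs <- function(truth, samples, locus_scores,
                                ploidy = rep(2L, nrow(truth)),
                                run1 = list(miscall_rate = 0.005,
                                            missing_rate = 0.02),
                                run2 = list(miscall_rate = 0.005,
                                            missing_rate = 0.02,
                                            divergent_multiplier = 3),
                                conv_weight = 4,
                                seed = 1L) {
  idx <- match(rownames(truth), locus_scores$locus_id)
  if (anyNA(idx)) stop("locus_scores does not cover every locus in truth")
  pconv <- locus_scores$pconvert[idx]
  grp <- samples$group[match(colnames(truth), samples$sample_id)]
  if (anyNA(grp)) stop("samples table does not cover every truth column")
  divergent <- grp %in% c("2", "3")

  set.seed(seed)
  one_run <- function(miscall_rate, missing_rate, divergent_multiplier = 1) {
    p_loc <- pmin(1, miscall_rate * (1 + conv_weight * (1 - pconv)))
    p <- outer(p_loc, ifelse(divergent, divergent_multiplier, 1))
    p <- pmin(p, 1)
    n <- length(truth)
    mis <- matrix(runif(n) < p, nrow(truth))
    u <- matrix(runif(n), nrow(truth))      # direction of the miscall
    out <- truth
    dip <- ploidy == 2L
    shift <- 1L + (u > 0.5)
    out[mis & dip] <- (truth[mis & dip] + shift[mis & dip]) %% 3L
    out[mis & !dip] <- 1L - truth[mis & !dip]
    out[matrix(runif(n) < missing_rate, nrow(truth))] <- NA_integer_
    dimnames(out) <- dimnames(truth)
    out
  }
  a1 <- one_run(run1$miscall_rate, run1$missing_rate)
  dm <- if (is.null(run2$divergent_multiplier)) 3 else run2$divergent_multiplier
  a2 <- one_run(run2$miscall_rate, run2$missing_rate, dm)
  list(analysis1 = a1, analysis2 = a2)
}
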