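# shared simulated fixtures, built once per test run

# small mixed cohort: 3 chromosomes, hybrids, one clone pair, chloroplast
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(sim_config(
        seed = 11, n_chromosomes = 3L, chromosome_lengths = rep(2e6, 3),
        n_loci = rep(80L, 3), group_sizes = c(8L, 4L, 4L),
        n_hybrids = 2L, n_clone_pairs = 1L, chloroplast_n_loci = 20L))
    }
    cache
  }
})

# deep cohort for binomial clone-mismatch / clonal-identity checks:
# one 50,000-locus chromosome, minimal samples, elevated somatic rate
clone_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(sim_config(
        seed = 23, n_chromosomes = 1L, chromosome_lengths = 5e6,
        n_loci = 50000L, group_sizes = c(3L, 1L, 1L), n_hybrids = 0L,
        n_clone_pairs = 2L, somatic_mutation_rate = 1e-4,
        mean_depth = 20, chloroplast_n_loci = 5L))
    }
    cache
  }
})

# planted-structure cohort: 3 groups x 10 founders, 2,000 diploid loci at
# divergence 0.3, no hybrids/clones; returns the diploid truth matrix too
structured_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- simulate_cohort(sim_config(
        seed = 31, n_chromosomes = 4L, chromosome_lengths = rep(5e6, 4),
        n_loci = rep(500L, 4), group_sizes = c(10L, 10L, 10L),
        divergence = c(0.3, 0.3, 0.3), n_hybrids = 0L, n_clone_pairs = 0L,
        chloroplast_n_loci = 5L))
      dip <- co$variants$sites$ploidy == 2L
      cache <<- list(cohort = co, truth_dip = co$truth[dip, , drop = FALSE])
    }
    cache
  }
})

# hand-built variant_set with full control over evidence fields
make_variant_set <- function(gt, dp = NULL, ad_alt = NULL, gq = NULL,
                             bq = NULL, mq = NULL, ploidy = NULL,
                             ref = NULL, alt = NULL, chrom = NULL,
                             pos = NULL) {
  n <- nrow(gt)
  if (is.null(rownames(gt))) rownames(gt) <- sprintf("L%03d", seq_len(n))
  if (is.null(colnames(gt))) colnames(gt) <- sprintf("S%02d", seq_len(ncol(gt)))
  fill <- function(m, default) {
    if (is.null(m)) m <- default
    if (length(m) == 1L) m <- matrix(m, n, ncol(gt))
    dimnames(m) <- dimnames(gt)
    m
  }
  sites <- data.frame(
    locus_id = rownames(gt),
    chrom = if (is.null(chrom)) "chr1" else chrom,
    pos = if (is.null(pos)) seq_len(n) * 100L else pos,
    ref = if (is.null(ref)) "A" else ref,
    alt = if (is.null(alt)) "G" else alt,
    mq = if (is.null(mq)) 60 else mq,
    ploidy = if (is.null(ploidy)) 2L else ploidy,
    stringsAsFactors = FALSE)
  dp <- fill(dp, 30)
  ad_alt <- fill(ad_alt, 15)
  variant_set(sites, gt, dp, dp - ad_alt, ad_alt, fill(gq, 99), fill(bq, 40))
}
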