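test_that("the same seed reproduces the cohort and its files byte for byte", {
  cfg <- sim_config(seed = 7, n_chromosomes = 2L,
                    chromosome_lengths = rep(1e6, 2), n_loci = rep(50L, 2),
                    group_sizes = c(4L, 3L, 3L), n_hybrids = 1L,
                    n_clone_pairs = 1L, chloroplast_n_loci = 10L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$variants$gt, b$variants$gt)
  expect_identical(a$scores, b$scores)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_fixture_bundle(a, d1)
  p2 <- write_fixture_bundle(b, d2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("clone pairs are identical at zero somatic rate and Binomial(n, q) apart otherwise", {
  cfg0 <- sim_config(seed = 5, n_chromosomes = 1L, chromosome_lengths = 1e6,
                     n_loci = 500L, group_sizes = c(4L, 2L, 2L),
                     n_hybrids = 0L, n_clone_pairs = 2L,
                     somatic_mutation_rate = 0, chloroplast_n_loci = 10L)
  co0 <- simulate_cohort(cfg0)
  clones <- co0$samples[co0$samples$role == "clone", ]
  for (i in seq_len(nrow(clones))) {
    expect_identical(co0$truth[, clones$sample_id[i]],
                     co0$truth[, clones$clone_of[i]])
  }

  # mismatch count over n nuclear loci is Binomial(n, somatic rate)
  co <- clone_cohort()
  n <- sum(co$variants$sites$ploidy == 2L)
  q <- co$config$somatic_mutation_rate
  clones <- co$samples[co$samples$role == "clone", ]
  for (i in seq_len(nrow(clones))) {
    dip <- co$variants$sites$ploidy == 2L
    mism <- sum(co$truth[dip, clones$sample_id[i]] !=
                  co$truth[dip, clones$clone_of[i]])
    expect_lt(abs(mism - n * q), 4 * sqrt(n * q * (1 - q)))
  }
})

test_that("zero divergence collapses group frequencies to the ancestral value", {
  cfg <- sim_config(seed = 13, n_chromosomes = 2L,
                    chromosome_lengths = rep(2e6, 2), n_loci = rep(300L, 2),
                    group_sizes = c(10L, 10L, 10L), divergence = c(0, 0, 0),
                    n_hybrids = 0L, n_clone_pairs = 0L,
                    chloroplast_n_loci = 5L)
  co <- simulate_cohort(cfg)
  dip <- co$variants$sites$ploidy == 2L
  grp <- co$samples$group
  freq <- sapply(c("1", "2", "3"), function(g) {
    rowMeans(co$truth[dip, grp == g, drop = FALSE]) / 2
  })
  # Hudson-style FST numerator should vanish up to sampling error
  fst_num <- (freq[, 1] - freq[, 2])^2 -
    freq[, 1] * (1 - freq[, 1]) / (2 * 10 - 1) -
    freq[, 2] * (1 - freq[, 2]) / (2 * 10 - 1)
  expect_lt(abs(mean(fst_num)), 0.01)
})

test_that("hybrids are more heterozygous than their divergent-group parents", {
  co <- small_cohort()   # divergence 0.3, hybrid parents from groups 1 and 2
  dip <- co$variants$sites$ploidy == 2L
  hy <- co$samples[co$samples$role == "hybrid", ]
  het <- function(s) mean(co$truth[dip, s] == 1L)
  expect_gt(mean(vapply(hy$sample_id, het, numeric(1))),
            mean(vapply(c(hy$parent1, hy$parent2), het, numeric(1))))
})

test_that("array runs equal truth when miscall and missing rates are zero", {
  co <- small_cohort()
  scores <- data.frame(locus_id = rownames(co$truth),
                       pconvert = 0.5, stringsAsFactors = FALSE)
  runs <- simulate_array_runs(
    co$truth, co$samples, scores, ploidy = co$variants$sites$ploidy,
    run1 = list(miscall_rate = 0, missing_rate = 0),
    run2 = list(miscall_rate = 0, missing_rate = 0), seed = 3)
  expect_identical(runs$analysis1, co$truth)
  expect_identical(runs$analysis2, co$truth)
})

test_that("miscall counts follow the per-cell binomial rate", {
  co <- structured_cohort()$cohort
  truth <- co$truth[co$variants$sites$ploidy == 2L, ][1:500, 1:20]
  scores <- data.frame(locus_id = rownames(truth), pconvert = 1.0,
                       stringsAsFactors = FALSE)  # no convertibility penalty
  runs <- simulate_array_runs(
    truth, co$samples, scores,
    run1 = list(miscall_rate = 0.01, missing_rate = 0),
    run2 = list(miscall_rate = 0, missing_rate = 0, divergent_multiplier = 1),
    seed = 9)
  n_cells <- length(truth)
  expect_identical(n_cells, 10000L)
  miscalls <- sum(runs$analysis1 != truth)
  expect_lt(abs(miscalls - n_cells * 0.01),
            3 * sqrt(n_cells * 0.01 * 0.99))
  expect_identical(runs$analysis2, truth)
})

test_that("the fixture bundle round-trips and degenerate configs error", {
  co <- small_cohort()
  d <- withr::local_tempdir()
  runs <- simulate_array_runs(
    co$truth, co$samples,
    data.frame(locus_id = rownames(co$truth), pconvert = 0.9),
    ploidy = co$variants$sites$ploidy, seed = 2)
  paths <- write_fixture_bundle(co, d, runs)
  vs <- read_vcf(paths[["vcf"]])
  expect_identical(vs$gt[, ], co$variants$gt[, ])
  expect_equal(vs$sites$pos, co$variants$sites$pos)
  expect_equal(vs$sites$mq, co$variants$sites$mq)
  expect_identical(vs$sites$ploidy, co$variants$sites$ploidy)
  expect_false(is.null(vs$dp))   # GT:AD:DP:GQ declared and parsed
  expect_identical(vs$dp[, ], co$variants$dp[, ] + 0)
  expect_identical(read_call_matrix(paths[["truth"]]), co$truth)
  expect_identical(read_call_matrix(paths[["analysis2"]]), runs$analysis2)

  expect_error(write_fixture_bundle(list(samples = data.frame()), d),
               "empty cohort")
  expect_error(sim_config(group_sizes = c(2L, 2L, 2L), n_clone_pairs = 5L),
               "clone")
  expect_error(sim_config(missing_rate = 1.5), "probabilities")
})
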