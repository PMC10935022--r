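#' Quality-control thresholds for post-calling variant filtering
#'
#' Defaults are the filter set applied to the resequencing-derived discovery
#' panel: site map quality >= 25, per-call mean base quality >= 30, genotype
#' quality >= 20, per-call depth in `[min_dp, dp_upper_multiplier x
#' per-sample median)`, an exact equal-tailed Binomial(depth, 0.5)
#' allele-balance test on heterozygous calls at 5% total tail area, at most
#' 2 alleles per site, and fewer than half of samples missing.
#'
#' @param min_mq minimum site map quality.
#' @param min_bq minimum per-call mean base quality.
#' @param min_gq minimum genotype quality.
#' @param min_dp minimum per-call read depth (inclusive).
#' @param dp_upper_multiplier upper depth bound as a multiple of the
#'   per-sample median depth (exclusive).
#' @param allele_balance_alpha total tail area of the binomial
#'   allele-balance test (split equally between the two tails).
#' @param max_alleles maximum number of alleles at a retained site.
#' @param max_missing_fraction sites with at least this fraction of samples
#'   missing are dropped.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_mq = 25, min_bq = 30, min_gq = 20, min_dp = 10,
                          dp_upper_multiplier = 2,
                          allele_balance_alpha = 0.05,
                          max_alleles = 2, max_missing_fraction = 0.5) {
  th <- list(min_mq = min_mq, min_bq = min_bq, min_gq = min_gq,
             min_dp = min_dp, dp_upper_multiplier = dp_upper_multiplier,
             allele_balance_alpha = allele_balance_alpha,
             max_alleles = max_alleles,
             max_missing_fraction = max_missing_fraction)
  if (any(unlist(th) <= 0)) stop("all thresholds must be positive")
  if (allele_balance_alpha >= 1) {
    stop("allele_balance_alpha must lie in (0, 1)")
  }
  class(th) <- "qc_thresholds"
  th
}

#' Median read depth of one sample over its called sites
#'
#' The median is taken over all sites where the sample has a genotype call;
#' for an even count the mean of the two middle values is used.
#'
#' @param vs a [variant_set()] carrying a `dp` matrix.
#' @param sample_id sample to summarise.
#' @return The median depth (numeric scalar).
#' @export
sample_median_depth <- function(vs, sample_id) {
  if (!sample_id %in% colnames(vs$gt)) {
    stop("sample not present: ", sample_id)
  }
  if (is.null(vs$dp)) stop("variant set carries no depth (DP) field")
  called <- !is.na(vs$gt[, sample_id])
  if (!any(called)) stop("all calls missing for sample ", sample_id)
  median(vs$dp[called, sample_id], na.rm = TRUE)
}

#' Exact binomial allele-balance test for heterozygous calls
#'
#' A heterozygous call passes when its alternate-read count lies outside
#' both tails of the exact Binomial(`dp`, 0.5) distribution, each tail
#' holding `alpha/2` of total probability mass: the call passes iff
#' `P(X <= k) > alpha/2` and `P(X >= k) > alpha/2`.
#'
#' @param dp read depth (vectorised).
#' @param alt_reads alternate-allele read count (vectorised).
#' @param alpha total tail area (default 0.05).
#' @return Logical vector: `TRUE` where the call passes.
#' @export
allele_balance_pass <- function(dp, alt_reads, alpha = 0.05) {
  if (any(dp < 1, na.rm = TRUE)) stop("dp must be >= 1")
  if (any(alt_reads > dp | alt_reads < 0, na.rm = TRUE)) {
    stop("alt_reads must lie in [0, dp]")
  }
  lower <- pbinom(alt_reads, dp, 0.5)                  # P(X <= k)
  upper <- pbinom(alt_reads - 1, dp, 0.5, lower.tail = FALSE)  # P(X >= k)
  lower > alpha / 2 & upper > alpha / 2
}

#' Apply the post-calling quality-control filter set
#'
#' Call-level filters (site map quality, base quality, genotype quality,
#' depth-versus-median, allele balance on heterozygotes) mask failing calls
#' to missing; site-level filters then drop sites with more than
#' `max_alleles` alleles or with at least `max_missing_fraction` of samples
#' missing. Per-sample median depths are computed on the input set before
#' any masking. Filters whose evidence field is absent from the variant set
#' are skipped with a warning.
#'
#' @param vs a [variant_set()].
#' @param thresholds a [qc_thresholds()].
#' @return A list with `variants` (the retained, masked [variant_set()]) and
#'   `report`, a list holding per-stage masked-call and dropped-site tallies
#'   (`stages` data.frame with columns `stage`, `masked_calls`,
#'   `removed_sites`, `retained_sites`), `median_depth` per sample, and
#'   `retained` locus ids.
#' @export
apply_qc <- function(vs, thresholds = qc_thresholds()) {
  th <- thresholds
  gt <- vs$gt
  n_sites_in <- nrow(gt)
  stages <- list()
  note <- function(stage, masked, removed, retained) {
    stages[[length(stages) + 1L]] <<- data.frame(
      stage = stage, masked_calls = masked, removed_sites = removed,
      retained_sites = retained, stringsAsFactors = FALSE)
  }
  mask_count <- function(bad) sum(bad & !is.na(gt))

  ## site map quality: all calls at a failing site are masked
  fail_mq <- !is.na(vs$sites$mq) & vs$sites$mq < th$min_mq
  bad <- matrix(fail_mq, nrow(gt), ncol(gt))
  note("map_quality", mask_count(bad), 0L, n_sites_in)
  gt[bad] <- NA_integer_

  ## per-call mean base quality
  if (is.null(vs$bq)) {
    warning("BQ absent; base-quality filter skipped")
    note("base_quality", 0L, 0L, n_sites_in)
  } else {
    bad <- !is.na(vs$bq) & vs$bq < th$min_bq
    note("base_quality", mask_count(bad), 0L, n_sites_in)
    gt[bad] <- NA_integer_
  }

  ## genotype quality
  if (is.null(vs$gq)) {
    warning("GQ absent; genotype-quality filter skipped")
    note("genotype_quality", 0L, 0L, n_sites_in)
  } else {
    bad <- !is.na(vs$gq) & vs$gq < th$min_gq
    note("genotype_quality", mask_count(bad), 0L, n_sites_in)
    gt[bad] <- NA_integer_
  }

  ## depth window: min_dp <= DP < multiplier x per-sample median (input set)
  med <- NULL
  if (is.null(vs$dp)) {
    warning("DP absent; depth filter skipped")
    note("depth", 0L, 0L, n_sites_in)
  } else {
    med <- vapply(colnames(vs$gt),
                  function(s) sample_median_depth(vs, s), numeric(1))
    upper <- matrix(th$dp_upper_multiplier * med, nrow(gt), ncol(gt),
                    byrow = TRUE)
    bad <- !is.na(vs$dp) & (vs$dp < th$min_dp | vs$dp >= upper)
    note("depth", mask_count(bad), 0L, n_sites_in)
    gt[bad] <- NA_integer_
  }

  ## allele balance on heterozygous calls
  if (is.null(vs$dp) || is.null(vs$ad_alt)) {
    warning("DP or AD absent; allele-balance filter skipped")
    note("allele_balance", 0L, 0L, n_sites_in)
  } else {
    het <- !is.na(gt) & gt == 1L &
      matrix(vs$sites$ploidy == 2L, nrow(gt), ncol(gt))
    idx <- which(het & !is.na(vs$dp) & !is.na(vs$ad_alt) & vs$dp >= 1)
    bad <- matrix(FALSE, nrow(gt), ncol(gt))
    if (length(idx)) {
      bad[idx] <- !allele_balance_pass(vs$dp[idx], vs$ad_alt[idx],
                                       th$allele_balance_alpha)
    }
    note("allele_balance", mask_count(bad), 0L, n_sites_in)
    gt[bad] <- NA_integer_
  }

  ## site-level: allele count
  n_alleles <- 1L + lengths(strsplit(vs$sites$alt, ",", fixed = TRUE))
  drop_al <- n_alleles > th$max_alleles
  note("max_alleles", 0L, sum(drop_al), n_sites_in - sum(drop_al))

  ## site-level: missingness among remaining sites
  miss_frac <- rowMeans(is.na(gt))
  drop_miss <- !drop_al & miss_frac >= th$max_missing_fraction
  keep <- !drop_al & !drop_miss
  note("missingness", 0L, sum(drop_miss), sum(keep))

  out <- vs
  out$gt <- gt
  out <- subset_loci(out, which(keep))
  report <- list(
    stages = do.call(rbind, stages),
    median_depth = med,
    n_input_sites = n_sites_in,
    retained = out$sites$locus_id
  )
  list(variants = out, report = report)
}
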