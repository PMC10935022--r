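#' Classify probe performance from a call set
#'
#' A surrogate for the proprietary cluster-geometry classifier: a locus
#' whose call rate falls below `call_rate_threshold` is
#' `CallRateBelowThreshold`; otherwise a locus with both alleles observed
#' and minor-allele count of at least `min_minor_count` is
#' `PolyHighResolution` (PHR); a monomorphic locus is `MonoHighResolution`;
#' anything else (a single minor-allele observation) is `Other`.
#'
#' @param calls loci x samples dosage matrix (NA = NoCall).
#' @param call_rate_threshold minimum fraction of samples called.
#' @param min_minor_count minimum minor-allele count for PHR.
#' @param ploidy per-locus ploidy (default all diploid).
#' @return data.frame with `locus_id`, `category`, `cluster_call_rate`,
#'   `minor_count`.
#' @export
classify_probes <- function(calls, call_rate_threshold = 0.97,
                            min_minor_count = 2,
                            ploidy = rep(2L, nrow(calls))) {
  if (ncol(calls) == 0L) stop("empty sample set")
  called <- !is.na(calls)
  call_rate <- rowMeans(called)
  alt <- rowSums(calls, na.rm = TRUE)
  tot <- as.numeric(ploidy) * rowSums(called)
  minor <- pmin(alt, tot - alt)
  category <- ifelse(call_rate < call_rate_threshold, "CallRateBelowThreshold",
              ifelse(minor >= min_minor_count, "PolyHighResolution",
              ifelse(minor == 0, "MonoHighResolution", "Other")))
  category[tot == 0 & call_rate >= call_rate_threshold] <- "Other"
  data.frame(locus_id = rownames(calls), category = category,
             cluster_call_rate = call_rate, minor_count = minor,
             stringsAsFactors = FALSE)
}

#' Two-run call-consistency test
#'
#' Compares the calls of two array analyses sample-by-sample at each locus
#' and retains loci whose calls do not differ between runs. By default a
#' sample is discordant only when both runs made a call and the calls
#' differ (NoCall-versus-call pairs are ignored, matching the concordance
#' convention); set `nocall_discordant = TRUE` to count those pairs as
#' discordant instead.
#'
#' @param callset_1,callset_2 loci x samples dosage matrices sharing
#'   dimnames.
#' @param loci optional locus ids to restrict to (e.g. the PHR loci of the
#'   first analysis).
#' @param nocall_discordant treat call-vs-NoCall pairs as discordant.
#' @return data.frame with `locus_id`, `n_discordant`, `consistent`.
#' @export
call_consistency <- function(callset_1, callset_2, loci = NULL,
                             nocall_discordant = FALSE) {
  if (!identical(dimnames(callset_1), dimnames(callset_2))) {
    stop("call sets must share locus and sample indices")
  }
  if (!is.null(loci)) {
    missing_loci <- setdiff(loci, rownames(callset_1))
    if (length(missing_loci)) stop("loci absent from call sets")
    callset_1 <- callset_1[loci, , drop = FALSE]
    callset_2 <- callset_2[loci, , drop = FALSE]
  }
  both <- !is.na(callset_1) & !is.na(callset_2)
  disc <- both & callset_1 != callset_2
  if (nocall_discordant) {
    disc <- disc | xor(is.na(callset_1), is.na(callset_2))
  }
  n_disc <- rowSums(disc)
  data.frame(locus_id = rownames(callset_1), n_discordant = n_disc,
             consistent = n_disc == 0L, stringsAsFactors = FALSE)
}

#' Select the best probe per locus by sequence concordance
#'
#' For loci tiled with probes on both strands, keeps the probe whose calls
#' agree best with the sequence-derived genotypes; ties are broken in
#' favour of the forward strand, then by lexicographic probe id, so the
#' selection is deterministic.
#'
#' @param probes data.frame with `locus_id`, `probe_id`, `strand`
#'   (`"fwd"`/`"rev"`), `concordance` (percent or fraction, any consistent
#'   scale).
#' @return One row per locus (input locus order).
#' @export
select_best_probes <- function(probes) {
  if (nrow(probes) == 0L) stop("no probes supplied")
  if (any(!probes$strand %in% c("fwd", "rev"))) stop("strand must be fwd/rev")
  split_idx <- split(seq_len(nrow(probes)), probes$locus_id)
  if (any(lengths(split_idx) == 0L)) stop("locus with zero probes")
  best <- vapply(split_idx, function(ix) {
    p <- probes[ix, ]
    ord <- order(-p$concordance, p$strand != "fwd", p$probe_id)
    ix[ord[1L]]
  }, integer(1))
  out <- probes[best[match(unique(probes$locus_id), names(best))], ]
  rownames(out) <- NULL
  out
}

# largest-remainder apportionment of `total` over strata with weights `counts`
largest_remainder <- function(counts, total) {
  if (total > sum(counts)) stop("target exceeds available candidates")
  exact <- total * counts / sum(counts)
  quota <- floor(exact)
  short <- total - sum(quota)
  if (short > 0) {
    ord <- order(exact - quota, decreasing = TRUE)
    quota[ord[seq_len(short)]] <- quota[ord[seq_len(short)]] + 1L
  }
  # never allocate beyond a stratum's candidate count
  over <- quota > counts
  while (any(over)) {
    excess <- sum(quota[over] - counts[over])
    quota[over] <- counts[over]
    room <- which(quota < counts)
    ord <- room[order(exact[room] - quota[room], decreasing = TRUE)]
    for (i in ord) {
      if (excess == 0) break
      add <- min(excess, counts[i] - quota[i])
      quota[i] <- quota[i] + add
      excess <- excess - add
    }
    over <- quota > counts
  }
  as.integer(quota)
}

#' Seeded random downselection to a target array size
#'
#' Allocates the autosomal quota per chromosome proportionally to candidate
#' counts (largest-remainder rounding, so quotas sum exactly to the
#' target), then samples without replacement with the given seed; the
#' chloroplast quota is sampled separately. The report includes
#' per-chromosome counts and the maximum inter-SNP gap per chromosome.
#'
#' @param candidates site table of candidate loci (`locus_id`, `chrom`,
#'   `pos`, `ploidy`; chloroplast = `ploidy == 1`).
#' @param target_total total SNPs on the array (autosomal + chloroplast).
#' @param chloroplast_target chloroplast SNP count within `target_total`.
#' @param seed integer seed.
#' @return list with `selected` (locus ids), `report` (data.frame of
#'   per-chromosome candidates, quota, selected count, max gap in bp).
#' @export
downselect <- function(candidates, target_total, chloroplast_target, seed) {
  if (chloroplast_target > target_total) {
    stop("chloroplast_target exceeds target_total")
  }
  cp <- candidates$ploidy == 1L
  auto <- candidates[!cp, ]
  chlo <- candidates[cp, ]
  auto_target <- target_total - chloroplast_target
  if (auto_target > nrow(auto)) stop("autosomal target exceeds candidates")
  if (chloroplast_target > nrow(chlo)) {
    stop("chloroplast target exceeds candidates")
  }
  chroms <- sort(unique(auto$chrom))
  counts <- vapply(chroms, function(ch) sum(auto$chrom == ch), integer(1))
  quota <- largest_remainder(counts, auto_target)
  set.seed(seed)
  picked <- character(0)
  for (k in seq_along(chroms)) {
    ids <- auto$locus_id[auto$chrom == chroms[k]]
    picked <- c(picked, sort(sample(ids, quota[k])))
  }
  if (chloroplast_target > 0) {
    picked <- c(picked, sort(sample(chlo$locus_id, chloroplast_target)))
  }
  sel <- candidates[candidates$locus_id %in% picked, ]
  report <- do.call(rbind, lapply(
    c(chroms, if (chloroplast_target > 0) unique(chlo$chrom)),
    function(ch) {
      pos <- sort(sel$pos[sel$chrom == ch])
      data.frame(chrom = ch,
                 candidates = sum(candidates$chrom == ch),
                 selected = length(pos),
                 max_gap_bp = if (length(pos) > 1) max(diff(pos)) else NA_integer_,
                 stringsAsFactors = FALSE)
    }))
  list(selected = sel$locus_id, report = report)
}
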