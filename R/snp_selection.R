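# TRUE for each locus lying inside any window on its chromosome
loci_in_windows <- function(chrom, pos, windows) {
  if (nrow(windows) == 0L) return(rep(FALSE, length(pos)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  s <- GenomicRanges::GRanges(windows$chrom,
                              IRanges::IRanges(windows$start, windows$end))
  IRanges::overlapsAny(q, s)
}

#' Assign loci to the divergence groups in which they are polymorphic
#'
#' Per group, the alternate-allele frequency is the summed alternate allele
#' count divided by the total called allele count (ploidy x non-missing
#' calls); a locus is polymorphic in a group when that frequency strictly
#' exceeds `threshold`. Samples whose `group` label is not one of
#' `groups` (hybrids, clones labelled by group are included via their
#' label) contribute only through their own group column. A group with zero
#' non-missing calls at a locus yields `NA` frequency and is excluded for
#' that locus.
#'
#' @param gt loci x samples dosage matrix.
#' @param samples sample table with `sample_id` and `group` columns.
#' @param threshold strict lower bound on the alternate-allele frequency.
#' @param ploidy per-locus ploidy vector (default all diploid).
#' @param groups group labels to assess (default `c("1","2","3")`).
#' @return data.frame with `locus_id`, one frequency column `freq_<g>` and
#'   one logical column `poly_<g>` per group, and `n_groups`, the number of
#'   groups in which the locus is polymorphic.
#' @export
assign_groups <- function(gt, samples, threshold = 0.1,
                          ploidy = rep(2L, nrow(gt)),
                          groups = c("1", "2", "3")) {
  grp <- samples$group[match(colnames(gt), samples$sample_id)]
  out <- data.frame(locus_id = rownames(gt), stringsAsFactors = FALSE)
  poly <- matrix(FALSE, nrow(gt), length(groups))
  for (k in seq_along(groups)) {
    cols <- which(!is.na(grp) & grp == groups[k])
    if (!length(cols)) {
      out[[paste0("freq_", groups[k])]] <- NA_real_
      next
    }
    sub <- gt[, cols, drop = FALSE]
    called <- !is.na(sub)
    alt <- rowSums(sub, na.rm = TRUE)
    tot <- as.numeric(ploidy) * rowSums(called)
    freq <- ifelse(tot > 0, alt / tot, NA_real_)
    out[[paste0("freq_", groups[k])]] <- freq
    poly[, k] <- !is.na(freq) & freq > threshold
  }
  for (k in seq_along(groups)) out[[paste0("poly_", groups[k])]] <- poly[, k]
  out$n_groups <- rowSums(poly)
  out
}

#' Build merged genic windows from a GFF3 annotation
#'
#' One window per gene, `[start - flank_bp, end + flank_bp]`, clipped to
#' `[1, chromosome length]`; overlapping windows are merged. The window
#' covers the whole gene body (exons, introns, UTRs) plus flanks, applied
#' strand-agnostically.
#'
#' @param gff3 path to a GFF3 file, or a data.frame with `chrom`, `start`,
#'   `end` (gene features).
#' @param flank_bp flank size in bp on each side (default 5000).
#' @param chrom_lengths optional named vector used to clip window ends;
#'   when reading a GFF3 file, `##sequence-region` pragmas supply lengths
#'   automatically.
#' @return data.frame with `chrom`, `start`, `end` of merged windows.
#' @export
build_genic_windows <- function(gff3, flank_bp = 5000, chrom_lengths = NULL) {
  if (is.character(gff3)) {
    gr <- tryCatch(rtracklayer::import(gff3, format = "gff3"),
                   error = function(e) stop("failed to parse GFF3 '", gff3,
                                            "': ", conditionMessage(e)))
    gr <- gr[gr$type == "gene"]
    if (is.null(chrom_lengths)) {
      sl <- GenomeInfoDb::seqlengths(gr)
      if (length(sl) && !all(is.na(sl))) {
        chrom_lengths <- sl
      } else {
        # fall back to the ##sequence-region pragmas
        hdr <- grep("^##sequence-region", readLines(gff3, n = 1000L),
                    value = TRUE)
        if (length(hdr)) {
          parts <- strsplit(trimws(hdr), "\\s+")
          chrom_lengths <- setNames(
            vapply(parts, function(p) as.integer(p[4]), integer(1)),
            vapply(parts, function(p) p[2], ""))
        }
      }
    }
    genes <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                        start = GenomicRanges::start(gr),
                        end = GenomicRanges::end(gr),
                        stringsAsFactors = FALSE)
  } else {
    genes <- gff3[, c("chrom", "start", "end")]
  }
  if (nrow(genes) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  if (any(genes$start > genes$end)) stop("gene with start > end")
  start <- pmax(1L, genes$start - flank_bp)
  end <- genes$end + flank_bp
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[genes$chrom]
    end <- ifelse(!is.na(lim), pmin(end, lim), end)
  }
  gr <- GenomicRanges::reduce(
    GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(start, end)))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Variant filtering part 1: group polymorphism, genic windows,
#' transversions, indels
#'
#' Sequentially removes autosomal loci that are (1) polymorphic in no
#' group, (2) outside every genic window, (3) A/T or G/C transversion SNPs
#' (both alleles would need the same probe colour channel), and (4) indels.
#' Chloroplast loci pass through all four stages unfiltered and are carried
#' into the retained set.
#'
#' @param sites site table (`locus_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `ploidy`); chloroplast loci are those with `ploidy == 1`.
#' @param assignments output of [assign_groups()] covering the same loci.
#' @param windows merged genic windows from [build_genic_windows()].
#' @return list with `retained` (locus ids, input order) and `stages`
#'   (data.frame of per-stage removed/retained counts; stage counts
#'   telescope: input = retained + sum of removals).
#' @export
filter_part1 <- function(sites, assignments, windows) {
  idx <- match(sites$locus_id, assignments$locus_id)
  if (anyNA(idx)) stop("assignments do not cover all loci")
  n_groups <- assignments$n_groups[idx]
  exempt <- sites$ploidy == 1L   # chloroplast track passes through
  keep <- rep(TRUE, nrow(sites))
  stages <- data.frame(stage = character(), removed = integer(),
                       retained = integer(), stringsAsFactors = FALSE)
  log_stage <- function(stage, drop) {
    keep <<- keep & !drop
    stages <<- rbind(stages, data.frame(
      stage = stage, removed = sum(drop), retained = sum(keep),
      stringsAsFactors = FALSE))
  }

  log_stage("group_polymorphism", keep & !exempt & n_groups == 0)
  genic <- loci_in_windows(sites$chrom, sites$pos, windows)
  log_stage("genic_window", keep & !exempt & !genic)
  is_snp <- nchar(sites$ref) == 1 & nchar(sites$alt) == 1 &
    !grepl(",", sites$alt, fixed = TRUE)
  pair <- paste0(pmin(sites$ref, sites$alt), pmax(sites$ref, sites$alt))
  transversion <- is_snp & pair %in% c("AT", "CG")
  log_stage("at_gc_transversion", keep & !exempt & transversion)
  indel <- is_indel_allele(sites$ref, sites$alt)
  log_stage("indel", keep & !exempt & indel)

  list(retained = sites$locus_id[keep], stages = stages,
       n_input = nrow(sites))
}

#' Strand-tiling decision for one locus
#'
#' Applies the convertibility-score decision rules: if both strand probes
#' are buildable and their scores are equal, the variant is tiled on both
#' strands; otherwise the buildable strand with the higher score is chosen
#' if that score exceeds `hi` (0.818); failing that, it is chosen if the
#' score exceeds `lo` (0.69); otherwise the locus is rejected. Chloroplast
#' loci bypass the score rules: they are accepted (on the better buildable
#' strand) whenever at least one strand is recommended.
#'
#' @param fwd,rev lists (or one-row data.frames) with elements `locus_id`,
#'   `pconvert`, `buildable`, and optionally `recommended`.
#' @param hi higher-strand acceptance threshold (strict).
#' @param lo fallback acceptance threshold (strict).
#' @param chloroplast logical: apply the chloroplast passthrough rule.
#' @return One of `"both_strands"`, `"fwd_only"`, `"rev_only"`, `"reject"`.
#' @export
tile_decision <- function(fwd, rev, hi = 0.818, lo = 0.69,
                          chloroplast = FALSE) {
  if (!identical(fwd$locus_id, rev$locus_id)) {
    stop("fwd and rev candidates refer to different loci")
  }
  fb <- isTRUE(fwd$buildable)
  rb <- isTRUE(rev$buildable)
  if (chloroplast) {
    rec <- isTRUE(fwd$recommended) || isTRUE(rev$recommended)
    if (!rec) return("reject")
    if (fb && (!rb || fwd$pconvert >= rev$pconvert)) return("fwd_only")
    if (rb) return("rev_only")
    return("reject")
  }
  if (!fb && !rb) return("reject")
  if (fb && rb && fwd$pconvert == rev$pconvert) return("both_strands")
  scores <- c(if (fb) fwd$pconvert else -Inf, if (rb) rev$pconvert else -Inf)
  best <- which.max(scores)           # ties cannot occur across strands here
  top <- scores[best]
  if (top > hi || top > lo) {
    return(if (best == 1L) "fwd_only" else "rev_only")
  }
  "reject"
}

#' Vectorised strand-tiling decisions over a score table
#'
#' @param scores per locus-strand table with `locus_id`, `strand`
#'   (`"fwd"`/`"rev"`), `pconvert`, `buildable`, `recommended`.
#' @param sites site table used to flag chloroplast loci (`ploidy == 1`);
#'   may be `NULL` for all-autosomal input.
#' @param hi,lo thresholds as in [tile_decision()].
#' @param recommended_only restrict tiling to loci recommended on at least
#'   one strand (default `TRUE`, mirroring the focus on recommended
#'   variants).
#' @return data.frame with `locus_id` and `decision`.
#' @export
tile_decisions <- function(scores, sites = NULL, hi = 0.818, lo = 0.69,
                           recommended_only = TRUE) {
  fwd <- scores[scores$strand == "fwd", ]
  rev_ <- scores[scores$strand == "rev", ]
  fwd <- fwd[match(unique(scores$locus_id), fwd$locus_id), ]
  rev_ <- rev_[match(unique(scores$locus_id), rev_$locus_id), ]
  cp <- rep(FALSE, nrow(fwd))
  if (!is.null(sites)) {
    cp <- sites$ploidy[match(fwd$locus_id, sites$locus_id)] == 1L
    cp[is.na(cp)] <- FALSE
  }
  dec <- vapply(seq_len(nrow(fwd)), function(i) {
    if (recommended_only &&
        !(isTRUE(fwd$recommended[i]) || isTRUE(rev_$recommended[i]))) {
      return("reject")
    }
    tile_decision(as.list(fwd[i, ]), as.list(rev_[i, ]), hi, lo,
                  chloroplast = cp[i])
  }, "")
  data.frame(locus_id = fwd$locus_id, decision = dec,
             stringsAsFactors = FALSE)
}
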