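#' Construct a variant set
#'
#' A `variant_set` bundles the per-site fields of a multi-sample call set:
#' a site table and aligned loci x samples matrices of genotype calls and the
#' per-call evidence the quality-control filters consume.
#'
#' @param sites data.frame with columns `locus_id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt` (comma-separated when multi-allelic), `mq` (site map
#'   quality), `ploidy` (1 or 2).
#' @param gt integer matrix of allele dosages (`NA` = missing call).
#' @param dp,ad_ref,ad_alt,gq,bq numeric matrices of per-call read depth,
#'   reference / alternate allele read counts, genotype quality, and mean
#'   base quality; same dimensions and dimnames as `gt`. Any may be `NULL`
#'   when the source file lacks the field (dependent filters are then
#'   skipped with a warning).
#'
#' @return An object of class `variant_set`.
#' @export
variant_set <- function(sites, gt, dp = NULL, ad_ref = NULL, ad_alt = NULL,
                        gq = NULL, bq = NULL) {
  stopifnot(is.data.frame(sites), is.matrix(gt))
  required <- c("locus_id", "chrom", "pos", "ref", "alt", "mq", "ploidy")
  missing_cols <- setdiff(required, names(sites))
  if (length(missing_cols)) {
    stop("sites is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(sites$locus_id)) stop("duplicated locus ids")
  if (nrow(sites) != nrow(gt)) stop("sites and gt row counts differ")
  rownames(gt) <- sites$locus_id
  for (nm in c("dp", "ad_ref", "ad_alt", "gq", "bq")) {
    m <- get(nm)
    if (!is.null(m) && !identical(dim(m), dim(gt))) {
      stop("dimension mismatch between gt and ", nm)
    }
  }
  hap <- sites$ploidy == 1L
  if (any(gt[hap, , drop = FALSE] > 1, na.rm = TRUE)) {
    stop("haploid loci must not carry genotype 2")
  }
  if (any(gt < 0, na.rm = TRUE)) stop("negative genotype codes")
  structure(
    list(sites = sites, gt = gt, dp = dp, ad_ref = ad_ref, ad_alt = ad_alt,
         gq = gq, bq = bq),
    class = "variant_set"
  )
}

#' @exportS3Method base::print
print.variant_set <- function(x, ...) {
  cat(sprintf(
    "variant_set: %d loci (%d haploid) x %d samples; evidence fields: %s\n",
    nrow(x$sites), sum(x$sites$ploidy == 1L), ncol(x$gt),
    paste(Filter(function(f) !is.null(x[[f]]),
                 c("dp", "ad_ref", "ad_alt", "gq", "bq")),
          collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.variant_set <- function(x) dim(x$gt)

# subset a variant_set by locus index or locus_id, keeping matrices aligned
subset_loci <- function(vs, keep) {
  if (is.character(keep)) keep <- match(keep, vs$sites$locus_id)
  if (anyNA(keep)) stop("unknown locus id in subset")
  pick <- function(m) if (is.null(m)) NULL else m[keep, , drop = FALSE]
  variant_set(vs$sites[keep, , drop = FALSE], pick(vs$gt), pick(vs$dp),
              pick(vs$ad_ref), pick(vs$ad_alt), pick(vs$gq), pick(vs$bq))
}

is_indel_allele <- function(ref, alt) {
  # multi-allelic alts are comma separated; an indel iff any allele length
  # differs from the reference length
  alt_lens <- lapply(strsplit(alt, ",", fixed = TRUE), nchar)
  mapply(function(r, a) any(a != r), nchar(ref), alt_lens)
}
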