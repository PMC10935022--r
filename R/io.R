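dosage_to_gt_string <- function(gt, ploidy) {
  if (ploidy == 1L) {
    out <- as.character(gt)
    out[is.na(gt)] <- "."
  } else {
    out <- c("0/0", "0/1", "1/1")[gt + 1L]
    out[is.na(gt)] <- "./."
  }
  out
}

#' Write a variant set to a VCF v4.2 file
#'
#' Emits a plain-text multi-sample VCF with `GT:AD:DP:GQ:BQ` FORMAT fields
#' and the site map quality as `MQ` in INFO. Haploid loci are written with
#' single-allele genotypes.
#'
#' @param vs a [variant_set()].
#' @param path output file path (`.gz` suffix writes gzip-compressed text).
#' @param contig_lengths optional named vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vs, path, contig_lengths = NULL) {
  sites <- vs$sites
  n <- nrow(sites)
  hdr <- c("##fileformat=VCFv4.2", "##source=snpforge")
  if (!is.null(contig_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths),
                          as.integer(contig_lengths)))
  }
  hdr <- c(
    hdr,
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Site mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele read depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=BQ,Number=1,Type=Float,Description=\"Mean base quality of supporting reads\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(vs$gt)), collapse = "\t")
  )
  fmt_num <- function(m, i) {
    if (is.null(m)) rep(".", ncol(vs$gt)) else {
      v <- m[i, ]
      out <- as.character(v)
      out[is.na(v)] <- "."
      out
    }
  }
  body <- vapply(seq_len(n), function(i) {
    gt_str <- dosage_to_gt_string(vs$gt[i, ], sites$ploidy[i])
    ad <- paste(fmt_num(vs$ad_ref, i), fmt_num(vs$ad_alt, i), sep = ",")
    cells <- paste(gt_str, ad, fmt_num(vs$dp, i), fmt_num(vs$gq, i),
                   fmt_num(vs$bq, i), sep = ":")
    paste(c(sites$chrom[i], sites$pos[i], sites$locus_id[i], sites$ref[i],
            sites$alt[i], ".", "PASS", sprintf("MQ=%s", sites$mq[i]),
            "GT:AD:DP:GQ:BQ", cells), collapse = "\t")
  }, "")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Read a multi-sample VCF into a variant set
#'
#' Parses a VCF v4.2 file (plain or gzipped) via \pkg{vcfR} and converts
#' genotypes to allele dosages. Multi-allelic records are retained with all
#' alternate alleles (they are removed later by the biallelic filter); any
#' non-reference allele counts toward the dosage. Missing AD/DP/GQ/BQ
#' fields yield `NULL` matrices and a warning, and the dependent QC filters
#' are skipped.
#'
#' @param path VCF file path.
#' @return A [variant_set()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  mq <- suppressWarnings(as.numeric(vcfR::extract.info(v, "MQ")))
  gt_str <- vcfR::extract.gt(v, element = "GT")
  # a site is haploid iff no sample shows an allele separator at that site
  ploidy <- apply(gt_str, 1, function(r) {
    r <- r[!is.na(r) & r != "."]
    if (length(r) && !any(grepl("[/|]", r))) 1L else 2L
  })
  dose <- function(s) {
    if (is.na(s) || s %in% c(".", "./.", ".|.")) return(NA_integer_)
    al <- strsplit(s, "[/|]")[[1]]
    if (any(al == ".")) return(NA_integer_)
    sum(al != "0")
  }
  gt <- matrix(vapply(gt_str, dose, integer(1)), nrow(gt_str),
               dimnames = dimnames(gt_str))
  grab <- function(el, fun = as.numeric) {
    if (!grepl(paste0("(^|:)", el, "(:|$)"), v@gt[1, "FORMAT"])) {
      warning("FORMAT field ", el, " absent; dependent filters will be skipped")
      return(NULL)
    }
    m <- vcfR::extract.gt(v, element = el)
    matrix(suppressWarnings(fun(m)), nrow(m), dimnames = dimnames(m))
  }
  dp <- grab("DP")
  gq <- grab("GQ")
  bq <- grab("BQ")
  ad <- if (grepl("(^|:)AD(:|$)", v@gt[1, "FORMAT"])) {
    vcfR::extract.gt(v, element = "AD")
  } else NULL
  ad_ref <- ad_alt <- NULL
  if (!is.null(ad)) {
    parts <- strsplit(as.vector(ad), ",", fixed = TRUE)
    num1 <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
    num2 <- suppressWarnings(
      as.numeric(vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, "")))
    ad_ref <- matrix(num1, nrow(ad), dimnames = dimnames(ad))
    ad_alt <- matrix(num2, nrow(ad), dimnames = dimnames(ad))
  }
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- sprintf("%s_%s", fix$CHROM, fix$POS)[
    is.na(ids) | ids == "."]
  sites <- data.frame(locus_id = ids, chrom = fix$CHROM,
                      pos = as.integer(fix$POS), ref = fix$REF,
                      alt = fix$ALT, mq = mq, ploidy = ploidy,
                      stringsAsFactors = FALSE)
  variant_set(sites, gt, dp, ad_ref, ad_alt, gq, bq)
}

#' Write a gene annotation track as GFF3
#'
#' @param genes data.frame with `chrom`, `start`, `end`, `gene_id`.
#' @param path output path.
#' @param contig_lengths optional named vector; emitted as
#'   `##sequence-region` pragmas so readers recover contig bounds.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path, contig_lengths = NULL) {
  hdr <- "##gff-version 3"
  if (!is.null(contig_lengths)) {
    hdr <- c(hdr, sprintf("##sequence-region %s 1 %d", names(contig_lengths),
                          as.integer(contig_lengths)))
  }
  body <- sprintf("%s\tsnpforge\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                  genes$chrom, as.integer(genes$start),
                  as.integer(genes$end), genes$gene_id)
  writeLines(c(hdr, body), path)
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genotype-call matrix as TSV
#'
#' First column `locus_id`, then one column per sample; missing calls are
#' written as `NoCall`.
#' @param m loci x samples dosage matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_call_matrix <- function(m, path) {
  df <- as.data.frame(m, check.names = FALSE)
  df[] <- lapply(df, function(x) ifelse(is.na(x), "NoCall", as.character(x)))
  df <- cbind(locus_id = rownames(m), df)
  write_tsv(df, path)
}

#' Read a genotype-call matrix written by [write_call_matrix()]
#' @param path TSV path.
#' @return loci x samples integer matrix with `NA` for `NoCall`.
#' @export
read_call_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$locus_id
  storage.mode(m) <- "character"
  out <- suppressWarnings(matrix(as.integer(m), nrow(m), dimnames = dimnames(m)))
  out
}

#' Write the full simulated fixture bundle to disk
#'
#' Writes the multi-sample VCF, GFF3 annotation, sample metadata, per-strand
#' convertibility scores, the truth table, and (optionally) the two array-run
#' call sets, all as plain text.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if absent).
#' @param runs optional [simulate_array_runs()] result.
#' @return Named character vector of written file paths.
#' @export
write_fixture_bundle <- function(cohort, dir, runs = NULL) {
  if (nrow(cohort$samples) == 0L) stop("empty cohort: no samples to write")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- cohort$config
  contigs <- c(setNames(as.integer(cfg$chromosome_lengths),
                        sprintf("chr%d", seq_len(cfg$n_chromosomes))),
               chrCP = as.integer(cfg$chloroplast_length))
  paths <- c(
    vcf = file.path(dir, "variants.vcf"),
    gff3 = file.path(dir, "annotation.gff3"),
    samples = file.path(dir, "samples.tsv"),
    scores = file.path(dir, "pconvert.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_vcf(cohort$variants, paths[["vcf"]], contigs)
  write_gff3(cohort$genes, paths[["gff3"]], contigs)
  write_tsv(cohort$samples, paths[["samples"]])
  write_tsv(cohort$scores, paths[["scores"]])
  write_call_matrix(cohort$truth, paths[["truth"]])
  if (!is.null(runs)) {
    paths <- c(paths,
               analysis1 = file.path(dir, "calls_analysis1.tsv"),
               analysis2 = file.path(dir, "calls_analysis2.tsv"))
    write_call_matrix(runs$analysis1, paths[["analysis1"]])
    write_call_matrix(runs$analysis2, paths[["analysis2"]])
  }
  paths
}
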