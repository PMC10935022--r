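samples_for <- function(m, groups) {
  data.frame(sample_id = colnames(m), group = as.character(groups),
             stringsAsFactors = FALSE)
}

test_that("group alt-allele frequencies and the strict 0.1 bound behave as stated", {
  # 4 diploid samples [het, hom_ref x3] -> freq 1/8 = 0.125 -> polymorphic
  m <- matrix(c(1L, 0L, 0L, 0L), 1, 4,
              dimnames = list("L1", paste0("s", 1:4)))
  a <- assign_groups(m, samples_for(m, rep(1, 4)))
  expect_equal(a$freq_1, 0.125)
  expect_true(a$poly_1)

  # all hom_ref -> 0, not polymorphic
  m0 <- matrix(0L, 1, 4, dimnames = list("L1", paste0("s", 1:4)))
  expect_false(assign_groups(m0, samples_for(m0, rep(1, 4)))$poly_1)

  # freq exactly 0.1 is NOT polymorphic (strict >)
  m5 <- matrix(c(1L, 0L, 0L, 0L, 0L), 1, 5,
               dimnames = list("L1", paste0("s", 1:5)))
  a5 <- assign_groups(m5, samples_for(m5, rep(1, 5)))
  expect_equal(a5$freq_1, 0.1)
  expect_false(a5$poly_1)

  # a group with zero non-missing calls is excluded (NA frequency)
  mna <- matrix(c(1L, NA, NA), 1, 3, dimnames = list("L1", paste0("s", 1:3)))
  ana <- assign_groups(mna, samples_for(mna, c(1, 2, 2)))
  expect_true(is.na(ana$freq_2))
  expect_false(ana$poly_2)
})

test_that("with a single group the frequency is the plain site frequency", {
  co <- structured_cohort()
  m <- co$truth_dip[1:200, ]
  one <- samples_for(m, rep(1, ncol(m)))
  a <- assign_groups(m, one)
  expect_equal(a$freq_1, unname(rowSums(m)) / (2 * ncol(m)))
})

test_that("genic windows extend, clip, and merge", {
  genes <- data.frame(chrom = "chr1", start = c(10000L, 16000L, 100000L),
                      end = c(12000L, 18000L, 101000L))
  w <- build_genic_windows(genes, flank_bp = 5000)
  # first two genes' windows [5000,17000] and [11000,23000] merge
  expect_equal(w$start, c(5000L, 95000L))
  expect_equal(w$end, c(23000L, 106000L))

  w2 <- build_genic_windows(data.frame(chrom = "chr1", start = 3000L,
                                       end = 4000L), flank_bp = 5000)
  expect_equal(w2$start, 1L)   # clipped at the chromosome start
  expect_equal(w2$end, 9000L)

  # via GFF3 round trip, with sequence-region clipping at the end
  d <- withr::local_tempdir()
  path <- file.path(d, "genes.gff3")
  write_gff3(data.frame(chrom = "chr1", start = 99000L, end = 99800L,
                        gene_id = "g1"), path, c(chr1 = 100000L))
  w3 <- build_genic_windows(path, flank_bp = 5000)
  expect_equal(w3$start, 94000L)
  expect_equal(w3$end, 100000L)   # clipped to the declared contig length
})

test_that("part-1 filtering removes the documented classes and telescopes", {
  sites <- data.frame(
    locus_id = paste0("L", 1:6),
    chrom = "chr1", pos = c(1000L, 2000L, 3000L, 4000L, 5000L, 900000L),
    ref = c("A", "A", "C", "AC", "A", "A"),
    alt = c("T", "G", "G", "A", "G", "G"),
    mq = 60, ploidy = 2L, stringsAsFactors = FALSE)
  sites <- rbind(sites, data.frame(
    locus_id = "CP1", chrom = "chrCP", pos = 10L, ref = "A", alt = "T",
    mq = 60, ploidy = 1L, stringsAsFactors = FALSE))
  asg <- data.frame(locus_id = sites$locus_id,
                    n_groups = c(1, 1, 1, 1, 0, 1, 0))
  win <- data.frame(chrom = "chr1", start = 1L, end = 10000L)
  res <- filter_part1(sites, asg, win)
  # L1 A/T transversion; L3 C/G transversion; L4 indel; L5 no group;
  # L6 outside windows; chloroplast passes through untouched
  expect_setequal(res$retained, c("L2", "CP1"))
  st <- res$stages
  expect_equal(st$removed[st$stage == "group_polymorphism"], 1L)
  expect_equal(st$removed[st$stage == "genic_window"], 1L)
  expect_equal(st$removed[st$stage == "at_gc_transversion"], 2L)
  expect_equal(st$removed[st$stage == "indel"], 1L)
  expect_equal(res$n_input, sum(st$removed) + length(res$retained))
  expect_equal(st$retained[nrow(st)], length(res$retained))
})

test_that("tile decisions match a hand-enumerated oracle on the threshold grid", {
  oracle <- function(f, r) {
    if (f == r) return("both_strands")
    m <- max(f, r)
    pick <- if (f > r) "fwd_only" else "rev_only"
    if (m > 0.818) return(pick)
    if (m > 0.69) return(pick)
    "reject"
  }
  grid <- c(0, 0.5, 0.69, 0.6901, 0.818, 0.8181, 1.0)
  cand <- function(p, buildable = TRUE) {
    list(locus_id = "L1", pconvert = p, buildable = buildable,
         recommended = TRUE)
  }
  for (f in grid) for (r in grid) {
    expect_identical(tile_decision(cand(f), cand(r)), oracle(f, r))
  }
})

test_that("unbuildable strands and chloroplast passthrough are handled", {
  cand <- function(p, buildable = TRUE, rec = TRUE) {
    list(locus_id = "L1", pconvert = p, buildable = buildable,
         recommended = rec)
  }
  expect_identical(tile_decision(cand(0.9, FALSE), cand(0.9, FALSE)), "reject")
  # equal scores but one unbuildable: falls through to the max rule
  expect_identical(tile_decision(cand(0.9), cand(0.9, FALSE)), "fwd_only")
  expect_identical(tile_decision(cand(0.5, FALSE), cand(0.7)), "rev_only")
  # chloroplast: accepted when recommended, regardless of score
  expect_identical(tile_decision(cand(0.2), cand(0.1), chloroplast = TRUE),
                   "fwd_only")
  expect_identical(
    tile_decision(cand(0.2, rec = FALSE), cand(0.1, rec = FALSE),
                  chloroplast = TRUE), "reject")
  other <- cand(0.5)
  other$locus_id <- "L2"
  expect_error(tile_decision(cand(0.5), other), "different loci")
})

test_that("vectorised tiling respects the recommended-only restriction", {
  scores <- data.frame(
    locus_id = rep(c("A", "B"), each = 2),
    strand = rep(c("fwd", "rev"), 2),
    pconvert = c(0.9, 0.9, 0.95, 0.2),
    buildable = TRUE,
    recommended = c(TRUE, TRUE, FALSE, FALSE))
  td <- tile_decisions(scores)
  expect_identical(td$decision[td$locus_id == "A"], "both_strands")
  expect_identical(td$decision[td$locus_id == "B"], "reject")
  td2 <- tile_decisions(scores, recommended_only = FALSE)
  expect_identical(td2$decision[td2$locus_id == "B"], "fwd_only")
})
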