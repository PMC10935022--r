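---
title: "Designing and validating a SNP genotyping array: methods and models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and validating a SNP genotyping array: methods and models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpforge)
```

## The problem

Fixed-content SNP genotyping arrays are designed from a resequenced
*discovery panel*: variants are called against a reference genome, heavily
filtered, scored for probe convertibility, tiled on one or both strands,
screened on a validation panel, and finally downselected to the array's
capacity. The motivating application is citrus, where the panel spans three
strata of very different divergence — a core group (mandarins, pummelos and
their hybrids), citrons, and more distant relatives including papedas — plus
interspecific hybrids and many vegetatively propagated (clonal) accessions.
This package implements each computational stage of that workflow as a
tested, reusable function, together with a cohort simulator so the whole
pipeline runs end-to-end with no external data.

## The simulated cohort

`simulate_cohort()` generates founders in three divergence groups under a
Balding–Nichols model: for ancestral frequency $p \sim U(0.05, 0.95)$ and
group differentiation $F$, the group frequency is drawn from
$\mathrm{Beta}\!\left(p\frac{1-F}{F},\ (1-p)\frac{1-F}{F}\right)$, so $F$
acts as a per-group $F_{ST}$. Founder genotypes are
$\mathrm{Binomial}(2, p_g)$; hybrids receive one allele sampled from each
parent's genotype; clones copy their source and then mutate each nuclear
locus independently at the somatic mutation rate. A haploid chloroplast
track is carried separately: maternally copied in hybrids (first parent) and
copied exactly in clones — somatic mutations are modelled as nuclear only.

Read-level evidence mirrors what the post-calling filters consume: depth is
$\mathrm{Poisson}(\bar d)$ (no overdispersion; the simplest model consistent
with a stated mean — a dispersion hook could be added), alternate-read
counts are $\mathrm{Binomial}(d, \mu)$ with $\mu$ equal to the base error
rate, one half, or one minus the base error rate according to the true
genotype, and genotype/base/map qualities are emitted consistently with that
evidence. Per-strand probe convertibility scores are drawn from two Beta
distributions with a higher mean for genic loci (genic targeting converts
better in practice); the exact score model of the commercial in-silico step
is proprietary, so the scores are inputs here, never computed from sequence.

Defaults are the study conditions of the motivating panel: group sizes
29/4/8, nine chromosomes, a target depth of 30x, divergence 0.3 per group,
and gene density/length chosen to match the citrus annotation (about 80
genes per Mb of roughly 1.3 kb). Locus counts (200 per chromosome, 50
chloroplast; 5 Mb chromosomes) are desk-scale choices so a full run takes
seconds; every downstream check is statistical, not tied to genome size.

What the simulator does **not** emulate: probe hybridisation chemistry and
intensity space (so the probe classifier here is a documented surrogate, see
below), linkage disequilibrium decay along chromosomes (loci are exchangeable
within a chromosome), indel realism beyond length differences, and reference
bias. Passing tests therefore demonstrate the *logic* of every filter and
analysis on data whose truth is known — they do not certify performance
numbers on real germplasm.

## Quality control (`apply_qc`)

Per-call filters mask to missing: site map quality < 25, mean base quality
< 30, genotype quality < 20, depth outside $[10,\ 2\times\mathrm{median})$
(per-sample median, half-open upper bound exactly as printed), and the
allele-balance test on heterozygotes. Site-level filters then drop sites
with more than two alleles or with at least half the samples missing.

The allele-balance test is exact: a heterozygote with $k$ alternate reads
out of depth $d$ passes iff $P(X \le k) > \alpha/2$ and
$P(X \ge k) > \alpha/2$ under $X \sim \mathrm{Binomial}(d, 0.5)$, with
$\alpha = 0.05$ total tail area. "5% of total area" is interpreted as
equal-tailed (2.5% per tail); with the symmetric null these regions coincide
with minimum-mass regions up to discreteness. The test suite checks the
implementation against exhaustive pmf enumeration for every $(d \le 60, k)$.

Two numerical choices deserve note. Per-sample median depths are computed on
the input set before any masking (no iteration scheme is defined for the
filter, and recomputing after masking would make the filter
order-dependent); on Poisson-distributed depth this also makes the filter
idempotent in practice. And failing calls are masked rather than sites
dropped, matching per-sample annotations feeding a site-level missingness
test; only the biallelic and missingness filters act on whole sites.

## SNP selection

`assign_groups()` computes per-group alternate-allele frequencies from
genotype calls (missing calls excluded from the denominator — the only
frequency available post-VCF) and flags a locus polymorphic in a group when
the frequency strictly exceeds 0.1. `build_genic_windows()` expands each
annotated gene body by 5 kb on each side, clips to the chromosome, and
merges overlaps; windows are strand-agnostic and built from gene features
(whether the original filter used transcripts or strand-aware flanks is not
recoverable, and gene bodies are the conservative superset).
`filter_part1()` then removes, in order: loci polymorphic in no group, loci
outside all genic windows, A/T and G/C transversions (both alleles would
need the same colour channel on the array), and indels. Chloroplast loci
pass through part 1 untouched and rejoin the candidate set.

`tile_decision()` encodes the strand-tiling rules: equal convertibility
scores on two buildable strands tile both; otherwise the better strand is
taken if its score exceeds 0.818, or failing that 0.69; otherwise the locus
is rejected. Thresholds are strict (`>`) exactly as printed. Tiling is
restricted to loci recommended on at least one strand, and chloroplast loci
are accepted whenever recommended, bypassing the score rules.

## Array validation

The commercial genotype-cluster classifier is proprietary, so
`classify_probes()` is an explicit surrogate: a locus is
*PolyHighResolution* (PHR) when its call rate reaches 0.97 (the sample-QC
call-rate threshold in the reference workflow) and both alleles are seen
with a minor-allele count of at least 2; monomorphic loci are
*MonoHighResolution*; below the call-rate bar is *CallRateBelowThreshold*.
The surrogate cannot produce the intensity-space classes (OTV, hemizygous).

`simulate_array_runs()` produces the two analyses the consistency filter
compares. Analysis 2 emulates genotyping at lowered sample-QC thresholds;
since the error structure of that setting is not documented, the model
chosen here inflates the miscall rate for divergent-group samples (groups 2
and 3) by a configurable factor — an assumption, flagged as such. Miscall
probability also rises as convertibility falls,
$p = r\,(1 + w\,(1-P_{\mathrm{convert}}))$ with weight $w = 4$ by default.
`call_consistency()` retains loci whose calls do not differ between runs; a
call-versus-NoCall pair is *not* discordant by default (matching the
concordance convention that excludes NoCall), with a flag to flip that
behaviour. `select_best_probes()` keeps the strand probe with the higher
sequence concordance (ties: forward strand, then probe id).
`downselect()` apportions the autosomal target over chromosomes by largest
remainder (deterministic, sums exactly, error below one SNP per
chromosome), samples without replacement under the given seed, draws the
chloroplast quota from its own stratum, and reports per-chromosome counts
and maximum inter-SNP gaps.

## Metrics and population analyses

Heterozygosity is the percentage of called diploid loci that are
heterozygous; concordance is the percentage of jointly-called loci that
agree (NoCall excluded from both denominators — the same convention
throughout); clonal identity is all pairwise concordances within clone
groups. PCA uses dosage coding with missing calls imputed to the locus mean
(the standard default for genotype PCA), column centering, and no scaling.
LD pruning drops the later locus of any pair with $r^2$ at or above the
threshold, scanning each chromosome in position order against the last 50
retained loci (the scan needs a window; 50 is ample when threshold 1 is
used only to remove duplicated loci); monomorphic loci are kept and skipped.

Trees are built by neighbor joining on allele-sharing distances,
$d(a,b) = 1 - \frac{\text{shared alleles}}{2 \times \text{joint loci}}$.
The NJ implementation is deterministic: Q-criterion ties break on the
smallest index pair, and negative branch lengths are clamped to zero with
the excess moved to the adjacent branch so the pair distance is preserved.
The reference workflow built its main trees by maximum likelihood through
an external pipeline whose exact configuration is not recoverable; NJ is
used for all trees here because the reference analysis itself uses NJ for
its sequence-data and error-simulation trees, and because NJ is exactly
testable — it provably reconstructs additive distances, which the suite
verifies against patristic-distance oracles on random trees. Its settings
of "no MAF filter, no missingness filter" before tree building are the
defaults here. Bootstrap support resamples loci with replacement and scores
each internal edge by the percentage of replicates containing the same
bipartition; topologies are compared by Robinson–Foulds distance (the count
of bipartitions unique to one tree), a deterministic stand-in for visual
tree comparison.

## Genotyping-error robustness

`build_error_universe()` restricts to loci where every target sample is
called and agrees between array and sequence matrices. `inject_errors()`
flips exactly $\lfloor \text{rate} \times |\text{universe}| \rfloor$ loci
per target sample (floor: deterministic and conservative), heterozygotes to
a homozygote chosen uniformly (the minimal assumption for the direction,
seeded) and homozygotes to heterozygous; draws are independent per sample
(array errors are per-sample events), with a flag for a shared locus set.
`stability_report()` projects the perturbed matrix onto the baseline PCA
basis — one coordinate system, so zero injected error gives exactly zero
displacement — and reports the Robinson–Foulds distance between trees,
whether each target's nearest group centroid in PC1–PC3 changed, and the
maximum displacement normalised by the mean between-group centroid
distance. At the tested rates (0/3/5%) on a well-differentiated cohort the
assignments do not move, reproducing the qualitative robustness finding as
a pass/fail assertion.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(seed = 1)
manifest <- run_pipeline(cfg, "pipeline_out")
str(manifest$counts)
manifest$stability
```

The manifest records per-stage counts (which telescope: each stage retains
no more than the last), every threshold used, and an md5 hash per output
file; rerunning with the same seed reproduces every file byte for byte.

## Problem sizes and limitations

The suite and the acceptance script run cohorts of 30–47 samples and
2,000–5,000 loci with 200 bootstrap replicates — sizes chosen so that a
full check completes in about a minute while every statistical assertion
retains 4-sigma headroom. Known limitations: the probe classifier is a
surrogate (no intensity modelling); trio-based Mendelian screening is not
implemented; admixture-model fitting is out of scope; and simulated loci
carry no LD structure, so LD pruning at thresholds below 1 is exercised on
constructed fixtures rather than the simulated cohort.
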