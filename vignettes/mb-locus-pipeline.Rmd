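---
title: "Mapping and reconstructing the Mb structural variant: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping and reconstructing the Mb structural variant: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbsv)
```

`mbsv` is a reimplementation, on synthetic data, of the multi-stage analysis
that localises the chicken Muffs-and-beard (Mb) locus and reconstructs the
complex structural variant behind it. This vignette explains the models each
stage assumes, the tunable parameters and their defaults, the numerical
choices, and what the synthetic-data generators do and do not emulate.

## The target of the reconstruction

The derived *Mb* haplotype differs from the wild-type chromosome by three
duplicated segments: CNV1 (1,702,269–1,721,521 bp), CNV2
(3,578,409–3,592,890 bp) and CNV3 (4,470,331–4,503,417 bp). Copies of CNV3
and CNV2 are joined to a second copy of CNV1 and the whole cassette is
inserted directly downstream of the original CNV1, giving the segment order
CNV1–CNV3–CNV2–CNV1. The three novel adjacencies carry, respectively, a 2-nt
microhomology, a 2-nt untemplated insertion and an 8-nt untemplated
insertion. `mb_sv_spec()` encodes exactly this architecture;
`mb_breakpoints(scale)` divides the printed coordinates by a scale factor so
the same architecture fits on a toy chromosome. All coordinates in the
package are 1-based inclusive; conversion to 0-based half-open happens only
when writing bedGraph/BEDPE.

```{r}
mb_sv_spec(scale = 20)
```

## Synthetic-data generators

**Toy genomes and derived haplotypes.** `random_toy_genome()` draws an
i.i.d. base sequence (42% GC, typical of an avian autosome).
`build_derived_haplotype()` inserts the cassette after `insertion_after`,
keeping the original copies in place. Microhomology junctions are *enforced*:
the right-hand flank of the junction is edited so that the two joined flanks
genuinely share the requested bases, and the edited reference travels with
the result (`attr(, "reference")`) because it is the reference downstream
detection must align against. The builder also keeps every junction's stated
description *canonical*: a single flank base that would let an aligner absorb
homology or insertion bases beyond the planted coordinates is rotated to a
different base (positions tied together by homology enforcement are rotated
in pairs). Without this, the generator's ground truth and any maximal-exact-
match aligner would legitimately disagree on the breakpoint representation.
The derived length always equals
`ref + sum(segments) − sum(homologies) + sum(insertions)`; for the published
breakpoints that is +66,830 bp.

**F2 intercross.** `simulate_cross()` models a cross between two fully
inbred founder lines. Meioses follow the Haldane map function
(`r = (1 − e^{−2d/100})/2`, no crossover interference) — the original study
does not state a meiosis model, and Haldane is the conventional neutral
choice. Founders are fixed for alternative alleles at every informative
marker; an `informativeness` parameter dilutes this. The phenotype model is
a fully penetrant dominant locus by default (`penetrance` is a knob; the
"incompletely dominant" description of the real trait refers to expression
strength, not carrier penetrance, so 1.0 is the default). The
birth-covariate model makes an expressing bird show the trait at birth with
probability `birth_covariate_rate = 0.3`: the real mapping used the
at-birth record as a covariate and still found an extreme 10-week signal, so
the birth record must be far from fully predictive; facial feathering
develops progressively after hatch. The simulated genome also carries
unlinked background chromosomes (default 4 × 26 markers) so that a *genomic*
kinship matrix can be computed from markers mostly unlinked to the trait, as
with a genome-wide SNP chip.

**Pooled depth.** `simulate_pool_depth()` draws per-window depth from a
negative binomial with mean `mean_depth × CN/2`; the default
`overdispersion = 0` is the Poisson limit, because only mean pool depths
(95× and 97×, the package defaults) are reported for the real pools. Mapping
quality is Gaussian per window, depressed inside configurable low-MQ
regions.

**Reads, pyro signals, Ct tables.** `simulate_junction_reads()` places
error-free or uniformly-erroring single-end reads uniformly (no base-quality
or insert-size model — a stated non-goal). `simulate_pyro_signal()` makes
peak heights dosage-proportional (`signal_per_copy × copies` + truncated
Gaussian noise). `simulate_ct_table()` writes
`Ct = ref_Ct + offset − log2(relative expression) + noise` in sextuplicate,
the replication of the real qPCR design. `mb_expression_panel()` encodes the
seven-gene pattern: continuous ectopic facial expression for HOXB8 (silent
in wild type), postnatal-only differences for CCR7/SMARCE1/KRT222, dorsal-
dominated differences for SMARCD2, no consistent differential for PSMC5 and
HOXB7.

What the generators deliberately do **not** emulate: linked marker panels
with realistic LD decay, genotyping-error processes in the cross, paired-end
reads, GC-dependent coverage, and qPCR efficiency differences between
genes. Passing tests therefore demonstrate the correctness of the
algorithms under their stated models, not robustness to every artefact of
real data.

## Association scan

QC follows the published thresholds with strict inequalities: individual
call rate > 0.9, SNP call rate > 0.9, MAF ≥ 0.05, pedigree-based Mendelian
error rate ≤ 5% per individual and per SNP (offending single calls are set
missing), W-linked markers removed, heterozygous Z-linked calls in females
(the heterogametic sex in birds) masked. QC order matters for none of the
tested datasets, and applying the filter twice is a no-op on them.

The scan itself is a two-stage GRAMMAR-style approximation of a linear mixed
model, analysing the binary trait on the 0/1 scale: the null model
`y = Xβ + u + e` with `u ~ N(0, σ²_g K)` is fitted once by maximum
likelihood on the eigendecomposition of the kinship matrix `K`, and each
marker is then tested by correlating its genotypes (pairwise-complete) with
the environmental residuals; p-values come from the t distribution with
`n − 2` df. This reproduces the plain covariate-adjusted score test exactly
when `K = I`, and is calibrated on null simulations (KS-uniform p-values,
nominal type-I error at α = 0.05 and 0.01).

One numerical pitfall deserves emphasis: **proximal contamination**. If `K`
is computed from the markers of the trait chromosome itself, the polygenic
term absorbs the Mendelian locus — in our simulations the residual
correlation with the causal genotype collapsed from 0.77 to 0.06 and the
peak p-value from ~10⁻¹⁰⁰ to 0.18. The real analysis was protected by its
genome-wide chip (the trait chromosome contributes ~0.1% of the kinship);
with a handful of simulated chromosomes the package instead computes the
kinship leave-one-chromosome-out (`compute_kinship(gm, exclude_chrom =
"chr27")`), the standard remedy in modern mixed-model GWAS. The conditional
scan (`conditional_scan()`) appends the top marker's mean-imputed genotype
to the covariates and skips the marker itself.

`bonferroni_threshold(n, alpha)` is `alpha/n`; with the real study's 43,493
SNPs that is 1.15 × 10⁻⁶. `ld_r2()` is the squared Pearson correlation of
genotype codes.

## Line origin, linkage and shared IBD

The published line-origin computation used a proprietary "trim" algorithm;
`infer_line_origin()` is a behavioural, not bit-exact, replacement: a
3-state HMM over `{HH, HL, LL}` (both alleles from the HB line, one each,
both from the HQLA line) with Haldane transition probabilities between
positions, emissions driven by the founder-line allele frequencies with a
per-allele error parameter (default 0.001), and the F2 prior
`{¼, ½, ¼}`. Posteriors are computed by forward–backward jointly over
markers and the 1-cM grid (grid points simply have uninformative
emissions — no ad-hoc interpolation). With fully informative markers and
zero error the posteriors are exact 0/1 calls; with markers carrying no
line information the posterior equals the prior.

`linkage_scan()` regresses the phenotype on the additive (`P(HH) − P(LL)`)
and dominance (`P(HL)`) expectations of line origin plus the covariate and
reports the 2-df F statistic per grid point; if a class is absent the test
drops to 1 df with a notice. `randomization_threshold()` is the
`(1 − α)` quantile of the maximum F over phenotype permutations (phenotype
and covariate permuted together; 1000 permutations in the source analysis,
`n_perm ≥ 100` enforced), reproducible under a fixed seed.

`shared_ibd_interval()` hard-calls posteriors above 0.99 (positions failing
the threshold are *unknown* and cannot disqualify a position — uncertainty
must not shrink the interval) and intersects under the dominant model:
every affected bird carries ≥ 1 HB-origin allele, every unaffected bird
carries none. The longest qualifying run is snapped outward to the nearest
flanking markers and reported with the recombinant individuals that define
each boundary; a phenocopy legitimately empties the result, which is
reported as such rather than an error.

## Read-depth CNV scan

"1-kb sliding window" is implemented as a non-overlapping 1-kb tiling — the
published per-window MQ rule is only well-defined on a tiling. The MQ filter
flags windows strictly below `mean(MQ) − 3 SD(MQ)`; on the real data this
rule evaluated to MQ < 30, which the package reproduces as a special case
(mean 60, SD 10). Fold change divides each pool's window depths by that
pool's genome-wide median (the original analysis does not state its normalization;
median normalization is scale-invariant and robust to the CNVs themselves),
then takes log2 ratios; windows filtered in either pool or with zero depth
are excluded rather than assigned ±∞. `segment_cnv()` merges runs of
windows with |log2FC| ≥ 0.58 (≈ log2 1.5) of the same sign, bridging at most
one non-qualifying window, into calls of ≥ 3 windows — call thresholds are
package defaults (the original analysis reports loci, not thresholds) and are exposed
as arguments.

## Junction detection, classification and assembly

`detect_junctions()` performs seed-and-extend split alignment with exact
matching: reads that do not align contiguously anywhere contribute their
maximal exact prefix and suffix matches (anchors ≥ 20 bp, forward
orientation only — all duplications in the target architecture are forward;
inverted gains are rejected, not mis-assembled). A read whose prefix and
suffix land on discordant loci votes for an adjacency; votes are clustered
within ±2 bp and clusters need ≥ 2 supporting reads. Coordinates follow the
maximal-prefix convention, under which a junction with microhomology `h`
satisfies `derived = ref[..left_end] ⧺ ref[right_start + h..]`.

`classify_junction()` makes the microhomology/insertion distinction
operational: with `a` the maximal consensus prefix assignable to the left
flank and `s` the maximal suffix assignable to the right flank,
`homology = max(0, a + s − n)` and any bases matching neither flank are the
untemplated insertion; exactly one of the two is nonzero (both zero is a
blunt join). The original observations report a 2-nt "overlap" at one
junction and 2-nt/8-nt "insertions" at the others without defining the
classifier; the maximal-dual-assignment convention is this package's
choice and is what the round-trip tests pin down.

`assemble_allele()` builds the breakpoint graph: nodes are backbone pieces
(multiplicity 1) and duplicated segments (multiplicity `round(2^log2FC)` per
haplotype, from the CNV calls), edges are reference adjacencies plus
detected junctions; window-resolution CNV boundaries are refined to the
base-precise junction coordinates. It enumerates every walk from the first
to the last backbone piece that consumes all multiplicities, then applies
two structural constraints:

* **Backbone intactness** — a duplication-only event cannot reorder the
  chromosome outside the duplicated segments, so walks visiting backbone
  pieces out of genomic order are discarded. (Without this constraint the
  three-junction pattern admits spurious reconstructions that interleave
  the backbone.)
* **Insertion locus** — the junction multiset plus copy counts are invariant
  under circular permutation of the cassette placement: the same three
  junctions are equally consistent with the cassette sitting at CNV1 or at
  CNV2. `insertion_locus_hint` (in practice: where the depth gain abuts the
  first novel junction, or the diagnostic PCR locus) selects among the
  survivors. With no hint, *all* consistent walks are returned as an
  ambiguity object — the caller decides; an exhaustive permutation oracle
  in the test suite confirms the enumeration.

`resolve_copy_order()` settles which CNV1 copy is ancestral using a
recombinant bird: every assignment of the copy-specific allele to a copy is
crossed with every recombination hypothesis (which side of the crossover is
the variant haplotype × which copy contains the breakpoint); each
combination predicts the recombinant's phenotype (does the chromosome retain
any novel junction?) and its genotype at the diagnostic site. For the
observed evidence — a non-carrier bird, genotype T/C at the site, crossover
just inside the duplicated interval — the unique consistent assignment puts
the panel-absent C allele on the distal copy, labelling it the new copy and
the proximal copy the original. Uninformative evidence yields an
`unresolved` flag, contradictory evidence an error; a call is never forced.

## Dosage genotyping and diagnostics

At the diagnostic site inside the tandem-duplicated interval every
chromosome contributes one T (original copy) and each *Mb* chromosome one
additional C (new copy): expected T:C is "T only" for mb/mb, 2:1 for Mb/mb,
1:1 for Mb/Mb — total copies `2 + (# Mb alleles)`. `call_genotype_pyro()`
tests each class by Pearson chi-squared goodness of fit on peak heights
rescaled to 100 pseudo-counts (peak heights are continuous; the effective
count makes the test well-defined and is configurable). A class expecting
*zero* signal for an allele needs its own rule — a chi-squared cell with
zero expectation is undefined — so such a class is rejected exactly when
that allele's observed share of total signal exceeds `zero_tol = 0.10`
(a peak below 10% of signal is indistinguishable from background). Classes
surviving at α = 0.05 are counted: a unique survivor is the call, anything
else is `ambiguous` — never forced, since the workflow backstops ambiguous
birds with the junction PCR diagnostic. Under the generator's own noise
model (signal 100/copy, SD 5) the caller is ≥ 99% correct with zero wrong
calls on 1000 simulated birds, and calls are invariant to rescaling all
peaks. `insilico_pcr()` uses exact primer matching (no mismatch or
3'-tolerance model) on the plus strand with a 10-kb product cap, which is
sufficient for junction-diagnostic assays on toy genomes.

## Relative expression and candidate triage

`delta_delta_ct()` pairs target and reference-gene replicates per sample:
`ΔCt = Ct_gene − Ct_ref`, `ΔΔCt = ΔCt − mean ΔCt(calibrator)`, fold
`2^−ΔΔCt`. The computation is exactly invariant to plate-wide Ct shifts and
unbiased on the log scale at zero noise. Group comparisons are Welch t-tests
on the ΔΔCt scale with the conventional tiers (*** p<0.001, ** p<0.01,
* p<0.05); the original analysis states only the tiers, so the test choice is ours. When both replicate groups are exactly constant (a
zero-noise simulation), p is defined as 1 for identical means and 0
otherwise. No multiple-testing correction is applied across genes and
stages, matching the original per-panel significance reporting; a
Benjamini–Hochberg adjustment can be applied externally to the returned
p-values.

`classify_candidate()` encodes what "consistent with establishing the
phenotype during development" means operationally: (a) a significant
carrier-vs-wild-type facial-skin differential, in the carrier direction, at
*every* assayed embryonic stage and in adults; and (b) wild-type facial
expression below `silent_floor = 0.05` of the carrier level ("barely
detectable" is a qualitative description; 5% is the package's
operationalisation and is configurable). On the synthetic seven-gene panel
exactly one gene — the HOXB8-like pattern — satisfies both; genes
differential only postnatally (CCR7-like) fail (a), genes with modest
ubiquitous differences (SMARCD2-like) fail (b).

## Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` run the SV workflow at 1/20 of the
printed coordinates (a ~230-kb toy chromosome, 50-bp windows — preserving
the window:CNV size ratio of the real 1-kb analysis), crosses of 50–800
birds with 41 focal markers plus background chromosomes, 10–20× read
coverage, and 60–100 replicate null scans for the calibration properties;
the full-coordinate derived allele (+66,830 bp) is built once to verify the
length arithmetic. Every stochastic step takes an explicit integer seed, and
each generator call is bit-for-bit reproducible given its seed.

## Known limitations

* The mixed model is an approximation (GRAMMAR residuals, ML variance
  components); it is calibrated under the null but slightly conservative
  for extremely strong signals, which is immaterial here.
* The line-origin HMM is a documented stand-in for the unpublished "trim"
  algorithm; agreement is behavioural (exact at zero noise), not bit-exact.
* Junction detection assumes exact anchors; with per-base error rates
  above ~1% on 150-bp reads, support counting (not coordinates) degrades
  first.
* The assembler handles forward-orientation copy gains; inversions and
  backbone-rearranging events are rejected explicitly.
* Only single-chromosome architectures with non-nested duplicated segments
  are generated and assembled; nested or overlapping duplications are out
  of scope.
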