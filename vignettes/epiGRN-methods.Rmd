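---
title: "Methods: hub-centered genetic regulatory networks from association and epistasis"
author: "epiGRN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hub-centered genetic regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`epiGRN` reconstructs the genetic regulatory neighbourhood of a
transcription-factor (TF) hub gene in a panel of unrelated individuals.
This vignette is the package's account of the statistics it implements,
the choices that were genuinely open, and what the bundled simulations
do and do not establish.

## The setting

The intended data are a candidate-gene association study: a panel of a
few hundred unrelated individuals genotyped at SNPs in the hub TF and
in a set of candidate genes, phenotyped for quantitative traits (the
motivating application is tree growth — DBH, height, stem volume — and
wood properties — hemicellulose, holocellulose, alpha-cellulose and
lignin content, fiber length and width, microfibril angle), with
population-structure membership coefficients (a Q matrix), promoter
sequences (2,000 bp upstream of the TSS) and a tissue expression matrix
for the same genes.

## Target discovery

A gene is called a putative hub target when two independent lines of
evidence agree:

* its promoter contains an exact occurrence of a TF binding motif
  (defaults: `TCACGTGA`, the conserved WUS-box, and the alternative
  core `TAAT`), and
* its expression profile across tissues is strongly correlated with
  the hub's (Pearson |r| > 0.8, *strict*: r = 0.8 exactly does not
  qualify).

Scanning is exact-string on both strands; occurrences may overlap; a
motif that is its own reverse complement (as `TCACGTGA` is) is counted
once, on the forward strand, so both-strand scanning never double
counts it. Positions are reported as bp upstream of the TSS, position 1
being the base immediately 5' of the TSS, and a hit's position is the
offset of its base nearest the TSS; the windowed positional summary
(`motifWindowFractions`) uses closed windows (defaults 300–600 and
650–950 bp) with all hits in the denominator. The anchor-base and
closed-interval conventions are package choices — the field reports
windows without defining either.

Two open points were resolved as follows. A gene qualifies as
motif-bearing if it carries *any* scanned motif (`requireMotif` narrows
this to one motif class). The differential-expression screen
(`screenDE`; FC ≥ 2 or ≤ 0.5, q ≤ 0.10, p ≤ 1e-3, all inclusive) is a
separate operation rather than being hard-wired before or after the
correlation filter, because published descriptions of such pipelines
are ambiguous about the order; callers compose the two in either order.
Correlations over as few as four tissues are honoured as-is, as a pure
threshold with no significance attached — with n = 4 the sample r is
extremely noisy, which is a property of the design, not of the
implementation (see Limitations).

## Single-locus association

For each SNP and trait the package fits, on complete cases, the fixed
effects model

y = β₀ + Q γ + a·x + d·z + ε,  x ∈ {−1, 0, +1}, z ∈ {−0.5, +0.5, −0.5}

where x counts minor-allele copies (centered at the heterozygote) and z
flags heterozygosity. Under this classical F∞ parameterization *a* is
half the difference between the homozygote means and *d* is the
heterozygote deviation from the homozygote midpoint; with no
covariates, the coefficients reproduce those contrasts of the raw class
means exactly. The genotypic effect *m* is the 2-df
extra-sum-of-squares F test of the genotype factor over the covariate
model, with R² = (SSE_reduced − SSE_full) / SS_total. The codings
themselves are a package decision: the classical parameterization
implied by least-squares additive/dominance testing in unrelated
panels, since source descriptions never state codings.

Population structure enters as fixed covariates (the Q columns), not as
a kinship random effect. This is a deliberate simplification of
mixed-model association: the least-squares machinery matches the
"unrelated individuals" test the workflow is built around, and kinship
matrices are typically unavailable for such panels. Where a true MLM
matters, effect sizes will differ; the covariate adjustment still
removes mean-level stratification (a property-tested behaviour: a
structure-confounded null SNP is inflated without Q and calibrated with
it).

Minor alleles are determined per site *from the loaded cohort*, never
from VCF REF/ALT, so additive effects are oriented consistently; ties
at frequency 0.5 count the ALT allele. Missing genotypes are handled
per test by complete-case restriction (no imputation). Genotype classes
with fewer than `minClassN = 3` individuals are dropped from a test;
SNPs left with two classes get an additive slope only (the dominance
code is then collinear) and are reason-coded; monomorphic SNPs are
retained in the container, flagged, and skipped with a reason — never
silently dropped.

Multiple testing uses Benjamini–Hochberg (`stats::p.adjust`) within
each (trait, effect-type) family — the family definition is
configurable because the convention varies between analysts.
Significance defaults are p ≤ 0.01 and FDR < 0.1; a stricter FDR ≤ 0.01
preset is recognised by the config validator (both conventions appear
in the literature this workflow descends from, and the package follows
the more permissive one by default, flagging the other as a note).
`significanceTransform` implements the reporting convention
log₁₀(1/p).

## Epistasis

Pairs of SNPs are tested with the eight-column genetic design

x₁, z₁, x₂, z₂, x₁x₂ (A×A), x₁z₂ (A×D), z₁x₂ (D×A), z₁z₂ (D×D),

fit by least squares with the same covariates. This realizes the
extended Kempthorne partition — orthogonal two-locus contrasts
generalized to unequal observed genotype frequencies — as a regression:
with every 3×3 cell equally occupied, the mean-centered codes and the
products of centered codes are mutually orthogonal (a tested
invariant), and least squares generalizes that partition to the
frequencies actually observed. Each epistatic coefficient gets a 1-df
full-versus-dropped-term F test; a joint 4-df test covers the whole
interaction block. D×A is reported separately from A×D: locus order
matters.

Empty or near-empty cells make interaction contrasts inestimable. The
default occupancy rule — all three marginal classes at each locus with
at least 3 individuals, and at least 5 of the 9 cells non-empty — skips
hopeless pairs with a reason code; pairs that pass but are still rank
deficient (e.g. duplicated SNPs) have the aliased effects reported as
non-estimable (NA), never as zero. Whether covariates belong in the
pair model is unstated in the source tradition; they are included by
default for consistency with the single-locus scan.

Combination tables (`combinationEffects`) mirror the classic
effect/frequency report. For A×A each individual contributes its four
ordered allele pairings at weight 1/4, so a combination's frequency is
essentially the product of its allele frequencies at unlinked loci —
the only weighting consistent with such published tables — and by
construction frequencies sum to 1 and frequency-weighted effects sum to
0 (tested to 1e-12/1e-9 on complete data). A×D and D×A cross an allele
(weight 1/2 per copy) with a genotype; D×D is plain cell means. The
printed "effect" column of legacy epistasis software may use an
internal scaling that is not recoverable from published tables; this
package reports the least-squares coefficient and the weighted-mean
deviations and documents them as such, without asserting numerical
equality to any specific historical output.

## Linkage disequilibrium

r² is the squared Pearson correlation of minor-allele-count vectors on
complete cases (composite genotypic LD — the data are unphased, and
composite r² is standard practice there); it is symmetric and invariant
to allele orientation, and exactly 1 for duplicated or mirrored
columns. Decay is fitted with the Hill–Weir expectation

E(r²) = [(10 + C·d) / ((2 + C·d)(11 + C·d))] ·
        [1 + ((3 + C·d)(12 + 12·C·d + (C·d)²)) / (n(2 + C·d)(11 + C·d))]

with d the distance in bp, n the sample size, and a single free
parameter C (per-bp population recombination), fitted by nonlinear
least squares — a golden-section search on log C over [1e-10, 1e3] with
a local polish, which recovers a known C to 1e-6 relative error on
noiseless curve data. The curve is monotone non-increasing and tends to
1/n, so `crossingBp(fit, 0.1)` (the conventional "LD has decayed"
threshold) is finite whenever the asymptote lies below the threshold
and `Inf` otherwise; an all-r²-equal input drives C to the lower search
bound, which is flagged as a boundary fit. The exact functional form is
documented here because the "expected r²" label alone does not pin it
down. Restricting pairs to one gene (intragenic decay) is supported via
`ldPairs(gene=)`, since candidate-gene panels usually report decay
within the gene of interest.

## Network construction

Significant SNP pairs (p ≤ α and q ≤ FDR, per family) collapse to
undirected gene-gene edges with their SNP-pair support; within-gene
pairs are dropped (a gene is never its own neighbour). The hub is layer
1; genes sharing an edge with the hub are layer 2; genes reachable only
indirectly are layer 3. The depth cap (default 3, configurable) keeps
deeper reachable genes in the outermost layer, matching the three-layer
convention of published hub networks while allowing a fourth layer
where a trait-specific network calls for it. Genes unreachable from the
hub are excluded and listed. Layer assignment equals BFS distance from
the hub (property-tested against an independent hand-coded BFS on 1,000
random graphs) and construction is order-independent with lexicographic
tie-breaks. Pooling across traits is the union of per-trait significant
edges (each edge records its traits), documented as this package's
definition rather than an assertion about any particular published
network. Connectivity is reported as the fraction of a candidate-gene
universe assigned to layers 2+, hub excluded from both sides.

## The synthetic-data module

The generator exists so every downstream stage is testable without
external data, and its defaults are the bundled demo's study
conditions: 435 unrelated individuals (a typical forest-tree
association panel), a hub gene plus 10 target and 3 decoy genes, MAF
drawn uniformly from (0.15, 0.5) for background SNPs with
effect-carrying SNPs pinned at MAF 0.4 (the information for an A×A
contrast lives in the double-homozygote cells, whose expected counts
scale like n·p⁴ and vanish at low MAF — a demo whose planted network
is only sometimes detectable would demonstrate nothing), SNPs spaced
24 bp apart (the density of a dense candidate-gene resequencing
panel), two traits with residual SD 1 and additive/dominance/A×A
effects of 0.5–1.2 trait units (single-SNP R² in the sub-percent to
few-percent range typical of such panels), two uniform structure
components with effects ±0.5, and planted expression correlations of
|r| ∈ {0.9, 0.95, 0.98} so that realized four-tissue correlations
usually clear the 0.8 threshold.

Genotypes are drawn as two independent Bernoulli(MAF) haplotypes per
individual (HWE); LD blocks copy the anchor SNP's haplotype state with
probability ρ per haplotype, which pins the ρ = 1 ⇒ r² = 1 corner
exactly and gives tunable intermediate LD — chosen over multivariate-
normal thresholding precisely for that exact corner and its simplicity.
Phenotypes are the single-locus codes and their products times the
effect coefficients plus Q effects and Gaussian noise, the exact
generative mirror of the fitted models (σ → 0 recovery to 1e-8 is a
tested invariant). Expression targets are r·(standardized hub) +
√(1−r²)·noise, shifted positive by a constant — a shift, not an
exponential, so the planted Pearson correlation is preserved.
Promoter backgrounds are i.i.d. at a requested GC content and are
guaranteed motif-free on both strands by resampling collision windows,
so a scan of planted promoters returns exactly the planted sites.

What the generator does **not** emulate: coalescent genealogy and
realistic allele-frequency spectra, kinship/cryptic relatedness beyond
supplied Q effects, RNA-seq count noise, genotyping error or
missingness mechanisms. Passing tests therefore demonstrate
correctness of the statistics under a clean generative model, not
robustness to those real-data features.

## Numerical choices

* All fits go through one QR path with pivoting; aliased coefficients
  surface as NA ("non-estimable"), never 0. Tests cross-check every
  p-value against independent `lm()`/`anova()` fits to 1e-10.
* Adjusted genotype/cell means are observations corrected to the
  covariate mean, then averaged per class — well-defined even when
  some interaction contrasts are aliased.
* Seeds: every pipeline stage derives a named substream from the root
  seed via a fixed integer recurrence (kept below 2³¹), so identical
  configs reproduce byte-identical outputs and stages can be re-run
  standalone.
* Problem sizes in the test and acceptance suites (e.g. 2,000-test
  null calibrations, 500-replicate recovery studies, 100 random oracle
  panels) were chosen as the smallest sizes at which the Monte-Carlo
  error of each check is comfortably below its tolerance.

## Known limitations

* **Fixed-effect structure adjustment.** Q columns capture mean-level
  stratification only; no kinship random effect is fitted.
* **Orientation-induced marginal bias under unmodeled epistasis.**
  Because codes count the *realized* minor allele, E[x] ≤ 0 in finite
  samples. If a SNP participates in an epistatic interaction that the
  single-locus model omits, that interaction leaks a small bias
  (order c·E[x̄], ~0.015 trait units in the demo conditions) into the
  SNP's marginal additive estimate. Any fixed orientation convention
  has an analogue of this; the joint two-locus fit is unbiased.
* **Four-condition correlations.** With n = 4 tissues the sample
  Pearson r has enormous variance; the strict 0.8 threshold is a
  screening device, not an inference.
* **Exact-string motifs.** No PWM scanning or motif discovery; degenerate
  sites (beyond N in the subject) are not supported.
* **Desk-scale epistasis.** Pair lists are explicit or hub-vs-target;
  exhaustive genome-wide all-pairs scans are out of scope.
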