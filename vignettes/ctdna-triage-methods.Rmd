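---
title: "Methods: ctDNA detection and group triage from targeted cfDNA panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ctDNA detection and group triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdnatriage)
```

## Scope and assumptions

`ctdnatriage` implements the downstream decision layer of a targeted cfDNA
sequencing analysis for mCRPC: it consumes per-caller SNV/indel and SV call
sets, per-target mean depths, and upstream ctDNA aneuploidy fraction
estimates, and produces copy-ratio calls, filtered pathogenic mutations,
AR-GSR classifications, a three-group ctDNA-positivity assignment, and
survival summaries. Read processing, the variant and SV callers themselves,
annotation lookup, and the aneuploidy estimator are all upstream: their
outputs are inputs here, and the synthetic cohort generator emulates them.

Standing assumptions: cfDNA derives from male patients (one germline X
copy, which drives both the control-region scaling and the chrX dilution
identity); the tumor compartment is a single clone mixed into diploid
normal cfDNA at fraction $f$; depth is proportional to local copy number
within a sample once a per-sample baseline is removed.

## Copy-number model

For each sample the mean depth of a target is normalized by a control
scale built from five control regions, exactly one of which (C2) is on
chrX. With one germline X, C2 carries half the per-copy depth of the
autosomal controls, so the scale doubles C2 for chrX targets and halves
the autosomal controls for autosomal targets. The two scales differ by a
factor of 2 (neutral chrX targets normalize to 0.5, neutral autosomal
targets to 2.0); the asymmetry is deliberately left as specified, because
the subsequent ratio against the panel of normals cancels it.

The panel of normals is built once from all samples with aneuploidy
fraction ≤ 0.05 (at least two required) as the per-target arithmetic mean
of normalized depths, and reused for every query sample. The fraction
cutoff assumes ≤ 5% tumor content contributes negligible copy signal; the
generator enforces this by drawing alteration-bearing samples above the
cutoff (see below).

Gain and loss calls use *strict* inequalities: gain iff
$\log_2 r > 0.3$, loss iff $\log_2 r < -0.3$ and the sample is
ctDNA-positive. The textual rule uses strict inequalities while some
figure legends read "≥ 0.3"; we adopt the strict form, so the boundary
value 0.3 is neutral. Loss calls are gated on positivity because shallow
losses in low-tumor-content samples are unreliable; the pipeline therefore
calls states in a second pass after classification. The median of the five
control values is the middle order statistic; an even count would use the
mean of the middle two, but the control set is fixed at five.

## Mutation filtering

Both callers' records are decomposed before intersection: equal-length
multi-nucleotide substitutions split into per-base SNVs at differing
positions (VAF and alt reads inherited — recomputation per base is not
possible without read-level data), shared prefix/suffix bases trimmed, and
indels left-aligned against a ±20 bp reference context carried in the
input schema (so no genome access is needed). The only universal prefilter
is ≥ 6 alternate-allele reads; per-caller internal thresholds are treated
as properties of the upstream callers and emulated by the generator.
Consensus requires an identical (chrom, pos, ref, alt) key in both sets,
ignoring genotype/ploidy; the consensus record carries the first caller's
numeric fields (configurable via `carry=`), mirroring the convention of
keeping one designated caller's measurements.

The pathogenicity filter keeps curated (Likely) Oncogenic variants, or
uncurated (Likely) Oncogenic variants without a splice-site/splice-region
consequence. The oncogenicity label of an uncurated variant comes from a
secondary annotation source; the schema holds it in the same
`oncogenicity` field with `oncokb_curated = FALSE`. A gene-specific ledger
removes known germline/non-pathogenic changes; the legacy symbol "KMTC2"
is mapped to KMT2C through a configurable synonym table. FOXA1 bypasses
the curation rules entirely (kept unless synonymous or one of three listed
substitutions) because curation coverage for its mCRPC-relevant variants
is sparse.

Germline/somatic classification is annotation-free: HSD3B1 variants are
always likely germline (its pathogenic allele is a common germline
polymorphism); variants in genes outside the six recurrent somatic drivers
(AR, TP53, PTEN, ERF, PIK3CA, CDK12) with VAF in the inclusive window
[0.45, 0.55] or strictly above 0.95 are likely germline. Window bounds are
inclusive ("between 0.45–0.55"), the upper tail strict. On synthetic data
with somatic VAFs at $f/2$ the rule recovers planted labels whenever
$f/2 < 0.45$.

## Breakend algebra and AR-GSR rules

All SVs are reduced to breakend pairs; each breakend records which flank
it retains. Orientations determine the type on one chromosome
(left/right = DEL, right/left = DUP, equal = INV); cross-chromosome events
are TRA. Cross-caller matching compares chromosome pairs and requires
*both* breakend distances ≤ 1000 bp; SV type and orientation are *not*
compared, since callers disagree on type more often than on position.
Merging is single-linkage (the pairwise comparison is naturally
transitive-closed); chaining is possible in principle, so cluster sizes
are logged (`n_members`) and the tolerance kept small. The cluster
representative is the member from the lexicographically smallest caller
ID, with read support aggregated as per-field maxima across members — the
aggregation is not specified upstream, and maxima match the intent of
"best supporting evidence". Within-caller duplicates are collapsed by
exact key first.

AR-GSR detection requires a breakend in the AR gene body (the gene-body
interval itself, no flank), ≥ 2 of 4 callers, and ≥ 3 split plus ≥ 3
discordant reads. The four LBD-truncation rules are interval predicates
over the AR exon model, evaluated 1→4 with the first match recorded (the
truncation flag itself is precedence-free). Conventions fixed here:
"breakpoint" means either breakend position; the span of a
same-chromosome event is the 0-based half-open interval between its
breakpoints; "fully overlaps" means span containment; cross-chromosome
events use only the AR-side breakend; rule 3's "flanking one or more of
exons 3–7" is read as the DUP span containing at least one whole exon in
that range; and rule 4's "retains the centromeric side" maps to
`retains_left` at the AR breakend, because AR is plus-strand on chrX with
exons 1–3 centromere-proximal. Rule 2 applies to DUP, INV and BND events.
A brute-force oracle enumerating (type × breakpoint-grid) placements over
a toy AR model with round-number coordinates verifies the classifier
exactly; the toy model (eight exons across 1000–8999, stop codon at 8900)
is the reference geometry for all rule tests. A genome-backed AR exon
model is user-supplied configuration via `load_panel()`; the package
deliberately ships no real-genome coordinates.

The ecDNA signature is ≥ 2 AR-GSRs plus AR gene-body gain
($\log_2 > 0.3$, strict) — a pattern of amplification with internal
rearrangement consistent with extrachromosomal circular amplicons.

## Classification and reporting

The aneuploidy threshold is the healthy-donor control mean plus three
sample standard deviations (n−1 denominator; with the printed control
moments either denominator reproduces 0.1421). Group 1 requires a
fraction *strictly* above the threshold; a sample exactly at threshold is
"at or below" and eligible for Group 2. The Group 2 trigger "likely
somatic SNV" means pathogenic *and* likely somatic, since only pathogenic
variants survive the filter. Percentages in reports round half away from
zero to whole percent, matching the printed style of the worked examples.

Survival uses the product-limit estimator via the survival package, with
the median as the smallest observed time with $S(t) \le 0.5$ (undefined if
never reached), events preceding censorings at ties, and log-log
confidence intervals. The log-rank test covers the overall comparison;
pairwise comparisons in three-group reports are BH-adjusted. Median
confidence intervals are reported but not part of any fixed check, since
they depend on the realized censoring pattern.

## Synthetic cohort generator

The generator is first-class, tested code and defines the study
conditions: 776 samples mixed 200/256/320 across Groups 1/2/3, eight
control assays at mean 0.0698 / SD 0.0241, planted amplifications (AR and
enhancer to 10 copies — an ecDNA-scale gain; MYC/MYCN to 6), single-copy
TSG losses, somatic VAFs at $f/2$ under diploid admixture with binomial
read sampling at 400× depth, germline VAFs near 0.5, per-caller SV jitter
uniform within ±500 bp (half the matching tolerance, so all
representations of one event stay within one cluster), per-caller
sensitivities of 0.95 (SNV) and 0.85 (SV), caller-private false positives
that can never reach consensus, cfDNA yields increasing with fraction,
and exponential survival with per-group medians 23/29/47 months under 20%
independent exponential censoring (medians chosen as round values near
the reported per-group survival). Where the source material gives no
value, these are one-time choices of what is realistic for this assay
class, not tuning knobs.

Two structural choices make planted labels recoverable by construction.
First, groups are planted *relative to the realized threshold*: controls
are drawn first, and Group 1 fractions are placed above, Groups 2/3 below,
the resulting mean + 3 SD. Second, samples carrying copy-number
alterations are drawn above the panel-of-normals cutoff (fraction ≥
0.055), keeping the depth reference alteration-free, and Group 2 fractions
sit above the minimal detectable fraction of at least one planted trigger
(e.g. $f > 0.2311/(\mathrm{CN_t}-1)$ for a chrX gain); when a planted
trigger is unreachable below the realized threshold, an AR-GSR (detectable
at any fraction) is added. With `noise_free = TRUE` every noise source is
zeroed and the pipeline recovers 100% of planted labels — the closed-loop
test. What passing these tests does *not* show: robustness to GC and
mappability bias, fragment-length effects, subclonal structure, clonal
hematopoiesis, caller-correlated errors, or panel-design artifacts — none
of which the generator emulates.

## Numerical conventions

Intervals are 0-based half-open internally (BED-native); point positions
(breakends, variant positions) are 1-based (VCF-native) and converted at
the interval boundary, so a breakend exactly at a half-open interval end
is outside. All threshold comparisons at 0.3/−0.3 and at the aneuploidy
threshold are strict; the germline VAF window is inclusive. Degenerate
inputs are named errors: missing control regions or depths, non-positive
control depths, an unbuildable panel of normals (< 2 eligible samples),
absent AR model, malformed breakend ALT strings, non-positive survival
times, sample-ID mismatches between classification and survival inputs.
Left-alignment stops silently at the context-window boundary rather than
guessing bases.

## Problem sizes

The test suite runs the closed loop at 80–1000 samples, the dilution
regression at 220–500 samples, the LBD oracle over ~20,000 grid
placements, consensus-merge oracles over ~200 jittered SVs, and log-rank
power/permutation checks at 400–1000 records; the full suite completes in
about a minute on one CPU, and `scripts/acceptance.R` (776 samples) in a
few seconds.

## Limitations

The package classifies; it does not estimate tumor fraction, deconvolve
clonal hematopoiesis, call copy number genome-wide, or fit
covariate-adjusted hazard models. The copy model ignores GC/mappability
correction (assumed handled upstream or absent in synthetic data). The
two- and four-caller consensus logic assumes within-caller deduplicated
inputs and treats caller identity as exchangeable beyond the
lexicographic representative choice. Whether cross-caller SV intersection
should also require matching SV types is left open upstream; positions
only is the more permissive reading and is what is implemented.
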