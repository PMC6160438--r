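---
title: "Models and methods behind TriPlatVal"
author: "TriPlatVal authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind TriPlatVal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TriPlatVal)
```

# Overview

TriPlatVal implements the analytical core of a clinical tumor-profiling
workflow that sequences each paired tumor/normal case on three platforms:
whole-genome (WGS), whole-exome (WES) and total-RNA sequencing. The premise
of such a workflow is that concordance *between* platforms can replace
orthogonal confirmatory testing: a somatic call supported independently by
two platforms is, for practical purposes, validated. Everything in the
package serves that idea — cross-platform validation of SNVs/indels,
Fisher-exact adjudication of capture-validation markers, tumor purity and
tumor-in-normal contamination estimation, detection-power modeling,
splice-aware linking of RNA fusions to DNA structural variants, driver
curation with pathogenicity tiering, and a synthetic generator that makes
the whole system testable without sequencing data.

All internal coordinates are 1-based inclusive; BED/BEDPE/refFlat inputs
are converted at the I/O boundary and converted back on write. Indels are
stored VCF-anchored (leading shared base). Every threshold is a named key
in `defaultConfig()`.

# Cross-platform validation

Candidate SNVs/indels arrive with per-platform tumor/normal read counts
and de novo detection flags. Where a platform did not call the variant,
counts are extracted by direct pileup interrogation (`tallyReadCounts`):
reads flagged as optical/PCR duplicates are excluded, as are bases below
quality 15 (inclusive floor); reads carrying a third allele count toward
depth only. A variant is cross-validated when any of four criteria holds
(`crossValidate`), evaluated 1→4 with the first match reported:

1. de novo detection by both WGS and WES;
2. detection by exactly one DNA platform, with ≥ 1 mutant tumor read and
   zero mutant normal reads on the other;
3. a high-quality call on one platform with a clean normal (zero mutant
   reads at ≥ 20X) on the other;
4. a high-quality call with ≥ 20X normal coverage on the detecting
   platform plus ≥ 1 mutant read in RNA tumor.

Precedence only affects the reported label; status is unchanged by order
because the criteria are combined by "any". Two readings deliberately
fixed here: "absent in normal" is a literal zero after tallying (a
tolerance would weaken the filter), and the ≥ 20X floor attaches to the
cross-validating platform's normal in criterion 3 but to the detecting
platform's normal in criterion 4 (closest-antecedent reading; both are
config keys). Variants that fail remain in the output as `UNCONFIRMED` —
final removal is a reporting choice, and the audit trail
(`attr(x, "audit")`) records every decision.

The caller-side support rule (`supportFilter`) requires ≥ 3 mutant reads
of quality ≥ 20 at the site and within a ±5 nt window, and ≥ 10 nt of
flanking sequence on at least one read. Whether the window constraint
applies per base or per read is not observable from the inputs this
package accepts; the default applies each read's minimum quality over the
window when that column is provided (`window_scope` config key).

# Capture-validation adjudication

Capture validation re-sequences candidate loci after targeted enrichment.
`assignValidationStatus` reproduces the adjudication cascade: counts are
tallied with a class-specific base-quality floor (15 for SNVs, 5 for
indels — indel base calls are systematically lower quality); zero mutant
reads at depth > 20 is `WILDTYPE` and at depth ≤ 20 `NOT_ASSESSABLE`; a
two-sided Fisher exact test then compares tumor and normal counts. Markers
with mutant normal reads and either p ≥ 0.05 or normal MAF ≥ 0.2 are
`GERMLINE`; markers with p ≤ 0.05 are `SOMATIC`, additionally requiring
tumor MAF > 0.05 when the normal carries mutant reads (tumor-in-normal
contamination would otherwise masquerade as significance) and ≥ 10 mutant
reads for homopolymer-context markers discovered by WES only (homopolymer
slippage artifacts). At the p = 0.05 boundary both germline and somatic
conditions are textually satisfiable; the germline rule fires first —
conservative for clinical reporting. Everything else lands in the
`NOT_ASSESSABLE` manual-review bucket. Expert adjustments are an explicit
override list (`adjudicateMarkers(..., overrides = )`), never silent
algorithm behavior.

The Fisher p-value is the standard conditional-hypergeometric two-sided
test (`stats::fisher.test` under the hood); the test suite verifies it
against an independent exhaustive enumeration for every table with
N ≤ 60, using the invariance of p under row/column swap and transpose to
reduce the enumeration.

Homopolymer context is not defined by the upstream workflow this models;
the package uses a mononucleotide run of ≥ 7 bp overlapping the site
(`homopolymer_run_length` config key).

# Tumor purity, contamination and subclone testing

For a germline-heterozygous SNV the LOH score is
$|AF_{tumor} - AF_{germline}|$. Exact copy bookkeeping over a mixture of
$x\%$ aberrant and $(100-x)\%$ diploid cells gives the expected score
$x/(400-2x)$ for single-copy loss and $x/(100(2-\mathrm{CNA}))$ for
copy-neutral LOH. A region's tumor fraction combines its LOH score $ai$
with the magnitude of copy decrease:
$$2\,ai + \frac{\mathrm{CNA}}{2}(1 - 2\,ai),$$
clamped to $[0,1]$. The copy-number term enters as a *magnitude* in
$[0,1]$: the signed convention (0 to −1) fails its own worked endpoints
(with $ai = 1/6$ and a half-clonal single-copy loss the region fraction
must be 0.5, which only the magnitude form yields), as the package's
copy-simulation tests demonstrate.

Region fractions from CNA/LOH regions are clustered with `mclust`
(BIC selection over 1–5 components) and the highest cluster center is the
CNV/LOH-based purity. Somatic MAFs restricted to diploid non-LOH regions
are clustered the same way; since a clonal heterozygous variant sits at
MAF = purity/2, the default transform doubles the center
(`mafTransform = "double"`); a strict-literal mode reports the raw center
for users who want the untransformed convention. The final purity is the
larger of the two available estimates. The germline allele fraction is
taken as observed rather than fixed at 0.5 (robust to mild germline
skew); a config flag restores the idealized value.

The fraction of cells carrying a variant follows from its MAF and ploidy
model: $2m$ for a heterozygous diploid site, $m$ under copy-neutral LOH
(both copies mutant), $2m/(1+m)$ hemizygous. Applied to pooled normal
counts at clonally somatic markers this yields the tumor-in-normal
contamination; fractions are reported unrounded. The probability that a
variant with expected mutant fraction $p$ leaves no trace in $n$ normal
reads is $(1-p)^n$ (`absenceProbability`) — the binomial test used to
decide whether a subclone is genuinely absent from a sample rather than
merely unobserved.

# Limits of detection

Under independent binomial read sampling, a platform at depth $d$ detects
a variant of allele fraction $f$ with probability
$P[\mathrm{Bin}(d,f) \ge k]$, computed with the binomial survival
function. The integrated two-platform rule — ≥ 3 mutant reads on one
platform (de novo detection) and ≥ 1 on the other (cross-validation
support) — has probability
$$P(A) + P(B) - P(a \ge 3)\,P(b \ge 3),$$
with $A$ and $B$ the two orientations. This rule was reconstructed from
the workflow's two published operating points (95.7% at 30x+100x and
99.1% at 45x+100x for $f = 0.1$), both of which it reproduces exactly; at
the achieved mean coverages 38x+110x it gives 98.2%. The reconstruction
matches the printed numbers but is not guaranteed to be the original
authors' exact procedure (their supplementary model may carry error or
mappability terms). Depth is treated as fixed by default; a Poisson-depth
mode (`empiricalPower(..., poissonDepth = TRUE)`) exists for sensitivity
analysis. Monte-Carlo resampling (`empiricalPower`) cross-checks the
closed form within binomial standard error.

# Linking RNA fusions to DNA structural variants

Splicing moves RNA fusion breakpoints away from the causal DNA junction,
so linking uses transcript-orientation intervals: the DNA breakpoint
assigned to the 5′ gene must lie in [RNA breakpoint, transcription end
site] and the 3′-gene breakpoint in [transcription start site, RNA
breakpoint], both ends inclusive and evaluated strand-aware ("downstream"
for a minus-strand gene means lower genomic coordinates). The SV
orientation must support the fusion product: under the convention that
`+` retains the lower-coordinate side of a breakpoint, the 5′-gene
breakpoint must retain the promoter-proximal segment and the 3′-gene
breakpoint the terminator-proximal one.

The pairwise rule alone can leave a fusion compatible with several SVs —
any junction in any upstream intron satisfies the 3′-side interval. The
assignment layer (`linkFusions`) therefore applies splice parsimony: each
fusion is assigned to the rule-satisfying SV minimizing the total
DNA–RNA breakpoint distance, because splicing joins the first available
exon boundary downstream of the causal junction. On the bundled
complex-amplification fixture (`makeGeneFixture("fig2")`: three fusion
isoforms into consecutive exons, one direct junction in the intron
between the first and second of those exons, one three-chromosome
junction further upstream at an amplicon boundary) this recovers the
expected pattern: the most proximal isoform links only to the upstream
junction, the distal isoforms to the direct one.

RNA junctions slightly outside the annotated gene are accommodated by a
config-keyed gene-body extension (default 5 kb), off in strict mode.
CNA-boundary matching (`matchSvToCna`) uses a 1 kb default tolerance —
segmentation boundary precision is typically sub-kb. `integrateEvents`
builds review events as connected components over three edge kinds:
rule-satisfying fusion–SV pairs, SV–CNA boundary matches, and shared-gene
membership; event identifiers are deterministic (members sorted, events
ordered by smallest member key).

# Driver curation and pathogenicity tiers

`curateDriverCatalog` filters a mutation catalog to experimentally
verified, genome-wide-screen records; drops sites carried by more than 10
of 6,500 non-cancer controls (germline polymorphisms); and removes
hypermutated samples — ≥ 100 coding variants *and* within the top 10%
most-mutated of their own study, operationalised as descending rank ≤
ceiling(0.10 × study size). Genes with a truncating-record fraction
≥ 0.3 become tumor suppressors; sites recurring in ≥ 3 samples become
oncogene hotspots. The 0.3 and 3 defaults are this package's choices —
the source workflow never quantifies "over-representation" — and both are
config keys.

`assignTier` applies first-match rules in the order Pathogenic → Likely
Pathogenic → Uncertain: hotspot mutations in known cancer genes from any
cancer type; truncations of tumor suppressors with a known role in the
case's cancer type; and recurrent SV/CNA classes used for molecular
diagnosis of that type are Pathogenic. Mutations in type-linked genes
with unclear impact, or clearly functional changes in cancer genes
without a type association, are Likely Pathogenic; unclear impact without
a type association is Uncertain. Expert override uses the same mechanism
as capture-validation overrides.

# Performance metrics

PPV is true predicted positives over predicted positives; sensitivity is
true positives over actual positives, with "rescue" variants (support
sufficient to cross-validate but not to detect) counted as false
negatives of the rescue platform alone, or pooled, per policy. Undefined
ratios surface as `NA`, never silently 0 or 1. Coverage QC passes a
germline DNA sample at ≥ 80% of coding exons with ≥ 20X de-duplicated
coverage and tumor RNA at ≥ 30%; all comparisons are inclusive
throughout the package (the source text mixes ≥ and > loosely; uniform
inclusivity is config-overridable). WGS↔WES copy-number concordance
declares a region detected in WES when an overlapping WES segment shows a
log2 shift ≥ 0.2 in magnitude with the expected sign, with a relaxed
0.1 threshold available for sensitivity checks.

# The synthetic generator

`simulateMultiplatformSample` draws a full fixture bundle from a declared
truth (`sampleTruth`): per variant, the expected mutant fraction follows
the same allele-copy arithmetic as the purity module (tumor:
purity × subclone fraction; normal: contamination × subclone fraction),
then counts are drawn binomially. Study conditions are the defaults:
purity 0.81 (the emulated cohort's average; tests sweep 0.2–1.0), tumor
depths 38X WGS / 110X WES / 30X RNA and normal depths 36X / 103X (the
achieved means), no contamination unless requested. Per-site depths are
Poisson around the platform mean — real coverage is never uniform, and a
fixed depth would place every MAF on a lattice of multiples of 1/depth,
which model-based clustering over-fits with spurious narrow components.
The default truth carries 200 clonal diploid somatic SNVs (a realistic
genome-wide yield for a mutationally quiet pediatric tumor, and the data
scale the clustering step is meant for) and four multi-megabase CNA/LOH
regions with 500 germline-het SNPs each (~1 per several kb). Segment LOH
scores are phase-aware region averages, as an upstream segmentation tool
would report; the per-site AF table is also emitted. Random draws are
keyed per (site, platform, seed), so editing one site never perturbs
another fixture site.

What the generator does **not** emulate: sequencing error (off by
default, matching the detection models; a per-base rate is available),
mapping artifacts, GC waviness, subclonal copy-number architecture, or
read-level data. Passing tests therefore demonstrate correctness of the
statistical machinery under its stated model, not robustness to
alignment-level artifacts.

`simulateCapvalExperiment` draws capture counts for markers of known
status (somatic at a true MAF, germline at 0.5/0.5, wildtype at zero
mutant reads), enabling exact confusion-matrix comparisons between
adjudicated and true statuses.

# Numerical and testing choices

Problem sizes in the shipped tests: the cross-validation classifier is
verified against an independently coded decision table over its full
2,304-case enumeration grid; Fisher adjudication against exhaustive
enumeration for all tables N ≤ 60 (symmetry-reduced); purity recovery
over 20 synthetic samples spanning purity 0.2–1.0 at the default depths,
requiring |estimate − truth| ≤ 0.05 in ≥ 90% of samples; Monte-Carlo
power at 10^4–10^5 iterations against the closed form within three
standard errors. Degenerate inputs are handled explicitly: zero-depth
MAFs are `NA`, empty mixture inputs and unknown cancer types are errors,
single-point mixtures return the point, all fractions are clamped to
[0, 1], and CNA-boundary ties are returned sorted by distance then
coordinate.

# Known limitations

The quality tier ("high"/"low") of a call is accepted as input — the
upstream definition is caller-specific and not reproduced here. The
detection-power rule is a reconstruction (see above). The purity
estimator inherits mclust's behavior on small inputs (fewer than ~5
regions fall back to the highest value). Linking operates on gene-side
breakpoints only; intermediate segments of multi-chromosome SVs are
carried as annotations, not modeled. PPV/sensitivity of the original
cohort are not reproducible without the sequencing data; the metrics
module reproduces the ratio arithmetic and is validated on synthetic
experiments where truth is known exactly.
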