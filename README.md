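# TriPlatVal

Cross-platform validation and integrative analysis of somatic variants
from three-platform tumor sequencing.

Clinical tumor profiling increasingly sequences each paired tumor/normal
case on three platforms — whole genome (WGS), whole exome (WES) and total
RNA — so that concordance *between* platforms replaces orthogonal
confirmatory testing. TriPlatVal implements the analytical core of such a
workflow for clinical bioinformaticians and methods developers:

- **Cross-platform validation** of SNVs/indels under a four-criteria
  concordance rule, with pileup read tallying (duplicate exclusion, base
  quality ≥ 15) for platforms that did not call the variant de novo.
- **Capture-validation adjudication**: a two-sided Fisher exact test on
  tumor/normal counts feeding a rule cascade that assigns
  WILDTYPE / SOMATIC / GERMLINE / NOT_ASSESSABLE.
- **Tumor purity** from LOH scores and copy-number segments. For a
  germline-het SNV, LOH score = |AF<sub>tumor</sub> −
  AF<sub>germline</sub>|; a region with LOH score *ai* and copy-number
  decrease CNA has tumor fraction 2·*ai* + (CNA/2)(1 − 2·*ai*). Region
  fractions and somatic MAFs are clustered with `mclust`, and the final
  purity is the larger of the CNV/LOH- and MAF-based estimates.
- **Tumor-in-normal contamination** and a binomial absence test
  (1 − p)<sup>n</sup> for subclone structure.
- **Limits of detection**: P(detect) = P[Bin(d, f) ≥ 3] per platform;
  integrated two-platform power P(A) + P(B) − P(a≥3)P(b≥3) under the rule
  "≥ 3 mutant reads on one platform and ≥ 1 on the other".
- **DNA–RNA structural variant linking**: splice-aware,
  transcript-orientation interval rules with breakpoint-orientation
  checks, CNA-boundary matching and connected-component review events.
- **Driver curation and pathogenicity tiers** (P / LP / UNCERTAIN) as a
  first-match rule engine.
- **A synthetic multi-platform generator** with exact allele-copy truth,
  so every module is testable without sequencing data.

## Worked example

An internal tandem duplication sits under chromosome-arm LOH: 96 mutant
of 120 reads in tumor WGS, zero mutant reads among 121 in the normal.
WES did not call it de novo but carries supporting reads.

```r
library(TriPlatVal)

v <- VariantCall(GenomicSite("chr13", 28608262, "T", "TGGA"), "ITD",
  evidence = list(
    WGS = PlatformEvidence(ReadCounts(96, 24), ReadCounts(0, 121, 121),
                           detected = TRUE, quality = "high"),
    WES = PlatformEvidence(ReadCounts(40, 60), ReadCounts(0, 103, 103),
                           detected = FALSE)))
crossValidate(v)
#> $status
#> [1] "CROSS_VALIDATED"
#> $criterion
#> [1] 2
#> $supportingPlatform
#> [1] "WES"

cellFraction(96/120, "CN_LOH")          # fraction of tumor cells with the ITD
#> [1] 0.8
absenceProbability(121, 0.077 * 0.80)   # zero reads in a 7.7%-contaminated normal?
#> [1] 0.00046
integratedDetectProb(30, 100, 0.1)      # two-platform power at VAF 0.1
#> [1] 0.957
```

The variant cross-validates by criterion 2 (tumor support, clean normal,
on the other platform). 80% of tumor cells carry the ITD (both copies
mutant under LOH, so cell fraction = MAF); if the normal sample contained
7.7% tumor cells all carrying it, seeing zero mutant reads in 121 would
have probability 0.00046 — so the subclone is genuinely absent from the
normal, not merely missed.

End to end on synthetic data with known truth:

```r
b <- simulateMultiplatformSample(sampleTruth(purity = 0.6), seed = 7)
recoverPurity(b, seed = 7)
#> PurityEstimate cnvLoh=0.609 maf=0.587 final=0.609
```

A command-line front end over the same functions is installed at
`inst/cli/triplatval.R` with subcommands `crossval`, `capval`, `purity`,
`power`, `svlink`, `classify`, `metrics` and `simulate`.

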