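## Shared builders for tests. All fixtures are generated in code.

evd <- function(tumorMut = 0, tumorTot = 0, normMut = 0, normTot = 0,
                detected = FALSE, quality = NULL) {
    PlatformEvidence(ReadCounts(tumorMut, tumorTot - tumorMut, tumorTot),
                     ReadCounts(normMut, normTot - normMut, normTot),
                     detected = detected, quality = quality)
}

makeCall <- function(wgs = evd(), wes = evd(), rna = evd()) {
    VariantCall(GenomicSite("chr1", 1000, "A", "T"),
                evidence = list(WGS = wgs, WES = wes, RNA = rna))
}

makeRecord <- function(tumorMut, tumorTot, normMut = 0, normTot = 0,
                       variantClass = "SNV", discoveredBy = character(),
                       homopolymer = FALSE) {
    ValidationRecord(GenomicSite("chr1", 500, "A", "G"),
                     tumor = ReadCounts(tumorMut, tumorTot - tumorMut,
                                        tumorTot),
                     normal = ReadCounts(normMut, normTot - normMut,
                                         normTot),
                     variantClass = variantClass,
                     discoveredBy = discoveredBy,
                     homopolymer = homopolymer)
}

## Independent enumeration oracle for the two-sided Fisher exact test:
## sums hypergeometric probabilities of all tables with the observed
## margins whose probability does not exceed the observed table's.
fisherOracle <- function(a, b, c, d) {
    r1 <- a + b; c1 <- a + c; n <- a + b + c + d
    if (n == 0) return(1)
    ks <- max(0, c1 - (n - r1)):min(r1, c1)
    probs <- dhyper(ks, r1, n - r1, c1)
    pObs <- dhyper(a, r1, n - r1, c1)
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

## Independent brute-force implementation of the four cross-validation
## criteria, coded directly from the rule statements (no shared helpers
## with the package implementation).
crossValOracle <- function(det, qual, tumorMut, normMut, normTot,
                           rnaTumorMut, minNormalDepth = 20) {
    ## det/qual/...: named per-platform vectors (WGS, WES)
    if (!any(c(det["WGS"], det["WES"], FALSE)))
        if (rnaTumorMut < 0) stop("unused")  # never reached
    if (det[["WGS"]] && det[["WES"]]) return(1L)
    oneOf <- xor(det[["WGS"]], det[["WES"]])
    if (oneOf) {
        p <- if (det[["WGS"]]) "WGS" else "WES"
        o <- if (p == "WGS") "WES" else "WGS"
        if (tumorMut[[o]] >= 1 && normMut[[o]] == 0) return(2L)
        if (qual[[p]] == "high" && normMut[[o]] == 0 &&
            normTot[[o]] >= minNormalDepth) return(3L)
        if (qual[[p]] == "high" && normTot[[p]] >= minNormalDepth &&
            rnaTumorMut >= 1) return(4L)
    }
    NA_integer_
}
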