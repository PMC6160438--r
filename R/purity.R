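#' @include AllClasses.R
NULL

#' LOH score of a germline-heterozygous site
#'
#' The absolute difference between the tumor and germline allele fractions.
#' A site in a region of clonal single-copy loss at 100\% tumor purity has
#' tumor allele fraction 1 for the retained allele and scores 0.5.
#'
#' @param tumorAf,germlineAf Allele fractions in [0, 1].
#' @return Score in [0, 0.5] for germline-heterozygous input.
#' @examples
#' lohScore(1.0, 0.5)  # 0.5
#' @export
lohScore <- function(tumorAf, germlineAf) {
    if (any(tumorAf < 0 | tumorAf > 1) || any(germlineAf < 0 | germlineAf > 1))
        stop("allele fractions must lie in [0, 1]")
    abs(tumorAf - germlineAf)
}

#' Expected LOH score for a given tumor-cell percentage
#'
#' Closed forms for the expected LOH score when x\% of cells carry the
#' aberration, derived from allele-copy bookkeeping over a mixture of
#' aberrant and diploid-heterozygous cells:
#' single-copy loss gives \code{x / (400 - 2x)}; copy-neutral LOH (and more
#' generally LOH over a region whose average copy-number decrease is
#' \code{cna} copies) gives \code{x / (100 * (2 - cna))}.
#'
#' @param x Percentage of cells carrying the aberration, in [0, 100].
#' @param mode \code{"LOSS"} or \code{"CN_LOH"}.
#' @param cna Copy-number decrease in copies used by the CN-LOH form
#'   (0 for pure copy-neutral LOH); ignored for \code{"LOSS"}.
#' @return Expected LOH score.
#' @examples
#' expectedLoh(100, "LOSS")       # 0.5
#' expectedLoh(50, "LOSS")        # 1/6
#' expectedLoh(100, "CN_LOH", 0)  # 0.5
#' @export
expectedLoh <- function(x, mode = c("LOSS", "CN_LOH"), cna = 0) {
    mode <- match.arg(mode)
    if (any(x < 0 | x > 100))
        stop("'x' must lie in [0, 100] percent")
    switch(mode,
           LOSS = x / (400 - 2 * x),
           CN_LOH = x / (100 * (2 - cna)))
}

#' Tumor fraction of a CNA/LOH region
#'
#' Combines the LOH score \code{ai} of a region with the magnitude of its
#' copy-number decrease into the fraction of tumor cells in the region:
#' \code{2*ai + (cnaMag/2) * (1 - 2*ai)}, clamped to [0, 1]. \code{cnaMag}
#' is the magnitude of decrease in copies (0 for copy-neutral LOH, 1 for
#' clonal single-copy loss); the formula is exact for mixtures of
#' single-copy-loss and CN-LOH cells against a diploid background.
#'
#' @param ai Region LOH score in [0, 0.5].
#' @param cnaMag Copy-number decrease magnitude in [0, 1].
#' @return Tumor fraction in [0, 1].
#' @examples
#' regionTumorFraction(0.5, 1)     # 1: clonal loss in a pure tumor
#' regionTumorFraction(0.25, 0)    # 0.5: CN-LOH in half the cells
#' regionTumorFraction(1/6, 0.5)   # 0.5: single-copy loss in half the cells
#' @export
regionTumorFraction <- function(ai, cnaMag) {
    if (any(ai < 0 | ai > 0.5)) stop("'ai' must lie in [0, 0.5]")
    if (any(cnaMag < 0 | cnaMag > 1)) stop("'cnaMag' must lie in [0, 1]")
    pmin(1, pmax(0, 2 * ai + (cnaMag / 2) * (1 - 2 * ai)))
}

#' Highest Gaussian-mixture cluster center
#'
#' Fits univariate Gaussian mixtures with 1..\code{maxComponents}
#' components by model-based clustering (mclust), selects the model by BIC
#' and returns the largest component mean. Degenerate inputs (a single
#' value, or all values identical) return that value directly.
#'
#' @param values Numeric vector of fractions (at least one value).
#' @param maxComponents Maximum number of mixture components (default 5).
#' @param seed Optional integer seed for reproducible fitting.
#' @return The highest cluster center.
#' @importFrom mclust Mclust mclustBIC
#' @importFrom stats sd
#' @export
mixtureModeEstimate <- function(values, maxComponents = 5L, seed = NULL) {
    if (!length(values)) stop("'values' must contain at least one value")
    if (length(values) == 1L || sd(values) == 0) return(values[1L])
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", globalenv()))
            get(".Random.seed", globalenv()) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
        set.seed(seed)
    }
    fit <- Mclust(values, G = seq_len(maxComponents), verbose = FALSE)
    if (is.null(fit)) return(max(values))
    max(fit$parameters$mean)
}

#' Estimate sample tumor purity
#'
#' Two component estimates are combined: the CNV/LOH-based purity is the
#' highest mixture cluster center of per-region tumor fractions
#' (\code{\link{regionTumorFraction}} over CNA/LOH regions); the MAF-based
#' purity is derived from the highest cluster center of somatic mutant
#' allele fractions restricted to diploid non-LOH regions. For heterozygous
#' variants in such regions a fully clonal mutation sits at MAF = purity/2,
#' so the default transform doubles the center
#' (\code{mafTransform = "double"}); \code{"literal"} reports the raw
#' center. The final purity is the larger of the two available estimates.
#'
#' @param regionFractions Numeric vector of per-region tumor fractions
#'   (may be empty).
#' @param somaticDiploidMafs Numeric vector of somatic MAFs in diploid
#'   non-LOH regions (may be empty).
#' @param maxComponents,seed Passed to \code{\link{mixtureModeEstimate}}.
#' @param mafTransform \code{"double"} (default) or \code{"literal"}.
#' @return A \linkS4class{PurityEstimate}.
#' @export
estimateSamplePurity <- function(regionFractions = numeric(),
                                 somaticDiploidMafs = numeric(),
                                 maxComponents = 5L, seed = NULL,
                                 mafTransform = c("double", "literal")) {
    mafTransform <- match.arg(mafTransform)
    if (!length(regionFractions) && !length(somaticDiploidMafs))
        stop("both inputs empty: need region fractions and/or somatic MAFs")
    cnvLoh <- if (length(regionFractions))
        min(1, max(0, mixtureModeEstimate(regionFractions, maxComponents,
                                          seed)))
    else NA_real_
    mafP <- if (length(somaticDiploidMafs)) {
        center <- mixtureModeEstimate(somaticDiploidMafs, maxComponents, seed)
        if (mafTransform == "double") center <- 2 * center
        min(1, max(0, center))
    } else NA_real_
    new("PurityEstimate", cnvLohPurity = cnvLoh, mafPurity = mafP,
        final = max(c(cnvLoh, mafP), na.rm = TRUE))
}

#' Fraction of cells carrying a variant
#'
#' Converts a mutant allele fraction to the fraction of cells carrying the
#' variant under a ploidy model: heterozygous diploid (one mutant of two
#' copies) gives \code{2*maf}; copy-neutral LOH (both copies mutant) gives
#' \code{maf}; hemizygous (one mutant copy, one copy total in carriers, two
#' in non-carriers) gives \code{2*maf / (1 + maf)}. Clamped to [0, 1].
#'
#' @param maf Mutant allele fraction in [0, 1].
#' @param model One of \code{"HETEROZYGOUS_DIPLOID"}, \code{"CN_LOH"},
#'   \code{"HEMIZYGOUS"}.
#' @return Cell fraction in [0, 1].
#' @examples
#' cellFraction(15/34, "HETEROZYGOUS_DIPLOID")  # 0.88
#' cellFraction(96/120, "CN_LOH")               # 0.80
#' @export
cellFraction <- function(maf,
                         model = c("HETEROZYGOUS_DIPLOID", "CN_LOH",
                                   "HEMIZYGOUS")) {
    model <- match.arg(model)
    if (any(maf < 0 | maf > 1)) stop("'maf' must lie in [0, 1]")
    f <- switch(model,
                HETEROZYGOUS_DIPLOID = 2 * maf,
                CN_LOH = maf,
                HEMIZYGOUS = 2 * maf / (1 + maf))
    pmin(1, pmax(0, f))
}

#' Tumor-in-normal contamination estimate
#'
#' Fraction of tumor cells in the normal sample, from pooled normal-sample
#' read counts at markers believed clonal in the tumor:
#' \code{\link{cellFraction}} applied to the pooled normal MAF.
#'
#' @param normalMutant,normalTotal Pooled mutant and total read counts in
#'   the normal sample at clonal somatic markers.
#' @param model Ploidy model, as \code{\link{cellFraction}}.
#' @return Contamination fraction in [0, 1].
#' @examples
#' contaminationEstimate(4, 103)  # about 0.078
#' @export
contaminationEstimate <- function(normalMutant, normalTotal,
                                  model = "HETEROZYGOUS_DIPLOID") {
    if (normalTotal <= 0) stop("zero depth: cannot estimate contamination")
    cellFraction(normalMutant / normalTotal, model)
}

#' Probability of observing zero mutant reads
#'
#' The binomial probability of drawing no mutant reads in \code{depth}
#' independent reads when each read is mutant with probability \code{p}:
#' \code{(1 - p)^depth}. Used to test whether a variant's absence from a
#' sample is compatible with its expected mutant fraction.
#'
#' @param depth Read depth (>= 0).
#' @param p Expected mutant read fraction in [0, 1].
#' @return Probability in [0, 1].
#' @examples
#' absenceProbability(121, 0.077 * 0.80)  # about 0.00046
#' @export
absenceProbability <- function(depth, p) {
    if (depth < 0) stop("'depth' must be >= 0")
    if (any(p < 0 | p > 1)) stop("'p' must lie in [0, 1]")
    (1 - p)^depth
}

#' Per-region purity report
#'
#' Convenience wrapper: computes region tumor fractions from LOH segments
#' (with matched copy-number decrease magnitudes) and somatic MAFs, then
#' estimates sample purity.
#'
#' @param lohScores Numeric vector of region LOH scores (ai).
#' @param cnaMags Matching copy-number decrease magnitudes in [0, 1].
#' @param somaticDiploidMafs Somatic MAFs from diploid non-LOH regions.
#' @param ... Passed to \code{\link{estimateSamplePurity}}.
#' @return A \linkS4class{PurityEstimate}.
#' @export
purityFromSegments <- function(lohScores, cnaMags,
                               somaticDiploidMafs = numeric(), ...) {
    stopifnot(length(lohScores) == length(cnaMags))
    fractions <- regionTumorFraction(lohScores, cnaMags)
    estimateSamplePurity(fractions, somaticDiploidMafs, ...)
}
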