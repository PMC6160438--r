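#' @include AllClasses.R
NULL

#' Single-platform detection probability
#'
#' Probability that a platform sequencing to \code{depth} reads yields at
#' least \code{minReads} mutant reads for a variant at allele fraction
#' \code{vaf}, under independent binomial read sampling:
#' \code{P[Binomial(depth, vaf) >= minReads]}, evaluated with the
#' numerically stable binomial survival function.
#'
#' @param depth Read depth (>= 0).
#' @param vaf Variant allele fraction in [0, 1].
#' @param minReads Detection threshold in mutant reads (default 3).
#' @return Probability in [0, 1].
#' @examples
#' platformDetectProb(30, 0.1, 3)   # 0.5886
#' platformDetectProb(100, 0.1, 3)  # 0.9981
#' @importFrom stats pbinom
#' @export
platformDetectProb <- function(depth, vaf, minReads = 3L) {
    if (any(vaf < 0 | vaf > 1)) stop("'vaf' must lie in [0, 1]")
    if (any(depth < 0)) stop("'depth' must be >= 0")
    if (minReads <= 0) return(rep(1, length.out = max(length(depth),
                                                      length(vaf))))
    pbinom(minReads - 1, size = depth, prob = vaf, lower.tail = FALSE)
}

#' Integrated cross-platform detection probability
#'
#' Probability that a variant is detected by the two-platform rule: at
#' least \code{minDetect} mutant reads on one platform (de novo detection)
#' and at least \code{minSupport} mutant reads on the other
#' (cross-validation support), with platforms sampling reads independently.
#' Computed as \code{P(A) + P(B) - P(a >= minDetect) * P(b >= minDetect)}
#' where \code{A}/\code{B} are the two orientations of the rule.
#'
#' @param depthA,depthB Read depths of the two platforms.
#' @param vaf Variant allele fraction in [0, 1].
#' @param minDetect Mutant reads required for de novo detection (default 3).
#' @param minSupport Mutant reads required for cross-platform support
#'   (default 1).
#' @return Probability in [0, 1].
#' @examples
#' integratedDetectProb(30, 100, 0.1)   # 0.9569 -> 95.7%
#' integratedDetectProb(45, 100, 0.1)   # 0.9910 -> 99.1%
#' @export
integratedDetectProb <- function(depthA, depthB, vaf, minDetect = 3L,
                                 minSupport = 1L) {
    pa_d <- platformDetectProb(depthA, vaf, minDetect)
    pb_d <- platformDetectProb(depthB, vaf, minDetect)
    pa_s <- platformDetectProb(depthA, vaf, minSupport)
    pb_s <- platformDetectProb(depthB, vaf, minSupport)
    pa_d * pb_s + pb_d * pa_s - pa_d * pb_d
}

#' Monte-Carlo detection power
#'
#' In silico resampling of the integrated detection rule: mutant read
#' counts are drawn per platform from Binomial(depth, vaf) and the fraction
#' of iterations satisfying the rule is reported with its standard error.
#' Optionally depths themselves are drawn Poisson around their means
#' (sensitivity analysis; off by default, matching the closed form).
#'
#' @param depthA,depthB Platform read depths (means in Poisson mode).
#' @param vaf Variant allele fraction.
#' @param minDetect,minSupport Detection rule thresholds.
#' @param nIter Number of Monte-Carlo iterations.
#' @param seed Integer seed for reproducibility.
#' @param poissonDepth Draw depths Poisson(depth) per iteration.
#' @return List with \code{estimate}, \code{se} and \code{nIter}.
#' @importFrom stats rbinom rpois
#' @export
empiricalPower <- function(depthA, depthB, vaf, minDetect = 3L,
                           minSupport = 1L, nIter = 1e5L, seed = NULL,
                           poissonDepth = FALSE) {
    stopifnot(nIter >= 1)
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", globalenv()))
            get(".Random.seed", globalenv()) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
        set.seed(seed)
    }
    da <- if (poissonDepth) rpois(nIter, depthA) else rep(depthA, nIter)
    db <- if (poissonDepth) rpois(nIter, depthB) else rep(depthB, nIter)
    a <- rbinom(nIter, da, vaf)
    b <- rbinom(nIter, db, vaf)
    hit <- (a >= minDetect & b >= minSupport) |
           (b >= minDetect & a >= minSupport)
    est <- mean(hit)
    list(estimate = est, se = sqrt(est * (1 - est) / nIter), nIter = nIter)
}

#' Limit-of-detection curve
#'
#' Integrated detection probability over a grid of allele fractions at
#' fixed platform depths.
#'
#' @param depthA,depthB Platform read depths.
#' @param vafGrid Allele fractions to evaluate (default 0.01..0.5).
#' @param minDetect,minSupport Detection rule thresholds.
#' @return data.frame with columns vaf, power.
#' @export
detectionPowerCurve <- function(depthA, depthB,
                                vafGrid = seq(0.01, 0.5, by = 0.01),
                                minDetect = 3L, minSupport = 1L) {
    data.frame(vaf = vafGrid,
               power = vapply(vafGrid, function(v)
                   integratedDetectProb(depthA, depthB, v, minDetect,
                                        minSupport), numeric(1)))
}
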