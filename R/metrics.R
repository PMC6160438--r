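#' @include AllClasses.R
NULL

#' Positive predictive value
#'
#' True predicted positives divided by total predicted positives. With no
#' predicted positives the ratio is undefined and NA is returned (never 0).
#'
#' @param truePositive,predictedPositive Counts.
#' @return Fraction, or NA when undefined.
#' @examples
#' computePpv(83, 84)  # 0.988
#' @export
computePpv <- function(truePositive, predictedPositive) {
    stopifnot(truePositive >= 0, predictedPositive >= 0,
              truePositive <= predictedPositive)
    if (predictedPositive == 0) return(NA_real_)
    truePositive / predictedPositive
}

#' Sensitivity with rescue semantics
#'
#' True positives divided by actual positives. A variant not detected, or
#' detected but removed by cross-validation filtering, counts as a false
#' negative. Rescue variants (support on a platform sufficient for
#' cross-validation but not for de novo detection) are counted as false
#' negatives in the rescue platform alone
#' (\code{rescuePolicy = "count_rescue_as_fn_in_platform"}) or as true
#' positives of the pooled test (\code{"pooled"}).
#'
#' @param truePositive,actualPositive Counts (excluding rescue).
#' @param rescueCount Number of rescue variants (default 0).
#' @param rescuePolicy \code{"count_rescue_as_fn_in_platform"} (default) or
#'   \code{"pooled"}.
#' @return Fraction, or NA when there are no actual positives.
#' @examples
#' computeSensitivity(83, 88)  # 0.943
#' @export
computeSensitivity <- function(truePositive, actualPositive,
                               rescueCount = 0L,
                               rescuePolicy = c(
                                   "count_rescue_as_fn_in_platform",
                                   "pooled")) {
    rescuePolicy <- match.arg(rescuePolicy)
    stopifnot(truePositive >= 0, actualPositive >= 0, rescueCount >= 0)
    tp <- truePositive
    ap <- actualPositive
    if (rescuePolicy == "pooled") tp <- tp + rescueCount
    if (rescuePolicy == "count_rescue_as_fn_in_platform")
        ap <- ap + rescueCount
    if (ap == 0) return(NA_real_)
    min(1, tp / ap)
}

#' Coverage quality control
#'
#' Pass/fail per sample from the fraction of coding exons reaching the
#' depth floor in a de-duplicated alignment. Germline DNA (WGS or WES)
#' requires at least 80\% of coding exons at >= 20X; tumor total RNA
#' requires at least 30\% of exons at >= 20X. Comparisons are inclusive.
#'
#' @param exonFraction Fraction of exons at or above the depth floor.
#' @param platform \code{"germline_wgs"}, \code{"germline_wes"} or
#'   \code{"rna"}.
#' @param thresholds Named list with \code{germline_exon_fraction} (0.80)
#'   and \code{rna_exon_fraction} (0.30).
#' @return List with \code{pass}, \code{metric} (the fraction) and
#'   \code{threshold}.
#' @export
coverageQc <- function(exonFraction,
                       platform = c("germline_wgs", "germline_wes", "rna"),
                       thresholds = defaultConfig()$metrics) {
    platform <- match.arg(platform)
    stopifnot(exonFraction >= 0, exonFraction <= 1)
    thr <- if (platform == "rna") thresholds$rna_exon_fraction
           else thresholds$germline_exon_fraction
    list(pass = exonFraction >= thr, metric = exonFraction, threshold = thr)
}

#' WGS/WES copy-number concordance over regions of interest
#'
#' For each region (carrying its expected direction, "gain" or "loss", from
#' the WGS truth), the region counts as detected in WES when some
#' overlapping WES segment shows a log2 shift of at least
#' \code{log2Threshold} in magnitude with the matching sign. Direction
#' consistency compares the sign of the strongest overlapping WES segment
#' against the expected direction.
#'
#' @param wesSegments \link[GenomicRanges]{GRanges} with metadata column
#'   \code{log2Ratio}.
#' @param regions \link[GenomicRanges]{GRanges} with metadata column
#'   \code{direction} ("gain" or "loss").
#' @param log2Threshold Magnitude threshold (default 0.2).
#' @return data.frame with one row per region: region, direction,
#'   detected_in_wes, direction_consistent, best_log2 (NA when no overlap).
#' @importFrom GenomicRanges findOverlaps mcols
#' @importFrom S4Vectors queryHits subjectHits
#' @export
wesCnaConcordance <- function(wesSegments, regions, log2Threshold = 0.2) {
    hits <- findOverlaps(regions, wesSegments)
    rows <- lapply(seq_along(regions), function(i) {
        dir <- mcols(regions)$direction[i]
        segIdx <- subjectHits(hits)[queryHits(hits) == i]
        l2 <- mcols(wesSegments)$log2Ratio[segIdx]
        best <- if (length(l2)) l2[which.max(abs(l2))] else NA_real_
        wantSign <- if (dir == "gain") 1 else -1
        detected <- length(l2) > 0 &&
            any(abs(l2) >= log2Threshold & sign(l2) == wantSign)
        consistent <- !is.na(best) && sign(best) == wantSign
        data.frame(region = i, direction = dir, detected_in_wes = detected,
                   direction_consistent = consistent, best_log2 = best,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
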