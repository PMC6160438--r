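#' @include AllClasses.R
NULL

#' Tally read counts from per-read observations
#'
#' Implements the "matrix" read-count extraction used to interrogate a
#' platform that did not detect a variant de novo: reads flagged as
#' optical/PCR duplicates are excluded, as are reads whose base quality at
#' the queried site falls below the floor (default 15, inclusive). Reads
#' carrying a third allele count toward depth but toward neither mutant nor
#' reference.
#'
#' @param observations data.frame with columns \code{allele} (one of
#'   "mutant", "reference", "other"), \code{baseQuality} (integer >= 0) and
#'   \code{duplicate} (logical). Extra columns are ignored.
#' @param minBaseQuality Inclusive base-quality floor (default 15).
#' @return A \linkS4class{ReadCounts}.
#' @examples
#' obs <- data.frame(allele = c("mutant", "reference", "reference"),
#'                   baseQuality = 30, duplicate = FALSE)
#' tallyReadCounts(obs)
#' @export
tallyReadCounts <- function(observations, minBaseQuality = 15L) {
    stopifnot(is.data.frame(observations))
    if (!nrow(observations)) return(ReadCounts())
    need <- c("allele", "baseQuality", "duplicate")
    missing <- setdiff(need, names(observations))
    if (length(missing))
        stop("observations missing column(s): ",
             paste(missing, collapse = ", "))
    if (any(observations$baseQuality < 0))
        stop("negative base quality in observations")
    keep <- !observations$duplicate &
        observations$baseQuality >= minBaseQuality
    a <- observations$allele[keep]
    ReadCounts(mutant = sum(a == "mutant"),
               reference = sum(a == "reference"),
               total = length(a))
}

#' Variant call-support quality filter
#'
#' The caller-side support rule: at least \code{minSupporting} mutant reads
#' with read quality at or above \code{minReadQuality} at the variant site
#' and within a +/- \code{window} nucleotide window, and at least one mutant
#' read with \code{minFlank} or more nucleotides of flanking sequence on its
#' shorter side.
#'
#' The window-quality requirement is applied to each read's minimum quality
#' over the window when a \code{windowMinQuality} column is supplied
#' (\code{windowScope = "site_and_window"}, the default) and to the site
#' base alone otherwise.
#'
#' @param tumorObservations data.frame of mutant-supporting reads with
#'   columns \code{readQuality} and \code{flankLength}; optional
#'   \code{windowMinQuality}.
#' @param minSupporting Minimum supporting read count (default 3).
#' @param minReadQuality Inclusive read-quality floor (default 20).
#' @param minFlank Minimum flank length in nt (default 10).
#' @param windowScope \code{"site_and_window"} or \code{"site_only"}.
#' @return List with \code{pass} (logical) and \code{reason} ("" on pass,
#'   else "no support", "count" or "flank").
#' @export
supportFilter <- function(tumorObservations, minSupporting = 3L,
                          minReadQuality = 20L, minFlank = 10L,
                          windowScope = c("site_and_window", "site_only")) {
    windowScope <- match.arg(windowScope)
    obs <- tumorObservations
    if (is.null(obs) || !nrow(obs))
        return(list(pass = FALSE, reason = "no support"))
    q <- obs$readQuality
    if (windowScope == "site_and_window" && "windowMinQuality" %in% names(obs))
        q <- pmin(q, obs$windowMinQuality)
    supporting <- sum(q >= minReadQuality)
    if (supporting < minSupporting)
        return(list(pass = FALSE, reason = "count"))
    if (!any(obs$flankLength >= minFlank))
        return(list(pass = FALSE, reason = "flank"))
    list(pass = TRUE, reason = "")
}

#' Four-criteria cross-platform validation
#'
#' A variant is cross-validated when any of four criteria holds, evaluated
#' in order with the first match reported:
#' \enumerate{
#'   \item de novo detection by both WGS and WES;
#'   \item de novo detection by exactly one of WGS/WES, with at least one
#'     mutant read in the other platform's tumor and none in its normal;
#'   \item de novo detection by one platform at high quality, with no mutant
#'     reads in the other platform's normal at depth >= \code{minNormalDepth};
#'   \item de novo detection by one platform at high quality with normal
#'     depth >= \code{minNormalDepth} on that platform, and at least one
#'     mutant read in RNA-Seq tumor.
#' }
#' "Absent in normal" is a literal zero mutant-read count after tallying.
#' Criterion 3's depth floor attaches to the cross-validating platform's
#' normal; criterion 4's to the detecting platform's normal.
#'
#' @param variant A \linkS4class{VariantCall} with per-platform evidence.
#' @param minNormalDepth Normal-depth floor for criteria 3 and 4
#'   (default 20).
#' @return List with \code{status} ("CROSS_VALIDATED" or "UNCONFIRMED"),
#'   \code{criterion} (1--4 or NA) and \code{supportingPlatform}.
#' @examples
#' v <- VariantCall(GenomicSite("chr1", 100, "A", "T"), evidence = list(
#'   WGS = PlatformEvidence(ReadCounts(10, 20), ReadCounts(0, 30),
#'                          detected = TRUE, quality = "high"),
#'   WES = PlatformEvidence(ReadCounts(12, 40), ReadCounts(0, 45),
#'                          detected = TRUE, quality = "high")))
#' crossValidate(v)$criterion  # 1
#' @export
crossValidate <- function(variant, minNormalDepth = 20L) {
    ev <- function(p) {
        e <- variant@evidence[[p]]
        if (is.null(e)) PlatformEvidence() else e
    }
    wgs <- ev("WGS"); wes <- ev("WES"); rna <- ev("RNA")
    if (!any(vapply(list(wgs, wes, rna), function(e) e@detected, logical(1))))
        stop("variant has no detected platform")

    unconfirmed <- list(status = "UNCONFIRMED", criterion = NA_integer_,
                        supportingPlatform = NA_character_)
    other <- c(WGS = "WES", WES = "WGS")

    ## criterion 1: detected by both DNA platforms
    if (wgs@detected && wes@detected)
        return(list(status = "CROSS_VALIDATED", criterion = 1L,
                    supportingPlatform = "WGS+WES"))

    dna <- list(WGS = wgs, WES = wes)
    detectedDna <- names(dna)[vapply(dna, function(e) e@detected, logical(1))]

    ## criterion 2: >=1 tumor mutant read, absent in normal, other platform
    if (length(detectedDna) == 1L) {
        o <- other[[detectedDna]]
        oe <- dna[[o]]
        if (oe@tumor@mutant >= 1L && oe@normal@mutant == 0L)
            return(list(status = "CROSS_VALIDATED", criterion = 2L,
                        supportingPlatform = o))
    }

    ## criterion 3: high-quality call; other platform's normal clean at depth
    for (p in detectedDna) {
        if (!identical(dna[[p]]@quality, "high")) next
        oe <- dna[[other[[p]]]]
        if (oe@normal@mutant == 0L && oe@normal@total >= minNormalDepth)
            return(list(status = "CROSS_VALIDATED", criterion = 3L,
                        supportingPlatform = other[[p]]))
    }

    ## criterion 4: high-quality call with covered normal; RNA tumor support
    for (p in detectedDna) {
        if (!identical(dna[[p]]@quality, "high")) next
        if (dna[[p]]@normal@total >= minNormalDepth &&
            rna@tumor@mutant >= 1L)
            return(list(status = "CROSS_VALIDATED", criterion = 4L,
                        supportingPlatform = "RNA"))
    }

    unconfirmed
}

#' Cross-validate a table of variants
#'
#' Applies \code{\link{crossValidate}} to each call, appending status,
#' criterion and supporting-platform columns plus an audit trail. Variants
#' failing cross-validation are retained with UNCONFIRMED status.
#'
#' @param calls List of \linkS4class{VariantCall}.
#' @param minNormalDepth Passed to \code{\link{crossValidate}}.
#' @return data.frame with one row per call: chrom, pos, ref, alt, class,
#'   status, criterion, supporting_platform; attribute \code{audit} carries
#'   the decision log.
#' @export
crossValidateTable <- function(calls, minNormalDepth = 20L) {
    rows <- lapply(calls, function(v) {
        res <- crossValidate(v, minNormalDepth)
        data.frame(chrom = v@site@chrom, pos = v@site@pos,
                   ref = v@site@refAllele, alt = v@site@altAllele,
                   class = v@variantClass, status = res$status,
                   criterion = res$criterion,
                   supporting_platform = res$supportingPlatform,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    audit <- do.call(rbind, lapply(seq_along(calls), function(i) {
        v <- calls[[i]]
        auditRecord(siteKey(v@site@chrom, v@site@pos, v@site@refAllele,
                            v@site@altAllele),
                    rule = if (is.na(out$criterion[i])) "crossval:none"
                           else paste0("crossval:criterion", out$criterion[i]),
                    outcome = out$status[i])
    }))
    attr(out, "audit") <- audit
    out
}
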