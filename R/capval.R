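#' @include AllClasses.R
NULL

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Two-sided p-value for the table [tumor mutant a, tumor reference b;
#' normal mutant c, normal reference d], defined as the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed the observed table's.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return p-value in [0, 1].
#' @examples
#' fisherExactTwoSided(2, 0, 0, 2)  # 1/3
#' @importFrom stats fisher.test
#' @export
fisherExactTwoSided <- function(a, b, c, d) {
    cells <- c(a, b, c, d)
    if (any(cells < 0) || any(cells != round(cells)))
        stop("cell counts must be non-negative integers")
    if (sum(cells) == 0) return(1)
    m <- matrix(as.integer(cells), nrow = 2, byrow = TRUE)
    min(1, fisher.test(m, alternative = "two.sided")$p.value)
}

#' Adjudicate a capture-validation marker
#'
#' Rule cascade applied to tumor/normal capture read counts (tallied with a
#' class-specific base-quality floor: 15 for SNVs, 5 for indels):
#' \enumerate{
#'   \item 0 tumor mutant reads at tumor depth > 20 -> WILDTYPE;
#'   \item 0 tumor mutant reads at tumor depth <= 20 -> NOT_ASSESSABLE;
#'   \item Fisher exact p on tumor vs normal counts; mutant reads in normal
#'     with (p >= alpha or normal MAF >= \code{germlineNormalMaf})
#'     -> GERMLINE;
#'   \item p <= alpha and (no normal mutant reads or tumor MAF >
#'     \code{somaticMinTumorMaf}) -> SOMATIC, additionally requiring at
#'     least \code{homopolymerMinMutant} tumor mutant reads when the marker
#'     sits in homopolymer context and was discovered by WES only,
#'     regardless of depth;
#'   \item otherwise NOT_ASSESSABLE (manual-review bucket).
#' }
#' At the boundary p = alpha both germline and somatic conditions hold; the
#' germline rule fires first (conservative for clinical reporting).
#'
#' @param record A \linkS4class{ValidationRecord}.
#' @param params Named list of cutoffs; defaults from
#'   \code{defaultConfig()$capval}.
#' @return The record with \code{status} and \code{fisherP} filled; the
#'   rule that fired is recorded in \code{attr(, "rule")}.
#' @examples
#' r <- ValidationRecord(GenomicSite("chr1", 100, "A", "T"),
#'                       tumor = ReadCounts(10, 20), normal = ReadCounts(0, 50))
#' validationStatus(assignValidationStatus(r))  # "SOMATIC"
#' @export
assignValidationStatus <- function(record, params = defaultConfig()$capval) {
    tum <- record@tumor; nor <- record@normal
    if (tum@total == 0L && nor@total == 0L)
        stop("missing counts: zero depth in both tumor and normal")
    finish <- function(status, rule, p = NA_real_) {
        record@status <- status
        record@fisherP <- p
        attr(record, "rule") <- rule
        record
    }
    ## (i)/(ii): no mutant evidence in tumor
    if (tum@mutant == 0L) {
        if (tum@total > params$wildtype_min_depth)
            return(finish("WILDTYPE", "capval:wildtype"))
        return(finish("NOT_ASSESSABLE", "capval:low_depth_no_mutant"))
    }
    p <- fisherExactTwoSided(tum@mutant, tum@reference,
                             nor@mutant, nor@reference)
    normalMaf <- maf(nor); tumorMaf <- maf(tum)
    ## (iii) germline
    if (nor@mutant > 0L &&
        (p >= params$alpha ||
         (!is.na(normalMaf) && normalMaf >= params$germline_normal_maf)))
        return(finish("GERMLINE", "capval:germline", p))
    ## (iv) somatic
    if (p <= params$alpha &&
        (nor@mutant == 0L ||
         (!is.na(tumorMaf) && tumorMaf > params$somatic_min_tumor_maf))) {
        wesOnlyHomopolymer <- record@homopolymer &&
            identical(sort(record@discoveredBy), "WES")
        if (wesOnlyHomopolymer &&
            tum@mutant < params$homopolymer_min_mutant)
            return(finish("NOT_ASSESSABLE", "capval:homopolymer_support", p))
        return(finish("SOMATIC", "capval:somatic", p))
    }
    finish("NOT_ASSESSABLE", "capval:manual_review", p)
}

#' Adjudicate a table of capture-validation markers
#'
#' Applies \code{\link{assignValidationStatus}} to each record and then any
#' manual status overrides (the clinical workflow's expert adjustments are
#' modeled as an explicit override list, not as algorithm behavior).
#'
#' @param records List of \linkS4class{ValidationRecord}.
#' @param params Cutoffs as in \code{\link{assignValidationStatus}}.
#' @param overrides Optional data.frame with columns chrom, pos, ref, alt,
#'   status; matching markers receive the given status.
#' @return data.frame with site, counts, fisher_p, status, rule and
#'   overridden columns; attribute \code{audit} carries the decision log.
#' @export
adjudicateMarkers <- function(records, params = defaultConfig()$capval,
                              overrides = NULL) {
    rows <- lapply(records, function(r) {
        adj <- assignValidationStatus(r, params)
        data.frame(chrom = r@site@chrom, pos = r@site@pos,
                   ref = r@site@refAllele, alt = r@site@altAllele,
                   class = r@variantClass,
                   tumor_mutant = r@tumor@mutant, tumor_total = r@tumor@total,
                   normal_mutant = r@normal@mutant,
                   normal_total = r@normal@total,
                   fisher_p = adj@fisherP, status = adj@status,
                   rule = attr(adj, "rule"), overridden = FALSE,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (!is.null(overrides) && nrow(overrides)) {
        key <- siteKey(out$chrom, out$pos, out$ref, out$alt)
        okey <- siteKey(overrides$chrom, overrides$pos, overrides$ref,
                        overrides$alt)
        hit <- match(key, okey)
        sel <- !is.na(hit)
        out$status[sel] <- overrides$status[hit[sel]]
        out$rule[sel] <- "capval:override"
        out$overridden[sel] <- TRUE
    }
    audit <- do.call(rbind, Map(auditRecord,
        siteKey(out$chrom, out$pos, out$ref, out$alt),
        out$rule, out$status))
    rownames(audit) <- NULL
    attr(out, "audit") <- audit
    out
}

#' Homopolymer-context check
#'
#' A marker is in homopolymer context when a mononucleotide run of at least
#' \code{minRun} bases overlaps the variant site in its reference flank.
#'
#' @param flankSequence Reference sequence centered on the variant site.
#' @param sitePosition 1-based offset of the variant site within
#'   \code{flankSequence}.
#' @param minRun Minimum run length (default 7).
#' @return Logical.
#' @export
isHomopolymerContext <- function(flankSequence, sitePosition,
                                 minRun = 7L) {
    bases <- strsplit(toupper(flankSequence), "")[[1L]]
    n <- length(bases)
    stopifnot(sitePosition >= 1L, sitePosition <= n)
    r <- rle(bases)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    any(r$lengths >= minRun & starts <= sitePosition & ends >= sitePosition)
}
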