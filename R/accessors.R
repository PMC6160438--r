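#' @include AllGenerics.R
NULL

#' @rdname accessors
setMethod("mutantReads", "ReadCounts", function(x, ...) x@mutant)

#' @rdname accessors
setMethod("referenceReads", "ReadCounts", function(x, ...) x@reference)

#' @rdname accessors
setMethod("totalReads", "ReadCounts", function(x, ...) x@total)

#' @rdname accessors
setMethod("maf", "ReadCounts", function(x, ...) {
    if (x@total == 0L) NA_real_ else x@mutant / x@total
})

#' @rdname accessors
setMethod("site", "VariantCall", function(x, ...) x@site)

#' @rdname accessors
setMethod("site", "ValidationRecord", function(x, ...) x@site)

#' @rdname accessors
setMethod("variantClass", "VariantCall", function(x, ...) x@variantClass)

#' @rdname accessors
setMethod("variantClass", "ValidationRecord", function(x, ...) x@variantClass)

#' @rdname accessors
setMethod("platformEvidence", "VariantCall", function(x, platform, ...) {
    stopifnot(platform %in% .PLATFORMS)
    ev <- x@evidence[[platform]]
    if (is.null(ev)) PlatformEvidence() else ev
})

#' @rdname accessors
setMethod("validationStatus", "ValidationRecord", function(x, ...) x@status)

#' @rdname accessors
setMethod("fisherP", "ValidationRecord", function(x, ...) x@fisherP)

setMethod("txStartSite", "GeneModel", function(x) {
    if (x@strand == "+") x@txStart else x@txEnd
})

setMethod("txEndSite", "GeneModel", function(x) {
    if (x@strand == "+") x@txEnd else x@txStart
})

#' @rdname accessors
setMethod("exons", "GeneModel", function(x, ...) x@exons)

setMethod("finalPurity", "PurityEstimate", function(x, ...) x@final)

setMethod("show", "GenomicSite", function(object) {
    cat(sprintf("GenomicSite %s:%d %s>%s\n", object@chrom, object@pos,
                object@refAllele, object@altAllele))
})

setMethod("show", "ReadCounts", function(object) {
    m <- maf(object)
    cat(sprintf("ReadCounts mutant=%d reference=%d total=%d maf=%s\n",
                object@mutant, object@reference, object@total,
                if (is.na(m)) "NA" else sprintf("%.4g", m)))
})

setMethod("show", "VariantCall", function(object) {
    cat(sprintf("VariantCall [%s, %s] %s:%d %s>%s\n", object@variantClass,
                object@regionClass, object@site@chrom, object@site@pos,
                object@site@refAllele, object@site@altAllele))
    for (p in names(object@evidence)) {
        ev <- object@evidence[[p]]
        cat(sprintf("  %s: detected=%s%s tumor=%d/%d normal=%d/%d\n", p,
                    ev@detected,
                    if (is.null(ev@quality)) "" else paste0(" (", ev@quality, ")"),
                    ev@tumor@mutant, ev@tumor@total,
                    ev@normal@mutant, ev@normal@total))
    }
})

setMethod("show", "SvJunction", function(object) {
    cat(sprintf("SvJunction [%s] %s:%d(%s) -- %s:%d(%s) support=%d\n",
                object@svType, object@chromA, object@posA, object@strandA,
                object@chromB, object@posB, object@strandB,
                object@supportingReads))
})

setMethod("show", "FusionTranscript", function(object) {
    cat(sprintf("FusionTranscript %s>>%s  5':%s:%d  3':%s:%d  reads=%d\n",
                object@gene5p, object@gene3p, object@chrom5p, object@pos5p,
                object@chrom3p, object@pos3p, object@junctionReads))
})

setMethod("show", "GeneModel", function(object) {
    cat(sprintf("GeneModel %s %s:%d-%d(%s) exons=%d\n", object@name,
                object@chrom, object@txStart, object@txEnd, object@strand,
                length(object@exons)))
})

setMethod("show", "ValidationRecord", function(object) {
    cat(sprintf(
        "ValidationRecord [%s] %s:%d tumor=%d/%d normal=%d/%d status=%s\n",
        object@variantClass, object@site@chrom, object@site@pos,
        object@tumor@mutant, object@tumor@total,
        object@normal@mutant, object@normal@total, object@status))
})

setMethod("show", "PurityEstimate", function(object) {
    fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.3f", v)
    cat(sprintf("PurityEstimate cnvLoh=%s maf=%s final=%s\n",
                fmt(object@cnvLohPurity), fmt(object@mafPurity),
                fmt(object@final)))
})
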