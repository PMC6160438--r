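#' @import methods
#' @importFrom S4Vectors isSingleNumber isSingleString mcols mcols<-
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))
setClassUnion("logicalOrNULL", c("logical", "NULL"))

#' GenomicSite: a single variant locus
#'
#' A 1-based variant locus with VCF-style anchored ref/alt alleles. Indels
#' carry the leading shared base in both alleles so that allele-fraction
#' accounting is unambiguous.
#'
#' @slot chrom Chromosome name.
#' @slot pos 1-based position.
#' @slot refAllele Reference allele string.
#' @slot altAllele Alternate allele string.
#' @export
setClass("GenomicSite",
    representation(chrom = "character", pos = "integer",
                   refAllele = "character", altAllele = "character"))

setValidity("GenomicSite", function(object) {
    msg <- NULL
    if (!isSingleString(object@chrom) || !nzchar(object@chrom))
        msg <- c(msg, "'chrom' must be a non-empty string")
    if (length(object@pos) != 1L || is.na(object@pos) || object@pos < 1L)
        msg <- c(msg, "'pos' must be a single integer >= 1")
    if (identical(object@refAllele, object@altAllele))
        msg <- c(msg, "'refAllele' and 'altAllele' must differ")
    if (is.null(msg)) TRUE else msg
})

#' Construct a GenomicSite
#'
#' @param chrom Chromosome name.
#' @param pos 1-based position.
#' @param ref,alt Reference and alternate alleles (VCF-anchored for indels).
#' @return A \linkS4class{GenomicSite}.
#' @examples
#' GenomicSite("chr1", 100, "A", "T")
#' @export
GenomicSite <- function(chrom, pos, ref, alt) {
    new("GenomicSite", chrom = as.character(chrom), pos = as.integer(pos),
        refAllele = as.character(ref), altAllele = as.character(alt))
}

#' ReadCounts: mutant/reference/total read tally at a site
#'
#' Total may exceed mutant + reference because reads carrying a third allele
#' ("other") count toward depth but toward neither allele. The mutant allele
#' fraction is \code{mutant/total}, undefined (NA) at zero depth.
#'
#' @slot mutant Mutant-allele read count.
#' @slot reference Reference-allele read count.
#' @slot total Total read depth.
#' @export
setClass("ReadCounts",
    representation(mutant = "integer", reference = "integer",
                   total = "integer"))

setValidity("ReadCounts", function(object) {
    m <- object@mutant; r <- object@reference; t <- object@total
    msg <- NULL
    if (any(c(m, r, t) < 0L)) msg <- c(msg, "counts must be non-negative")
    if (t < m + r) msg <- c(msg, "'total' must be >= mutant + reference")
    if (is.null(msg)) TRUE else msg
})

#' Construct ReadCounts
#'
#' @param mutant,reference Mutant and reference read counts.
#' @param total Total depth; defaults to \code{mutant + reference}.
#' @return A \linkS4class{ReadCounts}.
#' @examples
#' maf(ReadCounts(15, 19))  # 15/34
#' @export
ReadCounts <- function(mutant = 0L, reference = 0L,
                       total = mutant + reference) {
    new("ReadCounts", mutant = as.integer(mutant),
        reference = as.integer(reference), total = as.integer(total))
}

#' PlatformEvidence: per-platform evidence for a variant
#'
#' @slot tumor,normal \linkS4class{ReadCounts} in tumor and matched normal.
#' @slot detected Whether the platform's caller detected the variant de novo.
#' @slot quality Quality tier, \code{"high"} or \code{"low"}; required when
#'   \code{detected} is TRUE.
#' @export
setClass("PlatformEvidence",
    representation(tumor = "ReadCounts", normal = "ReadCounts",
                   detected = "logical", quality = "characterOrNULL"))

setValidity("PlatformEvidence", function(object) {
    msg <- NULL
    if (length(object@detected) != 1L || is.na(object@detected))
        msg <- c(msg, "'detected' must be TRUE or FALSE")
    if (isTRUE(object@detected) && is.null(object@quality))
        msg <- c(msg, "'quality' tier required when detected")
    if (!is.null(object@quality) && !object@quality %in% c("high", "low"))
        msg <- c(msg, "'quality' must be \"high\" or \"low\"")
    if (is.null(msg)) TRUE else msg
})

#' Construct per-platform evidence
#'
#' @param tumor,normal \linkS4class{ReadCounts}.
#' @param detected Logical de novo detection flag.
#' @param quality \code{"high"}, \code{"low"}, or NULL when not detected.
#' @return A \linkS4class{PlatformEvidence}.
#' @export
PlatformEvidence <- function(tumor = ReadCounts(), normal = ReadCounts(),
                             detected = FALSE, quality = NULL) {
    new("PlatformEvidence", tumor = tumor, normal = normal,
        detected = detected, quality = quality)
}

.PLATFORMS <- c("WGS", "WES", "RNA")

#' VariantCall: a candidate SNV/indel with three-platform evidence
#'
#' @slot site The \linkS4class{GenomicSite}.
#' @slot variantClass One of \code{"SNV"}, \code{"INDEL"}, \code{"ITD"}.
#' @slot regionClass \code{"exonic"} or \code{"non-exonic"}.
#' @slot evidence Named list of \linkS4class{PlatformEvidence}, names in
#'   WGS/WES/RNA.
#' @slot annotations Free-form named list (gene, effect, hotspot flag, ...).
#' @export
setClass("VariantCall",
    representation(site = "GenomicSite", variantClass = "character",
                   regionClass = "character", evidence = "list",
                   annotations = "list"))

setValidity("VariantCall", function(object) {
    msg <- NULL
    if (!object@variantClass %in% c("SNV", "INDEL", "ITD"))
        msg <- c(msg, "variantClass must be SNV, INDEL or ITD")
    if (!object@regionClass %in% c("exonic", "non-exonic"))
        msg <- c(msg, "regionClass must be exonic or non-exonic")
    if (!all(names(object@evidence) %in% .PLATFORMS))
        msg <- c(msg, "evidence names must be among WGS, WES, RNA")
    ok <- vapply(object@evidence, is, logical(1), class2 = "PlatformEvidence")
    if (!all(ok)) msg <- c(msg, "evidence entries must be PlatformEvidence")
    if (is.null(msg)) TRUE else msg
})

#' Construct a VariantCall
#'
#' @param site A \linkS4class{GenomicSite}.
#' @param variantClass \code{"SNV"}, \code{"INDEL"} or \code{"ITD"}.
#' @param evidence Named list (WGS/WES/RNA) of \linkS4class{PlatformEvidence}.
#' @param regionClass \code{"exonic"} (default) or \code{"non-exonic"}.
#' @param annotations Named list of free-form annotations.
#' @return A \linkS4class{VariantCall}.
#' @export
VariantCall <- function(site, variantClass = "SNV", evidence = list(),
                        regionClass = "exonic", annotations = list()) {
    new("VariantCall", site = site, variantClass = variantClass,
        regionClass = regionClass, evidence = evidence,
        annotations = annotations)
}

#' SvJunction: a DNA structural-variant breakpoint pair
#'
#' Orientation convention: \code{"+"} means the segment at coordinates lower
#' than \code{pos} is retained in the derivative chromosome; \code{"-"} means
#' the higher-coordinate segment is retained.
#'
#' @slot chromA,posA,strandA First breakpoint.
#' @slot chromB,posB,strandB Second breakpoint.
#' @slot svType Free-form type label (e.g. "CTX"); multi-segment events note
#'   intermediate chromosomes here.
#' @slot supportingReads Number of junction-spanning reads.
#' @export
setClass("SvJunction",
    representation(chromA = "character", posA = "integer", strandA = "character",
                   chromB = "character", posB = "integer", strandB = "character",
                   svType = "character", supportingReads = "integer"))

setValidity("SvJunction", function(object) {
    msg <- NULL
    if (!object@strandA %in% c("+", "-") || !object@strandB %in% c("+", "-"))
        msg <- c(msg, "strands must be '+' or '-'")
    if (object@posA < 1L || object@posB < 1L)
        msg <- c(msg, "positions must be >= 1")
    if (object@supportingReads < 0L)
        msg <- c(msg, "supportingReads must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' Construct an SvJunction
#'
#' @param chromA,posA,strandA First oriented breakpoint (1-based).
#' @param chromB,posB,strandB Second oriented breakpoint.
#' @param svType Type label.
#' @param supportingReads Junction read support.
#' @return An \linkS4class{SvJunction}.
#' @export
SvJunction <- function(chromA, posA, strandA, chromB, posB, strandB,
                       svType = "SV", supportingReads = 0L) {
    new("SvJunction", chromA = as.character(chromA), posA = as.integer(posA),
        strandA = strandA, chromB = as.character(chromB),
        posB = as.integer(posB), strandB = strandB, svType = svType,
        supportingReads = as.integer(supportingReads))
}

#' FusionTranscript: an RNA chimeric junction
#'
#' RNA breakpoints routinely differ from the causal DNA breakpoints because
#' splicing joins the nearest exon boundaries.
#'
#' @slot gene5p,gene3p 5' and 3' partner gene names.
#' @slot chrom5p,pos5p RNA breakpoint on the 5' gene.
#' @slot chrom3p,pos3p RNA breakpoint on the 3' gene.
#' @slot junctionReads Chimeric junction read count.
#' @slot inFrame Optional reading-frame flag.
#' @export
setClass("FusionTranscript",
    representation(gene5p = "character", gene3p = "character",
                   chrom5p = "character", pos5p = "integer",
                   chrom3p = "character", pos3p = "integer",
                   junctionReads = "integer", inFrame = "logicalOrNULL"))

setValidity("FusionTranscript", function(object) {
    msg <- NULL
    if (object@pos5p < 1L || object@pos3p < 1L)
        msg <- c(msg, "breakpoint positions must be >= 1")
    if (object@junctionReads < 0L)
        msg <- c(msg, "junctionReads must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' Construct a FusionTranscript
#'
#' @param gene5p,gene3p Partner gene names.
#' @param chrom5p,pos5p,chrom3p,pos3p RNA breakpoints (1-based).
#' @param junctionReads Junction read count.
#' @param inFrame Optional logical.
#' @return A \linkS4class{FusionTranscript}.
#' @export
FusionTranscript <- function(gene5p, gene3p, chrom5p, pos5p, chrom3p, pos3p,
                             junctionReads = 0L, inFrame = NULL) {
    new("FusionTranscript", gene5p = gene5p, gene3p = gene3p,
        chrom5p = as.character(chrom5p), pos5p = as.integer(pos5p),
        chrom3p = as.character(chrom3p), pos3p = as.integer(pos3p),
        junctionReads = as.integer(junctionReads), inFrame = inFrame)
}

#' GeneModel: strand-aware transcript model
#'
#' Coordinates are 1-based inclusive genomic. \code{txStart}/\code{txEnd} are
#' genomic bounds; the transcription start and end *sites* are strand-aware
#' (see \code{\link{txStartSite}}).
#'
#' @slot name Gene name.
#' @slot chrom Chromosome.
#' @slot strand \code{"+"} or \code{"-"}.
#' @slot txStart,txEnd Genomic transcript bounds, txStart <= txEnd.
#' @slot exons \link[IRanges]{IRanges} of exons, sorted, non-overlapping,
#'   within the transcript bounds.
#' @importClassesFrom IRanges IRanges
#' @export
setClass("GeneModel",
    representation(name = "character", chrom = "character",
                   strand = "character", txStart = "integer",
                   txEnd = "integer", exons = "IRanges"))

setValidity("GeneModel", function(object) {
    msg <- NULL
    if (!object@strand %in% c("+", "-"))
        msg <- c(msg, "strand must be '+' or '-'")
    if (object@txStart > object@txEnd)
        msg <- c(msg, "txStart must be <= txEnd")
    ex <- object@exons
    if (length(ex)) {
        if (is.unsorted(IRanges::start(ex)))
            msg <- c(msg, "exons must be sorted by genomic coordinate")
        if (length(ex) > 1L &&
            any(IRanges::start(ex)[-1L] <= IRanges::end(ex)[-length(ex)]))
            msg <- c(msg, "exons must be non-overlapping")
        if (min(IRanges::start(ex)) < object@txStart ||
            max(IRanges::end(ex)) > object@txEnd)
            msg <- c(msg, "exons must lie within [txStart, txEnd]")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a GeneModel
#'
#' @param name Gene name.
#' @param chrom Chromosome.
#' @param strand \code{"+"} or \code{"-"}.
#' @param txStart,txEnd 1-based inclusive genomic transcript bounds.
#' @param exonStarts,exonEnds Parallel vectors of 1-based inclusive exon
#'   coordinates.
#' @return A \linkS4class{GeneModel}.
#' @importFrom IRanges IRanges
#' @export
GeneModel <- function(name, chrom, strand, txStart, txEnd,
                      exonStarts = txStart, exonEnds = txEnd) {
    new("GeneModel", name = name, chrom = as.character(chrom),
        strand = strand, txStart = as.integer(txStart),
        txEnd = as.integer(txEnd),
        exons = IRanges(as.integer(exonStarts), as.integer(exonEnds)))
}

#' ValidationRecord: a capture-validation marker
#'
#' @slot site \linkS4class{GenomicSite}.
#' @slot variantClass \code{"SNV"}, \code{"INDEL"} or \code{"ITD"}.
#' @slot tumor,normal \linkS4class{ReadCounts} from the capture experiment.
#' @slot discoveredBy Platforms that discovered the marker (subset of
#'   WGS/WES/RNA).
#' @slot homopolymer Homopolymer-context flag.
#' @slot status Adjudicated status or NA before adjudication.
#' @slot fisherP Two-sided Fisher exact p-value or NA.
#' @export
setClass("ValidationRecord",
    representation(site = "GenomicSite", variantClass = "character",
                   tumor = "ReadCounts", normal = "ReadCounts",
                   discoveredBy = "character", homopolymer = "logical",
                   status = "character", fisherP = "numeric"))

.VALSTATUS <- c("WILDTYPE", "SOMATIC", "GERMLINE", "NOT_ASSESSABLE")

setValidity("ValidationRecord", function(object) {
    msg <- NULL
    if (!all(object@discoveredBy %in% .PLATFORMS))
        msg <- c(msg, "discoveredBy must be among WGS, WES, RNA")
    if (!is.na(object@status) && !object@status %in% .VALSTATUS)
        msg <- c(msg, "invalid status")
    p <- object@fisherP
    if (!is.na(p) && (p < 0 || p > 1))
        msg <- c(msg, "fisherP must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' Construct a ValidationRecord
#'
#' @param site \linkS4class{GenomicSite}.
#' @param tumor,normal \linkS4class{ReadCounts}.
#' @param variantClass \code{"SNV"} (default), \code{"INDEL"} or \code{"ITD"}.
#' @param discoveredBy Character vector of discovering platforms.
#' @param homopolymer Logical homopolymer-context flag.
#' @return A \linkS4class{ValidationRecord} with status unset.
#' @export
ValidationRecord <- function(site, tumor, normal, variantClass = "SNV",
                             discoveredBy = character(), homopolymer = FALSE) {
    new("ValidationRecord", site = site, variantClass = variantClass,
        tumor = tumor, normal = normal, discoveredBy = discoveredBy,
        homopolymer = homopolymer, status = NA_character_,
        fisherP = NA_real_)
}

#' PurityEstimate: per-sample tumor purity
#'
#' @slot cnvLohPurity Estimate from CNV/LOH region tumor fractions.
#' @slot mafPurity Estimate from somatic diploid-region allele fractions.
#' @slot final The larger of the two available estimates.
#' @export
setClass("PurityEstimate",
    representation(cnvLohPurity = "numeric", mafPurity = "numeric",
                   final = "numeric"))

setValidity("PurityEstimate", function(object) {
    vals <- c(object@cnvLohPurity, object@mafPurity, object@final)
    msg <- NULL
    if (any(vals < 0 | vals > 1, na.rm = TRUE))
        msg <- c(msg, "purity values must lie in [0, 1]")
    avail <- c(object@cnvLohPurity, object@mafPurity)
    if (all(is.na(avail))) {
        msg <- c(msg, "at least one component estimate required")
    } else if (!isTRUE(all.equal(object@final, max(avail, na.rm = TRUE)))) {
        msg <- c(msg, "'final' must equal the larger available estimate")
    }
    if (is.null(msg)) TRUE else msg
})
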