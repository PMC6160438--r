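#' @include AllClasses.R
NULL

.TRUNCATING <- c("nonsense", "frameshift", "splice")

#' Curate a driver-gene catalog from a mutation catalog
#'
#' Filter pipeline over catalog records (one row per mutation observation):
#' \enumerate{
#'   \item keep only experimentally verified records from genome-wide
#'     screens;
#'   \item drop sites carried by more than \code{maxControlCarriers} of the
#'     non-cancer control cohort (germline polymorphisms masquerading as
#'     somatic);
#'   \item drop all records of hypermutated samples: at least
#'     \code{hypermutMinCoding} coding variants AND within the top
#'     \code{hypermutTopFraction} most-mutated samples of their own study
#'     (descending rank <= ceiling(fraction x study size));
#'   \item call a gene a tumor suppressor when its truncating-record
#'     fraction reaches \code{truncationFractionMin}, and an oncogene when
#'     any single site recurs in at least \code{hotspotMinRecurrence}
#'     distinct samples (those sites become its hotspots).
#' }
#'
#' @param records data.frame with columns gene, site (codon/site key),
#'   mutationClass (missense/nonsense/frameshift/splice/other), sample,
#'   study, verified (logical), genomeWide (logical), codingCount (coding
#'   variants of the sample).
#' @param controlCarrierCounts Named integer vector: site key -> carrier
#'   count in the control cohort (absent sites count 0).
#' @param maxControlCarriers Carrier-count cutoff (default 10; sites with 10
#'   are retained, 11 dropped).
#' @param hypermutMinCoding Coding-variant floor for hypermutators
#'   (default 100).
#' @param hypermutTopFraction Top fraction of a study defining
#'   hypermutators (default 0.10).
#' @param truncationFractionMin Truncating fraction calling a tumor
#'   suppressor (default 0.3).
#' @param hotspotMinRecurrence Samples sharing a site to call a hotspot
#'   (default 3).
#' @return List with \code{tumorSuppressors} (character),
#'   \code{oncogenes} (named list gene -> hotspot site keys),
#'   \code{survivors} (the filtered records).
#' @export
curateDriverCatalog <- function(records, controlCarrierCounts = integer(),
                                maxControlCarriers = 10L,
                                hypermutMinCoding = 100L,
                                hypermutTopFraction = 0.10,
                                truncationFractionMin = 0.3,
                                hotspotMinRecurrence = 3L) {
    stopifnot(is.data.frame(records))
    keep <- records$verified & records$genomeWide
    rec <- records[keep, , drop = FALSE]

    if (nrow(rec)) {
        carriers <- controlCarrierCounts[rec$site]
        carriers[is.na(carriers)] <- 0L
        rec <- rec[carriers <= maxControlCarriers, , drop = FALSE]
    }

    if (nrow(rec)) {
        if (any(is.na(rec$study)) || is.null(rec$study))
            stop("missing study id: hypermutation filtering needs 'study'")
        samples <- unique(rec[, c("study", "sample", "codingCount")])
        hyper <- character()
        for (st in unique(samples$study)) {
            ss <- samples[samples$study == st, , drop = FALSE]
            k <- ceiling(hypermutTopFraction * nrow(ss))
            topCut <- sort(ss$codingCount, decreasing = TRUE)[k]
            hit <- ss$codingCount >= hypermutMinCoding &
                   ss$codingCount >= topCut
            hyper <- c(hyper, ss$sample[hit])
        }
        rec <- rec[!rec$sample %in% hyper, , drop = FALSE]
    }

    tumorSuppressors <- character()
    oncogenes <- list()
    for (g in unique(rec$gene)) {
        gr <- rec[rec$gene == g, , drop = FALSE]
        truncFrac <- mean(gr$mutationClass %in% .TRUNCATING)
        if (truncFrac >= truncationFractionMin)
            tumorSuppressors <- c(tumorSuppressors, g)
        recurrence <- tapply(gr$sample, gr$site,
                             function(s) length(unique(s)))
        hot <- names(recurrence)[recurrence >= hotspotMinRecurrence]
        if (length(hot)) oncogenes[[g]] <- sort(hot)
    }
    list(tumorSuppressors = sort(tumorSuppressors), oncogenes = oncogenes,
         survivors = rec)
}

#' Flag a variant for review
#'
#' A variant is flagged when its gene appears on any driver list (SNVs and
#' indels) or when it is any CNA or SV. Review priority is elevated when
#' the mutation type is consistent with the gene's role in cancer:
#' truncation of a tumor suppressor, a hotspot match in an oncogene,
#' amplification of an amplification-listed gene, or deletion/truncating SV
#' of a deletion-listed gene.
#'
#' @param gene Gene name.
#' @param mutationClass One of missense/nonsense/frameshift/splice/other
#'   for SNVs and indels, or fusion/amplification/deletion/sv.
#' @param lists Driver lists: a list with elements \code{tumorSuppressors},
#'   \code{oncogenes} (named list gene -> hotspots), \code{fusionGenes},
#'   \code{cnaGenes} (named character: gene -> "amplification"/"deletion").
#' @param siteKey Optional codon/site key for hotspot matching.
#' @return List with \code{flagged} and \code{priority} ("normal" or
#'   "elevated").
#' @export
reviewFlag <- function(gene, mutationClass, lists, siteKey = NULL) {
    isSvCna <- mutationClass %in% c("fusion", "amplification", "deletion",
                                    "sv")
    inAnyList <- gene %in% c(lists$tumorSuppressors, names(lists$oncogenes),
                             lists$fusionGenes, names(lists$cnaGenes))
    flagged <- isSvCna || inAnyList
    elevated <- FALSE
    if (mutationClass %in% .TRUNCATING && gene %in% lists$tumorSuppressors)
        elevated <- TRUE
    if (!is.null(siteKey) && gene %in% names(lists$oncogenes) &&
        siteKey %in% lists$oncogenes[[gene]])
        elevated <- TRUE
    direction <- lists$cnaGenes[gene]
    if (!is.na(direction) && length(direction)) {
        if (mutationClass == "amplification" &&
            identical(unname(direction), "amplification"))
            elevated <- TRUE
        if (mutationClass %in% c("deletion", "sv") &&
            identical(unname(direction), "deletion"))
            elevated <- TRUE
    }
    list(flagged = flagged, priority = if (elevated) "elevated" else "normal")
}

#' Rule-based pathogenicity tier
#'
#' First-matching-rule assignment in the order Pathogenic -> Likely
#' Pathogenic -> Uncertain:
#' \itemize{
#'   \item P-i: hotspot SNV/indel in a known cancer gene, any cancer type;
#'   \item P-ii: nonsense/frameshift/splice mutation in a tumor suppressor
#'     with a known role in this cancer type;
#'   \item P-iii: recurrent fusion/deletion/truncation/amplification or
#'     arm-level abnormality currently used for molecular diagnosis of this
#'     cancer type;
#'   \item LP-i: any mutation type in a gene linked to this cancer type
#'     when the functional impact is unclear;
#'   \item LP-ii: a mutation with obvious functional effect on a cancer
#'     gene, in a tumor type with no known association to that gene;
#'   \item U-i: unclear functional impact in a cancer gene not known to
#'     play a role in this cancer type;
#'   \item default: UNCERTAIN.
#' }
#' Functional impact is considered clear for truncations of tumor
#' suppressors, hotspot mutations, and fusions/amplifications/deletions of
#' role-consistent genes.
#'
#' @param gene Gene name.
#' @param mutationClass missense/nonsense/frameshift/splice/other, or
#'   fusion/amplification/deletion/arm_level.
#' @param hotspot Logical: recurrent hotspot site.
#' @param cancerType Tumor type of the case.
#' @param context List with \code{knownCancerTypes} (character),
#'   \code{geneRoles} (named list: gene -> list(role =
#'   "tumor_suppressor"/"oncogene", cancerTypes = character of associated
#'   types)), \code{diagnosticMarkers} (named list: cancer type -> character
#'   of "gene:mutationClass" keys).
#' @return List with \code{tier} ("P", "LP", "UNCERTAIN") and \code{rule}.
#' @export
assignTier <- function(gene, mutationClass, hotspot, cancerType, context) {
    if (!cancerType %in% context$knownCancerTypes)
        stop("unknown cancer type '", cancerType, "'; known: ",
             paste(context$knownCancerTypes, collapse = ", "))
    role <- context$geneRoles[[gene]]
    isCancerGene <- !is.null(role)
    associated <- isCancerGene && cancerType %in% role$cancerTypes
    isTsg <- isCancerGene && identical(role$role, "tumor_suppressor")
    svClasses <- c("fusion", "amplification", "deletion", "arm_level",
                   "truncation_sv")
    markers <- context$diagnosticMarkers[[cancerType]]
    diagnostic <- mutationClass %in% svClasses &&
        paste0(gene, ":", mutationClass) %in% markers

    clearImpact <- (mutationClass %in% .TRUNCATING && isTsg) ||
        isTRUE(hotspot) ||
        (mutationClass %in% svClasses && isCancerGene)

    if (isTRUE(hotspot) && isCancerGene &&
        !mutationClass %in% svClasses)
        return(list(tier = "P", rule = "P-i"))
    if (mutationClass %in% .TRUNCATING && isTsg && associated)
        return(list(tier = "P", rule = "P-ii"))
    if (diagnostic)
        return(list(tier = "P", rule = "P-iii"))
    if (associated && !clearImpact)
        return(list(tier = "LP", rule = "LP-i"))
    if (clearImpact && isCancerGene && !associated)
        return(list(tier = "LP", rule = "LP-ii"))
    if (!clearImpact && isCancerGene && !associated)
        return(list(tier = "UNCERTAIN", rule = "U-i"))
    list(tier = "UNCERTAIN", rule = "default")
}
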