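#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Read-count, site and gene-model accessors used across the package.
#'
#' @param x An object.
#' @param ... Further arguments for methods.
#' @return The accessed slot value; \code{maf} returns \code{NA} at zero
#'   depth.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("mutantReads", function(x, ...) standardGeneric("mutantReads"))

#' @rdname accessors
#' @export
setGeneric("referenceReads", function(x, ...) standardGeneric("referenceReads"))

#' @rdname accessors
#' @export
setGeneric("totalReads", function(x, ...) standardGeneric("totalReads"))

#' @rdname accessors
#' @export
setGeneric("maf", function(x, ...) standardGeneric("maf"))

#' @rdname accessors
#' @export
setGeneric("site", function(x, ...) standardGeneric("site"))

#' @rdname accessors
#' @export
setGeneric("variantClass", function(x, ...) standardGeneric("variantClass"))

#' @rdname accessors
#' @export
setGeneric("platformEvidence", function(x, platform, ...)
    standardGeneric("platformEvidence"))

#' @rdname accessors
#' @export
setGeneric("validationStatus", function(x, ...)
    standardGeneric("validationStatus"))

#' @rdname accessors
#' @export
setGeneric("fisherP", function(x, ...) standardGeneric("fisherP"))

#' Strand-aware transcription start site
#'
#' The transcription start site in transcript orientation: the genomic
#' \code{txStart} for a plus-strand gene, the genomic \code{txEnd} for a
#' minus-strand gene.
#'
#' @param x A \linkS4class{GeneModel}.
#' @return Integer genomic position.
#' @examples
#' g <- GeneModel("G", "chr1", "-", 1000, 5000)
#' txStartSite(g)  # 5000
#' @export
setGeneric("txStartSite", function(x) standardGeneric("txStartSite"))

#' Strand-aware transcription end site
#'
#' @param x A \linkS4class{GeneModel}.
#' @return Integer genomic position.
#' @export
setGeneric("txEndSite", function(x) standardGeneric("txEndSite"))

#' @rdname accessors
#' @export
setGeneric("exons", function(x, ...) standardGeneric("exons"))

#' Final purity value
#'
#' @param x A \linkS4class{PurityEstimate}.
#' @param ... Unused.
#' @return Numeric purity in [0, 1].
#' @export
setGeneric("finalPurity", function(x, ...) standardGeneric("finalPurity"))
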