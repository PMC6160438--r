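#' @include AllClasses.R
NULL

## Internal coordinates are 1-based inclusive everywhere; conversion from
## 0-based half-open formats (BED, BEDPE, refFlat) happens only here, at the
## I/O boundary.

readLinesTab <- function(path) {
    lines <- readLines(path)
    lines[nzchar(lines) & !startsWith(lines, "#")]
}

splitTab <- function(line) strsplit(line, "\t", fixed = TRUE)[[1]]

asCount <- function(x, what, lineNo) {
    n <- suppressWarnings(as.integer(x))
    if (is.na(n))
        stop(sprintf("non-numeric %s '%s' at line %d", what, x, lineNo),
             call. = FALSE)
    n
}

.PLATFORM_PREFIX <- c(WGS = "wgs", WES = "wes", RNA = "rna")

.variantCountCols <- function(prefix) {
    paste0(prefix, c("_tumor_mutant", "_tumor_total",
                     "_normal_mutant", "_normal_total"))
}

#' Parse a tab-delimited variant table
#'
#' The table carries one candidate SNV/indel per row with per-platform
#' tumor/normal read counts and detection flags. Required columns: chrom,
#' pos, ref, alt, class. Optional per-platform columns (prefix wgs_/wes_/
#' rna_): \code{<p>_detected}, \code{<p>_quality}, \code{<p>_tumor_mutant},
#' \code{<p>_tumor_total}, \code{<p>_normal_mutant}, \code{<p>_normal_total}.
#' Unknown columns are preserved in the annotations of each call; row order
#' is preserved.
#'
#' @param path Path to the tab-delimited file (header required).
#' @return List of \linkS4class{VariantCall}, one per data row.
#' @export
parseVariantTable <- function(path) {
    lines <- readLinesTab(path)
    if (!length(lines)) stop("empty variant table: header required")
    header <- splitTab(lines[1L])
    required <- c("chrom", "pos", "ref", "alt", "class")
    missing <- setdiff(required, header)
    if (length(missing))
        stop("variant table missing required column(s): ",
             paste(missing, collapse = ", "))
    idx <- function(name) match(name, header)
    known <- c(required, "region",
               unlist(lapply(.PLATFORM_PREFIX, function(p)
                   c(paste0(p, "_detected"), paste0(p, "_quality"),
                     .variantCountCols(p)))))
    unknown <- setdiff(header, known)

    out <- vector("list", length(lines) - 1L)
    for (i in seq_along(out)) {
        lineNo <- i + 1L
        f <- splitTab(lines[lineNo])
        if (length(f) != length(header))
            stop(sprintf("line %d has %d fields, header has %d", lineNo,
                         length(f), length(header)))
        val <- function(name) {
            j <- idx(name)
            if (is.na(j)) NA_character_ else f[j]
        }
        evidence <- list()
        for (platform in names(.PLATFORM_PREFIX)) {
            p <- .PLATFORM_PREFIX[[platform]]
            cols <- .variantCountCols(p)
            if (!any(cols %in% header)) next
            present <- cols %in% header
            if (!all(present))
                stop("variant table has partial count columns for ",
                     platform, ": missing ",
                     paste(cols[!present], collapse = ", "))
            cnt <- vapply(cols, function(cn)
                asCount(val(cn), cn, lineNo), integer(1))
            tum <- tryCatch(
                ReadCounts(cnt[1L], cnt[2L] - cnt[1L], cnt[2L]),
                error = function(e) stop(sprintf(
                    "invariant violation in tumor counts at line %d: %s",
                    lineNo, conditionMessage(e)), call. = FALSE))
            if (cnt[1L] > cnt[2L])
                stop(sprintf("mutant > total at line %d (%s)", lineNo, p),
                     call. = FALSE)
            if (cnt[3L] > cnt[4L])
                stop(sprintf("mutant > total at line %d (%s normal)", lineNo,
                             p), call. = FALSE)
            nor <- ReadCounts(cnt[3L], cnt[4L] - cnt[3L], cnt[4L])
            det <- identical(tolower(val(paste0(p, "_detected"))), "true")
            qual <- val(paste0(p, "_quality"))
            if (is.na(qual) || !nzchar(qual)) qual <- if (det) "high" else NULL
            evidence[[platform]] <- PlatformEvidence(tum, nor, det, qual)
        }
        ann <- as.list(f[match(unknown, header)])
        names(ann) <- unknown
        region <- val("region")
        out[[i]] <- VariantCall(
            site = GenomicSite(val("chrom"), asCount(val("pos"), "pos",
                                                     lineNo),
                               val("ref"), val("alt")),
            variantClass = val("class"),
            evidence = evidence,
            regionClass = if (is.na(region)) "exonic" else region,
            annotations = ann)
    }
    out
}

#' Write a variant table
#'
#' Inverse of \code{\link{parseVariantTable}} over the typed fields.
#'
#' @param calls List of \linkS4class{VariantCall}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeVariantTable <- function(calls, path) {
    annKeys <- unique(unlist(lapply(calls, function(v) names(v@annotations))))
    header <- c("chrom", "pos", "ref", "alt", "class", "region")
    for (p in .PLATFORM_PREFIX)
        header <- c(header, paste0(p, "_detected"), paste0(p, "_quality"),
                    .variantCountCols(p))
    header <- c(header, annKeys)
    rows <- vapply(calls, function(v) {
        f <- c(v@site@chrom, v@site@pos, v@site@refAllele, v@site@altAllele,
               v@variantClass, v@regionClass)
        for (platform in names(.PLATFORM_PREFIX)) {
            ev <- v@evidence[[platform]]
            if (is.null(ev)) ev <- PlatformEvidence()
            f <- c(f, tolower(as.character(ev@detected)),
                   if (is.null(ev@quality)) "" else ev@quality,
                   ev@tumor@mutant, ev@tumor@total,
                   ev@normal@mutant, ev@normal@total)
        }
        extra <- vapply(annKeys, function(k) {
            x <- v@annotations[[k]]
            if (is.null(x)) "" else as.character(x)
        }, character(1))
        paste(c(f, extra), collapse = "\t")
    }, character(1))
    writeLines(c(paste(header, collapse = "\t"), rows), path)
    invisible(path)
}

#' Parse copy-number or LOH segments
#'
#' SEG input (header line expected: sample, chrom, start, end, n_markers,
#' log2) is taken as 1-based inclusive; BED input (no header: chrom, start,
#' end, score) is 0-based half-open and converted to 1-based inclusive
#' (start + 1, end).
#'
#' @param path Input path.
#' @param dialect \code{"SEG"} or \code{"BED"}.
#' @return A \link[GenomicRanges]{GRanges}; SEG carries metadata columns
#'   \code{sample}, \code{nMarkers}, \code{log2Ratio} and \code{cnaShift}
#'   (identity conversion of log2); BED carries \code{score}.
#' @importFrom GenomicRanges GRanges start end mcols
#' @importFrom IRanges IRanges
#' @export
parseSegments <- function(path, dialect = c("SEG", "BED")) {
    dialect <- match.arg(dialect)
    lines <- readLinesTab(path)
    if (dialect == "SEG" && length(lines)) lines <- lines[-1L]
    n <- length(lines)
    if (!n) return(GRanges())
    chrom <- character(n); s <- integer(n); e <- integer(n)
    score <- numeric(n); sample <- character(n); nm <- integer(n)
    for (i in seq_len(n)) {
        f <- splitTab(lines[i])
        lineNo <- i + (dialect == "SEG")
        if (dialect == "SEG") {
            if (length(f) < 6L)
                stop(sprintf("SEG line %d has %d fields, 6 required", lineNo,
                             length(f)))
            sample[i] <- f[1L]; chrom[i] <- f[2L]
            s[i] <- asCount(f[3L], "start", lineNo)
            e[i] <- asCount(f[4L], "end", lineNo)
            nm[i] <- asCount(f[5L], "n_markers", lineNo)
            score[i] <- as.numeric(f[6L])
        } else {
            if (length(f) < 4L)
                stop(sprintf("BED line %d has %d fields, 4 required", lineNo,
                             length(f)))
            chrom[i] <- f[1L]
            s[i] <- asCount(f[2L], "start", lineNo) + 1L
            e[i] <- asCount(f[3L], "end", lineNo)
            score[i] <- as.numeric(f[4L])
        }
        if (s[i] > e[i])
            stop(sprintf("reversed interval at line %d: start %d > end %d",
                         lineNo, s[i], e[i]))
    }
    gr <- GRanges(chrom, IRanges(s, e))
    if (dialect == "SEG") {
        mcols(gr)$sample <- sample
        mcols(gr)$nMarkers <- nm
        mcols(gr)$log2Ratio <- score
        mcols(gr)$cnaShift <- score   # identity conversion mode
    } else {
        mcols(gr)$score <- score
    }
    gr
}

#' Write segments
#'
#' Inverse of \code{\link{parseSegments}}; BED output converts back to
#' 0-based half-open.
#'
#' @param gr GRanges as returned by \code{\link{parseSegments}}.
#' @param path Output path.
#' @param dialect \code{"SEG"} or \code{"BED"}.
#' @return Invisibly, the path.
#' @importFrom GenomicRanges seqnames
#' @export
writeSegments <- function(gr, path, dialect = c("SEG", "BED")) {
    dialect <- match.arg(dialect)
    chrom <- as.character(seqnames(gr))
    if (dialect == "SEG") {
        rows <- sprintf("%s\t%s\t%d\t%d\t%d\t%g", mcols(gr)$sample, chrom,
                        start(gr), end(gr), mcols(gr)$nMarkers,
                        mcols(gr)$log2Ratio)
        rows <- c("sample\tchrom\tstart\tend\tn_markers\tlog2", rows)
    } else {
        rows <- sprintf("%s\t%d\t%d\t%g", chrom, start(gr) - 1L, end(gr),
                        mcols(gr)$score)
    }
    writeLines(rows, path)
    invisible(path)
}

#' Parse SV junctions from BEDPE
#'
#' Standard BEDPE: chrom1, start1, end1, chrom2, start2, end2, name, score,
#' strand1, strand2 (0-based half-open per mate). Each mate's representative
#' position is the strand-aware breakpoint base in 1-based coordinates: the
#' last retained base, i.e. the interval end for strand \code{"+"} (the
#' lower-coordinate segment is retained) and \code{start + 1} for strand
#' \code{"-"}.
#'
#' @param path Input path (no header).
#' @return List of \linkS4class{SvJunction}.
#' @export
parseBreakpoints <- function(path) {
    lines <- readLinesTab(path)
    lapply(seq_along(lines), function(i) {
        f <- splitTab(lines[i])
        if (length(f) < 10L)
            stop(sprintf(
                "BEDPE line %d has %d fields, 10 required (mate 2 missing?)",
                i, length(f)))
        strandA <- f[9L]; strandB <- f[10L]
        if (!strandA %in% c("+", "-") || !strandB %in% c("+", "-"))
            stop(sprintf("invalid strand at line %d: '%s'/'%s'", i, strandA,
                         strandB))
        repPos <- function(start0, end0, strand)
            if (strand == "+") end0 else start0 + 1L
        SvJunction(
            chromA = f[1L],
            posA = repPos(asCount(f[2L], "start1", i),
                          asCount(f[3L], "end1", i), strandA),
            strandA = strandA,
            chromB = f[4L],
            posB = repPos(asCount(f[5L], "start2", i),
                          asCount(f[6L], "end2", i), strandB),
            strandB = strandB,
            svType = f[7L],
            supportingReads = asCount(f[8L], "score", i))
    })
}

#' Write SV junctions as BEDPE
#'
#' Inverse of \code{\link{parseBreakpoints}}: each breakpoint becomes a
#' single-base interval whose strand-aware representative position
#' reproduces the input.
#'
#' @param junctions List of \linkS4class{SvJunction}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeBreakpoints <- function(junctions, path) {
    rows <- vapply(junctions, function(j) {
        sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s\t%d\t%s\t%s",
                j@chromA, j@posA - 1L, j@posA,
                j@chromB, j@posB - 1L, j@posB,
                j@svType, j@supportingReads, j@strandA, j@strandB)
    }, character(1))
    writeLines(rows, path)
    invisible(path)
}

#' Parse gene models from refFlat
#'
#' refFlat columns: geneName, name, chrom, strand, txStart, txEnd, cdsStart,
#' cdsEnd, exonCount, exonStarts, exonEnds (0-based half-open; exon lists
#' comma-separated). Converted to internal 1-based inclusive coordinates.
#'
#' @param path Input path (no header).
#' @return Named list of \linkS4class{GeneModel} keyed by gene name.
#' @export
parseGeneModels <- function(path) {
    lines <- readLinesTab(path)
    out <- lapply(seq_along(lines), function(i) {
        f <- splitTab(lines[i])
        if (length(f) < 11L)
            stop(sprintf("refFlat line %d has %d fields, 11 required", i,
                         length(f)))
        nExon <- asCount(f[9L], "exonCount", i)
        starts <- as.integer(strsplit(f[10L], ",", fixed = TRUE)[[1L]])
        ends <- as.integer(strsplit(f[11L], ",", fixed = TRUE)[[1L]])
        if (length(starts) != nExon || length(ends) != nExon)
            stop(sprintf("exonCount mismatch at line %d: declared %d, got %d/%d",
                         i, nExon, length(starts), length(ends)))
        GeneModel(name = f[1L], chrom = f[3L], strand = f[4L],
                  txStart = asCount(f[5L], "txStart", i) + 1L,
                  txEnd = asCount(f[6L], "txEnd", i),
                  exonStarts = starts + 1L, exonEnds = ends)
    })
    names(out) <- vapply(out, function(g) g@name, character(1))
    out
}

#' Write gene models as refFlat
#'
#' Inverse of \code{\link{parseGeneModels}} (cds columns are written equal to
#' the transcript bounds).
#'
#' @param genes List of \linkS4class{GeneModel}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeGeneModels <- function(genes, path) {
    rows <- vapply(genes, function(g) {
        ex <- g@exons
        sprintf("%s\t%s\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%s\t%s",
                g@name, g@name, g@chrom, g@strand,
                g@txStart - 1L, g@txEnd, g@txStart - 1L, g@txEnd,
                length(ex),
                paste0(paste(IRanges::start(ex) - 1L, collapse = ","), ","),
                paste0(paste(IRanges::end(ex), collapse = ","), ","))
    }, character(1))
    writeLines(rows, path)
    invisible(path)
}

#' Minimal VCF reader
#'
#' Reads a VCF 4.x file and maps each record to a \linkS4class{VariantCall}
#' whose evidence for \code{platform} is filled from the AD genotype field
#' of the named samples where present. INFO keys are preserved as
#' annotations. Multi-allelic records are expanded per alternate allele.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF.
#' @param platform Platform label for the evidence slot (default "WGS").
#' @param tumorSample,normalSample Sample names in the VCF; defaults to the
#'   first and second sample when present.
#' @param genome Genome tag passed to the reader (default "unknown").
#' @return List of \linkS4class{VariantCall}.
#' @importFrom VariantAnnotation readVcf ref alt info geno
#' @importFrom GenomicRanges seqnames start
#' @importFrom S4Vectors expand
#' @export
readVcfVariants <- function(path, platform = "WGS", tumorSample = NULL,
                            normalSample = NULL, genome = "unknown") {
    vcf <- suppressWarnings(readVcf(path, genome = genome))
    vcf <- expand(vcf)
    rr <- SummarizedExperiment::rowRanges(vcf)
    chrom <- as.character(seqnames(rr))
    pos <- start(rr)
    refA <- as.character(ref(vcf))
    altA <- as.character(alt(vcf))
    g <- geno(vcf)
    samples <- colnames(vcf)
    if (is.null(tumorSample) && length(samples) >= 1L)
        tumorSample <- samples[1L]
    if (is.null(normalSample) && length(samples) >= 2L)
        normalSample <- samples[2L]
    infoDf <- tryCatch(as.data.frame(info(vcf)), error = function(e) NULL)
    adCounts <- function(sampleName, i) {
        if (is.null(sampleName) || !"AD" %in% names(g)) return(ReadCounts())
        adArr <- g$AD
        ad <- if (length(dim(adArr)) == 3L) adArr[i, sampleName, ]
              else {
                  x <- adArr[i, sampleName]
                  if (is.list(x)) x[[1L]] else x
              }
        if (length(ad) < 2L || anyNA(ad)) return(ReadCounts())
        ReadCounts(mutant = ad[2L], reference = ad[1L])
    }
    lapply(seq_along(pos), function(i) {
        ann <- if (is.null(infoDf)) list() else as.list(infoDf[i, , drop = FALSE])
        ev <- list(PlatformEvidence(tumor = adCounts(tumorSample, i),
                                    normal = adCounts(normalSample, i),
                                    detected = TRUE, quality = "high"))
        names(ev) <- platform
        VariantCall(site = GenomicSite(chrom[i], pos[i], refA[i], altA[i]),
                    variantClass = if (nchar(refA[i]) == nchar(altA[i]))
                        "SNV" else "INDEL",
                    evidence = ev, annotations = ann)
    })
}
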