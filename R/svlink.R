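#' @include AllClasses.R
NULL

flipStrand <- function(s) if (s == "+") "-" else "+"

## Is (chrom,pos) within the gene body, optionally extended by ext bp?
inGeneBody <- function(gene, chrom, pos, ext = 0L) {
    chrom == gene@chrom && pos >= gene@txStart - ext &&
        pos <= gene@txEnd + ext
}

#' Link an RNA fusion transcript to a DNA SV junction
#'
#' Splicing moves RNA fusion breakpoints away from the causal DNA
#' breakpoints, so linking uses transcript-orientation intervals: the DNA
#' breakpoint assigned to the 5' gene must be the same as or downstream of
#' the RNA breakpoint, up to the transcription end site; the DNA breakpoint
#' assigned to the 3' gene must be the same as or upstream of the RNA
#' breakpoint, back to the transcription start site ("downstream" and
#' "upstream" in transcript orientation, so the genomic direction flips for
#' minus-strand genes; both interval ends are inclusive). In addition the
#' SV orientation must support the fusion product: under the convention
#' that strand \code{"+"} retains the lower-coordinate side of a
#' breakpoint, the 5'-gene breakpoint must retain the promoter-proximal
#' segment (breakpoint strand equals the gene strand) and the 3'-gene
#' breakpoint the terminator-proximal segment (breakpoint strand opposite
#' to the gene strand).
#'
#' Both assignments of the junction's two breakpoints to the two genes are
#' tried; the one placing each breakpoint on its gene's chromosome (and
#' satisfying the rules, when either does) is reported.
#'
#' @param fusion A \linkS4class{FusionTranscript}.
#' @param sv An \linkS4class{SvJunction}.
#' @param genes Named list of \linkS4class{GeneModel} containing both
#'   fusion partners.
#' @param geneBodyExtension Allowed slack (bp) beyond the annotated
#'   transcript bounds, for RNA junctions slightly outside the gene
#'   (default 0 = strict).
#' @return List with \code{linked}, \code{side5pOk}, \code{side3pOk},
#'   \code{orientationOk} and \code{distance} (total |DNA - RNA| breakpoint
#'   distance, NA when the assignment fails on chromosome).
#' @export
linkFusionToSv <- function(fusion, sv, genes, geneBodyExtension = 0L) {
    g5 <- genes[[fusion@gene5p]]
    if (is.null(g5)) stop("gene absent from models: ", fusion@gene5p)
    g3 <- genes[[fusion@gene3p]]
    if (is.null(g3)) stop("gene absent from models: ", fusion@gene3p)
    ext <- as.integer(geneBodyExtension)

    evalAssign <- function(chrom5, pos5, strand5, chrom3, pos3, strand3) {
        if (chrom5 != g5@chrom || chrom3 != g3@chrom)
            return(list(linked = FALSE, side5pOk = FALSE, side3pOk = FALSE,
                        orientationOk = FALSE, distance = NA_real_))
        ## 5' side: [RNA breakpoint, transcription end site] in transcript
        ## orientation
        side5 <- if (g5@strand == "+")
            pos5 >= fusion@pos5p && pos5 <= g5@txEnd + ext
        else
            pos5 <= fusion@pos5p && pos5 >= g5@txStart - ext
        ## 3' side: [transcription start site, RNA breakpoint]
        side3 <- if (g3@strand == "+")
            pos3 >= g3@txStart - ext && pos3 <= fusion@pos3p
        else
            pos3 <= g3@txEnd + ext && pos3 >= fusion@pos3p
        orient <- strand5 == g5@strand && strand3 == flipStrand(g3@strand)
        list(linked = side5 && side3 && orient, side5pOk = side5,
             side3pOk = side3, orientationOk = orient,
             distance = abs(pos5 - fusion@pos5p) + abs(pos3 - fusion@pos3p))
    }
    r1 <- evalAssign(sv@chromA, sv@posA, sv@strandA,
                     sv@chromB, sv@posB, sv@strandB)
    r2 <- evalAssign(sv@chromB, sv@posB, sv@strandB,
                     sv@chromA, sv@posA, sv@strandA)
    if (r1$linked) return(r1)
    if (r2$linked) return(r2)
    if (!is.na(r1$distance)) r1 else r2
}

#' Assign each fusion to its best-matching SV
#'
#' Evaluates \code{\link{linkFusionToSv}} for every fusion/SV pair and
#' assigns each fusion to the rule-satisfying SV with the smallest total
#' DNA-RNA breakpoint distance (splice parsimony: the causal junction for a
#' spliced fusion is the one in the immediately adjacent intron). Ties
#' break on SV input order.
#'
#' @param fusions List of \linkS4class{FusionTranscript}.
#' @param svs List of \linkS4class{SvJunction}.
#' @param genes Named list of \linkS4class{GeneModel}.
#' @param geneBodyExtension As \code{\link{linkFusionToSv}}.
#' @return data.frame with one row per fusion: fusion, linked, sv (index of
#'   the assigned SV or NA), candidates (number of rule-satisfying SVs),
#'   distance.
#' @export
linkFusions <- function(fusions, svs, genes, geneBodyExtension = 0L) {
    rows <- lapply(seq_along(fusions), function(i) {
        f <- fusions[[i]]
        res <- lapply(svs, linkFusionToSv, fusion = f, genes = genes,
                      geneBodyExtension = geneBodyExtension)
        ok <- vapply(res, function(r) isTRUE(r$linked), logical(1))
        dist <- vapply(res, function(r)
            if (is.na(r$distance)) Inf else r$distance, numeric(1))
        best <- if (any(ok)) which(ok)[which.min(dist[ok])] else NA_integer_
        data.frame(fusion = i,
                   gene5p = f@gene5p, gene3p = f@gene3p,
                   linked = any(ok), sv = best, candidates = sum(ok),
                   distance = if (any(ok)) dist[best] else NA_real_)
    })
    do.call(rbind, rows)
}

#' Match SV breakpoints to CNA segment boundaries
#'
#' Returns every copy-number segment boundary lying within
#' \code{toleranceBp} of either SV breakpoint (on the matching chromosome),
#' with its distance, sorted by distance then genomic coordinate.
#'
#' @param sv An \linkS4class{SvJunction}.
#' @param segments \link[GenomicRanges]{GRanges} of CNA segments.
#' @param toleranceBp Maximum breakpoint-boundary distance (default 1000).
#' @return data.frame with columns segment (index), boundary ("start" or
#'   "end"), chrom, boundary_pos, sv_breakpoint ("A"/"B"), distance.
#' @importFrom GenomicRanges seqnames start end
#' @export
matchSvToCna <- function(sv, segments, toleranceBp = 1000L) {
    out <- data.frame(segment = integer(), boundary = character(),
                      chrom = character(), boundary_pos = integer(),
                      sv_breakpoint = character(), distance = integer(),
                      stringsAsFactors = FALSE)
    if (!length(segments)) return(out)
    segChrom <- as.character(seqnames(segments))
    bps <- list(A = list(chrom = sv@chromA, pos = sv@posA),
                B = list(chrom = sv@chromB, pos = sv@posB))
    for (side in names(bps)) {
        bp <- bps[[side]]
        for (i in seq_along(segments)) {
            if (segChrom[i] != bp$chrom) next
            for (b in c("start", "end")) {
                bpos <- if (b == "start") start(segments)[i]
                        else end(segments)[i]
                d <- abs(bpos - bp$pos)
                if (d <= toleranceBp)
                    out <- rbind(out, data.frame(
                        segment = i, boundary = b, chrom = bp$chrom,
                        boundary_pos = bpos, sv_breakpoint = side,
                        distance = d, stringsAsFactors = FALSE))
            }
        }
    }
    out[order(out$distance, out$boundary_pos), , drop = FALSE]
}

## Gene names touched by each member type (used for shared-gene edges).
svGenes <- function(sv, genes) {
    hit <- vapply(genes, function(g)
        inGeneBody(g, sv@chromA, sv@posA) ||
        inGeneBody(g, sv@chromB, sv@posB), logical(1))
    names(genes)[hit]
}

cnaGenes <- function(segIndex, segments, genes) {
    chrom <- as.character(seqnames(segments))[segIndex]
    s <- start(segments)[segIndex]; e <- end(segments)[segIndex]
    hit <- vapply(genes, function(g)
        g@chrom == chrom && g@txStart <= e && g@txEnd >= s, logical(1))
    names(genes)[hit]
}

#' Integrate SVs, CNAs and fusions into review events
#'
#' Builds the graph whose nodes are the input members and whose edges are
#' (a) fusion-SV pairs satisfying the linking rule, (b) SV-CNA pairs with a
#' boundary match within tolerance, and (c) any two members sharing an
#' involved gene; returns its connected components as integrated events for
#' analyst review. Event ids are deterministic: members are sorted within
#' each event and events ordered by their smallest member key.
#'
#' @param svs List of \linkS4class{SvJunction}.
#' @param cnas \link[GenomicRanges]{GRanges} of CNA segments.
#' @param fusions List of \linkS4class{FusionTranscript}.
#' @param genes Named list of \linkS4class{GeneModel}.
#' @param toleranceBp SV-CNA boundary tolerance (default 1000).
#' @param geneBodyExtension As \code{\link{linkFusionToSv}}.
#' @return List of events, each a list with \code{id}, \code{members}
#'   (sorted keys like "fusion:1", "sv:2", "cna:1") and \code{genes}.
#' @importFrom GenomicRanges GRanges
#' @export
integrateEvents <- function(svs = list(), cnas = GRanges(),
                            fusions = list(), genes = list(),
                            toleranceBp = 1000L, geneBodyExtension = 0L) {
    keys <- c(if (length(fusions)) paste0("fusion:", seq_along(fusions)),
              if (length(svs)) paste0("sv:", seq_along(svs)),
              if (length(cnas)) paste0("cna:", seq_along(cnas)))
    n <- length(keys)
    if (!n) return(list())
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    union2 <- function(i, j) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[min(ri, rj)] <<- parent[max(ri, rj)] <<- min(ri, rj)
    }
    idx <- function(key) match(key, keys)

    memberGenes <- stats::setNames(vector("list", n), keys)
    for (i in seq_along(fusions))
        memberGenes[[paste0("fusion:", i)]] <-
            unique(c(fusions[[i]]@gene5p, fusions[[i]]@gene3p))
    for (i in seq_along(svs))
        memberGenes[[paste0("sv:", i)]] <- svGenes(svs[[i]], genes)
    for (i in seq_along(cnas))
        memberGenes[[paste0("cna:", i)]] <- cnaGenes(i, cnas, genes)

    ## (a) fusion-SV rule links
    for (i in seq_along(fusions)) for (j in seq_along(svs)) {
        ok <- tryCatch(
            linkFusionToSv(fusions[[i]], svs[[j]], genes,
                           geneBodyExtension)$linked,
            error = function(e) FALSE)
        if (isTRUE(ok)) union2(idx(paste0("fusion:", i)),
                               idx(paste0("sv:", j)))
    }
    ## (b) SV-CNA boundary matches
    for (j in seq_along(svs)) {
        m <- matchSvToCna(svs[[j]], cnas, toleranceBp)
        for (k in unique(m$segment))
            union2(idx(paste0("sv:", j)), idx(paste0("cna:", k)))
    }
    ## (c) shared-gene edges
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
        if (length(intersect(memberGenes[[i]], memberGenes[[j]])))
            union2(i, j)
    }

    roots <- vapply(seq_len(n), find, integer(1))
    comps <- split(keys, roots)
    comps <- lapply(comps, sort)
    comps <- comps[order(vapply(comps, `[`, character(1), 1L))]
    lapply(seq_along(comps), function(i) {
        members <- comps[[i]]
        list(id = sprintf("EV%03d", i), members = members,
             genes = sort(unique(unlist(memberGenes[members]))))
    })
}
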