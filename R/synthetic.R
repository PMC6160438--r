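#' @include AllClasses.R
NULL

## Deterministic per-site random streams: draws for one site/platform are
## keyed by (seed, site index, platform index), so editing one fixture site
## does not perturb the others.
withSiteSeed <- function(seed, siteIdx, platformIdx, expr) {
    old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else rm(list = ".Random.seed", envir = globalenv()))
    set.seed((as.numeric(seed) * 48271 + siteIdx * 7919 +
              platformIdx * 104729) %% 2147483647)
    force(expr)
}

#' Expected mutant allele fraction from purity/subclone/ploidy bookkeeping
#'
#' Exact allele-copy arithmetic for a somatic variant carried by a fraction
#' \code{cellFrac} of all cells in the specimen, against a diploid
#' background: heterozygous diploid carriers (1 mutant of 2 copies) give
#' \code{cellFrac/2}; copy-neutral LOH carriers (2 of 2) give
#' \code{cellFrac}; single-copy-loss carriers (1 of 1) give
#' \code{cellFrac/(2 - cellFrac)}.
#'
#' @param cellFrac Fraction of all cells carrying the variant (for a tumor
#'   sample, purity x subclone fraction; for a contaminated normal,
#'   contamination x subclone fraction).
#' @param state \code{"diploid"}, \code{"CN_LOH"} or \code{"LOSS"}.
#' @return Expected mutant read fraction.
#' @examples
#' expectedMutantFraction(0.077 * 0.80, "CN_LOH")  # 0.0616
#' @export
expectedMutantFraction <- function(cellFrac,
                                   state = c("diploid", "CN_LOH", "LOSS")) {
    state <- match.arg(state)
    if (any(cellFrac < 0 | cellFrac > 1))
        stop("'cellFrac' must lie in [0, 1]")
    switch(state,
           diploid = cellFrac / 2,
           CN_LOH = cellFrac,
           LOSS = cellFrac / (2 - cellFrac))
}

#' Specify the truth of a synthetic multi-platform sample
#'
#' Defaults emulate the modeled cohort: tumor purity 0.81 (the cohort
#' average; the cohort range 0.21-1.00 is exercised in tests), mean depths
#' 38X tumor WGS, 110X tumor WES, 30X RNA, 36X/103X normal WGS/WES, no
#' tumor-in-normal contamination. The region plan mixes clonal single-copy
#' loss and copy-neutral LOH regions with diploid background; somatic
#' variants are clonal heterozygous-diploid unless a subclone fraction or
#' ploidy state is given.
#'
#' @param purity Tumor purity in [0, 1].
#' @param contamination Fraction of tumor cells in the normal sample.
#' @param depths Named numeric: mean depths WGS, WES, RNA (tumor).
#' @param normalDepths Named numeric: mean depths WGS, WES (normal).
#' @param variants data.frame(chrom, pos, ref, alt, class, subcloneFraction,
#'   state) of somatic variants; a small default set is supplied.
#' @param regions data.frame(chrom, start, end, state, cellPct, nSites)
#'   copy-state plan; states "LOSS", "CN_LOH", "diploid"; cellPct is the
#'   percentage of tumor cells carrying the aberration.
#' @return List of class \code{sampleTruth}.
#' @export
sampleTruth <- function(purity = 0.81, contamination = 0,
                        depths = c(WGS = 38, WES = 110, RNA = 30),
                        normalDepths = c(WGS = 36, WES = 103),
                        variants = NULL, regions = NULL) {
    stopifnot(purity >= 0, purity <= 1,
              contamination >= 0, contamination <= 1)
    if (is.null(variants))
        variants <- data.frame(
            chrom = "chr1", pos = seq(1e6, by = 1e5, length.out = 200),
            ref = "A", alt = "T", class = "SNV",
            subcloneFraction = 1, state = "diploid",
            stringsAsFactors = FALSE)
    if (is.null(regions))
        regions <- data.frame(
            chrom = c("chr2", "chr2", "chr3", "chr3"),
            start = c(1e6, 2e7, 1e6, 2e7),
            end = c(1e7, 3e7, 1e7, 3e7),
            state = c("LOSS", "CN_LOH", "LOSS", "CN_LOH"),
            cellPct = 100, nSites = 500, stringsAsFactors = FALSE)
    ir <- IRanges::IRanges(regions$start, regions$end)
    byChrom <- split(ir, regions$chrom)
    for (grp in byChrom)
        if (length(grp) > 1L &&
            any(IRanges::countOverlaps(grp, grp) > 1L))
            stop("inconsistent region plan: overlapping states")
    structure(list(purity = purity, contamination = contamination,
                   depths = depths, normalDepths = normalDepths,
                   variants = variants, regions = regions),
              class = "sampleTruth")
}

#' Simulate a multi-platform sample with known truth
#'
#' Per somatic variant, the expected mutant fraction in tumor and normal is
#' computed exactly from purity/subclone/ploidy bookkeeping
#' (\code{\link{expectedMutantFraction}}; the normal-sample fraction uses
#' contamination x subclone fraction), then read counts are drawn
#' binomially at each platform's depth. Germline-heterozygous sites are
#' planted in each copy-state region and their tumor/germline allele
#' fractions drawn the same way, yielding the LOH segment scores an
#' upstream segmentation would report (phase-aware average over the
#' region's sites). Deterministic for a fixed seed; draws are keyed
#' per (site, platform, seed).
#'
#' @param truth A \code{\link{sampleTruth}}.
#' @param seed Integer seed.
#' @param errorRate Optional per-base sequencing error rate (default 0;
#'   the detection models assume error-free reads).
#' @return List with \code{variantTable} (per-variant per-platform counts
#'   plus expected fractions), \code{afTable} (per het site tumor/germline
#'   AFs), \code{segments} (\link[GenomicRanges]{GRanges} with ai and
#'   cnaShift), \code{somaticMafs} (observed tumor MAFs of diploid somatic
#'   variants at WGS), and \code{truth}.
#' @importFrom stats rbinom rpois
#' @importFrom GenomicRanges GRanges mcols
#' @importFrom IRanges IRanges
#' @export
simulateMultiplatformSample <- function(truth, seed, errorRate = 0) {
    stopifnot(inherits(truth, "sampleTruth"))
    v <- truth$variants
    nVar <- nrow(v)
    platforms <- names(truth$depths)
    ## per-site depth varies Poisson around the platform mean (coverage is
    ## never uniform); mutant reads binomial at the expected fraction
    drawCounts <- function(siteIdx, platformIdx, meanDepth, p) {
        p <- min(1, p + errorRate)
        withSiteSeed(seed, siteIdx, platformIdx, {
            depth <- rpois(1L, meanDepth)
            c(mutant = rbinom(1L, size = depth, prob = p), total = depth)
        })
    }

    vt <- v
    for (pi in seq_along(platforms)) {
        p <- platforms[pi]
        depthT <- as.integer(round(truth$depths[[p]]))
        depthN <- as.integer(round(
            if (p %in% names(truth$normalDepths))
                truth$normalDepths[[p]] else truth$depths[[p]]))
        prefix <- tolower(p)
        tm <- tt <- nm <- nt <- integer(nVar)
        for (i in seq_len(nVar)) {
            fTum <- expectedMutantFraction(
                truth$purity * v$subcloneFraction[i], v$state[i])
            fNor <- expectedMutantFraction(
                truth$contamination * v$subcloneFraction[i], v$state[i])
            ct <- drawCounts(i, pi, depthT, fTum)
            cn <- drawCounts(i, pi + 10L, depthN, fNor)
            tm[i] <- ct["mutant"]; tt[i] <- ct["total"]
            nm[i] <- cn["mutant"]; nt[i] <- cn["total"]
        }
        vt[[paste0(prefix, "_tumor_mutant")]] <- tm
        vt[[paste0(prefix, "_tumor_total")]] <- tt
        vt[[paste0(prefix, "_normal_mutant")]] <- nm
        vt[[paste0(prefix, "_normal_total")]] <- nt
        vt[[paste0(prefix, "_detected")]] <- tm >= 3L
        vt[[paste0(prefix, "_quality")]] <- ifelse(tm >= 3L, "high", "")
    }
    vt$expected_tumor_maf <- vapply(seq_len(nVar), function(i)
        expectedMutantFraction(truth$purity * v$subcloneFraction[i],
                               v$state[i]), numeric(1))

    ## germline-het sites in copy-state regions -> AF table + LOH segments
    reg <- truth$regions
    afRows <- list()
    ai <- numeric(nrow(reg)); cnaShift <- numeric(nrow(reg))
    depthWgsT <- as.integer(round(truth$depths[["WGS"]]))
    depthWgsN <- as.integer(round(truth$normalDepths[["WGS"]]))
    siteOffset <- nVar + 100L
    for (r in seq_len(nrow(reg))) {
        nSites <- reg$nSites[r]
        x <- truth$purity * reg$cellPct[r] / 100 * 100  # % of all cells
        trueAi <- switch(reg$state[r],
                         LOSS = expectedLoh(x, "LOSS"),
                         CN_LOH = expectedLoh(x, "CN_LOH", 0),
                         diploid = 0)
        cnaShift[r] <- if (reg$state[r] == "LOSS") -x / 100 else 0
        pos <- as.integer(seq(reg$start[r], reg$end[r],
                              length.out = nSites))
        phase <- withSiteSeed(seed, siteOffset + r, 99L,
                              sample(c(-1, 1), nSites, replace = TRUE))
        tAf <- gAf <- numeric(nSites)
        for (s in seq_len(nSites)) {
            idx <- siteOffset + r * 1000L + s
            tAf[s] <- withSiteSeed(seed, idx, 1L, {
                d <- max(1L, rpois(1L, depthWgsT))
                rbinom(1L, d, 0.5 + phase[s] * trueAi) / d
            })
            gAf[s] <- withSiteSeed(seed, idx, 2L, {
                d <- max(1L, rpois(1L, depthWgsN))
                rbinom(1L, d, 0.5) / d
            })
        }
        ## phase-aware segment score, as upstream segmentation reports
        ai[r] <- abs(mean(phase * (tAf - gAf)))
        afRows[[r]] <- data.frame(chrom = reg$chrom[r], pos = pos,
                                  tumor_af = tAf, germline_af = gAf,
                                  region = r, stringsAsFactors = FALSE)
    }
    segments <- GRanges(reg$chrom, IRanges(reg$start, reg$end))
    mcols(segments)$state <- reg$state
    mcols(segments)$ai <- ai
    mcols(segments)$cnaShift <- cnaShift

    diploidClonal <- v$state == "diploid" & vt$wgs_tumor_total > 0L
    somaticMafs <- (vt$wgs_tumor_mutant / vt$wgs_tumor_total)[diploidClonal]

    list(variantTable = vt, afTable = do.call(rbind, afRows),
         segments = segments, somaticMafs = somaticMafs, truth = truth)
}

#' Recover purity from a simulated sample
#'
#' Convenience wrapper running the purity estimator on a
#' \code{\link{simulateMultiplatformSample}} bundle: region tumor fractions
#' from the simulated LOH segment scores and copy-number shifts, MAF-based
#' estimate from the observed somatic MAFs.
#'
#' @param bundle Output of \code{\link{simulateMultiplatformSample}}.
#' @param seed Seed for the mixture fit.
#' @return A \linkS4class{PurityEstimate}.
#' @importFrom GenomicRanges mcols
#' @export
recoverPurity <- function(bundle, seed = 1L) {
    seg <- bundle$segments
    aberrant <- mcols(seg)$state != "diploid"
    purityFromSegments(
        lohScores = pmin(0.5, mcols(seg)$ai[aberrant]),
        cnaMags = pmin(1, abs(mcols(seg)$cnaShift[aberrant])),
        somaticDiploidMafs = bundle$somaticMafs,
        seed = seed)
}

#' Simulate a capture-validation experiment
#'
#' Draws capture read counts for markers of known status: somatic markers
#' draw tumor counts binomially at the true MAF and normal counts at
#' contamination x MAF; germline markers draw both samples around allele
#' fraction 0.5; wildtype markers yield zero mutant reads (no sequencing
#' error by default).
#'
#' @param statuses Character vector of true statuses (SOMATIC, GERMLINE,
#'   WILDTYPE).
#' @param tumorDepth,normalDepth Capture depths.
#' @param somaticMaf True tumor MAF of somatic markers (default 0.4).
#' @param contamination Tumor-in-normal contamination (default 0).
#' @param seed Integer seed.
#' @return data.frame with chrom, pos, ref, alt, counts and
#'   \code{true_status}.
#' @importFrom stats rbinom
#' @export
simulateCapvalExperiment <- function(statuses, tumorDepth = 200L,
                                     normalDepth = 200L, somaticMaf = 0.4,
                                     contamination = 0, seed = 1L) {
    n <- length(statuses)
    tm <- nm <- integer(n)
    for (i in seq_len(n)) {
        draws <- withSiteSeed(seed, i, 1L, {
            switch(statuses[i],
                SOMATIC = c(rbinom(1L, tumorDepth, somaticMaf),
                            rbinom(1L, normalDepth,
                                   contamination * somaticMaf)),
                GERMLINE = c(rbinom(1L, tumorDepth, 0.5),
                             rbinom(1L, normalDepth, 0.5)),
                WILDTYPE = c(0L, 0L),
                stop("unknown status: ", statuses[i]))
        })
        tm[i] <- draws[1L]; nm[i] <- draws[2L]
    }
    data.frame(chrom = "chr1", pos = seq_len(n) * 1000L, ref = "A",
               alt = "T", class = "SNV",
               tumor_mutant = tm, tumor_total = tumorDepth,
               normal_mutant = nm, normal_total = normalDepth,
               true_status = statuses, stringsAsFactors = FALSE)
}

#' Convert simulated capture markers to ValidationRecords
#'
#' @param df Output of \code{\link{simulateCapvalExperiment}}.
#' @return List of \linkS4class{ValidationRecord}.
#' @export
asValidationRecords <- function(df) {
    lapply(seq_len(nrow(df)), function(i)
        ValidationRecord(
            site = GenomicSite(df$chrom[i], df$pos[i], df$ref[i], df$alt[i]),
            tumor = ReadCounts(df$tumor_mutant[i],
                               df$tumor_total[i] - df$tumor_mutant[i]),
            normal = ReadCounts(df$normal_mutant[i],
                                df$normal_total[i] - df$normal_mutant[i]),
            variantClass = df$class[i]))
}

#' Deterministic gene/fusion/SV fixtures
#'
#' Named synthetic topologies for testing fusion-SV linking:
#' \describe{
#'   \item{fig2}{Two genes on chr10 (5' partner, plus strand, 5 exons) and
#'     chr4 (3' partner, plus strand, 15 exons); three fusion isoforms
#'     joining exon 1 of the 5' gene to exons 10, 11 and 12 of the 3' gene;
#'     two DNA SVs (a direct chr4-chr10 junction in intron 10 of the 3'
#'     gene, and a three-chromosome junction routed via chr11 whose
#'     gene-side breakpoints sit in intron 9 and intron 1); one amplicon
#'     segment whose boundary matches the three-chromosome SV breakpoint.}
#'   \item{minimal}{One gene, one self-fusion (tandem-duplication style)
#'     and one SV junction that links to it.}
#'   \item{strand_mirror}{The fig2 topology after coordinate reflection and
#'     strand flip of every gene and breakpoint; linking results are
#'     invariant under this transformation.}
#' }
#'
#' @param name One of \code{"fig2"}, \code{"minimal"},
#'   \code{"strand_mirror"}.
#' @return List with \code{genes} (named \linkS4class{GeneModel} list),
#'   \code{fusions}, \code{svs} and \code{cnas}
#'   (\link[GenomicRanges]{GRanges}).
#' @importFrom GenomicRanges GRanges mcols
#' @importFrom IRanges IRanges
#' @export
makeGeneFixture <- function(name = c("fig2", "minimal", "strand_mirror")) {
    name <- match.arg(name)
    if (name == "strand_mirror")
        return(reflectFixture(makeGeneFixture("fig2"), mirror = 3e6L))
    if (name == "minimal") {
        g <- GeneModel("GENE_M", "chr1", "+", 10001L, 50200L,
                       exonStarts = c(10001L, 20001L, 30001L),
                       exonEnds = c(10200L, 20200L, 30200L))
        ## tandem-duplication style self-fusion: exon 2 end spliced back to
        ## exon 2 start
        fus <- FusionTranscript("GENE_M", "GENE_M", "chr1", 20200L,
                                "chr1", 20001L, junctionReads = 15L)
        sv <- SvJunction("chr1", 25000L, "+", "chr1", 15000L, "-",
                         svType = "ITD", supportingReads = 10L)
        return(list(genes = list(GENE_M = g), fusions = list(fus),
                    svs = list(sv), cnas = GRanges()))
    }
    exonStartsB <- 1000001L + (0:14) * 10000L
    genes <- list(
        GENE_A = GeneModel("GENE_A", "chr10", "+", 500001L, 540300L,
                           exonStarts = 500001L + (0:4) * 10000L,
                           exonEnds = 500300L + (0:4) * 10000L),
        GENE_B = GeneModel("GENE_B", "chr4", "+", 1000001L, 1140200L,
                           exonStarts = exonStartsB,
                           exonEnds = exonStartsB + 199L))
    fusions <- list(
        exon10 = FusionTranscript("GENE_A", "GENE_B", "chr10", 500300L,
                                  "chr4", 1090001L, junctionReads = 8L),
        exon11 = FusionTranscript("GENE_A", "GENE_B", "chr10", 500300L,
                                  "chr4", 1100001L, junctionReads = 30L),
        exon12 = FusionTranscript("GENE_A", "GENE_B", "chr10", 500300L,
                                  "chr4", 1110001L, junctionReads = 22L))
    svs <- list(
        direct = SvJunction("chr10", 505000L, "+", "chr4", 1095000L, "-",
                            svType = "CTX", supportingReads = 25L),
        threeChrom = SvJunction("chr10", 506000L, "+", "chr4", 1085000L,
                                "-", svType = "CTX3_via_chr11",
                                supportingReads = 12L))
    cnas <- GRanges("chr4", IRanges(1085050L, 1250000L))
    mcols(cnas)$log2Ratio <- log2(22 / 2)
    mcols(cnas)$sample <- "SYNTH1"
    mcols(cnas)$nMarkers <- 500L
    list(genes = genes, fusions = fusions, svs = svs, cnas = cnas)
}

#' Reflect a gene/fusion/SV fixture
#'
#' Mirrors every coordinate (pos -> mirror - pos) and flips every strand,
#' preserving interval validity. Fusion-SV linking is invariant under this
#' transformation.
#'
#' @param fixture Output of \code{\link{makeGeneFixture}}.
#' @param mirror Reflection constant (must exceed all coordinates).
#' @return A fixture list of the same shape.
#' @importFrom GenomicRanges GRanges mcols seqnames start end
#' @importFrom IRanges IRanges
#' @export
reflectFixture <- function(fixture, mirror = 3e6L) {
    m <- as.integer(mirror)
    rg <- function(g) {
        ex <- g@exons
        GeneModel(g@name, g@chrom, flipStrand(g@strand),
                  txStart = m - g@txEnd, txEnd = m - g@txStart,
                  exonStarts = rev(m - IRanges::end(ex)),
                  exonEnds = rev(m - IRanges::start(ex)))
    }
    rf <- function(f) FusionTranscript(f@gene5p, f@gene3p, f@chrom5p,
                                       m - f@pos5p, f@chrom3p, m - f@pos3p,
                                       f@junctionReads, f@inFrame)
    rs <- function(s) SvJunction(s@chromA, m - s@posA, flipStrand(s@strandA),
                                 s@chromB, m - s@posB, flipStrand(s@strandB),
                                 s@svType, s@supportingReads)
    cn <- fixture$cnas
    rcn <- if (length(cn)) {
        out <- GRanges(seqnames(cn), IRanges(m - end(cn), m - start(cn)))
        mcols(out) <- mcols(cn)
        out
    } else cn
    list(genes = lapply(fixture$genes, rg),
         fusions = lapply(fixture$fusions, rf),
         svs = lapply(fixture$svs, rs), cnas = rcn)
}
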