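## Exhaustive interval oracle: positions binned before/inside/after the
## allowed interval on each side, crossed with gene strands and orientation
## correctness.
test_that("linking agrees with an exhaustive interval oracle", {
    for (strand5 in c("+", "-")) for (strand3 in c("+", "-")) {
        g5 <- GeneModel("G5", "chrA", strand5, 10000L, 60000L)
        g3 <- GeneModel("G3", "chrB", strand3, 10000L, 60000L)
        genes <- list(G5 = g5, G3 = g3)
        rna5 <- 30000L; rna3 <- 30000L
        fus <- FusionTranscript("G5", "G3", "chrA", rna5, "chrB", rna3)
        ## bins in transcript orientation for each side
        pos5Bins <- if (strand5 == "+")
            c(before = 20000L, inside = 45000L, after = 70000L)
        else c(before = 40000L, inside = 15000L, after = 5000L)
        pos3Bins <- if (strand3 == "+")
            c(before = 5000L, inside = 20000L, after = 40000L)
        else c(before = 70000L, inside = 45000L, after = 20000L)
        goodStrand5 <- strand5
        goodStrand3 <- if (strand3 == "+") "-" else "+"
        for (b5 in names(pos5Bins)) for (b3 in names(pos3Bins)) {
            for (orientOk in c(TRUE, FALSE)) {
                s5 <- if (orientOk) goodStrand5 else
                    setdiff(c("+", "-"), goodStrand5)
                sv <- SvJunction("chrA", pos5Bins[[b5]], s5,
                                 "chrB", pos3Bins[[b3]], goodStrand3)
                res <- linkFusionToSv(fus, sv, genes)
                want5 <- b5 == "inside"
                want3 <- b3 == "inside"
                want <- want5 && want3 && orientOk
                expect_identical(res$linked, want,
                                 info = sprintf("%s/%s %s/%s orient=%s",
                                                strand5, strand3, b5, b3,
                                                orientOk))
                if (want5 && want3) {
                    expect_identical(res$side5pOk, want5)
                    expect_identical(res$side3pOk, want3)
                    expect_identical(res$orientationOk, orientOk)
                }
            }
        }
        ## interval ends are inclusive ("the same or downstream")
        svEq <- SvJunction("chrA", rna5, goodStrand5, "chrB", rna3,
                           goodStrand3)
        expect_true(linkFusionToSv(fus, svEq, genes)$linked)
    }
})

test_that("linking errors identify a gene missing from the models", {
    fx <- makeGeneFixture("minimal")
    fus <- FusionTranscript("NOPE", "GENE_M", "chr1", 100, "chr1", 200)
    expect_error(linkFusionToSv(fus, fx$svs[[1]], fx$genes), "NOPE")
})

test_that("the complex-amplification fixture reproduces the linking pattern", {
    fx <- makeGeneFixture("fig2")
    links <- linkFusions(fx$fusions, fx$svs, fx$genes)
    ## exon-10 isoform: only the three-chromosome SV satisfies the rule
    ex10 <- links[links$fusion == 1, ]
    expect_true(ex10$linked)
    expect_equal(ex10$candidates, 1L)
    expect_equal(ex10$sv, 2L)
    ## intron-10 breakpoint is downstream of the exon-10 RNA breakpoint
    expect_false(linkFusionToSv(fx$fusions[[1]], fx$svs[[1]],
                                fx$genes)$side3pOk)
    ## exon-11/12 isoforms assign to the direct chr4-chr10 SV
    for (i in 2:3) {
        row <- links[links$fusion == i, ]
        expect_true(row$linked)
        expect_equal(row$sv, 1L)
    }
    ## the three-chromosome SV matches the amplicon boundary
    m <- matchSvToCna(fx$svs[[2]], fx$cnas, toleranceBp = 1000)
    expect_equal(nrow(m), 1L)
    expect_equal(m$distance, 50L)
    expect_equal(nrow(matchSvToCna(fx$svs[[1]], fx$cnas, 1000)), 0L)
})

test_that("linking is invariant under strand flip with coordinate mirroring", {
    fx <- makeGeneFixture("fig2")
    mir <- makeGeneFixture("strand_mirror")
    linksF <- linkFusions(fx$fusions, fx$svs, fx$genes)
    linksM <- linkFusions(mir$fusions, mir$svs, mir$genes)
    expect_equal(linksM$linked, linksF$linked)
    expect_equal(linksM$sv, linksF$sv)
    expect_equal(linksM$candidates, linksF$candidates)
    ## pairwise results identical too
    for (i in seq_along(fx$fusions)) for (j in seq_along(fx$svs)) {
        a <- linkFusionToSv(fx$fusions[[i]], fx$svs[[j]], fx$genes)
        b <- linkFusionToSv(mir$fusions[[i]], mir$svs[[j]], mir$genes)
        expect_identical(a$linked, b$linked)
    }
})

test_that("CNA boundary matching sorts by distance with ties kept", {
    seg <- GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(c(5000, 12000), c(9950, 20000)))
    sv <- SvJunction("chr1", 10000L, "+", "chr9", 500L, "-")
    m <- matchSvToCna(sv, seg, toleranceBp = 2050)
    ## boundaries at 9950 (d=50) and 12000 (d=2000)
    expect_equal(m$distance, c(50L, 2000L))
    expect_equal(m$boundary_pos, c(9950L, 12000L))
    ## equidistant boundaries: both returned, coordinate order
    seg2 <- GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(c(800, 10100), c(9900, 20000)))
    m2 <- matchSvToCna(sv, seg2, toleranceBp = 100)
    expect_equal(nrow(m2), 2L)
    expect_equal(m2$distance, c(100L, 100L))
    expect_equal(m2$boundary_pos, c(9900L, 10100L))
    expect_equal(nrow(matchSvToCna(sv, seg, toleranceBp = 10)), 0L)
})

test_that("integrated events partition the members", {
    fx <- makeGeneFixture("fig2")
    ev <- integrateEvents(fx$svs, fx$cnas, fx$fusions, fx$genes)
    expect_length(ev, 1L)
    expect_length(ev[[1]]$members, 6L)
    expect_setequal(ev[[1]]$genes, c("GENE_A", "GENE_B"))

    ## disjoint members give singleton events; membership partitions input
    gOther <- GeneModel("LONER", "chr9", "+", 1000L, 5000L)
    fusOther <- FusionTranscript("LONER", "LONER", "chr9", 2000, "chr9",
                                 1500)
    ev2 <- integrateEvents(fx$svs, fx$cnas, c(fx$fusions, fusOther),
                           c(fx$genes, list(LONER = gOther)))
    all_members <- unlist(lapply(ev2, `[[`, "members"))
    expect_equal(anyDuplicated(all_members), 0L)
    expect_length(all_members, 7L)
    expect_length(ev2, 2L)
    ## deterministic ids
    ev3 <- integrateEvents(fx$svs, fx$cnas, c(fx$fusions, fusOther),
                           c(fx$genes, list(LONER = gOther)))
    expect_identical(lapply(ev2, `[[`, "members"),
                     lapply(ev3, `[[`, "members"))
})
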