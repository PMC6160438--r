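test_that("variant table parsing preserves rows, order and annotations", {
    path <- withr::local_tempfile()
    writeLines(c(
        "chrom\tpos\tref\talt\tclass\tgene\twgs_detected\twgs_quality\twgs_tumor_mutant\twgs_tumor_total\twgs_normal_mutant\twgs_normal_total",
        "chr1\t100\tA\tT\tSNV\tKRAS\ttrue\thigh\t10\t30\t0\t28",
        "chr2\t200\tG\tGA\tINDEL\tTP53\tfalse\t\t1\t40\t0\t35"), path)
    calls <- parseVariantTable(path)
    expect_length(calls, 2L)
    expect_equal(site(calls[[1]])@pos, 100L)
    expect_equal(calls[[1]]@annotations$gene, "KRAS")
    expect_equal(variantClass(calls[[2]]), "INDEL")
    ev <- platformEvidence(calls[[1]], "WGS")
    expect_true(ev@detected)
    expect_equal(mutantReads(ev@tumor), 10L)

    writeLines("chrom\tpos\tref\talt\tclass", path)
    expect_length(parseVariantTable(path), 0L)
})

test_that("variant table errors name the offending column or line", {
    path <- withr::local_tempfile()
    writeLines(c("chrom\tpos\tref\talt", "chr1\t1\tA\tT"), path)
    expect_error(parseVariantTable(path), "class")

    writeLines(c(
        "chrom\tpos\tref\talt\tclass\twgs_tumor_mutant\twgs_tumor_total\twgs_normal_mutant\twgs_normal_total",
        "chr1\t100\tA\tT\tSNV\t5\t3\t0\t20"), path)
    expect_error(parseVariantTable(path), "line 2")

    writeLines(c(
        "chrom\tpos\tref\talt\tclass\twgs_tumor_mutant\twgs_tumor_total\twgs_normal_mutant\twgs_normal_total",
        "chr1\t100\tA\tT\tSNV\tx\t30\t0\t20"), path)
    expect_error(parseVariantTable(path), "non-numeric")
})

test_that("BED and SEG coordinate conventions convert at the boundary", {
    path <- withr::local_tempfile()
    writeLines("chr1\t0\t100\t0.3", path)
    gr <- parseSegments(path, "BED")
    expect_equal(GenomicRanges::start(gr), 1L)
    expect_equal(GenomicRanges::end(gr), 100L)
    expect_equal(gr$score, 0.3)

    writeLines(c("sample\tchrom\tstart\tend\tn_markers\tlog2",
                 "S1\tchr2\t500\t900\t40\t-1.0"), path)
    seg <- parseSegments(path, "SEG")
    expect_equal(GenomicRanges::start(seg), 500L)
    expect_equal(seg$cnaShift, -1.0)

    writeLines("chr1\t200\t100\t0.1", path)
    expect_error(parseSegments(path, "BED"), "reversed")
})

test_that("coordinate conversion is an involution on generated segments", {
    set.seed(42)
    path <- withr::local_tempfile()
    s0 <- sort(sample.int(1e6, 20))
    e0 <- s0 + sample.int(1e4, 20)
    writeLines(sprintf("chr%d\t%d\t%d\t%.3f", rep(1:2, 10), s0, e0,
                       runif(20, -1, 1)), path)
    gr <- parseSegments(path, "BED")
    path2 <- withr::local_tempfile()
    writeSegments(gr, path2, "BED")
    gr2 <- parseSegments(path2, "BED")
    expect_equal(GenomicRanges::start(gr2), GenomicRanges::start(gr))
    expect_equal(GenomicRanges::end(gr2), GenomicRanges::end(gr))
    expect_equal(gr2$score, gr$score)
    ## raw coordinates round-trip exactly
    expect_equal(GenomicRanges::start(gr2) - 1L, s0)
    expect_equal(GenomicRanges::end(gr2), e0)
})

test_that("BEDPE breakpoints are strand-aware and round-trip", {
    path <- withr::local_tempfile()
    writeLines("chr4\t999\t1000\tchr10\t1999\t2000\tCTX\t12\t+\t-", path)
    svs <- parseBreakpoints(path)
    expect_length(svs, 1L)
    sv <- svs[[1]]
    expect_equal(sv@posA, 1000L)  # '+': last retained base = interval end
    expect_equal(sv@posB, 2000L)  # '-': first retained base = start + 1
    expect_equal(sv@supportingReads, 12L)

    path2 <- withr::local_tempfile()
    writeBreakpoints(svs, path2)
    svs2 <- parseBreakpoints(path2)
    expect_equal(svs2[[1]]@posA, sv@posA)
    expect_equal(svs2[[1]]@posB, sv@posB)
    expect_equal(svs2[[1]]@strandB, "-")

    writeLines(character(), path)
    expect_length(parseBreakpoints(path), 0L)

    writeLines("chr4\t999\t1000\tchr10\t1999", path)
    expect_error(parseBreakpoints(path), "mate 2")

    writeLines("chr4\t999\t1000\tchr10\t1999\t2000\tCTX\t12\t+\t.", path)
    expect_error(parseBreakpoints(path), "strand")
})

test_that("refFlat gene models convert and validate", {
    path <- withr::local_tempfile()
    ## minus-strand gene: transcription start site is the genomic txEnd
    writeLines(paste("GENE1", "NM_1", "chr5", "-", "999", "5000", "999",
                     "5000", "2", "999,3000,", "1500,5000,", sep = "\t"),
               path)
    genes <- parseGeneModels(path)
    g <- genes$GENE1
    expect_equal(g@txStart, 1000L)
    expect_equal(txStartSite(g), 5000L)
    expect_equal(txEndSite(g), 1000L)
    expect_equal(IRanges::start(exons(g)), c(1000L, 3001L))

    path2 <- withr::local_tempfile()
    writeGeneModels(genes, path2)
    g2 <- parseGeneModels(path2)$GENE1
    expect_equal(g2@txStart, g@txStart)
    expect_equal(IRanges::end(exons(g2)), IRanges::end(exons(g)))

    writeLines(paste("GENE1", "NM_1", "chr5", "-", "999", "5000", "999",
                     "5000", "3", "999,3000,", "1500,5000,", sep = "\t"),
               path)
    expect_error(parseGeneModels(path), "exonCount mismatch")

    expect_error(GeneModel("G", "chr1", "+", 1, 1000,
                           exonStarts = c(1, 400), exonEnds = c(500, 900)),
                 "non-overlapping")
})

test_that("type invariants reject malformed objects", {
    expect_error(GenomicSite("chr1", 0, "A", "T"), ">= 1")
    expect_error(GenomicSite("chr1", 10, "A", "A"), "differ")
    expect_error(ReadCounts(5, 3, 7), "total")
    expect_error(PlatformEvidence(detected = TRUE), "quality")
    expect_error(SvJunction("chr1", 100, "*", "chr2", 200, "+"), "strand")
})

test_that("the minimal VCF reader maps sites and AD counts", {
    path <- withr::local_tempfile(fileext = ".vcf")
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
        "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR\tNORMAL",
        "chr7\t140453136\t.\tA\tT\t.\tPASS\tDP=60\tGT:AD\t0/1:20,10\t0/0:30,0"),
        path)
    calls <- readVcfVariants(path, platform = "WES")
    expect_length(calls, 1L)
    v <- calls[[1]]
    expect_equal(site(v)@pos, 140453136L)
    ev <- platformEvidence(v, "WES")
    expect_equal(mutantReads(ev@tumor), 10L)
    expect_equal(totalReads(ev@normal), 30L)
})

test_that("configuration merges user values over defaults", {
    cfg <- defaultConfig()
    expect_equal(cfg$crossval$min_base_quality, 15L)
    expect_equal(cfg$capval$alpha, 0.05)
    path <- withr::local_tempfile(fileext = ".yaml")
    writeLines(c("capval:", "  alpha: 0.01"), path)
    cfg2 <- readConfig(path)
    expect_equal(cfg2$capval$alpha, 0.01)
    expect_equal(cfg2$capval$germline_normal_maf, 0.2)  # untouched default
})
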