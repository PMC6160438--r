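test_that("read tallying excludes duplicates and low base quality", {
    obs <- data.frame(allele = c("mutant", "reference", "reference"),
                      baseQuality = 30, duplicate = FALSE)
    rc <- tallyReadCounts(obs)
    expect_equal(mutantReads(rc), 1L)
    expect_equal(referenceReads(rc), 2L)
    expect_equal(totalReads(rc), 3L)

    obs$duplicate <- c(TRUE, FALSE, FALSE)
    rc <- tallyReadCounts(obs)
    expect_equal(mutantReads(rc), 0L)
    expect_equal(totalReads(rc), 2L)

    ## boundary: quality 14 excluded, 15 included (inclusive floor)
    obs <- data.frame(allele = "mutant", baseQuality = c(14, 15),
                      duplicate = FALSE)
    expect_equal(mutantReads(tallyReadCounts(obs)), 1L)

    ## "other" alleles count toward depth only
    obs <- data.frame(allele = c("mutant", "other"), baseQuality = 30,
                      duplicate = FALSE)
    rc <- tallyReadCounts(obs)
    expect_equal(mutantReads(rc), 1L)
    expect_equal(totalReads(rc), 2L)

    expect_error(tallyReadCounts(data.frame(allele = "mutant",
                                            baseQuality = -1,
                                            duplicate = FALSE)),
                 "negative")
})

test_that("tallying matches direct enumeration and is permutation-invariant", {
    set.seed(7)
    for (i in 1:25) {
        n <- sample(0:12, 1)
        obs <- data.frame(
            allele = sample(c("mutant", "reference", "other"), n, TRUE),
            baseQuality = sample(0:40, n, TRUE),
            duplicate = sample(c(TRUE, FALSE), n, TRUE))
        rc <- tallyReadCounts(obs)
        ## direct enumeration oracle
        keep <- !obs$duplicate & obs$baseQuality >= 15
        expect_equal(mutantReads(rc), sum(obs$allele[keep] == "mutant"))
        expect_equal(totalReads(rc), sum(keep))
        ## permutation invariance
        if (n > 1) {
            perm <- obs[sample.int(n), , drop = FALSE]
            rc2 <- tallyReadCounts(perm)
            expect_equal(mutantReads(rc2), mutantReads(rc))
            expect_equal(referenceReads(rc2), referenceReads(rc))
        }
    }
})

test_that("support filter applies count and flank rules", {
    ok <- data.frame(readQuality = c(25, 25, 25),
                     flankLength = c(12, 5, 3))
    expect_true(supportFilter(ok)$pass)

    noFlank <- data.frame(readQuality = c(25, 25, 25),
                          flankLength = c(8, 5, 3))
    r <- supportFilter(noFlank)
    expect_false(r$pass)
    expect_equal(r$reason, "flank")

    tooFew <- data.frame(readQuality = c(40, 40), flankLength = c(15, 15))
    r <- supportFilter(tooFew)
    expect_false(r$pass)
    expect_equal(r$reason, "count")

    r <- supportFilter(data.frame(readQuality = numeric(),
                                  flankLength = numeric()))
    expect_false(r$pass)
    expect_equal(r$reason, "no support")
})

test_that("support filter agrees with rule enumeration over a grid", {
    ## exhaustive oracle over 0-4 reads x quality {19,20,40} x flank {8,10}
    for (n in 0:4) {
        if (n == 0) {
            expect_false(supportFilter(
                data.frame(readQuality = numeric(),
                           flankLength = numeric()))$pass)
            next
        }
        grid <- expand.grid(rep(list(c(19, 40)), n))
        flanks <- expand.grid(rep(list(c(8, 12)), n))
        for (qi in seq_len(nrow(grid))) for (fi in seq_len(nrow(flanks))) {
            q <- as.numeric(grid[qi, ]); fl <- as.numeric(flanks[fi, ])
            got <- supportFilter(data.frame(readQuality = q,
                                            flankLength = fl))$pass
            want <- sum(q >= 20) >= 3 && any(fl >= 10)
            expect_identical(got, want)
        }
    }
})

test_that("the four cross-validation criteria fire in order", {
    ## criterion 1: both DNA platforms detect
    v <- makeCall(wgs = evd(10, 30, 0, 25, TRUE, "high"),
                  wes = evd(12, 50, 0, 40, TRUE, "low"))
    r <- crossValidate(v)
    expect_equal(r$status, "CROSS_VALIDATED")
    expect_equal(r$criterion, 1L)

    ## criterion 2: tumor support, clean normal, in the other platform
    v <- makeCall(wgs = evd(10, 30, 0, 25, TRUE, "low"),
                  wes = evd(1, 40, 0, 10))
    r <- crossValidate(v)
    expect_equal(r$criterion, 2L)
    expect_equal(r$supportingPlatform, "WES")

    ## criterion 3: high-quality call, deep clean normal, no tumor support
    v <- makeCall(wgs = evd(10, 30, 0, 25, TRUE, "high"),
                  wes = evd(0, 40, 0, 20))
    expect_equal(crossValidate(v)$criterion, 3L)

    ## criterion 4: high-quality call with covered normal plus RNA support
    v <- makeCall(wes = evd(10, 30, 0, 25, TRUE, "high"),
                  rna = evd(2, 15))
    expect_equal(crossValidate(v)$criterion, 4L)

    ## unconfirmed: low quality, no cross-platform support
    v <- makeCall(wes = evd(10, 30, 0, 25, TRUE, "low"),
                  wgs = evd(0, 40, 0, 35), rna = evd(0, 10))
    r <- crossValidate(v)
    expect_equal(r$status, "UNCONFIRMED")
    expect_true(is.na(r$criterion))

    expect_error(crossValidate(makeCall()), "no detected platform")
})

test_that("classifier agrees with an independent decision table on a grid", {
    depths <- c(0, 19, 20, 50)
    counts <- c(0, 1, 5)
    cases <- 0L
    for (detW in c(TRUE, FALSE)) for (detE in c(TRUE, FALSE)) {
        if (!detW && !detE) next
        for (qW in c("high", "low")) for (qE in c("high", "low")) {
            for (tmO in counts) for (nmO in c(0L, 1L)) {
                for (ntO in depths) for (ntD in depths) {
                    for (rnaM in c(0L, 1L)) {
                        mkDna <- function(det, q)
                            if (det) evd(5, 30, 0, ntD, TRUE, q)
                            else evd(tmO, 30, nmO, ntO + nmO, FALSE)
                        v <- makeCall(wgs = mkDna(detW, qW),
                                      wes = mkDna(detE, qE),
                                      rna = evd(rnaM, 10))
                        got <- crossValidate(v)$criterion
                        want <- crossValOracle(
                            det = c(WGS = detW, WES = detE),
                            qual = c(WGS = qW, WES = qE),
                            tumorMut = c(WGS = if (detW) 5 else tmO,
                                         WES = if (detE) 5 else tmO),
                            normMut = c(WGS = if (detW) 0 else nmO,
                                        WES = if (detE) 0 else nmO),
                            normTot = c(WGS = if (detW) ntD else ntO + nmO,
                                        WES = if (detE) ntD else ntO + nmO),
                            rnaTumorMut = rnaM)
                        expect_identical(got, want)
                        cases <- cases + 1L
                    }
                }
            }
        }
    }
    expect_gt(cases, 1000L)
})

test_that("adding cross-platform support never revokes validation", {
    set.seed(11)
    for (i in 1:60) {
        normMut <- sample(0:1, 1)
        base <- makeCall(
            wgs = evd(sample(0:8, 1), 30, 0, sample(c(0, 19, 25), 1),
                      TRUE, sample(c("high", "low"), 1)),
            wes = evd(sample(0:2, 1), 30, normMut,
                      normMut + sample(0:40, 1)),
            rna = evd(sample(0:1, 1), 10))
        before <- crossValidate(base)$status
        ## add mutant support in WES tumor (keep normal unchanged)
        ev <- base@evidence
        wes <- ev$WES
        ev$WES <- PlatformEvidence(
            ReadCounts(mutantReads(wes@tumor) + 3,
                       referenceReads(wes@tumor),
                       totalReads(wes@tumor) + 3),
            wes@normal, wes@detected, wes@quality)
        more <- VariantCall(base@site, evidence = ev)
        after <- crossValidate(more)$status
        if (before == "CROSS_VALIDATED")
            expect_equal(after, "CROSS_VALIDATED")
    }
})

test_that("table-level cross-validation appends status and audit trail", {
    calls <- list(
        makeCall(wgs = evd(10, 30, 0, 25, TRUE, "high"),
                 wes = evd(12, 50, 0, 40, TRUE, "high")),
        makeCall(wes = evd(10, 30, 0, 25, TRUE, "low"),
                 wgs = evd(0, 40, 0, 35)))
    out <- crossValidateTable(calls)
    expect_equal(out$status, c("CROSS_VALIDATED", "UNCONFIRMED"))
    audit <- attr(out, "audit")
    expect_equal(nrow(audit), 2L)
    expect_match(audit$rule[1], "criterion1")
})
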