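catalogRecords <- function() {
    data.frame(
        gene = c(rep("TSG1", 6), rep("ONC1", 5), rep("PASS1", 2)),
        site = c(paste0("TSG1:", 1:6), rep("ONC1:600", 4), "ONC1:7",
                 "PASS1:1", "PASS1:2"),
        mutationClass = c(rep("nonsense", 4), "missense", "frameshift",
                          rep("missense", 5), "missense", "missense"),
        sample = c(paste0("S", 1:6), paste0("S", 7:11), "S12", "S13"),
        study = "STUDY_A",
        verified = TRUE, genomeWide = TRUE,
        codingCount = 20L, stringsAsFactors = FALSE)
}

test_that("catalog curation applies the polymorphism and hypermutator filters", {
    rec <- catalogRecords()
    lists <- curateDriverCatalog(rec)
    expect_true("TSG1" %in% lists$tumorSuppressors)
    expect_equal(lists$oncogenes$ONC1, "ONC1:600")
    expect_false("PASS1" %in% lists$tumorSuppressors)

    ## control-carrier boundary: 10 carriers retained, 11 dropped
    carriers <- c("TSG1:1" = 11L, "TSG1:2" = 10L)
    filtered <- curateDriverCatalog(rec, carriers)
    expect_false("TSG1:1" %in% filtered$survivors$site)
    expect_true("TSG1:2" %in% filtered$survivors$site)

    ## non-verified or non-genome-wide records are dropped up front
    rec2 <- rec
    rec2$verified[rec2$gene == "ONC1"] <- FALSE
    expect_null(curateDriverCatalog(rec2)$oncogenes$ONC1)
})

test_that("hypermutator removal is conjunctive: count floor AND top decile", {
    rec <- catalogRecords()
    ## 20 samples in the study; S7 has 150 coding variants, top 5%
    extra <- data.frame(gene = "FILLER", site = paste0("F:", 1:9),
                        mutationClass = "missense",
                        sample = paste0("X", 1:9), study = "STUDY_A",
                        verified = TRUE, genomeWide = TRUE, codingCount = 10L,
                        stringsAsFactors = FALSE)
    rec$codingCount[rec$sample == "S7"] <- 150L
    out <- curateDriverCatalog(rbind(rec, extra))
    expect_false("S7" %in% out$survivors$sample)
    ## 150 coding variants but mid-pack in a hypermutated study: retained
    rec3 <- rbind(rec, extra)
    rec3$codingCount <- 150L
    rec3$codingCount[rec3$sample %in% paste0("X", 1:9)] <- 500L
    out3 <- curateDriverCatalog(rec3)
    expect_true("S7" %in% out3$survivors$sample)
    ## top decile but below the count floor: retained
    rec4 <- catalogRecords()
    rec4$codingCount[rec4$sample == "S7"] <- 90L
    out4 <- curateDriverCatalog(rbind(rec4, extra))
    expect_true("S7" %in% out4$survivors$sample)

    rec5 <- catalogRecords()
    rec5$study <- NA
    expect_error(curateDriverCatalog(rec5), "study")
})

test_that("curation is idempotent on its own survivors", {
    rec <- catalogRecords()
    rec$codingCount[rec$sample == "S7"] <- 150L
    first <- curateDriverCatalog(rec)
    second <- curateDriverCatalog(first$survivors)
    expect_identical(first$tumorSuppressors, second$tumorSuppressors)
    expect_identical(first$oncogenes, second$oncogenes)
    expect_identical(first$survivors, second$survivors)
})

driverLists <- function() {
    list(tumorSuppressors = "TP53L",
         oncogenes = list(KRASL = "KRASL:12"),
         fusionGenes = "FUSG",
         cnaGenes = c(MYCNL = "amplification", CDKN2AL = "deletion"))
}

test_that("review flags follow list membership and role consistency", {
    lists <- driverLists()
    r <- reviewFlag("TP53L", "nonsense", lists)
    expect_true(r$flagged)
    expect_equal(r$priority, "elevated")
    r <- reviewFlag("RANDOM", "missense", lists)
    expect_false(r$flagged)
    r <- reviewFlag("KRASL", "missense", lists, siteKey = "KRASL:12")
    expect_equal(r$priority, "elevated")
    r <- reviewFlag("KRASL", "missense", lists, siteKey = "KRASL:99")
    expect_true(r$flagged)
    expect_equal(r$priority, "normal")
    ## every CNA/SV is flagged; role-consistent direction elevates
    r <- reviewFlag("MYCNL", "amplification", lists)
    expect_true(r$flagged)
    expect_equal(r$priority, "elevated")
    r <- reviewFlag("MYCNL", "deletion", lists)
    expect_equal(r$priority, "normal")
    r <- reviewFlag("UNLISTED", "deletion", lists)
    expect_true(r$flagged)
})

tierContext <- function() {
    list(knownCancerTypes = c("AML", "NBL"),
         geneRoles = list(
             TSGA = list(role = "tumor_suppressor", cancerTypes = "AML"),
             ONCA = list(role = "oncogene", cancerTypes = "AML")),
         diagnosticMarkers = list(AML = c("ONCA:fusion", "TSGA:deletion")))
}

test_that("tier rules fire in the stated precedence", {
    ctx <- tierContext()
    expect_equal(assignTier("ONCA", "missense", TRUE, "NBL", ctx)$rule,
                 "P-i")   # hotspot, any cancer type
    expect_equal(assignTier("TSGA", "frameshift", FALSE, "AML", ctx)$rule,
                 "P-ii")
    expect_equal(assignTier("ONCA", "fusion", FALSE, "AML", ctx)$rule,
                 "P-iii")
    r <- assignTier("TSGA", "missense", FALSE, "AML", ctx)
    expect_equal(r$tier, "LP")   # associated gene, unclear impact
    expect_equal(r$rule, "LP-i")
    r <- assignTier("TSGA", "nonsense", FALSE, "NBL", ctx)
    expect_equal(r$tier, "LP")   # clear impact, no association to this type
    expect_equal(r$rule, "LP-ii")
    r <- assignTier("TSGA", "missense", FALSE, "NBL", ctx)
    expect_equal(r$tier, "UNCERTAIN")
    expect_equal(r$rule, "U-i")
    expect_equal(assignTier("RANDOM", "missense", FALSE, "AML", ctx)$rule,
                 "default")
    expect_error(assignTier("TSGA", "missense", FALSE, "OSTEO", ctx),
                 "unknown cancer type")
})

test_that("tiering is total and hotspot removal never raises the tier", {
    ctx <- tierContext()
    ord <- c(P = 3L, LP = 2L, UNCERTAIN = 1L)
    classes <- c("missense", "nonsense", "frameshift", "splice", "other",
                 "fusion", "amplification", "deletion", "arm_level")
    genes <- c("TSGA", "ONCA", "RANDOM")
    for (g in genes) for (cl in classes) for (ct in c("AML", "NBL")) {
        hot <- assignTier(g, cl, TRUE, ct, ctx)
        cold <- assignTier(g, cl, FALSE, ct, ctx)
        expect_true(hot$tier %in% names(ord))
        expect_true(cold$tier %in% names(ord))
        expect_gte(ord[[hot$tier]], ord[[cold$tier]])
    }
})

test_that("tiering agrees with an independently coded decision table", {
    ctx <- tierContext()
    ## independent re-statement of the rules over the annotation grid
    oracle <- function(g, cl, hot, ct) {
        role <- ctx$geneRoles[[g]]
        cg <- !is.null(role)
        assoc <- cg && ct %in% role$cancerTypes
        tsg <- cg && identical(role$role, "tumor_suppressor")
        svc <- cl %in% c("fusion", "amplification", "deletion", "arm_level",
                         "truncation_sv")
        trunc <- cl %in% c("nonsense", "frameshift", "splice")
        clear <- (trunc && tsg) || hot || (svc && cg)
        if (hot && cg && !svc) return("P")
        if (trunc && tsg && assoc) return("P")
        if (svc && paste0(g, ":", cl) %in% ctx$diagnosticMarkers[[ct]])
            return("P")
        if (assoc && !clear) return("LP")
        if (clear && cg && !assoc) return("LP")
        "UNCERTAIN"
    }
    classes <- c("missense", "nonsense", "splice", "fusion", "deletion",
                 "arm_level")
    for (g in c("TSGA", "ONCA", "RANDOM")) for (cl in classes)
        for (hot in c(TRUE, FALSE)) for (ct in c("AML", "NBL")) {
            expect_equal(assignTier(g, cl, hot, ct, ctx)$tier,
                         oracle(g, cl, hot, ct),
                         info = paste(g, cl, hot, ct))
        }
})
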