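writeG2G <- function(rows) {
    p <- tempfile(fileext = ".tsv")
    writeLines(c("#tax_id\tGeneID\tGO_ID\tEvidence\tQualifier\tGO_term\tPubMed\tCategory",
                 rows), p)
    p
}

test_that("readGene2GO strips placeholders, NOT qualifiers and duplicates", {
    p <- writeG2G(c(
        "9606\t1\tGO:0000002\tIDA\t\tx\t-\tProcess",
        "9606\t1\tGO:0008150\tIEA\t\tx\t-\tProcess",      # placeholder root
        "9606\t2\tGO:0000002\tIMP\tNOT\tx\t-\tProcess",   # NOT qualifier
        "9606\t2\tGO:0000003\tIDA\t\tx\t-\tFunction",
        "9606\t2\tGO:0000003\tIEA\t\tx\t-\tFunction"))    # duplicate pair
    tab <- readGene2GO(p)
    a <- annotations(tab)
    expect_equal(nrow(a), 2L)
    expect_false(any(a$goTerm == "GO:0008150"))
    expect_false(any(grepl("NOT", a$qualifier)))
    expect_equal(a$category, c("biological_process",
                               "molecular_function"))
})

test_that("taxa and evidence filters compose order-independently", {
    p <- writeG2G(c(
        "9606\t1\tGO:0000010\tIDA\t\tx\t-\tProcess",
        "9606\t2\tGO:0000011\tIEA\t\tx\t-\tProcess",
        "10090\t3\tGO:0000012\tIDA\t\tx\t-\tProcess",
        "7227\t4\tGO:0000013\tISS\t\tx\t-\tProcess"))
    both <- annotations(readGene2GO(p, taxa = c(9606, 10090),
                                    evidenceAllow = "IDA"))
    taxaFirst <- annotations(readGene2GO(p, taxa = c(9606, 10090)))
    taxaFirst <- taxaFirst[taxaFirst$evidence == "IDA", ]
    evFirst <- annotations(readGene2GO(p, evidenceAllow = "IDA"))
    evFirst <- evFirst[evFirst$taxon %in% c(9606, 10090), ]
    rownames(taxaFirst) <- rownames(evFirst) <- NULL
    expect_equal(both, taxaFirst)
    expect_equal(both, evFirst)
    expect_equal(both$geneId, c("1", "3"))
})

test_that("readGene2GO names the missing column in schema errors", {
    p <- tempfile(fileext = ".tsv")
    writeLines(c("#tax_id\tGeneID\tEvidence\tQualifier\tCategory",
                 "9606\t1\tIDA\t\tProcess"), p)
    expect_error(readGene2GO(p), "GO_ID")
})

test_that("synthetic gene2go filtering matches the generator's ledger", {
    res <- runSimulate("planted-pairs", seed = 13,
                       outDir = file.path(tempdir(), "io-ledger"))
    led <- res$ledger
    raw <- readLines(res$files[["gene2go"]])
    nRaw <- sum(!startsWith(raw, "#"))
    expect_equal(nRaw, led$fileRowCounts$gene2go)
    tab <- readGene2GO(res$files[["gene2go"]], taxa = 9606)
    ## raw rows minus non-target taxa, NOT rows, placeholder rows and
    ## duplicates equals the surviving annotation count
    g <- led$gene2go
    expect_equal(nrow(annotations(tab)),
                 nRaw - g$nNonTargetTaxonRows - g$nNotRows -
                     g$nPlaceholderRows - g$nDuplicatedRows)
})

test_that("readGeneDisease keeps direct rows and normalizes disease ids", {
    p <- tempfile(fileext = ".tsv")
    writeLines(c(
        "# curated associations",
        "# GeneSymbol\tGeneID\tDiseaseName\tDiseaseID\tDirectEvidence",
        "ESR1\t2099\tosteoporosis, postmenopausal\tMESH:D015663\ttherapeutic",
        "TP53\t7157\tneoplasms\tD009369\tmarker/mechanism",
        "BRCA1\t672\tbreast neoplasms\tMESH:D001943\tmarker/mechanism",
        "EGFR\t1956\tlung neoplasms\tMESH:D008175\t",
        "KRAS\t3845\tcolonic neoplasms\tMESH:D003110\t"), p)
    tab <- readGeneDisease(p, directOnly = TRUE)
    a <- associations(tab)
    expect_equal(nrow(a), 3L)
    expect_true("MESH:D015663" %in% a$objectId)
    expect_equal(a$objectId[a$subjectId == "7157"], "MESH:D009369")
    all5 <- readGeneDisease(p, directOnly = FALSE)
    expect_equal(nrow(associations(all5)), 5L)
})

test_that("malformed disease ids are skipped with a message", {
    p <- tempfile(fileext = ".tsv")
    writeLines(c(
        "GeneSymbol\tGeneID\tDiseaseName\tDiseaseID\tDirectEvidence",
        "A\t1\tgood\tMESH:D000001\tmarker/mechanism",
        "B\t2\tbad\t???\tmarker/mechanism"), p)
    expect_message(tab <- readGeneDisease(p), "malformed disease id")
    expect_equal(nrow(associations(tab)), 1L)
})

test_that("readChemAssoc applies the therapeutic evidence filter", {
    p <- tempfile(fileext = ".tsv")
    writeLines(c(
        "# ChemicalName\tChemicalID\tDiseaseName\tDiseaseID\tDirectEvidence",
        "a\tMESH:C1\tx\tMESH:D1\ttherapeutic",
        "b\tMESH:C2\tx\tMESH:D1\tTherapeutic",
        "c\tMESH:C3\tx\tMESH:D1\tmarker/mechanism",
        "d\tMESH:C4\ty\tMESH:D2\tmarker/mechanism",
        "e\tMESH:C5\ty\tMESH:D2\tmarker/mechanism"), p)
    expect_equal(nrow(associations(readChemAssoc(p, "therapeutic"))), 2L)
    expect_equal(nrow(associations(readChemAssoc(p))), 5L)
    expect_equal(associationType(readChemAssoc(p)), "chem_disease")
})

test_that("readDiseaseHierarchy loads parents and slim labels, rejects cycles", {
    p <- tempfile(fileext = ".tsv")
    writeLines(c(
        "# DiseaseID\tDiseaseName\tParentIDs\tSlimCategories",
        "MESH:D009369\tcancer\t\tcancer",
        "MESH:D008175\tlung neoplasm\tMESH:D009369\tcancer|respiratory tract disease"),
        p)
    h <- readDiseaseHierarchy(p)
    expect_true("MESH:D008175" %in% descendants(h, "MESH:D009369"))
    expect_setequal(slimCategories(h)[["MESH:D008175"]],
                    c("cancer", "respiratory tract disease"))

    p2 <- tempfile(fileext = ".tsv")
    writeLines(c("DiseaseID\tDiseaseName\tParentIDs\tSlimCategories",
                 "MESH:D1\ta\tMESH:D2\t",
                 "MESH:D2\tb\tMESH:D1\t"), p2)
    expect_error(readDiseaseHierarchy(p2), "cyclic")
})

test_that("hierarchy closure equals a naive traversal on a random tree", {
    set.seed(42)
    n <- 50L
    ids <- sprintf("MESH:D%06d", seq_len(n))
    parent <- c("", vapply(2:n, function(i)
        sample(ids[seq_len(i - 1L)], 1L), ""))
    p <- tempfile(fileext = ".tsv")
    writeLines(c("DiseaseID\tDiseaseName\tParentIDs\tSlimCategories",
                 paste(ids, paste0("d", seq_len(n)), parent, "",
                       sep = "\t")), p)
    h <- readDiseaseHierarchy(p)
    edges <- edgeDf(ids[-1L], parent[-1L])
    for (d in sample(ids, 10L))
        expect_equal(ancestors(h, d), bruteAncestors(edges, d))
    naiveDesc <- function(d)
        sort(unique(c(d, unlist(lapply(ids[parent == d], naiveDesc)))))
    for (d in sample(ids, 10L))
        expect_equal(descendants(h, d), naiveDesc(d))
})

test_that("generator round trip: gene-disease reader recovers the ledger counts", {
    res <- runSimulate("basic", seed = 31,
                       outDir = file.path(tempdir(), "io-rt"))
    led <- res$ledger
    direct <- readGeneDisease(res$files[["gene_disease"]],
                              directOnly = TRUE)
    expect_equal(nrow(associations(direct)),
                 led$geneDisease$nDirectRows)
    all <- readGeneDisease(res$files[["gene_disease"]],
                           directOnly = FALSE)
    expect_equal(nrow(associations(all)),
                 led$geneDisease$nDirectRows + led$geneDisease$nInferredRows)
    ## per-disease curated gene counts match the ledger exactly
    a <- associations(direct)
    counts <- tapply(a$subjectId, a$objectId,
                     function(v) length(unique(v)))
    for (d in names(led$diseaseGeneCounts))
        expect_equal(unname(counts[[d]]), led$diseaseGeneCounts[[d]])
})
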