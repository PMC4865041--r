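## small synthetic pair-matrix instance used by several tests
makePairInstance <- function(seed, nDiseases = 12, nGenes = 40,
                             nTerms = 25) {
    set.seed(seed)
    diseases <- sprintf("MESH:D%06d", seq_len(nDiseases))
    gdDf <- unique(data.frame(
        subjectId = as.character(sample(nGenes, nDiseases * 8,
                                        replace = TRUE)),
        objectId = sample(diseases, nDiseases * 8, replace = TRUE),
        stringsAsFactors = FALSE))
    annDf <- unique(data.frame(
        geneId = as.character(sample(nGenes, nGenes * 4, replace = TRUE)),
        goTerm = sprintf("GO:%07d", sample(nTerms, nGenes * 4,
                                           replace = TRUE)),
        stringsAsFactors = FALSE))
    gd <- gdTable(gdDf$subjectId, gdDf$objectId)
    inf <- suppressWarnings(inferGODisease(
        annTable(annDf$geneId, annDf$goTerm), gd))
    list(gd = gd, inf = inf, gdDf = gdDf, annDf = annDf)
}

test_that("pair counts follow the handshake formula", {
    x <- makePairInstance(1, nDiseases = 2)
    rec <- buildPairMatrix(x$gd, x$inf)
    n <- length(unique(inferenceRecords(x$inf)$disease))
    expect_equal(nrow(rec), choose(n, 2))
    x2 <- makePairInstance(2, nDiseases = 9)
    rec2 <- buildPairMatrix(x2$gd, x2$inf)
    n2 <- length(unique(inferenceRecords(x2$inf)$disease))
    expect_equal(nrow(rec2), n2 * (n2 - 1) / 2)
    expect_true(all(rec2$diseaseA < rec2$diseaseB))
})

test_that("every matrix field equals a naive per-pair set computation", {
    x <- makePairInstance(7)
    rec <- buildPairMatrix(x$gd, x$inf)
    r <- inferenceRecords(x$inf)
    universe <- length(unique(r$goTerm))
    for (i in seq_len(nrow(rec))) {
        A <- rec$diseaseA[i]; B <- rec$diseaseB[i]
        gA <- unique(x$gdDf$subjectId[x$gdDf$objectId == A])
        gB <- unique(x$gdDf$subjectId[x$gdDf$objectId == B])
        tA <- unique(r$goTerm[r$disease == A])
        tB <- unique(r$goTerm[r$disease == B])
        expect_equal(rec$nGenesA[i], length(gA))
        expect_equal(rec$nGenesB[i], length(gB))
        expect_equal(rec$nSharedGenes[i], length(intersect(gA, gB)))
        expect_equal(rec$nGoA[i], length(tA))
        expect_equal(rec$nGoB[i], length(tB))
        expect_equal(rec$nSharedGo[i], length(intersect(tA, tB)))
        expect_equal(rec$jaccard[i],
                     length(intersect(tA, tB)) / length(union(tA, tB)))
        expect_equal(rec$pRaw[i],
                     hypergeomOverlapP(length(intersect(tA, tB)),
                                       length(tA), length(tB), universe))
        expect_true(rec$nSharedGenes[i] <= min(rec$nGenesA[i],
                                               rec$nGenesB[i]))
        expect_true(rec$nSharedGo[i] <= min(rec$nGoA[i], rec$nGoB[i]))
    }
    expect_equal(rec$pAdj, pmin(1, nrow(rec) * rec$pRaw))
})

test_that("the disjoint-gene filter keeps only gene-disjoint, GO-sharing pairs", {
    rec <- data.frame(diseaseA = "a", diseaseB = "b", nGenesA = 10L,
                      nGenesB = 10L, nSharedGenes = c(1L, 0L, 0L),
                      nGoA = 5L, nGoB = 5L, nSharedGo = c(3L, 0L, 3L),
                      jaccard = 0.1, pctA = 1, pctB = 1, pRaw = 0.5,
                      pAdj = 1)
    out <- filterDisjointGenes(rec)
    expect_equal(nrow(out), 1L)
    expect_equal(out$nSharedGenes, 0L)
    expect_equal(out$nSharedGo, 3L)
})

test_that("gene parity at A=50 admits exactly 45-55 and matches a sweep oracle", {
    rec <- data.frame(diseaseA = "a", diseaseB = sprintf("b%03d", 1:100),
                      nGenesA = 50L, nGenesB = 1:100,
                      nSharedGenes = 0L, nGoA = 5L, nGoB = 5L,
                      nSharedGo = 1L, jaccard = 0.1, pctA = 1, pctB = 1,
                      pRaw = 0.5, pAdj = 1)
    keep <- filterGeneParity(rec)
    expect_equal(range(keep$nGenesB), c(45L, 55L))
    ## brute-force application of the stated rule
    oracle <- vapply(1:100, function(b) {
        50 >= 10 && b >= 10 && min(50, b) >= 0.9 * max(50, b)
    }, NA)
    expect_equal(keep$nGenesB, (1:100)[oracle])
    ## equal counts always pass at or above the minimum
    eq <- rec; eq$nGenesB <- eq$nGenesA
    expect_equal(nrow(filterGeneParity(eq)), 100L)
})

test_that("filters are idempotent and commute", {
    x <- makePairInstance(11)
    rec <- buildPairMatrix(x$gd, x$inf)
    a <- filterGeneParity(filterDisjointGenes(rec), minGenes = 3)
    b <- filterDisjointGenes(filterGeneParity(rec, minGenes = 3))
    expect_equal(a, b)
    expect_equal(filterDisjointGenes(a), a[names(a)])
    expect_equal(filterGeneParity(a, minGenes = 3), a)
})

test_that("Jaccard similarity has the expected values and properties", {
    expect_equal(jaccardSimilarity(c("a", "b", "c"), c("b", "c", "d")), 0.5)
    expect_equal(jaccardSimilarity(c("a", "b"), c("a", "b")), 1)
    expect_equal(jaccardSimilarity("a", "b"), 0)
    expect_error(jaccardSimilarity(character(0), character(0)),
                 "undefined")
})

test_that("disease comparators rank by jaccard with deterministic tie-breaks", {
    rec <- data.frame(
        diseaseA = c("q", "q", "q", "a"),
        diseaseB = c("x", "y", "z", "q"),
        nGenesA = 10L, nGenesB = 10L, nSharedGenes = 0L,
        nGoA = 10L, nGoB = 10L,
        nSharedGo = c(4L, 6L, 6L, 2L),
        jaccard = c(0.9, 0.5, 0.5, 0.2),
        pctA = 1, pctB = 1, pRaw = 0.5, pAdj = 1)
    out <- diseaseComps("q", rec, k = 10)
    expect_equal(out$disease, c("x", "y", "z", "a"))
    ## permuting input order leaves the ranking identical
    out2 <- diseaseComps("q", rec[c(3, 1, 4, 2), ], k = 10)
    expect_equal(out, out2)
    expect_equal(nrow(diseaseComps("a", rec, k = 5)), 1L)
    expect_error(diseaseComps("nope", rec), "no record")
})

test_that("overlap percentages recompute from counts at integer precision", {
    rec <- data.frame(nGoA = 4L, nGoB = 5L, nSharedGo = 1L)
    expect_equal(overlapPercentages(rec), c(pctA = 25, pctB = 20))
    recFull <- data.frame(nGoA = 7L, nGoB = 7L, nSharedGo = 7L)
    expect_equal(overlapPercentages(recFull), c(pctA = 100, pctB = 100))
    set.seed(3)
    for (i in 1:20) {
        r <- data.frame(nGoA = sample(1:500, 1), nGoB = sample(1:500, 1))
        r$nSharedGo <- sample(0:min(r$nGoA, r$nGoB), 1)
        expect_equal(overlapPercentages(r),
                     c(pctA = round(100 * r$nSharedGo / r$nGoA),
                       pctB = round(100 * r$nSharedGo / r$nGoB)))
    }
    expect_error(overlapPercentages(data.frame(nGoA = 0L, nGoB = 1L,
                                               nSharedGo = 0L)),
                 "undefined")
})

test_that("the matrix writer round-trips through gzip", {
    x <- makePairInstance(5)
    rec <- buildPairMatrix(x$gd, x$inf)
    p <- tempfile(fileext = ".tsv.gz")
    writePairMatrix(rec, p, comments = "toy run")
    lines <- readLines(p)
    expect_equal(sum(!startsWith(lines, "#")) - 1L, nrow(rec))
    hdr <- strsplit(lines[!startsWith(lines, "#")][1L], "\t")[[1L]]
    expect_equal(hdr, names(rec))
})
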