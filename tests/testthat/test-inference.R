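test_that("the transitive join produces products of annotations and curations", {
    ## 1 gene, 1 term, 1 disease -> exactly 1 inference
    inf <- inferGODisease(annTable("1", "GO:0000010"),
                          gdTable("1", "MESH:D000001"))
    r <- inferenceRecords(inf)
    expect_equal(nrow(r), 1L)
    expect_equal(r$genes[[1L]], "1")
    ## gene with 2 terms and 3 diseases -> 6 inferences
    inf2 <- inferGODisease(
        annTable(c("5", "5"), c("GO:0000011", "GO:0000012")),
        gdTable(rep("5", 3), paste0("MESH:D00000", 2:4)))
    expect_equal(nrow(inferenceRecords(inf2)), 6L)
})

test_that("disjoint gene identifier spaces warn and return an empty set", {
    expect_warning(
        inf <- inferGODisease(annTable("1", "GO:0000010"),
                              gdTable("2", "MESH:D000001")),
        "disjoint")
    expect_equal(nrow(inferenceRecords(inf)), 0L)
})

test_that("the join equals a triple-nested-loop oracle on random instances", {
    set.seed(404)
    for (rep in 1:20) {
        nG <- sample(5:30, 1); nT <- sample(3:15, 1); nD <- sample(3:10, 1)
        annDf <- unique(data.frame(
            geneId = as.character(sample(nG, 120, replace = TRUE)),
            goTerm = sprintf("GO:%07d", sample(nT, 120, replace = TRUE)),
            stringsAsFactors = FALSE))
        gdDf <- unique(data.frame(
            subjectId = as.character(sample(nG, 80, replace = TRUE)),
            objectId = sprintf("MESH:D%06d", sample(nD, 80, replace = TRUE)),
            stringsAsFactors = FALSE))
        inf <- suppressWarnings(inferGODisease(
            annTable(annDf$geneId, annDf$goTerm),
            gdTable(gdDf$subjectId, gdDf$objectId)))
        expect_equal(flattenInferences(inf), bruteInfer(annDf, gdDf))
    }
})

test_that("rollupGO propagates diseases to ancestors and is idempotent", {
    ## chain: leaf -> mid -> top; inference only at the leaf
    g <- makeGraph(edgeDf(c("GO:leaf", "GO:mid"), c("GO:mid", "GO:top")))
    inf <- inferGODisease(annTable("1", "GO:leaf"),
                          gdTable("1", "MESH:D000001"), graph = g)
    up <- rollupGO(inf, g)
    r <- inferenceRecords(up)
    expect_setequal(r$goTerm, c("GO:leaf", "GO:mid", "GO:top"))
    expect_true(all(vapply(r$genes, identical, NA, "1")))
    expect_equal(inferenceRecords(rollupGO(up, g)), r)
})

test_that("a parent term displays diseases inferred to its specific descendants", {
    ## apoptotic-process shape: parent with a specific child carrying the
    ## inference; the parent view shows the child's diseases too
    g <- makeGraph(edgeDf(c("GO:aicd", "GO:apoptosis"),
                          c("GO:apoptosis", "GO:bioproc")))
    inf <- inferGODisease(annTable(c("10", "11"), c("GO:aicd", "GO:apoptosis")),
                          gdTable(c("10", "11"),
                                  c("MESH:D000100", "MESH:D000200")),
                          graph = g)
    up <- inferenceRecords(rollupGO(inf, g))
    atParent <- up$disease[up$goTerm == "GO:apoptosis"]
    expect_setequal(atParent, c("MESH:D000100", "MESH:D000200"))
})

test_that("rollupGO never shrinks disease sets on random DAGs", {
    g <- randomDAG(30, seed = 8)
    ts <- sample(goTerms(g), 10)
    inf <- suppressWarnings(inferGODisease(
        annTable(as.character(1:10), ts),
        gdTable(as.character(1:10),
                sprintf("MESH:D%06d", rep(1:5, 2)))))
    up <- rollupGO(inf, g)
    before <- inferenceRecords(inf)
    after <- inferenceRecords(up)
    for (i in seq_len(nrow(before))) {
        j <- which(after$goTerm == before$goTerm[i] &
                   after$disease == before$disease[i])
        expect_length(j, 1L)
        expect_true(all(before$genes[[i]] %in% after$genes[[j]]))
    }
    expect_equal(inferenceRecords(rollupGO(up, g)), after)
})

test_that("rollupDisease merges a disease with its subtypes", {
    p <- tempfile(fileext = ".tsv")
    writeLines(c("DiseaseID\tDiseaseName\tParentIDs\tSlimCategories",
                 "MESH:D010024\tosteoporosis\t\t",
                 "MESH:D015663\tosteoporosis, postmenopausal\tMESH:D010024\t",
                 "MESH:D000001\tother\t\t"), p)
    h <- readDiseaseHierarchy(p)
    gd <- gdTable(c("101", "102", "103"),
                  c("MESH:D010024", "MESH:D015663", "MESH:D000001"))
    merged <- rollupDisease(gd, h, "MESH:D010024")
    expect_setequal(merged$genes, c("101", "102"))
    leaf <- rollupDisease(gd, h, "MESH:D015663")
    expect_equal(leaf$genes, "102")
})

test_that("rollupDisease equals a naive recursive union on a random hierarchy", {
    set.seed(77)
    n <- 30L
    ids <- sprintf("MESH:D%06d", seq_len(n))
    parent <- c("", vapply(2:n, function(i)
        sample(ids[seq_len(i - 1L)], 1L), ""))
    p <- tempfile(fileext = ".tsv")
    writeLines(c("DiseaseID\tDiseaseName\tParentIDs\tSlimCategories",
                 paste(ids, ids, parent, "", sep = "\t")), p)
    h <- readDiseaseHierarchy(p)
    gd <- gdTable(as.character(1000 + seq_len(n)), ids)
    naive <- function(d) sort(unique(c(
        as.character(1000 + match(d, ids)),
        unlist(lapply(ids[parent == d], naive)))))
    for (d in sample(ids, 8L))
        expect_equal(rollupDisease(gd, h, d)$genes, naive(d))
})

test_that("CC queries union diseases over descendants, uniquely", {
    ns <- c("GO:cc" = "cellular_component",
            "GO:cc1" = "cellular_component",
            "GO:cc2" = "cellular_component",
            "GO:bp" = "biological_process")
    g <- makeGraph(edgeDf(c("GO:cc1", "GO:cc2"), c("GO:cc", "GO:cc")),
                   namespace = ns, extraTerms = "GO:bp")
    inf <- inferGODisease(
        annTable(c("1", "2", "3"), c("GO:cc1", "GO:cc2", "GO:cc2"),
                 branch = "cellular_component"),
        gdTable(c("1", "2", "3"),
                c("MESH:D000001", "MESH:D000001", "MESH:D000002")))
    expect_equal(diseasesForCCTerm(inf, g, "GO:cc"),
                 c("MESH:D000001", "MESH:D000002"))
    expect_equal(diseasesForCCTerm(inf, g, "GO:cc1"), "MESH:D000001")
    expect_error(diseasesForCCTerm(inf, g, "GO:bp"),
                 "not in the cellular_component branch")
})

test_that("CC rollup equals brute-force union over enumerated descendants", {
    res <- runSimulate("basic", seed = 17,
                       outDir = file.path(tempdir(), "cc-bf"))
    g <- suppressWarnings(parseOBO(res$files[["ontology"]]))
    ann <- readGene2GO(res$files[["gene2go"]], taxa = 9606)
    gd <- readGeneDisease(res$files[["gene_disease"]])
    inf <- inferGODisease(ann, gd, graph = g)
    r <- inferenceRecords(inf)
    ccTerms <- goTerms(g)[termNamespace(g) == "cellular_component"]
    for (t in sample(ccTerms, 5L)) {
        fam <- descendants(g, t, relations = c("is_a", "part_of"))
        expected <- sort(unique(unlist(lapply(fam, function(u)
            r$disease[r$goTerm == u]))))
        expect_equal(diseasesForCCTerm(inf, g, t), expected)
    }
})

test_that("slimBin counts one contribution per category with rounding", {
    p <- tempfile(fileext = ".tsv")
    rows <- c("MESH:D000001\ta\t\tcancer",
              "MESH:D000002\tb\t\tcancer",
              "MESH:D000003\tc\t\tmetabolic disease",
              "MESH:D000004\td\t\tnervous system disease",
              "MESH:D000005\te\t\t")
    writeLines(c("DiseaseID\tDiseaseName\tParentIDs\tSlimCategories",
                 rows), p)
    h <- readDiseaseHierarchy(p)
    b <- slimBin(sprintf("MESH:D%06d", 1:4), h)
    expect_equal(b$percent[b$category == "cancer"], 50)
    expect_equal(sort(b$percent), c(25, 25, 50))
    ## all one category
    b1 <- slimBin(c("MESH:D000001", "MESH:D000002"), h)
    expect_equal(b1$percent, 100)
    ## no slim mapping -> uncategorized
    b2 <- slimBin("MESH:D000005", h)
    expect_equal(b2$category, "uncategorized")
})

test_that("branch files are deterministic and fixed under write-read-write", {
    g <- makeGraph(edgeDf("GO:0000002", "GO:0000001"))
    inf <- inferGODisease(
        annTable(c("1", "2"), c("GO:0000002", "GO:0000001")),
        gdTable(c("1", "2"), c("MESH:D000001", "MESH:D000002")),
        graph = g)
    d1 <- file.path(tempdir(), "inf-w1")
    d2 <- file.path(tempdir(), "inf-w2")
    f1 <- writeInferenceFiles(inf, d1)
    back <- readInferenceFiles(f1)
    f2 <- writeInferenceFiles(back, d2)
    expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
    bp <- readLines(f1[["biological_process"]])
    expect_equal(sum(!startsWith(bp, "#")), 2L)
    ## empty set -> three header-only files
    f0 <- writeInferenceFiles(
        new("InferenceSet", records = inferenceRecords(inf)[0, ]),
        file.path(tempdir(), "inf-w0"))
    expect_length(f0, 3L)
    for (p in f0)
        expect_true(all(startsWith(readLines(p), "#")))
})
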