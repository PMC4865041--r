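## Seeded synthetic-data generator.  Emits every input dialect the
## readers consume (OBO ontology, gene2go annotations, gene-disease,
## chemical-gene, chemical-disease, gene-gene, disease hierarchy)
## together with a ground-truth ledger, including planted disease pairs
## that share GO biological processes through disjoint gene sets.

#' Synthetic-data generator configuration
#'
#' Defaults describe the study conditions the pipeline is exercised
#' under: a three-branch DAG with a deep biological_process branch,
#' sparse many-to-many gene-GO and gene-disease annotations, and planted
#' disease pairs whose genes are disjoint but annotated to a common pool
#' of GO-BP terms.
#'
#' @param seed master seed; every emitted file uses its own stream
#'   derived from (seed, file tag), so adding a file never perturbs the
#'   others.
#' @param nTerms named integer vector: non-root terms per branch.
#' @param dagDepth maximum granularity level of generated terms.
#' @param nGenes total genes (planted pairs reserve a disjoint slice).
#' @param nDiseases total diseases (planted pairs use 2 each).
#' @param annotationDensity mean GO annotations per background gene.
#' @param curationDensity mean curated genes per background disease.
#' @param nPlantedPairs number of planted disjoint-gene/high-GO-overlap
#'   disease pairs.
#' @param plantedStrength probability in (0, 1] that a planted gene is
#'   annotated to each term of its pair's shared GO-BP pool.
#' @param plantedPoolSize shared GO-BP terms per planted pair.
#' @param nChemicals chemicals in the chemical tables.
#' @param therapeuticFraction fraction of chemical-disease rows labeled
#'   "therapeutic" (others "marker/mechanism").
#' @param nGGEdges gene-gene interaction edges.
#' @return a validated list of class \code{"simConfig"}.
#' @export
simConfig <- function(seed = 1L,
                      nTerms = c(biological_process = 250L,
                                 molecular_function = 40L,
                                 cellular_component = 40L),
                      dagDepth = 6L,
                      nGenes = 320L,
                      nDiseases = 60L,
                      annotationDensity = 6,
                      curationDensity = 16,
                      nPlantedPairs = 5L,
                      plantedStrength = 0.8,
                      plantedPoolSize = 20L,
                      nChemicals = 25L,
                      therapeuticFraction = 0.5,
                      nGGEdges = 150L) {
    cfg <- list(seed = as.integer(seed), nTerms = nTerms,
                dagDepth = as.integer(dagDepth),
                nGenes = as.integer(nGenes),
                nDiseases = as.integer(nDiseases),
                annotationDensity = annotationDensity,
                curationDensity = curationDensity,
                nPlantedPairs = as.integer(nPlantedPairs),
                plantedStrength = plantedStrength,
                plantedPoolSize = as.integer(plantedPoolSize),
                nChemicals = as.integer(nChemicals),
                therapeuticFraction = therapeuticFraction,
                nGGEdges = as.integer(nGGEdges))
    counts <- c(cfg$nTerms, cfg$dagDepth, cfg$nGenes, cfg$nDiseases,
                cfg$nChemicals)
    if (any(counts <= 0L) || cfg$nGGEdges < 0L || cfg$nPlantedPairs < 0L)
        stop("config error: counts must be positive")
    if (cfg$plantedStrength <= 0 || cfg$plantedStrength > 1)
        stop("config error: plantedStrength must lie in (0, 1]")
    if (2L * cfg$nPlantedPairs > cfg$nDiseases)
        stop("config error: planted pairs exceed available diseases")
    if (cfg$nPlantedPairs > 0L &&
        cfg$nPlantedPairs * cfg$plantedPoolSize >
        cfg$nTerms[["biological_process"]] %/% 2L)
        stop("config error: planted GO pools exceed half the BP branch")
    if (cfg$nPlantedPairs * 2L * 16L + 20L > cfg$nGenes)
        stop("config error: too few genes to reserve planted gene sets")
    class(cfg) <- "simConfig"
    cfg
}

## deterministic per-file stream seed (< 2^31), from (seed, tag)
.streamSeed <- function(seed, tag) {
    b <- utf8ToInt(tag)
    h <- sum(b * seq_along(b)) %% 100003L
    as.integer((as.numeric(seed) * 7919 + h * 10007) %% 2147483399 + 1)
}

.setStream <- function(seed, tag) {
    set.seed(.streamSeed(seed, tag), kind = "Mersenne-Twister",
             normal.kind = "Inversion", sample.kind = "Rejection")
}

## ---- ontology generation ----

## generates one branch's term table and edges; level-1 chain guarantees
## every level is populated, remaining terms pick random levels
.simBranch <- function(branch, n, depth, startIdx) {
    root <- .GO_ROOTS[[branch]]
    ids <- sprintf("GO:%07d", startIdx + seq_len(n))
    lvl <- integer(n)
    lvl[seq_len(min(depth, n))] <- seq_len(min(depth, n))
    if (n > depth)
        lvl[(depth + 1L):n] <- sample(seq_len(depth), n - depth,
                                      replace = TRUE,
                                      prob = pmin(seq_len(depth), 4))
    o <- order(lvl, seq_len(n))
    ids <- ids[o]; lvl <- lvl[o]
    child <- character(); parent <- character(); rel <- character()
    for (i in seq_len(n)) {
        cand <- if (lvl[i] == 1L) root else ids[lvl == lvl[i] - 1L]
        p1 <- if (length(cand) == 1L) cand else sample(cand, 1L)
        child <- c(child, ids[i]); parent <- c(parent, p1)
        rel <- c(rel, "is_a")
        ## occasional second parent -> diamonds in the DAG
        if (lvl[i] > 1L && stats::runif(1) < 0.25) {
            cand2 <- setdiff(ids[lvl < lvl[i]], p1)
            if (length(cand2)) {
                p2 <- if (length(cand2) == 1L) cand2 else sample(cand2, 1L)
                child <- c(child, ids[i]); parent <- c(parent, p2)
                rel <- c(rel, "is_a")
            }
        }
        ## part_of edges only in the cellular_component branch
        if (branch == "cellular_component" && lvl[i] > 1L &&
            stats::runif(1) < 0.2) {
            cand3 <- ids[lvl < lvl[i]]
            p3 <- if (length(cand3) == 1L) cand3 else sample(cand3, 1L)
            child <- c(child, ids[i]); parent <- c(parent, p3)
            rel <- c(rel, "part_of")
        }
    }
    list(root = root, ids = ids, level = lvl,
         edges = data.frame(child = child, parent = parent, relation = rel,
                            stringsAsFactors = FALSE))
}

.writeOBO <- function(branches, path, altId, obsolete) {
    lines <- c("format-version: 1.2", "ontology: synthetic-go", "")
    for (br in names(branches)) {
        b <- branches[[br]]
        e <- b$edges
        stanza <- function(id, name, extra = character()) {
            c("[Term]", paste0("id: ", id), paste0("name: ", name),
              paste0("namespace: ", br), extra, "")
        }
        lines <- c(lines, stanza(b$root, br))
        for (id in b$ids) {
            extra <- character()
            alt <- names(altId)[altId == id]
            if (length(alt)) extra <- c(extra, paste0("alt_id: ", alt))
            ee <- e[e$child == id, , drop = FALSE]
            for (j in seq_len(nrow(ee))) {
                if (ee$relation[j] == "is_a")
                    extra <- c(extra, paste0("is_a: ", ee$parent[j], " ! ",
                                             "term ", ee$parent[j]))
                else
                    extra <- c(extra, paste0("relationship: part_of ",
                                             ee$parent[j]))
            }
            lines <- c(lines, stanza(id, paste("term", id), extra))
        }
    }
    for (ob in obsolete)
        lines <- c(lines, "[Term]", paste0("id: ", ob),
                   paste0("name: obsolete term ", ob),
                   "is_obsolete: true", "")
    writeLines(lines, path)
}

## ---- main generator ----

#' Generate a complete synthetic input bundle
#'
#' Emits a parseable OBO ontology, gene2go-dialect annotations (with
#' deliberate dialect chaff: NOT-qualified rows, non-target taxa on
#' dedicated genes, branch-root placeholder rows and duplicates, all of
#' which the readers filter), a CTD-dialect gene-disease table (with
#' inferred no-evidence rows), chemical-gene, chemical-disease and
#' gene-gene tables, and a disease hierarchy with subtype links and slim
#' categories.  Planted disease pairs receive disjoint, size-matched
#' gene sets whose genes are annotated to a pair-specific pool of shared
#' GO-BP terms, so the pair survives the disjoint-gene and gene-parity
#' filters with high Jaccard similarity.
#'
#' Identical config and seed give byte-identical output trees.
#'
#' @param config a \code{\link{simConfig}}.
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with \code{files} (named paths),
#'   \code{ledger} (ground truth; also serialized to ledger.json) and
#'   \code{config}.
#' @export
simulateBundle <- function(config, outDir) {
    stopifnot(inherits(config, "simConfig"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    seed <- config$seed

    ## -- ontology --
    .setStream(seed, "ontology")
    branches <- list()
    startIdx <- 100000L
    for (br in .GO_BRANCHES) {
        branches[[br]] <- .simBranch(br, config$nTerms[[br]],
                                     config$dagDepth, startIdx)
        startIdx <- startIdx + config$nTerms[[br]] + 1000L
    }
    ## alt ids and an obsolete term per branch (dialect realism)
    altId <- character()
    obsolete <- character()
    for (br in .GO_BRANCHES) {
        tgt <- branches[[br]]$ids[1:2]
        alt <- sprintf("GO:%07d", 900000L + length(altId) + 1:2)
        altId[alt] <- tgt
        obsolete <- c(obsolete,
                      sprintf("GO:%07d", 950000L + length(obsolete) + 1L))
    }
    oboPath <- file.path(outDir, "ontology.obo")
    .writeOBO(branches, oboPath, altId, obsolete)

    termLevels <- lapply(branches, function(b)
        setNames(b$level, b$ids))

    ## -- entities --
    geneIds <- as.character(1000L + seq_len(config$nGenes))
    diseaseIds <- sprintf("MESH:D%06d", 500000L + seq_len(config$nDiseases))
    diseaseNames <- sprintf("disease %03d", seq_len(config$nDiseases))
    names(diseaseNames) <- diseaseIds
    chemIds <- sprintf("MESH:C%06d", 600000L + seq_len(config$nChemicals))

    ## -- planted structure --
    .setStream(seed, "planted")
    nP <- config$nPlantedPairs
    planted <- list()
    reserved <- character(0)
    usedBP <- character(0)
    bp <- branches$biological_process
    midBP <- bp$ids[bp$level >= 2L & bp$level <= config$dagDepth - 1L]
    genePtr <- 0L
    for (i in seq_len(nP)) {
        s <- sample(11:16, 1L)
        gA <- geneIds[genePtr + seq_len(s)]; genePtr <- genePtr + s
        gB <- geneIds[genePtr + seq_len(s)]; genePtr <- genePtr + s
        pool <- sample(setdiff(midBP, usedBP), config$plantedPoolSize)
        usedBP <- c(usedBP, pool)
        planted[[i]] <- list(
            diseaseA = diseaseIds[2L * i - 1L],
            diseaseB = diseaseIds[2L * i],
            genesA = gA, genesB = gB,
            sharedGo = sort(pool, method = "radix"))
        reserved <- c(reserved, gA, gB)
    }
    background <- setdiff(geneIds, reserved)

    ## -- gene2go annotations --
    .setStream(seed, "gene2go")
    midWeight <- function(br) {
        lv <- termLevels[[br]]
        w <- stats::dnorm(lv, mean = (config$dagDepth + 1) / 2, sd = 1.5)
        w / sum(w)
    }
    wBP <- midWeight("biological_process")
    wMF <- midWeight("molecular_function")
    wCC <- midWeight("cellular_component")
    rows <- list()
    addRow <- function(gene, terms, branchName, taxon = 9606L,
                       qualifier = "") {
        if (!length(terms)) return()
        ev <- sample(c("IEA", "IDA", "IMP", "ISS", "TAS"), length(terms),
                     replace = TRUE)
        rows[[length(rows) + 1L]] <<- data.frame(
            tax_id = taxon, GeneID = gene, GO_ID = terms, Evidence = ev,
            Qualifier = qualifier, Category = branchName,
            stringsAsFactors = FALSE)
    }
    for (i in seq_len(nP)) {
        p <- planted[[i]]
        for (g in c(p$genesA, p$genesB)) {
            keep <- stats::runif(config$plantedPoolSize) <
                config$plantedStrength
            if (!any(keep)) keep[sample(config$plantedPoolSize, 1L)] <- TRUE
            extraBP <- sample(bp$ids, 2L, prob = wBP[bp$ids])
            addRow(g, c(p$sharedGo[keep], extraBP), "Process")
            addRow(g, sample(branches$molecular_function$ids, 1L,
                             prob = wMF[branches$molecular_function$ids]),
                   "Function")
            addRow(g, sample(branches$cellular_component$ids, 1L,
                             prob = wCC[branches$cellular_component$ids]),
                   "Component")
        }
    }
    for (g in background) {
        k <- max(1L, stats::rpois(1L, config$annotationDensity))
        brs <- sample(c("Process", "Function", "Component"), k,
                      replace = TRUE, prob = c(0.6, 0.2, 0.2))
        nB <- sum(brs == "Process"); nM <- sum(brs == "Function")
        nC <- k - nB - nM
        if (nB) addRow(g, unique(sample(bp$ids, nB, prob = wBP[bp$ids])),
                       "Process")
        if (nM) addRow(g, unique(sample(branches$molecular_function$ids,
                                        min(nM, config$nTerms[["molecular_function"]]),
                                        prob = wMF[branches$molecular_function$ids])),
                       "Function")
        if (nC) addRow(g, unique(sample(branches$cellular_component$ids,
                                        min(nC, config$nTerms[["cellular_component"]]),
                                        prob = wCC[branches$cellular_component$ids])),
                       "Component")
    }
    ## dialect chaff, all filtered by the reader or harmless to inference:
    ## non-Eumetazoa taxa on dedicated genes, NOT qualifiers, placeholder
    ## roots, and duplicated rows
    flyGenes <- as.character(90000L + 1:5)
    for (g in flyGenes)
        addRow(g, sample(bp$ids, 2L), "Process", taxon = 7227L)
    notGenes <- as.character(91000L + 1:3)
    for (g in notGenes)
        addRow(g, sample(bp$ids, 1L), "Process", qualifier = "NOT")
    addRow(as.character(92000L), unname(.GO_ROOTS), "Process")
    ann <- do.call(rbind, rows)
    ## collapse incidental (gene, term) repeats so the intentional
    ## duplicates below are the only ones the reader must remove
    ann <- ann[!duplicated(ann[c("GeneID", "GO_ID")]), , drop = FALSE]
    nBeforeDup <- nrow(ann)
    dupIdx <- sample(nrow(ann), 5L)
    ann <- rbind(ann, ann[dupIdx, , drop = FALSE])
    g2gPath <- file.path(outDir, "gene2go.tsv")
    writeLines(c("#tax_id\tGeneID\tGO_ID\tEvidence\tQualifier\tGO_term\tPubMed\tCategory",
                 paste(ann$tax_id, ann$GeneID, ann$GO_ID, ann$Evidence,
                       ann$Qualifier, paste("term", ann$GO_ID), "-",
                       ann$Category, sep = "\t")),
               g2gPath)

    ## -- gene-disease --
    .setStream(seed, "gene_disease")
    gdRows <- list()
    addGD <- function(genes, disease, evidence) {
        if (!length(genes)) return()
        gdRows[[length(gdRows) + 1L]] <<- data.frame(
            GeneSymbol = paste0("G", genes), GeneID = genes,
            DiseaseName = diseaseNames[[disease]], DiseaseID = disease,
            DirectEvidence = evidence, stringsAsFactors = FALSE)
    }
    diseaseGenes <- list()
    for (i in seq_len(nP)) {
        p <- planted[[i]]
        addGD(p$genesA, p$diseaseA, "marker/mechanism")
        addGD(p$genesB, p$diseaseB, "marker/mechanism")
        diseaseGenes[[p$diseaseA]] <- p$genesA
        diseaseGenes[[p$diseaseB]] <- p$genesB
    }
    for (d in diseaseIds[(2L * nP + 1L):config$nDiseases]) {
        k <- sample(4:28, 1L)
        g <- sample(background, min(k, length(background)))
        ev <- ifelse(stats::runif(length(g)) < 0.9, "marker/mechanism",
                     "therapeutic")
        addGD(g, d, ev)
        diseaseGenes[[d]] <- sort(g, method = "radix")
    }
    gd <- do.call(rbind, gdRows)
    nDirect <- nrow(gd)
    ## inferred chaff rows (empty DirectEvidence)
    nChaff <- min(10L, length(background), config$nDiseases)
    chaffGenes <- sample(background, nChaff)
    chaffDiseases <- sample(diseaseIds, nChaff)
    infChaff <- data.frame(
        GeneSymbol = paste0("G", chaffGenes),
        GeneID = chaffGenes,
        DiseaseName = diseaseNames[chaffDiseases],
        DiseaseID = chaffDiseases,
        DirectEvidence = "", stringsAsFactors = FALSE)
    gd <- rbind(gd, infChaff)
    gdPath <- file.path(outDir, "gene_disease.tsv")
    writeLines(c("# Synthetic curated gene-disease associations",
                 "# CTD dialect",
                 "# GeneSymbol\tGeneID\tDiseaseName\tDiseaseID\tDirectEvidence\tPubMedIDs",
                 paste(gd$GeneSymbol, gd$GeneID, gd$DiseaseName,
                       gd$DiseaseID, gd$DirectEvidence, "-", sep = "\t")),
               gdPath)

    ## -- chemical tables --
    .setStream(seed, "chem_disease")
    nTher <- round(config$therapeuticFraction * config$nChemicals)
    cdRows <- lapply(seq_len(config$nChemicals), function(j) {
        ds <- sample(diseaseIds, sample(1:3, 1L))
        ev <- if (j <= nTher) "therapeutic" else "marker/mechanism"
        data.frame(ChemicalName = sprintf("chem %03d", j),
                   ChemicalID = chemIds[j],
                   DiseaseName = diseaseNames[ds], DiseaseID = ds,
                   DirectEvidence = ev, stringsAsFactors = FALSE)
    })
    cd <- do.call(rbind, cdRows)
    cdPath <- file.path(outDir, "chem_disease.tsv")
    writeLines(c("# Synthetic chemical-disease associations",
                 "# ChemicalName\tChemicalID\tDiseaseName\tDiseaseID\tDirectEvidence",
                 paste(cd$ChemicalName, cd$ChemicalID, cd$DiseaseName,
                       cd$DiseaseID, cd$DirectEvidence, sep = "\t")),
               cdPath)

    .setStream(seed, "chem_gene")
    cgRows <- lapply(seq_len(config$nChemicals), function(j) {
        k <- max(1L, stats::rpois(1L, 8))
        g <- sample(geneIds, min(k, length(geneIds)))
        data.frame(ChemicalName = sprintf("chem %03d", j),
                   ChemicalID = chemIds[j], GeneSymbol = paste0("G", g),
                   GeneID = g,
                   InteractionActions = sample(
                       c("increases^expression", "decreases^expression",
                         "affects^binding"), length(g), replace = TRUE),
                   stringsAsFactors = FALSE)
    })
    cg <- do.call(rbind, cgRows)
    cgPath <- file.path(outDir, "chem_gene.tsv")
    writeLines(c("# Synthetic chemical-gene interactions",
                 "# ChemicalName\tChemicalID\tGeneSymbol\tGeneID\tInteractionActions",
                 paste(cg$ChemicalName, cg$ChemicalID, cg$GeneSymbol,
                       cg$GeneID, cg$InteractionActions, sep = "\t")),
               cgPath)

    ## -- gene-gene edges --
    .setStream(seed, "gene_gene")
    g1 <- sample(geneIds, config$nGGEdges, replace = TRUE)
    g2 <- sample(geneIds, config$nGGEdges, replace = TRUE)
    keep <- g1 != g2
    gg <- data.frame(gene1 = paste0("G", g1[keep]),
                     gene2 = paste0("G", g2[keep]),
                     type = sample(c("physical association", "genetic"),
                                   sum(keep), replace = TRUE),
                     stringsAsFactors = FALSE)
    gg <- gg[!duplicated(data.frame(pmin(gg$gene1, gg$gene2),
                                    pmax(gg$gene1, gg$gene2))), ,
             drop = FALSE]
    ggPath <- file.path(outDir, "gene_gene.tsv")
    writeLines(c("gene1\tgene2\ttype",
                 paste(gg$gene1, gg$gene2, gg$type, sep = "\t")),
               ggPath)

    ## -- disease hierarchy with subtype links and slim categories --
    .setStream(seed, "hierarchy")
    slimLabels <- c("cancer", "nervous system disease",
                    "metabolic disease", "immune system disease",
                    "cardiovascular disease", "digestive system disease",
                    "genetic disease", "respiratory tract disease")
    slimOf <- lapply(seq_len(config$nDiseases), function(i)
        sample(slimLabels, sample(1:2, 1L, prob = c(0.7, 0.3))))
    names(slimOf) <- diseaseIds
    parentsOf <- setNames(vector("list", config$nDiseases), diseaseIds)
    bgIdx <- (2L * nP + 1L):config$nDiseases
    if (length(bgIdx) >= 12L) {
        subtypeChild <- bgIdx[seq(2L, 12L, by = 2L)]
        subtypeParent <- bgIdx[seq(1L, 11L, by = 2L)]
        for (j in seq_along(subtypeChild))
            parentsOf[[diseaseIds[subtypeChild[j]]]] <-
                diseaseIds[subtypeParent[j]]
    }
    dhPath <- file.path(outDir, "disease_hierarchy.tsv")
    writeLines(c("# Synthetic MEDIC-style disease hierarchy",
                 "# DiseaseID\tDiseaseName\tParentIDs\tSlimCategories",
                 paste(diseaseIds, diseaseNames,
                       vapply(parentsOf, paste, "", collapse = "|"),
                       vapply(slimOf, paste, "", collapse = "|"),
                       sep = "\t")),
               dhPath)

    ## -- ledger --
    slimContrib <- table(unlist(slimOf, use.names = FALSE))
    ledger <- list(
        seed = seed,
        nGenes = config$nGenes, nDiseases = config$nDiseases,
        nChemicals = config$nChemicals,
        fileRowCounts = list(
            gene2go = nrow(ann), gene_disease = nrow(gd),
            chem_disease = nrow(cd), chem_gene = nrow(cg),
            gene_gene = nrow(gg), disease_hierarchy = config$nDiseases),
        gene2go = list(
            nDuplicatedRows = nrow(ann) - nBeforeDup,
            nNotRows = length(notGenes),
            nPlaceholderRows = 3L,
            nNonTargetTaxonRows = 2L * length(flyGenes)),
        geneDisease = list(nDirectRows = nDirect,
                           nInferredRows = nrow(infChaff)),
        diseaseGeneCounts = lapply(diseaseGenes, length),
        plantedPairs = planted,
        slimContributions = as.list(slimContrib),
        subtypeLinks = Filter(length, parentsOf))
    ledgerPath <- file.path(outDir, "ledger.json")
    jsonlite::write_json(ledger, ledgerPath, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    files <- c(ontology = oboPath, gene2go = g2gPath,
               gene_disease = gdPath, chem_disease = cdPath,
               chem_gene = cgPath, gene_gene = ggPath,
               disease_hierarchy = dhPath, ledger = ledgerPath)
    invisible(list(files = files, ledger = ledger, config = config))
}

#' Plant a drug-repositioning scenario
#'
#' Emits the chemical-disease, chemical-gene and annotation files of a
#' two-disease repositioning benchmark shaped like the anchored Venn
#' analysis: a configurable number of anchor chemicals therapeutic for
#' both diseases, disease-specific chemical sets, a reference gene set
#' equal to the intersection of the anchors' interacting genes, a known
#' number of candidates whose reference coverage strictly exceeds the
#' threshold, and a shared GO-BP term set of which a known subset is
#' annotated to the reference genes.
#'
#' @param config a \code{\link{simConfig}} (supplies the seed).
#' @param outDir output directory.
#' @param nAnchors chemicals therapeutic for both diseases (default 2).
#' @param nOnlyA,nOnlyB disease-specific chemical counts (defaults 28
#'   and 39).
#' @param referenceSize size of the planted anchor-intersection gene set
#'   (default 277).
#' @param nHighCoverage candidates planted above the coverage threshold
#'   (default 4).
#' @param threshold strict coverage threshold (default 0.5).
#' @param sharedGoSize,coveredGoSize size of the planted shared GO-BP
#'   term set and of its subset annotated to reference genes (defaults
#'   320 and 307).
#' @return invisibly, list(files, ledger, config); ledger.json is
#'   written alongside the files.
#' @export
plantRepositioningScenario <- function(config, outDir,
                                       nAnchors = 2L, nOnlyA = 28L,
                                       nOnlyB = 39L,
                                       referenceSize = 277L,
                                       nHighCoverage = 4L,
                                       threshold = 0.5,
                                       sharedGoSize = 320L,
                                       coveredGoSize = 307L) {
    stopifnot(inherits(config, "simConfig"))
    if (nHighCoverage > nOnlyB)
        stop("config error: more high-coverage candidates than candidates")
    if (coveredGoSize > sharedGoSize)
        stop("config error: covered terms exceed shared terms")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    seed <- config$seed
    .setStream(seed, "repositioning")

    dA <- "MESH:D700001"; dB <- "MESH:D700002"
    dn <- c("disease alpha", "disease beta")
    names(dn) <- c(dA, dB)
    anchors <- sprintf("MESH:C%06d", 800000L + seq_len(nAnchors))
    onlyA <- sprintf("MESH:C%06d", 810000L + seq_len(nOnlyA))
    onlyB <- sprintf("MESH:C%06d", 820000L + seq_len(nOnlyB))
    markerOnly <- sprintf("MESH:C%06d", 830000L + 1:5)

    cd <- rbind(
        data.frame(chem = rep(anchors, each = 2L),
                   disease = rep(c(dA, dB), nAnchors), ev = "therapeutic"),
        data.frame(chem = onlyA, disease = dA, ev = "therapeutic"),
        data.frame(chem = onlyB, disease = dB, ev = "therapeutic"),
        data.frame(chem = markerOnly,
                   disease = sample(c(dA, dB), 5L, replace = TRUE),
                   ev = "marker/mechanism"))
    cdPath <- file.path(outDir, "chem_disease.tsv")
    writeLines(c("# Synthetic repositioning scenario: chemical-disease",
                 "# ChemicalName\tChemicalID\tDiseaseName\tDiseaseID\tDirectEvidence",
                 paste(paste0("chem ", cd$chem), cd$chem, dn[cd$disease],
                       cd$disease, cd$ev, sep = "\t")),
               cdPath)

    ## genes: reference = intersection of the two anchors' gene sets
    genePool <- as.character(1000L + seq_len(referenceSize + 400L))
    reference <- genePool[seq_len(referenceSize)]
    extras <- genePool[-seq_len(referenceSize)]
    anchorSets <- list()
    anchorSets[[anchors[1L]]] <- c(reference, extras[1:150])
    if (nAnchors >= 2L)
        anchorSets[[anchors[2L]]] <- c(reference, extras[151:270])
    if (nAnchors > 2L) for (j in 3:nAnchors)
        anchorSets[[anchors[j]]] <- c(reference,
                                      sample(extras, 50L))
    ## candidate coverage: high strictly above threshold, low strictly
    ## below; bounds leave a margin of one gene on each side
    hiMin <- floor(threshold * referenceSize) + 2L
    loMax <- max(1L, floor(threshold * referenceSize) - 10L)
    highChems <- onlyB[seq_len(nHighCoverage)]
    candSets <- list()
    for (j in seq_along(onlyB)) {
        ch <- onlyB[j]
        k <- if (ch %in% highChems)
                 sample(hiMin:min(referenceSize, hiMin + 80L), 1L)
             else sample(5L:loMax, 1L)
        candSets[[ch]] <- c(sample(reference, k), sample(extras, 3L))
    }
    for (ch in onlyA) candSets[[ch]] <- sample(genePool, 8L)
    allSets <- c(anchorSets, candSets)
    cgRows <- lapply(names(allSets), function(ch)
        data.frame(chem = ch, gene = allSets[[ch]],
                   stringsAsFactors = FALSE))
    cg <- do.call(rbind, cgRows)
    cgPath <- file.path(outDir, "chem_gene.tsv")
    writeLines(c("# Synthetic repositioning scenario: chemical-gene",
                 "# ChemicalName\tChemicalID\tGeneSymbol\tGeneID\tInteractionActions",
                 paste(paste0("chem ", cg$chem), cg$chem,
                       paste0("G", cg$gene), cg$gene, "affects^binding",
                       sep = "\t")),
               cgPath)

    ## shared GO-BP terms: coveredGoSize of them annotated to reference
    ## genes, the remainder to non-reference genes only
    sharedGo <- sprintf("GO:%07d", 700000L + seq_len(sharedGoSize))
    covered <- sharedGo[seq_len(coveredGoSize)]
    uncovered <- setdiff(sharedGo, covered)
    annRows <- data.frame(
        tax_id = 9606L,
        GeneID = c(sample(reference, coveredGoSize, replace = TRUE),
                   sample(extras, length(uncovered), replace = TRUE)),
        GO_ID = c(covered, uncovered),
        Evidence = "IEA", Qualifier = "", Category = "Process",
        stringsAsFactors = FALSE)
    g2gPath <- file.path(outDir, "gene2go.tsv")
    writeLines(c("#tax_id\tGeneID\tGO_ID\tEvidence\tQualifier\tGO_term\tPubMed\tCategory",
                 paste(annRows$tax_id, annRows$GeneID, annRows$GO_ID,
                       annRows$Evidence, annRows$Qualifier,
                       paste("term", annRows$GO_ID), "-",
                       annRows$Category, sep = "\t")),
               g2gPath)

    ledger <- list(
        seed = seed,
        diseaseA = dA, diseaseB = dB,
        vennSplit = list(onlyA = nOnlyA, both = nAnchors, onlyB = nOnlyB),
        anchors = anchors,
        referenceSize = referenceSize,
        highCoverageChemicals = highChems,
        threshold = threshold,
        sharedGoSize = sharedGoSize,
        coveredGoSize = coveredGoSize,
        sharedGo = sharedGo)
    ledgerPath <- file.path(outDir, "ledger.json")
    jsonlite::write_json(ledger, ledgerPath, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    files <- c(chem_disease = cdPath, chem_gene = cgPath,
               gene2go = g2gPath, ledger = ledgerPath)
    invisible(list(files = files, ledger = ledger, config = config))
}
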