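## End-to-end workflows wiring the stages together.  These are the
## library-level commands behind inst/scripts/godisnet.R; every command
## is a thin shell over the module functions and echoes its
## configuration into "#"-comment provenance headers so outputs are
## self-describing.

.configComments <- function(cfg) {
    vapply(names(cfg), function(k)
        paste0("config ", k, ": ",
               paste(format(cfg[[k]], trim = TRUE), collapse = ",")),
        "")
}

#' Run the synthetic-data generator by preset
#'
#' @param preset \code{"basic"} (small bundle, no planted structure),
#'   \code{"planted-pairs"} (5 planted disjoint-gene/high-GO-overlap
#'   disease pairs against 50 background diseases) or
#'   \code{"repositioning"} (planted 28/2/39 Venn split, 277-gene
#'   reference, 4 candidates above 50 percent coverage).
#' @param seed master seed.
#' @param outDir output directory.
#' @return invisibly, the generator's list(files, ledger, config).
#' @export
runSimulate <- function(preset = c("basic", "planted-pairs",
                                   "repositioning"),
                        seed = 1L, outDir) {
    preset <- match.arg(preset)
    if (missing(outDir)) stop("usage error: outDir is required")
    switch(preset,
           basic = simulateBundle(
               simConfig(seed = seed,
                         nTerms = c(biological_process = 60L,
                                    molecular_function = 20L,
                                    cellular_component = 20L),
                         dagDepth = 4L, nGenes = 120L, nDiseases = 20L,
                         nPlantedPairs = 0L, nChemicals = 10L,
                         nGGEdges = 60L),
               outDir),
           "planted-pairs" = simulateBundle(
               simConfig(seed = seed, nPlantedPairs = 5L,
                         nDiseases = 60L),
               outDir),
           repositioning = plantRepositioningScenario(
               simConfig(seed = seed), outDir))
}

#' Run the GO-disease inference workflow
#'
#' Reads a gene2go-dialect annotation file and a CTD-dialect
#' gene-disease file, generates the transitive GO-disease inferences and
#' writes the three branch download files.
#'
#' @param gene2goPath,geneDiseasePath input files.
#' @param oboPath optional OBO file for term names/namespaces.
#' @param outDir output directory for the branch files.
#' @param taxa,evidenceAllow,directOnly import filters (see
#'   \code{\link{readGene2GO}}, \code{\link{readGeneDisease}}).
#' @param branch optional subset of branches to write.
#' @return invisibly, list(inferences, files).
#' @export
runInfer <- function(gene2goPath, geneDiseasePath, oboPath = NULL,
                     outDir, taxa = "all", evidenceAllow = "all",
                     directOnly = TRUE, branch = NULL) {
    ann <- readGene2GO(gene2goPath, taxa = taxa,
                       evidenceAllow = evidenceAllow)
    gd <- readGeneDisease(geneDiseasePath, directOnly = directOnly)
    graph <- if (!is.null(oboPath)) parseOBO(oboPath) else NULL
    inf <- inferGODisease(ann, gd, graph = graph)
    files <- writeInferenceFiles(inf, outDir)
    if (!is.null(branch)) {
        drop <- setdiff(names(files), branch)
        unlink(files[drop])
        files <- files[branch]
    }
    invisible(list(inferences = inf, files = files))
}

#' Run the disease-pair matrix workflow
#'
#' Builds the all-vs-all disease-pair matrix from inferred GO-BP terms,
#' applies the disjoint-gene and gene-count-parity filters, and writes
#' the matrix with Jaccard similarity and Bonferroni-adjusted overlap
#' p-values.
#'
#' @param gene2goPath,geneDiseasePath input files.
#' @param oboPath optional OBO file.
#' @param out output TSV path (".gz" for gzip).
#' @param minGenes,tolerance parity-filter parameters.
#' @param noSharedGenes apply the disjoint-gene filter (default TRUE).
#' @param universe optional GO-BP universe-size override for the
#'   hypergeometric test.
#' @param taxa,evidenceAllow import filters.
#' @return invisibly, the filtered pair-matrix data.frame.
#' @export
runPairs <- function(gene2goPath, geneDiseasePath, oboPath = NULL, out,
                     minGenes = 10, tolerance = 0.10,
                     noSharedGenes = TRUE, universe = NULL,
                     taxa = "all", evidenceAllow = "all") {
    ann <- readGene2GO(gene2goPath, taxa = taxa,
                       evidenceAllow = evidenceAllow)
    gd <- readGeneDisease(geneDiseasePath, directOnly = TRUE)
    graph <- if (!is.null(oboPath)) parseOBO(oboPath) else NULL
    inf <- inferGODisease(ann, gd, graph = graph)
    records <- buildPairMatrix(gd, inf, universe = universe)
    if (noSharedGenes) records <- filterDisjointGenes(records)
    records <- filterGeneParity(records, minGenes = minGenes,
                                tolerance = tolerance)
    if (!missing(out) && !is.null(out))
        writePairMatrix(records, out, comments = .configComments(list(
            minGenes = minGenes, tolerance = tolerance,
            noSharedGenes = noSharedGenes)))
    invisible(records)
}

#' Run the drug-repositioning ranking workflow
#'
#' Venn-partitions the therapeutic chemicals of two diseases, builds the
#' reference gene set from the shared chemicals' gene interactions, and
#' ranks the disease-B-specific chemicals by reference coverage.
#'
#' @param chemDiseasePath,chemGenePath input files.
#' @param diseaseA,diseaseB disease ids.
#' @param evidence evidence label for the Venn (default
#'   \code{"therapeutic"}).
#' @param threshold strict coverage flag threshold (default 0.5).
#' @param out optional ranking TSV path.
#' @return invisibly, list(venn, reference, ranking).
#' @export
runRank <- function(chemDiseasePath, chemGenePath, diseaseA, diseaseB,
                    evidence = "therapeutic", threshold = 0.5,
                    out = NULL) {
    cd <- readChemAssoc(chemDiseasePath)
    cg <- readChemAssoc(chemGenePath)
    venn <- vennChemicals(cd, diseaseA, diseaseB, evidence = evidence)
    if (!length(venn$both))
        stop("no chemical is associated with both diseases under '",
             evidence, "' evidence; no reference set can be built")
    reference <- referenceGeneSet(venn$both, cg)
    ranking <- rankCandidates(venn$onlyB, reference, cg,
                              threshold = threshold)
    if (!is.null(out))
        writeRanking(ranking, out, comments = .configComments(list(
            diseaseA = diseaseA, diseaseB = diseaseB,
            evidence = evidence, threshold = threshold,
            referenceSize = length(reference))))
    invisible(list(venn = venn, reference = reference,
                   ranking = ranking))
}
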