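## Drug-repositioning workflow: Venn partition of therapeutic chemicals,
## cross-gene-set interaction nexus, reference-gene-set construction, and
## coverage-based candidate ranking.

#' Venn partition of chemicals associated with two diseases
#'
#' Splits the chemicals curated to either disease into those specific to
#' A, specific to B, or shared -- the VennViewer-style comparison used to
#' spot chemicals already therapeutic for both diseases.
#'
#' @param chemDisease an \linkS4class{AssociationTable} of type
#'   \code{"chem_disease"}.
#' @param diseaseA,diseaseB disease ids.
#' @param evidence keep only rows with this evidence label (exact,
#'   case-insensitive), e.g. \code{"therapeutic"}; \code{NULL} keeps all.
#' @return list with sorted character vectors \code{onlyA}, \code{both},
#'   \code{onlyB} (pairwise disjoint; their union is every chemical
#'   associated with either disease).  A disease with no rows yields an
#'   empty side with a warning.
#' @export
vennChemicals <- function(chemDisease, diseaseA, diseaseB,
                          evidence = NULL) {
    stopifnot(associationType(chemDisease) == "chem_disease")
    a <- associations(chemDisease)
    if (!is.null(evidence))
        a <- a[tolower(a$evidence) == tolower(evidence), , drop = FALSE]
    chemsFor <- function(d) {
        s <- unique(a$subjectId[a$objectId == d])
        if (!length(s))
            warning("no chemical associations for disease ", d)
        s
    }
    sA <- chemsFor(diseaseA)
    sB <- chemsFor(diseaseB)
    list(onlyA = sort(setdiff(sA, sB), method = "radix"),
         both = sort(intersect(sA, sB), method = "radix"),
         onlyB = sort(setdiff(sB, sA), method = "radix"))
}

#' Gene-gene interactions bridging two gene sets
#'
#' Finds the interaction edges with one endpoint in each of two disjoint
#' gene sets and summarises per-gene cross-degrees, identifying nexus
#' genes that link one set to many genes of the other (the Set
#' Analyzer-style view).  Edges are treated as undirected;
#' direction-bearing rows are symmetrised.
#'
#' @param genesA,genesB character vectors (expected disjoint; a warning
#'   is issued otherwise).
#' @param edges data.frame with columns \code{gene1}, \code{gene2} and
#'   optionally \code{type}.
#' @param includeWithinSet also report edges internal to one set
#'   (default FALSE: cross-set edges only).
#' @return list with \code{edges} (the selected rows, deduplicated as
#'   undirected pairs), \code{degree} (named integer vector of cross-set
#'   degrees, decreasing) and \code{nexus} (genes ordered by degree).
#' @export
crossSetInteractions <- function(genesA, genesB, edges,
                                 includeWithinSet = FALSE) {
    if (length(intersect(genesA, genesB)))
        warning("gene sets overlap; overlapping genes count for both sides")
    if (!nrow(edges)) {
        return(list(edges = edges, degree = integer(0),
                    nexus = character(0)))
    }
    if (is.null(edges$type)) edges$type <- ""
    ## undirected dedup: orient each edge lexicographically
    g1 <- pmin(edges$gene1, edges$gene2)
    g2 <- pmax(edges$gene1, edges$gene2)
    und <- data.frame(gene1 = g1, gene2 = g2, type = edges$type,
                      stringsAsFactors = FALSE)
    und <- und[!duplicated(und[c("gene1", "gene2")]), , drop = FALSE]
    cross <- (und$gene1 %in% genesA & und$gene2 %in% genesB) |
             (und$gene1 %in% genesB & und$gene2 %in% genesA)
    if (includeWithinSet) {
        within <- (und$gene1 %in% genesA & und$gene2 %in% genesA) |
                  (und$gene1 %in% genesB & und$gene2 %in% genesB)
        keep <- cross | within
    } else keep <- cross
    sel <- und[keep, , drop = FALSE]
    rownames(sel) <- NULL
    deg <- sort(table(c(sel$gene1, sel$gene2)), decreasing = TRUE)
    deg <- structure(as.integer(deg), names = names(deg))
    list(edges = sel, degree = deg, nexus = names(deg))
}

#' Reference gene set shared by a group of chemicals
#'
#' Intersection of the interacting-gene sets of the given chemicals --
#' e.g. the genes with which both anchor therapies interact, used as the
#' molecular milepost for ranking repositioning candidates.
#'
#' @param chemicals character vector of chemical ids.
#' @param chemGene an \linkS4class{AssociationTable} of type
#'   \code{"chem_gene"}.
#' @return sorted character vector of gene ids; a chemical with no
#'   interactions raises an error naming it.
#' @export
referenceGeneSet <- function(chemicals, chemGene) {
    stopifnot(associationType(chemGene) == "chem_gene")
    a <- associations(chemGene)
    sets <- lapply(chemicals, function(ch) {
        g <- unique(a$objectId[a$subjectId == ch])
        if (!length(g))
            stop("chemical ", ch, " has no curated gene interactions")
        g
    })
    sort(Reduce(intersect, sets), method = "radix")
}

#' Rank repositioning candidates by reference-gene coverage
#'
#' For each candidate chemical, counts how many reference genes it
#' interacts with; coverage is that count over the reference size.
#' Candidates are ranked by decreasing coverage (ties by chemical id)
#' and flagged when coverage strictly exceeds the threshold ("more than
#' 50 percent" with the default).
#'
#' @param candidates character vector of chemical ids.
#' @param reference nonempty character vector of gene ids.
#' @param chemGene an \linkS4class{AssociationTable} of type
#'   \code{"chem_gene"}.
#' @param threshold coverage flag threshold, strict (default 0.5).
#' @return data.frame with columns \code{chemical}, \code{genesHit},
#'   \code{referenceSize}, \code{coverage}, \code{flagged}.
#' @export
rankCandidates <- function(candidates, reference, chemGene,
                           threshold = 0.5) {
    if (!length(reference)) stop("reference gene set is empty")
    stopifnot(associationType(chemGene) == "chem_gene")
    a <- associations(chemGene)
    reference <- unique(reference)
    hits <- vapply(candidates, function(ch)
        length(intersect(unique(a$objectId[a$subjectId == ch]),
                         reference)), 0L)
    cov <- hits / length(reference)
    o <- order(-cov, candidates, method = "radix")
    out <- data.frame(chemical = candidates[o],
                      genesHit = unname(hits[o]),
                      referenceSize = length(reference),
                      coverage = unname(cov[o]),
                      flagged = unname(cov[o] > threshold),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Fraction of shared GO terms annotated to a reference gene set
#'
#' Checks how much of a disease pair's shared inferred GO-BP signal is
#' carried by the reference gene set: the subset of \code{sharedGo}
#' directly annotated to at least one reference gene, and its fraction
#' of the shared terms.
#'
#' @param reference character vector of gene ids.
#' @param annTab an \linkS4class{AnnotationTable}.
#' @param sharedGo nonempty character vector of GO term ids.
#' @return list with \code{covered} (sorted term subset) and
#'   \code{fraction}.
#' @export
annotateReferenceWithGO <- function(reference, annTab, sharedGo) {
    if (!length(sharedGo)) stop("sharedGo is empty")
    a <- annotations(annTab)
    refTerms <- unique(a$goTerm[a$geneId %in% reference])
    covered <- sort(intersect(unique(sharedGo), refTerms),
                    method = "radix")
    list(covered = covered,
         fraction = length(covered) / length(unique(sharedGo)))
}

#' Write a candidate ranking as TSV
#'
#' @param ranking data.frame from \code{\link{rankCandidates}}.
#' @param path output path.
#' @param comments optional "#"-prefixed provenance lines.
#' @return \code{path}, invisibly.
#' @export
writeRanking <- function(ranking, path, comments = NULL) {
    con <- file(path, "wt")
    on.exit(close(con))
    if (length(comments)) writeLines(paste0("# ", comments), con)
    writeLines(paste(names(ranking), collapse = "\t"), con)
    if (nrow(ranking))
        writeLines(do.call(paste, c(lapply(ranking, as.character),
                                    sep = "\t")), con)
    invisible(path)
}
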