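## Central S4 containers for the GO-disease inference pipeline.

#' @import methods
NULL

## GO root placeholders used by external databases; stripped on import and
## forbidden inside AnnotationTable / InferenceSet objects.
.GO_ROOTS <- c(biological_process = "GO:0008150",
               molecular_function = "GO:0003674",
               cellular_component = "GO:0005575")

.GO_BRANCHES <- names(.GO_ROOTS)

#' OntologyGraph: a Gene Ontology DAG
#'
#' Holds the terms, labels, branch namespaces and parent edges (by named
#' relation, \code{is_a} and \code{part_of}) of a GO-style ontology.
#' Obsolete terms and alternate identifiers are retained for lookup but
#' excluded from traversal.
#'
#' @slot terms character vector of non-obsolete term identifiers.
#' @slot termName named character, term -> label.
#' @slot termNamespace named character, term -> one of
#'   \code{biological_process}, \code{molecular_function},
#'   \code{cellular_component}.
#' @slot edges data.frame with columns \code{child}, \code{parent},
#'   \code{relation}.
#' @slot obsolete character vector of obsolete term ids (never traversed).
#' @slot altId named character mapping alternate id -> canonical id.
#'
#' @details Validity enforces that \code{is_a} edges never cross branch
#' namespaces, that the \code{is_a} subgraph is acyclic, and that every
#' non-root term reaches exactly one branch root via \code{is_a}.
#'
#' @exportClass OntologyGraph
setClass("OntologyGraph",
         representation(terms = "character",
                        termName = "character",
                        termNamespace = "character",
                        edges = "data.frame",
                        obsolete = "character",
                        altId = "character"))

.findIsaCycle <- function(terms, edges) {
    ## Kahn's algorithm on is_a edges; returns NULL or one cycle's members.
    isa <- edges[edges$relation == "is_a", , drop = FALSE]
    indeg <- integer(length(terms))
    names(indeg) <- terms
    tab <- table(isa$child)
    indeg[names(tab)] <- as.integer(tab)
    childrenOf <- split(isa$child, isa$parent)
    queue <- terms[indeg == 0L]
    seen <- 0L
    while (length(queue)) {
        t <- queue[[1L]]
        queue <- queue[-1L]
        seen <- seen + 1L
        for (ch in childrenOf[[t]]) {
            indeg[[ch]] <- indeg[[ch]] - 1L
            if (indeg[[ch]] == 0L) queue <- c(queue, ch)
        }
    }
    if (seen == length(terms)) return(NULL)
    names(indeg)[indeg > 0L]
}

setValidity("OntologyGraph", function(object) {
    msgs <- character()
    e <- object@edges
    if (!all(c("child", "parent", "relation") %in% names(e)))
        return("edges must have columns child, parent, relation")
    known <- c(object@terms, object@obsolete)
    if (nrow(e) && !all(c(e$child, e$parent) %in% known))
        msgs <- c(msgs, "edges reference unknown terms")
    ns <- object@termNamespace
    isa <- e[e$relation == "is_a", , drop = FALSE]
    if (nrow(isa)) {
        crosses <- ns[isa$child] != ns[isa$parent]
        if (any(crosses, na.rm = TRUE))
            msgs <- c(msgs, sprintf(
                "is_a edge leaves its branch: %s -> %s",
                isa$child[which(crosses)[1L]], isa$parent[which(crosses)[1L]]))
    }
    cyc <- .findIsaCycle(object@terms, e)
    if (!is.null(cyc))
        msgs <- c(msgs, sprintf("cyclic is_a involving: %s",
                                paste(cyc, collapse = ", ")))
    if (length(msgs)) msgs else TRUE
})

#' AnnotationTable: direct gene-to-GO annotations
#'
#' One row per (gene, GO term) pair, carrying the evidence code, qualifier,
#' source taxon and GO branch, as imported from a gene2go-dialect file.
#'
#' @slot annotations data.frame with columns \code{geneId},
#'   \code{geneSymbol}, \code{goTerm}, \code{evidence}, \code{qualifier},
#'   \code{taxon}, \code{category} (branch namespace).
#'
#' @details Validity forbids the three GO branch-root placeholders and
#' duplicate (gene, term) pairs: both are removed by
#' \code{\link{readGene2GO}} before construction.
#'
#' @exportClass AnnotationTable
setClass("AnnotationTable",
         representation(annotations = "data.frame"))

setValidity("AnnotationTable", function(object) {
    a <- object@annotations
    need <- c("geneId", "geneSymbol", "goTerm", "evidence", "qualifier",
              "taxon", "category")
    if (!all(need %in% names(a)))
        return(paste("annotations must have columns:",
                     paste(setdiff(need, names(a)), collapse = ", ")))
    msgs <- character()
    if (any(a$goTerm %in% .GO_ROOTS))
        msgs <- c(msgs, "placeholder branch-root terms present")
    if (anyDuplicated(a[c("geneId", "goTerm")]))
        msgs <- c(msgs, "duplicate (gene, GO term) pairs")
    if (length(msgs)) msgs else TRUE
})

#' AssociationTable: directly curated subject-object associations
#'
#' Generic container for the three CTD-dialect association files:
#' gene-disease, chemical-gene and chemical-disease.  Each row carries a
#' subject, an object and a (possibly empty) direct-evidence label such as
#' \code{"marker/mechanism"} or \code{"therapeutic"}; rows with an empty
#' label are CTD's inferred rows.
#'
#' @slot associations data.frame with columns \code{subjectId},
#'   \code{subjectName}, \code{objectId}, \code{objectName},
#'   \code{evidence}.
#' @slot type one of \code{"gene_disease"}, \code{"chem_gene"},
#'   \code{"chem_disease"}.
#'
#' @exportClass AssociationTable
setClass("AssociationTable",
         representation(associations = "data.frame", type = "character"))

setValidity("AssociationTable", function(object) {
    a <- object@associations
    need <- c("subjectId", "subjectName", "objectId", "objectName",
              "evidence")
    if (!all(need %in% names(a)))
        return(paste("associations must have columns:",
                     paste(setdiff(need, names(a)), collapse = ", ")))
    msgs <- character()
    ids <- c(a$subjectId, a$objectId)
    if (any(!nzchar(ids)))
        msgs <- c(msgs, "empty subject or object identifiers")
    if (any(ids != trimws(ids)))
        msgs <- c(msgs, "identifiers are not whitespace-trimmed")
    if (!object@type %in% c("gene_disease", "chem_gene", "chem_disease"))
        msgs <- c(msgs, "unknown association type")
    if (length(msgs)) msgs else TRUE
})

#' DiseaseHierarchy: MEDIC-style disease vocabulary
#'
#' Parent links between disease terms (e.g. a subtype under its parent
#' disease) plus the mapping of each disease to zero or more generic
#' slim-list categories used for binning.
#'
#' @slot parents named list, disease id -> character vector of parent ids.
#' @slot slim named list, disease id -> character vector of slim categories.
#' @slot diseaseName named character, disease id -> display name.
#'
#' @exportClass DiseaseHierarchy
setClass("DiseaseHierarchy",
         representation(parents = "list", slim = "list",
                        diseaseName = "character"))

setValidity("DiseaseHierarchy", function(object) {
    ids <- names(object@parents)
    child <- rep(ids, lengths(object@parents))
    edges <- data.frame(
        child = child,
        parent = as.character(unlist(object@parents, use.names = FALSE)),
        relation = rep("is_a", length(child)), stringsAsFactors = FALSE)
    all_ids <- unique(c(ids, edges$parent))
    cyc <- .findIsaCycle(all_ids, edges)
    if (!is.null(cyc))
        return(sprintf("cyclic hierarchy involving: %s",
                       paste(cyc, collapse = ", ")))
    TRUE
})

#' InferenceSet: GO-disease inferences with their gene networks
#'
#' One record per inferred (GO term, disease) pair.  The inference gene
#' network of a record is the set of genes simultaneously annotated to the
#' GO term and directly curated to the disease; it is recomputable from the
#' inputs and stored sorted.
#'
#' @slot records data.frame with columns \code{goTerm}, \code{goName},
#'   \code{branch}, \code{disease}, \code{diseaseName} and list-column
#'   \code{genes} (sorted character vectors, each nonempty).
#'
#' @exportClass InferenceSet
setClass("InferenceSet", representation(records = "data.frame"))

setValidity("InferenceSet", function(object) {
    r <- object@records
    need <- c("goTerm", "goName", "branch", "disease", "diseaseName",
              "genes")
    if (!all(need %in% names(r)))
        return(paste("records must have columns:",
                     paste(setdiff(need, names(r)), collapse = ", ")))
    msgs <- character()
    if (anyDuplicated(r[c("goTerm", "disease")]))
        msgs <- c(msgs, "duplicate (GO term, disease) records")
    if (any(r$goTerm %in% .GO_ROOTS))
        msgs <- c(msgs, "placeholder branch-root terms present")
    if (nrow(r) && any(lengths(r$genes) == 0L))
        msgs <- c(msgs, "record with empty inference gene network")
    if (nrow(r) && !all(r$branch %in% .GO_BRANCHES))
        msgs <- c(msgs, "branch outside the three GO namespaces")
    if (length(msgs)) msgs else TRUE
})
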