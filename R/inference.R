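## GO-disease inference generation, DAG and disease-hierarchy rollup,
## CC descendant queries, slim binning, and the three branch download
## files.

.emptyInferenceRecords <- function() {
    data.frame(goTerm = character(), goName = character(),
               branch = character(), disease = character(),
               diseaseName = character(),
               genes = I(list()), stringsAsFactors = FALSE)
}

.sortRecords <- function(r) {
    o <- order(r$goTerm, r$disease, method = "radix")
    r <- r[o, , drop = FALSE]
    rownames(r) <- NULL
    r
}

## one display name per disease id; conflicting names resolve to the
## lexicographically smallest, logged
.resolveNames <- function(ids, names) {
    out <- tapply(names, ids, function(v) {
        u <- sort(unique(v), method = "radix")
        u[1L]
    })
    conflicts <- tapply(names, ids, function(v) length(unique(v)) > 1L)
    if (any(conflicts))
        message(sum(conflicts), " identifier(s) with conflicting display ",
                "names resolved to the lexicographically smallest")
    out
}

#' Generate GO-disease inferences via shared genes
#'
#' The core transitive-inference join: a GO term t and a disease d are
#' inferred to be related whenever at least one gene is both directly
#' annotated to t and directly curated to d.  Each inferred (t, d) pair
#' carries its inference gene network -- the sorted set of genes realising
#' the join.
#'
#' @param annTab an \linkS4class{AnnotationTable} of direct gene-GO
#'   annotations.
#' @param geneDisease an \linkS4class{AssociationTable} of type
#'   \code{"gene_disease"}, restricted to the direct-evidence view.
#' @param graph optional \linkS4class{OntologyGraph} supplying term names
#'   and namespaces (otherwise taken from the annotation table).
#' @return an \linkS4class{InferenceSet}.  When the two gene identifier
#'   spaces are disjoint, an empty set is returned with a warning (this
#'   signals an identifier-mapping failure, not an empty biology).
#' @export
inferGODisease <- function(annTab, geneDisease, graph = NULL) {
    stopifnot(is(annTab, "AnnotationTable"),
              is(geneDisease, "AssociationTable"))
    if (associationType(geneDisease) != "gene_disease")
        stop("geneDisease must be a gene_disease association table")
    ann <- annotations(annTab)
    gd <- associations(geneDisease)
    common <- intersect(ann$geneId, gd$subjectId)
    if (!length(common)) {
        warning("gene identifier spaces of the annotation and association ",
                "tables are disjoint; returning an empty inference set")
        return(new("InferenceSet", records = .emptyInferenceRecords()))
    }
    a <- ann[ann$geneId %in% common, c("geneId", "goTerm", "category")]
    g <- gd[gd$subjectId %in% common,
            c("subjectId", "objectId", "objectName")]
    g <- g[!duplicated(g[c("subjectId", "objectId")]), , drop = FALSE]
    m <- merge(a, g, by.x = "geneId", by.y = "subjectId")
    if (!nrow(m))
        return(new("InferenceSet", records = .emptyInferenceRecords()))
    key <- paste(m$goTerm, m$objectId, sep = "\001")
    genes <- lapply(split(m$geneId, key),
                    function(v) sort(unique(v), method = "radix"))
    first <- m[!duplicated(key), , drop = FALSE]
    fkey <- paste(first$goTerm, first$objectId, sep = "\001")
    dn <- .resolveNames(gd$objectId, gd$objectName)
    branch <- first$category
    goName <- first$goTerm
    if (!is.null(graph)) {
        canon <- resolveTermId(graph, first$goTerm)
        known <- !is.na(canon)
        goName[known] <- unname(termName(graph)[canon[known]])
        branch[known] <- unname(termNamespace(graph)[canon[known]])
    }
    rec <- data.frame(goTerm = first$goTerm,
                      goName = goName,
                      branch = branch,
                      disease = first$objectId,
                      diseaseName = unname(dn[first$objectId]),
                      stringsAsFactors = FALSE)
    rec$genes <- I(unname(genes[fkey]))
    new("InferenceSet", records = .sortRecords(rec))
}

#' Subsume inferences over the GO DAG
#'
#' Propagates each inference upward so that every ancestor term carries
#' the diseases (and the union of inference genes) of all its descendants.
#' The operation is idempotent and never shrinks a term's disease set.
#' The three branch-root placeholders are excluded from the result.
#'
#' @param inferences an \linkS4class{InferenceSet}.
#' @param graph an \linkS4class{OntologyGraph} containing every inferred
#'   term.
#' @param relations relations to traverse (default \code{"is_a"}).
#' @return an \linkS4class{InferenceSet} with records at every ancestor.
#' @export
rollupGO <- function(inferences, graph, relations = "is_a") {
    r <- inferenceRecords(inferences)
    if (!nrow(r)) return(inferences)
    terms <- unique(r$goTerm)
    canon <- resolveTermId(graph, terms)
    if (anyNA(canon))
        stop("term(s) absent from the ontology: ",
             paste(terms[is.na(canon)], collapse = ", "))
    anc <- lapply(terms, function(t) ancestors(graph, t, relations))
    names(anc) <- terms
    reps <- lengths(anc)[r$goTerm]
    up <- data.frame(
        goTerm = unlist(anc[r$goTerm], use.names = FALSE),
        disease = rep(r$disease, reps),
        diseaseName = rep(r$diseaseName, reps),
        stringsAsFactors = FALSE)
    up$genes <- rep(r$genes, reps)
    up <- up[!(up$goTerm %in% .GO_ROOTS), , drop = FALSE]
    key <- paste(up$goTerm, up$disease, sep = "\001")
    genes <- lapply(split(up$genes, key), function(v)
        sort(unique(unlist(v, use.names = FALSE)), method = "radix"))
    first <- up[!duplicated(key), , drop = FALSE]
    fkey <- paste(first$goTerm, first$disease, sep = "\001")
    out <- data.frame(
        goTerm = first$goTerm,
        goName = unname(termName(graph)[first$goTerm]),
        branch = unname(termNamespace(graph)[first$goTerm]),
        disease = first$disease,
        diseaseName = first$diseaseName,
        stringsAsFactors = FALSE)
    out$genes <- I(unname(genes[fkey]))
    new("InferenceSet", records = .sortRecords(out))
}

#' Merge records over a disease and its hierarchy descendants
#'
#' Collects the payload curated or inferred to a disease together with
#' everything curated to any of its descendants (disease sub-types), the
#' way a parent disease term aggregates its sub-types in a MEDIC-style
#' vocabulary (e.g. osteoporosis plus postmenopausal osteoporosis).
#'
#' @param x an \linkS4class{AssociationTable} (gene-disease) or an
#'   \linkS4class{InferenceSet}.
#' @param hierarchy a \linkS4class{DiseaseHierarchy} containing
#'   \code{disease}.
#' @param disease the query disease id.
#' @return a list with \code{disease}, \code{diseases} (the query plus
#'   its descendants), \code{records} (the merged rows), and the merged
#'   payload sets: \code{genes} for an association table; \code{terms}
#'   and \code{genes} for an inference set.
#' @export
rollupDisease <- function(x, hierarchy, disease) {
    fam <- descendants(hierarchy, disease)
    if (is(x, "AssociationTable")) {
        a <- associations(x)
        rec <- a[a$objectId %in% fam, , drop = FALSE]
        rownames(rec) <- NULL
        list(disease = disease, diseases = fam, records = rec,
             genes = sort(unique(rec$subjectId), method = "radix"))
    } else if (is(x, "InferenceSet")) {
        r <- inferenceRecords(x)
        rec <- r[r$disease %in% fam, , drop = FALSE]
        rownames(rec) <- NULL
        list(disease = disease, diseases = fam, records = rec,
             terms = sort(unique(rec$goTerm), method = "radix"),
             genes = sort(unique(unlist(rec$genes, use.names = FALSE)),
                          method = "radix"))
    } else stop("x must be an AssociationTable or an InferenceSet")
}

#' Unique diseases inferred to a cellular-component term or its
#' descendants
#'
#' Mirrors querying one GO-CC term and collecting the diseases inferred
#' to that term as well as to any descendant CC term, filtered to a
#' unique list.
#'
#' @param inferences an \linkS4class{InferenceSet}.
#' @param graph an \linkS4class{OntologyGraph}.
#' @param term a cellular_component term id.
#' @param relations relations used for the descendant query; CC queries
#'   traverse \code{part_of} in addition to \code{is_a} by default.
#' @return sorted character vector of unique disease ids.
#' @export
diseasesForCCTerm <- function(inferences, graph, term,
                              relations = c("is_a", "part_of")) {
    term <- .checkTerm(graph, term)
    if (!identical(unname(termNamespace(graph, term)),
                   "cellular_component"))
        stop("term ", term, " is not in the cellular_component branch")
    fam <- descendants(graph, term, relations)
    r <- inferenceRecords(inferences)
    sort(unique(r$disease[r$goTerm %in% fam]), method = "radix")
}

#' Bin diseases into generic slim categories
#'
#' Each disease contributes once per slim category it maps to; a disease
#' with no slim category is counted under \code{"uncategorized"}.
#' Percentages are over total contributions, rounded to integers.
#'
#' @param diseases character vector of disease ids.
#' @param hierarchy a \linkS4class{DiseaseHierarchy} with a slim mapping.
#' @return data.frame with columns \code{category}, \code{count},
#'   \code{percent}, sorted by decreasing count (ties by category name).
#' @export
slimBin <- function(diseases, hierarchy) {
    diseases <- unique(diseases)
    if (!length(diseases)) stop("empty disease set: percentages undefined")
    slim <- slimCategories(hierarchy)
    cats <- lapply(diseases, function(d) {
        s <- slim[[d]]
        if (is.null(s) || !length(s)) "uncategorized" else s
    })
    all <- unlist(cats, use.names = FALSE)
    tab <- table(all)
    out <- data.frame(category = names(tab), count = as.integer(tab),
                      percent = round(100 * as.integer(tab) / length(all)),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$count, out$category, method = "radix"), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}

## ---- branch download files ----

.branchFileName <- function(branch)
    sprintf("GO_disease_%s.tsv", branch)

#' Write the three GO-disease branch inference files
#'
#' Emits one CTD-download-style TSV per GO branch with a "#"-prefixed
#' provenance header, columns GOName, GOID, DiseaseName, DiseaseID,
#' InferenceGeneSymbols (pipe-separated, sorted) and InferenceGeneCount,
#' rows sorted by (GOID, DiseaseID).  Output bytes are deterministic for
#' equal input.
#'
#' @param inferences an \linkS4class{InferenceSet}.
#' @param outDir output directory (created if needed).
#' @return named character vector of the three file paths.
#' @export
writeInferenceFiles <- function(inferences, outDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    r <- inferenceRecords(inferences)
    paths <- character(0)
    for (branch in .GO_BRANCHES) {
        p <- file.path(outDir, .branchFileName(branch))
        rb <- r[r$branch == branch, , drop = FALSE]
        rb <- .sortRecords(rb)
        lines <- c(
            "# GO-Disease-Gene Inference Network",
            paste0("# branch: ", branch),
            "# generated by goDiseaseNet",
            "# Fields:",
            "# GOName\tGOID\tDiseaseName\tDiseaseID\tInferenceGeneSymbols\tInferenceGeneCount")
        if (nrow(rb)) {
            gsym <- vapply(rb$genes, paste, "", collapse = "|")
            lines <- c(lines, paste(rb$goName, rb$goTerm, rb$diseaseName,
                                    rb$disease, gsym, lengths(rb$genes),
                                    sep = "\t"))
        }
        writeLines(lines, p)
        paths[branch] <- p
    }
    paths
}

#' Read GO-disease branch inference files back into an InferenceSet
#'
#' @param paths one or more files written by
#'   \code{\link{writeInferenceFiles}} (the branch is read from the
#'   "# branch:" header comment).
#' @return an \linkS4class{InferenceSet}.
#' @export
readInferenceFiles <- function(paths) {
    recs <- lapply(paths, function(p) {
        lines <- readLines(p)
        branch <- sub("^# branch: ", "",
                      grep("^# branch: ", lines, value = TRUE)[1L])
        body <- lines[!startsWith(lines, "#")]
        body <- body[nzchar(body)]
        if (!length(body)) return(.emptyInferenceRecords())
        parts <- strsplit(body, "\t")
        data.frame(
            goTerm = vapply(parts, `[`, "", 2L),
            goName = vapply(parts, `[`, "", 1L),
            branch = branch,
            disease = vapply(parts, `[`, "", 4L),
            diseaseName = vapply(parts, `[`, "", 3L),
            genes = I(lapply(parts, function(p)
                strsplit(p[5L], "|", fixed = TRUE)[[1L]])),
            stringsAsFactors = FALSE)
    })
    new("InferenceSet", records = .sortRecords(do.call(rbind, recs)))
}

## ---- accessors & show ----

#' @describeIn accessors inference records of an InferenceSet.
#' @export
setMethod("inferenceRecords", "InferenceSet", function(x, ...) x@records)

setMethod("show", "InferenceSet", function(object) {
    r <- object@records
    cat("InferenceSet with", nrow(r), "GO-disease inferences (",
        length(unique(r$goTerm)), "GO terms,",
        length(unique(r$disease)), "diseases,",
        length(unique(unlist(r$genes))), "genes )\n")
    if (nrow(r)) {
        tab <- table(r$branch)
        for (b in names(tab))
            cat("  ", b, ": ", tab[[b]], " inferences\n", sep = "")
    }
})
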