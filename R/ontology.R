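## OBO parsing and DAG queries: ancestor/descendant closures, granularity
## levels, level histograms.

#' Parse a Gene Ontology OBO file
#'
#' Reads an OBO 1.2/1.4 flat file into an \linkS4class{OntologyGraph}.
#' Recognised tags inside \code{[Term]} stanzas: \code{id}, \code{name},
#' \code{namespace}, \code{alt_id}, \code{is_a},
#' \code{relationship: part_of}, \code{is_obsolete}.  Other stanza types
#' and tags are ignored.  Obsolete terms are dropped from traversal with a
#' warning; alternate ids resolve to their canonical term.
#'
#' @param path path to an OBO file.
#' @return an \linkS4class{OntologyGraph}.
#' @examples
#' obo <- system.file("extdata", "mini.obo", package = "goDiseaseNet")
#' g <- parseOBO(obo)
#' goTerms(g)
#' @export
parseOBO <- function(path) {
    lines <- readLines(path)
    ## stanza boundaries
    stanzaAt <- grep("^\\[", lines)
    termAt <- which(lines == "[Term]")
    if (!length(termAt))
        stop("no [Term] stanzas found in ", path)
    ends <- vapply(termAt, function(i) {
        nxt <- stanzaAt[stanzaAt > i]
        if (length(nxt)) nxt[1L] - 1L else length(lines)
    }, integer(1))

    ids <- character(); nms <- character(); nss <- character()
    obsolete <- character(); altFrom <- character(); altTo <- character()
    eChild <- character(); eParent <- character(); eRel <- character()

    for (s in seq_along(termAt)) {
        block <- lines[(termAt[s] + 1L):ends[s]]
        block <- block[nzchar(block) & !startsWith(block, "!")]
        hit <- regmatches(block, regexec("^([A-Za-z_]+):\\s*(.*)$", block))
        bad <- which(lengths(hit) != 3L)
        if (length(bad))
            stop(sprintf("malformed stanza line %d: '%s'",
                         termAt[s] + bad[1L], block[bad[1L]]))
        key <- vapply(hit, `[`, "", 2L)
        val <- trimws(vapply(hit, `[`, "", 3L))
        ## strip trailing "! comment"
        val <- sub("\\s*!.*$", "", val)
        id <- val[key == "id"][1L]
        if (is.na(id))
            stop(sprintf("stanza starting at line %d has no id", termAt[s]))
        if (any(key == "is_obsolete") &&
            tolower(val[key == "is_obsolete"][1L]) == "true") {
            obsolete <- c(obsolete, id)
            next
        }
        ids <- c(ids, id)
        nms <- c(nms, if (any(key == "name")) val[key == "name"][1L] else id)
        nss <- c(nss, if (any(key == "namespace"))
                          val[key == "namespace"][1L] else NA_character_)
        for (a in val[key == "alt_id"]) {
            altFrom <- c(altFrom, a); altTo <- c(altTo, id)
        }
        for (p in val[key == "is_a"]) {
            eChild <- c(eChild, id); eParent <- c(eParent, p)
            eRel <- c(eRel, "is_a")
        }
        for (r in val[key == "relationship"]) {
            parts <- strsplit(r, "\\s+")[[1L]]
            if (length(parts) >= 2L && parts[1L] == "part_of") {
                eChild <- c(eChild, id); eParent <- c(eParent, parts[2L])
                eRel <- c(eRel, "part_of")
            }
        }
    }
    if (length(obsolete))
        warning(length(obsolete), " obsolete term(s) dropped from traversal")
    edges <- data.frame(child = eChild, parent = eParent, relation = eRel,
                        stringsAsFactors = FALSE)
    ## drop edges touching obsolete terms
    edges <- edges[!(edges$child %in% obsolete) &
                   !(edges$parent %in% obsolete), , drop = FALSE]
    names(nms) <- ids
    names(nss) <- ids
    names(altTo) <- altFrom
    cyc <- .findIsaCycle(ids, edges)
    if (!is.null(cyc))
        stop("cyclic is_a relation involving: ", paste(cyc, collapse = ", "))
    new("OntologyGraph", terms = ids, termName = nms, termNamespace = nss,
        edges = edges, obsolete = obsolete, altId = altTo)
}

#' Resolve term identifiers to canonical ids
#'
#' Maps alternate ids (\code{alt_id}) to their canonical term; canonical
#' ids pass through unchanged.
#'
#' @param graph an \linkS4class{OntologyGraph}.
#' @param ids character vector of term ids.
#' @return character vector of canonical ids (NA where unknown).
#' @export
resolveTermId <- function(graph, ids) {
    out <- ids
    isAlt <- ids %in% names(graph@altId)
    out[isAlt] <- unname(graph@altId[ids[isAlt]])
    out[!(out %in% graph@terms)] <- NA_character_
    out
}

.checkTerm <- function(graph, term) {
    t <- resolveTermId(graph, term)
    if (is.na(t)) stop("unknown term: ", term)
    t
}

## adjacency lists restricted to a relation set
.parentAdj <- function(graph, relations) {
    e <- graph@edges[graph@edges$relation %in% relations, , drop = FALSE]
    split(e$parent, factor(e$child, levels = unique(e$child)))
}

.childAdj <- function(graph, relations) {
    e <- graph@edges[graph@edges$relation %in% relations, , drop = FALSE]
    split(e$child, factor(e$parent, levels = unique(e$parent)))
}

.closure <- function(start, adj) {
    seen <- structure(TRUE, names = start)
    frontier <- start
    while (length(frontier)) {
        nxt <- unique(unlist(adj[frontier], use.names = FALSE))
        nxt <- nxt[!(nxt %in% names(seen))]
        if (!length(nxt)) break
        seen <- c(seen, structure(rep(TRUE, length(nxt)), names = nxt))
        frontier <- nxt
    }
    names(seen)
}

#' @describeIn ancestors closure over the GO DAG.
#' @export
setMethod("ancestors", "OntologyGraph", function(x, term,
                                                 relations = "is_a") {
    term <- .checkTerm(x, term)
    sort(.closure(term, .parentAdj(x, relations)))
})

#' @describeIn descendants closure over the GO DAG (inverse of
#'   \code{ancestors}).
#' @export
setMethod("descendants", "OntologyGraph", function(x, term,
                                                   relations = "is_a") {
    term <- .checkTerm(x, term)
    sort(.closure(term, .childAdj(x, relations)))
})

#' @describeIn ancestors closure over the disease hierarchy
#'   (\code{relations} is ignored).
#' @export
setMethod("ancestors", "DiseaseHierarchy", function(x, term,
                                                    relations = "is_a") {
    if (!term %in% names(x@parents)) stop("unknown disease: ", term)
    sort(.closure(term, x@parents))
})

#' @describeIn descendants closure over the disease hierarchy
#'   (\code{relations} is ignored).
#' @export
setMethod("descendants", "DiseaseHierarchy", function(x, term,
                                                      relations = "is_a") {
    if (!term %in% names(x@parents)) stop("unknown disease: ", term)
    ids <- names(x@parents)
    children <- split(rep(ids, lengths(x@parents)),
                      unlist(x@parents, use.names = FALSE))
    sort(.closure(term, children))
})

## all per-term levels within the branch containing `roots`, by BFS
.branchLevels <- function(graph, root) {
    adj <- .childAdj(graph, "is_a")
    lvl <- structure(0L, names = root)
    frontier <- root
    d <- 0L
    while (length(frontier)) {
        d <- d + 1L
        nxt <- unique(unlist(adj[frontier], use.names = FALSE))
        nxt <- nxt[!(nxt %in% names(lvl))]
        if (!length(nxt)) break
        lvl <- c(lvl, structure(rep(d, length(nxt)), names = nxt))
        frontier <- nxt
    }
    lvl
}

#' @describeIn termLevel shortest is_a distance from the branch root.
#' @export
setMethod("termLevel", "OntologyGraph", function(x, term) {
    term <- .checkTerm(x, term)
    roots <- branchRoots(x)
    ## BFS upward from the term; first root hit gives the shortest path
    adj <- .parentAdj(x, "is_a")
    frontier <- term
    seen <- term
    d <- 0L
    repeat {
        if (any(frontier %in% roots)) return(d)
        nxt <- unique(unlist(adj[frontier], use.names = FALSE))
        nxt <- nxt[!(nxt %in% seen)]
        if (!length(nxt))
            stop("term ", term, " is not connected to a branch root via is_a")
        seen <- c(seen, nxt)
        frontier <- nxt
        d <- d + 1L
    }
})

#' Histogram of GO granularity levels
#'
#' Bins a set of terms by granularity level (shortest is_a distance from
#' the branch root) into caller-supplied level ranges and reports counts
#' with integer-rounded percentages.
#'
#' @param graph an \linkS4class{OntologyGraph}.
#' @param terms character vector of term ids (all must have a level).
#' @param bins named list of integer ranges, e.g.
#'   \code{list("1-2" = 1:2, "3" = 3, "4" = 4, "5-9" = 5:9)}.
#' @return data.frame with columns \code{bin}, \code{count},
#'   \code{percent} (percent = 100 * count / total, rounded to integer).
#'   Counts partition the input set; a term whose level falls in no bin
#'   raises an error.
#' @export
levelHistogram <- function(graph, terms, bins) {
    if (!length(terms)) stop("empty term set: percentages are undefined")
    lv <- vapply(terms, function(t) termLevel(graph, t), integer(1))
    counts <- vapply(bins, function(rng) sum(lv %in% rng), integer(1))
    if (sum(counts) != length(terms))
        stop("bins do not partition the term set (levels observed: ",
             paste(sort(unique(lv)), collapse = ", "), ")")
    data.frame(bin = names(bins), count = unname(counts),
               percent = round(100 * unname(counts) / length(terms)),
               stringsAsFactors = FALSE)
}

## ---- accessors & show ----

#' @describeIn accessors term ids of an ontology.
#' @export
setMethod("goTerms", "OntologyGraph", function(x, ...) x@terms)

#' @describeIn accessors roots (terms without is_a parents) named by
#'   namespace.
#' @export
setMethod("branchRoots", "OntologyGraph", function(x, ...) {
    isa <- x@edges[x@edges$relation == "is_a", , drop = FALSE]
    r <- x@terms[!(x@terms %in% isa$child)]
    structure(r, names = x@termNamespace[r])
})

#' @describeIn accessors term labels.
#' @export
setMethod("termName", "OntologyGraph", function(x, term = NULL) {
    if (is.null(term)) return(x@termName)
    x@termName[resolveTermId(x, term)]
})

#' @describeIn accessors term branch namespaces.
#' @export
setMethod("termNamespace", "OntologyGraph", function(x, term = NULL) {
    if (is.null(term)) return(x@termNamespace)
    x@termNamespace[resolveTermId(x, term)]
})

setMethod("show", "OntologyGraph", function(object) {
    cat("OntologyGraph with", length(object@terms), "terms,",
        nrow(object@edges), "edges\n")
    tab <- table(object@termNamespace)
    for (b in names(tab)) cat("  ", b, ": ", tab[[b]], " terms\n", sep = "")
    if (length(object@obsolete))
        cat("  (", length(object@obsolete), " obsolete terms excluded)\n",
            sep = "")
})
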