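## All-vs-all disease-pair matrix: shared curated genes vs shared inferred
## GO-BP terms, the disjoint-gene and gene-count-parity filters, Jaccard
## ranking and overlap percentages.

#' Jaccard similarity of two sets
#'
#' @param setA,setB character vectors (not both empty).
#' @return |A intersect B| / |A union B|, a real in [0, 1]; symmetric.
#' @examples
#' jaccardSimilarity(c("a", "b", "c"), c("b", "c", "d"))  # 0.5
#' @export
jaccardSimilarity <- function(setA, setB) {
    setA <- unique(setA); setB <- unique(setB)
    u <- length(union(setA, setB))
    if (u == 0L) stop("Jaccard similarity is undefined for two empty sets")
    length(intersect(setA, setB)) / u
}

#' Build the all-vs-all disease-pair matrix
#'
#' Compares every disease having at least one inferred GO biological-
#' process term against every other such disease, recording for each
#' unordered pair the directly curated gene counts, the gene
#' intersection, the inferred GO-BP term counts, the term intersection,
#' the Jaccard similarity of the term sets, the per-disease overlap
#' percentages, and a hypergeometric overlap p-value with its Bonferroni
#' adjustment over the matrix.
#'
#' @param geneDisease direct-evidence gene-disease
#'   \linkS4class{AssociationTable} (supplies the curated gene sets).
#' @param bpInferences an \linkS4class{InferenceSet}; only
#'   biological_process records are used.
#' @param universe size of the GO-BP term universe for the
#'   hypergeometric test; default is the number of distinct GO-BP terms
#'   with at least one inference in \code{bpInferences}.
#' @return data.frame with one row per unordered pair (diseaseA <
#'   diseaseB lexicographically) and columns \code{diseaseA},
#'   \code{diseaseB}, \code{nGenesA}, \code{nGenesB},
#'   \code{nSharedGenes}, \code{nGoA}, \code{nGoB}, \code{nSharedGo},
#'   \code{jaccard}, \code{pctA}, \code{pctB}, \code{pRaw}, \code{pAdj}.
#'   Fewer than two eligible diseases give a zero-row frame.
#' @export
buildPairMatrix <- function(geneDisease, bpInferences, universe = NULL) {
    r <- inferenceRecords(bpInferences)
    r <- r[r$branch == "biological_process", , drop = FALSE]
    goSets <- lapply(split(r$goTerm, r$disease), unique)
    gd <- associations(geneDisease)
    geneSets <- lapply(split(gd$subjectId, gd$objectId), unique)
    diseases <- sort(names(goSets), method = "radix")
    n <- length(diseases)
    if (is.null(universe)) universe <- length(unique(r$goTerm))
    if (n < 2L) return(.emptyPairMatrix())
    idx <- t(combn(n, 2L))
    A <- diseases[idx[, 1L]]; B <- diseases[idx[, 2L]]
    gA <- geneSets[A]; gB <- geneSets[B]
    tA <- goSets[A]; tB <- goSets[B]
    nGenesA <- vapply(gA, length, 0L)
    nGenesB <- vapply(gB, length, 0L)
    nSharedGenes <- mapply(function(x, y) length(intersect(x, y)), gA, gB)
    nGoA <- lengths(tA)
    nGoB <- lengths(tB)
    nSharedGo <- mapply(function(x, y) length(intersect(x, y)), tA, tB)
    jac <- nSharedGo / (nGoA + nGoB - nSharedGo)
    pRaw <- mapply(function(k, K, m) hypergeomOverlapP(k, K, m, universe),
                   nSharedGo, nGoA, nGoB)
    out <- data.frame(
        diseaseA = A, diseaseB = B,
        nGenesA = unname(nGenesA), nGenesB = unname(nGenesB),
        nSharedGenes = unname(as.integer(nSharedGenes)),
        nGoA = unname(nGoA), nGoB = unname(nGoB),
        nSharedGo = unname(as.integer(nSharedGo)),
        jaccard = unname(jac),
        pctA = unname(100 * nSharedGo / nGoA),
        pctB = unname(100 * nSharedGo / nGoB),
        pRaw = unname(pRaw),
        stringsAsFactors = FALSE)
    out$pAdj <- bonferroniAdjust(out$pRaw)
    rownames(out) <- NULL
    out
}

.emptyPairMatrix <- function() {
    data.frame(diseaseA = character(), diseaseB = character(),
               nGenesA = integer(), nGenesB = integer(),
               nSharedGenes = integer(), nGoA = integer(),
               nGoB = integer(), nSharedGo = integer(),
               jaccard = numeric(), pctA = numeric(), pctB = numeric(),
               pRaw = numeric(), pAdj = numeric(),
               stringsAsFactors = FALSE)
}

#' Keep disease pairs with no curated gene in common
#'
#' Retains pairs whose curated gene sets are disjoint while still sharing
#' at least one inferred GO-BP term -- the filter that removes overlap
#' explained trivially by shared genes.
#'
#' @param records a pair-matrix data.frame from
#'   \code{\link{buildPairMatrix}}.
#' @return the filtered records (idempotent; commutes with
#'   \code{\link{filterGeneParity}}).
#' @export
filterDisjointGenes <- function(records) {
    out <- records[records$nSharedGenes == 0L & records$nSharedGo >= 1L, ,
                   drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Keep disease pairs with comparable curation depth
#'
#' Both diseases must have at least \code{minGenes} directly curated
#' genes, and the two gene counts must be within \code{tolerance} of each
#' other: min(nA, nB) >= (1 - tolerance) * max(nA, nB).  With the
#' defaults, a disease with 50 curated genes admits partners with 45-55.
#'
#' @param records a pair-matrix data.frame.
#' @param minGenes minimum curated gene count per disease (default 10).
#' @param tolerance relative gene-count tolerance in [0, 1) (default
#'   0.10).
#' @return the filtered records (idempotent; commutes with
#'   \code{\link{filterDisjointGenes}}).
#' @export
filterGeneParity <- function(records, minGenes = 10, tolerance = 0.10) {
    stopifnot(tolerance >= 0, tolerance < 1)
    lo <- pmin(records$nGenesA, records$nGenesB)
    hi <- pmax(records$nGenesA, records$nGenesB)
    keep <- records$nGenesA >= minGenes & records$nGenesB >= minGenes &
        lo >= (1 - tolerance) * hi
    out <- records[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Rank diseases comparable to a target disease
#'
#' Returns the diseases paired with \code{target} ranked by descending
#' Jaccard similarity of inferred GO-BP terms; ties break by descending
#' shared-term count, then ascending disease id.
#'
#' @param target a disease id appearing in at least one record.
#' @param records a pair-matrix data.frame (typically post-filter).
#' @param k maximum number of comparators to return (default 20).
#' @return data.frame with columns \code{disease}, \code{jaccard},
#'   \code{nSharedGo}.
#' @export
diseaseComps <- function(target, records, k = 20L) {
    hit <- records$diseaseA == target | records$diseaseB == target
    if (!any(hit)) stop("disease ", target, " appears in no record")
    r <- records[hit, , drop = FALSE]
    other <- ifelse(r$diseaseA == target, r$diseaseB, r$diseaseA)
    o <- order(-r$jaccard, -r$nSharedGo, other, method = "radix")
    out <- data.frame(disease = other[o], jaccard = r$jaccard[o],
                      nSharedGo = r$nSharedGo[o],
                      stringsAsFactors = FALSE)
    head(out, k)
}

#' Per-disease overlap percentages of a pair record
#'
#' The shared inferred GO-BP terms of a pair as a percentage of each
#' disease's own term count, reported at integer precision as plotted.
#'
#' @param record a single pair-matrix row.
#' @return named numeric c(pctA, pctB), integer-rounded.
#' @export
overlapPercentages <- function(record) {
    if (record$nGoA <= 0 || record$nGoB <= 0)
        stop("overlap percentages undefined for a zero term count")
    c(pctA = round(100 * record$nSharedGo / record$nGoA),
      pctB = round(100 * record$nSharedGo / record$nGoB))
}

#' Write a disease-pair matrix as TSV
#'
#' One header line then one row per pair, sorted by (diseaseA, diseaseB);
#' gzip-transparent when \code{path} ends in \code{.gz}.
#'
#' @param records a pair-matrix data.frame.
#' @param path output path.
#' @param comments optional character vector written as "#"-prefixed
#'   provenance lines before the header.
#' @return \code{path}, invisibly.
#' @export
writePairMatrix <- function(records, path, comments = NULL) {
    o <- order(records$diseaseA, records$diseaseB, method = "radix")
    records <- records[o, , drop = FALSE]
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wt")
           else file(path, "wt")
    on.exit(close(con))
    if (length(comments)) writeLines(paste0("# ", comments), con)
    writeLines(paste(names(records), collapse = "\t"), con)
    if (nrow(records)) {
        body <- do.call(paste, c(lapply(records, as.character),
                                 sep = "\t"))
        writeLines(body, con)
    }
    invisible(path)
}
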