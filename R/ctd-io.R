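## Readers for the gene2go and CTD association-table dialects.
## Dialect notes: lines beginning "#" are comments; the LAST comment line
## may carry the header (CTD download convention); fields are
## tab-separated; multi-valued cells use "|".  All readers are transparent
## to gzip via R connections.

## read a CTD-dialect TSV; returns data.frame with header-derived names
.readCtdTsv <- function(path) {
    con <- file(path, "rt")
    on.exit(close(con))
    lines <- readLines(con)
    cmt <- startsWith(lines, "#")
    header <- NULL
    if (any(cmt)) {
        lastCmt <- max(which(cmt))
        cand <- sub("^#\\s*", "", lines[lastCmt])
        if (grepl("\t", cand)) header <- strsplit(cand, "\t")[[1L]]
    }
    body <- lines[!cmt]
    if (is.null(header) && length(body)) {
        ## headerless comment block or no comments: first body line is header
        header <- strsplit(body[1L], "\t")[[1L]]
        body <- body[-1L]
    }
    body <- body[nzchar(body)]
    if (!length(body)) {
        df <- as.data.frame(setNames(rep(list(character()), length(header)),
                                     header))
        return(df)
    }
    parts <- strsplit(body, "\t")
    n <- length(header)
    pad <- lapply(parts, function(p) {
        length(p) <- n
        ifelse(is.na(p), "", p)
    })
    df <- as.data.frame(do.call(rbind, pad), stringsAsFactors = FALSE)
    names(df) <- header
    rownames(df) <- NULL
    df
}

.requireColumn <- function(df, aliases, what, path) {
    hit <- which(tolower(names(df)) %in% tolower(aliases))
    if (!length(hit))
        stop(sprintf("schema error in %s: missing required column '%s'",
                     path, aliases[1L]))
    names(df)[hit[1L]]
}

#' Read direct gene-to-GO annotations (gene2go dialect)
#'
#' Parses an NCBI gene2go-style tab-separated file and applies the import
#' filters used when building GO-disease inferences: restriction to a
#' taxon allow-list, restriction to an evidence-code allow-list, removal
#' of rows whose qualifier contains \code{NOT}, removal of the three GO
#' branch-root placeholders (GO:0008150, GO:0003674, GO:0005575), and
#' deduplication on (gene, GO term).
#'
#' @param path tab-separated file with a header line (optionally
#'   "#"-prefixed) naming taxon, gene, GO id, evidence, qualifier and
#'   category columns.
#' @param taxa integer vector of taxon ids to keep, or \code{"all"}.
#' @param evidenceAllow character vector of evidence codes to keep, or
#'   \code{"all"}.
#' @param dropNotQualifier drop rows whose qualifier contains "NOT"
#'   (default TRUE).
#' @return an \linkS4class{AnnotationTable}.
#' @export
readGene2GO <- function(path, taxa = "all", evidenceAllow = "all",
                        dropNotQualifier = TRUE) {
    df <- .readCtdTsv(path)
    cTax <- .requireColumn(df, c("tax_id", "taxon", "taxid"), "tax_id", path)
    cGene <- .requireColumn(df, c("GeneID", "gene_id", "gene"), "GeneID", path)
    cGo <- .requireColumn(df, c("GO_ID", "go_id", "go_term", "GO"), "GO_ID",
                          path)
    cEv <- .requireColumn(df, c("Evidence", "evidence_code"), "Evidence",
                          path)
    cQual <- .requireColumn(df, "Qualifier", "Qualifier", path)
    cCat <- .requireColumn(df, c("Category", "branch", "namespace"),
                           "Category", path)
    cSym <- which(tolower(names(df)) %in% c("genesymbol", "gene_symbol",
                                            "symbol"))
    out <- data.frame(
        geneId = trimws(df[[cGene]]),
        geneSymbol = if (length(cSym)) trimws(df[[cSym[1L]]])
                     else trimws(df[[cGene]]),
        goTerm = trimws(df[[cGo]]),
        evidence = trimws(df[[cEv]]),
        qualifier = trimws(df[[cQual]]),
        taxon = suppressWarnings(as.integer(df[[cTax]])),
        category = .normalizeBranch(df[[cCat]]),
        stringsAsFactors = FALSE)
    if (!identical(taxa, "all"))
        out <- out[out$taxon %in% as.integer(taxa), , drop = FALSE]
    if (!identical(evidenceAllow, "all"))
        out <- out[out$evidence %in% evidenceAllow, , drop = FALSE]
    if (dropNotQualifier)
        out <- out[!grepl("NOT", out$qualifier, fixed = TRUE), , drop = FALSE]
    out <- out[!(out$goTerm %in% .GO_ROOTS), , drop = FALSE]
    out <- out[!duplicated(out[c("geneId", "goTerm")]), , drop = FALSE]
    rownames(out) <- NULL
    if (!nrow(out))
        warning("no annotation rows survive filtering of ", path)
    new("AnnotationTable", annotations = out)
}

.normalizeBranch <- function(x) {
    x <- tolower(trimws(x))
    map <- c(process = "biological_process",
             biological_process = "biological_process",
             "function" = "molecular_function",
             molecular_function = "molecular_function",
             component = "cellular_component",
             cellular_component = "cellular_component")
    out <- unname(map[x])
    ifelse(is.na(out), x, out)
}

## Normalize disease ids to prefix:accession (MESH:D010024).  Bare MeSH
## accessions (D/C + digits) get a MESH: prefix; bare digit runs get OMIM:.
.normalizeDiseaseId <- function(id) {
    id <- trimws(id)
    ok <- grepl("^[A-Za-z]+:[A-Za-z0-9.]+$", id)
    bareMesh <- !ok & grepl("^[DC][0-9]{6}$", id)
    bareOmim <- !ok & grepl("^[0-9]{3,}$", id)
    id[bareMesh] <- paste0("MESH:", id[bareMesh])
    id[bareOmim] <- paste0("OMIM:", id[bareOmim])
    id[!(ok | bareMesh | bareOmim)] <- NA_character_
    id
}

#' Read curated gene-disease associations (CTD dialect)
#'
#' @param path CTD-dialect TSV: "#"-prefixed comment lines with the header
#'   as the last comment (a plain header line is also accepted); columns
#'   for gene symbol, gene id, disease name, disease id and direct
#'   evidence.
#' @param directOnly when TRUE (default), drop rows with an empty
#'   direct-evidence field (CTD's inferred rows).
#' @return an \linkS4class{AssociationTable} of type \code{"gene_disease"}
#'   with genes as subjects and diseases as objects; disease ids are
#'   normalized to \code{prefix:accession} form, and rows with a malformed
#'   disease id are skipped with a message.
#' @export
readGeneDisease <- function(path, directOnly = TRUE) {
    df <- .readCtdTsv(path)
    cSym <- .requireColumn(df, c("GeneSymbol", "gene_symbol"), "GeneSymbol",
                           path)
    cGene <- .requireColumn(df, c("GeneID", "gene_id"), "GeneID", path)
    cDn <- .requireColumn(df, c("DiseaseName", "disease_name"), "DiseaseName",
                          path)
    cDid <- .requireColumn(df, c("DiseaseID", "disease_id"), "DiseaseID",
                           path)
    cEv <- .requireColumn(df, c("DirectEvidence", "direct_evidence"),
                          "DirectEvidence", path)
    geneId <- trimws(df[[cGene]])
    geneId <- ifelse(nzchar(geneId), geneId, trimws(df[[cSym]]))
    did <- .normalizeDiseaseId(df[[cDid]])
    bad <- is.na(did)
    if (any(bad)) {
        message(sum(bad), " row(s) with malformed disease id skipped")
    }
    out <- data.frame(
        subjectId = geneId[!bad],
        subjectName = trimws(df[[cSym]])[!bad],
        objectId = did[!bad],
        objectName = trimws(df[[cDn]])[!bad],
        evidence = trimws(df[[cEv]])[!bad],
        stringsAsFactors = FALSE)
    tab <- new("AssociationTable", associations = out, type = "gene_disease")
    if (directOnly) directEvidence(tab) else tab
}

#' Read chemical-gene or chemical-disease associations (CTD dialect)
#'
#' @param path CTD-dialect TSV with chemical name/id columns plus either
#'   gene or disease columns; the type is detected from the header.
#' @param evidenceFilter keep only rows whose direct-evidence label equals
#'   this value (exact, case-insensitive), or \code{NULL} for all rows.
#' @return an \linkS4class{AssociationTable} with chemicals as subjects.
#' @export
readChemAssoc <- function(path, evidenceFilter = NULL) {
    df <- .readCtdTsv(path)
    cCn <- .requireColumn(df, c("ChemicalName", "chemical_name"),
                          "ChemicalName", path)
    cCid <- .requireColumn(df, c("ChemicalID", "chemical_id"), "ChemicalID",
                           path)
    lowered <- tolower(names(df))
    isDisease <- any(lowered %in% c("diseaseid", "disease_id"))
    if (isDisease) {
        cOid <- .requireColumn(df, c("DiseaseID", "disease_id"), "DiseaseID",
                               path)
        cOn <- .requireColumn(df, c("DiseaseName", "disease_name"),
                              "DiseaseName", path)
        cEv <- .requireColumn(df, c("DirectEvidence", "direct_evidence"),
                              "DirectEvidence", path)
        oid <- .normalizeDiseaseId(df[[cOid]])
        bad <- is.na(oid)
        if (any(bad)) message(sum(bad),
                              " row(s) with malformed disease id skipped")
        ev <- trimws(df[[cEv]])[!bad]
        out <- data.frame(subjectId = trimws(df[[cCid]])[!bad],
                          subjectName = trimws(df[[cCn]])[!bad],
                          objectId = oid[!bad],
                          objectName = trimws(df[[cOn]])[!bad],
                          evidence = ev, stringsAsFactors = FALSE)
        type <- "chem_disease"
    } else {
        cOid <- .requireColumn(df, c("GeneID", "gene_id"), "GeneID", path)
        cOn <- .requireColumn(df, c("GeneSymbol", "gene_symbol"),
                              "GeneSymbol", path)
        cEv <- which(lowered %in% c("interactionactions",
                                    "interaction_actions", "directevidence"))
        ev <- if (length(cEv)) trimws(df[[cEv[1L]]])
              else rep("", nrow(df))
        out <- data.frame(subjectId = trimws(df[[cCid]]),
                          subjectName = trimws(df[[cCn]]),
                          objectId = trimws(df[[cOid]]),
                          objectName = trimws(df[[cOn]]),
                          evidence = ev, stringsAsFactors = FALSE)
        type <- "chem_gene"
    }
    if (!is.null(evidenceFilter))
        out <- out[tolower(out$evidence) == tolower(evidenceFilter), ,
                   drop = FALSE]
    rownames(out) <- NULL
    new("AssociationTable", associations = out, type = type)
}

#' Read a MEDIC-style disease hierarchy with slim categories
#'
#' @param path TSV with columns for disease id, disease name, parent ids
#'   (pipe-separated, possibly empty) and slim-category labels
#'   (pipe-separated, possibly empty).
#' @return a \linkS4class{DiseaseHierarchy}; a cycle among parent links is
#'   a validation error naming the cycle's members.
#' @export
readDiseaseHierarchy <- function(path) {
    df <- .readCtdTsv(path)
    cId <- .requireColumn(df, c("DiseaseID", "disease_id"), "DiseaseID",
                          path)
    cNm <- .requireColumn(df, c("DiseaseName", "disease_name"),
                          "DiseaseName", path)
    cPar <- .requireColumn(df, c("ParentIDs", "parent_ids", "parents"),
                           "ParentIDs", path)
    cSlim <- .requireColumn(df, c("SlimCategories", "slim_categories",
                                  "slim"), "SlimCategories", path)
    splitPipe <- function(x) {
        out <- strsplit(x, "|", fixed = TRUE)
        lapply(out, function(v) trimws(v[nzchar(trimws(v))]))
    }
    ids <- trimws(df[[cId]])
    parents <- setNames(splitPipe(df[[cPar]]), ids)
    slim <- setNames(splitPipe(df[[cSlim]]), ids)
    nm <- setNames(trimws(df[[cNm]]), ids)
    new("DiseaseHierarchy", parents = parents, slim = slim,
        diseaseName = nm)
}

#' Read a gene-gene interaction edge list
#'
#' @param path two-column TSV (gene, gene) with an optional third
#'   interaction-type column; a header line is detected when the first
#'   line's fields repeat known names (gene1/gene2) or start with "#".
#' @return data.frame with columns \code{gene1}, \code{gene2},
#'   \code{type}.
#' @export
readGeneGeneEdges <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    header <- grepl("^#", lines[1L]) ||
        grepl("^gene", tolower(lines[1L]))
    if (header) lines <- lines[-1L]
    parts <- strsplit(lines, "\t")
    data.frame(
        gene1 = vapply(parts, `[`, "", 1L),
        gene2 = vapply(parts, `[`, "", 2L),
        type = vapply(parts, function(p)
            if (length(p) >= 3L) p[3L] else "", ""),
        stringsAsFactors = FALSE)
}

## ---- accessors & show ----

#' @describeIn accessors annotation rows of an AnnotationTable.
#' @export
setMethod("annotations", "AnnotationTable", function(x, ...) x@annotations)

#' @describeIn accessors association rows of an AssociationTable.
#' @export
setMethod("associations", "AssociationTable", function(x, ...)
    x@associations)

#' @describeIn accessors the association type string.
#' @export
setMethod("associationType", "AssociationTable", function(x) x@type)

#' @describeIn directEvidence rows with a nonempty evidence label.
#' @export
setMethod("directEvidence", "AssociationTable", function(x) {
    a <- x@associations
    new("AssociationTable",
        associations = a[nzchar(a$evidence), , drop = FALSE],
        type = x@type)
})

#' @describeIn slimCategories slim mapping accessor.
#' @export
setMethod("slimCategories", "DiseaseHierarchy", function(x) x@slim)

setMethod("show", "AnnotationTable", function(object) {
    a <- object@annotations
    cat("AnnotationTable with", nrow(a), "annotations (",
        length(unique(a$geneId)), "genes,",
        length(unique(a$goTerm)), "GO terms )\n")
})

setMethod("show", "AssociationTable", function(object) {
    a <- object@associations
    cat("AssociationTable <", object@type, "> with ", nrow(a), " rows (",
        length(unique(a$subjectId)), " subjects, ",
        length(unique(a$objectId)), " objects)\n", sep = "")
})

setMethod("show", "DiseaseHierarchy", function(object) {
    cat("DiseaseHierarchy with", length(object@parents), "diseases,",
        length(unique(unlist(object@slim))), "slim categories\n")
})
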