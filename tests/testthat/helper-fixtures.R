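## In-code fixtures and independent oracles shared across the suite.

## build an OntologyGraph directly from an edge table (single-branch BP
## by default); terms are inferred from the edges plus `extraTerms`
makeGraph <- function(edges, namespace = "biological_process",
                      extraTerms = character()) {
    terms <- unique(c(edges$child, edges$parent, extraTerms))
    ns <- if (length(namespace) == 1L)
              setNames(rep(namespace, length(terms)), terms)
          else namespace[terms]
    new("OntologyGraph", terms = terms,
        termName = setNames(paste("term", terms), terms),
        termNamespace = ns,
        edges = edges, obsolete = character(0),
        altId = setNames(character(0), character(0)))
}

edgeDf <- function(child, parent, relation = "is_a") {
    data.frame(child = child, parent = parent, relation = relation,
               stringsAsFactors = FALSE)
}

## random single-root DAG; node i only points to earlier nodes, so the
## result is acyclic and every term reaches ids[1]
randomDAG <- function(nTerms, seed, p2 = 0.3) {
    set.seed(seed)
    ids <- sprintf("GO:%07d", 1000000L + seq_len(nTerms))
    child <- character(); parent <- character()
    for (i in seq.int(2L, nTerms)) {
        np <- 1L + as.integer(i > 2L && runif(1) < p2)
        ps <- sample(ids[seq_len(i - 1L)], np)
        child <- c(child, rep(ids[i], np))
        parent <- c(parent, ps)
    }
    makeGraph(edgeDf(child, parent))
}

## naive recursive ancestor closure over an edge table
bruteAncestors <- function(edges, term, relations = "is_a") {
    e <- edges[edges$relation %in% relations, , drop = FALSE]
    ps <- e$parent[e$child == term]
    sort(unique(c(term, unlist(lapply(ps, function(p)
        bruteAncestors(e, p, relations))))))
}

## enumerate the lengths of ALL root-to-term is_a paths (for shortest-
## path checks independent of BFS)
allPathLengths <- function(edges, term, root) {
    if (term == root) return(0L)
    ps <- edges$parent[edges$child == term & edges$relation == "is_a"]
    unlist(lapply(ps, function(p)
        1L + allPathLengths(edges, p, root)))
}

## quick constructors for the S4 tables
annTable <- function(gene, term, branch = "biological_process",
                     taxon = 9606L) {
    new("AnnotationTable", annotations = data.frame(
        geneId = as.character(gene), geneSymbol = paste0("G", gene),
        goTerm = term, evidence = "IDA", qualifier = "",
        taxon = taxon, category = branch, stringsAsFactors = FALSE))
}

gdTable <- function(gene, disease, evidence = "marker/mechanism") {
    new("AssociationTable", associations = data.frame(
        subjectId = as.character(gene), subjectName = paste0("G", gene),
        objectId = disease, objectName = paste("name", disease),
        evidence = evidence, stringsAsFactors = FALSE),
        type = "gene_disease")
}

cgTable <- function(chem, gene) {
    new("AssociationTable", associations = data.frame(
        subjectId = chem, subjectName = paste("chem", chem),
        objectId = as.character(gene), objectName = paste0("G", gene),
        evidence = "", stringsAsFactors = FALSE), type = "chem_gene")
}

cdTable <- function(chem, disease, evidence) {
    new("AssociationTable", associations = data.frame(
        subjectId = chem, subjectName = paste("chem", chem),
        objectId = disease, objectName = paste("name", disease),
        evidence = evidence, stringsAsFactors = FALSE),
        type = "chem_disease")
}

## triple-nested-loop transitive-inference join (independent oracle):
## returns sorted data.frame(goTerm, disease, genes = "a|b|c")
bruteInfer <- function(annDf, gdDf) {
    out <- list()
    for (t in unique(annDf$goTerm)) {
        for (d in unique(gdDf$objectId)) {
            genes <- character()
            for (g in unique(annDf$geneId)) {
                if (any(annDf$geneId == g & annDf$goTerm == t) &&
                    any(gdDf$subjectId == g & gdDf$objectId == d))
                    genes <- c(genes, g)
            }
            if (length(genes))
                out[[length(out) + 1L]] <- data.frame(
                    goTerm = t, disease = d,
                    genes = paste(sort(genes, method = "radix"),
                                  collapse = "|"),
                    stringsAsFactors = FALSE)
        }
    }
    if (!length(out))
        return(data.frame(goTerm = character(), disease = character(),
                          genes = character(), stringsAsFactors = FALSE))
    r <- do.call(rbind, out)
    r <- r[order(r$goTerm, r$disease, method = "radix"), , drop = FALSE]
    rownames(r) <- NULL
    r
}

## flatten an InferenceSet to the oracle's shape
flattenInferences <- function(inf) {
    r <- inferenceRecords(inf)
    out <- data.frame(goTerm = r$goTerm, disease = r$disease,
                      genes = vapply(r$genes, paste, "", collapse = "|"),
                      stringsAsFactors = FALSE)
    out <- out[order(out$goTerm, out$disease, method = "radix"), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}

## hypergeometric upper tail by exhaustive subset enumeration:
## draw all n-subsets of 1..N, overlap with the fixed set 1..K
enumOverlapTail <- function(k, K, n, N) {
    if (n == 0L || N == 0L) return(as.numeric(k <= 0L))
    subsets <- utils::combn(N, n)
    ov <- apply(subsets, 2L, function(s) sum(s <= K))
    mean(ov >= k)
}

## textbook Pearson chi-square (independent of stats::chisq.test)
textbookChiSq <- function(obs) {
    E <- outer(rowSums(obs), colSums(obs)) / sum(obs)
    stat <- sum((obs - E)^2 / E)
    df <- (nrow(obs) - 1L) * (ncol(obs) - 1L)
    list(statistic = stat, p = stats::pchisq(stat, df,
                                             lower.tail = FALSE))
}

## serialize a parsed graph back to OBO text (round-trip oracle support)
writeGraphAsOBO <- function(graph, path) {
    lines <- c("format-version: 1.2", "")
    for (id in sort(goTerms(graph), method = "radix")) {
        lines <- c(lines, "[Term]", paste0("id: ", id),
                   paste0("name: ", termName(graph)[[id]]),
                   paste0("namespace: ", termNamespace(graph)[[id]]))
        e <- graph@edges[graph@edges$child == id, , drop = FALSE]
        e <- e[order(e$parent, e$relation, method = "radix"), ,
               drop = FALSE]
        for (j in seq_len(nrow(e)))
            lines <- c(lines,
                       if (e$relation[j] == "is_a")
                           paste0("is_a: ", e$parent[j])
                       else paste0("relationship: part_of ", e$parent[j]))
        lines <- c(lines, "")
    }
    writeLines(lines, path)
    path
}

## compare two graphs structurally
expectSameGraph <- function(g1, g2) {
    expect_setequal(goTerms(g1), goTerms(g2))
    expect_equal(termNamespace(g1)[sort(goTerms(g1))],
                 termNamespace(g2)[sort(goTerms(g2))])
    e1 <- g1@edges[order(g1@edges$child, g1@edges$parent,
                         g1@edges$relation), ]
    e2 <- g2@edges[order(g2@edges$child, g2@edges$parent,
                         g2@edges$relation), ]
    rownames(e1) <- rownames(e2) <- NULL
    expect_equal(e1, e2)
}
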