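#' Reflexive-transitive ancestor closure
#'
#' @param x an \linkS4class{OntologyGraph} or
#'   \linkS4class{DiseaseHierarchy}.
#' @param term a term (or disease) identifier.
#' @param relations character vector of relation names to traverse
#'   (ontology only); default \code{"is_a"}.
#' @return character vector of identifiers, always containing \code{term}.
#' @export
setGeneric("ancestors", function(x, term, relations = "is_a")
    standardGeneric("ancestors"))

#' Reflexive-transitive descendant closure
#'
#' @inheritParams ancestors
#' @return character vector of identifiers, always containing \code{term}.
#' @export
setGeneric("descendants", function(x, term, relations = "is_a")
    standardGeneric("descendants"))

#' Granularity level of a GO term
#'
#' Length of the shortest \code{is_a} path from the branch root down to the
#' term; roots sit at level 0, their direct children at level 1.  Higher
#' level means a more specific term.
#'
#' @param x an \linkS4class{OntologyGraph}.
#' @param term a term identifier (alternate ids are resolved).
#' @return nonnegative integer.
#' @export
setGeneric("termLevel", function(x, term) standardGeneric("termLevel"))

#' Accessors for ontology and table containers
#'
#' @param x the object.
#' @param ... unused.
#' @return \code{goTerms}: the non-obsolete term ids; \code{branchRoots}:
#'   named vector of the three branch roots present; \code{termName} /
#'   \code{termNamespace}: named character vectors (optionally subset by
#'   \code{term}); \code{associations} / \code{annotations} /
#'   \code{inferenceRecords}: the underlying data.frame.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("goTerms", function(x, ...) standardGeneric("goTerms"))

#' @rdname accessors
#' @export
setGeneric("branchRoots", function(x, ...) standardGeneric("branchRoots"))

#' @rdname accessors
#' @param term optional term id(s) to subset to.
#' @export
setGeneric("termName", function(x, term = NULL) standardGeneric("termName"))

#' @rdname accessors
#' @export
setGeneric("termNamespace", function(x, term = NULL)
    standardGeneric("termNamespace"))

#' @rdname accessors
#' @export
setGeneric("annotations", function(x, ...) standardGeneric("annotations"))

#' @rdname accessors
#' @export
setGeneric("associations", function(x, ...) standardGeneric("associations"))

#' @rdname accessors
#' @export
setGeneric("associationType", function(x) standardGeneric("associationType"))

#' @rdname accessors
#' @export
setGeneric("inferenceRecords", function(x, ...)
    standardGeneric("inferenceRecords"))

#' Direct-evidence view of an association table
#'
#' Restricts an \linkS4class{AssociationTable} to rows carrying a nonempty
#' direct-evidence label (dropping CTD's inferred rows).
#'
#' @param x an \linkS4class{AssociationTable}.
#' @return an \linkS4class{AssociationTable}.
#' @export
setGeneric("directEvidence", function(x) standardGeneric("directEvidence"))

#' Slim-category mapping of a disease hierarchy
#'
#' @param x a \linkS4class{DiseaseHierarchy}.
#' @return named list, disease id -> character vector of slim categories.
#' @export
setGeneric("slimCategories", function(x) standardGeneric("slimCategories"))
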