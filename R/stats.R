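## Overlap significance: hypergeometric 2x2 test, Pearson chi-square,
## Bonferroni adjustment.

#' Hypergeometric significance of a set overlap
#'
#' Upper-tail probability P(X >= k) that two sets of sizes K and n drawn
#' from a universe of N elements share at least the observed k elements,
#' with X ~ Hypergeometric(N, K, n).  This is the one-sided 2x2
#' contingency-table test of overlap enrichment; the tail is evaluated in
#' log space by \code{stats::phyper} for numerical stability.
#'
#' @param k observed overlap count.
#' @param K size of set A.
#' @param n size of set B.
#' @param N universe size (e.g. all candidate GO-BP terms).
#' @return a real in (0, 1].
#' @examples
#' hypergeomOverlapP(5, 5, 5, 10)  # 1 / choose(10, 5)
#' @export
hypergeomOverlapP <- function(k, K, n, N) {
    if (K > N || n > N)
        stop("set sizes exceed the universe (K, n must be <= N)")
    if (k < max(0, K + n - N) || k > min(K, n))
        stop("overlap k outside the feasible range [",
             max(0, K + n - N), ", ", min(K, n), "]")
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Pearson chi-square test of an r x c count table
#'
#' Statistic sum((O - E)^2 / E) with expectations from the row/column
#' margins, referred to the chi-square distribution with
#' (r - 1)(c - 1) degrees of freedom (no continuity correction).
#'
#' @param observed numeric matrix of counts with positive margins and
#'   positive expected counts.
#' @return list with \code{statistic}, \code{df}, \code{p}.
#' @export
chiSquareP <- function(observed) {
    observed <- as.matrix(observed)
    if (any(rowSums(observed) == 0) || any(colSums(observed) == 0))
        stop("zero row or column margin: expected counts undefined")
    ct <- suppressWarnings(stats::chisq.test(observed, correct = FALSE))
    if (any(ct$expected <= 0))
        stop("nonpositive expected cell count")
    list(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p = unname(ct$p.value))
}

#' Bonferroni adjustment of p-values
#'
#' Each adjusted value is min(1, m * p), preserving order.  \code{m}
#' defaults to the number of p-values (the usual family size for a
#' pairwise comparison matrix).
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @param m family size; \code{"auto"} (default) uses
#'   \code{length(p)}; an explicit m must be >= length(p).
#' @return numeric vector of adjusted p-values.
#' @export
bonferroniAdjust <- function(p, m = "auto") {
    if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
    if (identical(m, "auto")) m <- length(p)
    if (m < length(p)) stop("family size m must be >= length(p)")
    pmin(1, m * p)
}

#' Set-membership contingency table for multi-set overlap
#'
#' Default construction for testing the significance of overlap among
#' several term sets (e.g. the inferred GO-BP terms of three diseases)
#' with \code{\link{chiSquareP}}: one row per set, columns counting the
#' universe terms inside and outside the set.  The universe defaults to
#' the union of the sets.
#'
#' @param sets named list of character vectors.
#' @param universe character vector containing every set element.
#' @return integer matrix, |sets| x 2, columns \code{member} /
#'   \code{nonmember}.
#' @export
overlapContingency <- function(sets, universe = NULL) {
    if (is.null(universe)) universe <- unique(unlist(sets))
    if (!all(unlist(sets) %in% universe))
        stop("universe must contain every set element")
    m <- t(vapply(sets, function(s) {
        inside <- length(intersect(unique(s), universe))
        c(member = inside, nonmember = length(universe) - inside)
    }, c(member = 0L, nonmember = 0L)))
    m
}
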