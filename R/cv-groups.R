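# Chromosome-balanced cross-validation: pairs on one chromosome always share
# a fold, and chromosomes are greedily paired largest-with-smallest so folds
# carry similar numbers of pairs.

#' Assign chromosome-balanced cross-validation groups
#'
#' Greedy pairing of chromosomes by pair count: the chromosome with the
#' most pairs forms its own group; the remaining chromosomes, sorted by
#' count, are repeatedly combined current-largest with current-smallest
#' into two-chromosome groups; an odd leftover chromosome forms its own
#' group. With `C` chromosomes carrying pairs this yields
#' `1 + ceiling((C - 1) / 2)` groups — 12 groups for the 23 human
#' chromosomes 1-22 and X. Count ties are broken by lexicographic
#' chromosome name; group labels `cv-0`, `cv-1`, ... are ordered by
#' descending group pair count.
#'
#' @param x either a named numeric vector of per-chromosome pair counts
#'   (zero-count chromosomes are ignored) or a [BenchmarkDataset-class],
#'   whose pairs (both labels) are counted per chromosome.
#' @return a [CvAssignment-class].
#' @examples
#' assignChromCV(c(chrA = 10, chrB = 6, chrC = 5, chrD = 1))
#' @export
setGeneric("assignChromCV", function(x) standardGeneric("assignChromCV"))

#' @rdname assignChromCV
#' @export
setMethod("assignChromCV", "numeric", function(x) {
    x <- x[x > 0]
    if (length(x) == 0L)
        stop("no chromosome carries any pair")
    ord <- order(-x, names(x), method = "radix")
    chroms <- names(x)[ord]
    counts <- unname(x[ord])
    groups <- list(chroms[1L])
    rest <- chroms[-1L]
    while (length(rest) >= 2L) {
        groups[[length(groups) + 1L]] <- c(rest[1L], rest[length(rest)])
        rest <- rest[-c(1L, length(rest))]
    }
    if (length(rest) == 1L) groups[[length(groups) + 1L]] <- rest
    sizes <- vapply(groups, function(g) sum(x[g]), numeric(1))
    minName <- vapply(groups, min, character(1))
    gord <- order(-sizes, minName, method = "radix")
    labels <- paste0("cv-", seq_along(groups) - 1L)
    map <- character(0)
    for (i in seq_along(gord)) {
        g <- groups[[gord[i]]]
        map[g] <- labels[i]
    }
    new("CvAssignment", groups = map,
        sizes = setNames(sizes[gord], labels))
})

#' @rdname assignChromCV
#' @export
setMethod("assignChromCV", "BenchmarkDataset", function(x) {
    counts <- table(benchmarkPairs(x)$chrom)
    assignChromCV(setNames(as.numeric(counts), names(counts)))
})

#' @describeIn CvAssignment-class chromosome -> group mapping.
#' @param x,object a `CvAssignment`.
#' @export
cvGroups <- function(x) x@groups

#' @rdname cvGroups
#' @export
cvGroupSizes <- function(x) x@sizes

setMethod("show", "CvAssignment", function(object) {
    cat("CvAssignment:", length(unique(object@groups)), "group(s) over",
        length(object@groups), "chromosome(s)\n")
    for (g in names(object@sizes)) {
        cat("  ", g, " (", object@sizes[[g]], " pairs): ",
            paste(sort(names(object@groups)[object@groups == g]),
                  collapse = ", "), "\n", sep = "")
    }
})

#' Stamp CV groups onto a dataset
#'
#' `setChromCV()` writes `assignment`'s group of each pair's chromosome
#' into the `cv_group` column; `addChromCV()` computes the assignment from
#' the dataset itself first.
#'
#' @param dataset a [BenchmarkDataset-class].
#' @param assignment a [CvAssignment-class] covering every chromosome with
#'   pairs (missing chromosomes are an error listing them).
#' @return the dataset with `cv_group` filled in.
#' @export
setChromCV <- function(dataset, assignment) {
    p <- benchmarkPairs(dataset)
    missing <- setdiff(unique(p$chrom), names(cvGroups(assignment)))
    if (length(missing))
        stop("chromosomes absent from the CV assignment: ",
             paste(sort(missing), collapse = ", "))
    p$cv_group <- unname(cvGroups(assignment)[p$chrom])
    .replacePairs(dataset, p)
}

#' @rdname setChromCV
#' @export
addChromCV <- function(dataset) {
    setChromCV(dataset, assignChromCV(dataset))
}

#' Transfer a training CV assignment to a test dataset
#'
#' For cross-cell-type evaluation the test pairs inherit the chromosome
#' grouping of the training dataset, so that no chromosome is ever split
#' between a training fold and the test fold scored by its model.
#'
#' @param trainAssignment the training dataset's [CvAssignment-class].
#' @param dataset the test [BenchmarkDataset-class].
#' @return the test dataset with `cv_group` taken from the training
#'   assignment.
#' @export
transferCV <- function(trainAssignment, dataset) {
    setChromCV(dataset, trainAssignment)
}

#' Randomised cross-validation folds (leakage comparator)
#'
#' Assigns pairs to `k` folds uniformly at random, ignoring chromosomes.
#' This reproduces the traditional CV scheme whose positional leakage the
#' chromosome-based grouping exists to prevent; it is provided for
#' side-by-side comparisons, not for benchmarking.
#'
#' @param dataset a [BenchmarkDataset-class].
#' @param k number of folds; default 12.
#' @param seed RNG seed.
#' @return the dataset with `cv_group` set to `rnd-0` ... `rnd-(k-1)`.
#' @export
randomCV <- function(dataset, k = 12L, seed = 1L) {
    p <- benchmarkPairs(dataset)
    p$cv_group <- withSeed(seed,
        paste0("rnd-", sample.int(k, nrow(p), replace = TRUE) - 1L))
    .replacePairs(dataset, p)
}
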