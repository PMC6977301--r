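# Evaluation: step-wise precision-recall curves and AUPR, set-level
# precision/recall for the closest-gene method, dataset overlap, and
# benchmark characterisation summaries.

#' Precision-recall curve and AUPR
#'
#' Thresholds are placed at the distinct score values in decreasing order;
#' all pairs sharing a score enter the confusion counts at one threshold,
#' so the curve has no dependence on the ordering of ties. The area is the
#' step-wise sum \eqn{\sum_i (R_i - R_{i-1}) P_i} (no interpolation).
#' Under all-equal scores the single-threshold curve gives an AUPR equal
#' to the positive fraction, the random-ranking baseline.
#'
#' @param scores numeric scores, higher = more confident.
#' @param labels 0/1 labels aligned with `scores`; both classes must be
#'   present.
#' @return a [PrecisionRecallCurve-class].
#' @examples
#' aupr(prCurve(c(4, 3, 2, 1), c(1, 1, 0, 0)))
#' @export
prCurve <- function(scores, labels) {
    stopifnot(length(scores) == length(labels))
    labels <- as.integer(labels)
    P <- sum(labels == 1L)
    N <- sum(labels == 0L)
    if (P == 0L || N == 0L)
        stop("precision-recall needs both classes present")
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]
    y <- labels[ord]
    last <- cumsum(rle(s)$lengths)  # last index of each distinct score
    tp <- cumsum(y)[last]
    n <- last
    precision <- tp / n
    recall <- tp / P
    aupr <- sum(diff(c(0, recall)) * precision)
    new("PrecisionRecallCurve", thresholds = s[last], precision = precision,
        recall = recall, aupr = aupr)
}

#' @describeIn PrecisionRecallCurve-class area under the curve.
#' @param x,object a `PrecisionRecallCurve`.
#' @export
aupr <- function(x) x@aupr

setMethod("show", "PrecisionRecallCurve", function(object) {
    cat("PrecisionRecallCurve:", length(object@thresholds),
        "threshold(s), AUPR =", signif(object@aupr, 4), "\n")
})

#' Export a precision-recall curve as TSV
#'
#' @param curve a [PrecisionRecallCurve-class].
#' @param file path.
#' @return `file`, invisibly.
#' @export
writePrCurve <- function(curve, file) {
    fwrite(data.table(threshold = curve@thresholds,
                      precision = curve@precision, recall = curve@recall),
           file, sep = "\t", eol = "\n")
    invisible(file)
}

#' Set-level precision and recall
#'
#' For all-or-nothing predictions (such as the closest-gene assignment):
#' precision is the fraction of predicted pairs that are positive and
#' recall the fraction of positive pairs predicted. Pair sets are
#' identified by their `element|gene` keys.
#'
#' @param predicted,positive character vectors of pair keys (see
#'   [pairKeys()]); an empty positive set is an error, an empty predicted
#'   set yields precision 0.
#' @return named numeric vector `c(precision, recall)`.
#' @export
overallPrecisionRecall <- function(predicted, positive) {
    positive <- unique(positive)
    predicted <- unique(predicted)
    if (length(positive) == 0L)
        stop("the positive pair set is empty")
    hit <- length(intersect(predicted, positive))
    c(precision = if (length(predicted) == 0L) 0 else hit / length(predicted),
      recall = hit / length(positive))
}

#' Pair keys of a dataset or pair table
#'
#' @param x a [BenchmarkDataset-class] or data.frame with `element_id` and
#'   `gene_id`.
#' @param label optional label filter (1 = positives, 0 = negatives).
#' @return character vector of `element|gene` keys.
#' @export
pairKeys <- function(x, label = NULL) {
    p <- if (is(x, "BenchmarkDataset")) benchmarkPairs(x) else x
    if (!is.null(label) && !is.null(p$label))
        p <- p[p$label == label, , drop = FALSE]
    pairKey(p$element_id, p$gene_id)
}

#' Overlap coefficient between two positive pair sets
#'
#' The number of pairs shared between the two sets divided by the size of
#' the smaller set; 1 for identical sets, 0 for disjoint ones.
#'
#' @param a,b character vectors of pair keys; both must be non-empty.
#' @return a number in \[0, 1\].
#' @examples
#' overlapCoefficient(c("a", "b", "c"), c("b", "c", "d", "e"))
#' @export
overlapCoefficient <- function(a, b) {
    a <- unique(a)
    b <- unique(b)
    if (length(a) == 0L || length(b) == 0L)
        stop("overlap coefficient of an empty set is undefined")
    length(intersect(a, b)) / min(length(a), length(b))
}

#' Characterise a benchmark dataset
#'
#' Summary statistics of a curated dataset: class counts and positive
#' fraction, nearest-rank distance percentiles of the positive pairs
#' (the 95th equals the dataset's negative-candidate cutoff by
#' construction), the histogram of positively linked genes per element,
#' and optionally the mean expression of positive-pair genes (averaging
#' the replicate columns per gene) and the mean per-element track signal.
#'
#' @param dataset a [BenchmarkDataset-class].
#' @param expression optional data.frame/matrix of replicate expression
#'   values with gene identifiers as row names.
#' @param signal optional named numeric vector of per-element mean track
#'   signal.
#' @return a list with elements `nPos`, `nNeg`, `positiveFraction`,
#'   `distancePercentiles`, `genesPerElement`, `expression` (mean TPM per
#'   positive-pair gene, with `nMissing` genes absent from the table) and
#'   `meanSignal`.
#' @export
characterizeDataset <- function(dataset, expression = NULL, signal = NULL) {
    p <- benchmarkPairs(dataset)
    pos <- p[p$label == 1L, , drop = FALSE]
    out <- list(nPos = nrow(pos), nNeg = sum(p$label == 0L))
    out$positiveFraction <- if (nrow(p)) out$nPos / nrow(p) else NA_real_
    probs <- c(5, 25, 50, 75, 95)
    out$distancePercentiles <- if (nrow(pos))
        setNames(vapply(probs, function(q)
            nearestRankPercentile(pos$distance, q), numeric(1)),
            paste0("p", probs))
    else setNames(rep(NA_real_, length(probs)), paste0("p", probs))
    out$genesPerElement <- table(table(pos$element_id))
    if (!is.null(expression)) {
        genes <- unique(pos$gene_id)
        present <- genes %in% rownames(expression)
        means <- if (any(present))
            rowMeans(as.matrix(expression[genes[present], , drop = FALSE]))
        else numeric(0)
        out$expression <- list(meanTpm = means, nMissing = sum(!present))
    }
    if (!is.null(signal)) {
        els <- unique(pos$element_id)
        out$meanSignal <- mean(signal[intersect(els, names(signal))])
    }
    out
}
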