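# Benchmark curation: positive pairs from assay evidence, distance-percentile
# negatives, the ambiguity-stripped and fixed-ratio dataset variants, and the
# matched subsets used to dissect supervised-model performance.

#' Construct a curation policy
#'
#' @param promoterWindow bp each side of a TSS within which an interaction
#'   anchor is considered to cover the gene's promoter (inclusive).
#' @param negativePercentile percentile of positive-pair distances defining
#'   the negative-candidate distance cutoff (nearest-rank convention).
#' @param fixedRatio negatives drawn per positive in fixed-ratio variants.
#' @param minNegatives minimum eligible negatives an element must have to
#'   stay in a fixed-ratio variant.
#' @param matchedRatio negatives per positive in matched subsets.
#' @param nDistanceBins equal-occupancy distance bins for distance-matched
#'   subsets.
#' @param seed integer seed from which every random draw in curation flows.
#' @return a [CurationPolicy-class].
#' @examples
#' curationPolicy()
#' @export
curationPolicy <- function(promoterWindow = 2000, negativePercentile = 95,
                           fixedRatio = 4L, minNegatives = 4L,
                           matchedRatio = 2L, nDistanceBins = 5L,
                           seed = 1L) {
    new("CurationPolicy", promoterWindow = as.numeric(promoterWindow),
        negativePercentile = as.numeric(negativePercentile),
        fixedRatio = as.integer(fixedRatio),
        minNegatives = as.integer(minNegatives),
        matchedRatio = as.integer(matchedRatio),
        nDistanceBins = as.integer(nDistanceBins), seed = as.integer(seed))
}

setMethod("show", "CurationPolicy", function(object) {
    cat("CurationPolicy: promoter window ±", object@promoterWindow,
        "bp; negatives within p", object@negativePercentile,
        " of positive distances; fixed ratio 1:", object@fixedRatio,
        " (min ", object@minNegatives, "); matched 1:", object@matchedRatio,
        "; ", object@nDistanceBins, " distance bins; seed ", object@seed,
        "\n", sep = "")
})

#' Positive pairs from 3D chromatin interaction links
#'
#' For each link and each anchor orientation, if one anchor intersects at
#' least one distal element and the opposite anchor lies within the
#' promoter window of at least one TSS, element-gene pairs are emitted for
#' every intersecting element: when the TSS-side anchor covers the window
#' of exactly one distinct gene the pairs are unambiguous; when it covers
#' two or more genes, pairs are emitted for all of them flagged ambiguous.
#' The element anchor and TSS anchor must be different anchors of the link.
#' Pairs are deduplicated across links and orientations; a pair keeps the
#' ambiguous flag only if every link supporting it was ambiguous.
#'
#' @param links a [ChromatinLinks-class].
#' @param elements distal elements ([GenomicRanges::GRanges] with
#'   `element_id`), i.e. [selectDistalElements()] output.
#' @param tss a [TssIndex-class].
#' @param policy a [CurationPolicy-class]; only `promoterWindow` is used.
#' @return data.frame of positives with columns `element_id`, `gene_id`,
#'   `ambiguous` (0/1) and `distance` (bp to the gene's nearest TSS).
#'   The number of links yielding no pair is attached as attribute
#'   `"nUnlinked"`.
#' @export
pairsFromLinks <- function(links, elements, tss, policy = curationPolicy()) {
    W <- policy@promoterWindow
    linked <- logical(length(links))
    anchors <- list(links@anchor1, links@anchor2)
    found <- list()
    for (ori in list(c(1L, 2L), c(2L, 1L))) {
        aE <- anchors[[ori[1L]]]
        aT <- anchors[[ori[2L]]] + W  # TSS point within +/- W of the anchor
        elHits <- findOverlaps(aE, elements, ignore.strand = TRUE)
        tssHits <- findOverlaps(aT, tss, ignore.strand = TRUE)
        if (length(elHits) == 0L || length(tssHits) == 0L) next
        elDt <- data.table(link = queryHits(elHits),
                           element_id = mcols(elements)$element_id[subjectHits(elHits)])
        geneDt <- unique(data.table(link = queryHits(tssHits),
                                    gene_id = mcols(tss)$gene_id[subjectHits(tssHits)]))
        geneDt[, nGenes := .N, by = "link"]
        merged <- merge(elDt, geneDt, by = "link", allow.cartesian = TRUE)
        if (nrow(merged) == 0L) next
        linked[unique(merged$link)] <- TRUE
        merged[, ambiguous := nGenes >= 2L]
        found[[length(found) + 1L]] <-
            merged[, c("element_id", "gene_id", "ambiguous"), with = FALSE]
    }
    if (length(found)) {
        all <- rbindlist(found)
        agg <- all[, list(ambiguous = as.integer(all(ambiguous))),
                   by = c("element_id", "gene_id")]
        out <- as.data.frame(agg)
        out <- orderPairs(out)
        rownames(out) <- NULL
    } else {
        out <- data.frame(element_id = character(), gene_id = character(),
                          ambiguous = integer())
    }
    out$distance <- pairGeneDistances(out, elements, tss)
    nUnlinked <- sum(!linked)
    if (nUnlinked > 0)
        message(nUnlinked, " link(s) produced no element-gene pair")
    attr(out, "nUnlinked") <- nUnlinked
    out
}

#' Positive pairs from variant-gene or perturbation-gene associations
#'
#' A positive pair is emitted for every element containing the associated
#' variant position (or overlapping the perturbed region), paired with the
#' association's gene. Associations whose gene is absent from the TSS index
#' are skipped and counted. The explicit gene makes ambiguity flags
#' unnecessary for these assays.
#'
#' @param associations data.frame with columns `chrom`, `gene_id` and
#'   either `pos` (0-based variant position) or `start`/`end` (0-based
#'   half-open perturbed region), as returned by [readEqtl()] /
#'   [readCrisprQtl()].
#' @param elements distal elements restricted to the assay's biosample.
#' @param tss a [TssIndex-class].
#' @return data.frame of positives (`element_id`, `gene_id`, `ambiguous`
#'   all 0, `distance`), deduplicated; skipped-gene count in attribute
#'   `"nSkippedGenes"`.
#' @export
pairsFromAssociations <- function(associations, elements, tss) {
    known <- unique(mcols(tss)$gene_id)
    inAnn <- associations$gene_id %in% known
    if (any(!inAnn))
        message(sum(!inAnn), " association(s) with genes absent from the ",
                "annotation skipped")
    assoc <- associations[inAnn, , drop = FALSE]
    if (!is.null(assoc$pos)) {
        qry <- GRanges(assoc$chrom, IRanges(as.integer(assoc$pos) + 1L,
                                            width = 1L))
    } else {
        qry <- GRanges(assoc$chrom, IRanges(as.integer(assoc$start) + 1L,
                                            as.integer(assoc$end)))
    }
    hits <- findOverlaps(qry, elements, ignore.strand = TRUE)
    out <- unique(data.frame(
        element_id = mcols(elements)$element_id[subjectHits(hits)],
        gene_id = assoc$gene_id[queryHits(hits)]))
    out <- orderPairs(out)
    rownames(out) <- NULL
    out$ambiguous <- integer(nrow(out))
    out$distance <- pairGeneDistances(out, elements, tss)
    attr(out, "nSkippedGenes") <- sum(!inAnn)
    out
}

#' Distance cutoff for negative-pair generation
#'
#' The nearest-rank percentile (the `ceil(p/100 * n)`-th order statistic)
#' of the positive-pair distances. Invariant under permutation of the
#' input; a single positive returns its own distance.
#'
#' @param positives data.frame of positive pairs with a `distance` column.
#' @param percentile percentile in (0, 100]; default 95.
#' @return the cutoff in bp.
#' @export
negativeCutoff <- function(positives, percentile = 95) {
    d <- positives$distance
    d <- d[is.finite(d)]
    if (length(d) == 0L)
        stop("no positive pairs with finite distances")
    nearestRankPercentile(d, percentile)
}

#' Generate negative pairs under a distance cutoff
#'
#' For every element that appears in at least one positive pair with
#' distance at most `cutoff`, each annotation gene whose nearest TSS lies
#' within `cutoff` of the element (inclusive) becomes a negative pair,
#' unless the gene is already positive for that element or, with
#' `excludeAmbiguousPairs`, the element is ambiguously linked to it.
#' Positives further than the cutoff are retained upstream as positives but
#' spawn no negatives here.
#'
#' @param positives data.frame of positive pairs (`element_id`, `gene_id`,
#'   `distance`).
#' @param elements distal elements.
#' @param tss a [TssIndex-class]; its genes are the candidate universe.
#' @param cutoff distance cutoff in bp, from [negativeCutoff()].
#' @param excludeAmbiguousPairs optional data.frame (`element_id`,
#'   `gene_id`) of ambiguous pairs whose genes must not become negatives
#'   for those elements.
#' @return data.frame of negatives (`element_id`, `gene_id`, `ambiguous`
#'   all 0, `distance`).
#' @export
generateNegatives <- function(positives, elements, tss, cutoff,
                              excludeAmbiguousPairs = NULL) {
    elig <- unique(positives$element_id[is.finite(positives$distance) &
                                        positives$distance <= cutoff])
    empty <- data.frame(element_id = character(), gene_id = character(),
                        ambiguous = integer(), distance = numeric())
    if (length(elig) == 0L) return(empty)
    elSub <- elements[mcols(elements)$element_id %in% elig]
    # expand one base beyond the cutoff: a TSS at gap == cutoff starts one
    # base past the expanded edge under the closed-interval convention
    hits <- findOverlaps(elSub + (cutoff + 1), tss, ignore.strand = TRUE)
    if (length(hits) == 0L) return(empty)
    cand <- data.table(element_id = mcols(elSub)$element_id[queryHits(hits)],
                       gene_id = mcols(tss)$gene_id[subjectHits(hits)],
                       pos = start(tss)[subjectHits(hits)],
                       start = start(elSub)[queryHits(hits)],
                       end = end(elSub)[queryHits(hits)])
    cand[, gap := pointIntervalGap(pos, start, end)]
    cand <- cand[, list(distance = min(gap)), by = c("element_id", "gene_id")]
    cand <- cand[cand$distance <= cutoff, ]
    posKeys <- pairKey(positives$element_id, positives$gene_id)
    cand <- cand[!pairKey(cand$element_id, cand$gene_id) %in% posKeys, ]
    if (!is.null(excludeAmbiguousPairs) && nrow(excludeAmbiguousPairs) > 0) {
        ambKeys <- pairKey(excludeAmbiguousPairs$element_id,
                           excludeAmbiguousPairs$gene_id)
        cand <- cand[!pairKey(cand$element_id, cand$gene_id) %in% ambKeys, ]
    }
    out <- as.data.frame(cand)
    out$ambiguous <- integer(nrow(out))
    out <- orderPairs(out[, c("element_id", "gene_id", "ambiguous", "distance")])
    rownames(out) <- NULL
    out
}

# Assemble positives + negatives into the canonical pair frame with element
# coordinates (0-based half-open) attached.
.assemblePairs <- function(positives, negatives, elements) {
    both <- rbind(
        if (nrow(positives)) cbind(positives[c("element_id", "gene_id",
                                               "ambiguous", "distance")],
                                   label = 1L),
        if (nrow(negatives)) cbind(negatives[c("element_id", "gene_id",
                                               "ambiguous", "distance")],
                                   label = 0L))
    if (is.null(both) || nrow(both) == 0L) return(emptyPairFrame())
    et <- as.data.frame(elementTable(elements))
    et$start <- et$start - 1L  # back to 0-based half-open for the interface
    m <- match(both$element_id, et$element_id)
    out <- data.frame(element_id = both$element_id, chrom = et$chrom[m],
                      start = et$start[m], end = et$end[m],
                      gene_id = both$gene_id, label = both$label,
                      ambiguous = as.integer(both$ambiguous),
                      distance = both$distance,
                      cv_group = NA_character_)
    out <- out[order(out$element_id, out$gene_id, method = "radix"), ]
    rownames(out) <- NULL
    out
}

#' Curate a benchmark dataset from positive pairs
#'
#' Computes the negative-candidate distance cutoff from the positives,
#' generates negatives under it and assembles the natural-ratio dataset.
#'
#' @param positives output of [pairsFromLinks()] or
#'   [pairsFromAssociations()].
#' @param elements distal elements active in the dataset's biosample.
#' @param tss a [TssIndex-class].
#' @param policy a [CurationPolicy-class].
#' @param datasetId,assay,biosample dataset annotation strings.
#' @return a [BenchmarkDataset-class] with `variant = "all_natural"`.
#' @export
curateDataset <- function(positives, elements, tss,
                          policy = curationPolicy(),
                          datasetId = "dataset", assay = "chiapet",
                          biosample = "synthetic") {
    cutoff <- negativeCutoff(positives, policy@negativePercentile)
    negatives <- generateNegatives(positives, elements, tss, cutoff)
    new("BenchmarkDataset", datasetId = datasetId, assay = assay,
        biosample = biosample, variant = "all_natural",
        pairs = .assemblePairs(positives, negatives, elements),
        cutoff = as.numeric(cutoff), policy = policy)
}

#' @describeIn BenchmarkDataset-class pair table accessor.
#' @param x,object a `BenchmarkDataset`.
#' @export
benchmarkPairs <- function(x) x@pairs

#' @rdname benchmarkPairs
#' @export
positives <- function(x) x@pairs[x@pairs$label == 1L, , drop = FALSE]

#' @rdname benchmarkPairs
#' @export
negatives <- function(x) x@pairs[x@pairs$label == 0L, , drop = FALSE]

#' @rdname benchmarkPairs
#' @export
datasetId <- function(x) x@datasetId

#' @rdname benchmarkPairs
#' @export
datasetVariant <- function(x) x@variant

#' @rdname benchmarkPairs
#' @export
cutoffDistance <- function(x) x@cutoff

setMethod("show", "BenchmarkDataset", function(object) {
    p <- object@pairs
    cat("BenchmarkDataset '", object@datasetId, "' (", object@assay, ", ",
        object@biosample, ", ", object@variant, ")\n", sep = "")
    cat("  ", sum(p$label == 1L), " positives (", sum(p$ambiguous == 1L),
        " ambiguous), ", sum(p$label == 0L), " negatives; cutoff ",
        object@cutoff, " bp\n", sep = "")
})

.replacePairs <- function(dataset, pairs, variant = dataset@variant,
                          cutoff = dataset@cutoff) {
    pairs <- pairs[order(pairs$element_id, pairs$gene_id, method = "radix"), ,
                   drop = FALSE]
    rownames(pairs) <- NULL
    initialize(dataset, pairs = pairs, variant = variant,
               cutoff = as.numeric(cutoff))
}

#' Remove ambiguous pairs and regenerate negatives
#'
#' Drops every pair flagged ambiguous, recomputes the distance cutoff from
#' the remaining positives and regenerates negatives excluding, per
#' element, the genes that element was ambiguously linked to. Applied to an
#' eQTL or CRISPR dataset it is a no-op with a warning, since those assays
#' list the linked gene explicitly.
#'
#' @param dataset a [BenchmarkDataset-class] from a 3D chromatin assay.
#' @param elements,tss the inputs the dataset was curated from.
#' @return a [BenchmarkDataset-class] with variant `"noambig_natural"`.
#' @export
stripAmbiguous <- function(dataset, elements, tss) {
    if (dataset@assay %in% c("eqtl", "crisprqtl")) {
        warning("ambiguity filtering is not required for assays that ",
                "explicitly list the linked gene; dataset unchanged")
        return(dataset)
    }
    pos <- positives(dataset)
    keep <- pos[pos$ambiguous == 0L, , drop = FALSE]
    amb <- pos[pos$ambiguous == 1L, c("element_id", "gene_id"), drop = FALSE]
    if (nrow(keep) == 0L)
        return(.replacePairs(dataset, emptyPairFrame(),
                             variant = "noambig_natural", cutoff = NA_real_))
    cutoff <- negativeCutoff(keep, dataset@policy@negativePercentile)
    negs <- generateNegatives(keep, elements, tss, cutoff,
                              excludeAmbiguousPairs = amb)
    .replacePairs(dataset, .assemblePairs(keep, negs, elements),
                  variant = "noambig_natural", cutoff = cutoff)
}

#' Fixed-ratio dataset variant
#'
#' Per element: negatives that are positive for the same element in any
#' other benchmark dataset are removed; elements left with fewer eligible
#' negatives than `fixedRatio` per positive pair (at least `minNegatives`)
#' are dropped entirely, positives included, so every retained element
#' carries exactly `fixedRatio` negatives per positive; the excess
#' negatives are discarded by seeded sampling without replacement, so
#' identical seeds give identical datasets.
#'
#' @param dataset a natural-ratio [BenchmarkDataset-class].
#' @param crossPositives optional data.frame (`element_id`, `gene_id`) of
#'   positive pairs from other benchmark datasets.
#' @param policy defaults to the dataset's policy.
#' @return a [BenchmarkDataset-class] with a `*_fixed` variant tag.
#' @export
fixedRatioVariant <- function(dataset, crossPositives = NULL,
                              policy = dataset@policy) {
    p <- benchmarkPairs(dataset)
    pos <- p[p$label == 1L, , drop = FALSE]
    neg <- p[p$label == 0L, , drop = FALSE]
    crossKeys <- if (!is.null(crossPositives) && nrow(crossPositives) > 0)
        pairKey(crossPositives$element_id, crossPositives$gene_id)
    else character()
    kept <- withSeed(policy@seed, {
        out <- vector("list", length(unique(pos$element_id)))
        for (i in seq_along(els <- sort(unique(pos$element_id)))) {
            e <- els[[i]]
            posE <- pos[pos$element_id == e, , drop = FALSE]
            negE <- neg[neg$element_id == e, , drop = FALSE]
            negE <- negE[!pairKey(negE$element_id, negE$gene_id) %in%
                         crossKeys, , drop = FALSE]
            need <- max(policy@minNegatives,
                        policy@fixedRatio * nrow(posE))
            if (nrow(negE) < need) next
            if (nrow(negE) > need)
                negE <- negE[sort(sample.int(nrow(negE), need)), ,
                             drop = FALSE]
            out[[i]] <- rbind(posE, negE)
        }
        out
    })
    kept <- kept[!vapply(kept, is.null, logical(1))]
    pairs <- if (length(kept)) do.call(rbind, kept) else emptyPairFrame()
    variant <- if (grepl("natural$", dataset@variant))
        sub("natural$", "fixed", dataset@variant) else
        paste0(dataset@variant, "_fixed")
    .replacePairs(dataset, pairs, variant = variant)
}

#' Matched subsets for supervised-model dissection
#'
#' Four restricted resamplings of a dataset, all at a 1:`matchedRatio`
#' positive:negative ratio and all seeded by the policy:
#' \describe{
#'   \item{ratio}{per element, subsample to 1 positive and `matchedRatio`
#'     negatives.}
#'   \item{promoter}{restrict to genes appearing in at least one positive
#'     and one negative pair, then enforce the ratio as above.}
#'   \item{distance}{bin pairs by `nDistanceBins` equal-occupancy quantile
#'     bins of the positive distances and sample the same number of
#'     positives (with `matchedRatio` negatives each) from every bin.}
#'   \item{promoter_distance}{the promoter restriction followed by the
#'     distance-matched sampling.}
#' }
#' Elements or bins without eligible negatives are dropped and counted in
#' attribute `"nDropped"` of the returned pair table.
#'
#' @param dataset a [BenchmarkDataset-class] with both labels present.
#' @param mode one of `"ratio"`, `"promoter"`, `"distance"`,
#'   `"promoter_distance"`.
#' @param policy defaults to the dataset's policy.
#' @return a [BenchmarkDataset-class] with variant `matched_<mode>`.
#' @export
matchedSubsets <- function(dataset,
                           mode = c("ratio", "promoter", "distance",
                                    "promoter_distance"),
                           policy = dataset@policy) {
    mode <- match.arg(mode)
    p <- benchmarkPairs(dataset)
    if (!any(p$label == 1L) || !any(p$label == 0L))
        stop("matched subsets need both positive and negative pairs")
    nDropped <- 0L
    if (mode %in% c("promoter", "promoter_distance")) {
        posGenes <- unique(p$gene_id[p$label == 1L])
        negGenes <- unique(p$gene_id[p$label == 0L])
        keepGenes <- intersect(posGenes, negGenes)
        p <- p[p$gene_id %in% keepGenes, , drop = FALSE]
    }
    r <- policy@matchedRatio
    pairs <- if (mode %in% c("ratio", "promoter")) {
        withSeed(policy@seed, {
            out <- list()
            for (e in sort(unique(p$element_id[p$label == 1L]))) {
                posE <- p[p$element_id == e & p$label == 1L, , drop = FALSE]
                negE <- p[p$element_id == e & p$label == 0L, , drop = FALSE]
                if (nrow(negE) < r) { nDropped <- nDropped + 1L; next }
                posE <- posE[sample.int(nrow(posE), 1L), , drop = FALSE]
                negE <- negE[sort(sample.int(nrow(negE), r)), , drop = FALSE]
                out[[e]] <- rbind(posE, negE)
            }
            if (length(out)) do.call(rbind, out) else emptyPairFrame()
        })
    } else {
        pos <- p[p$label == 1L, , drop = FALSE]
        neg <- p[p$label == 0L, , drop = FALSE]
        probs <- seq(0, 1, length.out = policy@nDistanceBins + 1L)
        breaks <- unique(quantile(pos$distance, probs = probs, type = 1,
                                  names = FALSE))
        if (length(breaks) < 2L) breaks <- c(breaks, breaks + 1)
        posBin <- cut(pos$distance, breaks, include.lowest = TRUE)
        negBin <- cut(neg$distance, breaks, include.lowest = TRUE)
        nPos <- table(posBin)
        nNeg <- table(negBin)
        eligible <- names(nPos)[nPos >= 1L & nNeg[names(nPos)] >= r]
        nDropped <- nlevels(posBin) - length(eligible)
        if (length(eligible) == 0L) {
            warning("no distance bin has eligible negatives; ",
                    "the matched subset is empty")
            emptyPairFrame()
        } else {
            nPer <- min(pmin(nPos[eligible],
                             as.integer(nNeg[eligible]) %/% r))
            withSeed(policy@seed, {
                out <- list()
                for (b in eligible) {
                    posB <- pos[which(posBin == b), , drop = FALSE]
                    negB <- neg[which(negBin == b), , drop = FALSE]
                    out[[b]] <- rbind(
                        posB[sort(sample.int(nrow(posB), nPer)), ,
                             drop = FALSE],
                        negB[sort(sample.int(nrow(negB), r * nPer)), ,
                             drop = FALSE])
                }
                do.call(rbind, out)
            })
        }
    }
    ds <- .replacePairs(dataset, pairs,
                        variant = paste0("matched_", mode))
    attr(ds@pairs, "nDropped") <- nDropped
    ds
}

#' Write / read a benchmark dataset as TSV
#'
#' One row per pair: dataset_id, element_id, chrom, start, end (0-based
#' half-open element coordinates), gene_id, label, ambiguous, distance,
#' cv_group. Rows are written in canonical (element, gene) order, so equal
#' datasets produce byte-identical files.
#'
#' @param dataset a [BenchmarkDataset-class].
#' @param file path.
#' @return `file` invisibly for the writer; a [BenchmarkDataset-class] for
#'   the reader (with a default policy and `NA` cutoff, which are not part
#'   of the TSV interface).
#' @export
writeBenchmark <- function(dataset, file) {
    p <- benchmarkPairs(dataset)
    out <- cbind(dataset_id = dataset@datasetId, p)
    fwrite(out, file, sep = "\t", eol = "\n", na = "NA", quote = FALSE)
    invisible(file)
}

#' @rdname writeBenchmark
#' @export
readBenchmark <- function(file) {
    dt <- as.data.frame(fread(file, header = TRUE, sep = "\t",
                              colClasses = list(character = "cv_group")))
    stopifnot(all(c("dataset_id", .PAIR_COLS) %in% names(dt)))
    id <- unique(dt$dataset_id)
    if (length(id) != 1L)
        stop("benchmark TSV must contain a single dataset_id")
    new("BenchmarkDataset", datasetId = id, assay = "unknown",
        biosample = "unknown", variant = "unknown",
        pairs = dt[, .PAIR_COLS], cutoff = NA_real_,
        policy = curationPolicy())
}
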