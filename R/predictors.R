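# Target-gene prediction methods: closest gene, inverse distance, the two
# signal-correlation methods, rank averaging, and the gradient-boosted
# supervised harness with chromosome-held-out cross-validation.

.scoreFrame <- function(element_id, gene_id, score, method) {
    data.frame(element_id = element_id, gene_id = gene_id,
               score = as.numeric(score), method = method)
}

#' Closest-gene assignment
#'
#' Assigns every element to the gene owning its nearest TSS, with
#' equidistant ties broken by lexicographically smaller gene identifier.
#' Elements on chromosomes without any TSS are skipped and counted in
#' attribute `"nSkipped"`. Build the index with `proteinCodingOnly = TRUE`
#' to restrict predictions to coding genes.
#'
#' @param elements [GenomicRanges::GRanges] with `element_id`.
#' @param tss a [TssIndex-class].
#' @return data.frame with one row per assigned element: `element_id`,
#'   `gene_id`, `distance`.
#' @export
closestGenePrediction <- function(elements, tss) {
    nd <- nearestTssDistance(elements, tss)
    skipped <- is.na(nd$distance)
    out <- data.frame(element_id = mcols(elements)$element_id[!skipped],
                      gene_id = nd$gene_id[!skipped],
                      distance = nd$distance[!skipped])
    out <- out[order(out$element_id, method = "radix"), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "nSkipped") <- sum(skipped)
    out
}

#' Inverse-distance scores
#'
#' Ranks candidate pairs by the reciprocal of the element-to-nearest-TSS
#' distance, so closer genes score higher. A zero distance (possible only
#' for degenerate, non-distal inputs) is capped at score 1.
#'
#' @param x a [BenchmarkDataset-class] or a data.frame with `element_id`,
#'   `gene_id` and `distance` columns.
#' @return score frame (`element_id`, `gene_id`, `score`, `method`).
#' @export
distanceScore <- function(x) {
    p <- if (is(x, "BenchmarkDataset")) benchmarkPairs(x) else x
    .scoreFrame(p$element_id, p$gene_id,
                ifelse(p$distance <= 0, 1, 1 / p$distance), "distance")
}

#' Construct a signal matrix
#'
#' @param values non-negative numeric matrix, rows = elements/sites/genes,
#'   columns = biosamples (both named).
#' @param groups optional cell-type group label per column; group-averaged
#'   correlation collapses each group to its mean column.
#' @return a [SignalMatrix-class].
#' @export
signalMatrix <- function(values, groups = NULL) {
    new("SignalMatrix", values = values,
        groups = if (is.null(groups)) character() else as.character(groups))
}

#' @describeIn SignalMatrix-class value matrix and column grouping.
#' @param x,object a `SignalMatrix`.
#' @export
signalValues <- function(x) x@values

#' @rdname signalValues
#' @export
signalGroups <- function(x) x@groups

#' @rdname signalValues
#' @export
setMethod("dim", "SignalMatrix", function(x) dim(x@values))

setMethod("show", "SignalMatrix", function(object) {
    cat("SignalMatrix:", nrow(object@values), "row(s) x",
        ncol(object@values), "biosample(s)")
    if (length(object@groups))
        cat(" in", length(unique(object@groups)), "group(s)")
    cat("\n")
})

#' Collapse a signal matrix to per-group column means
#'
#' @param x a [SignalMatrix-class]. Without a grouping the values are
#'   returned unchanged (every column its own group).
#' @return numeric matrix, one column per group.
#' @export
groupAverage <- function(x) {
    v <- signalValues(x)
    g <- signalGroups(x)
    if (length(g) == 0L) return(v)
    lev <- unique(g)
    out <- vapply(lev, function(gr)
        rowMeans(v[, g == gr, drop = FALSE]), numeric(nrow(v)))
    if (nrow(v) == 1L) out <- matrix(out, nrow = 1L, dimnames = list(rownames(v), lev))
    out
}

#' Map each TSS to its closest element
#'
#' The accessibility-correlation method compares an element's signal with
#' the signal of TSS-proximal elements: for every TSS in the index, the
#' closest element (ties broken by lexicographic element identifier) is
#' recorded.
#'
#' @param tss a [TssIndex-class].
#' @param elements [GenomicRanges::GRanges] with `element_id` (typically
#'   the full element registry, not just distal elements).
#' @return data.frame with columns `gene_id`, `pos` (0-based TSS position)
#'   and `element_id`; TSSs on element-free chromosomes are omitted.
#' @export
buildTssElementMap <- function(tss, elements) {
    tt <- tssTable(tss)
    et <- elementTable(elements)
    hits <- merge(data.table(tt, .row = seq_len(nrow(tt))), et,
                  by = "chrom", allow.cartesian = TRUE)
    out <- data.frame(gene_id = character(), pos = integer(),
                      element_id = character())
    if (nrow(hits)) {
        hits[, gap := pointIntervalGap(pos, start, end)]
        setorder(hits, .row, gap, element_id)
        best <- hits[!duplicated(hits$.row), ]
        out <- unique(data.frame(gene_id = best$gene_id, pos = best$pos - 1L,
                                 element_id = best$element_id))
    }
    rownames(out) <- NULL
    out
}

.pcc <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
}

#' Accessibility-accessibility correlation scores
#'
#' For each pair, the element's signal row and each of the gene's
#' TSS-proximal elements' rows are collapsed to per-group means and the
#' Pearson correlation computed; the pair's score is the maximum
#' correlation over the gene's TSS elements. Pairs whose element or gene
#' has no usable signal, or with fewer than `minGroups` signal groups, get
#' the sentinel score -100, which ranks below every finite correlation.
#'
#' @param pairs data.frame with `element_id` and `gene_id` (e.g.
#'   [benchmarkPairs()]).
#' @param elementSignals a [SignalMatrix-class] over element identifiers.
#' @param tssElementMap output of [buildTssElementMap()].
#' @param minGroups minimum number of signal groups required; default 3.
#' @return score frame with `method = "dnase-dnase"`.
#' @export
dnaseDnaseScore <- function(pairs, elementSignals, tssElementMap,
                            minGroups = 3L) {
    ga <- groupAverage(elementSignals)
    geneEls <- split(tssElementMap$element_id, tssElementMap$gene_id)
    score <- rep(.SENTINEL, nrow(pairs))
    if (ncol(ga) >= minGroups) {
        for (i in seq_len(nrow(pairs))) {
            e <- pairs$element_id[i]
            if (!e %in% rownames(ga)) next
            tssEl <- unique(geneEls[[pairs$gene_id[i]]])
            tssEl <- tssEl[tssEl %in% rownames(ga)]
            if (length(tssEl) == 0L) next
            cc <- vapply(tssEl, function(t) .pcc(ga[e, ], ga[t, ]),
                         numeric(1))
            cc <- cc[is.finite(cc)]
            if (length(cc)) score[i] <- max(cc)
        }
    }
    .scoreFrame(pairs$element_id, pairs$gene_id, score, "dnase-dnase")
}

#' Accessibility-expression correlation scores
#'
#' Each element is matched to an accessibility site; when several sites
#' overlap the element, the site with the strongest signal in the focal
#' biosample is chosen. The score is the Pearson correlation between the
#' chosen site's signal row and the gene's expression row across the
#' shared biosample panel. Pairs without a matched site, without the gene
#' in the expression matrix, or with a zero-variance row get the sentinel
#' score -100.
#'
#' @param pairs data.frame with `element_id` and `gene_id`.
#' @param siteSignals [SignalMatrix-class] over site identifiers.
#' @param expression [SignalMatrix-class] over gene identifiers, sharing
#'   `siteSignals`' column panel.
#' @param elementSites data.frame (`element_id`, `site_id`) of candidate
#'   sites per element; one element may have several.
#' @param focalColumn the biosample column used to pick among candidate
#'   sites; defaults to the first column.
#' @return score frame with `method = "dnase-expression"`.
#' @export
dnaseExpressionScore <- function(pairs, siteSignals, expression,
                                 elementSites,
                                 focalColumn = colnames(signalValues(siteSignals))[1L]) {
    sv <- signalValues(siteSignals)
    ev <- signalValues(expression)
    if (!identical(colnames(sv), colnames(ev)))
        stop("site and expression matrices must share one biosample panel")
    # strongest site in the focal biosample, ties by lexicographic site id
    es <- as.data.table(elementSites)
    es <- es[es$site_id %in% rownames(sv), ]
    chosen <- character(0)
    if (nrow(es)) {
        es[, focal := sv[site_id, focalColumn]]
        setorder(es, element_id, -focal, site_id)
        es <- es[!duplicated(es$element_id), ]
        chosen <- setNames(es$site_id, es$element_id)
    }
    score <- rep(.SENTINEL, nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
        site <- chosen[pairs$element_id[i]]
        g <- pairs$gene_id[i]
        if (is.na(site) || !g %in% rownames(ev)) next
        cc <- .pcc(sv[site, ], ev[g, ])
        if (is.finite(cc)) score[i] <- cc
    }
    .scoreFrame(pairs$element_id, pairs$gene_id, score, "dnase-expression")
}

#' Average-rank combination of two scoring methods
#'
#' Converts each method's scores to ranks (rank 1 = highest score, ties
#' get their mean rank) over the identical pair universe and combines them
#' as minus the mean rank, so that higher combined scores remain better.
#' Averaging a method with itself preserves its ranking exactly.
#'
#' @param a,b score frames over the same pairs (sentinel scores allowed);
#'   differing pair sets are an error listing the symmetric difference.
#' @return score frame with `method = "average-rank"`.
#' @export
averageRankScore <- function(a, b) {
    ka <- pairKey(a$element_id, a$gene_id)
    kb <- pairKey(b$element_id, b$gene_id)
    extra <- c(setdiff(ka, kb), setdiff(kb, ka))
    if (length(extra))
        stop("score frames cover different pairs: ",
             paste(sort(extra), collapse = ", "))
    sb <- b$score[match(ka, kb)]
    ra <- rank(-a$score, ties.method = "average")
    rb <- rank(-sb, ties.method = "average")
    .scoreFrame(a$element_id, a$gene_id, -(ra + rb) / 2, "average-rank")
}

.regionMean <- function(track, trackName, chrom, start, end) {
    if (is.na(start) || is.na(end) || end < start) return(0)
    v <- track[[chrom]]
    if (is.null(v))
        stop("track '", trackName, "' has no data for chromosome ", chrom)
    v <- as.numeric(v)
    a <- max(1L, as.integer(start))
    b <- min(length(v), as.integer(end))
    if (b < a) return(0)
    sum(v[a:b]) / (b - a + 1)
}

.CORE4 <- c("DNase", "H3K4me3", "H3K27ac", "CTCF")

#' Extract epigenomic features for supervised prediction
#'
#' For every candidate pair, the mean signal of each track is computed over
#' three regions — the element (enhancer), the promoter (the gene's
#' nearest TSS extended `promoterWindow` bp each side) and the intervening
#' window between element and promoter (features 0 when they are adjacent
#' or overlapping) — and the element-gene distance is appended. The
#' `core4` schema uses the DNase, H3K4me3, H3K27ac and CTCF tracks
#' (13 features); `core3` drops CTCF (10 features); `full` uses every
#' provided track (3 per track + distance).
#'
#' @param dataset a [BenchmarkDataset-class].
#' @param tracks named list of signal tracks; each track is a named list
#'   (or `RleList`) of per-chromosome numeric coverage vectors, 1-based.
#' @param tss a [TssIndex-class] used to locate each gene's nearest TSS.
#' @param schema `"core4"`, `"core3"` or `"full"`.
#' @param promoterWindow bp each side of the TSS; default 2000.
#' @return data.frame of named numeric features, one row per pair in the
#'   dataset's canonical order, with row names `element|gene`.
#' @export
extractFeatures <- function(dataset, tracks, tss,
                            schema = c("core4", "core3", "full"),
                            promoterWindow = 2000) {
    schema <- match.arg(schema)
    wanted <- switch(schema, core4 = .CORE4, core3 = setdiff(.CORE4, "CTCF"),
                     full = names(tracks))
    missing <- setdiff(wanted, names(tracks))
    if (length(missing))
        stop("schema '", schema, "' needs track(s): ",
             paste(missing, collapse = ", "))
    p <- benchmarkPairs(dataset)
    elGR <- GRanges(p$chrom, IRanges(p$start + 1L, p$end))
    nd <- nearestTssDistance(elGR, tss, genes = p$gene_id)
    if (anyNA(nd$distance))
        stop("some pairs reference genes without TSSs on their chromosome")
    tssPos1 <- integer(nrow(p))  # 1-based nearest TSS position per pair
    tt <- tssTable(tss)
    for (i in seq_len(nrow(p))) {
        cand <- tt[tt$gene_id == p$gene_id[i] & tt$chrom == p$chrom[i], ]
        gaps <- pointIntervalGap(cand$pos, p$start[i] + 1L, p$end[i])
        tssPos1[i] <- cand$pos[which.min(gaps)]
    }
    promStart <- pmax(1L, tssPos1 - as.integer(promoterWindow))
    promEnd <- tssPos1 + as.integer(promoterWindow)
    elStart <- p$start + 1L
    elEnd <- p$end
    winStart <- ifelse(elEnd < promStart, elEnd + 1L,
                ifelse(promEnd < elStart, promEnd + 1L, NA_integer_))
    winEnd <- ifelse(elEnd < promStart, promStart - 1L,
              ifelse(promEnd < elStart, elStart - 1L, NA_integer_))
    feats <- list()
    for (tr in wanted) {
        for (reg in c("enhancer", "promoter", "window")) {
            s <- switch(reg, enhancer = elStart, promoter = promStart,
                        window = winStart)
            e <- switch(reg, enhancer = elEnd, promoter = promEnd,
                        window = winEnd)
            feats[[paste(tr, reg, sep = "_")]] <- vapply(seq_len(nrow(p)),
                function(i) .regionMean(tracks[[tr]], tr, p$chrom[i],
                                        s[i], e[i]),
                numeric(1))
        }
    }
    feats$distance <- p$distance
    out <- as.data.frame(feats)
    rownames(out) <- pairKey(p$element_id, p$gene_id)
    out
}

.fitBoost <- function(x, y, nrounds, eta, maxDepth, seed, nthread) {
    d <- xgboost::xgb.DMatrix(as.matrix(x), label = y)
    withSeed(seed, xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = eta,
                      max_depth = maxDepth, nthread = nthread),
        data = d, nrounds = nrounds, verbose = 0))
}

#' Chromosome-held-out supervised cross-validation
#'
#' For each CV group, a gradient-boosted classifier is trained on all
#' other groups and scores the held-out group; the out-of-fold scores are
#' concatenated so every pair is scored exactly once, never by a model
#' that saw its own chromosome. A fold whose training labels are
#' single-class is an error.
#'
#' @param features numeric feature data.frame/matrix, one row per pair.
#' @param labels 0/1 vector aligned with `features`.
#' @param groups CV group label per pair (e.g. the `cv_group` column after
#'   [addChromCV()]).
#' @param nrounds,eta,maxDepth gradient-boosting hyperparameters; defaults
#'   4000 rounds, learning rate 0.1, depth 5.
#' @param seed RNG seed for the learner.
#' @param nthread learner threads; default 1.
#' @return numeric out-of-fold scores aligned with the input rows, with
#'   the fold of each pair in attribute `"fold"` and the hyperparameters
#'   in attribute `"params"`.
#' @export
supervisedCV <- function(features, labels, groups, nrounds = 4000L,
                         eta = 0.1, maxDepth = 5L, seed = 1L,
                         nthread = 1L) {
    stopifnot(nrow(features) == length(labels),
              length(labels) == length(groups))
    scores <- rep(NA_real_, length(labels))
    for (g in sort(unique(groups))) {
        fold <- groups == g
        if (length(unique(labels[!fold])) < 2L)
            stop("training labels for fold '", g, "' are single-class")
        bst <- .fitBoost(features[!fold, , drop = FALSE], labels[!fold],
                         nrounds, eta, maxDepth, seed, nthread)
        scores[fold] <- predict(bst,
            xgboost::xgb.DMatrix(as.matrix(features[fold, , drop = FALSE])))
    }
    attr(scores, "fold") <- groups
    attr(scores, "params") <- list(nrounds = nrounds, eta = eta,
                                   maxDepth = maxDepth, seed = seed)
    scores
}

#' Apply a supervised model across cell types
#'
#' Trains one model per test fold on the training biosample's pairs
#' outside that fold and scores the test biosample's pairs inside it. Test
#' CV groups must be transferred from the training assignment (see
#' [transferCV()]) so that no chromosome is shared between a model's
#' training data and the test pairs it scores. With identical train and
#' test inputs this reduces to [supervisedCV()].
#'
#' @param trainFeatures,trainLabels,trainGroups training biosample data.
#' @param testFeatures,testGroups test biosample data; feature schemas
#'   must match exactly (differing columns are an error listing them).
#' @inheritParams supervisedCV
#' @return numeric scores for the test pairs.
#' @export
crossCellApply <- function(trainFeatures, trainLabels, trainGroups,
                           testFeatures, testGroups, nrounds = 4000L,
                           eta = 0.1, maxDepth = 5L, seed = 1L,
                           nthread = 1L) {
    diffCols <- c(setdiff(colnames(trainFeatures), colnames(testFeatures)),
                  setdiff(colnames(testFeatures), colnames(trainFeatures)))
    if (length(diffCols))
        stop("feature schemas differ in: ",
             paste(unique(diffCols), collapse = ", "))
    testFeatures <- testFeatures[, colnames(trainFeatures), drop = FALSE]
    scores <- rep(NA_real_, nrow(testFeatures))
    for (g in sort(unique(testGroups))) {
        fold <- testGroups == g
        trainSel <- trainGroups != g
        if (length(unique(trainLabels[trainSel])) < 2L)
            stop("training labels for fold '", g, "' are single-class")
        bst <- .fitBoost(trainFeatures[trainSel, , drop = FALSE],
                         trainLabels[trainSel], nrounds, eta, maxDepth,
                         seed, nthread)
        scores[fold] <- predict(bst,
            xgboost::xgb.DMatrix(as.matrix(testFeatures[fold, , drop = FALSE])))
    }
    scores
}
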