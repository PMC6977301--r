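# Independent brute-force oracles, written in plain 0-based arithmetic with
# explicit loops. They deliberately share no code with the package internals:
# the package works on 1-based GRanges via overlap machinery, the oracles on
# raw 0-based tables.

suppressMessages({
    library(GenomicRanges)
    library(IRanges)
})

# gap between a 0-based point and a 0-based half-open interval [s, e)
oracleGap <- function(p, s, e) {
    if (p >= e) p - e else if (p < s) s - p - 1 else 0
}

# nearest TSS of an interval over a 0-based TSS table (chrom, pos, gene_id);
# ties broken by lexicographic gene_id
oracleNearest <- function(chrom, s0, e0, tssDf, genes = NULL) {
    cand <- tssDf[tssDf$chrom == chrom, , drop = FALSE]
    if (!is.null(genes)) cand <- cand[cand$gene_id %in% genes, , drop = FALSE]
    if (nrow(cand) == 0L) return(list(gene = NA_character_, d = NA_real_))
    d <- vapply(seq_len(nrow(cand)),
                function(i) oracleGap(cand$pos[i], s0, e0), numeric(1))
    best <- min(d)
    list(gene = sort(cand$gene_id[d == best])[1L], d = best)
}

# is the 0-based point p within `w` bp of any base of [s, e)?
oracleInWindow <- function(p, s, e, w) {
    nearest <- min(max(p, s), e - 1)
    abs(p - nearest) <= w
}

# positive pairs from a raw 0-based link table (chromA,startA,endA,chromB,
# startB,endB), elements (chrom,start,end,element_id; 0-based half-open) and
# a TSS table; both orientations, ambiguity by multi-gene TSS-side anchors,
# pair-level flag = all supporting links ambiguous
oraclePairsFromLinks <- function(linkDf, elDf, tssDf, w = 2000) {
    acc <- list()
    for (i in seq_len(nrow(linkDf))) {
        for (ori in 1:2) {
            if (ori == 1) {
                ac <- linkDf$chromA[i]; as0 <- linkDf$startA[i]; ae0 <- linkDf$endA[i]
                bc <- linkDf$chromB[i]; bs0 <- linkDf$startB[i]; be0 <- linkDf$endB[i]
            } else {
                ac <- linkDf$chromB[i]; as0 <- linkDf$startB[i]; ae0 <- linkDf$endB[i]
                bc <- linkDf$chromA[i]; bs0 <- linkDf$startA[i]; be0 <- linkDf$endA[i]
            }
            els <- character(0)
            for (j in seq_len(nrow(elDf)))
                if (elDf$chrom[j] == ac && elDf$start[j] < ae0 &&
                    elDf$end[j] > as0)
                    els <- c(els, elDf$element_id[j])
            genes <- character(0)
            for (j in seq_len(nrow(tssDf)))
                if (tssDf$chrom[j] == bc &&
                    oracleInWindow(tssDf$pos[j], bs0, be0, w))
                    genes <- c(genes, tssDf$gene_id[j])
            genes <- unique(genes)
            if (length(els) == 0L || length(genes) == 0L) next
            amb <- length(genes) >= 2L
            for (e in els) for (g in genes)
                acc[[length(acc) + 1L]] <- data.frame(
                    element_id = e, gene_id = g, ambiguous = amb)
        }
    }
    if (length(acc) == 0L)
        return(data.frame(element_id = character(), gene_id = character(),
                          ambiguous = integer()))
    all <- do.call(rbind, acc)
    keys <- unique(paste(all$element_id, all$gene_id))
    out <- do.call(rbind, lapply(keys, function(k) {
        rows <- all[paste(all$element_id, all$gene_id) == k, ]
        data.frame(element_id = rows$element_id[1L],
                   gene_id = rows$gene_id[1L],
                   ambiguous = as.integer(all(rows$ambiguous)))
    }))
    out <- out[order(out$element_id, out$gene_id), ]
    rownames(out) <- NULL
    out
}

# positives from variant positions (0-based) or regions against elements
oraclePairsFromAssociations <- function(assocDf, elDf, tssDf) {
    acc <- list()
    knownGenes <- unique(tssDf$gene_id)
    for (i in seq_len(nrow(assocDf))) {
        if (!assocDf$gene_id[i] %in% knownGenes) next
        for (j in seq_len(nrow(elDf))) {
            if (elDf$chrom[j] != assocDf$chrom[i]) next
            hit <- if (!is.null(assocDf$pos))
                assocDf$pos[i] >= elDf$start[j] && assocDf$pos[i] < elDf$end[j]
            else
                assocDf$start[i] < elDf$end[j] && assocDf$end[i] > elDf$start[j]
            if (hit)
                acc[[length(acc) + 1L]] <- data.frame(
                    element_id = elDf$element_id[j],
                    gene_id = assocDf$gene_id[i])
        }
    }
    if (length(acc) == 0L)
        return(data.frame(element_id = character(), gene_id = character()))
    out <- unique(do.call(rbind, acc))
    out <- out[order(out$element_id, out$gene_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}

# nearest-rank percentile by direct order statistics
oraclePercentile <- function(x, p) {
    sort(x)[max(1, ceiling(p / 100 * length(x)))]
}

# negatives by exhaustive (element, gene) scan under the cutoff
oracleNegatives <- function(posDf, elDf, tssDf, cutoff, ambDf = NULL) {
    posKey <- paste(posDf$element_id, posDf$gene_id)
    ambKey <- if (!is.null(ambDf)) paste(ambDf$element_id, ambDf$gene_id)
              else character(0)
    eligEl <- unique(posDf$element_id[posDf$distance <= cutoff])
    genes <- unique(tssDf$gene_id)
    acc <- list()
    for (e in eligEl) {
        row <- elDf[elDf$element_id == e, ]
        for (g in genes) {
            nr <- oracleNearest(row$chrom, row$start, row$end, tssDf,
                                genes = g)
            if (is.na(nr$d) || nr$d > cutoff) next
            k <- paste(e, g)
            if (k %in% posKey || k %in% ambKey) next
            acc[[length(acc) + 1L]] <- data.frame(element_id = e,
                                                  gene_id = g,
                                                  distance = nr$d)
        }
    }
    if (length(acc) == 0L)
        return(data.frame(element_id = character(), gene_id = character(),
                          distance = numeric()))
    out <- do.call(rbind, acc)
    out <- out[order(out$element_id, out$gene_id), ]
    rownames(out) <- NULL
    out
}

# all-threshold precision-recall by re-scanning the data at every threshold
oraclePrCurve <- function(scores, labels) {
    P <- sum(labels == 1)
    thr <- sort(unique(scores), decreasing = TRUE)
    prec <- rec <- numeric(length(thr))
    for (i in seq_along(thr)) {
        pred <- scores >= thr[i]
        tp <- sum(pred & labels == 1)
        prec[i] <- tp / sum(pred)
        rec[i] <- tp / P
    }
    list(precision = prec, recall = rec,
         aupr = sum(diff(c(0, rec)) * prec))
}
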