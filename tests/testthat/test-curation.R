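# Pair derivation, negative generation and the dataset variants.

test_that("a multi-gene TSS-side anchor makes every pair ambiguous", {
    # two genes with promoter windows under one anchor, one lone gene
    tss <- toyTss("chr1", c(50000, 52000, 90000), c("GA", "GB", "GC"))
    els <- toyElements("chr1", c(10000, 20000), c(10300, 20300),
                       c("E1", "E2"))
    links <- toyLinks(data.frame(
        chromA = "chr1", startA = c(10000, 20000, 30000),
        endA = c(10300, 20300, 30300),
        chromB = "chr1", startB = c(50500, 89500, 70000),
        endB = c(51500, 90500, 70500)))
    expect_message(pos <- pairsFromLinks(links, els, toyTss("chr1",
        c(50000, 52000, 90000), c("GA", "GB", "GC"))), "1 link")
    expect_equal(attr(pos, "nUnlinked"), 1L)  # the anchor in the desert
    # anchor near GA covers GB's window too (52000 within 2 kb of 51500-1)
    ambPairs <- pos[pos$ambiguous == 1L, ]
    expect_setequal(pairKey(ambPairs$element_id, ambPairs$gene_id),
                    c("E1|GA", "E1|GB"))
    expect_identical(pos$gene_id[pos$ambiguous == 0L], "GC")
    expect_identical(pos$element_id[pos$ambiguous == 0L], "E2")
})

test_that("link-derived pairs equal exhaustive enumeration on random toys", {
    for (seed in c(101, 102)) {
        lay <- randomLayout(seed, nTss = 30, nEl = 12, span = 300000)
        obj <- layoutToObjects(lay)
        linkDf <- withr::with_seed(seed + 1, {
            sa <- sample.int(295000, 20)
            sb <- sample.int(295000, 20)
            data.frame(chromA = sample(c("chr1", "chr2"), 20, replace = TRUE),
                       startA = sa, endA = sa + sample(200:3000, 20, TRUE),
                       chromB = sample(c("chr1", "chr2"), 20, replace = TRUE),
                       startB = sb, endB = sb + sample(200:3000, 20, TRUE))
        })
        linkDf <- linkDf[linkDf$chromA == linkDf$chromB, ]
        got <- suppressMessages(
            pairsFromLinks(toyLinks(linkDf), obj$elements, obj$tss))
        want <- oraclePairsFromLinks(linkDf, lay$elDf, lay$tssDf)
        expect_equal(got[c("element_id", "gene_id", "ambiguous")], want,
                     ignore_attr = TRUE)
    }
})

test_that("association-derived pairs require containment", {
    tss <- toyTss("chr1", c(50000, 90000), c("GA", "GB"))
    els <- toyElements("chr1", c(10000, 20000), c(10300, 20300),
                       c("E1", "E2"))
    assoc <- data.frame(chrom = "chr1", pos = c(10100, 15000, 10299, 10300),
                        gene_id = c("GA", "GA", "GB", "GB"))
    pos <- pairsFromAssociations(assoc, els, tss)
    # inside [10000,10300): 10100 and 10299; 10300 is just outside
    expect_setequal(pairKeys(pos), c("E1|GA", "E1|GB"))
    expect_true(all(pos$ambiguous == 0L))
    # a gene missing from the annotation is skipped and counted
    assoc2 <- rbind(assoc, data.frame(chrom = "chr1", pos = 10100,
                                      gene_id = "GZ"))
    expect_message(p2 <- pairsFromAssociations(assoc2, els, tss),
                   "1 association")
    expect_equal(attr(p2, "nSkippedGenes"), 1L)
})

test_that("association pairs equal a brute-force containment scan", {
    lay <- randomLayout(111, nTss = 25, nEl = 15, span = 150000)
    obj <- layoutToObjects(lay)
    assoc <- withr::with_seed(112, data.frame(
        chrom = sample(c("chr1", "chr2"), 50, replace = TRUE),
        pos = sample.int(150000, 50),
        gene_id = sample(lay$tssDf$gene_id, 50, replace = TRUE)))
    got <- pairsFromAssociations(assoc, obj$elements, obj$tss)
    want <- oraclePairsFromAssociations(assoc, lay$elDf, lay$tssDf)
    expect_equal(got[c("element_id", "gene_id")], want, ignore_attr = TRUE)
})

test_that("the negative cutoff follows the nearest-rank convention", {
    pos <- data.frame(distance = 1:20)
    # ceil(0.95 * 20) = 19th order statistic
    expect_equal(negativeCutoff(pos), 19)
    expect_equal(negativeCutoff(data.frame(distance = 777)), 777)
    shuffled <- data.frame(distance = sample(1:20))
    expect_equal(negativeCutoff(shuffled), 19)
    expect_error(negativeCutoff(data.frame(distance = numeric())),
                 "no positive")
    # direct order-statistic oracle at several percentiles
    x <- withr::with_seed(5, runif(37, 0, 1e6))
    for (p in c(25, 50, 95, 100))
        expect_equal(negativeCutoff(data.frame(distance = x), p),
                     oraclePercentile(x, p))
})

test_that("negatives respect the cutoff boundary and positive exclusion", {
    # gene exactly at cutoff kept, cutoff+1 excluded, positives never negative
    tss <- toyTss("chr1", c(50000, 60001, 60002), c("GPOS", "GAT", "GBEYOND"))
    els <- toyElements("chr1", 40000, 40300, "E1")
    pos <- data.frame(element_id = "E1", gene_id = "GPOS",
                      ambiguous = 0L, distance = 9700)
    gapAt <- oracleGap(60001, 40000, 40300)
    gapBeyond <- oracleGap(60002, 40000, 40300)
    neg <- generateNegatives(pos, els, tss, cutoff = gapAt)
    expect_identical(neg$gene_id, "GAT")
    expect_equal(neg$distance, gapAt)
    expect_equal(gapBeyond, gapAt + 1)
    expect_false("GPOS" %in% neg$gene_id)
})

test_that("negative generation equals a brute-force (element, gene) scan", {
    for (seed in c(121, 122)) {
        lay <- randomLayout(seed, nTss = 30, nEl = 10, span = 300000)
        obj <- layoutToObjects(lay)
        pos <- withr::with_seed(seed, data.frame(
            element_id = sample(lay$elDf$element_id, 6),
            gene_id = sample(lay$tssDf$gene_id, 6)))
        pos$ambiguous <- 0L
        pos$distance <- vapply(seq_len(nrow(pos)), function(i) {
            row <- lay$elDf[lay$elDf$element_id == pos$element_id[i], ]
            oracleNearest(row$chrom, row$start, row$end, lay$tssDf,
                          genes = pos$gene_id[i])$d
        }, numeric(1))
        pos <- pos[is.finite(pos$distance), ]
        cutoff <- oraclePercentile(pos$distance, 95)
        got <- generateNegatives(pos, obj$elements, obj$tss, cutoff)
        want <- oracleNegatives(pos, lay$elDf, lay$tssDf, cutoff)
        expect_equal(got[c("element_id", "gene_id", "distance")], want,
                     ignore_attr = TRUE)
    }
})

test_that("stripping ambiguity filters pairs and regenerates negatives", {
    tss <- toyTss("chr1", c(50000, 52000, 90000, 100000),
                  c("GA", "GB", "GC", "GD"))
    els <- toyElements("chr1", c(10000, 60000), c(10300, 60300),
                       c("E1", "E2"))
    links <- toyLinks(data.frame(
        chromA = "chr1", startA = c(10000, 60000),
        endA = c(10300, 60300),
        chromB = "chr1", startB = c(50500, 89500),
        endB = c(51500, 90500)))
    pos <- pairsFromLinks(links, els, tss)
    ds <- curateDataset(pos, els, tss)
    stripped <- stripAmbiguous(ds, els, tss)
    sp <- benchmarkPairs(stripped)
    # the manual filter: ambiguous positives E1|GA, E1|GB are gone
    expect_false(any(sp$ambiguous == 1L))
    expect_setequal(pairKeys(positives(stripped)), "E2|GC")
    # ambiguous genes are excluded as negatives for their element
    expect_false(any(sp$element_id == "E1" & sp$gene_id %in% c("GA", "GB")))
    expect_identical(datasetVariant(stripped), "noambig_natural")

    # with no ambiguous pairs the operation is the identity
    noAmb <- curateDataset(pos[pos$ambiguous == 0L, ], els, tss)
    again <- stripAmbiguous(noAmb, els, tss)
    expect_identical(benchmarkPairs(again), benchmarkPairs(noAmb))
    expect_equal(cutoffDistance(again), cutoffDistance(noAmb))

    # only ambiguous positives: an empty dataset remains
    onlyAmb <- curateDataset(pos, els, tss)
    onlyAmb <- toyDataset(positives(onlyAmb)[positives(onlyAmb)$ambiguous == 1L, ])
    expect_equal(nrow(benchmarkPairs(stripAmbiguous(onlyAmb, els, tss))), 0L)

    # explicit-gene assays are a no-op with a warning
    eq <- toyDataset(data.frame(element_id = "E1", gene_id = "GA",
                                label = 1L), assay = "eqtl")
    expect_warning(out <- stripAmbiguous(eq, els, tss), "not required")
    expect_identical(benchmarkPairs(out), benchmarkPairs(eq))
})

test_that("fixed-ratio variants enforce the per-element ratio rules", {
    mkpairs <- function(e, nPos, nNeg) {
        rbind(data.frame(element_id = e, gene_id = sprintf("%s-P%d", e,
                                                           seq_len(nPos)),
                         label = 1L),
              data.frame(element_id = e, gene_id = sprintf("%s-N%d", e,
                                                           seq_len(nNeg)),
                         label = 0L))
    }
    ds <- toyDataset(rbind(mkpairs("E1", 1, 10),  # plenty: keep 4 of 10
                           mkpairs("E2", 1, 3),   # 3 < 4: dropped entirely
                           mkpairs("E3", 2, 8)))  # 2 positives: keep 8
    fx <- fixedRatioVariant(ds)
    p <- benchmarkPairs(fx)
    expect_false("E2" %in% p$element_id)
    expect_equal(sum(p$element_id == "E1" & p$label == 0L), 4L)
    expect_equal(sum(p$element_id == "E3" & p$label == 0L), 8L)
    expect_equal(sum(p$label == 0L) / sum(p$label == 1L), 4)
    expect_identical(datasetVariant(fx), "all_fixed")

    # cross-dataset positives are ineligible as negatives; E1 falls below
    # the required 4 eligible negatives and is dropped entirely
    cross <- data.frame(element_id = "E1",
                        gene_id = sprintf("E1-N%d", 1:7))
    fx2 <- fixedRatioVariant(ds, crossPositives = cross)
    p2 <- benchmarkPairs(fx2)
    expect_false("E1" %in% p2$element_id)
    expect_equal(sum(p2$element_id == "E3" & p2$label == 0L), 8L)

    # determinism: same seed identical, different seed same positives
    fxA <- fixedRatioVariant(ds)
    fxB <- fixedRatioVariant(ds)
    expect_identical(benchmarkPairs(fxA), benchmarkPairs(fxB))
    fxC <- fixedRatioVariant(ds, policy = curationPolicy(seed = 99L))
    expect_identical(pairKeys(positives(fxA)), pairKeys(positives(fxC)))
})

test_that("matched subsets obey their restriction rules", {
    withr::with_seed(7, {
        els <- sprintf("E%02d", 1:12)
        pairs <- do.call(rbind, lapply(seq_along(els), function(i) {
            nNeg <- sample(2:6, 1)
            # the first two negatives reuse other elements'" positive genes,
            # so every gene appears with both labels somewhere
            negGenes <- c(sprintf("GP%02d", (i %% 12) + 1),
                          sprintf("GP%02d", ((i + 1) %% 12) + 1),
                          sprintf("GN%02d-%d", i, seq_len(nNeg)))
            rbind(data.frame(element_id = els[i],
                             gene_id = sprintf("GP%02d", i), label = 1L,
                             distance = sample(1e3:2e5, 1)),
                  data.frame(element_id = els[i], gene_id = negGenes,
                             label = 0L,
                             distance = sample(1e3:2e5, nNeg + 2)))
        }))
    })
    ds <- toyDataset(pairs)

    rat <- benchmarkPairs(matchedSubsets(ds, "ratio"))
    expect_equal(sum(rat$label == 0L) / sum(rat$label == 1L), 2)
    expect_true(all(table(rat$element_id[rat$label == 1L]) == 1))

    prom <- benchmarkPairs(matchedSubsets(ds, "promoter"))
    # genes appearing only as positives are excluded by the matching rule
    expect_true(all(prom$gene_id %in%
                    intersect(pairs$gene_id[pairs$label == 1L],
                              pairs$gene_id[pairs$label == 0L])))

    dist <- benchmarkPairs(matchedSubsets(ds, "distance"))
    posPerBin <- table(cut(dist$distance[dist$label == 1L],
                           unique(quantile(pairs$distance[pairs$label == 1L],
                                           seq(0, 1, length.out = 6),
                                           type = 1)),
                           include.lowest = TRUE))
    posPerBin <- posPerBin[posPerBin > 0]
    expect_true(max(posPerBin) - min(posPerBin) <= 1)
    expect_equal(sum(dist$label == 0L) / sum(dist$label == 1L), 2)

    pd <- matchedSubsets(ds, "promoter_distance")
    expect_identical(datasetVariant(pd), "matched_promoter_distance")
})

test_that("curated datasets keep labels disjoint and negatives in range", {
    sb <- suppressMessages(simulateBenchmark(simulationConfig(seed = 42L)))
    p <- benchmarkPairs(sb$dataset)
    keys <- pairKey(p$element_id, p$gene_id)
    expect_false(any(duplicated(keys)))
    expect_true(all(p$distance[p$label == 0L] <=
                    cutoffDistance(sb$dataset)))
    st <- stripAmbiguous(sb$dataset, sb$annotation$elements,
                         sb$annotation$tss)
    fx <- fixedRatioVariant(st)
    fp <- benchmarkPairs(fx)
    expect_false(any(duplicated(pairKey(fp$element_id, fp$gene_id))))
    if (sum(fp$label == 1L) > 0)
        expect_equal(sum(fp$label == 0L) / sum(fp$label == 1L),
                     fx@policy@fixedRatio)
})

test_that("benchmark TSVs round-trip through write and read", {
    sb <- suppressMessages(simulateBenchmark(simulationConfig(seed = 5L)))
    f <- tempfile(fileext = ".tsv")
    writeBenchmark(sb$dataset, f)
    back <- readBenchmark(f)
    expect_identical(datasetId(back), datasetId(sb$dataset))
    expect_equal(benchmarkPairs(back), benchmarkPairs(sb$dataset))
})
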