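# Scoring methods: baselines, correlations, rank combination, supervised CV.

test_that("closest-gene assignment breaks ties lexicographically", {
    # two TSSs equidistant from the element: gaps 2999 on both sides
    els <- toyElements("chr1", 7000, 7400, "E1")
    tss <- toyTss("chr1", c(4000, 10399), c("GB", "GA"))
    expect_equal(oracleGap(4000, 7000, 7400), oracleGap(10399, 7000, 7400))
    got <- closestGenePrediction(els, tss)
    expect_identical(got$gene_id, "GA")
    # element on a TSS-free chromosome is skipped and counted
    els2 <- suppressWarnings(c(els, toyElements("chr9", 100, 300, "E2")))
    got2 <- closestGenePrediction(els2, tss)
    expect_equal(attr(got2, "nSkipped"), 1L)
    expect_identical(got2$element_id, "E1")
})

test_that("closest-gene matches a brute-force nearest scan", {
    lay <- randomLayout(201, nTss = 40, nEl = 0)
    obj <- layoutToObjects(lay)
    els <- withr::with_seed(202, {
        s <- sample.int(195000, 500)
        data.frame(chrom = sample(c("chr1", "chr2"), 500, replace = TRUE),
                   start = s, end = s + 250,
                   element_id = sprintf("Q%03d", 1:500))
    })
    got <- closestGenePrediction(
        toyElements(els$chrom, els$start, els$end, els$element_id), obj$tss)
    for (i in seq_len(nrow(got))) {
        row <- els[els$element_id == got$element_id[i], ]
        exp <- oracleNearest(row$chrom, row$start, row$end, lay$tssDf)
        expect_identical(got$gene_id[i], exp$gene)
        expect_identical(got$distance[i], as.numeric(exp$d))
    }
    # restricting to protein-coding genes can never predict a non-coding one
    tssMixed <- tssIndexFromTable(data.frame(
        chrom = lay$tssDf$chrom, pos = lay$tssDf$pos, strand = "+",
        gene_id = lay$tssDf$gene_id,
        gene_type = rep(c("protein_coding", "lincRNA"), length.out = 40)))
    coding <- tssMixed[mcols(tssMixed)$gene_type == "protein_coding"]
    codingIdx <- new("TssIndex", coding)
    pred <- closestGenePrediction(
        toyElements(els$chrom, els$start, els$end, els$element_id),
        codingIdx)
    nonCoding <- mcols(tssMixed)$gene_id[mcols(tssMixed)$gene_type != "protein_coding"]
    expect_false(any(pred$gene_id %in% nonCoding))
})

test_that("inverse-distance scores rank pairs by proximity", {
    p <- data.frame(element_id = "E", gene_id = c("G1", "G2", "G3"),
                    distance = c(1000, 1, 0))
    s <- distanceScore(p)
    expect_equal(s$score, c(0.001, 1, 1))  # zero distance capped at 1
    rnd <- withr::with_seed(7, data.frame(
        element_id = "E", gene_id = sprintf("G%03d", 1:100),
        distance = sample.int(1e6, 100)))
    sc <- distanceScore(rnd)
    expect_identical(order(-sc$score), order(rnd$distance))
})

test_that("group-averaged signal correlation takes the best TSS element", {
    m <- rbind(
        EH1 = c(1, 2, 3, 4, 5, 6),
        TA  = c(2, 4, 6, 8, 10, 12),  # perfectly correlated with EH1
        TB  = c(6, 5, 4, 3, 2, 1),    # perfectly anti-correlated
        TC  = c(1, 1, 2, 2, 1, 1))
    colnames(m) <- paste0("B", 1:6)
    sm <- signalMatrix(m)
    map <- data.frame(gene_id = c("G", "G", "G"), pos = c(0, 1, 2),
                      element_id = c("TA", "TB", "TC"))
    p <- data.frame(element_id = "EH1", gene_id = "G")
    got <- dnaseDnaseScore(p, sm, map)
    # max over the three per-TSS correlations, computed independently
    expect_equal(got$score,
                 max(cor(m["EH1", ], m["TA", ]), cor(m["EH1", ], m["TB", ]),
                     cor(m["EH1", ], m["TC", ])))
    expect_equal(got$score, 1)
    gotB <- dnaseDnaseScore(p, sm, map[2, ])
    expect_equal(gotB$score, -1)
    # grouping averages columns before correlating
    smG <- signalMatrix(m, groups = c("g1", "g1", "g2", "g2", "g3", "g3"))
    gotG <- dnaseDnaseScore(p, smG, map[1, , drop = FALSE])
    ga <- cbind(rowMeans(m[, 1:2]), rowMeans(m[, 3:4]), rowMeans(m[, 5:6]))
    expect_equal(gotG$score, cor(ga["EH1", ], ga["TA", ]))
    # fewer groups than required gives the sentinel
    sm2 <- signalMatrix(m[, 1:2])
    expect_equal(dnaseDnaseScore(p, sm2, map)$score, -100)
})

test_that("expression correlation picks the strongest site and flags gaps", {
    sites <- rbind(S1 = c(5, 1, 1, 1), S2 = c(9, 2, 2, 2),
                   S3 = c(1, 8, 8, 8))
    colnames(sites) <- paste0("B", 1:4)
    expr <- rbind(GA = c(9, 2, 2, 2), GFLAT = c(3, 3, 3, 3))
    colnames(expr) <- paste0("B", 1:4)
    overlap <- data.frame(element_id = c("E1", "E1", "E1", "E2"),
                          site_id = c("S1", "S2", "S3", "S3"))
    p <- data.frame(element_id = c("E1", "E2", "E3", "E1"),
                    gene_id = c("GA", "GA", "GA", "GFLAT"))
    got <- dnaseExpressionScore(p, signalMatrix(sites), signalMatrix(expr),
                                overlap, focalColumn = "B1")
    # E1's strongest site in B1 is S2 (9 > 5 > 1), verified exhaustively
    best <- names(which.max(sites[c("S1", "S2", "S3"), "B1"]))
    expect_equal(got$score[1], cor(sites[best, ], expr["GA", ]))
    expect_equal(got$score[2], cor(sites["S3", ], expr["GA", ]))
    # no overlapping site, and a constant expression row: sentinel -100
    expect_equal(got$score[3], -100)
    expect_equal(got$score[4], -100)
    # sentinel pairs rank below every finite-scored pair
    expect_true(all(got$score[3:4] < got$score[1:2]))
})

test_that("average rank combines methods symmetrically", {
    p <- data.frame(element_id = "E", gene_id = c("G1", "G2", "G3"))
    a <- cbind(p, score = c(3, 2, 1), method = "m1")
    b <- cbind(p, score = c(10, 20, 30), method = "m2")
    avg <- averageRankScore(a, b)
    # G1 ranked 1st by a and 3rd by b; G2 2nd by both: equal combined scores
    expect_equal(avg$score[1], avg$score[2])
    # a method averaged with itself preserves its ranking exactly
    self <- averageRankScore(a, a)
    expect_identical(order(-self$score), order(-a$score))
    # brute-force rank averaging on random scores
    rnd <- withr::with_seed(11, list(sa = rnorm(100), sb = rnorm(100)))
    pa <- data.frame(element_id = "E", gene_id = sprintf("G%03d", 1:100),
                     score = rnd$sa)
    pb <- data.frame(element_id = "E", gene_id = sprintf("G%03d", 1:100),
                     score = rnd$sb)
    comb <- averageRankScore(pa, pb)
    want <- -(rank(-rnd$sa) + rank(-rnd$sb)) / 2
    expect_equal(comb$score, want)
    # mismatched universes are an error naming the odd pairs
    expect_error(averageRankScore(pa, pb[-1, ]), "E\\|G001")
})

test_that("feature extraction follows the region schema", {
    tss <- toyTss("chr1", 20000, "G1")
    pairs <- data.frame(element_id = "E1", chrom = "chr1", start = 5000L,
                        end = 5400L, gene_id = "G1", label = 1L,
                        ambiguous = 0L, distance = 14600,
                        cv_group = NA_character_)
    ds <- toyDataset(pairs)
    mkTrack <- function(val) list(chr1 = rep(val, 60000))
    tracks <- list(DNase = mkTrack(2), H3K4me3 = mkTrack(1),
                   H3K27ac = mkTrack(4), CTCF = mkTrack(0),
                   Other = mkTrack(7))
    f4 <- extractFeatures(ds, tracks, tss, "core4")
    expect_equal(ncol(f4), 13L)  # 3 regions x 4 tracks + distance
    expect_setequal(colnames(f4),
                    c(outer(c("DNase", "H3K4me3", "H3K27ac", "CTCF"),
                            c("enhancer", "promoter", "window"),
                            paste, sep = "_"), "distance"))
    f3 <- extractFeatures(ds, tracks, tss, "core3")
    expect_equal(ncol(f3), 10L)
    full <- extractFeatures(ds, tracks, tss, "full")
    expect_equal(ncol(full), 3L * 5L + 1L)
    # an all-zero track contributes zero features everywhere
    expect_equal(unname(unlist(f4[, grep("CTCF", names(f4))])), c(0, 0, 0))
    expect_equal(f4$DNase_enhancer, 2)
    expect_equal(f4$distance, 14600)
    # adjacent element and promoter leave no intervening window
    touching <- toyDataset(data.frame(
        element_id = "E2", chrom = "chr1", start = 17000L, end = 18500L,
        gene_id = "G1", label = 1L, ambiguous = 0L, distance = 1500,
        cv_group = NA_character_))
    ft <- extractFeatures(touching, tracks, tss, "core4")
    expect_equal(unname(unlist(ft[, grep("window", names(ft))])),
                 rep(0, 4))
    # a track missing the needed chromosome is a named error
    ds2 <- toyDataset(data.frame(element_id = "E1", chrom = "chr2",
                                 start = 5000L, end = 5400L,
                                 gene_id = "G2", label = 1L))
    tss2 <- toyTss("chr2", 20000, "G2")
    expect_error(extractFeatures(ds2, tracks, tss2, "core4"),
                 "DNase.*chr2")
    expect_error(extractFeatures(ds, tracks[c("DNase", "CTCF")], tss,
                                 "core4"),
                 "H3K4me3")
})

test_that("supervised CV separates a planted feature and audits folds", {
    n <- 240
    dat <- withr::with_seed(42, {
        groups <- paste0("cv-", rep(0:5, each = n / 6))
        labels <- rbinom(n, 1, 0.3)
        feats <- data.frame(signal = labels + rnorm(n, 0, 0.05),
                            junk = rnorm(n))
        list(groups = groups, labels = labels, feats = feats)
    })
    sc <- supervisedCV(dat$feats, dat$labels, dat$groups, nrounds = 40)
    expect_false(anyNA(sc))
    expect_identical(attr(sc, "fold"), dat$groups)
    expect_gt(aupr(prCurve(as.numeric(sc), dat$labels)), 0.95)
    # single-class training folds are refused
    labs <- c(rep(1L, 10), rep(1L, 10), rep(0L, 10))
    grps <- rep(c("a", "b", "c"), each = 10)
    expect_error(supervisedCV(data.frame(x = rnorm(30)), labs, grps,
                              nrounds = 5),
                 "single-class")
})

test_that("cross-cell application reduces to within-type CV when identical", {
    n <- 120
    dat <- withr::with_seed(43, {
        list(groups = paste0("cv-", rep(0:3, each = n / 4)),
             labels = rbinom(n, 1, 0.4),
             feats = data.frame(a = rnorm(n), b = rnorm(n)))
    })
    dat$feats$a <- dat$feats$a + dat$labels
    within <- supervisedCV(dat$feats, dat$labels, dat$groups, nrounds = 20)
    across <- crossCellApply(dat$feats, dat$labels, dat$groups,
                             dat$feats, dat$groups, nrounds = 20)
    expect_equal(as.numeric(within), across)
    # schema mismatch is an error listing the differing columns
    other <- dat$feats
    names(other) <- c("a", "zz")
    expect_error(crossCellApply(dat$feats, dat$labels, dat$groups,
                                other, dat$groups, nrounds = 5),
                 "zz")
})
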