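# Synthetic fixtures: a toy genome with genes, distal elements and planted
# element-gene interactions emitted in every assay dialect, plus signal and
# expression panels with a tunable planted co-activity. Everything is
# deterministic under the config seed.

#' Construct simulation settings
#'
#' @param nChrom,chromLength chromosome count and length (bp).
#' @param genesPerChrom genes per chromosome (one TSS each).
#' @param bidirectionalRate probability that a gene is placed with its TSS
#'   within 4 kb of the previous gene's TSS (a divergent promoter pair),
#'   the mechanism that makes interaction anchors ambiguous.
#' @param noncodingRate fraction of genes given a non-coding biotype.
#' @param elementsPerChrom distal candidate elements per chromosome.
#' @param linksPerAssay planted interactions emitted per assay.
#' @param distMeanLog,distSdLog log-normal parameters of the planted
#'   element-gene distance distribution (bp).
#' @param maxDistance truncation of planted distances (bp).
#' @param panelWidth biosample columns in the signal/expression panels.
#' @param coActivity planted element-gene co-activity strength in
#'   \[0, 1\]; 0 removes all shared signal.
#' @param noise log-scale Gaussian noise level on the panels.
#' @param seed master seed; every random draw in the generator flows from
#'   it.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(nChrom = 4L, chromLength = 4e6,
                             genesPerChrom = 80L, bidirectionalRate = 0.2,
                             noncodingRate = 0.1, elementsPerChrom = 25L,
                             linksPerAssay = 30L,
                             distMeanLog = log(5e4), distSdLog = 0.8,
                             maxDistance = 1e6, panelWidth = 32L,
                             coActivity = 0.9, noise = 0.3, seed = 1L) {
    new("SimulationConfig", nChrom = as.integer(nChrom),
        chromLength = as.numeric(chromLength),
        genesPerChrom = as.integer(genesPerChrom),
        bidirectionalRate = as.numeric(bidirectionalRate),
        noncodingRate = as.numeric(noncodingRate),
        elementsPerChrom = as.integer(elementsPerChrom),
        linksPerAssay = as.integer(linksPerAssay),
        distMeanLog = as.numeric(distMeanLog),
        distSdLog = as.numeric(distSdLog),
        maxDistance = as.numeric(maxDistance),
        panelWidth = as.integer(panelWidth),
        coActivity = as.numeric(coActivity), noise = as.numeric(noise),
        seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", object@nChrom, "chromosome(s) x",
        object@chromLength, "bp,", object@genesPerChrom, "genes and",
        object@elementsPerChrom, "elements each;",
        object@linksPerAssay, "links/assay; co-activity",
        object@coActivity, "; seed", object@seed, "\n")
})

#' Simulate a toy annotation
#'
#' Places `genesPerChrom` genes per chromosome on a jittered grid, with a
#' `bidirectionalRate` fraction relocated to form divergent promoter pairs
#' with TSSs less than 4 kb apart (whose shared promoter windows later
#' create ambiguous anchors), then scatters elements rejected until
#' strictly further than 2 kb from every TSS, so every emitted element is
#' distal by construction.
#'
#' @param config a [SimulationConfig-class].
#' @return list with `tss` (a [TssIndex-class]), `elements`
#'   ([GenomicRanges::GRanges] with `element_id`) and `genes` (data.frame
#'   with `gene_id`, `symbol`, `gene_type`, `chrom`, `tss` 0-based,
#'   `strand`).
#' @export
simulateAnnotation <- function(config) {
    slot <- config@chromLength / config@genesPerChrom
    if (slot < 12000)
        stop("infeasible spacing: ", config@genesPerChrom,
             " genes do not fit in ", config@chromLength, " bp")
    withSeed(config@seed, {
        genes <- list()
        for (ci in seq_len(config@nChrom)) {
            chrom <- paste0("chr", ci)
            base <- (seq_len(config@genesPerChrom) - 0.5) * slot
            pos <- round(base + runif(config@genesPerChrom,
                                      -slot / 8, slot / 8))
            strand <- sample(c("+", "-"), config@genesPerChrom,
                             replace = TRUE)
            close <- runif(config@genesPerChrom) < config@bidirectionalRate
            close[1L] <- FALSE
            for (i in which(close)) {
                pos[i] <- pos[i - 1L] + sample(500:3500, 1L)
                strand[i - 1L] <- "-"
                strand[i] <- "+"
            }
            type <- ifelse(runif(config@genesPerChrom) < config@noncodingRate,
                           "lincRNA", "protein_coding")
            genes[[ci]] <- data.frame(
                gene_id = sprintf("GSIM%02d%03d", ci,
                                  seq_len(config@genesPerChrom)),
                symbol = sprintf("SYM%02d%03d", ci,
                                 seq_len(config@genesPerChrom)),
                gene_type = type, chrom = chrom, tss = pos, strand = strand)
        }
        genes <- do.call(rbind, genes)
        # elements: rejection sampling away from every TSS
        els <- list()
        for (ci in seq_len(config@nChrom)) {
            chrom <- paste0("chr", ci)
            tpos <- genes$tss[genes$chrom == chrom]
            got <- 0L
            starts <- integer(0)
            widths <- integer(0)
            attempts <- 0L
            while (got < config@elementsPerChrom) {
                attempts <- attempts + 1L
                if (attempts > 100000L)
                    stop("could not place elements away from TSSs")
                w <- sample(150:350, 1L)
                s <- round(runif(1, 0, config@chromLength - w))  # 0-based
                gaps <- pointIntervalGap(tpos + 1L, s + 1L, s + w)
                if (min(gaps) > 2000) {
                    got <- got + 1L
                    starts[got] <- s
                    widths[got] <- w
                }
            }
            ord <- order(starts)
            els[[ci]] <- data.frame(chrom = chrom, start = starts[ord],
                                    width = widths[ord])
        }
        els <- do.call(rbind, els)
        els$element_id <- sprintf("ESIM%05d", seq_len(nrow(els)))
        elements <- GRanges(els$chrom,
                            IRanges(els$start + 1L, width = els$width))
        mcols(elements)$element_id <- els$element_id
        tss <- tssIndexFromTable(data.frame(
            chrom = genes$chrom, pos = genes$tss, strand = genes$strand,
            gene_id = genes$gene_id, gene_type = genes$gene_type))
        list(tss = tss, elements = elements, genes = genes)
    })
}

# Sample n planted (element, gene) pairs whose distances follow the
# configured truncated log-normal: distances are drawn from the analytic
# distribution and matched to the nearest available candidate distance in
# the (element x gene) pool, which is dense enough for the matching error
# to be negligible.
.plantPairs <- function(annotation, config, n) {
    et <- elementTable(annotation$elements)
    tt <- tssTable(annotation$tss)
    cand <- merge(as.data.table(et), as.data.table(tt), by = "chrom",
                  allow.cartesian = TRUE)
    cand[, gap := pointIntervalGap(pos, start, end)]
    cand <- cand[cand$gap <= config@maxDistance, ]
    setorder(cand, gap, element_id, gene_id)
    draws <- pmin(rlnorm(n, config@distMeanLog, config@distSdLog),
                  config@maxDistance)
    idx <- vapply(draws, function(d) which.min(abs(cand$gap - d)),
                  integer(1))
    cand[idx, c("element_id", "chrom", "start", "end", "gene_id", "pos",
                "gap"), with = FALSE]
}

# Generator-side bookkeeping of what a set of emitted anchor pairs links:
# every element overlapping anchor A and every gene with a TSS within the
# promoter window of anchor B, by direct arithmetic on the annotation
# tables. Coordinates are 0-based half-open.
.linkTruth <- function(anchors, annotation, window = 2000) {
    et <- as.data.table(elementTable(annotation$elements))
    gt <- as.data.table(annotation$genes)
    rows <- list()
    for (i in seq_len(nrow(anchors))) {
        a <- anchors[i, ]
        ee <- et[et$chrom == a$chromA & et$start <= a$endA &
                 et$end >= a$startA + 1L, ]  # 1-based overlap test
        nearBase <- pmin(pmax(gt$tss, a$startB), a$endB - 1L)
        gg <- gt[gt$chrom == a$chromB & abs(gt$tss - nearBase) <= window, ]
        if (nrow(ee) == 0L || nrow(gg) == 0L) next
        rows[[length(rows) + 1L]] <- data.table(
            element_id = rep(ee$element_id, each = nrow(gg)),
            gene_id = rep(gg$gene_id, nrow(ee)),
            ambiguous = nrow(gg) >= 2L)
    }
    if (length(rows) == 0L)
        return(data.frame(element_id = character(), gene_id = character(),
                          ambiguous = integer()))
    all <- rbindlist(rows)
    agg <- all[, list(ambiguous = as.integer(all(ambiguous))),
               by = c("element_id", "gene_id")]
    out <- orderPairs(as.data.frame(agg))
    rownames(out) <- NULL
    out
}

# Desert intervals: no TSS within `margin` and no element overlap, so a
# link anchored there can never produce a pair in either orientation.
.desertIntervals <- function(annotation, config, n, width = 1000,
                             margin = 5000) {
    et <- as.data.table(elementTable(annotation$elements))
    gt <- as.data.table(annotation$genes)
    out <- data.table(chrom = character(n), start = numeric(n),
                      end = numeric(n))
    got <- 0L
    attempts <- 0L
    while (got < n) {
        attempts <- attempts + 1L
        if (attempts > 100000L) stop("could not place desert anchors")
        chrom <- paste0("chr", sample.int(config@nChrom, 1L))
        s <- round(runif(1, 0, config@chromLength - width))
        tpos <- gt$tss[gt$chrom == chrom]
        if (min(abs(tpos - pmin(pmax(tpos, s), s + width - 1L))) <= margin)
            next
        ee <- et[et$chrom == chrom & et$start <= s + width &
                 et$end >= s + 1L, ]
        if (nrow(ee) > 0L) next
        got <- got + 1L
        out[got, `:=`(chrom = chrom, start = s, end = s + width)]
    }
    out
}

# Anchor pairs (0-based half-open) around planted (element, gene) pairs.
.plantedAnchors <- function(planted) {
    n <- nrow(planted)
    pad <- sample(0:200, n, replace = TRUE)
    a <- sample(200:1500, n, replace = TRUE)
    b <- sample(200:1500, n, replace = TRUE)
    data.table(chromA = planted$chrom,
               startA = pmax(0, planted$start - 1L - pad),
               endA = planted$end + pad,
               chromB = planted$chrom,
               startB = pmax(0, planted$pos - 1L - a),
               endB = planted$pos + b)
}

#' Emit planted interactions in every assay dialect
#'
#' Samples planted element-gene pairs with log-normally distributed
#' distances and writes one file per assay dialect: ChIA-PET clusters
#' (with sub-threshold decoy rows), a Hi-C loop list (bare chromosome
#' names, header line), a capture Hi-C table (scores in column 11, decoys
#' at or below the threshold), a variant-gene eQTL export (GEUVADIS-style
#' columns, versioned gene identifiers) and a region-gene perturbation
#' table (gene symbols). Links anchored in gene deserts are added as
#' guaranteed non-pairing rows. The planted truth — all pairs the emitted
#' above-threshold links support, ambiguity included — is computed by
#' direct arithmetic on the annotation tables and returned per assay.
#'
#' @param annotation output of [simulateAnnotation()].
#' @param config the same [SimulationConfig-class].
#' @param dir output directory (created if needed).
#' @return list with `files` (named paths per assay), `truth` (data.frame
#'   `element_id`, `gene_id`, `ambiguous`, `assay`) and `geneMap` (symbol
#'   -> gene_id, for the perturbation reader).
#' @export
simulateLinks <- function(annotation, config, dir = tempfile("fixtures")) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    n <- config@linksPerAssay
    withSeed(config@seed + 1L, {
        truths <- list()
        files <- c()

        ## ChIA-PET: planted + sub-threshold decoys + desert links
        planted <- .plantPairs(annotation, config, n)
        anch <- .plantedAnchors(planted)
        anch$count <- 4L + rpois(n, 4)
        decoys <- .plantedAnchors(.plantPairs(annotation, config,
                                              ceiling(n / 3)))
        decoys$count <- sample(1:3, nrow(decoys), replace = TRUE)
        desert <- .desertIntervals(annotation, config, ceiling(n / 3))
        desertRows <- data.table(chromA = desert$chrom,
                                 startA = desert$start, endA = desert$end,
                                 chromB = desert$chrom,
                                 startB = desert$start + 100,
                                 endB = desert$end + 100,
                                 count = 4L + rpois(nrow(desert), 2))
        # desert "links" reuse their own locus for both anchors; shift B a
        # little so anchors differ
        tab <- rbind(anch, decoys, desertRows)
        tab <- tab[sample.int(nrow(tab)), ]
        f <- file.path(dir, "chiapet.tsv")
        fwrite(tab, f, sep = "\t", col.names = FALSE, eol = "\n")
        files["chiapet"] <- f
        truths[["chiapet"]] <- .linkTruth(anch, annotation)

        ## Hi-C loop list: all rows count, bare chromosome names
        planted <- .plantPairs(annotation, config, n)
        anch <- .plantedAnchors(planted)
        desert <- .desertIntervals(annotation, config, ceiling(n / 4))
        hic <- rbind(anch,
                     data.table(chromA = desert$chrom, startA = desert$start,
                                endA = desert$end, chromB = desert$chrom,
                                startB = desert$start + 100,
                                endB = desert$end + 100))
        hic <- hic[sample.int(nrow(hic)), ]
        out <- data.table(chr1 = sub("^chr", "", hic$chromA),
                          x1 = hic$startA, x2 = hic$endA,
                          chr2 = sub("^chr", "", hic$chromB),
                          y1 = hic$startB, y2 = hic$endB,
                          observed = 10L + rpois(nrow(hic), 20))
        f <- file.path(dir, "hiccups.txt")
        fwrite(out, f, sep = "\t", eol = "\n")
        files["hic"] <- f
        truths[["hic"]] <- .linkTruth(hic, annotation)

        ## Capture Hi-C: score in column 11, strict threshold at 10
        planted <- .plantPairs(annotation, config, n)
        anch <- .plantedAnchors(planted)
        anch$score <- 10 + round(rexp(n, 0.5), 3)
        decoys <- .plantedAnchors(.plantPairs(annotation, config,
                                              ceiling(n / 3)))
        decoys$score <- round(runif(nrow(decoys), 0, 10), 3)
        chic <- rbind(anch, decoys)
        chic <- chic[sample.int(nrow(chic)), ]
        out <- data.table(chrom1 = chic$chromA, start1 = chic$startA,
                          end1 = chic$endA, chrom2 = chic$chromB,
                          start2 = chic$startB, end2 = chic$endB,
                          bait = "bait", other = "other",
                          readsA = 10L, readsB = 10L,
                          log_ratio = chic$score)
        f <- file.path(dir, "chic.tsv")
        fwrite(out, f, sep = "\t", eol = "\n")
        files["chic"] <- f
        truths[["chic"]] <- .linkTruth(anch[anch$score > 10, ], annotation)

        ## eQTL: variant uniform inside the element, explicit gene
        planted <- .plantPairs(annotation, config, n)
        vpos1 <- planted$start +
            floor(runif(n) * (planted$end - planted$start + 1L))
        out <- data.table(SNP_ID = sprintf("rs%06d", seq_len(n)),
                          CHR_SNP = planted$chrom, SNPpos = vpos1,
                          GENE_ID = paste0(planted$gene_id, ".1"))
        f <- file.path(dir, "eqtl.tsv")
        fwrite(out, f, sep = "\t", eol = "\n")
        files["eqtl"] <- f
        et <- as.data.table(elementTable(annotation$elements))
        hits <- merge(data.table(chrom = planted$chrom, pos = vpos1,
                                 gene_id = planted$gene_id),
                      et, by = "chrom", allow.cartesian = TRUE)
        hits <- hits[hits$pos >= hits$start & hits$pos <= hits$end, ]
        tq <- unique(data.frame(element_id = hits$element_id,
                                gene_id = hits$gene_id))
        tq$ambiguous <- integer(nrow(tq))
        truths[["eqtl"]] <- orderPairs(tq)

        ## CRISPR perturbation: the element's own interval, gene symbol
        planted <- .plantPairs(annotation, config, n)
        sym <- annotation$genes$symbol[match(planted$gene_id,
                                             annotation$genes$gene_id)]
        out <- data.table(chrom = planted$chrom, start = planted$start - 1L,
                          end = planted$end, gene = sym)
        f <- file.path(dir, "crisprqtl.tsv")
        fwrite(out, f, sep = "\t", eol = "\n")
        files["crisprqtl"] <- f
        hits <- merge(data.table(chrom = planted$chrom,
                                 rs = planted$start, re = planted$end,
                                 gene_id = planted$gene_id),
                      et, by = "chrom", allow.cartesian = TRUE)
        hits <- hits[hits$rs <= hits$end & hits$re >= hits$start, ]
        tq <- unique(data.frame(element_id = hits$element_id,
                                gene_id = hits$gene_id))
        tq$ambiguous <- integer(nrow(tq))
        truths[["crisprqtl"]] <- orderPairs(tq)

        truth <- do.call(rbind, lapply(names(truths), function(a) {
            t <- truths[[a]]
            if (nrow(t)) cbind(t, assay = a) else NULL
        }))
        rownames(truth) <- NULL
        geneMap <- setNames(annotation$genes$gene_id,
                            annotation$genes$symbol)
        list(files = files, truth = truth, geneMap = geneMap)
    })
}

#' Simulate signal and expression panels with planted co-activity
#'
#' Elements get sparse baseline activity (a minority of biosample columns
#' active) and genes broad baseline activity, emulating the observation
#' that promoters and gene expression are far less cell-type-specific
#' than distal elements. Every true pair then receives a shared latent
#' activity component scaled by `coActivity`, so at strength 0 element
#' and gene rows are independent and at high strength true pairs
#' correlate across the panel. Finally log-scale Gaussian noise is
#' applied and values clipped at zero.
#'
#' @param annotation output of [simulateAnnotation()].
#' @param truth data.frame of true pairs (`element_id`, `gene_id`), e.g.
#'   from [simulateLinks()].
#' @param config the [SimulationConfig-class]; uses `panelWidth`,
#'   `coActivity`, `noise` and `seed`.
#' @return list with `elementSignals` and `expression`, both
#'   [SignalMatrix-class] over the same biosample panel.
#' @export
simulateSignalPanels <- function(annotation, truth, config) {
    withSeed(config@seed + 2L, {
        cols <- sprintf("B%03d", seq_len(config@panelWidth))
        eids <- mcols(annotation$elements)$element_id
        gids <- annotation$genes$gene_id
        w <- config@panelWidth
        elM <- matrix(0, nrow = length(eids), ncol = w,
                      dimnames = list(eids, cols))
        for (i in seq_along(eids)) {
            on <- runif(w) < 0.25
            elM[i, on] <- runif(sum(on), 2, 6)
        }
        gnM <- matrix(0, nrow = length(gids), ncol = w,
                      dimnames = list(gids, cols))
        for (i in seq_along(gids)) {
            on <- runif(w) < 0.85
            gnM[i, on] <- runif(sum(on), 2, 6)
        }
        tp <- unique(truth[, c("element_id", "gene_id")])
        for (i in seq_len(nrow(tp))) {
            f <- (runif(w) < 0.4) * runif(w, 2, 6)
            e <- tp$element_id[i]
            g <- tp$gene_id[i]
            if (e %in% eids) elM[e, ] <- elM[e, ] + config@coActivity * f
            if (g %in% gids) gnM[g, ] <- gnM[g, ] + config@coActivity * f
        }
        if (config@noise > 0) {
            elM <- pmax(elM * exp(matrix(rnorm(length(elM), 0,
                                               config@noise),
                                         nrow = nrow(elM))), 0)
            gnM <- pmax(gnM * exp(matrix(rnorm(length(gnM), 0,
                                               config@noise),
                                         nrow = nrow(gnM))), 0)
        }
        list(elementSignals = signalMatrix(elM),
             expression = signalMatrix(gnM))
    })
}

#' Locus-shared feature panel for leakage experiments
#'
#' Emulates the feature structure that inflates randomised
#' cross-validation: pairs of one element (locus) share that locus's
#' latent feature vector, and within a locus positives are offset from
#' negatives along a direction that is random per locus. A model that has
#' seen a locus in training can separate its held-out pairs (it learns
#' the locus-specific direction from near-identical training examples),
#' but the direction does not transfer across loci, so under
#' chromosome-held-out folds the features carry no usable signal. The gap
#' between randomised and chromosome-based CV performance on these
#' features is therefore pure leakage.
#'
#' @param dataset a [BenchmarkDataset-class].
#' @param nFeatures latent dimensions per locus; default 6.
#' @param labelEffect within-locus offset magnitude between positives and
#'   negatives; default 1.
#' @param noise pair-level feature noise sd; default 0.1.
#' @param seed RNG seed.
#' @return numeric feature data.frame, one row per pair.
#' @export
locusFeatures <- function(dataset, nFeatures = 6L, labelEffect = 1,
                          noise = 0.1, seed = 1L) {
    p <- benchmarkPairs(dataset)
    withSeed(seed, {
        els <- sort(unique(p$element_id))
        z <- matrix(rnorm(length(els) * nFeatures), nrow = length(els),
                    dimnames = list(els, paste0("f", seq_len(nFeatures))))
        delta <- matrix(rnorm(length(els) * nFeatures), nrow = length(els),
                        dimnames = list(els, colnames(z)))
        out <- z[p$element_id, , drop = FALSE] +
            labelEffect * p$label * delta[p$element_id, , drop = FALSE] +
            matrix(rnorm(nrow(p) * nFeatures, 0, noise), nrow = nrow(p))
        out <- as.data.frame(out)
        rownames(out) <- pairKey(p$element_id, p$gene_id)
        out
    })
}

#' One-call synthetic benchmark
#'
#' Runs the full pipeline on fixtures: simulate an annotation, emit the
#' requested assay's file, parse it back through the matching reader,
#' derive positives, curate negatives and assign chromosome CV groups.
#'
#' @param config a [SimulationConfig-class].
#' @param assay one of `"chiapet"`, `"hic"`, `"chic"`, `"eqtl"`,
#'   `"crisprqtl"`.
#' @param dir fixture directory (temporary by default).
#' @param policy a [CurationPolicy-class]; its seed defaults to the
#'   config's.
#' @return list with `dataset` (a [BenchmarkDataset-class] with CV groups
#'   assigned), `annotation`, `sim` (fixture files + truth) and
#'   `positives`.
#' @export
simulateBenchmark <- function(config = simulationConfig(),
                              assay = c("chiapet", "hic", "chic", "eqtl",
                                        "crisprqtl"),
                              dir = tempfile("fixtures"),
                              policy = curationPolicy(seed = config@seed)) {
    assay <- match.arg(assay)
    ann <- simulateAnnotation(config)
    sim <- simulateLinks(ann, config, dir)
    pos <- switch(assay,
        chiapet = pairsFromLinks(readChiaPet(sim$files["chiapet"]),
                                 ann$elements, ann$tss, policy),
        hic = pairsFromLinks(readHiccups(sim$files["hic"]),
                             ann$elements, ann$tss, policy),
        chic = pairsFromLinks(readChic(sim$files["chic"]),
                              ann$elements, ann$tss, policy),
        eqtl = pairsFromAssociations(readEqtl(sim$files["eqtl"], "geuvadis"),
                                     ann$elements, ann$tss),
        crisprqtl = pairsFromAssociations(
            readCrisprQtl(sim$files["crisprqtl"], sim$geneMap),
            ann$elements, ann$tss))
    ds <- curateDataset(pos, ann$elements, ann$tss, policy,
                        datasetId = paste0("sim-", assay), assay = assay)
    ds <- addChromCV(ds)
    list(dataset = ds, annotation = ann, sim = sim, positives = pos)
}
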