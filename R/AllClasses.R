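#' @import methods
#' @importFrom GenomicRanges GRanges findOverlaps seqnames start end width
#'   resize mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom GenomeInfoDb seqlevels
#' @importFrom data.table data.table as.data.table fread fwrite setkey := .N
#'   setorder rbindlist
#' @importFrom stats cor quantile rbinom rnorm runif rpois rexp qlnorm rlnorm
#'   setNames
#' @importFrom utils head tail
NULL

#' Transcription start site index
#'
#' A [GenomicRanges::GRanges] of width-1 ranges, one per distinct
#' (gene, position, strand) transcription start site, with metadata columns
#' `gene_id` and `gene_type`. The TSS of a plus-strand transcript is its
#' first base and that of a minus-strand transcript its last base, so the
#' index always stores the 5' end of transcription.
#'
#' @seealso [readTss()], [tssIndexFromTable()]
#' @export
setClass("TssIndex", contains = "GRanges")

setValidity("TssIndex", function(object) {
    msg <- character()
    if (length(object) > 0 && !all(width(object) == 1L))
        msg <- c(msg, "all TSS ranges must have width 1")
    if (!all(c("gene_id", "gene_type") %in% names(mcols(object))))
        msg <- c(msg, "metadata columns 'gene_id' and 'gene_type' are required")
    if (length(object) > 0 && !all(as.character(GenomicRanges::strand(object)) %in% c("+", "-")))
        msg <- c(msg, "strand must be '+' or '-' for every TSS")
    if (length(msg)) msg else TRUE
})

#' Normalised chromatin interaction links
#'
#' Paired anchors from a 3D chromatin assay (ChIA-PET clusters, Hi-C loop
#' calls or capture Hi-C interactions) after dialect parsing, filtering and
#' chromosome-name normalisation. Both anchors of every link lie on the same
#' chromosome; trans-chromosomal records are dropped at parse time.
#'
#' @slot anchor1,anchor2 [GenomicRanges::GRanges] of equal length.
#' @slot support numeric evidence per link (read count for ChIA-PET,
#'   log observed/expected for capture Hi-C, 1 for loop calls).
#' @slot assay one of `"chiapet"`, `"hic"`, `"chic"`.
#' @export
setClass("ChromatinLinks",
    representation(anchor1 = "GRanges", anchor2 = "GRanges",
                   support = "numeric", assay = "character"))

setValidity("ChromatinLinks", function(object) {
    msg <- character()
    if (length(object@anchor1) != length(object@anchor2) ||
        length(object@anchor1) != length(object@support))
        msg <- c(msg, "anchor1, anchor2 and support must have equal length")
    if (length(object@assay) != 1L ||
        !object@assay %in% c("chiapet", "hic", "chic"))
        msg <- c(msg, "assay must be one of 'chiapet', 'hic', 'chic'")
    if (any(object@support < 0))
        msg <- c(msg, "support must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Benchmark curation policy
#'
#' Holds every tunable constant of the curation procedure: the promoter
#' window (bp each side of a TSS) used to call a TSS-side anchor, the
#' percentile of positive-pair distances defining the negative-candidate
#' cutoff, the fixed negative:positive ratio and the minimum negatives an
#' element must retain in fixed-ratio sets, the matched-subset ratio, the
#' number of equal-occupancy distance bins, and the RNG seed from which all
#' sampling flows.
#'
#' @seealso [curationPolicy()]
#' @export
setClass("CurationPolicy",
    representation(promoterWindow = "numeric", negativePercentile = "numeric",
                   fixedRatio = "integer", minNegatives = "integer",
                   matchedRatio = "integer", nDistanceBins = "integer",
                   seed = "integer"))

setValidity("CurationPolicy", function(object) {
    msg <- character()
    if (object@promoterWindow <= 0) msg <- c(msg, "promoterWindow must be positive")
    if (object@negativePercentile <= 0 || object@negativePercentile > 100)
        msg <- c(msg, "negativePercentile must lie in (0, 100]")
    for (s in c("fixedRatio", "minNegatives", "matchedRatio", "nDistanceBins"))
        if (slot(object, s) < 1L) msg <- c(msg, paste(s, "must be a positive integer"))
    if (length(msg)) msg else TRUE
})

#' A curated benchmark dataset of candidate element-gene pairs
#'
#' One row of `pairs` per candidate pair: `element_id`, element coordinates
#' (`chrom`, `start`, `end`; 0-based half-open as in BED), `gene_id`,
#' `label` (1 positive / 0 negative), `ambiguous` (1 when the pair derives
#' only from interaction links whose TSS-side anchor covered the promoter
#' windows of multiple genes), `distance` (bp between the element and the
#' gene's nearest TSS) and `cv_group` (chromosome-based cross-validation
#' group, `NA` until assigned).
#'
#' @slot datasetId,assay,biosample,variant character scalars; `variant` is
#'   one of `all_natural`, `all_fixed`, `noambig_natural`, `noambig_fixed`,
#'   or a matched-subset tag.
#' @slot pairs data.frame as described above.
#' @slot cutoff the distance cutoff (bp) under which negatives were drawn.
#' @slot policy the [CurationPolicy-class] used.
#' @export
setClass("BenchmarkDataset",
    representation(datasetId = "character", assay = "character",
                   biosample = "character", variant = "character",
                   pairs = "data.frame", cutoff = "numeric",
                   policy = "CurationPolicy"))

.PAIR_COLS <- c("element_id", "chrom", "start", "end", "gene_id",
                "label", "ambiguous", "distance", "cv_group")

setValidity("BenchmarkDataset", function(object) {
    msg <- character()
    p <- object@pairs
    if (!all(.PAIR_COLS %in% names(p)))
        msg <- c(msg, paste("pairs must contain columns:",
                            paste(.PAIR_COLS, collapse = ", ")))
    else {
        if (anyDuplicated(paste(p$element_id, p$gene_id)))
            msg <- c(msg, "(element_id, gene_id) must be unique within a dataset")
        if (any(p$label == 0 & p$ambiguous == 1))
            msg <- c(msg, "ambiguous pairs must be positive")
        if (any(p$distance < 0, na.rm = TRUE))
            msg <- c(msg, "distances must be non-negative")
    }
    if (length(msg)) msg else TRUE
})

#' Chromosome-based cross-validation assignment
#'
#' Maps each chromosome to one CV group such that every chromosome belongs
#' to exactly one group. Built greedily from per-chromosome pair counts: the
#' chromosome with most pairs forms its own group, then the remaining
#' chromosomes are repeatedly paired largest-with-smallest so the groups end
#' up with similar numbers of pairs.
#'
#' @slot groups named character vector, chromosome -> group label.
#' @slot sizes named numeric vector, group label -> total pair count.
#' @seealso [assignChromCV()], [transferCV()]
#' @export
setClass("CvAssignment",
    representation(groups = "character", sizes = "numeric"))

setValidity("CvAssignment", function(object) {
    msg <- character()
    if (is.null(names(object@groups)) || anyDuplicated(names(object@groups)))
        msg <- c(msg, "groups must be uniquely named by chromosome")
    if (!all(object@groups %in% names(object@sizes)))
        msg <- c(msg, "every group label must appear in sizes")
    if (length(msg)) msg else TRUE
})

#' Element-or-gene by biosample signal panel
#'
#' A rectangular non-negative numeric matrix of signal (or expression)
#' values with row identifiers (elements, sites or genes) and column
#' identifiers (biosamples), plus an optional grouping of columns into
#' cell-type categories used by the group-averaged correlation predictor.
#'
#' @slot values numeric matrix with row and column names.
#' @slot groups character: either length 0 (no grouping) or one group label
#'   per column.
#' @seealso [signalMatrix()]
#' @export
setClass("SignalMatrix",
    representation(values = "matrix", groups = "character"))

setValidity("SignalMatrix", function(object) {
    msg <- character()
    v <- object@values
    if (is.null(rownames(v)) || is.null(colnames(v)))
        msg <- c(msg, "values must have row and column names")
    if (length(object@groups) && length(object@groups) != ncol(v))
        msg <- c(msg, "groups must be empty or have one label per column")
    if (any(!is.finite(v)) || any(v < 0))
        msg <- c(msg, "values must be finite and non-negative")
    if (length(msg)) msg else TRUE
})

#' Precision-recall curve
#'
#' Step-wise precision-recall curve over descending score thresholds, with
#' all tied scores entering the confusion counts at a single threshold, and
#' its area (AUPR) computed by step-wise summation
#' \eqn{\sum_i (R_i - R_{i-1}) P_i}.
#'
#' @slot thresholds distinct scores in decreasing order.
#' @slot precision,recall one value per threshold.
#' @slot aupr area under the curve, in \[0, 1\].
#' @seealso [prCurve()], [aupr()]
#' @export
setClass("PrecisionRecallCurve",
    representation(thresholds = "numeric", precision = "numeric",
                   recall = "numeric", aupr = "numeric"))

setValidity("PrecisionRecallCurve", function(object) {
    msg <- character()
    n <- length(object@thresholds)
    if (length(object@precision) != n || length(object@recall) != n)
        msg <- c(msg, "thresholds, precision and recall must have equal length")
    if (n > 1 && any(diff(object@recall) < 0))
        msg <- c(msg, "recall must be non-decreasing along the curve")
    if (object@aupr < 0 || object@aupr > 1)
        msg <- c(msg, "aupr must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Synthetic benchmark simulation settings
#'
#' Controls the toy genome and evidence generator: chromosome count and
#' length (bp), genes per chromosome and the rate of divergent gene pairs
#' with nearby TSSs (which create ambiguous interaction anchors), elements
#' per chromosome, links emitted per assay, the log-normal positive-pair
#' distance distribution and its truncation, the biosample panel width, the
#' planted element-gene co-activity strength, the log-scale noise level and
#' the master seed.
#'
#' @seealso [simulationConfig()]
#' @export
setClass("SimulationConfig",
    representation(nChrom = "integer", chromLength = "numeric",
                   genesPerChrom = "integer", bidirectionalRate = "numeric",
                   noncodingRate = "numeric", elementsPerChrom = "integer",
                   linksPerAssay = "integer", distMeanLog = "numeric",
                   distSdLog = "numeric", maxDistance = "numeric",
                   panelWidth = "integer", coActivity = "numeric",
                   noise = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    for (s in c("nChrom", "chromLength", "genesPerChrom", "elementsPerChrom",
                "linksPerAssay", "panelWidth"))
        if (slot(object, s) < 1) msg <- c(msg, paste(s, "must be positive"))
    for (s in c("bidirectionalRate", "noncodingRate", "coActivity"))
        if (slot(object, s) < 0 || slot(object, s) > 1)
            msg <- c(msg, paste(s, "must lie in [0, 1]"))
    if (object@noise < 0) msg <- c(msg, "noise must be non-negative")
    if (length(msg)) msg else TRUE
})
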