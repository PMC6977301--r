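# Shared internal helpers: coordinate arithmetic, percentiles, seeding.

# Sentinel score for pairs whose correlation is undefined or whose inputs
# are missing; must rank below every finite score.
.SENTINEL <- -100

#' @noRd
pairKey <- function(element_id, gene_id) paste(element_id, gene_id, sep = "|")

# Gap between a 1-based point and a 1-based closed interval: 0 when the
# point lies in (or is adjacent to) the interval, otherwise the number of
# bases strictly between them. Matches GenomicRanges::distance() and is
# symmetric under coordinate reflection.
#' @noRd
pointIntervalGap <- function(pos, start, end) {
    ifelse(pos < start, start - pos - 1,
    ifelse(pos > end,   pos - end - 1, 0))
}

# Nearest-rank percentile: the ceil(p/100 * n)-th order statistic.
#' @noRd
nearestRankPercentile <- function(x, p) {
    if (length(x) == 0L)
        stop("cannot take a percentile of an empty vector")
    stopifnot(p > 0, p <= 100)
    xs <- sort(x)
    xs[max(1L, as.integer(ceiling(p / 100 * length(xs))))]
}

#' Normalise chromosome naming convention
#'
#' Rewrites chromosome names to a single convention, either UCSC-style
#' (`"chr1"`) or bare (`"1"`). Applied at parse time to all assay dialects
#' because public interaction files mix the two conventions.
#'
#' @param x character vector of chromosome names.
#' @param style `"chr"` to enforce the `chr` prefix, `"plain"` to strip it.
#' @return character vector of rewritten names.
#' @examples
#' normalizeChromNames(c("1", "chrX"), "chr")
#' @export
normalizeChromNames <- function(x, style = c("chr", "plain")) {
    style <- match.arg(style)
    bare <- sub("^chr", "", as.character(x))
    if (style == "chr") paste0("chr", bare) else bare
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All randomised operations in the package flow through this.
#' @noRd
withSeed <- function(seed, code) {
    withr::with_seed(as.integer(seed), code)
}

# data.table of TSS positions: gene_id, gene_type, chrom, pos (1-based).
#' @noRd
tssTable <- function(tss) {
    data.table(gene_id = mcols(tss)$gene_id,
               gene_type = mcols(tss)$gene_type,
               chrom = as.character(seqnames(tss)),
               pos = start(tss))
}

# data.table of element intervals: element_id, chrom, start, end (1-based
# closed).
#' @noRd
elementTable <- function(elements) {
    data.table(element_id = mcols(elements)$element_id,
               chrom = as.character(seqnames(elements)),
               start = start(elements), end = end(elements))
}

# Per-pair distance between the element interval and the nearest TSS of the
# paired gene. `pairs` needs element_id and gene_id columns; returns the
# distances in the order of `pairs` (Inf when the gene has no TSS on the
# element's chromosome).
#' @noRd
pairGeneDistances <- function(pairs, elements, tss) {
    if (nrow(pairs) == 0L) return(numeric())
    et <- elementTable(elements)
    tt <- tssTable(tss)
    dt <- data.table(element_id = pairs$element_id, gene_id = pairs$gene_id,
                     .row = seq_len(nrow(pairs)))
    dt <- merge(dt, et, by = "element_id", sort = FALSE)
    hits <- merge(dt, tt, by = "gene_id", sort = FALSE,
                  allow.cartesian = TRUE, suffixes = c("", ".tss"))
    hits <- hits[hits$chrom == hits$chrom.tss, ]
    d <- rep(Inf, nrow(pairs))
    if (nrow(hits)) {
        hits[, `:=`(gap = pointIntervalGap(pos, start, end))]
        mins <- hits[, list(gap = min(gap)), by = ".row"]
        d[mins$.row] <- mins$gap
    }
    d
}

# Canonical ordering of a pair table: deterministic output files and
# reproducible sampling depend on it.
#' @noRd
orderPairs <- function(pairs) {
    pairs[order(pairs$element_id, pairs$gene_id, method = "radix"), ,
          drop = FALSE]
}

#' @noRd
emptyPairFrame <- function() {
    data.frame(element_id = character(), chrom = character(),
               start = integer(), end = integer(), gene_id = character(),
               label = integer(), ambiguous = integer(),
               distance = numeric(), cv_group = character(),
               stringsAsFactors = FALSE)
}
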