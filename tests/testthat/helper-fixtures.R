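# Small fixture builders used across the suites. All coordinates in these
# helpers are 0-based half-open, converted at the constructor boundary.

toyTss <- function(chrom, pos, gene_id, strand = "+",
                   gene_type = "protein_coding") {
    n <- length(gene_id)
    tssIndexFromTable(data.frame(chrom = rep_len(chrom, n), pos = pos,
                                 strand = rep_len(strand, n),
                                 gene_id = gene_id,
                                 gene_type = rep_len(gene_type, n)))
}

toyElements <- function(chrom, start, end, element_id) {
    gr <- GRanges(chrom, IRanges(start + 1L, end))
    mcols(gr)$element_id <- element_id
    gr
}

toyLinks <- function(df, support = rep(1, nrow(df)), assay = "hic") {
    new("ChromatinLinks",
        anchor1 = GRanges(df$chromA, IRanges(df$startA + 1L, df$endA)),
        anchor2 = GRanges(df$chromB, IRanges(df$startB + 1L, df$endB)),
        support = as.numeric(support), assay = assay)
}

# random interval/TSS layouts for oracle comparisons
randomLayout <- function(seed, nTss = 40, nEl = 15, nChrom = 2,
                         span = 200000) {
    withr::with_seed(seed, {
        chroms <- paste0("chr", seq_len(nChrom))
        tssDf <- data.frame(
            chrom = sample(chroms, nTss, replace = TRUE),
            pos = sample.int(span, nTss),
            gene_id = sprintf("G%03d", seq_len(nTss)))
        s <- sample.int(span - 500, nEl)
        elDf <- data.frame(
            chrom = sample(chroms, nEl, replace = TRUE),
            start = s, end = s + sample(100:400, nEl, replace = TRUE),
            element_id = sprintf("E%03d", seq_len(nEl)))
        list(tssDf = tssDf, elDf = elDf)
    })
}

layoutToObjects <- function(layout) {
    list(tss = toyTss(layout$tssDf$chrom, layout$tssDf$pos,
                      layout$tssDf$gene_id),
         elements = toyElements(layout$elDf$chrom, layout$elDf$start,
                                layout$elDf$end, layout$elDf$element_id))
}

# wrap a hand-built pair frame into a BenchmarkDataset
toyDataset <- function(pairs, cutoff = Inf, assay = "chiapet",
                       policy = curationPolicy()) {
    defaults <- list(chrom = "chr1", start = 0L, end = 200L,
                     ambiguous = 0L, distance = 1000,
                     cv_group = NA_character_)
    for (nm in names(defaults))
        if (is.null(pairs[[nm]])) pairs[[nm]] <- defaults[[nm]]
    pairs <- pairs[, c("element_id", "chrom", "start", "end", "gene_id",
                       "label", "ambiguous", "distance", "cv_group")]
    new("BenchmarkDataset", datasetId = "toy", assay = assay,
        biosample = "toy", variant = "all_natural", pairs = pairs,
        cutoff = as.numeric(cutoff), policy = policy)
}
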