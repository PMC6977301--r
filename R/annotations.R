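# Gene annotation and candidate-element input: GTF transcript parsing into a
# TSS index, BED element reading, distance queries and distal selection.

.gtfAttr <- function(attrs, key) {
    # Tolerates both `key "value";` (GTF) and `key=value` (GFF-ish exports).
    pat <- paste0("(^|;)\\s*", key, "[ =]+\"?([^\";]+)\"?")
    m <- regexpr(pat, attrs, perl = TRUE)
    out <- rep(NA_character_, length(attrs))
    ok <- m != -1L
    if (any(ok)) {
        frag <- regmatches(attrs, m)
        out[ok] <- sub(pat, "\\2", frag, perl = TRUE)
    }
    out
}

#' Build a TSS index from a table of start sites
#'
#' @param table data.frame with columns `chrom`, `pos` (0-based base-pair
#'   position of the start site), `strand` (`"+"`/`"-"`), `gene_id` and
#'   optionally `gene_type` (defaults to `"protein_coding"`).
#' @return a [TssIndex-class]; duplicate (gene, position, strand) rows are
#'   collapsed.
#' @examples
#' tssIndexFromTable(data.frame(chrom = "chr1", pos = 100,
#'                              strand = "+", gene_id = "G1"))
#' @export
tssIndexFromTable <- function(table) {
    stopifnot(all(c("chrom", "pos", "strand", "gene_id") %in% names(table)))
    if (is.null(table$gene_type)) table$gene_type <- "protein_coding"
    dt <- unique(data.table(chrom = as.character(table$chrom),
                            pos = as.integer(table$pos),
                            strand = as.character(table$strand),
                            gene_id = as.character(table$gene_id),
                            gene_type = as.character(table$gene_type)))
    setorder(dt, chrom, pos, gene_id)
    gr <- GRanges(dt$chrom, IRanges(dt$pos + 1L, width = 1L),
                  strand = dt$strand)
    mcols(gr)$gene_id <- dt$gene_id
    mcols(gr)$gene_type <- dt$gene_type
    new("TssIndex", gr)
}

#' Load transcription start sites from a GTF annotation
#'
#' Reads `transcript` records and derives one TSS per transcript: the
#' transcript start for plus-strand records and the transcript end for
#' minus-strand records (the 5' end of transcription in both cases).
#' Identical (gene, position, strand) sites arising from transcripts that
#' share a start are collapsed. Attribute strings may use either the
#' `key "value";` or the `key=value` dialect; `gene_type` and
#' `gene_biotype` are both recognised as the biotype key.
#'
#' @param file path to a GTF file (1-based inclusive coordinates, as usual).
#' @param proteinCodingOnly keep only records with biotype
#'   `"protein_coding"`.
#' @param exclude character vector of gene identifiers to drop, e.g. known
#'   problematic annotations.
#' @return a [TssIndex-class].
#' @seealso [tssIndexFromTable()], [exportTssBed()]
#' @export
readTss <- function(file, proteinCodingOnly = FALSE, exclude = character()) {
    lines <- readLines(file)
    keep <- !startsWith(lines, "#") & nzchar(lines)
    lineno <- which(keep)
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 9L))
        stop("line ", lineno[which(nf < 9L)[1L]],
             ": expected 9 tab-separated GTF fields")
    feat <- vapply(fields, `[[`, character(1), 3L)
    sel <- feat == "transcript"
    if (!any(sel))
        stop("no transcript records found in ", file)
    fields <- fields[sel]
    lineno <- lineno[sel]
    chrom <- vapply(fields, `[[`, character(1), 1L)
    startc <- as.integer(vapply(fields, `[[`, character(1), 4L))
    endc <- as.integer(vapply(fields, `[[`, character(1), 5L))
    strand <- vapply(fields, `[[`, character(1), 7L)
    attrs <- vapply(fields, `[[`, character(1), 9L)
    bad <- !strand %in% c("+", "-")
    if (any(bad))
        stop("line ", lineno[which(bad)[1L]], ": missing or invalid strand")
    gene_id <- .gtfAttr(attrs, "gene_id")
    if (anyNA(gene_id))
        stop("line ", lineno[which(is.na(gene_id))[1L]],
             ": missing gene_id attribute")
    gene_type <- .gtfAttr(attrs, "gene_type")
    alt <- is.na(gene_type)
    if (any(alt)) gene_type[alt] <- .gtfAttr(attrs[alt], "gene_biotype")
    gene_type[is.na(gene_type)] <- "unknown"
    # 5' end: GTF is 1-based inclusive, so 0-based TSS = start-1 (+) / end-1 (-)
    pos0 <- ifelse(strand == "+", startc - 1L, endc - 1L)
    tab <- data.frame(chrom = chrom, pos = pos0, strand = strand,
                      gene_id = gene_id, gene_type = gene_type)
    if (length(exclude)) tab <- tab[!tab$gene_id %in% exclude, , drop = FALSE]
    if (proteinCodingOnly)
        tab <- tab[tab$gene_type == "protein_coding", , drop = FALSE]
    tssIndexFromTable(tab)
}

#' Read candidate regulatory elements from BED4+
#'
#' Columns: chromosome, 0-based start, end (exclusive), element identifier;
#' any further columns are ignored.
#'
#' @param file path to a BED file with at least 4 columns.
#' @return [GenomicRanges::GRanges] with an `element_id` metadata column.
#' @export
readElements <- function(file) {
    dt <- fread(file, header = FALSE, sep = "\t", fill = TRUE)
    if (ncol(dt) < 4L)
        stop("element BED must have at least 4 columns (chrom, start, end, id)")
    if (any(dt[[3L]] <= dt[[2L]]))
        stop("element intervals must satisfy end > start")
    if (anyDuplicated(dt[[4L]]))
        stop("element identifiers must be unique")
    gr <- GRanges(as.character(dt[[1L]]),
                  IRanges(as.integer(dt[[2L]]) + 1L, as.integer(dt[[3L]])))
    mcols(gr)$element_id <- as.character(dt[[4L]])
    gr
}

#' Export a TSS index as BED6
#'
#' One line per TSS: chrom, 0-based position, position + 1, gene_id, score 0
#' and strand.
#'
#' @param tss a [TssIndex-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
exportTssBed <- function(tss, file) {
    dt <- data.table(chrom = as.character(seqnames(tss)),
                     start = start(tss) - 1L, end = start(tss),
                     name = mcols(tss)$gene_id, score = 0L,
                     strand = as.character(GenomicRanges::strand(tss)))
    fwrite(dt, file, sep = "\t", col.names = FALSE, eol = "\n")
    invisible(file)
}

#' Distance from intervals to their nearest TSS
#'
#' For each query interval, finds the closest transcription start site and
#' the gap to it: 0 when a TSS lies within (or immediately adjacent to) the
#' interval, otherwise the number of bases between the TSS and the nearest
#' interval edge. With `genes`, the search is restricted to the TSSs of
#' those genes (recycled along queries).
#'
#' @param query [GenomicRanges::GRanges] of intervals.
#' @param tss a [TssIndex-class].
#' @param genes optional character vector of gene identifiers (length 1 or
#'   `length(query)`) restricting the TSS set per query.
#' @return data.frame with columns `gene_id` (nearest gene, ties broken by
#'   lexicographic identifier) and `distance`; both `NA` when no eligible
#'   TSS exists on the query's chromosome.
#' @export
nearestTssDistance <- function(query, tss, genes = NULL) {
    if (length(tss) == 0L) stop("TSS index is empty")
    qt <- data.table(chrom = as.character(seqnames(query)),
                     start = start(query), end = end(query),
                     .row = seq_along(query))
    tt <- tssTable(tss)
    if (!is.null(genes)) {
        genes <- rep_len(as.character(genes), nrow(qt))
        qt$gene_id <- genes
        hits <- merge(qt, tt, by = c("chrom", "gene_id"), sort = FALSE,
                      allow.cartesian = TRUE)
    } else {
        hits <- merge(qt, tt, by = "chrom", sort = FALSE,
                      allow.cartesian = TRUE)
    }
    out <- data.frame(gene_id = rep(NA_character_, nrow(qt)),
                      distance = rep(NA_real_, nrow(qt)))
    if (nrow(hits)) {
        hits[, `:=`(gap = pointIntervalGap(pos, start, end))]
        setorder(hits, .row, gap, gene_id)
        best <- hits[!duplicated(hits$.row), ]
        out$gene_id[best$.row] <- best$gene_id
        out$distance[best$.row] <- best$gap
    }
    out
}

#' Select distal regulatory elements
#'
#' Retains elements strictly further than `minDistance` from every TSS in
#' the index (an element exactly at the cutoff is dropped). Elements on
#' chromosomes without any TSS are retained: nothing annotated lies near
#' them.
#'
#' @param elements [GenomicRanges::GRanges] with `element_id`.
#' @param tss a [TssIndex-class]; an empty index is an error because
#'   distality is undefined.
#' @param minDistance bp; default 2000.
#' @return the retained subset of `elements`. Idempotent.
#' @export
selectDistalElements <- function(elements, tss, minDistance = 2000) {
    if (length(tss) == 0L)
        stop("cannot select distal elements against an empty TSS index")
    if (length(elements) == 0L) return(elements)
    nd <- nearestTssDistance(elements, tss)
    elements[is.na(nd$distance) | nd$distance > minDistance]
}
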