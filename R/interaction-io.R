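# Assay evidence parsers: ChIA-PET clusters, Hi-C loop lists, capture Hi-C
# interaction tables, eQTL exports and CRISPR perturbation tables, each
# normalised into a common record shape at parse time.

.makeLinks <- function(chrom1, s1, e1, chrom2, s2, e2, support, assay,
                       chromStyle) {
    chrom1 <- normalizeChromNames(chrom1, chromStyle)
    chrom2 <- normalizeChromNames(chrom2, chromStyle)
    cis <- chrom1 == chrom2
    if (any(!cis))
        message(sum(!cis), " trans-chromosomal link(s) dropped")
    a1 <- GRanges(chrom1[cis], IRanges(as.integer(s1[cis]) + 1L,
                                       as.integer(e1[cis])))
    a2 <- GRanges(chrom2[cis], IRanges(as.integer(s2[cis]) + 1L,
                                       as.integer(e2[cis])))
    new("ChromatinLinks", anchor1 = a1, anchor2 = a2,
        support = as.numeric(support[cis]), assay = assay)
}

#' @describeIn ChromatinLinks-class number of links.
#' @param x,object a `ChromatinLinks`.
#' @export
setMethod("length", "ChromatinLinks", function(x) length(x@anchor1))

#' @describeIn ChromatinLinks-class anchor accessors and support.
#' @export
anchorOne <- function(x) x@anchor1

#' @rdname anchorOne
#' @export
anchorTwo <- function(x) x@anchor2

#' @rdname anchorOne
#' @export
linkSupport <- function(x) x@support

#' @rdname anchorOne
#' @export
linkAssay <- function(x) x@assay

setMethod("show", "ChromatinLinks", function(object) {
    cat("ChromatinLinks:", length(object), object@assay, "link(s)\n")
})

#' Read ChIA-PET interaction clusters
#'
#' Tab-separated, no header: the two anchors in columns 1-6 (chrom, 0-based
#' start, end, twice) and the supporting read count in column 7. Clusters
#' supported by fewer than `minReads` reads are discarded;
#' trans-chromosomal clusters are dropped with a message.
#'
#' @param file path to the cluster table.
#' @param minReads minimum read support (column 7); default 4, i.e. records
#'   with column 7 >= 4 are retained.
#' @param chromStyle chromosome naming convention to normalise to.
#' @return a [ChromatinLinks-class] with `assay = "chiapet"`.
#' @export
readChiaPet <- function(file, minReads = 4, chromStyle = "chr") {
    dt <- fread(file, header = FALSE, sep = "\t")
    if (ncol(dt) < 7L)
        stop("ChIA-PET cluster table needs at least 7 columns")
    cnt <- suppressWarnings(as.numeric(dt[[7L]]))
    if (anyNA(cnt))
        stop("line ", which(is.na(cnt))[1L],
             ": non-numeric read count in column 7")
    keep <- cnt >= minReads
    dt <- dt[keep]
    .makeLinks(dt[[1L]], dt[[2L]], dt[[3L]], dt[[4L]], dt[[5L]], dt[[6L]],
               cnt[keep], "chiapet", chromStyle)
}

#' Read a Hi-C loop list
#'
#' Header line followed by one loop per row with the two anchors in the
#' first six data columns (chrom, 0-based start, end, twice). Loop callers
#' commonly omit the `chr` prefix; names are normalised to `chromStyle`.
#' No score filtering is applied: every well-formed row becomes a link with
#' support 1.
#'
#' @inheritParams readChiaPet
#' @return a [ChromatinLinks-class] with `assay = "hic"`.
#' @export
readHiccups <- function(file, chromStyle = "chr") {
    dt <- fread(file, header = TRUE, sep = "\t")
    if (ncol(dt) < 6L)
        stop("loop list needs at least 6 columns")
    s1 <- as.integer(dt[[2L]]); e1 <- as.integer(dt[[3L]])
    s2 <- as.integer(dt[[5L]]); e2 <- as.integer(dt[[6L]])
    bad <- e1 <= s1 | e2 <= s2
    if (any(bad))
        stop("line ", which(bad)[1L] + 1L,
             ": anchor with end <= start")
    .makeLinks(dt[[1L]], s1, e1, dt[[4L]], s2, e2,
               rep(1, nrow(dt)), "hic", chromStyle)
}

#' Read capture Hi-C significant interactions
#'
#' Header line followed by one interaction per row: anchors in columns 1-3
#' and 4-6 (chrom, 0-based start, end) and the log(observed/expected)
#' statistic in column 11. Interactions with a statistic strictly greater
#' than `minLogRatio` are retained (a value exactly at the threshold is
#' dropped).
#'
#' @inheritParams readChiaPet
#' @param minLogRatio retention threshold on column 11; default 10.
#' @return a [ChromatinLinks-class] with `assay = "chic"`.
#' @export
readChic <- function(file, minLogRatio = 10, chromStyle = "chr") {
    dt <- fread(file, header = TRUE, sep = "\t")
    if (ncol(dt) < 11L)
        stop("capture Hi-C table is missing column 11 (log observed/expected)")
    score <- suppressWarnings(as.numeric(dt[[11L]]))
    if (anyNA(score))
        stop("line ", which(is.na(score))[1L] + 1L,
             ": non-numeric score in column 11")
    keep <- score > minLogRatio
    dt <- dt[keep]
    .makeLinks(dt[[1L]], dt[[2L]], dt[[3L]], dt[[4L]], dt[[5L]], dt[[6L]],
               score[keep], "chic", chromStyle)
}

#' Describe an eQTL export layout
#'
#' Column layouts of public eQTL releases vary; a dialect names the columns
#' carrying the variant position and the gene identifier. Two presets are
#' built in: `"geuvadis"` (columns `CHR_SNP`, `SNPpos`, `GENE_ID`) and
#' `"gtex"` (a `variant_id` of the form `chrom_pos_ref_alt_build` plus
#' `gene_id`).
#'
#' @param chromCol,posCol column names for the variant chromosome and
#'   1-based position (ignored when `variantCol` is given).
#' @param geneCol column name of the gene identifier.
#' @param variantCol optional column holding an underscore-delimited
#'   variant identifier from which chromosome and position are parsed.
#' @return a list usable as the `dialect` argument of [readEqtl()].
#' @export
eqtlDialect <- function(chromCol = NULL, posCol = NULL, geneCol,
                        variantCol = NULL) {
    if (is.null(variantCol) && (is.null(chromCol) || is.null(posCol)))
        stop("either variantCol or both chromCol and posCol are required")
    structure(list(chromCol = chromCol, posCol = posCol, geneCol = geneCol,
                   variantCol = variantCol), class = "eqtlDialect")
}

.EQTL_DIALECTS <- list(
    geuvadis = function() eqtlDialect(chromCol = "CHR_SNP", posCol = "SNPpos",
                                      geneCol = "GENE_ID"),
    gtex = function() eqtlDialect(variantCol = "variant_id",
                                  geneCol = "gene_id"))

#' Read variant-gene associations from an eQTL export
#'
#' Parses one association per row under the selected dialect, normalises
#' gene identifiers by stripping a trailing version suffix
#' (`ENSG...123.4` -> `ENSG...123`), normalises chromosome names and
#' deduplicates identical (variant, gene) rows. Rows whose variant
#' coordinate cannot be parsed are skipped; the skipped count is attached
#' as attribute `"skipped"` and reported as a warning.
#'
#' @param file path to the tab-separated export (header required).
#' @param dialect `"geuvadis"`, `"gtex"`, or an [eqtlDialect()] object.
#' @param chromStyle chromosome naming convention to normalise to.
#' @return data.frame with columns `chrom`, `pos` (0-based variant
#'   position) and `gene_id`.
#' @export
readEqtl <- function(file, dialect = c("geuvadis", "gtex"),
                     chromStyle = "chr") {
    if (is.character(dialect))
        dialect <- .EQTL_DIALECTS[[match.arg(dialect)]]()
    stopifnot(inherits(dialect, "eqtlDialect"))
    dt <- fread(file, header = TRUE, sep = "\t")
    if (!is.null(dialect$variantCol)) {
        vid <- as.character(dt[[dialect$variantCol]])
        parts <- strsplit(vid, "_", fixed = TRUE)
        chrom <- vapply(parts, function(p) if (length(p) >= 2) p[[1L]] else NA_character_,
                        character(1))
        pos1 <- suppressWarnings(as.integer(vapply(parts,
                  function(p) if (length(p) >= 2) p[[2L]] else NA_character_,
                  character(1))))
    } else {
        chrom <- as.character(dt[[dialect$chromCol]])
        pos1 <- suppressWarnings(as.integer(dt[[dialect$posCol]]))
    }
    gene <- sub("\\.\\d+$", "", as.character(dt[[dialect$geneCol]]))
    ok <- !is.na(pos1) & !is.na(chrom) & nzchar(chrom) & pos1 >= 1L
    skipped <- sum(!ok)
    if (skipped > 0)
        warning(skipped, " eQTL record(s) with unmappable variant ",
                "coordinates skipped")
    out <- unique(data.table(chrom = normalizeChromNames(chrom[ok], chromStyle),
                             pos = pos1[ok] - 1L, gene_id = gene[ok]))
    setorder(out, chrom, pos, gene_id)
    out <- as.data.frame(out)
    attr(out, "skipped") <- skipped
    out
}

#' Read CRISPR perturbation region-gene links
#'
#' Header line followed by one tested region per row: chromosome, 0-based
#' start, end, and the target gene symbol in the first four columns.
#' Symbols are mapped to annotation gene identifiers through `geneMap`;
#' rows with unmapped symbols yield no link and are counted in the
#' `"unmapped"` attribute.
#'
#' @param file path to the perturbation table.
#' @param geneMap named character vector, gene symbol -> gene identifier.
#' @param chromStyle chromosome naming convention to normalise to.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `gene_id`.
#' @export
readCrisprQtl <- function(file, geneMap, chromStyle = "chr") {
    dt <- fread(file, header = TRUE, sep = "\t")
    if (ncol(dt) < 4L)
        stop("perturbation table needs at least 4 columns")
    sym <- as.character(dt[[4L]])
    mapped <- sym %in% names(geneMap)
    if (any(!mapped))
        message(sum(!mapped), " perturbation record(s) with unmapped gene ",
                "symbols dropped")
    out <- unique(data.table(
        chrom = normalizeChromNames(dt[[1L]][mapped], chromStyle),
        start = as.integer(dt[[2L]][mapped]),
        end = as.integer(dt[[3L]][mapped]),
        gene_id = unname(geneMap[sym[mapped]])))
    if (any(out$end <= out$start))
        stop("perturbed regions must satisfy end > start")
    setorder(out, chrom, start, gene_id)
    out <- as.data.frame(out)
    attr(out, "unmapped") <- sum(!mapped)
    out
}

#' Write normalised links as TSV
#'
#' One row per link: chromA, startA, endA, chromB, startB, endB (0-based
#' half-open), support, assay.
#'
#' @param links a [ChromatinLinks-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeLinks <- function(links, file) {
    dt <- data.table(chromA = as.character(seqnames(links@anchor1)),
                     startA = start(links@anchor1) - 1L,
                     endA = end(links@anchor1),
                     chromB = as.character(seqnames(links@anchor2)),
                     startB = start(links@anchor2) - 1L,
                     endB = end(links@anchor2),
                     support = links@support, assay = links@assay)
    fwrite(dt, file, sep = "\t", eol = "\n")
    invisible(file)
}
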