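#' Read a BED / narrowPeak file into a GRanges
#'
#' Parses BED3, BED6 or ENCODE narrowPeak. Coordinates on disk are 0-based
#' half-open and are converted to the 1-based closed convention of
#' [GenomicRanges::GRanges] on the way in; `writeBed()` reverses the
#' conversion, so a write/read round trip is exact. `track`, `browser` and
#' `#` comment lines are skipped. For narrowPeak input (10 columns) the
#' summit offset in column 10 is stored as an absolute 1-based `summit`
#' position in the metadata columns (`NA` when the offset is -1).
#'
#' @param path path to a tab-separated BED-family file.
#' @return a `GRanges`; extra columns become metadata columns
#'   (`name`, `score`, `signalValue`, `pValue`, `qValue`, `summit`).
#' @examples
#' tf <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t10\t20", "chr1\t30\t40\tpk1\t5\t+"), tf)
#' readBed(tf)
#' @export
readBed <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    raw <- readLines(path)
    keep <- !grepl("^(track|browser|#)", raw) & nzchar(trimws(raw))
    lineNo <- which(keep)
    raw <- raw[keep]
    if (length(raw) == 0L)
        return(GenomicRanges::GRanges())
    fields <- strsplit(raw, "\t", fixed = TRUE)
    ncols <- lengths(fields)
    if (any(ncols < 3L))
        stop("line ", lineNo[which(ncols < 3L)[1L]],
             ": fewer than 3 tab-separated columns")
    nc <- min(ncols)
    getCol <- function(i) vapply(fields, `[[`, character(1), i)
    chrom <- getCol(1)
    start0 <- suppressWarnings(as.numeric(getCol(2)))
    end0 <- suppressWarnings(as.numeric(getCol(3)))
    bad <- which(is.na(start0) | is.na(end0) |
                 start0 != floor(start0) | end0 != floor(end0))
    if (length(bad))
        stop("line ", lineNo[bad[1L]], ": non-integer coordinates")
    bad <- which(start0 >= end0 | start0 < 0)
    if (length(bad))
        stop("line ", lineNo[bad[1L]],
             ": invalid interval (need 0 <= start < end)")
    strand <- if (nc >= 6L) {
        s <- getCol(6)
        s[!s %in% c("+", "-")] <- "*"
        s
    } else "*"
    gr <- GenomicRanges::GRanges(
        seqnames = chrom,
        ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
        strand = strand)
    if (nc >= 4L) gr$name <- getCol(4)
    if (nc >= 5L) gr$score <- suppressWarnings(as.numeric(getCol(5)))
    if (nc >= 10L) {
        gr$signalValue <- suppressWarnings(as.numeric(getCol(7)))
        gr$pValue <- suppressWarnings(as.numeric(getCol(8)))
        gr$qValue <- suppressWarnings(as.numeric(getCol(9)))
        off <- suppressWarnings(as.numeric(getCol(10)))
        gr$summit <- ifelse(off < 0, NA_real_, start0 + off + 1L)
    }
    gr
}

#' Write a GRanges as BED
#'
#' Inverse of [readBed()]: 1-based closed ranges go out as 0-based
#' half-open lines. Metadata columns `name` and `score` are emitted when
#' present (BED6 with strand); otherwise BED3.
#'
#' @param gr a `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path) {
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(gr)),
        start = GenomicRanges::start(gr) - 1L,
        end = GenomicRanges::end(gr),
        stringsAsFactors = FALSE)
    if (!is.null(gr$name) || !is.null(gr$score)) {
        df$name <- if (is.null(gr$name)) "." else gr$name
        df$score <- if (is.null(gr$score)) 0 else gr$score
        s <- as.character(GenomicRanges::strand(gr))
        s[s == "*"] <- "."
        df$strand <- s
    }
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a gene-model table
#'
#' Expects a header line with columns `gene_id`, `chrom`, `strand`,
#' `start`, `end` and optionally `symbol`. Coordinates follow the BED
#' convention (0-based half-open) and are converted to 1-based closed.
#' Every gene must be stranded; the strand determines the TSS
#' (see [geneTss()]).
#'
#' @param path path to the TSV.
#' @return a `GRanges` with metadata columns `gene_id` and `symbol`.
#' @export
readGeneTable <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "strand", "start", "end")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("gene table missing column(s): ", paste(miss, collapse = ", "))
    makeGeneModels(gene_id = df$gene_id, chrom = df$chrom,
                   strand = df$strand, start = df$start, end = df$end,
                   symbol = if ("symbol" %in% names(df)) df$symbol else NULL)
}

#' Construct gene models from BED-convention coordinates
#'
#' @param gene_id gene identifiers (unique).
#' @param chrom chromosome names.
#' @param strand `"+"` or `"-"` (mandatory; the TSS is strand-dependent).
#' @param start,end 0-based half-open gene span.
#' @param symbol optional gene symbols.
#' @return a `GRanges` with `gene_id` and `symbol` metadata columns.
#' @export
makeGeneModels <- function(gene_id, chrom, strand, start, end,
                           symbol = NULL) {
    if (anyDuplicated(gene_id))
        stop("gene ids must be unique")
    if (!all(strand %in% c("+", "-")))
        stop("gene strand must be '+' or '-'")
    if (any(end - start < 1))
        stop("gene length must be >= 1")
    gr <- GenomicRanges::GRanges(
        seqnames = chrom,
        ranges = IRanges::IRanges(start = start + 1L, end = end),
        strand = strand)
    gr$gene_id <- as.character(gene_id)
    gr$symbol <- if (is.null(symbol)) as.character(gene_id)
                 else as.character(symbol)
    names(gr) <- gr$gene_id
    gr
}

#' Write gene models back to the gene-table TSV dialect
#' @param genes a `GRanges` from [makeGeneModels()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneTable <- function(genes, path) {
    df <- data.frame(
        gene_id = genes$gene_id,
        symbol = genes$symbol,
        chrom = as.character(GenomicRanges::seqnames(genes)),
        strand = as.character(GenomicRanges::strand(genes)),
        start = GenomicRanges::start(genes) - 1L,
        end = GenomicRanges::end(genes),
        stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Strand-aware transcription start sites
#'
#' The TSS of a plus-strand gene is its first base; the TSS of a
#' minus-strand gene is its last base.
#'
#' @param genes stranded gene-model `GRanges`.
#' @return integer vector of 1-based TSS positions, named by gene id.
#' @export
geneTss <- function(genes) {
    s <- as.character(GenomicRanges::strand(genes))
    if (any(s == "*"))
        stop("all genes must be stranded to define a TSS")
    tss <- ifelse(s == "+", GenomicRanges::start(genes),
                  GenomicRanges::end(genes))
    names(tss) <- genes$gene_id
    tss
}

#' Merge intervals into a disjoint set
#'
#' Union of the input base set: overlapping and abutting intervals are
#' merged, output sorted by (chromosome, start). Used to collapse
#' strong-enhancer segments pooled across cell lines into one set of
#' putative enhancer regions.
#'
#' @param gr a `GRanges` (strand ignored).
#' @return a disjoint, sorted `GRanges` covering the same bases.
#' @export
mergeIntervals <- function(gr) {
    GenomicRanges::reduce(gr, ignore.strand = TRUE)
}

#' Drop peaks overlapping blacklist regions
#'
#' A peak is removed when it shares at least one base with any blacklist
#' interval (e.g. ENCODE regions with anomalous signal). Order of the
#' retained peaks is preserved.
#'
#' @param peaks a `GRanges` of peaks.
#' @param blacklist a `GRanges` of regions to exclude.
#' @return the retained peaks.
#' @export
removeBlacklisted <- function(peaks, blacklist) {
    if (length(blacklist) == 0L || length(peaks) == 0L)
        return(peaks)
    hit <- IRanges::overlapsAny(peaks, blacklist, ignore.strand = TRUE)
    peaks[!hit]
}

#' Does a query interval overlap any region?
#'
#' @param query a `GRanges` (one or more query intervals).
#' @param regions a `GRanges` of regions (may be unmerged).
#' @return logical vector, `TRUE` where the query shares >= 1 base with
#'   at least one region.
#' @export
overlapsAnyRegion <- function(query, regions) {
    if (length(regions) == 0L)
        return(rep(FALSE, length(query)))
    IRanges::overlapsAny(query, regions, ignore.strand = TRUE)
}

#' Write peaks as ENCODE narrowPeak
#'
#' Ten-column BED6+4; the `summit` metadata column (absolute 1-based
#' position) is emitted as the 0-based offset of column 10, or -1 when
#' missing, so [readBed()] round-trips summits exactly.
#'
#' @param peaks a `GRanges`, optionally with `score` and `summit`
#'   metadata columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeNarrowPeak <- function(peaks, path) {
    start0 <- GenomicRanges::start(peaks) - 1L
    summit <- if (is.null(peaks$summit)) rep(NA_real_, length(peaks))
              else peaks$summit
    off <- ifelse(is.na(summit), -1L, summit - 1L - start0)
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(peaks)),
        start = start0,
        end = GenomicRanges::end(peaks),
        name = if (is.null(peaks$name)) paste0("peak_", seq_along(peaks))
               else peaks$name,
        score = if (is.null(peaks$score)) 0 else peaks$score,
        strand = ".",
        signalValue = if (is.null(peaks$signalValue)) 0
                      else peaks$signalValue,
        pValue = -1, qValue = -1, peak = off,
        stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read promoter (or genome) sequences from FASTA
#' @param path FASTA path.
#' @return a [Biostrings::DNAStringSet] named by record id.
#' @export
readPromoterFasta <- function(path) {
    Biostrings::readDNAStringSet(path)
}

#' Write sequences to FASTA
#' @param seqs a named `DNAStringSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePromoterFasta <- function(seqs, path) {
    Biostrings::writeXStringSet(seqs, path)
    invisible(path)
}
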