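#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: with p-values sorted ascending,
#' `q_(i) = min_(j >= i) m * p_(j) / j`, capped at 1 and returned in the
#' original order. Delegates to [stats::p.adjust()] with `method = "BH"`
#' after validating the input range.
#'
#' @param p numeric p-values in \[0, 1\] (no `NA`).
#' @return adjusted p-values, same length and order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhAdjust <- function(p) {
    if (length(p) == 0L) return(numeric())
    if (anyNA(p) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    p.adjust(p, method = "BH")
}

#' Differential-transcription selection thresholds
#'
#' Defaults follow the nascent-RNA knockdown screen: genes must have mean
#' RPKM above 0.25 across samples, length of at least 300 bases, absolute
#' log2 fold change above 0.58 (1.5-fold), and FDR-adjusted p below 0.1.
#' Thresholds are applied strictly (`>`, `<`), so boundary values fail;
#' the length bound is inclusive (`>=` 300).
#'
#' @param rpkmMin,lengthMin,lfcMin,padjMax the four thresholds.
#' @return a named list of class `"DESelectionConfig"`.
#' @export
deSelectionConfig <- function(rpkmMin = 0.25, lengthMin = 300,
                              lfcMin = 0.58, padjMax = 0.1) {
    stopifnot(rpkmMin > 0, lengthMin > 0, lfcMin > 0, padjMax > 0)
    structure(list(rpkmMin = rpkmMin, lengthMin = lengthMin,
                   lfcMin = lfcMin, padjMax = padjMax),
              class = "DESelectionConfig")
}

#' Select differentially transcribed genes for one contrast
#'
#' Applies the four filters of [deSelectionConfig()] to the per-gene
#' statistics of a single (cell line, shRNA) knockdown contrast. A gene
#' with a missing adjusted p-value fails (it cannot clear the FDR filter);
#' this is reported in the returned table, not an error.
#'
#' @param stats data.frame with columns `gene_id`, `cell_line`, `shRNA`,
#'   `log2fc`, `padj`, `mean_rpkm`, `gene_length` for one contrast.
#' @param cfg a [deSelectionConfig()].
#' @return data.frame: `gene_id`, `cell_line`, `shRNA`, `pass` (logical),
#'   `direction` (sign of log2fc: -1, 0 or 1).
#' @export
selectDeContrast <- function(stats, cfg = deSelectionConfig()) {
    need <- c("gene_id", "log2fc", "padj", "mean_rpkm", "gene_length")
    miss <- setdiff(need, names(stats))
    if (length(miss))
        stop("stats missing column(s): ", paste(miss, collapse = ", "))
    if (length(unique(paste(stats$cell_line, stats$shRNA))) > 1L)
        stop("selectDeContrast expects a single (cell_line, shRNA) contrast")
    pass <- !is.na(stats$padj) &
        stats$mean_rpkm > cfg$rpkmMin &
        stats$gene_length >= cfg$lengthMin &
        abs(stats$log2fc) > cfg$lfcMin &
        stats$padj < cfg$padjMax
    data.frame(
        gene_id = stats$gene_id,
        cell_line = if ("cell_line" %in% names(stats)) stats$cell_line
                    else NA_character_,
        shRNA = if ("shRNA" %in% names(stats)) stats$shRNA
                else NA_character_,
        pass = pass,
        direction = sign(stats$log2fc),
        stringsAsFactors = FALSE)
}

#' Intersect per-contrast calls into directional gene sets
#'
#' A gene is *upregulated by the factor* when it passes with negative
#' knockdown log2 fold change in at least one shRNA of every cell line;
#' *downregulated* is the symmetric positive-direction set. Genes that
#' qualify in opposite directions across cell lines are conflicted and
#' belong to neither set.
#'
#' @param calls data.frame of stacked [selectDeContrast()] outputs across
#'   all configured contrasts (2 cell lines x 2 shRNAs by default).
#' @return a [DirectionalGeneSets].
#' @export
intersectDirectional <- function(calls) {
    stopifnot(all(c("gene_id", "cell_line", "pass", "direction") %in%
                  names(calls)))
    lines <- unique(calls$cell_line)
    if (length(lines) < 2L)
        stop("need contrasts from at least two cell lines")
    passing <- calls[calls$pass, , drop = FALSE]
    qual <- function(dir) {
        hit <- passing[sign(passing$direction) == dir, , drop = FALSE]
        byGene <- split(hit$cell_line, hit$gene_id)
        names(byGene)[vapply(byGene, function(cl)
            all(lines %in% cl), logical(1))]
    }
    upQ <- qual(-1)    # down after knockdown => factor-activated
    downQ <- qual(1)
    conflicted <- intersect(upQ, downQ)
    new("DirectionalGeneSets",
        upregulated = sort(setdiff(upQ, conflicted)),
        downregulated = sort(setdiff(downQ, conflicted)),
        conflicted = sort(conflicted),
        evidence = passing[, c("gene_id", "cell_line", "shRNA",
                               "direction")])
}

#' Expressed background for survival testing
#'
#' A gene belongs to the background when its nascent-RNA RPKM exceeds the
#' threshold in at least one replicate of *each* cell line.
#'
#' @param rpkm long data.frame: `gene_id`, `cell_line`, `replicate`,
#'   `rpkm`.
#' @param threshold RPKM cut-off (strict `>`), default 0.5.
#' @return character vector of gene ids, sorted.
#' @export
expressedBackground <- function(rpkm, threshold = 0.5) {
    stopifnot(all(c("gene_id", "cell_line", "rpkm") %in% names(rpkm)))
    lines <- unique(rpkm$cell_line)
    agg <- stats::aggregate(rpkm$rpkm,
                            by = list(gene_id = rpkm$gene_id,
                                      cell_line = rpkm$cell_line),
                            FUN = max)
    ok <- agg[agg$x > threshold, , drop = FALSE]
    byGene <- split(ok$cell_line, ok$gene_id)
    sort(names(byGene)[vapply(byGene, function(cl)
        all(lines %in% cl), logical(1))])
}

#' Expressed gene set for peak annotation
#'
#' Genes with mean nascent-RNA RPKM strictly above the threshold (default
#' 0.25); peaks are only assigned to TSSs of these genes. When a gene
#' appears in several contrasts its mean RPKM values are averaged first.
#'
#' @param stats data.frame with `gene_id` and `mean_rpkm`.
#' @param threshold mean-RPKM cut-off (strict `>`).
#' @return character vector of gene ids, sorted.
#' @export
expressedForPeaks <- function(stats, threshold = 0.25) {
    stopifnot(all(c("gene_id", "mean_rpkm") %in% names(stats)))
    m <- tapply(stats$mean_rpkm, stats$gene_id, mean)
    sort(names(m)[m > threshold])
}
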