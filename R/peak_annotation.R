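#' Peak-to-gene annotation parameters
#'
#' @param proximalBp promoter window half-width: a gene whose nearest
#'   candidate peak lies within this distance of the TSS is proximally
#'   bound (default 5 kb, boundary inclusive).
#' @param distalBp outer window: failing proximal, a nearest candidate
#'   peak within this distance is distal (default 100 kb, inclusive).
#' @param referencePoint distance is measured from the peak summit when
#'   available, falling back to the interval midpoint; set
#'   `"midpoint"` to ignore summits.
#' @return a named list of class `"PeakAnnotationConfig"`.
#' @export
peakAnnotationConfig <- function(proximalBp = 5000, distalBp = 100000,
                                 referencePoint = c("summit", "midpoint")) {
    referencePoint <- match.arg(referencePoint)
    stopifnot(proximalBp > 0, proximalBp < distalBp)
    structure(list(proximalBp = proximalBp, distalBp = distalBp,
                   referencePoint = referencePoint),
              class = "PeakAnnotationConfig")
}

peakRefPoint <- function(peaks, referencePoint = "summit") {
    mid <- floor((GenomicRanges::start(peaks) +
                  GenomicRanges::end(peaks)) / 2)
    if (referencePoint == "summit" && !is.null(peaks$summit)) {
        ref <- peaks$summit
        ref[is.na(ref)] <- mid[is.na(ref)]
        ref
    } else {
        mid
    }
}

#' Assign each peak to the closest expressed gene's TSS
#'
#' Distance is `|reference point - TSS|`, minimised over genes on the same
#' chromosome. Peaks on chromosomes without genes are unassigned (dropped
#' from the output). Ties between equidistant TSSs are broken toward the
#' lexicographically smaller gene id, making the assignment deterministic.
#' This assignment also defines reciprocity for [classifyReplicate()]:
#' a gene's candidate peaks are exactly the peaks assigned to it.
#'
#' @param peaks one replicate's peaks (`GRanges`, blacklist-filtered).
#' @param genes expressed gene models (`GRanges`).
#' @param cfg a [peakAnnotationConfig()].
#' @return data.frame: `peak_idx` (row in `peaks`), `gene_id`,
#'   `signed_distance` (reference point minus TSS), `distance`.
#' @export
assignPeaks <- function(peaks, genes, cfg = peakAnnotationConfig()) {
    if (length(peaks) == 0L || length(genes) == 0L)
        return(data.frame(peak_idx = integer(), gene_id = character(),
                          signed_distance = numeric(),
                          distance = numeric()))
    ref <- peakRefPoint(peaks, cfg$referencePoint)
    tss <- geneTss(genes)
    geneChrom <- as.character(GenomicRanges::seqnames(genes))
    peakChrom <- as.character(GenomicRanges::seqnames(peaks))
    out <- vector("list", length(unique(peakChrom)))
    oi <- 0L
    for (ch in unique(peakChrom)) {
        gSel <- which(geneChrom == ch)
        if (length(gSel) == 0L) next
        pSel <- which(peakChrom == ch)
        gid <- genes$gene_id[gSel]
        gts <- tss[gSel]
        ord <- order(gts, gid)
        gts <- gts[ord]; gid <- gid[ord]
        pref <- ref[pSel]
        idx <- findInterval(pref, gts)
        assigned <- character(length(pSel))
        sdist <- numeric(length(pSel))
        for (k in seq_along(pSel)) {
            i <- idx[k]
            dl <- if (i >= 1L) abs(pref[k] - gts[i]) else Inf
            dr <- if (i < length(gts)) abs(pref[k] - gts[i + 1L]) else Inf
            d <- min(dl, dr)
            # all genes whose TSS attains the minimal distance
            cand <- gid[abs(pref[k] - gts) == d]
            assigned[k] <- min(cand)
            sdist[k] <- pref[k] - gts[match(assigned[k], gid)]
        }
        oi <- oi + 1L
        out[[oi]] <- data.frame(peak_idx = pSel, gene_id = assigned,
                                signed_distance = sdist,
                                distance = abs(sdist),
                                stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out[seq_len(oi)])
    if (is.null(res))
        return(data.frame(peak_idx = integer(), gene_id = character(),
                          signed_distance = numeric(),
                          distance = numeric()))
    res[order(res$peak_idx), , drop = FALSE]
}

#' Classify genes as proximal / distal / none for one replicate
#'
#' A gene's candidate peaks are the peaks assigned to it by
#' [assignPeaks()] (the reciprocal-closest rule: a peak closer to another
#' gene's TSS never counts, even if it lies within the window). With `d`
#' the distance of the nearest candidate peak: proximal when
#' `d <= proximalBp`, else distal when `d <= distalBp`, else none; genes
#' without candidate peaks are none.
#'
#' @param assignment output of [assignPeaks()] for this replicate.
#' @param genes the expressed gene models used for the assignment.
#' @param cfg a [peakAnnotationConfig()].
#' @return data.frame: `gene_id`, `class` (proximal/distal/none),
#'   `nearest_distance` (`NA` when no candidate peak).
#' @export
classifyReplicate <- function(assignment, genes,
                              cfg = peakAnnotationConfig()) {
    nearest <- tapply(assignment$distance, assignment$gene_id, min)
    d <- nearest[genes$gene_id]
    cls <- ifelse(is.na(d), "none",
           ifelse(d <= cfg$proximalBp, "proximal",
           ifelse(d <= cfg$distalBp, "distal", "none")))
    data.frame(gene_id = genes$gene_id, class = unname(cls),
               nearest_distance = unname(as.numeric(d)),
               stringsAsFactors = FALSE)
}

#' Cross-cell-line consensus binding class
#'
#' A gene is **proximal** when at least one replicate in every cell line
#' classifies it proximal. Otherwise it is **distal** when at least one
#' replicate in every cell line classifies it distal and no replicate
#' anywhere classifies it proximal (a gene with both proximal and distal
#' replicate calls that fails the proximal rule is demoted to neither,
#' since its replicates are then not uniformly distal). Everything else,
#' including genes with no peak at all, is **neither**.
#'
#' @param perReplicate data.frame: `gene_id`, `cell_line`, `replicate`,
#'   `class` (stacked [classifyReplicate()] outputs with labels).
#' @return data.frame: `gene_id`, `consensus_class`.
#' @export
consensusClassification <- function(perReplicate) {
    stopifnot(all(c("gene_id", "cell_line", "class") %in%
                  names(perReplicate)))
    lines <- unique(perReplicate$cell_line)
    one <- function(df) {
        byLine <- split(df$class, df$cell_line)
        P <- all(vapply(byLine, function(cl) any(cl == "proximal"),
                        logical(1))) && all(lines %in% names(byLine))
        D <- all(vapply(byLine, function(cl) any(cl == "distal"),
                        logical(1))) && all(lines %in% names(byLine))
        anyProx <- any(df$class == "proximal")
        if (P) "proximal"
        else if (D && !anyProx) "distal"
        else "neither"
    }
    cls <- vapply(split(perReplicate, perReplicate$gene_id), one,
                  character(1))
    data.frame(gene_id = names(cls), consensus_class = unname(cls),
               stringsAsFactors = FALSE)
}

#' Annotate binding for a full replicate set
#'
#' Convenience wrapper running [assignPeaks()] and [classifyReplicate()]
#' per (cell line, replicate) and [consensusClassification()] across them.
#'
#' @param peaksByRep named list of `GRanges`, each carrying `cell_line`
#'   and `replicate` metadata columns (as from [simulatePeaks()]).
#' @param genes expressed gene models.
#' @param cfg a [peakAnnotationConfig()].
#' @return list with `calls` (gene_id, consensus_class, nearest_distance
#'   = minimum over replicates), `perReplicate` (stacked replicate
#'   classes), `assignments` (stacked peak assignments with labels), and
#'   the input `peaksByRep`.
#' @export
annotateBinding <- function(peaksByRep, genes,
                            cfg = peakAnnotationConfig()) {
    perRep <- list(); asg <- list()
    for (nm in names(peaksByRep)) {
        pk <- peaksByRep[[nm]]
        a <- assignPeaks(pk, genes, cfg)
        cl <- classifyReplicate(a, genes, cfg)
        cl$cell_line <- pk$cell_line[1]
        cl$replicate <- pk$replicate[1]
        a$cell_line <- pk$cell_line[1]
        a$replicate <- pk$replicate[1]
        a$rep_name <- nm
        perRep[[nm]] <- cl
        asg[[nm]] <- a
    }
    perRep <- do.call(rbind, c(perRep, list(make.row.names = FALSE)))
    asg <- do.call(rbind, c(asg, list(make.row.names = FALSE)))
    cons <- consensusClassification(perRep)
    nd <- tapply(perRep$nearest_distance, perRep$gene_id,
                 function(x) if (all(is.na(x))) NA_real_
                             else min(x, na.rm = TRUE))
    cons$nearest_distance <- as.numeric(nd[cons$gene_id])
    list(calls = cons, perReplicate = perRep, assignments = asg,
         peaksByRep = peaksByRep)
}

#' Peaks reproducible across two cell lines
#'
#' A peak of one cell line is retained when it overlaps at least one peak
#' from at least one replicate of the other cell line (and symmetrically).
#'
#' @param peaksA,peaksB a `GRanges` or list of per-replicate `GRanges`
#'   for each cell line.
#' @return list with the retained `A` and `B` peaks (same shape as the
#'   inputs).
#' @export
commonPeaks <- function(peaksA, peaksB) {
    asList <- function(x) if (inherits(x, "GRanges")) list(x) else x
    la <- asList(peaksA); lb <- asList(peaksB)
    allA <- suppressWarnings(do.call(c, unname(la)))
    allB <- suppressWarnings(do.call(c, unname(lb)))
    keepA <- lapply(la, function(gr)
        gr[IRanges::overlapsAny(gr, allB, ignore.strand = TRUE)])
    keepB <- lapply(lb, function(gr)
        gr[IRanges::overlapsAny(gr, allA, ignore.strand = TRUE)])
    if (inherits(peaksA, "GRanges")) keepA <- keepA[[1]]
    if (inherits(peaksB, "GRanges")) keepB <- keepB[[1]]
    list(A = keepA, B = keepB)
}

#' Enhancer overlap of bound genes
#'
#' Flags each gene whose assigned peaks (any replicate) overlap at least
#' one merged enhancer region, and reports the flagged fraction among
#' bound genes (consensus proximal or distal).
#'
#' @param annotation output of [annotateBinding()].
#' @param enhancers merged enhancer regions (`GRanges`,
#'   see [mergeIntervals()]).
#' @return list with `perGene` (gene_id, enhancer_flag) and `fraction`
#'   (flagged / bound; `NA` when there are no bound genes).
#' @export
enhancerOverlapReport <- function(annotation, enhancers) {
    asg <- annotation$assignments
    flagged <- character(0)
    for (nm in unique(asg$rep_name)) {
        rows <- asg[asg$rep_name == nm, , drop = FALSE]
        pk <- annotation$peaksByRep[[nm]][rows$peak_idx]
        ov <- overlapsAnyRegion(pk, enhancers)
        flagged <- union(flagged, rows$gene_id[ov])
    }
    calls <- annotation$calls
    perGene <- data.frame(
        gene_id = calls$gene_id,
        enhancer_flag = calls$gene_id %in% flagged,
        stringsAsFactors = FALSE)
    bound <- calls$consensus_class %in% c("proximal", "distal")
    fraction <- if (!any(bound)) NA_real_
                else mean(perGene$enhancer_flag[bound])
    list(perGene = perGene, fraction = fraction)
}
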