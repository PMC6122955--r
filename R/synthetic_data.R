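# Deterministic sub-stream derivation: every per-(cell line, replicate) or
# per-stage draw reseeds from the caller's seed through this map, so a
# single integer seed reproduces the whole bundle byte-for-byte.
subSeed <- function(seed, i, j = 0L) {
    as.integer((as.numeric(seed) + 104729 * i + 7919 * j) %% 2147483587)
}

#' Simulate a gene annotation
#'
#' Lays out genes along `nChrom` chromosomes with exponentially distributed
#' TSS spacing (mean `meanSpacing`), random strands, and log-normal gene
#' lengths (median ~20 kb, `sdlog = 2` by default) so that a small fraction
#' of genes falls below the 300-base differential-transcription length
#' filter. All TSS positions are distinct by construction.
#'
#' @param nChrom number of chromosomes (>= 1).
#' @param genesPerChrom genes per chromosome (>= 1).
#' @param meanSpacing mean TSS-to-TSS spacing in bases (>= 1000).
#' @param seed integer seed.
#' @param lengthMeanlog,lengthSdlog log-normal gene-length parameters.
#' @return a stranded gene-model `GRanges` (see [makeGeneModels()]).
#' @examples
#' genes <- simulateGenome(1, 10, 1e5, seed = 1)
#' length(genes)
#' @export
simulateGenome <- function(nChrom = 2, genesPerChrom = 100,
                           meanSpacing = 50000, seed = 1,
                           lengthMeanlog = log(20000), lengthSdlog = 2) {
    stopifnot(nChrom >= 1, genesPerChrom >= 1, meanSpacing >= 1000)
    set.seed(subSeed(seed, 1L))
    recs <- lapply(seq_len(nChrom), function(ci) {
        gaps <- rexp(genesPerChrom, rate = 1 / meanSpacing)
        tss <- cumsum(pmax(round(gaps), 2000)) + 100000
        strand <- sample(c("+", "-"), genesPerChrom, replace = TRUE)
        len <- pmax(round(rlnorm(genesPerChrom, lengthMeanlog,
                                 lengthSdlog)), 50)
        start1 <- ifelse(strand == "+", tss, pmax(tss - len + 1, 1))
        end1 <- ifelse(strand == "+", tss + len - 1, tss)
        data.frame(chrom = paste0("chrS", ci), strand = strand,
                   start1 = start1, end1 = end1)
    })
    df <- do.call(rbind, recs)
    n <- nrow(df)
    ids <- sprintf("g%04d", seq_len(n))
    gr <- GenomicRanges::GRanges(
        seqnames = df$chrom,
        ranges = IRanges::IRanges(start = df$start1, end = df$end1),
        strand = df$strand)
    gr$gene_id <- ids
    gr$symbol <- ids
    names(gr) <- ids
    lens <- tapply(GenomicRanges::end(gr),
                   as.character(GenomicRanges::seqnames(gr)), max) + 200000
    lens <- setNames(as.integer(lens), names(lens))
    GenomeInfoDb::seqlengths(gr) <- lens[GenomeInfoDb::seqlevels(gr)]
    gr
}

#' Simulate replicated ChIP peaks with planted bound genes
#'
#' A random `boundFraction` of genes is designated bound; in each
#' (cell line, replicate), each bound gene receives one peak of width
#' `peakWidth` centred at its TSS plus Normal(0, `placementSd`) noise with
#' probability `1 - dropout`. Background peaks are placed uniformly at
#' `backgroundRate` peaks per megabase. Peak summits are recorded at the
#' placed centre.
#'
#' @param genes gene-model `GRanges` with seqlengths.
#' @param boundFraction fraction of genes planted as bound, in \[0, 1\].
#' @param cellLines,replicatesPerLine sample layout labels/counts.
#' @param placementSd SD (bases) of peak centre around the TSS.
#' @param dropout per-replicate probability a bound gene's peak is missed.
#' @param backgroundRate background peaks per Mb.
#' @param peakWidth fixed peak width in bases.
#' @param seed integer seed.
#' @param boundGenes optional explicit bound gene ids; overrides
#'   `boundFraction` sampling.
#' @return list with `peaks` (named list of `GRanges`, one per
#'   `"{line}_rep{k}"`, metadata columns `cell_line`, `replicate`,
#'   `summit`) and `truth` (a [SimTruth]).
#' @export
simulatePeaks <- function(genes, boundFraction = 0.2,
                          cellLines = c("cellA", "cellB"),
                          replicatesPerLine = 2, placementSd = 200,
                          dropout = 0.1, backgroundRate = 5,
                          peakWidth = 300, seed = 1,
                          boundGenes = NULL) {
    stopifnot(boundFraction >= 0, boundFraction <= 1,
              dropout >= 0, dropout <= 1)
    set.seed(subSeed(seed, 2L))
    if (is.null(boundGenes)) {
        nBound <- round(boundFraction * length(genes))
        bound <- sort(sample(genes$gene_id, nBound))
    } else {
        stopifnot(all(boundGenes %in% genes$gene_id))
        bound <- sort(as.character(boundGenes))
    }
    tss <- geneTss(genes)
    chrOf <- setNames(as.character(GenomicRanges::seqnames(genes)),
                      genes$gene_id)
    seqlens <- GenomeInfoDb::seqlengths(genes)
    half <- floor(peakWidth / 2)
    out <- list()
    for (i in seq_along(cellLines)) {
        for (j in seq_len(replicatesPerLine)) {
            set.seed(subSeed(seed, 100L + i, j))
            keep <- bound[runif(length(bound)) >= dropout]
            ctr <- round(tss[keep] + rnorm(length(keep), 0, placementSd))
            chrom <- chrOf[keep]
            bg <- lapply(names(seqlens), function(ch) {
                nbg <- rpois(1, backgroundRate * seqlens[[ch]] / 1e6)
                if (nbg == 0) return(NULL)
                data.frame(chrom = ch,
                           ctr = round(runif(nbg, half + 1,
                                             seqlens[[ch]] - half)))
            })
            bg <- do.call(rbind, bg)
            chrom <- c(chrom, bg$chrom)
            ctr <- c(ctr, bg$ctr)
            ctr <- pmax(ctr, half + 1)
            gr <- GenomicRanges::GRanges(
                seqnames = chrom,
                ranges = IRanges::IRanges(start = ctr - half,
                                          end = ctr - half + peakWidth - 1))
            gr$cell_line <- cellLines[i]
            gr$replicate <- paste0("rep", j)
            gr$summit <- unname(ctr)
            names(gr) <- NULL
            out[[paste0(cellLines[i], "_rep", j)]] <- sort(gr)
        }
    }
    list(peaks = out,
         truth = SimTruth(boundGenes = bound, seed = seed))
}

#' Simulate knockdown differential-transcription tables
#'
#' Produces one per-gene statistics table per (cell line, shRNA) contrast.
#' Activated genes (upregulated by the factor) get knockdown log2 fold
#' change ~ Normal(-`effectLog2fc`, `noiseSd`); repressed genes the
#' mirrored positive effect; all other genes ~ Normal(0, `noiseSd`).
#' P-values are the two-sided Normal tail of `log2fc / noiseSd`, so null
#' p-values are Uniform(0, 1) by construction; adjusted p-values come from
#' [bhAdjust()] within each contrast. Mean RPKM is log-normal with a
#' `lowRpkmFraction` of genes expected below the 0.25 expression filter.
#'
#' @param genes gene-model `GRanges`.
#' @param activated,repressed disjoint gene-id sets with planted effects.
#' @param effectLog2fc planted |log2 fold change| (default 1.5).
#' @param noiseSd Normal noise SD on log2fc.
#' @param cellLines,shRNAs contrast layout.
#' @param lowRpkmFraction expected fraction of genes with mean RPKM < 0.25.
#' @param seed integer seed.
#' @return list with `stats` (long data.frame: gene_id, cell_line, shRNA,
#'   log2fc, pvalue, padj, mean_rpkm, gene_length) and `truth`.
#' @export
simulateDeTables <- function(genes, activated = character(),
                             repressed = character(), effectLog2fc = 1.5,
                             noiseSd = 0.2,
                             cellLines = c("cellA", "cellB"),
                             shRNAs = c("sh1", "sh2"),
                             lowRpkmFraction = 0.1, seed = 1) {
    stopifnot(length(intersect(activated, repressed)) == 0L)
    ids <- genes$gene_id
    lens <- GenomicRanges::width(genes)
    mu <- numeric(length(ids))
    mu[ids %in% activated] <- -effectLog2fc
    mu[ids %in% repressed] <- effectLog2fc
    rpkmMeanlog <- log(0.25) - stats::qnorm(lowRpkmFraction)
    tabs <- list()
    k <- 0L
    for (i in seq_along(cellLines)) {
        for (j in seq_along(shRNAs)) {
            k <- k + 1L
            set.seed(subSeed(seed, 200L + i, j))
            lfc <- mu + rnorm(length(ids), 0, noiseSd)
            if (noiseSd > 0) {
                p <- 2 * pnorm(-abs(lfc) / noiseSd)
            } else {
                lfc <- mu
                p <- ifelse(abs(lfc) > 0, 1e-300, 1)
            }
            rpkm <- rlnorm(length(ids), rpkmMeanlog, 1)
            tabs[[k]] <- data.frame(
                gene_id = ids, cell_line = cellLines[i], shRNA = shRNAs[j],
                log2fc = lfc, pvalue = p, padj = bhAdjust(p),
                mean_rpkm = rpkm, gene_length = lens,
                stringsAsFactors = FALSE)
        }
    }
    list(stats = do.call(rbind, tabs),
         truth = SimTruth(activatedGenes = sort(activated),
                          repressedGenes = sort(repressed), seed = seed))
}

#' Simulate promoter windows with planted consensus sites
#'
#' One sequence of length `2 * windowBp` per gene (the +/- `windowBp`
#' promoter window around the TSS), i.i.d. bases at the given GC content.
#' Genes in `motifGenes` receive exactly `plantedPerGene` non-overlapping
#' forward-strand insertions of a concrete realisation of the consensus
#' (degenerate IUPAC positions instantiated uniformly from their base
#' class); insertion positions are recorded.
#'
#' @param genes gene-model `GRanges`.
#' @param motif a [MotifModel] with an IUPAC consensus.
#' @param motifGenes gene ids to receive planted sites.
#' @param plantedPerGene insertions per motif gene.
#' @param windowBp half-window size; the sequence length is `2 * windowBp`.
#' @param gc GC content of the background bases, in \[0, 1\].
#' @param seed integer seed.
#' @return list with `sequences` (a named `DNAStringSet`), `plantedSites`
#'   (data.frame: gene_id, start, end), and `truth`.
#' @export
simulatePromoters <- function(genes, motif, motifGenes = character(),
                              plantedPerGene = 2, windowBp = 5000,
                              gc = 0.4, seed = 1) {
    m <- motifWidth(motif)
    if (is.na(motif@consensus))
        stop("simulatePromoters needs a consensus motif")
    if (windowBp < m)
        stop("window must be at least the motif length")
    L <- 2L * as.integer(windowBp)
    if (plantedPerGene * m > L)
        stop("planted sites cannot fit in the promoter window")
    set.seed(subSeed(seed, 3L))
    baseProb <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    classes <- iupacClasses()
    consChars <- strsplit(motif@consensus, "")[[1]]
    seqs <- character(length(genes))
    sites <- list()
    for (gi in seq_along(genes)) {
        chars <- sample(names(baseProb), L, replace = TRUE, prob = baseProb)
        gid <- genes$gene_id[gi]
        if (gid %in% motifGenes) {
            occupied <- rep(FALSE, L)
            starts <- integer(0)
            for (k in seq_len(plantedPerGene)) {
                cand <- which(vapply(seq_len(L - m + 1), function(s) {
                    !any(occupied[s:(s + m - 1)])
                }, logical(1)))
                if (length(cand) == 0L)
                    stop("planted sites cannot fit for gene ", gid)
                s <- if (length(cand) == 1L) cand else sample(cand, 1L)
                inst <- vapply(consChars,
                               function(cc) sample(classes[[cc]], 1L),
                               character(1))
                chars[s:(s + m - 1)] <- inst
                occupied[s:(s + m - 1)] <- TRUE
                starts <- c(starts, s)
            }
            sites[[gid]] <- data.frame(gene_id = gid, start = sort(starts),
                                       end = sort(starts) + m - 1L,
                                       stringsAsFactors = FALSE)
        }
        seqs[gi] <- paste(chars, collapse = "")
    }
    ss <- Biostrings::DNAStringSet(seqs)
    names(ss) <- genes$gene_id
    plantedSites <- if (length(sites)) do.call(rbind, c(sites,
                        list(make.row.names = FALSE)))
                    else data.frame(gene_id = character(),
                                    start = integer(), end = integer())
    list(sequences = ss, plantedSites = plantedSites,
         truth = SimTruth(motifGenes = sort(as.character(motifGenes)),
                          seed = seed))
}

#' Simulate a survival cohort with planted hazard genes
#'
#' Expression is log-normal on a positive scale. The per-sample log hazard
#' is `sum(beta_g * z_g)` over the planted hazard genes, where `z_g` is the
#' z-score of `log10(x + 1)` across samples (the same transform the Cox
#' stage applies). Survival time is the minimum of an Exponential event
#' time with rate `baselineRate * exp(eta)` and an independent Exponential
#' censoring time with rate `censorRate`; a `censorRate` of 0 disables
#' censoring. A fraction of samples is labelled with a histology from the
#' neuroendocrine exclusion list so the cohort filter has work to do.
#'
#' @param nSamples cohort size (>= 20).
#' @param genes gene-model `GRanges`.
#' @param hazardGenes named numeric, planted log-hazard coefficient per
#'   gene id (may be empty).
#' @param baselineRate baseline event rate per time unit.
#' @param censorRate censoring rate (0 disables).
#' @param excludedFraction fraction of samples labelled with an excluded
#'   histology.
#' @param seed integer seed.
#' @param exprMeanlog,exprSdlog log-normal expression parameters.
#' @return list with `expression` (genes x samples matrix), `clinical`
#'   (data.frame: sample_id, time, event, histology), and `truth`.
#' @export
simulateCohort <- function(nSamples = 300, genes,
                           hazardGenes = setNames(numeric(), character()),
                           baselineRate = 0.1, censorRate = 0.05,
                           excludedFraction = 0.1, seed = 1,
                           exprMeanlog = 3, exprSdlog = 1) {
    stopifnot(nSamples >= 20)
    if (length(hazardGenes) && !all(names(hazardGenes) %in% genes$gene_id))
        stop("hazardGenes must reference simulated gene ids")
    set.seed(subSeed(seed, 4L))
    ids <- genes$gene_id
    expr <- matrix(rlnorm(length(ids) * nSamples, exprMeanlog, exprSdlog),
                   nrow = length(ids),
                   dimnames = list(ids,
                                   sprintf("s%04d", seq_len(nSamples))))
    eta <- rep(0, nSamples)
    for (g in names(hazardGenes)) {
        lx <- log10(expr[g, ] + 1)
        z <- if (stats::sd(lx) > 0) (lx - mean(lx)) / stats::sd(lx) else 0 * lx
        eta <- eta + hazardGenes[[g]] * z
    }
    tEvent <- rexp(nSamples, rate = baselineRate * exp(eta))
    tCens <- if (censorRate > 0) rexp(nSamples, rate = censorRate)
             else rep(Inf, nSamples)
    time <- pmin(tEvent, tCens)
    event <- as.integer(tEvent <= tCens)
    nExcl <- round(excludedFraction * nSamples)
    histology <- rep("pancreas-adenocarcinoma ductal type", nSamples)
    if (nExcl > 0) {
        excl <- sample(nSamples, nExcl)
        histology[excl] <- sample(neuroendocrineExclusionLabels(),
                                  nExcl, replace = TRUE)
    }
    clinical <- data.frame(
        sample_id = colnames(expr), time = time, event = event,
        histology = histology, stringsAsFactors = FALSE)
    list(expression = expr, clinical = clinical,
         truth = SimTruth(hazardGenes = hazardGenes, seed = seed))
}
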