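#' Pipeline configuration
#'
#' Collects every tunable of the synthetic-input generators and of the
#' analysis stages, with the study defaults: a 200-gene genome on two
#' chromosomes, two cell lines with two ChIP replicates and two knockdown
#' shRNAs each, a 300-patient cohort, +/- 5 kb promoter windows, the
#' 14-base degenerate consensus as the scanned motif, FDR thresholds 0.1
#' and 0.25, and 10,000 permutations.
#'
#' @param seed global integer seed; every stochastic stage derives its
#'   own sub-stream from it.
#' @param nChrom,genesPerChrom,meanSpacing genome layout
#'   (see [simulateGenome()]).
#' @param boundFraction,placementSd,dropout,backgroundRate,peakWidth peak
#'   simulation (see [simulatePeaks()]).
#' @param cellLines,replicatesPerLine,shRNAs sample layout.
#' @param activatedFraction,repressedFraction fractions of genes planted
#'   as factor-activated / repressed when truths do not coincide.
#' @param effectLog2fc,noiseSd knockdown effect size and noise
#'   (see [simulateDeTables()]).
#' @param nSamples,baselineRate,censorRate,excludedFraction,hazardBeta
#'   cohort simulation (see [simulateCohort()]).
#' @param motifConsensus,plantedPerGene,windowBp,gc,nDecoys motif stage.
#' @param permutations,fdrThresholds survival stage.
#' @param coincideTruth when `TRUE` (default) the planted activated,
#'   bound, motif and hazard gene sets coincide, giving the pipeline a
#'   recoverable end-to-end signal; when `FALSE` they are drawn
#'   independently.
#' @return a named list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(seed = 1, nChrom = 2, genesPerChrom = 100,
                           meanSpacing = 50000, boundFraction = 0.15,
                           cellLines = c("cellA", "cellB"),
                           replicatesPerLine = 2,
                           placementSd = 200, dropout = 0.1,
                           backgroundRate = 5, peakWidth = 300,
                           shRNAs = c("sh1", "sh2"),
                           activatedFraction = 0.15,
                           repressedFraction = 0.05,
                           effectLog2fc = 1.5, noiseSd = 0.2,
                           nSamples = 300, baselineRate = 0.1,
                           censorRate = 0.05, excludedFraction = 0.1,
                           hazardBeta = 0.8,
                           motifConsensus = "DGTTAATNATTAAC",
                           plantedPerGene = 2, windowBp = 5000,
                           gc = 0.4, nDecoys = 10,
                           permutations = 10000,
                           fdrThresholds = c(0.1, 0.25),
                           coincideTruth = TRUE) {
    cfg <- as.list(environment())
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Simulate a complete input bundle with coherent planted truth
#'
#' Runs every generator with sub-seeds derived from the global seed. With
#' `coincideTruth = TRUE` the factor-activated genes are exactly the bound
#' genes, carry the planted motif in their promoters, and carry the
#' planted positive log-hazard coefficient — the configuration in which
#' the full pipeline should re-discover the planted set. When `dir` is
#' given, all inputs and truth tables are also written in the plain-text
#' dialects the readers consume (narrowPeak, BED, TSV, FASTA), plus a
#' serialized copy of the effective configuration.
#'
#' @param config a [pipelineConfig()].
#' @param dir optional output directory.
#' @return the in-memory bundle: genes, peak lists, DE tables, RPKM
#'   table, promoter sequences, enhancers, blacklist, cohort, motif and
#'   decoys, and a merged [SimTruth].
#' @export
simulateInputBundle <- function(config = pipelineConfig(), dir = NULL) {
    seed <- config$seed
    genes <- simulateGenome(config$nChrom, config$genesPerChrom,
                            config$meanSpacing, seed = seed)
    ids <- genes$gene_id
    set.seed(subSeed(seed, 10L))
    nBound <- round(config$boundFraction * length(ids))
    bound <- sort(sample(ids, nBound))
    if (config$coincideTruth) {
        activated <- bound
        repressed <- sort(sample(setdiff(ids, bound),
                          round(config$repressedFraction * length(ids))))
        motifGenes <- bound
        hazardIds <- bound
    } else {
        activated <- sort(sample(ids,
                          round(config$activatedFraction * length(ids))))
        repressed <- sort(sample(setdiff(ids, activated),
                          round(config$repressedFraction * length(ids))))
        motifGenes <- sort(sample(ids, nBound))
        hazardIds <- sort(sample(ids, max(1, round(0.1 * length(ids)))))
    }
    hazard <- setNames(rep(config$hazardBeta, length(hazardIds)),
                       hazardIds)

    pk <- simulatePeaks(genes, boundFraction = 0,
                        cellLines = config$cellLines,
                        replicatesPerLine = config$replicatesPerLine,
                        placementSd = config$placementSd,
                        dropout = config$dropout,
                        backgroundRate = config$backgroundRate,
                        peakWidth = config$peakWidth, seed = seed,
                        boundGenes = bound)
    de <- simulateDeTables(genes, activated = activated,
                           repressed = repressed,
                           effectLog2fc = config$effectLog2fc,
                           noiseSd = config$noiseSd,
                           cellLines = config$cellLines,
                           shRNAs = config$shRNAs, seed = seed)
    motif <- motifModel("consensus", consensus = config$motifConsensus,
                        windowBp = config$windowBp)
    prom <- simulatePromoters(genes, motif, motifGenes = motifGenes,
                              plantedPerGene = config$plantedPerGene,
                              windowBp = config$windowBp,
                              gc = config$gc, seed = seed)
    cohort <- simulateCohort(config$nSamples, genes,
                             hazardGenes = hazard,
                             baselineRate = config$baselineRate,
                             censorRate = config$censorRate,
                             excludedFraction = config$excludedFraction,
                             seed = seed)

    # per-replicate RPKM around each gene's simulated mean, for the
    # expressed-background definition
    set.seed(subSeed(seed, 11L))
    meanRpkm <- tapply(de$stats$mean_rpkm, de$stats$gene_id, mean)[ids]
    rpkmRows <- list()
    for (cl in config$cellLines)
        for (r in seq_len(config$replicatesPerLine))
            rpkmRows[[paste(cl, r)]] <- data.frame(
                gene_id = ids, cell_line = cl,
                replicate = paste0("rep", r),
                rpkm = as.numeric(meanRpkm) *
                    exp(rnorm(length(ids), 0, 0.2)),
                stringsAsFactors = FALSE)
    rpkmTable <- do.call(rbind, c(rpkmRows, list(make.row.names = FALSE)))

    # enhancer segments near most bound-gene TSSs plus random background;
    # a small random blacklist
    set.seed(subSeed(seed, 12L))
    tss <- geneTss(genes)
    seqlens <- GenomeInfoDb::seqlengths(genes)
    enhGenes <- sample(bound, round(0.75 * length(bound)))
    enhCtr <- round(tss[enhGenes] + rnorm(length(enhGenes), 0, 300))
    enhChrom <- as.character(GenomicRanges::seqnames(genes))[
        match(enhGenes, ids)]
    nRand <- 30L
    randChrom <- sample(names(seqlens), nRand, replace = TRUE)
    randCtr <- round(runif(nRand, 2000, seqlens[randChrom] - 2000))
    enhancers <- mergeIntervals(GenomicRanges::GRanges(
        seqnames = c(enhChrom, randChrom),
        ranges = IRanges::IRanges(
            start = pmax(c(enhCtr, randCtr) - 1000, 1),
            width = 2000)))
    nBl <- 10L
    blChrom <- sample(names(seqlens), nBl, replace = TRUE)
    blStart <- round(runif(nBl, 1, seqlens[blChrom] - 5000))
    blacklist <- mergeIntervals(GenomicRanges::GRanges(
        seqnames = blChrom,
        ranges = IRanges::IRanges(start = blStart, width = 5000)))

    truth <- SimTruth(boundGenes = bound, activatedGenes = activated,
                      repressedGenes = repressed, hazardGenes = hazard,
                      motifGenes = motifGenes, seed = seed)
    bundle <- list(genes = genes, peaks = pk$peaks, deStats = de$stats,
                   rpkmTable = rpkmTable, promoters = prom$sequences,
                   plantedSites = prom$plantedSites,
                   expression = cohort$expression,
                   clinical = cohort$clinical,
                   enhancers = enhancers, blacklist = blacklist,
                   motif = motif,
                   decoys = decoyMotifs(motif, config$nDecoys,
                                        seed = seed),
                   truth = truth, config = config)
    if (!is.null(dir))
        writeInputBundle(bundle, dir)
    bundle
}

#' Write a simulated bundle to disk in standard formats
#'
#' @param bundle output of [simulateInputBundle()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeInputBundle <- function(bundle, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
    writeGeneTable(bundle$genes, file.path(dir, "genes.tsv"))
    for (nm in names(bundle$peaks))
        writeNarrowPeak(bundle$peaks[[nm]],
                        file.path(dir, "peaks",
                                  paste0(nm, ".narrowPeak")))
    writeBed(bundle$enhancers, file.path(dir, "enhancers.bed"))
    writeBed(bundle$blacklist, file.path(dir, "blacklist.bed"))
    write.table(bundle$deStats, file.path(dir, "de_stats.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(bundle$rpkmTable, file.path(dir, "rpkm.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writePromoterFasta(bundle$promoters,
                       file.path(dir, "promoters.fa"))
    expr <- data.frame(gene_id = rownames(bundle$expression),
                       bundle$expression, check.names = FALSE)
    write.table(expr, file.path(dir, "expression.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(bundle$clinical, file.path(dir, "clinical.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    tr <- bundle$truth
    truthDf <- rbind(
        data.frame(set = "bound", gene_id = tr@boundGenes,
                   value = NA_real_),
        data.frame(set = "activated", gene_id = tr@activatedGenes,
                   value = NA_real_),
        data.frame(set = "repressed", gene_id = tr@repressedGenes,
                   value = NA_real_),
        data.frame(set = "motif", gene_id = tr@motifGenes,
                   value = NA_real_),
        data.frame(set = "hazard", gene_id = names(tr@hazardGenes),
                   value = unname(tr@hazardGenes)))
    write.table(truthDf, file.path(dir, "truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cfg <- bundle$config
    writeLines(paste0(names(cfg), "=",
                      vapply(cfg, function(v)
                          paste(as.character(v), collapse = ","),
                          character(1))),
               file.path(dir, "config.txt"))
    invisible(dir)
}

#' Run the integrated target-nomination pipeline
#'
#' Executes the full analysis chain on a simulated (or equivalently
#' structured) input bundle: (1) differential-transcription selection per
#' contrast and cross-cell-line directional intersection; (2) blacklist
#' filtering, peak-to-TSS assignment restricted to expressed genes,
#' per-replicate classification and cross-cell-line consensus, plus
#' enhancer overlap; (3) motif over-representation of the scanned motif
#' against shuffled decoys, foreground = upregulated genes, background =
#' all other genes with promoter sequence; (4) per-gene Cox survival
#' association with FDR thresholding, signed-significance ranking, and
#' the gene-set permutation test, for the upregulated,
#' upregulated-and-bound, and downregulated sets at each FDR threshold.
#'
#' @param bundle an input bundle from [simulateInputBundle()].
#' @param permutations overrides the configured permutation count.
#' @param verbose print per-stage record counts.
#' @return a report list; see the package vignette for the layout.
#' @export
runPipeline <- function(bundle, permutations = NULL, verbose = FALSE) {
    cfg <- bundle$config
    N <- if (is.null(permutations)) cfg$permutations else permutations
    say <- function(...) if (verbose) message(...)

    ## stage 1: differential transcription
    st <- bundle$deStats
    calls <- do.call(rbind, lapply(
        split(st, paste(st$cell_line, st$shRNA)),
        selectDeContrast))
    deSets <- intersectDirectional(calls)
    say("DE: ", length(deSets@upregulated), " upregulated, ",
        length(deSets@downregulated), " downregulated")

    ## stage 2: peak annotation on expressed genes
    expressedIds <- expressedForPeaks(st)
    exprGenes <- bundle$genes[bundle$genes$gene_id %in% expressedIds]
    filt <- lapply(bundle$peaks, removeBlacklisted,
                   blacklist = bundle$blacklist)
    annCfg <- peakAnnotationConfig()
    annotation <- annotateBinding(filt, exprGenes, annCfg)
    calls2 <- annotation$calls
    boundIds <- calls2$gene_id[
        calls2$consensus_class %in% c("proximal", "distal")]
    enh <- enhancerOverlapReport(annotation, bundle$enhancers)
    up <- deSets@upregulated
    upCls <- calls2$consensus_class[match(up, calls2$gene_id)]
    upCls[is.na(upCls)] <- "neither"
    bindingProportions <- c(
        proximal = mean(upCls == "proximal"),
        distal = mean(upCls == "distal"),
        neither = mean(upCls == "neither"))
    say("binding: ", length(boundIds), " bound expressed genes; ",
        "enhancer fraction ", signif(enh$fraction, 3))

    ## stage 3: motif over-representation, upregulated vs rest;
    ## consensus motifs are scanned as indicator matrices at the 85%
    ## relative-score threshold so the background rate stays
    ## non-degenerate at panel scale
    fgIds <- intersect(up, names(bundle$promoters))
    bgIds <- setdiff(names(bundle$promoters), fgIds)
    motifs <- lapply(c(list(bundle$motif), unname(bundle$decoys)),
                     consensusToPwm)
    enrich <- lapply(motifs, function(mo)
        motifEnrichment(bundle$promoters[fgIds],
                        bundle$promoters[bgIds], mo))
    ranking <- rankMotifs(enrich)
    rankingDf <- data.frame(
        motif = vapply(ranking, function(r) r@motifName, character(1)),
        zscore = vapply(ranking, function(r) r@zScore, numeric(1)),
        gene_hits = vapply(ranking, function(r) r@geneHits, numeric(1)))
    say("motifs: top = ", rankingDf$motif[1],
        " (z = ", signif(rankingDf$zscore[1], 4), ")")

    ## stage 4: survival
    clin <- filterCohort(bundle$clinical)
    background <- intersect(expressedBackground(bundle$rpkmTable),
                            rownames(bundle$expression))
    sets <- list(upregulated = up,
                 upregulated_bound = intersect(up, boundIds),
                 downregulated = deSets@downregulated)
    fitPool <- intersect(union(background, unlist(sets)),
                         rownames(bundle$expression))
    fitsAll <- geneSetSurvival(fitPool, bundle$expression, clin)
    survivalReports <- list()
    for (sn in names(sets)) {
        gs <- intersect(sets[[sn]], rownames(bundle$expression))
        # the permutation null draws from the expressed background, so
        # the observed set is scored on its background members
        gsPerm <- intersect(gs, background)
        if (length(gs) < 2 || length(gsPerm) < 2 ||
            length(background) <= length(gsPerm)) {
            say("survival: skipping ", sn, " (too small)")
            next
        }
        ranked <- geneSetSurvival(gs, bundle$expression, clin)
        perThr <- list()
        for (thr in cfg$fdrThresholds) {
            perm <- permutationTest(gsPerm, background,
                                    bundle$expression,
                                    clin, N = N, threshold = thr,
                                    direction = "reduced",
                                    seed = subSeed(cfg$seed, 20L,
                                                   round(100 * thr)),
                                    fits = fitsAll)
            perThr[[as.character(thr)]] <- list(
                significant = countSignificant(ranked, thr, "reduced"),
                permutation = perm)
        }
        survivalReports[[sn]] <- list(ranked = ranked,
                                      thresholds = perThr)
        say("survival[", sn, "]: n = ", length(gs),
            ", p(FDR<0.1) = ",
            signif(empiricalP(perThr[[1]]$permutation), 3))
    }

    list(deSets = deSets,
         expressedGenes = expressedIds,
         binding = list(calls = calls2, boundGenes = boundIds,
                        upregulatedProportions = bindingProportions,
                        enhancerFraction = enh$fraction),
         motifRanking = rankingDf,
         survival = survivalReports,
         background = background,
         truth = bundle$truth,
         config = cfg)
}
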