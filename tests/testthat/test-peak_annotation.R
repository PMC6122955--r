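# genes at given 0-based TSS positions, + strand, 1 kb long
genesAt <- function(tss, ids = NULL, chrom = "c1") {
    if (is.null(ids)) ids <- sprintf("g%02d", seq_along(tss))
    makeGeneModels(gene_id = ids, chrom = chrom, strand = "+",
                   start = tss, end = tss + 1000)
}

# width-1 peaks whose reference point is the given 0-based position
peaksAt <- function(pos, chrom = "c1", cellLine = "A", rep = "rep1") {
    gr <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(start = pos + 1L, width = 1L))
    gr$cell_line <- cellLine
    gr$replicate <- rep
    gr$summit <- pos + 1L
    gr
}

test_that("assignPeaks picks the nearest TSS with deterministic ties", {
    cfg <- peakAnnotationConfig()
    a <- assignPeaks(peaksAt(12000), genesAt(10000), cfg)
    expect_equal(a$gene_id, "g01")
    expect_equal(a$distance, 2000)
    expect_equal(a$signed_distance, 2000)

    a2 <- assignPeaks(peaksAt(6000), genesAt(c(0, 10000)), cfg)
    expect_equal(a2$gene_id, "g02")
    expect_equal(a2$distance, 4000)

    # exact tie: lexicographically smaller gene id wins
    a3 <- assignPeaks(peaksAt(5000),
                      genesAt(c(0, 10000), ids = c("gB", "gA")), cfg)
    expect_equal(a3$gene_id, "gA")

    # peaks on a chromosome without genes are unassigned
    a4 <- assignPeaks(peaksAt(100, chrom = "c9"), genesAt(0), cfg)
    expect_equal(nrow(a4), 0L)
})

test_that("classifyReplicate applies windows to reciprocal candidates", {
    cfg <- peakAnnotationConfig()
    g <- genesAt(0)
    cl <- classifyReplicate(assignPeaks(peaksAt(2000), g, cfg), g, cfg)
    expect_equal(cl$class, "proximal")
    cl2 <- classifyReplicate(assignPeaks(peaksAt(60000), g, cfg), g, cfg)
    expect_equal(cl2$class, "distal")
    cl3 <- classifyReplicate(assignPeaks(peaksAt(150000), g, cfg), g, cfg)
    expect_equal(cl3$class, "none")

    # boundary inclusivity: exactly 5 kb is proximal, 100 kb distal
    expect_equal(classifyReplicate(
        assignPeaks(peaksAt(5000), g, cfg), g, cfg)$class, "proximal")
    expect_equal(classifyReplicate(
        assignPeaks(peaksAt(100000), g, cfg), g, cfg)$class, "distal")

    # reciprocity: the single peak belongs to g02, so g01 has no
    # candidate even though the peak is within its distal window
    g2 <- genesAt(c(0, 10000))
    asg <- assignPeaks(peaksAt(6000), g2, cfg)
    cl4 <- classifyReplicate(asg, g2, cfg)
    expect_equal(cl4$class[cl4$gene_id == "g01"], "none")
    expect_equal(cl4$class[cl4$gene_id == "g02"], "proximal")
})

consensusOf <- function(a1, a2, b1, b2) {
    consensusClassification(data.frame(
        gene_id = "g", cell_line = c("A", "A", "B", "B"),
        replicate = c("r1", "r2", "r1", "r2"),
        class = c(a1, a2, b1, b2)))$consensus_class
}

test_that("consensus follows the proximal-first replicate rule", {
    # >= 1 proximal replicate in each line wins regardless of the rest
    expect_equal(consensusOf("proximal", "proximal",
                             "proximal", "distal"), "proximal")
    expect_equal(consensusOf("distal", "distal",
                             "distal", "distal"), "distal")
    # proximal calls present but not in both lines: neither
    expect_equal(consensusOf("proximal", "distal",
                             "distal", "distal"), "neither")
    # distal support in both lines with a missed replicate: still distal
    expect_equal(consensusOf("distal", "none",
                             "distal", "distal"), "distal")
    # distal in one line only: neither
    expect_equal(consensusOf("distal", "none",
                             "none", "none"), "neither")
    expect_equal(consensusOf("none", "none", "none", "none"), "neither")
})

test_that("commonPeaks keeps peaks reproduced in the other cell line", {
    a <- peaksAt(c(100, 5000))
    b <- peaksAt(c(100, 9000), cellLine = "B")
    both <- commonPeaks(a, b)
    expect_equal(GenomicRanges::start(both$A), 101)
    expect_equal(GenomicRanges::start(both$B), 101)

    # identical sets: everything retained; disjoint ranges: nothing
    same <- commonPeaks(a, a)
    expect_length(same$A, 2L)
    none <- commonPeaks(peaksAt(0), peaksAt(10))
    expect_length(none$A, 0L)

    # replicate lists: overlap with any replicate suffices
    lst <- commonPeaks(list(r1 = peaksAt(100)),
                       list(r1 = peaksAt(50000, cellLine = "B"),
                            r2 = peaksAt(100, cellLine = "B")))
    expect_length(lst$A$r1, 1L)
})

test_that("enhancer overlap reports the bound-gene fraction", {
    g <- genesAt(c(0, 50000, 100000))
    mk <- function(pos, cl, rep)
        peaksAt(pos, cellLine = cl, rep = rep)
    peaksByRep <- list(
        A_rep1 = mk(c(100, 50100, 100100), "A", "rep1"),
        B_rep1 = mk(c(100, 50100, 100100), "B", "rep1"))
    ann <- annotateBinding(peaksByRep, g)
    expect_true(all(ann$calls$consensus_class == "proximal"))
    # enhancers cover the peaks of the first two genes only
    enh <- mergeIntervals(GenomicRanges::GRanges("c1",
        IRanges::IRanges(start = c(50, 50050), width = 200)))
    repCall <- enhancerOverlapReport(ann, enh)
    expect_equal(repCall$fraction, 2 / 3)
    expect_setequal(
        repCall$perGene$gene_id[repCall$perGene$enhancer_flag],
        c("g01", "g02"))
    # no enhancers: fraction 0; no bound genes: fraction missing
    expect_equal(enhancerOverlapReport(ann,
        GenomicRanges::GRanges())$fraction, 0)
})

test_that("planted bound genes come out consensus proximal with clean peaks", {
    g <- simulateGenome(2, 40, 5e4, seed = 21)
    pk <- simulatePeaks(g, boundFraction = 0.25, dropout = 0,
                        placementSd = 400, backgroundRate = 0,
                        seed = 21)
    ann <- annotateBinding(pk$peaks, g)
    calls <- ann$calls
    bound <- boundGenes(pk$truth)
    cls <- calls$consensus_class[match(bound, calls$gene_id)]
    expect_true(all(cls == "proximal"))
    # and with no background, nothing else is proximal or distal
    others <- calls$consensus_class[!calls$gene_id %in% bound]
    expect_true(all(others == "neither"))
})

test_that("whole-module results agree with the brute-force oracle", {
    cfg <- peakAnnotationConfig()
    set.seed(31)
    for (inst in 1:25) {
        nGenes <- sample(3:20, 1)
        tss0 <- sample(0:300000, nGenes)
        ids <- sprintf("g%02d", sample(99, nGenes))
        chrom <- sample(c("c1", "c2"), nGenes, replace = TRUE)
        genes <- makeGeneModels(ids, chrom, "+", tss0, tss0 + 500)
        oGenes <- data.frame(gene_id = ids, chrom = chrom,
                             tss = tss0 + 1)
        peaksByRep <- list()
        oraclePerRep <- list()
        for (cl in c("A", "B")) for (r in c("rep1", "rep2")) {
            nPk <- sample(2:25, 1)
            pos <- sample(0:300000, nPk)
            pchrom <- sample(c("c1", "c2"), nPk, replace = TRUE)
            gr <- GenomicRanges::GRanges(pchrom,
                IRanges::IRanges(start = pos + 1L, width = 1L))
            gr$cell_line <- cl; gr$replicate <- r
            gr$summit <- pos + 1L
            nm <- paste0(cl, "_", r)
            peaksByRep[[nm]] <- gr
            oAsg <- oracleAssign(
                data.frame(chrom = pchrom, ref = pos + 1), oGenes)
            oraclePerRep[[nm]] <- data.frame(
                gene_id = oGenes$gene_id, cell_line = cl,
                class = unname(oracleClassify(oAsg, oGenes)))
        }
        ann <- annotateBinding(peaksByRep, genes, cfg)
        oAll <- do.call(rbind, oraclePerRep)
        for (g in oGenes$gene_id) {
            expOracle <- oracleConsensus(
                oAll[oAll$gene_id == g, c("cell_line", "class")])
            got <- ann$calls$consensus_class[ann$calls$gene_id == g]
            expect_equal(got, expOracle,
                         label = paste("instance", inst, "gene", g))
        }
    }
})
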