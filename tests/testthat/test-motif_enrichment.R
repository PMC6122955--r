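hnf1a <- motifModel("HNF1A", consensus = "DGTTAATNATTAAC")

test_that("the tandem-repeat reporter yields one forward hit per repeat", {
    unit <- "CTTGGTTAATGATTAACCAGA"
    seq8 <- paste(rep(unit, 8), collapse = "")
    hits <- scanSequence(seq8, hnf1a, strands = "forward")
    expect_equal(nrow(hits), 8L)
    expect_equal(hits$start, 4L + 21L * 0:7)   # no junction matches
})

test_that("consensus scanning matches the position-by-position oracle", {
    expect_equal(nrow(scanSequence("", hnf1a)), 0L)
    set.seed(51)
    for (rep in 1:20) {
        s <- paste(sample(c("A", "C", "G", "T", "N"), 300,
                          replace = TRUE,
                          prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
                   collapse = "")
        mo <- motifModel("m", consensus = sample(
            c("DGTTAATNATTAAC", "RYSW", "TTAA", "NNGC"), 1))
        got <- scanSequence(s, mo, strands = "both")
        want <- oracleScanBoth(s, mo@consensus)
        expect_equal(got$start[got$strand == "+"], want$fwd)
        expect_equal(sort(got$start[got$strand == "-"]), want$rev)
    }
})

test_that("a palindromic site is reported on both strands at one locus", {
    hits <- scanSequence("GGTTAATCATTAACC", hnf1a, strands = "both")
    expect_equal(nrow(hits), 2L)
    expect_setequal(hits$strand, c("+", "-"))
})

test_that("sequence N matches nothing, even motif N", {
    hits <- scanSequence("CTTGGTTAATNATTAACCAGA", hnf1a)
    expect_equal(nrow(hits), 0L)
    expect_error(motifModel("bad", consensus = "AXGT"), "IUPAC")
})

test_that("matrix mode thresholds the relative score", {
    set.seed(8)
    m <- 6
    mat <- matrix(stats::runif(4 * m), nrow = 4,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    mo <- motifModel("pwm", matrix = mat, relThreshold = 0.8)
    s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
               collapse = "")
    got <- scanSequence(s, mo, strands = "forward")
    # independent rescan: direct relative-score computation per offset
    chars <- strsplit(s, "")[[1]]
    sMin <- sum(apply(mat, 2, min)); sMax <- sum(apply(mat, 2, max))
    want <- integer(0)
    for (i in 1:(400 - m + 1)) {
        S <- sum(mat[cbind(match(chars[i:(i + m - 1)],
                                 c("A", "C", "G", "T")), 1:m)])
        if ((S - sMin) / (sMax - sMin) >= 0.8) want <- c(want, i)
    }
    expect_equal(got$start, want)
    # the top-scoring sequence itself always matches
    best <- paste(c("A", "C", "G", "T")[apply(mat, 2, which.max)],
                  collapse = "")
    expect_equal(nrow(scanSequence(best, mo, strands = "forward")), 1L)
})

test_that("scanning a sequence plus its reverse complement is symmetric", {
    set.seed(9)
    s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
               collapse = "")
    rc <- oracleRevComp(s)
    expect_equal(nrow(scanSequence(s, hnf1a, "both")),
                 nrow(scanSequence(rc, hnf1a, "both")))
})

test_that("extractWindows cuts, clips and strand-flips genome windows", {
    genome <- Biostrings::DNAStringSet(c(
        c1 = paste(rep("ACGT", 5000), collapse = "")))
    gPlus <- makeGeneModels("gp", "c1", "+", 5000, 6000)
    w <- extractWindows(gPlus, genome, windowBp = 5000)
    expect_equal(Biostrings::width(w), 10000L)   # [0, 10000)
    expect_equal(as.character(w[[1]]),
                 as.character(Biostrings::subseq(genome[[1]], 1, 10000)))

    gEdge <- makeGeneModels("ge", "c1", "+", 1000, 2000)
    expect_equal(Biostrings::width(extractWindows(gEdge, genome, 5000)),
                 6000L)                          # clipped to [0, 6000)

    gMinus <- makeGeneModels("gm", "c1", "-", 4000, 6000)
    wm <- extractWindows(gMinus, genome, 1000)
    fwd <- Biostrings::subseq(genome[[1]], 5000, 6999)
    expect_equal(as.character(wm[[1]]),
                 as.character(Biostrings::reverseComplement(fwd)))

    expect_warning(extractWindows(
        makeGeneModels("gx", "cX", "+", 0, 100), genome, 100),
        "skipped")
})

test_that("enrichmentZscore evaluates the binomial formula", {
    r <- enrichmentZscore(10, 1000, 50, 10000)
    expect_equal(r@pBg, 0.005)
    expect_equal(r@mu, 5)
    expect_equal(r@sigma, sqrt(1000 * 0.005 * 0.995))
    expect_equal(zScore(r), (10 - 5) / sqrt(4.975))
    # z = 0 exactly when the foreground count equals its expectation
    expect_equal(zScore(enrichmentZscore(5, 1000, 50, 10000)), 0)
    # degenerate background
    r0 <- enrichmentZscore(3, 100, 0, 1000)
    expect_true(r0@degenerateBackground)
    expect_true(is.na(zScore(r0)))
})

test_that("rankMotifs orders by z, then gene hits, then name", {
    mk <- function(z, gh, nm) {
        r <- enrichmentZscore(10, 1000, 50, 10000, motifName = nm,
                              geneHits = gh)
        r@zScore <- z
        r
    }
    rs <- list(mk(1, 5, "a"), mk(3, 1, "b"), mk(2, 9, "c"))
    expect_equal(vapply(rankMotifs(rs), function(r) r@motifName,
                        character(1)), c("b", "c", "a"))
    tied <- list(mk(2, 1, "a"), mk(2, 7, "b"),
                 { x <- mk(NA_real_, 3, "z"); x })
    expect_equal(vapply(rankMotifs(tied), function(r) r@motifName,
                        character(1)), c("b", "a", "z"))
})

test_that("consensus and matrix scans agree on N-free sequences", {
    set.seed(71)
    pwm <- consensusToPwm(hnf1a, relThreshold = 1)   # exact matches only
    seqs <- Biostrings::DNAStringSet(vapply(1:10, function(i)
        paste(c(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                "GGTTAATGATTAAC"), collapse = ""), character(1)))
    names(seqs) <- paste0("s", 1:10)
    expect_equal(countMotifHits(seqs, pwm, "both")$hits,
                 countMotifHits(seqs, hnf1a, "both")$hits)
    # at 85% the matrix scan can only gain near-match hits
    pwm85 <- consensusToPwm(hnf1a, relThreshold = 0.85)
    expect_true(all(countMotifHits(seqs, pwm85, "both")$hits >=
                    countMotifHits(seqs, hnf1a, "both")$hits))
})

test_that("planted motifs are recovered ahead of shuffled decoys", {
    g <- simulateGenome(2, 75, 5e4, seed = 61)
    fgIds <- g$gene_id[1:30]
    planted <- fgIds[1:9]   # 30% of the foreground
    pr <- simulatePromoters(g, hnf1a, motifGenes = planted,
                            plantedPerGene = 3, windowBp = 2500,
                            seed = 61)
    fg <- pr$sequences[fgIds]
    bg <- pr$sequences[setdiff(g$gene_id, fgIds)]
    # matrix scan at the 85% relative threshold keeps the background
    # hit rate of a stringent 14-mer non-degenerate at panel scale
    scanSet <- lapply(c(list(hnf1a),
                        unname(decoyMotifs(hnf1a, 10, seed = 61))),
                      consensusToPwm)
    res <- lapply(scanSet, function(mo) motifEnrichment(fg, bg, mo))
    ranked <- rankMotifs(res)
    expect_equal(ranked[[1]]@motifName, "HNF1A")
    expect_gt(zScore(ranked[[1]]), 5)
})
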