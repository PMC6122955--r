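test_that("bhAdjust implements the step-up rule", {
    expect_equal(bhAdjust(0.03), 0.03)
    expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
    # evenly spaced p: every adjusted value collapses to the largest
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)),
                 oracleBH(c(0.01, 0.02, 0.03, 0.04)))
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
    expect_error(bhAdjust(c(0.5, -0.1)), "\\[0, 1\\]")
})

test_that("bhAdjust is pointwise >= input and monotone in p", {
    set.seed(1)
    for (rep in 1:25) {
        p <- runif(sample(1:60, 1))
        q <- bhAdjust(p)
        expect_true(all(q >= p))
        expect_true(all(q <= 1))
        ord <- order(p)
        expect_true(all(diff(q[ord]) >= -1e-15))
        expect_equal(q, oracleBH(p), tolerance = 1e-14)
    }
})

toyStats <- function() {
    # rows span every filter boundary
    data.frame(
        gene_id = sprintf("g%02d", 1:12),
        cell_line = "cellA", shRNA = "sh1",
        log2fc = c(0.60, -0.60, 0.58, -0.58, 0, 2, -2, 0.9,
                   -0.9, 1.5, -1.5, 0.7),
        padj = c(0.05, 0.05, 0.05, 0.05, 0.01, 0.10, 0.09, NA,
                 0.05, 0.05, 0.05, 0.05),
        mean_rpkm = c(1, 1, 1, 1, 1, 1, 1, 1, 0.25, 0.26, 1, 1),
        gene_length = c(500, 500, 500, 500, 500, 500, 500, 500,
                        500, 500, 299, 300),
        stringsAsFactors = FALSE)
}

test_that("selectDeContrast applies all four filters strictly", {
    calls <- selectDeContrast(toyStats())
    # row-by-row oracle: strict >, >=, <, with NA padj failing
    expect_true(calls$pass[calls$gene_id == "g01"])    # lfc 0.60 passes
    expect_true(calls$pass[calls$gene_id == "g02"])
    expect_false(calls$pass[calls$gene_id == "g03"])   # lfc 0.58 boundary
    expect_false(calls$pass[calls$gene_id == "g04"])
    expect_false(calls$pass[calls$gene_id == "g05"])   # lfc 0
    expect_false(calls$pass[calls$gene_id == "g06"])   # padj 0.10 boundary
    expect_true(calls$pass[calls$gene_id == "g07"])
    expect_false(calls$pass[calls$gene_id == "g08"])   # missing padj
    expect_false(calls$pass[calls$gene_id == "g09"])   # rpkm 0.25 boundary
    expect_true(calls$pass[calls$gene_id == "g10"])
    expect_false(calls$pass[calls$gene_id == "g11"])   # length 299
    expect_true(calls$pass[calls$gene_id == "g12"])    # length 300 passes
    expect_equal(calls$direction[calls$gene_id == "g02"], -1)
    expect_error(selectDeContrast(rbind(
        toyStats(), transform(toyStats(), shRNA = "sh2"))),
        "single")
})

dirCalls <- function(...) {
    # each arg: c(gene, cell_line, shRNA, pass, direction)
    rows <- list(...)
    data.frame(
        gene_id = vapply(rows, `[[`, character(1), 1),
        cell_line = vapply(rows, `[[`, character(1), 2),
        shRNA = vapply(rows, `[[`, character(1), 3),
        pass = as.logical(vapply(rows, `[[`, character(1), 4)),
        direction = as.numeric(vapply(rows, `[[`, character(1), 5)),
        stringsAsFactors = FALSE)
}

test_that("intersectDirectional requires one passing shRNA per cell line", {
    # negative pass in one cell line only: excluded
    calls <- dirCalls(c("g1", "A", "sh1", "TRUE", "-1"),
                      c("g1", "B", "sh1", "FALSE", "-1"),
                      c("g2", "A", "sh1", "FALSE", "1"),
                      c("g2", "B", "sh1", "FALSE", "1"))
    sets <- intersectDirectional(calls)
    expect_length(upregulated(sets), 0L)

    # negative pass in one shRNA of each line: upregulated
    calls2 <- dirCalls(c("g1", "A", "sh2", "TRUE", "-1"),
                       c("g1", "B", "sh1", "TRUE", "-1"),
                       c("g1", "B", "sh2", "FALSE", "1"))
    expect_equal(upregulated(intersectDirectional(calls2)), "g1")

    # opposite directions in the two lines: neither set
    calls3 <- dirCalls(c("g1", "A", "sh1", "TRUE", "-1"),
                       c("g1", "B", "sh1", "TRUE", "1"),
                       c("g2", "A", "sh1", "TRUE", "1"),
                       c("g2", "B", "sh1", "TRUE", "1"))
    sets3 <- intersectDirectional(calls3)
    expect_length(upregulated(sets3), 0L)
    expect_equal(downregulated(sets3), "g2")

    # qualifying in both directions in both lines: conflicted
    calls4 <- dirCalls(c("g1", "A", "sh1", "TRUE", "-1"),
                       c("g1", "A", "sh2", "TRUE", "1"),
                       c("g1", "B", "sh1", "TRUE", "-1"),
                       c("g1", "B", "sh2", "TRUE", "1"))
    sets4 <- intersectDirectional(calls4)
    expect_length(upregulated(sets4), 0L)
    expect_length(downregulated(sets4), 0L)
    expect_equal(sets4@conflicted, "g1")
})

test_that("row order of the input tables never changes any output set", {
    g <- simulateGenome(1, 60, 5e4, seed = 12)
    de <- simulateDeTables(g, activated = g$gene_id[1:10],
                           repressed = g$gene_id[11:15], seed = 12)
    st <- de$stats
    calls <- do.call(rbind, lapply(
        split(st, paste(st$cell_line, st$shRNA)), selectDeContrast))
    set.seed(1)
    shuf <- st[sample(nrow(st)), ]
    calls2 <- do.call(rbind, lapply(
        split(shuf, paste(shuf$cell_line, shuf$shRNA)),
        selectDeContrast))
    s1 <- intersectDirectional(calls)
    s2 <- intersectDirectional(calls2)
    expect_identical(upregulated(s1), upregulated(s2))
    expect_identical(downregulated(s1), downregulated(s2))
})

test_that("planted activated genes are recovered with high sensitivity", {
    sens <- numeric(20)
    fp <- numeric(20)
    for (i in 1:20) {
        g <- simulateGenome(1, 100, 5e4, seed = 100 + i)
        act <- g$gene_id[1:20]
        de <- simulateDeTables(g, activated = act, effectLog2fc = 1,
                               noiseSd = 0.2, seed = 100 + i)
        st <- de$stats
        calls <- do.call(rbind, lapply(
            split(st, paste(st$cell_line, st$shRNA)), selectDeContrast))
        up <- upregulated(intersectDirectional(calls))
        # sensitivity among genes that can pass the expression/length
        # filters at all (simulated RPKM and length are random)
        eligible <- act[act %in% st$gene_id[
            st$mean_rpkm > 0.25 & st$gene_length >= 300]]
        sens[i] <- length(intersect(up, eligible)) /
            max(1, length(eligible))
        fp[i] <- length(setdiff(up, act))
    }
    expect_gte(mean(sens), 0.9)
    expect_lt(mean(fp), 0.1 * 100)
})

test_that("expressedBackground needs one passing replicate in each line", {
    rpkm <- data.frame(
        gene_id = rep(c("g1", "g2"), each = 4),
        cell_line = rep(rep(c("A", "B"), each = 2), 2),
        replicate = rep(c("r1", "r2"), 4),
        rpkm = c(0.6, 0.1, 0.0, 0.0,    # g1: fails in B
                 0.6, 0.1, 0.51, 0.2))  # g2: passes both
    expect_equal(expressedBackground(rpkm), "g2")

    set.seed(3)
    rnd <- data.frame(
        gene_id = rep(sprintf("g%02d", 1:30), each = 4),
        cell_line = rep(rep(c("A", "B"), each = 2), 30),
        replicate = rep(c("r1", "r2"), 60),
        rpkm = stats::rexp(120, 2))
    got <- expressedBackground(rnd, threshold = 0.5)
    oracle <- character()
    for (g in unique(rnd$gene_id)) {
        okA <- max(rnd$rpkm[rnd$gene_id == g & rnd$cell_line == "A"]) > 0.5
        okB <- max(rnd$rpkm[rnd$gene_id == g & rnd$cell_line == "B"]) > 0.5
        if (okA && okB) oracle <- c(oracle, g)
    }
    expect_setequal(got, oracle)
})

test_that("expressedForPeaks applies a strict mean-RPKM threshold", {
    st <- data.frame(gene_id = c("g1", "g2", "g3"),
                     mean_rpkm = c(0.25, 0.26, 5))
    expect_setequal(expressedForPeaks(st), c("g2", "g3"))
    set.seed(4)
    rnd <- data.frame(gene_id = sprintf("g%02d", 1:50),
                      mean_rpkm = stats::rexp(50, 3))
    expect_setequal(expressedForPeaks(rnd),
                    rnd$gene_id[rnd$mean_rpkm > 0.25])
})
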