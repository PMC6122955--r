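# Independent brute-force oracles. These deliberately re-derive each
# quantity by enumeration or nested loops, sharing no code with the
# package implementations they check.

# --- interval arithmetic on enumerated base sets (BED convention) -------

# intervals as data.frame(chrom, start, end), 0-based half-open
oracleBaseSet <- function(df) {
    if (nrow(df) == 0L) return(character())
    unlist(lapply(seq_len(nrow(df)), function(i) {
        if (df$end[i] <= df$start[i]) return(character())
        paste0(df$chrom[i], ":", seq(df$start[i], df$end[i] - 1L))
    }))
}

oracleOverlaps <- function(a, b) {
    # single intervals: share >= 1 base?
    length(intersect(oracleBaseSet(a), oracleBaseSet(b))) > 0L
}

grToBedDf <- function(gr) {
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr),
               stringsAsFactors = FALSE)
}

# --- Benjamini-Hochberg step-up, literal formula ------------------------

oracleBH <- function(p) {
    m <- length(p)
    ord <- order(p)
    ps <- p[ord]
    q <- numeric(m)
    for (i in seq_len(m))
        q[i] <- min(1, min(m * ps[i:m] / (i:m)))
    out <- numeric(m)
    out[ord] <- q
    out
}

# --- nearest-TSS assignment / classification / consensus ----------------

# genes: data.frame(gene_id, chrom, tss); peaks: data.frame(chrom, ref)
oracleAssign <- function(peaks, genes) {
    pk <- integer(0); gid <- character(0); dist <- numeric(0)
    for (i in seq_len(nrow(peaks))) {
        best <- NULL; bestD <- Inf
        for (j in seq_len(nrow(genes))) {
            if (genes$chrom[j] != peaks$chrom[i]) next
            d <- abs(peaks$ref[i] - genes$tss[j])
            if (d < bestD || (d == bestD &&
                              genes$gene_id[j] < best)) {
                best <- genes$gene_id[j]; bestD <- d
            }
        }
        if (!is.null(best)) {
            pk <- c(pk, i); gid <- c(gid, best); dist <- c(dist, bestD)
        }
    }
    data.frame(peak = pk, gene_id = gid, distance = dist)
}

oracleClassify <- function(assignment, genes, proximal = 5000,
                           distal = 100000) {
    cls <- setNames(rep("none", nrow(genes)), genes$gene_id)
    for (g in genes$gene_id) {
        d <- assignment$distance[assignment$gene_id == g]
        if (length(d) == 0L) next
        d <- min(d)
        if (d <= proximal) cls[g] <- "proximal"
        else if (d <= distal) cls[g] <- "distal"
    }
    cls
}

# classes: data.frame(cell_line, class) per gene
oracleConsensus <- function(classes) {
    lines <- unique(classes$cell_line)
    prox <- TRUE; dist <- TRUE
    for (ln in lines) {
        cl <- classes$class[classes$cell_line == ln]
        if (!any(cl == "proximal")) prox <- FALSE
        if (!any(cl == "distal")) dist <- FALSE
    }
    if (prox) return("proximal")
    if (dist && !any(classes$class == "proximal")) return("distal")
    "neither"
}

# --- IUPAC scanning, position by position -------------------------------

oracleIupac <- function() {
    list(A = "A", C = "C", G = "G", T = "T",
         R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
         W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
         B = c("C", "G", "T"), D = c("A", "G", "T"),
         H = c("A", "C", "T"), V = c("A", "C", "G"),
         N = c("A", "C", "G", "T"))
}

oracleRevComp <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

oracleScanForward <- function(seq, consensus) {
    cls <- oracleIupac()
    sc <- strsplit(seq, "")[[1]]
    cc <- strsplit(consensus, "")[[1]]
    m <- length(cc); L <- length(sc)
    hits <- integer(0)
    if (L < m) return(hits)
    for (i in seq_len(L - m + 1)) {
        ok <- TRUE
        for (j in seq_len(m)) {
            b <- sc[i + j - 1]
            if (b == "N" || !(b %in% cls[[cc[j]]])) { ok <- FALSE; break }
        }
        if (ok) hits <- c(hits, i)
    }
    hits
}

oracleScanBoth <- function(seq, consensus) {
    m <- nchar(consensus); L <- nchar(seq)
    fwd <- oracleScanForward(seq, consensus)
    rcHits <- oracleScanForward(oracleRevComp(seq), consensus)
    rev <- if (length(rcHits)) L - rcHits - m + 2L else integer(0)
    list(fwd = fwd, rev = sort(rev))
}

# --- Cox partial likelihood (Efron ties), grid maximiser ----------------

oracleCoxLoglik <- function(beta, time, event, x) {
    eta <- beta * x
    w <- exp(eta)
    ll <- 0
    for (t in sort(unique(time[event == 1]))) {
        D <- which(time == t & event == 1)
        R <- which(time >= t)
        d <- length(D)
        ll <- ll + sum(eta[D])
        sumR <- sum(w[R]); sumD <- sum(w[D])
        for (l in seq_len(d) - 1)
            ll <- ll - log(sumR - (l / d) * sumD)
    }
    ll
}

oracleCoxGridBeta <- function(time, event, x, lo = -5, hi = 5) {
    # coarse grid then a fine pass around the coarse maximiser
    coarse <- seq(lo, hi, by = 1e-2)
    ll <- vapply(coarse, oracleCoxLoglik, numeric(1),
                 time = time, event = event, x = x)
    b0 <- coarse[which.max(ll)]
    fine <- seq(b0 - 2e-2, b0 + 2e-2, by = 1e-5)
    llf <- vapply(fine, oracleCoxLoglik, numeric(1),
                  time = time, event = event, x = x)
    fine[which.max(llf)]
}

# --- exhaustive permutation null ----------------------------------------

# exact empirical p over all size-k subsets of the background, using the
# same add-one form with N = number of subsets
oracleExactPermutationP <- function(waldP, dirOk, setGenes, background,
                                    k, threshold) {
    score <- function(gs) {
        q <- oracleBH(waldP[gs])
        mean(q < threshold & dirOk[gs])
    }
    obs <- score(setGenes)
    subs <- utils::combn(background, k, simplify = FALSE)
    nulls <- vapply(subs, score, numeric(1))
    list(observed = obs, nulls = nulls,
         p = (1 + sum(nulls >= obs)) / (length(nulls) + 1))
}
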