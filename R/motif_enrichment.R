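iupacClasses <- function() {
    list(A = "A", C = "C", G = "G", T = "T",
         R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
         W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
         B = c("C", "G", "T"), D = c("A", "G", "T"),
         H = c("A", "C", "T"), V = c("A", "C", "G"),
         N = c("A", "C", "G", "T"))
}

#' Per-position probability that the consensus matches i.i.d. bases
#'
#' Closed-form match probability of an IUPAC consensus under an i.i.d.
#' base model with the given GC content: the product over consensus
#' positions of the probability that a random base falls in the position's
#' IUPAC class. Useful for expected background hit counts.
#'
#' @param motif a consensus [MotifModel].
#' @param gc GC content of the base model.
#' @return a probability.
#' @export
consensusMatchProbability <- function(motif, gc = 0.4) {
    stopifnot(!is.na(motif@consensus))
    baseProb <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2,
                  T = (1 - gc) / 2)
    cls <- iupacClasses()
    prod(vapply(strsplit(motif@consensus, "")[[1]],
                function(cc) sum(baseProb[cls[[cc]]]), numeric(1)))
}

#' Scan a sequence for motif hits
#'
#' Consensus mode: a position is a hit when every sequence base lies in
#' the corresponding IUPAC class; an `N` in the *sequence* matches nothing
#' (conservative masking), even against a motif `N`. Matrix mode: a
#' position is a hit when the relative score
#' `(S - Smin) / (Smax - Smin)` reaches the motif's `relThreshold`.
#' Reverse-strand hits are found by scanning the reverse complement and
#' are reported in forward coordinates (start of the motif span on the
#' forward strand). Overlapping hits are all reported.
#'
#' @param seq a `DNAString` or character sequence over A/C/G/T/N.
#' @param motif a [MotifModel].
#' @param strands scan the forward strand only or both strands.
#' @return data.frame: `start` (1-based forward coordinate), `strand`,
#'   `score` (relative matrix score; 1 for consensus hits).
#' @examples
#' hnf1a <- motifModel("HNF1A", consensus = "DGTTAATNATTAAC")
#' scanSequence("CTTGGTTAATGATTAACCAGA", hnf1a, strands = "forward")
#' @export
scanSequence <- function(seq, motif, strands = c("both", "forward")) {
    strands <- match.arg(strands)
    if (is.character(seq)) seq <- Biostrings::DNAString(seq)
    L <- length(seq)
    m <- motifWidth(motif)
    empty <- data.frame(start = integer(), strand = character(),
                        score = numeric())
    if (L < m || m == 0L) return(empty)
    scanOne <- function(s) {
        if (!is.na(motif@consensus)) {
            v <- Biostrings::matchPattern(
                Biostrings::DNAString(motif@consensus), s,
                fixed = "subject")
            st <- BiocGenerics::start(v)
            ok <- !grepl("N", as.character(v), fixed = TRUE)
            data.frame(start = st[ok], score = rep(1, sum(ok)))
        } else {
            mat <- motif@matrix
            chars <- strsplit(as.character(s), "")[[1]]
            idx <- match(chars, c("A", "C", "G", "T"))
            npos <- length(chars) - m + 1L
            S <- rep(0, npos)
            valid <- rep(TRUE, npos)
            for (j in seq_len(m)) {
                ij <- idx[seq_len(npos) + j - 1L]
                valid <- valid & !is.na(ij)
                ij[is.na(ij)] <- 1L
                S <- S + mat[cbind(ij, j)]
            }
            sMin <- sum(apply(mat, 2, min))
            sMax <- sum(apply(mat, 2, max))
            rel <- (S - sMin) / (sMax - sMin)
            hit <- valid & rel >= motif@relThreshold
            data.frame(start = which(hit), score = rel[hit])
        }
    }
    fwd <- scanOne(seq)
    fwd$strand <- rep("+", nrow(fwd))
    res <- fwd
    if (strands == "both") {
        rev <- scanOne(Biostrings::reverseComplement(seq))
        if (nrow(rev)) {
            rev$start <- L - rev$start - m + 2L
            rev$strand <- "-"
            res <- rbind(res, rev)
        }
    }
    res <- res[order(res$start, res$strand), c("start", "strand", "score")]
    rownames(res) <- NULL
    res
}

#' Count motif hits per sequence
#'
#' @param seqs a named `DNAStringSet`.
#' @param motif a [MotifModel].
#' @param strands forward only or both strands.
#' @return data.frame: `name`, `hits`, `positions` (scanned positions:
#'   `len - m + 1` per strand, 0 for sequences shorter than the motif).
#' @export
countMotifHits <- function(seqs, motif, strands = c("both", "forward")) {
    strands <- match.arg(strands)
    m <- motifWidth(motif)
    nStrand <- if (strands == "both") 2L else 1L
    if (!is.na(motif@consensus)) {
        # vectorized count; sequences containing N take the per-sequence
        # path so that masked bases never match
        pat <- Biostrings::DNAString(motif@consensus)
        hits <- Biostrings::vcountPattern(pat, seqs, fixed = "subject")
        if (strands == "both")
            hits <- hits + Biostrings::vcountPattern(
                pat, Biostrings::reverseComplement(seqs),
                fixed = "subject")
        hasN <- Biostrings::alphabetFrequency(seqs)[, "N"] > 0
        for (i in which(hasN))
            hits[i] <- nrow(scanSequence(seqs[[i]], motif, strands))
        hits <- as.numeric(hits)
    } else {
        # matrix mode: absolute threshold equivalent to the relative
        # score cut-off, scored at C speed; N-containing sequences fall
        # back to the per-position scanner (countPWM would weight N as
        # 0 instead of masking the window)
        mat <- motif@matrix
        sMin <- sum(apply(mat, 2, min))
        sMax <- sum(apply(mat, 2, max))
        thr <- sMin + motif@relThreshold * (sMax - sMin)
        hasN <- Biostrings::alphabetFrequency(seqs)[, "N"] > 0
        hits <- numeric(length(seqs))
        for (i in seq_along(seqs)) {
            if (hasN[i]) {
                hits[i] <- nrow(scanSequence(seqs[[i]], motif, strands))
            } else {
                s <- seqs[[i]]
                h <- Biostrings::countPWM(mat, s, min.score = thr)
                if (strands == "both")
                    h <- h + Biostrings::countPWM(
                        mat, Biostrings::reverseComplement(s),
                        min.score = thr)
                hits[i] <- h
            }
        }
    }
    positions <- nStrand * pmax(Biostrings::width(seqs) - m + 1L, 0L)
    data.frame(name = if (is.null(names(seqs)))
                   as.character(seq_along(seqs)) else names(seqs),
               hits = hits, positions = positions,
               stringsAsFactors = FALSE)
}

#' Extract promoter windows around TSSs
#'
#' Two input modes. Genome mode: `sequences` is named by chromosome and
#' the window `[tss - windowBp, tss + windowBp)` is cut out, clipped to
#' the sequence bounds, and reverse-complemented for minus-strand genes so
#' that "upstream" is strand-consistent. Per-gene mode: `sequences` is
#' already keyed by gene id (e.g. from [simulatePromoters()]) and is
#' returned for the requested genes as-is. Genes without a sequence are
#' skipped with a warning.
#'
#' @param genes gene-model `GRanges`.
#' @param sequences a named `DNAStringSet` (chromosomes or gene ids).
#' @param windowBp half-window in bases.
#' @return a `DNAStringSet` named by gene id.
#' @export
extractWindows <- function(genes, sequences, windowBp = 5000) {
    ids <- genes$gene_id
    if (all(ids %in% names(sequences)))
        return(sequences[ids])
    chrom <- as.character(GenomicRanges::seqnames(genes))
    known <- chrom %in% names(sequences)
    if (!all(known)) {
        warning("no sequence for ", sum(!known), " gene(s); skipped")
        genes <- genes[known]
        chrom <- chrom[known]
        ids <- ids[known]
    }
    tss <- geneTss(genes)
    strand <- as.character(GenomicRanges::strand(genes))
    out <- vector("list", length(ids))
    for (i in seq_along(ids)) {
        s <- sequences[[chrom[i]]]
        from <- max(1L, tss[i] - windowBp)
        to <- min(length(s), tss[i] + windowBp - 1L)
        w <- Biostrings::subseq(s, from, to)
        if (strand[i] == "-") w <- Biostrings::reverseComplement(w)
        out[[i]] <- w
    }
    ss <- Biostrings::DNAStringSet(out)
    names(ss) <- ids
    ss
}

#' Binomial over-representation z-score
#'
#' With background per-position hit rate `pBg = bgHits / bgLen`, the
#' expected foreground count is `mu = fgLen * pBg`,
#' `sigma = sqrt(fgLen * pBg * (1 - pBg))`, and
#' `z = (fgHits - mu) / sigma` (no continuity correction). An exact
#' two-sided binomial p-value on the same model is reported alongside.
#' A degenerate background rate (0 or 1) yields an undefined z, flagged.
#'
#' @param fgHits,fgLen foreground hit count and scanned positions.
#' @param bgHits,bgLen background hit count and scanned positions.
#' @param motifName label carried into the result.
#' @param geneHits number of foreground genes with >= 1 hit (optional).
#' @return a [MotifEnrichmentResult].
#' @export
enrichmentZscore <- function(fgHits, fgLen, bgHits, bgLen,
                             motifName = "motif", geneHits = NA_real_) {
    stopifnot(fgLen > 0, bgLen > 0, bgHits <= bgLen, fgHits <= fgLen)
    pBg <- bgHits / bgLen
    degenerate <- pBg <= 0 || pBg >= 1
    mu <- fgLen * pBg
    sigma <- sqrt(fgLen * pBg * (1 - pBg))
    z <- if (degenerate) NA_real_ else (fgHits - mu) / sigma
    bp <- if (degenerate) NA_real_
          else binom.test(round(fgHits), round(fgLen), pBg)$p.value
    new("MotifEnrichmentResult", motifName = motifName,
        fgHits = as.numeric(fgHits), fgLen = as.numeric(fgLen),
        bgHits = as.numeric(bgHits), bgLen = as.numeric(bgLen),
        pBg = pBg, mu = mu, sigma = sigma, zScore = z, binomP = bp,
        geneHits = as.numeric(geneHits),
        degenerateBackground = degenerate)
}

#' Score motif over-representation in a foreground vs background set
#'
#' Scans both sets (both strands), pools hit counts and scanned positions,
#' and computes the binomial z-score of [enrichmentZscore()].
#'
#' @param fgSeqs,bgSeqs named `DNAStringSet`s of promoter windows.
#' @param motif a [MotifModel].
#' @param strands scanning mode.
#' @return a [MotifEnrichmentResult].
#' @export
motifEnrichment <- function(fgSeqs, bgSeqs, motif,
                            strands = c("both", "forward")) {
    strands <- match.arg(strands)
    fg <- countMotifHits(fgSeqs, motif, strands)
    bg <- countMotifHits(bgSeqs, motif, strands)
    enrichmentZscore(sum(fg$hits), sum(fg$positions),
                     sum(bg$hits), sum(bg$positions),
                     motifName = motif@name,
                     geneHits = sum(fg$hits > 0))
}

#' Rank motif enrichment results
#'
#' Descending by z-score with undefined z last; ties broken by the number
#' of foreground genes with a hit (descending), then by motif name.
#'
#' @param results list of [MotifEnrichmentResult]s.
#' @return the list, reordered.
#' @export
rankMotifs <- function(results) {
    z <- vapply(results, function(r) r@zScore, numeric(1))
    gh <- vapply(results, function(r) r@geneHits, numeric(1))
    nm <- vapply(results, function(r) r@motifName, character(1))
    gh[is.na(gh)] <- -Inf
    ord <- order(is.na(z), -ifelse(is.na(z), -Inf, z), -gh, nm)
    results[ord]
}

#' Convert an IUPAC consensus into a matrix motif
#'
#' Builds the indicator position matrix of the consensus (weight 1 for
#' bases in the position's IUPAC class, 0 otherwise) scanned at a
#' relative-score threshold, the matrix-scan idiom of promoter
#' over-representation tools: at the default 85% threshold a 14-base
#' consensus tolerates up to two mismatching positions. This keeps the
#' background hit rate non-degenerate at gene-panel scale, where exact
#' matches to a stringent consensus can be absent from the background
#' entirely.
#'
#' @param motif a consensus [MotifModel].
#' @param relThreshold relative score threshold for the matrix scan.
#' @return a matrix-mode [MotifModel] with the same name.
#' @export
consensusToPwm <- function(motif, relThreshold = 0.85) {
    stopifnot(!is.na(motif@consensus))
    cls <- iupacClasses()
    chars <- strsplit(motif@consensus, "")[[1]]
    mat <- matrix(0, nrow = 4, ncol = length(chars),
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    for (j in seq_along(chars))
        mat[cls[[chars[j]]], j] <- 1
    motifModel(motif@name, matrix = mat, relThreshold = relThreshold,
               windowBp = motif@windowBp)
}

#' Generate decoy consensus motifs by letter shuffling
#'
#' Shuffles the consensus letters of a motif `n` times (rejecting exact
#' duplicates of the original), giving decoys with identical length and
#' information content for ranking controls.
#'
#' @param motif a consensus [MotifModel].
#' @param n number of decoys.
#' @param seed integer seed.
#' @return list of consensus [MotifModel]s named `decoy01`, `decoy02`, ...
#' @export
decoyMotifs <- function(motif, n = 10, seed = 1) {
    stopifnot(!is.na(motif@consensus))
    set.seed(subSeed(seed, 5L))
    chars <- strsplit(motif@consensus, "")[[1]]
    out <- vector("list", n)
    for (i in seq_len(n)) {
        repeat {
            cand <- paste(sample(chars), collapse = "")
            if (cand != motif@consensus) break
        }
        out[[i]] <- motifModel(sprintf("decoy%02d", i), consensus = cand,
                               relThreshold = motif@relThreshold,
                               windowBp = motif@windowBp)
    }
    names(out) <- vapply(out, function(m) m@name, character(1))
    out
}
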