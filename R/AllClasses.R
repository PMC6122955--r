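#' @import methods
#' @importFrom stats p.adjust pchisq pnorm rnorm runif rexp rpois rlnorm
#'   binom.test setNames quantile
#' @importFrom utils read.delim write.table head
NULL

#' Planted ground truth of a synthetic input bundle
#'
#' Records which simulated genes carry planted signal so that downstream
#' stages can be scored against a known answer: genes with ChIP peaks placed
#' at their TSS, genes transcriptionally activated or repressed by the
#' factor (i.e. down- or up-regulated after knockdown), genes whose promoter
#' windows received consensus motif insertions, and genes whose expression
#' drives the simulated hazard.
#'
#' @slot boundGenes character, gene ids with planted peaks.
#' @slot activatedGenes character, gene ids with planted negative knockdown
#'   log2 fold changes (factor-activated).
#' @slot repressedGenes character, gene ids with planted positive knockdown
#'   log2 fold changes.
#' @slot hazardGenes named numeric, planted log-hazard coefficient per gene.
#' @slot motifGenes character, gene ids with planted consensus sites.
#' @slot seed integer seed the generator was called with.
#'
#' @export
setClass("SimTruth",
    representation(
        boundGenes = "character",
        activatedGenes = "character",
        repressedGenes = "character",
        hazardGenes = "numeric",
        motifGenes = "character",
        seed = "integer"
    ),
    prototype(
        boundGenes = character(),
        activatedGenes = character(),
        repressedGenes = character(),
        hazardGenes = setNames(numeric(), character()),
        motifGenes = character(),
        seed = NA_integer_
    )
)

setValidity("SimTruth", function(object) {
    msg <- character()
    if (length(intersect(object@activatedGenes, object@repressedGenes)) > 0L)
        msg <- c(msg, "activatedGenes and repressedGenes must be disjoint")
    if (length(object@hazardGenes) > 0L && is.null(names(object@hazardGenes)))
        msg <- c(msg, "hazardGenes must be a named numeric vector")
    if (length(msg)) msg else TRUE
})

#' @describeIn SimTruth construct a SimTruth object
#' @param boundGenes,activatedGenes,repressedGenes,hazardGenes,motifGenes,seed
#'   see the corresponding slots.
#' @export
SimTruth <- function(boundGenes = character(), activatedGenes = character(),
                     repressedGenes = character(),
                     hazardGenes = setNames(numeric(), character()),
                     motifGenes = character(), seed = NA_integer_) {
    new("SimTruth", boundGenes = as.character(boundGenes),
        activatedGenes = as.character(activatedGenes),
        repressedGenes = as.character(repressedGenes),
        hazardGenes = hazardGenes,
        motifGenes = as.character(motifGenes),
        seed = as.integer(seed))
}

#' @export
setGeneric("boundGenes", function(x) standardGeneric("boundGenes"))
#' @export
setGeneric("activatedGenes", function(x) standardGeneric("activatedGenes"))
#' @export
setGeneric("repressedGenes", function(x) standardGeneric("repressedGenes"))
#' @export
setGeneric("hazardGenes", function(x) standardGeneric("hazardGenes"))
#' @export
setGeneric("motifGenes", function(x) standardGeneric("motifGenes"))

#' @describeIn SimTruth gene ids with planted peaks
#' @param x a `SimTruth`
#' @export
setMethod("boundGenes", "SimTruth", function(x) x@boundGenes)
#' @describeIn SimTruth gene ids activated by the factor
#' @export
setMethod("activatedGenes", "SimTruth", function(x) x@activatedGenes)
#' @describeIn SimTruth gene ids repressed by the factor
#' @export
setMethod("repressedGenes", "SimTruth", function(x) x@repressedGenes)
#' @describeIn SimTruth named log-hazard coefficients
#' @export
setMethod("hazardGenes", "SimTruth", function(x) x@hazardGenes)
#' @describeIn SimTruth gene ids with planted motif sites
#' @export
setMethod("motifGenes", "SimTruth", function(x) x@motifGenes)

setMethod("show", "SimTruth", function(object) {
    cat("SimTruth (seed ", object@seed, ")\n", sep = "")
    cat("  bound genes:     ", length(object@boundGenes), "\n", sep = "")
    cat("  activated genes: ", length(object@activatedGenes), "\n", sep = "")
    cat("  repressed genes: ", length(object@repressedGenes), "\n", sep = "")
    cat("  hazard genes:    ", length(object@hazardGenes), "\n", sep = "")
    cat("  motif genes:     ", length(object@motifGenes), "\n", sep = "")
})

#' IUPAC consensus or weight-matrix motif
#'
#' A motif is either a degenerate IUPAC consensus string (e.g. the
#' HNF1A-type palindromic consensus `DGTTAATNATTAAC`) or a position weight
#' matrix with rows A, C, G, T. Matrix motifs are matched at a relative
#' score threshold: a window is a hit when
#' `(S - Smin) / (Smax - Smin) >= relThreshold`.
#'
#' @slot name motif label.
#' @slot consensus IUPAC consensus string, or `NA` for matrix motifs.
#' @slot matrix numeric matrix (4 x width, rows A/C/G/T) or a 0-column
#'   placeholder for consensus motifs.
#' @slot relThreshold relative score threshold in (0, 1], matrix mode only.
#' @slot windowBp half-width of the promoter scan window around the TSS.
#'
#' @export
setClass("MotifModel",
    representation(
        name = "character",
        consensus = "character",
        matrix = "matrix",
        relThreshold = "numeric",
        windowBp = "numeric"
    )
)

IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

setValidity("MotifModel", function(object) {
    msg <- character()
    hasCons <- !is.na(object@consensus)
    hasMat <- ncol(object@matrix) > 0L
    if (!hasCons && !hasMat)
        msg <- c(msg, "motif needs a consensus or a matrix")
    if (hasCons) {
        bad <- setdiff(strsplit(object@consensus, "")[[1]], IUPAC_CODES)
        if (length(bad))
            msg <- c(msg, paste0("invalid IUPAC code(s): ",
                                 paste(bad, collapse = ", ")))
    }
    if (hasMat && (nrow(object@matrix) != 4L ||
                   !identical(rownames(object@matrix), c("A", "C", "G", "T"))))
        msg <- c(msg, "matrix must have rows A, C, G, T")
    if (object@relThreshold <= 0 || object@relThreshold > 1)
        msg <- c(msg, "relThreshold must be in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' @describeIn MotifModel construct a motif from a consensus or a matrix
#' @param name,consensus,matrix,relThreshold,windowBp see slots.
#' @export
motifModel <- function(name, consensus = NA_character_, matrix = NULL,
                       relThreshold = 0.85, windowBp = 5000) {
    if (is.null(matrix))
        matrix <- base::matrix(numeric(), nrow = 4, ncol = 0,
                               dimnames = list(c("A", "C", "G", "T"), NULL))
    new("MotifModel", name = name,
        consensus = toupper(as.character(consensus)),
        matrix = matrix, relThreshold = relThreshold, windowBp = windowBp)
}

#' @describeIn MotifModel motif width in bases
#' @param x a `MotifModel`
#' @export
motifWidth <- function(x) {
    if (!is.na(x@consensus)) nchar(x@consensus) else ncol(x@matrix)
}

setMethod("show", "MotifModel", function(object) {
    cat("MotifModel '", object@name, "': ", sep = "")
    if (!is.na(object@consensus)) {
        cat("consensus ", object@consensus, "\n", sep = "")
    } else {
        cat("PWM, width ", ncol(object@matrix),
            ", relative threshold ", object@relThreshold, "\n", sep = "")
    }
})

#' Motif over-representation result
#'
#' Binomial z-score for over-representation of a motif in foreground
#' promoter windows relative to a background set. Hits are counted per
#' scanned nucleotide position (both strands); the background hit rate
#' `pBg = bgHits / bgLen` gives the expected foreground count
#' `mu = fgLen * pBg` and `sigma = sqrt(fgLen * pBg * (1 - pBg))`, so
#' `z = (fgHits - mu) / sigma`. An exact two-sided binomial p-value on the
#' same model is reported alongside.
#'
#' @slot motifName motif label.
#' @slot fgHits,fgLen foreground hit count and scanned positions.
#' @slot bgHits,bgLen background hit count and scanned positions.
#' @slot pBg,mu,sigma,zScore derived statistics (see description).
#' @slot binomP exact two-sided binomial p-value.
#' @slot geneHits number of foreground genes with at least one hit.
#' @slot degenerateBackground `TRUE` when `pBg` is 0 or 1, in which case
#'   `zScore` is `NA`.
#'
#' @export
setClass("MotifEnrichmentResult",
    representation(
        motifName = "character",
        fgHits = "numeric", fgLen = "numeric",
        bgHits = "numeric", bgLen = "numeric",
        pBg = "numeric", mu = "numeric", sigma = "numeric",
        zScore = "numeric", binomP = "numeric",
        geneHits = "numeric",
        degenerateBackground = "logical"
    )
)

setValidity("MotifEnrichmentResult", function(object) {
    msg <- character()
    if (object@fgHits > object@fgLen)
        msg <- c(msg, "fgHits must not exceed fgLen")
    if (object@bgHits > object@bgLen)
        msg <- c(msg, "bgHits must not exceed bgLen")
    if (!is.na(object@sigma) && object@sigma < 0)
        msg <- c(msg, "sigma must be non-negative")
    if (length(msg)) msg else TRUE
})

#' @export
setGeneric("zScore", function(x) standardGeneric("zScore"))
#' @describeIn MotifEnrichmentResult the over-representation z-score
#' @param x a `MotifEnrichmentResult`
#' @export
setMethod("zScore", "MotifEnrichmentResult", function(x) x@zScore)

setMethod("show", "MotifEnrichmentResult", function(object) {
    cat("MotifEnrichmentResult '", object@motifName, "'\n", sep = "")
    cat("  foreground: ", object@fgHits, " hits / ", object@fgLen,
        " positions (", object@geneHits, " genes with a hit)\n", sep = "")
    cat("  background: ", object@bgHits, " hits / ", object@bgLen,
        " positions (rate ", signif(object@pBg, 4), ")\n", sep = "")
    if (object@degenerateBackground) {
        cat("  z-score: undefined (degenerate background)\n")
    } else {
        cat("  z-score: ", signif(object@zScore, 6),
            "  (binomial p = ", signif(object@binomP, 4), ")\n", sep = "")
    }
})

#' Gene-set survival permutation test result
#'
#' Null distribution of the fraction of genes in a random same-size gene set
#' (drawn from an expressed background) that are significantly associated
#' with survival in a given direction at an FDR threshold. The empirical
#' p-value uses the add-one estimator
#' `(1 + #\{null >= observed\}) / (N + 1)`.
#'
#' @slot observedFraction fraction of the tested set significant in the
#'   tested direction at the FDR threshold.
#' @slot nullFractions the `N` permuted fractions.
#' @slot empiricalP add-one empirical p-value.
#' @slot N permutation count.
#' @slot threshold FDR threshold used (typically 0.1 or 0.25).
#' @slot direction `"reduced"` (hazard ratio > 1) or `"increased"`.
#' @slot relativeSe coefficient of variation of the p-value estimate at
#'   significance level 0.05, `sqrt((1 - p) / (N p))`.
#' @slot seed seed used for the permutation draws.
#'
#' @export
setClass("PermutationTestResult",
    representation(
        observedFraction = "numeric",
        nullFractions = "numeric",
        empiricalP = "numeric",
        N = "integer",
        threshold = "numeric",
        direction = "character",
        relativeSe = "numeric",
        seed = "integer"
    )
)

setValidity("PermutationTestResult", function(object) {
    msg <- character()
    if (length(object@nullFractions) != object@N)
        msg <- c(msg, "nullFractions must have length N")
    if (object@empiricalP <= 0 || object@empiricalP > 1)
        msg <- c(msg, "empiricalP must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' @export
setGeneric("empiricalP", function(x) standardGeneric("empiricalP"))
#' @export
setGeneric("observedFraction", function(x) standardGeneric("observedFraction"))
#' @export
setGeneric("nullFractions", function(x) standardGeneric("nullFractions"))

#' @describeIn PermutationTestResult the add-one empirical p-value
#' @param x a `PermutationTestResult`
#' @export
setMethod("empiricalP", "PermutationTestResult", function(x) x@empiricalP)
#' @describeIn PermutationTestResult the observed significant fraction
#' @export
setMethod("observedFraction", "PermutationTestResult",
          function(x) x@observedFraction)
#' @describeIn PermutationTestResult the permuted null fractions
#' @export
setMethod("nullFractions", "PermutationTestResult",
          function(x) x@nullFractions)

setMethod("show", "PermutationTestResult", function(object) {
    cat("PermutationTestResult (", object@direction, " survival, FDR < ",
        object@threshold, ")\n", sep = "")
    cat("  observed fraction: ", signif(object@observedFraction, 4),
        "\n", sep = "")
    cat("  null mean:         ",
        signif(mean(object@nullFractions), 4), "\n", sep = "")
    cat("  empirical p:       ", signif(object@empiricalP, 4),
        "  (N = ", object@N, ")\n", sep = "")
})

#' Directional differentially transcribed gene sets
#'
#' Cross-cell-line intersection of per-contrast differential-transcription
#' calls. `upregulated` holds genes transcriptionally activated by the
#' factor, i.e. genes *down* after knockdown in at least one shRNA of every
#' cell line; `downregulated` holds the symmetric set; genes qualifying in
#' opposite directions across cell lines go to `conflicted` and belong to
#' neither set.
#'
#' @slot upregulated,downregulated,conflicted character gene-id sets.
#' @slot evidence data.frame of the per-contrast passing calls
#'   (gene_id, cell_line, shRNA, direction).
#'
#' @export
setClass("DirectionalGeneSets",
    representation(
        upregulated = "character",
        downregulated = "character",
        conflicted = "character",
        evidence = "data.frame"
    )
)

setValidity("DirectionalGeneSets", function(object) {
    if (length(intersect(object@upregulated, object@downregulated)) > 0L)
        "upregulated and downregulated must be disjoint"
    else TRUE
})

#' @export
setGeneric("upregulated", function(x) standardGeneric("upregulated"))
#' @export
setGeneric("downregulated", function(x) standardGeneric("downregulated"))

#' @describeIn DirectionalGeneSets factor-activated genes (down after
#'   knockdown in both cell lines)
#' @param x a `DirectionalGeneSets`
#' @export
setMethod("upregulated", "DirectionalGeneSets", function(x) x@upregulated)
#' @describeIn DirectionalGeneSets factor-repressed genes
#' @export
setMethod("downregulated", "DirectionalGeneSets", function(x) x@downregulated)

setMethod("show", "DirectionalGeneSets", function(object) {
    cat("DirectionalGeneSets\n")
    cat("  upregulated (down after knockdown): ",
        length(object@upregulated), "\n", sep = "")
    cat("  downregulated (up after knockdown): ",
        length(object@downregulated), "\n", sep = "")
    cat("  conflicted across cell lines:       ",
        length(object@conflicted), "\n", sep = "")
})
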