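#' Histology labels excluded from the survival cohort
#'
#' The cohort filter keeps primary solid tumours of non-neuroendocrine
#' origin; samples whose histology field matches any of these strings
#' (case-insensitively, after whitespace normalisation) are rejected.
#'
#' @return character vector of exclusion labels.
#' @export
neuroendocrineExclusionLabels <- function() {
    c("82463 neuroendocrine carcinoma nos",
      "moderately differentiated ductal adenocarcinoma 60% + neuroendocrine 40%",
      "neuroendocrine",
      "neuroendocrine carcinoma",
      "neuroendocrine carcinoma nos")
}

#' Expression-to-covariate transform
#'
#' `log10(x + 1)`; the added constant preserves zeros.
#'
#' @param x nonnegative abundance value(s).
#' @return the transformed covariate.
#' @export
preprocessExpression <- function(x) {
    if (any(x < 0, na.rm = TRUE))
        stop("expression values must be nonnegative")
    log10(x + 1)
}

normalizeLabel <- function(x) {
    tolower(gsub("\\s+", " ", trimws(x)))
}

#' Filter a cohort by histology exclusion labels
#'
#' @param clinical data.frame with at least `sample_id` and `histology`.
#' @param exclusionLabels labels to reject; matching is case-insensitive
#'   with whitespace collapsed.
#' @return the retained rows of `clinical`.
#' @export
filterCohort <- function(clinical,
                         exclusionLabels = neuroendocrineExclusionLabels()) {
    if (length(exclusionLabels) == 0L) return(clinical)
    drop <- normalizeLabel(clinical$histology) %in%
        normalizeLabel(exclusionLabels)
    clinical[!drop, , drop = FALSE]
}

#' Univariate Cox proportional-hazards fit
#'
#' Fits `Surv(time, event) ~ covariate` by partial likelihood with Efron
#' handling of tied event times (Breslow available via `ties`). The Wald
#' p-value is `(beta / se)^2` against chi-squared with 1 df. A constant
#' covariate is a degeneracy error; a monotone likelihood (risk perfectly
#' separating events) is flagged as non-converged with the coefficient
#' capped at |15|.
#'
#' @param time,event follow-up times (> 0) and event indicators (0/1).
#' @param covariate numeric covariate, same length.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return list: `beta`, `se`, `hr`, `wald_p`, `converged`.
#' @export
fitCoxUnivariate <- function(time, event, covariate, ties = "efron") {
    stopifnot(length(time) == length(event),
              length(time) == length(covariate))
    if (sum(event) < 2)
        stop("need at least 2 observed events")
    if (stats::sd(covariate) == 0)
        stop("degenerate covariate (constant)")
    fit <- survival::coxph(
        survival::Surv(time, event) ~ covariate,
        ties = ties,
        control = survival::coxph.control(iter.max = 50, eps = 1e-9))
    beta <- unname(stats::coef(fit))
    se <- sqrt(unname(diag(stats::vcov(fit))))
    converged <- is.finite(beta) && abs(beta) <= 15
    if (!converged)
        beta <- sign(beta) * 15
    waldP <- pchisq((beta / se)^2, df = 1, lower.tail = FALSE)
    list(beta = beta, se = se, hr = exp(beta), wald_p = waldP,
         converged = converged)
}

#' Per-gene survival association for a gene set
#'
#' For each gene, fits a univariate Cox model on the `log10(x + 1)`
#' expression covariate, then adjusts Wald p-values by Benjamini-Hochberg
#' *within the input gene set*. Direction is "reduced" survival when the
#' hazard ratio exceeds 1, "increased" otherwise, and the signed score is
#' `-log10(fdr_q)` with reduced-survival genes positive. Genes whose fit
#' fails (e.g. constant expression) are dropped from the table and from
#' the FDR denominator, with a message.
#'
#' @param genes gene ids to test (must be rows of `expression`).
#' @param expression genes x samples nonnegative matrix.
#' @param clinical data.frame with `sample_id`, `time`, `event`, aligned
#'   to the expression columns by `sample_id`.
#' @param ties tie handling for the Cox fits.
#' @return data.frame ordered by `signed_score` descending: `gene_id`,
#'   `beta`, `se`, `hr`, `wald_p`, `fdr_q`, `direction`, `signed_score`,
#'   `converged`.
#' @export
geneSetSurvival <- function(genes, expression, clinical, ties = "efron") {
    miss <- setdiff(genes, rownames(expression))
    if (length(miss))
        stop("genes absent from expression matrix: ",
             paste(head(miss, 5), collapse = ", "))
    idx <- match(clinical$sample_id, colnames(expression))
    if (anyNA(idx))
        stop("clinical samples missing from expression matrix")
    expr <- expression[, idx, drop = FALSE]
    rows <- vector("list", length(genes))
    failed <- character(0)
    for (i in seq_along(genes)) {
        g <- genes[i]
        cov <- preprocessExpression(expr[g, ])
        f <- tryCatch(
            fitCoxUnivariate(clinical$time, clinical$event, cov,
                             ties = ties),
            error = function(e) NULL)
        if (is.null(f)) { failed <- c(failed, g); next }
        rows[[i]] <- data.frame(
            gene_id = g, beta = f$beta, se = f$se, hr = f$hr,
            wald_p = f$wald_p, converged = f$converged,
            stringsAsFactors = FALSE)
    }
    if (length(failed))
        message("excluded ", length(failed),
                " gene(s) with failed Cox fits")
    res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(res) || nrow(res) == 0L)
        stop("no gene could be fitted")
    res$fdr_q <- bhAdjust(res$wald_p)
    res$direction <- ifelse(res$hr > 1, "reduced", "increased")
    res$signed_score <- -log10(res$fdr_q) *
        ifelse(res$direction == "reduced", 1, -1)
    res <- res[order(-res$signed_score, res$gene_id), , drop = FALSE]
    rownames(res) <- NULL
    res[, c("gene_id", "beta", "se", "hr", "wald_p", "fdr_q",
            "direction", "signed_score", "converged")]
}

#' Count genes significant at an FDR threshold in one direction
#'
#' @param results output of [geneSetSurvival()].
#' @param threshold FDR threshold (strict `<`), e.g. 0.1 or 0.25.
#' @param direction `"reduced"` or `"increased"`.
#' @return list: `count`, `fraction` (`NA` for empty results).
#' @export
countSignificant <- function(results, threshold = 0.1,
                             direction = c("reduced", "increased")) {
    direction <- match.arg(direction)
    if (nrow(results) == 0L)
        return(list(count = 0L, fraction = NA_real_))
    hit <- results$fdr_q < threshold & results$direction == direction
    list(count = sum(hit), fraction = mean(hit))
}

#' Gene-set survival permutation test
#'
#' Scores the tested gene set by the fraction of its genes significantly
#' associated with survival in the tested direction at the FDR threshold,
#' then builds a null by drawing `N` random same-size gene sets from the
#' background and scoring each identically (FDR re-computed *within* each
#' drawn set, mirroring the observed set). Per-gene Cox fits are computed
#' once and cached across permutations. The empirical p-value is the
#' add-one estimator `(1 + #\{null >= observed\}) / (N + 1)`.
#'
#' @param setGenes tested gene set.
#' @param background background gene pool (should contain `setGenes`;
#'   warned otherwise).
#' @param expression,clinical cohort data as in [geneSetSurvival()].
#' @param N permutation count (default 10000; < 100 warns).
#' @param threshold FDR threshold, typically 0.1 or 0.25.
#' @param direction tested survival direction.
#' @param seed integer seed for the permutation draws.
#' @param ties tie handling for the Cox fits.
#' @param fits optional precomputed [geneSetSurvival()] table covering
#'   `union(setGenes, background)`; only its `wald_p` and `direction`
#'   columns are used (the per-set FDR is always recomputed), so passing
#'   a cached table cannot change the result.
#' @return a [PermutationTestResult].
#' @export
permutationTest <- function(setGenes, background, expression, clinical,
                            N = 10000, threshold = 0.1,
                            direction = c("reduced", "increased"),
                            seed = 1, ties = "efron", fits = NULL) {
    direction <- match.arg(direction)
    N <- as.integer(N)
    if (N < 100)
        warning("N < 100 permutations gives an unstable empirical p")
    if (!all(setGenes %in% background))
        warning("setGenes is not a subset of the background")
    if (length(background) <= length(setGenes))
        stop("background must be larger than the tested set")
    allGenes <- union(setGenes, background)
    if (is.null(fits))
        fits <- geneSetSurvival(allGenes, expression, clinical,
                                ties = ties)
    else if (!all(allGenes %in% fits$gene_id))
        stop("precomputed fits must cover the set and background genes")
    waldP <- setNames(fits$wald_p, fits$gene_id)
    dirOk <- setNames(fits$direction == direction, fits$gene_id)
    scoreSet <- function(gs) {
        gs <- gs[gs %in% names(waldP)]   # drop genes whose fit failed
        if (length(gs) == 0L) return(0)
        q <- bhAdjust(waldP[gs])
        mean(q < threshold & dirOk[gs])
    }
    observed <- scoreSet(setGenes)
    bgPool <- background[background %in% names(waldP)]
    k <- length(setGenes)
    set.seed(subSeed(seed, 6L))
    nulls <- vapply(seq_len(N), function(i)
        scoreSet(sample(bgPool, k)), numeric(1))
    empirical <- (1 + sum(nulls >= observed)) / (N + 1)
    new("PermutationTestResult",
        observedFraction = observed, nullFractions = nulls,
        empiricalP = empirical, N = N, threshold = threshold,
        direction = direction,
        relativeSe = permutationRelativeSe(0.05, N),
        seed = as.integer(seed))
}

#' Relative standard error of an empirical permutation p-value
#'
#' Coefficient of variation `sqrt((1 - p) / (N * p))` of the empirical
#' p-value estimate at significance level `p` with `N` permutations; at
#' `p = 0.05` and `N = 10000` this is below 10%, the design criterion for
#' the default permutation count.
#'
#' @param p significance level in (0, 1).
#' @param N permutation count (>= 1).
#' @return the relative standard error (a proportion).
#' @examples
#' permutationRelativeSe(0.05, 10000)
#' @export
permutationRelativeSe <- function(p, N) {
    stopifnot(p > 0, p < 1, N >= 1)
    sqrt((1 - p) / (N * p))
}
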