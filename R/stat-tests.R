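# Nonparametric tests turning replicate measurements into pairwise
# outcomes and gene selections.

#' One-sided Wilcoxon rank-sum p-value
#'
#' Directional rank-sum test of H0: mu_x = mu_y against the chosen shift
#' alternative. The exact tail probability is used when the pooled sample
#' holds at most 20 observations and no ties; otherwise the tie-corrected
#' normal approximation with continuity correction. Both branches are
#' deterministic. A pooled sample with all values identical carries no
#' directional evidence and returns p = 1.
#'
#' Note that \code{p_less + p_greater >= 1} always holds for this test
#' (the two tails overlap at the observed statistic), so at any level
#' alpha <= 0.5 at most one direction can be significant.
#'
#' @param x,y numeric vectors of replicate measurements, each of length
#'   >= 2, finite.
#' @param direction \code{"less"} tests H1: mu_x < mu_y, \code{"greater"}
#'   tests H1: mu_x > mu_y.
#' @return p-value in [0, 1].
#' @examples
#' wilcoxonOneSided(1:5, 6:10, "less")   # 1/252
#' @export
wilcoxonOneSided <- function(x, y, direction = c("less", "greater")) {
    direction <- match.arg(direction)
    x <- as.numeric(x); y <- as.numeric(y)
    if (length(x) < 2L || length(y) < 2L)
        stop("each group needs at least 2 observations")
    if (!all(is.finite(x)) || !all(is.finite(y)))
        stop("measurements must be finite")
    pooled <- c(x, y)
    if (length(unique(pooled)) == 1L)
        return(1)
    useExact <- length(pooled) <= 20L && !anyDuplicated(pooled)
    res <- suppressWarnings(
        wilcox.test(x, y, alternative = direction, exact = useExact,
                    correct = TRUE))
    unname(res$p.value)
}

# Both one-sided p-values for one pair.
pairPValuePair <- function(x, y) {
    c(p_less = wilcoxonOneSided(x, y, "less"),
      p_greater = wilcoxonOneSided(x, y, "greater"))
}

#' Directional p-values for every treatment pair
#'
#' Computes both one-sided rank-sum p-values for each of the
#' \code{choose(K, 2)} unordered pairs of treatment groups, in canonical
#' pair order. This table is the sufficient input for the fixed-level
#' pattern call and the ladder search: re-thresholding it at different
#' levels requires no re-testing.
#'
#' @param samples named list of numeric replicate vectors, one per
#'   treatment group, in canonical label order.
#' @return data.frame with columns \code{first}, \code{second},
#'   \code{p_less} (H1: first < second) and \code{p_greater}.
#' @examples
#' pairPValues(list(A = 1:5, B = 6:10, C = 11:15))
#' @export
pairPValues <- function(samples) {
    labels <- names(samples)
    if (is.null(labels) || anyDuplicated(labels))
        stop("samples must be a named list with unique treatment labels")
    if (length(samples) < 2L)
        stop("need at least 2 treatment groups")
    pi <- pairIndices(length(samples))
    res <- t(apply(pi, 1L, function(rw)
        pairPValuePair(samples[[rw[1L]]], samples[[rw[2L]]])))
    data.frame(first = labels[pi[, 1L]], second = labels[pi[, 2L]],
               p_less = res[, 1L], p_greater = res[, 2L],
               stringsAsFactors = FALSE)
}

#' Ternary outcome of one pairwise comparison
#'
#' Resolves the comparison of two treatment groups at significance level
#' alpha: \code{"first_less"} if the p-value for H1: mu_x < mu_y is at
#' most alpha, \code{"second_less"} if the opposite tail is, and
#' \code{"tie"} otherwise. Significance is inclusive (p <= alpha) so that
#' candidate levels taken from observed p-values are attainable. At
#' alpha <= 0.5 at most one strict direction can fire because the two
#' one-sided p-values sum to at least 1.
#'
#' @param x,y replicate vectors (first and second group of the pair).
#' @param alpha significance level in (0, 1).
#' @return list with \code{p_less}, \code{p_greater}, and \code{outcome}
#'   (one of \code{"first_less"}, \code{"second_less"}, \code{"tie"}).
#' @examples
#' pairOutcome(1:5, 6:10, 0.05)$outcome   # "first_less"
#' @export
pairOutcome <- function(x, y, alpha = 0.05) {
    if (!(alpha > 0 && alpha < 1))
        stop("alpha must be in (0, 1)")
    p <- pairPValuePair(x, y)
    outcome <- if (p[["p_less"]] <= alpha) "first_less"
        else if (p[["p_greater"]] <= alpha) "second_less"
        else "tie"
    list(p_less = p[["p_less"]], p_greater = p[["p_greater"]],
         outcome = outcome)
}

#' Kruskal-Wallis p-value across treatment groups
#'
#' Tie-corrected Kruskal-Wallis rank test with chi-square reference
#' (df = number of groups - 1). A degenerate input in which every pooled
#' value is identical carries no evidence and returns p = 1 rather than
#' erroring, so constant genes are silently never selected.
#'
#' @param groups list of >= 2 numeric vectors, each of length >= 2.
#' @return p-value in [0, 1].
#' @examples
#' kruskalWallis(list(1:5, 6:10, 11:15))
#' @export
kruskalWallis <- function(groups) {
    if (!is.list(groups) || length(groups) < 2L)
        stop("need at least 2 treatment groups")
    if (any(lengths(groups) < 2L))
        stop("each group needs at least 2 observations")
    values <- unlist(groups, use.names = FALSE)
    if (!all(is.finite(values)))
        stop("measurements must be finite")
    if (length(unique(values)) == 1L)
        return(1)
    g <- factor(rep(seq_along(groups), lengths(groups)))
    unname(kruskal.test(values, g)$p.value)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; a thin validated front over
#' \code{\link[stats]{p.adjust}(method = "BH")}.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bhAdjust <- function(pvalues) {
    pvalues <- as.numeric(pvalues)
    if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
        stop("p-values must lie in [0, 1]")
    p.adjust(pvalues, method = "BH")
}

#' Select differentially expressed genes
#'
#' Screens every gene of an experiment with the Kruskal-Wallis test across
#' its treatment groups and keeps genes significant at \code{level},
#' optionally after Benjamini-Hochberg adjustment. Genes with missing
#' values are excluded with a warning; input gene order is preserved.
#'
#' @param experiment an \linkS4class{OrderExperiment}.
#' @param level significance threshold (default 0.05).
#' @param useFdr apply BH adjustment before thresholding (default FALSE).
#' @return character vector of selected gene identifiers.
#' @examples
#' sim <- simulateExperiment(nGenes = 5, delta = 6, seed = 1)
#' selectGenes(sim$experiment)
#' @export
selectGenes <- function(experiment, level = 0.05, useFdr = FALSE) {
    stopifnot(is(experiment, "OrderExperiment"))
    if (!(level > 0 && level <= 1))
        stop("level must be in (0, 1]")
    mat <- SummarizedExperiment::assay(experiment)
    grp <- SummarizedExperiment::colData(experiment)$group
    genes <- rownames(mat)
    complete <- !apply(mat, 1L, anyNA)
    if (any(!complete))
        warning(sprintf("excluding %d gene(s) with missing values",
                        sum(!complete)))
    keep <- genes[complete]
    pv <- vapply(keep, function(g)
        kruskalWallis(split(mat[g, ], grp)), numeric(1))
    if (useFdr)
        pv <- bhAdjust(pv)
    keep[pv <= level]
}
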