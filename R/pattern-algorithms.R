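# Pattern-calling algorithms: fixed-level pattern, varying-level
# orderable-pattern ladder search, and bootstrap multi-pattern assignment.

#' Algorithm configuration
#'
#' Builds a validated \linkS4class{AlgoConfig}. Defaults: base level 0.05,
#' ladder cap 0.5, 1000 bootstrap iterations, ladder search inside the
#' bootstrap, tie-consistency as the orderability predicate, reporting
#' cutoff 0.05 on bootstrap frequencies, ladder scanned from its smallest
#' candidate (extension mode off).
#'
#' @param alpha base significance level in (0, 1).
#' @param alphaMax largest candidate level the ladder search may use;
#'   values above 0.5 trigger a warning, as both strict directions can
#'   then fire for one pair.
#' @param M bootstrap iterations.
#' @param innerMethod \code{"varying"} or \code{"fixed"}: pattern call
#'   applied to each bootstrap replicate.
#' @param predicate orderability predicate (see [isOrderable()]).
#' @param seed integer RNG seed, or NA to leave the RNG alone.
#' @param fMin minimum frequency for a reported bootstrap pattern record.
#' @param extensionMode restrict ladder candidates to levels >= alpha, so
#'   the search result is always an orderable extension of the base
#'   pattern.
#' @return An \linkS4class{AlgoConfig}.
#' @examples
#' algoConfig(M = 200, seed = 1)
#' @export
algoConfig <- function(alpha = 0.05, alphaMax = 0.5, M = 1000L,
                       innerMethod = c("varying", "fixed"),
                       predicate = c("tie-consistent", "delta-free",
                                     "weak-order"),
                       seed = NA_integer_, fMin = 0.05,
                       extensionMode = FALSE) {
    if (alphaMax > 0.5)
        warning("alphaMax above 0.5: both strict directions can be ",
                "significant for one pair; first-less takes precedence")
    new("AlgoConfig", alpha = alpha, alphaMax = alphaMax,
        M = as.integer(M), innerMethod = match.arg(innerMethod),
        predicate = match.arg(predicate), seed = as.integer(seed),
        fMin = fMin, extensionMode = extensionMode)
}

setMethod("show", "AlgoConfig", function(object) {
    cat(sprintf(paste0(
        "AlgoConfig: alpha=%g alphaMax=%g M=%d inner=%s predicate=%s ",
        "fMin=%g extensionMode=%s seed=%s\n"),
        object@alpha, object@alphaMax, object@M, object@innerMethod,
        object@predicate, object@fMin, object@extensionMode,
        ifelse(is.na(object@seed), "none", object@seed)))
})

#' Threshold a directional p-value table into a pattern
#'
#' For each pair: strict first-less when \code{p_less <= alpha}, strict
#' second-less when \code{p_greater <= alpha}, tie otherwise (first-less
#' checked first; at alpha <= 0.5 the two can never both fire).
#'
#' @param pvals data.frame as returned by [pairPValues()] (canonical pair
#'   order).
#' @param labels treatment labels in canonical order.
#' @param alpha significance level in (0, 1).
#' @return A \linkS4class{Pattern}.
#' @examples
#' pv <- data.frame(first = c("A", "A", "B"), second = c("B", "C", "C"),
#'                  p_less = c(0.4, 0.01, 0.02),
#'                  p_greater = c(0.7, 0.99, 0.98))
#' patternCode(patternAtAlpha(pv, c("A", "B", "C"), 0.05))   # "011"
#' @export
patternAtAlpha <- function(pvals, labels, alpha) {
    if (!(alpha > 0 && alpha < 1))
        stop("alpha must be in (0, 1)")
    rel <- ifelse(pvals$p_less <= alpha, 1L,
                  ifelse(pvals$p_greater <= alpha, 2L, 0L))
    Pattern(labels, rel)
}

#' Fixed-level pattern of one gene
#'
#' Applies the directional pairwise test to every pair of treatment
#' groups at a single significance level and assembles the resulting
#' ternary outcomes into the gene's pattern.
#'
#' @param samples named list of replicate vectors, one per treatment
#'   group, in canonical label order.
#' @param alpha significance level (default 0.05).
#' @return A \linkS4class{Pattern}.
#' @examples
#' patternFixedAlpha(list(A = 1:5, B = 2:6, C = 11:15), alpha = 0.05)
#' @export
patternFixedAlpha <- function(samples, alpha = 0.05) {
    patternAtAlpha(pairPValues(samples), names(samples), alpha)
}

#' Candidate significance ladder
#'
#' The sorted unique values of \code{min(p_less, p_greater)} over all
#' pairs: exactly the levels at which thresholding the p-value table can
#' change the pattern. Only candidates at or below \code{alphaMax} are
#' returned; the result is strictly increasing and possibly empty.
#'
#' @param pvals directional p-value table from [pairPValues()], or a
#'   named list of replicate vectors (converted via [pairPValues()]).
#' @param alphaMax ladder cap (default 0.5).
#' @return increasing numeric vector of candidate levels.
#' @examples
#' alphaLadder(list(A = 1:5, B = 6:10, C = 3:7))
#' @export
alphaLadder <- function(pvals, alphaMax = 0.5) {
    if (is.list(pvals) && !is.data.frame(pvals))
        pvals <- pairPValues(pvals)
    cand <- sort(unique(pmin(pvals$p_less, pvals$p_greater)))
    cand[cand <= alphaMax]
}

# Ladder search on a precomputed p-value table. Returns
# list(pattern = Pattern or NULL, alphaUsed = numeric or NA).
searchOrderableFromPValues <- function(pvals, labels, config) {
    nonTrivialOrderable <- function(P)
        strictCount(P) >= 1L && isOrderable(P, config@predicate)
    if (config@extensionMode) {
        base <- patternAtAlpha(pvals, labels, config@alpha)
        if (nonTrivialOrderable(base))
            return(list(pattern = base, alphaUsed = config@alpha))
        cand <- alphaLadder(pvals, config@alphaMax)
        cand <- cand[cand >= config@alpha]
    } else {
        cand <- alphaLadder(pvals, config@alphaMax)
    }
    for (a in cand) {
        P <- patternAtAlpha(pvals, labels, a)
        if (nonTrivialOrderable(P))
            return(list(pattern = P, alphaUsed = a))
    }
    list(pattern = NULL, alphaUsed = NA_real_)
}

#' Varying-level search for an orderable pattern
#'
#' Scans the candidate significance ladder of a gene in increasing order
#' and returns the pattern at the first level that is orderable (under
#' the configured predicate) and non-trivial (at least one strict
#' outcome), together with the level used. When no candidate at or below
#' \code{alphaMax} qualifies, failure is returned as a value
#' (\code{pattern = NULL}), not an error. With
#' \code{extensionMode = TRUE} the base pattern at \code{alpha} is tried
#' first and only candidates at or above \code{alpha} are scanned, so any
#' result is an orderable extension of the base pattern.
#'
#' @param samples named list of replicate vectors per treatment group.
#' @param config an \linkS4class{AlgoConfig}.
#' @return list with elements \code{pattern} (\linkS4class{Pattern} or
#'   \code{NULL}) and \code{alphaUsed} (numeric or NA).
#' @examples
#' res <- orderablePatternVaryingAlpha(
#'     list(A = 1:5, B = 2:6, C = 11:15), algoConfig())
#' res$alphaUsed
#' @export
orderablePatternVaryingAlpha <- function(samples, config = algoConfig()) {
    stopifnot(is(config, "AlgoConfig"))
    searchOrderableFromPValues(pairPValues(samples), names(samples), config)
}

# Deterministic per-gene seed derived from a root seed and gene index;
# kept below 2^31 - 1.
deriveSeed <- function(seed, index) {
    if (is.na(seed))
        return(NA_integer_)
    as.integer((as.double(seed) + 7919 * as.double(index)) %% 2147483647)
}

#' Bootstrap multi-pattern assignment for one gene
#'
#' When the base pattern at \code{alpha} is already orderable it is
#' returned alone with frequency 1 and no resampling. Otherwise every
#' treatment group involved in at least one tie of the base pattern is
#' resampled with replacement M times (groups involved only in strict
#' outcomes keep their original replicates), a pattern is called on each
#' replicate set by the configured inner method, and the distinct
#' patterns are returned with their bootstrap frequencies. Iterations in
#' which the ladder search fails contribute a "no-pattern" record
#' (\code{pattern_code} NA) so that frequencies always sum to 1 over M.
#'
#' @param samples named list of replicate vectors per treatment group.
#' @param config an \linkS4class{AlgoConfig}; \code{config@seed} (when not
#'   NA) makes the assignment reproducible.
#' @param gene gene identifier stored in the result.
#' @return A \linkS4class{PatternAssignment}. Use [patternRecords()] to
#'   retrieve records, filtered at \code{config@fMin} or raw.
#' @examples
#' pa <- multiplePatternsBootstrap(
#'     list(A = 1:5, B = 6:10, C = 11:15),
#'     algoConfig(M = 50, seed = 1))
#' patternRecords(pa)
#' @export
multiplePatternsBootstrap <- function(samples, config = algoConfig(),
                                      gene = "gene") {
    stopifnot(is(config, "AlgoConfig"))
    labels <- names(samples)
    pv <- pairPValues(samples)
    base <- patternAtAlpha(pv, labels, config@alpha)
    if (isOrderable(base, config@predicate)) {
        rec <- data.frame(pattern_code = patternCode(base), frequency = 1,
                          alpha_used = config@alpha, orderable = TRUE,
                          stringsAsFactors = FALSE)
        return(new("PatternAssignment", gene = gene, labels = labels,
                   records = rec, method = "base"))
    }
    m <- relationMatrix(base)
    tie <- m == 0L & t(m) == 0L
    diag(tie) <- FALSE
    resample <- which(rowSums(tie) > 0L)
    if (!is.na(config@seed))
        set.seed(config@seed)
    codes <- character(config@M)
    alphas <- numeric(config@M)
    boot <- samples
    for (k in seq_len(config@M)) {
        for (i in resample) {
            v <- samples[[i]]
            boot[[i]] <- v[sample.int(length(v), length(v), replace = TRUE)]
        }
        pvk <- pairPValues(boot)
        if (config@innerMethod == "fixed") {
            Pk <- patternAtAlpha(pvk, labels, config@alpha)
            codes[k] <- patternCode(Pk)
            alphas[k] <- config@alpha
        } else {
            res <- searchOrderableFromPValues(pvk, labels, config)
            if (is.null(res$pattern)) {
                codes[k] <- NA_character_
                alphas[k] <- NA_real_
            } else {
                codes[k] <- patternCode(res$pattern)
                alphas[k] <- res$alphaUsed
            }
        }
    }
    uniq <- unique(codes)
    rec <- do.call(rbind, lapply(uniq, function(cd) {
        sel <- if (is.na(cd)) is.na(codes) else !is.na(codes) & codes == cd
        a <- alphas[sel]
        a <- a[!is.na(a)]
        data.frame(
            pattern_code = cd,
            frequency = sum(sel) / config@M,
            # modal level among the iterations producing this pattern
            alpha_used = if (length(a))
                as.numeric(names(sort(table(a), decreasing = TRUE))[1L])
                else NA_real_,
            orderable = if (is.na(cd)) FALSE else
                isOrderable(patternFromCode(cd, labels), config@predicate),
            stringsAsFactors = FALSE)
    }))
    rec <- rec[order(-rec$frequency, rec$pattern_code), , drop = FALSE]
    rownames(rec) <- NULL
    new("PatternAssignment", gene = gene, labels = labels, records = rec,
        method = "bootstrap")
}

#' @rdname patternRecords
#' @export
setGeneric("patternRecords",
    function(object, ...) standardGeneric("patternRecords"))

#' Records of a pattern assignment
#'
#' @param object a \linkS4class{PatternAssignment}.
#' @param minFrequency drop records below this bootstrap frequency
#'   (default 0: return all, including the NA-coded "no-pattern" mass).
#' @param ... unused.
#' @return data.frame with columns \code{pattern_code}, \code{frequency},
#'   \code{alpha_used}, \code{orderable}.
#' @aliases patternRecords
#' @export
setMethod("patternRecords", "PatternAssignment",
    function(object, minFrequency = 0, ...) {
        rec <- object@records
        rec[rec$frequency >= minFrequency, , drop = FALSE]
    })

setMethod("show", "PatternAssignment", function(object) {
    cat(sprintf("PatternAssignment for gene '%s' (%s method)\n",
                object@gene, object@method))
    print(object@records)
})
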